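#' Default pipeline configuration
#'
#' Every stage threshold defaults to the value documented in the stage's own
#' help page; the simulation defaults are the desk-scale recovery world
#' (10 Mb genome, 0.2x coverage, 101 bp pairs, the [default_family_specs()]
#' satellitome).
#'
#' @param ... named overrides.
#' @return named list (class `run_config`).
#' @export
default_config <- function(...) {
  cfg <- list(
    species_code = "Sim",
    genome_size = 1e7,
    coverage = 0.2,
    read_length = 101L,
    insert_mean = 300L,
    error_rate = 0.005,
    master_seed = 1L,
    n_pairs = NA,             # optional cap on pairs entering the analysis
    min_read_length = NA,     # clean_reads default: half the read length
    max_n = 0L,
    cluster_k = 21L,
    min_shared = 10L,
    min_abundance = 0.001,
    detect_k = 15L,
    circularity = 0.5,
    dedupe_identity = 80,
    min_aligned = 30,
    max_divergence = 35,
    match_identity = 78.5,
    match_aligned_fraction = 0.8,
    ratio_threshold = 10,
    absence_floor = 0.001,
    two_samples = TRUE)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as flat key=value text
#'
#' Lossless round trip for every scalar field.
#'
#' @param config a `run_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  vals <- vapply(config, function(v)
    format(v, scientific = FALSE, trim = TRUE), character(1))
  writeLines(paste0(names(config), "=", vals), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  keys <- sub("=.*$", "", lines)
  vals <- sub("^[^=]*=", "", lines)
  base <- default_config()
  out <- lapply(seq_along(keys), function(i) {
    v <- vals[i]
    proto <- base[[keys[i]]]
    if (is.null(proto) || is.character(proto)) return(v)
    if (is.logical(proto)) return(as.logical(v))
    if (is.integer(proto)) return(as.integer(v))
    suppressWarnings(num <- as.numeric(v))
    if (is.na(num) && v != "NA") v else num
  })
  names(out) <- keys
  cfg <- base
  cfg[names(out)] <- out
  structure(cfg, class = "run_config")
}

stop_stage <- function(stage, code, msg, ...) {
  stop(errorCondition(sprintf("[stage %s / %s] %s", stage, code,
                              sprintf(msg, ...)),
                      stage = stage, code = code,
                      class = c("satkit_pipeline_error", "satkit_error")))
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose)
    message(format(Sys.time(), "%H:%M:%S "), sprintf(fmt, ...))
}

#' Run the full satellitome pipeline on simulated samples
#'
#' Orchestrates simulate -> prep -> cluster -> detect -> catalog -> quantify
#' -> compare as one reproducible run: all stage outputs are written under
#' `out_dir` and a manifest records per-stage outputs, file digests, seeds and
#' wall-clock. Identical config + master seed reproduce identical TSV digests.
#'
#' Discovery (clustering + tandem detection) runs on the reference (male)
#' sample; both samples are then quantified against the resulting catalog and
#' compared for sex-biased abundance.
#'
#' @param config a `run_config` (see [default_config()]).
#' @param out_dir output directory (created).
#' @param specs family specs to plant; default [default_family_specs()]
#'   derived from the master seed.
#' @param verbose log each stage with its effective thresholds.
#' @return (invisibly) list with `catalog`, `truth`, `read_sets`,
#'   `clusters`, `candidates`, `abundance`, `divergence`, `landscape`,
#'   `sex_bias`, `coverage`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("satkit_run_"),
                         specs = NULL, verbose = FALSE) {
  t_all <- proc.time()[["elapsed"]]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, files, t0) {
    manifest[[length(manifest) + 1L]] <<- data.table::data.table(
      stage = stage, file = files,
      md5 = unname(tools::md5sum(files)),
      seconds = round(proc.time()[["elapsed"]] - t0, 2))
  }
  seed <- config$master_seed
  samples <- if (isTRUE(config$two_samples)) c("male", "female") else "male"

  ## simulate -----------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  if (is.null(specs)) specs <- default_family_specs(derive_seed(seed, 3L))
  decoys <- attr(specs, "decoys")
  genomes <- list(); read_sets <- list(); truth <- list()
  for (sx in samples) {
    g <- tryCatch(
      build_genome(specs, config$genome_size, sex = sx,
                   seed = derive_seed(seed, 10L), decoys = decoys),
      error = function(e) stop_stage("simulate", "build_genome", conditionMessage(e)))
    rs <- sample_reads(g$template, config$coverage, config$read_length,
                       config$insert_mean, config$error_rate,
                       seed = derive_seed(seed, 20L + match(sx, samples)))
    genomes[[sx]] <- g$template
    truth[[sx]] <- g$truth
    read_sets[[sx]] <- rs
    write_truth_tsv(g$truth, file.path(out_dir, paste0("truth_", sx, ".tsv")))
    write_template_bed(g$template, file.path(out_dir, paste0("template_", sx, ".bed")))
    write_read_fastq(rs, file.path(out_dir, paste0("reads_", sx)))
  }
  note("simulate", file.path(out_dir, c(paste0("truth_", samples, ".tsv"),
                                        paste0("template_", samples, ".bed"))), t0)
  pipeline_log(verbose, "simulate: %s bp genome, %.2fx coverage, %d families",
               format(config$genome_size, big.mark = ","), config$coverage,
               length(specs))

  ## prep ---------------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  coverage <- list()
  for (sx in samples) {
    if (!is.na(config$n_pairs) && config$n_pairs <= 0)
      stop_stage("prep", "empty_read_set", "n_pairs is %s", config$n_pairs)
    rs <- clean_reads(read_sets[[sx]],
                      min_length = if (is.na(config$min_read_length)) NULL
                                   else config$min_read_length,
                      max_n = config$max_n)
    if (!is.na(config$n_pairs) && config$n_pairs < n_pairs(rs))
      rs <- subsample_pairs(rs, config$n_pairs,
                            seed = derive_seed(seed, 30L + match(sx, samples)))
    if (n_pairs(rs) == 0)
      stop_stage("prep", "empty_read_set", "no read pairs left after cleaning")
    read_sets[[sx]] <- rs
    coverage[[sx]] <- coverage_report(rs$total_bases, config$genome_size)
    write_interleaved_fasta(rs, file.path(out_dir, paste0("reads_", sx, ".fasta")))
  }
  cov_tab <- data.table::rbindlist(lapply(samples, function(sx)
    data.table::data.table(sample = sx,
                           analysed_bases = coverage[[sx]]$analysed_bases,
                           genome_size = coverage[[sx]]$genome_size,
                           coverage = coverage[[sx]]$coverage,
                           coverage_display = coverage[[sx]]$coverage_display,
                           in_range = coverage[[sx]]$in_range)))
  data.table::fwrite(cov_tab, file.path(out_dir, "coverage.tsv"), sep = "\t")
  note("prep", file.path(out_dir, "coverage.tsv"), t0)
  pipeline_log(verbose, "prep: %s", paste(sprintf("%s=%sx", samples,
    vapply(coverage, `[[`, character(1), "coverage_display")), collapse = " "))

  ## cluster (reference sample) -----------------------------------------
  t0 <- proc.time()[["elapsed"]]
  ref_sample <- samples[1]
  il <- interleaved_reads(read_sets[[ref_sample]])
  graph <- tryCatch(
    build_read_graph(il, k = config$cluster_k, min_shared = config$min_shared),
    error = function(e) stop_stage("cluster", "graph", conditionMessage(e)))
  clusters <- filter_clusters(cluster_reads(graph),
                              min_abundance = config$min_abundance)
  write_clusters_tsv(clusters, file.path(out_dir, "clusters.tsv"))
  note("cluster", file.path(out_dir, "clusters.tsv"), t0)
  pipeline_log(verbose, "cluster: k=%d min_shared=%d min_abundance=%g%% -> %d clusters",
               config$cluster_k, config$min_shared, config$min_abundance,
               length(clusters$members))

  ## detect --------------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  candidates <- detect_satellites(clusters, il, k = config$detect_k,
                                  circularity_min = config$circularity)
  write_candidates(candidates, file.path(out_dir, "candidates.tsv"),
                   file.path(out_dir, "monomers.fasta"))
  note("detect", file.path(out_dir, c("candidates.tsv", "monomers.fasta")), t0)
  pipeline_log(verbose, "detect: k=%d circularity>=%.2f -> %d candidates",
               config$detect_k, config$circularity, length(candidates))

  ## catalog + quantify ---------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  fams <- dedupe_candidates(candidates, min_identity = config$dedupe_identity)
  if (length(fams) == 0)
    stop_stage("catalog", "no_families", "no satellite families detected")
  refs <- lapply(seq_along(fams), function(i)
    build_reference(fams[[i]]$consensus, sprintf("fam%03d", i)))
  hits_by_sample <- list(); gp_by_sample <- list()
  for (sx in samples) {
    hits_by_sample[[sx]] <- mask_reads(read_sets[[sx]], refs,
                                       min_aligned = config$min_aligned,
                                       max_divergence = config$max_divergence)
    gp_by_sample[[sx]] <- genome_proportion(hits_by_sample[[sx]],
      families = vapply(refs, `[[`, character(1), "name"))
  }
  for (i in seq_along(fams)) {
    fams[[i]]$per_sample_abundance <- vapply(samples, function(sx) {
      gp <- gp_by_sample[[sx]]
      gp$percent[gp$family == refs[[i]]$name]
    }, numeric(1))
  }
  catalog <- rank_and_name(fams, config$species_code, ref_sample)
  # map provisional reference names to final family names via the consensus
  tmp2final <- setNames(
    catalog$families$name[match(vapply(fams, `[[`, character(1), "consensus"),
                                catalog$families$consensus)],
    vapply(refs, `[[`, character(1), "name"))
  abundance <- list(); divergence <- list(); landscape <- list()
  for (sx in samples) {
    h <- hits_by_sample[[sx]]
    h[, family := tmp2final[family]]
    hits_by_sample[[sx]] <- h
    gp <- genome_proportion(h, families = catalog$families$name)
    abundance[[sx]] <- data.table::data.table(name = gp$family, sample = sx,
                                              percent = gp$percent)
    divergence[[sx]] <- divergence_stats(h, sample = sx)
    ls <- build_landscape(h)
    ls[, sample := sx]
    landscape[[sx]] <- ls
  }
  abundance <- data.table::rbindlist(abundance)
  divergence <- data.table::rbindlist(divergence)
  landscape <- data.table::rbindlist(landscape)
  catalog$abundance <- abundance[!abundance$name %in% c("ALL", "unmasked"), ]
  write_catalog_fasta(catalog, file.path(out_dir, "catalog.fasta"))
  write_catalog_tsv(catalog, file.path(out_dir, "catalog.tsv"),
                    divergence = divergence)
  data.table::fwrite(abundance, file.path(out_dir, "abundance.tsv"), sep = "\t")
  data.table::fwrite(landscape, file.path(out_dir, "landscape.tsv"), sep = "\t")
  note("catalog", file.path(out_dir, c("catalog.fasta", "catalog.tsv")), t0)
  note("quantify", file.path(out_dir, c("abundance.tsv", "landscape.tsv")), t0)
  pipeline_log(verbose, "catalog: %d families (dedupe>=%g%%), masking min_aligned=%g max_div=%g%%",
               nrow(catalog$families), config$dedupe_identity,
               config$min_aligned, config$max_divergence)

  ## compare --------------------------------------------------------------
  sex_bias <- NULL
  if (length(samples) == 2) {
    t0 <- proc.time()[["elapsed"]]
    wide <- presence_matrix(catalog$abundance)
    ab2 <- data.frame(family = wide$name,
                      male = wide[["male"]] %||% 0,
                      female = wide[["female"]] %||% 0)
    sex_bias <- flag_sex_biased(ab2, ratio_threshold = config$ratio_threshold,
                                absence_floor = config$absence_floor)
    data.table::fwrite(sex_bias, file.path(out_dir, "sex_bias.tsv"), sep = "\t")
    data.table::fwrite(wide, file.path(out_dir, "presence_matrix.tsv"), sep = "\t")
    note("compare", file.path(out_dir, c("sex_bias.tsv", "presence_matrix.tsv")), t0)
    pipeline_log(verbose, "compare: ratio_threshold=%g absence_floor=%g%% -> %d Y candidates",
                 config$ratio_threshold, config$absence_floor,
                 sum(sex_bias$y_linked_candidate))
  }
  manifest <- data.table::rbindlist(manifest)
  data.table::fwrite(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t")
  pipeline_log(verbose, "done in %.1f s", proc.time()[["elapsed"]] - t_all)
  invisible(list(catalog = catalog, truth = truth, read_sets = read_sets,
                 segments = lapply(genomes, `[[`, "segments"),
                 clusters = clusters, candidates = candidates,
                 hits = hits_by_sample, abundance = abundance,
                 divergence = divergence, landscape = landscape,
                 sex_bias = sex_bias, coverage = coverage,
                 manifest = manifest, out_dir = out_dir))
}
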