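#' Specification of a planted satellite DNA family
#'
#' Describes one satDNA family for the genome simulator: its monomer, the
#' fraction of the genome it should occupy, how diverged individual copies are
#' from the consensus, and the genomic compartment that dictates array
#' placement (cosmetic) and sex restriction (Y-linked families are only
#' emitted into male genomes).
#'
#' @param family_id label for the family.
#' @param monomer consensus monomer sequence (>= 2 bases, ACGT).
#' @param target_proportion fraction of the genome occupied by the family
#'   (0-1); all specs of one genome must sum to <= 0.9.
#' @param divergence_rate expected per-base substitution rate of copies
#'   relative to the consensus (0-0.35).
#' @param ts_tv_ratio transition:transversion ratio of the substitutions.
#' @param compartment one of `"autosomal_heterochromatin"`, `"y_linked"`,
#'   `"euchromatic_dispersed"`.
#' @param n_arrays number of tandem arrays the copies are split into.
#' @return an object of class `sat_family_spec`.
#' @export
sat_family_spec <- function(family_id, monomer, target_proportion,
                            divergence_rate = 0, ts_tv_ratio = 2,
                            compartment = c("autosomal_heterochromatin",
                                            "y_linked", "euchromatic_dispersed"),
                            n_arrays = 2L) {
  compartment <- match.arg(compartment)
  monomer <- toupper(monomer)
  if (nchar(monomer) < 2) stop_invalid("monomer length must be >= 2")
  if (!grepl("^[ACGT]+$", monomer)) stop_invalid("monomer must be ACGT only")
  if (target_proportion <= 0 || target_proportion > 0.9)
    stop_invalid("target_proportion must be in (0, 0.9]")
  if (divergence_rate < 0 || divergence_rate > 0.35)
    stop_invalid("divergence_rate must be in [0, 0.35]")
  if (ts_tv_ratio <= 0) stop_invalid("ts_tv_ratio must be positive")
  if (n_arrays < 1) stop_invalid("n_arrays must be >= 1")
  structure(list(family_id = as.character(family_id), monomer = monomer,
                 target_proportion = target_proportion,
                 divergence_rate = divergence_rate,
                 ts_tv_ratio = ts_tv_ratio, compartment = compartment,
                 n_arrays = as.integer(n_arrays)),
            class = "sat_family_spec")
}

#' Specification of a dispersed TE-like decoy repeat
#'
#' Decoys are full-length interspersed copies of a non-tandem element; their
#' clusters must *not* be called satellites downstream.
#'
#' @param decoy_id label.
#' @param length element length in bases.
#' @param proportion fraction of the genome occupied.
#' @param divergence per-base substitution rate of copies vs the element.
#' @param ts_tv_ratio transition:transversion ratio.
#' @export
te_decoy_spec <- function(decoy_id, length = 1500L, proportion = 0.01,
                          divergence = 0.03, ts_tv_ratio = 2) {
  structure(list(decoy_id = as.character(decoy_id), length = as.integer(length),
                 proportion = proportion, divergence = divergence,
                 ts_tv_ratio = ts_tv_ratio),
            class = "te_decoy_spec")
}

# substitute bases in a character vector of single bases; per-base independent,
# transition:transversion mix per ts_tv_ratio; returns list(chars, n_sub)
mutate_chars <- function(chars, rate, ts_tv) {
  n <- length(chars)
  if (rate <= 0 || n == 0) return(list(chars = chars, n_sub = 0L))
  n_sub <- rbinom(1L, n, rate)
  if (n_sub == 0L) return(list(chars = chars, n_sub = 0L))
  pos <- sample.int(n, n_sub)
  is_ts <- runif(n_sub) < ts_tv / (ts_tv + 1)
  old <- chars[pos]
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  tv1 <- c(A = "C", G = "C", C = "A", T = "A")
  tv2 <- c(A = "T", G = "T", C = "G", T = "G")
  pick2 <- runif(n_sub) < 0.5
  new <- ifelse(is_ts, transition[old], ifelse(pick2, tv1[old], tv2[old]))
  chars[pos] <- unname(new)
  list(chars = chars, n_sub = n_sub)
}

# mutate a whole array string; per-base substitution == per-copy independent
# substitution since positions are independent
mutate_string <- function(s, rate, ts_tv) {
  m <- mutate_chars(strsplit(s, "", fixed = TRUE)[[1]], rate, ts_tv)
  list(seq = paste0(m$chars, collapse = ""), n_sub = m$n_sub)
}

#' Generate a random satellite monomer
#'
#' Bases are drawn i.i.d. with P(A) = P(T) = at_content/2.
#'
#' @param length monomer length in bases (2-2000).
#' @param at_content expected A+T fraction, in (0, 1) exclusive.
#' @param seed RNG seed.
#' @return a DNA string of the requested length.
#' @export
generate_monomer <- function(length, at_content, seed) {
  if (length < 2 || length > 2000) stop_invalid("length must be in [2, 2000]")
  if (at_content <= 0 || at_content >= 1)
    stop_invalid("at_content must be in (0, 1) exclusive")
  with_seed(seed, random_dna(length, at_content))
}

# TRUE when the monomer is primitive (not a power of a shorter string) and all
# its cyclic k-mers are distinct, so the de Bruijn ring has exactly rul nodes
monomer_is_clean <- function(monomer, k = 15L) {
  L <- nchar(monomer)
  for (p in seq_len(L - 1)) {
    if (L %% p == 0 &&
        paste0(strrep(substr(monomer, 1, p), L / p)) == monomer) return(FALSE)
  }
  kk <- min(k, L + 1L)  # k > L always yields distinct k-mers for primitive monomers
  if (L >= kk) {
    doubled <- strrep(monomer, 2)
    kmers <- substring(doubled, seq_len(L), seq_len(L) + kk - 1)
    if (anyDuplicated(kmers)) return(FALSE)
  }
  TRUE
}

#' Build a simulated genome with planted satellite families
#'
#' Lays out tandem arrays of each family inside a random background genome and
#' mutates every copy independently at the family's divergence rate.
#' Heterochromatin-compartment families are placed as contiguous blocks at the
#' pseudo-chromosome ends, dispersed families as scattered arrays (placement is
#' cosmetic and does not affect downstream statistics). Y-linked families are
#' emitted only when `sex = "male"`; in female genomes their bases are replaced
#' by background so the total length and all other family base counts are
#' identical for the same seed.
#'
#' @param specs list of [sat_family_spec()] objects.
#' @param total_length genome length in bases.
#' @param sex `"male"` or `"female"`.
#' @param seed RNG seed; array content of each family is derived
#'   deterministically from it, independent of sex.
#' @param sample_id label stored in the template.
#' @param decoys optional list of [te_decoy_spec()] objects.
#' @return list with `template` (class `genome_template`: sample_id, sex,
#'   total_length, sequence, segments as 0-based half-open intervals) and
#'   `truth` (data.table: family_id, monomer, rul, compartment, bases,
#'   proportion, mean_divergence, n_copies; decoys appear with compartment
#'   `"te_decoy"`).
#' @export
build_genome <- function(specs, total_length, sex = c("male", "female"), seed,
                         sample_id = NULL, decoys = NULL) {
  sex <- match.arg(sex)
  if (inherits(specs, "sat_family_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "sat_family_spec")))
  props <- vapply(specs, `[[`, numeric(1), "target_proportion") +
    sum(vapply(decoys %||% list(), `[[`, numeric(1), "proportion"))
  if (sum(vapply(specs, `[[`, numeric(1), "target_proportion")) > 0.9)
    stop_invalid("sum of target proportions exceeds 0.9")
  max_rul <- max(vapply(specs, function(s) nchar(s$monomer), numeric(1)))
  if (total_length < 100 * max_rul)
    stop_invalid("total_length must be >= 100 x the longest monomer")
  if (is.null(sample_id)) sample_id <- paste0("sim_", sex)

  front <- list(); back <- list(); middle <- list()
  truth <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    rul <- nchar(sp$monomer)
    target_bases <- round(sp$target_proportion * total_length)
    n_copies <- max(1L, round(target_bases / rul))
    emit <- !(sp$compartment == "y_linked" && sex == "female")
    fam_seed <- derive_seed(seed, 1000L + i)
    arrays <- with_seed(fam_seed, {
      cps <- rep(n_copies %/% sp$n_arrays, sp$n_arrays)
      extra <- n_copies %% sp$n_arrays
      if (extra > 0) cps[seq_len(extra)] <- cps[seq_len(extra)] + 1L
      cps <- cps[cps > 0]
      n_sub_total <- 0L
      seqs <- character(length(cps))
      for (a in seq_along(cps)) {
        m <- mutate_string(strrep(sp$monomer, cps[a]), sp$divergence_rate,
                           sp$ts_tv_ratio)
        seqs[a] <- m$seq
        n_sub_total <- n_sub_total + m$n_sub
      }
      list(seqs = seqs, n_sub = n_sub_total, copies = cps)
    })
    fam_bases <- sum(nchar(arrays$seqs))
    if (emit) {
      blocks <- lapply(arrays$seqs, function(s) list(label = sp$family_id, seq = s))
      if (sp$compartment == "euchromatic_dispersed") {
        middle <- c(middle, blocks)
      } else {
        half <- seq_along(blocks) %% 2 == 1
        front <- c(front, blocks[half])
        back <- c(back, blocks[!half])
      }
    } else {
      # female genome: same footprint, background content
      filler <- with_seed(derive_seed(fam_seed, 1L), random_dna(fam_bases, 0.5))
      middle <- c(middle, list(list(label = "background", seq = filler)))
    }
    truth[[i]] <- data.table::data.table(
      family_id = sp$family_id, monomer = sp$monomer, rul = rul,
      compartment = sp$compartment,
      bases = if (emit) fam_bases else 0L,
      proportion = if (emit) fam_bases / total_length else 0,
      mean_divergence = if (emit) arrays$n_sub / fam_bases else NA_real_,
      n_copies = if (emit) n_copies else 0L)
  }
  for (j in seq_along(decoys %||% list())) {
    dc <- decoys[[j]]
    dc_seed <- derive_seed(seed, 5000L + j)
    element <- with_seed(dc_seed, random_dna(dc$length, 0.5))
    n_copies <- max(1L, round(dc$proportion * total_length / dc$length))
    copies <- with_seed(derive_seed(dc_seed, 1L), {
      vapply(seq_len(n_copies), function(ii)
        mutate_string(element, dc$divergence, dc$ts_tv_ratio)$seq, character(1))
    })
    middle <- c(middle, lapply(copies, function(s) list(label = dc$decoy_id, seq = s)))
    truth[[length(truth) + 1L]] <- data.table::data.table(
      family_id = dc$decoy_id, monomer = element, rul = dc$length,
      compartment = "te_decoy", bases = sum(nchar(copies)),
      proportion = sum(nchar(copies)) / total_length,
      mean_divergence = dc$divergence, n_copies = n_copies)
  }

  rep_bases <- sum(vapply(c(front, middle, back), function(b) nchar(b$seq), numeric(1)))
  bg_total <- total_length - rep_bases
  if (bg_total < 0) stop_invalid("planted repeats exceed total_length")
  layout <- with_seed(derive_seed(seed, 77L), {
    # short background spacers between adjacent terminal-heterochromatin
    # blocks: reads must not span two families' arrays in one fragment
    n_junctions <- max(0L, length(front) - 1L) + max(0L, length(back) - 1L)
    spacer <- if (n_junctions > 0) min(500L, bg_total %/% (2L * n_junctions + 2L)) else 0L
    with_spacers <- function(blocks) {
      if (length(blocks) < 2 || spacer == 0) return(blocks)
      out <- list(blocks[[1]])
      for (b in blocks[-1]) {
        out <- c(out, list(list(label = "background",
                                seq = random_dna(spacer, 0.5))), list(b))
      }
      out
    }
    front <- with_spacers(front)
    back <- with_spacers(back)
    bg_rest <- bg_total - n_junctions * spacer
    mid <- if (length(middle)) middle[sample.int(length(middle))] else list()
    n_gaps <- length(mid) + 1L
    gaps <- as.vector(rmultinom(1L, bg_rest, rep(1, n_gaps)))
    blocks <- front
    for (g in seq_len(n_gaps)) {
      if (gaps[g] > 0)
        blocks <- c(blocks, list(list(label = "background",
                                      seq = random_dna(gaps[g], 0.5))))
      if (g <= length(mid)) blocks <- c(blocks, mid[g])
    }
    c(blocks, back)
  })
  lens <- vapply(layout, function(b) nchar(b$seq), numeric(1))
  ends <- cumsum(lens)
  segments <- data.table::data.table(
    start = c(0, head(ends, -1)), end = ends,
    label = vapply(layout, `[[`, character(1), "label"))
  template <- structure(list(sample_id = sample_id, sex = sex,
                             total_length = as.numeric(total_length),
                             sequence = paste0(vapply(layout, `[[`, character(1), "seq"),
                                               collapse = ""),
                             segments = segments),
                        class = "genome_template")
  stopifnot(nchar(template$sequence) == total_length)
  list(template = template, truth = data.table::rbindlist(truth))
}

#' @export
print.genome_template <- function(x, ...) {
  cat(sprintf("genome_template '%s' (%s): %s bp, %d segments\n",
              x$sample_id, x$sex, format(x$total_length, big.mark = ","),
              nrow(x$segments)))
  invisible(x)
}

# majority-overlap segment label for 0-based half-open mate intervals
interval_origin <- function(starts0, ends0, segments) {
  seg_start <- segments$start
  i1 <- findInterval(starts0, seg_start)
  i2 <- findInterval(ends0 - 1, seg_start)
  lab <- segments$label[i1]
  mixed <- which(i1 != i2)
  for (m in mixed) {
    idx <- i1[m]:i2[m]
    ov <- pmin(segments$end[idx], ends0[m]) - pmax(segments$start[idx], starts0[m])
    lab[m] <- segments$label[idx][which.max(ov)]
  }
  lab
}

#' Sample paired-end reads from a genome template
#'
#' Fragments of constant length `insert_mean` are drawn uniformly; mate 1 is
#' the forward strand of the fragment start, mate 2 the reverse complement of
#' the fragment end. A uniform per-base substitution error is applied. Each
#' mate carries the majority-overlap origin label of its source interval so
#' downstream recovery can be scored against truth.
#'
#' @param template a `genome_template`.
#' @param coverage fold coverage of emitted bases over the template length
#'   (0 gives an empty read set; must be <= 5).
#' @param read_length read length in bases (>= 50).
#' @param insert_mean fragment length (>= 2 x read_length; held constant).
#' @param error_rate per-base sequencing error rate.
#' @param seed RNG seed.
#' @return an object of class [read_set].
#' @export
sample_reads <- function(template, coverage, read_length = 101L,
                         insert_mean = 300L, error_rate = 0.005, seed = 1L) {
  stopifnot(inherits(template, "genome_template"))
  if (coverage < 0 || coverage > 5) stop_invalid("coverage must be in [0, 5]")
  if (read_length < 50) stop_invalid("read_length must be >= 50")
  if (insert_mean < 2 * read_length)
    stop_invalid("insert_mean must be >= 2 x read_length")
  n_pairs <- round(coverage * template$total_length / (2 * read_length))
  if (n_pairs == 0)
    return(read_set(template$sample_id, character(0), character(0),
                    read_length = read_length))
  with_seed(seed, {
    starts <- sample.int(template$total_length - insert_mean + 1L, n_pairs,
                         replace = TRUE)  # 1-based fragment starts
    r1 <- substring(template$sequence, starts, starts + read_length - 1L)
    e2 <- starts + insert_mean - 1L
    r2 <- revcomp(substring(template$sequence, e2 - read_length + 1L, e2))
    add_errors <- function(reads) {
      nerr <- rbinom(length(reads), read_length, error_rate)
      for (i in which(nerr > 0)) {
        ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
        pos <- sample.int(read_length, nerr[i])
        ch[pos] <- vapply(ch[pos], function(b)
          sample(setdiff(DNA_BASES, b), 1L), character(1))
        reads[i] <- paste0(ch, collapse = "")
      }
      reads
    }
    r1 <- add_errors(r1)
    r2 <- add_errors(r2)
    o1 <- interval_origin(starts - 1, starts - 1 + read_length, template$segments)
    o2 <- interval_origin(e2 - read_length, e2, template$segments)
    read_set(template$sample_id, r1, r2, origin1 = o1, origin2 = o2,
             start1 = starts - 1L, start2 = e2 - read_length,
             read_length = read_length)
  })
}

#' Write simulation truth as TSV
#' @param truth truth table from [build_genome()].
#' @param path output file.
#' @export
write_truth_tsv <- function(truth, path) {
  data.table::fwrite(truth, path, sep = "\t")
  invisible(path)
}

#' Write a genome template's segments as BED-like TSV (0-based half-open)
#' @param template a `genome_template`.
#' @param path output file.
#' @export
write_template_bed <- function(template, path) {
  seg <- data.table::copy(template$segments)
  seg[, chrom := template$sample_id]
  data.table::setcolorder(seg, c("chrom", "start", "end", "label"))
  data.table::fwrite(seg, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Default planted satellitome used by the recovery experiments
#'
#' Eight families spanning genome proportions 10% down to 0.05%, copy-level
#' divergences 0-10%, one Y-linked 9-bp GATA-variant microsatellite, one
#' GC-rich family, plus a dispersed TE-like decoy at 1%. Large families carry
#' low divergence (recent heterochromatic amplification); the most diverged
#' family (10%) sits at 2% proportion so it is still densely sampled at low
#' coverage. Monomers are derived deterministically from `master_seed` and are
#' regenerated until primitive with distinct cyclic 15-mers.
#'
#' @param master_seed master seed the monomer sequences are derived from.
#' @return list of [sat_family_spec()]; the decoy list is attached as
#'   attribute `"decoys"`.
#' @export
default_family_specs <- function(master_seed = 20260910L) {
  tab <- data.frame(
    id   = c("SimSat_A", "SimSat_B", "SimSat_C", "SimSat_D",
             "SimSat_E", "SimSat_F", "SimSat_G", "SimSat_H"),
    rul  = c(166L, 9L, 120L, 50L, 83L, 25L, 130L, 60L),
    prop = c(0.10, 0.05, 0.02, 0.01, 0.005, 0.002, 0.001, 0.0005),
    div  = c(0.02, 0.01, 0.10, 0.05, 0.03, 0.04, 0.02, 0.00),
    at   = c(0.65, NA, 0.60, 0.70, 0.55, 0.70, 0.45, 0.65),
    comp = c("autosomal_heterochromatin", "y_linked", "euchromatic_dispersed",
             "autosomal_heterochromatin", "autosomal_heterochromatin",
             "autosomal_heterochromatin", "euchromatic_dispersed",
             "autosomal_heterochromatin"),
    n_arrays = c(8L, 4L, 40L, 6L, 4L, 4L, 10L, 2L))
  specs <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (tab$id[i] == "SimSat_B") {
      monomer <- "GATAGATTA"  # canonical Y-linked GATA-variant microsatellite
    } else {
      s <- derive_seed(master_seed, 300L + i)
      repeat {
        monomer <- generate_monomer(tab$rul[i], tab$at[i], s)
        if (monomer_is_clean(monomer)) break
        s <- s + 1L
      }
    }
    specs[[i]] <- sat_family_spec(tab$id[i], monomer, tab$prop[i], tab$div[i],
                                  ts_tv_ratio = 2, compartment = tab$comp[i],
                                  n_arrays = tab$n_arrays[i])
  }
  attr(specs, "decoys") <- list(te_decoy_spec("TEdecoy_1", length = 1500L,
                                              proportion = 0.01,
                                              divergence = 0.03))
  specs
}
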