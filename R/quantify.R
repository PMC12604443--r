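#' Build the concatenated consensus reference for a family
#'
#' Repeat units longer than 100 bp are concatenated into dimers; units of
#' 100 bp or shorter into approximately 200 bp fragments (`round(200 / rul)`
#' copies, round-half-to-even, minimum 2). At the 100 bp boundary both rules
#' coincide (2 copies, 200 bp). The concatemer guarantees that reads spanning
#' a monomer junction still align contiguously.
#'
#' @param consensus monomer sequence (rul >= 2).
#' @param name family name carried into the reference.
#' @return object of class `reference_seq`: `name`, `sequence`, `n_copies`,
#'   `rul`.
#' @export
build_reference <- function(consensus, name = "family") {
  rul <- nchar(consensus)
  if (rul < 2) stop_invalid("consensus must be >= 2 bases")
  n_copies <- if (rul > 100) 2L else max(2L, as.integer(round(200 / rul)))
  structure(list(name = name, sequence = strrep(consensus, n_copies),
                 n_copies = n_copies, rul = as.integer(rul)),
            class = "reference_seq")
}

#' Build references for every family of a catalog (in rank order)
#' @param catalog a `sat_catalog`.
#' @export
build_references <- function(catalog) {
  lapply(seq_len(nrow(catalog$families)), function(i)
    build_reference(catalog$families$consensus[i], catalog$families$name[i]))
}

#' Kimura 2-parameter divergence
#'
#' `d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))`, returned in percent. P is
#' the proportion of aligned sites showing transitions, Q transversions.
#' Outside the model's domain (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) the
#' distance is saturated: the value is `NA` and the `"saturated"` attribute is
#' set.
#'
#' @param P,Q transition / transversion proportions (vectorised; `P, Q >= 0`,
#'   `P + Q <= 1`).
#' @return numeric vector of divergences in percent with logical attribute
#'   `"saturated"`.
#' @export
k2p <- function(P, Q) {
  if (any(P < 0) || any(Q < 0)) stop_invalid("P and Q must be non-negative")
  if (any(P + Q > 1 + 1e-12)) stop_invalid("P + Q must not exceed 1")
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  saturated <- a <= 0 | b <= 0
  d <- ifelse(saturated, NA_real_, -0.5 * log(a * sqrt(b)))
  out <- 100 * d
  attr(out, "saturated") <- saturated
  out
}

#' Mask reads against concatenated consensus references
#'
#' Reads are pre-screened by shared k-mers (k = `screen_k`, per strand), then
#' locally aligned to every candidate reference on both strands; each read is
#' assigned to at most one family (best alignment score; ties broken by
#' forward strand, then catalog rank = order of `references`). The aligner is
#' ungapped (best-scoring diagonal run, match +1 / mismatch -1), matching the
#' substitution-only divergence model of the simulator; with no indel columns
#' the P/Q denominators are simply the aligned bases. Hits shorter than
#' `min_aligned` aligned bases or more diverged than `max_divergence` percent
#' K2P (or saturated) are discarded.
#'
#' @param reads a [read_set] (interleaved) or character vector of reads.
#' @param references list of `reference_seq` in catalog rank order.
#' @param min_aligned minimum aligned bases per hit (default 30).
#' @param max_divergence maximum K2P percent per hit (default 35, beyond any
#'   plausibly alignable satellite copy).
#' @param screen_k k-mer length of the pre-screen (default 13).
#' @param screen_min_hits minimum shared k-mers (per strand) for a read to be
#'   aligned at all (default 2).
#' @return data.table: `read`, `family`, `strand`, `score`, `aligned_bases`,
#'   `P`, `Q`, `k2p`, with attribute `"total_bases"` when `reads` was a
#'   `read_set`.
#' @export
mask_reads <- function(reads, references, min_aligned = 30,
                       max_divergence = 35, screen_k = 13L,
                       screen_min_hits = 2L) {
  if (length(references) == 0) stop_invalid("references must be non-empty")
  total_bases <- NULL
  if (inherits(reads, "read_set")) {
    total_bases <- reads$total_bases
    reads <- interleaved_reads(reads)
  }
  nm <- names(reads) %||% as.character(seq_along(reads))
  ref_names <- vapply(references, `[[`, character(1), "name")
  empty <- data.table::data.table(read = character(0), family = character(0),
                                  strand = character(0), score = numeric(0),
                                  aligned_bases = integer(0), P = numeric(0),
                                  Q = numeric(0), k2p = numeric(0))
  if (length(reads) == 0) {
    data.table::setattr(empty, "total_bases", total_bases)
    return(empty)
  }
  ref_seqs <- vapply(references, `[[`, character(1), "sequence")
  raw <- .cpp_mask_best_hits(unname(reads), ref_seqs, as.integer(screen_k),
                             as.integer(screen_min_hits))
  if (nrow(raw) == 0) {
    data.table::setattr(empty, "total_bases", total_bases)
    return(empty)
  }
  h <- data.table::data.table(
    read = nm[raw$read_idx], family = ref_names[raw$ref_idx],
    strand = raw$strand, score = as.numeric(raw$score),
    aligned_bases = raw$aligned_bases,
    P = raw$n_transitions / raw$aligned_bases,
    Q = raw$n_transversions / raw$aligned_bases)
  div <- k2p(h$P, h$Q)
  h[, k2p := as.numeric(div)]
  h <- h[h$aligned_bases >= min_aligned & !attr(div, "saturated") &
           !is.na(h$k2p) & h$k2p <= max_divergence, ]
  data.table::setattr(h, "total_bases", total_bases)
  h
}

#' Per-family genome proportion from mask hits
#'
#' Family percent = 100 x aligned bases of its hits / total analysed bases;
#' an "ALL" row sums over families and an "unmasked" row carries the
#' remainder, so the three partitions always total 100%.
#'
#' @param hits table from [mask_reads()].
#' @param total_bases total analysed bases (> 0); defaults to the
#'   `"total_bases"` attribute of `hits`.
#' @param families optional family names to force into the result with 0%.
#' @return data.table (`family`, `percent`).
#' @export
genome_proportion <- function(hits, total_bases = NULL, families = NULL) {
  total_bases <- total_bases %||% attr(hits, "total_bases")
  if (is.null(total_bases) || total_bases <= 0)
    stop_invalid("total_bases must be > 0")
  per <- if (nrow(hits)) {
    stats::aggregate(hits$aligned_bases, by = list(family = hits$family), sum)
  } else data.frame(family = character(0), x = numeric(0))
  fams <- union(families %||% character(0), per$family)
  pc <- 100 * per$x[match(fams, per$family)] / total_bases
  pc[is.na(pc)] <- 0
  out <- data.table::data.table(family = fams, percent = pc)
  data.table::rbindlist(list(out,
    data.table::data.table(family = c("ALL", "unmasked"),
                           percent = c(sum(pc), 100 - sum(pc)))))
}

#' Per-family K2P divergence statistics (min / mean / max, percent)
#' @param hits table from [mask_reads()].
#' @param sample optional sample label column.
#' @export
divergence_stats <- function(hits, sample = NA_character_) {
  if (nrow(hits) == 0)
    return(data.table::data.table(name = character(0), sample = character(0),
                                  min = numeric(0), mean = numeric(0),
                                  max = numeric(0)))
  dt <- data.table::as.data.table(hits)
  out <- dt[, list(min = min(k2p), mean = mean(k2p), max = max(k2p)),
            by = "family"]
  data.table::setnames(out, "family", "name")
  out[, sample := sample]
  data.table::setcolorder(out, c("name", "sample", "min", "mean", "max"))
  out[]
}

#' Abundance-vs-divergence landscapes
#'
#' Bins each family's masked abundance (percent of analysed bases) into
#' half-open 1% K2P intervals \[0,1), \[1,2), ...; the "ALL" landscape is the
#' element-wise sum over families. Bin masses sum to the family's genome
#' proportion.
#'
#' @param hits table from [mask_reads()].
#' @param total_bases total analysed bases; defaults to the `"total_bases"`
#'   attribute of `hits`.
#' @return data.table (`family`, `bin_low`, `bin_high`, `percent`), only
#'   non-empty bins, stable-ordered.
#' @export
build_landscape <- function(hits, total_bases = NULL) {
  total_bases <- total_bases %||% attr(hits, "total_bases")
  if (is.null(total_bases) || total_bases <= 0)
    stop_invalid("total_bases must be > 0")
  if (nrow(hits) == 0)
    return(data.table::data.table(family = character(0), bin_low = integer(0),
                                  bin_high = integer(0), percent = numeric(0)))
  dt <- data.table::as.data.table(hits)
  dt[, bin_low := as.integer(floor(k2p))]
  per <- dt[, list(percent = 100 * sum(aligned_bases) / total_bases),
            by = c("family", "bin_low")]
  all <- per[, list(family = "ALL", percent = sum(percent)), by = "bin_low"]
  out <- data.table::rbindlist(list(per, all), use.names = TRUE)
  out[, bin_high := bin_low + 1L]
  data.table::setcolorder(out, c("family", "bin_low", "bin_high", "percent"))
  data.table::setorder(out, family, bin_low)
  out[]
}
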