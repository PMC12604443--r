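#' Build the weighted de Bruijn (k-mer) graph of a read cluster
#'
#' Nodes are canonical k-mers with multiplicities (forward and reverse
#' complement occurrences pooled); directed edges are the (k-1)-overlaps
#' observed in the reads and are implicit in the k-mer set: a node's
#' successors are the four single-base extensions of its suffix that exist in
#' the graph. Satellite clusters produce a dominant ring whose length equals
#' the repeat unit length.
#'
#' @param reads character vector of the cluster's reads.
#' @param k k-mer length (< shortest read length, <= 31).
#' @return object of class `kmer_graph`: `k`, `kmer`, `count`, `total_mass`.
#' @export
build_kmer_graph <- function(reads, k = 15L) {
  if (length(reads) == 0)
    return(structure(list(k = as.integer(k), kmer = character(0),
                          count = numeric(0), total_mass = 0),
                     class = "kmer_graph"))
  if (k >= min(nchar(reads)))
    stop_invalid("k (%d) must be smaller than the read length", k)
  counts <- .cpp_kmer_counts(unname(reads), as.integer(k))
  structure(list(k = as.integer(k), kmer = counts$kmer, count = counts$count,
                 total_mass = sum(counts$count)),
            class = "kmer_graph")
}

#' @export
print.kmer_graph <- function(x, ...) {
  cat(sprintf("kmer_graph: %d distinct canonical %d-mers, mass %.0f\n",
              length(x$kmer), x$k, x$total_mass))
  invisible(x)
}

#' Find the dominant cycle of a k-mer graph (satellite monomer candidate)
#'
#' Follows the heaviest successor from the heaviest nodes of the graph; the
#' heaviest simple cycle found is reported as the monomer (canonical
#' rotation). Circularity is the fraction of the cluster's k-mer mass
#' attributable to the ring: a k-mer contributes when it lies within
#' `max_mismatch` substitutions of some cyclic k-mer of the monomer (either
#' strand), which keeps SNV bubbles around the consensus ring counted as ring
#' mass. Clusters of linear (non-tandem) sequence have no cycle, or one whose
#' circularity falls below the threshold, and return `NULL`.
#'
#' @param graph a `kmer_graph`.
#' @param circularity_min minimum circularity for a satellite call
#'   (default 0.5).
#' @param max_mismatch Hamming radius for ring attribution; default
#'   `floor(k / 4)`.
#' @param n_starts number of heaviest nodes used as walk starts.
#' @param max_steps cap on walk length (bounds the detectable monomer size).
#' @param max_rul optional upper bound on accepted monomer length; candidates
#'   with longer rings return `NULL` (used by the fallback sweep, where small
#'   k makes long spurious rings likely).
#' @return a `monomer_candidate` (fields `monomer`, `rul`, `circularity`,
#'   `cycle_mass`, `total_mass`, `k`) or `NULL`.
#' @export
find_dominant_cycle <- function(graph, circularity_min = 0.5,
                                max_mismatch = NULL, n_starts = 5L,
                                max_steps = 2500L, max_rul = Inf) {
  stopifnot(inherits(graph, "kmer_graph"))
  if (length(graph$kmer) == 0) return(NULL)
  if (is.null(max_mismatch)) max_mismatch <- floor(graph$k / 4)
  res <- .cpp_dominant_cycle(graph$kmer, graph$count, graph$k,
                             as.integer(n_starts), as.integer(max_steps))
  if (is.null(res$monomer)) return(NULL)
  if (nchar(res$monomer) > max_rul) return(NULL)
  ring_mass <- .cpp_mass_near_cycle(graph$kmer, graph$count, res$monomer,
                                    graph$k, as.integer(max_mismatch))
  circ <- ring_mass / graph$total_mass
  if (circ < circularity_min) return(NULL)
  structure(list(monomer = canonical_rotation(res$monomer),
                 rul = nchar(res$monomer), circularity = circ,
                 cycle_mass = ring_mass, total_mass = graph$total_mass,
                 k = graph$k),
            class = "monomer_candidate")
}

#' @export
print.monomer_candidate <- function(x, ...) {
  cat(sprintf("monomer_candidate: rul %d, circularity %.3f\n%s\n",
              x$rul, x$circularity, x$monomer))
  invisible(x)
}

# Booth's least-rotation algorithm; returns the 0-based start index of the
# lexicographically smallest rotation
least_rotation_index <- function(s) {
  v <- utf8ToInt(s)
  n <- length(v)
  vv <- c(v, v)
  f <- rep(-1L, 2L * n)
  kk <- 0L
  for (j in 1L:(2L * n - 1L)) {
    sj <- vv[j + 1L]
    i <- f[j - kk]
    while (i != -1L && sj != vv[kk + i + 2L]) {
      if (sj < vv[kk + i + 2L]) kk <- j - i - 1L
      i <- f[i + 1L]
    }
    if (sj != vv[kk + i + 2L]) {
      if (sj < vv[kk + 1L]) kk <- j
      f[j - kk + 1L] <- -1L
    } else {
      f[j - kk + 1L] <- i + 1L
    }
  }
  kk
}

rotate_string <- function(s, i) {
  if (i == 0) return(s)
  n <- nchar(s)
  paste0(substr(s, i + 1, n), substr(s, 1, i))
}

#' Canonical rotation of a monomer
#'
#' Returns the lexicographically smallest string among all rotations of the
#' monomer and all rotations of its reverse complement, so identical
#' satellites detected in different samples, phases or strands compare equal.
#' Idempotent. Uses Booth's least-rotation algorithm on both strands.
#'
#' @param monomer non-empty DNA string (vectorised).
#' @export
canonical_rotation <- function(monomer) {
  vapply(monomer, function(m) {
    if (nchar(m) == 0) stop_invalid("monomer must be non-empty")
    fwd <- rotate_string(m, least_rotation_index(m))
    rcm <- revcomp(m)
    rev <- rotate_string(rcm, least_rotation_index(rcm))
    if (fwd <= rev) fwd else rev
  }, character(1), USE.NAMES = FALSE)
}

#' Detect satellite monomers across read clusters
#'
#' Runs [build_kmer_graph()] + [find_dominant_cycle()] on every cluster. The
#' main k defaults to 15 with an automatic fallback sweep over smaller odd k
#' when no ring is found: the fallback exists for monomers shorter than the
#' main k whose ring the main k cannot resolve, so a fallback candidate is
#' only accepted when its repeat unit is at most that k long (de Bruijn
#' graphs at small k are dense enough that long spurious cycles appear in
#' linear sequence). The first k yielding an acceptable ring wins, resolving
#' ties toward shorter periods.
#'
#' @param clusters a `read_clusters` object (post-filtering).
#' @param reads the interleaved read vector the clusters index into.
#' @param k main de Bruijn k-mer length.
#' @param fallback_k decreasing k values tried when `k` finds no ring.
#' @param circularity_min satellite call threshold (default 0.5).
#' @return list of candidates; each carries `cluster_id`, `abundance_percent`
#'   and `n_reads` in addition to the `monomer_candidate` fields.
#' @export
detect_satellites <- function(clusters, reads, k = 15L,
                              fallback_k = c(13L, 11L, 9L),
                              circularity_min = 0.5) {
  stopifnot(inherits(clusters, "read_clusters"))
  out <- list()
  for (ci in seq_along(clusters$members)) {
    rd <- unname(reads[clusters$members[[ci]]])
    cand <- NULL
    for (kk in c(k, fallback_k)) {
      if (kk >= min(nchar(rd))) next
      g <- build_kmer_graph(rd, kk)
      cand <- find_dominant_cycle(g, circularity_min = circularity_min,
                                  max_rul = if (kk == k) Inf else kk)
      if (!is.null(cand)) break
    }
    if (is.null(cand)) next
    cand$cluster_id <- clusters$table$cluster_id[ci]
    cand$abundance_percent <- clusters$table$abundance_percent[ci]
    cand$n_reads <- clusters$table$n_reads[ci]
    out[[length(out) + 1L]] <- cand
  }
  out
}

#' Write monomer candidates as TSV + FASTA
#' @param candidates list from [detect_satellites()].
#' @param tsv_path,fasta_path output files.
#' @export
write_candidates <- function(candidates, tsv_path, fasta_path) {
  tab <- data.table::data.table(
    cluster_id = vapply(candidates, `[[`, character(1), "cluster_id"),
    rul = vapply(candidates, `[[`, numeric(1), "rul"),
    circularity = vapply(candidates, `[[`, numeric(1), "circularity"),
    abundance_percent = vapply(candidates, `[[`, numeric(1), "abundance_percent"),
    monomer = vapply(candidates, `[[`, character(1), "monomer"))
  data.table::fwrite(tab, tsv_path, sep = "\t")
  hdr <- sprintf(">cluster%s_len%d", sub("^CL", "", tab$cluster_id), as.integer(tab$rul))
  writeLines(as.vector(rbind(hdr, tab$monomer)), fasta_path)
  invisible(tsv_path)
}
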