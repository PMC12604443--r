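#' Build a read similarity graph from shared canonical k-mers
#'
#' Nodes are reads; an undirected edge joins two reads sharing at least
#' `min_shared` distinct canonical k-mers (canonical = lexicographic minimum
#' of the k-mer and its reverse complement, so the graph is strand-symmetric).
#' Defaults (k = 21, min_shared = 10) make chance connections between
#' unrelated 101-mers essentially impossible: two random reads share an
#' expected 81 x 81 / 4^21 < 1e-9 canonical 21-mers, and an edge additionally
#' needs ten of them.
#'
#' @param reads a [read_set] (interleaved internally) or character vector.
#' @param k k-mer length (<= shortest read, <= 31).
#' @param min_shared minimum number of distinct shared canonical k-mers. Reads
#'   from tandem arrays of very short monomers hold fewer distinct k-mers than
#'   this in total, so the effective per-pair threshold is
#'   `min(min_shared, ceiling(adaptive_frac x smaller repertoire))`.
#' @param adaptive_frac fraction of the smaller read's distinct-k-mer
#'   repertoire required when it is below `min_shared` (default 0.8).
#' @param max_reads memory guardrail: explicit error (never silent truncation)
#'   when the read set is larger.
#' @param max_pair_instances guardrail on the k-mer co-occurrence volume.
#' @return object of class `read_graph`: read names, edge table
#'   (`from`, `to`, `shared`; 1-based read indices), `n_reads`, parameters.
#' @export
build_read_graph <- function(reads, k = 21L, min_shared = 10L,
                             adaptive_frac = 0.8, max_reads = 2e5,
                             max_pair_instances = 4e8) {
  origin <- NULL
  if (inherits(reads, "read_set")) {
    il <- interleaved_reads(reads)
    origin <- attr(il, "origin")
    reads <- il
  } else if (!is.null(attr(reads, "origin"))) origin <- attr(reads, "origin")
  if (length(reads) > max_reads)
    stop_invalid("read set (%d) exceeds max_reads (%d); subsample first",
                 length(reads), max_reads)
  if (length(reads) && k > min(nchar(reads)))
    stop_invalid("k (%d) exceeds the shortest read length", k)
  if (min_shared < 1) stop_invalid("min_shared must be >= 1")
  edges <- .cpp_kmer_edges(unname(reads), as.integer(k), as.integer(min_shared),
                           max_pair_instances, adaptive_frac)
  structure(list(n_reads = length(reads), read_names = names(reads),
                 origin = origin,
                 edges = data.table::as.data.table(edges),
                 k = as.integer(k), min_shared = as.integer(min_shared)),
            class = "read_graph")
}

#' @export
print.read_graph <- function(x, ...) {
  cat(sprintf("read_graph: %d reads, %d edges (k=%d, min_shared=%d)\n",
              x$n_reads, nrow(x$edges), x$k, x$min_shared))
  invisible(x)
}

#' Group reads into clusters (connected components)
#'
#' Clusters are the connected components of the read graph, ordered by
#' decreasing abundance (% of analysed reads); singleton reads form no
#' cluster. Ties are broken by the smallest member read index so cluster ids
#' are deterministic and invariant to input order up to relabelling.
#'
#' @param graph a `read_graph` from [build_read_graph()].
#' @return object of class `read_clusters`: list `members` of integer vectors
#'   (read indices), summary table (`cluster_id`, `n_reads`,
#'   `abundance_percent`), `n_total_reads`, and the graph's read names/origins.
#' @export
cluster_reads <- function(graph) {
  stopifnot(inherits(graph, "read_graph"))
  if (nrow(graph$edges) == 0) {
    return(structure(list(members = list(),
                          table = data.table::data.table(
                            cluster_id = character(0), n_reads = integer(0),
                            abundance_percent = numeric(0)),
                          n_total_reads = graph$n_reads,
                          read_names = graph$read_names, origin = graph$origin),
                     class = "read_clusters"))
  }
  g <- igraph::graph_from_edgelist(as.matrix(graph$edges[, c("from", "to")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, graph$n_reads - igraph::vcount(g)))
  comp <- igraph::components(g)
  members <- split(seq_len(graph$n_reads), comp$membership)
  members <- members[lengths(members) >= 2]
  ord <- order(-lengths(members),
               vapply(members, min, integer(1)))
  members <- unname(members[ord])
  tab <- data.table::data.table(
    cluster_id = sprintf("CL%04d", seq_along(members)),
    n_reads = lengths(members),
    abundance_percent = 100 * lengths(members) / graph$n_reads)
  structure(list(members = members, table = tab,
                 n_total_reads = graph$n_reads,
                 read_names = graph$read_names, origin = graph$origin),
            class = "read_clusters")
}

#' @export
print.read_clusters <- function(x, ...) {
  cat(sprintf("read_clusters: %d clusters over %d reads\n",
              length(x$members), x$n_total_reads))
  if (nrow(x$table)) print(head(x$table, 10))
  invisible(x)
}

#' Retain clusters above an abundance cut-off
#'
#' The threshold is strict: a cluster must *exceed* `min_abundance` percent of
#' analysed reads (a cluster at exactly the threshold is dropped).
#'
#' @param clusters a `read_clusters` object.
#' @param min_abundance abundance threshold in percent (default 0.001).
#' @export
filter_clusters <- function(clusters, min_abundance = 0.001) {
  stopifnot(inherits(clusters, "read_clusters"))
  if (min_abundance < 0) stop_invalid("min_abundance must be >= 0")
  keep <- clusters$table$abundance_percent > min_abundance
  out <- clusters
  out$members <- clusters$members[keep]
  out$table <- clusters$table[keep]
  out
}

#' Write the cluster summary table as TSV
#' @param clusters a `read_clusters` object.
#' @param path output file; a companion `<path>.members` file maps cluster_id
#'   to read names.
#' @export
write_clusters_tsv <- function(clusters, path) {
  data.table::fwrite(clusters$table, path, sep = "\t")
  mem <- data.table::data.table(
    cluster_id = rep(clusters$table$cluster_id, lengths(clusters$members)),
    read = if (!is.null(clusters$read_names))
      clusters$read_names[unlist(clusters$members)] else unlist(clusters$members))
  data.table::fwrite(mem, paste0(path, ".members"), sep = "\t")
  invisible(path)
}
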