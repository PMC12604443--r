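#' Match two satellite catalogs by consensus similarity
#'
#' Every family pair is scored with [monomer_identity()] (rotation-, strand-
#' and period-multiple-aware); pairs reaching both thresholds are candidate
#' matches, and a greedy best-identity assignment makes each family map to at
#' most one partner. The result is symmetric in the two catalogs.
#'
#' @param catalog_a,catalog_b `sat_catalog` objects.
#' @param min_identity minimum percent identity (default 78.5, the weakest
#'   reported cross-species satellite consensus similarity).
#' @param min_aligned_fraction minimum fraction of the shorter consensus
#'   covered (default 0.8).
#' @return data.table (`family_a`, `family_b`, `identity`,
#'   `aligned_fraction`).
#' @export
match_catalogs <- function(catalog_a, catalog_b, min_identity = 78.5,
                           min_aligned_fraction = 0.8) {
  fa <- catalog_a$families
  fb <- catalog_b$families
  cand <- list()
  for (i in seq_len(nrow(fa))) for (j in seq_len(nrow(fb))) {
    mi <- monomer_identity(fa$consensus[i], fb$consensus[j])
    if (mi$identity >= min_identity &&
        mi$aligned_fraction >= min_aligned_fraction)
      cand[[length(cand) + 1L]] <- data.table::data.table(
        family_a = fa$name[i], family_b = fb$name[j],
        identity = mi$identity, aligned_fraction = mi$aligned_fraction)
  }
  if (length(cand) == 0)
    return(data.table::data.table(family_a = character(0),
                                  family_b = character(0),
                                  identity = numeric(0),
                                  aligned_fraction = numeric(0)))
  tab <- data.table::rbindlist(cand)
  data.table::setorder(tab, -identity, family_a, family_b)
  used_a <- character(0); used_b <- character(0); keep <- logical(nrow(tab))
  for (r in seq_len(nrow(tab))) {
    if (!(tab$family_a[r] %in% used_a) && !(tab$family_b[r] %in% used_b)) {
      keep[r] <- TRUE
      used_a <- c(used_a, tab$family_a[r])
      used_b <- c(used_b, tab$family_b[r])
    }
  }
  out <- tab[keep]
  data.table::setorder(out, family_a)
  out[]
}

#' Match all catalog pairs of a named collection
#'
#' @param catalogs named list of `sat_catalog` objects (>= 2).
#' @inheritParams match_catalogs
#' @return data.table with columns `catalog_a`, `family_a`, `catalog_b`,
#'   `family_b`, `identity`, `aligned_fraction`.
#' @export
match_all_catalogs <- function(catalogs, min_identity = 78.5,
                               min_aligned_fraction = 0.8) {
  stopifnot(length(catalogs) >= 2, !is.null(names(catalogs)))
  nm <- names(catalogs)
  out <- list()
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i >= j) next
    m <- match_catalogs(catalogs[[i]], catalogs[[j]],
                        min_identity, min_aligned_fraction)
    if (nrow(m)) {
      m[, catalog_a := nm[i]]
      m[, catalog_b := nm[j]]
      out[[length(out) + 1L]] <- m
    }
  }
  if (length(out) == 0)
    return(data.table::data.table(catalog_a = character(0),
                                  family_a = character(0),
                                  catalog_b = character(0),
                                  family_b = character(0),
                                  identity = numeric(0),
                                  aligned_fraction = numeric(0)))
  res <- data.table::rbindlist(out, use.names = TRUE)
  data.table::setcolorder(res, c("catalog_a", "family_a", "catalog_b",
                                 "family_b", "identity", "aligned_fraction"))
  res[]
}

#' Venn-style shared-family counts across catalogs
#'
#' Family groups are the connected components of the cross-catalog match
#' graph (transitive closure of the pairwise matches; inconsistent triads are
#' thereby resolved by the spanning of retained best-identity matches). Each
#' group is assigned to the exact subset of catalogs it is detected in, and
#' the number of groups per subset is reported. Counts over all subsets sum to
#' the total number of family groups.
#'
#' @param matches table from [match_all_catalogs()].
#' @param catalogs the named list of catalogs the matches were computed from.
#' @return data.table (`region` such as "A" or "A&B", `n_families`).
#' @export
shared_family_counts <- function(matches, catalogs) {
  stopifnot(!is.null(names(catalogs)))
  nodes <- unlist(lapply(names(catalogs), function(nm)
    paste0(nm, "::", catalogs[[nm]]$families$name)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(matches)) {
    from <- paste0(matches$catalog_a, "::", matches$family_a)
    to <- paste0(matches$catalog_b, "::", matches$family_b)
    g <- igraph::add_edges(g, rbind(from, to))
  }
  comp <- igraph::components(g)
  groups <- split(nodes, comp$membership)
  region <- vapply(groups, function(grp) {
    cats <- sort(unique(sub("::.*$", "", grp)))
    paste(cats, collapse = "&")
  }, character(1))
  tab <- table(region)
  out <- data.table::data.table(region = names(tab),
                                n_families = as.integer(tab))
  data.table::setorder(out, region)
  out[]
}

#' Flag families with male/female abundance asymmetry (Y-linkage candidates)
#'
#' A family is a Y-linkage candidate when its male/female abundance ratio
#' reaches `ratio_threshold`; zero female abundance is replaced by
#' `absence_floor` (the discovery threshold) so ratios stay finite, and a
#' family present in the male but absent in the female is always flagged.
#' Families with a moderate excess (ratio >= `cnp_threshold` but below the
#' Y threshold, e.g. an autosomal heterochromatin polymorphism between
#' populations) are labelled `copy_number_polymorphism` rather than Y-linked.
#'
#' @param abundance data.frame with columns `family`, `male`, `female`
#'   (percent of genome), both samples quantified with the same catalog.
#' @param ratio_threshold male/female ratio calling a Y candidate
#'   (default 10).
#' @param absence_floor pseudo-abundance for zero denominators, in percent
#'   (default 0.001, the cluster discovery threshold).
#' @param cnp_threshold ratio labelling a copy-number-polymorphism candidate
#'   (default 2).
#' @return data.table (`family`, `male_abundance`, `female_abundance`,
#'   `ratio`, `y_linked_candidate`, `label`).
#' @export
flag_sex_biased <- function(abundance, ratio_threshold = 10,
                            absence_floor = 0.001, cnp_threshold = 2) {
  stopifnot(all(c("family", "male", "female") %in% names(abundance)))
  male <- abundance$male
  female <- abundance$female
  ratio <- male / pmax(female, absence_floor)
  y <- ratio >= ratio_threshold | (female <= 0 & male > 0)
  label <- ifelse(y, "y_linked_candidate",
                  ifelse(ratio >= cnp_threshold, "copy_number_polymorphism",
                         "balanced"))
  data.table::data.table(family = abundance$family, male_abundance = male,
                         female_abundance = female, ratio = ratio,
                         y_linked_candidate = y, label = label)
}

#' Presence/abundance matrix of families across samples
#'
#' @param abundance long table (`name`, `sample`, `percent`).
#' @return wide data.table, one row per family, one abundance column per
#'   sample plus `detected_<sample>` logical columns (detected means
#'   abundance > 0).
#' @export
presence_matrix <- function(abundance) {
  dt <- data.table::as.data.table(abundance)
  wide <- data.table::dcast(dt, name ~ sample, value.var = "percent",
                            fill = 0)
  for (s in setdiff(names(wide), "name"))
    wide[[paste0("detected_", s)]] <- wide[[s]] > 0
  wide[]
}
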