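#' Rotation-, strand- and period-multiple-aware identity of two monomers
#'
#' The shorter monomer is tiled to the length of the longer (so a 4-bp unit
#' can merge with its 8/9-bp expansions), the longer is doubled (so every
#' rotation is a substring), and the tiled unit is aligned end-to-end
#' (pattern-global, subject-local) on both strands. The global pattern
#' anchoring is essential: a purely local alignment would trim to any short
#' exact stretch and report 100% identity for unrelated monomers. Symmetric
#' in its arguments.
#'
#' @param a,b monomer DNA strings.
#' @return list with `identity` (percent, matches / alignment columns
#'   including gap columns) and `aligned_fraction` (pattern bases paired to
#'   subject bases / pattern length).
#' @export
monomer_identity <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  pattern <- strrep(a, max(1L, round(nchar(b) / nchar(a))))
  subject <- strrep(b, 2L)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  best <- NULL
  for (p in c(pattern, revcomp(pattern))) {
    aln <- Biostrings::pairwiseAlignment(p, subject, type = "global-local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2)
    if (is.null(best) || Biostrings::score(aln) > Biostrings::score(best))
      best <- aln
  }
  pa <- strsplit(as.character(Biostrings::alignedPattern(best)), "", fixed = TRUE)[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(best)), "", fixed = TRUE)[[1]]
  n_cols <- length(pa)
  paired <- pa != "-" & sa != "-"
  ident <- if (n_cols == 0) 0 else 100 * sum(pa == sa & paired) / n_cols
  list(identity = ident,
       aligned_fraction = sum(paired) / nchar(pattern))
}

#' Merge duplicate monomer candidates into satellite families
#'
#' Candidates whose canonical monomers align at `min_identity` percent or
#' better (rotation-, strand- and period-multiple-aware, with at least 80% of
#' the shorter unit covered) are merged into one family. Candidates are
#' processed in decreasing abundance; the most abundant member provides the
#' family consensus, merged members contribute their abundance.
#'
#' @param candidates list from [detect_satellites()].
#' @param min_identity merge threshold in percent (default 80, below the
#'   weakest reported cross-species satellite match of 78.5% so intraspecific
#'   variants always merge).
#' @return list of family prototypes: `consensus`, `rul`, `circularity`,
#'   `abundance_percent`, `cluster_ids`.
#' @export
dedupe_candidates <- function(candidates, min_identity = 80) {
  if (length(candidates) == 0) return(list())
  ord <- order(-vapply(candidates, `[[`, numeric(1), "abundance_percent"),
               vapply(candidates, `[[`, numeric(1), "rul"),
               vapply(candidates, `[[`, character(1), "monomer"))
  fams <- list()
  for (ci in ord) {
    cand <- candidates[[ci]]
    merged <- FALSE
    for (fi in seq_along(fams)) {
      mi <- monomer_identity(cand$monomer, fams[[fi]]$consensus)
      if (mi$identity >= min_identity && mi$aligned_fraction >= 0.8) {
        fams[[fi]]$abundance_percent <- fams[[fi]]$abundance_percent +
          cand$abundance_percent
        fams[[fi]]$cluster_ids <- c(fams[[fi]]$cluster_ids, cand$cluster_id)
        merged <- TRUE
        break
      }
    }
    if (!merged)
      fams[[length(fams) + 1L]] <- list(consensus = cand$monomer,
                                        rul = cand$rul,
                                        circularity = cand$circularity,
                                        abundance_percent = cand$abundance_percent,
                                        cluster_ids = cand$cluster_id)
  }
  fams
}

#' A+T content of a sequence, in percent
#' @param sequence non-empty DNA string (vectorised).
#' @export
at_content <- function(sequence) {
  if (any(nchar(sequence) == 0)) stop_invalid("sequence must be non-empty")
  100 * (nchar(gsub("[^ATat]", "", sequence))) / nchar(sequence)
}

#' Rank families by reference-sample abundance and assign names
#'
#' Families are sorted by decreasing abundance in the reference sample and
#' named `<SpeciesCode>Sat<NNN>-<RUL>` with a zero-padded 3-digit rank, e.g.
#' the most abundant family with a 166-bp unit in species code "Trub" becomes
#' "TrubSat001-166". Ties are broken by smaller repeat unit length, then by
#' lexicographic consensus.
#'
#' @param families list of family prototypes (from [dedupe_candidates()]),
#'   each additionally carrying `per_sample_abundance`, a named numeric vector
#'   of genome percentages.
#' @param species_code label prefix.
#' @param reference_sample sample id whose abundance anchors the ranking;
#'   every family must have an abundance entry for it.
#' @return object of class `sat_catalog`: `species_code`, `reference_sample`,
#'   `families` table (name, rank, rul, at_content, consensus) and long-format
#'   `abundance` table (name, sample, percent).
#' @export
rank_and_name <- function(families, species_code, reference_sample) {
  if (length(families) == 0) {
    return(structure(list(species_code = species_code,
                          reference_sample = reference_sample,
                          families = data.table::data.table(
                            name = character(0), rank = integer(0),
                            rul = integer(0), at_content = numeric(0),
                            consensus = character(0)),
                          abundance = data.table::data.table(
                            name = character(0), sample = character(0),
                            percent = numeric(0))),
                     class = "sat_catalog"))
  }
  ref_ab <- vapply(families, function(f) {
    ab <- f$per_sample_abundance
    if (is.null(ab) || !(reference_sample %in% names(ab)))
      stop_invalid("family lacks abundance in reference sample '%s'",
                   reference_sample)
    ab[[reference_sample]]
  }, numeric(1))
  ord <- order(-ref_ab,
               vapply(families, `[[`, numeric(1), "rul"),
               vapply(families, `[[`, character(1), "consensus"))
  families <- families[ord]
  rul <- vapply(families, `[[`, numeric(1), "rul")
  tab <- data.table::data.table(
    name = sprintf("%sSat%03d-%d", species_code, seq_along(families),
                   as.integer(rul)),
    rank = seq_along(families),
    rul = as.integer(rul),
    at_content = at_content(vapply(families, `[[`, character(1), "consensus")),
    consensus = vapply(families, `[[`, character(1), "consensus"))
  ab <- data.table::rbindlist(lapply(seq_along(families), function(i) {
    a <- families[[i]]$per_sample_abundance
    data.table::data.table(name = tab$name[i], sample = names(a),
                           percent = as.numeric(a))
  }))
  structure(list(species_code = species_code,
                 reference_sample = reference_sample,
                 families = tab, abundance = ab),
            class = "sat_catalog")
}

#' @export
print.sat_catalog <- function(x, ...) {
  cat(sprintf("sat_catalog '%s': %d families (reference sample '%s')\n",
              x$species_code, nrow(x$families), x$reference_sample))
  if (nrow(x$families)) print(x$families[, c("name", "rul", "at_content")])
  invisible(x)
}

#' Write / read a satellite catalog as FASTA
#'
#' Headers are the family names; the round trip is lossless for names,
#' consensus sequences and the rank/RUL encoded in the names.
#'
#' @param catalog a `sat_catalog`.
#' @param path FASTA file.
#' @export
write_catalog_fasta <- function(catalog, path) {
  writeLines(as.vector(rbind(paste0(">", catalog$families$name),
                             catalog$families$consensus)), path)
  invisible(path)
}

#' @rdname write_catalog_fasta
#' @param species_code,reference_sample metadata restored on read.
#' @export
read_catalog_fasta <- function(path, species_code = NA_character_,
                               reference_sample = NA_character_) {
  seqs <- Biostrings::readDNAStringSet(path)
  name <- names(seqs)
  rul <- as.integer(sub("^.*-", "", name))
  rank <- as.integer(sub("^.*Sat(\\d+)-.*$", "\\1", name))
  if (is.na(species_code) && length(name))
    species_code <- sub("Sat\\d+-\\d+$", "", name[1])
  structure(list(species_code = species_code,
                 reference_sample = reference_sample,
                 families = data.table::data.table(
                   name = name, rank = rank, rul = rul,
                   at_content = at_content(as.character(seqs)),
                   consensus = as.character(seqs)),
                 abundance = data.table::data.table(
                   name = character(0), sample = character(0),
                   percent = numeric(0))),
            class = "sat_catalog")
}

#' Write the catalog summary as TSV
#'
#' One row per family with A+T content and, when available, per-sample
#' abundance and K2P divergence statistics; "ND" marks families not detected
#' in a sample.
#'
#' @param catalog a `sat_catalog`.
#' @param path output file.
#' @param divergence optional long table (name, sample, min, mean, max).
#' @export
write_catalog_tsv <- function(catalog, path, divergence = NULL) {
  tab <- data.table::copy(catalog$families)
  if (nrow(catalog$abundance)) {
    for (s in unique(catalog$abundance$sample)) {
      ab <- catalog$abundance[catalog$abundance$sample == s, ]
      v <- ab$percent[match(tab$name, ab$name)]
      tab[[paste0("abundance_", s)]] <-
        ifelse(is.na(v) | v <= 0, "ND", sprintf("%.4f", v))
    }
  }
  if (!is.null(divergence) && nrow(divergence)) {
    for (s in unique(divergence$sample)) {
      dv <- divergence[divergence$sample == s, ]
      i <- match(tab$name, dv$name)
      tab[[paste0("k2p_", s)]] <- ifelse(is.na(i), "ND",
        sprintf("%.2f/%.2f/%.2f", dv$min[i], dv$mean[i], dv$max[i]))
    }
  }
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}
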