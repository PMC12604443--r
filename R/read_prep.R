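#' Paired read set container
#'
#' Holds cleaned/subsampled paired reads with per-sample metadata. Origin
#' labels (which planted family or background interval a mate came from) are
#' optional and only present for simulated data.
#'
#' @param sample_id sample label.
#' @param read1,read2 character vectors of mate sequences, aligned one-to-one.
#' @param id pair identifiers (generated when missing).
#' @param origin1,origin2 optional per-mate origin labels.
#' @param start1,start2 optional 0-based template start positions of the
#'   mates (simulated data only; enables exact truth accounting).
#' @param read_length nominal read length.
#' @return object of class `read_set` with fields `sample_id`, `id`, `read1`,
#'   `read2`, `origin1`, `origin2`, `start1`, `start2`, `read_length`,
#'   `total_bases`.
#' @export
read_set <- function(sample_id, read1, read2, id = NULL,
                     origin1 = NULL, origin2 = NULL,
                     start1 = NULL, start2 = NULL, read_length = NULL) {
  if (length(read1) != length(read2))
    stop_invalid("read1 and read2 must have the same length")
  n <- length(read1)
  if (is.null(id)) id <- sprintf("%s_%07d", sample_id, seq_len(n))
  if (is.null(read_length)) read_length <- if (n) max(nchar(c(read1, read2))) else 0L
  structure(list(sample_id = sample_id, id = id,
                 read1 = read1, read2 = read2,
                 origin1 = origin1, origin2 = origin2,
                 start1 = start1, start2 = start2,
                 read_length = as.integer(read_length),
                 total_bases = sum(nchar(read1)) + sum(nchar(read2))),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set '%s': %d pairs, %s bases\n", x$sample_id,
              length(x$read1), format(x$total_bases, big.mark = ",")))
  invisible(x)
}

#' Number of read pairs in a read set
#' @param reads a `read_set`.
#' @export
n_pairs <- function(reads) length(reads$read1)

subset_pairs <- function(reads, idx) {
  read_set(reads$sample_id, reads$read1[idx], reads$read2[idx],
           id = reads$id[idx],
           origin1 = if (!is.null(reads$origin1)) reads$origin1[idx],
           origin2 = if (!is.null(reads$origin2)) reads$origin2[idx],
           start1 = if (!is.null(reads$start1)) reads$start1[idx],
           start2 = if (!is.null(reads$start2)) reads$start2[idx],
           read_length = reads$read_length)
}

#' Remove low-quality read pairs
#'
#' A pair is kept only when *both* mates are at least `min_length` bases long
#' and contain at most `max_n` ambiguous (non-ACGT) bases; mates are never
#' orphaned.
#'
#' @param reads a [read_set].
#' @param min_length minimum mate length; defaults to half the read length.
#' @param max_n maximum number of ambiguous bases per mate (default 0).
#' @return a filtered `read_set` (possibly empty).
#' @export
clean_reads <- function(reads, min_length = NULL, max_n = 0L) {
  stopifnot(inherits(reads, "read_set"))
  if (is.null(min_length)) min_length <- floor(reads$read_length / 2)
  if (min_length < 1) stop_invalid("min_length must be >= 1")
  count_n <- function(x) nchar(x) - nchar(gsub("[^ACGT]", "", x))
  keep <- nchar(reads$read1) >= min_length & nchar(reads$read2) >= min_length &
    count_n(reads$read1) <= max_n & count_n(reads$read2) <= max_n
  subset_pairs(reads, which(keep))
}

#' Randomly subsample read pairs without replacement
#'
#' @param reads a [read_set].
#' @param n_pairs number of pairs to keep (must not exceed available pairs).
#' @param seed RNG seed; the selection is order-stable for a fixed seed.
#' @export
subsample_pairs <- function(reads, n_pairs, seed) {
  stopifnot(inherits(reads, "read_set"))
  avail <- length(reads$read1)
  if (n_pairs > avail)
    stop_invalid("n_pairs (%d) exceeds available pairs (%d)", n_pairs, avail)
  if (n_pairs == avail) return(reads)
  idx <- with_seed(seed, sort(sample.int(avail, n_pairs)))
  subset_pairs(reads, idx)
}

#' Coverage bookkeeping report
#'
#' Coverage = analysed bases / genome size. The display value is truncated
#' (not rounded) to two decimals, matching the convention of reporting
#' 271 Mb / 1187 Mb as "about 0.22x"; the full-precision value is stored. The
#' report flags whether coverage lies in the recommended closed interval
#' \[0.1, 0.5\] for graph-based repeat discovery.
#'
#' @param analysed_bases number of bases entering the analysis.
#' @param genome_size genome size in bases (> 0).
#' @return object of class `coverage_report` with fields `analysed_bases`,
#'   `genome_size`, `coverage`, `coverage_display`, `in_range`.
#' @export
coverage_report <- function(analysed_bases, genome_size) {
  if (genome_size <= 0) stop_invalid("genome_size must be > 0")
  if (analysed_bases < 0) stop_invalid("analysed_bases must be >= 0")
  cov <- analysed_bases / genome_size
  structure(list(analysed_bases = analysed_bases, genome_size = genome_size,
                 coverage = cov,
                 coverage_display = sprintf("%.2f", truncate_decimals(cov, 2)),
                 in_range = cov >= 0.1 && cov <= 0.5),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("coverage %sx (%s / %s bases)%s\n", x$coverage_display,
              format(x$analysed_bases, big.mark = ","),
              format(x$genome_size, big.mark = ","),
              if (x$in_range) " [within 0.1-0.5x]" else " [outside 0.1-0.5x]"))
  invisible(x)
}

#' Interleave a read set into a single vector of reads
#'
#' Mates are adjacent (id/1, id/2), the hand-off format to clustering.
#'
#' @param reads a [read_set].
#' @return named character vector; per-read origin labels (if present) are
#'   attached as attribute `"origin"`.
#' @export
interleaved_reads <- function(reads) {
  stopifnot(inherits(reads, "read_set"))
  n <- length(reads$read1)
  out <- character(2 * n)
  nm <- character(2 * n)
  out[seq(1, by = 2, length.out = n)] <- reads$read1
  out[seq(2, by = 2, length.out = n)] <- reads$read2
  nm[seq(1, by = 2, length.out = n)] <- paste0(reads$id, "/1")
  nm[seq(2, by = 2, length.out = n)] <- paste0(reads$id, "/2")
  names(out) <- nm
  if (!is.null(reads$origin1)) {
    org <- character(2 * n)
    org[seq(1, by = 2, length.out = n)] <- reads$origin1
    org[seq(2, by = 2, length.out = n)] <- reads$origin2
    attr(out, "origin") <- org
  }
  out
}

#' Write a read set as FASTQ (Phred+33, dummy quality "I")
#'
#' @param reads a [read_set].
#' @param prefix output path prefix; `<prefix>_1.fastq[.gz]` and
#'   `<prefix>_2.fastq[.gz]` are written.
#' @param gzip compress output.
#' @return the two file paths, invisibly.
#' @export
write_read_fastq <- function(reads, prefix, gzip = TRUE) {
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- paste0(prefix, c("_1", "_2"), ext)
  for (m in 1:2) {
    seqs <- reads[[paste0("read", m)]]
    org <- reads[[paste0("origin", m)]]
    hdr <- paste0("@", reads$id, "/", m,
                  if (!is.null(org)) paste0(" origin=", org) else "")
    lines <- as.vector(rbind(hdr, seqs, "+", strrep("I", nchar(seqs))))
    con <- if (gzip) gzfile(paths[m], "wb") else file(paths[m], "wb")
    writeLines(lines, con, sep = "\n")
    close(con)
  }
  invisible(paths)
}

#' Read paired FASTQ files into a read set
#'
#' Accepts plain or gzip-compressed FASTQ. `origin=` comments written by
#' [write_read_fastq()] are recovered when present.
#'
#' @param file1,file2 FASTQ paths for mate 1 and mate 2.
#' @param sample_id sample label.
#' @export
read_fastq_pairs <- function(file1, file2, sample_id) {
  parse_fq <- function(path) {
    lines <- readLines(path)
    if (length(lines) %% 4 != 0) stop_invalid("malformed FASTQ: %s", path)
    hdr <- lines[seq(1, length(lines), by = 4)]
    seqs <- toupper(lines[seq(2, length(lines), by = 4)])
    id <- sub("^@", "", sub("[ /].*$", "", hdr))
    origin <- ifelse(grepl("origin=", hdr), sub("^.*origin=", "", hdr), NA)
    list(id = id, seq = seqs,
         origin = if (all(is.na(origin))) NULL else origin)
  }
  f1 <- parse_fq(file1)
  f2 <- parse_fq(file2)
  if (length(f1$seq) != length(f2$seq))
    stop_invalid("mate files differ in read count")
  read_set(sample_id, f1$seq, f2$seq, id = f1$id,
           origin1 = f1$origin, origin2 = f2$origin)
}

#' Write interleaved FASTA (mates adjacent)
#' @param reads a [read_set].
#' @param path output file.
#' @export
write_interleaved_fasta <- function(reads, path) {
  il <- interleaved_reads(reads)
  org <- attr(il, "origin")
  hdr <- paste0(">", names(il),
                if (!is.null(org)) paste0(" origin=", org) else "")
  writeLines(as.vector(rbind(hdr, unname(il))), path)
  invisible(path)
}

#' Read interleaved FASTA written by [write_interleaved_fasta()]
#' @param path FASTA file.
#' @return named character vector of reads with optional `"origin"` attribute.
#' @export
read_interleaved_fasta <- function(path) {
  lines <- readLines(path)
  hdr_i <- grep("^>", lines)
  if (!all(diff(hdr_i) == 2) || length(lines) != 2 * length(hdr_i))
    stop_invalid("expected strictly one sequence line per record: %s", path)
  hdr <- lines[hdr_i]
  out <- toupper(lines[hdr_i + 1])
  names(out) <- sub("^>", "", sub(" .*$", "", hdr))
  origin <- ifelse(grepl("origin=", hdr), sub("^.*origin=", "", hdr), NA)
  if (!all(is.na(origin))) attr(out, "origin") <- origin
  out
}
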