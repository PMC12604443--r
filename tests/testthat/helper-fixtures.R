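# fixtures are generated in code; no binary data ships with the package

rand_dna <- function(n, seed = NULL, at = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
         collapse = "")
}

# substitute exactly n_mut random positions (test-side, independent of the
# package's mutation code)
mutate_n <- function(seq, n_mut, seed) {
  set.seed(seed)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(ch), n_mut)
  ch[pos] <- vapply(ch[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  paste0(ch, collapse = "")
}

# brute-force oracle for canonical_rotation: enumerate all rotations of both
# strands and take the minimum
brute_canonical <- function(m) {
  n <- nchar(m)
  rots <- function(s) vapply(0:(n - 1), function(i)
    paste0(substr(s, i + 1, n), substr(s, 1, i)), character(1))
  min(c(rots(m), rots(revcomp(m))))
}

# minimum Hamming distance between a and b over all rotations of both strands
# of b (equal lengths required)
rotation_hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  n <- nchar(a)
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  best <- n
  for (s in c(b, revcomp(b))) {
    sv <- strsplit(s, "", fixed = TRUE)[[1]]
    for (i in 0:(n - 1)) {
      rot <- c(sv[(i + 1):n], sv[seq_len(i)])[seq_len(n)]
      if (i == 0) rot <- sv
      best <- min(best, sum(av != rot))
    }
  }
  best
}

# reads tiled from a long sequence at the given offsets (exact, no errors)
tile_reads <- function(seq, n, len = 101, seed = 1) {
  set.seed(seed)
  starts <- sample.int(nchar(seq) - len + 1, n, replace = TRUE)
  substring(seq, starts, starts + len - 1)
}

# a small paired read set with known content
fixture_read_set <- function(n = 20, len = 60, seed = 42, sample_id = "fix") {
  set.seed(seed)
  r1 <- vapply(seq_len(n), function(i) rand_dna(len), character(1))
  r2 <- vapply(seq_len(n), function(i) rand_dna(len), character(1))
  read_set(sample_id, r1, r2, read_length = len)
}

# three catalogs drawn from one ancestral monomer library with planted
# independent losses; returns catalogs plus the expected Venn partition
library_fixture <- function(seed) {
  set.seed(seed)
  n_fam <- 10
  lens <- sample(30:200, n_fam)
  ancestral <- vapply(seq_len(n_fam), function(i)
    generate_monomer(lens[i], 0.6, seed * 100 + i), character(1))
  presence <- list(A = 1:8, B = c(1:6, 9), C = c(1:4, 10))
  catalogs <- lapply(names(presence), function(sp) {
    fams <- lapply(presence[[sp]], function(i) {
      mono <- mutate_n(ancestral[i], max(1L, round(0.05 * lens[i])),
                       seed * 1000 + i * 10 + match(sp, names(presence)))
      list(consensus = mono, rul = nchar(mono),
           per_sample_abundance = c(ref = 1 / i))
    })
    rank_and_name(fams, species_code = sp, reference_sample = "ref")
  })
  names(catalogs) <- names(presence)
  list(catalogs = catalogs,
       expected = c("A" = 2L, "A&B" = 2L, "A&B&C" = 4L, "B" = 1L, "C" = 1L))
}

# exact family base content of a simulated read set: per-mate overlap with the
# template's family segments (arrays are never adjacent, so a mate overlaps at
# most one family segment and its flanks)
family_read_bases <- function(rs, segments, family_id) {
  seg <- segments[segments$label == family_id, ]
  if (nrow(seg) == 0 || is.null(rs$start1)) return(0)
  len <- rs$read_length
  tot <- 0
  for (st in list(rs$start1, rs$start2)) {
    en <- st + len
    for (off in 0:1) {
      j <- findInterval(st, seg$start) + off
      ok <- j >= 1 & j <= nrow(seg)
      ov <- pmax(0, pmin(seg$end[pmax(j, 1)], en) - pmax(seg$start[pmax(j, 1)], st))
      tot <- tot + sum(ov[ok])
    }
  }
  tot
}

# fraction of a cluster's reads that carry >= 1 base of family sequence
cluster_family_fraction <- function(members, rs, segments, family_id) {
  seg <- segments[segments$label == family_id, ]
  len <- rs$read_length
  # interleaved read index i -> pair ceiling(i/2), mate 2 - i %% 2
  pair <- ceiling(members / 2)
  st <- ifelse(members %% 2 == 1, rs$start1[pair], rs$start2[pair])
  en <- st + len
  has <- vapply(seq_along(st), function(i) {
    j <- findInterval(st[i], seg$start)
    any(vapply(c(j, j + 1), function(jj) {
      jj >= 1 && jj <= nrow(seg) &&
        min(seg$end[jj], en[i]) - max(seg$start[jj], st[i]) > 0
    }, logical(1)))
  }, logical(1))
  mean(has)
}
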