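test_that("reference construction follows the dimer / ~200 bp rule", {
  r166 <- build_reference(rand_dna(166, seed = 1))
  expect_equal(r166$n_copies, 2)
  expect_equal(nchar(r166$sequence), 332)
  r9 <- build_reference("GATAGATTA")
  expect_equal(r9$n_copies, 22)   # round(200 / 9)
  expect_equal(nchar(r9$sequence), 198)
  r100 <- build_reference(rand_dna(100, seed = 2))
  expect_equal(r100$n_copies, 2)  # boundary: both branches coincide
  expect_equal(nchar(r100$sequence), 200)
  # round-half-to-even and the minimum of 2 copies
  expect_equal(build_reference(rand_dna(80, seed = 3))$n_copies, 2)   # 2.5 -> 2
  expect_equal(build_reference(rand_dna(180, seed = 4))$n_copies, 2)  # 1.1 -> min 2
  expect_error(build_reference("A"), class = "satkit_invalid_parameter")
})

test_that("k2p matches an independent evaluation and flags saturation", {
  expect_equal(as.numeric(k2p(0, 0)), 0)
  # -50 * log(0.75 * sqrt(0.9)) evaluated independently at high precision
  expect_equal(as.numeric(k2p(0.1, 0.05)), 17.0181165, tolerance = 1e-6)
  # independent evaluation via a different arithmetic path (log1p form)
  oracle <- function(P, Q) -50 * (log1p(-(2 * P + Q)) + 0.5 * log1p(-2 * Q))
  grid <- expand.grid(P = seq(0, 0.30, length.out = 10),
                      Q = seq(0, 0.20, length.out = 10))
  expect_equal(as.numeric(k2p(grid$P, grid$Q)), oracle(grid$P, grid$Q),
               tolerance = 1e-9)
  # saturation on the domain boundary
  v <- k2p(0.5, 0)
  expect_true(is.na(as.numeric(v)))
  expect_true(attr(v, "saturated"))
  expect_true(attr(k2p(0, 0.5), "saturated"))
  expect_error(k2p(-0.1, 0), class = "satkit_invalid_parameter")
  expect_error(k2p(0.6, 0.6), class = "satkit_invalid_parameter")
})

test_that("k2p is zero iff P=Q=0 and strictly increasing in each argument", {
  ps <- seq(0, 0.3, by = 0.03)
  for (q in c(0, 0.05, 0.1)) {
    vals <- as.numeric(k2p(ps, rep(q, length(ps))))
    expect_true(all(diff(vals) > 0))
  }
  qs <- seq(0, 0.2, by = 0.02)
  for (p in c(0, 0.1, 0.2)) {
    vals <- as.numeric(k2p(rep(p, length(qs)), qs))
    expect_true(all(diff(vals) > 0))
  }
  expect_true(all(as.numeric(k2p(ps[-1], 0)) > 0))
})

test_that("mask_reads assigns exact reads with zero divergence, skips junk", {
  mono <- rand_dna(80, seed = 12)
  ref <- build_reference(mono, "famA")
  # read = exact substring of the reference
  rd_exact <- substr(ref$sequence, 11, 111)
  # read from a mutated copy (about 5% divergence)
  rd_mut <- mutate_n(substr(strrep(mono, 4), 31, 131), 5, seed = 5)
  # reverse-complement read must hit on the minus strand
  rd_rc <- revcomp(rd_exact)
  rd_bg <- rand_dna(101, seed = 99)
  hits <- mask_reads(c(a = rd_exact, b = rd_mut, c = rd_rc, d = rd_bg),
                     list(ref))
  expect_equal(sort(hits$read), c("a", "b", "c"))
  ha <- hits[hits$read == "a", ]
  expect_equal(ha$P + ha$Q, 0)
  expect_equal(ha$k2p, 0)
  expect_equal(ha$aligned_bases, 101)
  expect_identical(hits$strand[hits$read == "c"], "-")
  hb <- hits[hits$read == "b", ]
  expect_gte(hb$k2p, 1); expect_lte(hb$k2p, 12)
  expect_error(mask_reads(c("ACGT"), list()),
               class = "satkit_invalid_parameter")
})

test_that("genome_proportion partitions analysed bases exactly", {
  hits <- data.table::data.table(
    read = c("r1", "r2", "r3"), family = c("f1", "f1", "f2"),
    strand = "+", score = 90, aligned_bases = c(101, 50, 80),
    P = 0, Q = 0, k2p = c(0, 2.2, 7.9))
  gp <- genome_proportion(hits, total_bases = 10100)
  expect_equal(gp$percent[gp$family == "f1"], 100 * 151 / 10100)
  expect_equal(gp$percent[gp$family == "f2"], 100 * 80 / 10100)
  expect_equal(gp$percent[gp$family == "ALL"],
               sum(gp$percent[gp$family %in% c("f1", "f2")]))
  expect_equal(gp$percent[gp$family == "ALL"] +
                 gp$percent[gp$family == "unmasked"], 100)
  # no hits: zero percent for requested families
  gp0 <- genome_proportion(hits[0], total_bases = 1000, families = "f1")
  expect_equal(gp0$percent[gp0$family == "f1"], 0)
  expect_error(genome_proportion(hits, total_bases = 0),
               class = "satkit_invalid_parameter")
})

test_that("landscapes bin abundance by integer K2P and stay additive", {
  hits <- data.table::data.table(
    read = sprintf("r%d", 1:5),
    family = c("f1", "f1", "f1", "f2", "f2"),
    strand = "+", score = 90, aligned_bases = c(100, 100, 100, 50, 50),
    P = 0, Q = 0, k2p = c(0.2, 0.9, 3.5, 0.2, 12.01))
  ls <- build_landscape(hits, total_bases = 1000)
  f1 <- ls[ls$family == "f1", ]
  expect_equal(f1$bin_low, c(0L, 3L))
  expect_equal(f1$percent, c(20, 10))
  expect_equal(f1$bin_high, f1$bin_low + 1L)
  # per-family bins sum to the family proportion
  gp <- genome_proportion(hits, total_bases = 1000)
  expect_equal(sum(f1$percent), gp$percent[gp$family == "f1"])
  # aggregate landscape = element-wise sum over families
  all_bins <- ls[ls$family == "ALL", ]
  expect_equal(sum(all_bins$percent),
               sum(ls$percent[ls$family %in% c("f1", "f2")]))
  expect_equal(all_bins$percent[all_bins$bin_low == 0L], 25)
})
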