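test_that("generate_monomer respects length, composition and determinism", {
  m <- generate_monomer(166, 0.6, seed = 1)
  expect_equal(nchar(m), 166)
  expect_lt(abs(at_content(m) / 100 - 0.6), 0.1)
  expect_identical(m, generate_monomer(166, 0.6, seed = 1))
  expect_false(identical(m, generate_monomer(166, 0.6, seed = 2)))
  expect_error(generate_monomer(1, 0.5, seed = 1), class = "satkit_invalid_parameter")
  expect_error(generate_monomer(10, 0, seed = 1), class = "satkit_invalid_parameter")
  expect_error(generate_monomer(10, 1, seed = 1), class = "satkit_invalid_parameter")
})

test_that("build_genome bookkeeping: proportions, conservation, segments", {
  sp <- sat_family_spec("gata", "GATA", 0.10, divergence_rate = 0, n_arrays = 2)
  g <- build_genome(list(sp), 1e6, sex = "male", seed = 3)
  tr <- g$truth
  expect_equal(tr$rul, 4)
  expect_lt(abs(tr$proportion - 0.10) / 0.10, 0.02)
  expect_equal(tr$mean_divergence, 0)
  seg <- g$template$segments
  # exact conservation and 0-based half-open tiling
  expect_identical(seg$start[1], 0)
  expect_identical(seg$end[nrow(seg)], 1e6)
  expect_true(all(seg$start[-1] == seg$end[-nrow(seg)]))
  expect_equal(sum(seg$end - seg$start), 1e6)
  expect_equal(sum((seg$end - seg$start)[seg$label == "gata"]), tr$bases)
  expect_equal(nchar(g$template$sequence), 1e6)
  expect_error(build_genome(list(sat_family_spec("x", "GATA", 0.8),
                                 sat_family_spec("y", "ACGT", 0.2)),
                            1e5, sex = "male", seed = 1),
               class = "satkit_invalid_parameter")
})

test_that("y_linked families are emitted only into male genomes", {
  specs <- list(
    sat_family_spec("auto", generate_monomer(50, 0.6, 7), 0.05,
                    divergence_rate = 0.02),
    sat_family_spec("ylink", generate_monomer(40, 0.7, 8), 0.03,
                    divergence_rate = 0.01, compartment = "y_linked"))
  gm <- build_genome(specs, 5e5, sex = "male", seed = 11)
  gf <- build_genome(specs, 5e5, sex = "female", seed = 11)
  expect_gt(gm$truth$bases[gm$truth$family_id == "ylink"], 0)
  expect_identical(gf$truth$bases[gf$truth$family_id == "ylink"], 0L)
  expect_identical(gf$truth$proportion[gf$truth$family_id == "ylink"], 0)
  # sex asymmetry invariant: non-Y base counts identical at equal seed
  expect_identical(gm$truth$bases[gm$truth$family_id == "auto"],
                   gf$truth$bases[gf$truth$family_id == "auto"])
  expect_equal(nchar(gf$template$sequence), 5e5)
})

test_that("copy divergence is calibrated (within 20% relative for d <= 0.2)", {
  for (d in c(0.05, 0.1, 0.2)) {
    sp <- sat_family_spec("f", generate_monomer(50, 0.6, 1), 0.2,
                          divergence_rate = d, n_arrays = 3)
    g <- build_genome(list(sp), 1e5, sex = "male", seed = round(1000 * d))
    # 400 copies of a 50-mer: realised mean divergence close to d
    expect_gte(g$truth$n_copies, 200)
    expect_lt(abs(g$truth$mean_divergence - d) / d, 0.2)
  }
})

test_that("sample_reads respects coverage arithmetic and read geometry", {
  sp <- sat_family_spec("f", "GATAGATTA", 0.05, 0)
  g <- build_genome(list(sp), 1e6, sex = "male", seed = 1)
  rs <- sample_reads(g$template, 0.2, 101, 300, error_rate = 0, seed = 9)
  expect_lt(abs(rs$total_bases - 0.2 * 1e6) / (0.2 * 1e6), 0.05)
  expect_equal(n_pairs(rs), 990)  # round(0.2e6 / 202)
  expect_true(all(nchar(rs$read1) == 101), all(nchar(rs$read2) == 101))
  # mates come from opposite strands of one fragment: with zero error and a
  # pure-background genome, mate 2 must map on the reverse strand; spot-check
  # that reads are substrings of the genome or its reverse complement
  expect_true(grepl(rs$read1[1], g$template$sequence, fixed = TRUE))
  expect_true(grepl(revcomp(rs$read2[1]), g$template$sequence, fixed = TRUE))
  # zero coverage: empty set, no error
  rs0 <- sample_reads(g$template, 0, seed = 1)
  expect_equal(n_pairs(rs0), 0)
  expect_error(sample_reads(g$template, 0.1, 101, 150, seed = 1),
               class = "satkit_invalid_parameter")
})

test_that("FASTQ output is byte-identical for a fixed seed and round-trips", {
  sp <- sat_family_spec("f", "GATAGATTA", 0.1, 0.01)
  g <- build_genome(list(sp), 5e4, sex = "male", seed = 2)
  rs <- sample_reads(g$template, 0.3, 101, 300, 0.005, seed = 5)
  p1 <- write_read_fastq(rs, file.path(tempdir(), "rs_a"), gzip = FALSE)
  rs_again <- sample_reads(g$template, 0.3, 101, 300, 0.005, seed = 5)
  p2 <- write_read_fastq(rs_again, file.path(tempdir(), "rs_b"), gzip = FALSE)
  expect_identical(readLines(p1[1]), readLines(p2[1]))
  expect_identical(readLines(p1[2]), readLines(p2[2]))
  rt <- read_fastq_pairs(p1[1], p1[2], "f")
  expect_identical(rt$read1, rs$read1)
  expect_identical(rt$read2, rs$read2)
  expect_identical(rt$origin1, rs$origin1)
})

test_that("default_family_specs define the stated recovery world", {
  specs <- default_family_specs(123L)
  expect_length(specs, 8)
  expect_equal(vapply(specs, function(s) nchar(s$monomer), numeric(1)),
               c(166, 9, 120, 50, 83, 25, 130, 60))
  expect_equal(sum(vapply(specs, `[[`, numeric(1), "target_proportion")),
               0.1885)
  expect_equal(sum(vapply(specs, `[[`, character(1), "compartment") == "y_linked"), 1)
  expect_identical(specs[[2]]$monomer, "GATAGATTA")
  # one family below 50% A+T (the GC-rich one)
  ats <- at_content(vapply(specs, `[[`, character(1), "monomer"))
  expect_equal(sum(ats < 50), 1)
  expect_length(attr(specs, "decoys"), 1)
})
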