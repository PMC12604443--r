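test_that("clean_reads drops or keeps whole pairs, never orphans", {
  rs <- read_set("s",
                 read1 = c("ACGTACGTAC", "ACGTNCGTAC", "ACGT", "ACGTACGTAC"),
                 read2 = c("TTTTGGGGCC", "TTTTGGGGCC", "TTTTGGGGCC", "TGCN"),
                 read_length = 10)
  out <- clean_reads(rs, min_length = 5, max_n = 0)
  expect_equal(n_pairs(out), 1)  # pair 2 (N in mate 1), 3 (short), 4 (short+N) dropped
  expect_identical(out$read1, "ACGTACGTAC")
  expect_equal(out$total_bases, 20)
  # already-clean input is returned unchanged
  rs2 <- fixture_read_set(n = 10, len = 60)
  out2 <- clean_reads(rs2, min_length = 30, max_n = 0)
  expect_identical(out2$read1, rs2$read1)
  expect_identical(out2$id, rs2$id)
  # min_length beyond read length empties the set
  expect_equal(n_pairs(clean_reads(rs2, min_length = 100)), 0)
})

test_that("subsample_pairs is uniform-without-replacement, stable and paired", {
  rs <- fixture_read_set(n = 50, len = 60)
  s1 <- subsample_pairs(rs, 20, seed = 7)
  s2 <- subsample_pairs(rs, 20, seed = 7)
  expect_identical(s1$id, s2$id)
  expect_equal(n_pairs(s1), 20)
  expect_false(anyDuplicated(s1$id) > 0)
  # pairing preserved: mate i of the subsample is the original mate of that id
  m <- match(s1$id, rs$id)
  expect_identical(s1$read1, rs$read1[m])
  expect_identical(s1$read2, rs$read2[m])
  # n = available returns the identical multiset; n = 0 empties
  expect_identical(subsample_pairs(rs, 50, seed = 1)$id, rs$id)
  expect_equal(n_pairs(subsample_pairs(rs, 0, seed = 1)), 0)
  expect_error(subsample_pairs(rs, 51, seed = 1),
               class = "satkit_invalid_parameter")
})

test_that("clean-then-subsample commutes with subsampling the clean set", {
  rs <- fixture_read_set(n = 40, len = 60)  # all reads already clean
  a <- subsample_pairs(clean_reads(rs, min_length = 30), 15, seed = 3)
  b <- clean_reads(subsample_pairs(rs, 15, seed = 3), min_length = 30)
  expect_identical(a$id, b$id)
  expect_identical(a$read1, b$read1)
})

test_that("coverage_report reproduces the 271 Mb / 1187 Mb accounting", {
  cr <- coverage_report(271e6, 1187e6)
  expect_equal(cr$coverage, 271 / 1187)
  expect_identical(cr$coverage_display, "0.22")  # truncated, not rounded
  expect_true(cr$in_range)
  # boundary: exactly 0.50 lies inside the closed recommended interval
  cr2 <- coverage_report(593.5e6, 1187e6)
  expect_identical(cr2$coverage_display, "0.50")
  expect_true(cr2$in_range)
  cr3 <- coverage_report(0, 1187e6)
  expect_equal(cr3$coverage, 0)
  expect_false(cr3$in_range)
  expect_error(coverage_report(1, 0), class = "satkit_invalid_parameter")
})

test_that("interleaved FASTA hand-off keeps mate adjacency and origins", {
  rs <- fixture_read_set(n = 5, len = 60)
  rs$origin1 <- rep("background", 5)
  rs$origin2 <- rep("famX", 5)
  il <- interleaved_reads(rs)
  expect_length(il, 10)
  expect_identical(unname(il[1]), rs$read1[1])
  expect_identical(unname(il[2]), rs$read2[1])
  expect_match(names(il)[1], "/1$")
  expect_match(names(il)[2], "/2$")
  expect_identical(attr(il, "origin")[1:2], c("background", "famX"))
  path <- tempfile(fileext = ".fasta")
  write_interleaved_fasta(rs, path)
  back <- read_interleaved_fasta(path)
  expect_identical(unname(back), unname(il))
  expect_identical(names(back), names(il))
  expect_identical(attr(back, "origin"), attr(il, "origin"))
})
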