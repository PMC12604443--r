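make_catalog <- function(monomers, code, abundances = NULL) {
  if (is.null(abundances)) abundances <- rev(seq_along(monomers))
  fams <- lapply(seq_along(monomers), function(i)
    list(consensus = monomers[[i]], rul = nchar(monomers[[i]]),
         per_sample_abundance = c(ref = abundances[i])))
  rank_and_name(fams, species_code = code, reference_sample = "ref")
}

test_that("match_catalogs finds identical and diverged partners, symmetric", {
  m1 <- rand_dna(80, seed = 1)
  m2 <- rand_dna(120, seed = 2)
  m3 <- rand_dna(60, seed = 3)
  # catalog B carries m1 mutated to ~80% identity (16/80 substituted) and an
  # exact rotation of m2 on the other strand
  m1_div <- mutate_n(m1, 16, seed = 4)
  m2_rot <- revcomp(paste0(substr(m2, 41, 120), substr(m2, 1, 40)))
  A <- make_catalog(list(m1, m2, m3), "Aaa")
  B <- make_catalog(list(m1_div, m2_rot), "Bbb")
  mm <- match_catalogs(A, B, min_identity = 78.5)
  expect_equal(nrow(mm), 2)
  exact <- mm[mm$identity == 100, ]
  expect_equal(nrow(exact), 1)  # the rotated reverse complement of m2
  diverged <- mm[mm$identity < 100, ]
  expect_gte(diverged$identity, 78.5)
  expect_lte(diverged$identity, 85)
  # stricter threshold excludes the diverged pair
  mm85 <- match_catalogs(A, B, min_identity = 85)
  expect_equal(nrow(mm85), 1)
  # symmetry: swapping arguments yields the same pairs
  mm_rev <- match_catalogs(B, A, min_identity = 78.5)
  expect_setequal(paste(mm$family_a, mm$family_b),
                  paste(mm_rev$family_b, mm_rev$family_a))
  # unrelated families remain unmatched
  expect_false(any(grepl("-60$", c(mm$family_a, mm$family_b))))
})

test_that("shared_family_counts partitions families Venn-style", {
  mono <- lapply(1:10, function(i) rand_dna(50 + i, seed = 300 + i))
  A <- make_catalog(mono, "Aaa")
  B <- make_catalog(mono[1:7], "Bbb")
  cats <- list(A = A, B = B)
  counts <- shared_family_counts(match_all_catalogs(cats), cats)
  expect_equal(counts$n_families[counts$region == "A&B"], 7)
  expect_equal(counts$n_families[counts$region == "A"], 3)
  expect_equal(sum(counts$n_families), 10)
  # identical catalogs: everything shared
  cats2 <- list(A = make_catalog(mono[1:5], "Aaa"),
                B = make_catalog(mono[1:5], "Bbb"))
  counts2 <- shared_family_counts(match_all_catalogs(cats2), cats2)
  expect_equal(counts2$region, "A&B")
  expect_equal(counts2$n_families, 5)
})

test_that("flag_sex_biased reproduces the printed asymmetry calls", {
  ab <- data.frame(family = c("TrubSat002-9", "TrubSat001-166", "flat"),
                   male = c(3.77, 20.43, 1.0),
                   female = c(0.02, 5.48, 1.0))
  fl <- flag_sex_biased(ab, ratio_threshold = 10)
  # 3.77 / 0.02 = 188.5: the Y-linked GATA-variant family
  expect_equal(fl$ratio[1], 188.5)
  expect_true(fl$y_linked_candidate[1])
  # 20.43 / 5.48 = 3.73: autosomal copy-number polymorphism, not Y-linked
  expect_equal(fl$ratio[2], 20.43 / 5.48, tolerance = 1e-9)
  expect_false(fl$y_linked_candidate[2])
  expect_identical(fl$label[2], "copy_number_polymorphism")
  # equal abundance: balanced
  expect_false(fl$y_linked_candidate[3])
  expect_identical(fl$label[3], "balanced")
  # present in male, absent in female: always flagged, finite ratio
  fl2 <- flag_sex_biased(data.frame(family = "x", male = 0.005, female = 0))
  expect_true(fl2$y_linked_candidate)
  expect_true(is.finite(fl2$ratio))
})

test_that("presence matrix marks detection from abundance", {
  ab <- data.table::data.table(
    name = c("f1", "f1", "f2", "f2"),
    sample = c("male", "female", "male", "female"),
    percent = c(2, 1, 0.5, 0))
  pm <- presence_matrix(ab)
  expect_true(pm$detected_male[pm$name == "f2"])
  expect_false(pm$detected_female[pm$name == "f2"])
  expect_equal(pm$female[pm$name == "f1"], 1)
})
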