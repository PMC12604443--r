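test_that("at_content counts A+T in percent", {
  expect_equal(at_content("GATA"), 75)
  expect_equal(at_content("GC"), 0)
  expect_equal(at_content("GATAGATTA"), 100 * 7 / 9, tolerance = 1e-9)
  expect_error(at_content(""), class = "satkit_invalid_parameter")
})

test_that("dedupe merges identical, variant and period-multiple monomers", {
  cand <- function(monomer, ab, id) list(monomer = monomer, rul = nchar(monomer),
                                         circularity = 0.9,
                                         abundance_percent = ab,
                                         cluster_id = id, n_reads = 10L)
  # identical canonical monomers collapse
  fams <- dedupe_candidates(list(cand("GATAGATTA", 3, "CL1"),
                                 cand("AATCTATCT", 1, "CL2")))
  expect_length(fams, 1)
  expect_equal(fams[[1]]$abundance_percent, 4)
  # GATA and its 9-bp expansion merge under the period-multiple rule
  fams2 <- dedupe_candidates(list(cand("GATAGATTA", 3, "CL1"),
                                  cand("GATA", 1, "CL2")))
  expect_length(fams2, 1)
  expect_equal(fams2[[1]]$rul, 9)  # highest-abundance member keeps consensus
  # unrelated monomers stay separate
  fams3 <- dedupe_candidates(list(cand(rand_dna(60, seed = 1), 2, "CL1"),
                                  cand(rand_dna(60, seed = 2), 1, "CL2")))
  expect_length(fams3, 2)
})

test_that("rank_and_name follows the abundance-rank / RUL convention", {
  fam <- function(mono, ab) list(consensus = mono, rul = nchar(mono),
                                 per_sample_abundance = ab)
  fams <- list(fam(rand_dna(9, seed = 3), c(male = 3.77, female = 0.02)),
               fam(rand_dna(166, seed = 4), c(male = 20.43, female = 5.48)),
               fam(rand_dna(25, seed = 5), c(male = 0.5, female = 0.6)))
  cat <- rank_and_name(fams, species_code = "Trub", reference_sample = "male")
  expect_equal(cat$families$name,
               c("TrubSat001-166", "TrubSat002-9", "TrubSat003-25"))
  expect_equal(cat$families$rank, 1:3)
  # ties break by smaller rul, then lexicographic consensus
  t1 <- fam(paste0(strrep("C", 19), "A"), c(male = 1))
  t2 <- fam("ACGTACGTAA", c(male = 1))
  t3 <- fam("AAGTACGTAC", c(male = 1))
  cat2 <- rank_and_name(list(t1, t2, t3), "X", "male")
  expect_equal(cat2$families$rul, c(10L, 10L, 20L))
  expect_equal(cat2$families$consensus[1:2],
               sort(c(t2$consensus, t3$consensus)))
  # renaming is stable: same input, same names
  cat3 <- rank_and_name(fams, species_code = "Trub", reference_sample = "male")
  expect_identical(cat$families$name, cat3$families$name)
  expect_error(rank_and_name(list(fam(rand_dna(10, seed = 1), c(other = 1))),
                             "X", "male"),
               class = "satkit_invalid_parameter")
})

test_that("catalog FASTA round-trips losslessly", {
  fams <- lapply(c(166, 9, 25), function(L)
    list(consensus = rand_dna(L, seed = L), rul = L,
         per_sample_abundance = c(male = 100 / L)))
  cat <- rank_and_name(fams, "Sim", "male")
  path <- tempfile(fileext = ".fasta")
  write_catalog_fasta(cat, path)
  back <- read_catalog_fasta(path, reference_sample = "male")
  expect_identical(back$families$name, cat$families$name)
  expect_identical(back$families$consensus, cat$families$consensus)
  expect_identical(back$families$rul, cat$families$rul)
  expect_identical(back$species_code, "Sim")
})

test_that("catalog TSV marks families not detected in a sample as ND", {
  fams <- list(list(consensus = rand_dna(40, seed = 1), rul = 40,
                    per_sample_abundance = c(male = 2, female = 0)))
  cat <- rank_and_name(fams, "Sim", "male")
  path <- tempfile(fileext = ".tsv")
  write_catalog_tsv(cat, path)
  tab <- read.delim(path)
  expect_identical(tab$abundance_female, "ND")
  expect_false(tab$abundance_male == "ND")
})
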