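test_that("edges require shared canonical k-mers, strand-symmetrically", {
  r <- rand_dna(101, seed = 1)
  # two identical 101-mers: 81 distinct shared 21-mers -> edge
  g <- build_read_graph(c(r, r), k = 21, min_shared = 10)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$shared, 81)
  # read vs its reverse complement: canonical k-mers make the edge
  g2 <- build_read_graph(c(r, revcomp(r)), k = 21, min_shared = 10)
  expect_equal(nrow(g2$edges), 1)
  expect_equal(g2$edges$shared, 81)
  # two unrelated reads share (essentially) no k-mer
  g3 <- build_read_graph(c(r, rand_dna(101, seed = 2)), k = 21, min_shared = 1)
  expect_equal(nrow(g3$edges), 0)
  expect_error(build_read_graph(c("ACGT"), k = 21),
               class = "satkit_invalid_parameter")
})

test_that("low-complexity reads connect via the adaptive threshold", {
  # reads from a (GATAGATTA)n array hold only 9 distinct canonical 21-mers,
  # fewer than min_shared = 10; the pair must still be joined
  arr <- strrep("GATAGATTA", 40)
  reads <- c(substr(arr, 1, 101), substr(arr, 10, 110))
  g <- build_read_graph(reads, k = 21, min_shared = 10)
  expect_equal(nrow(g$edges), 1)
})

test_that("clusters are components ordered by abundance; singletons dropped", {
  a <- rand_dna(101, seed = 10)
  b <- rand_dna(101, seed = 20)
  reads <- c(rep(a, 100), rep(b, 10), vapply(1:890, function(i)
    rand_dna(101, seed = 1000 + i), character(1)))
  cl <- cluster_reads(build_read_graph(reads, k = 21, min_shared = 10))
  expect_equal(cl$table$n_reads, c(100, 10))
  expect_equal(cl$table$abundance_percent, c(10, 1))
  expect_equal(cl$table$cluster_id, c("CL0001", "CL0002"))
  # disjointness and completeness
  mem <- unlist(cl$members)
  expect_false(anyDuplicated(mem) > 0)
  expect_lte(length(mem), length(reads))
  # empty graph -> empty collection
  cl0 <- cluster_reads(build_read_graph(reads[200:250], k = 21))
  expect_equal(length(cl0$members), 0)
})

test_that("component structure is invariant under read input order", {
  set.seed(99)
  fam <- strrep(generate_monomer(40, 0.6, 5), 20)
  reads <- c(tile_reads(fam, 30, seed = 2),
             vapply(1:40, function(i) rand_dna(101, seed = 2000 + i),
                    character(1)))
  part_of <- function(rd) {
    cl <- cluster_reads(build_read_graph(rd, k = 21, min_shared = 10))
    # canonical partition signature: sorted member sequences per cluster
    sort(vapply(cl$members, function(m)
      paste(sort(rd[m]), collapse = "|"), character(1)))
  }
  perm <- sample(length(reads))
  expect_identical(part_of(reads), part_of(reads[perm]))
})

test_that("filter_clusters is strictly 'exceeding'", {
  cl <- structure(list(
    members = list(1:2, 3:4),
    table = data.table::data.table(
      cluster_id = c("CL0001", "CL0002"),
      n_reads = c(2L, 2L),
      abundance_percent = c(0.001, 0.0011)),
    n_total_reads = 200000L, read_names = NULL, origin = NULL),
    class = "read_clusters")
  out <- filter_clusters(cl, min_abundance = 0.001)
  expect_equal(out$table$cluster_id, "CL0002")  # exactly-at-threshold dropped
  all_kept <- filter_clusters(cl, min_abundance = 0)
  expect_equal(nrow(all_kept$table), 2)
})
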