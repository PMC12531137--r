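# Association/similarity I/O, dataset summaries and configuration.

test_that("dense association files round-trip losslessly", {
  # identity 2x2
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("\td1\td2", "m1\t1\t0", "m2\t0\t1"), f)
  ds <- read_association(f, "dense")
  expect_equal(unname(ds$A), matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(ds$microbe_ids, c("m1", "m2"))

  # seeded random 10x20 matrix survives write -> read exactly
  set.seed(42)
  A <- matrix(rbinom(200, 1, 0.3), 10, 20)
  ds0 <- mda_dataset(A)
  g <- withr::local_tempfile(fileext = ".tsv")
  write_association(ds0, g, "dense")
  ds1 <- read_association(g, "dense")
  expect_identical(ds1$A, ds0$A)

  # auto-detection picks dense for a header-led file
  expect_identical(read_association(f)$A, ds$A)
})

test_that("edge-list association files round-trip and default absent pairs to 0", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("m1\td2\t1", f)
  ds <- read_association(f, "edgelist", microbe_ids = "m1",
                         drug_ids = c("d1", "d2"))
  expect_equal(unname(ds$A), matrix(c(0, 1), 1, 2))

  set.seed(7)
  A <- matrix(rbinom(200, 1, 0.2), 10, 20)
  A[1, 1] <- 1  # keep every id present via the dense declaration below
  ds0 <- mda_dataset(A)
  g <- withr::local_tempfile(fileext = ".tsv")
  write_association(ds0, g, "edgelist")
  ds1 <- read_association(g, "edgelist", microbe_ids = ds0$microbe_ids,
                          drug_ids = ds0$drug_ids)
  expect_identical(ds1$A, ds0$A)
})

test_that("malformed association input is rejected with a useful error", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("\td1", "m1\t2"), f)
  expect_error(read_association(f, "dense"), "non-binary")

  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("m1\td1\t1", "m1\td1\t0"), g)
  expect_error(read_association(g, "edgelist"), "conflicting")

  h <- withr::local_tempfile(fileext = ".tsv")
  writeLines("m1\td9\t1", h)
  expect_error(read_association(h, "edgelist", microbe_ids = "m1",
                                drug_ids = "d1"), "d9")
  expect_error(mda_dataset(matrix(0.5, 1, 1)), "0 or 1")
  expect_error(mda_dataset(matrix(0, 2, 2), c("a", "a"), c("x", "y")),
               "duplicate")
})

test_that("dataset_summary matches a brute-force count and the known densities", {
  # reference dataset sizes and their printed densities
  mk <- function(nm, nd, k) {
    A <- matrix(0, nm, nd)
    A[seq_len(k)] <- 1
    mda_dataset(A)
  }
  expect_equal(dataset_summary(mk(173, 1373, 2470))$density_percent, 1.04)
  expect_equal(dataset_summary(mk(95, 175, 933))$density_percent, 5.61)
  expect_equal(dataset_summary(mk(2, 2, 0))$density_percent, 0)

  set.seed(5)
  A <- matrix(rbinom(600, 1, 0.1), 20, 30)
  s <- dataset_summary(mda_dataset(A))
  brute <- 0
  for (i in 1:20) for (j in 1:30) brute <- brute + (A[i, j] != 0)
  expect_equal(s$n_associations, brute)
  expect_equal(s$density_percent, round(100 * brute / 600, 2))
})

test_that("similarity reading reindexes, validates and symmetrizes", {
  ids <- c("a", "b", "c")
  S <- matrix(c(1, .2, .3, .2, 1, .4, .3, .4, 1), 3, dimnames = list(ids, ids))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_similarity(S, f)
  expect_equal(read_similarity(f, ids), S)

  # permuted rows/columns come back in canonical order with values kept
  perm <- c("c", "a", "b")
  g <- withr::local_tempfile(fileext = ".tsv")
  write_similarity(S[perm, perm], g)
  expect_equal(read_similarity(g, ids), S)

  # asymmetric input is averaged with a warning
  asym <- matrix(c(1, 0.4, 0.2, 1), 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("a", "b")))
  h <- withr::local_tempfile(fileext = ".tsv")
  write_similarity(asym, h)
  expect_warning(out <- read_similarity(h, c("a", "b")), "symmetrizing")
  expect_equal(unname(out), matrix(c(1, 0.3, 0.3, 1), 2))

  expect_error(validate_similarity(matrix(c(1, 2, 2, 1), 2)), "\\[0, 1\\]")
  expect_error(read_similarity(f, c("a", "b", "zzz")), "zzz")
})

test_that("configuration defaults, YAML round-trip and overrides work", {
  cfg <- mda_config()
  expect_equal(cfg$embed_dim, 256L)
  expect_equal(cfg$epochs, 400L)
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$alpha, 0.11)
  expect_equal(cfg$lambda_m, 1)
  expect_equal(cfg$n_heads, 5L)
  expect_equal(cfg$hgcn_layers, 2L)
  expect_equal(cfg$knn_k, 13L)
  expect_equal(cfg$ko_c, 9L)

  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("embed_dim: 16", "epochs: 7", "n_heads: 2"), f)
  cfg2 <- read_config(f)
  expect_equal(cfg2$embed_dim, 16L)
  expect_equal(cfg2$epochs, 7L)
  cfg3 <- read_config(f, epochs = 9)
  expect_equal(cfg3$epochs, 9L)
  writeLines("not_a_field: 1", f)
  expect_error(read_config(f), "unknown config")
  expect_error(mda_config(embed_dim = 4, n_heads = 8), "n_heads")
})
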