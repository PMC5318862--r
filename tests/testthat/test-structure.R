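test_that("patristic distances match brute-force path sums", {
  dm <- patristic_matrix(t4())
  expect_equal(dm["A", "B"], 2)
  expect_equal(dm["A", "C"], 4)
  expect_equal(dm["A", "A"], 0)
  for (seed in 1:20) {
    tr <- random_tree(sample(4:15, 1), seed)
    dm <- patristic_matrix(tr)
    expect_equal(dm, t(dm))
    o <- oracle_patristic(tr)
    expect_equal(dm[rownames(o), colnames(o)], o, tolerance = 1e-9)
  }
  nolen <- ape::rtree(5); nolen$edge.length <- NULL
  expect_error(patristic_matrix(nolen), "missing branch lengths")
})

test_that("mpd and mntd reproduce hand-computed fixture values", {
  dm <- patristic_matrix(t4())
  expect_equal(mpd(c("A", "B", "C"), dm), 10 / 3)
  expect_equal(mpd(c("A", "B"), dm), 2)
  expect_equal(mntd(c("A", "B", "C"), dm), 8 / 3)
  expect_equal(mntd(c("A", "B", "C", "D"), dm), 2)
  expect_equal(mntd(c("C", "D"), dm), 2)
  expect_error(mpd("A", dm), "fewer than 2")
  expect_error(mntd("A", dm), "fewer than 2")
  expect_error(mpd(c("A", "zz"), dm), "missing")
})

test_that("mpd/mntd agree with independent loops on random draws", {
  for (seed in 1:25) {
    tr <- random_tree(sample(5:20, 1), seed)
    dm <- patristic_matrix(tr)
    comm <- withr::with_seed(seed + 1000,
                             sample(tr$tip.label,
                                    sample(2:ape::Ntip(tr), 1)))
    expect_equal(mpd(comm, dm), oracle_mpd(comm, dm), tolerance = 1e-9)
    expect_equal(mntd(comm, dm), oracle_mntd(comm, dm), tolerance = 1e-9)
  }
})

test_that("ses_index applies the clustering sign and rank p-value", {
  nulls <- c(rnorm(997, 3, 0.5), 3 - 0.5, 3 + 0.5)
  s <- ses_index(2, nulls, flip_sign = TRUE)
  expect_equal(s$ses, -(2 - mean(nulls)) / sd(nulls))
  expect_gt(s$ses, 0)  # smaller than null => clustering => positive

  s2 <- ses_index(5, rep(5, 99), flip_sign = TRUE)
  expect_true(s2$degenerate)
  expect_true(is.na(s2$ses))
  expect_equal(s2$p, 1)

  nulls3 <- seq(2.001, 3, length.out = 999)
  s3 <- ses_index(2, nulls3, flip_sign = TRUE)
  expect_equal(s3$p, 1 / 1000)
  expect_error(ses_index(1, numeric()), "empty")
})

test_that("the tip-shuffle null stays within same-size community bounds", {
  # every shuffled community is a same-size subset, so null values must lie
  # within the exhaustive min/max over subsets (pool <= 8, exhaustive)
  tr <- simulate_tree(8, "yule", seed = 9)
  dm <- patristic_matrix(tr)
  comm <- tr$tip.label[c(1, 3, 5)]
  mat <- matrix(0L, 1, 8, dimnames = list("r1", tr$tip.label))
  mat[1, comm] <- 1L
  res <- analyze_structure(tr, mat, n_perm = 199, seed = 4)
  subsets <- utils::combn(tr$tip.label, 3, simplify = FALSE)
  mpd_rng <- range(vapply(subsets, oracle_mpd, 0, dm = dm))
  mntd_rng <- range(vapply(subsets, oracle_mntd, 0, dm = dm))
  nri <- res[res$metric == "NRI", ]
  nti <- res[res$metric == "NTI", ]
  expect_gte(nri$null_mean, mpd_rng[1])
  expect_lte(nri$null_mean, mpd_rng[2])
  expect_gte(nti$null_mean, mntd_rng[1])
  expect_lte(nti$null_mean, mntd_rng[2])
})

test_that("NRI/NTI are invariant to relabeling and branch-length scaling", {
  tr <- simulate_tree(30, "yule", seed = 2)
  mat <- simulate_communities(
    tr, list(r1 = community_spec("clustered", 8),
             r2 = community_spec("random", 8)), seed = 5)
  base <- analyze_structure(tr, mat, n_perm = 199, seed = 7)

  # uniform branch-length scaling: SES is scale-free
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 7.3
  scaled <- analyze_structure(tr2, mat, n_perm = 199, seed = 7)
  expect_equal(scaled$ses, base$ses, tolerance = 1e-9)
  expect_equal(scaled$p, base$p)

  # permuting taxon identities consistently in tree and matrix
  perm <- withr::with_seed(11, sample(tr$tip.label))
  tr3 <- tr; tr3$tip.label <- perm[match(tr$tip.label, tr$tip.label)]
  relab <- stats::setNames(perm, tr$tip.label)
  tr3 <- tr; tr3$tip.label <- unname(relab[tr$tip.label])
  mat3 <- mat; colnames(mat3) <- unname(relab[colnames(mat)])
  relabelled <- analyze_structure(tr3, mat3[, sort(colnames(mat3))],
                                  n_perm = 199, seed = 7)
  expect_equal(relabelled$observed, base$observed, tolerance = 1e-9)
})

test_that("a community equal to the whole pool is degenerate", {
  tr <- simulate_tree(10, "yule", seed = 3)
  mat <- matrix(1L, 1, 10, dimnames = list("all", tr$tip.label))
  res <- analyze_structure(tr, mat, n_perm = 99, seed = 1)
  expect_true(all(res$degenerate))
  expect_true(all(is.na(res$ses)))
  expect_true(all(res$p == 1))
})

test_that("tiny communities yield degenerate rows, oversized pools error", {
  tr <- simulate_tree(10, "yule", seed = 3)
  mat <- matrix(0L, 2, 10, dimnames = list(c("r1", "r2"), tr$tip.label))
  mat[1, 1:4] <- 1L
  mat[2, 5] <- 1L  # singleton region
  res <- analyze_structure(tr, mat, n_perm = 49, seed = 1)
  expect_true(all(res$degenerate[res$region == "r2"]))
  expect_false(any(res$degenerate[res$region == "r1"]))
  expect_error(analyze_structure(tr, mat, pool = tr$tip.label[1:2]),
               "outside the pool")
})

test_that("structure analysis is bit-identical under a fixed seed", {
  tr <- simulate_tree(40, "yule", seed = 8)
  mat <- simulate_communities(
    tr, list(a = community_spec("clustered", 10),
             b = community_spec("overdispersed", 10)), seed = 2)
  r1 <- analyze_structure(tr, mat, n_perm = 99, seed = 123)
  r2 <- analyze_structure(tr, mat, n_perm = 99, seed = 123)
  expect_identical(r1, r2)
})

test_that("clustered communities score NRI > 0, overdispersed < 0", {
  tr <- simulate_tree(100, "yule", seed = 21)
  mat <- simulate_communities(
    tr, list(cl = community_spec("clustered", 20),
             ov = community_spec("overdispersed", 20)), seed = 22)
  res <- analyze_structure(tr, mat, n_perm = 199, seed = 23)
  expect_gt(res$ses[res$region == "cl" & res$metric == "NRI"], 0)
  expect_lt(res$ses[res$region == "ov" & res$metric == "NRI"], 0)
})
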