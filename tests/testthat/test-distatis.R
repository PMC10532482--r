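test_that("double centering matches the hand-evaluated 2x2 example", {
  d <- its2_dist(matrix(c(0, 2, 2, 0), 2), c("a", "b"))
  s <- double_center(d, square_first = FALSE)
  expect_equal(s, matrix(c(0.5, -0.5, -0.5, 0.5), 2), ignore_attr = TRUE)
  expect_equal(double_center(its2_dist(matrix(0, 2, 2, dimnames =
    list(c("a", "b"), c("a", "b"))))), matrix(0, 2, 2), ignore_attr = TRUE)
  expect_error(double_center(d, masses = c(0.6, 0.6)), "sum to 1")
})

test_that("centering recovers squared Euclidean distances", {
  set.seed(3)
  for (r in 1:10) {
    d <- random_euclidean_dist(6)
    s <- double_center(d, square_first = TRUE)
    rec <- outer(diag(s), diag(s), `+`) - 2 * s
    expect_equal(rec, d$values^2, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("MFA normalization scales the top eigenvalue to one", {
  s <- diag(c(2, 1))
  ns <- mfa_normalize(s)
  expect_equal(ns$lambda1, 2)
  expect_equal(eigen(ns$matrix)$values, c(1, 0.5))
  # idempotence
  expect_equal(mfa_normalize(ns$matrix)$matrix, ns$matrix)
  expect_error(mfa_normalize(matrix(0, 2, 2)), "degenerate")
})

test_that("RV coefficient has the expected values", {
  s <- diag(2)
  expect_equal(rv_coefficient(s, s), 1)
  expect_equal(rv_coefficient(diag(2), diag(c(1, 0))), 1 / sqrt(2))
  expect_equal(round(rv_coefficient(diag(2), diag(c(1, 0))), 6), 0.707107)
  expect_equal(rv_coefficient(diag(c(1, 0)), diag(c(0, 1))), 0)
  expect_error(rv_coefficient(matrix(0, 2, 2), diag(2)), "zero-norm")
})

test_that("identical tables get equal weights and reproduce the table", {
  set.seed(4)
  d <- random_euclidean_dist(5)
  res <- distatis(list(d, d, d))
  expect_equal(res$alpha, rep(1 / 3, 3))
  expect_equal(res$rv_matrix, matrix(1, 3, 3))
  expect_equal(res$compromise, res$normalized[[1]], tolerance = 1e-12)
  # compromise distances proportional to squared input distances
  ratio <- res$compromise_distance$values / d$values^2
  off <- ratio[upper.tri(ratio)]
  expect_lt(diff(range(off)), 1e-10)
})

test_that("three-taxon example matches an independent step-by-step oracle", {
  d1 <- its2_dist(matrix(c(0, 1, 2, 1, 0, 1.5, 2, 1.5, 0), 3),
                  c("a", "b", "c"))
  d2 <- its2_dist(matrix(c(0, 0.8, 1.2, 0.8, 0, 2, 1.2, 2, 0), 3),
                  c("a", "b", "c"))
  # --- independent re-derivation with explicit arithmetic ---
  centre <- function(dd) {
    delta <- dd^2
    j <- diag(3) - matrix(1 / 3, 3, 3)
    s <- -0.5 * j %*% delta %*% j
    s / eigen(s, symmetric = TRUE)$values[1]
  }
  s1 <- centre(d1$values)
  s2 <- centre(d2$values)
  rv <- sum(s1 * s2) / sqrt(sum(s1 * s1) * sum(s2 * s2))
  cmat <- matrix(c(1, rv, rv, 1), 2)
  ev <- eigen(cmat, symmetric = TRUE)$vectors[, 1]
  ev <- abs(ev)
  alpha_expected <- ev / sum(ev)      # = c(0.5, 0.5) by symmetry of C
  splus_expected <- alpha_expected[1] * s1 + alpha_expected[2] * s2
  # --- package path ---
  res <- distatis(list(d1, d2), square_first = TRUE)
  expect_equal(res$alpha, alpha_expected, tolerance = 1e-10)
  expect_equal(res$rv_matrix[1, 2], rv, tolerance = 1e-10)
  expect_equal(res$compromise, splus_expected, tolerance = 1e-10)
  dplus <- outer(diag(splus_expected), diag(splus_expected), `+`) -
    2 * splus_expected
  expect_equal(res$compromise_distance$values, dplus, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("compromise invariants hold on Euclidean fixtures", {
  set.seed(11)
  d1 <- random_euclidean_dist(8)
  d2 <- random_euclidean_dist(8)
  res <- distatis(list(d1, d2))
  expect_true(all(res$alpha > 0))
  expect_equal(sum(res$alpha), 1)
  expect_true(all(res$rv_matrix >= 0 & res$rv_matrix <= 1 + 1e-12))
  expect_equal(diag(res$rv_matrix), c(1, 1))
  expect_true(isSymmetric(res$compromise))
  expect_gte(min(eigen(res$compromise, only.values = TRUE)$values), -1e-8)
  expect_equal(unname(diag(res$compromise_distance$values)), rep(0, 8))
})

test_that("weights are equivariant under taxon relabeling", {
  set.seed(12)
  d1 <- random_euclidean_dist(6)
  d2 <- random_euclidean_dist(6)
  res <- distatis(list(d1, d2))
  perm <- sample(6)
  p1 <- its2_dist(d1$values[perm, perm], d1$labels[perm])
  p2 <- its2_dist(d2$values[perm, perm], d2$labels[perm])
  resp <- distatis(list(p1, p2))
  expect_equal(resp$alpha, res$alpha, tolerance = 1e-10)
  expect_equal(resp$compromise_distance$values[d1$labels, d1$labels],
               res$compromise_distance$values, tolerance = 1e-10)
})

test_that("blending one table toward the other raises the RV coefficient", {
  set.seed(14)
  d1 <- random_euclidean_dist(7)
  d2 <- random_euclidean_dist(7, labels = d1$labels)
  rvs <- vapply(seq(0, 1, by = 0.25), function(t) {
    blend <- its2_dist((1 - t) * d2$values + t * d1$values, d1$labels)
    res <- distatis(list(d1, blend))
    res$rv_matrix[1, 2]
  }, 0)
  expect_true(all(diff(rvs) >= -1e-9))
})

test_that("label mismatches are reported", {
  d1 <- random_euclidean_dist(4, labels = c("a", "b", "c", "d"))
  d2 <- random_euclidean_dist(4, labels = c("a", "b", "c", "e"))
  expect_error(distatis(list(d1, d2)), "label mismatch")
})

test_that("compromise_to_distance implements the centering identity", {
  expect_equal(compromise_to_distance(diag(2), c("a", "b"))$values["a", "b"],
               2)
  expect_equal(compromise_to_distance(matrix(0, 2, 2), c("a", "b"))$values,
               matrix(0, 2, 2), ignore_attr = TRUE)
  expect_error(compromise_to_distance(matrix(c(0, 1, 1, 0), 2),
                                      c("a", "b")),
               "not positive semidefinite")
})
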