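test_that("compute_rdm matches closed-form distances", {
  # identical rows -> 0 for every measure
  x <- pattern_set(rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(4, 0, 1)))
  for (m in c("correlation", "euclidean")) {
    r <- compute_rdm(x, m)
    expect_equal(r$d[pair_index(1, 2, 3)], 0, tolerance = 1e-12)
  }
  r <- compute_rdm(x, "mahalanobis", noise_covariance = diag(3))
  expect_equal(r$d[pair_index(1, 2, 3)], 0, tolerance = 1e-12)

  # perfect anticorrelation -> 1 - (-1) = 2
  y <- pattern_set(rbind(a = c(1, 2, 5), b = -c(1, 2, 5)))
  expect_equal(compute_rdm(y, "correlation")$d, 2)

  # Pythagorean euclidean
  z <- pattern_set(rbind(a = c(0, 0), b = c(3, 4)))
  expect_equal(compute_rdm(z, "euclidean")$d, 5)

  # mahalanobis with identity covariance = euclidean
  ps <- random_pattern_set(6, 4, seed = 11)
  expect_equal(compute_rdm(ps, "mahalanobis", noise_covariance = diag(4))$d,
               compute_rdm(ps, "euclidean")$d, tolerance = 1e-12)
})

test_that("compute_rdm output satisfies the RDM invariants on random input", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(3:9, 1); p <- sample(3:7, 1)
    ps <- random_pattern_set(n, p, seed = 100 + i)
    cv <- crossprod(matrix(rnorm(4 * p * p), 4 * p, p)) / (4 * p)
    for (m in c("correlation", "euclidean")) {
      r <- compute_rdm(ps, m)
      expect_length(r$d, n * (n - 1) / 2)
      expect_true(all(r$d >= 0))
      sq <- rdm_square(r)
      expect_equal(sq, t(sq))
      expect_equal(diag(sq), rep(0, n), ignore_attr = TRUE)
    }
    r <- compute_rdm(ps, "mahalanobis", noise_covariance = cv)
    expect_true(all(r$d >= 0))
    # mahalanobis(cov) == euclidean on whitened patterns
    e <- eigen(cv, symmetric = TRUE)
    wps <- pattern_set(ps$data %*% e$vectors %*% diag(1 / sqrt(e$values)) %*%
                         t(e$vectors), ps$labels)
    expect_equal(r$d, compute_rdm(wps, "euclidean")$d, tolerance = 1e-8)
  }
})

test_that("measure-specific invariances hold", {
  ps <- random_pattern_set(7, 9, seed = 31)
  # correlation distance: per-pattern positive affine rescaling
  gains <- runif(7, 0.5, 3)
  shifts <- rnorm(7)
  scaled <- pattern_set(ps$data * gains + shifts, ps$labels)
  expect_equal(compute_rdm(scaled, "correlation")$d,
               compute_rdm(ps, "correlation")$d, tolerance = 1e-10)
  # euclidean: common constant vector added to all patterns
  shift <- matrix(rnorm(9), 7, 9, byrow = TRUE)
  shifted <- pattern_set(ps$data + shift, ps$labels)
  expect_equal(compute_rdm(shifted, "euclidean")$d,
               compute_rdm(ps, "euclidean")$d, tolerance = 1e-10)
})

test_that("compute_rdm errors name the offending condition / covariance", {
  bad <- pattern_set(rbind(good = c(1, 2, 3), flat = c(5, 5, 5)))
  expect_error(compute_rdm(bad, "correlation"), "flat")
  ps <- random_pattern_set(4, 3, seed = 41)
  singular <- matrix(1, 3, 3)
  expect_error(compute_rdm(ps, "mahalanobis", noise_covariance = singular),
               "singular")
  # regularization rescues it
  expect_s3_class(compute_rdm(ps, "mahalanobis", noise_covariance = singular,
                              regularize = 0.1), "rdm")
})

test_that("vectorize / squareform respect the canonical order", {
  expect_length(rdm_vectorize(rdm_square(runif(6))), 6)   # N=4 -> 6 pairs
  expect_length(rdm(0.3, labels = c("a", "b"))$d, 1)      # N=2 -> 1 pair
  # explicit order: (1,2),(1,3),(1,4),(2,3),(2,4),(3,4)
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 12; m[1, 3] <- m[3, 1] <- 13
  m[1, 4] <- m[4, 1] <- 14; m[2, 3] <- m[3, 2] <- 23
  m[2, 4] <- m[4, 2] <- 24; m[3, 4] <- m[4, 3] <- 34
  expect_equal(rdm_vectorize(m), c(12, 13, 14, 23, 24, 34))
  expect_equal(pair_index(c(1, 1, 1, 2, 2, 3), c(2, 3, 4, 3, 4, 4), 4), 1:6)
  # round trip on random symmetric zero-diagonal matrices
  set.seed(5)
  for (n in c(2, 5, 9)) {
    v <- runif(n * (n - 1) / 2)
    expect_equal(rdm_vectorize(rdm_square(v)), v)
  }
  # matches the dist() convention
  x <- matrix(rnorm(15), 5, 3)
  expect_equal(rdm_vectorize(as.matrix(dist(x))), as.numeric(dist(x)))
  # asymmetry rejected
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(rdm_vectorize(bad), "asymmetric")
  expect_error(rdm_vectorize(diag(2) * 3), "diagonal")
})

test_that("transforms behave as defined", {
  coll <- random_collection(3, 6, seed = 51)
  z <- transform_rdms(coll, "z")
  for (r in z$rdms) {
    expect_equal(mean(r$d), 0, tolerance = 1e-12)
    expect_equal(sd(r$d), 1, tolerance = 1e-12)
  }
  pc <- transform_rdms(coll, "percentile")
  for (k in seq_along(coll$rdms)) {
    expect_equal(pc$rdms[[k]]$d[which.max(coll$rdms[[k]]$d)], 100)
    expect_true(all(pc$rdms[[k]]$d >= 0 & pc$rdms[[k]]$d <= 100))
  }
  # midrank ties
  r4 <- rdm(c(0.1, 0.3, 0.3, 0.9, 0.05, 0.6), labels = cond_labels(4))
  expect_equal(transform_rdms(r4, "rank")$d[1:4], c(2, 3.5, 3.5, 6))
  expect_equal(rank(c(0.1, 0.3, 0.3, 0.9)), c(1, 2.5, 2.5, 4))
  # constant RDM rejected for rank-based transforms
  const <- rdm_collection(list(flat = rdm(rep(1, 3), cond_labels(3))))
  expect_error(transform_rdms(const, "z"), "flat")
})

test_that("average_rdms is the squared-distance minimizer", {
  coll <- random_collection(4, 5, seed = 61)
  avg <- average_rdms(coll)
  # identical inputs -> idempotence
  same <- rdm_collection(list(coll$rdms[[1]], coll$rdms[[1]]))
  expect_equal(average_rdms(same)$d, coll$rdms[[1]]$d)
  expect_equal(average_rdms(rdm_collection(list(
    rdm(c(0, 1, 0.4), c("a", "b", "c")),
    rdm(c(1, 0, 0.6), c("a", "b", "c")))))$d, c(0.5, 0.5, 0.5))
  # mean beats 100 random perturbations on mean squared distance
  cost <- function(v) mean(vapply(coll$rdms,
                                  function(r) sum((v - r$d)^2), numeric(1)))
  base <- cost(avg$d)
  set.seed(62)
  for (i in 1:100)
    expect_gt(cost(avg$d + rnorm(length(avg$d), sd = 0.05)), base)
  # mismatched condition sets refused
  other <- random_rdm(6, 1)
  expect_error(rdm_collection(list(coll$rdms[[1]], other)), "different")
})
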