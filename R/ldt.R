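#' Pooled error covariance from residuals
#'
#' Sample covariance of the residual rows (time points x channels),
#' optionally stabilized by diagonal loading. When there are no more
#' residual rows than channels the sample covariance is singular and
#' loading is forced (with a warning).
#'
#' @param residuals T x P numeric matrix of residuals.
#' @param regularize diagonal loading factor: `lambda = regularize *
#'   mean(diag(S))` is added to the diagonal of the sample covariance `S`.
#' @return P x P covariance matrix.
#' @export
pooled_error_covariance <- function(residuals, regularize = 0) {
  residuals <- as.matrix(residuals)
  if (nrow(residuals) <= 1L) stop("need more than one residual row")
  s <- stats::cov(residuals)
  if (regularize == 0 && nrow(residuals) <= ncol(residuals)) {
    warning("T <= P: sample covariance is singular; forcing diagonal ",
            "loading (regularize = 0.1)")
    regularize <- 0.1
  }
  if (regularize > 0) {
    load <- mean(diag(s))
    if (load == 0) load <- 1      # all-zero residuals: fall back to identity
    s <- s + diag(regularize * load, ncol(s))
  }
  s
}

#' Fisher linear-discriminant weights
#'
#' The discriminant direction for separating two pattern estimates under
#' error covariance `sigma`: `w = sigma^-1 (p1 - p2)`.
#'
#' @param p1,p2 pattern vectors (length P).
#' @param sigma P x P error covariance; must be invertible (regularize
#'   beforehand, e.g. with [pooled_error_covariance()]).
#' @return weight vector of length P.
#' @export
fit_discriminant <- function(p1, p2, sigma) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  sigma <- as.matrix(sigma)
  if (length(p1) != length(p2) || nrow(sigma) != length(p1) ||
      ncol(sigma) != length(p1))
    stop("dimension mismatch between patterns and covariance")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-12)
    stop("singular covariance: regularize before fitting the discriminant")
  as.numeric(solve(sigma, p1 - p2))
}

#' Bundle two independent data partitions for LD-t computation
#'
#' The two partitions must come from independent data (disjoint runs or
#' sessions) and share condition labels and channel count. Partition 1 is
#' the training set (discriminant fit, error covariance); partition 2 is
#' the test set (contrast and its standard error).
#'
#' @param patterns1,patterns2 [pattern_set()] objects (condition estimates).
#' @param residuals1,residuals2 T x P residual matrices for the respective
#'   partitions.
#' @param dof2,dof1 residual degrees of freedom of each partition (e.g. T
#'   minus the number of regression columns for GLM estimates; default
#'   `nrow(residuals) - n_conditions`). `dof1` is only used when folds are
#'   swapped (see [ldt_rdm()]).
#' @param gram_inv2,gram_inv1 optional K x K matrix `(X'X)^-1` of the
#'   partition's design (condition columns only); scales the variance of a
#'   condition contrast. Default: identity (one independent unit-variance
#'   estimate per condition, so a pairwise contrast has variance scale 2).
#' @param regularize diagonal-loading factor for the pooled covariance.
#' @return Object of class `partitioned_data` (precomputes the pooled
#'   partition-1 covariance `sigma`).
#' @export
partitioned_data <- function(patterns1, patterns2, residuals1, residuals2,
                             dof2 = NULL, gram_inv2 = NULL,
                             dof1 = NULL, gram_inv1 = NULL,
                             regularize = 0) {
  stopifnot(inherits(patterns1, "pattern_set"),
            inherits(patterns2, "pattern_set"))
  if (!identical(patterns1$labels, patterns2$labels))
    stop("partitions must share condition labels (in order)")
  p <- ncol(patterns1$data)
  if (ncol(patterns2$data) != p)
    stop("partitions must share the channel count")
  residuals1 <- as.matrix(residuals1)
  residuals2 <- as.matrix(residuals2)
  if (ncol(residuals1) != p || ncol(residuals2) != p)
    stop("residual channel count does not match the patterns")
  k <- length(patterns1$labels)
  if (is.null(dof2)) dof2 <- nrow(residuals2) - k
  if (is.null(dof1)) dof1 <- nrow(residuals1) - k
  if (dof2 < 1L || dof1 < 1L)
    stop("residual degrees of freedom must be >= 1 in both partitions")
  if (is.null(gram_inv2)) gram_inv2 <- diag(1, k)
  if (is.null(gram_inv1)) gram_inv1 <- diag(1, k)
  gram_inv2 <- as.matrix(gram_inv2)
  gram_inv1 <- as.matrix(gram_inv1)
  if (any(dim(gram_inv2) != k) || any(dim(gram_inv1) != k))
    stop("gram_inv matrices must be ", k, " x ", k)
  sigma <- pooled_error_covariance(residuals1, regularize)
  sigma_swap <- pooled_error_covariance(residuals2, regularize)
  structure(list(patterns1 = patterns1, patterns2 = patterns2,
                 residuals1 = residuals1, residuals2 = residuals2,
                 sigma = sigma, sigma_swap = sigma_swap,
                 dof2 = dof2, gram_inv2 = gram_inv2,
                 dof1 = dof1, gram_inv1 = gram_inv1,
                 labels = patterns1$labels),
            class = "partitioned_data")
}

#' Linear-discriminant t value for one condition pair
#'
#' Crossvalidated, noise-normalized pattern separability: a Fisher linear
#' discriminant is fit to partition 1 (`w = sigma^-1 (p1 - p2)`, with
#' `sigma` pooled from partition-1 residuals), the partition-2 condition
#' contrast and residuals are projected onto `w`, and the t value is the
#' projected contrast divided by its standard error (error variance
#' estimated from the projected partition-2 residuals at the partition-2
#' residual degrees of freedom). Positive when the partition-2 contrast
#' agrees in direction with the discriminant; unlike a distance, it can be
#' negative, and it is t-distributed around 0 when the true pattern
#' separation is 0 — so `pt(t, dof, lower.tail = FALSE)` gives an instant
#' per-pair discriminability p-value.
#'
#' @param data a [partitioned_data()] object.
#' @param pair length-2 vector of condition labels or indices.
#' @param swap internal: fit on partition 2 and test on partition 1
#'   (used for fold symmetrization).
#' @return list with `t_value`, `dof`, `pair`.
#' @export
ld_t <- function(data, pair, swap = FALSE) {
  stopifnot(inherits(data, "partitioned_data"))
  idx <- resolve_pair(data$labels, pair)
  if (swap) {
    train <- data$patterns2; test <- data$patterns1
    test_res <- data$residuals1
    dof <- data$dof1
    gram <- data$gram_inv1
    sigma <- data$sigma_swap
  } else {
    train <- data$patterns1; test <- data$patterns2
    test_res <- data$residuals2
    dof <- data$dof2
    gram <- data$gram_inv2
    sigma <- data$sigma
  }
  w <- fit_discriminant(train$data[idx[1], ], train$data[idx[2], ], sigma)

  contrast <- sum((test$data[idx[1], ] - test$data[idx[2], ]) * w)
  proj_res <- as.numeric(test_res %*% w)
  if (dof < 1L) stop("nonpositive residual degrees of freedom")
  sigma2_proj <- sum(proj_res^2) / dof
  if (sigma2_proj == 0)
    stop("zero projected residual variance for pair (",
         data$labels[idx[1]], ", ", data$labels[idx[2]], ")")
  scale2 <- gram[idx[1], idx[1]] + gram[idx[2], idx[2]] -
    2 * gram[idx[1], idx[2]]
  t_value <- contrast / sqrt(sigma2_proj * scale2)
  list(t_value = t_value, dof = dof,
       pair = data$labels[idx])
}

resolve_pair <- function(labels, pair) {
  if (length(pair) != 2L) stop("pair must have exactly 2 conditions")
  if (is.character(pair)) {
    idx <- match(pair, labels)
    if (anyNA(idx)) stop("unknown condition label(s): ",
                         paste(pair[is.na(idx)], collapse = ", "))
  } else idx <- as.integer(pair)
  if (idx[1] == idx[2]) stop("pair must name two distinct conditions")
  if (any(idx < 1L | idx > length(labels)))
    stop("condition index out of range")
  idx
}

#' LD-t RDM over all condition pairs
#'
#' Computes the LD-t for every condition pair in both crossvalidation
#' directions (fit on partition 1 / test on partition 2, and the reverse)
#' and stores the fold average in the standard RDM layout with measure
#' `"ld_t"`. Entries may be negative; under the null they scatter
#' symmetrically around zero.
#'
#' @param data a [partitioned_data()] object.
#' @return an [rdm()] with measure `"ld_t"`.
#' @export
ldt_rdm <- function(data) {
  stopifnot(inherits(data, "partitioned_data"))
  labels <- data$labels
  n <- length(labels)
  if (n < 2L) stop("need at least 2 conditions")
  d <- numeric(n * (n - 1) / 2)
  pos <- 0L
  for (j in seq_len(n - 1L)) {
    for (i in seq.int(j + 1L, n)) {
      pos <- pos + 1L
      t12 <- tryCatch(ld_t(data, c(j, i))$t_value, error = function(e)
        stop("pair (", labels[j], ", ", labels[i], "): ",
             conditionMessage(e), call. = FALSE))
      t21 <- tryCatch(ld_t(data, c(j, i), swap = TRUE)$t_value,
                      error = function(e)
        stop("pair (", labels[j], ", ", labels[i], "): ",
             conditionMessage(e), call. = FALSE))
      d[pos] <- (t12 + t21) / 2
    }
  }
  rdm(d, labels = labels, measure = "ld_t")
}

#' Crossvalidated Mahalanobis contrast (reference statistic)
#'
#' The unnormalized crossvalidated distance underlying the LD-t:
#' `(p1a - p2a)' sigma^-1 (p1b - p2b)`, i.e. the partition-2 contrast
#' projected on the discriminant fit to partition 1. Exposed for
#' validation against [ld_t()].
#'
#' @inheritParams ld_t
#' @return numeric contrast value.
#' @export
crossval_mahalanobis <- function(data, pair) {
  stopifnot(inherits(data, "partitioned_data"))
  idx <- resolve_pair(data$labels, pair)
  d1 <- data$patterns1$data[idx[1], ] - data$patterns1$data[idx[2], ]
  d2 <- data$patterns2$data[idx[1], ] - data$patterns2$data[idx[2], ]
  as.numeric(d1 %*% solve(data$sigma, d2))
}
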