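#' @useDynLib repsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor sd dist rnorm runif
NULL

RDM_MEASURES <- c("correlation", "euclidean", "mahalanobis", "ld_t", "model",
                  "other")

#' Construct a pattern set
#'
#' A pattern set holds one subject's (or one data partition's) activity
#' estimates: one multichannel activity pattern per experimental condition.
#' Rows are conditions, columns are response channels (voxels, electrodes,
#' units).
#'
#' @param data numeric matrix, conditions x channels. Row names are used as
#'   condition labels when `labels` is not given.
#' @param labels character vector of unique condition labels (length
#'   `nrow(data)`).
#' @return An object of class `pattern_set` with elements `data` (the matrix,
#'   labels as row names) and `labels`.
#' @examples
#' ps <- pattern_set(matrix(rnorm(12), 4, 3), labels = c("a", "b", "c", "d"))
#' @export
pattern_set <- function(data, labels = rownames(data)) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("pattern data must be numeric")
  if (nrow(data) < 2L) stop("a pattern set needs at least 2 conditions")
  if (ncol(data) < 1L) stop("a pattern set needs at least 1 channel")
  if (anyNA(data)) stop("pattern data contains missing values")
  if (is.null(labels)) labels <- paste0("cond", seq_len(nrow(data)))
  labels <- as.character(labels)
  if (length(labels) != nrow(data))
    stop("number of labels (", length(labels), ") does not match number of ",
         "conditions (", nrow(data), ")")
  if (anyDuplicated(labels))
    stop("condition labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  rownames(data) <- labels
  structure(list(data = data, labels = labels), class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat("pattern_set:", nrow(x$data), "conditions x", ncol(x$data), "channels\n")
  invisible(x)
}

#' Construct a representational dissimilarity matrix (RDM) object
#'
#' The RDM is the central exchange object of the package: the vector of
#' pairwise dissimilarities between condition-evoked activity patterns.
#' Only the upper triangle is stored, in row-major order with the diagonal
#' excluded: pairs (1,2), (1,3), ..., (1,N), (2,3), ... This order is
#' identical to the one produced by [stats::dist()] and is used consistently
#' by every function in the package.
#'
#' @param dissimilarities numeric vector of length `N*(N-1)/2`, or a square
#'   symmetric matrix with zero diagonal (vectorized internally).
#' @param labels character vector of N condition labels.
#' @param measure one of `"correlation"`, `"euclidean"`, `"mahalanobis"`,
#'   `"ld_t"`, `"model"`, `"other"`. Dissimilarities must be non-negative for
#'   the three pattern distance measures; `ld_t` entries may be negative.
#' @return An object of class `rdm` with elements `d`, `labels`, `measure`.
#' @export
rdm <- function(dissimilarities, labels, measure = "other") {
  measure <- match.arg(measure, RDM_MEASURES)
  if (is.matrix(dissimilarities))
    dissimilarities <- rdm_vectorize(dissimilarities)
  d <- as.numeric(dissimilarities)
  if (anyNA(d)) stop("RDM dissimilarities contain missing values")
  n <- n_conditions_for_pairs(length(d))
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("vector of length ", length(d), " implies ", n, " conditions but ",
         length(labels), " labels were given")
  if (anyDuplicated(labels)) stop("condition labels must be unique")
  if (measure %in% c("correlation", "euclidean", "mahalanobis") &&
      any(d < -1e-12))
    stop("negative dissimilarities are not allowed for measure '", measure, "'")
  structure(list(d = d, labels = labels, measure = measure), class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat("rdm:", length(x$labels), "conditions,", length(x$d), "dissimilarities,",
      "measure =", x$measure, "\n")
  invisible(x)
}

n_conditions_for_pairs <- function(npairs) {
  n <- (1 + sqrt(1 + 8 * npairs)) / 2
  if (npairs < 1L || abs(n - round(n)) > 1e-9)
    stop("vector length ", npairs, " is not N*(N-1)/2 for any integer N")
  as.integer(round(n))
}

#' Vectorize a square RDM / restore the square form
#'
#' `rdm_vectorize` extracts the upper triangle of a square symmetric
#' zero-diagonal matrix in row-major order; `rdm_square` is its inverse.
#' For a symmetric matrix the row-major upper triangle coincides with the
#' column-major lower triangle, so this is the same pair order as
#' [stats::dist()].
#'
#' @param m square numeric matrix, symmetric with zero diagonal (checked to
#'   relative tolerance `tol`).
#' @param tol relative symmetry tolerance.
#' @return `rdm_vectorize`: numeric vector of length `N*(N-1)/2`.
#' @export
rdm_vectorize <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("RDM matrix must be square")
  scale <- max(abs(m), 1)
  if (max(abs(m - t(m))) > tol * scale)
    stop("matrix is asymmetric beyond tolerance (max |m - t(m)| = ",
         format(max(abs(m - t(m)))), ")")
  if (max(abs(diag(m))) > tol * scale)
    stop("matrix diagonal is not zero")
  m[lower.tri(m)]
}

#' @param v dissimilarity vector in the canonical order.
#' @param labels optional condition labels used as dimnames.
#' @return `rdm_square`: the N x N symmetric matrix, or `rdm_square(x)` for
#'   an `rdm` object.
#' @rdname rdm_vectorize
#' @export
rdm_square <- function(v, labels = NULL) {
  if (inherits(v, "rdm")) {
    labels <- v$labels
    v <- v$d
  }
  n <- n_conditions_for_pairs(length(v))
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m <- m + t(m)
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

#' Index of a condition pair inside the canonical dissimilarity vector
#'
#' @param i,j condition indices (1-based, i != j, order-free).
#' @param n number of conditions.
#' @return integer position of pair (i, j) in the vectorized upper triangle.
#' @export
pair_index <- function(i, j, n) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (any(lo == hi)) stop("diagonal entries are not stored")
  if (any(lo < 1L) || any(hi > n)) stop("condition index out of range")
  as.integer(n * (lo - 1) - lo * (lo - 1) / 2 + hi - lo)
}

#' Compute an RDM from activity patterns
#'
#' For each pair of conditions the chosen dissimilarity between their
#' activity patterns is computed: `correlation` is 1 minus the Pearson
#' correlation across channels; `euclidean` is the root sum of squared
#' channel differences (not normalized by channel count); `mahalanobis` is
#' the Euclidean distance after whitening channels by the inverse noise
#' covariance.
#'
#' @param patterns a [pattern_set()].
#' @param measure `"correlation"`, `"euclidean"` or `"mahalanobis"`.
#' @param noise_covariance P x P noise covariance, required for
#'   `mahalanobis`. If numerically singular it must be regularized
#'   (see `regularize`).
#' @param regularize diagonal loading factor: `lambda = regularize *
#'   mean(diag(noise_covariance))` is added to the diagonal. Default 0
#'   (no loading); singular covariances then raise an error.
#' @return An [rdm()] over the same condition labels.
#' @export
compute_rdm <- function(patterns, measure = c("correlation", "euclidean",
                                              "mahalanobis"),
                        noise_covariance = NULL, regularize = 0) {
  stopifnot(inherits(patterns, "pattern_set"))
  measure <- match.arg(measure)
  x <- patterns$data
  if (measure == "correlation") {
    if (ncol(x) < 2L)
      stop("correlation distance needs at least 2 channels")
    v <- apply(x, 1, sd)
    if (any(v == 0))
      stop("zero-variance pattern(s) with correlation measure: ",
           paste(patterns$labels[v == 0], collapse = ", "))
    d <- 1 - cor(t(x))
    d <- d[lower.tri(d)]
    d[d < 0] <- 0  # clip tiny negative rounding of 1 - cor
  } else {
    if (measure == "mahalanobis") {
      if (is.null(noise_covariance))
        stop("mahalanobis measure requires a noise_covariance")
      x <- whiten_patterns(x, noise_covariance, regularize)
    }
    d <- as.numeric(dist(x))
  }
  rdm(d, labels = patterns$labels, measure = measure)
}

# Whiten channels: x %*% C^{-1/2} so Euclidean distance afterwards equals
# the Mahalanobis distance under covariance C.
whiten_patterns <- function(x, covariance, regularize = 0) {
  covariance <- as.matrix(covariance)
  if (nrow(covariance) != ncol(x) || ncol(covariance) != ncol(x))
    stop("noise_covariance must be ", ncol(x), " x ", ncol(x))
  if (regularize > 0)
    covariance <- covariance +
      diag(regularize * mean(diag(covariance)), ncol(covariance))
  e <- eigen(covariance, symmetric = TRUE)
  if (min(e$values) <= max(e$values) * 1e-10)
    stop("noise covariance is singular; supply a regularization ",
         "(diagonal loading) factor")
  x %*% e$vectors %*% diag(1 / sqrt(e$values), length(e$values)) %*%
    t(e$vectors)
}

#' Bundle RDMs that share one condition set
#'
#' @param rdms list of [rdm()] objects with identical condition labels in
#'   identical order.
#' @param roles per-RDM role tag: `"subject_estimate"`, `"candidate"` or
#'   `"reference"`; recycled if length 1.
#' @param names optional RDM names (default: names of `rdms` or `rdm1..k`).
#' @return Object of class `rdm_collection`.
#' @export
rdm_collection <- function(rdms, roles = "subject_estimate", names = NULL) {
  if (inherits(rdms, "rdm")) rdms <- list(rdms)
  if (length(rdms) < 1L) stop("empty RDM collection")
  if (!all(vapply(rdms, inherits, TRUE, "rdm")))
    stop("all members must be rdm objects")
  ref <- rdms[[1]]$labels
  for (k in seq_along(rdms))
    if (!identical(rdms[[k]]$labels, ref))
      stop("RDM ", k, " has a different condition set or order")
  roles <- rep_len(match.arg(roles,
                             c("subject_estimate", "candidate", "reference"),
                             several.ok = TRUE),
                   length(rdms))
  if (is.null(names)) names <- base::names(rdms)
  if (is.null(names)) names <- paste0("rdm", seq_along(rdms))
  names(rdms) <- names
  structure(list(rdms = rdms, roles = roles, labels = ref),
            class = "rdm_collection")
}

#' @export
print.rdm_collection <- function(x, ...) {
  cat("rdm_collection:", length(x$rdms), "RDMs over",
      length(x$labels), "conditions (",
      paste(unique(x$roles), collapse = ", "), ")\n")
  invisible(x)
}

#' @export
length.rdm_collection <- function(x) length(x$rdms)

# All dissimilarity vectors as an n_rdms x n_pairs matrix.
collection_matrix <- function(collection) {
  do.call(rbind, lapply(collection$rdms, `[[`, "d"))
}

#' Transform the dissimilarities of each RDM in a collection
#'
#' `rank` replaces each dissimilarity vector by its ranks (midranks for
#' ties), `z` standardizes each vector to mean 0 and unit sd, and
#' `percentile` maps each entry to its percentile in `[0, 100]`. These
#' transforms precede averaging and noise-ceiling computation: after rank
#' (Spearman) or z (Pearson) transformation, squared Euclidean distance
#' between RDM vectors is proportional to the corresponding correlation
#' distance.
#'
#' @param collection an [rdm_collection()] (a single [rdm()] is accepted).
#' @param transform `"none"`, `"rank"`, `"z"` or `"percentile"`.
#' @return A collection (or single rdm) of the same shape.
#' @export
transform_rdms <- function(collection,
                           transform = c("none", "rank", "z", "percentile")) {
  transform <- match.arg(transform)
  single <- inherits(collection, "rdm")
  if (single) collection <- rdm_collection(list(collection))
  if (transform != "none") {
    for (k in seq_along(collection$rdms)) {
      d <- collection$rdms[[k]]$d
      if (transform %in% c("rank", "z", "percentile") && length(unique(d)) == 1L)
        stop("RDM '", names(collection$rdms)[k],
             "' has constant dissimilarities; '", transform,
             "' transform is undefined")
      collection$rdms[[k]]$d <- switch(
        transform,
        rank = rank(d),
        z = (d - mean(d)) / sd(d),
        percentile = 100 * (rank(d) - 1) / (length(d) - 1))
    }
  }
  if (single) collection$rdms[[1]] else collection
}

#' Average the RDMs of a collection
#'
#' Entrywise mean of the dissimilarity vectors after the requested
#' transform. With the rank (Spearman) or z (Pearson) transform the mean
#' RDM minimizes the average squared Euclidean distance to the transformed
#' single-subject RDMs and therefore maximizes the average correlation of
#' the respective type.
#'
#' @inheritParams transform_rdms
#' @return An [rdm()] with measure `"other"` (a derived average).
#' @export
average_rdms <- function(collection, transform = "none") {
  if (inherits(collection, "rdm")) collection <- rdm_collection(list(collection))
  collection <- transform_rdms(collection, transform)
  m <- collection_matrix(collection)
  rdm(colMeans(m), labels = collection$labels, measure = "other")
}
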