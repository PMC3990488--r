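#' Kendall's tau-a rank correlation
#'
#' tau-a is the proportion of pairs of observations that are consistently
#' ordered in both variables: `(concordant - discordant) / (n*(n-1)/2)`.
#' Pairs tied in either variable count in the denominator but in neither
#' tally, so tau-a penalizes predictions with tied values. This makes it the
#' recommended coefficient when candidate models predict tied dissimilarities
#' (categorical models); tau-b rescales ties away and — like Spearman —
#' overestimates such models.
#'
#' The production path is an O(n log n) merge-sort algorithm (compiled);
#' [kendall_tau_a_ref()] is a direct O(n^2) pair enumeration retained as an
#' independent reference.
#'
#' @param a,b numeric vectors of equal length n >= 2.
#' @return the coefficient, in `[-1, 1]`.
#' @export
kendall_tau_a <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop("length mismatch: ", length(a), " vs ", length(b))
  if (length(a) < 2L) stop("kendall_tau_a needs at least 2 values")
  if (anyNA(a) || anyNA(b)) stop("missing values are not supported")
  kendall_tau_a_cpp(a, b)
}

#' @rdname kendall_tau_a
#' @export
kendall_tau_a_ref <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop("length mismatch: ", length(a), " vs ", length(b))
  n <- length(a)
  if (n < 2L) stop("kendall_tau_a needs at least 2 values")
  sa <- sign(outer(a, a, `-`))
  sb <- sign(outer(b, b, `-`))
  prod <- (sa * sb)[lower.tri(sa)]
  (sum(prod == 1) - sum(prod == -1)) / (n * (n - 1) / 2)
}

#' Correlate two RDMs
#'
#' The coefficient is computed on the vectorized upper triangles only
#' (each condition pair enters once; diagonals never enter). Rank
#' correlations (`spearman`, `kendall_tau_a`) are recommended because a
#' model RDM is normally taken to predict only the rank order of the
#' dissimilarities.
#'
#' @param rdm1,rdm2 [rdm()] objects over the same conditions.
#' @param method `"pearson"`, `"spearman"` or `"kendall_tau_a"`.
#' @return the correlation coefficient.
#' @export
compare_rdms <- function(rdm1, rdm2,
                         method = c("spearman", "pearson", "kendall_tau_a")) {
  stopifnot(inherits(rdm1, "rdm"), inherits(rdm2, "rdm"))
  method <- match.arg(method)
  if (!identical(rdm1$labels, rdm2$labels))
    stop("RDMs have different condition sets or orders")
  corr_vec(rdm1$d, rdm2$d, method)
}

# correlation between two dissimilarity vectors; tau_a tolerates constant
# vectors (tau = 0), pearson/spearman do not (undefined).
corr_vec <- function(x, y, method) {
  if (method == "kendall_tau_a") return(kendall_tau_a(x, y))
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant dissimilarity vector: ", method,
         " correlation is undefined")
  cor(x, y, method = if (method == "pearson") "pearson" else "spearman")
}

#' Matrix of pairwise RDM correlations
#'
#' Compares every pair of RDMs in a collection, yielding a symmetric
#' matrix with unit diagonal — the step-2 overview of which brain and model
#' representations resemble each other.
#'
#' @param collection an [rdm_collection()] with >= 2 members.
#' @param method passed to [compare_rdms()].
#' @return Object of class `rdm_comparison_matrix`: list with `values`
#'   (M x M), `labels`, `method`.
#' @export
rdm_correlation_matrix <- function(collection,
                                   method = c("spearman", "pearson",
                                              "kendall_tau_a")) {
  stopifnot(inherits(collection, "rdm_collection"))
  method <- match.arg(method)
  m <- length(collection$rdms)
  if (m < 2L) stop("need at least 2 RDMs")
  nm <- names(collection$rdms)
  values <- diag(1, m)
  dimnames(values) <- list(nm, nm)
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      r <- tryCatch(
        compare_rdms(collection$rdms[[i]], collection$rdms[[j]], method),
        error = function(e) stop("comparing '", nm[i], "' with '", nm[j],
                                 "': ", conditionMessage(e), call. = FALSE))
      values[i, j] <- values[j, i] <- r
    }
  }
  structure(list(values = values, labels = nm, method = method),
            class = "rdm_comparison_matrix")
}

#' @export
print.rdm_comparison_matrix <- function(x, ...) {
  cat("rdm_comparison_matrix (", x$method, "):\n", sep = "")
  print(round(x$values, 3))
  invisible(x)
}
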