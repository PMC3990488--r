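#' Package-wide inference defaults
#'
#' Random-effects (signed-rank across subjects) inference requires 12 or
#' more subjects; the fixed-effects stimulus-label randomization test
#' requires 20 or more conditions. Both thresholds can be overridden
#' explicitly, with a logged notice.
#'
#' @return named list of default thresholds and resampling sizes.
#' @export
rsa_defaults <- function() {
  list(min_subjects_signed_rank = 12L,
       min_conditions_randomization = 20L,
       n_permutations = 10000L,
       n_bootstrap = 1000L)
}

#' Choose the default statistical tests for an analysis
#'
#' Implements the default decision process: with 12 or more subjects the
#' subject is treated as a random effect and both RDM relatedness and
#' pairwise candidate comparisons use signed-rank tests across subjects.
#' With fewer subjects but 20 or more conditions, relatedness is tested by
#' stimulus-label randomization (fixed effects) and candidate comparisons by
#' bootstrap resampling of the stimulus set. Any procedure can be requested
#' explicitly through `overrides`, except randomization below the condition
#' minimum, which is refused.
#'
#' @param n_subjects,n_conditions data shape.
#' @param overrides optional named list with any of `relatedness_test`,
#'   `comparison_test`, `bootstrap_unit`, `n_permutations`, `n_bootstrap`.
#' @param seed integer seed recorded in the plan and used by the stochastic
#'   procedures.
#' @return Object of class `test_plan`.
#' @export
select_tests <- function(n_subjects, n_conditions, overrides = NULL,
                         seed = 1L) {
  defaults <- rsa_defaults()
  if (n_subjects < 1L || n_conditions < 2L)
    stop("need n_subjects >= 1 and n_conditions >= 2")
  plan <- if (n_subjects >= defaults$min_subjects_signed_rank) {
    list(relatedness_test = "signed_rank_across_subjects",
         comparison_test = "signed_rank_across_subjects",
         bootstrap_unit = "none")
  } else if (n_conditions >= defaults$min_conditions_randomization) {
    list(relatedness_test = "stimulus_label_randomization",
         comparison_test = "bootstrap",
         bootstrap_unit = "stimuli")
  } else if (is.null(overrides)) {
    stop("no default test available: ", n_subjects, " subjects < ",
         defaults$min_subjects_signed_rank,
         " (signed-rank across subjects unavailable) and ", n_conditions,
         " conditions < ", defaults$min_conditions_randomization,
         " (stimulus-label randomization unavailable); pass overrides to ",
         "request a procedure explicitly")
  } else {
    list(relatedness_test = NULL, comparison_test = NULL,
         bootstrap_unit = "none")
  }
  plan$n_permutations <- defaults$n_permutations
  plan$n_bootstrap <- defaults$n_bootstrap
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides),
                       c("relatedness_test", "comparison_test",
                         "bootstrap_unit", "n_permutations", "n_bootstrap"))
    if (length(unknown))
      stop("unknown override field(s): ", paste(unknown, collapse = ", "))
    if (identical(overrides$relatedness_test,
                  "stimulus_label_randomization") &&
        n_conditions < defaults$min_conditions_randomization)
      stop("stimulus-label randomization refused: ", n_conditions,
           " conditions < required minimum of ",
           defaults$min_conditions_randomization)
    for (f in names(overrides)) plan[[f]] <- overrides[[f]]
    message("test plan overrides requested explicitly: ",
            paste(names(overrides), collapse = ", "))
  }
  if (is.null(plan$relatedness_test) || is.null(plan$comparison_test))
    stop("test plan incomplete: overrides must supply relatedness_test ",
         "and comparison_test when no default applies")
  plan$seed <- as.integer(seed)
  plan$n_subjects <- as.integer(n_subjects)
  plan$n_conditions <- as.integer(n_conditions)
  structure(plan, class = "test_plan")
}

#' @export
print.test_plan <- function(x, ...) {
  cat("test_plan: relatedness =", x$relatedness_test,
      "| comparison =", x$comparison_test,
      if (x$bootstrap_unit != "none") paste("(unit:", x$bootstrap_unit, ")"),
      "| seed =", x$seed, "\n")
  invisible(x)
}

# ---- Wilcoxon signed-rank --------------------------------------------------

# One- or two-sided signed-rank p-value for H0: symmetric around 0.
# Zeros are dropped (Wilcoxon convention); all-zero input gives p = 1.
# Exact null distribution (stats::psignrank) for n <= 25 without tied
# absolute values, normal approximation with tie correction otherwise.
signed_rank_p <- function(x, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  x <- x[x != 0]
  n <- length(x)
  if (n == 0L) return(1)
  r <- rank(abs(x))
  w <- sum(r[x > 0])
  ties <- anyDuplicated(abs(x)) > 0L
  if (n <= 25L && !ties) {
    p_ge <- 1 - stats::psignrank(w - 1, n)
    p_le <- stats::psignrank(w, n)
  } else {
    mu <- n * (n + 1) / 4
    tie_table <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_table^3 - tie_table) / 48
    if (sigma2 <= 0) return(1)
    p_ge <- stats::pnorm(w - mu, sd = sqrt(sigma2), lower.tail = FALSE)
    p_le <- stats::pnorm(w - mu, sd = sqrt(sigma2))
  }
  switch(alternative,
         greater = p_ge,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# Per-subject correlations of one candidate with each subject RDM.
subject_correlations <- function(subject_rdms, candidate, method) {
  vapply(subject_rdms$rdms,
         function(s) corr_vec(s$d, candidate$d, method), numeric(1))
}

#' Test RDM relatedness by a signed-rank test across subjects
#'
#' One-sided test of whether the candidate RDM is related to the reference
#' representation: the candidate's correlation with each single-subject
#' reference-RDM estimate is computed and tested against zero across
#' subjects. Treats subject as a random effect.
#'
#' @param subject_rdms [rdm_collection()] of single-subject reference RDM
#'   estimates.
#' @param candidate a candidate [rdm()] over the same conditions.
#' @param method correlation type, as in [compare_rdms()].
#' @return one-sided p-value.
#' @export
test_relatedness_signed_rank <- function(subject_rdms, candidate,
                                         method = c("spearman", "pearson",
                                                    "kendall_tau_a")) {
  stopifnot(inherits(subject_rdms, "rdm_collection"),
            inherits(candidate, "rdm"))
  method <- match.arg(method)
  if (!identical(subject_rdms$labels, candidate$labels))
    stop("candidate condition set does not match the subject RDMs")
  r <- subject_correlations(subject_rdms, candidate, method)
  if (all(r == 0)) {
    warning("all per-subject correlations are exactly 0; p = 1")
    return(1)
  }
  signed_rank_p(r, "greater")
}

# all permutations of 1..n (n! rows); only used when n! is small
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

# Map a condition permutation to the corresponding permutation of the
# canonical pair vector: entry for pair (i, j) moves to pair (perm[i], perm[j]).
permute_pair_vector <- function(v, perm) {
  n <- length(perm)
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  v[pair_index(perm[idx[, 2]], perm[idx[, 1]], n)]
}

#' Test RDM relatedness by stimulus-label randomization
#'
#' Fixed-effects test of relatedness between a candidate RDM and the
#' reference representation. The null hypothesis — that the RDMs are
#' unrelated, and the condition labels therefore exchangeable — is
#' simulated by re-ordering the condition labels of the reference RDMs
#' (the same permutation applied to rows and columns) and recomputing the
#' statistic: the mean across subjects of the candidate/subject-RDM
#' correlation. When `factorial(n_conditions) <= n_permutations` all
#' permutations are enumerated and the p-value is exact; otherwise random
#' permutations are drawn and p = (1 + #\{null >= observed\}) /
#' (1 + n_permutations), which can never be 0.
#'
#' @inheritParams test_relatedness_signed_rank
#' @param n_permutations number of random permutations (or the enumeration
#'   threshold).
#' @param seed integer seed for the random permutations.
#' @param min_conditions required number of conditions (default 20);
#'   the test is refused below it unless `override = TRUE`.
#' @param override logical; explicitly request the test below
#'   `min_conditions` (logged).
#' @return list with `p`, `observed`, `null` (null statistics),
#'   `n_permutations_used`, `exhaustive`.
#' @export
test_relatedness_randomization <- function(subject_rdms, candidate,
                                           method = c("spearman", "pearson",
                                                      "kendall_tau_a"),
                                           n_permutations = 10000L,
                                           seed = 1L,
                                           min_conditions =
                                             rsa_defaults()$min_conditions_randomization,
                                           override = FALSE) {
  stopifnot(inherits(subject_rdms, "rdm_collection"),
            inherits(candidate, "rdm"))
  method <- match.arg(method)
  if (!identical(subject_rdms$labels, candidate$labels))
    stop("candidate condition set does not match the subject RDMs")
  n <- length(subject_rdms$labels)
  if (n < min_conditions) {
    if (!override)
      stop("stimulus-label randomization requires at least ", min_conditions,
           " conditions (got ", n, "); pass override = TRUE to request it ",
           "explicitly")
    message("stimulus-label randomization explicitly requested with ", n,
            " conditions (minimum ", min_conditions, ")")
  }

  stat_fun <- make_mean_corr_stat(subject_rdms, method)
  observed <- stat_fun(candidate$d)

  exhaustive <- factorial(n) <= n_permutations
  if (exhaustive) {
    perms <- all_permutations(n)
    # row 1 is the identity == the observed statistic; the remaining n!-1
    # permutations form the null sample, so p = (1 + k) / n! overall
    null <- apply(perms[-1, , drop = FALSE], 1, function(p)
      stat_fun(permute_pair_vector(candidate$d, p)))
    n_used <- nrow(perms)
  } else {
    set.seed(as.integer(seed))
    null <- vapply(seq_len(n_permutations), function(b)
      stat_fun(permute_pair_vector(candidate$d, sample.int(n))), numeric(1))
    n_used <- n_permutations
  }
  p <- (1 + sum(null >= observed)) / (1 + length(null))
  list(p = p, observed = observed, null = null,
       n_permutations_used = n_used, exhaustive = exhaustive)
}

# Statistic closure: mean across subjects of corr(candidate vector, subject
# RDM). For pearson/spearman the subject vectors are pre-standardized so
# each evaluation is a single matrix-vector product.
make_mean_corr_stat <- function(subject_rdms, method) {
  m <- collection_matrix(subject_rdms)           # n_sub x n_pairs
  if (method == "kendall_tau_a") {
    function(v) mean(apply(m, 1, kendall_tau_a, v))
  } else {
    if (method == "spearman") m <- t(apply(m, 1, rank))
    if (any(apply(m, 1, sd) == 0))
      stop("constant subject RDM: ", method, " correlation is undefined")
    ms <- t(scale(t(m)))                         # rows: mean 0, sd 1
    np <- ncol(m)
    function(v) {
      if (method == "spearman") v <- rank(v)
      s <- sd(v)
      if (s == 0)
        stop("constant dissimilarity vector: ", method,
             " correlation is undefined")
      mean(ms %*% ((v - mean(v)) / s)) / (np - 1)
    }
  }
}

#' Pairwise candidate comparison by signed-rank tests across subjects
#'
#' For each pair of candidate RDMs, the difference of their correlations
#' with the reference RDM is computed within each subject and tested across
#' subjects with a two-sided signed-rank test. Returns raw (unadjusted)
#' p-values; apply [adjust_multiple()] to control multiple testing.
#'
#' @inheritParams test_relatedness_signed_rank
#' @param candidates [rdm_collection()] of candidate RDMs.
#' @return list with `p` (M x M symmetric matrix, diagonal `NA`) and
#'   `correlations` (n_subjects x M per-subject correlation matrix).
#' @export
compare_candidates_signed_rank <- function(subject_rdms, candidates,
                                           method = c("spearman", "pearson",
                                                      "kendall_tau_a")) {
  stopifnot(inherits(subject_rdms, "rdm_collection"),
            inherits(candidates, "rdm_collection"))
  method <- match.arg(method)
  corrs <- vapply(candidates$rdms,
                  function(cand) subject_correlations(subject_rdms, cand,
                                                      method),
                  numeric(length(subject_rdms$rdms)))
  m <- length(candidates$rdms)
  p <- matrix(NA_real_, m, m,
              dimnames = list(names(candidates$rdms),
                              names(candidates$rdms)))
  if (m >= 2L) {
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        p[i, j] <- p[j, i] <-
          signed_rank_p(corrs[, i] - corrs[, j], "two.sided")
      }
    }
  }
  list(p = p, correlations = corrs)
}

#' Pairwise candidate comparison by bootstrap resampling
#'
#' Simulates repeated sampling from the population of stimuli and/or
#' subjects: per bootstrap sample, the chosen units are resampled with
#' replacement, all RDMs are restricted to the resampled condition pairs
#' (pairs formed by duplicate draws of the same condition are excluded —
#' their dissimilarity is structurally zero and would bias rank
#' correlations), and each candidate's mean correlation with the subject
#' RDMs is recomputed. The p-value for a candidate pair is the two-sided
#' tail proportion of the bootstrap distribution of their difference around
#' zero; the error bar is the bootstrap standard deviation of each
#' candidate's statistic.
#'
#' @inheritParams compare_candidates_signed_rank
#' @param unit resampling unit: `"stimuli"`, `"subjects"` or `"both"`.
#' @param n_bootstrap number of bootstrap samples (>= 100).
#' @param seed integer seed.
#' @return list with `p` (M x M), `error_bars` (length M), `statistics`
#'   (n_bootstrap x M matrix), `n_redrawn`.
#' @export
compare_candidates_bootstrap <- function(subject_rdms, candidates,
                                         unit = c("stimuli", "subjects",
                                                  "both"),
                                         method = c("spearman", "pearson",
                                                    "kendall_tau_a"),
                                         n_bootstrap = 1000L, seed = 1L) {
  stopifnot(inherits(subject_rdms, "rdm_collection"),
            inherits(candidates, "rdm_collection"))
  unit <- match.arg(unit)
  method <- match.arg(method)
  if (n_bootstrap < 100L) stop("n_bootstrap must be at least 100")
  n <- length(subject_rdms$labels)
  if (unit %in% c("stimuli", "both") && n < 5L)
    stop("stimulus resampling requires at least 5 conditions")
  n_sub <- length(subject_rdms$rdms)
  m <- length(candidates$rdms)
  subj_mat <- collection_matrix(subject_rdms)
  cand_mat <- collection_matrix(candidates)

  set.seed(as.integer(seed))
  stats_mat <- matrix(NA_real_, n_bootstrap, m)
  n_redrawn <- 0L
  for (b in seq_len(n_bootstrap)) {
    repeat {
      cond_idx <- if (unit %in% c("stimuli", "both"))
        sample.int(n, replace = TRUE) else seq_len(n)
      if (length(unique(cond_idx)) >= 3L) break
      n_redrawn <- n_redrawn + 1L
    }
    sub_idx <- if (unit %in% c("subjects", "both"))
      sample.int(n_sub, replace = TRUE) else seq_len(n_sub)
    # pairs of distinct resampled conditions, indexed into the pair vector
    pairs <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
    a <- cond_idx[pairs[, 2]]
    bcond <- cond_idx[pairs[, 1]]
    keep <- a != bcond
    pidx <- pair_index(a[keep], bcond[keep], n)
    sm <- subj_mat[sub_idx, pidx, drop = FALSE]
    cm <- cand_mat[, pidx, drop = FALSE]
    stats_mat[b, ] <- vapply(seq_len(m), function(k)
      mean(apply(sm, 1, function(s) corr_vec(s, cm[k, ], method))),
      numeric(1))
  }
  colnames(stats_mat) <- names(candidates$rdms)

  p <- matrix(NA_real_, m, m, dimnames = dimnames(stats_mat)[c(2, 2)])
  if (m >= 2L) {
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        dd <- stats_mat[, i] - stats_mat[, j]
        p[i, j] <- p[j, i] <- if (all(dd == 0)) 1 else
          min(1, 2 * min(mean(dd <= 0), mean(dd >= 0)))
      }
    }
  }
  if (n_redrawn > 0L)
    message(n_redrawn, " bootstrap draw(s) redrawn (fewer than 3 distinct ",
            "conditions)")
  list(p = p, error_bars = apply(stats_mat, 2, sd), statistics = stats_mat,
       n_redrawn = n_redrawn)
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up control of the false-discovery rate
#' (default), or Bonferroni control of the familywise error rate:
#' BH rejects all p-values up to the largest k with
#' `p_(k) <= k * alpha / m`; Bonferroni rejects `p <= alpha / m`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param procedure `"fdr_bh"` or `"fwe_bonferroni"`.
#' @param alpha nominal level.
#' @return list with `reject` (logical mask in input order), `threshold`
#'   (largest p-value rejected, or 0 if none), `procedure`, `alpha`.
#' @export
adjust_multiple <- function(p_values, procedure = c("fdr_bh",
                                                    "fwe_bonferroni"),
                            alpha = 0.05) {
  procedure <- match.arg(procedure)
  p <- as.numeric(p_values)
  if (length(p) == 0L)
    return(list(reject = logical(0), threshold = 0,
                procedure = procedure, alpha = alpha))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (procedure == "fwe_bonferroni") {
    reject <- p <= alpha / m
  } else {
    o <- order(p)
    ps <- p[o]
    below <- which(ps <= seq_len(m) * alpha / m)
    reject <- rep(FALSE, m)
    if (length(below)) reject[o[seq_len(max(below))]] <- TRUE
  }
  list(reject = reject,
       threshold = if (any(reject)) max(p[reject]) else 0,
       procedure = procedure, alpha = alpha)
}

#' Full candidate-RDM inference
#'
#' Assembles the complete step-3 analysis: per-candidate mean correlation
#' with the single-subject reference RDMs (bar heights), one-sided
#' relatedness p-values, the adjusted matrix of pairwise candidate
#' comparisons, per-candidate error bars, the noise ceiling, and a
#' provenance record (`tests_used`) that makes the run reproducible given
#' the seed. Candidate RDMs whose role marks them as measured (subject
#' estimates or reference RDMs, which carry noise) are flagged: their
#' pairwise comparisons with noiseless models should not be formally
#' interpreted.
#'
#' @inheritParams compare_candidates_signed_rank
#' @param plan a [select_tests()] plan; default: selected from the data
#'   shape.
#' @param mc_procedure multiple-comparison procedure for the pairwise
#'   matrix, see [adjust_multiple()].
#' @param alpha level for the adjusted pairwise rejections.
#' @return Object of class `inference_result`.
#' @export
run_inference <- function(subject_rdms, candidates, plan = NULL,
                          method = c("spearman", "pearson",
                                     "kendall_tau_a"),
                          mc_procedure = "fdr_bh", alpha = 0.05) {
  stopifnot(inherits(subject_rdms, "rdm_collection"),
            inherits(candidates, "rdm_collection"))
  method <- match.arg(method)
  n_sub <- length(subject_rdms$rdms)
  n_cond <- length(subject_rdms$labels)
  if (is.null(plan)) plan <- select_tests(n_sub, n_cond)
  m <- length(candidates$rdms)
  cand_names <- names(candidates$rdms)

  corrs <- vapply(candidates$rdms,
                  function(cand) subject_correlations(subject_rdms, cand,
                                                      method),
                  numeric(n_sub))
  mean_corr <- colMeans(corrs)

  relatedness_p <- if (plan$relatedness_test ==
                       "signed_rank_across_subjects") {
    vapply(candidates$rdms, function(cand)
      test_relatedness_signed_rank(subject_rdms, cand, method), numeric(1))
  } else {
    vapply(candidates$rdms, function(cand)
      test_relatedness_randomization(subject_rdms, cand, method,
                                     n_permutations = plan$n_permutations,
                                     seed = plan$seed)$p, numeric(1))
  }

  if (plan$comparison_test == "signed_rank_across_subjects") {
    cmp <- compare_candidates_signed_rank(subject_rdms, candidates, method)
    raw_p <- cmp$p
    error_bars <- apply(corrs, 2, sd) / sqrt(n_sub)  # across-subject SEM
  } else {
    cmp <- compare_candidates_bootstrap(subject_rdms, candidates,
                                        unit = plan$bootstrap_unit,
                                        method = method,
                                        n_bootstrap = plan$n_bootstrap,
                                        seed = plan$seed)
    raw_p <- cmp$p
    error_bars <- cmp$error_bars
  }

  pairwise_p <- raw_p
  off <- upper.tri(raw_p)
  if (m >= 2L) {
    adj <- adjust_multiple(raw_p[off], mc_procedure, alpha)
    rejected <- matrix(FALSE, m, m, dimnames = dimnames(raw_p))
    rejected[off] <- adj$reject
    rejected <- rejected | t(rejected)
  } else {
    rejected <- matrix(FALSE, m, m, dimnames = dimnames(raw_p))
  }

  ceiling <- estimate_noise_ceiling(subject_rdms, method)

  structure(list(
    candidate_names = cand_names,
    mean_corr = mean_corr,
    relatedness_p = relatedness_p,
    pairwise_p = pairwise_p,
    pairwise_rejected = rejected,
    error_bars = error_bars,
    ceiling = ceiling,
    noise_affected = candidates$roles %in% c("subject_estimate",
                                             "reference"),
    method = method,
    tests_used = list(plan = unclass(plan), mc_procedure = mc_procedure,
                      alpha = alpha, seed = plan$seed,
                      package_version =
                        as.character(utils::packageVersion("repsim")))),
    class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat("inference_result (", x$method, "), ",
      length(x$candidate_names), " candidates\n", sep = "")
  df <- data.frame(candidate = x$candidate_names,
                   mean_corr = round(x$mean_corr, 4),
                   relatedness_p = signif(x$relatedness_p, 3),
                   noise_affected = x$noise_affected)
  print(df, row.names = FALSE)
  cat(sprintf("noise ceiling: [%.4f, %.4f]\n",
              x$ceiling$lower, x$ceiling$upper))
  invisible(x)
}
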