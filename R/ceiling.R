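#' Estimate the noise ceiling for a group of subject RDMs
#'
#' The noise ceiling bounds the group-average RDM correlation that the
#' unknown true model could achieve, given inter-subject variability.
#' The upper bound is the average correlation between a "central" RDM —
#' overfitted to the group — and each single-subject RDM; the lower bound
#' replaces the central RDM by the leave-one-subject-out average, which
#' removes the overfitting and underestimates the true model's performance.
#'
#' The central RDM depends on the correlation type: the mean of z-transformed
#' subject RDMs for Pearson, the mean of rank-transformed RDMs for Spearman
#' (both exactly maximize the respective average correlation), and for
#' Kendall's tau-a the rank-transform mean refined by a greedy coordinate
#' search (tau-a has no closed-form maximizer; the refined upper bound is
#' approximate, and refinement is skipped for RDMs larger than
#' `refine_max_pairs` pairs where the rank-mean initialization is used
#' directly).
#'
#' @param subject_rdms [rdm_collection()] of >= 2 single-subject RDM
#'   estimates.
#' @param method correlation type, as in [compare_rdms()].
#' @param refine_max_pairs tau-a only: maximum number of dissimilarity pairs
#'   for which greedy refinement of the central RDM runs (default 1000).
#' @param max_sweeps,tol tau-a refinement: stop after `max_sweeps` passes or
#'   when a full pass improves the mean tau-a by less than `tol`.
#' @return Object of class `noise_ceiling`: list with `lower`, `upper`,
#'   `method`, `n_subjects`.
#' @export
estimate_noise_ceiling <- function(subject_rdms,
                                   method = c("spearman", "pearson",
                                              "kendall_tau_a"),
                                   refine_max_pairs = 1000,
                                   max_sweeps = 100, tol = 1e-6) {
  stopifnot(inherits(subject_rdms, "rdm_collection"))
  method <- match.arg(method)
  n_sub <- length(subject_rdms$rdms)
  if (n_sub < 2L) stop("noise ceiling needs at least 2 subject RDMs")
  if (n_sub == 2L)
    warning("only 2 subjects: the lower bound degenerates to the ",
            "between-subject correlation")

  raw <- collection_matrix(subject_rdms)
  transform <- switch(method, pearson = "z", "rank")
  trans <- collection_matrix(transform_rdms(subject_rdms, transform))

  central <- colMeans(trans)
  if (method == "kendall_tau_a" && ncol(trans) <= refine_max_pairs)
    central <- refine_central_tau_a(central, trans, max_sweeps, tol)

  upper <- mean(vapply(seq_len(n_sub),
                       function(i) corr_vec(central, raw[i, ], method),
                       numeric(1)))
  lower <- mean(vapply(seq_len(n_sub), function(i) {
    loo <- colMeans(trans[-i, , drop = FALSE])
    corr_vec(loo, raw[i, ], method)
  }, numeric(1)))

  structure(list(lower = lower, upper = upper, method = method,
                 n_subjects = n_sub),
            class = "noise_ceiling")
}

#' @export
print.noise_ceiling <- function(x, ...) {
  cat(sprintf("noise_ceiling (%s, %d subjects): [%.4f, %.4f]\n",
              x$method, x$n_subjects, x$lower, x$upper))
  invisible(x)
}

# Greedy coordinate refinement of the tau-a central RDM: for each pair
# coordinate, try the subjects' rank values at that coordinate and keep the
# one maximizing the mean tau-a with the subject RDMs. Monotone by
# construction; each sweep can only improve the objective.
refine_central_tau_a <- function(central, trans, max_sweeps, tol) {
  n_sub <- nrow(trans)
  mean_tau <- function(v)
    mean(vapply(seq_len(n_sub),
                function(i) kendall_tau_a(v, trans[i, ]), numeric(1)))
  best <- mean_tau(central)
  for (sweep in seq_len(max_sweeps)) {
    start <- best
    for (k in seq_along(central)) {
      candidates <- unique(trans[, k])
      candidates <- candidates[candidates != central[k]]
      for (v in candidates) {
        trial <- central
        trial[k] <- v
        score <- mean_tau(trial)
        if (score > best) {
          best <- score
          central <- trial
        }
      }
    }
    if (best - start < tol) break
  }
  central
}
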