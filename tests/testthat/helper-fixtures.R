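# Fixtures are built in code; nothing is read from disk.

cond_labels <- function(n) sprintf("c%02d", seq_len(n))

# tie-free random RDM over n conditions
random_rdm <- function(n, seed, measure = "other") {
  set.seed(seed)
  rdm(runif(n * (n - 1) / 2), labels = cond_labels(n), measure = measure)
}

random_collection <- function(n_rdms, n_cond, seed,
                              roles = "subject_estimate") {
  rdm_collection(lapply(seq_len(n_rdms),
                        function(i) random_rdm(n_cond, seed + i)),
                 roles = roles)
}

random_pattern_set <- function(n_cond, n_chan, seed) {
  set.seed(seed)
  pattern_set(matrix(rnorm(n_cond * n_chan), n_cond, n_chan),
              labels = cond_labels(n_cond))
}

# direct O(n^2) Spearman for cross-checks
spearman_ref <- function(a, b) stats::cor(rank(a), rank(b))

# small partitioned dataset with known true patterns; residual rows are raw
# noise draws, so the residual dof equals the row count
toy_partitioned <- function(B, noise_sd = 1, t_res = 40, seed = 1,
                            est_sd = NULL) {
  set.seed(seed)
  n <- nrow(B); p <- ncol(B)
  labels <- if (is.null(rownames(B))) cond_labels(n) else rownames(B)
  if (is.null(est_sd)) est_sd <- noise_sd
  mk <- function() {
    est <- pattern_set(B + est_sd * matrix(rnorm(n * p), n, p),
                       labels = labels)
    res <- noise_sd * matrix(rnorm(t_res * p), t_res, p)
    list(est = est, res = res)
  }
  a <- mk(); b <- mk()
  partitioned_data(a$est, b$est, a$res, b$res,
                   dof2 = t_res, dof1 = t_res)
}
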