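test_that("select_tests implements the default decision process", {
  plan <- select_tests(12, 92)
  expect_equal(plan$relatedness_test, "signed_rank_across_subjects")
  expect_equal(plan$comparison_test, "signed_rank_across_subjects")

  plan <- select_tests(4, 92)
  expect_equal(plan$relatedness_test, "stimulus_label_randomization")
  expect_equal(plan$comparison_test, "bootstrap")
  expect_equal(plan$bootstrap_unit, "stimuli")

  # few conditions: randomization unavailable, signed-rank still applies
  plan <- select_tests(20, 6)
  expect_equal(plan$relatedness_test, "signed_rank_across_subjects")

  # neither criterion met -> error naming both
  err <- tryCatch(select_tests(4, 6), error = conditionMessage)
  expect_match(err, "12")
  expect_match(err, "20")

  # explicit override honored with a notice
  expect_message(
    plan <- select_tests(4, 6,
                         overrides = list(relatedness_test =
                                            "signed_rank_across_subjects",
                                          comparison_test = "bootstrap",
                                          bootstrap_unit = "subjects")),
    "explicitly")
  expect_equal(plan$comparison_test, "bootstrap")
  # randomization below the condition minimum refused even as override
  expect_error(select_tests(4, 6,
                            overrides = list(relatedness_test =
                                               "stimulus_label_randomization")),
               "refused")
})

test_that("signed-rank relatedness test matches the exact null", {
  # exact distribution equals full 2^n sign enumeration
  for (n in c(5, 8)) {
    set.seed(200 + n)
    x <- abs(rnorm(n)) * sample(c(-1, 1), n, TRUE)
    r <- rank(abs(x))
    w_obs <- sum(r[x > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_null <- signs %*% r
    p_oracle <- mean(w_null >= w_obs)
    expect_equal(repsim:::signed_rank_p(x, "greater"), p_oracle,
                 tolerance = 1e-12)
  }

  # 12 subjects all positive -> smallest attainable one-sided p = 2^-12
  # (pearson: continuous correlations, so no tied ranks across subjects)
  labels <- cond_labels(6)
  base <- random_rdm(6, 211)
  subs <- rdm_collection(lapply(1:12, function(i) {
    set.seed(300 + i)
    rdm(base$d + rnorm(15, sd = 0.2), labels)
  }))
  p <- test_relatedness_signed_rank(subs, base, "pearson")
  expect_equal(p, 2^-12, tolerance = 1e-12)

  # symmetric +/- c correlations -> p >= 0.5
  expect_gte(repsim:::signed_rank_p(c(0.3, -0.3, 0.3, -0.3), "greater"), 0.5)
  # all zero differences -> p = 1
  expect_equal(repsim:::signed_rank_p(rep(0, 6), "two.sided"), 1)
})

test_that("signed-rank test is calibrated under the null", {
  set.seed(42)
  labels <- cond_labels(10)
  rej <- replicate(1000, {
    subs <- rdm_collection(lapply(1:12, function(i) rdm(runif(45), labels)))
    cand <- rdm(runif(45), labels, measure = "model")
    test_relatedness_signed_rank(subs, cand, "spearman") <= 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("randomization test enumerates exhaustively and is never 0 or >1", {
  # 6 conditions -> 720 unique permutations, exhaustive mode
  subs <- random_collection(3, 6, seed = 221)
  cand <- subs$rdms[[1]]
  res <- suppressMessages(
    test_relatedness_randomization(subs, cand, "spearman",
                                   n_permutations = 10000, override = TRUE))
  expect_true(res$exhaustive)
  expect_equal(res$n_permutations_used, 720)

  # candidate == sole reference, tie-free: only identity attains the max
  one <- rdm_collection(list(random_rdm(5, 222)))
  res5 <- suppressMessages(
    test_relatedness_randomization(one, one$rdms[[1]], "spearman",
                                   n_permutations = 1000, override = TRUE))
  expect_equal(res5$p, 1 / 120)

  # Monte-Carlo mode: p in (0, 1] by the +1 correction
  big <- random_collection(3, 20, seed = 223)
  res20 <- test_relatedness_randomization(big, random_rdm(20, 7), "spearman",
                                          n_permutations = 99, seed = 3)
  expect_gt(res20$p, 0)
  expect_lte(res20$p, 1)
  # refused below the condition minimum without an override
  expect_error(test_relatedness_randomization(subs, cand, "spearman"),
               "at least 20")
})

test_that("randomization p-values are approximately uniform under the null", {
  set.seed(44)
  labels <- cond_labels(20)
  ps <- replicate(400, {
    subs <- rdm_collection(lapply(1:4, function(i) rdm(runif(190), labels)))
    cand <- rdm(runif(190), labels, measure = "model")
    test_relatedness_randomization(subs, cand, "spearman",
                                   n_permutations = 199,
                                   seed = sample.int(1e6, 1))$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
  rate <- mean(ps <= 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("pairwise signed-rank comparisons behave at the boundaries", {
  subs <- random_collection(12, 6, seed = 231)
  cand <- random_rdm(6, 232)
  cands <- rdm_collection(list(a = cand, b = cand, c = random_rdm(6, 233)),
                          roles = "candidate")
  res <- compare_candidates_signed_rank(subs, cands, "spearman")
  expect_equal(res$p["a", "b"], 1)            # identical candidates
  expect_equal(res$p, t(res$p))               # symmetry
  expect_true(all(is.na(diag(res$p))))
  expect_equal(dim(res$correlations), c(12L, 3L))
})

test_that("bootstrap comparison resamples correctly", {
  subs <- random_collection(4, 12, seed = 241)
  cand <- random_rdm(12, 242)
  cands <- rdm_collection(list(a = cand, b = cand, c = random_rdm(12, 243)),
                          roles = "candidate")
  res <- compare_candidates_bootstrap(subs, cands, unit = "stimuli",
                                      method = "spearman",
                                      n_bootstrap = 150, seed = 5)
  expect_equal(res$p["a", "b"], 1)            # all differences exactly 0
  expect_true(all(res$error_bars > 0))        # nonzero resampling variance
  expect_equal(dim(res$statistics), c(150L, 3L))
  # deterministic given seed
  res2 <- compare_candidates_bootstrap(subs, cands, unit = "stimuli",
                                       method = "spearman",
                                       n_bootstrap = 150, seed = 5)
  expect_identical(res$statistics, res2$statistics)
  expect_error(compare_candidates_bootstrap(subs, cands,
                                            n_bootstrap = 50), "100")
})

test_that("bootstrap error bars shrink roughly as 1/sqrt(n_conditions)", {
  # noise enters at the pattern level, so dissimilarity errors are
  # correlated across pairs sharing a condition and the information
  # scales with conditions, not pairs
  sds <- sapply(c(40, 160), function(nc) {
    set.seed(250 + nc)
    truth_pat <- pattern_set(matrix(rnorm(nc * 30), nc, 30),
                             cond_labels(nc))
    truth <- compute_rdm(truth_pat, "euclidean")
    subs <- rdm_collection(lapply(
      noisy_subjects(truth_pat, 4, noise_sd = 0.8, seed = 260 + nc),
      compute_rdm, measure = "euclidean"))
    cands <- rdm_collection(list(model = truth), roles = "candidate")
    res <- compare_candidates_bootstrap(subs, cands, unit = "stimuli",
                                        method = "spearman",
                                        n_bootstrap = 150, seed = 6)
    res$error_bars[["model"]]
  })
  ratio <- sds[1] / sds[2]       # expected ~ sqrt(160/40) = 2
  expect_gt(ratio, 2 / 1.5)
  expect_lt(ratio, 2 * 1.5)
})

test_that("adjust_multiple implements BH step-up and Bonferroni", {
  # hand-enumerated step-up: k* = 4 (0.04 <= 4 * 0.05 / 5)
  res <- adjust_multiple(c(0.01, 0.02, 0.03, 0.04, 0.5), "fdr_bh", 0.05)
  expect_equal(res$reject, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(res$threshold, 0.04)
  # matches stats::p.adjust as an independent route
  set.seed(271)
  for (i in 1:50) {
    p <- runif(sample(3:30, 1))^sample(1:3, 1)
    mine <- adjust_multiple(p, "fdr_bh", 0.05)$reject
    ref <- stats::p.adjust(p, "BH") <= 0.05
    expect_equal(mine, unname(ref))
  }
  # all tiny -> all rejected by both procedures
  expect_true(all(adjust_multiple(rep(0.001, 8), "fdr_bh")$reject))
  expect_true(all(adjust_multiple(rep(0.001, 8), "fwe_bonferroni")$reject))
  # BH rejection set contains the Bonferroni set
  for (i in 1:100) {
    p <- runif(20)^2
    bh <- adjust_multiple(p, "fdr_bh")$reject
    bf <- adjust_multiple(p, "fwe_bonferroni")$reject
    expect_true(all(bh[bf]))
  }
  expect_length(adjust_multiple(numeric(0))$reject, 0)
})

test_that("BH controls the empirical FDR in simulation", {
  set.seed(281)
  m <- 50; m0 <- 30
  fdp <- replicate(2000, {
    p <- c(runif(m0), rbeta(m - m0, 0.15, 1))
    rej <- adjust_multiple(p, "fdr_bh", 0.05)$reject
    if (!any(rej)) 0 else sum(rej[seq_len(m0)]) / sum(rej)
  })
  expect_lte(mean(fdp), 0.05 + 0.02)
})

test_that("run_inference assembles a reproducible result", {
  sc <- suppressWarnings(make_fig4_scenario(seed = 3, n_conditions = 24,
                                            n_channels = 30, n_subjects = 12,
                                            embed_iter = 150))
  res <- run_inference(sc$subject_rdms, sc$candidates, method = "spearman")
  expect_s3_class(res, "inference_result")
  expect_length(res$mean_corr, 5)
  expect_true(all(res$relatedness_p >= 0 & res$relatedness_p <= 1))
  expect_equal(res$pairwise_p, t(res$pairwise_p))
  expect_true(all(res$error_bars > 0))
  expect_lte(res$ceiling$lower, res$ceiling$upper)
  # subject-derived candidate flagged as noise-affected
  expect_identical(res$noise_affected,
                   sc$candidates$roles == "subject_estimate")
  expect_true(res$noise_affected[[5]])
  # byte-identical on rerun
  res2 <- run_inference(sc$subject_rdms, sc$candidates, method = "spearman")
  expect_identical(res, res2)
  # single candidate: empty pairwise matrix, relatedness present
  solo <- rdm_collection(list(only = sc$candidates$rdms[[1]]),
                         roles = "candidate")
  rs <- run_inference(sc$subject_rdms, solo, method = "spearman")
  expect_true(all(is.na(rs$pairwise_p)))
  expect_length(rs$relatedness_p, 1)
})

test_that("true model wins pairwise comparisons in the simulated regime", {
  wins <- sapply(1:5, function(s) {
    sc <- suppressWarnings(make_fig4_scenario(seed = 400 + s,
                                              n_conditions = 24,
                                              n_channels = 30,
                                              n_subjects = 12,
                                              embed_iter = 150))
    cands <- rdm_collection(list(true_model = sc$candidates$rdms$true_model,
                                 control = sc$candidates$rdms$unrelated_control),
                            roles = "candidate")
    cmp <- compare_candidates_signed_rank(sc$subject_rdms, cands,
                                          "kendall_tau_a")
    cmp$p["true_model", "control"] < 0.05
  })
  expect_gte(mean(wins), 0.8)
})
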