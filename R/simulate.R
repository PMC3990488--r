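#' Generate patterns whose distances conform to a target RDM
#'
#' Samples N points i.i.d. from an isotropic Gaussian in `n_channels`
#' dimensions and drives them toward the target geometry with pairwise
#' spring forces: each pair of points is moved along its difference vector
#' proportionally to the gap between its target and current distance. A
#' proposed step is only accepted if it reduces the metric stress (the
#' root-sum-of-squares distance error relative to the target scale), so the
#' stress trajectory is non-increasing by construction; on rejection the
#' step size is halved.
#'
#' Targets that are not realizable in `n_channels` dimensions (or not
#' Euclidean at all) converge to a strictly positive residual stress, which
#' is reported rather than hidden.
#'
#' @param target an [rdm()] with non-negative (Euclidean-scale)
#'   dissimilarities.
#' @param n_channels embedding dimensionality P.
#' @param seed integer seed for the Gaussian initialization.
#' @param max_iter iteration cap.
#' @param tol stop once stress falls below this value.
#' @param step initial force step size.
#' @param init `"random"` (isotropic Gaussian) or `"cmds"` (classical MDS
#'   coordinates as a fast initializer, padded/truncated to `n_channels`).
#' @return list with `patterns` ([pattern_set()]), `stress` (final),
#'   `trajectory` (stress per accepted iteration), `converged`.
#' @export
patterns_from_rdm <- function(target, n_channels, seed = 1L,
                              max_iter = 500L, tol = 1e-3, step = 0.1,
                              init = c("random", "cmds")) {
  stopifnot(inherits(target, "rdm"))
  init <- match.arg(init)
  if (n_channels < 1L) stop("n_channels must be >= 1")
  if (any(target$d < 0)) stop("target RDM must be non-negative")
  n <- length(target$labels)
  tmat <- rdm_square(target$d)
  tnorm <- sqrt(sum(target$d^2))
  if (tnorm == 0) stop("target RDM is all-zero")

  set.seed(as.integer(seed))
  x <- matrix(rnorm(n * n_channels), n, n_channels)
  if (init == "cmds") {
    k <- min(n_channels, n - 1L)
    cm <- suppressWarnings(stats::cmdscale(tmat, k = k))
    x[, seq_len(ncol(cm))] <- cm
    x[, -seq_len(ncol(cm))] <- 0
    if (ncol(cm) < n_channels)
      x[, seq.int(ncol(cm) + 1L, n_channels)] <-
        1e-6 * x[, seq.int(ncol(cm) + 1L, n_channels), drop = FALSE]
  }

  stress_of <- function(dmat)
    sqrt(sum((dmat[lower.tri(dmat)] - target$d)^2)) / tnorm
  dmat <- as.matrix(dist(x))
  stress <- stress_of(dmat)
  trajectory <- stress
  for (it in seq_len(max_iter)) {
    if (stress < tol) break
    dsafe <- dmat
    dsafe[dsafe == 0] <- 1e-12
    coef <- (tmat - dmat) / dsafe
    diag(coef) <- 0
    prop <- x + (step / (n - 1)) * (rowSums(coef) * x - coef %*% x)
    dprop <- as.matrix(dist(prop))
    sprop <- stress_of(dprop)
    if (sprop < stress) {
      x <- prop; dmat <- dprop; stress <- sprop
      trajectory <- c(trajectory, stress)
      step <- min(step * 1.1, 1)     # re-grow after an accepted move
    } else {
      step <- step / 2
      if (step < 1e-12) break
    }
  }
  converged <- stress < tol
  if (!converged)
    warning("force embedding did not reach tol = ", tol,
            " (residual stress ", format(stress, digits = 4),
            "); the target may not be realizable in ", n_channels,
            " dimensions")
  list(patterns = pattern_set(x, labels = target$labels),
       stress = stress, trajectory = trajectory, converged = converged)
}

#' Simulate noisy per-subject pattern sets
#'
#' Each simulated subject observes the ground-truth patterns plus
#' independent isotropic Gaussian noise. Each subject uses its own seeded
#' random stream derived from `seed`, so any subject can be regenerated
#' independently.
#'
#' @param patterns ground-truth [pattern_set()].
#' @param n_subjects number of subjects.
#' @param noise_sd per-entry Gaussian noise standard deviation (response
#'   units).
#' @param seed integer base seed.
#' @return list of `n_subjects` pattern sets.
#' @export
noisy_subjects <- function(patterns, n_subjects = 12L, noise_sd = 1,
                           seed = 1L) {
  stopifnot(inherits(patterns, "pattern_set"))
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  lapply(seq_len(n_subjects), function(i) {
    set.seed((as.integer(seed) + 7919L * i) %% .Machine$integer.max)
    pattern_set(patterns$data +
                  noise_sd * matrix(rnorm(length(patterns$data)),
                                    nrow(patterns$data)),
                labels = patterns$labels)
  })
}

#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma parameterization (response peak ~6 s, undershoot
#' peak ~16 s, undershoot ratio 1/6), sampled at `dt`-second resolution and
#' scaled to unit peak.
#'
#' @param t time points in seconds.
#' @param peak_delay,under_delay,peak_disp,under_disp,ratio shape
#'   parameters (seconds / dispersion / undershoot ratio).
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, peak_delay = 6, under_delay = 16,
                             peak_disp = 1, under_disp = 1, ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    ratio * stats::dgamma(t, shape = under_delay / under_disp,
                          scale = under_disp)
  h / max(h)
}

# Gaussian smoothing along one margin; kernel sd in samples, kernel
# normalized to unit sum, nearest-value boundary handling.
gaussian_smooth_1d <- function(x, sd_samples) {
  if (sd_samples <= 0) return(x)
  half <- max(1L, ceiling(3 * sd_samples))
  k <- stats::dnorm(seq(-half, half), sd = sd_samples)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + n)]
}

#' Simulate GLM-style fMRI time-series data
#'
#' Builds a design matrix X from per-condition stimulus onsets convolved
#' with the canonical double-gamma HRF, then returns `Y = X B + E`, where
#' the error matrix E is Gaussian noise optionally smoothed in time and in
#' space (over a 3D voxel grid) by Gaussian convolution to create realistic
#' temporal and spatial autocorrelation.
#'
#' @param B conditions x voxels matrix of true response amplitudes.
#' @param n_timepoints number of volumes (rows of Y).
#' @param tr repetition time in seconds.
#' @param noise_sd pre-smoothing noise standard deviation.
#' @param temporal_smooth_fwhm temporal smoothing FWHM in seconds (0 = white
#'   noise in time).
#' @param spatial_smooth_fwhm spatial smoothing FWHM in mm (0 = spatially
#'   white; requires `vol_dim`).
#' @param vol_dim optional 3-vector: voxel-grid dimensions with
#'   `prod(vol_dim) == ncol(B)`, used for spatial smoothing.
#' @param voxel_size_mm voxel edge lengths in mm.
#' @param stimulus_isi inter-stimulus interval in seconds; each condition
#'   occurs once per cycle, in a seeded random order, as many times as fits.
#' @param seed integer seed.
#' @return list with `Y` (n_timepoints x voxels), `X` (n_timepoints x
#'   conditions), `E`, `onsets` (per-condition onset times in s).
#' @export
simulate_fmri <- function(B, n_timepoints, tr = 2, noise_sd = 1,
                          temporal_smooth_fwhm = 0, spatial_smooth_fwhm = 0,
                          vol_dim = NULL, voxel_size_mm = c(3, 3, 3),
                          stimulus_isi = 4, seed = 1L) {
  B <- as.matrix(B)
  k <- nrow(B)
  set.seed(as.integer(seed))
  isi_vols <- stimulus_isi / tr
  min_t <- ceiling(k * isi_vols) + ceiling(24 / tr)
  if (n_timepoints < min_t)
    stop("n_timepoints = ", n_timepoints, " too small for ", k,
         " conditions at isi = ", stimulus_isi, " s (need >= ", min_t, ")")

  n_cycles <- floor((n_timepoints - ceiling(24 / tr)) / (k * isi_vols))
  onsets <- vector("list", k)
  slot <- 0
  for (cyc in seq_len(max(n_cycles, 1L))) {
    for (cond in sample.int(k)) {
      t0 <- slot * stimulus_isi
      onsets[[cond]] <- c(onsets[[cond]], t0)
      slot <- slot + 1
    }
  }
  hrf_t <- seq(0, 30, by = tr)
  hrf <- hrf_double_gamma(hrf_t)
  X <- matrix(0, n_timepoints, k)
  for (cond in seq_len(k)) {
    stick <- numeric(n_timepoints)
    vols <- round(onsets[[cond]] / tr) + 1L
    vols <- vols[vols <= n_timepoints]
    stick[vols] <- 1
    conv <- stats::convolve(stick, rev(hrf), type = "open")[
      seq_len(n_timepoints)]
    X[, cond] <- conv
  }

  E <- matrix(rnorm(n_timepoints * ncol(B), sd = noise_sd),
              n_timepoints, ncol(B))
  if (temporal_smooth_fwhm > 0) {
    sd_samp <- temporal_smooth_fwhm / 2.3548 / tr
    E <- apply(E, 2, gaussian_smooth_1d, sd_samples = sd_samp)
  }
  if (spatial_smooth_fwhm > 0) {
    if (is.null(vol_dim))
      stop("spatial smoothing requires vol_dim")
    if (prod(vol_dim) != ncol(B))
      stop("prod(vol_dim) must equal ncol(B)")
    for (t_i in seq_len(n_timepoints)) {
      vol <- array(E[t_i, ], dim = vol_dim)
      E[t_i, ] <- as.numeric(smooth_volume_3d(vol, spatial_smooth_fwhm,
                                              voxel_size_mm))
    }
  }
  list(Y = X %*% B + E, X = X, E = E, onsets = onsets)
}

# Separable 3D Gaussian smoothing; fwhm in mm, anisotropic voxels honored.
smooth_volume_3d <- function(vol, fwhm_mm, voxel_size_mm) {
  for (axis in 1:3) {
    sd_samp <- fwhm_mm / 2.3548 / voxel_size_mm[axis]
    if (sd_samp <= 0) next
    vol <- apply_along_axis(vol, axis,
                            function(v) gaussian_smooth_1d(v, sd_samp))
  }
  vol
}

apply_along_axis <- function(vol, axis, fun) {
  margins <- setdiff(1:3, axis)
  out <- apply(vol, margins, fun)
  # apply puts the function dimension first; restore original order
  aperm(out, order(c(axis, margins)))
}

#' Ordinary least-squares GLM estimation
#'
#' @param Y time x voxels data matrix.
#' @param X time x conditions design matrix (full column rank).
#' @return list with `B` (conditions x voxels estimates), `residuals`
#'   (time x voxels), `gram_inv` (`(X'X)^-1`), `dof` (rows minus columns).
#' @export
glm_estimate <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop("Y and X must have the same number of rows")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design matrix X is rank deficient")
  B <- qr.coef(qx, Y)
  fitted <- X %*% B
  list(B = B, residuals = Y - fitted, gram_inv = chol2inv(qr.R(qx)),
       dof = nrow(X) - ncol(X))
}

# block-structured categorical RDM: value[i, j] = level of the finest
# shared grouping; groups is a list of integer membership vectors, levels
# the corresponding dissimilarity per grouping (coarsest first)
categorical_rdm <- function(groups, levels, between, labels,
                            measure = "model") {
  n <- length(labels)
  m <- matrix(between, n, n)
  for (g in seq_along(groups)) {
    same <- outer(groups[[g]], groups[[g]], `==`)
    m[same] <- levels[g]
  }
  diag(m) <- 0
  rdm(rdm_vectorize(m), labels = labels, measure = measure)
}

#' Synthetic group-study scenario (condition-rich design)
#'
#' Builds a full synthetic analogue of a condition-rich group study: a
#' block-structured ground-truth RDM with two main clusters (animate /
#' inanimate) and a finer face sub-cluster mixed with a continuous
#' item-level geometry, ground-truth patterns embedded by
#' [patterns_from_rdm()], noisy single-subject pattern sets and their RDMs,
#' and a candidate set containing the true model, two categorical models
#' predicting tied dissimilarities, an unrelated control model, and one
#' noise-affected (subject-derived) candidate.
#'
#' Defaults follow the scale of a 92-image, 100-channel, 12-subject
#' experiment. `noise_sd` defaults to 0.2, calibrated once so that the
#' mean Spearman correlation between a single-subject RDM and the
#' ground-truth RDM is roughly 0.5 at this geometry.
#'
#' @param seed integer seed controlling every random component.
#' @param n_conditions,n_channels,n_subjects scenario size.
#' @param noise_sd isotropic noise sd added to the ground-truth patterns.
#' @param categorical_weight mixing weight of the categorical component in
#'   the ground-truth RDM (the continuous component gets 1 minus this).
#' @param embed_iter force-embedding iteration cap.
#' @return list with `ground_truth` (target rdm), `true_rdm` (RDM of the
#'   embedded noiseless patterns), `true_patterns`, `subject_rdms`
#'   (collection), `candidates` (collection), `category` (condition ->
#'   cluster id), `noise_sd`, `embedding_stress`.
#' @export
make_fig4_scenario <- function(seed = 1L, n_conditions = 92L,
                               n_channels = 100L, n_subjects = 12L,
                               noise_sd = 0.21, categorical_weight = 0.7,
                               embed_iter = 300L) {
  n <- n_conditions
  labels <- sprintf("cond%02d", seq_len(n))
  half <- floor(n / 2)
  quarter <- floor(n / 4)
  category <- ifelse(seq_len(n) <= half, 1L, 2L)    # animate / inanimate
  face <- as.integer(seq_len(n) <= quarter)         # face sub-cluster

  set.seed(as.integer(seed))
  # continuous item-level geometry: cluster centers + within-cluster scatter
  feat_dim <- 8L
  centers <- rbind(c(2, rep(0, feat_dim - 1)),
                   c(-2, rep(0, feat_dim - 1)))
  face_shift <- c(0, 1.2, rep(0, feat_dim - 2))
  feats <- centers[category, ] +
    outer(face, face_shift) +
    0.8 * matrix(rnorm(n * feat_dim), n, feat_dim)
  cont <- as.matrix(dist(feats))
  cont <- cont / max(cont)

  catm <- matrix(1, n, n)
  catm[outer(category, category, `==`)] <- 0.4
  catm[outer(face, face, `&`)] <- 0.15
  diag(catm) <- 0

  target <- (1 - categorical_weight) * cont + categorical_weight * catm
  target <- target / mean(target[lower.tri(target)])
  ground_truth <- rdm(rdm_vectorize(target), labels = labels,
                      measure = "model")

  emb <- patterns_from_rdm(ground_truth, n_channels,
                           seed = seed + 1L, max_iter = embed_iter,
                           tol = 0.01, init = "cmds")
  true_patterns <- emb$patterns
  true_rdm <- compute_rdm(true_patterns, "euclidean")
  true_rdm$measure <- "model"

  subj_sets <- noisy_subjects(true_patterns, n_subjects, noise_sd,
                              seed = seed + 2L)
  subject_rdms <- rdm_collection(
    lapply(subj_sets, compute_rdm, measure = "euclidean"),
    roles = "subject_estimate",
    names = sprintf("subject%02d", seq_len(n_subjects)))

  cat_animacy <- categorical_rdm(list(category), levels = 0.5,
                                 between = 1, labels = labels)
  # animacy plus face sub-cluster: three tied levels
  face_groups <- ifelse(face == 1L, 3L, category)
  cat_faces <- categorical_rdm(list(category, face_groups),
                               levels = c(0.6, 0.3), between = 1,
                               labels = labels)

  set.seed(as.integer(seed) + 3L)
  unrel <- matrix(rnorm(n * feat_dim), n, feat_dim)
  control <- rdm(as.numeric(dist(unrel)) / max(dist(unrel)),
                 labels = labels, measure = "model")

  # one extra noisy "brain" candidate: carries measurement noise, flagged
  brain_set <- noisy_subjects(true_patterns, 1L, noise_sd,
                              seed = seed + 4L)[[1]]
  brain_cand <- compute_rdm(brain_set, "euclidean")

  candidates <- rdm_collection(
    list(true_model = true_rdm,
         categorical_faces = cat_faces,
         categorical_animacy = cat_animacy,
         unrelated_control = control,
         other_brain = brain_cand),
    roles = c("candidate", "candidate", "candidate", "candidate",
              "subject_estimate"))

  list(ground_truth = ground_truth, true_rdm = true_rdm,
       true_patterns = true_patterns, subject_rdms = subject_rdms,
       candidates = candidates, category = category,
       noise_sd = noise_sd, embedding_stress = emb$stress)
}

#' Synthetic searchlight scenario with a planted region
#'
#' Emulates a group searchlight experiment: each subject's volume holds one
#' 3D map per condition; voxels inside a small planted region carry
#' patterns whose correlation geometry follows a two-cluster model RDM,
#' while the rest of the masked volume is spatially smoothed noise with no
#' condition structure.
#'
#' @param seed integer seed.
#' @param dim 3-vector of volume dimensions.
#' @param n_conditions number of conditions (split into two equal clusters).
#' @param n_subjects number of subjects.
#' @param planted_corner,planted_size corner index and edge length of the
#'   cubic planted region.
#' @param signal cluster separation amplitude.
#' @param noise_sd voxelwise noise sd.
#' @param smooth_fwhm_mm spatial noise smoothing FWHM.
#' @param voxel_size_mm voxel size.
#' @return list with `volumes` (list of [volume()] per subject), `mask`,
#'   `model` ([rdm()]), `planted` (logical array), `dim`, `voxel_size_mm`.
#' @export
make_searchlight_scenario <- function(seed = 1L, dim = c(12L, 12L, 8L),
                                      n_conditions = 64L, n_subjects = 20L,
                                      planted_corner = c(4L, 4L, 3L),
                                      planted_size = 3L, signal = 1.5,
                                      noise_sd = 1,
                                      smooth_fwhm_mm = 6,
                                      voxel_size_mm = c(3, 3, 3)) {
  labels <- sprintf("cond%02d", seq_len(n_conditions))
  cluster <- rep(1:2, each = n_conditions / 2)[seq_len(n_conditions)]
  model <- categorical_rdm(list(cluster), levels = 0, between = 1,
                           labels = labels)

  mask <- array(TRUE, dim)     # full-grid mask; borders exercise clipping
  planted <- array(FALSE, dim)
  pc <- planted_corner
  planted[pc[1]:(pc[1] + planted_size - 1L),
          pc[2]:(pc[2] + planted_size - 1L),
          pc[3]:(pc[3] + planted_size - 1L)] <- TRUE
  planted_idx <- which(planted)

  volumes <- lapply(seq_len(n_subjects), function(s) {
    set.seed((as.integer(seed) + 104729L * s) %% .Machine$integer.max)
    data <- array(0, c(dim, n_conditions))
    # per-voxel cluster response profiles, shared across a subject
    a <- rnorm(length(planted_idx), sd = signal)
    b <- rnorm(length(planted_idx), sd = signal)
    for (k in seq_len(n_conditions)) {
      noise <- smooth_volume_3d(array(rnorm(prod(dim), sd = noise_sd), dim),
                                smooth_fwhm_mm, voxel_size_mm)
      slice <- noise
      base <- if (cluster[k] == 1L) a else b
      slice[planted_idx] <- slice[planted_idx] + base +
        0.3 * signal * rnorm(length(planted_idx))
      data[, , , k] <- slice
    }
    volume(data, mask, voxel_size_mm)
  })

  list(volumes = volumes, mask = mask, model = model, planted = planted,
       dim = dim, voxel_size_mm = voxel_size_mm)
}

#' Synthetic two-partition GLM scenario for LD-t analysis
#'
#' Simulates, per subject, two independent fMRI partitions from the same
#' true patterns (two categories, each with two subcategories), estimates
#' condition patterns and residuals by OLS in each partition, and bundles
#' them as [partitioned_data()] ready for [ldt_rdm()].
#'
#' @param seed integer seed.
#' @param n_conditions conditions (divisible by 4 for the 2x2 hierarchy).
#' @param n_voxels channels per subject.
#' @param n_subjects subjects.
#' @param signal amplitude of the categorical pattern structure (0 = null).
#' @param noise_sd fMRI noise sd.
#' @param n_timepoints volumes per partition.
#' @return list with `data` (per-subject [partitioned_data()]), `category`,
#'   `subcategory`, `labels`.
#' @export
make_ldt_scenario <- function(seed = 1L, n_conditions = 16L, n_voxels = 24L,
                              n_subjects = 20L, signal = 1, noise_sd = 1,
                              n_timepoints = NULL) {
  labels <- sprintf("cond%02d", seq_len(n_conditions))
  category <- rep(1:2, each = n_conditions / 2)[seq_len(n_conditions)]
  subcategory <- rep(1:4, each = max(1, n_conditions / 4))[
    seq_len(n_conditions)]
  if (is.null(n_timepoints))
    n_timepoints <- ceiling(n_conditions * 2) + 16L

  data <- lapply(seq_len(n_subjects), function(s) {
    sseed <- (as.integer(seed) + 15485863L * s) %% .Machine$integer.max
    set.seed(sseed)
    cat_profile <- matrix(rnorm(2 * n_voxels), 2)
    sub_profile <- matrix(rnorm(4 * n_voxels), 4)
    B <- signal * (cat_profile[category, ] + 0.5 * sub_profile[subcategory, ]) +
      0.2 * signal * matrix(rnorm(n_conditions * n_voxels), n_conditions)
    part <- lapply(1:2, function(pt)
      simulate_fmri(B, n_timepoints, noise_sd = noise_sd,
                    temporal_smooth_fwhm = 4, seed = sseed + pt))
    est <- lapply(part, function(p) glm_estimate(p$Y, p$X))
    partitioned_data(
      pattern_set(est[[1]]$B, labels), pattern_set(est[[2]]$B, labels),
      est[[1]]$residuals, est[[2]]$residuals,
      dof2 = est[[2]]$dof, gram_inv2 = est[[2]]$gram_inv,
      dof1 = est[[1]]$dof, gram_inv1 = est[[1]]$gram_inv,
      regularize = if (n_timepoints <= n_voxels) 0.1 else 0)
  })
  list(data = data, category = category, subcategory = subcategory,
       labels = labels)
}
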