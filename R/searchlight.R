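#' Construct a 4D volume (one 3D map per condition)
#'
#' @param data numeric array X x Y x Z x N (N conditions).
#' @param mask logical (or 0/1) array X x Y x Z marking in-brain voxels.
#' @param voxel_size_mm length-3 voxel edge lengths in mm.
#' @param labels optional condition labels (default `cond1..N`).
#' @return Object of class `volume`.
#' @export
volume <- function(data, mask, voxel_size_mm = c(3, 3, 3), labels = NULL) {
  if (length(dim(data)) != 4L) stop("data must be a 4D array (X, Y, Z, N)")
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(mask), dim(data)[1:3]))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match data spatial shape ",
         paste(dim(data)[1:3], collapse = "x"))
  n <- dim(data)[4]
  if (n < 2L) stop("need at least 2 conditions")
  vox_in_mask <- apply(data, 4, function(v) v[mask])
  if (anyNA(vox_in_mask)) stop("missing values inside the mask")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be 3 positive lengths")
  if (is.null(labels)) labels <- paste0("cond", seq_len(n))
  structure(list(data = data, mask = mask,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 labels = as.character(labels)),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat("volume:", paste(dim(x$data)[1:3], collapse = "x"), "voxels,",
      dim(x$data)[4], "conditions,", sum(x$mask), "in mask\n")
  invisible(x)
}

#' Spherical searchlight neighborhoods
#'
#' For every in-mask voxel, lists the in-mask voxels whose center-to-center
#' Euclidean distance in millimetres (anisotropic voxel sizes honored) is at
#' most `radius_mm`. Every neighborhood contains its own center; spheres
#' are clipped at mask borders, never reaching outside the mask.
#'
#' @param mask logical 3D array.
#' @param voxel_size_mm length-3 voxel size in mm.
#' @param radius_mm sphere radius in mm (>= 0).
#' @return list with `centers` (linear voxel indices of in-mask centers) and
#'   `neighbors` (list of linear-index vectors, parallel to `centers`).
#' @export
spherical_neighborhoods <- function(mask, voxel_size_mm = c(3, 3, 3),
                                    radius_mm = 6) {
  mask <- array(as.logical(mask), dim(mask))
  if (radius_mm < 0) stop("radius_mm must be >= 0")
  if (!any(mask)) stop("empty mask")
  dm <- dim(mask)
  # relative integer offsets within the sphere
  ranges <- lapply(1:3, function(a) {
    r <- floor(radius_mm / voxel_size_mm[a])
    seq.int(-r, r)
  })
  off <- as.matrix(expand.grid(ranges[[1]], ranges[[2]], ranges[[3]]))
  mm <- sweep(off, 2, voxel_size_mm, `*`)
  off <- off[rowSums(mm^2) <= radius_mm^2 + 1e-9, , drop = FALSE]

  centers <- which(mask)
  coord <- arrayInd(centers, dm)
  neighbors <- vector("list", length(centers))
  for (i in seq_along(centers)) {
    nb <- sweep(off, 2, coord[i, ], `+`)
    ok <- nb[, 1] >= 1L & nb[, 1] <= dm[1] &
      nb[, 2] >= 1L & nb[, 2] <= dm[2] &
      nb[, 3] >= 1L & nb[, 3] <= dm[3]
    nb <- nb[ok, , drop = FALSE]
    lin <- nb[, 1] + dm[1] * (nb[, 2] - 1L) + dm[1] * dm[2] * (nb[, 3] - 1L)
    neighbors[[i]] <- unname(lin[mask[lin]])
  }
  list(centers = centers, neighbors = neighbors)
}

#' Searchlight RDM-correlation map for one subject
#'
#' At each in-mask voxel, the RDM across conditions is computed from the
#' patterns of its spherical neighborhood and compared with a model RDM.
#' The resulting correlation is written into a 3D map (NA outside the mask
#' and at undefined centers).
#'
#' @param vol a [volume()].
#' @param model model [rdm()] with as many conditions as the volume.
#' @param radius_mm searchlight radius in mm.
#' @param dissimilarity pattern dissimilarity inside each searchlight
#'   (`"correlation"` or `"euclidean"`).
#' @param comparison RDM comparison method (see [compare_rdms()]);
#'   `"spearman"` by default — tau-a is supported but markedly slower.
#' @param min_voxels centers whose clipped neighborhood is smaller than this
#'   are left undefined.
#' @param neighborhoods optional precomputed [spherical_neighborhoods()]
#'   (reused across subjects).
#' @return list with `r_map` (3D array), `n_undefined`.
#' @export
searchlight_map <- function(vol, model, radius_mm = 6,
                            dissimilarity = c("correlation", "euclidean"),
                            comparison = c("spearman", "pearson",
                                           "kendall_tau_a"),
                            min_voxels = 10L, neighborhoods = NULL) {
  stopifnot(inherits(vol, "volume"), inherits(model, "rdm"))
  dissimilarity <- match.arg(dissimilarity)
  comparison <- match.arg(comparison)
  n <- dim(vol$data)[4]
  if (length(model$labels) != n)
    stop("model RDM has ", length(model$labels), " conditions; volume has ",
         n)
  if (is.null(neighborhoods))
    neighborhoods <- spherical_neighborhoods(vol$mask, vol$voxel_size_mm,
                                             radius_mm)
  nvox <- prod(dim(vol$mask))
  flat <- matrix(vol$data, nvox, n)       # voxels x conditions
  model_d <- if (comparison == "spearman") rank(model$d) else model$d

  r_map <- array(NA_real_, dim(vol$mask))
  n_undefined <- 0L
  for (i in seq_along(neighborhoods$centers)) {
    nb <- neighborhoods$neighbors[[i]]
    if (length(nb) < min_voxels) {
      n_undefined <- n_undefined + 1L
      next
    }
    pats <- t(flat[nb, , drop = FALSE])   # conditions x voxels
    d <- if (dissimilarity == "correlation") {
      if (any(rowSums((pats - rowMeans(pats))^2) == 0)) {
        n_undefined <- n_undefined + 1L
        next
      }
      cm <- 1 - stats::cor(t(pats))
      cm[lower.tri(cm)]
    } else {
      as.numeric(dist(pats))
    }
    r_map[neighborhoods$centers[i]] <- if (comparison == "kendall_tau_a") {
      kendall_tau_a(d, model_d)
    } else {
      if (stats::sd(d) == 0) {
        n_undefined <- n_undefined + 1L
        NA_real_
      } else if (comparison == "spearman") {
        stats::cor(rank(d), model_d)
      } else {
        stats::cor(d, model_d)
      }
    }
  }
  if (n_undefined > 0L)
    message(n_undefined, " searchlight center(s) undefined (too small or ",
            "constant patterns)")
  list(r_map = r_map, n_undefined = n_undefined)
}

#' Group inference on searchlight maps
#'
#' At each voxel defined in every subject, a one-sided signed-rank test
#' across the subject-specific correlation values gives a p-value; the
#' in-mask p map is thresholded by Benjamini-Hochberg FDR control at
#' `alpha`. Undefined voxels are excluded from the FDR family. Reuses the
#' same signed-rank and BH implementations as the ROI-level inference
#' module.
#'
#' @param r_maps list of per-subject 3D correlation maps (identical
#'   dimensions, NA outside each subject's defined set).
#' @param alpha FDR level.
#' @return list with `p_map` (3D array, NA where undefined),
#'   `threshold_mask` (logical 3D array of FDR survivors), `n_tested`.
#' @export
searchlight_group_inference <- function(r_maps, alpha = 0.05) {
  if (length(r_maps) < 4L) stop("group inference needs >= 4 subjects")
  dims <- dim(r_maps[[1]])
  for (m in r_maps)
    if (!identical(dim(m), dims)) stop("r_map dimension mismatch")
  stack <- vapply(r_maps, as.numeric, numeric(prod(dims)))
  defined <- rowSums(is.na(stack)) == 0L
  idx <- which(defined)
  p <- vapply(idx, function(v) signed_rank_p(stack[v, ], "greater"),
              numeric(1))
  p_map <- array(NA_real_, dims)
  p_map[idx] <- p
  adj <- adjust_multiple(p, "fdr_bh", alpha)
  threshold_mask <- array(FALSE, dims)
  threshold_mask[idx] <- adj$reject
  list(p_map = p_map, threshold_mask = threshold_mask,
       n_tested = length(idx))
}
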