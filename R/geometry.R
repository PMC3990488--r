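#' 2D arrangement of conditions by metric-stress MDS
#'
#' Places the conditions in the plane so that their pairwise Euclidean
#' distances approximate the RDM dissimilarities, minimizing the metric
#' (raw) stress by SMACOF majorization. The best of `n_restarts` seeded
#' initializations (classical MDS plus random configurations) is returned.
#' Reported stress is normalized:
#' `sqrt(sum((dist - delta)^2) / sum(delta^2))`.
#'
#' @param x an [rdm()] with at least 3 conditions.
#' @param seed integer seed for the random restarts.
#' @param n_restarts number of initializations (the first is classical
#'   MDS).
#' @param max_iter,tol majorization iteration cap and relative stress
#'   improvement tolerance.
#' @return Object of class `arrangement_2d`: list with `coordinates`
#'   (N x 2, labeled rows), `stress`, `labels`.
#' @export
mds_2d <- function(x, seed = 1L, n_restarts = 4L, max_iter = 300L,
                   tol = 1e-9) {
  stopifnot(inherits(x, "rdm"))
  n <- length(x$labels)
  if (n < 3L) stop("MDS needs at least 3 conditions")
  delta <- rdm_square(x$d)
  denom <- sum(x$d^2)
  if (denom == 0) stop("all-zero RDM cannot be arranged")

  set.seed(as.integer(seed))
  inits <- vector("list", n_restarts)
  inits[[1]] <- tryCatch(stats::cmdscale(delta, k = 2),
                         error = function(e) NULL)
  if (is.null(inits[[1]]) || ncol(inits[[1]]) < 2L)
    inits[[1]] <- matrix(rnorm(2 * n), n, 2)
  for (r in seq_len(n_restarts)[-1])
    inits[[r]] <- matrix(rnorm(2 * n, sd = mean(x$d)), n, 2)

  best <- NULL
  for (cfg in inits) {
    res <- smacof_2d(cfg, delta, max_iter, tol)
    if (is.null(best) || res$stress < best$stress) best <- res
  }
  coords <- best$coordinates
  rownames(coords) <- x$labels
  structure(list(coordinates = coords,
                 stress = sqrt(best$raw_stress / denom),
                 labels = x$labels),
            class = "arrangement_2d")
}

#' @export
print.arrangement_2d <- function(x, ...) {
  cat("arrangement_2d:", length(x$labels), "conditions, stress =",
      format(x$stress, digits = 4), "\n")
  invisible(x)
}

# SMACOF majorization for metric MDS in 2D (Guttman transform updates).
smacof_2d <- function(conf, delta, max_iter, tol) {
  n <- nrow(delta)
  raw <- function(cfg) {
    d <- as.matrix(dist(cfg))
    sum((d[lower.tri(d)] - delta[lower.tri(delta)])^2)
  }
  s_old <- raw(conf)
  for (it in seq_len(max_iter)) {
    d <- as.matrix(dist(conf))
    d[d == 0] <- 1e-12
    b <- -delta / d
    diag(b) <- 0
    diag(b) <- -rowSums(b)
    conf_new <- (b %*% conf) / n
    s_new <- raw(conf_new)
    if (s_new > s_old) break     # numerical safety: majorization stalled
    conf <- conf_new
    if (s_old - s_new < tol * max(s_old, 1e-300)) {
      s_old <- s_new
      break
    }
    s_old <- s_new
  }
  list(coordinates = conf, raw_stress = s_old, stress = s_old)
}

#' Hierarchical agglomerative clustering of an RDM
#'
#' Standard agglomerative merge sequence over the RDM's dissimilarities,
#' exposing the categorical structure of the representation. Thin wrapper
#' around [stats::hclust()] that preserves the RDM's labels and records the
#' linkage used.
#'
#' @param x an [rdm()].
#' @param linkage `"average"`, `"single"` or `"complete"`.
#' @return Object of classes `cluster_tree` and `hclust` (so all `hclust`
#'   methods apply); element `linkage` records the tag.
#' @export
hierarchical_cluster <- function(x, linkage = c("average", "single",
                                                "complete")) {
  stopifnot(inherits(x, "rdm"))
  linkage <- match.arg(linkage)
  d <- stats::as.dist(rdm_square(x$d, labels = x$labels))
  h <- stats::hclust(d, method = linkage)
  h$linkage <- linkage
  class(h) <- c("cluster_tree", "hclust")
  h
}

#' Cut a cluster tree into k groups
#'
#' @param tree a [hierarchical_cluster()] result.
#' @param k number of groups.
#' @return named integer vector of group memberships.
#' @export
cut_clusters <- function(tree, k) {
  stats::cutree(structure(unclass(tree), class = "hclust"), k = k)
}
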