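## Low-dimensional embedding of the distance matrix
##
## Classical (Torgerson) MDS: double-center the squared distances,
## eigendecompose, and read coordinates off the leading eigenvectors scaled
## by the square root of their eigenvalues.  Fisher distance matrices are
## generally non-Euclidean, so some eigenvalues are negative; they are
## reported in the spectrum but never used for coordinates.

#' Classical multidimensional scaling of a distance matrix
#'
#' @param D symmetric distance matrix with zero diagonal (e.g. from
#'   [distance_matrix_factorized()]).
#' @param d requested embedding dimension, `1 <= d <= K - 1`.  If fewer than
#'   `d` eigenvalues are strictly positive the embedding is truncated, with a
#'   warning.
#' @return An object of class `sm_embedding`: list with `points` (K x d'
#'   coordinate matrix, rows labeled by group, columns ordered by descending
#'   eigenvalue), `eig` (the full signed spectrum, descending), `d` (the
#'   dimension actually used), `labels`.
#' @details Coordinates are centered by construction.  For reproducible
#'   output files each eigenvector's sign is fixed so that its first
#'   coordinate of non-negligible magnitude is positive.
#' @examples
#' pts <- cbind(c(0, 1, 2), c(0, 0, 0))
#' D <- as.matrix(dist(pts))
#' classical_mds(D, d = 1)$points
#' @export
classical_mds <- function(D, d = 2L) {
  D <- as.matrix(D)
  K <- nrow(D)
  if (K != ncol(D) || max(abs(D - t(D))) > 1e-8 || any(abs(diag(D)) > 1e-12))
    abort_qm("`D` must be a symmetric matrix with zero diagonal",
             "qm_validation_error")
  if (d < 1L || d > K - 1L)
    abort_qm(sprintf("`d` must be in 1 .. %d", K - 1L), "qm_domain_error")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("g", seq_len(K))

  B <- -0.5 * scale(t(scale(t(D^2), scale = FALSE)), scale = FALSE)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)  # eigenvalues already descending

  tol <- max(abs(e$values), 0) * 1e-10
  npos <- sum(e$values > tol)
  d_used <- min(d, npos)
  if (d_used < d)
    warn_qm(sprintf(
      "only %d strictly positive eigenvalue(s): embedding truncated from %d to %d dimension(s)",
      npos, d, d_used), "qm_reduced_dimension")

  pts <- matrix(0, K, d_used)
  if (d_used > 0L) {
    V <- e$vectors[, seq_len(d_used), drop = FALSE]
    # deterministic sign: first coordinate of appreciable size made positive
    for (j in seq_len(d_used)) {
      i <- which(abs(V[, j]) > 1e-8)[1L]
      if (!is.na(i) && V[i, j] < 0) V[, j] <- -V[, j]
    }
    pts <- V %*% diag(sqrt(e$values[seq_len(d_used)]), d_used)
  }
  dimnames(pts) <- list(labels, if (d_used > 0L) paste0("MDS", seq_len(d_used)))
  structure(list(points = pts, eig = e$values, d = d_used, labels = labels),
            class = "sm_embedding")
}

#' @export
print.sm_embedding <- function(x, ...) {
  cat(sprintf("Classical MDS embedding: %d groups in %d dimension(s)\n",
              nrow(x$points), x$d))
  pos <- x$eig[x$eig > 0]
  cat(sprintf("  positive eigenvalues: %d (leading: %s)\n", length(pos),
              paste(signif(utils::head(pos, 4), 4), collapse = ", ")))
  if (any(x$eig < 0))
    cat(sprintf("  most negative eigenvalue: %s (non-Euclidean input)\n",
                signif(min(x$eig), 4)))
  invisible(x)
}

#' Scree report of an eigenvalue spectrum
#'
#' Summarises the positive part of an MDS spectrum — eigenvalues, normalized
#' cumulative shares — and suggests an embedding dimension at the elbow,
#' taken as the largest second difference of the positive eigenvalues.
#' The suggestion is advisory; for a flat spectrum (no elbow) it equals the
#' number of positive eigenvalues and `flat` is set.
#'
#' @param spectrum numeric eigenvalue vector (descending) or an
#'   [sm_embedding][classical_mds()] object.
#' @return An object of class `qm_scree`: list with `eig_positive`,
#'   `cumulative_share`, `suggestion`, `flat`, `n_negative`.
#' @export
scree <- function(spectrum) {
  if (inherits(spectrum, "sm_embedding")) spectrum <- spectrum$eig
  if (!length(spectrum)) abort_qm("empty spectrum", "qm_domain_error")
  spectrum <- sort(spectrum, decreasing = TRUE)
  tol <- max(abs(spectrum)) * 1e-8
  pos <- spectrum[spectrum > tol]
  n_neg <- sum(spectrum < -tol)
  if (!length(pos))
    return(structure(list(eig_positive = numeric(), cumulative_share = numeric(),
                          suggestion = 0L, flat = TRUE, n_negative = n_neg),
                     class = "qm_scree"))
  share <- cumsum(pos) / sum(pos)
  p <- length(pos)
  if (p <= 2L) {
    suggestion <- p
    flat <- p == 2L && abs(pos[1L] - pos[2L]) <= tol
    if (p == 2L && !flat) suggestion <- if (pos[1L] / pos[2L] > 10) 1L else 2L
  } else {
    # second difference centered at index j+1; the elbow sits just before
    # the index where curvature peaks
    d2 <- pos[1:(p - 2L)] - 2 * pos[2:(p - 1L)] + pos[3:p]
    flat <- max(d2) <= tol
    suggestion <- if (flat) p else which.max(d2)
  }
  if (p == 1L) flat <- FALSE
  structure(list(eig_positive = pos, cumulative_share = share,
                 suggestion = as.integer(suggestion), flat = flat,
                 n_negative = n_neg),
            class = "qm_scree")
}

#' @export
print.qm_scree <- function(x, ...) {
  cat(sprintf("Scree report: %d positive eigenvalue(s), %d negative\n",
              length(x$eig_positive), x$n_negative))
  if (length(x$eig_positive)) {
    show <- utils::head(seq_along(x$eig_positive), 10)
    cat("  dim  eigenvalue  cumulative share\n")
    for (i in show)
      cat(sprintf("  %3d  %10.4g  %.3f\n", i, x$eig_positive[i],
                  x$cumulative_share[i]))
  }
  cat(sprintf("  suggested dimension: %d%s\n", x$suggestion,
              if (x$flat) " (flat spectrum, no clear elbow)" else ""))
  invisible(x)
}

#' PCA reduction of an embedding
#'
#' Projects an existing coordinate matrix onto its leading principal
#' components.  This is the second stage of the two-stage "full-rank MDS,
#' then PCA to 2-D" reduction used when the distance matrix is intrinsically
#' high-dimensional but a planar view is wanted.
#'
#' @param coords K x d coordinate matrix (or an
#'   [sm_embedding][classical_mds()], whose points are used).
#' @param target number of components to keep, `<= d`.
#' @return List with `points` (K x target scores), `variance_retained`
#'   (fraction in `[0, 1]`), `sdev` (all singular standard deviations).
#' @export
pca_reduce <- function(coords, target = 2L) {
  if (inherits(coords, "sm_embedding")) coords <- coords$points
  coords <- as.matrix(coords)
  if (target < 1L || target > ncol(coords))
    abort_qm(sprintf("`target` must be in 1 .. %d", ncol(coords)),
             "qm_dimension_error")
  pr <- stats::prcomp(coords, center = TRUE, scale. = FALSE)
  tot <- sum(pr$sdev^2)
  keep <- seq_len(min(target, length(pr$sdev)))
  pts <- pr$x[, keep, drop = FALSE]
  if (ncol(pts) < target)  # rank-deficient input: pad with exact zeros
    pts <- cbind(pts, matrix(0, nrow(pts), target - ncol(pts)))
  retained <- if (tot > 0) sum(pr$sdev[keep]^2) / tot else 1
  rownames(pts) <- rownames(coords)
  colnames(pts) <- paste0("PC", seq_len(target))
  list(points = pts, variance_retained = retained, sdev = pr$sdev)
}

#' Procrustes alignment of one configuration onto another
#'
#' Finds the translation, rotation/reflection and isotropic scaling of
#' `source` that minimise the summed squared differences to `target`, and
#' reports the disparity (residual sum of squares normalised by the total
#' centered variance of the target — 0 means the configurations match up to
#' a similarity transform).  Reflections are allowed, as embeddings from MDS
#' are only defined up to orthogonal transforms.
#'
#' @param source K x d coordinates to be aligned.
#' @param target K x d reference coordinates (must have positive variance).
#' @return List with `aligned` (source mapped into target's frame),
#'   `disparity`, `rotation`, `scale`, `translation`.
#' @export
procrustes_align <- function(source, target) {
  if (inherits(source, "sm_embedding")) source <- source$points
  if (inherits(target, "sm_embedding")) target <- target$points
  source <- as.matrix(source); target <- as.matrix(target)
  if (!identical(dim(source), dim(target)))
    abort_qm("`source` and `target` must have identical dimensions",
             "qm_schema_error")
  tc <- scale(target, scale = FALSE)
  ss_target <- sum(tc^2)
  if (ss_target <= 0)
    abort_qm("`target` has zero variance; alignment is undefined",
             "qm_degenerate_target")
  fit <- vegan::procrustes(X = target, Y = source, scale = TRUE,
                           symmetric = FALSE)
  aligned <- fit$Yrot + matrix(fit$xmean, nrow(target), ncol(target),
                               byrow = TRUE)
  list(aligned = aligned,
       disparity = sum((aligned - target)^2) / ss_target,
       rotation = fit$rotation, scale = fit$scale,
       translation = fit$translation)
}
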