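## Fisher geometry on the probability hypersphere
##
## In square-root coordinates xi_I = sqrt(p_I) every categorical distribution
## is a unit vector on the positive quadrant of the (N-1)-sphere, and the
## Fisher-Rao geodesic distance between two distributions is the great-circle
## arc length: D = arccos(sum_I xi^1_I xi^2_I).  The inner product is the
## Bhattacharyya coefficient; for factorized distributions it factorizes as a
## product of per-question terms, which is what keeps the method tractable
## when the number of response strings is exponential in the number of
## questions.

#' Bhattacharyya coefficient of two factorized group distributions
#'
#' Computes `prod_q sum_a sqrt(f^1_q(a) * f^2_q(a))`.  Algebraically this
#' equals the full-enumeration inner product `sum_I xi^1_I xi^2_I` of the two
#' factorized joints — the product distributes over the sum — but it never
#' enumerates the exponentially many strings.
#'
#' @param m1,m2 [group_marginals][estimate_group_marginals()] objects sharing
#'   the same questions and alphabets.
#' @return The coefficient, in `[0, 1]` up to floating-point noise.
#' @examples
#' tab <- response_table(data.frame(Q = c("a", "a", "a", "b")),
#'                       groups = c(1, 1, 2, 2))
#' m1 <- estimate_group_marginals(tab, "1")
#' m2 <- estimate_group_marginals(tab, "2")
#' bhattacharyya_factorized(m1, m2)  # sqrt(0.5)
#' @export
bhattacharyya_factorized <- function(m1, m2) {
  stopifnot(inherits(m1, "group_marginals"), inherits(m2, "group_marginals"))
  check_same_schema(m1, m2)
  c_ <- 1
  for (q in seq_along(m1$questions))
    c_ <- c_ * sum(sqrt(m1$freqs[[q]] * m2$freqs[[q]]))
  c_
}

#' Fisher distance from a Bhattacharyya coefficient
#'
#' The great-circle arc length `arccos(c)`.  Products of many per-question
#' sums can exceed 1 by a few ulps, so values in `(1, 1 + 1e-9]` are clipped
#' silently; anything below `-1e-12` or above `1 + 1e-9` signals a broken
#' upstream distribution and raises an error.
#'
#' @param c_ Bhattacharyya coefficient (inner product of two unit vectors on
#'   the positive quadrant).
#' @return Distance in radians, in `[0, pi/2]` for valid inputs.
#' @export
fisher_distance <- function(c_) {
  if (!is.numeric(c_) || anyNA(c_) || any(!is.finite(c_)))
    abort_qm("Bhattacharyya coefficient must be finite", "qm_numeric_domain_error")
  if (any(c_ < -1e-12) || any(c_ > 1 + 1e-9))
    abort_qm(sprintf(
      "coefficient outside [0, 1] beyond tolerance (range %.17g .. %.17g): upstream distribution is broken",
      min(c_), max(c_)), "qm_numeric_domain_error")
  acos(pmin(pmax(c_, 0), 1))
}

# shared validation + labeling for K x K distance matrices
as_distance_matrix <- function(D, labels) {
  dimnames(D) <- list(labels, labels)
  D
}

#' Fisher distance matrix from factorized group estimates
#'
#' All-to-all great-circle distances between the groups' factorized
#' distributions, via the per-question Bhattacharyya product.  This is the
#' default distance path of the method.
#'
#' @param groups list of [group_marginals][estimate_group_marginals()]
#'   objects with a common schema (at least two).
#' @return Symmetric K x K matrix of distances in radians, zero diagonal,
#'   labeled by group.
#' @seealso [distance_matrix_joint()] for the full-enumeration ground-truth
#'   path.
#' @export
distance_matrix_factorized <- function(groups) {
  if (length(groups) < 2L)
    abort_qm("at least two groups are required", "qm_schema_error")
  lapply(groups, function(g) stopifnot(inherits(g, "group_marginals")))
  for (g in groups[-1L]) check_same_schema(groups[[1L]], g)
  K <- length(groups)
  # per-question sqrt-frequency matrices: row = group, col = answer
  nq <- length(groups[[1L]]$questions)
  C <- matrix(1, K, K)
  for (q in seq_len(nq)) {
    S <- t(vapply(groups, function(g) sqrt(g$freqs[[q]]),
                  numeric(length(groups[[1L]]$alphabets[[q]]))))
    C <- C * tcrossprod(S)
  }
  D <- fisher_distance(C)
  diag(D) <- 0
  D <- (D + t(D)) / 2
  labels <- vapply(groups, `[[`, character(1), "group")
  as_distance_matrix(D, labels)
}

#' Fisher distance matrix from full joint distributions
#'
#' Direct evaluation of `arccos(sum_I xi^i_I xi^j_I)` on explicit probability
#' vectors.  Used for ground truth in validation (the simulated curve
#' distributions are not factorized) and as the enumeration oracle for the
#' factorized path.
#'
#' @param joints list of [joint_distribution()] objects over the same string
#'   space (at least two).
#' @param labels optional group labels for the matrix dimnames.
#' @return Symmetric K x K matrix of distances in radians, zero diagonal.
#' @export
distance_matrix_joint <- function(joints, labels = NULL) {
  if (length(joints) < 2L)
    abort_qm("at least two distributions are required", "qm_schema_error")
  lapply(joints, function(j) stopifnot(inherits(j, "joint_distribution")))
  n <- length(joints[[1L]]$p)
  if (any(vapply(joints, function(j) length(j$p), integer(1)) != n))
    abort_qm("joint distributions live on different string spaces",
             "qm_schema_error")
  Xi <- vapply(joints, function(j) sqrt(j$p), numeric(n))
  C <- crossprod(Xi)
  D <- fisher_distance(C)
  diag(D) <- 0
  D <- (D + t(D)) / 2
  if (is.null(labels)) labels <- paste0("g", seq_along(joints))
  as_distance_matrix(D, labels)
}
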