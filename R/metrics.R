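## Validation metrics: multipartite information, distance-matrix agreement,
## and the question-ablation procedure for attributing an outlying group to
## specific questions.

#' Multipartite information (total correlation) of a joint distribution
#'
#' The KL divergence of the joint from the product of its per-question
#' marginals, in nats:
#' `MI = sum_I p_I * ln(p_I / prod_q p_q(a_q(I)))`.
#' Zero if and only if the questions are independent, so any factorized
#' joint scores 0 exactly; strings with `p_I = 0` contribute nothing.
#' Tiny negative totals from floating-point cancellation (above `-1e-12`)
#' are clamped to 0.
#'
#' @param joint a [joint_distribution()].
#' @return MI in nats (single non-negative number).  For a one-question
#'   distribution the product of marginals is the joint itself, so the
#'   result is 0 by definition.
#' @examples
#' # perfectly correlated pair of binary questions: MI = ln 2
#' j <- joint_distribution(c(0.5, 0, 0, 0.5), c("Q1", "Q2"),
#'                         list(Q1 = c("a", "b"), Q2 = c("a", "b")))
#' multipartite_information(j)
#' @export
multipartite_information <- function(joint) {
  stopifnot(inherits(joint, "joint_distribution"))
  sizes <- lengths(joint$alphabets)
  nq <- length(sizes)
  if (nq < 2L) return(0)
  p <- joint$p
  idx <- index_to_answers(seq_along(p), sizes)
  log_prod_marg <- numeric(length(p))
  for (q in seq_len(nq)) {
    marg <- vapply(seq_len(sizes[q]),
                   function(a) sum(p[idx[, q] == a]), numeric(1))
    log_prod_marg <- log_prod_marg + log(marg)[idx[, q]]
  }
  pos <- p > 0  # marginals are >= p_I, so log terms are finite wherever p > 0
  mi <- sum(p[pos] * (log(p[pos]) - log_prod_marg[pos]))
  if (mi < 0) {
    if (mi < -1e-12)
      abort_qm(sprintf("multipartite information came out negative (%.3g)", mi),
               "qm_numeric_domain_error")
    mi <- 0
  }
  mi
}

#' Pearson correlation between two distance matrices
#'
#' Correlates the strictly-upper-triangle entries only: the diagonal is
#' identically zero and the lower triangle duplicates the upper, so
#' including either would bias the coefficient.
#'
#' @param d1,d2 symmetric K x K distance matrices with matching group order.
#' @return Pearson's r over the `K(K-1)/2` distinct pairs.
#' @export
matrix_pearson <- function(d1, d2) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!identical(dim(d1), dim(d2)))
    abort_qm("distance matrices have different shapes", "qm_schema_error")
  up <- upper.tri(d1)
  x <- d1[up]; y <- d2[up]
  if (length(x) < 2L)
    abort_qm("at least three groups are needed for a defined correlation",
             "qm_undefined_correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort_qm("a distance matrix is constant; correlation is undefined",
             "qm_undefined_correlation")
  stats::cor(x, y)
}

#' Euclidean distance matrix of embedding coordinates
#'
#' @param coords K x d coordinate matrix (or an
#'   [sm_embedding][classical_mds()]).
#' @return Symmetric K x K Euclidean distance matrix, zero diagonal.
#' @export
embedding_distances <- function(coords) {
  if (inherits(coords, "sm_embedding")) coords <- coords$points
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L)
    abort_qm("at least two points are required", "qm_schema_error")
  D <- as.matrix(stats::dist(coords))
  dimnames(D) <- list(rownames(coords), rownames(coords))
  D
}

#' Run the full simulation-validation pipeline
#'
#' Simulates a grouped study on a hypersphere curve, runs the estimation and
#' embedding pipeline on the sampled responses, and scores the recovered
#' geometry against the exact one: Pearson correlation between the
#' theoretical Fisher distance matrix (computed from the ground-truth
#' joints) and the Euclidean distance matrix of the low-dimensional
#' embedding.  The per-group multipartite information of the ground-truth
#' joints is recorded alongside, as the natural colouring of points along
#' the curve.
#'
#' @inheritParams simulate_study
#' @param d embedding dimension for the classical MDS step (default 2).
#' @param alpha smoothing pseudocount for the estimation step (default 0,
#'   the plug-in estimator).
#' @return An object of class `qm_validation`: list with `r` (Pearson
#'   correlation), `mi` (per-group MI in nats), `d`, `k_groups`,
#'   `n_per_group`, `placement`, `alpha`, `seed`, `spec`, and the matrices
#'   `d_theory`, `d_estimated`, `embedding`.
#' @examples
#' \donttest{
#' rep <- run_validation(curve_spec(1, 3, 8, 3), k_groups = 20,
#'                       n_per_group = 25, seed = 7)
#' rep$r
#' }
#' @export
run_validation <- function(spec, k_groups, n_per_group, d = 2L, seed = 1L,
                           placement = c("uniform", "random"), alpha = 0) {
  placement <- match.arg(placement)
  study <- simulate_study(spec, k_groups, n_per_group, placement, seed)
  marg <- lapply(levels(study$table$groups), function(g)
    estimate_group_marginals(study$table, g, alpha = alpha))
  d_est <- distance_matrix_factorized(marg)
  emb <- classical_mds(d_est, d = d)
  d_emb <- embedding_distances(emb)
  d_theory <- distance_matrix_joint(study$joints, labels = names(study$joints))
  r <- matrix_pearson(d_theory, d_emb)
  mi <- vapply(study$joints, multipartite_information, numeric(1))
  structure(
    list(r = r, mi = mi, d = emb$d, k_groups = as.integer(k_groups),
         n_per_group = as.integer(n_per_group), placement = placement,
         alpha = alpha, seed = as.integer(seed), spec = spec,
         d_theory = d_theory, d_estimated = d_est, embedding = emb),
    class = "qm_validation"
  )
}

#' @export
print.qm_validation <- function(x, ...) {
  cat(sprintf(
    "Validation run: K = %d, n = %d per group, d = %d, seed = %d\n",
    x$k_groups, x$n_per_group, x$d, x$seed))
  cat(sprintf("  Pearson r (theory vs embedding): %.4f\n", x$r))
  cat(sprintf("  multipartite information range: %.4g .. %.4g nats\n",
              min(x$mi), max(x$mi)))
  invisible(x)
}

# total-least-squares perpendicular distance of the focal centroid from the
# line through the non-focal centroids (first principal direction)
tls_offline_distance <- function(points, focal_rows) {
  other <- points[-focal_rows, , drop = FALSE]
  centre <- colMeans(other)
  centred <- sweep(other, 2, centre)
  sv <- svd(centred)
  dir <- sv$v[, 1L]
  focal <- colMeans(points[focal_rows, , drop = FALSE]) - centre
  resid <- focal - sum(focal * dir) * dir
  sqrt(sum(resid^2))
}

#' Attribute an outlying group to individual questions by ablation
#'
#' Measures how far a focal group sits from the linear trend formed by the
#' remaining groups in the low-dimensional embedding, then repeats the whole
#' pipeline with each question removed in turn.  A question whose removal
#' collapses the focal group back onto the trend is the one driving the
#' outlier.  The line is fitted to the non-focal group points by total least
#' squares (first principal direction), and the offset is the focal
#' centroid's perpendicular distance to it — both rotation-invariant, so the
#' arbitrary orientation of each MDS solution cannot affect the profile.
#'
#' @param table a [response_table()] with at least three groups and two
#'   questions.
#' @param focal_group one group label, or a vector of labels whose embedded
#'   points are pooled into a single centre of mass (e.g. all smoking strata
#'   of one ethnicity).
#' @param d embedding dimension (default 2).
#' @param alpha smoothing pseudocount passed to the estimation step.
#' @return An object of class `qm_ablation`: data frame with columns
#'   `question`, `distance` (focal offset with that question removed) and
#'   `drop` (baseline minus distance), sorted by decreasing `drop`; the
#'   all-questions baseline distance is in `attr(, "baseline")`.
#' @export
ablate_questions <- function(table, focal_group, d = 2L, alpha = 0) {
  stopifnot(inherits(table, "response_table"))
  groups <- levels(table$groups)
  focal_group <- as.character(focal_group)
  if (!all(focal_group %in% groups))
    abort_qm("focal group label(s) not present in the table",
             "qm_group_not_found")
  if (length(setdiff(groups, focal_group)) < 2L)
    abort_qm("need at least two non-focal groups to fit a trend line",
             "qm_fit_error")
  if (length(table$questions) < 2L)
    abort_qm("need at least two questions to ablate", "qm_domain_error")

  offset_for <- function(keep_questions) {
    sub <- response_table(
      table$answers[, keep_questions, drop = FALSE], table$groups,
      questions = table$questions[keep_questions],
      alphabets = table$alphabets[keep_questions])
    marg <- lapply(groups, function(g)
      estimate_group_marginals(sub, g, alpha = alpha))
    emb <- classical_mds(distance_matrix_factorized(marg), d = d)
    tls_offline_distance(emb$points, match(focal_group, groups))
  }

  nq <- length(table$questions)
  baseline <- offset_for(seq_len(nq))
  dist_without <- vapply(seq_len(nq),
                         function(q) offset_for(setdiff(seq_len(nq), q)),
                         numeric(1))
  out <- data.frame(question = table$questions,
                    distance = dist_without,
                    drop = baseline - dist_without,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$drop), ]
  rownames(out) <- NULL
  attr(out, "baseline") <- baseline
  class(out) <- c("qm_ablation", "data.frame")
  out
}

#' @export
print.qm_ablation <- function(x, ...) {
  cat(sprintf("Question ablation profile (baseline offset %.4g)\n",
              attr(x, "baseline")))
  print.data.frame(x, ...)
  invisible(x)
}
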