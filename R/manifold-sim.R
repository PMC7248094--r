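## Simulation framework: one-parameter curves on the probability hypersphere
##
## Synthetic studies place K groups on a known curve in the statistical
## manifold, sample categorical responses from each group's exact joint
## distribution, and retain the ground truth, so that the whole pipeline
## (estimate -> Fisher distances -> MDS) can be scored against the curve it
## is supposed to recover.

#' Specification of a hypersphere curve
#'
#' The curve lives on the positive quadrant of the unit (N-1)-sphere with
#' `N = n_a^n_q` response strings.  It is parameterised by `t` in `[0, 1]`
#' through the generalised spherical angles: angle `kappa` follows
#' `(pi/2) * sin^2(m * pi * t)` while every other angle grows linearly as
#' `(pi/2) * t`.  `kappa` selects which angle oscillates; `m` (a positive
#' integer) sets how many oscillations occur on `[0, 1]` and hence how
#' non-linear the family is.
#'
#' @param kappa index of the oscillating angle, in `1 .. N-1`.
#' @param m number of sine oscillations (positive integer).
#' @param n_q number of questions.
#' @param n_a number of answers per question.
#' @return An object of class `curve_spec` with the fields above plus the
#'   derived string count `n_strings`.
#' @examples
#' curve_spec(kappa = 1, m = 3, n_q = 8, n_a = 3)
#' @export
curve_spec <- function(kappa, m, n_q, n_a) {
  stopifnot(length(kappa) == 1L, length(m) == 1L,
            length(n_q) == 1L, length(n_a) == 1L)
  n_q <- as.integer(n_q); n_a <- as.integer(n_a)
  if (n_q < 1L || n_a < 2L)
    abort_qm("need n_q >= 1 and n_a >= 2", "qm_domain_error")
  n_strings <- n_a^n_q
  if (n_strings < 2)
    abort_qm("the hypersphere needs at least two strings", "qm_domain_error")
  if (m < 1 || m != round(m))
    abort_qm("`m` must be a positive integer", "qm_domain_error")
  if (kappa < 1 || kappa > n_strings - 1 || kappa != round(kappa))
    abort_qm(sprintf("`kappa` must be an integer in 1 .. %d", n_strings - 1),
             "qm_domain_error")
  structure(list(kappa = as.integer(kappa), m = as.integer(m),
                 n_q = n_q, n_a = n_a, n_strings = as.integer(n_strings)),
            class = "curve_spec")
}

#' @export
print.curve_spec <- function(x, ...) {
  cat(sprintf(
    "Hypersphere curve: kappa = %d, m = %d, N_Q = %d, N_A = %d (N = %d strings)\n",
    x$kappa, x$m, x$n_q, x$n_a, x$n_strings))
  invisible(x)
}

#' Generalised spherical coordinates to square-root coordinates
#'
#' Maps `N - 1` angles in `[0, pi/2]` to the unit vector
#' `xi_1 = cos(phi_1)`, `xi_j = sin(phi_1)...sin(phi_{j-1}) cos(phi_j)`,
#' `xi_N = sin(phi_1)...sin(phi_{N-1})`.  Restricting the angles to the first
#' quadrant keeps every component non-negative, i.e. the image is a valid
#' square-root probability vector.
#'
#' @param angles numeric vector of `N - 1` angles, each in `[0, pi/2]`.
#' @return Unit vector of length `N` with non-negative components.
#' @examples
#' spherical_to_sqrt_coords(c(pi / 4, pi / 4))  # (sqrt(2)/2, 1/2, 1/2)
#' @export
spherical_to_sqrt_coords <- function(angles) {
  if (length(angles) < 1L || anyNA(angles) ||
      any(angles < 0) || any(angles > pi / 2))
    abort_qm("all angles must lie in [0, pi/2]", "qm_domain_error")
  n <- length(angles) + 1L
  s <- cumprod(sin(angles))
  xi <- numeric(n)
  xi[1L] <- cos(angles[1L])
  if (n > 2L) xi[2:(n - 1L)] <- s[1:(n - 2L)] * cos(angles[2:(n - 1L)])
  xi[n] <- s[n - 1L]
  xi
}

#' Angles of the curve at parameter t
#'
#' @param t curve parameter in `[0, 1]`.
#' @param spec a [curve_spec()].
#' @return Numeric vector of `N - 1` angles in `[0, pi/2]`.
#' @export
curve_angles <- function(t, spec) {
  stopifnot(inherits(spec, "curve_spec"))
  if (length(t) != 1L || is.na(t) || t < 0 || t > 1)
    abort_qm("`t` must be a single value in [0, 1]", "qm_domain_error")
  angles <- rep((pi / 2) * t, spec$n_strings - 1L)
  angles[spec$kappa] <- (pi / 2) * sin(spec$m * pi * t)^2
  # sin^2 can exceed pi/2 mapping only by rounding; clamp defensively
  pmin(angles, pi / 2)
}

#' Exact joint distribution at a point on the curve
#'
#' Squares the square-root coordinates: `p_I = xi_I^2`, with coordinate `j`
#' bound to the j-th response string in the package's lexicographic order.
#'
#' @inheritParams curve_angles
#' @return A [joint_distribution()] with the standard question labels
#'   `Q1..Qn_q` and answer codes `letters[1:n_a]`.
#' @export
curve_distribution <- function(t, spec) {
  stopifnot(inherits(spec, "curve_spec"))
  xi <- spherical_to_sqrt_coords(curve_angles(t, spec))
  p <- xi^2
  p <- p / sum(p)  # renormalise away rounding in the squares
  questions <- paste0("Q", seq_len(spec$n_q))
  alphabets <- stats::setNames(
    rep(list(letters[seq_len(spec$n_a)]), spec$n_q), questions)
  joint_distribution(p, questions, alphabets)
}

#' Sample respondent records from a joint distribution
#'
#' Draws `n` response strings i.i.d. from the categorical distribution over
#' all strings and decodes each back to per-question answer codes via the
#' lexicographic string-order convention.  Deterministic under a fixed RNG
#' state; pass `seed` to fix one locally.
#'
#' @param joint a [joint_distribution()].
#' @param n number of respondents to draw.
#' @param seed optional integer seed (applied with [set.seed()]).
#' @return Character matrix with `n` rows and one column per question.
#' @export
sample_responses <- function(joint, n, seed = NULL) {
  stopifnot(inherits(joint, "joint_distribution"))
  if (n < 1) abort_qm("`n` must be at least 1", "qm_domain_error")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(length(joint$p), size = n, replace = TRUE, prob = joint$p)
  sizes <- lengths(joint$alphabets)
  ai <- index_to_answers(idx, sizes)
  out <- matrix("", nrow = n, ncol = length(joint$questions),
                dimnames = list(NULL, joint$questions))
  for (q in seq_along(joint$questions))
    out[, q] <- joint$alphabets[[q]][ai[, q]]
  out
}

#' Simulate a grouped questionnaire study on a hypersphere curve
#'
#' Places `K` groups on the curve — uniformly spaced on `[0, 1]` including
#' both endpoints, or at sorted uniform random positions — computes each
#' group's exact joint distribution, and samples `n_per_group` respondents
#' per group.  One RNG stream drives the whole study; groups are sampled in
#' order of increasing `t`, so the draw for group k depends on `K` (adding
#' groups changes all draws).
#'
#' @param spec a [curve_spec()].
#' @param k_groups number of groups `K >= 2`.
#' @param n_per_group respondents sampled per group.
#' @param placement `"uniform"` (default) or `"random"` placement of the
#'   group parameters on `[0, 1]`.
#' @param seed integer seed; the study is fully reproducible from
#'   `(spec, k_groups, n_per_group, placement, seed)`.
#' @return An object of class `simulated_study`: list with `table` (a
#'   [response_table()]), `joints` (per-group ground-truth
#'   [joint_distribution()]s), `t` (per-group curve parameters), plus the
#'   echoed `spec`, `placement`, `seed`.
#' @examples
#' study <- simulate_study(curve_spec(1, 1, 2, 2), k_groups = 3,
#'                         n_per_group = 10, seed = 42)
#' study$t
#' @export
simulate_study <- function(spec, k_groups, n_per_group,
                           placement = c("uniform", "random"), seed = 1L) {
  stopifnot(inherits(spec, "curve_spec"))
  placement <- match.arg(placement)
  if (k_groups < 2L) abort_qm("need at least two groups", "qm_domain_error")
  if (n_per_group < 1L) abort_qm("need at least one respondent per group",
                                 "qm_domain_error")
  set.seed(seed)
  t_k <- if (placement == "uniform") seq(0, 1, length.out = k_groups)
         else sort(stats::runif(k_groups))
  labels <- sprintf("g%02d", seq_len(k_groups))
  joints <- lapply(t_k, curve_distribution, spec = spec)
  names(joints) <- labels
  answer_blocks <- lapply(joints, sample_responses, n = n_per_group)
  answers <- do.call(rbind, answer_blocks)
  groups <- rep(labels, each = n_per_group)
  tab <- response_table(answers, groups,
                        questions = joints[[1L]]$questions,
                        alphabets = joints[[1L]]$alphabets)
  structure(
    list(table = tab, joints = joints, t = stats::setNames(t_k, labels),
         spec = spec, placement = placement, seed = seed,
         n_per_group = as.integer(n_per_group)),
    class = "simulated_study"
  )
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "Simulated study: %d groups x %d respondents on curve (kappa=%d, m=%d, N_Q=%d, N_A=%d), %s placement, seed %d\n",
    length(x$joints), x$n_per_group, x$spec$kappa, x$spec$m,
    x$spec$n_q, x$spec$n_a, x$placement, x$seed))
  invisible(x)
}
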