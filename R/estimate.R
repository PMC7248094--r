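#' Estimate per-question answer frequencies for one group
#'
#' Non-parametric plug-in estimate of a group's response distribution under
#' the factorization assumption: questions are treated as independent within
#' the group, so the joint probability of a response string is the product of
#' per-question marginal frequencies.  With the default `alpha = 0` the
#' estimate is the raw relative frequency `count / n`.
#'
#' A positive pseudocount `alpha` applies additive (Dirichlet) smoothing,
#' `(count + alpha) / (n + alpha * |alphabet|)`.  This is exposed because two
#' groups with disjoint observed support on any single question sit at the
#' maximal Fisher distance pi/2 regardless of the remaining questions; a
#' small `alpha` softens that hard orthogonality when it is an artefact of
#' small samples.
#'
#' @param table a [response_table()].
#' @param group a group label present in `table`.
#' @param alpha smoothing pseudocount, `>= 0` (default 0: plug-in estimator).
#' @return An object of class `group_marginals`: list with `group`, `n`,
#'   `freqs` (named list, per question, of named probability vectors over the
#'   full alphabet), `alpha`, `questions`, `alphabets`.
#' @examples
#' tab <- response_table(data.frame(Q1 = c("a", "a"), Q2 = c("a", "b")),
#'                       groups = c("g", "g"))
#' estimate_group_marginals(tab, "g")
#' @seealso [factorized_joint()], [string_probability()],
#'   [distance_matrix_factorized()]
#' @export
estimate_group_marginals <- function(table, group, alpha = 0) {
  stopifnot(inherits(table, "response_table"))
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0)
    abort_qm("`alpha` must be a single non-negative number", "qm_domain_error")
  if (!group %in% levels(table$groups))
    abort_qm(sprintf("group '%s' not found in response table", group),
             "qm_group_not_found")
  rows <- which(table$groups == group)
  n <- length(rows)
  if (n == 0L)
    abort_qm(sprintf("group '%s' has no respondents", group), "qm_empty_group")

  freqs <- vector("list", length(table$questions))
  names(freqs) <- table$questions
  for (q in seq_along(table$questions)) {
    a <- table$answers[rows, q]
    if (anyNA(a))
      abort_qm(sprintf(
        "group '%s' has missing answers for question '%s'; clean the table first",
        group, table$questions[q]), "qm_missing_answer")
    alphabet <- table$alphabets[[q]]
    if (!all(a %in% alphabet))
      abort_qm(sprintf(
        "group '%s', question '%s': answer code(s) outside the alphabet: %s",
        group, table$questions[q],
        paste(unique(setdiff(a, alphabet)), collapse = ", ")),
        "qm_domain_error")
    counts <- table(factor(a, levels = alphabet))
    f <- (as.numeric(counts) + alpha) / (n + alpha * length(alphabet))
    names(f) <- alphabet
    freqs[[q]] <- f
  }
  structure(
    list(group = as.character(group), n = n, freqs = freqs, alpha = alpha,
         questions = table$questions, alphabets = table$alphabets),
    class = "group_marginals"
  )
}

#' @export
print.group_marginals <- function(x, ...) {
  cat(sprintf("Group '%s' marginals (n = %d, alpha = %g)\n",
              x$group, x$n, x$alpha))
  for (q in x$questions) {
    f <- x$freqs[[q]]
    cat(sprintf("  %s: %s\n", q,
                paste(sprintf("%s=%.4g", names(f), f), collapse = " ")))
  }
  invisible(x)
}

# shared schema check for pairwise/groupwise operations
check_same_schema <- function(m1, m2) {
  if (!identical(m1$questions, m2$questions) ||
      !identical(m1$alphabets, m2$alphabets))
    abort_qm("group marginals have different question sets or alphabets",
             "qm_schema_error")
  invisible(TRUE)
}

#' Materialize the factorized joint distribution
#'
#' Expands a set of per-question marginals into the full probability vector
#' over all `N = prod(|alphabet_q|)` response strings,
#' `p_I = prod_q f_q(a_q(I))`, in the package's lexicographic string order
#' (question 1 most significant).  Intended for small questionnaires and for
#' ground-truth comparisons: `N` grows exponentially with the number of
#' questions, so the expansion is refused above `max_strings` — all distance
#' computations have factorized-path equivalents that never enumerate.
#'
#' @param m a [group_marginals][estimate_group_marginals()] object.
#' @param max_strings refuse expansion beyond this many strings (default 1e6).
#' @return A `joint_distribution` object: list with `p` (probability vector
#'   of length N), `questions`, `alphabets`.
#' @examples
#' tab <- response_table(data.frame(Q1 = c("a", "a"), Q2 = c("a", "b")),
#'                       groups = c("g", "g"))
#' factorized_joint(estimate_group_marginals(tab, "g"))$p
#' @export
factorized_joint <- function(m, max_strings = 1e6) {
  stopifnot(inherits(m, "group_marginals"))
  n_strings <- prod(lengths(m$alphabets))
  if (n_strings > max_strings)
    abort_qm(sprintf(
      paste0("joint distribution would have %.3g strings (cap %.3g); ",
             "use the factorized-path operations instead of enumerating"),
      n_strings, max_strings), "qm_size_error")
  # kronecker keeps question 1 most significant: index of Q1 varies slowest
  p <- Reduce(kronecker, m$freqs)
  joint_distribution(p, m$questions, m$alphabets)
}

#' Construct a joint distribution over response strings
#'
#' @param p probability vector over all response strings, in lexicographic
#'   string order (question 1 most significant).
#' @param questions question identifiers.
#' @param alphabets named list of answer codes per question;
#'   `prod(lengths(alphabets))` must equal `length(p)`.
#' @return An object of class `joint_distribution`.
#' @export
joint_distribution <- function(p, questions, alphabets) {
  p <- as.numeric(p)
  if (length(p) != prod(lengths(alphabets)))
    abort_qm("length of p must equal the number of response strings",
             "qm_schema_error")
  if (anyNA(p) || any(p < 0))
    abort_qm("joint probabilities must be non-negative and non-missing",
             "qm_distribution_error")
  if (abs(sum(p) - 1) > 1e-8)
    abort_qm(sprintf("joint probabilities sum to %.10g, not 1", sum(p)),
             "qm_distribution_error")
  structure(list(p = p, questions = questions, alphabets = alphabets),
            class = "joint_distribution")
}

#' @export
print.joint_distribution <- function(x, ...) {
  cat(sprintf(
    "Joint distribution over %d response strings (%d questions)\n",
    length(x$p), length(x$questions)))
  invisible(x)
}

#' Probability of a single response string under factorized marginals
#'
#' Evaluates `prod_q f_q(a_q)` directly, without enumerating the joint.
#' Agrees with the corresponding entry of [factorized_joint()] whenever that
#' expansion is feasible.
#'
#' @inheritParams factorized_joint
#' @param answers character vector of answer codes, one per question, in
#'   question order.
#' @return A single probability.
#' @export
string_probability <- function(m, answers) {
  stopifnot(inherits(m, "group_marginals"))
  if (length(answers) != length(m$questions))
    abort_qm("one answer per question is required", "qm_schema_error")
  p <- 1
  for (q in seq_along(m$questions)) {
    f <- m$freqs[[q]]
    a <- as.character(answers[q])
    if (!a %in% names(f))
      abort_qm(sprintf("question '%s': answer code '%s' not in alphabet",
                       m$questions[q], a), "qm_domain_error")
    p <- p * f[[a]]
  }
  p
}
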