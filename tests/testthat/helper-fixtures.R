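# Fixture builders shared across the suite.  Everything is generated in code
# under explicit seeds; no data files.

# Build a group_marginals object directly from a list of frequency vectors.
marginals_from_freqs <- function(freqs, group = "g") {
  questions <- names(freqs)
  if (is.null(questions)) {
    questions <- paste0("Q", seq_along(freqs))
    names(freqs) <- questions
  }
  alphabets <- lapply(freqs, function(f) {
    if (is.null(names(f))) letters[seq_along(f)] else names(f)
  })
  freqs <- Map(function(f, a) stats::setNames(as.numeric(f), a), freqs, alphabets)
  structure(
    list(group = group, n = NA_integer_, freqs = freqs, alpha = 0,
         questions = questions, alphabets = alphabets),
    class = "group_marginals"
  )
}

# Random factorized marginals (Dirichlet-uniform per question).
random_marginals <- function(n_q, n_a, group = "g") {
  freqs <- lapply(seq_len(n_q), function(q) {
    x <- stats::rgamma(n_a, shape = 1)
    x / sum(x)
  })
  names(freqs) <- paste0("Q", seq_len(n_q))
  marginals_from_freqs(freqs, group)
}

# Random (non-factorized) joint distribution over n_a^n_q strings.
random_joint <- function(n_q, n_a) {
  n <- n_a^n_q
  p <- stats::rgamma(n, shape = 1)
  p <- p / sum(p)
  questions <- paste0("Q", seq_len(n_q))
  alphabets <- stats::setNames(rep(list(letters[seq_len(n_a)]), n_q), questions)
  joint_distribution(p, questions, alphabets)
}

# Independent full-enumeration oracle for the factorized joint: builds the
# string grid with expand.grid (last question varying fastest, matching the
# package's lexicographic convention) and multiplies frequencies per row.
oracle_factorized_joint <- function(m) {
  grid <- expand.grid(rev(m$alphabets), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(grid)), drop = FALSE]  # back to question order
  apply(grid, 1L, function(row)
    prod(mapply(function(f, a) f[[a]], m$freqs, row)))
}

# Full-enumeration Fisher distance between two factorized groups.
oracle_fisher_distance <- function(m1, m2) {
  p1 <- oracle_factorized_joint(m1)
  p2 <- oracle_factorized_joint(m2)
  acos(min(1, sum(sqrt(p1 * p2))))
}

# Response table sampled from per-group factorized marginals (large n so the
# estimates are close to the generating frequencies).
table_from_marginals <- function(freq_list, n_per_group) {
  blocks <- lapply(names(freq_list), function(g) {
    joint <- factorized_joint(marginals_from_freqs(freq_list[[g]], g))
    sample_responses(joint, n_per_group)
  })
  answers <- do.call(rbind, blocks)
  groups <- rep(names(freq_list), each = n_per_group)
  response_table(answers, groups)
}
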