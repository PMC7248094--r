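two_question_table <- function() {
  response_table(
    data.frame(Q1 = c("a", "a"), Q2 = c("a", "b")),
    groups = c("g", "g"),
    alphabets = list(Q1 = c("a", "b"), Q2 = c("a", "b"))
  )
}

test_that("plug-in marginals are exact relative frequencies", {
  m <- estimate_group_marginals(two_question_table(), "g")
  expect_identical(m$freqs$Q1, c(a = 1, b = 0))     # exact rationals at alpha = 0
  expect_identical(m$freqs$Q2, c(a = 0.5, b = 0.5))
  expect_equal(m$n, 2L)
})

test_that("marginals are valid probability tables on arbitrary data", {
  set.seed(11)
  for (rep in 1:5) {
    freqs <- lapply(1:3, function(q) { x <- rgamma(3, 1); x / sum(x) })
    names(freqs) <- paste0("Q", 1:3)
    tab <- table_from_marginals(list(g1 = freqs, g2 = freqs), 40)
    for (g in c("g1", "g2")) {
      m <- estimate_group_marginals(tab, g)
      for (f in m$freqs) {
        expect_lt(abs(sum(f) - 1), 1e-12)
        expect_true(all(f >= 0 & f <= 1))
      }
    }
  }
})

test_that("identical records give point-mass marginals", {
  tab <- response_table(data.frame(Q1 = rep("b", 5), Q2 = rep("a", 5)),
                        groups = rep("g", 5),
                        alphabets = list(Q1 = c("a", "b"), Q2 = c("a", "b")))
  m <- estimate_group_marginals(tab, "g")
  expect_identical(m$freqs$Q1, c(a = 0, b = 1))
  expect_identical(m$freqs$Q2, c(a = 1, b = 0))
})

test_that("estimation rejects unknown groups and missing answers", {
  tab <- two_question_table()
  expect_error(estimate_group_marginals(tab, "nope"),
               class = "qm_group_not_found")
  tab_na <- response_table(data.frame(Q1 = c("a", NA)), groups = c("g", "g"),
                           alphabets = list(Q1 = c("a", "b")))
  expect_error(estimate_group_marginals(tab_na, "g"),
               class = "qm_missing_answer")
})

test_that("smoothing pulls every frequency strictly toward uniform", {
  set.seed(21)
  tab <- table_from_marginals(
    list(g = list(Q1 = c(0.8, 0.15, 0.05), Q2 = c(0.5, 0.3, 0.2))), 50)
  alphas <- c(0, 0.5, 1, 5, 50)
  prev <- estimate_group_marginals(tab, "g", alpha = alphas[1])
  for (a in alphas[-1]) {
    cur <- estimate_group_marginals(tab, "g", alpha = a)
    for (q in names(cur$freqs)) {
      u <- 1 / length(cur$freqs[[q]])
      gap_prev <- abs(prev$freqs[[q]] - u)
      gap_cur <- abs(cur$freqs[[q]] - u)
      at_uniform <- gap_prev < 1e-12
      expect_true(all(gap_cur[!at_uniform] < gap_prev[!at_uniform]))
      expect_true(all(gap_cur[at_uniform] < 1e-12))
    }
  }
})

test_that("factorized joint is the product of marginals in string order", {
  m <- marginals_from_freqs(list(Q1 = c(a = 1, b = 0), Q2 = c(a = 0.5, b = 0.5)))
  j <- factorized_joint(m)
  expect_equal(j$p, c(0.5, 0.5, 0, 0))  # strings aa, ab, ba, bb
  u <- marginals_from_freqs(list(Q1 = c(0.5, 0.5), Q2 = c(0.5, 0.5)))
  expect_equal(factorized_joint(u)$p, rep(0.25, 4))
})

test_that("joint invariants hold for estimate-then-expand on random fixtures", {
  set.seed(31)
  for (rep in 1:10) {
    n_q <- sample(1:4, 1); n_a <- sample(2:3, 1)
    freqs <- lapply(seq_len(n_q), function(q) { x <- rgamma(n_a, 1); x / sum(x) })
    names(freqs) <- paste0("Q", seq_len(n_q))
    tab <- table_from_marginals(list(g = freqs), 30)
    j <- factorized_joint(estimate_group_marginals(tab, "g"))
    expect_lt(abs(sum(j$p) - 1), 1e-12)
    expect_true(all(j$p >= 0))
    expect_lt(abs(sum(sqrt(j$p)^2) - 1), 1e-12)
  }
})

test_that("joint expansion refuses to enumerate above the string cap", {
  m <- marginals_from_freqs(list(Q1 = rep(1 / 3, 3), Q2 = rep(1 / 3, 3)))
  expect_error(factorized_joint(m, max_strings = 8), class = "qm_size_error")
})

test_that("string_probability matches the enumerated joint entry", {
  set.seed(41)
  m <- random_marginals(3, 3)
  j <- factorized_joint(m)
  strings <- qmanifold:::enumerate_strings(m$alphabets)
  for (i in sample(nrow(strings), 10))
    expect_lt(abs(string_probability(m, strings[i, ]) - j$p[i]), 1e-15)
  pm <- marginals_from_freqs(list(Q1 = c(a = 1, b = 0), Q2 = c(a = 0, b = 1)))
  expect_identical(string_probability(pm, c("a", "b")), 1)
  expect_identical(string_probability(pm, c("b", "b")), 0)
  expect_error(string_probability(pm, c("z", "b")), class = "qm_domain_error")
})

test_that("re-estimation from a large sample recovers the generating frequencies", {
  set.seed(51)
  freqs <- list(Q1 = c(0.6, 0.3, 0.1), Q2 = c(0.25, 0.25, 0.5))
  n <- 1e4
  tab <- table_from_marginals(list(g = freqs), n)
  m <- estimate_group_marginals(tab, "g")
  for (q in names(freqs)) {
    f_true <- freqs[[q]]
    bound <- 4 * sqrt(f_true * (1 - f_true) / n)
    expect_true(all(abs(m$freqs[[q]] - f_true) <= bound))
  }
})

test_that("validate_table reports small groups, missing cells and foreign codes", {
  tab <- response_table(
    data.frame(Q1 = c("a", "b", "z", "a", "a"), Q2 = c("x", NA, "x", "y", "x")),
    groups = c("g1", "g1", "g1", "g2", "g2"),
    alphabets = list(Q1 = c("a", "b", "c"), Q2 = c("x", "y")))
  rep <- validate_table(tab, min_group_size = 3)
  expect_equal(rep$small_groups$group, "g2")
  expect_equal(rep$small_groups$n, 2L)
  expect_equal(rep$missing_cells$row, 2L)
  expect_equal(rep$foreign_answers$row, 3L)
  expect_equal(rep$foreign_answers$code, "z")
  expect_true("c" %in% rep$unused_codes$code)
  # advisory only: clean table yields empty findings
  clean <- validate_table(two_question_table(), min_group_size = 1)
  expect_equal(nrow(clean$small_groups), 0L)
  expect_equal(nrow(clean$missing_cells), 0L)
  expect_equal(nrow(clean$foreign_answers), 0L)
})
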