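## Response-string ordering convention
##
## A respondent's answers to the N_Q questions form a response string
## I = (a_1, ..., a_NQ).  All joint probability vectors in this package are
## indexed by the lexicographic order of these strings over the answer codes,
## with question 1 the most significant position (so the last question varies
## fastest).  This fixed bijection between coordinate index and string is what
## makes joint vectors comparable across groups and reproducible across runs.

#' Convert answer-code indices to a string index
#'
#' @param answer_idx integer matrix (rows = strings) or vector of 1-based
#'   answer positions within each question's alphabet, one column per question.
#' @param sizes integer vector of alphabet sizes per question.
#' @return 1-based string indices under the lexicographic convention
#'   (question 1 most significant).
#' @keywords internal
string_index <- function(answer_idx, sizes) {
  if (is.null(dim(answer_idx))) answer_idx <- matrix(answer_idx, nrow = 1L)
  nq <- length(sizes)
  stopifnot(ncol(answer_idx) == nq)
  # place value of question q is prod(sizes[(q+1):nq])
  place <- rev(cumprod(rev(c(sizes[-1L], 1L))))
  as.integer(1L + (answer_idx - 1L) %*% place)
}

#' Decode string indices back to answer-code indices
#'
#' Inverse of [string_index()]; mixed-radix decoding with question 1 most
#' significant.
#'
#' @inheritParams string_index
#' @param idx 1-based string indices.
#' @return integer matrix, one row per index, one column per question.
#' @keywords internal
index_to_answers <- function(idx, sizes) {
  nq <- length(sizes)
  out <- matrix(0L, nrow = length(idx), ncol = nq)
  rem <- as.integer(idx) - 1L
  for (q in nq:1L) {
    out[, q] <- rem %% sizes[q] + 1L
    rem <- rem %/% sizes[q]
  }
  out
}

#' Enumerate all response strings for a set of alphabets
#'
#' @param alphabets named list of character vectors (answer codes), in
#'   question order.
#' @return character matrix with `prod(lengths(alphabets))` rows, one column
#'   per question, rows in the package's lexicographic string order.
#' @keywords internal
enumerate_strings <- function(alphabets) {
  sizes <- lengths(alphabets)
  n <- prod(sizes)
  idx <- index_to_answers(seq_len(n), sizes)
  out <- matrix("", nrow = n, ncol = length(alphabets),
                dimnames = list(NULL, names(alphabets)))
  for (q in seq_along(alphabets)) out[, q] <- alphabets[[q]][idx[, q]]
  out
}
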