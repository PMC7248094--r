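#' Grouped categorical response table
#'
#' The basic data container: one row per respondent, one categorical answer
#' per question, plus a group label per respondent.  Answer codes are opaque
#' strings; no ordinal interpretation is ever attached to them.
#'
#' Alphabets (the set of admissible codes per question) are inferred from the
#' data by default, or can be supplied to pin the dimensions of the joint
#' distribution — answer codes never observed in a given group keep an
#' estimated frequency of 0 so that probability vectors stay aligned across
#' groups.
#'
#' The constructor tolerates missing (`NA`) answers and, when alphabets are
#' supplied explicitly, answers outside the alphabet; both are reported by
#' [validate_table()] rather than rejected here, so that a table can be
#' inspected before cleaning.  Estimation functions do reject them.
#'
#' @param answers data frame or character matrix of answer codes, one column
#'   per question, one row per respondent.
#' @param groups vector of group labels, one per respondent.
#' @param questions question identifiers; defaults to the column names of
#'   `answers`.
#' @param alphabets optional named list of character vectors giving the
#'   admissible answer codes per question, in a fixed order.  Default: the
#'   sorted unique observed codes.
#' @return An object of class `response_table`: a list with elements
#'   `answers` (character matrix), `groups` (factor), `questions`,
#'   `alphabets`.
#' @examples
#' tab <- response_table(
#'   data.frame(Q1 = c("a", "a", "b"), Q2 = c("x", "y", "x")),
#'   groups = c("g1", "g1", "g2")
#' )
#' tab
#' @export
response_table <- function(answers, groups, questions = colnames(answers),
                           alphabets = NULL) {
  answers <- as.matrix(answers)
  storage.mode(answers) <- "character"
  if (is.null(questions)) questions <- paste0("Q", seq_len(ncol(answers)))
  if (length(questions) != ncol(answers))
    abort_qm("number of question identifiers must match number of answer columns",
             "qm_schema_error")
  if (nrow(answers) != length(groups))
    abort_qm("one group label is required per respondent", "qm_schema_error")
  if (nrow(answers) == 0L)
    abort_qm("response table must contain at least one respondent", "qm_schema_error")
  colnames(answers) <- questions
  groups <- factor(groups)
  if (any(is.na(groups)))
    abort_qm("group labels may not be missing", "qm_schema_error")
  if (is.null(alphabets)) {
    alphabets <- lapply(seq_len(ncol(answers)), function(q)
      sort(unique(stats::na.omit(answers[, q]))))
    names(alphabets) <- questions
  } else {
    if (!setequal(names(alphabets), questions))
      abort_qm("alphabet names must match the question identifiers", "qm_schema_error")
    alphabets <- lapply(alphabets[questions], as.character)
  }
  if (any(lengths(alphabets) == 0L))
    abort_qm("every question needs a non-empty alphabet", "qm_schema_error")
  structure(
    list(answers = answers, groups = groups,
         questions = questions, alphabets = alphabets),
    class = "response_table"
  )
}

#' @export
print.response_table <- function(x, ...) {
  cat(sprintf("Response table: %d respondents, %d questions, %d groups\n",
              nrow(x$answers), length(x$questions), nlevels(x$groups)))
  cat("  questions: ", paste(x$questions, collapse = ", "), "\n", sep = "")
  cat("  alphabet sizes: ", paste(lengths(x$alphabets), collapse = ", "),
      "\n", sep = "")
  cat("  groups: ", paste(levels(x$groups), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.response_table <- function(x) dim(x$answers)

#' Check a response table for conditions that degrade estimation
#'
#' Purely advisory: reports (without modifying anything) groups whose sample
#' size is below `min_group_size`, cells with missing answers, answers that
#' fall outside the declared alphabet, and alphabet codes never observed.
#' Small groups are the method's main failure mode — their estimated
#' distributions can land anywhere on the manifold by chance — and simulation
#' evidence puts the knee of the accuracy curve at roughly 20-25 respondents
#' per group, hence the default threshold.
#'
#' @param table a [response_table()].
#' @param min_group_size advisory minimum respondents per group (default 20).
#' @return An object of class `qm_validation_report`: list with
#'   `small_groups` (data frame group/n), `missing_cells` (row/question),
#'   `foreign_answers` (row/question/code), `unused_codes`
#'   (question/code), and the threshold used.
#' @examples
#' tab <- response_table(data.frame(Q1 = c("a", "b", "a")),
#'                       groups = c("g1", "g1", "g2"))
#' validate_table(tab, min_group_size = 2)
#' @export
validate_table <- function(table, min_group_size = 20L) {
  stopifnot(inherits(table, "response_table"))
  n_by_group <- table(table$groups)
  small <- n_by_group[n_by_group < min_group_size]
  small_groups <- data.frame(group = names(small), n = as.integer(small),
                             stringsAsFactors = FALSE)

  missing_cells <- which(is.na(table$answers), arr.ind = TRUE)
  missing_cells <- data.frame(
    row = as.integer(missing_cells[, 1L]),
    question = table$questions[missing_cells[, 2L]],
    stringsAsFactors = FALSE)

  foreign <- lapply(seq_along(table$questions), function(q) {
    a <- table$answers[, q]
    bad <- which(!is.na(a) & !(a %in% table$alphabets[[q]]))
    if (!length(bad)) return(NULL)
    data.frame(row = bad, question = table$questions[q], code = a[bad],
               stringsAsFactors = FALSE)
  })
  foreign_answers <- do.call(rbind, c(foreign, list(
    data.frame(row = integer(), question = character(), code = character(),
               stringsAsFactors = FALSE))))

  unused <- lapply(seq_along(table$questions), function(q) {
    codes <- setdiff(table$alphabets[[q]], table$answers[, q])
    if (!length(codes)) return(NULL)
    data.frame(question = table$questions[q], code = codes,
               stringsAsFactors = FALSE)
  })
  unused_codes <- do.call(rbind, c(unused, list(
    data.frame(question = character(), code = character(),
               stringsAsFactors = FALSE))))

  structure(
    list(small_groups = small_groups, missing_cells = missing_cells,
         foreign_answers = foreign_answers, unused_codes = unused_codes,
         min_group_size = as.integer(min_group_size)),
    class = "qm_validation_report"
  )
}

#' @export
print.qm_validation_report <- function(x, ...) {
  cat("Response-table validation report\n")
  if (nrow(x$small_groups)) {
    cat(sprintf("  groups below n = %d:\n", x$min_group_size))
    for (i in seq_len(nrow(x$small_groups)))
      cat(sprintf("    %s (n = %d)\n", x$small_groups$group[i], x$small_groups$n[i]))
  } else cat(sprintf("  all groups have n >= %d\n", x$min_group_size))
  cat(sprintf("  missing answers: %d cell(s)\n", nrow(x$missing_cells)))
  cat(sprintf("  answers outside alphabet: %d cell(s)\n", nrow(x$foreign_answers)))
  cat(sprintf("  declared but unused codes: %d\n", nrow(x$unused_codes)))
  invisible(x)
}
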