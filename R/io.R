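## CSV round-tripping
##
## The on-disk format for responses is a plain CSV: one header row with the
## grouping column(s) followed by question identifiers, one respondent per
## row, answers as opaque strings.  Distance matrices are labeled square
## CSVs written with 17 significant digits so that reading them back
## reproduces the doubles bit-for-bit.

#' Read a response table from CSV
#'
#' When more than one grouping column is named, groups are formed as their
#' cross-product (levels joined with `"."`), e.g. ethnicity x smoking
#' status.
#'
#' @param path CSV file: header row, one respondent per row, UTF-8.
#' @param group_cols name(s) of the grouping column(s); every other column
#'   is treated as a question.
#' @param alphabets optional named list pinning the answer codes per
#'   question (see [response_table()]).
#' @return A [response_table()].
#' @export
read_responses <- function(path, group_cols = "group", alphabets = NULL) {
  if (!file.exists(path))
    abort_qm(sprintf("file not found: %s", path), "qm_parse_error")
  df <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    fileEncoding = "UTF-8"),
    error = function(e) abort_qm(sprintf("cannot parse '%s': %s", path,
                                         conditionMessage(e)),
                                 "qm_parse_error"))
  if (nrow(df) == 0L)
    abort_qm(sprintf("'%s' contains no respondents", path), "qm_parse_error")
  missing_cols <- setdiff(group_cols, names(df))
  if (length(missing_cols))
    abort_qm(sprintf("grouping column(s) not found: %s",
                     paste(missing_cols, collapse = ", ")), "qm_parse_error")
  groups <- do.call(paste, c(df[group_cols], sep = "."))
  questions <- setdiff(names(df), group_cols)
  if (!length(questions))
    abort_qm("no question columns remain after removing grouping columns",
             "qm_parse_error")
  ans <- df[questions]
  ans[ans == ""] <- NA_character_
  response_table(ans, groups, questions = questions, alphabets = alphabets)
}

#' Write a response table to CSV
#'
#' Inverse of [read_responses()] with a single grouping column named
#' `group`.
#'
#' @param table a [response_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(table, path) {
  stopifnot(inherits(table, "response_table"))
  df <- data.frame(group = as.character(table$groups),
                   table$answers, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a labeled distance matrix as CSV (full precision)
#'
#' @param D labeled square matrix (radians for Fisher distances).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path) {
  D <- as.matrix(D)
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("g", seq_len(nrow(D)))
  body <- apply(D, c(1, 2), fmt17)
  df <- data.frame(group = labels, body, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("group", labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix()]
#'
#' @param path CSV path.
#' @return Labeled square numeric matrix.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  labels <- df[[1L]]
  D <- as.matrix(df[-1L])
  storage.mode(D) <- "double"
  dimnames(D) <- list(labels, colnames(df)[-1L])
  D
}

#' Write embedding coordinates as CSV (full precision)
#'
#' @param emb an [sm_embedding][classical_mds()] or coordinate matrix.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(emb, path) {
  pts <- if (inherits(emb, "sm_embedding")) emb$points else as.matrix(emb)
  labels <- rownames(pts)
  if (is.null(labels)) labels <- paste0("g", seq_len(nrow(pts)))
  body <- apply(pts, c(1, 2), fmt17)
  if (is.null(dim(body))) body <- matrix(body, ncol = ncol(pts))
  df <- data.frame(group = labels, body, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("group", colnames(pts))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
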