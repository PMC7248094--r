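#' Run the full embedding pipeline and write an artifact bundle
#'
#' Executes estimate -> Fisher distances -> classical MDS (followed by a PCA
#' reduction to 2-D in the `"subak"` style, which first embeds at full rank)
#' and writes the distance matrix, the embedding coordinates, a scree/
#' eigenvalue report (JSON) and a run log to `out_dir`.  Given the same
#' configuration and seed, the output files are byte-identical except for
#' the timestamp line of the log.
#'
#' @param config a list with either `input` (path to a response CSV, plus
#'   optional `group_cols`, default `"group"`) or `sim` (arguments for
#'   [simulate_study()]: `kappa`, `m`, `n_q`, `n_a`, `k_groups`,
#'   `n_per_group`, optional `placement`), and optionally `alpha` (default
#'   0), `d` (integer dimension or `"auto"` for the scree suggestion;
#'   default 2), `seed` (default 1), `style` (`"default"` or `"subak"`),
#'   `alphabets`.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with the `response_table` used, `distances`,
#'   `embedding`, `scree`, the paths written, and — for simulated input —
#'   the [run_validation()]-style correlation against the theoretical
#'   distance matrix.
#' @examples
#' \donttest{
#' out <- run_pipeline(
#'   list(sim = list(kappa = 1, m = 1, n_q = 2, n_a = 2,
#'                   k_groups = 5, n_per_group = 30), seed = 3),
#'   out_dir = tempfile("qm"))
#' out$scree$suggestion
#' }
#' @export
run_pipeline <- function(config, out_dir) {
  stage <- "configuration"
  written <- character()
  on_fail <- function(e) {
    file.remove(written[file.exists(written)])
    abort_qm(sprintf("pipeline failed at stage '%s': %s", stage,
                     conditionMessage(e)),
             "qm_pipeline_error")
  }
  tryCatch({
    has_input <- !is.null(config$input); has_sim <- !is.null(config$sim)
    if (has_input == has_sim)
      abort_qm("exactly one of `input` and `sim` must be given",
               "qm_config_error")
    alpha <- if (is.null(config$alpha)) 0 else config$alpha
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    style <- if (is.null(config$style)) "default" else config$style
    d_req <- if (is.null(config$d)) 2L else config$d
    if (!style %in% c("default", "subak"))
      abort_qm("`style` must be 'default' or 'subak'", "qm_config_error")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

    stage <- "read"
    theory <- NULL
    if (has_input) {
      gcols <- if (is.null(config$group_cols)) "group" else config$group_cols
      tab <- read_responses(config$input, gcols, config$alphabets)
    } else {
      s <- config$sim
      spec <- curve_spec(s$kappa, s$m, s$n_q, s$n_a)
      placement <- if (is.null(s$placement)) "uniform" else s$placement
      study <- simulate_study(spec, s$k_groups, s$n_per_group, placement, seed)
      tab <- study$table
      theory <- distance_matrix_joint(study$joints, names(study$joints))
    }

    stage <- "estimate"
    marg <- lapply(levels(tab$groups), function(g)
      estimate_group_marginals(tab, g, alpha = alpha))

    stage <- "distance"
    D <- distance_matrix_factorized(marg)

    stage <- "mds"
    K <- nrow(D)
    full_rank <- K - 1L
    d_use <- if (identical(style, "subak")) full_rank
             else if (identical(d_req, "auto")) full_rank
             else as.integer(d_req)
    emb <- suppressWarnings(classical_mds(D, d = d_use))
    sc <- scree(emb)
    if (identical(d_req, "auto") && !identical(style, "subak") &&
        sc$suggestion >= 1L && sc$suggestion < emb$d) {
      emb <- classical_mds(D, d = sc$suggestion)
    }
    coords <- emb$points
    retained <- NULL
    if (identical(style, "subak")) {
      stage <- "pca"
      red <- pca_reduce(coords, target = min(2L, ncol(coords)))
      coords <- red$points
      retained <- red$variance_retained
    }

    stage <- "write"
    p_dist <- file.path(out_dir, "distance_matrix.csv")
    p_emb <- file.path(out_dir, "embedding.csv")
    p_scree <- file.path(out_dir, "scree.json")
    p_log <- file.path(out_dir, "run_log.txt")
    written <- c(p_dist, p_emb, p_scree, p_log)
    write_distance_matrix(D, p_dist)
    write_embedding(coords, p_emb)
    report <- list(eigenvalues = emb$eig,
                   positive = sc$eig_positive,
                   cumulative_share = sc$cumulative_share,
                   suggested_dimension = sc$suggestion,
                   flat = sc$flat,
                   dimension_used = ncol(coords),
                   variance_retained = retained,
                   seed = seed, alpha = alpha, style = style)
    if (!is.null(theory) && nrow(theory) >= 3L) {
      r <- matrix_pearson(theory, embedding_distances(coords))
      report$validation_r <- r
    }
    jsonlite::write_json(report, p_scree, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    writeLines(c(
      sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      sprintf("qmanifold version: %s",
              as.character(utils::packageVersion("qmanifold"))),
      sprintf("R version: %s", R.version.string),
      sprintf("seed: %d", seed),
      sprintf("alpha: %g", alpha),
      sprintf("dimension used: %d", ncol(coords)),
      sprintf("style: %s", style),
      "string order: lexicographic over answer codes, question 1 most significant (v1)"
    ), p_log)

    invisible(list(table = tab, marginals = marg, distances = D,
                   embedding = emb, coords = coords, scree = sc,
                   variance_retained = retained,
                   validation_r = report$validation_r,
                   paths = list(distances = p_dist, embedding = p_emb,
                                scree = p_scree, log = p_log)))
  }, qm_error = function(e) on_fail(e), error = function(e) on_fail(e))
}
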