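#' Run the full caste-transition analysis
#'
#' End-to-end pipeline over a colony dataset: descriptive caste summary
#' (rates, CIs, Wald letters), the 28-model grid fit, QAICc ranking with
#' Akaike weights, post-selection refinement, and with-gain / no-gain
#' trajectories of the refined model.  Every number in the returned
#' report is the direct output of the corresponding package operation;
#' the writers below only format.
#'
#' @param input `"fixture"` for the embedded 15-colony dataset, or a path
#'   to a colony CSV.
#' @param aggregation binomial cell resolution for the likelihood,
#'   `"by_colony_stage"` (default; each colony x stage cell is one
#'   binomial observation) or `"by_species_stage"`.  The two give
#'   identical estimates and weights (see [negative_log_likelihood()]);
#'   the choice fixes the scale of the reported `-lnL` and the default
#'   `n_eff`.
#' @param c_hat overdispersion factor for QAICc (default fixed 2.9; see
#'   [estimate_overdispersion()]).
#' @param n_eff effective sample size for QAICc; `NULL` uses the number
#'   of binomial cells.
#' @param count_chat_param whether `c_hat` counts as a parameter in K.
#' @param initial_rate stage-1 infection rate for the recursion.
#' @param settings optimizer settings.
#' @param outdir optional directory; when given, the report tables are
#'   written there as CSV/JSON.
#' @return an `analysis_report` list: `descriptive`, `selection_table`,
#'   `refinement`, `trajectories`, `fits`, `config_echo`.
#' @export
run_full_analysis <- function(input = "fixture",
                              aggregation = c("by_colony_stage",
                                              "by_species_stage"),
                              c_hat = 2.9, n_eff = NULL,
                              count_chat_param = TRUE,
                              initial_rate = 1.0,
                              settings = fit_settings(),
                              outdir = NULL) {
  aggregation <- match.arg(aggregation)
  data <- if (identical(input, "fixture")) table1_fixture()
          else load_colony_csv(input)
  cells <- pool(data, aggregation)

  descriptive <- caste_summary_table(data)
  overall <- list(
    n_tested = sum(data$n_tested), n_infected = sum(data$n_infected),
    prevalence_pct = round(100 * sum(data$n_infected) / sum(data$n_tested), 2))

  grid <- enumerate_model_grid()
  fits <- lapply(grid, fit_model, cells = cells, settings = settings,
                 initial_rate = initial_rate)
  if (any(!vapply(fits, function(f) isTRUE(f$converged), logical(1)))) {
    warning("one or more grid fits did not converge; see selection table",
            call. = FALSE)
  }
  selection <- rank_and_weight(fits, c_hat = c_hat, n_eff = n_eff,
                               count_chat_param = count_chat_param)
  best_id <- selection$model_id[1]
  best_fit <- fits[[best_id]]
  best_fit$se <- hessian_standard_errors(best_fit, cells)
  refinement <- refine_model(best_fit, cells, c_hat = c_hat, n_eff = n_eff,
                             count_chat_param = count_chat_param,
                             settings = settings)
  final <- refinement$selected
  trajectories <- trajectory_table(final$params, final$spec$equation,
                                   initial_rate)
  # annotate species with unobserved stages
  observed <- unique(cells[, c("species", "stage_ordinal")])
  trajectories$partial_data <- !paste(trajectories$species,
                                      trajectories$stage_ordinal) %in%
    paste(observed$species, observed$stage_ordinal) &
    trajectories$stage_ordinal %in% .model_stages

  report <- structure(
    list(descriptive = descriptive, overall = overall,
         selection_table = selection, refinement = refinement,
         trajectories = trajectories, fits = fits,
         equation_support = equation_support(selection),
         config_echo = list(input = input, aggregation = aggregation,
                            c_hat = c_hat,
                            n_eff = n_eff %||% nrow(cells),
                            count_chat_param = count_chat_param,
                            initial_rate = initial_rate,
                            settings = settings)),
    class = "analysis_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Overall prevalence: %d/%d (%.2f%%)\n",
              x$overall$n_infected, x$overall$n_tested,
              x$overall$prevalence_pct))
  cat("\nCaste summary:\n")
  print(x$descriptive, row.names = FALSE)
  cat("\nTop of the selection table:\n")
  print(utils::head(x$selection_table[, c("model_id", "equation",
                                          "loss_pattern", "gain_pattern",
                                          "neg_log_lik", "K", "qaicc",
                                          "weight")], 5), row.names = FALSE)
  cat(sprintf("\nEquation-2 support: %.3f\n", x$equation_support))
  cat("\nRefined model:\n")
  print(x$refinement$selected)
  invisible(x)
}

#' Write a model-selection table to CSV (and JSON)
#'
#' One row per model in grid numbering with the QAICc ranking columns
#' and a flag on the selected (lowest-QAICc) model.
#'
#' @param rows a selection table from [rank_and_weight()].
#' @param path output path; `.csv` extension writes CSV, `.json` JSON.
#' @export
write_selection_table <- function(rows, path) {
  if (!nrow(rows)) stop("empty selection table", call. = FALSE)
  out <- rows[order(rows$model_id), , drop = FALSE]
  out$best <- !is.na(out$delta_qaicc) & out$delta_qaicc == 0
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write all report tables of an analysis
#'
#' @param report an `analysis_report`.
#' @param outdir output directory (created if missing).
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$descriptive,
                   file.path(outdir, "caste_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  write_selection_table(report$selection_table,
                        file.path(outdir, "selection_table.csv"))
  utils::write.csv(report$trajectories,
                   file.path(outdir, "trajectories.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(report$refinement$merge_log)) {
    utils::write.csv(report$refinement$merge_log,
                     file.path(outdir, "refinement_log.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  fin <- report$refinement$selected
  jsonlite::write_json(
    list(label = fin$spec$label, K = fin$K,
         neg_log_lik = fin$neg_log_lik,
         parameters = stats::setNames(as.list(fin$theta),
                                      fin$spec$par_info$label),
         config = report$config_echo),
    file.path(outdir, "refined_model.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
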