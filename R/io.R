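#' Read a delimited survival table
#'
#' Reads a CSV/TSV subject-level survival table with required columns
#' `time`, `event`, `unit`, `year` plus covariate columns.  The delimiter
#' is sniffed from the header line (comma or tab).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_survival_table <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = sep,
                                      stringsAsFactors = FALSE))
}

#' Write fit outputs to a directory
#'
#' Writes the posterior draws (`draws.csv`, one column per scalar
#' parameter), the posterior summary (`summary.json`: estimates with 95%
#' credible limits, DIC, acceptance rates), and the Cox-Snell residuals
#' (`residuals.csv`).
#'
#' @param fit A `staft_fit`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fit_outputs <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(fit$draws, file.path(dir, "draws.csv"), row.names = FALSE)
  res <- cox_snell_residuals(fit)
  utils::write.csv(res, file.path(dir, "residuals.csv"), row.names = FALSE)
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite needed for summary.json", call. = FALSE)
  }
  summary_list <- list(
    model = fit$spec$model, family = fit$spec$family,
    n = nrow(fit$data), I = fit$graph$I, J = fit$spec$J,
    estimates = fit$summary,
    dic = if (is.null(fit$dic)) NULL else unclass(fit$dic),
    acceptance = fit$acceptance
  )
  jsonlite::write_json(summary_list, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
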