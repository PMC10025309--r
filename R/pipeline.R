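# End-to-end pipeline: read a long measurement table, normalize if needed,
# compute per-replicate and aggregated index tables, trend statistics and
# ANOVA/Tukey comparisons, and write the report bundle as CSV + a plain-text
# summary. The pipeline is a pure function of (input, config, seed).

#' Pipeline configuration
#'
#' @param input Path to a long-format measurement CSV
#'   ([read_measurement_table()]).
#' @param out_dir Output directory (created if absent).
#' @param condition_variable Restrict to `"temperature_C"` or `"pH"` series;
#'   `NULL` processes every series in the input.
#' @param mode Index computation mode, see [index_table()].
#' @param alpha Significance threshold in (0, 1).
#' @param carbon_range Index scope (default C10--C18).
#' @param value_kind `"relative_abundance"` or `"peak_area"`; peak areas are
#'   normalized to their profile's basis before analysis.
#' @param seed Optional integer recorded in the log (the core pipeline is
#'   deterministic; the seed matters only for simulation subcommands).
#' @return A `run_config` list.
#' @export
run_config <- function(input, out_dir,
                       condition_variable = NULL,
                       mode = "per_replicate",
                       alpha = 0.05,
                       carbon_range = c(10, 18),
                       value_kind = "relative_abundance",
                       seed = NULL) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  if (!file.exists(input)) stop("input not found: ", input, call. = FALSE)
  mode <- match.arg(mode, c("per_replicate", "ratio_of_means"))
  value_kind <- match.arg(value_kind, c("relative_abundance", "peak_area"))
  if (!is.null(condition_variable)) {
    condition_variable <- match.arg(condition_variable, fa_condition_levels)
  }
  structure(list(input = input, out_dir = out_dir,
                 condition_variable = condition_variable, mode = mode,
                 alpha = alpha, carbon_range = carbon_range,
                 value_kind = value_kind, seed = seed),
            class = "run_config")
}

.log_stage <- function(stage, ...) {
  message(sprintf("[hydroxyFA] %s: %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Reads the input, builds one [experiment_series()] per strain and
#' condition variable, and writes per series: the normalized profile table,
#' replicate-level and aggregated index tables, a trend report, and
#' ANOVA/Tukey comparison tables for every index defined on at least two
#' levels. A structured log line per stage records row counts; empty
#' outputs are never written silently.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of output file paths plus the in-memory
#'   tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  .log_stage("read", "input %s", config$input)
  df <- read_measurement_table(config$input)
  .log_stage("read", "%d measurement rows", nrow(df))
  series_list <- as_experiment_series(df, value_kind = config$value_kind)
  if (!is.null(config$condition_variable)) {
    keep <- vapply(series_list, function(s) {
      s$condition_variable == config$condition_variable
    }, logical(1))
    series_list <- series_list[keep]
  }
  if (length(series_list) == 0L) {
    stop("no experiment series match the configuration", call. = FALSE)
  }
  outputs <- list()
  tables <- list()
  for (nm in names(series_list)) {
    series <- series_list[[nm]]
    if (config$value_kind == "peak_area") {
      series$profiles <- lapply(series$profiles, normalize_profile)
      series <- experiment_series(series$profiles)
    }
    tag <- gsub(":", "_", nm)
    prof_tab <- series_to_table(series)
    idx_rep <- index_table(series, mode = "per_replicate",
                           carbon_range = config$carbon_range)
    idx_agg <- index_table(series, mode = "ratio_of_means",
                           carbon_range = config$carbon_range)
    trends <- withCallingHandlers(
      trend_report(series, alpha = config$alpha,
                   carbon_range = config$carbon_range),
      warning = function(w) {
        .log_stage("trends", "%s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    # ANOVA/Tukey per index across condition levels
    rm_ <- series_response_matrix(series, carbon_range = config$carbon_range)
    aov_rows <- lapply(fa_index_names, function(ix) {
      y <- rm_[[ix]]
      ok <- is.finite(y)
      if (sum(ok) < 4L || length(unique(rm_$condition_value[ok])) < 2L ||
          any(table(rm_$condition_value[ok]) < 2L)) {
        return(NULL)
      }
      at <- anova_tukey(y[ok], rm_$condition_value[ok],
                        alpha = config$alpha)
      if (at$degenerate) return(NULL)
      cmp <- at$comparisons
      cmp$response <- ix
      cmp$f_statistic <- at$f_statistic
      cmp$anova_p <- at$p_value
      cmp
    })
    aov_tab <- do.call(rbind, aov_rows)
    paths <- c(profiles = file.path(config$out_dir,
                                    paste0(tag, "_profiles.csv")),
               indices_replicate = file.path(config$out_dir,
                                             paste0(tag, "_indices_replicate.csv")),
               indices_aggregate = file.path(config$out_dir,
                                             paste0(tag, "_indices_aggregate.csv")),
               trends = file.path(config$out_dir, paste0(tag, "_trends.csv")))
    write_measurement_table(prof_tab, paths[["profiles"]])
    utils::write.csv(idx_rep, paths[["indices_replicate"]],
                     row.names = FALSE)
    utils::write.csv(idx_agg, paths[["indices_aggregate"]],
                     row.names = FALSE)
    utils::write.csv(trends, paths[["trends"]], row.names = FALSE)
    if (!is.null(aov_tab) && nrow(aov_tab) > 0) {
      paths[["anova_tukey"]] <- file.path(config$out_dir,
                                          paste0(tag, "_anova_tukey.csv"))
      utils::write.csv(aov_tab, paths[["anova_tukey"]], row.names = FALSE)
    }
    .log_stage("series", "%s: %d profiles -> %d index rows, %d trends",
               nm, length(series$profiles), nrow(idx_rep),
               if (is.null(trends)) 0L else nrow(trends))
    outputs[[nm]] <- paths
    tables[[nm]] <- list(profiles = prof_tab, indices_replicate = idx_rep,
                         indices_aggregate = idx_agg, trends = trends,
                         anova_tukey = aov_tab)
  }
  summary_path <- file.path(config$out_dir, "summary.txt")
  lines <- c(
    sprintf("hydroxyFA %s pipeline run",
            as.character(utils::packageVersion("hydroxyFA"))),
    sprintf("R %s", getRversion()),
    sprintf("input: %s", config$input),
    sprintf("mode: %s; alpha: %g; scope: C%d-C%d", config$mode,
            config$alpha, config$carbon_range[1], config$carbon_range[2]),
    sprintf("seed: %s", if (is.null(config$seed)) "none" else config$seed),
    vapply(names(series_list), function(nm) {
      sprintf("series %s: %d profiles over levels %s", nm,
              length(series_list[[nm]]$profiles),
              paste(series_list[[nm]]$levels, collapse = ", "))
    }, character(1))
  )
  writeLines(lines, summary_path)
  .log_stage("done", "wrote %d series bundle(s) to %s",
             length(outputs), config$out_dir)
  invisible(list(outputs = outputs, tables = tables,
                 summary = summary_path))
}
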