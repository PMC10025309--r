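# Interchange formats. Long-format CSV (one row per strain x condition x
# replicate x compound) is the pipeline schema; wide mean/sd CSVs mirroring
# the printed layout of the reference culture tables are packaged as
# fixtures.

measurement_schema <- c("strain_id", "condition_variable", "condition_value",
                        "replicate_id", "basis", "fa_label", "value")

# Normalize typography that leaks out of typeset tables.
.ascii_norm <- function(x) {
  x <- gsub("−", "-", x)   # unicode minus
  x <- gsub("±", "+/-", x) # plus-minus
  trimws(x)
}

#' Read a long-format measurement table
#'
#' Expected columns: `strain_id`, `condition_variable` (`temperature_C` or
#' `pH`), `condition_value`, `replicate_id`, `basis` (`total_FAs` or
#' `total_3OH_FAs`), `fa_label`, `value`, and optionally `detected`. An
#' empty value, `NA` or the literal `"n.d."` marks a compound as not
#' detected. UTF-8, decimal point, header required. Schema violations are
#' reported with the offending column or row.
#'
#' @param path CSV file path.
#' @param default_3oh Parse bare labels as 3-OH FAs; defaults to `TRUE` for
#'   rows on the `total_3OH_FAs` basis and `FALSE` otherwise.
#' @return Data frame with the schema columns, parsed descriptor columns
#'   and a logical `detected`.
#' @export
read_measurement_table <- function(path, default_3oh = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  missing_cols <- setdiff(measurement_schema, names(df))
  if (length(missing_cols) > 0) {
    stop("input table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (nm in names(df)) df[[nm]] <- .ascii_norm(df[[nm]])
  val_raw <- df$value
  nd <- is.na(val_raw) | val_raw == "" | tolower(val_raw) == "n.d." |
    tolower(val_raw) == "nd"
  value <- suppressWarnings(as.numeric(val_raw))
  bad <- which(!nd & is.na(value))
  if (length(bad) > 0) {
    stop("non-numeric value(s) in column 'value' at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  df$value <- ifelse(nd, NA_real_, value)
  if ("detected" %in% names(df)) {
    det <- tolower(df$detected) %in% c("true", "t", "1", "yes")
    df$detected <- det & !nd
  } else {
    df$detected <- !nd
  }
  df$condition_value <- suppressWarnings(as.numeric(df$condition_value))
  if (anyNA(df$condition_value)) {
    stop("non-numeric condition_value at data row(s) ",
         paste(utils::head(which(is.na(df$condition_value)), 5),
               collapse = ", "), call. = FALSE)
  }
  bad_basis <- !df$basis %in% fa_basis_levels
  if (any(bad_basis)) {
    stop("unknown basis at data row(s) ",
         paste(utils::head(which(bad_basis), 5), collapse = ", "),
         ": expected one of ", paste(fa_basis_levels, collapse = ", "),
         call. = FALSE)
  }
  bad_cv <- !df$condition_variable %in% fa_condition_levels
  if (any(bad_cv)) {
    stop("unknown condition_variable at data row(s) ",
         paste(utils::head(which(bad_cv), 5), collapse = ", "), call. = FALSE)
  }
  d3 <- if (is.null(default_3oh)) df$basis == "total_3OH_FAs" else
    rep(isTRUE(default_3oh), nrow(df))
  desc <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    d <- parse_fa_name(df$fa_label[i], default_3oh = d3[i])
    data.frame(fa_key = fa_key(d), carbon_number = d$carbon_number,
               branching = d$branching, n_unsaturations = d$n_unsaturations,
               hydroxylated_3 = d$hydroxylated_3, stringsAsFactors = FALSE)
  }))
  cbind(df, desc)
}

#' Assemble experiment series from a long measurement table
#'
#' Splits the table by strain and condition variable and builds one
#' [experiment_series()] per combination, one [sample_profile()] per
#' (condition value, replicate).
#'
#' @param df Data frame from [read_measurement_table()].
#' @param value_kind Value kind of the table (default
#'   `"relative_abundance"`).
#' @param check_closure Passed to [sample_profile()].
#' @return Named list of `experiment_series` (names
#'   `"<strain>:<condition_variable>"`).
#' @export
as_experiment_series <- function(df, value_kind = "relative_abundance",
                                 check_closure = FALSE) {
  split_keys <- interaction(df$strain_id, df$condition_variable, drop = TRUE,
                            sep = ":")
  lapply(split(df, split_keys), function(sub) {
    prof_keys <- interaction(sub$condition_value, sub$replicate_id,
                             drop = TRUE)
    profiles <- lapply(split(sub, prof_keys), function(pr) {
      m <- pr[, c("fa_key", "carbon_number", "branching", "n_unsaturations",
                  "hydroxylated_3", "value", "detected")]
      rownames(m) <- NULL
      sample_profile(m, strain_id = pr$strain_id[1L],
                     condition_variable = pr$condition_variable[1L],
                     condition_value = pr$condition_value[1L],
                     replicate_id = pr$replicate_id[1L],
                     basis = pr$basis[1L],
                     value_kind = value_kind,
                     check_closure = check_closure)
    })
    experiment_series(unname(profiles))
  })
}

#' Flatten an experiment series to the long CSV schema
#'
#' @param series An [experiment_series()].
#' @return Data frame in the [read_measurement_table()] schema.
#' @export
series_to_table <- function(series) {
  stopifnot(inherits(series, "experiment_series"))
  out <- lapply(series$profiles, function(p) {
    m <- p$measurements
    data.frame(strain_id = p$strain_id,
               condition_variable = p$condition_variable,
               condition_value = p$condition_value,
               replicate_id = p$replicate_id,
               basis = p$basis,
               fa_label = m$fa_key,
               value = m$value,
               detected = m$detected,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a measurement table (or series) to CSV
#'
#' Undetected values are written as `"n.d."`.
#'
#' @param x Data frame in the long schema or an [experiment_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(x, path) {
  if (inherits(x, "experiment_series")) x <- series_to_table(x)
  x <- x[, intersect(c(measurement_schema, "detected"), names(x))]
  x$value <- ifelse(is.na(x$value), "n.d.", format(x$value, trim = TRUE))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- packaged reference tables ----------------------------------------

# Three soil Bacteroidetes strains (closest relatives: Flavobacterium
# pectinovorum = strainA, Pedobacter lusitanus = strainB, Pedobacter
# panaciterrae = strainC) grown in triplicate across growth temperatures
# (5-25 C at the strain's optimal pH) and pH (5-8 at 25 C). Tables 1-3:
# non-hydroxy FAs as % of total FAs; tables 4-6: 3-OH FAs as % of total
# 3-OH FAs plus the derived indices.
fixture_meta <- list(
  table1 = list(strain_id = "strainA", basis = "total_FAs",
                default_3oh = FALSE,
                fixed_condition = c(temperature_C = "pH 8",
                                    pH = "25C")),
  table2 = list(strain_id = "strainB", basis = "total_FAs",
                default_3oh = FALSE,
                fixed_condition = c(temperature_C = "pH 5", pH = "25C")),
  table3 = list(strain_id = "strainC", basis = "total_FAs",
                default_3oh = FALSE,
                fixed_condition = c(temperature_C = "pH 5", pH = "25C")),
  table4 = list(strain_id = "strainA", basis = "total_3OH_FAs",
                default_3oh = TRUE,
                fixed_condition = c(temperature_C = "pH 8", pH = "25C")),
  table5 = list(strain_id = "strainB", basis = "total_3OH_FAs",
                default_3oh = TRUE,
                fixed_condition = c(temperature_C = "pH 5", pH = "25C")),
  table6 = list(strain_id = "strainC", basis = "total_3OH_FAs",
                default_3oh = TRUE,
                fixed_condition = c(temperature_C = "pH 5", pH = "25C"))
)

.read_fixture_block <- function(name, condition_variable) {
  suffix <- if (condition_variable == "temperature_C") "temperature" else "pH"
  fn <- sprintf("%s_%s.csv", name, suffix)
  path <- system.file("extdata", fn, package = "hydroxyFA")
  if (!nzchar(path)) stop("fixture file missing: ", fn, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  mean_cols <- grep("^mean_", names(df), value = TRUE)
  lvls <- as.numeric(sub("^mean_", "", mean_cols))
  cells <- do.call(rbind, lapply(seq_along(mean_cols), function(i) {
    data.frame(condition_variable = condition_variable,
               condition_value = lvls[i],
               row_type = df$row_type,
               label = df$label,
               mean = as.numeric(df[[mean_cols[i]]]),
               sd = as.numeric(df[[sub("^mean", "sd", mean_cols[i])]]),
               stringsAsFactors = FALSE)
  }))
  cells$detected <- !is.na(cells$mean)
  trends <- data.frame(condition_variable = condition_variable,
                       row_type = df$row_type, label = df$label,
                       r_squared = as.numeric(df$r_squared),
                       p_value = as.numeric(df$p_value),
                       stringsAsFactors = FALSE)
  list(cells = cells, trends = trends, path = path)
}

#' Load a packaged reference table
#'
#' Returns the mean +/- sd cells and printed regression statistics of one
#' of the six packaged culture tables, transcribed from triplicate
#' experiments on three soil Bacteroidetes strains. `table1`--`table3` hold
#' non-hydroxy fatty acids (percent of total FAs) for strains A--C;
#' `table4`--`table6` hold 3-OH fatty acids (percent of total 3-OH FAs)
#' plus class totals, branching ratios and the RIAN/RAN15/RAN17 indices.
#' File integrity is verified against md5 sums frozen at transcription
#' time.
#'
#' @param name `"table1"` ... `"table6"`.
#' @param check Verify md5 checksums (default `TRUE`).
#' @return An object of class `fa_fixture`: a list with `name`,
#'   `strain_id`, `basis`, `default_3oh`, `fixed_condition` (named by
#'   condition variable), `cells` (long data frame: `condition_variable`,
#'   `condition_value`, `row_type`, `label`, `mean`, `sd`, `detected`) and
#'   `trends` (printed R-squared and p per row and condition variable).
#' @export
load_fixture <- function(name, check = TRUE) {
  name <- match.arg(name, names(fixture_meta))
  meta <- fixture_meta[[name]]
  blocks <- lapply(c("temperature_C", "pH"), function(cv) {
    bl <- .read_fixture_block(name, cv)
    if (check) {
      fn <- basename(bl$path)
      want <- fixture_manifest()[fn]
      got <- unname(tools::md5sum(bl$path))
      if (!is.na(want) && !identical(unname(want), got)) {
        stop("fixture integrity error: ", fn, " has md5 ", got,
             ", expected ", want, call. = FALSE)
      }
    }
    bl
  })
  structure(
    list(name = name, strain_id = meta$strain_id, basis = meta$basis,
         default_3oh = meta$default_3oh,
         fixed_condition = meta$fixed_condition,
         cells = rbind(blocks[[1L]]$cells, blocks[[2L]]$cells),
         trends = rbind(blocks[[1L]]$trends, blocks[[2L]]$trends)),
    class = "fa_fixture"
  )
}

#' @export
print.fa_fixture <- function(x, ...) {
  cat(sprintf("<fa_fixture> %s: strain %s, basis %s, %d cells\n",
              x$name, x$strain_id, x$basis, nrow(x$cells)))
  invisible(x)
}

#' Extract one condition column of a fixture as an aggregate profile
#'
#' Builds an [aggregate_profile()] from the individual-compound rows of one
#' table column, so that [class_totals()], [rian()] and friends can run on
#' the printed means.
#'
#' @param fx An `fa_fixture` from [load_fixture()].
#' @param condition_variable `"temperature_C"` or `"pH"`.
#' @param condition_value The column's condition value.
#' @return An [aggregate_profile()].
#' @export
fixture_aggregate <- function(fx, condition_variable, condition_value) {
  stopifnot(inherits(fx, "fa_fixture"))
  sub <- fx$cells[fx$cells$condition_variable == condition_variable &
                    fx$cells$condition_value == condition_value &
                    fx$cells$row_type == "fa", ]
  if (nrow(sub) == 0L) {
    stop("no such fixture column: ", condition_variable, " = ",
         condition_value, call. = FALSE)
  }
  desc <- parse_fa_names(sub$label, default_3oh = fx$default_3oh)
  desc$mean <- sub$mean
  desc$sd <- sub$sd
  desc$detected <- sub$detected
  desc$n_detected <- ifelse(sub$detected, 3L, 0L)
  aggregate_profile(desc, n_replicates = 3L, basis = fx$basis,
                    strain_id = fx$strain_id,
                    condition_variable = condition_variable,
                    condition_value = condition_value)
}

#' Look up one printed fixture cell
#'
#' @param fx An `fa_fixture`.
#' @param label Row label as printed (e.g. `"anteiso_over_normal"`,
#'   `"iso C_15"`, `"RIAN"`).
#' @param condition_variable,condition_value Column coordinates.
#' @return List with `mean`, `sd`, `detected`.
#' @export
fixture_cell <- function(fx, label, condition_variable, condition_value) {
  stopifnot(inherits(fx, "fa_fixture"))
  sub <- fx$cells[fx$cells$label == label &
                    fx$cells$condition_variable == condition_variable &
                    fx$cells$condition_value == condition_value, ]
  if (nrow(sub) != 1L) {
    stop("fixture cell not found: ", label, " at ", condition_variable,
         " = ", condition_value, call. = FALSE)
  }
  list(mean = sub$mean, sd = sub$sd, detected = sub$detected)
}
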