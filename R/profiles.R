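# Sample compositions: measurement tables, closure to 100%, branching-class
# totals, replicate aggregation, and the experiment-series container (one
# strain grown across temperature or pH levels at a fixed other condition).

fa_basis_levels <- c("total_FAs", "total_3OH_FAs")
fa_condition_levels <- c("temperature_C", "pH")
fa_value_kinds <- c("relative_abundance", "peak_area", "amount")

#' Build a measurement table from labels and values
#'
#' Parses each label with [parse_fa_name()] and binds the numeric values.
#' A value of `NA` encodes "not detected" (n.d.): the compound was looked for
#' but not found. Undetected values are stored as missing, never as zero.
#'
#' @param labels Character vector of fatty-acid labels (any dialect).
#' @param values Numeric vector of non-negative values (`NA` = not detected).
#' @param detected Logical vector; defaults to `!is.na(values)`.
#' @param default_3oh Passed to [parse_fa_name()] for labels without an
#'   explicit 3-OH marker.
#' @return A data frame with descriptor columns plus `value` and `detected`.
#' @export
fa_measurements <- function(labels, values, detected = !is.na(values),
                            default_3oh = FALSE) {
  if (length(labels) != length(values)) {
    stop("labels and values must have the same length", call. = FALSE)
  }
  values <- as.numeric(values)
  if (any(values < 0, na.rm = TRUE)) {
    stop("measurement values must be non-negative", call. = FALSE)
  }
  m <- parse_fa_names(labels, default_3oh = default_3oh)
  if (anyDuplicated(m$fa_key)) {
    stop("duplicate fatty-acid descriptors: ",
         paste(unique(m$fa_key[duplicated(m$fa_key)]), collapse = ", "),
         call. = FALSE)
  }
  m$value <- ifelse(detected, values, NA_real_)
  m$detected <- as.logical(detected)
  m
}

#' One replicate's fatty-acid composition
#'
#' A `sample_profile` holds one culture replicate's measurements together
#' with its provenance: strain, varied condition (growth temperature in
#' degrees Celsius or pH), fixed condition, replicate id, and the
#' normalization basis. Two bases are first-class and must never be mixed:
#' `"total_FAs"` (percent of all fatty acids) and `"total_3OH_FAs"` (percent
#' of the 3-hydroxy fatty acids only, the basis on which the proxy indices
#' are defined). On the `"total_3OH_FAs"` basis every descriptor must be
#' 3-hydroxylated.
#'
#' @param measurements Data frame from [fa_measurements()].
#' @param strain_id Character strain identifier.
#' @param condition_variable `"temperature_C"` or `"pH"`.
#' @param condition_value Numeric value of the varied condition.
#' @param replicate_id Character replicate identifier.
#' @param basis `"total_FAs"` or `"total_3OH_FAs"`.
#' @param fixed_condition Free-text description of the held-fixed condition
#'   (e.g. `"pH 8"`).
#' @param value_kind `"relative_abundance"` (percent of basis), `"peak_area"`
#'   (arbitrary GC-MS units) or `"amount"`.
#' @param check_closure For relative abundances, require the detected values
#'   to sum to 100 within `closure_tol` (printed tables are rounded, hence
#'   the tolerance).
#' @param closure_tol Closure tolerance in percentage points (default 0.5).
#' @return An object of class `sample_profile`.
#' @export
sample_profile <- function(measurements, strain_id = "",
                           condition_variable = "temperature_C",
                           condition_value = NA_real_,
                           replicate_id = "r1",
                           basis = "total_3OH_FAs",
                           fixed_condition = "",
                           value_kind = "relative_abundance",
                           check_closure = TRUE, closure_tol = 0.5) {
  condition_variable <- match.arg(condition_variable, fa_condition_levels)
  basis <- match.arg(basis, fa_basis_levels)
  value_kind <- match.arg(value_kind, fa_value_kinds)
  req <- c("fa_key", "carbon_number", "branching", "n_unsaturations",
           "hydroxylated_3", "value", "detected")
  if (!all(req %in% names(measurements))) {
    stop("measurements lack required columns: ",
         paste(setdiff(req, names(measurements)), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(measurements$fa_key)) {
    stop("duplicate descriptors in profile", call. = FALSE)
  }
  if (any(measurements$detected & is.na(measurements$value))) {
    stop("detected measurements must carry a value", call. = FALSE)
  }
  if (basis == "total_3OH_FAs" && !all(measurements$hydroxylated_3)) {
    stop("basis 'total_3OH_FAs' admits only 3-hydroxylated descriptors",
         call. = FALSE)
  }
  if (value_kind == "relative_abundance") {
    v <- measurements$value[measurements$detected]
    if (any(v < 0 | v > 100)) {
      stop("relative abundances must lie in [0, 100]", call. = FALSE)
    }
    if (check_closure && length(v) > 0 && abs(sum(v) - 100) > closure_tol) {
      stop(sprintf("detected relative abundances sum to %.3f, not 100 +/- %.2f",
                   sum(v), closure_tol), call. = FALSE)
    }
  }
  structure(
    list(strain_id = as.character(strain_id),
         condition_variable = condition_variable,
         condition_value = as.numeric(condition_value),
         fixed_condition = as.character(fixed_condition),
         replicate_id = as.character(replicate_id),
         basis = basis,
         value_kind = value_kind,
         measurements = measurements),
    class = "sample_profile"
  )
}

#' @export
print.sample_profile <- function(x, ...) {
  cat(sprintf("<sample_profile> strain %s, %s = %s (%s), replicate %s\n",
              x$strain_id, x$condition_variable, format(x$condition_value),
              x$fixed_condition, x$replicate_id))
  cat(sprintf("  basis %s, %s; %d compounds (%d detected)\n",
              x$basis, x$value_kind, nrow(x$measurements),
              sum(x$measurements$detected)))
  invisible(x)
}

#' Normalize peak areas to a closed relative-abundance composition
#'
#' Replaces each detected value by `100 * value / sum(detected values)`, so
#' that the detected parts sum to exactly 100 (closure). Undetected entries
#' are preserved as undetected. The operation is idempotent and invariant to
#' rescaling all areas by a positive constant.
#'
#' @param x A [sample_profile()] (any `value_kind`) or a measurement data
#'   frame from [fa_measurements()].
#' @param basis Normalization basis of the result; defaults to the profile's
#'   own basis. For `"total_3OH_FAs"` all descriptors must be 3-hydroxylated.
#' @return A `sample_profile` with `value_kind = "relative_abundance"`.
#' @export
normalize_profile <- function(x, basis = NULL) {
  if (is.data.frame(x)) {
    x <- sample_profile(x, basis = if (is.null(basis)) "total_FAs" else basis,
                        value_kind = "peak_area", check_closure = FALSE)
  }
  stopifnot(inherits(x, "sample_profile"))
  if (is.null(basis)) basis <- x$basis
  basis <- match.arg(basis, fa_basis_levels)
  m <- x$measurements
  tot <- sum(m$value[m$detected])
  if (!is.finite(tot) || tot <= 0) {
    stop("degenerate input: no detected measurement with a positive value",
         call. = FALSE)
  }
  m$value[m$detected] <- 100 * m$value[m$detected] / tot
  sample_profile(m, strain_id = x$strain_id,
                 condition_variable = x$condition_variable,
                 condition_value = x$condition_value,
                 replicate_id = x$replicate_id,
                 basis = basis, fixed_condition = x$fixed_condition,
                 value_kind = "relative_abundance",
                 check_closure = FALSE)
}

#' Branching-class totals of the 3-OH fatty acids
#'
#' Sums the detected iso, anteiso and normal 3-hydroxy fatty acids with
#' carbon numbers inside `carbon_range` (default C10--C18, the range over
#' which the proxy indices are defined). Undetected homologues contribute 0;
#' an empty class yields 0.
#'
#' @param x A [sample_profile()] or [aggregate_profile()].
#' @param carbon_range Length-2 numeric, inclusive carbon-number scope.
#' @return Named numeric vector `c(iso =, anteiso =, normal =)`.
#' @export
class_totals <- function(x, carbon_range = c(10, 18)) {
  UseMethod("class_totals")
}

.class_totals_impl <- function(m, values, carbon_range) {
  sel <- m$detected & m$hydroxylated_3 &
    m$carbon_number >= carbon_range[1] & m$carbon_number <= carbon_range[2]
  out <- c(iso = 0, anteiso = 0, normal = 0)
  if (any(sel)) {
    s <- tapply(values[sel], factor(m$branching[sel], levels = names(out)),
                sum)
    s[is.na(s)] <- 0
    out[names(s)] <- s
  }
  out
}

#' @export
class_totals.sample_profile <- function(x, carbon_range = c(10, 18)) {
  .class_totals_impl(x$measurements, x$measurements$value, carbon_range)
}

#' @export
class_totals.aggregate_profile <- function(x, carbon_range = c(10, 18)) {
  .class_totals_impl(x, x$mean, carbon_range)
}

#' Aggregate replicate profiles into mean +/- sd per compound
#'
#' Reproduces the "mean +/- sd" cells of a culture table: for each compound,
#' the mean and sample standard deviation (n - 1 denominator) across
#' replicates. By default undetected values are treated as missing and
#' dropped compound-wise; with `zero_impute = TRUE` they enter the average
#' as zero.
#'
#' @param profiles List of [sample_profile()] objects at one condition level,
#'   sharing strain, basis and condition.
#' @param zero_impute Logical; impute 0 for undetected values.
#' @return An object of class `aggregate_profile`: a data frame with
#'   descriptor columns plus `mean`, `sd`, `n_detected` and `detected`
#'   (detected in at least one replicate), with attributes `n_replicates`,
#'   `basis`, `strain_id`, `condition_variable`, `condition_value`.
#' @export
aggregate_replicates <- function(profiles, zero_impute = FALSE) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  stopifnot(all(vapply(profiles, inherits, logical(1), "sample_profile")))
  basis <- unique(vapply(profiles, function(p) p$basis, character(1)))
  if (length(basis) != 1L) {
    stop("cannot aggregate profiles on mixed bases: ",
         paste(basis, collapse = " vs "), call. = FALSE)
  }
  kind <- unique(vapply(profiles, function(p) p$value_kind, character(1)))
  if (length(kind) != 1L) {
    stop("cannot aggregate profiles of mixed value kinds", call. = FALSE)
  }
  meas <- lapply(profiles, function(p) p$measurements)
  keys <- unique(unlist(lapply(meas, function(m) m$fa_key)))
  desc <- do.call(rbind, meas)
  desc <- desc[!duplicated(desc$fa_key),
               c("fa_key", "carbon_number", "branching", "n_unsaturations",
                 "hydroxylated_3")]
  desc <- desc[match(keys, desc$fa_key), ]
  vals <- vapply(meas, function(m) {
    v <- m$value[match(keys, m$fa_key)]
    if (zero_impute) v[is.na(v)] <- 0
    v
  }, numeric(length(keys)))
  vals <- matrix(vals, nrow = length(keys))
  desc$mean <- apply(vals, 1, function(r) {
    if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE)
  })
  desc$sd <- apply(vals, 1, function(r) {
    if (sum(!is.na(r)) < 2L) NA_real_ else stats::sd(r, na.rm = TRUE)
  })
  desc$n_detected <- apply(vals, 1, function(r) sum(!is.na(r)))
  desc$detected <- !is.na(desc$mean)
  rownames(desc) <- NULL
  aggregate_profile(desc,
                    n_replicates = length(profiles),
                    basis = basis,
                    strain_id = profiles[[1L]]$strain_id,
                    condition_variable = profiles[[1L]]$condition_variable,
                    condition_value = profiles[[1L]]$condition_value)
}

#' Construct an aggregate profile
#'
#' Low-level constructor used by [aggregate_replicates()] and by the fixture
#' loader. `x` must carry the descriptor columns plus `mean`, `sd` and
#' `detected`.
#'
#' @param x Data frame of per-compound means and standard deviations.
#' @param n_replicates Number of replicates behind each cell.
#' @param basis,strain_id,condition_variable,condition_value Metadata.
#' @return An `aggregate_profile`.
#' @export
aggregate_profile <- function(x, n_replicates = NA_integer_,
                              basis = "total_3OH_FAs", strain_id = "",
                              condition_variable = "temperature_C",
                              condition_value = NA_real_) {
  req <- c("fa_key", "carbon_number", "branching", "n_unsaturations",
           "hydroxylated_3", "mean", "sd", "detected")
  if (!all(req %in% names(x))) {
    stop("aggregate profile lacks columns: ",
         paste(setdiff(req, names(x)), collapse = ", "), call. = FALSE)
  }
  if (any(x$sd < 0, na.rm = TRUE)) stop("sd must be >= 0", call. = FALSE)
  structure(x,
            class = c("aggregate_profile", "data.frame"),
            n_replicates = as.integer(n_replicates),
            basis = match.arg(basis, fa_basis_levels),
            strain_id = as.character(strain_id),
            condition_variable = match.arg(condition_variable,
                                           fa_condition_levels),
            condition_value = as.numeric(condition_value))
}

profile_basis <- function(x) {
  if (inherits(x, "sample_profile")) x$basis else attr(x, "basis")
}

#' One strain's profiles across a varied condition
#'
#' Groups replicate profiles of one strain along a temperature or pH
#' gradient at a fixed other condition. All profiles must share strain,
#' condition variable and basis; at least two distinct condition levels are
#' required, each with at least one replicate.
#'
#' @param profiles List of [sample_profile()] objects.
#' @return An object of class `experiment_series` with elements `strain_id`,
#'   `condition_variable`, `basis`, `levels` (sorted distinct condition
#'   values) and `profiles`.
#' @export
experiment_series <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 2L)
  stopifnot(all(vapply(profiles, inherits, logical(1), "sample_profile")))
  strain <- unique(vapply(profiles, function(p) p$strain_id, character(1)))
  cvar <- unique(vapply(profiles, function(p) p$condition_variable,
                        character(1)))
  basis <- unique(vapply(profiles, function(p) p$basis, character(1)))
  if (length(strain) != 1L || length(cvar) != 1L || length(basis) != 1L) {
    stop("all profiles in a series must share strain_id, condition_variable ",
         "and basis", call. = FALSE)
  }
  lv <- sort(unique(vapply(profiles, function(p) p$condition_value,
                           numeric(1))))
  if (length(lv) < 2L || any(is.na(lv))) {
    stop("an experiment series needs >= 2 distinct, non-missing condition ",
         "levels", call. = FALSE)
  }
  structure(
    list(strain_id = strain, condition_variable = cvar, basis = basis,
         levels = lv, profiles = profiles),
    class = "experiment_series"
  )
}

#' @export
print.experiment_series <- function(x, ...) {
  cat(sprintf("<experiment_series> strain %s: %s at %s; %d profiles\n",
              x$strain_id, x$condition_variable,
              paste(x$levels, collapse = ", "), length(x$profiles)))
  invisible(x)
}

series_profiles_at <- function(series, level) {
  Filter(function(p) isTRUE(p$condition_value == level), series$profiles)
}
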