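# Synthetic culture series with the statistical structure the analysis
# assumes: a log-linear composition model. For each condition level L and
# replicate, the composition is
#   closure(exp(log(baseline) + slope * (L - ref) + offset + noise))
# where slope combines a branching-class slope and an optional per-homologue
# deviation, noise is iid Gaussian in log space (multiplicative measurement
# error, keeps parts positive), and closure rescales to 100%. Values below
# the detection floor become "not detected", mirroring how trace homologues
# vanish from printed tables.

#' Specification of a synthetic strain experiment
#'
#' @param strain_id Strain label.
#' @param labels Character vector of fatty-acid labels (any dialect) forming
#'   the descriptor universe.
#' @param baseline Named (or positionally matched) positive vector: the
#'   composition at the reference condition, in percent (rescaled to close
#'   to 100).
#' @param class_slopes Named vector `c(iso =, anteiso =, normal =)` of
#'   per-unit-condition slopes in natural-log abundance space. A common
#'   shift across all classes is absorbed by closure; only differences
#'   matter, e.g. `iso - anteiso` is the injected log iso/anteiso trend.
#' @param homologue_slopes Optional per-compound slope deviations (added to
#'   the class slope), same length as `labels`; default 0.
#' @param homologue_offsets Optional per-compound constant log offsets;
#'   default 0.
#' @param noise_sd Replicate-level log-space noise sd (default 0.05, i.e.
#'   about 5% relative scatter, the magnitude seen in triplicate culture
#'   tables).
#' @param detection_floor Relative abundance (percent) below which a value
#'   is reported as not detected (default 0.02, just under the smallest
#'   values printed in culture tables).
#' @param n_replicates Replicates per level (default 3).
#' @param levels Condition levels (default growth temperatures 5--25 C).
#' @param ref_level Reference condition for the baseline (default
#'   `max(levels)`).
#' @param condition_variable `"temperature_C"` or `"pH"`.
#' @param fixed_condition Free-text description of the held-fixed condition.
#' @param default_3oh Parse bare labels as 3-OH FAs (default `TRUE`).
#' @param basis Profile basis (default `"total_3OH_FAs"`).
#' @return An object of class `strain_sim_spec`.
#' @seealso [generate_series()], [sim_preset()], [recover_parameters()]
#' @export
strain_sim_spec <- function(strain_id, labels, baseline,
                            class_slopes = c(iso = 0, anteiso = 0, normal = 0),
                            homologue_slopes = NULL,
                            homologue_offsets = NULL,
                            noise_sd = 0.05, detection_floor = 0.02,
                            n_replicates = 3L,
                            levels = c(5, 10, 15, 20, 25),
                            ref_level = NULL,
                            condition_variable = "temperature_C",
                            fixed_condition = "",
                            default_3oh = TRUE,
                            basis = "total_3OH_FAs") {
  if (length(labels) == 0L) stop("empty descriptor universe", call. = FALSE)
  desc <- parse_fa_names(labels, default_3oh = default_3oh)
  if (length(baseline) != length(labels) || any(!is.finite(baseline)) ||
      any(baseline <= 0)) {
    stop("baseline must be a positive vector matching 'labels'",
         call. = FALSE)
  }
  if (!all(c("iso", "anteiso", "normal") %in% names(class_slopes))) {
    stop("class_slopes needs named elements iso, anteiso, normal",
         call. = FALSE)
  }
  if (is.null(homologue_slopes)) homologue_slopes <- rep(0, length(labels))
  if (is.null(homologue_offsets)) homologue_offsets <- rep(0, length(labels))
  stopifnot(length(homologue_slopes) == length(labels),
            length(homologue_offsets) == length(labels))
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  levels <- sort(unique(as.numeric(levels)))
  if (length(levels) < 2L) stop("need >= 2 condition levels", call. = FALSE)
  if (is.null(ref_level)) ref_level <- max(levels)
  structure(
    list(strain_id = strain_id, labels = labels, descriptors = desc,
         baseline = 100 * baseline / sum(baseline),
         class_slopes = class_slopes[c("iso", "anteiso", "normal")],
         homologue_slopes = homologue_slopes,
         homologue_offsets = homologue_offsets,
         noise_sd = noise_sd, detection_floor = detection_floor,
         n_replicates = as.integer(n_replicates), levels = levels,
         ref_level = ref_level, condition_variable = condition_variable,
         fixed_condition = fixed_condition, basis = basis),
    class = "strain_sim_spec"
  )
}

#' Generate a synthetic experiment series
#'
#' Draws `n_replicates` compositions per condition level under the
#' log-linear model of [strain_sim_spec()]. Deterministic for a fixed
#' `seed`. Before detection flooring every replicate closes exactly to
#' 100%; flooring then removes parts below `detection_floor`, so the
#' detected sum can fall slightly short of 100, as in real tables.
#'
#' @param spec A [strain_sim_spec()].
#' @param seed Optional integer seed (`set.seed`).
#' @return An [experiment_series()].
#' @export
generate_series <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "strain_sim_spec"))
  if (!is.null(seed)) set.seed(seed)
  k <- length(spec$labels)
  log_base <- log(spec$baseline) + spec$homologue_offsets
  slope <- spec$class_slopes[spec$descriptors$branching] +
    spec$homologue_slopes
  profiles <- list()
  for (lv in spec$levels) {
    for (r in seq_len(spec$n_replicates)) {
      eta <- log_base + slope * (lv - spec$ref_level) +
        stats::rnorm(k, sd = spec$noise_sd)
      vals <- 100 * exp(eta - max(eta)) / sum(exp(eta - max(eta)))
      m <- spec$descriptors
      m$value <- vals
      m$detected <- TRUE
      m <- apply_detection_floor(m, spec$detection_floor)
      profiles[[length(profiles) + 1L]] <- sample_profile(
        m, strain_id = spec$strain_id,
        condition_variable = spec$condition_variable,
        condition_value = lv,
        replicate_id = paste0("r", r),
        basis = spec$basis,
        fixed_condition = spec$fixed_condition,
        value_kind = "relative_abundance",
        check_closure = FALSE)
    }
  }
  experiment_series(profiles)
}

#' Preset simulation specs matched to the packaged reference strains
#'
#' Builds a [strain_sim_spec()] from the temperature block of one of the
#' packaged reference tables ([load_fixture()]): the baseline is the mean
#' composition at the reference temperature (25 C), and per-homologue and
#' per-class log-abundance slopes are fitted by least squares to the table's
#' level means (homologues not detected at 25 C are omitted from the
#' universe). The presets therefore reproduce each strain's observed
#' branching-class trends -- anteiso homologues rising as temperature falls
#' -- without asserting any mechanistic membrane model.
#'
#' @param strain `"strainA"`, `"strainB"` or `"strainC"` (reference tables
#'   4--6 respectively).
#' @param noise_sd,detection_floor,n_replicates Passed through to
#'   [strain_sim_spec()].
#' @return A `strain_sim_spec`.
#' @export
sim_preset <- function(strain = c("strainA", "strainB", "strainC"),
                       noise_sd = 0.05, detection_floor = 0.02,
                       n_replicates = 3L) {
  strain <- match.arg(strain)
  tab <- c(strainA = "table4", strainB = "table5", strainC = "table6")[[strain]]
  fx <- load_fixture(tab)
  cells <- fx$cells
  cells <- cells[cells$condition_variable == "temperature_C" &
                   cells$row_type == "fa", ]
  ref <- max(cells$condition_value)
  at_ref <- cells[cells$condition_value == ref & !is.na(cells$mean), ]
  labels <- at_ref$label
  baseline <- at_ref$mean
  lv <- sort(unique(cells$condition_value))
  # per-homologue log-linear slope over the levels where the compound is
  # detected (needs >= 3 levels, else slope 0)
  hom_slope <- vapply(labels, function(lb) {
    sub <- cells[cells$label == lb & !is.na(cells$mean), ]
    if (nrow(sub) < 3L) return(0)
    stats::coef(stats::lm(log(mean) ~ condition_value, data = sub))[[2L]]
  }, numeric(1))
  desc <- parse_fa_names(labels, default_3oh = TRUE)
  cls_slope <- vapply(c("iso", "anteiso", "normal"), function(cl) {
    sel <- desc$branching == cl
    if (!any(sel)) return(0)
    # abundance-weighted class slope, anchored at the reference composition
    sum(baseline[sel] * hom_slope[sel]) / sum(baseline[sel])
  }, numeric(1))
  strain_sim_spec(
    strain_id = strain, labels = labels, baseline = baseline,
    class_slopes = cls_slope,
    homologue_slopes = hom_slope - cls_slope[desc$branching],
    noise_sd = noise_sd, detection_floor = detection_floor,
    n_replicates = n_replicates, levels = lv, ref_level = ref,
    condition_variable = "temperature_C",
    fixed_condition = fx$fixed_condition["temperature_C"])
}

#' Recover injected branching-class trends from a series
#'
#' Regresses the natural log of each branching-class ratio (iso/anteiso,
#' iso/normal, anteiso/normal) on the condition over replicate-level points
#' and reports slope estimates with t-based confidence intervals. Under the
#' generator's model the true log iso/anteiso slope is
#' `class_slopes["iso"] - class_slopes["anteiso"]`, and likewise for the
#' other ratios, so coverage of these intervals validates the whole
#' generate-then-analyse loop. Replicates with an undefined ratio are
#' dropped pairwise.
#'
#' @param series An [experiment_series()].
#' @param level Confidence level (default 0.95).
#' @param carbon_range Index scope (default C10--C18).
#' @return Data frame: `ratio`, `slope`, `se`, `ci_lower`, `ci_upper`,
#'   `p_value`, `n`.
#' @export
recover_parameters <- function(series, level = 0.95,
                               carbon_range = c(10, 18)) {
  stopifnot(inherits(series, "experiment_series"))
  x <- vapply(series$profiles, function(p) p$condition_value, numeric(1))
  cts <- t(vapply(series$profiles, class_totals, numeric(3),
                  carbon_range = carbon_range))
  ratios <- list(
    iso_over_anteiso = cts[, "iso"] / cts[, "anteiso"],
    iso_over_normal = cts[, "iso"] / cts[, "normal"],
    anteiso_over_normal = cts[, "anteiso"] / cts[, "normal"]
  )
  out <- lapply(names(ratios), function(nm) {
    y <- log(ratios[[nm]])
    y[!is.finite(y)] <- NA_real_
    if (sum(is.finite(y)) < 3L) {
      return(data.frame(ratio = nm, slope = NA_real_, se = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_,
                        p_value = NA_real_, n = sum(is.finite(y))))
    }
    ft <- fit_linear_trend(x, y, response_id = nm)
    tq <- stats::qt(1 - (1 - level) / 2, df = ft$n_points - 2L)
    data.frame(ratio = nm, slope = ft$slope, se = ft$slope_se,
               ci_lower = ft$slope - tq * ft$slope_se,
               ci_upper = ft$slope + tq * ft$slope_se,
               p_value = ft$p_value, n = ft$n_points)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
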