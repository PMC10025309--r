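# The 3-OH FA proxy indices. With I, A, N the summed iso, anteiso and
# normal 3-OH FAs in the C10-C18 range:
#   RIAN  = -log10((I + A) / N)        (proposed soil-pH proxy)
#   RAN15 = anteiso-C15 / normal-C15   (proposed temperature proxy)
#   RAN17 = anteiso-C17 / normal-C17   (proposed temperature proxy)
# A zero or undetected denominator leaves an index undefined (NA), matching
# how culture tables print "n.d." when e.g. normal-C15 is absent.

#' RIAN from branching-class totals
#'
#' `-log10((iso + anteiso) / normal)`, undefined (`NA`) when `normal <= 0`
#' or `iso + anteiso <= 0`. The logarithm is base 10: with class totals
#' I = 80.69, A = 8.55, N = 10.77 the index is -0.92, matching published
#' culture values, whereas a natural log would give -2.11.
#'
#' @param iso,anteiso,normal Non-negative class totals (any common unit;
#'   the ratio cancels the closure constant).
#' @return Numeric scalar or `NA`.
#' @export
rian_from_totals <- function(iso, anteiso, normal) {
  if (any(c(iso, anteiso, normal) < 0, na.rm = TRUE)) {
    stop("class totals must be non-negative", call. = FALSE)
  }
  ia <- iso + anteiso
  if (!is.finite(normal) || normal <= 0 || !is.finite(ia) || ia <= 0) {
    return(NA_real_)
  }
  -log10(ia / normal)
}

.check_3oh_basis <- function(x, what) {
  b <- profile_basis(x)
  if (!identical(b, "total_3OH_FAs")) {
    stop(what, " requires a profile on the 'total_3OH_FAs' basis, got '",
         b, "'", call. = FALSE)
  }
  invisible(TRUE)
}

#' RIAN index of a profile
#'
#' @param x A [sample_profile()] or [aggregate_profile()] on the
#'   `"total_3OH_FAs"` basis. Peak-area profiles are accepted: the index is
#'   a ratio, so closure cancels and areas give the same value as relative
#'   abundances.
#' @param carbon_range Carbon-number scope of the class totals (default
#'   C10--C18).
#' @return Numeric scalar or `NA` if undefined.
#' @seealso [rian_from_totals()], [ran15()], [ran17()], [branching_ratios()]
#' @export
rian <- function(x, carbon_range = c(10, 18)) {
  .check_3oh_basis(x, "RIAN")
  ct <- class_totals(x, carbon_range)
  rian_from_totals(ct[["iso"]], ct[["anteiso"]], ct[["normal"]])
}

# Value of the saturated 3-OH homologue with given carbon number and
# branching; NA when absent or undetected.
.homologue_value <- function(x, carbon, branching) {
  m <- if (inherits(x, "sample_profile")) x$measurements else x
  vals <- if (inherits(x, "sample_profile")) m$value else m$mean
  sel <- m$hydroxylated_3 & m$carbon_number == carbon &
    m$branching == branching & m$n_unsaturations == 0L & m$detected
  if (!any(sel)) NA_real_ else vals[which(sel)[1L]]
}

.anteiso_over_normal_at <- function(x, carbon) {
  num <- .homologue_value(x, carbon, "anteiso")
  den <- .homologue_value(x, carbon, "normal")
  if (!is.finite(den) || den <= 0 || !is.finite(num)) return(NA_real_)
  num / den
}

#' RAN15 and RAN17 indices
#'
#' Abundance ratio of the anteiso to the normal 3-OH FA homologue at C15
#' (`ran15`) or C17 (`ran17`). Undefined (`NA`) when the normal homologue is
#' undetected or zero.
#'
#' @inheritParams rian
#' @return Numeric scalar or `NA`.
#' @export
ran15 <- function(x) {
  .check_3oh_basis(x, "RAN15")
  .anteiso_over_normal_at(x, 15L)
}

#' @rdname ran15
#' @export
ran17 <- function(x) {
  .check_3oh_basis(x, "RAN17")
  .anteiso_over_normal_at(x, 17L)
}

#' Branching-class ratios
#'
#' Iso/anteiso, iso/normal and anteiso/normal ratios of the C10--C18 3-OH FA
#' class totals, with the undefined-on-zero-denominator rule.
#'
#' @inheritParams rian
#' @return Named numeric vector `c(iso_over_anteiso =, iso_over_normal =,
#'   anteiso_over_normal =)`.
#' @export
branching_ratios <- function(x, carbon_range = c(10, 18)) {
  .check_3oh_basis(x, "branching ratios")
  ct <- class_totals(x, carbon_range)
  rat <- function(num, den) if (den <= 0) NA_real_ else num / den
  c(iso_over_anteiso = rat(ct[["iso"]], ct[["anteiso"]]),
    iso_over_normal = rat(ct[["iso"]], ct[["normal"]]),
    anteiso_over_normal = rat(ct[["anteiso"]], ct[["normal"]]))
}

#' All indices and class totals of one profile
#'
#' @inheritParams rian
#' @param small_denom Threshold (in percent of total 3-OH FAs) below which a
#'   RAN denominator is flagged as numerically unstable: near-zero normal
#'   homologues (e.g. a normal-C17 of 0.07 +/- 0.06) make the ratio blow up.
#' @return A one-row data frame with columns `I`, `A`, `N` (class totals),
#'   `RIAN`, `RAN15`, `RAN17`, the three branching ratios, and logical flags
#'   `ran15_small_denom`, `ran17_small_denom`.
#' @export
index_set <- function(x, carbon_range = c(10, 18), small_denom = 0.1) {
  .check_3oh_basis(x, "index set")
  ct <- class_totals(x, carbon_range)
  br <- branching_ratios(x, carbon_range)
  d15 <- .homologue_value(x, 15L, "normal")
  d17 <- .homologue_value(x, 17L, "normal")
  data.frame(
    I = ct[["iso"]], A = ct[["anteiso"]], N = ct[["normal"]],
    RIAN = rian_from_totals(ct[["iso"]], ct[["anteiso"]], ct[["normal"]]),
    RAN15 = .anteiso_over_normal_at(x, 15L),
    RAN17 = .anteiso_over_normal_at(x, 17L),
    iso_over_anteiso = br[["iso_over_anteiso"]],
    iso_over_normal = br[["iso_over_normal"]],
    anteiso_over_normal = br[["anteiso_over_normal"]],
    ran15_small_denom = is.finite(d15) && d15 < small_denom,
    ran17_small_denom = is.finite(d17) && d17 < small_denom
  )
}

fa_index_names <- c("I", "A", "N", "RIAN", "RAN15", "RAN17",
                    "iso_over_anteiso", "iso_over_normal",
                    "anteiso_over_normal")

#' Per-level index table of an experiment series
#'
#' Two computation modes:
#' * `"per_replicate"` (default): each index is computed on every replicate
#'   and summarized as mean and sample sd per condition level -- this is how
#'   printed "index +/- sd" rows arise.
#' * `"ratio_of_means"`: replicates are first aggregated
#'   ([aggregate_replicates()]) and the indices computed once from the mean
#'   composition; no sd is available. Used for checking table-level values.
#'
#' Replicates on which an index is undefined are dropped from its summary;
#' `n_defined` reports how many contributed.
#'
#' @param series An [experiment_series()] on the `"total_3OH_FAs"` basis.
#' @param mode `"per_replicate"` or `"ratio_of_means"`.
#' @inheritParams index_set
#' @return Long data frame: `condition_value`, `index`, `value`, `sd`,
#'   `n_defined`, `mode`.
#' @export
index_table <- function(series, mode = c("per_replicate", "ratio_of_means"),
                        carbon_range = c(10, 18)) {
  stopifnot(inherits(series, "experiment_series"))
  mode <- match.arg(mode)
  out <- lapply(series$levels, function(lv) {
    prs <- series_profiles_at(series, lv)
    if (mode == "per_replicate") {
      per <- do.call(rbind, lapply(prs, index_set, carbon_range = carbon_range))
      vals <- per[, fa_index_names, drop = FALSE]
      data.frame(
        condition_value = lv,
        index = fa_index_names,
        value = vapply(vals, function(v) {
          if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
        }, numeric(1)),
        sd = vapply(vals, function(v) {
          if (sum(!is.na(v)) < 2L) NA_real_ else stats::sd(v, na.rm = TRUE)
        }, numeric(1)),
        n_defined = vapply(vals, function(v) sum(!is.na(v)), numeric(1)),
        row.names = NULL
      )
    } else {
      agg <- aggregate_replicates(prs)
      is1 <- index_set(agg, carbon_range = carbon_range)
      data.frame(
        condition_value = lv,
        index = fa_index_names,
        value = as.numeric(is1[1, fa_index_names]),
        sd = NA_real_,
        n_defined = as.numeric(!is.na(as.numeric(is1[1, fa_index_names]))),
        row.names = NULL
      )
    }
  })
  out <- do.call(rbind, out)
  out$mode <- mode
  out
}
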