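# Shared builders for tests: profiles from named abundance vectors, and
# simulated triplicate columns drawn from printed mean +/- sd cells.

make_profile <- function(vals, basis = "total_3OH_FAs", default_3oh = TRUE,
                         value_kind = "relative_abundance",
                         check_closure = FALSE, ...) {
  m <- fa_measurements(names(vals), unname(vals), default_3oh = default_3oh)
  sample_profile(m, basis = basis, value_kind = value_kind,
                 check_closure = check_closure, ...)
}

# One synthetic replicate of a fixture column: homologue abundances drawn
# from independent normals with the printed means and sds (floored just
# above zero to stay a composition).
draw_fixture_replicate <- function(fx, condition_variable, condition_value,
                                   replicate_id = "r1") {
  ap <- fixture_aggregate(fx, condition_variable, condition_value)
  det <- ap$detected
  sds <- ifelse(is.na(ap$sd), 0, ap$sd)
  vals <- rep(NA_real_, nrow(ap))
  vals[det] <- pmax(stats::rnorm(sum(det), ap$mean[det], sds[det]), 1e-6)
  m <- data.frame(fa_key = ap$fa_key, carbon_number = ap$carbon_number,
                  branching = ap$branching,
                  n_unsaturations = ap$n_unsaturations,
                  hydroxylated_3 = ap$hydroxylated_3,
                  value = vals, detected = det)
  sample_profile(m, strain_id = attr(ap, "strain_id"),
                 condition_variable = condition_variable,
                 condition_value = condition_value,
                 replicate_id = replicate_id,
                 basis = attr(ap, "basis"),
                 value_kind = "relative_abundance", check_closure = FALSE)
}
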