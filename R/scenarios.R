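#' The default trial configuration
#'
#' The worked example throughout the package: 20 hospitals, 8 clinics per
#' hospital, 6 providers per clinic, 6 participants per provider; ICCs 0.05
#' (provider), 0.01 (clinic), 0.01 (hospital); 8 independent unit-variance
#' outcomes; unweighted-average composite; intervention shifting only the
#' first outcome (diet); 10 rural and 10 urban hospitals for the subgroup
#' question; alpha 0.05.
#'
#' @param randomization_level Level at which randomization occurs.
#' @param subgroups If `TRUE`, attach the 10 rural / 10 urban labels.
#' @return A [hier_design()] / [variance_model()].
#' @export
default_design <- function(randomization_level = "isu", subgroups = FALSE) {
  hier_design(20, 8, 6, 6, randomization_level = randomization_level,
              subgroups = if (subgroups) rep(c("rural", "urban"), each = 10))
}

#' @rdname default_design
#' @export
default_variance_model <- function() variance_model(0.05, 0.01, 0.01, 1, diag(8))

#' Define a runnable power scenario
#'
#' Binds a design, variance model, outcome mode and (optionally) a subgroup
#' analysis style into one scenario whose analytic power and empirical power
#' can be evaluated at any effect size.  The effect always shifts the single
#' `affected_outcome` by the requested number of outcome SDs.
#'
#' @param design A [hier_design()].
#' @param vm A [variance_model()].
#' @param outcome_mode `"composite"` or `"multivariate"`.
#' @param analysis `NULL`, or `"pooled"` / `"stratified"` for the subgroup
#'   question (requires subgroup labels and ISU randomization).
#' @param affected_outcome Index of the shifted outcome.
#' @param variance_df Stratified-analysis error-df convention, see
#'   [reduce_subgroup()].
#' @param id Scenario identifier used in curve output.
#' @return Object of class `trial_scenario`.
#' @export
trial_scenario <- function(design, vm, outcome_mode = "composite",
                           analysis = NULL, affected_outcome = 1L,
                           variance_df = "stratum", id = NULL) {
  if (!is.null(analysis)) {
    analysis <- match.arg(analysis, c("pooled", "stratified"))
    if (is.null(design$subgroups))
      stop("subgroup analysis requires subgroup labels on the design")
  }
  if (is.null(id)) {
    id <- if (!is.null(analysis)) analysis
          else paste(c(isu = "hospital", l2 = "clinic", l3 = "provider",
                       l4 = "participant")[design$randomization_level],
                     outcome_mode, sep = ".")
  }
  structure(list(design = design, vm = vm, outcome_mode = outcome_mode,
                 analysis = analysis, affected_outcome = affected_outcome,
                 variance_df = variance_df, id = id),
            class = "trial_scenario")
}

#' Reduced model of a scenario at a given effect size
#'
#' @param scenario A [trial_scenario()].
#' @param delta Effect on the affected outcome, in SD units.
#' @return A [reduced_glm()], or a list of two for stratified analyses.
#' @export
scenario_glm <- function(scenario, delta) {
  eff <- effect_spec(delta, m = scenario$vm$m,
                     affected_outcome = scenario$affected_outcome)
  if (!is.null(scenario$analysis))
    reduce_subgroup(scenario$design, scenario$vm, eff, scenario$analysis,
                    scenario$variance_df)
  else if (scenario$design$randomization_level == "isu")
    reduce_between(scenario$design, scenario$vm, eff, scenario$outcome_mode)
  else
    reduce_within(scenario$design, scenario$vm, eff, scenario$outcome_mode)
}

#' Analytic power of a scenario at a given effect size
#'
#' For stratified analyses the two strata are exchangeable under the
#' symmetric alternative assumed here, so the (identical) power of the first
#' stratum's test is returned.
#'
#' @inheritParams scenario_glm
#' @param alpha Type I error rate.
#' @return A `power_result`.
#' @export
scenario_power <- function(scenario, delta, alpha = 0.05) {
  g <- scenario_glm(scenario, delta)
  if (!inherits(g, "reduced_glm")) g <- g[[1]]
  glh_power(g, alpha = alpha)
}

#' The scenario families of the default trial
#'
#' Seven scenarios: composite-outcome randomization at each of the four
#' levels, the multivariate outcome under hospital randomization, and the
#' pooled and stratified subgroup analyses.
#'
#' @param vm A [variance_model()].
#' @return Named list of [trial_scenario()] objects.
#' @export
default_scenarios <- function(vm = default_variance_model()) {
  sg <- default_design("isu", subgroups = TRUE)
  list(
    hospital.composite    = trial_scenario(default_design("isu"), vm),
    clinic.composite      = trial_scenario(default_design("l2"), vm),
    provider.composite    = trial_scenario(default_design("l3"), vm),
    participant.composite = trial_scenario(default_design("l4"), vm),
    hospital.multivariate = trial_scenario(default_design("isu"), vm,
                                           outcome_mode = "multivariate"),
    pooled                = trial_scenario(sg, vm, analysis = "pooled"),
    stratified            = trial_scenario(sg, vm, analysis = "stratified")
  )
}

comparison_result <- function(curves, conclusion, question) {
  structure(list(curves = do.call(rbind, curves), conclusion = conclusion,
                 question = question),
            class = "power_comparison")
}

#' @export
print.power_comparison <- function(x, ...) {
  cat("Power comparison:", x$question, "\n")
  for (nm in names(x$conclusion))
    cat(" ", nm, ":", format(x$conclusion[[nm]]), "\n")
  invisible(x)
}

#' Design question 1: level of randomization
#'
#' Composite-outcome power curves for randomization at the hospital, clinic,
#' provider and participant level on a shared effect grid.  The conclusion
#' flags are computed from the curves: under the default configuration power
#' is ordered participant >= provider >= clinic >= hospital pointwise,
#' because the variance of the within-ISU arm difference sheds every
#' variance component shared above the randomized level.
#'
#' @param vm A [variance_model()].
#' @param effect_grid Effect magnitudes (SD units).
#' @param alpha Type I error rate.
#' @return A `power_comparison`: combined curve data frame plus computed
#'   conclusion flags.
#' @export
run_randomization_comparison <- function(vm = default_variance_model(),
                                         effect_grid = seq(0, 1, length.out = 100),
                                         alpha = 0.05) {
  sc <- default_scenarios(vm)[c("hospital.composite", "clinic.composite",
                                "provider.composite", "participant.composite")]
  curves <- lapply(sc, power_curve, effect_grid = effect_grid, alpha = alpha)
  p <- lapply(curves, `[[`, "power")
  conclusion <- list(
    participant_ge_provider = all(p[[4]] >= p[[3]] - 1e-12),
    provider_ge_clinic      = all(p[[3]] >= p[[2]] - 1e-12),
    clinic_ge_hospital      = all(p[[2]] >= p[[1]] - 1e-12),
    best_level = c("hospital", "clinic", "provider", "participant")[
      which.max(vapply(p, function(z) sum(z), 0))]
  )
  comparison_result(curves, conclusion, "level of randomization (composite outcome)")
}

#' Design question 2: composite versus multivariate outcome
#'
#' Under hospital-level randomization with one shifted outcome, compares
#' power for the unweighted composite (t test, 1 df) against the grand
#' multivariate null (Hotelling T2 over all 8 outcomes).  With independent
#' unit-variance outcomes and equal weights, diluting a one-outcome shift
#' into the composite divides the noncentrality by the number of outcomes,
#' so the multivariate noncentrality is 8 times the composite one.
#'
#' @inheritParams run_randomization_comparison
#' @return A `power_comparison` with the computed noncentrality ratio and
#'   pointwise winner.
#' @export
run_outcome_comparison <- function(vm = default_variance_model(),
                                   effect_grid = seq(0, 1, length.out = 100),
                                   alpha = 0.05) {
  sc <- default_scenarios(vm)[c("hospital.composite", "hospital.multivariate")]
  curves <- lapply(sc, power_curve, effect_grid = effect_grid, alpha = alpha)
  pc <- curves[[1]]$power; pm <- curves[[2]]$power
  pos <- curves[[1]]$effect > 0
  ratio <- if (any(pos))
    curves[[2]]$noncentrality[pos][1] / curves[[1]]$noncentrality[pos][1]
  else NA_real_
  conclusion <- list(
    multivariate_ge_composite = all(pm >= pc - 1e-12),
    noncentrality_ratio = ratio
  )
  comparison_result(curves, conclusion,
                    "composite versus multivariate outcome (hospital randomization)")
}

#' Design question 3: pooled versus stratified subgroup analysis
#'
#' Composite outcome, hospital-level randomization, 10 rural and 10 urban
#' hospitals, equal intervention effect in both subgroups (zero
#' interaction).  The pooled model keeps all 20 hospitals (4 cells, error df
#' 16); each stratified model keeps 10 (error df 8) and carries half the
#' noncentrality.
#'
#' @inheritParams run_randomization_comparison
#' @param variance_df Stratified error-df convention, see [reduce_subgroup()].
#' @return A `power_comparison`.
#' @export
run_subgroup_comparison <- function(vm = default_variance_model(),
                                    effect_grid = seq(0, 1, length.out = 100),
                                    alpha = 0.05, variance_df = "stratum") {
  sg <- default_design("isu", subgroups = TRUE)
  sc <- list(
    pooled = trial_scenario(sg, vm, analysis = "pooled"),
    stratified = trial_scenario(sg, vm, analysis = "stratified",
                                variance_df = variance_df)
  )
  curves <- lapply(sc, power_curve, effect_grid = effect_grid, alpha = alpha)
  conclusion <- list(
    pooled_ge_stratified = all(curves[[1]]$power >= curves[[2]]$power - 1e-12)
  )
  comparison_result(curves, conclusion,
                    "pooled versus stratified subgroup analysis (composite outcome)")
}
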