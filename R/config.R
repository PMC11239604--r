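#' Read a run configuration from YAML
#'
#' Configuration keys (all optional; defaults are the worked-example trial):
#' `levels` (named sizes `isu`, `l2`, `l3`, `l4`), `randomization_level`,
#' `iccs` (named `provider`, `clinic`, `hospital`), `sigma2`,
#' `outcome_covariance` (m x m, or `"identity"` with `n_outcomes`),
#' `composite_weights`, `subgroups` (per-ISU labels, or `true` for the
#' default 10 rural / 10 urban split), `affected_outcome`, `alpha`,
#' `effect_grid` (either a list of values or `max`/`points`), `reps`,
#' `seed`, `scenarios` (subset of the default scenario names).
#'
#' @param path YAML file path.
#' @return A validated `run_config` list with elements `vm`, `alpha`,
#'   `effect_grid`, `reps`, `seed`, `scenarios`, `raw`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  build_run_config(cfg)
}

#' Default run configuration
#'
#' @return The `run_config` built from the packaged default YAML
#'   (`inst/extdata/default_config.yaml`).
#' @export
default_run_config <- function() {
  read_run_config(system.file("extdata", "default_config.yaml",
                              package = "hierpower", mustWork = TRUE))
}

build_run_config <- function(cfg) {
  lv <- cfg$levels %||% list(isu = 20, l2 = 8, l3 = 6, l4 = 6)
  iccs <- cfg$iccs %||% list(provider = 0.05, clinic = 0.01, hospital = 0.01)
  m <- cfg$n_outcomes %||% 8
  Sigma <- cfg$outcome_covariance %||% "identity"
  if (identical(Sigma, "identity")) Sigma <- diag(m)
  else Sigma <- matrix(unlist(Sigma), nrow = m, byrow = TRUE)
  vm <- variance_model(iccs$provider, iccs$clinic, iccs$hospital,
                       cfg$sigma2 %||% 1, Sigma,
                       composite_weights = unlist(cfg$composite_weights))
  subgroups <- cfg$subgroups
  if (isTRUE(subgroups)) subgroups <- rep(c("rural", "urban"),
                                          each = lv$isu / 2)
  grid <- cfg$effect_grid
  if (is.null(grid)) grid <- list(max = 1, points = 100)
  effect_grid <- if (is.list(grid))
    seq(0, grid$max %||% 1, length.out = grid$points %||% 100)
  else sort(unlist(grid))
  scen_names <- cfg$scenarios %||% names(default_scenarios())
  make_design <- function(rl, with_sub = FALSE)
    hier_design(lv$isu, lv$l2, lv$l3, lv$l4, randomization_level = rl,
                subgroups = if (with_sub) subgroups)
  aff <- cfg$affected_outcome %||% 1
  all_sc <- list(
    hospital.composite    = trial_scenario(make_design("isu"), vm,
                                           affected_outcome = aff),
    clinic.composite      = trial_scenario(make_design("l2"), vm,
                                           affected_outcome = aff),
    provider.composite    = trial_scenario(make_design("l3"), vm,
                                           affected_outcome = aff),
    participant.composite = trial_scenario(make_design("l4"), vm,
                                           affected_outcome = aff),
    hospital.multivariate = trial_scenario(make_design("isu"), vm,
                                           outcome_mode = "multivariate",
                                           affected_outcome = aff),
    pooled     = if (!is.null(subgroups))
      trial_scenario(make_design("isu", TRUE), vm, analysis = "pooled",
                     affected_outcome = aff),
    stratified = if (!is.null(subgroups))
      trial_scenario(make_design("isu", TRUE), vm, analysis = "stratified",
                     affected_outcome = aff)
  )
  all_sc <- Filter(Negate(is.null), all_sc)
  unknown <- setdiff(scen_names, names(all_sc))
  if (length(unknown))
    stop("unknown scenario name(s): ", paste(unknown, collapse = ", "),
         "; valid options: ", paste(names(all_sc), collapse = ", "))
  structure(list(
    vm = vm, scenarios = all_sc[scen_names],
    alpha = cfg$alpha %||% 0.05, effect_grid = effect_grid,
    reps = cfg$reps %||% 10000, seed = cfg$seed %||% 2024, raw = cfg
  ), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compute all configured power curves and write CSV / figure outputs
#'
#' Produces one combined CSV of analytic power curves (columns `scenario`,
#' `effect`, `ndf`, `ddf`, `noncentrality`, `power`), a figure per design
#' question when ggplot2 is available, and a copy of the resolved
#' configuration for provenance.  Outputs are deterministic: rerunning with
#' the same configuration reproduces identical CSV bytes.
#'
#' @param config A `run_config` (see [read_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the combined curve data frame.
#' @export
run_curves <- function(config = default_run_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  curves <- do.call(rbind, lapply(config$scenarios, power_curve,
                                  effect_grid = config$effect_grid,
                                  alpha = config$alpha))
  rownames(curves) <- NULL
  utils::write.csv(curves, file.path(out_dir, "power_curves.csv"),
                   row.names = FALSE)
  write_provenance(config, out_dir)
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    groups <- list(
      randomization = c("hospital.composite", "clinic.composite",
                        "provider.composite", "participant.composite"),
      outcome = c("hospital.composite", "hospital.multivariate"),
      subgroup = c("pooled", "stratified")
    )
    for (g in names(groups)) {
      sub <- curves[curves$scenario %in% groups[[g]], ]
      if (length(unique(sub$scenario)) < 2) next
      ggplot2::ggsave(file.path(out_dir, paste0("power_", g, ".png")),
                      plot_power_curves(sub), width = 6, height = 4, dpi = 150)
    }
  }
  invisible(curves)
}

#' Validate analytic power against Monte-Carlo simulation
#'
#' For each configured scenario and each requested effect size, computes the
#' analytic power and the empirical rejection rate over `reps` simulated
#' trials, and flags agreement within 3 binomial standard errors.
#'
#' @param config A `run_config`.
#' @param deltas Effect sizes to check (default: 0 and the grid midpoint).
#' @param out_dir Optional output directory for `validation.csv`.
#' @return Data frame with columns `scenario`, `delta`, `analytic`,
#'   `empirical`, `se`, `pass`.
#' @export
run_validation <- function(config = default_run_config(),
                           deltas = NULL, out_dir = NULL) {
  if (is.null(deltas))
    deltas <- c(0, stats::median(config$effect_grid))
  rows <- list()
  for (nm in names(config$scenarios)) {
    sc <- config$scenarios[[nm]]
    for (d in deltas) {
      ana <- scenario_power(sc, d, alpha = config$alpha)$power
      emp <- empirical_power(sc, d, reps = config$reps,
                             seed = config$seed, alpha = config$alpha)
      tol <- 3 * max(emp$se, sqrt(ana * (1 - ana) / config$reps))
      rows[[length(rows) + 1]] <- data.frame(
        scenario = nm, delta = d, analytic = ana, empirical = emp$power,
        se = emp$se, pass = abs(ana - emp$power) <= tol)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "validation.csv"),
                     row.names = FALSE)
    write_provenance(config, out_dir)
  }
  out
}

write_provenance <- function(config, out_dir) {
  resolved <- config$raw
  resolved$seed <- config$seed
  resolved$alpha <- config$alpha
  yaml::write_yaml(resolved, file.path(out_dir, "config_resolved.yaml"))
  invisible(NULL)
}
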