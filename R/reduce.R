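#' Power-equivalent reduced multivariate linear model
#'
#' Constructor for the ISU-level general linear multivariate model that
#' carries exactly the same power as the full mixed-model analysis under
#' balance.  Each row is one independent sampling unit; the general linear
#' hypothesis is `H0: C B U = Theta0` with between-ISU contrast `C` and
#' within-ISU (outcome) contrast `U`.
#'
#' Rarely called directly: use [reduce_between()], [reduce_within()] or
#' [reduce_subgroup()].
#'
#' @param cell_counts ISUs per design cell (cell-means coding, so
#'   `X'X = diag(cell_counts)`).
#' @param cell_labels Names of the design cells.
#' @param B q x p matrix of population cell means on the reduced scale.
#' @param SigmaStar p x p error covariance of one ISU row.
#' @param C a x q between-ISU contrast (full row rank).
#' @param U p x b within-ISU contrast (full column rank).
#' @param Theta0 a x b null-value matrix (default zero).
#' @param outcome_mode `"multivariate"` or `"composite"`.
#' @param label Human-readable scenario tag.
#' @return Object of class `reduced_glm` with elements above plus `n_rows`
#'   (N), `rank_r` (model df) and `nu` (error df, N - rank).
#' @export
reduced_glm <- function(cell_counts, cell_labels, B, SigmaStar, C, U,
                        Theta0 = NULL, outcome_mode = "composite",
                        label = "") {
  B <- as.matrix(B); SigmaStar <- as.matrix(SigmaStar)
  C <- matrix(C, ncol = nrow(B)); U <- matrix(U, nrow = ncol(B))
  a <- nrow(C); b <- ncol(U)
  if (is.null(Theta0)) Theta0 <- matrix(0, a, b)
  N <- sum(cell_counts); r <- length(cell_counts)
  if (qr(C)$rank < a) stop("C must have full row rank")
  if (qr(U)$rank < b) stop("U must have full column rank")
  if (N - r < 1) stop("no error degrees of freedom: N - rank must be >= 1")
  if (ncol(C) != nrow(B) || nrow(U) != ncol(B))
    stop("conformability failure between C, B, U")
  ev <- eigen(SigmaStar, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("SigmaStar must be positive definite")
  structure(list(
    n_rows = N, rank_r = r, nu = N - r,
    cell_counts = cell_counts, cell_labels = cell_labels,
    B = B, SigmaStar = SigmaStar, C = C, U = U, Theta0 = Theta0,
    outcome_mode = outcome_mode, label = label
  ), class = "reduced_glm")
}

# effect on the reduced outcome scale: full delta vector or composite w'delta
reduced_effect <- function(vm, effect, outcome_mode) {
  if (outcome_mode == "multivariate") effect$delta
  else sum(vm$composite_weights * effect$delta)
}

outcome_factor <- function(vm, outcome_mode) {
  if (outcome_mode == "multivariate") vm$Sigma
  else drop(crossprod(vm$composite_weights, vm$Sigma %*% vm$composite_weights))
}

#' Reduce an ISU-randomized trial to a two-sample multivariate model
#'
#' With randomization at the ISU (hospital) level, each ISU is summarized by
#' its grand mean vector.  The reduced model has two cells (arms), error
#' covariance `vbar * Sigma` where `vbar` is the variance of an ISU mean
#' under the cluster model, and tests the arm difference.
#'
#' @param design A [hier_design()] with `randomization_level = "isu"`.
#' @param vm A [variance_model()].
#' @param effect An [effect_spec()].
#' @param outcome_mode `"multivariate"` (p = m) or `"composite"` (p = 1).
#' @return A [reduced_glm()] with rank 2 and error df `n_isu - 2`.
#' @examples
#' d <- hier_design(20, 8, 6, 6, "isu")
#' vm <- variance_model()
#' reduce_between(d, vm, effect_spec(1, m = 8), "composite")
#' @export
reduce_between <- function(design, vm, effect,
                           outcome_mode = c("composite", "multivariate")) {
  outcome_mode <- match.arg(outcome_mode)
  if (design$randomization_level != "isu")
    stop("reduce_between requires ISU-level randomization")
  if (length(effect$delta) != vm$m)
    stop("effect dimension does not match the outcome covariance")
  n <- design$n_participants_per_isu
  vbar <- contrast_variance(design, vm, rep(1 / n, n))
  eff <- reduced_effect(vm, effect, outcome_mode)
  p <- length(eff)
  B <- rbind(treated = eff, control = rep(0, p))
  SigmaStar <- vbar * outcome_factor(vm, outcome_mode)
  if (outcome_mode == "composite") SigmaStar <- matrix(SigmaStar)
  reduced_glm(
    cell_counts = c(design$n_isu / 2, design$n_isu / 2),
    cell_labels = c("treated", "control"),
    B = B, SigmaStar = SigmaStar,
    C = matrix(c(1, -1), 1), U = diag(1, p),
    outcome_mode = outcome_mode,
    label = paste0("hospital-level randomization, ", outcome_mode)
  )
}

#' Reduce a within-ISU-randomized trial to a one-group paired model
#'
#' With randomization at the clinic, provider or participant level, each ISU
#' contributes its (treated mean, control mean) pair per outcome (p = 2m, or
#' 2 for the composite).  The design matrix is a unit column (rank 1, error
#' df N - 1); the within-ISU contrast takes the arm difference, in which all
#' variance components shared by the two arms cancel.
#'
#' @inheritParams reduce_between
#' @return A [reduced_glm()] with rank 1 and error df `n_isu - 1`.
#' @export
reduce_within <- function(design, vm, effect,
                          outcome_mode = c("composite", "multivariate")) {
  outcome_mode <- match.arg(outcome_mode)
  if (design$randomization_level == "isu")
    stop("reduce_within requires within-ISU randomization")
  if (length(effect$delta) != vm$m)
    stop("effect dimension does not match the outcome covariance")
  M2 <- arm_mean_moments(design, vm)
  eff <- reduced_effect(vm, effect, outcome_mode)
  ofac <- outcome_factor(vm, outcome_mode)
  if (outcome_mode == "multivariate") {
    m <- vm$m
    B <- matrix(c(eff, rep(0, m)), 1)          # (treated means, control means)
    SigmaStar <- kronecker(M2, ofac)
    U <- rbind(diag(1, m), -diag(1, m))
  } else {
    B <- matrix(c(eff, 0), 1)
    SigmaStar <- M2 * ofac
    U <- matrix(c(1, -1), 2)
  }
  lvl <- c(l2 = "clinic", l3 = "provider", l4 = "participant")
  reduced_glm(
    cell_counts = design$n_isu, cell_labels = "all",
    B = B, SigmaStar = SigmaStar, C = matrix(1), U = U,
    outcome_mode = outcome_mode,
    label = paste0(lvl[design$randomization_level],
                   "-level randomization, ", outcome_mode)
  )
}

#' Reduce a subgroup trial: pooled or stratified analysis
#'
#' ISU-level randomization with a two-level ISU subgroup (e.g. rural/urban
#' hospitals) and the composite outcome, as in the pooled-versus-stratified
#' comparison.  The pooled analysis keeps all ISUs in one model with four
#' cells (arm x subgroup); the intervention main effect is tested averaged
#' over subgroup, and the subgroup-by-intervention interaction is kept in
#' the model (costing one error df) but its population value is zero.  The
#' stratified analysis fits a separate two-cell model per subgroup, each on
#' half the ISUs.
#'
#' @inheritParams reduce_between
#' @param analysis `"pooled"` or `"stratified"`.
#' @param variance_df For the stratified analysis: `"stratum"` (default)
#'   charges each stratum its own error df (N/2 - 2); `"whole"` assumes the
#'   error variance is estimated from the entire sample under the four-cell
#'   model (error df N - 4).
#' @return A [reduced_glm()] (pooled) or a named list of two (stratified).
#' @export
reduce_subgroup <- function(design, vm, effect,
                            analysis = c("pooled", "stratified"),
                            variance_df = c("stratum", "whole")) {
  analysis <- match.arg(analysis)
  variance_df <- match.arg(variance_df)
  if (design$randomization_level != "isu")
    stop("subgroup analyses assume ISU-level randomization")
  if (is.null(design$subgroups))
    stop("design has no subgroup labels")
  strata <- sort(unique(design$subgroups))
  if (length(strata) != 2) stop("exactly two subgroups are supported")
  sizes <- table(design$subgroups)[strata]
  n <- design$n_participants_per_isu
  vbar <- contrast_variance(design, vm, rep(1 / n, n))
  sstar <- vbar * outcome_factor(vm, "composite")
  eff <- reduced_effect(vm, effect, "composite")

  if (analysis == "pooled") {
    labs <- as.vector(outer(c("treated", "control"), strata, paste, sep = "."))
    B <- matrix(rep(c(eff, 0), 2), 4, 1)   # equal effect in both subgroups
    return(reduced_glm(
      cell_counts = rep(sizes / 2, each = 2), cell_labels = labs,
      B = B, SigmaStar = matrix(sstar),
      C = matrix(c(1, -1, 1, -1) / 2, 1), U = matrix(1),
      outcome_mode = "composite",
      label = "pooled subgroup analysis, composite"
    ))
  }

  out <- lapply(strata, function(s) {
    ns <- sizes[[s]]
    g <- reduced_glm(
      cell_counts = c(ns / 2, ns / 2),
      cell_labels = paste(c("treated", "control"), s, sep = "."),
      B = matrix(c(eff, 0), 2, 1), SigmaStar = matrix(sstar),
      C = matrix(c(1, -1), 1), U = matrix(1),
      outcome_mode = "composite",
      label = paste0("stratified subgroup analysis (", s, "), composite")
    )
    if (variance_df == "whole") g$nu <- design$n_isu - 4
    g
  })
  names(out) <- strata
  out
}

#' @export
print.reduced_glm <- function(x, ...) {
  cat("Power-equivalent reduced model:", x$label, "\n")
  cat(sprintf("  N = %d ISUs in %d cell(s) [%s], error df = %d\n",
              x$n_rows, x$rank_r,
              paste(x$cell_labels, x$cell_counts, sep = ":", collapse = ", "),
              x$nu))
  cat("  Cell means B:\n")
  print(round(x$B, 6))
  cat("  Row covariance SigmaStar:\n")
  print(round(x$SigmaStar, 8))
  cat("  Between contrast C:", paste(round(x$C, 4), collapse = " "), "\n")
  cat("  Within contrast U (t):",
      paste(apply(round(x$U, 4), 2, paste, collapse = ","), collapse = " | "),
      "\n")
  invisible(x)
}

#' Write a labelled plain-text audit report of a reduced model
#'
#' @param x A [reduced_glm()].
#' @param file Path, or `""` for stdout.
#' @export
write_reduced_glm <- function(x, file = "") {
  txt <- utils::capture.output(print(x))
  writeLines(txt, con = file)
  invisible(x)
}
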