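# Participant ordering within an ISU is fixed throughout the package:
# clinic-major, then provider, then participant, so position
# ((c-1)*P + (p-1))*S + s holds participant s of provider p in clinic c.
isu_indices <- function(design) {
  C <- design$n_l2; P <- design$n_l3; S <- design$n_l4
  list(
    n = C * P * S,
    provider = rep(seq_len(C * P), each = S),
    clinic   = rep(seq_len(C), each = P * S)
  )
}

# Bilinear form a' V b on the within-ISU cluster covariance, evaluated by
# counting shared variance components rather than materializing V:
# V = sigma2 * (rho_e I + rho_p Zp Zp' + rho_c Zc Zc' + rho_h J).
cluster_bilinear <- function(design, vm, a, b) {
  idx <- isu_indices(design)
  sa_p <- rowsum(a, idx$provider); sb_p <- rowsum(b, idx$provider)
  sa_c <- rowsum(a, idx$clinic);   sb_c <- rowsum(b, idx$clinic)
  vm$sigma2 * (vm$rho_residual * sum(a * b) +
               vm$rho_provider * sum(sa_p * sb_p) +
               vm$rho_clinic   * sum(sa_c * sb_c) +
               vm$rho_hospital * sum(a) * sum(b))
}

#' Within-ISU cluster correlation matrix
#'
#' The (C*P*S) x (C*P*S) covariance of the participants of one hospital for
#' a single outcome: diagonal `sigma2`, off-diagonal `sigma2 * (rho_hospital
#' + rho_clinic [same clinic] + rho_provider [same provider])`.
#'
#' @param design A [hier_design()].
#' @param vm A [variance_model()].
#' @return A symmetric positive semi-definite matrix.
#' @export
cluster_correlation_matrix <- function(design, vm) {
  idx <- isu_indices(design)
  same_p <- outer(idx$provider, idx$provider, "==")
  same_c <- outer(idx$clinic, idx$clinic, "==")
  V <- vm$rho_hospital + vm$rho_clinic * same_c + vm$rho_provider * same_p
  diag(V) <- 1
  vm$sigma2 * V
}

#' Full ISU covariance: cluster model x outcome covariance
#'
#' The covariance of all outcomes on all participants of one ISU, as the
#' Kronecker product of the three-level exchangeable cluster covariance with
#' the m x m outcome covariance `Sigma`.  Rows are ordered participant-major
#' (all m outcomes of participant 1, then participant 2, ...).
#'
#' Intended for inspection and for test oracles on small designs; power
#' computations never materialize this matrix.
#'
#' @inheritParams cluster_correlation_matrix
#' @return A `(C*P*S*m)` square symmetric PSD matrix.
#' @examples
#' d <- hier_design(2, 1, 1, 2, randomization_level = "isu")
#' vm <- variance_model(Sigma = diag(1))
#' isu_covariance(d, vm)  # off-diagonal 0.07
#' @export
isu_covariance <- function(design, vm) {
  kronecker(cluster_correlation_matrix(design, vm), vm$Sigma)
}

#' Variance of a weighted participant contrast
#'
#' Computes `a' V a * (w' Sigma w)` for a per-participant coefficient vector
#' `a` within one ISU, by counting shared variance components — the full
#' covariance is never built, so the evaluation is cheap for any design
#' size.  With `outcome_weights = NULL` the outcome factor is 1, i.e. the
#' pure cluster-model quadratic form is returned.
#'
#' @inheritParams cluster_correlation_matrix
#' @param coefficients Numeric vector of length `C*P*S` (clinic-major
#'   ordering).
#' @param outcome_weights Optional length-m outcome weight vector `w`.
#' @return Scalar variance.
#' @examples
#' d <- hier_design(2, 8, 6, 6, randomization_level = "isu")
#' vm <- variance_model(Sigma = diag(1))
#' contrast_variance(d, vm, rep(1/288, 288))  # variance of a hospital mean
#' @export
contrast_variance <- function(design, vm, coefficients, outcome_weights = NULL) {
  if (length(coefficients) != design$n_participants_per_isu)
    stop("coefficients must have length ", design$n_participants_per_isu)
  wSw <- if (is.null(outcome_weights)) 1 else {
    if (length(outcome_weights) != vm$m)
      stop("outcome_weights must have length ", vm$m)
    drop(crossprod(outcome_weights, vm$Sigma %*% outcome_weights))
  }
  cluster_bilinear(design, vm, coefficients, coefficients) * wSw
}

# Treated-participant indicator within one ISU for within-ISU randomization,
# under the balanced split: the first half of units in each immediate parent
# is assigned to intervention (exchangeability makes the pattern immaterial).
treated_pattern <- function(design) {
  C <- design$n_l2; P <- design$n_l3; S <- design$n_l4
  switch(design$randomization_level,
    l2 = rep(rep(c(TRUE, FALSE), each = C / 2 * P * S), times = 1),
    l3 = rep(rep(rep(c(TRUE, FALSE), each = P / 2 * S), times = C), times = 1),
    l4 = rep(rep(c(TRUE, FALSE), each = S / 2), times = C * P),
    stop("treated_pattern requires within-ISU randomization")
  )
}

#' Moments of the (intervention, control) arm means within one ISU
#'
#' For randomization within ISUs (clinic, provider, or participant level),
#' returns the 2 x 2 covariance matrix of the treated-arm mean and the
#' control-arm mean of one ISU, on the per-outcome scale.  The variances are
#' `contrast_variance` with equal weights over each arm's participants; the
#' covariance collects the variance components shared across arms (those at
#' and above the parent of the randomized level).
#'
#' @inheritParams cluster_correlation_matrix
#' @return A 2 x 2 matrix with dimnames `treated`/`control`; attribute
#'   `var_diff` holds the variance of the within-ISU arm difference.
#' @export
arm_mean_moments <- function(design, vm) {
  if (design$randomization_level == "isu")
    stop("arm_mean_moments is defined for within-ISU randomization only")
  tr <- treated_pattern(design)
  n_arm <- sum(tr)
  aT <- ifelse(tr, 1 / n_arm, 0)
  aC <- ifelse(tr, 0, 1 / n_arm)
  M <- matrix(c(cluster_bilinear(design, vm, aT, aT),
                cluster_bilinear(design, vm, aT, aC),
                cluster_bilinear(design, vm, aT, aC),
                cluster_bilinear(design, vm, aC, aC)),
              2, 2, dimnames = list(c("treated", "control"),
                                    c("treated", "control")))
  structure(M, var_diff = M[1, 1] + M[2, 2] - 2 * M[1, 2])
}
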