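#' Balanced multilevel trial design
#'
#' Describes a balanced four-level hierarchy: participants nested in
#' providers, providers in clinics, clinics in hospitals.  Hospitals are the
#' independent sampling units (ISUs); clustering at the provider, clinic and
#' hospital levels induces correlation among participant outcomes.
#' Randomization to intervention or control can occur at any of the four
#' levels.  When randomization is within ISUs, arms are split equally within
#' each immediate parent unit (e.g. 4 intervention / 4 control clinics in
#' every hospital), so the count at the randomized level must be even.
#'
#' @param n_isu Number of independent sampling units (hospitals).
#' @param n_l2 Clinics per hospital.
#' @param n_l3 Providers per clinic.
#' @param n_l4 Participants per provider.
#' @param randomization_level One of `"isu"` (hospital), `"l2"` (clinic),
#'   `"l3"` (provider), `"l4"` (participant).
#' @param subgroups Optional character vector of length `n_isu` labelling
#'   each ISU's subgroup (e.g. `"rural"` / `"urban"`).  Each subgroup must
#'   admit at least 2 ISUs per arm.
#' @return An object of class `hier_design`.
#' @examples
#' d <- hier_design(20, 8, 6, 6, randomization_level = "isu")
#' d$n_participants_per_isu  # 288
#' @export
hier_design <- function(n_isu, n_l2, n_l3, n_l4,
                        randomization_level = c("isu", "l2", "l3", "l4"),
                        subgroups = NULL) {
  randomization_level <- match.arg(randomization_level)
  counts <- c(n_isu = n_isu, n_l2 = n_l2, n_l3 = n_l3, n_l4 = n_l4)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all level counts must be positive integers")
  if (randomization_level == "isu") {
    if (n_isu %% 2 != 0)
      stop("ISU-level randomization with equal allocation requires an even ",
           "number of ISUs")
  } else {
    k <- switch(randomization_level, l2 = n_l2, l3 = n_l3, l4 = n_l4)
    if (k %% 2 != 0)
      stop("randomized level must have an even count within its parent ",
           "for equal allocation (got ", k, ")")
  }
  if (!is.null(subgroups)) {
    if (length(subgroups) != n_isu)
      stop("subgroups must label every ISU (length ", n_isu, ")")
    tab <- table(subgroups)
    if (any(tab < 4) || any(tab %% 2 != 0))
      stop("each subgroup needs an even number of ISUs, at least 2 per arm")
  }
  structure(list(
    n_isu = as.integer(n_isu), n_l2 = as.integer(n_l2),
    n_l3 = as.integer(n_l3), n_l4 = as.integer(n_l4),
    randomization_level = randomization_level,
    subgroups = subgroups,
    n_participants_per_isu = as.integer(n_l2 * n_l3 * n_l4)
  ), class = "hier_design")
}

#' @export
print.hier_design <- function(x, ...) {
  lvl <- c(isu = "hospital (ISU)", l2 = "clinic", l3 = "provider",
           l4 = "participant")[x$randomization_level]
  cat("Balanced multilevel design:", x$n_isu, "hospitals x", x$n_l2,
      "clinics x", x$n_l3, "providers x", x$n_l4, "participants\n")
  cat("Randomization at the", lvl, "level, equal allocation\n")
  if (!is.null(x$subgroups)) {
    tab <- table(x$subgroups)
    cat("Subgroups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Variance model: intraclass correlations and outcome covariance
#'
#' The three-level exchangeable cluster correlation model: two participants
#' sharing a provider correlate at `rho_provider + rho_clinic +
#' rho_hospital`, sharing only a clinic at `rho_clinic + rho_hospital`,
#' sharing only a hospital at `rho_hospital`.  The residual (participant)
#' component is `1 - rho_provider - rho_clinic - rho_hospital` and must be
#' positive.  The full participant covariance is the Kronecker product of
#' this cluster model (scaled by `sigma2`) with the outcome covariance
#' `Sigma`.
#'
#' @param rho_provider,rho_clinic,rho_hospital Intraclass correlations, each
#'   in `[0, 1)`.
#' @param sigma2 Total variance of one outcome on one participant.
#' @param Sigma m x m outcome covariance matrix (default: 8 x 8 identity,
#'   i.e. independent outcomes with unit variance).
#' @param composite_weights Length-m weights defining the composite outcome
#'   (default: the unweighted average, `1/m` each).
#' @return An object of class `variance_model`.
#' @export
variance_model <- function(rho_provider = 0.05, rho_clinic = 0.01,
                           rho_hospital = 0.01, sigma2 = 1,
                           Sigma = diag(8), composite_weights = NULL) {
  rhos <- c(rho_provider, rho_clinic, rho_hospital)
  if (any(rhos < 0) || any(rhos >= 1))
    stop("intraclass correlations must lie in [0, 1)")
  rho_e <- 1 - sum(rhos)
  if (rho_e <= 0)
    stop("intraclass correlations sum to >= 1: no positive residual ",
         "variance component remains")
  if (sigma2 <= 0) stop("sigma2 must be positive")
  Sigma <- as.matrix(Sigma)
  if (!isSymmetric(Sigma, tol = 1e-10))
    stop("Sigma must be symmetric")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("Sigma must be positive definite")
  m <- nrow(Sigma)
  if (is.null(composite_weights)) composite_weights <- rep(1 / m, m)
  if (length(composite_weights) != m)
    stop("composite_weights must have length ", m)
  structure(list(
    rho_provider = rho_provider, rho_clinic = rho_clinic,
    rho_hospital = rho_hospital, rho_residual = rho_e,
    sigma2 = sigma2, Sigma = Sigma, m = m,
    composite_weights = composite_weights
  ), class = "variance_model")
}

#' @export
print.variance_model <- function(x, ...) {
  cat("Three-level cluster variance model\n")
  cat(sprintf("  ICCs: provider %.3g, clinic %.3g, hospital %.3g (residual %.3g)\n",
              x$rho_provider, x$rho_clinic, x$rho_hospital, x$rho_residual))
  cat(sprintf("  sigma2 = %.3g, %d outcomes\n", x$sigma2, x$m))
  invisible(x)
}

#' Intervention effect specification
#'
#' Mean differences (intervention minus control), in units of one outcome
#' standard deviation.  The canonical alternative shifts exactly one
#' outcome (e.g. diet) by `delta` and leaves the others unchanged.
#'
#' @param delta Effect magnitude(s).  Either a full length-m vector, or a
#'   scalar applied to `affected_outcome` when `m` is given.
#' @param m Number of outcomes (needed when `delta` is scalar).
#' @param affected_outcome Index of the single shifted outcome.
#' @return An object of class `effect_spec` with a length-m `delta` vector.
#' @examples
#' effect_spec(0.5, m = 8)            # shift outcome 1 by half an SD
#' effect_spec(c(0, 0, 0.3, 0, 0, 0, 0, 0))
#' @export
effect_spec <- function(delta, m = NULL, affected_outcome = 1L) {
  if (length(delta) == 1 && !is.null(m)) {
    v <- numeric(m)
    v[affected_outcome] <- delta
    delta <- v
  }
  if (any(!is.finite(delta))) stop("delta must be finite")
  structure(list(delta = as.numeric(delta),
                 affected_outcome = as.integer(affected_outcome)),
            class = "effect_spec")
}
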