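#' Noncentrality of the general linear hypothesis
#'
#' For `H0: C B U = Theta0` on a reduced model with cell-means design,
#' computes the b x b noncentrality matrix
#' `Omega = (CBU - Theta0)' [C (X'X)^-1 C']^-1 (CBU - Theta0) (U' Sigma* U)^-1`
#' and its trace `lambda`.  `lambda` is invariant to nonsingular rescaling
#' of the rows of `C` and the columns of `U`.
#'
#' @param glm A [reduced_glm()].
#' @return List with `Omega` (b x b) and `lambda` (its trace).
#' @export
glh_noncentrality <- function(glm) {
  M <- glm$C %*% diag(1 / glm$cell_counts, length(glm$cell_counts)) %*% t(glm$C)
  E <- crossprod(glm$U, glm$SigmaStar %*% glm$U)
  if (rcond(E) < 1e-14) stop("U' SigmaStar U is singular")
  D <- glm$C %*% glm$B %*% glm$U - glm$Theta0
  Omega <- t(D) %*% solve(M, D) %*% solve(E)
  list(Omega = Omega, lambda = sum(diag(Omega)))
}

#' Noncentral-F power
#'
#' Tail probability of the noncentral F beyond the central critical value:
#' `P[F'(ndf, ddf, lambda) > F_crit(alpha)]`.  Equals `alpha` exactly at
#' `lambda = 0` and increases to 1 with `lambda`.
#'
#' @param lambda Noncentrality (>= 0).
#' @param ndf,ddf Numerator and denominator degrees of freedom.
#' @param alpha Type I error rate.
#' @return Power in `[alpha, 1]`.
#' @examples
#' f_power(0, 1, 18, 0.05)      # exactly 0.05
#' f_power(10.07, 1, 18, 0.05)  # ~0.85
#' @export
f_power <- function(lambda, ndf, ddf, alpha = 0.05) {
  if (any(lambda < 0)) stop("noncentrality must be nonnegative")
  if (ndf <= 0 || ddf <= 0) stop("degrees of freedom must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  crit <- stats::qf(1 - alpha, ndf, ddf)
  stats::pf(crit, ndf, ddf, ncp = lambda, lower.tail = FALSE)
}

# McKeon denominator df for the Hotelling-Lawley trace F approximation;
# exact whenever min(a, b) = 1 (reduces to nu for b = 1 and to nu - b + 1
# for a = 1, the Hotelling T^2 to F conversion).
mckeon_ddf <- function(a, b, nu) {
  if (b == 1) return(nu)
  if (a == 1) {
    if (nu - b + 1 <= 0) stop("error df too small: need nu > b - 1")
    return(nu - b + 1)
  }
  if (nu <= b + 3) stop("error df too small for the McKeon approximation")
  B1 <- (nu + a - b - 1) * (nu - 1) / ((nu - b - 3) * (nu - b))
  4 + (a * b + 2) / (B1 - 1)
}

#' Power of the general linear hypothesis test on a reduced model
#'
#' Computes the power of the Hotelling-Lawley trace test under the McKeon F
#' reference distribution — under balance, identical to the power of the
#' mixed-model Wald test with Kenward-Roger degrees of freedom.  When either
#' contrast rank is 1 (`min(a, b) = 1`, every scenario shipped here) the
#' result is the exact noncentral-F power; otherwise the McKeon denominator
#' df and the noncentral-F approximation to the trace are used and the
#' result is flagged approximate.
#'
#' @param glm A [reduced_glm()] (or the output of [reduce_subgroup()] in
#'   stratified mode, in which case one result per stratum is returned).
#' @param alpha Type I error rate.
#' @return Object of class `power_result`: `alpha`, ranks `a` and `b`,
#'   `ndf`, `ddf`, `lambda`, `power`, `exact` flag.
#' @examples
#' d <- hier_design(20, 8, 6, 6, "isu")
#' glh_power(reduce_between(d, variance_model(), effect_spec(1, m = 8),
#'                          "composite"))
#' @export
glh_power <- function(glm, alpha = 0.05) {
  if (!inherits(glm, "reduced_glm") && is.list(glm))
    return(lapply(glm, glh_power, alpha = alpha))
  a <- nrow(glm$C); b <- ncol(glm$U)
  nc <- glh_noncentrality(glm)
  ddf <- mckeon_ddf(a, b, glm$nu)
  structure(list(
    alpha = alpha, a = a, b = b, ndf = a * b, ddf = ddf,
    lambda = nc$lambda, power = f_power(nc$lambda, a * b, ddf, alpha),
    exact = min(a, b) == 1, label = glm$label
  ), class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("%s\n  F(%g, %g), lambda = %.4f, alpha = %.3g: power = %.4f%s\n",
              if (nzchar(x$label)) x$label else "General linear hypothesis",
              x$ndf, x$ddf, x$lambda, x$alpha, x$power,
              if (x$exact) "" else " (McKeon approximation)"))
  invisible(x)
}

#' Power curve over a grid of effect sizes
#'
#' Evaluates analytic power along a grid of effect magnitudes (in SD units
#' of one outcome).  The default grid has 100 evenly spaced points on
#' `[0, 1]`, matching a one-SD axis anchor.
#'
#' @param scenario A [trial_scenario()].
#' @param effect_grid Ascending nonnegative effect magnitudes.
#' @param alpha Type I error rate.
#' @return Data frame of class `power_curve` with columns `scenario`,
#'   `effect`, `ndf`, `ddf`, `noncentrality`, `power`.
#' @export
power_curve <- function(scenario, effect_grid = seq(0, 1, length.out = 100),
                        alpha = 0.05) {
  if (length(effect_grid) == 0 || any(effect_grid < 0) ||
      is.unsorted(effect_grid))
    stop("effect_grid must be a nonempty ascending nonnegative grid")
  rows <- lapply(effect_grid, function(d) {
    pr <- scenario_power(scenario, d, alpha = alpha)
    data.frame(scenario = scenario$id, effect = d, ndf = pr$ndf,
               ddf = pr$ddf, noncentrality = pr$lambda, power = pr$power)
  })
  structure(do.call(rbind, rows), class = c("power_curve", "data.frame"))
}
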