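# Precomputed row layout of a full trial: one row per participant, in
# hospital / clinic / provider / participant order.
trial_layout <- function(design) {
  H <- design$n_isu; C <- design$n_l2; P <- design$n_l3; S <- design$n_l4
  n <- H * C * P * S
  hospital <- rep(seq_len(H), each = C * P * S)
  clinic_g <- rep(seq_len(H * C), each = P * S)       # globally unique ids
  provider_g <- rep(seq_len(H * C * P), each = S)
  if (design$randomization_level == "isu") {
    if (is.null(design$subgroups)) {
      treated_isu <- hospital <= H / 2
    } else {
      # equal arms within each subgroup: first half of each subgroup treated
      treated_by_isu <- logical(H)
      for (s in unique(design$subgroups)) {
        ids <- which(design$subgroups == s)
        treated_by_isu[ids[seq_len(length(ids) / 2)]] <- TRUE
      }
      treated_isu <- treated_by_isu[hospital]
    }
    treated <- treated_isu
  } else {
    treated <- rep(treated_pattern(design), times = H)
  }
  list(
    n = n, H = H,
    hospital = hospital,
    clinic = rep(rep(seq_len(C), each = P * S), times = H),
    provider = rep(rep(seq_len(P), each = S), times = H * C),
    participant = rep(seq_len(S), times = H * C * P),
    clinic_g = clinic_g, provider_g = provider_g,
    treated = treated,
    subgroup = if (is.null(design$subgroups)) NULL
               else design$subgroups[hospital],
    n_per_isu = C * P * S
  )
}

# One replicate's n x m outcome matrix: cell means plus additive Gaussian
# random effects drawn hospital -> clinic -> provider -> residual, each
# component carrying the outcome covariance Sigma (Kronecker model).
sim_outcomes <- function(layout, vm, delta, R_chol) {
  m <- vm$m
  comp <- function(k, rho) {
    if (rho == 0) return(NULL)
    matrix(stats::rnorm(k * m), k, m) %*% (sqrt(rho * vm$sigma2) * R_chol)
  }
  Zh <- comp(layout$H, vm$rho_hospital)
  Zc <- comp(max(layout$clinic_g), vm$rho_clinic)
  Zp <- comp(max(layout$provider_g), vm$rho_provider)
  Y <- matrix(stats::rnorm(layout$n * m), layout$n, m) %*%
       (sqrt(vm$rho_residual * vm$sigma2) * R_chol)
  if (!is.null(Zh)) Y <- Y + Zh[layout$hospital, , drop = FALSE]
  if (!is.null(Zc)) Y <- Y + Zc[layout$clinic_g, , drop = FALSE]
  if (!is.null(Zp)) Y <- Y + Zp[layout$provider_g, , drop = FALSE]
  if (any(delta != 0))
    Y[layout$treated, ] <- sweep(Y[layout$treated, , drop = FALSE], 2,
                                 delta, "+")
  Y
}

#' Simulate one complete multilevel trial
#'
#' Draws a full long-format dataset from the assumed data-generating
#' process: outcome = cell mean + hospital effect + clinic effect + provider
#' effect + participant residual, with component variances `rho_hospital`,
#' `rho_clinic`, `rho_provider`, `rho_residual` times `sigma2` and each
#' component carrying the outcome covariance `Sigma`.  Arm assignment is a
#' fixed balanced pattern (the first half of the units within each parent),
#' which is without loss of generality under exchangeability.
#'
#' @param design A [hier_design()].
#' @param vm A [variance_model()].
#' @param effect An [effect_spec()] (intervention minus control mean shift).
#' @param seed Optional integer seed; identical seed gives an identical
#'   dataset.
#' @return Data frame of class `trial_dataset` with columns `hospital`,
#'   `clinic`, `provider`, `participant`, `arm`, (optional) `subgroup`, and
#'   outcome columns `y1 ... ym`.
#' @examples
#' d <- hier_design(4, 2, 2, 2, "isu")
#' vm <- variance_model(Sigma = diag(2))
#' simulate_trial(d, vm, effect_spec(0.5, m = 2), seed = 1)
#' @export
simulate_trial <- function(design, vm, effect, seed = NULL) {
  if (length(effect$delta) != vm$m)
    stop("effect dimension does not match the outcome covariance")
  if (!is.null(seed)) set.seed(seed)
  lay <- trial_layout(design)
  Y <- sim_outcomes(lay, vm, effect$delta, chol(vm$Sigma))
  colnames(Y) <- paste0("y", seq_len(vm$m))
  out <- data.frame(
    hospital = lay$hospital, clinic = lay$clinic, provider = lay$provider,
    participant = lay$participant,
    arm = ifelse(lay$treated, "treated", "control")
  )
  if (!is.null(lay$subgroup)) out$subgroup <- lay$subgroup
  out <- cbind(out, as.data.frame(Y))
  class(out) <- c("trial_dataset", "data.frame")
  out
}

# Aligned cluster-mean test.  Reduces the data exactly as the reduced model
# specifies and applies the matching exact F test; under balance this
# reproduces the KR mixed-model Wald test decision.
cluster_mean_test <- function(Y, lay, scenario, alpha = 0.05) {
  vm <- scenario$vm
  H <- lay$H
  treated_isu <- rowsum(as.numeric(lay$treated), lay$hospital)[, 1] > 0
  composite <- !identical(scenario$outcome_mode, "multivariate")
  if (composite) yc <- drop(Y %*% vm$composite_weights)

  if (!is.null(scenario$analysis)) {
    sub_isu <- tapply(lay$subgroup, lay$hospital, `[`, 1)
    hm <- rowsum(yc, lay$hospital)[, 1] / lay$n_per_isu
    cell <- interaction(treated_isu, sub_isu, drop = TRUE)
    cm <- tapply(hm, cell, mean)
    resid <- hm - cm[cell]
    if (sum(resid^2) < 1e-300) stop("degenerate (constant) cluster means")
    strata <- sort(unique(sub_isu))
    if (scenario$analysis == "pooled") {
      mse <- sum(resid^2) / (H - 4)
      nc <- table(cell)
      tr_cell <- grepl("^TRUE", names(cm))
      est <- mean(cm[tr_cell]) - mean(cm[!tr_cell])
      se <- sqrt(mse * sum(1 / nc) / 4)
      stat <- (est / se)^2
      df <- c(1, H - 4)
    } else {
      s <- strata[1]                       # strata exchangeable; test first
      sel <- sub_isu == s
      x <- hm[sel & treated_isu]; y <- hm[sel & !treated_isu]
      est <- mean(x) - mean(y)
      if (scenario$variance_df == "whole") {
        mse <- sum(resid^2) / (H - 4)
        df2 <- H - 4
      } else {
        mse <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
               (length(x) + length(y) - 2)
        df2 <- length(x) + length(y) - 2
      }
      stat <- est^2 / (mse * (1 / length(x) + 1 / length(y)))
      df <- c(1, df2)
    }
  } else if (scenario$design$randomization_level == "isu") {
    if (composite) {
      hm <- rowsum(yc, lay$hospital)[, 1] / lay$n_per_isu
      x <- hm[treated_isu]; y <- hm[!treated_isu]
      n1 <- length(x); n2 <- length(y)
      sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
      if (sp2 < 1e-300) stop("degenerate (constant) cluster means")
      stat <- (mean(x) - mean(y))^2 / (sp2 * (1 / n1 + 1 / n2))
      df <- c(1, n1 + n2 - 2)
    } else {
      HM <- rowsum(Y, lay$hospital) / lay$n_per_isu
      X <- HM[treated_isu, , drop = FALSE]; Z <- HM[!treated_isu, , drop = FALSE]
      n1 <- nrow(X); n2 <- nrow(Z); b <- ncol(HM); nu <- n1 + n2 - 2
      S <- (crossprod(sweep(X, 2, colMeans(X))) +
            crossprod(sweep(Z, 2, colMeans(Z)))) / nu
      if (rcond(S) < 1e-14) stop("degenerate cluster-mean covariance")
      d <- colMeans(X) - colMeans(Z)
      T2 <- (n1 * n2 / (n1 + n2)) * drop(crossprod(d, solve(S, d)))
      stat <- (nu - b + 1) / (nu * b) * T2
      df <- c(b, nu - b + 1)
    }
  } else {
    tr <- lay$treated
    n_arm <- sum(tr[lay$hospital == 1])
    if (composite) {
      dm <- rowsum(yc * ifelse(tr, 1, -1), lay$hospital)[, 1] / n_arm
      v <- stats::var(dm)
      if (v < 1e-300) stop("degenerate (constant) cluster means")
      stat <- H * mean(dm)^2 / v
      df <- c(1, H - 1)
    } else {
      D <- rowsum(Y * ifelse(tr, 1, -1), lay$hospital) / n_arm
      b <- ncol(D); nu <- H - 1
      S <- stats::cov(D)
      if (rcond(S) < 1e-14) stop("degenerate cluster-mean covariance")
      dbar <- colMeans(D)
      T2 <- H * drop(crossprod(dbar, solve(S, dbar)))
      stat <- (nu - b + 1) / (nu * b) * T2
      df <- c(b, nu - b + 1)
    }
  }
  crit <- stats::qf(1 - alpha, df[1], df[2])
  list(statistic = stat, df = df, reject = stat > crit,
       p.value = stats::pf(stat, df[1], df[2], lower.tail = FALSE))
}

#' Analyze a simulated trial with the aligned cluster-mean test
#'
#' Reduces the dataset exactly as the corresponding power-equivalent model
#' specifies (ISU grand means under hospital-level randomization, within-ISU
#' arm-mean differences otherwise, composite weighting where applicable) and
#' applies the matching exact F / Hotelling T2 test at level `alpha`.
#'
#' @param dataset A `trial_dataset` from [simulate_trial()], balanced and
#'   matching the scenario's design.
#' @param scenario A [trial_scenario()].
#' @param alpha Type I error rate.
#' @return List with `statistic` (on the F scale), `df`, `p.value`,
#'   `reject`.
#' @export
analyze_trial <- function(dataset, scenario, alpha = 0.05) {
  ycols <- grep("^y[0-9]+$", names(dataset), value = TRUE)
  if (length(ycols) != scenario$vm$m)
    stop("dataset has ", length(ycols), " outcomes but the scenario expects ",
         scenario$vm$m)
  lay <- trial_layout(scenario$design)
  if (nrow(dataset) != lay$n)
    stop("dataset is not balanced for this design (expected ", lay$n, " rows)")
  ord <- order(dataset$hospital, dataset$clinic, dataset$provider,
               dataset$participant)
  dataset <- dataset[ord, ]
  expected_arm <- ifelse(lay$treated, "treated", "control")
  if (!identical(as.character(dataset$arm), expected_arm))
    stop("arm assignment does not match the scenario's randomization level")
  Y <- as.matrix(dataset[, ycols, drop = FALSE])
  cluster_mean_test(Y, lay, scenario, alpha = alpha)
}

#' Empirical power by Monte-Carlo simulation
#'
#' Simulates `reps` independent trials at effect size `delta`, analyzes each
#' with the scenario's aligned cluster-mean test, and returns the rejection
#' proportion with its binomial standard error.  This is the independent
#' check on every analytic power value: under the model, analytic and
#' empirical power agree within Monte-Carlo error.
#'
#' @param scenario A [trial_scenario()].
#' @param delta Effect on the affected outcome (SD units).
#' @param reps Number of replicates (>= 100).
#' @param seed Integer seed; results are reproducible given the seed.
#' @param alpha Type I error rate.
#' @return Object of class `sim_result`: `reps`, `rejections`, `power`,
#'   `se`, `seed`, `delta`.
#' @export
empirical_power <- function(scenario, delta, reps = 10000, seed = 1,
                            alpha = 0.05) {
  if (reps < 100) stop("reps must be at least 100")
  set.seed(seed)
  vm <- scenario$vm
  eff <- effect_spec(delta, m = vm$m,
                     affected_outcome = scenario$affected_outcome)
  lay <- trial_layout(scenario$design)
  R_chol <- chol(vm$Sigma)
  rej <- 0L
  for (r in seq_len(reps)) {
    Y <- sim_outcomes(lay, vm, eff$delta, R_chol)
    if (cluster_mean_test(Y, lay, scenario, alpha = alpha)$reject)
      rej <- rej + 1L
  }
  phat <- rej / reps
  structure(list(reps = reps, rejections = rej, power = phat,
                 se = sqrt(phat * (1 - phat) / reps),
                 seed = seed, delta = delta, scenario = scenario$id),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Empirical power [%s, delta = %g]: %.4f (SE %.4f, %d/%d, seed %d)\n",
              x$scenario, x$delta, x$power, x$se, x$rejections, x$reps,
              x$seed))
  invisible(x)
}
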