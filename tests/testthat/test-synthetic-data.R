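test_that("simulated trials have the stated shape and are seed-deterministic", {
  d <- default_design("isu", subgroups = TRUE)
  vm <- paper_vm()
  ds <- simulate_trial(d, vm, effect_spec(0.5, m = 8), seed = 11)
  expect_equal(nrow(ds), 20 * 8 * 6 * 6)
  expect_equal(sum(grepl("^y[0-9]+$", names(ds))), 8)
  expect_equal(sort(unique(ds$arm)), c("control", "treated"))
  expect_equal(as.vector(table(ds$arm)), c(2880, 2880))
  expect_equal(table(ds$subgroup)[["rural"]], 2880)
  ds2 <- simulate_trial(d, vm, effect_spec(0.5, m = 8), seed = 11)
  expect_identical(ds, ds2)
  ds3 <- simulate_trial(d, vm, effect_spec(0.5, m = 8), seed = 12)
  expect_false(identical(ds, ds3))
  # treated mean shifted on outcome 1 only (large-ish check, loose tol)
  shift <- colMeans(ds[ds$arm == "treated", paste0("y", 1:8)]) -
           colMeans(ds[ds$arm == "control", paste0("y", 1:8)])
  expect_equal(unname(shift[1]), 0.5, tolerance = 0.5)
})

test_that("same-provider pairs correlate at the summed ICCs", {
  d <- hier_design(20, 8, 6, 6, "isu")
  vm <- paper_vm1()
  set.seed(21)
  xs <- ys <- NULL
  for (r in 1:4) {
    ds <- simulate_trial(d, vm, effect_spec(0, m = 1))
    y <- matrix(ds$y1, nrow = 6)        # columns = providers, rows = participants
    pairs <- combn(6, 2)
    xs <- c(xs, as.vector(y[pairs[1, ], ]))
    ys <- c(ys, as.vector(y[pairs[2, ], ]))
  }
  # >= 2000 same-provider pairs; known zero mean and unit variance
  expect_gte(length(xs), 2000)
  expect_lt(abs(mean(xs * ys) - 0.07), 0.01)
})

test_that("hospital composite means recover the analytic variance", {
  # many ISUs in one simulated draw: empirical variance of the hospital
  # composite mean must match vbar * w'Sigma w within 5%
  d <- hier_design(5000, 8, 6, 6, "isu")
  vm <- paper_vm()
  set.seed(31)
  lay <- hierpower:::trial_layout(d)
  Y <- hierpower:::sim_outcomes(lay, vm, rep(0, 8), chol(vm$Sigma))
  hm <- rowsum(drop(Y %*% vm$composite_weights), lay$hospital)[, 1] / 288
  expect_equal(var(hm), 0.001940104, tolerance = 0.05)
  # residual-only model: component draws vanish, variance is sigma2/(n*8)
  vm0 <- variance_model(0, 0, 0, 1, diag(8))
  Y0 <- hierpower:::sim_outcomes(lay, vm0, rep(0, 8), chol(vm0$Sigma))
  hm0 <- rowsum(drop(Y0 %*% vm0$composite_weights), lay$hospital)[, 1] / 288
  expect_equal(var(hm0), 1 / (288 * 8), tolerance = 0.05)
})

test_that("the aligned test reduces to the textbook statistic on ISU means", {
  d <- hier_design(20, 1, 1, 1, "isu")   # one participant per hospital
  vm1 <- variance_model(0, 0, 0, 1, diag(1), composite_weights = 1)
  sc <- trial_scenario(d, vm1)
  set.seed(41)
  vals <- rnorm(20, mean = rep(c(0.8, 0), each = 10))
  ds <- simulate_trial(d, vm1, effect_spec(0, m = 1), seed = 1)
  ds$y1 <- vals
  res <- analyze_trial(ds, sc)
  tt <- t.test(vals[1:10], vals[11:20], var.equal = TRUE)
  expect_equal(res$statistic, unname(tt$statistic)^2)
  expect_equal(res$df[2], 18)
  expect_equal(res$p.value, tt$p.value)
  # degenerate variance guard
  ds$y1 <- rep(1, 20)
  expect_error(analyze_trial(ds, sc), "degenerate")
  # mismatched design is rejected
  sc2 <- trial_scenario(hier_design(20, 1, 1, 2, "l4"), vm1)
  expect_error(analyze_trial(ds, sc2), "balanced|rows")
})

test_that("empirical power is reproducible and matches its SE arithmetic", {
  sc <- default_scenarios()$hospital.composite
  r1 <- empirical_power(sc, 0.5, reps = 200, seed = 5)
  r2 <- empirical_power(sc, 0.5, reps = 200, seed = 5)
  expect_identical(r1$power, r2$power)
  expect_equal(r1$se, sqrt(r1$power * (1 - r1$power) / 200))
  expect_equal(r1$power, r1$rejections / r1$reps)
  # agreement with the analytic value at a moderate effect (3 SE, 800 reps)
  r3 <- empirical_power(sc, 0.4, reps = 800, seed = 6)
  ana <- scenario_power(sc, 0.4)$power
  expect_lt(abs(r3$power - ana), 3 * sqrt(ana * (1 - ana) / 800))
  expect_error(empirical_power(sc, 0.5, reps = 50), "at least 100")
})
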