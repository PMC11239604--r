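test_that("hospital-level reduction matches the closed-form moments", {
  d <- hier_design(20, 8, 6, 6, "isu")
  vm <- paper_vm()
  g <- reduce_between(d, vm, effect_spec(1, m = 8), "composite")
  vbar <- 0.01 + 0.01 / 8 + 0.05 / 48 + 0.93 / 288
  expect_equal(drop(g$SigmaStar), vbar / 8)      # w'Sigma w = 1/8
  expect_equal(drop(g$B), c(treated = 1 / 8, control = 0))
  expect_equal(g$rank_r, 2)
  expect_equal(g$nu, 18)
  # null case: identical rows
  g0 <- reduce_between(d, vm, effect_spec(0, m = 8), "composite")
  expect_equal(unname(g0$B[1, ]), unname(g0$B[2, ]))
  # multivariate mode: CBU picks out the single shifted outcome
  gm <- reduce_between(d, vm, effect_spec(0.4, m = 8), "multivariate")
  expect_equal(drop(gm$C %*% gm$B %*% gm$U), c(0.4, rep(0, 7)))
  expect_equal(gm$SigmaStar, vbar * diag(8))
})

test_that("within-ISU reduction cancels shared components in the difference", {
  vm <- paper_vm()
  d4 <- hier_design(20, 8, 6, 6, "l4")
  g <- reduce_within(d4, vm, effect_spec(1, m = 8), "composite")
  expect_equal(g$rank_r, 1)
  expect_equal(g$nu, 19)
  expect_equal(drop(crossprod(g$U, g$SigmaStar %*% g$U)),
               2 * 0.93 / 144 / 8)
  # the arm-difference covariance keeps only components below the parent of
  # the randomized level: the hospital ICC never appears, and the closed
  # forms below are free of rho_hospital
  vmh <- paper_vm()
  closed <- list(
    l2 = 2 * (0.01 / 4 + 0.05 / 24 + 0.93 / 144),  # clinic randomization
    l3 = 2 * (0.05 / 24 + 0.93 / 144),             # provider randomization
    l4 = 2 * (0.93 / 144)                          # participant randomization
  )
  for (lvl in names(closed)) {
    dd <- hier_design(20, 8, 6, 6, lvl)
    gg <- reduce_within(dd, vmh, effect_spec(1, m = 8), "multivariate")
    E <- crossprod(gg$U, gg$SigmaStar %*% gg$U)
    expect_equal(E, closed[[lvl]] * diag(8))
  }
  # no clustering: reduces to independent arms (cov 0, var sigma2/arm size)
  vm0 <- variance_model(0, 0, 0, 1, diag(8))
  g0 <- reduce_within(d4, vm0, effect_spec(1, m = 8), "composite")
  expect_equal(g0$SigmaStar[1, 2], 0)
  expect_equal(g0$SigmaStar[1, 1], (1 / 144) / 8)
})

test_that("subgroup reductions keep the stated cell and df bookkeeping", {
  vm <- paper_vm()
  sg <- default_design("isu", subgroups = TRUE)
  eff <- effect_spec(1, m = 8)
  gp <- reduce_subgroup(sg, vm, eff, "pooled")
  expect_equal(gp$rank_r, 4)
  expect_equal(gp$nu, 16)
  expect_equal(gp$cell_counts, rep(5, 4), ignore_attr = TRUE)
  # pooled contrast equals the common arm difference under zero interaction
  expect_equal(drop(gp$C %*% gp$B %*% gp$U), 1 / 8)
  gs <- reduce_subgroup(sg, vm, eff, "stratified")
  expect_length(gs, 2)
  expect_equal(gs[[1]]$n_rows, 10)
  expect_equal(gs[[1]]$nu, 8)
  gw <- reduce_subgroup(sg, vm, eff, "stratified", variance_df = "whole")
  expect_equal(gw[[1]]$nu, 16)
  # zero effect: identical rows everywhere
  g0 <- reduce_subgroup(sg, vm, effect_spec(0, m = 8), "pooled")
  expect_true(all(g0$B == g0$B[1, 1]))
  expect_error(reduce_subgroup(default_design("isu"), vm, eff, "pooled"),
               "subgroup")
})

test_that("effect passes through linearly and composite mode is consistent", {
  vm <- paper_vm()
  for (lvl in c("isu", "l4")) {
    d <- hier_design(20, 8, 6, 6, lvl)
    red <- if (lvl == "isu") reduce_between else reduce_within
    g1 <- red(d, vm, effect_spec(0.3, m = 8), "multivariate")
    g2 <- red(d, vm, effect_spec(0.6, m = 8), "multivariate")
    expect_equal(2 * (g1$C %*% g1$B %*% g1$U), g2$C %*% g2$B %*% g2$U)
    # composite model = multivariate model post-multiplied by the weights
    w <- vm$composite_weights
    gc <- red(d, vm, effect_spec(0.3, m = 8), "composite")
    expect_equal(drop(gc$B %*% gc$U), drop(g1$B %*% g1$U %*% w))
    Em <- crossprod(g1$U, g1$SigmaStar %*% g1$U)
    expect_equal(drop(crossprod(gc$U, gc$SigmaStar %*% gc$U)),
                 drop(crossprod(w, Em %*% w)))
  }
})
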