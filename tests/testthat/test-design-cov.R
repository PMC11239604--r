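test_that("design and variance-model invariants are enforced", {
  expect_error(hier_design(20, 8, 6, 5, "l4"), "even")
  expect_error(hier_design(20, 7, 6, 6, "l2"), "even")
  expect_error(hier_design(21, 8, 6, 6, "isu"), "even")
  expect_s3_class(hier_design(20, 7, 6, 6, "l4"), "hier_design")
  expect_error(hier_design(20, 8, 6, 6, "isu",
                           subgroups = c(rep("a", 18), rep("b", 2))),
               "subgroup")
  expect_error(variance_model(0.6, 0.3, 0.2), "residual")
  expect_error(variance_model(-0.1, 0, 0), "\\[0, 1\\)")
  expect_error(variance_model(Sigma = matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("exchangeable covariance reproduces the shared-component sums", {
  vm <- paper_vm1()
  # two participants sharing provider, clinic, hospital: 0.05+0.01+0.01
  d <- hier_design(2, 1, 1, 2, "isu")
  expect_equal(isu_covariance(d, vm),
               matrix(c(1, 0.07, 0.07, 1), 2))
  # two providers sharing clinic and hospital only: 0.01+0.01
  d2 <- hier_design(2, 1, 2, 1, "isu")
  expect_equal(isu_covariance(d2, vm)[1, 2], 0.02)
  # no clustering: identity
  d0 <- hier_design(2, 1, 1, 2, "isu")
  vm0 <- variance_model(0, 0, 0, 1, diag(1))
  expect_equal(isu_covariance(d0, vm0), diag(2))
  # correlation ladder: provider > clinic > hospital sharing
  d3 <- hier_design(2, 2, 2, 2, "isu")
  V <- cluster_correlation_matrix(d3, vm)
  expect_gt(V[1, 2], V[1, 3])   # same provider vs same clinic
  expect_gt(V[1, 3], V[1, 5])   # same clinic vs same hospital only
  expect_equal(V[1, 2], 0.07)
  expect_equal(V[1, 3], 0.02)
  expect_equal(V[1, 5], 0.01)
})

test_that("Kronecker structure carries the outcome covariance", {
  Sig <- matrix(c(1, 0.3, 0.3, 1), 2)
  vm <- variance_model(0.05, 0.01, 0.01, 1, Sig)
  d <- hier_design(2, 1, 1, 2, "isu")
  K <- isu_covariance(d, vm)
  expect_equal(dim(K), c(4, 4))
  expect_equal(K[1:2, 1:2], Sig, ignore_attr = TRUE)
  expect_equal(K[1:2, 3:4], 0.07 * Sig, ignore_attr = TRUE)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
})

test_that("contrast_variance matches hand values and scales by w'Sigma w", {
  vm <- paper_vm1()
  d <- hier_design(2, 1, 1, 2, "isu")
  expect_equal(contrast_variance(d, vm, c(1, 1) / 2), 0.535)
  expect_equal(contrast_variance(d, vm, c(1, -1)), 2 * 0.93)
  d288 <- hier_design(20, 8, 6, 6, "isu")
  expect_equal(contrast_variance(d288, vm, rep(1 / 288, 288)),
               0.01 + 0.01 / 8 + 0.05 / 48 + 0.93 / 288)
  # outcome weights multiply by w'Sigma w (composite of 8 iid outcomes: 1/8)
  vm8 <- paper_vm()
  expect_equal(contrast_variance(d288, vm8, rep(1 / 288, 288), rep(1 / 8, 8)),
               (0.01 + 0.01 / 8 + 0.05 / 48 + 0.93 / 288) / 8)
  expect_error(contrast_variance(d, vm, c(1, 1, 1)), "length")
})

test_that("counting formula equals brute force for all small designs", {
  vm <- paper_vm1()
  set.seed(42)
  grid <- expand.grid(C = 1:3, P = 1:3, S = 1:4)
  grid <- grid[grid$C * grid$P * grid$S <= 36, ]
  for (i in seq_len(nrow(grid))) {
    C <- grid$C[i]; P <- grid$P[i]; S <- grid$S[i]
    d <- hier_design(2, C, P, S, "isu")
    V <- brute_cluster_matrix(C, P, S, 0.05, 0.01, 0.01)
    for (k in 1:3) {
      a <- rnorm(C * P * S)
      expect_equal(contrast_variance(d, vm, a), brute_quad(V, a),
                   tolerance = 1e-12)
    }
  }
})

test_that("covariance is invariant under within-level permutations", {
  vm <- paper_vm1()
  d <- hier_design(2, 2, 2, 2, "isu")
  V <- cluster_correlation_matrix(d, vm)
  # swap the two participants of provider 1 (rows/cols 1 and 2)
  p <- c(2, 1, 3:8)
  expect_equal(V[p, p], V, ignore_attr = TRUE)
  # swap the two providers of clinic 1 (blocks 1:2 and 3:4)
  p <- c(3, 4, 1, 2, 5:8)
  expect_equal(V[p, p], V, ignore_attr = TRUE)
  # swap the two clinics (blocks 1:4 and 5:8)
  p <- c(5:8, 1:4)
  expect_equal(V[p, p], V, ignore_attr = TRUE)
})

test_that("arm mean moments agree with the brute-force oracle", {
  vm <- paper_vm1()
  # clinic-level randomization, 4T/4C clinics of 36 participants each
  d <- hier_design(20, 8, 6, 6, "l2")
  M <- arm_mean_moments(d, vm)
  expect_equal(M[1, 1], 0.01 + 0.01 / 4 + 0.05 / 24 + 0.93 / 144)
  expect_equal(M[1, 2], 0.01)
  expect_equal(attr(M, "var_diff"), 2 * (0.01 / 4 + 0.05 / 24 + 0.93 / 144))
  # participant-level: only the residual component survives the difference
  d4 <- hier_design(20, 8, 6, 6, "l4")
  expect_equal(attr(arm_mean_moments(d4, vm), "var_diff"), 2 * 0.93 / 144)
  # brute-force check of the full 2x2 on a small clinic-randomized design
  ds <- hier_design(2, 2, 2, 3, "l2")
  V <- brute_cluster_matrix(2, 2, 3, 0.05, 0.01, 0.01)
  tr <- rep(c(TRUE, FALSE), each = 6)
  aT <- ifelse(tr, 1 / 6, 0); aC <- ifelse(tr, 0, 1 / 6)
  Ms <- arm_mean_moments(ds, vm)
  expect_equal(Ms[1, 1], brute_quad(V, aT), tolerance = 1e-12)
  expect_equal(Ms[2, 2], brute_quad(V, aC), tolerance = 1e-12)
  expect_equal(Ms[1, 2], brute_quad(V, aT, aC), tolerance = 1e-12)
  # iid case
  vm0 <- variance_model(0, 0, 0, 1, diag(1))
  M0 <- arm_mean_moments(d, vm0)
  expect_equal(M0[1, 2], 0)
  expect_equal(M0[1, 1], 1 / 144)
  expect_error(arm_mean_moments(hier_design(20, 8, 6, 6, "isu"), vm),
               "within-ISU")
})
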