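# Independent brute-force oracles: build the within-ISU covariance matrix
# element by element (no shared code with the counting formulas) and
# evaluate quadratic/bilinear forms on it directly.

brute_cluster_matrix <- function(C, P, S, rho_p, rho_c, rho_h, sigma2 = 1) {
  n <- C * P * S
  prov <- rep(seq_len(C * P), each = S)
  clin <- rep(seq_len(C), each = P * S)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    V[i, j] <- if (i == j) sigma2 else
      sigma2 * (rho_h + rho_c * (clin[i] == clin[j]) +
                rho_p * (prov[i] == prov[j]))
  }
  V
}

brute_quad <- function(V, a, b = a) drop(t(a) %*% V %*% b)

# default worked-example pieces used across test files
paper_vm  <- function() variance_model(0.05, 0.01, 0.01, 1, diag(8))
paper_vm1 <- function() variance_model(0.05, 0.01, 0.01, 1, diag(1))
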