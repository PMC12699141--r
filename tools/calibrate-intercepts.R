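# Derivation of the hard-coded intercepts in tapir_scenario().
#
# Finds, by Monte-Carlo root-finding on a large covariate draw, the logit
# intercepts for which the reference scenario's expected naive occupancy is
# 0.392 and the expected per-occasion detection probability at occupied
# sites is 0.46. Run once; the resulting values (-0.4706, -0.2485) are
# hard-coded in R/simulate.R.

set.seed(42)
R <- diag(4); R[1:3, 1:3] <- 0.3; diag(R) <- 1
n <- 4e6
X <- scale(matrix(rnorm(n * 4), n, 4) %*% chol(R))
beta_psi <- c(0.334, 0.232, -0.100, -0.354)
beta_p <- c(0.30, 0, 0.35, 0)
J <- 15

psi0 <- uniroot(function(a) mean(plogis(a + X %*% beta_psi)) - 0.392,
                c(-2, 1), tol = 1e-7)$root
psi <- plogis(psi0 + X %*% beta_psi)
z <- rbinom(n, 1, psi)
p0 <- uniroot(function(b) {
  p <- plogis(b + X %*% beta_p)
  sum(p * z) / sum(z) - 0.46
}, c(-2, 1), tol = 1e-7)$root

p <- plogis(p0 + X %*% beta_p)
cat("psi intercept:", round(psi0, 4), "\n")
cat("p intercept:  ", round(p0, 4), "\n")
cat("check: E[naive occupancy] =", round(mean(psi * (1 - (1 - p)^J)), 4),
    "  E[p | occupied] =", round(sum(p * z) / sum(z), 4), "\n")
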