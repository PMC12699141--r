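test_that("site likelihood matches hand values and the enumeration oracle", {
  expect_equal(site_likelihood(c(1, 0, 1), 0.5, 0.5), 0.0625)
  expect_equal(site_likelihood(c(0, 0, 0), 0.5, 0.5), 0.5625)
  # occupancy forced: plain Bernoulli product
  expect_equal(site_likelihood(c(1, 0), 1, c(0.3, 0.6)), 0.3 * 0.4)
  # missing occasions drop out of the product
  expect_equal(site_likelihood(c(1, NA, 0), 0.5, 0.4),
               0.5 * 0.4 * 0.6)
  set.seed(101)
  for (i in 1:50) {
    J <- sample(1:4, 1)
    h <- c(0, 1, NA)[sample(1:3, J, replace = TRUE)]
    if (all(is.na(h))) h[1] <- 0
    psi <- runif(1)
    p <- runif(J)
    expect_equal(site_likelihood(h, psi, p),
                 enum_site_likelihood(h, psi, p), tolerance = 1e-12)
  }
  expect_error(site_likelihood(c(0, 1), 0.5, c(0.1, 0.2, 0.3)), "length")
})

test_that("site likelihoods sum to one over all possible histories", {
  set.seed(33)
  for (J in 1:4) {
    hs <- all_histories(J)
    psi <- runif(1)
    p <- runif(J)
    total <- sum(apply(hs, 1, site_likelihood, psi = psi, p = p))
    expect_equal(total, 1, tolerance = 1e-12)
  }
})

test_that("negative log-likelihood is additive and matches the oracle", {
  dm1 <- detection_matrix(matrix(c(0, 0, 0), 1, 3))
  cov1 <- data.frame(site_id = dm1$site_ids)
  expect_equal(occu_nll(c(0, 0), dm1, cov1), -log(0.5625))
  # two identical sites: exactly twice the one-site value
  dm2 <- detection_matrix(matrix(0, 2, 3))
  cov2 <- data.frame(site_id = dm2$site_ids)
  expect_equal(occu_nll(c(0, 0), dm2, cov2), 2 * -log(0.5625))
  # against the enumeration oracle on 5 random sites with a covariate
  set.seed(8)
  y <- matrix(rbinom(5 * 4, 1, 0.4), 5, 4)
  y[1, 1] <- NA
  y[2, ] <- 0
  dm <- detection_matrix(y)
  cov <- data.frame(site_id = dm$site_ids, x = rnorm(5))
  par <- c(0.3, -0.2, -0.1, 0.4)  # psi: int + x; p: int + x
  psi <- plogis(par[1] + par[2] * cov$x)
  p <- plogis(par[3] + par[4] * cov$x)
  oracle <- -sum(vapply(1:5, function(i) {
    log(enum_site_likelihood(y[i, ], psi[i], rep(p[i], 4)))
  }, numeric(1)))
  expect_equal(occu_nll(par, dm, cov, psi_terms = "x", p_terms = "x"),
               oracle, tolerance = 1e-10)
})

test_that("intercept-only MLE reproduces the grid-search oracle", {
  sim <- make_test_sim(n_sites = 60)
  fit <- occu_fit(sim$matrix, sim$covariates)
  d <- rowSums(sim$matrix$y == 1, na.rm = TRUE)
  m <- rowSums(!is.na(sim$matrix$y))
  oracle <- grid_search_mle(d, m, step = 1e-3)
  # the grid point nearest the optimum can be off by half a step
  expect_lt(abs(plogis(coef(fit)[[1]]) - oracle$psi), 1e-3)
  expect_lt(abs(plogis(coef(fit)[[2]]) - oracle$p), 1e-3)
  expect_gte(fit$loglik, oracle$loglik - 1e-6)
})

test_that("estimates recover simulation truth within 2 SE at large n", {
  design <- sim_design(n_sites = 2000, J = 15,
                       psi_intercept = qlogis(0.6), p_intercept = qlogis(0.3))
  sim <- simulate_camtrap(design, seed = 99)
  fit <- occu_fit(sim$matrix, sim$covariates)
  td <- tidy(fit)
  expect_true(fit$converged)
  expect_lt(abs(td$estimate[1] - qlogis(0.6)), 2 * td$std.error[1])
  expect_lt(abs(td$estimate[2] - qlogis(0.3)), 2 * td$std.error[2])
  # AICc consistent with loglik, K, n
  expect_equal(fit$aicc, aicc(fit$loglik, fit$K, fit$n_sites))
  # vcov symmetric with positive diagonal
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-8)
  expect_true(all(diag(fit$vcov) > 0))
})

test_that("saturated detection drives psi to the boundary and flags it", {
  y <- matrix(1L, 30, 5)
  dm <- detection_matrix(y)
  cov <- data.frame(site_id = dm$site_ids)
  fit <- occu_fit(dm, cov)
  expect_true(fit$boundary)
  expect_gt(plogis(coef(fit)[[1]]), 0.99)
  # detection MLE approaches the plain Bernoulli rate (here 1, boundary)
  expect_gt(plogis(coef(fit)[[2]]), 0.99)
})

test_that("with near-certain occupancy the detection MLE is the Bernoulli rate", {
  # every site detected at least once, psi pushed to 1: p-hat equals
  # total detections / total surveyed occasions
  set.seed(12)
  y <- matrix(rbinom(200 * 10, 1, 0.5), 200, 10)
  y[rowSums(y) == 0, 1] <- 1L
  dm <- detection_matrix(y)
  cov <- data.frame(site_id = dm$site_ids)
  fit <- occu_fit(dm, cov)
  expect_equal(plogis(coef(fit)[[2]]), mean(y), tolerance = 1e-3)
})

test_that("predictions are monotone, bounded, and Wald-consistent", {
  sim <- make_test_sim()
  fit <- occu_fit(sim$matrix, sim$covariates,
                  psi_terms = c("forest_d", "past"), p_terms = "forest_d")
  at0 <- predict(fit, quantity = "psi")
  expect_equal(at0$estimate, plogis(coef(fit)[["psi_(Intercept)"]]))
  # increasing a positive-coefficient covariate increases the prediction
  b <- coef(fit)[["psi_forest_d"]]
  grid <- predict(fit, newdata = data.frame(forest_d = c(-1, 0, 1)),
                  quantity = "psi")
  if (b > 0) expect_true(all(diff(grid$estimate) > 0))
  expect_true(all(grid$lower <= grid$estimate & grid$estimate <= grid$upper))
  expect_true(all(grid$lower >= 0 & grid$upper <= 1))
  # CI endpoints equal logistic(eta +/- 1.96 se) with se from the
  # quadratic form x' V x on the psi block
  x <- c(1, 0.5, -0.3)
  V <- vcov(fit)[1:3, 1:3]
  eta <- sum(x * coef(fit)[1:3])
  se <- sqrt(drop(t(x) %*% V %*% x))
  pr <- predict(fit, newdata = data.frame(forest_d = 0.5, past = -0.3),
                quantity = "psi")
  expect_equal(pr$lower, plogis(eta - qnorm(0.975) * se), tolerance = 1e-10)
  expect_equal(pr$upper, plogis(eta + qnorm(0.975) * se), tolerance = 1e-10)
  expect_error(predict(fit, newdata = data.frame(nope = 1)), "nope")
})

test_that("tidy and glance expose the fit in broom shape", {
  sim <- make_test_sim()
  fit <- occu_fit(sim$matrix, sim$covariates, psi_terms = "forest_d")
  td <- tidy(fit)
  expect_named(td, c("submodel", "term", "estimate", "std.error",
                     "statistic", "p.value"))
  expect_equal(nrow(td), 3)
  gl <- glance(fit)
  expect_equal(gl$K, 3)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})
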