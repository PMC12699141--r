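test_that("AICc formula, limits, and guards", {
  expect_equal(aicc(-100, 5, 40), 200 + 10 + 60 / 34)
  expect_equal(aicc(-50, 0, 10), 100)
  expect_equal(aicc(-100, 5, 1e9), -2 * -100 + 10, tolerance = 1e-6)
  expect_error(aicc(-100, 5, 6), "n > K")
})

test_that("model enumeration covers all covariate subsets", {
  expect_equal(nrow(enumerate_model_specs(character(), character())), 1)
  expect_equal(nrow(enumerate_model_specs(c("a", "b"), "c")), 8)
  specs66 <- enumerate_model_specs(letters[1:6], letters[7:12])
  expect_equal(nrow(specs66), 4096)
  expect_equal(anyDuplicated(specs66$label), 0)
  # intercept-only member present
  expect_true("p(.)Psi(.)" %in% specs66$label)
  expect_error(enumerate_model_specs(letters[1:8], letters[1:8]),
               "max_terms")
  capped <- enumerate_model_specs(letters[1:4], character(), max_terms = 1)
  expect_equal(nrow(capped), 5)
})

test_that("ranking, deltas, and Akaike weights follow the definitions", {
  sim <- make_test_sim()
  specs <- enumerate_model_specs("forest_d", "forest_d")
  set <- fit_models(specs, sim$matrix, sim$covariates)
  expect_s3_class(set, "occu_model_set")
  expect_equal(nrow(set), 4)
  expect_equal(set$delta[1], 0)
  expect_false(is.unsorted(set$AICc))
  expect_equal(sum(set$weight), 1, tolerance = 1e-10)
  expect_equal(set$weight,
               exp(-set$delta / 2) / sum(exp(-set$delta / 2)),
               tolerance = 1e-12)
  # ranking is a permutation: nothing lost or duplicated
  expect_setequal(set$label, specs$label)

  # two-model arithmetic: AICc 100 vs 102
  f1 <- set$fit[[1]]; f2 <- set$fit[[2]]
  f1$aicc <- 100; f2$aicc <- 102
  two <- rank_models(list(f1, f2))
  expect_equal(two$weight, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-10)
  # equal AICc: equal weights
  f2$aicc <- 100
  eq <- rank_models(list(f1, f2, f2))
  expect_equal(eq$weight, rep(1 / 3, 3))
})

test_that("non-converged fits are excluded with a warning", {
  sim <- make_test_sim()
  f <- occu_fit(sim$matrix, sim$covariates)
  bad <- f
  bad$converged <- FALSE
  bad$label <- "p(.)Psi(broken)"
  expect_warning(set <- rank_models(list(f, bad)), "non-converged")
  expect_equal(nrow(set), 1)
  expect_equal(attr(set, "n_excluded"), 1)
  expect_error(suppressWarnings(rank_models(list(bad))), "No converged")
})

test_that("confidence set uses a strict delta threshold and renormalizes", {
  sim <- make_test_sim()
  f <- occu_fit(sim$matrix, sim$covariates)
  mk <- function(aicc_val, lab) {
    g <- f; g$aicc <- aicc_val; g$label <- lab; g
  }
  set <- rank_models(list(mk(100, "m0"), mk(101.5, "m1"), mk(102, "m2"),
                          mk(104, "m3")))
  cs <- confidence_set(set, threshold = 2)
  # delta exactly 2.0 excluded
  expect_setequal(cs$label, c("m0", "m1"))
  expect_equal(sum(cs$weight), 1, tolerance = 1e-12)
  # weights over the full set preserved alongside
  expect_true(all(cs$weight_all < cs$weight))
  single <- confidence_set(rank_models(list(mk(100, "only"))), 2)
  expect_equal(single$weight, 1)
})

test_that("model averaging does shrinkage arithmetic exactly", {
  sim <- make_test_sim()
  full <- occu_fit(sim$matrix, sim$covariates, psi_terms = "forest_d")
  null <- occu_fit(sim$matrix, sim$covariates)
  set <- confidence_set(rank_models(list(full, null)), threshold = Inf)
  avg <- model_average(set, terms = "occupancy:forest_d")
  w <- set$weight[set$label == full$label]
  b <- coef(full)[["psi_forest_d"]]
  v <- vcov(full)["psi_forest_d", "psi_forest_d"]
  # shrinkage: absent model contributes 0
  expect_equal(avg$estimate, w * b, tolerance = 1e-12)
  est <- w * b
  se_expected <- w * sqrt(v + (b - est)^2) + (1 - w) * abs(est)
  expect_equal(avg$std.error, se_expected, tolerance = 1e-12)
  # conditional averaging over the one containing model returns it unshrunk
  avgc <- model_average(set, terms = "occupancy:forest_d",
                        method = "conditional")
  expect_equal(avgc$estimate, b, tolerance = 1e-12)
  expect_equal(avgc$std.error, sqrt(v), tolerance = 1e-12)
  expect_error(model_average(set, terms = "occupancy:unicorn"), "unicorn")
})

test_that("two equal-weight models average to the midpoint", {
  sim <- make_test_sim()
  f <- occu_fit(sim$matrix, sim$covariates, psi_terms = "forest_d")
  f1 <- f; f1$aicc <- 100; f1$label <- "m1"
  f2 <- f; f2$aicc <- 100; f2$label <- "m2"
  f2$coef[["psi_forest_d"]] <- 0.4
  f1$coef[["psi_forest_d"]] <- 0.2
  set <- confidence_set(rank_models(list(f1, f2)), 2)
  avg <- model_average(set, terms = "occupancy:forest_d")
  expect_equal(avg$estimate, 0.3, tolerance = 1e-12)
  # averaged estimate invariant to fit ordering
  set_rev <- confidence_set(rank_models(list(f2, f1)), 2)
  expect_equal(model_average(set_rev, terms = "occupancy:forest_d")$estimate,
               avg$estimate, tolerance = 1e-12)
})

test_that("single-member averaging reduces to the member", {
  sim <- make_test_sim()
  fit <- occu_fit(sim$matrix, sim$covariates, psi_terms = "forest_d")
  set <- confidence_set(rank_models(list(fit)), 2)
  avg <- model_average(set, terms = "occupancy:forest_d")
  expect_equal(avg$estimate, coef(fit)[["psi_forest_d"]], tolerance = 1e-12)
  expect_equal(avg$std.error,
               sqrt(vcov(fit)["psi_forest_d", "psi_forest_d"]),
               tolerance = 1e-12)
  pr_set <- average_predictions(set, newdata = data.frame(forest_d = 0.7),
                                quantity = "psi")
  pr_fit <- predict(fit, newdata = data.frame(forest_d = 0.7),
                    quantity = "psi")
  expect_equal(pr_set$estimate, pr_fit$estimate, tolerance = 1e-10)
  expect_equal(pr_set$lower, pr_fit$lower, tolerance = 1e-8)
  expect_equal(pr_set$upper, pr_fit$upper, tolerance = 1e-8)
})

test_that("averaged predictions are convex combinations of members", {
  sim <- make_test_sim()
  set <- fit_models(enumerate_model_specs(c("forest_d", "past"), "forest_d"),
                    sim$matrix, sim$covariates)
  cs <- confidence_set(set, threshold = Inf)
  nd <- data.frame(forest_d = 1, past = -1)
  avg <- average_predictions(cs, newdata = nd, quantity = "psi")
  members <- vapply(cs$fit, function(f) {
    use <- nd[intersect(names(nd), f$psi_terms)]
    predict(f, newdata = use, quantity = "psi")$estimate
  }, numeric(1))
  expect_gte(avg$estimate, min(members))
  expect_lte(avg$estimate, max(members))
  expect_true(avg$lower <= avg$estimate && avg$estimate <= avg$upper)
})

test_that("a dominant model controls the average", {
  sim <- make_test_sim()
  f <- occu_fit(sim$matrix, sim$covariates, psi_terms = "forest_d")
  f1 <- f; f1$aicc <- 100; f1$label <- "best"
  f2 <- f; f2$aicc <- 115; f2$label <- "far"
  set <- confidence_set(rank_models(list(f1, f2)), threshold = Inf)
  avg <- model_average(set, terms = "occupancy:forest_d")
  b <- coef(f)[["psi_forest_d"]]
  se <- sqrt(vcov(f)["psi_forest_d", "psi_forest_d"])
  expect_lt(abs(avg$estimate - b), 0.01 * se)
})

test_that("model tables round-trip through CSV", {
  sim <- make_test_sim()
  set <- fit_models(enumerate_model_specs("forest_d", character()),
                    sim$matrix, sim$covariates)
  path <- withr::local_tempfile(fileext = ".csv")
  write_model_table(set, path)
  back <- read_model_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tidy(set)),
               tolerance = 1e-12)
})
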