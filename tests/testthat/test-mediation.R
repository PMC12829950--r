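# Simple mediation world on plain columns (no cohort machinery): the
# module accepts any complete table.
sim_mediation <- function(n, a, b, cp, seed, sd_m = 1, sd_y = 1) {
  set.seed(seed)
  x <- rnorm(n)
  m <- a * x + rnorm(n, 0, sd_m)
  y <- cp * x + b * m + rnorm(n, 0, sd_y)
  data.frame(x = x, m = m, y = y, z1 = rnorm(n), z2 = rbinom(n, 1, 0.4))
}

test_that("mediation_spec enforces its invariants", {
  expect_error(mediation_spec("x", "m", "y", covariates = c("x")), "exposure")
  expect_error(mediation_spec("x", "m", "y", covariates = c("m")), "mediator")
  expect_error(mediation_spec("x", "m", "y", covariates = "z1", n_boot = 0),
               "n_boot")
  expect_error(mediation_spec("x", "m", "y", covariates = "z1", ci_level = 1),
               "ci_level")
})

test_that("the difference method equals product-of-coefficients exactly", {
  # nested-OLS identity: holds on *any* data with shared covariates
  for (seed in 1:5) {
    d <- sim_mediation(80, a = runif(1, -1, 1), b = runif(1, -1, 1),
                       cp = runif(1, -1, 1), seed = seed)
    sp <- mediation_spec("x", "m", "y", covariates = c("z1", "z2"),
                         n_boot = 1, seed = 1)
    e <- indirect_effect(fit_three_models(d, sp))
    expect_equal(e$indirect_effect, e$path_a * e$path_b, tolerance = 1e-8)
    expect_equal(e$total_effect, e$direct_effect + e$indirect_effect,
                 tolerance = 1e-10)
  }
})

test_that("planted coefficients are recovered and a = 0 gives c == c'", {
  d <- sim_mediation(5000, a = 0.5, b = 0.8, cp = 0.2, seed = 7,
                     sd_m = sqrt(1 - 0.25), sd_y = 0.4)
  sp <- mediation_spec("x", "m", "y", covariates = character(0),
                       n_boot = 1, seed = 1)
  e <- indirect_effect(fit_three_models(d, sp))
  expect_lt(abs(e$path_a - 0.5), 0.03)
  expect_lt(abs(e$path_b - 0.8), 0.03)
  expect_lt(abs(e$direct_effect - 0.2), 0.03)

  d0 <- sim_mediation(3000, a = 0, b = 0.8, cp = 0.3, seed = 8)
  e0 <- indirect_effect(fit_three_models(d0, sp))
  expect_lt(abs(e0$total_effect - e0$direct_effect), 0.05)

  db <- sim_mediation(3000, a = 0.5, b = 0, cp = 0.3, seed = 9)
  eb <- indirect_effect(fit_three_models(db, sp))
  expect_lt(abs(eb$indirect_effect), 0.05)
})

test_that("rank deficiency is reported with the collinear columns", {
  d <- sim_mediation(60, 0.5, 0.5, 0.2, seed = 10)
  d$x2 <- d$x
  sp <- mediation_spec("x", "m", "y", covariates = c("x2"), n_boot = 1, seed = 1)
  expect_error(fit_three_models(d, sp), "x2")
})

test_that("nonlinear terms collapse to the linear estimand when inactive", {
  d <- sim_mediation(400, 0.5, 0.6, 0.2, seed = 11)
  sp_lin <- mediation_spec("x", "m", "y", covariates = "z1", n_boot = 1, seed = 1)
  sp_non <- mediation_spec("x", "m", "y", covariates = "z1", n_boot = 1,
                           seed = 1, include_square = TRUE,
                           include_interaction = TRUE)
  e_lin <- indirect_effect(fit_three_models(d, sp_lin))
  e_non <- indirect_effect(fit_three_models(d, sp_non))
  # same data, inactive curvature: estimands agree up to estimation noise
  expect_equal(e_non$indirect_effect, e_lin$indirect_effect, tolerance = 0.1)

  # APD equals the coefficient exactly in the linear model
  m_lin <- fit_three_models(d, sp_lin)
  e <- indirect_effect(m_lin)
  expect_equal(e$total_effect, unname(m_lin$model1$coef["x"]), tolerance = 1e-10)
})

test_that("inconsistent mediation reports a ratio above 1 with the flag", {
  # direct and indirect of opposite signs, |indirect| > |total|
  d <- sim_mediation(4000, a = 0.7, b = 0.8, cp = -0.3, seed = 12,
                     sd_m = 0.5, sd_y = 0.5)
  sp <- mediation_spec("x", "m", "y", covariates = character(0),
                       n_boot = 1, seed = 1)
  e <- indirect_effect(fit_three_models(d, sp))
  expect_gt(e$mediation_ratio, 1)
  expect_true(e$ratio_over_100)
})

test_that("bias-correction arithmetic follows the stated formulas", {
  # half of the replicates below the estimate -> z0 = 0, percentile CI
  boot <- c(seq(-1, -0.01, length.out = 50), seq(0.01, 1, length.out = 50))
  bc <- hfpefmed:::bc_interval(boot, 0, 0.95)
  expect_equal(bc$z0, 0)
  expect_equal(bc$probs, c(0.025, 0.975))
  expect_equal(bc$ci, unname(quantile(boot, c(0.025, 0.975))))

  # fraction below = 0.6 -> z0 = qnorm(0.6) ~ 0.2533, shifted percentiles
  boot2 <- seq(0, 1, length.out = 1000)
  point <- 0.6 - 1e-9
  bc2 <- hfpefmed:::bc_interval(boot2, point, 0.95)
  expect_equal(bc2$z0, qnorm(0.6), tolerance = 1e-3)
  expect_equal(bc2$probs, pnorm(2 * qnorm(0.6) + qnorm(c(0.025, 0.975))),
               tolerance = 1e-3)
})

test_that("bootstrap CI is seed-deterministic and sign-equivariant", {
  d <- sim_mediation(200, 0.5, 0.6, 0.2, seed = 13)
  sp <- mediation_spec("x", "m", "y", covariates = "z1", n_boot = 100, seed = 99)
  r1 <- bootstrap_ci(d, sp)
  r2 <- bootstrap_ci(d, sp)
  expect_identical(r1[c("ci_lower", "ci_upper", "indirect_effect")],
                   r2[c("ci_lower", "ci_upper", "indirect_effect")])

  dneg <- d; dneg$y <- -d$y
  rn <- bootstrap_ci(dneg, sp)
  expect_equal(rn$ci_lower, -r1$ci_upper, tolerance = 1e-10)
  expect_equal(rn$ci_upper, -r1$ci_lower, tolerance = 1e-10)
  expect_equal(rn$indirect_effect, -r1$indirect_effect, tolerance = 1e-12)
})

test_that("run_grid produces one bookkept cell per subtype x exposure x outcome", {
  gen <- toy_cohort(n = 240, seed = 14)
  tbl <- gen$cohort
  w <- capture_warnings(run_grid(tbl, gen$truth$true_labels, exposures = "eGFR",
                                 outcomes = "GWW", n_boot = 5, seed = 3))
  expect_true(any(grepl("RD", w)))
  grid <- suppressWarnings(
    run_grid(tbl, gen$truth$true_labels,
             exposures = c("eGFR", "BNP"), outcomes = c("GWW", "GWE"),
             n_boot = 50, seed = 3))
  expect_equal(nrow(grid$results), 8)
  expect_true(all(is.finite(grid$results$ci_lower)))
  expect_true(all(grid$results$n > 0))
  expect_equal(dim(grid$indirect_matrix), c(4, 2))

  # a subtype too small for the covariate set is skipped with a reason
  small <- tbl[c(which(gen$truth$true_labels == 0),
                 which(gen$truth$true_labels == 1)[1:5]), ]
  lab_small <- c(rep(0, sum(gen$truth$true_labels == 0)), rep(1, 5))
  g2 <- suppressWarnings(run_grid(small, lab_small, exposures = "BNP",
                                  outcomes = "GWW", n_boot = 20, seed = 4))
  expect_true(!is.null(g2$skipped))
  expect_match(g2$skipped$reason[1], "n=5")
})
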