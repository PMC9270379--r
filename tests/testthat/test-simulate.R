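test_that("ANOVA-structure simulator honours its degenerate and seed contracts", {
  tab <- simulate_anova_trial(g = 43, e = 4, r = 3, seed = 5)
  expect_equal(nrow(tab), 516L)
  expect_true(design_of(tab)$balanced)

  flat <- simulate_anova_trial(g = 4, e = 3, r = 2, grand_mean = 100,
                               sd_environment = 0, sd_genotype = 0,
                               sd_gxe = 0, sd_rep_within_env = 0,
                               sd_residual = 0, seed = 1)
  expect_equal(flat$yield, rep(100, 24))

  a <- simulate_anova_trial(g = 8, e = 5, r = 3, seed = 7)
  b <- simulate_anova_trial(g = 8, e = 5, r = 3, seed = 7)
  expect_identical(a$yield, b$yield)
  expect_false(identical(
    a$yield, simulate_anova_trial(g = 8, e = 5, r = 3, seed = 8)$yield))

  expect_error(simulate_anova_trial(g = 0, e = 4, r = 3), "g >= 1")
})

test_that("factor substreams are independent: resizing one factor leaves others' draws alone", {
  a <- simulate_anova_trial(g = 6, e = 4, r = 3, seed = 11)
  b <- simulate_anova_trial(g = 6, e = 4, r = 3, sd_genotype = 50,
                            seed = 11)
  # genotype effects change scale, environment effects are untouched
  expect_identical(attr(a, "true_effects")$environment,
                   attr(b, "true_effects")$environment)
  expect_identical(attr(a, "true_effects")$gxe, attr(b, "true_effects")$gxe)
  expect_equal(attr(b, "true_effects")$genotype,
               attr(a, "true_effects")$genotype * 5)
})

test_that("strong simulated GxE is detected by the joint ANOVA F test", {
  # power check: with sd_gxe = 30 against sd_residual = 5 the interaction
  # F test at alpha = 0.001 should reject essentially always
  rejections <- vapply(1:200, function(s) {
    tab <- simulate_anova_trial(g = 43, e = 4, r = 3, sd_gxe = 30,
                                sd_residual = 5, seed = 1000 + s)
    an <- joint_anova(tab)
    an$p[an$factor == "Genotypes x Environment (GxE)"] < 0.001
  }, logical(1))
  expect_gt(mean(rejections), 0.95)
})

test_that("bisegmented simulator reproduces hand-computed cell means", {
  # sigma = 0, beta = (100, 1, 0), I = (-2, -1, 1, 2): Ibar+ = 1.5 so
  # T = (0, 0, -0.5, 0.5), and with beta2 = 0 the means are 100 + I
  tab <- simulate_biseg_trial(cbind(100, 1, 0), index = c(-2, -1, 1, 2),
                              sigma = 0, r = 2, seed = 1)
  cm <- cell_means(tab)
  expect_equal(unname(cm["G01", c("E1", "E2", "E3", "E4")]),
               c(98, 99, 101, 102))
  # with beta2 = 1 the hinge contributes T: (98, 99, 100.5, 102.5)
  tab2 <- simulate_biseg_trial(cbind(100, 1, 1), index = c(-2, -1, 1, 2),
                               sigma = 0, r = 2, seed = 1)
  expect_equal(unname(cell_means(tab2)["G01", c("E1", "E2", "E3", "E4")]),
               c(98, 99, 100.5, 102.5))

  expect_error(simulate_biseg_trial(cbind(100, 1), c(-1, 1)),
               "three columns")
  expect_error(simulate_biseg_trial(cbind(100, 1, 0), c(0, 0, 0)),
               "positive")
  expect_warning(simulate_biseg_trial(cbind(100, 1, 0), c(-1, 3),
                                      sigma = 0, r = 2), "sum to zero")
})

test_that("with beta2 = 0 the single-slope and bisegmented fits coincide", {
  tab <- simulate_biseg_trial(cbind(c(100, 90), c(1.2, 0.7), c(0, 0)),
                              index = c(-4, -2, 2, 4), sigma = 0, r = 3,
                              seed = 2)
  des <- design_from_index(c(-4, -2, 2, 4))
  ff <- suppressWarnings(frequentist_fit(tab, des))  # perfect fit
  expect_equal(ff$estimates$beta2, c(0, 0), tolerance = 1e-8)
  expect_equal(ff$estimates$beta1, c(1.2, 0.7), tolerance = 1e-8)
  expect_equal(ff$estimates$r_squared, c(1, 1), tolerance = 1e-10)
})

test_that("same seed gives bit-identical bisegmented tables", {
  beta <- cbind(c(100, 105), c(0.8, 1.1), c(0.2, -0.3))
  a <- simulate_biseg_trial(beta, c(-3, -1, 1, 3), sigma = 4, r = 3,
                            seed = 21)
  b <- simulate_biseg_trial(beta, c(-3, -1, 1, 3), sigma = 4, r = 3,
                            seed = 21)
  expect_identical(a$yield, b$yield)
})

test_that("empirical variance components of a large simulation approach their targets", {
  tab <- simulate_anova_trial(g = 200, e = 40, r = 10, grand_mean = 100,
                              sd_environment = 15, sd_genotype = 10,
                              sd_gxe = 5, sd_rep_within_env = 2,
                              sd_residual = 8, seed = 31)
  an <- joint_anova(tab)
  ms <- function(f) an$ms[an$factor == f]
  msr <- attr(an, "msr")
  d <- design_of(tab)
  # method-of-moments components from the fixed-effects mean squares
  vc_env <- (ms("Environment (E)") - msr) / (d$g * d$r)
  vc_gen <- (ms("Genotypes (G)") - msr) / (d$e * d$r)
  vc_gxe <- (ms("Genotypes x Environment (GxE)") - msr) / d$r
  # high-df components converge within 5% at this size
  expect_lt(abs(msr - 8^2) / 8^2, 0.05)
  expect_lt(abs(vc_gxe - 5^2) / 5^2, 0.05)
  # few-level factors converge at their own chi-square rate: 3-sigma bands
  expect_lt(abs(vc_gen - 10^2) / 10^2, 3 * sqrt(2 / (d$g - 1)))
  expect_lt(abs(vc_env - 15^2) / 15^2, 3 * sqrt(2 / (d$e - 1)))
})
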