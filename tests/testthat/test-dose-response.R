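test_that("viability equation matches hand arithmetic and is affine-invariant", {
  expect_equal(percent_viability(0.90, 0.90, 0.05), 100)
  expect_equal(percent_viability(0.05, 0.90, 0.05), 0)
  expect_equal(percent_viability(0.45, 0.90, 0.05), 100 * 0.40 / 0.85,
               tolerance = 1e-12)
  expect_error(percent_viability(0.4, 0.05, 0.06), "non-positive")
  # scaling every absorbance by c > 0 leaves viability unchanged
  set.seed(41)
  for (rep in 1:20) {
    tr <- runif(1, 0.1, 1); ctl <- runif(1, 0.5, 1.5); bl <- runif(1, 0, 0.08)
    cc <- runif(1, 0.5, 3)
    expect_equal(percent_viability(cc * tr, cc * ctl, cc * bl),
                 percent_viability(tr, ctl, bl), tolerance = 1e-9)
  }
})

test_that("plate tables convert to per-well viability", {
  pl <- gen_mtt(mtt_scenario("C_ORI", noise_sd = 0), seed = 1)
  vb <- plate_viability(pl)
  expect_setequal(unique(vb$dose), c(0, 25, 50, 100, 200, 400))
  expect_equal(vb$viability[vb$dose == 0], rep(100, 4), tolerance = 1e-9)
  expect_equal(unique(vb$viability[vb$dose == 400]),
               fourpl(400, 100, 0, 114.9, 1.5), tolerance = 1e-9)
  expect_error(plate_viability(pl[pl$role != "blank", ]), "blank")
  expect_error(plate_viability(data.frame(x = 1)), "missing column")
})

test_that("noiseless 4PL data round-trips to the true parameters", {
  d <- expand.grid(dose = c(0, 12.5, 25, 50, 100, 200, 400), rep = 1:2)
  d$viability <- fourpl(d$dose, 100, 0, 50, 1.5)
  fit <- fit_4pl(viability ~ dose, d, boot = 0)
  expect_true(fit$converged)
  co <- coef(fit)
  expect_equal(co[["top"]], 100, tolerance = 1e-6)
  expect_equal(co[["ic50"]], 50, tolerance = 1e-6)
  expect_equal(co[["hill"]], 1.5, tolerance = 1e-6)
  expect_lt(abs(co[["bottom"]]), 1e-4)
  expect_equal(fit$ic50_abs, 50, tolerance = 1e-6)
  expect_true(fit$ic50_in_range)
  # residuals and fitted are consistent
  expect_equal(fitted(fit) + residuals(fit), d$viability, tolerance = 1e-9)
  expect_equal(predict(fit, data.frame(dose = 50)), 50, tolerance = 1e-5)
})

test_that("flat viability raises the no-inhibition flag", {
  vb <- plate_viability(gen_flat_scenario(seed = 2))
  fit <- fit_4pl(viability ~ dose, vb)
  expect_true(fit$no_inhibition)
  expect_false(fit$converged)
  expect_true(all(is.na(coef(fit))))
  expect_error(predict(fit), "non-converged")
  expect_output(print(fit), "NO INHIBITION")
})

test_that("fit_4pl validates its design", {
  d <- data.frame(dose = c(0, 10, 20), viability = c(100, 60, 30))
  expect_error(fit_4pl(viability ~ dose, d), "4 distinct doses")
  d2 <- data.frame(dose = c(0, 1, 2, 4, -1), viability = 1:5)
  expect_error(fit_4pl(viability ~ dose, d2), "non-negative")
})

test_that("IC50 estimation is calibrated at the peptide monotherapy scenario", {
  # 100 seeded plates at the study design; the reported IC50 is the dose at
  # 50% viability from each fitted curve
  ic <- vapply(1:100, function(s) {
    vb <- plate_viability(gen_mtt(mtt_scenario("C_ORI"), seed = s))
    fit_4pl(viability ~ dose, vb, boot = 0)$ic50_abs
  }, numeric(1))
  expect_lt(abs(stats::median(ic) - 114.9) / 114.9, 0.02)
  # noise-propagated SD oracle: delta-method at the true parameters
  truth <- c(top = 100, bottom = 0, ic50 = 114.9, hill = 1.5)
  dose <- rep(c(0, 25, 50, 100, 200, 400), each = 4)
  grad_f <- function(p, d) fourpl(d, p[1], p[2], p[3], p[4])
  J <- sapply(seq_along(truth), function(j) {
    h <- truth; h[j] <- h[j] + 1e-6
    (grad_f(h, dose) - grad_f(truth, dose)) / 1e-6
  })
  Vp <- 25 * solve(crossprod(J))  # sigma^2 (J'J)^-1, sigma = 5 points
  g <- sapply(seq_along(truth), function(j) {
    h <- truth; h[j] <- h[j] + 1e-6
    (absolute_ic50(setNames(h, names(truth))) -
       absolute_ic50(truth)) / 1e-6
  })
  nominal_sd <- sqrt(drop(t(g) %*% Vp %*% g))
  expect_lt(stats::sd(ic), 3 * nominal_sd)
})

test_that("bootstrap SD accompanies the IC50 and simulate() regenerates data", {
  vb <- plate_viability(gen_mtt(mtt_scenario("C_ORI"), seed = 5))
  fit <- fit_4pl(viability ~ dose, vb, boot = 99)
  expect_true(is.finite(fit$ic50_sd_boot) && fit$ic50_sd_boot > 0)
  expect_true(is.finite(fit$ic50_abs_sd_boot))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(vb), 4L))
  expect_equal(sims$dose, vb$dose)
  # bootstrap is seeded: identical refit gives identical SD
  fit2 <- fit_4pl(viability ~ dose, vb, boot = 99)
  expect_identical(fit$ic50_sd_boot, fit2$ic50_sd_boot)
  # summary and confint expose curvature-based uncertainty
  expect_output(print(summary(fit)), "Std. Error")
  ci <- confint(fit, "ic50")
  expect_lt(ci[1], coef(fit)[["ic50"]])
  expect_gt(ci[2], coef(fit)[["ic50"]])
})

test_that("ANOVA + Dunnett flags separate conditions correctly", {
  # identical conditions: nothing significant
  set.seed(43)
  same <- data.frame(condition = rep(c("control", "t1"), each = 6),
                     viability = rnorm(12, 100, 3))
  cc <- compare_conditions(same)
  expect_gt(cc$dunnett$p_adjusted[1], 0.05)
  expect_equal(cc$dunnett$flag[1], "")

  # control ~N(100,1) vs treated ~N(50,1): decisively significant
  set.seed(44)
  strong <- data.frame(
    condition = rep(c("control", "treated"), each = 4),
    viability = c(rnorm(4, 100, 1), rnorm(4, 50, 1)))
  cs <- compare_conditions(strong)
  expect_lt(cs$dunnett$p_adjusted[1], 0.01)
  expect_equal(cs$dunnett$flag[1], "**")
  expect_lt(cs$dunnett$estimate[1], 0)

  # adjusted p never smaller than raw p
  set.seed(45)
  multi <- data.frame(
    condition = rep(c("control", "a", "b", "c"), each = 4),
    viability = rnorm(16, 100, 5) - rep(c(0, 3, 6, 9), each = 4))
  cm <- compare_conditions(multi)
  expect_true(all(cm$dunnett$p_adjusted >= cm$dunnett$p_raw - 1e-12))
  expect_equal(nrow(cm$dunnett), 3L)

  expect_error(compare_conditions(data.frame(
    condition = c("control", "control", "t"), viability = c(1, 2, 3))),
    "replicates")
  expect_error(compare_conditions(same, control = "nope"), "not found")
})

test_that("combination grids compare cells against margins and control", {
  grid_data <- function(effect, seed = NULL) {
    cells <- rbind(
      data.frame(dose_a = 0, dose_b = 0, mu = 100),
      data.frame(dose_a = 200, dose_b = 0, mu = 70),
      data.frame(dose_a = 0, dose_b = 0.125, mu = 70),
      data.frame(dose_a = 200, dose_b = 0.125, mu = 70 - effect))
    if (!is.null(seed)) set.seed(seed)
    do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
      data.frame(dose_a = cells$dose_a[i], dose_b = cells$dose_b[i],
                 viability = if (is.null(seed))
                   cells$mu[i] + c(-1, 0, 1, 0) else
                   rnorm(4, cells$mu[i], 2))))
  }
  # combo replicates literally equal to both margins: estimate 0, p ~ 1
  # (the degenerate zero contrasts make the mvt integration warn; harmless)
  eq <- suppressWarnings(combination_analysis(grid_data(0)))
  margin_rows <- eq$comparisons$reference != "0|0"
  expect_true(all(eq$comparisons$p_adjusted[margin_rows] > 0.9))
  expect_true(all(abs(eq$comparisons$estimate[margin_rows]) < 1e-9))

  # combo 10 points below margins: significantly lower viability
  lower <- combination_analysis(grid_data(10, 47))
  lr <- lower$comparisons[margin_rows, ]
  expect_true(all(lr$p_adjusted < 0.05))
  expect_true(all(lr$direction == "lower viability"))

  # per-cell summaries carry mean, sd, n
  expect_equal(nrow(eq$cells), 4L)
  expect_true(all(eq$cells$n == 4L))

  incomplete <- grid_data(0, 48)
  incomplete <- incomplete[!(incomplete$dose_a == 200 &
                               incomplete$dose_b == 0), ]
  expect_error(combination_analysis(incomplete), "margin")
})
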