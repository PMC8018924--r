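test_that("noise-free single-state data recover every variant exactly", {
  for (variant in c("1-par", "2-par", "2-par-I", "3-par", "water-3-par-q")) {
    dat <- gen_for(variant, seed = 42)
    fit <- fit_correction(training_rows(dat),
                          variant, phase = dat$truth$phase)
    truth <- dat$truth
    for (nm in c("c_mu", "c_V", "c_q", "d")) {
      expect_lt(abs(fit$params[[nm]] - truth[[nm]]), 1e-8, label = paste(variant, nm))
    }
    expect_lt(fit$rmse, 1e-8)
  }
})

test_that("zero-signal data drive the volume coefficient to zero", {
  dat <- gen_for("1-par", seed = 8)
  rows <- training_rows(dat)
  rows$dG_ref <- rows$E_sol - rows$E_gas + rows$mu_ex  # exactly the 1-par model with c_V = 0
  fit <- fit_correction(rows, "1-par")
  expect_lt(abs(fit$params$c_V), 1e-10)
})

test_that("nested variants have monotone training RMSE", {
  dat <- gen_for("3-par", n = 60, noise = 1.0, seed = 5)
  rows <- training_rows(dat)
  r1 <- fit_correction(rows, "1-par")$rmse
  r2i <- fit_correction(rows, "2-par-I")$rmse
  r3 <- fit_correction(rows, "3-par")$rmse
  expect_lte(r3, r2i + 1e-12)
  expect_lte(r2i, r1 + 1e-12)
})

test_that("degenerate designs fail loudly", {
  dat <- gen_for("3-par", n = 10, seed = 3)
  rows <- training_rows(dat)
  expect_error(fit_correction(rows[1:2, ], "3-par"), "fewer records")
  flat <- rows; flat$V_m <- 100
  expect_error(fit_correction(flat, "3-par"), "V_m")
  noq <- rows  # all-neutral set cannot identify a charge coefficient
  expect_error(fit_correction(noq, "water-3-par-q", phase = "cyclohexane"), "q")
  expect_error(fit_correction(rows[, setdiff(names(rows), "mu_ex")], "3-par"),
               "missing column")
})

test_that("OLS residuals are orthogonal to each free-parameter column", {
  dat <- gen_for("3-par", n = 50, noise = 0.7, seed = 9)
  fit <- fit_correction(training_rows(dat), "3-par")
  dots <- crossprod(fit$residual_cols, fit$residuals)
  expect_true(all(abs(dots) < 1e-8 * nrow(fit$residual_cols)))
})

test_that("the fit is invariant to row order and dataset duplication", {
  dat <- gen_for("2-par-I", n = 30, noise = 0.4, seed = 10)
  rows <- training_rows(dat)
  f0 <- fit_correction(rows, "2-par-I")
  f_perm <- fit_correction(rows[sample(nrow(rows)), ], "2-par-I")
  f_dup <- fit_correction(rbind(rows, rows), "2-par-I")
  expect_equal(f_perm$params$c_V, f0$params$c_V, tolerance = 1e-10)
  expect_equal(f_dup$params$c_V, f0$params$c_V, tolerance = 1e-10)
  expect_equal(f_dup$params$d, f0$params$d, tolerance = 1e-10)
  expect_equal(f_dup$rmse, f0$rmse, tolerance = 1e-10)
})

test_that("pKa calibration interpolates exact affine data", {
  dg <- c(-3, 0, 2, 5, 9)
  fit <- fit_pka(dg, 0.7 * dg + 2)
  expect_equal(fit$params$a, 0.7, tolerance = 1e-10)
  expect_equal(fit$params$b, 2, tolerance = 1e-10)
  expect_lt(fit$rmse, 1e-10)

  two <- fit_pka(c(0, 4), c(1, 3))  # exact line through two points
  expect_equal(two$params$a, 0.5, tolerance = 1e-12)
  expect_equal(two$params$b, 1, tolerance = 1e-12)

  expect_error(fit_pka(c(1, 1, 1), c(2, 3, 4)), "all dG_deprot values equal")
  expect_error(fit_pka(1, 2), "at least 2")
})

test_that("pKa calibration recovers generator ground truth", {
  cfg <- generator_config(n_compounds = 60, noise_sd = 0, seed = 14)
  tit <- generate_titratable(cfg)
  tit <- tit[tit$site_type != "none", ]
  fit <- fit_pka(tit$dG_deprot_obs, tit$pka_true)
  expect_lt(abs(fit$params$a - cfg$true_pka_params$a), 1e-8)
  expect_lt(abs(fit$params$b - cfg$true_pka_params$b), 1e-8)
})

test_that("ensemble-aware fit reduces to the linear fit for one-state species", {
  dat <- gen_for("3-par", n = 25, noise = 0.3, seed = 16)
  lin <- fit_correction(training_rows(dat), "3-par")
  ens <- fit_correction_ensemble(dat$states, dat$reference, "3-par")
  for (nm in c("c_mu", "c_V", "d")) {
    expect_lt(abs(ens$params[[nm]] - lin$params[[nm]]), 1e-8, label = nm)
  }
})

test_that("ensemble-aware fit recovers parameters from multi-conformer data", {
  cfg <- generator_config(n_compounds = 40,
                          tautomers_per_compound = c(1L, 2L),
                          conformers_per_state = c(2L, 4L),
                          true_params = truth_for("3-par"),
                          noise_sd = 0, seed = 17)
  dat <- generate_states(cfg)
  fit <- fit_correction_ensemble(dat$states, dat$reference, "3-par")
  for (nm in c("c_mu", "c_V", "d")) {
    expect_lt(abs(fit$params[[nm]] - dat$truth[[nm]]), 1e-6, label = nm)
  }
  # starting at the truth converges immediately
  at_truth <- fit_correction_ensemble(
    dat$states, dat$reference, "3-par",
    init = c(c_mu = dat$truth$c_mu, c_V = dat$truth$c_V, d = dat$truth$d))
  expect_lte(at_truth$iterations, 2L)
})

test_that("parameter recovery is unbiased with noise shrinking as 1/sqrt(n)", {
  est <- function(n, reps, seed0) {
    vapply(seq_len(reps), function(r) {
      dat <- gen_for("3-par", n = n, noise = 0.5, seed = seed0 + r)
      fit_correction(training_rows(dat), "3-par")$params$c_V
    }, numeric(1))
  }
  e50 <- est(50, 60, 1000)
  e500 <- est(500, 60, 2000)
  truth <- truth_for("3-par")$c_V
  # bias indistinguishable from zero at the Monte-Carlo resolution
  expect_lt(abs(mean(e500) - truth), 3 * stats::sd(e500) / sqrt(length(e500)))
  rmse50 <- sqrt(mean((e50 - truth)^2))
  rmse500 <- sqrt(mean((e500 - truth)^2))
  ratio <- rmse50 / rmse500
  expect_gt(ratio, sqrt(10) * 0.6)  # expected sqrt(500/50) ~ 3.16
  expect_lt(ratio, sqrt(10) * 1.6)
})

test_that("fitted parameters round-trip through the plain-text config", {
  p <- truth_for("3-par")
  q <- correction_params("2-par-I", c_V = -0.109, d = -1.66, phase = "cyclohexane")
  path <- withr::local_tempfile(fileext = ".cfg")
  write_correction_config(p, path)
  write_correction_config(q, path)
  back <- read_correction_config(path)
  expect_named(back, c("cyclohexane/3-par", "cyclohexane/2-par-I"))
  expect_equal(back[["cyclohexane/3-par"]]$c_mu, p$c_mu)
  expect_equal(back[["cyclohexane/2-par-I"]]$d, q$d)
})
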