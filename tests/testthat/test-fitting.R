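test_that("rate constants follow from k_ex and p_A exactly", {
  rc <- derive_rate_constants(286, 0.942)
  expect_equal(round(rc$k_ab), 17)
  expect_equal(round(rc$k_ba), 269)
  rc <- derive_rate_constants(146, 0.930)
  expect_equal(round(rc$k_ab), 10)
  expect_equal(round(rc$k_ba), 136)
  rc <- derive_rate_constants(273, 0.944)
  expect_equal(round(rc$k_ab), 15)
  expect_equal(round(rc$k_ba), 258)
  # conservation is exact, and the degenerate case is handled
  set.seed(2)
  k <- runif(20, 0, 5000); p <- runif(20, 0, 1)
  rc <- derive_rate_constants(k, p)
  expect_identical(rc$k_ab + rc$k_ba, k)
  expect_equal(derive_rate_constants(100, 1), list(k_ab = 0, k_ba = 100))
})

test_that("the published-table audit finds the one inconsistent cell", {
  chk <- table1_check()
  expect_true(all(chk$k_ab_consistent))
  expect_equal(chk$k_ba_consistent, c(TRUE, FALSE, TRUE, TRUE))
  # the inconsistent cell: printed 254 vs k_ex * p_A = 258.3
  expect_equal(chk$k_ba[chk$state == "indole"], 287 * 0.9)
})

test_that("flat fits recover the weighted mean with unit reduced chi-square", {
  curves <- make_curves(delta_delta = 0, r2_0 = c(`600` = 14, `850` = 16),
                        noise = 0.3, sigma = 0.3, seed = 4)
  f <- fit_flat(curves)
  for (fld in c("600", "850")) {
    b <- curves[curves$field_mhz == as.numeric(fld), ]
    expect_equal(f$r2_0[[fld]], sum(b$r2_eff / b$sigma^2) / sum(1 / b$sigma^2))
  }
  expect_gt(f$chi2_reduced, 0.3)
  expect_lt(f$chi2_reduced, 2.5)
  # a dispersive curve is a terrible flat fit
  disp <- make_curves(noise = 0.3, sigma = 0.3, seed = 5)
  expect_gt(fit_flat(disp)$chi2_reduced, 10)
  # single-field input gives a single-field answer
  one <- curves[curves$field_mhz == 600, ]
  expect_named(fit_flat(one)$r2_0, "600")
})

test_that("noiseless two-site curves are recovered to optimizer precision", {
  curves <- make_curves(k_ex = 273, p_a = 0.944, delta_delta = 2.5,
                        noise = 0, sigma = 0.3)
  fit <- fit_residue_two_site(curves)
  expect_true(fit$converged)
  expect_equal(fit$k_ex, 273, tolerance = 1e-3)
  expect_equal(fit$p_a, 0.944, tolerance = 1e-3)
  expect_equal(fit$delta_delta, 2.5, tolerance = 1e-3)
  expect_equal(unname(fit$r2_0), c(14, 16), tolerance = 1e-3)
})

test_that("model selection prefers flat on flat data and obeys alpha", {
  flat_data <- make_curves(delta_delta = 0, noise = 0.3, sigma = 0.3,
                           seed = 8)
  flat <- fit_flat(flat_data)
  two <- fit_residue_two_site(flat_data)
  sel <- select_model(flat, two)
  expect_identical(sel$model, "flat")
  # alpha = 1 always prefers the larger model
  expect_identical(select_model(flat, two, alpha = 1)$model, "two_site")
  # dispersive data select two-site decisively
  disp_data <- make_curves(noise = 0.3, sigma = 0.3, seed = 9)
  sel2 <- select_model(fit_flat(disp_data), fit_residue_two_site(disp_data))
  expect_identical(sel2$model, "two_site")
  expect_lt(sel2$p_value, 1e-6)
})

test_that("the F statistic matches its textbook form on constructed fits", {
  # chi-square halved by 3 extra parameters on 20 points
  mk <- function(chi2, n_par) {
    structure(list(chi2 = chi2, n_par = n_par, n_points = 20,
                   df = 20 - n_par, converged = TRUE, chi2_reduced =
                     chi2 / (20 - n_par)),
              class = "residue_fit")
  }
  sel <- select_model(mk(40, 2), mk(20, 5), alpha = 0.01)
  f_manual <- ((40 - 20) / 3) / (20 / 15)
  expect_equal(sel$f_statistic, f_manual)
  expect_equal(sel$p_value, pf(f_manual, 3, 15, lower.tail = FALSE))
  # p = 0.0134: not significant at the default 0.01, significant at 0.05
  expect_identical(sel$model, "flat")
  expect_identical(select_model(mk(40, 2), mk(20, 5), alpha = 0.05)$model,
                   "two_site")
  # identical fits: F = 0, p = 1, flat preferred
  sel0 <- select_model(mk(20, 2), mk(20, 5))
  expect_identical(sel0$model, "flat")
  expect_equal(sel0$p_value, 1)
})

test_that("classification separates fittable, broadened and quiet residues", {
  cfg <- disp_config()$fitting
  # clean dispersive curve: reliably fittable
  disp <- make_curves(noise = 0.3, sigma = 0.3, seed = 12)
  flat <- fit_flat(disp); two <- fit_residue_two_site(disp)
  sel <- select_model(flat, two)
  expect_identical(classify_residue(disp, flat, two, sel), "two_site_fittable")
  # flat curve: no exchange
  quiet <- make_curves(delta_delta = 0, noise = 0.3, sigma = 0.3, seed = 13)
  flat_q <- fit_flat(quiet); two_q <- fit_residue_two_site(quiet)
  expect_identical(
    classify_residue(quiet, flat_q, two_q, select_model(flat_q, two_q)),
    "no_exchange")
  # an intensity-flagged residue is broadened even when the curve is flat
  expect_identical(
    classify_residue(quiet, flat_q, two_q, select_model(flat_q, two_q),
                     intensity_flagged = TRUE),
    "broadened_unfittable")
  # broadened-class curves (slow exchange, large shift difference, weak
  # noisy peaks): always recognised as exchanging, mostly without a
  # trustworthy two-site parameter set
  sc <- state_scenario("s", 286, 0.942, seed = 77,
                       roster = list(two_site = integer(0), broadened = 1:8,
                                     no_exchange = integer(0)))
  broad <- generate_state_dataset(sc)$curves
  cls <- screen_residues(broad)$summary$classification
  expect_false(any(cls == "no_exchange"))
  expect_gte(sum(cls == "broadened_unfittable"), 4)
})

test_that("reported single-residue uncertainties are calibrated", {
  # the fitted k_ex should sit within 3 standard errors of truth in the
  # vast majority of noisy replicates
  hits <- 0; n_rep <- 15
  for (i in seq_len(n_rep)) {
    curves <- make_curves(k_ex = 273, p_a = 0.944, delta_delta = 2.5,
                          noise = 0, sigma = 0.35, seed = 300 + i)
    curves$r2_eff <- curves$r2_eff + rnorm(nrow(curves), 0, 0.35)
    fit <- fit_residue_two_site(curves)
    if (fit$converged && abs(fit$k_ex - 273) <= 3 * fit$se[["k_ex"]]) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, n_rep - 2)
})

test_that("elevated exchange-free rates are flagged per field", {
  tab <- data.frame(residue = rep(1:6, 2), field_mhz = rep(c(600, 850),
                                                           each = 6),
                    r2_0 = c(rep(15, 6), 15, 15, 15, 15, 15, 15))
  expect_false(any(flag_elevated_r20(tab)$r2_0_elevated))
  tab$r2_0[3] <- 15 + 3 * sd(c(rep(15, 5), 30)) # clearly above the pack
  tab$r2_0[3] <- 30
  flags <- flag_elevated_r20(tab)
  expect_true(flags$r2_0_elevated[3])
  expect_equal(sum(flags$r2_0_elevated), 1)
  # invariant to row order
  perm <- sample(nrow(tab))
  flags_p <- flag_elevated_r20(tab[perm, ])
  expect_equal(flags_p$r2_0_elevated,
               flags$r2_0_elevated[perm])
})
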