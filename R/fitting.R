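#' Forward and reverse rate constants from k_ex and p_A
#'
#' For two-site exchange A <-> B at equilibrium, detailed balance gives
#' `k_AB = k_ex * p_B` and `k_BA = k_ex * p_A`, so `k_AB + k_BA = k_ex`
#' exactly.
#'
#' @param k_ex Exchange rate constant (s^-1).
#' @param p_a Major-state population (fraction in [0, 1]).
#' @return List with `k_ab` and `k_ba` (s^-1).
#' @export
#' @examples
#' derive_rate_constants(286, 0.942)  # k_ab ~ 17, k_ba ~ 269
derive_rate_constants <- function(k_ex, p_a) {
  stopifnot(is.numeric(k_ex), all(k_ex >= 0),
            is.numeric(p_a), all(p_a >= 0), all(p_a <= 1))
  list(k_ab = k_ex * (1 - p_a), k_ba = k_ex * p_a)
}

## split one residue's rows of a dispersion table into per-field blocks,
## each sorted by nu; attaches the nitrogen Larmor frequency
.curve_blocks <- function(curves, ratio = disp_config()$model$nitrogen_proton_ratio) {
  stopifnot(all(c("field_mhz", "nu_cpmg_hz", "r2_eff", "sigma") %in% names(curves)))
  lapply(split(curves, curves$field_mhz), function(b) {
    b <- b[order(b$nu_cpmg_hz), ]
    list(field_mhz = b$field_mhz[1], n_mhz = ratio * b$field_mhz[1],
         nu = b$nu_cpmg_hz, y = b$r2_eff, sigma = b$sigma)
  })
}

#' Flat (no-exchange) null fit for one residue
#'
#' Null model: R2eff is constant in the pulsing frequency, one level per
#' field (the exchange-free rate is field-dependent). Weighted mean per
#' field and the resulting chi-square.
#'
#' @param curves Rows of a dispersion table for a single residue (both
#'   fields).
#' @return Object of class `residue_fit` with `model = "flat"`, per-field
#'   `r2_0`, `chi2`, `chi2_reduced`, `n_points`, `df`, `n_par`.
#' @export
fit_flat <- function(curves) {
  blocks <- .curve_blocks(curves)
  r2_0 <- numeric(0); chi2 <- 0; n <- 0
  for (b in blocks) {
    if (length(b$y) < 3) stop("fit_flat needs >= 3 points per field")
    w <- 1 / b$sigma^2
    m <- sum(w * b$y) / sum(w)
    r2_0[as.character(b$field_mhz)] <- m
    chi2 <- chi2 + sum(((b$y - m) / b$sigma)^2)
    n <- n + length(b$y)
  }
  df <- n - length(blocks)
  structure(list(residue = curves$residue[1], model = "flat",
                 r2_0 = r2_0, chi2 = chi2,
                 chi2_reduced = chi2 / df, n_points = n, df = df,
                 n_par = length(blocks)),
            class = "residue_fit")
}

## weighted residual vector for the two-site model;
## theta = (k_ex, p_b, delta_delta, r2_0 per field)
.two_site_residuals <- function(theta, blocks) {
  unlist(lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    pred <- .cr_r2eff(theta[1], theta[2], theta[3], theta[3 + i], b$nu, b$n_mhz)
    (b$y - pred) / b$sigma
  }), use.names = FALSE)
}

## finite-difference Jacobian of a residual function at theta
.fd_jacobian <- function(fn, theta, ...) {
  r0 <- fn(theta, ...)
  J <- matrix(NA_real_, length(r0), length(theta))
  for (j in seq_along(theta)) {
    h <- max(1e-6 * abs(theta[j]), 1e-8)
    th <- theta; th[j] <- th[j] + h
    J[, j] <- (fn(th, ...) - r0) / h
  }
  J
}

## covariance of theta at the weighted-least-squares optimum
.wls_covariance <- function(fn, theta, chi2_reduced, ...) {
  J <- .fd_jacobian(fn, theta, ...)
  jtj <- crossprod(J)
  cov <- tryCatch(solve(jtj), error = function(e) NULL)
  if (is.null(cov)) return(matrix(NA_real_, length(theta), length(theta)))
  max(chi2_reduced, 1e-12) * cov
}

## shift-difference starting guess from the observed dispersion amplitude
## via the fast-exchange relation Rex ~ p_a p_b dw^2 / k_ex
.dd_heuristic <- function(blocks, k_ex, p_b) {
  rex <- max(vapply(blocks, function(b) {
    lo <- mean(head(b$y, 2)); hi <- mean(b$y[seq(length(b$y) - 1, length(b$y))])
    lo - hi
  }, numeric(1)), 0.5)
  n_mhz <- max(vapply(blocks, `[[`, numeric(1), "n_mhz"))
  dw <- sqrt(rex * k_ex / ((1 - p_b) * p_b))
  min(max(dw / (2 * pi * n_mhz), 0.25), 8)
}

#' Two-site Carver-Richards fit for one residue
#'
#' Weighted least squares of the closed-form two-site model against one
#' residue's dispersion curves, jointly over all fields present: shared
#' `k_ex`, `p_b`, `delta_delta` (ppm, field-independent) and one
#' exchange-free `r2_0` per field. Fits use Levenberg-Marquardt with box
#' bounds and a multi-start grid over (k_ex, p_b) with a dispersion-
#' amplitude heuristic for the shift difference; the best final chi-square
#' wins, ties going to the smaller k_ex. Reported parameters follow the
#' conventions p_a >= 0.5 and delta_delta >= 0 (the sign of the shift
#' difference is not identifiable from dispersion data).
#'
#' @param curves Rows of a dispersion table for a single residue. Two
#'   fields are recommended; single-field data are accepted with a warning
#'   (p_b and delta_delta are then poorly identifiable).
#' @param config Fitting configuration, see [disp_config()].
#' @param starts `"full"` for the complete start grid, `"quick"` for a
#'   reduced grid (k_ex grid at a single p_b), or a list of numeric start
#'   vectors `c(k_ex, p_b, delta_delta)`.
#' @return Object of class `residue_fit` with `model = "two_site"`: the
#'   fitted `exchange_parameters` view (`k_ex`, `p_a`, `p_b`,
#'   `delta_delta`, per-field `r2_0`), standard errors (`se`), `chi2`,
#'   `chi2_reduced`, convergence diagnostics and the start that won. If no
#'   start converges the fit is marked `converged = FALSE`.
#' @export
fit_residue_two_site <- function(curves, config = disp_config()$fitting,
                                 starts = "full") {
  blocks <- .curve_blocks(curves)
  n_fields <- length(blocks)
  if (n_fields < 2) {
    warning("single-field data: p_b and delta_delta are poorly identifiable")
  }
  for (b in blocks) {
    if (length(b$y) < 5) warning("fewer than 5 points per field for residue ",
                                 curves$residue[1])
  }
  bounds <- config$bounds
  lower <- c(bounds$k_ex[1], bounds$p_b[1], bounds$delta_delta[1],
             rep(bounds$r2_0[1], n_fields))
  upper <- c(bounds$k_ex[2], bounds$p_b[2], bounds$delta_delta[2],
             rep(bounds$r2_0[2], n_fields))
  r2_0_start <- vapply(blocks, function(b)
    mean(b$y[seq(max(1, length(b$y) - 2), length(b$y))]), numeric(1))

  start_list <- if (is.list(starts)) {
    starts
  } else {
    grid <- expand.grid(k_ex = config$start_grid$k_ex,
                        p_b = if (identical(starts, "quick")) 0.05
                              else config$start_grid$p_b)
    lapply(seq_len(nrow(grid)), function(i) {
      k <- grid$k_ex[i]; pb <- grid$p_b[i]
      c(k, pb, .dd_heuristic(blocks, k, pb))
    })
  }

  best <- NULL
  for (s in start_list) {
    theta0 <- pmin(pmax(c(s, r2_0_start), lower), upper)
    fit <- tryCatch(
      nls.lm(par = theta0, lower = lower, upper = upper,
             fn = .two_site_residuals, blocks = blocks,
             control = nls.lm.control(maxiter = 200, ftol = 1e-12,
                                      ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    chi2 <- fit$deviance
    if (is.null(best) || chi2 < best$chi2 * (1 - 1e-8) ||
        (abs(chi2 - best$chi2) <= best$chi2 * 1e-8 + 1e-12 &&
         fit$par[1] < best$theta[1])) {
      best <- list(theta = fit$par, chi2 = chi2, start = s,
                   info = fit$info, message = fit$message)
    }
  }

  n <- sum(vapply(blocks, function(b) length(b$y), integer(1)))
  n_par <- 3 + n_fields
  if (is.null(best)) {
    return(structure(list(residue = curves$residue[1], model = "two_site",
                          converged = FALSE, n_points = n, df = n - n_par,
                          n_par = n_par, chi2 = Inf, chi2_reduced = Inf),
                     class = "residue_fit"))
  }
  best$theta <- unname(best$theta)
  df <- n - n_par
  chi2_red <- best$chi2 / max(df, 1)
  cov <- .wls_covariance(.two_site_residuals, best$theta, chi2_red,
                         blocks = blocks)
  se <- sqrt(pmax(diag(cov), 0))
  fields <- vapply(blocks, `[[`, numeric(1), "field_mhz")
  structure(list(
    residue = curves$residue[1], model = "two_site", converged = TRUE,
    k_ex = best$theta[1], p_b = best$theta[2], p_a = 1 - best$theta[2],
    delta_delta = best$theta[3],
    r2_0 = setNames(best$theta[3 + seq_len(n_fields)], fields),
    se = setNames(se, c("k_ex", "p_b", "delta_delta",
                        paste0("r2_0_", fields))),
    chi2 = best$chi2, chi2_reduced = chi2_red, n_points = n, df = df,
    n_par = n_par, start = best$start, lm_info = best$info),
    class = "residue_fit")
}

#' Model selection between the flat and two-site fits
#'
#' F-test on the weighted residual sums of squares of the nested models,
#' with `Delta df` equal to the number of extra two-site parameters; the
#' two-site model is chosen when the F-test p-value is at or below `alpha`
#' (default 0.01). AIC (chi-square + 2 * parameters, valid for comparing
#' fits on identical data and weights) is reported alongside.
#'
#' @param flat,two_site `residue_fit` objects from [fit_flat()] and
#'   [fit_residue_two_site()] on the same data.
#' @param alpha F-test level.
#' @return List with `model` ("flat"/"two_site"), `f_statistic`, `p_value`,
#'   `aic` (named vector).
#' @export
select_model <- function(flat, two_site, alpha = disp_config()$fitting$alpha) {
  stopifnot(inherits(flat, "residue_fit"), inherits(two_site, "residue_fit"),
            flat$n_points == two_site$n_points)
  aic <- c(flat = flat$chi2 + 2 * flat$n_par,
           two_site = two_site$chi2 + 2 * two_site$n_par)
  if (!isTRUE(two_site$converged)) {
    return(list(model = "flat", f_statistic = NA_real_, p_value = NA_real_,
                aic = aic))
  }
  ddf <- two_site$n_par - flat$n_par
  if (two_site$chi2 <= 0) {
    f <- Inf; p <- 0
  } else {
    f <- ((flat$chi2 - two_site$chi2) / ddf) / (two_site$chi2 / two_site$df)
    p <- pf(f, ddf, two_site$df, lower.tail = FALSE)
  }
  list(model = if (p <= alpha) "two_site" else "flat",
       f_statistic = f, p_value = p, aic = aic)
}

## robust data-based dispersion amplitude: mean of the two slowest-pulsing
## R2eff minus mean of the two fastest, maximised over fields
.observed_rex <- function(curves) {
  max(vapply(.curve_blocks(curves), function(b) {
    k <- length(b$y)
    mean(b$y[1:min(2, k)]) - mean(b$y[seq(max(1, k - 1), k)])
  }, numeric(1)))
}

#' Classify a residue's dispersion behaviour
#'
#' Three-way classification mirroring how dispersion data are reported:
#' `two_site_fittable` (curve fits reliably to two-site exchange: selected
#' two-site model, relative uncertainties on k_ex and delta_delta below
#' `max_rel_uncertainty`, reduced chi-square below `max_chi2_reduced`),
#' `broadened_unfittable` (clear exchange contribution -- observed
#' dispersion amplitude above `min_rex_amplitude` or the intensity record
#' was flagged -- but no reliable fit), else `no_exchange`.
#'
#' @param curves The residue's dispersion rows (for the data-based
#'   amplitude).
#' @param flat,two_site The two fits.
#' @param selection Output of [select_model()].
#' @param config Thresholds, see [disp_config()].
#' @param intensity_flagged TRUE if the residue had peaks broadened beyond
#'   detection in the intensity data.
#' @return Character scalar classification.
#' @export
classify_residue <- function(curves, flat, two_site, selection,
                             config = disp_config()$fitting,
                             intensity_flagged = FALSE) {
  reliable <- FALSE
  if (selection$model == "two_site" && isTRUE(two_site$converged)) {
    rel <- c(two_site$se["k_ex"] / two_site$k_ex,
             two_site$se["delta_delta"] / max(two_site$delta_delta, 1e-12))
    reliable <- all(is.finite(rel)) && all(rel < config$max_rel_uncertainty) &&
      two_site$chi2_reduced < config$max_chi2_reduced
  }
  if (reliable) return("two_site_fittable")
  dispersive <- .observed_rex(curves) > config$min_rex_amplitude
  if (dispersive || intensity_flagged) return("broadened_unfittable")
  "no_exchange"
}

#' Screen every residue of a dispersion table
#'
#' Runs the flat fit, the two-site fit, model selection and classification
#' for each residue of one state's dispersion table.
#'
#' @param dispersion Dispersion table (single state).
#' @param config Fitting configuration.
#' @param starts Start policy passed to [fit_residue_two_site()].
#' @param flagged_residues Residues with intensity records broadened beyond
#'   detection.
#' @return List with `summary` (one row per residue: classification,
#'   fitted parameters, uncertainties, chi2_reduced, F-test p) and `fits`
#'   (named list of per-residue flat/two-site fit objects).
#' @export
screen_residues <- function(dispersion, config = disp_config()$fitting,
                            starts = "full", flagged_residues = integer(0)) {
  rows <- list(); fits <- list()
  for (curves in split(dispersion, dispersion$residue)) {
    res <- curves$residue[1]
    flat <- fit_flat(curves)
    two <- fit_residue_two_site(curves, config, starts)
    sel <- select_model(flat, two, config$alpha)
    cls <- classify_residue(curves, flat, two, sel, config,
                            intensity_flagged = res %in% flagged_residues)
    fits[[as.character(res)]] <- list(flat = flat, two_site = two,
                                      selection = sel)
    rows[[length(rows) + 1L]] <- data.frame(
      residue = res, classification = cls, model = sel$model,
      k_ex = if (isTRUE(two$converged)) two$k_ex else NA_real_,
      k_ex_se = if (isTRUE(two$converged)) unname(two$se["k_ex"]) else NA_real_,
      p_b = if (isTRUE(two$converged)) two$p_b else NA_real_,
      delta_delta = if (isTRUE(two$converged)) two$delta_delta else NA_real_,
      chi2_reduced_two_site = two$chi2_reduced,
      chi2_reduced_flat = flat$chi2_reduced,
      p_value = sel$p_value, rex_observed = .observed_rex(curves))
  }
  summary <- do.call(rbind, rows)
  summary <- summary[order(summary$residue), ]
  rownames(summary) <- NULL
  list(summary = summary, fits = fits)
}

#' Flag residues with elevated exchange-free R2
#'
#' Residues whose fitted exchange-free rate sits above the mean by more
#' than `k_sd` standard deviations (per field, and per state if a `state`
#' column is present) are flagged; elevated R2_0 can indicate exchange on
#' a faster microsecond timescale than the CPMG window.
#'
#' @param r20_table Data frame with columns `residue`, `field_mhz`, `r2_0`
#'   and optionally `state`.
#' @param k_sd Flagging threshold in SD units (default 1).
#' @return Input with a logical `r2_0_elevated` column; invariant to row
#'   order.
#' @export
flag_elevated_r20 <- function(r20_table, k_sd = disp_config()$fitting$r20_flag_k_sd) {
  stopifnot(all(c("residue", "field_mhz", "r2_0") %in% names(r20_table)))
  grp <- if ("state" %in% names(r20_table)) {
    interaction(r20_table$state, r20_table$field_mhz, drop = TRUE)
  } else factor(r20_table$field_mhz)
  thr <- ave(r20_table$r2_0, grp, FUN = function(x) {
    s <- sd(x); if (!is.finite(s)) s <- 0
    mean(x) + k_sd * s
  })
  r20_table$r2_0_elevated <- r20_table$r2_0 > thr
  r20_table
}

#' Audit the printed rate-constant arithmetic of a parameter table
#'
#' Recomputes k_AB and k_BA from (k_ex, p_A) via
#' [derive_rate_constants()] and compares with printed values, flagging
#' any cell whose printed integer differs from the rounded recomputation
#' (an internal-consistency check that detects transcription errata).
#'
#' @param table Data frame with columns `state`, `k_ex`, `p_a` (fraction),
#'   `k_ab_printed`, `k_ba_printed`; defaults to [table1_parameters()].
#' @return The table augmented with `k_ab`, `k_ba` (computed, unrounded)
#'   and logical `k_ab_consistent`, `k_ba_consistent`.
#' @export
table1_check <- function(table = table1_parameters()) {
  rc <- derive_rate_constants(table$k_ex, table$p_a)
  table$k_ab <- rc$k_ab
  table$k_ba <- rc$k_ba
  table$k_ab_consistent <- round(rc$k_ab) == table$k_ab_printed
  table$k_ba_consistent <- round(rc$k_ba) == table$k_ba_printed
  table
}
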