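## parameter layout for the global fit:
## theta = (k_ex, p_b, delta_delta[1..R], r2_0[residue x field, field-major
## within residue]); blocks_by_res is a list (one per residue) of per-field
## blocks as produced by .curve_blocks()
.global_residuals <- function(theta, blocks_by_res) {
  k_ex <- theta[1]; p_b <- theta[2]
  n_res <- length(blocks_by_res)
  dd <- theta[2 + seq_len(n_res)]
  idx <- 2 + n_res
  out <- vector("list", n_res)
  for (r in seq_len(n_res)) {
    blocks <- blocks_by_res[[r]]
    res <- vector("list", length(blocks))
    for (i in seq_along(blocks)) {
      b <- blocks[[i]]
      idx <- idx + 1L
      pred <- .cr_r2eff(k_ex, p_b, dd[r], theta[idx], b$nu, b$n_mhz)
      res[[i]] <- (b$y - pred) / b$sigma
    }
    out[[r]] <- unlist(res, use.names = FALSE)
  }
  unlist(out, use.names = FALSE)
}

.global_fit_once <- function(theta0, lower, upper, blocks_by_res) {
  tryCatch(
    nls.lm(par = theta0, lower = lower, upper = upper,
           fn = .global_residuals, blocks_by_res = blocks_by_res,
           control = nls.lm.control(maxiter = 400, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
}

#' Select residues for a shared-parameter global fit
#'
#' Residues fit reliably to two-site exchange with individually similar
#' kinetics and populations are grouped: membership requires the
#' individual (k_ex, p_b) to fall within a log2 ellipse around the group
#' median (default semi-axes one log2 unit, i.e. a factor of 2 in each
#' coordinate).
#'
#' @param screen Output of [screen_residues()] (its `summary` element is
#'   used).
#' @param config Fitting configuration.
#' @return Integer vector of member residues.
#' @export
select_global_group <- function(screen, config = disp_config()$fitting) {
  s <- screen$summary
  cand <- s[s$classification == "two_site_fittable" & is.finite(s$k_ex) &
              is.finite(s$p_b), ]
  if (!nrow(cand)) return(integer(0))
  ax <- config$group_ellipse_log2
  d2 <- (log2(cand$k_ex / median(cand$k_ex)) / ax[["k_ex"]])^2 +
        (log2(cand$p_b / median(cand$p_b)) / ax[["p_b"]])^2
  sort(cand$residue[d2 <= 1])
}

#' Global two-site fit with shared exchange parameters
#'
#' Joint weighted least squares of the Carver-Richards model over a group
#' of residues and all fields: one k_ex and one p_a shared by every
#' residue and field, one shift difference per residue (shared across
#' fields, in ppm), and one exchange-free R2_0 per residue per field.
#' Parameter uncertainties for the shared parameters are reported both
#' from the covariance at the optimum and, optionally, by bootstrap
#' resampling of residues.
#'
#' @param dispersion Dispersion table (single state).
#' @param members Residues to include; every member should individually be
#'   two-site fittable (see [select_global_group()]). Groups of fewer than
#'   3 residues are fit with a warning.
#' @param state_label Label stored in the result.
#' @param config Fitting configuration.
#' @param residue_fits Optional [screen_residues()] output providing
#'   starting values; otherwise a quick per-residue prescreen is run.
#'   `"none"` skips the prescreen and relies on the coarse start grid.
#' @param n_boot Number of bootstrap replicates over residues (0 to skip).
#' @param boot_seed Seed for the bootstrap resampling.
#' @return Object of class `global_fit`: `k_ex`, `k_ex_se`, `p_a`, `p_b`,
#'   `p_a_se`, the derived `k_ab`/`k_ba` (exact: k_ab + k_ba = k_ex),
#'   bootstrap SEs when requested, per-residue table (`delta_delta` with
#'   SE, per-field `r2_0`), `chi2_reduced`, sizes, and convergence info.
#' @export
fit_global <- function(dispersion, members, state_label = dispersion$state[1],
                       config = disp_config()$fitting, residue_fits = NULL,
                       n_boot = 0, boot_seed = 1L) {
  members <- sort(unique(members))
  if (length(members) < 3) {
    warning("global fit over fewer than 3 residues: shared parameters will ",
            "be weakly constrained")
  }
  disp <- dispersion[dispersion$residue %in% members, ]
  if (!nrow(disp)) stop("no dispersion data for the requested members")
  fields_by_res <- lapply(split(disp$field_mhz, disp$residue), unique)
  common <- Reduce(intersect, fields_by_res)
  if (!length(common)) {
    stop("member residues share no common field: cannot fit globally")
  }
  blocks_by_res <- lapply(split(disp, disp$residue), .curve_blocks)
  blocks_by_res <- blocks_by_res[order(as.integer(names(blocks_by_res)))]
  n_res <- length(blocks_by_res)

  # starting values from per-residue two-site fits
  if (identical(residue_fits, "none")) {
    residue_fits <- list(summary = data.frame(
      residue = integer(), k_ex = numeric(), p_b = numeric(),
      delta_delta = numeric()))
  } else if (is.null(residue_fits)) {
    residue_fits <- screen_residues(disp, config, starts = "quick")
  }
  s <- residue_fits$summary
  s <- s[s$residue %in% members & is.finite(s$k_ex), ]
  k0 <- if (nrow(s)) median(s$k_ex) else 300
  pb0 <- if (nrow(s)) median(s$p_b) else 0.05
  dd0 <- vapply(names(blocks_by_res), function(r) {
    v <- s$delta_delta[s$residue == as.integer(r)]
    if (length(v) && is.finite(v[1])) v[1] else 2
  }, numeric(1))
  r20_0 <- unlist(lapply(blocks_by_res, function(blocks)
    vapply(blocks, function(b)
      mean(b$y[seq(max(1, length(b$y) - 2), length(b$y))]), numeric(1))))

  bounds <- config$bounds
  n_r20 <- length(r20_0)
  lower <- c(bounds$k_ex[1], bounds$p_b[1], rep(bounds$delta_delta[1], n_res),
             rep(bounds$r2_0[1], n_r20))
  upper <- c(bounds$k_ex[2], bounds$p_b[2], rep(bounds$delta_delta[2], n_res),
             rep(bounds$r2_0[2], n_r20))
  # multi-start on the shared parameters: the per-residue-median start plus
  # the coarse (k_ex, p_b) grid, each with heuristic shift differences;
  # Levenberg-Marquardt is run from the most promising starts only
  cand <- list(c(k0, pb0))
  for (k in config$start_grid$k_ex) for (pb in config$start_grid$p_b) {
    cand[[length(cand) + 1L]] <- c(k, pb)
  }
  theta_list <- lapply(cand, function(s) {
    dd <- vapply(blocks_by_res, .dd_heuristic, numeric(1),
                 k_ex = s[1], p_b = s[2])
    pmin(pmax(c(s[1], s[2], dd, r20_0), lower), upper)
  })
  theta_list[[1]][2 + seq_len(n_res)] <-     # median start keeps the
    pmin(pmax(dd0, lower[3]), upper[3])      # per-residue fitted dd
  chi0 <- vapply(theta_list, function(th)
    sum(.global_residuals(th, blocks_by_res)^2), numeric(1))
  run <- unique(c(1L, order(chi0)[1:min(3, length(chi0))]))
  fit <- NULL
  for (i in run) {
    f <- .global_fit_once(theta_list[[i]], lower, upper, blocks_by_res)
    if (is.null(f)) next
    if (is.null(fit) || f$deviance < fit$deviance * (1 - 1e-8) ||
        (abs(f$deviance - fit$deviance) <= fit$deviance * 1e-8 &&
         f$par[1] < fit$par[1])) fit <- f
  }
  if (is.null(fit)) stop("global fit failed to converge")

  n <- sum(vapply(blocks_by_res, function(blocks)
    sum(vapply(blocks, function(b) length(b$y), integer(1))), integer(1)))
  n_par <- length(fit$par)
  df <- n - n_par
  chi2_red <- fit$deviance / max(df, 1)
  cov <- .wls_covariance(.global_residuals, fit$par, chi2_red,
                         blocks_by_res = blocks_by_res)
  se <- sqrt(pmax(diag(cov), 0))

  theta <- unname(fit$par)
  residues <- as.integer(names(blocks_by_res))
  res_table <- data.frame(
    residue = residues,
    delta_delta = theta[2 + seq_len(n_res)],
    delta_delta_se = se[2 + seq_len(n_res)])
  idx <- 2 + n_res
  for (r in seq_len(n_res)) {
    for (b in blocks_by_res[[r]]) {
      idx <- idx + 1L
      col <- paste0("r2_0_", b$field_mhz)
      if (!col %in% names(res_table)) res_table[[col]] <- NA_real_
      res_table[[col]][r] <- theta[idx]
    }
  }

  boot <- NULL
  if (n_boot > 0) {
    set.seed(boot_seed)
    reps <- matrix(NA_real_, n_boot, 2,
                   dimnames = list(NULL, c("k_ex", "p_b")))
    for (b in seq_len(n_boot)) {
      pick <- sample(n_res, n_res, replace = TRUE)
      bb <- blocks_by_res[pick]
      th0 <- c(theta[1], theta[2], theta[2 + pick],
               unlist(lapply(pick, function(r) {
                 base <- 2 + n_res +
                   cumsum(c(0, vapply(blocks_by_res,
                                      length, integer(1))))[r]
                 theta[base + seq_along(blocks_by_res[[r]])]
               })))
      lo <- c(lower[1:2], rep(bounds$delta_delta[1], n_res),
              rep(bounds$r2_0[1], length(th0) - 2 - n_res))
      hi <- c(upper[1:2], rep(bounds$delta_delta[2], n_res),
              rep(bounds$r2_0[2], length(th0) - 2 - n_res))
      bf <- .global_fit_once(th0, lo, hi, bb)
      if (!is.null(bf)) reps[b, ] <- bf$par[1:2]
    }
    boot <- list(k_ex_se = sd(reps[, "k_ex"], na.rm = TRUE),
                 p_a_se = sd(reps[, "p_b"], na.rm = TRUE),
                 n_effective = sum(is.finite(reps[, "k_ex"])))
  }

  rc <- derive_rate_constants(theta[1], 1 - theta[2])
  structure(list(
    state_label = state_label, members = residues,
    k_ex = theta[1], k_ex_se = se[1],
    p_b = theta[2], p_a = 1 - theta[2], p_a_se = se[2],
    k_ab = rc$k_ab, k_ba = rc$k_ba,
    bootstrap = boot, residues = res_table,
    chi2 = fit$deviance, chi2_reduced = chi2_red,
    n_points = n, n_par = n_par, df = df, lm_info = fit$info),
    class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf("Global two-site fit [%s]: %d residues, %d points\n",
              x$state_label, length(x$members), x$n_points))
  cat(sprintf("  k_ex = %.1f +/- %.1f s^-1   p_A = %.1f%% (p_B = %.1f%%)\n",
              x$k_ex, x$k_ex_se, 100 * x$p_a, 100 * x$p_b))
  cat(sprintf("  k_AB = %.1f s^-1   k_BA = %.1f s^-1   chi2_red = %.2f\n",
              x$k_ab, x$k_ba, x$chi2_reduced))
  invisible(x)
}

## fit one residue's (delta_delta, r2_0 per field) with the shared
## (k_ex, p_b) held fixed; returns the reduced chi-square
.conditional_residue_fit <- function(blocks, k_ex, p_b, bounds) {
  fn <- function(theta) {
    unlist(lapply(seq_along(blocks), function(i) {
      b <- blocks[[i]]
      pred <- .cr_r2eff(k_ex, p_b, theta[1], theta[1 + i], b$nu, b$n_mhz)
      (b$y - pred) / b$sigma
    }), use.names = FALSE)
  }
  r20_0 <- vapply(blocks, function(b)
    mean(b$y[seq(max(1, length(b$y) - 2), length(b$y))]), numeric(1))
  theta0 <- c(.dd_heuristic(blocks, k_ex, p_b), r20_0)
  lower <- c(bounds$delta_delta[1], rep(bounds$r2_0[1], length(blocks)))
  upper <- c(bounds$delta_delta[2], rep(bounds$r2_0[2], length(blocks)))
  fit <- tryCatch(
    nls.lm(par = pmin(pmax(theta0, lower), upper), lower = lower,
           upper = upper, fn = fn,
           control = nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(Inf)
  n <- sum(vapply(blocks, function(b) length(b$y), integer(1)))
  fit$deviance / max(n - length(theta0), 1)
}

#' Expand a global-fit group by conditional refitting
#'
#' Second membership pass: residues with a model-selected dispersion
#' (two-site preferred over flat) that were left out of the initial
#' (k_ex, p_b)-similarity group are refit with the shared exchange
#' parameters of an existing global fit held fixed (only the residue's
#' shift difference and exchange-free rates free). Residues the shared
#' kinetics describe acceptably (conditional reduced chi-square below the
#' threshold) are admitted. This rescues residues whose unconstrained
#' individual fits are ill-conditioned or landed in a degenerate parameter
#' basin -- the situation global fitting exists to resolve; single-residue
#' parameter precision is not required once the kinetics are shared.
#'
#' @param dispersion Dispersion table (single state).
#' @param screen Output of [screen_residues()].
#' @param global_fit A `global_fit` from the initial group.
#' @param config Fitting configuration.
#' @return Integer vector: the expanded member set.
#' @export
expand_global_group <- function(dispersion, screen, global_fit,
                                config = disp_config()$fitting) {
  s <- screen$summary
  cand <- setdiff(s$residue[s$model == "two_site"], global_fit$members)
  keep <- vapply(cand, function(res) {
    blocks <- .curve_blocks(dispersion[dispersion$residue == res, ])
    chi2_red <- .conditional_residue_fit(blocks, global_fit$k_ex,
                                         global_fit$p_b, config$bounds)
    chi2_red < config$max_chi2_reduced
  }, logical(1))
  sort(unique(c(global_fit$members, cand[keep])))
}

#' Run the full single-state fitting pipeline
#'
#' Screen every residue (flat vs two-site, classification), select the
#' global group by (k_ex, p_b) similarity, fit globally, expand the group
#' by conditional refitting under the shared parameters, and refit. This
#' is the analysis path from a dispersion table to one state's global
#' exchange parameters.
#'
#' @param dispersion Dispersion table (single state).
#' @param state_label State label for the result.
#' @param config Fitting configuration.
#' @param starts Start policy for the per-residue screen.
#' @param n_boot Bootstrap replicates for the final global fit.
#' @param boot_seed Bootstrap seed.
#' @return List with `screen`, `group` (final members) and `global` (the
#'   final `global_fit`).
#' @export
fit_state_pipeline <- function(dispersion, state_label = dispersion$state[1],
                               config = disp_config()$fitting,
                               starts = "full", n_boot = 0, boot_seed = 1L) {
  screen <- screen_residues(dispersion, config, starts)
  group <- select_global_group(screen, config)
  if (length(group) < 2) {
    stop("fewer than 2 residues selected for the global group")
  }
  gf <- fit_global(dispersion, group, state_label, config,
                   residue_fits = screen)
  # iterate membership expansion until the group is stable: each pass
  # admits fittable residues the current shared kinetics describe, then
  # refits the shared parameters over the enlarged group
  for (pass in 1:4) {
    expanded <- expand_global_group(dispersion, screen, gf, config)
    if (setequal(expanded, gf$members)) break
    gf <- fit_global(dispersion, expanded, state_label, config,
                     residue_fits = screen)
  }
  if (n_boot > 0) {
    gf <- fit_global(dispersion, gf$members, state_label, config,
                     residue_fits = screen, n_boot = n_boot,
                     boot_seed = boot_seed)
  }
  list(screen = screen, group = gf$members, global = gf)
}
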