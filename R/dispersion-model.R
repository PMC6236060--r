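#' Static-field context
#'
#' Bundles the static field, expressed as the 1H Larmor frequency in MHz,
#' with the derived 15N Larmor frequency. The nitrogen frequency carries the
#' field dependence of the chemical-shift difference between exchanging
#' states: a shift difference in ppm converts to rad/s as
#' `delta_delta * nitrogen_larmor_mhz * 2 * pi`.
#'
#' @param proton_larmor_mhz Positive scalar, 1H Larmor frequency (MHz).
#' @param nitrogen_proton_ratio Gyromagnetic-ratio quotient
#'   |gamma(15N)/gamma(1H)|; default from [disp_config()].
#' @return Object of class `field_context`.
#' @export
#' @examples
#' field_context(850)$nitrogen_larmor_mhz
field_context <- function(proton_larmor_mhz,
                          nitrogen_proton_ratio = disp_config()$model$nitrogen_proton_ratio) {
  stopifnot(is.numeric(proton_larmor_mhz), length(proton_larmor_mhz) == 1L,
            is.finite(proton_larmor_mhz), proton_larmor_mhz > 0)
  structure(list(proton_larmor_mhz = proton_larmor_mhz,
                 nitrogen_larmor_mhz = nitrogen_proton_ratio * proton_larmor_mhz),
            class = "field_context")
}

#' Convert a 15N shift difference from ppm to rad/s
#'
#' @param delta_delta Shift difference in ppm (sign-carrying).
#' @param field A `field_context`.
#' @return Angular frequency difference in rad/s.
#' @export
ppm_to_rad_per_sec <- function(delta_delta, field) {
  stopifnot(inherits(field, "field_context"))
  delta_delta * field$nitrogen_larmor_mhz * 2 * pi
}

#' Two-site exchange parameters
#'
#' The kinetic/thermodynamic state of a two-site exchange process plus one
#' residue's spectroscopic parameters: exchange rate constant `k_ex`
#' (= k_AB + k_BA), major-state population `p_a` (convention: p_a >= 0.5,
#' which breaks the A/B labelling degeneracy), 15N chemical-shift difference
#' `delta_delta` between the states (ppm), and the exchange-free transverse
#' relaxation rate `r2_0` (s^-1, per field).
#'
#' @param k_ex Exchange rate constant, s^-1 (>= 0).
#' @param p_a Major-state population, in [0.5, 1].
#' @param delta_delta Shift difference in ppm; sign is not identifiable from
#'   dispersion data alone and only its magnitude affects the model.
#' @param r2_0 Exchange-free R2, s^-1 (>= 0).
#' @return Object of class `exchange_parameters`; `p_b` is stored as
#'   `1 - p_a` so the populations sum to one by construction.
#' @export
#' @examples
#' exchange_parameters(k_ex = 286, p_a = 0.942, delta_delta = 2, r2_0 = 15)
exchange_parameters <- function(k_ex, p_a, delta_delta, r2_0) {
  stopifnot(is.numeric(k_ex), length(k_ex) == 1L, is.finite(k_ex), k_ex >= 0,
            is.numeric(p_a), length(p_a) == 1L, p_a >= 0.5, p_a <= 1,
            is.numeric(delta_delta), length(delta_delta) == 1L, is.finite(delta_delta),
            is.numeric(r2_0), length(r2_0) == 1L, is.finite(r2_0), r2_0 >= 0)
  structure(list(k_ex = k_ex, p_a = p_a, p_b = 1 - p_a,
                 delta_delta = delta_delta, r2_0 = r2_0),
            class = "exchange_parameters")
}

#' Constant-time CPMG schedule
#'
#' A constant-time CPMG experiment holds the total relaxation period `T_cp`
#' fixed while varying the pulsing frequency. Convention used throughout:
#' `tau_cp` is the time between successive 180-degree pulses and
#' `nu_cpmg = 1/(2 * tau_cp)`, so a schedule point with pulsing frequency
#' `nu` places `2 * T_cp * nu` refocusing pulses in the period, which must
#' be a whole number.
#'
#' @param nu_cpmg_hz Vector of pulsing frequencies (Hz). Default: 12 values,
#'   approximately log-spaced over 25-1000 Hz, all commensurate with a 40 ms
#'   period.
#' @param total_cpmg_period Constant-time period T_cp in seconds.
#' @return Object of class `cpmg_schedule` with fields `nu_cpmg_hz`,
#'   `tau_cp_s`, `n_pulses`, `total_cpmg_period`.
#' @export
#' @examples
#' cpmg_schedule()$n_pulses
cpmg_schedule <- function(nu_cpmg_hz = default_nu_grid(),
                          total_cpmg_period = disp_config()$model$total_cpmg_period) {
  stopifnot(is.numeric(nu_cpmg_hz), all(is.finite(nu_cpmg_hz)), all(nu_cpmg_hz > 0),
            is.numeric(total_cpmg_period), total_cpmg_period > 0)
  nu <- sort(unique(nu_cpmg_hz))
  n_pulses <- 2 * total_cpmg_period * nu
  if (any(abs(n_pulses - round(n_pulses)) > 1e-6)) {
    bad <- nu[abs(n_pulses - round(n_pulses)) > 1e-6]
    stop("nu_cpmg values not commensurate with the constant-time period (",
         "non-integer pulse count): ", paste(signif(bad, 6), collapse = ", "))
  }
  structure(list(nu_cpmg_hz = nu, tau_cp_s = 1 / (2 * nu),
                 n_pulses = as.integer(round(n_pulses)),
                 total_cpmg_period = total_cpmg_period),
            class = "cpmg_schedule")
}

#' Default pulsing-frequency grid
#'
#' Twelve approximately log-spaced pulsing frequencies between 25 and
#' 1000 Hz, each commensurate with the 40 ms constant-time period
#' (i.e. multiples of 12.5 Hz).
#'
#' @param total_cpmg_period Constant-time period (s).
#' @return Numeric vector of nu_cpmg values (Hz).
#' @export
default_nu_grid <- function(total_cpmg_period = disp_config()$model$total_cpmg_period) {
  n_pulses <- c(2, 3, 4, 5, 8, 11, 15, 21, 29, 41, 57, 80)
  n_pulses / (2 * total_cpmg_period)
}

#' Carver-Richards intermediates
#'
#' The algebraic intermediates of the closed-form two-site expression:
#' Psi = k_ex^2 - delta_omega^2, zeta = -2 * delta_omega * k_ex * (p_a - p_b),
#' the dimensionless D+ / D- factors and the eta+ / eta- arguments
#' (eta_pm = (tau_cp / sqrt(2)) * sqrt(+-Psi + sqrt(Psi^2 + zeta^2))).
#' D+ - D- = 1 identically.
#'
#' @param params An `exchange_parameters` object.
#' @param tau_cp Delay between successive 180-degree pulses (s); vectorised.
#' @param field A `field_context`.
#' @return List with `psi`, `zeta`, `d_plus`, `d_minus`, `eta_plus`,
#'   `eta_minus` (the eta elements have the length of `tau_cp`).
#' @export
cr_intermediates <- function(params, tau_cp, field) {
  stopifnot(inherits(params, "exchange_parameters"),
            inherits(field, "field_context"),
            all(is.finite(tau_cp)), all(tau_cp > 0))
  dw <- ppm_to_rad_per_sec(params$delta_delta, field)
  psi <- params$k_ex^2 - dw^2
  zeta <- -2 * dw * params$k_ex * (params$p_a - params$p_b)
  root <- sqrt(psi^2 + zeta^2)
  if (root == 0) { # k_ex = 0 and dw = 0: no exchange process at all
    return(list(psi = psi, zeta = zeta, d_plus = 1, d_minus = 0,
                eta_plus = rep(0, length(tau_cp)),
                eta_minus = rep(0, length(tau_cp))))
  }
  list(psi = psi, zeta = zeta,
       d_plus  = 0.5 * ( 1 + (psi + 2 * dw^2) / root),
       d_minus = 0.5 * (-1 + (psi + 2 * dw^2) / root),
       eta_plus  = tau_cp / sqrt(2) * sqrt(pmax(root + psi, 0)),
       eta_minus = tau_cp / sqrt(2) * sqrt(pmax(root - psi, 0)))
}

## Fast unclassed evaluator used by the fitting engine; vectorised over nu.
## Identical mathematics to carver_richards_r2eff().
.cr_r2eff <- function(k_ex, p_b, delta_delta, r2_0, nu_cpmg, nitrogen_larmor_mhz) {
  if (k_ex <= 0 || p_b <= 0 || delta_delta == 0) {
    return(rep(r2_0, length(nu_cpmg)))
  }
  dw <- delta_delta * nitrogen_larmor_mhz * 2 * pi
  p_a <- 1 - p_b
  tau <- 1 / (2 * nu_cpmg)
  psi <- k_ex^2 - dw^2
  zeta <- -2 * dw * k_ex * (p_a - p_b)
  root <- sqrt(psi^2 + zeta^2)
  d_plus  <- 0.5 * ( 1 + (psi + 2 * dw^2) / root)
  d_minus <- 0.5 * (-1 + (psi + 2 * dw^2) / root)
  eta_p <- tau / sqrt(2) * sqrt(pmax(root + psi, 0))
  eta_m <- tau / sqrt(2) * sqrt(pmax(root - psi, 0))
  # cosh(eta_p) overflows near eta_p ~ 710; switch to the asymptotic
  # acosh(x) ~ log(2x) well before that (exact to < 1e-26 at eta_p = 30)
  ach <- numeric(length(tau))
  big <- eta_p > 30
  if (any(big)) ach[big] <- eta_p[big] + log(d_plus)
  if (any(!big)) {
    arg <- d_plus * cosh(eta_p[!big]) - d_minus * cos(eta_m[!big])
    ach[!big] <- acosh(pmax(arg, 1)) # clamp round-off excursions below 1
  }
  r2_0 + 0.5 * (k_ex - ach / tau)
}

#' Closed-form Carver-Richards effective relaxation rate
#'
#' Evaluates the closed-form two-site exchange expression for the effective
#' transverse relaxation rate under a CPMG train,
#' `R2eff(1/tau_cp) = R2_0 + 1/2 * (k_ex - (1/tau_cp) * acosh(D+ cosh(eta+)
#' - D- cos(eta-)))`, with the intermediates of [cr_intermediates()]. The
#' expression assumes equal exchange-free R2 in both states. Numerical
#' guards: the acosh argument is clamped to >= 1 against round-off (the
#' argument only approaches 1 as the exchange contribution vanishes), and
#' for large eta+ the asymptotic form `acosh(x) ~ eta+ + log(D+)` is used to
#' avoid cosh overflow.
#'
#' @param params An `exchange_parameters` object.
#' @param tau_cp Delay between successive 180-degree pulses (s); vectorised.
#' @param field A `field_context`.
#' @return R2eff in s^-1, same length as `tau_cp`.
#' @export
#' @examples
#' p <- exchange_parameters(286, 0.942, 2, 15)
#' carver_richards_r2eff(p, tau_cp = 1 / (2 * 50), field_context(850))
carver_richards_r2eff <- function(params, tau_cp, field) {
  stopifnot(inherits(params, "exchange_parameters"),
            inherits(field, "field_context"))
  if (!all(is.finite(tau_cp)) || any(tau_cp <= 0)) {
    stop("tau_cp must be finite and positive")
  }
  out <- .cr_r2eff(params$k_ex, params$p_b, params$delta_delta, params$r2_0,
                   nu_cpmg = 1 / (2 * tau_cp),
                   nitrogen_larmor_mhz = field$nitrogen_larmor_mhz)
  if (any(!is.finite(out))) stop("non-finite R2eff from Carver-Richards evaluation")
  out
}

## closed-form expm of a 2x2 complex matrix (A traceless decomposition);
## for traceless B, B^2 = (B11^2 + B12*B21) * I
.expm2 <- function(A) {
  tr2 <- (A[1, 1] + A[2, 2]) / 2
  B <- A
  B[1, 1] <- B[1, 1] - tr2
  B[2, 2] <- B[2, 2] - tr2
  q2 <- B[1, 1]^2 + B[1, 2] * B[2, 1]
  q <- sqrt(q2)
  if (Mod(q) < 1e-6) {
    E <- diag(2) + B * (1 + q2 / 6) + (B %*% B) / 2
  } else {
    E <- cosh(q) * diag(2) + (sinh(q) / q) * B
  }
  exp(tr2) * E
}

#' Numerical Bloch-McConnell effective relaxation rate
#'
#' Independent oracle for [carver_richards_r2eff()]: propagates two-site
#' transverse magnetization through the full constant-time CPMG train under
#' the exchange-coupled evolution matrix, with ideal instantaneous
#' 180-degree pulses implemented as complex conjugation of the transverse
#' components. Magnetization starts at the equilibrium populations
#' `(p_a, p_b)`. Both states carry the same exchange-free R2 (the
#' assumption of the closed form).
#'
#' The default readout, `detect = "major"`, returns
#' `-(1/T_cp) * log(|M_A(T_cp)| / p_a)`: the experiment measures the
#' intensity of the observable major-state resonance. `detect = "total"`
#' uses the magnitude of the summed transverse magnetization instead; the
#' two coincide except in slow exchange where the minor-state line is
#' resolved.
#'
#' @param params An `exchange_parameters` object.
#' @param tau_cp Delay between successive 180-degree pulses (s); vectorised.
#'   Each value must place an integer number of pulses in the constant-time
#'   period.
#' @param field A `field_context`.
#' @param schedule A `cpmg_schedule`; supplies the constant-time period.
#' @param detect `"major"` or `"total"` (see Details).
#' @return R2eff in s^-1, same length as `tau_cp`.
#' @export
#' @examples
#' p <- exchange_parameters(286, 0.942, 2, 15)
#' bloch_mcconnell_r2eff(p, 1 / (2 * 50), field_context(850), cpmg_schedule())
bloch_mcconnell_r2eff <- function(params, tau_cp, field,
                                  schedule = cpmg_schedule(),
                                  detect = c("major", "total")) {
  stopifnot(inherits(params, "exchange_parameters"),
            inherits(field, "field_context"),
            inherits(schedule, "cpmg_schedule"),
            all(is.finite(tau_cp)), all(tau_cp > 0))
  detect <- match.arg(detect)
  t_cp <- schedule$total_cpmg_period
  n <- t_cp / tau_cp
  if (any(abs(n - round(n)) > 1e-6)) {
    stop("tau_cp not commensurate with the constant-time period: ",
         "non-integer pulse count")
  }
  n <- as.integer(round(n))
  dw <- ppm_to_rad_per_sec(params$delta_delta, field)
  k_ab <- params$k_ex * params$p_b
  k_ba <- params$k_ex * params$p_a
  A <- matrix(c(-params$r2_0 - k_ab,              k_ba,
                k_ab,               -1i * dw - params$r2_0 - k_ba),
              2, 2, byrow = TRUE)
  m0 <- c(params$p_a, params$p_b)
  vapply(seq_along(tau_cp), function(i) {
    U <- .expm2(A * tau_cp[i] / 2)
    M <- m0
    for (k in seq_len(n[i])) M <- U %*% Conj(U %*% M)
    if (detect == "major") {
      -log(Mod(M[1]) / params$p_a) / t_cp
    } else {
      -log(Mod(sum(M))) / t_cp
    }
  }, numeric(1))
}

#' Dispersion amplitude
#'
#' Size of the dispersion under the closed form: R2eff at the slowest
#' pulsing frequency of the schedule minus R2eff at the fastest. Zero when
#' there is no exchange contribution (p_b = 0 or delta_delta = 0) and
#' non-negative for any two-site parameter set.
#'
#' @param params An `exchange_parameters` object.
#' @param field A `field_context`.
#' @param schedule A `cpmg_schedule` with at least two pulsing frequencies.
#' @return Amplitude in s^-1.
#' @export
rex_amplitude <- function(params, field, schedule = cpmg_schedule()) {
  stopifnot(inherits(schedule, "cpmg_schedule"))
  if (length(schedule$nu_cpmg_hz) < 2) {
    stop("schedule must contain at least two pulsing frequencies")
  }
  taus <- 1 / (2 * range(schedule$nu_cpmg_hz))  # c(slowest, fastest) in tau
  r2 <- carver_richards_r2eff(params, taus, field)
  r2[1] - r2[2]
}
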