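#' Default configuration for the dispersion analysis pipeline
#'
#' All tunable constants live here: physical constants, the CPMG timing
#' defaults, the uncertainty policy for rates derived from intensities,
#' fitting grids/bounds/thresholds, and the geometric cutoffs of the
#' interaction-network module. Every user-facing function that consumes a
#' piece of this list takes it (or the relevant element) as an argument, so
#' overriding a default is a matter of editing the returned list.
#'
#' Units: rates in s^-1, chemical-shift differences in ppm, fields as 1H
#' Larmor frequency in MHz, times in seconds, distances in Angstrom.
#'
#' @return Nested list of defaults.
#' @export
#' @examples
#' cfg <- disp_config()
#' cfg$fitting$bounds$k_ex
disp_config <- function() {
  list(
    model = list(
      # |gamma(15N)/gamma(1H)|: nitrogen Larmor = this * proton Larmor
      nitrogen_proton_ratio = 0.10137,
      total_cpmg_period = 0.040,
      fields_mhz = c(600, 850)
    ),
    io = list(
      # sigma(R2eff) when no uncertainty column is present:
      # relative fraction of R2eff with an absolute floor
      sigma_relative = 0.02,
      sigma_floor = 0.3
    ),
    fitting = list(
      start_grid = list(
        k_ex = c(100, 300, 1000, 3000),
        p_b = c(0.02, 0.05, 0.10)
      ),
      bounds = list(
        k_ex = c(1, 1e5),
        p_b = c(0.001, 0.5),
        delta_delta = c(0, 10),
        r2_0 = c(0.1, 100)
      ),
      alpha = 0.01,               # F-test level for flat vs two-site
      max_rel_uncertainty = 0.5,  # on k_ex and delta_delta for "fittable"
      max_chi2_reduced = 3,
      min_rex_amplitude = 2,      # s^-1, broadened-candidate floor
      r20_flag_k_sd = 1,
      group_ellipse_log2 = c(k_ex = 1, p_b = 1)  # factor-2 semi-axes
    ),
    network = list(
      hbond_cutoff = 3.5,
      hydrophobic_cutoff = 4.5,
      proximity_cutoff = 6.0,
      hydrophobic_residues = c("ALA", "VAL", "LEU", "ILE", "MET",
                               "PHE", "TRP", "PRO", "TYR"),
      max_path_len = 6,
      palette = list(
        classification = c(two_site_fittable = "purple",
                           broadened_unfittable = "pink"),
        state_diff = c(reference_only = "blue", other_only = "red"),
        cluster_overlay = c(exchange_only = "yellow",
                            cluster_only = "blue", both = "green")
      )
    )
  )
}
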