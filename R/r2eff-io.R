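#' Effective relaxation rate from a constant-time intensity ratio
#'
#' In a constant-time CPMG experiment every pulsing frequency shares the
#' same relaxation period, so R2eff follows from a single intensity ratio
#' against the reference plane (recorded with the CPMG block omitted):
#' `R2eff = -(1/T_cp) * log(I / I0)`.
#'
#' @param intensity Peak intensity at a given pulsing frequency (a.u.);
#'   vectorised. Non-positive intensities (peaks broadened beyond detection)
#'   yield `NA` with a warning rather than an error; downstream conversion
#'   flags such records as exchange-broadened.
#' @param reference_intensity Reference-plane intensity (a.u., > 0).
#' @param total_cpmg_period Constant-time period T_cp (s).
#' @return R2eff in s^-1.
#' @export
#' @examples
#' compute_r2eff(0.5, 1, 0.040)  # log(2)/0.040 = 17.33 s^-1
compute_r2eff <- function(intensity, reference_intensity,
                          total_cpmg_period = disp_config()$model$total_cpmg_period) {
  stopifnot(is.numeric(intensity),
            is.numeric(reference_intensity), length(reference_intensity) == 1L,
            is.finite(reference_intensity), reference_intensity > 0,
            is.numeric(total_cpmg_period), total_cpmg_period > 0)
  out <- rep(NA_real_, length(intensity))
  ok <- is.finite(intensity) & intensity > 0
  if (any(!ok)) {
    warning("non-positive intensity: record(s) exchange-broadened beyond detection")
  }
  out[ok] <- -log(intensity[ok] / reference_intensity) / total_cpmg_period
  out
}

#' Default uncertainty policy for R2eff
#'
#' When no measured uncertainty is available, sigma(R2eff) is taken as a
#' flat relative fraction of R2eff with an absolute floor (defaults: 2%
#' with a 0.3 s^-1 floor, typical CPMG repeatability).
#'
#' @param r2_eff R2eff values (s^-1).
#' @param relative,floor Policy parameters; defaults from [disp_config()].
#' @return Sigma values (s^-1).
#' @export
default_sigma <- function(r2_eff,
                          relative = disp_config()$io$sigma_relative,
                          floor = disp_config()$io$sigma_floor) {
  pmax(relative * abs(r2_eff), floor)
}

#' Convert an intensity table to a dispersion table
#'
#' Input: one row per (state, field, residue, nu_cpmg) with a peak
#' intensity; the `nu_cpmg_hz = 0` row of each (state, field, residue)
#' group is the reference plane (exactly one required). Output: the
#' standard dispersion table with R2eff and sigma. Sigma comes from
#' duplicate nu_cpmg measurements where present (pooled SD of duplicates,
#' propagated as their SD), otherwise from [default_sigma()].
#' Records with non-positive intensity are returned separately as
#' exchange-broadened-beyond-detection.
#'
#' @param intensities Data frame with columns `state`, `field_mhz`,
#'   `residue`, `nu_cpmg_hz`, `intensity`.
#' @param total_cpmg_period Constant-time period (s).
#' @param sigma_relative,sigma_floor Fallback uncertainty policy.
#' @return List with `dispersion` (data frame: state, field_mhz, residue,
#'   nu_cpmg_hz, r2_eff, sigma) and `broadened_records` (rows whose
#'   intensity was non-positive).
#' @export
intensities_to_dispersion <- function(intensities,
                                      total_cpmg_period = disp_config()$model$total_cpmg_period,
                                      sigma_relative = disp_config()$io$sigma_relative,
                                      sigma_floor = disp_config()$io$sigma_floor) {
  need <- c("state", "field_mhz", "residue", "nu_cpmg_hz", "intensity")
  if (!all(need %in% names(intensities))) {
    stop("intensity table must have columns: ", paste(need, collapse = ", "))
  }
  key <- interaction(intensities$state, intensities$field_mhz,
                     intensities$residue, drop = TRUE)
  out <- list(); bad <- list()
  for (grp in split(intensities, key)) {
    ref <- grp[grp$nu_cpmg_hz == 0, , drop = FALSE]
    if (nrow(ref) != 1L) {
      stop("expected exactly one reference (nu_cpmg_hz = 0) plane for ",
           grp$state[1], "/", grp$field_mhz[1], "/residue ", grp$residue[1],
           ", found ", nrow(ref))
    }
    pts <- grp[grp$nu_cpmg_hz > 0, , drop = FALSE]
    usable <- is.finite(pts$intensity) & pts$intensity > 0
    if (any(!usable)) bad[[length(bad) + 1L]] <- pts[!usable, , drop = FALSE]
    pts <- pts[usable, , drop = FALSE]
    if (!nrow(pts)) next
    r2 <- suppressWarnings(
      compute_r2eff(pts$intensity, ref$intensity, total_cpmg_period))
    sig <- default_sigma(r2, sigma_relative, sigma_floor)
    # duplicate planes: replace the policy sigma with the empirical spread
    dup <- ave(r2, pts$nu_cpmg_hz, FUN = length) > 1
    if (any(dup)) {
      spread <- ave(r2, pts$nu_cpmg_hz, FUN = sd)
      sig[dup] <- pmax(spread[dup], sigma_floor / 3)
    }
    out[[length(out) + 1L]] <- data.frame(
      state = pts$state, field_mhz = pts$field_mhz, residue = pts$residue,
      nu_cpmg_hz = pts$nu_cpmg_hz, r2_eff = r2, sigma = sig)
  }
  dispersion <- if (length(out)) do.call(rbind, out) else
    data.frame(state = character(), field_mhz = numeric(), residue = integer(),
               nu_cpmg_hz = numeric(), r2_eff = numeric(), sigma = numeric())
  dispersion <- dispersion[order(dispersion$state, dispersion$field_mhz,
                                 dispersion$residue, dispersion$nu_cpmg_hz), ]
  rownames(dispersion) <- NULL
  broadened <- if (length(bad)) do.call(rbind, bad) else intensities[0, ]
  rownames(broadened) <- NULL
  list(dispersion = dispersion, broadened_records = broadened)
}

.dispersion_columns <- c("state", "field_mhz", "residue", "nu_cpmg_hz", "r2_eff")

#' Read a dispersion table
#'
#' Reads the tabular dispersion exchange format: delimited text (comma or
#' tab, sniffed from the header line) with columns `state`, `field_mhz`,
#' `residue`, `nu_cpmg_hz`, `r2_eff` and optionally `sigma`. Missing sigma
#' is filled by [default_sigma()]. Duplicate (state, field, residue,
#' nu_cpmg) rows and non-numeric numeric fields are errors naming the
#' offending line.
#'
#' @param path File path.
#' @param sigma_relative,sigma_floor Fallback uncertainty policy used when
#'   the file has no `sigma` column.
#' @return Data frame sorted by state, field, residue, nu_cpmg.
#' @export
read_dispersion_table <- function(path,
                                  sigma_relative = disp_config()$io$sigma_relative,
                                  sigma_floor = disp_config()$io$sigma_floor) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, colClasses = "character",
                   stringsAsFactors = FALSE, check.names = TRUE)
  if (!all(.dispersion_columns %in% names(df))) {
    stop("dispersion table must have columns: ",
         paste(.dispersion_columns, collapse = ", "))
  }
  for (col in c("field_mhz", "residue", "nu_cpmg_hz", "r2_eff",
                intersect("sigma", names(df)))) {
    val <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(val) && any(is.na(val) & !is.na(df[[col]]))) {
      line <- which(is.na(val) & !is.na(df[[col]]))[1] + 1L # + header line
      stop("non-numeric value in column '", col, "' at line ", line,
           " of ", path)
    }
    df[[col]] <- val
  }
  if (!all(is.finite(df$r2_eff))) stop("non-finite r2_eff values in ", path)
  key <- paste(df$state, df$field_mhz, df$residue, df$nu_cpmg_hz)
  if (anyDuplicated(key)) {
    line <- which(duplicated(key))[1] + 1L
    stop("duplicate (state, field, residue, nu_cpmg) row at line ", line,
         " of ", path)
  }
  if (!"sigma" %in% names(df)) {
    df$sigma <- default_sigma(df$r2_eff, sigma_relative, sigma_floor)
  }
  if (any(df$sigma <= 0)) stop("sigma must be positive")
  df$residue <- as.integer(df$residue)
  df <- df[order(df$state, df$field_mhz, df$residue, df$nu_cpmg_hz), ]
  rownames(df) <- NULL
  df
}

#' Write a dispersion table
#'
#' Inverse of [read_dispersion_table()]: numeric fields are written with 15
#' significant digits so a write/read round trip preserves them to at least
#' 12 significant digits.
#'
#' @param dispersion Data frame with the standard dispersion columns.
#' @param path Output path; the delimiter is chosen from the extension
#'   (`.tsv` gives tab, anything else comma).
#' @return `path`, invisibly.
#' @export
write_dispersion_table <- function(dispersion, path) {
  stopifnot(all(.dispersion_columns %in% names(dispersion)))
  cols <- c(.dispersion_columns, intersect("sigma", names(dispersion)))
  out <- dispersion[, cols]
  for (col in setdiff(cols, c("state", "residue"))) {
    out[[col]] <- formatC(out[[col]], format = "g", digits = 15)
  }
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
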