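#' Mean residue ellipticity from a raw CD reading
#'
#' Converts an observed ellipticity in millidegrees to mean residue
#' ellipticity: `MRE = theta_mdeg / (10 * path_cm * conc_M * n_residues)`,
#' in deg cm^2 dmol^-1.
#'
#' @param theta_mdeg observed ellipticity, mdeg (any sign).
#' @param protein_conc_M protein concentration, mol/L (> 0).
#' @param n_residues number of amino-acid residues (> 0; 583 for bovine
#'   serum albumin).
#' @param path_cm cuvette path length, cm (> 0).
#' @return mean residue ellipticity, deg cm^2 dmol^-1.
#' @export
mre_from_ellipticity <- function(theta_mdeg, protein_conc_M,
                                 n_residues = 583, path_cm = 0.1) {
  check_number(protein_conc_M, "protein_conc_M", positive = TRUE)
  check_number(n_residues, "n_residues", positive = TRUE)
  check_number(path_cm, "path_cm", positive = TRUE)
  theta_mdeg / (10 * path_cm * protein_conc_M * n_residues)
}

#' Alpha-helix content from the 208 nm mean residue ellipticity
#'
#' The standard single-wavelength estimate:
#' `helix% = 100 * (-MRE208 - 4000) / (33000 - 4000)`, clamped to
#' `[0, 100]`. The endpoints are the MRE of a pure random coil (-4000) and
#' a pure helix (-33000) at 208 nm.
#'
#' @param mre_208 mean residue ellipticity at 208 nm, deg cm^2 dmol^-1.
#' @return helix content in percent, clamped to [0, 100].
#' @examples
#' helix_estimate(-20472)  # 56.8
#' @export
helix_estimate <- function(mre_208) {
  h <- 100 * (-mre_208 - 4000) / (33000 - 4000)
  pmin(pmax(h, 0), 100)
}

#' Helix content from a measured CD spectrum
#'
#' Reads the ellipticity at 208 nm (linear interpolation), converts it to
#' mean residue ellipticity with [mre_from_ellipticity()], and applies
#' [helix_estimate()].
#'
#' @param s a cd [spectrum()] with intensities in mdeg; the grid must cover
#'   208 nm.
#' @param protein_conc_M protein concentration, mol/L; defaults to the value
#'   recorded in the spectrum metadata.
#' @inheritParams mre_from_ellipticity
#' @return an object of class `cd_estimate`: `mre_208`, `helix_percent`,
#'   `inputs`.
#' @examples
#' s <- simulate_cd_spectrum(56.8)
#' cd_estimate(s)$helix_percent
#' @export
cd_estimate <- function(s, protein_conc_M = s$meta$protein_conc_M,
                        n_residues = 583, path_cm = 0.1) {
  stopifnot(is_spectrum(s))
  if (s$kind != "cd") stop("cd_estimate needs a cd spectrum", call. = FALSE)
  if (is.null(protein_conc_M)) {
    stop("protein_conc_M not given and absent from spectrum metadata",
         call. = FALSE)
  }
  if (min(s$x) > 208 || max(s$x) < 208) {
    stop("spectrum grid does not cover 208 nm", call. = FALSE)
  }
  theta <- stats::approx(s$x, s$y, xout = 208)$y
  mre <- mre_from_ellipticity(theta, protein_conc_M, n_residues, path_cm)
  structure(list(mre_208 = mre, helix_percent = helix_estimate(mre),
                 inputs = list(theta_mdeg_208 = theta,
                               protein_conc_M = protein_conc_M,
                               n_residues = n_residues, path_cm = path_cm)),
            class = "cd_estimate")
}

#' @export
print.cd_estimate <- function(x, ...) {
  cat(sprintf("<cd_estimate: MRE(208) = %.0f deg cm2/dmol, helix = %.1f%%>\n",
              x$mre_208, x$helix_percent))
  invisible(x)
}

#' Rule-based summary of conformational-change probes
#'
#' Collects the spectral probes of a binding study into one structured
#' reading. Any probe may be `NULL` (reported as not measured). Rules:
#' a tryptophan-channel (delta-lambda = 60 nm) synchronous shift beyond
#' `zero_tol_nm` indicates an altered Trp microenvironment; a
#' tyrosine-channel (delta-lambda = 15 nm) shift within tolerance indicates
#' an unchanged Tyr microenvironment; a negative emission or synchronous
#' shift (blue shift) indicates increased hydrophobicity around the
#' fluorophore; a hypochromic absorbance trend corroborates complex
#' formation; amide-I infrared band shifts and helix-content loss corroborate
#' a secondary-structure change.
#'
#' @param emission_shift_nm shift of the emission band maximum, nm.
#' @param sync15_shift_nm synchronous-scan shift at delta-lambda = 15 nm
#'   (tyrosine channel), nm.
#' @param sync60_shift_nm synchronous-scan shift at delta-lambda = 60 nm
#'   (tryptophan channel), nm.
#' @param uv_trend [absorbance_trend()] result.
#' @param ir_shifts_cm1 named or unnamed numeric vector of infrared band
#'   shifts, cm^-1.
#' @param cd_helix_change change in helix content, percentage points
#'   (bound minus free).
#' @param zero_tol_nm shifts with absolute value below this are treated as
#'   zero (default 0.5 nm, below typical 1-2 nm sampling).
#' @return an object of class `conformational_report`: per-probe values,
#'   per-probe readings, and overall flags `trp_changed`, `tyr_changed`,
#'   `blue_shift`, `any_change`.
#' @examples
#' conformational_report(sync60_shift_nm = -3, sync15_shift_nm = 0)
#' @export
conformational_report <- function(emission_shift_nm = NULL,
                                  sync15_shift_nm = NULL,
                                  sync60_shift_nm = NULL, uv_trend = NULL,
                                  ir_shifts_cm1 = NULL,
                                  cd_helix_change = NULL,
                                  zero_tol_nm = 0.5) {
  nonzero <- function(x) !is.null(x) && abs(x) >= zero_tol_nm
  readings <- list()
  reading <- function(probe, value, text) {
    readings[[probe]] <<- list(
      value = value,
      reading = if (is.null(value)) "not measured" else text)
  }
  reading("emission_shift_nm", emission_shift_nm,
          if (nonzero(emission_shift_nm)) {
            if (emission_shift_nm < 0) {
              "emission band blue-shifted: increased hydrophobicity around the fluorophore"
            } else {
              "emission band red-shifted: increased polarity around the fluorophore"
            }
          } else "emission band position unchanged")
  reading("sync15_shift_nm", sync15_shift_nm,
          if (nonzero(sync15_shift_nm)) {
            "Tyr microenvironment altered"
          } else "Tyr microenvironment unchanged")
  reading("sync60_shift_nm", sync60_shift_nm,
          if (nonzero(sync60_shift_nm)) {
            "Trp microenvironment altered"
          } else "Trp microenvironment unchanged")
  reading("uv_trend", uv_trend,
          if (identical(uv_trend, "hypochromic")) {
            "hypochromic absorbance: consistent with complex formation"
          } else if (identical(uv_trend, "hyperchromic")) {
            "hyperchromic absorbance"
          } else "no absorbance trend")
  ir_changed <- !is.null(ir_shifts_cm1) && any(abs(ir_shifts_cm1) > 0)
  reading("ir_shifts_cm1", ir_shifts_cm1,
          if (ir_changed) {
            "amide band shift: secondary-structure perturbation"
          } else "amide bands unchanged")
  cd_changed <- !is.null(cd_helix_change) && abs(cd_helix_change) > 0.1
  reading("cd_helix_change", cd_helix_change,
          if (cd_changed) {
            sprintf("helix content changed by %.1f points", cd_helix_change)
          } else "helix content unchanged")
  trp <- nonzero(sync60_shift_nm)
  tyr <- nonzero(sync15_shift_nm)
  blue <- (nonzero(emission_shift_nm) && emission_shift_nm < 0) ||
    (nonzero(sync60_shift_nm) && sync60_shift_nm < 0)
  any_change <- trp || tyr || blue ||
    identical(uv_trend, "hypochromic") ||
    identical(uv_trend, "hyperchromic") || ir_changed || cd_changed
  structure(list(probes = readings, trp_changed = trp, tyr_changed = tyr,
                 blue_shift = blue, any_change = any_change,
                 zero_tol_nm = zero_tol_nm),
            class = "conformational_report")
}

#' @export
print.conformational_report <- function(x, ...) {
  if (!x$any_change) {
    cat("<conformational_report: no conformational change detected>\n")
    return(invisible(x))
  }
  cat("<conformational_report>\n")
  for (nm in names(x$probes)) {
    p <- x$probes[[nm]]
    if (is.null(p$value)) next
    cat(sprintf("  %s = %s: %s\n", nm,
                paste(format(p$value, digits = 4), collapse = ", "),
                p$reading))
  }
  invisible(x)
}
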