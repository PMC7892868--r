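#' Measured spectra, titration series and excitation-emission matrices
#'
#' `spectrum()` constructs a single measured curve: an ordered wavelength
#' (nm, optical kinds) or wavenumber (cm^-1, `"ir"`) grid with one intensity
#' per grid point. Intensities are arbitrary fluorescence units for the
#' fluorescence kinds, absorbance units for `"absorbance"`, and ellipticity in
#' mdeg for `"cd"`.
#'
#' @param kind one of `"emission"`, `"excitation"`, `"absorbance"`,
#'   `"synchronous"`, `"cd"`, `"ir"`.
#' @param x strictly increasing numeric grid (nm, or cm^-1 for `"ir"`).
#' @param y numeric intensities, same length as `x`, all finite.
#' @param temperature_K optional sample temperature in kelvin (> 0).
#' @param excitation_nm optional excitation wavelength (fluorescence kinds).
#' @param protein_conc_M,ligand_conc_M optional concentrations in mol/L.
#' @param label optional free-text label.
#' @return an object of class `spectrum`: a list with elements `kind`, `x`,
#'   `y` and `meta`.
#' @examples
#' s <- spectrum("emission", 300:400, exp(-((300:400) - 345)^2 / 200),
#'               temperature_K = 298, excitation_nm = 280)
#' peak_max(s)
#' @export
spectrum <- function(kind, x, y, temperature_K = NULL, excitation_nm = NULL,
                     protein_conc_M = NULL, ligand_conc_M = NULL,
                     label = NULL) {
  meta <- list(temperature_K = temperature_K, excitation_nm = excitation_nm,
               protein_conc_M = protein_conc_M, ligand_conc_M = ligand_conc_M,
               label = label)
  meta <- meta[!vapply(meta, is.null, logical(1L))]
  validate_spectrum(structure(list(kind = kind, x = as.numeric(x),
                                   y = as.numeric(y), meta = meta),
                              class = "spectrum"))
}

spectrum_kinds <- c("emission", "excitation", "absorbance", "synchronous",
                    "cd", "ir")

validate_spectrum <- function(s) {
  if (!is.character(s$kind) || length(s$kind) != 1L ||
      !s$kind %in% spectrum_kinds) {
    stop("spectrum `kind` must be one of: ",
         paste(spectrum_kinds, collapse = ", "), call. = FALSE)
  }
  if (length(s$x) != length(s$y)) {
    stop("spectrum grid and intensities must have equal length", call. = FALSE)
  }
  if (length(s$x) < 2L) stop("spectrum needs at least 2 points", call. = FALSE)
  if (anyNA(s$x) || any(!is.finite(s$x))) {
    stop("spectrum grid must be finite", call. = FALSE)
  }
  if (any(diff(s$x) <= 0)) {
    stop("spectrum grid must be strictly increasing", call. = FALSE)
  }
  if (anyNA(s$y) || any(!is.finite(s$y))) {
    stop("spectrum intensities must be finite", call. = FALSE)
  }
  tk <- s$meta$temperature_K
  if (!is.null(tk) && (!is.numeric(tk) || tk <= 0)) {
    stop("temperature_K must be > 0", call. = FALSE)
  }
  s
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %s %g-%g>\n", x$kind, length(x$x),
              x_unit(x), min(x$x), max(x$x)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "spectrum")

x_unit <- function(s) if (s$kind == "ir") "cm-1" else "nm"

#' Fluorescence titration series at one temperature
#'
#' A titration of fixed protein concentration against increasing quencher
#' concentration, recorded as the emission intensity at one observation
#' wavelength. The first point must be the quencher-free measurement
#' (`Q = 0`); its intensity defines F0 for all quenching fits.
#'
#' @param Q quencher concentrations in mol/L: non-negative, strictly
#'   increasing, starting at exactly 0, with at least 3 points above 0.
#' @param F fluorescence intensities (> 0), one per concentration.
#' @param protein_conc_M protein concentration in mol/L.
#' @param temperature_K sample temperature in kelvin.
#' @param excitation_nm excitation wavelength in nm.
#' @param observation_nm emission wavelength at which F is read, in nm.
#' @return an object of class `titration_series` with a `points` data frame
#'   (columns `Q_molar`, `F`) plus the design metadata.
#' @examples
#' ts <- titration_series(Q = c(0, 2, 4, 8) * 1e-6, F = c(100, 91, 83, 71),
#'                        protein_conc_M = 5e-6, temperature_K = 298,
#'                        excitation_nm = 280, observation_nm = 345)
#' stern_volmer_fit(ts)
#' @export
titration_series <- function(Q, F, protein_conc_M = 5e-6,
                             temperature_K = 298, excitation_nm = 280,
                             observation_nm = 345) {
  Q <- as.numeric(Q); F <- as.numeric(F)
  if (length(Q) != length(F)) {
    stop("Q and F must have equal length", call. = FALSE)
  }
  if (length(Q) < 4L || sum(Q > 0) < 3L) {
    stop("a titration needs the Q = 0 point and at least 3 points with Q > 0",
         call. = FALSE)
  }
  if (Q[1L] != 0) stop("first point must have Q == 0 (defines F0)",
                       call. = FALSE)
  if (any(Q < 0) || any(diff(Q) <= 0)) {
    stop("Q must be non-negative, unique and strictly increasing",
         call. = FALSE)
  }
  if (anyNA(F) || any(!is.finite(F)) || any(F <= 0)) {
    stop("all intensities F must be finite and > 0", call. = FALSE)
  }
  check_number(temperature_K, "temperature_K", positive = TRUE)
  structure(list(points = data.frame(Q_molar = Q, F = F),
                 protein_conc_M = protein_conc_M,
                 temperature_K = temperature_K,
                 excitation_nm = excitation_nm,
                 observation_nm = observation_nm),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "<titration_series: %d points, Q 0-%.3g M, T = %g K, obs %g nm>\n",
    nrow(x$points), max(x$points$Q_molar), x$temperature_K,
    x$observation_nm))
  invisible(x)
}

is_titration_series <- function(x) inherits(x, "titration_series")

# F0 is by construction the intensity of the Q = 0 point.
titration_f0 <- function(series) series$points$F[1L]

#' Excitation-emission matrix (EEM)
#'
#' A 2-D fluorescence landscape: intensity indexed by excitation wavelength
#' (rows) and emission wavelength (columns).
#'
#' @param ex_nm strictly increasing excitation grid (nm).
#' @param em_nm strictly increasing emission grid (nm).
#' @param z intensity matrix, `length(ex_nm)` rows by `length(em_nm)`
#'   columns, all finite and >= 0.
#' @return an object of class `eem`.
#' @examples
#' e <- simulate_eem(blobs = data.frame(ex = 280, em = 340, height = 100,
#'                                      sigma = 15))
#' eem_peaks(e)
#' @export
eem <- function(ex_nm, em_nm, z) {
  ex_nm <- as.numeric(ex_nm); em_nm <- as.numeric(em_nm)
  z <- as.matrix(z)
  if (nrow(z) != length(ex_nm) || ncol(z) != length(em_nm)) {
    stop("z must be length(ex_nm) x length(em_nm)", call. = FALSE)
  }
  if (any(diff(ex_nm) <= 0) || any(diff(em_nm) <= 0)) {
    stop("EEM grids must be strictly increasing", call. = FALSE)
  }
  if (anyNA(z) || any(!is.finite(z)) || any(z < 0)) {
    stop("EEM intensities must be finite and >= 0", call. = FALSE)
  }
  structure(list(ex_nm = ex_nm, em_nm = em_nm, z = unname(z)), class = "eem")
}

#' @export
print.eem <- function(x, ...) {
  cat(sprintf("<eem: %d x %d, ex %g-%g nm, em %g-%g nm>\n",
              length(x$ex_nm), length(x$em_nm), min(x$ex_nm), max(x$ex_nm),
              min(x$em_nm), max(x$em_nm)))
  invisible(x)
}

is_eem <- function(x) inherits(x, "eem")
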