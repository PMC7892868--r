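#' Locate the peak of a spectrum
#'
#' Finds the grid point of maximal intensity, optionally restricted to a
#' window, and refines interior maxima by the vertex of the parabola through
#' the maximal sample and its two neighbours. Boundary maxima are returned as
#' the boundary sample without refinement. Ties in the sampled maximum are
#' broken toward lower x.
#'
#' @param s a [spectrum()].
#' @param window optional length-2 numeric `c(lo, hi)` restricting the search.
#' @return a `peak_call`: list with `x_at_max`, `y_at_max` and `interpolated`
#'   (`TRUE` when the parabolic refinement was applied).
#' @examples
#' s <- spectrum("emission", 300:400, dnorm(300:400, 345, 12))
#' peak_max(s)$x_at_max
#' @export
peak_max <- function(s, window = NULL) {
  stopifnot(is_spectrum(s))
  idx <- seq_along(s$x)
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1L] < window[2L])
    idx <- which(s$x >= window[1L] & s$x <= window[2L])
  }
  if (length(idx) < 3L) {
    stop("peak_max needs at least 3 grid points in the window", call. = FALSE)
  }
  x <- s$x[idx]; y <- s$y[idx]
  if (diff(range(y)) == 0) {
    stop("degenerate peak: all intensities equal in window", call. = FALSE)
  }
  i <- which.max(y)  # first occurrence -> tie toward lower x
  if (i == 1L || i == length(y)) {
    return(structure(list(x_at_max = x[i], y_at_max = y[i],
                          interpolated = FALSE), class = "peak_call"))
  }
  v <- parabola_vertex(x[(i - 1L):(i + 1L)], y[(i - 1L):(i + 1L)])
  # Guard: a flat or inverted triple falls back to the sampled maximum.
  if (is.null(v) || v$x < x[i - 1L] || v$x > x[i + 1L]) {
    return(structure(list(x_at_max = x[i], y_at_max = y[i],
                          interpolated = FALSE), class = "peak_call"))
  }
  structure(list(x_at_max = v$x, y_at_max = v$y, interpolated = TRUE),
            class = "peak_call")
}

#' @export
print.peak_call <- function(x, ...) {
  cat(sprintf("<peak: x = %.4g, y = %.4g%s>\n", x$x_at_max, x$y_at_max,
              if (x$interpolated) ", interpolated" else ""))
  invisible(x)
}

# Vertex of the quadratic through three points (supports non-uniform grids).
parabola_vertex <- function(x3, y3) {
  co <- unname(solve(cbind(1, x3, x3^2), y3))
  if (co[3L] >= 0) return(NULL)  # not concave: no interior maximum
  xv <- -co[2L] / (2 * co[3L])
  list(x = xv, y = co[1L] + co[2L] * xv + co[3L] * xv^2)
}

#' Signed shift between the peaks of two spectra
#'
#' Computes `peak_max(b) - peak_max(a)` within a common window, in grid units
#' (nm for optical kinds, cm^-1 for infrared). A blue shift of an emission
#' band is negative.
#'
#' @param a,b two [spectrum()] objects of the same kind.
#' @param window optional length-2 window passed to [peak_max()].
#' @return signed numeric shift.
#' @examples
#' g <- function(mu) spectrum("emission", 300:400, dnorm(300:400, mu, 12))
#' band_shift(g(345), g(331))  # -14
#' @export
band_shift <- function(a, b, window = NULL) {
  stopifnot(is_spectrum(a), is_spectrum(b))
  if (a$kind != b$kind) {
    stop("band_shift requires spectra of the same kind", call. = FALSE)
  }
  peak_max(b, window)$x_at_max - peak_max(a, window)$x_at_max
}

#' Constant-offset synchronous scan through an EEM
#'
#' Extracts S(lambda_ex) = z(lambda_ex, lambda_ex + delta_nm), the synchronous
#' fluorescence spectrum at wavelength offset `delta_nm`, interpolating
#' linearly along the emission axis where the offset target falls between
#' emission samples. The scan domain is restricted to excitation points whose
#' offset target is covered by the emission grid. Offsets of 15 nm and 60 nm
#' isolate the tyrosine and tryptophan channels of serum albumins.
#'
#' @param e an [eem()].
#' @param delta_nm wavelength offset (emission minus excitation), nm.
#' @return a [spectrum()] of kind `"synchronous"` on the covered excitation
#'   grid.
#' @export
synchronous_scan <- function(e, delta_nm) {
  stopifnot(is_eem(e))
  check_number(delta_nm, "delta_nm")
  target <- e$ex_nm + delta_nm
  covered <- target >= min(e$em_nm) & target <= max(e$em_nm)
  if (!any(covered)) {
    stop(sprintf(
      "no excitation point has lambda_ex + %g nm inside the emission grid",
      delta_nm), call. = FALSE)
  }
  ii <- which(covered)
  y <- vapply(ii, function(i) {
    stats::approx(e$em_nm, e$z[i, ], xout = target[i])$y
  }, numeric(1L))
  spectrum("synchronous", x = e$ex_nm[ii], y = y,
           label = sprintf("synchronous scan, delta = %g nm", delta_nm))
}

#' Locate EEM peaks with Rayleigh-scatter masking
#'
#' Finds local maxima of the intensity surface under 8-neighbourhood
#' comparison, after masking the first-order Rayleigh ridge
#' (|em - ex| <= halfwidth) and the second-order ridge
#' (|em - 2 ex| <= halfwidth). Masked cells cannot be peaks, but their raw
#' intensities still take part in neighbour comparisons, so the flanks of a
#' scatter ridge are not reported as spurious maxima. Peaks are returned
#' sorted by intensity, descending.
#'
#' @param e an [eem()].
#' @param scatter_halfwidth_nm half-width of the scatter masks in nm
#'   (default 10, covering a 5 nm slit).
#' @return data frame with columns `ex_nm`, `em_nm`, `intensity`; zero rows
#'   when no unmasked local maximum exists (e.g. a flat EEM).
#' @export
eem_peaks <- function(e, scatter_halfwidth_nm = 10) {
  stopifnot(is_eem(e))
  check_number(scatter_halfwidth_nm, "scatter_halfwidth_nm", positive = TRUE)
  nex <- length(e$ex_nm); nem <- length(e$em_nm)
  EX <- matrix(e$ex_nm, nex, nem)
  EM <- matrix(e$em_nm, nex, nem, byrow = TRUE)
  masked <- abs(EM - EX) <= scatter_halfwidth_nm |
    abs(EM - 2 * EX) <= scatter_halfwidth_nm
  hits <- list()
  for (i in seq_len(nex)) {
    for (j in seq_len(nem)) {
      if (masked[i, j]) next
      zi <- e$z[i, j]
      is_max <- TRUE
      for (di in -1:1) {
        for (dj in -1:1) {
          if (di == 0L && dj == 0L) next
          a <- i + di; b <- j + dj
          if (a < 1L || a > nex || b < 1L || b > nem) next
          if (e$z[a, b] >= zi) { is_max <- FALSE; break }
        }
        if (!is_max) break
      }
      if (is_max) {
        hits[[length(hits) + 1L]] <- c(e$ex_nm[i], e$em_nm[j], zi)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(ex_nm = numeric(0), em_nm = numeric(0),
                      intensity = numeric(0)))
  }
  m <- do.call(rbind, hits)
  out <- data.frame(ex_nm = m[, 1L], em_nm = m[, 2L], intensity = m[, 3L])
  out[order(-out$intensity), , drop = FALSE]
}

#' Classify the absorbance trend across a titration
#'
#' Reads the absorbance at a probe wavelength (linear interpolation) from
#' each spectrum of a titration-ordered series and classifies the trend by
#' the sign of the least-squares slope against titration index. A relative
#' end-to-end change below `rel_tol` is reported as `"none"`. A hypochromic
#' trend (decreasing absorbance on ligand addition) is the signature of
#' complex formation at the protein's 280 nm aromatic band.
#'
#' @param series list of absorbance [spectrum()] objects in titration order.
#' @param probe_nm probe wavelength, default 280 nm.
#' @param rel_tol relative end-to-end change below which the trend is
#'   `"none"` (default 0.01).
#' @return one of `"hypochromic"`, `"hyperchromic"`, `"none"`.
#' @export
absorbance_trend <- function(series, probe_nm = 280, rel_tol = 0.01) {
  if (!is.list(series) || length(series) < 2L ||
      !all(vapply(series, is_spectrum, logical(1L)))) {
    stop("series must be a list of at least 2 spectra", call. = FALSE)
  }
  a <- vapply(series, function(s) {
    if (probe_nm < min(s$x) || probe_nm > max(s$x)) {
      stop(sprintf("probe wavelength %g nm outside spectrum grid", probe_nm),
           call. = FALSE)
    }
    stats::approx(s$x, s$y, xout = probe_nm)$y
  }, numeric(1L))
  rel_change <- (a[length(a)] - a[1L]) / abs(a[1L])
  if (abs(rel_change) < rel_tol) return("none")
  slope <- ols_line(seq_along(a), a)$slope
  if (slope < 0) "hypochromic" else "hyperchromic"
}
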