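# Independent oracles and fixture builders used across the suite.

# Closed-form OLS via the normal equations (independent of stats::lm).
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  ssr <- sum((y - mean(y))^2)
  r2 <- 1 - sum((y - intercept - slope * x)^2) / ssr
  list(slope = slope, intercept = intercept, r2 = r2)
}

# Brute-force enumeration of masked 8-neighbourhood maxima on an EEM,
# written against the definition rather than the package's loop.
eem_peaks_oracle <- function(e, hw = 10) {
  nex <- length(e$ex_nm); nem <- length(e$em_nm)
  mask <- outer(e$ex_nm, e$em_nm, function(ex, em) {
    abs(em - ex) <= hw | abs(em - 2 * ex) <= hw
  })
  out <- NULL
  for (i in seq_len(nex)) {
    for (j in seq_len(nem)) {
      if (mask[i, j]) next
      ni <- max(1L, i - 1L):min(nex, i + 1L)
      nj <- max(1L, j - 1L):min(nem, j + 1L)
      nb_z <- e$z[ni, nj, drop = FALSE]
      nb_z[which(ni == i), which(nj == j)] <- -Inf
      if (all(e$z[i, j] > nb_z)) {
        out <- rbind(out, c(e$ex_nm[i], e$em_nm[j], e$z[i, j]))
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(ex_nm = numeric(0), em_nm = numeric(0),
                      intensity = numeric(0)))
  }
  df <- data.frame(ex_nm = out[, 1], em_nm = out[, 2], intensity = out[, 3])
  df[order(-df$intensity), ]
}

# Gaussian band fixture.
gaussian_spectrum <- function(kind = "emission", grid = seq(250, 600, 1),
                              center = 345, sigma = 12, height = 1000,
                              ...) {
  spectrum(kind, grid, height * exp(-(grid - center)^2 / (2 * sigma^2)), ...)
}

# Reference series: Stern-Volmer and binding constants printed for the
# BSA/MiADMSA system, used as simulator truths throughout the suite.
ref_ksv_by_T <- data.frame(temperature_K = c(298, 303, 308, 318),
                           ksv_Minv = c(4.95, 5.02, 5.53, 6.16) * 1e4)
ref_kb_by_T <- data.frame(temperature_K = c(298, 303, 308, 318),
                          kb_Minv = c(1.60, 1.62, 1.69, 1.79) * 1e4)
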