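#' Stern-Volmer fit of a quenching titration
#'
#' Fits `F0/F = 1 + Ksv * [Q]` by ordinary least squares of `F0/F` on `[Q]`
#' over all titration points (the `Q = 0` point contributes `F0/F = 1`).
#' `Ksv` is the slope; the bimolecular quenching rate constant is
#' `Kq = Ksv / tau0` with `tau0` the unquenched fluorophore lifetime.
#' R^2 is the squared Pearson correlation.
#'
#' A `Kq` exceeding the diffusion-controlled limit of 2e10 1/(M s) is
#' reported via `exceeds_diffusion_limit` as an advisory only: the
#' quenching-mechanism call is made from the temperature trend of `Ksv`
#' ([classify_mechanism()]), never from this flag.
#'
#' @param series a [titration_series()].
#' @param tau0_s unquenched fluorophore lifetime in seconds (default 1e-8,
#'   the standard value for the Trp/Tyr/Phe fluorophores of serum albumin).
#' @return an object of class `quenching_fit`: `ksv_Minv`, `intercept`,
#'   `r2`, `kq_Minv_s`, `tau0_s`, `n_points`, `temperature_K`, `flag`
#'   (`"ok"`, `"degenerate"` or `"negative_slope"`), and
#'   `exceeds_diffusion_limit`.
#' @examples
#' ts <- simulate_titration(truth_params("dynamic", ksv_Minv = 4.95e4))
#' fit <- stern_volmer_fit(ts)
#' c(fit$ksv_Minv, fit$kq_Minv_s)
#' @export
stern_volmer_fit <- function(series, tau0_s = 1e-8) {
  stopifnot(is_titration_series(series))
  check_number(tau0_s, "tau0_s", positive = TRUE)
  q <- series$points$Q_molar
  f <- series$points$F
  if (length(q) < 3L) stop("need at least 3 usable points", call. = FALSE)
  f0 <- titration_f0(series)
  ratio <- f0 / f
  fit <- ols_line(q, ratio)
  flag <- "ok"
  if (stats::sd(ratio) == 0) flag <- "degenerate"
  else if (fit$slope < 0) flag <- "negative_slope"
  ksv <- if (flag == "degenerate") 0 else fit$slope
  kq <- ksv / tau0_s
  structure(list(ksv_Minv = ksv,
                 intercept = if (flag == "degenerate") 1 else fit$intercept,
                 r2 = fit$r2, kq_Minv_s = kq, tau0_s = tau0_s,
                 n_points = fit$n, temperature_K = series$temperature_K,
                 flag = flag,
                 exceeds_diffusion_limit = kq > 2e10),
            class = "quenching_fit")
}

#' @export
print.quenching_fit <- function(x, ...) {
  cat(sprintf(
    "<quenching_fit: Ksv = %.4g 1/M, Kq = %.4g 1/(M s), R2 = %.4f, T = %g K%s>\n",
    x$ksv_Minv, x$kq_Minv_s, x$r2, x$temperature_K,
    if (x$flag != "ok") paste0(", flag = ", x$flag) else ""))
  invisible(x)
}

#' Bimolecular quenching rate constant
#'
#' `Kq = Ksv / tau0`: converts a Stern-Volmer constant to the bimolecular
#' quenching rate constant given the unquenched fluorophore lifetime.
#'
#' @param ksv_Minv Stern-Volmer constant, 1/M.
#' @param tau0_s fluorophore lifetime, s (> 0; default 1e-8).
#' @return Kq in 1/(M s).
#' @examples
#' bimolecular_rate(4.95e4)  # 4.95e12
#' @export
bimolecular_rate <- function(ksv_Minv, tau0_s = 1e-8) {
  if (!is.numeric(tau0_s) || any(tau0_s <= 0)) {
    stop("tau0_s must be > 0", call. = FALSE)
  }
  ksv_Minv / tau0_s
}

#' Classify the quenching mechanism from the temperature trend of Ksv
#'
#' Dynamic (collisional) quenching accelerates with temperature, so `Ksv`
#' rises; static (ground-state complex) quenching weakens, so `Ksv` falls.
#' The call is `"dynamic"` when every consecutive relative change exceeds
#' `-rel_threshold` and the total relative change exceeds `+rel_threshold`;
#' `"static"` by the mirrored rule; otherwise `"indeterminate"`.
#'
#' @param fits list of [stern_volmer_fit()] results at distinct temperatures,
#'   or a data frame with columns `temperature_K` and `ksv_Minv`.
#' @param rel_threshold relative-change tolerance (default 0.02).
#' @return an object of class `mechanism_call`: `label`, `ksv_by_T`,
#'   `rel_change_threshold`.
#' @export
classify_mechanism <- function(fits, rel_threshold = 0.02) {
  tab <- if (is.data.frame(fits)) {
    fits[c("temperature_K", "ksv_Minv")]
  } else {
    data.frame(
      temperature_K = vapply(fits, `[[`, numeric(1L), "temperature_K"),
      ksv_Minv = vapply(fits, `[[`, numeric(1L), "ksv_Minv"))
  }
  if (anyDuplicated(tab$temperature_K)) {
    stop("duplicate temperatures", call. = FALSE)
  }
  tab <- tab[order(tab$temperature_K), , drop = FALSE]
  if (nrow(tab) < 3L) stop("need Ksv at >= 3 temperatures", call. = FALSE)
  k <- tab$ksv_Minv
  if (any(k <= 0)) {
    label <- "indeterminate"
  } else {
    d <- diff(k) / k[-length(k)]
    total <- (k[length(k)] - k[1L]) / k[1L]
    label <- if (all(d > -rel_threshold) && total > rel_threshold) {
      "dynamic"
    } else if (all(d < rel_threshold) && total < -rel_threshold) {
      "static"
    } else {
      "indeterminate"
    }
  }
  structure(list(label = label, ksv_by_T = tab,
                 rel_change_threshold = rel_threshold),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("<mechanism: %s (threshold %.2g)>\n", x$label,
              x$rel_change_threshold))
  invisible(x)
}

#' Double-logarithmic (modified Stern-Volmer) binding fit
#'
#' Fits `log10((F0 - F)/F) = log10(Kb) + n * log10([Q])` by OLS over the
#' `Q > 0` points, yielding the apparent binding constant `Kb` (from the
#' intercept) and the apparent number of binding sites `n` (the slope).
#' Points with `F >= F0` (no measurable quenching) are dropped with a
#' warning; fewer than 3 surviving points is an error.
#'
#' @param series a [titration_series()].
#' @return an object of class `binding_fit`: `kb_Minv`, `n_sites`, `r2`,
#'   `temperature_K`, `n_points`.
#' @examples
#' ts <- simulate_titration(truth_params("hill_binding", kb_Minv = 1.6e4,
#'                                       n_sites = 1.1))
#' double_log_fit(ts)
#' @export
double_log_fit <- function(series) {
  stopifnot(is_titration_series(series))
  f0 <- titration_f0(series)
  pts <- series$points[series$points$Q_molar > 0, , drop = FALSE]
  bad <- pts$F >= f0
  if (any(bad)) {
    warning(sprintf("dropping %d point(s) with F >= F0 (no quenching)",
                    sum(bad)), call. = FALSE)
    pts <- pts[!bad, , drop = FALSE]
  }
  if (nrow(pts) < 3L) {
    stop("fewer than 3 usable points for the double-log fit", call. = FALSE)
  }
  fit <- ols_line(log10(pts$Q_molar), log10((f0 - pts$F) / pts$F))
  structure(list(kb_Minv = 10^fit$intercept, n_sites = fit$slope,
                 r2 = fit$r2, temperature_K = series$temperature_K,
                 n_points = fit$n),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit: Kb = %.4g 1/M, n = %.3f, R2 = %.4f, T = %g K>\n",
              x$kb_Minv, x$n_sites, x$r2, x$temperature_K))
  invisible(x)
}

#' Classify a binding constant against the reversible-transport range
#'
#' Drugs must bind serum albumin reversibly to be stored and distributed;
#' binding constants in 1e4 to 15e4 1/M (boundaries inclusive) indicate
#' average affinity and reversible complexation.
#'
#' @param kb_Minv binding constant, 1/M (> 0).
#' @return one of `"below_reversible_range"`, `"reversible_transport_range"`,
#'   `"above_reversible_range"`.
#' @examples
#' classify_affinity(1.60e4)
#' @export
classify_affinity <- function(kb_Minv) {
  check_number(kb_Minv, "kb_Minv", positive = TRUE)
  if (kb_Minv < 1e4) "below_reversible_range"
  else if (kb_Minv <= 15e4) "reversible_transport_range"
  else "above_reversible_range"
}

#' Competitive site-marker displacement analysis
#'
#' Compares the ligand's binding constant measured alone (`kb_free`) with
#' the constants measured in the presence of site-specific marker drugs
#' (e.g. ranitidine for Sudlow site I, ibuprofen for site II). The marker
#' producing the largest relative reduction `r_i = 1 - kb_i / kb_free`
#' identifies the shared binding site; if the top two reductions differ by
#' less than `tie_tol` the call is `"indeterminate"`.
#'
#' @param kb_free binding constant without marker, 1/M (> 0).
#' @param markers data frame with columns `marker`, `kb_Minv`, `site`.
#' @param tie_tol minimum separation of the top two reductions
#'   (default 0.05).
#' @return an object of class `site_assignment`: `assigned_site`, `kb_free`,
#'   `table` (markers with their reductions), `tie_tol`.
#' @examples
#' site_marker_analysis(1.60e4, data.frame(
#'   marker = c("ranitidine", "ibuprofen"),
#'   kb_Minv = c(1.16e4, 0.91e4),
#'   site = c("site I", "site II")))
#' @export
site_marker_analysis <- function(kb_free, markers, tie_tol = 0.05) {
  check_number(kb_free, "kb_free", positive = TRUE)
  markers <- as.data.frame(markers)
  stopifnot(all(c("marker", "kb_Minv", "site") %in% names(markers)),
            nrow(markers) >= 1L)
  if (any(markers$kb_Minv <= 0)) {
    stop("marker binding constants must be > 0", call. = FALSE)
  }
  markers$reduction <- 1 - markers$kb_Minv / kb_free
  ord <- order(-markers$reduction)
  markers <- markers[ord, , drop = FALSE]
  assigned <- markers$site[1L]
  if (nrow(markers) >= 2L &&
      (markers$reduction[1L] - markers$reduction[2L]) < tie_tol) {
    assigned <- "indeterminate"
  }
  structure(list(assigned_site = assigned, kb_free = kb_free,
                 table = markers, tie_tol = tie_tol),
            class = "site_assignment")
}

#' @export
print.site_assignment <- function(x, ...) {
  cat(sprintf("<site_assignment: %s>\n", x$assigned_site))
  print(x$table, row.names = FALSE)
  invisible(x)
}
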