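#' Default study design for the simulator
#'
#' The generator defaults mirror the experimental design the analysis is
#' meant for: serum albumin at 5 uM titrated with a quencher over 0-128 uM
#' (a doubling ladder), excitation at 280 nm, emission read at 345 nm, and
#' temperatures 298, 303, 308 and 318 K.
#'
#' @return named list with `protein_conc_M`, `q_grid_M`, `temperatures_K`,
#'   `excitation_nm`, `observation_nm`.
#' @export
study_design <- function() {
  list(protein_conc_M = 5e-6,
       q_grid_M = c(0, 2, 4, 8, 16, 32, 64, 128) * 1e-6,
       temperatures_K = c(298, 303, 308, 318),
       excitation_nm = 280,
       observation_nm = 345)
}

#' Ground-truth parameters for simulated quenching data
#'
#' Bundles the generative model and its constants for [simulate_titration()]
#' and [simulate_emission_spectrum()]. Models:
#' \describe{
#'   \item{dynamic}{collisional quenching, `F = F0 / (1 + ksv * Q)`}
#'   \item{static}{ground-state complexation with association constant `ka`,
#'     same Stern-Volmer form at a single temperature: `F = F0 / (1 + ka * Q)`}
#'   \item{combined}{`F0/F = (1 + ksv * Q) * (1 + ka * Q)`}
#'   \item{hill_binding}{`(F0 - F)/F = kb * Q^n`, the double-log binding
#'     model}
#' }
#' Noise is multiplicative Gaussian per point: `F * (1 + eps)`,
#' `eps ~ N(0, noise_rel_sigma)`, seeded and independent per point, matching
#' photomultiplier noise that scales with signal.
#'
#' @param model one of `"dynamic"`, `"static"`, `"combined"`,
#'   `"hill_binding"`.
#' @param ksv_Minv Stern-Volmer constant, 1/M (dynamic, combined).
#' @param ka_Minv association constant, 1/M (static, combined).
#' @param kb_Minv,n_sites binding constant (1/M^n) and site count
#'   (hill_binding).
#' @param f0 unquenched baseline intensity (arbitrary units).
#' @param band_center_start_nm,band_center_end_nm emission band centre at
#'   zero and at maximal quenching (defaults 345 and 331 nm).
#' @param band_sigma_nm Gaussian band width, nm.
#' @param noise_rel_sigma relative noise SD, in [0, 0.2).
#' @param seed integer RNG seed.
#' @return an object of class `truth_params`.
#' @export
truth_params <- function(model = c("dynamic", "static", "combined",
                                   "hill_binding"),
                         ksv_Minv = NULL, ka_Minv = NULL, kb_Minv = NULL,
                         n_sites = NULL, f0 = 1000,
                         band_center_start_nm = 345,
                         band_center_end_nm = 331, band_sigma_nm = 12,
                         noise_rel_sigma = 0, seed = 1L) {
  model <- match.arg(model)
  need <- switch(model,
                 dynamic = "ksv_Minv",
                 static = "ka_Minv",
                 combined = c("ksv_Minv", "ka_Minv"),
                 hill_binding = c("kb_Minv", "n_sites"))
  vals <- list(ksv_Minv = ksv_Minv, ka_Minv = ka_Minv, kb_Minv = kb_Minv,
               n_sites = n_sites)
  for (nm in need) {
    if (is.null(vals[[nm]])) {
      stop(sprintf("model `%s` requires `%s`", model, nm), call. = FALSE)
    }
    if (vals[[nm]] < 0) {
      stop(sprintf("`%s` must be >= 0", nm), call. = FALSE)
    }
  }
  extra <- setdiff(names(vals)[!vapply(vals, is.null, logical(1L))], need)
  if (length(extra)) {
    stop(sprintf("model `%s` does not use: %s", model,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  check_number(f0, "f0", positive = TRUE)
  check_number(band_sigma_nm, "band_sigma_nm", positive = TRUE)
  if (noise_rel_sigma < 0 || noise_rel_sigma >= 0.2) {
    stop("noise_rel_sigma must be in [0, 0.2)", call. = FALSE)
  }
  structure(list(model = model, ksv_Minv = ksv_Minv, ka_Minv = ka_Minv,
                 kb_Minv = kb_Minv, n_sites = n_sites, f0 = f0,
                 band_center_start_nm = band_center_start_nm,
                 band_center_end_nm = band_center_end_nm,
                 band_sigma_nm = band_sigma_nm,
                 noise_rel_sigma = noise_rel_sigma,
                 seed = as.integer(seed)),
            class = "truth_params")
}

# Noise-free model intensity at concentrations Q.
model_intensity <- function(p, Q) {
  switch(p$model,
         dynamic = p$f0 / (1 + p$ksv_Minv * Q),
         static = p$f0 / (1 + p$ka_Minv * Q),
         combined = p$f0 / ((1 + p$ksv_Minv * Q) * (1 + p$ka_Minv * Q)),
         hill_binding = p$f0 / (1 + p$kb_Minv * Q^p$n_sites))
}

#' Simulate a fluorescence quenching titration
#'
#' Generates a [titration_series()] from known ground truth: intensities from
#' the model in `p` (see [truth_params()]), each multiplied by an independent
#' seeded Gaussian factor `1 + eps`. With `noise_rel_sigma = 0` every point
#' satisfies the defining model equation exactly.
#'
#' @param p a [truth_params()].
#' @param q_grid quencher concentrations in mol/L, starting at 0, strictly
#'   increasing; defaults to the doubling ladder of [study_design()].
#' @param temperature_K,protein_conc_M design metadata carried on the series.
#' @return a [titration_series()].
#' @examples
#' p <- truth_params("dynamic", ksv_Minv = 5e4)
#' ts <- simulate_titration(p)
#' stern_volmer_fit(ts)$ksv_Minv
#' @export
simulate_titration <- function(p, q_grid = study_design()$q_grid_M,
                               temperature_K = 298, protein_conc_M = 5e-6) {
  stopifnot(inherits(p, "truth_params"))
  if (q_grid[1L] != 0 || any(diff(q_grid) <= 0)) {
    stop("q_grid must start at 0 and be strictly increasing", call. = FALSE)
  }
  f <- model_intensity(p, q_grid)
  f <- with_seed(p$seed, {
    f * (1 + stats::rnorm(length(f), 0, p$noise_rel_sigma))
  })
  titration_series(Q = q_grid, F = f, protein_conc_M = protein_conc_M,
                   temperature_K = temperature_K,
                   excitation_nm = study_design()$excitation_nm,
                   observation_nm = study_design()$observation_nm)
}

#' Simulate an emission spectrum at one quencher concentration
#'
#' A Gaussian emission band whose height is the model intensity for `Q`
#' (shared kernel with [simulate_titration()]) and whose centre moves
#' linearly from `band_center_start_nm` to `band_center_end_nm` as the
#' quenched fraction `(F0 - F)/F0` goes from 0 to its value at `q_max`.
#' This emulates the blue shift of the protein emission band under
#' progressive quenching.
#'
#' @param p a [truth_params()].
#' @param Q quencher concentration, mol/L.
#' @param grid emission wavelength grid, nm; must cover both band centres.
#' @param q_max concentration at which the band centre reaches
#'   `band_center_end_nm` (default 128 uM, the design endpoint).
#' @return an emission [spectrum()].
#' @export
simulate_emission_spectrum <- function(p, Q, grid = seq(250, 600, by = 1),
                                       q_max = 1.28e-4) {
  stopifnot(inherits(p, "truth_params"))
  lo <- min(p$band_center_start_nm, p$band_center_end_nm)
  hi <- max(p$band_center_start_nm, p$band_center_end_nm)
  if (min(grid) > lo || max(grid) < hi) {
    stop("grid must cover both band centres", call. = FALSE)
  }
  f <- model_intensity(p, Q)
  qf_max <- (p$f0 - model_intensity(p, q_max)) / p$f0
  qf <- (p$f0 - f) / p$f0
  frac <- if (qf_max > 0) qf / qf_max else 0
  center <- p$band_center_start_nm +
    frac * (p$band_center_end_nm - p$band_center_start_nm)
  y <- f * exp(-(grid - center)^2 / (2 * p$band_sigma_nm^2))
  y <- with_seed(p$seed, {
    y * (1 + stats::rnorm(length(y), 0, p$noise_rel_sigma))
  })
  spectrum("emission", x = grid, y = y, excitation_nm = 280,
           ligand_conc_M = Q,
           label = sprintf("simulated emission, Q = %.3g M", Q))
}

#' Simulate an excitation-emission matrix
#'
#' Sum of 2-D Gaussian blobs, optionally with a first-order Rayleigh scatter
#' ridge along `em == ex`, plus optional multiplicative noise. Deterministic
#' given the seed.
#'
#' @param blobs data frame with columns `ex`, `em`, `height`, `sigma`
#'   (centres inside the grids); zero rows give a flat zero EEM.
#' @param ex_nm,em_nm excitation and emission grids (defaults: ex 230-330,
#'   em 280-420, 2 nm steps).
#' @param scatter add a Rayleigh ridge along `em == ex`?
#' @param scatter_sigma ridge width, nm.
#' @param noise_rel_sigma relative noise SD.
#' @param seed integer RNG seed.
#' @return an [eem()].
#' @export
simulate_eem <- function(blobs, ex_nm = seq(230, 330, by = 2),
                         em_nm = seq(280, 420, by = 2), scatter = FALSE,
                         scatter_sigma = 5, noise_rel_sigma = 0, seed = 1L) {
  blobs <- as.data.frame(blobs)
  if (nrow(blobs) > 0) {
    stopifnot(all(c("ex", "em", "height", "sigma") %in% names(blobs)))
    if (any(blobs$ex < min(ex_nm) | blobs$ex > max(ex_nm) |
            blobs$em < min(em_nm) | blobs$em > max(em_nm))) {
      stop("blob centres must lie inside the grids", call. = FALSE)
    }
  }
  EX <- matrix(ex_nm, length(ex_nm), length(em_nm))
  EM <- matrix(em_nm, length(ex_nm), length(em_nm), byrow = TRUE)
  z <- matrix(0, length(ex_nm), length(em_nm))
  for (k in seq_len(nrow(blobs))) {
    z <- z + blobs$height[k] *
      exp(-((EX - blobs$ex[k])^2 + (EM - blobs$em[k])^2) /
            (2 * blobs$sigma[k]^2))
  }
  if (scatter) {
    ridge_height <- 1.5 * max(c(blobs$height, 1))
    z <- z + ridge_height * exp(-(EM - EX)^2 / (2 * scatter_sigma^2))
  }
  if (noise_rel_sigma > 0) {
    z <- with_seed(seed, {
      z * (1 + stats::rnorm(length(z), 0, noise_rel_sigma))
    })
    z[z < 0] <- 0
  }
  eem(ex_nm = ex_nm, em_nm = em_nm, z = z)
}

#' Thermodynamic ground truth for binding-constant temperature series
#'
#' @param dH_J_per_mol binding enthalpy, J/mol.
#' @param dS_J_per_mol_K binding entropy, J/(mol K).
#' @param temperatures_K at least 3 strictly increasing temperatures, K.
#' @return an object of class `thermo_truth`.
#' @export
thermo_truth <- function(dH_J_per_mol, dS_J_per_mol_K,
                         temperatures_K = study_design()$temperatures_K) {
  check_number(dH_J_per_mol, "dH_J_per_mol")
  check_number(dS_J_per_mol_K, "dS_J_per_mol_K")
  if (length(temperatures_K) < 3L || any(temperatures_K <= 0) ||
      any(diff(temperatures_K) <= 0)) {
    stop("need >= 3 strictly increasing positive temperatures", call. = FALSE)
  }
  structure(list(dH_J_per_mol = dH_J_per_mol,
                 dS_J_per_mol_K = dS_J_per_mol_K,
                 temperatures_K = temperatures_K),
            class = "thermo_truth")
}

#' Exact binding constants implied by a van't Hoff truth
#'
#' Inverts the van't Hoff relation: `Kb(T) = 10^(-dH / (2.303 R T) +
#' dS / (2.303 R))` with R = 8.314 J/(K mol), no noise. [vant_hoff_fit()] on
#' the output recovers the truth exactly.
#'
#' @param t a [thermo_truth()].
#' @return data frame with columns `temperature_K`, `kb_Minv`.
#' @export
simulate_kb_series <- function(t) {
  stopifnot(inherits(t, "thermo_truth"))
  T_K <- t$temperatures_K
  kb <- 10^(-t$dH_J_per_mol / (LOG10_FACTOR * R_GAS * T_K) +
              t$dS_J_per_mol_K / (LOG10_FACTOR * R_GAS))
  data.frame(temperature_K = T_K, kb_Minv = kb)
}

#' Simulate a far-UV circular dichroism spectrum of a helical protein
#'
#' Two negative Gaussian bands at 208 and 222 nm (the alpha-helix n->pi*
#' signature), scaled so that the 208 nm mean-residue ellipticity equals
#' `-(helix_percent/100 * 29000 + 4000)` deg cm^2 dmol^-1. The spectrum is
#' emitted in instrument units (mdeg) at the stated measurement conditions,
#' so [cd_estimate()] is a true round trip through the unit conversion.
#'
#' @param helix_percent alpha-helix content, 0-100.
#' @param grid wavelength grid, nm (default 200-260, 0.5 nm; includes 208).
#' @param noise_rel_sigma relative noise SD.
#' @param seed integer RNG seed.
#' @param protein_conc_M,n_residues,path_cm measurement conditions (defaults:
#'   2.5 uM, 583 residues, 0.1 cm).
#' @return a cd [spectrum()] with intensities in mdeg.
#' @export
simulate_cd_spectrum <- function(helix_percent, grid = seq(200, 260, by = 0.5),
                                 noise_rel_sigma = 0, seed = 1L,
                                 protein_conc_M = 2.5e-6, n_residues = 583,
                                 path_cm = 0.1) {
  if (!is.numeric(helix_percent) || length(helix_percent) != 1L ||
      is.na(helix_percent) || helix_percent < 0 || helix_percent > 100) {
    stop("helix_percent must be in [0, 100]", call. = FALSE)
  }
  if (min(grid) > 208 || max(grid) < 222) {
    stop("grid must cover the 208 and 222 nm bands", call. = FALSE)
  }
  mre_208 <- -(helix_percent / 100 * 29000 + 4000)
  # Band shape: 208 nm band plus a 222 nm band at 0.95 relative amplitude
  # (typical helix CD); normalised so the value at 208 nm is exactly 1.
  shape <- function(l) {
    exp(-(l - 208)^2 / (2 * 5.5^2)) + 0.95 * exp(-(l - 222)^2 / (2 * 6.5^2))
  }
  mre <- mre_208 * shape(grid) / shape(208)
  theta_mdeg <- mre * (10 * path_cm * protein_conc_M * n_residues)
  theta_mdeg <- with_seed(seed, {
    theta_mdeg * (1 + stats::rnorm(length(theta_mdeg), 0, noise_rel_sigma))
  })
  spectrum("cd", x = grid, y = theta_mdeg, protein_conc_M = protein_conc_M,
           label = sprintf("simulated CD, helix %.1f%%", helix_percent))
}
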