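#' Van't Hoff fit of binding constants across temperature
#'
#' Fits `log10(Kb) = -dH / (2.303 R T) + dS / (2.303 R)` by OLS of
#' `log10(Kb)` on `1/T`, with R = 8.314 J/(K mol): the binding enthalpy is
#' `dH = -slope * 2.303 * R` and the entropy `dS = intercept * 2.303 * R`.
#'
#' @param kb_by_T data frame with columns `temperature_K` (>= 3 strictly
#'   increasing values) and `kb_Minv` (> 0).
#' @return list with `dH_J_per_mol`, `dS_J_per_mol_K`, `r2`, `slope`,
#'   `intercept`, `n`.
#' @examples
#' vant_hoff_fit(data.frame(temperature_K = c(298, 303, 308, 318),
#'                          kb_Minv = c(1.60, 1.62, 1.69, 1.79) * 1e4))
#' @export
vant_hoff_fit <- function(kb_by_T) {
  kb_by_T <- as.data.frame(kb_by_T)
  stopifnot(all(c("temperature_K", "kb_Minv") %in% names(kb_by_T)))
  T_K <- kb_by_T$temperature_K
  kb <- kb_by_T$kb_Minv
  if (length(T_K) < 3L) {
    stop("van't Hoff fit needs >= 3 temperatures", call. = FALSE)
  }
  if (any(T_K <= 0) || any(diff(T_K) <= 0)) {
    stop("temperatures must be positive and strictly increasing",
         call. = FALSE)
  }
  if (any(kb <= 0)) stop("binding constants must be > 0", call. = FALSE)
  fit <- ols_line(1 / T_K, log10(kb))
  list(dH_J_per_mol = -fit$slope * LOG10_FACTOR * R_GAS,
       dS_J_per_mol_K = fit$intercept * LOG10_FACTOR * R_GAS,
       r2 = fit$r2, slope = fit$slope, intercept = fit$intercept, n = fit$n)
}

#' Gibbs free energy of binding
#'
#' `dG = dH - T * dS`, exact arithmetic. All energies in J/mol, entropy in
#' J/(mol K).
#'
#' @param dH_J_per_mol binding enthalpy, J/mol.
#' @param dS_J_per_mol_K binding entropy, J/(mol K).
#' @param T_K temperature, K (> 0); vectorised.
#' @return dG in J/mol.
#' @examples
#' gibbs(4500, 19, 298)  # -1162 J/mol
#' @export
gibbs <- function(dH_J_per_mol, dS_J_per_mol_K, T_K) {
  if (any(T_K <= 0)) stop("T_K must be > 0", call. = FALSE)
  dH_J_per_mol - T_K * dS_J_per_mol_K
}

#' Classify the dominant binding forces from the signs of dH and dS
#'
#' The standard sign rules for protein-ligand binding: positive dH and dS
#' indicate hydrophobic interactions; negative dH and dS indicate van der
#' Waals forces and hydrogen bonding; negative dH with positive dS indicates
#' electrostatic interactions. Values within the tolerances of zero give
#' `"indeterminate"`.
#'
#' @param dH_J_per_mol binding enthalpy, J/mol.
#' @param dS_J_per_mol_K binding entropy, J/(mol K).
#' @param tol_dH,tol_dS dead-band half-widths around zero (defaults 1 J/mol
#'   and 0.01 J/(mol K)).
#' @return one of `"hydrophobic"`, `"vdw_hbond"`, `"electrostatic"`,
#'   `"indeterminate"`.
#' @examples
#' classify_forces(4500, 19)  # hydrophobic
#' @export
classify_forces <- function(dH_J_per_mol, dS_J_per_mol_K, tol_dH = 1,
                            tol_dS = 0.01) {
  if (dH_J_per_mol > tol_dH && dS_J_per_mol_K > tol_dS) "hydrophobic"
  else if (dH_J_per_mol < -tol_dH && dS_J_per_mol_K < -tol_dS) "vdw_hbond"
  else if (dH_J_per_mol < -tol_dH && dS_J_per_mol_K > tol_dS) "electrostatic"
  else "indeterminate"
}

#' Is a binding process spontaneous?
#'
#' @param dG_J_per_mol Gibbs free energy, J/mol; vectorised.
#' @return `TRUE` where `dG < 0` (the boundary `dG == 0` is treated as
#'   non-spontaneous).
#' @export
spontaneity <- function(dG_J_per_mol) dG_J_per_mol < 0

#' Full thermodynamic analysis of a binding-constant temperature series
#'
#' Runs [vant_hoff_fit()], evaluates [gibbs()] at each input temperature,
#' and attaches the force classification and spontaneity calls.
#'
#' @inheritParams vant_hoff_fit
#' @param tol_dH,tol_dS tolerances passed to [classify_forces()].
#' @return an object of class `thermo_fit`: `dH_J_per_mol`,
#'   `dS_J_per_mol_K`, `r2`, `dG_by_T` (data frame `temperature_K`,
#'   `dG_J_per_mol`, `spontaneous`), `force_label`.
#' @export
thermo_analysis <- function(kb_by_T, tol_dH = 1, tol_dS = 0.01) {
  fit <- vant_hoff_fit(kb_by_T)
  T_K <- sort(as.data.frame(kb_by_T)$temperature_K)
  dG <- gibbs(fit$dH_J_per_mol, fit$dS_J_per_mol_K, T_K)
  structure(list(dH_J_per_mol = fit$dH_J_per_mol,
                 dS_J_per_mol_K = fit$dS_J_per_mol_K, r2 = fit$r2,
                 dG_by_T = data.frame(temperature_K = T_K,
                                      dG_J_per_mol = dG,
                                      spontaneous = spontaneity(dG)),
                 force_label = classify_forces(fit$dH_J_per_mol,
                                               fit$dS_J_per_mol_K,
                                               tol_dH, tol_dS)),
            class = "thermo_fit")
}

#' @export
print.thermo_fit <- function(x, ...) {
  cat(sprintf("<thermo_fit: dH = %.3f kJ/mol, dS = %.2f J/(mol K), %s>\n",
              x$dH_J_per_mol / 1000, x$dS_J_per_mol_K, x$force_label))
  print(x$dG_by_T, row.names = FALSE)
  invisible(x)
}

#' Check reported thermodynamic parameters against the van't Hoff fit
#'
#' Refits the binding constants and compares the fitted dH and dS with
#' externally reported values (e.g. from a publication or an instrument
#' report). A relative deviation above `rel_tol` raises the corresponding
#' discrepancy flag. This catches unit-scale inconsistencies such as an
#' entropy printed on the kJ scale in a J-scale column.
#'
#' @inheritParams vant_hoff_fit
#' @param dH_ref_J_per_mol,dS_ref_J_per_mol_K reported values, J/mol and
#'   J/(mol K).
#' @param rel_tol relative tolerance (default 0.1).
#' @return list: `fit` (the [vant_hoff_fit()] result), `dH_consistent`,
#'   `dS_consistent`, `dH_rel_dev`, `dS_rel_dev`.
#' @examples
#' kb <- data.frame(temperature_K = c(298, 303, 308, 318),
#'                  kb_Minv = c(1.60, 1.62, 1.69, 1.79) * 1e4)
#' vant_hoff_consistency(kb, 4500, 19)$dS_consistent  # FALSE: fit gives ~96
#' @export
vant_hoff_consistency <- function(kb_by_T, dH_ref_J_per_mol,
                                  dS_ref_J_per_mol_K, rel_tol = 0.1) {
  fit <- vant_hoff_fit(kb_by_T)
  rel_dev <- function(est, ref) {
    if (ref == 0) abs(est) else abs(est - ref) / abs(ref)
  }
  dH_dev <- rel_dev(fit$dH_J_per_mol, dH_ref_J_per_mol)
  dS_dev <- rel_dev(fit$dS_J_per_mol_K, dS_ref_J_per_mol_K)
  list(fit = fit, dH_consistent = dH_dev <= rel_tol,
       dS_consistent = dS_dev <= rel_tol,
       dH_rel_dev = dH_dev, dS_rel_dev = dS_dev)
}
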