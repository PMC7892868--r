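#' Default configuration for a full simulated binding study
#'
#' The default truth encodes the reference study design: Stern-Volmer
#' constants {4.95, 5.02, 5.53, 6.16}e4 1/M and binding constants
#' {1.60, 1.62, 1.69, 1.79}e4 1/M (n = 1.1) at 298/303/308/318 K, noiseless,
#' with site-marker displacement constants 1.16e4 (ranitidine, site I) and
#' 0.91e4 (ibuprofen, site II), and reported thermodynamic parameters
#' dH = 4500 J/mol, dS = 19 J/(mol K) for the consistency check.
#'
#' @param seed integer seed for all simulated data.
#' @return a named configuration list accepted by [run_study()].
#' @export
default_study_config <- function(seed = 1L) {
  d <- study_design()
  list(
    seed = as.integer(seed),
    tau0_s = 1e-8,
    noise_rel_sigma = 0,
    f0 = 1000,
    q_grid_M = d$q_grid_M,
    truth = list(
      ksv_by_T = data.frame(temperature_K = d$temperatures_K,
                            ksv_Minv = c(4.95, 5.02, 5.53, 6.16) * 1e4),
      kb_by_T = data.frame(temperature_K = d$temperatures_K,
                           kb_Minv = c(1.60, 1.62, 1.69, 1.79) * 1e4),
      n_sites = 1.1),
    site_markers = data.frame(
      marker = c("ranitidine", "ibuprofen"),
      kb_Minv = c(1.16e4, 0.91e4),
      site = c("site I", "site II")),
    reported_thermo = list(dH_J_per_mol = 4500, dS_J_per_mol_K = 19),
    probes = TRUE,
    mechanism_rel_threshold = 0.02,
    site_tie_tol = 0.05)
}

#' Read a study configuration from JSON or YAML
#'
#' Missing keys fall back to [default_study_config()]. Data-frame blocks
#' (`truth$ksv_by_T`, `truth$kb_by_T`, `site_markers`) may be given as
#' column lists.
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @param seed seed used for defaults when the file does not set one.
#' @return a configuration list.
#' @export
read_study_config <- function(path, seed = 1L) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = ,
                yml = yaml::read_yaml(path),
                stop("config must be .json, .yaml or .yml", call. = FALSE))
  cfg <- utils::modifyList(default_study_config(seed), raw)
  for (blk in c("ksv_by_T", "kb_by_T")) {
    if (!is.null(cfg$truth[[blk]])) {
      cfg$truth[[blk]] <- as.data.frame(cfg$truth[[blk]])
    }
  }
  if (!is.null(cfg$site_markers)) {
    cfg$site_markers <- as.data.frame(cfg$site_markers)
  }
  cfg
}

#' Run the full simulated binding study
#'
#' Orchestrates the whole workflow from a configuration: simulates a
#' quenching titration and a binding titration per temperature from the
#' configured truth, fits Stern-Volmer and double-log models, classifies the
#' quenching mechanism, runs the van't Hoff analysis with force and
#' spontaneity calls and the reported-value consistency check, performs
#' site-marker displacement analysis, and (optionally) simulates and reads
#' the conformational probes. Deterministic given the configuration and seed.
#'
#' @param config configuration list; see [default_study_config()].
#' @return an object of class `study_report`.
#' @examples
#' rep <- run_study(default_study_config(seed = 1))
#' rep$quenching_table
#' @export
run_study <- function(config = default_study_config()) {
  defaults <- default_study_config(config$seed %||% 1L)
  cfg <- config
  for (nm in setdiff(names(defaults), names(cfg))) cfg[[nm]] <- defaults[[nm]]
  seed <- as.integer(cfg$seed)
  # A stage is skipped by setting its block to NA (an absent key takes the
  # default; a NULL element would simply vanish from an R list).
  as_block <- function(x) if (is.data.frame(x)) x else NULL
  ksv_tab <- as_block(cfg$truth$ksv_by_T)
  kb_tab <- as_block(cfg$truth$kb_by_T)
  cfg$site_markers <- as_block(cfg$site_markers)
  if (!is.list(cfg$reported_thermo)) cfg$reported_thermo <- NULL

  # Stern-Volmer stage: one quenching titration per temperature.
  sv_fits <- list()
  if (!is.null(ksv_tab)) {
    sv_fits <- lapply(seq_len(nrow(ksv_tab)), function(i) {
      p <- truth_params("dynamic", ksv_Minv = ksv_tab$ksv_Minv[i],
                        f0 = cfg$f0, noise_rel_sigma = cfg$noise_rel_sigma,
                        seed = seed + i)
      stern_volmer_fit(
        simulate_titration(p, q_grid = cfg$q_grid_M,
                           temperature_K = ksv_tab$temperature_K[i]),
        tau0_s = cfg$tau0_s)
    })
  }

  # Binding stage: one double-log titration per temperature.
  dl_fits <- list()
  if (!is.null(kb_tab)) {
    dl_fits <- lapply(seq_len(nrow(kb_tab)), function(i) {
      p <- truth_params("hill_binding", kb_Minv = kb_tab$kb_Minv[i],
                        n_sites = cfg$truth$n_sites %||% 1,
                        f0 = cfg$f0, noise_rel_sigma = cfg$noise_rel_sigma,
                        seed = seed + 100L + i)
      double_log_fit(
        simulate_titration(p, q_grid = cfg$q_grid_M,
                           temperature_K = kb_tab$temperature_K[i]))
    })
  }

  if (is.null(ksv_tab) && is.null(kb_tab)) {
    stop("config must provide truth$ksv_by_T and/or truth$kb_by_T",
         call. = FALSE)
  }
  temps <- if (!is.null(ksv_tab)) ksv_tab$temperature_K
           else kb_tab$temperature_K
  pick <- function(fits, field) {
    if (!length(fits)) return(rep(NA_real_, length(temps)))
    vapply(fits, function(f) f[[field]] %||% NA_real_, numeric(1L))
  }
  quenching_table <- data.frame(
    temperature_K = temps,
    ksv_Minv = pick(sv_fits, "ksv_Minv"),
    kq_Minv_s = pick(sv_fits, "kq_Minv_s"),
    r2_sv = pick(sv_fits, "r2"),
    kb_Minv = pick(dl_fits, "kb_Minv"),
    n_sites = pick(dl_fits, "n_sites"),
    r2_dl = pick(dl_fits, "r2"))
  flags <- if (length(sv_fits)) {
    vapply(sv_fits, `[[`, character(1L), "flag")
  } else character(0)

  mechanism <- if (length(sv_fits) >= 3L && all(flags == "ok")) {
    classify_mechanism(sv_fits, rel_threshold = cfg$mechanism_rel_threshold)
  } else NULL

  thermo <- NULL
  consistency <- NULL
  affinity <- NULL
  if (length(dl_fits) >= 3L) {
    fitted_kb <- data.frame(
      temperature_K = vapply(dl_fits, `[[`, numeric(1L), "temperature_K"),
      kb_Minv = vapply(dl_fits, `[[`, numeric(1L), "kb_Minv"))
    thermo <- thermo_analysis(fitted_kb)
    affinity <- classify_affinity(fitted_kb$kb_Minv[1L])
    if (!is.null(cfg$reported_thermo)) {
      consistency <- vant_hoff_consistency(
        fitted_kb, cfg$reported_thermo$dH_J_per_mol,
        cfg$reported_thermo$dS_J_per_mol_K)
    }
  }

  sites <- NULL
  if (!is.null(cfg$site_markers) && length(dl_fits)) {
    sites <- site_marker_analysis(dl_fits[[1L]]$kb_Minv, cfg$site_markers,
                                  tie_tol = cfg$site_tie_tol)
  }

  probes <- if (isTRUE(cfg$probes) && !is.null(ksv_tab) &&
                ksv_tab$ksv_Minv[1L] > 0) {
    simulate_probe_summary(cfg, seed)
  } else NULL

  structure(list(quenching_table = quenching_table,
                 sv_flags = flags,
                 mechanism = mechanism,
                 thermo = thermo,
                 thermo_consistency = consistency,
                 affinity = affinity,
                 site_assignment = sites,
                 conformational = probes,
                 provenance = list(seed = seed,
                                   config_hash = config_hash(cfg),
                                   package_version =
                                     as.character(utils::packageVersion("specbind")))),
            class = "study_report")
}

# Simulate the conformational probe battery and summarise it.
simulate_probe_summary <- function(cfg, seed) {
  p <- truth_params("dynamic", ksv_Minv = cfg$truth$ksv_by_T$ksv_Minv[1L],
                    f0 = cfg$f0, noise_rel_sigma = cfg$noise_rel_sigma,
                    seed = seed + 200L)
  q_top <- max(cfg$q_grid_M)
  em_free <- simulate_emission_spectrum(p, 0, q_max = q_top)
  em_bound <- simulate_emission_spectrum(p, q_top, q_max = q_top)
  emission_shift <- band_shift(em_free, em_bound, window = c(300, 400))

  # Synchronous channels: the tryptophan blob (on the delta = 60 nm line)
  # moves from ex 278 to 275 nm on binding; the tyrosine blob (on the
  # delta = 15 nm line) loses intensity but does not move.
  ex_grid <- seq(240, 330, by = 1)
  em_grid <- seq(250, 420, by = 1)
  eem_free <- simulate_eem(
    data.frame(ex = c(278, 295), em = c(338, 310), height = c(100, 60),
               sigma = c(12, 10)),
    ex_nm = ex_grid, em_nm = em_grid,
    noise_rel_sigma = cfg$noise_rel_sigma, seed = seed + 201L)
  eem_bound <- simulate_eem(
    data.frame(ex = c(275, 295), em = c(335, 310), height = c(70, 45),
               sigma = c(12, 10)),
    ex_nm = ex_grid, em_nm = em_grid,
    noise_rel_sigma = cfg$noise_rel_sigma, seed = seed + 202L)
  sync60 <- band_shift(synchronous_scan(eem_free, 60),
                       synchronous_scan(eem_bound, 60),
                       window = c(250, 310))
  sync15 <- band_shift(synchronous_scan(eem_free, 15),
                       synchronous_scan(eem_bound, 15),
                       window = c(270, 320))

  # Hypochromic UV trend at the 280 nm aromatic band.
  uv_grid <- seq(240, 320, by = 1)
  uv <- lapply(0:4, function(i) {
    spectrum("absorbance", uv_grid,
             (1 - 0.04 * i) * 0.5 * exp(-(uv_grid - 280)^2 / (2 * 15^2)))
  })
  uv_trend <- absorbance_trend(uv)

  # Amide-I infrared band shift 1636 -> 1638 cm^-1.
  ir_grid <- seq(1500, 1750, by = 1)
  ir_band <- function(center) {
    spectrum("ir", ir_grid, exp(-(ir_grid - center)^2 / (2 * 20^2)))
  }
  ir_shift <- band_shift(ir_band(1636), ir_band(1638))

  # Helix-content change from simulated CD spectra.
  helix_free <- cd_estimate(simulate_cd_spectrum(
    56.8, noise_rel_sigma = cfg$noise_rel_sigma, seed = seed + 203L))
  helix_bound <- cd_estimate(simulate_cd_spectrum(
    50.8, noise_rel_sigma = cfg$noise_rel_sigma, seed = seed + 204L))

  conformational_report(
    emission_shift_nm = emission_shift,
    sync15_shift_nm = sync15,
    sync60_shift_nm = sync60,
    uv_trend = uv_trend,
    ir_shifts_cm1 = c(amide_I = ir_shift),
    cd_helix_change = helix_bound$helix_percent - helix_free$helix_percent)
}

# Deterministic hash of the canonical JSON form of the configuration.
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' @export
print.study_report <- function(x, ...) {
  cat(render_tables(x))
  invisible(x)
}

#' Render a study report as markdown tables
#'
#' Produces a quenching/binding table (one row per temperature: Ksv, Kq, R2,
#' Kb, n, R2) and a thermodynamics block (dH, dS, dG per temperature, force
#' and spontaneity calls), followed by the mechanism, affinity, site and
#' conformational summaries. Constants are displayed to 3 significant
#' digits; energies on the kJ scale with 3 decimals.
#'
#' @param report a `study_report` from [run_study()].
#' @return a single markdown character string.
#' @export
render_tables <- function(report) {
  stopifnot(inherits(report, "study_report"))
  qt <- report$quenching_table
  lines <- c(
    "## Quenching and binding parameters",
    "",
    "| T (K) | Ksv (1/M) | Kq (1/(M s)) | R2 | Kb (1/M) | n | R2 |",
    "|---|---|---|---|---|---|---|",
    vapply(seq_len(nrow(qt)), function(i) {
      sprintf("| %g | %s | %s | %s | %s | %s | %s |",
              qt$temperature_K[i], fmt_sig3(qt$ksv_Minv[i]),
              fmt_sig3(qt$kq_Minv_s[i]), fmt_sig3(qt$r2_sv[i]),
              fmt_sig3(qt$kb_Minv[i]), fmt_sig3(qt$n_sites[i]),
              fmt_sig3(qt$r2_dl[i]))
    }, character(1L)),
    "")
  if (length(report$sv_flags) && any(report$sv_flags != "ok")) {
    lines <- c(lines, sprintf("Degenerate quenching fits flagged: %s.",
                              paste(unique(report$sv_flags[report$sv_flags != "ok"]),
                                    collapse = ", ")), "")
  }
  if (!is.null(report$mechanism)) {
    lines <- c(lines, sprintf("Quenching mechanism: **%s**.",
                              report$mechanism$label), "")
  }
  if (!is.null(report$affinity)) {
    lines <- c(lines, sprintf("Affinity class at the lowest temperature: %s.",
                              report$affinity), "")
  }
  if (is.null(report$thermo)) {
    lines <- c(lines, "## Thermodynamics", "",
               "Thermodynamic analysis omitted: no usable binding-constant series.",
               "")
  } else {
    th <- report$thermo
    lines <- c(lines,
      "## Thermodynamics",
      "",
      sprintf("dH = %s kJ/mol, dS = %s J/(mol K) (= %s kJ/(mol K)), R2 = %s",
              fmt_kj(th$dH_J_per_mol), fmt_sig3(th$dS_J_per_mol_K),
              fmt_sig3(th$dS_J_per_mol_K / 1000), fmt_sig3(th$r2)),
      "",
      "| T (K) | dG (kJ/mol) | spontaneous |",
      "|---|---|---|",
      vapply(seq_len(nrow(th$dG_by_T)), function(i) {
        sprintf("| %g | %s | %s |", th$dG_by_T$temperature_K[i],
                fmt_kj(th$dG_by_T$dG_J_per_mol[i]),
                ifelse(th$dG_by_T$spontaneous[i], "yes", "no"))
      }, character(1L)),
      "",
      sprintf("Dominant binding forces: **%s**.", th$force_label),
      "")
    if (!is.null(report$thermo_consistency)) {
      cc <- report$thermo_consistency
      lines <- c(lines, sprintf(
        "Reported-value check: dH %s (rel. dev. %s), dS %s (rel. dev. %s).",
        ifelse(cc$dH_consistent, "consistent", "DISCREPANT"),
        fmt_sig3(cc$dH_rel_dev),
        ifelse(cc$dS_consistent, "consistent", "DISCREPANT"),
        fmt_sig3(cc$dS_rel_dev)), "")
    }
  }
  if (!is.null(report$site_assignment)) {
    lines <- c(lines, sprintf("Site-marker displacement assigns binding to: **%s**.",
                              report$site_assignment$assigned_site), "")
  }
  if (!is.null(report$conformational)) {
    cr <- report$conformational
    lines <- c(lines, "## Conformational probes", "")
    for (nm in names(cr$probes)) {
      p <- cr$probes[[nm]]
      if (is.null(p$value)) next
      lines <- c(lines, sprintf("- %s = %s: %s", nm,
                                paste(format(p$value, digits = 4),
                                      collapse = ", "), p$reading))
    }
    lines <- c(lines, "")
  }
  paste(lines, collapse = "\n")
}

#' Write a study report to disk
#'
#' Writes the full report as JSON (lossless, `digits = NA`) and the rendered
#' markdown tables alongside it.
#'
#' @param report a `study_report`.
#' @param json_path output JSON path.
#' @param md_path output markdown path; default swaps the extension.
#' @return invisibly, `json_path`.
#' @export
write_report <- function(report, json_path,
                         md_path = paste0(tools::file_path_sans_ext(json_path),
                                          ".md")) {
  stopifnot(inherits(report, "study_report"))
  jsonlite::write_json(unclass_deep(report), json_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")
  writeLines(render_tables(report), md_path)
  invisible(json_path)
}

# Strip S3 classes recursively so jsonlite serialises plainly.
unclass_deep <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    return(lapply(x, unclass_deep))
  }
  x
}
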