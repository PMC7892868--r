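#' Read and write spectra, titrations and EEMs as CSV + JSON sidecars
#'
#' All on-disk formats are plain text: a comma-separated CSV ("." decimal,
#' UTF-8, mandatory header) holding the numeric data, and a JSON sidecar
#' holding the metadata. `read_spectrum()` expects columns `x,y`;
#' the sidecar supplies `kind`, `x_unit` and the optional metadata fields.
#'
#' @param path CSV file path.
#' @param sidecar JSON sidecar path; defaults to `path` with a `.json`
#'   extension.
#' @return `read_spectrum()` returns a [spectrum()]; `write_spectrum()`
#'   invisibly returns the CSV path.
#' @seealso [read_titration()], [read_eem()]
#' @export
read_spectrum <- function(path, sidecar = sidecar_path(path)) {
  df <- read_xy_csv(path, c("x", "y"))
  bad <- which(diff(df$x) <= 0)
  if (length(bad)) {
    stop(sprintf("%s: grid not strictly increasing at data row %d (x = %g)",
                 path, bad[1L] + 1L, df$x[bad[1L] + 1L]), call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$kind)) {
    stop("sidecar ", sidecar, " is missing `kind`", call. = FALSE)
  }
  spectrum(kind = meta$kind, x = df$x, y = df$y,
           temperature_K = meta$temperature_K,
           excitation_nm = meta$excitation_nm,
           protein_conc_M = meta$protein_conc_M,
           ligand_conc_M = meta$ligand_conc_M,
           label = meta$label)
}

#' @rdname read_spectrum
#' @param s a [spectrum()].
#' @export
write_spectrum <- function(s, path, sidecar = sidecar_path(path)) {
  stopifnot(is_spectrum(s))
  write_xy_csv(data.frame(x = s$x, y = s$y), path)
  meta <- c(list(kind = s$kind, x_unit = x_unit(s)), s$meta)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write titration series
#'
#' The CSV carries columns `Q_molar,F`; the sidecar carries the design
#' metadata (protein concentration, temperature, excitation and observation
#' wavelengths).
#'
#' @inheritParams read_spectrum
#' @return `read_titration()` returns a [titration_series()].
#' @export
read_titration <- function(path, sidecar = sidecar_path(path)) {
  df <- read_xy_csv(path, c("Q_molar", "F"))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  titration_series(Q = df$Q_molar, F = df$F,
                   protein_conc_M = meta$protein_conc_M %||% 5e-6,
                   temperature_K = meta$temperature_K %||% 298,
                   excitation_nm = meta$excitation_nm %||% 280,
                   observation_nm = meta$observation_nm %||% 345)
}

#' @rdname read_titration
#' @param series a [titration_series()].
#' @export
write_titration <- function(series, path, sidecar = sidecar_path(path)) {
  stopifnot(is_titration_series(series))
  write_xy_csv(series$points, path)
  meta <- list(protein_conc_M = series$protein_conc_M,
               temperature_K = series$temperature_K,
               excitation_nm = series$excitation_nm,
               observation_nm = series$observation_nm)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write excitation-emission matrices
#'
#' The CSV layout is a matrix block: the first row holds the emission grid
#' (first cell blank), each following row holds one excitation wavelength in
#' its first column and the intensities across the emission grid.
#'
#' @inheritParams read_spectrum
#' @return `read_eem()` returns an [eem()].
#' @export
read_eem <- function(path) {
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character")
  if (nrow(raw) < 2L || ncol(raw) < 2L) {
    stop("EEM CSV must have a grid row, a grid column and data", call. = FALSE)
  }
  em <- as.numeric(raw[1L, -1L])
  ex <- as.numeric(raw[-1L, 1L])
  z <- matrix(as.numeric(as.matrix(raw[-1L, -1L])),
              nrow = length(ex), ncol = length(em))
  if (anyNA(em) || anyNA(ex) || anyNA(z)) {
    stop("non-numeric cells in EEM CSV ", path, call. = FALSE)
  }
  eem(ex_nm = ex, em_nm = em, z = z)
}

#' @rdname read_eem
#' @param e an [eem()].
#' @export
write_eem <- function(e, path) {
  stopifnot(is_eem(e))
  num <- function(v) format(v, digits = 17, trim = TRUE, scientific = FALSE)
  header <- paste(c("", num(e$em_nm)), collapse = ",")
  rows <- vapply(seq_along(e$ex_nm), function(i) {
    paste(c(num(e$ex_nm[i]), num(e$z[i, ])), collapse = ",")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Strict two-column numeric CSV reader with row-level error reporting.
read_xy_csv <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- lapply(cols, function(cn) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]) | is.na(df[[cn]]))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric value in column `%s`, data row %d (%s)",
                   path, cn, bad[1L], df[[cn]][bad[1L]]), call. = FALSE)
    }
    v
  })
  names(out) <- cols
  as.data.frame(out, check.names = FALSE)
}

write_xy_csv <- function(df, path) {
  fmt <- vapply(df, function(col) {
    format(col, digits = 17, trim = TRUE, scientific = FALSE)
  }, FUN.VALUE = character(nrow(df)))
  fmt <- matrix(fmt, nrow = nrow(df))
  lines <- c(paste(names(df), collapse = ","),
             apply(fmt, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}
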