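## CSV readers/writers for the solution-phase experiments.
## Convention: RFC-4180 CSV with a header row; concentration columns carry
## their unit as a suffix (conc_uM, conc_M, ...); file-level metadata rides
## in leading '#'-comment lines as 'key: value'. All concentrations are
## molar internally.

.unit_factor <- function(unit) {
  switch(unit,
         M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9,
         stop("unknown concentration unit '", unit, "'", call. = FALSE))
}

# split "conc_uM" -> list(base = "conc", factor = 1e-6); no suffix -> factor 1
.parse_unit_col <- function(colname) {
  m <- regmatches(colname, regexec("^(.*)_(M|mM|uM|nM)$", colname))[[1]]
  if (length(m) == 3L) list(base = m[2], factor = .unit_factor(m[3]))
  else list(base = colname, factor = 1)
}

.read_csv_meta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^\\s*#", lines)
  meta <- list()
  for (l in lines[is_meta]) {
    l <- sub("^\\s*#\\s*", "", l)
    kv <- regmatches(l, regexec("^([^:]+):\\s*(.*)$", l))[[1]]
    if (length(kv) == 3L) meta[[trimws(kv[2])]] <- trimws(kv[3])
  }
  body <- lines[!is_meta]
  if (!length(body)) stop("format error: no data rows in ", path, call. = FALSE)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE, check.names = FALSE)
  list(meta = meta, df = df)
}

.require_numeric <- function(x, colname) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad))
    stop("format error: non-numeric value '", x[bad[1]], "' in column '",
         colname, "', data row ", bad[1], call. = FALSE)
  if (anyNA(v))
    stop("format error: missing value in column '", colname, "', data row ",
         which(is.na(v))[1], call. = FALSE)
  v
}

.meta_conc <- function(meta, base) {
  hit <- grep(paste0("^", base, "(_(M|mM|uM|nM))?$"), names(meta), value = TRUE)
  if (!length(hit)) return(NULL)
  u <- .parse_unit_col(hit[1])
  as.numeric(meta[[hit[1]]]) * u$factor
}

#' Construct a fluorescence titration table
#'
#' @param conc Quencher (titrant) concentrations in M, strictly increasing.
#' @param intensity Fluorescence intensities (arbitrary units), all > 0.
#' @param analyte_label Label of the titrated species (default "AD").
#' @param fixed_species_conc Fixed concentration of the fluorophore-bearing
#'   species (M), or \code{NA} if not applicable.
#' @return A \code{data.frame} of class \code{"titration_table"} with columns
#'   \code{conc} (M) and \code{intensity}, rows sorted by concentration.
#' @export
titration_table <- function(conc, intensity, analyte_label = "AD",
                            fixed_species_conc = NA_real_) {
  conc <- as.numeric(conc); intensity <- as.numeric(intensity)
  if (length(conc) != length(intensity))
    stop("format error: conc and intensity lengths differ", call. = FALSE)
  if (length(conc) < 3L)
    stop("format error: a titration needs at least 3 points, got ",
         length(conc), call. = FALSE)
  o <- order(conc)
  conc <- conc[o]; intensity <- intensity[o]
  d <- which(diff(conc) == 0)
  if (length(d))
    stop("format error: duplicated concentration ", conc[d[1]], " (rows ",
         d[1], " and ", d[1] + 1L, " after sorting)", call. = FALSE)
  if (any(conc < 0))
    stop("format error: negative concentration", call. = FALSE)
  if (any(intensity <= 0))
    stop("format error: non-positive intensity at row ",
         which(intensity <= 0)[1], call. = FALSE)
  structure(data.frame(conc = conc, intensity = intensity),
            analyte_label = analyte_label,
            fixed_species_conc = as.numeric(fixed_species_conc),
            class = c("titration_table", "data.frame"))
}

#' Read a titration CSV
#'
#' Expects a header with a concentration column (unit-suffixed, e.g.
#' \code{conc_uM}) and an \code{intensity} column; optional leading
#' \code{#}-comment metadata lines \code{analyte_label} and
#' \code{fixed_species_conc_uM}. Rows are sorted by concentration.
#'
#' @param path CSV path.
#' @return \code{\link{titration_table}}.
#' @export
read_titration_csv <- function(path) {
  r <- .read_csv_meta(path)
  cols <- vapply(names(r$df), function(n) .parse_unit_col(n)$base, "")
  ci <- which(cols == "conc")
  ii <- which(cols == "intensity")
  if (!length(ci)) stop("format error: missing concentration column 'conc_*'",
                        call. = FALSE)
  if (!length(ii)) stop("format error: missing column 'intensity'",
                        call. = FALSE)
  u <- .parse_unit_col(names(r$df)[ci[1]])
  conc <- .require_numeric(r$df[[ci[1]]], names(r$df)[ci[1]]) * u$factor
  intensity <- .require_numeric(r$df[[ii[1]]], "intensity")
  fx <- .meta_conc(r$meta, "fixed_species_conc")
  titration_table(conc, intensity,
                  analyte_label = r$meta$analyte_label %||% "AD",
                  fixed_species_conc = fx %||% NA_real_)
}

#' Write a titration table to CSV
#'
#' Inverse of \code{\link{read_titration_csv}}; concentrations are written
#' in uM with full double precision.
#'
#' @param t \code{\link{titration_table}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_titration_csv <- function(t, path) {
  stopifnot(inherits(t, "titration_table"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# analyte_label: %s", attr(t, "analyte_label")), con)
  fx <- attr(t, "fixed_species_conc")
  if (!is.na(fx))
    writeLines(sprintf("# fixed_species_conc_uM: %.15g", fx * 1e6), con)
  writeLines("conc_uM,intensity", con)
  writeLines(sprintf("%.15g,%.15g", t$conc * 1e6, t$intensity), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an ITC injection table
#'
#' @param volumes_uL Per-injection volumes in uL (all > 0, >= 2 injections).
#' @param heats_ucal Integrated (control-subtracted) heats per injection,
#'   ucal.
#' @param cell_volume_uL Working cell volume, uL.
#' @param temperature_K Experiment temperature, K.
#' @param cell_conc Protein concentration in the cell, M.
#' @param syringe_conc Total titrant (AD) concentration in the syringe, M.
#' @return List of class \code{"injection_table"}.
#' @export
injection_table <- function(volumes_uL, heats_ucal, cell_volume_uL,
                            temperature_K, cell_conc, syringe_conc) {
  volumes_uL <- as.numeric(volumes_uL); heats_ucal <- as.numeric(heats_ucal)
  if (length(volumes_uL) != length(heats_ucal))
    stop("format error: volumes and heats lengths differ", call. = FALSE)
  if (length(volumes_uL) < 2L)
    stop("format error: need at least 2 injections", call. = FALSE)
  if (any(volumes_uL <= 0)) stop("format error: injection volumes must be > 0",
                                 call. = FALSE)
  if (cell_volume_uL <= 0) stop("format error: cell_volume_uL must be > 0",
                                call. = FALSE)
  stopifnot(temperature_K > 0, cell_conc >= 0, syringe_conc >= 0)
  structure(list(
    cell_volume_uL = cell_volume_uL,
    temperature_K = temperature_K,
    cell_conc = cell_conc,
    syringe_conc = syringe_conc,
    injections = data.frame(volume_uL = volumes_uL, heat_ucal = heats_ucal)
  ), class = "injection_table")
}

#' Read an ITC injection CSV
#'
#' Header metadata comment lines carry the design
#' (\code{cell_volume_uL}, \code{temperature_K}, \code{cell_conc_uM},
#' \code{syringe_conc_uM}); columns are \code{volume_uL} and
#' \code{heat_ucal}.
#'
#' @param path CSV path.
#' @return \code{\link{injection_table}}.
#' @export
read_injection_csv <- function(path) {
  r <- .read_csv_meta(path)
  need <- c("volume_uL", "heat_ucal")
  miss <- setdiff(need, names(r$df))
  if (length(miss))
    stop("format error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (k in c("cell_volume_uL", "temperature_K"))
    if (is.null(r$meta[[k]]))
      stop("format error: missing metadata line '# ", k, ": ...'",
           call. = FALSE)
  cc <- .meta_conc(r$meta, "cell_conc")
  sc <- .meta_conc(r$meta, "syringe_conc")
  if (is.null(cc) || is.null(sc))
    stop("format error: missing cell_conc/syringe_conc metadata",
         call. = FALSE)
  injection_table(
    volumes_uL = .require_numeric(r$df$volume_uL, "volume_uL"),
    heats_ucal = .require_numeric(r$df$heat_ucal, "heat_ucal"),
    cell_volume_uL = as.numeric(r$meta$cell_volume_uL),
    temperature_K = as.numeric(r$meta$temperature_K),
    cell_conc = cc, syringe_conc = sc)
}

#' Write an ITC injection table to CSV
#' @param x \code{\link{injection_table}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_injection_csv <- function(x, path) {
  stopifnot(inherits(x, "injection_table"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("# cell_volume_uL: %.15g", x$cell_volume_uL),
    sprintf("# temperature_K: %.15g", x$temperature_K),
    sprintf("# cell_conc_uM: %.15g", x$cell_conc * 1e6),
    sprintf("# syringe_conc_uM: %.15g", x$syringe_conc * 1e6),
    "volume_uL,heat_ucal"), con)
  writeLines(sprintf("%.15g,%.15g", x$injections$volume_uL,
                     x$injections$heat_ucal), con)
  invisible(path)
}

#' Construct a spectrum / melt-curve table
#'
#' Generic x/y table for CD spectra (x in nm) and thermal melts (x in degC).
#'
#' @param x Strictly monotone abscissa (nm or degC).
#' @param y Ordinate (ellipticity in mdeg, or intensity).
#' @param x_unit Either \code{"nm"} or \code{"degC"}.
#' @return \code{data.frame} of class \code{"spectrum_table"}.
#' @export
spectrum_table <- function(x, y, x_unit = c("nm", "degC")) {
  x_unit <- match.arg(x_unit)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("format error: x and y lengths differ", call. = FALSE)
  d <- diff(x)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("format error: x must be strictly monotone", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("format error: non-finite values", call. = FALSE)
  structure(data.frame(x = x, y = y), x_unit = x_unit,
            class = c("spectrum_table", "data.frame"))
}

#' Read a spectrum or melt CSV
#'
#' Accepts column pairs \code{wavelength_nm}/\code{ellipticity_mdeg} or
#' \code{temperature_C}/\code{ellipticity_mdeg} (generic \code{x},\code{y}
#' also accepted, unit defaulting to nm).
#'
#' @param path CSV path.
#' @return \code{\link{spectrum_table}}.
#' @export
read_spectrum_csv <- function(path) {
  r <- .read_csv_meta(path)
  nm <- names(r$df)
  if ("wavelength_nm" %in% nm) {
    x <- .require_numeric(r$df$wavelength_nm, "wavelength_nm"); unit <- "nm"
  } else if ("temperature_C" %in% nm) {
    x <- .require_numeric(r$df$temperature_C, "temperature_C"); unit <- "degC"
  } else if ("x" %in% nm) {
    x <- .require_numeric(r$df$x, "x"); unit <- r$meta$x_unit %||% "nm"
  } else stop("format error: no abscissa column found", call. = FALSE)
  yc <- intersect(c("ellipticity_mdeg", "intensity", "y"), nm)
  if (!length(yc)) stop("format error: no ordinate column found",
                        call. = FALSE)
  spectrum_table(x, .require_numeric(r$df[[yc[1]]], yc[1]), x_unit = unit)
}

#' Write a spectrum table to CSV
#' @param s \code{\link{spectrum_table}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "spectrum_table"))
  xcol <- if (attr(s, "x_unit") == "nm") "wavelength_nm" else "temperature_C"
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0(xcol, ",ellipticity_mdeg"), con)
  writeLines(sprintf("%.15g,%.15g", s$x, s$y), con)
  invisible(path)
}
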