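#' Spectrum collections
#'
#' A `spec_set` holds one or more sampled spectra on a common wavelength grid:
#' a numeric grid (nm), a value matrix with one column per measurement, and a
#' metadata table (`species`, `module`, `rep`). Reflectance is stored as a
#' fraction (percent inputs are divided by 100); irradiance is in arbitrary
#' units (the von Kries adaptation step cancels any overall scale).
#'
#' @param wl Numeric vector of strictly increasing wavelengths in nm.
#' @param values Numeric matrix, `length(wl)` rows, one column per spectrum
#'   (a vector is taken as a single spectrum).
#' @param species,module,rep Metadata vectors recycled to the number of
#'   columns. `module` must be one of `r paste(beesignal_modules(), collapse=", ")`
#'   or `NA` for context spectra (illuminant and similar).
#' @param kind `"reflectance"` or `"irradiance"`.
#' @return An object of class `spec_set`.
#' @export
spec_set <- function(wl, values, species = NA_character_, module = NA_character_,
                     rep = 1L, kind = c("reflectance", "irradiance")) {
  kind <- match.arg(kind)
  if (is.vector(values)) values <- matrix(values, ncol = 1L)
  values <- as.matrix(values)
  wl <- as.numeric(wl)
  if (length(wl) < 2L) stop("a spectrum needs at least 2 wavelengths", call. = FALSE)
  if (any(diff(wl) <= 0)) stop("non-monotone grid: wavelengths must be strictly increasing", call. = FALSE)
  if (nrow(values) != length(wl)) stop("values must have one row per wavelength", call. = FALSE)
  if (kind == "reflectance") values <- clip_reflectance(values)
  if (any(values < 0)) stop("negative spectral values", call. = FALSE)
  n <- ncol(values)
  meta <- data.frame(
    species = rep_len(as.character(species), n),
    module = rep_len(as.character(module), n),
    rep = rep_len(as.character(rep), n),
    stringsAsFactors = FALSE
  )
  bad <- !is.na(meta$module) & !meta$module %in% beesignal_modules()
  if (any(bad)) {
    stop("unknown module token(s): ", paste(unique(meta$module[bad]), collapse = ", "),
         call. = FALSE)
  }
  colnames(values) <- ifelse(is.na(meta$species), paste0("ctx", seq_len(n)),
                             paste(meta$species, meta$module, meta$rep, sep = "__"))
  structure(list(wl = wl, values = values, meta = meta, kind = kind),
            class = "spec_set")
}

#' Recognised flower-module tokens
#'
#' The four flower colour modules plus `leaf`; column names in wide spectra
#' tables must use these tokens.
#' @return Character vector of module names.
#' @export
beesignal_modules <- function() c("sepal", "petal", "lip_tip", "lip_base", "leaf")

# Instrument noise can put reflectance slightly below zero; values in
# [-0.005, 0) are clipped to 0, anything lower is a data error.
clip_reflectance <- function(values, tol = 0.005) {
  neg <- values < 0
  if (any(values < -tol)) {
    stop(sprintf("reflectance below -%g after unit normalization; check the input", tol),
         call. = FALSE)
  }
  if (any(neg)) values[neg] <- 0
  values
}

#' Read a wide table of reflectance spectra
#'
#' The expected layout is FReD-style: the first column is wavelength (nm) and
#' every remaining column is one measurement named `<species>__<module>__<rep>`
#' (module one of [beesignal_modules()]). Percent reflectance is auto-detected
#' when the maximum value exceeds 1.5 and divided by 100.
#'
#' @param path Path to a CSV or TSV file (delimiter sniffed from the header).
#' @param unit_hint `"auto"` (default), `"percent"` or `"fraction"`.
#' @return A `spec_set` of reflectance spectra.
#' @export
read_spectra <- function(path, unit_hint = c("auto", "percent", "fraction")) {
  unit_hint <- match.arg(unit_hint)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("spectra table needs a wavelength column plus measurements", call. = FALSE)
  wl <- as.numeric(tab[[1L]])
  if (anyNA(wl)) stop("non-numeric wavelength column", call. = FALSE)
  if (any(diff(wl) <= 0)) stop("non-monotone grid", call. = FALSE)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  is_percent <- switch(unit_hint,
    percent = TRUE,
    fraction = FALSE,
    auto = max(values, na.rm = TRUE) > 1.5
  )
  if (is_percent) values <- values / 100
  parts <- strsplit(colnames(values), "__", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad)) {
    stop("column names must follow species__module__rep (offending: ",
         paste(colnames(values)[bad], collapse = ", "), ")", call. = FALSE)
  }
  spec_set(wl, values,
           species = vapply(parts, `[`, "", 1L),
           module = vapply(parts, `[`, "", 2L),
           rep = vapply(parts, `[`, "", 3L),
           kind = "reflectance")
}

#' Resample spectra onto the working grid
#'
#' Linear interpolation onto an integer nm grid (default 300-700 nm, the range
#' used by all downstream integrals). Wavelengths outside the input range are
#' filled with the nearest edge value and a warning is raised; inputs covering
#' less than half of the target range are rejected.
#'
#' @param x A `spec_set`.
#' @param grid Target wavelengths (nm); default `300:700`.
#' @return A `spec_set` on `grid`.
#' @export
resample_spectra <- function(x, grid = 300:700) {
  stopifnot(inherits(x, "spec_set"))
  lo <- max(min(x$wl), min(grid))
  hi <- min(max(x$wl), max(grid))
  coverage <- (hi - lo) / (max(grid) - min(grid))
  if (coverage < 0.5) {
    stop(sprintf("input grid covers only %.0f%% of [%d, %d]", 100 * coverage,
                 min(grid), max(grid)), call. = FALSE)
  }
  if (min(x$wl) > min(grid) || max(x$wl) < max(grid)) {
    warning(sprintf("input covers %g-%g nm; edges of [%d, %d] filled with boundary values",
                    min(x$wl), max(x$wl), min(grid), max(grid)), call. = FALSE)
  }
  vals <- apply(x$values, 2L, function(v) stats::approx(x$wl, v, xout = grid, rule = 2)$y)
  out <- x
  out$wl <- as.numeric(grid)
  out$values <- matrix(vals, nrow = length(grid), dimnames = list(NULL, colnames(x$values)))
  out
}

#' Average replicate spectra per species and module
#'
#' Pointwise arithmetic mean over replicates, returning one spectrum per
#' species x module combination (`rep = "mean"`).
#'
#' @param x A `spec_set`.
#' @return A `spec_set` with one column per species x module.
#' @export
mean_spectra <- function(x) {
  stopifnot(inherits(x, "spec_set"))
  if (ncol(x$values) == 0L) stop("empty spectrum set", call. = FALSE)
  key <- paste(x$meta$species, x$meta$module, sep = "__")
  groups <- unique(key)
  vals <- vapply(groups, function(g) rowMeans(x$values[, key == g, drop = FALSE]),
                 numeric(length(x$wl)))
  first <- match(groups, key)
  spec_set(x$wl, vals, species = x$meta$species[first], module = x$meta$module[first],
           rep = "mean", kind = x$kind)
}

# Extract one column as a plain list(wl, value); internal convenience.
spec_column <- function(x, j) list(wl = x$wl, value = x$values[, j])

#' @export
print.spec_set <- function(x, ...) {
  cat(sprintf("<spec_set> %d %s spectr%s on %g-%g nm (%d points)\n",
              ncol(x$values), x$kind, if (ncol(x$values) == 1L) "um" else "a",
              min(x$wl), max(x$wl), length(x$wl)))
  if (!all(is.na(x$meta$species))) {
    cat(sprintf("  %d species x %d module(s)\n",
                length(unique(stats::na.omit(x$meta$species))),
                length(unique(stats::na.omit(x$meta$module)))))
  }
  invisible(x)
}

#' @export
plot.spec_set <- function(x, ..., percent = TRUE) {
  v <- if (percent && x$kind == "reflectance") 100 * x$values else x$values
  graphics::matplot(x$wl, v, type = "l", lty = 1,
                    xlab = "wavelength (nm)",
                    ylab = if (percent && x$kind == "reflectance") "reflectance (%)" else x$kind,
                    ...)
  invisible(x)
}

#' Packaged default illuminant (forest-shade approximation)
#'
#' A smooth synthetic approximation to forest-shade irradiance (green-enhanced
#' canopy light), shipped as a plain CSV in `inst/extdata`. It is a stand-in
#' for measured forest-shade curves and should be replaced with a measured
#' spectrum via `path` when one is available. Units are arbitrary: all
#' downstream quantities are invariant to illuminant scale.
#'
#' @param path Optional CSV (wavelength, value) overriding the packaged curve.
#' @return A single-spectrum `spec_set` of kind `"irradiance"`.
#' @export
default_illuminant <- function(path = NULL) {
  path <- path %||% system.file("extdata", "forest_shade_synthetic.csv", package = "beesignal")
  tab <- utils::read.csv(path)
  spec_set(tab[[1L]], tab[[2L]], kind = "irradiance")
}

#' Packaged default leaf background
#'
#' A smooth synthetic approximation of a green-leaf reflectance spectrum
#' (low UV/blue/red, chlorophyll bump near 550 nm), shipped as a plain CSV and
#' user-replaceable via `path`.
#'
#' @param path Optional CSV (wavelength, value as fraction) overriding the
#'   packaged curve.
#' @return A single-spectrum `spec_set` of kind `"reflectance"`.
#' @export
default_background <- function(path = NULL) {
  path <- path %||% system.file("extdata", "leaf_background_synthetic.csv", package = "beesignal")
  tab <- utils::read.csv(path)
  spec_set(tab[[1L]], tab[[2L]], kind = "reflectance")
}
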