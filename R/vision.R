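#' Visual pigment sensitivity template
#'
#' Govardovskii et al. (2000) A1 rhodopsin nomogram (alpha plus beta band)
#' evaluated on a wavelength grid and normalized to a maximum of 1. Used to
#' reconstruct full receptor sensitivity curves from the printed peak
#' wavelengths when measured curves are unavailable.
#'
#' @param peak_nm Peak sensitivity wavelength (nm), within the grid range.
#' @param wl Wavelength grid (nm), default `300:700`.
#' @return Numeric vector of sensitivities (max 1) on `wl`.
#' @export
receptor_template <- function(peak_nm, wl = 300:700) {
  if (peak_nm < min(wl) || peak_nm > max(wl))
    stop("peak outside the wavelength grid", call. = FALSE)
  x <- peak_nm / wl
  a <- 0.8795 + 0.0459 * exp(-(peak_nm - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * peak_nm
  bw <- -40.5 + 0.195 * peak_nm
  beta <- 0.26 * exp(-((wl - lmb) / bw)^2)
  s <- alpha + beta
  s / max(s)
}

#' Trichromatic bee visual system
#'
#' Receptor sensitivity curves for a UV/blue/green trichromat. Defaults are the
#' *Bombus terrestris* peaks (328, 428, 536 nm) rebuilt from the A1 template;
#' measured curves can be supplied instead via `curves` (a 3-column matrix on
#' `wl`, columns uv/blue/green) or a spectra CSV via `path`.
#'
#' @param peaks Named numeric vector `c(uv=, blue=, green=)` of peak
#'   wavelengths in increasing order.
#' @param wl Wavelength grid (nm).
#' @param curves Optional measured sensitivity matrix overriding the template.
#' @param path Optional CSV (wavelength + 3 sensitivity columns) overriding.
#' @return A `visual_system`: sensitivity matrix with attribute `peaks`.
#' @export
bee_sensitivities <- function(peaks = c(uv = 328, blue = 428, green = 536),
                              wl = 300:700, curves = NULL, path = NULL) {
  if (!is.null(path)) {
    tab <- utils::read.csv(path)
    wl_in <- tab[[1L]]
    curves <- vapply(2:4, function(j) stats::approx(wl_in, tab[[j]], xout = wl, rule = 2)$y,
                     numeric(length(wl)))
  }
  if (is.null(curves)) {
    curves <- vapply(peaks, receptor_template, numeric(length(wl)), wl = wl)
  } else {
    curves <- as.matrix(curves)
    if (nrow(curves) != length(wl)) stop("sensitivity curves must match the grid", call. = FALSE)
    curves <- sweep(curves, 2L, apply(curves, 2L, max), "/")
    peaks <- wl[apply(curves, 2L, which.max)]
  }
  if (any(curves < 0)) stop("sensitivities must be non-negative", call. = FALSE)
  if (is.unsorted(peaks, strictly = TRUE))
    stop("receptor peaks must be ordered uv < blue < green", call. = FALSE)
  colnames(curves) <- c("uv", "blue", "green")
  structure(curves, wl = wl, peaks = stats::setNames(as.numeric(peaks), colnames(curves)),
            class = c("visual_system", "matrix"))
}

#' Viewing context for vision modelling
#'
#' Bundles the visual system, illuminant and adapting background on a common
#' grid and precomputes the von Kries adaptation factors
#' \eqn{R_i = 1 / \int S_i(\lambda) R_b(\lambda) I(\lambda) d\lambda}
#' so the adapting background yields unit quantum catch in every channel.
#'
#' @param visual_system A [bee_sensitivities()] object.
#' @param illuminant Irradiance `spec_set` (default: packaged forest-shade
#'   approximation).
#' @param background Reflectance `spec_set` of the adapting background
#'   (default: packaged leaf approximation).
#' @param grid Working grid (nm).
#' @return An object of class `viewing_context`.
#' @export
viewing_context <- function(visual_system = bee_sensitivities(wl = grid),
                            illuminant = default_illuminant(),
                            background = default_background(),
                            grid = 300:700) {
  sens <- unclass(visual_system)
  if (nrow(sens) != length(grid)) stop("visual system not on the working grid", call. = FALSE)
  ill <- resample_spectra(illuminant, grid)$values[, 1L]
  bg <- resample_spectra(background, grid)$values[, 1L]
  w <- trapezoid_weights(grid)
  denom <- colSums(sens * (bg * ill * w))
  if (any(denom <= 0)) stop("zero background quantum catch in some channel", call. = FALSE)
  structure(list(sens = sens, illuminant = ill, background = bg, grid = as.numeric(grid),
                 weights = w, von_kries = 1 / denom,
                 peaks = attr(visual_system, "peaks")),
            class = "viewing_context")
}

#' @export
print.viewing_context <- function(x, ...) {
  cat(sprintf("<viewing_context> trichromat peaks %s nm, grid %g-%g nm\n",
              paste(x$peaks, collapse = "/"), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Background-adapted quantum catches
#'
#' Trapezoid integration of stimulus x sensitivity x illuminant per channel,
#' normalized by the background catch (von Kries): the adapting background
#' itself yields `P = 1` in each channel.
#'
#' @param x Reflectance `spec_set` (resampled to the context grid if needed).
#' @param ctx A [viewing_context()].
#' @return Matrix (one row per spectrum) with columns `uv`, `blue`, `green`.
#' @export
quantum_catch <- function(x, ctx) {
  stopifnot(inherits(ctx, "viewing_context"))
  if (inherits(x, "spec_set")) {
    if (!isTRUE(all.equal(x$wl, ctx$grid))) x <- resample_spectra(x, ctx$grid)
    v <- x$values
  } else {
    v <- as.matrix(x)
    if (nrow(v) != length(ctx$grid)) stop("stimulus not on the context grid", call. = FALSE)
  }
  m <- ctx$sens * (ctx$illuminant * ctx$weights)  # channel weighting functions
  p <- sweep(crossprod(v, m), 2L, ctx$von_kries, "*")
  colnames(p) <- c("uv", "blue", "green")
  p
}

#' Hexagon colour loci
#'
#' Receptor excitations `E = P / (P + 1)` and Chittka's hexagon coordinates
#' `x = (sqrt(3)/2) (E_G - E_UV)`, `y = E_B - (E_UV + E_G)/2`. The adapting
#' background maps to the achromatic centre (0, 0) with all `E = 0.5`; every
#' locus lies within the hexagon circumradius 1.
#'
#' @param p Quantum-catch matrix from [quantum_catch()] (or anything coercible
#'   to a 3-column non-negative matrix ordered uv, blue, green).
#' @return Data frame with columns `e_uv`, `e_blue`, `e_green`, `x`, `y`.
#' @export
hexagon_locus <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 3L) stop("quantum catches must have 3 channels", call. = FALSE)
  if (any(p < 0)) stop("quantum catches must be non-negative", call. = FALSE)
  e <- p / (p + 1)
  out <- data.frame(
    e_uv = e[, 1L], e_blue = e[, 2L], e_green = e[, 3L],
    x = (sqrt(3) / 2) * (e[, 3L] - e[, 1L]),
    y = e[, 2L] - (e[, 1L] + e[, 3L]) / 2
  )
  rownames(out) <- rownames(p)
  out
}

#' Chromatic contrast (hexagon distance)
#'
#' Euclidean distance between two hexagon loci in (x, y), in hexagon units.
#'
#' @param a,b Hexagon loci (rows are recycled to a common length).
#' @return Numeric vector of distances `dS`.
#' @export
chromatic_contrast <- function(a, b) {
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
}

#' Achromatic (green-channel) contrast
#'
#' With two loci, the intrafloral green contrast `dL = |E_G,a - E_G,b|`.
#' With `b = NULL`, the extrafloral achromatic signal of a patch: its
#' background-adapted green excitation `lum = E_G` (the background itself
#' scores 0.5).
#'
#' @param a Hexagon locus (or loci).
#' @param b Optional second locus; omit for patch-vs-background `lum`.
#' @return Numeric vector (`dL` or `lum`).
#' @export
achromatic_contrast <- function(a, b = NULL) {
  if (is.null(b)) return(a$e_green)
  abs(a$e_green - b$e_green)
}

#' Monochromatic locus (hexagon boundary)
#'
#' Projects narrow-band stimuli (top-hat reflectance of `bandwidth_nm`, unit
#' reflectance, centred at each grid wavelength) through the viewing context,
#' tracing the boundary used as the saturation reference for spectral purity.
#'
#' @param ctx A [viewing_context()].
#' @param bandwidth_nm Top-hat full width (nm), at least the grid step;
#'   default 10.
#' @return Data frame of class `mono_locus`: `lambda`, `x`, `y`, `radius`.
#' @export
monochromatic_locus <- function(ctx, bandwidth_nm = 10) {
  stopifnot(inherits(ctx, "viewing_context"))
  grid <- ctx$grid
  if (bandwidth_nm < min(diff(grid)))
    stop("bandwidth must be at least the grid step", call. = FALSE)
  half <- bandwidth_nm / 2
  stim <- vapply(grid, function(l) as.numeric(abs(grid - l) <= half),
                 numeric(length(grid)))
  loc <- hexagon_locus(quantum_catch(stim, ctx))
  out <- data.frame(lambda = grid, x = loc$x, y = loc$y,
                    radius = sqrt(loc$x^2 + loc$y^2))
  class(out) <- c("mono_locus", "data.frame")
  out
}

#' @export
plot.mono_locus <- function(x, ...) {
  graphics::plot(x$x, x$y, type = "l", asp = 1, xlab = "x (hexagon units)",
                 ylab = "y (hexagon units)", ...)
  graphics::points(0, 0, pch = 3)
  invisible(x)
}

#' Spectral purity
#'
#' Saturation of a locus relative to the monochromatic boundary: the ratio of
#' its radial distance from the achromatic centre to the radial distance of a
#' reference boundary point, clamped to \[0, 1\]. The reference is the boundary
#' point closest in hue angle (`mode = "ray"`, the default: the boundary point
#' on the locus's own ray from the centre, which makes purity scale linearly
#' with radial distance) or the nearest boundary point in Euclidean (x, y)
#' distance (`mode = "nearest"`); ties break towards shorter wavelengths. The
#' monochromatic locus is strongly non-convex, so the nearest-Euclidean
#' reference can sit on a different branch of the curve and inflate the ratio
#' for weakly saturated loci; the ray reference does not. A locus at the exact
#' centre has purity 0 and an undefined (`NA`) boundary wavelength.
#'
#' Boundary points whose radius falls below `min_radius_frac` of the maximum
#' boundary radius are excluded from the reference search: the monochromatic
#' locus collapses towards the achromatic centre at the long-wavelength end
#' (the trichromat is nearly blind there), and those degenerate points are not
#' meaningful saturation references.
#'
#' @param locus Data frame of hexagon loci (columns `x`, `y`).
#' @param boundary A [monochromatic_locus()].
#' @param mode `"nearest"` (default) or `"ray"`.
#' @param min_radius_frac Degenerate-boundary trim (default 0.1).
#' @return Data frame with `purity` and `boundary_lambda`.
#' @export
spectral_purity <- function(locus, boundary, mode = c("ray", "nearest"),
                            min_radius_frac = 0.1) {
  mode <- match.arg(mode)
  stopifnot(inherits(boundary, "mono_locus"), nrow(boundary) > 0L)
  boundary <- boundary[boundary$radius >= min_radius_frac * max(boundary$radius), ]
  r <- sqrt(locus$x^2 + locus$y^2)
  n <- length(r)
  purity <- numeric(n)
  lambda <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (r[i] < 1e-12) next
    crit <- if (mode == "nearest") {
      (boundary$x - locus$x[i])^2 + (boundary$y - locus$y[i])^2
    } else {
      d <- abs(atan2(boundary$y, boundary$x) - atan2(locus$y[i], locus$x[i]))
      pmin(d, 2 * pi - d)
    }
    j <- which.min(crit)  # which.min takes the first (smallest lambda) on ties
    purity[i] <- min(r[i] / boundary$radius[j], 1)
    lambda[i] <- boundary$lambda[j]
  }
  data.frame(purity = purity, boundary_lambda = lambda, row.names = rownames(locus))
}

# The ten module/leaf pairs, extrafloral (vs leaf background) first.
contrast_pairs <- function() {
  rbind(
    data.frame(a = "leaf", b = c("sepal", "petal", "lip_tip", "lip_base"),
               type = "extrafloral"),
    data.frame(a = c("sepal", "sepal", "sepal", "petal", "petal", "lip_tip"),
               b = c("petal", "lip_tip", "lip_base", "lip_tip", "lip_base", "lip_base"),
               type = "intrafloral")
  )
}

#' Chromatic and achromatic contrast table
#'
#' One record per species x available module pair over the ten combinations
#' (leaf vs each of the four modules, plus the six intrafloral pairs). The
#' adapting leaf background serves as the leaf term: its locus is the
#' achromatic centre, so leaf-module `dS` equals the module's radial distance
#' and leaf-module `dL = |E_G - 0.5|`. `lum` is the green excitation of the
#' (non-leaf) patch for extrafloral pairs.
#'
#' @param mspec Mean reflectance `spec_set` (one column per species x module).
#' @param ctx A [viewing_context()].
#' @return Data frame: `species`, `pair`, `type`, `dS`, `dL`, `lum`.
#' @export
contrast_table <- function(mspec, ctx) {
  stopifnot(inherits(mspec, "spec_set"))
  loc <- hexagon_locus(quantum_catch(mspec, ctx))
  meta <- mspec$meta
  pairs <- contrast_pairs()
  leaf <- data.frame(e_uv = 0.5, e_blue = 0.5, e_green = 0.5, x = 0, y = 0)
  out <- vector("list", length(unique(meta$species)))
  species <- unique(meta$species)
  for (k in seq_along(species)) {
    sp <- species[k]
    idx <- stats::setNames(which(meta$species == sp), meta$module[meta$species == sp])
    rows <- list()
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$a[i]; b <- pairs$b[i]
      la <- if (a == "leaf") leaf else if (a %in% names(idx)) loc[idx[[a]], ] else NULL
      lb <- if (b %in% names(idx)) loc[idx[[b]], ] else NULL
      if (is.null(la) || is.null(lb)) next
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, pair = paste(a, b, sep = "-"), type = pairs$type[i],
        dS = chromatic_contrast(la, lb),
        dL = achromatic_contrast(la, lb),
        lum = if (pairs$type[i] == "extrafloral") lb$e_green else NA_real_
      )
    }
    out[[k]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$pair <- factor(res$pair, levels = paste(pairs$a, pairs$b, sep = "-"))
  res
}
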