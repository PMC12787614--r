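#' Band-wise mean reflectance
#'
#' Arithmetic mean percent reflectance over the four inclusive wavebands:
#' ultraviolet 301-400 nm, blue 401-500 nm, green 501-600 nm, red 601-700 nm.
#'
#' @param x A reflectance `spec_set` on the 300-700 nm grid.
#' @return Data frame (one row per spectrum): `uv`, `blue`, `green`, `red`
#'   in percent, plus the spectrum metadata.
#' @export
band_means <- function(x) {
  stopifnot(inherits(x, "spec_set"))
  bands <- list(uv = c(301, 400), blue = c(401, 500), green = c(501, 600), red = c(601, 700))
  if (min(x$wl) > 301 || max(x$wl) < 700)
    stop("spectra must cover 301-700 nm; resample first", call. = FALSE)
  pct <- 100 * x$values
  out <- vapply(bands, function(b) colMeans(pct[x$wl >= b[1] & x$wl <= b[2], , drop = FALSE]),
                numeric(ncol(pct)))
  out <- as.data.frame(matrix(out, ncol = 4L, dimnames = list(colnames(x$values), names(bands))))
  cbind(x$meta, out)
}

#' Default band thresholds (% reflectance)
#'
#' Reflecting/absorbing cut-offs per band: 10 (UV), 30 (blue), 40 (green),
#' 60 (red), with the green-override margin of 50%.
#' @return Named numeric vector.
#' @export
default_thresholds <- function() c(uv = 10, blue = 30, green = 40, red = 60, green_margin = 50)

# (blue, green, red) state -> hue. The observed categories fix most entries;
# the remaining combinations complete the table consistently.
hue_lookup <- c(
  "+++" = "White", "-++" = "Yellow", "-+-" = "Green", "--+" = "Red",
  "+--" = "Blue", "++-" = "Cyan", "+-+" = "Pink", "---" = "Black"
)

#' Categorize band means into UV/hue colour categories
#'
#' Each band is scored reflecting (`+`) when its mean percent reflectance meets
#' its threshold (inclusive). A green band that passes its threshold is
#' reclassified as absorbing when it is at least `green_margin`% lower than the
#' larger of the blue and red means (`green_rule = "relative"`, the default:
#' green <= (1 - margin/100) * max(blue, red)), or when the absolute difference
#' reaches `green_margin` percentage points (`green_rule = "absolute"`). The
#' blue/green/red states map to one of 8 hues, prefixed by the UV state, e.g.
#' `"UV+Yellow"` or `"UV-Black"`.
#'
#' @param bm Data frame with columns `uv`, `blue`, `green`, `red` (percent),
#'   e.g. from [band_means()].
#' @param thresholds Named vector as [default_thresholds()].
#' @param green_rule `"relative"` (default) or `"absolute"`.
#' @return Data frame: `uv_state`, `hue`, `category`.
#' @export
categorize_color <- function(bm, thresholds = default_thresholds(),
                             green_rule = c("relative", "absolute")) {
  green_rule <- match.arg(green_rule)
  st <- function(band) ifelse(bm[[band]] >= thresholds[[band]], "+", "-")
  uv <- st("uv"); b <- st("blue"); g <- st("green"); r <- st("red")
  ref <- pmax(bm$blue, bm$red)
  margin <- thresholds[["green_margin"]]
  override <- if (green_rule == "relative") {
    bm$green <= (1 - margin / 100) * ref
  } else {
    ref - bm$green >= margin
  }
  g[g == "+" & override] <- "-"
  hue <- unname(hue_lookup[paste0(b, g, r)])
  data.frame(uv_state = uv, hue = hue, category = paste0("UV", uv, hue),
             row.names = rownames(bm))
}

#' Per-species, per-module colour category table
#'
#' Band means and categories for every species x module mean spectrum.
#'
#' @param mspec Mean reflectance `spec_set` from [mean_spectra()].
#' @param ... Passed to [categorize_color()].
#' @return Tidy data frame keyed by `species`, `module` with band means and
#'   `category`.
#' @export
category_table <- function(mspec, ...) {
  bm <- band_means(mspec)
  cat <- categorize_color(bm, ...)
  out <- cbind(bm[, c("species", "module", "uv", "blue", "green", "red")],
               cat[, c("uv_state", "hue", "category")])
  rownames(out) <- NULL
  out
}
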