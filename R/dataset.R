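#' Size variables of the analysis table
#'
#' The nine floral/display size variables: five linear measures (mm), frontal
#' flower area (mm^2), flower radius (mm, derived as sqrt(area/pi) when not
#' supplied), and two display counts.
#' @return Character vector of column names.
#' @export
size_variables <- function() {
  c("petal_length", "sepal_length", "lip_length", "inflorescence_length",
    "flower_depth", "flower_area", "flower_radius",
    "flowers_per_inflorescence", "inflorescences_per_individual")
}

reward_types <- c("deceit", "nectar", "oil", "fragrance", "unknown")

# reward presence follows deterministically from reward type
presence_from_type <- function(type) {
  ifelse(type == "deceit", "rewardless",
         ifelse(type == "unknown", "unknown", "rewarding"))
}

#' Load and validate the species trait table
#'
#' Expects one row per species with a `species` column, a `reward_type` column
#' (deceit, nectar, oil, fragrance, unknown; empty/NA normalized to unknown),
#' the nine [size_variables()] (flower_radius optional; derived from area), and
#' an optional `its_mm` column of mean pollinator intertegular spans.
#' `reward_presence` is derived: deceit is rewardless; nectar, oil and
#' fragrance are rewarding; unknown stays unknown.
#'
#' @param path CSV path, or a data frame already in memory.
#' @return Validated data frame of species records.
#' @export
load_traits <- function(path) {
  tr <- if (is.data.frame(path)) path else utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"species" %in% names(tr)) stop("traits need a `species` column", call. = FALSE)
  if (anyDuplicated(tr$species)) stop("duplicate species in trait table", call. = FALSE)
  tr$reward_type <- tolower(trimws(tr$reward_type %||% "unknown"))
  tr$reward_type[is.na(tr$reward_type) | tr$reward_type == ""] <- "unknown"
  bad <- !tr$reward_type %in% reward_types
  if (any(bad)) {
    stop("reward_type outside vocabulary: ", paste(unique(tr$reward_type[bad]), collapse = ", "),
         call. = FALSE)
  }
  tr$reward_presence <- presence_from_type(tr$reward_type)
  if (!"flower_radius" %in% names(tr) && "flower_area" %in% names(tr))
    tr$flower_radius <- sqrt(tr$flower_area / pi)
  missing_cols <- setdiff(size_variables(), names(tr))
  if (length(missing_cols))
    stop("missing size variables: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  for (v in size_variables()) {
    if (any(tr[[v]] < 0, na.rm = TRUE)) stop("negative values in ", v, call. = FALSE)
  }
  if ("its_mm" %in% names(tr) && any(tr$its_mm <= 0, na.rm = TRUE))
    stop("its_mm must be positive when present", call. = FALSE)
  tr
}

#' Mean intertegular span of a species' visitors
#'
#' Species-level ITS is used when the reference table has it; otherwise the
#' genus mean is used. The returned value is the mean across visitors; an empty
#' or unmatched visitor list gives `NA`.
#'
#' @param visitors Character vector of visitor names (`"Genus species"` or
#'   `"Genus"`).
#' @param its_ref Reference data frame with columns `species` (may be `NA` for
#'   genus-level rows), `genus`, `its_mm`.
#' @return Mean ITS in mm, or `NA_real_`.
#' @export
its_lookup <- function(visitors, its_ref) {
  stopifnot(all(c("genus", "its_mm") %in% names(its_ref)))
  if (length(visitors) == 0L) return(NA_real_)
  genus_mean <- tapply(its_ref$its_mm, its_ref$genus, mean, na.rm = TRUE)
  one <- function(v) {
    hit <- if ("species" %in% names(its_ref)) which(its_ref$species == v) else integer()
    if (length(hit)) return(mean(its_ref$its_mm[hit], na.rm = TRUE))
    gen <- strsplit(trimws(v), "\\s+")[[1L]][1L]
    if (gen %in% names(genus_mean)) return(unname(genus_mean[[gen]]))
    NA_real_
  }
  vals <- vapply(visitors, one, numeric(1))
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

#' Partition species into the three analysis subsets
#'
#' * `size` subset: complete size variables and at least one measured flower
#'   module (used for the size PCA and modularity models);
#' * `color` subset: all four flower modules plus complete sizes (global and
#'   colour PCAs);
#' * `its` subset: members of the size subset with pollinator ITS data.
#'
#' @param traits Trait table from [load_traits()].
#' @param spectra_meta Metadata of the mean spectra (`species`, `module`
#'   columns), e.g. `mean_spectra(x)$meta`.
#' @return Object of class `analysis_subsets`: list of species-id vectors
#'   `size`, `color`, `its`.
#' @export
make_subsets <- function(traits, spectra_meta) {
  flower_mods <- setdiff(beesignal_modules(), "leaf")
  mods_by_sp <- split(spectra_meta$module, spectra_meta$species)
  n_mods <- vapply(traits$species, function(s)
    length(intersect(flower_mods, mods_by_sp[[s]] %||% character())), integer(1))
  sizes_ok <- stats::complete.cases(traits[, size_variables()])
  size_sub <- traits$species[sizes_ok & n_mods >= 1L]
  color_sub <- traits$species[sizes_ok & n_mods == length(flower_mods)]
  its_sub <- if ("its_mm" %in% names(traits)) {
    intersect(size_sub, traits$species[!is.na(traits$its_mm)])
  } else character()
  structure(list(size = size_sub, color = color_sub, its = its_sub),
            class = "analysis_subsets")
}

#' @export
print.analysis_subsets <- function(x, ...) {
  cat(sprintf("<analysis_subsets> size: %d | color (all 4 modules): %d | its: %d species\n",
              length(x$size), length(x$color), length(x$its)))
  invisible(x)
}
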