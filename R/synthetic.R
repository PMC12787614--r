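#' Band-mean targets realised by each colour category
#'
#' The generator places noiseless band means at least 5 percentage points
#' inside each category's threshold region: absorbing bands sit at
#' 4/15/20/40% (UV/blue/green/red) and reflecting bands at 16/45/55/75%.
#' These targets never trigger the green override for green-reflecting hues.
#'
#' @param category Category label, e.g. `"UV+Yellow"`.
#' @return Named numeric vector `c(uv, blue, green, red)` in percent.
#' @export
category_band_targets <- function(category) {
  m <- regmatches(category, regexec("^UV([+-])(.+)$", category))[[1L]]
  if (length(m) != 3L || !m[3L] %in% hue_lookup)
    stop("unknown colour category: ", category, call. = FALSE)
  key <- names(hue_lookup)[match(m[3L], hue_lookup)]
  states <- c(m[2L], strsplit(key, "")[[1L]])
  lo <- c(uv = 4, blue = 15, green = 20, red = 40)
  hi <- c(uv = 16, blue = 45, green = 55, red = 75)
  stats::setNames(ifelse(states == "+", hi, lo), names(lo))
}

#' All sixteen colour categories
#' @return Character vector of the 16 UV x hue category labels.
#' @export
all_categories <- function() {
  as.vector(outer(c("UV+", "UV-"), unname(hue_lookup), paste0))
}

#' Synthesize a reflectance spectrum realizing a colour category
#'
#' A smooth curve built from logistic steps at the band boundaries (400.5,
#' 500.5, 600.5 nm; scale 4 nm) whose plateau levels are the
#' [category_band_targets()] of the category, plus optional Gaussian noise
#' (percent units) clipped at zero.
#'
#' @param category Category label, e.g. `"UV-Black"`.
#' @param noise_sd Noise standard deviation in percent reflectance (default 0).
#' @param seed Optional integer seed (same seed, same spectrum).
#' @param wl Wavelength grid (default `300:700`).
#' @return Numeric vector of fractional reflectance on `wl`.
#' @export
make_spectrum <- function(category, noise_sd = 0, seed = NULL, wl = 300:700) {
  spectrum_from_targets(category_band_targets(category), noise_sd, seed, wl)
}

# Smooth logistic-step curve through arbitrary band plateaus (percent).
spectrum_from_targets <- function(v, noise_sd = 0, seed = NULL, wl = 300:700) {
  step <- function(center) stats::plogis((wl - center) / 4)
  pct <- v[["uv"]] +
    (v[["blue"]] - v[["uv"]]) * step(400.5) +
    (v[["green"]] - v[["blue"]]) * step(500.5) +
    (v[["red"]] - v[["green"]]) * step(600.5)
  if (noise_sd > 0) {
    pct <- pct + with_seed(seed, stats::rnorm(length(wl), 0, noise_sd))
    pct <- pmax(pct, 0)
  }
  pct / 100
}

# Continuous within-category variation: a brightness latent scales the mean
# level and a saturation latent scales the contrast among bands; plateaus are
# clipped into category-safe boxes (3 points inside each threshold) so the
# realized category never flips.
jitter_targets <- function(targets, saturation = 0, brightness = 0,
                           thresholds = default_thresholds()) {
  thr <- thresholds[c("uv", "blue", "green", "red")]
  m <- mean(targets)
  v <- m * exp(0.30 * brightness) + (targets - m) * exp(0.55 * saturation)
  plus <- targets >= thr
  lo <- ifelse(plus, thr + 3, 0.5)
  hi <- ifelse(plus, 97, thr - 3)
  v <- pmin(pmax(v, lo), hi)
  # keep green-reflecting plateaus clear of the green-override rule
  if (plus[["green"]])
    v[["green"]] <- max(v[["green"]], 0.5 * max(v[["blue"]], v[["red"]]) + 3)
  v
}

#' Simulate a pure-birth tree
#'
#' Yule (pure-birth) tree scaled to unit root-to-tip height; ultrametric by
#' construction.
#'
#' @param n_tips Number of tips (>= 3).
#' @param birth_rate Speciation rate (default 1).
#' @param seed Optional integer seed.
#' @return An `ape::phylo` tree with tips `sp001, sp002, ...`.
#' @export
make_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (n_tips < 3L) stop("need at least 3 tips", call. = FALSE)
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = birth_rate, death = 0))
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / h
  tree$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  tree
}

# Category probabilities per reward type and module. Modes are disjoint across
# rewards (deceptive displays UV+White tepals, oil UV+Yellow lip tips,
# fragrance UV-Black lip bases / UV-Green lip tips, nectar UV-Yellow lip
# tips), mirroring the qualitative reward-category associations the pipeline
# is meant to detect.
default_category_probs <- function() {
  p <- function(...) {
    v <- c(...)
    v / sum(v)
  }
  tepal <- list(
    deceit = p("UV+White" = .65, "UV-White" = .15, "UV-Red" = .15, "UV+Pink" = .05),
    nectar = p("UV-White" = .50, "UV-Green" = .20, "UV+White" = .15, "UV-Yellow" = .15),
    oil = p("UV-Black" = .60, "UV-Yellow" = .20, "UV-Green" = .20),
    fragrance = p("UV-Black" = .50, "UV-Green" = .30, "UV-Cyan" = .20),
    unknown = p("UV-White" = .25, "UV+White" = .15, "UV-Green" = .20,
                "UV-Yellow" = .20, "UV-Black" = .10, "UV-Red" = .10)
  )
  lip_tip <- list(
    deceit = p("UV-White" = .40, "UV-Yellow" = .30, "UV+White" = .20, "UV-Red" = .10),
    nectar = p("UV-Yellow" = .60, "UV-White" = .25, "UV-Green" = .15),
    oil = p("UV+Yellow" = .65, "UV-Black" = .25, "UV-Yellow" = .10),
    fragrance = p("UV-Green" = .60, "UV-Black" = .20, "UV-Yellow" = .20),
    unknown = p("UV-Yellow" = .30, "UV-White" = .20, "UV-Green" = .20,
                "UV+Yellow" = .15, "UV-Black" = .15)
  )
  lip_base <- list(
    deceit = p("UV+Pink" = .50, "UV-Yellow" = .30, "UV+White" = .20),
    nectar = p("UV-Yellow" = .50, "UV-White" = .30, "UV-Red" = .20),
    oil = p("UV+Yellow" = .50, "UV-Black" = .30, "UV-Yellow" = .20),
    fragrance = p("UV+Black" = .35, "UV-Cyan" = .35, "UV-Black" = .30),
    unknown = p("UV-Yellow" = .35, "UV-White" = .20, "UV-Black" = .20,
                "UV-Green" = .15, "UV+Pink" = .10)
  )
  list(sepal = tepal, petal = tepal, lip_tip = lip_tip, lip_base = lip_base)
}

#' Scenario configuration for the synthetic community
#'
#' Defaults are the "paper-like" study conditions: 95 species in the printed
#' reward-group sizes (47 unknown, 19 deceit, 8 nectar, 10 oil, 11 fragrance),
#' 21 species with at least one missing flower module (leaving 74 complete),
#' 35 species with pollinator ITS, 2% spectral noise, three replicate spectra,
#' a chromatic-contrast/flower-size coupling of 0.5 and an achromatic/display
#' coupling of -0.3 (signs and magnitudes chosen to mirror the reported
#' integration structure), and a 30% Brownian share in the size latents.
#'
#' @param n_species Total species count.
#' @param reward_counts Named integer vector over reward types (sums to
#'   `n_species`).
#' @param rho_c Correlation between realized chromatic contrast and the
#'   flower-size latent.
#' @param rho_a Correlation between realized achromatic contrast and the
#'   display-size latent.
#' @param noise_sd Spectral noise sd (percent).
#' @param n_replicates Replicate spectra per module.
#' @param n_incomplete Species with >= 1 missing flower module.
#' @param missing_weights Relative module-missingness weights among incomplete
#'   species.
#' @param n_its Species with pollinator ITS data.
#' @param bm_share Fraction of residual size-latent variance following
#'   Brownian motion on the tree.
#' @param birth_rate Pure-birth rate of the simulated tree.
#' @param category_probs Per-module, per-reward category distributions
#'   (default [default_category_probs()] internally).
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(n_species = 95,
                            reward_counts = c(unknown = 47, deceit = 19, nectar = 8,
                                              oil = 10, fragrance = 11),
                            rho_c = 0.5, rho_a = -0.3,
                            noise_sd = 2, n_replicates = 3,
                            n_incomplete = 21,
                            missing_weights = c(sepal = 10, petal = 16, lip_tip = 4, lip_base = 10),
                            n_its = 35, bm_share = 0.3, birth_rate = 1,
                            category_probs = NULL) {
  if (sum(reward_counts) != n_species)
    stop("reward_counts must sum to n_species", call. = FALSE)
  if (abs(rho_c) >= 1 || abs(rho_a) >= 1) stop("couplings must be in (-1, 1)", call. = FALSE)
  if (n_incomplete >= n_species) stop("n_incomplete must leave complete species", call. = FALSE)
  structure(list(n_species = n_species, reward_counts = reward_counts,
                 rho_c = rho_c, rho_a = rho_a, noise_sd = noise_sd,
                 n_replicates = n_replicates, n_incomplete = n_incomplete,
                 missing_weights = missing_weights, n_its = n_its,
                 bm_share = bm_share, birth_rate = birth_rate,
                 category_probs = category_probs %||% default_category_probs()),
            class = "scenario_config")
}

#' Generate a complete synthetic study
#'
#' Produces every input the pipeline consumes, with known ground truth:
#' replicate reflectance spectra per species x module (categories drawn from
#' reward-specific distributions), a trait table (nine size variables coupled
#' to the realized colour metrics through latent flower-size and display-size
#' factors with the configured correlations, plus a Brownian component on a
#' pure-birth tree), pollinator ITS for a subset, the tree, and a truth record
#' holding every latent quantity. All randomness flows from `seed` through a
#' fixed splitting scheme; the same seed yields a byte-identical bundle.
#'
#' @param cfg A [scenario_config()].
#' @param seed Integer seed (mandatory for reproducibility).
#' @param ctx Viewing context used to realize the colour metrics the sizes are
#'   coupled to (default [viewing_context()]).
#' @return Object of class `orchid_community`: `spectra` (replicate
#'   `spec_set`), `traits`, `tree`, `truth`.
#' @export
make_community <- function(cfg = scenario_config(), seed = 1, ctx = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  seeds <- seed_stream(seed, 7)
  n <- cfg$n_species
  species <- sprintf("sp%03d", seq_len(n))
  mods <- setdiff(beesignal_modules(), "leaf")

  rewards <- with_seed(seeds[[1]], sample(rep(names(cfg$reward_counts), cfg$reward_counts)))
  tree <- make_tree(n, cfg$birth_rate, seed = seeds[[2]])

  # module presence: a fixed number of species lose >= 1 module
  present <- matrix(TRUE, n, length(mods), dimnames = list(species, mods))
  present <- with_seed(seeds[[3]], {
    inc <- sample.int(n, cfg$n_incomplete)
    # weights are target missing counts among the incomplete species
    w <- pmin(cfg$missing_weights[mods] / cfg$n_incomplete, 0.95)
    for (i in inc) {
      miss <- stats::runif(length(mods)) < w
      if (!any(miss)) miss[sample.int(length(mods), 1L)] <- TRUE
      if (all(miss)) miss[sample.int(length(mods), 1L)] <- FALSE  # keep >= 1 module
      present[i, miss] <- FALSE
    }
    present
  })

  # categories and replicate spectra; species-level saturation and brightness
  # latents create the continuous chromatic and achromatic axes the colour
  # PCA is meant to recover
  wl <- 300:700
  cats <- matrix(NA_character_, n, length(mods), dimnames = list(species, mods))
  sat <- bri <- numeric(n)
  spectra <- with_seed(seeds[[4]], {
    sat <- stats::rnorm(n)
    bri <- stats::rnorm(n)
    values <- list(); meta_sp <- meta_mod <- meta_rep <- character()
    for (i in seq_len(n)) {
      for (m in mods) {
        if (!present[i, m]) next
        probs <- cfg$category_probs[[m]][[rewards[i]]]
        cats[i, m] <- sample(names(probs), 1L, prob = probs)
        targets <- jitter_targets(category_band_targets(cats[i, m]), sat[i], bri[i])
        for (r in seq_len(cfg$n_replicates)) {
          values[[length(values) + 1L]] <- spectrum_from_targets(targets, cfg$noise_sd, wl = wl)
          meta_sp <- c(meta_sp, species[i]); meta_mod <- c(meta_mod, m)
          meta_rep <- c(meta_rep, as.character(r))
        }
      }
    }
    spec_set(wl, do.call(cbind, values), species = meta_sp, module = meta_mod, rep = meta_rep)
  })

  # realized colour metrics the size latents couple to
  ctx <- ctx %||% viewing_context()
  mspec <- mean_spectra(spectra)
  loc <- hexagon_locus(quantum_catch(mspec, ctx))
  key <- mspec$meta$species
  chromatic <- tapply(sqrt(loc$x^2 + loc$y^2), key, mean)[species]
  achromatic <- tapply(loc$e_green, key, mean)[species]
  c_std <- as.vector(scale(chromatic))
  a_std <- as.vector(scale(achromatic))

  # size latents: coupled part + Brownian + independent residual
  C <- vcv_matrix(tree)[species, species]
  L <- t(chol(C / mean(diag(C))))
  traits <- with_seed(seeds[[5]], {
    resid_f <- sqrt(cfg$bm_share) * as.vector(L %*% stats::rnorm(n)) +
      sqrt(1 - cfg$bm_share) * stats::rnorm(n)
    resid_d <- sqrt(cfg$bm_share) * as.vector(L %*% stats::rnorm(n)) +
      sqrt(1 - cfg$bm_share) * stats::rnorm(n)
    # residualize against the colour metrics so the configured couplings are
    # realized exactly in-sample (controlled covariance)
    orth <- function(r, z) as.vector(scale(stats::residuals(stats::lm(r ~ z))))
    f <- cfg$rho_c * c_std + sqrt(1 - cfg$rho_c^2) * orth(resid_f, c_std)
    d <- cfg$rho_a * a_std + sqrt(1 - cfg$rho_a^2) * orth(resid_d, a_std)
    e <- function(sd) stats::rnorm(n, 0, sd)
    area <- 600 * exp(0.8 * f + 0.20 * e(1))
    data.frame(
      species = species, reward_type = rewards,
      reward_presence = presence_from_type(rewards),
      petal_length = 25 * exp(0.40 * f + 0.12 * e(1)),
      sepal_length = 28 * exp(0.38 * f + 0.12 * e(1)),
      lip_length = 20 * exp(0.35 * f + 0.15 * e(1)),
      inflorescence_length = 180 * exp(0.50 * d + 0.20 * e(1)),
      flower_depth = 12 * exp(0.45 * f + 0.20 * e(1)),
      flower_area = area,
      flower_radius = sqrt(area / pi),
      flowers_per_inflorescence = pmax(1, round(exp(1.6 + 0.6 * d + 0.25 * e(1)))),
      inflorescences_per_individual = pmax(1, round(exp(0.8 + 0.5 * d + 0.30 * e(1)))),
      f_latent = f, d_latent = d,
      stringsAsFactors = FALSE
    )
  })
  traits$its_mm <- NA_real_
  traits <- with_seed(seeds[[6]], {
    its_sp <- sample(species, cfg$n_its)
    idx <- match(its_sp, species)
    traits$its_mm[idx] <- 3.0 * exp(0.20 * a_std[idx] + 0.15 * stats::rnorm(cfg$n_its))
    traits
  })
  truth <- list(seed = seed, config = cfg, rewards = stats::setNames(rewards, species),
                categories = cats, present = present,
                saturation = stats::setNames(sat, species),
                brightness = stats::setNames(bri, species),
                chromatic = stats::setNames(as.vector(chromatic), species),
                achromatic = stats::setNames(as.vector(achromatic), species),
                f_latent = stats::setNames(traits$f_latent, species),
                d_latent = stats::setNames(traits$d_latent, species))
  traits$f_latent <- traits$d_latent <- NULL
  structure(list(spectra = spectra, traits = traits, tree = tree, truth = truth),
            class = "orchid_community")
}

#' @export
print.orchid_community <- function(x, ...) {
  cat(sprintf("<orchid_community> %d species, %d spectra, seed %s\n",
              nrow(x$traits), ncol(x$spectra$values), x$truth$seed))
  print(table(x$traits$reward_type))
  invisible(x)
}

#' Write a synthetic community to disk
#'
#' Emits exactly the file formats the pipeline consumes: `spectra.csv` (wide,
#' percent reflectance), `traits.csv`, `tree.nwk`, and `truth.json`.
#'
#' @param x An [make_community()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(x, dir) {
  stopifnot(inherits(x, "orchid_community"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wide <- data.frame(wavelength = x$spectra$wl,
                     100 * x$spectra$values, check.names = FALSE)
  utils::write.csv(wide, file.path(dir, "spectra.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(x$traits, file.path(dir, "traits.csv"), row.names = FALSE, quote = FALSE)
  ape::write.tree(x$tree, file.path(dir, "tree.nwk"))
  truth <- x$truth
  truth$config <- unclass(truth$config)
  truth$categories <- as.data.frame(truth$categories)
  truth$present <- as.data.frame(truth$present)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(dir)
}
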