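# Shared fixtures, built in code at test time.

.fixture_env <- new.env(parent = emptyenv())

# Default viewing context, built once per session.
test_ctx <- function() {
  if (is.null(.fixture_env$ctx)) .fixture_env$ctx <- viewing_context()
  .fixture_env$ctx
}

test_boundary <- function() {
  if (is.null(.fixture_env$boundary))
    .fixture_env$boundary <- monochromatic_locus(test_ctx())
  .fixture_env$boundary
}

# Random smooth broadband reflectance spectra (constant base plus a few
# Gaussian bumps), independent of the package's own generator.
random_smooth_spectra <- function(n, seed = 1, wl = 300:700) {
  set.seed(seed)
  vals <- vapply(seq_len(n), function(i) {
    v <- runif(1, 0.05, 0.6)
    for (k in seq_len(sample(1:3, 1))) {
      v <- v + runif(1, -0.3, 0.4) *
        exp(-((wl - runif(1, 300, 700)) / runif(1, 30, 90))^2)
    }
    pmax(v, 0.001)
  }, numeric(length(wl)))
  spec_set(wl, vals)
}

# Small wide-format spectra CSV on disk; returns the path.
write_spectra_csv <- function(df, percent = TRUE) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Minimal valid trait table for n species.
toy_traits <- function(n, reward = "unknown", seed = 1) {
  set.seed(seed)
  data.frame(
    species = sprintf("sp%03d", seq_len(n)),
    reward_type = rep_len(reward, n),
    petal_length = runif(n, 10, 40), sepal_length = runif(n, 10, 40),
    lip_length = runif(n, 5, 30), inflorescence_length = runif(n, 50, 400),
    flower_depth = runif(n, 2, 25), flower_area = runif(n, 100, 2000),
    flowers_per_inflorescence = sample(1:40, n, replace = TRUE),
    inflorescences_per_individual = sample(1:10, n, replace = TRUE)
  )
}

# A small paper-like community for pipeline tests.
small_config <- function(...) {
  scenario_config(
    n_species = 40,
    reward_counts = c(unknown = 16, deceit = 8, nectar = 6, oil = 5, fragrance = 5),
    n_incomplete = 8, n_its = 15, ...
  )
}

# Tip groups split at the most balanced clade of the tree (phylogenetically
# clustered grouping for the phylANOVA calibration).
clade_groups <- function(tree) {
  pp <- ape::prop.part(tree)
  sizes <- lengths(pp)
  n <- length(tree$tip.label)
  j <- which.min(abs(sizes - n / 2))
  inside <- tree$tip.label[pp[[j]]]
  stats::setNames(factor(ifelse(tree$tip.label %in% inside, "A", "B")), tree$tip.label)
}

# Brownian-motion tip traits on a tree (independent re-implementation via the
# Cholesky factor of the phylogenetic covariance).
bm_traits <- function(tree, n_sim = 1) {
  C <- ape::vcv.phylo(tree)
  L <- t(chol(C))
  m <- L %*% matrix(stats::rnorm(nrow(C) * n_sim), nrow(C), n_sim)
  rownames(m) <- rownames(C)
  m
}
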