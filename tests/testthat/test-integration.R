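test_that("OLS fit recovers exact and null relationships with diagnostics", {
  x <- seq(-2, 2, length.out = 30)
  f <- ols_fit(2 * x, x)
  expect_equal(f$slope, 2, tolerance = 1e-10)
  expect_equal(f$r2, 1, tolerance = 1e-10)

  set.seed(14)
  f0 <- ols_fit(rnorm(200), rnorm(200))
  expect_lt(abs(f0$slope), 0.2)
  expect_true(all(c("shapiro_p", "bp_p") %in% names(f0)))
  expect_identical(f0$n, 200L)

  expect_error(ols_fit(rnorm(10), rep(1, 10)), "zero variance")
  expect_error(ols_fit(c(1, 2, NA), c(1, NA, 3)), "at least 3")
})

test_that("integration suite emits the four colour-size models plus ITS models on the subset", {
  set.seed(6)
  n <- 50
  sp <- sprintf("sp%03d", 1:n)
  scores <- data.frame(species = sp, PC1_color = rnorm(n), PC2_color = rnorm(n),
                       PC1_size = rnorm(n), PC2_size = rnorm(n),
                       PC1_final = rnorm(n), PC2_final = rnorm(n))
  out <- integration_suite(scores)
  expect_identical(nrow(out), 4L)
  expect_setequal(paste(out$response, out$predictor),
                  c("PC1_color PC1_size", "PC1_color PC2_size",
                    "PC2_color PC1_size", "PC2_color PC2_size"))

  its <- stats::setNames(c(runif(20, 2, 5), rep(NA, 30)), sp)
  out2 <- integration_suite(scores, its = its)
  expect_identical(nrow(out2), 10L)
  expect_true(all(out2$n[out2$predictor == "ITS"] == 20L))
})

test_that("only the built-in colour-size coupling is detected across replicates", {
  set.seed(99)
  hits <- matrix(0, 60, 4)
  for (r in seq_len(60)) {
    n <- 74
    chrom_axis <- rnorm(n)
    scores <- data.frame(
      species = sprintf("sp%03d", 1:n),
      PC1_color = rnorm(n),
      PC2_color = chrom_axis,
      PC1_size = 0.55 * chrom_axis + sqrt(1 - 0.55^2) * rnorm(n),
      PC2_size = rnorm(n)
    )
    out <- integration_suite(scores)
    hits[r, ] <- out$p < 0.01
  }
  coupled <- paste(c("PC1_color", "PC1_color", "PC2_color", "PC2_color"),
                   c("PC1_size", "PC2_size", "PC1_size", "PC2_size")) ==
    "PC2_color PC1_size"
  expect_gte(mean(hits[, coupled]), 0.9)
  expect_lte(max(colMeans(hits[, !coupled])), 0.05)
})

test_that("modularity LMM recovers a pair effect and orders marginal means", {
  # balanced synthetic design: 40 species x 10 pairs, species intercepts,
  # sepal-petal contrasts built lowest
  set.seed(33)
  n_sp <- 40
  sp <- sprintf("sp%03d", 1:n_sp)
  pairs <- levels(contrast_table(
    mean_spectra(spec_set(300:700, matrix(0.3, 401, 4), species = "q",
                          module = c("sepal", "petal", "lip_tip", "lip_base"))),
    test_ctx())$pair)
  df <- expand.grid(species = sp, pair = pairs, stringsAsFactors = FALSE)
  b_sp <- stats::setNames(rnorm(n_sp, 0, 0.5), sp)
  delta <- ifelse(df$pair == "sepal-petal", -1, 0)
  df$dS <- 2 + delta + b_sp[df$species] + rnorm(nrow(df), 0, 0.4)
  df$dL <- df$dS; df$lum <- 0.5
  df$type <- ifelse(grepl("^leaf", df$pair), "extrafloral", "intrafloral")
  df$pair <- factor(df$pair, levels = pairs)

  traits <- load_traits(toy_traits(n_sp, reward = rep(c("deceit", "oil"), 20)))
  sizes <- data.frame(species = sp, PC1_size = rnorm(n_sp), PC2_size = rnorm(n_sp))
  fit <- lmm_modularity(df, traits, sizes, response = "chromatic", reward = "type")

  an <- as.data.frame(fit$anova)
  expect_lt(an["pair", "Pr(>F)"], 1e-6)
  expect_gt(an["reward", "Pr(>F)"], 0.05)
  emm <- fit$emmeans
  expect_identical(as.character(emm$pair[which.min(emm$emmean)]), "sepal-petal")
  expect_gte(fit$r2_conditional, fit$r2_marginal)
  # conditional - marginal R2 equals the random-effect share by construction
  expect_equal(fit$r2_conditional - fit$r2_marginal,
               unname(fit$variances["species"] / sum(fit$variances)),
               tolerance = 1e-10)
  expect_gt(fit$variances[["species"]], 0.1)
})

test_that("with no species variance the LMM fixed effects collapse to OLS", {
  set.seed(44)
  n_sp <- 30
  sp <- sprintf("sp%03d", 1:n_sp)
  pairs <- c("leaf-sepal", "leaf-petal", "sepal-petal")
  df <- expand.grid(species = sp, pair = pairs, stringsAsFactors = FALSE)
  df$pair <- factor(df$pair, levels = pairs)
  df$type <- ifelse(grepl("^leaf", df$pair), "extrafloral", "intrafloral")
  df$dS <- 1 + 0.5 * (df$pair == "leaf-petal") + rnorm(nrow(df), 0, 0.3)
  df$dL <- df$dS; df$lum <- 0.5
  traits <- load_traits(toy_traits(n_sp, reward = rep(c("deceit", "oil"), 15)))
  sizes <- data.frame(species = sp, PC1_size = rnorm(n_sp), PC2_size = rnorm(n_sp))
  fit <- suppressWarnings(lmm_modularity(df, traits, sizes, response = "chromatic"))
  expect_lt(fit$variances[["species"]], 0.01)
  mdf <- merge(merge(df, sizes, by = "species"),
               traits[, c("species", "reward_presence")], by = "species")
  mdf$reward <- factor(mdf$reward_presence)
  ref <- stats::lm(dS ~ pair + reward + PC1_size + PC2_size, data = mdf)
  keep <- intersect(names(stats::coef(ref)), names(lme4::fixef(fit$model)))
  expect_equal(lme4::fixef(fit$model)[keep], stats::coef(ref)[keep], tolerance = 1e-6)
})
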