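#' Per-species colour variables
#'
#' Computes the contrast table, the band means and categories, and spectral
#' purity per module, then assembles the 34-column colour matrix used by the
#' ordination stage (see [build_color_matrix()]).
#'
#' @param mspec Mean reflectance `spec_set` (species x module columns).
#' @param ctx A [viewing_context()].
#' @param bandwidth_nm Monochromatic-locus bandwidth (nm).
#' @return List: `contrasts`, `categories`, `purity`, `loci` (hexagon x/y per
#'   species x module), `color_matrix`.
#' @export
color_variables <- function(mspec, ctx, bandwidth_nm = 10) {
  contrasts <- contrast_table(mspec, ctx)
  categories <- category_table(mspec)
  loc <- hexagon_locus(quantum_catch(mspec, ctx))
  boundary <- monochromatic_locus(ctx, bandwidth_nm)
  pur <- spectral_purity(loc, boundary)
  purity <- data.frame(species = mspec$meta$species, module = mspec$meta$module,
                       purity = pur$purity, boundary_lambda = pur$boundary_lambda)
  loci <- data.frame(species = mspec$meta$species, module = mspec$meta$module,
                     x = loc$x, y = loc$y)
  list(contrasts = contrasts, categories = categories, purity = purity, loci = loci,
       color_matrix = build_color_matrix(contrasts, categories, purity))
}

#' Run the full reward-signal analysis
#'
#' Orchestrates the stages in dependency order: spectra (resampling and
#' replicate averaging), bee-vision modelling, colour categorization, subset
#' assembly, nested PCA, reward-clustering tests (PERMANOVA, pairwise
#' PERMANOVA, PERMDISP on PCA and hexagon spaces; chi-square per module),
#' phylogenetic comparative tests (Blomberg's K, phylogenetic ANOVA on the six
#' PC scores), and integration/modularity models. Every stochastic stage draws
#' its seed from `seed` through a fixed splitting scheme, recorded in the
#' result; reruns with the same inputs and seed are identical.
#'
#' @param spectra Replicate reflectance `spec_set` (or a path readable by
#'   [read_spectra()]).
#' @param traits Trait table (or CSV path) for [load_traits()].
#' @param tree Optional `phylo` tree (or Newick path) for the phylogenetic
#'   stage; `NULL` skips it.
#' @param ctx Viewing context (default [viewing_context()]).
#' @param config Named list of stage sizes overriding the defaults:
#'   `n_perm` (999), `chisq_B` (1e4), `k_rand` (999), `phylo_sims` (1000),
#'   `bandwidth_nm` (10).
#' @param seed Integer master seed (default 1).
#' @return Object of class `orchid_study` with elements `spectra_mean`,
#'   `color` (colour variables), `subsets`, `ordination`, `permanova`,
#'   `pairwise`, `permdisp`, `chisq`, `phylo_k`, `phylo_anova`, `integration`,
#'   `modularity`, `config`, `seed`.
#' @export
run_study <- function(spectra, traits, tree = NULL, ctx = NULL,
                      config = list(), seed = 1) {
  cfg <- utils::modifyList(list(n_perm = 999, chisq_B = 1e4, k_rand = 999,
                                phylo_sims = 1000, bandwidth_nm = 10), config)
  if (is.character(spectra)) spectra <- read_spectra(spectra)
  traits <- load_traits(traits)
  if (is.character(tree)) tree <- read_newick(tree, species = traits$species)
  ctx <- ctx %||% viewing_context()
  seeds <- seed_stream(seed, 5)

  mspec <- mean_spectra(resample_spectra(spectra, ctx$grid))
  color <- color_variables(mspec, ctx, cfg$bandwidth_nm)
  subsets <- make_subsets(traits, mspec$meta)

  color_mat <- color$color_matrix[intersect(rownames(color$color_matrix), subsets$color), ,
                                  drop = FALSE]
  size_rows <- match(subsets$size, traits$species)
  size_mat <- as.matrix(traits[size_rows, size_variables()])
  rownames(size_mat) <- subsets$size
  ord <- nested_pca(color_mat, size_mat)

  reward_of <- function(sp, which) traits[[paste0("reward_", which)]][match(sp, traits$species)]

  # coordinate sets tested for reward clustering
  spaces <- list(
    final = list(coords = as.matrix(ord$scores[, c("PC1_final", "PC2_final")]),
                 species = ord$scores$species),
    color = list(coords = as.matrix(ord$scores[, c("PC1_color", "PC2_color")]),
                 species = ord$scores$species),
    size = list(coords = as.matrix(ord$size_scores[, c("PC1_size", "PC2_size")]),
                species = ord$size_scores$species)
  )
  for (m in setdiff(beesignal_modules(), "leaf")) {
    li <- color$loci[color$loci$module == m, ]
    spaces[[paste0("hex_", m)]] <- list(coords = cbind(x = li$x, y = li$y),
                                        species = li$species)
  }

  perm_seeds <- seed_stream(seeds[[1]], 3 * length(spaces) * 2)
  k <- 0L
  permanova_res <- list(); pairwise_res <- list(); permdisp_res <- list()
  for (s in names(spaces)) {
    for (rw in c("presence", "type")) {
      gr <- reward_of(spaces[[s]]$species, rw)
      nm <- paste(s, rw, sep = "_")
      permanova_res[[nm]] <- permanova(spaces[[s]]$coords, gr, cfg$n_perm,
                                       seed = perm_seeds[[k + 1L]])
      pairwise_res[[nm]] <- pairwise_permanova(spaces[[s]]$coords, gr, cfg$n_perm,
                                               seed = perm_seeds[[k + 2L]])
      permdisp_res[[nm]] <- permdisp(spaces[[s]]$coords, gr, cfg$n_perm,
                                     seed = perm_seeds[[k + 3L]])
      k <- k + 3L
    }
  }

  chisq_seeds <- seed_stream(seeds[[2]], 4)
  chisq_res <- list()
  mods <- setdiff(beesignal_modules(), "leaf")
  for (i in seq_along(mods)) {
    cc <- color$categories[color$categories$module == mods[i], ]
    tab <- table(reward_of(cc$species, "type"), cc$category)
    chisq_res[[mods[i]]] <- tryCatch(
      chi_square_sim(tab, B = cfg$chisq_B, seed = chisq_seeds[[i]]),
      error = function(e) NULL)
  }

  phylo_k <- phylo_anova_res <- NULL
  if (!is.null(tree)) {
    axes <- c("PC1_final", "PC2_final", "PC1_color", "PC2_color", "PC1_size", "PC2_size")
    k_seeds <- seed_stream(seeds[[3]], length(axes))
    pa_seeds <- seed_stream(seeds[[4]], 2 * length(axes))
    phylo_k <- list(); phylo_anova_res <- list()
    for (i in seq_along(axes)) {
      ax <- axes[i]
      src <- if (grepl("size", ax)) ord$size_scores else ord$scores
      v <- stats::setNames(src[[ax]], src$species)
      phylo_k[[ax]] <- blomberg_k(v, tree, n_rand = cfg$k_rand, seed = k_seeds[[i]])
      for (j in 1:2) {
        rw <- c("presence", "type")[j]
        phylo_anova_res[[paste(ax, rw, sep = "_")]] <-
          phyl_anova(v, reward_of(names(v), rw), tree, n_sim = cfg$phylo_sims,
                     seed = pa_seeds[[2 * (i - 1) + j]])
      }
    }
  }

  its <- if ("its_mm" %in% names(traits))
    stats::setNames(traits$its_mm, traits$species) else NULL
  integration <- integration_suite(ord$scores, its = its)
  modularity <- modularity_suite(color$contrasts, traits, ord$size_scores)

  structure(list(
    spectra_mean = mspec, color = color, subsets = subsets, ordination = ord,
    permanova = permanova_res, pairwise = pairwise_res, permdisp = permdisp_res,
    chisq = chisq_res, phylo_k = phylo_k, phylo_anova = phylo_anova_res,
    integration = integration, modularity = modularity,
    traits = traits, config = cfg, seed = seed
  ), class = "orchid_study")
}

#' @export
print.orchid_study <- function(x, ...) {
  cat("== Reward-signal study ==\n")
  print(x$subsets)
  print(x$ordination)
  cat("\nPERMANOVA by reward (final PCA space):\n")
  for (nm in c("final_presence", "final_type")) {
    r <- x$permanova[[nm]]
    cat(sprintf("  %-16s F = %5.2f  R2 = %.2f  p = %s\n", nm, r$F, r$R2, format_p(r$p)))
  }
  cat("\nChi-square (reward type x colour category):\n")
  for (m in names(x$chisq)) {
    r <- x$chisq[[m]]
    if (is.null(r)) next
    cat(sprintf("  %-9s X2 = %6.2f  p = %s\n", m, r$statistic, format_p(r$p_sim)))
  }
  if (!is.null(x$phylo_k)) {
    cat("\nBlomberg's K:\n")
    for (ax in names(x$phylo_k)) {
      r <- x$phylo_k[[ax]]
      cat(sprintf("  %-10s K = %.2f  p = %s\n", ax, r$K, format_p(r$p)))
    }
  }
  cat("\nColour-size integration (OLS):\n")
  pc <- x$integration[x$integration$predictor != "ITS", ]
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("  %s ~ %s: R2 = %.2f, F = %.2f, p = %s\n",
                pc$response[i], pc$predictor[i], pc$r2[i], pc$F[i], format_p(pc$p[i])))
  }
  invisible(x)
}
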