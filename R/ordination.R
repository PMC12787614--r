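#' Z-score a numeric matrix
#'
#' Columns are centred to mean 0 and scaled to unit standard deviation
#' (denominator n - 1). Constant columns are an error.
#'
#' @param m Numeric matrix or data frame.
#' @return Matrix of z-scores with `center`/`scale` attributes.
#' @export
zscore <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing values: supply complete cases", call. = FALSE)
  s <- apply(m, 2L, stats::sd)
  if (any(s == 0)) {
    stop("constant column(s): ", paste(colnames(m)[s == 0], collapse = ", "), call. = FALSE)
  }
  scale(m, center = TRUE, scale = s)
}

#' Correlation-matrix principal component analysis
#'
#' PCA of z-scored variables (an eigen-decomposition of the correlation
#' matrix). Component signs are fixed so that each component's
#' largest-magnitude loading is positive, making the output deterministic.
#'
#' @param m Numeric matrix/data frame (rows = observations, complete cases).
#' @return Object of class `pca_model`: `loadings`, `eigenvalues`, `pct_var`,
#'   `scores`, `center`, `scale`, `n`.
#' @export
pca_cor <- function(m) {
  z <- zscore(m)
  pr <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  for (j in seq_len(ncol(pr$rotation))) {
    i <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  ev <- pr$sdev^2
  structure(list(
    loadings = pr$rotation,
    eigenvalues = ev,
    pct_var = 100 * ev / sum(ev),
    scores = pr$x,
    center = attr(z, "scaled:center"),
    scale = attr(z, "scaled:scale"),
    n = nrow(z)
  ), class = "pca_model")
}

#' @export
print.pca_model <- function(x, n_comp = min(4L, length(x$pct_var)), ...) {
  cat(sprintf("<pca_model> %d observations x %d variables\n", x$n, nrow(x$loadings)))
  pct <- x$pct_var[seq_len(n_comp)]
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_along(pct), pct), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.pca_model <- function(x, comps = c(1L, 2L), ...) {
  graphics::plot(x$scores[, comps], asp = 1,
                 xlab = sprintf("PC%d (%.1f%%)", comps[1], x$pct_var[comps[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", comps[2], x$pct_var[comps[2]]), ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(x)
}

#' Nested colour/size PCA hierarchy
#'
#' Separate correlation-matrix PCAs of the colour variables and of the size
#' variables, followed by a final PCA on the four upstream scores
#' (`PC1_color`, `PC2_color`, `PC1_size`, `PC2_size`). The nesting balances
#' the uneven variable counts so colour is not weighted over size. A global
#' PCA on all variables jointly is also returned for reference. The size PCA
#' uses every row of `size_mat`; the colour and final PCAs use the rows of
#' `color_mat` (which must be a subset of the size rows, matched by rowname).
#'
#' @param color_mat Colour-variable matrix (complete cases; species rownames).
#' @param size_mat Size-variable matrix (species rownames).
#' @return Object of class `nested_pca`: the four `pca_model`s, the per-species
#'   `scores` data frame (six PCs, colour-subset species) and `size_scores`
#'   (two PCs, all size rows).
#' @export
nested_pca <- function(color_mat, size_mat) {
  color_mat <- as.matrix(color_mat)
  size_mat <- as.matrix(size_mat)
  if (is.null(rownames(color_mat)) || is.null(rownames(size_mat)))
    stop("matrices must carry species rownames", call. = FALSE)
  common <- rownames(color_mat)
  if (!all(common %in% rownames(size_mat)))
    stop("colour-table species missing from size table", call. = FALSE)

  pca_color <- pca_cor(color_mat)
  pca_size <- pca_cor(size_mat)

  four <- cbind(
    PC1_color = pca_color$scores[, 1L],
    PC2_color = pca_color$scores[, 2L],
    PC1_size = pca_size$scores[common, 1L],
    PC2_size = pca_size$scores[common, 2L]
  )
  pca_final <- pca_cor(four)
  pca_global <- pca_cor(cbind(color_mat, size_mat[common, , drop = FALSE]))

  scores <- data.frame(
    species = common,
    four,
    PC1_final = pca_final$scores[, 1L],
    PC2_final = pca_final$scores[, 2L],
    row.names = common
  )
  size_scores <- data.frame(
    species = rownames(size_mat),
    PC1_size = pca_size$scores[, 1L],
    PC2_size = pca_size$scores[, 2L],
    row.names = rownames(size_mat)
  )
  structure(list(pca_color = pca_color, pca_size = pca_size, pca_final = pca_final,
                 pca_global = pca_global, scores = scores, size_scores = size_scores),
            class = "nested_pca")
}

#' @export
print.nested_pca <- function(x, ...) {
  f2 <- function(p) sum(p$pct_var[1:2])
  cat("<nested_pca>\n")
  cat(sprintf("  colour PCA (%d vars): first two PCs %.1f%% (%.1f + %.1f)\n",
              nrow(x$pca_color$loadings), f2(x$pca_color),
              x$pca_color$pct_var[1], x$pca_color$pct_var[2]))
  cat(sprintf("  size PCA   (%d vars): first two PCs %.1f%% (%.1f + %.1f)\n",
              nrow(x$pca_size$loadings), f2(x$pca_size),
              x$pca_size$pct_var[1], x$pca_size$pct_var[2]))
  cat(sprintf("  final PCA  (4 scores): PC1 %.1f%%, PC2 %.1f%%\n",
              x$pca_final$pct_var[1], x$pca_final$pct_var[2]))
  cat(sprintf("  global PCA (%d vars): first two PCs %.1f%%\n",
              nrow(x$pca_global$loadings), f2(x$pca_global)))
  invisible(x)
}

#' Assemble the colour-variable matrix
#'
#' The 34 colour variables per species: for each of the four flower modules,
#' the chromatic contrast against the leaf background (`dS`), the extrafloral
#' achromatic signal (`lum`), spectral purity, and the four band means
#' (4 x 7 = 28), plus the six intrafloral chromatic contrasts. Intrafloral
#' achromatic contrasts (`dL`) are deliberately excluded from ordination
#' input. Only species with all four modules yield complete rows; incomplete
#' rows are dropped.
#'
#' @param contrasts Output of [contrast_table()].
#' @param categories Output of [category_table()] (band means are reused).
#' @param purity Data frame `species`, `module`, `purity` (see
#'   [color_variables()] for the assembled pipeline version).
#' @return Numeric matrix with species rownames, 34 columns.
#' @export
build_color_matrix <- function(contrasts, categories, purity) {
  mods <- setdiff(beesignal_modules(), "leaf")
  species <- sort(unique(categories$species))
  cols <- list()
  for (m in mods) {
    extv <- contrasts[contrasts$pair == paste0("leaf-", m), ]
    cols[[paste0("dS_", m)]] <- extv$dS[match(species, extv$species)]
    cols[[paste0("lum_", m)]] <- extv$lum[match(species, extv$species)]
    pv <- purity[purity$module == m, ]
    cols[[paste0("purity_", m)]] <- pv$purity[match(species, pv$species)]
    bv <- categories[categories$module == m, ]
    for (b in c("uv", "blue", "green", "red")) {
      cols[[paste0(b, "_", m)]] <- bv[[b]][match(species, bv$species)]
    }
  }
  intra <- contrast_pairs()
  intra <- intra[intra$type == "intrafloral", ]
  for (i in seq_len(nrow(intra))) {
    pr <- paste(intra$a[i], intra$b[i], sep = "-")
    cv <- contrasts[contrasts$pair == pr, ]
    cols[[paste0("dS_", intra$a[i], "_", intra$b[i])]] <- cv$dS[match(species, cv$species)]
  }
  m <- do.call(cbind, cols)
  rownames(m) <- species
  m[stats::complete.cases(m), , drop = FALSE]
}
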