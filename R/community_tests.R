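# One-factor PERMANOVA on Euclidean coordinates, with the sums of squares
# computed directly from the coordinates (equivalent to the distance-matrix
# partitioning for Euclidean distances, and much faster under permutation).

permanova_ss <- function(coords, groups) {
  n <- nrow(coords)
  tot <- sum(coords^2) - sum(colSums(coords)^2) / n
  gs <- rowsum(coords, groups)            # per-group coordinate sums
  ng <- tabulate(groups)
  within <- sum(coords^2) - sum(gs^2 / ng)
  c(total = tot, within = within, between = tot - within)
}

permanova_f <- function(ss, n, g) {
  (ss[["between"]] / (g - 1)) / (ss[["within"]] / (n - g))
}

#' PERMANOVA (one factor, Euclidean distances)
#'
#' Permutational multivariate analysis of variance following Anderson's
#' partitioning of squared Euclidean distances. The pseudo-F is
#' `(SSB/(g-1)) / (SSW/(n-g))`, `R^2 = SSB/SST`, and the p-value is
#' `(count of permuted F >= observed + 1) / (n_perm + 1)` under free
#' permutation of observation labels.
#'
#' @param coords Numeric matrix of coordinates (rows = observations).
#' @param groups Grouping factor (>= 2 levels; single-member groups allowed
#'   with a warning).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed for the permutations.
#' @return Object of class `permanova`: `F`, `R2`, `p`, `n`, `groups`,
#'   `n_perm`, `ss`, `df`, `seed`.
#' @export
permanova <- function(coords, groups, n_perm = 999, seed = NULL) {
  coords <- as.matrix(coords)
  keep <- stats::complete.cases(coords) & !is.na(groups)
  coords <- coords[keep, , drop = FALSE]
  groups <- droplevels(factor(groups[keep]))
  n <- nrow(coords)
  g <- nlevels(groups)
  if (g < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(tabulate(groups) < 2L)) warning("group(s) with a single member", call. = FALSE)
  ss <- permanova_ss(coords, groups)
  f_obs <- permanova_f(ss, n, g)
  eps <- sqrt(.Machine$double.eps)
  f_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      permanova_f(permanova_ss(coords[sample.int(n), , drop = FALSE], groups), n, g)
    }, numeric(1))
  })
  structure(list(
    F = unname(f_obs), R2 = unname(ss[["between"]] / ss[["total"]]),
    p = (sum(f_perm >= f_obs - eps) + 1) / (n_perm + 1),
    n = n, groups = levels(groups), n_perm = n_perm,
    ss = ss, df = c(between = g - 1L, within = n - g), seed = seed
  ), class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (Euclidean, %d permutations)\n", x$n_perm))
  cat(sprintf("  n = %d, groups = %d (%s)\n", x$n, length(x$groups),
              paste(x$groups, collapse = ", ")))
  cat(sprintf("  F = %.3f, R2 = %.3f, p = %s\n", x$F, x$R2, format_p(x$p)))
  invisible(x)
}

#' Pairwise PERMANOVAs between group levels
#'
#' One two-group PERMANOVA per unordered pair of levels; raw p-values are
#' reported (no multiplicity correction).
#'
#' @inheritParams permanova
#' @return Data frame: `group1`, `group2`, `n`, `F`, `R2`, `p`.
#' @export
pairwise_permanova <- function(coords, groups, n_perm = 999, seed = NULL) {
  groups <- droplevels(factor(groups))
  lev <- levels(groups)
  if (length(lev) < 2L) stop("need at least 2 groups", call. = FALSE)
  cmb <- utils::combn(lev, 2L)
  seeds <- seed_stream(seed, ncol(cmb))
  rows <- lapply(seq_len(ncol(cmb)), function(k) {
    sel <- groups %in% cmb[, k]
    r <- permanova(as.matrix(coords)[sel, , drop = FALSE], groups[sel],
                   n_perm = n_perm, seed = seeds[[k]])
    data.frame(group1 = cmb[1L, k], group2 = cmb[2L, k], n = r$n,
               F = r$F, R2 = r$R2, p = r$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' PERMDISP: multivariate homogeneity of dispersions
#'
#' Distances of observations to their group spatial median (via
#' `vegan::betadisper`), a permutation test of the dispersion ANOVA F
#' (`vegan::permutest`) and post-hoc Tukey HSD comparisons of group
#' dispersions.
#'
#' @inheritParams permanova
#' @param type Center type passed to `vegan::betadisper` (`"median"` default).
#' @return Object of class `permdisp`: group dispersions, `F`, `p`,
#'   `pairwise` Tukey table.
#' @export
permdisp <- function(coords, groups, n_perm = 999, seed = NULL, type = "median") {
  coords <- as.matrix(coords)
  keep <- stats::complete.cases(coords) & !is.na(groups)
  groups <- droplevels(factor(groups[keep]))
  bd <- vegan::betadisper(stats::dist(coords[keep, , drop = FALSE]), groups, type = type)
  pt <- with_seed(seed, vegan::permutest(bd, permutations = n_perm))
  tk <- stats::TukeyHSD(bd)
  structure(list(
    dispersions = tapply(bd$distances, bd$group, mean),
    F = pt$tab$F[1L],
    p = pt$tab[1L, "Pr(>F)"],
    n = length(bd$distances), groups = levels(groups), n_perm = n_perm,
    pairwise = tk$group, seed = seed
  ), class = "permdisp")
}

#' @export
print.permdisp <- function(x, ...) {
  cat(sprintf("PERMDISP (%d permutations): F = %.3f, p = %s\n",
              x$n_perm, x$F, format_p(x$p)))
  cat("  mean dispersion by group:\n")
  print(round(x$dispersions, 4))
  invisible(x)
}

#' Chi-square test with Monte-Carlo p-value and standardized residuals
#'
#' Pearson chi-square on a contingency table with the p-value simulated from
#' `B` random tables with fixed margins (Patefield's algorithm via
#' `stats::chisq.test(simulate.p.value = TRUE)`). Cell residuals are adjusted
#' standardized residuals `(O - E) / sqrt(E (1 - row share)(1 - col share))`
#' by default, or plain Pearson residuals `(O - E)/sqrt(E)` with
#' `residuals = "pearson"`. Zero-margin rows/columns are dropped with a
#' warning.
#'
#' @param tab Matrix or table of non-negative integer counts.
#' @param B Number of Monte-Carlo replicates (default 1e6, as for small tables
#'   in community analyses; reduce for quick runs).
#' @param seed Optional integer seed.
#' @param residuals `"adjusted"` (default) or `"pearson"`.
#' @return Object of class `chisq_sim`: `statistic`, `p_sim`, `B`, `observed`,
#'   `expected`, `SR`.
#' @export
chi_square_sim <- function(tab, B = 1e6, seed = NULL,
                           residuals = c("adjusted", "pearson")) {
  residuals <- match.arg(residuals)
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers", call. = FALSE)
  zr <- rowSums(tab) == 0; zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("dropping zero-margin rows/columns", call. = FALSE)
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("table must be at least 2x2 after dropping", call. = FALSE)
  ct <- with_seed(seed, stats::chisq.test(tab, simulate.p.value = TRUE, B = B))
  structure(list(
    statistic = unname(ct$statistic),
    p_sim = unname(ct$p.value),
    B = B,
    observed = ct$observed,
    expected = ct$expected,
    SR = if (residuals == "adjusted") ct$stdres else ct$residuals,
    residual_type = residuals, seed = seed
  ), class = "chisq_sim")
}

#' @export
print.chisq_sim <- function(x, ...) {
  cat(sprintf("Pearson chi-square, simulated p (B = %g)\n", x$B))
  cat(sprintf("  X2 = %.3f, p = %s\n", x$statistic, format_p(x$p_sim)))
  cat(sprintf("  %s standardized residuals: range %.2f to %.2f\n",
              x$residual_type, min(x$SR), max(x$SR)))
  invisible(x)
}
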