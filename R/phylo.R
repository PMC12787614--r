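#' Read and validate a Newick tree
#'
#' Parses a Newick file (or string), requiring branch lengths and unique tip
#' labels. Polytomies are allowed. When `species` is supplied, tips absent
#' from it are dropped with a warning.
#'
#' @param path Path to a Newick file, or a Newick string.
#' @param species Optional character vector of analysis species ids.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path, species = NULL) {
  tree <- if (grepl(";", path, fixed = TRUE)) ape::read.tree(text = path)
          else ape::read.tree(path)
  if (is.null(tree)) stop("malformed Newick input", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels", call. = FALSE)
  if (!is.null(species)) {
    drop <- setdiff(tree$tip.label, species)
    if (length(drop)) {
      warning(sprintf("dropping %d tip(s) absent from the trait table", length(drop)),
              call. = FALSE)
      tree <- ape::drop.tip(tree, drop)
    }
  }
  tree
}

#' Phylogenetic variance-covariance matrix
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j under
#' Brownian motion; the diagonal holds root-to-tip depths.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @return Symmetric n x n matrix with tip-label dimnames.
#' @export
vcv_matrix <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  ape::vcv.phylo(tree)
}

# Phylogenetic GLS mean and the two mean squared errors entering K.
k_ratio <- function(x, iC, diagC_sum, n) {
  one_iC <- colSums(iC)
  ahat <- sum(one_iC * x) / sum(one_iC)
  d <- x - ahat
  mse0 <- sum(d * d)
  mse <- sum(d * (iC %*% d))
  mse0 / mse
}

#' Blomberg's K phylogenetic signal
#'
#' `K = (MSE0/MSE)_observed / (MSE0/MSE)_expected`, where `MSE0` is the mean
#' squared deviation of tip values from the phylogenetic GLS mean, `MSE` is
#' the phylogenetically corrected mean square, and the Brownian expectation is
#' `(tr(C) - n / (1'C^-1 1)) / (n - 1)`. `K = 1` is the Brownian-motion
#' expectation; the p-value shuffles trait values across tips and counts how
#' often the shuffled `MSE0/MSE` meets the observed one.
#'
#' @param x Named numeric trait vector (names = tip labels; >= 4 values).
#' @param tree An `ape::phylo` tree containing those tips.
#' @param n_rand Number of randomizations (default 1000).
#' @param seed Optional integer seed.
#' @return Object of class `blomberg_k`: `K`, `p`, `n`, `n_rand`.
#' @export
blomberg_k <- function(x, tree, n_rand = 1000, seed = NULL) {
  x <- x[!is.na(x)]
  if (is.null(names(x))) stop("trait vector must be named by tip label", call. = FALSE)
  tips <- intersect(tree$tip.label, names(x))
  if (length(tips) < 4L) stop("need at least 4 tips with trait values", call. = FALSE)
  if (stats::sd(x[tips]) == 0) stop("constant trait", call. = FALSE)
  if (length(tips) < length(tree$tip.label))
    tree <- ape::drop.tip(tree, setdiff(tree$tip.label, tips))
  C <- vcv_matrix(tree)[tips, tips]
  iC <- solve(C)
  n <- length(tips)
  expected <- (sum(diag(C)) - n / sum(iC)) / (n - 1)
  obs <- k_ratio(x[tips], iC, sum(diag(C)), n)
  k <- obs / expected
  p <- NA_real_
  if (n_rand > 0) {
    rand <- with_seed(seed, vapply(seq_len(n_rand), function(i)
      k_ratio(sample(x[tips]), iC, sum(diag(C)), n), numeric(1)))
    eps <- sqrt(.Machine$double.eps)
    p <- (sum(rand >= obs - eps) + 1) / (n_rand + 1)
  }
  structure(list(K = unname(k), p = p, n = n, n_rand = n_rand, seed = seed),
            class = "blomberg_k")
}

#' @export
print.blomberg_k <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.3f (n = %d), randomization p = %s (%d reps)\n",
              x$K, x$n, format_p(x$p), x$n_rand))
  invisible(x)
}

# Vectorized one-way ANOVA F for each column of Y.
anova_f_cols <- function(Y, groups) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  g <- nlevels(groups)
  ng <- tabulate(groups)
  gs <- rowsum(Y, groups)
  ssw <- colSums(Y^2) - colSums(gs^2 / ng)
  sst <- colSums(Y^2) - colSums(Y)^2 / n
  ((sst - ssw) / (g - 1)) / (ssw / (n - g))
}

# Pairwise pooled-variance t statistics for each column of Y.
pairwise_t_cols <- function(Y, groups, cmb) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  g <- nlevels(groups)
  ng <- tabulate(groups)
  gs <- rowsum(Y, groups)
  means <- gs / ng
  msw <- (colSums(Y^2) - colSums(gs^2 / ng)) / (n - g)
  t(vapply(seq_len(ncol(cmb)), function(k) {
    i <- cmb[1L, k]; j <- cmb[2L, k]
    (means[i, ] - means[j, ]) / sqrt(msw * (1 / ng[i] + 1 / ng[j]))
  }, numeric(ncol(Y))))
}

#' Phylogenetic ANOVA (Brownian-simulation null)
#'
#' One-way ANOVA of a tip trait across groups, with the null distribution of F
#' generated by simulating Brownian-motion traits on the tree (rate = REML
#' estimate from the data; F is scale-invariant, so the rate affects only the
#' reported `sig2`). `p = (count of simulated F >= observed + 1)/(n_sim + 1)`.
#' Post-hoc pairwise pooled-variance t-tests use the same simulated null with
#' Holm adjustment.
#'
#' @param x Named numeric trait vector (tips).
#' @param groups Grouping factor named by (or aligned with) `x`.
#' @param tree An `ape::phylo` tree containing the tips.
#' @param n_sim Number of Brownian simulations (default 5000).
#' @param seed Optional integer seed.
#' @param posthoc Compute pairwise table (default TRUE).
#' @return Object of class `phyl_anova`: `F`, `p_phylo`, `n_sim`, `sig2`,
#'   `pairwise` (groups, t, p, p_holm).
#' @export
phyl_anova <- function(x, groups, tree, n_sim = 5000, seed = NULL, posthoc = TRUE) {
  if (is.null(names(x))) stop("trait vector must be named by tip label", call. = FALSE)
  groups <- stats::setNames(as.character(groups), names(x))
  keep <- !is.na(x) & !is.na(groups)
  tips <- intersect(tree$tip.label, names(x)[keep])
  if (!all(names(x)[keep] %in% tree$tip.label))
    stop("trait species absent from the tree", call. = FALSE)
  x <- x[tips]
  gr <- droplevels(factor(groups[tips]))
  if (nlevels(gr) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (length(tips) < length(tree$tip.label))
    tree <- ape::drop.tip(tree, setdiff(tree$tip.label, tips))
  C <- vcv_matrix(tree)[tips, tips]
  iC <- solve(C)
  n <- length(tips)
  one_iC <- colSums(iC)
  ahat <- sum(one_iC * x) / sum(one_iC)
  sig2 <- sum((x - ahat) * (iC %*% (x - ahat))) / (n - 1)  # REML Brownian rate

  f_obs <- unname(anova_f_cols(matrix(x, ncol = 1L), gr))
  L <- t(chol(C))
  sims <- with_seed(seed, L %*% matrix(stats::rnorm(n * n_sim), n, n_sim))
  f_sim <- anova_f_cols(sims, gr)
  eps <- sqrt(.Machine$double.eps)
  p <- (sum(f_sim >= f_obs - eps) + 1) / (n_sim + 1)

  pw <- NULL
  if (posthoc && nlevels(gr) > 1L) {
    cmb <- utils::combn(nlevels(gr), 2L)
    t_obs <- pairwise_t_cols(matrix(x, ncol = 1L), gr, cmb)[, 1L]
    t_sim <- pairwise_t_cols(sims, gr, cmb)
    p_pair <- vapply(seq_along(t_obs), function(k)
      (sum(abs(t_sim[k, ]) >= abs(t_obs[k]) - eps) + 1) / (n_sim + 1), numeric(1))
    pw <- data.frame(group1 = levels(gr)[cmb[1L, ]], group2 = levels(gr)[cmb[2L, ]],
                     t = t_obs, p = p_pair, p_holm = stats::p.adjust(p_pair, "holm"))
  }
  structure(list(F = f_obs, p_phylo = p, n = n, n_sim = n_sim, sig2 = sig2,
                 groups = levels(gr), pairwise = pw, seed = seed),
            class = "phyl_anova")
}

#' @export
print.phyl_anova <- function(x, ...) {
  cat(sprintf("Phylogenetic ANOVA (%d BM simulations)\n", x$n_sim))
  cat(sprintf("  n = %d, groups: %s\n", x$n, paste(x$groups, collapse = ", ")))
  cat(sprintf("  F = %.3f, simulation p = %s\n", x$F, format_p(x$p_phylo)))
  invisible(x)
}
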