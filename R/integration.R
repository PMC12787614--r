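#' Ordinary least-squares fit for one color-size pair
#'
#' Simple linear regression `y ~ x` with slope inference and residual
#' diagnostics (Shapiro-Wilk normality; Breusch-Pagan heteroskedasticity).
#'
#' @param y,x Numeric vectors; incomplete pairs are dropped (>= 3 required).
#' @param labels Optional `c(response, predictor)` names for printing.
#' @return Object of class `ols_fit`: `slope`, `intercept`, `se`, `t`, `p`,
#'   `r2`, `F`, `n`, `shapiro_w`, `shapiro_p`, `bp_stat`, `bp_p`.
#' @export
ols_fit <- function(y, x, labels = c("y", "x")) {
  keep <- stats::complete.cases(y, x)
  y <- y[keep]; x <- x[keep]
  if (length(y) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance in the predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  co <- s$coefficients
  sh <- stats::shapiro.test(stats::residuals(fit))
  bp <- lmtest::bptest(fit)
  structure(list(
    slope = unname(co["x", "Estimate"]), intercept = unname(co["(Intercept)", "Estimate"]),
    se = unname(co["x", "Std. Error"]), t = unname(co["x", "t value"]),
    p = unname(co["x", "Pr(>|t|)"]), r2 = unname(s$r.squared),
    F = unname(s$fstatistic[1L]), n = length(y),
    shapiro_w = unname(sh$statistic), shapiro_p = unname(sh$p.value),
    bp_stat = unname(bp$statistic), bp_p = unname(bp$p.value),
    labels = labels, model = fit
  ), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS %s ~ %s (n = %d)\n", x$labels[1], x$labels[2], x$n))
  cat(sprintf("  slope = %.4f (SE %.4f), t = %.2f, p = %s\n",
              x$slope, x$se, x$t, format_p(x$p)))
  cat(sprintf("  R2 = %.3f, F = %.2f\n", x$r2, x$F))
  invisible(x)
}

#' Colour-size integration models
#'
#' The four OLS models relating colour and size principal components
#' (`PC1_color`/`PC2_color` each against `PC1_size`/`PC2_size`), plus, when
#' ITS is supplied, each of the six PC axes regressed on mean pollinator
#' intertegular span over the ITS subset.
#'
#' @param scores Per-species scores data frame from [nested_pca()] (columns
#'   `PC1_color`, `PC2_color`, `PC1_size`, `PC2_size`, `PC1_final`,
#'   `PC2_final`, rownames/`species`).
#' @param its Optional named numeric vector of ITS (mm) per species.
#' @return Data frame with one row per model: `response`, `predictor`, `n`,
#'   `slope`, `se`, `t`, `p`, `r2`, `F`.
#' @export
integration_suite <- function(scores, its = NULL) {
  combos <- expand.grid(response = c("PC1_color", "PC2_color"),
                        predictor = c("PC1_size", "PC2_size"),
                        stringsAsFactors = FALSE)
  combos <- combos[order(combos$response, combos$predictor), ]
  row_of <- function(fit, response, predictor) {
    data.frame(response = response, predictor = predictor, n = fit$n,
               slope = fit$slope, se = fit$se, t = fit$t, p = fit$p,
               r2 = fit$r2, F = fit$F)
  }
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    r <- combos$response[i]; pr <- combos$predictor[i]
    row_of(ols_fit(scores[[r]], scores[[pr]], labels = c(r, pr)), r, pr)
  })
  if (!is.null(its)) {
    common <- intersect(scores$species, names(its)[!is.na(its)])
    axes <- intersect(c("PC1_color", "PC2_color", "PC1_size", "PC2_size",
                        "PC1_final", "PC2_final"), names(scores))
    for (ax in axes) {
      fit <- ols_fit(scores[match(common, scores$species), ax], its[common],
                     labels = c(ax, "ITS"))
      rows[[length(rows) + 1L]] <- row_of(fit, ax, "ITS")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Linear mixed model for intrafloral modularity
#'
#' Fits `contrast ~ pair + reward + PC1_size + PC2_size + (1 | sp)` by REML
#' (`lmerTest`), where `contrast` is the chromatic (`dS`) or achromatic
#' response across module pairs. For the achromatic response, extrafloral rows
#' use the patch's green signal deviation from the adapted background
#' (`|lum - 0.5|`) and intrafloral rows use `dL`, stacked in one response with
#' `pair` distinguishing them. Per-term F-tests use Satterthwaite denominator
#' degrees of freedom; marginal and conditional R^2 follow the
#' Nakagawa-Schielzeth variance partition; pairwise comparisons between `pair`
#' levels are estimated marginal means with Tukey adjustment.
#'
#' @param contrasts Contrast table from [contrast_table()].
#' @param traits Trait table with `species` and reward columns.
#' @param size_scores Data frame with `species`, `PC1_size`, `PC2_size`.
#' @param response `"chromatic"` or `"achromatic"`.
#' @param reward `"presence"` or `"type"`.
#' @return Object of class `lmm_modularity`: the fitted model, `anova` table,
#'   `r2_marginal`, `r2_conditional`, `variances`, `emmeans_pairs`, `singular`.
#' @export
lmm_modularity <- function(contrasts, traits, size_scores,
                           response = c("chromatic", "achromatic"),
                           reward = c("presence", "type")) {
  response <- match.arg(response)
  reward <- match.arg(reward)
  df <- contrasts
  df$value <- if (response == "chromatic") df$dS else
    ifelse(df$type == "extrafloral", abs(df$lum - 0.5), df$dL)
  rw_col <- paste0("reward_", reward)
  df$reward <- factor(traits[[rw_col]][match(df$species, traits$species)])
  df$PC1_size <- size_scores$PC1_size[match(df$species, size_scores$species)]
  df$PC2_size <- size_scores$PC2_size[match(df$species, size_scores$species)]
  df$sp <- factor(df$species)
  df <- df[stats::complete.cases(df[, c("value", "pair", "reward", "PC1_size", "PC2_size")]), ]
  df$pair <- droplevels(df$pair)

  fit <- lmerTest::lmer(value ~ pair + reward + PC1_size + PC2_size + (1 | sp),
                        data = df, REML = TRUE)
  singular <- lme4::isSingular(fit)
  if (singular) warning("singular random-effect fit (species variance ~ 0)", call. = FALSE)
  an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")

  vc <- as.data.frame(lme4::VarCorr(fit))
  var_sp <- vc$vcov[vc$grp == "sp"]
  var_res <- vc$vcov[vc$grp == "Residual"]
  var_fix <- stats::var(as.vector(stats::model.matrix(fit) %*% lme4::fixef(fit)))
  tot <- var_fix + var_sp + var_res
  emm <- emmeans::emmeans(fit, pairwise ~ pair, adjust = "tukey", lmer.df = "satterthwaite")

  structure(list(
    model = fit, anova = an,
    r2_marginal = var_fix / tot, r2_conditional = (var_fix + var_sp) / tot,
    variances = c(fixed = var_fix, species = var_sp, residual = var_res),
    emmeans = as.data.frame(emm$emmeans),
    emmeans_pairs = as.data.frame(emm$contrasts),
    singular = singular, response = response, reward = reward, n = nrow(df)
  ), class = "lmm_modularity")
}

#' @export
print.lmm_modularity <- function(x, ...) {
  cat(sprintf("Intrafloral modularity LMM: %s contrast, reward %s (n = %d rows)\n",
              x$response, x$reward, x$n))
  cat(sprintf("  R2 marginal = %.3f, conditional = %.3f%s\n",
              x$r2_marginal, x$r2_conditional, if (x$singular) " [singular fit]" else ""))
  print(round(as.data.frame(x$anova)[, c("F value", "Pr(>F)")], 4))
  invisible(x)
}

#' All four modularity models
#'
#' Chromatic and achromatic responses crossed with reward presence and type.
#'
#' @inheritParams lmm_modularity
#' @return Named list of four [lmm_modularity()] results.
#' @export
modularity_suite <- function(contrasts, traits, size_scores) {
  grid <- expand.grid(response = c("chromatic", "achromatic"),
                      reward = c("presence", "type"), stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i)
    lmm_modularity(contrasts, traits, size_scores, grid$response[i], grid$reward[i]))
  names(out) <- paste(grid$response, grid$reward, sep = "_")
  out
}
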