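#' Per-feature two-group linear model fits
#'
#' Fits, for every feature at once, the ordinary least-squares model
#' `log2 value ~ group (+ batch)`. The group coefficient is the log2 fold
#' change treated minus control; residual variance and degrees of freedom
#' feed the empirical-Bayes moderation step.
#'
#' @param logmatrix Numeric features x samples matrix on the log2 scale.
#' @param group Two-level factor/character vector per sample; the second
#'   level is treated.
#' @param batch Optional batch labels per sample, entered as covariates.
#' @return List with `effect` (group coefficient per feature), `s2`
#'   (residual variance), `df` (residual degrees of freedom, scalar),
#'   `stdev_unscaled` (sqrt of the group coefficient's unscaled variance,
#'   i.e. the design leverage), and `design`.
#' @export
fit_feature_linear_models <- function(logmatrix, group, batch = NULL) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) stop("group must have two levels")
  if (min(table(group)) < 2L) stop("need >= 2 samples per group")
  n <- ncol(logmatrix)
  if (length(group) != n) stop("one group label per sample required")
  g <- as.numeric(group == levels(group)[2])
  design <- cbind(intercept = 1, group = g)
  if (!is.null(batch)) {
    batch <- as.factor(batch)
    if (length(batch) != n) stop("one batch label per sample required")
    if (nlevels(batch) > 1L)
      design <- cbind(design, stats::model.matrix(~batch)[, -1, drop = FALSE])
  }
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design))
    stop("confounded design: batch is collinear with group")
  d <- n - ncol(design)
  if (d < 1L) stop("no residual degrees of freedom")
  coef <- t(qr.coef(qr_d, t(logmatrix)))
  fitted <- coef %*% t(design)
  rss <- rowSums((logmatrix - fitted)^2)
  xtx_inv <- chol2inv(qr.R(qr_d))
  list(
    effect = stats::setNames(coef[, "group"], rownames(logmatrix)),
    s2 = stats::setNames(rss / d, rownames(logmatrix)),
    df = d,
    stdev_unscaled = sqrt(xtx_inv[2, 2]),
    design = design
  )
}

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used to moment-match the prior df from var(log s2).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderation of per-feature variances
#'
#' Assumes the per-feature residual variances follow a scaled F
#' distribution (s2 ~ s0^2 * F(d, d0)) and estimates the prior degrees of
#' freedom `d0` and prior variance `s0^2` by moment-matching the mean and
#' variance of `log(s2)` via digamma/trigamma inversion. The posterior
#' variance for each feature is the precision-weighted compromise
#' `s2_post = (d0 * s0^2 + d * s2) / (d0 + d)`.
#'
#' Zero variances (exact fits) are excluded from prior estimation but
#' still receive a posterior; callers should flag them (see [de_test()]).
#'
#' @param s2 Per-feature residual variances.
#' @param df Residual degrees of freedom (scalar, >= 1).
#' @return List with `d0`, `s0_2`, and `s2_post` (same length as `s2`).
#'   `d0` may be `Inf`, in which case every posterior equals `s0_2`.
#' @export
moderate_variances <- function(s2, df) {
  if (df < 1) stop("residual df must be >= 1")
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 10) stop("need >= 10 features with positive residual variance")
  z <- log(s2[ok])
  e_mean <- mean(z) - digamma(df / 2) + log(df / 2)
  e_var <- stats::var(z) - trigamma(df / 2)
  if (e_var > 0) {
    d0 <- 2 * trigamma_inverse(e_var)
    s0_2 <- exp(e_mean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(e_mean)
  }
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2))
             else (d0 * s0_2 + df * s2) / (d0 + df)
  list(d0 = d0, s0_2 = s0_2,
       s2_post = stats::setNames(s2_post, names(s2)))
}

#' Moderated t statistics and p-values
#'
#' `t = effect / (sqrt(s2_post) * stdev_unscaled)` referred to a Student-t
#' distribution with `d0 + d` degrees of freedom (two-sided).
#'
#' @param effect Per-feature group coefficients (log2 scale).
#' @param s2_post Posterior variances from [moderate_variances()].
#' @param df_total Total degrees of freedom `d0 + d` (may be `Inf`,
#'   giving a normal reference).
#' @param stdev_unscaled Design leverage from
#'   [fit_feature_linear_models()].
#' @return List with `t` and two-sided `p`; features with `s2_post == 0`
#'   get `NA` in both (exact fits, to be flagged upstream).
#' @export
moderated_t <- function(effect, s2_post, df_total, stdev_unscaled) {
  se <- sqrt(s2_post) * stdev_unscaled
  t <- ifelse(se > 0, effect / se, NA_real_)
  p <- 2 * stats::pt(-abs(t), df = df_total)
  list(t = t, p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR control with monotonicity enforcement, capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   propagated).
#' @return Adjusted p-values in the input order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Apply the dual differential-expression threshold
#'
#' A feature is DE iff `fdr < fdr_cut` and `|logFC| > lfc_cut`, both
#' inequalities strict; the DE set is partitioned into up (logFC > 0) and
#' down.
#'
#' @param de A `de_table` data frame (columns `feature_id`, `logFC`,
#'   `fdr`).
#' @param fdr_cut,lfc_cut Thresholds (defaults 0.05 and 0.5).
#' @return The table with `is_de` and `direction` (`"up"`, `"down"`, or
#'   `NA` for non-DE) recomputed.
#' @export
call_de <- function(de, fdr_cut = 0.05, lfc_cut = 0.5) {
  de$is_de <- !is.na(de$fdr) & de$fdr < fdr_cut & abs(de$logFC) > lfc_cut
  de$direction <- ifelse(de$is_de, ifelse(de$logFC > 0, "up", "down"),
                         NA_character_)
  de
}

#' Moderated-t differential expression for one omic
#'
#' The full per-omic test: pre-test transform ([pretest_transform()]),
#' per-feature linear models with the proteome's batch covariate,
#' empirical-Bayes variance moderation, moderated-t p-values,
#' Benjamini-Hochberg correction and the dual DE threshold. Exact-fit
#' features (zero residual variance even after moderation) are flagged
#' with `exact_fit = TRUE`, get `NA` p-values, and are excluded from
#' ranking downstream rather than being assigned p = 0.
#'
#' @param om An [omics_matrix()].
#' @param fdr_cut,lfc_cut DE thresholds.
#' @param use_batch Include the batch covariate when present (default
#'   TRUE).
#' @return A `de_table` data frame: `feature_id`, `logFC`, `t`, `p`,
#'   `fdr`, `is_de`, `direction`, `exact_fit`, with attributes `d0`,
#'   `s0_2`, `df_total` and `omic_kind`.
#' @export
de_test <- function(om, fdr_cut = 0.05, lfc_cut = 0.5, use_batch = TRUE) {
  stopifnot(inherits(om, "omics_matrix"))
  prep <- pretest_transform(om)
  batch <- if (use_batch) prep$omics$batch else NULL
  fit <- fit_feature_linear_models(prep$logvalues, prep$omics$group, batch)
  mod <- moderate_variances(fit$s2, fit$df)
  df_total <- mod$d0 + fit$df
  tt <- moderated_t(fit$effect, mod$s2_post, df_total, fit$stdev_unscaled)
  de <- data.frame(
    feature_id = names(fit$effect),
    logFC = unname(fit$effect),
    t = unname(tt$t),
    p = unname(tt$p),
    fdr = benjamini_hochberg(unname(tt$p)),
    exact_fit = unname(!is.finite(tt$p)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  de <- call_de(de, fdr_cut, lfc_cut)
  attr(de, "d0") <- mod$d0
  attr(de, "s0_2") <- mod$s0_2
  attr(de, "df_total") <- df_total
  attr(de, "omic_kind") <- om$omic_kind
  class(de) <- c("de_table", "data.frame")
  de
}

#' Named DE feature sets from a DE table
#'
#' @param de A `de_table`.
#' @return List with `up`, `down` and `all` feature-id vectors.
#' @export
de_sets <- function(de) {
  list(
    up = de$feature_id[de$is_de & de$logFC > 0],
    down = de$feature_id[de$is_de & de$logFC < 0],
    all = de$feature_id[de$is_de]
  )
}
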