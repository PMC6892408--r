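# Cohort-level inference on the morphometry table: two-way factorial ANOVA
# (genotype x age with interaction) followed by Tukey HSD over all group
# pairs, with the figure-legend star convention.

#' Two-way factorial ANOVA with interaction
#'
#' Fits the full-factorial linear model `response ~ A * B` with
#' sum-to-zero contrasts. Balanced designs use the classical sequential
#' sum-of-squares decomposition (which Type III reproduces exactly there);
#' unbalanced designs use Type-III sums of squares, matching the behaviour
#' of the commercial statistics software family this analysis mirrors.
#' F statistics are `MS_effect / MS_residual` and p-values come from the F
#' distribution. The degrees-of-freedom identity
#' `df_A + df_B + df_AB + df_resid = N - 1` is asserted on every fit.
#'
#' @param data data.frame of animal records (one row per animal).
#' @param factor_a,factor_b Column names of the two factors.
#' @param response Column name of the response metric. Rows with missing
#'   response are dropped listwise.
#' @return Object of class `anova_result`: `effects` data.frame (term, df,
#'   sumsq, meansq, statistic, p_value), `residual` (df, sumsq), `design`
#'   summary and `ss_type`.
#' @export
two_way_anova <- function(data, factor_a, factor_b, response) {
  stopifnot(is.data.frame(data),
            all(c(factor_a, factor_b, response) %in% names(data)))
  d <- data.frame(y = data[[response]],
                  A = factor(data[[factor_a]]),
                  B = factor(data[[factor_b]]))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  d$A <- droplevels(d$A); d$B <- droplevels(d$B)
  if (nlevels(d$A) < 2 || nlevels(d$B) < 2)
    stop("each factor needs at least 2 levels")
  counts <- table(d$A, d$B)
  if (any(counts == 0))
    stop("empty design cell: Type-III decomposition undefined")
  if (!any(counts >= 2))
    stop("at least one design cell needs >= 2 observations")
  balanced <- length(unique(as.vector(counts))) == 1

  fit <- stats::lm(y ~ A * B, data = d,
                   contrasts = list(A = "contr.sum", B = "contr.sum"))
  if (stats::df.residual(fit) < 1) stop("no residual degrees of freedom")

  if (balanced) {
    # the zero-residual-variance diagnostic below supersedes anova.lm's
    # "essentially perfect fit" warning
    tab <- suppressWarnings(stats::anova(fit))
    eff <- tab[rownames(tab) != "Residuals", , drop = FALSE]
    res <- tab["Residuals", ]
    effects <- data.frame(
      term = sub("^A$", factor_a, sub("^B$", factor_b,
               sub("^A:B$", paste0(factor_a, ":", factor_b), rownames(eff)))),
      df = eff$Df, sumsq = eff$`Sum Sq`, meansq = eff$`Mean Sq`,
      statistic = eff$`F value`, p_value = eff$`Pr(>F)`,
      stringsAsFactors = FALSE)
    res_df <- res$Df; res_ss <- res$`Sum Sq`
    ss_type <- "classical (balanced)"
  } else {
    tab <- car::Anova(fit, type = 3)
    keep <- !rownames(tab) %in% c("(Intercept)", "Residuals")
    eff <- tab[keep, , drop = FALSE]
    effects <- data.frame(
      term = sub("^A$", factor_a, sub("^B$", factor_b,
               sub("^A:B$", paste0(factor_a, ":", factor_b), rownames(eff)))),
      df = eff$Df, sumsq = eff$`Sum Sq`,
      meansq = eff$`Sum Sq` / eff$Df,
      statistic = eff$`F value`, p_value = eff$`Pr(>F)`,
      stringsAsFactors = FALSE)
    res_df <- tab["Residuals", "Df"]
    res_ss <- tab["Residuals", "Sum Sq"]
    ss_type <- "Type III (sum-to-zero contrasts)"
  }

  if (res_ss <= .Machine$double.eps * sum(d$y^2)) {
    warning("zero residual variance: F and p undefined, reported as NA")
    effects$statistic <- NA_real_
    effects$p_value <- NA_real_
  }
  stopifnot(sum(effects$df) + res_df == nrow(d) - 1)

  structure(list(
    effects = effects,
    residual = list(df = res_df, sumsq = res_ss),
    design = list(factor_a = factor_a, levels_a = levels(d$A),
                  factor_b = factor_b, levels_b = levels(d$B),
                  n = nrow(d), cell_counts = counts, balanced = balanced),
    ss_type = ss_type,
    response = response
  ), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Two-way ANOVA of %s (%s), n = %d\n",
              x$response, x$ss_type, x$design$n))
  df <- x$effects
  df$stars <- significance_stars(df$p_value)
  print(df, row.names = FALSE, digits = 4)
  cat(sprintf("Residuals: df = %d, SS = %.4g\n",
              x$residual$df, x$residual$sumsq))
  invisible(x)
}

#' All-pairs Tukey honest significant difference comparisons
#'
#' Studentized-range adjusted p-values for every unordered group pair,
#' using the pooled within-group variance from the one-way fit.
#'
#' @param data data.frame of animal records.
#' @param group_factor Column name of the grouping factor (for the usual
#'   four-group layout pass an interaction column, e.g.
#'   `interaction(genotype, age)` stored as a column).
#' @param response Response column name; missing responses are dropped.
#' @return Object of class `tukey_table`: data.frame with `group_i`,
#'   `group_j`, `diff` (mean of i minus mean of j), `p_adj`, `significant`
#'   (`p_adj < 0.05`) and `stars`.
#' @export
tukey_hsd <- function(data, group_factor, response) {
  stopifnot(is.data.frame(data),
            all(c(group_factor, response) %in% names(data)))
  d <- data.frame(y = data[[response]], g = factor(data[[group_factor]]))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  d$g <- droplevels(d$g)
  if (nlevels(d$g) < 2) stop("need at least 2 groups")
  if (any(table(d$g) < 2)) stop("every group needs >= 2 observations")

  fit <- stats::aov(y ~ g, data = d)
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  tk <- stats::TukeyHSD(fit)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- data.frame(
    group_i = vapply(pairs, `[`, "", 1),
    group_j = vapply(pairs, `[`, "", 2),
    diff = tk[, "diff"],
    p_adj = tk[, "p adj"],
    stringsAsFactors = FALSE)
  if (mse <= .Machine$double.eps * mean(d$y^2)) {
    warning("zero pooled within-group variance: adjusted p undefined (NA)")
    out$p_adj <- NA_real_
  }
  out$significant <- !is.na(out$p_adj) & out$p_adj < 0.05
  out$stars <- significance_stars(out$p_adj)
  rownames(out) <- NULL
  class(out) <- c("tukey_table", class(out))
  out
}

#' Star annotation for p-values
#'
#' Strict-inequality binning: `p < 0.05` "*", `p < 0.01` "**",
#' `p < 0.001` "***", `p < 0.0001` "****", otherwise (including exactly
#' 0.05, or missing) "ns".
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Character vector of `"ns"`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @export
significance_stars <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  out <- rep("ns", length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[!is.na(p) & p < 0.0001] <- "****"
  out
}
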