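# Shared statistical machinery: BH-FDR, signed-rank, Kruskal-Wallis,
# Spearman, and the mixed-effects ANOVA contract. Standard tests delegate to
# base R; this layer fixes the exact contracts the analyses rely on (signed
# Z statistics, tie handling, degenerate-input behaviour).

#' Benjamini-Hochberg false-discovery-rate control
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return Tibble with `p`, `q` (monotone BH-adjusted values) and `reject`.
#' @export
bh_fdr <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0) abort("empty p-value vector")
  if (any(pvals < 0 | pvals > 1)) abort("p-values must lie in [0, 1]")
  q <- p.adjust(pvals, method = "BH")
  tibble(p = pvals, q = q, reject = q <= alpha)
}

#' Wilcoxon signed-rank test with a signed Z statistic
#'
#' One-sample (or paired, when `y` is given) two-tailed signed-rank test.
#' Zero differences are dropped. For n <= 25 without ties the p-value comes
#' from the exact null distribution; otherwise from the normal approximation
#' with tie correction. The reported `z` is always the (signed) normal
#' approximation, positive when the differences tend to be positive.
#'
#' @param x Numeric vector (differences, or first sample).
#' @param y Optional second sample for a paired test.
#' @param exact_max Largest n for the exact path (default 25).
#' @return A `recall_htest` list: `statistic` (V, sum of positive ranks),
#'   `z`, `p`, `n` (after zero removal), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) abort("all differences are zero")
  if (n < 5) abort("need at least 5 non-zero differences")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / 48
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tie_corr)
  z <- (v - mu) / sigma
  has_ties <- any(ties > 1)
  if (n <= exact_max && !has_ties) {
    p <- suppressWarnings(wilcox.test(d, exact = TRUE)$p.value)
    method <- "exact"
  } else {
    p <- 2 * pnorm(abs(z), lower.tail = FALSE)
    method <- "normal approximation"
  }
  structure(list(statistic = v, z = z, p = p, n = n,
                 method = paste("Wilcoxon signed rank,", method)),
            class = "recall_htest")
}

#' Kruskal-Wallis rank test across groups
#'
#' Wraps `kruskal.test` with one guard: when every observation is tied (zero
#' rank variance) the statistic is defined as 0 with p = 1.
#'
#' @param groups List of numeric vectors, or a values vector plus `g`.
#' @param g Optional grouping factor when `groups` is a vector.
#' @return A `recall_htest` list: `statistic` (H), `df`, `p`.
#' @export
kruskal_wallis <- function(groups, g = NULL) {
  if (is.list(groups)) {
    values <- unlist(groups, use.names = FALSE)
    g <- factor(rep(seq_along(groups), lengths(groups)))
  } else {
    values <- groups
    g <- factor(g)
  }
  if (nlevels(g) < 2) abort("need at least two groups")
  if (any(tabulate(g) == 0)) abort("empty group")
  if (length(unique(values)) == 1L) {
    return(structure(list(statistic = 0, df = nlevels(g) - 1, p = 1,
                          method = "Kruskal-Wallis (degenerate: all tied)"),
                     class = "recall_htest"))
  }
  kt <- kruskal.test(values, g)
  structure(list(statistic = unname(kt$statistic), df = unname(kt$parameter),
                 p = kt$p.value, method = "Kruskal-Wallis"),
            class = "recall_htest")
}

#' Spearman rank correlation
#'
#' @param x,y Numeric vectors (n >= 5, non-constant).
#' @return A `recall_htest` list: `estimate` (rho), `p` (t-approximation).
#' @export
spearman_cor <- function(x, y) {
  if (length(x) < 5) abort("need at least 5 observations")
  if (sd(x) == 0 || sd(y) == 0) abort("constant input")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  structure(list(estimate = unname(ct$estimate), p = ct$p.value,
                 n = length(x), method = "Spearman rank correlation"),
            class = "recall_htest")
}

#' @export
print.recall_htest <- function(x, ...) {
  cat("<", x$method, ">\n", sep = "")
  flds <- setdiff(names(x), "method")
  for (f in flds) cat(" ", f, "=", format(x[[f]], digits = 4), "\n")
  invisible(x)
}

#' @method tidy recall_htest
#' @export
tidy.recall_htest <- function(x, ...) {
  tibble(statistic = x$statistic %||% x$estimate,
         z = x$z %||% NA_real_,
         estimate = x$estimate %||% NA_real_,
         p.value = x$p, method = x$method)
}

#' Mixed-effects ANOVA on per-electrode summary amplitudes
#'
#' Fits a random-intercept model `response ~ f1 * f2 * ... +
#' (1 | patient / electrode)` (electrode nested in patient) by REML and
#' reports Type-III F tests per fixed effect with Kenward-Roger degrees of
#' freedom (Satterthwaite when pbkrtest is unavailable). With a single
#' patient the random structure reduces to `(1 | electrode)`.
#'
#' @param data Data frame with the response, factor columns, and `patient`,
#'   `electrode` identifiers.
#' @param response Response column name (dB amplitude).
#' @param fixed Character vector of fixed-factor column names (crossed).
#' @param df_method `"kenward-roger"` (default) or `"satterthwaite"`.
#' @return A `recall_mixed_anova` object wrapping the fitted model and a
#'   tidy table of effects.
#' @export
mixed_anova <- function(data, response, fixed,
                        df_method = c("kenward-roger", "satterthwaite")) {
  df_method <- match.arg(df_method)
  if (df_method == "kenward-roger" &&
      !requireNamespace("pbkrtest", quietly = TRUE)) {
    df_method <- "satterthwaite"
  }
  data <- as.data.frame(data)
  for (f in fixed) data[[f]] <- factor(data[[f]])
  data$patient <- factor(data$patient)
  data$electrode <- factor(data$electrode)
  if (nlevels(data$patient) == 1 && nlevels(data$electrode) == 1)
    abort("unidentifiable model: single patient and single electrode")
  ranef_term <- if (nlevels(data$patient) > 1) "(1|patient/electrode)"
                else "(1|electrode)"
  fml <- stats::as.formula(paste(response, "~",
                                 paste(fixed, collapse = " * "), "+",
                                 ranef_term))
  # sum-to-zero contrasts so Type-III tests are meaningful
  contr <- lapply(setNames(fixed, fixed), function(f) "contr.sum")
  fit <- lmerTest::lmer(fml, data = data, REML = TRUE,
                        contrasts = contr)
  ddf <- if (df_method == "kenward-roger") "Kenward-Roger" else "Satterthwaite"
  at <- suppressMessages(stats::anova(fit, type = 3, ddf = ddf))
  table <- tibble(
    effect = rownames(at),
    F = at$`F value`,
    df1 = at$NumDF,
    df2 = at$DenDF,
    p = at$`Pr(>F)`
  )
  structure(list(fit = fit, table = table, df_method = ddf, formula = fml),
            class = "recall_mixed_anova")
}

#' @export
print.recall_mixed_anova <- function(x, ...) {
  cat("<mixed_anova> ", deparse(x$formula), " [", x$df_method, " df]\n",
      sep = "")
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' @method tidy recall_mixed_anova
#' @export
tidy.recall_mixed_anova <- function(x, ...) x$table

#' @method glance recall_mixed_anova
#' @export
glance.recall_mixed_anova <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  tibble(
    n_obs = stats::nobs(x$fit),
    sigma = stats::sigma(x$fit),
    var_random = sum(vc$vcov[vc$grp != "Residual"]),
    df_method = x$df_method
  )
}
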