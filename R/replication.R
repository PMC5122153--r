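# Replication and effect-size statistics: genotype contrasts on breeding
# values, variance explained by a locus, allele frequencies, Mendelian
# ratios and small-group comparisons.

#' Least-squares means contrast between genotype groups
#'
#' Fits a Gaussian linear model of the response on the genotype class plus
#' optional covariate factors (corner-point constraints), computes the
#' least-squares mean of each genotype — the model prediction averaged
#' over a balanced grid of the covariate levels — and a two-sided t test
#' of the contrast between two genotype classes.
#'
#' @param data Data frame.
#' @param response Name of the numeric response column (e.g. a breeding
#'   value).
#' @param genotype Name of the genotype column (factor-like, e.g. `"+/+"`,
#'   `"+/-"`).
#' @param covariates Character vector of covariate column names (treated
#'   as factors), e.g. farm and birth year.
#' @param contrast Length-2 character vector of genotype levels to
#'   contrast; default the first two levels.
#' @return List of class `effect_summary`: `lsmeans` (named vector),
#'   `contrast` (estimate, second minus first level), `se`, `t`, `df`,
#'   `p`.
#' @export
lsmeans_contrast <- function(data, response, genotype,
                             covariates = character(), contrast = NULL) {
  data[[genotype]] <- factor(data[[genotype]])
  glev <- levels(data[[genotype]])
  if (length(glev) < 2L) stop_("need at least 2 genotype classes")
  for (cv in covariates) data[[cv]] <- factor(data[[cv]])
  rhs <- paste(c(genotype, covariates), collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(fml, data = data)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop_("aliased (confounded) terms in the design: ",
          paste(bad, collapse = ", "))
  }
  # balanced grid over covariate levels, one block per genotype
  grid_args <- c(stats::setNames(list(glev), genotype),
                 lapply(stats::setNames(covariates, covariates),
                        function(cv) levels(data[[cv]])))
  grid <- do.call(expand.grid, c(grid_args, stringsAsFactors = TRUE))
  mm <- stats::model.matrix(stats::delete.response(stats::terms(fit)), grid)
  # averaging matrix: one row per genotype, balanced over covariates
  L <- t(vapply(glev, function(g)
    colMeans(mm[grid[[genotype]] == g, , drop = FALSE]),
    numeric(ncol(mm))))
  beta <- stats::coef(fit)
  lsm <- drop(L %*% beta)
  contrast <- contrast %||% glev[1:2]
  if (!all(contrast %in% glev)) stop_("unknown genotype level in contrast")
  lc <- L[contrast[2L], ] - L[contrast[1L], ]
  est <- sum(lc * beta)
  se <- sqrt(drop(t(lc) %*% stats::vcov(fit) %*% lc))
  tval <- est / se
  df <- fit$df.residual
  out <- list(lsmeans = stats::setNames(lsm, glev),
              contrast = est, contrast_levels = contrast, se = se,
              t = tval, df = df,
              p = 2 * stats::pt(-abs(tval), df))
  class(out) <- "effect_summary"
  out
}

#' @export
print.effect_summary <- function(x, ...) {
  cat("Least-squares means:\n")
  print(round(x$lsmeans, 4))
  cat(sprintf("Contrast %s - %s: %.4g (SE %.4g), t(%d) = %.3f, P = %.3g\n",
              x$contrast_levels[2L], x$contrast_levels[1L], x$contrast,
              x$se, x$df, x$t, x$p))
  invisible(x)
}

#' Allele frequency from carrier counts
#'
#' \eqn{(carriers + 2 \cdot homozygotes) / (2n)}, reported to 3 decimal
#' places; the count arithmetic is integer-exact.
#'
#' @param carriers Number of heterozygous carriers.
#' @param homozygotes Number of homozygotes for the allele.
#' @param n Number of genotyped animals.
#' @return Frequency rounded to 3 decimals, with the exact value as
#'   attribute `exact`.
#' @examples
#' allele_freq(311, 0, 6364)  # 0.024
#' @export
allele_freq <- function(carriers, homozygotes = 0, n) {
  if (n <= 0) stop_("n must be positive")
  if (carriers + homozygotes > n)
    stop_("more carriers than genotyped animals")
  exact <- (carriers + 2 * homozygotes) / (2 * n)
  structure(round(exact, 3), exact = exact)
}

#' Genetic variance explained by a biallelic locus
#'
#' Under additive allele-substitution coding the locus contributes
#' \eqn{2 p (1 - p) a^2} to the genetic variance; the proportion explained
#' divides by the total genetic variance and is capped at 1 with a
#' warning. With no homozygous carriers observed, a carrier-coded effect
#' is treated as the allele-substitution effect (flagged in the output).
#'
#' @param effect Allele-substitution effect `a` in response units.
#' @param freq Allele frequency in `(0, 1)`.
#' @param total_genetic_variance Total genetic variance of the trait
#'   (> 0).
#' @return List: `locus_variance`, `proportion`, `coding` flag.
#' @export
variance_explained <- function(effect, freq, total_genetic_variance) {
  if (freq <= 0 || freq >= 1) stop_("freq must lie in (0, 1)")
  if (total_genetic_variance <= 0)
    stop_("total genetic variance must be positive")
  lv <- 2 * freq * (1 - freq) * effect^2
  prop <- lv / total_genetic_variance
  if (prop > 1) {
    warning("locus variance exceeds the total genetic variance; capped at 1")
    prop <- 1
  }
  list(locus_variance = lv, proportion = prop,
       coding = "carrier effect treated as allele-substitution effect")
}

#' Pearson goodness-of-fit test of a Mendelian ratio
#'
#' @param observed Integer counts per genotype class.
#' @param ratio Expected ratio (e.g. `c(1, 2, 1)`), strictly positive.
#' @return List: `chisq`, `df` (classes - 1), `p`.
#' @examples
#' mendelian_chisq(c(37, 76, 29), c(1, 2, 1))
#' @export
mendelian_chisq <- function(observed, ratio) {
  if (length(observed) != length(ratio))
    stop_("observed and ratio lengths differ")
  if (any(ratio <= 0)) stop_("expected ratio must be strictly positive")
  if (sum(observed) <= 0) stop_("no observations")
  expected <- sum(observed) * ratio / sum(ratio)
  chisq <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Pairwise group comparisons (Tukey--Kramer or Welch t tests)
#'
#' `"tukey_kramer"` uses the studentized-range distribution with the
#' unequal-`n` (Kramer) correction and the pooled within-group variance;
#' `"t_test"` performs two-sided Welch tests without multiplicity
#' adjustment. With two balanced groups, the Tukey--Kramer p-value equals
#' the pooled-variance t test via the identity \eqn{q = t\sqrt{2}}.
#'
#' @param values Numeric response vector.
#' @param group Group labels (coerced to factor).
#' @param method `"tukey_kramer"` or `"t_test"`.
#' @return Data frame with one row per pair: `group1`, `group2`, `diff`,
#'   `p`.
#' @export
group_comparisons <- function(values, group,
                              method = c("tukey_kramer", "t_test")) {
  method <- match.arg(method)
  group <- factor(group)
  k <- nlevels(group)
  if (k < 2L) stop_("need at least 2 groups")
  ns <- tapply(values, group, length)
  if (any(ns < 2L)) stop_("each group needs at least 2 observations")
  means <- tapply(values, group, mean)
  vars <- tapply(values, group, stats::var)
  pairs <- utils::combn(levels(group), 2L)
  if (method == "tukey_kramer") {
    df <- length(values) - k
    mse <- sum((ns - 1) * vars) / df
    rows <- apply(pairs, 2L, function(pr) {
      d <- means[pr[2L]] - means[pr[1L]]
      se <- sqrt(mse / 2 * (1 / ns[pr[1L]] + 1 / ns[pr[2L]]))
      q <- abs(d) / se
      data.frame(group1 = pr[1L], group2 = pr[2L], diff = unname(d),
                 p = stats::ptukey(q, nmeans = k, df = df,
                                   lower.tail = FALSE))
    })
  } else {
    if (any(vars == 0))
      stop_("a group has zero variance; the Welch t test is undefined")
    rows <- apply(pairs, 2L, function(pr) {
      tt <- stats::t.test(values[group == pr[2L]], values[group == pr[1L]])
      data.frame(group1 = pr[1L], group2 = pr[2L],
                 diff = unname(diff(rev(tt$estimate))), p = tt$p.value)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
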