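#' Merge per-animal CNV calls into CNV regions
#'
#' A CNV region (CNVR) is the union of overlapping same-type calls on a
#' chromosome. Regions carried by fewer than `min_animals` distinct
#' animals, or at carrier frequency not exceeding `min_freq`, are dropped
#' (the "detected in at least two animals" and "frequency > 1%" filters).
#' Loss and gain calls are merged separately. Coordinates are 1-based
#' inclusive; only truly overlapping calls are unioned (adjacent calls are
#' not).
#'
#' @param calls Data frame with columns `animal`, `chrom`, `start`, `end`,
#'   `type` (`"loss"`/`"gain"`); a `cn` column is allowed and ignored.
#' @param cohort_size Number of animals in the cohort (denominator of the
#'   carrier frequency).
#' @param min_animals Minimum number of distinct carriers (default 2).
#' @param min_freq Regions with `n_carriers / cohort_size <= min_freq` are
#'   dropped (default 0.01).
#' @param chromosomes Optional character vector of valid chromosome names;
#'   calls elsewhere raise an error.
#' @return Data frame with one row per retained region: `region`, `chrom`,
#'   `start`, `end`, `type`, `n_carriers`, `freq`, and a list column
#'   `carriers` of animal ids, sorted by chromosome then start. Result is
#'   idempotent and invariant to the order of the input calls.
#' @export
merge_cnvrs <- function(calls, cohort_size, min_animals = 2,
                        min_freq = 0.01, chromosomes = NULL) {
  need <- c("animal", "chrom", "start", "end", "type")
  if (!all(need %in% names(calls)))
    stop_("calls need columns ", paste(need, collapse = ", "))
  if (nrow(calls) == 0L)
    return(data.frame(region = character(), chrom = character(),
                      start = integer(), end = integer(),
                      type = character(), n_carriers = integer(),
                      freq = numeric()))
  if (any(calls$start >= calls$end) || any(calls$start <= 0))
    stop_("calls must have positive coordinates with start < end")
  if (!is.null(chromosomes) && !all(calls$chrom %in% chromosomes))
    stop_("calls on unknown chromosome: ",
          paste(unique(setdiff(calls$chrom, chromosomes)), collapse = ", "))
  calls$chrom <- as.character(calls$chrom)
  calls$animal <- as.character(calls$animal)

  pieces <- split(calls, list(calls$chrom, calls$type), drop = TRUE)
  regs <- lapply(pieces, function(cc) {
    ir <- IRanges::IRanges(start = cc$start, end = cc$end)
    red <- IRanges::reduce(ir, min.gapwidth = 0L, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    data.frame(chrom = cc$chrom[1L], start = IRanges::start(red),
               end = IRanges::end(red), type = cc$type[1L],
               carriers = I(lapply(revmap, function(i)
                 sort(unique(cc$animal[i])))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, regs)
  out$n_carriers <- lengths(out$carriers)
  out$freq <- out$n_carriers / cohort_size
  out <- out[out$n_carriers >= min_animals & out$freq > min_freq, ,
             drop = FALSE]
  ord <- order(suppressWarnings(as.numeric(out$chrom)), out$chrom,
               out$start, out$end)
  out <- out[ord, , drop = FALSE]
  out$region <- sprintf("CNVR_%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("region", "chrom", "start", "end", "type", "n_carriers", "freq",
          "carriers")]
}

# REML machinery of the one-random-effect linear mixed model
# y = X b + u + e, u ~ N(0, K s2g), e ~ N(0, I s2e), on the
# eigendecomposed scale. lambda = s2g / s2e.
reml_profile <- function(yt, Xt, d, lambda, xtx_logdet) {
  n <- length(yt)
  p <- ncol(Xt)
  w <- lambda * d + 1
  XtWX <- crossprod(Xt, Xt / w)
  bhat <- solve(XtWX, crossprod(Xt, yt / w))
  r <- yt - Xt %*% bhat
  rss <- sum(r^2 / w)
  s2e <- max(rss / (n - p), 1e-300)  # guard the perfect-fit degeneracy
  ll <- -0.5 * ((n - p) * log(2 * pi * s2e) + sum(log(w)) +
                  as.numeric(determinant(XtWX)$modulus) - xtx_logdet +
                  (n - p))
  list(ll = ll, bhat = drop(bhat), s2e = s2e, XtWX = XtWX)
}

#' Mixed-model association test for a CNV region
#'
#' Wald test of a carrier code against a quantitative phenotype under the
#' linear mixed model \eqn{y = W\alpha + x\beta + u + \epsilon} with
#' \eqn{u \sim N(0, G\sigma^2_g)} and the variance ratio
#' \eqn{\lambda = \sigma^2_g/\sigma^2_e} estimated by REML through a 1-D
#' optimisation on the eigendecomposed model (the GEMMA-style scan).
#' With `lambda = 0` (or `G` the identity) the test reduces exactly to the
#' ordinary-least-squares Wald test.
#'
#' @param y Numeric phenotype (e.g. per-animal breeding values).
#' @param x Numeric predictor, typically carrier coding 0/1 (no homozygous
#'   deletion carriers) or dosage 0/1/2.
#' @param K Relationship matrix (see [grm()]), or `NULL` for the identity.
#' @param covariates Optional numeric matrix/data frame of covariates.
#' @param lambda Optional fixed variance ratio; `NULL` (default) estimates
#'   it by REML.
#' @param eig Optional pre-computed `eigen(K, symmetric = TRUE)` (reused
#'   across regions by [cnv_scan()]).
#' @return List of class `lmm_assoc`: `beta`, `se`, `wald`, `p`,
#'   `neg_log10_p`, `lambda`, `sigma2_e`, `sigma2_g`.
#' @export
lmm_assoc <- function(y, x, K = NULL, covariates = NULL, lambda = NULL,
                      eig = NULL) {
  y <- as.numeric(y)
  x <- as.numeric(x)
  n <- length(y)
  if (length(x) != n) stop_("y and x lengths differ")
  if (stats::var(x) == 0) stop_("monomorphic predictor")
  X <- cbind(`(Intercept)` = 1, covariates, x = x)
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop_("covariates are collinear with x")

  if (is.null(eig)) {
    if (is.null(K)) {
      eig <- list(values = rep(1, n), vectors = diag(n))
    } else {
      if (!isTRUE(all.equal(K, t(K), tolerance = 1e-8)))
        stop_("K must be symmetric")
      eig <- eigen(K, symmetric = TRUE)
      if (min(eig$values) < -1e-6 * max(abs(eig$values)))
        stop_("K is not positive semi-definite")
    }
  }
  d <- pmax(eig$values, 0)
  yt <- drop(crossprod(eig$vectors, y))
  Xt <- crossprod(eig$vectors, X)
  xtx_logdet <- as.numeric(determinant(crossprod(X))$modulus)

  if (is.null(lambda)) {
    opt <- stats::optimize(function(lg)
      -reml_profile(yt, Xt, d, exp(lg), xtx_logdet)$ll,
      interval = c(-12, 12), tol = 1e-8)
    lambda <- exp(opt$minimum)
    # the boundary (no polygenic variance) may beat the interior optimum
    if (reml_profile(yt, Xt, d, 0, xtx_logdet)$ll >=
        reml_profile(yt, Xt, d, lambda, xtx_logdet)$ll)
      lambda <- 0
  }
  fit <- reml_profile(yt, Xt, d, lambda, xtx_logdet)
  vb <- fit$s2e * solve(fit$XtWX)
  j <- ncol(X)
  se <- sqrt(vb[j, j])
  beta <- unname(fit$bhat[j])
  wald <- (beta / se)^2
  p <- max(stats::pchisq(wald, 1L, lower.tail = FALSE), 4.9e-324)
  out <- list(beta = beta, se = se, wald = wald, p = p,
              neg_log10_p = -log10(p), lambda = lambda,
              sigma2_e = fit$s2e, sigma2_g = lambda * fit$s2e)
  class(out) <- "lmm_assoc"
  out
}

#' @export
print.lmm_assoc <- function(x, ...) {
  cat(sprintf("LMM Wald test: beta = %.4g (SE %.4g), P = %.3g, lambda = %.3g\n",
              x$beta, x$se, x$p, x$lambda))
  invisible(x)
}

#' Genome-wide CNVR association scan
#'
#' Runs [lmm_assoc()] for every region against a per-animal phenotype
#' (typically breeding values from [ebv()]), with a single eigendecomposition
#' of the relationship matrix shared across regions, and attaches the
#' genomic inflation factor and the Bonferroni threshold.
#'
#' @param phenotype Named numeric vector (names = animal ids).
#' @param regions Output of [merge_cnvrs()] (needs the `carriers` list
#'   column).
#' @param K Relationship matrix over the phenotyped animals (see [grm()]),
#'   or `NULL` for the identity.
#' @param covariates Optional covariate matrix (rows matching `phenotype`).
#' @param alpha Genome-wide significance level for the Bonferroni
#'   threshold.
#' @return Data frame of class `cnv_scan`: one row per region with `beta`,
#'   `se`, `p`, `neg_log10_p`, plus attributes `lambda_gc`, `m`,
#'   `bonferroni` (list from [bonferroni_threshold()]). Regions whose
#'   carrier coding is monomorphic among phenotyped animals are skipped
#'   with a warning.
#' @export
cnv_scan <- function(phenotype, regions, K = NULL, covariates = NULL,
                     alpha = 0.05) {
  ids <- names(phenotype)
  if (is.null(ids)) stop_("phenotype must be named by animal id")
  eig <- if (is.null(K)) NULL else {
    K <- K[ids, ids]
    eigen(K, symmetric = TRUE)
  }
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    xr <- as.numeric(ids %in% regions$carriers[[i]])
    if (stats::var(xr) == 0) {
      warning("region ", regions$region[i],
              " is monomorphic among phenotyped animals; skipped")
      return(NULL)
    }
    fit <- lmm_assoc(phenotype, xr, K = NULL, covariates = covariates,
                     eig = eig %||% list(values = rep(1, length(ids)),
                                         vectors = diag(length(ids))))
    data.frame(region = regions$region[i], chrom = regions$chrom[i],
               start = regions$start[i], end = regions$end[i],
               beta = fit$beta, se = fit$se, p = fit$p,
               neg_log10_p = fit$neg_log10_p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  m <- nrow(out)
  attr(out, "lambda_gc") <- lambda_gc(out$p)
  attr(out, "m") <- m
  attr(out, "bonferroni") <- bonferroni_threshold(alpha, m)
  class(out) <- c("cnv_scan", "data.frame")
  out
}

#' Genomic inflation factor
#'
#' \eqn{\lambda_{GC}}: the median association chi-square statistic divided
#' by the null median of \eqn{\chi^2_1} (0.45494); values near 1 indicate
#' no stratification inflation.
#'
#' @param pvalues Numeric p-values in `(0, 1]`.
#' @return The inflation factor (scalar).
#' @export
lambda_gc <- function(pvalues) {
  if (length(pvalues) == 0L) stop_("empty p-value vector")
  if (any(pvalues <= 0 | pvalues > 1)) stop_("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(pvalues, df = 1L, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1L)
}

#' Bonferroni multiple-testing threshold
#'
#' @param alpha Family-wise error rate in `(0, 1)`.
#' @param m Number of tests (at least 1).
#' @return List with `p_threshold` (`alpha / m`) and `neg_log10` (reported
#'   to 3 decimal places).
#' @examples
#' bonferroni_threshold(0.05, 116)  # 4.31e-4, -log10 = 3.365
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_("alpha must lie in (0, 1)")
  if (m < 1) stop_("m must be at least 1")
  thr <- alpha / m
  list(p_threshold = thr, neg_log10 = round(-log10(thr), 3))
}

#' Composite linkage disequilibrium between two dosage vectors
#'
#' Squared Pearson correlation of the dosages (composite LD), e.g. between
#' a CNVR carrier code and surrounding SNPs.
#'
#' @param genotype_a,genotype_b Numeric dosage vectors over the same
#'   animals.
#' @return \eqn{r^2} (scalar).
#' @export
ld_r2 <- function(genotype_a, genotype_b) {
  if (length(genotype_a) != length(genotype_b))
    stop_("dosage vectors must cover the same animals")
  if (stats::var(genotype_a) == 0 || stats::var(genotype_b) == 0)
    stop_("monomorphic vector")
  stats::cor(genotype_a, genotype_b)^2
}

#' Plot-ready Manhattan table
#'
#' Adds cumulative genome coordinates, deterministic (chromosome, position)
#' ordering and alternating chromosome colours to association results.
#'
#' @param results Data frame with `chrom`, `start` (or `pos`) and
#'   `neg_log10_p` columns, e.g. a [cnv_scan()] result.
#' @return Data frame with columns of `results` plus `pos`, `cum_pos` and
#'   `color` (`"blue"` for odd-rank chromosomes, `"red"` for even), with
#'   attribute `ticks` (data frame of per-chromosome axis positions).
#'   Empty input gives an empty table.
#' @export
manhattan_table <- function(results) {
  res <- as.data.frame(results)
  if (nrow(res) == 0L) return(res)
  if (!"pos" %in% names(res)) res$pos <- res$start
  chroms <- unique(res$chrom[order(suppressWarnings(as.numeric(res$chrom)),
                                   res$chrom)])
  res <- res[order(match(res$chrom, chroms), res$pos), , drop = FALSE]
  span <- vapply(chroms, function(ch) max(res$pos[res$chrom == ch]),
                 numeric(1))
  offset <- stats::setNames(c(0, cumsum(span))[seq_along(chroms)], chroms)
  res$cum_pos <- res$pos + offset[res$chrom]
  rank <- match(res$chrom, chroms)
  res$color <- ifelse(rank %% 2L == 1L, "blue", "red")
  ticks <- data.frame(chrom = chroms,
                      at = vapply(chroms, function(ch)
                        mean(range(res$cum_pos[res$chrom == ch])),
                        numeric(1)))
  rownames(res) <- NULL
  attr(res, "ticks") <- ticks
  res
}

#' Manhattan plot of a CNVR scan
#'
#' @param x A [cnv_scan()] result (or any table [manhattan_table()]
#'   accepts).
#' @param threshold Genome-wide `-log10(p)` threshold line; defaults to
#'   the scan's Bonferroni threshold when available.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cnv_scan <- function(x, threshold = NULL, ...) {
  tbl <- manhattan_table(x)
  if (nrow(tbl) == 0L) return(invisible(NULL))
  threshold <- threshold %||% attr(x, "bonferroni")$neg_log10
  graphics::plot(tbl$cum_pos, tbl$neg_log10_p, col = tbl$color, pch = 19,
                 xaxt = "n", xlab = "Chromosome",
                 ylab = expression(-log[10](italic(P))),
                 ylim = c(0, max(tbl$neg_log10_p, threshold) * 1.05), ...)
  ticks <- attr(tbl, "ticks")
  graphics::axis(1, at = ticks$at, labels = ticks$chrom)
  if (!is.null(threshold))
    graphics::abline(h = threshold, lty = 2)
  invisible(tbl)
}
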