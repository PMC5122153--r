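test_that("merge_cnvrs unions overlapping same-type calls and filters", {
  calls <- data.frame(animal = c("a1", "a2"), chrom = "8",
                      start = c(100, 150), end = c(200, 250),
                      type = "loss")
  r <- merge_cnvrs(calls, cohort_size = 100)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(100, 250))
  expect_equal(r$n_carriers, 2)
  expect_equal(r$carriers[[1]], c("a1", "a2"))

  # a single animal never makes a region
  solo <- merge_cnvrs(calls[1, ], cohort_size = 100)
  expect_equal(nrow(solo), 0)

  # the same animal twice is still one carrier
  rep2 <- calls
  rep2$animal <- "a1"
  expect_equal(nrow(merge_cnvrs(rep2, cohort_size = 100)), 0)

  # frequency rule: 2 carriers in 200 = 0.01, not > 0.01 -> dropped
  expect_equal(nrow(merge_cnvrs(calls, cohort_size = 200)), 0)
  expect_equal(nrow(merge_cnvrs(calls, cohort_size = 199)), 1)

  # loss and gain never merge; adjacent (non-overlapping) calls neither
  mixed <- data.frame(animal = c("a1", "a2", "a3", "a4"), chrom = "1",
                      start = c(100, 150, 300, 201), end = c(200, 250, 400, 300),
                      type = c("loss", "loss", "loss", "gain"))
  r2 <- merge_cnvrs(mixed, cohort_size = 10, min_animals = 1, min_freq = 0)
  expect_equal(nrow(r2[r2$type == "loss", ]), 2)
  expect_equal(nrow(r2[r2$type == "gain", ]), 1)

  adj <- data.frame(animal = c("a1", "a2"), chrom = "1",
                    start = c(100, 201), end = c(200, 300), type = "loss")
  expect_equal(nrow(merge_cnvrs(adj, 10, min_animals = 1, min_freq = 0)), 2)

  expect_error(merge_cnvrs(calls, 100, chromosomes = c("1", "2")),
               "unknown chromosome")
  bad <- calls
  bad$end <- bad$start
  expect_error(merge_cnvrs(bad, 100), "start < end")
})

test_that("merge_cnvrs is idempotent and order-invariant", {
  set.seed(5)
  for (i in 1:40) {
    calls <- random_calls(sample(5:25, 1))
    r1 <- merge_cnvrs(calls, cohort_size = 50, min_freq = 0)
    r2 <- merge_cnvrs(calls[sample(nrow(calls)), ], cohort_size = 50,
                      min_freq = 0)
    expect_equal(r1, r2)
    # feeding the regions back in as calls reproduces them
    if (nrow(r1) > 0) {
      again <- do.call(rbind, lapply(seq_len(nrow(r1)), function(j)
        data.frame(animal = r1$carriers[[j]], chrom = r1$chrom[j],
                   start = r1$start[j], end = r1$end[j], type = r1$type[j])))
      r3 <- merge_cnvrs(again, cohort_size = 50, min_freq = 0)
      expect_equal(r3[, c("chrom", "start", "end", "type", "n_carriers")],
                   r1[, c("chrom", "start", "end", "type", "n_carriers")])
    }
  }
})

test_that("lmm_assoc equals the OLS Wald test under identity kinship", {
  set.seed(8)
  n <- 120
  x <- rbinom(n, 1, 0.2)
  y <- 0.3 * x + rnorm(n)
  fit <- lmm_assoc(y, x)
  ols <- summary(lm(y ~ x))$coefficients["x", ]
  expect_equal(fit$beta, unname(ols["Estimate"]), tolerance = 1e-7)
  expect_equal(fit$se, unname(ols["Std. Error"]), tolerance = 1e-7)
  ols_p <- pchisq((ols["Estimate"] / ols["Std. Error"])^2, 1,
                  lower.tail = FALSE)
  expect_equal(fit$p, unname(ols_p), tolerance = 1e-6)

  # forcing lambda = 0 reduces to OLS even with a non-trivial K
  K <- grm(sim_snp_genotypes(n, 300, seed = 3))
  f0 <- lmm_assoc(y, x, K, lambda = 0)
  expect_equal(f0$beta, unname(ols["Estimate"]), tolerance = 1e-10)
  expect_equal(f0$se, unname(ols["Std. Error"]), tolerance = 1e-10)
})

test_that("lmm_assoc handles perfect fit and degenerate input", {
  x <- rep(c(0, 1), each = 10)
  fit <- lmm_assoc(x, x)
  expect_equal(fit$beta, 1)
  expect_lt(fit$p, 1e-200)
  expect_gt(fit$p, 0)
  expect_error(lmm_assoc(rnorm(10), rep(1, 10)), "monomorphic")
  expect_error(lmm_assoc(rnorm(10), rnorm(9)), "lengths differ")
})

test_that("lmm_assoc recovers a polygenic signal's variance ratio", {
  set.seed(14)
  n <- 300
  g <- sim_snp_genotypes(n, 600, ids = paste0("a", 1:n))
  K <- grm(g)
  eK <- eigen(K, symmetric = TRUE)
  u <- eK$vectors %*% (sqrt(pmax(eK$values, 0)) * rnorm(n))
  x <- rbinom(n, 1, 0.3)
  y <- drop(0.5 * x + 2 * u + rnorm(n))   # lambda = 4
  fit <- lmm_assoc(y, x, K)
  expect_gt(fit$lambda, 1)
  expect_lt(abs(fit$beta - 0.5), 3 * fit$se)
})

test_that("carrier effects are detected above a permuted null", {
  set.seed(99)
  n <- 800
  thr <- bonferroni_threshold(0.05, 116)$p_threshold
  hits <- null_hits <- 0
  g <- sim_snp_genotypes(n, 400, ids = paste0("a", 1:n))
  K <- grm(g)
  eK <- eigen(K, symmetric = TRUE)
  for (i in 1:25) {
    x <- rbinom(n, 1, 0.05)
    y <- 0.5 * x + rnorm(n)
    hits <- hits + (lmm_assoc(y, x, eig = eK)$p < thr)
    null_hits <- null_hits + (lmm_assoc(sample(y), x, eig = eK)$p < thr)
  }
  expect_gt(hits, null_hits)
})

test_that("lambda_gc behaves at its anchor points", {
  expect_equal(lambda_gc(rep(0.5, 11)), 1.0)
  set.seed(2)
  p <- runif(1e5)
  expect_lt(abs(lambda_gc(p) - 1), 0.02)
  expect_gt(lambda_gc(p / 2), 1)
  expect_error(lambda_gc(numeric(0)), "empty")
  expect_error(lambda_gc(c(0.5, 0)), "0, 1")
})

test_that("bonferroni_threshold arithmetic", {
  b <- bonferroni_threshold(0.05, 116)
  expect_equal(b$p_threshold, 0.05 / 116)
  expect_equal(b$neg_log10, 3.365)
  expect_equal(bonferroni_threshold(0.05, 1)$p_threshold, 0.05)
  expect_equal(bonferroni_threshold(0.05, 5e5)$p_threshold, 1e-7)
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "at least 1")
})

test_that("ld_r2 is a squared Pearson correlation of dosages", {
  v <- c(0, 1, 2, 0, 1)
  expect_equal(ld_r2(v, v), 1)
  a <- c(1, -1, 1, -1)
  b <- c(1, 1, -1, -1)
  expect_equal(ld_r2(a, b), 0)
  # hand computation: cov = 0.5, var_a = 11/12, var_b = 1/3 -> r2 = 9/11
  expect_equal(ld_r2(c(0, 1, 2, 0), c(0, 1, 1, 0)), 9 / 11)
  expect_error(ld_r2(c(1, 1, 1), c(0, 1, 2)), "monomorphic")
})

test_that("manhattan_table orders, offsets and colours deterministically", {
  expect_equal(nrow(manhattan_table(data.frame())), 0)
  set.seed(4)
  res <- data.frame(chrom = as.character(sample(1:29, 116, replace = TRUE)),
                    start = sample.int(1e6, 116),
                    neg_log10_p = -log10(runif(116)))
  t1 <- manhattan_table(res)
  t2 <- manhattan_table(res[sample(116), ])
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 116)
  expect_true(!is.unsorted(t1$cum_pos))
  expect_setequal(unique(t1$color), c("blue", "red"))
})

test_that("cnv_scan ties regions, LMM, inflation and threshold together", {
  set.seed(10)
  n <- 200
  ids <- paste0("an", 1:n)
  g <- sim_snp_genotypes(n, 300, ids = ids)
  K <- grm(g)
  # 30 random loss regions incl. one with a real effect
  calls <- do.call(rbind, lapply(1:30, function(r) {
    carriers <- sample(ids, sample(5:20, 1))
    data.frame(animal = carriers, chrom = as.character(sample(1:10, 1)),
               start = 1e4 * r, end = 1e4 * r + 5000, type = "loss")
  }))
  regions <- merge_cnvrs(calls, cohort_size = n, min_freq = 0)
  y <- rnorm(n)
  hit <- regions$region[1]
  y[ids %in% regions$carriers[[1]]] <- y[ids %in% regions$carriers[[1]]] + 2
  names(y) <- ids
  scan <- cnv_scan(y, regions, K)
  expect_s3_class(scan, "cnv_scan")
  expect_equal(attr(scan, "m"), nrow(scan))
  expect_equal(attr(scan, "bonferroni")$p_threshold, 0.05 / nrow(scan))
  expect_lt(scan$p[scan$region == hit],
            attr(scan, "bonferroni")$p_threshold)
  expect_lt(attr(scan, "lambda_gc"), 2)
  # the plot method returns the plotted table invisibly
  png_file <- tempfile(fileext = ".png")
  grDevices::png(png_file)
  tbl <- plot(scan)
  grDevices::dev.off()
  expect_equal(nrow(tbl), nrow(scan))
})
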