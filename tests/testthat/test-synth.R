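test_that("sim_pedigree produces founders, links and deterministic output", {
  p0 <- sim_pedigree(10, 0, seed = 1)
  expect_equal(nrow(p0), 10)
  expect_true(all(is.na(p0$sire)) && all(is.na(p0$dam)))
  expect_equal(a_matrix(p0), diag(10), ignore_attr = "dimnames")

  p1 <- sim_pedigree(2, 1, n_per_gen = 1, seed = 1)
  A <- a_matrix(p1)
  off <- p1$animal[p1$generation == 1]
  expect_equal(unname(A[off, p1$animal[1]]), 0.5)

  expect_identical(sim_pedigree(50, 3, seed = 9), sim_pedigree(50, 3, seed = 9))
  expect_error(sim_pedigree(10, -1), "non-negative")
  expect_error(sim_pedigree(1, 0), "at least 2")
})

test_that("sim_cnv_genotypes follows HWE and the no-homozygote constraint", {
  expect_true(all(sim_cnv_genotypes(0, 500, seed = 1) == 2L))

  cn <- sim_cnv_genotypes(0.024, 1e5, forbid_homozygotes = FALSE, seed = 2)
  carrier_frac <- mean(cn == 1L)
  expected <- 2 * 0.024 * 0.976
  expect_lt(abs(carrier_frac - expected),
            3 * sqrt(expected * (1 - expected) / 1e5))

  suppressMessages(cn2 <- sim_cnv_genotypes(0.5, 2000, seed = 3))
  expect_false(any(cn2 == 0L))
  expect_gt(attr(cn2, "n_redrawn"), 0)

  expect_error(sim_cnv_genotypes(0.6, 10), "minor allele")
})

test_that("sim_records calibrates incidence to the 30-60 D target", {
  # no genetic, permanent or fixed variation: incidence is the pure
  # threshold probability
  cfg <- sim_config(variance_components = list(sigma2_a = 0, sigma2_pe = 0,
                                               sigma2_e = 1),
                    fixed_effect_sd = 0, age_slope = 0, records_per_cow = 1)
  ped <- data.frame(animal = sprintf("c%05d", 1:1e5), sire = NA, dam = NA)
  rec <- sim_records(ped, cfg, cows = ped$animal, seed = 5)
  expect_lt(abs(mean(rec$y) - 0.2197),
            3 * sqrt(0.2197 * (1 - 0.2197) / 1e5))
  expect_lt(abs(attr(rec, "truth")$mu - qnorm(0.2197)), 1e-6)
})

test_that("a null CNV effect leaves carrier incidence unchanged", {
  cfg <- sim_config(cnv_liability_effect = 0, cnv_risk_allele_freq = 0.3,
                    fixed_effect_sd = 0, records_per_cow = 2)
  ped <- data.frame(animal = sprintf("c%04d", 1:4000), sire = NA, dam = NA)
  cn <- sim_cnv_genotypes(0.3, 4000, seed = 6)
  names(cn) <- ped$animal
  rec <- sim_records(ped, cfg, cnv_copy = cn, cows = ped$animal, seed = 7)
  carrier <- cn[rec$animal] == 1L
  diff <- abs(mean(rec$y[carrier]) - mean(rec$y[!carrier]))
  expect_lt(diff, 4 * sqrt(0.25 / sum(carrier)))
})

test_that("simulated breeding values realize the requested variance", {
  cfg <- sim_config(variance_components = list(sigma2_a = 0.3,
                                               sigma2_pe = 0.05,
                                               sigma2_e = 1),
                    records_per_cow = 3)
  ped <- data.frame(animal = sprintf("c%04d", 1:2000), sire = NA, dam = NA)
  rec <- sim_records(ped, cfg, cows = ped$animal, seed = 8)
  a <- attr(rec, "truth")$a
  expect_lt(abs(var(a) - 0.3), 3 * 0.3 * sqrt(2 / length(a)))
})

test_that("period outcomes follow the sequential risk-set rule", {
  periods <- sim_config()$period_definitions
  rec <- data.frame(id = 1:4, return_day = c(25, NA, 70, 130))
  out <- prepare_period_outcomes(rec, periods)

  r1 <- out[out$id == 1, ]
  expect_equal(r1$y[r1$period == "18-29"], 1)
  expect_false("30-60" %in% r1$period)   # excluded downstream

  r2 <- out[out$id == 2, ]                # never returned: 0 everywhere
  expect_equal(nrow(r2), 5)
  expect_true(all(r2$y == 0))

  r3 <- out[out$id == 3, ]
  expect_equal(r3$y[r3$period %in% c("18-29", "30-60")], c(0, 0))
  expect_equal(r3$y[r3$period == "61-90"], 1)
  expect_false("91-140" %in% r3$period)

  expect_error(prepare_period_outcomes(data.frame(return_day = -3)),
               "negative")
})

test_that("risk-set sizes shrink monotonically across windows", {
  cfg <- sim_config(rng_seed = 21)
  days <- sim_return_days(20000, cfg, seed = 1)
  out <- prepare_period_outcomes(data.frame(return_day = days),
                                 cfg$period_definitions)
  counts <- table(out$period)
  expect_true(all(diff(as.numeric(counts)) < 0))
  # realized incidences track Table-style targets
  inc <- as.numeric(tapply(out$y, out$period, mean))
  expect_equal(inc, cfg$target_incidence, tolerance = 0.05)
})

test_that("array signals show the one-copy LRR depression only in carriers", {
  sig0 <- sim_array_signals(c(1, 1e5), c(4e4, 6e4), rep(FALSE, 30),
                            n_markers = 60, seed = 3)
  expect_lt(abs(mean(sig0$lrr)), 0.02)

  carriers <- rep(c(TRUE, FALSE), c(10, 30))
  sig <- sim_array_signals(c(1, 1e5), c(4e4, 6e4), carriers,
                           n_markers = 200, seed = 4)
  inside <- sig$markers$in_deletion
  expect_lt(abs(mean(sig$lrr[carriers, inside]) - (-0.45)), 0.05)
  expect_lt(abs(mean(sig$lrr[carriers, !inside])), 0.05)
  expect_lt(abs(mean(sig$lrr[!carriers, ])), 0.05)

  # hemizygous carriers lose the heterozygous BAF band inside the deletion
  het_band <- function(b) mean(b > 0.3 & b < 0.7)
  expect_equal(het_band(sig$baf[carriers, inside]), 0)
  expect_gt(het_band(sig$baf[!carriers, inside]), 0.1)

  expect_warning(sim_array_signals(c(1, 1000), c(500, 501), carriers,
                                   n_markers = 3, seed = 5),
                 "no markers")
})

test_that("junction fixtures are deterministic and internally consistent", {
  f1 <- sim_junction_fixture(63, 1000, 300, seed = 11)
  f2 <- sim_junction_fixture(63, 1000, 300, seed = 11)
  expect_identical(f1$reference, f2$reference)
  expect_identical(f1$junction, f2$junction)

  # the two arm copies in the reference are identical, same orientation
  with(f1$truth, {
    expect_equal(substr(f1$reference, left_arm[1], left_arm[2]),
                 substr(f1$reference, right_arm[1], right_arm[2]))
  })

  expect_error(sim_junction_fixture(63, 50, 300), "exceed")
  expect_error(sim_junction_fixture(63, 1000, flank = 5), "anchor")

  dir <- tempfile()
  f3 <- sim_junction_fixture(20, 500, 100, seed = 12, dir = dir)
  expect_true(all(file.exists(f3$files)))
  ref <- Biostrings::readDNAStringSet(f3$files["reference"])
  expect_equal(as.character(ref[[1]]), f3$reference)
  truth <- jsonlite::read_json(f3$files["truth"], simplifyVector = TRUE)
  expect_equal(truth$arm_length, 20)
})

test_that("sim_cohort wires the generators together consistently", {
  cfg <- sim_config(n_founders = 30, n_generations = 1, n_per_gen = 40,
                    records_per_cow = 2, n_snp = 50, rng_seed = 33)
  co <- sim_cohort(cfg)
  expect_true(all(co$records$animal %in% co$pedigree$animal))
  expect_false(any(co$cnv_copy == 0L))
  expect_equal(dim(co$snp), c(70, 50))
  expect_named(co$true_breeding_values, co$pedigree$animal)
  # same master seed, same cohort
  co2 <- sim_cohort(cfg)
  expect_identical(co$records$y, co2$records$y)
})

test_that("sim_config survives a JSON round trip", {
  cfg <- sim_config(n_founders = 25, cnv_liability_effect = 0.42,
                    rng_seed = 77)
  path <- tempfile(fileext = ".json")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back, cfg)
  # the restored config drives the generators identically
  expect_identical(sim_cohort(back)$records$y, sim_cohort(cfg)$records$y)
})

test_that("pedigree and records CSV round-trip", {
  ped <- sim_pedigree(8, 1, 8, seed = 3)
  pf <- tempfile(fileext = ".csv")
  write_pedigree(ped, pf)
  back <- read_pedigree(pf)
  expect_equal(back$animal, ped$animal)
  expect_equal(is.na(back$sire), is.na(ped$sire))

  cfg <- sim_config(n_founders = 6, n_generations = 0, records_per_cow = 2)
  rec <- sim_records(sim_pedigree(6, 0, seed = 1), cfg,
                     cows = sprintf("G0_%04d", 1:6), seed = 2)
  rf <- tempfile(fileext = ".csv")
  write_records(rec, rf)
  back <- read_records(rf)
  expect_equal(back$y, rec$y)
  expect_s3_class(back$farm, "factor")
})
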