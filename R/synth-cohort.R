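#' Configuration for a synthetic cattle cohort
#'
#' Collects the generator parameters for [sim_cohort()] and friends, with
#' defaults matching the stated world the package targets: repeated binary
#' return-to-estrus records on the liability scale with residual variance
#' fixed at 1, national-evaluation variance components for the 30--60 day
#' post-AI window (\eqn{\sigma^2_a = 0.01}, \eqn{\sigma^2_{pe} = 0.03}),
#' five post-AI return windows with incidences 23.00, 21.97, 16.91, 8.47
#' and 3.30 per cent, and a deleted-type CNV segregating at risk-allele
#' frequency 0.02 with no homozygous carriers.
#'
#' @param n_founders Number of unrelated founder animals.
#' @param n_generations Number of descendant generations to simulate.
#' @param n_per_gen Offspring per descendant generation (default
#'   `n_founders`).
#' @param records_per_cow Repeated AI records per cow.
#' @param variance_components Named list with `sigma2_a`, `sigma2_pe`,
#'   `sigma2_e`; `sigma2_e` must be 1 (probit identifiability).
#' @param fixed_effect_levels Named integer vector: number of levels for the
#'   `parity`, `farm` and `ym` (year-month of AI) fixed factors.
#' @param fixed_effect_sd Standard deviation (liability units) of the
#'   simulated level effects for each fixed factor.
#' @param age_slope Partial regression on age at AI, liability units per
#'   month.
#' @param period_definitions List of `c(first_day, last_day)` post-AI
#'   return windows; must be disjoint and ordered.
#' @param target_incidence Per-window return rate among cows still at risk
#'   (proportions, one per window).
#' @param focal_period Index of the window whose binary trait
#'   [sim_records()] simulates.
#' @param cnv_risk_allele_freq Deletion allele frequency.
#' @param cnv_liability_effect Liability added to CNV carriers.
#' @param lrr_shift,lrr_sd One-copy log-R-ratio shift and marker noise SD
#'   for [sim_array_signals()].
#' @param n_snp Number of SNP markers for the genomic relationship matrix.
#' @param rng_seed Master seed; every sub-generator derives its own stream
#'   from it via [split_seed()]-style offsets.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 100,
                       n_generations = 2,
                       n_per_gen = n_founders,
                       records_per_cow = 3,
                       variance_components = list(sigma2_a = 0.01,
                                                  sigma2_pe = 0.03,
                                                  sigma2_e = 1),
                       fixed_effect_levels = c(parity = 4, farm = 8, ym = 12),
                       fixed_effect_sd = 0.1,
                       age_slope = 0.002,
                       period_definitions = list(c(18, 29), c(30, 60),
                                                 c(61, 90), c(91, 140),
                                                 c(141, 285)),
                       target_incidence = c(0.2300, 0.2197, 0.1691,
                                            0.0847, 0.0330),
                       focal_period = 2,
                       cnv_risk_allele_freq = 0.02,
                       cnv_liability_effect = 0.3,
                       lrr_shift = -0.45,
                       lrr_sd = 0.2,
                       n_snp = 500,
                       rng_seed = 1L) {
  vc <- variance_components
  stopifnot(all(c("sigma2_a", "sigma2_pe", "sigma2_e") %in% names(vc)))
  if (!isTRUE(all.equal(vc$sigma2_e, 1)))
    stop_("sigma2_e is fixed at 1 on the liability scale")
  if (vc$sigma2_a < 0 || vc$sigma2_pe < 0)
    stop_("variance components must be non-negative")
  check_proportion(target_incidence, "target_incidence")
  check_proportion(cnv_risk_allele_freq, "cnv_risk_allele_freq")
  if (!all(c("parity", "farm", "ym") %in% names(fixed_effect_levels)))
    stop_("fixed_effect_levels needs named counts for parity, farm, ym")
  if (length(target_incidence) != length(period_definitions))
    stop_("one target incidence per period is required")
  pd <- do.call(rbind, period_definitions)
  if (any(pd[, 1L] > pd[, 2L]) || any(pd[, 1L] <= 0))
    stop_("period day-ranges must be positive with first_day <= last_day")
  if (length(period_definitions) > 1L &&
      any(pd[-1L, 1L] <= pd[-nrow(pd), 2L]))
    stop_("period day-ranges must be disjoint and ordered")
  cfg <- list(n_founders = n_founders, n_generations = n_generations,
              n_per_gen = n_per_gen, records_per_cow = records_per_cow,
              variance_components = vc,
              fixed_effect_levels = fixed_effect_levels,
              fixed_effect_sd = fixed_effect_sd, age_slope = age_slope,
              period_definitions = period_definitions,
              target_incidence = target_incidence,
              focal_period = focal_period,
              cnv_risk_allele_freq = cnv_risk_allele_freq,
              cnv_liability_effect = cnv_liability_effect,
              lrr_shift = lrr_shift, lrr_sd = lrr_sd, n_snp = n_snp,
              rng_seed = rng_seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a pedigree
#'
#' Founders (generation 0) have unknown parents; each later generation
#' samples a sire and a dam from the previous generation. Sexes are
#' assigned so that both are always available as parents.
#'
#' @param n_founders Number of founders (at least 2).
#' @param n_generations Number of descendant generations (0 for an
#'   unrelated cohort).
#' @param n_per_gen Offspring per generation.
#' @param seed Optional seed; the caller's RNG state is untouched.
#' @return Data frame with columns `animal`, `sire`, `dam`, `sex`
#'   (`"M"`/`"F"`) and `generation`. Unknown parents are `NA`.
#' @export
sim_pedigree <- function(n_founders, n_generations, n_per_gen = n_founders,
                         seed = NULL) {
  if (n_founders < 2) stop_("n_founders must be at least 2")
  if (n_generations < 0) stop_("n_generations must be non-negative")
  with_seed(seed, {
    id <- function(g, i) sprintf("G%d_%04d", g, i)
    ped <- data.frame(animal = id(0, seq_len(n_founders)),
                      sire = NA_character_, dam = NA_character_,
                      sex = rep_len(c("M", "F"), n_founders),
                      generation = 0L, stringsAsFactors = FALSE)
    for (g in seq_len(n_generations)) {
      prev <- ped[ped$generation == g - 1L, ]
      males <- prev$animal[prev$sex == "M"]
      females <- prev$animal[prev$sex == "F"]
      if (!length(males) || !length(females))
        stop_("previous generation lacks one sex; increase n_founders")
      gen <- data.frame(
        animal = id(g, seq_len(n_per_gen)),
        sire = sample(males, n_per_gen, replace = TRUE),
        dam = sample(females, n_per_gen, replace = TRUE),
        sex = sample(c("M", "F"), n_per_gen, replace = TRUE),
        generation = g, stringsAsFactors = FALSE)
      # guarantee both sexes so the next generation can be bred
      if (n_per_gen >= 2) gen$sex[1:2] <- c("M", "F")
      ped <- rbind(ped, gen)
    }
    ped
  })
}

#' Simulate copy numbers at a deleted-type CNV
#'
#' Draws deletion-allele counts under Hardy--Weinberg equilibrium at the
#' given risk-allele frequency and returns diploid copy numbers
#' (2 = non-carrier, 1 = heterozygous carrier, 0 = homozygous deletion).
#' With `forbid_homozygotes` (the default, matching a population in which
#' no live homozygous carriers are observed), two-copy-deleted draws are
#' redrawn as heterozygous carriers and their count is reported via the
#' `n_redrawn` attribute and a message.
#'
#' @param freq Risk (deletion) allele frequency in `[0, 0.5]`; the deletion
#'   is the minor allele by construction.
#' @param n Number of animals.
#' @param forbid_homozygotes Disallow copy number 0?
#' @param seed Optional seed.
#' @return Integer vector of copy numbers with attribute `n_redrawn`.
#' @export
sim_cnv_genotypes <- function(freq, n, forbid_homozygotes = TRUE,
                              seed = NULL) {
  if (!is.numeric(freq) || freq < 0 || freq > 0.5)
    stop_("freq must lie in [0, 0.5]: the deletion is the minor allele")
  with_seed(seed, {
    del_alleles <- stats::rbinom(n, 2L, freq)
    n_redrawn <- 0L
    if (forbid_homozygotes) {
      hom <- del_alleles == 2L
      n_redrawn <- sum(hom)
      del_alleles[hom] <- 1L
      if (n_redrawn > 0)
        message(n_redrawn,
                " homozygous-deletion draw(s) redrawn as carriers")
    }
    cn <- 2L - del_alleles
    attr(cn, "n_redrawn") <- n_redrawn
    cn
  })
}

#' Simulate SNP genotypes in Hardy--Weinberg equilibrium
#'
#' @param n Number of animals (row names taken from `ids` if given).
#' @param m Number of markers.
#' @param maf_range Range from which per-marker allele frequencies are drawn
#'   uniformly.
#' @param ids Optional animal ids for row names.
#' @param seed Optional seed.
#' @return `n` x `m` integer dosage matrix in `{0, 1, 2}`.
#' @export
sim_snp_genotypes <- function(n, m, maf_range = c(0.05, 0.5), ids = NULL,
                              seed = NULL) {
  with_seed(seed, {
    p <- stats::runif(m, maf_range[1L], maf_range[2L])
    g <- vapply(p, function(pk) stats::rbinom(n, 2L, pk), integer(n))
    g <- matrix(as.integer(g), nrow = n, ncol = m)
    rownames(g) <- ids
    colnames(g) <- sprintf("snp%04d", seq_len(m))
    g
  })
}

#' Simulate repeated binary return-to-estrus records
#'
#' Assembles, per AI record, the liability
#' \deqn{U = \mu + PARITY_i + FARM_j + YM_k + b \cdot AGE + a + pe + e}
#' with breeding values \eqn{a \sim N(0, A\sigma^2_a)} structured by the
#' pedigree, permanent environmental effects \eqn{pe \sim N(0,
#' \sigma^2_{pe})} per cow, residual \eqn{e \sim N(0, 1)}, and scores the
#' binary outcome as \eqn{Y = 1} when \eqn{U > 0}. The intercept \eqn{\mu}
#' is calibrated numerically so the marginal incidence matches the focal
#' period's target; CNV carriers (copy number 1) receive
#' `cnv_liability_effect` on top of the calibrated predictor.
#'
#' @param pedigree Pedigree data frame as from [sim_pedigree()].
#' @param config A [sim_config()] object.
#' @param cnv_copy Optional named integer vector of CNV copy numbers per
#'   animal (names matching pedigree ids).
#' @param cows Ids of the animals that receive records; defaults to females
#'   of the last generation if `sex`/`generation` columns are present,
#'   otherwise all animals.
#' @param seed Optional seed (defaults to a stream split from
#'   `config$rng_seed`).
#' @return Data frame with one row per record: `animal`, `parity`, `farm`,
#'   `ym` (factors), `age` (months), `y` (0/1). The simulation truth is
#'   attached as attribute `truth`: a list with `a` (all animals), `pe`,
#'   `mu`, the drawn fixed-level effects and the focal target incidence.
#' @export
sim_records <- function(pedigree, config, cnv_copy = NULL, cows = NULL,
                        seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  vc <- config$variance_components
  seed <- seed %||% split_seed(config$rng_seed, 3L)
  with_seed(seed, {
    ids <- as.character(pedigree$animal)
    if (is.null(cows)) {
      cows <- if (all(c("sex", "generation") %in% names(pedigree))) {
        last <- max(pedigree$generation)
        pedigree$animal[pedigree$sex == "F" & pedigree$generation == last]
      } else ids
    }
    cows <- as.character(cows)
    if (!all(cows %in% ids)) stop_("some cows are absent from the pedigree")
    if (!is.null(cnv_copy) && !all(cows %in% names(cnv_copy)))
      stop_("cnv_copy must be named and cover every cow")

    # breeding values with pedigree covariance A * sigma2_a
    n_all <- length(ids)
    a <- stats::setNames(numeric(n_all), ids)
    if (vc$sigma2_a > 0) {
      founders_only <- all(is.na(pedigree$sire) | pedigree$sire %in%
                             c("0", "")) &&
        all(is.na(pedigree$dam) | pedigree$dam %in% c("0", ""))
      if (founders_only) {            # A = I; skip the dense factorization
        a[] <- stats::rnorm(n_all, 0, sqrt(vc$sigma2_a))
      } else {
        A <- a_matrix(pedigree)[ids, ids]
        L <- chol(A + diag(1e-10, n_all))
        a[] <- sqrt(vc$sigma2_a) * drop(crossprod(L, stats::rnorm(n_all)))
      }
    }
    pe <- stats::setNames(
      stats::rnorm(length(cows), 0, sqrt(vc$sigma2_pe)), cows)

    lev <- config$fixed_effect_levels
    if (any(lev < 1)) stop_("each fixed factor needs at least one level")
    eff <- lapply(lev, function(k) {
      e <- stats::rnorm(k, 0, config$fixed_effect_sd)
      e - mean(e)
    })

    k <- config$records_per_cow
    rec <- data.frame(
      animal = rep(cows, each = k),
      parity = rep_len(seq_len(k), length(cows) * k),
      stringsAsFactors = FALSE)
    rec$parity <- pmin(rec$parity, lev[["parity"]])
    farm_of <- stats::setNames(
      sample.int(lev[["farm"]], length(cows), replace = TRUE), cows)
    rec$farm <- farm_of[rec$animal]
    rec$ym <- sample.int(lev[["ym"]], nrow(rec), replace = TRUE)
    rec$age <- 22 + 11 * (rec$parity - 1) + stats::runif(nrow(rec), 0, 6)

    eta0 <- eff$parity[rec$parity] + eff$farm[rec$farm] + eff$ym[rec$ym] +
      config$age_slope * rec$age + a[rec$animal] + pe[rec$animal]

    # calibrate mu so that mean incidence = target: P(eta0 + mu + e > 0)
    target <- config$target_incidence[config$focal_period]
    f <- function(mu) mean(stats::pnorm(eta0 + mu)) - target
    mu <- stats::uniroot(f, c(-20, 20), tol = 1e-10)$root

    eta <- eta0 + mu
    if (!is.null(cnv_copy))
      eta <- eta + config$cnv_liability_effect *
        (2L - as.integer(cnv_copy[rec$animal]))
    rec$y <- as.integer(eta + stats::rnorm(nrow(rec)) > 0)
    for (col in c("parity", "farm", "ym"))
      rec[[col]] <- factor(rec[[col]])
    attr(rec, "truth") <- list(a = a, pe = pe, mu = mu, effects = eff,
                               target_incidence = target)
    rec
  })
}

#' Simulate day of return to estrus per AI record
#'
#' Sequential risk-set model: for each record and each window in order, a
#' cow still at risk returns within that window with the window's target
#' incidence; the day is uniform within the window. Cows that never return
#' get `NA`.
#'
#' @param n Number of records.
#' @param config A [sim_config()] object (windows and incidences).
#' @param seed Optional seed.
#' @return Integer vector of return days (`NA` = no 2nd AI).
#' @export
sim_return_days <- function(n, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed %||% split_seed(config$rng_seed, 4L), {
    day <- rep(NA_integer_, n)
    at_risk <- rep(TRUE, n)
    for (k in seq_along(config$period_definitions)) {
      pd <- config$period_definitions[[k]]
      ret <- at_risk & stats::runif(n) < config$target_incidence[k]
      day[ret] <- as.integer(floor(stats::runif(sum(ret), pd[1L],
                                                pd[2L] + 1)))
      at_risk <- at_risk & !ret
    }
    day
  })
}

#' Per-window binary datasets from return days
#'
#' Converts day-of-return records into one binary dataset per post-AI
#' window under the sequential risk-set rule: a record whose 2nd AI fell in
#' an earlier window (or before the first window) is excluded from later
#' windows; a record with no 2nd AI is 0 in every window.
#'
#' @param records Data frame with a `return_day` column (`NA` = no return);
#'   other columns are carried through.
#' @param periods List of `c(first_day, last_day)` windows (default: the
#'   [sim_config()] windows).
#' @return Data frame stacking the per-window risk sets, with columns of
#'   `records` plus `period` (factor `"18-29"`, ...) and the binary
#'   outcome `y`.
#' @export
prepare_period_outcomes <- function(records,
                                    periods = sim_config()$period_definitions) {
  if (!"return_day" %in% names(records))
    stop_("records must carry a 'return_day' column")
  day <- records$return_day
  if (any(day < 0, na.rm = TRUE)) stop_("negative return day")
  out <- lapply(seq_along(periods), function(k) {
    pd <- periods[[k]]
    # at risk unless the cow returned before this window opened
    keep <- is.na(day) | day >= pd[1L]
    df <- records[keep, , drop = FALSE]
    d <- day[keep]
    df$period <- sprintf("%d-%d", pd[1L], pd[2L])
    df$y <- as.integer(!is.na(d) & d >= pd[1L] & d <= pd[2L])
    df
  })
  out <- do.call(rbind, out)
  out$period <- factor(out$period,
                       levels = vapply(periods,
                                       function(p) sprintf("%d-%d", p[1L],
                                                           p[2L]), ""))
  rownames(out) <- NULL
  out
}

#' Simulate SNP-array signals over a deleted interval
#'
#' Non-carriers have log-R-ratio (LRR) mean 0 everywhere; carriers are
#' shifted by `lrr_shift` at markers inside the deleted interval only.
#' B-allele frequencies (BAF) follow the three-cluster diploid pattern
#' outside the deletion; inside it, carriers are hemizygous and show no
#' heterozygous band.
#'
#' @param region `c(start, end)` of the simulated window (bp).
#' @param deletion `c(start, end)` of the deleted interval, inside `region`.
#' @param carriers Logical vector (or carrier ids if `ids` given): which
#'   animals carry one deleted copy.
#' @param n_markers Number of markers, placed uniformly over `region`.
#' @param lrr_shift,lrr_sd Carrier one-copy LRR shift (default -0.45) and
#'   per-marker noise SD (default 0.2).
#' @param ids Optional animal ids.
#' @param seed Optional seed.
#' @return List with `markers` (data frame: position, in_deletion),
#'   `lrr` and `baf` (animals x markers matrices).
#' @export
sim_array_signals <- function(region, deletion, carriers, n_markers = 50,
                              lrr_shift = -0.45, lrr_sd = 0.2, ids = NULL,
                              seed = NULL) {
  if (deletion[1L] < region[1L] || deletion[2L] > region[2L])
    stop_("deleted interval must lie inside the region")
  if (!is.logical(carriers)) {
    if (is.null(ids)) stop_("carrier ids require 'ids'")
    carriers <- ids %in% carriers
  }
  n <- length(carriers)
  with_seed(seed, {
    pos <- sort(as.integer(stats::runif(n_markers, region[1L], region[2L])))
    inside <- pos >= deletion[1L] & pos <= deletion[2L]
    if (!any(inside)) warning("no markers fall inside the deleted interval")
    shift <- outer(carriers, inside) * lrr_shift
    lrr <- shift + matrix(stats::rnorm(n * n_markers, 0, lrr_sd),
                          n, n_markers)
    p <- stats::runif(n_markers, 0.05, 0.95)
    b1 <- matrix(stats::rbinom(n * n_markers, 1L, rep(p, each = n)), n)
    b2 <- matrix(stats::rbinom(n * n_markers, 1L, rep(p, each = n)), n)
    dose <- (b1 + b2) / 2                      # diploid BAF in {0, .5, 1}
    hemi <- outer(carriers, inside, "&")       # single allele remains
    dose[hemi] <- b1[hemi]
    baf <- pmin(pmax(dose + matrix(stats::rnorm(n * n_markers, 0, 0.02),
                                   n), 0), 1)
    dimnames(lrr) <- dimnames(baf) <- list(ids, sprintf("m%03d",
                                                        seq_len(n_markers)))
    list(markers = data.frame(position = pos, in_deletion = inside),
         lrr = lrr, baf = baf)
  })
}

#' Simulate an NAHR junction fixture
#'
#' Builds a reference sequence containing two identical same-orientation
#' homology arms separated by the deletion interior, and the corresponding
#' deleted-allele (junction) sequence carrying a single arm copy, as left
#' behind by non-allelic homologous recombination. Coordinates are 1-based
#' inclusive; the deletion length uses the end-minus-start (difference)
#' convention, so it equals `arm_length + interior length`.
#'
#' @param arm_length Homology arm length in bp (0 for a unique breakpoint).
#' @param deletion_length Deleted length, difference convention; must
#'   exceed `arm_length`.
#' @param flank Flanking sequence length on each side; must be at least
#'   `anchor_min`.
#' @param anchor_min Minimum anchor a consumer needs on each side.
#' @param seed Optional seed.
#' @param dir Optional directory: writes `reference.fa`, `junction.fa` and
#'   `truth.json` there.
#' @return List with `reference` and `junction` (character sequences),
#'   `truth` (arm coordinates, deletion interval and length), and `files`
#'   (paths, if `dir` was given).
#' @export
sim_junction_fixture <- function(arm_length = 63, deletion_length = 2000,
                                 flank = 300, anchor_min = 20, seed = NULL,
                                 dir = NULL) {
  if (arm_length < 0) stop_("arm_length must be non-negative")
  if (deletion_length <= arm_length)
    stop_("deletion_length must exceed arm_length")
  if (flank < anchor_min)
    stop_("flank shorter than the read-anchor minimum (", anchor_min, ")")
  with_seed(seed, {
    bases <- function(k) paste(sample(c("A", "C", "G", "T"), k,
                                      replace = TRUE), collapse = "")
    interior_len <- deletion_length - arm_length
    arm <- if (arm_length > 0) bases(arm_length) else ""
    left <- bases(flank)
    interior <- bases(interior_len)
    right <- bases(flank)
    reference <- paste0(left, arm, interior, arm, right)
    junction <- paste0(left, arm, right)
    la <- if (arm_length > 0) c(flank + 1L, flank + arm_length) else
      c(NA_integer_, NA_integer_)
    ra <- if (arm_length > 0)
      c(flank + arm_length + interior_len + 1L,
        flank + 2L * arm_length + interior_len) else
      c(NA_integer_, NA_integer_)
    truth <- list(arm_length = arm_length,
                  left_arm = la, right_arm = ra,
                  deletion_length = deletion_length,
                  deleted_interval = c(flank + arm_length,
                                       flank + arm_length + deletion_length),
                  flank = flank)
    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      ref_fa <- file.path(dir, "reference.fa")
      jun_fa <- file.path(dir, "junction.fa")
      truth_js <- file.path(dir, "truth.json")
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(c(reference = reference)), ref_fa)
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(c(junction = junction)), jun_fa)
      jsonlite::write_json(truth, truth_js, auto_unbox = TRUE, digits = NA)
      files <- c(reference = ref_fa, junction = jun_fa, truth = truth_js)
    }
    list(reference = reference, junction = junction, truth = truth,
         files = files)
  })
}

#' Simulate a complete synthetic cohort
#'
#' One call wires the generators together: pedigree, CNV copy numbers
#' (no homozygous carriers), SNP genotypes, and repeated binary records
#' with the CNV liability effect applied to carriers. All randomness flows
#' from `config$rng_seed` through per-generator sub-streams.
#'
#' @param config A [sim_config()] object.
#' @return List of class `synthetic_cohort`: `pedigree`, `records`,
#'   `cnv_copy` (named copy numbers), `snp` (dosage matrix for all
#'   pedigree animals), `true_breeding_values`, `config`.
#' @export
sim_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  ped <- sim_pedigree(config$n_founders, config$n_generations,
                      config$n_per_gen,
                      seed = split_seed(config$rng_seed, 1L))
  ids <- ped$animal
  cn <- sim_cnv_genotypes(config$cnv_risk_allele_freq, length(ids),
                          forbid_homozygotes = TRUE,
                          seed = split_seed(config$rng_seed, 2L))
  cn <- stats::setNames(as.integer(cn), ids)
  rec <- sim_records(ped, config, cnv_copy = cn,
                     seed = split_seed(config$rng_seed, 3L))
  snp <- sim_snp_genotypes(length(ids), config$n_snp, ids = ids,
                           seed = split_seed(config$rng_seed, 5L))
  out <- list(pedigree = ped, records = rec, cnv_copy = cn, snp = snp,
              true_breeding_values = attr(rec, "truth")$a,
              config = config)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$pedigree), "animals,",
      nrow(x$records), "records,",
      sum(x$cnv_copy == 1L), "CNV carriers\n")
  invisible(x)
}
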