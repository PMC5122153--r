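# Independent oracles and fixture builders used across the suite.

# Recursive coancestry (path-counting) oracle for the numerator
# relationship matrix: A = 2 * kinship, kin(i,i) = 0.5 (1 + kin(s,d)).
kinship_oracle <- function(ped) {
  ids <- ped$animal
  sire <- match(ped$sire, ids)
  dam <- match(ped$dam, ids)
  ord <- match(ids, ids)  # assume parents precede offspring in input
  kin <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (i == j) {
      f <- kin(sire[i], dam[i])
      return(0.5 * (1 + f))
    }
    if (i < j) { tmp <- i; i <- j; j <- tmp }  # i is the later animal
    0.5 * (kin(sire[i], j) + kin(dam[i], j))
  }
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(i))
    A[i, j] <- A[j, i] <- 2 * kin(i, j)
  A
}

# random small pedigree with parents drawn among earlier animals (or
# unknown); topologically ordered by construction
random_small_pedigree <- function(n) {
  sire <- dam <- rep(NA_character_, n)
  ids <- paste0("x", seq_len(n))
  for (i in seq_len(n)) {
    if (i >= 3 && stats::runif(1) < 0.7) {
      pr <- sample(seq_len(i - 1L), 2)
      sire[i] <- ids[pr[1L]]
      dam[i] <- ids[pr[2L]]
    }
  }
  data.frame(animal = ids, sire = sire, dam = dam,
             stringsAsFactors = FALSE)
}

# Brute-force longest-common-flanking-substring oracle for junction arms:
# a split after read position s is valid when the prefix occurs in the
# reference at some i and the suffix at some j strictly downstream
# (j > i + s); the number of valid splits minus one is the arm length.
arm_oracle <- function(reference, read, anchor_min = 20) {
  Lr <- nchar(read)
  occurs <- function(pat) {
    h <- gregexpr(pat, reference, fixed = TRUE)[[1L]]
    if (h[1L] == -1L) integer(0) else as.integer(h)
  }
  valid <- integer(0)
  for (s in seq(anchor_min, Lr - anchor_min)) {
    pi <- occurs(substr(read, 1L, s))
    si <- occurs(substr(read, s + 1L, Lr))
    if (length(pi) && length(si) && max(si) > min(pi) + s)
      valid <- c(valid, s)
  }
  if (!length(valid)) return(NA_integer_)
  max(valid) - min(valid)
}

# Henderson mixed-model-equations solve for the Gaussian repeated-records
# animal model with fixed variances (sigma2_e = 1).
mme_oracle <- function(y, X, anim_idx, pe_idx, A, s2a, s2pe) {
  n_a <- nrow(A)
  n_pe <- max(pe_idx)
  Za <- matrix(0, length(y), n_a)
  Za[cbind(seq_along(y), anim_idx)] <- 1
  Zp <- matrix(0, length(y), n_pe)
  Zp[cbind(seq_along(y), pe_idx)] <- 1
  W <- cbind(X, Za, Zp)
  lhs <- crossprod(W)
  ia <- ncol(X) + seq_len(n_a)
  ip <- ncol(X) + n_a + seq_len(n_pe)
  lhs[ia, ia] <- lhs[ia, ia] + solve(A) / s2a
  lhs[ip, ip] <- lhs[ip, ip] + diag(n_pe) / s2pe
  sol <- solve(lhs, crossprod(W, y))
  list(b = sol[seq_len(ncol(X))], a = sol[ia], pe = sol[ip])
}

# toy gene model mirroring an exon-2-to-6 deletion that fuses exons 1 and
# 7 in frame: wild type 324 aa, deleted type 170 aa, deleted + 90-bp
# retained intron 200 aa (synthetic stand-in; real exon coordinates are
# not reproduced)
toy_gene <- function() {
  exons <- data.frame(
    start = c(1001, 1351, 1651, 1951, 2251, 2551, 2813, 3116),
    end   = c(1150, 1450, 1750, 2050, 2350, 2612, 3025, 3415))
  gene <- gene_model(exons, cds = c(1051, 3315), gene_id = "toy")
  list(gene = gene,
       deletion = c(1200, 2700),          # removes exons 2..6 entirely
       intron78 = data.frame(start = 3026, end = 3115))  # 90 bp
}

# random CNV call set on a couple of chromosomes
random_calls <- function(n_calls, n_animals = 50) {
  start <- sample.int(5000, n_calls, replace = TRUE)
  data.frame(animal = sample(paste0("an", seq_len(n_animals)), n_calls,
                             replace = TRUE),
             chrom = sample(c("1", "2"), n_calls, replace = TRUE),
             start = start,
             end = start + sample.int(400, n_calls, replace = TRUE),
             type = sample(c("loss", "gain"), n_calls, replace = TRUE),
             stringsAsFactors = FALSE)
}
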