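#' Pedigree numerator relationship matrix (tabular method)
#'
#' Computes Wright's numerator relationship matrix \eqn{A} from a pedigree by
#' the tabular method: \eqn{a_{ii} = 1 + \tfrac12 a_{s_i d_i}} and
#' \eqn{a_{ij} = \tfrac12 (a_{j s_i} + a_{j d_i})}, where unknown parents
#' contribute zero. Diagonal entries equal \eqn{1 + F_i} with \eqn{F_i} the
#' inbreeding coefficient; unknown parents are treated as unrelated,
#' non-inbred founders.
#'
#' @param pedigree A data frame with columns `animal`, `sire`, `dam`
#'   (additional columns are ignored). Unknown parents are coded `NA`, `0` or
#'   `""`. Parents that never appear in the `animal` column are added as
#'   implicit founders.
#' @return A symmetric positive-semidefinite numeric matrix with the animal
#'   ids as dimnames, ordered as in the input (implicit founders first).
#' @examples
#' ped <- data.frame(animal = c("s", "d", "o"),
#'                   sire   = c(NA, NA, "s"),
#'                   dam    = c(NA, NA, "d"))
#' a_matrix(ped)["o", "s"]  # parent-offspring: 0.5
#' @seealso [grm()] for the SNP-based genomic relationship matrix.
#' @export
a_matrix <- function(pedigree) {
  ped <- normalize_pedigree(pedigree)
  ord <- pedigree_topo_order(ped)
  ids <- ped$animal[ord]
  sire <- match(ped$sire[ord], ids)
  dam <- match(ped$dam[ord], ids)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- sire[i]
    d <- dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      rel <- numeric(i - 1L)
      if (!is.na(s)) rel <- rel + A[j, s]
      if (!is.na(d)) rel <- rel + A[j, d]
      A[j, i] <- A[i, j] <- 0.5 * rel
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A[ped$animal, ped$animal, drop = FALSE]
}

# Canonical pedigree columns: character ids, NA for unknown parents,
# implicit founders appended for parents never listed as animals.
normalize_pedigree <- function(pedigree) {
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(pedigree)))
    stop_("pedigree must have columns 'animal', 'sire', 'dam'")
  ped <- data.frame(lapply(pedigree[need], as.character),
                    stringsAsFactors = FALSE)
  for (col in c("sire", "dam"))
    ped[[col]][ped[[col]] %in% c("0", "", "NA") | is.na(ped[[col]])] <- NA
  if (anyNA(ped$animal) || any(ped$animal %in% c("0", "")))
    stop_("animal ids must be non-missing and non-zero")
  if (anyDuplicated(ped$animal))
    stop_("duplicated animal id: ", ped$animal[duplicated(ped$animal)][1L])
  extra <- setdiff(c(ped$sire, ped$dam), c(ped$animal, NA))
  if (length(extra)) {
    ped <- rbind(data.frame(animal = extra, sire = NA_character_,
                            dam = NA_character_, stringsAsFactors = FALSE),
                 ped)
  }
  ped
}

# Kahn topological order (parents before offspring); errors on a cycle,
# naming one animal involved.
pedigree_topo_order <- function(ped) {
  n <- nrow(ped)
  sire <- match(ped$sire, ped$animal)
  dam <- match(ped$dam, ped$animal)
  indeg <- (!is.na(sire)) + (!is.na(dam))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sire[i], dam[i]))
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[1L]
    queue <- queue[-1L]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    bad <- ped$animal[setdiff(seq_len(n), ord)][1L]
    stop_("pedigree contains a cycle involving animal '", bad, "'")
  }
  ord
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' Builds the genomic relationship matrix \eqn{G = Z Z' / (2 \sum_k p_k
#' (1 - p_k))} from a matrix of allele dosages, where \eqn{Z} is the
#' genotype matrix column-centred at twice the sample allele frequency.
#' Missing genotypes are mean-imputed per marker and monomorphic markers are
#' dropped (their count is reported as an attribute and a message).
#'
#' @param genotypes Numeric matrix, animals in rows, markers in columns,
#'   dosages in `{0, 1, 2}` (`NA` allowed). Row names are carried over.
#' @return Symmetric numeric matrix of genomic relationships with attribute
#'   `n_dropped`, the number of monomorphic markers removed.
#' @export
grm <- function(genotypes) {
  M <- as.matrix(genotypes)
  if (!is.numeric(M)) stop_("genotypes must be numeric dosages in {0,1,2}")
  p <- colMeans(M, na.rm = TRUE) / 2
  poly <- is.finite(p) & apply(M, 2L, function(g)
    length(unique(g[!is.na(g)])) > 1L)
  n_dropped <- sum(!poly)
  if (!any(poly)) stop_("all markers are monomorphic; G is undefined")
  if (n_dropped > 0)
    message(n_dropped, " monomorphic marker(s) dropped")
  M <- M[, poly, drop = FALSE]
  p <- p[poly]
  # mean imputation per marker
  if (anyNA(M)) {
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- 2 * p[idx[, 2L]]
  }
  Z <- sweep(M, 2L, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(rownames(genotypes), rownames(genotypes))
  attr(G, "n_dropped") <- n_dropped
  G
}

#' Read or write a relationship matrix as TSV
#'
#' The format is a tab-separated table with a header row of animal ids and
#' one row per animal (first column the id).
#'
#' @param x Relationship matrix (symmetric, with dimnames).
#' @param path File path.
#' @return `read_relmat()` returns the matrix; `write_relmat()` returns
#'   `path` invisibly.
#' @export
write_relmat <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_relmat
#' @export
read_relmat <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}
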