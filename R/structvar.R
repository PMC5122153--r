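# Sequence-level characterization of a deletion arising by non-allelic
# homologous recombination: homology arms, breakpoint ambiguity, transcript
# consequence, and qPCR copy number.

as_seq <- function(x) {
  if (inherits(x, "XString") || inherits(x, "XStringSet"))
    x <- as.character(x)
  if (length(x) != 1L || !is.character(x)) stop_("expected one sequence")
  toupper(x)
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = ""))
}

# all start positions of fixed `pattern` in `subject`
find_all <- function(pattern, subject) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) integer(0) else as.integer(hits)
}

#' Locate NAHR homology arms from a junction sequence
#'
#' Aligns a deletion-allele (junction) sequence against the reference: the
#' read's prefix anchors at the left flank, its suffix at the right flank,
#' and the overlap of the two maximal exact extensions is the homology arm
#' — the identical same-orientation segment present on both sides of the
#' ancestral locus. The breakpoint cannot be placed more precisely than
#' the arm, so it is reported as an ambiguity interval of arm length; when
#' a single coordinate pair is required the arm-adjacent bounds are used
#' (deletion start = end of the left arm copy, deletion end = end of the
#' right arm copy), and the deletion length follows the end-minus-start
#' (difference) convention. Matching is exact; coordinates are 1-based
#' inclusive.
#'
#' @param reference Reference sequence (character or `DNAString`).
#' @param junction_read Deleted-allele sequence spanning the junction.
#' @param anchor_min Minimum anchor length on each side (default 20 bp).
#' @return List of class `junction_model`: `arm_length`, `arm_seq`,
#'   `left_arm` and `right_arm` (1-based inclusive intervals, `NA` when
#'   `arm_length` is 0), `breakpoints` (arm-adjacent deletion bounds),
#'   `deletion_length` (difference convention), `ambiguity` (= arm
#'   length).
#' @export
find_homology_arms <- function(reference, junction_read, anchor_min = 20) {
  ref <- as_seq(reference)
  read <- as_seq(junction_read)
  Lr <- nchar(read)
  if (Lr < 2 * anchor_min)
    stop_("junction read shorter than two anchors")

  left_seed <- substr(read, 1L, anchor_min)
  right_seed <- substr(read, Lr - anchor_min + 1L, Lr)
  lhits <- find_all(left_seed, ref)
  rhits <- find_all(right_seed, ref)
  if (!length(lhits) || !length(rhits)) {
    rc <- revcomp(ref)
    if ((length(lhits) || length(find_all(left_seed, rc))) &&
        (length(rhits) || length(find_all(right_seed, rc))))
      stop_("not NAHR-compatible (same-directed arms required)")
    stop_("no junction found")
  }
  lp <- lhits[1L]                                  # leftmost prefix locus
  rpe <- max(rhits) + anchor_min - 1L              # rightmost suffix locus end

  rr <- strsplit(ref, "", fixed = TRUE)[[1L]]
  rd <- strsplit(read, "", fixed = TRUE)[[1L]]
  # maximal exact prefix extension at the left locus
  kmax <- min(Lr, length(rr) - lp + 1L)
  cmp <- rd[seq_len(kmax)] != rr[lp + seq_len(kmax) - 1L]
  kL <- if (any(cmp)) which(cmp)[1L] - 1L else kmax
  # maximal exact suffix extension at the right locus
  kmax <- min(Lr, rpe)
  cmp <- rev(rd)[seq_len(kmax)] != rr[rpe - seq_len(kmax) + 1L]
  kR <- if (any(cmp)) which(cmp)[1L] - 1L else kmax

  if (kL + kR < Lr) stop_("no junction found")
  arm <- kL + kR - Lr
  del_len <- rpe - Lr - lp + 1L
  if (del_len <= 0)
    stop_("no junction found")
  left_arm <- if (arm > 0) c(lp + Lr - kR, lp + kL - 1L) else
    c(NA_integer_, NA_integer_)
  right_arm <- if (arm > 0) c(rpe - kR + 1L, rpe - Lr + kL) else
    c(NA_integer_, NA_integer_)
  # arm-adjacent bounds: deletion runs from the end of the left arm copy
  # to the end of the right copy (difference convention)
  left_bp <- lp + kL - 1L
  out <- list(arm_length = arm,
              arm_seq = if (arm > 0) substr(read, Lr - kR + 1L, kL) else "",
              left_arm = left_arm, right_arm = right_arm,
              breakpoints = c(left_bp, left_bp + del_len),
              deletion_length = del_len, ambiguity = arm,
              anchor_min = anchor_min)
  class(out) <- "junction_model"
  out
}

#' @export
print.junction_model <- function(x, ...) {
  cat(sprintf(
    "NAHR junction: %d bp homology arm, %d bp deletion (%d..%d)\n",
    x$arm_length, x$deletion_length, x$breakpoints[1L], x$breakpoints[2L]))
  if (x$arm_length > 0)
    cat(sprintf("  arm copies at %d..%d and %d..%d (ambiguity %d bp)\n",
                x$left_arm[1L], x$left_arm[2L], x$right_arm[1L],
                x$right_arm[2L], x$ambiguity))
  invisible(x)
}

#' Interval length under an explicit coordinate convention
#'
#' Genomic reports mix two conventions: deletion and CNVR spans are quoted
#' as `end - start` (difference), while homology arms are inclusive base
#' counts (`end - start + 1`). Both are exposed explicitly rather than
#' guessed into one.
#'
#' @param start,end Interval bounds in bp (`end > start`).
#' @param convention `"difference"` or `"inclusive"`.
#' @return Length in bp.
#' @examples
#' deletion_length(378127, 412061, "difference")  # 33934
#' deletion_length(378065, 378127, "inclusive")   # 63
#' @export
deletion_length <- function(start, end,
                            convention = c("difference", "inclusive")) {
  convention <- match.arg(convention)
  if (any(end <= start)) stop_("end must exceed start")
  end - start + if (convention == "inclusive") 1L else 0L
}

#' Build a gene model
#'
#' @param exons Data frame with `start`, `end` (1-based inclusive, plus
#'   strand, ordered 5' to 3' along the genome), non-overlapping.
#' @param cds `c(start, end)` of the coding region (within the exon
#'   union).
#' @param gene_id Identifier.
#' @param strand Only `"+"` is supported.
#' @return List of class `gene_model` with `exons`, `introns` (derived),
#'   `cds`, `gene_id`, `strand`.
#' @export
gene_model <- function(exons, cds, gene_id = "gene", strand = "+") {
  if (strand != "+")
    stop_("only plus-strand gene models are supported; flip coordinates")
  ex <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  if (any(ex$end < ex$start)) stop_("exon end before start")
  if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)]))
    stop_("exons overlap")
  introns <- if (nrow(ex) > 1L)
    data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1L] - 1L)
  else data.frame(start = integer(), end = integer())
  if (cds[1L] > cds[2L]) stop_("cds start after end")
  out <- list(exons = ex, introns = introns, cds = cds, gene_id = gene_id,
              strand = strand)
  class(out) <- "gene_model"
  out
}

#' Read a gene model from a GFF-like TSV
#'
#' Expects columns `feature` (`exon`/`CDS`), `start`, `end`; one CDS row
#' gives the coding span.
#'
#' @param path TSV file path.
#' @param gene_id Identifier for the model.
#' @return A [gene_model()].
#' @export
read_gene_model <- function(path, gene_id = "gene") {
  df <- utils::read.delim(path)
  ex <- df[tolower(df$feature) == "exon", ]
  cds <- df[tolower(df$feature) == "cds", ]
  if (nrow(cds) != 1L) stop_("expected exactly one CDS row")
  gene_model(ex, c(cds$start, cds$end), gene_id = gene_id)
}

overlap_width <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2) + 1L)
}

#' Predict the transcript consequence of a genomic deletion
#'
#' Exons falling entirely inside the deleted interval are removed and the
#' remaining exons are spliced in genomic order; optionally, retained
#' introns (unspliced in the mutant transcript) are inserted at their
#' anatomical position. The reading frame is evaluated on the fused coding
#' sequence: in-frame when its length is a multiple of 3, frameshift
#' otherwise, and a null allele when no coding sequence survives (or, with
#' a premature stop, when the predicted protein is shorter than 10% of
#' wild type). Protein length counts `CDS/3 - 1` residues (the stop codon
#' is not a residue) and the approximate mass uses 0.111 kDa per residue.
#'
#' @param gene A [gene_model()].
#' @param deletion `c(start, end)` of the deleted interval (1-based
#'   inclusive), or `NULL` for the wild type.
#' @param retained_introns Optional data frame (`start`, `end`) of introns
#'   retained in the mutant transcript.
#' @return List of class `transcript_consequence`: `removed_exons`,
#'   `retained_exons` (indices), `transcript_length`, `cds_length`,
#'   `frame` (`"in-frame"`, `"frameshift"` or `"null"`),
#'   `protein_length_aa`, `protein_mass_kda`, `is_null`.
#' @export
predict_transcript_consequence <- function(gene, deletion = NULL,
                                           retained_introns = NULL) {
  stopifnot(inherits(gene, "gene_model"))
  ex <- gene$exons
  nex <- nrow(ex)
  removed <- if (is.null(deletion)) rep(FALSE, nex) else
    ex$start >= deletion[1L] & ex$end <= deletion[2L]
  keep <- which(!removed)
  blocks <- data.frame(start = ex$start[keep], end = ex$end[keep],
                       kind = rep("exon", length(keep)),
                       stringsAsFactors = FALSE)
  if (!is.null(retained_introns) && nrow(retained_introns) > 0L)
    blocks <- rbind(blocks,
                    data.frame(start = retained_introns$start,
                               end = retained_introns$end, kind = "intron",
                               stringsAsFactors = FALSE))
  blocks <- blocks[order(blocks$start), , drop = FALSE]

  transcript_length <- sum(blocks$end - blocks$start + 1L)
  cds_length <- if (nrow(blocks)) sum(mapply(
    overlap_width, blocks$start, blocks$end,
    MoreArgs = list(s2 = gene$cds[1L], e2 = gene$cds[2L]))) else 0L
  start_present <- any(blocks$kind == "exon" &
                         blocks$start <= gene$cds[1L] &
                         blocks$end >= gene$cds[1L])
  wt_cds <- sum(mapply(overlap_width, ex$start, ex$end,
                       MoreArgs = list(s2 = gene$cds[1L],
                                       e2 = gene$cds[2L])))
  wt_aa <- wt_cds / 3 - 1

  if (!start_present || cds_length < 3L) {
    frame <- "null"
    aa <- 0
  } else if (cds_length %% 3L == 0L) {
    frame <- "in-frame"
    aa <- cds_length / 3 - 1
  } else {
    frame <- "frameshift"
    # without sequence, the premature stop is unknowable; report the frame
    aa <- NA_real_
  }
  is_null <- frame == "null" ||
    (!is.na(aa) && wt_aa > 0 && aa < 0.1 * wt_aa)
  out <- list(removed_exons = which(removed), retained_exons = keep,
              retained_introns = retained_introns,
              transcript_length = transcript_length,
              cds_length = cds_length, frame = frame,
              protein_length_aa = aa,
              protein_mass_kda = if (is.na(aa)) NA_real_ else
                round(0.111 * aa, 1),
              wild_type_aa = wt_aa, is_null = is_null)
  class(out) <- "transcript_consequence"
  out
}

#' @export
print.transcript_consequence <- function(x, ...) {
  cat(sprintf("Transcript consequence: %s", x$frame))
  if (length(x$removed_exons))
    cat(sprintf("; exons removed: %s",
                paste(x$removed_exons, collapse = ",")))
  cat("\n")
  if (!is.na(x$protein_length_aa))
    cat(sprintf("  predicted protein: %d aa (~%.1f kDa)\n",
                as.integer(x$protein_length_aa), x$protein_mass_kda))
  if (x$is_null) cat("  null allele\n")
  invisible(x)
}

#' Copy number by the comparative Ct method
#'
#' Relative qPCR quantification against a two-copy calibrator:
#' \eqn{\Delta C_T} = target \eqn{C_T} minus reference \eqn{C_T} per
#' replicate, \eqn{\Delta\Delta C_T} = mean \eqn{\Delta C_T}(sample) -
#' mean \eqn{\Delta C_T}(calibrator), and copy number
#' \eqn{CN = 2 \times 2^{-\Delta\Delta C_T}}. The SEM is propagated from
#' the replicate spread by the delta method
#' (\eqn{SEM_{CN} = CN \ln 2 \cdot SEM_{\Delta\Delta C_T}}). Adding a
#' constant to all \eqn{C_T} values of a sample and its reference leaves
#' the estimate unchanged.
#'
#' @param sample,calibrator Data frames with numeric columns `target_ct`
#'   and `ref_ct`, one row per replicate (the calibrator is assumed to
#'   carry two copies).
#' @return List with `copy_number`, `sem`, `ddct`.
#' @export
ddct_copy_number <- function(sample, calibrator) {
  dct <- function(x, who) {
    if (!all(c("target_ct", "ref_ct") %in% names(x)))
      stop_(who, " needs 'target_ct' and 'ref_ct' columns")
    if (anyNA(x$ref_ct)) stop_("missing reference Ct in ", who)
    if (nrow(x) < 1L) stop_(who, " needs at least one replicate")
    if (any(x$target_ct <= 0) || any(x$ref_ct <= 0))
      stop_("Ct values must be positive")
    x$target_ct - x$ref_ct
  }
  ds <- dct(sample, "sample")
  dc <- dct(calibrator, "calibrator")
  sem2 <- function(v) if (length(v) > 1L) stats::var(v) / length(v) else 0
  ddct <- mean(ds) - mean(dc)
  cn <- 2 * 2^(-ddct)
  sem_ddct <- sqrt(sem2(ds) + sem2(dc))
  list(copy_number = cn, sem = cn * log(2) * sem_ddct, ddct = ddct)
}
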