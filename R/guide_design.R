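# Guide (protospacer) selection for SpCas9.
#
# A candidate is a 20-nt protospacer immediately 5' of an NGG PAM. Candidates
# are scored against the 9-nt target-context motif 5'-HNNGRSGGH-3' (last five
# spacer bases, the PAM, and the base 3' of the PAM, read on the protospacer
# strand; SGG is the only NGG-compatible 3-mer inside the motif, which fixes
# that anchoring), filtered by the predicted folding free energy of the
# targeting sequence, and checked for contiguity against genomic sequence so
# that guides picked from cDNA do not span exon-exon junctions.

.MOTIF <- "HNNGRSGGH"

#' Count mismatches against the target-context motif
#'
#' Scores a 9-nt context window (spacer positions 16-20, the 3-nt PAM, and
#' one base 3' of the PAM, all on the protospacer strand) against
#' `HNNGRSGGH`: H = not G, N = any, R = purine, S = G/C. Positions matching
#' N can never mismatch, so counts lie in \[0, 9\] with at most 7 informative
#' positions.
#'
#' @param context character vector of 9-nt windows.
#' @return integer vector of mismatch counts; 0 = perfect conformity.
#' @export
#' @examples
#' motif_mismatch_count("ACTGAGGGA")  # 0
#' motif_mismatch_count("GCTGAGGGA")  # 1 (G violates the leading H)
motif_mismatch_count <- function(context) {
  context <- check_dna(context, allow_n = FALSE, what = "motif context")
  if (any(nchar(context) != 9L)) stop("motif context must be exactly 9 nt", call. = FALSE)
  classes <- strsplit(.MOTIF, "")[[1]]
  mm <- integer(length(context))
  for (i in seq_len(9L)) {
    base_i <- substring(context, i, i)
    ok <- base_i %in% .IUPAC_SETS[[classes[i]]]
    mm <- mm + !ok
  }
  mm
}

#' Predicted cleavage site of a guide
#'
#' SpCas9 cuts bluntly 3 bp upstream of the PAM (between protospacer
#' positions 17 and 18). Coordinates here are 0-based: `pam_start` is the
#' reference coordinate of the PAM's first base read 5'->3' on the
#' protospacer strand, and the returned value is a 0-based insertion point
#' (the cut falls immediately before that reference position).
#'
#' @param pam_start integer vector, 0-based coordinate of the PAM first base
#'   on the protospacer strand (for a minus-strand guide this is the
#'   rightmost reference position of the PAM triplet).
#' @param strand `"+"` or `"-"`, recycled.
#' @return integer vector of 0-based insertion points.
#' @export
#' @examples
#' cleavage_site(120, "+")  # 117
#' cleavage_site(102, "-")  # 106: PAM occupies [100,103), protospacer [103,123)
cleavage_site <- function(pam_start, strand) {
  stopifnot(all(strand %in% c("+", "-")))
  strand <- rep_len(strand, length(pam_start))
  cut <- ifelse(strand == "+", pam_start - 3L, pam_start + 4L)
  if (any(cut < 0L)) {
    stop("cleavage coordinate underflow: PAM too close to the sequence start",
         call. = FALSE)
  }
  as.integer(cut)
}

# Scan one strand of `seq` (already oriented 5'->3') for 20-mer + NGG + 1
# context base. Returns 0-based pam starts in that orientation.
.scan_one_strand <- function(seq) {
  n <- nchar(seq)
  if (n < 24L) return(integer(0))
  # PAM start p (0-based) needs spacer [p-20, p) and context base at p+3.
  p <- 20:(n - 4L)
  gg <- substring(seq, p + 2L, p + 3L) == "GG"   # 1-based positions p+2..p+3
  p[gg]
}

#' Scan a locus for SpCas9 protospacer candidates
#'
#' Finds every 20-nt protospacer followed by an NGG PAM on both strands,
#' drops candidates whose 9-nt motif context window would run off the locus,
#' and reports motif mismatch counts, predicted hairpin folding free energy
#' of the targeting sequence, and the predicted cleavage position.
#'
#' @param locus a single sequence (character), or a named character vector of
#'   length 1 as returned by [read_fasta()].
#' @param contig contig label used in the output (defaults to the name of
#'   `locus`, or `"locus"`).
#' @param compute_dg compute `delta_g` per candidate via [predict_fold_dg()]
#'   (default `TRUE`).
#' @return a `data.frame` of class `guide_candidates` with one row per
#'   candidate: `guide_id`, `contig`, `strand`, `spacer`, `pam`,
#'   `pam_start` (1-based first PAM base on the protospacer strand),
#'   `cleavage_pos` (cut falls after this 1-based reference base),
#'   `spacer_start` (1-based leftmost reference coordinate of the
#'   protospacer), `context`, `motif_mismatches`, `delta_g`,
#'   `passes_filter` (`NA` until [filter_guides()] is applied).
#' @export
scan_protospacers <- function(locus, contig = NULL, compute_dg = TRUE) {
  if (is.list(locus)) locus <- locus$seq
  if (is.null(contig)) contig <- if (!is.null(names(locus))) names(locus)[1] else "locus"
  locus <- check_dna(locus[[1]], allow_n = TRUE, what = "locus")
  n <- nchar(locus)
  if (n < 24L) {
    message("locus shorter than 24 nt: no protospacer can be scanned")
    return(.empty_candidates())
  }
  rows <- list()
  for (str in c("+", "-")) {
    s <- if (str == "+") locus else reverse_complement(locus)
    pams <- .scan_one_strand(s)
    if (!length(pams)) next
    spacer <- substring(s, pams - 19L, pams)          # 1-based [p-20, p)
    pam <- substring(s, pams + 1L, pams + 3L)
    context <- substring(s, pams - 4L, pams + 4L)     # spacer 16-20 + PAM + 1
    keep <- !grepl("N", paste0(spacer, pam, context), fixed = TRUE)
    if (!any(keep)) next
    pams <- pams[keep]; spacer <- spacer[keep]; pam <- pam[keep]
    context <- context[keep]
    if (str == "+") {
      pam_start0 <- pams
      spacer_start0 <- pams - 20L
    } else {
      # position q (0-based) on the rc maps to n - 1 - q on the reference
      pam_start0 <- n - 1L - pams
      spacer_start0 <- n - pams                       # leftmost ref coord
    }
    cut0 <- cleavage_site(pam_start0, str)
    rows[[str]] <- data.frame(
      contig = contig, strand = str, spacer = spacer, pam = pam,
      pam_start = pam_start0 + 1L, cleavage_pos = cut0,
      spacer_start = spacer_start0 + 1L, context = context,
      motif_mismatches = motif_mismatch_count(context),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(.empty_candidates())
  out <- do.call(rbind, rows)
  out <- out[order(out$spacer_start, out$strand), , drop = FALSE]
  out$delta_g <- if (compute_dg) predict_fold_dg(out$spacer) else NA_real_
  out$passes_filter <- NA
  out$guide_id <- sprintf("%s_g%03d", out$contig, seq_len(nrow(out)))
  rownames(out) <- NULL
  out <- out[, c("guide_id", "contig", "strand", "spacer", "pam", "pam_start",
                 "cleavage_pos", "spacer_start", "context", "motif_mismatches",
                 "delta_g", "passes_filter")]
  class(out) <- c("guide_candidates", "data.frame")
  out
}

.empty_candidates <- function() {
  out <- data.frame(guide_id = character(), contig = character(),
                    strand = character(), spacer = character(),
                    pam = character(), pam_start = integer(),
                    cleavage_pos = integer(), spacer_start = integer(),
                    context = character(), motif_mismatches = integer(),
                    delta_g = numeric(), passes_filter = logical(),
                    stringsAsFactors = FALSE)
  class(out) <- c("guide_candidates", "data.frame")
  out
}

#' Predicted hairpin folding free energy of a targeting sequence
#'
#' Minimum free energy over simple hairpin structures (one helix of stacked
#' canonical pairs, terminal loop >= 3 nt, T read as U) under the bundled
#' nearest-neighbor table ([fold_params()]); 0.0 when no structure is
#' stabilizing. Guides are kept when the value is greater than
#' -1.5 kcal/mol, i.e. when the targeting sequence has no strongly stable
#' self-structure to impede DNA hybridization.
#'
#' @param spacer character vector of targeting sequences (DNA alphabet).
#' @param backend optional function `(spacer) -> kcal/mol` replacing the
#'   bundled estimator (e.g. a ViennaRNA wrapper); its value is used
#'   verbatim.
#' @return numeric vector of folding free energies (kcal/mol, always <= 0
#'   for the bundled estimator).
#' @export
#' @examples
#' predict_fold_dg(strrep("A", 20))            # 0: nothing pairs
#' predict_fold_dg("GGGGGGGGAAAACCCCCCCC")     # strongly negative
predict_fold_dg <- function(spacer, backend = NULL) {
  spacer <- check_dna(spacer, allow_n = FALSE, what = "targeting sequence")
  if (!is.null(backend)) return(vapply(spacer, backend, numeric(1), USE.NAMES = FALSE))
  vapply(spacer, .hairpin_mfe_dp, numeric(1), USE.NAMES = FALSE)
}

# Dynamic program over closing pairs: M[i, j] = best energy of a hairpin
# whose outermost pair is (i, j); either close the terminal loop here or
# stack (i+1, j-1) on top. MFE = min(0, min M).
.hairpin_mfe_dp <- function(seq) {
  b <- chartr("T", "U", seq)
  b <- strsplit(b, "")[[1]]
  n <- length(b)
  if (n < 5L) return(0)
  loops <- .FOLD_LOOPS
  M <- matrix(NA_real_, n, n)
  for (span in 4:(n - 1)) {          # j - i; loop >= 3 needs span >= 4
    for (i in seq_len(n - span)) {
      j <- i + span
      p <- .pair_label(b[i], b[j])
      if (is.na(p)) next
      loop_len <- j - i - 1L
      best <- if (loop_len >= 3L) loops[loop_len] else Inf
      if (j - 1L > i + 1L && !is.na(M[i + 1L, j - 1L])) {
        inner <- .pair_label(b[i + 1L], b[j - 1L])
        stacked <- .FOLD_STACKS[p, inner] + M[i + 1L, j - 1L]
        if (stacked < best) best <- stacked
      }
      if (is.finite(best)) M[i, j] <- best
    }
  }
  mfe <- suppressWarnings(min(M, na.rm = TRUE))
  min(0, mfe)
}

#' Verify that a guide matches contiguous genomic sequence
#'
#' Guides picked from cDNA can accidentally span an exon-exon junction, in
#' which case the genomic target does not exist as a contiguous 23-mer. This
#' check is `TRUE` iff the spacer+PAM 23-mer (or its reverse complement)
#' occurs contiguously in `genome`; when an exon annotation is supplied, the
#' match must additionally lie entirely within a single exon.
#'
#' @param spacer_pam the 23-nt spacer+PAM sequence.
#' @param genome genomic sequence (single character string, or named vector
#'   from [read_fasta()]; the first/only record is searched, or the record
#'   named by the annotation's contig when present).
#' @param annotation optional exon annotation: a `GRanges` (see
#'   [read_exons()]) or a data.frame with columns `contig`, `start`, `end`
#'   (1-based inclusive).
#' @return logical.
#' @export
verify_genomic_contiguity <- function(spacer_pam, genome, annotation = NULL) {
  spacer_pam <- check_dna(spacer_pam, allow_n = FALSE, what = "spacer+PAM")
  stopifnot(length(spacer_pam) == 1L)
  an <- .exons_to_df(annotation)
  genome_name <- if (!is.null(names(genome))) names(genome)[1] else NA_character_
  g <- check_dna(genome[[1]], allow_n = TRUE, what = "genome")
  hits <- list()
  for (q in c(spacer_pam, reverse_complement(spacer_pam))) {
    m <- gregexpr(q, g, fixed = TRUE)[[1]]
    if (m[1] != -1L) {
      hits[[length(hits) + 1L]] <- data.frame(start = as.integer(m),
                                              end = as.integer(m) + nchar(q) - 1L)
    }
  }
  if (!length(hits)) return(FALSE)
  hits <- do.call(rbind, hits)
  if (is.null(an)) return(TRUE)
  if (!is.na(genome_name) && genome_name %in% an$contig) {
    an <- an[an$contig == genome_name, , drop = FALSE]
  }
  any(vapply(seq_len(nrow(hits)), function(i) {
    any(an$start <= hits$start[i] & hits$end[i] <= an$end)
  }, logical(1)))
}

#' Filter and rank guide candidates
#'
#' Keeps candidates whose predicted folding free energy exceeds
#' `dg_threshold` (default -1.5 kcal/mol) and whose motif mismatch count is
#' at most `max_motif_mismatches` (default 0, i.e. perfect conformity to
#' `HNNGRSGGH`), then ranks by (mismatches ascending, `delta_g` descending,
#' reference coordinate ascending). The ranking is total and deterministic.
#'
#' @param candidates a `guide_candidates` data frame from
#'   [scan_protospacers()] with `delta_g` computed.
#' @param dg_threshold folding free energy cutoff, kcal/mol (exclusive).
#' @param max_motif_mismatches maximum tolerated motif mismatches.
#' @return the retained rows, ranked, with `passes_filter = TRUE`.
#' @export
filter_guides <- function(candidates, dg_threshold = -1.5, max_motif_mismatches = 0L) {
  stopifnot(is.data.frame(candidates))
  if (any(is.na(candidates$delta_g)) && nrow(candidates)) {
    stop("delta_g must be computed for all candidates before filtering", call. = FALSE)
  }
  keep <- candidates$delta_g > dg_threshold &
    candidates$motif_mismatches <= max_motif_mismatches
  out <- candidates[keep, , drop = FALSE]
  ord <- order(out$motif_mismatches, -out$delta_g, out$spacer_start, out$strand)
  out <- out[ord, , drop = FALSE]
  out$passes_filter <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  class(out) <- c("guide_candidates", "data.frame")
  out
}

#' Write guide candidates to TSV
#'
#' Columns: `guide_id`, `contig`, `strand`, `spacer`, `pam`, `pam_start`
#' (1-based), `cleavage_pos` (1-based: the cut falls immediately after this
#' base), `motif_mismatches`, `delta_g_kcal_mol`, `passes_filter`.
#'
#' @param candidates `guide_candidates` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_guides_tsv <- function(candidates, path) {
  out <- data.frame(
    guide_id = candidates$guide_id, contig = candidates$contig,
    strand = candidates$strand, spacer = candidates$spacer,
    pam = candidates$pam, pam_start = candidates$pam_start,
    cleavage_pos = candidates$cleavage_pos,
    motif_mismatches = candidates$motif_mismatches,
    delta_g_kcal_mol = candidates$delta_g,
    passes_filter = candidates$passes_filter, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
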