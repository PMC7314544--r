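# UMI-deduplicated amplicon deep-sequencing quantification of editing
# outcomes: merge read pairs, quality-filter, locate locus flanks, extract
# and deduplicate the randomized barcode, classify unique amplicons, and
# summarize frequencies with the UMI-space limit of detection.

.OUTCOME_LEVELS <- c("EXACT_REF", "TEMPLATED_PTS", "INDEL", "SNP",
                     "AMBIGUOUS_1BP", "UNALIGNED")

#' Merge one read pair by best ungapped overlap
#'
#' R2 is reverse-complemented internally (it is given in sequencing
#' orientation). The best ungapped overlap of at least `min_overlap` bases
#' with mismatch fraction at most `max_mismatch_frac` is taken (lowest
#' mismatch fraction; ties prefer the longer overlap). Overlap disagreements
#' resolve toward the higher-quality base and merged qualities are the
#' per-base maximum. Returns `NULL` when no acceptable overlap exists
#' (a reported outcome, not an error).
#'
#' @param r1_seq,r1_qual,r2_seq,r2_qual sequences and Phred+33 quality
#'   strings of the two reads.
#' @param min_overlap minimum acceptable overlap (default 20).
#' @param max_mismatch_frac maximum mismatch fraction in the overlap
#'   (default 0.1).
#' @return list with `seq`, `qual`, `overlap`, `mismatches`, or `NULL`.
#' @export
merge_pair <- function(r1_seq, r1_qual, r2_seq, r2_qual,
                       min_overlap = 20L, max_mismatch_frac = 0.1) {
  res <- cpp_merge_pairs(r1_seq, r1_qual, r2_seq, r2_qual,
                         as.integer(min_overlap), max_mismatch_frac)
  if (!res$merged[1]) return(NULL)
  list(seq = res$seq[1], qual = res$qual[1],
       overlap = res$overlap[1], mismatches = res$mismatches[1])
}

#' Merge many read pairs
#'
#' Vectorized form of [merge_pair()] over aligned read data frames (columns
#' `name`, `seq`, `qual`).
#'
#' @param r1,r2 read data frames (see [read_fastq_pairs()]).
#' @inheritParams merge_pair
#' @return data frame: `name`, `merged` (logical), `seq`, `qual`,
#'   `overlap`, `mismatches`.
#' @export
merge_pairs <- function(r1, r2, min_overlap = 20L, max_mismatch_frac = 0.1) {
  stopifnot(nrow(r1) == nrow(r2))
  res <- cpp_merge_pairs(r1$seq, r1$qual, r2$seq, r2$qual,
                         as.integer(min_overlap), max_mismatch_frac)
  data.frame(name = r1$name, merged = res$merged, seq = res$seq,
             qual = res$qual, overlap = res$overlap,
             mismatches = res$mismatches, stringsAsFactors = FALSE)
}

#' Quality filter
#'
#' `TRUE` iff at least `min_fraction` of bases have Phred at or above
#' `min_q`. The defaults implement the strict rule "100% of bases with
#' quality scores of at least 30".
#'
#' @param qual character vector of Phred+33 quality strings.
#' @param min_q Phred threshold (default 30).
#' @param min_fraction required fraction of bases at or above `min_q`
#'   (default 1.0 = every base).
#' @return logical vector.
#' @export
quality_filter <- function(qual, min_q = 30L, min_fraction = 1.0) {
  cpp_qual_fraction_ge(qual, as.integer(min_q)) >= min_fraction - 1e-12
}

#' Locate and trim expected locus flanks
#'
#' Both flanks must be found in the amplicon by semi-global alignment
#' (flank aligned end-to-end, free endpoints in the amplicon) with
#' edit-distance errors per flank at most `max_error_rate * nchar(flank)` —
#' cutadapt semantics with substitutions and indels both counted. Reads
#' missing either flank are rejected (reported, not an error). The trimmed
#' sequence runs from the start of the 5' flank match to the end of the 3'
#' flank match, so with flanks taken from the reference ends it is directly
#' comparable to the reference amplicon.
#'
#' @param seqs character vector of merged amplicon sequences.
#' @param flank5,flank3 expected flank sequences (>= `min_overlap` nt).
#' @param min_overlap minimum flank length used (default 50).
#' @param max_error_rate maximum errors per flank, as a fraction of flank
#'   length (default 0.1).
#' @return data frame: `accepted`, `trimmed`, `start5`, `end5`, `start3`,
#'   `end3` (1-based match coordinates), `edits5`, `edits3`.
#' @export
match_and_trim_flanks <- function(seqs, flank5, flank3, min_overlap = 50L,
                                  max_error_rate = 0.1) {
  flank5 <- check_dna(flank5, allow_n = FALSE, what = "flank5")
  flank3 <- check_dna(flank3, allow_n = FALSE, what = "flank3")
  if (nchar(flank5) < min_overlap || nchar(flank3) < min_overlap) {
    stop(sprintf("flanks must be at least %d nt", min_overlap), call. = FALSE)
  }
  n <- length(seqs)
  max5 <- floor(max_error_rate * nchar(flank5) + 1e-9)
  max3 <- floor(max_error_rate * nchar(flank3) + 1e-9)
  out <- data.frame(accepted = logical(n), trimmed = NA_character_,
                    start5 = NA_integer_, end5 = NA_integer_,
                    start3 = NA_integer_, end3 = NA_integer_,
                    edits5 = NA_integer_, edits3 = NA_integer_,
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  # Fast path: exact flank occurrences (the large majority of real reads).
  loc5 <- regexpr(flank5, seqs, fixed = TRUE)
  loc3 <- .last_fixed_match(flank3, seqs)
  need_dp5 <- loc5 == -1L
  need_dp3 <- loc3 == -1L
  s5 <- ifelse(need_dp5, NA_integer_, as.integer(loc5))
  e5 <- s5 + nchar(flank5) - 1L
  ed5 <- ifelse(need_dp5, NA_integer_, 0L)
  s3 <- ifelse(need_dp3, NA_integer_, as.integer(loc3))
  e3 <- s3 + nchar(flank3) - 1L
  ed3 <- ifelse(need_dp3, NA_integer_, 0L)
  if (any(need_dp5)) {
    m <- cpp_semiglobal_locate(flank5, seqs[need_dp5])
    s5[need_dp5] <- m[, "start"]; e5[need_dp5] <- m[, "end"]
    ed5[need_dp5] <- m[, "edits"]
  }
  if (any(need_dp3)) {
    m <- cpp_semiglobal_locate(flank3, seqs[need_dp3])
    s3[need_dp3] <- m[, "start"]; e3[need_dp3] <- m[, "end"]
    ed3[need_dp3] <- m[, "edits"]
  }
  ok <- ed5 <= max5 & ed3 <= max3 & s5 <= e3 & e5 < s3
  ok[is.na(ok)] <- FALSE
  out$accepted <- ok
  out$start5 <- s5; out$end5 <- e5; out$start3 <- s3; out$end3 <- e3
  out$edits5 <- as.integer(ed5); out$edits3 <- as.integer(ed3)
  out$trimmed[ok] <- substring(seqs[ok], s5[ok], e3[ok])
  out
}

# Rightmost exact occurrence of `pattern` in each of `texts` (-1 if none).
.last_fixed_match <- function(pattern, texts) {
  vapply(gregexpr(pattern, texts, fixed = TRUE), function(m) {
    if (m[1] == -1L) -1L else as.integer(m[length(m)])
  }, integer(1))
}

#' Extract the randomized molecular barcode (UMI)
#'
#' The UMI is carried on the forward primer, so it reads out as the first
#' `k` bases of the merged amplicon (after any fixed `offset`). A 6-base
#' UMI distinguishes 4^6 = 4096 molecules.
#'
#' @param seqs merged amplicon sequences.
#' @param quals matching quality strings (optional).
#' @param k UMI length (default 6).
#' @param offset fixed bases before the UMI (default 0).
#' @return data frame: `ok` (long enough), `umi`, `seq` (remainder after
#'   UMI removal), `qual` (remainder qualities, or `NA`).
#' @export
extract_umi <- function(seqs, quals = NULL, k = 6L, offset = 0L) {
  long_enough <- nchar(seqs) > k + offset
  umi <- ifelse(long_enough, substring(seqs, offset + 1L, offset + k), NA_character_)
  rest <- ifelse(long_enough, substring(seqs, offset + k + 1L), NA_character_)
  qual_rest <- if (is.null(quals)) NA_character_ else
    ifelse(long_enough, substring(quals, offset + k + 1L), NA_character_)
  data.frame(ok = long_enough, umi = umi, seq = rest, qual = qual_rest,
             stringsAsFactors = FALSE)
}

#' Number of distinct UMIs of length k
#' @param umi_len barcode length in bases.
#' @return 4^umi_len.
#' @export
umi_space <- function(umi_len = 6L) {
  if (any(umi_len < 1L)) stop("umi_len must be >= 1", call. = FALSE)
  4^umi_len
}

#' Deduplicate amplicons by (UMI, sequence)
#'
#' PCR duplicates share both the randomized barcode and the amplicon
#' sequence; records with an identical (UMI, sequence) pair collapse into
#' one unique bin with a duplicate count. Downstream frequencies use unique
#' bins only. Two genuinely distinct molecules that drew the same UMI *and*
#' have the same sequence are indistinguishable — this is the limit of
#' detection of the barcoding scheme, not an artifact of the collapse.
#'
#' @param umi,seq aligned vectors of UMIs and amplicon sequences.
#' @return data frame: `umi`, `seq`, `duplicate_count`, sorted by decreasing
#'   count then key; one row per unique bin.
#' @export
deduplicate <- function(umi, seq) {
  stopifnot(length(umi) == length(seq))
  if (!length(umi)) {
    return(data.frame(umi = character(), seq = character(),
                      duplicate_count = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(umi, seq, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(umi = vapply(parts, `[`, character(1), 1L),
                    seq = vapply(parts, `[`, character(1), 2L),
                    duplicate_count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(-out$duplicate_count, out$umi, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify an amplicon against the reference
#'
#' Precedence follows the published counting rules, with templated repair
#' taking priority over the indel rule (a PTS-bearing read with extra errors
#' is still templated):
#' 1. `TEMPLATED_PTS` — the PTS aligns somewhere in the read with at most
#'    `pts_max_mismatch` edits (0 = exact substring);
#' 2. `INDEL` — length differs from the reference by more than 1 bp;
#' 3. `EXACT_REF` — identical to the reference;
#' 4. `SNP` — same length, at least one mismatch;
#' 5. `AMBIGUOUS_1BP` — length differs by exactly 1 bp (left unassigned by
#'    the >1 bp indel rule; excluded from both mutation frequencies).
#'
#' @param seqs character vector of amplicon sequences (flank-trimmed).
#' @param reference reference amplicon sequence.
#' @param pts PTS cassette sequence (default canonical).
#' @param pts_max_mismatch maximum edits tolerated in the PTS match
#'   (default 2, mirroring manual reclassification of PTS-with-mutation
#'   reads; 0 recovers the strict substring rule).
#' @return factor with levels `EXACT_REF`, `TEMPLATED_PTS`, `INDEL`, `SNP`,
#'   `AMBIGUOUS_1BP`, `UNALIGNED`.
#' @export
classify_amplicon <- function(seqs, reference, pts = pts_sequence(),
                              pts_max_mismatch = 2L) {
  reference <- check_dna(reference, allow_n = FALSE, what = "reference")
  pts <- check_dna(pts, allow_n = FALSE, what = "PTS")
  n <- length(seqs)
  cls <- rep(NA_character_, n)
  valid <- !is.na(seqs) & nzchar(seqs)
  cls[!valid] <- "UNALIGNED"
  has_pts <- valid & grepl(pts, seqs, fixed = TRUE)
  if (pts_max_mismatch > 0L) {
    cand <- valid & !has_pts & nchar(seqs) >= nchar(pts) - pts_max_mismatch
    if (any(cand)) {
      m <- cpp_semiglobal_locate(pts, seqs[cand])
      has_pts[cand] <- m[, "edits"] <= pts_max_mismatch
    }
  }
  cls[has_pts] <- "TEMPLATED_PTS"
  rest <- valid & !has_pts
  dlen <- nchar(seqs) - nchar(reference)
  cls[rest & abs(dlen) > 1L] <- "INDEL"
  cls[rest & dlen == 0L & seqs == reference] <- "EXACT_REF"
  cls[rest & dlen == 0L & seqs != reference] <- "SNP"
  cls[rest & abs(dlen) == 1L] <- "AMBIGUOUS_1BP"
  factor(cls, levels = .OUTCOME_LEVELS)
}

#' Limit of detection of the UMI scheme
#'
#' The smallest mutation frequency resolvable from unique reads, in percent:
#' one molecule out of the whole barcode space, `100 / 4^umi_len`. For the
#' standard 6-base barcode this is 0.0244% (displayed as ~0.02%).
#'
#' @param umi_len barcode length (>= 1).
#' @return percent.
#' @export
detection_limit <- function(umi_len = 6L) {
  if (any(umi_len < 1L)) stop("umi_len must be >= 1", call. = FALSE)
  100 / 4^umi_len
}

#' Summarize classified unique amplicons
#'
#' Per-class unique-read counts and frequencies (percent of unique bins),
#' plus the UMI-space limit of detection. Templated and indel frequencies
#' are the two editing-outcome readouts; 1-bp length differences
#' (`AMBIGUOUS_1BP`) are excluded from both by construction of the classes.
#'
#' @param classes factor from [classify_amplicon()] over unique bins.
#' @param umi_len UMI length used (for the limit of detection).
#' @return object of class `editing_summary`: `counts`, `total`,
#'   `templated_pct`, `indel_pct`, `snp_pct`, `limit_of_detection_pct`.
#' @export
summarize_editing <- function(classes, umi_len = 6L) {
  if (!length(classes)) stop("no unique amplicons to summarize", call. = FALSE)
  classes <- factor(classes, levels = .OUTCOME_LEVELS)
  counts <- table(classes)
  total <- sum(counts)
  pct <- function(k) 100 * as.numeric(counts[[k]]) / total
  structure(list(counts = counts, total = total,
                 templated_pct = pct("TEMPLATED_PTS"),
                 indel_pct = pct("INDEL"),
                 snp_pct = pct("SNP"),
                 exact_pct = pct("EXACT_REF"),
                 limit_of_detection_pct = detection_limit(umi_len),
                 umi_len = umi_len), class = "editing_summary")
}

#' @export
print.editing_summary <- function(x, ...) {
  cat(sprintf("editing summary over %d unique amplicons:\n", x$total))
  for (k in names(x$counts)) {
    cat(sprintf("  %-14s %6d  (%6.3f%%)\n", k, x$counts[[k]],
                100 * x$counts[[k]] / x$total))
  }
  cat(sprintf("  limit of detection: %.4f%% (umi_len = %d)\n",
              x$limit_of_detection_pct, x$umi_len))
  invisible(x)
}

#' Run the full editing-outcome quantification pipeline
#'
#' merge -> quality filter -> UMI extraction -> flank match/trim ->
#' (UMI, sequence) deduplication -> classification -> summary. Every input
#' read pair is accounted for exactly once in the returned dispositions.
#'
#' @param r1,r2 read data frames (columns `name`, `seq`, `qual`), or a
#'   `fastq_pairs` object in `r1` with `r2` missing.
#' @param reference reference amplicon sequence (no UMI).
#' @param pts PTS sequence.
#' @param umi_len UMI length (default 6).
#' @param umi_offset fixed bases before the UMI on the merged read.
#' @param min_q,min_fraction quality-filter parameters (default: every base
#'   at or above Q30).
#' @param flank5,flank3 expected flank sequences; default the first/last
#'   `flank_len` bases of `reference`.
#' @param flank_len default flank length (50).
#' @param flank_max_error maximum flank error rate (0.1).
#' @param merge_min_overlap,merge_max_mismatch merge parameters.
#' @param pts_max_mismatch PTS match tolerance for classification.
#' @return object of class `editing_run`: `summary` (an `editing_summary`),
#'   `unique` (deduplicated bins with class), `dispositions` (per read
#'   pair: one of `merge_rejected`, `quality_rejected`, `umi_rejected`,
#'   `flank_rejected`, `binned`), `params`.
#' @export
quantify_run <- function(r1, r2 = NULL, reference, pts = pts_sequence(),
                         umi_len = 6L, umi_offset = 0L,
                         min_q = 30L, min_fraction = 1.0,
                         flank5 = NULL, flank3 = NULL, flank_len = 50L,
                         flank_max_error = 0.1,
                         merge_min_overlap = 20L, merge_max_mismatch = 0.1,
                         pts_max_mismatch = 2L) {
  if (inherits(r1, "fastq_pairs")) { r2 <- r1$r2; r1 <- r1$r1 }
  stopifnot(is.data.frame(r1), is.data.frame(r2), nrow(r1) == nrow(r2))
  reference <- check_dna(reference, allow_n = FALSE, what = "reference")
  if (is.null(flank5)) flank5 <- substr(reference, 1L, flank_len)
  if (is.null(flank3)) {
    flank3 <- substr(reference, nchar(reference) - flank_len + 1L, nchar(reference))
  }
  n <- nrow(r1)
  disp <- rep(NA_character_, n)

  m <- merge_pairs(r1, r2, merge_min_overlap, merge_max_mismatch)
  disp[!m$merged] <- "merge_rejected"
  idx <- which(m$merged)

  qc_ok <- quality_filter(m$qual[idx], min_q, min_fraction)
  disp[idx[!qc_ok]] <- "quality_rejected"
  idx <- idx[qc_ok]

  um <- extract_umi(m$seq[idx], m$qual[idx], k = umi_len, offset = umi_offset)
  disp[idx[!um$ok]] <- "umi_rejected"
  keep <- um$ok
  idx <- idx[keep]; um <- um[keep, , drop = FALSE]

  fl <- match_and_trim_flanks(um$seq, flank5, flank3,
                              min_overlap = min(flank_len, nchar(flank5), nchar(flank3)),
                              max_error_rate = flank_max_error)
  disp[idx[!fl$accepted]] <- "flank_rejected"
  keep <- fl$accepted
  idx <- idx[keep]
  disp[idx] <- "binned"

  uniq <- deduplicate(um$umi[keep], fl$trimmed[keep])
  if (nrow(uniq)) {
    uniq$class <- classify_amplicon(uniq$seq, reference, pts, pts_max_mismatch)
  } else {
    uniq$class <- factor(character(), levels = .OUTCOME_LEVELS)
  }
  summary <- if (nrow(uniq)) summarize_editing(uniq$class, umi_len) else NULL

  params <- list(umi_len = umi_len, umi_offset = umi_offset, min_q = min_q,
                 min_fraction = min_fraction, flank_len = nchar(flank5),
                 flank_max_error = flank_max_error,
                 merge_min_overlap = merge_min_overlap,
                 merge_max_mismatch = merge_max_mismatch,
                 pts_max_mismatch = pts_max_mismatch, pts = pts)
  structure(list(summary = summary, unique = uniq,
                 dispositions = data.frame(name = r1$name, disposition = disp,
                                           stringsAsFactors = FALSE),
                 params = params), class = "editing_run")
}

#' @export
print.editing_run <- function(x, ...) {
  tab <- table(x$dispositions$disposition)
  cat("editing run:", sum(tab), "read pairs\n")
  for (k in names(tab)) cat(sprintf("  %-16s %d\n", k, tab[[k]]))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' Write an editing run to disk
#'
#' Per-read TSV (read id, disposition), unique-bin TSV (umi, seq, count,
#' class) and a JSON summary with counts, percentages, the limit of
#' detection and all parameters.
#'
#' @param run an `editing_run`.
#' @param out_prefix path prefix for `<prefix>_reads.tsv`,
#'   `<prefix>_unique.tsv`, `<prefix>_summary.json`.
#' @return invisibly, the paths written.
#' @export
write_editing_run <- function(run, out_prefix) {
  paths <- c(reads = paste0(out_prefix, "_reads.tsv"),
             unique = paste0(out_prefix, "_unique.tsv"),
             summary = paste0(out_prefix, "_summary.json"))
  write.table(run$dispositions, paths["reads"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(run$unique, paths["unique"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  s <- run$summary
  json <- list(total_unique = s$total,
               counts = as.list(setNames(as.integer(s$counts), names(s$counts))),
               templated_pct = s$templated_pct, indel_pct = s$indel_pct,
               snp_pct = s$snp_pct, exact_pct = s$exact_pct,
               limit_of_detection_pct = s$limit_of_detection_pct,
               params = run$params)
  jsonlite::write_json(json, paths["summary"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
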