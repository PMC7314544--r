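# Repair oligonucleotide design: the premature termination sequence (PTS)
# cassette and homology-directed repair templates built around a guide's
# predicted cleavage site.

.PTS_SEQ <- "TTTATTTAATTAAATAAA"

#' Canonical PTS sequence
#' @return the 18-nt premature termination sequence as a character string.
#' @export
pts_sequence <- function() .PTS_SEQ

#' Construct the premature termination sequence cassette
#'
#' The PTS is an 18-base palindromic cassette,
#' `5'-TTTATTTAATTAAATAAA-3'`, that terminates both translation and
#' transcription no matter how it lands: it encodes a TAA stop codon in every
#' reading frame on both strands, a polyadenylation signal (AATAAA) on both
#' strands, and a PacI restriction site (TTAATTAA) usable for genotyping by
#' digest. Because it is its own reverse complement it knocks out a gene when
#' inserted in either orientation. All of these properties are re-validated
#' at construction time.
#'
#' @return object of class `pts_cassette` with elements `seq` and `report`
#'   (the [validate_pts_like()] report).
#' @export
make_pts <- function() {
  rep <- validate_pts_like(.PTS_SEQ)
  stopifnot(rep$palindrome, rep$stops_all_frames_both_strands,
            rep$polya_both_strands, rep$pacI)
  structure(list(seq = .PTS_SEQ, report = rep), class = "pts_cassette")
}

#' @export
print.pts_cassette <- function(x, ...) {
  cat("PTS cassette:", x$seq, sprintf("(%d nt, palindromic)\n", nchar(x$seq)))
  invisible(x)
}

#' Validate PTS-like structural properties of a sequence
#'
#' Four independent checks that make a termination cassette
#' orientation-independent: (1) the sequence is its own reverse complement;
#' (2) a stop codon occurs in all three reading frames on both strands;
#' (3) the polyadenylation signal AATAAA occurs on both strands; (4) a PacI
#' site (TTAATTAA) is present. Match positions (1-based) are reported for
#' the sequence elements.
#'
#' @param seq a single sequence.
#' @return list of class `pts_validation`: logicals `palindrome`,
#'   `stops_all_frames_both_strands`, `polya_both_strands`, `pacI`, plus
#'   `polya_pos` / `pacI_pos` (1-based start positions on the given strand)
#'   and `stops_by_frame` (3 x 2 logical matrix).
#' @export
validate_pts_like <- function(seq) {
  seq <- check_dna(seq, allow_n = FALSE, what = "PTS-like sequence")
  stopifnot(length(seq) == 1L)
  rc <- reverse_complement(seq)
  stops <- if (nchar(seq) >= 3L) {
    cbind(sense = stop_codons_by_frame(seq), antisense = stop_codons_by_frame(rc))
  } else {
    matrix(FALSE, 3, 2, dimnames = list(paste0("frame", 0:2), c("sense", "antisense")))
  }
  find_all <- function(pat, s) {
    m <- gregexpr(pat, s, fixed = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
  }
  polya_s <- find_all("AATAAA", seq)
  polya_a <- find_all("AATAAA", rc)
  paci <- find_all("TTAATTAA", seq)
  structure(list(
    palindrome = identical(seq, rc),
    stops_all_frames_both_strands = all(stops),
    polya_both_strands = length(polya_s) > 0L && length(polya_a) > 0L,
    pacI = length(paci) > 0L,
    stops_by_frame = stops,
    polya_pos = list(sense = polya_s, antisense = polya_a),
    pacI_pos = paci), class = "pts_validation")
}

# Resolve the 0-based cleavage insertion point from a guide argument: a
# guide_candidates row, a list with $cleavage_pos, or a bare number
# (interpreted as the 0-based insertion point, as returned by
# cleavage_site()).
.guide_cut0 <- function(guide) {
  if (is.data.frame(guide)) {
    stopifnot(nrow(guide) == 1L)
    return(as.integer(guide$cleavage_pos))
  }
  if (is.list(guide) && !is.null(guide$cleavage_pos)) {
    return(as.integer(guide$cleavage_pos))
  }
  as.integer(guide)
}

.new_repair_template <- function(id, seq, payload, left, right, orientation,
                                 modifications, insertion_point, source_locus,
                                 seq_rc = NULL) {
  structure(list(id = id, seq = seq, seq_rc = seq_rc, payload = payload,
                 left_arm_len = left, right_arm_len = right,
                 orientation = orientation, modifications = modifications,
                 insertion_point = insertion_point,
                 source_locus = source_locus), class = "repair_template")
}

#' @export
print.repair_template <- function(x, ...) {
  cat(sprintf("repair template %s (%s, arms %d/%d nt, payload %s, %d nt)\n",
              x$id, x$orientation, x$left_arm_len, x$right_arm_len,
              if (is.character(x$payload)) x$payload else "point edit",
              nchar(x$seq)))
  invisible(x)
}

#' Design a knockout repair oligonucleotide
#'
#' Copies `arm_len` bases of locus sequence upstream and downstream of the
#' guide's cleavage site (itself 3 bp upstream of the PAM) and inserts the
#' PTS cassette at the cut, so homology-directed repair writes the
#' termination cassette into the gene. With the 50-base default the template
#' is the PTS inserted into 100 bp of locus sequence centered on the cut.
#'
#' @param locus locus sequence (character, or named vector from
#'   [read_fasta()]).
#' @param guide a single-row `guide_candidates` data frame, or a 0-based
#'   cleavage insertion point.
#' @param arm_len homology arm length per side (default 50).
#' @param orientation `"sense"`, `"antisense"` (reverse complement of the
#'   sense design) or `"duplex"` (both strands; see `modifications`).
#' @param pts payload cassette (default the canonical PTS).
#' @param modifications character vector of 5' modification flags carried as
#'   annotation only (e.g. `"5p_phosphorylation"`, `"5p_phosphorothioate"`);
#'   they never alter sequence computation.
#' @param id template identifier.
#' @return object of class `repair_template`.
#' @export
design_knockout_template <- function(locus, guide, arm_len = 50L,
                                     orientation = c("sense", "antisense", "duplex"),
                                     pts = pts_sequence(),
                                     modifications = character(),
                                     id = "ko_template") {
  orientation <- match.arg(orientation)
  locus_name <- if (!is.null(names(locus))) names(locus)[1] else "locus"
  if (is.list(locus)) { locus_name <- locus$name %||% locus_name; locus <- locus$seq }
  locus <- check_dna(locus[[1]], allow_n = FALSE, what = "locus")
  cut0 <- .guide_cut0(guide)
  n <- nchar(locus)
  if (cut0 < arm_len || cut0 + arm_len > n) {
    stop(sprintf(paste0("insufficient flank for arm_len %d at cut %d: need %d ",
                        "bases each side, have %d upstream and %d downstream"),
                 arm_len, cut0, arm_len, cut0, n - cut0), call. = FALSE)
  }
  left <- substr(locus, cut0 - arm_len + 1L, cut0)        # 1-based (cut0-arm, cut0]
  right <- substr(locus, cut0 + 1L, cut0 + arm_len)
  sense <- paste0(left, pts, right)
  seq <- switch(orientation, sense = sense,
                antisense = reverse_complement(sense), duplex = sense)
  seq_rc <- if (orientation == "duplex") reverse_complement(sense) else NULL
  .new_repair_template(id, seq, payload = "PTS", left = arm_len,
                       right = arm_len, orientation = orientation,
                       modifications = modifications,
                       insertion_point = cut0, source_locus = locus_name,
                       seq_rc = seq_rc)
}

#' Design a point-mutation repair oligonucleotide
#'
#' Copies `arm_len` bases either side of the cleavage site and substitutes
#' `replacement` at a reference span inside that window — e.g. a single-codon
#' swap plus, optionally, explicit PAM-blocking silent changes supplied as
#' part of the edit. Total homology is `2*arm_len` minus the replaced span
#' length.
#'
#' @param locus locus sequence.
#' @param guide guide (as in [design_knockout_template()]).
#' @param edit_start,edit_end 0-based half-open reference span to replace
#'   (`edit_start == edit_end` inserts at that point).
#' @param replacement replacement bases (may be `""` for a pure deletion).
#' @param arm_len homology arm length per side (default 100, i.e. 200 bases
#'   of flanking homology centered on the cut).
#' @param orientation as in [design_knockout_template()].
#' @param id template identifier.
#' @return object of class `repair_template`.
#' @export
design_point_mutation_template <- function(locus, guide, edit_start, edit_end,
                                           replacement, arm_len = 100L,
                                           orientation = c("sense", "antisense"),
                                           id = "pm_template") {
  orientation <- match.arg(orientation)
  locus_name <- if (!is.null(names(locus))) names(locus)[1] else "locus"
  locus <- check_dna(locus[[1]], allow_n = FALSE, what = "locus")
  if (nzchar(replacement)) {
    replacement <- check_dna(replacement, allow_n = FALSE, what = "replacement")
  }
  cut0 <- .guide_cut0(guide)
  n <- nchar(locus)
  win_lo <- cut0 - arm_len            # 0-based half-open window [win_lo, win_hi)
  win_hi <- cut0 + arm_len
  if (win_lo < 0L || win_hi > n) {
    stop(sprintf("insufficient flank for arm_len %d at cut %d", arm_len, cut0),
         call. = FALSE)
  }
  if (edit_start < win_lo || edit_end > win_hi || edit_start > edit_end) {
    stop(sprintf("edit span [%d,%d) outside the homology window [%d,%d)",
                 edit_start, edit_end, win_lo, win_hi), call. = FALSE)
  }
  before <- substr(locus, win_lo + 1L, edit_start)
  after <- substr(locus, edit_end + 1L, win_hi)
  sense <- paste0(before, replacement, after)
  seq <- if (orientation == "sense") sense else reverse_complement(sense)
  .new_repair_template(id, seq,
                       payload = list(edit_start = edit_start, edit_end = edit_end,
                                      replacement = replacement),
                       left = arm_len, right = arm_len,
                       orientation = orientation, modifications = character(),
                       insertion_point = cut0, source_locus = locus_name)
}

#' Default knockout template panel
#'
#' Emits the panel of single- and double-stranded PTS repair templates used
#' to compare delivery formats: full-length sense and antisense
#' single-stranded oligos, an unmodified duplex, duplexes annotated with
#' 5'-phosphorylation or 5'-phosphorothioate ends, and truncated
#' single-arm (5'-arm-only / 3'-arm-only) sense oligos. The exact roster is
#' configurable; arm lengths of the truncated variants default to the full
#' arm length.
#'
#' @param locus locus sequence.
#' @param guide guide (as in [design_knockout_template()]).
#' @param arm_len full homology arm length per side (default 50).
#' @param truncated_arm_len arm length of the single-arm variants
#'   (default 50).
#' @param roster which templates to emit, a subset of
#'   `c("sense","antisense","duplex","duplex_phos","duplex_thio",
#'   "arm5_only","arm3_only")`.
#' @return list of `repair_template` objects, class `repair_template_panel`.
#' @export
template_panel <- function(locus, guide, arm_len = 50L, truncated_arm_len = 50L,
                           roster = c("sense", "antisense", "duplex",
                                      "duplex_phos", "duplex_thio",
                                      "arm5_only", "arm3_only")) {
  roster <- match.arg(roster, several.ok = TRUE)
  cut0 <- .guide_cut0(guide)
  pts <- pts_sequence()
  locus_chr <- if (is.list(locus)) locus$seq else locus[[1]]
  mk <- function(nm) {
    switch(nm,
      sense = design_knockout_template(locus, cut0, arm_len, "sense", id = "S"),
      antisense = design_knockout_template(locus, cut0, arm_len, "antisense", id = "A"),
      duplex = design_knockout_template(locus, cut0, arm_len, "duplex", id = "D"),
      duplex_phos = design_knockout_template(locus, cut0, arm_len, "duplex",
                                             modifications = "5p_phosphorylation",
                                             id = "D-phos"),
      duplex_thio = design_knockout_template(locus, cut0, arm_len, "duplex",
                                             modifications = "5p_phosphorothioate",
                                             id = "D-thio"),
      arm5_only = {
        t <- design_knockout_template(locus_chr, cut0, truncated_arm_len,
                                      "sense", id = "S-5arm")
        t$seq <- substr(t$seq, 1L, truncated_arm_len + nchar(pts))
        t$right_arm_len <- 0L
        t
      },
      arm3_only = {
        t <- design_knockout_template(locus_chr, cut0, truncated_arm_len,
                                      "sense", id = "S-3arm")
        t$seq <- substr(t$seq, truncated_arm_len + 1L, nchar(t$seq))
        t$left_arm_len <- 0L
        t
      })
  }
  out <- lapply(roster, mk)
  names(out) <- vapply(out, `[[`, character(1), "id")
  structure(out, class = "repair_template_panel")
}

#' Export repair templates as FASTA plus a TSV manifest
#'
#' @param panel a `repair_template_panel`, or a list of `repair_template`s.
#' @param fasta_path,manifest_path output paths (either may be `NULL` to
#'   skip).
#' @return the manifest data frame, invisibly.
#' @export
write_templates <- function(panel, fasta_path = NULL, manifest_path = NULL) {
  if (inherits(panel, "repair_template")) panel <- list(panel)
  man <- do.call(rbind, lapply(panel, function(t) {
    data.frame(template_id = t$id, orientation = t$orientation,
               length_nt = nchar(t$seq),
               left_arm_len = t$left_arm_len, right_arm_len = t$right_arm_len,
               payload = if (is.character(t$payload)) t$payload else "point_edit",
               modifications = paste(t$modifications, collapse = ";"),
               insertion_point = t$insertion_point,  # 1-based: cut after this base
               source_locus = t$source_locus, stringsAsFactors = FALSE)
  }))
  rownames(man) <- NULL
  if (!is.null(fasta_path)) {
    seqs <- character(0)
    for (t in panel) {
      seqs[t$id] <- t$seq
      if (!is.null(t$seq_rc)) seqs[paste0(t$id, "_bottom")] <- t$seq_rc
    }
    write_fasta(seqs, fasta_path)
  }
  if (!is.null(manifest_path)) {
    write.table(man, manifest_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(man)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
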