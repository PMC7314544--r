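# Independent oracles used to cross-check the package's implementations.
# Each oracle deliberately uses a different algorithm (or a different
# library) than the code path it checks.

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Exhaustive enumeration of simple hairpins: every (start, end, helix length)
# triple, energies summed directly from the shared parameter tables. The
# implementation under test is a dynamic program over closing pairs; this
# oracle never recurses.
oracle_hairpin_mfe <- function(seq) {
  par <- fold_params()
  b <- strsplit(chartr("T", "U", seq), "")[[1]]
  n <- length(b)
  pair <- function(i, j) {
    p <- paste0(b[i], b[j])
    if (p %in% rownames(par$stacks)) p else NA_character_
  }
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i < 4L) next
      # grow a helix of h pairs (i+k, j-k), k = 0..h-1
      stack_sum <- 0
      h <- 0L
      repeat {
        p_out <- pair(i + h, j - h)
        if (is.na(p_out)) break
        if (h > 0L) {
          stack_sum <- stack_sum + par$stacks[pair(i + h - 1L, j - h + 1L), p_out]
        }
        h <- h + 1L
        loop_len <- (j - h + 1L) - (i + h - 1L) - 1L
        if (loop_len < 3L) break
        e <- stack_sum + par$hairpin_loop[loop_len]
        if (e < best) best <- e
      }
    }
  }
  best
}

# Positionwise motif mismatch count built from Biostrings' IUPAC map rather
# than the package's own class table.
oracle_motif_mismatches <- function(contexts, motif = "HNNGRSGGH") {
  map <- Biostrings::IUPAC_CODE_MAP
  classes <- strsplit(motif, "")[[1]]
  sets <- lapply(classes, function(cl) strsplit(map[[cl]], "")[[1]])
  mm <- integer(length(contexts))
  for (i in seq_along(classes)) {
    mm <- mm + !(substring(contexts, i, i) %in% sets[[i]])
  }
  mm
}

# Brute-force protospacer count: every 0-based spacer start i with
# locus[i+21, i+23) == "GG" and a full 9-nt context window, on both strands.
oracle_scan_count <- function(locus) {
  count_one <- function(s) {
    n <- nchar(s)
    if (n < 24L) return(0L)
    cnt <- 0L
    for (i in 0:(n - 24L)) {
      if (substr(s, i + 22L, i + 23L) == "GG") cnt <- cnt + 1L
    }
    cnt
  }
  count_one(locus) + count_one(choanoedit::reverse_complement(locus))
}

# Semi-global edit distance (pattern end-to-end, free ends in the subject)
# via Biostrings::pairwiseAlignment with unit costs; -score is the edit
# distance of the best location.
oracle_semiglobal_edits <- function(pattern, text) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(pattern = pattern, subject = text,
                                      type = "global-local",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = 1)
  -as.integer(Biostrings::score(al))
}

# Expected unique bins from a simulation truth table: collapse molecules by
# (UMI, molecule sequence), summing read counts; classes carried through
# (identical sequences always share a true class).
oracle_collapse_truth <- function(truth) {
  key <- paste(truth$umi, truth$seq, sep = "\r")
  agg <- tapply(truth$n_reads, key, sum)
  cls <- tapply(truth$true_class, key, function(x) unique(x)[1])
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(umi = vapply(parts, `[`, character(1), 1L),
                    seq = vapply(parts, `[`, character(1), 2L),
                    duplicate_count = as.integer(agg),
                    true_class = unname(cls), stringsAsFactors = FALSE)
  out[order(out$umi, out$seq), , drop = FALSE]
}

map_truth_class <- function(x) {
  c(EXACT = "EXACT_REF", TEMPLATED = "TEMPLATED_PTS",
    INDEL = "INDEL", SNP = "SNP")[x]
}
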