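# Sequence I/O and nucleotide-string utilities shared by all modules.
#
# Conventions: sequences are plain uppercase character strings over A/C/G/T
# (N tolerated in reference inputs only); coordinates are 0-based half-open
# internally and 1-based inclusive in every user-facing table.

.VALID_REF_CHARS <- c("A", "C", "G", "T", "N")

#' Validate a nucleotide string
#'
#' @param seq character vector of sequences.
#' @param allow_n allow ambiguous N (reference inputs only; designed outputs
#'   must be unambiguous).
#' @param what label used in error messages.
#' @return `seq`, uppercased, invisibly usable.
#' @keywords internal
check_dna <- function(seq, allow_n = TRUE, what = "sequence") {
  seq <- toupper(seq)
  allowed <- if (allow_n) "ACGTN" else "ACGT"
  bad <- grepl(sprintf("[^%s]", allowed), seq)
  if (any(bad)) {
    ch <- unique(unlist(strsplit(gsub(sprintf("[%s]", allowed), "", seq[bad]), "")))
    stop(sprintf("invalid character(s) %s in %s (allowed: %s)",
                 paste(sQuote(ch), collapse = ", "), what, allowed),
         call. = FALSE)
  }
  if (any(!nzchar(seq))) stop(sprintf("empty %s", what), call. = FALSE)
  seq
}

#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that uppercases
#' sequences, preserves record order, and rejects records containing
#' characters outside A/C/G/T/N (ambiguity codes beyond N, or RNA `U`, are
#' format errors: this toolkit works on DNA references).
#'
#' @param path path to a FASTA file (gzip transparent).
#' @return named character vector of uppercase sequences, in file order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgt"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  x <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                error = function(e) stop(sprintf("malformed FASTA %s: %s", path,
                                                 conditionMessage(e)), call. = FALSE))
  if (length(x) == 0L) stop(sprintf("no FASTA records in %s", path), call. = FALSE)
  seqs <- toupper(as.character(x))
  if (any(!nzchar(seqs))) {
    i <- which(!nzchar(seqs))[1L]
    stop(sprintf("empty FASTA record %d (%s) in %s", i, names(x)[i], path), call. = FALSE)
  }
  check_dna(seqs, allow_n = TRUE, what = sprintf("FASTA records of %s", path))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

.read_fastq_one <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTQ file not found: %s", path), call. = FALSE)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop(sprintf("malformed FASTQ %s: %s", path,
                                     conditionMessage(e)), call. = FALSE))
  qual <- as.character(S4Vectors::mcols(x)$qualities)
  seqs <- toupper(as.character(x))
  if (any(nchar(qual) != nchar(seqs))) {
    i <- which(nchar(qual) != nchar(seqs))[1L]
    stop(sprintf("sequence/quality length mismatch at record %d of %s", i, path),
         call. = FALSE)
  }
  # Sanger Phred+33 only: printable '!'..'~' maps to [0, 93]. Anything below
  # '!' is not representable; scores that would exceed 93 are not printable.
  ascii <- unlist(lapply(qual, utf8ToInt), use.names = FALSE)
  if (length(ascii) && (min(ascii) < 33L || max(ascii) > 126L)) {
    stop(sprintf("quality characters outside Sanger Phred+33 range in %s ", path),
         call. = FALSE)
  }
  data.frame(name = unname(names(x)), seq = unname(seqs), qual = unname(qual),
             stringsAsFactors = FALSE)
}

#' Read a paired-end FASTQ run
#'
#' Reads two Sanger Phred+33 FASTQ files and pairs records by order. Names
#' may differ by a `/1` / `/2` (or ` 1:...` / ` 2:...`) suffix.
#'
#' @param path_r1,path_r2 paths to the R1 and R2 FASTQ files.
#' @return list with data frames `r1` and `r2` (columns `name`, `seq`,
#'   `qual`), one row per read, rows aligned across the two.
#' @export
read_fastq_pairs <- function(path_r1, path_r2) {
  r1 <- .read_fastq_one(path_r1)
  r2 <- .read_fastq_one(path_r2)
  if (nrow(r1) != nrow(r2)) {
    stop(sprintf("read pairing error: %d records in %s but %d in %s",
                 nrow(r1), path_r1, nrow(r2), path_r2), call. = FALSE)
  }
  structure(list(r1 = r1, r2 = r2), class = "fastq_pairs")
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads data frame with columns `name`, `seq`, `qual`.
#' @param path output path; `.gz` suffix enables gzip.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("name", "seq", "qual") %in% names(reads)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(paste0("@", reads$name, "\n", reads$seq, "\n+\n", reads$qual),
             con, sep = "\n")
  invisible(path)
}

#' Convert Phred+33 quality strings to integer scores
#'
#' `"!"` is Phred 0 and `"?"` is Phred 30.
#'
#' @param qual character vector of quality strings.
#' @return list of integer vectors.
#' @export
phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' Convert integer Phred scores to a Phred+33 string
#' @param q integer vector in \[0, 93\].
#' @return single quality string.
#' @export
int_to_phred <- function(q) {
  if (any(q < 0L | q > 93L)) stop("Phred scores must lie in [0, 93]", call. = FALSE)
  intToUtf8(q + 33L)
}

#' Reverse complement
#'
#' Standard Watson-Crick complement, reversed. Vectorized. The 18-nt PTS
#' cassette is its own reverse complement, which is why it can be inserted in
#' either orientation.
#'
#' @param seq character vector over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("AAAC")                # "GTTT"
#' reverse_complement("TTTATTTAATTAAATAAA")  # palindromic PTS
reverse_complement <- function(seq) {
  seq <- check_dna(seq, allow_n = TRUE, what = "reverse_complement input")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Stop-codon presence per reading frame
#'
#' Scans non-overlapping codons starting at offsets 0, 1 and 2 of the given
#' strand and reports whether any of TAA/TAG/TGA occurs in each frame. The
#' PTS cassette carries a TAA in every frame on both strands.
#'
#' @param seq a single sequence, length >= 3.
#' @return logical vector of length 3, names `frame0`..`frame2`.
#' @export
stop_codons_by_frame <- function(seq) {
  seq <- check_dna(seq, allow_n = FALSE, what = "stop_codons_by_frame input")
  if (length(seq) != 1L) stop("expected a single sequence", call. = FALSE)
  n <- nchar(seq)
  if (n < 3L) stop("sequence shorter than one codon", call. = FALSE)
  stops <- c("TAA", "TAG", "TGA")
  out <- vapply(0:2, function(off) {
    if (1L + off > n - 2L) return(FALSE)
    starts <- seq.int(1L + off, n - 2L, by = 3L)
    any(substring(seq, starts, starts + 2L) %in% stops)
  }, logical(1))
  names(out) <- paste0("frame", 0:2)
  out
}

# Positionwise IUPAC class sets (motif patterns may use any of these).
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Positionwise IUPAC pattern match
#'
#' @param pattern IUPAC pattern (single string); may use ambiguity codes.
#' @param seq concrete sequence of equal length over A/C/G/T.
#' @return `TRUE` iff every position of `seq` is in the IUPAC class of the
#'   corresponding pattern position.
#' @export
#' @examples
#' iupac_match("NGG", "AGG")  # TRUE: the SpCas9 PAM consensus
#' iupac_match("H", "G")      # FALSE: H = not G
iupac_match <- function(pattern, seq) {
  pattern <- toupper(pattern); seq <- toupper(seq)
  if (nchar(pattern) != nchar(seq)) {
    stop("pattern and sequence lengths differ", call. = FALSE)
  }
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(seq, "")[[1]]
  if (!all(p %in% names(.IUPAC_SETS))) {
    stop("pattern contains non-IUPAC characters", call. = FALSE)
  }
  if (!all(s %in% c("A", "C", "G", "T"))) {
    stop("sequence must be concrete A/C/G/T", call. = FALSE)
  }
  all(mapply(function(pp, ss) ss %in% .IUPAC_SETS[[pp]], p, s))
}

#' Read exon annotation from GFF3
#'
#' Imports a GFF3 file and keeps `exon` features as a
#' [GenomicRanges::GRanges] (1-based inclusive, as in GFF3). Used to verify
#' that a candidate guide matches contiguous genomic sequence inside one exon
#' rather than an exon-exon junction of the cDNA it was picked from.
#'
#' @param path path to a GFF3 file.
#' @return `GRanges` of exons.
#' @export
read_exons <- function(path) {
  if (!file.exists(path)) stop(sprintf("GFF3 file not found: %s", path), call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0L) warning(sprintf("no exon features found in %s", path))
  BiocGenerics::sort(gr)
}

# Normalize an exon annotation (GRanges or data.frame with contig/start/end)
# to a data.frame with 1-based inclusive start/end.
.exons_to_df <- function(annotation) {
  if (is.null(annotation)) return(NULL)
  if (methods::is(annotation, "GRanges")) {
    data.frame(contig = as.character(GenomicRanges::seqnames(annotation)),
               start = GenomicRanges::start(annotation),
               end = GenomicRanges::end(annotation),
               stringsAsFactors = FALSE)
  } else {
    an <- as.data.frame(annotation)
    if ("seqnames" %in% names(an) && !"contig" %in% names(an)) {
      an$contig <- an$seqnames
    }
    stopifnot(all(c("contig", "start", "end") %in% names(an)))
    an[, c("contig", "start", "end")]
  }
}
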