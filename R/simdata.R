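# Synthetic-data generators: loci with a planted motif-conforming guide,
# paired-end amplicon runs with UMIs and controlled editing-outcome
# frequencies, and noisy logistic growth series. Defaults emulate the
# stated experimental world: a ~450 bp amplicon around the cleavage site,
# 2 x 300 nt MiSeq reads (~300 pairs per sample), a 6-nt randomized barcode
# in the forward primer, templated-repair frequency ~1.5% and untemplated
# indels ~0.1%.

# Planted 24-nt guide context: 20-nt spacer (unstructured, last five bases
# ACTGA = HNNGR), PAM GGG (SGG) and a final A (H) -> motif mismatches 0,
# folding dG 0. Planted verbatim regardless of the requested GC content.
.PLANT_SPACER <- "AAAAAAAAAAAAAAAACTGA"
.PLANT_BLOCK <- paste0(.PLANT_SPACER, "GGG", "A")

.random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate a locus with a planted motif-perfect guide
#'
#' Random sequence at the requested GC content; when `ensure_guide` is set,
#' a 24-nt block containing a motif-conforming, unstructured plus-strand
#' protospacer (mismatches 0, folding dG 0) is planted at a recorded
#' position near the middle so that knockout templates with default arms
#' always fit.
#'
#' @param length locus length (>= 150).
#' @param gc GC fraction of the random background (the planted block itself
#'   is fixed and AT-rich; with `gc = 1` the background is pure G/C and the
#'   plant still applies).
#' @param seed integer seed (`NULL` = current RNG state).
#' @param ensure_guide plant the guide block (default `TRUE`).
#' @param name locus name.
#' @return object of class `sim_locus`: `name`, `seq`, and (when planted)
#'   `guide` = list(`spacer`, `pam`, `pam_start` (1-based), `cleavage_pos`
#'   (0-based insertion point / 1-based cut-after-base)).
#' @export
simulate_locus <- function(length = 300L, gc = 0.5, seed = NULL,
                           ensure_guide = TRUE, name = "sim_locus") {
  if (length < 150L) stop("locus length must be >= 150", call. = FALSE)
  if (gc < 0 || gc > 1) stop("gc must lie in [0, 1]", call. = FALSE)
  gen <- function() {
    seq <- .random_dna(length, gc)
    guide <- NULL
    if (ensure_guide) {
      block <- .PLANT_BLOCK
      # center the plant, jittered, keeping >= 60 nt margins
      lo <- max(61L, floor(length / 2) - 40L)
      hi <- min(length - nchar(block) - 60L, floor(length / 2) + 40L)
      if (hi < lo) stop("locus too short to plant a guide with margins", call. = FALSE)
      at <- sample(lo:hi, 1L)          # 1-based start of the block
      seq <- paste0(substr(seq, 1L, at - 1L), block,
                    substr(seq, at + nchar(block), length))
      pam_start1 <- at + 20L           # 1-based first PAM base
      guide <- list(spacer = .PLANT_SPACER, pam = "GGG", strand = "+",
                    pam_start = pam_start1,
                    cleavage_pos = cleavage_site(pam_start1 - 1L, "+"))
    }
    structure(list(name = name, seq = seq, guide = guide), class = "sim_locus")
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' @export
print.sim_locus <- function(x, ...) {
  cat(sprintf("simulated locus %s (%d nt)", x$name, nchar(x$seq)))
  if (!is.null(x$guide)) {
    cat(sprintf("; planted + guide, PAM at %d, cut after base %d",
                x$guide$pam_start, x$guide$cleavage_pos))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.character.sim_locus <- function(x, ...) x$seq

#' Specification of a simulated amplicon sequencing run
#'
#' Validates and assembles the parameters of [simulate_amplicon_run()].
#' Outcome frequencies are per true molecule: `templated_frac` get the PTS
#' inserted at the cleavage point, `indel_frac` get an untemplated
#' insertion/deletion of size >= 2 at the cut, and remaining molecules carry
#' per-base substitutions at `snp_rate` (default 0: the SNP class of real
#' runs is dominated by PCR/sequencing error, which the quality model
#' already produces). Base-call errors are injected per read copy with
#' probability `10^(-Q/10)` from each emitted quality score.
#'
#' @param reference reference amplicon (`sim_locus` or character). Default:
#'   a 450-nt simulated locus with a planted guide.
#' @param cut_pos 0-based insertion point of edits (default: the planted
#'   guide's cleavage position; required for a bare character reference).
#' @param templated_frac,indel_frac,snp_rate outcome frequencies.
#' @param indel_sizes candidate indel sizes (default 2:10, uniform).
#' @param n_molecules number of true molecules (default 100, which at the
#'   default PCR duplication gives ~300 read pairs).
#' @param dup_mean mean reads per molecule, geometric (default 3).
#' @param read_len paired-end read length (default 300).
#' @param umi_len UMI length (default 6).
#' @param q_mean,q_sd per-base quality profile (Phred; default 36 +/- 1).
#' @param inject_errors inject base-call errors consistent with the emitted
#'   qualities (default `TRUE`; `FALSE` emits Q40 everywhere and no errors).
#' @param seed integer seed.
#' @return validated spec, class `amplicon_sim_spec`.
#' @export
amplicon_sim_spec <- function(reference = NULL, cut_pos = NULL,
                              templated_frac = 0.015, indel_frac = 0.001,
                              snp_rate = 0, indel_sizes = 2:10,
                              n_molecules = 100L, dup_mean = 3,
                              read_len = 300L, umi_len = 6L,
                              q_mean = 36, q_sd = 1, inject_errors = TRUE,
                              seed = 1L) {
  if (is.null(reference)) {
    reference <- simulate_locus(450L, seed = seed + 7777L, name = "sim_amplicon")
  }
  if (inherits(reference, "sim_locus")) {
    if (is.null(cut_pos)) cut_pos <- reference$guide$cleavage_pos
    reference <- reference$seq
  }
  reference <- check_dna(reference, allow_n = FALSE, what = "reference amplicon")
  if (is.null(cut_pos)) stop("cut_pos required for a character reference", call. = FALSE)
  stopifnot(templated_frac >= 0, indel_frac >= 0, snp_rate >= 0,
            templated_frac + indel_frac <= 1, all(indel_sizes >= 2),
            n_molecules >= 1, dup_mean >= 1, read_len >= 50, umi_len >= 1)
  if (cut_pos <= 0 || cut_pos >= nchar(reference)) {
    stop("cut_pos must lie strictly inside the reference", call. = FALSE)
  }
  structure(list(reference = reference, cut_pos = as.integer(cut_pos),
                 templated_frac = templated_frac, indel_frac = indel_frac,
                 snp_rate = snp_rate, indel_sizes = as.integer(indel_sizes),
                 n_molecules = as.integer(n_molecules), dup_mean = dup_mean,
                 read_len = as.integer(read_len), umi_len = as.integer(umi_len),
                 q_mean = q_mean, q_sd = q_sd, inject_errors = inject_errors,
                 seed = as.integer(seed), pts = pts_sequence()),
            class = "amplicon_sim_spec")
}

.apply_molecule_edit <- function(ref, cut0, class, spec) {
  switch(class,
    EXACT = ref,
    TEMPLATED = paste0(substr(ref, 1L, cut0), spec$pts,
                       substr(ref, cut0 + 1L, nchar(ref))),
    INDEL = {
      size <- if (length(spec$indel_sizes) == 1L) spec$indel_sizes else
        sample(spec$indel_sizes, 1L)
      if (runif(1) < 0.5) {  # insertion of random bases at the cut
        ins <- paste(sample(c("A", "C", "G", "T"), size, replace = TRUE),
                     collapse = "")
        paste0(substr(ref, 1L, cut0), ins, substr(ref, cut0 + 1L, nchar(ref)))
      } else {               # deletion starting at the cut
        paste0(substr(ref, 1L, cut0), substr(ref, cut0 + size + 1L, nchar(ref)))
      }
    },
    SNP = {
      b <- strsplit(ref, "")[[1]]
      hit <- which(runif(length(b)) < spec$snp_rate)
      for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
      paste(b, collapse = "")
    })
}

#' Simulate a paired-end amplicon sequencing run
#'
#' Each molecule draws a true outcome (templated PTS insertion at the cut,
#' untemplated indel of size >= 2, per-base SNPs, or exact reference), a UMI
#' uniform over `4^umi_len` (collisions are simulated honestly, so the
#' limit-of-detection property of the barcoding scheme manifests), and a
#' geometric number of PCR duplicate read pairs that share UMI and template.
#' The sequenced fragment is `UMI + molecule`; R1 is its first `read_len`
#' bases and R2 the reverse complement of its last `read_len` bases, with
#' base-call errors injected per the quality profile. Deterministic per
#' seed.
#'
#' @param spec an [amplicon_sim_spec()] (or arguments forwarded to it).
#' @param ... forwarded to [amplicon_sim_spec()] when `spec` is missing.
#' @return object of class `amplicon_sim`: `r1`, `r2` (read data frames),
#'   `truth` (molecule id, umi, true class, molecule sequence, n_reads),
#'   `spec`.
#' @export
simulate_amplicon_run <- function(spec = NULL, ...) {
  if (is.null(spec)) spec <- amplicon_sim_spec(...)
  stopifnot(inherits(spec, "amplicon_sim_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_molecules
    u <- runif(n)
    class <- ifelse(u < spec$templated_frac, "TEMPLATED",
                    ifelse(u < spec$templated_frac + spec$indel_frac, "INDEL",
                           ifelse(spec$snp_rate > 0, "SNP", "EXACT")))
    umi_idx <- sample.int(4^spec$umi_len, n, replace = TRUE) - 1L
    bases <- c("A", "C", "G", "T")
    umi <- vapply(umi_idx, function(ix) {
      paste(bases[(ix %/% 4^((spec$umi_len - 1):0)) %% 4 + 1], collapse = "")
    }, character(1))
    mol_seq <- character(n)
    true_class <- character(n)
    for (i in seq_len(n)) {
      s <- .apply_molecule_edit(spec$reference, spec$cut_pos, class[i], spec)
      # a SNP draw that hits zero bases is an exact molecule
      true_class[i] <- if (class[i] == "SNP" && s == spec$reference) "EXACT" else class[i]
      mol_seq[i] <- s
    }
    n_reads <- rgeom(n, 1 / spec$dup_mean) + 1L
    frag <- paste0(umi, mol_seq)
    fl <- nchar(frag)
    rl <- pmin(spec$read_len, fl)
    fwd <- substr(frag, 1L, rl)
    rev <- reverse_complement(substring(frag, fl - rl + 1L, fl))
    idx <- rep.int(seq_len(n), n_reads)
    name <- sprintf("mol%06d_read%02d", idx, sequence(n_reads))
    if (spec$inject_errors) {
      c1 <- cpp_call_reads(fwd[idx], spec$q_mean, spec$q_sd)
      c2 <- cpp_call_reads(rev[idx], spec$q_mean, spec$q_sd)
      r1_seq <- c1$seq; r1_qual <- c1$qual
      r2_seq <- c2$seq; r2_qual <- c2$qual
    } else {
      q40 <- strrep(int_to_phred(40L), rl)
      r1_seq <- fwd[idx]; r1_qual <- q40[idx]
      r2_seq <- rev[idx]; r2_qual <- q40[idx]
    }
    structure(list(
      r1 = data.frame(name = name, seq = r1_seq, qual = r1_qual,
                      stringsAsFactors = FALSE),
      r2 = data.frame(name = name, seq = r2_seq, qual = r2_qual,
                      stringsAsFactors = FALSE),
      truth = data.frame(molecule = sprintf("mol%06d", seq_len(n)), umi = umi,
                         true_class = true_class, seq = mol_seq,
                         n_reads = n_reads, stringsAsFactors = FALSE),
      spec = spec), class = "amplicon_sim")
  })
}

#' Write a simulated run to FASTQ plus truth table and provenance JSON
#'
#' @param run an `amplicon_sim`.
#' @param out_prefix path prefix; writes `<prefix>_R1.fastq.gz`,
#'   `<prefix>_R2.fastq.gz`, `<prefix>_truth.tsv`, `<prefix>_spec.json`.
#' @param gzip gzip the FASTQ files (default `TRUE`).
#' @return invisibly, the paths written.
#' @export
write_amplicon_run <- function(run, out_prefix, gzip = TRUE) {
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- c(r1 = paste0(out_prefix, "_R1", ext),
             r2 = paste0(out_prefix, "_R2", ext),
             truth = paste0(out_prefix, "_truth.tsv"),
             spec = paste0(out_prefix, "_spec.json"))
  write_fastq(run$r1, paths["r1"])
  write_fastq(run$r2, paths["r2"])
  write.table(run$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(unclass(run$spec), paths["spec"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Simulate logistic growth time courses
#'
#' Logistic densities with multiplicative log-normal noise of the stated
#' coefficient of variation. The default sampling grid mirrors a typical
#' bench design: 13 timepoints every 12 h, three replicate wells.
#'
#' @param K,P0,T_const logistic parameters (see [logistic_density()]).
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 = exact values).
#' @param times observation times, hours.
#' @param replicates number of replicate series.
#' @param seed integer seed.
#' @return data frame: `replicate`, `time_h`, `density_cells_per_ml`.
#' @export
simulate_growth_series <- function(K = 1e7, P0 = 1e4, T_const = 12,
                                   noise_cv = 0.2,
                                   times = seq(0, 144, by = 12),
                                   replicates = 3L, seed = 1L) {
  gen <- function() {
    mu <- logistic_density(times, K, P0, T_const)
    sdlog <- sqrt(log(1 + noise_cv^2))
    do.call(rbind, lapply(seq_len(replicates), function(r) {
      noise <- if (noise_cv > 0) {
        exp(rnorm(length(mu), -sdlog^2 / 2, sdlog))
      } else rep(1, length(mu))
      data.frame(replicate = r, time_h = times,
                 density_cells_per_ml = mu * noise)
    }))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
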