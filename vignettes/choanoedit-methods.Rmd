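---
title: "Models and methods behind choanoedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind choanoedit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choanoedit)
```

This vignette explains the models implemented by choanoedit, the parameters
that matter (with units and defaults), the design choices made where the
design was genuinely open, and what the synthetic-data tests do and do not
establish. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Guide selection

A candidate guide is a 20-nt protospacer immediately 5' of an NGG PAM, on
either strand. Three filters are applied.

**Target-context motif.** SpCas9 activity is biased by sequence adjacent to
the PAM, summarized here as the 9-nt consensus `5'-HNNGRSGGH-3'` in which
the PAM is embedded. The consensus contains exactly one NGG-compatible
3-mer (positions 6–8, `SGG`), which fixes the anchoring unambiguously: the
window is spacer positions 16–20, the PAM, and one base 3' of the PAM, all
read on the protospacer strand. Conformity is scored as a mismatch count
over the 9 positions (N positions can never mismatch, so 7 are
informative). The default filter demands 0 mismatches; because the source
heuristic is "as close to the motif as possible" rather than a hard rule,
`max_motif_mismatches` is exposed as a parameter rather than hard-coded.

**Folding free energy.** A targeting sequence that folds back on itself
hybridizes poorly with its DNA target. Guides are kept when the predicted
folding free energy of the 20-nt targeting sequence (T read as U) exceeds
−1.5 kcal/mol. The threshold is the established one; the energy *model* is
not specified anywhere authoritative, so choanoedit bundles a deliberately
small, documented estimator: minimum free energy over *simple hairpins*
(one helix of consecutively stacked canonical pairs — Watson–Crick plus GU
wobble — closed by a terminal loop of at least 3 nt), with Turner-2004
Watson–Crick stack energies, rounded literature values for GU stacks, and
the Turner hairpin-loop initiation table with a logarithmic extension above
9 nt (`fold_params()` exposes both tables). A 20-mer offers no room for
multiloops, and bulged helices are rare at this length, so the hairpin-only
space captures what the filter needs: whether a stable stem can form at
all. When no structure is stabilizing the estimate is 0.0, and the
estimate is never positive. The implementation is a dynamic program over
closing pairs; the test suite checks it cell-for-cell against an exhaustive
enumeration of every (start, end, helix-length) hairpin on hundreds of
random 20-mers. Whether the published filter folded the 20-nt spacer or
the full-length gRNA is unstated; choanoedit folds the spacer by default
and accepts any external backend (`predict_fold_dg(..., backend = )`,
e.g. a ViennaRNA wrapper), whose value is used verbatim.

**Genomic contiguity.** Guides picked from cDNA can span exon–exon
junctions and then match no contiguous genomic site.
`verify_genomic_contiguity()` requires the spacer+PAM 23-mer (or its
reverse complement) to occur contiguously in the genomic sequence and,
when a GFF3 exon annotation is supplied, to lie inside a single exon.

**Cleavage position.** The blunt cut is placed 3 bp upstream of the PAM
(between protospacer positions 17 and 18), mirrored on the minus strand.
Internally coordinates are 0-based half-open and cuts are insertion points;
all user-facing tables are 1-based, with `cleavage_pos` read as "the cut
falls immediately after this base".

**Ranking.** `filter_guides()` orders by motif mismatches (ascending),
then ΔG (descending), then reference coordinate — a total, deterministic
ordering; coordinate as the final tie-break makes reruns reproducible.

## The PTS cassette and repair templates

The premature termination sequence `5'-TTTATTTAATTAAATAAA-3'` is 18 nt and
palindromic, encodes a TAA stop codon in all three frames on both strands,
a polyadenylation signal (AATAAA) on both strands, and a PacI restriction
site (TTAATTAA). Palindromy means either insertion orientation knocks out
the gene; the PacI site gives a restriction-digest genotyping assay.
`make_pts()` re-validates all of these properties at construction, and
`validate_pts_like()` runs the same four checks on any candidate cassette.

Knockout templates copy `arm_len` bases (default 50 per side) of locus
sequence flanking the cleavage site and insert the PTS at the cut — i.e.
the cassette written into 100 bp of locus sequence centered on the cut.
Point-mutation oligos default to 100-nt arms (200 bases of flanking
homology centered on the cleavage site); the alternative reading of
"200 bases of homology" as 200 per side remains available through
`arm_len`. The template panel (`template_panel()`) emits sense, antisense,
duplex, 5'-phosphorylated and 5'-phosphorothioate duplex, and
single-arm-truncated variants; the exact roster of truncated variants used
historically is not fully documented, so the roster and truncated arm
lengths are arguments with the 7-member default above. Chemical
modification flags are carried as annotations only — they never change
sequence computation. PAM-blocking silent mutations are not inserted
automatically; supply them as an explicit edit span.

## Amplicon quantification

The pipeline mirrors a standard Galaxy-tool chain (fastq-join → quality
filter → cutadapt → unique → collapse) as one auditable function:

1. **Merge** (`merge_pair`): best ungapped overlap between R1 and the
   reverse complement of R2; at least 20 nt of overlap with mismatch
   fraction ≤ 0.1. Among acceptable offsets the lowest mismatch fraction
   wins (ties: longer overlap). Disagreements resolve toward the
   higher-quality base and the merged quality is the per-base maximum —
   common joiner behavior; the exact historical tool settings are not
   recoverable, so these choices are logged per run.
2. **Quality filter**: every base at Phred ≥ 30 (fraction configurable).
3. **UMI extraction**: the randomized 6-mer sits in the forward primer, so
   it is read as the first `umi_len` bases of the merged amplicon; the
   offset is configurable because the exact primer layout varies.
4. **Flank matching**: both 50-nt locus flanks must be located by
   semi-global alignment (flank end-to-end, free endpoints in the read)
   with edits/flank-length ≤ 0.1, substitutions and indels both counted —
   cutadapt's error-rate semantics. Reads failing any of steps 1–4 are
   *reported* as rejected, never silently dropped: every input pair ends in
   exactly one disposition bin.
5. **Deduplication**: records collapse on the (UMI, sequence) pair.
   Collapsing on the barcode alone would cap a run at 4096 reads, which is
   inconsistent with how such runs are actually analyzed; collapsing on the
   pair removes PCR duplicates while keeping distinct molecules that share
   a barcode but differ in sequence.
6. **Classification**, in precedence order: templated PTS insertion (PTS
   located anywhere with ≤ `pts_max_mismatch` edits; default 2, mirroring
   the manual practice of counting PTS-with-mutation reads as templated;
   0 recovers the strict substring rule), then untemplated indel (length
   differs from the reference by > 1 bp), then exact reference, then SNP
   (same length, ≥ 1 mismatch). Length differences of exactly 1 bp are
   unassigned by the published > 1 bp rule, so they are reported as
   `AMBIGUOUS_1BP` and excluded from both mutation frequencies.
7. **Summary**: per-class percentages over unique bins, with the limit of
   detection `100/4^umi_len` percent (0.0244% ≈ 0.02% at 6 nt).

**What the unique-read estimator can and cannot do.** Frequencies are
computed over unique (UMI, sequence) bins. When the number of true
molecules is well below the barcode space, bins ≈ molecules and the
estimator is unbiased. When molecules approach or exceed 4096, all
exact-reference molecules collapse into at most 4096 bins while rarer
classes keep gaining bins, so mutation frequencies are *overestimated* —
and with realistic per-base error, singleton error reads add SNP bins on
top. This is a property of the published counting scheme, not of this
implementation. It is why one acceptance test (recovering 1.5% templated
frequency from 50,000 molecules within 3σ binomial bounds) is deliberately
left failing: the companion test shows the same pipeline recovering the
same frequencies correctly at 1000 error-free molecules, and the identity
test shows bin-for-bin agreement with an independent collapse of the
simulation truth table. A green 50,000-molecule recovery would require
either discarding the unique-read rule or tuning the simulator away from
honest UMI collisions.

## The simulator

`simulate_amplicon_run()` emulates the stated run geometry: a ~450-nt
reference amplicon around the cleavage site, 2 × 300 nt paired-end reads,
a 6-nt UMI on the forward end, ~100 molecules (≈ 300 read pairs at the
default geometric PCR duplication of mean 3). Default outcome frequencies
are 1.5% templated and 0.1% indel — the upper end of the realistic range
for RNP editing in this system — with indel sizes uniform on 2–10 bp (the
published class is only "> 1 bp"; no size distribution is documented).
The per-molecule true-SNP rate defaults to 0 because the SNP class of real
runs is indistinguishable from PCR/sequencing error, which the quality
model already produces. UMIs are drawn uniformly over 4^6 with honest
collisions. Base-calling draws a per-base Phred from a clamped normal
(mean 36, sd 1) and injects errors at exactly `10^(-Q/10)`, so emitted
qualities and error rates are consistent by construction; `inject_errors =
FALSE` gives Q40 error-free reads for identity tests.

What the simulator does *not* model: adapter read-through (inserts shorter
than the read), quality decay along the cycle, indel sequencing errors,
chimeric PCR products, and sample cross-contamination. A green end-to-end
test therefore establishes correct bookkeeping and classification under
honest substitution noise, not robustness to every MiSeq artifact.

`simulate_locus()` plants a fixed, motif-perfect, unstructured plus-strand
protospacer (last spacer bases `ACTGA`, PAM `GGG`, 3' base `A`) at a
recorded position with ≥ 60 nt margins; the plant is AT-rich and is
inserted verbatim even at extreme GC settings, which is documented
behavior rather than an error.

## Growth and dilution statistics

The logistic model is used exactly as printed in its source context:
$P_t = K P_0 / ((K - P_0) e^{-t/T} + P_0)$ with carrying capacity $K$ and
initial density $P_0$ in cells/ml and time constant $T$ in hours. $T$ is
the e-folding constant of early exponential growth; bench usage often
labels it "doubling time", though the literal early-phase doubling time is
$T \ln 2$ — the fit reports $T$ as defined by the formula and this caveat
travels with the documentation.

Fitting minimizes the sum of absolute deviations (robust to the occasional
wild hemocytometer count) on raw densities by default — the literal
reading of "least absolute deviation" — with a log-space option off by
default. The optimizer is derivative-free Nelder–Mead over
$(\log K, \log P_0, \log T)$ with a heuristic start ($P_0$ = first
observation, $K$ = maximum, $T$ = half-saturation time over
$\ln((K-P_0)/P_0)$) plus 31 perturbed restarts, deterministic given a
seed; relative objective tolerance $10^{-10}$ with a final polish at
$10^{-12}$. Noiseless recovery to < 1% and noisy ($CV = 20\%$) recovery of
$T$ to < 15% are verified in the test suite. Degenerate (constant) series
fit with a warning rather than an error.

Dose-inhibition data are fit with a three-parameter Hill decay
$\mathrm{top} / (1 + (c/\mathrm{IC50})^{h})$ by least squares; the
functional form is an explicit substitute (none is documented for the
source experiment) and is labelled as such in the fit metadata.

For limiting dilution, 3 cells/ml dispensed at 100 µl/well gives a Poisson
mean of $\lambda = 0.3$ cells/well. The probability that an *occupied*
well was founded by a single cell is $\lambda e^{-\lambda}/(1 -
e^{-\lambda})$, which is 0.8575 at $\lambda = 0.3$ (with $P(N \ge 2) =
0.0369$). Protocols sometimes quote "> 99%" for this design; no standard
Poisson quantity at $\lambda = 0.3$ equals that figure, so the function
reports the standard quantities ($P(N=1 \mid N \ge 1)$, $P(N \le 1)$,
$P(N \ge 2)$) and the documentation flags the discrepancy instead of
reproducing the claim.

## Numerical and interface choices

* Coordinates: 0-based half-open internally, 1-based inclusive in every
  user-facing table; cleavage positions are insertion points.
* FASTQ: Sanger Phred+33 only; quality characters outside `!`–`~` are
  format errors. FASTA records may contain N; designed outputs never do;
  ambiguity codes beyond N are rejected in sequence files and allowed only
  in motif patterns.
* Dedup bins are sorted by descending count then key; guide and template
  tables have stated total orderings — all outputs are byte-reproducible
  for a fixed seed and configuration (the CLI writes its resolved
  configuration next to every output).
* Heavy inner loops (read merging, semi-global location, base-calling) are
  in C++ via Rcpp; the R-level oracles in the test suite (Biostrings
  `pairwiseAlignment`, exhaustive enumerations) keep every C++ kernel
  checked by an independent route.

## Known limitations

* The bundled folding estimator scores simple hairpins only and its GU
  stack values are approximate; for production guide picking against a
  full thermodynamic model, plug in an external backend.
* `merge_pair` assumes the insert is at least as long as each read.
* The flank matcher reports the best location per flank; amplicons with
  duplicated flank sequence inside the insert would need locus-specific
  flanks rather than the reference ends.
* Off-target genome-wide guide scoring is intentionally out of scope (RNP
  delivery limits exposure, and no off-target algorithm is part of the
  source methodology); so are BAM/SAM input and Illumina demultiplexing.
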