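# Bundled nearest-neighbor parameter set for the hairpin-only RNA folding
# estimator used to filter guide targeting sequences.
#
# The guide filter only needs a conservative estimate of whether the 20-nt
# targeting sequence can fold back on itself into a stable hairpin (which
# impedes hybridization with the DNA target), so the bundled model scores
# simple hairpins only: one helix of consecutively stacked base pairs closed
# by a terminal loop of >= 3 nt. Watson-Crick stack free energies are the
# standard Turner 2004 DeltaG(37 C) values (kcal/mol); GU-wobble stacks are
# rounded literature values of the same family. Hairpin-loop initiation
# penalties are the Turner 3-9 nt table with a logarithmic Jacobson-Stockmayer
# extension above 9. An external folding backend (e.g. ViennaRNA) can replace
# this estimator via the `backend` argument of predict_fold_dg().

.FOLD_PAIRS <- c("AU", "UA", "CG", "GC", "GU", "UG")

.build_stack_table <- function() {
  m <- matrix(NA_real_, 6, 6, dimnames = list(.FOLD_PAIRS, .FOLD_PAIRS))
  set <- function(p1, p2, dg) m[p1, p2] <<- dg
  # Watson-Crick / Watson-Crick (Turner 2004).  Row = closing pair (i, j),
  # column = stacked pair (i + 1, j - 1); labels read (5' base, 3' base).
  set("AU", "AU", -0.93); set("AU", "UA", -1.10); set("AU", "CG", -2.24)
  set("AU", "GC", -2.08); set("UA", "AU", -1.33); set("UA", "UA", -0.93)
  set("UA", "CG", -2.35); set("UA", "GC", -2.11); set("CG", "AU", -2.11)
  set("CG", "UA", -2.08); set("CG", "CG", -3.26); set("CG", "GC", -2.36)
  set("GC", "AU", -2.35); set("GC", "UA", -2.24); set("GC", "CG", -3.42)
  set("GC", "GC", -3.26)
  # GU wobble stacks (approximate Turner-family values).
  set("AU", "GU", -0.55); set("AU", "UG", -1.36)
  set("UA", "GU", -1.00); set("UA", "UG", -1.27)
  set("CG", "GU", -1.41); set("CG", "UG", -2.11)
  set("GC", "GU", -1.53); set("GC", "UG", -2.51)
  set("GU", "AU", -1.27); set("GU", "UA", -1.36); set("GU", "CG", -2.51)
  set("GU", "GC", -2.11); set("GU", "GU", -0.50); set("GU", "UG", +1.29)
  set("UG", "AU", -1.00); set("UG", "UA", -0.55); set("UG", "CG", -1.53)
  set("UG", "GC", -1.41); set("UG", "GU", +0.30); set("UG", "UG", -0.50)
  m
}

.build_hairpin_loops <- function(max_loop = 30L) {
  base <- c(NA, NA, 5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4)  # loop sizes 1..9
  out <- numeric(max_loop)
  out[seq_along(base)] <- base
  for (n in 10:max_loop) out[n] <- 6.4 + 1.75 * 0.001987 * 310.15 * log(n / 9)
  out  # out[n] = initiation DeltaG for a loop of n unpaired nt; n < 3 unusable
}

.FOLD_STACKS <- .build_stack_table()
.FOLD_LOOPS <- .build_hairpin_loops()

#' Bundled hairpin folding parameters
#'
#' Returns the nearest-neighbor parameter tables used by the bundled
#' hairpin-only folding estimator: the 6x6 stack free-energy matrix over
#' pairs AU/UA/CG/GC/GU/UG (row = closing pair at (i, j), column = pair
#' stacked at (i+1, j-1), kcal/mol at 37 C) and the hairpin-loop initiation
#' penalty indexed by loop length in nt (loops shorter than 3 are
#' disallowed). Exposed so that independent reimplementations (e.g. the
#' exhaustive-enumeration oracle in the test suite) can share the parameters
#' while exercising a different algorithm.
#'
#' @return list with elements `stacks` (matrix) and `hairpin_loop` (numeric
#'   vector, `hairpin_loop[n]` = penalty for an n-nt loop).
#' @export
fold_params <- function() {
  list(stacks = .FOLD_STACKS, hairpin_loop = .FOLD_LOOPS)
}

# Pair label for RNA bases a, b (e.g. "A","U" -> "AU"), or NA if not pairable.
.pair_label <- function(a, b) {
  p <- paste0(a, b)
  ifelse(p %in% .FOLD_PAIRS, p, NA_character_)
}
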