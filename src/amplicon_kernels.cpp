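// Inner loops of the amplicon pipeline: paired-end read merging by best
// ungapped overlap, semi-global (pattern-global, text-local) edit-distance
// location, and quality-string scans. Kept in C++ because a MiSeq-scale run
// is ~1e5 read pairs.

#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'N': return 'N';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (auto& c : out) c = comp(c);
  return out;
}

// Merge read pairs by the best ungapped overlap between R1 and the reverse
// complement of R2 (R2 given in sequencing orientation). The rc(R2) start is
// slid to offsets d = 0 .. len1 - min_overlap within R1; the candidate with
// the lowest mismatch fraction wins (ties: longer overlap, then smaller d).
// Disagreements resolve toward the higher-quality base (tie: R1); merged
// quality is the max of the two. Assumes the insert is at least as long as
// each read (no adapter read-through).
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector r1_seq, CharacterVector r1_qual,
                     CharacterVector r2_seq, CharacterVector r2_qual,
                     int min_overlap, double max_mismatch_frac) {
  int n = r1_seq.size();
  CharacterVector mseq(n), mqual(n);
  LogicalVector merged(n);
  IntegerVector overlap_len(n), mismatches(n);
  for (int i = 0; i < n; ++i) {
    std::string s1 = as<std::string>(r1_seq[i]);
    std::string q1 = as<std::string>(r1_qual[i]);
    std::string s2 = revcomp(as<std::string>(r2_seq[i]));
    std::string q2 = as<std::string>(r2_qual[i]);
    std::reverse(q2.begin(), q2.end());
    int L1 = s1.size(), L2 = s2.size();
    int best_d = -1, best_ov = 0, best_mm = 0;
    double best_frac = 2.0;
    for (int d = 0; d + min_overlap <= L1; ++d) {
      int ov = std::min(L1 - d, L2);
      if (ov < min_overlap) break;
      int allowed = (int)std::floor(max_mismatch_frac * ov + 1e-9);
      int mm = 0;
      bool ok = true;
      for (int k = 0; k < ov; ++k) {
        if (s1[d + k] != s2[k]) {
          if (++mm > allowed) { ok = false; break; }
        }
      }
      if (!ok) continue;
      double frac = (double)mm / ov;
      if (frac < best_frac - 1e-12 ||
          (std::abs(frac - best_frac) <= 1e-12 && ov > best_ov)) {
        best_frac = frac; best_d = d; best_ov = ov; best_mm = mm;
      }
    }
    if (best_d < 0) {
      merged[i] = false;
      mseq[i] = NA_STRING; mqual[i] = NA_STRING;
      overlap_len[i] = 0; mismatches[i] = NA_INTEGER;
      continue;
    }
    int d = best_d, ov = best_ov;
    int total = std::max(L1, d + L2);
    std::string out_s(total, 'N'), out_q(total, '!');
    for (int k = 0; k < d; ++k) { out_s[k] = s1[k]; out_q[k] = q1[k]; }
    for (int k = 0; k < ov; ++k) {
      char b1 = s1[d + k], b2 = s2[k];
      char c1 = q1[d + k], c2 = q2[k];
      char q = std::max(c1, c2);
      char b = (b1 == b2) ? b1 : (c2 > c1 ? b2 : b1);
      out_s[d + k] = b; out_q[d + k] = q;
    }
    for (int k = ov; k < L2; ++k) { out_s[d + k] = s2[k]; out_q[d + k] = q2[k]; }
    for (int k = d + L2; k < L1; ++k) { out_s[k] = s1[k]; out_q[k] = q1[k]; }
    merged[i] = true;
    mseq[i] = out_s; mqual[i] = out_q;
    overlap_len[i] = ov; mismatches[i] = best_mm;
  }
  return List::create(_["merged"] = merged, _["seq"] = mseq, _["qual"] = mqual,
                      _["overlap"] = overlap_len, _["mismatches"] = mismatches);
}

// Semi-global alignment: pattern aligned end-to-end, free start/end in the
// text (unit costs for substitution/insertion/deletion). Returns, per text,
// the minimal edit distance and the 1-based [start, end] of the best match
// (ties broken toward the leftmost end, then the longest match).
// [[Rcpp::export]]
IntegerMatrix cpp_semiglobal_locate(std::string pattern, CharacterVector texts) {
  int m = pattern.size();
  int n_tx = texts.size();
  IntegerMatrix out(n_tx, 3);
  colnames(out) = CharacterVector::create("edits", "start", "end");
  std::vector<int> prev(m + 1), curr(m + 1);
  std::vector<int> oprev(m + 1), ocurr(m + 1);
  for (int t = 0; t < n_tx; ++t) {
    std::string text = as<std::string>(texts[t]);
    int n = text.size();
    // column j = 0: aligning pattern prefix against nothing
    for (int i = 0; i <= m; ++i) { prev[i] = i; oprev[i] = 0; }
    int best = prev[m], best_end = 0, best_start = 0;
    for (int j = 1; j <= n; ++j) {
      curr[0] = 0; ocurr[0] = j;  // free start in text
      for (int i = 1; i <= m; ++i) {
        int sub = prev[i - 1] + (pattern[i - 1] == text[j - 1] ? 0 : 1);
        int del = prev[i] + 1;   // consume text char (gap in pattern)
        int ins = curr[i - 1] + 1;  // consume pattern char (gap in text)
        int v = sub, o = oprev[i - 1];
        if (del < v) { v = del; o = oprev[i]; }
        if (ins < v) { v = ins; o = ocurr[i - 1]; }
        curr[i] = v; ocurr[i] = o;
      }
      if (curr[m] < best) { best = curr[m]; best_end = j; best_start = ocurr[m]; }
      std::swap(prev, curr); std::swap(oprev, ocurr);
    }
    out(t, 0) = best;
    out(t, 1) = best_start + 1;  // 1-based first text position of the match
    out(t, 2) = best_end;        // 1-based last text position
  }
  return out;
}

// Fraction of bases with Phred >= min_q, per Phred+33 quality string.
// [[Rcpp::export]]
NumericVector cpp_qual_fraction_ge(CharacterVector quals, int min_q) {
  int n = quals.size();
  NumericVector out(n);
  char thr = (char)(min_q + 33);
  for (int i = 0; i < n; ++i) {
    std::string q = as<std::string>(quals[i]);
    if (q.empty()) { out[i] = 0.0; continue; }
    int ok = 0;
    for (char c : q) if (c >= thr) ++ok;
    out[i] = (double)ok / q.size();
  }
  return out;
}

// Base-calling with per-base Phred draws from a clamped normal profile and
// error injection at probability 10^(-Q/10), using R's RNG so runs are
// reproducible under a set seed. Returns called sequences and Phred+33
// quality strings.
// [[Rcpp::export]]
List cpp_call_reads(CharacterVector seqs, double q_mean, double q_sd) {
  int n = seqs.size();
  CharacterVector out_s(n), out_q(n);
  const char* bases = "ACGT";
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string q(s.size(), '!');
    for (size_t k = 0; k < s.size(); ++k) {
      int qq = (int)std::lround(R::rnorm(q_mean, q_sd));
      if (qq < 2) qq = 2;
      if (qq > 41) qq = 41;
      q[k] = (char)(qq + 33);
      if (unif_rand() < std::pow(10.0, -qq / 10.0)) {
        char cur = s[k];
        char nb;
        do { nb = bases[(int)(unif_rand() * 4) & 3]; } while (nb == cur);
        s[k] = nb;
      }
    }
    out_s[i] = s; out_q[i] = q;
  }
  return List::create(_["seq"] = out_s, _["qual"] = out_q);
}
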