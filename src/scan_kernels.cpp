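#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Watson-Crick complement; anything non-ACGT complements to 0 (never matches).
static inline char wc(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 0;
  }
}

static inline bool is_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// Stem-loop scan: for every candidate loop (start, length) extend the paired
// arms outward greedily under the mismatch budget, trim trailing mismatches,
// and keep arms that are maximal (not extendable inward, i.e. the loop's two
// end bases do not pair while a >= min_loop loop would remain).
// [[Rcpp::export(name = ".cpp_find_hairpins")]]
DataFrame cpp_find_hairpins(std::string seq, int min_stem, int max_stem,
                            int min_loop, int max_loop, int max_mismatch) {
  const int n = (int) seq.size();
  std::vector<int> gs, ge, sl, ls, le, mm_out;
  std::vector<std::string> stem_seq, loop_seq;

  for (int l = 0; l < n; ++l) {          // loop start (0-based)
    for (int L = min_loop; L <= max_loop; ++L) {
      int loop_end = l + L - 1;           // inclusive
      if (loop_end + 1 >= n || l == 0) {
        if (l == 0) break; else continue;
      }
      // greedy outward extension
      int i = l - 1, j = loop_end + 1, k = 0, mm = 0;
      std::vector<bool> matched;
      while (k < max_stem && i >= 0 && j < n) {
        char a = seq[(size_t) i], b = seq[(size_t) j];
        if (is_base(a) && wc(a) == b) {
          matched.push_back(true);
          ++k; --i; ++j;
        } else if (mm < max_mismatch && is_base(a) && is_base(b)) {
          matched.push_back(false);
          ++mm; ++k; --i; ++j;
        } else break;
      }
      // a stem must not end on a mismatched pair
      while (k > 0 && !matched[(size_t) (k - 1)]) {
        if (!matched[(size_t) (k - 1)]) --mm;
        --k;
      }
      if (k < min_stem) continue;
      // inward maximality: arms extendable into the loop => nested candidate
      if (L - 2 >= min_loop) {
        char a = seq[(size_t) l], b = seq[(size_t) loop_end];
        if (is_base(a) && wc(a) == b) continue;
      }
      int start = l - k, end = loop_end + k;   // 0-based inclusive
      gs.push_back(start + 1);
      ge.push_back(end + 1);
      sl.push_back(k);
      ls.push_back(l + 1);
      le.push_back(loop_end + 1);
      mm_out.push_back(mm);
      stem_seq.push_back(seq.substr((size_t) start, (size_t) k));
      loop_seq.push_back(seq.substr((size_t) l, (size_t) L));
    }
  }
  return DataFrame::create(
    _["genome_start"] = gs, _["genome_end"] = ge, _["stem_len"] = sl,
    _["loop_start"] = ls, _["loop_end"] = le,
    _["stem_seq"] = stem_seq, _["loop_seq"] = loop_seq,
    _["mismatches_in_stem"] = mm_out,
    _["stringsAsFactors"] = false);
}

// Perfect tandem-repeat scan.  For each unit length u the predicate
// s[i] == s[i-u] is run-length scanned; each maximal run yields at most one
// locus (leftmost full-copy window), reported only for primitive units.
// [[Rcpp::export(name = ".cpp_scan_ssrs")]]
DataFrame cpp_scan_ssrs(std::string seq, IntegerVector min_copies) {
  const int n = (int) seq.size();
  const int max_u = min_copies.size();
  std::vector<int> start, end, unit_len, copies;
  std::vector<std::string> unit;

  for (int u = 1; u <= max_u; ++u) {
    int run = 0;
    for (int i = u; i <= n; ++i) {
      bool ok = i < n && is_base(seq[(size_t) i]) &&
        is_base(seq[(size_t) (i - u)]) && seq[(size_t) i] == seq[(size_t) (i - u)];
      if (ok) { ++run; continue; }
      if (run > 0) {
        int b = i - 1;                 // last matching index
        int a0 = b - run + 1 - u;      // start of the repeated stretch
        int stretch = run + u;
        int cp = stretch / u;
        if (cp >= min_copies[u - 1]) {
          std::string un = seq.substr((size_t) a0, (size_t) u);
          bool primitive = true;
          for (int d = 1; d < u; ++d) {
            if (u % d != 0) continue;
            bool per = true;
            for (int t = d; t < u; ++t)
              if (un[(size_t) t] != un[(size_t) (t - d)]) { per = false; break; }
            if (per) { primitive = false; break; }
          }
          if (primitive) {
            start.push_back(a0 + 1);
            end.push_back(a0 + cp * u);
            unit_len.push_back(u);
            copies.push_back(cp);
            unit.push_back(un);
          }
        }
        run = 0;
      }
    }
  }
  return DataFrame::create(
    _["start"] = start, _["end"] = end, _["unit_len"] = unit_len,
    _["copies"] = copies, _["unit"] = unit,
    _["stringsAsFactors"] = false);
}

static inline int base2bits(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  default:  return -1;
  }
}

// All maximal common substrings of X and Y with length >= min_len, found by
// k-mer seeding plus ungapped extension; per-diagonal bookkeeping keeps the
// scan near-linear on repeat-rich input.  Coordinates are 1-based.
// [[Rcpp::export(name = ".cpp_common_substrings")]]
DataFrame cpp_common_substrings(std::string x, std::string y, int min_len) {
  const int nx = (int) x.size(), ny = (int) y.size();
  std::vector<int> xs, ys, ln;
  int k = min_len < 20 ? min_len : 20;
  if (k < 1 || nx < k || ny < k)
    return DataFrame::create(_["x_start"] = xs, _["y_start"] = ys, _["len"] = ln);

  std::unordered_map<uint64_t, std::vector<int> > seeds;
  seeds.reserve((size_t) ny);
  for (int j = 0; j + k <= ny; ++j) {
    uint64_t h = 0; bool ok = true;
    for (int t = 0; t < k; ++t) {
      int b = base2bits(y[(size_t) (j + t)]);
      if (b < 0) { ok = false; break; }
      h = (h << 2) | (uint64_t) b;
    }
    if (ok) seeds[h].push_back(j);
  }

  std::unordered_map<long long, int> diag_end;  // diagonal (i - j) -> covered end i
  for (int i = 0; i + k <= nx; ++i) {
    uint64_t h = 0; bool ok = true;
    for (int t = 0; t < k; ++t) {
      int b = base2bits(x[(size_t) (i + t)]);
      if (b < 0) { ok = false; break; }
      h = (h << 2) | (uint64_t) b;
    }
    if (!ok) continue;
    auto it = seeds.find(h);
    if (it == seeds.end()) continue;
    for (int j : it->second) {
      long long d = (long long) i - (long long) j;
      auto de = diag_end.find(d);
      if (de != diag_end.end() && de->second >= i) continue;  // inside known match
      int i0 = i, j0 = j;
      while (i0 > 0 && j0 > 0 && x[(size_t) (i0 - 1)] == y[(size_t) (j0 - 1)] &&
             is_base(x[(size_t) (i0 - 1)])) { --i0; --j0; }
      int i1 = i + k - 1, j1 = j + k - 1;
      while (i1 + 1 < nx && j1 + 1 < ny &&
             x[(size_t) (i1 + 1)] == y[(size_t) (j1 + 1)] &&
             is_base(x[(size_t) (i1 + 1)])) { ++i1; ++j1; }
      int len = i1 - i0 + 1;
      diag_end[d] = i1;
      if (len >= min_len) {
        xs.push_back(i0 + 1); ys.push_back(j0 + 1); ln.push_back(len);
      }
    }
  }
  return DataFrame::create(_["x_start"] = xs, _["y_start"] = ys, _["len"] = ln);
}
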