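// Core string machinery: maximal-repetition (run) enumeration, greedy
// single-edit extension into approximate STR occurrences, and the canonical
// repeat-unit algebra (primitive root + minimum over rotations and
// reverse-complement rotations, alphabet order A < C < G < T).
//
// Coordinates are 0-based half-open throughout this file.

#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
  }
  return 'N';
}

static std::string upperize(std::string s) {
  for (char& c : s)
    if (c >= 'a' && c <= 'z') c = (char)(c - 'a' + 'A');
  return s;
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) c = comp_base(c);
  return r;
}

// Shortest prefix p of u such that u = p^k (primitive root).
static std::string primitive_root(const std::string& u) {
  const int n = (int)u.size();
  for (int d = 1; d <= n / 2; ++d) {
    if (n % d != 0) continue;
    bool ok = true;
    for (int i = d; i < n; ++i)
      if (u[i] != u[i - d]) { ok = false; break; }
    if (ok) return u.substr(0, d);
  }
  return u;
}

// Representative form: primitive root first, then lexicographic minimum over
// all rotations of the root and of its reverse complement.
static std::string canonical_str(const std::string& u0) {
  const std::string u = primitive_root(u0);
  const std::string rc = revcomp_str(u);
  const int n = (int)u.size();
  std::string best = u;
  for (int r = 0; r < n; ++r) {
    std::string a = u.substr(r) + u.substr(0, r);
    if (a < best) best = a;
    std::string b = rc.substr(r) + rc.substr(0, r);
    if (b < best) best = b;
  }
  return best;
}

static void validate_acgt(const std::string& s, const char* what) {
  if (s.empty()) stop("%s must be a non-empty ACGT string", what);
  for (char c : s)
    if (!is_acgt(c))
      stop("%s contains a non-ACGT character ('%c')", what, c);
}

// ---------------------------------------------------------------------------
// Maximal repetitions (runs): maximal periodicities with minimal period p and
// exponent >= 2, reported with their primitive unit seq[start, start + p).

struct Run {
  int start, end, period;
};

// Period-anchor enumeration within the ACGT block [lo, hi).  For each period
// p, anchors are spaced p apart; any run of exponent >= 2 contains two
// consecutive anchors (a, a + p), from which forward/backward longest common
// extensions recover the full run.  Duplicate spans keep the smallest period
// (a span maximal under p is maximal under its minimal period, which divides
// p, so the minimal-period candidate is always generated).
static void runs_in_block(const std::string& s, int lo, int hi,
                          std::vector<Run>& out) {
  const int n = hi - lo;
  if (n < 2) return;
  std::map<std::pair<int, int>, int> best;
  for (int p = 1; p <= n / 2; ++p) {
    for (int a = lo; a + p < hi; a += p) {
      const int b = a + p;
      int f = 0;
      while (b + f < hi && s[a + f] == s[b + f]) ++f;
      int g = 0;
      while (a - 1 - g >= lo && s[a - 1 - g] == s[b - 1 - g]) ++g;
      if (f + g >= p) {
        const std::pair<int, int> key(a - g, b + f);
        std::map<std::pair<int, int>, int>::iterator it = best.find(key);
        if (it == best.end() || p < it->second) best[key] = p;
      }
    }
  }
  for (std::map<std::pair<int, int>, int>::iterator it = best.begin();
       it != best.end(); ++it) {
    Run r;
    r.start = it->first.first;
    r.end = it->first.second;
    r.period = it->second;
    out.push_back(r);
  }
}

// Direct-from-definition O(n^3) enumerator (testing oracle): for every span,
// compute the minimal period by scanning, then test exponent and maximality.
static void runs_in_block_brute(const std::string& s, int lo, int hi,
                                std::vector<Run>& out) {
  for (int l = lo; l < hi; ++l) {
    for (int r = l + 2; r <= hi; ++r) {
      const int len = r - l;
      int p = 0;
      for (int q = 1; q < len; ++q) {
        bool ok = true;
        for (int i = l; i + q < r; ++i)
          if (s[i] != s[i + q]) { ok = false; break; }
        if (ok) { p = q; break; }
      }
      if (p == 0 || len < 2 * p) continue;
      if (l - 1 >= lo && s[l - 1] == s[l - 1 + p]) continue;
      if (r < hi && s[r] == s[r - p]) continue;
      Run run;
      run.start = l;
      run.end = r;
      run.period = p;
      out.push_back(run);
    }
  }
}

static std::vector<std::pair<int, int> > acgt_blocks(const std::string& s) {
  std::vector<std::pair<int, int> > b;
  const int n = (int)s.size();
  int i = 0;
  while (i < n) {
    if (!is_acgt(s[i])) { ++i; continue; }
    int j = i;
    while (j < n && is_acgt(s[j])) ++j;
    b.push_back(std::make_pair(i, j));
    i = j;
  }
  return b;
}

static std::vector<Run> all_runs(const std::string& s, bool brute) {
  std::vector<Run> runs;
  std::vector<std::pair<int, int> > blocks = acgt_blocks(s);
  for (size_t k = 0; k < blocks.size(); ++k) {
    if (brute)
      runs_in_block_brute(s, blocks[k].first, blocks[k].second, runs);
    else
      runs_in_block(s, blocks[k].first, blocks[k].second, runs);
  }
  return runs;
}

struct RunLess {
  const std::string* s;
  bool operator()(const Run& a, const Run& b) const {
    if (a.start != b.start) return a.start < b.start;
    if (a.end != b.end) return a.end < b.end;
    return s->compare(a.start, a.period, *s, b.start, b.period) < 0;
  }
};

// [[Rcpp::export]]
DataFrame cpp_maximal_repetitions(std::string seq, bool brute) {
  seq = upperize(seq);
  std::vector<Run> runs = all_runs(seq, brute);
  RunLess cmp;
  cmp.s = &seq;
  std::sort(runs.begin(), runs.end(), cmp);
  const int m = (int)runs.size();
  IntegerVector start(m), end(m);
  CharacterVector unit(m);
  for (int i = 0; i < m; ++i) {
    start[i] = runs[i].start;
    end[i] = runs[i].end;
    unit[i] = seq.substr(runs[i].start, runs[i].period);
  }
  return DataFrame::create(_["start"] = start, _["end"] = end,
                           _["unit"] = unit,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Greedy single-edit extension (approximate repetition).  The alignment with
// the periodic continuation of the unit must decompose into exact blocks of
// length >= |unit| separated by single edits; an edit is accepted only when
// followed outward by >= |unit| exact periodic bases.  Edit preference:
// mismatch > deletion > insertion.  Left boundary is extended to exhaustion
// first, then the right.  The phase of the periodic continuation is fixed by
// the seed frame; indel edits shift it.

static inline int posmod(int x, int p) {
  int m = x % p;
  return m < 0 ? m + p : m;
}

struct Ext {
  int start, end, mm, ins, del;
};

static Ext extend_in_block(const std::string& s, int lo, int hi, int st,
                           int en, const std::string& unit) {
  const int p = (int)unit.size();
  Ext e;
  e.start = st;
  e.end = en;
  e.mm = e.ins = e.del = 0;
  // read-base / pattern-base consumption per edit type:
  // mismatch consumes both, deletion consumes pattern only, insertion read only
  static const int DR[3] = {1, 0, 1};
  static const int DE[3] = {1, 1, 0};

  // left, to exhaustion
  {
    int lp = st, ep = -1;  // next comparison: s[lp-1] vs unit[posmod(ep, p)]
    for (;;) {
      while (lp - 1 >= lo && s[lp - 1] == unit[posmod(ep, p)]) { --lp; --ep; }
      if (lp <= lo) break;
      bool accepted = false;
      for (int k = 0; k < 3 && !accepted; ++k) {
        const int lp2 = lp - DR[k], ep2 = ep - DE[k];
        if (lp2 < lo) continue;
        int m = 0;
        while (m < p && lp2 - 1 - m >= lo &&
               s[lp2 - 1 - m] == unit[posmod(ep2 - m, p)])
          ++m;
        if (m >= p) {
          if (k == 0) ++e.mm; else if (k == 1) ++e.del; else ++e.ins;
          lp = lp2;
          ep = ep2;
          accepted = true;
        }
      }
      if (!accepted) break;
    }
    e.start = lp;
  }

  // right
  {
    int rp = en, ep = en - st;  // next comparison: s[rp] vs unit[posmod(ep, p)]
    for (;;) {
      while (rp < hi && s[rp] == unit[posmod(ep, p)]) { ++rp; ++ep; }
      if (rp >= hi) break;
      bool accepted = false;
      for (int k = 0; k < 3 && !accepted; ++k) {
        const int rp2 = rp + DR[k], ep2 = ep + DE[k];
        if (rp2 > hi) continue;
        int m = 0;
        while (m < p && rp2 + m < hi && s[rp2 + m] == unit[posmod(ep2 + m, p)])
          ++m;
        if (m >= p) {
          if (k == 0) ++e.mm; else if (k == 1) ++e.del; else ++e.ins;
          rp = rp2;
          ep = ep2;
          accepted = true;
        }
      }
      if (!accepted) break;
    }
    e.end = rp;
  }
  return e;
}

// [[Rcpp::export]]
List cpp_extend(std::string seq, int start, int end, std::string unit) {
  seq = upperize(seq);
  unit = upperize(unit);
  validate_acgt(unit, "unit");
  const int n = (int)seq.size();
  const int p = (int)unit.size();
  if (start < 0 || end > n || end - start < 2 * p)
    stop("seed repetition [start, end) must lie in seq and span >= 2 units");
  for (int i = start; i < end; ++i) {
    if (!is_acgt(seq[i]))
      stop("seed repetition contains a non-ACGT character");
    if (seq[i] != unit[(i - start) % p])
      stop("seed [start, end) is not an exact repetition of unit");
  }
  int lo = start, hi = end;
  while (lo - 1 >= 0 && is_acgt(seq[lo - 1])) --lo;
  while (hi < n && is_acgt(seq[hi])) ++hi;
  Ext e = extend_in_block(seq, lo, hi, start, end, unit);
  return List::create(_["start"] = e.start, _["end"] = e.end,
                      _["n_mismatch"] = e.mm, _["n_insertion"] = e.ins,
                      _["n_deletion"] = e.del,
                      _["n_mutations"] = e.mm + e.ins + e.del);
}

// ---------------------------------------------------------------------------
// Full per-read scan: runs -> unit-length filter -> extension -> canonical
// units -> same-unit overlap pruning (keep longest, ties leftmost) ->
// min_length filter.

struct Occ {
  int start, end, mm, ins, del;
  std::string canon, raw;
};

static void scan_one(const std::string& seq, int unit_min, int unit_max,
                     int min_length, std::vector<Occ>& kept) {
  std::vector<std::pair<int, int> > blocks = acgt_blocks(seq);
  std::vector<Occ> occs;
  for (size_t bi = 0; bi < blocks.size(); ++bi) {
    const int lo = blocks[bi].first, hi = blocks[bi].second;
    std::vector<Run> runs;
    runs_in_block(seq, lo, hi, runs);
    for (size_t ri = 0; ri < runs.size(); ++ri) {
      const Run& r = runs[ri];
      if (r.period < unit_min || r.period > unit_max) continue;
      const std::string raw = seq.substr(r.start, r.period);
      Ext e = extend_in_block(seq, lo, hi, r.start, r.end, raw);
      Occ o;
      o.start = e.start;
      o.end = e.end;
      o.mm = e.mm;
      o.ins = e.ins;
      o.del = e.del;
      o.raw = raw;
      o.canon = canonical_str(raw);
      occs.push_back(o);
    }
  }
  // prune same-canonical-unit overlaps: longest first, ties leftmost
  std::vector<int> idx(occs.size());
  for (size_t i = 0; i < occs.size(); ++i) idx[i] = (int)i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    const int la = occs[a].end - occs[a].start;
    const int lb = occs[b].end - occs[b].start;
    if (la != lb) return la > lb;
    if (occs[a].start != occs[b].start) return occs[a].start < occs[b].start;
    return occs[a].canon < occs[b].canon;
  });
  std::map<std::string, std::vector<std::pair<int, int> > > taken;
  for (size_t k = 0; k < idx.size(); ++k) {
    const Occ& o = occs[idx[k]];
    std::vector<std::pair<int, int> >& iv = taken[o.canon];
    bool clash = false;
    for (size_t j = 0; j < iv.size(); ++j)
      if (o.start < iv[j].second && iv[j].first < o.end) { clash = true; break; }
    if (clash) continue;
    iv.push_back(std::make_pair(o.start, o.end));
    const int want = (min_length > 0) ? min_length
                                      : 2 * (int)o.raw.size();
    if (o.end - o.start >= want) kept.push_back(o);
  }
  std::sort(kept.begin(), kept.end(), [](const Occ& a, const Occ& b) {
    if (a.start != b.start) return a.start < b.start;
    if (a.end != b.end) return a.end < b.end;
    return a.canon < b.canon;
  });
}

// [[Rcpp::export]]
DataFrame cpp_scan_reads(CharacterVector seqs, int unit_min, int unit_max,
                         int min_length) {
  std::vector<int> read_i;
  std::vector<int> start, end, mm, ins, del;
  std::vector<std::string> canon, raw;
  for (int i = 0; i < seqs.size(); ++i) {
    const std::string seq = upperize(as<std::string>(seqs[i]));
    std::vector<Occ> kept;
    scan_one(seq, unit_min, unit_max, min_length, kept);
    for (size_t k = 0; k < kept.size(); ++k) {
      read_i.push_back(i + 1);
      start.push_back(kept[k].start);
      end.push_back(kept[k].end);
      mm.push_back(kept[k].mm);
      ins.push_back(kept[k].ins);
      del.push_back(kept[k].del);
      canon.push_back(kept[k].canon);
      raw.push_back(kept[k].raw);
    }
  }
  return DataFrame::create(
      _["read"] = wrap(read_i), _["unit"] = wrap(canon),
      _["raw_unit"] = wrap(raw), _["start"] = wrap(start),
      _["end"] = wrap(end), _["n_mismatch"] = wrap(mm),
      _["n_insertion"] = wrap(ins), _["n_deletion"] = wrap(del),
      _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Canonical-unit algebra, vectorized.

// [[Rcpp::export]]
CharacterVector cpp_minimal_unit(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i) {
    std::string s = upperize(as<std::string>(x[i]));
    validate_acgt(s, "input");
    out[i] = primitive_root(s);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical_unit(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i) {
    std::string s = upperize(as<std::string>(x[i]));
    validate_acgt(s, "input");
    out[i] = canonical_str(s);
  }
  return out;
}

// One representative per equivalence class of primitive k-mers under rotation
// and reverse complement, with orbit sizes.
// [[Rcpp::export]]
DataFrame cpp_representative_units(int k) {
  if (k < 1 || k > 15) stop("k must be between 1 and 15");
  static const char B[4] = {'A', 'C', 'G', 'T'};
  const long long total = 1LL << (2 * k);
  std::map<std::string, int> cls;
  std::string s(k, 'A');
  for (long long code = 0; code < total; ++code) {
    long long c = code;
    for (int j = k - 1; j >= 0; --j) {
      s[j] = B[c & 3];
      c >>= 2;
    }
    if ((int)primitive_root(s).size() != k) continue;
    ++cls[canonical_str(s)];
  }
  const int m = (int)cls.size();
  CharacterVector unit(m);
  IntegerVector size(m);
  int i = 0;
  for (std::map<std::string, int>::iterator it = cls.begin(); it != cls.end();
       ++it, ++i) {
    unit[i] = it->first;
    size[i] = it->second;
  }
  return DataFrame::create(_["unit"] = unit, _["class_size"] = size,
                           _["stringsAsFactors"] = false);
}
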