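#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <string>
#include <vector>
#include <algorithm>
#include <cmath>
#include <chrono>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Sequence primitives on std::string over {A,C,G,T}
// ---------------------------------------------------------------------------

static inline int base_index(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static int max_run_str(const std::string& s) {
  if (s.empty()) return 0;
  int best = 1, cur = 1;
  for (size_t i = 1; i < s.size(); ++i) {
    if (s[i] == s[i - 1]) {
      if (++cur > best) best = cur;
    } else {
      cur = 1;
    }
  }
  return best;
}

static int lead_run_str(const std::string& s) {
  if (s.empty()) return 0;
  int r = 1;
  for (size_t i = 1; i < s.size() && s[i] == s[0]; ++i) ++r;
  return r;
}

static int trail_run_str(const std::string& s) {
  if (s.empty()) return 0;
  int r = 1;
  for (size_t i = s.size() - 1; i > 0 && s[i - 1] == s[i]; --i) ++r;
  return r;
}

static int gc_count_str(const std::string& s) {
  int g = 0;
  for (char c : s)
    if (c == 'G' || c == 'C') ++g;
  return g;
}

static bool has_blacklisted(const std::string& s,
                            const std::vector<std::string>& bl) {
  for (const auto& b : bl)
    if (!b.empty() && s.find(b) != std::string::npos) return true;
  return false;
}

// GC bounds are inclusive; counts are integers so compare against the exact
// rational bound with a tiny slack for the double multiply only.
static inline bool gc_ok(int gc, int len, double gc_min, double gc_max) {
  double g = (double)gc;
  return g >= gc_min * len - 1e-9 && g <= gc_max * len + 1e-9;
}

// 0 = pass, 1 = homopolymer, 2 = gc, 3 = blacklist (fixed evaluation order)
static int comp_code_str(const std::string& s, int m, double gc_min,
                         double gc_max, const std::vector<std::string>& bl) {
  if (max_run_str(s) > m) return 1;
  if (!gc_ok(gc_count_str(s), (int)s.size(), gc_min, gc_max)) return 2;
  if (has_blacklisted(s, bl)) return 3;
  return 0;
}

// ---------------------------------------------------------------------------
// Packed 2-bit representation for fast Hamming distance
// ---------------------------------------------------------------------------

typedef std::vector<uint64_t> packed_t;

static packed_t pack_seq(const std::string& s) {
  packed_t w((s.size() + 31) / 32, 0ULL);
  for (size_t i = 0; i < s.size(); ++i)
    w[i >> 5] |= (uint64_t)base_index(s[i]) << ((i & 31) << 1);
  return w;
}

static inline int packed_hamming(const packed_t& a, const packed_t& b) {
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    uint64_t v = a[i] ^ b[i];
    v = (v | (v >> 1)) & 0x5555555555555555ULL;
    d += __builtin_popcountll(v);
  }
  return d;
}

// ---------------------------------------------------------------------------
// Markov chain sequence generation (uses R's RNG for reproducibility)
// ---------------------------------------------------------------------------

static inline int unif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static std::string markov_seq(int len, double delta, int order_m) {
  std::string s;
  if (len <= 0) return s;
  s.reserve(len);
  s.push_back(BASES[unif_int(4)]);
  int run = 1;  // trailing-run length of the generated prefix
  for (int k = 1; k < len; ++k) {
    int h = std::min(run, order_m);  // run <= k already
    double p_rep = std::pow(delta, (double)h);
    char last = s.back();
    char next;
    if (unif_rand() < p_rep) {
      next = last;
    } else {
      int li = base_index(last);
      int j = unif_int(3);
      next = BASES[j < li ? j : j + 1];
    }
    run = (next == last) ? run + 1 : 1;
    s.push_back(next);
  }
  return s;
}

// first linker base: uniform over the 3 bases != last batch base;
// second: uniform over the 3 bases != first linker base.
static void append_linker(std::string& s) {
  int last = base_index(s.back());
  int j = unif_int(3);
  int l1 = j < last ? j : j + 1;
  s.push_back(BASES[l1]);
  j = unif_int(3);
  int l2 = j < l1 ? j : j + 1;
  s.push_back(BASES[l2]);
}

// ---------------------------------------------------------------------------
// Per-batch metadata for O(1) junction-aware composition checks
// ---------------------------------------------------------------------------

struct BatchMeta {
  int len, gc, trail, max_run;
  char last;
  std::string tail;  // last (max_bl - 1) characters, for junction blacklist
};

static std::vector<BatchMeta> make_batch_meta(
    const std::vector<std::string>& batches,
    const std::vector<std::string>& bl) {
  size_t max_bl = 0;
  for (const auto& b : bl) max_bl = std::max(max_bl, b.size());
  std::vector<BatchMeta> out;
  out.reserve(batches.size());
  for (const auto& b : batches) {
    BatchMeta m;
    m.len = (int)b.size();
    m.gc = gc_count_str(b);
    m.trail = trail_run_str(b);
    m.max_run = max_run_str(b);
    m.last = b.empty() ? 'N' : b.back();
    size_t k = max_bl > 1 ? std::min(b.size(), max_bl - 1) : 0;
    m.tail = b.substr(b.size() - k, k);
    out.push_back(m);
  }
  return out;
}

struct CandMeta {
  int len, gc, lead, max_run;
  char first;
  bool own_bl_hit;
  std::string head;  // first (max_bl - 1) characters
};

static CandMeta make_cand_meta(const std::string& c,
                               const std::vector<std::string>& bl) {
  size_t max_bl = 0;
  for (const auto& b : bl) max_bl = std::max(max_bl, b.size());
  CandMeta m;
  m.len = (int)c.size();
  m.gc = gc_count_str(c);
  m.lead = lead_run_str(c);
  m.max_run = max_run_str(c);
  m.first = c.empty() ? 'N' : c[0];
  m.own_bl_hit = has_blacklisted(c, bl);
  size_t k = max_bl > 1 ? std::min(c.size(), max_bl - 1) : 0;
  m.head = c.substr(0, k);
  return m;
}

// Composition check of (batch + candidate) without building the concatenation.
// Assumes the batch itself passes the filters (validated upstream), so the
// only new homopolymer run is the junction run and any blacklist hit in the
// junction window spans the junction. Returns 0/1/2/3 as comp_code_str.
static int concat_comp_code(const BatchMeta& b, const CandMeta& c, int m,
                            double gc_min, double gc_max,
                            const std::vector<std::string>& bl) {
  if (c.max_run > m) return 1;
  if (b.last == c.first && b.trail + c.lead > m) return 1;
  if (!gc_ok(b.gc + c.gc, b.len + c.len, gc_min, gc_max)) return 2;
  if (c.own_bl_hit) return 3;
  if (!b.tail.empty() || !c.head.empty()) {
    std::string window = b.tail + c.head;
    if (has_blacklisted(window, bl)) return 3;
  }
  return 0;
}

static std::vector<std::string> to_vec(const CharacterVector& x) {
  std::vector<std::string> out;
  out.reserve(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out.push_back(as<std::string>(x[i]));
  return out;
}

// ---------------------------------------------------------------------------
// Exported primitives
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_hamming(CharacterVector a, CharacterVector b) {
  R_xlen_t n = a.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string x = as<std::string>(a[i]), y = as<std::string>(b[i]);
    int d = 0;
    for (size_t k = 0; k < x.size(); ++k)
      if (x[k] != y[k]) ++d;
    out[i] = d;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_max_run(CharacterVector x) {
  IntegerVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = max_run_str(as<std::string>(x[i]));
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_gc_count(CharacterVector x) {
  IntegerVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = gc_count_str(as<std::string>(x[i]));
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_contains_blacklisted(CharacterVector x,
                                       CharacterVector blacklist) {
  std::vector<std::string> bl = to_vec(blacklist);
  LogicalVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = has_blacklisted(as<std::string>(x[i]), bl);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_comp_code(CharacterVector x, int m, double gc_min,
                            double gc_max, CharacterVector blacklist) {
  std::vector<std::string> bl = to_vec(blacklist);
  IntegerVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = comp_code_str(as<std::string>(x[i]), m, gc_min, gc_max, bl);
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_markov_generate(int n, int len, double delta,
                                    int order_m) {
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) out[i] = markov_seq(len, delta, order_m);
  return out;
}

// Minimum pairwise Hamming distance within a set (equal-length sequences).
// [[Rcpp::export]]
List cpp_pairwise_min(CharacterVector x) {
  R_xlen_t n = x.size();
  if (n < 2)
    return List::create(_["min"] = R_PosInf, _["i"] = NA_INTEGER,
                        _["j"] = NA_INTEGER);
  std::vector<packed_t> p;
  p.reserve(n);
  for (R_xlen_t i = 0; i < n; ++i) p.push_back(pack_seq(as<std::string>(x[i])));
  int best = INT_MAX, bi = 0, bj = 1;
  for (R_xlen_t i = 0; i < n; ++i) {
    if ((i & 255) == 0) Rcpp::checkUserInterrupt();
    for (R_xlen_t j = i + 1; j < n; ++j) {
      int d = packed_hamming(p[i], p[j]);
      if (d < best) {
        best = d;
        bi = (int)i;
        bj = (int)j;
        if (best == 0) goto done;
      }
    }
  }
done:
  return List::create(_["min"] = (double)best, _["i"] = bi + 1,
                      _["j"] = bj + 1);
}

// Exhaustive pairwise minima over the assembled n_b x n_t library, split by
// pair class: same batch (batch index equal), same target, differing in both.
// [[Rcpp::export]]
List cpp_exhaustive_minima(CharacterVector batches, CharacterVector targets) {
  int nb = (int)batches.size(), nt = (int)targets.size();
  std::vector<packed_t> p;
  p.reserve((size_t)nb * nt);
  for (int i = 0; i < nb; ++i)
    for (int j = 0; j < nt; ++j)
      p.push_back(pack_seq(as<std::string>(batches[i]) +
                           as<std::string>(targets[j])));
  double mb = R_PosInf, mt = R_PosInf, md = R_PosInf, mall = R_PosInf;
  size_t n = p.size();
  for (size_t a = 0; a < n; ++a) {
    if ((a & 127) == 0) Rcpp::checkUserInterrupt();
    int ia = (int)(a / nt), ja = (int)(a % nt);
    for (size_t b = a + 1; b < n; ++b) {
      int ib = (int)(b / nt), jb = (int)(b % nt);
      int d = packed_hamming(p[a], p[b]);
      if (d < mall) mall = d;
      if (ia == ib) {
        if (d < mb) mb = d;
      } else if (ja == jb) {
        if (d < mt) mt = d;
      } else {
        if (d < md) md = d;
      }
    }
  }
  return List::create(_["same_batch"] = mb, _["same_target"] = mt,
                      _["diff_both"] = md, _["overall"] = mall);
}

// ---------------------------------------------------------------------------
// Batch-code generation (rejection sampling; delta = 1/4, m = 1 proposals)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_generate_batches(int n_b, int l_b, int m_filter, double gc_min,
                          double gc_max, CharacterVector blacklist, int d_b,
                          double max_attempts, CharacterVector existing,
                          CharacterVector forbidden_tails) {
  std::vector<std::string> bl = to_vec(blacklist);
  std::vector<std::string> ftails = to_vec(forbidden_tails);
  std::vector<std::string> linked, core, linker;
  std::vector<packed_t> packed;
  for (R_xlen_t i = 0; i < existing.size(); ++i) {
    std::string e = as<std::string>(existing[i]);
    linked.push_back(e);
    packed.push_back(pack_seq(e));
  }
  long long proposed = 0, comparisons = 0;
  long long rej[4] = {0, 0, 0, 0};  // hamming, homopolymer, gc, blacklist
  bool feasible = true;
  while ((int)core.size() < n_b && feasible) {
    long long attempts = 0;
    for (;;) {
      if ((double)attempts++ >= max_attempts) {
        feasible = false;
        break;
      }
      if ((proposed & 8191) == 0) Rcpp::checkUserInterrupt();
      ++proposed;
      std::string cand = markov_seq(l_b, 0.25, 1);
      append_linker(cand);
      // evaluation order: Hamming -> homopolymer -> GC -> blacklist
      packed_t pw = pack_seq(cand);
      bool ok = true;
      if (d_b > 0) {
        for (const auto& q : packed) {
          ++comparisons;
          if (packed_hamming(q, pw) < d_b) {
            ++rej[0];
            ok = false;
            break;
          }
        }
      }
      if (!ok) continue;
      int c = comp_code_str(cand, m_filter, gc_min, gc_max, bl);
      if (c == 0 && !ftails.empty()) {
        // optional tail screen: a linked code must not end with a long
        // proper prefix of a blacklist entry (junction-poisoning guard)
        for (const auto& t : ftails) {
          if (cand.size() >= t.size() &&
              cand.compare(cand.size() - t.size(), t.size(), t) == 0) {
            c = 3;
            break;
          }
        }
      }
      if (c != 0) {
        ++rej[c];
        continue;
      }
      core.push_back(cand.substr(0, l_b));
      linker.push_back(cand.substr(l_b, 2));
      linked.push_back(cand);
      packed.push_back(std::move(pw));
      break;
    }
  }
  // linked includes the pre-existing codes at the front; new ones follow
  return List::create(
      _["batch"] = wrap(core), _["linker"] = wrap(linker),
      _["linked"] = wrap(std::vector<std::string>(
          linked.end() - core.size(), linked.end())),
      _["proposed"] = (double)proposed, _["accepted"] = (double)core.size(),
      _["comparisons"] = (double)comparisons,
      _["rej_hamming"] = (double)rej[0], _["rej_homopolymer"] = (double)rej[1],
      _["rej_gc"] = (double)rej[2], _["rej_blacklist"] = (double)rej[3],
      _["completed"] = feasible);
}

// ---------------------------------------------------------------------------
// Target-code generation
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_generate_targets(int n_t, int l_t, CharacterVector linked_batches,
                          double delta, int order_m, int m_filter,
                          double gc_min, double gc_max,
                          CharacterVector blacklist, int d_t,
                          double max_attempts, CharacterVector existing) {
  std::vector<std::string> bl = to_vec(blacklist);
  std::vector<std::string> batches = to_vec(linked_batches);
  std::vector<BatchMeta> meta = make_batch_meta(batches, bl);
  std::vector<std::string> targets;
  std::vector<packed_t> packed;
  for (R_xlen_t i = 0; i < existing.size(); ++i) {
    std::string e = as<std::string>(existing[i]);
    packed.push_back(pack_seq(e));
  }
  long long proposed = 0, comparisons = 0, concat_checks = 0;
  long long rej[4] = {0, 0, 0, 0};
  std::vector<double> attempts_per_code;
  attempts_per_code.reserve(n_t);
  bool feasible = true;
  while ((int)targets.size() < n_t && feasible) {
    long long attempts = 0;
    for (;;) {
      if ((double)attempts++ >= max_attempts) {
        feasible = false;
        break;
      }
      if ((proposed & 8191) == 0) Rcpp::checkUserInterrupt();
      ++proposed;
      std::string cand = markov_seq(l_t, delta, order_m);
      packed_t pw = pack_seq(cand);
      // Hamming against previously accepted targets first
      bool ok = true;
      if (d_t > 0) {
        for (const auto& q : packed) {
          ++comparisons;
          if (packed_hamming(q, pw) < d_t) {
            ++rej[0];
            ok = false;
            break;
          }
        }
      }
      if (!ok) continue;
      // composition of every concatenation linked_batch + candidate
      CandMeta cm = make_cand_meta(cand, bl);
      int code = 0;
      for (const auto& b : meta) {
        ++concat_checks;
        code = concat_comp_code(b, cm, m_filter, gc_min, gc_max, bl);
        if (code != 0) break;
      }
      if (code != 0) {
        ++rej[code];
        continue;
      }
      targets.push_back(cand);
      packed.push_back(std::move(pw));
      attempts_per_code.push_back((double)attempts);
      break;
    }
  }
  return List::create(
      _["targets"] = wrap(targets), _["proposed"] = (double)proposed,
      _["accepted"] = (double)targets.size(),
      _["comparisons"] = (double)comparisons,
      _["concat_checks"] = (double)concat_checks,
      _["rej_hamming"] = (double)rej[0], _["rej_homopolymer"] = (double)rej[1],
      _["rej_gc"] = (double)rej[2], _["rej_blacklist"] = (double)rej[3],
      _["attempts_per_code"] = wrap(attempts_per_code),
      _["completed"] = feasible);
}

// One grid-search trial: generate s candidates at delta and count how many
// pass the composition filters against every linked batch code (no
// target-target Hamming at grid-search time).
// [[Rcpp::export]]
int cpp_pass_rate_trial(CharacterVector linked_batches, int s, int l_t,
                        double delta, int order_m, int m_filter, double gc_min,
                        double gc_max, CharacterVector blacklist) {
  std::vector<std::string> bl = to_vec(blacklist);
  std::vector<std::string> batches = to_vec(linked_batches);
  std::vector<BatchMeta> meta = make_batch_meta(batches, bl);
  int pass = 0;
  for (int i = 0; i < s; ++i) {
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
    std::string cand = markov_seq(l_t, delta, order_m);
    CandMeta cm = make_cand_meta(cand, bl);
    bool ok = true;
    for (const auto& b : meta) {
      if (concat_comp_code(b, cm, m_filter, gc_min, gc_max, bl) != 0) {
        ok = false;
        break;
      }
    }
    if (ok) ++pass;
  }
  return pass;
}

// ---------------------------------------------------------------------------
// Naive single-piece baseline
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_generate_naive(int n, int len, int m_filter, double gc_min,
                        double gc_max, CharacterVector blacklist, int d,
                        double max_candidates) {
  std::vector<std::string> bl = to_vec(blacklist);
  std::vector<std::string> codes;
  std::vector<packed_t> packed;
  long long proposed = 0, comparisons = 0;
  long long rej[4] = {0, 0, 0, 0};
  bool completed = true;
  // progress checkpoints (codes generated, elapsed seconds) for extrapolation
  std::vector<double> ck_codes, ck_secs;
  auto t0 = std::chrono::steady_clock::now();
  long long next_ck = 8;
  while ((int)codes.size() < n) {
    if ((double)proposed >= max_candidates) {
      completed = false;
      break;
    }
    if ((proposed & 8191) == 0) Rcpp::checkUserInterrupt();
    ++proposed;
    std::string cand = markov_seq(len, 0.25, 1);  // uniform over S^len
    packed_t pw = pack_seq(cand);
    bool ok = true;
    if (d > 0) {
      for (const auto& q : packed) {
        ++comparisons;
        if (packed_hamming(q, pw) < d) {
          ++rej[0];
          ok = false;
          break;
        }
      }
    }
    if (!ok) continue;
    int c = comp_code_str(cand, m_filter, gc_min, gc_max, bl);
    if (c != 0) {
      ++rej[c];
      continue;
    }
    codes.push_back(cand);
    packed.push_back(std::move(pw));
    if ((long long)codes.size() >= next_ck) {
      std::chrono::duration<double> el = std::chrono::steady_clock::now() - t0;
      ck_codes.push_back((double)codes.size());
      ck_secs.push_back(el.count());
      next_ck *= 2;
    }
  }
  std::chrono::duration<double> el = std::chrono::steady_clock::now() - t0;
  if (!codes.empty() &&
      (ck_codes.empty() || ck_codes.back() < (double)codes.size())) {
    ck_codes.push_back((double)codes.size());
    ck_secs.push_back(el.count());
  }
  return List::create(
      _["codes"] = wrap(codes), _["proposed"] = (double)proposed,
      _["accepted"] = (double)codes.size(),
      _["comparisons"] = (double)comparisons,
      _["rej_hamming"] = (double)rej[0], _["rej_homopolymer"] = (double)rej[1],
      _["rej_gc"] = (double)rej[2], _["rej_blacklist"] = (double)rej[3],
      _["completed"] = completed, _["elapsed"] = el.count(),
      _["checkpoint_codes"] = wrap(ck_codes),
      _["checkpoint_secs"] = wrap(ck_secs));
}

// ---------------------------------------------------------------------------
// Composition scan of every assembled concatenation (streaming; handles
// arbitrary, possibly corrupted components, so it builds each concatenation)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_scan_library(CharacterVector batches, CharacterVector targets,
                      int m_filter, double gc_min, double gc_max,
                      CharacterVector blacklist, int max_report) {
  std::vector<std::string> bl = to_vec(blacklist);
  std::vector<std::string> bs = to_vec(batches), ts = to_vec(targets);
  long long violations = 0;
  std::vector<int> vi, vj, vf;
  std::string full;
  for (size_t i = 0; i < bs.size(); ++i) {
    Rcpp::checkUserInterrupt();
    for (size_t j = 0; j < ts.size(); ++j) {
      full.assign(bs[i]);
      full += ts[j];
      int c = comp_code_str(full, m_filter, gc_min, gc_max, bl);
      if (c != 0) {
        ++violations;
        if ((int)vi.size() < max_report) {
          vi.push_back((int)i + 1);
          vj.push_back((int)j + 1);
          vf.push_back(c);
        }
      }
    }
  }
  return List::create(_["violations"] = (double)violations,
                      _["batch_index"] = wrap(vi), _["target_index"] = wrap(vj),
                      _["filter_code"] = wrap(vf));
}
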