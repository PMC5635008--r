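// Sequence-scanning kernels: canonical k-mer extraction, circular gap-free
// alignment of reads against tandem-repeat monomers, periodicity profiling,
// multimer run counting and paired-end read simulation.
//
// Alphabet is strict ACGT; any other character never matches (encodes -1).
// Transitions are A<->G and C<->T (2-bit codes XOR to 2).

#include <Rcpp.h>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

static inline int baseCode(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

static inline char compBase(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
  }
  return 'N';
}

static std::string revcompStr(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = compBase(r[i]);
  return r;
}

static inline bool isTransition(int a, int b) { return (a ^ b) == 2; }

// Canonical k-mer codes (min of forward and reverse-complement 2-bit codes)
// for one sequence. k must be <= 26 so codes are exact in doubles.
static void kmerCodes(const std::string& s, int k,
                      std::vector<uint64_t>& out) {
  out.clear();
  const int n = (int)s.size();
  if (n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t f = 0, r = 0;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = baseCode(s[i]);
    if (b < 0) { valid = 0; f = 0; r = 0; continue; }
    f = ((f << 2) | (uint64_t)b) & mask;
    r = (r >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++valid >= k) out.push_back(f < r ? f : r);
  }
}

// [[Rcpp::export]]
List cpp_kmer_sets(CharacterVector seqs, int k) {
  if (k < 2 || k > 26) stop("k must be in [2, 26]");
  const int n = seqs.size();
  List res(n);
  std::vector<uint64_t> buf;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    kmerCodes(s, k, buf);
    std::sort(buf.begin(), buf.end());
    buf.erase(std::unique(buf.begin(), buf.end()), buf.end());
    NumericVector v(buf.size());
    for (size_t j = 0; j < buf.size(); ++j) v[j] = (double)buf[j];
    res[i] = v;
  }
  return res;
}

// Mean per-site identity between s[i] and s[i+p] for each candidate period p.
// NA where fewer than min_sites positions can be compared.
// [[Rcpp::export]]
NumericVector cpp_period_profile(std::string s, int min_p, int max_p,
                                 int min_sites) {
  const int n = (int)s.size();
  if (min_p < 1) stop("min_p must be >= 1");
  if (max_p < min_p) stop("max_p must be >= min_p");
  NumericVector out(max_p - min_p + 1, NA_REAL);
  for (int p = min_p; p <= max_p; ++p) {
    int sites = n - p;
    if (sites < min_sites) continue;
    int m = 0;
    for (int i = 0; i < sites; ++i) if (s[i] == s[i + p]) ++m;
    out[p - min_p] = (double)m / sites;
  }
  out.attr("periods") = seq(min_p, max_p);
  return out;
}

struct AlnBest {
  int score, strand, offset, start, len;   // start: 0-based in oriented read
  bool any;
  AlnBest() : score(-1), strand(1), offset(0), start(0), len(0), any(false) {}
};

// Best-scoring gap-free segment (Kadane, match +1 / mismatch -1) of `read`
// against the circular tandem of `unit`, over both strands and all phases.
static AlnBest circBest(const std::string& read, const std::string& rcread,
                        const std::string& unit) {
  const int rl = (int)read.size(), L = (int)unit.size();
  AlnBest best;
  for (int strand = 0; strand < 2; ++strand) {
    const std::string& r = strand == 0 ? read : rcread;
    for (int o = 0; o < L; ++o) {
      int cur = 0, curStart = 0;
      for (int i = 0; i < rl; ++i) {
        int sc = (r[i] == unit[(o + i) % L]) ? 1 : -1;
        if (cur <= 0) { cur = sc; curStart = i; }
        else cur += sc;
        if (cur > best.score) {
          best.score = cur; best.strand = strand == 0 ? 1 : -1;
          best.offset = o; best.start = curStart; best.len = i - curStart + 1;
          best.any = true;
        }
      }
    }
  }
  return best;
}

static void segCounts(const std::string& r, const std::string& unit,
                      const AlnBest& b, int& matches, int& ts, int& tv) {
  const int L = (int)unit.size();
  matches = ts = tv = 0;
  for (int i = b.start; i < b.start + b.len; ++i) {
    int a = baseCode(r[i]), u = baseCode(unit[(b.offset + i) % L]);
    if (a >= 0 && a == u) ++matches;
    else if (a >= 0 && u >= 0 && isTransition(a, u)) ++ts;
    else ++tv;
  }
}

// [[Rcpp::export]]
List cpp_circ_align(std::string read, std::string unit) {
  if (read.empty() || unit.empty()) stop("empty sequence");
  std::string rc = revcompStr(read);
  AlnBest b = circBest(read, rc, unit);
  const std::string& r = b.strand == 1 ? read : rc;
  int matches, ts, tv;
  segCounts(r, unit, b, matches, ts, tv);
  // map segment start back to original read coordinates (1-based)
  int start1 = (b.strand == 1) ? b.start + 1
                               : (int)read.size() - (b.start + b.len) + 1;
  return List::create(
    _["strand"] = b.strand, _["offset"] = b.offset + 1,
    _["start"] = start1, _["length"] = b.len, _["score"] = b.score,
    _["matches"] = matches, _["transitions"] = ts, _["transversions"] = tv,
    _["identity"] = b.len > 0 ? (double)matches / b.len : NA_REAL);
}

// Assign each read to its best-matching monomer. Candidate (read, unit) pairs
// are pre-filtered by shared canonical seed k-mers with the doubled unit, then
// scored by circular gap-free alignment; hits must reach min_len aligned bases
// at min_ident identity. Returns one row per assigned read.
// [[Rcpp::export]]
DataFrame cpp_mask(CharacterVector reads, CharacterVector units,
                   double min_ident, int min_len, int seed_k) {
  const int nr = reads.size(), nu = units.size();
  if (nu == 0) stop("no units");
  if (seed_k < 2 || seed_k > 26) stop("seed_k must be in [2, 26]");
  std::vector<std::string> U(nu);
  std::vector<std::unordered_set<uint64_t>> seeds(nu);
  std::vector<uint64_t> buf;
  for (int u = 0; u < nu; ++u) {
    U[u] = as<std::string>(units[u]);
    std::string doubled = U[u] + U[u];
    kmerCodes(doubled, seed_k, buf);
    seeds[u].insert(buf.begin(), buf.end());
  }
  std::vector<int> o_read, o_unit, o_start, o_len, o_m, o_ts, o_tv, o_str;
  for (int i = 0; i < nr; ++i) {
    std::string rd = as<std::string>(reads[i]);
    kmerCodes(rd, seed_k, buf);
    std::sort(buf.begin(), buf.end());
    buf.erase(std::unique(buf.begin(), buf.end()), buf.end());
    std::string rc;
    AlnBest best; int bestU = -1, bm = 0, bts = 0, btv = 0;
    for (int u = 0; u < nu; ++u) {
      bool cand = false;
      for (size_t j = 0; j < buf.size(); ++j)
        if (seeds[u].count(buf[j])) { cand = true; break; }
      if (!cand) continue;
      if (rc.empty()) rc = revcompStr(rd);
      AlnBest b = circBest(rd, rc, U[u]);
      if (!b.any || b.len < min_len) continue;
      int matches, ts, tv;
      const std::string& rr = b.strand == 1 ? rd : rc;
      segCounts(rr, U[u], b, matches, ts, tv);
      if ((double)matches / b.len < min_ident) continue;
      if (b.score > best.score) {
        best = b; bestU = u; bm = matches; bts = ts; btv = tv;
      }
    }
    if (bestU >= 0) {
      int start1 = (best.strand == 1)
        ? best.start + 1 : (int)rd.size() - (best.start + best.len) + 1;
      o_read.push_back(i + 1); o_unit.push_back(bestU + 1);
      o_start.push_back(start1); o_len.push_back(best.len);
      o_m.push_back(bm); o_ts.push_back(bts); o_tv.push_back(btv);
      o_str.push_back(best.strand);
    }
  }
  return DataFrame::create(
    _["read"] = o_read, _["unit"] = o_unit, _["start"] = o_start,
    _["length"] = o_len, _["matches"] = o_m, _["transitions"] = o_ts,
    _["transversions"] = o_tv, _["strand"] = o_str);
}

// Longest run of consecutive full monomer copies (each at >= min_ident
// identity) found in each read, over both strands and all phases.
// [[Rcpp::export]]
IntegerVector cpp_multimer_runs(CharacterVector reads, std::string unit,
                                double min_ident) {
  const int nr = reads.size(), L = (int)unit.size();
  if (L == 0) stop("empty unit");
  IntegerVector out(nr);
  for (int i = 0; i < nr; ++i) {
    std::string rd = as<std::string>(reads[i]);
    std::string rc = revcompStr(rd);
    const int rl = (int)rd.size();
    int bestRun = 0;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& r = strand == 0 ? rd : rc;
      for (int o = 0; o < L; ++o) {
        // copy windows start where the circular unit coordinate wraps to 0
        int first = (L - o % L) % L;
        int run = 0;
        for (int s = first; s + L <= rl; s += L) {
          int m = 0;
          for (int j = 0; j < L; ++j) if (r[s + j] == unit[j]) ++m;
          if ((double)m / L >= min_ident) { if (++run > bestRun) bestRun = run; }
          else run = 0;
        }
      }
    }
    out[i] = bestRun;
  }
  return out;
}

// Paired-end read simulator over a (haploid) genome string. Uniform fragment
// starts, both strands, Gaussian insert length, independent per-base
// substitution errors. Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
List cpp_sim_reads(std::string genome, int n_pairs, int read_len,
                   int insert_mean, double insert_sd, double error_rate) {
  const int G = (int)genome.size();
  if (n_pairs <= 0) stop("n_pairs must be positive");
  if (read_len > insert_mean) stop("read_len must be <= insert_mean");
  if (insert_mean > G) stop("insert_mean must be <= genome length");
  CharacterVector r1(n_pairs), r2(n_pairs);
  IntegerVector starts(n_pairs), inserts(n_pairs), strands(n_pairs);
  const char* B = "ACGT";
  for (int i = 0; i < n_pairs; ++i) {
    int ins = insert_mean;
    if (insert_sd > 0) {
      ins = (int)std::lround(R::rnorm((double)insert_mean, insert_sd));
      if (ins < read_len) ins = read_len;
      if (ins > G) ins = G;
    }
    int start = 1 + (int)std::floor(unif_rand() * (G - ins + 1));
    if (start > G - ins + 1) start = G - ins + 1;
    bool minus = unif_rand() < 0.5;
    std::string frag = genome.substr(start - 1, ins);
    if (minus) frag = revcompStr(frag);
    std::string a = frag.substr(0, read_len);
    std::string b = revcompStr(frag.substr(ins - read_len, read_len));
    if (error_rate > 0) {
      for (int j = 0; j < read_len; ++j) {
        if (unif_rand() < error_rate) {
          int c = baseCode(a[j]);
          int alt = (int)std::floor(unif_rand() * 3);
          a[j] = B[(c + 1 + alt) % 4];
        }
        if (unif_rand() < error_rate) {
          int c = baseCode(b[j]);
          int alt = (int)std::floor(unif_rand() * 3);
          b[j] = B[(c + 1 + alt) % 4];
        }
      }
    }
    r1[i] = a; r2[i] = b;
    starts[i] = start; inserts[i] = ins; strands[i] = minus ? -1 : 1;
  }
  return List::create(_["reads1"] = r1, _["reads2"] = r2,
                      _["start"] = starts, _["insert"] = inserts,
                      _["strand"] = strands);
}

// Mismatch tally of simulated reads against their source coordinates
// (error-model verification).
// [[Rcpp::export]]
NumericVector cpp_pair_mismatch(std::string genome, CharacterVector reads1,
                                CharacterVector reads2, IntegerVector start,
                                IntegerVector insert, IntegerVector strand) {
  const int n = reads1.size();
  double mm = 0, bases = 0;
  for (int i = 0; i < n; ++i) {
    std::string a = as<std::string>(reads1[i]);
    std::string b = as<std::string>(reads2[i]);
    int rl = (int)a.size();
    std::string frag = genome.substr(start[i] - 1, insert[i]);
    if (strand[i] < 0) frag = revcompStr(frag);
    std::string ta = frag.substr(0, rl);
    std::string tb = revcompStr(frag.substr(insert[i] - rl, rl));
    for (int j = 0; j < rl; ++j) {
      if (a[j] != ta[j]) ++mm;
      if (b[j] != tb[j]) ++mm;
      bases += 2;
    }
  }
  return NumericVector::create(mm, bases);
}
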