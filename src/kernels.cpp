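// Performance kernels: gamete formation under a no-interference Poisson
// crossover model, and packed-bit Hamming matching of core haplotypes
// against purebred libraries. All randomness goes through R's RNG so that
// set.seed() in R fully determines simulation output.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
using namespace Rcpp;

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

// Fill `gam` (and optionally `ogam`) with one gamete formed from the two
// parental rows h1/h2 (and origin rows o1/o2). Crossover count is
// Poisson(mapLen), breakpoint positions uniform on [0, mapLen], starting
// chromatid chosen uniformly. Haplotype and origin are cut at the same
// breakpoints.
static void make_gamete(const int* h1, const int* h2,
                        const int* o1, const int* o2,
                        const double* pos, int L, double mapLen,
                        int* gam, int* ogam) {
  int nx = (int) R::rpois(mapLen);
  int cur = (unif_rand() < 0.5) ? 0 : 1; // starting chromatid
  if (nx == 0) {
    const int* h = cur == 0 ? h1 : h2;
    std::copy(h, h + L, gam);
    if (ogam) {
      const int* o = cur == 0 ? o1 : o2;
      std::copy(o, o + L, ogam);
    }
    return;
  }
  std::vector<double> bp(nx);
  for (int k = 0; k < nx; ++k) bp[k] = unif_rand() * mapLen;
  std::sort(bp.begin(), bp.end());
  int k = 0;
  for (int j = 0; j < L; ++j) {
    while (k < nx && pos[j] >= bp[k]) { ++k; cur = 1 - cur; }
    gam[j] = cur == 0 ? h1[j] : h2[j];
    if (ogam) ogam[j] = cur == 0 ? o1[j] : o2[j];
  }
}

// copy a column-major R matrix into a row-major buffer (rows contiguous)
static std::vector<int> to_row_major(const IntegerMatrix& X) {
  const int n = X.nrow(), m = X.ncol();
  std::vector<int> out((size_t)n * m);
  const int* src = INTEGER(X);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i)
      out[(size_t)i * m + j] = src[(size_t)j * n + i];
  return out;
}

static void from_row_major(const std::vector<int>& buf, IntegerMatrix& X) {
  const int n = X.nrow(), m = X.ncol();
  int* dst = INTEGER(X);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i)
      dst[(size_t)j * n + i] = buf[(size_t)i * m + j];
}

// One generation of mating. H holds two haplotype rows per individual
// (rows 2i-1, 2i in R's 1-based view). dams/sires are 0-based individual
// indices, one per offspring; offspring i receives a maternal gamete from
// dams[i] and a paternal gamete from sires[i].
// [[Rcpp::export]]
IntegerMatrix cpp_next_gen(const IntegerMatrix& H, const NumericVector& pos,
                           const IntegerVector& dams, const IntegerVector& sires,
                           double mapLen) {
  const int L = H.ncol();
  const int n_off = dams.size();
  if (sires.size() != n_off) stop("dams and sires must have equal length");
  std::vector<int> Hr = to_row_major(H);
  std::vector<int> outBuf((size_t)2 * n_off * L);
  for (int i = 0; i < n_off; ++i) {
    for (int par = 0; par < 2; ++par) {
      const int p = par == 0 ? dams[i] : sires[i];
      const int* h1 = &Hr[(size_t)(2 * p) * L];
      const int* h2 = &Hr[(size_t)(2 * p + 1) * L];
      make_gamete(h1, h2, nullptr, nullptr, REAL(pos), L, mapLen,
                  &outBuf[(size_t)(2 * i + par) * L], nullptr);
    }
  }
  IntegerMatrix out(2 * n_off, L);
  from_row_major(outBuf, out);
  return out;
}

// As cpp_next_gen, but parental origin rows O are cut at the same
// breakpoints as the haplotypes, so true breed origin is tracked through
// every meiosis.
// [[Rcpp::export]]
List cpp_next_gen_traced(const IntegerMatrix& H, const IntegerMatrix& O,
                         const NumericVector& pos,
                         const IntegerVector& dams, const IntegerVector& sires,
                         double mapLen) {
  const int L = H.ncol();
  const int n_off = dams.size();
  if (O.nrow() != H.nrow() || O.ncol() != L) stop("origin matrix shape mismatch");
  if (sires.size() != n_off) stop("dams and sires must have equal length");
  std::vector<int> Hr = to_row_major(H);
  std::vector<int> Or = to_row_major(O);
  std::vector<int> hBuf((size_t)2 * n_off * L), oBuf((size_t)2 * n_off * L);
  for (int i = 0; i < n_off; ++i) {
    for (int par = 0; par < 2; ++par) {
      const int p = par == 0 ? dams[i] : sires[i];
      const size_t row = (size_t)(2 * i + par) * L;
      make_gamete(&Hr[(size_t)(2 * p) * L], &Hr[(size_t)(2 * p + 1) * L],
                  &Or[(size_t)(2 * p) * L], &Or[(size_t)(2 * p + 1) * L],
                  REAL(pos), L, mapLen, &hBuf[row], &oBuf[row]);
    }
  }
  IntegerMatrix outH(2 * n_off, L), outO(2 * n_off, L);
  from_row_major(hBuf, outH);
  from_row_major(oBuf, outO);
  return List::create(_["haplotypes"] = outH, _["origins"] = outO);
}

// Single gamete with origin tracking; used by the R-level meiosis().
// [[Rcpp::export]]
List cpp_gamete(const IntegerVector& h1, const IntegerVector& h2,
                const IntegerVector& o1, const IntegerVector& o2,
                const NumericVector& pos, double mapLen) {
  const int L = h1.size();
  IntegerVector gam(L), ogam(L);
  make_gamete(h1.begin(), h2.begin(), o1.begin(), o2.begin(),
              REAL(pos), L, mapLen, gam.begin(), ogam.begin());
  return List::create(_["haplotype"] = gam, _["origin"] = ogam);
}

static std::vector<uint64_t> pack_rows(const IntegerMatrix& X, int& nw) {
  const int n = X.nrow(), w = X.ncol();
  nw = (w + 63) / 64;
  std::vector<uint64_t> out((size_t)n * nw, 0ULL);
  for (int j = 0; j < w; ++j) {
    const int word = j / 64, bit = j % 64;
    const uint64_t mask = 1ULL << bit;
    for (int i = 0; i < n; ++i)
      if (X(i, j)) out[(size_t)i * nw + word] |= mask;
  }
  return out;
}

namespace {
struct KeyHash {
  size_t operator()(const std::vector<uint64_t>& k) const {
    uint64_t h = 1469598103934665603ULL;
    for (uint64_t w : k) {
      h ^= w;
      h *= 1099511628211ULL;
      h ^= h >> 29;
    }
    return (size_t)h;
  }
};
}

// pack the window [start, stop) of a column-major 0/1 matrix into per-row
// word vectors
static std::vector<std::vector<uint64_t>> pack_window(const IntegerMatrix& X,
                                                      int start, int stop) {
  const int n = X.nrow();
  const int w = stop - start;
  const int nw = (w + 63) / 64;
  std::vector<std::vector<uint64_t>> out(n, std::vector<uint64_t>(nw, 0ULL));
  const int* src = INTEGER(X);
  for (int j = 0; j < w; ++j) {
    const int64_t colOff = (int64_t)(start + j) * n;
    const int word = j / 64, bit = j % 64;
    const uint64_t mask = 1ULL << bit;
    for (int i = 0; i < n; ++i)
      if (src[colOff + i]) out[i][word] |= mask;
  }
  return out;
}

// Fewest-mismatch breed assignment of every target haplotype within one core
// window [start, stop): 2 = exotic library holds the strictly best match,
// 1 = local does, 0 = tie (or the winner fails minMatchFrac; pass a negative
// value to disable that check). Targets found verbatim in exactly one
// library are called without a distance scan; the remainder are deduplicated
// and matched by packed-bit Hamming distance with early abandoning.
// [[Rcpp::export]]
IntegerVector cpp_assign_window(const IntegerMatrix& targets,
                                const IntegerMatrix& libExotic,
                                const IntegerMatrix& libLocal,
                                int winStart, int winStop, double minMatchFrac) {
  const int w = winStop - winStart;
  if (w <= 0) stop("empty window");
  if (libExotic.nrow() == 0 || libLocal.nrow() == 0) stop("empty haplotype library");
  auto T = pack_window(targets, winStart, winStop);
  auto E = pack_window(libExotic, winStart, winStop);
  auto L = pack_window(libLocal, winStart, winStop);

  std::unordered_set<std::vector<uint64_t>, KeyHash> setE(E.begin(), E.end());
  std::unordered_set<std::vector<uint64_t>, KeyHash> setL(L.begin(), L.end());
  // deduplicate the libraries for the distance scan
  std::vector<std::vector<uint64_t>> uE(setE.begin(), setE.end());
  std::vector<std::vector<uint64_t>> uL(setL.begin(), setL.end());

  const int nT = (int)T.size();
  IntegerVector call(nT);
  std::unordered_map<std::vector<uint64_t>, int, KeyHash> seen; // key -> call
  seen.reserve(nT * 2);

  auto minDist = [w](const std::vector<uint64_t>& t,
                     const std::vector<std::vector<uint64_t>>& lib) {
    int mn = w + 1;
    const int nw = (int)t.size();
    for (const auto& l : lib) {
      int d = 0;
      for (int wd = 0; wd < nw; ++wd) {
        d += popcount64(t[wd] ^ l[wd]);
        if (d >= mn) break;
      }
      if (d < mn) {
        mn = d;
        if (mn == 0) break;
      }
    }
    return mn;
  };

  for (int i = 0; i < nT; ++i) {
    auto it = seen.find(T[i]);
    if (it != seen.end()) {
      call[i] = it->second;
      continue;
    }
    const bool inE = setE.count(T[i]) > 0;
    const bool inL = setL.count(T[i]) > 0;
    int c;
    if (inE && inL) {
      c = 0; // both libraries contain a perfect match: tie
    } else if (inE || inL) {
      c = inE ? 2 : 1; // a zero-distance match in one library always wins
    } else {
      const int mE = minDist(T[i], uE);
      const int mL = minDist(T[i], uL);
      if (mE < mL) c = 2;
      else if (mL < mE) c = 1;
      else c = 0;
      if (c != 0 && minMatchFrac >= 0.0) {
        const int win = mE < mL ? mE : mL;
        if (1.0 - (double)win / w < minMatchFrac) c = 0;
      }
    }
    seen.emplace(T[i], c);
    call[i] = c;
  }
  return call;
}

// For each target row, the minimum Hamming distance over library rows and
// the number of library rows attaining it. Rows are packed into 64-bit
// words so one XOR/popcount compares 64 loci at a time.
// [[Rcpp::export]]
List cpp_min_hamming(const IntegerMatrix& targets, const IntegerMatrix& lib) {
  if (targets.ncol() != lib.ncol()) stop("targets and library differ in width");
  if (lib.nrow() == 0) stop("empty haplotype library");
  int nw = 0, nw2 = 0;
  std::vector<uint64_t> T = pack_rows(targets, nw);
  std::vector<uint64_t> L = pack_rows(lib, nw2);
  const int nT = targets.nrow(), nL = lib.nrow();
  IntegerVector best(nT), nbest(nT);
  for (int i = 0; i < nT; ++i) {
    const uint64_t* t = &T[(size_t)i * nw];
    int mn = targets.ncol() + 1, cnt = 0;
    for (int k = 0; k < nL; ++k) {
      const uint64_t* l = &L[(size_t)k * nw];
      int d = 0;
      for (int wd = 0; wd < nw; ++wd) {
        d += popcount64(t[wd] ^ l[wd]);
        if (d > mn) break;
      }
      if (d < mn) { mn = d; cnt = 1; }
      else if (d == mn) ++cnt;
    }
    best[i] = mn;
    nbest[i] = cnt;
  }
  return List::create(_["min"] = best, _["nmin"] = nbest);
}
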