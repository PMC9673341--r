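// Exact-k-mer LCA classifier core. Canonical k-mers (lexicographic min of a
// k-mer and its reverse complement, 2-bit packed) map to the LCA of all
// source genomes containing them. Classification scores every node on the
// root paths of the hit taxids by the sum of hit counts along its own root
// path, and reports the deepest maximal node (ties at equal depth collapse
// to their LCA).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

struct KmerIndex {
  int k;
  std::unordered_map<uint64_t, int32_t> kmers;          // canonical k-mer -> LCA taxid
  std::unordered_map<int32_t, int32_t> parent;          // taxid -> parent taxid
  std::unordered_map<int32_t, int32_t> depth;           // taxid -> root distance
};

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static int32_t lca2(const KmerIndex& ix, int32_t a, int32_t b) {
  int da = ix.depth.at(a), db_ = ix.depth.at(b);
  while (da > db_) { a = ix.parent.at(a); --da; }
  while (db_ > da) { b = ix.parent.at(b); --db_; }
  while (a != b) { a = ix.parent.at(a); b = ix.parent.at(b); }
  return a;
}

// enumerate canonical k-mers of seq; k-mers containing non-ACGT are skipped.
// emits (canonical kmer) via callback; also reports per-position taxid for
// the LCA-map string when lookup != nullptr.
template <typename F>
static void for_each_canonical_kmer(const std::string& seq, int k, F&& fun) {
  const int n = (int)seq.size();
  if (n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bits(seq[i]);
    if (b < 0) { valid = 0; fwd = rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++valid >= k) {
      fun(i - k + 1, fwd < rev ? fwd : rev);
    }
  }
}

// [[Rcpp::export(name = ".cpp_build_index")]]
SEXP cpp_build_index(std::vector<std::string> seqs, IntegerVector taxids,
                     int k, IntegerVector tax_taxid, IntegerVector tax_parent,
                     IntegerVector tax_depth) {
  if (k < 3 || k > 31 || k % 2 == 0)
    stop("k must be odd and within [3, 31]");
  Rcpp::XPtr<KmerIndex> ix(new KmerIndex(), true);
  ix->k = k;
  for (int i = 0; i < tax_taxid.size(); ++i) {
    ix->parent[tax_taxid[i]] = tax_parent[i];
    ix->depth[tax_taxid[i]] = tax_depth[i];
  }
  for (size_t g = 0; g < seqs.size(); ++g) {
    int32_t tid = taxids[g];
    if (ix->parent.find(tid) == ix->parent.end())
      stop("genome taxid %d is absent from the taxonomy", tid);
    for_each_canonical_kmer(seqs[g], k, [&](int, uint64_t km) {
      auto it = ix->kmers.find(km);
      if (it == ix->kmers.end()) ix->kmers[km] = tid;
      else if (it->second != tid) it->second = lca2(*ix, it->second, tid);
    });
  }
  return ix;
}

// [[Rcpp::export(name = ".cpp_index_stats")]]
List cpp_index_stats(SEXP xp) {
  Rcpp::XPtr<KmerIndex> ix(xp);
  return List::create(_["k"] = ix->k,
                      _["n_kmers"] = (double)ix->kmers.size(),
                      _["n_taxa"] = (double)ix->parent.size());
}

struct HitTally {
  std::unordered_map<int32_t, int32_t> hits;   // taxid -> k-mer hit count
  int total = 0;
};

static void tally_seq(const KmerIndex& ix, const std::string& seq, HitTally& t,
                      std::vector<int32_t>* permer) {
  const int n = (int)seq.size();
  if (permer) {
    permer->clear();
    if (n >= ix.k) permer->assign(n - ix.k + 1, 0);
  }
  for_each_canonical_kmer(seq, ix.k, [&](int pos, uint64_t km) {
    auto it = ix.kmers.find(km);
    int32_t tid = (it == ix.kmers.end()) ? 0 : it->second;
    if (permer) (*permer)[pos] = tid;
    if (tid != 0) { t.hits[tid]++; t.total++; }
  });
}

// deepest node with maximal root-path hit score among ancestors-or-self of
// hit taxids; ties at equal depth collapse to their LCA. Returns 0 when no
// k-mer hit the index.
static int32_t resolve(const KmerIndex& ix, const HitTally& t, int* out_score) {
  if (t.hits.empty()) { if (out_score) *out_score = 0; return 0; }
  // candidate set: union of root paths of hit taxids
  std::unordered_map<int32_t, char> cand;
  for (auto& kv : t.hits) {
    int32_t n = kv.first;
    while (true) {
      if (!cand.insert({n, 1}).second) break;
      int32_t p = ix.parent.at(n);
      if (p == n) break;
      n = p;
    }
  }
  int best_score = -1, best_depth = -1;
  std::vector<int32_t> best;
  for (auto& kv : cand) {
    int32_t n = kv.first;
    int score = 0;
    int32_t m = n;
    while (true) {
      auto h = t.hits.find(m);
      if (h != t.hits.end()) score += h->second;
      int32_t p = ix.parent.at(m);
      if (p == m) break;
      m = p;
    }
    int d = ix.depth.at(n);
    if (score > best_score) { best_score = score; best_depth = d; best.assign(1, n); }
    else if (score == best_score) {
      if (d > best_depth) { best_depth = d; best.assign(1, n); }
      else if (d == best_depth) best.push_back(n);
    }
  }
  int32_t ans = best[0];
  for (size_t i = 1; i < best.size(); ++i) ans = lca2(ix, ans, best[i]);
  if (out_score) *out_score = best_score;
  return ans;
}

static std::string rle_map(const std::vector<int32_t>& permer) {
  std::string out;
  size_t i = 0;
  while (i < permer.size()) {
    size_t j = i;
    while (j < permer.size() && permer[j] == permer[i]) ++j;
    if (!out.empty()) out += ' ';
    out += std::to_string(permer[i]) + ":" + std::to_string(j - i);
    i = j;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_classify")]]
List cpp_classify(SEXP xp, std::vector<std::string> r1,
                  Nullable<CharacterVector> r2_, bool emit_map) {
  Rcpp::XPtr<KmerIndex> ix(xp);
  bool paired = r2_.isNotNull();
  std::vector<std::string> r2;
  if (paired) {
    CharacterVector v(r2_);
    if ((size_t)v.size() != r1.size())
      stop("mate count mismatch: %d vs %d", (int)r1.size(), (int)v.size());
    r2.reserve(v.size());
    for (auto s : v) r2.push_back(as<std::string>(s));
  }
  int n = (int)r1.size();
  IntegerVector taxid(n), score(n);
  CharacterVector lenfield(n), lcamap(n);
  std::vector<int32_t> pm1, pm2;
  for (int i = 0; i < n; ++i) {
    HitTally t;
    tally_seq(*ix, r1[i], t, emit_map ? &pm1 : nullptr);
    if (paired) tally_seq(*ix, r2[i], t, emit_map ? &pm2 : nullptr);
    int sc = 0;
    taxid[i] = resolve(*ix, t, &sc);
    score[i] = sc;
    lenfield[i] = paired
      ? std::to_string(r1[i].size()) + "|" + std::to_string(r2[i].size())
      : std::to_string(r1[i].size());
    if (emit_map) {
      std::string m = rle_map(pm1);
      if (paired) m += " |:| " + rle_map(pm2);
      lcamap[i] = m;
    }
  }
  return List::create(_["taxid"] = taxid, _["score"] = score,
                      _["length_field"] = lenfield, _["lca_map"] = lcamap);
}

// [[Rcpp::export(name = ".cpp_read_hits")]]
DataFrame cpp_read_hits(SEXP xp, std::string r1, std::string r2, bool paired) {
  Rcpp::XPtr<KmerIndex> ix(xp);
  HitTally t;
  tally_seq(*ix, r1, t, nullptr);
  if (paired) tally_seq(*ix, r2, t, nullptr);
  std::vector<int32_t> tid; std::vector<int32_t> cnt;
  for (auto& kv : t.hits) { tid.push_back(kv.first); cnt.push_back(kv.second); }
  return DataFrame::create(_["taxid"] = tid, _["count"] = cnt);
}
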