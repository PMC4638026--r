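// Core sequence machinery: greedy overlap-consensus assembly, ungapped
// seed-and-extend local similarity search, reference read mapping and
// shared k-mer statistics. All routines are deterministic: no RNG, ties
// broken by explicit rank order.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return 4;
  }
}

static std::vector<uint8_t> encode(const std::string &s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (uint8_t)base_code(s[i]);
  return v;
}

static std::vector<uint8_t> revcomp(const std::vector<uint8_t> &v) {
  std::vector<uint8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    uint8_t b = v[v.size() - 1 - i];
    r[i] = b < 4 ? (uint8_t)(3 - b) : (uint8_t)4;
  }
  return r;
}

// Enumerate valid (ACGT-only) k-mers with their positions. step >= 1 thins
// the scan; index building always uses step 1.
template <typename F>
static void for_each_kmer(const std::vector<uint8_t> &s, int k, int step,
                          F fun) {
  if ((int)s.size() < k) return;
  uint64_t kmer = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;  // valid trailing bases
  for (size_t i = 0; i < s.size(); ++i) {
    if (s[i] > 3) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | s[i]) & mask;
    if (++run >= k) {
      size_t pos = i + 1 - k;
      if (step == 1 || pos % step == 0) fun(kmer, (int)pos);
    }
  }
}

// ---------------------------------------------------------------------------
// shared k-mer statistics

// [[Rcpp::export]]
double cpp_max_shared_kmer_fraction(CharacterVector seqs, int k) {
  int n = seqs.size();
  std::vector<std::vector<uint64_t>> sets(n);
  std::unordered_map<uint64_t, std::vector<int>> owners;
  for (int i = 0; i < n; ++i) {
    std::vector<uint8_t> enc = encode(as<std::string>(seqs[i]));
    std::vector<uint64_t> km;
    km.reserve(enc.size());
    for_each_kmer(enc, k, 1, [&](uint64_t x, int) { km.push_back(x); });
    std::sort(km.begin(), km.end());
    km.erase(std::unique(km.begin(), km.end()), km.end());
    sets[i] = km;
    for (uint64_t x : km) owners[x].push_back(i);
  }
  std::unordered_map<uint64_t, int> pair_shared;
  for (auto &kv : owners) {
    const std::vector<int> &o = kv.second;
    if (o.size() < 2) continue;
    for (size_t a = 0; a < o.size(); ++a)
      for (size_t b = a + 1; b < o.size(); ++b)
        pair_shared[((uint64_t)o[a] << 32) | (uint32_t)o[b]]++;
  }
  double best = 0.0;
  for (auto &kv : pair_shared) {
    int i = (int)(kv.first >> 32), j = (int)(kv.first & 0xffffffffu);
    size_t denom = std::min(sets[i].size(), sets[j].size());
    if (denom == 0) continue;
    best = std::max(best, (double)kv.second / (double)denom);
  }
  return best;
}

// ---------------------------------------------------------------------------
// greedy overlap-consensus assembly

struct Overlap {
  int i, j;       // read indices, i < j
  int orient;     // 0: i fwd vs j fwd; 1: i rc vs j fwd
  int offset;     // start of oriented i in j coordinates (may be negative)
  int ovl;        // overlap length
  int matches;    // matching columns in the overlap
};

struct Transform { int s; long long o; };  // frame -> parent frame

static inline Transform compose(const Transform &t1, const Transform &t2) {
  // t1: child->mid, t2: mid->root
  Transform t;
  t.s = t1.s ^ t2.s;
  t.o = t2.s ? (t2.o - t1.o) : (t2.o + t1.o);
  return t;
}

static inline Transform invert(const Transform &t) {
  Transform r;
  r.s = t.s;
  r.o = t.s ? t.o : -t.o;
  return r;
}

struct UnionFind {
  std::vector<int> parent, size;
  std::vector<Transform> up;  // node frame -> parent frame
  explicit UnionFind(int n) : parent(n), size(n, 1), up(n) {
    for (int i = 0; i < n; ++i) { parent[i] = i; up[i] = {0, 0}; }
  }
  int find(int x, Transform &acc) {
    std::vector<int> path;
    Transform t = {0, 0};
    int cur = x;
    while (parent[cur] != cur) { path.push_back(cur); cur = parent[cur]; }
    // recompute transform along path root-ward and compress
    for (int idx = (int)path.size() - 1; idx >= 0; --idx) {
      int node = path[idx];
      up[node] = compose(up[node], (parent[node] == cur) ? Transform{0, 0}
                                                         : up[parent[node]]);
      parent[node] = cur;
    }
    // NOTE: after compression every node on path points to root with the
    // correct composed transform (processed root-most first).
    acc = (x == cur) ? Transform{0, 0} : up[x];
    return cur;
  }
};

// Evaluate the ungapped overlap between oriented read a and read b (fwd)
// at a given offset. Returns overlap length and matches.
static inline void eval_overlap(const std::vector<uint8_t> &a,
                                const std::vector<uint8_t> &b, int offset,
                                int &ovl, int &matches) {
  int la = (int)a.size(), lb = (int)b.size();
  int qs = std::max(0, -offset);
  int qe = std::min(la, lb - offset);
  ovl = qe - qs;
  matches = 0;
  if (ovl <= 0) { ovl = 0; return; }
  for (int q = qs; q < qe; ++q)
    if (a[q] == b[q + offset] && a[q] < 4) ++matches;
}

// [[Rcpp::export]]
List cpp_assemble(CharacterVector seqs, IntegerVector rank,
                  double min_identity, double min_overlap_frac,
                  int min_overlap_abs, int seed_kmer) {
  int n = seqs.size();
  std::vector<std::vector<uint8_t>> fwd(n), rev(n);
  std::vector<int> len(n);
  int min_len = 1 << 30;
  for (int i = 0; i < n; ++i) {
    fwd[i] = encode(as<std::string>(seqs[i]));
    rev[i] = revcomp(fwd[i]);
    len[i] = (int)fwd[i].size();
    min_len = std::min(min_len, len[i]);
  }
  if (n == 0) return List::create(Named("members") = List());

  int k = seed_kmer;
  // every valid overlap spans >= req positions in the query, hence contains
  // req - k + 1 exact k-mer starts on error-free data; scanning with a
  // conservative step keeps seeding exhaustive while cutting hash lookups
  int req = std::max(min_overlap_abs,
                     (int)std::ceil(min_overlap_frac * min_len));
  int step = std::max(1, (req - k + 1) / 2);
  // deterministic work guards for deep coverage piles: a read in a pile of
  // hundreds of overlapping mates needs only a bounded number of anchors
  // to end up in the right contig
  const size_t max_eval = 512;
  const int max_accept = 128;

  size_t total_kmers = 0;
  for (int j = 0; j < n; ++j)
    if (len[j] >= k) total_kmers += (size_t)(len[j] - k + 1);
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  index.reserve(total_kmers + total_kmers / 4);
  for (int j = 0; j < n; ++j)
    for_each_kmer(fwd[j], k, 1, [&](uint64_t x, int pos) {
      index[x].push_back({j, pos});
    });

  std::unordered_map<uint64_t, Overlap> best;  // keyed by (i,j)
  best.reserve((size_t)n * 4);
  std::vector<std::pair<int, int>> cand;  // (j, offset) for one orientation
  for (int i = 0; i < n; ++i) {
    int accepted = 0;
    for (int orient = 0; orient < 2 && accepted < max_accept; ++orient) {
      const std::vector<uint8_t> &qi = orient ? rev[i] : fwd[i];
      cand.clear();
      for_each_kmer(qi, k, step, [&](uint64_t x, int qpos) {
        if (cand.size() >= 8 * max_eval) return;
        auto it = index.find(x);
        if (it == index.end()) return;
        for (auto &hit : it->second)
          if (hit.first > i) cand.push_back({hit.first, hit.second - qpos});
      });
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      if (cand.size() > max_eval) cand.resize(max_eval);
      for (auto &cj : cand) {
        if (accepted >= max_accept) break;
        int j = cj.first, offset = cj.second;
        int ovl, matches;
        eval_overlap(qi, fwd[j], offset, ovl, matches);
        int shorter = std::min(len[i], len[j]);
        if (ovl < min_overlap_abs ||
            ovl + 1e-9 < min_overlap_frac * shorter)
          continue;
        if ((double)matches < min_identity * ovl - 1e-9) continue;
        Overlap o{i, j, orient, offset, ovl, matches};
        uint64_t pk = ((uint64_t)i << 32) | (uint32_t)j;
        auto bi = best.find(pk);
        if (bi == best.end()) {
          best[pk] = o;
          ++accepted;
          continue;
        }
        Overlap &b = bi->second;
        double ident_o = (double)o.matches / o.ovl;
        double ident_b = (double)b.matches / b.ovl;
        if (o.ovl > b.ovl ||
            (o.ovl == b.ovl && (ident_o > ident_b + 1e-12 ||
             (std::abs(ident_o - ident_b) <= 1e-12 &&
              (o.orient < b.orient ||
               (o.orient == b.orient && o.offset < b.offset))))))
          b = o;
      }
    }
  }

  std::vector<Overlap> ovls;
  ovls.reserve(best.size());
  for (auto &kv : best) ovls.push_back(kv.second);
  std::sort(ovls.begin(), ovls.end(), [&](const Overlap &a, const Overlap &b) {
    if (a.ovl != b.ovl) return a.ovl > b.ovl;
    double ia = (double)a.matches / a.ovl, ib = (double)b.matches / b.ovl;
    if (ia != ib) return ia > ib;
    int ra = std::min(rank[a.i], rank[a.j]), rb = std::min(rank[b.i], rank[b.j]);
    if (ra != rb) return ra < rb;
    ra = std::max(rank[a.i], rank[a.j]); rb = std::max(rank[b.i], rank[b.j]);
    if (ra != rb) return ra < rb;
    if (a.orient != b.orient) return a.orient < b.orient;
    return a.offset < b.offset;
  });

  UnionFind uf(n);
  for (const Overlap &o : ovls) {
    Transform ti, tj;
    int ri = uf.find(o.i, ti), rj = uf.find(o.j, tj);
    if (ri == rj) continue;  // already placed; keep first (best) placement
    // transform i-frame -> j-frame
    Transform tij;
    if (o.orient == 0) tij = {0, o.offset};
    else tij = {1, (long long)o.offset + len[o.i] - 1};
    // ri-frame -> rj-frame
    Transform t = compose(compose(invert(ti), tij), tj);
    if (uf.size[ri] >= uf.size[rj]) {
      uf.parent[rj] = ri;
      uf.up[rj] = invert(t);
      uf.size[ri] += uf.size[rj];
    } else {
      uf.parent[ri] = rj;
      uf.up[ri] = t;
      uf.size[rj] += uf.size[ri];
    }
  }

  // gather components
  std::vector<int> root(n), strand(n);
  std::vector<long long> start(n);
  std::unordered_map<int, std::vector<int>> comps;
  for (int i = 0; i < n; ++i) {
    Transform t;
    int r = uf.find(i, t);
    root[i] = r;
    strand[i] = t.s;
    start[i] = t.s ? (t.o - (len[i] - 1)) : t.o;
    comps[r].push_back(i);
  }
  std::vector<int> roots;
  for (auto &kv : comps) roots.push_back(kv.first);
  std::sort(roots.begin(), roots.end(), [&](int a, int b) {
    return *std::min_element(comps[a].begin(), comps[a].end()) <
           *std::min_element(comps[b].begin(), comps[b].end());
  });

  int nc = (int)roots.size();
  List members(nc), offsets(nc), strands(nc);
  CharacterVector consensus(nc);
  NumericVector mean_cov(nc);
  LogicalVector ambiguous(nc);
  const char *bases = "ACGTN";
  for (int c = 0; c < nc; ++c) {
    std::vector<int> &mem = comps[roots[c]];
    std::sort(mem.begin(), mem.end());
    long long mn = start[mem[0]], mx = start[mem[0]] + len[mem[0]];
    for (int m : mem) {
      mn = std::min(mn, start[m]);
      mx = std::max(mx, start[m] + len[m]);
    }
    int L = (int)(mx - mn);
    std::vector<std::array<int, 4>> cnt((size_t)L, {0, 0, 0, 0});
    long long total_bases = 0;
    for (int m : mem) {
      const std::vector<uint8_t> &s = strand[m] ? rev[m] : fwd[m];
      int off = (int)(start[m] - mn);
      for (int p = 0; p < len[m]; ++p)
        if (s[p] < 4) { cnt[off + p][s[p]]++; total_bases++; }
    }
    std::string cons(L, 'N');
    bool amb = false;
    for (int p = 0; p < L; ++p) {
      int bi = 4, bv = 0;
      for (int b = 0; b < 4; ++b)
        if (cnt[p][b] > bv) { bv = cnt[p][b]; bi = b; }
      cons[p] = bases[bi];
      if (bi == 4) amb = true;
    }
    IntegerVector mm(mem.size()), oo(mem.size()), ss(mem.size());
    for (size_t q = 0; q < mem.size(); ++q) {
      mm[q] = mem[q] + 1;
      oo[q] = (int)(start[mem[q]] - mn);
      ss[q] = strand[mem[q]];
    }
    members[c] = mm;
    offsets[c] = oo;
    strands[c] = ss;
    consensus[c] = cons;
    mean_cov[c] = (double)total_bases / L;
    ambiguous[c] = amb;
  }
  return List::create(Named("members") = members,
                      Named("offsets") = offsets,
                      Named("strands") = strands,
                      Named("consensus") = consensus,
                      Named("mean_coverage") = mean_cov,
                      Named("ambiguous") = ambiguous);
}

// ---------------------------------------------------------------------------
// ungapped seed-and-extend local search (match +1 / mismatch -2, X-drop)

struct Hsp {
  int q, s, strand;
  int qstart, qend, sstart, send;  // 0-based half-open, oriented query frame
  int length, matches, score;
};

static void extend_hsp(const std::vector<uint8_t> &q,
                       const std::vector<uint8_t> &s, int qpos, int spos,
                       int k, int xdrop, Hsp &out) {
  // seed assumed exact over k columns
  int score = k, best = k;
  int qe = qpos + k, se = spos + k;
  int best_qe = qe;
  int lq = (int)q.size(), ls = (int)s.size();
  // right extension
  int cq = qe, cs = se, run = score;
  while (cq < lq && cs < ls) {
    run += (q[cq] == s[cs] && q[cq] < 4) ? 1 : -2;
    ++cq; ++cs;
    if (run > best) { best = run; best_qe = cq; }
    if (run < best - xdrop) break;
  }
  // left extension
  int best_qs = qpos;
  int lrun = best, lbest = best;
  cq = qpos - 1; cs = spos - 1;
  while (cq >= 0 && cs >= 0) {
    lrun += (q[cq] == s[cs] && q[cq] < 4) ? 1 : -2;
    if (lrun > lbest) { lbest = lrun; best_qs = cq; }
    if (lrun < lbest - xdrop) break;
    --cq; --cs;
  }
  out.qstart = best_qs;
  out.qend = best_qe;
  out.sstart = spos - (qpos - best_qs);
  out.send = se + (best_qe - (qpos + k));
  out.length = out.qend - out.qstart;
  out.score = lbest;
  int matches = 0;
  for (int i = 0; i < out.length; ++i)
    if (q[out.qstart + i] == s[out.sstart + i] && q[out.qstart + i] < 4)
      ++matches;
  out.matches = matches;
}

// [[Rcpp::export]]
DataFrame cpp_local_search(CharacterVector qseqs, CharacterVector sseqs,
                           int word, int xdrop, int min_score) {
  int nq = qseqs.size(), ns = sseqs.size();
  std::vector<std::vector<uint8_t>> subj(ns);
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  for (int j = 0; j < ns; ++j) {
    subj[j] = encode(as<std::string>(sseqs[j]));
    for_each_kmer(subj[j], word, 1, [&](uint64_t x, int pos) {
      index[x].push_back({j, pos});
    });
  }

  std::vector<Hsp> results;
  std::unordered_map<uint64_t, size_t> best_for_pair;
  std::unordered_set<uint64_t> diag_seen;
  for (int qi = 0; qi < nq; ++qi) {
    std::vector<uint8_t> qf = encode(as<std::string>(qseqs[qi]));
    for (int strand = 0; strand < 2; ++strand) {
      std::vector<uint8_t> q = strand ? revcomp(qf) : qf;
      diag_seen.clear();
      for_each_kmer(q, word, 1, [&](uint64_t x, int qpos) {
        auto it = index.find(x);
        if (it == index.end()) return;
        for (auto &hit : it->second) {
          int j = hit.first, spos = hit.second;
          int diag = spos - qpos;
          uint64_t dkey = ((uint64_t)j << 33) | (uint32_t)(diag + (1 << 30));
          if (!diag_seen.insert(dkey).second) continue;
          Hsp h;
          h.q = qi; h.s = j; h.strand = strand;
          extend_hsp(q, subj[j], qpos, spos, word, xdrop, h);
          if (h.score < min_score) continue;
          uint64_t pk = ((uint64_t)qi << 32) | (uint32_t)j;
          auto bf = best_for_pair.find(pk);
          if (bf == best_for_pair.end()) {
            best_for_pair[pk] = results.size();
            results.push_back(h);
          } else {
            Hsp &b = results[bf->second];
            if (h.score > b.score ||
                (h.score == b.score && (h.length > b.length ||
                 (h.length == b.length && h.strand < b.strand))))
              b = h;
          }
        }
      });
    }
  }

  int m = (int)results.size();
  IntegerVector q(m), s(m), strand(m), qstart(m), qend(m), sstart(m),
      send(m), length(m), matches(m), score(m);
  for (int i = 0; i < m; ++i) {
    const Hsp &h = results[i];
    q[i] = h.q + 1;
    s[i] = h.s + 1;
    strand[i] = h.strand;
    qstart[i] = h.qstart;
    qend[i] = h.qend;
    sstart[i] = h.sstart;
    send[i] = h.send;
    length[i] = h.length;
    matches[i] = h.matches;
    score[i] = h.score;
  }
  return DataFrame::create(
      Named("q") = q, Named("s") = s, Named("strand") = strand,
      Named("qstart") = qstart, Named("qend") = qend,
      Named("sstart") = sstart, Named("send") = send,
      Named("length") = length, Named("matches") = matches,
      Named("score") = score);
}

// ---------------------------------------------------------------------------
// read mapping against one reference

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, CharacterVector reference,
                   double min_identity, double min_frac, int word,
                   int xdrop) {
  std::vector<uint8_t> ref = encode(as<std::string>(reference[0]));
  int L = (int)ref.size();
  std::unordered_map<uint64_t, std::vector<int>> index;
  for_each_kmer(ref, word, 1, [&](uint64_t x, int pos) {
    index[x].push_back(pos);
  });

  int n = reads.size();
  LogicalVector mapped(n);
  IntegerVector coverage(L);
  std::unordered_set<uint64_t> diag_seen;
  for (int i = 0; i < n; ++i) {
    std::vector<uint8_t> rf = encode(as<std::string>(reads[i]));
    int rl = (int)rf.size();
    Hsp best;
    best.score = -1;
    for (int strand = 0; strand < 2; ++strand) {
      std::vector<uint8_t> q = strand ? revcomp(rf) : rf;
      diag_seen.clear();
      for_each_kmer(q, word, 1, [&](uint64_t x, int qpos) {
        auto it = index.find(x);
        if (it == index.end()) return;
        for (int spos : it->second) {
          int diag = spos - qpos;
          uint64_t dkey = (uint32_t)(diag + (1 << 30));
          if (!diag_seen.insert(dkey).second) continue;
          Hsp h;
          h.q = i; h.s = 0; h.strand = strand;
          // subject here is the reference
          std::vector<uint8_t> &sref = ref;
          extend_hsp(q, sref, qpos, spos, word, xdrop, h);
          if (h.score > best.score ||
              (h.score == best.score && h.length > best.length))
            best = h;
        }
      });
    }
    bool ok = best.score >= 0 && best.length >= min_frac * rl - 1e-9 &&
              best.matches >= min_identity * best.length - 1e-9;
    mapped[i] = ok;
    if (ok)
      for (int p = best.sstart; p < best.send && p < L; ++p)
        if (p >= 0) coverage[p]++;
  }
  return List::create(Named("mapped") = mapped,
                      Named("coverage") = coverage);
}
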