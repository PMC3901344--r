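#include <Rcpp.h>
#include <array>
#include <map>
#include <queue>
#include <unordered_map>
using namespace Rcpp;

// Greedy overlap-layout assembly of substitution-only short reads.
//
// Contigs are repeatedly merged at their longest suffix-prefix overlap of
// length >= min_overlap with ungapped identity >= min_identity, both strands
// considered. Consensus is per-position majority vote over the reads
// supporting each column. Input reads are deduplicated onto a canonical
// strand and sorted, which makes the whole procedure independent of read
// order; remaining ties are broken by the lexicographically smaller merged
// sequence.

namespace {

struct Contig {
  std::string seq;
  std::vector<std::array<int, 4>> cnt;  // per-position A,C,G,T support
  long nreads = 0;
  long plus = 0, minus = 0;             // strand votes of member reads
  bool alive = true;
  int version = 0;
};

int base_idx(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; default: return 3;
  }
}
char idx_base(int i) { return "ACGT"[i]; }

std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
    }
  }
  return r;
}

bool encode_kmer(const std::string &s, int pos, int k, uint64_t &out) {
  uint64_t h = 0;
  for (int i = 0; i < k; ++i) {
    h = (h << 2) | static_cast<uint64_t>(base_idx(s[pos + i]));
  }
  out = h;
  return true;
}

struct IdxEntry {
  int id;
  bool rc;
  uint8_t off;  // k-mer offset into the (oriented) contig prefix
};

struct Assembler {
  int min_overlap;
  double min_identity;
  int k;
  static const int max_seed_off = 32;
  std::vector<Contig> contigs;
  // k-mers of the first max_seed_off+1 positions of each contig (both
  // orientations). Seeding at several offsets keeps merges findable when a
  // contig's very first bases carry read errors (coverage-1 regions).
  std::unordered_map<uint64_t, std::vector<IdxEntry>> prefix_idx;

  void index_contig(int id) {
    const Contig &c = contigs[id];
    int len = c.seq.size();
    if (len < k) return;
    int omax = std::min(max_seed_off, len - k);
    std::string rc = revcomp(c.seq);
    for (int o = 0; o <= omax; ++o) {
      uint64_t h;
      encode_kmer(c.seq, o, k, h);
      prefix_idx[h].push_back({id, false, (uint8_t)o});
      encode_kmer(rc, o, k, h);
      prefix_idx[h].push_back({id, true, (uint8_t)o});
    }
  }

  // Count mismatches between suffix of a (last L chars) and prefix of b.
  bool overlap_ok(const std::string &a, const std::string &b, int L) {
    int allowed = (int)std::floor((1.0 - min_identity) * L + 1e-9);
    int mm = 0;
    int off = (int)a.size() - L;
    for (int t = 0; t < L; ++t) {
      if (a[off + t] != b[t] && ++mm > allowed) return false;
    }
    return true;
  }

  // Best merge partner for contig i as the left-hand side: the partner j
  // (possibly reverse-complemented) with the longest qualifying
  // suffix-prefix overlap. Both orientations of i itself are searched
  // (a merge whose left side is the reverse complement of i is otherwise
  // invisible when j's stored orientation does not cooperate). Returns
  // the overlap length or 0; `out_rc_i` says whether i must be flipped
  // before merging.
  int best_partner(int i, int &out_j, bool &out_rc, bool &out_rc_i) {
    int bestL = 0; int bestj = -1; bool bestrc = false, bestrci = false;
    std::string bestmerged;
    for (int irc = 0; irc < 2; ++irc) {
      const std::string iseq = irc ? revcomp(contigs[i].seq)
                                   : contigs[i].seq;
      int leni = iseq.size();
      // a seed window at position p of i matching offset o of a partner's
      // prefix implies an overlap of L = leni - p + o
      for (int p = leni - k; p >= 0; --p) {
        if (leni - p + max_seed_off < min_overlap) continue;
        uint64_t h;
        encode_kmer(iseq, p, k, h);
        auto it = prefix_idx.find(h);
        if (it == prefix_idx.end()) continue;
        for (auto &cand : it->second) {
          int j = cand.id;
          if (j == i || !contigs[j].alive) continue;
          int L = leni - p + cand.off;
          if (L < min_overlap || L >= leni) continue;
          if (L < bestL) continue;
          const std::string jseq = cand.rc ? revcomp(contigs[j].seq)
                                           : contigs[j].seq;
          int lenj = jseq.size();
          if (lenj < cand.off + k) continue;
          // stale index entry: contig changed since indexing
          uint64_t hj; encode_kmer(jseq, cand.off, k, hj);
          if (hj != h) continue;
          if (lenj <= L) continue;  // containment, handled separately
          if (!overlap_ok(iseq, jseq, L)) continue;
          if (L > bestL) {
            bestL = L; bestj = j; bestrc = cand.rc; bestrci = (irc == 1);
            bestmerged = iseq + jseq.substr(L);
          } else {  // tie: lexicographically smallest merged sequence
            std::string merged = iseq + jseq.substr(L);
            if (bestj < 0 || merged < bestmerged) {
              bestj = j; bestrc = cand.rc; bestrci = (irc == 1);
              bestmerged = merged;
            }
          }
        }
      }
    }
    if (bestj < 0) return 0;
    out_j = bestj; out_rc = bestrc; out_rc_i = bestrci;
    return bestL;
  }

  void flip(Contig &c) {
    c.seq = revcomp(c.seq);
    std::reverse(c.cnt.begin(), c.cnt.end());
    for (auto &a : c.cnt) {
      std::swap(a[0], a[3]);  // A<->T
      std::swap(a[1], a[2]);  // C<->G
    }
    std::swap(c.plus, c.minus);
  }

  int merge(int i, int j, bool rc_j, int L) {
    Contig cj = contigs[j];
    if (rc_j) flip(cj);
    Contig &ci = contigs[i];
    Contig m;
    int leni = ci.seq.size(), lenj = cj.seq.size();
    m.cnt = ci.cnt;
    int off = leni - L;
    for (int t = 0; t < L; ++t) {
      for (int x = 0; x < 4; ++x) m.cnt[off + t][x] += cj.cnt[t][x];
    }
    for (int t = L; t < lenj; ++t) m.cnt.push_back(cj.cnt[t]);
    m.seq.resize(m.cnt.size());
    for (size_t t = 0; t < m.cnt.size(); ++t) {
      int bx = 0;
      for (int x = 1; x < 4; ++x) if (m.cnt[t][x] > m.cnt[t][bx]) bx = x;
      m.seq[t] = idx_base(bx);
    }
    m.nreads = ci.nreads + cj.nreads;
    m.plus = ci.plus + cj.plus;
    m.minus = ci.minus + cj.minus;
    contigs[i].alive = false;
    contigs[j].alive = false;
    contigs.push_back(std::move(m));
    int id = contigs.size() - 1;
    index_contig(id);
    return id;
  }

  // One greedy pass: longest-overlap-first merging driven by a lazy
  // max-heap. Returns the number of merges performed. A contig whose best
  // overlap was interior to a partner at the time its entry was examined
  // can become mergeable later, so the caller iterates passes to a
  // fixpoint.
  long run_pass() {
    using Entry = std::tuple<int, std::string, int, int>;  // L, seq, id, ver
    auto cmp = [](const Entry &a, const Entry &b) {
      if (std::get<0>(a) != std::get<0>(b))
        return std::get<0>(a) < std::get<0>(b);      // larger L first
      return std::get<1>(a) > std::get<1>(b);        // smaller seq first
    };
    std::priority_queue<Entry, std::vector<Entry>, decltype(cmp)> heap(cmp);
    for (int i = 0; i < (int)contigs.size(); ++i) {
      if (!contigs[i].alive) continue;
      int j; bool rc, rci;
      int L = best_partner(i, j, rc, rci);
      if (L > 0) heap.push({L, contigs[i].seq, i, contigs[i].version});
    }
    long merges = 0;
    while (!heap.empty()) {
      auto [L, seq, i, ver] = heap.top();
      heap.pop();
      if (!contigs[i].alive || contigs[i].version != ver) continue;
      int j; bool rc, rci;
      int Lnow = best_partner(i, j, rc, rci);
      if (Lnow == 0) continue;
      if (Lnow < L) {  // partner changed; requeue at current priority
        heap.push({Lnow, contigs[i].seq, i, contigs[i].version});
        continue;
      }
      if (rci) {
        flip(contigs[i]);
        contigs[i].version++;
      }
      int id = merge(i, j, rc, Lnow);
      ++merges;
      int j2; bool rc2, rci2;
      int L2 = best_partner(id, j2, rc2, rci2);
      if (L2 > 0) heap.push({L2, contigs[id].seq, id, contigs[id].version});
    }
    return merges;
  }

  void run() {
    long m;
    int pass = 0;
    while ((m = run_pass()) > 0) {
      ++pass;
      if (std::getenv("MINICHROM_ASM_DEBUG"))
        Rprintf("pass %d merges %ld\n", pass, m);
    }
  }

  // Absorb contigs that are exact substrings (either strand) of a longer
  // surviving contig: their reads support interior columns.
  void absorb_contained() {
    std::vector<int> alive_ids;
    for (int i = 0; i < (int)contigs.size(); ++i)
      if (contigs[i].alive) alive_ids.push_back(i);
    std::sort(alive_ids.begin(), alive_ids.end(), [&](int a, int b) {
      if (contigs[a].seq.size() != contigs[b].seq.size())
        return contigs[a].seq.size() > contigs[b].seq.size();
      return contigs[a].seq < contigs[b].seq;
    });
    for (size_t s = 1; s < alive_ids.size(); ++s) {
      int small = alive_ids[s];
      for (size_t t = 0; t < s; ++t) {
        int big = alive_ids[t];
        if (!contigs[big].alive || !contigs[small].alive) continue;
        if (contigs[big].seq.size() <= contigs[small].seq.size()) continue;
        size_t pos = contigs[big].seq.find(contigs[small].seq);
        bool rc = false;
        if (pos == std::string::npos) {
          pos = contigs[big].seq.find(revcomp(contigs[small].seq));
          rc = true;
        }
        if (pos == std::string::npos) continue;
        Contig cs = contigs[small];
        if (rc) flip(cs);
        Contig &cb = contigs[big];
        for (size_t u = 0; u < cs.seq.size(); ++u)
          for (int x = 0; x < 4; ++x) cb.cnt[pos + u][x] += cs.cnt[u][x];
        cb.nreads += cs.nreads;
        cb.plus += cs.plus;
        cb.minus += cs.minus;
        contigs[small].alive = false;
        break;
      }
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List assemble_reads(CharacterVector reads, int min_overlap,
                    double min_identity) {
  if (reads.size() == 0) stop("empty read set");
  if (min_identity <= 0 || min_identity > 1)
    stop("min_identity must be in (0, 1]");
  // Deduplicate onto a canonical strand; sorted map gives a deterministic,
  // permutation-independent starting order.
  std::map<std::string, std::pair<long, long>> uniq;  // seq -> (plus, minus)
  for (int i = 0; i < reads.size(); ++i) {
    std::string r = as<std::string>(reads[i]);
    std::string rc = revcomp(r);
    if (rc < r) {
      uniq[rc].second += 1;
    } else {
      uniq[r].first += 1;
    }
  }
  Assembler asmb;
  asmb.min_overlap = min_overlap;
  asmb.min_identity = min_identity;
  asmb.k = std::min(16, min_overlap);
  for (auto &kv : uniq) {
    Contig c;
    c.seq = kv.first;
    c.cnt.assign(c.seq.size(), {0, 0, 0, 0});
    long support = kv.second.first + kv.second.second;
    for (size_t t = 0; t < c.seq.size(); ++t)
      c.cnt[t][base_idx(c.seq[t])] = (int)support;
    c.nreads = support;
    c.plus = kv.second.first;
    c.minus = kv.second.second;
    asmb.contigs.push_back(std::move(c));
  }
  for (int i = 0; i < (int)asmb.contigs.size(); ++i) asmb.index_contig(i);
  asmb.run();
  asmb.absorb_contained();
  std::vector<int> out_ids;
  for (int i = 0; i < (int)asmb.contigs.size(); ++i)
    if (asmb.contigs[i].alive) out_ids.push_back(i);
  std::sort(out_ids.begin(), out_ids.end(), [&](int a, int b) {
    if (asmb.contigs[a].seq.size() != asmb.contigs[b].seq.size())
      return asmb.contigs[a].seq.size() > asmb.contigs[b].seq.size();
    return asmb.contigs[a].seq < asmb.contigs[b].seq;
  });
  List out(out_ids.size());
  for (size_t s = 0; s < out_ids.size(); ++s) {
    Contig &c = asmb.contigs[out_ids[s]];
    // report on the strand supported by the majority of member reads
    bool flip_out = (c.minus > c.plus);
    std::string seq = flip_out ? revcomp(c.seq) : c.seq;
    IntegerVector support(c.cnt.size());
    for (size_t t = 0; t < c.cnt.size(); ++t) {
      int tot = 0;
      for (int x = 0; x < 4; ++x) tot += c.cnt[t][x];
      support[flip_out ? (c.cnt.size() - 1 - t) : t] = tot;
    }
    out[s] = List::create(_["sequence"] = seq,
                          _["n_reads"] = (double)c.nreads,
                          _["support"] = support);
  }
  return out;
}

// In-silico circularity check: if the contig's prefix and suffix overlap by
// >= min_overlap at >= min_identity, trim the terminal redundancy and call
// the contig circular. Longest qualifying self-overlap (up to half the
// contig) is used, so a perfectly doubled circle collapses to one copy.
// [[Rcpp::export]]
List circularize_contig(std::string seq, int min_overlap,
                        double min_identity) {
  int n = seq.size();
  for (int L = n / 2; L >= min_overlap; --L) {
    int allowed = (int)std::floor((1.0 - min_identity) * L + 1e-9);
    int mm = 0;
    bool ok = true;
    int off = n - L;
    for (int t = 0; t < L; ++t) {
      if (seq[t] != seq[off + t] && ++mm > allowed) { ok = false; break; }
    }
    if (ok) {
      return List::create(_["sequence"] = seq.substr(0, n - L),
                          _["circular"] = true);
    }
  }
  return List::create(_["sequence"] = seq, _["circular"] = false);
}
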