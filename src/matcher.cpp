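#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Seed-and-extend read matcher against a small panel of reference
// sequences, with a fitting-alignment DP rescue for indel-containing
// reads.  Discordances are counted as events: one mismatched base or one
// indel run of any length each count 1.

static const int NEG = -1;

static inline int base2bit(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return NEG;
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    default: c = 'N';
    }
  }
  return r;
}

struct Hit {
  int ref;       // 0-based reference index
  int strand;    // +1 forward, -1 reverse complement
  int start;     // 0-based start on reference
  int span;      // reference span of the alignment
  int nevent;    // discordance events
  std::string edits;
};

// k-mer index over the references: encoded k-mer -> (ref, pos) list
struct SeedIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > map;
};

static void build_index(const std::vector<std::string>& refs, int k, SeedIndex& idx) {
  idx.k = k;
  idx.map.clear();
  for (int r = 0; r < (int)refs.size(); ++r) {
    const std::string& s = refs[r];
    if ((int)s.size() < k) continue;
    uint64_t key = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int run = 0;  // valid bases accumulated
    for (int i = 0; i < (int)s.size(); ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k) idx.map[key].emplace_back(r, i - k + 1);
    }
  }
}

// count mismatches of read placed at refstart (full containment), abort
// early past maxmm; fill positions if within budget
static int count_mismatches(const std::string& read, const std::string& ref,
                            int refstart, int maxmm, std::vector<int>& pos) {
  pos.clear();
  int n = read.size();
  if (refstart < 0 || refstart + n > (int)ref.size()) return maxmm + 1;
  int mm = 0;
  for (int i = 0; i < n; ++i) {
    if (read[i] != ref[refstart + i]) {
      if (++mm > maxmm) return mm;
      pos.push_back(i);
    }
  }
  return mm;
}

// Fitting alignment of the whole read into a reference window with
// event costs (mismatch 1, gap-open 1, gap-extend 0).  Leading/trailing
// reference bases are free; the read must be consumed in full (overhangs
// become insertion events).  Returns nevent or INF if > maxmm, and the
// edit transcript in reference coordinates.
static int fit_align(const std::string& read, const std::string& ref,
                     int ws, int we, int maxmm,
                     int& out_start, int& out_span, std::string& out_edits) {
  const int INF = 1000000;
  int n = read.size();
  if (ws < 0) ws = 0;
  if (we > (int)ref.size()) we = ref.size();
  int m = we - ws;
  if (m <= 0) return INF;
  // states: 0 = M (diag), 1 = I (read gap / insertion), 2 = D (ref gap /
  // deletion).  Primary objective: minimize event cost; secondary:
  // maximize diagonal (aligned) columns, so degenerate all-insertion
  // alignments never shadow a real placement.
  std::vector<int> M((n + 1) * (m + 1), INF), I((n + 1) * (m + 1), INF),
      D((n + 1) * (m + 1), INF);
  std::vector<int> dM((n + 1) * (m + 1), -1), dI((n + 1) * (m + 1), -1),
      dD((n + 1) * (m + 1), -1);
  std::vector<signed char> bM((n + 1) * (m + 1), -1), bI((n + 1) * (m + 1), -1),
      bD((n + 1) * (m + 1), -1);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  auto better = [](int c1, int d1, int c2, int d2) {
    return c1 < c2 || (c1 == c2 && d1 > d2);
  };
  for (int j = 0; j <= m; ++j) { M[at(0, j)] = 0; dM[at(0, j)] = 0; }
  for (int i = 1; i <= n; ++i) {
    int rowmin = INF;
    for (int j = 0; j <= m; ++j) {
      // insertion: consume read base, no ref base; only interior
      // insertions are allowed (the read aligns end to end), so an
      // insertion cannot open before the first aligned read base
      int open = (i == 1 || M[at(i - 1, j)] == INF) ? INF : M[at(i - 1, j)] + 1;
      if (better(open, dM[at(i - 1, j)], I[at(i - 1, j)], dI[at(i - 1, j)])) {
        I[at(i, j)] = open; dI[at(i, j)] = dM[at(i - 1, j)]; bI[at(i, j)] = 0;
      } else {
        I[at(i, j)] = I[at(i - 1, j)]; dI[at(i, j)] = dI[at(i - 1, j)];
        bI[at(i, j)] = 1;
      }
      if (j >= 1) {
        // match/mismatch
        int sub = read[i - 1] == ref[ws + j - 1] ? 0 : 1;
        int best = INF, bd = -1; signed char bp = -1;
        if (better(M[at(i - 1, j - 1)], dM[at(i - 1, j - 1)], best, bd)) {
          best = M[at(i - 1, j - 1)]; bd = dM[at(i - 1, j - 1)]; bp = 0;
        }
        if (better(I[at(i - 1, j - 1)], dI[at(i - 1, j - 1)], best, bd)) {
          best = I[at(i - 1, j - 1)]; bd = dI[at(i - 1, j - 1)]; bp = 1;
        }
        if (better(D[at(i - 1, j - 1)], dD[at(i - 1, j - 1)], best, bd)) {
          best = D[at(i - 1, j - 1)]; bd = dD[at(i - 1, j - 1)]; bp = 2;
        }
        if (best < INF) {
          M[at(i, j)] = best + sub; dM[at(i, j)] = bd + 1; bM[at(i, j)] = bp;
        }
        // deletion: consume ref base, no read base
        int dopen = M[at(i, j - 1)] == INF ? INF : M[at(i, j - 1)] + 1;
        if (better(dopen, dM[at(i, j - 1)], D[at(i, j - 1)], dD[at(i, j - 1)])) {
          D[at(i, j)] = dopen; dD[at(i, j)] = dM[at(i, j - 1)]; bD[at(i, j)] = 0;
        } else {
          D[at(i, j)] = D[at(i, j - 1)]; dD[at(i, j)] = dD[at(i, j - 1)];
          bD[at(i, j)] = 1;
        }
      }
      rowmin = std::min(rowmin, std::min(M[at(i, j)],
                        std::min(I[at(i, j)], D[at(i, j)])));
    }
    // costs only grow down rows: once every cell exceeds the event budget
    // no alignment within it exists
    if (rowmin > maxmm) return INF;
  }
  // best end: state M at row n, any column (trailing ref is free, but the
  // alignment must not end inside a gap -- no trailing indels)
  int best = INF, bdiag = -1, bj = -1, bs = -1;
  for (int j = 0; j <= m; ++j) {
    if (better(M[at(n, j)], dM[at(n, j)], best, bdiag)) {
      best = M[at(n, j)]; bdiag = dM[at(n, j)]; bj = j; bs = 0;
    }
  }
  if (best > maxmm) return INF;
  // traceback
  struct Ed { char type; int pos; std::string seq; };
  std::vector<Ed> eds;
  int i = n, j = bj, st = bs;
  int end_j = bj;
  while (i > 0) {
    if (st == 0) {  // M
      signed char bp = bM[at(i, j)];
      if (read[i - 1] != ref[ws + j - 1]) {
        eds.push_back({'X', ws + j - 1,
                       std::string(1, ref[ws + j - 1]) + ">" + read[i - 1]});
      }
      --i; --j; st = bp;
    } else if (st == 1) {  // I: read base inserted before ref pos ws+j
      std::string ins;
      while (i > 0 && st == 1) {
        ins.insert(ins.begin(), read[i - 1]);
        signed char bp = bI[at(i, j)];
        --i;
        st = (bp == 0) ? 0 : 1;
      }
      eds.push_back({'I', ws + j, ins});
    } else {  // D: ref bases deleted
      std::string del;
      while (st == 2) {
        del.insert(del.begin(), ref[ws + j - 1]);
        signed char bp = bD[at(i, j)];
        --j;
        st = (bp == 0) ? 0 : 2;
      }
      eds.push_back({'D', ws + j, del});
    }
  }
  int start_j = j;  // alignment consumed ref window columns (start_j, end_j]
  out_start = ws + start_j;
  out_span = end_j - start_j;
  std::reverse(eds.begin(), eds.end());
  std::string tr;
  for (auto& e : eds) {
    if (!tr.empty()) tr += ";";
    tr += e.type;
    tr += std::to_string(e.pos);
    tr += ":";
    tr += e.seq;
  }
  out_edits = tr;
  return best;
}

// [[Rcpp::export]]
DataFrame cpp_match_reads(CharacterVector reads, CharacterVector refs,
                          int max_events = 2, int band = 8, int seed_len = 30,
                          bool indel_rescue = true) {
  std::vector<std::string> R(refs.size());
  for (int i = 0; i < refs.size(); ++i) R[i] = as<std::string>(refs[i]);
  SeedIndex idx;
  build_index(R, seed_len, idx);

  std::vector<int> o_read, o_ref, o_strand, o_start, o_span, o_nev;
  std::vector<std::string> o_edits;
  std::vector<int> mmpos;

  for (int q = 0; q < reads.size(); ++q) {
    std::string fwd = as<std::string>(reads[q]);
    bool any_sub_hit = false;
    // (candidate, strand) pairs that failed the ungapped pass; the gapped
    // rescue runs only when the whole read found no ungapped placement
    std::vector<std::pair<std::pair<int,int>,int> > failed_all;
    for (int strand = 0; strand < 2; ++strand) {
      std::string rd = strand == 0 ? fwd : revcomp(fwd);
      int n = rd.size();
      if (n < seed_len) continue;
      // pigeonhole seeds: max_events+1 non-overlapping k-mers (as many as fit)
      std::vector<int> offs;
      for (int s = 0; s <= max_events; ++s) {
        int off = s * seed_len;
        if (off + seed_len <= n) offs.push_back(off);
      }
      if ((int)offs.size() > 1 && offs.back() + seed_len < n)
        offs.back() = n - seed_len;  // cover the read tail
      std::unordered_set<long long> seen;
      std::vector<std::pair<int,int> > cands;  // (ref, diag start)
      for (int off : offs) {
        uint64_t key = 0; bool ok = true;
        for (int i = 0; i < seed_len; ++i) {
          int b = base2bit(rd[off + i]);
          if (b < 0) { ok = false; break; }
          key = (key << 2) | (uint64_t)b;
        }
        if (!ok) continue;
        auto it = idx.map.find(key);
        if (it == idx.map.end()) continue;
        for (auto& hp : it->second) {
          long long sig = ((long long)hp.first << 32) ^ (long long)(hp.second - off + (1 << 30));
          if (seen.insert(sig).second) cands.emplace_back(hp.first, hp.second - off);
        }
      }
      std::unordered_set<long long> emitted;
      for (auto& c : cands) {
        int mm = count_mismatches(rd, R[c.first], c.second, max_events, mmpos);
        if (mm <= max_events) {
          any_sub_hit = true;
          std::string tr;
          for (int p : mmpos) {
            if (!tr.empty()) tr += ";";
            tr += "X" + std::to_string(c.second + p) + ":" +
                  std::string(1, R[c.first][c.second + p]) + ">" + rd[p];
          }
          long long sig = ((long long)c.first << 33) ^ ((long long)c.second << 1);
          if (emitted.insert(sig).second) {
            o_read.push_back(q + 1); o_ref.push_back(c.first + 1);
            o_strand.push_back(strand == 0 ? 1 : -1);
            o_start.push_back(c.second); o_span.push_back(n);
            o_nev.push_back(mm); o_edits.push_back(tr);
          }
        } else if (indel_rescue) {
          failed_all.push_back({c, strand});
        }
      }
    }
    if (indel_rescue && !any_sub_hit) {
      std::unordered_set<long long> emitted;
      std::string rc = revcomp(fwd);
      for (auto& cs : failed_all) {
        const std::string& rd = cs.second == 0 ? fwd : rc;
        int n = rd.size();
        auto& c = cs.first;
        int st = 0, sp = 0; std::string tr;
        int ev = fit_align(rd, R[c.first], c.second - band, c.second + n + band,
                           max_events, st, sp, tr);
        if (ev <= max_events) {
          long long sig = ((long long)c.first << 33) ^ ((long long)st << 1) ^
                          (long long)cs.second;
          if (emitted.insert(sig).second) {
            o_read.push_back(q + 1); o_ref.push_back(c.first + 1);
            o_strand.push_back(cs.second == 0 ? 1 : -1);
            o_start.push_back(st); o_span.push_back(sp);
            o_nev.push_back(ev); o_edits.push_back(tr);
          }
        }
      }
    }
  }
  return DataFrame::create(_["read"] = o_read, _["ref"] = o_ref,
                           _["strand"] = o_strand, _["start"] = o_start,
                           _["span"] = o_span, _["nevent"] = o_nev,
                           _["edits"] = o_edits,
                           _["stringsAsFactors"] = false);
}

// All exact occurrences of each query within each subject.
// [[Rcpp::export]]
DataFrame cpp_find_occurrences(CharacterVector queries, CharacterVector subjects) {
  std::vector<int> o_q, o_s, o_start;
  for (int s = 0; s < subjects.size(); ++s) {
    std::string subj = as<std::string>(subjects[s]);
    for (int q = 0; q < queries.size(); ++q) {
      std::string pat = as<std::string>(queries[q]);
      if (pat.empty() || pat.size() > subj.size()) continue;
      size_t p = subj.find(pat, 0);
      while (p != std::string::npos) {
        o_q.push_back(q + 1); o_s.push_back(s + 1); o_start.push_back((int)p);
        p = subj.find(pat, p + 1);
      }
    }
  }
  return DataFrame::create(_["query"] = o_q, _["subject"] = o_s,
                           _["start"] = o_start);
}
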