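// Smith-Waterman local alignment with affine gaps, plus a seed-and-extend
// fragment mapper used for fragment-based ANI and scaffold rescue.
//
// Sequences arrive as 0-based integer codes (DNA: A=0, C=1, G=2, T=3,
// ambiguous >= 4; protein: row index into the substitution matrix).
// A gap of length L costs gap_open + L * gap_extend.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

const double NEG_INF = -1e30;

struct AlnResult {
  double score;
  int a_start, a_end, b_start, b_end; // 1-based inclusive; 0 when empty
  int matches, aligned;
  bool empty;
};

// Full affine-gap Smith-Waterman with traceback. Pointer matrices are
// byte-packed: bits 0-1 = H origin (0 stop, 1 diag, 2 E, 3 F),
// bit 2 = E extends E, bit 3 = F extends F.
AlnResult sw_full(const int* a, int na, const int* b, int nb,
                  const NumericMatrix& S, double go, double ge) {
  AlnResult res{0.0, 0, 0, 0, 0, 0, 0, true};
  if (na == 0 || nb == 0) return res;
  double bytes = (double)na * (double)nb;
  if (bytes > 2.5e8)
    stop("alignment matrix too large (%d x %d); use seed_and_extend()", na, nb);

  std::vector<uint8_t> ptr((size_t)na * nb, 0);
  std::vector<double> Hprev(nb + 1, 0.0), Hcur(nb + 1, 0.0);
  std::vector<double> Eprev; // E only depends on current row (gap in a)
  std::vector<double> Fcol(nb + 1, NEG_INF);
  double open = go + ge;

  double best = 0.0;
  int bi = 0, bj = 0;
  int ncode = S.nrow();

  for (int i = 1; i <= na; ++i) {
    double Erow = NEG_INF;
    Hcur[0] = 0.0;
    int ai = a[i - 1];
    for (int j = 1; j <= nb; ++j) {
      int bj_ = b[j - 1];
      double sub = (ai < ncode && bj_ < ncode) ? S(ai, bj_) : -1e9;
      uint8_t p = 0;
      // E: gap in a (moving along b)
      double e_open = Hcur[j - 1] - open;
      double e_ext = Erow - ge;
      if (e_ext > e_open) { Erow = e_ext; p |= 4; } else Erow = e_open;
      // F: gap in b (moving along a)
      double f_open = Hprev[j] - open;
      double f_ext = Fcol[j] - ge;
      if (f_ext > f_open) { Fcol[j] = f_ext; p |= 8; } else Fcol[j] = f_open;

      double diag = Hprev[j - 1] + sub;
      double h = 0.0; uint8_t o = 0;
      if (diag > h) { h = diag; o = 1; }
      if (Erow > h) { h = Erow; o = 2; }
      if (Fcol[j] > h) { h = Fcol[j]; o = 3; }
      Hcur[j] = h;
      ptr[(size_t)(i - 1) * nb + (j - 1)] = (uint8_t)(p | o);
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }

  res.score = best;
  if (best <= 0.0) return res;

  // traceback from the first (lowest i, then j) maximal cell
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
  int matches = 0, aligned = 0;
  int ae = bi, be = bj;
  while (i > 0 && j > 0) {
    uint8_t p = ptr[(size_t)(i - 1) * nb + (j - 1)];
    if (state == 0) {
      uint8_t o = p & 3;
      if (o == 0) break;
      if (o == 1) {
        ++aligned;
        if (a[i - 1] == b[j - 1]) ++matches;
        --i; --j;
      } else if (o == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // E: gap in a, consume b
      ++aligned;
      bool ext = (p & 4) != 0;
      --j;
      if (!ext) state = 0;
    } else { // F: gap in b, consume a
      ++aligned;
      bool ext = (p & 8) != 0;
      --i;
      if (!ext) state = 0;
    }
  }
  res.empty = false;
  res.a_start = i + 1; res.a_end = ae;
  res.b_start = j + 1; res.b_end = be;
  res.matches = matches; res.aligned = aligned;
  return res;
}

List aln_to_list(const AlnResult& r) {
  return List::create(
      _["score"] = r.score, _["a_start"] = r.a_start, _["a_end"] = r.a_end,
      _["b_start"] = r.b_start, _["b_end"] = r.b_end,
      _["matches"] = r.matches, _["aligned"] = r.aligned,
      _["empty"] = r.empty);
}

inline bool kmer_key(const int* s, int pos, int k, uint64_t& key) {
  key = 0;
  for (int t = 0; t < k; ++t) {
    int c = s[pos + t];
    if (c < 0 || c > 3) return false;
    key = (key << 2) | (uint64_t)c;
  }
  return true;
}

} // namespace

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double gap_open, double gap_extend) {
  AlnResult r = sw_full(INTEGER(a), a.size(), INTEGER(b), b.size(),
                        S, gap_open, gap_extend);
  return aln_to_list(r);
}

// Score-only banded-free Smith-Waterman (two rows, no traceback).
// [[Rcpp::export(name = ".sw_score_cpp")]]
double sw_score_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                    double gap_open, double gap_extend) {
  int na = a.size(), nb = b.size();
  if (na == 0 || nb == 0) return 0.0;
  std::vector<double> Hprev(nb + 1, 0.0), Hcur(nb + 1, 0.0), Fcol(nb + 1, NEG_INF);
  double open = gap_open + gap_extend;
  double best = 0.0;
  int ncode = S.nrow();
  const int* ap = INTEGER(a); const int* bp = INTEGER(b);
  for (int i = 1; i <= na; ++i) {
    double Erow = NEG_INF;
    Hcur[0] = 0.0;
    int ai = ap[i - 1];
    for (int j = 1; j <= nb; ++j) {
      int bj = bp[j - 1];
      double sub = (ai < ncode && bj < ncode) ? S(ai, bj) : -1e9;
      Erow = std::max(Hcur[j - 1] - open, Erow - gap_extend);
      Fcol[j] = std::max(Hprev[j] - open, Fcol[j] - gap_extend);
      double h = std::max(0.0, Hprev[j - 1] + sub);
      h = std::max(h, std::max(Erow, Fcol[j]));
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
  }
  return best;
}

// Map a set of DNA fragments onto a target sequence: exact k-mer seeds
// hashed once over the target, best-supported diagonal band selected per
// fragment and orientation, then full affine SW on the windowed target.
// Both strands are searched; the better-scoring orientation is reported
// (ties favour the forward strand). Returns one row per fragment.
// [[Rcpp::export(name = ".map_fragments_cpp")]]
DataFrame map_fragments_cpp(List frags, IntegerVector target, int k,
                            NumericMatrix S, double gap_open,
                            double gap_extend, int margin,
                            int max_hits_per_kmer) {
  int nt = target.size();
  const int* tp = INTEGER(target);
  std::unordered_map<uint64_t, std::vector<int>> index;
  if (nt >= k) {
    index.reserve((size_t)nt);
    for (int pos = 0; pos + k <= nt; ++pos) {
      uint64_t key;
      if (!kmer_key(tp, pos, k, key)) continue;
      auto& v = index[key];
      if ((int)v.size() < max_hits_per_kmer) v.push_back(pos);
    }
  }

  int nf = frags.size();
  NumericVector score(nf);
  NumericVector identity(nf);
  IntegerVector matches(nf), aligned(nf);
  IntegerVector q_start(nf), q_end(nf), t_start(nf), t_end(nf);
  CharacterVector strand(nf);
  LogicalVector has_hit(nf);

  for (int f = 0; f < nf; ++f) {
    IntegerVector fr = frags[f];
    int nq = fr.size();
    std::vector<int> fwd(fr.begin(), fr.end());
    std::vector<int> rev(nq);
    for (int i = 0; i < nq; ++i) {
      int c = fwd[nq - 1 - i];
      rev[i] = (c >= 0 && c <= 3) ? 3 - c : c;
    }

    AlnResult best{0.0, 0, 0, 0, 0, 0, 0, true};
    char best_strand = '+';
    int best_ws = 0;

    for (int ori = 0; ori < 2; ++ori) {
      const std::vector<int>& q = (ori == 0) ? fwd : rev;
      if (nq < k) continue;
      // collect seeds as (diag, tpos)
      std::vector<std::pair<int, int>> seeds;
      for (int pos = 0; pos + k <= nq; ++pos) {
        uint64_t key;
        if (!kmer_key(q.data(), pos, k, key)) continue;
        auto it = index.find(key);
        if (it == index.end()) continue;
        for (int tpos : it->second) seeds.push_back({tpos - pos, tpos});
      }
      if (seeds.empty()) continue;
      // vote on diagonal buckets of width 16
      std::unordered_map<int, int> votes;
      for (auto& s : seeds) votes[s.first >> 4]++;
      int best_bucket = 0, best_votes = -1;
      for (auto& kv : votes)
        if (kv.second > best_votes ||
            (kv.second == best_votes && kv.first < best_bucket)) {
          best_bucket = kv.first; best_votes = kv.second;
        }
      int dmin = (best_bucket - 1) << 4, dmax = ((best_bucket + 2) << 4) - 1;
      int ws = nt, we = 0;
      for (auto& s : seeds) {
        if (s.first < dmin || s.first > dmax) continue;
        int d = s.first;
        ws = std::min(ws, d);
        we = std::max(we, d + nq);
      }
      ws = std::max(0, ws - margin);
      we = std::min(nt, we + margin);
      if (we <= ws) continue;
      AlnResult r = sw_full(q.data(), nq, tp + ws, we - ws, S,
                            gap_open, gap_extend);
      if (!r.empty && r.score > best.score) {
        best = r; best_strand = (ori == 0) ? '+' : '-'; best_ws = ws;
      }
    }

    if (best.empty) {
      score[f] = 0.0; identity[f] = NA_REAL;
      matches[f] = 0; aligned[f] = 0;
      q_start[f] = NA_INTEGER; q_end[f] = NA_INTEGER;
      t_start[f] = NA_INTEGER; t_end[f] = NA_INTEGER;
      strand[f] = NA_STRING; has_hit[f] = false;
    } else {
      score[f] = best.score;
      identity[f] = best.aligned > 0 ? (double)best.matches / best.aligned : 0.0;
      matches[f] = best.matches; aligned[f] = best.aligned;
      int qs = best.a_start, qe = best.a_end;
      if (best_strand == '-') { // map back to forward fragment coordinates
        int nq2 = ((IntegerVector)frags[f]).size();
        qs = nq2 - best.a_end + 1;
        qe = nq2 - best.a_start + 1;
      }
      q_start[f] = qs; q_end[f] = qe;
      t_start[f] = best.b_start + best_ws; t_end[f] = best.b_end + best_ws;
      strand[f] = std::string(1, best_strand);
      has_hit[f] = true;
    }
  }

  return DataFrame::create(
      _["score"] = score, _["identity"] = identity, _["matches"] = matches,
      _["aligned"] = aligned, _["q_start"] = q_start, _["q_end"] = q_end,
      _["t_start"] = t_start, _["t_end"] = t_end, _["strand"] = strand,
      _["has_hit"] = has_hit, _["stringsAsFactors"] = false);
}
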