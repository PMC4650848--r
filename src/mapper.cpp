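// Seed-and-extend mapping of short reads against a unigene reference, and
// multi-sample pileup accumulation. Hot loops only; all policy (thresholds,
// genotype model, classification) lives in R.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static inline char comp_char(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g'; case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_char(c);
  return r;
}

struct Placement {
  int ref;        // 0-based reference index
  int start;      // 0-based reference start
  bool fwd;
  int mm;         // mismatches
  int gapbases;   // inserted + deleted bases
  int score;
  std::string cigar;
  bool valid;
  bool edge_mm;   // Hamming path: a mismatch within EDGE bases of an end
};

// Full small-window DP: global in the read, free leading/trailing gaps in
// the reference window. Affine gap costs (mismatch 3, gap open 4, gap
// extend 1) so a contiguous indel is strictly cheaper than an equivalent
// split placement -- keeps indel representation consistent across reads.
static Placement align_window(const std::string& read, const std::string& ref,
                              int ws, int we, int ref_idx, bool fwd,
                              int max_mm, int max_indel) {
  Placement out; out.valid = false;
  const int m = (int)read.size();
  const int n = we - ws;
  if (n <= 0) return out;
  const int INF = 1 << 28;
  const int MIS = 3, OPEN = 4, EXT = 1;
  const int W = n + 1;
  // three states: 0 = M (diag), 1 = I (read gap / insertion),
  //               2 = D (ref gap / deletion)
  std::vector<int> Mp(W), Ip(W), Dp(W), Mc(W), Ic(W), Dc(W);
  // tb packs, per (i, j, state), the predecessor state (2 bits each)
  std::vector<uint8_t> tb((size_t)(m + 1) * W);
  // terminal soft-clips: up to MAXCLIP bases at either read end may be
  // clipped at CLIP per base, so an indel (or error) in the last few bases
  // is clipped instead of being forced into fake substitutions -- the same
  // reason full-size aligners soft-clip read ends.
  const int CLIP = 1, MAXCLIP = 5;
  for (int j = 0; j <= n; ++j) { Mp[j] = 0; Ip[j] = INF; Dp[j] = INF; }
  int best_cost = INF, best_i = -1, best_j = -1; uint8_t best_state = 0;
  for (int i = 1; i <= m; ++i) {
    Mc[0] = INF;
    Ic[0] = OPEN + EXT * i;
    Dc[0] = INF;
    tb[(size_t)i * W] = 1 << 2;
    int rc = base_code(read[i - 1]);
    // fresh start with a clipped read prefix of i-1 bases
    int fresh = (i - 1 <= MAXCLIP) ? CLIP * (i - 1) : INF;
    for (int j = 1; j <= n; ++j) {
      int fc = base_code(ref[ws + j - 1]);
      int sub = (rc < 4 && rc == fc) ? 0 : MIS;
      // M state
      int bm = Mp[j - 1]; uint8_t pm = 0;
      if (Ip[j - 1] < bm) { bm = Ip[j - 1]; pm = 1; }
      if (Dp[j - 1] < bm) { bm = Dp[j - 1]; pm = 2; }
      if (fresh < bm) { bm = fresh; pm = 3; }
      Mc[j] = (bm >= INF) ? INF : bm + sub;
      // I state (consumes read base)
      int bi = Mp[j] + OPEN + EXT; uint8_t pi = 0;
      if (Ip[j] + EXT < bi) { bi = Ip[j] + EXT; pi = 1; }
      Ic[j] = (bi >= INF) ? INF : bi;
      // D state (consumes ref base)
      int bd = Mc[j - 1] + OPEN + EXT; uint8_t pd = 0;
      if (Dc[j - 1] + EXT < bd) { bd = Dc[j - 1] + EXT; pd = 2; }
      Dc[j] = (bd >= INF) ? INF : bd;
      tb[(size_t)i * W + j] = (uint8_t)(pm | (pi << 2) | (pd << 4));
      // finish here with a clipped read suffix of m-i bases
      if (m - i <= MAXCLIP) {
        int fin = Mc[j] + CLIP * (m - i);
        if (fin < best_cost) { best_cost = fin; best_i = i; best_j = j; best_state = 0; }
        fin = Ic[j] + CLIP * (m - i);
        if (fin < best_cost) { best_cost = fin; best_i = i; best_j = j; best_state = 1; }
      }
    }
    std::swap(Mp, Mc); std::swap(Ip, Ic); std::swap(Dp, Dc);
  }
  if (best_cost >= INF || best_i <= 0) return out;
  // traceback from the best end cell; tb holds predecessor states
  int i = best_i, j = best_j; uint8_t st = best_state;
  int suffix_clip = m - best_i, prefix_clip = 0;
  std::string ops; ops.reserve(m + 8);
  int mm = 0, gapb = 0;
  while (i > 0) {
    uint8_t packed = tb[(size_t)i * W + j];
    if (st == 0) {
      int rc = base_code(read[i - 1]);
      int fc = base_code(ref[ws + j - 1]);
      if (!(rc < 4 && rc == fc)) ++mm;
      ops.push_back('M');
      uint8_t pred = packed & 3;
      --i; --j;
      if (pred == 3) { prefix_clip = i; break; } // clipped read prefix
      st = pred;
      if (j < 0) return out;
    } else if (st == 1) {
      ops.push_back('I'); ++gapb;
      st = (packed >> 2) & 3; --i;
    } else {
      ops.push_back('D'); ++gapb;
      st = (packed >> 4) & 3; --j;
    }
  }
  if (mm > max_mm || gapb > max_indel) return out;
  std::reverse(ops.begin(), ops.end());
  // collapse run-length cigar, with soft-clip flanks
  std::string cig;
  if (prefix_clip > 0) { cig += std::to_string(prefix_clip); cig.push_back('S'); }
  for (size_t p = 0; p < ops.size();) {
    size_t q = p; while (q < ops.size() && ops[q] == ops[p]) ++q;
    cig += std::to_string(q - p); cig.push_back(ops[p]);
    p = q;
  }
  if (suffix_clip > 0) { cig += std::to_string(suffix_clip); cig.push_back('S'); }
  out.ref = ref_idx; out.start = ws + j; out.fwd = fwd;
  out.mm = mm; out.gapbases = gapb;
  out.score = m - best_cost;
  out.cigar = cig; out.valid = true;
  out.edge_mm = false;
  return out;
}

static Placement hamming_at(const std::string& read, const std::string& ref,
                            int start, int ref_idx, bool fwd, int max_mm) {
  Placement out; out.valid = false;
  const int m = (int)read.size();
  const int EDGE = 5;
  if (start < 0 || start + m > (int)ref.size()) return out;
  int mm = 0; bool edge = false;
  for (int i = 0; i < m; ++i) {
    int rc = base_code(read[i]);
    int fc = base_code(ref[start + i]);
    if (!(rc < 4 && rc == fc)) {
      if (++mm > max_mm) return out;
      if (i < EDGE || i >= m - EDGE) edge = true;
    }
  }
  out.ref = ref_idx; out.start = start; out.fwd = fwd;
  out.mm = mm; out.gapbases = 0; out.score = m - 3 * mm;
  out.cigar = std::to_string(m) + "M";
  out.valid = true;
  out.edge_mm = edge;
  return out;
}

typedef std::unordered_map<uint32_t, std::vector<uint64_t> > KmerIndex;

static void build_kmer_index(const std::vector<std::string>& refs, int k, KmerIndex& idx) {
  const uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  for (size_t r = 0; r < refs.size(); ++r) {
    const std::string& s = refs[r];
    if ((int)s.size() < k) continue;
    uint32_t key = 0; int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int c = base_code(s[i]);
      if (c > 3) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint32_t)c) & mask;
      if (++valid >= k) {
        uint64_t posting = ((uint64_t)r << 32) | (uint64_t)(i + 1 - k);
        idx[key].push_back(posting);
      }
    }
  }
}

// Map a batch of reads. Returns one row per read; ref_idx = NA when unmapped.
// [[Rcpp::export(name = ".cpp_map_reads")]]
DataFrame cpp_map_reads(CharacterVector ref_seqs, CharacterVector read_seqs,
                        int k, int max_mm, int max_indel) {
  std::vector<std::string> refs(ref_seqs.size());
  for (int i = 0; i < ref_seqs.size(); ++i) refs[i] = as<std::string>(ref_seqs[i]);
  KmerIndex idx;
  build_kmer_index(refs, k, idx);

  const int n = read_seqs.size();
  IntegerVector o_ref(n), o_pos(n), o_nm(n), o_mq(n), o_score(n);
  CharacterVector o_strand(n), o_cigar(n);
  const uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);

  for (int ri = 0; ri < n; ++ri) {
    std::string fwd = as<std::string>(read_seqs[ri]);
    const int m = (int)fwd.size();
    Placement best; best.valid = false;
    int second_score = -(1 << 28);
    bool tie = false;

    if (m >= k) {
      std::string rev = revcomp(fwd);
      for (int strand = 0; strand < 2; ++strand) {
        const std::string& rd = (strand == 0) ? fwd : rev;
        // seed offsets: tile every k, plus the final k-mer
        std::vector<int> offs;
        for (int o = 0; o + k <= m; o += k) offs.push_back(o);
        if (!offs.empty() && offs.back() != m - k) offs.push_back(m - k);
        // collect candidate (ref, diag)
        std::vector<std::pair<int,int> > cands;
        for (int oi = 0; oi < (int)offs.size(); ++oi) {
          int o = offs[oi];
          uint32_t key = 0; bool ok = true;
          for (int t = 0; t < k; ++t) {
            int c = base_code(rd[o + t]);
            if (c > 3) { ok = false; break; }
            key = ((key << 2) | (uint32_t)c) & mask;
          }
          if (!ok) continue;
          KmerIndex::const_iterator it = idx.find(key);
          if (it == idx.end()) continue;
          const std::vector<uint64_t>& posts = it->second;
          for (size_t pi = 0; pi < posts.size(); ++pi) {
            int pref = (int)(posts[pi] >> 32);
            int poff = (int)(posts[pi] & 0xFFFFFFFFu);
            cands.push_back(std::make_pair(pref, poff - o));
          }
        }
        std::sort(cands.begin(), cands.end());
        cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
        // cluster diagonals within max_indel per reference
        size_t ci = 0;
        while (ci < cands.size()) {
          size_t cj = ci;
          while (cj + 1 < cands.size() && cands[cj + 1].first == cands[ci].first &&
                 cands[cj + 1].second - cands[cj].second <= std::max(max_indel, 1))
            ++cj;
          int pref = cands[ci].first;
          const std::string& rs = refs[pref];
          Placement pl; pl.valid = false;
          // cheap path: mismatch-only at each seeded diagonal
          for (size_t t = ci; t <= cj; ++t) {
            Placement h = hamming_at(rd, rs, cands[t].second, pref, strand == 0, max_mm);
            if (h.valid && (!pl.valid || h.score > pl.score)) pl = h;
          }
          // run the gapped/clipped DP when mismatch-only failed, or when the
          // mismatches sit at the read ends (possible misrepresented indel)
          if ((!pl.valid || pl.edge_mm) && max_indel > 0) {
            int diag = cands[ci].second;
            int ws = std::max(0, diag - max_indel);
            int we = std::min((int)rs.size(), diag + m + max_indel);
            Placement g = align_window(rd, rs, ws, we, pref, strand == 0,
                                       max_mm, max_indel);
            if (g.valid && (!pl.valid || g.score > pl.score)) pl = g;
          }
          if (pl.valid) {
            if (!best.valid) { best = pl; }
            else if (pl.score > best.score) { second_score = best.score; best = pl; tie = false; }
            else if (pl.score > second_score) {
              second_score = pl.score;
              if (pl.score == best.score) tie = true;
            }
          }
          ci = cj + 1;
        }
      }
    }

    if (!best.valid) {
      o_ref[ri] = NA_INTEGER; o_pos[ri] = NA_INTEGER; o_nm[ri] = NA_INTEGER;
      o_mq[ri] = NA_INTEGER; o_score[ri] = NA_INTEGER;
      o_strand[ri] = NA_STRING; o_cigar[ri] = NA_STRING;
    } else {
      int mq;
      if (tie) mq = 0;
      else if (second_score <= -(1 << 27)) mq = 60;
      else mq = std::min(60, 5 * (best.score - second_score));
      o_ref[ri] = best.ref + 1;
      o_pos[ri] = best.start + 1;
      o_nm[ri] = best.mm + best.gapbases;
      o_mq[ri] = mq;
      o_score[ri] = best.score;
      o_strand[ri] = best.fwd ? "+" : "-";
      o_cigar[ri] = best.cigar;
    }
  }
  return DataFrame::create(
    _["ref_idx"] = o_ref, _["pos"] = o_pos, _["strand"] = o_strand,
    _["cigar"] = o_cigar, _["nm"] = o_nm, _["mapq"] = o_mq, _["score"] = o_score,
    _["stringsAsFactors"] = false);
}

// Multi-sample pileup accumulation. seq/qual are given in reference (forward)
// orientation. Returns aggregated SNV observations, indel observations, and
// per-site read-coverage / mapping-quality accumulators.
// [[Rcpp::export(name = ".cpp_pileup")]]
List cpp_pileup(IntegerVector ref_idx, IntegerVector pos, IntegerVector sample_idx,
                CharacterVector seq, CharacterVector qual, CharacterVector cigar,
                IntegerVector mapq, int min_bq) {
  const int n = ref_idx.size();
  std::unordered_map<uint64_t, int> snv;           // base observations
  std::unordered_map<uint64_t, std::pair<int, double> > cover; // reads, sum mq^2
  // indel observations: emitted per event, aggregated in R
  std::vector<int> iv_ref, iv_pos, iv_sample, iv_len, iv_qual;
  std::vector<std::string> iv_type, iv_seq;

  for (int r = 0; r < n; ++r) {
    if (ref_idx[r] == NA_INTEGER) continue;
    const uint64_t uref = (uint64_t)ref_idx[r];
    const uint64_t usam = (uint64_t)sample_idx[r];
    std::string sq = as<std::string>(seq[r]);
    std::string ql = as<std::string>(qual[r]);
    std::string cg = as<std::string>(cigar[r]);
    int fp = pos[r];      // 1-based reference pointer
    int rp = 0;           // 0-based read pointer
    double mq2 = (double)mapq[r] * (double)mapq[r];
    size_t ci = 0;
    while (ci < cg.size()) {
      int len = 0;
      while (ci < cg.size() && cg[ci] >= '0' && cg[ci] <= '9') {
        len = len * 10 + (cg[ci] - '0'); ++ci;
      }
      char op = cg[ci++];
      if (op == 'M') {
        for (int t = 0; t < len; ++t) {
          int q = (int)ql[rp] - 33;
          int b = base_code(sq[rp]);
          uint64_t ckey = (uref << 28) | (uint64_t)fp;
          std::pair<int, double>& cv = cover[ckey];
          cv.first += 1;
          cv.second += mq2;
          if (q >= min_bq && b < 4) {
            uint64_t key = (uref << 48) | ((uint64_t)fp << 20) | (usam << 8) |
              ((uint64_t)b << 6) | (uint64_t)std::min(q, 63);
            snv[key] += 1;
          }
          ++rp; ++fp;
        }
      } else if (op == 'I') {
        if (fp > 1) {
          iv_ref.push_back((int)uref); iv_pos.push_back(fp - 1);
          iv_sample.push_back((int)usam); iv_type.push_back("I");
          iv_len.push_back(len); iv_seq.push_back(sq.substr(rp, len));
          iv_qual.push_back((int)ql[rp] - 33);
        }
        rp += len;
      } else if (op == 'S') {
        rp += len; // soft-clipped read bases: present in SEQ, not aligned
      } else if (op == 'D') {
        if (fp > 1) {
          iv_ref.push_back((int)uref); iv_pos.push_back(fp - 1);
          iv_sample.push_back((int)usam); iv_type.push_back("D");
          iv_len.push_back(len); iv_seq.push_back("");
          iv_qual.push_back(rp > 0 ? (int)ql[rp - 1] - 33 : 30);
        }
        for (int t = 0; t < len; ++t) {
          uint64_t ckey = (uref << 28) | (uint64_t)fp;
          cover[ckey].first += 1;
          cover[ckey].second += mq2;
          ++fp;
        }
      } else {
        stop("unsupported CIGAR op '%s'", std::string(1, op).c_str());
      }
    }
  }

  // materialize SNV table
  {
    R_xlen_t ns = (R_xlen_t)snv.size();
    IntegerVector s_ref(ns), s_pos(ns), s_sam(ns), s_base(ns), s_q(ns), s_n(ns);
    R_xlen_t i = 0;
    for (std::unordered_map<uint64_t, int>::const_iterator it = snv.begin();
         it != snv.end(); ++it, ++i) {
      uint64_t key = it->first;
      s_q[i] = (int)(key & 0x3F);
      s_base[i] = (int)((key >> 6) & 0x3);
      s_sam[i] = (int)((key >> 8) & 0xFFF);
      s_pos[i] = (int)((key >> 20) & 0xFFFFFFF);
      s_ref[i] = (int)(key >> 48);
      s_n[i] = it->second;
    }
    R_xlen_t nc = (R_xlen_t)cover.size();
    IntegerVector c_ref(nc), c_pos(nc), c_reads(nc);
    NumericVector c_mq2(nc);
    i = 0;
    for (std::unordered_map<uint64_t, std::pair<int, double> >::const_iterator it =
           cover.begin(); it != cover.end(); ++it, ++i) {
      c_pos[i] = (int)(it->first & 0xFFFFFFF);
      c_ref[i] = (int)(it->first >> 28);
      c_reads[i] = it->second.first;
      c_mq2[i] = it->second.second;
    }
    return List::create(
      _["snv"] = DataFrame::create(
        _["ref_idx"] = s_ref, _["pos"] = s_pos, _["sample_idx"] = s_sam,
        _["base"] = s_base, _["qual"] = s_q, _["count"] = s_n),
      _["indel"] = DataFrame::create(
        _["ref_idx"] = wrap(iv_ref), _["pos"] = wrap(iv_pos),
        _["sample_idx"] = wrap(iv_sample), _["type"] = wrap(iv_type),
        _["len"] = wrap(iv_len), _["seq"] = wrap(iv_seq),
        _["qual"] = wrap(iv_qual), _["stringsAsFactors"] = false),
      _["cover"] = DataFrame::create(
        _["ref_idx"] = c_ref, _["pos"] = c_pos, _["n_reads"] = c_reads,
        _["mq2_sum"] = c_mq2));
  }
}
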