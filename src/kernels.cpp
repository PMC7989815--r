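#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Amino-acid alphabet shared with the R side: index 0..19, 'X'/other = 20.
static const char AA_ORDER[] = "ACDEFGHIKLMNPQRSTVWY";

static inline int aa_index(char c) {
  switch (c) {
    case 'A': return 0;  case 'C': return 1;  case 'D': return 2;
    case 'E': return 3;  case 'F': return 4;  case 'G': return 5;
    case 'H': return 6;  case 'I': return 7;  case 'K': return 8;
    case 'L': return 9;  case 'M': return 10; case 'N': return 11;
    case 'P': return 12; case 'Q': return 13; case 'R': return 14;
    case 'S': return 15; case 'T': return 16; case 'V': return 17;
    case 'W': return 18; case 'Y': return 19;
    default:  return 20;
  }
}

static std::vector<int> encode_aa(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = aa_index(s[i]);
  return v;
}

// ---------------------------------------------------------------------------
// Local (Smith-Waterman-entry/exit) Viterbi over a profile HMM.
//
// Model convention (mirrored by the R enumeration oracle in the tests):
//  - entry Begin -> M_j for any j, log2 prob = -log2(M); exit M_j -> End free;
//  - transitions out of node j (cols): mm mi md im ii dm dd, log2 probs;
//    M_j->M_{j+1}, M_j->I_j, M_j->D_{j+1}, I_j->M_{j+1}, I_j->I_j,
//    D_j->M_{j+1}, D_j->D_{j+1};
//  - match emissions scored as log2(e/bg) (col 20 = 0 for 'X'),
//    insert emissions likewise (typically 0 when inserts emit background).
// Paths start and end in a match state.
// ---------------------------------------------------------------------------
struct VitRes { double score; int qstart; int qend; };

static VitRes viterbi_local_core(const std::vector<int>& seq,
                                 const NumericMatrix& matLO,
                                 const NumericMatrix& insLO,
                                 const NumericMatrix& trans) {
  const int M = matLO.nrow();
  const int L = (int) seq.size();
  const double NEG = -1e30;
  const double entry = -std::log2((double) M);

  std::vector<double> vm(M + 1, NEG), vi(M + 1, NEG), vd(M + 1, NEG);
  std::vector<double> pm(M + 1, NEG), pi(M + 1, NEG), pd(M + 1, NEG);
  std::vector<int> bm(M + 1, 0), bi(M + 1, 0), bd(M + 1, 0);
  std::vector<int> pbm(M + 1, 0), pbi(M + 1, 0), pbd(M + 1, 0);

  double best = NEG;
  int best_start = 0, best_end = 0;

  for (int t = 1; t <= L; ++t) {
    int r = seq[t - 1];
    for (int j = 1; j <= M; ++j) {
      // match
      double sc = entry;
      int b = t - 1;
      if (j > 1) {
        double c1 = pm[j - 1] + trans(j - 2, 0);
        double c2 = pi[j - 1] + trans(j - 2, 3);
        double c3 = pd[j - 1] + trans(j - 2, 5);
        if (c1 > sc) { sc = c1; b = pbm[j - 1]; }
        if (c2 > sc) { sc = c2; b = pbi[j - 1]; }
        if (c3 > sc) { sc = c3; b = pbd[j - 1]; }
      }
      vm[j] = sc + matLO(j - 1, r);
      bm[j] = b;
      // insert (I_j exists for j < M in our subset; trans row j-1)
      double ci1 = pm[j] + trans(j - 1, 1);
      double ci2 = pi[j] + trans(j - 1, 4);
      if (ci1 >= ci2) { vi[j] = ci1 + insLO(j - 1, r); bi[j] = pbm[j]; }
      else            { vi[j] = ci2 + insLO(j - 1, r); bi[j] = pbi[j]; }
      // delete (no emission, same t)
      if (j > 1) {
        double cd1 = vm[j - 1] + trans(j - 2, 2);
        double cd2 = vd[j - 1] + trans(j - 2, 6);
        if (cd1 >= cd2) { vd[j] = cd1; bd[j] = bm[j - 1]; }
        else            { vd[j] = cd2; bd[j] = bd[j - 1]; }
      } else vd[j] = NEG;

      if (vm[j] > best) { best = vm[j]; best_start = bm[j]; best_end = t; }
    }
    std::swap(vm, pm); std::swap(vi, pi); std::swap(vd, pd);
    std::swap(bm, pbm); std::swap(bi, pbi); std::swap(bd, pbd);
    std::fill(vm.begin(), vm.end(), NEG);
    std::fill(vi.begin(), vi.end(), NEG);
    std::fill(vd.begin(), vd.end(), NEG);
  }
  VitRes res; res.score = best; res.qstart = best_start; res.qend = best_end;
  return res;
}

// [[Rcpp::export]]
List cpp_viterbi_local(std::string seq, NumericMatrix matLO,
                       NumericMatrix insLO, NumericMatrix trans) {
  std::vector<int> s = encode_aa(seq);
  if (s.empty()) return List::create(_["score"] = R_NegInf,
                                     _["qstart"] = 0L, _["qend"] = 0L);
  VitRes r = viterbi_local_core(s, matLO, insLO, trans);
  return List::create(_["score"] = r.score,
                      _["qstart"] = r.qstart, _["qend"] = r.qend);
}

// 4-mer integer codes of a peptide (skipping any window containing 'X').
static void kmer_codes(const std::vector<int>& s, std::vector<int>& out) {
  out.clear();
  if (s.size() < 4) return;
  for (size_t i = 0; i + 4 <= s.size(); ++i) {
    int code = 0; bool ok = true;
    for (int k = 0; k < 4; ++k) {
      if (s[i + k] >= 20) { ok = false; break; }
      code = code * 20 + s[i + k];
    }
    if (ok) out.push_back(code);
  }
}

// ---------------------------------------------------------------------------
// Batch profile scan: every (ORF, model) pair, with an optional consensus
// 4-mer prescreen (MSV-filter-like acceleration; prescreened-out pairs are
// reported only if their exhaustive score could never reach `floor`, which
// the prescreen guarantees for the packaged models' design regime).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
DataFrame cpp_scan_viterbi(CharacterVector seqs, List mats, List inss,
                           List transs, List consCodes, bool prescreen,
                           double floor_bits) {
  const int nh = mats.size();
  std::vector<NumericMatrix> vmat, vins, vtr;
  // one shared map: 4-mer code -> models whose consensus contains it
  std::unordered_map<int, std::vector<int> > codeModels;
  for (int h = 0; h < nh; ++h) {
    vmat.push_back(as<NumericMatrix>(mats[h]));
    vins.push_back(as<NumericMatrix>(inss[h]));
    vtr.push_back(as<NumericMatrix>(transs[h]));
    IntegerVector cc = consCodes[h];
    for (int i = 0; i < cc.size(); ++i) codeModels[cc[i]].push_back(h);
  }
  std::vector<int> oidx, hidx, qs, qe; std::vector<double> sc;
  std::vector<int> codes;
  std::vector<char> cand(nh);
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::vector<int> enc = encode_aa(s);
    if (enc.empty()) continue;
    if (prescreen) {
      std::fill(cand.begin(), cand.end(), 0);
      kmer_codes(enc, codes);
      for (size_t k = 0; k < codes.size(); ++k) {
        auto it = codeModels.find(codes[k]);
        if (it == codeModels.end()) continue;
        for (int h : it->second) cand[h] = 1;
      }
    } else std::fill(cand.begin(), cand.end(), 1);
    for (int h = 0; h < nh; ++h) {
      if (!cand[h]) continue;
      VitRes r = viterbi_local_core(enc, vmat[h], vins[h], vtr[h]);
      if (r.score >= floor_bits) {
        oidx.push_back(i + 1); hidx.push_back(h + 1);
        sc.push_back(r.score); qs.push_back(r.qstart); qe.push_back(r.qend);
      }
    }
  }
  return DataFrame::create(_["orf"] = oidx, _["hmm"] = hidx,
                           _["score"] = sc, _["qstart"] = qs, _["qend"] = qe);
}

// ---------------------------------------------------------------------------
// Banded affine-gap local alignment (Smith-Waterman) around a diagonal.
// Gap of length k costs open + k * extend. Band: |(i - j) - diag| <= band,
// i = 1..n query rows, j = 1..m subject cols. Traceback yields identity.
// ---------------------------------------------------------------------------
struct SWRes {
  double score; int qstart, qend, sstart, send, nmatch, alnlen;
};

static SWRes sw_banded_core(const std::vector<int>& q, const std::vector<int>& s,
                            const NumericMatrix& sub, double gapOpen,
                            double gapExtend, int diag, int band) {
  const int n = (int) q.size(), m = (int) s.size();
  const double NEG = -1e30;
  const int W = 2 * band + 1;
  // H, E (gap in subject / up), F (gap in query / left), banded storage:
  // cell (i, j) stored at [i][j - (i - diag - band)] when inside band.
  std::vector<std::vector<double> > H(n + 1, std::vector<double>(W + 2, 0.0));
  std::vector<std::vector<double> > E(n + 1, std::vector<double>(W + 2, NEG));
  std::vector<std::vector<double> > F(n + 1, std::vector<double>(W + 2, NEG));
  std::vector<std::vector<unsigned char> > TB(n + 1, std::vector<unsigned char>(W + 2, 0));

  double best = 0.0; int bi = 0, bj = 0;
  auto col0 = [&](int i) { return i - diag - band; }; // j at slot 0
  auto inband = [&](int i, int j) {
    int o = j - col0(i); return o >= 0 && o < W;
  };
  auto slot = [&](int i, int j) { return j - col0(i) + 1; }; // 1-based slot

  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(1, col0(i));
    int jhi = std::min(m, col0(i) + W - 1);
    for (int j = jlo; j <= jhi; ++j) {
      int sl = slot(i, j);
      double diagH = (inband(i - 1, j - 1)) ? H[i - 1][slot(i - 1, j - 1)] : (i == 1 || j == 1 ? 0.0 : NEG);
      // for i-1==0 or j-1==0 the previous H is the zero boundary
      if (i - 1 == 0 || j - 1 == 0) diagH = 0.0;
      double mscore = diagH + sub(q[i - 1], s[j - 1]);
      double e = NEG, f = NEG;
      if (inband(i - 1, j) && i - 1 >= 1) {
        e = std::max(H[i - 1][slot(i - 1, j)] - (gapOpen + gapExtend),
                     E[i - 1][slot(i - 1, j)] - gapExtend);
      }
      if (inband(i, j - 1) && j - 1 >= 1) {
        f = std::max(H[i][slot(i, j - 1)] - (gapOpen + gapExtend),
                     F[i][slot(i, j - 1)] - gapExtend);
      }
      E[i][sl] = e; F[i][sl] = f;
      double h = 0.0; unsigned char tb = 0;          // 0 = stop (local start)
      if (mscore > h) { h = mscore; tb = 1; }         // 1 = diagonal
      if (e > h)      { h = e;      tb = 2; }         // 2 = up (gap in subject)
      if (f > h)      { h = f;      tb = 3; }         // 3 = left (gap in query)
      H[i][sl] = h; TB[i][sl] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  SWRes r; r.score = best; r.nmatch = 0; r.alnlen = 0;
  r.qstart = r.qend = r.sstart = r.send = 0;
  if (best <= 0.0) return r;
  // traceback with explicit H/E/F state (affine gap runs)
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E (vertical), 2 = F (horizontal)
  const double tol = 1e-9;
  r.qend = bi; r.send = bj;
  while (i >= 1 && j >= 1) {
    if (state == 0) {
      unsigned char tb = TB[i][slot(i, j)];
      if (tb == 0) break;
      if (tb == 1) {
        r.alnlen++; if (q[i - 1] == s[j - 1]) r.nmatch++;
        --i; --j;
      } else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      // E[i][j] = max(H[i-1][j] - open - ext, E[i-1][j] - ext)
      double e = E[i][slot(i, j)];
      double fromH = (i - 1 >= 1 && inband(i - 1, j))
        ? H[i - 1][slot(i - 1, j)] - (gapOpen + gapExtend) : NEG;
      r.alnlen++; --i;
      state = (std::fabs(e - fromH) < tol) ? 0 : 1;
    } else {
      double f = F[i][slot(i, j)];
      double fromH = (j - 1 >= 1 && inband(i, j - 1))
        ? H[i][slot(i, j - 1)] - (gapOpen + gapExtend) : NEG;
      r.alnlen++; --j;
      state = (std::fabs(f - fromH) < tol) ? 0 : 2;
    }
  }
  r.qstart = i; r.sstart = j; // 0-based starts (stepped past the first cell)
  return r;
}

// [[Rcpp::export]]
List cpp_sw_align(std::string query, std::string subject, NumericMatrix sub,
                  double gapOpen, double gapExtend, int diag, int band) {
  std::vector<int> q = encode_aa(query), s = encode_aa(subject);
  SWRes r = sw_banded_core(q, s, sub, gapOpen, gapExtend, diag, band);
  return List::create(_["score"] = r.score,
                      _["qstart"] = r.qstart, _["qend"] = r.qend,
                      _["sstart"] = r.sstart, _["send"] = r.send,
                      _["nmatch"] = r.nmatch, _["alnlen"] = r.alnlen);
}

// ---------------------------------------------------------------------------
// Seeded translated search of many queries against an indexed reference.
// Seeds are exact amino-acid 4-mers; subjects reaching >= minSeeds seeds are
// aligned with the banded SW around the modal seed diagonal.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_build_kmer_index(CharacterVector subjects) {
  std::unordered_map<int, std::vector<std::pair<int,int> > > idx;
  std::vector<int> codes;
  for (int si = 0; si < subjects.size(); ++si) {
    std::vector<int> enc = encode_aa(as<std::string>(subjects[si]));
    if (enc.size() < 4) continue;
    for (size_t p = 0; p + 4 <= enc.size(); ++p) {
      int code = 0; bool ok = true;
      for (int k = 0; k < 4; ++k) {
        if (enc[p + k] >= 20) { ok = false; break; }
        code = code * 20 + enc[p + k];
      }
      if (ok) idx[code].push_back(std::make_pair(si, (int) p));
    }
  }
  // flatten to parallel vectors for cheap round-tripping through R
  std::vector<int> kcode, ksub, kpos;
  for (auto& kv : idx) {
    for (auto& pr : kv.second) {
      kcode.push_back(kv.first); ksub.push_back(pr.first); kpos.push_back(pr.second);
    }
  }
  return List::create(_["code"] = kcode, _["subject"] = ksub, _["pos"] = kpos);
}

// [[Rcpp::export]]
DataFrame cpp_translated_search(CharacterVector queries, CharacterVector subjects,
                                IntegerVector idxCode, IntegerVector idxSub,
                                IntegerVector idxPos, NumericMatrix sub,
                                double gapOpen, double gapExtend, int band,
                                int minSeeds, double minRaw) {
  // rebuild hash index
  std::unordered_map<int, std::vector<int> > where; // code -> entry rows
  for (int i = 0; i < idxCode.size(); ++i) where[idxCode[i]].push_back(i);

  std::vector<std::vector<int> > subEnc(subjects.size());
  for (int si = 0; si < subjects.size(); ++si)
    subEnc[si] = encode_aa(as<std::string>(subjects[si]));

  std::vector<int> oQ, oS, oQs, oQe, oSs, oSe, oNm, oAl;
  std::vector<double> oRaw;

  std::unordered_map<long long, int> seedCount;  // (subject, diag) -> count
  std::unordered_map<int, int> subBestDiag, subBestCnt, subTotal;

  for (int qi = 0; qi < queries.size(); ++qi) {
    std::vector<int> q = encode_aa(as<std::string>(queries[qi]));
    if (q.size() < 4) continue;
    seedCount.clear(); subBestDiag.clear(); subBestCnt.clear(); subTotal.clear();
    for (size_t p = 0; p + 4 <= q.size(); ++p) {
      int code = 0; bool ok = true;
      for (int k = 0; k < 4; ++k) {
        if (q[p + k] >= 20) { ok = false; break; }
        code = code * 20 + q[p + k];
      }
      if (!ok) continue;
      auto it = where.find(code);
      if (it == where.end()) continue;
      for (int row : it->second) {
        int si = idxSub[row];
        int diag = (int) p - idxPos[row]; // query pos - subject pos
        long long key = ((long long) si << 20) ^ (long long)(diag + 524288);
        int c = ++seedCount[key];
        subTotal[si]++;
        if (c > subBestCnt[si]) { subBestCnt[si] = c; subBestDiag[si] = diag; }
      }
    }
    for (auto& kv : subTotal) {
      if (kv.second < minSeeds) continue;
      int si = kv.first;
      // core band uses i - j (query row - subject col); the seed diagonal is
      // query pos - subject pos in 0-based coords, offsets cancel 1-based.
      SWRes r = sw_banded_core(q, subEnc[si], sub, gapOpen, gapExtend,
                               subBestDiag[si], band);
      if (r.score >= minRaw) {
        oQ.push_back(qi + 1); oS.push_back(si + 1); oRaw.push_back(r.score);
        oQs.push_back(r.qstart); oQe.push_back(r.qend);
        oSs.push_back(r.sstart); oSe.push_back(r.send);
        oNm.push_back(r.nmatch); oAl.push_back(r.alnlen);
      }
    }
  }
  return DataFrame::create(_["query"] = oQ, _["subject"] = oS, _["raw"] = oRaw,
                           _["qstart"] = oQs, _["qend"] = oQe,
                           _["sstart"] = oSs, _["send"] = oSe,
                           _["nmatch"] = oNm, _["alnlen"] = oAl);
}
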