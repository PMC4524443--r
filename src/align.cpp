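#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Nucleotide encoding: A,C,G,T -> 0..3, anything else (N/ambiguity) -> 4.
// Ambiguity codes never match anything, including themselves.
static inline int enc(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return 4;
  }
}

struct Hsp {
  int qs, qe, ss, se;   // 0-based half-open
  int score, matches, alnlen;
};

// Full Smith-Waterman with affine gaps (gap of length L costs open + L*ext,
// open and ext both negative) on a small window, with traceback so that
// identity can be reported. Returns best local alignment.
static bool sw_window(const std::vector<int>& q, int q0, int q1,
                      const std::vector<int>& s, int s0, int s1,
                      int match, int mismatch, int gap_open, int gap_ext,
                      Hsp& out) {
  const int m = q1 - q0, n = s1 - s0;
  if (m <= 0 || n <= 0) return false;
  const int NEG = INT_MIN / 4;
  std::vector<int> M((m + 1) * (n + 1), 0);
  std::vector<int> X((m + 1) * (n + 1), NEG); // gap in subject (consume query)
  std::vector<int> Y((m + 1) * (n + 1), NEG); // gap in query (consume subject)
  std::vector<uint8_t> tb((m + 1) * (n + 1), 0); // 2 bits M, 2 bits X, 2 bits Y
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int idx = i * (n + 1) + j;
      const int diag = (i - 1) * (n + 1) + (j - 1);
      const int up   = (i - 1) * (n + 1) + j;
      const int left = i * (n + 1) + (j - 1);
      int qi = q[q0 + i - 1], sj = s[s0 + j - 1];
      int sub = (qi == sj && qi < 4) ? match : mismatch;
      // X: gap in subject, i.e. query char aligned to '-'
      int xo = M[up] + gap_open + gap_ext;
      int xe = X[up] + gap_ext;
      X[idx] = std::max(xo, xe);
      uint8_t tx = (xe > xo) ? 1 : 0;
      // Y: gap in query
      int yo = M[left] + gap_open + gap_ext;
      int ye = Y[left] + gap_ext;
      Y[idx] = std::max(yo, ye);
      uint8_t ty = (ye > yo) ? 1 : 0;
      // M: best of diag extensions or restart (local)
      int md = M[diag] + sub, xd = X[diag] + sub, yd = Y[diag] + sub;
      int v = std::max(std::max(md, xd), std::max(yd, 0));
      uint8_t tm = 0; // 0=from M, 1=from X, 2=from Y, 3=start
      if (v == 0 && md <= 0 && xd <= 0 && yd <= 0) tm = 3;
      else if (v == md) tm = 0;
      else if (v == xd) tm = 1;
      else tm = 2;
      M[idx] = v;
      tb[idx] = (uint8_t)(tm | (tx << 2) | (ty << 4));
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  if (best <= 0) return false;
  // traceback from (bi,bj) in state M
  int i = bi, j = bj, state = 0; // 0=M,1=X,2=Y
  int matches = 0, alnlen = 0;
  int ei = bi, ej = bj;
  while (true) {
    const int idx = i * (n + 1) + j;
    if (state == 0) {
      uint8_t tm = tb[idx] & 3;
      int qi = q[q0 + i - 1], sj = s[s0 + j - 1];
      if (qi == sj && qi < 4) ++matches;
      ++alnlen; --i; --j;
      if (tm == 3) break;
      state = tm;
      if (i == 0 || j == 0) break;
    } else if (state == 1) {
      uint8_t tx = (tb[idx] >> 2) & 3;
      ++alnlen; --i;
      state = tx ? 1 : 0;
      if (i == 0) break;
    } else {
      uint8_t ty = (tb[idx] >> 4) & 3;
      ++alnlen; --j;
      state = ty ? 2 : 0;
      if (j == 0) break;
    }
  }
  out.qs = q0 + i; out.qe = q0 + ei;
  out.ss = s0 + j; out.se = s0 + ej;
  out.score = best; out.matches = matches; out.alnlen = alnlen;
  return true;
}

// Seed-and-extend local alignment: exact k-mer seeds, ungapped X-drop
// extension to delimit a candidate region, then full affine local DP on the
// region expanded by a margin. Overlapping extensions are deduplicated
// keeping the highest-scoring HSP per overlapping query/subject region.
// [[Rcpp::export]]
DataFrame cpp_seed_extend(std::string qstr, std::string sstr,
                          int match, int mismatch, int gap_open, int gap_ext,
                          int k, int xdrop, int margin) {
  const int m = (int)qstr.size(), n = (int)sstr.size();
  std::vector<int> q(m), s(n);
  for (int i = 0; i < m; ++i) q[i] = enc(qstr[i]);
  for (int i = 0; i < n; ++i) s[i] = enc(sstr[i]);
  std::vector<Hsp> kept;
  if (m >= k && n >= k && k <= 15) {
    // hash query k-mers (ACGT-only windows)
    std::unordered_map<uint32_t, std::vector<int> > qmers;
    uint32_t key = 0, mask = (k >= 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1);
    int run = 0;
    for (int i = 0; i < m; ++i) {
      if (q[i] < 4) { key = ((key << 2) | (uint32_t)q[i]) & mask; ++run; }
      else { run = 0; key = 0; }
      if (run >= k) qmers[key].push_back(i - k + 1);
    }
    // scan subject, collect seeds
    std::vector<std::pair<int,int> > seeds; // (qpos, spos)
    key = 0; run = 0;
    for (int j = 0; j < n; ++j) {
      if (s[j] < 4) { key = ((key << 2) | (uint32_t)s[j]) & mask; ++run; }
      else { run = 0; key = 0; }
      if (run >= k) {
        auto it = qmers.find(key);
        if (it != qmers.end()) {
          int sp = j - k + 1;
          for (int qp : it->second) seeds.push_back(std::make_pair(qp, sp));
        }
      }
    }
    // sort by diagonal then subject position for deterministic processing
    std::sort(seeds.begin(), seeds.end(),
              [](const std::pair<int,int>& a, const std::pair<int,int>& b) {
                int da = a.second - a.first, db = b.second - b.first;
                if (da != db) return da < db;
                return a.second < b.second;
              });
    for (size_t si = 0; si < seeds.size(); ++si) {
      int qp = seeds[si].first, sp = seeds[si].second;
      bool covered = false;
      for (const Hsp& h : kept)
        if (qp >= h.qs && qp < h.qe && sp >= h.ss && sp < h.se) { covered = true; break; }
      if (covered) continue;
      // ungapped X-drop extension (seed treated as scored run)
      int sc = 0, mx = 0;
      int qr = qp, sr = sp;             // right frontier (best extent, exclusive later)
      int bq = qp - 1, bs = sp - 1;     // best right end (inclusive)
      bool any = false;
      while (qr < m && sr < n) {
        sc += (q[qr] == s[sr] && q[qr] < 4) ? match : mismatch;
        if (sc > mx) { mx = sc; bq = qr; bs = sr; any = true; }
        if (mx - sc > xdrop) break;
        ++qr; ++sr;
      }
      if (!any) continue;
      int qe0 = bq + 1, se0 = bs + 1;
      // left extension
      sc = mx;
      int ql = qp - 1, sl = sp - 1;
      int lq = qp, ls = sp;
      while (ql >= 0 && sl >= 0) {
        sc += (q[ql] == s[sl] && q[ql] < 4) ? match : mismatch;
        if (sc > mx) { mx = sc; lq = ql; ls = sl; }
        if (mx - sc > xdrop) break;
        --ql; --sl;
      }
      // gapped re-alignment window around the ungapped footprint; grown
      // when the local optimum touches the window edge (an indel can stop
      // the ungapped extension well inside the true aligned region)
      int mg = margin;
      Hsp h;
      bool got = false;
      while (true) {
        int q0 = std::max(0, lq - mg), q1 = std::min(m, qe0 + mg);
        int s0 = std::max(0, ls - mg), s1 = std::min(n, se0 + mg);
        got = sw_window(q, q0, q1, s, s0, s1, match, mismatch, gap_open,
                        gap_ext, h);
        if (!got) break;
        bool touch = (h.qs <= q0 && q0 > 0) || (h.qe >= q1 && q1 < m) ||
                     (h.ss <= s0 && s0 > 0) || (h.se >= s1 && s1 < n);
        if (!touch || mg >= 1000) break;
        mg *= 4;
      }
      if (!got) continue;
      // dedup: drop/replace when overlapping an existing HSP on both axes
      bool skip = false;
      for (size_t t = 0; t < kept.size(); ++t) {
        Hsp& o = kept[t];
        bool qov = h.qs < o.qe && o.qs < h.qe;
        bool sov = h.ss < o.se && o.ss < h.se;
        if (qov && sov) {
          if (h.score > o.score) { o = h; }
          skip = true; break;
        }
      }
      if (!skip) kept.push_back(h);
    }
  }
  std::sort(kept.begin(), kept.end(), [](const Hsp& a, const Hsp& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.ss != b.ss) return a.ss < b.ss;
    return a.qs < b.qs;
  });
  // final pass: after replacements, re-deduplicate overlaps (keep best first)
  std::vector<Hsp> fin;
  for (const Hsp& h : kept) {
    bool drop = false;
    for (const Hsp& o : fin) {
      bool qov = h.qs < o.qe && o.qs < h.qe;
      bool sov = h.ss < o.se && o.ss < h.se;
      if (qov && sov) { drop = true; break; }
    }
    if (!drop) fin.push_back(h);
  }
  int nr = (int)fin.size();
  IntegerVector qs(nr), qe(nr), ss(nr), se(nr), score(nr), matches(nr), alnlen(nr);
  for (int i = 0; i < nr; ++i) {
    qs[i] = fin[i].qs; qe[i] = fin[i].qe;
    ss[i] = fin[i].ss; se[i] = fin[i].se;
    score[i] = fin[i].score; matches[i] = fin[i].matches; alnlen[i] = fin[i].alnlen;
  }
  return DataFrame::create(_["qstart"] = qs, _["qend"] = qe,
                           _["sstart"] = ss, _["send"] = se,
                           _["raw_score"] = score, _["matches"] = matches,
                           _["aln_length"] = alnlen);
}

// Banded global profile-profile alignment with affine gaps (Gotoh).
// Profiles are 6 x L matrices of per-column symbol frequencies in row order
// A, C, G, T, N(other), gap. Column-column substitution score is the
// sum-of-pairs expectation over residues; existing gap fractions score 0.
// Band covers diagonal offsets [dmin, dmax]; callers must make it wide
// enough to contain the optimum (full band for exactness).
// Returns list(score, ops) with ops: 0 = column from both, 1 = gap inserted
// in A (B column consumed), 2 = gap inserted in B.
// [[Rcpp::export]]
List cpp_profile_align(NumericMatrix A, NumericMatrix B,
                       double match, double mismatch,
                       double gap_open, double gap_ext, int band) {
  const int La = A.ncol(), Lb = B.ncol();
  const double NEG = -1e18;
  int dmin = std::min(0, Lb - La) - band;
  int dmax = std::max(0, Lb - La) + band;
  const int W = dmax - dmin + 1;
  // residue content per column (excluding gap fraction)
  std::vector<double> resA(La), resB(Lb), matA(5 * La), matB(5 * Lb);
  for (int i = 0; i < La; ++i) {
    double r = 0; for (int x = 0; x < 5; ++x) { matA[5 * i + x] = A(x, i); r += A(x, i); }
    resA[i] = r;
  }
  for (int j = 0; j < Lb; ++j) {
    double r = 0; for (int x = 0; x < 5; ++x) { matB[5 * j + x] = B(x, j); r += B(x, j); }
    resB[j] = r;
  }
  auto colscore = [&](int i, int j) -> double {
    // expected pair score; N (index 4) mismatches everything incl. itself
    const double* fa = &matA[5 * i];
    const double* fb = &matB[5 * j];
    double mt = 0;
    for (int x = 0; x < 4; ++x) mt += fa[x] * fb[x];
    double tot = resA[i] * resB[j];
    return match * mt + mismatch * (tot - mt);
  };
  auto gapcost_open = [&](double resfrac) { return (gap_open + gap_ext) * resfrac; };
  auto gapcost_ext  = [&](double resfrac) { return gap_ext * resfrac; };
  // score rows are rolled (previous + current); the traceback matrix is
  // byte-sized, keeping memory ~ (La+1) * band even for very long inputs
  std::vector<double> Mp(W, NEG), Xp(W, NEG), Yp(W, NEG);
  std::vector<double> Mc(W, NEG), Xc(W, NEG), Yc(W, NEG);
  std::vector<uint8_t> tb((size_t)(La + 1) * W, 0);
  auto OFF = [&](int i, int j) -> int { return j - i - dmin; };
  auto TIDX = [&](int i, int j) -> size_t { return (size_t)i * W + OFF(i, j); };
  auto inband = [&](int i, int j) { int d = j - i; return d >= dmin && d <= dmax && j >= 0 && j <= Lb; };
  // row 0
  Mc[OFF(0, 0)] = 0.0;
  for (int j = 1; j <= Lb && inband(0, j); ++j) {
    Yc[OFF(0, j)] = (j == 1 ? 0.0 : Yc[OFF(0, j - 1)]) +
                    (j == 1 ? gapcost_open(resB[0]) : gapcost_ext(resB[j - 1]));
    tb[TIDX(0, j)] = (uint8_t)((j == 1 ? 0 : 1) << 4);
  }
  for (int i = 1; i <= La; ++i) {
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    std::fill(Mc.begin(), Mc.end(), NEG);
    std::fill(Xc.begin(), Xc.end(), NEG);
    std::fill(Yc.begin(), Yc.end(), NEG);
    if (inband(i, 0)) {
      double prevX = (i == 1) ? 0.0 : Xp[OFF(i - 1, 0)];
      Xc[OFF(i, 0)] = prevX +
                      (i == 1 ? gapcost_open(resA[0]) : gapcost_ext(resA[i - 1]));
      tb[TIDX(i, 0)] = (uint8_t)((i == 1 ? 0 : 1) << 2);
    }
    int jlo = std::max(1, i + dmin), jhi = std::min(Lb, i + dmax);
    for (int j = jlo; j <= jhi; ++j) {
      double sub = colscore(i - 1, j - 1);
      // X: gap column added to B (A column i consumed); from row i-1, same j
      double xo = NEG, xe = NEG;
      if (inband(i - 1, j)) {
        xo = Mp[OFF(i - 1, j)] + gapcost_open(resA[i - 1]);
        xe = Xp[OFF(i - 1, j)] + gapcost_ext(resA[i - 1]);
      }
      double xv = std::max(xo, xe);
      uint8_t tx = (xe > xo) ? 1 : 0;
      // Y: gap column added to A (B column j consumed); same row, j-1
      double yo = NEG, ye = NEG;
      if (inband(i, j - 1)) {
        yo = Mc[OFF(i, j - 1)] + gapcost_open(resB[j - 1]);
        ye = Yc[OFF(i, j - 1)] + gapcost_ext(resB[j - 1]);
      }
      double yv = std::max(yo, ye);
      uint8_t ty = (ye > yo) ? 1 : 0;
      double md = NEG, xd = NEG, yd = NEG;
      if (inband(i - 1, j - 1)) {
        md = Mp[OFF(i - 1, j - 1)];
        xd = Xp[OFF(i - 1, j - 1)];
        yd = Yp[OFF(i - 1, j - 1)];
      }
      double best = std::max(md, std::max(xd, yd));
      uint8_t tm = (best == md) ? 0 : ((best == xd) ? 1 : 2);
      Mc[OFF(i, j)] = best + sub;
      Xc[OFF(i, j)] = xv;
      Yc[OFF(i, j)] = yv;
      tb[TIDX(i, j)] = (uint8_t)(tm | (tx << 2) | (ty << 4));
    }
  }
  double sM = Mc[OFF(La, Lb)], sX = Xc[OFF(La, Lb)], sY = Yc[OFF(La, Lb)];
  double score = std::max(sM, std::max(sX, sY));
  int state = (score == sM) ? 0 : ((score == sX) ? 1 : 2);
  std::vector<int> ops;
  int i = La, j = Lb;
  while (i > 0 || j > 0) {
    const size_t idx = TIDX(i, j);
    if (state == 0) {
      uint8_t tm = tb[idx] & 3;
      ops.push_back(0); --i; --j;
      state = tm;
    } else if (state == 1) {
      uint8_t tx = (tb[idx] >> 2) & 3;
      ops.push_back(2); --i;
      state = tx ? 1 : 0;
    } else {
      uint8_t ty = (tb[idx] >> 4) & 3;
      ops.push_back(1); --j;
      state = ty ? 2 : 0;
    }
    if (i == 0 && j > 0 && state != 2) state = 2;
    if (j == 0 && i > 0 && state != 1) state = 1;
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = score, _["ops"] = wrap(ops));
}
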