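// Affine-gap pairwise DNA alignment (Gotoh) with three modes:
//   local   - Smith-Waterman, best-scoring local region
//   global  - Needleman-Wunsch over both full sequences
//   overlap - end-gap-free global: terminal gaps on either sequence are free;
//             identity is computed over the aligned core only
//
// Scoring convention: match/mismatch are added per aligned pair; a gap of
// length L costs gap_open + L * gap_extend (gap penalties positive, mismatch
// a negative score). Identity is matches / alignment columns, gaps counting
// as non-match columns. Score matrices are kept as rolling rows; only the
// byte-sized traceback matrices are stored in full.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

namespace {

const int NEG_INF = std::numeric_limits<int>::min() / 4;

struct AlnResult {
  int score;
  int qstart, qend, sstart, send;  // 0-based half-open
  int matches, columns, mismatches, gapopens;
  std::string qaln, saln;
};

enum State { SM = 0, SX = 1, SY = 2 };

AlnResult align_core(const std::string& q, const std::string& s,
                     int mode,  // 0 local, 1 global, 2 overlap
                     int match, int mismatch, int gap_open, int gap_extend) {
  const int m = (int)q.size(), n = (int)s.size();
  const int ncol = n + 1;
  const int open_cost = gap_open + gap_extend;

  // ptr codes: 0 = stop (fresh start / free edge), 1..3 = previous state + 1
  std::vector<unsigned char> pM((size_t)(m + 1) * ncol, 0),
      pX((size_t)(m + 1) * ncol, 0), pY((size_t)(m + 1) * ncol, 0);

  std::vector<int> Mprev(ncol), Xprev(ncol), Yprev(ncol),
      Mcur(ncol), Xcur(ncol), Ycur(ncol);

  // row 0
  Mprev[0] = 0; Xprev[0] = NEG_INF; Yprev[0] = NEG_INF;
  for (int j = 1; j <= n; ++j) {
    Xprev[j] = NEG_INF;
    if (mode == 1) {
      Mprev[j] = NEG_INF;
      Yprev[j] = -(gap_open + j * gap_extend);
      pY[j] = (j == 1) ? (SM + 1) : (SY + 1);
    } else {
      Mprev[j] = 0;
      Yprev[j] = NEG_INF;
    }
  }

  int best = (mode == 0) ? 0 : NEG_INF;
  int bi = 0, bj = 0, bstate = SM;
  if (mode == 1) { bi = m; bj = n; }

  for (int i = 1; i <= m; ++i) {
    const char qc = q[(size_t)i - 1];
    const size_t rowoff = (size_t)i * ncol;
    // column 0
    Ycur[0] = NEG_INF;
    if (mode == 1) {
      Mcur[0] = NEG_INF;
      Xcur[0] = -(gap_open + i * gap_extend);
      pX[rowoff] = (i == 1) ? (SM + 1) : (SX + 1);
    } else {
      Mcur[0] = 0;
      Xcur[0] = NEG_INF;
    }
    for (int j = 1; j <= n; ++j) {
      const char sc = s[(size_t)j - 1];
      const int sub = (qc == sc && qc != 'N') ? match : mismatch;
      // diagonal into M
      int bestd = Mprev[j - 1]; unsigned char pd = SM + 1;
      if (Xprev[j - 1] > bestd) { bestd = Xprev[j - 1]; pd = SX + 1; }
      if (Yprev[j - 1] > bestd) { bestd = Yprev[j - 1]; pd = SY + 1; }
      int mv = (bestd <= NEG_INF / 2) ? NEG_INF : bestd + sub;
      unsigned char pm = pd;
      if (mode == 0 && mv < 0) { mv = 0; pm = 0; }  // local reset
      Mcur[j] = mv;
      pM[rowoff + j] = pm;

      // X: gap in subject (consume query char i)
      int xv = NEG_INF; unsigned char px = 0;
      if (Mprev[j] > NEG_INF / 2 && Mprev[j] - open_cost > xv) {
        xv = Mprev[j] - open_cost; px = SM + 1;
      }
      if (Xprev[j] > NEG_INF / 2 && Xprev[j] - gap_extend > xv) {
        xv = Xprev[j] - gap_extend; px = SX + 1;
      }
      Xcur[j] = xv;
      pX[rowoff + j] = px;

      // Y: gap in query (consume subject char j)
      int yv = NEG_INF; unsigned char py = 0;
      if (Mcur[j - 1] > NEG_INF / 2 && Mcur[j - 1] - open_cost > yv) {
        yv = Mcur[j - 1] - open_cost; py = SM + 1;
      }
      if (Ycur[j - 1] > NEG_INF / 2 && Ycur[j - 1] - gap_extend > yv) {
        yv = Ycur[j - 1] - gap_extend; py = SY + 1;
      }
      Ycur[j] = yv;
      pY[rowoff + j] = py;

      if (mode == 0 && mv > best) { best = mv; bi = i; bj = j; bstate = SM; }
    }
    if (mode == 2 && Mcur[n] > best) {  // last column
      best = Mcur[n]; bi = i; bj = n; bstate = SM;
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  // Mprev now holds row m
  if (mode == 1) {
    best = Mprev[n]; bstate = SM;
    if (Xprev[n] > best) { best = Xprev[n]; bstate = SX; }
    if (Yprev[n] > best) { best = Yprev[n]; bstate = SY; }
  } else if (mode == 2) {
    for (int j = 0; j <= n; ++j) {
      if (Mprev[j] > best) { best = Mprev[j]; bi = m; bj = j; bstate = SM; }
    }
  }

  AlnResult res;
  res.score = best;
  res.matches = res.columns = res.mismatches = res.gapopens = 0;

  // traceback
  std::string qa, sa;
  int i = bi, j = bj, state = bstate;
  while (i > 0 || j > 0) {
    unsigned char p;
    const size_t off = (size_t)i * ncol + j;
    if (state == SM) {
      p = pM[off];
      if (p == 0) break;  // local fresh start or free edge start
      qa.push_back(q[(size_t)i - 1]);
      sa.push_back(s[(size_t)j - 1]);
      --i; --j;
      state = p - 1;
    } else if (state == SX) {
      p = pX[off];
      if (p == 0) break;
      qa.push_back(q[(size_t)i - 1]);
      sa.push_back('-');
      --i;
      state = p - 1;
    } else {
      p = pY[off];
      if (p == 0) break;
      qa.push_back('-');
      sa.push_back(s[(size_t)j - 1]);
      --j;
      state = p - 1;
    }
    if (i == 0 && j == 0) break;
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  res.qaln = qa; res.saln = sa;
  res.qstart = i; res.qend = bi;
  res.sstart = j; res.send = bj;
  res.columns = (int)qa.size();
  bool gq = false, gs = false;
  for (size_t k = 0; k < qa.size(); ++k) {
    if (qa[k] == '-') {
      if (!gq) { ++res.gapopens; gq = true; }
      gs = false;
    } else if (sa[k] == '-') {
      if (!gs) { ++res.gapopens; gs = true; }
      gq = false;
    } else {
      gq = gs = false;
      if (qa[k] == sa[k] && qa[k] != 'N') ++res.matches;
      else ++res.mismatches;
    }
  }
  return res;
}

int mode_code(const std::string& mode) {
  if (mode == "local") return 0;
  if (mode == "global") return 1;
  if (mode == "overlap") return 2;
  stop("unknown alignment mode: " + mode);
  return -1;
}

}  // namespace

// [[Rcpp::export]]
DataFrame cpp_align_batch(CharacterVector query, CharacterVector subject,
                          std::string mode = "local", int match = 2,
                          int mismatch = -3, int gap_open = 5,
                          int gap_extend = 2, bool keep_strings = false) {
  const int code = mode_code(mode);
  R_xlen_t nq = query.size(), ns = subject.size();
  R_xlen_t n = std::max(nq, ns);
  if (nq != ns && nq != 1 && ns != 1)
    stop("query and subject must have equal length (or length 1)");
  IntegerVector score(n), qstart(n), qend(n), sstart(n), send(n), matches(n),
      columns(n), mismatches(n), gapopens(n);
  NumericVector identity(n);
  CharacterVector qaln(n), saln(n);
  for (R_xlen_t k = 0; k < n; ++k) {
    std::string q = as<std::string>(query[nq == 1 ? 0 : k]);
    std::string s = as<std::string>(subject[ns == 1 ? 0 : k]);
    AlnResult r = align_core(q, s, code, match, mismatch, gap_open, gap_extend);
    score[k] = r.score; qstart[k] = r.qstart; qend[k] = r.qend;
    sstart[k] = r.sstart; send[k] = r.send;
    matches[k] = r.matches; columns[k] = r.columns;
    mismatches[k] = r.mismatches; gapopens[k] = r.gapopens;
    identity[k] = r.columns > 0 ? 100.0 * r.matches / r.columns : NA_REAL;
    if (keep_strings) { qaln[k] = r.qaln; saln[k] = r.saln; }
  }
  if (keep_strings)
    return DataFrame::create(
        _["score"] = score, _["identity"] = identity, _["matches"] = matches,
        _["columns"] = columns, _["mismatches"] = mismatches,
        _["gapopens"] = gapopens, _["qstart"] = qstart, _["qend"] = qend,
        _["sstart"] = sstart, _["send"] = send, _["qaln"] = qaln,
        _["saln"] = saln, _["stringsAsFactors"] = false);
  return DataFrame::create(
      _["score"] = score, _["identity"] = identity, _["matches"] = matches,
      _["columns"] = columns, _["mismatches"] = mismatches,
      _["gapopens"] = gapopens, _["qstart"] = qstart, _["qend"] = qend,
      _["sstart"] = sstart, _["send"] = send, _["stringsAsFactors"] = false);
}
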