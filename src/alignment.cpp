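#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh three-state DP).
// A gap of length g costs gap_open + g * gap_extend.
// Among maximum-score alignments the one with the most matched columns is
// taken, and among those the one with the fewest columns; this makes the
// reported identity (matches / alignment columns) deterministic.

namespace {

struct Cell {
  double score;
  int matches;
  int cols;
};

const double NEG_INF = -1e18;

inline bool better(const Cell &a, const Cell &b) {
  if (a.score != b.score) return a.score > b.score;
  if (a.matches != b.matches) return a.matches > b.matches;
  return a.cols < b.cols;
}

inline Cell step(const Cell &c, double ds, int dm, int dc) {
  Cell out;
  out.score = c.score + ds;
  out.matches = c.matches + dm;
  out.cols = c.cols + dc;
  return out;
}

inline Cell best3(const Cell &a, const Cell &b, const Cell &c) {
  Cell out = a;
  if (better(b, out)) out = b;
  if (better(c, out)) out = c;
  return out;
}

} // namespace

// [[Rcpp::export(name = ".nw_align_stats")]]
List nw_align_stats(std::string a, std::string b,
                    double match = 1.0, double mismatch = -1.0,
                    double gap_open = 2.0, double gap_extend = 1.0) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0)
    stop("both sequences must be non-empty");

  // rows: positions in a (0..n), rolling over i; columns j in 0..m
  std::vector<Cell> M(m + 1), X(m + 1), Y(m + 1);
  std::vector<Cell> Mp(m + 1), Xp(m + 1), Yp(m + 1);

  Cell dead = {NEG_INF, 0, 0};
  Mp[0] = {0.0, 0, 0};
  Xp[0] = dead;
  Yp[0] = dead;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = dead;
    Xp[j] = dead;
    Yp[j] = {-gap_open - j * gap_extend, 0, j}; // gap in a (consume b)
  }

  for (int i = 1; i <= n; ++i) {
    M[0] = dead;
    Y[0] = dead;
    X[0] = {-gap_open - i * gap_extend, 0, i}; // gap in b (consume a)
    for (int j = 1; j <= m; ++j) {
      bool is_match = a[i - 1] == b[j - 1];
      double s = is_match ? match : mismatch;
      Cell diag = best3(Mp[j - 1], Xp[j - 1], Yp[j - 1]);
      M[j] = (diag.score <= NEG_INF / 2) ? dead
                                         : step(diag, s, is_match ? 1 : 0, 1);
      // X: a[i-1] aligned to a gap; open from M/Y of previous row, extend X
      Cell fromM = step(Mp[j], -gap_open - gap_extend, 0, 1);
      Cell fromY = step(Yp[j], -gap_open - gap_extend, 0, 1);
      Cell fromX = step(Xp[j], -gap_extend, 0, 1);
      X[j] = best3(fromM, fromY, fromX);
      // Y: b[j-1] aligned to a gap; open from M/X of this row, extend Y
      Cell gM = step(M[j - 1], -gap_open - gap_extend, 0, 1);
      Cell gX = step(X[j - 1], -gap_open - gap_extend, 0, 1);
      Cell gY = step(Y[j - 1], -gap_extend, 0, 1);
      Y[j] = best3(gM, gX, gY);
    }
    std::swap(M, Mp);
    std::swap(X, Xp);
    std::swap(Y, Yp);
  }

  Cell fin = best3(Mp[m], Xp[m], Yp[m]);
  return List::create(_["score"] = fin.score,
                      _["matches"] = fin.matches,
                      _["columns"] = fin.cols,
                      _["identity"] = (double)fin.matches / (double)fin.cols);
}

// Ungapped X-drop extension along a fixed diagonal.
// chars: the scaffold as a raw character string; p, q: 1-based positions of
// the last already-matched columns of the two copies; dir = +1 extends right,
// -1 extends left. Returns the offset (>= 0) of the furthest extension whose
// running score is maximal (first such offset).
// [[Rcpp::export(name = ".xdrop_extend")]]
int xdrop_extend(std::string seq, int p, int q, int dir, double xdrop = 12.0,
                 double match = 1.0, double mismatch = -1.0) {
  int n = seq.size();
  double score = 0.0, best = 0.0;
  int best_off = 0;
  int off = 0;
  while (true) {
    ++off;
    int ip = p + dir * off, iq = q + dir * off;
    if (ip < 1 || iq < 1 || ip > n || iq > n) break;
    score += (seq[ip - 1] == seq[iq - 1]) ? match : mismatch;
    if (score > best) {
      best = score;
      best_off = off;
    }
    if (best - score > xdrop) break;
  }
  return best_off;
}
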