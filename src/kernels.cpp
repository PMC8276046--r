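#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 8-neighbourhood offsets, ring order starting East, counter-clockwise in
// (row, col) image coordinates with row increasing downwards:
// 0=E 1=SE 2=S 3=SW 4=W 5=NW 6=N 7=NE. 4-neighbours sit at even indices.
static const int DR[8] = {0, 1, 1, 1, 0, -1, -1, -1};
static const int DC[8] = {1, 1, 0, -1, -1, -1, 0, 1};

// Lookup tables over the 256 neighbour configurations: T8 = number of
// 8-connected foreground components in the punctured neighbourhood, T4B =
// number of 4-connected background components touching a 4-neighbour of the
// centre. A foreground pixel is (8,4)-simple iff T8 == 1 and T4B == 1:
// deleting it then changes neither foreground connectivity nor hole count.
static int T8_LUT[256];
static int T4B_LUT[256];
static bool LUT_READY = false;

static int find_root(int *par, int i) {
  while (par[i] != i) { par[i] = par[par[i]]; i = par[i]; }
  return i;
}

static void build_luts() {
  for (int cfg = 0; cfg < 256; ++cfg) {
    bool fg[8];
    for (int i = 0; i < 8; ++i) fg[i] = (cfg >> i) & 1;

    // union-find over the 8 ring cells under 8- resp. 4-adjacency of their
    // actual coordinates (the ring has diagonal chords under 8-adjacency)
    int par8[8], par4[8];
    for (int i = 0; i < 8; ++i) { par8[i] = i; par4[i] = i; }
    for (int i = 0; i < 8; ++i) {
      for (int j = i + 1; j < 8; ++j) {
        int dr = DR[i] - DR[j], dc = DC[i] - DC[j];
        int adr = dr < 0 ? -dr : dr, adc = dc < 0 ? -dc : dc;
        bool adj8 = (adr <= 1 && adc <= 1);
        bool adj4 = (adr + adc == 1);
        if (adj8 && fg[i] && fg[j]) {
          int a = find_root(par8, i), b = find_root(par8, j);
          par8[a] = b;
        }
        if (adj4 && !fg[i] && !fg[j]) {
          int a = find_root(par4, i), b = find_root(par4, j);
          par4[a] = b;
        }
      }
    }
    int t8 = 0;
    for (int i = 0; i < 8; ++i)
      if (fg[i] && find_root(par8, i) == i) ++t8;
    // background components counted only if they contain a 4-neighbour
    bool counted[8] = {false};
    int t4b = 0;
    for (int i = 0; i < 8; i += 2) {
      if (!fg[i]) {
        int r = find_root(par4, i);
        if (!counted[r]) { counted[r] = true; ++t4b; }
      }
    }
    T8_LUT[cfg] = t8;
    T4B_LUT[cfg] = t4b;
  }
  LUT_READY = true;
}

static inline int neigh_config(const LogicalMatrix &m, int r, int c) {
  int nr = m.nrow(), nc = m.ncol(), cfg = 0;
  for (int i = 0; i < 8; ++i) {
    int rr = r + DR[i], cc = c + DC[i];
    if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && m(rr, cc)) cfg |= (1 << i);
  }
  return cfg;
}

static inline int popcount8(int cfg) {
  int n = 0;
  for (int i = 0; i < 8; ++i) n += (cfg >> i) & 1;
  return n;
}

// Homotopic thinning: directional sub-iterations (N, S, E, W border pixels),
// deterministic raster order, sequential deletion of simple non-endpoints,
// iterated to convergence. Out-of-image neighbours are background.
// [[Rcpp::export]]
LogicalMatrix thin_homotopic_cpp(LogicalMatrix mask) {
  if (!LUT_READY) build_luts();
  LogicalMatrix m = clone(mask);
  int nr = m.nrow(), nc = m.ncol();
  // border directions in ring indices: N=6, S=2, E=0, W=4
  static const int DIRS[4] = {6, 2, 0, 4};
  bool changed = true;
  std::vector<std::pair<int, int> > cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 4; ++d) {
      int dr = DR[DIRS[d]], dc = DC[DIRS[d]];
      // two-phase: mark this direction's border pixels first so deletions
      // cannot cascade through the layer within one sub-iteration
      cand.clear();
      for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
          if (!m(r, c)) continue;
          int rr = r + dr, cc = c + dc;
          bool border = !(rr >= 0 && rr < nr && cc >= 0 && cc < nc && m(rr, cc));
          if (border) cand.push_back(std::make_pair(r, c));
        }
      }
      // sequential deletion, simplicity re-checked against the current image
      for (size_t i = 0; i < cand.size(); ++i) {
        int r = cand[i].first, c = cand[i].second;
        int cfg = neigh_config(m, r, c);
        int n = popcount8(cfg);
        if (n < 2) continue; // keep endpoints and isolated pixels
        if (T8_LUT[cfg] == 1 && T4B_LUT[cfg] == 1) {
          m(r, c) = FALSE;
          changed = true;
        }
      }
    }
  }
  return m;
}

// True where a foreground pixel is (8,4)-simple with >= 2 neighbours;
// convergence check used by tests (a thinned image has none).
// [[Rcpp::export]]
LogicalMatrix simple_points_cpp(LogicalMatrix mask) {
  if (!LUT_READY) build_luts();
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c)) { out(r, c) = FALSE; continue; }
      int cfg = neigh_config(mask, r, c);
      out(r, c) = (popcount8(cfg) >= 2 && T8_LUT[cfg] == 1 && T4B_LUT[cfg] == 1);
    }
  return out;
}

// Connected-component labelling, conn = 4 or 8, labels in raster-scan
// discovery order starting at 1; background stays 0.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int conn) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      // column-major scan matches R's storage; discovery order documented
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      ++next;
      lab(r0, c0) = next;
      q.push(std::make_pair(r0, c0));
      while (!q.empty()) {
        int r = q.front().first, c = q.front().second;
        q.pop();
        for (int i = 0; i < 8; ++i) {
          if (conn == 4 && (i % 2)) continue;
          int rr = r + DR[i], cc = c + DC[i];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && !lab(rr, cc)) {
            lab(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

// Median filter over an arbitrary offset window (rows of `offsets` are
// (dr, dc), centre included by the caller). If threshold >= 0, a pixel is
// replaced by the window median only when it deviates from it by more than
// the threshold (ImageJ-style outlier removal); threshold < 0 replaces
// unconditionally (plain median / despeckle). Windows are clipped at the
// image border.
// [[Rcpp::export]]
NumericMatrix median_window_cpp(NumericMatrix x, IntegerMatrix offsets,
                                double threshold) {
  int nr = x.nrow(), nc = x.ncol(), k = offsets.nrow();
  NumericMatrix out = clone(x);
  std::vector<double> buf;
  buf.reserve(k);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      buf.clear();
      for (int i = 0; i < k; ++i) {
        int rr = r + offsets(i, 0), cc = c + offsets(i, 1);
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc) buf.push_back(x(rr, cc));
      }
      size_t n = buf.size(), h = n / 2;
      std::nth_element(buf.begin(), buf.begin() + h, buf.end());
      double med = buf[h];
      if (n % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + h - 1, buf.begin() + h);
        med = 0.5 * (med + buf[h - 1]);
      }
      if (threshold < 0.0 || std::abs(x(r, c) - med) > threshold)
        out(r, c) = med;
    }
  }
  return out;
}

// Stamp filled discs of per-point radius onto a logical canvas; used by the
// synthetic generator so that rendered masks are exact and 8-connected.
// [[Rcpp::export]]
LogicalMatrix stamp_discs_cpp(LogicalMatrix canvas, NumericVector row,
                              NumericVector col, NumericVector radius) {
  LogicalMatrix m = clone(canvas);
  int nr = m.nrow(), nc = m.ncol();
  for (int i = 0; i < row.size(); ++i) {
    int r0 = (int)std::lround(row[i]), c0 = (int)std::lround(col[i]);
    double rad = radius[i];
    int ir = (int)std::floor(rad);
    for (int dr = -ir; dr <= ir; ++dr) {
      for (int dc = -ir; dc <= ir; ++dc) {
        if ((double)dr * dr + (double)dc * dc > rad * rad + 1e-9) continue;
        int rr = r0 + dr, cc = c0 + dc;
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc) m(rr, cc) = TRUE;
      }
    }
  }
  return m;
}
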