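// Pixel-level primitives for the foci-counting pipeline.
//
// Greyscale morphological reconstruction uses the hybrid algorithm
// (raster forward/backward sweeps followed by FIFO propagation), which
// reaches the same fixpoint as iterated geodesic dilation but in
// near-linear time. Regional maxima are found by flood-filling
// equal-valued plateaus and checking their borders.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

// neighbour offsets; first 4 are the 4-connected set
static const int DR[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
static const int DC[8] = {0, 0, -1, 1, -1, 1, -1, 1};

static inline int nNeigh(int conn) { return conn == 4 ? 4 : 8; }

// [[Rcpp::export]]
NumericMatrix cpp_reconstruct(NumericMatrix marker, NumericMatrix mask,
                              int conn = 8) {
  const int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask must have the same shape");
  const int nb = nNeigh(conn);
  NumericMatrix J = clone(marker);

  // forward sweep (column-major, same order as R storage)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = J(r, c);
      for (int k = 0; k < nb; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (cc < c || (cc == c && rr < r)) {  // already-visited neighbours
          if (J(rr, cc) > v) v = J(rr, cc);
        }
      }
      J(r, c) = std::min(v, mask(r, c));
    }
  }

  // backward sweep + queue seeding
  std::queue<int> fifo;
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      double v = J(r, c);
      for (int k = 0; k < nb; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (cc > c || (cc == c && rr > r)) {
          if (J(rr, cc) > v) v = J(rr, cc);
        }
      }
      v = std::min(v, mask(r, c));
      J(r, c) = v;
      for (int k = 0; k < nb; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (cc > c || (cc == c && rr > r)) {
          if (J(rr, cc) < v && J(rr, cc) < mask(rr, cc)) {
            fifo.push(c * nr + r);
            k = nb;  // seed once
          }
        }
      }
    }
  }

  while (!fifo.empty()) {
    int p = fifo.front();
    fifo.pop();
    int r = p % nr, c = p / nr;
    double v = J(r, c);
    for (int k = 0; k < nb; ++k) {
      int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (J(rr, cc) < v && mask(rr, cc) != J(rr, cc)) {
        J(rr, cc) = std::min(v, mask(rr, cc));
        fifo.push(cc * nr + rr);
      }
    }
  }
  return J;
}

// [[Rcpp::export]]
LogicalMatrix cpp_regional_maxima(NumericMatrix img, int conn = 8) {
  const int nr = img.nrow(), nc = img.ncol();
  const int nb = nNeigh(conn);
  LogicalMatrix out(nr, nc);
  std::vector<char> visited((size_t)nr * nc, 0);
  std::vector<int> plateau;

  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      int p0 = c0 * nr + r0;
      if (visited[p0]) continue;
      const double v = img(r0, c0);
      bool isMax = true;
      plateau.clear();
      std::queue<int> q;
      q.push(p0);
      visited[p0] = 1;
      while (!q.empty()) {
        int p = q.front();
        q.pop();
        plateau.push_back(p);
        int r = p % nr, c = p / nr;
        for (int k = 0; k < nb; ++k) {
          int rr = r + DR[k], cc = c + DC[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          double w = img(rr, cc);
          if (w > v) {
            isMax = false;
          } else if (w == v) {
            int pq = cc * nr + rr;
            if (!visited[pq]) {
              visited[pq] = 1;
              q.push(pq);
            }
          }
        }
      }
      if (isMax)
        for (size_t i = 0; i < plateau.size(); ++i) {
          int p = plateau[i];
          out(p % nr, p / nr) = true;
        }
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int conn = 8) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int nb = nNeigh(conn);
  IntegerMatrix lab(nr, nc);
  int next = 0;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
      ++next;
      std::queue<int> q;
      q.push(c0 * nr + r0);
      lab(r0, c0) = next;
      while (!q.empty()) {
        int p = q.front();
        q.pop();
        int r = p % nr, c = p / nr;
        for (int k = 0; k < nb; ++k) {
          int rr = r + DR[k], cc = c + DC[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(cc * nr + rr);
          }
        }
      }
    }
  }
  return lab;
}

// Fill background regions not reachable from the image border.
// Background is traversed 4-connected (complementary to 8-connected
// foreground, the standard pairing for consistent topology).
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix reached(nr, nc);
  std::queue<int> q;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; c += (nc > 1 ? nc - 1 : 1)) {
      if (!mask(r, c) && !reached(r, c)) {
        reached(r, c) = true;
        q.push(c * nr + r);
      }
      if (nc == 1) break;
    }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; r += (nr > 1 ? nr - 1 : 1)) {
      if (!mask(r, c) && !reached(r, c)) {
        reached(r, c) = true;
        q.push(c * nr + r);
      }
      if (nr == 1) break;
    }
  while (!q.empty()) {
    int p = q.front();
    q.pop();
    int r = p % nr, c = p / nr;
    for (int k = 0; k < 4; ++k) {
      int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (!mask(rr, cc) && !reached(rr, cc)) {
        reached(rr, cc) = true;
        q.push(cc * nr + rr);
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = mask(r, c) || !reached(r, c);
  return out;
}

// Edge-preserving bilateral filter; window truncated at borders so no
// pixel values are invented beyond the image.
// [[Rcpp::export]]
NumericMatrix cpp_bilateral(NumericMatrix img, double sigmaSpatial,
                            double sigmaRange, int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  const int w = 2 * radius + 1;
  std::vector<double> ws((size_t)w * w);
  const double invS = 1.0 / (2.0 * sigmaSpatial * sigmaSpatial);
  const double invR = 1.0 / (2.0 * sigmaRange * sigmaRange);
  for (int dc = -radius; dc <= radius; ++dc)
    for (int dr = -radius; dr <= radius; ++dr)
      ws[(size_t)(dc + radius) * w + (dr + radius)] =
          std::exp(-(double)(dr * dr + dc * dc) * invS);

  for (int c = 0; c < nc; ++c) {
    const int c0 = std::max(0, c - radius), c1 = std::min(nc - 1, c + radius);
    for (int r = 0; r < nr; ++r) {
      const int r0 = std::max(0, r - radius), r1 = std::min(nr - 1, r + radius);
      const double v = img(r, c);
      double num = 0.0, den = 0.0;
      for (int cc = c0; cc <= c1; ++cc) {
        const double* wcol = &ws[(size_t)(cc - c + radius) * w];
        for (int rr = r0; rr <= r1; ++rr) {
          const double u = img(rr, cc);
          const double d = u - v;
          const double wgt = wcol[rr - r + radius] * std::exp(-d * d * invR);
          num += wgt * u;
          den += wgt;
        }
      }
      out(r, c) = num / den;
    }
  }
  return out;
}

// Local mean over an odd 'block' window, truncated at borders.
// [[Rcpp::export]]
NumericMatrix cpp_box_mean(NumericMatrix img, int block) {
  const int nr = img.nrow(), nc = img.ncol();
  const int b = block / 2;
  // integral image with a zero first row/column
  std::vector<double> S((size_t)(nr + 1) * (nc + 1), 0.0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      S[(size_t)(c + 1) * (nr + 1) + (r + 1)] =
          img(r, c) + S[(size_t)c * (nr + 1) + (r + 1)] +
          S[(size_t)(c + 1) * (nr + 1) + r] - S[(size_t)c * (nr + 1) + r];
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    const int c0 = std::max(0, c - b), c1 = std::min(nc - 1, c + b);
    for (int r = 0; r < nr; ++r) {
      const int r0 = std::max(0, r - b), r1 = std::min(nr - 1, r + b);
      const double s = S[(size_t)(c1 + 1) * (nr + 1) + (r1 + 1)] -
                       S[(size_t)c0 * (nr + 1) + (r1 + 1)] -
                       S[(size_t)(c1 + 1) * (nr + 1) + r0] +
                       S[(size_t)c0 * (nr + 1) + r0];
      out(r, c) = s / ((double)(r1 - r0 + 1) * (c1 - c0 + 1));
    }
  }
  return out;
}
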