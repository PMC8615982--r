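// Generalized Gauss integrals of a polygonal space curve (the Calpha
// backbone). The building block is the pairwise writhe matrix w(a, b): the
// Gauss double integral over edge pair (a, b), evaluated exactly as the
// signed solid angle of the tetrahedron spanned by the two segments
// (Klenin & Langowski style). Descriptors are sums of products of w (or
// |w|) over chord patterns of order <= 3; prefix-sum tables collapse the
// last chord so order-2 terms cost O(m^2) and order-3 terms O(m^4) with an
// O(1) inner step.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

inline void cross3(const double *a, const double *b, double *out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

inline double norm3(const double *a) {
  return std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
}

inline double clamp1(double x) {
  return x > 1.0 ? 1.0 : (x < -1.0 ? -1.0 : x);
}

// Gauss double integral over segments (p1->p2), (p3->p4), times 2 so that
// the writhe of the curve is the sum over unordered edge pairs.
double edge_pair_writhe(const double *p1, const double *p2,
                        const double *p3, const double *p4) {
  double r13[3], r14[3], r23[3], r24[3], r12[3], r34[3];
  for (int k = 0; k < 3; ++k) {
    r13[k] = p3[k] - p1[k];
    r14[k] = p4[k] - p1[k];
    r23[k] = p3[k] - p2[k];
    r24[k] = p4[k] - p2[k];
    r12[k] = p2[k] - p1[k];
    r34[k] = p4[k] - p3[k];
  }
  double n1[3], n2[3], n3[3], n4[3];
  cross3(r13, r14, n1);
  cross3(r14, r24, n2);
  cross3(r24, r23, n3);
  cross3(r23, r13, n4);
  double l1 = norm3(n1), l2 = norm3(n2), l3 = norm3(n3), l4 = norm3(n4);
  if (l1 < 1e-12 || l2 < 1e-12 || l3 < 1e-12 || l4 < 1e-12) return 0.0;
  for (int k = 0; k < 3; ++k) {
    n1[k] /= l1; n2[k] /= l2; n3[k] /= l3; n4[k] /= l4;
  }
  double omega =
      std::asin(clamp1(n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2])) +
      std::asin(clamp1(n2[0] * n3[0] + n2[1] * n3[1] + n2[2] * n3[2])) +
      std::asin(clamp1(n3[0] * n4[0] + n3[1] * n4[1] + n3[2] * n4[2])) +
      std::asin(clamp1(n4[0] * n1[0] + n4[1] * n1[1] + n4[2] * n1[2]));
  double cr[3];
  cross3(r34, r12, cr);
  double sgn = cr[0] * r13[0] + cr[1] * r13[1] + cr[2] * r13[2];
  double s = (sgn > 0) - (sgn < 0);
  return 2.0 * s * omega / (4.0 * M_PI);
}

// prefix table P[x][y] = sum_{a <= x, b <= y, a < b} w[a][b], 1-based with
// zero row/column 0.
struct Prefix {
  int m;
  std::vector<double> p;
  void build(const std::vector<double> &w, int m_) {
    m = m_;
    p.assign((size_t)(m + 1) * (m + 1), 0.0);
    for (int x = 1; x <= m; ++x) {
      for (int y = 1; y <= m; ++y) {
        double v = (x < y) ? w[(size_t)(x - 1) * m + (y - 1)] : 0.0;
        p[(size_t)x * (m + 1) + y] = v +
            p[(size_t)(x - 1) * (m + 1) + y] +
            p[(size_t)x * (m + 1) + (y - 1)] -
            p[(size_t)(x - 1) * (m + 1) + (y - 1)];
      }
    }
  }
  inline double at(int x, int y) const {
    if (x < 0) x = 0;
    if (y < 0) y = 0;
    if (x > m) x = m;
    if (y > m) y = m;
    return p[(size_t)x * (m + 1) + y];
  }
  // sum over chords (c, d), c in [c1, c2], d in [d1, d2], with c2 < d1
  inline double rect(int c1, int c2, int d1, int d2) const {
    if (c1 > c2 || d1 > d2) return 0.0;
    return at(c2, d2) - at(c1 - 1, d2) - at(c2, d1 - 1) + at(c1 - 1, d1 - 1);
  }
  // sum over chords (c, d) with l <= c < d <= r
  inline double tri(int l, int r) const {
    if (l >= r) return 0.0;
    return at(r, r) - at(l - 1, r);
  }
};

// the 15 perfect matchings of positions 1..6
const int MATCHINGS[15][6] = {
  {1, 2, 3, 4, 5, 6}, {1, 2, 3, 5, 4, 6}, {1, 2, 3, 6, 4, 5},
  {1, 3, 2, 4, 5, 6}, {1, 3, 2, 5, 4, 6}, {1, 3, 2, 6, 4, 5},
  {1, 4, 2, 3, 5, 6}, {1, 4, 2, 5, 3, 6}, {1, 4, 2, 6, 3, 5},
  {1, 5, 2, 3, 4, 6}, {1, 5, 2, 4, 3, 6}, {1, 5, 2, 6, 3, 4},
  {1, 6, 2, 3, 4, 5}, {1, 6, 2, 4, 3, 5}, {1, 6, 2, 5, 3, 4}
};

} // namespace

// [[Rcpp::export]]
NumericVector gauss_integrals_cpp(NumericMatrix ca) {
  const int n = ca.nrow();
  NumericVector out(31);
  if (n < 4) return out;
  const int m = n - 1; // edges
  std::vector<double> pts((size_t)n * 3);
  for (int i = 0; i < n; ++i) {
    pts[i * 3] = ca(i, 0);
    pts[i * 3 + 1] = ca(i, 1);
    pts[i * 3 + 2] = ca(i, 2);
  }
  std::vector<double> w((size_t)m * m, 0.0), wa((size_t)m * m, 0.0);
  double writhe = 0.0, acn = 0.0;
  for (int a = 0; a < m; ++a) {
    for (int b = a + 2; b < m; ++b) {
      double v = edge_pair_writhe(&pts[a * 3], &pts[(a + 1) * 3],
                                  &pts[b * 3], &pts[(b + 1) * 3]);
      w[(size_t)a * m + b] = v;
      wa[(size_t)a * m + b] = std::fabs(v);
      writhe += v;
      acn += std::fabs(v);
    }
  }
  out[0] = writhe; // I(1,2)
  out[1] = acn;    // |I|(1,2), average crossing number

  Prefix Pw, Pa;
  Pw.build(w, m);
  Pa.build(wa, m);
  auto W = [&](int a, int b) { return w[(size_t)(a - 1) * m + (b - 1)]; };
  auto Wa = [&](int a, int b) { return wa[(size_t)(a - 1) * m + (b - 1)]; };

  // order 2: patterns (12)(34), (13)(24), (14)(23), each with the four
  // signed/absolute factor combinations (ss, as, sa, aa)
  double o2[3][4] = {{0}};
  for (int a = 1; a <= m; ++a) {
    for (int b = a + 2; b <= m; ++b) {
      double ws = W(a, b), wab = Wa(a, b);
      if (wab == 0.0) continue;
      // (12)(34): second chord entirely after b
      double s2 = Pw.tri(b + 1, m), a2 = Pa.tri(b + 1, m);
      o2[0][0] += ws * s2;  o2[0][1] += wab * s2;
      o2[0][2] += ws * a2;  o2[0][3] += wab * a2;
      // (13)(24): second chord (c, d), a < c < b, d > b
      s2 = Pw.rect(a + 1, b - 1, b + 1, m);
      a2 = Pa.rect(a + 1, b - 1, b + 1, m);
      o2[1][0] += ws * s2;  o2[1][1] += wab * s2;
      o2[1][2] += ws * a2;  o2[1][3] += wab * a2;
      // (14)(23): second chord nested inside (a, b)
      s2 = Pw.tri(a + 1, b - 1);
      a2 = Pa.tri(a + 1, b - 1);
      o2[2][0] += ws * s2;  o2[2][1] += wab * s2;
      o2[2][2] += ws * a2;  o2[2][3] += wab * a2;
    }
  }
  int oi = 2;
  for (int p = 0; p < 3; ++p) {
    for (int c = 0; c < 4; ++c) out[oi++] = o2[p][c];
  }

  // order 3: the 15 signed matchings, plus fully-absolute variants of
  // (12)(34)(56) (index 0) and (14)(25)(36) (index 7)
  double o3[15] = {0}, o3abs[2] = {0};
  // per matching: which position pairs with 6, and the two fixed chords as
  // positions among the remaining ordered positions (ranks 0..3)
  int mate6[15], fixA0[15], fixA1[15], fixB0[15], fixB1[15], rank_q[15];
  for (int t = 0; t < 15; ++t) {
    const int *mm = MATCHINGS[t];
    int pairpos[7];
    for (int k = 0; k < 3; ++k) {
      pairpos[mm[2 * k]] = mm[2 * k + 1];
      pairpos[mm[2 * k + 1]] = mm[2 * k];
    }
    int q = pairpos[6];
    mate6[t] = q;
    int rest[4], rn = 0;
    for (int p = 1; p <= 5; ++p) {
      if (p != q) rest[rn++] = p;
    }
    int chord[2][2], cn = 0;
    for (int k = 0; k < 3; ++k) {
      int p1 = mm[2 * k], p2 = mm[2 * k + 1];
      if (p2 == 6) continue;
      int r1 = -1, r2 = -1;
      for (int r = 0; r < 4; ++r) {
        if (rest[r] == p1) r1 = r;
        if (rest[r] == p2) r2 = r;
      }
      chord[cn][0] = r1;
      chord[cn][1] = r2;
      ++cn;
    }
    fixA0[t] = chord[0][0]; fixA1[t] = chord[0][1];
    fixB0[t] = chord[1][0]; fixB1[t] = chord[1][1];
    // rank of q among the 4 fixed positions: number of fixed positions < q
    int rq = 0;
    for (int r = 0; r < 4; ++r) {
      if (rest[r] < q) ++rq;
    }
    rank_q[t] = rq;
  }

  for (int i1 = 1; i1 <= m; ++i1) {
    for (int i2 = i1 + 1; i2 <= m; ++i2) {
      for (int i3 = i2 + 1; i3 <= m; ++i3) {
        for (int i4 = i3 + 1; i4 <= m; ++i4) {
          int idx[4] = {i1, i2, i3, i4};
          for (int t = 0; t < 15; ++t) {
            double f1 = W(idx[fixA0[t]], idx[fixA1[t]]);
            double f2 = W(idx[fixB0[t]], idx[fixB1[t]]);
            bool want_abs = (t == 0 || t == 7);
            if (f1 == 0.0 || f2 == 0.0) {
              if (!want_abs) continue;
            }
            int rq = rank_q[t];
            double s3, a3;
            if (rq == 4) { // q above all fixed: both endpoints after i4
              s3 = Pw.tri(i4 + 1, m);
              a3 = Pa.tri(i4 + 1, m);
            } else {
              int lo = (rq == 0) ? 1 : idx[rq - 1] + 1;
              int hi = idx[rq] - 1;
              s3 = Pw.rect(lo, hi, i4 + 1, m);
              a3 = Pa.rect(lo, hi, i4 + 1, m);
            }
            o3[t] += f1 * f2 * s3;
            if (want_abs) {
              double g1 = std::fabs(f1), g2 = std::fabs(f2);
              o3abs[t == 0 ? 0 : 1] += g1 * g2 * a3;
            }
          }
        }
      }
    }
  }
  for (int t = 0; t < 15; ++t) out[oi++] = o3[t];
  out[oi++] = o3abs[0];
  out[oi++] = o3abs[1];
  return out;
}
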