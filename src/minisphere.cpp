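#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact minimal enclosing sphere of a 3D point set.
// Primary path: Welzl's randomized move-to-front algorithm (expected O(n)).
// Oracle path (tests only): exhaustive enumeration over boundary subsets.

namespace {

struct Ball {
  double c[3];
  double r2;  // squared radius; r2 < 0 means "empty"
};

inline double dist2(const double* a, const double* b) {
  double d0 = a[0] - b[0], d1 = a[1] - b[1], d2 = a[2] - b[2];
  return d0 * d0 + d1 * d1 + d2 * d2;
}

inline bool contains(const Ball& B, const double* p, double tol) {
  if (B.r2 < 0) return false;
  return dist2(B.c, p) <= B.r2 + tol * (1.0 + B.r2);
}

Ball ball0() { Ball B; B.c[0] = B.c[1] = B.c[2] = 0; B.r2 = -1; return B; }

Ball ball1(const double* a) {
  Ball B; B.c[0] = a[0]; B.c[1] = a[1]; B.c[2] = a[2]; B.r2 = 0; return B;
}

Ball ball2(const double* a, const double* b) {
  Ball B;
  for (int t = 0; t < 3; ++t) B.c[t] = 0.5 * (a[t] + b[t]);
  B.r2 = dist2(B.c, a);
  return B;
}

// circumscribed ball with all 3 points on the boundary (circumcircle of the
// triangle, embedded in 3D); invalid (r2 < 0) if the points are collinear
Ball circum3(const double* A, const double* B_, const double* C) {
  double a[3], b[3];
  for (int t = 0; t < 3; ++t) { a[t] = B_[t] - A[t]; b[t] = C[t] - A[t]; }
  double axb[3] = { a[1] * b[2] - a[2] * b[1],
                    a[2] * b[0] - a[0] * b[2],
                    a[0] * b[1] - a[1] * b[0] };
  double n2 = axb[0] * axb[0] + axb[1] * axb[1] + axb[2] * axb[2];
  double la = a[0] * a[0] + a[1] * a[1] + a[2] * a[2];
  double lb = b[0] * b[0] + b[1] * b[1] + b[2] * b[2];
  Ball R = ball0();
  double scale = std::max(la, lb);
  if (n2 <= 1e-24 * scale * scale * scale) return R;  // collinear
  // c = A + [ la*(b x (a x b)) + lb*((a x b) x a) ] / (2 |a x b|^2)
  double t1[3] = { b[1] * axb[2] - b[2] * axb[1],
                   b[2] * axb[0] - b[0] * axb[2],
                   b[0] * axb[1] - b[1] * axb[0] };   // b x (a x b)
  double t2[3] = { axb[1] * a[2] - axb[2] * a[1],
                   axb[2] * a[0] - axb[0] * a[2],
                   axb[0] * a[1] - axb[1] * a[0] };   // (a x b) x a
  for (int t = 0; t < 3; ++t)
    R.c[t] = A[t] + (la * t1[t] + lb * t2[t]) / (2.0 * n2);
  R.r2 = dist2(R.c, A);
  return R;
}

// circumsphere of 4 points; invalid if coplanar
Ball circum4(const double* A, const double* B_, const double* C,
             const double* D) {
  double M[3][3], rhs[3];
  const double* P[3] = { B_, C, D };
  for (int r = 0; r < 3; ++r) {
    double s = 0;
    for (int t = 0; t < 3; ++t) {
      M[r][t] = 2.0 * (P[r][t] - A[t]);
      s += P[r][t] * P[r][t] - A[t] * A[t];
    }
    rhs[r] = s;
  }
  // Gaussian elimination with partial pivoting
  int piv[3] = { 0, 1, 2 };
  Ball R = ball0();
  for (int col = 0; col < 3; ++col) {
    int best = col;
    for (int r = col + 1; r < 3; ++r)
      if (std::fabs(M[r][col]) > std::fabs(M[best][col])) best = r;
    if (std::fabs(M[best][col]) < 1e-12) return R;  // coplanar
    if (best != col) {
      for (int t = 0; t < 3; ++t) std::swap(M[col][t], M[best][t]);
      std::swap(rhs[col], rhs[best]);
      std::swap(piv[col], piv[best]);
    }
    for (int r = col + 1; r < 3; ++r) {
      double f = M[r][col] / M[col][col];
      for (int t = col; t < 3; ++t) M[r][t] -= f * M[col][t];
      rhs[r] -= f * rhs[col];
    }
  }
  for (int r = 2; r >= 0; --r) {
    double s = rhs[r];
    for (int t = r + 1; t < 3; ++t) s -= M[r][t] * R.c[t];
    R.c[r] = s / M[r][r];
  }
  R.r2 = dist2(R.c, A);
  return R;
}

// smallest ball with all support points on its boundary; robust to
// degenerate (collinear/coplanar) supports by falling back to sub-supports
Ball ball_support(const std::vector<const double*>& S) {
  size_t k = S.size();
  if (k == 0) return ball0();
  if (k == 1) return ball1(S[0]);
  double tol = 1e-10;
  Ball best = ball0();
  best.r2 = R_PosInf;
  bool found = false;
  // try all subsets of size >= 2 (size-1 cannot bound 2+ distinct points)
  for (size_t i = 0; i < k; ++i)
    for (size_t j = i + 1; j < k; ++j) {
      Ball B = ball2(S[i], S[j]);
      bool ok = true;
      for (size_t t = 0; t < k && ok; ++t) ok = contains(B, S[t], tol);
      if (ok && B.r2 < best.r2) { best = B; found = true; }
    }
  if (k >= 3) {
    for (size_t i = 0; i < k; ++i)
      for (size_t j = i + 1; j < k; ++j)
        for (size_t l = j + 1; l < k; ++l) {
          Ball B = circum3(S[i], S[j], S[l]);
          if (B.r2 < 0) continue;
          bool ok = true;
          for (size_t t = 0; t < k && ok; ++t) ok = contains(B, S[t], tol);
          if (ok && B.r2 < best.r2) { best = B; found = true; }
        }
  }
  if (k == 4) {
    Ball B = circum4(S[0], S[1], S[2], S[3]);
    if (B.r2 >= 0) {
      bool ok = true;
      for (size_t t = 0; t < k && ok; ++t) ok = contains(B, S[t], tol);
      if (ok && B.r2 < best.r2) { best = B; found = true; }
    }
  }
  if (!found) return ball0();
  return best;
}

Ball welzl(std::vector<const double*>& pts, size_t n,
           std::vector<const double*>& support) {
  Ball B = ball_support(support);
  if (support.size() == 4) return B;
  for (size_t i = 0; i < n; ++i) {
    if (!contains(B, pts[i], 1e-10)) {
      support.push_back(pts[i]);
      B = welzl(pts, i, support);
      support.pop_back();
      // move-to-front: keep influential points early
      const double* p = pts[i];
      for (size_t j = i; j > 0; --j) pts[j] = pts[j - 1];
      pts[0] = p;
    }
  }
  return B;
}

}  // namespace

// [[Rcpp::export(name = ".miniball_cpp")]]
NumericVector miniball_cpp(NumericMatrix pts) {
  R_xlen_t n = pts.nrow();
  if (n < 1) stop("need at least one point");
  std::vector<double> buf(3 * n);
  std::vector<const double*> P(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    buf[3 * i] = pts(i, 0); buf[3 * i + 1] = pts(i, 1);
    buf[3 * i + 2] = pts(i, 2);
    P[i] = &buf[3 * i];
  }
  std::vector<const double*> support;
  Ball B = welzl(P, (size_t)n, support);
  return NumericVector::create(B.c[0], B.c[1], B.c[2],
                               std::sqrt(std::max(0.0, B.r2)));
}

// Independent oracle: exhaustive enumeration over all boundary subsets of
// size 1..4; returns the smallest ball that encloses every point. O(n^4 * n).
// [[Rcpp::export(name = ".miniball_bruteforce_cpp")]]
NumericVector miniball_bruteforce_cpp(NumericMatrix pts) {
  R_xlen_t n = pts.nrow();
  if (n < 1) stop("need at least one point");
  std::vector<double> buf(3 * n);
  std::vector<const double*> P(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    buf[3 * i] = pts(i, 0); buf[3 * i + 1] = pts(i, 1);
    buf[3 * i + 2] = pts(i, 2);
    P[i] = &buf[3 * i];
  }
  const double tol = 1e-9;
  Ball best = ball0();
  best.r2 = R_PosInf;
  if (n == 1) { best = ball1(P[0]); }
  for (R_xlen_t i = 0; i < n; ++i)
    for (R_xlen_t j = i + 1; j < n; ++j) {
      Ball B = ball2(P[i], P[j]);
      if (B.r2 >= best.r2) continue;
      bool ok = true;
      for (R_xlen_t t = 0; t < n && ok; ++t) ok = contains(B, P[t], tol);
      if (ok) best = B;
    }
  for (R_xlen_t i = 0; i < n; ++i)
    for (R_xlen_t j = i + 1; j < n; ++j)
      for (R_xlen_t l = j + 1; l < n; ++l) {
        Ball B = circum3(P[i], P[j], P[l]);
        if (B.r2 < 0 || B.r2 >= best.r2) continue;
        bool ok = true;
        for (R_xlen_t t = 0; t < n && ok; ++t) ok = contains(B, P[t], tol);
        if (ok) best = B;
      }
  for (R_xlen_t i = 0; i < n; ++i)
    for (R_xlen_t j = i + 1; j < n; ++j)
      for (R_xlen_t l = j + 1; l < n; ++l)
        for (R_xlen_t m = l + 1; m < n; ++m) {
          Ball B = circum4(P[i], P[j], P[l], P[m]);
          if (B.r2 < 0 || B.r2 >= best.r2) continue;
          bool ok = true;
          for (R_xlen_t t = 0; t < n && ok; ++t) ok = contains(B, P[t], tol);
          if (ok) best = B;
        }
  return NumericVector::create(best.c[0], best.c[1], best.c[2],
                               std::sqrt(std::max(0.0, best.r2)));
}
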