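#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Dominant (Perron) eigenvalue of a non-negative 3x3 matrix via the
// characteristic cubic. For non-negative matrices the spectral radius is
// itself an eigenvalue, so the largest real root is the dominant one.
static double dom_eig3(const double A[3][3]) {
  const double tr = A[0][0] + A[1][1] + A[2][2];
  // sum of principal 2x2 minors
  const double m = (A[0][0] * A[1][1] - A[0][1] * A[1][0]) +
                   (A[0][0] * A[2][2] - A[0][2] * A[2][0]) +
                   (A[1][1] * A[2][2] - A[1][2] * A[2][1]);
  const double det =
      A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
      A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
      A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  // lambda^3 - tr lambda^2 + m lambda - det = 0; depressed cubic y^3+py+q
  const double p = m - tr * tr / 3.0;
  const double q = -2.0 * tr * tr * tr / 27.0 + tr * m / 3.0 - det;
  const double shift = tr / 3.0;
  const double disc = -4.0 * p * p * p - 27.0 * q * q;
  double y;
  if (p < -1e-14 && disc >= 0) {
    // three real roots: trigonometric form, k = 0 gives the largest
    const double r = 2.0 * std::sqrt(-p / 3.0);
    double arg = 3.0 * q / (2.0 * p) * std::sqrt(-3.0 / p);
    if (arg > 1.0) arg = 1.0;
    if (arg < -1.0) arg = -1.0;
    y = r * std::cos(std::acos(arg) / 3.0);
  } else {
    double rad = q * q / 4.0 + p * p * p / 27.0;
    if (rad < 0) rad = 0;
    const double s = std::sqrt(rad);
    y = std::cbrt(-q / 2.0 + s) + std::cbrt(-q / 2.0 - s);
  }
  // deflate by the found root and consider the remaining (possibly equal
  // or nearly equal) roots: rounding near repeated roots can make either
  // branch return a non-dominant real root, and the Perron root is the
  // maximum real one
  const double disc2 = -3.0 * y * y - 4.0 * p;
  if (disc2 >= 0) {
    const double r2 = (-y + std::sqrt(disc2)) / 2.0;
    if (r2 > y) y = r2;
  }
  return y + shift;
}

static double growth_frac(double s1, double lam, double T) {
  const double r = s1 / lam;
  if (std::fabs(r - 1.0) < 1e-9) return 1.0 / T;
  const double rT = std::pow(r, T);
  const double rT1 = std::pow(r, T - 1.0);
  double g = (rT - rT1) / (rT - 1.0);
  if (g < 0.0) g = 0.0;
  if (g > 1.0) g = 1.0;
  return g;
}

static void fill_matrix(double A[3][3], const double* v, double g) {
  // v = (s0, s1, s2, s3, b, e, h, f)
  const double s0 = v[0], s1 = v[1], s2 = v[2], s3 = v[3], b = v[4],
               e = v[5], h = v[6], f = v[7];
  A[0][0] = s1 * (1.0 - g); A[0][1] = (e / 2.0) * h * f * s0; A[0][2] = 0.0;
  A[1][0] = s1 * g;         A[1][1] = s2 * b;                 A[1][2] = s3 * b;
  A[2][0] = 0.0;            A[2][1] = s2 * (1.0 - b);         A[2][2] = s3 * (1.0 - b);
}

// [[Rcpp::export(name = ".solve_stage_cpp")]]
List solve_stage_cpp(NumericVector vitals, double T, double tol = 1e-6,
                     int max_iter = 500, double lambda0 = 1.0) {
  double A[3][3];
  const double* v = vitals.begin();
  double lam = lambda0, lam_prev = lambda0, g;
  bool converged = false;
  int it = 0;
  if (T < 1.0) {
    // recruitment and first breeding coincide: sub-adult stage has zero
    // duration, all survivors transition immediately
    g = 1.0;
    fill_matrix(A, v, g);
    lam = dom_eig3(A);
    converged = true;
  } else {
    for (it = 1; it <= max_iter; ++it) {
      g = growth_frac(v[1], lam, T);
      fill_matrix(A, v, g);
      const double lam2 = dom_eig3(A);
      lam_prev = lam;
      if (std::fabs(lam2 - lam) < tol) {
        lam = lam2;
        converged = true;
        break;
      }
      lam = lam2;
    }
    g = growth_frac(v[1], lam, T);
    fill_matrix(A, v, g);
  }
  NumericMatrix Aout(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) Aout(i, j) = A[i][j];
  return List::create(_["A"] = Aout, _["lambda"] = lam, _["g"] = g,
                      _["converged"] = converged, _["iterations"] = it,
                      _["lambda_prev"] = lam_prev);
}

// [[Rcpp::export(name = ".dominant_eig3_cpp")]]
double dominant_eig3_cpp(NumericMatrix A) {
  double a[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) a[i][j] = A(i, j);
  return dom_eig3(a);
}

// Stable stage distribution by power iteration (matrix assumed primitive
// enough for the uses inside the likelihood; the R-level API uses eigen()).
static void ssd3(const double A[3][3], double w[3]) {
  double v[3] = {1.0 / 3, 1.0 / 3, 1.0 / 3}, nv[3];
  for (int it = 0; it < 400; ++it) {
    for (int i = 0; i < 3; ++i)
      nv[i] = A[i][0] * v[0] + A[i][1] * v[1] + A[i][2] * v[2];
    double s = nv[0] + nv[1] + nv[2];
    if (s <= 0) { w[0] = w[1] = w[2] = 1.0 / 3; return; }
    for (int i = 0; i < 3; ++i) v[i] = nv[i] / s;
  }
  for (int i = 0; i < 3; ++i) w[i] = v[i];
}

// Deterministic latent trajectory of total female abundance for the
// state-space likelihood: start at N1 spread over the stable stage
// distribution of the initial matrix, project with Apre up to and including
// year switch_idx - 1, with Apost from switch_idx on (1-based year index of
// first post-switch transition target; 0 means Apre throughout).
// [[Rcpp::export(name = ".project_totals_cpp")]]
NumericVector project_totals_cpp(NumericMatrix Apre, NumericMatrix Apost,
                                 int switch_idx, double N1, int n_years) {
  double a[3][3], b[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) { a[i][j] = Apre(i, j); b[i][j] = Apost(i, j); }
  double w[3];
  ssd3(a, w);
  double n[3] = {N1 * w[0], N1 * w[1], N1 * w[2]}, nn[3];
  NumericVector out(n_years);
  out[0] = N1;
  for (int t = 1; t < n_years; ++t) {
    const bool post = (switch_idx > 0) && (t >= switch_idx);
    const double(*M)[3] = post ? b : a;
    for (int i = 0; i < 3; ++i)
      nn[i] = M[i][0] * n[0] + M[i][1] * n[1] + M[i][2] * n[2];
    for (int i = 0; i < 3; ++i) n[i] = nn[i];
    out[t] = n[0] + n[1] + n[2];
  }
  return out;
}
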