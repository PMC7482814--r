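#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gauss-Legendre nodes/weights on [-1, 1] by Newton iteration on the
// Legendre polynomial roots (standard Golub-Welsch-free construction).
static void gauss_legendre(int n, std::vector<double> &x, std::vector<double> &w) {
  x.assign(n, 0.0);
  w.assign(n, 0.0);
  int m = (n + 1) / 2;
  for (int i = 0; i < m; ++i) {
    double z = std::cos(M_PI * (i + 0.75) / (n + 0.5));
    double z1 = 2.0, pp = 0.0;
    while (std::fabs(z - z1) > 1e-14) {
      double p1 = 1.0, p2 = 0.0;
      for (int j = 0; j < n; ++j) {
        double p3 = p2;
        p2 = p1;
        p1 = ((2.0 * j + 1.0) * z * p2 - j * p3) / (j + 1.0);
      }
      pp = n * (z * p1 - p2) / (z * z - 1.0);
      z1 = z;
      z = z1 - p1 / pp;
    }
    x[i] = -z;
    x[n - 1 - i] = z;
    w[i] = 2.0 / ((1.0 - z * z) * pp * pp);
    w[n - 1 - i] = w[i];
  }
}

// log of integral_0^{w0} w^a / (W + B w)^c dw via Gauss-Legendre on (0, w0),
// evaluated in log space (the integrand spans hundreds of orders of magnitude
// once c = m(n-1)/2 is large).
static double log_data_integral(double a, double W, double B, double c,
                                double w0,
                                const std::vector<double> &gx,
                                const std::vector<double> &gw) {
  int n = gx.size();
  double mx = R_NegInf;
  std::vector<double> lg(n);
  for (int i = 0; i < n; ++i) {
    double w = 0.5 * w0 * (gx[i] + 1.0);
    double denom = W + B * w;
    if (denom < 1e-300) denom = 1e-300;
    lg[i] = a * std::log(w) - c * std::log(denom) + std::log(0.5 * w0 * gw[i]);
    if (lg[i] > mx) mx = lg[i];
  }
  if (!R_FINITE(mx)) return mx;
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::exp(lg[i] - mx);
  return mx + std::log(s);
}

// log integral_0^{p0} p^b (1-p)^{nb-b} dp  (incomplete beta in closed form)
static double log_prior_integral(int b, int nb, double p0) {
  double sh1 = b + 1.0, sh2 = nb - b + 1.0;
  return R::pbeta(p0, sh1, sh2, 1, 1) + R::lbeta(sh1, sh2);
}

struct RegionStats {
  double W; // within sum of squares, summed over series
  double B; // between sum of squares about per-series grand means
};

// contribution of rows (a, c] (0-based, exclusive a) as one block
static RegionStats region_stats(int a, int c, int m,
                                const std::vector<double> &S1,
                                const std::vector<double> &S2,
                                const std::vector<double> &gmean,
                                int n) {
  RegionStats r = {0.0, 0.0};
  double len = c - a;
  for (int s = 0; s < m; ++s) {
    double sum = S1[(size_t)c * m + s] - S1[(size_t)a * m + s];
    double ssq = S2[(size_t)c * m + s] - S2[(size_t)a * m + s];
    double mean = sum / len;
    double w = ssq - sum * sum / len;
    if (w < 0) w = 0; // numerical guard
    r.W += w;
    double d = mean - gmean[s];
    r.B += len * d * d;
  }
  return r;
}

// [[Rcpp::export(name = ".bcp_gibbs_cpp")]]
List bcp_gibbs_cpp(NumericMatrix X, double p0, double w0,
                   int burnin, int mcmc) {
  int n = X.nrow(), m = X.ncol();
  int nb = n - 1; // inter-probe boundaries
  if (n < 2) stop("need at least 2 rows");

  // prefix sums over rows, per series
  std::vector<double> S1((size_t)(n + 1) * m, 0.0), S2((size_t)(n + 1) * m, 0.0);
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < m; ++s) {
      double v = X(i, s);
      S1[(size_t)(i + 1) * m + s] = S1[(size_t)i * m + s] + v;
      S2[(size_t)(i + 1) * m + s] = S2[(size_t)i * m + s] + v * v;
    }
  std::vector<double> gmean(m);
  for (int s = 0; s < m; ++s) gmean[s] = S1[(size_t)n * m + s] / n;

  RegionStats whole = region_stats(0, n, m, S1, S2, gmean, n);
  bool degenerate = (whole.W + whole.B) < 1e-10; // essentially constant data

  std::vector<double> gx, gw;
  gauss_legendre(40, gx, gw);

  double cexp = 0.5 * (double)m * (n - 1); // exponent of (W + Bw) per E&E, per series

  std::vector<int> U(nb, 0);
  double Wcur = whole.W, Bcur = whole.B;
  int bcur = 0;

  std::vector<double> rho(nb, 0.0);
  std::vector<double> pmean((size_t)n * m, 0.0);
  std::vector<double> blockmean(m);

  int total = burnin + mcmc;
  for (int sweep = 0; sweep < total; ++sweep) {
    for (int j = 0; j < nb; ++j) {
      // neighbouring active boundaries ignoring j: block region (a, c]
      int a = 0;
      for (int q = j - 1; q >= 0; --q)
        if (U[q]) { a = q + 1; break; }
      int c = n;
      for (int q = j + 1; q < nb; ++q)
        if (U[q]) { c = q + 1; break; }

      RegionStats merged = region_stats(a, c, m, S1, S2, gmean, n);
      RegionStats left = region_stats(a, j + 1, m, S1, S2, gmean, n);
      RegionStats right = region_stats(j + 1, c, m, S1, S2, gmean, n);

      double Wrest, Brest;
      int b_others = bcur - U[j];
      if (U[j]) {
        Wrest = Wcur - left.W - right.W;
        Brest = Bcur - left.B - right.B;
      } else {
        Wrest = Wcur - merged.W;
        Brest = Bcur - merged.B;
      }
      if (Wrest < 0) Wrest = 0;
      if (Brest < 0) Brest = 0;

      double W0 = Wrest + merged.W, B0 = Brest + merged.B;
      double W1 = Wrest + left.W + right.W, B1 = Brest + left.B + right.B;
      int b0 = b_others, b1 = b_others + 1;

      double lodds = log_prior_integral(b1, nb, p0) - log_prior_integral(b0, nb, p0);
      if (!degenerate) {
        double a1 = 0.5 * (double)m * b1, a0 = 0.5 * (double)m * b0;
        lodds += log_data_integral(a1, W1, B1, cexp, w0, gx, gw) -
                 log_data_integral(a0, W0, B0, cexp, w0, gx, gw);
      }
      if (lodds > 500) lodds = 500;
      if (lodds < -500) lodds = -500;
      double p1 = 1.0 / (1.0 + std::exp(-lodds));

      int newU = (unif_rand() < p1) ? 1 : 0;
      if (newU != U[j]) {
        if (newU) {
          Wcur = Wrest + left.W + right.W;
          Bcur = Brest + left.B + right.B;
          bcur += 1;
        } else {
          Wcur = Wrest + merged.W;
          Bcur = Brest + merged.B;
          bcur -= 1;
        }
        U[j] = newU;
      }
    }

    if (sweep >= burnin) {
      for (int j = 0; j < nb; ++j) rho[j] += U[j];
      // within-block means per series for this sweep
      int a = 0;
      for (int j = 0; j <= nb; ++j) {
        bool boundary = (j == nb) || (U[j] == 1);
        if (!boundary) continue;
        int c = j + 1;
        double len = c - a;
        for (int s = 0; s < m; ++s)
          blockmean[s] = (S1[(size_t)c * m + s] - S1[(size_t)a * m + s]) / len;
        for (int i = a; i < c; ++i)
          for (int s = 0; s < m; ++s) pmean[(size_t)i * m + s] += blockmean[s];
        a = c;
      }
    }
  }

  NumericVector rho_out(nb);
  for (int j = 0; j < nb; ++j) rho_out[j] = rho[j] / mcmc;
  NumericMatrix pm(n, m);
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < m; ++s) pm(i, s) = pmean[(size_t)i * m + s] / mcmc;

  return List::create(_["rho"] = rho_out, _["posterior_means"] = pm);
}
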