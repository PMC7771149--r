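// Blocked MCMC scan for the bivariate defense-trait model (binomial
// neckteeth + cumulative-logit pedestal, shared design, per-mother random
// intercepts). One call runs a single chain; seeding and the gamma -> beta
// back-transformation happen on the R side. Uses R's RNG throughout, so
// set.seed() in R makes a chain bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double log1pexp_d(double x) {
  return (x > 0 ? x : 0) + std::log1p(std::exp(-std::fabs(x)));
}

static inline double logistic(double x) {
  return 1.0 / (1.0 + std::exp(-x));
}

// Univariate slice sampling (Neal 2003), stepping out + shrinkage.
template <class F>
static double slice_update_cpp(double x0, F f, double w,
                               double lower = -INFINITY,
                               double upper = INFINITY) {
  double fx0 = f(x0);
  if (!std::isfinite(fx0)) return x0;
  double logy = fx0 - R::rexp(1.0);
  double u = R::runif(0.0, 1.0);
  double L = x0 - w * u;
  double Rr = L + w;
  const int max_steps = 100;
  int j = (int)std::floor(max_steps * R::runif(0.0, 1.0));
  int kk = max_steps - 1 - j;
  while (j > 0 && L > lower) {
    double v = f(L);
    if (!(std::isfinite(v) && v > logy)) break;
    L -= w; --j;
  }
  while (kk > 0 && Rr < upper) {
    double v = f(Rr);
    if (!(std::isfinite(v) && v > logy)) break;
    Rr += w; --kk;
  }
  if (L < lower) L = lower;
  if (Rr > upper) Rr = upper;
  for (;;) {
    double x1 = R::runif(L, Rr);
    double fx1 = f(x1);
    if (std::isfinite(fx1) && fx1 >= logy) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
    if (Rr - L < 1e-12) return x0;
  }
}

static inline double half_normal_lpdf(double s, double sd) {
  if (s < 0) return -INFINITY;
  return M_LN2 - 0.5 * std::log(2.0 * M_PI) - std::log(sd) -
         0.5 * s * s / (sd * sd);
}

// [[Rcpp::export(name = ".defense_chain_cpp")]]
arma::mat defense_chain_cpp(const arma::mat& Qn, const arma::mat& Qp,
                            const arma::mat& An, const arma::mat& Ap,
                            const arma::vec& qt1N, const arma::vec& AqN,
                            double qAqN, const arma::vec& qt1P,
                            const arma::vec& p1, const arma::vec& AqP,
                            double qAqP, const arma::ivec& kvec,
                            const arma::vec& lchk, const arma::ivec& cls,
                            const arma::ivec& midx,
                            const arma::ivec& mstart,
                            const arma::ivec& mrec, int trials,
                            int n_iter, int warmup, int scans, double tsd,
                            double ranef_sd, arma::vec gN, arma::vec gP,
                            arma::vec tau, arma::vec zN, arma::vec zP,
                            double sN, double sP) {
  const int n = Qn.n_rows;
  const int pN = Qn.n_cols;
  const int pP = Qp.n_cols;
  const int M = mstart.n_elem - 1;
  const int n_keep = n_iter - warmup;
  const int n_state = pN + pP + 2 + 2 + M + M;
  arma::mat out(n_keep, n_state);

  arma::vec etaN = Qn * gN + sN * zN.elem(arma::conv_to<arma::uvec>::from(midx));
  arma::vec etaP = Qp * gP + sP * zP.elem(arma::conv_to<arma::uvec>::from(midx));

  arma::vec wN(pN, arma::fill::value(2.0));
  arma::vec wP(pP, arma::fill::value(2.0));
  double wt1 = 0.5, wt2 = 0.5;

  // full-data log-likelihoods given a candidate shift along a direction
  auto llN_dir = [&](const arma::vec& dir, double d) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = etaN[i] + dir[i] * d;
      s += lchk[i] + kvec[i] * e - trials * log1pexp_d(e);
    }
    return s;
  };
  auto llP_at = [&](const arma::vec& dir, double d, double t1, double t2) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = etaP[i] + dir[i] * d;
      double p;
      if (cls[i] == 1) p = logistic(t1 - e);
      else if (cls[i] == 2) p = logistic(t2 - e) - logistic(t1 - e);
      else p = 1.0 - logistic(t2 - e);
      s += std::log(p > 1e-300 ? p : 1e-300);
    }
    return s;
  };
  const arma::vec zero_dir(n, arma::fill::zeros);

  for (int iter = 1; iter <= n_iter; ++iter) {
    double adapt_gamma = (iter <= warmup) ? std::pow(iter + 10.0, -0.6) : 0.0;
    for (int scan = 0; scan < scans; ++scan) {
      // neckteeth coefficients (orthogonalized scale)
      for (int j = 0; j < pN; ++j) {
        const double cur = gN[j];
        const double aj = An(j, j);
        const double cj = arma::dot(An.row(j), gN.t()) - aj * cur;
        arma::vec qj = Qn.col(j);
        auto fj = [&](double v) {
          return llN_dir(qj, v - cur) - 0.5 * aj * v * v - cj * v;
        };
        double x = slice_update_cpp(cur, fj, wN[j]);
        if (x != cur) etaN += qj * (x - cur);
        if (adapt_gamma > 0) {
          wN[j] += adapt_gamma * (2.5 * std::fabs(x - cur) - wN[j]);
          if (wN[j] < 0.05) wN[j] = 0.05;
        }
        gN[j] = x;
      }
      // pedestal coefficients
      for (int j = 0; j < pP; ++j) {
        const double cur = gP[j];
        const double aj = Ap(j, j);
        const double cj = arma::dot(Ap.row(j), gP.t()) - aj * cur;
        arma::vec qj = Qp.col(j);
        auto fj = [&](double v) {
          return llP_at(qj, v - cur, tau[0], tau[1]) -
                 0.5 * aj * v * v - cj * v;
        };
        double x = slice_update_cpp(cur, fj, wP[j]);
        if (x != cur) etaP += qj * (x - cur);
        if (adapt_gamma > 0) {
          wP[j] += adapt_gamma * (2.5 * std::fabs(x - cur) - wP[j]);
          if (wP[j] < 0.05) wP[j] = 0.05;
        }
        gP[j] = x;
      }
      // thresholds as center and gap
      {
        double ctr = 0.5 * (tau[0] + tau[1]);
        double gap = tau[1] - tau[0];
        auto fc = [&](double v) {
          double t1 = v - gap / 2, t2 = v + gap / 2;
          return llP_at(zero_dir, 0.0, t1, t2) +
                 R::dnorm(t1, 0.0, tsd, 1) + R::dnorm(t2, 0.0, tsd, 1);
        };
        double newc = slice_update_cpp(ctr, fc, wt1);
        if (adapt_gamma > 0) {
          wt1 += adapt_gamma * (2.5 * std::fabs(newc - ctr) - wt1);
          if (wt1 < 0.05) wt1 = 0.05;
        }
        ctr = newc;
        auto fg = [&](double v) {
          if (v <= 0) return R_NegInf;
          double t1 = ctr - v / 2, t2 = ctr + v / 2;
          return llP_at(zero_dir, 0.0, t1, t2) +
                 R::dnorm(t1, 0.0, tsd, 1) + R::dnorm(t2, 0.0, tsd, 1);
        };
        double newg = slice_update_cpp(gap, fg, wt2, 0.0);
        if (adapt_gamma > 0) {
          wt2 += adapt_gamma * (2.5 * std::fabs(newg - gap) - wt2);
          if (wt2 < 0.05) wt2 = 0.05;
        }
        gap = newg;
        tau[0] = ctr - gap / 2;
        tau[1] = ctr + gap / 2;
      }
      // directional slice: thresholds together with the projected overall
      // level of the pedestal predictor
      {
        double gAq = arma::dot(AqP, gP);
        auto fd = [&](double d) {
          return llP_at(p1, d, tau[0] + d, tau[1] + d) -
                 0.5 * qAqP * d * d - gAq * d +
                 R::dnorm(tau[0] + d, 0.0, tsd, 1) +
                 R::dnorm(tau[1] + d, 0.0, tsd, 1);
        };
        double d = slice_update_cpp(0.0, fd, 0.5);
        if (d != 0.0) {
          gP += d * qt1P;
          tau[0] += d;
          tau[1] += d;
          etaP += d * p1;
        }
      }
      // per-mother random intercepts (non-centered z; u = sigma * z)
      for (int m = 0; m < M; ++m) {
        auto fzN = [&](double z) {
          double s = -0.5 * z * z;
          for (int r = mstart[m]; r < mstart[m + 1]; ++r) {
            int i = mrec[r];
            double e = etaN[i] + sN * (z - zN[m]);
            s += lchk[i] + kvec[i] * e - trials * log1pexp_d(e);
          }
          return s;
        };
        double z1 = slice_update_cpp(zN[m], fzN, 1.5);
        if (z1 != zN[m]) {
          for (int r = mstart[m]; r < mstart[m + 1]; ++r) {
            etaN[mrec[r]] += sN * (z1 - zN[m]);
          }
          zN[m] = z1;
        }
        auto fzP = [&](double z) {
          double s = -0.5 * z * z;
          for (int r = mstart[m]; r < mstart[m + 1]; ++r) {
            int i = mrec[r];
            double e = etaP[i] + sP * (z - zP[m]);
            double p;
            if (cls[i] == 1) p = logistic(tau[0] - e);
            else if (cls[i] == 2) p = logistic(tau[1] - e) - logistic(tau[0] - e);
            else p = 1.0 - logistic(tau[1] - e);
            s += std::log(p > 1e-300 ? p : 1e-300);
          }
          return s;
        };
        z1 = slice_update_cpp(zP[m], fzP, 1.5);
        if (z1 != zP[m]) {
          for (int r = mstart[m]; r < mstart[m + 1]; ++r) {
            etaP[mrec[r]] += sP * (z1 - zP[m]);
          }
          zP[m] = z1;
        }
      }
      // exact Gibbs moves along the likelihood-invariant translation ridges
      {
        double prec = M + sN * sN * qAqN;
        double mean = (-arma::accu(zN) + sN * arma::dot(AqN, gN)) / prec;
        double delta = R::rnorm(mean, 1.0 / std::sqrt(prec));
        zN += delta;
        gN -= sN * delta * qt1N;
      }
      {
        double prec = M + 2.0 * sP * sP / (tsd * tsd);
        double mean = -(arma::accu(zP) + sP * (tau[0] + tau[1]) / (tsd * tsd)) /
                      prec;
        double delta = R::rnorm(mean, 1.0 / std::sqrt(prec));
        zP += delta;
        tau[0] += sP * delta;
        tau[1] += sP * delta;
        etaP += sP * delta;
      }
      // random-effect scales (slice on log sigma; the scale enters the
      // likelihood directly in the non-centered parameterization)
      {
        arma::vec zrec(n);
        for (int i = 0; i < n; ++i) zrec[i] = zN[midx[i]];
        auto fs = [&](double ls) {
          double s = std::exp(ls);
          return llN_dir(zrec, s - sN) + half_normal_lpdf(s, ranef_sd) + ls;
        };
        double ls1 = slice_update_cpp(std::log(sN), fs, 0.5);
        double s1 = std::exp(ls1);
        if (s1 != sN) {
          etaN += (s1 - sN) * zrec;
          sN = s1;
        }
      }
      {
        arma::vec zrec(n);
        for (int i = 0; i < n; ++i) zrec[i] = zP[midx[i]];
        auto fs = [&](double ls) {
          double s = std::exp(ls);
          return llP_at(zrec, s - sP, tau[0], tau[1]) +
                 half_normal_lpdf(s, ranef_sd) + ls;
        };
        double ls1 = slice_update_cpp(std::log(sP), fs, 0.5);
        double s1 = std::exp(ls1);
        if (s1 != sP) {
          etaP += (s1 - sP) * zrec;
          sP = s1;
        }
      }
    }
    if (iter > warmup) {
      int r = iter - warmup - 1;
      int c = 0;
      for (int j = 0; j < pN; ++j) out(r, c++) = gN[j];
      for (int j = 0; j < pP; ++j) out(r, c++) = gP[j];
      out(r, c++) = tau[0];
      out(r, c++) = tau[1];
      out(r, c++) = sN;
      out(r, c++) = sP;
      for (int m = 0; m < M; ++m) out(r, c++) = sN * zN[m];
      for (int m = 0; m < M; ++m) out(r, c++) = sP * zP[m];
    }
  }
  return out;
}
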