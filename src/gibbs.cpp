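// Gibbs sampler for a hierarchical Gaussian factorial ("ANOVA-style")
// model: y_i = beta0 + sum_f beta_f[level_f(i)] + eps, eps ~ N(0, sigma^2),
// with beta_f[j] ~ N(0, scale_f^2) i.i.d. within each effect family f and
// half-Gaussian hyperpriors on every scale. Within a family the indicator
// columns are orthogonal (each observation hits exactly one level), so the
// conditional update of a family is a set of independent normal draws;
// scales are updated by slice sampling on the log scale.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// univariate slice sampler (stepping out + shrinkage) on x = log(param)
template <typename F>
double slice_sample(double x0, F logpost, double w = 1.0, int max_steps = 50) {
  double f0 = logpost(x0);
  double logy = f0 + std::log(R::runif(0.0, 1.0));
  double u = R::runif(0.0, w);
  double L = x0 - u, Rr = x0 + (w - u);
  int j = max_steps, k = max_steps;
  while (j-- > 0 && logpost(L) > logy) L -= w;
  while (k-- > 0 && logpost(Rr) > logy) Rr += w;
  for (int it = 0; it < 100; ++it) {
    double x1 = R::runif(L, Rr);
    if (logpost(x1) >= logy) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
  }
  return x0;
}

// [[Rcpp::export]]
List gibbs_anova(NumericVector y,
                 IntegerMatrix idx,        // n x F, 1-based level per family
                 IntegerVector nlev,       // F
                 NumericVector prior_scale_fam,  // F, half-Gaussian SDs
                 double prior_mean_beta0,
                 double prior_sd_beta0,
                 double prior_scale_sigma,
                 int n_warmup, int n_save, int thin,
                 IntegerMatrix pred_idx,   // M x F
                 IntegerVector pred_group, // M, 1-based group of each row
                 int n_groups,
                 bool keep_coef) {
  const int n = y.size();
  const int F = nlev.size();
  const int M = pred_idx.nrow();

  // per-family level counts
  std::vector<std::vector<double>> beta(F);
  std::vector<std::vector<int>> counts(F);
  for (int f = 0; f < F; ++f) {
    beta[f].assign(nlev[f], 0.0);
    counts[f].assign(nlev[f], 0);
    for (int i = 0; i < n; ++i) counts[f][idx(i, f) - 1]++;
  }
  // the saturated family (if any) has at most one observation per level
  int saturated = -1;
  for (int f = 0; f < F; ++f) {
    bool ok = true;
    for (int j = 0; j < nlev[f]; ++j) {
      if (counts[f][j] > 1) { ok = false; break; }
    }
    if (ok && (saturated < 0 || nlev[f] > nlev[saturated])) saturated = f;
  }

  double ybar = mean(y);
  double ysd = sd(y);
  if (!(ysd > 0)) ysd = 1.0;
  double beta0 = ybar;
  double sigma = ysd;
  std::vector<double> scale(F, ysd / 2.0);

  std::vector<double> fit(n, beta0);

  int total_coef = 0;
  for (int f = 0; f < F; ++f) total_coef += nlev[f];

  NumericVector d_beta0(n_save), d_sigma(n_save);
  NumericMatrix d_scale(n_save, F);
  NumericMatrix d_cells(n_save, n_groups);
  NumericMatrix d_coef(keep_coef ? n_save : 1,
                       keep_coef ? total_coef : 1);

  std::vector<int> group_sizes(n_groups, 0);
  for (int m = 0; m < M; ++m) group_sizes[pred_group[m] - 1]++;

  const int n_iter = n_warmup + n_save * thin;
  int save_i = 0;

  for (int it = 0; it < n_iter; ++it) {
    double sig2 = sigma * sigma;

    // beta0
    {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += y[i] - (fit[i] - beta0);
      double prec = n / sig2 + 1.0 / (prior_sd_beta0 * prior_sd_beta0);
      double mu = (s / sig2 + prior_mean_beta0 /
                   (prior_sd_beta0 * prior_sd_beta0)) / prec;
      double nb0 = R::rnorm(mu, std::sqrt(1.0 / prec));
      double diff = nb0 - beta0;
      for (int i = 0; i < n; ++i) fit[i] += diff;
      beta0 = nb0;
    }

    // effect families
    for (int f = 0; f < F; ++f) {
      int K = nlev[f];
      std::vector<double> S(K, 0.0);
      for (int i = 0; i < n; ++i) {
        int j = idx(i, f) - 1;
        S[j] += y[i] - (fit[i] - beta[f][j]);
      }
      double sc2 = scale[f] * scale[f];
      std::vector<double> nb(K);
      for (int j = 0; j < K; ++j) {
        double prec = counts[f][j] / sig2 + 1.0 / sc2;
        double mu = (S[j] / sig2) / prec;
        nb[j] = R::rnorm(mu, std::sqrt(1.0 / prec));
      }
      for (int i = 0; i < n; ++i) {
        int j = idx(i, f) - 1;
        fit[i] += nb[j] - beta[f][j];
      }
      beta[f] = nb;

      // family scale: half-Gaussian(0, A) prior, slice on log-scale
      double ssb = 0.0;
      for (int j = 0; j < K; ++j) ssb += nb[j] * nb[j];
      double A = prior_scale_fam[f];
      auto logpost = [&](double ls) {
        double s_ = std::exp(ls);
        return -K * ls - ssb / (2.0 * s_ * s_)
               - (s_ * s_) / (2.0 * A * A) + ls;  // + ls: log-scale Jacobian
      };
      double ls_new = slice_sample(std::log(scale[f]), logpost);
      scale[f] = std::exp(ls_new);
      if (scale[f] < 1e-8) scale[f] = 1e-8;

      // interweaved (non-centered) scale update to break the funnel: with
      // eta = beta/scale held fixed, the scale enters the likelihood
      // linearly, so its conditional is Gaussian (half-Gaussian prior is
      // |N(0, A^2)|; sign flips are absorbed into eta by symmetry)
      {
        double sz2 = 0.0, szr = 0.0;
        double inv_s = 1.0 / scale[f];
        for (int i = 0; i < n; ++i) {
          double z = beta[f][idx(i, f) - 1] * inv_s;
          double r = y[i] - (fit[i] - beta[f][idx(i, f) - 1]);
          sz2 += z * z;
          szr += z * r;
        }
        double prec = sz2 / sig2 + 1.0 / (A * A);
        double mu_s = (szr / sig2) / prec;
        double s_new = R::rnorm(mu_s, std::sqrt(1.0 / prec));
        double ratio = s_new * inv_s;  // beta -> beta * s_new / s_old
        for (int i = 0; i < n; ++i) {
          fit[i] += (ratio - 1.0) * beta[f][idx(i, f) - 1];
        }
        for (int j = 0; j < K; ++j) beta[f][j] *= ratio;
        scale[f] = std::fabs(s_new);
        if (scale[f] < 1e-8) scale[f] = 1e-8;
      }
    }

    // recentring move along the non-identified direction shared by beta0
    // and each family's common mean: shift delta leaves the likelihood
    // unchanged, so its conditional under the priors is exactly Gaussian;
    // this removes the random-walk mixing of the raw parameterization
    for (int f = 0; f < F; ++f) {
      int K = nlev[f];
      double sc2 = scale[f] * scale[f];
      double s02 = prior_sd_beta0 * prior_sd_beta0;
      double sumb = 0.0;
      for (int j = 0; j < K; ++j) sumb += beta[f][j];
      double prec = K / sc2 + 1.0 / s02;
      double mu = (sumb / sc2 - (beta0 - prior_mean_beta0) / s02) / prec;
      double delta = R::rnorm(mu, std::sqrt(1.0 / prec));
      for (int j = 0; j < K; ++j) beta[f][j] -= delta;
      beta0 += delta;
    }

    // noise scale
    {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) {
        double r = y[i] - fit[i];
        sse += r * r;
      }
      double A = prior_scale_sigma;
      auto logpost = [&](double ls) {
        double s_ = std::exp(ls);
        return -n * ls - sse / (2.0 * s_ * s_)
               - (s_ * s_) / (2.0 * A * A) + ls;
      };
      sigma = std::exp(slice_sample(std::log(sigma), logpost));
      if (sigma < 1e-10) sigma = 1e-10;
    }

    // partially collapsed update for the saturated family (at most one
    // observation per level): only sigma^2 + scale^2 is likelihood-
    // identified there, so the centered sweep mixes the split glacially.
    // Integrate its coefficients out, slice both scales under the
    // marginal N(r | 0, sigma^2 + scale^2), then redraw the coefficients
    // from their exact conditional.
    if (saturated >= 0) {
      const int f = saturated;
      double sse_r = 0.0;
      std::vector<double> r(n);
      for (int i = 0; i < n; ++i) {
        r[i] = y[i] - fit[i] + beta[f][idx(i, f) - 1];
        sse_r += r[i] * r[i];
      }
      // joint move in (v, rho) with v = sigma^2 + scale^2 and
      // rho = scale^2 / v: the likelihood pins v only, so rho is drawn
      // exactly from its prior-induced conditional on a grid, which jumps
      // across the ridge instead of random-walking along it
      double Asg = prior_scale_sigma, Asf = prior_scale_fam[f];
      double v = sigma * sigma + scale[f] * scale[f];
      double rho = (scale[f] * scale[f]) / v;
      auto logpost_v = [&](double x) {
        double v_ = std::exp(x);
        return -(0.5 * n - 1.0) * x - sse_r / (2.0 * v_)
               - v_ * ((1.0 - rho) / (2.0 * Asg * Asg) +
                       rho / (2.0 * Asf * Asf));
      };
      v = std::exp(slice_sample(std::log(v), logpost_v));
      {
        const int G = 256;
        std::vector<double> w(G);
        double wmax = -1e300;
        for (int g = 0; g < G; ++g) {
          double rg = (g + 0.5) / G;
          w[g] = -v * ((1.0 - rg) / (2.0 * Asg * Asg) +
                       rg / (2.0 * Asf * Asf))
                 - 0.5 * std::log(rg * (1.0 - rg));
          if (w[g] > wmax) wmax = w[g];
        }
        double tot = 0.0;
        for (int g = 0; g < G; ++g) { w[g] = std::exp(w[g] - wmax); tot += w[g]; }
        double u = R::runif(0.0, tot), acc = 0.0;
        int pick = G - 1;
        for (int g = 0; g < G; ++g) {
          acc += w[g];
          if (u <= acc) { pick = g; break; }
        }
        rho = (pick + 0.5) / G;
      }
      sigma = std::sqrt((1.0 - rho) * v);
      double s_f = std::sqrt(rho * v);
      if (sigma < 1e-10) sigma = 1e-10;
      if (s_f < 1e-8) s_f = 1e-8;
      scale[f] = s_f;
      double sg2 = sigma * sigma, sf2 = s_f * s_f;
      double shrink = sf2 / (sf2 + sg2);
      double csd = std::sqrt(sf2 * sg2 / (sf2 + sg2));
      for (int i = 0; i < n; ++i) {
        beta[f][idx(i, f) - 1] = R::rnorm(shrink * r[i], csd);
      }
      for (int j = 0; j < nlev[f]; ++j) {
        if (counts[f][j] == 0) beta[f][j] = R::rnorm(0.0, s_f);
      }
      // rebuild fit with the new saturated-family contribution
      for (int i = 0; i < n; ++i) {
        fit[i] = y[i] - r[i] + beta[f][idx(i, f) - 1];
      }
    }

    if (it >= n_warmup && ((it - n_warmup) % thin) == 0) {
      d_beta0[save_i] = beta0;
      d_sigma[save_i] = sigma;
      for (int f = 0; f < F; ++f) d_scale(save_i, f) = scale[f];
      // group-averaged predicted cell values
      std::vector<double> acc(n_groups, 0.0);
      for (int m = 0; m < M; ++m) {
        double mu = beta0;
        for (int f = 0; f < F; ++f) mu += beta[f][pred_idx(m, f) - 1];
        acc[pred_group[m] - 1] += mu;
      }
      for (int g = 0; g < n_groups; ++g)
        d_cells(save_i, g) = acc[g] / group_sizes[g];
      if (keep_coef) {
        int col = 0;
        for (int f = 0; f < F; ++f)
          for (int j = 0; j < nlev[f]; ++j)
            d_coef(save_i, col++) = beta[f][j];
      }
      ++save_i;
    }
  }

  List out = List::create(
    Named("beta0") = d_beta0,
    Named("sigma") = d_sigma,
    Named("scales") = d_scale,
    Named("cells") = d_cells);
  if (keep_coef) out["coef"] = d_coef;
  return out;
}
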