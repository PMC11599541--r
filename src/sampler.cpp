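// Metropolis-within-Gibbs sampler for the three-tier hierarchical model.
//
// Gaussian tiers (soil, foliage): coefficient vectors and site effects have
// Normal priors and Gaussian likelihoods, so they are updated with exact
// conjugate Gibbs draws; residual and site sds use adaptive random-walk
// Metropolis on the log scale. The beta tier (herbivory) is non-conjugate
// throughout: every coefficient, site effect, the site sd and the precision
// phi use adaptive scalar random-walk Metropolis. Step sizes adapt towards
// a 0.44 acceptance rate during burn-in only, so retained draws come from a
// fixed kernel. All randomness flows through R's RNG: a chain is fully
// reproducible from set.seed() on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// draw from N(A^{-1} b, A^{-1}) for s.p.d. precision A
arma::vec mvn_prec_draw(const arma::mat& A, const arma::vec& b) {
  arma::mat R = arma::chol(A); // A = R' R, R upper
  arma::vec m = arma::solve(arma::trimatu(R), arma::solve(arma::trimatl(R.t()), b));
  arma::vec z(b.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) z(i) = R::norm_rand();
  return m + arma::solve(arma::trimatu(R), z);
}

struct AdaptStep {
  double ls;    // log step size
  int acc;
  int tries;
  explicit AdaptStep(double step = 0.2) : ls(std::log(step)), acc(0), tries(0) {}
  double step() const { return std::exp(ls); }
  void record(bool accepted) { ++tries; if (accepted) ++acc; }
  void adapt(int batch) {
    if (tries == 0) return;
    double rate = double(acc) / tries;
    double delta = std::min(0.1, 1.0 / std::sqrt(double(batch)));
    ls += (rate > 0.44 ? delta : -delta);
    acc = 0; tries = 0;
  }
};

// log target for a log-sd parameter of a Gaussian block:
// n observations with residual sum of squares rss, half-Normal(scale) prior,
// plus the log-scale Jacobian.
double lsig_target(double lsig, double rss, double n, double scale) {
  double s2 = std::exp(2.0 * lsig);
  return -n * lsig - rss / (2.0 * s2) - s2 / (2.0 * scale * scale) + lsig;
}

inline double beta_row_ll(double eta, double phi, double ly, double l1y,
                          double lgphi) {
  double mu = 1.0 / (1.0 + std::exp(-eta));
  double a = mu * phi, b = (1.0 - mu) * phi;
  if (a <= 0.0 || b <= 0.0) return -std::numeric_limits<double>::infinity();
  return (a - 1.0) * ly + (b - 1.0) * l1y - std::lgamma(a) - std::lgamma(b) + lgphi;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix hbm_sample_chain(const arma::mat& Xs, const arma::mat& Ys,
                               const arma::mat& Xf, const arma::mat& Yf,
                               const arma::mat& Xh, const arma::vec& yh,
                               const arma::ivec& site, int n_sites,
                               int n_iter, int n_burn, int thin,
                               double coef_sd, double sd_scale,
                               double phi_shape, double phi_rate,
                               List init) {
  const int ns = Xs.n_rows, ps = Xs.n_cols, ne = Ys.n_cols;
  const int nt = Xf.n_rows, pf = Xf.n_cols, nr = Yf.n_cols;
  const int ph = Xh.n_cols;
  const double cprec = 1.0 / (coef_sd * coef_sd);

  // state
  arma::mat soil_beta = as<arma::mat>(init["soil_beta"]);     // ps x ne
  arma::vec soil_lsig = arma::log(as<arma::vec>(init["soil_sigma"]));
  arma::mat fol_beta = as<arma::mat>(init["fol_beta"]);       // pf x nr
  arma::vec fol_lsig = arma::log(as<arma::vec>(init["fol_sigma"]));
  arma::vec fol_lsite = arma::log(as<arma::vec>(init["fol_site_sd"]));
  arma::mat fol_u = as<arma::mat>(init["fol_u"]);             // ns x nr
  arma::vec herb_beta = as<arma::vec>(init["herb_beta"]);     // ph
  arma::vec herb_u = as<arma::vec>(init["herb_u"]);           // n_sites
  double herb_lsite = std::log(as<double>(init["herb_site_sd"]));
  double herb_lphi = std::log(as<double>(init["herb_phi"]));

  // precomputations
  arma::mat XtX_s = Xs.t() * Xs;
  arma::mat Xty_s = Xs.t() * Ys; // ps x ne
  arma::mat XtX_f = Xf.t() * Xf;
  arma::vec ly = arma::log(yh), l1y = arma::log(1.0 - yh);

  std::vector<std::vector<int>> rows_site(n_sites);
  for (int i = 0; i < nt; ++i) rows_site[site(i)].push_back(i);
  std::vector<std::vector<int>> rows_col(ph);
  for (int j = 0; j < ph; ++j)
    for (int i = 0; i < nt; ++i)
      if (Xh(i, j) != 0.0) rows_col[j].push_back(i);

  // herbivory running state
  double phi = std::exp(herb_lphi), lgphi = std::lgamma(phi);
  arma::vec eta(nt), llv(nt);
  auto refresh_eta = [&]() {
    eta = Xh * herb_beta;
    for (int i = 0; i < nt; ++i) eta(i) += herb_u(site(i));
  };
  auto refresh_ll = [&]() {
    for (int i = 0; i < nt; ++i)
      llv(i) = beta_row_ll(eta(i), phi, ly(i), l1y(i), lgphi);
  };
  refresh_eta();
  refresh_ll();

  // adaptive steps
  std::vector<AdaptStep> st_soil_sig(ne), st_fol_sig(nr), st_fol_site(nr);
  std::vector<AdaptStep> st_herb_beta(ph, AdaptStep(0.1));
  std::vector<AdaptStep> st_herb_u(n_sites, AdaptStep(0.2));
  AdaptStep st_herb_site(0.2), st_herb_phi(0.2);

  // joint proposal for the herbivory coefficient vector, using a covariance
  // estimated from the chain's own burn-in history (frozen afterwards);
  // this speeds mixing across the correlated site-level predictors
  arma::vec bmean = herb_beta;
  arma::mat bscat(ph, ph, arma::fill::zeros);
  int bcount = 0;
  arma::mat bchol;
  bool have_bchol = false;
  double block_ls = std::log(1.0);
  int block_acc = 0, block_tries = 0;

  const int n_keep = (n_iter - n_burn) / thin;
  const int npar = ne * (ps + 1) + nr * (pf + 2 + n_sites) + ph + 1 + n_sites + 1;
  NumericMatrix out(n_keep, npar);

  int kept = 0, batch = 0;
  for (int it = 0; it < n_iter; ++it) {
    // ---- soil tier ----
    for (int e = 0; e < ne; ++e) {
      double s2 = std::exp(2.0 * soil_lsig(e));
      arma::mat A = XtX_s / s2;
      A.diag() += cprec;
      soil_beta.col(e) = mvn_prec_draw(A, Xty_s.col(e) / s2);
      arma::vec res = Ys.col(e) - Xs * soil_beta.col(e);
      double rss = arma::dot(res, res);
      double cur = soil_lsig(e);
      double prop = cur + st_soil_sig[e].step() * R::norm_rand();
      double d = lsig_target(prop, rss, double(ns), sd_scale) -
                 lsig_target(cur, rss, double(ns), sd_scale);
      bool acc = std::log(R::unif_rand()) < d;
      if (acc) soil_lsig(e) = prop;
      st_soil_sig[e].record(acc);
    }

    // ---- foliage tier ----
    for (int r = 0; r < nr; ++r) {
      double s2 = std::exp(2.0 * fol_lsig(r));
      double tau2 = std::exp(2.0 * fol_lsite(r));
      arma::vec yadj = Yf.col(r);
      for (int i = 0; i < nt; ++i) yadj(i) -= fol_u(site(i), r);
      arma::mat A = XtX_f / s2;
      A.diag() += cprec;
      fol_beta.col(r) = mvn_prec_draw(A, (Xf.t() * yadj) / s2);
      // site effects: conjugate scalar normals
      arma::vec res = Yf.col(r) - Xf * fol_beta.col(r);
      for (int s = 0; s < n_sites; ++s) {
        double sum = 0.0;
        for (int i : rows_site[s]) sum += res(i);
        double prec = rows_site[s].size() / s2 + 1.0 / tau2;
        fol_u(s, r) = sum / s2 / prec + R::norm_rand() / std::sqrt(prec);
      }
      // residual sd
      double rss = 0.0;
      for (int i = 0; i < nt; ++i) {
        double d = res(i) - fol_u(site(i), r);
        rss += d * d;
      }
      double cur = fol_lsig(r);
      double prop = cur + st_fol_sig[r].step() * R::norm_rand();
      double d = lsig_target(prop, rss, double(nt), sd_scale) -
                 lsig_target(cur, rss, double(nt), sd_scale);
      bool acc = std::log(R::unif_rand()) < d;
      if (acc) fol_lsig(r) = prop;
      st_fol_sig[r].record(acc);
      // site sd
      double uss = arma::dot(fol_u.col(r), fol_u.col(r));
      cur = fol_lsite(r);
      prop = cur + st_fol_site[r].step() * R::norm_rand();
      d = lsig_target(prop, uss, double(n_sites), sd_scale) -
          lsig_target(cur, uss, double(n_sites), sd_scale);
      acc = std::log(R::unif_rand()) < d;
      if (acc) fol_lsite(r) = prop;
      st_fol_site[r].record(acc);
    }

    // ---- herbivory tier ----
    for (int j = 0; j < ph; ++j) {
      double cur = herb_beta(j);
      double db = st_herb_beta[j].step() * R::norm_rand();
      double prop = cur + db;
      double d = -(prop * prop - cur * cur) * 0.5 * cprec;
      std::vector<double> newll(rows_col[j].size()), neweta(rows_col[j].size());
      for (size_t k = 0; k < rows_col[j].size(); ++k) {
        int i = rows_col[j][k];
        neweta[k] = eta(i) + Xh(i, j) * db;
        newll[k] = beta_row_ll(neweta[k], phi, ly(i), l1y(i), lgphi);
        d += newll[k] - llv(i);
      }
      bool acc = std::isfinite(d) && std::log(R::unif_rand()) < d;
      if (acc) {
        herb_beta(j) = prop;
        for (size_t k = 0; k < rows_col[j].size(); ++k) {
          int i = rows_col[j][k];
          eta(i) = neweta[k];
          llv(i) = newll[k];
        }
      }
      st_herb_beta[j].record(acc);
    }
    {
      double tau2 = std::exp(2.0 * herb_lsite);
      for (int s = 0; s < n_sites; ++s) {
        double cur = herb_u(s);
        double du = st_herb_u[s].step() * R::norm_rand();
        double prop = cur + du;
        double d = -(prop * prop - cur * cur) / (2.0 * tau2);
        std::vector<double> newll(rows_site[s].size()), neweta(rows_site[s].size());
        for (size_t k = 0; k < rows_site[s].size(); ++k) {
          int i = rows_site[s][k];
          neweta[k] = eta(i) + du;
          newll[k] = beta_row_ll(neweta[k], phi, ly(i), l1y(i), lgphi);
          d += newll[k] - llv(i);
        }
        bool acc = std::isfinite(d) && std::log(R::unif_rand()) < d;
        if (acc) {
          herb_u(s) = prop;
          for (size_t k = 0; k < rows_site[s].size(); ++k) {
            int i = rows_site[s][k];
            eta(i) = neweta[k];
            llv(i) = newll[k];
          }
        }
        st_herb_u[s].record(acc);
      }
      // site sd (prior-only target over the site effects)
      double uss = arma::dot(herb_u, herb_u);
      double cur = herb_lsite;
      double prop = cur + st_herb_site.step() * R::norm_rand();
      double d = lsig_target(prop, uss, double(n_sites), sd_scale) -
                 lsig_target(cur, uss, double(n_sites), sd_scale);
      bool acc = std::log(R::unif_rand()) < d;
      if (acc) herb_lsite = prop;
      st_herb_site.record(acc);
      // phi
      cur = herb_lphi;
      prop = cur + st_herb_phi.step() * R::norm_rand();
      double newphi = std::exp(prop), newlg = std::lgamma(newphi);
      double dd = phi_shape * (prop - cur) - phi_rate * (newphi - phi);
      arma::vec newllv(nt);
      for (int i = 0; i < nt; ++i) {
        newllv(i) = beta_row_ll(eta(i), newphi, ly(i), l1y(i), newlg);
        dd += newllv(i) - llv(i);
      }
      acc = std::isfinite(dd) && std::log(R::unif_rand()) < dd;
      if (acc) {
        herb_lphi = prop;
        phi = newphi;
        lgphi = newlg;
        llv = newllv;
      }
      st_herb_phi.record(acc);
    }

    // ---- herbivory coefficient block move ----
    if (it < n_burn) {
      ++bcount;
      arma::vec d1 = herb_beta - bmean;
      bmean += d1 / bcount;
      bscat += d1 * (herb_beta - bmean).t();
      if (bcount >= 500 && bcount % 200 == 0) {
        arma::mat S = bscat / (bcount - 1) * (2.38 * 2.38 / ph);
        S.diag() += 1e-9;
        have_bchol = arma::chol(bchol, S);
      }
    }
    if (have_bchol) {
      arma::vec z(ph);
      for (int j = 0; j < ph; ++j) z(j) = R::norm_rand();
      arma::vec db = std::exp(block_ls) * (bchol.t() * z);
      arma::vec prop = herb_beta + db;
      double d = 0.5 * cprec * (arma::dot(herb_beta, herb_beta) -
                                arma::dot(prop, prop));
      arma::vec neweta = eta + Xh * db;
      arma::vec newll(nt);
      for (int i = 0; i < nt; ++i) {
        newll(i) = beta_row_ll(neweta(i), phi, ly(i), l1y(i), lgphi);
        d += newll(i) - llv(i);
      }
      bool acc = std::isfinite(d) && std::log(R::unif_rand()) < d;
      if (acc) {
        herb_beta = prop;
        eta = neweta;
        llv = newll;
      }
      ++block_tries;
      if (acc) ++block_acc;
      if (it < n_burn && block_tries >= 50) {
        double rate = double(block_acc) / block_tries;
        double delta = std::min(0.1, 1.0 / std::sqrt(double(it / 50 + 1)));
        block_ls += (rate > 0.23 ? delta : -delta);
        block_acc = 0;
        block_tries = 0;
      }
    }

    // ---- adaptation (burn-in only) ----
    if (it < n_burn && (it + 1) % 50 == 0) {
      ++batch;
      for (auto& a : st_soil_sig) a.adapt(batch);
      for (auto& a : st_fol_sig) a.adapt(batch);
      for (auto& a : st_fol_site) a.adapt(batch);
      for (auto& a : st_herb_beta) a.adapt(batch);
      for (auto& a : st_herb_u) a.adapt(batch);
      st_herb_site.adapt(batch);
      st_herb_phi.adapt(batch);
    }

    // ---- record ----
    if (it >= n_burn && (it - n_burn + 1) % thin == 0) {
      int c = 0;
      for (int e = 0; e < ne; ++e) {
        for (int j = 0; j < ps; ++j) out(kept, c++) = soil_beta(j, e);
        out(kept, c++) = std::exp(soil_lsig(e));
      }
      for (int r = 0; r < nr; ++r) {
        for (int j = 0; j < pf; ++j) out(kept, c++) = fol_beta(j, r);
        out(kept, c++) = std::exp(fol_lsig(r));
        out(kept, c++) = std::exp(fol_lsite(r));
        for (int s = 0; s < n_sites; ++s) out(kept, c++) = fol_u(s, r);
      }
      for (int j = 0; j < ph; ++j) out(kept, c++) = herb_beta(j);
      out(kept, c++) = std::exp(herb_lsite);
      for (int s = 0; s < n_sites; ++s) out(kept, c++) = herb_u(s);
      out(kept, c++) = std::exp(herb_lphi);
      ++kept;
    }
    if ((it + 1) % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
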