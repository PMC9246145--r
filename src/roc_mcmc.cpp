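// Likelihood kernels and MCMC sampler for the selection-mutation-drift
// multinomial codon model. Within each synonymous family the probability of
// codon i in gene g is softmax over members of -(dM[i, regime(g)] +
// dEta[i] * phi[g]); observed codon counts are multinomial given those
// probabilities (the multinomial normalizing constant is dropped — it is
// constant in the parameters).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Per-gene, per-family log-likelihood contribution.
static inline double family_ll(const IntegerMatrix &counts,
                               const std::vector<int> &mem,
                               const NumericMatrix &dm,
                               const NumericVector &deta, double phi, int reg,
                               int g) {
  const int m = (int)mem.size();
  double x[8];
  double xmax = -INFINITY;
  int tot = 0;
  for (int j = 0; j < m; ++j) {
    const int c = mem[j];
    x[j] = -(dm(c, reg) + deta[c] * phi);
    if (x[j] > xmax) xmax = x[j];
    tot += counts(g, c);
  }
  if (tot == 0) return 0.0;
  double se = 0.0, dot = 0.0;
  for (int j = 0; j < m; ++j) {
    se += std::exp(x[j] - xmax);
    dot += counts(g, mem[j]) * x[j];
  }
  return dot - tot * (xmax + std::log(se));
}

static std::vector<std::vector<int>> unpack_members(const List &members) {
  std::vector<std::vector<int>> mem(members.size());
  for (int f = 0; f < members.size(); ++f) {
    IntegerVector mv = members[f];
    if (mv.size() > 8) stop("family with more than 8 codons");
    mem[f] = std::vector<int>(mv.begin(), mv.end());
  }
  return mem;
}

// [[Rcpp::export]]
NumericMatrix roc_loglik_matrix(IntegerMatrix counts, NumericMatrix dm,
                                NumericVector deta, NumericVector phi,
                                IntegerVector regime, List members) {
  const int n = counts.nrow();
  const int nfam = members.size();
  std::vector<std::vector<int>> mem = unpack_members(members);
  NumericMatrix out(n, nfam);
  for (int g = 0; g < n; ++g) {
    const int reg = regime[g] - 1;
    const double ph = phi[g];
    for (int f = 0; f < nfam; ++f) {
      out(g, f) = family_ll(counts, mem[f], dm, deta, ph, reg, g);
    }
  }
  return out;
}

static inline double ldnorm(double x, double mu, double sd) {
  const double z = (x - mu) / sd;
  return -0.5 * z * z - std::log(sd) - 0.9189385332046727; // log(sqrt(2*pi))
}

// Adaptive Metropolis-within-Gibbs chain. Blocks:
//  - all log(phi) jointly proposed, accepted per gene (conditionally
//    independent given the codon coefficients);
//  - per family and regime, the non-reference mutation-bias entries;
//  - per family, the non-reference selection entries (shared across regimes);
//  - log s_phi (lognormal scale of expression).
// Proposal scales adapt toward `target_accept` during burn-in only.
// [[Rcpp::export]]
List roc_mcmc_chain(IntegerMatrix counts, List members, IntegerVector regime,
                    int n_regimes, NumericMatrix dm_init,
                    NumericVector deta_init, NumericVector phi_init,
                    double s_phi, int iterations, int burn_in, int thin,
                    double tau, double target_accept, int adapt_interval,
                    bool fix_phi) {
  const int n = counts.nrow();
  const int nfam = members.size();
  std::vector<std::vector<int>> mem = unpack_members(members);

  // non-reference members per family: all but the last (alphabetical order,
  // reference = alphabetically last member, coefficients pinned at 0)
  std::vector<std::vector<int>> nonref(nfam);
  int nfree = 0;
  for (int f = 0; f < nfam; ++f) {
    nonref[f] = std::vector<int>(mem[f].begin(), mem[f].end() - 1);
    nfree += (int)nonref[f].size();
  }
  const int nfree_dm = nfree * n_regimes;

  NumericMatrix dm = clone(dm_init);
  NumericVector deta = clone(deta_init);
  NumericVector phi = clone(phi_init);
  NumericVector logphi(n);
  for (int g = 0; g < n; ++g) logphi[g] = std::log(phi[g]);
  // the expression spread s_phi is a fixed prior constant: the likelihood
  // is affine-invariant in phi, so the spread is only weakly identified by
  // shape and is treated as part of the prior specification

  // cached per-gene per-family log-likelihood
  NumericMatrix famll(n, nfam);
  NumericVector ll_gene(n);
  auto refresh = [&]() {
    for (int g = 0; g < n; ++g) {
      double tot = 0.0;
      for (int f = 0; f < nfam; ++f) {
        famll(g, f) = family_ll(counts, mem[f], dm, deta, phi[g],
                                regime[g] - 1, g);
        tot += famll(g, f);
      }
      ll_gene[g] = tot;
    }
  };
  refresh();

  // proposal scales
  NumericVector sd_phi(n, 0.5);
  const int nblocks = nfam * (n_regimes + 1);
  NumericVector sd_block(nblocks, 0.1);

  // adaptation bookkeeping
  NumericVector acc_phi(n, 0.0);
  NumericVector acc_block(nblocks, 0.0);
  int batch = 0;

  const int n_keep = (iterations - burn_in) / thin;
  NumericMatrix phi_samples(n_keep, fix_phi ? 0 : n);
  NumericMatrix dm_samples(n_keep, nfree_dm);
  NumericMatrix deta_samples(n_keep, nfree);
  NumericVector sphi_samples(n_keep);
  NumericVector dev_samples(n_keep);
  int kept = 0;

  double gauge_kappa = 0.0;

  NumericVector prop_row(nfam);
  std::vector<double> newcol(n);

  for (int t = 1; t <= iterations; ++t) {
    const double mu0 = -0.5 * s_phi * s_phi;

    // ---- phi update (vectorized proposal, per-gene acceptance)
    if (!fix_phi) {
      for (int g = 0; g < n; ++g) {
        const double lp_new = logphi[g] + norm_rand() * sd_phi[g];
        const double ph_new = std::exp(lp_new);
        double ll_new = 0.0;
        const int reg = regime[g] - 1;
        for (int f = 0; f < nfam; ++f) {
          prop_row[f] = family_ll(counts, mem[f], dm, deta, ph_new, reg, g);
          ll_new += prop_row[f];
        }
        const double lr = (ll_new - ll_gene[g]) + ldnorm(lp_new, mu0, s_phi) -
                          ldnorm(logphi[g], mu0, s_phi);
        if (std::log(unif_rand()) < lr) {
          logphi[g] = lp_new;
          phi[g] = ph_new;
          for (int f = 0; f < nfam; ++f) famll(g, f) = prop_row[f];
          ll_gene[g] = ll_new;
          acc_phi[g] += 1.0;
        }
      }
    }

    // ---- codon-coefficient blocks
    int b = 0;
    for (int f = 0; f < nfam; ++f) {
      const std::vector<int> &nr = nonref[f];
      // mutation-bias block per regime: only genes of that regime affected
      for (int r = 0; r < n_regimes; ++r, ++b) {
        std::vector<double> old_vals(nr.size());
        double dprior = 0.0;
        for (size_t j = 0; j < nr.size(); ++j) {
          old_vals[j] = dm(nr[j], r);
          const double nv = old_vals[j] + norm_rand() * sd_block[b];
          dm(nr[j], r) = nv;
          dprior += (old_vals[j] * old_vals[j] - nv * nv) / (2.0 * tau * tau);
        }
        double dll = 0.0;
        for (int g = 0; g < n; ++g) {
          if (regime[g] - 1 != r) { newcol[g] = famll(g, f); continue; }
          newcol[g] = family_ll(counts, mem[f], dm, deta, phi[g], r, g);
          dll += newcol[g] - famll(g, f);
        }
        if (std::log(unif_rand()) < dll + dprior) {
          for (int g = 0; g < n; ++g) {
            if (regime[g] - 1 == r) {
              ll_gene[g] += newcol[g] - famll(g, f);
              famll(g, f) = newcol[g];
            }
          }
          acc_block[b] += 1.0;
        } else {
          for (size_t j = 0; j < nr.size(); ++j) dm(nr[j], r) = old_vals[j];
        }
      }
      // selection block: shared across regimes, affects every gene
      {
        std::vector<double> old_vals(nr.size());
        double dprior = 0.0;
        for (size_t j = 0; j < nr.size(); ++j) {
          old_vals[j] = deta[nr[j]];
          const double nv = old_vals[j] + norm_rand() * sd_block[b];
          deta[nr[j]] = nv;
          dprior += (old_vals[j] * old_vals[j] - nv * nv) / (2.0 * tau * tau);
        }
        double dll = 0.0;
        for (int g = 0; g < n; ++g) {
          newcol[g] =
              family_ll(counts, mem[f], dm, deta, phi[g], regime[g] - 1, g);
          dll += newcol[g] - famll(g, f);
        }
        if (std::log(unif_rand()) < dll + dprior) {
          for (int g = 0; g < n; ++g) {
            ll_gene[g] += newcol[g] - famll(g, f);
            famll(g, f) = newcol[g];
          }
          acc_block[b] += 1.0;
        } else {
          for (size_t j = 0; j < nr.size(); ++j) deta[nr[j]] = old_vals[j];
        }
        ++b;
      }
    }

    // ---- gauge fixing: the likelihood is exactly invariant under the
    // two-parameter family phi -> (phi - kappa) / lambda, deta -> lambda *
    // deta, dm -> dm + kappa * deta, so the location and scale of
    // expression are conventions, not estimable quantities; left free, the
    // prior slowly drags chains along this ridge into a degenerate funnel
    // of compressed phi and inflated selection coefficients. The convention
    // is pinned every iteration by the orbit point matching the prior:
    // mean(phi) = 1 and var(log phi) = s_phi^2. The spread condition is
    // strictly monotone in kappa, so its root is unique for any shape of
    // the phi configuration (warm-started Newton, bisection fallback).
    if (!fix_phi) {
      double m = 0.0, minphi = phi[0];
      for (int g = 0; g < n; ++g) {
        m += phi[g];
        minphi = std::min(minphi, phi[g]);
      }
      m /= n;
      const double s2 = s_phi * s_phi;
      auto gval = [&](double k, double &deriv) {
        double A = 0.0, B = 0.0, W = 0.0, YW = 0.0;
        for (int g = 0; g < n; ++g) {
          const double d = phi[g] - k;
          const double y = std::log(d);
          const double w = 1.0 / d;
          A += y;
          B += y * y;
          W += w;
          YW += y * w;
        }
        A /= n; B /= n; W /= n; YW /= n;
        deriv = -2.0 * (YW - A * W); // d var / d kappa > 0
        return (B - A * A) - s2;
      };
      const double hi = minphi * (1.0 - 1e-9) - 1e-300;
      double kap = std::min(gauge_kappa, hi - 1e-12);
      bool ok = false;
      for (int it = 0; it < 12; ++it) {
        double deriv;
        const double g0 = gval(kap, deriv);
        if (std::fabs(g0) < 1e-11) { ok = true; break; }
        double kn = kap - g0 / deriv;
        if (!std::isfinite(kn) || kn >= hi) kn = 0.5 * (kap + hi);
        if (std::fabs(kn - kap) < 1e-13 * (1.0 + std::fabs(kap))) {
          kap = kn;
          ok = true;
          break;
        }
        kap = kn;
      }
      if (!ok) {
        // bisection: var -> 0 far left, -> +inf at the right edge
        double span = 1.0, lo = minphi - span, d_;
        bool found = false;
        for (int it = 0; it < 200; ++it) {
          if (gval(lo, d_) < 0.0) { found = true; break; }
          span *= 2.0;
          lo = minphi - span;
        }
        if (found) {
          double a = lo, b = hi;
          for (int it = 0; it < 100; ++it) {
            const double c = 0.5 * (a + b);
            if (gval(c, d_) < 0.0) a = c; else b = c;
          }
          kap = 0.5 * (a + b);
          ok = true;
        }
      }
      double lam = ok ? (m - kap) : m; // fallback: unit mean only
      if (!ok) kap = 0.0;
      if (lam > 0.0 && kap < minphi && std::isfinite(lam)) {
        gauge_kappa = kap;
        for (int g = 0; g < n; ++g) {
          phi[g] = (phi[g] - kap) / lam;
          logphi[g] = std::log(phi[g]);
        }
        for (int f = 0; f < nfam; ++f) {
          for (int c : nonref[f]) {
            for (int r = 0; r < n_regimes; ++r) dm(c, r) += kap * deta[c];
            deta[c] *= lam;
          }
        }
        // the cached likelihood is unchanged by construction
      }
    }

    // ---- reflection move: the posterior has a mirror mode in which all
    // selection coefficients are negated and expression ranks inverted.
    // This deterministic involution (Jacobian 1) proposes the mirror image
    // of the current state — logphi reflected about its prior location,
    // deta negated, dm compensated so typical-gene codon probabilities are
    // preserved — letting chains jump between modes and settle in the
    // better one.
    if (!fix_phi && t % 100 == 0) {
      const double mu0r = -0.5 * s_phi * s_phi; // s_phi may have just moved
      const double cc = std::exp(mu0r); // geometric center of phi's prior
      double ll_old = 0.0;
      for (int g = 0; g < n; ++g) ll_old += ll_gene[g];
      NumericMatrix dm2(dm.nrow(), n_regimes);
      NumericVector deta2(deta.size());
      double dprior = 0.0;
      for (int f = 0; f < nfam; ++f) {
        for (int c : mem[f]) {
          deta2[c] = -deta[c];
          for (int r = 0; r < n_regimes; ++r) {
            dm2(c, r) = dm(c, r) + 2.0 * deta[c] * cc;
          }
        }
        for (int c : nonref[f]) {
          for (int r = 0; r < n_regimes; ++r) {
            dprior += (dm(c, r) * dm(c, r) - dm2(c, r) * dm2(c, r)) /
                      (2.0 * tau * tau);
          }
        }
      }
      NumericVector phi2(n);
      for (int g = 0; g < n; ++g) phi2[g] = std::exp(2.0 * mu0r - logphi[g]);
      double ll_new = 0.0;
      NumericMatrix famll2(n, nfam);
      for (int g = 0; g < n; ++g) {
        const int reg = regime[g] - 1;
        for (int f = 0; f < nfam; ++f) {
          famll2(g, f) = family_ll(counts, mem[f], dm2, deta2, phi2[g], reg, g);
          ll_new += famll2(g, f);
        }
      }
      if (std::log(unif_rand()) < ll_new - ll_old + dprior) {
        dm = dm2;
        deta = deta2;
        famll = famll2;
        for (int g = 0; g < n; ++g) {
          phi[g] = phi2[g];
          logphi[g] = 2.0 * mu0r - logphi[g];
          ll_gene[g] = 0.0;
          for (int f = 0; f < nfam; ++f) ll_gene[g] += famll(g, f);
        }
      }
    }

    // ---- adaptation (burn-in only, to preserve detailed balance afterwards)
    if (t <= burn_in && t % adapt_interval == 0) {
      ++batch;
      const double delta = std::min(0.25, 1.0 / std::sqrt((double)batch));
      const double denom = (double)adapt_interval;
      for (int g = 0; g < n; ++g) {
        sd_phi[g] *= std::exp((acc_phi[g] / denom > target_accept) ? delta : -delta);
        acc_phi[g] = 0.0;
      }
      for (int j = 0; j < nblocks; ++j) {
        sd_block[j] *= std::exp((acc_block[j] / denom > target_accept) ? delta : -delta);
        acc_block[j] = 0.0;
      }
    }
    if (t == burn_in) { // reset acceptance counters for post-burn-in rates
      std::fill(acc_phi.begin(), acc_phi.end(), 0.0);
      std::fill(acc_block.begin(), acc_block.end(), 0.0);
    }

    // periodic full refresh of the cached likelihood to stop float drift
    if (t % 2000 == 0) refresh();

    // ---- storage
    if (t > burn_in && (t - burn_in) % thin == 0) {
      if (!fix_phi) {
        for (int g = 0; g < n; ++g) phi_samples(kept, g) = phi[g];
      }
      int col = 0;
      for (int f = 0; f < nfam; ++f) {
        for (int r = 0; r < n_regimes; ++r) {
          for (size_t j = 0; j < nonref[f].size(); ++j) {
            dm_samples(kept, col++) = dm(nonref[f][j], r);
          }
        }
      }
      col = 0;
      for (int f = 0; f < nfam; ++f) {
        for (size_t j = 0; j < nonref[f].size(); ++j) {
          deta_samples(kept, col++) = deta[nonref[f][j]];
        }
      }
      sphi_samples[kept] = s_phi;
      double dev = 0.0;
      for (int g = 0; g < n; ++g) dev += ll_gene[g];
      dev_samples[kept] = -2.0 * dev;
      ++kept;
    }
  }

  const double post_iters = (double)(iterations - burn_in);
  return List::create(
      _["phi"] = phi_samples, _["dm"] = dm_samples, _["deta"] = deta_samples,
      _["s_phi"] = sphi_samples, _["deviance"] = dev_samples,
      _["accept_phi"] = fix_phi ? NumericVector(0)
                                : (NumericVector)(acc_phi / post_iters),
      _["accept_block"] = (NumericVector)(acc_block / post_iters),
      _["final"] = List::create(_["dm"] = dm, _["deta"] = deta,
                                _["phi"] = phi, _["s_phi"] = s_phi));
}
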