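#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the six-class hybrid genotype-frequency model.
//
// Latent state: per-individual class z (rows of W give the class's
// gene-pair weights w00/w01/w11 = P(both gene copies from pool 0 / one from
// each / both from pool 1)), per-locus allele frequencies of the two
// parental gene pools (Jeffreys Beta(1/2,1/2) priors), class mixing
// proportions (Jeffreys Dirichlet(1/2,...)), and per-(individual, locus)
// gene-pair source indicators used for conjugate frequency updates.
// Missing genotypes (negative codes) contribute likelihood 1.
// All randomness comes from the R RNG, so set.seed() makes runs
// bit-reproducible.

static inline double clamp01(double x) {
  if (x < 1e-12) return 1e-12;
  if (x > 1.0 - 1e-12) return 1.0 - 1e-12;
  return x;
}

// [[Rcpp::export]]
List hybrid_gibbs_cpp(IntegerMatrix G, NumericMatrix W,
                      int burnin, int sweeps) {
  const int n = G.nrow();
  const int L = G.ncol();
  const int C = W.nrow();

  std::vector<int> z(n);
  std::vector<double> theta0(L), theta1(L), pi(C, 1.0 / C);

  // initialise pool frequencies from per-locus sample counts (independent
  // posterior-style draws per pool) and classes from the two parentals
  for (int l = 0; l < L; ++l) {
    double alt = 0.0, ref = 0.0;
    for (int i = 0; i < n; ++i) {
      int g = G(i, l);
      if (g >= 0) { alt += g; ref += 2 - g; }
    }
    theta0[l] = clamp01(R::rbeta(0.5 + alt, 0.5 + ref));
    theta1[l] = clamp01(R::rbeta(0.5 + alt, 0.5 + ref));
  }
  for (int i = 0; i < n; ++i) z[i] = (unif_rand() < 0.5) ? 0 : 1;

  // per-locus genotype log-probabilities for each class (C x L x 3) and the
  // three gene-pair-source genotype probabilities (f00, f01, f11)
  std::vector<double> f00(L * 3), f01(L * 3), f11(L * 3);
  std::vector<double> logclass(C * L * 3);
  std::vector<double> loglik(n * C);
  std::vector<double> alt0(L), ref0(L), alt1(L), ref1(L);
  NumericMatrix post(n, C);

  const int total = burnin + sweeps;
  for (int sweep = 0; sweep < total; ++sweep) {
    // genotype distributions given gene-pair source
    for (int l = 0; l < L; ++l) {
      const double t0 = theta0[l], t1 = theta1[l];
      f00[l * 3 + 0] = (1 - t0) * (1 - t0);
      f00[l * 3 + 1] = 2 * t0 * (1 - t0);
      f00[l * 3 + 2] = t0 * t0;
      f01[l * 3 + 0] = (1 - t0) * (1 - t1);
      f01[l * 3 + 1] = t0 * (1 - t1) + t1 * (1 - t0);
      f01[l * 3 + 2] = t0 * t1;
      f11[l * 3 + 0] = (1 - t1) * (1 - t1);
      f11[l * 3 + 1] = 2 * t1 * (1 - t1);
      f11[l * 3 + 2] = t1 * t1;
    }
    for (int c = 0; c < C; ++c) {
      const double w0 = W(c, 0), w1 = W(c, 1), w2 = W(c, 2);
      for (int l = 0; l < L; ++l)
        for (int g = 0; g < 3; ++g)
          logclass[(c * L + l) * 3 + g] =
            std::log(w0 * f00[l * 3 + g] + w1 * f01[l * 3 + g] +
                     w2 * f11[l * 3 + g]);
    }

    // class update
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < C; ++c)
        loglik[i * C + c] = std::log(pi[c]);
    for (int l = 0; l < L; ++l) {
      for (int i = 0; i < n; ++i) {
        const int g = G(i, l);
        if (g < 0) continue;
        for (int c = 0; c < C; ++c)
          loglik[i * C + c] += logclass[(c * L + l) * 3 + g];
      }
    }
    for (int i = 0; i < n; ++i) {
      double m = loglik[i * C];
      for (int c = 1; c < C; ++c) m = std::max(m, loglik[i * C + c]);
      double tot = 0.0;
      double p[16];
      for (int c = 0; c < C; ++c) {
        p[c] = std::exp(loglik[i * C + c] - m);
        tot += p[c];
      }
      double u = unif_rand() * tot;
      int c = 0;
      while (c < C - 1 && u > p[c]) { u -= p[c]; ++c; }
      z[i] = c;
    }

    // gene-pair source augmentation -> pool allele counts
    std::fill(alt0.begin(), alt0.end(), 0.0);
    std::fill(ref0.begin(), ref0.end(), 0.0);
    std::fill(alt1.begin(), alt1.end(), 0.0);
    std::fill(ref1.begin(), ref1.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double w0 = W(z[i], 0), w1 = W(z[i], 1), w2 = W(z[i], 2);
      for (int l = 0; l < L; ++l) {
        const int g = G(i, l);
        if (g < 0) continue;
        const double q00 = w0 * f00[l * 3 + g];
        const double q01 = w1 * f01[l * 3 + g];
        const double q11 = w2 * f11[l * 3 + g];
        double u = unif_rand() * (q00 + q01 + q11);
        if (u < q00) {
          alt0[l] += g; ref0[l] += 2 - g;
        } else if (u < q00 + q11) {
          alt1[l] += g; ref1[l] += 2 - g;
        } else {
          if (g == 0) { ref0[l] += 1; ref1[l] += 1; }
          else if (g == 2) { alt0[l] += 1; alt1[l] += 1; }
          else {
            const double t0 = theta0[l], t1 = theta1[l];
            const double a = t0 * (1 - t1); // alt copy came from pool 0
            const double b = t1 * (1 - t0);
            if (unif_rand() * (a + b) < a) { alt0[l] += 1; ref1[l] += 1; }
            else { ref0[l] += 1; alt1[l] += 1; }
          }
        }
      }
    }

    // conjugate updates
    for (int l = 0; l < L; ++l) {
      theta0[l] = clamp01(R::rbeta(0.5 + alt0[l], 0.5 + ref0[l]));
      theta1[l] = clamp01(R::rbeta(0.5 + alt1[l], 0.5 + ref1[l]));
    }
    std::vector<double> gam(C);
    double gtot = 0.0;
    std::vector<int> nc(C, 0);
    for (int i = 0; i < n; ++i) nc[z[i]]++;
    for (int c = 0; c < C; ++c) {
      gam[c] = R::rgamma(0.5 + nc[c], 1.0);
      gtot += gam[c];
    }
    for (int c = 0; c < C; ++c) pi[c] = gam[c] / gtot;

    if (sweep >= burnin)
      for (int i = 0; i < n; ++i) post(i, z[i]) += 1.0;
  }

  for (int i = 0; i < n; ++i)
    for (int c = 0; c < C; ++c) post(i, c) /= sweeps;

  return List::create(_["posterior"] = post,
                      _["theta0"] = NumericVector(theta0.begin(), theta0.end()),
                      _["theta1"] = NumericVector(theta1.begin(), theta1.end()));
}
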