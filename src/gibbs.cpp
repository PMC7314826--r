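#include <Rcpp.h>
using namespace Rcpp;

// Draw an index in [0, K) proportional to w (unnormalised), using R's RNG.
static inline int sample_prop(const std::vector<double>& w, int K, double tot) {
  double u = unif_rand() * tot;
  double acc = 0.0;
  for (int k = 0; k < K; ++k) {
    acc += w[k];
    if (u <= acc) return k;
  }
  return K - 1;
}

// Collapsed Gibbs engine for the multi-modal mixed-membership model.
//
// Tokens are given as parallel 1-based vectors (d, q, v) in the canonical
// visit order. Runs n_sweeps systematic-scan sweeps starting from the
// supplied assignment z (1-based). Posterior-mean estimates of phi and theta
// are accumulated over retained sweeps (sweep > burn_in, thinning `thin`).
// When record == true the full assignment vector is stored after every
// sweep (small corpora only; used by exactness diagnostics).
//
// [[Rcpp::export]]
List cpp_gibbs_run(IntegerVector z_init, IntegerVector d, IntegerVector q,
                   IntegerVector v, int D, int K, IntegerVector Vq,
                   double alpha, double beta, int n_sweeps, int burn_in,
                   int thin, bool record) {
  const int N = z_init.size();
  const int Q = Vq.size();

  std::vector<int> z(N);
  for (int i = 0; i < N; ++i) z[i] = z_init[i] - 1;

  // count tables
  std::vector<int> cdk(D * K, 0), ckq(K * Q, 0), nd(D, 0);
  std::vector< std::vector<int> > ckqv(Q);
  for (int qq = 0; qq < Q; ++qq) ckqv[qq].assign(K * Vq[qq], 0);
  for (int i = 0; i < N; ++i) {
    int di = d[i] - 1, qi = q[i] - 1, vi = v[i] - 1, k = z[i];
    cdk[di * K + k]++; ckq[k * Q + qi]++; ckqv[qi][k * Vq[qi] + vi]++;
    nd[di]++;
  }

  std::vector<double> phi_acc_flat;
  std::vector<double> theta_acc(D * K, 0.0);
  std::vector<int> phi_off(Q, 0);
  int phi_len = 0;
  for (int qq = 0; qq < Q; ++qq) { phi_off[qq] = phi_len; phi_len += K * Vq[qq]; }
  phi_acc_flat.assign(phi_len, 0.0);
  int n_saved = 0;

  IntegerMatrix z_rec(record ? n_sweeps : 0, record ? N : 0);

  std::vector<double> w(K);
  for (int s = 0; s < n_sweeps; ++s) {
    for (int i = 0; i < N; ++i) {
      const int di = d[i] - 1, qi = q[i] - 1, vi = v[i] - 1;
      const int Vqi = Vq[qi];
      int k = z[i];
      cdk[di * K + k]--; ckq[k * Q + qi]--; ckqv[qi][k * Vqi + vi]--;
      double tot = 0.0;
      for (int kk = 0; kk < K; ++kk) {
        double p = (cdk[di * K + kk] + alpha) *
                   (ckqv[qi][kk * Vqi + vi] + beta) /
                   (ckq[kk * Q + qi] + Vqi * beta);
        w[kk] = p; tot += p;
      }
      k = sample_prop(w, K, tot);
      z[i] = k;
      cdk[di * K + k]++; ckq[k * Q + qi]++; ckqv[qi][k * Vqi + vi]++;
    }
    if (record) {
      for (int i = 0; i < N; ++i) z_rec(s, i) = z[i] + 1;
    }
    if (s >= burn_in && ((s - burn_in) % thin == 0)) {
      ++n_saved;
      for (int qq = 0; qq < Q; ++qq) {
        const int Vqq = Vq[qq];
        for (int k = 0; k < K; ++k) {
          const double den = ckq[k * Q + qq] + Vqq * beta;
          for (int vv = 0; vv < Vqq; ++vv) {
            phi_acc_flat[phi_off[qq] + k * Vqq + vv] +=
              (ckqv[qq][k * Vqq + vv] + beta) / den;
          }
        }
      }
      for (int di = 0; di < D; ++di) {
        const double den = nd[di] + K * alpha;
        for (int k = 0; k < K; ++k) {
          theta_acc[di * K + k] += (cdk[di * K + k] + alpha) / den;
        }
      }
    }
  }

  List phi(Q);
  for (int qq = 0; qq < Q; ++qq) {
    NumericMatrix m(K, Vq[qq]);
    for (int k = 0; k < K; ++k)
      for (int vv = 0; vv < Vq[qq]; ++vv)
        m(k, vv) = n_saved > 0
          ? phi_acc_flat[phi_off[qq] + k * Vq[qq] + vv] / n_saved
          : NA_REAL;
    phi[qq] = m;
  }
  NumericMatrix theta(D, K);
  for (int di = 0; di < D; ++di)
    for (int k = 0; k < K; ++k)
      theta(di, k) = n_saved > 0 ? theta_acc[di * K + k] / n_saved : NA_REAL;

  IntegerVector z_out(N);
  for (int i = 0; i < N; ++i) z_out[i] = z[i] + 1;

  IntegerMatrix cdk_out(D, K);
  for (int di = 0; di < D; ++di)
    for (int k = 0; k < K; ++k) cdk_out(di, k) = cdk[di * K + k];
  List ckqv_out(Q);
  for (int qq = 0; qq < Q; ++qq) {
    IntegerMatrix m(K, Vq[qq]);
    for (int k = 0; k < K; ++k)
      for (int vv = 0; vv < Vq[qq]; ++vv) m(k, vv) = ckqv[qq][k * Vq[qq] + vv];
    ckqv_out[qq] = m;
  }
  IntegerMatrix ckq_out(K, Q);
  for (int k = 0; k < K; ++k)
    for (int qq = 0; qq < Q; ++qq) ckq_out(k, qq) = ckq[k * Q + qq];

  List out = List::create(
    _["z"] = z_out, _["phi"] = phi, _["theta"] = theta,
    _["n_saved"] = n_saved, _["c_dk"] = cdk_out, _["c_kqv"] = ckqv_out,
    _["c_kq"] = ckq_out);
  if (record) out["z_record"] = z_rec;
  return out;
}

// Left-to-right sequential estimator of a held-out document's marginal
// log-likelihood under fitted per-question answer distributions phi
// (list of K x V_q matrices) and symmetric Dirichlet prior alpha on the
// document's phenotype proportions. Tokens (qdoc, vdoc; 1-based) are laid
// out in a fixed order. For each position n, each of R particles resamples
// z_{<n} in one pass, records the predictive probability of token n, then
// samples z_n.
//
// [[Rcpp::export]]
double cpp_left_to_right(IntegerVector qdoc, IntegerVector vdoc, List phi,
                         double alpha, int R) {
  const int N = qdoc.size();
  if (N == 0) return 0.0;
  const int K = as<NumericMatrix>(phi[0]).nrow();

  std::vector<NumericMatrix> ph(phi.size());
  for (int qq = 0; qq < phi.size(); ++qq) ph[qq] = as<NumericMatrix>(phi[qq]);

  // per-particle assignments and topic counts
  std::vector< std::vector<int> > z(R, std::vector<int>(N, 0));
  std::vector< std::vector<int> > ck(R, std::vector<int>(K, 0));
  std::vector<double> w(K);

  double logp = 0.0;
  for (int n = 0; n < N; ++n) {
    const int qn = qdoc[n] - 1, vn = vdoc[n] - 1;
    double psum = 0.0;
    for (int r = 0; r < R; ++r) {
      // resample earlier positions given current counts and phi
      for (int i = 0; i < n; ++i) {
        const int qi = qdoc[i] - 1, vi = vdoc[i] - 1;
        ck[r][z[r][i]]--;
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          double p = (ck[r][k] + alpha) * ph[qi](k, vi);
          w[k] = p; tot += p;
        }
        const int k = sample_prop(w, K, tot);
        z[r][i] = k; ck[r][k]++;
      }
      // predictive probability of token n for this particle
      double pn = 0.0, tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double mix = (ck[r][k] + alpha) / (n + K * alpha);
        pn += mix * ph[qn](k, vn);
        double p = (ck[r][k] + alpha) * ph[qn](k, vn);
        w[k] = p; tot += p;
      }
      psum += pn;
      const int k = sample_prop(w, K, tot);
      z[r][n] = k; ck[r][k]++;
    }
    logp += std::log(psum / R);
  }
  return logp;
}
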