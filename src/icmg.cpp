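// Collapsed Gibbs sampler for the interaction component model (ICMg).
// Each network link carries a latent component label; a sweep revisits every
// link in fixed input order, removes it from the sufficient statistics,
// samples a new label from the collapsed conditional
//   p(z | rest) ~ (n_z + alpha) * (q_{z,i} + beta)(q_{z,j} + beta)
//                 / ((2 n_z + 1 + M beta)(2 n_z + M beta)),
// and re-inserts it. Uses R's RNG stream so set.seed() governs everything.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static void recount(const IntegerVector& from, const IntegerVector& to,
                    const std::vector<int>& z, int C, int M,
                    std::vector<int>& nz, std::vector<int>& q) {
  std::fill(nz.begin(), nz.end(), 0);
  std::fill(q.begin(), q.end(), 0);
  int L = from.size();
  for (int l = 0; l < L; ++l) {
    nz[z[l]]++;
    q[z[l] * M + from[l]]++;
    q[z[l] * M + to[l]]++;
  }
}

// [[Rcpp::export]]
List cpp_icmg(IntegerVector from, IntegerVector to, int M, int C,
              double alpha, double beta, int burn_in, int thin,
              int sampling_iters, bool keep_draws, bool check_counts) {
  int L = from.size();
  double Mb = M * beta;

  // init: one global component-probability draw theta ~ Dirichlet(alpha),
  // then multinomial link labels
  std::vector<double> theta(C);
  double tsum = 0.0;
  for (int c = 0; c < C; ++c) { theta[c] = R::rgamma(alpha, 1.0); tsum += theta[c]; }
  for (int c = 0; c < C; ++c) theta[c] /= tsum;

  std::vector<int> z(L);
  for (int l = 0; l < L; ++l) {
    double u = unif_rand(), acc = 0.0;
    int c = C - 1;
    for (int k = 0; k < C; ++k) { acc += theta[k]; if (u < acc) { c = k; break; } }
    z[l] = c;
  }

  std::vector<int> nz(C), q((size_t)C * M);
  recount(from, to, z, C, M, nz, q);

  std::vector<double> w(C);
  auto sweep = [&]() {
    for (int l = 0; l < L; ++l) {
      int i = from[l], j = to[l], zc = z[l];
      nz[zc]--; q[zc * M + i]--; q[zc * M + j]--;
      double tot = 0.0;
      for (int c = 0; c < C; ++c) {
        double n_c = nz[c];
        w[c] = (n_c + alpha) *
               (q[c * M + i] + beta) * (q[c * M + j] + beta) /
               ((2.0 * n_c + 1.0 + Mb) * (2.0 * n_c + Mb));
        tot += w[c];
      }
      double u = unif_rand() * tot, acc = 0.0;
      int pick = C - 1;
      for (int c = 0; c < C; ++c) { acc += w[c]; if (u < acc) { pick = c; break; } }
      z[l] = pick;
      nz[pick]++; q[pick * M + i]++; q[pick * M + j]++;
    }
  };

  std::vector<int> nz_chk(C), q_chk((size_t)C * M);
  auto check = [&]() {
    recount(from, to, z, C, M, nz_chk, q_chk);
    long snz = 0;
    for (int c = 0; c < C; ++c) {
      if (nz_chk[c] != nz[c]) stop("count invariant violated: n_z");
      snz += nz[c];
      long sq = 0;
      for (int i = 0; i < M; ++i) {
        if (q_chk[c * M + i] != q[c * M + i]) stop("count invariant violated: q");
        sq += q[c * M + i];
      }
      if (sq != 2L * nz[c]) stop("count invariant violated: sum_i q[z][i] != 2 n_z");
    }
    if (snz != L) stop("count invariant violated: sum n_z != N_links");
  };

  for (int it = 0; it < burn_in; ++it) {
    sweep();
    if (check_counts) check();
    if ((it & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix acc_q(C, M); // accumulated co-occurrences over retained samples
  int nsamp = 0;
  int n_keep = keep_draws ? sampling_iters / thin : 0;
  IntegerMatrix draws(n_keep, keep_draws ? L : 0);
  for (int it = 1; it <= sampling_iters; ++it) {
    sweep();
    if (check_counts) check();
    if (it % thin == 0) {
      for (int c = 0; c < C; ++c)
        for (int i = 0; i < M; ++i)
          acc_q(c, i) += q[c * M + i];
      if (keep_draws && nsamp < n_keep)
        for (int l = 0; l < L; ++l) draws(nsamp, l) = z[l] + 1;
      ++nsamp;
    }
    if ((it & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["acc_q"] = acc_q,
                      _["n_samples"] = nsamp,
                      _["draws"] = draws,
                      _["z_final"] = IntegerVector(z.begin(), z.end()),
                      _["n_z"] = IntegerVector(nz.begin(), nz.end()));
}
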