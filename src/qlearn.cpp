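// Inner loop of the Q-learning likelihood: replaying a compiled choice log
// under given parameters. Kept in C++ because simplex fitting evaluates it
// thousands of times.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
double qlearn_nll_cpp(const IntegerVector& action, const IntegerVector& reward,
                      const IntegerMatrix& avail, const IntegerMatrix& nxt,
                      const LogicalVector& terminal, double alpha,
                      double gamma, double beta, double tau) {
  const int n = action.size();
  std::vector<double> q(10, 0.0);
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    const int a1 = avail(i, 0) - 1, a2 = avail(i, 1) - 1;
    const int a = action[i] - 1;
    const double z1 = beta * q[a1], z2 = beta * q[a2];
    const double zmax = z1 > z2 ? z1 : z2;
    const double e1 = std::exp(z1 - zmax), e2 = std::exp(z2 - zmax);
    double pa = (a == a1 ? e1 : e2) / (e1 + e2);
    if (pa < 1e-12) pa = 1e-12;
    nll -= std::log(pa);
    double mx = 0.0;
    if (!terminal[i]) {
      const double q1 = q[nxt(i, 0) - 1], q2 = q[nxt(i, 1) - 1];
      mx = q1 > q2 ? q1 : q2;
    }
    q[a] += alpha * (reward[i] + gamma * mx - q[a]);
    for (int k = 0; k < 10; ++k) q[k] *= tau;
  }
  return nll;
}
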