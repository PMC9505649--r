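#include <Rcpp.h>
using namespace Rcpp;

// Implicit-Euler stepping of the semi-discrete system M dC/dt = -A C,
// where M (FEM mass) and A (stiffness + interface coupling) are tridiagonal.
// Diagonals are stored per row: Ml[i]/Al[i] couple node i to node i-1,
// Mu[i]/Au[i] couple node i to node i+1 (Ml[0] and Mu[n-1] unused).
// `steps` is the sequence of step sizes; after step k the state is recorded
// when record[k] != 0. Each step solves (M + dt*A) C_new = M C_old with the
// Thomas algorithm; the system is strictly diagonally dominant in the
// generalized (M-matrix) sense for the discretizations used here, so no
// pivoting is required.
// [[Rcpp::export]]
NumericMatrix step_implicit_euler(NumericVector Md, NumericVector Ml, NumericVector Mu,
                                  NumericVector Ad, NumericVector Al, NumericVector Au,
                                  NumericVector C0, NumericVector steps,
                                  IntegerVector record) {
  const int n = Md.size();
  int nrec = 0;
  for (int k = 0; k < record.size(); ++k) nrec += (record[k] != 0);
  NumericMatrix out(n, nrec);

  std::vector<double> c(C0.begin(), C0.end());
  std::vector<double> d(n), dl(n), du(n), rhs(n), w(n);

  int col = 0;
  for (int k = 0; k < steps.size(); ++k) {
    const double dt = steps[k];
    for (int i = 0; i < n; ++i) {
      d[i]  = Md[i] + dt * Ad[i];
      dl[i] = Ml[i] + dt * Al[i];
      du[i] = Mu[i] + dt * Au[i];
    }
    // rhs = M * c
    for (int i = 0; i < n; ++i) {
      double v = Md[i] * c[i];
      if (i > 0)     v += Ml[i] * c[i - 1];
      if (i < n - 1) v += Mu[i] * c[i + 1];
      rhs[i] = v;
    }
    // Thomas solve (M + dt A) c = rhs
    w[0] = du[0] / d[0];
    rhs[0] /= d[0];
    for (int i = 1; i < n; ++i) {
      const double m = d[i] - dl[i] * w[i - 1];
      w[i] = du[i] / m;
      rhs[i] = (rhs[i] - dl[i] * rhs[i - 1]) / m;
    }
    c[n - 1] = rhs[n - 1];
    for (int i = n - 2; i >= 0; --i) c[i] = rhs[i] - w[i] * c[i + 1];

    if (record[k] != 0) {
      for (int i = 0; i < n; ++i) out(i, col) = c[i];
      ++col;
    }
  }
  return out;
}
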