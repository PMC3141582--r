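// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// fused 2-D fluid stage: skew-symmetric advection, Crank-Nicolson
// spectral momentum solve, implicit reservoir-port pressure solve and
// exact discrete projection, in one pass. Mirrors the R reference
// operators (advect_diffuse_predictor + project_with_ports); the test
// suite asserts agreement to machine precision.

static arma::mat cdiff(const arma::mat& a, int dim, double h) {
  // centered periodic difference along dim (0 = rows/x, 1 = cols/y)
  return (arma::shift(a, -1, dim) - arma::shift(a, +1, dim)) / (2.0 * h);
}

// [[Rcpp::export]]
List fluid_stage_cpp(const arma::cx_mat& zhat_base,
                     const arma::mat& u1, const arma::mat& u2,
                     const arma::mat& adv1, const arma::mat& adv2,
                     SEXP force1, SEXP force2,
                     double dt_frac, double rho, double h,
                     double cfl_limit,
                     const arma::mat& cn_num, const arma::mat& cn_den,
                     const arma::mat& s1, const arma::mat& s2,
                     const arma::mat& inv_poisson,
                     List port_what, List port_ghat,
                     const arma::mat& response,
                     const arma::vec& Pres, const arma::vec& Rres,
                     bool want_p) {
  double umax = std::max(arma::abs(adv1).max(), arma::abs(adv2).max());
  double co = umax * dt_frac / h;
  if (co > cfl_limit)
    stop("CFL violation: Courant number %.3f exceeds limit %.3f", co, cfl_limit);

  // skew-symmetric advection
  arma::mat a1 = 0.5 * (adv1 % cdiff(adv1, 0, h) + adv2 % cdiff(adv1, 1, h) +
                        cdiff(adv1 % adv1, 0, h) + cdiff(adv2 % adv1, 1, h));
  arma::mat a2 = 0.5 * (adv1 % cdiff(adv2, 0, h) + adv2 % cdiff(adv2, 1, h) +
                        cdiff(adv1 % adv2, 0, h) + cdiff(adv2 % adv2, 1, h));
  arma::mat r1 = u1 - dt_frac * a1;
  arma::mat r2 = u2 - dt_frac * a2;
  if (force1 != R_NilValue) {
    r1 += (dt_frac / rho) * as<arma::mat>(force1);
    r2 += (dt_frac / rho) * as<arma::mat>(force2);
  }

  // packed momentum solve (real spectral factors act on both fields)
  arma::cx_mat zstar = (arma::fft2(arma::cx_mat(r1, r2)) +
                        cn_num % zhat_base) % cn_den;

  // unpack the two real-field spectra: uh = (z + conj(z(-k)))/2
  int n1 = zstar.n_rows, n2 = zstar.n_cols;
  arma::uvec rev1(n1), rev2(n2);
  rev1(0) = 0; for (int i = 1; i < n1; ++i) rev1(i) = n1 - i;
  rev2(0) = 0; for (int j = 1; j < n2; ++j) rev2(j) = n2 - j;
  arma::cx_mat zc = arma::conj(zstar(rev1, rev2));
  arma::cx_mat uh = 0.5 * (zstar + zc);
  arma::cx_mat vh = std::complex<double>(0, -0.5) * (zstar - zc);

  std::complex<double> I(0, 1);
  double scale = rho / dt_frac;
  arma::cx_mat phat = (I * scale) * (inv_poisson % (s1 % uh + s2 % vh));

  int np = port_what.size();
  arma::vec Q;
  if (np > 0) {
    int N = n1 * n2;
    arma::vec pbar0(np);
    for (int k = 0; k < np; ++k) {
      const arma::cx_mat& wc = as<arma::cx_mat>(port_what[k]);
      pbar0(k) = arma::accu(arma::real(wc % phat)) / N * h * h;
    }
    arma::mat A = arma::diagmat(Rres) - scale * response;
    Q = arma::solve(A, Pres - pbar0);
    for (int k = 0; k < np; ++k) {
      phat -= (scale * Q(k)) * as<arma::cx_mat>(port_ghat[k]);
    }
  }

  std::complex<double> corr(0, dt_frac / rho);
  uh -= corr * (s1 % phat);
  vh -= corr * (s2 % phat);
  arma::cx_mat z = arma::ifft2(uh + I * vh);

  List out = List::create(
    Named("u") = List::create(arma::mat(arma::real(z)), arma::mat(arma::imag(z))),
    Named("Q") = Q);
  if (want_p) out["p"] = arma::mat(arma::real(arma::ifft2(phat)));
  return out;
}
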