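#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Ray-averaged cylindrical-wave unit-excitation fields.
//
// For an antenna at (xa, ya) and a pixel at distance d, the scalar wave is
//   s = A * exp(-i * kbar * d_m) / sqrt(max(d_m, dmin_m))
// where kbar is the complex wavenumber k = (w/c0) * sqrt(eps_r - i*sigma/(w*eps0))
// averaged over equally spaced samples along the straight antenna->pixel ray
// (material looked up per sample; free space outside the grid). Principal
// square root gives Re(k) > 0, Im(k) < 0, so the e^{+iwt} time convention
// yields decay in lossy media. The scalar is assigned to the in-plane unit
// vector transverse to the ray.
//
// eps_r, sigma: n_rows x n_cols maps; xc (n_cols), yc (n_rows) pixel-centre
// mm coordinates; ant: n_ant x 2 positions (mm); amp: field amplitude at 1 m
// for a 1 V drive (V/m * sqrt(m)).
//
// Returns a complex cube (n_rows, n_cols, 2*n_ant): slices 2a, 2a+1 hold the
// x and y components of antenna a's field.
// [[Rcpp::export]]
arma::cx_cube cpp_unit_fields(const arma::mat& eps_r, const arma::mat& sigma,
                              const arma::vec& xc, const arma::vec& yc,
                              const arma::mat& ant, double pixel_mm,
                              double frequency, double amp,
                              double dmin_mm) {
  const int nr = eps_r.n_rows, nc = eps_r.n_cols, na = ant.n_rows;
  const double eps0 = 8.8541878128e-12, c0 = 299792458.0;
  const double w = 2.0 * M_PI * frequency;
  const double k0 = w / c0;
  const std::complex<double> I(0.0, 1.0);
  const double step_mm = 0.5 * pixel_mm;

  arma::cx_cube out(nr, nc, 2 * na, arma::fill::zeros);
  for (int a = 0; a < na; ++a) {
    const double xa = ant(a, 0), ya = ant(a, 1);
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        const double dx = xc(c) - xa, dy = yc(r) - ya;
        double d_mm = std::sqrt(dx * dx + dy * dy);
        double ux, uy;
        if (d_mm < 1e-9) { ux = 0.0; uy = 1.0; d_mm = 0.0; }
        else { ux = dx / d_mm; uy = dy / d_mm; }
        const int ns = std::max(1, (int)std::ceil(d_mm / step_mm));
        std::complex<double> ksum(0.0, 0.0);
        for (int k = 0; k < ns; ++k) {
          const double t = (k + 0.5) / ns;
          const double px = xa + t * dx, py = ya + t * dy;
          // same half-open pixel mapping as point_to_pixel()
          const int cc = (int)std::floor((px - xc(0)) / pixel_mm + 0.5);
          const int rr = (int)std::floor((yc(0) - py) / pixel_mm + 0.5);
          double er = 1.0, sg = 0.0;
          if (rr >= 0 && rr < nr && cc >= 0 && cc < nc) {
            er = eps_r(rr, cc); sg = sigma(rr, cc);
          }
          ksum += k0 * std::sqrt(std::complex<double>(er, -sg / (w * eps0)));
        }
        const std::complex<double> kbar = ksum / (double)ns;
        const double d_m = d_mm * 1e-3;
        const double dg = std::max(d_m, dmin_mm * 1e-3);
        const std::complex<double> s =
          amp * std::exp(-I * kbar * d_m) / std::sqrt(dg);
        out(r, c, 2 * a)     = s * (-uy);
        out(r, c, 2 * a + 1) = s * ux;
      }
    }
  }
  return out;
}
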