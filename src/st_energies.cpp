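#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Iterative radix-2 Cooley-Tukey FFT (in place), for power-of-two n.
// The generic-length path below uses Armadillo's FFT instead; this one
// exists because the band-energy kernel performs ~50 voice transforms
// per channel per epoch and dominates the pipeline's run time.
namespace {

struct Fft2Plan {
  uword n = 0;
  std::vector<uword> rev;
  std::vector<std::complex<double>> tw;  // twiddles e^{-2pi i k/n}, k<n/2
  void build(uword n_) {
    n = n_;
    rev.assign(n, 0);
    uword lg = 0;
    while ((uword(1) << lg) < n) ++lg;
    for (uword i = 0; i < n; ++i) {
      uword r = 0;
      for (uword b = 0; b < lg; ++b) if (i & (uword(1) << b)) r |= uword(1) << (lg - 1 - b);
      rev[i] = r;
    }
    tw.resize(n / 2);
    for (uword k = 0; k < n / 2; ++k) {
      double a = -2.0 * M_PI * double(k) / double(n);
      tw[k] = std::complex<double>(std::cos(a), std::sin(a));
    }
  }
  void forward(std::complex<double>* a) const {
    for (uword i = 0; i < n; ++i) {
      if (rev[i] > i) std::swap(a[i], a[rev[i]]);
    }
    for (uword len = 2; len <= n; len <<= 1) {
      uword step = n / len;
      for (uword i = 0; i < n; i += len) {
        for (uword j = 0; j < len / 2; ++j) {
          std::complex<double> u = a[i + j];
          std::complex<double> v = a[i + j + len / 2] * tw[j * step];
          a[i + j] = u + v;
          a[i + j + len / 2] = u - v;
        }
      }
    }
  }
};

bool is_pow2(uword n) { return n > 0 && (n & (n - 1)) == 0; }

}  // namespace

// Per-frequency, per-time-block S-transform energies of all channels of
// one epoch. Each frequency row of the S-transform is the inverse DFT of
// the (shifted) signal spectrum multiplied by the Gaussian voice window
// spectrum G; when the analysis frequency falls on an integer DFT bin
// the shift is a pure index rotation, otherwise the modulated signal is
// transformed explicitly. Returns channels x (n_freq * n_blocks), block
// index fastest.
// [[Rcpp::export]]
arma::mat st_half_energies_cpp(const arma::mat& segment,
                               const arma::cx_mat& G,
                               const arma::ivec& shifts,
                               const arma::cx_mat& modulators,
                               const int n_blocks) {
  const uword nch = segment.n_rows, n = segment.n_cols, nf = G.n_cols;
  const uword block = n / n_blocks;
  mat out(nch, nf * n_blocks);
  const bool p2 = is_pow2(n);
  Fft2Plan plan;
  if (p2) plan.build(n);
  std::vector<std::complex<double>> buf(n);
  const double inv_n2 = 1.0 / (double(n) * double(n));

  auto spectrum = [&](const cx_vec& v) -> cx_vec {
    if (p2) {
      cx_vec out_v(n);
      std::copy(v.begin(), v.end(), buf.begin());
      plan.forward(buf.data());
      std::copy(buf.begin(), buf.end(), out_v.begin());
      return out_v;
    }
    return fft(v);
  };

  for (uword ch = 0; ch < nch; ++ch) {
    cx_vec x(segment.row(ch).t(), vec(n, fill::zeros));
    cx_vec X = spectrum(x);
    for (uword f = 0; f < nf; ++f) {
      // voice spectrum Y, stored conjugated so a forward FFT yields the
      // conjugate of n * ifft(Y); |.|^2 is unaffected
      if (shifts(f) >= 0) {
        const uword k = static_cast<uword>(shifts(f));
        for (uword m = 0; m < n; ++m) {
          buf[m] = std::conj(X((m + k) % n) * G(m, f));
        }
      } else {
        cx_vec Xm = spectrum(cx_vec(x % modulators.col(f)));
        for (uword m = 0; m < n; ++m) buf[m] = std::conj(Xm(m) * G(m, f));
      }
      if (p2) {
        plan.forward(buf.data());
        for (int b = 0; b < n_blocks; ++b) {
          double s = 0.0;
          for (uword i = b * block; i < (b + 1) * block; ++i) {
            s += std::norm(buf[i]);
          }
          out(ch, f * n_blocks + b) = s * inv_n2;
        }
      } else {
        cx_vec Y(n);
        for (uword m = 0; m < n; ++m) Y(m) = std::conj(buf[m]);
        cx_vec y = ifft(Y);
        for (int b = 0; b < n_blocks; ++b) {
          double s = 0.0;
          for (uword i = b * block; i < (b + 1) * block; ++i) {
            s += std::norm(y(i));
          }
          out(ch, f * n_blocks + b) = s;
        }
      }
    }
  }
  return out;
}
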