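#include <RcppArmadillo.h>
#include <cstdint>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Bootstrap refitting of the log-linear 3D Gaussian blob model
//
//   I(r) = I0 * exp(-1/2 r' A r),   ln I = ln I0 - 1/2 r' A r
//
// fitted by ordinary least squares over the intercept plus the 6 distinct
// entries of the symmetric matrix A. The blob's variance matrix is
// Sigma = A^-1; the principal standard deviations are 1/sqrt(eigenvalues(A)).
//
// The resampling RNG is a self-contained splitmix64 stream seeded from
// (root seed, segment label) so that per-segment results do not depend on
// the order in which segments are processed, and are identical across
// platforms and across R sessions.

namespace {

inline uint64_t splitmix64(uint64_t& x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

inline uint64_t child_state(double seed_root, int label) {
  uint64_t st = (uint64_t)(int64_t)seed_root;
  st ^= 0x9E3779B97F4A7C15ULL * (uint64_t)(label + 1);
  // warm up so nearby (seed, label) pairs decorrelate
  splitmix64(st);
  splitmix64(st);
  return st;
}

// model row for offset (z, y, x):
// (1, -z^2/2, -y^2/2, -x^2/2, -z*y, -z*x, -y*x)
inline void fill_row(double z, double y, double x, double* row) {
  row[0] = 1.0;
  row[1] = -0.5 * z * z;
  row[2] = -0.5 * y * y;
  row[3] = -0.5 * x * x;
  row[4] = -z * y;
  row[5] = -z * x;
  row[6] = -y * x;
}

struct FitOut {
  bool valid;
  double amplitude;
  arma::vec stds;  // ascending, length 3
  arma::mat A;
};

// Solve the normal equations and eigen-decompose A. Validity requires a
// positive-definite cross-product matrix (full-rank regression) and a
// positive-definite fitted A.
FitOut solve_fit(const arma::mat& XtX, const arma::vec& Xty) {
  FitOut out;
  out.valid = false;
  out.amplitude = NA_REAL;
  out.stds = arma::vec(3, arma::fill::value(NA_REAL));

  arma::mat R;
  if (!arma::chol(R, XtX)) return out;  // rank-deficient system
  arma::vec beta = arma::solve(arma::trimatu(R),
                               arma::solve(arma::trimatl(R.t()), Xty));
  arma::mat A(3, 3);
  A(0, 0) = beta(1);
  A(1, 1) = beta(2);
  A(2, 2) = beta(3);
  A(0, 1) = A(1, 0) = beta(4);
  A(0, 2) = A(2, 0) = beta(5);
  A(1, 2) = A(2, 1) = beta(6);
  out.A = A;
  out.amplitude = std::exp(beta(0));

  arma::vec ev;
  if (!arma::eig_sym(ev, A)) return out;
  if (ev(0) <= 0.0) return out;  // A not positive definite: not a blob
  out.valid = true;
  // eigenvalues ascending -> stds = 1/sqrt(ev) descending; store ascending
  out.stds(0) = 1.0 / std::sqrt(ev(2));
  out.stds(1) = 1.0 / std::sqrt(ev(1));
  out.stds(2) = 1.0 / std::sqrt(ev(0));
  return out;
}

}  // namespace

// Single log-linear Gaussian fit (reference path for tests / full-data fit).
// offsets: n x 3 matrix of (z, y, x) voxel offsets from the segment peak.
// [[Rcpp::export(name = ".cpp_fit_gaussian")]]
List cpp_fit_gaussian(NumericMatrix offsets, NumericVector intens,
                      int min_voxels) {
  const int n = offsets.nrow();
  arma::mat XtX(7, 7, arma::fill::zeros);
  arma::vec Xty(7, arma::fill::zeros);
  double row[7];
  int n_pos = 0;
  for (int i = 0; i < n; ++i) {
    double I = intens[i];
    if (!(I > 0.0) || !R_finite(I)) continue;
    ++n_pos;
    fill_row(offsets(i, 0), offsets(i, 1), offsets(i, 2), row);
    double li = std::log(I);
    for (int a = 0; a < 7; ++a) {
      Xty(a) += row[a] * li;
      for (int b = a; b < 7; ++b) XtX(a, b) += row[a] * row[b];
    }
  }
  XtX = arma::symmatu(XtX);

  if (n_pos < min_voxels) {
    return List::create(_["valid"] = false, _["amplitude"] = NA_REAL,
                        _["sigma_matrix"] = R_NilValue,
                        _["principal_stds"] = NumericVector::create(
                            NA_REAL, NA_REAL, NA_REAL),
                        _["n_used"] = n_pos);
  }
  FitOut f = solve_fit(XtX, Xty);
  SEXP sigma = R_NilValue;
  if (f.valid) {
    arma::mat S = arma::inv_sympd(f.A);
    sigma = wrap(S);
  }
  return List::create(_["valid"] = f.valid, _["amplitude"] = f.amplitude,
                      _["sigma_matrix"] = sigma,
                      _["principal_stds"] = wrap(f.stds),
                      _["n_used"] = n_pos);
}

// Bootstrap loop. Each iteration draws n voxels with replacement from the
// n-voxel region list, drops non-positive intensities, refits, and PASSes
// iff the fit is valid and every principal std lies in [std_min, std_max]
// (and the amplitude in [amp_min, amp_max]). Invalid fits count as FAIL.
//
// fail_limit >= 0 enables early rejection: once the failure count reaches
// fail_limit the final p-value is guaranteed to be >= fail_limit/n_iter, so
// iteration stops; p_value is then reported as NA and rejected = TRUE.
// [[Rcpp::export(name = ".cpp_bootstrap")]]
List cpp_bootstrap(NumericMatrix offsets, NumericVector intens, int n_iter,
                   double seed, int label, double std_min, double std_max,
                   double amp_min, double amp_max, int min_voxels,
                   int fail_limit, bool keep) {
  const int n = offsets.nrow();
  uint64_t rng = child_state(seed, label);

  // precompute model rows and log-intensities
  arma::mat X(n, 7);
  std::vector<double> logI(n);
  std::vector<uint8_t> pos(n);
  double row[7];
  for (int i = 0; i < n; ++i) {
    fill_row(offsets(i, 0), offsets(i, 1), offsets(i, 2), row);
    for (int a = 0; a < 7; ++a) X(i, a) = row[a];
    double I = intens[i];
    pos[i] = (I > 0.0 && R_finite(I)) ? 1 : 0;
    logI[i] = pos[i] ? std::log(I) : 0.0;
  }

  NumericMatrix stds_keep;
  LogicalVector valid_keep, pass_keep;
  NumericVector amp_keep;
  if (keep) {
    stds_keep = NumericMatrix(n_iter, 3);
    std::fill(stds_keep.begin(), stds_keep.end(), NA_REAL);
    valid_keep = LogicalVector(n_iter, false);
    pass_keep = LogicalVector(n_iter, false);
    amp_keep = NumericVector(n_iter, NA_REAL);
  }

  int n_fail = 0, n_done = 0, n_pass = 0, n_valid = 0;
  arma::vec pass_sum(3, arma::fill::zeros), pass_sumsq(3, arma::fill::zeros);
  arma::vec valid_sum(3, arma::fill::zeros), valid_sumsq(3, arma::fill::zeros);

  arma::mat XtX(7, 7);
  arma::vec Xty(7);

  for (int it = 0; it < n_iter; ++it) {
    if (fail_limit >= 0 && n_fail >= fail_limit) break;
    XtX.zeros();
    Xty.zeros();
    int n_pos = 0;
    for (int d = 0; d < n; ++d) {
      int idx = (int)(splitmix64(rng) % (uint64_t)n);
      if (!pos[idx]) continue;
      ++n_pos;
      const double li = logI[idx];
      for (int a = 0; a < 7; ++a) {
        const double xa = X(idx, a);
        Xty(a) += xa * li;
        for (int b = a; b < 7; ++b) XtX(a, b) += xa * X(idx, b);
      }
    }
    ++n_done;

    bool valid = false, pass = false;
    if (n_pos >= min_voxels) {
      FitOut f = solve_fit(arma::symmatu(XtX), Xty);
      valid = f.valid;
      if (valid) {
        ++n_valid;
        valid_sum += f.stds;
        valid_sumsq += arma::square(f.stds);
        pass = f.stds(0) >= std_min && f.stds(2) <= std_max &&
               f.amplitude >= amp_min && f.amplitude <= amp_max;
        if (pass) {
          ++n_pass;
          pass_sum += f.stds;
          pass_sumsq += arma::square(f.stds);
        }
        if (keep) {
          for (int a = 0; a < 3; ++a) stds_keep(it, a) = f.stds(a);
          amp_keep[it] = f.amplitude;
        }
      }
    }
    if (keep) {
      valid_keep[it] = valid;
      pass_keep[it] = pass;
    }
    if (!pass) ++n_fail;
  }

  const bool complete = (n_done == n_iter);
  double p_value = complete ? (double)n_fail / (double)n_iter : NA_REAL;

  auto mean_sd = [](const arma::vec& s, const arma::vec& ss, int m) {
    NumericVector mean(3, NA_REAL), sd(3, NA_REAL);
    if (m > 0)
      for (int a = 0; a < 3; ++a) mean[a] = s(a) / m;
    if (m > 1)
      for (int a = 0; a < 3; ++a) {
        double v = (ss(a) - s(a) * s(a) / m) / (m - 1);
        sd[a] = v > 0 ? std::sqrt(v) : 0.0;
      }
    return List::create(mean, sd);
  };
  List vs = mean_sd(valid_sum, valid_sumsq, n_valid);
  List ps = mean_sd(pass_sum, pass_sumsq, n_pass);

  List out = List::create(
      _["p_value"] = p_value, _["n_iterations"] = n_iter,
      _["n_done"] = n_done, _["n_fail"] = n_fail, _["n_valid"] = n_valid,
      _["n_pass"] = n_pass, _["rejected"] = !complete,
      _["mean_stds"] = vs[0], _["sd_stds"] = vs[1],
      _["pass_mean_stds"] = ps[0], _["pass_sd_stds"] = ps[1]);
  if (keep) {
    out["per_resample_stds"] = stds_keep;
    out["per_resample_amplitude"] = amp_keep;
    out["valid"] = valid_keep;
    out["pass"] = pass_keep;
  }
  return out;
}
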