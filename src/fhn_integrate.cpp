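#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Explicit Euler--Maruyama integration of the delay-coupled FitzHugh-Nagumo
// network:
//
//   eps * dx_i/dt = x_i - x_i^3/3 - y_i + g * sum_j J_ij (x_j(t - tau) - x_i(t))
//       dy_i/dt   = x_i + a + A sin(2 pi t / Te) + D xi_i(t)
//
// Noise enters the slow variable only; the discrete update adds
// noise_amp * sqrt(dt) * eta with eta ~ N(0,1) i.i.d. per neuron per step,
// where noise_amp is D (amplitude convention, default) or sqrt(2 D)
// (intensity convention) -- chosen by the caller.
//
// The delay history x_j(t - tau) for t < tau is the initial condition x_j(0).
// A ring buffer of H = round(tau/dt) state snapshots implements the delay.
//
// Randomness comes from a dedicated mt19937_64 stream seeded from `seed`,
// independent of R's RNG, so trajectories are bit-reproducible across calls
// and platforms for a given seed.
//
// [[Rcpp::export]]
List fhn_integrate_cpp(IntegerMatrix edges, int N,
                       double eps, double a, double A, double Te,
                       double g, double D, double tau,
                       double dt, double t_total, double t_transient,
                       double seed, bool sqrt2_noise,
                       NumericVector x0, NumericVector y0,
                       int record_stride, bool record_raster) {
  if (N <= 0) stop("N must be positive");
  if (dt <= 0) stop("dt must be positive");
  const int E = edges.nrow();
  std::vector<int> ea(E), eb(E);
  std::vector<double> deg(N, 0.0);
  for (int e = 0; e < E; ++e) {
    int ia = edges(e, 0), ib = edges(e, 1);
    if (ia < 0 || ia >= N || ib < 0 || ib >= N)
      stop("edge index out of range");
    ea[e] = ia; eb[e] = ib;
    deg[ia] += 1.0; deg[ib] += 1.0;
  }

  const long nsteps = (long)std::llround(t_total / dt);
  const long ntrans = (long)std::llround(t_transient / dt);
  if (ntrans >= nsteps) stop("t_transient must be smaller than t_total");
  const long H = (long)std::llround(tau / dt);
  if (std::fabs(H * dt - tau) > 1e-9)
    stop("tau must be an integer multiple of dt (tolerance 1e-9)");

  std::vector<double> x(N), y(N), s(N), xd(N);
  for (int i = 0; i < N; ++i) { x[i] = x0[i % x0.size()]; y[i] = y0[i % y0.size()]; }

  // delay ring buffer: slot (step mod H) holds x at step - H once filled;
  // initialised to the t = 0 state, which doubles as the pre-history.
  std::vector<double> hist;
  if (H > 0) {
    hist.resize((size_t)H * N);
    for (long h = 0; h < H; ++h)
      for (int i = 0; i < N; ++i) hist[(size_t)h * N + i] = x[i];
  }

  const double amp = sqrt2_noise ? std::sqrt(2.0 * D) : D;
  const double noise_fac = amp * std::sqrt(dt);
  const bool noisy = noise_fac > 0.0;
  const double two_pi_over_Te = 2.0 * M_PI / Te;

  std::mt19937_64 rng((uint64_t)std::llround(seed) + 0x9E3779B97F4A7C15ULL);
  std::normal_distribution<double> gauss(0.0, 1.0);

  const long nrec = nsteps - ntrans;
  NumericVector Xout(nrec), tout(nrec);
  const long nras = record_raster ? (nrec + record_stride - 1) / record_stride : 0;
  NumericMatrix raster(record_raster ? nras : 0, record_raster ? N : 0);
  NumericVector tras(nras);

  long r = 0, rr = 0;
  for (long step = 0; step < nsteps; ++step) {
    const double t = step * dt;

    // delayed state
    const double *xdp;
    if (H > 0) {
      size_t slot = (size_t)(step % H) * N;
      for (int i = 0; i < N; ++i) xd[i] = hist[slot + i];
      // overwrite the slot with the current state: it is read again at step + H
      for (int i = 0; i < N; ++i) hist[slot + i] = x[i];
      xdp = xd.data();
    } else {
      xdp = x.data();
    }

    // coupling input s_i = sum_j J_ij x_j(t - tau)
    std::fill(s.begin(), s.end(), 0.0);
    for (int e = 0; e < E; ++e) {
      s[ea[e]] += xdp[eb[e]];
      s[eb[e]] += xdp[ea[e]];
    }

    const double sig = a + A * std::sin(two_pi_over_Te * t);
    double mf = 0.0;
    for (int i = 0; i < N; ++i) {
      const double xi = x[i];
      const double dx = (xi - xi * xi * xi / 3.0 - y[i] +
                         g * (s[i] - deg[i] * xi)) / eps;
      double yn = y[i] + dt * (xi + sig);
      if (noisy) yn += noise_fac * gauss(rng);
      x[i] = xi + dt * dx;
      y[i] = yn;
      mf += x[i];
    }
    mf /= N;

    if (step >= ntrans) {
      if (!std::isfinite(mf))
        stop("state diverged (non-finite mean field) at t = %f", (step + 1) * dt);
      Xout[r] = mf;
      tout[r] = (step + 1) * dt;
      if (record_raster && (r % record_stride) == 0) {
        for (int i = 0; i < N; ++i) raster(rr, i) = x[i];
        tras[rr] = (step + 1) * dt;
        ++rr;
      }
      ++r;
    }
    if ((step & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(_["time"] = tout, _["X"] = Xout,
                          _["x_final"] = NumericVector(x.begin(), x.end()),
                          _["y_final"] = NumericVector(y.begin(), y.end()));
  if (record_raster) {
    out["raster"] = raster;
    out["raster_time"] = tras;
  }
  return out;
}
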