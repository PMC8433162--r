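#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK4 integration of the toy plankton community:
//   dP_i/dt = mu_i P_i - sum_j G_ij Z_j - mP P_i
//   mu_i    = mu_max_i * a(T) * N / (N + kN_i),  a(T) = exp(Ea (T - Tref))
//   G_ij    = gmax_j phi_ij P_i Pi_j / (kg^2 + Pi_j^2),  Pi_j = sum_i phi_ij P_i
//   dZ_j/dt = lambda sum_i G_ij Z_j - mZ Z_j^2
//   dN/dt   = S(t) - sum_i mu_i P_i + r * losses
// losses = unassimilated grazing + both mortalities, so r = 1 closes the
// nitrogen budget exactly. States are clipped at zero after each step.
//
// Forcing S(t), T(t) is linear-in-time between per-year nodes. Output is the
// annual mean of every state variable.

struct Deriv {
  int np, nz;
  const double *mu_max, *kN, *gmax, *phi; // phi: np x nz, column-major
  double kg2, lambda, mP, mZ, mZlin, r, Ea, Tref;
  mutable std::vector<double> mu, grazP; // scratch, sized once

  void operator()(const double N, const double *P, const double *Z,
                  const double S, const double T,
                  double &dN, double *dP, double *dZ) const {
    const double aT = std::exp(Ea * (T - Tref));
    double uptake = 0.0, sumP = 0.0, sumZ2 = 0.0, sumZ = 0.0;
    std::fill(grazP.begin(), grazP.end(), 0.0);
    for (int i = 0; i < np; ++i) {
      mu[i] = mu_max[i] * aT * N / (N + kN[i]);
      uptake += mu[i] * P[i];
      sumP += P[i];
    }
    double intake_tot = 0.0;
    for (int j = 0; j < nz; ++j) {
      const double *ph = phi + (size_t)j * np;
      double Pi = 0.0;
      for (int i = 0; i < np; ++i) Pi += ph[i] * P[i];
      const double gfac = gmax[j] * Pi / (kg2 + Pi * Pi);
      const double intake = gfac * Pi * Z[j];
      intake_tot += intake;
      for (int i = 0; i < np; ++i) grazP[i] += gfac * ph[i] * P[i] * Z[j];
      dZ[j] = lambda * intake - mZ * Z[j] * Z[j] - mZlin * Z[j];
      sumZ2 += Z[j] * Z[j];
      sumZ += Z[j];
    }
    for (int i = 0; i < np; ++i)
      dP[i] = mu[i] * P[i] - grazP[i] - mP * P[i];
    const double losses = (1.0 - lambda) * intake_tot + mP * sumP +
      mZ * sumZ2 + mZlin * sumZ;
    dN = S - uptake + r * losses;
  }
};

// [[Rcpp::export]]
List sim_cell_rk4(NumericVector P0, NumericVector Z0, double N0,
                  NumericVector mu_max, NumericVector kN,
                  NumericVector gmax, NumericMatrix phi, double k_graze,
                  double lambda, double mP, double mZ, double mZlin,
                  double recycle, double Ea, double Tref,
                  NumericVector S_year, NumericVector T_year,
                  double dt, int steps_per_year, double floor_val) {
  const int np = P0.size(), nz = Z0.size(), ny = S_year.size();
  if (T_year.size() != ny) stop("S_year and T_year lengths differ");
  if (phi.nrow() != np || phi.ncol() != nz) stop("phi must be np x nz");

  Deriv f;
  f.np = np; f.nz = nz;
  f.mu_max = mu_max.begin(); f.kN = kN.begin(); f.gmax = gmax.begin();
  f.phi = phi.begin();
  f.kg2 = k_graze * k_graze; f.lambda = lambda;
  f.mP = mP; f.mZ = mZ; f.mZlin = mZlin; f.r = recycle;
  f.Ea = Ea; f.Tref = Tref;
  f.mu.resize(np); f.grazP.resize(np);

  std::vector<double> P(P0.begin(), P0.end()), Z(Z0.begin(), Z0.end());
  double N = N0;

  NumericMatrix P_ann(ny, np), Z_ann(ny, nz);
  NumericVector N_ann(ny);

  std::vector<double> k1P(np), k2P(np), k3P(np), k4P(np), tmpP(np);
  std::vector<double> k1Z(nz), k2Z(nz), k3Z(nz), k4Z(nz), tmpZ(nz);
  double k1N, k2N, k3N, k4N;

  for (int y = 0; y < ny; ++y) {
    std::vector<double> Pacc(np, 0.0), Zacc(nz, 0.0);
    double Nacc = 0.0;
    for (int s = 0; s < steps_per_year; ++s) {
      // forcing: linear between this year's node and the next
      const double frac = (s + 0.5) / steps_per_year;
      const int y2 = (y + 1 < ny) ? y + 1 : y;
      const double S = S_year[y] + frac * (S_year[y2] - S_year[y]);
      const double T = T_year[y] + frac * (T_year[y2] - T_year[y]);

      f(N, P.data(), Z.data(), S, T, k1N, k1P.data(), k1Z.data());
      for (int i = 0; i < np; ++i) tmpP[i] = P[i] + 0.5 * dt * k1P[i];
      for (int j = 0; j < nz; ++j) tmpZ[j] = Z[j] + 0.5 * dt * k1Z[j];
      f(N + 0.5 * dt * k1N, tmpP.data(), tmpZ.data(), S, T, k2N,
        k2P.data(), k2Z.data());
      for (int i = 0; i < np; ++i) tmpP[i] = P[i] + 0.5 * dt * k2P[i];
      for (int j = 0; j < nz; ++j) tmpZ[j] = Z[j] + 0.5 * dt * k2Z[j];
      f(N + 0.5 * dt * k2N, tmpP.data(), tmpZ.data(), S, T, k3N,
        k3P.data(), k3Z.data());
      for (int i = 0; i < np; ++i) tmpP[i] = P[i] + dt * k3P[i];
      for (int j = 0; j < nz; ++j) tmpZ[j] = Z[j] + dt * k3Z[j];
      f(N + dt * k3N, tmpP.data(), tmpZ.data(), S, T, k4N,
        k4P.data(), k4Z.data());

      N += dt / 6.0 * (k1N + 2 * k2N + 2 * k3N + k4N);
      for (int i = 0; i < np; ++i) {
        P[i] += dt / 6.0 * (k1P[i] + 2 * k2P[i] + 2 * k3P[i] + k4P[i]);
        if (P[i] < floor_val) P[i] = 0; // positivity clip + extinction floor
      }
      for (int j = 0; j < nz; ++j) {
        Z[j] += dt / 6.0 * (k1Z[j] + 2 * k2Z[j] + 2 * k3Z[j] + k4Z[j]);
        if (Z[j] < floor_val) Z[j] = 0;
      }
      if (N < 0) N = 0;
      if (!std::isfinite(N)) {
        stop("integration error: nutrient became non-finite at year %d, step %d",
             y + 1, s + 1);
      }
      for (int i = 0; i < np; ++i) {
        if (!std::isfinite(P[i]))
          stop("integration error: phytoplankton %d non-finite at year %d, step %d",
               i + 1, y + 1, s + 1);
      }
      for (int j = 0; j < nz; ++j) {
        if (!std::isfinite(Z[j]))
          stop("integration error: zooplankton %d non-finite at year %d, step %d",
               j + 1, y + 1, s + 1);
      }
      Nacc += N;
      for (int i = 0; i < np; ++i) Pacc[i] += P[i];
      for (int j = 0; j < nz; ++j) Zacc[j] += Z[j];
    }
    N_ann[y] = Nacc / steps_per_year;
    for (int i = 0; i < np; ++i) P_ann(y, i) = Pacc[i] / steps_per_year;
    for (int j = 0; j < nz; ++j) Z_ann(y, j) = Zacc[j] / steps_per_year;
  }

  NumericVector Pf(P.begin(), P.end()), Zf(Z.begin(), Z.end());
  return List::create(_["phyto"] = P_ann, _["zoo"] = Z_ann,
                      _["nutrient"] = N_ann, _["P_final"] = Pf,
                      _["Z_final"] = Zf, _["N_final"] = N);
}
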