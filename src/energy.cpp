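#include <Rcpp.h>
using namespace Rcpp;

// Pairwise coarse-grained interaction energy between two bead sets.
//
// Electrostatics: screened Coulomb with distance-dependent dielectric
// eps(r) = 4r, i.e. E = 332 * qi*qj / (4 * r * r) = 83 * qi*qj / r^2
// (kcal/mol with charges in e and r in Angstrom), applied within `cutoff`.
// Sterics: soft-sphere repulsion eps_rep * (sigma_ij / r)^8 with
// sigma_ij = radius_i + radius_j.
// Near-coincident beads (r < 0.5 A) are evaluated at r = 0.5 A and counted
// in the third return slot so callers can flag the pose.
//
// Returns c(electrostatic, steric, n_capped).
// [[Rcpp::export(name = ".cg_pair_energy")]]
NumericVector cg_pair_energy(const NumericMatrix& A, const NumericVector& qa,
                             const NumericVector& ra,
                             const NumericMatrix& B, const NumericVector& qb,
                             const NumericVector& rb,
                             double eps_rep, double cutoff) {
  const int na = A.nrow(), nb = B.nrow();
  const double c2 = cutoff * cutoff;
  double elec = 0.0, ster = 0.0;
  int capped = 0;
  for (int i = 0; i < na; ++i) {
    const double xi = A(i, 0), yi = A(i, 1), zi = A(i, 2);
    const double qi = qa[i], ri = ra[i];
    for (int j = 0; j < nb; ++j) {
      const double dx = xi - B(j, 0);
      const double dy = yi - B(j, 1);
      const double dz = zi - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > c2) continue;
      if (d2 < 0.25) { d2 = 0.25; ++capped; }
      const double qq = qi * qb[j];
      if (qq != 0.0) elec += 83.0 * qq / d2;
      const double s = ri + rb[j];
      double s2 = (s * s) / d2;   // (sigma/r)^2
      double s8 = s2 * s2;        // ^4
      s8 *= s8;                   // ^8
      ster += eps_rep * s8;
    }
  }
  return NumericVector::create(elec, ster, (double)capped);
}

// Same electrostatic model evaluated at probe points (unit probe charge):
// V(p) = sum_i 332 * q_i / (4 * r_i^2) over beads within `cutoff`.
// [[Rcpp::export(name = ".cg_potential")]]
NumericVector cg_potential(const NumericMatrix& probes,
                           const NumericMatrix& beads,
                           const NumericVector& q, double cutoff) {
  const int np = probes.nrow(), nb = beads.nrow();
  const double c2 = cutoff * cutoff;
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    const double xi = probes(i, 0), yi = probes(i, 1), zi = probes(i, 2);
    double v = 0.0;
    for (int j = 0; j < nb; ++j) {
      if (q[j] == 0.0) continue;
      const double dx = xi - beads(j, 0);
      const double dy = yi - beads(j, 1);
      const double dz = zi - beads(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > c2) continue;
      if (d2 < 1e-12) d2 = 1e-12;
      v += 83.0 * q[j] / d2;
    }
    out[i] = v;
  }
  return out;
}

static inline double pair_energy(const NumericMatrix& P,
                                 const NumericVector& qp,
                                 const NumericVector& rp,
                                 const NumericMatrix& R,
                                 const NumericVector& qr,
                                 const NumericVector& rr,
                                 double eps_rep, double c2) {
  double e = 0.0;
  const int na = P.nrow(), nb = R.nrow();
  for (int i = 0; i < na; ++i) {
    const double xi = P(i, 0), yi = P(i, 1), zi = P(i, 2);
    const double qi = qp[i], ri = rp[i];
    for (int j = 0; j < nb; ++j) {
      const double dx = xi - R(j, 0);
      const double dy = yi - R(j, 1);
      const double dz = zi - R(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > c2) continue;
      if (d2 < 0.25) d2 = 0.25;
      const double qq = qi * qr[j];
      if (qq != 0.0) e += 83.0 * qq / d2;
      const double s = ri + rr[j];
      double s2 = (s * s) / d2;
      double s8 = s2 * s2;
      s8 *= s8;
      e += eps_rep * s8;
    }
  }
  return e;
}

// One simulated-annealing search over rigid-body + virtual-torsion space.
// Uses R's RNG (reproducible under set.seed). Template bias (harmonic to
// tpl_coords over tpl_idx, 1-based) is added to the search energy when
// bias_k > 0 and tpl_idx is non-empty.
// [[Rcpp::export(name = ".sa_run")]]
List sa_run(NumericMatrix coords, int n_res,
            const NumericVector& qp, const NumericVector& rp,
            const NumericMatrix& rec, const NumericVector& qr,
            const NumericVector& rr, double eps_rep, double cutoff,
            const NumericVector& center, double radius,
            int steps, int quench, double t_start, double t_end,
            double step_trans, double step_rot, double step_tor,
            const IntegerVector& tpl_idx, const NumericMatrix& tpl_coords,
            double bias_k) {
  RNGScope scope;
  const double c2 = cutoff * cutoff;
  const double r2 = radius * radius;
  const int nb = coords.nrow();
  const int nr = rec.nrow();
  const int n_tor = n_res > 3 ? n_res - 3 : 0;
  const bool biased = bias_k > 0.0 && tpl_idx.size() > 0;

  // flat buffers: [x0..x_{nb-1}, y0.., z0..]
  std::vector<double> cur(3 * nb), cand(3 * nb), best(3 * nb);
  for (int i = 0; i < nb; ++i)
    for (int d = 0; d < 3; ++d) cur[d * nb + i] = coords(i, d);

  std::vector<double> rx(nr), ry(nr), rz(nr), rq(nr), rrad(nr);
  for (int j = 0; j < nr; ++j) {
    rx[j] = rec(j, 0); ry[j] = rec(j, 1); rz[j] = rec(j, 2);
    rq[j] = qr[j]; rrad[j] = rr[j];
  }

  auto energy_of = [&](const std::vector<double>& M) {
    double e = 0.0;
    for (int i = 0; i < nb; ++i) {
      const double xi = M[i], yi = M[nb + i], zi = M[2 * nb + i];
      const double qi = qp[i], ri = rp[i];
      for (int j = 0; j < nr; ++j) {
        const double dx = xi - rx[j], dy = yi - ry[j], dz = zi - rz[j];
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 > c2) continue;
        if (d2 < 0.25) d2 = 0.25;
        const double qq = qi * rq[j];
        if (qq != 0.0) e += 83.0 * qq / d2;
        const double sgm = ri + rrad[j];
        double s2 = (sgm * sgm) / d2;
        double s8 = s2 * s2;
        s8 *= s8;
        e += eps_rep * s8;
      }
    }
    if (biased) {
      for (int k = 0; k < tpl_idx.size(); ++k) {
        const int i = tpl_idx[k] - 1;
        const double dx = M[i] - tpl_coords(k, 0);
        const double dy = M[nb + i] - tpl_coords(k, 1);
        const double dz = M[2 * nb + i] - tpl_coords(k, 2);
        e += bias_k * (dx * dx + dy * dy + dz * dz);
      }
    }
    return e;
  };
  auto in_sphere = [&](const std::vector<double>& M) {
    for (int i = 0; i < nb; ++i) {
      const double dx = M[i] - center[0];
      const double dy = M[nb + i] - center[1];
      const double dz = M[2 * nb + i] - center[2];
      if (dx * dx + dy * dy + dz * dz <= r2) return true;
    }
    return false;
  };
  auto rotate_range = [&](std::vector<double>& M, const int* idx, int nidx,
                          const double* o, const double* axis,
                          double angle) {
    double n = std::sqrt(axis[0] * axis[0] + axis[1] * axis[1] +
                         axis[2] * axis[2]);
    if (n < 1e-12) return;
    const double ux = axis[0] / n, uy = axis[1] / n, uz = axis[2] / n;
    const double ca = std::cos(angle), sa = std::sin(angle);
    const double R00 = ca + ux * ux * (1 - ca);
    const double R01 = ux * uy * (1 - ca) - uz * sa;
    const double R02 = ux * uz * (1 - ca) + uy * sa;
    const double R10 = uy * ux * (1 - ca) + uz * sa;
    const double R11 = ca + uy * uy * (1 - ca);
    const double R12 = uy * uz * (1 - ca) - ux * sa;
    const double R20 = uz * ux * (1 - ca) - uy * sa;
    const double R21 = uz * uy * (1 - ca) + ux * sa;
    const double R22 = ca + uz * uz * (1 - ca);
    for (int k = 0; k < nidx; ++k) {
      const int i = idx[k];
      const double x = M[i] - o[0];
      const double y = M[nb + i] - o[1];
      const double z = M[2 * nb + i] - o[2];
      M[i] = o[0] + R00 * x + R01 * y + R02 * z;
      M[nb + i] = o[1] + R10 * x + R11 * y + R12 * z;
      M[2 * nb + i] = o[2] + R20 * x + R21 * y + R22 * z;
    }
  };

  double e = energy_of(cur);
  best = cur;
  double best_e = e;
  const int total = steps + quench;
  std::vector<int> all_idx(nb), mv_idx;
  for (int i = 0; i < nb; ++i) all_idx[i] = i;
  mv_idx.reserve(nb);

  for (int s = 1; s <= total; ++s) {
    double temp = 0.0;
    if (s <= steps) {
      temp = t_start * std::pow(t_end / t_start,
                                (double)(s - 1) /
                                    (double)(steps > 1 ? steps - 1 : 1));
    }
    double scl = std::sqrt(temp / t_start);
    if (scl < 0.15) scl = 0.15;
    cand = cur;
    const double u = unif_rand();
    if (u < 0.4 || n_res < 2) {
      const double dx = norm_rand() * step_trans * scl;
      const double dy = norm_rand() * step_trans * scl;
      const double dz = norm_rand() * step_trans * scl;
      for (int i = 0; i < nb; ++i) {
        cand[i] += dx;
        cand[nb + i] += dy;
        cand[2 * nb + i] += dz;
      }
    } else if (u < 0.7 || n_tor == 0) {
      double ctr[3] = {0, 0, 0};
      for (int i = 0; i < nb; ++i) {
        ctr[0] += cand[i];
        ctr[1] += cand[nb + i];
        ctr[2] += cand[2 * nb + i];
      }
      ctr[0] /= nb; ctr[1] /= nb; ctr[2] /= nb;
      double ax[3] = {norm_rand(), norm_rand(), norm_rand()};
      rotate_range(cand, all_idx.data(), nb, ctr, ax,
                   norm_rand() * step_rot * scl);
    } else {
      // torsion about Calpha(bond)-Calpha(bond+1), bond in 2..n_res-2
      int bond = 2 + (int)(unif_rand() * n_tor);
      if (bond > n_res - 2) bond = n_res - 2;
      double origin[3] = {cand[bond - 1], cand[nb + bond - 1],
                          cand[2 * nb + bond - 1]};
      double ax[3] = {cand[bond] - origin[0], cand[nb + bond] - origin[1],
                      cand[2 * nb + bond] - origin[2]};
      mv_idx.clear();
      for (int i = bond + 1; i < n_res; ++i) mv_idx.push_back(i);
      for (int i = n_res + bond; i < 2 * n_res; ++i) mv_idx.push_back(i);
      rotate_range(cand, mv_idx.data(), (int)mv_idx.size(), origin, ax,
                   norm_rand() * step_tor * scl);
    }
    if (!in_sphere(cand)) continue;
    const double ec = energy_of(cand);
    if (ec <= e || (temp > 0 && unif_rand() < std::exp(-(ec - e) / temp))) {
      cur.swap(cand);
      e = ec;
      if (e < best_e) {
        best = cur;
        best_e = e;
      }
    }
  }
  NumericMatrix out(nb, 3);
  for (int i = 0; i < nb; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = best[d * nb + i];
  return List::create(Named("coords") = out, Named("energy") = best_e);
}

// Build pose coordinates from a DOF vector theta =
// (translation[3], rotation vector[3], torsion increments[n_res-3])
// applied to reference coordinates `ref` (2*n_res x 3: Calpha rows then
// sidechain rows). Torsion j rotates every bead beyond the
// Calpha(j+1)-Calpha(j+2) bond, matching the R-level move.
// [[Rcpp::export(name = ".pose_dof")]]
NumericMatrix pose_dof(const NumericVector& theta, const NumericMatrix& ref,
                       int n_res) {
  const int nb = ref.nrow();
  NumericMatrix M = clone(ref);
  const int n_tor = n_res > 3 ? n_res - 3 : 0;
  auto rotate = [&](const std::vector<int>& idx, const double* o,
                    const double* axis, double angle) {
    double n = std::sqrt(axis[0] * axis[0] + axis[1] * axis[1] +
                         axis[2] * axis[2]);
    if (n < 1e-12) return;
    const double ux = axis[0] / n, uy = axis[1] / n, uz = axis[2] / n;
    const double ca = std::cos(angle), sa = std::sin(angle);
    const double R00 = ca + ux * ux * (1 - ca);
    const double R01 = ux * uy * (1 - ca) - uz * sa;
    const double R02 = ux * uz * (1 - ca) + uy * sa;
    const double R10 = uy * ux * (1 - ca) + uz * sa;
    const double R11 = ca + uy * uy * (1 - ca);
    const double R12 = uy * uz * (1 - ca) - ux * sa;
    const double R20 = uz * ux * (1 - ca) - uy * sa;
    const double R21 = uz * uy * (1 - ca) + ux * sa;
    const double R22 = ca + uz * uz * (1 - ca);
    for (size_t k = 0; k < idx.size(); ++k) {
      const int i = idx[k];
      const double x = M(i, 0) - o[0];
      const double y = M(i, 1) - o[1];
      const double z = M(i, 2) - o[2];
      M(i, 0) = o[0] + R00 * x + R01 * y + R02 * z;
      M(i, 1) = o[1] + R10 * x + R11 * y + R12 * z;
      M(i, 2) = o[2] + R20 * x + R21 * y + R22 * z;
    }
  };
  for (int j = 0; j < n_tor; ++j) {
    const double ang = theta[6 + j];
    if (ang == 0.0) continue;
    const int bond = j + 2;  // 1-based bond index in 2..n_res-2
    double o[3] = {M(bond - 1, 0), M(bond - 1, 1), M(bond - 1, 2)};
    double ax[3] = {M(bond, 0) - o[0], M(bond, 1) - o[1],
                    M(bond, 2) - o[2]};
    std::vector<int> mv;
    for (int i = bond + 1; i < n_res; ++i) mv.push_back(i);
    for (int i = n_res + bond; i < 2 * n_res; ++i) mv.push_back(i);
    rotate(mv, o, ax, ang);
  }
  double w[3] = {theta[3], theta[4], theta[5]};
  const double ang = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  if (ang > 1e-12) {
    double ctr[3] = {0, 0, 0};
    for (int i = 0; i < nb; ++i) {
      ctr[0] += M(i, 0);
      ctr[1] += M(i, 1);
      ctr[2] += M(i, 2);
    }
    ctr[0] /= nb; ctr[1] /= nb; ctr[2] /= nb;
    std::vector<int> all(nb);
    for (int i = 0; i < nb; ++i) all[i] = i;
    rotate(all, ctr, w, ang);
  }
  for (int i = 0; i < nb; ++i) {
    M(i, 0) += theta[0];
    M(i, 1) += theta[1];
    M(i, 2) += theta[2];
  }
  return M;
}
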