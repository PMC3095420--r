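#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pairwise Lennard-Jones (+ optional Coulomb) over inter-group pairs with a
// CHARMM-style switching function. Groups: unit index >= 0 for DNA
// nucleotides, -1 for the rigid CNT substrate. Pairs within the same group
// are excluded (intra-unit geometry is maintained by harmonic restraints;
// the tube is rigid so its internal energy is a constant), as are the
// explicitly listed bonded head-tail pairs.
//
// coords are in nm, eps in kcal/mol, sigma in nm; gradient is returned in
// kcal/mol/nm.
// Build a Verlet pair list of all inter-group pairs within r_list. Used by
// the minimizer to avoid re-scanning the full N^2 pair set at every energy
// evaluation; the list is refreshed between optimizer chunks.
// [[Rcpp::export(name = ".nb_pairs")]]
List nb_pairs(NumericMatrix coords, IntegerVector group,
              IntegerVector excl_i, IntegerVector excl_j, double r_list) {
  const int n = coords.nrow();
  const double r2max = r_list * r_list;
  std::vector<double> excl_keys;
  for (int k = 0; k < excl_i.size(); ++k) {
    int a = excl_i[k], b = excl_j[k];
    if (a > b) std::swap(a, b);
    excl_keys.push_back((double)a * n + b);
  }
  std::sort(excl_keys.begin(), excl_keys.end());
  std::vector<int> pi, pj;
  const double *x = &coords(0, 0), *y = &coords(0, 1), *z = &coords(0, 2);
  for (int i = 0; i < n - 1; ++i) {
    const int gi = group[i];
    for (int j = i + 1; j < n; ++j) {
      if (gi == group[j]) continue;
      const double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
      if (dx * dx + dy * dy + dz * dz > r2max) continue;
      if (!excl_keys.empty() &&
          std::binary_search(excl_keys.begin(), excl_keys.end(),
                             (double)i * n + j)) continue;
      pi.push_back(i); pj.push_back(j);
    }
  }
  return List::create(_["i"] = wrap(pi), _["j"] = wrap(pj));
}

// [[Rcpp::export(name = ".nb_energy")]]
List nb_energy(NumericMatrix coords, IntegerVector group,
               NumericVector eps, NumericVector sigma, NumericVector charge,
               double scale, double cutoff, double r_on,
               IntegerVector excl_i, IntegerVector excl_j,
               bool want_grad) {
  const int n = coords.nrow();
  const double coul_k = 33.20636; // kcal mol^-1 nm e^-2
  const bool finite_cut = std::isfinite(cutoff);
  const double cut2 = finite_cut ? cutoff * cutoff : 0.0;
  const double ron2 = r_on * r_on;
  const double roff2 = cut2;
  const double denom = finite_cut
    ? (roff2 - ron2) * (roff2 - ron2) * (roff2 - ron2) : 1.0;
  bool any_charge = false;
  for (int i = 0; i < n; ++i) if (charge[i] != 0.0) { any_charge = true; break; }

  // hash the excluded pairs into a set keyed by i * n + j (i < j)
  std::vector<double> excl_keys;
  excl_keys.reserve(excl_i.size());
  for (int k = 0; k < excl_i.size(); ++k) {
    int a = excl_i[k], b = excl_j[k];
    if (a > b) std::swap(a, b);
    excl_keys.push_back((double)a * n + b);
  }
  std::sort(excl_keys.begin(), excl_keys.end());

  double e_cnt_dna = 0.0, e_dna_dna = 0.0;
  NumericMatrix grad(want_grad ? n : 1, 3);

  const double *x = &coords(0, 0), *y = &coords(0, 1), *z = &coords(0, 2);
  for (int i = 0; i < n - 1; ++i) {
    const int gi = group[i];
    for (int j = i + 1; j < n; ++j) {
      if (gi == group[j]) continue;
      if (!excl_keys.empty()) {
        double key = (double)i * n + j;
        if (std::binary_search(excl_keys.begin(), excl_keys.end(), key)) continue;
      }
      const double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (finite_cut && r2 > cut2) continue;
      const double sig = 0.5 * (sigma[i] + sigma[j]);
      const double epsij = scale * std::sqrt(eps[i] * eps[j]);
      const double s2 = sig * sig / r2;
      const double s6 = s2 * s2 * s2;
      double v = 4.0 * epsij * s6 * (s6 - 1.0);
      const double r = std::sqrt(r2);
      // dV/dr
      double dvdr = -24.0 * epsij * s6 * (2.0 * s6 - 1.0) / r;
      if (any_charge && charge[i] != 0.0 && charge[j] != 0.0) {
        const double vc = coul_k * charge[i] * charge[j] / r;
        v += vc;
        dvdr += -vc / r;
      }
      double sw = 1.0, dswdr = 0.0;
      if (finite_cut && r2 > ron2) {
        const double a = roff2 - r2;
        sw = a * a * (roff2 + 2.0 * r2 - 3.0 * ron2) / denom;
        // d/dr of switch
        dswdr = (2.0 * a * (-2.0 * r) * (roff2 + 2.0 * r2 - 3.0 * ron2) +
                 a * a * 4.0 * r) / denom;
      }
      const double e = v * sw;
      if (gi < 0 || group[j] < 0) e_cnt_dna += e; else e_dna_dna += e;
      if (want_grad) {
        const double f = (dvdr * sw + v * dswdr) / r; // dE/dr / r
        grad(i, 0) -= f * dx; grad(i, 1) -= f * dy; grad(i, 2) -= f * dz;
        grad(j, 0) += f * dx; grad(j, 1) += f * dy; grad(j, 2) += f * dz;
      }
    }
  }
  return List::create(_["cnt_dna"] = e_cnt_dna, _["dna_dna"] = e_dna_dna,
                      _["grad"] = grad);
}

// Same potential as nb_energy but evaluated over an explicit pair list.
// [[Rcpp::export(name = ".nb_energy_pairs")]]
List nb_energy_pairs(NumericMatrix coords, IntegerVector group,
                     NumericVector eps, NumericVector sigma,
                     NumericVector charge, double scale, double cutoff,
                     double r_on, IntegerVector pair_i, IntegerVector pair_j,
                     bool want_grad) {
  const int n = coords.nrow();
  const int m = pair_i.size();
  const double coul_k = 33.20636;
  const bool finite_cut = std::isfinite(cutoff);
  const double cut2 = finite_cut ? cutoff * cutoff : 0.0;
  const double ron2 = r_on * r_on;
  const double roff2 = cut2;
  const double denom = finite_cut
    ? (roff2 - ron2) * (roff2 - ron2) * (roff2 - ron2) : 1.0;
  bool any_charge = false;
  for (int i = 0; i < n; ++i) if (charge[i] != 0.0) { any_charge = true; break; }
  double e_cnt_dna = 0.0, e_dna_dna = 0.0;
  NumericMatrix grad(want_grad ? n : 1, 3);
  const double *x = &coords(0, 0), *y = &coords(0, 1), *z = &coords(0, 2);
  for (int p = 0; p < m; ++p) {
    const int i = pair_i[p], j = pair_j[p];
    const double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (finite_cut && r2 > cut2) continue;
    const double sig = 0.5 * (sigma[i] + sigma[j]);
    const double epsij = scale * std::sqrt(eps[i] * eps[j]);
    const double s2 = sig * sig / r2;
    const double s6 = s2 * s2 * s2;
    double v = 4.0 * epsij * s6 * (s6 - 1.0);
    const double r = std::sqrt(r2);
    double dvdr = -24.0 * epsij * s6 * (2.0 * s6 - 1.0) / r;
    if (any_charge && charge[i] != 0.0 && charge[j] != 0.0) {
      const double vc = coul_k * charge[i] * charge[j] / r;
      v += vc;
      dvdr += -vc / r;
    }
    double sw = 1.0, dswdr = 0.0;
    if (finite_cut && r2 > ron2) {
      const double a = roff2 - r2;
      sw = a * a * (roff2 + 2.0 * r2 - 3.0 * ron2) / denom;
      dswdr = (2.0 * a * (-2.0 * r) * (roff2 + 2.0 * r2 - 3.0 * ron2) +
               a * a * 4.0 * r) / denom;
    }
    const double e = v * sw;
    if (group[i] < 0 || group[j] < 0) e_cnt_dna += e; else e_dna_dna += e;
    if (want_grad) {
      const double f = (dvdr * sw + v * dswdr) / r;
      grad(i, 0) -= f * dx; grad(i, 1) -= f * dy; grad(i, 2) -= f * dz;
      grad(j, 0) += f * dx; grad(j, 1) += f * dy; grad(j, 2) += f * dz;
    }
  }
  return List::create(_["cnt_dna"] = e_cnt_dna, _["dna_dna"] = e_dna_dna,
                      _["grad"] = grad);
}

// Harmonic distance restraints sum k (r - r0)^2; k in kcal/mol/nm^2.
// [[Rcpp::export(name = ".restraint_energy")]]
List restraint_energy(NumericMatrix coords, IntegerVector pi, IntegerVector pj,
                      NumericVector r0, NumericVector k, bool want_grad) {
  const int m = pi.size();
  const int n = coords.nrow();
  double e = 0.0;
  NumericMatrix grad(want_grad ? n : 1, 3);
  const double *x = &coords(0, 0), *y = &coords(0, 1), *z = &coords(0, 2);
  for (int p = 0; p < m; ++p) {
    const int i = pi[p], j = pj[p];
    const double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) r = 1e-12;
    const double d = r - r0[p];
    e += k[p] * d * d;
    if (want_grad) {
      const double f = 2.0 * k[p] * d / r;
      grad(i, 0) -= f * dx; grad(i, 1) -= f * dy; grad(i, 2) -= f * dz;
      grad(j, 0) += f * dx; grad(j, 1) += f * dy; grad(j, 2) += f * dz;
    }
  }
  return List::create(_["energy"] = e, _["grad"] = grad);
}

// Grayscale morphological dilation of a height field by a tip profile:
// out(p) = max_s [ h(p + s) - tip(s) ], where tip(s) >= 0 is the depth of
// the (inverted) tip surface at lateral offset s from the apex. The tip is
// supplied as a stencil of integer pixel offsets with their depths.
// [[Rcpp::export(name = ".dilate_height")]]
NumericMatrix dilate_height(NumericMatrix h, IntegerVector off_r,
                            IntegerVector off_c, NumericVector depth) {
  const int nr = h.nrow(), nc = h.ncol(), m = off_r.size();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double best = R_NegInf;
      for (int k = 0; k < m; ++k) {
        const int rr = r + off_r[k], cc = c + off_c[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const double v = h(rr, cc) - depth[k];
        if (v > best) best = v;
      }
      out(r, c) = best;
    }
  }
  return out;
}
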