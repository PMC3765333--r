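#include <Rcpp.h>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

// Maternal haplotype / sire-gamete index coding: 0 = TM, 1 = Tm, 2 = tM, 3 = tm.
// Bit 2 (h >> 1) is the first-locus allele (0 = T), bit 1 (h & 1) the second
// (0 = M).  Offspring genotype classes are ordered TTMM, TTMm, TTmm, TtMM,
// TtMm, Ttmm, ttMM, ttMm, ttmm, i.e. class = 3*(#t alleles) + (#m alleles).

static inline int hap_t(int h) { return h >> 1; }
static inline int hap_m(int h) { return h & 1; }

// The four sire gamete slots for a sire carrying haplotypes h1/h2:
// slot 0 = h1 intact, slot 1 = h2 intact (probability (1-c)/2 each),
// slot 2 = first-locus allele of h1 with second-locus allele of h2,
// slot 3 = the reciprocal recombinant (probability c/2 each).
static void sire_slots(int h1, int h2, int slots[4]) {
  slots[0] = h1;
  slots[1] = h2;
  slots[2] = 2 * hap_t(h1) + hap_m(h2);
  slots[3] = 2 * hap_t(h2) + hap_m(h1);
}

// Accumulate the 9 offspring-class probabilities from the 16 latent cells
// (sire gamete slot x maternal haplotype).
static void class_probs_cells(int h1, int h2, const double f[4], double c,
                              double phi[9]) {
  int slots[4];
  sire_slots(h1, h2, slots);
  double pg[4] = {0.5 * (1.0 - c), 0.5 * (1.0 - c), 0.5 * c, 0.5 * c};
  for (int j = 0; j < 9; j++) phi[j] = 0.0;
  for (int s = 0; s < 4; s++) {
    int g = slots[s];
    for (int m = 0; m < 4; m++) {
      int cls = 3 * (hap_t(g) + hap_t(m)) + (hap_m(g) + hap_m(m));
      phi[cls] += pg[s] * f[m];
    }
  }
}

static double loglik_from_probs(const double n[9], const double phi[9]) {
  double ll = 0.0;
  for (int j = 0; j < 9; j++) {
    if (n[j] > 0.0) {
      if (phi[j] <= 0.0) return R_NegInf;
      ll += n[j] * std::log(phi[j]);
    }
  }
  return ll;
}

// One E-step at the supplied parameters: expected maternal-haplotype
// fractions, expected recombinant-gamete fraction, and the observed-data
// log-likelihood at (f, c).
static double estep(const double n[9], int h1, int h2, const double f[4],
                    double c, double fnew[4], double *cnew) {
  int slots[4];
  sire_slots(h1, h2, slots);
  double pg[4] = {0.5 * (1.0 - c), 0.5 * (1.0 - c), 0.5 * c, 0.5 * c};
  double denom[9];
  for (int j = 0; j < 9; j++) denom[j] = 0.0;
  double w[16];
  int cls16[16];
  int k = 0;
  for (int s = 0; s < 4; s++) {
    int g = slots[s];
    for (int m = 0; m < 4; m++, k++) {
      int cls = 3 * (hap_t(g) + hap_t(m)) + (hap_m(g) + hap_m(m));
      cls16[k] = cls;
      w[k] = pg[s] * f[m];
      denom[cls] += w[k];
    }
  }
  double N = 0.0, ll = 0.0;
  for (int j = 0; j < 9; j++) {
    N += n[j];
    if (n[j] > 0.0) {
      if (denom[j] <= 0.0) return R_NegInf;
      ll += n[j] * std::log(denom[j]);
    }
  }
  for (int m = 0; m < 4; m++) fnew[m] = 0.0;
  double R = 0.0;
  k = 0;
  for (int s = 0; s < 4; s++) {
    for (int m = 0; m < 4; m++, k++) {
      int cls = cls16[k];
      if (n[cls] > 0.0 && denom[cls] > 0.0) {
        double e = n[cls] * w[k] / denom[cls];
        fnew[m] += e;
        if (s >= 2) R += e;
      }
    }
  }
  if (N > 0.0) {
    for (int m = 0; m < 4; m++) fnew[m] /= N;
    R /= N;
  }
  *cnew = R;
  return ll;
}

// [[Rcpp::export(name = ".em_fit_cpp")]]
List em_fit_cpp(NumericVector n, int h1, int h2, NumericVector f0, double c0,
                double tol, int maxit, bool estimate_c, bool constrain_le) {
  double nn[9];
  for (int j = 0; j < 9; j++) nn[j] = n[j];
  double f[4] = {f0[0], f0[1], f0[2], f0[3]};
  double c = c0;
  double ll_prev = R_NegInf;
  bool converged = false, monotone = true;
  int iter = 0;
  double ll = R_NegInf;
  for (iter = 1; iter <= maxit; iter++) {
    double fnew[4], cnew;
    ll = estep(nn, h1, h2, f, c, fnew, &cnew);
    if (!R_FINITE(ll)) break;  // current params give zero prob to observed data
    if (ll < ll_prev - 1e-8 * (1.0 + std::fabs(ll_prev))) monotone = false;
    ll_prev = ll;
    if (!estimate_c) cnew = c;
    if (cnew < 0.0) cnew = 0.0;
    if (cnew > 0.5) cnew = 0.5;
    if (constrain_le) {
      double fT = fnew[0] + fnew[1];
      double fM = fnew[0] + fnew[2];
      fnew[0] = fT * fM;
      fnew[1] = fT * (1.0 - fM);
      fnew[2] = (1.0 - fT) * fM;
      fnew[3] = (1.0 - fT) * (1.0 - fM);
    }
    double delta = std::fabs(cnew - c);
    for (int m = 0; m < 4; m++) {
      double d = std::fabs(fnew[m] - f[m]);
      if (d > delta) delta = d;
    }
    for (int m = 0; m < 4; m++) f[m] = fnew[m];
    c = cnew;
    if (delta < tol) { converged = true; break; }
  }
  // log-likelihood at the returned parameters
  double phi[9];
  class_probs_cells(h1, h2, f, c, phi);
  ll = loglik_from_probs(nn, phi);
  return List::create(_["f"] = NumericVector::create(f[0], f[1], f[2], f[3]),
                      _["c"] = c, _["loglik"] = ll, _["n_iter"] = iter,
                      _["converged"] = converged, _["monotone"] = monotone);
}

// [[Rcpp::export(name = ".em_estep_cpp")]]
List em_estep_cpp(NumericVector n, int h1, int h2, NumericVector f, double c) {
  double nn[9];
  for (int j = 0; j < 9; j++) nn[j] = n[j];
  double ff[4] = {f[0], f[1], f[2], f[3]};
  double fnew[4], cnew;
  double ll = estep(nn, h1, h2, ff, c, fnew, &cnew);
  return List::create(
      _["f_i"] = NumericVector::create(fnew[0], fnew[1], fnew[2], fnew[3]),
      _["c_i"] = cnew, _["loglik"] = ll);
}

// ---------------------------------------------------------------------------
// Brute-force grid maximization of the half-sib pair likelihood.  This is an
// independent implementation path: the nine class probabilities are written
// out directly as the Table-6 cell sums for the coupling phase (repulsion is
// the same expressions with c replaced by 1-c), not via the latent-cell
// enumeration the EM uses.
// ---------------------------------------------------------------------------

static double loglik_direct(const double n[9], double c, double fT, double fM,
                            double delta) {
  double ft = 1.0 - fT, fm = 1.0 - fM;
  double fTM = delta + fT * fM;
  double fTm = -delta + fT * fm;
  double ftM = -delta + ft * fM;
  double ftm = delta + ft * fm;
  if (fTM < 0.0 || fTm < 0.0 || ftM < 0.0 || ftm < 0.0) return R_NegInf;
  double phi[9];
  phi[0] = 0.5 * (1 - c) * fTM;
  phi[1] = 0.5 * (1 - c) * fTm + 0.5 * c * fTM;
  phi[2] = 0.5 * c * fTm;
  phi[3] = 0.5 * (1 - c) * ftM + 0.5 * c * fTM;
  phi[4] = 0.5 * (1 - c) * (ftm + fTM) + 0.5 * c * (ftM + fTm);
  phi[5] = 0.5 * (1 - c) * fTm + 0.5 * c * ftm;
  phi[6] = 0.5 * c * ftM;
  phi[7] = 0.5 * (1 - c) * ftM + 0.5 * c * ftm;
  phi[8] = 0.5 * (1 - c) * ftm;
  return loglik_from_probs(n, phi);
}

// [[Rcpp::export(name = ".grid_search_cpp")]]
List grid_search_cpp(NumericVector n, bool coupling, double step, int refine) {
  double nn[9];
  for (int j = 0; j < 9; j++) {
    nn[j] = n[j];
    if (!coupling) nn[j] = n[j];
  }
  // repulsion phase: evaluate coupling expressions at 1-c, report c
  double c_lo = 0.0, c_hi = 0.5;
  double fT_lo = step, fT_hi = 1.0 - step;
  double fM_lo = step, fM_hi = 1.0 - step;
  bool have_d_range = false;
  double d_lo0 = 0.0, d_hi0 = 0.0;  // refined delta window (around incumbent)
  double best_ll = R_NegInf, best_c = 0.0, best_fT = 0.5, best_fM = 0.5,
         best_d = 0.0;
  double st = step;
  for (int level = 0; level <= refine; level++) {
    int nc = (int)std::floor((c_hi - c_lo) / st + 1e-9) + 1;
    int nT = (int)std::floor((fT_hi - fT_lo) / st + 1e-9) + 1;
    int nM = (int)std::floor((fM_hi - fM_lo) / st + 1e-9) + 1;
    for (int ic = 0; ic < nc; ic++) {
      double c = c_lo + ic * st;
      double ceval = coupling ? c : 1.0 - c;
      for (int iT = 0; iT < nT; iT++) {
        double fT = fT_lo + iT * st;
        for (int iM = 0; iM < nM; iM++) {
          double fM = fM_lo + iM * st;
          double ft = 1.0 - fT, fm = 1.0 - fM;
          double dmin = std::max(-fT * fM, -ft * fm);
          double dmax = std::min(fT * fm, ft * fM);
          if (have_d_range) {
            if (d_lo0 > dmin) dmin = d_lo0;
            if (d_hi0 < dmax) dmax = d_hi0;
            if (dmin > dmax) continue;
          }
          int nd = (int)std::floor((dmax - dmin) / st + 1e-9) + 1;
          for (int id = 0; id <= nd; id++) {
            double d = (id == nd) ? dmax : dmin + id * st;
            double ll = loglik_direct(nn, ceval, fT, fM, d);
            if (ll > best_ll) {
              best_ll = ll; best_c = c; best_fT = fT; best_fM = fM; best_d = d;
            }
          }
        }
      }
    }
    // shrink the window around the incumbent and refine the lattice
    c_lo = std::max(0.0, best_c - st);
    c_hi = std::min(0.5, best_c + st);
    fT_lo = std::max(1e-6, best_fT - st);
    fT_hi = std::min(1.0 - 1e-6, best_fT + st);
    fM_lo = std::max(1e-6, best_fM - st);
    fM_hi = std::min(1.0 - 1e-6, best_fM + st);
    d_lo0 = best_d - st;
    d_hi0 = best_d + st;
    have_d_range = true;
    st /= 10.0;
  }
  return List::create(_["c"] = best_c, _["f_T"] = best_fT, _["f_M"] = best_fM,
                      _["delta"] = best_d, _["loglik"] = best_ll);
}
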