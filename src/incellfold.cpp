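#include <Rcpp.h>
using namespace Rcpp;

// Sequential internal-to-Cartesian (NeRF) placement.
// refA/refB/refC are 0-based indices of previously placed atoms (a-b-c-d
// dihedral chain, c = bonding parent); -1 flags the canonical seed atoms:
// atom 0 at the origin, atom 1 on +x, atom 2 in the xy-plane.
// theta = bond angle b-c-d, tor = a-b-c-d dihedral (radians); for atom i the
// dihedral used is tor0[i] + angles[dof[i]] when dof[i] >= 0.
// [[Rcpp::export]]
NumericMatrix nerf_build_cpp(IntegerVector refA, IntegerVector refB,
                             IntegerVector refC, NumericVector bond,
                             NumericVector theta, NumericVector tor0,
                             IntegerVector dof, NumericVector angles) {
  const int n = refA.size();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double tor = tor0[i];
    if (dof[i] >= 0) tor += angles[dof[i]];
    if (refC[i] < 0) {              // first atom
      out(i, 0) = 0.0; out(i, 1) = 0.0; out(i, 2) = 0.0;
      continue;
    }
    double C[3] = { out(refC[i], 0), out(refC[i], 1), out(refC[i], 2) };
    if (refB[i] < 0) {              // second atom: along +x from atom 0
      out(i, 0) = C[0] + bond[i]; out(i, 1) = C[1]; out(i, 2) = C[2];
      continue;
    }
    double B[3] = { out(refB[i], 0), out(refB[i], 1), out(refB[i], 2) };
    double A[3];
    if (refA[i] < 0) {  // third atom: virtual reference keeps it in the
                        // xy-plane of the canonical frame
      A[0] = B[0]; A[1] = B[1] + 1.0; A[2] = B[2];
    } else {
      A[0] = out(refA[i], 0); A[1] = out(refA[i], 1); A[2] = out(refA[i], 2);
    }
    double ab[3] = { B[0] - A[0], B[1] - A[1], B[2] - A[2] };
    double bc[3] = { C[0] - B[0], C[1] - B[1], C[2] - B[2] };
    double nbc = std::sqrt(bc[0] * bc[0] + bc[1] * bc[1] + bc[2] * bc[2]);
    for (int k = 0; k < 3; ++k) bc[k] /= nbc;
    double nv[3] = { ab[1] * bc[2] - ab[2] * bc[1],
                     ab[2] * bc[0] - ab[0] * bc[2],
                     ab[0] * bc[1] - ab[1] * bc[0] };
    double nn = std::sqrt(nv[0] * nv[0] + nv[1] * nv[1] + nv[2] * nv[2]);
    for (int k = 0; k < 3; ++k) nv[k] /= nn;
    double mv[3] = { nv[1] * bc[2] - nv[2] * bc[1],
                     nv[2] * bc[0] - nv[0] * bc[2],
                     nv[0] * bc[1] - nv[1] * bc[0] };
    double d0 = -bond[i] * std::cos(theta[i]);
    double d1 = bond[i] * std::sin(theta[i]) * std::cos(tor);
    double d2 = -bond[i] * std::sin(theta[i]) * std::sin(tor);
    out(i, 0) = C[0] + d0 * bc[0] + d1 * mv[0] + d2 * nv[0];
    out(i, 1) = C[1] + d0 * bc[1] + d1 * mv[1] + d2 * nv[1];
    out(i, 2) = C[2] + d0 * bc[2] + d1 * mv[2] + d2 * nv[2];
  }
  return out;
}

// Soft-sphere repulsion over a precomputed nonbonded pair list:
// sum over pairs of max(0, rmin_ij - r_ij)^2 (pair indices 0-based).
// [[Rcpp::export]]
double repulsion_cpp(NumericMatrix xyz, IntegerVector pi_, IntegerVector pj_,
                     NumericVector rmin) {
  const int m = pi_.size();
  double e = 0.0;
  for (int k = 0; k < m; ++k) {
    int i = pi_[k], j = pj_[k];
    double dx = xyz(i, 0) - xyz(j, 0);
    double dy = xyz(i, 1) - xyz(j, 1);
    double dz = xyz(i, 2) - xyz(j, 2);
    double r2 = dx * dx + dy * dy + dz * dz;
    double rm = rmin[k];
    if (r2 < rm * rm) {
      double d = rm - std::sqrt(r2);
      e += d * d;
    }
  }
  return e;
}

// r^-6-summed effective distance per restraint group:
// r_eff = (sum over options r^-6)^(-1/6).  oi/oj: 0-based atom indices per
// option; grp: 0-based group id per option (groups need not be contiguous
// but must lie in [0, ngroup)).
// [[Rcpp::export]]
NumericVector reff_cpp(NumericMatrix xyz, IntegerVector oi, IntegerVector oj,
                       IntegerVector grp, int ngroup) {
  NumericVector acc(ngroup, 0.0);
  const int m = oi.size();
  for (int k = 0; k < m; ++k) {
    int i = oi[k], j = oj[k];
    double dx = xyz(i, 0) - xyz(j, 0);
    double dy = xyz(i, 1) - xyz(j, 1);
    double dz = xyz(i, 2) - xyz(j, 2);
    double r2 = dx * dx + dy * dy + dz * dz;
    acc[grp[k]] += 1.0 / (r2 * r2 * r2);
  }
  NumericVector out(ngroup);
  for (int g = 0; g < ngroup; ++g)
    out[g] = (acc[g] > 0.0) ? std::pow(acc[g], -1.0 / 6.0) : R_PosInf;
  return out;
}

// All pairwise distances between two 0-based index sets (used by the NOE
// simulator's brute-force proton-pair scan).
// [[Rcpp::export]]
NumericVector pair_dist_cpp(NumericMatrix xyz, IntegerVector ii,
                            IntegerVector jj) {
  const int m = ii.size();
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    double dx = xyz(ii[k], 0) - xyz(jj[k], 0);
    double dy = xyz(ii[k], 1) - xyz(jj[k], 1);
    double dz = xyz(ii[k], 2) - xyz(jj[k], 2);
    out[k] = std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  return out;
}

// ---- internal helpers shared by the Monte Carlo kernels ----------------

namespace {

struct Model {
  // atom plan
  const int *refA, *refB, *refC;
  const double *bond, *theta, *tor0;
  const int *dof;
  int n_atoms;
  // nonbonded pairs
  const int *pi, *pj; const double *rmin; int n_pairs;
  // restraints (per option) and per-group data
  const int *oi, *oj, *grp; int n_opt, n_grp;
  const double *upper, *lower;
  // dihedral restraints
  const int *aco_dof; const double *aco_lo, *aco_hi; int n_aco;
  double dihedral_weight;
  // prior parameters
  double k_rep, k_tor;
  int n_dof;
};

inline double wrapdeg(double a) {
  a -= 360.0 * std::floor(a / 360.0 + 0.5);  // [-180, 180)
  if (a <= -180.0) a += 360.0;
  return a;
}

void build_coords(const Model &m, const double *angles_deg, double *xyz) {
  const double D2R = M_PI / 180.0;
  for (int i = 0; i < m.n_atoms; ++i) {
    double tor = m.tor0[i];
    if (m.dof[i] >= 0) tor += angles_deg[m.dof[i]] * D2R;
    if (m.refC[i] < 0) { xyz[3*i]=0; xyz[3*i+1]=0; xyz[3*i+2]=0; continue; }
    const double *C = xyz + 3 * m.refC[i];
    if (m.refB[i] < 0) {
      xyz[3*i] = C[0] + m.bond[i]; xyz[3*i+1] = C[1]; xyz[3*i+2] = C[2];
      continue;
    }
    const double *B = xyz + 3 * m.refB[i];
    double A[3];
    if (m.refA[i] < 0) { A[0]=B[0]; A[1]=B[1]+1.0; A[2]=B[2]; }
    else { const double *Ap = xyz + 3 * m.refA[i];
           A[0]=Ap[0]; A[1]=Ap[1]; A[2]=Ap[2]; }
    double ab[3] = {B[0]-A[0], B[1]-A[1], B[2]-A[2]};
    double bc[3] = {C[0]-B[0], C[1]-B[1], C[2]-B[2]};
    double nbc = std::sqrt(bc[0]*bc[0]+bc[1]*bc[1]+bc[2]*bc[2]);
    bc[0]/=nbc; bc[1]/=nbc; bc[2]/=nbc;
    double nv[3] = {ab[1]*bc[2]-ab[2]*bc[1], ab[2]*bc[0]-ab[0]*bc[2],
                    ab[0]*bc[1]-ab[1]*bc[0]};
    double nn = std::sqrt(nv[0]*nv[0]+nv[1]*nv[1]+nv[2]*nv[2]);
    nv[0]/=nn; nv[1]/=nn; nv[2]/=nn;
    double mv[3] = {nv[1]*bc[2]-nv[2]*bc[1], nv[2]*bc[0]-nv[0]*bc[2],
                    nv[0]*bc[1]-nv[1]*bc[0]};
    double ct = std::cos(m.theta[i]), st = std::sin(m.theta[i]);
    double d0 = -m.bond[i]*ct, d1 = m.bond[i]*st*std::cos(tor),
           d2 = -m.bond[i]*st*std::sin(tor);
    xyz[3*i]   = C[0] + d0*bc[0] + d1*mv[0] + d2*nv[0];
    xyz[3*i+1] = C[1] + d0*bc[1] + d1*mv[1] + d2*nv[1];
    xyz[3*i+2] = C[2] + d0*bc[2] + d1*mv[2] + d2*nv[2];
  }
}

double repulsion(const Model &m, const double *xyz) {
  double e = 0.0;
  for (int k = 0; k < m.n_pairs; ++k) {
    const double *a = xyz + 3*m.pi[k], *b = xyz + 3*m.pj[k];
    double dx=a[0]-b[0], dy=a[1]-b[1], dz=a[2]-b[2];
    double r2 = dx*dx+dy*dy+dz*dz, rm = m.rmin[k];
    if (r2 < rm*rm) { double d = rm - std::sqrt(r2); e += d*d; }
  }
  return e;
}

void reff_groups(const Model &m, const double *xyz, double *reff) {
  for (int g = 0; g < m.n_grp; ++g) reff[g] = 0.0;
  for (int k = 0; k < m.n_opt; ++k) {
    const double *a = xyz + 3*m.oi[k], *b = xyz + 3*m.oj[k];
    double dx=a[0]-b[0], dy=a[1]-b[1], dz=a[2]-b[2];
    double r2 = dx*dx+dy*dy+dz*dz;
    reff[m.grp[k]] += 1.0/(r2*r2*r2);
  }
  for (int g = 0; g < m.n_grp; ++g)
    reff[g] = std::pow(reff[g], -1.0/6.0);
}

double torsion_energy(const Model &m, const double *angles_deg) {
  const double D2R = M_PI / 180.0;
  double e = 0.0;
  for (int k = 0; k < m.n_dof; ++k)
    e += 1.0 + std::cos(3.0 * angles_deg[k] * D2R);
  return e;
}

double aco_term(const Model &m, const double *angles_deg) {
  double e = 0.0;
  for (int k = 0; k < m.n_aco; ++k) {
    double a = angles_deg[m.aco_dof[k]];
    double lo = m.aco_lo[k], hi = m.aco_hi[k];
    if (a >= lo && a <= hi) continue;
    double dlo = std::fabs(wrapdeg(a - lo)), dhi = std::fabs(wrapdeg(a - hi));
    double v = dlo < dhi ? dlo : dhi;
    e += m.dihedral_weight * v * v;
  }
  return e;
}

// restraint target function (distance + dihedral violations)
double target_fn(const Model &m, const double *reff) {
  double t = 0.0;
  for (int g = 0; g < m.n_grp; ++g) {
    if (reff[g] > m.upper[g]) { double v = reff[g]-m.upper[g]; t += v*v; }
    if (reff[g] < m.lower[g]) { double v = m.lower[g]-reff[g]; t += v*v; }
  }
  return t;
}

Model model_from(List plan, List pairs, List rest, List aco,
                 double k_rep, double k_tor, double dihedral_weight) {
  Model m;
  IntegerVector refA = plan["refA"], refB = plan["refB"], refC = plan["refC"],
                dof = plan["dof"];
  NumericVector bond = plan["bond"], theta = plan["angle"], tor0 = plan["tor0"];
  m.refA = INTEGER(refA); m.refB = INTEGER(refB); m.refC = INTEGER(refC);
  m.dof = INTEGER(dof);
  m.bond = REAL(bond); m.theta = REAL(theta); m.tor0 = REAL(tor0);
  m.n_atoms = refA.size();
  IntegerVector pi_ = pairs["i"], pj_ = pairs["j"];
  NumericVector rmin = pairs["rmin"];
  m.pi = INTEGER(pi_); m.pj = INTEGER(pj_); m.rmin = REAL(rmin);
  m.n_pairs = pi_.size();
  IntegerVector oi = rest["oi"], oj = rest["oj"], grp = rest["grp"];
  NumericVector up = rest["upper"], lo = rest["lower"];
  m.oi = INTEGER(oi); m.oj = INTEGER(oj); m.grp = INTEGER(grp);
  m.upper = REAL(up); m.lower = REAL(lo);
  m.n_opt = oi.size(); m.n_grp = as<int>(rest["ngroup"]);
  IntegerVector adof = aco["dof"];
  NumericVector alo = aco["lo"], ahi = aco["hi"];
  m.aco_dof = INTEGER(adof); m.aco_lo = REAL(alo); m.aco_hi = REAL(ahi);
  m.n_aco = adof.size();
  m.dihedral_weight = dihedral_weight;
  m.k_rep = k_rep; m.k_tor = k_tor;
  m.n_dof = 0;
  for (int i = 0; i < m.n_atoms; ++i)
    if (m.dof[i] + 1 > m.n_dof) m.n_dof = m.dof[i] + 1;
  return m;
}

} // namespace

// Simulated-annealing chain: single-torsion Metropolis on
// target + prior_weight * (k_rep * repulsion + k_tor * torsion term),
// geometric schedules supplied as per-step vectors.  Uses R's RNG.
// [[Rcpp::export]]
List anneal_chain_cpp(List plan, List pairs, List rest, List aco,
                      NumericVector angles0, NumericVector temps,
                      NumericVector widths, double k_rep, double k_tor,
                      double prior_weight, double dihedral_weight,
                      int n_dof_total) {
  Model m = model_from(plan, pairs, rest, aco, k_rep, k_tor,
                       dihedral_weight);
  m.n_dof = n_dof_total;
  int n_steps = temps.size();
  std::vector<double> ang(angles0.begin(), angles0.end());
  std::vector<double> xyz(3 * m.n_atoms), reff(std::max(m.n_grp, 1));
  auto eval = [&](const double *a, double &target, double &prior) {
    build_coords(m, a, xyz.data());
    if (m.n_grp > 0) reff_groups(m, xyz.data(), reff.data());
    target = (m.n_grp > 0 ? target_fn(m, reff.data()) : 0.0) +
             aco_term(m, a);
    prior = m.k_rep * repulsion(m, xyz.data()) +
            m.k_tor * torsion_energy(m, a);
  };
  double target, prior;
  eval(ang.data(), target, prior);
  double obj = target + prior_weight * prior;
  std::vector<double> best = ang;
  double best_target = target, best_obj = obj;
  int n_accept = 0;
  for (int s = 0; s < n_steps; ++s) {
    int k = (int)(R::unif_rand() * m.n_dof);
    if (k >= m.n_dof) k = m.n_dof - 1;
    double old = ang[k];
    ang[k] = wrapdeg(old + R::norm_rand() * widths[s]);
    double t2, p2;
    eval(ang.data(), t2, p2);
    double obj2 = t2 + prior_weight * p2;
    if (obj2 <= obj || R::unif_rand() < std::exp((obj - obj2) / temps[s])) {
      obj = obj2; target = t2; prior = p2;
      ++n_accept;
      if (t2 < best_target || (t2 <= best_target && obj2 < best_obj)) {
        best = ang; best_target = t2; best_obj = obj2;
      }
    } else {
      ang[k] = old;
    }
  }
  double bp, bt;
  eval(best.data(), bt, bp);
  return List::create(_["angles"] = NumericVector(best.begin(), best.end()),
                      _["target"] = best_target, _["prior"] = bp,
                      _["accept_rate"] = (double)n_accept / n_steps);
}

// A batch of tempered Metropolis torsion moves for one replica of the
// Bayesian refinement.  The state's log-posterior core is
//   loglik(reff; c, sigma) - E_prior   (nuisance priors are constant here
// and added at the R level).  Returns the updated angles, core
// log-posterior, per-group effective distances and acceptance count.
// [[Rcpp::export]]
List rexmc_batch_cpp(List plan, List pairs, List rest, List aco,
                     NumericVector angles0, NumericVector logI,
                     IntegerVector spec_of_group, NumericVector c_s,
                     NumericVector sigma_s, int n_inner, double beta,
                     double width, double cprob, double cwidth,
                     double k_rep, double k_tor, double dihedral_weight,
                     int n_dof_total) {
  Model m = model_from(plan, pairs, rest, aco, k_rep, k_tor,
                       dihedral_weight);
  m.n_dof = n_dof_total;
  std::vector<double> ang(angles0.begin(), angles0.end());
  std::vector<double> xyz(3 * m.n_atoms), reff(std::max(m.n_grp, 1)),
      reff_prop(std::max(m.n_grp, 1));
  auto core_lp = [&](const double *a, double *rf) {
    build_coords(m, a, xyz.data());
    double lp = -(m.k_rep * repulsion(m, xyz.data()) +
                  m.k_tor * torsion_energy(m, a) + aco_term(m, a));
    if (m.n_grp > 0) {
      reff_groups(m, xyz.data(), rf);
      for (int g = 0; g < m.n_grp; ++g) {
        int s = spec_of_group[g];
        double mu = c_s[s] - 6.0 * std::log(rf[g]);
        double r = logI[g] - mu;
        lp += -r * r / (2.0 * sigma_s[s] * sigma_s[s]) -
              std::log(sigma_s[s]);
      }
    }
    return lp;
  };
  double lp = core_lp(ang.data(), reff.data());
  int n_accept = 0;
  std::vector<double> prop(ang.size());
  for (int s = 0; s < n_inner; ++s) {
    prop = ang;
    if (R::unif_rand() < cprob) {
      for (int k = 0; k < m.n_dof; ++k)
        prop[k] = wrapdeg(prop[k] + R::norm_rand() * cwidth);
    } else {
      int k = (int)(R::unif_rand() * m.n_dof);
      if (k >= m.n_dof) k = m.n_dof - 1;
      prop[k] = wrapdeg(prop[k] + R::norm_rand() * width);
    }
    double lp2 = core_lp(prop.data(), reff_prop.data());
    if (std::log(R::unif_rand()) < beta * (lp2 - lp)) {
      ang.swap(prop); reff.swap(reff_prop); lp = lp2;
      ++n_accept;
    }
  }
  return List::create(_["angles"] = NumericVector(ang.begin(), ang.end()),
                      _["core_lp"] = lp,
                      _["reff"] = NumericVector(reff.begin(), reff.end()),
                      _["n_accept"] = n_accept);
}
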