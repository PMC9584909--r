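// Cartesian simulated annealing of a multi-state model against the
// target function (upper/lower limits with r^-6 state averaging,
// flat-bottom symmetry restraints, Karplus coupling restraints) plus
// harmonic reference bonds. Metropolis moves perturb one atom of one
// state; energy differences are evaluated incrementally from per-atom
// adjacency lists. Randomness comes from R's RNG so set.seed() in R
// makes runs bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  int natoms, nstates;
  std::vector<double> x; // natoms*3*nstates, atom-major within state
  double &at(int a, int k, int s) { return x[(s * natoms + a) * 3 + k]; }
  double dist(int a, int b, int s) const {
    const double *pa = &x[(s * natoms + a) * 3];
    const double *pb = &x[(s * natoms + b) * 3];
    double dx = pa[0] - pb[0], dy = pa[1] - pb[1], dz = pa[2] - pb[2];
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  }
};

struct Problem {
  IntegerVector di, dj;            // distance restraints (0-based)
  NumericVector dup, dlo;          // limits
  NumericVector w;                 // state weights
  IntegerVector ca1, ca2, ca3, ca4; // couplings
  NumericVector ctar, cA, cB, cC, ctol;
  double w_coupling;
  IntegerVector sym_atoms;         // 0-based atoms under symmetry restraint
  std::vector<char> is_sym;        // per-atom flag
  double sym_width, sym_weight;
  IntegerVector bi, bj; NumericVector br0; double w_bond;
  std::vector<std::vector<int>> a2d, a2c, a2b; // adjacency
};

double dist_term(const Problem &p, const Model &m, int r) {
  double inv6 = 0.0;
  for (int s = 0; s < m.nstates; ++s) {
    double d = m.dist(p.di[r], p.dj[r], s);
    if (d < 1e-6) d = 1e-6;
    inv6 += p.w[s] * std::pow(d, -6.0);
  }
  double reff = std::pow(inv6, -1.0 / 6.0);
  double e = 0.0;
  if (reff > p.dup[r]) { double v = reff - p.dup[r]; e += v * v; }
  if (reff < p.dlo[r]) { double v = p.dlo[r] - reff; e += v * v; }
  return e;
}

double torsion_cos(const Model &m, int a, int b, int c, int d, int s) {
  double b1[3], b2[3], b3[3];
  for (int k = 0; k < 3; ++k) {
    b1[k] = m.x[(s * m.natoms + b) * 3 + k] - m.x[(s * m.natoms + a) * 3 + k];
    b2[k] = m.x[(s * m.natoms + c) * 3 + k] - m.x[(s * m.natoms + b) * 3 + k];
    b3[k] = m.x[(s * m.natoms + d) * 3 + k] - m.x[(s * m.natoms + c) * 3 + k];
  }
  double n1[3] = {b1[1] * b2[2] - b1[2] * b2[1],
                  b1[2] * b2[0] - b1[0] * b2[2],
                  b1[0] * b2[1] - b1[1] * b2[0]};
  double n2[3] = {b2[1] * b3[2] - b2[2] * b3[1],
                  b2[2] * b3[0] - b2[0] * b3[2],
                  b2[0] * b3[1] - b2[1] * b3[0]};
  double s1 = n1[0] * n1[0] + n1[1] * n1[1] + n1[2] * n1[2];
  double s2 = n2[0] * n2[0] + n2[1] * n2[1] + n2[2] * n2[2];
  double den = std::sqrt(s1 * s2);
  if (den < 1e-12) return 1.0;
  double ct = (n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2]) / den;
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

double coupling_term(const Problem &p, const Model &m, int r) {
  double j = 0.0;
  for (int s = 0; s < m.nstates; ++s) {
    double ct = torsion_cos(m, p.ca1[r], p.ca2[r], p.ca3[r], p.ca4[r], s);
    j += p.w[s] * (p.cA[r] * ct * ct + p.cB[r] * ct + p.cC[r]);
  }
  double v = std::fabs(j - p.ctar[r]) - p.ctol[r];
  return v > 0 ? p.w_coupling * v * v : 0.0;
}

double bond_term(const Problem &p, const Model &m, int r, int s) {
  double v = m.dist(p.bi[r], p.bj[r], s) - p.br0[r];
  return p.w_bond * v * v;
}

// symmetry energy of one atom against all state pairs involving state s,
// or (s < 0) over all state pairs
double sym_term_atom(const Problem &p, const Model &m, int a, int s) {
  if (!p.is_sym[a] || m.nstates < 2) return 0.0;
  double e = 0.0;
  for (int s1 = 0; s1 < m.nstates - 1; ++s1)
    for (int s2 = s1 + 1; s2 < m.nstates; ++s2) {
      if (s >= 0 && s1 != s && s2 != s) continue;
      double dx = 0.0;
      for (int k = 0; k < 3; ++k) {
        double d = m.x[(s1 * m.natoms + a) * 3 + k] -
                   m.x[(s2 * m.natoms + a) * 3 + k];
        dx += d * d;
      }
      double v = std::sqrt(dx) - p.sym_width;
      if (v > 0) e += p.sym_weight * v * v;
    }
  return e;
}

// energy of all terms touching atom a in state s
double local_energy(const Problem &p, const Model &m, int a, int s) {
  double e = 0.0;
  for (int r : p.a2d[a]) e += dist_term(p, m, r);
  for (int r : p.a2c[a]) e += coupling_term(p, m, r);
  for (int r : p.a2b[a]) e += bond_term(p, m, r, s);
  e += sym_term_atom(p, m, a, s);
  return e;
}

double total_energy(const Problem &p, const Model &m, double *parts) {
  double eu = 0.0;
  for (int r = 0; r < p.di.size(); ++r) eu += dist_term(p, m, r);
  double ec = 0.0;
  for (int r = 0; r < p.ca1.size(); ++r) ec += coupling_term(p, m, r);
  double eb = 0.0;
  for (int r = 0; r < p.bi.size(); ++r)
    for (int s = 0; s < m.nstates; ++s) eb += bond_term(p, m, r, s);
  double es = 0.0;
  for (int a = 0; a < m.natoms; ++a) es += sym_term_atom(p, m, a, -1);
  if (parts) { parts[0] = eu; parts[1] = ec; parts[2] = es; parts[3] = eb; }
  return eu + ec + es + eb;
}

Problem build_problem(int natoms, List restraints, NumericVector weights) {
  Problem p;
  p.di = restraints["di"]; p.dj = restraints["dj"];
  p.dup = restraints["dup"]; p.dlo = restraints["dlo"];
  p.w = weights;
  p.ca1 = restraints["ca1"]; p.ca2 = restraints["ca2"];
  p.ca3 = restraints["ca3"]; p.ca4 = restraints["ca4"];
  p.ctar = restraints["ctar"]; p.cA = restraints["cA"];
  p.cB = restraints["cB"]; p.cC = restraints["cC"];
  p.ctol = restraints["ctol"];
  p.w_coupling = as<double>(restraints["w_coupling"]);
  p.sym_atoms = restraints["sym_atoms"];
  p.sym_width = as<double>(restraints["sym_width"]);
  p.sym_weight = as<double>(restraints["sym_weight"]);
  p.bi = restraints["bi"]; p.bj = restraints["bj"];
  p.br0 = restraints["br0"];
  p.w_bond = as<double>(restraints["w_bond"]);
  p.is_sym.assign(natoms, 0);
  for (int k = 0; k < p.sym_atoms.size(); ++k) p.is_sym[p.sym_atoms[k]] = 1;
  p.a2d.assign(natoms, {}); p.a2c.assign(natoms, {}); p.a2b.assign(natoms, {});
  for (int r = 0; r < p.di.size(); ++r) {
    p.a2d[p.di[r]].push_back(r); p.a2d[p.dj[r]].push_back(r);
  }
  for (int r = 0; r < p.ca1.size(); ++r) {
    p.a2c[p.ca1[r]].push_back(r); p.a2c[p.ca2[r]].push_back(r);
    p.a2c[p.ca3[r]].push_back(r); p.a2c[p.ca4[r]].push_back(r);
  }
  for (int r = 0; r < p.bi.size(); ++r) {
    p.a2b[p.bi[r]].push_back(r); p.a2b[p.bj[r]].push_back(r);
  }
  return p;
}

} // namespace

// [[Rcpp::export(name = ".anneal_cpp")]]
List anneal_cpp(NumericVector coords0, int natoms, int nstates,
                List restraints, NumericVector weights,
                int nsteps, double t0, double t1,
                double step0, double step1) {
  Model m;
  m.natoms = natoms; m.nstates = nstates;
  m.x.assign(coords0.begin(), coords0.end());
  Problem p = build_problem(natoms, restraints, weights);

  double e = total_energy(p, m, nullptr);
  double ct = (nsteps > 1) ? std::pow(t1 / t0, 1.0 / (nsteps - 1)) : 1.0;
  double cs = (nsteps > 1) ? std::pow(step1 / step0, 1.0 / (nsteps - 1)) : 1.0;
  double T = t0, step = step0;
  int accepted = 0;

  for (int it = 0; it < nsteps; ++it) {
    int a = (int)(unif_rand() * natoms); if (a >= natoms) a = natoms - 1;
    int s = (int)(unif_rand() * nstates); if (s >= nstates) s = nstates - 1;
    double old_e = local_energy(p, m, a, s);
    double save[3];
    for (int k = 0; k < 3; ++k) {
      save[k] = m.at(a, k, s);
      m.at(a, k, s) = save[k] + step * norm_rand();
    }
    double de = local_energy(p, m, a, s) - old_e;
    if (de <= 0 || (T > 0 && unif_rand() < std::exp(-de / T))) {
      e += de; ++accepted;
    } else {
      for (int k = 0; k < 3; ++k) m.at(a, k, s) = save[k];
    }
    T *= ct; step *= cs;
  }

  double parts[4];
  double efin = total_energy(p, m, parts);
  return List::create(_["coords"] = NumericVector(m.x.begin(), m.x.end()),
                      _["energy"] = efin,
                      _["tf"] = parts[0] + parts[1] + parts[2],
                      _["terms"] = NumericVector::create(
                        _["distance"] = parts[0], _["coupling"] = parts[1],
                        _["symmetry"] = parts[2], _["bond"] = parts[3]),
                      _["accepted"] = accepted);
}

// numerical gradient from per-atom local energies (central differences);
// each coordinate only touches the terms in its atom's adjacency lists
// [[Rcpp::export(name = ".energy_grad_cpp")]]
List energy_grad_cpp(NumericVector coords, int natoms, int nstates,
                     List restraints, NumericVector weights, double h) {
  Model m;
  m.natoms = natoms; m.nstates = nstates;
  m.x.assign(coords.begin(), coords.end());
  Problem p = build_problem(natoms, restraints, weights);
  NumericVector grad(coords.size());
  for (int s = 0; s < nstates; ++s)
    for (int a = 0; a < natoms; ++a)
      for (int k = 0; k < 3; ++k) {
        double save = m.at(a, k, s);
        m.at(a, k, s) = save + h;
        double ep = local_energy(p, m, a, s);
        m.at(a, k, s) = save - h;
        double em = local_energy(p, m, a, s);
        m.at(a, k, s) = save;
        grad[(s * natoms + a) * 3 + k] = (ep - em) / (2.0 * h);
      }
  double parts[4];
  double e = total_energy(p, m, parts);
  return List::create(_["energy"] = e, _["grad"] = grad,
                      _["tf"] = parts[0] + parts[1] + parts[2]);
}

// [[Rcpp::export(name = ".energy_cpp")]]
List energy_cpp(NumericVector coords, int natoms, int nstates,
                List restraints, NumericVector weights) {
  Model m;
  m.natoms = natoms; m.nstates = nstates;
  m.x.assign(coords.begin(), coords.end());
  Problem p = build_problem(natoms, restraints, weights);
  double parts[4];
  double e = total_energy(p, m, parts);
  return List::create(_["energy"] = e,
                      _["tf"] = parts[0] + parts[1] + parts[2],
                      _["terms"] = NumericVector::create(
                        _["distance"] = parts[0], _["coupling"] = parts[1],
                        _["symmetry"] = parts[2], _["bond"] = parts[3]));
}
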