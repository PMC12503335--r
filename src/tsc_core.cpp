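#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <cmath>
#include <vector>
using namespace Rcpp;

// Core numerical kernels for the transcription-supercoiling coupling model.
// Geometry works on a circle of length L with genes as half-open intervals
// [begin, begin + length); orientation is +1 (forward, increasing
// coordinates) or -1 (reverse). The promoter of a forward gene sits at
// `begin`, that of a reverse gene at `begin + length`; the effect of gene j
// on the supercoiling at gene i's promoter is evaluated at the middle of
// gene j (the average polymerase position).

static inline double pos_mod(double x, double L) {
  double r = x - L * std::floor(x / L);
  if (r >= L) r -= L;  // guard the floor rounding edge
  if (r < 0.0) r = 0.0;
  return r;
}

// d(sigma_i)/d(e_j): signed coupling coefficient of the twin-domain model.
// Upstream + same strand -> +1, upstream + opposite -> -1, downstream signs
// reversed; magnitude c * max(1 - d/dmax, 0); exact antipodal tie -> 0.
static double coupling_coef(double begin_i, double len_i, int ori_i,
                            double begin_j, double len_j, int ori_j,
                            double L, double c, double dmax, bool circular) {
  double prom = (ori_i > 0) ? begin_i : begin_i + len_i;
  double mid = begin_j + 0.5 * len_j;
  double d;
  bool downstream;
  if (circular) {
    prom = pos_mod(prom, L);
    mid = pos_mod(mid, L);
    // arc length from the promoter to mid, walking in i's reading direction
    double fwd_arc = pos_mod(mid - prom, L);
    double down = (ori_i > 0) ? fwd_arc : pos_mod(prom - mid, L);
    double up = L - down;
    if (down == up) return 0.0;  // antipodal tie: no defined side
    if (down < up) {
      d = down;
      downstream = true;
    } else {
      d = up;
      downstream = false;
    }
  } else {
    // linear (non-circular) arrangement: used for contiguous subnetworks
    double off = (mid - prom) * ((ori_i > 0) ? 1.0 : -1.0);
    d = std::fabs(off);
    downstream = (off >= 0.0);
  }
  double w = 1.0 - d / dmax;
  if (w <= 0.0) return 0.0;
  bool same = (ori_i == ori_j);
  double eta;
  if (downstream)
    eta = same ? -1.0 : 1.0;
  else
    eta = same ? 1.0 : -1.0;
  return eta * c * w;
}

// [[Rcpp::export]]
NumericMatrix cpp_interaction_matrix(NumericVector begin, NumericVector len,
                                     IntegerVector ori, double L, double c,
                                     double dmax, bool circular) {
  int n = begin.size();
  NumericMatrix M(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;  // genes do not interact with themselves
      M(i, j) = coupling_coef(begin[i], len[i], ori[i], begin[j], len[j],
                              ori[j], L, c, dmax, circular);
    }
  }
  return M;
}

// Sparse (CSR) coupling structure; genomes are much longer than dmax so
// each gene only couples to a handful of neighbors.
struct Coupling {
  std::vector<int> ptr, idx;
  std::vector<double> val;
  int n;
};

static Coupling build_coupling(const double* begin, const double* len,
                               const int* ori, int n, double L, double c,
                               double dmax, bool circular) {
  Coupling S;
  S.n = n;
  S.ptr.assign(n + 1, 0);
  S.idx.reserve(16 * n);
  S.val.reserve(16 * n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      double v = coupling_coef(begin[i], len[i], ori[i], begin[j], len[j],
                               ori[j], L, c, dmax, circular);
      if (v != 0.0) {
        S.idx.push_back(j);
        S.val.push_back(v);
      }
    }
    S.ptr[i + 1] = (int)S.idx.size();
  }
  return S;
}

static inline double sigmoid_opening(double sigma, double sigma_half,
                                     double eps) {
  double z = (sigma - sigma_half) / eps;
  if (z > 700.0) return 0.0;  // saturate instead of overflowing exp()
  if (z < -700.0) return 1.0;
  return 1.0 / (1.0 + std::exp(z));
}

// One application of the expression update map G, and its max-norm
// residual ||G(e) - e||; knocked-out entries are held at 0.
static double apply_map(const Coupling& S, double sigma0, double sigma_half,
                        double eps, double m, const std::vector<char>& knocked,
                        const std::vector<double>& e,
                        std::vector<double>& out) {
  int n = S.n;
  double resid = 0.0;
  for (int i = 0; i < n; ++i) {
    if (knocked[i]) {
      out[i] = 0.0;
      continue;
    }
    double sigma = sigma0;
    for (int k = S.ptr[i]; k < S.ptr[i + 1]; ++k)
      sigma += S.val[k] * e[S.idx[k]];
    double U = sigmoid_opening(sigma, sigma_half, eps);
    out[i] = std::exp(m * (U - 1.0));
    double d = std::fabs(out[i] - e[i]);
    if (d > resid) resid = d;
  }
  return resid;
}

// Newton polish: solve G(e) - e = 0 directly with the analytic Jacobian.
// Used as a last resort when the damped substitution orbits a limit cycle
// around an unstable fixed point of the map: the equilibrium phenotype is
// defined as a solution of the equation system, and Newton converges to
// it regardless of the substitution dynamics' local stability. Returns
// true on success (residual < tol), with e updated in place.
static bool newton_polish(const Coupling& S, double sigma0, double sigma_half,
                          double eps, double m,
                          const std::vector<char>& knocked, double tol,
                          std::vector<double>& e) {
  int n = S.n;
  arma::mat A(n, n);
  arma::vec F(n), x(n);
  std::vector<double> ge(n);
  double resid = apply_map(S, sigma0, sigma_half, eps, m, knocked, e, ge);
  for (int pass = 0; pass < 50; ++pass) {
    if (resid < 0.5 * tol) return true;
    // Jacobian of G(e) - e
    A.zeros();
    for (int i = 0; i < n; ++i) {
      A(i, i) = -1.0;
      if (knocked[i]) continue;
      double sigma = sigma0;
      for (int k = S.ptr[i]; k < S.ptr[i + 1]; ++k)
        sigma += S.val[k] * e[S.idx[k]];
      double U = sigmoid_opening(sigma, sigma_half, eps);
      double gi = std::exp(m * (U - 1.0));
      double dUdS = -U * (1.0 - U) / eps;
      double pref = gi * m * dUdS;
      for (int k = S.ptr[i]; k < S.ptr[i + 1]; ++k) {
        if (knocked[S.idx[k]]) continue;
        A(i, S.idx[k]) += pref * S.val[k];
      }
      F(i) = ge[i] - e[i];
    }
    for (int i = 0; i < n; ++i)
      if (knocked[i]) F(i) = 0.0;
    bool ok = arma::solve(x, A, -F, arma::solve_opts::no_approx);
    if (!ok) return false;
    // backtracking line search on the residual
    double step = 1.0;
    std::vector<double> trial(n);
    for (int ls = 0; ls < 8; ++ls) {
      for (int i = 0; i < n; ++i) {
        double v = e[i] + step * x(i);
        if (v < 0.0) v = 0.0;
        if (v > 1.0) v = 1.0;
        trial[i] = knocked[i] ? 0.0 : v;
      }
      double r = apply_map(S, sigma0, sigma_half, eps, m, knocked, trial, ge);
      if (r < resid || r < 0.5 * tol) {
        e = trial;
        resid = r;
        break;
      }
      step *= 0.5;
      if (ls == 7) return false;  // no descent direction: give up
    }
  }
  return resid < 0.5 * tol;
}

// Synchronous fixed-point iteration of e -> exp(m*(U(sigma(e)) - 1)),
// starting from e_1/2, with knocked-out genes pinned to exactly 0.
// The update is damped adaptively: whenever the max-norm change fails to
// shrink a few times in a row (the signature of the period-2 oscillations
// that strongly coupled convergent pairs can produce under plain
// substitution), the damping factor is halved, down to 1/64. Damping
// moves the iterate along the same update direction and so never changes
// the fixed point reached, only the path to it.
static int iterate_expression(const Coupling& S, double sigma0,
                              double sigma_half, double eps, double m,
                              const std::vector<char>& knocked, double tol,
                              int max_iter, double damping,
                              std::vector<double>& e, bool& converged,
                              std::vector<std::vector<double> >* traj) {
  int n = S.n;
  double e_min = std::exp(-m);
  double e_half = 0.5 * (e_min + 1.0);
  e.assign(n, e_half);
  for (int i = 0; i < n; ++i)
    if (knocked[i]) e[i] = 0.0;
  if (traj) traj->push_back(e);
  std::vector<double> enew(n), prev_step(n, 0.0), cur_step(n, 0.0);
  converged = false;
  // damping = 1 selects the adaptive policy (start undamped, retune on
  // oscillation, extrapolate slow tails); damping < 1 runs a plain fixed
  // damped iteration with no adaptation.
  bool adaptive = (damping >= 1.0);
  bool tune_w = adaptive;
  double w = damping;
  double best_delta = R_PosInf;
  double prev_lambda = R_PosInf, prev_lambda2 = R_PosInf;
  double prejump_delta = R_PosInf;
  int since_improve = 0, since_jump = 0, jump_cooldown = 10, newton_attempts = 0;
  bool check_jump = false;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    double delta = 0.0, resid = 0.0, dot_pc = 0.0, dot_pp = 0.0;
    for (int i = 0; i < n; ++i) {
      if (knocked[i]) {
        enew[i] = 0.0;
        cur_step[i] = 0.0;
        continue;
      }
      double sigma = sigma0;
      for (int k = S.ptr[i]; k < S.ptr[i + 1]; ++k)
        sigma += S.val[k] * e[S.idx[k]];
      double z = (sigma - sigma_half) / eps;
      double target;
      if (z >= 36.0) {
        target = e_min;  // promoter fully closed to double precision
      } else if (z <= -36.0) {
        target = 1.0;    // promoter fully open
      } else {
        double U = 1.0 / (1.0 + std::exp(z));
        target = std::exp(m * (U - 1.0));
      }
      double r = std::fabs(target - e[i]);
      if (r > resid) resid = r;
      enew[i] = (w >= 1.0) ? target : e[i] + w * (target - e[i]);
      double d = enew[i] - e[i];
      cur_step[i] = d;
      dot_pc += prev_step[i] * d;
      dot_pp += prev_step[i] * prev_step[i];
      d = std::fabs(d);
      if (d > delta) delta = d;
    }
    // convergence is judged on the undamped self-consistency residual
    // ||G(e) - e||, not the (possibly damped) step size, so a converged
    // state is self-consistent to tol no matter what damping was in play
    if (resid < tol) {
      converged = true;
      break;
    }
    e.swap(enew);
    if (traj) traj->push_back(e);
    if (!adaptive) continue;  // user-fixed damping: plain iteration
    // safety net: if the exploratory damping schedule has not converged
    // reasonably quickly, pin the damping to a conservative 0.2, which
    // empirically contracts on every genome tried (slow rotating modes
    // included); the extrapolation jumps below stay active to shortcut
    // the slow monotone tails this produces.
    // final resort: when damped substitution is plainly orbiting (a limit
    // cycle around an unstable fixed point), switch to Newton on the
    // fixed-point equations themselves
    int stage3 = (max_iter / 2 < 800) ? max_iter / 2 : 800;
    if (newton_attempts < 5 && it >= stage3 + newton_attempts * 400) {
      ++newton_attempts;
      if (newton_polish(S, sigma0, sigma_half, eps, m, knocked, tol, e)) {
        converged = true;
        if (traj) traj->push_back(e);
        break;
      }
    }
    int stage2 = (max_iter / 4 < 200) ? max_iter / 4 : 200;
    if (tune_w && it >= stage2) {
      tune_w = false;
      w = 0.2;
      jump_cooldown = 10;
      since_jump = 0;
      check_jump = false;
      best_delta = R_PosInf;
      since_improve = 0;
      prev_lambda = prev_lambda2 = R_PosInf;
    }
    ++since_jump;
    // a jump that did not reduce the step size hit a rotating (complex)
    // mode that the scalar extrapolation cannot represent: back off with
    // an exponentially growing cooldown, so misfires cost little while
    // genuinely slow monotone tails can still be rescued later
    if (check_jump) {
      check_jump = false;
      if (delta > prejump_delta) {
        jump_cooldown = (jump_cooldown < 1000) ? jump_cooldown * 4 : 4000;
      } else {
        jump_cooldown = 10;
      }
    }
    // lambda estimates the dominant eigenvalue of the *damped* update map
    // from the alignment of successive steps; it is only trusted when
    // three consecutive estimates agree (a single dominant real mode).
    double lambda = (dot_pp > 0.0) ? dot_pc / dot_pp : R_PosInf;
    bool stable = R_finite(lambda) && R_finite(prev_lambda) &&
                  R_finite(prev_lambda2) &&
                  std::fabs(lambda - prev_lambda) <
                    0.005 * std::fabs(lambda) + 1e-12 &&
                  std::fabs(lambda - prev_lambda2) <
                    0.01 * std::fabs(lambda) + 1e-12;
    if (stable && since_jump >= jump_cooldown &&
        lambda > 0.5 && lambda < 0.9999) {
      // slow monotone tail (e.g. strong divergent-pair positive
      // feedback, or heavy damping): the remaining geometric series sums
      // to step * lambda / (1 - lambda). The jump targets the same fixed
      // point -- the plain iterations that follow still decide
      // convergence.
      double f = lambda / (1.0 - lambda);
      if (f > 1e8) f = 1e8;
      for (int i = 0; i < n; ++i) {
        if (knocked[i]) continue;
        double v = e[i] + f * cur_step[i];
        if (v < 0.0) v = 0.0;
        if (v > 1.0) v = 1.0;
        e[i] = v;
      }
      since_jump = 0;
      prejump_delta = delta;
      check_jump = true;
      prev_lambda = prev_lambda2 = R_PosInf;
      best_delta = R_PosInf;
      since_improve = 0;
      std::fill(prev_step.begin(), prev_step.end(), 0.0);
      continue;
    }
    if (tune_w && stable && since_jump >= 10 && lambda < -0.3) {
      // oscillatory dominant mode: infer the undamped eigenvalue and
      // re-damp close to its optimum instead of blindly halving, which
      // avoids the very slow tails produced by over-damping.
      double lam_undamped = 1.0 - (1.0 - lambda) / w;
      double w_new = 1.5 / (1.0 + std::fabs(lam_undamped));
      if (w_new < 1.0 / 64.0) w_new = 1.0 / 64.0;
      if (w_new > 1.0) w_new = 1.0;
      if (std::fabs(w_new - w) > 0.05 * w) {
        w = w_new;
        since_jump = 0;
        prev_lambda = prev_lambda2 = R_PosInf;
        best_delta = R_PosInf;
        since_improve = 0;
        prev_step.swap(cur_step);
        continue;
      }
    }
    prev_lambda2 = prev_lambda;
    prev_lambda = lambda;
    prev_step.swap(cur_step);
    // last-resort fallback: halve the damping when the iteration keeps
    // failing to make a new best (mixed or complex modes that defeat the
    // scalar-mode diagnostics above)
    if (delta < best_delta) {
      best_delta = delta;
      since_improve = 0;
    } else if (tune_w && ++since_improve >= 20 && w > 1.0 / 64.0) {
      w *= 0.5;
      since_improve = 0;
      prev_lambda = prev_lambda2 = R_PosInf;
    }
  }
  return (it > max_iter) ? max_iter : it;
}

static void final_state(const Coupling& S, double sigma0, double sigma_half,
                        double eps, const std::vector<double>& e,
                        std::vector<double>& sigma, std::vector<double>& U) {
  int n = S.n;
  sigma.assign(n, sigma0);
  U.assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int k = S.ptr[i]; k < S.ptr[i + 1]; ++k)
      sigma[i] += S.val[k] * e[S.idx[k]];
    U[i] = sigmoid_opening(sigma[i], sigma_half, eps);
  }
}

// [[Rcpp::export]]
List cpp_fixed_point(NumericMatrix M, double sigma0, double sigma_half,
                     double eps, double m, LogicalVector knocked, double tol,
                     int max_iter, double damping, bool record_trajectory) {
  int n = M.nrow();
  Coupling S;
  S.n = n;
  S.ptr.assign(n + 1, 0);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (M(i, j) != 0.0) {
        S.idx.push_back(j);
        S.val.push_back(M(i, j));
      }
    }
    S.ptr[i + 1] = (int)S.idx.size();
  }
  std::vector<char> ko(n, 0);
  for (int i = 0; i < n; ++i) ko[i] = knocked[i] ? 1 : 0;
  std::vector<double> e;
  std::vector<std::vector<double> > traj;
  bool converged;
  int iters = iterate_expression(S, sigma0, sigma_half, eps, m, ko, tol,
                                 max_iter, damping, e, converged,
                                 record_trajectory ? &traj : (std::vector<std::vector<double> >*)0);
  std::vector<double> sigma, U;
  final_state(S, sigma0, sigma_half, eps, e, sigma, U);
  List out = List::create(
      _["expression"] = NumericVector(e.begin(), e.end()),
      _["sigma_local"] = NumericVector(sigma.begin(), sigma.end()),
      _["opening"] = NumericVector(U.begin(), U.end()),
      _["iterations"] = iters, _["converged"] = converged);
  if (record_trajectory) {
    NumericMatrix T((int)traj.size(), n);
    for (int t = 0; t < (int)traj.size(); ++t)
      for (int i = 0; i < n; ++i) T(t, i) = traj[t][i];
    out["trajectory"] = T;
  }
  return out;
}

// Full fitness evaluation of one genome in both environments: build the
// coupling, solve the fixed point twice, then per-type mean expressions,
// gap g (squared distance to targets) and fitness exp(-k*g).
// type_code: 0 = A, 1 = B, 2 = AB.
// [[Rcpp::export]]
List cpp_evaluate_genome(NumericVector begin, NumericVector len,
                         IntegerVector ori, IntegerVector type_code, double L,
                         double sigma_basal, double c, double dmax,
                         double sigma_half, double eps, double m,
                         double ds_A, double ds_B, double k_selection,
                         double tol, int max_iter, double damping) {
  int n = begin.size();
  Coupling S = build_coupling(&begin[0], &len[0], &ori[0], n, L, c, dmax, true);
  std::vector<char> ko(n, 0);
  double e_min = std::exp(-m);
  double e_half = 0.5 * (e_min + 1.0);
  double ds[2] = {ds_A, ds_B};
  NumericMatrix mean_expr(3, 2), act(3, 2);
  double type_n[3] = {0, 0, 0};
  for (int i = 0; i < n; ++i) type_n[type_code[i]] += 1.0;
  bool all_converged = true;
  int iter_total = 0;
  for (int env = 0; env < 2; ++env) {
    std::vector<double> e;
    bool converged;
    iter_total += iterate_expression(S, sigma_basal + ds[env], sigma_half, eps,
                                     m, ko, tol, max_iter, damping, e,
                                     converged, 0);
    if (!converged) all_converged = false;
    for (int i = 0; i < n; ++i) {
      int t = type_code[i];
      mean_expr(t, env) += e[i];
      if (e[i] > e_half) act(t, env) += 1.0;
    }
    for (int t = 0; t < 3; ++t)
      if (type_n[t] > 0) mean_expr(t, env) /= type_n[t];
  }
  // targets: env A wants A and AB at 1, B at e^-m; env B symmetric
  double target[3][2] = {{1.0, e_min}, {e_min, 1.0}, {1.0, 1.0}};
  double gap = 0.0;
  for (int env = 0; env < 2; ++env)
    for (int t = 0; t < 3; ++t) {
      double d = mean_expr(t, env) - target[t][env];
      gap += d * d;
    }
  double fitness = std::exp(-k_selection * gap);
  return List::create(_["fitness"] = fitness, _["gap"] = gap,
                      _["mean_expression"] = mean_expr,
                      _["activated"] = act, _["converged"] = all_converged,
                      _["iterations"] = iter_total);
}

// ---- genome operators -----------------------------------------------------
// Inversions operate on parallel coordinate vectors; gene identity is
// tracked through the returned permutation so R-side attributes (id, type,
// basal expression) can follow. Coordinates are kept integer-valued so the
// involution property is bit-exact.

// An inversion endpoint is a cut between base pairs: it is invalid only
// if it would split a gene, i.e. fall strictly inside its occupied
// interval. Cutting exactly at a gene's first or one-past-last coordinate
// is legal (the gene stays intact), which also makes every inversion
// reversible: after the inversion a gene may start or end exactly at a
// former endpoint.
static bool endpoint_splits_gene(double x, const NumericVector& begin,
                                 const NumericVector& len, double L) {
  int n = begin.size();
  for (int k = 0; k < n; ++k) {
    double off = pos_mod(x - begin[k], L);
    if (off > 0.0 && off < len[k]) return true;
  }
  return false;
}

static void invert_segment(std::vector<double>& begin,
                           std::vector<double>& len, std::vector<int>& ori,
                           std::vector<int>& perm, double a, double b) {
  int n = (int)begin.size();
  for (int k = 0; k < n; ++k) {
    if (begin[k] >= a && begin[k] + len[k] <= b) {
      begin[k] = a + b - (begin[k] + len[k]);
      ori[k] = -ori[k];
    }
  }
  // restore begin order (nearly sorted: insertion sort)
  for (int k = 1; k < n; ++k) {
    double bk = begin[k], lk = len[k];
    int ok = ori[k], pk = perm[k];
    int j = k - 1;
    while (j >= 0 && begin[j] > bk) {
      begin[j + 1] = begin[j];
      len[j + 1] = len[j];
      ori[j + 1] = ori[j];
      perm[j + 1] = perm[j];
      --j;
    }
    begin[j + 1] = bk;
    len[j + 1] = lk;
    ori[j + 1] = ok;
    perm[j + 1] = pk;
  }
}

// [[Rcpp::export]]
List cpp_apply_inversion(NumericVector begin, NumericVector len,
                         IntegerVector ori, double L, double start_bp,
                         double end_bp) {
  if (endpoint_splits_gene(start_bp, begin, len, L) ||
      endpoint_splits_gene(end_bp, begin, len, L)) {
    stop("inversion endpoint lies inside a gene");
  }
  double a = (start_bp < end_bp) ? start_bp : end_bp;
  double b = (start_bp < end_bp) ? end_bp : start_bp;
  int n = begin.size();
  std::vector<double> nb(begin.begin(), begin.end());
  std::vector<double> nl(len.begin(), len.end());
  std::vector<int> no(ori.begin(), ori.end());
  std::vector<int> perm(n);
  for (int k = 0; k < n; ++k) perm[k] = k + 1;
  if (a != b) invert_segment(nb, nl, no, perm, a, b);
  return List::create(_["begin"] = NumericVector(nb.begin(), nb.end()),
                      _["length"] = NumericVector(nl.begin(), nl.end()),
                      _["orientation"] = IntegerVector(no.begin(), no.end()),
                      _["perm"] = IntegerVector(perm.begin(), perm.end()));
}

// Draw one endpoint uniformly over the integer non-coding positions.
static double draw_intergenic(const std::vector<double>& begin,
                              const std::vector<double>& len, double L) {
  int n = (int)begin.size();
  double total = L;
  for (int k = 0; k < n; ++k) total -= len[k];
  double u = std::floor(unif_rand() * total);
  if (u >= total) u = total - 1.0;
  // walk the gaps in begin order (gap k follows gene k)
  for (int k = 0; k < n; ++k) {
    double gap_start = begin[k] + len[k];
    double gap_len = ((k + 1 < n) ? begin[k + 1] : begin[0] + L) -
                     (begin[k] + len[k]);
    if (u < gap_len) return pos_mod(gap_start + u, L);
    u -= gap_len;
  }
  return pos_mod(begin[0] + L - 1.0, L);  // unreachable for valid genomes
}

// [[Rcpp::export]]
NumericVector cpp_sample_inversion(NumericVector begin, NumericVector len,
                                   double L) {
  std::vector<double> b(begin.begin(), begin.end());
  std::vector<double> l(len.begin(), len.end());
  double total = L;
  for (size_t k = 0; k < l.size(); ++k) total -= l[k];
  if (total < 1.0) stop("genome has no intergenic material to cut");
  double p1 = draw_intergenic(b, l, L);
  double p2 = draw_intergenic(b, l, L);
  return NumericVector::create(p1, p2);
}

// Poisson-many sequential inversions; single code path shared with the
// one-shot operators above.
// [[Rcpp::export]]
List cpp_mutate(NumericVector begin, NumericVector len, IntegerVector ori,
                double L, double lam) {
  int n = begin.size();
  std::vector<double> nb(begin.begin(), begin.end());
  std::vector<double> nl(len.begin(), len.end());
  std::vector<int> no(ori.begin(), ori.end());
  std::vector<int> perm(n);
  for (int k = 0; k < n; ++k) perm[k] = k + 1;
  int K = (int)R::rpois(lam);
  for (int s = 0; s < K; ++s) {
    double p1 = draw_intergenic(nb, nl, L);
    double p2 = draw_intergenic(nb, nl, L);
    double a = (p1 < p2) ? p1 : p2;
    double b = (p1 < p2) ? p2 : p1;
    if (a != b) invert_segment(nb, nl, no, perm, a, b);
  }
  return List::create(_["begin"] = NumericVector(nb.begin(), nb.end()),
                      _["length"] = NumericVector(nl.begin(), nl.end()),
                      _["orientation"] = IntegerVector(no.begin(), no.end()),
                      _["perm"] = IntegerVector(perm.begin(), perm.end()),
                      _["n_inversions"] = K);
}
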