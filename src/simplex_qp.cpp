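// Simplex-constrained quadratic programming for convex dictionary updates.
//
// A dictionary column restricted to its representative set is d = X w with w
// on the probability simplex.  Substituting into the quadratic surrogate
// Tr(D A D') - 2 Tr(D B) and dropping terms that do not involve column j
// gives
//
//   f(w) = a * w' Q w + 2 q' w,   Q = X'X (PSD),  a = A[j,j] >= 0,
//
// with q = X' (sum_{l != j} A[j,l] D[:,l] - B[j,:]').  Representative
// patches are frequently (near-)duplicates, so Q is routinely singular; the
// solver is a primal active-set method whose equality subproblems fall back
// to a pseudo-inverse, which handles those flat faces exactly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Euclidean projection onto the probability simplex (sort-based).
static vec project_simplex(const vec& v) {
  const uword m = v.n_elem;
  vec u = sort(v, "descend");
  vec css = cumsum(u);
  double tau = 0.0;
  for (uword i = 0; i < m; ++i) {
    double t = (css(i) - 1.0) / (double)(i + 1);
    if (u(i) - t > 0.0) tau = t;
  }
  vec w = v - tau;
  w.transform([](double x) { return x > 0.0 ? x : 0.0; });
  return w;
}

// KKT residual on the simplex for gradient g at feasible w:
// mu = min_i g_i; coordinates with mass must satisfy g_i = mu.
static double kkt_residual(const vec& g, const vec& w) {
  double mu = g.min();
  double r = 0.0;
  for (uword i = 0; i < g.n_elem; ++i) {
    if (w(i) > 1e-12) r = std::max(r, g(i) - mu);
  }
  return r / std::max(1.0, std::abs(mu));
}

struct QpResult {
  vec w;
  double obj;
  int iters;
  double kkt;
};

// Equality-constrained subproblem on support S: minimize a w'Qw + 2q'w with
// 1'w = 1, free signs.  KKT system [2aQ_S, 1; 1', 0] [w; nu] = [-2q_S; 1].
static bool solve_eqp(const mat& Q, const vec& q, double a, const uvec& S,
                      vec& wS, double& nu) {
  const uword s = S.n_elem;
  mat M(s + 1, s + 1, fill::zeros);
  M.submat(0, 0, s - 1, s - 1) = 2.0 * a * Q.submat(S, S);
  M.submat(0, s, s - 1, s).ones();
  M.submat(s, 0, s, s - 1).ones();
  vec rhs(s + 1);
  rhs.head(s) = -2.0 * q.elem(S);
  rhs(s) = 1.0;
  vec sol;
  bool ok = solve(sol, M, rhs, solve_opts::no_approx);
  if (!ok) {
    // singular face (duplicate representatives): tiny ridge, then pinv
    mat Mr = M;
    Mr.submat(0, 0, s - 1, s - 1) += 1e-10 * eye(s, s);
    ok = solve(sol, Mr, rhs, solve_opts::no_approx);
  }
  if (!ok) {
    mat Mp;
    if (!pinv(Mp, M)) return false;
    sol = Mp * rhs;
  }
  wS = sol.head(s);
  nu = -sol(s);       // stationarity reads 2aQ_S w + 2q_S = nu on the face
  return true;
}

static QpResult solve_qp(const mat& Q, const vec& q, double a,
                         const vec& w0, int max_iter, double tol) {
  const uword m = Q.n_rows;
  auto fval = [&](const vec& x) { return a * dot(x, Q * x) + 2.0 * dot(q, x); };
  if (m == 1) {
    vec w1(1, fill::ones);
    return {w1, fval(w1), 0, 0.0};
  }
  if (a <= 1e-300) {                       // linear objective: vertex optimum
    uword j = q.index_min();
    vec w(m, fill::zeros);
    w(j) = 1.0;
    vec g = 2.0 * q;
    return {w, fval(w), 0, kkt_residual(g, w)};
  }
  vec w = project_simplex(w0);
  vec w_best = w;
  double f_best = fval(w);
  int stall = 0;
  sword pending = -1;             // index forced into the next working set
  int it = 0;
  const double tol_neg = 1e-12, tol_dual = 1e-12;
  while (it < max_iter) {
    ++it;
    // rebuild the working set from the current point every iteration
    std::vector<uword> sv;
    for (uword i = 0; i < m; ++i)
      if (w(i) > 1e-14 || (sword)i == pending) sv.push_back(i);
    pending = -1;
    uvec S(sv.size());
    for (size_t i = 0; i < sv.size(); ++i) S(i) = sv[i];
    vec wS;
    double nu;
    if (!solve_eqp(Q, q, a, S, wS, nu)) break;
    if (wS.min() >= -tol_neg) {
      // accept the face solution; check dual feasibility off the face
      w.zeros();
      for (uword i = 0; i < S.n_elem; ++i) w(S(i)) = std::max(wS(i), 0.0);
      w /= accu(w);
      double f_cur = fval(w);
      if (f_cur < f_best - 1e-12 * std::max(1.0, std::abs(f_best))) {
        f_best = f_cur; w_best = w; stall = 0;
      } else {
        ++stall;
      }
      vec g = 2.0 * a * (Q * w) + 2.0 * q;
      double best = 0.0;
      sword add = -1;
      for (uword i = 0; i < m; ++i) {
        if (w(i) > 1e-14) continue;
        double viol = nu - g(i);
        if (viol > best + tol_dual) { best = viol; add = (sword)i; }
      }
      if (add < 0) { w_best = w; f_best = f_cur; break; }   // KKT holds
      if (stall >= 3) break;      // equal-objective faces: stop cycling
      pending = add;
    } else {
      // step from the current point toward wS until a coordinate hits zero
      vec wcur(S.n_elem);
      for (uword i = 0; i < S.n_elem; ++i) wcur(i) = w(S(i));
      double alpha = 1.0;
      uword blk = S.n_elem;
      for (uword i = 0; i < S.n_elem; ++i) {
        if (wS(i) < wcur(i) - 1e-18) {
          double r = wcur(i) / (wcur(i) - wS(i));
          if (r < alpha) { alpha = r; blk = i; }
        }
      }
      vec wnew = wcur + alpha * (wS - wcur);
      if (blk < S.n_elem) wnew(blk) = 0.0;      // exact zero for the blocker
      w.zeros();
      for (uword i = 0; i < S.n_elem; ++i) w(S(i)) = std::max(wnew(i), 0.0);
      double s = accu(w);
      if (s <= 0) break;
      w /= s;
      double f_cur = fval(w);
      if (f_cur < f_best - 1e-12 * std::max(1.0, std::abs(f_best))) {
        f_best = f_cur; w_best = w; stall = 0;
      }
    }
  }
  vec g = 2.0 * a * (Q * w_best) + 2.0 * q;
  return {w_best, fval(w_best), it, kkt_residual(g, w_best)};
}

// [[Rcpp::export]]
Rcpp::List cpp_solve_simplex_qp(const arma::mat& Q, const arma::vec& q,
                                double a, const arma::vec& w0,
                                int max_iter = 10000, double tol = 1e-8) {
  QpResult r = solve_qp(Q, q, a, w0, max_iter, tol);
  return Rcpp::List::create(Rcpp::Named("w") = r.w,
                            Rcpp::Named("objective") = r.obj,
                            Rcpp::Named("iters") = r.iters,
                            Rcpp::Named("kkt") = r.kkt);
}

// [[Rcpp::export]]
arma::vec cpp_project_simplex(const arma::vec& v) {
  return project_simplex(v);
}

// Exhaustive one-out removal search.  X is d x M (current reps plus the
// newly appended sample in the last column); for each leave-one-out subset
// the simplex QP is solved and the candidate with the smallest objective is
// returned (1-based index of the removed column; ties -> smallest index).
// w0full (length M) warm-starts each subproblem, typically with the
// element's current weights and zero mass on the newcomer.
// [[Rcpp::export]]
Rcpp::List cpp_best_removal(const arma::mat& X, double a, const arma::vec& g,
                            int max_iter = 10000, double tol = 1e-8,
                            Rcpp::Nullable<Rcpp::NumericVector> w0full = R_NilValue) {
  const uword M = X.n_cols;
  mat Qfull = X.t() * X;
  vec qfull = X.t() * g;
  vec warm;
  bool have_warm = w0full.isNotNull();
  if (have_warm) warm = Rcpp::as<vec>(w0full.get());
  vec objs(M);
  std::vector<vec> ws(M);
  for (uword i = 0; i < M; ++i) {
    uvec keep(M - 1);
    uword c = 0;
    for (uword j = 0; j < M; ++j) if (j != i) keep(c++) = j;
    mat Q = Qfull.submat(keep, keep);
    vec q = qfull.elem(keep);
    vec w0(M - 1);
    if (have_warm) {
      w0 = warm.elem(keep);
      double s = accu(w0);
      if (s > 1e-8) w0 /= s; else w0.fill(1.0 / (double)(M - 1));
    } else {
      w0.fill(1.0 / (double)(M - 1));
    }
    QpResult r = solve_qp(Q, q, a, w0, max_iter, tol);
    objs(i) = r.obj;
    ws[i] = r.w;
  }
  uword best = objs.index_min();
  return Rcpp::List::create(Rcpp::Named("removed") = (int)(best + 1),
                            Rcpp::Named("w") = ws[best],
                            Rcpp::Named("objectives") = objs);
}

// Nonnegative lasso by cyclic coordinate descent:
// argmin_{c >= 0} ||x - D c||^2 + lambda ||c||_1, parameterized by
// G = D'D and b = D'x.
// [[Rcpp::export]]
arma::vec cpp_nn_lasso(const arma::mat& G, const arma::vec& b, double lambda,
                       int max_iter = 500, double tol = 1e-10) {
  const uword K = G.n_rows;
  vec code(K, fill::zeros);
  vec gd = G.diag();
  for (int it = 0; it < max_iter; ++it) {
    double delta = 0.0;
    for (uword j = 0; j < K; ++j) {
      if (gd(j) <= 0.0) continue;
      double r = b(j) - dot(G.row(j), code) + gd(j) * code(j);
      double nw = (r - lambda / 2.0) / gd(j);
      if (nw < 0.0) nw = 0.0;
      delta = std::max(delta, std::abs(nw - code(j)));
      code(j) = nw;
    }
    if (delta < tol) break;
  }
  return code;
}
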