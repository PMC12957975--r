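// Core numerical routines: coordinate-descent l1 solver, block coordinate
// descent for the l2,1 (group) problem, a dual coordinate-descent linear SVM,
// and the nested leave-one-out cross-validation engines.  Everything here is
// deterministic: fixed cyclic update orders, no RNG.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// ---------------------------------------------------------------------------
// Lasso: min_w 0.5 * ||y - X w||^2 + lambda * ||w||_1
// Cyclic coordinate descent with residual updates; warm-started path over a
// caller-supplied lambda sequence (solved in the order given; callers pass
// decreasing sequences).  Convergence is certified by the KKT conditions.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
Rcpp::List cpp_lasso_path(const arma::mat& X, const arma::vec& y,
                          const arma::vec& lambdas, double tol, int max_iter) {
  const uword n = X.n_rows, p = X.n_cols, K = lambdas.n_elem;
  vec nj(p);
  for (uword j = 0; j < p; ++j) nj(j) = dot(X.col(j), X.col(j));
  const double nmax = nj.max() > 0 ? nj.max() : 1.0;

  mat W(p, K, fill::zeros);
  vec w(p, fill::zeros);
  vec res = y;
  ivec iters(K, fill::zeros);
  vec kkts(K, fill::zeros);

  // one coordinate update; returns |change|
  auto update = [&](uword j, double lam) -> double {
    if (nj(j) <= 1e-300) { w(j) = 0.0; return 0.0; }
    const double z = nj(j) * w(j) + dot(X.col(j), res);
    const double wn = soft(z, lam) / nj(j);
    const double d = wn - w(j);
    if (d != 0.0) {
      res -= d * X.col(j);
      w(j) = wn;
    }
    return std::fabs(d);
  };

  for (uword l = 0; l < K; ++l) {
    const double lam = lambdas(l);
    int it = 0;
    double viol = datum::inf;
    // active-set strategy: full sweep + KKT check, then iterate the active
    // set to convergence before the next full pass
    while (it < max_iter) {
      for (uword j = 0; j < p; ++j) update(j, lam);
      ++it;
      viol = 0.0;
      for (uword j = 0; j < p; ++j) {
        if (nj(j) <= 1e-300) continue;
        const double v = dot(X.col(j), res);
        double vi;
        if (w(j) > 0)      vi = std::fabs(v - lam);
        else if (w(j) < 0) vi = std::fabs(v + lam);
        else               vi = std::max(std::fabs(v) - lam, 0.0);
        if (vi > viol) viol = vi;
      }
      if (viol <= tol) break;
      uvec active = find(w != 0.0);
      while (it < max_iter) {
        double md = 0.0;
        for (uword a = 0; a < active.n_elem; ++a) {
          const double d = update(active(a), lam);
          if (d > md) md = d;
        }
        ++it;
        if (md * nmax <= 0.1 * std::max(tol, 1e-300)) break;
      }
    }
    iters(l) = it;
    kkts(l) = viol;
    W.col(l) = w;
  }
  return Rcpp::List::create(Rcpp::Named("coef") = W,
                            Rcpp::Named("iters") = iters,
                            Rcpp::Named("kkt") = kkts);
}

// ---------------------------------------------------------------------------
// Group (l2,1) problem in Gram form.  For subjects i = 1..N with Gram
// matrices G_i = [Z_i' Z_i] over all m columns, target column r, solve
//   min_W sum_i ( 0.5 w_i' G_i w_i - G_i[,r]' w_i ) + lambda * sum_j ||W_j.||_2
// over W (m x N) with row r fixed to zero.  Row-wise proximal block
// coordinate descent; with equal per-subject diagonals (z-scored columns,
// where G_i[j,j] = T - 1 for all i) each row update is the exact closed-form
// block soft-threshold.  Warm-started over the lambda path.
// ---------------------------------------------------------------------------

static void group_cd_core(const cube& G, const uvec& subj, uword target,
                          double lam, mat& W, mat& GV, double tol,
                          int max_iter, int& iters_out, double& kkt_out) {
  const uword m = G.n_rows, N = subj.n_elem;
  // per-row majorizing curvature: max_i G_i[j,j]
  vec dmax(m);
  for (uword j = 0; j < m; ++j) {
    double d = 0.0;
    for (uword i = 0; i < N; ++i) d = std::max(d, G(j, j, subj(i)));
    dmax(j) = d > 1e-300 ? d : 1.0;
  }
  vec u(N), del(N);
  // one block (row) update; returns max |change| over subjects
  auto update_row = [&](uword j) -> double {
    double unorm2 = 0.0;
    for (uword i = 0; i < N; ++i) {
      const double grad = GV(j, i) - G(j, target, subj(i));
      u(i) = W(j, i) - grad / dmax(j);
      unorm2 += u(i) * u(i);
    }
    const double unorm = std::sqrt(unorm2);
    const double thr = lam / dmax(j);
    const double shrink = unorm > thr ? (1.0 - thr / unorm) : 0.0;
    double md = 0.0;
    for (uword i = 0; i < N; ++i) {
      const double d = shrink * u(i) - W(j, i);
      if (d != 0.0) {
        GV.col(i) += d * G.slice(subj(i)).col(j);
        W(j, i) += d;
        const double ad = std::fabs(d);
        if (ad > md) md = ad;
      }
    }
    return md;
  };
  int it = 0;
  double viol = datum::inf;
  while (it < max_iter) {
    for (uword j = 0; j < m; ++j) {
      if (j != target) update_row(j);
    }
    ++it;
    // KKT certificate: g_j stacks c_ij - (G_i w_i)_j over subjects
    viol = 0.0;
    for (uword j = 0; j < m; ++j) {
      if (j == target) continue;
      double gnorm2 = 0.0, wnorm2 = 0.0;
      for (uword i = 0; i < N; ++i) {
        const double g = G(j, target, subj(i)) - GV(j, i);
        gnorm2 += g * g;
        wnorm2 += W(j, i) * W(j, i);
      }
      double vi;
      if (wnorm2 > 0.0) {
        const double wnorm = std::sqrt(wnorm2);
        double s2 = 0.0;
        for (uword i = 0; i < N; ++i) {
          const double g = G(j, target, subj(i)) - GV(j, i);
          const double d = g - lam * W(j, i) / wnorm;
          s2 += d * d;
        }
        vi = std::sqrt(s2);
      } else {
        vi = std::max(std::sqrt(gnorm2) - lam, 0.0);
      }
      if (vi > viol) viol = vi;
    }
    if (viol <= tol) break;
    // iterate active rows before the next full pass
    std::vector<uword> act;
    for (uword j = 0; j < m; ++j) {
      if (j == target) continue;
      for (uword i = 0; i < N; ++i) {
        if (W(j, i) != 0.0) { act.push_back(j); break; }
      }
    }
    while (it < max_iter) {
      double md = 0.0;
      for (size_t a = 0; a < act.size(); ++a) {
        const double d = update_row(act[a]);
        if (d > md) md = d;
      }
      ++it;
      if (md * dmax.max() <= 0.1 * std::max(tol, 1e-300)) break;
    }
  }
  iters_out = it;
  kkt_out = viol;
}

// [[Rcpp::export]]
Rcpp::List cpp_group_cd(const arma::cube& G, int target,
                        const arma::vec& lambdas, double tol, int max_iter) {
  const uword m = G.n_rows, N = G.n_slices, K = lambdas.n_elem;
  uvec subj = regspace<uvec>(0, N - 1);
  mat W(m, N, fill::zeros), GV(m, N, fill::zeros);
  Rcpp::List out(K);
  ivec iters(K);
  vec kkts(K);
  for (uword l = 0; l < K; ++l) {
    int it; double kk;
    group_cd_core(G, subj, (uword)target, lambdas(l), W, GV, tol, max_iter,
                  it, kk);
    iters(l) = it; kkts(l) = kk;
    out[l] = W;
  }
  return Rcpp::List::create(Rcpp::Named("coef") = out,
                            Rcpp::Named("iters") = iters,
                            Rcpp::Named("kkt") = kkts);
}

// lambda_max of the group problem per ROI, from Gram slices restricted to a
// subject subset: max_{j != r} sqrt( sum_i G_i[j, r]^2 ).
static double gsr_lambda_max(const cube& G, const uvec& subj) {
  const uword m = G.n_rows, N = subj.n_elem;
  double lm = 0.0;
  for (uword r = 0; r < m; ++r) {
    for (uword j = 0; j < m; ++j) {
      if (j == r) continue;
      double s2 = 0.0;
      for (uword i = 0; i < N; ++i) {
        const double g = G(j, r, subj(i));
        s2 += g * g;
      }
      if (s2 > lm * lm) lm = std::sqrt(s2);
    }
  }
  return lm;
}

// [[Rcpp::export]]
double cpp_gsr_lambda_max(const arma::cube& G) {
  uvec subj = regspace<uvec>(0, G.n_slices - 1);
  return gsr_lambda_max(G, subj);
}

// ---------------------------------------------------------------------------
// Network assembly helpers
// ---------------------------------------------------------------------------

// Fisher z with magnitude clipping at 1 - 1e-7 (atanh undefined at +-1;
// regression weights can exceed 1 in magnitude).
static inline double fisher_z_clip(double w, int& nclip) {
  const double cap = 1.0 - 1e-7;
  if (w > cap)  { ++nclip; w = cap; }
  if (w < -cap) { ++nclip; w = -cap; }
  return std::atanh(w);
}

// raw (R x R, row r = regression weights for ROI r) -> symmetric
// connectivity matrix: Fisher z on nonzeros first, then bidirectional
// averaging, zero diagonal.
static mat finalize_raw(const mat& raw, int& nclip) {
  const uword R = raw.n_rows;
  mat Z(R, R, fill::zeros);
  for (uword i = 0; i < R; ++i)
    for (uword j = 0; j < R; ++j)
      if (i != j && raw(i, j) != 0.0) Z(i, j) = fisher_z_clip(raw(i, j), nclip);
  mat S = 0.5 * (Z + Z.t());
  S.diag().zeros();
  return S;
}

// [[Rcpp::export]]
Rcpp::List cpp_finalize_network(const arma::mat& raw) {
  int nclip = 0;
  mat S = finalize_raw(raw, nclip);
  return Rcpp::List::create(Rcpp::Named("matrix") = S,
                            Rcpp::Named("n_clipped") = nclip);
}

// Sparse-network path for a set of subjects sharing one penalty: for each ROI
// r solve the group problem over all subjects (N = 1 gives the per-subject
// sparse-representation network).  Returns, per lambda, the raw weight cube
// raw(r, j, i) and the shared row support per ROI.
// [[Rcpp::export]]
Rcpp::List cpp_network_path(const arma::cube& G, const arma::vec& lambdas,
                            double tol, int max_iter) {
  const uword R = G.n_rows, N = G.n_slices, K = lambdas.n_elem;
  uvec subj = regspace<uvec>(0, N - 1);
  Rcpp::List raws(K), supports(K);
  for (uword l = 0; l < K; ++l) {
    raws[l] = cube(R, R, N, fill::zeros);
    supports[l] = Rcpp::List(R);
  }
  for (uword r = 0; r < R; ++r) {
    mat W(R, N, fill::zeros), GV(R, N, fill::zeros);
    for (uword l = 0; l < K; ++l) {
      int it; double kk;
      group_cd_core(G, subj, r, lambdas(l), W, GV, tol, max_iter, it, kk);
      // fill the stored array in place: raw[r + R*j + R*R*i]
      Rcpp::NumericVector rv = raws[l];
      for (uword j = 0; j < R; ++j)
        for (uword i = 0; i < N; ++i)
          rv[r + R * j + R * R * i] = W(j, i);
      std::vector<int> sup;
      for (uword j = 0; j < R; ++j) {
        double s2 = 0.0;
        for (uword i = 0; i < N; ++i) s2 += W(j, i) * W(j, i);
        if (s2 > 0.0) sup.push_back((int)j + 1);  // 1-based
      }
      Rcpp::List supl = supports[l];
      supl[r] = Rcpp::IntegerVector(sup.begin(), sup.end());
    }
  }
  return Rcpp::List::create(Rcpp::Named("raw") = raws,
                            Rcpp::Named("support") = supports);
}

// Coordinate-descent lasso in Gram form:
// min_w 0.5 w'G w - c'w + lam ||w||_1  (lam = 0 gives least squares).
static void lasso_gram_cd(const mat& G, const vec& c, double lam, vec& w,
                          double tol, int max_iter) {
  const uword p = G.n_cols;
  vec gv = G * w;
  for (int it = 0; it < max_iter; ++it) {
    double maxdelta = 0.0;
    for (uword j = 0; j < p; ++j) {
      const double d = G(j, j);
      if (d <= 1e-300) { w(j) = 0.0; continue; }
      const double z = d * w(j) + c(j) - gv(j);
      const double wn = soft(z, lam) / d;
      const double del = wn - w(j);
      if (del != 0.0) {
        gv += del * G.col(j);
        w(j) = wn;
        if (std::fabs(del) > maxdelta) maxdelta = std::fabs(del);
      }
    }
    double viol = 0.0;
    for (uword j = 0; j < p; ++j) {
      const double v = c(j) - gv(j);
      double vi;
      if (w(j) > 0)      vi = std::fabs(v - lam);
      else if (w(j) < 0) vi = std::fabs(v + lam);
      else               vi = std::max(std::fabs(v) - lam, 0.0);
      if (vi > viol) viol = vi;
    }
    if (viol <= tol) break;
  }
}

// Encode a held-out subject on a fixed per-ROI support: a sparse fit
// restricted to the support (from the subject's own Gram).  With
// lambda_enc > 0 the restricted problem is an l1 fit at that penalty (used
// by the GSR cross-validation engine at lambda/sqrt(N), the single-subject
// equivalent of the group penalty, so held-out features carry the same
// shrinkage as training features); with lambda_enc = 0 it is unregularized
// least squares with a small trace-normalized ridge fallback when the
// restricted system is numerically singular.
static mat encode_from_gram(const mat& Gs, const Rcpp::List& supports,
                            double lambda_enc, double ridge_rel,
                            double tol, int& n_ridge) {
  const uword R = Gs.n_rows;
  mat raw(R, R, fill::zeros);
  for (uword r = 0; r < R; ++r) {
    Rcpp::IntegerVector sup = supports[r];
    const uword k = sup.size();
    if (k == 0) continue;
    uvec A(k);
    for (uword a = 0; a < k; ++a) A(a) = (uword)(sup[a] - 1);
    mat GA = Gs.submat(A, A);
    vec cA = Gs.submat(A, uvec{r});
    vec w(k, fill::zeros);
    if (lambda_enc > 0.0) {
      lasso_gram_cd(GA, cA, lambda_enc, w, tol, 10000);
    } else {
      bool ok = solve(w, GA, cA, solve_opts::no_approx);
      if (!ok || !w.is_finite()) {
        ++n_ridge;
        const double eps = ridge_rel * (trace(GA) / (double)k);
        ok = solve(w, GA + eps * eye(k, k), cA);
        if (!ok) w.zeros(k);
      }
    }
    for (uword a = 0; a < k; ++a) raw(r, A(a)) = w(a);
  }
  return raw;
}

// [[Rcpp::export]]
Rcpp::List cpp_encode_from_gram(const arma::mat& G, const Rcpp::List& supports,
                                double lambda_enc, double ridge_rel,
                                double tol) {
  int n_ridge = 0;
  mat raw = encode_from_gram(G, supports, lambda_enc, ridge_rel, tol, n_ridge);
  return Rcpp::List::create(Rcpp::Named("raw") = raw,
                            Rcpp::Named("n_ridge") = n_ridge);
}

// ---------------------------------------------------------------------------
// Linear SVM (soft margin, hinge loss) by dual coordinate descent, bias via
// an augmented constant feature.  Deterministic cyclic updates.
// ---------------------------------------------------------------------------

static void svm_dcd(const mat& X, const vec& y, double C, double tol,
                    int max_pass, vec& w, int& npass) {
  const uword n = X.n_rows, p = X.n_cols;
  vec alpha(n, fill::zeros);
  w.zeros(p + 1);  // last entry = bias (augmented feature value 1)
  vec Q(n);
  for (uword i = 0; i < n; ++i) Q(i) = dot(X.row(i), X.row(i)) + 1.0;
  npass = 0;
  while (npass < max_pass) {
    double maxpg = 0.0;
    for (uword i = 0; i < n; ++i) {
      const double dec = dot(X.row(i), w.head(p)) + w(p);
      const double Gr = y(i) * dec - 1.0;
      double pg = Gr;
      if (alpha(i) <= 0.0 && Gr >= 0.0) pg = 0.0;
      if (alpha(i) >= C && Gr <= 0.0) pg = 0.0;
      if (std::fabs(pg) > maxpg) maxpg = std::fabs(pg);
      if (std::fabs(pg) > 1e-14) {
        double an = alpha(i) - Gr / Q(i);
        an = std::min(std::max(an, 0.0), C);
        const double d = (an - alpha(i)) * y(i);
        if (d != 0.0) {
          w.head(p) += d * X.row(i).t();
          w(p) += d;
          alpha(i) = an;
        }
      }
    }
    ++npass;
    if (maxpg < tol) break;
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_svm_linear(const arma::mat& X, const arma::vec& y, double C,
                          double tol, int max_pass) {
  vec w; int npass;
  svm_dcd(X, y, C, tol, max_pass, w, npass);
  const uword p = X.n_cols;
  return Rcpp::List::create(Rcpp::Named("w") = vec(w.head(p)),
                            Rcpp::Named("b") = w(p),
                            Rcpp::Named("passes") = npass);
}

// ---------------------------------------------------------------------------
// Nested LOOCV engines
// ---------------------------------------------------------------------------

struct BestModel {
  int correct = -1;
  int inet = -1, ilasso = -1;
  int vote = 0;               // vote cast on the outer test subject
  int val_pred = 0;
  bool empty = false;         // empty selection -> majority-class classifier
  std::vector<int> sel;       // 1-based feature columns
  std::vector<double> wsel;   // SVM weights on the standardized scale
  double b = 0.0;
};

// Grid-point preference: inner hold-out correctness first; among ties a
// real (non-empty) selection beats the degenerate majority-class model,
// then the sparser model wins (larger lasso penalty, then larger network
// penalty).
static bool better(int correct, bool empty, int ilasso, int inet,
                   const BestModel& best) {
  if (correct != best.correct) return correct > best.correct;
  if (empty != best.empty) return !empty;
  if (ilasso != best.ilasso) return ilasso > best.ilasso;
  return inet > best.inet;
}

// Evaluate one inner split for one network-lambda index: lasso path over the
// feature-selection grid, SVM per selection, correctness on the inner
// held-out subject; updates `best` under the tie-break rule
// (correctness, then smaller lasso lambda, then smaller network lambda).
static void eval_net_features(const mat& Ftr, const vec& ytr,
                              const rowvec& fval, double yval,
                              const rowvec& ftest, const vec& lasso_grid,
                              double C, double svm_tol, int svm_max_pass,
                              double lasso_tol_rel, int lasso_max_iter,
                              int inet, BestModel& best) {
  const uword n = Ftr.n_rows, P = Ftr.n_cols, K = lasso_grid.n_elem;
  rowvec mu = mean(Ftr, 0);
  rowvec sd = stddev(Ftr, 0, 0);  // sample sd (n-1)
  uvec dead = find(sd < 1e-12);
  rowvec sdz = sd;
  sdz.elem(dead).ones();
  mat Fs = Ftr;
  Fs.each_row() -= mu;
  Fs.each_row() /= sdz;
  for (uword d = 0; d < dead.n_elem; ++d) Fs.col(dead(d)).zeros();
  const double ybar = mean(ytr);
  vec yc = ytr - ybar;

  // lasso path, solved at decreasing lambda (objective uses the 1/(2n)
  // convention, so the path solver sees n * lambda)
  vec lams = sort(lasso_grid, "descend") * (double)n;
  Rcpp::List path = cpp_lasso_path(Fs, yc, lams,
                                   lasso_tol_rel * (double)n, lasso_max_iter);
  mat coefs = Rcpp::as<mat>(path["coef"]);  // P x K, descending lambda order

  const int maj = (accu(ytr > 0) * 2 >= (double)n) ? 1 : -1;  // tie -> +1

  std::vector<int> prev_sel;
  vec prev_w;
  double prev_b = 0.0;
  bool have_prev = false;

  for (uword il = 0; il < K; ++il) {          // ascending lasso grid
    const uword cidx = K - 1 - il;            // column in descending path
    std::vector<int> sel;
    for (uword j = 0; j < P; ++j)
      if (coefs(j, cidx) != 0.0) sel.push_back((int)j + 1);

    int correct, vote_test, val_pred;
    vec wsel;
    double b = 0.0;
    bool empty = sel.empty();
    if (empty) {
      val_pred = maj;
      vote_test = maj;
      correct = (maj == (int)yval) ? 1 : 0;
    } else {
      if (have_prev && sel == prev_sel) {
        wsel = prev_w; b = prev_b;
      } else {
        const uword k = sel.size();
        uvec A(k);
        for (uword a = 0; a < k; ++a) A(a) = (uword)(sel[a] - 1);
        mat Xs = Fs.cols(A);
        int npass;
        vec waug;
        svm_dcd(Xs, ytr, C, svm_tol, svm_max_pass, waug, npass);
        wsel = waug.head(k);
        b = waug(k);
        prev_sel = sel; prev_w = wsel; prev_b = b; have_prev = true;
      }
      // standardize held-out rows with training statistics
      double dv = b, dt = b;
      for (size_t a = 0; a < sel.size(); ++a) {
        const uword j = (uword)(sel[a] - 1);
        const double sj = sdz(j);
        const bool isdead = (sd(j) < 1e-12);
        const double zv = isdead ? 0.0 : (fval(j) - mu(j)) / sj;
        const double zt = isdead ? 0.0 : (ftest(j) - mu(j)) / sj;
        dv += wsel(a) * zv;
        dt += wsel(a) * zt;
      }
      val_pred = dv >= 0 ? 1 : -1;
      vote_test = dt >= 0 ? 1 : -1;
      correct = (val_pred == (int)yval) ? 1 : 0;
    }
    if (better(correct, empty, (int)il, inet, best)) {
      best.correct = correct;
      best.ilasso = (int)il;
      best.inet = inet;
      best.vote = vote_test;
      best.val_pred = val_pred;
      best.empty = empty;
      best.sel = sel;
      best.wsel = empty ? std::vector<double>()
                        : arma::conv_to<std::vector<double>>::from(wsel);
      best.b = empty ? 0.0 : b;
    }
  }
}

static Rcpp::List pack_fold(int test_id, const ivec& held, const ivec& votes,
                            const std::vector<BestModel>& models,
                            double yt) {
  const int M = votes.n_elem;
  int pos = 0;
  for (int j = 0; j < M; ++j) if (votes(j) > 0) ++pos;
  const double frac = (double)pos / (double)M;
  const int final_label = (frac >= 0.5) ? 1 : -1;
  Rcpp::List inner(M);
  for (int j = 0; j < M; ++j) {
    const BestModel& b = models[j];
    inner[j] = Rcpp::List::create(
      Rcpp::Named("held_out") = held(j),
      Rcpp::Named("net_index") = b.inet + 1,
      Rcpp::Named("lasso_index") = b.ilasso + 1,
      Rcpp::Named("inner_correct") = b.correct,
      Rcpp::Named("empty_selection") = b.empty,
      Rcpp::Named("selected") = Rcpp::IntegerVector(b.sel.begin(), b.sel.end()),
      Rcpp::Named("svm_w") = Rcpp::NumericVector(b.wsel.begin(), b.wsel.end()),
      Rcpp::Named("svm_b") = b.b,
      Rcpp::Named("vote") = (int)votes(j));
  }
  return Rcpp::List::create(
    Rcpp::Named("test_index") = test_id,
    Rcpp::Named("truth") = (int)yt,
    Rcpp::Named("votes") = votes,
    Rcpp::Named("vote_fraction") = frac,
    Rcpp::Named("final_label") = final_label,
    Rcpp::Named("inner") = inner);
}

// Engine for methods whose per-subject networks do not depend on which other
// subjects are in a training subset (Pearson correlation; per-subject sparse
// representation with a subject-relative lambda grid).  `Flist` holds one
// N x P feature matrix per network-lambda index.
// [[Rcpp::export]]
Rcpp::List cpp_cv_fixed(const Rcpp::List& Flist, const arma::vec& y,
                        const arma::vec& lasso_grid, double C,
                        double svm_tol, int svm_max_pass,
                        double lasso_tol_rel, int lasso_max_iter) {
  const int Knet = Flist.size();
  std::vector<mat> F(Knet);
  for (int k = 0; k < Knet; ++k) F[k] = Rcpp::as<mat>(Flist[k]);
  const uword N = F[0].n_rows;

  Rcpp::List folds(N);
  for (uword t = 0; t < N; ++t) {
    uvec train(N - 1);
    uword q = 0;
    for (uword s = 0; s < N; ++s) if (s != t) train(q++) = s;
    const uword M = N - 1;
    ivec votes(M), held(M);
    std::vector<BestModel> models(M);
    for (uword j = 0; j < M; ++j) {
      const uword jsub = train(j);
      uvec subset(M - 1);
      uword q2 = 0;
      for (uword s = 0; s < M; ++s) if (s != j) subset(q2++) = train(s);
      vec ytr = y.elem(subset);
      BestModel best;
      for (int k = 0; k < Knet; ++k) {
        mat Ftr = F[k].rows(subset);
        eval_net_features(Ftr, ytr, F[k].row(jsub), y(jsub), F[k].row(t),
                          lasso_grid, C, svm_tol, svm_max_pass,
                          lasso_tol_rel, lasso_max_iter, k, best);
      }
      models[j] = best;
      votes(j) = best.vote;
      held(j) = (int)jsub + 1;
    }
    folds[t] = pack_fold((int)t + 1, held, votes, models, y(t));
  }
  return folds;
}

// Extract the upper-triangle feature row (pairs (i,j), i<j, in the order
// (1,2),(1,3),...,(1,R),(2,3),...) from a symmetric matrix.
static void upper_row(const mat& S, rowvec& f) {
  const uword R = S.n_rows;
  uword k = 0;
  for (uword i = 0; i < R; ++i)
    for (uword j = i + 1; j < R; ++j) f(k++) = S(i, j);
}

// Group sparse representation engine.  The group problem for every training
// subset is solved from per-subject Gram matrices; held-out subjects (the
// inner validation subject and the outer test subject) are encoded by
// support-restricted least squares so that their own data never enter
// support learning.
// [[Rcpp::export]]
Rcpp::List cpp_cv_gsr(const arma::cube& G, const arma::vec& y,
                      const arma::vec& rel_grid, const arma::vec& lasso_grid,
                      double C, double svm_tol, int svm_max_pass,
                      double group_tol_rel, int group_max_iter,
                      double lasso_tol_rel, int lasso_max_iter,
                      double ridge_rel) {
  const uword R = G.n_rows, N = G.n_slices;
  const uword P = R * (R - 1) / 2;
  const int Knet = rel_grid.n_elem;
  // diagonal scale (= T - 1 for z-scored columns) sets the solver tolerance
  double dscale = 0.0;
  for (uword i = 0; i < N; ++i) dscale = std::max(dscale, G.slice(i).max());
  const double gtol = group_tol_rel * std::max(dscale, 1.0);

  int n_ridge_total = 0;

  Rcpp::List folds(N);
  for (uword t = 0; t < N; ++t) {
    uvec train(N - 1);
    uword q = 0;
    for (uword s = 0; s < N; ++s) if (s != t) train(q++) = s;
    const uword M = N - 1;
    ivec votes(M), held(M);
    std::vector<BestModel> models(M);

    for (uword j = 0; j < M; ++j) {
      const uword jsub = train(j);
      uvec subset(M - 1);
      uword q2 = 0;
      for (uword s = 0; s < M; ++s) if (s != j) subset(q2++) = train(s);
      const uword n = subset.n_elem;
      vec ytr = y.elem(subset);

      const double lmax = gsr_lambda_max(G, subset);
      // solve at decreasing lambda for warm starts; store by grid index
      uvec ord = sort_index(rel_grid, "descend");
      std::vector<mat> feats(Knet);       // n x P
      std::vector<rowvec> fval(Knet), ftest(Knet);

      // per-ROI warm-started path across the (descending) lambda sequence
      std::vector<mat> Wr(R), GVr(R);
      for (uword r = 0; r < R; ++r) {
        Wr[r] = mat(R, n, fill::zeros);
        GVr[r] = mat(R, n, fill::zeros);
      }
      for (int lo = 0; lo < Knet; ++lo) {
        const int k = (int)ord(lo);
        const double lam = rel_grid(k) * lmax;
        Rcpp::List supports(R);
        cube raws(R, R, n, fill::zeros);
        for (uword r = 0; r < R; ++r) {
          int it; double kk;
          group_cd_core(G, subset, r, lam, Wr[r], GVr[r], gtol,
                        group_max_iter, it, kk);
          std::vector<int> sup;
          for (uword jj = 0; jj < R; ++jj) {
            double s2 = 0.0;
            for (uword i = 0; i < n; ++i) s2 += Wr[r](jj, i) * Wr[r](jj, i);
            if (s2 > 0.0) sup.push_back((int)jj + 1);
          }
          supports[r] = Rcpp::IntegerVector(sup.begin(), sup.end());
          for (uword i = 0; i < n; ++i)
            for (uword jj = 0; jj < R; ++jj) raws(r, jj, i) = Wr[r](jj, i);
        }
        // training-subject features
        feats[k] = mat(n, P);
        rowvec f(P);
        int nclip = 0;
        for (uword i = 0; i < n; ++i) {
          mat S = finalize_raw(raws.slice(i), nclip);
          upper_row(S, f);
          feats[k].row(i) = f;
        }
        // encode held-out subjects at the single-subject equivalent penalty
        const double lam_enc = lam / std::sqrt((double)n);
        mat rawv = encode_from_gram(G.slice(jsub), supports, lam_enc,
                                    ridge_rel, gtol, n_ridge_total);
        mat Sv = finalize_raw(rawv, nclip);
        fval[k] = rowvec(P);
        upper_row(Sv, fval[k]);
        mat rawt = encode_from_gram(G.slice(t), supports, lam_enc,
                                    ridge_rel, gtol, n_ridge_total);
        mat St = finalize_raw(rawt, nclip);
        ftest[k] = rowvec(P);
        upper_row(St, ftest[k]);
      }

      BestModel best;
      for (int k = 0; k < Knet; ++k)
        eval_net_features(feats[k], ytr, fval[k], y(jsub), ftest[k],
                          lasso_grid, C, svm_tol, svm_max_pass,
                          lasso_tol_rel, lasso_max_iter, k, best);
      models[j] = best;
      votes(j) = best.vote;
      held(j) = (int)jsub + 1;
    }
    folds[t] = pack_fold((int)t + 1, held, votes, models, y(t));
  }
  return Rcpp::List::create(Rcpp::Named("folds") = folds,
                            Rcpp::Named("n_ridge") = n_ridge_total);
}
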