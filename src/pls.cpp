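// Fast PLS1 (NIPALS) with k-fold RMSECV, the inner loop of the wavelength
// selectors. NIPALS yields nested models, so one fit gives predictions for
// every component count up to ncomp at almost no extra cost; the CV helpers
// exploit that for component selection.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Fit PLS1 on (X, y); fill betas (p x ncomp, column a = coefficients of the
// (a+1)-component model) and intercepts. Components stop early if residual
// X or y variance is exhausted; later columns then repeat the last model.
static void pls1_betas(const mat& X, const vec& y, int ncomp,
                       mat& betas, rowvec& intercepts) {
  const uword p = X.n_cols;
  rowvec xm = mean(X, 0);
  double ym = mean(y);
  mat E = X.each_row() - xm;
  vec f = y - ym;

  mat W(p, ncomp, fill::zeros), P(p, ncomp, fill::zeros);
  vec q(ncomp, fill::zeros);
  int used = 0;
  for (int a = 0; a < ncomp; ++a) {
    vec w = E.t() * f;
    double wn = norm(w);
    if (wn < 1e-12) break;
    w /= wn;
    vec t = E * w;
    double tt = dot(t, t);
    if (tt < 1e-12) break;
    vec pv = E.t() * t / tt;
    double qa = dot(f, t) / tt;
    E -= t * pv.t();
    f -= qa * t;
    W.col(a) = w;
    P.col(a) = pv;
    q(a) = qa;
    ++used;
  }

  betas.zeros(p, ncomp);
  intercepts.zeros(ncomp);
  for (int a = 0; a < ncomp; ++a) {
    int k = std::min(a + 1, used);
    if (k == 0) { intercepts(a) = ym; continue; }
    mat Wk = W.cols(0, k - 1);
    mat Pk = P.cols(0, k - 1);
    vec beta = Wk * solve(Pk.t() * Wk, q.subvec(0, k - 1));
    betas.col(a) = beta;
    intercepts(a) = ym - dot(xm, beta);
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_pls_fit(const arma::mat& X, const arma::vec& y, int ncomp) {
  mat betas;
  rowvec intercepts;
  pls1_betas(X, y, ncomp, betas, intercepts);
  return Rcpp::List::create(Rcpp::Named("coef") = betas,
                            Rcpp::Named("intercept") = intercepts);
}

// Out-of-fold squared errors for every component count 1..max_ncomp.
// fold_ids are 1-based fold labels of length n.
static vec cv_sse_path(const mat& X, const vec& y, int max_ncomp,
                       const ivec& fold_ids, int n_folds) {
  const uword n = X.n_rows;
  vec sse(max_ncomp, fill::zeros);
  for (int f = 1; f <= n_folds; ++f) {
    uvec test = find(fold_ids == f);
    uvec train = find(fold_ids != f);
    if (test.n_elem == 0) continue;
    mat Xtr = X.rows(train);
    vec ytr = y.elem(train);
    mat Xte = X.rows(test);
    vec yte = y.elem(test);
    int nc = std::min((int)std::min((uword)max_ncomp, Xtr.n_cols),
                      (int)Xtr.n_rows - 1);
    if (nc < 1) nc = 1;
    mat betas;
    rowvec intercepts;
    pls1_betas(Xtr, ytr, nc, betas, intercepts);
    for (int a = 0; a < max_ncomp; ++a) {
      int k = std::min(a, nc - 1);
      vec pred = Xte * betas.col(k) + intercepts(k);
      sse(a) += accu(square(yte - pred));
    }
  }
  return sse / (double)n;
}

// [[Rcpp::export]]
arma::vec cpp_cv_rmse_path(const arma::mat& X, const arma::vec& y,
                           int max_ncomp, const arma::ivec& fold_ids) {
  int n_folds = fold_ids.max();
  return sqrt(cv_sse_path(X, y, max_ncomp, fold_ids, n_folds));
}

// Pooled RMSECV of the column subset cols0 (0-based) at a fixed component
// count (capped by subset size and training-set size). Empty subset falls
// back to the training-mean predictor.
static double rmsecv_subset(const mat& X, const vec& y, const uvec& cols0,
                            int ncomp, const ivec& fold_ids, int n_folds) {
  const uword n = X.n_rows;
  double sse = 0.0;
  for (int f = 1; f <= n_folds; ++f) {
    uvec test = find(fold_ids == f);
    uvec train = find(fold_ids != f);
    if (test.n_elem == 0) continue;
    vec ytr = y.elem(train);
    vec yte = y.elem(test);
    if (cols0.n_elem == 0) {
      double m = mean(ytr);
      sse += accu(square(yte - m));
      continue;
    }
    mat Xtr = X.submat(train, cols0);
    mat Xte = X.submat(test, cols0);
    int nc = std::min((int)std::min((uword)ncomp, cols0.n_elem),
                      (int)train.n_elem - 1);
    if (nc < 1) nc = 1;
    mat betas;
    rowvec intercepts;
    pls1_betas(Xtr, ytr, nc, betas, intercepts);
    vec pred = Xte * betas.col(nc - 1) + intercepts(nc - 1);
    sse += accu(square(yte - pred));
  }
  return std::sqrt(sse / (double)n);
}

// [[Rcpp::export]]
double cpp_rmsecv_subset(const arma::mat& X, const arma::vec& y,
                         const arma::uvec& cols0, int ncomp,
                         const arma::ivec& fold_ids) {
  return rmsecv_subset(X, y, cols0, ncomp, fold_ids, fold_ids.max());
}

// One IRIV sweep: for every row k of the binary inclusion matrix A
// (n_rows x p), column 0 of the result is the RMSECV of the row's design
// as given; column j (1-based over variables) is the RMSECV with variable
// j's inclusion flipped. Component count = min(cap, |subset|, n_train - 1).
// [[Rcpp::export]]
arma::mat cpp_iriv_rmsecv(const arma::mat& X, const arma::vec& y,
                          const arma::imat& A, int ncomp_cap,
                          const arma::ivec& fold_ids) {
  const uword n_rows = A.n_rows;
  const uword p = A.n_cols;
  int n_folds = fold_ids.max();
  mat out(n_rows, p + 1);

  for (uword k = 0; k < n_rows; ++k) {
    std::vector<uword> incl;
    incl.reserve(p);
    for (uword j = 0; j < p; ++j)
      if (A(k, j) == 1) incl.push_back(j);
    uvec base(incl);
    out(k, 0) = rmsecv_subset(X, y, base, ncomp_cap, fold_ids, n_folds);

    for (uword j = 0; j < p; ++j) {
      std::vector<uword> flip;
      flip.reserve(incl.size() + 1);
      bool present = (A(k, j) == 1);
      for (uword c : incl)
        if (c != j) flip.push_back(c);
      if (!present) {
        flip.push_back(j);
        std::sort(flip.begin(), flip.end());
      }
      uvec sub(flip);
      out(k, j + 1) = rmsecv_subset(X, y, sub, ncomp_cap, fold_ids, n_folds);
    }
    if (k % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
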