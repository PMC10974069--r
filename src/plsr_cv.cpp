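#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Pooled held-out NIPALS PLS1 predictions for component counts 1..maxcomp.
// For each fold: autoscale the training rows (zero-variance columns are
// neutralized), run NIPALS with X-deflation, and accumulate held-out
// predictions sequentially per component. Degenerate tails (X fully
// deflated) carry the last attainable prediction forward.
static mat cv_predictions_core(const mat& X, const vec& y,
                               const ivec& fold_id, const int maxcomp) {
  const uword n = X.n_rows, p = X.n_cols;
  const int nfold = fold_id.max();
  mat pred(n, (uword)maxcomp, fill::zeros);

  for (int f = 1; f <= nfold; ++f) {
    uvec test = find(fold_id == f);
    uvec train = find(fold_id != f);
    if (test.n_elem == 0) continue;

    mat Xt = X.rows(train);
    vec yt = y.elem(train);
    rowvec xm = mean(Xt, 0);
    rowvec xs = stddev(Xt, 0, 0);  // ddof = 1
    xs.elem(find(xs < 1e-12)).fill(datum::inf);  // zero-variance -> scaled to 0
    double ym = mean(yt), ys = stddev(yt);
    if (ys < 1e-12) ys = 1.0;

    mat Xc = Xt;
    Xc.each_row() -= xm;
    Xc.each_row() /= xs;
    vec yc = (yt - ym) / ys;

    mat Xv = X.rows(test);
    Xv.each_row() -= xm;
    Xv.each_row() /= xs;
    vec yhat(test.n_elem, fill::zeros);  // scaled-space running prediction

    int ncomp_max = std::min<int>(maxcomp, std::min<uword>(train.n_elem - 1, p));
    int k = 0;
    for (; k < ncomp_max; ++k) {
      vec w = Xc.t() * yc;
      double wn = norm(w);
      if (wn < 1e-12) break;
      w /= wn;
      vec t = Xc * w;
      double tt = dot(t, t);
      if (tt < 1e-24) break;
      vec pl = Xc.t() * t / tt;
      double q = dot(yc, t) / tt;
      vec tv = Xv * w;
      yhat += q * tv;
      Xc -= t * pl.t();
      Xv -= tv * pl.t();
      yc -= q * t;
      for (uword j = 0; j < test.n_elem; ++j)
        pred(test(j), (uword)k) = ym + ys * yhat(j);
    }
    for (int kk = k; kk < maxcomp; ++kk)
      for (uword j = 0; j < test.n_elem; ++j)
        pred(test(j), (uword)kk) = (k > 0) ? pred(test(j), (uword)(k - 1)) : ym;
  }
  return pred;
}

// [[Rcpp::export(name = ".plsr_cv_predictions")]]
Rcpp::NumericMatrix plsr_cv_predictions(const arma::mat& X,
                                        const arma::vec& y,
                                        const arma::ivec& fold_id,
                                        const int maxcomp) {
  return Rcpp::wrap(cv_predictions_core(X, y, fold_id, maxcomp));
}

// Batch GA fitness: for each row of `masks`, cross-validate PLSR on the
// column subset and return min-over-ncomp pooled RMSEcv. Masks with fewer
// than min_bands columns get +Inf. The per-mask component cap is
// min(maxcomp, n_bands, smallest training fold - 1).
// [[Rcpp::export(name = ".ga_population_fitness")]]
Rcpp::NumericVector ga_population_fitness(const arma::mat& X,
                                          const arma::vec& y,
                                          const Rcpp::LogicalMatrix& masks,
                                          const arma::ivec& fold_id,
                                          const int maxcomp,
                                          const int min_bands) {
  const int npop = masks.nrow();
  const uword n = X.n_rows;
  // smallest training-fold size
  const int nfold = fold_id.max();
  uword max_fold = 0;
  for (int f = 1; f <= nfold; ++f) {
    uword sz = accu(fold_id == f);
    if (sz > max_fold) max_fold = sz;
  }
  const int train_cap = (int)(n - max_fold) - 1;

  Rcpp::NumericVector out(npop);
  for (int i = 0; i < npop; ++i) {
    std::vector<uword> cols;
    for (int j = 0; j < masks.ncol(); ++j)
      if (masks(i, j)) cols.push_back((uword)j);
    if ((int)cols.size() < min_bands) {
      out[i] = R_PosInf;
      continue;
    }
    int mc = std::min<int>(maxcomp, std::min<int>((int)cols.size(), train_cap));
    if (mc < 1) { out[i] = R_PosInf; continue; }
    mat Xs = X.cols(uvec(cols));
    mat pred = cv_predictions_core(Xs, y, fold_id, mc);
    double best = datum::inf;
    for (int k = 0; k < mc; ++k) {
      double rmse = std::sqrt(accu(square(pred.col(k) - y)) / n);
      if (rmse < best) best = rmse;
    }
    out[i] = best;
  }
  return out;
}
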