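// Mini-batch training epoch for the fully connected regressor.
//
// The network state (weights, biases, Adam moments) is updated in place:
// the matrices are created fresh inside train() and owned exclusively by
// it, so aliasing R's copy-on-write semantics is safe here and avoids
// reallocating ~megabyte temporaries for every Adam update.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;


// one epoch of Adam/MSE training; returns mean train loss over the epoch,
// or NA if the loss became non-finite
// [[Rcpp::export]]
double mlp_train_epoch(NumericMatrix Xtr, NumericMatrix Ytr,
                       IntegerVector order, int batch_size,
                       List W_, List b_, List mW_, List vW_,
                       List mb_, List vb_,
                       double lr, double beta1, double beta2, double eps,
                       int step0, bool relu) {
  const arma::mat X(Xtr.begin(), Xtr.nrow(), Xtr.ncol(), false, true);
  const arma::mat Y(Ytr.begin(), Ytr.nrow(), Ytr.ncol(), false, true);
  const int L = W_.size();
  // aliasing views into the R-owned arrays: emplace_back constructs the
  // non-copying advanced-constructor matrices in place (a push_back of a
  // temporary would deep-copy and break the in-place contract)
  std::vector<arma::mat> W, mW, vW;
  std::vector<arma::vec> b, mb, vb;
  W.reserve(L); mW.reserve(L); vW.reserve(L);
  b.reserve(L); mb.reserve(L); vb.reserve(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix wl = as<NumericMatrix>(W_[l]);
    NumericMatrix mwl = as<NumericMatrix>(mW_[l]);
    NumericMatrix vwl = as<NumericMatrix>(vW_[l]);
    NumericVector bl = as<NumericVector>(b_[l]);
    NumericVector mbl = as<NumericVector>(mb_[l]);
    NumericVector vbl = as<NumericVector>(vb_[l]);
    W.emplace_back(wl.begin(), wl.nrow(), wl.ncol(), false, false);
    mW.emplace_back(mwl.begin(), mwl.nrow(), mwl.ncol(), false, false);
    vW.emplace_back(vwl.begin(), vwl.nrow(), vwl.ncol(), false, false);
    b.emplace_back(bl.begin(), bl.size(), false, false);
    mb.emplace_back(mbl.begin(), mbl.size(), false, false);
    vb.emplace_back(vbl.begin(), vbl.size(), false, false);
  }
  const int n = order.size();
  const int n_out = Y.n_cols;
  double loss_sum = 0.0;
  int step = step0;

  std::vector<arma::mat> Z(L - 1), H(L - 1), gW(L);
  std::vector<arma::vec> gb(L);

  for (int start = 0; start < n; start += batch_size) {
    const int nb = std::min(batch_size, n - start);
    arma::uvec idx(nb);
    for (int i = 0; i < nb; ++i) idx[i] = order[start + i] - 1;
    arma::mat xb = X.rows(idx);
    arma::mat yb = Y.rows(idx);

    // forward
    arma::mat a = xb;
    for (int l = 0; l < L - 1; ++l) {
      Z[l] = a * W[l];
      Z[l].each_row() += b[l].t();
      H[l] = relu ? arma::clamp(Z[l], 0.0, arma::datum::inf) : Z[l];
      a = H[l];
    }
    arma::mat P = a * W[L - 1];
    P.each_row() += b[L - 1].t();

    arma::mat err = P - yb;
    const double loss = arma::accu(arma::square(err)) / (nb * n_out);
    if (!std::isfinite(loss)) return NA_REAL;
    loss_sum += loss * nb;

    // backward
    arma::mat d = err * (2.0 / (nb * n_out));
    for (int l = L - 1; l >= 0; --l) {
      const arma::mat &inp = (l == 0) ? xb : H[l - 1];
      gW[l] = inp.t() * d;
      gb[l] = arma::sum(d, 0).t();
      if (l > 0) {
        d = d * W[l].t();
        if (relu) d %= arma::conv_to<arma::mat>::from(Z[l - 1] > 0.0);
      }
    }

    // adam
    ++step;
    const double c1 = 1.0 - std::pow(beta1, step);
    const double c2 = 1.0 - std::pow(beta2, step);
    for (int l = 0; l < L; ++l) {
      mW[l] = beta1 * mW[l] + (1.0 - beta1) * gW[l];
      vW[l] = beta2 * vW[l] + (1.0 - beta2) * arma::square(gW[l]);
      W[l] -= lr * (mW[l] / c1) / (arma::sqrt(vW[l] / c2) + eps);
      mb[l] = beta1 * mb[l] + (1.0 - beta1) * gb[l];
      vb[l] = beta2 * vb[l] + (1.0 - beta2) * arma::square(gb[l]);
      b[l] -= lr * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + eps);
    }
  }
  return loss_sum / n;
}

// batched forward pass (used for the per-epoch test-loss evaluation)
// [[Rcpp::export]]
NumericMatrix mlp_forward_cpp(NumericMatrix X_, List W_, List b_,
                              bool relu) {
  const arma::mat X(X_.begin(), X_.nrow(), X_.ncol(), false, true);
  const int L = W_.size();
  arma::mat a = X;
  for (int l = 0; l < L; ++l) {
    NumericMatrix Wl = as<NumericMatrix>(W_[l]);
    NumericVector bl = as<NumericVector>(b_[l]);
    const arma::mat W(Wl.begin(), Wl.nrow(), Wl.ncol(), false, true);
    const arma::vec b(bl.begin(), bl.size(), false, true);
    a = a * W;
    a.each_row() += b.t();
    if (relu && l < L - 1) a = arma::clamp(a, 0.0, arma::datum::inf);
  }
  return wrap(a);
}
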