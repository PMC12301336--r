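#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Transformer encoder layer (post-norm, ReLU feed-forward) forward and
// backward. Mirrors the reference math exactly: multi-head scaled
// dot-product attention with fused Q/K/V projection, residual + LayerNorm,
// two-layer ReLU feed-forward, residual + LayerNorm. Dropout masks are
// drawn from R's RNG in column-major order, matching matrix(runif(n)).

static const double LN_EPS = 1e-5;

static arma::mat draw_mask(int nr, int nc, double rate) {
  arma::mat m(nr, nc);
  double keep = 1.0 - rate;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      m(i, j) = (unif_rand() >= rate) ? 1.0 / keep : 0.0;
  return m;
}

static void layernorm_fwd(const arma::mat& X, const arma::vec& g,
                          const arma::vec& b, arma::mat& out,
                          arma::mat& xhat, arma::vec& inv) {
  int d = X.n_cols;
  arma::vec mu = arma::mean(X, 1);
  arma::mat xc = X.each_col() - mu;
  arma::vec v = arma::sum(arma::square(xc), 1) / d;
  inv = 1.0 / arma::sqrt(v + LN_EPS);
  xhat = xc.each_col() % inv;
  out = xhat.each_row() % g.t();
  out.each_row() += b.t();
}

static void layernorm_bwd(const arma::mat& dout, const arma::mat& xhat,
                          const arma::vec& inv, const arma::vec& g,
                          arma::mat& dX, arma::vec& dg, arma::vec& db) {
  int d = xhat.n_cols;
  arma::mat dxhat = dout.each_row() % g.t();
  dg = arma::sum(dout % xhat, 0).t();
  db = arma::sum(dout, 0).t();
  arma::vec rs1 = arma::sum(dxhat, 1) / d;
  arma::vec rs2 = arma::sum(dxhat % xhat, 1) / d;
  dX = dxhat;
  dX.each_col() -= rs1;
  dX -= xhat.each_col() % rs2;
  dX.each_col() %= inv;
}

// rowwise softmax with max subtraction
static arma::mat softmax_rows(const arma::mat& S) {
  arma::vec m = arma::max(S, 1);
  arma::mat e = arma::exp(S.each_col() - m);
  arma::vec z = arma::sum(e, 1);
  return e.each_col() / z;
}

// params: list(attn = list(heads = list(list(Wq, Wk, Wv), ...), Wo),
//              W1, b1, W2, b2, ln1 = list(g, b), ln2 = list(g, b))
// [[Rcpp::export]]
List encoder_fwd_cpp(const arma::mat& X, List params, double dropout,
                     bool train_mode) {
  RNGScope scope;
  List attn = params["attn"];
  List heads = attn["heads"];
  arma::mat Wo = as<arma::mat>(attn["Wo"]);
  int h = heads.size();
  List h0 = heads[0];
  int dk = as<arma::mat>(h0["Wq"]).n_cols;
  int T = X.n_rows, dm = X.n_cols;
  double scale = 1.0 / std::sqrt((double)dk);

  arma::mat Wall(dm, 3 * h * dk);
  for (int i = 0; i < h; ++i) {
    List hp = heads[i];
    Wall.cols(i * 3 * dk, i * 3 * dk + dk - 1) = as<arma::mat>(hp["Wq"]);
    Wall.cols(i * 3 * dk + dk, i * 3 * dk + 2 * dk - 1) = as<arma::mat>(hp["Wk"]);
    Wall.cols(i * 3 * dk + 2 * dk, i * 3 * dk + 3 * dk - 1) = as<arma::mat>(hp["Wv"]);
  }
  arma::mat PRJ = X * Wall;
  if (!PRJ.is_finite()) stop("non-finite values encountered in attention projections");

  arma::mat M(T, h * dk);
  List Ps(h);
  for (int i = 0; i < h; ++i) {
    arma::mat Q = PRJ.cols(i * 3 * dk, i * 3 * dk + dk - 1);
    arma::mat K = PRJ.cols(i * 3 * dk + dk, i * 3 * dk + 2 * dk - 1);
    arma::mat V = PRJ.cols(i * 3 * dk + 2 * dk, i * 3 * dk + 3 * dk - 1);
    arma::mat S = Q * K.t() * scale;
    if (!S.is_finite()) stop("non-finite values encountered in attention logits");
    arma::mat P = softmax_rows(S);
    M.cols(i * dk, (i + 1) * dk - 1) = P * V;
    Ps[i] = P;
  }
  arma::mat mo = M * Wo;

  arma::mat m1, m2;
  bool use_drop = train_mode && dropout > 0;
  if (use_drop) m1 = draw_mask(T, dm, dropout);
  arma::mat r1 = use_drop ? arma::mat(X + mo % m1) : arma::mat(X + mo);

  arma::mat y, xhat1;
  arma::vec inv1;
  layernorm_fwd(r1, as<arma::vec>(as<List>(params["ln1"])["g"]),
    as<arma::vec>(as<List>(params["ln1"])["b"]), y, xhat1, inv1);

  arma::mat W1 = as<arma::mat>(params["W1"]);
  arma::vec b1 = as<arma::vec>(params["b1"]);
  arma::mat W2 = as<arma::mat>(params["W2"]);
  arma::vec b2 = as<arma::vec>(params["b2"]);
  arma::mat Z1 = y * W1;
  Z1.each_row() += b1.t();
  arma::mat H1 = arma::clamp(Z1, 0.0, arma::datum::inf);
  arma::mat F = H1 * W2;
  F.each_row() += b2.t();
  if (use_drop) m2 = draw_mask(T, dm, dropout);
  arma::mat r2 = use_drop ? arma::mat(y + F % m2) : arma::mat(y + F);

  arma::mat out, xhat2;
  arma::vec inv2;
  layernorm_fwd(r2, as<arma::vec>(as<List>(params["ln2"])["g"]),
    as<arma::vec>(as<List>(params["ln2"])["b"]), out, xhat2, inv2);

  List cache = List::create(
    _["X"] = X, _["M"] = M, _["Ps"] = Ps, _["PRJ"] = PRJ, _["Wall"] = Wall,
    _["y"] = y, _["H1"] = H1,
    _["xhat1"] = xhat1, _["inv1"] = inv1,
    _["xhat2"] = xhat2, _["inv2"] = inv2,
    _["m1"] = R_NilValue, _["m2"] = R_NilValue,
    _["dk"] = dk, _["heads"] = h
  );
  if (use_drop) {
    cache["m1"] = m1;
    cache["m2"] = m2;
  }
  return List::create(_["out"] = out, _["scores"] = Ps, _["cache"] = cache);
}

// [[Rcpp::export]]
List encoder_bwd_cpp(const arma::mat& dout, List cache, List params) {
  List attn = params["attn"];
  List heads = attn["heads"];
  arma::mat Wo = as<arma::mat>(attn["Wo"]);
  arma::mat W1 = as<arma::mat>(params["W1"]);
  arma::mat W2 = as<arma::mat>(params["W2"]);
  int h = cache["heads"];
  int dk = cache["dk"];
  double scale = 1.0 / std::sqrt((double)dk);

  arma::mat X = as<arma::mat>(cache["X"]);
  arma::mat M = as<arma::mat>(cache["M"]);
  arma::mat PRJ = as<arma::mat>(cache["PRJ"]);
  arma::mat Wall = as<arma::mat>(cache["Wall"]);
  arma::mat y = as<arma::mat>(cache["y"]);
  arma::mat H1 = as<arma::mat>(cache["H1"]);
  List Ps = cache["Ps"];
  bool use_drop = !Rf_isNull(cache["m1"]);

  // second LayerNorm
  arma::mat dr2, dX2;
  arma::vec dg2, db2ln;
  layernorm_bwd(dout, as<arma::mat>(cache["xhat2"]),
    as<arma::vec>(cache["inv2"]),
    as<arma::vec>(as<List>(params["ln2"])["g"]), dr2, dg2, db2ln);

  arma::mat dF = use_drop ? arma::mat(dr2 % as<arma::mat>(cache["m2"])) : dr2;
  arma::mat dW2 = H1.t() * dF;
  arma::vec db2 = arma::sum(dF, 0).t();
  arma::mat dH1 = dF * W2.t();
  arma::mat dZ1 = dH1;
  dZ1.elem(arma::find(H1 <= 0)).zeros();
  arma::mat dW1 = y.t() * dZ1;
  arma::vec db1 = arma::sum(dZ1, 0).t();
  arma::mat dy = dr2 + dZ1 * W1.t();

  // first LayerNorm
  arma::mat dr1;
  arma::vec dg1, db1ln;
  layernorm_bwd(dy, as<arma::mat>(cache["xhat1"]),
    as<arma::vec>(cache["inv1"]),
    as<arma::vec>(as<List>(params["ln1"])["g"]), dr1, dg1, db1ln);

  arma::mat da = use_drop ? arma::mat(dr1 % as<arma::mat>(cache["m1"])) : dr1;

  // attention backward
  arma::mat dM = da * Wo.t();
  arma::mat dWo = M.t() * da;
  arma::mat dPRJ(X.n_rows, 3 * h * dk, arma::fill::zeros);
  for (int i = 0; i < h; ++i) {
    arma::mat P = as<arma::mat>(Ps[i]);
    arma::mat Q = PRJ.cols(i * 3 * dk, i * 3 * dk + dk - 1);
    arma::mat K = PRJ.cols(i * 3 * dk + dk, i * 3 * dk + 2 * dk - 1);
    arma::mat V = PRJ.cols(i * 3 * dk + 2 * dk, i * 3 * dk + 3 * dk - 1);
    arma::mat dH = dM.cols(i * dk, (i + 1) * dk - 1);
    arma::mat dP = dH * V.t();
    arma::mat dV = P.t() * dH;
    arma::vec rs = arma::sum(dP % P, 1);
    arma::mat dS = P % (dP.each_col() - rs);
    dPRJ.cols(i * 3 * dk, i * 3 * dk + dk - 1) = dS * K * scale;
    dPRJ.cols(i * 3 * dk + dk, i * 3 * dk + 2 * dk - 1) = dS.t() * Q * scale;
    dPRJ.cols(i * 3 * dk + 2 * dk, i * 3 * dk + 3 * dk - 1) = dV;
  }
  arma::mat gWall = X.t() * dPRJ;
  arma::mat dX = dr1 + dPRJ * Wall.t();

  List gheads(h);
  for (int i = 0; i < h; ++i) {
    gheads[i] = List::create(
      _["Wq"] = gWall.cols(i * 3 * dk, i * 3 * dk + dk - 1),
      _["Wk"] = gWall.cols(i * 3 * dk + dk, i * 3 * dk + 2 * dk - 1),
      _["Wv"] = gWall.cols(i * 3 * dk + 2 * dk, i * 3 * dk + 3 * dk - 1)
    );
  }
  List grads = List::create(
    _["attn"] = List::create(_["heads"] = gheads, _["Wo"] = dWo),
    _["W1"] = dW1, _["b1"] = db1, _["W2"] = dW2, _["b2"] = db2,
    _["ln1"] = List::create(_["g"] = dg1, _["b"] = db1ln),
    _["ln2"] = List::create(_["g"] = dg2, _["b"] = db2ln)
  );
  return List::create(_["dX"] = dX, _["grads"] = grads);
}

// ---- fused per-pair stack: encoder layers + mean pool + ReLU projection --
// The forward keeps every intermediate in a C++ cache behind an external
// pointer, so nothing is copied back to R between forward and backward.

struct LayerCache {
  arma::mat X, M, PRJ, Wall, y, H1, xhat1, xhat2, m1, m2;
  arma::vec inv1, inv2;
  std::vector<arma::mat> P;
  bool drop;
};

struct StackCache {
  std::vector<LayerCache> layers;
  arma::mat Z;      // final token matrix
  arma::vec m;      // mean-pooled token
  arma::vec z;      // pre-activation of the projection
  int dk, h;
};

static void layer_forward(const arma::mat& X, List params, double dropout,
                          bool train_mode, LayerCache& lc, arma::mat& out) {
  List attn = params["attn"];
  List heads = attn["heads"];
  arma::mat Wo = as<arma::mat>(attn["Wo"]);
  int h = heads.size();
  List h0 = heads[0];
  int dk = as<arma::mat>(h0["Wq"]).n_cols;
  int T = X.n_rows, dm = X.n_cols;
  double scale = 1.0 / std::sqrt((double)dk);

  lc.X = X;
  lc.Wall.set_size(dm, 3 * h * dk);
  for (int i = 0; i < h; ++i) {
    List hp = heads[i];
    lc.Wall.cols(i * 3 * dk, i * 3 * dk + dk - 1) = as<arma::mat>(hp["Wq"]);
    lc.Wall.cols(i * 3 * dk + dk, i * 3 * dk + 2 * dk - 1) = as<arma::mat>(hp["Wk"]);
    lc.Wall.cols(i * 3 * dk + 2 * dk, i * 3 * dk + 3 * dk - 1) = as<arma::mat>(hp["Wv"]);
  }
  lc.PRJ = X * lc.Wall;
  if (!lc.PRJ.is_finite()) stop("non-finite values encountered in attention projections");
  lc.M.set_size(T, h * dk);
  lc.P.resize(h);
  for (int i = 0; i < h; ++i) {
    arma::mat Q = lc.PRJ.cols(i * 3 * dk, i * 3 * dk + dk - 1);
    arma::mat K = lc.PRJ.cols(i * 3 * dk + dk, i * 3 * dk + 2 * dk - 1);
    arma::mat V = lc.PRJ.cols(i * 3 * dk + 2 * dk, i * 3 * dk + 3 * dk - 1);
    arma::mat S = Q * K.t() * scale;
    if (!S.is_finite()) stop("non-finite values encountered in attention logits");
    lc.P[i] = softmax_rows(S);
    lc.M.cols(i * dk, (i + 1) * dk - 1) = lc.P[i] * V;
  }
  arma::mat mo = lc.M * Wo;
  lc.drop = train_mode && dropout > 0;
  arma::mat r1;
  if (lc.drop) {
    lc.m1 = draw_mask(T, dm, dropout);
    r1 = X + mo % lc.m1;
  } else {
    r1 = X + mo;
  }
  layernorm_fwd(r1, as<arma::vec>(as<List>(params["ln1"])["g"]),
    as<arma::vec>(as<List>(params["ln1"])["b"]), lc.y, lc.xhat1, lc.inv1);
  // lc.y now holds the post-LN1 activations
  arma::mat W1 = as<arma::mat>(params["W1"]);
  arma::vec b1 = as<arma::vec>(params["b1"]);
  arma::mat W2 = as<arma::mat>(params["W2"]);
  arma::vec b2 = as<arma::vec>(params["b2"]);
  arma::mat Z1 = lc.y * W1;
  Z1.each_row() += b1.t();
  lc.H1 = arma::clamp(Z1, 0.0, arma::datum::inf);
  arma::mat F = lc.H1 * W2;
  F.each_row() += b2.t();
  arma::mat r2;
  if (lc.drop) {
    lc.m2 = draw_mask(T, dm, dropout);
    r2 = lc.y + F % lc.m2;
  } else {
    r2 = lc.y + F;
  }
  arma::vec ln2g = as<arma::vec>(as<List>(params["ln2"])["g"]);
  arma::vec ln2b = as<arma::vec>(as<List>(params["ln2"])["b"]);
  layernorm_fwd(r2, ln2g, ln2b, out, lc.xhat2, lc.inv2);
}

static void layer_backward(const arma::mat& dout, const LayerCache& lc,
                           List params, arma::mat& dX, List& grads) {
  List attn = params["attn"];
  List heads = attn["heads"];
  arma::mat Wo = as<arma::mat>(attn["Wo"]);
  arma::mat W1 = as<arma::mat>(params["W1"]);
  arma::mat W2 = as<arma::mat>(params["W2"]);
  int h = lc.P.size();
  int dk = lc.M.n_cols / h;
  double scale = 1.0 / std::sqrt((double)dk);

  arma::mat dr2;
  arma::vec dg2, db2ln;
  layernorm_bwd(dout, lc.xhat2, lc.inv2,
    as<arma::vec>(as<List>(params["ln2"])["g"]), dr2, dg2, db2ln);
  arma::mat dF = lc.drop ? arma::mat(dr2 % lc.m2) : dr2;
  arma::mat dW2 = lc.H1.t() * dF;
  arma::vec db2 = arma::sum(dF, 0).t();
  arma::mat dZ1 = dF * W2.t();
  dZ1.elem(arma::find(lc.H1 <= 0)).zeros();
  arma::mat dW1 = lc.y.t() * dZ1;
  arma::vec db1 = arma::sum(dZ1, 0).t();
  arma::mat dy = dr2 + dZ1 * W1.t();
  arma::mat dr1;
  arma::vec dg1, db1ln;
  layernorm_bwd(dy, lc.xhat1, lc.inv1,
    as<arma::vec>(as<List>(params["ln1"])["g"]), dr1, dg1, db1ln);
  arma::mat da = lc.drop ? arma::mat(dr1 % lc.m1) : dr1;

  arma::mat dM = da * Wo.t();
  arma::mat dWo = lc.M.t() * da;
  arma::mat dPRJ(lc.X.n_rows, 3 * h * dk, arma::fill::zeros);
  for (int i = 0; i < h; ++i) {
    const arma::mat& P = lc.P[i];
    arma::mat Q = lc.PRJ.cols(i * 3 * dk, i * 3 * dk + dk - 1);
    arma::mat K = lc.PRJ.cols(i * 3 * dk + dk, i * 3 * dk + 2 * dk - 1);
    arma::mat V = lc.PRJ.cols(i * 3 * dk + 2 * dk, i * 3 * dk + 3 * dk - 1);
    arma::mat dH = dM.cols(i * dk, (i + 1) * dk - 1);
    arma::mat dP = dH * V.t();
    arma::mat dV = P.t() * dH;
    arma::vec rs = arma::sum(dP % P, 1);
    arma::mat dS = P % (dP.each_col() - rs);
    dPRJ.cols(i * 3 * dk, i * 3 * dk + dk - 1) = dS * K * scale;
    dPRJ.cols(i * 3 * dk + dk, i * 3 * dk + 2 * dk - 1) = dS.t() * Q * scale;
    dPRJ.cols(i * 3 * dk + 2 * dk, i * 3 * dk + 3 * dk - 1) = dV;
  }
  arma::mat gWall = lc.X.t() * dPRJ;
  dX = dr1 + dPRJ * lc.Wall.t();

  List gheads(h);
  for (int i = 0; i < h; ++i) {
    gheads[i] = List::create(
      _["Wq"] = gWall.cols(i * 3 * dk, i * 3 * dk + dk - 1),
      _["Wk"] = gWall.cols(i * 3 * dk + dk, i * 3 * dk + 2 * dk - 1),
      _["Wv"] = gWall.cols(i * 3 * dk + 2 * dk, i * 3 * dk + 3 * dk - 1)
    );
  }
  grads = List::create(
    _["attn"] = List::create(_["heads"] = gheads, _["Wo"] = dWo),
    _["W1"] = dW1, _["b1"] = db1, _["W2"] = dW2, _["b2"] = db2,
    _["ln1"] = List::create(_["g"] = dg1, _["b"] = db1ln),
    _["ln2"] = List::create(_["g"] = dg2, _["b"] = db2ln)
  );
}

// [[Rcpp::export]]
List graph_stack_fwd_cpp(const arma::mat& X0, List layers, const arma::mat& Wp,
                         const arma::vec& bp, double dropout, bool train_mode,
                         bool want_scores) {
  RNGScope scope;
  int L = layers.size();
  XPtr<StackCache> ptr(new StackCache(), true);
  ptr->layers.resize(L);
  arma::mat X = X0;
  for (int l = 0; l < L; ++l) {
    arma::mat out;
    layer_forward(X, layers[l], dropout, train_mode, ptr->layers[l], out);
    X = out;
  }
  ptr->Z = X;
  ptr->m = arma::mean(X, 0).t();
  ptr->z = Wp.t() * ptr->m + bp;
  arma::vec feature = arma::clamp(ptr->z, 0.0, arma::datum::inf);

  List scores = R_NilValue;
  if (want_scores) {
    List sc(0);
    for (int l = 0; l < L; ++l) {
      for (size_t i = 0; i < ptr->layers[l].P.size(); ++i) {
        sc.push_back(ptr->layers[l].P[i]);
      }
    }
    scores = sc;
  }
  return List::create(_["feature"] = feature, _["scores"] = scores,
    _["cache"] = ptr);
}

// [[Rcpp::export]]
List graph_stack_bwd_cpp(const arma::vec& dfeat, SEXP cache_ptr, List layers,
                         const arma::mat& Wp) {
  XPtr<StackCache> ptr(cache_ptr);
  int L = layers.size();
  arma::vec dz = dfeat;
  dz.elem(arma::find(ptr->z <= 0)).zeros();
  arma::mat gWp = ptr->m * dz.t();
  arma::vec dm = Wp * dz;
  int T = ptr->Z.n_rows;
  arma::mat dX = arma::repmat(dm.t() / T, T, 1);
  List enc_grads(L);
  for (int l = L - 1; l >= 0; --l) {
    arma::mat dX_prev;
    List g;
    layer_backward(dX, ptr->layers[l], layers[l], dX_prev, g);
    enc_grads[l] = g;
    dX = dX_prev;
  }
  return List::create(
    _["dX"] = dX,
    _["enc"] = enc_grads,
    _["pool"] = List::create(_["Wp"] = gWp, _["bp"] = dz)
  );
}
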