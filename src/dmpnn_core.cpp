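// Single-precision training core for the directed message-passing model.
// Layout convention: feature matrices are stored transposed (features x
// items) so that edge/atom gathers touch contiguous columns; weight
// matrices are (out x in). The R layer owns double-precision prediction;
// this core only accelerates the training loop.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::uvec;

struct Adj {
  std::vector<unsigned int> ptr;  // length n_out + 1
  std::vector<unsigned int> idx;  // gathered column indices
  std::vector<float> w;           // optional weights (empty = all ones)
};

static Adj as_adj(const List& l) {
  Adj a;
  IntegerVector ptr = l["ptr"];
  IntegerVector idx = l["idx"];
  a.ptr.assign(ptr.begin(), ptr.end());
  a.idx.assign(idx.begin(), idx.end());
  if (l.containsElementNamed("w") && !Rf_isNull(l["w"])) {
    NumericVector w = l["w"];
    a.w.assign(w.begin(), w.end());
  }
  return a;
}

// out.col(i) = sum_k w_k * X.col(idx[k]) over the i-th list
static fmat gather_sum(const fmat& X, const Adj& a, arma::uword n_out) {
  fmat out(X.n_rows, n_out, arma::fill::zeros);
  for (arma::uword i = 0; i < n_out; ++i) {
    for (unsigned int k = a.ptr[i]; k < a.ptr[i + 1]; ++k) {
      if (a.w.empty()) out.col(i) += X.col(a.idx[k]);
      else out.col(i) += a.w[k] * X.col(a.idx[k]);
    }
  }
  return out;
}

// transpose of gather_sum: scatter each output column back to its sources
static fmat scatter_add(const fmat& D, const Adj& a, arma::uword n_in) {
  fmat out(D.n_rows, n_in, arma::fill::zeros);
  for (arma::uword i = 0; i < D.n_cols; ++i) {
    for (unsigned int k = a.ptr[i]; k < a.ptr[i + 1]; ++k) {
      if (a.w.empty()) out.col(a.idx[k]) += D.col(i);
      else out.col(a.idx[k]) += a.w[k] * D.col(i);
    }
  }
  return out;
}

struct GraphBatch {
  fmat Xedge, Xatom;   // d_in x E, d_atom x N
  Adj a, b, s;         // edge->edge, atom->edge, mol->atom
  arma::uword E, N, M;
};

static GraphBatch as_graph_batch(const List& l) {
  GraphBatch g;
  g.Xedge = arma::conv_to<fmat>::from(
      arma::mat(as<arma::mat>(l["Xedge"]))).t();
  g.Xatom = arma::conv_to<fmat>::from(
      arma::mat(as<arma::mat>(l["Xatom"]))).t();
  g.a = as_adj(l["a"]);
  g.b = as_adj(l["b"]);
  g.s = as_adj(l["s"]);
  g.E = g.Xedge.n_cols;
  g.N = g.Xatom.n_cols;
  g.M = g.s.ptr.size() - 1;
  return g;
}

struct Batch {
  GraphBatch graph;
  bool has_solvent = false;
  GraphBatch solvent;
  std::vector<unsigned int> smap;  // record -> unique-solvent column
  fmat cond;                       // 2 x M (classification)
  fvec y;
};

struct Encoder {
  fmat W_in, W_h, W_a;
  Encoder zeros_like() const {
    Encoder z;
    z.W_in.zeros(W_in.n_rows, W_in.n_cols);
    z.W_h.zeros(W_h.n_rows, W_h.n_cols);
    z.W_a.zeros(W_a.n_rows, W_a.n_cols);
    return z;
  }
};

struct EncCache {
  std::vector<fmat> H;   // depth+1 states (h x E)
  std::vector<fmat> C;   // concat/message inputs per iteration
  fmat Z, Ca, Aatom, emb;
};

struct Session {
  Encoder enc, solv;
  bool has_solv = false;
  std::vector<fmat> fW;
  std::vector<fvec> fb;
  Encoder m_enc, v_enc, m_solv, v_solv;
  std::vector<fmat> m_fW, v_fW;
  std::vector<fvec> m_fb, v_fb;
  long step = 0;
  int depth = 3, sdepth = 3;
  int rule = 0;  // 0 = concat, 1 = add
  int task = 0;  // 0 = classification, 1 = regression
  float clip = 10.0f;
  std::vector<Batch> train_batches, val_batches;
};

static fmat relu(const fmat& x) { return arma::clamp(x, 0.0f, arma::datum::inf); }

static EncCache encoder_forward(const GraphBatch& g, const Encoder& e,
                                int depth, int rule) {
  EncCache c;
  arma::uword h = e.W_in.n_rows;
  if (g.E > 0) {
    c.H.push_back(relu(e.W_in * g.Xedge));
    for (int t = 0; t < depth; ++t) {
      fmat Mt = gather_sum(c.H[t], g.a, g.E);
      if (rule == 0) {
        fmat Ct = arma::join_cols(c.H[t], Mt);
        c.C.push_back(Ct);
        c.H.push_back(relu(e.W_h * Ct));
      } else {
        c.C.push_back(Mt);
        c.H.push_back(relu(c.H[0] + e.W_h * Mt));
      }
    }
    c.Z = gather_sum(c.H[depth], g.b, g.N);
  } else {
    c.Z.zeros(h, g.N);
  }
  c.Ca = arma::join_cols(g.Xatom, c.Z);
  c.Aatom = relu(e.W_a * c.Ca);
  c.emb = gather_sum(c.Aatom, g.s, g.M);
  return c;
}

static void encoder_backward(const GraphBatch& g, const Encoder& e,
                             const EncCache& c, const fmat& d_emb,
                             int depth, int rule, Encoder& grad) {
  fmat dA = scatter_add(d_emb, g.s, g.N);
  dA %= arma::conv_to<fmat>::from(c.Aatom > 0);
  grad.W_a += dA * c.Ca.t();
  fmat dCa = e.W_a.t() * dA;
  arma::uword d_atom = g.Xatom.n_rows;
  arma::uword h = e.W_in.n_rows;
  if (g.E == 0) return;
  fmat dH = scatter_add(dCa.rows(d_atom, d_atom + h - 1), g.b, g.E);
  fmat dH0_extra;
  bool have_extra = false;
  for (int t = depth - 1; t >= 0; --t) {
    fmat gmask = dH % arma::conv_to<fmat>::from(c.H[t + 1] > 0);
    grad.W_h += gmask * c.C[t].t();
    if (rule == 0) {
      fmat dC = e.W_h.t() * gmask;
      dH = dC.rows(0, h - 1) + scatter_add(dC.rows(h, 2 * h - 1), g.a, g.E);
    } else {
      fmat dM = e.W_h.t() * gmask;
      dH = scatter_add(dM, g.a, g.E);
      if (have_extra) dH0_extra += gmask; else { dH0_extra = gmask; have_extra = true; }
    }
  }
  if (have_extra) dH += dH0_extra;
  dH %= arma::conv_to<fmat>::from(c.H[0] > 0);
  grad.W_in += dH * g.Xedge.t();
}

struct FfnCache {
  std::vector<fmat> acts;  // inputs to each layer (d x M)
  fmat out;
};

static FfnCache ffn_forward(const fmat& U, const std::vector<fmat>& W,
                            const std::vector<fvec>& b) {
  FfnCache c;
  fmat X = U;
  for (size_t l = 0; l < W.size(); ++l) {
    c.acts.push_back(X);
    fmat Zl = W[l] * X;
    Zl.each_col() += b[l];
    X = (l + 1 < W.size()) ? relu(Zl) : Zl;
  }
  c.out = X;
  return c;
}

static fmat ffn_backward(const FfnCache& c, const std::vector<fmat>& W,
                         const fmat& d_out, std::vector<fmat>& gW,
                         std::vector<fvec>& gb) {
  fmat d = d_out;
  for (int l = (int)W.size() - 1; l >= 0; --l) {
    gW[l] += d * c.acts[l].t();
    gb[l] += arma::sum(d, 1);
    d = W[l].t() * d;
    if (l > 0) d %= arma::conv_to<fmat>::from(c.acts[l] > 0);
  }
  return d;
}

static Encoder enc_from_list(const List& l) {
  Encoder e;
  // R stores (in x out); transpose to (out x in)
  e.W_in = arma::conv_to<fmat>::from(as<arma::mat>(l["W_in"])).t();
  e.W_h = arma::conv_to<fmat>::from(as<arma::mat>(l["W_h"])).t();
  e.W_a = arma::conv_to<fmat>::from(as<arma::mat>(l["W_a"])).t();
  return e;
}

static List enc_to_list(const Encoder& e) {
  return List::create(
    _["W_in"] = arma::conv_to<arma::mat>::from(e.W_in.t()),
    _["W_h"] = arma::conv_to<arma::mat>::from(e.W_h.t()),
    _["W_a"] = arma::conv_to<arma::mat>::from(e.W_a.t()));
}

// [[Rcpp::export]]
SEXP pk_cpp_new_session(List params, List config) {
  Session* s = new Session();
  s->enc = enc_from_list(params["encoder"]);
  if (!Rf_isNull(params["solvent"])) {
    s->has_solv = true;
    s->solv = enc_from_list(params["solvent"]);
    s->m_solv = s->solv.zeros_like();
    s->v_solv = s->solv.zeros_like();
  }
  List ffn = params["ffn"];
  for (int l = 0; l < ffn.size(); ++l) {
    List layer = ffn[l];
    fmat W = arma::conv_to<fmat>::from(as<arma::mat>(layer["W"])).t();
    fvec b = arma::conv_to<fvec>::from(as<arma::vec>(layer["b"]));
    s->fW.push_back(W);
    s->fb.push_back(b);
    s->m_fW.push_back(arma::zeros<fmat>(W.n_rows, W.n_cols));
    s->v_fW.push_back(arma::zeros<fmat>(W.n_rows, W.n_cols));
    s->m_fb.push_back(arma::zeros<fvec>(b.n_elem));
    s->v_fb.push_back(arma::zeros<fvec>(b.n_elem));
  }
  s->m_enc = s->enc.zeros_like();
  s->v_enc = s->enc.zeros_like();
  s->depth = as<int>(config["depth"]);
  s->sdepth = as<int>(config["solvent_depth"]);
  s->rule = as<std::string>(config["update_rule"]) == "concat" ? 0 : 1;
  s->task = as<std::string>(config["task"]) == "classification" ? 0 : 1;
  s->clip = as<double>(config["grad_clip"]);
  XPtr<Session> p(s, true);
  return p;
}

static Batch as_batch(const List& l, int task) {
  Batch b;
  b.graph = as_graph_batch(l["graph"]);
  b.y = arma::conv_to<fvec>::from(as<arma::vec>(l["y"]));
  if (task == 0) {
    b.cond = arma::conv_to<fmat>::from(as<arma::mat>(l["cond"])).t();
  } else {
    b.has_solvent = true;
    b.solvent = as_graph_batch(l["solvent"]);
    IntegerVector sm = l["smap"];
    b.smap.assign(sm.begin(), sm.end());
  }
  return b;
}

// [[Rcpp::export]]
void pk_cpp_load_batches(SEXP ptr, List batches, bool validation) {
  XPtr<Session> s(ptr);
  std::vector<Batch>& dst = validation ? s->val_batches : s->train_batches;
  dst.clear();
  for (int i = 0; i < batches.size(); ++i) {
    dst.push_back(as_batch(batches[i], s->task));
  }
}

static double enc_sumsq(const Encoder& e) {
  return arma::accu(arma::square(e.W_in)) + arma::accu(arma::square(e.W_h)) +
         arma::accu(arma::square(e.W_a));
}

static void enc_scale(Encoder& e, float f) {
  e.W_in *= f; e.W_h *= f; e.W_a *= f;
}

static void adam_mat(fmat& w, fmat& m, fmat& v, const fmat& g, float lr,
                     float c1, float c2) {
  m = 0.9f * m + 0.1f * g;
  v = 0.999f * v + 0.001f * (g % g);
  w -= lr * (m / c1) / (arma::sqrt(v / c2) + 1e-8f);
}

static void adam_vec(fvec& w, fvec& m, fvec& v, const fvec& g, float lr,
                     float c1, float c2) {
  m = 0.9f * m + 0.1f * g;
  v = 0.999f * v + 0.001f * (g % g);
  w -= lr * (m / c1) / (arma::sqrt(v / c2) + 1e-8f);
}

// One full pass over the loaded training batches; returns the mean batch
// loss (BCE on logits or MSE on normalized targets).
// [[Rcpp::export]]
double pk_cpp_train_epoch(SEXP ptr, double lr) {
  XPtr<Session> s(ptr);
  double total_loss = 0;
  for (Batch& b : s->train_batches) {
    EncCache ec = encoder_forward(b.graph, s->enc, s->depth, s->rule);
    EncCache sc;
    fmat U;
    if (s->task == 0) {
      U = arma::join_cols(ec.emb, b.cond);
    } else {
      sc = encoder_forward(b.solvent, s->solv, s->sdepth, s->rule);
      fmat semb(sc.emb.n_rows, b.smap.size());
      for (size_t i = 0; i < b.smap.size(); ++i) semb.col(i) = sc.emb.col(b.smap[i]);
      U = arma::join_cols(ec.emb, semb);
    }
    FfnCache fc = ffn_forward(U, s->fW, s->fb);
    arma::uword M = b.y.n_elem;
    fvec z = fc.out.row(0).t();
    fvec dz(M);
    double loss;
    if (s->task == 0) {
      fvec sp = arma::log1p(arma::exp(-arma::abs(z)));
      loss = arma::mean(arma::clamp(z, 0.0f, arma::datum::inf) - z % b.y + sp);
      fvec sig = 1.0f / (1.0f + arma::exp(-z));
      dz = (sig - b.y) / (float)M;
    } else {
      fvec r = z - b.y;
      loss = arma::mean(r % r);
      dz = 2.0f * r / (float)M;
    }
    total_loss += loss;

    Encoder g_enc = s->enc.zeros_like();
    Encoder g_solv;
    if (s->has_solv) g_solv = s->solv.zeros_like();
    std::vector<fmat> g_fW;
    std::vector<fvec> g_fb;
    for (size_t l = 0; l < s->fW.size(); ++l) {
      g_fW.push_back(arma::zeros<fmat>(s->fW[l].n_rows, s->fW[l].n_cols));
      g_fb.push_back(arma::zeros<fvec>(s->fb[l].n_elem));
    }
    fmat d_out = dz.t();
    fmat dU = ffn_backward(fc, s->fW, d_out, g_fW, g_fb);
    arma::uword h = s->enc.W_in.n_rows;
    fmat d_emb = dU.rows(0, h - 1);
    encoder_backward(b.graph, s->enc, ec, d_emb, s->depth, s->rule, g_enc);
    if (s->task == 1) {
      arma::uword hs = s->solv.W_in.n_rows;
      fmat d_semb = dU.rows(h, h + hs - 1);
      fmat d_su(hs, sc.emb.n_cols, arma::fill::zeros);
      for (size_t i = 0; i < b.smap.size(); ++i) d_su.col(b.smap[i]) += d_semb.col(i);
      encoder_backward(b.solvent, s->solv, sc, d_su, s->sdepth, s->rule, g_solv);
    }

    double ss = enc_sumsq(g_enc);
    if (s->has_solv) ss += enc_sumsq(g_solv);
    for (size_t l = 0; l < g_fW.size(); ++l) {
      ss += arma::accu(arma::square(g_fW[l])) + arma::accu(arma::square(g_fb[l]));
    }
    double gn = std::sqrt(ss);
    if (std::isfinite(s->clip) && gn > s->clip) {
      float f = s->clip / gn;
      enc_scale(g_enc, f);
      if (s->has_solv) enc_scale(g_solv, f);
      for (size_t l = 0; l < g_fW.size(); ++l) { g_fW[l] *= f; g_fb[l] *= f; }
    }

    s->step += 1;
    float c1 = 1.0f - std::pow(0.9f, (float)s->step);
    float c2 = 1.0f - std::pow(0.999f, (float)s->step);
    adam_mat(s->enc.W_in, s->m_enc.W_in, s->v_enc.W_in, g_enc.W_in, lr, c1, c2);
    adam_mat(s->enc.W_h, s->m_enc.W_h, s->v_enc.W_h, g_enc.W_h, lr, c1, c2);
    adam_mat(s->enc.W_a, s->m_enc.W_a, s->v_enc.W_a, g_enc.W_a, lr, c1, c2);
    if (s->task == 1) {
      adam_mat(s->solv.W_in, s->m_solv.W_in, s->v_solv.W_in, g_solv.W_in, lr, c1, c2);
      adam_mat(s->solv.W_h, s->m_solv.W_h, s->v_solv.W_h, g_solv.W_h, lr, c1, c2);
      adam_mat(s->solv.W_a, s->m_solv.W_a, s->v_solv.W_a, g_solv.W_a, lr, c1, c2);
    }
    for (size_t l = 0; l < s->fW.size(); ++l) {
      adam_mat(s->fW[l], s->m_fW[l], s->v_fW[l], g_fW[l], lr, c1, c2);
      adam_vec(s->fb[l], s->m_fb[l], s->v_fb[l], g_fb[l], lr, c1, c2);
    }
  }
  return total_loss / (double)s->train_batches.size();
}

// Forward-only predictions (logits / normalized outputs) on the loaded
// validation batches, concatenated in load order.
// [[Rcpp::export]]
NumericVector pk_cpp_predict_loaded(SEXP ptr, bool validation) {
  XPtr<Session> s(ptr);
  std::vector<Batch>& src = validation ? s->val_batches : s->train_batches;
  std::vector<double> out;
  for (Batch& b : src) {
    EncCache ec = encoder_forward(b.graph, s->enc, s->depth, s->rule);
    fmat U;
    if (s->task == 0) {
      U = arma::join_cols(ec.emb, b.cond);
    } else {
      EncCache sc = encoder_forward(b.solvent, s->solv, s->sdepth, s->rule);
      fmat semb(sc.emb.n_rows, b.smap.size());
      for (size_t i = 0; i < b.smap.size(); ++i) semb.col(i) = sc.emb.col(b.smap[i]);
      U = arma::join_cols(ec.emb, semb);
    }
    FfnCache fc = ffn_forward(U, s->fW, s->fb);
    for (arma::uword i = 0; i < fc.out.n_cols; ++i) out.push_back(fc.out(0, i));
  }
  return wrap(out);
}

// [[Rcpp::export]]
List pk_cpp_get_params(SEXP ptr) {
  XPtr<Session> s(ptr);
  List ffn(s->fW.size());
  for (size_t l = 0; l < s->fW.size(); ++l) {
    ffn[l] = List::create(
      _["W"] = arma::conv_to<arma::mat>::from(s->fW[l].t()),
      _["b"] = arma::conv_to<arma::vec>::from(s->fb[l]));
  }
  return List::create(
    _["encoder"] = enc_to_list(s->enc),
    _["solvent"] = s->has_solv ? (SEXP)enc_to_list(s->solv) : R_NilValue,
    _["ffn"] = ffn);
}
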