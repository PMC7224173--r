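// Conditional sequence-to-sequence gap-filling model: an attention
// encoder-decoder with tied token embeddings on both sides, trained by
// maximising target-sequence likelihood with per-example Adam updates.
// Encoder states are position-tagged input embeddings; each decoder step
// queries them with a learned projection of the previous target embedding
// plus a decoder position embedding, combines the attended context through a
// tanh layer and emits a softmax over the vocabulary. Written with explicit
// gradients so training is fully deterministic given the seed.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

static const int BOS = 2;  // 0-based; R side reserves 3 = <s>
static const int EOS = 3;  // 0-based; R side reserves 4 = </s>

struct Params {
  mat E, Penc, Pdec, Wq, Wc, Wo;
  rowvec bc, bo;
};

static Params unpack(const List& p) {
  Params w;
  w.E = as<mat>(p["E"]); w.Penc = as<mat>(p["Penc"]); w.Pdec = as<mat>(p["Pdec"]);
  w.Wq = as<mat>(p["Wq"]); w.Wc = as<mat>(p["Wc"]); w.Wo = as<mat>(p["Wo"]);
  w.bc = as<rowvec>(p["bc"]); w.bo = as<rowvec>(p["bo"]);
  return w;
}

static List pack(const Params& w) {
  return List::create(_["E"] = w.E, _["Penc"] = w.Penc, _["Pdec"] = w.Pdec,
                      _["Wq"] = w.Wq, _["Wc"] = w.Wc, _["Wo"] = w.Wo,
                      _["bc"] = w.bc, _["bo"] = w.bo);
}

// [[Rcpp::export]]
List cpp_seq2seq_init(int V, int d, int max_in, int max_out, int seed) {
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::normal_distribution<double> norm(0.0, 0.08);
  auto fill = [&](mat& M, int r, int c) {
    M.set_size(r, c);
    for (int j = 0; j < c; ++j) for (int i = 0; i < r; ++i) M(i, j) = norm(rng);
  };
  Params w;
  fill(w.E, V, d); fill(w.Penc, max_in + 1, d); fill(w.Pdec, max_out + 1, d);
  fill(w.Wq, d, d); fill(w.Wc, 2 * d, d); fill(w.Wo, d, V);
  w.bc = rowvec(d, arma::fill::zeros);
  w.bo = rowvec(V, arma::fill::zeros);
  return pack(w);
}

static rowvec softmax_row(const rowvec& x) {
  rowvec e = arma::exp(x - x.max());
  return e / arma::accu(e);
}

static vec softmax_col(const vec& x) {
  vec e = arma::exp(x - x.max());
  return e / arma::accu(e);
}

// encoder states for an input sequence (BOS prepended, truncated to Penc rows)
static mat encode(const Params& w, const std::vector<int>& x) {
  int m = std::min((int)x.size() + 1, (int)w.Penc.n_rows);
  mat H(m, w.E.n_cols);
  H.row(0) = w.E.row(BOS) + w.Penc.row(0);
  for (int i = 1; i < m; ++i) H.row(i) = w.E.row(x[i - 1]) + w.Penc.row(i);
  return H;
}

struct StepOut {
  rowvec u, q, st, p;
  vec a;
};

static StepOut step_forward(const Params& w, const mat& H, int prev, int t) {
  StepOut s;
  double scale = std::sqrt((double)w.E.n_cols);
  int tp = std::min(t, (int)w.Pdec.n_rows - 1);
  s.u = w.E.row(prev) + w.Pdec.row(tp);
  s.q = s.u * w.Wq;
  vec sc = H * s.q.t() / scale;
  s.a = softmax_col(sc);
  rowvec c = (H.t() * s.a).t();
  rowvec uc = arma::join_rows(s.u, c);
  s.st = arma::tanh(uc * w.Wc + w.bc);
  s.p = softmax_row(s.st * w.Wo + w.bo);
  return s;
}

// forward + backward over one pair; returns summed NLL, token count; grads
// accumulated into g (same shapes as w)
static double example_grad(const Params& w, Params& g,
                           const std::vector<int>& x,
                           const std::vector<int>& y) {
  mat H = encode(w, x);
  int m = H.n_rows, d = w.E.n_cols;
  double scale = std::sqrt((double)d);
  mat dH(m, d, arma::fill::zeros);
  double nll = 0.0;
  int prev = BOS;
  for (size_t t = 0; t < y.size(); ++t) {
    StepOut s = step_forward(w, H, prev, (int)t);
    int yt = y[t];
    nll -= std::log(std::max(s.p(yt), 1e-12));
    rowvec dlogits = s.p;
    dlogits(yt) -= 1.0;
    g.Wo += s.st.t() * dlogits;
    g.bo += dlogits;
    rowvec dst = dlogits * w.Wo.t();
    rowvec dz = dst % (1.0 - s.st % s.st);
    rowvec c = (H.t() * s.a).t();
    rowvec uc = arma::join_rows(s.u, c);
    g.Wc += uc.t() * dz;
    g.bc += dz;
    rowvec duc = dz * w.Wc.t();
    rowvec du = duc.cols(0, d - 1);
    rowvec dc = duc.cols(d, 2 * d - 1);
    dH += s.a * dc;
    vec da = H * dc.t();
    vec ds = s.a % (da - arma::dot(s.a, da));
    rowvec dq = (ds.t() * H) / scale;
    dH += ds * s.q / scale;
    g.Wq += s.u.t() * dq;
    du += dq * w.Wq.t();
    int tp = std::min((int)t, (int)w.Pdec.n_rows - 1);
    g.E.row(prev) += du;
    g.Pdec.row(tp) += du;
    prev = yt;
  }
  g.Penc.rows(0, m - 1) += dH;
  g.E.row(BOS) += dH.row(0);
  for (int i = 1; i < m; ++i) g.E.row(x[i - 1]) += dH.row(i);
  return nll;
}

static double example_nll(const Params& w, const std::vector<int>& x,
                          const std::vector<int>& y) {
  mat H = encode(w, x);
  double nll = 0.0;
  int prev = BOS;
  for (size_t t = 0; t < y.size(); ++t) {
    StepOut s = step_forward(w, H, prev, (int)t);
    nll -= std::log(std::max(s.p(y[t]), 1e-12));
    prev = y[t];
  }
  return nll;
}

static std::vector<std::vector<int>> to_cpp(const List& seqs, bool add_eos) {
  std::vector<std::vector<int>> out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    IntegerVector v = seqs[i];
    std::vector<int> s(v.size());
    for (int j = 0; j < v.size(); ++j) s[j] = v[j] - 1;  // to 0-based
    if (add_eos) s.push_back(EOS);
    out[i] = s;
  }
  return out;
}

struct Adam {
  mat mE, vE, mPe, vPe, mPd, vPd, mWq, vWq, mWc, vWc, mWo, vWo;
  rowvec mbc, vbc, mbo, vbo;
  long t = 0;
  void init(const Params& w) {
    mE = vE = mat(arma::size(w.E), arma::fill::zeros);
    mPe = vPe = mat(arma::size(w.Penc), arma::fill::zeros);
    mPd = vPd = mat(arma::size(w.Pdec), arma::fill::zeros);
    mWq = vWq = mat(arma::size(w.Wq), arma::fill::zeros);
    mWc = vWc = mat(arma::size(w.Wc), arma::fill::zeros);
    mWo = vWo = mat(arma::size(w.Wo), arma::fill::zeros);
    mbc = vbc = rowvec(w.bc.n_elem, arma::fill::zeros);
    mbo = vbo = rowvec(w.bo.n_elem, arma::fill::zeros);
  }
  template <typename T>
  void upd(T& w, T& g, T& mm, T& vv, double lr) {
    mm = 0.9 * mm + 0.1 * g;
    vv = 0.999 * vv + 0.001 * (g % g);
    double bc1 = 1.0 - std::pow(0.9, (double)t);
    double bc2 = 1.0 - std::pow(0.999, (double)t);
    w -= lr * (mm / bc1) / (arma::sqrt(vv / bc2) + 1e-8);
    g.zeros();
  }
  void step(Params& w, Params& g, double lr) {
    ++t;
    upd(w.E, g.E, mE, vE, lr); upd(w.Penc, g.Penc, mPe, vPe, lr);
    upd(w.Pdec, g.Pdec, mPd, vPd, lr); upd(w.Wq, g.Wq, mWq, vWq, lr);
    upd(w.Wc, g.Wc, mWc, vWc, lr); upd(w.Wo, g.Wo, mWo, vWo, lr);
    upd(w.bc, g.bc, mbc, vbc, lr); upd(w.bo, g.bo, mbo, vbo, lr);
  }
};

// [[Rcpp::export]]
List cpp_seq2seq_train(List params, List inputs, List targets,
                       List val_inputs, List val_targets,
                       int epochs, double lr, int seed) {
  Params w = unpack(params);
  Params g = unpack(params);
  g.E.zeros(); g.Penc.zeros(); g.Pdec.zeros(); g.Wq.zeros(); g.Wc.zeros();
  g.Wo.zeros(); g.bc.zeros(); g.bo.zeros();
  Adam opt;
  opt.init(w);
  auto X = to_cpp(inputs, false);
  auto Y = to_cpp(targets, true);
  auto Xv = to_cpp(val_inputs, false);
  auto Yv = to_cpp(val_targets, true);
  std::mt19937 rng(static_cast<unsigned>(seed) + 17u);
  std::vector<int> order(X.size());
  for (size_t i = 0; i < X.size(); ++i) order[i] = (int)i;
  NumericVector tr_loss(epochs), va_loss(epochs);
  for (int e = 0; e < epochs; ++e) {
    std::shuffle(order.begin(), order.end(), rng);
    double nll = 0.0;
    long ntok = 0;
    for (int i : order) {
      nll += example_grad(w, g, X[i], Y[i]);
      ntok += (long)Y[i].size();
      opt.step(w, g, lr);
    }
    tr_loss[e] = nll / std::max(ntok, 1L);
    double vnll = 0.0;
    long vtok = 0;
    for (size_t i = 0; i < Xv.size(); ++i) {
      vnll += example_nll(w, Xv[i], Yv[i]);
      vtok += (long)Yv[i].size();
    }
    va_loss[e] = Xv.size() ? vnll / std::max(vtok, 1L) : NA_REAL;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = pack(w), _["train_loss"] = tr_loss,
                      _["val_loss"] = va_loss);
}

// [[Rcpp::export]]
List cpp_seq2seq_logprob(List params, List inputs, List targets) {
  Params w = unpack(params);
  auto X = to_cpp(inputs, false);
  auto Y = to_cpp(targets, true);
  NumericVector lp(X.size());
  IntegerVector nt(X.size());
  for (size_t i = 0; i < X.size(); ++i) {
    lp[i] = -example_nll(w, X[i], Y[i]);
    nt[i] = (int)Y[i].size();
  }
  return List::create(_["logprob"] = lp, _["n_tokens"] = nt);
}

struct Hyp {
  std::vector<int> toks;
  double lp;
  int prev;
  bool done;
};

static std::vector<int> decode_one(const Params& w, const std::vector<int>& x,
                                   int max_out, int beam, double& score) {
  mat H = encode(w, x);
  if (beam <= 1) {
    std::vector<int> out;
    int prev = BOS;
    double lp = 0.0;
    for (int t = 0; t < max_out; ++t) {
      StepOut s = step_forward(w, H, prev, t);
      int best = (int)s.p.index_max();
      lp += std::log(std::max(s.p(best), 1e-12));
      if (best == EOS) break;
      out.push_back(best);
      prev = best;
    }
    score = out.empty() ? lp : lp / (double)(out.size() + 1);
    return out;
  }
  std::vector<Hyp> live{{{}, 0.0, BOS, false}};
  std::vector<Hyp> finished;
  for (int t = 0; t < max_out && !live.empty(); ++t) {
    std::vector<Hyp> next;
    for (const Hyp& h : live) {
      StepOut s = step_forward(w, H, h.prev, t);
      std::vector<int> idx(s.p.n_elem);
      for (size_t i = 0; i < s.p.n_elem; ++i) idx[i] = (int)i;
      int k = std::min((int)s.p.n_elem, beam);
      std::partial_sort(idx.begin(), idx.begin() + k, idx.end(),
                        [&](int a, int b) {
                          if (s.p(a) != s.p(b)) return s.p(a) > s.p(b);
                          return a < b;
                        });
      for (int j = 0; j < k; ++j) {
        Hyp nh = h;
        nh.lp += std::log(std::max(s.p(idx[j]), 1e-12));
        if (idx[j] == EOS) {
          nh.done = true;
          finished.push_back(nh);
        } else {
          nh.toks.push_back(idx[j]);
          nh.prev = idx[j];
          next.push_back(nh);
        }
      }
    }
    std::stable_sort(next.begin(), next.end(),
                     [](const Hyp& a, const Hyp& b) { return a.lp > b.lp; });
    if ((int)next.size() > beam) next.resize(beam);
    live = next;
  }
  for (Hyp& h : live) finished.push_back(h);  // ran out of length
  std::stable_sort(finished.begin(), finished.end(),
                   [](const Hyp& a, const Hyp& b) { return a.lp > b.lp; });
  const Hyp& best = finished.front();
  score = best.toks.empty() ? best.lp : best.lp / (double)(best.toks.size() + 1);
  return best.toks;
}

// [[Rcpp::export]]
List cpp_seq2seq_decode(List params, List inputs, int max_out, int beam) {
  Params w = unpack(params);
  auto X = to_cpp(inputs, false);
  List outs(X.size());
  NumericVector scores(X.size());
  for (size_t i = 0; i < X.size(); ++i) {
    double sc = 0.0;
    std::vector<int> y = decode_one(w, X[i], max_out, beam, sc);
    IntegerVector v(y.size());
    for (size_t j = 0; j < y.size(); ++j) v[j] = y[j] + 1;  // back to 1-based
    outs[i] = v;
    scores[i] = sc;
  }
  return List::create(_["tokens"] = outs, _["score"] = scores);
}
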