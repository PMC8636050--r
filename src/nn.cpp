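// Channel-synergy network core: per-channel weight-tied LSTMs, temporal
// convolution, depthwise spatial convolution, separable convolution,
// channel attention, dense softmax head. Forward and hand-derived backward
// passes, templated on element type so training can run in single
// precision while gradient checks run in double.

#include <RcppArmadillo.h>
#include <map>
#include <vector>
#include <string>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct Cfg {
  int C, L, H, F1, D, r, N, ktemp, ksep, lstm_layers;
  bool tie, has_dw, has_sep, sep_pw, has_att;
  int half, n_units, FL, W1, Hr, P;
};

static Cfg parse_cfg(const Rcpp::List& cl) {
  Cfg c;
  c.C = cl["C"]; c.L = cl["L"]; c.H = cl["lstm_hidden"];
  c.F1 = cl["F1"]; c.D = cl["D"]; c.r = cl["attention_reduction"];
  c.N = cl["n_classes"]; c.ktemp = cl["temporal_kernel"];
  c.ksep = cl["separable_kernel"]; c.lstm_layers = cl["lstm_layers"];
  c.tie = cl["tie_symmetric_lstm"];
  c.has_dw = cl["has_depthwise"]; c.has_sep = cl["has_separable"];
  c.sep_pw = cl["sep_pointwise"]; c.has_att = cl["has_attention"];
  if (c.tie && c.C % 2 != 0)
    Rcpp::stop("channel count must be even when symmetric tying is on");
  c.half = c.C / 2;
  c.n_units = c.tie ? c.half : c.C;
  c.FL = (c.lstm_layers > 0) ? c.H : c.L;
  c.W1 = c.has_dw ? c.D * c.F1 : c.F1;
  if (c.ktemp % 2 == 0 || (c.has_sep && c.ksep % 2 == 0))
    Rcpp::stop("convolution kernels must be odd for symmetric same-padding");
  if (c.ktemp > c.FL) Rcpp::stop("temporal kernel longer than feature length");
  if (c.has_sep && c.ksep > c.FL) Rcpp::stop("separable kernel longer than feature length");
  if (c.has_att) {
    if (c.W1 % c.r != 0)
      Rcpp::stop("attention reduction r must divide the channel width");
    c.Hr = c.W1 / c.r;
  } else c.Hr = 0;
  c.P = c.W1 * c.FL;
  return c;
}

struct Slice { std::string name; int r, c; size_t off; };

static std::vector<Slice> layout(const Cfg& c) {
  std::vector<Slice> s;
  size_t off = 0;
  auto add = [&](const std::string& n, int r, int cc) {
    s.push_back({n, r, cc, off});
    off += (size_t)r * cc;
  };
  for (int layer = 1; layer <= c.lstm_layers; ++layer) {
    int in = (layer == 1) ? 1 : c.H;
    for (int u = 0; u < c.n_units; ++u) {
      std::string p = "l" + std::to_string(layer) + "_u" + std::to_string(u);
      add(p + "_Wx", 4 * c.H, in);
      add(p + "_Wh", 4 * c.H, c.H);
      add(p + "_b", 4 * c.H, 1);
    }
  }
  add("t_W", c.F1, c.ktemp);
  add("t_b", c.F1, 1);
  if (c.has_dw) { add("dw_W", c.D * c.F1, c.C); add("dw_b", c.D * c.F1, 1); }
  if (c.has_sep) {
    add("s_W", c.W1, c.ksep);
    add("s_b1", c.W1, 1);
    if (c.sep_pw) { add("s_P", c.W1, c.W1); add("s_b2", c.W1, 1); }
  }
  if (c.has_att) {
    add("a_W1", c.Hr, c.W1); add("a_b1", c.Hr, 1);
    add("a_W2", c.W1, c.Hr); add("a_b2", c.W1, 1);
  }
  add("o_W", c.N, c.P);
  add("o_b", c.N, 1);
  return s;
}

// Parameter views aliasing one flat buffer.
template <typename T>
struct Pars {
  std::map<std::string, Mat<T>> m;
  Pars(T* buf, const std::vector<Slice>& sl) {
    for (const auto& s : sl)
      m.emplace(s.name, Mat<T>(buf + s.off, s.r, s.c, false, true));
  }
  Mat<T>& operator[](const std::string& n) {
    auto it = m.find(n);
    if (it == m.end()) Rcpp::stop("missing parameter slice " + n);
    return it->second;
  }
};

template <typename T> static inline void sigm_inplace(Mat<T>& x) {
  x.transform([](T v) { return (T)1 / ((T)1 + std::exp(-v)); });
}
template <typename T> static inline void tanh_inplace(Mat<T>& x) {
  x.transform([](T v) { return std::tanh(v); });
}
template <typename T> static inline void elu_inplace(Mat<T>& x) {
  x.transform([](T v) { return v > 0 ? v : std::expm1(v); });
}
// ELU derivative recovered from the activation value (alpha = 1).
template <typename T> static inline Mat<T> elu_deriv(const Mat<T>& y) {
  Mat<T> d = y;
  d.transform([](T v) { return v > 0 ? (T)1 : v + (T)1; });
  return d;
}

// Channels processed by LSTM unit u (mirror channels share the unit).
static std::vector<int> unit_channels(const Cfg& c, int u) {
  if (c.tie) return {u, u + c.half};
  return {u};
}

// ---------------------------------------------------------------------------
// LSTM stack cache (per unit): everything backward-through-time needs.
template <typename T>
struct LstmCache {
  // per layer: gate activations and states, each H x S, one slice per step
  std::vector<Cube<T>> gi, gf, gg, go, cc, tc, hh;
  Mat<T> xin;  // layer-1 scalar inputs, S x L
};

// Forward through the (possibly stacked) LSTM for one unit.
// Returns final hidden state of the top layer (H x S); fills cache if asked.
template <typename T>
static Mat<T> lstm_unit_forward(const Cfg& c, Pars<T>& P, int u,
                                const Mat<T>& xin, bool keep,
                                LstmCache<T>* cache) {
  int H = c.H, S = xin.n_rows, L = c.L;
  if (keep) {
    cache->xin = xin;
    cache->gi.assign(c.lstm_layers, Cube<T>(H, S, L));
    cache->gf.assign(c.lstm_layers, Cube<T>(H, S, L));
    cache->gg.assign(c.lstm_layers, Cube<T>(H, S, L));
    cache->go.assign(c.lstm_layers, Cube<T>(H, S, L));
    cache->cc.assign(c.lstm_layers, Cube<T>(H, S, L));
    cache->tc.assign(c.lstm_layers, Cube<T>(H, S, L));
    cache->hh.assign(c.lstm_layers, Cube<T>(H, S, L));
  }
  Cube<T> below;  // lower-layer hidden states (H x S x L)
  Mat<T> htop;
  for (int layer = 1; layer <= c.lstm_layers; ++layer) {
    std::string p = "l" + std::to_string(layer) + "_u" + std::to_string(u);
    Mat<T>& Wx = P[p + "_Wx"];
    Mat<T>& Wh = P[p + "_Wh"];
    Mat<T>& b = P[p + "_b"];
    Mat<T> h(H, S, fill::zeros), cst(H, S, fill::zeros);
    Cube<T> hs;
    bool need_seq = (layer < c.lstm_layers);  // next layer consumes all steps
    if (need_seq && !keep) hs.set_size(H, S, L);
    for (int t = 0; t < L; ++t) {
      Mat<T> G;
      if (layer == 1) {
        // scalar input: rank-1 contribution
        G = Wx * xin.col(t).t();           // (4H x 1) * (1 x S)
      } else {
        G = Wx * (keep ? cache->hh[layer - 2].slice(t) : below.slice(t));
      }
      G += Wh * h;
      G.each_col() += b.col(0);
      Mat<T> i = G.rows(0, H - 1), f = G.rows(H, 2 * H - 1),
             g = G.rows(2 * H, 3 * H - 1), o = G.rows(3 * H, 4 * H - 1);
      sigm_inplace(i); sigm_inplace(f); tanh_inplace(g); sigm_inplace(o);
      cst = f % cst + i % g;
      Mat<T> tc = cst; tanh_inplace(tc);
      h = o % tc;
      if (keep) {
        cache->gi[layer - 1].slice(t) = i; cache->gf[layer - 1].slice(t) = f;
        cache->gg[layer - 1].slice(t) = g; cache->go[layer - 1].slice(t) = o;
        cache->cc[layer - 1].slice(t) = cst; cache->tc[layer - 1].slice(t) = tc;
        cache->hh[layer - 1].slice(t) = h;
      } else if (need_seq) {
        hs.slice(t) = h;
      }
    }
    if (need_seq && !keep) below = std::move(hs);
    htop = h;
  }
  return htop;
}

// Backward through the LSTM stack for one unit. dh_top_final is the gradient
// on the top layer's final hidden state (H x S). Gradients accumulate into G.
template <typename T>
static void lstm_unit_backward(const Cfg& c, Pars<T>& P, Pars<T>& G, int u,
                               const LstmCache<T>& cache,
                               const Mat<T>& dh_top_final) {
  int H = c.H, L = c.L;
  int S = cache.xin.n_rows;
  // per-step gradient flowing into each layer's hidden state from above
  Cube<T> dh_from_above;  // for layer below the one just processed
  for (int layer = c.lstm_layers; layer >= 1; --layer) {
    std::string p = "l" + std::to_string(layer) + "_u" + std::to_string(u);
    Mat<T>& Wx = P[p + "_Wx"];
    Mat<T>& Wh = P[p + "_Wh"];
    Mat<T>& dWx = G[p + "_Wx"];
    Mat<T>& dWh = G[p + "_Wh"];
    Mat<T>& db = G[p + "_b"];
    const Cube<T>& gi = cache.gi[layer - 1];
    const Cube<T>& gf = cache.gf[layer - 1];
    const Cube<T>& gg = cache.gg[layer - 1];
    const Cube<T>& go = cache.go[layer - 1];
    const Cube<T>& cc = cache.cc[layer - 1];
    const Cube<T>& tc = cache.tc[layer - 1];
    Cube<T> dx_below;
    if (layer > 1) dx_below.zeros(H, S, L);
    Mat<T> dh(H, S, fill::zeros), dc(H, S, fill::zeros);
    if (layer == c.lstm_layers) dh = dh_top_final;
    for (int t = L - 1; t >= 0; --t) {
      if (layer < c.lstm_layers) dh += dh_from_above.slice(t);
      const Mat<T>& i = gi.slice(t);
      const Mat<T>& f = gf.slice(t);
      const Mat<T>& g = gg.slice(t);
      const Mat<T>& o = go.slice(t);
      const Mat<T>& tct = tc.slice(t);
      Mat<T> dG(4 * H, S);
      dc += dh % o % ((T)1 - tct % tct);
      Mat<T> cprev = (t > 0) ? cc.slice(t - 1) : Mat<T>(H, S, fill::zeros);
      dG.rows(0, H - 1) = (dc % g) % i % ((T)1 - i);
      dG.rows(H, 2 * H - 1) = (dc % cprev) % f % ((T)1 - f);
      dG.rows(2 * H, 3 * H - 1) = (dc % i) % ((T)1 - g % g);
      dG.rows(3 * H, 4 * H - 1) = (dh % tct) % o % ((T)1 - o);
      // recurrent and input contributions
      if (t > 0) {
        dWh += dG * cache.hh[layer - 1].slice(t - 1).t();
      }
      db.col(0) += sum(dG, 1);
      if (layer == 1) {
        dWx += dG * cache.xin.col(t);           // (4H x S) * (S x 1)
      } else {
        dWx += dG * cache.hh[layer - 2].slice(t).t();
        dx_below.slice(t) = Wx.t() * dG;
      }
      dh = Wh.t() * dG;
      dc = dc % f;
    }
    if (layer > 1) dh_from_above = std::move(dx_below);
  }
}

// ---------------------------------------------------------------------------
// Convolution / attention blocks (per-window matrices).

// temporal conv: in (C x FL) -> out (F1*C x FL), row (f*C + c); ELU applied.
template <typename T>
static Mat<T> temporal_forward(const Cfg& c, Pars<T>& P, const Mat<T>& in) {
  int off = (c.ktemp - 1) / 2;
  Mat<T> pad(c.C, c.FL + c.ktemp - 1, fill::zeros);
  pad.cols(off, off + c.FL - 1) = in;
  Mat<T>& W = P["t_W"];
  Mat<T>& b = P["t_b"];
  Mat<T> out(c.F1 * c.C, c.FL);
  for (int f = 0; f < c.F1; ++f) {
    Mat<T> acc(c.C, c.FL, fill::zeros);
    for (int t = 0; t < c.ktemp; ++t)
      acc += W(f, t) * pad.cols(t, t + c.FL - 1);
    acc += b(f, 0);
    out.rows(f * c.C, (f + 1) * c.C - 1) = acc;
  }
  elu_inplace(out);
  return out;
}

// backward: returns dIn; accumulates dW, db. `out` is the post-ELU output.
template <typename T>
static Mat<T> temporal_backward(const Cfg& c, Pars<T>& P, Pars<T>& G,
                                const Mat<T>& in, const Mat<T>& out,
                                Mat<T> dout) {
  int off = (c.ktemp - 1) / 2;
  dout %= elu_deriv(out);
  Mat<T> pad(c.C, c.FL + c.ktemp - 1, fill::zeros);
  pad.cols(off, off + c.FL - 1) = in;
  Mat<T> dpad(c.C, c.FL + c.ktemp - 1, fill::zeros);
  Mat<T>& W = P["t_W"];
  Mat<T>& dW = G["t_W"];
  Mat<T>& db = G["t_b"];
  for (int f = 0; f < c.F1; ++f) {
    Mat<T> df = dout.rows(f * c.C, (f + 1) * c.C - 1);
    db(f, 0) += accu(df);
    for (int t = 0; t < c.ktemp; ++t) {
      dW(f, t) += accu(df % pad.cols(t, t + c.FL - 1));
      dpad.cols(t, t + c.FL - 1) += W(f, t) * df;
    }
  }
  return dpad.cols(off, off + c.FL - 1);
}

// depthwise spatial conv: in (F1*C x FL) -> out (D*F1 x FL); ELU.
// When absent (ablated), a parameter-free channel average collapses C.
template <typename T>
static Mat<T> depthwise_forward(const Cfg& c, Pars<T>& P, const Mat<T>& in) {
  Mat<T> out(c.W1, c.FL);
  if (!c.has_dw) {
    for (int f = 0; f < c.F1; ++f)
      out.row(f) = mean(in.rows(f * c.C, (f + 1) * c.C - 1), 0);
    return out;
  }
  Mat<T>& W = P["dw_W"];
  Mat<T>& b = P["dw_b"];
  for (int f = 0; f < c.F1; ++f) {
    Mat<T> block = in.rows(f * c.C, (f + 1) * c.C - 1);     // C x FL
    out.rows(f * c.D, (f + 1) * c.D - 1) =
        W.rows(f * c.D, (f + 1) * c.D - 1) * block;          // D x FL
  }
  out.each_col() += b.col(0);
  elu_inplace(out);
  return out;
}

template <typename T>
static Mat<T> depthwise_backward(const Cfg& c, Pars<T>& P, Pars<T>& G,
                                 const Mat<T>& in, const Mat<T>& out,
                                 Mat<T> dout) {
  Mat<T> din(c.F1 * c.C, c.FL, fill::zeros);
  if (!c.has_dw) {
    for (int f = 0; f < c.F1; ++f)
      din.rows(f * c.C, (f + 1) * c.C - 1) =
          repmat(dout.row(f) / (T)c.C, c.C, 1);
    return din;
  }
  dout %= elu_deriv(out);
  Mat<T>& W = P["dw_W"];
  Mat<T>& dW = G["dw_W"];
  Mat<T>& db = G["dw_b"];
  db.col(0) += sum(dout, 1);
  for (int f = 0; f < c.F1; ++f) {
    Mat<T> block = in.rows(f * c.C, (f + 1) * c.C - 1);
    Mat<T> dblk = dout.rows(f * c.D, (f + 1) * c.D - 1);     // D x FL
    dW.rows(f * c.D, (f + 1) * c.D - 1) += dblk * block.t();
    din.rows(f * c.C, (f + 1) * c.C - 1) +=
        W.rows(f * c.D, (f + 1) * c.D - 1).t() * dblk;
  }
  return din;
}

// separable conv: per-channel depthwise (1 x ksep), then optional pointwise
// channel mixing; single ELU after the block. z1 cache = linear depthwise out.
template <typename T>
static Mat<T> separable_forward(const Cfg& c, Pars<T>& P, const Mat<T>& in,
                                Mat<T>& z1) {
  int off = (c.ksep - 1) / 2;
  Mat<T> pad(c.W1, c.FL + c.ksep - 1, fill::zeros);
  pad.cols(off, off + c.FL - 1) = in;
  Mat<T>& W = P["s_W"];
  z1.zeros(c.W1, c.FL);
  for (int t = 0; t < c.ksep; ++t)
    z1 += pad.cols(t, t + c.FL - 1).each_col() % W.col(t);
  z1.each_col() += P["s_b1"].col(0);
  Mat<T> out;
  if (c.sep_pw) {
    out = P["s_P"] * z1;
    out.each_col() += P["s_b2"].col(0);
  } else {
    out = z1;
  }
  elu_inplace(out);
  return out;
}

template <typename T>
static Mat<T> separable_backward(const Cfg& c, Pars<T>& P, Pars<T>& G,
                                 const Mat<T>& in, const Mat<T>& z1,
                                 const Mat<T>& out, Mat<T> dout) {
  dout %= elu_deriv(out);
  Mat<T> dz1;
  if (c.sep_pw) {
    G["s_P"] += dout * z1.t();
    G["s_b2"].col(0) += sum(dout, 1);
    dz1 = P["s_P"].t() * dout;
  } else {
    dz1 = dout;
  }
  G["s_b1"].col(0) += sum(dz1, 1);
  int off = (c.ksep - 1) / 2;
  Mat<T> pad(c.W1, c.FL + c.ksep - 1, fill::zeros);
  pad.cols(off, off + c.FL - 1) = in;
  Mat<T> dpad(c.W1, c.FL + c.ksep - 1, fill::zeros);
  Mat<T>& W = P["s_W"];
  Mat<T>& dW = G["s_W"];
  for (int t = 0; t < c.ksep; ++t) {
    dW.col(t) += sum(dz1 % pad.cols(t, t + c.FL - 1), 1);
    dpad.cols(t, t + c.FL - 1) += dz1.each_col() % W.col(t);
  }
  return dpad.cols(off, off + c.FL - 1);
}

template <typename T>
struct AttCache {
  Col<T> sa, sm, ra, rm, w;   // pooled stats, relu outputs, gate weights
  uvec amax;                  // argmax position per channel
};

// channel attention: avg/max pool over length, shared 2-layer MLP, sigmoid
// gate broadcast over the input.
template <typename T>
static Mat<T> attention_forward(const Cfg& c, Pars<T>& P, const Mat<T>& in,
                                AttCache<T>& cch) {
  cch.sa = mean(in, 1);
  cch.amax.set_size(c.W1);
  cch.sm.set_size(c.W1);
  for (int ch = 0; ch < c.W1; ++ch) {
    cch.amax(ch) = in.row(ch).index_max();
    cch.sm(ch) = in(ch, cch.amax(ch));
  }
  Mat<T>& W1m = P["a_W1"];
  Mat<T>& W2m = P["a_W2"];
  Col<T> b1 = P["a_b1"].col(0), b2 = P["a_b2"].col(0);
  cch.ra = clamp(W1m * cch.sa + b1, (T)0, std::numeric_limits<T>::max());
  cch.rm = clamp(W1m * cch.sm + b1, (T)0, std::numeric_limits<T>::max());
  Col<T> z = W2m * cch.ra + b2 + W2m * cch.rm + b2;
  cch.w = (T)1 / ((T)1 + exp(-z));
  return in.each_col() % cch.w;
}

template <typename T>
static Mat<T> attention_backward(const Cfg& c, Pars<T>& P, Pars<T>& G,
                                 const Mat<T>& in, const AttCache<T>& cch,
                                 const Mat<T>& dout) {
  Mat<T> din = dout.each_col() % cch.w;
  Col<T> dw = sum(dout % in, 1);
  Col<T> dz = dw % cch.w % ((T)1 - cch.w);
  Mat<T>& W1m = P["a_W1"];
  Mat<T>& W2m = P["a_W2"];
  G["a_b2"].col(0) += (T)2 * dz;       // bias added in both branches
  Col<T> dsa, dsm;
  {
    G["a_W2"] += dz * cch.ra.t();
    Col<T> dr = W2m.t() * dz;
    dr.elem(find(cch.ra <= (T)0)).zeros();
    G["a_W1"] += dr * cch.sa.t();
    G["a_b1"].col(0) += dr;
    dsa = W1m.t() * dr;
  }
  {
    G["a_W2"] += dz * cch.rm.t();
    Col<T> dr = W2m.t() * dz;
    dr.elem(find(cch.rm <= (T)0)).zeros();
    G["a_W1"] += dr * cch.sm.t();
    G["a_b1"].col(0) += dr;
    dsm = W1m.t() * dr;
  }
  din.each_col() += dsa / (T)c.FL;
  for (int ch = 0; ch < c.W1; ++ch) din(ch, cch.amax(ch)) += dsm(ch);
  return din;
}

// ---------------------------------------------------------------------------
// Full forward (optionally keeping stage activations) and loss+gradient.

template <typename T>
struct BatchCaches {
  std::vector<LstmCache<T>> lstm;                 // per unit
  Cube<T> ftemp, fconv, fdconv, fsep_z1, fsep, fatt;
  std::vector<AttCache<T>> att;                   // per window
  Mat<T> probs;                                   // N x B
};

// Run LSTM stage for the whole batch; X is (C x L x B).
template <typename T>
static Cube<T> lstm_stage(const Cfg& c, Pars<T>& P, const Cube<T>& X,
                          bool keep, std::vector<LstmCache<T>>* caches) {
  int B = X.n_slices;
  Cube<T> ftemp(c.C, c.FL, B);
  for (int u = 0; u < c.n_units; ++u) {
    std::vector<int> chans = unit_channels(c, u);
    int S = chans.size() * B;
    Mat<T> xin(S, c.L);
    for (size_t j = 0; j < chans.size(); ++j)
      for (int b = 0; b < B; ++b)
        for (int t = 0; t < c.L; ++t)
          xin(j * B + b, t) = X(chans[j], t, b);
    Mat<T> h = lstm_unit_forward<T>(c, P, u, xin, keep,
                                    keep ? &(*caches)[u] : nullptr);
    for (size_t j = 0; j < chans.size(); ++j)
      for (int b = 0; b < B; ++b)
        ftemp.slice(b).row(chans[j]) = h.col(j * B + b).t();
  }
  return ftemp;
}

template <typename T>
static void forward_pass(const Cfg& c, Pars<T>& P, const Cube<T>& X,
                         bool keep, BatchCaches<T>& cc) {
  int B = X.n_slices;
  if (c.lstm_layers > 0) {
    if (keep) cc.lstm.resize(c.n_units);
    cc.ftemp = lstm_stage<T>(c, P, X, keep, &cc.lstm);
  } else {
    cc.ftemp = X;
  }
  cc.fconv.set_size(c.F1 * c.C, c.FL, B);
  cc.fdconv.set_size(c.W1, c.FL, B);
  cc.fsep_z1.set_size(c.W1, c.FL, B);
  cc.fsep.set_size(c.W1, c.FL, B);
  cc.fatt.set_size(c.W1, c.FL, B);
  cc.att.resize(B);
  Mat<T>& Wo = P["o_W"];
  Col<T> bo = P["o_b"].col(0);
  cc.probs.set_size(c.N, B);
  for (int b = 0; b < B; ++b) {
    cc.fconv.slice(b) = temporal_forward<T>(c, P, cc.ftemp.slice(b));
    cc.fdconv.slice(b) = depthwise_forward<T>(c, P, cc.fconv.slice(b));
    if (c.has_sep) {
      Mat<T> z1;
      cc.fsep.slice(b) = separable_forward<T>(c, P, cc.fdconv.slice(b), z1);
      cc.fsep_z1.slice(b) = z1;
    } else {
      cc.fsep.slice(b) = cc.fdconv.slice(b);
    }
    if (c.has_att) {
      cc.fatt.slice(b) = attention_forward<T>(c, P, cc.fsep.slice(b), cc.att[b]);
    } else {
      cc.fatt.slice(b) = cc.fsep.slice(b);
    }
    Col<T> logits = Wo * vectorise(cc.fatt.slice(b)) + bo;
    logits -= logits.max();
    Col<T> e = exp(logits);
    cc.probs.col(b) = e / accu(e);
  }
}

template <typename T>
static double backward_pass(const Cfg& c, Pars<T>& P, Pars<T>& G,
                            const Cube<T>& X, const ivec& y,
                            const Col<T>& clw, BatchCaches<T>& cc) {
  int B = X.n_slices;
  T wsum = 0;
  for (int b = 0; b < B; ++b) wsum += clw(y(b));
  double loss = 0;
  Cube<T> dftemp(c.C, c.FL, B, fill::zeros);
  Mat<T>& Wo = P["o_W"];
  for (int b = 0; b < B; ++b) {
    T w = clw(y(b));
    loss += -w * std::log(std::max(cc.probs(y(b), b),
                                   (T)1e-12)) / (double)wsum;
    Col<T> dlog = cc.probs.col(b) * (w / wsum);
    dlog(y(b)) -= w / wsum;
    G["o_W"] += dlog * vectorise(cc.fatt.slice(b)).t();
    G["o_b"].col(0) += dlog;
    Mat<T> datt(Wo.t() * dlog);
    datt.reshape(c.W1, c.FL);
    Mat<T> dsep = c.has_att
      ? attention_backward<T>(c, P, G, cc.fsep.slice(b), cc.att[b], datt)
      : datt;
    Mat<T> ddconv = c.has_sep
      ? separable_backward<T>(c, P, G, cc.fdconv.slice(b),
                              cc.fsep_z1.slice(b), cc.fsep.slice(b), dsep)
      : dsep;
    Mat<T> dconv = depthwise_backward<T>(c, P, G, cc.fconv.slice(b),
                                         cc.fdconv.slice(b), ddconv);
    dftemp.slice(b) = temporal_backward<T>(c, P, G, cc.ftemp.slice(b),
                                           cc.fconv.slice(b), dconv);
  }
  if (c.lstm_layers > 0) {
    for (int u = 0; u < c.n_units; ++u) {
      std::vector<int> chans = unit_channels(c, u);
      int S = chans.size() * B;
      Mat<T> dh(c.H, S);
      for (size_t j = 0; j < chans.size(); ++j)
        for (int b = 0; b < B; ++b)
          dh.col(j * B + b) = dftemp.slice(b).row(chans[j]).t();
      lstm_unit_backward<T>(c, P, G, u, cc.lstm[u], dh);
    }
  }
  return loss;
}

// ---------------------------------------------------------------------------
// R entry points.

// [[Rcpp::export]]
Rcpp::List cpp_param_layout(Rcpp::List cfg) {
  Cfg c = parse_cfg(cfg);
  std::vector<Slice> sl = layout(c);
  size_t total = 0;
  Rcpp::CharacterVector names(sl.size());
  Rcpp::IntegerVector nr(sl.size()), ncl(sl.size()), off(sl.size());
  for (size_t i = 0; i < sl.size(); ++i) {
    names[i] = sl[i].name; nr[i] = sl[i].r; ncl[i] = sl[i].c;
    off[i] = sl[i].off;
    total += (size_t)sl[i].r * sl[i].c;
  }
  return Rcpp::List::create(Rcpp::Named("name") = names,
                            Rcpp::Named("nrow") = nr,
                            Rcpp::Named("ncol") = ncl,
                            Rcpp::Named("offset") = off,
                            Rcpp::Named("total") = (double)total);
}

template <typename T>
static Rcpp::List forward_impl(const Rcpp::NumericVector& x,
                               const Rcpp::NumericVector& theta,
                               const Cfg& c, bool stages) {
  Rcpp::IntegerVector dim = x.attr("dim");
  int B = dim[2];
  Cube<T> X(c.C, c.L, B);
  std::copy(x.begin(), x.end(), X.memptr());
  std::vector<T> buf(theta.begin(), theta.end());
  std::vector<Slice> sl = layout(c);
  Pars<T> P(buf.data(), sl);
  BatchCaches<T> cc;
  forward_pass<T>(c, P, X, false, cc);
  Rcpp::NumericMatrix probs(B, c.N);
  for (int b = 0; b < B; ++b)
    for (int k = 0; k < c.N; ++k) probs(b, k) = cc.probs(k, b);
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("probs") = probs);
  if (stages) {
    auto cube_out = [&](const Cube<T>& q) {
      Rcpp::NumericVector v(q.n_elem);
      std::copy(q.begin(), q.end(), v.begin());
      v.attr("dim") = Rcpp::IntegerVector::create(q.n_rows, q.n_cols,
                                                  q.n_slices);
      return v;
    };
    out["F_temp"] = cube_out(cc.ftemp);
    out["F_conv"] = cube_out(cc.fconv);
    out["F_dconv"] = cube_out(cc.fdconv);
    out["F_sepconv"] = cube_out(cc.fsep);
    out["F_attended"] = cube_out(cc.fatt);
    if (c.has_att) {
      Rcpp::NumericMatrix aw(c.W1, B);
      for (int b = 0; b < B; ++b)
        for (int ch = 0; ch < c.W1; ++ch) aw(ch, b) = cc.att[b].w(ch);
      out["attention"] = aw;
    }
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_nn_forward(Rcpp::NumericVector x, Rcpp::NumericVector theta,
                          Rcpp::List cfg, bool stages = false,
                          std::string precision = "double") {
  Cfg c = parse_cfg(cfg);
  if (precision == "single") return forward_impl<float>(x, theta, c, stages);
  return forward_impl<double>(x, theta, c, stages);
}

template <typename T>
static Rcpp::List loss_grad_impl(const Rcpp::NumericVector& x,
                                 const Rcpp::IntegerVector& y,
                                 const Rcpp::NumericVector& class_weights,
                                 const Rcpp::NumericVector& theta,
                                 const Cfg& c) {
  Rcpp::IntegerVector dim = x.attr("dim");
  int B = dim[2];
  if (y.size() != B) Rcpp::stop("label count does not match batch size");
  Cube<T> X(c.C, c.L, B);
  std::copy(x.begin(), x.end(), X.memptr());
  std::vector<T> buf(theta.begin(), theta.end());
  std::vector<Slice> sl = layout(c);
  Pars<T> P(buf.data(), sl);
  std::vector<T> gbuf(theta.size(), (T)0);
  Pars<T> G(gbuf.data(), sl);
  ivec yy(B);
  for (int b = 0; b < B; ++b) {
    if (y[b] < 0 || y[b] >= c.N) Rcpp::stop("label out of range");
    yy(b) = y[b];
  }
  Col<T> clw(c.N);
  for (int k = 0; k < c.N; ++k) clw(k) = class_weights[k];
  BatchCaches<T> cc;
  forward_pass<T>(c, P, X, true, cc);
  double loss = backward_pass<T>(c, P, G, X, yy, clw, cc);
  Rcpp::NumericVector grad(theta.size());
  std::copy(gbuf.begin(), gbuf.end(), grad.begin());
  Rcpp::NumericMatrix probs(B, c.N);
  for (int b = 0; b < B; ++b)
    for (int k = 0; k < c.N; ++k) probs(b, k) = cc.probs(k, b);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad,
                            Rcpp::Named("probs") = probs);
}

// [[Rcpp::export]]
Rcpp::List cpp_nn_loss_grad(Rcpp::NumericVector x, Rcpp::IntegerVector y,
                            Rcpp::NumericVector class_weights,
                            Rcpp::NumericVector theta, Rcpp::List cfg,
                            std::string precision = "double") {
  Cfg c = parse_cfg(cfg);
  if (precision == "single")
    return loss_grad_impl<float>(x, y, class_weights, theta, c);
  return loss_grad_impl<double>(x, y, class_weights, theta, c);
}
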