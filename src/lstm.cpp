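// Minimal LSTM next-word language model: forward, truncated-free BPTT over
// whole (short) sentences, Adam, softmax cross-entropy. Deliberately
// self-contained and deterministic: all randomness comes from an internal
// xorshift generator seeded from R, so identical seeds give bit-identical
// parameters on a fixed BLAS.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

void fill_uniform(arma::mat& m, XorShift& rng, double a) {
  for (arma::uword i = 0; i < m.n_elem; ++i) m(i) = (2.0 * rng.unif() - 1.0) * a;
}

struct Params {
  arma::mat E, W, U, Wy;
  arma::vec b, by;
};

struct Adam {
  arma::mat mE, vE, mW, vW, mU, vU, mWy, vWy;
  arma::vec mb, vb, mby, vby;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  explicit Adam(const Params& p)
      : mE(arma::size(p.E), arma::fill::zeros), vE(arma::size(p.E), arma::fill::zeros),
        mW(arma::size(p.W), arma::fill::zeros), vW(arma::size(p.W), arma::fill::zeros),
        mU(arma::size(p.U), arma::fill::zeros), vU(arma::size(p.U), arma::fill::zeros),
        mWy(arma::size(p.Wy), arma::fill::zeros), vWy(arma::size(p.Wy), arma::fill::zeros),
        mb(arma::size(p.b), arma::fill::zeros), vb(arma::size(p.b), arma::fill::zeros),
        mby(arma::size(p.by), arma::fill::zeros), vby(arma::size(p.by), arma::fill::zeros) {}

  template <typename T>
  void upd(T& w, T& m, T& v, const T& g, double lr) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    T mh = m / (1 - std::pow(b1, (double)t));
    T vh = v / (1 - std::pow(b2, (double)t));
    w -= lr * mh / (arma::sqrt(vh) + eps);
  }
  void step(Params& p, Params& g, double lr) {
    ++t;
    upd(p.E, mE, vE, g.E, lr);   upd(p.W, mW, vW, g.W, lr);
    upd(p.U, mU, vU, g.U, lr);   upd(p.Wy, mWy, vWy, g.Wy, lr);
    upd(p.b, mb, vb, g.b, lr);   upd(p.by, mby, vby, g.by, lr);
  }
};

inline arma::mat sigm(const arma::mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// column-wise log-softmax, numerically stable
arma::mat log_softmax(const arma::mat& logits) {
  arma::rowvec mx = arma::max(logits, 0);
  arma::mat z = logits.each_row() - mx;
  arma::rowvec lse = arma::log(arma::sum(arma::exp(z), 0));
  return z.each_row() - lse;
}

double grad_norm(const Params& g) {
  double s = arma::accu(g.E % g.E) + arma::accu(g.W % g.W) +
             arma::accu(g.U % g.U) + arma::accu(g.Wy % g.Wy) +
             arma::accu(g.b % g.b) + arma::accu(g.by % g.by);
  return std::sqrt(s);
}

void scale_params(Params& g, double f) {
  g.E *= f; g.W *= f; g.U *= f; g.Wy *= f; g.b *= f; g.by *= f;
}

Params params_from_list(const List& lp) {
  Params p;
  p.E  = as<arma::mat>(lp["E"]);
  p.W  = as<arma::mat>(lp["W"]);
  p.U  = as<arma::mat>(lp["U"]);
  p.Wy = as<arma::mat>(lp["Wy"]);
  p.b  = as<arma::vec>(lp["b"]);
  p.by = as<arma::vec>(lp["by"]);
  return p;
}

// forward one sequence; returns log2 prob of each target (input = BOS then
// targets shifted right)
arma::vec score_sequence(const Params& p, const std::vector<int>& targets,
                         int bos_id) {
  const int H = p.U.n_rows / 1, hid = p.U.n_cols;
  (void)H;
  arma::vec h(hid, arma::fill::zeros), c(hid, arma::fill::zeros);
  arma::vec out((size_t)targets.size());
  int prev = bos_id;
  for (size_t t = 0; t < targets.size(); ++t) {
    arma::vec x = p.E.col(prev);
    arma::vec z = p.W * x + p.U * h + p.b;
    arma::vec i = 1.0 / (1.0 + arma::exp(-z.subvec(0, hid - 1)));
    arma::vec f = 1.0 / (1.0 + arma::exp(-z.subvec(hid, 2 * hid - 1)));
    arma::vec o = 1.0 / (1.0 + arma::exp(-z.subvec(2 * hid, 3 * hid - 1)));
    arma::vec g = arma::tanh(z.subvec(3 * hid, 4 * hid - 1));
    c = f % c + i % g;
    h = o % arma::tanh(c);
    arma::vec logits = p.Wy * h + p.by;
    double mx = logits.max();
    double lse = mx + std::log(arma::accu(arma::exp(logits - mx)));
    out(t) = (logits(targets[t]) - lse) / std::log(2.0);
    prev = targets[t];
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
List cpp_lstm_train(List sentences, int vocab_size, int bos_id, int emb_dim,
                    int hidden_dim, int epochs, int batch_size, double lr,
                    double clip, int seed) {
  const int V = vocab_size, D = emb_dim, H = hidden_dim;
  const int n_sent = sentences.size();
  std::vector<std::vector<int>> data(n_sent);
  for (int s = 0; s < n_sent; ++s) {
    IntegerVector v = sentences[s];
    data[s] = std::vector<int>(v.begin(), v.end());
  }

  XorShift rng((uint64_t)seed * 2654435761ULL + 1ULL);
  Params p;
  p.E.set_size(D, V);   fill_uniform(p.E, rng, 0.08);
  p.W.set_size(4 * H, D); fill_uniform(p.W, rng, 0.08);
  p.U.set_size(4 * H, H); fill_uniform(p.U, rng, 0.08);
  p.Wy.set_size(V, H);  fill_uniform(p.Wy, rng, 0.08);
  p.b = arma::vec(4 * H, arma::fill::zeros);
  // encourage remembering early in training
  p.b.subvec(H, 2 * H - 1).fill(1.0);
  p.by = arma::vec(V, arma::fill::zeros);

  Adam adam(p);
  std::vector<int> order(n_sent);
  for (int i = 0; i < n_sent; ++i) order[i] = i;
  NumericVector epoch_loss(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates with the internal generator: deterministic across platforms
    for (int i = n_sent - 1; i > 0; --i) {
      int j = (int)(rng.next() % (uint64_t)(i + 1));
      std::swap(order[i], order[j]);
    }
    double total_nll = 0.0; long total_tok = 0;
    for (int start = 0; start < n_sent; start += batch_size) {
      int B = std::min(batch_size, n_sent - start);
      int T = 0;
      for (int bi = 0; bi < B; ++bi)
        T = std::max(T, (int)data[order[start + bi]].size());
      if (T == 0) continue;

      arma::imat X(T, B), Y(T, B);
      arma::mat mask(T, B, arma::fill::zeros);
      for (int bi = 0; bi < B; ++bi) {
        const std::vector<int>& s = data[order[start + bi]];
        int prev = bos_id;
        for (int t = 0; t < T; ++t) {
          if (t < (int)s.size()) {
            X(t, bi) = prev; Y(t, bi) = s[t]; mask(t, bi) = 1.0; prev = s[t];
          } else { X(t, bi) = bos_id; Y(t, bi) = 0; }
        }
      }

      arma::cube Hs(H, B, T), Cs(H, B, T), Gs(4 * H, B, T);
      arma::cube dLog(V, B, T, arma::fill::zeros);
      arma::mat h(H, B, arma::fill::zeros), c(H, B, arma::fill::zeros);
      long batch_tok = (long)arma::accu(mask);

      for (int t = 0; t < T; ++t) {
        arma::mat x(D, B);
        for (int bi = 0; bi < B; ++bi) x.col(bi) = p.E.col(X(t, bi));
        arma::mat z = p.W * x + p.U * h;
        z.each_col() += p.b;
        arma::mat i = sigm(z.rows(0, H - 1));
        arma::mat f = sigm(z.rows(H, 2 * H - 1));
        arma::mat o = sigm(z.rows(2 * H, 3 * H - 1));
        arma::mat g = arma::tanh(z.rows(3 * H, 4 * H - 1));
        arma::mat c_new = f % c + i % g;
        arma::mat h_new = o % arma::tanh(c_new);
        // reset finished sequences so state (and gradient) cannot leak
        c_new.each_row() %= mask.row(t);
        h_new.each_row() %= mask.row(t);
        arma::mat gates(4 * H, B);
        gates.rows(0, H - 1) = i; gates.rows(H, 2 * H - 1) = f;
        gates.rows(2 * H, 3 * H - 1) = o; gates.rows(3 * H, 4 * H - 1) = g;
        Gs.slice(t) = gates;
        Cs.slice(t) = c_new; Hs.slice(t) = h_new;

        arma::mat logits = p.Wy * h_new;
        logits.each_col() += p.by;
        arma::mat lp = log_softmax(logits);
        arma::mat probs = arma::exp(lp);
        for (int bi = 0; bi < B; ++bi) {
          if (mask(t, bi) == 0.0) continue;
          total_nll -= lp(Y(t, bi), bi);
          probs(Y(t, bi), bi) -= 1.0;
        }
        probs.each_row() %= mask.row(t);
        dLog.slice(t) = probs;
        h = h_new; c = c_new;
      }
      total_tok += batch_tok;

      Params gr;
      gr.E = arma::mat(D, V, arma::fill::zeros);
      gr.W = arma::mat(4 * H, D, arma::fill::zeros);
      gr.U = arma::mat(4 * H, H, arma::fill::zeros);
      gr.Wy = arma::mat(V, H, arma::fill::zeros);
      gr.b = arma::vec(4 * H, arma::fill::zeros);
      gr.by = arma::vec(V, arma::fill::zeros);

      arma::mat dh(H, B, arma::fill::zeros), dc(H, B, arma::fill::zeros);
      for (int t = T - 1; t >= 0; --t) {
        const arma::mat& dlog = dLog.slice(t);
        gr.Wy += dlog * Hs.slice(t).t();
        gr.by += arma::sum(dlog, 1);
        dh += p.Wy.t() * dlog;
        dh.each_row() %= mask.row(t);
        dc.each_row() %= mask.row(t);

        arma::mat i = Gs.slice(t).rows(0, H - 1);
        arma::mat f = Gs.slice(t).rows(H, 2 * H - 1);
        arma::mat o = Gs.slice(t).rows(2 * H, 3 * H - 1);
        arma::mat g = Gs.slice(t).rows(3 * H, 4 * H - 1);
        arma::mat c_t = Cs.slice(t);
        arma::mat c_prev = (t > 0) ? arma::mat(Cs.slice(t - 1))
                                   : arma::mat(H, B, arma::fill::zeros);
        arma::mat tc = arma::tanh(c_t);
        arma::mat do_ = dh % tc;
        dc += dh % o % (1.0 - tc % tc);
        arma::mat di = dc % g, df = dc % c_prev, dg = dc % i;
        arma::mat dc_prev = dc % f;
        arma::mat dz(4 * H, B);
        dz.rows(0, H - 1) = di % i % (1.0 - i);
        dz.rows(H, 2 * H - 1) = df % f % (1.0 - f);
        dz.rows(2 * H, 3 * H - 1) = do_ % o % (1.0 - o);
        dz.rows(3 * H, 4 * H - 1) = dg % (1.0 - g % g);
        dz.each_row() %= mask.row(t);

        arma::mat x(D, B);
        for (int bi = 0; bi < B; ++bi) x.col(bi) = p.E.col(X(t, bi));
        gr.W += dz * x.t();
        arma::mat h_prev = (t > 0) ? arma::mat(Hs.slice(t - 1))
                                   : arma::mat(H, B, arma::fill::zeros);
        gr.U += dz * h_prev.t();
        gr.b += arma::sum(dz, 1);
        arma::mat dx = p.W.t() * dz;
        for (int bi = 0; bi < B; ++bi)
          if (mask(t, bi) != 0.0) gr.E.col(X(t, bi)) += dx.col(bi);
        dh = p.U.t() * dz;
        dc = dc_prev;
      }

      scale_params(gr, 1.0 / (double)batch_tok);
      double gn = grad_norm(gr);
      if (clip > 0 && gn > clip) scale_params(gr, clip / gn);
      adam.step(p, gr, lr);
    }
    epoch_loss[ep] = total_tok ? (total_nll / total_tok) / std::log(2.0) : NA_REAL;
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["E"] = p.E, _["W"] = p.W, _["U"] = p.U,
                      _["Wy"] = p.Wy, _["b"] = p.b, _["by"] = p.by,
                      _["epoch_loss_bits"] = epoch_loss);
}

// [[Rcpp::export]]
NumericVector cpp_lstm_logprobs(List params, IntegerVector targets, int bos_id) {
  Params p = params_from_list(params);
  std::vector<int> tg(targets.begin(), targets.end());
  arma::vec lp = score_sequence(p, tg, bos_id);
  return NumericVector(lp.begin(), lp.end());
}

// [[Rcpp::export]]
NumericVector cpp_lstm_next_dist(List params, IntegerVector prefix, int bos_id) {
  Params p = params_from_list(params);
  const int hid = p.U.n_cols;
  arma::vec h(hid, arma::fill::zeros), c(hid, arma::fill::zeros);
  std::vector<int> seq;
  seq.push_back(bos_id);
  for (int i = 0; i < prefix.size(); ++i) seq.push_back(prefix[i]);
  for (size_t t = 0; t < seq.size(); ++t) {
    arma::vec x = p.E.col(seq[t]);
    arma::vec z = p.W * x + p.U * h + p.b;
    arma::vec i = 1.0 / (1.0 + arma::exp(-z.subvec(0, hid - 1)));
    arma::vec f = 1.0 / (1.0 + arma::exp(-z.subvec(hid, 2 * hid - 1)));
    arma::vec o = 1.0 / (1.0 + arma::exp(-z.subvec(2 * hid, 3 * hid - 1)));
    arma::vec g = arma::tanh(z.subvec(3 * hid, 4 * hid - 1));
    c = f % c + i % g;
    h = o % arma::tanh(c);
  }
  arma::vec logits = p.Wy * h + p.by;
  double mx = logits.max();
  arma::vec e = arma::exp(logits - mx);
  arma::vec pr = e / arma::accu(e);
  return NumericVector(pr.begin(), pr.end());
}
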