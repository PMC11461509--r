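// Inner loops of the averaged-perceptron BIO tagger: per-token feature-sum
// scoring, transition-constrained greedy decoding, one training epoch, and
// batched softmax-margin uncertainty. Feature ids are 1-based indices into
// the model vocabulary; id 0 marks a feature unseen at training time.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static void sent_scores(const NumericMatrix& W, const IntegerVector& feat,
                        const IntegerVector& ptr, std::vector<double>& S,
                        int T, int L) {
  std::fill(S.begin(), S.begin() + (size_t)T * L, 0.0);
  for (int t = 0; t < T; ++t) {
    for (int k = ptr[t]; k < ptr[t + 1]; ++k) {
      int f = feat[k];
      if (f <= 0) continue;
      for (int l = 0; l < L; ++l) S[(size_t)t * L + l] += W(f - 1, l);
    }
  }
}

static void greedy_decode(const std::vector<double>& S, int T, int L,
                          const LogicalMatrix& allowed, const LogicalVector& start_ok,
                          std::vector<int>& out) {
  int prev = -1;
  for (int t = 0; t < T; ++t) {
    int best = -1;
    double bs = 0.0;
    for (int l = 0; l < L; ++l) {
      bool ok = (prev < 0) ? (bool)start_ok[l] : (bool)allowed(prev, l);
      if (!ok) continue;
      double s = S[(size_t)t * L + l];
      if (best < 0 || s > bs) { best = l; bs = s; }
    }
    out[t] = best;
    prev = best;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_scores(const NumericMatrix& W, const IntegerVector& feat,
                         const IntegerVector& ptr) {
  int T = ptr.size() - 1, L = W.ncol();
  NumericMatrix out(T, L);
  if (T == 0) return out;
  std::vector<double> S((size_t)T * L);
  sent_scores(W, feat, ptr, S, T, L);
  for (int t = 0; t < T; ++t)
    for (int l = 0; l < L; ++l) out(t, l) = S[(size_t)t * L + l];
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_decode(const NumericMatrix& W, const IntegerVector& feat,
                         const IntegerVector& ptr, const LogicalMatrix& allowed,
                         const LogicalVector& start_ok) {
  int T = ptr.size() - 1, L = W.ncol();
  IntegerVector res(T);
  if (T == 0) return res;
  std::vector<double> S((size_t)T * L);
  std::vector<int> pred(T);
  sent_scores(W, feat, ptr, S, T, L);
  greedy_decode(S, T, L, allowed, start_ok, pred);
  for (int t = 0; t < T; ++t) res[t] = pred[t] + 1;  // 1-based labels
  return res;
}

// [[Rcpp::export]]
List cpp_decode_many(const NumericMatrix& W, const List& feats, const List& ptrs,
                     const LogicalMatrix& allowed, const LogicalVector& start_ok) {
  int n = feats.size();
  List out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = cpp_decode(W, feats[i], ptrs[i], allowed, start_ok);
  }
  return out;
}

// One epoch of structured averaged-perceptron training. W is the raw weight
// matrix, Wa the timestamp-weighted accumulator (averaged weights are
// W - Wa / t_final); both are updated in place. `order` gives the 1-based
// sentence visiting order. Returns the updated timestamp counter.
// [[Rcpp::export]]
double cpp_train_epoch(NumericMatrix W, NumericMatrix Wa, double t0,
                       const List& feats, const List& ptrs, const List& golds,
                       const IntegerVector& order, const LogicalMatrix& allowed,
                       const LogicalVector& start_ok) {
  double t = t0;
  int L = W.ncol();
  std::vector<double> S;
  std::vector<int> pred;
  for (int oi = 0; oi < order.size(); ++oi) {
    int si = order[oi] - 1;
    IntegerVector feat = feats[si];
    IntegerVector ptr = ptrs[si];
    IntegerVector gold = golds[si];
    int T = ptr.size() - 1;
    if (T == 0) continue;
    if ((int)pred.size() < T) { pred.resize(T); }
    if (S.size() < (size_t)T * L) S.resize((size_t)T * L);
    sent_scores(W, feat, ptr, S, T, L);
    greedy_decode(S, T, L, allowed, start_ok, pred);
    for (int tt = 0; tt < T; ++tt) {
      int g = gold[tt] - 1, p = pred[tt];
      if (g == p) continue;
      for (int k = ptr[tt]; k < ptr[tt + 1]; ++k) {
        int f = feat[k];
        if (f <= 0) continue;
        W(f - 1, g) += 1.0; Wa(f - 1, g) += t;
        W(f - 1, p) -= 1.0; Wa(f - 1, p) -= t;
      }
    }
    t += 1.0;
  }
  return t;
}

// Mean over tokens of (1 - softmax margin between the two best labels);
// empty sentences score 0 (nothing to gain from annotating them).
// [[Rcpp::export]]
NumericVector cpp_uncertainty(const NumericMatrix& W, const List& feats,
                              const List& ptrs) {
  int n = feats.size(), L = W.ncol();
  NumericVector out(n);
  std::vector<double> S;
  for (int i = 0; i < n; ++i) {
    IntegerVector feat = feats[i];
    IntegerVector ptr = ptrs[i];
    int T = ptr.size() - 1;
    if (T == 0) { out[i] = 0.0; continue; }
    if (S.size() < (size_t)T * L) S.resize((size_t)T * L);
    sent_scores(W, feat, ptr, S, T, L);
    double acc = 0.0;
    for (int t = 0; t < T; ++t) {
      double mx = S[(size_t)t * L];
      for (int l = 1; l < L; ++l) mx = std::max(mx, S[(size_t)t * L + l]);
      double Z = 0.0;
      for (int l = 0; l < L; ++l) Z += std::exp(S[(size_t)t * L + l] - mx);
      double p1 = -1.0, p2 = -1.0;
      for (int l = 0; l < L; ++l) {
        double p = std::exp(S[(size_t)t * L + l] - mx) / Z;
        if (p > p1) { p2 = p1; p1 = p; } else if (p > p2) { p2 = p; }
      }
      acc += 1.0 - (p1 - p2);
    }
    out[i] = acc / T;
  }
  return out;
}
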