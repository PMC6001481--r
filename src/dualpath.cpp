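// Dual-path network core: forward propagation, per-step error
// backpropagation (Elman regime: the context layer is treated as a fixed
// input, no unrolling through time) and greedy production.
//
// Weight matrices are borrowed from the R side without copying and updated
// in place; the R wrappers own the reference-semantics contract.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

static inline vec sigm(const vec& x) { return 1.0 / (1.0 + arma::exp(-x)); }

static inline vec softmax_(const vec& x) {
  vec e = arma::exp(x - x.max());
  return e / arma::accu(e);
}

// borrow an R matrix / vector as an armadillo view (no copy, writable)
#define MATV(nm, key) NumericMatrix nm##_r = as<NumericMatrix>(w[key]); \
  mat nm(nm##_r.begin(), nm##_r.nrow(), nm##_r.ncol(), false, true);
#define VECV(nm, key) NumericVector nm##_r = as<NumericVector>(w[key]); \
  vec nm(nm##_r.begin(), nm##_r.size(), false, true);
#define MATVL(nm, key, lst) NumericMatrix nm##_r = as<NumericMatrix>(lst[key]); \
  mat nm(nm##_r.begin(), nm##_r.nrow(), nm##_r.ncol(), false, true);
#define VECVL(nm, key, lst) NumericVector nm##_r = as<NumericVector>(lst[key]); \
  vec nm(nm##_r.begin(), nm##_r.size(), false, true);
// momentum update: velocity accumulates the step's gradient, the weight
// moves along the velocity; plain gradient descent when momentum is 0
#define UPD(Wm, Vm, g, rate) \
  if (momentum > 0) { Vm = momentum * Vm + (g); Wm -= (rate) * Vm; } \
  else { Wm -= (rate) * (g); }

struct Dims { uword W, C, CC, H, R, P, E; };

// One forward+optional-backward pass over a token sequence.  Tokens are
// 1-based word indices including the terminating end-of-sentence token;
// the sentence-initial previous word is `start_idx`.
// [[Rcpp::export]]
List cpp_process_batch(List w, List sents, List binds, List evs,
                       NumericVector lr_lex, NumericVector lr_syn,
                       bool use_softmax, double strength, int start_idx,
                       bool collect, double momentum, List vel,
                       Nullable<NumericVector> init_context = R_NilValue,
                       Nullable<NumericVector> init_crolecopy = R_NilValue) {
  MATV(pc, "prev_cconcept");     // C x W
  MATV(pcc, "prev_ccompress");   // CC x W
  MATV(ch, "ccompress_hidden");  // H x CC
  MATV(hh, "context_hidden");    // H x H
  MATV(eh, "eventsem_hidden");   // H x E
  MATV(rh, "crole_hidden");      // H x R
  MATV(cch, "crolecopy_hidden"); // H x R
  MATV(hr, "hidden_role");       // R x H
  MATV(hc, "hidden_compress");   // P x H
  MATV(cw, "compress_word");     // W x P
  MATV(kw, "concept_word");      // W x C
  VECV(bh, "bias_hidden");
  VECV(bc, "bias_compress");
  VECV(bcc, "bias_ccompress");
  VECV(bw, "bias_word");
  MATVL(v_pc, "prev_cconcept", vel);
  MATVL(v_pcc, "prev_ccompress", vel);
  MATVL(v_ch, "ccompress_hidden", vel);
  MATVL(v_hh, "context_hidden", vel);
  MATVL(v_eh, "eventsem_hidden", vel);
  MATVL(v_rh, "crole_hidden", vel);
  MATVL(v_cch, "crolecopy_hidden", vel);
  MATVL(v_hr, "hidden_role", vel);
  MATVL(v_hc, "hidden_compress", vel);
  MATVL(v_cw, "compress_word", vel);
  MATVL(v_kw, "concept_word", vel);
  VECVL(v_bh, "bias_hidden", vel);
  VECVL(v_bc, "bias_compress", vel);
  VECVL(v_bcc, "bias_ccompress", vel);
  VECVL(v_bw, "bias_word", vel);

  Dims d;
  d.W = cw.n_rows; d.C = pc.n_rows; d.CC = pcc.n_rows; d.H = ch.n_rows;
  d.R = hr.n_rows; d.P = hc.n_rows; d.E = eh.n_cols;

  int n = sents.size();
  List sse_out(n);
  List outputs(n);

  for (int i = 0; i < n; ++i) {
    IntegerVector toks = sents[i];
    IntegerMatrix bind = binds[i];
    NumericVector ev_r = evs[i];
    vec ev(ev_r.begin(), ev_r.size(), false, true);
    double ll = lr_lex[i], ls = lr_syn[i];
    bool learn = (ll > 0.0) || (ls > 0.0);

    mat F(d.R, d.C, arma::fill::zeros);
    for (int k = 0; k < bind.nrow(); ++k)
      F(bind(k, 0) - 1, bind(k, 1) - 1) = strength;

    vec context(d.H);
    if (init_context.isNotNull()) {
      NumericVector c0(init_context);
      context = vec(c0.begin(), c0.size());
    } else {
      context.fill(0.5);
    }
    vec crolecopy(d.R, arma::fill::zeros);
    if (init_crolecopy.isNotNull()) {
      NumericVector cc0(init_crolecopy);
      crolecopy = vec(cc0.begin(), cc0.size());
    }

    int T = toks.size();
    NumericVector sse(T);
    NumericMatrix outmat;
    if (collect) outmat = NumericMatrix(T, d.W);

    int prev = start_idx;
    for (int t = 0; t < T; ++t) {
      int target = toks[t];
      uword p = prev - 1;

      vec cconcept = sigm(pc.col(p));
      vec ccompress = sigm(pcc.col(p) + bcc);
      vec crole = sigm(F * cconcept);
      vec hidden = sigm(ch * ccompress + hh * context + eh * ev +
                        rh * crole + cch * crolecopy + bh);
      vec role = sigm(hr * hidden);
      vec concept = sigm(F.t() * role);
      vec compress = sigm(hc * hidden + bc);
      vec net_out = cw * compress + kw * concept + bw;
      vec out = use_softmax ? softmax_(net_out) : sigm(net_out);

      vec tgt(d.W, arma::fill::zeros);
      tgt(target - 1) = 1.0;
      vec diff = out - tgt;
      sse[t] = arma::accu(arma::square(diff));
      if (collect)
        for (uword j = 0; j < d.W; ++j) outmat(t, j) = out(j);

      if (learn) {
        // softmax outputs train under multinomial cross-entropy (delta
        // o - t); logistic outputs train under summed squared error, whose
        // delta carries the activation-function derivative o(1 - o) --
        // the entrenchment factor
        vec dout = use_softmax ? diff : vec(diff % out % (1.0 - out));
        vec dcompress = (cw.t() * dout) % compress % (1.0 - compress);
        vec dconcept = (kw.t() * dout) % concept % (1.0 - concept);
        vec drole = (F * dconcept) % role % (1.0 - role);
        vec dhidden = (hc.t() * dcompress + hr.t() * drole) %
                      hidden % (1.0 - hidden);
        vec dccompress = (ch.t() * dhidden) % ccompress % (1.0 - ccompress);
        vec dcrole = (rh.t() * dhidden) % crole % (1.0 - crole);
        vec dcconcept = (F.t() * dcrole) % cconcept % (1.0 - cconcept);

        // lexical groups
        UPD(cw, v_cw, dout * compress.t(), ll);
        UPD(kw, v_kw, dout * concept.t(), ll);
        UPD(hc, v_hc, dcompress * hidden.t(), ll);
        UPD(bw, v_bw, dout, ll);
        // syntactic groups
        UPD(hr, v_hr, drole * hidden.t(), ls);
        UPD(ch, v_ch, dhidden * ccompress.t(), ls);
        UPD(hh, v_hh, dhidden * context.t(), ls);
        UPD(eh, v_eh, dhidden * ev.t(), ls);
        UPD(rh, v_rh, dhidden * crole.t(), ls);
        UPD(cch, v_cch, dhidden * crolecopy.t(), ls);
        UPD(bh, v_bh, dhidden, ls);
        UPD(bc, v_bc, dcompress, ls);
        UPD(bcc, v_bcc, dccompress, ls);
        if (momentum > 0) {
          v_pcc.col(p) = momentum * v_pcc.col(p) + dccompress;
          pcc.col(p) -= ls * v_pcc.col(p);
          v_pc.col(p) = momentum * v_pc.col(p) + dcconcept;
          pc.col(p) -= ls * v_pc.col(p);
        } else {
          pcc.col(p) -= ls * dccompress;
          pc.col(p) -= ls * dcconcept;
        }
      }

      context = hidden;
      crolecopy = arma::max(crolecopy, crole);
      prev = target;
    }
    sse_out[i] = sse;
    if (collect) outputs[i] = outmat;
  }
  if (collect)
    return List::create(_["sse"] = sse_out, _["outputs"] = outputs);
  return List::create(_["sse"] = sse_out, _["outputs"] = R_NilValue);
}

// Greedy generation: argmax output fed back as the next previous word until
// the end-of-sentence token or max_len.  Ties break to the lowest token
// index; the sentence-start token is never produced.
// [[Rcpp::export]]
IntegerVector cpp_produce(List w, IntegerMatrix bind, NumericVector ev_r,
                          bool use_softmax, double strength, int start_idx,
                          int eos_idx, int max_len) {
  MATV(pc, "prev_cconcept");
  MATV(pcc, "prev_ccompress");
  MATV(ch, "ccompress_hidden");
  MATV(hh, "context_hidden");
  MATV(eh, "eventsem_hidden");
  MATV(rh, "crole_hidden");
  MATV(cch, "crolecopy_hidden");
  MATV(hr, "hidden_role");
  MATV(hc, "hidden_compress");
  MATV(cw, "compress_word");
  MATV(kw, "concept_word");
  VECV(bh, "bias_hidden");
  VECV(bc, "bias_compress");
  VECV(bcc, "bias_ccompress");
  VECV(bw, "bias_word");

  uword W = cw.n_rows, C = pc.n_rows, H = ch.n_rows, R = hr.n_rows;
  vec ev(ev_r.begin(), ev_r.size(), false, true);
  mat F(R, C, arma::fill::zeros);
  for (int k = 0; k < bind.nrow(); ++k)
    F(bind(k, 0) - 1, bind(k, 1) - 1) = strength;

  vec context(H); context.fill(0.5);
  vec crolecopy(R, arma::fill::zeros);
  std::vector<int> produced;
  int prev = start_idx;
  for (int t = 0; t < max_len; ++t) {
    uword p = prev - 1;
    vec cconcept = sigm(pc.col(p));
    vec ccompress = sigm(pcc.col(p) + bcc);
    vec crole = sigm(F * cconcept);
    vec hidden = sigm(ch * ccompress + hh * context + eh * ev +
                      rh * crole + cch * crolecopy + bh);
    vec role = sigm(hr * hidden);
    vec concept = sigm(F.t() * role);
    vec compress = sigm(hc * hidden + bc);
    vec net_out = cw * compress + kw * concept + bw;
    vec out = use_softmax ? softmax_(net_out) : sigm(net_out);
    out(start_idx - 1) = -1.0;
    int word = static_cast<int>(out.index_max()) + 1;
    produced.push_back(word);
    if (word == eos_idx) break;
    context = hidden;
    crolecopy = arma::max(crolecopy, crole);
    prev = word;
  }
  return wrap(produced);
}
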