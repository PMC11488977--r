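// Forward and backward passes of the pathway-masked single-layer
// multi-head attention classifier. Parameter layout (all dense):
//   Wemb : (k*G) x m, row p*G + g holds the m-dim embedding weights of
//          gene g in pathway token p; rows with mask 0 are exactly 0.
//   cls  : m        trainable class token
//   Wq,Wk,Wv : m x m, head h occupies column block [h*dk, (h+1)*dk)
//   Wp   : m x T    prediction head;  b : T  bias
// Per cell: I = rbind(cls, tokens) ((1+k) x m); per head
// A = row-softmax(Q K' / sqrt(dk)); O = [A V_h]_h; p = softmax(O[0,] Wp + b).
// Loss is the summed KL(l || p) over the batch; gradients are of that sum.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double PEPS = 1e-8;   // floor inside log for KL

static void softmax_rows(mat &S) {
    for (uword r = 0; r < S.n_rows; ++r) {
        rowvec v = S.row(r) - S.row(r).max();
        rowvec e = exp(v);
        S.row(r) = e / accu(e);
    }
}

// Embed all cells into pathway tokens: returns cube (n, m, k).
static cube embed_all(const mat &X, const mat &Wemb, uword k) {
    const uword n = X.n_rows, G = X.n_cols, m = Wemb.n_cols;
    cube Tok(n, m, k);
    for (uword p = 0; p < k; ++p)
        Tok.slice(p) = X * Wemb.rows(p * G, (p + 1) * G - 1);
    return Tok;
}

// [[Rcpp::export(name = ".cppForward")]]
Rcpp::List cppForward(const arma::mat &X, const Rcpp::List &params,
                      int k_, int nHeads_, bool wantAttention,
                      bool wantFull) {
    const uword k = (uword)k_, nHeads = (uword)nHeads_;
    const mat Wemb = params["Wemb"];
    const vec cls = params["cls"];
    const mat Wq = params["Wq"], Wk = params["Wk"], Wv = params["Wv"];
    const mat Wp = params["Wp"];
    const vec b = params["b"];
    const uword n = X.n_rows, m = Wemb.n_cols, T = Wp.n_cols;
    const uword dk = m / nHeads;
    const double sc = 1.0 / std::sqrt((double)dk);

    cube Tok = embed_all(X, Wemb, k);
    mat probs(n, T);
    mat attn;
    if (wantAttention) attn.zeros(n, k);
    Rcpp::List full;   // per-head full attention matrices, first cell only

    mat I(1 + k, m);
    for (uword i = 0; i < n; ++i) {
        I.row(0) = cls.t();
        for (uword p = 0; p < k; ++p)
            I.row(p + 1) = Tok.slice(p).row(i);
        mat V = I * Wv;
        mat O(1 + k, m);
        for (uword h = 0; h < nHeads; ++h) {
            span cs(h * dk, (h + 1) * dk - 1);
            mat Qh = I * Wq.cols(cs);
            mat Kh = I * Wk.cols(cs);
            mat A = Qh * Kh.t() * sc;
            softmax_rows(A);
            O.cols(cs) = A * V.cols(cs);
            if (wantAttention)
                attn.row(i) += A.row(0).subvec(1, k) / (double)nHeads;
            if (wantFull && i == 0)
                full.push_back(A);
        }
        rowvec logits = O.row(0) * Wp + b.t();
        rowvec e = exp(logits - logits.max());
        probs.row(i) = e / accu(e);
    }

    Rcpp::List out = Rcpp::List::create(Rcpp::Named("probs") = probs);
    if (wantAttention) out["attention"] = attn;
    if (wantFull) out["fullAttention"] = full;
    return out;
}

// [[Rcpp::export(name = ".cppLoss")]]
double cppLoss(const arma::mat &target, const arma::mat &pred) {
    double loss = 0.0;
    for (uword i = 0; i < target.n_rows; ++i)
        for (uword j = 0; j < target.n_cols; ++j) {
            double l = target(i, j);
            if (l > 0)
                loss += l * (std::log(l) -
                             std::log(std::max(pred(i, j), PEPS)));
        }
    return loss;
}

// [[Rcpp::export(name = ".cppForwardBackward")]]
Rcpp::List cppForwardBackward(const arma::mat &X, const arma::mat &L,
                              const Rcpp::List &params,
                              const arma::vec &maskVec,
                              int k_, int nHeads_) {
    const uword k = (uword)k_, nHeads = (uword)nHeads_;
    const mat Wemb = params["Wemb"];
    const vec cls = params["cls"];
    const mat Wq = params["Wq"], Wk = params["Wk"], Wv = params["Wv"];
    const mat Wp = params["Wp"];
    const vec b = params["b"];
    const uword n = X.n_rows, G = X.n_cols, m = Wemb.n_cols, T = Wp.n_cols;
    const uword dk = m / nHeads;
    const double sc = 1.0 / std::sqrt((double)dk);

    cube Tok = embed_all(X, Wemb, k);
    cube dTok(n, m, k, fill::zeros);

    mat gWemb(Wemb.n_rows, m, fill::zeros);
    vec gcls(m, fill::zeros);
    mat gWq(m, m, fill::zeros), gWk(m, m, fill::zeros),
        gWv(m, m, fill::zeros);
    mat gWp(m, T, fill::zeros);
    vec gb(T, fill::zeros);
    double loss = 0.0;
    mat probs(n, T);

    mat I(1 + k, m);
    // Per-head caches so the backward pass reuses forward activations.
    std::vector<mat> Qs(nHeads), Ks(nHeads), As(nHeads);
    for (uword i = 0; i < n; ++i) {
        I.row(0) = cls.t();
        for (uword p = 0; p < k; ++p)
            I.row(p + 1) = Tok.slice(p).row(i);
        mat V = I * Wv;
        mat O(1 + k, m);
        for (uword h = 0; h < nHeads; ++h) {
            span cs(h * dk, (h + 1) * dk - 1);
            Qs[h] = I * Wq.cols(cs);
            Ks[h] = I * Wk.cols(cs);
            mat A = Qs[h] * Ks[h].t() * sc;
            softmax_rows(A);
            As[h] = A;
            O.cols(cs) = A * V.cols(cs);
        }
        rowvec logits = O.row(0) * Wp + b.t();
        rowvec e = exp(logits - logits.max());
        rowvec p = e / accu(e);
        probs.row(i) = p;
        for (uword j = 0; j < T; ++j) {
            double l = L(i, j);
            if (l > 0)
                loss += l * (std::log(l) - std::log(std::max(p(j), PEPS)));
        }

        // ---- backward ----
        rowvec dlog = p - L.row(i);            // d loss / d logits
        gWp += O.row(0).t() * dlog;
        gb += dlog.t();
        rowvec dO0 = dlog * Wp.t();            // only CLS row of O matters
        mat dI(1 + k, m, fill::zeros);
        mat dV(1 + k, m, fill::zeros);
        for (uword h = 0; h < nHeads; ++h) {
            span cs(h * dk, (h + 1) * dk - 1);
            mat dOh(1 + k, dk, fill::zeros);
            dOh.row(0) = dO0.cols(cs.a, cs.b);
            const mat &A = As[h];
            mat dA = dOh * V.cols(cs).t();
            dV.cols(cs) += A.t() * dOh;
            mat dS(1 + k, 1 + k);
            for (uword r = 0; r < 1 + k; ++r) {
                double dotval = dot(dA.row(r), A.row(r));
                dS.row(r) = A.row(r) % (dA.row(r) - dotval);
            }
            dS *= sc;
            mat dQ = dS * Ks[h];
            mat dK = dS.t() * Qs[h];
            dI += dQ * Wq.cols(cs).t() + dK * Wk.cols(cs).t();
            gWq.cols(cs) += I.t() * dQ;
            gWk.cols(cs) += I.t() * dK;
        }
        dI += dV * Wv.t();
        gWv += I.t() * dV;
        gcls += dI.row(0).t();
        for (uword p = 0; p < k; ++p)
            dTok.slice(p).row(i) = dI.row(p + 1);
    }

    for (uword p = 0; p < k; ++p)
        gWemb.rows(p * G, (p + 1) * G - 1) = X.t() * dTok.slice(p);
    gWemb.each_col() %= maskVec;   // masked positions never receive gradient

    return Rcpp::List::create(
        Rcpp::Named("loss") = loss,
        Rcpp::Named("probs") = probs,
        Rcpp::Named("grads") = Rcpp::List::create(
            Rcpp::Named("Wemb") = gWemb, Rcpp::Named("cls") = gcls,
            Rcpp::Named("Wq") = gWq, Rcpp::Named("Wk") = gWk,
            Rcpp::Named("Wv") = gWv, Rcpp::Named("Wp") = gWp,
            Rcpp::Named("b") = gb));
}
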