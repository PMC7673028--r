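// Batched one-directional LSTM forward / backward-through-time.
//
// Layout: X is an R array [B, D, T] (trace, feature, step) mapped to an
// arma::cube with slice t = the [B, D] input at step t. Gate blocks in the
// 4H-wide preactivation are (input, forget, output, candidate); the three
// sigmoid gates first. Sequences shorter than T are padded; state updates
// at padded steps are masked out, so h/c carry each sequence's last valid
// state and padding never reaches outputs or gradients.
//
// The caches handed back to R are flat [B*T, .] matrices (step-major), the
// same layout the R-side dense/flatten helpers use.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export]]
Rcpp::List cpp_lstm_forward(const arma::cube& X, const arma::ivec& lens,
                            const arma::mat& W, const arma::mat& U,
                            const arma::vec& b, const bool needHs,
                            const bool needCache) {
    const uword B = X.n_rows, D = X.n_cols, T = X.n_slices;
    const uword H = b.n_elem / 4;
    const rowvec bt = b.t();

    mat h(B, H, fill::zeros), cs(B, H, fill::zeros);
    cube Hs;
    if (needHs) Hs.zeros(B, H, T);
    mat Gflat, tcFlat, cPrevFlat, HprevFlat;
    if (needCache) {
        Gflat.set_size(B * T, 4 * H);
        tcFlat.set_size(B * T, H);
        cPrevFlat.set_size(B * T, H);
        HprevFlat.set_size(B * T, H);
    }

    bool ragged = false;
    for (uword i = 0; i < B; ++i)
        if ((uword)lens[i] < T) { ragged = true; break; }

    for (uword t = 0; t < T; ++t) {
        if (needCache) {
            HprevFlat.rows(t * B, t * B + B - 1) = h;
            cPrevFlat.rows(t * B, t * B + B - 1) = cs;
        }
        mat G = X.slice(t) * W + h * U;
        G.each_row() += bt;
        G.cols(0, 3 * H - 1) = sigm(G.cols(0, 3 * H - 1));
        G.cols(3 * H, 4 * H - 1) = tanh(G.cols(3 * H, 4 * H - 1));

        mat cNew = G.cols(H, 2 * H - 1) % cs +
                   G.cols(0, H - 1) % G.cols(3 * H, 4 * H - 1);
        mat tc = tanh(cNew);
        mat hNew = G.cols(2 * H, 3 * H - 1) % tc;

        if (needCache) {
            Gflat.rows(t * B, t * B + B - 1) = G;
            tcFlat.rows(t * B, t * B + B - 1) = tc;
        }
        if (!ragged) {
            cs = std::move(cNew);
            h = std::move(hNew);
        } else {
            for (uword i = 0; i < B; ++i) {
                if ((uword)lens[i] >= t + 1) {
                    cs.row(i) = cNew.row(i);
                    h.row(i) = hNew.row(i);
                }
            }
        }
        if (needHs) Hs.slice(t) = h;
    }

    Rcpp::List out = Rcpp::List::create(
        Rcpp::Named("hT") = h,
        Rcpp::Named("B") = (int)B, Rcpp::Named("D") = (int)D,
        Rcpp::Named("T") = (int)T);
    if (needHs) out["Hs"] = Hs;
    if (needCache) {
        out["Gflat"] = Gflat;
        out["tcFlat"] = tcFlat;
        out["cPrevFlat"] = cPrevFlat;
        out["HprevFlat"] = HprevFlat;
    }
    return out;
}

// dHs: [B, H, T] per-step output gradients (empty cube if none);
// dhT: [B, H] gradient on the running final state (empty if none).
// [[Rcpp::export]]
Rcpp::List cpp_lstm_backward(const arma::cube& X, const arma::ivec& lens,
                             const arma::mat& W, const arma::mat& U,
                             const arma::mat& Gflat, const arma::mat& tcFlat,
                             const arma::mat& cPrevFlat,
                             const arma::mat& HprevFlat,
                             const arma::cube& dHs, const arma::mat& dhT) {
    const uword B = X.n_rows, D = X.n_cols, T = X.n_slices;
    const uword H = U.n_rows;
    const mat tU = U.t();
    const bool hasDHs = dHs.n_elem > 0;

    bool ragged = false;
    for (uword i = 0; i < B; ++i)
        if ((uword)lens[i] < T) { ragged = true; break; }

    mat dh = dhT.n_elem > 0 ? dhT : mat(B, H, fill::zeros);
    mat dc(B, H, fill::zeros);
    mat dAflat(B * T, 4 * H);

    for (uword tt = T; tt-- > 0;) {
        const uword r0 = tt * B, r1 = tt * B + B - 1;
        if (hasDHs) dh += dHs.slice(tt);

        mat dhNew, dhPrev, dcNew, dcPrev0;
        if (!ragged) {
            dhNew = dh; dcNew = dc;
            dhPrev.zeros(B, H); dcPrev0.zeros(B, H);
        } else {
            dhNew.zeros(B, H); dhPrev.zeros(B, H);
            dcNew.zeros(B, H); dcPrev0.zeros(B, H);
            for (uword i = 0; i < B; ++i) {
                if ((uword)lens[i] >= tt + 1) {
                    dhNew.row(i) = dh.row(i);
                    dcNew.row(i) = dc.row(i);
                } else {
                    dhPrev.row(i) = dh.row(i);
                    dcPrev0.row(i) = dc.row(i);
                }
            }
        }

        const mat ig = Gflat(span(r0, r1), span(0, H - 1));
        const mat fg = Gflat(span(r0, r1), span(H, 2 * H - 1));
        const mat og = Gflat(span(r0, r1), span(2 * H, 3 * H - 1));
        const mat gg = Gflat(span(r0, r1), span(3 * H, 4 * H - 1));
        const mat tc = tcFlat.rows(r0, r1);
        const mat cPrev = cPrevFlat.rows(r0, r1);

        mat dog = dhNew % tc;
        mat dcn = dcNew + dhNew % og % (1.0 - tc % tc);

        mat dA(B, 4 * H);
        dA.cols(0, H - 1) = (dcn % gg) % ig % (1.0 - ig);
        dA.cols(H, 2 * H - 1) = (dcn % cPrev) % fg % (1.0 - fg);
        dA.cols(2 * H, 3 * H - 1) = dog % og % (1.0 - og);
        dA.cols(3 * H, 4 * H - 1) = (dcn % ig) % (1.0 - gg % gg);
        dAflat.rows(r0, r1) = dA;

        dh = dA * tU + dhPrev;
        dc = dcn % fg + dcPrev0;
    }

    // flat GEMMs for the weight gradients and input gradient
    mat Xflat(B * T, D);
    for (uword t = 0; t < T; ++t)
        Xflat.rows(t * B, t * B + B - 1) = X.slice(t);
    mat dW = Xflat.t() * dAflat;
    mat dU = HprevFlat.t() * dAflat;
    rowvec db = sum(dAflat, 0);
    mat dXflat = dAflat * W.t();
    cube dX(B, D, T);
    for (uword t = 0; t < T; ++t)
        dX.slice(t) = dXflat.rows(t * B, t * B + B - 1);

    return Rcpp::List::create(
        Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
        Rcpp::Named("dU") = dU, Rcpp::Named("db") = db.t());
}
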