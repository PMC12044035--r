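// A small 1-D convolutional network for spike rate regression, trained with
// Adam on mean-squared error. Architecture (fixed topology, sizes supplied
// from R): conv(f1, n1) - relu - conv(f2, n2) - relu - maxpool2 -
// conv(f3, n3) - relu - maxpool2 - dense(nd) - relu - linear(1).
// Convolutions are "valid" and realized as im2col + GEMM over whole
// minibatches. All randomness (weight init, shuffling) comes from a
// mt19937 stream with a Box-Muller transform, so results are reproducible
// across platforms for a given seed.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Arch {
    int W, f1, n1, f2, n2, f3, n3, nd;
    int L1, L2, P2, L3, P3, flat;
};

Arch makeArch(int W, int f1, int f2, int f3, int n1, int n2, int n3,
              int nd) {
    Arch a;
    a.W = W; a.f1 = f1; a.n1 = n1; a.f2 = f2; a.n2 = n2; a.f3 = f3;
    a.n3 = n3; a.nd = nd;
    a.L1 = W - f1 + 1;
    a.L2 = a.L1 - f2 + 1;
    if (a.L2 % 2) Rcpp::stop("layer-2 length must be even for pooling");
    a.P2 = a.L2 / 2;
    a.L3 = a.P2 - f3 + 1;
    if (a.L3 % 2) Rcpp::stop("layer-3 length must be even for pooling");
    a.P3 = a.L3 / 2;
    a.flat = a.P3 * a.n3;
    return a;
}

struct Params {
    mat W1, W2, W3, W4, W5;       // im2col weight matrices
    rowvec b1, b2, b3, b4;
    double b5;
};

class BoxMuller {
    std::mt19937 &g;
    bool has_;
    double spare_;
public:
    explicit BoxMuller(std::mt19937 &gen) : g(gen), has_(false),
                                            spare_(0) {}
    double operator()() {
        if (has_) { has_ = false; return spare_; }
        double u1, u2;
        do {
            u1 = (g() + 0.5) / 4294967296.0;
            u2 = (g() + 0.5) / 4294967296.0;
        } while (u1 <= 0);
        double r = std::sqrt(-2.0 * std::log(u1));
        spare_ = r * std::sin(6.283185307179586 * u2);
        has_ = true;
        return r * std::cos(6.283185307179586 * u2);
    }
};

mat heInit(int rows, int cols, int fanIn, BoxMuller &bm) {
    mat M(rows, cols);
    double sd = std::sqrt(2.0 / fanIn);
    for (uword j = 0; j < M.n_cols; ++j)
        for (uword i = 0; i < M.n_rows; ++i)
            M(i, j) = sd * bm();
    return M;
}

// im2col for layer 1: input X is B x W, output (B*L1) x f1, rows grouped
// per sample (sample-major, position within sample fastest).
mat im2col1(const mat &X, const Arch &a) {
    int B = X.n_rows;
    mat C(B * a.L1, a.f1);
    for (int b = 0; b < B; ++b)
        for (int p = 0; p < a.L1; ++p)
            for (int i = 0; i < a.f1; ++i)
                C(b * a.L1 + p, i) = X(b, p + i);
    return C;
}

// im2col for an internal layer: Z is (B*Lin) x nchan, output
// (B*Lout) x (f*nchan) with column index i * nchan + j.
mat im2colN(const mat &Z, int B, int Lin, int f, const int Lout) {
    int nch = Z.n_cols;
    mat C(B * Lout, f * nch);
    for (int b = 0; b < B; ++b)
        for (int p = 0; p < Lout; ++p)
            for (int i = 0; i < f; ++i)
                for (int j = 0; j < nch; ++j)
                    C(b * Lout + p, i * nch + j) = Z(b * Lin + p + i, j);
    return C;
}

// scatter-add inverse of im2colN
void col2imN(const mat &dC, mat &dZ, int B, int Lin, int f, int Lout) {
    int nch = dZ.n_cols;
    for (int b = 0; b < B; ++b)
        for (int p = 0; p < Lout; ++p)
            for (int i = 0; i < f; ++i)
                for (int j = 0; j < nch; ++j)
                    dZ(b * Lin + p + i, j) += dC(b * Lout + p, i * nch + j);
}

// max-pool rows pairwise within each sample: Z (B*L) x n -> (B*L/2) x n
mat pool2(const mat &Z, int B, int L, umat &argmax) {
    int P = L / 2;
    mat out(B * P, Z.n_cols);
    argmax.set_size(B * P, Z.n_cols);
    for (int b = 0; b < B; ++b)
        for (int p = 0; p < P; ++p)
            for (uword j = 0; j < Z.n_cols; ++j) {
                double v0 = Z(b * L + 2 * p, j), v1 = Z(b * L + 2 * p + 1, j);
                if (v0 >= v1) { out(b * P + p, j) = v0;
                                argmax(b * P + p, j) = 0; }
                else { out(b * P + p, j) = v1; argmax(b * P + p, j) = 1; }
            }
    return out;
}

void unpool2(const mat &dP, mat &dZ, int B, int L, const umat &argmax) {
    int P = L / 2;
    for (int b = 0; b < B; ++b)
        for (int p = 0; p < P; ++p)
            for (uword j = 0; j < dP.n_cols; ++j)
                dZ(b * L + 2 * p + argmax(b * P + p, j), j) +=
                    dP(b * P + p, j);
}

// flatten (B*P3) x n3 -> B x (P3*n3), column index p * n3 + j
mat flatten(const mat &Z, int B, int P) {
    int n = Z.n_cols;
    mat F(B, P * n);
    for (int b = 0; b < B; ++b)
        for (int p = 0; p < P; ++p)
            for (int j = 0; j < n; ++j)
                F(b, p * n + j) = Z(b * P + p, j);
    return F;
}

mat unflatten(const mat &dF, int B, int P, int n) {
    mat dZ(B * P, n);
    for (int b = 0; b < B; ++b)
        for (int p = 0; p < P; ++p)
            for (int j = 0; j < n; ++j)
                dZ(b * P + p, j) = dF(b, p * n + j);
    return dZ;
}

struct Cache {
    mat C1, Z1, C2, Z2, Zp2, C3, Z3, Zp3, F, H;
    umat am2, am3;
    vec out;
};

vec forward(const mat &X, const Params &P, const Arch &a, Cache *cache) {
    int B = X.n_rows;
    mat C1 = im2col1(X, a);
    mat Z1 = C1 * P.W1;
    Z1.each_row() += P.b1;
    Z1.transform([](double v) { return v > 0 ? v : 0.0; });
    mat C2 = im2colN(Z1, B, a.L1, a.f2, a.L2);
    mat Z2 = C2 * P.W2;
    Z2.each_row() += P.b2;
    Z2.transform([](double v) { return v > 0 ? v : 0.0; });
    umat am2;
    mat Zp2 = pool2(Z2, B, a.L2, am2);
    mat C3 = im2colN(Zp2, B, a.P2, a.f3, a.L3);
    mat Z3 = C3 * P.W3;
    Z3.each_row() += P.b3;
    Z3.transform([](double v) { return v > 0 ? v : 0.0; });
    umat am3;
    mat Zp3 = pool2(Z3, B, a.L3, am3);
    mat F = flatten(Zp3, B, a.P3);
    mat H = F * P.W4;
    H.each_row() += P.b4;
    H.transform([](double v) { return v > 0 ? v : 0.0; });
    vec out = H * P.W5 + P.b5;
    if (cache) {
        cache->C1 = std::move(C1); cache->Z1 = std::move(Z1);
        cache->C2 = std::move(C2); cache->Z2 = std::move(Z2);
        cache->Zp2 = std::move(Zp2); cache->C3 = std::move(C3);
        cache->Z3 = std::move(Z3); cache->Zp3 = std::move(Zp3);
        cache->F = std::move(F); cache->H = std::move(H);
        cache->am2 = std::move(am2); cache->am3 = std::move(am3);
        cache->out = out;
    }
    return out;
}

struct Grads {
    mat W1, W2, W3, W4;
    vec W5;
    rowvec b1, b2, b3, b4;
    double b5;
};

void backward(const mat &X, const vec &y, const Params &P, const Arch &a,
              const Cache &c, Grads &g) {
    int B = X.n_rows;
    vec dout = 2.0 * (c.out - y) / (double)B;   // d(MSE)/d(out)
    g.W5 = c.H.t() * dout;
    g.b5 = accu(dout);
    mat dH = dout * P.W5.t();
    dH %= conv_to<mat>::from(c.H > 0);
    g.W4 = c.F.t() * dH;
    g.b4 = sum(dH, 0);
    mat dF = dH * P.W4.t();
    mat dZp3 = unflatten(dF, B, a.P3, a.n3);
    mat dZ3(B * a.L3, a.n3, fill::zeros);
    unpool2(dZp3, dZ3, B, a.L3, c.am3);
    dZ3 %= conv_to<mat>::from(c.Z3 > 0);
    g.W3 = c.C3.t() * dZ3;
    g.b3 = sum(dZ3, 0);
    mat dC3 = dZ3 * P.W3.t();
    mat dZp2(B * a.P2, a.n2, fill::zeros);
    col2imN(dC3, dZp2, B, a.P2, a.f3, a.L3);
    mat dZ2(B * a.L2, a.n2, fill::zeros);
    unpool2(dZp2, dZ2, B, a.L2, c.am2);
    dZ2 %= conv_to<mat>::from(c.Z2 > 0);
    g.W2 = c.C2.t() * dZ2;
    g.b2 = sum(dZ2, 0);
    mat dC2 = dZ2 * P.W2.t();
    mat dZ1(B * a.L1, a.n1, fill::zeros);
    col2imN(dC2, dZ1, B, a.L1, a.f2, a.L2);
    dZ1 %= conv_to<mat>::from(c.Z1 > 0);
    g.W1 = c.C1.t() * dZ1;
    g.b1 = sum(dZ1, 0);
}

struct AdamState {
    mat m, v;
    AdamState(int r, int c) : m(r, c, fill::zeros), v(r, c, fill::zeros) {}
};

void adamStep(mat &W, const mat &g, AdamState &st, double lr, double t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    st.m = b1 * st.m + (1 - b1) * g;
    st.v = b2 * st.v + (1 - b2) * square(g);
    mat mh = st.m / (1 - std::pow(b1, t));
    mat vh = st.v / (1 - std::pow(b2, t));
    W -= lr * mh / (sqrt(vh) + eps);
}

Params paramsFromList(const Rcpp::List &w) {
    Params P;
    P.W1 = Rcpp::as<mat>(w["W1"]); P.W2 = Rcpp::as<mat>(w["W2"]);
    P.W3 = Rcpp::as<mat>(w["W3"]); P.W4 = Rcpp::as<mat>(w["W4"]);
    P.W5 = Rcpp::as<mat>(w["W5"]);
    P.b1 = Rcpp::as<rowvec>(w["b1"]); P.b2 = Rcpp::as<rowvec>(w["b2"]);
    P.b3 = Rcpp::as<rowvec>(w["b3"]); P.b4 = Rcpp::as<rowvec>(w["b4"]);
    P.b5 = Rcpp::as<double>(w["b5"]);
    return P;
}

Rcpp::List paramsToList(const Params &P) {
    return Rcpp::List::create(
        Rcpp::_["W1"] = P.W1, Rcpp::_["b1"] = P.b1,
        Rcpp::_["W2"] = P.W2, Rcpp::_["b2"] = P.b2,
        Rcpp::_["W3"] = P.W3, Rcpp::_["b3"] = P.b3,
        Rcpp::_["W4"] = P.W4, Rcpp::_["b4"] = P.b4,
        Rcpp::_["W5"] = P.W5, Rcpp::_["b5"] = P.b5);
}

} // namespace

// [[Rcpp::export(name = ".cnnTrain")]]
Rcpp::List cnnTrain(const arma::mat &X, const arma::vec &y,
                    int f1, int f2, int f3, int n1, int n2, int n3, int nd,
                    int epochs, int batchSize, double lr,
                    double valFraction, int patience, int seed) {
    Arch a = makeArch(X.n_cols, f1, f2, f3, n1, n2, n3, nd);
    int N = X.n_rows;
    std::mt19937 gen((unsigned)seed);
    BoxMuller bm(gen);

    Params P;
    P.W1 = heInit(a.f1, a.n1, a.f1, bm);
    P.W2 = heInit(a.f2 * a.n1, a.n2, a.f2 * a.n1, bm);
    P.W3 = heInit(a.f3 * a.n2, a.n3, a.f3 * a.n2, bm);
    P.W4 = heInit(a.flat, a.nd, a.flat, bm);
    P.W5 = heInit(a.nd, 1, a.nd, bm);
    P.b1 = rowvec(a.n1, fill::zeros); P.b2 = rowvec(a.n2, fill::zeros);
    P.b3 = rowvec(a.n3, fill::zeros); P.b4 = rowvec(a.nd, fill::zeros);
    P.b5 = 0.0;

    // deterministic shuffle, then split off the validation tail
    std::vector<int> idx(N);
    for (int i = 0; i < N; ++i) idx[i] = i;
    for (int i = N - 1; i > 0; --i) {
        int j = (int)(gen() % (unsigned)(i + 1));
        std::swap(idx[i], idx[j]);
    }
    int nVal = std::max(1, (int)std::floor(N * valFraction));
    int nTrain = N - nVal;
    if (nTrain < 1) Rcpp::stop("training set empty after validation split");
    uvec trIdx(nTrain), vaIdx(nVal);
    for (int i = 0; i < nTrain; ++i) trIdx[i] = idx[i];
    for (int i = 0; i < nVal; ++i) vaIdx[i] = idx[nTrain + i];
    mat Xtr = X.rows(trIdx), Xva = X.rows(vaIdx);
    vec ytr = y.elem(trIdx), yva = y.elem(vaIdx);

    AdamState sW1(P.W1.n_rows, P.W1.n_cols), sW2(P.W2.n_rows, P.W2.n_cols),
        sW3(P.W3.n_rows, P.W3.n_cols), sW4(P.W4.n_rows, P.W4.n_cols),
        sW5(a.nd, 1), sb1(1, a.n1), sb2(1, a.n2), sb3(1, a.n3),
        sb4(1, a.nd), sb5(1, 1);

    Params best = P;
    double bestVal = datum::inf;
    int bad = 0, adamT = 0, epochsRun = 0;
    std::vector<double> valHist, trainHist;

    for (int ep = 0; ep < epochs; ++ep) {
        // reshuffle training order each epoch
        std::vector<int> ord(nTrain);
        for (int i = 0; i < nTrain; ++i) ord[i] = i;
        for (int i = nTrain - 1; i > 0; --i) {
            int j = (int)(gen() % (unsigned)(i + 1));
            std::swap(ord[i], ord[j]);
        }
        double epLoss = 0;
        int nBatches = 0;
        for (int start = 0; start < nTrain; start += batchSize) {
            int end = std::min(start + batchSize, nTrain);
            uvec bidx(end - start);
            for (int i = start; i < end; ++i) bidx[i - start] = ord[i];
            mat Xb = Xtr.rows(bidx);
            vec yb = ytr.elem(bidx);
            Cache c;
            forward(Xb, P, a, &c);
            double loss = accu(square(c.out - yb)) / yb.n_elem;
            if (!std::isfinite(loss)) Rcpp::stop("training diverged: loss is not finite");
            epLoss += loss; ++nBatches;
            Grads g;
            backward(Xb, yb, P, a, c, g);
            ++adamT;
            adamStep(P.W1, g.W1, sW1, lr, adamT);
            adamStep(P.W2, g.W2, sW2, lr, adamT);
            adamStep(P.W3, g.W3, sW3, lr, adamT);
            adamStep(P.W4, g.W4, sW4, lr, adamT);
            mat w5 = P.W5; adamStep(w5, g.W5, sW5, lr, adamT); P.W5 = w5;
            mat b1 = P.b1; adamStep(b1, g.b1, sb1, lr, adamT); P.b1 = b1;
            mat b2 = P.b2; adamStep(b2, g.b2, sb2, lr, adamT); P.b2 = b2;
            mat b3 = P.b3; adamStep(b3, g.b3, sb3, lr, adamT); P.b3 = b3;
            mat b4 = P.b4; adamStep(b4, g.b4, sb4, lr, adamT); P.b4 = b4;
            mat b5m(1, 1); b5m(0, 0) = P.b5;
            mat g5(1, 1); g5(0, 0) = g.b5;
            adamStep(b5m, g5, sb5, lr, adamT); P.b5 = b5m(0, 0);
        }
        vec outVa = forward(Xva, P, a, nullptr);
        double valLoss = accu(square(outVa - yva)) / yva.n_elem;
        trainHist.push_back(epLoss / std::max(nBatches, 1));
        valHist.push_back(valLoss);
        ++epochsRun;
        if (valLoss < bestVal - 1e-12) {
            bestVal = valLoss; best = P; bad = 0;
        } else if (++bad >= patience) break;
    }
    return Rcpp::List::create(
        Rcpp::_["weights"] = paramsToList(best),
        Rcpp::_["valLoss"] = bestVal,
        Rcpp::_["trainLoss"] = trainHist,
        Rcpp::_["valHistory"] = valHist,
        Rcpp::_["epochsRun"] = epochsRun);
}

// [[Rcpp::export(name = ".cnnPredict")]]
arma::vec cnnPredict(const Rcpp::List &weights, const arma::mat &X,
                     int f1, int f2, int f3, int n1, int n2, int n3,
                     int nd) {
    Arch a = makeArch(X.n_cols, f1, f2, f3, n1, n2, n3, nd);
    Params P = paramsFromList(weights);
    // predict in chunks to bound memory
    int N = X.n_rows, chunk = 4096;
    vec out(N);
    for (int s = 0; s < N; s += chunk) {
        int e = std::min(s + chunk, N);
        out.subvec(s, e - 1) =
            forward(X.rows(s, e - 1), P, a, nullptr);
    }
    return out;
}
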