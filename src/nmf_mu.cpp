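// Multiplicative-update NMF inner loop. W0/H0 are seeded initial factors
// produced in R, so all randomness stays under R's RNG. The objective is
// evaluated after every full W/H update to build the per-iteration trace;
// iteration stops when the relative objective change falls below tol.

#include <RcppArmadillo.h>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".nmfUpdateLoop")]]
Rcpp::List nmfUpdateLoop(const arma::mat& V, arma::mat W, arma::mat H,
                         const std::string objective, const int maxIter,
                         const double tol) {
    const double eps = 1e-12;
    const bool kl = objective == "kl";
    double vlogv = 0.0, sumV = 0.0;
    if (kl) {
        sumV = accu(V);
        for (uword i = 0; i < V.n_elem; ++i)
            if (V[i] > 0) vlogv += V[i] * std::log(V[i]);
    }
    std::vector<double> trace;
    trace.reserve(maxIter);
    double prev = datum::inf;
    bool converged = false;
    int it = 0;
    mat WH, R;
    for (it = 1; it <= maxIter; ++it) {
        double obj;
        if (kl) {
            WH = W * H;
            R = V / (WH + eps);
            H %= (W.t() * R);
            H.each_col() /= (sum(W, 0).t() + eps);
            WH = W * H;
            R = V / (WH + eps);
            W %= (R * H.t());
            W.each_row() /= (sum(H, 1).t() + eps);
            WH = W * H;
            obj = vlogv - accu(V % log(WH + eps)) - sumV + accu(WH);
        } else {
            H %= (W.t() * V) / (W.t() * W * H + eps);
            W %= (V * H.t()) / (W * (H * H.t()) + eps);
            obj = 0.5 * accu(square(V - W * H));
        }
        trace.push_back(obj);
        if (std::isfinite(prev) &&
            std::abs(prev - obj) <= tol * std::max(std::abs(prev), eps)) {
            converged = true;
            break;
        }
        prev = obj;
    }
    if (!converged) it = maxIter;
    return Rcpp::List::create(Rcpp::Named("W") = W, Rcpp::Named("H") = H,
                              Rcpp::Named("trace") = trace,
                              Rcpp::Named("nIter") = it,
                              Rcpp::Named("converged") = converged);
}
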