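#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Marginal log-likelihood of a random-effect partial credit model,
// integrated over the latent trait by Gauss-Hermite quadrature.
//
// The latent trait of subject i is mu0 + gamma * g_i + sigma * e_i with
// e_i standard normal, so node positions are t_{g,q} = mu0 + gamma*g +
// sqrt(2)*sigma*z_q and weights w_q/sqrt(pi) (logw already includes the
// -log(pi)/2 term).  Category probabilities follow the partial credit
// parameterisation P(X=k) prop exp(k*t - sum_{l<=k} delta_l).
//
// Analytic gradients use the posterior node weights W_iq:
//   d/d mu0       sum_i sum_q W_iq (r_i - mtot_g(q))
//   d/d gamma     same restricted to g = 1
//   d/d log sigma sum_i sum_q W_iq (r_i - mtot_g(q)) * sqrt(2)*sigma*z_q
//   d/d delta_jl  sum_i sum_q W_iq (P(X_j >= l | t) - 1{x_ij >= l})
// where r_i is subject i's total score and mtot_g(q) the expected total
// score at node q for group g.

// [[Rcpp::export]]
List pcm_mll_cpp(const IntegerMatrix& X,
                 const IntegerVector& group,
                 const NumericMatrix& thr,
                 const double mu0,
                 const double gamma,
                 const double sigma,
                 const NumericVector& z,
                 const NumericVector& logw,
                 const bool want_grad,
                 const bool want_subject)
{
    const int N = X.nrow(), J = X.ncol(), M1 = thr.ncol(), M = M1 + 1;
    const int Q = z.size();
    const double s2 = std::sqrt(2.0);

    // cumulative thresholds per item: cum[j*M + k] = sum_{l<=k} delta_jl
    std::vector<double> cum((size_t)J * M);
    for (int j = 0; j < J; ++j) {
        cum[(size_t)j * M] = 0.0;
        for (int k = 1; k < M; ++k)
            cum[(size_t)j * M + k] = cum[(size_t)j * M + k - 1] + thr(j, k - 1);
    }

    bool has1 = false;
    for (int i = 0; i < N; ++i) if (group[i] == 1) { has1 = true; break; }
    const int G = has1 ? 2 : 1;

    // per-group node positions and item category log-probabilities
    std::vector<double> tg((size_t)G * Q);
    for (int g = 0; g < G; ++g)
        for (int q = 0; q < Q; ++q)
            tg[(size_t)g * Q + q] = mu0 + gamma * g + s2 * sigma * z[q];

    std::vector<double> logP((size_t)G * J * M * Q);
    std::vector<double> Pgeq, mtot;
    if (want_grad) {
        Pgeq.assign((size_t)G * J * M1 * Q, 0.0);
        mtot.assign((size_t)G * Q, 0.0);
    }
    std::vector<double> num(M);
    for (int g = 0; g < G; ++g) {
        for (int j = 0; j < J; ++j) {
            for (int q = 0; q < Q; ++q) {
                const double t = tg[(size_t)g * Q + q];
                double mx = -INFINITY;
                for (int k = 0; k < M; ++k) {
                    num[k] = k * t - cum[(size_t)j * M + k];
                    if (num[k] > mx) mx = num[k];
                }
                double sum = 0.0;
                for (int k = 0; k < M; ++k) { num[k] = std::exp(num[k] - mx); sum += num[k]; }
                const double lz = std::log(sum) + mx;
                for (int k = 0; k < M; ++k) {
                    const double p = num[k] / sum;
                    logP[(((size_t)g * J + j) * M + k) * Q + q] =
                        k * t - cum[(size_t)j * M + k] - lz;
                    if (want_grad) {
                        mtot[(size_t)g * Q + q] += k * p;
                        for (int l = 1; l <= k; ++l)
                            Pgeq[(((size_t)g * J + j) * M1 + (l - 1)) * Q + q] += p;
                    }
                }
            }
        }
    }

    NumericVector ll_i(want_subject ? N : 0);
    double total = 0.0;
    std::vector<double> a(Q), W(Q);
    std::vector<double> cW, u, cnt;
    double sum_r[2] = {0.0, 0.0};
    if (want_grad) {
        cW.assign((size_t)G * Q, 0.0);
        u.assign((size_t)G * Q, 0.0);
        cnt.assign((size_t)G * J * M1, 0.0);
    }

    for (int i = 0; i < N; ++i) {
        const int g = has1 ? group[i] : 0;
        for (int q = 0; q < Q; ++q) a[q] = logw[q];
        double r = 0.0;
        for (int j = 0; j < J; ++j) {
            const int x = X(i, j);
            const double* lp = &logP[(((size_t)g * J + j) * M + x) * Q];
            for (int q = 0; q < Q; ++q) a[q] += lp[q];
            r += x;
            if (want_grad)
                for (int l = 1; l <= x; ++l)
                    cnt[((size_t)g * J + j) * M1 + (l - 1)] += 1.0;
        }
        double mx = a[0];
        for (int q = 1; q < Q; ++q) if (a[q] > mx) mx = a[q];
        double s = 0.0;
        for (int q = 0; q < Q; ++q) { W[q] = std::exp(a[q] - mx); s += W[q]; }
        const double li = std::log(s) + mx;
        total += li;
        if (want_subject) ll_i[i] = li;
        if (want_grad) {
            sum_r[g] += r;
            for (int q = 0; q < Q; ++q) {
                const double w = W[q] / s;
                cW[(size_t)g * Q + q] += w;
                u[(size_t)g * Q + q] += w * r;
            }
        }
    }

    List out = List::create(_["loglik"] = total);
    if (want_subject) out["loglik_i"] = ll_i;
    if (want_grad) {
        double dmu = 0.0, dgam = 0.0, dls = 0.0;
        for (int g = 0; g < G; ++g) {
            double acc = 0.0, accs = 0.0;
            for (int q = 0; q < Q; ++q) {
                acc += cW[(size_t)g * Q + q] * mtot[(size_t)g * Q + q];
                accs += s2 * sigma * z[q] *
                    (u[(size_t)g * Q + q] - cW[(size_t)g * Q + q] * mtot[(size_t)g * Q + q]);
            }
            const double d = sum_r[g] - acc;
            dmu += d;
            if (g == 1) dgam += d;
            dls += accs;
        }
        NumericMatrix dthr(J, M1);
        for (int j = 0; j < J; ++j) {
            for (int l = 0; l < M1; ++l) {
                double v = 0.0;
                for (int g = 0; g < G; ++g) {
                    double e = 0.0;
                    for (int q = 0; q < Q; ++q)
                        e += cW[(size_t)g * Q + q] *
                             Pgeq[(((size_t)g * J + j) * M1 + l) * Q + q];
                    v += e - cnt[((size_t)g * J + j) * M1 + l];
                }
                dthr(j, l) = v;
            }
        }
        out["dthr"] = dthr;
        out["dmu"] = dmu;
        out["dgamma"] = dgam;
        out["dlogsigma"] = dls;
    }
    return out;
}

// Posterior mean and SD of the latent trait for each subject, given item
// thresholds, node positions on the latent scale and log prior weights.
// [[Rcpp::export]]
List pcm_posterior_cpp(const IntegerMatrix& X,
                       const NumericMatrix& thr,
                       const NumericVector& tnodes,
                       const NumericVector& logw)
{
    const int N = X.nrow(), J = X.ncol(), M1 = thr.ncol(), M = M1 + 1;
    const int Q = tnodes.size();

    std::vector<double> cum((size_t)J * M);
    for (int j = 0; j < J; ++j) {
        cum[(size_t)j * M] = 0.0;
        for (int k = 1; k < M; ++k)
            cum[(size_t)j * M + k] = cum[(size_t)j * M + k - 1] + thr(j, k - 1);
    }
    std::vector<double> logP((size_t)J * M * Q);
    std::vector<double> num(M);
    for (int j = 0; j < J; ++j) {
        for (int q = 0; q < Q; ++q) {
            const double t = tnodes[q];
            double mx = -INFINITY;
            for (int k = 0; k < M; ++k) {
                num[k] = k * t - cum[(size_t)j * M + k];
                if (num[k] > mx) mx = num[k];
            }
            double sum = 0.0;
            for (int k = 0; k < M; ++k) sum += std::exp(num[k] - mx);
            const double lz = std::log(sum) + mx;
            for (int k = 0; k < M; ++k)
                logP[((size_t)j * M + k) * Q + q] = k * t - cum[(size_t)j * M + k] - lz;
        }
    }

    NumericVector theta_hat(N), psd(N);
    std::vector<double> a(Q);
    for (int i = 0; i < N; ++i) {
        for (int q = 0; q < Q; ++q) a[q] = logw[q];
        for (int j = 0; j < J; ++j) {
            const double* lp = &logP[((size_t)j * M + X(i, j)) * Q];
            for (int q = 0; q < Q; ++q) a[q] += lp[q];
        }
        double mx = a[0];
        for (int q = 1; q < Q; ++q) if (a[q] > mx) mx = a[q];
        double s = 0.0, m = 0.0, m2 = 0.0;
        for (int q = 0; q < Q; ++q) {
            const double w = std::exp(a[q] - mx);
            s += w;
            m += w * tnodes[q];
            m2 += w * tnodes[q] * tnodes[q];
        }
        m /= s;
        m2 /= s;
        theta_hat[i] = m;
        const double v = m2 - m * m;
        psd[i] = v > 0.0 ? std::sqrt(v) : 0.0;
    }
    return List::create(_["theta_hat"] = theta_hat, _["psd"] = psd);
}
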