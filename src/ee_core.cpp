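// Weighted logistic estimating-equation solver used by every analysis path.
//
// Each taxon j is compared to the reference taxon through
//   logit(mu) = eta_{k} + Z' beta
// and (eta, beta) solves the weighted quasi-score
//   sum_i sum_k w_{ik} (r_{ik} - mu_{ik}) x_{ik} = 0,
// where r = Y_j / (Y_j + Y_ref) and w is the scheme weight (Y_j + Y_ref for
// the count scheme, 1 for the relative-abundance scheme).  The quasi-score is
// the gradient of sum w [r log mu + (1-r) log(1-mu)], so a damped Newton
// ascent with step halving is used.  A Firth-type Jeffreys correction
// (score augmented by h_i (1/2 - mu_i) with hat values of the weighted IRLS
// problem) handles sparse taxa and separation, where the plain solution may
// not exist.
//
// The batch entry point refits every taxon for every permutation replicate;
// this loop dominates benchmark runtime, hence C++.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double ETA_CLAMP = 30.0;
static const double BETA_DIVERGED = 25.0;
static const double BETA_SEPARATION = 10.0;

// log(1 + exp(e)) without overflow
static inline double softplus(double e) {
  return (e > 0.0) ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
}

static double wloglik(const vec& eta, const vec& r, const vec& w) {
  double s = 0.0;
  for (uword i = 0; i < eta.n_elem; ++i)
    s += w[i] * (r[i] * eta[i] - softplus(eta[i]));
  return s;
}

// One damped-Newton solve.  Returns true on convergence (inf-norm of the
// (adjusted) score below tol).  beta is updated in place.
static bool newton_fit(const mat& X, const vec& r, const vec& w,
                       bool firth, vec& beta, double tol, int maxit) {
  const uword p = X.n_cols;
  vec eta = clamp(X * beta, -ETA_CLAMP, ETA_CLAMP);
  vec mu = 1.0 / (1.0 + exp(-eta));
  double ll = wloglik(eta, r, w);

  for (int it = 0; it < maxit; ++it) {
    vec wirls = w % mu % (1.0 - mu);
    mat XW = X.each_col() % wirls;
    mat info = X.t() * XW;                     // p x p
    vec score = X.t() * (w % (r - mu));
    double logdet = 0.0;
    if (firth) {
      double sign;
      mat infoR = info + 1e-10 * eye(p, p);
      log_det(logdet, sign, infoR);
      mat infoInv;
      if (!inv_sympd(infoInv, infoR)) return false;
      vec h(X.n_rows);
      for (uword i = 0; i < X.n_rows; ++i)
        h[i] = wirls[i] * as_scalar(X.row(i) * infoInv * X.row(i).t());
      score += X.t() * (h % (0.5 - mu));
    }
    if (norm(score, "inf") < tol) return true;

    vec step;
    if (!solve(step, info + 1e-10 * eye(p, p), score)) return false;
    if (!step.is_finite()) return false;

    // step halving on the (penalized) objective
    double obj = firth ? ll + 0.5 * logdet : ll;
    double fac = 1.0;
    bool accepted = false;
    for (int half = 0; half < 25; ++half) {
      vec cand = beta + fac * step;
      vec etac = clamp(X * cand, -ETA_CLAMP, ETA_CLAMP);
      vec muc = 1.0 / (1.0 + exp(-etac));
      double llc = wloglik(etac, r, w);
      double objc = llc;
      if (firth) {
        vec wc = w % muc % (1.0 - muc);
        mat ic = X.t() * (X.each_col() % wc) + 1e-10 * eye(p, p);
        double ld, sg;
        log_det(ld, sg, ic);
        objc = llc + 0.5 * ld;
      }
      if (std::isfinite(objc) && (objc >= obj - 1e-12 || half == 24)) {
        beta = cand; eta = etac; mu = muc; ll = llc;
        accepted = std::isfinite(objc);
        break;
      }
      fac *= 0.5;
    }
    if (!accepted) return false;
    if (norm(beta, "inf") > BETA_DIVERGED && !firth) return false;
  }
  return false;
}

// Fit one taxon: plain EE first (unless forced to the corrected one), fall
// back to the Firth-type corrected EE on failure or apparent separation.
// Separation is diagnosed on the trailing dCheck (trait) coefficients only:
// source intercepts are legitimately large for rare taxa.
// status: 0 plain converged, 1 corrected EE used, 2 failed.
static int fit_taxon(const mat& X, const vec& r, const vec& w,
                     bool force_firth, int dCheck, vec& beta,
                     double tol, int maxit) {
  vec start = beta;
  if (!force_firth) {
    bool ok = newton_fit(X, r, w, false, beta, tol, maxit);
    if (ok) {
      bool sep = false;
      for (int t = 0; t < dCheck; ++t)
        if (std::abs(beta[X.n_cols - 1 - t]) > BETA_SEPARATION) sep = true;
      if (!sep) return 0;
    }
  }
  beta = start;
  bool ok = newton_fit(X, r, w, true, beta, tol, maxit);
  return ok ? 1 : 2;
}

// Single fit, exposed for the user-facing solveTaxonEE()/biasCorrectedEE().
// dCheck trailing coefficients are screened for separation on the plain path.
// The gradient tolerance scales with the mean weight so that count-scheme
// problems (weights in the thousands) converge at the same relative
// precision as unit-weight problems.
// [[Rcpp::export]]
Rcpp::List cppEEFit(const arma::mat& X, const arma::vec& r, const arma::vec& w,
                    bool firth, bool allowFallback, int dCheck,
                    double tol, int maxit) {
  uvec keep = find(w > 0);
  mat Xs = X.rows(keep);
  vec rs = r.elem(keep), ws = w.elem(keep);
  double tolEff = tol * std::max(1.0, mean(ws));
  vec beta = zeros<vec>(X.n_cols);
  int status;
  if (!allowFallback) {
    status = newton_fit(Xs, rs, ws, firth, beta, tolEff, maxit) ? (firth ? 1 : 0) : 2;
  } else {
    status = fit_taxon(Xs, rs, ws, firth, dCheck, beta, tolEff, maxit);
  }
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("status") = status,
                            Rcpp::Named("nUsed") = (int)keep.n_elem);
}

// Batch driver: all taxa x all permutation replicates under one weight scheme.
//
// Xfix     m x p0   source-intercept and covariate columns (trait excluded)
// traitRep m x d*(B+1)  trait column block per replicate, replicate 0 observed
// resp     m x J    response fractions Y_j / (Y_j + Y_ref)
// wt       m x J    scheme weights; 0 drops the measurement for that taxon
// fixMask  J x p0   1 if the fixed column is estimable for the taxon
// forceFirth J      1 = sparse taxon, always use the corrected EE
//
// Returns betaTrait (J*d) x (B+1) trait coefficients and status J x (B+1).
// [[Rcpp::export]]
Rcpp::List cppEEBatch(const arma::mat& Xfix, const arma::mat& traitRep, int d,
                      const arma::mat& resp, const arma::mat& wt,
                      const arma::umat& fixMask, const arma::ivec& forceFirth,
                      double tol, int maxit) {
  const uword J = resp.n_cols;
  const uword B1 = traitRep.n_cols / d;
  mat betaOut(J * d, B1); betaOut.fill(datum::nan);
  imat status(J, B1); status.fill(2);

  for (uword j = 0; j < J; ++j) {
    uvec rows = find(wt.col(j) > 0);
    if (rows.n_elem == 0) { status.row(j).fill(3); continue; }
    uvec fcols = find(fixMask.row(j).t() == 1);
    const uword p = fcols.n_elem + (uword)d;

    mat Xf = Xfix.submat(rows, fcols);
    mat Tr = traitRep.rows(rows);
    vec rj = resp.col(j); rj = rj.elem(rows);
    vec wj = wt.col(j);  wj = wj.elem(rows);
    double tolEff = tol * std::max(1.0, mean(wj));

    // intercept warm start at the pooled logit
    double rb = dot(wj, rj) / accu(wj);
    rb = std::min(std::max(rb, 1e-4), 1.0 - 1e-4);
    vec beta0 = zeros<vec>(p);
    for (uword c = 0; c < fcols.n_elem; ++c)
      if (max(abs(Xfix.col(fcols[c]))) == 1.0 && min(Xfix.col(fcols[c])) >= 0.0)
        beta0[c] = std::log(rb / (1.0 - rb));

    bool ff = forceFirth[j] == 1;
    mat X(rows.n_elem, p);
    X.cols(0, fcols.n_elem - 1) = Xf;
    vec betaObs;

    for (uword b = 0; b < B1; ++b) {
      X.cols(fcols.n_elem, p - 1) = Tr.cols(b * d, b * d + d - 1);
      vec beta = (b == 0) ? beta0 : betaObs;
      if (b > 0 && !beta.is_finite()) beta = beta0;
      int st = fit_taxon(X, rj, wj, ff, d, beta, tolEff, maxit);
      if (st == 2) {                           // retry from cold start
        beta = beta0;
        st = fit_taxon(X, rj, wj, true, d, beta, tolEff, maxit);
        if (st != 2) st = 1;
      }
      if (b == 0) betaObs = beta;
      status(j, b) = st;
      if (st != 2)
        for (int t = 0; t < d; ++t)
          betaOut(j * d + t, b) = beta[fcols.n_elem + t];
    }
  }
  return Rcpp::List::create(Rcpp::Named("beta") = betaOut,
                            Rcpp::Named("status") = status);
}
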