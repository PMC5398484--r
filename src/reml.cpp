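// REML objective and gradient for the matrix-variate interaction set model.
//
// Complete design: cov(vec(Y)) = Cs (x) Rs + Cn (x) I_N.  After whitening by
// Cn = Ln Ln', rotating contexts by the eigenvectors of Ln^-1 Cs Ln^-T and
// individuals by the eigenvectors of Rs, the covariance is diagonal with
// entries 1 + s_i d_j.  Only the top Se = rank(Rs) individual coordinates are
// stored (P = U1'Y, Q = U1'F); coordinates in the null space of Rs have unit
// weight and enter through Gram-matrix corrections, so one evaluation costs
// O(Se C^2 + Se K^2 C^2), independent of N.
//
// Stratified design: V[i,j] = Cs[c_i,c_j] Rs[i,j] + delta_ij Cn[c_i,c_i]
// with Rs = G G'/S.  With Cs = L L' (rank r), V = A A' + D where column
// block u of A is L[c_i,u] G[i,]/sqrt(S); Woodbury identities reduce every
// term to per-context Gram matrices precomputed once per region.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);
static const double BIG = 1e10;

// kind codes: 0 null, 1 block, 2 rank1, 3 full
static int n_par_s(int kind, int C) {
  switch (kind) {
  case 0: return 0;
  case 1: return 1;
  case 2: return C;
  default: return C * (C + 1) / 2;
  }
}

// column-major fill of the lower triangle
static mat fill_lower(const vec& th, int C, bool expdiag) {
  mat L(C, C, fill::zeros);
  int k = 0;
  for (int j = 0; j < C; ++j)
    for (int i = j; i < C; ++i) {
      double v = th(k++);
      L(i, j) = (expdiag && i == j) ? std::exp(v) : v;
    }
  return L;
}

static mat cs_from_theta(const vec& ths, int kind, int C) {
  if (kind == 0) return mat(C, C, fill::zeros);
  if (kind == 1) return mat(C, C, fill::ones) * (ths(0) * ths(0));
  if (kind == 2) return ths * ths.t();
  mat A = fill_lower(ths, C, false);
  return A * A.t();
}

// low-rank factor of Cs for the stratified layout (C x r)
static mat ls_from_theta(const vec& ths, int kind, int C) {
  if (kind == 0) return mat(C, 0);
  if (kind == 1) return mat(C, 1, fill::ones) * ths(0);
  if (kind == 2) return mat(ths);
  return fill_lower(ths, C, false);
}

// ------------------------------------------------------------------
// complete design
// ------------------------------------------------------------------

struct CompleteModel {
  int N, C, K, kind;
  vec d;                    // Se positive eigenvalues of Rs
  mat P, Q;                 // Se x C, Se x K
  mat YtY, FtF, FtY, QtQ;   // C x C, K x K, K x C, K x K
};

static double complete_eval(const CompleteModel& md, const vec& theta,
                            bool want_grad, vec& grad,
                            bool want_fit, mat& Bout, mat& CsOut, mat& CnOut) {
  const int C = md.C, K = md.K, N = md.N;
  const int Se = md.d.n_elem;
  const int ps = n_par_s(md.kind, C), pn = C * (C + 1) / 2;
  if ((int)theta.n_elem != ps + pn) Rcpp::stop("theta length mismatch");
  if (!theta.is_finite()) Rcpp::stop("non-finite parameter vector");

  vec ths = theta.head(ps), thn = theta.tail(pn);
  mat Cs = cs_from_theta(ths, md.kind, C);
  mat Ln = fill_lower(thn, C, true);
  if (!Ln.is_finite() || Ln.diag().min() < 1e-12 ||
      Ln.diag().max() / Ln.diag().min() > 1e10) return BIG;
  mat Cn = Ln * Ln.t();

  mat X1 = solve(trimatl(Ln), Cs, solve_opts::fast);
  mat Ct = solve(trimatl(Ln), X1.t(), solve_opts::fast).t();
  Ct = 0.5 * (Ct + Ct.t());
  vec s; mat E;
  if (!eig_sym(s, E, Ct)) return BIG;
  s = clamp(s, 0.0, datum::inf);
  mat M = solve(trimatu(trans(Ln)), E, solve_opts::fast);  // Ln^-T E, C x C

  mat W(Se, C);
  for (int i = 0; i < C; ++i) W.col(i) = 1.0 / (1.0 + s(i) * md.d);
  mat PM = md.P * M;
  mat MtYtYM = M.t() * md.YtY * M;
  double logdetCn = 2.0 * accu(log(Ln.diag()));
  double logdetK = N * logdetCn;
  for (int i = 0; i < C; ++i) logdetK += accu(log1p(s(i) * md.d));

  double yKy = 0.0;
  for (int i = 0; i < C; ++i)
    yKy += dot(W.col(i) - 1.0, square(PM.col(i))) + MtYtYM(i, i);

  const int p = K * C;
  double logdetA = 0.0, q = yKy;
  mat Bhat(K, C, fill::zeros), Ainv;
  if (K > 0) {
    mat FtYM = md.FtY * M;
    std::vector<mat> Gi(C);
    for (int i = 0; i < C; ++i) {
      mat Qw = md.Q.each_col() % (W.col(i) - 1.0);
      Gi[i] = md.Q.t() * Qw + md.FtF;
    }
    mat Amat(p, p, fill::zeros);
    vec bvec(p, fill::zeros);
    for (int a = 0; a < C; ++a) {
      for (int b = 0; b < C; ++b) {
        mat blk(K, K, fill::zeros);
        for (int i = 0; i < C; ++i) blk += M(a, i) * M(b, i) * Gi[i];
        Amat.submat(a * K, b * K, arma::size(K, K)) = blk;
      }
      vec rhs(K, fill::zeros);
      for (int i = 0; i < C; ++i)
        rhs += M(a, i) * (md.Q.t() * ((W.col(i) - 1.0) % PM.col(i)) + FtYM.col(i));
      bvec.subvec(a * K, a * K + K - 1) = rhs;
    }
    Amat = 0.5 * (Amat + Amat.t());
    mat R;
    if (!chol(R, Amat)) return BIG;
    logdetA = 2.0 * accu(log(R.diag()));
    vec beta = solve(trimatu(R), solve(trimatl(R.t()), bvec, solve_opts::fast), solve_opts::fast);
    q = yKy - dot(bvec, beta);
    Bhat = reshape(beta, K, C);
    if (want_grad) {
      mat Ri = inv(trimatu(R));
      Ainv = Ri * Ri.t();
    }
  }

  double negll = 0.5 * ((double)(N * C - p) * LOG2PI + logdetK + logdetA + q);
  if (!std::isfinite(negll)) return BIG;

  if (want_fit) { Bout = Bhat; CsOut = Cs; CnOut = Cn; }

  if (want_grad) {
    // residual pieces in the rotated basis
    mat BM = Bhat * M;                         // K x C (zero rows when K = 0)
    mat Rtop = PM;
    if (K > 0) Rtop -= md.Q * BM;
    mat Uw = Rtop % W;
    mat UdU = Uw.t() * (Uw.each_col() % md.d);
    mat UtU = Uw.t() * Uw;
    mat Rgram = md.YtY;
    if (K > 0) {
      Rgram -= md.FtY.t() * Bhat + Bhat.t() * md.FtY;
      Rgram += Bhat.t() * md.FtF * Bhat;
    }
    mat NullGram = M.t() * Rgram * M - Rtop.t() * Rtop;
    vec wd(C), w1(C);
    for (int i = 0; i < C; ++i) {
      wd(i) = dot(W.col(i), md.d);
      w1(i) = accu(W.col(i)) - (double)Se;
    }
    // K x K Gram families for the REML correction term
    std::vector<mat> Gd, Gw;
    if (K > 0) {
      Gd.resize(C * C); Gw.resize(C * C);
      for (int i = 0; i < C; ++i)
        for (int i2 = i; i2 < C; ++i2) {
          vec wdw = W.col(i) % md.d % W.col(i2);
          vec ww  = W.col(i) % W.col(i2);
          Gd[i * C + i2] = md.Q.t() * (md.Q.each_col() % wdw);
          Gw[i * C + i2] = md.Q.t() * (md.Q.each_col() % ww);
        }
    }
    mat FmQ = (K > 0) ? mat(md.FtF - md.QtQ) : mat();

    grad.set_size(ps + pn);
    for (int t = 0; t < ps + pn; ++t) {
      bool is_s = t < ps;
      mat Cdot(C, C, fill::zeros);
      if (is_s) {
        if (md.kind == 1) {
          Cdot.fill(2.0 * ths(0));
        } else if (md.kind == 2) {
          Cdot.col(t) += ths;
          Cdot.row(t) += ths.t();
        } else {  // full
          mat A = fill_lower(ths, md.C, false);
          int k = 0, ii = 0, jj = 0;
          for (int j = 0; j < C && k <= t; ++j)
            for (int i = j; i < C && k <= t; ++i) { ii = i; jj = j; ++k; }
          mat dA(C, C, fill::zeros); dA(ii, jj) = 1.0;
          Cdot = dA * A.t() + A * dA.t();
        }
      } else {
        int tn = t - ps, k = 0, ii = 0, jj = 0;
        for (int j = 0; j < C && k <= tn; ++j)
          for (int i = j; i < C && k <= tn; ++i) { ii = i; jj = j; ++k; }
        mat dL(C, C, fill::zeros);
        dL(ii, jj) = (ii == jj) ? Ln(ii, ii) : 1.0;
        Cdot = dL * Ln.t() + Ln * dL.t();
      }
      mat Phi = M.t() * Cdot * M;

      double term1 = 0.0, term2 = 0.0, term3 = 0.0;
      if (is_s) {
        for (int i = 0; i < C; ++i) term1 += Phi(i, i) * wd(i);
        term3 = accu(Phi % UdU);
      } else {
        for (int i = 0; i < C; ++i) term1 += Phi(i, i) * (w1(i) + (double)N);
        term3 = accu(Phi % (UtU + NullGram));
      }
      if (K > 0) {
        mat Z(p, p, fill::zeros);
        mat MPhiMt;
        if (!is_s) MPhiMt = M * Phi * M.t();
        for (int a = 0; a < C; ++a)
          for (int b = 0; b < C; ++b) {
            mat blk(K, K, fill::zeros);
            for (int i = 0; i < C; ++i)
              for (int i2 = 0; i2 < C; ++i2) {
                const mat& Gm = is_s ? Gd[std::min(i, i2) * C + std::max(i, i2)]
                                     : Gw[std::min(i, i2) * C + std::max(i, i2)];
                blk += M(a, i) * Phi(i, i2) * M(b, i2) * Gm;
              }
            if (!is_s) blk += MPhiMt(a, b) * FmQ;
            Z.submat(a * K, b * K, arma::size(K, K)) = blk;
          }
        term2 = accu(Ainv % Z);
      }
      grad(t) = 0.5 * (term1 - term2 - term3);
    }
  }
  return negll;
}

// [[Rcpp::export]]
SEXP cpp_complete_new(const arma::vec& d, const arma::mat& P, const arma::mat& Q,
                      const arma::mat& YtY, const arma::mat& FtF,
                      const arma::mat& FtY, int N, int kind) {
  CompleteModel* m = new CompleteModel;
  m->N = N; m->C = P.n_cols; m->K = Q.n_cols; m->kind = kind;
  m->d = d; m->P = P; m->Q = Q;
  m->YtY = YtY; m->FtF = FtF; m->FtY = FtY;
  m->QtQ = Q.t() * Q;
  Rcpp::XPtr<CompleteModel> ptr(m, true);
  return ptr;
}

// [[Rcpp::export]]
double cpp_complete_negll(SEXP xp, const arma::vec& theta) {
  Rcpp::XPtr<CompleteModel> ptr(xp);
  vec g; mat B, Cs, Cn;
  return complete_eval(*ptr, theta, false, g, false, B, Cs, Cn);
}

// [[Rcpp::export]]
arma::vec cpp_complete_grad(SEXP xp, const arma::vec& theta) {
  Rcpp::XPtr<CompleteModel> ptr(xp);
  vec g; mat B, Cs, Cn;
  double f = complete_eval(*ptr, theta, true, g, false, B, Cs, Cn);
  if (f >= BIG) g.zeros(theta.n_elem);
  return g;
}

// [[Rcpp::export]]
Rcpp::List cpp_complete_fitted(SEXP xp, const arma::vec& theta) {
  Rcpp::XPtr<CompleteModel> ptr(xp);
  vec g; mat B, Cs, Cn;
  double f = complete_eval(*ptr, theta, false, g, true, B, Cs, Cn);
  return Rcpp::List::create(Rcpp::Named("negll") = f,
                            Rcpp::Named("B") = B,
                            Rcpp::Named("Cs") = Cs,
                            Rcpp::Named("Cn") = Cn);
}

// ------------------------------------------------------------------
// stratified design
// ------------------------------------------------------------------

struct StratModel {
  int N, C, K, S, kind;
  std::vector<mat> H;    // C of S x S      G_a' G_a / S
  std::vector<mat> GtF;  // C of S x K      G_a' F_a / sqrt(S)
  std::vector<vec> Gty;  // C of S          G_a' y_a / sqrt(S)
  std::vector<mat> FtF;  // C of K x K
  std::vector<vec> Fty;  // C of K
  vec yty;               // C
  vec Na;                // C
};

static double strat_eval(const StratModel& md, const vec& theta,
                         bool want_fit, mat& Bout, mat& CsOut, vec& CnOut) {
  const int C = md.C, K = md.K, S = md.S, N = md.N;
  const int ps = n_par_s(md.kind, C);
  if ((int)theta.n_elem != ps + C) Rcpp::stop("theta length mismatch");
  if (!theta.is_finite()) Rcpp::stop("non-finite parameter vector");

  vec ths = theta.head(ps), thn = theta.tail(C);
  mat L = ls_from_theta(ths, md.kind, C);
  const int r = L.n_cols, m = r * S, p = K * C;
  vec dn = exp(2.0 * thn);
  if (!dn.is_finite() || dn.min() < 1e-300) return BIG;

  double logdetD = 0.0, ytDy = 0.0;
  for (int a = 0; a < C; ++a) {
    logdetD += md.Na(a) * 2.0 * thn(a);
    ytDy += md.yty(a) / dn(a);
  }
  mat XtDX(p, p, fill::zeros);
  vec XtDy(p, fill::zeros);
  for (int a = 0; a < C; ++a) {
    XtDX.submat(a * K, a * K, arma::size(K, K)) = md.FtF[a] / dn(a);
    XtDy.subvec(a * K, a * K + K - 1) = md.Fty[a] / dn(a);
  }

  double logdetV = logdetD, ytVy = ytDy;
  mat XtVX = XtDX;
  vec XtVy = XtDy;
  if (r > 0) {
    mat T(m, m, fill::eye);
    vec AtDy(m, fill::zeros);
    mat XtDA(p, m, fill::zeros);
    for (int u = 0; u < r; ++u) {
      for (int v = u; v < r; ++v) {
        mat blk(S, S, fill::zeros);
        for (int a = 0; a < C; ++a) {
          double cf = L(a, u) * L(a, v) / dn(a);
          if (cf != 0.0) blk += cf * md.H[a];
        }
        T.submat(u * S, v * S, arma::size(S, S)) += blk;
        if (v != u) T.submat(v * S, u * S, arma::size(S, S)) += blk.t();
      }
      for (int a = 0; a < C; ++a) {
        double cf = L(a, u) / dn(a);
        if (cf != 0.0) {
          AtDy.subvec(u * S, u * S + S - 1) += cf * md.Gty[a];
          XtDA.submat(a * K, u * S, arma::size(K, S)) += cf * md.GtF[a].t();
        }
      }
    }
    mat R;
    if (!chol(R, T)) return BIG;
    logdetV += 2.0 * accu(log(R.diag()));
    vec TiAtDy = solve(trimatu(R), solve(trimatl(R.t()), AtDy, solve_opts::fast), solve_opts::fast);
    ytVy = ytDy - dot(AtDy, TiAtDy);
    if (K > 0) {
      mat TiXtDAt = solve(trimatu(R), solve(trimatl(R.t()), XtDA.t(), solve_opts::fast), solve_opts::fast);
      XtVX = XtDX - XtDA * TiXtDAt;
      XtVy = XtDy - XtDA * TiAtDy;
    }
  }

  double logdetXVX = 0.0, q = ytVy;
  mat Bhat(K, C, fill::zeros);
  if (K > 0) {
    XtVX = 0.5 * (XtVX + XtVX.t());
    mat R2;
    if (!chol(R2, XtVX)) return BIG;
    logdetXVX = 2.0 * accu(log(R2.diag()));
    vec beta = solve(trimatu(R2), solve(trimatl(R2.t()), XtVy, solve_opts::fast), solve_opts::fast);
    q = ytVy - dot(XtVy, beta);
    Bhat = reshape(beta, K, C);
  }
  double negll = 0.5 * ((double)(N - p) * LOG2PI + logdetV + logdetXVX + q);
  if (!std::isfinite(negll)) return BIG;
  if (want_fit) { Bout = Bhat; CsOut = L * L.t(); CnOut = dn; }
  return negll;
}

// [[Rcpp::export]]
SEXP cpp_strat_new(Rcpp::List H, Rcpp::List GtF, Rcpp::List Gty,
                   Rcpp::List FtF, Rcpp::List Fty,
                   const arma::vec& yty, const arma::vec& Na,
                   int N, int K, int S, int kind) {
  StratModel* md = new StratModel;
  int C = H.size();
  md->N = N; md->C = C; md->K = K; md->S = S; md->kind = kind;
  md->yty = yty; md->Na = Na;
  for (int a = 0; a < C; ++a) {
    md->H.push_back(Rcpp::as<mat>(H[a]));
    md->GtF.push_back(Rcpp::as<mat>(GtF[a]));
    md->Gty.push_back(Rcpp::as<vec>(Gty[a]));
    md->FtF.push_back(Rcpp::as<mat>(FtF[a]));
    md->Fty.push_back(Rcpp::as<vec>(Fty[a]));
  }
  Rcpp::XPtr<StratModel> ptr(md, true);
  return ptr;
}

// [[Rcpp::export]]
double cpp_strat_negll(SEXP xp, const arma::vec& theta) {
  Rcpp::XPtr<StratModel> ptr(xp);
  mat B, Cs; vec Cn;
  return strat_eval(*ptr, theta, false, B, Cs, Cn);
}

// central finite differences of the stratified objective
// [[Rcpp::export]]
arma::vec cpp_strat_grad(SEXP xp, const arma::vec& theta) {
  Rcpp::XPtr<StratModel> ptr(xp);
  mat B, Cs; vec Cn;
  int P = theta.n_elem;
  vec g(P);
  for (int t = 0; t < P; ++t) {
    double h = 1e-5 * std::max(1.0, std::fabs(theta(t)));
    vec tp = theta, tm = theta;
    tp(t) += h; tm(t) -= h;
    double fp = strat_eval(*ptr, tp, false, B, Cs, Cn);
    double fm = strat_eval(*ptr, tm, false, B, Cs, Cn);
    g(t) = (fp - fm) / (2.0 * h);
  }
  if (!g.is_finite()) g.zeros();
  return g;
}

// [[Rcpp::export]]
Rcpp::List cpp_strat_fitted(SEXP xp, const arma::vec& theta) {
  Rcpp::XPtr<StratModel> ptr(xp);
  mat B, Cs; vec Cn;
  double f = strat_eval(*ptr, theta, true, B, Cs, Cn);
  return Rcpp::List::create(Rcpp::Named("negll") = f,
                            Rcpp::Named("B") = B,
                            Rcpp::Named("Cs") = Cs,
                            Rcpp::Named("Cn") = Cn);
}
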