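// Compiled training core: forward pass and reverse-mode parameter
// gradients for the relational graph convolution network. This mirrors the
// R implementation in R/model.R and R/grad.R, which remains the reference
// oracle (the two are compared numerically in the test suite). Only the
// unit-gate training path lives here; attribution passes (input and edge
// gate gradients) use the R path.
//
// State layout matches the R code: one d x (n_t * P) matrix per node type,
// column (p * n_t + v) holding node v of patient p.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Rel {
  int src, dst; // type index 0 = gene, 1 = cpg, 2 = mirna
  arma::uvec src_idx, dst_idx; // 0-based node indices per edge
  arma::vec inv_deg; // 1 / |N_r(dst)| per edge
  std::string wname; // parameter name of the relation weight
};

arma::mat getm(const List& params, const std::string& nm) {
  return as<arma::mat>(params[nm]);
}
arma::vec getv(const List& params, const std::string& nm) {
  return as<arma::vec>(params[nm]);
}

// neighbour aggregation: out.col(p*nd + dst[e]) += w_e * T.col(p*ns + src[e])
void scatter_edges(arma::mat& out, const arma::mat& T, const Rel& r,
                   int ns, int nd, int P) {
  const arma::uword ne = r.src_idx.n_elem;
  for (int p = 0; p < P; ++p) {
    const arma::uword off_s = (arma::uword)p * ns;
    const arma::uword off_d = (arma::uword)p * nd;
    for (arma::uword e = 0; e < ne; ++e) {
      out.unsafe_col(off_d + r.dst_idx[e]) +=
        r.inv_deg[e] * T.unsafe_col(off_s + r.src_idx[e]);
    }
  }
}

// transpose aggregation for the backward pass
void gather_edges(arma::mat& out, const arma::mat& G, const Rel& r,
                  int ns, int nd, int P) {
  const arma::uword ne = r.src_idx.n_elem;
  for (int p = 0; p < P; ++p) {
    const arma::uword off_s = (arma::uword)p * ns;
    const arma::uword off_d = (arma::uword)p * nd;
    for (arma::uword e = 0; e < ne; ++e) {
      out.unsafe_col(off_s + r.src_idx[e]) +=
        r.inv_deg[e] * G.unsafe_col(off_d + r.dst_idx[e]);
    }
  }
}

std::vector<Rel> parse_rels(const List& rels) {
  std::vector<Rel> out;
  for (int i = 0; i < rels.size(); ++i) {
    List rl = rels[i];
    Rel r;
    r.src = as<int>(rl["src"]);
    r.dst = as<int>(rl["dst"]);
    r.src_idx = as<arma::uvec>(rl["src_idx"]);
    r.dst_idx = as<arma::uvec>(rl["dst_idx"]);
    r.inv_deg = as<arma::vec>(rl["inv_deg"]);
    r.wname = as<std::string>(rl["wname"]);
    out.push_back(r);
  }
  return out;
}

struct ForwardCache {
  std::vector<std::array<arma::mat, 3>> H; // L+1 state sets
  std::vector<std::array<arma::mat, 3>> pre; // L pre-activations
  std::vector<std::array<arma::mat, 3>> drop; // dropout masks (may be empty)
  std::array<arma::mat, 3> Tt; // tanh readout features
  std::array<arma::mat, 3> alpha; // n_t x P attention
  std::array<arma::mat, 3> ztyp; // d x P modality vectors
  std::array<arma::mat, 3> u; // tanh(U z_t)
  arma::mat beta; // 3 x P
  arma::mat z, logits, probs;
};

const char* TYPE[3] = {"g", "c", "m"};

void forward_pass(const List& params, const std::vector<Rel>& rels,
                  const std::array<arma::mat, 3>& X,
                  const arma::imat& mask, int L, int d,
                  double dropout, bool training, ForwardCache& C) {
  const int P = X[0].n_cols;
  int n[3] = {(int)X[0].n_rows, (int)X[1].n_rows, (int)X[2].n_rows};

  // layer-0 projection of the (already mask-zeroed) scalar signals
  std::array<arma::mat, 3> H;
  for (int t = 0; t < 3; ++t) {
    arma::vec pw = getv(params, std::string("proj_w_") + TYPE[t]);
    arma::vec pb = getv(params, std::string("proj_b_") + TYPE[t]);
    arma::rowvec xv = arma::vectorise(X[t]).t();
    H[t] = pw * xv;
    H[t].each_col() += pb;
  }
  C.H.clear(); C.pre.clear(); C.drop.clear();
  C.H.push_back(H);

  for (int l = 1; l <= L; ++l) {
    arma::mat W0 = getm(params, "W0_" + std::to_string(l));
    std::array<arma::mat, 3> pre;
    for (int t = 0; t < 3; ++t) pre[t] = W0 * H[t];
    for (const Rel& r : rels) {
      arma::mat Wr = getm(params, "Wr_" + r.wname + "_" + std::to_string(l));
      arma::mat T = Wr * H[r.src];
      scatter_edges(pre[r.dst], T, r, n[r.src], n[r.dst], P);
    }
    std::array<arma::mat, 3> dm;
    for (int t = 0; t < 3; ++t) {
      H[t] = arma::clamp(pre[t], 0.0, arma::datum::inf);
      if (training && dropout > 0) {
        const double keep = 1.0 - dropout;
        dm[t].set_size(H[t].n_rows, H[t].n_cols);
        double* m = dm[t].memptr();
        for (arma::uword i = 0; i < dm[t].n_elem; ++i) {
          m[i] = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
        }
        H[t] %= dm[t];
      }
    }
    C.pre.push_back(pre);
    C.drop.push_back(dm);
    C.H.push_back(H);
  }

  // attentive readout per type
  for (int t = 0; t < 3; ++t) {
    arma::mat Watt = getm(params, std::string("Watt_") + TYPE[t]);
    arma::vec aatt = getv(params, std::string("aatt_") + TYPE[t]);
    C.Tt[t] = arma::tanh(Watt * H[t]);
    arma::rowvec sv = aatt.t() * C.Tt[t]; // 1 x n_t*P
    arma::mat score(sv.memptr(), n[t], P); // column p = patient p
    score.each_row() -= arma::max(score, 0);
    arma::mat al = arma::exp(score);
    al.each_row() /= arma::sum(al, 0);
    C.alpha[t] = al;
    // z_t[, p] = sum_v alpha[v, p] * H[, p*n+v]
    arma::mat zt(d, P, arma::fill::zeros);
    for (int p = 0; p < P; ++p) {
      for (int v = 0; v < n[t]; ++v) {
        zt.unsafe_col(p) += al(v, p) * H[t].unsafe_col((arma::uword)p * n[t] + v);
      }
    }
    C.ztyp[t] = zt;
  }

  // masked fusion
  arma::mat U = getm(params, "U");
  arma::vec q = getv(params, "q");
  arma::mat f(3, P);
  for (int t = 0; t < 3; ++t) {
    C.u[t] = arma::tanh(U * C.ztyp[t]);
    f.row(t) = q.t() * C.u[t];
  }
  for (int t = 0; t < 3; ++t) {
    for (int p = 0; p < P; ++p) {
      if (!mask(t, p)) f(t, p) = -arma::datum::inf;
    }
  }
  f.each_row() -= arma::max(f, 0);
  C.beta = arma::exp(f);
  C.beta.each_row() /= arma::sum(C.beta, 0);
  C.z.zeros(d, P);
  for (int t = 0; t < 3; ++t) {
    arma::mat tmp = C.ztyp[t];
    tmp.each_row() %= C.beta.row(t);
    C.z += tmp;
  }
  arma::mat Wo = getm(params, "Wo");
  arma::vec bo = getv(params, "bo");
  C.logits = Wo * C.z;
  C.logits.each_col() += bo;
  arma::mat lg = C.logits;
  lg.each_row() -= arma::max(lg, 0);
  C.probs = arma::exp(lg);
  C.probs.each_row() /= arma::sum(C.probs, 0);
}

} // namespace

// Forward pass returning class probabilities (prediction path).
// [[Rcpp::export(name = ".cpp_forward_probs")]]
arma::mat cpp_forward_probs(List params, List Xl, IntegerMatrix maskR,
                            List rels, int L, int d) {
  std::array<arma::mat, 3> X = {as<arma::mat>(Xl[0]), as<arma::mat>(Xl[1]),
                                as<arma::mat>(Xl[2])};
  arma::imat mask = as<arma::imat>(maskR);
  const int P = X[0].n_cols;
  for (int t = 0; t < 3; ++t) {
    for (int p = 0; p < P; ++p) {
      if (!mask(t, p)) X[t].col(p).zeros();
    }
  }
  std::vector<Rel> rv = parse_rels(rels);
  ForwardCache C;
  forward_pass(params, rv, X, mask, L, d, 0.0, false, C);
  return C.probs;
}

// One training evaluation: loss (cross-entropy + graph smoothness +
// weight decay) and gradients for every parameter.
// [[Rcpp::export(name = ".cpp_loss_grad")]]
List cpp_loss_grad(List params, List Xl, IntegerMatrix maskR,
                   IntegerVector y, List rels, List regs, int L, int d,
                   double lambda_gr, double lambda_wd, double dropout,
                   bool training) {
  std::array<arma::mat, 3> X = {as<arma::mat>(Xl[0]), as<arma::mat>(Xl[1]),
                                as<arma::mat>(Xl[2])};
  arma::imat mask = as<arma::imat>(maskR);
  const int P = X[0].n_cols;
  int n[3] = {(int)X[0].n_rows, (int)X[1].n_rows, (int)X[2].n_rows};
  for (int t = 0; t < 3; ++t) {
    for (int p = 0; p < P; ++p) {
      if (!mask(t, p)) X[t].col(p).zeros();
    }
  }
  std::vector<Rel> rv = parse_rels(rels);
  ForwardCache C;
  forward_pass(params, rv, X, mask, L, d, dropout, training, C);

  // loss pieces
  double ce = 0.0;
  for (int p = 0; p < P; ++p) ce += -std::log(C.probs(y[p] - 1, p));
  ce /= P;
  const std::array<arma::mat, 3>& HL = C.H[L];
  double reg = 0.0;
  // regs: list of (a, b, ia, ib, w) with 0-based node indices
  std::vector<List> regv;
  for (int i = 0; i < regs.size(); ++i) regv.push_back(List(regs[i]));
  for (const List& pr : regv) {
    int a = as<int>(pr["a"]), b = as<int>(pr["b"]);
    arma::uvec ia = as<arma::uvec>(pr["ia"]), ib = as<arma::uvec>(pr["ib"]);
    arma::vec w = as<arma::vec>(pr["w"]);
    for (int p = 0; p < P; ++p) {
      for (arma::uword e = 0; e < ia.n_elem; ++e) {
        arma::vec diff = HL[a].col((arma::uword)p * n[a] + ia[e]) -
          HL[b].col((arma::uword)p * n[b] + ib[e]);
        reg += w[e] * arma::dot(diff, diff);
      }
    }
  }
  reg /= P;
  double wd = 0.0;
  CharacterVector nms = params.names();
  for (int i = 0; i < params.size(); ++i) {
    NumericVector nv = params[i];
    for (R_xlen_t j = 0; j < nv.size(); ++j) wd += nv[j] * nv[j];
  }
  double loss = ce + lambda_gr * reg + lambda_wd * wd;

  // ---- backward ----
  std::map<std::string, arma::mat> g;
  arma::mat dlogits = C.probs;
  for (int p = 0; p < P; ++p) dlogits(y[p] - 1, p) -= 1.0;
  dlogits /= P;

  arma::mat Wo = getm(params, "Wo");
  g["Wo"] = dlogits * C.z.t();
  g["bo"] = arma::sum(dlogits, 1);
  arma::mat dz = Wo.t() * dlogits;

  // fusion backward
  arma::mat U = getm(params, "U");
  arma::vec q = getv(params, "q");
  arma::mat dbeta(3, P);
  std::array<arma::mat, 3> dztyp;
  for (int t = 0; t < 3; ++t) {
    dbeta.row(t) = arma::sum(dz % C.ztyp[t], 0);
    dztyp[t] = dz;
    dztyp[t].each_row() %= C.beta.row(t);
  }
  arma::rowvec ssum = arma::sum(C.beta % dbeta, 0);
  arma::mat df = dbeta;
  df.each_row() -= ssum;
  df %= C.beta;
  for (int t = 0; t < 3; ++t) {
    for (int p = 0; p < P; ++p) {
      if (!mask(t, p)) df(t, p) = 0.0;
    }
  }
  g["U"].zeros(d, d);
  g["q"].zeros(d, 1);
  for (int t = 0; t < 3; ++t) {
    arma::mat dpre_u = (q * df.row(t)) % (1.0 - arma::square(C.u[t]));
    g["U"] += dpre_u * C.ztyp[t].t();
    g["q"] += C.u[t] * df.row(t).t();
    dztyp[t] += U.t() * dpre_u;
  }

  // readout backward
  std::array<arma::mat, 3> dHL;
  for (int t = 0; t < 3; ++t) {
    arma::mat Watt = getm(params, std::string("Watt_") + TYPE[t]);
    arma::vec aatt = getv(params, std::string("aatt_") + TYPE[t]);
    const arma::mat& H = HL[t];
    const arma::mat& al = C.alpha[t];
    arma::mat dH(d, (arma::uword)n[t] * P, arma::fill::zeros);
    arma::mat dalpha(n[t], P);
    for (int p = 0; p < P; ++p) {
      for (int v = 0; v < n[t]; ++v) {
        const arma::uword c = (arma::uword)p * n[t] + v;
        dH.unsafe_col(c) = al(v, p) * dztyp[t].unsafe_col(p);
        dalpha(v, p) = arma::dot(dztyp[t].unsafe_col(p), H.unsafe_col(c));
      }
    }
    arma::rowvec sa = arma::sum(al % dalpha, 0);
    arma::mat dscore = dalpha;
    dscore.each_row() -= sa;
    dscore %= al;
    arma::rowvec dsvec(dscore.memptr(), (arma::uword)n[t] * P);
    arma::mat dTt = aatt * dsvec;
    g[std::string("aatt_") + TYPE[t]] = C.Tt[t] * dsvec.t();
    arma::mat dpreT = dTt % (1.0 - arma::square(C.Tt[t]));
    g[std::string("Watt_") + TYPE[t]] = dpreT * H.t();
    dHL[t] = dH + Watt.t() * dpreT;
  }

  // graph smoothness gradient at the final states
  if (lambda_gr > 0) {
    const double scl = 2.0 * lambda_gr / P;
    for (const List& pr : regv) {
      int a = as<int>(pr["a"]), b = as<int>(pr["b"]);
      arma::uvec ia = as<arma::uvec>(pr["ia"]), ib = as<arma::uvec>(pr["ib"]);
      arma::vec w = as<arma::vec>(pr["w"]);
      for (int p = 0; p < P; ++p) {
        for (arma::uword e = 0; e < ia.n_elem; ++e) {
          const arma::uword ca = (arma::uword)p * n[a] + ia[e];
          const arma::uword cb = (arma::uword)p * n[b] + ib[e];
          arma::vec diff = (scl * w[e]) * (HL[a].col(ca) - HL[b].col(cb));
          dHL[a].unsafe_col(ca) += diff;
          dHL[b].unsafe_col(cb) -= diff;
        }
      }
    }
  }

  // message-passing layers backward
  std::array<arma::mat, 3> dH = dHL;
  for (int l = L; l >= 1; --l) {
    const std::array<arma::mat, 3>& Hin = C.H[l - 1];
    const std::array<arma::mat, 3>& pre = C.pre[l - 1];
    const std::array<arma::mat, 3>& dm = C.drop[l - 1];
    arma::mat W0 = getm(params, "W0_" + std::to_string(l));
    std::array<arma::mat, 3> dpre, dHin;
    std::string w0name = "W0_" + std::to_string(l);
    g[w0name].zeros(d, d);
    for (int t = 0; t < 3; ++t) {
      if (dm[t].n_elem > 0) dH[t] %= dm[t];
      dpre[t] = dH[t];
      dpre[t].elem(arma::find(pre[t] <= 0)).zeros();
      g[w0name] += dpre[t] * Hin[t].t();
      dHin[t] = W0.t() * dpre[t];
    }
    for (const Rel& r : rv) {
      std::string wn = "Wr_" + r.wname + "_" + std::to_string(l);
      arma::mat Wr = getm(params, wn);
      arma::mat G(d, (arma::uword)n[r.src] * P, arma::fill::zeros);
      gather_edges(G, dpre[r.dst], r, n[r.src], n[r.dst], P);
      if (g.count(wn)) {
        g[wn] += G * Hin[r.src].t();
      } else {
        g[wn] = G * Hin[r.src].t();
      }
      dHin[r.src] += Wr.t() * G;
    }
    dH = dHin;
  }

  // input projection backward
  for (int t = 0; t < 3; ++t) {
    arma::rowvec xv = arma::vectorise(X[t]).t();
    g[std::string("proj_w_") + TYPE[t]] = dH[t] * xv.t();
    g[std::string("proj_b_") + TYPE[t]] = arma::sum(dH[t], 1);
  }

  // weight decay term and assembly in the parameter order of `params`
  List grads(params.size());
  grads.names() = nms;
  for (int i = 0; i < params.size(); ++i) {
    std::string nm = as<std::string>(nms[i]);
    arma::mat gi = g[nm];
    NumericVector orig = params[i];
    arma::vec gv = arma::vectorise(gi);
    NumericVector out(gv.begin(), gv.end());
    for (R_xlen_t j = 0; j < out.size(); ++j) {
      out[j] += 2.0 * lambda_wd * orig[j];
    }
    out.attr("dim") = orig.attr("dim");
    grads[i] = out;
  }
  return List::create(_["loss"] = loss, _["grads"] = grads);
}
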