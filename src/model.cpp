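// Compiled evaluation of the three-timescale pathway model.
//
// The network is packed once from R (packModel) into a plain C++ structure
// held by an external pointer; the right-hand side and the raw rate vectors
// are then evaluated without touching R objects, which keeps implicit
// (Jacobian-heavy) stiff integration and long plant-step loops cheap.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct ModSet {
  std::vector<int> idx;      // 0-based index into state (absolute) or u
  std::vector<double> F;
};

struct GeneR {
  std::vector<int> act;      // absolute state indices of TF activators
  std::vector<double> K;
  ModSet enhz, enhu, inhz, inhu, inhy;
  double b, d;
};

struct InterR {
  std::vector<int> act;
  std::vector<double> K;
  ModSet enhz, enhu, inhz, inhu, inhy;
  double rate;
};

struct ReactR {
  std::vector<int> sub;      // absolute state indices of substrates
  ModSet enhz, enhu, inhz, inhu;
  double K, Km;
  int cat;                   // absolute state index of catalyzing gene
};

struct Entry { int row; double sgn; };

struct Model {
  int p, s, m, c, q, n;
  std::vector<GeneR> genes;
  std::vector<InterR> inters;
  std::vector<ReactR> reacts;
  std::vector< std::vector<Entry> > NsCol, NmCol;
};

static const double MOD_CAP = 1.0 - 1e-9;

static inline double modEnh(const ModSet& md, const double* lev) {
  double out = 1.0;
  for (size_t i = 0; i < md.idx.size(); ++i) {
    double v = md.F[i] * lev[md.idx[i]];
    if (v > MOD_CAP) v = MOD_CAP;
    out *= (1.0 + v);
  }
  return out;
}

static void packMod(ModSet& md, List lm) {
  IntegerVector idx = lm["idx"]; NumericVector F = lm["F"];
  md.idx.assign(idx.begin(), idx.end());
  md.F.assign(F.begin(), F.end());
}

// [[Rcpp::export(name = ".model_build")]]
SEXP model_build(List spec) {
  Model* M = new Model();
  M->p = as<int>(spec["p"]); M->s = as<int>(spec["s"]);
  M->m = as<int>(spec["m"]); M->c = as<int>(spec["c"]);
  List genes = spec["genes"], inters = spec["inters"], reacts = spec["reacts"];
  M->q = inters.size(); M->n = reacts.size();
  for (int i = 0; i < (int)genes.size(); ++i) {
    List g = genes[i]; GeneR gr;
    IntegerVector act = g["act"]; NumericVector K = g["K"];
    gr.act.assign(act.begin(), act.end());
    gr.K.assign(K.begin(), K.end());
    packMod(gr.enhz, g["enhz"]); packMod(gr.enhu, g["enhu"]);
    packMod(gr.inhz, g["inhz"]); packMod(gr.inhu, g["inhu"]);
    packMod(gr.inhy, g["inhy"]);
    gr.b = as<double>(g["b"]); gr.d = as<double>(g["d"]);
    M->genes.push_back(gr);
  }
  for (int i = 0; i < M->q; ++i) {
    List g = inters[i]; InterR ir;
    IntegerVector act = g["act"]; NumericVector K = g["K"];
    ir.act.assign(act.begin(), act.end());
    ir.K.assign(K.begin(), K.end());
    packMod(ir.enhz, g["enhz"]); packMod(ir.enhu, g["enhu"]);
    packMod(ir.inhz, g["inhz"]); packMod(ir.inhu, g["inhu"]);
    packMod(ir.inhy, g["inhy"]);
    ir.rate = as<double>(g["rate"]);
    M->inters.push_back(ir);
  }
  for (int i = 0; i < M->n; ++i) {
    List g = reacts[i]; ReactR rr;
    IntegerVector sub = g["sub"];
    rr.sub.assign(sub.begin(), sub.end());
    packMod(rr.enhz, g["enhz"]); packMod(rr.enhu, g["enhu"]);
    packMod(rr.inhz, g["inhz"]); packMod(rr.inhu, g["inhu"]);
    rr.K = as<double>(g["K"]); rr.Km = as<double>(g["Km"]);
    rr.cat = as<int>(g["cat"]);
    M->reacts.push_back(rr);
  }
  IntegerMatrix Ns = spec["Ns"], Nm = spec["Nm"];
  M->NsCol.resize(M->q); M->NmCol.resize(M->n);
  for (int j = 0; j < M->q; ++j)
    for (int i = 0; i < M->s; ++i)
      if (Ns(i, j) != 0) M->NsCol[j].push_back({i, (double)Ns(i, j)});
  for (int j = 0; j < M->n; ++j)
    for (int i = 0; i < M->m; ++i)
      if (Nm(i, j) != 0) M->NmCol[j].push_back({i, (double)Nm(i, j)});
  XPtr<Model> ptr(M, true);
  return ptr;
}

static void computeRates(const Model* M, const double* st, const double* u,
                         double* e, double* rs, double* rm, double* xdot) {
  for (int i = 0; i < M->p; ++i) {
    const GeneR& g = M->genes[i];
    if (g.act.empty()) { xdot[i] = g.b - g.d; e[i] = 0.0; continue; }
    double prod = 1.0; bool zero = false;
    for (size_t a = 0; a < g.act.size(); ++a) {
      double y = st[g.act[a]];
      if (y == 0.0) { zero = true; break; }
      prod *= g.K[a] * y;
    }
    if (zero) { xdot[i] = g.b - g.d; e[i] = 0.0; continue; }
    e[i] = prod;
    double enh = modEnh(g.enhz, st) * modEnh(g.enhu, u);
    double inh = modEnh(g.inhz, st) * modEnh(g.inhu, u) * modEnh(g.inhy, st);
    xdot[i] = (prod * enh + g.b) / inh - g.d;
  }
  for (int j = 0; j < M->q; ++j) {
    const InterR& r = M->inters[j];
    double base = r.rate; bool zero = false;
    for (size_t a = 0; a < r.act.size(); ++a) {
      double y = st[r.act[a]];
      if (y == 0.0) { zero = true; break; }
      base *= r.K[a] * y;
    }
    if (zero) { rs[j] = 0.0; continue; }
    double enh = modEnh(r.enhz, st) * modEnh(r.enhu, u);
    double inh = modEnh(r.inhz, st) * modEnh(r.inhu, u) * modEnh(r.inhy, st);
    rs[j] = base * enh / inh;
  }
  for (int j = 0; j < M->n; ++j) {
    const ReactR& r = M->reacts[j];
    if (r.K == 0.0) { rm[j] = 0.0; continue; }
    double Z = 1.0;
    for (size_t a = 0; a < r.sub.size(); ++a) Z *= st[r.sub[a]];
    double base = r.K * st[r.cat] * Z / (r.Km + Z);
    double enh = modEnh(r.enhz, st) * modEnh(r.enhu, u);
    double inh = modEnh(r.inhz, st) * modEnh(r.inhu, u);
    rm[j] = base * enh / inh;
  }
}

// Shared derivative kernel used by both the .Call interface and the
// direct deSolve hook.
static void computeDeriv(const Model* M, const double* state,
                         const double* u, double omega1, double omega2,
                         bool wall_on, const int* pin, int npin,
                         const double* pinv, double* dy) {
  int N = M->p + M->s + M->m;
  std::vector<double> st(N);
  for (int i = 0; i < N; ++i)
    st[i] = std::min(std::max(state[i], 0.0), 1.0);
  for (int i = 0; i < npin; ++i) st[pin[i]] = pinv[i];
  std::vector<double> uc(M->c);
  for (int i = 0; i < M->c; ++i)
    uc[i] = std::min(std::max(u[i], 0.0), 1.0);
  std::vector<double> e(M->p), rs(M->q), rm(M->n);
  computeRates(M, st.data(), uc.data(), e.data(), rs.data(), rm.data(), dy);
  double w1 = 1.0 / omega1, w12 = 1.0 / (omega1 * omega2);
  for (int i = M->p; i < N; ++i) dy[i] = 0.0;
  for (int j = 0; j < M->q; ++j)
    for (const Entry& en : M->NsCol[j])
      dy[M->p + en.row] += w1 * en.sgn * rs[j];
  for (int j = 0; j < M->n; ++j)
    for (const Entry& en : M->NmCol[j])
      dy[M->p + M->s + en.row] += w12 * en.sgn * rm[j];
  if (wall_on) {
    // smooth restoring wall outside the unit box, scaled to each block's
    // own timescale (stiff solvers chatter on hard derivative projection)
    const double wall = 10.0;
    for (int i = 0; i < N; ++i) {
      double w = wall;
      if (i >= M->p && i < M->p + M->s) w = wall * w1;
      else if (i >= M->p + M->s) w = wall * w12;
      if (state[i] > 1.0) dy[i] += w * (1.0 - state[i]);
      else if (state[i] < 0.0) dy[i] -= w * state[i];
    }
  }
  for (int i = 0; i < npin; ++i) dy[pin[i]] = 0.0;
}

// Active-model slot for the zero-overhead deSolve hook (constant inputs).
static Model* ACT_M = nullptr;
static std::vector<double> ACT_U, ACT_PINV;
static std::vector<int> ACT_PIN;
static double ACT_W1 = 1.0, ACT_W2 = 1.0;
static bool ACT_WALL = true;

// [[Rcpp::export(name = ".model_activate")]]
void model_activate(SEXP mptr, NumericVector u, double omega1, double omega2,
                    bool wall, IntegerVector pin_idx, NumericVector pin_val) {
  XPtr<Model> M(mptr);
  ACT_M = M.get();
  ACT_U.assign(u.begin(), u.end());
  ACT_PIN.assign(pin_idx.begin(), pin_idx.end());
  ACT_PINV.assign(pin_val.begin(), pin_val.end());
  ACT_W1 = omega1; ACT_W2 = omega2; ACT_WALL = wall;
}

extern "C" void pathmpc_deriv(int* neq, double* t, double* y, double* ydot,
                              double* yout, int* ip) {
  (void)neq; (void)t; (void)yout; (void)ip;
  computeDeriv(ACT_M, y, ACT_U.data(), ACT_W1, ACT_W2, ACT_WALL,
               ACT_PIN.data(), (int)ACT_PIN.size(), ACT_PINV.data(), ydot);
}

#include <R_ext/Rdynload.h>
// deSolve resolves "pathmpc_deriv" by name; allow dynamic symbol lookup
// (the auto-generated registration turns it off).
// [[Rcpp::init]]
void pathmpc_dyn_init(DllInfo* dll) {
  R_useDynamicSymbols(dll, TRUE);
}

// Raw rate vectors (gene expression rates e, interaction rates r_s, fluxes
// r_m) and the unscaled subsystem derivatives, at a clamped state.
// [[Rcpp::export(name = ".model_rates")]]
List model_rates(SEXP mptr, NumericVector state, NumericVector u) {
  XPtr<Model> M(mptr);
  int N = M->p + M->s + M->m;
  std::vector<double> st(N);
  for (int i = 0; i < N; ++i)
    st[i] = std::min(std::max(state[i], 0.0), 1.0);
  std::vector<double> uc(M->c);
  for (int i = 0; i < M->c; ++i) uc[i] = u[i];
  NumericVector e(M->p), rs(M->q), rm(M->n), xdot(M->p);
  NumericVector gdot(M->s), hdot(M->m);
  computeRates(M, st.data(), uc.data(), e.begin(), rs.begin(), rm.begin(),
               xdot.begin());
  for (int j = 0; j < M->q; ++j)
    for (const Entry& en : M->NsCol[j]) gdot[en.row] += en.sgn * rs[j];
  for (int j = 0; j < M->n; ++j)
    for (const Entry& en : M->NmCol[j]) hdot[en.row] += en.sgn * rm[j];
  return List::create(_["e"] = e, _["rs"] = rs, _["rm"] = rm,
                      _["xdot"] = xdot, _["gdot"] = gdot, _["hdot"] = hdot);
}

// Full scaled derivative with box projection and optional pinned species.
// [[Rcpp::export(name = ".model_rhs")]]
NumericVector model_rhs(SEXP mptr, NumericVector state, NumericVector u,
                        double omega1, double omega2, bool project,
                        IntegerVector pin_idx, NumericVector pin_val) {
  XPtr<Model> M(mptr);
  int N = M->p + M->s + M->m;
  NumericVector dy(N);
  computeDeriv(M.get(), &state[0], &u[0], omega1, omega2, project,
               pin_idx.size() ? &pin_idx[0] : nullptr, pin_idx.size(),
               pin_val.size() ? &pin_val[0] : nullptr, &dy[0]);
  return dy;
}
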