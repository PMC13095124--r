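// Core numerical engine: convolution primitives, recurrent disinhibitory
// dynamics, accessory (adjoint) credit propagation, and the feedforward
// scale-selection pass.  Layer maps are arma::cube (rows x cols x channels),
// matching R's column-major array layout.  4-D kernels arrive as R arrays
// and are indexed through the K4 view below.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;

namespace {

// View over a 4-D R array (d1,d2,d3,d4), column-major.
struct K4 {
  const double* p;
  int d1, d2, d3, d4;
  explicit K4(const NumericVector& v) {
    IntegerVector d = v.attr("dim");
    if (d.size() != 4) stop("kernel must be a 4-d array");
    d1 = d[0]; d2 = d[1]; d3 = d[2]; d4 = d[3];
    p = v.begin();
  }
  inline double operator()(int a, int b, int c, int d) const {
    return p[a + d1 * (b + d2 * (c + d3 * d))];
  }
};

inline double relu(double x) { return x > 0.0 ? x : 0.0; }
inline double clip01(double x) { return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x); }

// Saturating gate g(x) = 100|x| / sqrt(1 + (100 x)^2); optional "bump"
// reading g(x) = 100|x| / (1 + (100 x)^2) kept for comparison.
inline double phi_fun(double x, bool bump) {
  double z = 100.0 * x;
  return bump ? std::fabs(z) / (1.0 + z * z)
              : std::fabs(z) / std::sqrt(1.0 + z * z);
}

// --- convolution primitives -------------------------------------------------

// 3x3 kernel, stride 3: in (3h,3w,Ci) -> out (h,w,Co).  W dims (3,3,Ci,Co).
cube conv3s3(const cube& in, const K4& W) {
  int h = in.n_rows / 3, w = in.n_cols / 3, Ci = in.n_slices, Co = W.d4;
  cube out(h, w, Co, arma::fill::zeros);
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int v = 0; v < 3; ++v)
        for (int u = 0; u < 3; ++u) {
          double k = W(u, v, ci, co);
          if (k == 0.0) continue;
          for (int j = 0; j < w; ++j)
            for (int i = 0; i < h; ++i)
              out(i, j, co) += k * in(3 * i + u, 3 * j + v, ci);
        }
  return out;
}

// Adjoint of conv3s3 w.r.t. its input: g (h,w,Co) -> (3h,3w,Ci).
cube adj_conv3s3(const cube& g, const K4& W, int Ci) {
  int h = g.n_rows, w = g.n_cols, Co = g.n_slices;
  cube out(3 * h, 3 * w, Ci, arma::fill::zeros);
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int v = 0; v < 3; ++v)
        for (int u = 0; u < 3; ++u) {
          double k = W(u, v, ci, co);
          if (k == 0.0) continue;
          for (int j = 0; j < w; ++j)
            for (int i = 0; i < h; ++i)
              out(3 * i + u, 3 * j + v, ci) += k * g(i, j, co);
        }
  return out;
}

// Transposed conv, 3x3 kernel, stride 3 (RF-aligned feedback):
// in (h,w,Cup) -> out (3h,3w,Clo).  W dims (3,3,Cup,Clo).
cube tconv3(const cube& in, const K4& W) {
  int h = in.n_rows, w = in.n_cols, Cup = in.n_slices, Clo = W.d4;
  cube out(3 * h, 3 * w, Clo, arma::fill::zeros);
  for (int clo = 0; clo < Clo; ++clo)
    for (int cup = 0; cup < Cup; ++cup)
      for (int v = 0; v < 3; ++v)
        for (int u = 0; u < 3; ++u) {
          double k = W(u, v, cup, clo);
          if (k == 0.0) continue;
          for (int j = 0; j < w; ++j)
            for (int i = 0; i < h; ++i)
              out(3 * i + u, 3 * j + v, clo) += k * in(i, j, cup);
        }
  return out;
}

// Adjoint of tconv3 w.r.t. its (coarse) input: g (3h,3w,Clo) -> (h,w,Cup).
cube adj_tconv3(const cube& g, const K4& W, int Cup) {
  int h = g.n_rows / 3, w = g.n_cols / 3, Clo = g.n_slices;
  cube out(h, w, Cup, arma::fill::zeros);
  for (int clo = 0; clo < Clo; ++clo)
    for (int cup = 0; cup < Cup; ++cup)
      for (int v = 0; v < 3; ++v)
        for (int u = 0; u < 3; ++u) {
          double k = W(u, v, cup, clo);
          if (k == 0.0) continue;
          for (int j = 0; j < w; ++j)
            for (int i = 0; i < h; ++i)
              out(i, j, cup) += k * g(3 * i + u, 3 * j + v, clo);
        }
  return out;
}

// von Neumann offsets within a 3x3 kernel (u,v): up, left, right, down.
const int VN_U[4] = {0, 1, 1, 2};
const int VN_V[4] = {1, 0, 2, 1};

// Horizontal conv, stride 1, kernel masked to the von Neumann neighborhood.
// out(i,j,co) += W(u,v,ci,co) * in(i+u-1, j+v-1, ci).  W dims (3,3,Ci,Co).
cube horconv(const cube& in, const K4& W) {
  int h = in.n_rows, w = in.n_cols, Ci = in.n_slices, Co = W.d4;
  cube out(h, w, Co, arma::fill::zeros);
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int o = 0; o < 4; ++o) {
        int du = VN_U[o] - 1, dv = VN_V[o] - 1;
        double k = W(VN_U[o], VN_V[o], ci, co);
        if (k == 0.0) continue;
        int i0 = std::max(0, -du), i1 = std::min(h, h - du);
        int j0 = std::max(0, -dv), j1 = std::min(w, w - dv);
        for (int j = j0; j < j1; ++j)
          for (int i = i0; i < i1; ++i)
            out(i, j, co) += k * in(i + du, j + dv, ci);
      }
  return out;
}

// Adjoint of horconv w.r.t. its input.
cube adj_horconv(const cube& g, const K4& W, int Ci) {
  int h = g.n_rows, w = g.n_cols, Co = g.n_slices;
  cube out(h, w, Ci, arma::fill::zeros);
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int o = 0; o < 4; ++o) {
        int du = VN_U[o] - 1, dv = VN_V[o] - 1;
        double k = W(VN_U[o], VN_V[o], ci, co);
        if (k == 0.0) continue;
        int i0 = std::max(0, -du), i1 = std::min(h, h - du);
        int j0 = std::max(0, -dv), j1 = std::min(w, w - dv);
        for (int j = j0; j < j1; ++j)
          for (int i = i0; i < i1; ++i)
            out(i + du, j + dv, ci) += k * g(i, j, co);
      }
  return out;
}

// Center-only lateral inhibition: out(i,j,co) = sum_ci LI0(1,1,ci,co)*in(i,j,ci).
cube centermix(const cube& in, const K4& W) {
  int h = in.n_rows, w = in.n_cols, Ci = in.n_slices, Co = W.d4;
  cube out(h, w, Co, arma::fill::zeros);
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci) {
      double k = W(1, 1, ci, co);
      if (k == 0.0) continue;
      out.slice(co) += k * in.slice(ci);
    }
  return out;
}

// Adjoint of centermix w.r.t. its input.
cube adj_centermix(const cube& g, const K4& W, int Ci) {
  int h = g.n_rows, w = g.n_cols, Co = g.n_slices;
  cube out(h, w, Ci, arma::fill::zeros);
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci) {
      double k = W(1, 1, ci, co);
      if (k == 0.0) continue;
      out.slice(ci) += k * g.slice(co);
    }
  return out;
}

// --- weight container -------------------------------------------------------

struct Weights {
  int L;
  std::vector<int> C;                  // channels per layer, index 0..L
  std::vector<NumericVector> ff2;      // ff2[l], l=1..L: (3,3,C[l-1],C[l])
  std::vector<NumericVector> fb;       // fb[l], l=0..L-1: (3,3,C[l+1],C[l])
  std::vector<NumericVector> hor;      // hor[l], l=1..L: (3,3,C[l],C[l])
  NumericVector li0;                   // (3,3,C0,C0), center-only
  std::vector<NumericVector> wskip;    // wskip[l], l=0..L: (K,K,C[l]) with K=3^l
  bool bump;

  explicit Weights(const List& w) {
    List ff2l = w["ff2"], fbl = w["fb"], horl = w["hor"], skipl = w["wskip"];
    L = ff2l.size();
    li0 = as<NumericVector>(w["li0"]);
    bump = w.containsElementNamed("phiBump") ? as<bool>(w["phiBump"]) : false;
    C.resize(L + 1);
    {
      IntegerVector d = as<NumericVector>(ff2l[0]).attr("dim");
      C[0] = d[2];
    }
    for (int l = 1; l <= L; ++l) {
      ff2.push_back(as<NumericVector>(ff2l[l - 1]));
      IntegerVector d = ff2.back().attr("dim");
      C[l] = d[3];
    }
    for (int l = 0; l < L; ++l) fb.push_back(as<NumericVector>(fbl[l]));
    for (int l = 1; l <= L; ++l) hor.push_back(as<NumericVector>(horl[l - 1]));
    for (int l = 0; l <= L; ++l) wskip.push_back(as<NumericVector>(skipl[l]));
  }
};

std::vector<mat> getPhiG(const List& phiG) {
  std::vector<mat> out;
  for (int i = 0; i < phiG.size(); ++i) out.push_back(as<mat>(phiG[i]));
  return out;
}

// One synchronous update: interneurons read the previous step's pyramidal
// activity (Yprev); pyramidal layers then sweep bottom-up within the step.
// Writes into Ynew/VIP/SOM/VIPpre without touching Yprev.
void step_core(const cube& phiX, const std::vector<mat>& phiG,
               const Weights& W, const std::vector<cube>& Yprev,
               std::vector<cube>& Ynew, std::vector<cube>& VIP,
               std::vector<cube>& SOM, std::vector<cube>& VIPpre) {
  int L = W.L;
  // interneurons (from t-1 activity)
  VIPpre[0] = tconv3(Yprev[1], K4(W.fb[0]));
  for (int l = 1; l <= L; ++l) {
    cube h = horconv(Yprev[l], K4(W.hor[l - 1]));
    if (l < L) h += tconv3(Yprev[l + 1], K4(W.fb[l]));
    VIPpre[l] = std::move(h);
  }
  for (int l = 0; l <= L; ++l) {
    VIP[l] = VIPpre[l];
    VIP[l].transform([](double x) { return clip01(x); });
    SOM[l] = 1.0 - VIP[l];
    SOM[l].transform([](double x) { return relu(x); });
  }
  // pyramidal sweep (same-step feedforward)
  cube rel = centermix(SOM[0], K4(W.li0));
  Ynew[0] = phiX % (-rel);
  Ynew[0].transform([](double x) { return relu(x); });
  for (int l = 1; l <= L; ++l) {
    cube ff = conv3s3(Ynew[l - 1], K4(W.ff2[l - 1]));
    ff -= SOM[l];
    for (int c = 0; c < (int)ff.n_slices; ++c) ff.slice(c) %= phiG[l - 1];
    ff.transform([](double x) { return relu(x); });
    Ynew[l] = std::move(ff);
  }
}

// Copy-semantics wrapper (single exposed step).
void step_once(const cube& phiX, const std::vector<mat>& phiG, const Weights& W,
               std::vector<cube>& Y, std::vector<cube>& VIP,
               std::vector<cube>& SOM, std::vector<cube>& VIPpre) {
  std::vector<cube> Yprev = Y;
  step_core(phiX, phiG, W, Yprev, Y, VIP, SOM, VIPpre);
}

double max_abs_diff(const std::vector<cube>& a, const std::vector<cube>& b) {
  double m = 0.0;
  for (size_t i = 0; i < a.size(); ++i) {
    double d = arma::abs(a[i] - b[i]).max();
    if (d > m) m = d;
  }
  return m;
}

void check_finite(const std::vector<cube>& Y) {
  for (const cube& y : Y)
    if (!y.is_finite()) stop("network activity diverged (non-finite values)");
}

mat qmap_of(const std::vector<cube>& Y, const Weights& W) {
  int H = Y[0].n_rows, Wd = Y[0].n_cols;
  mat Q(H, Wd, arma::fill::zeros);
  // input-layer skip: 1x1 convolution
  const NumericVector& w0 = W.wskip[0];
  for (int c = 0; c < W.C[0]; ++c) Q += w0[c] * Y[0].slice(c);
  for (int l = 1; l <= W.L; ++l) {
    int K = 1;
    for (int i = 0; i < l; ++i) K *= 3;
    const NumericVector& wl = W.wskip[l];
    const cube& Yl = Y[l];
    int h = Yl.n_rows, w = Yl.n_cols, C = Yl.n_slices;
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < w; ++j)
        for (int i = 0; i < h; ++i) {
          double y = Yl(i, j, c);
          if (y == 0.0) continue;
          for (int v = 0; v < K; ++v)
            for (int u = 0; u < K; ++u)
              Q(K * i + u, K * j + v) += wl[u + K * (v + K * c)] * y;
        }
  }
  return Q;
}

List state_to_list(const std::vector<cube>& v) {
  List out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = v[i];
  return out;
}

// Deep-copied state (as<cube> may alias R memory; the step map assigns into
// same-sized cubes, which would otherwise write through to the caller's
// objects).
std::vector<cube> list_to_state(const List& l) {
  std::vector<cube> v;
  for (int i = 0; i < l.size(); ++i) {
    cube view = as<cube>(l[i]);
    v.push_back(cube(view.memptr(), view.n_rows, view.n_cols, view.n_slices));
  }
  return v;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_phi")]]
NumericVector cpp_phi(NumericVector x, bool bump) {
  NumericVector out(clone(x));
  for (double& v : out) v = phi_fun(v, bump);
  return out;
}

// [[Rcpp::export(name = ".cpp_forward")]]
List cpp_forward(const arma::cube& phiX, List phiG, List w, int tmax,
                 double tol, bool record) {
  Weights W(w);
  std::vector<mat> G = getPhiG(phiG);
  if ((int)G.size() != W.L) stop("gate stack does not match network depth");
  int H = phiX.n_rows;
  std::vector<cube> Y, VIP, SOM, VIPpre;
  int r = H;
  Y.push_back(cube(H, phiX.n_cols, W.C[0], arma::fill::zeros));
  for (int l = 1; l <= W.L; ++l) {
    r /= 3;
    if ((int)G[l - 1].n_rows != r)
      stop("gate map at scale %d has wrong resolution", l);
    Y.push_back(cube(r, r, W.C[l], arma::fill::zeros));
  }
  VIP = Y; VIPpre = Y;
  // SOM interneurons are tonically active: baseline ReLU(1 - VIP) = 1
  SOM = Y;
  for (auto& s : SOM) s.ones();
  List hist;
  int T = tmax;
  bool converged = false;
  std::vector<cube> Ynew = Y, Vnew = VIP, Snew = SOM, Pnew = VIPpre;
  for (int t = 1; t <= tmax; ++t) {
    step_core(phiX, G, W, Y, Ynew, Vnew, Snew, Pnew);
    check_finite(Ynew);
    if (record) hist.push_back(state_to_list(Ynew));
    double d = std::max(max_abs_diff(Ynew, Y),
                        std::max(max_abs_diff(Vnew, VIP), max_abs_diff(Snew, SOM)));
    Y.swap(Ynew); VIP.swap(Vnew); SOM.swap(Snew); VIPpre.swap(Pnew);
    if (d <= tol) { T = t; converged = true; break; }
  }
  return List::create(_["Y"] = state_to_list(Y), _["VIP"] = state_to_list(VIP),
                      _["SOM"] = state_to_list(SOM),
                      _["VIPpre"] = state_to_list(VIPpre), _["T"] = T,
                      _["converged"] = converged, _["history"] = hist);
}

// [[Rcpp::export(name = ".cpp_step")]]
List cpp_step(const arma::cube& phiX, List phiG, List w, List Yl, List VIPl,
              List SOMl) {
  Weights W(w);
  std::vector<mat> G = getPhiG(phiG);
  std::vector<cube> Y = list_to_state(Yl), VIP = list_to_state(VIPl),
                    SOM = list_to_state(SOMl), VIPpre = VIP;
  step_once(phiX, G, W, Y, VIP, SOM, VIPpre);
  return List::create(_["Y"] = state_to_list(Y), _["VIP"] = state_to_list(VIP),
                      _["SOM"] = state_to_list(SOM),
                      _["VIPpre"] = state_to_list(VIPpre));
}

// [[Rcpp::export(name = ".cpp_qmap")]]
arma::mat cpp_qmap(List Yl, List w) {
  Weights W(w);
  std::vector<cube> Y = list_to_state(Yl);
  return qmap_of(Y, W);
}

// Accessory credit propagation (linearized adjoint at the fixed point) plus
// per-kernel gradients dQa/dw.  action is 0-based (row, col) in the output map.
// [[Rcpp::export(name = ".cpp_accessory")]]
List cpp_accessory(const arma::cube& phiX, List phiG, List w, List Yl,
                   List VIPprel, List SOMl, int ai, int aj, int tmax,
                   double tol) {
  Weights W(w);
  int L = W.L;
  std::vector<mat> G = getPhiG(phiG);
  std::vector<cube> Y = list_to_state(Yl), VIPpre = list_to_state(VIPprel),
                    SOM = list_to_state(SOMl);

  // direct readout credit (seed): one unit of credit at the chosen pixel.
  std::vector<cube> seed;
  for (int l = 0; l <= L; ++l) seed.push_back(cube(arma::size(Y[l]), arma::fill::zeros));
  for (int c = 0; c < W.C[0]; ++c) seed[0](ai, aj, c) = W.wskip[0][c];
  for (int l = 1; l <= L; ++l) {
    int K = 1;
    for (int i = 0; i < l; ++i) K *= 3;
    int fi = ai / K, fj = aj / K, u = ai - K * fi, v = aj - K * fj;
    for (int c = 0; c < W.C[l]; ++c)
      seed[l](fi, fj, c) = W.wskip[l][u + K * (v + K * c)];
  }

  // one backward application of the linearized step map: input zout (credit on
  // the step's output), output zin (credit on the step's input); m/n are the
  // pyramidal / VIP pre-activation credits at this application.
  auto backward = [&](const std::vector<cube>& zout, std::vector<cube>& zin,
                      std::vector<cube>& mker, std::vector<cube>& nker) {
    std::vector<cube> a = zout;  // credit on Ynew, accumulates same-step flow
    for (int l = 0; l <= L; ++l) {
      zin[l].zeros(); mker[l].zeros(); nker[l].zeros();
    }
    for (int l = L; l >= 1; --l) {
      cube m = a[l];
      for (int c = 0; c < (int)m.n_slices; ++c) m.slice(c) %= G[l - 1];
      m %= arma::conv_to<cube>::from(Y[l] > 0.0);
      mker[l] = m;
      a[l - 1] += adj_conv3s3(m, K4(W.ff2[l - 1]), W.C[l - 1]);
      cube cvip = m % arma::conv_to<cube>::from(SOM[l] > 0.0);
      cube n = cvip % arma::conv_to<cube>::from(
          (VIPpre[l] > 0.0) % (VIPpre[l] < 1.0));
      nker[l] = n;
      zin[l] += adj_horconv(n, K4(W.hor[l - 1]), W.C[l]);
      if (l < L) zin[l + 1] += adj_tconv3(n, K4(W.fb[l]), W.C[l + 1]);
    }
    // input layer
    cube m0 = a[0] % phiX;
    m0 %= arma::conv_to<cube>::from(Y[0] > 0.0);
    mker[0] = m0;
    cube csom0 = -adj_centermix(m0, K4(W.li0), W.C[0]);
    cube cvip0 = -csom0 % arma::conv_to<cube>::from(SOM[0] > 0.0);
    cube n0 = cvip0 % arma::conv_to<cube>::from(
        (VIPpre[0] > 0.0) % (VIPpre[0] < 1.0));
    nker[0] = n0;
    zin[1] += adj_tconv3(n0, K4(W.fb[0]), W.C[1]);
  };

  std::vector<cube> z = seed, zin = seed, mker = seed, nker = seed;
  for (auto& c : z) c.zeros();
  bool converged = false;
  int iters = tmax;
  for (int it = 1; it <= tmax; ++it) {
    backward(z, zin, mker, nker);
    std::vector<cube> znew(L + 1);
    for (int l = 0; l <= L; ++l) znew[l] = zin[l] + seed[l];
    double d = max_abs_diff(znew, z);
    z = znew;
    check_finite(z);
    if (d <= tol) { iters = it; converged = true; break; }
  }
  // final linear pass at the converged credit field
  backward(z, zin, mker, nker);

  // gradients dQa/dw
  List gff2(L), gfb(L), ghor(L);
  for (int l = 1; l <= L; ++l) {
    // FF2 grad: dW(u,v,ci,co) = sum m_l(i,j,co) * Y[l-1](3i+u,3j+v,ci)
    NumericVector gv(3 * 3 * W.C[l - 1] * W.C[l]);
    gv.attr("dim") = IntegerVector::create(3, 3, W.C[l - 1], W.C[l]);
    const cube& m = mker[l];
    const cube& Yin = Y[l - 1];
    int h = m.n_rows, wd = m.n_cols;
    for (int co = 0; co < W.C[l]; ++co)
      for (int ci = 0; ci < W.C[l - 1]; ++ci)
        for (int v = 0; v < 3; ++v)
          for (int u = 0; u < 3; ++u) {
            double s = 0.0;
            for (int j = 0; j < wd; ++j)
              for (int i = 0; i < h; ++i)
                s += m(i, j, co) * Yin(3 * i + u, 3 * j + v, ci);
            gv[u + 3 * (v + 3 * (ci + W.C[l - 1] * co))] = s;
          }
    gff2[l - 1] = gv;
    // Hor grad (von Neumann positions only)
    NumericVector gh(3 * 3 * W.C[l] * W.C[l]);
    gh.attr("dim") = IntegerVector::create(3, 3, W.C[l], W.C[l]);
    const cube& n = nker[l];
    const cube& Ysame = Y[l];
    for (int co = 0; co < W.C[l]; ++co)
      for (int ci = 0; ci < W.C[l]; ++ci)
        for (int o = 0; o < 4; ++o) {
          int du = VN_U[o] - 1, dv = VN_V[o] - 1;
          int i0 = std::max(0, -du), i1 = std::min(h, h - du);
          int j0 = std::max(0, -dv), j1 = std::min((int)n.n_cols, (int)n.n_cols - dv);
          double s = 0.0;
          for (int j = j0; j < j1; ++j)
            for (int i = i0; i < i1; ++i)
              s += n(i, j, co) * Ysame(i + du, j + dv, ci);
          gh[VN_U[o] + 3 * (VN_V[o] + 3 * (ci + W.C[l] * co))] = s;
        }
    ghor[l - 1] = gh;
  }
  for (int l = 0; l < L; ++l) {
    // FB grad: dW(u,v,cup,clo) = sum_coarse n_l(3i+u,3j+v,clo) * Y[l+1](i,j,cup)
    NumericVector gb(3 * 3 * W.C[l + 1] * W.C[l]);
    gb.attr("dim") = IntegerVector::create(3, 3, W.C[l + 1], W.C[l]);
    const cube& n = nker[l];
    const cube& Yup = Y[l + 1];
    int h = Yup.n_rows, wd = Yup.n_cols;
    for (int clo = 0; clo < W.C[l]; ++clo)
      for (int cup = 0; cup < W.C[l + 1]; ++cup)
        for (int v = 0; v < 3; ++v)
          for (int u = 0; u < 3; ++u) {
            double s = 0.0;
            for (int j = 0; j < wd; ++j)
              for (int i = 0; i < h; ++i)
                s += n(3 * i + u, 3 * j + v, clo) * Yup(i, j, cup);
            gb[u + 3 * (v + 3 * (cup + W.C[l + 1] * clo))] = s;
          }
    gfb[l] = gb;
  }
  // LI0 grad (center only): d(1,1,ci,co) = sum m0(i,j,co) * (-SOM0(i,j,ci))
  NumericVector gli(3 * 3 * W.C[0] * W.C[0]);
  gli.attr("dim") = IntegerVector::create(3, 3, W.C[0], W.C[0]);
  for (int co = 0; co < W.C[0]; ++co)
    for (int ci = 0; ci < W.C[0]; ++ci)
      gli[1 + 3 * (1 + 3 * (ci + W.C[0] * co))] =
          -arma::accu(mker[0].slice(co) % SOM[0].slice(ci));
  // skip grads: direct, local to the chosen pixel's footprint
  List gskip(L + 1);
  {
    NumericVector g0(W.C[0]);
    g0.attr("dim") = IntegerVector::create(1, 1, W.C[0]);
    for (int c = 0; c < W.C[0]; ++c) g0[c] = Y[0](ai, aj, c);
    gskip[0] = g0;
  }
  for (int l = 1; l <= L; ++l) {
    int K = 1;
    for (int i = 0; i < l; ++i) K *= 3;
    NumericVector gs(K * K * W.C[l]);
    gs.attr("dim") = IntegerVector::create(K, K, W.C[l]);
    int fi = ai / K, fj = aj / K, u = ai - K * fi, v = aj - K * fj;
    for (int c = 0; c < W.C[l]; ++c) gs[u + K * (v + K * c)] = Y[l](fi, fj, c);
    gskip[l] = gs;
  }

  return List::create(
      _["credit"] = state_to_list(z), _["creditPyr"] = state_to_list(mker),
      _["creditVIP"] = state_to_list(nker), _["iterations"] = iters,
      _["converged"] = converged,
      _["grads"] = List::create(_["ff2"] = gff2, _["fb"] = gfb, _["hor"] = ghor,
                                _["li0"] = gli, _["wskip"] = gskip));
}

// --- feedforward scale-selection pathway ------------------------------------

namespace {

// stride-1 same-padded conv of a single-channel map with nf kernels (k x k).
// Direct loops for small k, im2col + GEMM for large k.
cube conv_same_multi(const mat& x, const cube& ker) {
  int H = x.n_rows, W = x.n_cols, k = ker.n_rows, nf = ker.n_slices;
  int half = (k - 1) / 2;
  cube out(H, W, nf, arma::fill::zeros);
  if (k <= 3) {
    for (int f = 0; f < nf; ++f) {
      const mat& kk = ker.slice(f);
      mat& o = out.slice(f);
      for (int v = 0; v < k; ++v)
        for (int u = 0; u < k; ++u) {
          double kv = kk(u, v);
          if (kv == 0.0) continue;
          int du = u - half, dv = v - half;
          int i0 = std::max(0, -du), i1 = std::min(H, H - du);
          int j0 = std::max(0, -dv), j1 = std::min(W, W - dv);
          for (int j = j0; j < j1; ++j)
            for (int i = i0; i < i1; ++i)
              o(i, j) += kv * x(i + du, j + dv);
        }
    }
  } else {
    // one output column of blocks at a time
    mat Wm(nf, k * k);
    for (int f = 0; f < nf; ++f)
      Wm.row(f) = arma::vectorise(ker.slice(f)).t();
    mat cols(k * k, H);
    for (int j = 0; j < W; ++j) {
      cols.zeros();
      for (int v = 0; v < k; ++v) {
        int jj = j + v - half;
        if (jj < 0 || jj >= W) continue;
        for (int u = 0; u < k; ++u) {
          int r = u + k * v;
          int du = u - half;
          int i0 = std::max(0, -du), i1 = std::min(H, H - du);
          for (int i = i0; i < i1; ++i) cols(r, i) = x(i + du, jj);
        }
      }
      mat res = Wm * cols;  // nf x H
      for (int f = 0; f < nf; ++f)
        for (int i = 0; i < H; ++i) out(i, j, f) = res(f, i);
    }
  }
  return out;
}

}  // namespace

// Gate forward pass: X0 = ReLU(FF0 (x) image); per scale l:
// Xint = ReLU(FFint (x) X0) (kernel 3^(l-1), stride 1, same padding),
// pre  = FFout (x) Xint + b  (kernel 3^l, stride 3^l),
// sig  = logistic(pre), gate = ReLU(sig - 0.7).
// [[Rcpp::export(name = ".cpp_gate_forward")]]
List cpp_gate_forward(const arma::cube& image, List gw, bool wantInt) {
  NumericVector ff0 = gw["ff0"];
  double b0 = as<double>(gw["b0"]);
  List scales = gw["scales"];
  int L = scales.size();
  int H = image.n_rows, Wd = image.n_cols;
  mat x0(H, Wd, arma::fill::zeros);
  for (int c = 0; c < (int)image.n_slices; ++c) x0 += ff0[c] * image.slice(c);
  x0 += b0;
  x0.transform([](double v) { return relu(v); });

  List xint(L), sig(L), gate(L);
  int K = 1;
  for (int l = 1; l <= L; ++l) {
    K *= 3;
    List sc = scales[l - 1];
    cube wint = as<cube>(sc["wint"]);
    NumericVector bint = sc["bint"];
    cube wout = as<cube>(sc["wout"]);
    double bout = as<double>(sc["bout"]);
    int nf = wint.n_slices;
    cube xi = conv_same_multi(x0, wint);
    for (int f = 0; f < nf; ++f) xi.slice(f) += bint[f];
    xi.transform([](double v) { return relu(v); });
    if (H % K != 0 || Wd % K != 0)
      stop("image dimensions must be a multiple of 3^scale (pad first)");
    int h = H / K, w = Wd / K;
    mat pre(h, w, arma::fill::zeros);
    for (int f = 0; f < nf; ++f) {
      const mat& kk = wout.slice(f);
      const mat& xf = xi.slice(f);
      for (int j = 0; j < w; ++j)
        for (int i = 0; i < h; ++i) {
          double s = 0.0;
          for (int v = 0; v < K; ++v)
            for (int u = 0; u < K; ++u)
              s += kk(u, v) * xf(K * i + u, K * j + v);
          pre(i, j) += s;
        }
    }
    pre += bout;
    mat sg = 1.0 / (1.0 + arma::exp(-pre));
    mat gt = sg - 0.7;
    gt.transform([](double v) { return relu(v); });
    if (wantInt) xint[l - 1] = xi;
    sig[l - 1] = sg;
    gate[l - 1] = gt;
  }
  return List::create(_["x0"] = x0, _["xint"] = xint, _["sig"] = sig,
                      _["xgate"] = gate);
}

// Forward/backward pass for one gate-training patch at one scale.
// The patch (side = K + k - 1) holds the block plus its context rim; the
// K x K interior Xint positions feed the single gate output.  When the
// shared projection maps background to exactly zero (relu(b0) == 0), only
// the nonzero x0 pixels are iterated — stimuli are sparse, which makes the
// largest scale ~20x cheaper; otherwise a dense fallback runs the same
// arithmetic.
// [[Rcpp::export(name = ".cpp_gate_patch_pass")]]
List cpp_gate_patch_pass(const arma::cube& patch, double y, double wgt,
                         NumericVector ff0, double b0, const arma::cube& wint,
                         NumericVector bint, const arma::cube& wout,
                         double bout, int K, bool backward) {
  int side = patch.n_rows;
  int k = wint.n_rows, nf = wint.n_slices;
  mat x0 = ff0[0] * patch.slice(0) + ff0[1] * patch.slice(1) +
           ff0[2] * patch.slice(2) + b0;
  x0.transform([](double v) { return relu(v); });
  // active pixels
  std::vector<int> nzr, nzc;
  bool dense = relu(b0) > 0.0;
  for (int c = 0; c < side; ++c)
    for (int r = 0; r < side; ++r)
      if (dense || x0(r, c) > 0.0) { nzr.push_back(r); nzc.push_back(c); }
  // channel-contiguous view of the kernel for cache-friendly inner loops
  mat Wt(nf, k * k);
  for (int f = 0; f < nf; ++f)
    for (int v = 0; v < k; ++v)
      for (int u = 0; u < k; ++u) Wt(f, u + k * v) = wint(u, v, f);
  // Xint over the K x K interior positions
  mat xint(nf, K * K);
  for (int f = 0; f < nf; ++f) xint.row(f).fill(bint[f]);
  for (size_t t = 0; t < nzr.size(); ++t) {
    int r = nzr[t], c = nzc[t];
    double v = x0(r, c);
    if (v == 0.0) continue;
    int i0 = std::max(0, r - k + 1), i1 = std::min(K - 1, r);
    int j0 = std::max(0, c - k + 1), j1 = std::min(K - 1, c);
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i) {
        double* xi = xint.colptr(i + K * j);
        const double* wp = Wt.colptr((r - i) + k * (c - j));
        for (int f = 0; f < nf; ++f) xi[f] += wp[f] * v;
      }
  }
  arma::umat mask = xint > 0.0;
  xint.transform([](double v) { return relu(v); });
  double pre = bout;
  for (int j = 0; j < K; ++j)
    for (int i = 0; i < K; ++i)
      for (int f = 0; f < nf; ++f) pre += wout(i, j, f) * xint(f, i + K * j);
  double sig = 1.0 / (1.0 + std::exp(-pre));
  double eps = 1e-12;
  double loss = -wgt * (y * std::log(sig + eps) +
                        (1.0 - y) * std::log(1.0 - sig + eps));
  if (!backward)
    return List::create(_["loss"] = loss, _["sig"] = sig);
  double dpre = wgt * (sig - y);
  arma::cube gwout(K, K, nf);
  for (int f = 0; f < nf; ++f)
    for (int j = 0; j < K; ++j)
      for (int i = 0; i < K; ++i) gwout(i, j, f) = dpre * xint(f, i + K * j);
  mat dxint(nf, K * K);
  for (int j = 0; j < K; ++j)
    for (int i = 0; i < K; ++i) {
      int p = i + K * j;
      for (int f = 0; f < nf; ++f)
        dxint(f, p) = mask(f, p) ? dpre * wout(i, j, f) : 0.0;
    }
  NumericVector gbint(nf);
  for (int f = 0; f < nf; ++f) gbint[f] = arma::accu(dxint.row(f));
  mat Gt(nf, k * k, arma::fill::zeros);
  double gff0r = 0, gff0g = 0, gff0b = 0, gb0 = 0;
  for (size_t t = 0; t < nzr.size(); ++t) {
    int r = nzr[t], c = nzc[t];
    double v = x0(r, c);
    int i0 = std::max(0, r - k + 1), i1 = std::min(K - 1, r);
    int j0 = std::max(0, c - k + 1), j1 = std::min(K - 1, c);
    double dx0 = 0.0;
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i) {
        const double* dp = dxint.colptr(i + K * j);
        int off = (r - i) + k * (c - j);
        double* gp = Gt.colptr(off);
        const double* wp = Wt.colptr(off);
        for (int f = 0; f < nf; ++f) {
          double d = dp[f];
          gp[f] += d * v;
          dx0 += wp[f] * d;
        }
      }
    if (v > 0.0) {  // ReLU-active pixels transmit gradient to the projection
      gff0r += dx0 * patch(r, c, 0);
      gff0g += dx0 * patch(r, c, 1);
      gff0b += dx0 * patch(r, c, 2);
      gb0 += dx0;
    }
  }
  arma::cube gwint(k, k, nf);
  for (int f = 0; f < nf; ++f)
    for (int v = 0; v < k; ++v)
      for (int u = 0; u < k; ++u) gwint(u, v, f) = Gt(f, u + k * v);
  return List::create(
      _["loss"] = loss, _["sig"] = sig, _["gwint"] = gwint,
      _["gbint"] = gbint, _["gwout"] = gwout, _["gbout"] = dpre,
      _["gff0"] = NumericVector::create(gff0r, gff0g, gff0b),
      _["gb0"] = gb0);
}
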