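// Minimal 3D convolutional network with batch normalization, max pooling,
// fully connected layers with dropout, softmax output, Adam optimizer and a
// per-sample weighted cross-entropy objective.  Layout of a volume tensor is
// channel-major over an R column-major grid: index(c,x,y,z) = c*X*Y*Z + x +
// X*y + X*Y*z, so a flattened R array of dim (X,Y,Z) is exactly one channel.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <cstring>
#include <map>
#include <sstream>

using namespace Rcpp;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;

struct Shape3 {
  int C, X, Y, Z;
  R_xlen_t vox() const { return (R_xlen_t)X * Y * Z; }
  R_xlen_t size() const { return (R_xlen_t)C * vox(); }
};

struct NetSpec {
  int nx, ny, nz;
  std::vector<int> conv_channels;
  std::vector<bool> pool_after;   // pool after conv layer l?
  std::vector<int> fc_widths;     // last entry is the number of classes (2)
  double dropout;

  std::vector<Shape3> conv_in;    // input shape of each conv layer
  std::vector<Shape3> conv_out;   // shape after conv (before pooling)
  std::vector<Shape3> stage_out;  // shape after optional pooling
  int flat_dim;

  void trace() {
    Shape3 cur = {1, nx, ny, nz};
    conv_in.clear(); conv_out.clear(); stage_out.clear();
    for (size_t l = 0; l < conv_channels.size(); ++l) {
      conv_in.push_back(cur);
      cur.C = conv_channels[l];
      conv_out.push_back(cur);
      if (pool_after[l]) {
        cur.X /= 2; cur.Y /= 2; cur.Z /= 2;
        if (cur.X < 1 || cur.Y < 1 || cur.Z < 1)
          stop("pooling stage after conv layer %d reduces a spatial extent below 1", (int)l + 1);
      }
      stage_out.push_back(cur);
    }
    flat_dim = (int)cur.size();
  }
};

static NetSpec parse_spec(const List& spec) {
  NetSpec s;
  IntegerVector in_shape = spec["input_shape"];
  s.nx = in_shape[0]; s.ny = in_shape[1]; s.nz = in_shape[2];
  IntegerVector cc = spec["conv_channels"];
  s.conv_channels.assign(cc.begin(), cc.end());
  IntegerVector pa = spec["pool_after"];
  s.pool_after.assign(s.conv_channels.size(), false);
  for (int i = 0; i < pa.size(); ++i) {
    int l = pa[i];
    if (l < 1 || l > (int)s.conv_channels.size()) stop("pool_after index out of range");
    s.pool_after[l - 1] = true;
  }
  IntegerVector fw = spec["fc_widths"];
  s.fc_widths.assign(fw.begin(), fw.end());
  if (s.fc_widths.back() != 2) stop("final fully connected width must be 2");
  s.dropout = as<double>(spec["dropout"]);
  s.trace();
  return s;
}

// One named parameter tensor plus its gradient and Adam moments.
struct PTensor {
  std::string name;
  std::vector<double> v, g, m, a;
  bool trainable;
  PTensor(std::string nm, size_t n, bool tr) : name(nm), v(n, 0.0), trainable(tr) {
    if (tr) { g.assign(n, 0.0); m.assign(n, 0.0); a.assign(n, 0.0); }
  }
};

struct Params {
  std::vector<PTensor> t;
  std::map<std::string, int> idx;
  PTensor& get(const std::string& nm) {
    std::map<std::string, int>::iterator it = idx.find(nm);
    if (it == idx.end()) stop("missing parameter tensor '%s'", nm.c_str());
    return t[it->second];
  }
  const PTensor& cget(const std::string& nm) const {
    std::map<std::string, int>::const_iterator it = idx.find(nm);
    if (it == idx.end()) stop("missing parameter tensor '%s'", nm.c_str());
    return t[it->second];
  }
  void add(const std::string& nm, size_t n, bool tr) {
    idx[nm] = (int)t.size();
    t.push_back(PTensor(nm, n, tr));
  }
};

static std::string tname(const char* kind, size_t l, const char* what) {
  std::ostringstream os; os << kind << (l + 1) << "_" << what; return os.str();
}

static Params alloc_params(const NetSpec& s) {
  Params p;
  for (size_t l = 0; l < s.conv_channels.size(); ++l) {
    int cin = s.conv_in[l].C, cout = s.conv_out[l].C;
    p.add(tname("conv", l, "W"), (size_t)cout * cin * 27, true);
    p.add(tname("conv", l, "b"), cout, true);
    p.add(tname("conv", l, "gamma"), cout, true);
    p.add(tname("conv", l, "beta"), cout, true);
    p.add(tname("conv", l, "rmean"), cout, false);
    p.add(tname("conv", l, "rvar"), cout, false);
  }
  int prev = s.flat_dim;
  for (size_t l = 0; l < s.fc_widths.size(); ++l) {
    p.add(tname("fc", l, "W"), (size_t)s.fc_widths[l] * prev, true);
    p.add(tname("fc", l, "b"), s.fc_widths[l], true);
    prev = s.fc_widths[l];
  }
  return p;
}

static Params params_from_list(const NetSpec& s, const List& plist) {
  Params p = alloc_params(s);
  CharacterVector nms = plist.names();
  for (int i = 0; i < plist.size(); ++i) {
    std::string nm = as<std::string>(nms[i]);
    NumericVector v = plist[i];
    PTensor& pt = p.get(nm);
    if ((size_t)v.size() != pt.v.size())
      stop("parameter '%s' has length %d, expected %d", nm.c_str(), (int)v.size(), (int)pt.v.size());
    std::copy(v.begin(), v.end(), pt.v.begin());
  }
  return p;
}

static List params_to_list(const Params& p) {
  List out(p.t.size());
  CharacterVector nms(p.t.size());
  for (size_t i = 0; i < p.t.size(); ++i) {
    nms[i] = p.t[i].name;
    out[i] = NumericVector(p.t[i].v.begin(), p.t[i].v.end());
  }
  out.names() = nms;
  return out;
}

// ---- layer primitives -------------------------------------------------------

// Same-padded 3x3x3 convolution as 27 offset-shifted accumulation passes:
// out(p) += w(d) * in(p + d) over the range of p where p + d stays in
// bounds, which keeps the inner x loop branch-free and contiguous.
static void conv_fwd(const double* in, const Shape3& si, const double* W,
                     const double* b, int cout, double* out) {
  const int X = si.X, Y = si.Y, Z = si.Z, cin = si.C;
  const R_xlen_t XYZ = si.vox();
  for (int co = 0; co < cout; ++co) {
    double* op = out + (R_xlen_t)co * XYZ;
    for (R_xlen_t i = 0; i < XYZ; ++i) op[i] = b[co];
    for (int ci = 0; ci < cin; ++ci) {
      const double* wk = W + ((R_xlen_t)co * cin + ci) * 27;
      const double* ip = in + (R_xlen_t)ci * XYZ;
      int ki = 0;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx, ++ki) {
            const double w = wk[ki];
            if (w == 0.0) continue;
            const int x0 = dx < 0 ? -dx : 0, x1 = dx > 0 ? X - dx : X;
            const int y0 = dy < 0 ? -dy : 0, y1 = dy > 0 ? Y - dy : Y;
            const int z0 = dz < 0 ? -dz : 0, z1 = dz > 0 ? Z - dz : Z;
            const R_xlen_t shift = dx + (R_xlen_t)X * dy + (R_xlen_t)X * Y * dz;
            for (int z = z0; z < z1; ++z)
              for (int y = y0; y < y1; ++y) {
                double* orow = op + (R_xlen_t)X * y + (R_xlen_t)X * Y * z;
                const double* irow = ip + shift + (R_xlen_t)X * y + (R_xlen_t)X * Y * z;
                for (int x = x0; x < x1; ++x) orow[x] += w * irow[x];
              }
          }
    }
  }
}

static void conv_bwd(const double* in, const Shape3& si, const double* W,
                     int cout, const double* dout, double* din, double* dW, double* db) {
  const int X = si.X, Y = si.Y, Z = si.Z, cin = si.C;
  const R_xlen_t XYZ = si.vox();
  std::memset(din, 0, sizeof(double) * si.size());
  for (int co = 0; co < cout; ++co) {
    const double* dop = dout + (R_xlen_t)co * XYZ;
    double dbacc = 0.0;
    for (R_xlen_t i = 0; i < XYZ; ++i) dbacc += dop[i];
    db[co] += dbacc;
    for (int ci = 0; ci < cin; ++ci) {
      const double* wk = W + ((R_xlen_t)co * cin + ci) * 27;
      double* dwk = dW + ((R_xlen_t)co * cin + ci) * 27;
      const double* ip = in + (R_xlen_t)ci * XYZ;
      double* dip = din + (R_xlen_t)ci * XYZ;
      int ki = 0;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx, ++ki) {
            const double w = wk[ki];
            const int x0 = dx < 0 ? -dx : 0, x1 = dx > 0 ? X - dx : X;
            const int y0 = dy < 0 ? -dy : 0, y1 = dy > 0 ? Y - dy : Y;
            const int z0 = dz < 0 ? -dz : 0, z1 = dz > 0 ? Z - dz : Z;
            const R_xlen_t shift = dx + (R_xlen_t)X * dy + (R_xlen_t)X * Y * dz;
            double wacc = 0.0;
            for (int z = z0; z < z1; ++z)
              for (int y = y0; y < y1; ++y) {
                const R_xlen_t row = (R_xlen_t)X * y + (R_xlen_t)X * Y * z;
                const double* grow = dop + row;
                const double* irow = ip + shift + row;
                double* drow = dip + shift + row;
                for (int x = x0; x < x1; ++x) {
                  wacc += grow[x] * irow[x];
                  drow[x] += grow[x] * w;
                }
              }
            dwk[ki] += wacc;
          }
    }
  }
}

static void pool_fwd(const double* in, const Shape3& si, const Shape3& so,
                     double* out, int* arg) {
  const R_xlen_t XYZi = si.vox(), XYZo = so.vox();
  for (int c = 0; c < si.C; ++c) {
    const double* ip = in + (R_xlen_t)c * XYZi;
    double* op = out + (R_xlen_t)c * XYZo;
    int* ap = arg + (R_xlen_t)c * XYZo;
    for (int z = 0; z < so.Z; ++z)
      for (int y = 0; y < so.Y; ++y)
        for (int x = 0; x < so.X; ++x) {
          double best = -HUGE_VAL; int besti = -1;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                R_xlen_t ii = (2 * x + dx) + (R_xlen_t)si.X * (2 * y + dy) +
                              (R_xlen_t)si.X * si.Y * (2 * z + dz);
                if (ip[ii] > best) { best = ip[ii]; besti = (int)ii; }
              }
          R_xlen_t oo = x + (R_xlen_t)so.X * y + (R_xlen_t)so.X * so.Y * z;
          op[oo] = best; ap[oo] = besti;
        }
  }
}

static void pool_bwd(const double* dout, const Shape3& si, const Shape3& so,
                     const int* arg, double* din) {
  std::memset(din, 0, sizeof(double) * si.size());
  const R_xlen_t XYZi = si.vox(), XYZo = so.vox();
  for (int c = 0; c < si.C; ++c) {
    const double* dop = dout + (R_xlen_t)c * XYZo;
    const int* ap = arg + (R_xlen_t)c * XYZo;
    double* dip = din + (R_xlen_t)c * XYZi;
    for (R_xlen_t i = 0; i < XYZo; ++i) dip[ap[i]] += dop[i];
  }
}

static void fc_fwd(const double* in, int nin, const double* W, const double* b,
                   int nout, double* out) {
  for (int o = 0; o < nout; ++o) {
    const double* wr = W + (R_xlen_t)o * nin;
    double sacc = b[o];
    for (int i = 0; i < nin; ++i) sacc += wr[i] * in[i];
    out[o] = sacc;
  }
}

static void fc_bwd(const double* in, int nin, const double* W, int nout,
                   const double* dout, double* din, double* dW, double* db) {
  std::memset(din, 0, sizeof(double) * nin);
  for (int o = 0; o < nout; ++o) {
    double gv = dout[o];
    db[o] += gv;
    const double* wr = W + (R_xlen_t)o * nin;
    double* dwr = dW + (R_xlen_t)o * nin;
    for (int i = 0; i < nin; ++i) {
      dwr[i] += gv * in[i];
      din[i] += gv * wr[i];
    }
  }
}

// ---- forward cache for one mini-batch --------------------------------------

typedef std::vector<std::vector<double> > BatchBuf;  // [sample][tensor]

struct Cache {
  BatchBuf input;                   // raw flattened volumes
  std::vector<BatchBuf> conv_z;     // conv output, pre-BN
  std::vector<BatchBuf> bn_xhat;    // normalized activations
  std::vector<BatchBuf> relu_out;   // post-ReLU (pool input)
  std::vector<BatchBuf> stage_out;  // after optional pooling
  std::vector<std::vector<std::vector<int> > > pool_arg;
  std::vector<std::vector<double> > bn_mean, bn_var;  // per conv layer, per channel
  std::vector<BatchBuf> fc_in;      // input of each fc layer
  std::vector<BatchBuf> fc_z;       // fc pre-activation
  std::vector<BatchBuf> drop_mask;  // dropout mask per hidden fc layer
  BatchBuf probs;
};

// Forward a batch; inputs point at flattened volumes (length nx*ny*nz each).
static void forward_batch(const NetSpec& s, Params& p,
                          const std::vector<const double*>& xin,
                          bool training, std::mt19937_64& rng, Cache& C) {
  const int B = (int)xin.size();
  const size_t L = s.conv_channels.size();
  C.input.assign(B, std::vector<double>());
  C.conv_z.assign(L, BatchBuf(B));
  C.bn_xhat.assign(L, BatchBuf(B));
  C.relu_out.assign(L, BatchBuf(B));
  C.stage_out.assign(L, BatchBuf(B));
  C.pool_arg.assign(L, std::vector<std::vector<int> >(B));
  C.bn_mean.assign(L, std::vector<double>());
  C.bn_var.assign(L, std::vector<double>());

  for (int b = 0; b < B; ++b)
    C.input[b].assign(xin[b], xin[b] + s.conv_in[0].size());

  for (size_t l = 0; l < L; ++l) {
    const Shape3 si = s.conv_in[l], so = s.conv_out[l], sp = s.stage_out[l];
    const double* W = p.get(tname("conv", l, "W")).v.data();
    const double* bb = p.get(tname("conv", l, "b")).v.data();
    const double* gamma = p.get(tname("conv", l, "gamma")).v.data();
    const double* beta = p.get(tname("conv", l, "beta")).v.data();
    PTensor& rmean = p.get(tname("conv", l, "rmean"));
    PTensor& rvar = p.get(tname("conv", l, "rvar"));

    for (int b = 0; b < B; ++b) {
      const double* src = (l == 0) ? C.input[b].data() : C.stage_out[l - 1][b].data();
      C.conv_z[l][b].assign(so.size(), 0.0);
      conv_fwd(src, si, W, bb, so.C, C.conv_z[l][b].data());
    }

    // batch normalization per channel over batch and space
    const R_xlen_t XYZ = so.vox();
    std::vector<double> mean(so.C), var(so.C);
    if (training) {
      for (int c = 0; c < so.C; ++c) {
        double sm = 0.0;
        for (int b = 0; b < B; ++b) {
          const double* zp = C.conv_z[l][b].data() + (R_xlen_t)c * XYZ;
          for (R_xlen_t i = 0; i < XYZ; ++i) sm += zp[i];
        }
        double mu = sm / ((double)B * XYZ);
        double sv = 0.0;
        for (int b = 0; b < B; ++b) {
          const double* zp = C.conv_z[l][b].data() + (R_xlen_t)c * XYZ;
          for (R_xlen_t i = 0; i < XYZ; ++i) { double d = zp[i] - mu; sv += d * d; }
        }
        mean[c] = mu; var[c] = sv / ((double)B * XYZ);
        rmean.v[c] = (1.0 - BN_MOMENTUM) * rmean.v[c] + BN_MOMENTUM * mean[c];
        rvar.v[c] = (1.0 - BN_MOMENTUM) * rvar.v[c] + BN_MOMENTUM * var[c];
      }
    } else {
      for (int c = 0; c < so.C; ++c) { mean[c] = rmean.v[c]; var[c] = rvar.v[c]; }
    }
    C.bn_mean[l] = mean; C.bn_var[l] = var;

    for (int b = 0; b < B; ++b) {
      C.bn_xhat[l][b].assign(so.size(), 0.0);
      C.relu_out[l][b].assign(so.size(), 0.0);
      for (int c = 0; c < so.C; ++c) {
        double inv = 1.0 / std::sqrt(var[c] + BN_EPS);
        const double* zp = C.conv_z[l][b].data() + (R_xlen_t)c * XYZ;
        double* xh = C.bn_xhat[l][b].data() + (R_xlen_t)c * XYZ;
        double* ro = C.relu_out[l][b].data() + (R_xlen_t)c * XYZ;
        for (R_xlen_t i = 0; i < XYZ; ++i) {
          double xhv = (zp[i] - mean[c]) * inv;
          xh[i] = xhv;
          double av = gamma[c] * xhv + beta[c];
          ro[i] = av > 0.0 ? av : 0.0;
        }
      }
      if (s.pool_after[l]) {
        C.stage_out[l][b].assign(sp.size(), 0.0);
        C.pool_arg[l][b].assign(sp.size(), 0);
        pool_fwd(C.relu_out[l][b].data(), so, sp, C.stage_out[l][b].data(),
                 C.pool_arg[l][b].data());
      } else {
        C.stage_out[l][b] = C.relu_out[l][b];
      }
    }
  }

  // fully connected stack
  const size_t F = s.fc_widths.size();
  C.fc_in.assign(F, BatchBuf(B));
  C.fc_z.assign(F, BatchBuf(B));
  C.drop_mask.assign(F, BatchBuf(B));
  C.probs.assign(B, std::vector<double>(2, 0.0));
  double keep = 1.0 - s.dropout;
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  for (int b = 0; b < B; ++b) {
    std::vector<double> h = L > 0 ? C.stage_out[L - 1][b] : C.input[b];
    for (size_t l = 0; l < F; ++l) {
      C.fc_in[l][b] = h;
      int nin = (int)h.size(), nout = s.fc_widths[l];
      const double* W = p.get(tname("fc", l, "W")).v.data();
      const double* bb = p.get(tname("fc", l, "b")).v.data();
      std::vector<double> z(nout);
      fc_fwd(h.data(), nin, W, bb, nout, z.data());
      C.fc_z[l][b] = z;
      if (l + 1 < F) {
        for (int i = 0; i < nout; ++i) z[i] = z[i] > 0.0 ? z[i] : 0.0;
        std::vector<double> mask(nout, 1.0);
        if (training && s.dropout > 0.0) {
          for (int i = 0; i < nout; ++i)
            mask[i] = unif(rng) < keep ? 1.0 / keep : 0.0;
          for (int i = 0; i < nout; ++i) z[i] *= mask[i];
        }
        C.drop_mask[l][b] = mask;
      }
      h = z;
    }
    double mx = std::max(h[0], h[1]);
    double e0 = std::exp(h[0] - mx), e1 = std::exp(h[1] - mx);
    C.probs[b][0] = e0 / (e0 + e1);
    C.probs[b][1] = e1 / (e0 + e1);
  }
}

// Backward a batch given per-sample gradients w.r.t. the logits.
static void backward_batch(const NetSpec& s, Params& p, const Cache& C,
                           const std::vector<std::vector<double> >& dlogits) {
  const int B = (int)dlogits.size();
  const size_t L = s.conv_channels.size();
  const size_t F = s.fc_widths.size();

  BatchBuf dcur(B);
  for (int b = 0; b < B; ++b) dcur[b] = dlogits[b];

  for (size_t li = F; li-- > 0;) {
    int nout = s.fc_widths[li];
    PTensor& W = p.get(tname("fc", li, "W"));
    PTensor& bb = p.get(tname("fc", li, "b"));
    int nin = (int)(W.v.size() / nout);
    for (int b = 0; b < B; ++b) {
      std::vector<double> dz = dcur[b];
      if (li + 1 < F) {  // this layer is followed by ReLU then dropout
        const std::vector<double>& mask = C.drop_mask[li][b];
        const std::vector<double>& z = C.fc_z[li][b];
        for (int i = 0; i < nout; ++i) {
          if (!mask.empty()) dz[i] *= mask[i];
          if (z[i] <= 0.0) dz[i] = 0.0;
        }
      }
      std::vector<double> din(nin, 0.0);
      fc_bwd(C.fc_in[li][b].data(), nin, W.v.data(), nout, dz.data(),
             din.data(), W.g.data(), bb.g.data());
      dcur[b] = din;
    }
  }

  for (size_t l = L; l-- > 0;) {
    const Shape3 si = s.conv_in[l], so = s.conv_out[l], sp = s.stage_out[l];
    PTensor& W = p.get(tname("conv", l, "W"));
    PTensor& bb = p.get(tname("conv", l, "b"));
    PTensor& gamma = p.get(tname("conv", l, "gamma"));
    PTensor& beta = p.get(tname("conv", l, "beta"));
    const R_xlen_t XYZ = so.vox();

    // pooling backward (if any) then ReLU mask, into d(BN output)
    BatchBuf dbn(B);
    for (int b = 0; b < B; ++b) {
      std::vector<double> drelu;
      if (s.pool_after[l]) {
        drelu.assign(so.size(), 0.0);
        pool_bwd(dcur[b].data(), so, sp, C.pool_arg[l][b].data(), drelu.data());
      } else {
        drelu = dcur[b];
      }
      const std::vector<double>& ro = C.relu_out[l][b];
      for (R_xlen_t i = 0; i < (R_xlen_t)so.size(); ++i)
        if (ro[i] <= 0.0) drelu[i] = 0.0;
      dbn[b] = drelu;
    }

    // batch-norm backward per channel
    BatchBuf dz(B);
    for (int b = 0; b < B; ++b) dz[b].assign(so.size(), 0.0);
    const double M = (double)B * XYZ;
    for (int c = 0; c < so.C; ++c) {
      double inv = 1.0 / std::sqrt(C.bn_var[l][c] + BN_EPS);
      double sum_dxh = 0.0, sum_dxh_xh = 0.0, dg = 0.0, db_ = 0.0;
      for (int b = 0; b < B; ++b) {
        const double* dp = dbn[b].data() + (R_xlen_t)c * XYZ;
        const double* xh = C.bn_xhat[l][b].data() + (R_xlen_t)c * XYZ;
        for (R_xlen_t i = 0; i < XYZ; ++i) {
          double dxh = dp[i] * gamma.v[c];
          sum_dxh += dxh;
          sum_dxh_xh += dxh * xh[i];
          dg += dp[i] * xh[i];
          db_ += dp[i];
        }
      }
      gamma.g[c] += dg; beta.g[c] += db_;
      for (int b = 0; b < B; ++b) {
        const double* dp = dbn[b].data() + (R_xlen_t)c * XYZ;
        const double* xh = C.bn_xhat[l][b].data() + (R_xlen_t)c * XYZ;
        double* dzp = dz[b].data() + (R_xlen_t)c * XYZ;
        for (R_xlen_t i = 0; i < XYZ; ++i) {
          double dxh = dp[i] * gamma.v[c];
          dzp[i] = inv / M * (M * dxh - sum_dxh - xh[i] * sum_dxh_xh);
        }
      }
    }

    // conv backward
    for (int b = 0; b < B; ++b) {
      std::vector<double> din(si.size(), 0.0);
      const double* src = (l == 0) ? C.input[b].data() : C.stage_out[l - 1][b].data();
      conv_bwd(src, si, W.v.data(), so.C, dz[b].data(), din.data(),
               W.g.data(), bb.g.data());
      dcur[b] = din;
    }
  }
}

static void adam_step(Params& p, double lr, double wd, long step) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  double bc1 = 1.0 - std::pow(b1, (double)step);
  double bc2 = 1.0 - std::pow(b2, (double)step);
  for (size_t ti = 0; ti < p.t.size(); ++ti) {
    PTensor& pt = p.t[ti];
    if (!pt.trainable) continue;
    for (size_t i = 0; i < pt.v.size(); ++i) {
      double g = pt.g[i] + wd * pt.v[i];
      pt.m[i] = b1 * pt.m[i] + (1.0 - b1) * g;
      pt.a[i] = b2 * pt.a[i] + (1.0 - b2) * g * g;
      pt.v[i] -= lr * (pt.m[i] / bc1) / (std::sqrt(pt.a[i] / bc2) + eps);
      pt.g[i] = 0.0;
    }
  }
}

// ---- exported interface -----------------------------------------------------

// [[Rcpp::export]]
List cpp_cnn_init(List spec, int seed) {
  NetSpec s = parse_spec(spec);
  Params p = alloc_params(s);
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  for (size_t l = 0; l < s.conv_channels.size(); ++l) {
    PTensor& W = p.get(tname("conv", l, "W"));
    double sd = std::sqrt(2.0 / (s.conv_in[l].C * 27.0));
    for (size_t i = 0; i < W.v.size(); ++i) W.v[i] = sd * gauss(rng);
    PTensor& gm = p.get(tname("conv", l, "gamma"));
    std::fill(gm.v.begin(), gm.v.end(), 1.0);
    PTensor& rv = p.get(tname("conv", l, "rvar"));
    std::fill(rv.v.begin(), rv.v.end(), 1.0);
  }
  int prev = s.flat_dim;
  for (size_t l = 0; l < s.fc_widths.size(); ++l) {
    PTensor& W = p.get(tname("fc", l, "W"));
    double sd = std::sqrt(2.0 / (double)prev);
    for (size_t i = 0; i < W.v.size(); ++i) W.v[i] = sd * gauss(rng);
    prev = s.fc_widths[l];
  }
  return params_to_list(p);
}

// [[Rcpp::export]]
NumericMatrix cpp_cnn_predict(List spec, List plist, NumericMatrix X) {
  NetSpec s = parse_spec(spec);
  Params p = params_from_list(s, plist);
  int n = X.nrow();
  if ((R_xlen_t)X.ncol() != (R_xlen_t)s.nx * s.ny * s.nz)
    stop("volume length %d does not match network input shape", X.ncol());
  NumericMatrix out(n, 2);
  std::mt19937_64 rng(0);
  Cache C;
  std::vector<double> row((size_t)X.ncol());
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < X.ncol(); ++j) row[j] = X(i, j);
    std::vector<const double*> xin(1, row.data());
    forward_batch(s, p, xin, false, rng, C);
    out(i, 0) = C.probs[0][0];
    out(i, 1) = C.probs[0][1];
  }
  return out;
}

// Train with the per-sample weighted cross-entropy: each sample contributes
// -(w_i / n_total) * [y_i log p1 + (1 - y_i) log p0]; epoch loss is the sum
// over the whole training pass.
// [[Rcpp::export]]
List cpp_cnn_train(List spec, List plist, NumericMatrix X, IntegerVector y01,
                   NumericVector w, int n_total, int epochs, int batch_size,
                   double lr, double weight_decay, int seed) {
  NetSpec s = parse_spec(spec);
  Params p = params_from_list(s, plist);
  const int n = X.nrow();
  if (y01.size() != n || w.size() != n) stop("labels/weights length mismatch");
  if ((R_xlen_t)X.ncol() != (R_xlen_t)s.nx * s.ny * s.nz)
    stop("volume length does not match network input shape");

  std::mt19937_64 rng((uint64_t)seed);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  // copy rows once into contiguous buffers
  std::vector<std::vector<double> > rows(n, std::vector<double>((size_t)X.ncol()));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < X.ncol(); ++j) rows[i][j] = X(i, j);

  NumericVector loss_hist(epochs);
  Cache C;
  long step = 0;
  const double pclamp = 1e-12;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double epoch_loss = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      int B = std::min(batch_size, n - start);
      std::vector<const double*> xin(B);
      for (int b = 0; b < B; ++b) xin[b] = rows[order[start + b]].data();
      forward_batch(s, p, xin, true, rng, C);

      std::vector<std::vector<double> > dlogits(B, std::vector<double>(2, 0.0));
      for (int b = 0; b < B; ++b) {
        int i = order[start + b];
        int t = y01[i];
        double scale = w[i] / (double)n_total;
        double p1 = std::min(std::max(C.probs[b][1], pclamp), 1.0 - pclamp);
        epoch_loss -= scale * (t * std::log(p1) + (1 - t) * std::log(1.0 - p1));
        dlogits[b][0] = scale * (C.probs[b][0] - (t == 0 ? 1.0 : 0.0));
        dlogits[b][1] = scale * (C.probs[b][1] - (t == 1 ? 1.0 : 0.0));
      }
      backward_batch(s, p, C, dlogits);
      adam_step(p, lr, weight_decay, ++step);
    }
    if (!std::isfinite(epoch_loss))
      stop("non-finite training loss at epoch %d (lr=%g); training diverged", ep + 1, lr);
    loss_hist[ep] = epoch_loss;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = params_to_list(p), _["loss"] = loss_hist);
}
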