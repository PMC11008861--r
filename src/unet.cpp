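// 1-D encoder-decoder convolutional network (U-Net) for spectral recovery.
// Single precision, im2col + GEMM; all randomness (init, batch order) is
// supplied by the caller so training is a pure function of its arguments.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

namespace {

struct Arch {
  int L, depth, base, kernel;
};

// Channel bookkeeping -------------------------------------------------------
// encoder conv i (i = 0..depth-1): Cin = (i==0 ? 1 : base*2^(i-1)), Cout = base*2^i
// bottleneck:                     Cin = base*2^(depth-1), Cout = base*2^depth
// decoder conv i (depth-1..0):    Cin = 3*base*2^i, Cout = base*2^i
// output conv:                    Cin = base, Cout = 1, kernel 1

struct ConvSpec {
  int cin, cout, k;
};

std::vector<ConvSpec> conv_specs(const Arch& a) {
  std::vector<ConvSpec> s;
  for (int i = 0; i < a.depth; ++i)
    s.push_back({i == 0 ? 1 : a.base << (i - 1), a.base << i, a.kernel});
  s.push_back({a.base << (a.depth - 1), a.base << a.depth, a.kernel});
  for (int i = a.depth - 1; i >= 0; --i)
    s.push_back({3 * (a.base << i), a.base << i, a.kernel});
  s.push_back({a.base, 1, 1});
  return s;
}

struct Conv {
  ConvSpec spec;
  fmat W;   // cout x cin*k
  fvec b;
  fmat cols;  // cached im2col of last forward input
  fmat dW;
  fvec db;
  // adam state
  fmat mW, vW;
  fvec mb, vb;
};

fmat im2col(const fmat& A, int cin, int k, int L, int B) {
  const int pad = k / 2;
  fmat out(cin * k, (size_t)L * B, fill::zeros);
  for (int t = 0; t < k; ++t) {
    const int off = t - pad;
    const int j0 = std::max(0, -off), j1 = std::min(L, L - off);  // dest cols [j0, j1)
    if (j1 <= j0) continue;
    for (int s = 0; s < B; ++s) {
      out.submat(t * cin, (size_t)s * L + j0, (t + 1) * cin - 1, (size_t)s * L + j1 - 1) =
          A.cols((size_t)s * L + j0 + off, (size_t)s * L + j1 - 1 + off);
    }
  }
  return out;
}

fmat col2im(const fmat& C, int cin, int k, int L, int B) {
  const int pad = k / 2;
  fmat out(cin, (size_t)L * B, fill::zeros);
  for (int t = 0; t < k; ++t) {
    const int off = t - pad;
    const int j0 = std::max(0, -off), j1 = std::min(L, L - off);
    if (j1 <= j0) continue;
    for (int s = 0; s < B; ++s) {
      out.cols((size_t)s * L + j0 + off, (size_t)s * L + j1 - 1 + off) +=
          C.submat(t * cin, (size_t)s * L + j0, (t + 1) * cin - 1, (size_t)s * L + j1 - 1);
    }
  }
  return out;
}

fmat conv_forward(Conv& c, const fmat& A, int L, int B, bool cache) {
  fmat cols = im2col(A, c.spec.cin, c.spec.k, L, B);
  fmat Z = c.W * cols;
  Z.each_col() += c.b;
  if (cache) c.cols = std::move(cols);
  return Z;
}

fmat conv_backward(Conv& c, const fmat& dZ, int L, int B) {
  c.dW = dZ * c.cols.t();
  c.db = sum(dZ, 1);
  return col2im(c.W.t() * dZ, c.spec.cin, c.spec.k, L, B);
}

uvec even_idx(size_t n) { return regspace<uvec>(0, 2, 2 * n - 2); }
uvec odd_idx(size_t n) { return regspace<uvec>(1, 2, 2 * n - 1); }

// halve resolution by averaging pixel pairs (per-sample blocks have even
// length at every level, so global even/odd columns respect sample bounds)
fmat avgpool(const fmat& A) {
  const size_t n = A.n_cols / 2;
  return 0.5f * (A.cols(even_idx(n)) + A.cols(odd_idx(n)));
}

fmat avgpool_backward(const fmat& dP) {
  fmat dA(dP.n_rows, dP.n_cols * 2);
  dA.cols(even_idx(dP.n_cols)) = 0.5f * dP;
  dA.cols(odd_idx(dP.n_cols)) = 0.5f * dP;
  return dA;
}

fmat upsample(const fmat& A) {
  fmat U(A.n_rows, A.n_cols * 2);
  U.cols(even_idx(A.n_cols)) = A;
  U.cols(odd_idx(A.n_cols)) = A;
  return U;
}

fmat upsample_backward(const fmat& dU) {
  const size_t n = dU.n_cols / 2;
  return dU.cols(even_idx(n)) + dU.cols(odd_idx(n));
}

struct Net {
  Arch arch;
  std::vector<Conv> convs;  // enc(depth), bottleneck, dec(depth), out

  size_t n_params() const {
    size_t n = 0;
    for (const auto& c : convs) n += (size_t)c.spec.cout * c.spec.cin * c.spec.k + c.spec.cout;
    return n;
  }

  void load(const vec& p) {
    size_t at = 0;
    for (auto& c : convs) {
      const size_t nw = (size_t)c.spec.cout * c.spec.cin * c.spec.k;
      c.W = conv_to<fmat>::from(reshape(p.subvec(at, at + nw - 1), c.spec.cout, c.spec.cin * c.spec.k));
      at += nw;
      c.b = conv_to<fvec>::from(p.subvec(at, at + c.spec.cout - 1));
      at += c.spec.cout;
      c.mW.zeros(size(c.W)); c.vW.zeros(size(c.W));
      c.mb.zeros(c.spec.cout); c.vb.zeros(c.spec.cout);
    }
  }

  vec dump() const {
    vec p(n_params());
    size_t at = 0;
    for (const auto& c : convs) {
      const size_t nw = c.W.n_elem;
      p.subvec(at, at + nw - 1) = conv_to<vec>::from(vectorise(c.W));
      at += nw;
      p.subvec(at, at + c.b.n_elem - 1) = conv_to<vec>::from(c.b);
      at += c.b.n_elem;
    }
    return p;
  }

  // caches for backward
  std::vector<fmat> enc_act;    // post-ReLU encoder activations (skip inputs)
  std::vector<umat> enc_mask, dec_mask;
  umat bott_mask;

  fmat forward(const fmat& X0, int B, bool cache) {
    const int d = arch.depth;
    enc_act.assign(d, fmat());
    enc_mask.assign(d, umat());
    dec_mask.assign(d, umat());
    fmat A = X0;  // 1 x L*B
    int L = arch.L;
    for (int i = 0; i < d; ++i) {
      fmat Z = conv_forward(convs[i], A, L, B, cache);
      umat m = Z > 0;
      Z.elem(find(m == 0)).zeros();
      if (cache) enc_mask[i] = std::move(m);
      enc_act[i] = Z;
      A = avgpool(Z);
      L /= 2;
    }
    fmat Z = conv_forward(convs[d], A, L, B, cache);
    umat m = Z > 0;
    Z.elem(find(m == 0)).zeros();
    if (cache) bott_mask = std::move(m);
    A = std::move(Z);
    for (int i = d - 1; i >= 0; --i) {
      A = upsample(A);
      L *= 2;
      A = join_cols(enc_act[i], A);
      fmat Zi = conv_forward(convs[d + 1 + (d - 1 - i)], A, L, B, cache);
      umat mi = Zi > 0;
      Zi.elem(find(mi == 0)).zeros();
      if (cache) dec_mask[i] = std::move(mi);
      A = std::move(Zi);
    }
    return conv_forward(convs[2 * d + 1], A, L, B, cache);  // linear output, 1 x L*B
  }

  void backward(const fmat& dOut, int B) {
    const int d = arch.depth;
    int L = arch.L;
    fmat dA = conv_backward(convs[2 * d + 1], dOut, L, B);
    std::vector<fmat> skip_grad(d);
    for (int i = 0; i < d; ++i) {
      dA.elem(find(dec_mask[i] == 0)).zeros();
      fmat dJoin = conv_backward(convs[d + 1 + (d - 1 - i)], dA, L, B);
      const int cs = arch.base << i;
      skip_grad[i] = dJoin.rows(0, cs - 1);
      dA = upsample_backward(dJoin.rows(cs, dJoin.n_rows - 1));
      L /= 2;
    }
    dA.elem(find(bott_mask == 0)).zeros();
    dA = conv_backward(convs[d], dA, L, B);
    for (int i = d - 1; i >= 0; --i) {
      L *= 2;
      fmat dZ = avgpool_backward(dA) + skip_grad[i];
      dZ.elem(find(enc_mask[i] == 0)).zeros();
      dA = conv_backward(convs[i], dZ, L, B);
    }
  }

  void adam_step(float lr, float b1, float b2, float eps, int t) {
    const float c1 = 1.0f - std::pow(b1, (float)t);
    const float c2 = 1.0f - std::pow(b2, (float)t);
    for (auto& c : convs) {
      c.mW = b1 * c.mW + (1 - b1) * c.dW;
      c.vW = b2 * c.vW + (1 - b2) * square(c.dW);
      c.W -= lr * (c.mW / c1) / (sqrt(c.vW / c2) + eps);
      c.mb = b1 * c.mb + (1 - b1) * c.db;
      c.vb = b2 * c.vb + (1 - b2) * square(c.db);
      c.b -= lr * (c.mb / c1) / (sqrt(c.vb / c2) + eps);
    }
  }
};

Net make_net(const Arch& a) {
  Net net;
  net.arch = a;
  for (const auto& s : conv_specs(a)) {
    Conv c;
    c.spec = s;
    net.convs.push_back(std::move(c));
  }
  return net;
}

Arch arch_from(const Rcpp::IntegerVector& v) {
  Arch a{v[0], v[1], v[2], v[3]};
  if (a.L % (1 << a.depth) != 0) Rcpp::stop("input length not divisible by 2^depth");
  return a;
}

// rows of an R matrix (samples) laid side by side as 1 x L*B
fmat batch_matrix(const mat& X, const uvec& idx) {
  fmat out(1, (size_t)X.n_cols * idx.n_elem);
  for (size_t s = 0; s < idx.n_elem; ++s)
    out.cols((size_t)s * X.n_cols, (size_t)(s + 1) * X.n_cols - 1) =
        conv_to<frowvec>::from(X.row(idx[s]));
  return out;
}

}  // namespace

// [[Rcpp::export]]
int unet_param_count_cpp(Rcpp::IntegerVector arch) {
  return (int)make_net(arch_from(arch)).n_params();
}

// [[Rcpp::export]]
Rcpp::List unet_train_cpp(arma::mat X, arma::mat Y, arma::vec params0,
                          Rcpp::IntegerVector arch, int epochs, int batch_size,
                          double lr, arma::umat perm_1based,
                          double beta1 = 0.9, double beta2 = 0.999,
                          double eps = 1e-8) {
  Arch a = arch_from(arch);
  if ((int)X.n_cols != a.L || (int)Y.n_cols != a.L || X.n_rows != Y.n_rows)
    Rcpp::stop("pair length mismatch with configured input length");
  Net net = make_net(a);
  if (params0.n_elem != net.n_params()) Rcpp::stop("parameter vector has wrong length");
  net.load(params0);
  const int N = X.n_rows;
  vec history(epochs, fill::zeros);
  int t = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0.0;
    int n_batch = 0;
    for (int start = 0; start < N; start += batch_size) {
      const int B = std::min(batch_size, N - start);
      uvec idx =
          conv_to<uvec>::from(perm_1based.row(ep).cols(start, start + B - 1).t()) - 1;
      fmat Xb = batch_matrix(X, idx);
      fmat Tb = batch_matrix(Y, idx);
      fmat O = net.forward(Xb, B, true);
      fmat R = O - Tb;
      ep_loss += mean(mean(square(R)));
      ++n_batch;
      fmat dOut = (2.0f / (float)R.n_elem) * R;
      net.backward(dOut, B);
      net.adam_step((float)lr, (float)beta1, (float)beta2, (float)eps, ++t);
      Rcpp::checkUserInterrupt();
    }
    history[ep] = ep_loss / n_batch;
  }
  return Rcpp::List::create(Rcpp::Named("params") = net.dump(),
                            Rcpp::Named("history") = history);
}

// [[Rcpp::export]]
arma::mat unet_forward_cpp(arma::mat X, arma::vec params, Rcpp::IntegerVector arch,
                           int batch_size = 32) {
  Arch a = arch_from(arch);
  if ((int)X.n_cols != a.L) Rcpp::stop("input length mismatch");
  Net net = make_net(a);
  if (params.n_elem != net.n_params()) Rcpp::stop("parameter vector has wrong length");
  net.load(params);
  const int N = X.n_rows;
  mat out(N, a.L);
  for (int start = 0; start < N; start += batch_size) {
    const int B = std::min(batch_size, N - start);
    uvec idx = regspace<uvec>(start, start + B - 1);
    fmat O = net.forward(batch_matrix(X, idx), B, true);
    for (int s = 0; s < B; ++s)
      out.row(start + s) =
          conv_to<rowvec>::from(O.cols((size_t)s * a.L, (size_t)(s + 1) * a.L - 1));
  }
  return out;
}
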