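// Compiled training loop for the bidirectional adversarial model.
// Mirrors the R reference engine exactly: batch shuffles are precomputed in
// R (one sample.int per epoch) and latent noise is drawn from the R RNG in
// column-major order, so both engines are deterministic given the seed and
// agree to floating-point accuracy.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Net {
  std::vector<arma::mat> W;
  std::vector<arma::vec> b;
};

Net net_from_list(const List& layers) {
  Net net;
  for (R_xlen_t l = 0; l < layers.size(); ++l) {
    List layer = layers[l];
    net.W.push_back(as<arma::mat>(layer["W"]));
    net.b.push_back(as<arma::vec>(layer["b"]));
  }
  return net;
}

List net_to_list(const Net& net) {
  List out(net.W.size());
  for (size_t l = 0; l < net.W.size(); ++l) {
    out[l] = List::create(Named("W") = net.W[l], Named("b") = net.b[l]);
  }
  return out;
}

struct Cache {
  std::vector<arma::mat> a;  // activations, a[0] = input
  std::vector<arma::mat> z;  // pre-activations
};

enum OutAct { LINEAR = 0, SIGMOID = 1 };

arma::mat sigmoid(const arma::mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

Cache forward(const Net& net, const arma::mat& X, int out_act) {
  Cache c;
  const size_t L = net.W.size();
  c.a.resize(L + 1);
  c.z.resize(L);
  c.a[0] = X;
  for (size_t l = 0; l < L; ++l) {
    arma::mat zl = c.a[l] * net.W[l].t();
    zl.each_row() += net.b[l].t();
    c.z[l] = zl;
    if (l + 1 < L) {
      c.a[l + 1] = arma::clamp(zl, 0.0, arma::datum::inf);
    } else if (out_act == SIGMOID) {
      c.a[l + 1] = sigmoid(zl);
    } else {
      c.a[l + 1] = zl;
    }
  }
  return c;
}

// Backprop from the gradient w.r.t. the last pre-activation.
void backward(const Net& net, const Cache& c, const arma::mat& d_z_last,
              Net& grads, arma::mat* d_input) {
  const size_t L = net.W.size();
  grads.W.resize(L);
  grads.b.resize(L);
  arma::mat dz = d_z_last;
  for (size_t l = L; l-- > 0;) {
    grads.W[l] = dz.t() * c.a[l];
    grads.b[l] = arma::sum(dz, 0).t();
    arma::mat da = dz * net.W[l];
    if (l > 0) {
      dz = da % arma::conv_to<arma::mat>::from(c.z[l - 1] > 0);
    } else if (d_input != nullptr) {
      *d_input = da;
    }
  }
}

struct Adam {
  std::vector<arma::mat> mW, vW;
  std::vector<arma::vec> mb, vb;
  long t = 0;

  explicit Adam(const Net& net) {
    for (size_t l = 0; l < net.W.size(); ++l) {
      mW.push_back(arma::zeros<arma::mat>(arma::size(net.W[l])));
      vW.push_back(arma::zeros<arma::mat>(arma::size(net.W[l])));
      mb.push_back(arma::zeros<arma::vec>(net.b[l].n_elem));
      vb.push_back(arma::zeros<arma::vec>(net.b[l].n_elem));
    }
  }

  void step(Net& net, const Net& grads, double lr, double b1, double b2,
            double eps = 1e-8) {
    ++t;
    const double bc1 = 1.0 - std::pow(b1, (double)t);
    const double bc2 = 1.0 - std::pow(b2, (double)t);
    for (size_t l = 0; l < net.W.size(); ++l) {
      mW[l] = b1 * mW[l] + (1.0 - b1) * grads.W[l];
      vW[l] = b2 * vW[l] + (1.0 - b2) * arma::square(grads.W[l]);
      net.W[l] -= lr * (mW[l] / bc1) / (arma::sqrt(vW[l] / bc2) + eps);
      mb[l] = b1 * mb[l] + (1.0 - b1) * grads.b[l];
      vb[l] = b2 * vb[l] + (1.0 - b2) * arma::square(grads.b[l]);
      net.b[l] -= lr * (mb[l] / bc1) / (arma::sqrt(vb[l] / bc2) + eps);
    }
  }
};

// Fill column-major with sequential R rnorm draws, matching
// matrix(rnorm(m * k), m, k) in R.
arma::mat rnorm_mat(arma::uword m, arma::uword k) {
  arma::mat out(m, k);
  double* p = out.memptr();
  for (arma::uword i = 0; i < m * k; ++i) p[i] = norm_rand();
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".bigan_train_cpp")]]
List bigan_train_cpp(const arma::mat& X, List encoder0, List generator0,
                     List discriminator0, int epochs, int batch_size,
                     double lr, double lr_eg, double beta1, double beta2,
                     int lr_decay_linear, int gen_sigmoid, int latent_dim,
                     const IntegerMatrix& shuffles, int snap_start,
                     int snap_every) {
  Net enc = net_from_list(encoder0);
  Net gen = net_from_list(generator0);
  Net dis = net_from_list(discriminator0);
  Adam ad_e(enc), ad_g(gen), ad_d(dis);

  const arma::uword n = X.n_rows;
  const arma::uword input_dim = X.n_cols;
  const int gen_act = gen_sigmoid ? SIGMOID : LINEAR;
  List snapshots;

  for (int epoch = 1; epoch <= epochs; ++epoch) {
    const double fac =
        lr_decay_linear ? 1.0 - (epoch - 1.0) / (double)epochs : 1.0;
    const double lr_d_t = lr * fac;
    const double lr_eg_t = lr_eg * fac;

    for (arma::uword s = 0; s < n; s += batch_size) {
      const arma::uword e = std::min<arma::uword>(s + batch_size, n) - 1;
      arma::uvec idx(e - s + 1);
      for (arma::uword j = s; j <= e; ++j) {
        idx[j - s] = (arma::uword)shuffles(epoch - 1, j) - 1;
      }
      const arma::mat Xb = X.rows(idx);
      const arma::uword m = Xb.n_rows;
      const arma::mat Zb = rnorm_mat(m, latent_dim);

      // E/G forwards are shared by both phases: the discriminator step only
      // needs their outputs, and E/G do not change until their own update.
      Cache ce = forward(enc, Xb, LINEAR);
      Cache cg = forward(gen, Zb, gen_act);
      const arma::mat real_in = arma::join_rows(Xb, ce.a.back());
      const arma::mat fake_in = arma::join_rows(cg.a.back(), Zb);

      // --- discriminator step (E, G fixed) ---
      Cache cr = forward(dis, real_in, SIGMOID);
      Cache cf = forward(dis, fake_in, SIGMOID);
      Net gr, gf;
      backward(dis, cr, (cr.a.back() - 1.0) / (double)m, gr, nullptr);
      backward(dis, cf, cf.a.back() / (double)m, gf, nullptr);
      for (size_t l = 0; l < gr.W.size(); ++l) {
        gr.W[l] += gf.W[l];
        gr.b[l] += gf.b[l];
      }
      ad_d.step(dis, gr, lr_d_t, beta1, beta2);

      // --- encoder + generator step (D fixed), non-saturating labels ---
      Cache cr2 = forward(dis, real_in, SIGMOID);
      Cache cf2 = forward(dis, fake_in, SIGMOID);
      Net gdis;
      arma::mat d_in_f, d_in_r;
      backward(dis, cf2, (cf2.a.back() - 1.0) / (double)m, gdis, &d_in_f);
      backward(dis, cr2, cr2.a.back() / (double)m, gdis, &d_in_r);
      arma::mat d_gen_out = d_in_f.cols(0, input_dim - 1);
      if (gen_act == SIGMOID) {
        d_gen_out %= cg.a.back() % (1.0 - cg.a.back());
      }
      arma::mat d_enc_out =
          d_in_r.cols(input_dim, input_dim + latent_dim - 1);
      Net gG, gE;
      backward(gen, cg, d_gen_out, gG, nullptr);
      backward(enc, ce, d_enc_out, gE, nullptr);
      ad_g.step(gen, gG, lr_eg_t, beta1, beta2);
      ad_e.step(enc, gE, lr_eg_t, beta1, beta2);
    }

    if (snap_every > 0 && epoch > snap_start && epoch % snap_every == 0) {
      snapshots.push_back(List::create(Named("encoder") = net_to_list(enc),
                                       Named("discriminator") =
                                           net_to_list(dis)));
    }
  }

  return List::create(Named("encoder") = net_to_list(enc),
                      Named("generator") = net_to_list(gen),
                      Named("discriminator") = net_to_list(dis),
                      Named("snapshots") = snapshots);
}
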