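#include <Rcpp.h>
using namespace Rcpp;

// Helpers for the CNN layers. Activation tensors use the (H, W, B, C)
// layout (column-major), so index = h + H*(w + W*(b + B*c)).

// im2col: padded input (Hp, Wp, B, Cin) -> (Ho*Wo*B, kh*kw*Cin) matrix with
// column blocks ordered (di fastest, then dj, then ci), matching a weight
// array of dim (kh, kw, Cin, Cout) flattened to (kh*kw*Cin, Cout).
// [[Rcpp::export(name = ".conv_gather_cpp")]]
NumericMatrix conv_gather_cpp(NumericVector xp, IntegerVector dims,
                              int kh, int kw) {
  const int Hp = dims[0], Wp = dims[1], B = dims[2], Cin = dims[3];
  const int Ho = Hp - kh + 1, Wo = Wp - kw + 1;
  const R_xlen_t nrow = (R_xlen_t)Ho * Wo * B;
  NumericMatrix out(nrow, kh * kw * Cin);
  const double* x = xp.begin();
  for (int ci = 0; ci < Cin; ++ci) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int col = di + kh * (dj + kw * ci);
        double* o = &out(0, col);
        R_xlen_t r = 0;
        for (int b = 0; b < B; ++b) {
          const R_xlen_t base_bc = (R_xlen_t)Hp * Wp * (b + (R_xlen_t)B * ci);
          for (int w = 0; w < Wo; ++w) {
            const R_xlen_t base = base_bc + (R_xlen_t)Hp * (w + dj) + di;
            for (int h = 0; h < Ho; ++h) o[r++] = x[base + h];
          }
        }
      }
    }
  }
  return out;
}

// col2im with accumulation: dXcol (Ho*Wo*B, kh*kw*Cin) -> padded gradient
// (Hp, Wp, B, Cin). Exact adjoint of conv_gather_cpp, but rows ordered
// (h, w, b) as produced there... note gather writes rows in (b, w, h) order
// per column; scatter mirrors that ordering.
// [[Rcpp::export(name = ".conv_scatter_cpp")]]
NumericVector conv_scatter_cpp(NumericMatrix dXcol, IntegerVector dims,
                               int kh, int kw) {
  const int Hp = dims[0], Wp = dims[1], B = dims[2], Cin = dims[3];
  const int Ho = Hp - kh + 1, Wo = Wp - kw + 1;
  NumericVector dxp((R_xlen_t)Hp * Wp * B * Cin);
  double* x = dxp.begin();
  for (int ci = 0; ci < Cin; ++ci) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int col = di + kh * (dj + kw * ci);
        const double* o = &dXcol(0, col);
        R_xlen_t r = 0;
        for (int b = 0; b < B; ++b) {
          const R_xlen_t base_bc = (R_xlen_t)Hp * Wp * (b + (R_xlen_t)B * ci);
          for (int w = 0; w < Wo; ++w) {
            const R_xlen_t base = base_bc + (R_xlen_t)Hp * (w + dj) + di;
            for (int h = 0; h < Ho; ++h) x[base + h] += o[r++];
          }
        }
      }
    }
  }
  dxp.attr("dim") = dims;
  return dxp;
}

// max pooling with stride = window; returns pooled values and the argmax
// slot (1..ph*pw) for the backward pass.
// [[Rcpp::export(name = ".maxpool_cpp")]]
List maxpool_cpp(NumericVector x, IntegerVector dims, int ph, int pw) {
  const int H = dims[0], W = dims[1], B = dims[2], C = dims[3];
  const int Ho = H / ph, Wo = W / pw;
  const R_xlen_t n = (R_xlen_t)Ho * Wo * B * C;
  NumericVector out(n);
  IntegerVector amax(n);
  const double* xd = x.begin();
  R_xlen_t r = 0;
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      const R_xlen_t base_bc = (R_xlen_t)H * W * (b + (R_xlen_t)B * c);
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h) {
          double best = R_NegInf; int slot = 0, k = 0;
          for (int dj = 0; dj < pw; ++dj) {
            const R_xlen_t colbase = base_bc + (R_xlen_t)H * (w * pw + dj) + h * ph;
            for (int di = 0; di < ph; ++di) {
              ++k;
              const double v = xd[colbase + di];
              if (v > best) { best = v; slot = k; }
            }
          }
          out[r] = best; amax[r] = slot; ++r;
        }
      }
    }
  }
  // r runs (h, w, b, c) fastest-first? loops are c,b,w,h outer->inner, so
  // linear index r corresponds to h fastest: matches dim (Ho, Wo, B, C)
  out.attr("dim") = IntegerVector::create(Ho, Wo, B, C);
  amax.attr("dim") = IntegerVector::create(Ho, Wo, B, C);
  return List::create(_["out"] = out, _["amax"] = amax);
}

// scatter pooled gradients back through the argmax slots
// [[Rcpp::export(name = ".maxpool_back_cpp")]]
NumericVector maxpool_back_cpp(NumericVector dout, IntegerVector amax,
                               IntegerVector dims, int ph, int pw) {
  const int H = dims[0], W = dims[1], B = dims[2], C = dims[3];
  const int Ho = H / ph, Wo = W / pw;
  NumericVector dx((R_xlen_t)H * W * B * C);
  double* xd = dx.begin();
  const double* od = dout.begin();
  const int* am = amax.begin();
  R_xlen_t r = 0;
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      const R_xlen_t base_bc = (R_xlen_t)H * W * (b + (R_xlen_t)B * c);
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h) {
          const int slot = am[r] - 1;
          const int dj = slot / ph, di = slot % ph;
          xd[base_bc + (R_xlen_t)H * (w * pw + dj) + h * ph + di] += od[r];
          ++r;
        }
      }
    }
  }
  dx.attr("dim") = dims;
  return dx;
}
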