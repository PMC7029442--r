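// Low-level array ops for the cascade network: dilated 2-D convolution
// (forward + backward via im2col/GEMM), 2x2 max-pooling and bilinear
// resampling with its adjoint. Feature maps are H x W x C cubes matching
// R arrays dim = c(H, W, C); kernels are R arrays dim = c(kh, kw, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// "same" padding for a dilated kernel: pad = rate * (k - 1) / 2, so odd
// kernel sizes keep the output spatial size equal to the input.
static mat im2col_dil(const cube& x, int kh, int kw, int rate) {
    const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
    const int padh = rate * (kh - 1) / 2, padw = rate * (kw - 1) / 2;
    mat col(static_cast<uword>(kh) * kw * C, static_cast<uword>(H) * W,
            fill::zeros);
    for (int c = 0; c < C; ++c) {
        for (int q = 0; q < kw; ++q) {
            for (int p = 0; p < kh; ++p) {
                const uword ridx = p + q * kh + static_cast<uword>(c) * kh * kw;
                const int di = p * rate - padh, dj = q * rate - padw;
                const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
                const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
                if (i0 >= i1 || j0 >= j1) continue;
                for (int j = j0; j < j1; ++j) {
                    const double* src = &x(i0 + di, j + dj, c);
                    double* dst = &col(ridx, static_cast<uword>(j) * H + i0);
                    for (int i = i0; i < i1; ++i) {
                        *dst = *src++;
                        dst += col.n_rows;
                    }
                }
            }
        }
    }
    return col;
}

static cube col2im_dil(const mat& gcol, int H, int W, int C, int kh, int kw,
                       int rate) {
    const int padh = rate * (kh - 1) / 2, padw = rate * (kw - 1) / 2;
    cube gx(H, W, C, fill::zeros);
    for (int c = 0; c < C; ++c) {
        for (int q = 0; q < kw; ++q) {
            for (int p = 0; p < kh; ++p) {
                const uword ridx = p + q * kh + static_cast<uword>(c) * kh * kw;
                const int di = p * rate - padh, dj = q * rate - padw;
                const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
                const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
                if (i0 >= i1 || j0 >= j1) continue;
                for (int j = j0; j < j1; ++j) {
                    double* dst = &gx(i0 + di, j + dj, c);
                    const double* src = &gcol(ridx, static_cast<uword>(j) * H + i0);
                    for (int i = i0; i < i1; ++i) {
                        *dst++ += *src;
                        src += gcol.n_rows;
                    }
                }
            }
        }
    }
    return gx;
}

static void kernel_dims(const Rcpp::NumericVector& w, int dims[4]) {
    Rcpp::IntegerVector d = w.attr("dim");
    if (d.size() != 4) Rcpp::stop("kernel must be a 4-d array (kh, kw, Cin, Cout)");
    for (int i = 0; i < 4; ++i) dims[i] = d[i];
}

// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube& x, const Rcpp::NumericVector& w,
                      const arma::vec& b, int rate) {
    if (rate < 1) Rcpp::stop("dilation rate must be >= 1");
    int d[4];
    kernel_dims(w, d);
    const int kh = d[0], kw = d[1], Cin = d[2], Cout = d[3];
    if (static_cast<int>(x.n_slices) != Cin)
        Rcpp::stop("input has %d channels but kernel expects %d",
                   (int)x.n_slices, Cin);
    if (static_cast<int>(b.n_elem) != Cout)
        Rcpp::stop("bias length %d != output channels %d", (int)b.n_elem, Cout);
    const int H = x.n_rows, W = x.n_cols;
    const mat Wm(const_cast<double*>(w.begin()),
                 static_cast<uword>(kh) * kw * Cin, Cout, false, true);
    mat out;
    if (kh == 1 && kw == 1) {
        // 1x1 convolution: plain channel mixing, no im2col needed
        const mat xm(const_cast<double*>(x.memptr()),
                     static_cast<uword>(H) * W, Cin, false, true);
        out = xm * Wm;
    } else {
        out = im2col_dil(x, kh, kw, rate).t() * Wm;
    }
    out.each_row() += b.t();
    return cube(out.memptr(), H, W, Cout);
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_backward(const arma::cube& x, const Rcpp::NumericVector& w,
                               const arma::cube& gout, int rate) {
    int d[4];
    kernel_dims(w, d);
    const int kh = d[0], kw = d[1], Cin = d[2], Cout = d[3];
    const int H = x.n_rows, W = x.n_cols;
    const mat Wm(const_cast<double*>(w.begin()),
                 static_cast<uword>(kh) * kw * Cin, Cout, false, true);
    const mat G(const_cast<double*>(gout.memptr()),
                static_cast<uword>(H) * W, Cout, false, true);
    mat gWm;
    cube gx;
    if (kh == 1 && kw == 1) {
        const mat xm(const_cast<double*>(x.memptr()),
                     static_cast<uword>(H) * W, Cin, false, true);
        gWm = xm.t() * G;
        mat gxm = G * Wm.t();
        gx = cube(gxm.memptr(), H, W, Cin);
    } else {
        const mat col = im2col_dil(x, kh, kw, rate);
        gWm = col * G;
        gx = col2im_dil(Wm * G.t(), H, W, Cin, kh, kw, rate);
    }
    Rcpp::NumericVector gw(gWm.begin(), gWm.end());
    gw.attr("dim") = Rcpp::IntegerVector::create(kh, kw, Cin, Cout);
    return Rcpp::List::create(Rcpp::Named("gx") = gx,
                              Rcpp::Named("gw") = gw,
                              Rcpp::Named("gb") = arma::vec(sum(G, 0).t()));
}

// 2x2 max pooling, stride 2, floor mode (trailing odd row/col dropped).
// idx stores 1-based linear indices into x for the backward pass.
// [[Rcpp::export]]
Rcpp::List cpp_maxpool2(const arma::cube& x) {
    const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
    const int Ho = H / 2, Wo = W / 2;
    if (Ho < 1 || Wo < 1) Rcpp::stop("input too small to pool");
    cube y(Ho, Wo, C);
    Rcpp::IntegerVector idx(static_cast<R_xlen_t>(Ho) * Wo * C);
    R_xlen_t n = 0;
    for (int c = 0; c < C; ++c) {
        for (int j = 0; j < Wo; ++j) {
            for (int i = 0; i < Ho; ++i) {
                double best = -std::numeric_limits<double>::infinity();
                uword bi = 0;
                for (int dj = 0; dj < 2; ++dj) {
                    for (int di = 0; di < 2; ++di) {
                        const uword li = (2 * i + di) +
                            static_cast<uword>(2 * j + dj) * H +
                            static_cast<uword>(c) * H * W;
                        if (x(li) > best) { best = x(li); bi = li; }
                    }
                }
                y(i, j, c) = best;
                idx[n++] = static_cast<int>(bi) + 1;
            }
        }
    }
    idx.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, C);
    return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_backward(const Rcpp::IntegerVector& idx,
                                 const arma::cube& gout, int H, int W) {
    cube gx(H, W, gout.n_slices, fill::zeros);
    const R_xlen_t n = idx.size();
    for (R_xlen_t k = 0; k < n; ++k) gx(idx[k] - 1) += gout(k);
    return gx;
}

// Bilinear resampling to an arbitrary target size; source coordinate of
// output pixel i is (i + 0.5) * (H / Ho) - 0.5 clamped to [0, H - 1]
// (half-pixel centres, no corner alignment), so constants are preserved.
// [[Rcpp::export]]
arma::cube cpp_upsample_bilinear(const arma::cube& x, int Ho, int Wo) {
    const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
    if (Ho == H && Wo == W) return x;
    const double sh = static_cast<double>(H) / Ho,
                 sw = static_cast<double>(W) / Wo;
    std::vector<int> i0(Ho), i1(Ho), j0(Wo), j1(Wo);
    std::vector<double> wi(Ho), wj(Wo);
    for (int i = 0; i < Ho; ++i) {
        double f = std::min(std::max((i + 0.5) * sh - 0.5, 0.0), H - 1.0);
        i0[i] = static_cast<int>(std::floor(f));
        i1[i] = std::min(i0[i] + 1, H - 1);
        wi[i] = f - i0[i];
    }
    for (int j = 0; j < Wo; ++j) {
        double f = std::min(std::max((j + 0.5) * sw - 0.5, 0.0), W - 1.0);
        j0[j] = static_cast<int>(std::floor(f));
        j1[j] = std::min(j0[j] + 1, W - 1);
        wj[j] = f - j0[j];
    }
    cube y(Ho, Wo, C);
    for (int c = 0; c < C; ++c)
        for (int j = 0; j < Wo; ++j)
            for (int i = 0; i < Ho; ++i)
                y(i, j, c) =
                    (1 - wi[i]) * (1 - wj[j]) * x(i0[i], j0[j], c) +
                    wi[i] * (1 - wj[j]) * x(i1[i], j0[j], c) +
                    (1 - wi[i]) * wj[j] * x(i0[i], j1[j], c) +
                    wi[i] * wj[j] * x(i1[i], j1[j], c);
    return y;
}

// Adjoint of cpp_upsample_bilinear: scatter output gradients back to the
// source grid with the same interpolation weights.
// [[Rcpp::export]]
arma::cube cpp_upsample_bilinear_backward(const arma::cube& gout, int H, int W) {
    const int Ho = gout.n_rows, Wo = gout.n_cols, C = gout.n_slices;
    if (Ho == H && Wo == W) return gout;
    const double sh = static_cast<double>(H) / Ho,
                 sw = static_cast<double>(W) / Wo;
    std::vector<int> i0(Ho), i1(Ho), j0(Wo), j1(Wo);
    std::vector<double> wi(Ho), wj(Wo);
    for (int i = 0; i < Ho; ++i) {
        double f = std::min(std::max((i + 0.5) * sh - 0.5, 0.0), H - 1.0);
        i0[i] = static_cast<int>(std::floor(f));
        i1[i] = std::min(i0[i] + 1, H - 1);
        wi[i] = f - i0[i];
    }
    for (int j = 0; j < Wo; ++j) {
        double f = std::min(std::max((j + 0.5) * sw - 0.5, 0.0), W - 1.0);
        j0[j] = static_cast<int>(std::floor(f));
        j1[j] = std::min(j0[j] + 1, W - 1);
        wj[j] = f - j0[j];
    }
    cube gx(H, W, C, fill::zeros);
    for (int c = 0; c < C; ++c)
        for (int j = 0; j < Wo; ++j)
            for (int i = 0; i < Ho; ++i) {
                const double g = gout(i, j, c);
                gx(i0[i], j0[j], c) += (1 - wi[i]) * (1 - wj[j]) * g;
                gx(i1[i], j0[j], c) += wi[i] * (1 - wj[j]) * g;
                gx(i0[i], j1[j], c) += (1 - wi[i]) * wj[j] * g;
                gx(i1[i], j1[j], c) += wi[i] * wj[j] * g;
            }
    return gx;
}

// Stroke rasterisation for the synthetic scene generator: mark every pixel
// whose centre lies within width/2 of the segment (r0,c0)-(r1,c1); label is
// set to 1 and widthMap keeps the maximum nominal stroke width seen.
// [[Rcpp::export]]
void cpp_raster_segment(Rcpp::NumericMatrix label, Rcpp::NumericMatrix widthMap,
                        double r0, double c0, double r1, double c1,
                        double width) {
    const int H = label.nrow(), W = label.ncol();
    const double hw = width / 2.0;
    const int rlo = std::max(0, (int)std::floor(std::min(r0, r1) - hw) - 1);
    const int rhi = std::min(H - 1, (int)std::ceil(std::max(r0, r1) + hw) + 1);
    const int clo = std::max(0, (int)std::floor(std::min(c0, c1) - hw) - 1);
    const int chi = std::min(W - 1, (int)std::ceil(std::max(c0, c1) + hw) + 1);
    const double dr = r1 - r0, dc = c1 - c0;
    const double len2 = dr * dr + dc * dc;
    for (int j = clo; j <= chi; ++j) {
        for (int i = rlo; i <= rhi; ++i) {
            double t = len2 > 0 ? ((i - r0) * dr + (j - c0) * dc) / len2 : 0.0;
            t = std::min(std::max(t, 0.0), 1.0);
            const double pr = r0 + t * dr - i, pc = c0 + t * dc - j;
            if (pr * pr + pc * pc <= hw * hw) {
                label(i, j) = 1.0;
                if (width > widthMap(i, j)) widthMap(i, j) = width;
            }
        }
    }
}
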