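#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <climits>
using namespace Rcpp;

// Sliding-window GLCM texture map. qpad is the reflection-padded quantized
// image (levels 0..nLevels-1); offsets is a 2 x nTheta matrix of
// (drow, dcol) steps. Output: H x W x (5 * nTheta), statistic order per
// orientation: asm, contrast, correlation, variance, entropy.
// [[Rcpp::export(name = "texture_map_cpp")]]
NumericVector texture_map_cpp(IntegerMatrix qpad, int H, int W, int window,
                              IntegerMatrix offsets, int nLevels,
                              double logBase, bool symmetric,
                              LogicalMatrix mask) {
  const int k = (window - 1) / 2;
  const int nTheta = offsets.ncol();
  const int nFeat = 5 * nTheta;
  NumericVector out(static_cast<R_xlen_t>(H) * W * nFeat);
  std::vector<double> counts(static_cast<size_t>(nLevels) * nLevels);
  std::vector<double> px(nLevels), py(nLevels);
  std::vector<int> win(static_cast<size_t>(window) * window);
  const double logDen = std::log(logBase);

  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c)) continue;
      // copy the centered window (padded coords offset by k)
      for (int wc = 0; wc < window; ++wc)
        for (int wr = 0; wr < window; ++wr)
          win[wr + wc * window] = qpad(r + wr, c + wc);
      for (int t = 0; t < nTheta; ++t) {
        const int dr = offsets(0, t), dc = offsets(1, t);
        std::fill(counts.begin(), counts.end(), 0.0);
        double total = 0.0;
        for (int wc = 0; wc < window; ++wc) {
          const int c2 = wc + dc;
          if (c2 < 0 || c2 >= window) continue;
          for (int wr = 0; wr < window; ++wr) {
            const int r2 = wr + dr;
            if (r2 < 0 || r2 >= window) continue;
            const int i = win[wr + wc * window];
            const int j = win[r2 + c2 * window];
            counts[i + j * nLevels] += 1.0;
            total += 1.0;
            if (symmetric) { counts[j + i * nLevels] += 1.0; total += 1.0; }
          }
        }
        std::fill(px.begin(), px.end(), 0.0);
        std::fill(py.begin(), py.end(), 0.0);
        double asm_ = 0.0, contrast = 0.0, entropy = 0.0, sumij = 0.0;
        for (int j = 0; j < nLevels; ++j) {
          for (int i = 0; i < nLevels; ++i) {
            const double p = counts[i + j * nLevels] / total;
            if (p <= 0.0) continue;
            asm_ += p * p;
            contrast += p * (i - j) * (i - j);
            entropy -= p * std::log(p);
            sumij += p * i * j;
            px[i] += p;
            py[j] += p;
          }
        }
        entropy /= logDen;
        double muX = 0.0, muY = 0.0;
        for (int i = 0; i < nLevels; ++i) { muX += i * px[i]; muY += i * py[i]; }
        double vX = 0.0, vY = 0.0;
        for (int i = 0; i < nLevels; ++i) {
          vX += (i - muX) * (i - muX) * px[i];
          vY += (i - muY) * (i - muY) * py[i];
        }
        const double sxy = std::sqrt(vX) * std::sqrt(vY);
        const double num = sumij - muX * muY;
        const double correlation = sxy > 0.0 ? num / sxy : 0.0;
        const double variance = num; // verbatim sum (i j - muX muY) p
        const R_xlen_t base =
          static_cast<R_xlen_t>(r) + static_cast<R_xlen_t>(c) * H;
        const R_xlen_t plane = static_cast<R_xlen_t>(H) * W;
        out[base + (5 * t + 0) * plane] = asm_;
        out[base + (5 * t + 1) * plane] = contrast;
        out[base + (5 * t + 2) * plane] = correlation;
        out[base + (5 * t + 3) * plane] = variance;
        out[base + (5 * t + 4) * plane] = entropy;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, nFeat);
  return out;
}

static double blockNCC(const NumericMatrix &ref, const NumericMatrix &mov,
                       int r0, int c0, int r1, int c1, int block,
                       double refMean, double refVarSum) {
  double movSum = 0.0;
  for (int c = 0; c < block; ++c)
    for (int r = 0; r < block; ++r) movSum += mov(r1 + r, c1 + c);
  const double movMean = movSum / (block * block);
  double cross = 0.0, movVar = 0.0;
  for (int c = 0; c < block; ++c)
    for (int r = 0; r < block; ++r) {
      const double a = ref(r0 + r, c0 + c) - refMean;
      const double b = mov(r1 + r, c1 + c) - movMean;
      cross += a * b;
      movVar += b * b;
    }
  const double den = std::sqrt(refVarSum * movVar);
  if (den <= 0.0) return NA_REAL;
  return cross / den;
}

// Integer-displacement block matching by normalized cross-correlation.
// Tiles ref into block x block sub-blocks; for each, searches displacements
// within +/- search around (initDr, initDc) for the maximal NCC against mov.
// Returns per-block best displacement, best NCC, the 3x3 NCC patch around
// the peak (for sub-pixel refinement), a flat flag (zero-variance ref
// block) and the ref block variance.
// [[Rcpp::export(name = "block_match_cpp")]]
List block_match_cpp(NumericMatrix ref, NumericMatrix mov, int block,
                     int search, IntegerMatrix initDr, IntegerMatrix initDc) {
  const int H = ref.nrow(), W = ref.ncol();
  const int nbr = H / block, nbc = W / block;
  IntegerMatrix dr(nbr, nbc), dc(nbr, nbc);
  NumericMatrix ncc(nbr, nbc), refVar(nbr, nbc);
  LogicalMatrix flat(nbr, nbc);
  NumericVector patch(static_cast<R_xlen_t>(nbr) * nbc * 9, NA_REAL);
  const int span = 2 * search + 1;
  std::vector<double> surf(static_cast<size_t>(span) * span);

  for (int bc = 0; bc < nbc; ++bc) {
    for (int br = 0; br < nbr; ++br) {
      const int r0 = br * block, c0 = bc * block;
      double s = 0.0;
      for (int c = 0; c < block; ++c)
        for (int r = 0; r < block; ++r) s += ref(r0 + r, c0 + c);
      const double refMean = s / (block * block);
      double vsum = 0.0;
      for (int c = 0; c < block; ++c)
        for (int r = 0; r < block; ++r) {
          const double a = ref(r0 + r, c0 + c) - refMean;
          vsum += a * a;
        }
      refVar(br, bc) = vsum / (block * block);
      if (vsum <= 1e-12) { flat(br, bc) = true; ncc(br, bc) = NA_REAL; continue; }
      std::fill(surf.begin(), surf.end(), NA_REAL);
      double best = -2.0;
      int bestI = 0, bestJ = 0, bestD2 = INT_MAX;
      for (int j = 0; j < span; ++j) {
        const int ddc = initDc(br, bc) + j - search;
        const int c1 = c0 + ddc;
        if (c1 < 0 || c1 + block > W) continue;
        for (int i = 0; i < span; ++i) {
          const int ddr = initDr(br, bc) + i - search;
          const int r1 = r0 + ddr;
          if (r1 < 0 || r1 + block > H) continue;
          const double v = blockNCC(ref, mov, r0, c0, r1, c1, block,
                                    refMean, vsum);
          surf[i + j * span] = v;
          if (ISNAN(v)) continue;
          // ties (within 1e-12) resolved toward the initial displacement
          const int d2 = (i - search) * (i - search) +
                         (j - search) * (j - search);
          if (v > best + 1e-12 || (v > best - 1e-12 && d2 < bestD2)) {
            best = v; bestI = i; bestJ = j; bestD2 = d2;
          }
        }
      }
      if (best <= -2.0) { flat(br, bc) = true; ncc(br, bc) = NA_REAL; continue; }
      dr(br, bc) = initDr(br, bc) + bestI - search;
      dc(br, bc) = initDc(br, bc) + bestJ - search;
      ncc(br, bc) = best;
      for (int j = -1; j <= 1; ++j)
        for (int i = -1; i <= 1; ++i) {
          const int si = bestI + i, sj = bestJ + j;
          double v = NA_REAL;
          if (si >= 0 && si < span && sj >= 0 && sj < span)
            v = surf[si + sj * span];
          patch[static_cast<R_xlen_t>(br) +
                static_cast<R_xlen_t>(bc) * nbr +
                static_cast<R_xlen_t>((i + 1) + (j + 1) * 3) * nbr * nbc] = v;
        }
    }
  }
  patch.attr("dim") = IntegerVector::create(nbr, nbc, 9);
  return List::create(_["dr"] = dr, _["dc"] = dc, _["ncc"] = ncc,
                      _["patch"] = patch, _["flat"] = flat,
                      _["refVar"] = refVar);
}
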