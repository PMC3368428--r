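#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Zero-mean normalised cross-correlation of a (possibly masked) template
// against every full-overlap translation of a target image.  mask entries
// are 1 where the template pixel is valid (e.g. inside the rotated support)
// and 0 elsewhere; masked pixels are excluded from means and norms.

// [[Rcpp::export(name = ".ncc_offsets_cpp")]]
NumericMatrix ncc_offsets_cpp(NumericMatrix target, NumericMatrix templ,
                              NumericMatrix mask) {
  const int Ht = target.nrow(), Wt = target.ncol();
  const int h = templ.nrow(), w = templ.ncol();
  const int Ho = Ht - h + 1, Wo = Wt - w + 1;
  if (Ho < 1 || Wo < 1) stop("template larger than target");

  // template statistics under the mask
  double n_eff = 0.0, tsum = 0.0;
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j)
      if (mask(i, j) > 0.5) { n_eff += 1.0; tsum += templ(i, j); }
  if (n_eff < 2) stop("mask leaves fewer than two template pixels");
  double tmean = tsum / n_eff;
  double tss = 0.0;
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j)
      if (mask(i, j) > 0.5) {
        double d = templ(i, j) - tmean;
        tss += d * d;
      }
  if (tss <= 0) stop("zero-variance template: correlation undefined");

  NumericMatrix out(Ho, Wo);
  for (int oy = 0; oy < Ho; ++oy) {
    for (int ox = 0; ox < Wo; ++ox) {
      double gsum = 0.0;
      for (int i = 0; i < h; ++i)
        for (int j = 0; j < w; ++j)
          if (mask(i, j) > 0.5) gsum += target(oy + i, ox + j);
      double gmean = gsum / n_eff;
      double num = 0.0, gss = 0.0;
      for (int i = 0; i < h; ++i)
        for (int j = 0; j < w; ++j)
          if (mask(i, j) > 0.5) {
            double dg = target(oy + i, ox + j) - gmean;
            double dt = templ(i, j) - tmean;
            num += dg * dt;
            gss += dg * dg;
          }
      out(oy, ox) = (gss > 0) ? num / std::sqrt(gss * tss) : 0.0;
    }
  }
  return out;
}
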