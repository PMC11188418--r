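#include <Rcpp.h>
using namespace Rcpp;

// Clockwise direction offsets starting at the top-left diagonal:
// 1=(-1,-1) 2=(-1,0) 3=(-1,+1) 4=(0,+1) 5=(+1,+1) 6=(+1,0) 7=(+1,-1) 8=(0,-1)
static const int DR[8] = {-1, -1, -1, 0, 1, 1, 1, 0};
static const int DC[8] = {-1, 0, 1, 1, 1, 0, -1, -1};

// Dispersion (index-of-dispersion style coefficient of variation): sum of
// squared deviations over (n * mean), as a percent.  Sequential double
// accumulation so that plain R loops reproduce it bit for bit.
static inline double dispersion_ray(const double *v, int n) {
  double s = 0.0;
  for (int k = 0; k < n; ++k) s = s + v[k];
  double m = s / n;
  if (m == 0.0) return 0.0;
  double ssd = 0.0;
  for (int k = 0; k < n; ++k) {
    double d = v[k] - m;
    ssd = ssd + d * d;
  }
  return (ssd / (n * m)) * 100.0;
}

// R-LBP codes for every pixel whose full neighbourhood (offsets up to
// ray_length + 1 in each of the 8 directions) lies inside `img`; all other
// pixels get code 0.  The caller chooses the border policy: replicate-pad
// the image by ray_length + 1 and extract the interior, or pass the raw
// image so the border band is coded 0.
// [[Rcpp::export(name = ".rlbp_core")]]
IntegerMatrix rlbp_core(NumericMatrix img, double threshold, int ray_length,
                        int zero_cv_policy) {
  int H = img.nrow(), W = img.ncol();
  int need = ray_length + 1;
  IntegerMatrix out(H, W);
  std::vector<double> ray_a(need), ray_b(need + 1);
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      bool inside = (i - need >= 0) && (i + need < H) && (j - need >= 0) &&
                    (j + need < W);
      if (!inside) {
        out(i, j) = 0;
        continue;
      }
      double x0 = img(i, j);
      int code = 0;
      for (int d = 0; d < 8; ++d) {
        for (int k = 1; k <= need; ++k)
          ray_a[k - 1] = img(i + k * DR[d], j + k * DC[d]);
        ray_b[0] = x0;
        for (int k = 0; k < need; ++k) ray_b[k + 1] = ray_a[k];
        double cva = dispersion_ray(ray_a.data(), need);
        double cvb = dispersion_ray(ray_b.data(), need + 1);
        int bit;
        if (cva > 0.0) {
          bit = (std::abs(cva - cvb) / cva > threshold) ? 1 : 0;
        } else {
          bit = (cvb > 0.0) ? zero_cv_policy : 0;
        }
        code |= bit << (7 - d);
      }
      out(i, j) = code;
    }
  }
  return out;
}

// Classic 3x3 LBP: bit d is 1 iff neighbour d >= centre; direction 1 is the
// most significant bit.  Border pixels (no full 3x3 neighbourhood) get 0;
// the caller replicate-pads by 1 and extracts the interior.
// [[Rcpp::export(name = ".lbp_core")]]
IntegerMatrix lbp_core(NumericMatrix img) {
  int H = img.nrow(), W = img.ncol();
  IntegerMatrix out(H, W);
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      bool inside = (i - 1 >= 0) && (i + 1 < H) && (j - 1 >= 0) && (j + 1 < W);
      if (!inside) {
        out(i, j) = 0;
        continue;
      }
      double x0 = img(i, j);
      int code = 0;
      for (int d = 0; d < 8; ++d) {
        if (img(i + DR[d], j + DC[d]) >= x0) code |= 1 << (7 - d);
      }
      out(i, j) = code;
    }
  }
  return out;
}
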