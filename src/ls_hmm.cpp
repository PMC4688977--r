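// Li-Stephens haplotype-copying HMM kernels.
//
// State space: reference haplotypes (haploid chains) or ordered pairs of
// reference haplotypes (diploid chains). Transitions between adjacent
// markers follow the standard copying-model form
//   P(k -> k') = (1 - rho) [k' = k] + rho / H,
// which factorises per chain, so diploid forward/backward sums cost O(H^2)
// per marker and diploid Viterbi maxima cost O(H^2) via a four-candidate
// decomposition (stay/stay, stay/switch, switch/stay, switch/switch).
// Emissions allow a per-allele miscopy probability eps; missing observations
// emit uniformly.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline void pair_emission(int g, double eps, double ev[3]) {
  // ev[s] = P(genotype g | copied allele sum s), s = a_k + a_l
  const double q = 1.0 - eps;
  if (g < 0) { ev[0] = ev[1] = ev[2] = 1.0; return; }
  switch (g) {
  case 0: ev[0] = q * q;        ev[1] = q * eps;           ev[2] = eps * eps; break;
  case 1: ev[0] = 2 * q * eps;  ev[1] = q * q + eps * eps; ev[2] = 2 * q * eps; break;
  case 2: ev[0] = eps * eps;    ev[1] = q * eps;           ev[2] = q * q; break;
  default: stop("genotype must be 0, 1, 2 or negative (missing)");
  }
}

// [[Rcpp::export(name = ".ls_fb_haploid")]]
List ls_fb_haploid(IntegerMatrix ref, IntegerVector obs, NumericVector rho,
                   double eps) {
  const int H = ref.nrow(), M = ref.ncol();
  if (obs.size() != M) stop("obs length must equal marker count");
  if (rho.size() != M - 1 && M > 1) stop("rho must have length M - 1");
  const double q = 1.0 - eps;

  NumericMatrix fwd(H, M), bwd(H, M);
  std::vector<double> scale(M);
  double loglik = 0.0;

  // forward
  for (int j = 0; j < M; ++j) {
    double s = 0.0;
    for (int k = 0; k < H; ++k) {
      double prev;
      if (j == 0) {
        prev = 1.0 / H;
      } else {
        const double r = rho[j - 1];
        prev = (1.0 - r) * fwd(k, j - 1) + r / H; // prev column sums to 1
      }
      double e = 1.0;
      if (obs[j] >= 0) e = (ref(k, j) == obs[j]) ? q : eps;
      fwd(k, j) = prev * e;
      s += fwd(k, j);
    }
    if (s <= 0) stop("zero forward likelihood; rescaling failed");
    for (int k = 0; k < H; ++k) fwd(k, j) /= s;
    scale[j] = s;
    loglik += std::log(s);
  }

  // backward (same scale structure; normalised per marker)
  for (int k = 0; k < H; ++k) bwd(k, M - 1) = 1.0;
  for (int j = M - 2; j >= 0; --j) {
    const double r = rho[j];
    double tot = 0.0, sum_c = 0.0;
    std::vector<double> c(H);
    for (int k = 0; k < H; ++k) {
      double e = 1.0;
      if (obs[j + 1] >= 0) e = (ref(k, j + 1) == obs[j + 1]) ? q : eps;
      c[k] = e * bwd(k, j + 1);
      sum_c += c[k];
    }
    for (int k = 0; k < H; ++k) {
      bwd(k, j) = (1.0 - r) * c[k] + (r / H) * sum_c;
      tot += bwd(k, j);
    }
    for (int k = 0; k < H; ++k) bwd(k, j) /= tot;
  }

  NumericMatrix post(H, M);
  NumericVector allele_post(M);
  for (int j = 0; j < M; ++j) {
    double s = 0.0;
    for (int k = 0; k < H; ++k) { post(k, j) = fwd(k, j) * bwd(k, j); s += post(k, j); }
    double ap = 0.0;
    for (int k = 0; k < H; ++k) {
      post(k, j) /= s;
      const double m = ref(k, j) == 1 ? q : eps;
      ap += post(k, j) * m;
    }
    allele_post[j] = ap;
  }
  return List::create(_["state_post"] = post, _["allele_post"] = allele_post,
                      _["loglik"] = loglik);
}

// Apply the factorised pair transition to src (in place via dst): per chain
// dst = stay * src + sw * (marginal sum), chains applied sequentially.
static inline void pair_transition(const double *src, double *dst, int H,
                                   double stay, double sw,
                                   double *colsum, double *rowsum) {
  for (int l = 0; l < H; ++l) colsum[l] = 0.0;
  for (int k = 0; k < H; ++k) {
    const double *s = src + (size_t)k * H;
    for (int l = 0; l < H; ++l) colsum[l] += s[l];
  }
  for (int k = 0; k < H; ++k) {
    const double *s = src + (size_t)k * H;
    double *d = dst + (size_t)k * H;
    double rs = 0.0;
    for (int l = 0; l < H; ++l) {
      d[l] = stay * s[l] + sw * colsum[l];
      rs += d[l];
    }
    rowsum[k] = rs;
  }
  for (int k = 0; k < H; ++k) {
    double *d = dst + (size_t)k * H;
    const double add = sw * rowsum[k];
    for (int l = 0; l < H; ++l) d[l] = stay * d[l] + add;
  }
}

// [[Rcpp::export(name = ".ls_fb_diploid")]]
List ls_fb_diploid(IntegerMatrix ref, IntegerVector geno, NumericVector rho,
                   double eps) {
  const int H = ref.nrow(), M = ref.ncol();
  if (geno.size() != M) stop("genotype length must equal marker count");
  if (M > 1 && rho.size() < M - 1) stop("rho must have length M - 1");
  if ((double)H * H * M > 4e8) stop("pair-HMM state space too large; cap the conditioning panel (max_states)");
  const double q = 1.0 - eps;
  const int HH = H * H;
  const int *refp = INTEGER(ref);   // column-major H x M

  std::vector<double> F((size_t)HH * M);
  std::vector<double> cur(HH), tmp(HH), colsum(H), rowsum(H);
  double loglik = 0.0;

  // forward, stored per marker
  for (int j = 0; j < M; ++j) {
    double ev[3];
    pair_emission(geno[j], eps, ev);
    const int *rj = refp + (size_t)j * H;
    double s = 0.0;
    if (j == 0) {
      for (int k = 0; k < H; ++k) {
        const int ak = rj[k];
        double *c = &cur[(size_t)k * H];
        for (int l = 0; l < H; ++l) { c[l] = ev[ak + rj[l]] / HH; s += c[l]; }
      }
    } else {
      const double r = rho[j - 1], stay = 1.0 - r, sw = r / H;
      pair_transition(cur.data(), tmp.data(), H, stay, sw,
                      colsum.data(), rowsum.data());
      for (int k = 0; k < H; ++k) {
        const int ak = rj[k];
        const double *t = &tmp[(size_t)k * H];
        double *c = &cur[(size_t)k * H];
        for (int l = 0; l < H; ++l) { c[l] = t[l] * ev[ak + rj[l]]; s += c[l]; }
      }
    }
    if (s <= 0) stop("zero forward likelihood; rescaling failed");
    const double inv = 1.0 / s;
    for (int i = 0; i < HH; ++i) cur[i] *= inv;
    loglik += std::log(s);
    std::copy(cur.begin(), cur.end(), F.begin() + (size_t)HH * j);
  }

  // backward on the fly, accumulate posterior summaries
  NumericVector dosage(M), maxpost(M);
  std::vector<double> B(HH, 1.0), C(HH);
  for (int j = M - 1; j >= 0; --j) {
    const double *Fj = &F[(size_t)HH * j];
    const int *rj = refp + (size_t)j * H;
    double z = 0.0;
    for (int i = 0; i < HH; ++i) z += Fj[i] * B[i];
    double dose = 0.0, mp = 0.0;
    for (int k = 0; k < H; ++k) {
      const double mk = rj[k] == 1 ? q : eps;
      const double *f = Fj + (size_t)k * H;
      const double *b = &B[(size_t)k * H];
      for (int l = 0; l < H; ++l) {
        const double p = f[l] * b[l] / z;
        dose += p * (mk + (rj[l] == 1 ? q : eps));
        if (p > mp) mp = p;
      }
    }
    dosage[j] = dose; maxpost[j] = mp;
    if (j == 0) break;
    double ev[3];
    pair_emission(geno[j], eps, ev);
    for (int k = 0; k < H; ++k) {
      const int ak = rj[k];
      const double *b = &B[(size_t)k * H];
      double *c = &C[(size_t)k * H];
      for (int l = 0; l < H; ++l) c[l] = ev[ak + rj[l]] * b[l];
    }
    const double r = rho[j - 1], stay = 1.0 - r, sw = r / H;
    pair_transition(C.data(), B.data(), H, stay, sw,
                    colsum.data(), rowsum.data());
    double tot = 0.0;
    for (int i = 0; i < HH; ++i) tot += B[i];
    const double inv = 1.0 / tot;
    for (int i = 0; i < HH; ++i) B[i] *= inv;
  }

  return List::create(_["dosage"] = dosage, _["maxpost"] = maxpost,
                      _["loglik"] = loglik);
}

// [[Rcpp::export(name = ".ls_viterbi_diploid")]]
List ls_viterbi_diploid(IntegerMatrix ref, IntegerVector geno,
                        NumericVector rho, double eps) {
  const int H = ref.nrow(), M = ref.ncol();
  const int HH = H * H;
  if ((double)HH * M > 4e8) stop("pair-HMM state space too large; cap the conditioning panel");

  std::vector<double> V(HH), Vn(HH), rowmax(H), colmax(H);
  std::vector<unsigned char> code((size_t)HH * M, 0);
  std::vector<int> rowargAll((size_t)H * M, 0), colargAll((size_t)H * M, 0);
  std::vector<int> gkAll(M, 0), glAll(M, 0);
  const int *refp = INTEGER(ref);

  double ev[3];
  pair_emission(geno[0], eps, ev);
  {
    const int *r0 = refp;
    for (int k = 0; k < H; ++k) {
      const int ak = r0[k];
      double *v = &V[(size_t)k * H];
      for (int l = 0; l < H; ++l) v[l] = ev[ak + r0[l]] / HH;
    }
  }

  for (int j = 1; j < M; ++j) {
    // row/col/global maxima of previous V
    std::fill(rowmax.begin(), rowmax.end(), -1.0);
    std::fill(colmax.begin(), colmax.end(), -1.0);
    int *rowarg = &rowargAll[(size_t)H * j];
    int *colarg = &colargAll[(size_t)H * j];
    double gmax = -1.0; int gk = 0, gl = 0;
    for (int k = 0; k < H; ++k) {
      const double *v = &V[(size_t)k * H];
      double rm = -1.0; int ra = 0;
      for (int l = 0; l < H; ++l) {
        if (v[l] > rm) { rm = v[l]; ra = l; }
        if (v[l] > colmax[l]) { colmax[l] = v[l]; colarg[l] = k; }
      }
      rowmax[k] = rm; rowarg[k] = ra;
      if (rm > gmax) { gmax = rm; gk = k; gl = ra; }
    }
    gkAll[j] = gk; glAll[j] = gl;

    const double r = rho[j - 1], stay = 1.0 - r + r / H, sw = r / H;
    pair_emission(geno[j], eps, ev);
    unsigned char *cd = &code[(size_t)HH * j];
    const int *rj = refp + (size_t)j * H;
    double vmax = 0.0;
    const double ss = stay * stay, scw = stay * sw, sws = sw * sw;
    const double gcand = sws * gmax;
    for (int k = 0; k < H; ++k) {
      const int ak = rj[k];
      const double rcand = scw * rowmax[k];
      const double *v = &V[(size_t)k * H];
      double *vn = &Vn[(size_t)k * H];
      unsigned char *cdk = cd + (size_t)k * H;
      for (int l = 0; l < H; ++l) {
        double best = ss * v[l];
        unsigned char c = 0;
        if (rcand > best) { best = rcand; c = 1; }
        const double ccand = scw * colmax[l];
        if (ccand > best) { best = ccand; c = 2; }
        if (gcand > best) { best = gcand; c = 3; }
        const double vv = best * ev[ak + rj[l]];
        vn[l] = vv; cdk[l] = c;
        if (vv > vmax) vmax = vv;
      }
    }
    if (vmax <= 0) stop("zero Viterbi likelihood");
    const double inv = 1.0 / vmax;
    for (int i = 0; i < HH; ++i) V[i] = Vn[i] * inv;
  }

  // terminal argmax, ties to the lowest (k, l) index pair
  int k = 0, l = 0; double best = -1.0;
  for (int a = 0; a < H; ++a)
    for (int b = 0; b < H; ++b)
      if (V[a * H + b] > best) { best = V[a * H + b]; k = a; l = b; }

  IntegerVector path1(M), path2(M);
  path1[M - 1] = k + 1; path2[M - 1] = l + 1;
  for (int j = M - 1; j >= 1; --j) {
    const unsigned char c = code[(size_t)HH * j + k * H + l];
    int pk = k, pl = l;
    if (c == 1) pl = rowargAll[(size_t)H * j + k];
    else if (c == 2) pk = colargAll[(size_t)H * j + l];
    else if (c == 3) { pk = gkAll[j]; pl = glAll[j]; }
    k = pk; l = pl;
    path1[j - 1] = k + 1; path2[j - 1] = l + 1;
  }
  return List::create(_["path1"] = path1, _["path2"] = path2);
}
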