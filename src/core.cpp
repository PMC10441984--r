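#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Viterbi-style haplotype-copying DP. States are the columns of `haps`
// (one per reference haplotype); per-site cost is 1 for a mismatch with the
// target allele, plus `lambda` whenever the copied template switches.
// Ties prefer staying on the current template, then the lowest state index,
// so the traceback is deterministic.
// [[Rcpp::export]]
IntegerVector paint_dp_path(IntegerVector target, IntegerMatrix haps,
                            double lambda) {
  const int S = haps.nrow(), H = haps.ncol();
  if (target.size() != S) stop("target length != panel site count");
  if (H < 1) stop("empty reference panel");
  std::vector<double> prev(H), cur(H);
  // backpointer: 0 = stay, 1 = jump to best_prev[s-1]
  std::vector<unsigned char> bp((size_t)S * H, 0);
  std::vector<int> best_idx(S, 0);

  for (int h = 0; h < H; ++h)
    prev[h] = (haps(0, h) != target[0]) ? 1.0 : 0.0;
  {
    int b = 0;
    for (int h = 1; h < H; ++h) if (prev[h] < prev[b]) b = h;
    best_idx[0] = b;
  }
  for (int s = 1; s < S; ++s) {
    int pb = best_idx[s - 1];
    double jump = prev[pb] + lambda;
    for (int h = 0; h < H; ++h) {
      double mis = (haps(s, h) != target[s]) ? 1.0 : 0.0;
      if (prev[h] <= jump) {
        cur[h] = prev[h] + mis;
      } else {
        cur[h] = jump + mis;
        bp[(size_t)s * H + h] = 1;
      }
    }
    std::swap(prev, cur);
    int b = 0;
    for (int h = 1; h < H; ++h) if (prev[h] < prev[b]) b = h;
    best_idx[s] = b;
  }

  IntegerVector path(S);
  int h = best_idx[S - 1];
  path[S - 1] = h;
  for (int s = S - 1; s >= 1; --s) {
    if (bp[(size_t)s * H + h]) h = best_idx[s - 1];
    path[s - 1] = h;
  }
  return path + 1;  // 1-based template indices
}

// Total cost of the optimal copying path (for invariance tests).
// [[Rcpp::export]]
double paint_dp_cost(IntegerVector target, IntegerMatrix haps, double lambda) {
  const int S = haps.nrow(), H = haps.ncol();
  std::vector<double> prev(H), cur(H);
  for (int h = 0; h < H; ++h)
    prev[h] = (haps(0, h) != target[0]) ? 1.0 : 0.0;
  for (int s = 1; s < S; ++s) {
    double best = prev[0];
    for (int h = 1; h < H; ++h) if (prev[h] < best) best = prev[h];
    for (int h = 0; h < H; ++h) {
      double mis = (haps(s, h) != target[s]) ? 1.0 : 0.0;
      double stay = prev[h], jump = best + lambda;
      cur[h] = (stay <= jump ? stay : jump) + mis;
    }
    std::swap(prev, cur);
  }
  double best = prev[0];
  for (int h = 1; h < H; ++h) if (prev[h] < best) best = prev[h];
  return best;
}

// Weighted-LD pair sums for admixture dating. G is the centered genotype
// matrix (sites x individuals), w the per-site reference allele-frequency
// contrast, cm the genetic position. For every site pair within max_cm,
// accumulates per distance bin: sum(cov_xy * w_x*w_y), sum((w_x*w_y)^2)
// and the pair count.
// [[Rcpp::export]]
NumericMatrix wld_pair_bins(NumericMatrix G, NumericVector w,
                            NumericVector cm, double bin_cm, double max_cm) {
  const int S = G.nrow(), N = G.ncol();
  if (N < 2) stop("need >= 2 individuals");
  const int nb = (int)std::ceil(max_cm / bin_cm);
  NumericMatrix out(nb, 3);
  for (int i = 0; i < S; ++i) {
    for (int j = i + 1; j < S; ++j) {
      double d = cm[j] - cm[i];
      if (d >= max_cm) break;
      int b = (int)(d / bin_cm);
      if (b < 0 || b >= nb) continue;
      double dot = 0.0;
      for (int k = 0; k < N; ++k) dot += G(i, k) * G(j, k);
      double cov = dot / (N - 1);
      double ww = w[i] * w[j];
      out(b, 0) += cov * ww;
      out(b, 1) += ww * ww;
      out(b, 2) += 1.0;
    }
  }
  return out;
}

// Pairwise r^2 binned by physical distance (genotype correlation).
// G: sites x individuals dosage matrix, NA allowed. Returns per bin the
// sum of r^2 and the pair count.
// [[Rcpp::export]]
NumericMatrix r2_pair_bins(IntegerMatrix G, NumericVector pos,
                           double bin_bp, double max_bp) {
  const int S = G.nrow(), N = G.ncol();
  const int nb = (int)std::ceil(max_bp / bin_bp);
  NumericMatrix out(nb, 2);
  for (int i = 0; i < S; ++i) {
    for (int j = i + 1; j < S; ++j) {
      double d = pos[j] - pos[i];
      if (d > max_bp) break;
      int b = (d <= 0) ? 0 : (int)((d - 1) / bin_bp);
      if (b >= nb) continue;
      double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
      int n = 0;
      for (int k = 0; k < N; ++k) {
        int x = G(i, k), y = G(j, k);
        if (x == NA_INTEGER || y == NA_INTEGER) continue;
        ++n; sx += x; sy += y; sxx += (double)x * x; syy += (double)y * y;
        sxy += (double)x * y;
      }
      if (n < 2) continue;
      double vx = sxx - sx * sx / n, vy = syy - sy * sy / n;
      double cxy = sxy - sx * sy / n;
      if (vx <= 0 || vy <= 0) continue;
      double r2 = (cxy * cxy) / (vx * vy);
      out(b, 0) += r2;
      out(b, 1) += 1.0;
    }
  }
  return out;
}

static double group_homozygosity(const std::vector<int>& grp,
                                 const std::vector<int>& idx, int n0,
                                 std::vector<int>& cnt) {
  std::fill(cnt.begin(), cnt.end(), 0);
  for (size_t t = 0; t < idx.size(); ++t) cnt[grp[idx[t]]]++;
  double num = 0.0;
  for (size_t g = 0; g < cnt.size(); ++g)
    num += 0.5 * cnt[g] * (cnt[g] - 1.0);
  return num / (0.5 * n0 * (n0 - 1.0));
}

// Integrated EHH for one core allele class on one side.
// H: sites x haplotypes (0/1); carriers: 0-based haplotype indices carrying
// the core allele; core: 0-based core site; dir: +1 right / -1 left.
// Integrates EHH over |genetic distance| (trapezoid) until EHH < cutoff,
// a physical gap > max_gap_bp, or the chromosome edge.
static double ihh_one_side(const IntegerMatrix& H, const std::vector<int>& carriers,
                           int core, int dir, const NumericVector& cm,
                           const NumericVector& bp, double cutoff,
                           double max_gap_bp) {
  const int S = H.nrow();
  const int n0 = (int)carriers.size();
  std::vector<int> grp(H.ncol(), 0);
  std::vector<int> cnt(2 * n0 + 2, 0);
  double ehh_prev = 1.0, d_prev = cm[core], ihh = 0.0;
  int ngrp = 1;
  for (int s = core + dir; s >= 0 && s < S; s += dir) {
    if (std::fabs(bp[s] - bp[s - dir]) > max_gap_bp) break;
    // refine identity groups by the allele at s
    // new id = 2*old + allele, then compact
    std::vector<int> remap(2 * ngrp, -1);
    int nn = 0;
    for (int t = 0; t < n0; ++t) {
      int h = carriers[t];
      int key = 2 * grp[h] + (H(s, h) ? 1 : 0);
      if (remap[key] < 0) remap[key] = nn++;
      grp[h] = remap[key];
    }
    ngrp = nn;
    if ((int)cnt.size() < ngrp) cnt.resize(ngrp);
    double ehh = group_homozygosity(grp, carriers, n0, cnt);
    double d = cm[s];
    ihh += 0.5 * (ehh_prev + ehh) * std::fabs(d - d_prev);
    ehh_prev = ehh; d_prev = d;
    if (ehh < cutoff) break;
  }
  return ihh;
}

// iHH for derived (allele 1) and ancestral (allele 0) cores at each
// requested site. Returns cores x 2 matrix (iHH_derived, iHH_ancestral);
// NaN where a core class has < 2 carriers.
// [[Rcpp::export]]
NumericMatrix ehh_ihh_scan(IntegerMatrix H, NumericVector cm, NumericVector bp,
                           IntegerVector cores, double cutoff,
                           double max_gap_bp) {
  const int nc = cores.size(), nh = H.ncol();
  NumericMatrix out(nc, 2);
  for (int i = 0; i < nc; ++i) {
    int c = cores[i] - 1;
    std::vector<int> der, anc;
    for (int h = 0; h < nh; ++h)
      (H(c, h) ? der : anc).push_back(h);
    for (int a = 0; a < 2; ++a) {
      const std::vector<int>& car = a == 0 ? der : anc;
      if ((int)car.size() < 2) { out(i, a) = NA_REAL; continue; }
      out(i, a) = ihh_one_side(H, car, c, +1, cm, bp, cutoff, max_gap_bp) +
                  ihh_one_side(H, car, c, -1, cm, bp, cutoff, max_gap_bp);
    }
  }
  return out;
}

// EHH curve for one core allele class (for tests / plotting): returns the
// EHH value at every site, 1 at the core, NA outside the traversed range.
// [[Rcpp::export]]
NumericVector ehh_curve(IntegerMatrix H, IntegerVector carriers, int core,
                        NumericVector cm, NumericVector bp, double cutoff,
                        double max_gap_bp) {
  const int S = H.nrow();
  NumericVector out(S, NA_REAL);
  std::vector<int> car(carriers.size());
  for (int i = 0; i < carriers.size(); ++i) car[i] = carriers[i] - 1;
  const int n0 = (int)car.size();
  if (n0 < 2) stop("need >= 2 carrier haplotypes");
  int c0 = core - 1;
  out[c0] = 1.0;
  for (int dir = -1; dir <= 1; dir += 2) {
    std::vector<int> grp(H.ncol(), 0);
    std::vector<int> cnt(2, 0);
    int ngrp = 1;
    for (int s = c0 + dir; s >= 0 && s < S; s += dir) {
      if (std::fabs(bp[s] - bp[s - dir]) > max_gap_bp) break;
      std::vector<int> remap(2 * ngrp, -1);
      int nn = 0;
      for (int t = 0; t < n0; ++t) {
        int h = car[t];
        int key = 2 * grp[h] + (H(s, h) ? 1 : 0);
        if (remap[key] < 0) remap[key] = nn++;
        grp[h] = remap[key];
      }
      ngrp = nn;
      if ((int)cnt.size() < ngrp) cnt.resize(ngrp);
      out[s] = group_homozygosity(grp, car, n0, cnt);
      if (out[s] < cutoff) break;
    }
  }
  return out;
}
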