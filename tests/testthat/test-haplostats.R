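test_that("LD decay hits perfect-LD and background expectations", {
  set.seed(51)
  # duplicated site at distance d -> r^2 = 1 in that bin
  g1 <- rbinom(20, 2, 0.5)
  gt <- rbind(g1, g1)
  st <- site_table(c("chr1", "chr1"), c(100L, 600L), c("A", "A"),
                   c("G", "G"), gt, contig_len = c(chr1 = 1000))
  ld <- ld_decay(st, max_dist_bp = 1000, bin_bp = 1000)
  expect_equal(ld$curve$mean_r2[1], 1)
  # independent sites: background r^2 of order 1/(n individuals)
  n <- 25
  g <- matrix(rbinom(400 * n, 2, 0.5), 400, n)
  st2 <- site_table(rep("chr1", 400), seq_len(400) * 10L, rep("A", 400),
                    rep("G", 400), g, contig_len = c(chr1 = 4001))
  ld2 <- ld_decay(st2, max_dist_bp = 4000, bin_bp = 4000)
  expect_equal(ld2$curve$mean_r2[1], 1 / (n - 1), tolerance = 0.25)
  expect_error(ld_decay(subset_sites(st2, 1)), "fewer than 2")
})

test_that("half-decay distance matches the closed form", {
  d <- seq(50, 10000, by = 100)
  r2 <- 0.5 * exp(-d / 2000)
  expect_equal(half_decay_distance(d, r2), 2000 * log(2) + 25,
               tolerance = 0.02)   # +25: curve max sits at d = 50, not 0
  expect_true(is.na(half_decay_distance(d[1:3], r2[1:3])))
})

# independent re-implementation of the PLINK window-fraction rule:
# plain loops, no cumsums
roh_oracle <- function(het, pos, W = 100, max_het = 1, thr = 0.05,
                       min_kb = 100, dens = 200) {
  S <- length(het)
  nw <- S - W + 1
  wh <- vapply(seq_len(nw), function(i) sum(het[i:(i + W - 1)]) <= max_het,
               TRUE)
  inrun <- vapply(seq_len(S), function(j) {
    ws <- max(1, j - W + 1):min(nw, j)
    mean(wh[ws]) >= thr
  }, TRUE)
  runs <- NULL
  i <- 1
  while (i <= S) {
    if (inrun[i]) {
      j <- i
      while (j < S && inrun[j + 1]) j <- j + 1
      kb <- (pos[j] - pos[i] + 1) / 1000
      if (kb >= min_kb && kb / (j - i + 1) <= dens)
        runs <- rbind(runs, c(start = pos[i], end = pos[j]))
      i <- j + 1
    } else i <- i + 1
  }
  runs
}

test_that("ROH detector equals an independent window-rule oracle", {
  set.seed(52)
  truth <- small_truth(seed = 52, n_sites = 2000, L_bp = 5e6, n_adm = 6)
  fe <- data.frame(kind = "roh", chrom = "chr1", start = 2e6, end = 2.6e6,
                   ancestry = NA_integer_, f = NA_real_, n_ind = 6L)
  planted <- plant_features(truth, fe)
  st <- planted$target
  for (s in st$samples[1:3]) {
    got <- detect_roh(st, s)
    het <- !is.na(st$gt[, s]) & st$gt[, s] == 1L
    ora <- roh_oracle(het, st$pos)
    if (is.null(ora)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(nrow(got), nrow(ora))
      expect_equal(got$start, unname(ora[, "start"]))
      expect_equal(got$end, unname(ora[, "end"]))
    }
  }
})

test_that("ROH respects construction, length and density rules", {
  # fully heterozygous sample: no runs
  gt <- matrix(1L, 500, 1)
  st <- site_table(rep("chr1", 500), seq_len(500) * 1000L, rep("A", 500),
                   rep("G", 500), gt, samples = "x",
                   contig_len = c(chr1 = 500001))
  expect_equal(nrow(detect_roh(st, "x")), 0)
  # planted 500-kb autozygous interval in dense SNPs -> one covering run
  truth <- small_truth(seed = 53, n_sites = 6000, L_bp = 6e6, n_adm = 4)
  fe <- data.frame(kind = "roh", chrom = "chr1", start = 3e6, end = 3.5e6,
                   ancestry = NA_integer_, f = NA_real_, n_ind = 4L)
  st2 <- plant_features(truth, fe)$target
  r <- detect_roh(st2, st2$samples[1])
  hit <- r[r$end > 3e6 & r$start < 3.5e6, , drop = FALSE]
  expect_equal(nrow(hit), 1)
  cover <- (min(hit$end, 3.5e6) - max(hit$start, 3e6)) / 5e5
  expect_gte(cover, 0.9)
  # an 80-kb plant fails min_kb = 100
  truth3 <- small_truth(seed = 54, n_sites = 6000, L_bp = 6e6, n_adm = 4)
  fe3 <- data.frame(kind = "roh", chrom = "chr1", start = 3e6,
                    end = 3.08e6, ancestry = NA_integer_, f = NA_real_,
                    n_ind = 4L)
  st3 <- plant_features(truth3, fe3)$target
  r3 <- detect_roh(st3, st3$samples[1])
  expect_equal(nrow(r3[r3$end > 3e6 & r3$start < 3.08e6, ]), 0)
  # chromosome shorter than the window warns and yields nothing
  expect_warning(r4 <- detect_roh(subset_sites(st2, 1:50), st2$samples[1]),
                 "fewer SNPs")
  expect_equal(nrow(r4), 0)
})

test_that("EHH is 1 across identical haplotypes and iHS standardizes", {
  # identical haplotypes: EHH stays 1 over the whole region
  H <- matrix(rep(rbinom(50, 1, 0.5), 8), 50, 8)
  ehh <- ehh_curve(H, carriers = 1:8, core = 25,
                   cm = seq_len(50) / 100, bp = seq_len(50) * 1000,
                   cutoff = 0.05, max_gap_bp = 1e9)
  expect_true(all(ehh == 1))
  # standardization contract within frequency bins
  truth <- small_truth(seed = 55, n_sites = 3000, L_bp = 10e6, n_adm = 20)
  res <- ehh_ihs(truth$target, win = 50000)
  bin <- pmin(floor(res$snp$daf / 0.05), 19)
  for (b in unique(bin)) {
    v <- res$snp$ihs[bin == b]
    if (length(v) < 50) next
    expect_lt(abs(mean(v)), 0.05)
    expect_lt(abs(sd(v) - 1), 0.05)
  }
})

test_that("iHS is antisymmetric under ancestral/derived relabel", {
  truth <- small_truth(seed = 56, n_sites = 800, L_bp = 4e6, n_adm = 10)
  a <- ehh_ihs(truth$target, win = 50000)
  b <- ehh_ihs(truth$target,
               anc_alleles = rep(1L, length(truth$target$pos)),
               win = 50000)
  m <- merge(a$snp, b$snp, by = c("chrom", "pos"))
  expect_gt(nrow(m), 100)
  expect_equal(m$ihs_raw.x, -m$ihs_raw.y, tolerance = 1e-10)
})

# brute-force CLR oracle at a single alpha: enumerate the post-sweep class
# distribution by direct summation over hitchhike counts
clr_oracle <- function(k_sites, d_sites, bg, n, alpha) {
  trans <- function(ph) {
    m <- numeric(n - 1)
    pj <- matrix(0, n - 1, n + 1)
    for (j in 1:(n - 1)) {
      p <- j / n
      for (H in 0:n) {
        wH <- dbinom(H, n, ph)
        for (e in 0:(n - H)) {
          pe <- dbinom(e, n - H, p)
          pj[j, H + e + 1] <- pj[j, H + e + 1] + wH * p * pe
          pj[j, e + 1] <- pj[j, e + 1] + wH * (1 - p) * pe
        }
      }
    }
    marg <- colSums(bg * pj)[2:n] + 1e-12
    marg / sum(marg)
  }
  ll <- 0
  for (s in seq_along(k_sites)) {
    ph <- exp(-d_sites[s] / alpha)
    ph_lev <- seq(0, 1, length.out = 24)
    ph <- ph_lev[which.min(abs(ph_lev - ph))]  # same discretization
    ll <- ll + log(trans(ph)[k_sites[s]])
  }
  2 * (max(ll - sum(log(bg[k_sites])), 0))
}

test_that("CLR toy window equals the enumeration oracle", {
  set.seed(57)
  n <- 8
  g <- matrix(rbinom(300 * 4, 2, runif(300, 0.1, 0.9)), 300, 4)
  k <- rowSums(g)
  keep <- k > 0 & k < n
  st <- site_table(rep("chr1", 300), seq_len(300) * 300L, rep("A", 300),
                   rep("G", 300), g, contig_len = c(chr1 = 90001))
  alpha <- 5000
  got <- clr_scan(st, win = 90001, grid_per_win = 1, alpha_grid = alpha)
  bg <- tabulate(k[keep], nbins = n - 1)
  if (any(bg == 0)) bg <- bg + 1
  bg <- bg / sum(bg)
  tp <- 90001 / 2
  d <- abs(st$pos[keep] - 1 - tp)
  expect_equal(got$value,
               clr_oracle(k[keep], d, bg, n, alpha), tolerance = 1e-10)
})

test_that("CLR is non-negative and near zero under the null", {
  vals <- vapply(1:5, function(s) {
    set.seed(60 + s)
    g <- matrix(rbinom(150 * 10, 2, runif(150, 0.1, 0.9)), 150, 10)
    st <- site_table(rep("chr1", 150), sort(sample.int(5e4, 150)),
                     rep("A", 150), rep("G", 150), g,
                     contig_len = c(chr1 = 5e4))
    suppressWarnings(clr_scan(st, win = 5e4)$value)
  }, 0)
  expect_true(all(vals >= 0))
  expect_lt(median(vals), 1)
})

test_that("rank-and-intersect applies the two-method top-quantile rule", {
  set.seed(62)
  nw <- 1000
  grid <- data.frame(chrom = "chr1", start = (0:(nw - 1)) * 5e4,
                     end = (1:nw) * 5e4)
  v1 <- runif(nw); v2 <- runif(nw)
  # plant 10 double hits and 5 single hits
  dbl <- sample(nw, 10); sgl <- setdiff(sample(nw, 15), dbl)[1:5]
  v1[dbl] <- 3 + runif(10); v2[dbl] <- 3 + runif(10)
  v1[sgl] <- 2 + runif(5)   # elevated but outside A's top 1%
  scans <- list(A = data.frame(grid, value = v1),
                B = data.frame(grid, value = v2))
  res <- rank_and_intersect(scans, top_q = 0.01, min_methods = 2)
  expect_setequal(which(res$windows$candidate), dbl)
  expect_false(any(sgl %in% which(res$windows$candidate)))
  # monotone: raising top_q never removes a candidate
  res2 <- rank_and_intersect(scans, top_q = 0.05, min_methods = 2)
  expect_true(all(which(res$windows$candidate) %in%
                    which(res2$windows$candidate)))
  # refuses tiny scans
  expect_error(rank_and_intersect(lapply(scans, head, 50)), "100")
})
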