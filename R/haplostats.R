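#' LD decay curve and half-decay distance
#'
#' Mean genotype-correlation r^2 per physical distance bin. The half-decay
#' distance is where the curve first drops to half of its maximum, linearly
#' interpolated between bin midpoints.
#'
#' @param x a [site_table()].
#' @param samples sample subset.
#' @param max_dist_bp largest pair distance considered.
#' @param bin_bp distance bin width.
#' @return list with `curve` (data.frame `dist_bp` midpoint, `mean_r2`,
#'   `n_pairs`) and `half_decay_bp`.
#' @export
ld_decay <- function(x, samples = x$samples, max_dist_bp = 100e3,
                     bin_bp = 1000) {
  g <- x$gt[, samples, drop = FALSE]
  nb <- ceiling(max_dist_bp / bin_bp)
  acc <- matrix(0, nb, 2)
  for (cc in unique(x$chrom)) {
    ii <- which(x$chrom == cc)
    if (length(ii) < 2) next
    acc <- acc + r2_pair_bins(g[ii, , drop = FALSE],
                              as.numeric(x$pos[ii]), bin_bp, max_dist_bp)
  }
  if (sum(acc[, 2]) == 0) stop("fewer than 2 sites within range")
  curve <- data.frame(dist_bp = (seq_len(nb) - 0.5) * bin_bp,
                      mean_r2 = ifelse(acc[, 2] > 0, acc[, 1] / acc[, 2],
                                       NA_real_),
                      n_pairs = acc[, 2])
  list(curve = curve,
       half_decay_bp = half_decay_distance(curve$dist_bp, curve$mean_r2))
}

#' Half-decay distance of an LD curve
#'
#' First distance at which the curve drops to half of its maximum,
#' linearly interpolated between bin midpoints.
#'
#' @param dist_bp bin midpoints (increasing).
#' @param r2 mean r-squared per bin (NA bins ignored).
#' @return Half-decay distance in bp (NA if the curve never halves).
#' @export
half_decay_distance <- function(dist_bp, r2) {
  ok <- !is.na(r2)
  dist_bp <- dist_bp[ok]; r2 <- r2[ok]
  if (!length(r2)) return(NA_real_)
  half <- max(r2) / 2
  below <- which(r2 <= half)
  if (!length(below)) return(NA_real_)
  b <- below[1]
  if (b == 1) return(dist_bp[1])
  x0 <- dist_bp[b - 1]; x1 <- dist_bp[b]
  y0 <- r2[b - 1]; y1 <- r2[b]
  x0 + (y0 - half) / (y0 - y1) * (x1 - x0)
}

#' Detect runs of homozygosity with the PLINK window-fraction rule
#'
#' Slides windows of `window_snp` consecutive SNPs; a window is homozygous
#' if it contains at most `window_het` heterozygous calls. Each SNP's hit
#' fraction is the share of overlapping windows that are homozygous; a SNP
#' is in-run when the fraction reaches `window_threshold`. Maximal in-run
#' stretches become runs, then filtered by `min_kb` and the density rule
#' (run kb per SNP at most `density_kb_per_snp`). Defaults mirror PLINK's
#' `--homozyg-window-snp 100 --homozyg-density 200 --homozyg-window-het 1
#' --homozyg-kb 100 --homozyg-window-threshold 0.05`.
#'
#' @param x a [site_table()].
#' @param sample sample name.
#' @param window_snp,window_het,window_threshold,min_kb,density_kb_per_snp
#'   PLINK-style parameters.
#' @return data.frame `sample`, `chrom`, `start`, `end` (1-based bp of the
#'   first/last SNP), `n_snps`, `length_kb`.
#' @export
detect_roh <- function(x, sample, window_snp = 100, window_het = 1,
                       window_threshold = 0.05, min_kb = 100,
                       density_kb_per_snp = 200) {
  g <- x$gt[, sample]
  out <- NULL
  for (cc in unique(x$chrom)) {
    ii <- which(x$chrom == cc)
    S <- length(ii)
    if (S < window_snp) {
      warning("chromosome ", cc, " has fewer SNPs than window_snp; skipped")
      next
    }
    het <- as.integer(!is.na(g[ii]) & g[ii] == 1L)
    cs <- c(0L, cumsum(het))
    nw <- S - window_snp + 1L
    whet <- cs[(window_snp + 1):(S + 1)] - cs[1:nw]   # het count per window
    whom <- as.integer(whet <= window_het)
    csw <- c(0L, cumsum(whom))
    # windows overlapping SNP j: start index in [max(1, j-W+1), min(nw, j)]
    j <- seq_len(S)
    lo <- pmax(1L, j - window_snp + 1L); hi <- pmin(nw, j)
    n_over <- hi - lo + 1L
    n_hom <- csw[hi + 1L] - csw[lo]
    frac <- n_hom / n_over
    inrun <- frac >= window_threshold
    r <- rle(inrun)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      a <- starts[k]; b <- ends[k]
      len_kb <- (x$pos[ii[b]] - x$pos[ii[a]] + 1) / 1000
      nsnp <- b - a + 1L
      if (len_kb < min_kb) next
      if (len_kb / nsnp > density_kb_per_snp) next
      out <- rbind(out, data.frame(sample = sample, chrom = cc,
                                   start = x$pos[ii[a]], end = x$pos[ii[b]],
                                   n_snps = nsnp, length_kb = len_kb))
    }
  }
  if (is.null(out))
    out <- data.frame(sample = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_snps = integer(0), length_kb = numeric(0))
  out
}

#' Integrated haplotype score (iHS) scan
#'
#' For each core SNP, EHH curves for the derived and ancestral cores are
#' integrated (trapezoid over genetic distance) until EHH drops below
#' `cutoff`, a gap exceeds `max_gap_bp`, or the chromosome edge.
#' Unstandardized iHS = ln(iHH_ancestral / iHH_derived), standardized to
#' mean 0 / sd 1 within derived-frequency bins of width 0.05. SNPs with
#' derived frequency below `maf_min` or a core class with < 2 carriers are
#' excluded. Per nonoverlapping window both the mean |iHS| and the
#' fraction with |iHS| > 2 are reported.
#'
#' @param x a phased [site_table()].
#' @param samples sample subset.
#' @param anc_alleles optional 0/1 vector: the ancestral allele per site
#'   coded against the hap matrix (0 = ref ancestral). Default assumes the
#'   reference allele is ancestral; with simulated data pass the truth.
#' @param maf_min minimum derived-allele frequency (default 0.05).
#' @param max_gap_bp largest tolerated physical gap (default 200 kb).
#' @param cutoff EHH truncation level (default 0.05).
#' @param cM_per_Mb constant genetic map rate.
#' @param win summary window in bp (nonoverlapping, default 50 kb).
#' @return list with `snp` (per-SNP table: `chrom`, `pos`, `daf`,
#'   `ihs_raw`, `ihs`) and `window` (per-window `value` = mean |iHS|,
#'   `frac_gt2`, `n_sites`).
#' @export
ehh_ihs <- function(x, samples = x$samples, anc_alleles = NULL,
                    maf_min = 0.05, max_gap_bp = 200e3, cutoff = 0.05,
                    cM_per_Mb = 1, win = 50000) {
  H <- hap_matrix(x, samples)
  if (is.null(anc_alleles)) anc_alleles <- rep(0L, nrow(H))
  # recode so 1 = derived everywhere
  flip <- anc_alleles == 1L
  H[flip, ] <- 1L - H[flip, , drop = FALSE]
  daf <- rowMeans(H)
  snp <- NULL
  for (cc in unique(x$chrom)) {
    ii <- which(x$chrom == cc)
    cm <- (x$pos[ii] - 1) / 1e6 * cM_per_Mb
    cores <- which(daf[ii] >= maf_min & daf[ii] <= 1 - maf_min)
    if (!length(cores)) next
    ihh <- ehh_ihh_scan(H[ii, , drop = FALSE], cm, as.numeric(x$pos[ii]),
                        cores, cutoff, max_gap_bp)
    ok <- is.finite(ihh[, 1]) & is.finite(ihh[, 2]) & ihh[, 1] > 0 &
      ihh[, 2] > 0
    snp <- rbind(snp, data.frame(chrom = cc, pos = x$pos[ii][cores][ok],
                                 daf = daf[ii][cores][ok],
                                 ihs_raw = log(ihh[ok, 2] / ihh[ok, 1])))
  }
  if (is.null(snp) || nrow(snp) == 0)
    stop("no usable core SNPs for iHS")
  bin <- pmin(floor(snp$daf / 0.05), 19)
  snp$ihs <- NA_real_
  for (b in unique(bin)) {
    sel <- bin == b
    mu <- mean(snp$ihs_raw[sel]); sg <- sd(snp$ihs_raw[sel])
    snp$ihs[sel] <- if (is.na(sg) || sg == 0) 0 else
      (snp$ihs_raw[sel] - mu) / sg
  }
  grid <- window_grid(x, win, win)
  idx <- .window_sites(grid, snp$chrom, snp$pos)
  wv <- vapply(idx, function(i)
    if (length(i)) mean(abs(snp$ihs[i])) else NaN, 0)
  f2 <- vapply(idx, function(i)
    if (length(i)) mean(abs(snp$ihs[i]) > 2) else NaN, 0)
  ns <- lengths(idx)
  list(snp = snp,
       window = data.frame(grid[, c("chrom", "start", "end")],
                           n_sites = ns, value = wv, frac_gt2 = f2,
                           flagged = ns == 0))
}

#' Composite likelihood ratio (CLR) sweep scan
#'
#' Models the site-frequency spectrum near a sweep as a distortion of the
#' genome-wide background spectrum. A sweep of width `alpha` (bp) at test
#' point t hitchhikes each sampled lineage at distance d with probability
#' exp(-d/alpha); hitchhiked lineages carry the sweeping haplotype's
#' allele, escaped lineages resample the pre-sweep frequency. Class
#' probabilities are conditioned on polymorphism. Per window (nonoverlapping,
#' default 50 kb) CLR = 2 (max over alpha of the sweep log likelihood minus
#' the background log likelihood), maximized over `grid_per_win` test
#' points; alpha = 0 is the exact background model, so CLR >= 0.
#'
#' @param x a [site_table()].
#' @param samples sample subset.
#' @param win window size in bp.
#' @param grid_per_win test points per window.
#' @param alpha_grid sweep widths (bp); 0 is always included.
#' @param n_ph levels used to discretize the hitchhike probability.
#' @return data.frame of window statistics (`value` = CLR).
#' @export
clr_scan <- function(x, samples = x$samples, win = 50000, grid_per_win = 2,
                     alpha_grid = 10^seq(2.5, 5.5, length.out = 7),
                     n_ph = 24) {
  g <- x$gt[, samples, drop = FALSE]
  n <- 2L * length(samples)
  k <- rowSums(g, na.rm = TRUE)
  full <- rowSums(!is.na(g)) == length(samples)
  poly <- full & k > 0 & k < n
  bg <- tabulate(k[poly], nbins = n - 1)
  if (any(bg == 0)) {
    warning("background SFS has empty classes; add-one smoothing applied")
    bg <- bg + 1
  }
  bg <- bg / sum(bg)
  ph_levels <- seq(0, 1, length.out = n_ph)
  marg <- .clr_marginals(bg, n, ph_levels)          # n_ph x (n-1) class probs
  loglik_bg <- log(bg)
  grid <- window_grid(x, win, win)
  idx <- .window_sites(grid, x$chrom, x$pos)
  val <- rep(NaN, nrow(grid)); ns <- integer(nrow(grid))
  for (i in seq_along(idx)) {
    ii <- idx[[i]][poly[idx[[i]]]]
    ns[i] <- length(ii)
    if (!length(ii)) next
    pos <- x$pos[ii]; kk <- k[ii]
    l0 <- sum(loglik_bg[kk])
    tps <- grid$start[i] + (seq_len(grid_per_win) - 0.5) / grid_per_win *
      (grid$end[i] - grid$start[i])
    best <- 0
    for (tp in tps) {
      d <- abs(pos - 1 - tp)
      for (al in alpha_grid) {
        lev <- pmin(n_ph, pmax(1, round(exp(-d / al) * (n_ph - 1)) + 1))
        l1 <- sum(log(marg[cbind(lev, kk)]))
        if (l1 - l0 > best) best <- l1 - l0
      }
    }
    val[i] <- 2 * best
  }
  data.frame(grid[, c("chrom", "start", "end")], n_sites = ns,
             value = val, flagged = ns == 0 | grid$partial)
}

# Post-sweep class probabilities marginalized over the background SFS.
# For hitchhike probability ph: H ~ Bin(n, ph) lineages carry the sweeping
# haplotype's allele (derived with probability p = j/n), the remaining
# n - H lineages draw derived alleles Bin(n-H, p). Conditioned on
# 0 < k < n. Returns matrix length(ph_levels) x (n-1).
.clr_marginals <- function(bg, n, ph_levels) {
  out <- matrix(NA_real_, length(ph_levels), n - 1)
  for (li in seq_along(ph_levels)) {
    ph <- ph_levels[li]
    pk <- numeric(n + 1)                 # classes 0..n
    wH <- dbinom(0:n, n, ph)
    for (j in seq_len(n - 1)) {
      p <- j / n
      pj <- numeric(n + 1)
      for (H in 0:n) {
        if (wH[H + 1] < 1e-12) next
        esc <- dbinom(0:(n - H), n - H, p)
        # sweeping haplotype derived (prob p): k = H + Bin(n-H, p)
        pj[(H + 1):(n + 1)] <- pj[(H + 1):(n + 1)] + wH[H + 1] * p * esc
        # sweeping haplotype ancestral: k = Bin(n-H, p)
        pj[1:(n - H + 1)] <- pj[1:(n - H + 1)] + wH[H + 1] * (1 - p) * esc
      }
      pk <- pk + bg[j] * pj
    }
    seg <- pk[2:n] + 1e-12      # keep classes proper when ph -> 1 fixes all
    out[li, ] <- seg / sum(seg)
  }
  out
}

#' Empirical top-quantile ranking and multi-method intersection
#'
#' Resamples every scan to the coarsest grid (by maximal overlap), ranks
#' windows per scan (empirical rank = fraction of windows with a value at
#' least as large), and retains windows ranking within `top_q` in at least
#' `min_methods` scans; adjacent candidate windows are merged into regions.
#' Pass sign-flipped values for statistics where small means extreme.
#'
#' @param scans named list of window-statistic data.frames (`chrom`,
#'   `start`, `end`, `value`).
#' @param top_q top quantile (default 0.01).
#' @param min_methods minimum number of supporting scans (default 2).
#' @return list with `windows` (common grid + per-scan ranks + `n_hits` +
#'   `candidate`) and `regions` (merged candidate regions with supporting
#'   methods).
#' @export
rank_and_intersect <- function(scans, top_q = 0.01, min_methods = 2) {
  stopifnot(length(scans) >= 2, !is.null(names(scans)))
  sizes <- vapply(scans, function(s) median(s$end - s$start), 0)
  base <- scans[[which.max(sizes)]]
  grid <- base[, c("chrom", "start", "end")]
  nw <- nrow(grid)
  if (any(vapply(scans, nrow, 0L) < 100))
    stop("refusing empirical ranking with fewer than 100 windows")
  ranks <- matrix(NA_real_, nw, length(scans),
                  dimnames = list(NULL, names(scans)))
  for (s in seq_along(scans)) {
    sc <- scans[[s]]
    v <- .resample_max_overlap(grid, sc)
    ok <- is.finite(v)
    rk <- rep(NA_real_, nw)
    # fraction of finite windows with value >= this value
    rk[ok] <- (length(v[ok]) - rank(v[ok], ties.method = "min") + 1) /
      length(v[ok])
    ranks[, s] <- rk
  }
  hits <- ranks <= top_q
  n_hits <- rowSums(hits, na.rm = TRUE)
  cand <- n_hits >= min_methods
  windows <- data.frame(grid, ranks, n_hits = n_hits, candidate = cand)
  regions <- .merge_adjacent(windows[cand, , drop = FALSE],
                             colnames(ranks), hits[cand, , drop = FALSE])
  list(windows = windows, regions = regions)
}

.resample_max_overlap <- function(grid, sc) {
  v <- rep(NA_real_, nrow(grid))
  for (cc in unique(grid$chrom)) {
    gi <- which(grid$chrom == cc); si <- which(sc$chrom == cc)
    if (!length(si)) next
    for (i in gi) {
      ov <- pmin(grid$end[i], sc$end[si]) - pmax(grid$start[i], sc$start[si])
      b <- which.max(ov)
      if (length(b) && ov[b] > 0) v[i] <- sc$value[si[b]]
    }
  }
  v
}

.merge_adjacent <- function(wins, methods, hitm) {
  if (!nrow(wins))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0),
                      methods = character(0)))
  wins <- wins[order(wins$chrom, wins$start), , drop = FALSE]
  hitm <- hitm[order(wins$chrom, wins$start), , drop = FALSE]
  out <- NULL
  cur <- wins[1, ]; mset <- methods[which(hitm[1, ])]; nwin <- 1L
  for (i in seq_len(nrow(wins))[-1]) {
    if (wins$chrom[i] == cur$chrom && wins$start[i] <= cur$end) {
      cur$end <- max(cur$end, wins$end[i])
      mset <- union(mset, methods[which(hitm[i, ])])
      nwin <- nwin + 1L
    } else {
      out <- rbind(out, data.frame(chrom = cur$chrom, start = cur$start,
                                   end = cur$end, n_windows = nwin,
                                   methods = paste(sort(mset),
                                                   collapse = ",")))
      cur <- wins[i, ]; mset <- methods[which(hitm[i, ])]; nwin <- 1L
    }
  }
  rbind(out, data.frame(chrom = cur$chrom, start = cur$start, end = cur$end,
                        n_windows = nwin,
                        methods = paste(sort(mset), collapse = ",")))
}
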