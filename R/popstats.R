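#' Sliding-window grid over the contigs of a site table
#'
#' Windows are 0-based half-open, anchored at position 0 of each
#' chromosome; the last partial window is kept and flagged.
#'
#' @param x a [site_table()].
#' @param win,step window and step size in bp.
#' @return data.frame `chrom`, `start`, `end`, `partial`.
#' @export
window_grid <- function(x, win, step = win) {
  lens <- x$contig_len
  if (is.null(lens)) {
    lens <- tapply(x$pos, x$chrom, max)
    lens <- setNames(as.numeric(lens), names(lens))
  }
  out <- lapply(names(lens), function(cc) {
    L <- lens[[cc]]
    starts <- seq(0, max(0, L - 1), by = step)
    ends <- pmin(starts + win, L)
    keep <- ends > starts
    data.frame(chrom = cc, start = starts[keep], end = ends[keep],
               partial = ends[keep] - starts[keep] < win)
  })
  do.call(rbind, out)
}

# per-site heterozygosity 2j(n-j)/(n(n-1)) from a dosage matrix
.site_pi <- function(g) {
  nn <- 2 * rowSums(!is.na(g))
  j <- rowSums(g, na.rm = TRUE)
  h <- ifelse(nn >= 2, 2 * j * (nn - j) / (nn * (nn - 1)), NA_real_)
  list(h = h, n = nn, j = j)
}

# assign sites to windows of a grid; returns list of row-index vectors
.window_sites <- function(grid, chrom, pos) {
  lapply(seq_len(nrow(grid)), function(i) {
    which(chrom == grid$chrom[i] & pos - 1L >= grid$start[i] &
            pos - 1L < grid$end[i])
  })
}

#' Windowed nucleotide diversity (pi)
#'
#' Per-site pi is 2j(n-j)/(n(n-1)) for alt count j among n non-missing
#' haplotypes; the window value is the per-site sum divided by the window
#' length in bp. Windows of 50 kb with a 20 kb step are the scan default.
#'
#' @param x a [site_table()].
#' @param samples sample subset (default all).
#' @param win,step window / step in bp.
#' @return data.frame of window statistics (`chrom`, `start`, `end`,
#'   `n_sites`, `value`, `flagged`).
#' @export
pi_windows <- function(x, samples = x$samples, win = 50000, step = 20000) {
  g <- x$gt[, samples, drop = FALSE]
  if (2 * length(samples) < 2) stop("need >= 2 haplotypes")
  sp <- .site_pi(g)
  grid <- window_grid(x, win, step)
  idx <- .window_sites(grid, x$chrom, x$pos)
  val <- vapply(seq_along(idx), function(i) {
    h <- sp$h[idx[[i]]]
    sum(h, na.rm = TRUE) / (grid$end[i] - grid$start[i])
  }, 0)
  ns <- vapply(idx, function(i) sum(!is.na(sp$h[i])), 0L)
  data.frame(grid[, c("chrom", "start", "end")], n_sites = ns,
             value = val, flagged = ns == 0 | grid$partial)
}

# Tajima's D constants for n haplotypes
.tajima_const <- function(n) {
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' D = (pi_hat - S/a1) / sqrt(e1 S + e2 S (S-1)) with the standard
#' constants; pi_hat is the window sum of per-site mean pairwise
#' differences. Windows with no segregating sites are NaN and flagged.
#' Default grid: nonoverlapping 2-kb windows.
#'
#' @inheritParams pi_windows
#' @return data.frame of window statistics; `value` is D.
#' @export
tajimas_d <- function(x, samples = x$samples, win = 2000, step = 2000) {
  g <- x$gt[, samples, drop = FALSE]
  if (2 * length(samples) < 4) stop("Tajima's D needs >= 4 haplotypes")
  sp <- .site_pi(g)
  seg <- !is.na(sp$h) & sp$j > 0 & sp$j < sp$n & sp$n >= 4
  grid <- window_grid(x, win, step)
  idx <- .window_sites(grid, x$chrom, x$pos)
  val <- rep(NaN, nrow(grid)); ns <- integer(nrow(grid))
  for (i in seq_along(idx)) {
    ii <- idx[[i]][seg[idx[[i]]]]
    S <- length(ii); ns[i] <- S
    if (S == 0) next
    n_use <- round(median(sp$n[ii]))
    cst <- .tajima_const(n_use)
    pihat <- sum(sp$h[ii])
    denom <- sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
    val[i] <- (pihat - S / cst$a1) / denom
  }
  data.frame(grid[, c("chrom", "start", "end")], n_sites = ns,
             value = val, flagged = ns == 0 | grid$partial)
}

#' Diversity log-ratio between matched window grids
#'
#' value = ln(pi_target) - ln(pi_reference) per window; windows where
#' either pi is zero are NaN and flagged. Diversity troughs in the target
#' give strongly negative values.
#'
#' @param target_pi,reference_pi window tables from [pi_windows()] on the
#'   same grid.
#' @return data.frame of window statistics.
#' @export
theta_pi_ratio <- function(target_pi, reference_pi) {
  if (nrow(target_pi) != nrow(reference_pi) ||
      any(target_pi$chrom != reference_pi$chrom) ||
      any(target_pi$start != reference_pi$start) ||
      any(target_pi$end != reference_pi$end))
    stop("window grids do not match")
  v <- ifelse(target_pi$value > 0 & reference_pi$value > 0,
              log(target_pi$value) - log(reference_pi$value), NaN)
  data.frame(target_pi[, c("chrom", "start", "end")],
             n_sites = pmin(target_pi$n_sites, reference_pi$n_sites),
             value = v, flagged = !is.finite(v))
}

# Weir-Cockerham (1984) two-population per-site variance components.
# gA, gB: dosage matrices (sites x diploids). Returns a, b, c vectors.
wc_site_components <- function(gA, gB) {
  r <- 2
  nA <- rowSums(!is.na(gA)); nB <- rowSums(!is.na(gB))
  pA <- rowSums(gA, na.rm = TRUE) / (2 * nA)
  pB <- rowSums(gB, na.rm = TRUE) / (2 * nB)
  hA <- rowSums(gA == 1, na.rm = TRUE) / nA
  hB <- rowSums(gB == 1, na.rm = TRUE) / nB
  nbar <- (nA + nB) / 2
  nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / (r * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, usable = nA >= 2 & nB >= 2,
       poly = !(pA == 0 & pB == 0) & !(pA == 1 & pB == 1))
}

#' Windowed Weir-Cockerham FST between two populations
#'
#' Per-site variance components a, b, c (two populations, diploid); the
#' window value is the ratio of sums sum(a) / sum(a+b+c) — the "weighted"
#' estimator. Sites monomorphic across both populations are skipped;
#' negative window values are retained.
#'
#' @param x a [site_table()].
#' @param popA,popB character vectors of sample names.
#' @param win,step window / step in bp.
#' @return data.frame of window statistics.
#' @export
wc_fst_windows <- function(x, popA, popB, win = 50000, step = 20000) {
  if (!length(popA) || !length(popB)) stop("empty population")
  comp <- wc_site_components(x$gt[, popA, drop = FALSE],
                             x$gt[, popB, drop = FALSE])
  use <- comp$usable & comp$poly
  grid <- window_grid(x, win, step)
  idx <- .window_sites(grid, x$chrom, x$pos)
  val <- rep(NaN, nrow(grid)); ns <- integer(nrow(grid))
  for (i in seq_along(idx)) {
    ii <- idx[[i]][use[idx[[i]]]]
    ns[i] <- length(ii)
    if (!length(ii)) next
    denom <- sum(comp$a[ii] + comp$b[ii] + comp$c[ii])
    if (denom != 0) val[i] <- sum(comp$a[ii]) / denom
  }
  data.frame(grid[, c("chrom", "start", "end")], n_sites = ns,
             value = val, flagged = ns == 0 | grid$partial)
}

#' KING-robust pairwise kinship
#'
#' Within-cohort robust estimator
#' phi = (N_Aa,Aa - 2 N_AA,aa) / (N_Aa(i) + N_Aa(j)) from heterozygote and
#' opposite-homozygote counts, with the standard KING degree thresholds:
#' phi >= 0.3536 duplicate/MZ; (0.1768, 0.3536] 1st degree;
#' (0.0884, 0.1768] 2nd degree; below unrelated. Pairs with fewer than 100
#' jointly non-missing sites get phi = NaN and a flag.
#'
#' @param x a [site_table()].
#' @param samples sample subset (default all).
#' @return data.frame `id1`, `id2`, `n_sites`, `phi`, `degree`,
#'   `flag_related` (TRUE for 2nd degree or closer).
#' @export
king_kinship <- function(x, samples = x$samples) {
  g <- x$gt[, samples, drop = FALSE]
  poly <- rowSums(g, na.rm = TRUE) > 0 &
    rowSums(g, na.rm = TRUE) < 2 * rowSums(!is.na(g))
  if (sum(poly) < 1000)
    warning("fewer than 1,000 informative sites; kinship may be unstable")
  g <- g[poly, , drop = FALSE]
  ns <- length(samples)
  out <- NULL
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    gi <- g[, i]; gj <- g[, j]
    ok <- !is.na(gi) & !is.na(gj)
    n <- sum(ok)
    if (n < 100) {
      out <- rbind(out, data.frame(id1 = samples[i], id2 = samples[j],
                                   n_sites = n, phi = NaN,
                                   degree = "undetermined",
                                   flag_related = NA))
      next
    }
    het_het <- sum(gi[ok] == 1 & gj[ok] == 1)
    opp_hom <- sum((gi[ok] == 0 & gj[ok] == 2) | (gi[ok] == 2 & gj[ok] == 0))
    het_i <- sum(gi[ok] == 1); het_j <- sum(gj[ok] == 1)
    phi <- (het_het - 2 * opp_hom) / (het_i + het_j)
    degree <- if (phi >= 0.3536) "duplicate"
      else if (phi >= 0.1768) "1st"
      else if (phi >= 0.0884) "2nd"
      else "unrelated"
    out <- rbind(out, data.frame(id1 = samples[i], id2 = samples[j],
                                 n_sites = n, phi = phi, degree = degree,
                                 flag_related = degree != "unrelated"))
  }
  out
}
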