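#' Weighted-LD decay curve for single-pulse admixture dating
#'
#' For site pairs binned by genetic distance, accumulates the covariance
#' of target genotypes weighted by the product of the reference panels'
#' allele-frequency contrasts (p_A - p_B) at the two sites. The bin value
#' is the weighted regression amplitude sum(cov * w) / sum(w^2) with
#' w = w_x * w_y, which under a single pulse decays as
#' 2 m (1 - m) exp(-g d) with distance d in Morgans. Reference frequencies
#' come from the panels only; the target never enters the weights. Curves
#' are accumulated per chromosome so the fit can be jackknifed.
#'
#' @param target a [site_table()] of the admixed cohort (genotypes;
#'   phasing not required).
#' @param refA,refB phased or unphased [site_table()]s for the two source
#'   panels, on the identical site list.
#' @param cM_per_Mb constant genetic map rate, or `map` (below).
#' @param map optional data.frame `chrom`, `pos`, `cM` (monotone within
#'   chromosome) overriding the constant rate.
#' @param bin_cM,max_cM bin width and largest pair distance in cM.
#' @param min_pairs bins with fewer pairs are dropped at fit time.
#' @param max_sites per-chromosome cap on sites used (even thinning).
#' @return A `decay_curve`: `bins` (left edge, mid cM, value, n_pairs) and
#'   per-chromosome accumulators for the jackknife.
#' @export
weighted_ld_curve <- function(target, refA, refB, cM_per_Mb = 1, map = NULL,
                              bin_cM = 0.05, max_cM = 10, min_pairs = 50,
                              max_sites = 2000) {
  stopifnot(length(target$pos) == length(refA$pos),
            length(target$pos) == length(refB$pos))
  cm_all <- .genetic_pos(target, cM_per_Mb, map)
  pA <- alt_freq(refA); pB <- alt_freq(refB)
  w_all <- pA - pB
  nb <- ceiling(max_cM / bin_cM)
  chroms <- unique(target$chrom)
  per_chr <- array(0, dim = c(nb, 3, length(chroms)),
                   dimnames = list(NULL, c("num", "den", "n"), chroms))
  for (ci in seq_along(chroms)) {
    ii <- which(target$chrom == chroms[ci])
    if (length(ii) > max_sites)
      ii <- ii[unique(round(seq(1, length(ii), length.out = max_sites)))]
    G <- target$gt[ii, , drop = FALSE]
    G <- G - rowMeans(G, na.rm = TRUE)
    G[is.na(G)] <- 0
    per_chr[, , ci] <- wld_pair_bins(G, w_all[ii], cm_all[ii], bin_cM,
                                     max_cM)
  }
  num <- apply(per_chr[, "num", , drop = FALSE], 1, sum)
  den <- apply(per_chr[, "den", , drop = FALSE], 1, sum)
  npair <- apply(per_chr[, "n", , drop = FALSE], 1, sum)
  bins <- data.frame(left_cM = (seq_len(nb) - 1) * bin_cM,
                     mid_cM = (seq_len(nb) - 0.5) * bin_cM,
                     value = ifelse(den > 0, num / den, NA_real_),
                     n_pairs = npair)
  structure(list(bins = bins, per_chr = per_chr, bin_cM = bin_cM,
                 max_cM = max_cM, min_pairs = min_pairs,
                 chroms = chroms),
            class = "decay_curve")
}

.genetic_pos <- function(x, cM_per_Mb, map) {
  if (is.null(map)) return((x$pos - 1) / 1e6 * cM_per_Mb)
  out <- rep(NA_real_, length(x$pos))
  for (cc in unique(x$chrom)) {
    m <- map[map$chrom == cc, , drop = FALSE]
    if (is.unsorted(m$cM) || is.unsorted(m$pos))
      stop("genetic map must be monotone within chromosome")
    ii <- which(x$chrom == cc)
    out[ii] <- approx(m$pos, m$cM, xout = x$pos[ii], rule = 2)$y
  }
  out
}

#' @export
print.decay_curve <- function(x, ...) {
  ok <- is.finite(x$bins$value) & x$bins$n_pairs >= x$min_pairs
  cat(sprintf("decay_curve: %d/%d usable bins (%.2f-%.2f cM), %d chrom\n",
              sum(ok), nrow(x$bins), x$bin_cM, x$max_cM,
              length(x$chroms)))
  invisible(x)
}

#' Fit the exponential admixture-LD decay model
#'
#' Nonlinear least squares for value = A exp(-n d) + c with d in Morgans;
#' n is the admixture age in generations. Uncertainty comes from a
#' leave-one-chromosome-out jackknife (the curve is re-aggregated and
#' refit per deletion; standard jackknife variance). Bins closer than
#' `d_min_cM` are excluded to avoid background LD, as are bins with fewer
#' than `min_pairs` pairs.
#'
#' @param curve a `decay_curve` from [weighted_ld_curve()].
#' @param d_min_cM smallest fitted distance (default 0.5 cM).
#' @return list `A`, `n_hat`, `c`, `se` (jackknife SE of n_hat, NA with a
#'   single chromosome), `ci95` (n_hat -/+ 1.96 se), `bins_used`,
#'   `jackknife` (per-chromosome estimates), `flag` ("ok" or
#'   "no_dateable_admixture").
#' @export
fit_decay <- function(curve, d_min_cM = 0.5) {
  stopifnot(inherits(curve, "decay_curve"))
  fit1 <- function(bins) {
    use <- is.finite(bins$value) & bins$n_pairs >= curve$min_pairs &
      bins$mid_cM >= d_min_cM
    if (sum(use) < 10) stop("fewer than 10 usable bins")
    d <- bins$mid_cM[use] / 100
    v <- bins$value[use]
    c0 <- min(v); A0 <- max(v) - c0
    if (A0 <= 0) return(list(A = 0, n = NA_real_, c = c0))
    pos <- v - c0 + A0 * 1e-3
    lf <- stats::lm(log(pmax(pos, A0 * 1e-4)) ~ d)
    n0 <- max(1, min(2000, -coef(lf)[2]))
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ A * exp(-n * d) + c,
                        start = list(A = A0, n = n0, c = c0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) stop("decay fit did not converge: ",
                               conditionMessage(e)))
    co <- coef(fit)
    list(A = unname(co["A"]), n = unname(co["n"]), c = unname(co["c"]))
  }
  full <- fit1(curve$bins)
  flag <- if (is.na(full$n) || full$A <= 0) "no_dateable_admixture" else "ok"
  n_chr <- dim(curve$per_chr)[3]
  jk <- rep(NA_real_, n_chr)
  se <- NA_real_
  if (flag == "ok" && n_chr > 1) {
    for (ci in seq_len(n_chr)) {
      num <- apply(curve$per_chr[, "num", -ci, drop = FALSE], 1, sum)
      den <- apply(curve$per_chr[, "den", -ci, drop = FALSE], 1, sum)
      np <- apply(curve$per_chr[, "n", -ci, drop = FALSE], 1, sum)
      bins <- data.frame(mid_cM = curve$bins$mid_cM,
                         value = ifelse(den > 0, num / den, NA_real_),
                         n_pairs = np)
      jk[ci] <- tryCatch(fit1(bins)$n, error = function(e) NA_real_)
    }
    ok <- is.finite(jk)
    if (sum(ok) >= 2) {
      C <- sum(ok)
      se <- sqrt((C - 1) / C * sum((jk[ok] - mean(jk[ok]))^2))
    }
  }
  use <- is.finite(curve$bins$value) &
    curve$bins$n_pairs >= curve$min_pairs & curve$bins$mid_cM >= d_min_cM
  list(A = full$A, n_hat = full$n, c = full$c, se = se,
       ci95 = if (is.finite(se)) full$n + c(-1.96, 1.96) * se else
         c(NA_real_, NA_real_),
       bins_used = sum(use), jackknife = jk, flag = flag)
}

#' Admixture age from mean ancestry-tract lengths
#'
#' Under a single pulse, maximal ancestry-a tracts (proportion m_a) have
#' exponential lengths with mean 1 / ((1 - m_a) g) Morgans, so
#' g_hat = 1 / ((1 - m_a) mean_tract_length_Morgans); chromosome-end
#' censored tracts are excluded. Adjacent same-ancestry pieces are merged
#' into maximal runs first (a no-op for painting-derived tracts, which are
#' already maximal).
#'
#' @param tracts tract data.frame ([ancestry_tracts()] or simulator
#'   truth; columns `hap`, `chrom`, `start_bp`, `end_bp`, `ancestry`,
#'   `censored_left`, `censored_right`).
#' @param m per-ancestry genome-wide proportions.
#' @param cM_per_Mb constant genetic map rate.
#' @return data.frame `ancestry`, `m`, `n_tracts`, `mean_len_M`, `g_hat`,
#'   `wide_flag` (TRUE when < 30 uncensored tracts).
#' @export
tract_length_date <- function(tracts, m, cM_per_Mb = 1) {
  tracts <- .merge_tracts(tracts)
  K <- length(m)
  out <- .tld_core(tracts, m, K, cM_per_Mb)
  out
}

# merge adjacent same-ancestry pieces into maximal runs per hap/chrom
.merge_tracts <- function(tr) {
  tr <- tr[order(tr$hap, tr$chrom, tr$start_bp), , drop = FALSE]
  key <- paste(tr$hap, tr$chrom)
  new_run <- c(TRUE, key[-1] != key[-nrow(tr)] |
                 tr$ancestry[-1] != tr$ancestry[-nrow(tr)] |
                 tr$start_bp[-1] != tr$end_bp[-nrow(tr)])
  id <- cumsum(new_run)
  data.frame(
    hap = tr$hap[new_run], chrom = tr$chrom[new_run],
    start_bp = tr$start_bp[new_run],
    end_bp = as.numeric(tapply(tr$end_bp, id, max)),
    ancestry = tr$ancestry[new_run],
    censored_left = as.logical(tapply(tr$censored_left, id, any)),
    censored_right = as.logical(tapply(tr$censored_right, id, any)))
}

.tld_core <- function(tracts, m, K, cM_per_Mb) {
  out <- NULL
  for (k in seq_len(K)) {
    if (m[k] <= 0) next
    if (m[k] > 0.99)
      stop("tract dating undefined for near-fixed ancestry (m > 0.99)")
    tr <- tracts[tracts$ancestry == k & !tracts$censored_left &
                   !tracts$censored_right, , drop = FALSE]
    nt <- nrow(tr)
    wide <- nt < 30
    if (wide && nt > 0)
      warning("ancestry ", k, ": only ", nt,
              " uncensored tracts; estimate is wide")
    if (nt == 0) {
      out <- rbind(out, data.frame(ancestry = k, m = m[k], n_tracts = 0L,
                                   mean_len_M = NA_real_, g_hat = NA_real_,
                                   wide_flag = TRUE))
      next
    }
    len_M <- (tr$end_bp - tr$start_bp) * cM_per_Mb / 1e6 / 100
    Lbar <- mean(len_M)
    out <- rbind(out, data.frame(ancestry = k, m = m[k], n_tracts = nt,
                                 mean_len_M = Lbar,
                                 g_hat = 1 / ((1 - m[k]) * Lbar),
                                 wide_flag = wide))
  }
  out
}
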