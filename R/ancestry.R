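#' Paint one target haplotype against labelled reference panels
#'
#' Dynamic-programming haplotype copying: states are the reference
#' haplotypes, the per-site cost is 1 per allele mismatch and `lambda` per
#' template switch; the ancestry call at a site is the panel label of the
#' copied template on the optimal path. The final call is a per-site
#' majority vote across the `lambda_grid` (ties go to the smallest
#' lambda's call), echoing the bagging spirit of reference-copying
#' painters.
#'
#' @param target integer 0/1 vector (alleles of one haplotype).
#' @param panel_haps integer matrix sites x n_panel_haps.
#' @param panel_anc integer ancestry code (1..K) per panel haplotype.
#' @param lambda_grid switch penalties (default `c(1, 1.5, 2, 3, 5)`).
#' @return integer vector of ancestry codes per site.
#' @export
paint_haplotype <- function(target, panel_haps, panel_anc,
                            lambda_grid = c(1, 1.5, 2, 3, 5)) {
  stopifnot(length(panel_anc) == ncol(panel_haps),
            length(target) == nrow(panel_haps))
  if (length(unique(panel_anc)) < 1 || any(tabulate(panel_anc) == 0 &
        seq_along(tabulate(panel_anc)) %in% panel_anc))
    stop("empty reference panel for an ancestry")
  calls <- vapply(lambda_grid, function(l) {
    path <- paint_dp_path(as.integer(target), panel_haps, l)
    panel_anc[path]
  }, integer(length(target)))
  if (length(lambda_grid) == 1) return(as.integer(calls))
  apply(calls, 1, function(v) {
    tb <- tabulate(v)
    w <- which(tb == max(tb))
    if (length(w) == 1) w else v[1]       # tie -> smallest lambda's call
  })
}

#' Paint every haplotype of a cohort, per chromosome
#'
#' @param target a phased [site_table()] (the admixed cohort).
#' @param panels a `ref_panels` object from [make_panels()], or a list with
#'   elements `haps` (list of phased site_tables) and `labels`.
#' @param lambda_grid switch penalties.
#' @return An `ancestry_painting`: list with `anc` (integer matrix sites x
#'   haplotypes of ancestry codes), `labels`, `target`, `K`.
#' @export
paint_cohort <- function(target, panels, lambda_grid = c(1, 1.5, 2, 3, 5)) {
  ph <- lapply(seq_along(panels$haps), function(k)
    hap_matrix(panels$haps[[k]]))
  if (!is.null(panels$cfg))
    ph <- lapply(seq_along(ph), function(k)
      ph[[k]][, seq_len(panels$cfg$n_ref), drop = FALSE])
  panel_anc <- rep(seq_along(ph), vapply(ph, ncol, 0L))
  P <- do.call(cbind, ph)
  H <- target$hap
  anc <- matrix(NA_integer_, nrow(H), ncol(H))
  for (cc in unique(target$chrom)) {
    ii <- which(target$chrom == cc)
    for (h in seq_len(ncol(H)))
      anc[ii, h] <- paint_haplotype(H[ii, h], P[ii, , drop = FALSE],
                                    panel_anc, lambda_grid)
  }
  structure(list(anc = anc, labels = panels$labels %||%
                   paste0("anc", seq_along(ph)),
                 target = target, K = length(ph)),
            class = "ancestry_painting")
}

#' @export
print.ancestry_painting <- function(x, ...) {
  cat(sprintf("ancestry_painting: %d sites x %d haplotypes, K=%d\n",
              nrow(x$anc), ncol(x$anc), x$K))
  invisible(x)
}

#' Per-haplotype ancestry tracts from a painting
#'
#' Maximal constant-ancestry runs, with bp bounds at the midpoints between
#' flanking sites and chromosome ends at 0 / contig length (0-based
#' half-open; tracts tile each chromosome).
#'
#' @param painting an `ancestry_painting`.
#' @return data.frame `hap`, `chrom`, `start_bp`, `end_bp`, `ancestry`,
#'   `censored_left`, `censored_right`, `cM` (tract genetic length under
#'   the constant map attached by the caller via `attr(,"cM_per_Mb")`).
#' @export
ancestry_tracts <- function(painting) {
  st <- painting$target
  lens <- st$contig_len %||%
    setNames(as.numeric(tapply(st$pos, st$chrom, max)), unique(st$chrom))
  out <- NULL
  for (cc in unique(st$chrom)) {
    ii <- which(st$chrom == cc)
    pos0 <- st$pos[ii] - 1
    L <- lens[[cc]]
    mids <- c(0, floor((pos0[-1] + pos0[-length(pos0)]) / 2) + 1, L)
    for (h in seq_len(ncol(painting$anc))) {
      a <- painting$anc[ii, h]
      r <- rle(a)
      e <- cumsum(r$lengths); s <- e - r$lengths + 1L
      out <- rbind(out, data.frame(
        hap = h, chrom = cc, start_bp = mids[s], end_bp = mids[e + 1],
        ancestry = r$values,
        censored_left = s == 1L, censored_right = e == length(a)))
    }
  }
  out
}

#' Genome-wide ancestry proportions from a painting
#'
#' proportion = total bp assigned to the ancestry / total painted bp,
#' using the tract tiling of [ancestry_tracts()]; proportions sum to 1.
#'
#' @param painting an `ancestry_painting` (or a tract data.frame).
#' @return named numeric vector of per-ancestry proportions.
#' @export
global_proportions <- function(painting) {
  tr <- if (is.data.frame(painting)) painting else
    ancestry_tracts(painting)
  if (!nrow(tr)) stop("empty painting")
  K <- if (is.data.frame(painting)) max(tr$ancestry) else painting$K
  len <- tr$end_bp - tr$start_bp
  p <- vapply(seq_len(K), function(k) sum(len[tr$ancestry == k]), 0)
  p <- p / sum(p)
  names(p) <- if (!is.data.frame(painting)) painting$labels else
    paste0("anc", seq_len(K))
  p
}

#' Segment the cohort painting and test for ancestry excess
#'
#' Segment boundaries fall wherever any haplotype's ancestry call changes;
#' segments are maximal intervals with a constant cohort ancestry-count
#' vector, spanning from their first site to the next segment's first site
#' (0-based half-open, extended to the chromosome ends). For each segment
#' and ancestry with haplotype count x of 2N, f = x / 2N and the one-sided
#' upper-tail Z test against the genome-wide proportion p is
#' Z = (f - p) / sqrt(p (1 - p) / 2N). Segments with f at least `f_min`,
#' length at least `len_min` bp and p-value below `alpha` are retained as
#' high-frequency ancestral fragments; no multiple-testing correction is
#' applied.
#'
#' @param painting an `ancestry_painting`.
#' @param genome_p genome-wide proportion per ancestry (from
#'   [global_proportions()]).
#' @param f_min minimum segment haplotype frequency (default 0.75).
#' @param len_min minimum segment length in bp (default 1000).
#' @param alpha retention p-value threshold (default 0.01).
#' @return list with `segments` (every segment x ancestry with f > 0:
#'   `chrom`, `start`, `end`, `ancestry`, `f`, `z`, `p`, `length`,
#'   `retained`) and `retained` (the filtered subset).
#' @export
segment_and_test <- function(painting, genome_p, f_min = 0.75,
                             len_min = 1000, alpha = 0.01) {
  st <- painting$target
  n_hap <- ncol(painting$anc)
  if (n_hap < 10) warning("2N < 10: normal approximation is weak")
  lens <- st$contig_len %||%
    setNames(as.numeric(tapply(st$pos, st$chrom, max)), unique(st$chrom))
  segs <- NULL
  for (cc in unique(st$chrom)) {
    ii <- which(st$chrom == cc)
    A <- painting$anc[ii, , drop = FALSE]
    chg <- c(TRUE, rowSums(A[-1, , drop = FALSE] !=
                             A[-length(ii), , drop = FALSE]) > 0)
    sid <- cumsum(chg)
    first <- ii[!duplicated(sid)]
    pos0 <- st$pos[first] - 1
    starts <- c(0, pos0[-1])
    ends <- c(pos0[-1], lens[[cc]])
    for (s in seq_along(first)) {
      cnt <- tabulate(A[first[s] - ii[1] + 1, ], nbins = painting$K)
      segs <- rbind(segs, data.frame(
        chrom = cc, start = starts[s], end = ends[s],
        ancestry = seq_len(painting$K), count = cnt))
    }
  }
  segs <- segs[segs$count > 0, , drop = FALSE]
  segs$f <- segs$count / n_hap
  p <- genome_p[segs$ancestry]
  segs$z <- (segs$f - p) / sqrt(p * (1 - p) / n_hap)
  segs$p <- pnorm(segs$z, lower.tail = FALSE)
  segs$length <- segs$end - segs$start
  segs$retained <- segs$f >= f_min & segs$length >= len_min & segs$p < alpha
  rownames(segs) <- NULL
  list(segments = segs, retained = segs[segs$retained, , drop = FALSE])
}

#' Screen nonsynonymous sites by contrasting population frequencies
#'
#' Keeps nonsynonymous sites whose alternate-allele frequency exceeds
#' `target_freq_min` in the target population and stays below
#' `ref_freq_max` in the reference population. Sites with no called
#' genotypes in either population are excluded and counted.
#'
#' @param x a [site_table()].
#' @param classes output of [classify_sites()] with a `coding_effect`
#'   column.
#' @param target_pop,ref_pop character vectors of sample names.
#' @param target_freq_min,ref_freq_max frequency thresholds (defaults 0.7
#'   and 0.2).
#' @return data.frame of passing sites (`chrom`, `pos`, `ref`, `alt`,
#'   `freq_target`, `freq_ref`); excluded-site count in
#'   `attr(,"excluded")`.
#' @export
missense_screen <- function(x, classes, target_pop, ref_pop,
                            target_freq_min = 0.7, ref_freq_max = 0.2) {
  if (is.null(classes$coding_effect))
    stop("classes must carry a coding_effect column (CDS-aware run)")
  nonsyn <- !is.na(classes$coding_effect) &
    classes$coding_effect == "nonsynonymous"
  ft <- alt_freq(x, target_pop)
  fr <- alt_freq(x, ref_pop)
  miss <- nonsyn & (!is.finite(ft) | !is.finite(fr))
  keep <- nonsyn & !miss & ft > target_freq_min & fr < ref_freq_max
  out <- data.frame(chrom = x$chrom[keep], pos = x$pos[keep],
                    ref = x$ref[keep], alt = x$alt[keep],
                    freq_target = ft[keep], freq_ref = fr[keep])
  attr(out, "excluded") <- sum(miss)
  out
}
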