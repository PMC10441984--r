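#' Configuration for the synthetic admixed-cohort simulator
#'
#' Defines K source populations diverged from a common ancestor under the
#' Balding-Nichols model, and a target cohort formed by a single-pulse
#' admixture event `g` generations ago with mixing proportions `m`.
#' Ancestry tracts along each target haplotype follow a Poisson breakpoint
#' process with rate `g` per Morgan; within a tract the haplotype copies one
#' panel haplotype of the tract's ancestry, flipping each allele with
#' probability `eps`.
#'
#' @param K number of ancestries.
#' @param F Balding-Nichols divergence per ancestry (scalar or length K),
#'   each in [0, 1).
#' @param n_ref haplotypes per reference panel.
#' @param n_adm number of admixed diploid individuals.
#' @param L_bp chromosome length in bp (per chromosome).
#' @param n_sites SNP count per chromosome.
#' @param n_chr number of chromosomes.
#' @param cM_per_Mb constant recombination rate (bp -> cM).
#' @param m mixing proportions, length K, summing to 1.
#' @param g generations since the single admixture pulse (>= 1).
#' @param eps per-site copy-error rate in [0, 1).
#' @param seed integer seed stamped into every derived artifact.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(K = 4, F = 0.2, n_ref = 30, n_adm = 30,
                       L_bp = 50e6, n_sites = 20000, n_chr = 1,
                       cM_per_Mb = 1,
                       m = c(0.556, 0.332, 0.068, 0.044),
                       g = 30, eps = 0.001, seed = 1L) {
  F <- rep_len(F, K)
  if (length(m) != K) stop("m must have length K")
  if (abs(sum(m) - 1) > 1e-8) stop("mixing proportions must sum to 1")
  if (any(F < 0 | F >= 1)) stop("F must lie in [0, 1)")
  if (eps < 0 || eps >= 1) stop("eps must lie in [0, 1)")
  if (g < 1) stop("g must be >= 1")
  structure(list(K = K, F = F, n_ref = n_ref, n_adm = n_adm,
                 L_bp = L_bp, n_sites = n_sites, n_chr = as.integer(n_chr),
                 cM_per_Mb = cM_per_Mb, m = m, g = g, eps = eps,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate diverged reference panels under the Balding-Nichols model
#'
#' Per site an ancestral frequency p_anc ~ Uniform(0.05, 0.95) is drawn;
#' the frequency in ancestry k is Beta(p_anc (1-F)/F, (1-p_anc)(1-F)/F)
#' (exactly p_anc when F = 0). Panel haplotypes are Bernoulli draws;
#' positions are uniform over [0, L_bp), sorted, per chromosome.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `ref_panels`: `sites` (chrom, pos 1-based, cM),
#'   `freq` (sites x K ancestry frequencies), `p_anc`, `haps` (list of K
#'   phased [site_table()]s), `labels` (ancestry name per panel), `cfg`.
#' @export
make_panels <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  S <- cfg$n_sites
  chroms <- paste0("chr", seq_len(cfg$n_chr))
  chrom <- rep(chroms, each = S)
  pos <- unlist(lapply(seq_len(cfg$n_chr), function(i)
    sort(sample.int(cfg$L_bp, S)) ))
  n <- S * cfg$n_chr
  p_anc <- runif(n, 0.05, 0.95)
  freq <- matrix(NA_real_, n, cfg$K)
  for (k in seq_len(cfg$K)) {
    Fk <- cfg$F[k]
    freq[, k] <- if (Fk == 0) p_anc else
      rbeta(n, p_anc * (1 - Fk) / Fk, (1 - p_anc) * (1 - Fk) / Fk)
  }
  labels <- paste0("anc", seq_len(cfg$K))
  colnames(freq) <- labels
  contig_len <- setNames(rep(cfg$L_bp, cfg$n_chr), chroms)
  haps <- lapply(seq_len(cfg$K), function(k) {
    H <- matrix(rbinom(n * cfg$n_ref, 1, rep(freq[, k], cfg$n_ref)),
                n, cfg$n_ref)
    ns <- ceiling(cfg$n_ref / 2)
    if (cfg$n_ref %% 2 == 1) H <- cbind(H, H[, cfg$n_ref])  # pad to diploids
    gt <- H[, seq(1, 2 * ns, 2), drop = FALSE] +
          H[, seq(2, 2 * ns, 2), drop = FALSE]
    site_table(chrom, pos, rep("A", n), rep("G", n), gt,
               hap = H[, seq_len(2 * ns), drop = FALSE],
               samples = sprintf("%s_s%02d", labels[k], seq_len(ns)),
               contig_len = contig_len)
  })
  names(haps) <- labels
  structure(list(sites = data.frame(chrom = chrom, pos = pos,
                                    cM = (pos - 1) / 1e6 * cfg$cM_per_Mb),
                 freq = freq, p_anc = p_anc, haps = haps, labels = labels,
                 cfg = cfg),
            class = "ref_panels")
}

# haplotype columns of panel k as a plain matrix (n_sites x n_ref)
panel_hap <- function(panels, k) {
  H <- panels$haps[[k]]$hap
  H[, seq_len(panels$cfg$n_ref), drop = FALSE]
}

#' Simulate a single-pulse admixed cohort with known truth
#'
#' Per target haploid genome and chromosome, tract breakpoints follow a
#' Poisson process with rate `g` per Morgan; each tract's ancestry is an
#' independent draw from `m`; within a tract the haplotype copies one
#' uniformly chosen panel haplotype of that ancestry, flipping each allele
#' with probability `eps`.
#'
#' @param cfg a [sim_config()].
#' @param panels output of [make_panels()] (built from `cfg`).
#' @return A `truth_set`: `target` (phased [site_table()] of the cohort),
#'   `panels`, `tracts` (hap, chrom, start_bp, end_bp 0-based half-open,
#'   ancestry, censored flags), `true_prop` (tract-length-weighted realized
#'   ancestry shares), `g`, `cfg`, `features` (planted-feature registry).
#' @export
simulate_cohort <- function(cfg, panels) {
  stopifnot(inherits(panels, "ref_panels"))
  if (length(cfg$m) != cfg$K) stop("m length != K")
  set.seed(cfg$seed + 1L)
  S <- cfg$n_sites; n_hap <- 2L * cfg$n_adm
  L_M <- cfg$L_bp * cfg$cM_per_Mb / 1e6 / 100  # Morgans per chromosome
  chroms <- paste0("chr", seq_len(cfg$n_chr))
  hapm <- matrix(NA_integer_, S * cfg$n_chr, n_hap)
  tracts <- vector("list", n_hap * cfg$n_chr)
  ti <- 0L
  for (h in seq_len(n_hap)) {
    for (ci in seq_len(cfg$n_chr)) {
      rows <- ((ci - 1L) * S + 1L):(ci * S)
      pos <- panels$sites$pos[rows]
      # breakpoints: Poisson process, rate g per Morgan
      nb <- rpois(1, cfg$g * L_M)
      bp_M <- sort(runif(nb, 0, L_M))
      bp_bp <- floor(bp_M * 100 / cfg$cM_per_Mb * 1e6)
      bounds <- unique(c(0, bp_bp, cfg$L_bp))
      nt <- length(bounds) - 1L
      anc <- sample.int(cfg$K, nt, replace = TRUE, prob = cfg$m)
      for (t in seq_len(nt)) {
        lo <- bounds[t]; hi <- bounds[t + 1]
        idx <- which(pos > lo & pos <= hi)   # pos 1-based; tract [lo,hi)
        donor <- sample.int(cfg$n_ref, 1)
        if (length(idx)) {
          al <- panel_hap(panels, anc[t])[rows[idx], donor]
          if (cfg$eps > 0) {
            flip <- runif(length(al)) < cfg$eps
            al[flip] <- 1L - al[flip]
          }
          hapm[rows[idx], h] <- al
        }
        ti <- ti + 1L
        tracts[[ti]] <- data.frame(
          hap = h, chrom = chroms[ci], start_bp = lo, end_bp = hi,
          ancestry = anc[t],
          censored_left = lo == 0, censored_right = hi == cfg$L_bp)
      }
    }
  }
  tracts <- do.call(rbind, tracts[seq_len(ti)])
  len <- tracts$end_bp - tracts$start_bp
  true_prop <- vapply(seq_len(cfg$K), function(k)
    sum(len[tracts$ancestry == k]) / sum(len), 0)
  gt <- hapm[, seq(1, n_hap, 2), drop = FALSE] +
        hapm[, seq(2, n_hap, 2), drop = FALSE]
  target <- site_table(panels$sites$chrom, panels$sites$pos,
                       rep("A", nrow(hapm)), rep("G", nrow(hapm)),
                       gt, hap = hapm,
                       samples = sprintf("adm_s%02d", seq_len(cfg$n_adm)),
                       contig_len = setNames(rep(cfg$L_bp, cfg$n_chr),
                                             chroms))
  structure(list(target = target, panels = panels, tracts = tracts,
                 true_prop = true_prop, g = cfg$g, cfg = cfg,
                 features = data.frame(kind = character(0),
                                       chrom = character(0),
                                       start = numeric(0), end = numeric(0),
                                       ancestry = integer(0),
                                       f = numeric(0))),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf(
    "truth_set: %d diploids, %d sites x %d chr, K=%d, g=%g, realized m = %s\n",
    x$cfg$n_adm, x$cfg$n_sites, x$cfg$n_chr, x$cfg$K, x$g,
    paste(sprintf("%.3f", x$true_prop), collapse = "/")))
  invisible(x)
}

#' Plant positive-control features into a simulated cohort
#'
#' Three kinds of planted feature provide detector positive controls:
#' `excess` re-assigns ancestry `a` to a fraction `f` of haplotypes within
#' the interval (re-copying alleles from that ancestry's panel); `sweep`
#' replaces a fraction `f` of haplotypes in the interval with a single
#' donor haplotype (extended homozygosity and a skewed frequency spectrum);
#' `roh` copies haplotype 1 onto haplotype 2 of the chosen diploids over
#' the interval. Intervals are 0-based half-open bp. Planted features of
#' different kinds must not overlap.
#'
#' @param truth a `truth_set` from [simulate_cohort()].
#' @param features data.frame with columns `kind` ("excess", "sweep",
#'   "roh"), `chrom`, `start`, `end`, and per kind: `ancestry` + `f`
#'   (excess), `f` (sweep), `n_ind` (roh).
#' @return The modified `truth_set`, registry updated.
#' @export
plant_features <- function(truth, features) {
  stopifnot(inherits(truth, "truth_set"))
  cfg <- truth$cfg
  if (any(features$start < 0 | features$end > cfg$L_bp))
    stop("requested interval outside chromosome")
  if (nrow(features) > 1) {
    for (i in seq_len(nrow(features) - 1)) for (j in (i + 1):nrow(features)) {
      if (features$chrom[i] == features$chrom[j] &&
          features$kind[i] != features$kind[j] &&
          features$start[i] < features$end[j] &&
          features$start[j] < features$end[i])
        stop("overlapping planted features of different kinds")
    }
  }
  set.seed(cfg$seed + 2L)
  st <- truth$target
  n_hap <- 2L * cfg$n_adm
  for (i in seq_len(nrow(features))) {
    fe <- features[i, ]
    idx <- which(st$chrom == fe$chrom & st$pos > fe$start &
                   st$pos <= fe$end)
    if (!length(idx)) next
    if (fe$kind == "excess") {
      nsel <- ceiling(fe$f * n_hap)
      sel <- sample.int(n_hap, nsel)
      for (h in sel) {
        donor <- sample.int(cfg$n_ref, 1)
        al <- panel_hap(truth$panels, fe$ancestry)[idx, donor]
        if (cfg$eps > 0) {
          flip <- runif(length(al)) < cfg$eps
          al[flip] <- 1L - al[flip]
        }
        st$hap[idx, h] <- al
        # update truth tracts: mark interval as planted ancestry
        truth$tracts <- .override_tracts(truth$tracts, h, fe$chrom,
                                         fe$start, fe$end, fe$ancestry)
      }
    } else if (fe$kind == "sweep") {
      nsel <- ceiling(fe$f * n_hap)
      sel <- sample.int(n_hap, nsel)
      donor_hap <- st$hap[idx, sample.int(n_hap, 1)]
      for (h in sel) st$hap[idx, h] <- donor_hap
    } else if (fe$kind == "roh") {
      n_ind <- if (is.null(fe$n_ind) || is.na(fe$n_ind)) 1L else fe$n_ind
      ind <- sample.int(cfg$n_adm, n_ind)
      for (d in ind) st$hap[idx, 2 * d] <- st$hap[idx, 2 * d - 1]
    } else stop("unknown feature kind: ", fe$kind)
  }
  st$gt <- st$hap[, seq(1, n_hap, 2), drop = FALSE] +
           st$hap[, seq(2, n_hap, 2), drop = FALSE]
  colnames(st$gt) <- st$samples
  truth$target <- st
  fe <- features
  if (is.null(fe$ancestry)) fe$ancestry <- NA_integer_
  if (is.null(fe$f)) fe$f <- NA_real_
  truth$features <- rbind(truth$features,
                          fe[, c("kind", "chrom", "start", "end",
                                 "ancestry", "f")])
  # recompute realized proportions after ancestry overrides
  len <- truth$tracts$end_bp - truth$tracts$start_bp
  truth$true_prop <- vapply(seq_len(cfg$K), function(k)
    sum(len[truth$tracts$ancestry == k]) / sum(len), 0)
  truth
}

# split/override truth tracts of haplotype h over [start, end)
.override_tracts <- function(tr, h, chrom, start, end, ancestry) {
  mine <- tr$hap == h & tr$chrom == chrom
  keep <- tr[!mine, , drop = FALSE]
  cur <- tr[mine, , drop = FALSE]
  out <- NULL
  for (i in seq_len(nrow(cur))) {
    s <- cur$start_bp[i]; e <- cur$end_bp[i]
    if (e <= start || s >= end) { out <- rbind(out, cur[i, ]); next }
    if (s < start) { left <- cur[i, ]; left$end_bp <- start
                     left$censored_right <- FALSE
                     out <- rbind(out, left) }
    if (e > end) { right <- cur[i, ]; right$start_bp <- end
                   right$censored_left <- FALSE
                   out <- rbind(out, right) }
  }
  mid <- data.frame(hap = h, chrom = chrom, start_bp = start, end_bp = end,
                    ancestry = ancestry, censored_left = FALSE,
                    censored_right = FALSE)
  out <- rbind(out, mid)
  res <- rbind(keep, out)
  res[order(res$hap, res$chrom, res$start_bp), , drop = FALSE]
}

#' Export a truth_set to plain-text artifacts
#'
#' Writes the phased target VCF, one phased VCF per reference panel, the
#' true tracts as BED (haplotype id in the name column) and a JSON truth
#' manifest, all stamped with the simulation seed.
#'
#' @param truth a `truth_set`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
export_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(target = file.path(dir, "target.vcf"))
  write_phased_vcf(truth$target, paths["target"])
  for (k in seq_along(truth$panels$haps)) {
    p <- file.path(dir, sprintf("panel_%s.vcf", truth$panels$labels[k]))
    write_phased_vcf(truth$panels$haps[[k]], p)
    paths[paste0("panel_", k)] <- p
  }
  bed <- file.path(dir, "true_tracts.bed")
  tr <- truth$tracts
  write.table(data.frame(tr$chrom, tr$start_bp, tr$end_bp,
                         sprintf("hap%03d_anc%d", tr$hap, tr$ancestry)),
              bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  paths["tracts"] <- bed
  man <- file.path(dir, "truth.json")
  jsonlite::write_json(list(seed = truth$cfg$seed, g = truth$g,
                            m = truth$cfg$m, true_prop = truth$true_prop,
                            K = truth$cfg$K, n_adm = truth$cfg$n_adm,
                            n_sites = truth$cfg$n_sites,
                            n_chr = truth$cfg$n_chr, L_bp = truth$cfg$L_bp,
                            features = truth$features),
                       man, auto_unbox = TRUE, digits = NA)
  paths["manifest"] <- man
  invisible(paths)
}
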