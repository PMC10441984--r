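#' Biallelic SNP table with genotypes and optional phased haplotypes
#'
#' `site_table` is the package's central container: a set of biallelic SNP
#' records with coordinates, alleles, INFO metrics and per-sample diploid
#' dosages, optionally carrying the phased haplotype matrix. Positions are
#' stored 1-based as in VCF; all window arithmetic downstream is 0-based
#' half-open and converts at the boundary.
#'
#' @param chrom character vector of chromosome names (one per site).
#' @param pos integer vector of 1-based positions, strictly increasing
#'   within each chromosome.
#' @param ref,alt single-base reference / alternate alleles.
#' @param gt integer matrix (sites x samples) of alt-allele dosages in
#'   \{0, 1, 2, NA\}.
#' @param hap optional integer matrix (sites x 2*samples) of phased alleles
#'   (0/1); columns ordered sample1_hap1, sample1_hap2, sample2_hap1, ...
#' @param info optional data.frame of per-site INFO metrics (QD, FS, MQ,
#'   MQRankSum, ReadPosRankSum, SOR, DP ... numeric columns).
#' @param samples character vector of sample names (columns of `gt`).
#' @param contig_len optional named numeric vector of contig lengths in bp.
#'
#' @return An object of class `site_table`: a list with elements `chrom`,
#'   `pos`, `ref`, `alt`, `gt`, `hap`, `info`, `samples`, `contig_len`.
#' @export
site_table <- function(chrom, pos, ref, alt, gt, hap = NULL, info = NULL,
                       samples = colnames(gt), contig_len = NULL) {
  n <- length(pos)
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n)
  if (!is.matrix(gt)) gt <- matrix(gt, nrow = n)
  stopifnot(nrow(gt) == n)
  storage.mode(gt) <- "integer"
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(gt)))
  colnames(gt) <- samples
  if (any(!gt %in% c(0L, 1L, 2L, NA)))
    stop("dosages must be 0, 1, 2 or NA")
  for (cc in split(seq_len(n), chrom)) {
    if (is.unsorted(pos[cc], strictly = TRUE))
      stop("positions must be strictly increasing within chromosome")
  }
  bad <- nchar(ref) != 1L | nchar(alt) != 1L
  if (any(bad)) stop("site_table holds single-base biallelic SNPs only")
  if (!is.null(hap)) {
    storage.mode(hap) <- "integer"
    stopifnot(nrow(hap) == n, ncol(hap) == 2L * ncol(gt))
    ds <- hap[, seq(1, ncol(hap), 2), drop = FALSE] +
          hap[, seq(2, ncol(hap), 2), drop = FALSE]
    ok <- is.na(gt) | ds == gt
    if (!all(ok, na.rm = TRUE))
      stop("dosage must equal the sum of the phased alleles")
    colnames(hap) <- paste0(rep(samples, each = 2), "_", c(1, 2))
  }
  if (!is.null(info)) {
    info <- as.data.frame(info)
    stopifnot(nrow(info) == n)
  }
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), alt = as.character(alt),
                 gt = gt, hap = hap, info = info,
                 samples = samples, contig_len = contig_len),
            class = "site_table")
}

#' @export
print.site_table <- function(x, ...) {
  cat(sprintf("site_table: %d biallelic SNPs, %d samples (%s), %d contig(s)\n",
              length(x$pos), length(x$samples),
              if (is.null(x$hap)) "unphased" else "phased",
              length(unique(x$chrom))))
  invisible(x)
}

#' @export
dim.site_table <- function(x) c(length(x$pos), length(x$samples))

#' Subset a site_table by site index
#'
#' @param x a `site_table`.
#' @param i integer or logical index over sites.
#' @return A `site_table` with the selected sites.
#' @export
subset_sites <- function(x, i) {
  site_table(x$chrom[i], x$pos[i], x$ref[i], x$alt[i],
             x$gt[i, , drop = FALSE],
             hap = if (is.null(x$hap)) NULL else x$hap[i, , drop = FALSE],
             info = if (is.null(x$info)) NULL else x$info[i, , drop = FALSE],
             samples = x$samples, contig_len = x$contig_len)
}

#' Read a phased (or unphased) VCF into a site_table
#'
#' Retains biallelic SNP records only; multi-allelic sites and indels are
#' skipped and counted. Phase is read from the genotype separator: `|`
#' yields the ordered allele pair, `/` an unphased dosage.
#'
#' @param path path to a VCF 4.x file (plain or bgzipped).
#' @param samples optional character vector restricting the sample set.
#' @param require_phased if `TRUE` (default) an unphased heterozygous call
#'   raises an error naming the sample and site.
#' @return A [site_table()]; the number of skipped records is available as
#'   `attr(x, "skipped")`.
#' @export
read_phased_vcf <- function(path, samples = NULL, require_phased = TRUE) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  nrec <- nrow(fix)
  all_samples <- colnames(v@gt)[-1]
  if (is.null(all_samples)) all_samples <- character(0)
  if (is.null(samples)) samples <- all_samples
  missing_s <- setdiff(samples, all_samples)
  if (length(missing_s))
    stop("samples not in VCF: ", paste(missing_s, collapse = ", "))
  if (length(samples) == 0 && length(all_samples) > 0)
    stop("no samples matched")
  if (nrec == 0) {
    st <- site_table(character(0), integer(0), character(0), character(0),
                     gt = matrix(integer(0), 0, length(samples),
                                 dimnames = list(NULL, samples)),
                     samples = samples,
                     contig_len = .vcf_contig_lengths(path))
    attr(st, "skipped") <- 0L
    return(st)
  }
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  skipped <- sum(!keep)
  fix <- fix[keep, , drop = FALSE]
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  n <- nrow(fix)

  gtm <- matrix(NA_integer_, n, length(samples),
                dimnames = list(NULL, samples))
  hap <- NULL
  if (length(samples) > 0 && n > 0) {
    raw <- v@gt[keep, , drop = FALSE]
    fmt <- strsplit(raw[, 1], ":", fixed = TRUE)
    gt_idx <- vapply(fmt, function(f) match("GT", f), 1L)
    calls <- matrix("", n, length(samples))
    for (j in seq_along(samples)) {
      col <- raw[, samples[j]]
      parts <- strsplit(col, ":", fixed = TRUE)
      calls[, j] <- vapply(seq_len(n), function(i) parts[[i]][gt_idx[i]], "")
    }
    phased <- grepl("|", calls, fixed = TRUE)
    a1 <- suppressWarnings(as.integer(substr(calls, 1, 1)))
    a2 <- suppressWarnings(as.integer(substr(calls, 3, 3)))
    gtm[] <- a1 + a2
    if (require_phased) {
      bad <- !phased & !is.na(gtm)
      if (any(bad)) {
        w <- which(bad, arr.ind = TRUE)[1, ]
        stop(sprintf("unphased genotype for sample %s at %s:%d",
                     samples[w[2]], chrom[w[1]], pos[w[1]]))
      }
      hap <- matrix(NA_integer_, n, 2L * length(samples))
      hap[, seq(1, ncol(hap), 2)] <- a1
      hap[, seq(2, ncol(hap), 2)] <- a2
    }
  }
  info <- .parse_info(fix[, "INFO"])
  st <- site_table(chrom, pos, ref, alt, gtm, hap = hap, info = info,
                   samples = samples, contig_len = .vcf_contig_lengths(path))
  attr(st, "skipped") <- as.integer(skipped)
  st
}

.info_keys <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "SOR", "DP")

.parse_info <- function(info_str) {
  out <- lapply(.info_keys, function(k) {
    info_str[is.na(info_str)] <- ""
    m <- regexpr(paste0("(^|;)", k, "=[^;]+"), info_str)
    val <- rep(NA_real_, length(info_str))
    hit <- m > 0
    if (any(hit))
      val[hit] <- suppressWarnings(as.numeric(
        sub(paste0("^;?", k, "="), "", regmatches(info_str, m))))
    val
  })
  names(out) <- .info_keys
  df <- as.data.frame(out)
  if (all(vapply(df, function(x) all(is.na(x)), TRUE))) NULL else df
}

.vcf_contig_lengths <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  on.exit(close(con))
  hdr <- character(0)
  open(con, "r")
  repeat {
    l <- readLines(con, 1)
    if (!length(l) || !startsWith(l, "##")) break
    hdr <- c(hdr, l)
  }
  ctg <- grep("^##contig=", hdr, value = TRUE)
  if (!length(ctg)) return(NULL)
  ids <- sub(".*ID=([^,>]+).*", "\\1", ctg)
  lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", ctg)))
  setNames(lens, ids)
}

#' Write a site_table as a plain-text VCF 4.2 file
#'
#' Emits phased genotypes (`0|1`) when the table carries haplotypes,
#' otherwise unphased dosage calls. Round-trips positions, alleles and
#' dosages bit-exactly through [read_phased_vcf()].
#'
#' @param x a [site_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(x, path) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  for (k in .info_keys) {
    if (!is.null(x$info) && k %in% names(x$info))
      hdr <- c(hdr, sprintf(
        '##INFO=<ID=%s,Number=1,Type=Float,Description="%s">', k, k))
  }
  if (!is.null(x$contig_len))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(x$contig_len), as.integer(x$contig_len)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", x$samples),
                      collapse = "\t"))
  n <- length(x$pos)
  info_col <- rep(".", n)
  if (!is.null(x$info)) {
    parts <- lapply(names(x$info), function(k) {
      v <- x$info[[k]]
      ifelse(is.na(v), NA_character_, paste0(k, "=", format(v, trim = TRUE)))
    })
    info_col <- apply(do.call(cbind, parts), 1, function(r)
      if (all(is.na(r))) "." else paste(r[!is.na(r)], collapse = ";"))
  }
  if (!is.null(x$hap)) {
    a1 <- x$hap[, seq(1, ncol(x$hap), 2), drop = FALSE]
    a2 <- x$hap[, seq(2, ncol(x$hap), 2), drop = FALSE]
    gtxt <- matrix(paste0(a1, "|", a2), nrow = n)
    gtxt[is.na(a1) | is.na(a2)] <- ".|."
  } else {
    gtxt <- matrix(c("0/0", "0/1", "1/1")[x$gt + 1L], nrow = n)
    gtxt[is.na(x$gt)] <- "./."
  }
  body <- paste(x$chrom, x$pos, ".", x$ref, x$alt, ".", "PASS", info_col,
                "GT", sep = "\t")
  if (ncol(gtxt) > 0)
    body <- paste(body, apply(gtxt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Apply GATK-style hard filters to a site table
#'
#' Removes sites failing any of the standard INFO criteria
#' (QD < 2.0, FS > 60.0, MQ < 40.0, MQRankSum < -12.5,
#' ReadPosRankSum < -8.0, SOR > 3.0) or whose mean depth falls below
#' `depth_bounds[1]` times or above `depth_bounds[2]` times the cohort mean
#' depth. A missing INFO metric means that criterion is not applied, as in
#' GATK VariantFiltration. Inequalities are strict, so boundary values pass.
#'
#' @param x a [site_table()] carrying INFO metrics.
#' @param depth_bounds numeric length-2 multipliers of the cohort mean
#'   depth; default `c(1/3, 3)`.
#' @return The filtered `site_table`; removed-count in `attr(,"removed")`.
#' @export
apply_hard_filters <- function(x, depth_bounds = c(1 / 3, 3)) {
  if (any(depth_bounds < 0)) stop("depth bounds must be non-negative")
  n <- length(x$pos)
  if (n == 0) return(x)
  info <- x$info
  get <- function(k) if (!is.null(info) && k %in% names(info))
    info[[k]] else rep(NA_real_, n)
  fail <- .na_false(get("QD") < 2.0) |
    .na_false(get("FS") > 60.0) |
    .na_false(get("MQ") < 40.0) |
    .na_false(get("MQRankSum") < -12.5) |
    .na_false(get("ReadPosRankSum") < -8.0) |
    .na_false(get("SOR") > 3.0)
  dp <- get("DP")
  mu <- NULL
  if (!all(is.na(dp))) {
    # the depth reference is the mean of the original call set, so the
    # filter is idempotent; a pre-filtered table carries it as attribute
    mu <- attr(x, "depth_ref_mean") %||% mean(dp, na.rm = TRUE)
    fail <- fail | .na_false(dp < depth_bounds[1] * mu) |
      .na_false(dp > depth_bounds[2] * mu)
  }
  out <- subset_sites(x, !fail)
  attr(out, "removed") <- sum(fail)
  attr(out, "depth_ref_mean") <- mu
  out
}

.na_false <- function(x) !is.na(x) & x

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Alternate-allele frequencies per site
#'
#' @param x a [site_table()].
#' @param samples optional sample subset.
#' @return Numeric vector of alt-allele frequencies (NaN where no calls).
#' @export
alt_freq <- function(x, samples = x$samples) {
  g <- x$gt[, samples, drop = FALSE]
  rowSums(g, na.rm = TRUE) / (2 * rowSums(!is.na(g)))
}

#' Combine the samples of two site tables on the same site list
#'
#' @param a,b [site_table()]s with identical chrom/pos/ref/alt.
#' @return A `site_table` carrying the samples of both.
#' @export
bind_samples <- function(a, b) {
  stopifnot(identical(a$chrom, b$chrom), identical(a$pos, b$pos),
            identical(a$ref, b$ref), identical(a$alt, b$alt))
  hap <- if (!is.null(a$hap) && !is.null(b$hap)) cbind(a$hap, b$hap)
  site_table(a$chrom, a$pos, a$ref, a$alt, cbind(a$gt, b$gt), hap = hap,
             samples = c(a$samples, b$samples),
             contig_len = a$contig_len %||% b$contig_len)
}

#' Haplotype matrix for a sample subset
#'
#' @param x a phased [site_table()].
#' @param samples optional sample subset.
#' @return Integer matrix sites x (2 * length(samples)).
#' @export
hap_matrix <- function(x, samples = x$samples) {
  if (is.null(x$hap)) stop("site_table is not phased")
  idx <- match(samples, x$samples)
  if (anyNA(idx)) stop("unknown sample(s)")
  cols <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  x$hap[, cols, drop = FALSE]
}
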