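# Shared fixture builders. Everything is generated in code; no stored data.

# write a VCF from raw record lines (REF/ALT/INFO/GT free-form)
write_vcf_lines <- function(records, samples = c("s1", "s2"),
                            contig = "chr1", contig_len = 1e6) {
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", contig,
                   as.integer(contig_len)),
           '##INFO=<ID=QD,Number=1,Type=Float,Description="x">',
           '##INFO=<ID=FS,Number=1,Type=Float,Description="x">',
           '##INFO=<ID=MQ,Number=1,Type=Float,Description="x">',
           '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="x">',
           '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="x">',
           '##INFO=<ID=SOR,Number=1,Type=Float,Description="x">',
           '##INFO=<ID=DP,Number=1,Type=Float,Description="x">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="x">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

# a small phased site_table built directly from a haplotype matrix
st_from_hap <- function(hap, pos = NULL, chrom = "chr1", L = NULL) {
  n <- nrow(hap)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(L)) L <- max(pos) + 100
  gt <- hap[, seq(1, ncol(hap), 2), drop = FALSE] +
        hap[, seq(2, ncol(hap), 2), drop = FALSE]
  site_table(rep(chrom, n), pos, rep("A", n), rep("G", n), gt, hap = hap,
             contig_len = stats::setNames(L, chrom))
}

# tiny two-ancestry simulation used across detector tests
small_truth <- function(seed = 11, K = 2, F = 0.2, n_ref = 20, n_adm = 15,
                        L_bp = 10e6, n_sites = 3000, n_chr = 1,
                        m = NULL, g = 30, eps = 0.001) {
  if (is.null(m)) m <- rep(1 / K, K)
  cfg <- sim_config(K = K, F = F, n_ref = n_ref, n_adm = n_adm,
                    L_bp = L_bp, n_sites = n_sites, n_chr = n_chr,
                    m = m, g = g, eps = eps, seed = seed)
  simulate_cohort(cfg, make_panels(cfg))
}

# truth ancestry codes per site x haplotype from a truth_set
truth_anc_matrix <- function(truth) {
  st <- truth$target
  A <- matrix(NA_integer_, length(st$pos), 2L * truth$cfg$n_adm)
  tr <- truth$tracts
  for (i in seq_len(nrow(tr))) {
    idx <- which(st$chrom == tr$chrom[i] & st$pos > tr$start_bp[i] &
                   st$pos <= tr$end_bp[i])
    A[idx, tr$hap[i]] <- tr$ancestry[i]
  }
  A
}
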