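#' Gene models for site classification and segment annotation
#'
#' A light container for transcript/exon/CDS intervals. All coordinates are
#' 1-based inclusive (GFF convention); conversion to 0-based half-open
#' happens only inside window arithmetic.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   ("+"/"-"), `tx_start`, `tx_end`.
#' @param exons data.frame with columns `gene_id`, `start`, `end`.
#' @param cds optional data.frame with columns `gene_id`, `start`, `end`,
#'   `frame` (0/1/2, phase of the first base of the interval in its codon).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(genes, exons, cds = NULL) {
  genes <- as.data.frame(genes); exons <- as.data.frame(exons)
  stopifnot(all(c("gene_id", "chrom", "strand", "tx_start", "tx_end") %in%
                  names(genes)),
            all(c("gene_id", "start", "end") %in% names(exons)))
  sp <- genes$tx_start[match(exons$gene_id, genes$gene_id)]
  ep <- genes$tx_end[match(exons$gene_id, genes$gene_id)]
  if (any(exons$start < sp | exons$end > ep))
    stop("exons must lie within the transcript span")
  if (!is.null(cds)) {
    cds <- as.data.frame(cds)
    stopifnot(all(c("gene_id", "start", "end") %in% names(cds)))
    if (is.null(cds$frame)) cds$frame <- NA_integer_
    # exon containment: every CDS interval inside some exon of its gene
    for (i in seq_len(nrow(cds))) {
      e <- exons[exons$gene_id == cds$gene_id[i], , drop = FALSE]
      if (!any(e$start <= cds$start[i] & e$end >= cds$end[i]))
        stop("CDS interval outside exons for gene ", cds$gene_id[i])
    }
    .check_frames(cds, genes)
  }
  structure(list(genes = genes, exons = exons, cds = cds),
            class = "gene_model")
}

# stated frames must agree with cumulative CDS length in transcription order
.check_frames <- function(cds, genes) {
  for (g in unique(cds$gene_id)) {
    ci <- cds[cds$gene_id == g, , drop = FALSE]
    if (all(is.na(ci$frame))) next
    strand <- genes$strand[match(g, genes$gene_id)]
    ord <- order(ci$start, decreasing = identical(strand, "-"))
    ci <- ci[ord, , drop = FALSE]
    cum <- c(0, cumsum(ci$end - ci$start + 1))[seq_len(nrow(ci))]
    expect <- (3 - cum %% 3) %% 3
    bad <- !is.na(ci$frame) & ci$frame != expect
    if (any(bad))
      stop("contradictory CDS frames for gene ", g)
  }
  invisible(TRUE)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model: %d genes, %d exons, %s CDS intervals\n",
              nrow(x$genes), nrow(x$exons),
              if (is.null(x$cds)) "no" else nrow(x$cds)))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Uses gene/mRNA/exon/CDS features; the transcript span is the union of a
#' gene's mRNA (or gene) records.
#'
#' @param path GFF3 file.
#' @return A [gene_model()].
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$ID <- if (is.null(df$ID)) rep(NA_character_, nrow(df)) else
    as.character(df$ID)
  df$parent1 <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, "")
  strip <- function(s) sub("^(gene|transcript|mRNA):", "", s)
  # map every feature to its root gene id (follow Parent links upward)
  id2parent <- setNames(df$parent1, df$ID)
  root_of <- function(id) {
    seen <- character(0)
    while (!is.na(id) && id %in% names(id2parent) &&
           !is.na(id2parent[[id]]) && !(id %in% seen)) {
      seen <- c(seen, id)
      id <- id2parent[[id]]
    }
    id
  }
  owner <- ifelse(is.na(df$parent1), df$ID, df$parent1)
  root <- strip(vapply(owner, root_of, ""))
  is_g <- df$type == "gene"
  gsrc <- if (any(is_g)) df[is_g, , drop = FALSE] else df
  groot <- root[if (any(is_g)) which(is_g) else seq_len(nrow(df))]
  genes <- do.call(rbind, lapply(split(seq_along(groot), groot), function(i)
    data.frame(gene_id = groot[i[1]],
               chrom = as.character(gsrc$seqnames[i[1]]),
               strand = as.character(gsrc$strand[i[1]]),
               tx_start = min(gsrc$start[i]), tx_end = max(gsrc$end[i]))))
  feat <- function(type) {
    idx <- which(df$type == type)
    if (!length(idx)) return(NULL)
    out <- data.frame(gene_id = root[idx], start = df$start[idx],
                      end = df$end[idx])
    if (type == "CDS")
      out$frame <- suppressWarnings(as.integer(as.character(df$phase[idx])))
    out
  }
  ex <- feat("exon")
  if (is.null(ex)) ex <- data.frame(gene_id = character(0),
                                    start = integer(0), end = integer(0))
  gene_model(genes, ex, feat("CDS"))
}

#' Classify SNP sites by gene context
#'
#' Assigns exactly one class per site with precedence
#' exonic > UTR > intronic > upstream/downstream > intergenic. "Exonic"
#' means coding-exon (CDS) when CDS intervals are present for the gene,
#' otherwise any exon; exon-but-not-CDS positions are UTR. Sites within
#' `flank_bp` of a transcript span are upstream or downstream according to
#' the gene's strand. When `ref_seq` is supplied, exonic sites are
#' sub-classified synonymous / nonsynonymous through the standard codon
#' table.
#'
#' @param x a [site_table()].
#' @param genes a [gene_model()].
#' @param flank_bp flank width for up/downstream calls (default 1000 bp).
#' @param ref_seq optional named character vector of chromosome sequences
#'   (or a `Biostrings::DNAStringSet`) used for codon lookup.
#' @return data.frame with columns `chrom`, `pos`, `class` and (when
#'   `ref_seq` given) `coding_effect` in \{synonymous, nonsynonymous, NA\}.
#' @export
classify_sites <- function(x, genes, flank_bp = 1000, ref_seq = NULL) {
  stopifnot(inherits(genes, "gene_model"), flank_bp >= 0)
  n <- length(x$pos)
  sgr <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$pos, width = 1))
  mk <- function(chrom, start, end) GenomicRanges::GRanges(
    chrom, IRanges::IRanges(pmax(1L, as.integer(start)), as.integer(end)))
  g <- genes$genes
  chrom_of <- function(gene_id) g$chrom[match(gene_id, g$gene_id)]

  cls <- rep("intergenic", n)
  has_cds <- if (is.null(genes$cds)) character(0) else unique(genes$cds$gene_id)
  # exonic layer: CDS intervals, plus whole exons of CDS-less genes
  ex <- genes$exons
  ex_cdsless <- ex[!(ex$gene_id %in% has_cds), , drop = FALSE]
  exonic_tbl <- rbind(
    if (!is.null(genes$cds))
      data.frame(gene_id = genes$cds$gene_id, start = genes$cds$start,
                 end = genes$cds$end) else NULL,
    ex_cdsless[, c("gene_id", "start", "end")])
  hit <- function(tbl) {
    if (is.null(tbl) || nrow(tbl) == 0) return(rep(FALSE, n))
    gr <- mk(chrom_of(tbl$gene_id), tbl$start, tbl$end)
    IRanges::overlapsAny(sgr, gr)
  }
  utr_tbl <- .exon_minus_cds(genes)
  tx_tbl <- data.frame(gene_id = g$gene_id, start = g$tx_start,
                       end = g$tx_end)
  cls[hit(tx_tbl)] <- "intronic"
  cls[hit(utr_tbl)] <- "UTR"
  cls[hit(exonic_tbl)] <- "exonic"
  # flanks, split by strand
  left <- data.frame(gene_id = g$gene_id, start = g$tx_start - flank_bp,
                     end = g$tx_start - 1)
  right <- data.frame(gene_id = g$gene_id, start = g$tx_end + 1,
                      end = g$tx_end + flank_bp)
  up <- rbind(left[g$strand != "-", ], right[g$strand == "-", ])
  dn <- rbind(right[g$strand != "-", ], left[g$strand == "-", ])
  if (flank_bp > 0) {
    free <- cls == "intergenic"
    cls[free & hit(dn)] <- "downstream"
    cls[free & hit(up)] <- "upstream"   # upstream wins on overlap
  }
  out <- data.frame(chrom = x$chrom, pos = x$pos, class = cls,
                    stringsAsFactors = FALSE)
  if (!is.null(ref_seq) && !is.null(genes$cds))
    out$coding_effect <- .coding_effect(x, genes, cls, ref_seq)
  out
}

.exon_minus_cds <- function(genes) {
  if (is.null(genes$cds)) return(NULL)
  out <- NULL
  for (gidx in unique(genes$cds$gene_id)) {
    e <- genes$exons[genes$exons$gene_id == gidx, , drop = FALSE]
    cd <- genes$cds[genes$cds$gene_id == gidx, , drop = FALSE]
    er <- IRanges::IRanges(e$start, e$end)
    cr <- IRanges::IRanges(cd$start, cd$end)
    diffr <- IRanges::setdiff(er, cr)
    if (length(diffr))
      out <- rbind(out, data.frame(gene_id = gidx,
                                   start = IRanges::start(diffr),
                                   end = IRanges::end(diffr)))
  }
  out
}

.coding_effect <- function(x, genes, cls, ref_seq) {
  if (inherits(ref_seq, "DNAStringSet"))
    ref_seq <- setNames(as.character(ref_seq), names(ref_seq))
  code <- Biostrings::GENETIC_CODE
  eff <- rep(NA_character_, length(x$pos))
  g <- genes$genes
  for (gid in unique(genes$cds$gene_id)) {
    gi <- match(gid, g$gene_id)
    chrom <- g$chrom[gi]; strand <- g$strand[gi]
    if (!chrom %in% names(ref_seq)) next
    cd <- genes$cds[genes$cds$gene_id == gid, , drop = FALSE]
    cd <- cd[order(cd$start), , drop = FALSE]
    gpos <- unlist(lapply(seq_len(nrow(cd)), function(i)
      seq(cd$start[i], cd$end[i])))
    seq_fwd <- unlist(strsplit(substring(ref_seq[[chrom]],
                                         gpos, gpos), ""))
    if (strand == "-") {
      gpos <- rev(gpos)
      seq_cds <- rev(chartr("ACGT", "TGCA", seq_fwd))
    } else seq_cds <- seq_fwd
    in_cds <- which(x$chrom == chrom & x$pos %in% gpos &
                      cls == "exonic")
    for (si in in_cds) {
      k <- match(x$pos[si], gpos)          # 1-based index within CDS
      cidx <- (k - 1) %/% 3                # codon number (0-based)
      cpos <- (k - 1) %% 3 + 1
      codon <- seq_cds[(cidx * 3 + 1):(cidx * 3 + 3)]
      if (length(codon) < 3 || anyNA(codon)) next
      refb <- x$ref[si]; altb <- x$alt[si]
      if (strand == "-") { refb <- chartr("ACGT", "TGCA", refb)
                           altb <- chartr("ACGT", "TGCA", altb) }
      if (!identical(codon[cpos], refb)) next  # reference mismatch: skip
      alt_codon <- codon; alt_codon[cpos] <- altb
      aa_ref <- code[[paste(codon, collapse = "")]]
      aa_alt <- code[[paste(alt_codon, collapse = "")]]
      eff[si] <- if (identical(aa_ref, aa_alt)) "synonymous" else
        "nonsynonymous"
    }
  }
  eff
}

#' Annotate ancestry-excess segments with overlapping genes
#'
#' A gene is reported for a segment if its transcript span overlaps the
#' segment by at least 1 bp; gene lists are deduplicated per ancestry.
#'
#' @param segments data.frame with `chrom`, `start`, `end` (0-based
#'   half-open bp) and optionally `ancestry`.
#' @param genes a [gene_model()].
#' @return `segments` with a `genes` list-column, plus
#'   `attr(,"genes_by_ancestry")`: deduplicated gene vectors per ancestry.
#' @export
annotate_segments <- function(segments, genes) {
  stopifnot(inherits(genes, "gene_model"))
  g <- genes$genes
  gl <- vector("list", nrow(segments))
  if (nrow(segments)) {
    sgr <- GenomicRanges::GRanges(segments$chrom,
      IRanges::IRanges(segments$start + 1, segments$end))
    ggr <- GenomicRanges::GRanges(g$chrom,
      IRanges::IRanges(g$tx_start, g$tx_end))
    ov <- GenomicRanges::findOverlaps(sgr, ggr)
    for (i in seq_len(nrow(segments)))
      gl[[i]] <- sort(unique(
        g$gene_id[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]]))
  }
  segments$genes <- gl
  if (!is.null(segments$ancestry)) {
    ga <- lapply(split(gl, segments$ancestry),
                 function(l) sort(unique(unlist(l))))
    attr(segments, "genes_by_ancestry") <- ga
  }
  segments
}
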