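#' Informative-SNP filter settings
#'
#' The study design needs SNPs where both parents are deeply and cleanly
#' homozygous for their own allele (a parent showing a large fraction of the
#' other allele is the signature of collapsed paralogs or mapping bias) and
#' where both hybrids have enough allelic reads to test.  The thresholds
#' behind "sufficient parental reads" are not fixed by convention, so they
#' are all configurable and echoed into run summaries.
#'
#' @param min_parent_depth minimum reads in each parental sample (default 10).
#' @param min_parent_concordance minimum fraction of a parent's reads that
#'   carry its own allele (default 0.9).
#' @param require_exonic keep exonic SNPs only (default TRUE).
#' @param min_hybrid_depth minimum allelic reads in each hybrid (default 10).
#' @return a validated list of class \code{informative_filter_config}.
#' @export
informative_filter_config <- function(min_parent_depth = 10L,
                                      min_parent_concordance = 0.9,
                                      require_exonic = TRUE,
                                      min_hybrid_depth = 10L) {
  if (min_parent_depth < 0 || min_hybrid_depth < 0)
    stop("depth thresholds must be >= 0", call. = FALSE)
  if (min_parent_concordance < 0 || min_parent_concordance > 1)
    stop("'min_parent_concordance' must be in [0, 1]", call. = FALSE)
  structure(list(min_parent_depth = as.integer(min_parent_depth),
                 min_parent_concordance = min_parent_concordance,
                 require_exonic = isTRUE(require_exonic),
                 min_hybrid_depth = as.integer(min_hybrid_depth)),
            class = "informative_filter_config")
}

#' Count allele-supporting reads at SNPs from an alignment
#'
#' Pileup over the SNP positions of a coordinate-sorted alignment.  A read
#' base equal to the parent-1 allele increments \code{n_allele1}, equal to
#' the parent-2 allele \code{n_allele2}, anything else \code{n_other};
#' reads with a deletion spanning the SNP contribute to no counter.
#' Duplicate-marked and secondary alignments are excluded, as are bases
#' below the base-quality floor.  "Uniquely mapped" is operationalised
#' either as mapping quality >= \code{min_mapq} (default) or as an
#' alignment-count tag (e.g. NH) equal to 1.
#'
#' @param path SAM or BAM file.  SAM input is converted, sorted and indexed
#'   into a temporary BAM; BAM input is indexed on the fly if needed.
#' @param snps SNP table (snp_id, chrom, pos, allele1, allele2).
#' @param sample_id label for the output rows.
#' @param min_base_quality pileup base-quality floor (default 13).
#' @param min_mapq mapping-quality floor for the \code{"mapq"} uniqueness
#'   rule (default 20).
#' @param unique_method \code{"mapq"} or \code{"nh"} (NH tag == 1).
#' @return data.frame: snp_id, sample_id, n_allele1, n_allele2, n_other —
#'   one row per distinct SNP position.
#' @export
count_alleles_from_alignment <- function(path, snps, sample_id = "sample",
                                         min_base_quality = 13L,
                                         min_mapq = 20L,
                                         unique_method = c("mapq", "nh")) {
  unique_method <- match.arg(unique_method)
  usnps <- snps[!duplicated(paste(snps$chrom, snps$pos)), , drop = FALSE]
  bam <- prepare_bam(path)

  targets <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  missing <- setdiff(unique(usnps$chrom), names(targets))
  if (length(missing))
    warning("SNP contig(s) absent from alignment: ",
            paste(missing, collapse = ", "), "; zero counts reported")
  present <- usnps[!usnps$chrom %in% missing, , drop = FALSE]

  n1 <- n2 <- nother <- setNames(integer(nrow(usnps)), usnps$snp_id)
  if (nrow(present)) {
    which <- GenomicRanges::GRanges(
      present$chrom, IRanges::IRanges(present$pos, present$pos))
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isDuplicate = FALSE,
                                   isNotPassingQualityControls = FALSE)
    sbp <- if (unique_method == "nh")
      Rsamtools::ScanBamParam(which = which, flag = flag,
                              tagFilter = list(NH = 1L))
    else
      Rsamtools::ScanBamParam(which = which, flag = flag,
                              mapqFilter = as.integer(min_mapq))
    pp <- Rsamtools::PileupParam(max_depth = 10000000L,
                                 min_base_quality = as.integer(min_base_quality),
                                 min_mapq = 0L,
                                 min_nucleotide_depth = 1L,
                                 distinguish_strands = FALSE,
                                 distinguish_nucleotides = TRUE,
                                 include_deletions = FALSE,
                                 include_insertions = FALSE)
    pu <- Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = pp)
    if (nrow(pu)) {
      key <- paste(pu$seqnames, pu$pos)
      idx <- match(key, paste(present$chrom, present$pos))
      ok <- !is.na(idx)
      pu <- pu[ok, , drop = FALSE]; idx <- idx[ok]
      sid <- present$snp_id[idx]
      is1 <- as.character(pu$nucleotide) == present$allele1[idx]
      is2 <- as.character(pu$nucleotide) == present$allele2[idx]
      add <- function(tot, sel) {
        s <- tapply(pu$count[sel], sid[sel], sum)
        tot[names(s)] <- tot[names(s)] + as.integer(s)
        tot
      }
      n1 <- add(n1, is1); n2 <- add(n2, is2); nother <- add(nother, !is1 & !is2)
    }
  }
  data.frame(snp_id = usnps$snp_id, sample_id = sample_id,
             n_allele1 = unname(n1), n_allele2 = unname(n2),
             n_other = unname(nother), stringsAsFactors = FALSE)
}

# converts SAM to sorted+indexed BAM (tempfile); indexes an unindexed BAM
prepare_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = TRUE)
    return(bam)
  }
  if (!file.exists(paste0(path, ".bai"))) {
    ok <- tryCatch({ Rsamtools::indexBam(path); TRUE },
                   error = function(e) FALSE)
    if (!ok)
      stop("alignment '", path, "' could not be indexed; is it ",
           "coordinate-sorted?", call. = FALSE)
  }
  path
}

#' Select informative SNPs
#'
#' Keeps SNPs where (i) each parental sample has at least
#' \code{min_parent_depth} reads of which at least
#' \code{min_parent_concordance} carry that parent's own allele, (ii) the
#' SNP is exonic (optional) and (iii) both hybrids have at least
#' \code{min_hybrid_depth} allelic reads.  Parental depth counts all reads
#' at the site (including third-allele reads); hybrid depth counts allelic
#' reads only.
#'
#' @param counts long allelic-count table (snp_id, sample_id, n_allele1,
#'   n_allele2, n_other) covering both parents and both hybrids.
#' @param snps SNP table with \code{exonic} (and \code{gene_id}) columns.
#' @param cross a reciprocal [cross_design()].
#' @param config an [informative_filter_config()].
#' @param parent1_id,parent2_id sample ids of the allele-1 / allele-2
#'   parent.
#' @return list of class \code{informative_filter}: \code{snp_ids} (kept),
#'   \code{snps} (kept subset of \code{snps}), and \code{summary} with
#'   \code{n_total}, \code{n_kept}, \code{percent} (rounded to 2 decimals).
#' @export
filter_informative_snps <- function(counts, snps, cross = cross_design(),
                                    config = informative_filter_config(),
                                    parent1_id = "parent1",
                                    parent2_id = "parent2") {
  stopifnot(inherits(config, "informative_filter_config"))
  cross <- reciprocal_pair(cross)
  need <- c(parent1_id, parent2_id, cross$hybrid_id)
  have <- unique(counts$sample_id)
  if (length(setdiff(need, have)))
    stop("allelic counts missing for sample(s): ",
         paste(setdiff(need, have), collapse = ", "), call. = FALSE)

  ids <- unique(snps$snp_id)
  wide <- function(sample, col) {
    x <- counts[counts$sample_id == sample, , drop = FALSE]
    out <- setNames(rep(0L, length(ids)), ids)
    m <- match(x$snp_id, ids)
    out[m[!is.na(m)]] <- x[[col]][!is.na(m)]
    out
  }
  p1_1 <- wide(parent1_id, "n_allele1"); p1_2 <- wide(parent1_id, "n_allele2")
  p1_o <- wide(parent1_id, "n_other")
  p2_1 <- wide(parent2_id, "n_allele1"); p2_2 <- wide(parent2_id, "n_allele2")
  p2_o <- wide(parent2_id, "n_other")
  p1_tot <- p1_1 + p1_2 + p1_o
  p2_tot <- p2_1 + p2_2 + p2_o

  keep <- p1_tot >= config$min_parent_depth &
    p2_tot >= config$min_parent_depth &
    p1_1 >= config$min_parent_concordance * p1_tot &
    p2_2 >= config$min_parent_concordance * p2_tot
  for (h in cross$hybrid_id) {
    hd <- wide(h, "n_allele1") + wide(h, "n_allele2")
    keep <- keep & hd >= config$min_hybrid_depth
  }
  if (config$require_exonic) {
    exonic_ids <- unique(snps$snp_id[snps$exonic])
    keep <- keep & ids %in% exonic_ids
  }
  kept_ids <- ids[keep]
  structure(list(
    snp_ids = kept_ids,
    snps = snps[snps$snp_id %in% kept_ids, , drop = FALSE],
    summary = informative_summary(length(kept_ids), length(ids)),
    config = config), class = "informative_filter")
}

#' @export
print.informative_filter <- function(x, ...) {
  s <- x$summary
  cat(sprintf("informative SNPs: %d (%.2f%%) of %d kept\n",
              s$n_kept, s$percent, s$n_total))
  invisible(x)
}

#' Kept/total reporting arithmetic
#'
#' @param n_kept,n_total counts of kept and candidate SNPs.
#' @return list(n_total, n_kept, percent) with percent rounded to 2
#'   decimals, e.g. 46986 of 604729 gives 7.77.
#' @export
informative_summary <- function(n_kept, n_total) {
  list(n_total = as.integer(n_total), n_kept = as.integer(n_kept),
       percent = if (n_total > 0) round(100 * n_kept / n_total, 2) else NA_real_)
}

#' Sum allelic counts per gene
#'
#' Sums \code{n_allele1} / \code{n_allele2} over a gene's (informative)
#' SNPs, per sample.  A SNP assigned to several genes contributes to each
#' (so gene totals can double-count reads; see the per-SNP classification,
#' which is the primary route).  Genes without SNPs are absent from the
#' output.
#'
#' @param counts long allelic-count table.
#' @param snps SNP table with gene_id (rows without a gene are dropped).
#' @return data.frame: gene_id, sample_id, n_allele1, n_allele2.
#' @export
aggregate_gene_counts <- function(counts, snps) {
  map <- snps[!is.na(snps$gene_id), c("snp_id", "gene_id")]
  x <- merge(counts, map, by = "snp_id")
  if (!nrow(x))
    return(data.frame(gene_id = character(), sample_id = character(),
                      n_allele1 = integer(), n_allele2 = integer(),
                      stringsAsFactors = FALSE))
  agg <- aggregate(cbind(n_allele1, n_allele2) ~ gene_id + sample_id,
                   data = x, FUN = sum)
  agg <- agg[order(agg$gene_id, agg$sample_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
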