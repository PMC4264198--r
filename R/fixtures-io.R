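#' Write a simulation to plain-text fixture files
#'
#' Emits the full fixture bundle: reference FASTA, SNP VCF, gene models as
#' BED6 (0-based half-open) and GFF3 (1-based inclusive), and TSVs for
#' allelic counts, both count matrices, gene lengths, the truth table and
#' the cross design.  Reading the files back reproduces the in-memory
#' objects; with a fixed seed the files are byte-identical across runs.
#'
#' @param sim result of [simulate_all()].
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create '", dir, "'", call. = FALSE)
  p <- function(f) file.path(dir, f)
  paths <- c(reference = p("reference.fasta"), snps = p("snps.vcf"),
             genes_bed = p("genes.bed"), genes_gff = p("genes.gff3"),
             allelic_counts = p("allelic_counts.tsv"),
             genotype_counts = p("genotype_counts.tsv"),
             tissue_counts = p("tissue_counts.tsv"),
             gene_lengths = p("gene_lengths.tsv"),
             truth = p("truth.tsv"), cross = p("cross_design.tsv"))

  write_fasta(sim$reference, paths["reference"])
  write_snp_vcf(sim$snps, paths["snps"],
                contig_lengths = setNames(Biostrings::width(sim$reference),
                                          names(sim$reference)))
  write_gene_bed(sim$genes, paths["genes_bed"])
  write_gene_gff3(sim$genes, sim$exons, paths["genes_gff"])
  write_tsv(sim$allelic_counts, paths["allelic_counts"])
  write_count_matrix(sim$genotype_counts, paths["genotype_counts"])
  write_count_matrix(sim$tissue_counts, paths["tissue_counts"])
  write_tsv(data.frame(gene_id = names(sim$gene_lengths),
                       length = as.integer(sim$gene_lengths)),
            paths["gene_lengths"])
  write_tsv(sim$truth, paths["truth"])
  write_tsv(sim$cross, paths["cross"])
  invisible(paths)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, stringsAsFactors = FALSE, ...)
}

#' Count-matrix TSV round trip
#'
#' Writes/reads a genes x samples matrix with a \code{gene_id} first column.
#'
#' @param m integer matrix with row and column names.
#' @param path TSV path.
#' @return `read_count_matrix`: the matrix.
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), as.data.frame(m),
                   check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  m
}

#' @rdname write_count_matrix
#' @export
read_allelic_counts <- function(path) read_tsv(path)

# BED6: 0-based half-open; score column unused (0)
write_gene_bed <- function(genes, path) {
  bed <- data.frame(genes$chrom, genes$start - 1L, genes$end,
                    genes$gene_id, 0L, genes$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

write_gene_gff3 <- function(genes, exons, path) {
  g <- sprintf("%s\thybridASE\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
               genes$chrom, genes$start, genes$end, genes$strand,
               genes$gene_id)
  strand <- genes$strand[match(exons$gene_id, genes$gene_id)]
  e <- sprintf("%s\thybridASE\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
               exons$chrom, exons$start, exons$end, strand,
               exons$gene_id, stats::ave(seq_len(nrow(exons)),
                                         exons$gene_id, FUN = seq_along),
               exons$gene_id)
  writeLines(c("##gff-version 3", g, e), path)
  invisible(path)
}

#' Emit a synthetic alignment as SAM for known allelic counts
#'
#' The optional read-level extra: writes single-end reads over each SNP so
#' that the pileup recovers a prescribed allelic count table exactly.  Read
#' sequences are taken from the reference with the allele (or, for
#' \code{n_other}, a third base) substituted at the SNP.  Reads carry
#' \code{NH:i:1} and MAPQ 50 so they pass either uniqueness rule; set
#' \code{multimap_extra} to also emit reads with NH:i:2 / MAPQ 1 that a
#' correct filter must ignore.
#'
#' @param reference a [Biostrings::DNAStringSet].
#' @param snps SNP table (snp_id, chrom, pos, allele1, allele2).
#' @param counts allelic-count table for one sample (snp_id, n_allele1,
#'   n_allele2, n_other).
#' @param path output .sam path.
#' @param read_length read length in bp (default 36).
#' @param multimap_extra number of extra non-unique reads per SNP (default 0).
#' @return the path, invisibly.
#' @export
write_allelic_sam <- function(reference, snps, counts, path,
                              read_length = 36L, multimap_extra = 0L) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                   Biostrings::width(reference)))
  x <- merge(snps, counts, by = "snp_id")
  recs <- character(0)
  qn <- 0L
  third_base <- function(a1, a2) setdiff(c("A", "C", "G", "T"), c(a1, a2))[1L]
  for (i in seq_len(nrow(x))) {
    chrom <- x$chrom[i]; pos <- x$pos[i]
    clen <- Biostrings::width(reference[chrom])
    start <- max(1L, min(pos - read_length %/% 2L, clen - read_length + 1L))
    tpl <- as.character(Biostrings::extractAt(
      reference[[chrom]], IRanges::IRanges(start, start + read_length - 1L)))
    off <- pos - start + 1L
    mk <- function(base, n, mapq = 50L, nh = 1L) {
      if (n <= 0L) return(character(0))
      seq <- tpl
      substring(seq, off, off) <- base
      qn <<- qn + n
      sprintf("r%06d\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s\tNH:i:%d",
              (qn - n + 1L):qn, chrom, start, mapq, read_length, seq,
              strrep("I", read_length), nh)
    }
    recs <- c(recs, mk(x$allele1[i], x$n_allele1[i]),
              mk(x$allele2[i], x$n_allele2[i]),
              mk(third_base(x$allele1[i], x$allele2[i]), x$n_other[i]),
              mk(x$allele1[i], multimap_extra, mapq = 1L, nh = 2L))
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}
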