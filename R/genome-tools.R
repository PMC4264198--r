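#' Read / write reference sequences
#'
#' Thin wrappers around Biostrings with the conventions used throughout the
#' package (DNAStringSet keyed by chromosome name, 60-column FASTA).
#'
#' @param path FASTA file path.
#' @return `read_fasta`: a [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @param seqs a [Biostrings::DNAStringSet].
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Write SNPs as a minimal VCF
#'
#' Emits a VCF v4.2 subset: CHROM, POS (1-based), ID, REF (parent-1 allele),
#' ALT (parent-2 allele), plus contig header lines.
#'
#' @param snps SNP data.frame (snp_id, chrom, pos, allele1, allele2).
#' @param path output path.
#' @param contig_lengths optional named vector of chromosome lengths for the
#'   header.
#' @return the path, invisibly.
#' @export
write_snp_vcf <- function(snps, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=hybridASE-%s", packageVersion("hybridASE")))
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", sep = "\t"))
  body <- if (nrow(snps)) {
    paste(snps$chrom, snps$pos, snps$snp_id, snps$allele1, snps$allele2,
          ".", "PASS", ".", sep = "\t")
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Load biallelic SNVs from a VCF
#'
#' Reads the minimal VCF subset written by [write_snp_vcf()] (any VCF whose
#' first eight columns are standard will do).  Only biallelic single
#' nucleotide records are kept; indels and multi-allelic records are skipped
#' with a logged count.  When gene models are supplied, each SNP is
#' annotated with every overlapping gene (a SNP inside two overlapping genes
#' yields two rows) and an exonic flag.
#'
#' @param path VCF file.
#' @param gene_models optional result of [load_gene_models()] or the
#'   genes/exons pair from [simulate_genomes()].
#' @return data.frame: snp_id, chrom, pos, allele1, allele2, gene_id,
#'   exonic.  Attribute \code{n_skipped} counts dropped records.
#' @export
load_snps <- function(path, gene_models = NULL) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body)) {
    f <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(f)
    if (any(nf < 5L))
      stop("malformed VCF line ", which(nf < 5L)[1L] +
             sum(startsWith(lines, "#")), ": fewer than 5 fields",
           call. = FALSE)
    m <- t(vapply(f, function(x) x[1:5], character(5L)))
    pos <- suppressWarnings(as.integer(m[, 2L]))
    if (anyNA(pos))
      stop("malformed VCF line: non-integer POS", call. = FALSE)
    ref <- toupper(m[, 4L]); alt <- toupper(m[, 5L])
    keep <- nchar(ref) == 1L & nchar(alt) == 1L &
      ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
      !grepl(",", m[, 5L], fixed = TRUE)
    n_skipped <- sum(!keep)
    if (n_skipped)
      message("load_snps: skipped ", n_skipped,
              " non-biallelic/non-SNV record(s)")
    id <- m[keep, 3L]
    auto <- id == "." | id == ""
    id[auto] <- paste0(m[keep, 1L][auto], ":", pos[keep][auto])
    snps <- data.frame(snp_id = id, chrom = m[keep, 1L], pos = pos[keep],
                       allele1 = ref[keep], allele2 = alt[keep],
                       gene_id = NA_character_, exonic = FALSE,
                       stringsAsFactors = FALSE)
  } else {
    n_skipped <- 0L
    snps <- data.frame(snp_id = character(), chrom = character(),
                       pos = integer(), allele1 = character(),
                       allele2 = character(), gene_id = character(),
                       exonic = logical(), stringsAsFactors = FALSE)
  }
  if (!is.null(gene_models) && nrow(snps)) {
    snps <- annotate_snps(snps, gene_models)
  }
  attr(snps, "n_skipped") <- n_skipped
  snps
}

# assigns gene_id (one row per overlapping gene) and exonic flag
annotate_snps <- function(snps, gene_models) {
  genes <- gene_models$genes
  exons <- gene_models$exons
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos, snps$pos))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  no_hit <- setdiff(seq_len(nrow(snps)), qh)
  out <- snps[c(qh, no_hit), , drop = FALSE]
  out$gene_id <- c(genes$gene_id[S4Vectors::subjectHits(hits)],
                   rep(NA_character_, length(no_hit)))
  if (!is.null(exons) && nrow(exons)) {
    ex_gr <- GenomicRanges::GRanges(exons$chrom,
                                    IRanges::IRanges(exons$start, exons$end))
    out_gr <- GenomicRanges::GRanges(out$chrom,
                                     IRanges::IRanges(out$pos, out$pos))
    out$exonic <- IRanges::overlapsAny(out_gr, ex_gr)
  } else {
    out$exonic <- !is.na(out$gene_id)
  }
  out <- out[order(out$chrom, out$pos, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load gene models from BED or GFF3
#'
#' BED is interpreted as 0-based half-open and converted to the package's
#' internal 1-based inclusive convention on load (rtracklayer does this
#' conversion).  BED carries gene-level intervals only, so the exon table
#' equals the gene table; GFF3 files contribute exon features when present.
#'
#' @param path a .bed / .gff3 / .gff file.
#' @return list with data.frames \code{genes} (gene_id, chrom, start, end,
#'   strand, length) and \code{exons} (gene_id, chrom, start, end).
#' @export
load_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if (!is.null(df$type)) {
    gdf <- df[df$type == "gene", , drop = FALSE]
    edf <- df[df$type == "exon", , drop = FALSE]
    gene_id <- if (!is.null(gdf$ID)) gdf$ID else gdf$Name
    exon_gene <- if (!is.null(edf$Parent))
      vapply(edf$Parent, function(p) as.character(p)[1L], "") else edf$Name
    genes <- data.frame(gene_id = as.character(gene_id),
                        chrom = as.character(gdf$seqnames),
                        start = gdf$start, end = gdf$end,
                        strand = as.character(gdf$strand),
                        stringsAsFactors = FALSE)
    exons <- data.frame(gene_id = as.character(exon_gene),
                        chrom = as.character(edf$seqnames),
                        start = edf$start, end = edf$end,
                        stringsAsFactors = FALSE)
    if (!nrow(exons))
      exons <- genes[, c("gene_id", "chrom", "start", "end")]
  } else {
    genes <- data.frame(gene_id = as.character(df$name),
                        chrom = as.character(df$seqnames),
                        start = df$start, end = df$end,
                        strand = as.character(df$strand),
                        stringsAsFactors = FALSE)
    exons <- genes[, c("gene_id", "chrom", "start", "end")]
  }
  ulen <- vapply(split(exons, exons$gene_id), function(e)
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(e$start, e$end)))), 0)
  genes$length <- as.integer(ulen[genes$gene_id])
  list(genes = genes, exons = exons)
}

#' Build the alternate-parent pseudo-genome
#'
#' Substitutes the parent-2 allele at every SNP position of the reference
#' (parent-1) sequence.  The result differs from the reference at exactly
#' the SNP positions; lengths are preserved.  Any SNP whose recorded
#' parent-1 allele does not match the reference base aborts with the
#' offending positions listed (the classic symptom of a 0/1-based
#' coordinate mix-up).
#'
#' @param reference a [Biostrings::DNAStringSet] keyed by chromosome.
#' @param snps SNP data.frame (chrom, pos, allele1, allele2).
#' @return a DNAStringSet of the same shape with alleles swapped in.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
#' snp <- data.frame(snp_id = "s1", chrom = "chr1", pos = 3,
#'                   allele1 = "G", allele2 = "T")
#' as.character(build_pseudogenome(ref, snp))  # "ACTTACGT"
#' @export
build_pseudogenome <- function(reference, snps) {
  out <- reference
  if (!nrow(snps)) return(out)
  # drop duplicate (chrom,pos) rows from multi-gene SNP assignment
  snps <- snps[!duplicated(paste(snps$chrom, snps$pos)), , drop = FALSE]
  bad <- character()
  by_chr <- split(snps, snps$chrom)
  for (chr in names(by_chr)) {
    if (!chr %in% names(out))
      stop("SNP chromosome '", chr, "' absent from reference", call. = FALSE)
    s <- by_chr[[chr]]
    if (any(s$pos < 1L | s$pos > Biostrings::width(out[chr])))
      stop("SNP position outside chromosome '", chr, "'", call. = FALSE)
    at <- as.character(Biostrings::extractAt(
      out[[chr]], IRanges::IRanges(s$pos, s$pos)))
    mism <- at != s$allele1
    if (any(mism))
      bad <- c(bad, sprintf("%s:%d (ref %s, expected %s)", chr,
                            s$pos[mism], at[mism], s$allele1[mism]))
  }
  if (length(bad))
    stop("reference-base mismatch at SNP position(s): ",
         paste(head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "",
         " - check 0- vs 1-based coordinates", call. = FALSE)
  for (chr in names(by_chr)) {
    s <- by_chr[[chr]]
    out[[chr]] <- Biostrings::replaceLetterAt(
      out[[chr]], s$pos, paste(s$allele2, collapse = ""))
  }
  out
}
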