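#' Simulate per-gene truth labels
#'
#' Draws each gene's class independently with the configured proportions:
#' \code{ase_parent1} / \code{ase_parent2} (allele-specific, same genomic
#' allele favoured in both hybrids), \code{imprinted_maternal} /
#' \code{imprinted_paternal} (favoured allele follows parent of origin), or
#' \code{biallelic}.  The truth table records the expected parent-1 allele
#' fraction in each hybrid, DE status between the parents, and expression
#' breadth class.
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per gene: \code{gene_id}, \code{class},
#'   \code{af_hybrid12}, \code{af_hybrid21} (expected parent-1 allele
#'   fraction in the hybrid whose mother is parent1 / parent2),
#'   \code{de_status}, \code{log2fc}, \code{breadth_class},
#'   \code{specific_tissue}.
#' @examples
#' truth <- simulate_truth(sim_config(n_genes = 20, frac_ase = 0.5))
#' table(truth$class)
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + .SEED_TRUTH)
  n <- config$n_genes
  b <- config$bias_level

  p_ase <- config$frac_ase
  p_mat <- config$frac_imprinted_maternal
  p_pat <- config$frac_imprinted_paternal
  probs <- c(ase_parent1 = p_ase / 2, ase_parent2 = p_ase / 2,
             imprinted_maternal = p_mat, imprinted_paternal = p_pat,
             biallelic = 1 - p_ase - p_mat - p_pat)
  cls <- sample(names(probs), n, replace = TRUE, prob = probs)

  # expected parent-1 allele fraction per hybrid; hybrid12 has parent1 mother
  af12 <- af21 <- rep(0.5, n)
  af12[cls == "ase_parent1"] <- b;        af21[cls == "ase_parent1"] <- b
  af12[cls == "ase_parent2"] <- 1 - b;    af21[cls == "ase_parent2"] <- 1 - b
  af12[cls == "imprinted_maternal"] <- b; af21[cls == "imprinted_maternal"] <- 1 - b
  af12[cls == "imprinted_paternal"] <- 1 - b; af21[cls == "imprinted_paternal"] <- b

  de <- runif(n) < config$frac_de
  lfc <- ifelse(de, sample(c(-1, 1), n, replace = TRUE) * config$de_log2fc, 0)

  ts <- runif(n) < config$frac_tissue_specific
  data.frame(
    gene_id = sprintf("gene%04d", seq_len(n)),
    class = cls,
    af_hybrid12 = af12, af_hybrid21 = af21,
    de_status = de, log2fc = lfc,
    breadth_class = ifelse(ts, "tissue_specific", "broad"),
    specific_tissue = ifelse(ts, sample.int(config$n_tissues, n, replace = TRUE),
                             NA_integer_),
    stringsAsFactors = FALSE)
}

#' Simulate a reference genome, SNPs and gene models
#'
#' Generates a random nucleotide chromosome with tandem two-exon genes and
#' places biallelic SNPs at distinct positions inside exons.  The parent-1
#' allele is, by construction, the reference base; parent-2 carries a
#' different base at every SNP.  A gene too short for its requested SNP
#' count gets fewer SNPs (with a message).
#'
#' @param config a [sim_config()].
#' @return list with \code{reference} (a [Biostrings::DNAStringSet]),
#'   \code{snps} (data.frame: snp_id, chrom, pos, allele1, allele2, gene_id,
#'   exonic), \code{genes} (data.frame: gene_id, chrom, start, end, strand,
#'   length = union-exon bp) and \code{exons} (data.frame: gene_id, chrom,
#'   start, end).  Coordinates are 1-based inclusive.
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + .SEED_GENOME)
  n <- config$n_genes
  gap <- 200L
  intron <- 100L

  len <- sample(config$gene_length[1L]:config$gene_length[2L], n, replace = TRUE)
  end <- cumsum(len + gap)
  start <- end - len - gap + 1L
  end <- start + len - 1L
  chrom_len <- max(end) + gap
  strand <- sample(c("+", "-"), n, replace = TRUE)

  # two exons separated by a fixed intron; exon1 ~60% of the exonic span
  exonic_len <- len - intron
  e1_len <- pmax(50L, as.integer(round(exonic_len * 0.6)))
  e1 <- data.frame(gene_id = sprintf("gene%04d", seq_len(n)),
                   chrom = "chr1", start = start, end = start + e1_len - 1L)
  e2 <- data.frame(gene_id = e1$gene_id, chrom = "chr1",
                   start = e1$end + intron + 1L, end = end)
  exons <- rbind(e1, e2)
  exons <- exons[order(exons$start), , drop = FALSE]

  genes <- data.frame(gene_id = e1$gene_id, chrom = "chr1",
                      start = start, end = end, strand = strand,
                      length = (e1$end - e1$start + 1L) + (e2$end - e2$start + 1L),
                      stringsAsFactors = FALSE)

  ref <- paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
               collapse = "")
  reference <- Biostrings::DNAStringSet(ref)
  names(reference) <- "chr1"

  n_snp <- rpois(n, config$snps_per_gene)
  snp_rows <- vector("list", n)
  shrunk <- 0L
  for (i in seq_len(n)) {
    if (n_snp[i] == 0L) next
    exon_pos <- c(e1$start[i]:e1$end[i], e2$start[i]:e2$end[i])
    k <- n_snp[i]
    if (k > length(exon_pos)) {
      shrunk <- shrunk + 1L
      k <- length(exon_pos)
    }
    pos <- sort(sample(exon_pos, k))
    snp_rows[[i]] <- data.frame(chrom = "chr1", pos = pos,
                                gene_id = genes$gene_id[i],
                                stringsAsFactors = FALSE)
  }
  if (shrunk > 0L)
    message(shrunk, " gene(s) too short for the requested SNP count; reduced")
  snps <- do.call(rbind, snp_rows)
  if (is.null(snps)) {
    snps <- data.frame(snp_id = character(), chrom = character(),
                       pos = integer(), allele1 = character(),
                       allele2 = character(), gene_id = character(),
                       exonic = logical(), stringsAsFactors = FALSE)
  } else {
    a1 <- substring(ref, snps$pos, snps$pos)
    bases <- c("A", "C", "G", "T")
    a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1L), "",
                 USE.NAMES = FALSE)
    snps <- data.frame(snp_id = sprintf("snp%05d", seq_len(nrow(snps))),
                       chrom = snps$chrom, pos = snps$pos,
                       allele1 = a1, allele2 = a2, gene_id = snps$gene_id,
                       exonic = TRUE, stringsAsFactors = FALSE)
  }
  list(reference = reference, snps = snps, genes = genes, exons = exons)
}

#' Simulate per-SNP allelic read counts
#'
#' Per-SNP, per-sample sequencing depth follows a negative binomial
#' (Gamma-Poisson) law with mean \code{mean_snp_depth} and dispersion
#' \code{depth_dispersion}.  In hybrids the parent-1 allele count is
#' Binomial(depth, f) with f taken from the truth table (0.5 for biallelic
#' genes).  Parental samples are homozygous: reads carry the own allele
#' except for a flat \code{parent_error_rate} showing the other allele.
#'
#' @param config a [sim_config()].
#' @param truth truth table from [simulate_truth()].
#' @param snps SNP table from [simulate_genomes()].
#' @param cross a reciprocal [cross_design()]; mothers/fathers must be
#'   \code{"parent1"} / \code{"parent2"}.
#' @return data.frame in long format: snp_id, sample_id, n_allele1,
#'   n_allele2, n_other.
#' @export
simulate_allelic_counts <- function(config, truth, snps,
                                    cross = cross_design()) {
  stopifnot(inherits(config, "sim_config"))
  cross <- reciprocal_pair(cross, "parent1")
  if (!setequal(c(cross$mother, cross$father), c("parent1", "parent2")))
    stop("cross design genotypes must be 'parent1'/'parent2'", call. = FALSE)
  missing_genes <- setdiff(snps$gene_id, truth$gene_id)
  if (length(missing_genes))
    stop("truth table does not cover SNP-bearing gene(s): ",
         paste(head(missing_genes, 5L), collapse = ", "), call. = FALSE)
  set.seed(config$seed + .SEED_ALLELIC)

  m <- nrow(snps)
  af <- truth[match(snps$gene_id, truth$gene_id), c("af_hybrid12", "af_hybrid21")]
  # fraction columns are stated for mother=parent1 first; map to actual ids
  hyb_f <- list(af$af_hybrid12, af$af_hybrid21)
  names(hyb_f) <- cross$hybrid_id

  rdepth <- function(n) {
    if (config$depth_dispersion > 0)
      rnbinom(n, mu = config$mean_snp_depth, size = 1 / config$depth_dispersion)
    else rpois(n, config$mean_snp_depth)
  }
  out <- vector("list", 4L)
  err <- config$parent_error_rate
  for (s in c("parent1", "parent2")) {
    d <- rdepth(m)
    wrong <- rbinom(m, d, err)
    n1 <- if (s == "parent1") d - wrong else wrong
    out[[s]] <- data.frame(snp_id = snps$snp_id, sample_id = s,
                           n_allele1 = n1, n_allele2 = d - n1,
                           n_other = 0L, stringsAsFactors = FALSE)
  }
  for (h in cross$hybrid_id) {
    d <- rdepth(m)
    n1 <- rbinom(m, d, hyb_f[[h]])
    out[[h]] <- data.frame(snp_id = snps$snp_id, sample_id = h,
                           n_allele1 = n1, n_allele2 = d - n1,
                           n_other = 0L, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate expression count matrices
#'
#' Produces two count matrices: four genotype libraries (the two parents and
#' the two reciprocal hybrids, one library each, mirroring an
#' unreplicated design) and an \code{n_tissues}-column breadth panel.
#' Counts are negative binomial around gene-specific means; DE genes are
#' shifted by \code{de_log2fc} in parent2 (hybrids get the additive
#' mid-parent mean); tissue-specific genes concentrate 95\% of their mean
#' expression in one tissue while broad genes are uniform.
#'
#' @param config a [sim_config()].
#' @param truth truth table from [simulate_truth()].
#' @param gene_lengths optional bp lengths (defaults to draws from
#'   \code{config$gene_length}); used downstream for FPKM.
#' @return list with \code{genotype_counts} (genes x 4), \code{tissue_counts}
#'   (genes x n_tissues) and \code{gene_lengths} (named vector).
#' @export
simulate_expression_matrix <- function(config, truth, gene_lengths = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + .SEED_EXPR)
  n <- nrow(truth)
  base <- rlnorm(n, meanlog = log(config$mean_expression),
                 sdlog = config$expr_meanlog_sd)
  size <- if (config$expr_dispersion > 0) 1 / config$expr_dispersion else Inf

  mu_p1 <- base
  mu_p2 <- base * 2^truth$log2fc
  mu_hyb <- (mu_p1 + mu_p2) / 2
  mu <- cbind(parent1 = mu_p1, parent2 = mu_p2,
              hybrid12 = mu_hyb, hybrid21 = mu_hyb)
  rnb <- function(mu) {
    if (is.finite(size)) rnbinom(length(mu), mu = mu, size = size)
    else rpois(length(mu), mu)
  }
  geno <- apply(mu, 2L, rnb)
  rownames(geno) <- truth$gene_id
  storage.mode(geno) <- "integer"

  tn <- config$n_tissues
  w <- matrix(1 / tn, nrow = n, ncol = tn)
  ts <- which(truth$breadth_class == "tissue_specific")
  if (length(ts)) {
    w[ts, ] <- 0.05 / (tn - 1)
    w[cbind(ts, truth$specific_tissue[ts])] <- 0.95
  }
  mu_t <- base * tn * w   # total expression comparable to genotype libraries
  tissue <- matrix(rnb(mu_t), nrow = n, ncol = tn,
                   dimnames = list(truth$gene_id,
                                   sprintf("tissue%02d", seq_len(tn))))
  storage.mode(tissue) <- "integer"

  if (is.null(gene_lengths))
    gene_lengths <- sample(config$gene_length[1L]:config$gene_length[2L], n,
                           replace = TRUE)
  names(gene_lengths) <- truth$gene_id
  list(genotype_counts = geno, tissue_counts = tissue,
       gene_lengths = gene_lengths)
}

#' Run the whole generator
#'
#' Convenience wrapper tying the stages together with consistent gene
#' lengths (union-exon lengths from the simulated gene models feed FPKM).
#'
#' @param config a [sim_config()].
#' @param cross a reciprocal [cross_design()].
#' @return list with elements \code{config}, \code{truth}, \code{reference},
#'   \code{snps}, \code{genes}, \code{exons}, \code{allelic_counts},
#'   \code{genotype_counts}, \code{tissue_counts}, \code{gene_lengths},
#'   \code{cross}.
#' @examples
#' sim <- simulate_all(sim_config(n_genes = 30, seed = 42))
#' names(sim)
#' @export
simulate_all <- function(config, cross = cross_design()) {
  truth <- simulate_truth(config)
  gen <- simulate_genomes(config)
  ac <- simulate_allelic_counts(config, truth, gen$snps, cross)
  lens <- setNames(gen$genes$length, gen$genes$gene_id)[truth$gene_id]
  expr <- simulate_expression_matrix(config, truth, gene_lengths = lens)
  c(list(config = config, truth = truth, cross = cross,
         allelic_counts = ac), gen, expr)
}
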