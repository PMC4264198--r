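#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator.  Defaults describe a
#' small but realistic reciprocal-hybrid experiment: two inbred parents
#' differing at exonic SNPs, their two reciprocal F1 hybrids, and a
#' multi-tissue expression panel.
#'
#' @param n_genes number of genes to simulate.
#' @param gene_length integer vector of length 2, min/max gene span in bp.
#' @param snps_per_gene mean of the Poisson number of exonic SNPs per gene.
#' @param frac_ase proportion of genes with allele-specific expression
#'   (split evenly between the two parental directions).
#' @param frac_imprinted_maternal,frac_imprinted_paternal proportions of
#'   genes with maternal / paternal parent-of-origin bias.
#' @param bias_level major-allele fraction for biased genes, in (0.5, 1].
#' @param mean_snp_depth expected allelic reads per SNP per sample.
#' @param depth_dispersion negative-binomial dispersion of per-SNP depth
#'   (0 gives Poisson depth).
#' @param parent_error_rate rate at which a parental sample shows the other
#'   parent's allele (sequencing/alignment error); gives the informative
#'   filter's concordance rule something to chew on.
#' @param frac_de proportion of genes differentially expressed between the
#'   two parents.
#' @param de_log2fc absolute planted log2 fold change for DE genes.
#' @param mean_expression mean expression count scale for the count matrices.
#' @param expr_meanlog_sd log-normal sd of gene base means around
#'   \code{mean_expression} (default 1, a realistic inter-gene dynamic
#'   range; 0 puts every gene at the same depth).
#' @param expr_dispersion NB dispersion of the expression count matrices.
#' @param n_tissues number of tissues in the breadth panel (default 11).
#' @param frac_tissue_specific proportion of genes with tissue-specific
#'   expression (95\% of mean expression in one tissue); the rest are broad.
#' @param seed integer RNG seed; each generator stage derives its own
#'   sub-stream by a fixed offset so stages are independently reproducible.
#'
#' @return an object of class \code{sim_config} (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 50, frac_ase = 0.2, seed = 7)
#' @export
sim_config <- function(n_genes = 200,
                       gene_length = c(600L, 3000L),
                       snps_per_gene = 3,
                       frac_ase = 0.1,
                       frac_imprinted_maternal = 0,
                       frac_imprinted_paternal = 0,
                       bias_level = 0.9,
                       mean_snp_depth = 100,
                       depth_dispersion = 0.1,
                       parent_error_rate = 0.005,
                       frac_de = 0.1,
                       de_log2fc = 2,
                       mean_expression = 200,
                       expr_meanlog_sd = 1,
                       expr_dispersion = 0.1,
                       n_tissues = 11L,
                       frac_tissue_specific = 0.2,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), gene_length = as.integer(gene_length),
    snps_per_gene = snps_per_gene, frac_ase = frac_ase,
    frac_imprinted_maternal = frac_imprinted_maternal,
    frac_imprinted_paternal = frac_imprinted_paternal,
    bias_level = bias_level, mean_snp_depth = mean_snp_depth,
    depth_dispersion = depth_dispersion,
    parent_error_rate = parent_error_rate,
    frac_de = frac_de, de_log2fc = de_log2fc,
    mean_expression = mean_expression, expr_meanlog_sd = expr_meanlog_sd,
    expr_dispersion = expr_dispersion,
    n_tissues = as.integer(n_tissues),
    frac_tissue_specific = frac_tissue_specific,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  props <- c("frac_ase", "frac_imprinted_maternal", "frac_imprinted_paternal",
             "frac_de", "frac_tissue_specific")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stop(sprintf("'%s' must be a proportion in [0, 1]", p), call. = FALSE)
  }
  bias_sum <- cfg$frac_ase + cfg$frac_imprinted_maternal +
    cfg$frac_imprinted_paternal
  if (bias_sum > 1)
    stop("frac_ase + frac_imprinted_maternal + frac_imprinted_paternal ",
         "must not exceed 1 (got ", bias_sum, ")", call. = FALSE)
  if (cfg$bias_level <= 0.5 || cfg$bias_level > 1)
    stop("'bias_level' must lie in (0.5, 1]", call. = FALSE)
  if (cfg$n_genes < 1L) stop("'n_genes' must be >= 1", call. = FALSE)
  if (length(cfg$gene_length) != 2L || any(cfg$gene_length < 100L) ||
      cfg$gene_length[1L] > cfg$gene_length[2L])
    stop("'gene_length' must be c(min, max) with min >= 100", call. = FALSE)
  for (p in c("snps_per_gene", "mean_snp_depth", "depth_dispersion",
              "parent_error_rate", "mean_expression", "expr_meanlog_sd",
              "expr_dispersion"))
    if (cfg[[p]] < 0) stop(sprintf("'%s' must be >= 0", p), call. = FALSE)
  if (cfg$n_tissues < 2L) stop("'n_tissues' must be >= 2", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,",
      sprintf("ASE %.0f%%, imprinted %.0f%%/%.0f%% (mat/pat), bias %.2f,",
              100 * x$frac_ase, 100 * x$frac_imprinted_maternal,
              100 * x$frac_imprinted_paternal, x$bias_level),
      "depth", x$mean_snp_depth, "- seed", x$seed, "\n")
  invisible(x)
}

# fixed per-stage seed offsets (one global stream, sub-streams by offset)
.SEED_TRUTH  <- 101L
.SEED_GENOME <- 202L
.SEED_ALLELIC <- 303L
.SEED_EXPR   <- 404L

#' Reciprocal cross design
#'
#' A cross design maps each hybrid sample to its mother and father genotype;
#' it is what lets the caller distinguish allele-specific from imprinted
#' expression.  The default pairs \code{hybrid12} (parent1 mother) with its
#' reciprocal \code{hybrid21}.
#'
#' @param hybrid_id character vector of hybrid sample ids.
#' @param mother,father parental genotype ids for each hybrid.
#' @return data.frame with columns hybrid_id, mother, father.
#' @examples
#' cross_design()  # the default reciprocal pair
#' @export
cross_design <- function(hybrid_id = c("hybrid12", "hybrid21"),
                         mother = c("parent1", "parent2"),
                         father = c("parent2", "parent1")) {
  if (any(mother == father))
    stop("mother and father must differ for every hybrid", call. = FALSE)
  if (anyDuplicated(hybrid_id))
    stop("duplicate hybrid_id in cross design", call. = FALSE)
  data.frame(hybrid_id = as.character(hybrid_id),
             mother = as.character(mother),
             father = as.character(father),
             stringsAsFactors = FALSE)
}

# checks that a cross design is a reciprocal pair and returns it ordered
# with the hybrid whose mother is `parent1_id` first
reciprocal_pair <- function(cross, parent1_id = NULL) {
  if (nrow(cross) != 2L)
    stop("cross design must contain exactly two hybrids (a reciprocal pair)",
         call. = FALSE)
  if (!(cross$mother[1L] == cross$father[2L] &&
        cross$father[1L] == cross$mother[2L]))
    stop("the two hybrids do not form a reciprocal pair ",
         "(mother/father roles must be swapped)", call. = FALSE)
  if (is.null(parent1_id)) parent1_id <- cross$mother[1L]
  cross[order(cross$mother != parent1_id), , drop = FALSE]
}
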