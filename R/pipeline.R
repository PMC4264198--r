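#' Default pipeline configuration
#'
#' Every threshold that can alter a call, plus the seed, lives here and is
#' echoed verbatim into the run report.  The config is a plain list,
#' round-trippable through JSON.
#'
#' @param seed RNG seed driving the simulation stage.
#' @param out_dir output directory.
#' @param simulate generate fixtures first (default TRUE; otherwise
#'   \code{fixtures_dir} must point at an existing bundle).
#' @param fixtures_dir where fixtures are written/read.
#' @param sim named list of [sim_config()] overrides.
#' @param alpha SNP-level and DE significance level.
#' @param ase_threshold major-allele fraction rule (default 0.8).
#' @param min_fold DE fold-change rule (default 2).
#' @param min_reads detection threshold for detected-gene sets.
#' @param entropy_min_fpkm FPKM floor for expression breadth.
#' @param filter named list of [informative_filter_config()] overrides.
#' @param annotation_tsv optional gene_id/term TSV for enrichment.
#' @param tf_tsv optional gene_id/family TSV for the TF cross-tab.
#' @return a config list.
#' @export
default_run_config <- function(seed = 1L, out_dir = "hybridase_run",
                               simulate = TRUE, fixtures_dir = NULL,
                               sim = list(), alpha = 0.05,
                               ase_threshold = 0.8, min_fold = 2,
                               min_reads = 1L, entropy_min_fpkm = 1,
                               filter = list(), annotation_tsv = NULL,
                               tf_tsv = NULL) {
  list(seed = as.integer(seed), out_dir = out_dir, simulate = simulate,
       fixtures_dir = fixtures_dir,   # NULL: derived from out_dir at run time

       sim = sim, alpha = alpha, ase_threshold = ase_threshold,
       min_fold = min_fold, min_reads = as.integer(min_reads),
       entropy_min_fpkm = entropy_min_fpkm, filter = filter,
       annotation_tsv = annotation_tsv, tf_tsv = tf_tsv)
}

#' Run the full analysis pipeline
#'
#' Composable end-to-end driver: (optionally) simulate and write fixtures,
#' read every input back from disk (so each number in the report is
#' recomputable from the emitted files), build the pseudo-genome, filter
#' informative SNPs, test and classify SNPs, call ASE and imprinted genes,
#' run all six pairwise DE comparisons among the four genotypes, compute
#' FPKM and expression breadth over the tissue panel, optionally run
#' enrichment and the TF cross-tab, and write a JSON report.
#'
#' @param config list from [default_run_config()] (or a JSON file path).
#' @param quiet suppress progress messages.
#' @return the report list, invisibly; files under \code{config$out_dir}.
#' @export
run_pipeline <- function(config = default_run_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_json(config, simplifyVector = TRUE)
  cfg <- modifyList(default_run_config(), config)
  if (is.null(cfg$fixtures_dir))      # keep fixtures under the run dir
    cfg$fixtures_dir <- file.path(cfg$out_dir, "fixtures")
  say <- function(...) if (!quiet) message(...)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (isTRUE(cfg$simulate)) {
    say("simulating fixtures (seed ", cfg$seed, ")")
    scfg <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
    write_fixtures(simulate_all(scfg), cfg$fixtures_dir)
  }
  fx <- function(f) file.path(cfg$fixtures_dir, f)
  for (f in c("reference.fasta", "snps.vcf", "genes.gff3",
              "allelic_counts.tsv", "genotype_counts.tsv",
              "tissue_counts.tsv", "gene_lengths.tsv", "cross_design.tsv"))
    if (!file.exists(fx(f)))
      stop("missing fixture '", fx(f), "' - expected a bundle written by ",
           "write_fixtures() (FASTA/VCF/GFF3/TSV)", call. = FALSE)

  say("loading fixtures from ", cfg$fixtures_dir)
  reference <- read_fasta(fx("reference.fasta"))
  models <- load_gene_models(fx("genes.gff3"))
  snps <- load_snps(fx("snps.vcf"), models)
  counts <- read_allelic_counts(fx("allelic_counts.tsv"))
  cross <- read_tsv(fx("cross_design.tsv"))
  geno <- read_count_matrix(fx("genotype_counts.tsv"))
  tissue <- read_count_matrix(fx("tissue_counts.tsv"))
  lens_df <- read_tsv(fx("gene_lengths.tsv"))
  lens <- setNames(lens_df$length, lens_df$gene_id)

  say("building pseudo-genome")
  pseudo <- build_pseudogenome(reference, snps)
  write_fasta(pseudo, file.path(cfg$out_dir, "pseudogenome.fasta"))

  say("filtering informative SNPs")
  fcfg <- do.call(informative_filter_config, cfg$filter)
  flt <- filter_informative_snps(counts, snps, cross, fcfg)
  write_tsv(flt$snps, file.path(cfg$out_dir, "informative_snps.tsv"))

  say("classifying SNPs and calling genes")
  kept <- counts[counts$snp_id %in% flt$snp_ids, , drop = FALSE]
  cr <- reciprocal_pair(cross)
  bias <- do.call(rbind, lapply(cr$hybrid_id, function(h) {
    x <- kept[kept$sample_id == h, , drop = FALSE]
    cbind(snp_id = x$snp_id, hybrid_id = h,
          allelic_bias_test(x$n_allele1, x$n_allele2))
  }))
  patterns <- classify_snps(bias, cross, alpha = cfg$alpha,
                            threshold = cfg$ase_threshold)
  write_tsv(patterns, file.path(cfg$out_dir, "snp_patterns.tsv"))
  ase <- call_ase_genes(patterns, flt$snps)
  imp <- call_imprinted_genes(patterns, flt$snps)
  write_tsv(ase, file.path(cfg$out_dir, "ase_genes.tsv"))
  write_tsv(imp, file.path(cfg$out_dir, "imprinted_genes.tsv"))

  say("differential expression, 6 pairwise comparisons")
  sf <- size_factors(geno)
  model <- estimate_dispersions(geno, sf = sf)   # blind fit, all libraries
  pairs <- utils::combn(colnames(geno), 2L)
  deg_sets <- list()
  deg_counts <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    res <- call_degs(geno, a, b, model = model, sf = sf, alpha = cfg$alpha,
                     min_fold = cfg$min_fold)
    key <- paste(a, b, sep = "_vs_")
    write_tsv(res, file.path(cfg$out_dir, paste0("deg_", key, ".tsv")))
    deg_sets[[key]] <- res$gene_id[res$is_de]
    deg_counts[[key]] <- sum(res$is_de)
  }
  deg_overlap <- pairwise_deg_summary(deg_sets)

  say("expression breadth")
  fpkm <- compute_fpkm(tissue, lens[rownames(tissue)])
  breadth <- expression_breadth(fpkm, min_fpkm = cfg$entropy_min_fpkm)
  write_tsv(breadth, file.path(cfg$out_dir, "expression_breadth.tsv"))
  detected <- detected_gene_sets(geno, min_reads = cfg$min_reads)

  enr <- NULL
  if (!is.null(cfg$annotation_tsv)) {
    say("enrichment of ASE genes vs all genes")
    ann <- read_tsv(cfg$annotation_tsv)
    enr <- enrich_terms(ase$gene_id, rownames(geno), ann, alpha = cfg$alpha)
    write_tsv(enr, file.path(cfg$out_dir, "ase_enrichment.tsv"))
  }
  tf <- NULL
  if (!is.null(cfg$tf_tsv)) {
    tf <- tf_family_crosstab(ase$gene_id, read_tsv(cfg$tf_tsv))
    write_tsv(tf, file.path(cfg$out_dir, "ase_tf_families.tsv"))
  }

  report <- list(
    package_version = as.character(packageVersion("hybridASE")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = cfg,
    informative_snps = flt$summary,
    snp_patterns = as.list(table(patterns$pattern)),
    ase_genes = attr(ase, "summary"),
    imprinted_genes = attr(imp, "summary"),
    deg_counts = deg_counts,
    detected = list(per_genotype = lapply(detected$sets, length),
                    union = detected$union),
    breadth = list(n_included = sum(breadth$included),
                   mean_entropy = mean(breadth$entropy, na.rm = TRUE)),
    enrichment_terms_significant = if (!is.null(enr)) sum(enr$significant),
    tf_families = if (!is.null(tf)) attr(tf, "n_families"))
  write_json(report, file.path(cfg$out_dir, "report.json"),
             auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(list(report = report, ase = ase, imprinted = imp,
                 patterns = patterns, deg_sets = deg_sets,
                 deg_overlap = deg_overlap, breadth = breadth,
                 detected = detected, enrichment = enr, tf = tf))
}
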