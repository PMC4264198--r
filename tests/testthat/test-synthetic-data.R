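test_that("config validation rejects impossible proportions", {
  expect_error(sim_config(frac_ase = 0.6, frac_imprinted_maternal = 0.5),
               "must not exceed 1")
  expect_error(sim_config(bias_level = 0.5), "bias_level")
  expect_error(sim_config(frac_de = 1.2), "proportion")
})

test_that("truth classes follow the configured proportions", {
  # degenerate corners
  t0 <- simulate_truth(sim_config(n_genes = 50, frac_ase = 0, seed = 1))
  expect_true(all(t0$class == "biallelic"))
  t1 <- simulate_truth(sim_config(n_genes = 50, frac_ase = 1, seed = 1))
  expect_true(all(t1$class %in% c("ase_parent1", "ase_parent2")))

  # frozen Binomial(1000, 0.1) 99% interval: [76, 125] (qbinom at .005/.995)
  cfg <- sim_config(n_genes = 1000, frac_ase = 0.1, seed = 3)
  tr <- simulate_truth(cfg)
  n_ase <- sum(tr$class %in% c("ase_parent1", "ase_parent2"))
  expect_gte(n_ase, 76)
  expect_lte(n_ase, 125)
  expect_identical(tr, simulate_truth(cfg))  # rerun-identical
})

test_that("truth table encodes ASE vs imprinting correctly", {
  cfg <- sim_config(n_genes = 400, frac_ase = 0.2,
                    frac_imprinted_maternal = 0.1,
                    frac_imprinted_paternal = 0.1, bias_level = 0.9, seed = 4)
  tr <- simulate_truth(cfg)
  # ASE: same parent-1 fraction in both hybrids; imprinted: flipped
  a1 <- tr[tr$class == "ase_parent1", ]
  expect_true(all(a1$af_hybrid12 == 0.9 & a1$af_hybrid21 == 0.9))
  im <- tr[tr$class == "imprinted_maternal", ]
  expect_true(all(im$af_hybrid12 == 0.9 & im$af_hybrid21 == 1 - 0.9))
  ip <- tr[tr$class == "imprinted_paternal", ]
  expect_true(all(ip$af_hybrid12 == 1 - 0.9 & ip$af_hybrid21 == 0.9))
  # each gene has exactly one class
  expect_false(anyDuplicated(tr$gene_id) > 0)
})

test_that("simulated genomes respect construction invariants", {
  cfg <- sim_config(n_genes = 30, snps_per_gene = 4, seed = 9)
  g <- simulate_genomes(cfg)
  ref <- as.character(g$reference[[1]])
  # parent-1 allele is the reference base at every SNP
  expect_identical(substring(ref, g$snps$pos, g$snps$pos), g$snps$allele1)
  expect_true(all(g$snps$allele1 != g$snps$allele2))
  expect_false(anyDuplicated(g$snps$pos) > 0)
  # SNPs sit inside exons of their assigned gene
  ex <- g$exons[match(g$snps$gene_id, g$exons$gene_id), ]  # first exon only
  gene <- g$genes[match(g$snps$gene_id, g$genes$gene_id), ]
  expect_true(all(g$snps$pos >= gene$start & g$snps$pos <= gene$end))
  # determinism: byte-identical FASTA
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(g$reference, f1)
  write_fasta(simulate_genomes(cfg)$reference, f2)
  expect_identical(readLines(f1), readLines(f2))
  # mean-zero SNP request gives an empty set
  g0 <- simulate_genomes(sim_config(n_genes = 5, snps_per_gene = 0, seed = 1))
  expect_identical(nrow(g0$snps), 0L)
})

test_that("allelic counts have the planted allele fractions", {
  cfg <- sim_config(n_genes = 300, frac_ase = 0.3,
                    frac_imprinted_maternal = 0.15, bias_level = 0.9,
                    mean_snp_depth = 200, seed = 21)
  tr <- simulate_truth(cfg)
  g <- simulate_genomes(cfg)
  ac <- simulate_allelic_counts(cfg, tr, g$snps)
  cls <- tr$class[match(g$snps$gene_id[match(ac$snp_id, g$snps$snp_id)],
                        tr$gene_id)]
  frac <- ac$n_allele1 / (ac$n_allele1 + ac$n_allele2)

  mfrac <- function(class, sample) {
    sel <- cls == class & ac$sample_id == sample
    mean(frac[sel], na.rm = TRUE)
  }
  # ase_parent1: ~0.9 in both hybrids (3 binomial SDs at aggregate n)
  expect_equal(mfrac("ase_parent1", "hybrid12"), 0.9, tolerance = 0.02)
  expect_equal(mfrac("ase_parent1", "hybrid21"), 0.9, tolerance = 0.02)
  # imprinted_maternal: ~0.9 where mother is parent1, ~0.1 in reciprocal
  expect_equal(mfrac("imprinted_maternal", "hybrid12"), 0.9, tolerance = 0.02)
  expect_equal(mfrac("imprinted_maternal", "hybrid21"), 0.1, tolerance = 0.02)
  # biallelic hybrids centred on 0.5
  expect_equal(mfrac("biallelic", "hybrid12"), 0.5, tolerance = 0.02)
  # parents effectively pure for their own allele
  expect_gt(mfrac("biallelic", "parent1"), 0.99)
  expect_lt(mfrac("biallelic", "parent2"), 0.01)

  # zero mean depth gives all-zero counts
  ac0 <- simulate_allelic_counts(
    sim_config(n_genes = 300, mean_snp_depth = 0, seed = 21), tr, g$snps)
  expect_true(all(ac0$n_allele1 + ac0$n_allele2 + ac0$n_other == 0))

  # a hybrid without a cross design errors
  expect_error(simulate_allelic_counts(cfg, tr, g$snps,
                                       cross_design(hybrid_id = c("x", "y"),
                                                    mother = c("a", "b"),
                                                    father = c("b", "a"))),
               "parent1")
  # truth must cover SNP-bearing genes
  expect_error(simulate_allelic_counts(cfg, tr[-1, ], g$snps),
               "does not cover")
})

test_that("expression matrices encode DE and breadth truth", {
  cfg <- sim_config(n_genes = 200, frac_de = 0.2, de_log2fc = 2,
                    frac_tissue_specific = 0.3, expr_dispersion = 0.05,
                    seed = 31)
  tr <- simulate_truth(cfg)
  ex <- simulate_expression_matrix(cfg, tr)
  expect_identical(dim(ex$genotype_counts), c(200L, 4L))
  expect_identical(dim(ex$tissue_counts), c(200L, 11L))

  # planted fold change visible in parent means
  de_up <- tr$de_status & tr$log2fc > 0
  lr <- log2((ex$genotype_counts[de_up, "parent2"] + 1) /
               (ex$genotype_counts[de_up, "parent1"] + 1))
  expect_equal(mean(lr), 2, tolerance = 0.3)

  # entropy limits: tissue-specific concentrated, broad near log2(11)
  h <- shannon_entropy(ex$tissue_counts)
  expect_lt(mean(h[tr$breadth_class == "tissue_specific"], na.rm = TRUE),
            mean(h[tr$breadth_class == "broad"], na.rm = TRUE) - 1)
  # determinism
  ex2 <- simulate_expression_matrix(cfg, tr)
  expect_identical(ex$genotype_counts, ex2$genotype_counts)
  expect_identical(ex$tissue_counts, ex2$tissue_counts)
})

test_that("fixture files round-trip and are deterministic", {
  sim <- small_sim(seed = 77)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  p1 <- write_fixtures(sim, d1)
  write_fixtures(small_sim(seed = 77), d2)

  # byte-identical across reruns with the same config
  for (f in names(p1)) {
    expect_identical(readLines(file.path(d1, basename(p1[f]))),
                     readLines(file.path(d2, basename(p1[f]))),
                     info = f)
  }
  # VCF round trip reproduces the SnpRecord set
  models <- list(genes = sim$genes, exons = sim$exons)
  back <- load_snps(file.path(d1, "snps.vcf"), models)
  expect_setequal(back$snp_id, sim$snps$snp_id)
  m <- match(sim$snps$snp_id, back$snp_id)
  expect_identical(back$pos[m], sim$snps$pos)
  expect_identical(back$allele1[m], sim$snps$allele1)
  expect_identical(back$allele2[m], sim$snps$allele2)
  expect_identical(back$gene_id[m], sim$snps$gene_id)

  # truth row count, count matrices round trip
  expect_identical(nrow(read.delim(file.path(d1, "truth.tsv"))),
                   sim$config$n_genes)
  expect_identical(read_count_matrix(file.path(d1, "genotype_counts.tsv")),
                   sim$genotype_counts)

  # BED is 0-based half-open: shifting start by +1 recovers internal coords
  bed <- read.delim(file.path(d1, "genes.bed"), header = FALSE)
  m <- match(sim$genes$gene_id, bed$V4)
  expect_identical(bed$V2[m] + 1L, sim$genes$start)
  expect_identical(bed$V3[m], sim$genes$end)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("no gene is both ASE-class and imprinted-class", {
  tr <- simulate_truth(sim_config(n_genes = 2000, frac_ase = 0.3,
                                  frac_imprinted_maternal = 0.2,
                                  frac_imprinted_paternal = 0.2, seed = 8))
  expect_identical(anyDuplicated(tr$gene_id), 0L)
  # single class label per gene by construction; check the label space
  expect_true(all(tr$class %in% c("biallelic", "ase_parent1", "ase_parent2",
                                  "imprinted_maternal", "imprinted_paternal")))
})
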