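test_that("size factors match forced scalings and independent oracles", {
  m <- cbind(a = c(10L, 20L, 30L), b = c(10L, 20L, 30L))
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1, 1))

  m2 <- cbind(a = c(10L, 20L, 30L), b = c(20L, 40L, 60L))
  sf2 <- size_factors(m2)
  expect_equal(unname(sf2[2] / sf2[1]), 2)

  set.seed(3)
  m3 <- matrix(rnbinom(600, mu = 50, size = 5), ncol = 4,
               dimnames = list(NULL, paste0("s", 1:4)))
  expect_equal(unname(size_factors(m3)), unname(oracle_size_factors(m3)),
               tolerance = 1e-12)
  # cross-check against the reference implementation (it takes the median
  # of log-ratios, so agreement is close but not exact at even gene counts)
  expect_equal(unname(size_factors(m3)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m3)),
               tolerance = 1e-4)
  expect_error(size_factors(matrix(c(0L, 1L, 1L, 0L), 2)), "no gene")
})

test_that("dispersion fit recovers Poisson and NB regimes", {
  set.seed(7)
  n <- 3000
  mu <- rlnorm(n, log(100), 0.8)
  pois <- sapply(1:6, function(i) rpois(n, mu))
  colnames(pois) <- paste0("s", 1:6)
  fit_p <- estimate_dispersions(pois, sf = rep(1, 6))
  qs <- quantile(mu, c(0.3, 0.5, 0.7))
  # raw variance ~ 0 for Poisson data: v(q)/q^2 well below any real
  # overdispersion
  expect_true(all(fit_p$raw_variance(qs) / qs^2 < 0.05))

  nb <- sapply(1:6, function(i) rnbinom(n, mu = mu, size = 5))
  colnames(nb) <- paste0("s", 1:6)
  fit_nb <- estimate_dispersions(nb, sf = rep(1, 6))
  disp <- fit_nb$raw_variance(qs) / qs^2
  expect_true(all(disp > 0.1 & disp < 0.3))   # truth 0.2 +/- 50%

  # fitted curve monotone for a monotone mean-variance input
  expect_true(all(diff(fit_nb$raw_variance(seq(20, 500, by = 20))) > -1e-8))
})

test_that("NB exact test equals brute-force enumeration for totals <= 20", {
  set.seed(11)
  m <- matrix(rnbinom(2000, mu = 60, size = 8), ncol = 2,
              dimnames = list(NULL, c("A", "B")))
  model <- estimate_dispersions(m, sf = c(1, 1.3))
  for (kS in c(0L, 1L, 5L, 12L, 20L)) {
    for (kA in 0:kS) {
      p <- nb_exact_test(kA, kS - kA, 1, 1.3, model)
      o <- oracle_nb_exact(kA, kS - kA, 1, 1.3, model)
      expect_equal(log(p), log(o), tolerance = 1e-10,
                   info = sprintf("kA=%d kS=%d", kA, kS))
      expect_gt(p, 0); expect_lte(p, 1)
    }
  }
  # modal split: equal counts, equal size factors
  expect_equal(nb_exact_test(30L, 30L, 1, 1, model), 1)
  # scaling stability under the null: doubling counts and library sizes
  p1 <- nb_exact_test(50L, 60L, 1, 1, model)
  p2 <- nb_exact_test(100L, 120L, 2, 2, model)
  expect_lt(abs(log10(p2) - log10(p1)), 1)
})

test_that("BH adjustment matches hand computation and p.adjust", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  set.seed(13)
  p <- runif(200)^2
  expect_equal(adjust_bh(p), p.adjust(p, "BH"), tolerance = 1e-14)
  expect_true(all(adjust_bh(p) >= p))
  # permutation invariance
  o <- sample(seq_along(p))
  expect_equal(adjust_bh(p)[o], adjust_bh(p[o]))
})

test_that("DEG calling enforces the joint rule and finds planted effects", {
  cfg <- sim_config(n_genes = 600, frac_de = 0.1, de_log2fc = 2,
                    mean_expression = 500, expr_dispersion = 0.05, seed = 17)
  tr <- simulate_truth(cfg)
  ex <- simulate_expression_matrix(cfg, tr)
  res <- call_degs(ex$genotype_counts, "parent1", "parent2")

  # joint rule: significant but small fold change is not DE
  fake <- res
  small_fc <- abs(res$log2fc) < 1 & res$adjusted_p < 0.05
  expect_true(all(!res$is_de[small_fc]))

  planted <- tr$gene_id[tr$de_status]
  called <- res$gene_id[res$is_de]
  recall <- length(intersect(called, planted)) / length(planted)
  # scaled-down variant of the depth-500 power scenario (600 genes instead
  # of 1000, so the BH cutoff is a little harsher); the full-size bound of
  # 0.8 lives in the acceptance suite
  expect_gte(recall, 0.7)
  fdp <- length(setdiff(called, planted)) / max(1, length(called))
  expect_lte(fdp, 0.1)

  expect_error(call_degs(ex$genotype_counts, "parent1", "nope"), "nope")
})

test_that("null DE simulation stays near the alpha level", {
  cfg <- sim_config(n_genes = 800, frac_de = 0, mean_expression = 300,
                    expr_dispersion = 0.05, seed = 19)
  tr <- simulate_truth(cfg)
  ex <- simulate_expression_matrix(cfg, tr)
  res <- call_degs(ex$genotype_counts, "parent1", "parent2")
  # raw p < 0.05 rate: at most alpha plus Monte-Carlo slack (the blind
  # dispersion fit is conservative, so typically well below)
  expect_lte(mean(res$p_value < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 800))
  # and essentially nothing survives BH + fold rule
  expect_lte(sum(res$is_de), 0.01 * 800)
})

test_that("DEG overlap summaries count intersections and containment", {
  sets <- list(x = c("A", "B", "C"), y = c("B", "C", "D"), z = c("Z"))
  s <- pairwise_deg_summary(sets, reference = "x")
  xy <- s[s$set1 == "x" & s$set2 == "y", ]
  expect_identical(xy$n_intersection, 2L)
  expect_identical(xy$containment_pct, 100)
  xz <- s[s$set1 == "x" & s$set2 == "z", ]
  expect_identical(xz$n_intersection, 0L)
  ident <- pairwise_deg_summary(list(a = c("A", "B"), b = c("A", "B")),
                                reference = "a")
  expect_identical(ident$containment_pct, 100)
})

test_that("FPKM follows the closed formula and its scaling laws", {
  expect_equal(compute_fpkm(matrix(100L), lengths = 1000, totals = 1e6)[1],
               100)
  expect_equal(compute_fpkm(matrix(0L), lengths = 500, totals = 1e6)[1], 0)
  m <- matrix(c(10L, 40L), nrow = 1, dimnames = list("g", c("a", "b")))
  f1 <- compute_fpkm(m, lengths = 2000, totals = c(1e6, 1e6))
  f2 <- compute_fpkm(m, lengths = 2000, totals = c(2e6, 2e6))
  expect_equal(unname(f1 / f2), matrix(2, 1, 2))
  expect_error(compute_fpkm(m, lengths = 0), "lengths")
  expect_error(compute_fpkm(m, lengths = 10, totals = c(0, 1)), "totals")
})

test_that("entropy hits its closed forms, bounds and scale invariance", {
  expect_equal(shannon_entropy(rep(1, 11)), log2(11), tolerance = 1e-12)
  expect_equal(shannon_entropy(c(0, 0, 7, 0)), 0)
  expect_equal(shannon_entropy(c(0.75, 0.25)), 0.811278124459,
               tolerance = 1e-10)
  expect_true(is.na(shannon_entropy(c(0, 0, 0))))
  set.seed(23)
  x <- matrix(rexp(110), ncol = 11)
  h <- shannon_entropy(x)
  expect_true(all(h >= 0 & h <= log2(11) + 1e-12))
  expect_equal(shannon_entropy(17 * x), h, tolerance = 1e-12)  # H(cx)=H(x)
})

test_that("breadth analysis excludes low-FPKM genes and separates classes", {
  cfg <- sim_config(n_genes = 500, frac_tissue_specific = 0.4, seed = 29)
  tr <- simulate_truth(cfg)
  ex <- simulate_expression_matrix(cfg, tr)
  fpkm <- compute_fpkm(ex$tissue_counts, ex$gene_lengths)
  br <- expression_breadth(fpkm, min_fpkm = 1)
  expect_true(all(is.na(br$entropy[!br$included])))

  hts <- br$entropy[tr$breadth_class == "tissue_specific" & br$included]
  hbr <- br$entropy[tr$breadth_class == "broad" & br$included]
  # planted contrast, as a formal two-sample comparison
  expect_gte(length(hts), 50); expect_gte(length(hbr), 50)
  expect_lt(t.test(hts, hbr, alternative = "less")$p.value, 0.05)
})

test_that("detected-gene sets partition into Venn regions", {
  m <- matrix(0L, nrow = 4, ncol = 2,
              dimnames = list(paste0("g", 1:4), c("a", "b")))
  m["g1", ] <- c(5L, 5L); m["g2", "a"] <- 1L; m["g3", "b"] <- 2L
  d <- detected_gene_sets(m)
  expect_setequal(d$sets$a, c("g1", "g2"))
  expect_identical(sum(d$venn), d$union)
  expect_identical(d$union, 3L)
  expect_identical(unname(d$venn["a&b"]), 1L)
  # all-zero matrix: empty sets
  d0 <- detected_gene_sets(matrix(0L, 2, 2,
                                  dimnames = list(c("x", "y"), c("a", "b"))))
  expect_identical(lengths(d0$sets), c(a = 0L, b = 0L))

  # hybrids expressing the union of parental genes dominate both parents
  pa <- c(1L, 1L, 0L, 0L); pb <- c(0L, 0L, 1L, 1L)
  mm <- cbind(p1 = pa, p2 = pb, hyb = pmax(pa, pb))
  dd <- detected_gene_sets(mm)
  expect_gte(length(dd$sets$hyb),
             max(length(dd$sets$p1), length(dd$sets$p2)))
})
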