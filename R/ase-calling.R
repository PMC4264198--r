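#' Test a SNP's allelic counts for departure from 1:1
#'
#' The workhorse significance test behind both the ASE and the imprinting
#' criteria.  The default is the exact two-sided binomial test of the
#' allele-1 count against proportion 1/2 (the expected 1:1 ratio in an F1).
#' Alternatively, a Fisher's exact test compares the hybrid's allelic table
#' against the pooled parental allelic counts at the same SNP.
#'
#' All arguments are vectorised over SNPs.  A SNP with zero allelic depth is
#' untestable: fraction and p-value are NA.
#'
#' @param n_allele1,n_allele2 allelic read counts.
#' @param method \code{"binomial"} (default) or \code{"fisher"}.
#' @param parent_allele1,parent_allele2 pooled parental counts for the
#'   Fisher variant (ignored for the binomial test).
#' @return data.frame: allele1_fraction, p_value, total_depth, untestable.
#' @examples
#' allelic_bias_test(15, 0)$p_value    # 2 * 0.5^15
#' allelic_bias_test(10, 10)$p_value   # 1
#' @export
allelic_bias_test <- function(n_allele1, n_allele2,
                              method = c("binomial", "fisher"),
                              parent_allele1 = NULL, parent_allele2 = NULL) {
  method <- match.arg(method)
  n_allele1 <- as.integer(n_allele1)
  n_allele2 <- as.integer(n_allele2)
  if (any(n_allele1 < 0 | n_allele2 < 0, na.rm = TRUE))
    stop("allelic counts must be non-negative", call. = FALSE)
  tot <- n_allele1 + n_allele2
  frac <- ifelse(tot > 0, n_allele1 / tot, NA_real_)
  if (method == "binomial") {
    p <- binom_midless_p(n_allele1, tot)
  } else {
    if (is.null(parent_allele1) || is.null(parent_allele2))
      stop("Fisher mode needs pooled parental counts", call. = FALSE)
    p <- mapply(function(a, b, c, d) {
      if (a + b == 0L) return(NA_real_)
      stats::fisher.test(matrix(c(a, b, c, d), nrow = 2L, byrow = TRUE))$p.value
    }, n_allele1, n_allele2, as.integer(parent_allele1),
    as.integer(parent_allele2))
  }
  data.frame(allele1_fraction = frac, p_value = p, total_depth = tot,
             untestable = tot == 0L, stringsAsFactors = FALSE)
}

# exact two-sided binomial p vs 0.5, vectorised.  By symmetry of the null,
# the usual "sum of outcomes no more probable than observed" equals the
# mirrored tail sum: p = 2 * P(X <= min(k, n-k)), capped at 1 (and exactly
# 1 when k = n/2).
binom_midless_p <- function(k, n) {
  m <- pmin(k, n - k)
  p <- pmin(1, 2 * stats::pbinom(m, n, 0.5))
  p[n == 0L] <- NA_real_
  p[m == n - m & n > 0L] <- 1
  p
}

#' Classify SNPs as ASE, imprinted or biallelic across reciprocal hybrids
#'
#' Applies the joint criteria over both hybrids of a reciprocal pair:
#' \itemize{
#'   \item \code{ase_allele1}: significant bias (p < alpha) in both hybrids
#'     and allele-1 fraction > threshold in both (symmetric for
#'     \code{ase_allele2});
#'   \item \code{imprinted_maternal}: significant bias in both hybrids and
#'     the \emph{maternal}-allele fraction > threshold in both — i.e. the
#'     allele-1 fraction in the hybrid whose mother carries allele 1, and
#'     one minus it in the reciprocal (symmetric for paternal);
#'   \item \code{biallelic} otherwise.
#' }
#' With threshold > 0.5 the ASE and imprinting criteria are mutually
#' exclusive: they demand opposite allele-1 fractions in the reciprocal
#' hybrid.  Comparisons are strict (> threshold, < alpha).  A SNP untestable
#' in either hybrid is returned as biallelic with \code{untestable = TRUE}.
#'
#' @param bias data.frame with columns snp_id, hybrid_id, allele1_fraction,
#'   p_value (rows for both hybrids of the pair), e.g. built from
#'   [allelic_bias_test()] results.
#' @param cross the reciprocal [cross_design()].
#' @param alpha per-SNP significance level (default 0.05, uncorrected; pass
#'   BH-adjusted p-values in \code{bias} if correction is wanted).
#' @param threshold major-allele fraction rule (default 0.8, "more than
#'   80\%").
#' @param parent1_id genotype id whose genome carries allele 1.
#' @return data.frame: snp_id, pattern, fraction and p per hybrid,
#'   untestable flag.
#' @export
classify_snps <- function(bias, cross, alpha = 0.05, threshold = 0.8,
                          parent1_id = NULL) {
  cross <- reciprocal_pair(cross, parent1_id)
  hA <- cross$hybrid_id[1L]   # mother carries allele 1
  hB <- cross$hybrid_id[2L]
  a <- bias[bias$hybrid_id == hA, , drop = FALSE]
  b <- bias[bias$hybrid_id == hB, , drop = FALSE]
  ids <- union(a$snp_id, b$snp_id)
  if (!all(ids %in% a$snp_id) || !all(ids %in% b$snp_id))
    stop("bias results missing for one hybrid at some SNPs", call. = FALSE)
  ia <- match(ids, a$snp_id); ib <- match(ids, b$snp_id)
  fA <- a$allele1_fraction[ia]; pA <- a$p_value[ia]
  fB <- b$allele1_fraction[ib]; pB <- b$p_value[ib]

  untestable <- is.na(pA) | is.na(pB)
  sig <- !untestable & pA < alpha & pB < alpha
  pattern <- rep("biallelic", length(ids))
  pattern[sig & fA > threshold & fB > threshold] <- "ase_allele1"
  pattern[sig & (1 - fA) > threshold & (1 - fB) > threshold] <- "ase_allele2"
  # maternal fraction: allele-1 fraction where mother is parent-1, flipped
  # in the reciprocal
  mA <- fA; mB <- 1 - fB
  pattern[sig & mA > threshold & mB > threshold] <- "imprinted_maternal"
  pattern[sig & (1 - mA) > threshold & (1 - mB) > threshold] <- "imprinted_paternal"

  out <- data.frame(snp_id = ids, pattern = pattern,
                    frac_hybrid_a = fA, p_hybrid_a = pA,
                    frac_hybrid_b = fB, p_hybrid_b = pB,
                    untestable = untestable, stringsAsFactors = FALSE)
  attr(out, "hybrids") <- c(hybrid_a = hA, hybrid_b = hB)
  attr(out, "alpha") <- alpha
  attr(out, "threshold") <- threshold
  out
}

# shared gene-level aggregation for ASE and imprinting calls
call_genes_by_pattern <- function(patterns, snp_gene_map, classes) {
  map <- snp_gene_map[!is.na(snp_gene_map$gene_id),
                      c("snp_id", "gene_id"), drop = FALSE]
  x <- merge(patterns[, c("snp_id", "pattern")], map, by = "snp_id")
  genes_tested <- sort(unique(x$gene_id))
  hit <- x[x$pattern %in% classes, , drop = FALSE]
  if (nrow(hit)) {
    tab <- table(hit$gene_id, factor(hit$pattern, levels = classes))
    gene_id <- rownames(tab)
    n_by_class <- as.matrix(tab)
    major <- classes[max.col(n_by_class, ties.method = "first")]
    n_support <- n_by_class[cbind(seq_along(gene_id),
                                  match(major, classes))]
    n_conflict <- rowSums(n_by_class) - n_support
    calls <- data.frame(gene_id = gene_id, status = major,
                        n_supporting_snps = as.integer(n_support),
                        n_conflicting_snps = as.integer(n_conflict),
                        flag = ifelse(n_conflict > 0, "conflicting",
                                      "consistent"),
                        stringsAsFactors = FALSE)
  } else {
    calls <- data.frame(gene_id = character(), status = character(),
                        n_supporting_snps = integer(),
                        n_conflicting_snps = integer(), flag = character(),
                        stringsAsFactors = FALSE)
  }
  rownames(calls) <- NULL
  attr(calls, "summary") <- list(
    n_genes_tested = length(genes_tested),
    n_called = nrow(calls),
    percent = if (length(genes_tested))
      round(100 * nrow(calls) / length(genes_tested), 2) else NA_real_)
  calls
}

#' Call ASE genes from classified SNPs
#'
#' A gene is ASE if it has at least one ASE-pattern SNP.  A gene whose SNPs
#' disagree on direction (both \code{ase_allele1} and \code{ase_allele2})
#' stays ASE but is flagged \code{conflicting}, with the majority direction
#' reported as status.  The summary attribute carries the count and
#' percentage over genes with informative SNPs.
#'
#' @param patterns output of [classify_snps()].
#' @param snp_gene_map SNP table with snp_id and gene_id columns.
#' @return data.frame: gene_id, status, n_supporting_snps,
#'   n_conflicting_snps, flag; attribute \code{summary}.
#' @export
call_ase_genes <- function(patterns, snp_gene_map) {
  call_genes_by_pattern(patterns, snp_gene_map,
                        c("ase_allele1", "ase_allele2"))
}

#' Call imprinted genes from classified SNPs
#'
#' As [call_ase_genes()] but over the parent-of-origin patterns.  In leaf or
#' seedling tissue an empty result is the biologically expected outcome;
#' imprinting in plants is essentially an endosperm phenomenon.
#'
#' @inheritParams call_ase_genes
#' @return data.frame as in [call_ase_genes()] with maternal/paternal
#'   status values.
#' @export
call_imprinted_genes <- function(patterns, snp_gene_map) {
  call_genes_by_pattern(patterns, snp_gene_map,
                        c("imprinted_maternal", "imprinted_paternal"))
}

#' Summarise the maternal-allele fraction distribution of a hybrid
#'
#' Descriptive only (no formality): per-SNP maternal fraction with mean, SD,
#' skewness and a histogram table.  Centred near 0.5 with modest spread when
#' most genes are biallelic.
#'
#' @param counts long allelic-count table.
#' @param cross the reciprocal [cross_design()].
#' @param hybrid_id which hybrid to summarise.
#' @param parent1_id genotype carrying allele 1 (default: mother of the
#'   first hybrid in the ordered pair).
#' @param breaks histogram breaks over [0, 1] (default 20 equal bins).
#' @return list: fractions, mean, sd, skewness, histogram (data.frame of
#'   bin mids and counts), n.
#' @export
allelic_ratio_summary <- function(counts, cross, hybrid_id,
                                  parent1_id = NULL,
                                  breaks = seq(0, 1, by = 0.05)) {
  cross <- reciprocal_pair(cross, parent1_id)
  if (!hybrid_id %in% cross$hybrid_id)
    stop("unknown hybrid '", hybrid_id, "'", call. = FALSE)
  x <- counts[counts$sample_id == hybrid_id, , drop = FALSE]
  tot <- x$n_allele1 + x$n_allele2
  f1 <- ifelse(tot > 0, x$n_allele1 / tot, NA_real_)
  maternal_is_allele1 <- cross$mother[cross$hybrid_id == hybrid_id] ==
    cross$mother[1L]
  m <- if (maternal_is_allele1) f1 else 1 - f1
  m <- m[!is.na(m)]
  h <- graphics::hist(m, breaks = breaks, plot = FALSE)
  sk <- if (length(m) > 2L && stats::sd(m) > 0)
    mean((m - mean(m))^3) / stats::sd(m)^3 else 0
  list(fractions = m, mean = mean(m), sd = stats::sd(m), skewness = sk,
       histogram = data.frame(mid = h$mids, count = h$counts), n = length(m))
}
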