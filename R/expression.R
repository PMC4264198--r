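#' Median-of-ratios size factors
#'
#' Per-library scaling constants: for each gene with a positive geometric
#' mean across libraries, take the ratio of the library's count to that
#' geometric mean; the library's size factor is the median of those ratios.
#' Robust to a minority of differentially expressed genes.
#'
#' @param counts genes x samples non-negative integer matrix.
#' @return named numeric vector of positive size factors.
#' @examples
#' m <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
#' size_factors(m)  # b is twice a
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  log_gm <- rowMeans(log(counts))          # -Inf for genes with any zero
  use <- is.finite(log_gm)
  if (!any(use))
    stop("no gene is expressed in all samples; cannot estimate size factors",
         call. = FALSE)
  gm <- exp(log_gm)
  sf <- apply(counts, 2L, function(col) median(col[use] / gm[use]))
  if (any(!is.finite(sf) | sf <= 0))
    stop("degenerate size factor estimate", call. = FALSE)
  sf
}

#' Fit the mean-variance relation of normalised counts
#'
#' Blind (condition-free) moment estimation in the spirit of the classic
#' unreplicated-design fallback: per gene, the mean \eqn{q} and variance
#' \eqn{w} of size-factor-normalised counts across the pooled samples; then
#' a locally weighted regression of \eqn{\log w} on \eqn{\log q}.  The
#' fitted \emph{raw} variance is \eqn{v(q) = \max(\hat w(q) - q\,\xi, v_0)}
#' where \eqn{\xi} is the mean of the reciprocal size factors (the shot-noise
#' part) and \eqn{v_0} a small floor.  The full variance of a count in
#' library \eqn{j} at base mean \eqn{q} is \eqn{s_j q + s_j^2 v(q)}.
#'
#' When the samples pooled include different conditions, a plain local mean
#' of the per-gene variances would absorb real signal (with one degree of
#' freedom per gene the log-variance noise is enormous, sd about 2.2, so
#' even robust weighting cannot separate the signal).  The fit therefore
#' smooths a \emph{running median} of \eqn{\log w} along \eqn{\log q} and
#' corrects it by the exact chi-square median factor
#' \eqn{\log(\chi^2_{df,0.5}/df)}: the median of the null genes, which is
#' what a minority of truly changed genes cannot move.
#'
#' @param counts genes x samples count matrix (>= 2 samples).
#' @param sf size factors (default: computed from \code{counts}).
#' @param span smoothing fraction: both the running-median window and the
#'   lowess span on the log-log scale (default 0.3).
#' @param floor lower bound for the raw variance (default 1e-8).
#' @return object of class \code{nb_variance_model}: function
#'   \code{raw_variance(q)}, plus the per-gene (q, w) points used.
#' @export
estimate_dispersions <- function(counts, sf = NULL, span = 0.3,
                                 floor = 1e-8) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L)
    stop("need at least two samples to estimate dispersion", call. = FALSE)
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  q <- rowMeans(norm)
  w <- apply(norm, 1L, var)
  xi <- mean(1 / sf)

  use <- q > 0 & w > 0
  if (sum(use) < 10L)
    stop("too few genes with positive mean and variance for the fit",
         call. = FALSE)
  df <- ncol(counts) - 1L
  # median of chi2_df/df; log w is median-unbiased for log Var + this
  log_med_bias <- log(stats::qchisq(0.5, df) / df)

  o <- order(q[use])
  lq <- log(q[use])[o]
  lw <- log(w[use])[o]
  # the median window only needs to defeat outliers (a minority of truly
  # changed genes); keep it narrow and let lowess do the smoothing
  k <- min(201L, length(lw), max(3L, as.integer(0.05 * length(lw)) %/%
                                   2L * 2L + 1L))
  med <- stats::runmed(lw, k, endrule = "median")
  # the shrinking end windows of the running median are easily dominated
  # by truly changed genes (which migrate to extreme pooled means); keep
  # the central 90% of the rank range and extend flat beyond it
  n_use <- length(lq)
  trim <- max(1L, ceiling(0.05 * n_use)):min(n_use, floor(0.95 * n_use))
  fit <- lowess(lq[trim], med[trim], f = span, iter = 0L)
  # outside the fitted range, extend at constant dispersion (variance
  # proportional to q^2), not at constant variance
  raw_variance <- function(qq) {
    lqq <- log(pmax(qq, .Machine$double.xmin))
    lqb <- pmin(pmax(lqq, fit$x[1L]), fit$x[length(fit$x)])
    qb <- exp(lqb)
    lv <- approx(fit$x, fit$y, xout = lqb, rule = 2L,
                 ties = "ordered")$y - log_med_bias
    vb <- pmax(exp(lv) - qb * xi, floor)
    vb * (qq / qb)^2
  }
  structure(list(raw_variance = raw_variance, q = q, w = w, xi = xi,
                 sf = sf, span = span, floor = floor),
            class = "nb_variance_model")
}

#' @export
print.nb_variance_model <- function(x, ...) {
  cat("nb_variance_model over", length(x$sf), "samples,",
      sum(x$q > 0 & x$w > 0), "genes in fit; span", x$span, "\n")
  invisible(x)
}

# NB (or Poisson, if variance <= mean) log-pmf with mean mu, variance v
nb_logpmf <- function(k, mu, v) {
  if (v > mu + 1e-12) {
    size <- mu^2 / (v - mu)
    dnbinom(k, mu = mu, size = size, log = TRUE)
  } else {
    dpois(k, mu, log = TRUE)
  }
}

#' Conditioned negative-binomial exact test
#'
#' Tests whether the counts of a gene in two conditions are consistent with
#' a common expression level.  Conditioning on the total \eqn{k_S = k_A +
#' k_B}, the p-value is the probability, under NB laws for the two
#' conditions parameterised by the fitted mean-variance model, of all splits
#' \eqn{(a, k_S - a)} whose joint probability does not exceed that of the
#' observed split, normalised by the total probability over splits.
#' Accumulation is in log space.
#'
#' @param kA,kB summed counts of the gene in condition A / B.
#' @param sfA,sfB size factors of the samples making up each condition.
#' @param model an [estimate_dispersions()] fit.
#' @return two-sided p-value in (0, 1].
#' @export
nb_exact_test <- function(kA, kB, sfA, sfB, model) {
  stopifnot(inherits(model, "nb_variance_model"))
  kA <- as.integer(kA); kB <- as.integer(kB)
  if (kA < 0 || kB < 0) stop("counts must be non-negative", call. = FALSE)
  kS <- kA + kB
  if (kS == 0L) return(1)
  sA <- sum(sfA); sB <- sum(sfB)
  q0 <- kS / (sA + sB)
  v0 <- model$raw_variance(q0)
  muA <- q0 * sA; varA <- q0 * sA + v0 * sum(sfA^2)
  muB <- q0 * sB; varB <- q0 * sB + v0 * sum(sfB^2)

  a <- 0:kS
  lp <- nb_logpmf(a, muA, varA) + nb_logpmf(kS - a, muB, varB)
  lobs <- lp[kA + 1L]
  keep <- lp <= lobs
  logsum <- function(x) {
    m <- max(x)
    m + log(sum(exp(x - m)))
  }
  p <- exp(logsum(lp[keep]) - logsum(lp))
  min(1, p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sort ascending, multiply by m/rank, enforce
#' monotonicity from the largest down, cap at 1.  NA p-values propagate.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same order as input.
#' @export
adjust_bh <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  pv <- p[ok]
  m <- length(pv)
  o <- order(pv)
  adj <- pv[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out[ok][o] <- adj
  out
}

#' Differential expression between two conditions
#'
#' Runs the NB exact test per gene for one pairwise comparison.  Without
#' replicates (one library per condition) the mean-variance model is fitted
#' blind by pooling \emph{all} columns of the supplied matrix (the classic
#' unreplicated fallback) — conservative, as true between-condition
#' differences inflate the fitted variance.  A gene is called DE when the
#' BH-adjusted p-value is below \code{alpha} \emph{and} the fold change of
#' normalised means (stabilised with a pseudo-count) is at least
#' \code{min_fold}.
#'
#' @param counts genes x samples count matrix (can hold more samples than
#'   the two conditions; size factors and the default blind dispersion fit
#'   come from all columns supplied).
#' @param samples_a,samples_b column names (or indices) of the two
#'   conditions.
#' @param model optional [estimate_dispersions()] fit; default: blind fit on
#'   the compared samples.
#' @param sf optional size factors for all columns of \code{counts}.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param min_fold fold-change threshold (default 2).
#' @param pseudocount added to normalised means before the ratio (default 1).
#' @return data.frame: gene_id, mean_a, mean_b (normalised), log2fc,
#'   p_value, adjusted_p, is_de.
#' @export
call_degs <- function(counts, samples_a, samples_b, model = NULL, sf = NULL,
                      alpha = 0.05, min_fold = 2, pseudocount = 1) {
  counts <- as.matrix(counts)
  bad <- setdiff(c(samples_a, samples_b), colnames(counts))
  if (length(bad))
    stop("unknown condition sample(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(sf)) sf <- size_factors(counts)
  sfA <- sf[samples_a]; sfB <- sf[samples_b]
  if (is.null(model)) model <- estimate_dispersions(counts, sf = sf)
  kA <- as.integer(round(rowSums(counts[, samples_a, drop = FALSE])))
  kB <- as.integer(round(rowSums(counts[, samples_b, drop = FALSE])))
  p <- vapply(seq_along(kA), function(i)
    nb_exact_test(kA[i], kB[i], sfA, sfB, model), 0)
  mean_a <- kA / sum(sfA)
  mean_b <- kB / sum(sfB)
  lfc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))
  padj <- adjust_bh(p)
  data.frame(gene_id = rownames(counts),
             mean_a = mean_a, mean_b = mean_b, log2fc = lfc,
             p_value = p, adjusted_p = padj,
             is_de = padj < alpha & abs(lfc) >= log2(min_fold),
             stringsAsFactors = FALSE)
}

#' Overlap statistics between DEG sets
#'
#' Intersection sizes and containment percentages for pairs (optionally
#' against a reference set, e.g. "what fraction of the genes DE against both
#' parents is also DE between the parents").
#'
#' @param sets named list of character vectors (gene ids).
#' @param reference optional name of a set used for containment of every
#'   pairwise intersection.
#' @return data.frame: set1, set2, n1, n2, n_intersection, and when
#'   \code{reference} is given, n_in_reference and containment_pct.
#' @export
pairwise_deg_summary <- function(sets, reference = NULL) {
  nm <- names(sets)
  if (is.null(nm) || any(nm == ""))
    stop("'sets' must be a named list", call. = FALSE)
  pairs <- utils::combn(nm, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    s1 <- pairs[1L, j]; s2 <- pairs[2L, j]
    inter <- intersect(sets[[s1]], sets[[s2]])
    row <- data.frame(set1 = s1, set2 = s2,
                      n1 = length(sets[[s1]]), n2 = length(sets[[s2]]),
                      n_intersection = length(inter),
                      stringsAsFactors = FALSE)
    if (!is.null(reference)) {
      inref <- intersect(inter, sets[[reference]])
      row$n_in_reference <- length(inref)
      row$containment_pct <- if (length(inter))
        round(100 * length(inref) / length(inter), 2) else NA_real_
    }
    row
  })
  do.call(rbind, rows)
}

#' Fragments per kilobase per million mapped reads
#'
#' The standard closed formula on union-exon gene lengths:
#' \eqn{FPKM = 10^9 k / (L N)} with \eqn{k} the gene's count, \eqn{L} its
#' length in bp and \eqn{N} the library's mapped total.
#'
#' @param counts genes x samples matrix.
#' @param lengths gene lengths in bp (recycled across samples).
#' @param totals per-sample mapped totals (default: column sums).
#' @return FPKM matrix, same shape as \code{counts}.
#' @examples
#' compute_fpkm(matrix(100), lengths = 1000, totals = 1e6)  # 100
#' @export
compute_fpkm <- function(counts, lengths, totals = NULL) {
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop("gene lengths must be > 0", call. = FALSE)
  if (is.null(totals)) totals <- colSums(counts)
  if (any(totals <= 0)) stop("mapped totals must be > 0", call. = FALSE)
  sweep(counts / lengths, 2L, totals, "/") * 1e9
}

#' Shannon entropy of expression across tissues
#'
#' Expression breadth: normalise a gene's expression profile to proportions
#' \eqn{p_t} and return \eqn{H = -\sum_{p_t>0} p_t \log_2 p_t}, in bits.
#' \eqn{H} ranges from 0 (single tissue) to \eqn{\log_2 T} (uniform across
#' \eqn{T} tissues); high entropy means broad expression.  All-zero genes
#' are undefined (NA).
#'
#' @param x matrix (genes x tissues) or a single profile vector.
#' @return numeric vector of entropies (bits), NA for all-zero genes.
#' @examples
#' shannon_entropy(rep(1, 11))      # log2(11) = 3.4594
#' shannon_entropy(c(3, 1) / 4)     # 0.8113
#' @export
shannon_entropy <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (any(x < 0)) stop("expression values must be non-negative", call. = FALSE)
  tot <- rowSums(x)
  p <- x / tot
  h <- -rowSums(ifelse(p > 0, p * log2(p), 0))
  h[tot == 0] <- NA_real_
  unname(h)
}

#' Expression breadth over a tissue FPKM panel
#'
#' Applies the conventional analysis floor — genes whose FPKM never reaches
#' \code{min_fpkm} in any tissue are excluded (flagged NA) — then computes
#' Shannon entropy per gene.
#'
#' @param fpkm genes x tissues FPKM matrix.
#' @param min_fpkm inclusion floor (default 1).
#' @return data.frame: gene_id, entropy (NA when excluded), included.
#' @export
expression_breadth <- function(fpkm, min_fpkm = 1) {
  fpkm <- as.matrix(fpkm)
  included <- apply(fpkm, 1L, max) > min_fpkm
  h <- rep(NA_real_, nrow(fpkm))
  if (any(included)) h[included] <- shannon_entropy(fpkm[included, , drop = FALSE])
  data.frame(gene_id = rownames(fpkm) %||% as.character(seq_len(nrow(fpkm))),
             entropy = h, included = included, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detected-gene sets and their Venn partition
#'
#' A gene counts as detected in a genotype when it has at least
#' \code{min_reads} reads.  Returns the per-genotype sets, the size of every
#' Venn region (exclusive membership pattern) and the union size.
#'
#' @param counts genes x samples matrix.
#' @param min_reads detection threshold (default 1).
#' @return list: \code{sets} (named list of gene ids), \code{venn} (named
#'   integer vector keyed by membership pattern like "a&b"), \code{union}.
#' @export
detected_gene_sets <- function(counts, min_reads = 1L) {
  counts <- as.matrix(counts)
  genes <- rownames(counts) %||% as.character(seq_len(nrow(counts)))
  det <- counts >= min_reads
  sets <- lapply(seq_len(ncol(counts)), function(j) genes[det[, j]])
  names(sets) <- colnames(counts)
  member <- apply(det, 1L, function(z) paste(colnames(counts)[z],
                                             collapse = "&"))
  member <- member[member != ""]
  venn <- table(member)
  list(sets = sets, venn = setNames(as.integer(venn), names(venn)),
       union = sum(rowSums(det) > 0))
}

#' Recompute alignment-summary arithmetic
#'
#' Given a table of per-sample read counts, read lengths and uniquely mapped
#' read counts, recomputes total bases (reads x length) and the per-sample
#' and overall uniquely-mapped percentages (rounded to 2 decimals).
#'
#' @param x data.frame with columns sample, n_reads, read_length,
#'   n_unique_reads.
#' @return list: \code{table} (x plus n_bases and pct_unique columns) and
#'   \code{overall} (list n_reads, n_unique_reads, pct_unique).
#' @export
mapping_rate_summary <- function(x) {
  need <- c("sample", "n_reads", "read_length", "n_unique_reads")
  if (length(setdiff(need, names(x))))
    stop("summary table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  # doubles throughout: read counts x read length overflows 32-bit integers
  x$n_reads <- as.numeric(x$n_reads)
  x$n_unique_reads <- as.numeric(x$n_unique_reads)
  x$n_bases <- x$n_reads * x$read_length
  x$pct_unique <- round(100 * x$n_unique_reads / x$n_reads, 2)
  list(table = x,
       overall = list(n_reads = sum(x$n_reads),
                      n_unique_reads = sum(x$n_unique_reads),
                      pct_unique = round(100 * sum(x$n_unique_reads) /
                                           sum(x$n_reads), 2)))
}
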