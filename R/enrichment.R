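#' Hypergeometric gene-set over/under-representation
#'
#' For each annotation term, tests whether the study set contains more (or
#' fewer) genes with that term than expected by drawing the study set at
#' random from the background.  Both one-sided exact hypergeometric tails
#' are computed; the reported direction is the smaller tail.  Unannotated
#' genes still count in the background and study totals.
#'
#' @param study character vector of gene ids, must be a subset of
#'   \code{background}.  An empty study set yields an empty result.
#' @param background character vector of gene ids ("all genes" universe).
#' @param annotation data.frame with columns gene_id and term (a gene may
#'   carry many terms).
#' @param adjust \code{"BH"} (default) or \code{"none"} across terms.
#' @param alpha significance level recorded in the output flag.
#' @return data.frame: term, study_count, study_size, background_count,
#'   background_size, fold_enrichment, direction, p_over, p_under, p_value,
#'   adjusted_p, significant.
#' @examples
#' bg <- sprintf("g%03d", 1:100)
#' ann <- data.frame(gene_id = bg[1:10], term = "termA")
#' enrich_terms(bg[1:10], bg, ann)   # all of termA in a study of 10
#' @export
enrich_terms <- function(study, background, annotation,
                         adjust = c("BH", "none"), alpha = 0.05) {
  adjust <- match.arg(adjust)
  study <- unique(study); background <- unique(background)
  if (length(setdiff(study, background)))
    stop("study set is not a subset of the background", call. = FALSE)
  empty <- data.frame(term = character(), study_count = integer(),
                      study_size = integer(), background_count = integer(),
                      background_size = integer(), fold_enrichment = numeric(),
                      direction = character(), p_over = numeric(),
                      p_under = numeric(), p_value = numeric(),
                      adjusted_p = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  if (!length(study)) return(empty)
  ann <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "term")])
  if (!nrow(ann)) return(empty)

  N <- length(background)
  n <- length(study)
  K <- table(ann$term)
  in_study <- ann$gene_id %in% study
  k <- table(factor(ann$term[in_study], levels = names(K)))

  terms <- names(K)
  K <- as.integer(K); k <- as.integer(k)
  p_over <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  p_under <- phyper(k, K, N - K, n)
  direction <- ifelse(p_over <= p_under, "over", "under")
  p <- pmin(p_over, p_under)
  padj <- if (adjust == "BH") adjust_bh(p) else p
  out <- data.frame(term = terms, study_count = k, study_size = n,
                    background_count = K, background_size = N,
                    fold_enrichment = (k / n) / (K / N),
                    direction = direction, p_over = p_over,
                    p_under = p_under, p_value = p, adjusted_p = padj,
                    significant = padj < alpha, stringsAsFactors = FALSE)
  out[order(out$p_value), , drop = FALSE]
}

#' Cross-tabulate ASE genes against transcription-factor families
#'
#' Intersects a gene set (typically ASE calls) with an externally supplied
#' transcription-factor annotation and counts members per TF family.
#'
#' @param genes character vector of gene ids.
#' @param tf_table data.frame with columns gene_id and family.
#' @return data.frame (family, n) sorted by decreasing n; attributes
#'   \code{n_tf} (total TFs in the gene set) and \code{n_families}.
#' @export
tf_family_crosstab <- function(genes, tf_table) {
  hit <- tf_table[tf_table$gene_id %in% unique(genes), , drop = FALSE]
  hit <- unique(hit[, c("gene_id", "family")])
  if (!nrow(hit)) {
    out <- data.frame(family = character(), n = integer(),
                      stringsAsFactors = FALSE)
  } else {
    tab <- sort(table(hit$family), decreasing = TRUE)
    out <- data.frame(family = names(tab), n = as.integer(tab),
                      stringsAsFactors = FALSE)
  }
  attr(out, "n_tf") <- length(unique(hit$gene_id))
  attr(out, "n_families") <- nrow(out)
  out
}
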