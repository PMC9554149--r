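# Expression-level statistics: differential expression, co-expression
# screening, rank-based gene-set scoring, and hypergeometric enrichment.

#' Tag a genes-by-samples matrix with its expression scale
#'
#' Expression matrices are plain numeric matrices (genes as rows, samples as
#' columns) carrying a `scale` attribute, either `"count"` or `"tpm"`.
#'
#' @param values Non-negative numeric matrix with row and column names.
#' @param scale `"count"` or `"tpm"`.
#' @return The matrix with a `scale` attribute.
#' @export
expression_matrix <- function(values, scale = c("count", "tpm")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (any(values < 0)) stop("expression values must be non-negative")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  attr(values, "scale") <- scale
  values
}

.expr_scale <- function(x) {
  sc <- attr(x, "scale")
  if (is.null(sc)) "count" else sc
}

#' Median-of-ratios size factors
#'
#' DESeq-style normalization: per-sample median of the ratios of counts to
#' the per-gene geometric mean, computed over genes expressed in all samples.
#'
#' @param counts Count-scale expression matrix.
#' @return Numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use)) stop("no gene is expressed in every sample; cannot normalize")
  apply(counts[use, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - log_gm[use]))
  })
}

#' Differential expression between two sample classes
#'
#' Normalizes read counts by median-of-ratios size factors, then tests each
#' gene with a two-sided Welch t-test on log2(normalized + 1). The log2 fold
#' change is computed from the normalized class means with a pseudocount of
#' one. A gene is flagged as differentially expressed when
#' `|log2FC| >= fc_threshold` (inclusive) and `p < p_threshold` (strict).
#'
#' @param counts Count-scale expression matrix ([expression_matrix()]).
#' @param labels Factor or character vector of class labels per sample, with
#'   exactly two levels.
#' @param positive_class Label treated as the case group; fold changes are
#'   positive-class over the other class. Defaults to the second factor level.
#' @param fc_threshold Minimum absolute log2 fold change (default 1).
#' @param p_threshold P-value cutoff (default 0.05, strict).
#' @return A data.frame per gene: `gene_id`, `log2FC`, `p_value`, `is_deg`,
#'   `direction` (`"up"`/`"down"` relative to the positive class).
#' @export
differential_expression <- function(counts, labels, positive_class = NULL,
                                    fc_threshold = 1, p_threshold = 0.05) {
  if (.expr_scale(counts) != "count") {
    stop("differential_expression expects a count-scale matrix")
  }
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two classes")
  if (any(table(labels) < 2L)) stop("each class needs at least 2 samples")
  if (is.null(positive_class)) positive_class <- levels(labels)[2L]
  pos <- labels == positive_class
  if (!any(pos)) stop("positive_class not found in labels")

  norm <- sweep(counts, 2, size_factors(counts), "/")
  lg <- log2(norm + 1)
  mean_pos <- rowMeans(norm[, pos, drop = FALSE])
  mean_neg <- rowMeans(norm[, !pos, drop = FALSE])
  log2fc <- log2(mean_pos + 1) - log2(mean_neg + 1)

  pvals <- vapply(seq_len(nrow(lg)), function(i) {
    x <- lg[i, pos]; y <- lg[i, !pos]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (mean(x) == mean(y)) 1 else 0
    } else {
      stats::t.test(x, y)$p.value
    }
  }, numeric(1))

  is_deg <- abs(log2fc) >= fc_threshold & pvals < p_threshold
  data.frame(gene_id = rownames(counts), log2FC = log2fc, p_value = pvals,
             is_deg = is_deg,
             direction = ifelse(log2fc >= 0, "up", "down"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pearson co-expression screening
#'
#' Tests every anchor-candidate gene pair and retains those with Pearson
#' correlation strictly above `pcc_threshold` (one-sided: only positive
#' co-expression qualifies) and correlation-test p-value strictly below
#' `p_threshold`. Pairs involving a constant-expression gene are skipped
#' with a warning (the correlation is undefined).
#'
#' @param expr Expression matrix (either scale).
#' @param anchors,candidates Gene ids present in the matrix.
#' @param pcc_threshold Correlation threshold (default 0.6, strict `>`).
#' @param p_threshold P-value threshold (default 1e-4, strict `<`).
#' @return Data.frame of retained pairs: `anchor`, `candidate`, `pcc`, `p_value`.
#' @export
pearson_coexpression <- function(expr, anchors, candidates,
                                 pcc_threshold = 0.6, p_threshold = 1e-4) {
  missing <- setdiff(c(anchors, candidates), rownames(expr))
  if (length(missing) > 0L) {
    stop("genes absent from matrix: ", paste(missing, collapse = ", "))
  }
  if (ncol(expr) < 3L) stop("need at least 3 samples for correlation")
  const <- apply(expr[unique(c(anchors, candidates)), , drop = FALSE], 1,
                 function(v) stats::var(v) == 0)
  const_genes <- names(const)[const]
  if (length(const_genes) > 0L) {
    warning("constant-expression genes skipped: ",
            paste(const_genes, collapse = ", "))
  }
  out <- list()
  for (a in setdiff(anchors, const_genes)) {
    for (b in setdiff(candidates, const_genes)) {
      if (a == b) next
      ct <- stats::cor.test(expr[a, ], expr[b, ], method = "pearson")
      if (ct$estimate > pcc_threshold && ct$p.value < p_threshold) {
        out[[length(out) + 1L]] <- data.frame(
          anchor = a, candidate = b,
          pcc = unname(ct$estimate), p_value = ct$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(anchor = character(0), candidate = character(0),
                      pcc = numeric(0), p_value = numeric(0)))
  }
  do.call(rbind, out)
}

#' Per-sample rank-based gene-set score
#'
#' Single-sample enrichment score in the ssGSEA style: within each sample,
#' genes are ranked by expression and a rank-weighted running-sum statistic
#' (difference of the weighted in-set and unweighted out-of-set empirical
#' distribution functions, summed over the ranking) scores the set. The
#' score is invariant under any strictly monotone within-sample transform of
#' expression and increases when member genes move up in rank. When the set
#' covers every gene the score is defined as zero for all samples.
#'
#' @param expr Expression matrix (either scale).
#' @param set Character vector of member gene ids (a single gene set).
#' @param alpha Rank-weighting exponent (default 0.25, the conventional
#'   ssGSEA weight).
#' @return Named numeric vector, one score per sample.
#' @export
gene_set_score <- function(expr, set, alpha = 0.25) {
  members <- intersect(unique(set), rownames(expr))
  if (length(members) == 0L) {
    stop("gene set has empty intersection with the expression matrix")
  }
  n <- nrow(expr)
  in_set <- rownames(expr) %in% members
  if (all(in_set)) {
    return(stats::setNames(rep(0, ncol(expr)), colnames(expr)))
  }
  apply(expr, 2, function(v) {
    r <- rank(v, ties.method = "average")      # high expression = high rank
    ord <- order(r, decreasing = TRUE)
    inside <- in_set[ord]
    w <- r[ord]^alpha
    step_in <- ifelse(inside, w, 0)
    ecdf_in <- cumsum(step_in) / sum(step_in)
    ecdf_out <- cumsum(!inside) / (n - length(members))
    sum(ecdf_in - ecdf_out) / n
  })
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a query gene list
#' and each set in a collection, both intersected with a gene universe.
#'
#' @param query Character vector of gene ids (must lie in `universe`).
#' @param collection Named list of character vectors (gene sets, e.g. from
#'   [read_gmt()]).
#' @param universe Character vector of all testable gene ids.
#' @param p_threshold Sets with `p < p_threshold` are flagged enriched
#'   (default 1e-4).
#' @return Data.frame per set: `set`, `overlap`, `set_size`, `p_value`,
#'   `enriched`.
#' @export
enrichment_test <- function(query, collection, universe, p_threshold = 1e-4) {
  if (length(query) == 0L || length(universe) == 0L) {
    stop("query and universe must be non-empty")
  }
  query <- unique(query)
  universe <- unique(universe)
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(unique(collection[[nm]]), universe)
    k <- length(intersect(query, members))
    p <- stats::phyper(k - 1L, length(members),
                       length(universe) - length(members),
                       length(query), lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(members),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$enriched <- out$p_value < p_threshold
  out[order(out$p_value), ]
}
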