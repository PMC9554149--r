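# Expression-weighted per-sample aggregation of extracellular features.
#
# For sample s with expression P_i(s) of the i-th transmembrane protein:
#   S_EP(s) = sum_i P_i(s) * EP(i)    and analogously S_EN, S_EW, S_EH.
# The protein set is an explicit input (in the intended use, the
# differentially expressed transmembrane proteins); all proteins are summed
# together regardless of regulation direction.

#' Aggregate extracellular features per sample, weighted by expression
#'
#' Computes the four per-sample features S_EP, S_EN, S_EW, S_EH as the
#' expression-weighted sums of the per-protein features over the provided
#' protein set. Expression weights are taken from a TPM-scale matrix; a
#' count-scale matrix is accepted with a warning.
#'
#' @param expr Expression matrix (genes x samples); TPM scale expected.
#' @param vectors Feature table from [compute_feature_vectors()]; its
#'   `gene_id` column links proteins to matrix rows. Every gene must be
#'   present in the matrix.
#' @return Data.frame with one row per sample: `sample_id`, `S_EP`, `S_EN`,
#'   `S_EW`, `S_EH`.
#' @examples
#' expr <- expression_matrix(
#'   matrix(2, 1, 1, dimnames = list("G1", "s1")), scale = "tpm")
#' vec <- data.frame(protein_id = "P1", gene_id = "G1",
#'                   EP = 3, EN = 1, EC = 2, EW = 100, EH = -2)
#' aggregate_sample_features(expr, vec)  # S_EP = 6
#' @export
aggregate_sample_features <- function(expr, vectors) {
  if (.expr_scale(expr) != "tpm") {
    warning("expression matrix is not TPM scale; weights taken as given")
  }
  if (any(expr < 0)) stop("negative expression values")
  missing <- setdiff(vectors$gene_id, rownames(expr))
  if (length(missing) > 0L) {
    stop("feature-vector genes absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  P <- expr[vectors$gene_id, , drop = FALSE]   # proteins x samples
  agg <- function(feat) as.numeric(crossprod(P, vectors[[feat]]))
  data.frame(sample_id = colnames(expr),
             S_EP = agg("EP"), S_EN = agg("EN"),
             S_EW = agg("EW"), S_EH = agg("EH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-group medians of the sample features
#'
#' @param features Data.frame from [aggregate_sample_features()].
#' @param groups Named vector mapping `sample_id` to a group label (e.g.
#'   BMP, NBMP, NBMP-bone, NBMP-liver, NBMP-lung, GBM). Every sample must
#'   be labeled and no group may be empty.
#' @return Data.frame with one row per group and the median of each feature.
#' @export
group_medians <- function(features, groups) {
  g <- as.character(groups[features$sample_id])
  if (anyNA(g)) {
    stop("unlabeled samples: ",
         paste(features$sample_id[is.na(g)], collapse = ", "))
  }
  out <- do.call(rbind, lapply(split(features, g), function(f) {
    data.frame(n = nrow(f),
               S_EP = stats::median(f$S_EP), S_EN = stats::median(f$S_EN),
               S_EW = stats::median(f$S_EW), S_EH = stats::median(f$S_EH))
  }))
  out$group <- rownames(out)
  rownames(out) <- NULL
  out[, c("group", "n", "S_EP", "S_EN", "S_EW", "S_EH")]
}
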