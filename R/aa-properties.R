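# Amino-acid property tables used by the extracellular feature engine.

# Average molecular weights (Da) of the free amino acids.
.AA_WEIGHT_FREE <- c(
  A = 89.09,  R = 174.20, N = 132.12, D = 133.10, C = 121.16,
  E = 147.13, Q = 146.15, G = 75.07,  H = 155.16, I = 131.17,
  L = 131.17, K = 146.19, M = 149.21, F = 165.19, P = 115.13,
  S = 105.09, T = 119.12, W = 204.23, Y = 181.19, V = 117.15
)

# Average residue (dehydrated, in-chain) masses: free mass minus one water.
.AA_WEIGHT_RESIDUE <- .AA_WEIGHT_FREE - 18.02

# Kyte-Doolittle hydropathy index.
.AA_HYDROPATHY_KD <- c(
  A = 1.8,  R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  E = -3.5, Q = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8,  K = -3.9, M = 1.9,  F = 2.8,  P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Amino-acid property table
#'
#' Bundles the per-residue annotations needed to score extracellular protein
#' segments: the sets of positively charged (arginine, histidine, lysine) and
#' negatively charged (aspartate, glutamate) residues, a molecular-weight
#' vector `W` over the 20 standard amino acids, and a hydropathy vector `H`
#' (Kyte-Doolittle by default). Histidine is counted as positively charged
#' even though it is only partially protonated at physiological pH; this
#' matches the charge bookkeeping the feature definitions assume.
#'
#' @param weights Either `"free"` (average masses of the free amino acids,
#'   e.g. G = 75.07 Da; the default) or `"residue"` (dehydrated in-chain
#'   masses, free mass minus one water), or a named numeric vector over the
#'   20 one-letter codes.
#' @param hydropathy Either `"kd"` (Kyte-Doolittle) or a named numeric
#'   vector over the 20 one-letter codes.
#' @param positive_set,negative_set Character vectors of residue letters
#'   carrying positive / negative charge.
#'
#' @return An object of class `aa_property_table` with elements
#'   `positive_set`, `negative_set`, `W`, `H`, and `alphabet`.
#' @examples
#' tab <- aa_property_table()
#' tab$W[["G"]]
#' @export
aa_property_table <- function(weights = c("free", "residue"),
                              hydropathy = "kd",
                              positive_set = c("R", "H", "K"),
                              negative_set = c("D", "E")) {
  alphabet <- names(.AA_WEIGHT_FREE)
  if (is.character(weights)) {
    weights <- match.arg(weights)
    W <- switch(weights, free = .AA_WEIGHT_FREE, residue = .AA_WEIGHT_RESIDUE)
  } else {
    W <- weights
  }
  if (is.character(hydropathy) && length(hydropathy) == 1L) {
    hydropathy <- match.arg(hydropathy, "kd")
    H <- .AA_HYDROPATHY_KD
  } else {
    H <- hydropathy
  }
  for (v in list(W = W, H = H)) {
    if (!is.numeric(v) || is.null(names(v)) || !setequal(names(v), alphabet)) {
      stop("property vectors must be numeric and keyed by the 20 standard residues")
    }
  }
  W <- W[alphabet]; H <- H[alphabet]
  if (any(W <= 0)) stop("all molecular weights must be positive")
  if (length(intersect(positive_set, negative_set)) > 0L) {
    stop("positive_set and negative_set must be disjoint")
  }
  if (!all(c(positive_set, negative_set) %in% alphabet)) {
    stop("charge sets must use the 20-letter alphabet")
  }
  structure(
    list(positive_set = positive_set, negative_set = negative_set,
         W = W, H = H, alphabet = alphabet),
    class = "aa_property_table"
  )
}

#' Read an amino-acid property table from TSV
#'
#' Expects columns `residue`, `weight`, `hydropathy` covering the 20
#' standard one-letter codes.
#'
#' @param path Path to a tab-separated file.
#' @inheritParams aa_property_table
#' @return An `aa_property_table`.
#' @export
read_property_table <- function(path, positive_set = c("R", "H", "K"),
                                negative_set = c("D", "E")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue", "weight", "hydropathy")
  if (!all(need %in% names(df))) {
    stop("property table needs columns: ", paste(need, collapse = ", "))
  }
  W <- stats::setNames(df$weight, df$residue)
  H <- stats::setNames(df$hydropathy, df$residue)
  aa_property_table(weights = W, hydropathy = H,
                    positive_set = positive_set, negative_set = negative_set)
}
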