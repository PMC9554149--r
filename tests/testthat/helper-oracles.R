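# Independent brute-force oracles and small fixture builders. These
# deliberately avoid the package's internal composition/aggregation code
# paths: everything is recomputed with plain character loops.

# Character-by-character tally of the five extracellular features.
oracle_features <- function(segments, table) {
  chars <- unlist(strsplit(segments, ""))
  EP <- 0; EN <- 0; EW <- 0; EH <- 0
  for (ch in chars) {
    if (ch %in% table$positive_set) EP <- EP + 1
    if (ch %in% table$negative_set) EN <- EN + 1
    EW <- EW + table$W[[ch]]
    EH <- EH + table$H[[ch]]
  }
  c(EP = EP, EN = EN, EC = EP - EN, EW = EW, EH = EH)
}

# Qualifying extracellular subsequences extracted by a plain loop.
oracle_segments <- function(record, min_len = 10) {
  out <- character(0)
  for (i in seq_len(nrow(record$segments))) {
    s <- record$segments[i, ]
    if (s$segment_type == "extracellular" && (s$end - s$start + 1) >= min_len) {
      out <- c(out, substr(record$sequence, s$start, s$end))
    }
  }
  out
}

# Double-loop expression-weighted aggregation.
oracle_aggregate <- function(expr, vectors) {
  out <- matrix(0, ncol(expr), 4,
                dimnames = list(colnames(expr), c("S_EP", "S_EN", "S_EW", "S_EH")))
  for (s in seq_len(ncol(expr))) {
    for (i in seq_len(nrow(vectors))) {
      p <- expr[vectors$gene_id[i], s]
      out[s, ] <- out[s, ] + p * c(vectors$EP[i], vectors$EN[i],
                                   vectors$EW[i], vectors$EH[i])
    }
  }
  out
}

# Pairwise Mann-Whitney AUC with half credit for ties.
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# A random topology record with arbitrary (possibly sub-threshold) segments.
random_record <- function(id) {
  alphabet <- c("A","R","N","D","C","E","Q","G","H","I",
                "L","K","M","F","P","S","T","W","Y","V")
  total <- sample(60:300, 1)
  seq <- paste(sample(alphabet, total, replace = TRUE), collapse = "")
  segs <- list(); pos <- 1
  while (pos <= total) {
    len <- sample(3:40, 1)
    segs[[length(segs) + 1]] <- data.frame(
      segment_type = sample(c("extracellular", "transmembrane",
                              "intracellular"), 1),
      start = pos, end = min(pos + len - 1, total))
    pos <- pos + len
  }
  protein_record(sprintf("P%05d", id), sprintf("G%05d", id), seq,
                 do.call(rbind, segs))
}

# A tiny labeled expression fixture with exact values.
tiny_expr <- function(values, scale = "count") {
  expression_matrix(values, scale = scale)
}
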