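# Extracellular physicochemical features of transmembrane proteins.
#
# For protein i with extracellular residue-composition vector N(i):
#   EP(i) = N_R + N_H + N_K      (positive charges)
#   EN(i) = N_D + N_E            (negative charges)
#   EC(i) = EP(i) - EN(i)        (net charge)
#   EW(i) = W . N(i)             (total molecular weight, Da)
#   EH(i) = H . N(i)             (total hydropathy index)
# Extracellular segments shorter than `min_len` residues are omitted: they
# sit too close to the membrane to contribute to the cell-surface character.

.SEGMENT_TYPES <- c("extracellular", "transmembrane", "intracellular")
.AMBIGUITY_CODES <- c("X", "U", "B", "Z", "J", "O")

#' Construct a protein topology record
#'
#' A record holds one transmembrane protein's amino-acid sequence together
#' with its membrane-topology segments (1-based inclusive coordinates, the
#' UniProt convention) and the gene identifier linking it to expression data.
#'
#' @param protein_id,gene_id Identifiers (single strings).
#' @param sequence Amino-acid sequence (one-letter codes).
#' @param segments A data.frame with columns `segment_type`
#'   (`"extracellular"`, `"transmembrane"` or `"intracellular"`), `start`,
#'   `end`. Segments must be within the sequence, ordered, non-overlapping.
#'
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(protein_id, gene_id, sequence, segments) {
  stopifnot(is.character(protein_id), length(protein_id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  segments <- as.data.frame(segments)
  need <- c("segment_type", "start", "end")
  if (!all(need %in% names(segments)) || nrow(segments) == 0L) {
    stop("segments must be a non-empty data.frame with segment_type/start/end")
  }
  if (!all(segments$segment_type %in% .SEGMENT_TYPES)) {
    stop("unknown segment_type in protein ", protein_id)
  }
  n <- nchar(sequence)
  bad <- segments$start < 1L | segments$end > n | segments$start > segments$end
  if (any(bad)) {
    stop(sprintf("protein %s: segment %d [%d-%d] out of bounds for length-%d sequence",
                 protein_id, which(bad)[1L],
                 segments$start[which(bad)[1L]], segments$end[which(bad)[1L]], n))
  }
  segments <- segments[order(segments$start), , drop = FALSE]
  if (nrow(segments) > 1L &&
      any(segments$start[-1L] <= segments$end[-nrow(segments)])) {
    stop("protein ", protein_id, ": overlapping topology segments")
  }
  structure(list(protein_id = protein_id, gene_id = gene_id,
                 sequence = sequence, segments = segments),
            class = "protein_record")
}

#' Extract qualifying extracellular subsequences
#'
#' Returns the residue strings of the segments annotated `extracellular`,
#' in sequence order, keeping only segments of at least `min_len` residues
#' (segments with fewer than 10 amino acids are dropped by default).
#'
#' @param record A [protein_record].
#' @param min_len Minimum segment length in residues (default 10; a
#'   10-residue segment is kept, a 9-residue one is not).
#' @return A character vector of subsequences (possibly empty).
#' @export
extract_extracellular_segments <- function(record, min_len = 10L) {
  stopifnot(inherits(record, "protein_record"), min_len >= 1L)
  seg <- record$segments
  seg <- seg[seg$segment_type == "extracellular", , drop = FALSE]
  if (nrow(seg) == 0L) return(character(0))
  len <- seg$end - seg$start + 1L
  seg <- seg[len >= min_len, , drop = FALSE]
  if (nrow(seg) == 0L) return(character(0))
  substring(record$sequence, seg$start, seg$end)
}

# Residue composition vector N over the table alphabet; ambiguity codes are
# excluded (contribute nothing) with a warning, anything else errors.
.residue_composition <- function(segments, table) {
  counts <- stats::setNames(integer(length(table$alphabet)), table$alphabet)
  if (length(segments) == 0L) return(counts)
  chars <- strsplit(paste(segments, collapse = ""), "")[[1]]
  unknown <- setdiff(unique(chars), table$alphabet)
  amb <- intersect(unknown, .AMBIGUITY_CODES)
  if (length(amb) > 0L) {
    warning("ambiguity codes excluded from feature counts: ",
            paste(amb, collapse = ", "))
    unknown <- setdiff(unknown, amb)
  }
  if (length(unknown) > 0L) {
    stop("residues outside the 20-letter alphabet: ",
         paste(unknown, collapse = ", "))
  }
  tab <- table(factor(chars, levels = table$alphabet))
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Count extracellular charges
#'
#' Tallies the positively charged residues (EP: R + H + K), the negatively
#' charged residues (EN: D + E) and the net charge (EC = EP - EN) over a set
#' of extracellular subsequences.
#'
#' @param segments Character vector of residue strings.
#' @param table An [aa_property_table].
#' @return Named numeric vector with elements `EP`, `EN`, `EC`.
#' @examples
#' charge_counts("RHKDEGGGGG", aa_property_table())
#' @export
charge_counts <- function(segments, table = aa_property_table()) {
  N <- .residue_composition(segments, table)
  EP <- sum(N[table$positive_set])
  EN <- sum(N[table$negative_set])
  c(EP = EP, EN = EN, EC = EP - EN)
}

#' Total molecular weight and hydropathy of extracellular segments
#'
#' Inner products of the residue-composition vector with the weight vector
#' `W` (giving EW, in Da) and the hydropathy vector `H` (giving EH).
#'
#' @inheritParams charge_counts
#' @return Named numeric vector with elements `EW`, `EH`.
#' @export
physchem_sums <- function(segments, table = aa_property_table()) {
  N <- .residue_composition(segments, table)
  c(EW = sum(table$W * N), EH = sum(table$H * N))
}

#' Compute extracellular feature vectors for a set of proteins
#'
#' Applies the segment-length filter and the five feature definitions
#' (EP, EN, EC, EW, EH) to each protein record. A protein none of whose
#' extracellular segments passes the filter gets an all-zero vector.
#'
#' @param records List of [protein_record] objects with unique protein ids.
#' @param table An [aa_property_table].
#' @param min_len Minimum extracellular segment length (residues).
#' @return A data.frame with one row per protein: `protein_id`, `gene_id`,
#'   `EP`, `EN`, `EC`, `EW`, `EH`, `n_segments_used`.
#' @export
compute_feature_vectors <- function(records, table = aa_property_table(),
                                    min_len = 10L) {
  ids <- vapply(records, function(r) r$protein_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate protein_id: ", ids[duplicated(ids)][1L])
  }
  rows <- lapply(records, function(r) {
    segs <- extract_extracellular_segments(r, min_len = min_len)
    cc <- charge_counts(segs, table)
    ps <- physchem_sums(segs, table)
    data.frame(protein_id = r$protein_id, gene_id = r$gene_id,
               EP = cc[["EP"]], EN = cc[["EN"]], EC = cc[["EC"]],
               EW = ps[["EW"]], EH = ps[["EH"]],
               n_segments_used = length(segs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize feature vectors by regulation direction
#'
#' Per direction (`up` / `down`), counts proteins with strictly positive and
#' strictly negative net charge EC and hydropathy EH (zeros fall in neither
#' bucket) and reports the median molecular weight EW.
#'
#' @param vectors Data.frame as returned by [compute_feature_vectors()].
#' @param direction Named character vector (or factor) mapping `protein_id`
#'   to `"up"` or `"down"`.
#' @return A data.frame with rows per direction and columns `n`,
#'   `EC_positive`, `EC_negative`, `EH_positive`, `EH_negative`, `median_EW`.
#' @export
summarize_feature_table <- function(vectors, direction) {
  if (nrow(vectors) == 0L) stop("empty feature table")
  dir <- as.character(direction[vectors$protein_id])
  if (anyNA(dir)) {
    stop("missing direction for: ",
         paste(vectors$protein_id[is.na(dir)], collapse = ", "))
  }
  if (!all(dir %in% c("up", "down"))) stop("direction must be 'up' or 'down'")
  out <- do.call(rbind, lapply(split(vectors, dir), function(v) {
    data.frame(n = nrow(v),
               EC_positive = sum(v$EC > 0), EC_negative = sum(v$EC < 0),
               EH_positive = sum(v$EH > 0), EH_negative = sum(v$EH < 0),
               median_EW = stats::median(v$EW))
  }))
  out$direction <- rownames(out)
  rownames(out) <- NULL
  out[, c("direction", "n", "EC_positive", "EC_negative",
          "EH_positive", "EH_negative", "median_EW")]
}
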