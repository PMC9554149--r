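# Seeded synthetic cohorts emulating the study design the analysis assumes:
# a heavily imbalanced two-class primary-tumor cohort (brain-metastasized
# vs not), overdispersed negative-binomial read counts with a TPM-like
# companion matrix, ~100 planted differentially expressed transmembrane
# genes (mostly down in the positive class), a small set of informative
# enzymes elevated in the positive class, and a planted Fenton-reaction
# style gene set.

#' Synthetic cohort configuration
#'
#' Defaults mirror the study conditions: 44 positive (brain-metastasized)
#' vs 529 negative samples, negative-class destination subgroups in the
#' published bone/liver/lung proportions, 100 planted differentially
#' expressed transmembrane genes of which 97% are downregulated in the
#' positive class, and 20 informative enzymes elevated in the positive
#' class. The enzyme universe is scaled down from the full human enzyme
#' complement to keep simulation tractable.
#'
#' @param n_pos,n_neg Positive / negative class sizes (default 44 / 529).
#' @param subgroup_proportions Named destination fractions for the negative
#'   class; must sum to 1.
#' @param n_genes Total gene universe size.
#' @param n_tm_de Planted differentially expressed transmembrane genes.
#' @param frac_tm_down Fraction of planted TM genes downregulated in the
#'   positive class (default 0.97).
#' @param n_enzymes Enzyme gene count (default 200, a scaled-down universe).
#' @param n_enzyme_signal Informative enzymes, upregulated in the positive
#'   class (default 20).
#' @param n_fr_genes Size of the planted Fenton-reaction style gene set
#'   (default 64), mildly upregulated in the positive class.
#' @param effect_log2fc Planted absolute log2 fold change for TM and enzyme
#'   signal genes (default 2).
#' @param fr_log2fc Planted log2 fold change of the Fenton-set genes
#'   (default 0.75).
#' @param nb_dispersion Negative-binomial dispersion (default 0.1).
#' @param seed Integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_pos = 44L, n_neg = 529L,
                          subgroup_proportions = c(bone = 113, liver = 215,
                                                   lung = 261) / 589,
                          n_genes = 2000L, n_tm_de = 100L,
                          frac_tm_down = 0.97, n_enzymes = 200L,
                          n_enzyme_signal = 20L, n_fr_genes = 64L,
                          effect_log2fc = 2, fr_log2fc = 0.75,
                          nb_dispersion = 0.1, seed = 1L) {
  cfg <- list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
              subgroup_proportions = subgroup_proportions,
              n_genes = as.integer(n_genes), n_tm_de = as.integer(n_tm_de),
              frac_tm_down = frac_tm_down, n_enzymes = as.integer(n_enzymes),
              n_enzyme_signal = as.integer(n_enzyme_signal),
              n_fr_genes = as.integer(n_fr_genes),
              effect_log2fc = effect_log2fc, fr_log2fc = fr_log2fc,
              nb_dispersion = nb_dispersion, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_pos > 0, n_neg > 0, n_genes > 0, n_tm_de > 0, n_enzymes > 0,
              n_enzyme_signal > 0, n_fr_genes > 0, nb_dispersion > 0,
              frac_tm_down >= 0, frac_tm_down <= 1,
              effect_log2fc >= 0, fr_log2fc >= 0,
              n_enzyme_signal <= n_enzymes)
  })
  if (cfg$n_tm_de + cfg$n_enzymes + cfg$n_fr_genes > cfg$n_genes) {
    stop("n_genes too small for the planted gene groups")
  }
  if (abs(sum(cfg$subgroup_proportions) - 1) > 1e-6 ||
      any(cfg$subgroup_proportions < 0)) {
    stop("subgroup_proportions must be non-negative and sum to 1")
  }
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic expression cohort
#'
#' Draws gene baseline means log-normally, applies the planted fold changes
#' to the positive class (transmembrane genes mostly down, signal enzymes
#' and Fenton-set genes up), and samples negative-binomial read counts with
#' constant dispersion and log-normal library-size factors. A TPM-like
#' matrix is derived by length-normalizing the counts and rescaling every
#' column to sum to 1e6. Planted genes' baseline means are drawn from the
#' upper part of the mean distribution so that their empirical fold change
#' tracks the planted effect.
#'
#' @param config A [cohort_config()].
#' @return List with `counts` and `tpm` ([expression_matrix()]s), `labels`
#'   (data.frame `sample_id`, `class` in BMP/NBMP, `subgroup`), `truth`
#'   (planted gene ids, directions, per-gene means and log2 fold changes,
#'   gene lengths) and `gene_sets` (named list: the planted Fenton-style
#'   set and the enzyme universe).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_bg <- config$n_genes - config$n_tm_de - config$n_enzymes - config$n_fr_genes
  gene_ids <- c(sprintf("TM%04d", seq_len(config$n_tm_de)),
                sprintf("ENZ%04d", seq_len(config$n_enzymes)),
                sprintf("FR%04d", seq_len(config$n_fr_genes)),
                if (n_bg > 0) sprintf("BG%04d", seq_len(n_bg)))
  tm_ids <- grep("^TM", gene_ids, value = TRUE)
  enz_ids <- grep("^ENZ", gene_ids, value = TRUE)
  fr_ids <- grep("^FR", gene_ids, value = TRUE)
  planted <- c(tm_ids, enz_ids[seq_len(config$n_enzyme_signal)], fr_ids)

  base_mean <- stats::setNames(stats::rlnorm(config$n_genes, log(50), 1.2),
                               gene_ids)
  # planted genes sit in the moderately-to-highly expressed range so the
  # empirical fold change is not dominated by shot noise
  base_mean[planted] <- stats::rlnorm(length(planted), log(150), 0.6)

  lfc <- stats::setNames(rep(0, config$n_genes), gene_ids)
  n_down <- round(config$frac_tm_down * config$n_tm_de)
  tm_dir <- rep(c(-1, 1), c(n_down, config$n_tm_de - n_down))
  lfc[tm_ids] <- tm_dir * config$effect_log2fc
  enz_signal <- enz_ids[seq_len(config$n_enzyme_signal)]
  lfc[enz_signal] <- config$effect_log2fc
  lfc[fr_ids] <- config$fr_log2fc

  n <- config$n_pos + config$n_neg
  sample_ids <- sprintf("S%04d", seq_len(n))
  is_pos <- c(rep(TRUE, config$n_pos), rep(FALSE, config$n_neg))
  depth <- stats::rlnorm(n, 0, 0.2)

  mu <- outer(base_mean, depth)                      # genes x samples
  mu[, is_pos] <- mu[, is_pos] * 2^lfc
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$nb_dispersion),
                   nrow = config$n_genes,
                   dimnames = list(gene_ids, sample_ids))

  gene_length <- stats::setNames(stats::rlnorm(config$n_genes, log(1500), 0.35),
                                 gene_ids)
  rate <- counts / gene_length
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6

  subgroup <- c(rep("brain", config$n_pos),
                sample(names(config$subgroup_proportions), config$n_neg,
                       replace = TRUE, prob = config$subgroup_proportions))
  labels <- data.frame(sample_id = sample_ids,
                       class = ifelse(is_pos, "BMP", "NBMP"),
                       subgroup = subgroup, stringsAsFactors = FALSE)

  truth <- list(
    de_gene_ids = tm_ids,
    de_direction = stats::setNames(ifelse(tm_dir < 0, "down", "up"), tm_ids),
    informative_enzyme_ids = enz_signal,
    enzyme_ids = enz_ids,
    fr_gene_ids = fr_ids,
    base_mean = base_mean, log2fc = lfc, gene_length = gene_length)
  list(counts = expression_matrix(counts, "count"),
       tpm = expression_matrix(tpm, "tpm"),
       labels = labels, truth = truth,
       gene_sets = list(fenton_reaction = fr_ids, enzyme_universe = enz_ids))
}

#' Generate synthetic transmembrane protein records
#'
#' Builds random protein sequences over the 20-letter alphabet with
#' alternating membrane-topology segments (extracellular loops, 21-residue
#' transmembrane helices, intracellular loops). Loop lengths are drawn from
#' a mixture so that extracellular segments fall on both sides of the
#' 10-residue feature-filter threshold.
#'
#' @param n Number of records.
#' @param seed Integer seed.
#' @param length_range Two-element residue-count interval for total
#'   sequence length.
#' @param gene_ids Optional gene ids to attach (recycled from
#'   `sprintf("TM%04d", 1:n)` otherwise).
#' @return List of [protein_record] objects.
#' @export
generate_protein_records <- function(n, seed = 1L,
                                     length_range = c(120L, 600L),
                                     gene_ids = NULL) {
  if (n < 1L) stop("n must be positive")
  if (length(length_range) != 2L || length_range[1] > length_range[2]) {
    stop("inverted length_range")
  }
  if (is.null(gene_ids)) gene_ids <- sprintf("TM%04d", seq_len(n))
  stopifnot(length(gene_ids) == n)
  alphabet <- names(.AA_WEIGHT_FREE)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    total <- sample(seq(length_range[1], length_range[2]), 1L)
    seq_chars <- sample(alphabet, total, replace = TRUE)
    # alternate loop / TM-helix / loop ... starting on a random side
    types <- if (stats::runif(1) < 0.5) {
      c("extracellular", "transmembrane", "intracellular", "transmembrane")
    } else {
      c("intracellular", "transmembrane", "extracellular", "transmembrane")
    }
    segs <- list(); pos <- 1L; t_idx <- 1L
    while (pos <= total) {
      ty <- types[(t_idx - 1L) %% 4L + 1L]
      len <- if (ty == "transmembrane") 21L
             else if (stats::runif(1) < 0.25) sample(3:9, 1L)
             else sample(10:150, 1L)
      end <- min(pos + len - 1L, total)
      segs[[length(segs) + 1L]] <- data.frame(
        segment_type = ty, start = pos, end = end, stringsAsFactors = FALSE)
      pos <- end + 1L; t_idx <- t_idx + 1L
    }
    protein_record(sprintf("PROT%04d", i), gene_ids[i],
                   paste(seq_chars, collapse = ""), do.call(rbind, segs))
  })
}

#' Generate reaction-equation fixtures with known net proton truth
#'
#' Produces a list of reaction strings spanning proton-producing,
#' proton-consuming and neutral cases (including a coefficient greater than
#' one on the proton term and species whose names contain "+"), each with
#' its true net H+ coefficient.
#'
#' @param seed Integer seed (controls the randomized extra cases).
#' @param n_random Number of additional randomized reactions.
#' @return Data.frame with columns `reaction` and `true_net_h`.
#' @export
generate_reaction_fixtures <- function(seed = 1L, n_random = 10L) {
  fixed <- data.frame(
    reaction = c(
      "A + B → C",
      "ATP + L-seryl-[protein] -> ADP + H+ + O-phospho-L-seryl-[protein]",
      "X + 3 S-adenosyl-L-methionine → 3 H+ + Y",
      "H+ + bicarbonate → CO2 + H2O",
      "2 H+ + Q -> R + H+",
      "H2O + NAD+ + xanthine → H^+^ + NADH + urate"),
    true_net_h = c(0L, 1L, 3L, -1L, -1L, 1L),
    stringsAsFactors = FALSE)
  set.seed(seed)
  extra <- do.call(rbind, lapply(seq_len(n_random), function(i) {
    hs <- sample(0:3, 1L); hp <- sample(0:3, 1L)
    sub <- c(sprintf("SUB%d", seq_len(sample(1:3, 1L))),
             if (hs > 0) if (hs == 1L) "H+" else paste(hs, "H+"))
    prod <- c(sprintf("PRD%d", seq_len(sample(1:3, 1L))),
              if (hp > 0) if (hp == 1L) "H+" else paste(hp, "H+"))
    data.frame(reaction = paste(paste(sub, collapse = " + "), "->",
                                paste(prod, collapse = " + ")),
               true_net_h = hp - hs, stringsAsFactors = FALSE)
  }))
  rbind(fixed, extra)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes the count and TPM matrices, the label table, the planted gene
#' sets (GMT) and the simulation truth (JSON) into a directory.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             tpm = file.path(dir, "tpm.tsv"),
             labels = file.path(dir, "labels.tsv"),
             gene_sets = file.path(dir, "gene_sets.gmt"),
             truth = file.path(dir, "truth.json"))
  write_expression_tsv(cohort$counts, paths[["counts"]])
  write_expression_tsv(cohort$tpm, paths[["tpm"]])
  write_labels_tsv(cohort$labels, paths[["labels"]])
  write_gmt(cohort$gene_sets, paths[["gene_sets"]])
  jsonlite::write_json(cohort$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
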