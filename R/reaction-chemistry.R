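# Enzymatic reaction equations and net proton (H+) accounting.
#
# Reactions are flat stoichiometric equations, e.g.
#   "H2O + NAD+ + xanthine -> H+ + NADH + urate"
# Terms are separated by " + " (plus surrounded by spaces), so species names
# containing "+" such as "NAD+" survive. A term may carry an integer
# coefficient ("3 S-adenosyl-L-methionine"). Only explicit proton species
# count toward net H+ production; water and hydroxide are never decomposed.

.ARROWS <- c(" → ", " -> ")
.BIDIRECTIONAL <- c(" ↔ ", " <-> ", " <=> ", " ⇌ ")
.PROTON_SPELLINGS <- c("H+", "H^+^", "H⁺")

.normalize_species <- function(s) {
  s <- gsub("\\s+", " ", trimws(s))
  if (s %in% .PROTON_SPELLINGS) "H+" else s
}

.parse_side <- function(side, raw) {
  terms <- strsplit(side, " + ", fixed = TRUE)[[1]]
  terms <- trimws(terms)
  if (length(terms) == 0L || any(terms == "")) {
    stop("empty term in reaction side: ", raw)
  }
  coef <- rep(1L, length(terms))
  species <- character(length(terms))
  for (i in seq_along(terms)) {
    m <- regmatches(terms[i], regexec("^([0-9]+) (.+)$", terms[i]))[[1]]
    if (length(m) == 3L) {
      coef[i] <- as.integer(m[2])
      if (coef[i] < 1L) stop("malformed coefficient in term: ", terms[i])
      species[i] <- .normalize_species(m[3])
    } else {
      species[i] <- .normalize_species(terms[i])
    }
  }
  data.frame(coefficient = coef, species = species, stringsAsFactors = FALSE)
}

#' Parse an enzymatic reaction equation
#'
#' Splits a reaction string on a forward arrow (`"->"` or the Unicode right
#' arrow) into substrate and product stoichiometric terms. Bidirectional
#' arrows are rejected. Proton spellings `"H+"`, `"H^+^"` and the Unicode
#' superscript-plus form are normalized to `"H+"`.
#'
#' @param text A single reaction string.
#' @return An object of class `reaction_equation` with elements
#'   `substrates`, `products` (data.frames of `coefficient`, `species`) and
#'   `raw_text`.
#' @examples
#' parse_reaction("H2O + NAD+ + xanthine -> H+ + NADH + urate")
#' @export
parse_reaction <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  for (arr in .BIDIRECTIONAL) {
    if (grepl(arr, text, fixed = TRUE)) {
      stop("bidirectional reactions are not supported: ", text)
    }
  }
  side <- NULL
  for (arr in .ARROWS) {
    if (grepl(arr, text, fixed = TRUE)) {
      side <- strsplit(text, arr, fixed = TRUE)[[1]]
      break
    }
  }
  if (is.null(side) || length(side) != 2L) {
    stop("reaction must contain exactly one forward arrow: ", text)
  }
  structure(list(substrates = .parse_side(side[1], text),
                 products = .parse_side(side[2], text),
                 raw_text = text),
            class = "reaction_equation")
}

#' Render a reaction equation back to text
#'
#' @param rxn A `reaction_equation`.
#' @return A reaction string with `" -> "` arrow; unit coefficients omitted.
#' @export
render_reaction <- function(rxn) {
  fmt <- function(df) paste(
    ifelse(df$coefficient == 1L, df$species,
           paste(df$coefficient, df$species)),
    collapse = " + ")
  paste(fmt(rxn$substrates), "->", fmt(rxn$products))
}

#' Net proton coefficient of a reaction
#'
#' Summed stoichiometric coefficient of the proton species on the product
#' side minus the substrate side. Only explicit `H+` terms count; `H2O` and
#' `OH-` are not decomposed into protons.
#'
#' @param rxn A `reaction_equation` from [parse_reaction()].
#' @return Integer net H+ coefficient (positive = proton-producing).
#' @export
net_proton_coefficient <- function(rxn) {
  stopifnot(inherits(rxn, "reaction_equation"))
  h <- function(df) sum(df$coefficient[df$species == "H+"])
  as.integer(h(rxn$products) - h(rxn$substrates))
}

#' Classify reactions by net proton production
#'
#' @param rxns List of `reaction_equation` objects (or reaction strings,
#'   which are parsed).
#' @return List with `table` (data.frame `reaction`, `net_h`, `label` where
#'   label is `producing` / `consuming` / `neutral`) and `counts` (named
#'   vector of label counts).
#' @export
classify_h_producing <- function(rxns) {
  rxns <- lapply(rxns, function(r) {
    if (is.character(r)) parse_reaction(r) else r
  })
  net <- vapply(rxns, net_proton_coefficient, integer(1))
  label <- ifelse(net > 0, "producing", ifelse(net < 0, "consuming", "neutral"))
  tab <- data.frame(reaction = vapply(rxns, function(r) r$raw_text, character(1)),
                    net_h = net, label = label, stringsAsFactors = FALSE)
  counts <- vapply(c("producing", "consuming", "neutral"),
                   function(l) sum(label == l), integer(1))
  list(table = tab, counts = counts)
}

#' Read a reaction table
#'
#' Reads a TSV with one reaction per line. If the file has a header with a
#' `reaction` column, that column is used and any other columns (e.g. an
#' enzyme name and group-median expression values) are carried through;
#' otherwise each whole line is taken as a reaction string.
#'
#' @param path Path to the file.
#' @return Data.frame with at least a `reaction` column.
#' @export
read_reaction_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\\breaction\\b", first)) {
    utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                      fileEncoding = "UTF-8")
  } else {
    data.frame(reaction = readLines(path, encoding = "UTF-8"),
               stringsAsFactors = FALSE)
  }
}

#' Curated proton-producing reactions of brain-metastasis enzymes
#'
#' Returns the bundled table of the enzymatic reactions catalyzed by the 16
#' selected enzymes with elevated expression in brain-metastasized primary
#' tumors, together with their published group-median TPM values.
#'
#' @return Data.frame with columns `enzyme`, `median_tpm_bmp`,
#'   `median_tpm_nbmp`, `reaction`.
#' @export
bmp_enzyme_reactions <- function() {
  read_reaction_table(system.file("extdata", "bmp_enzyme_reactions.tsv",
                                  package = "brainmet", mustWork = TRUE))
}
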