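AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AMBIGUOUS_AA <- c("X", "B", "Z")

#' Construct a phenotype-labelled alignment
#'
#' The central tabular container for ortholog alignment analysis: one row per
#' species, holding the aligned sequence and a responder/non-responder label.
#'
#' @param species Character vector of species identifiers.
#' @param phenotype Character vector, each `"responder"` or `"nonresponder"`.
#' @param seq Character vector of aligned sequences (equal lengths; `-` gaps).
#' @param reference Species whose ungapped sequence defines residue numbering.
#'   Defaults to the first responder.
#' @return A tibble of class `phenotype_alignment` with columns `species`,
#'   `phenotype`, `seq` and a `reference` attribute.
#' @export
phenotype_alignment <- function(species, phenotype, seq, reference = NULL) {
  if (length(species) != length(phenotype) || length(species) != length(seq)) {
    stop_input("species, phenotype and seq must have equal length")
  }
  if (!all(phenotype %in% c("responder", "nonresponder"))) {
    stop_input("phenotype labels must be 'responder' or 'nonresponder'")
  }
  if (length(unique(nchar(seq))) != 1) {
    stop_input("aligned sequences must all have the same length")
  }
  if (!any(phenotype == "responder") || !any(phenotype == "nonresponder")) {
    stop_input("alignment needs at least one responder and one non-responder")
  }
  reference <- reference %||% species[phenotype == "responder"][1]
  if (!reference %in% species) {
    stop_input("reference species '", reference, "' not present in alignment")
  }
  out <- tibble(species = as.character(species), phenotype = phenotype,
                seq = toupper(seq))
  attr(out, "reference") <- reference
  class(out) <- c("phenotype_alignment", class(out))
  out
}

alignment_reference <- function(alignment) {
  ref <- attr(alignment, "reference")
  ref %||% alignment$species[alignment$phenotype == "responder"][1]
}

# alignment as a character matrix (rows = species, cols = alignment columns)
alignment_matrix <- function(alignment) {
  m <- do.call(rbind, strsplit(alignment$seq, ""))
  rownames(m) <- alignment$species
  m
}

#' Read an aligned FASTA plus a species-phenotype label table
#'
#' @param fasta Path to an aligned FASTA file (names are species ids).
#' @param labels Path to a two-column TSV (`species`, `phenotype`).
#' @param reference Reference species for residue numbering (default: first
#'   responder).
#' @return A [phenotype_alignment()].
#' @export
read_alignment <- function(fasta, labels, reference = NULL) {
  if (!file.exists(fasta)) stop_input("alignment file not found: ", fasta)
  if (!file.exists(labels)) stop_input("labels file not found: ", labels)
  aa <- Biostrings::readAAStringSet(fasta)
  lab <- utils::read.table(labels, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("species", "phenotype") %in% names(lab))) {
    stop_input("labels TSV must have columns 'species' and 'phenotype'")
  }
  sp <- names(aa)
  miss <- setdiff(sp, lab$species)
  if (length(miss) > 0) stop_input("species missing from labels: ",
                                   paste(miss, collapse = ", "))
  phen <- lab$phenotype[match(sp, lab$species)]
  phenotype_alignment(sp, phen, unname(as.character(aa)),
                      reference = reference)
}

#' Write an alignment as FASTA plus a labels TSV
#'
#' @param alignment A [phenotype_alignment()].
#' @param fasta,labels Output paths.
#' @return Invisibly, the alignment.
#' @export
write_alignment <- function(alignment, fasta, labels) {
  aa <- Biostrings::AAStringSet(setNames(alignment$seq, alignment$species))
  Biostrings::writeXStringSet(aa, fasta)
  utils::write.table(
    data.frame(species = alignment$species, phenotype = alignment$phenotype),
    labels, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(alignment)
}
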