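#' Coverage of a reference sequence by a candidate isoform
#'
#' Aligns the candidate against the reference with an end-to-end (global)
#' affine-gap alignment under BLOSUM62 and returns the fraction of reference
#' positions paired with a candidate residue. Used to pick one ortholog per
#' species among multiple isoforms.
#'
#' @param candidate,reference Protein sequences (single strings).
#' @param gap_opening,gap_extension Affine gap penalties (positive costs).
#' @return Coverage fraction in `[0, 1]`.
#' @examples
#' pairwise_coverage("MKTAYIA", "MKTAYIA")
#' @export
pairwise_coverage <- function(candidate, reference,
                              gap_opening = 10, gap_extension = 4) {
  for (s in c(candidate, reference)) {
    if (!is.character(s) || length(s) != 1 || nchar(s) == 0) {
      stop_input("sequences must be non-empty single strings")
    }
    bad <- setdiff(strsplit(toupper(s), "")[[1]], c(AA_ALPHABET, AMBIGUOUS_AA))
    if (length(bad) > 0) {
      stop_input("invalid amino-acid characters: ", paste(unique(bad), collapse = ", "))
    }
  }
  mat <- get_blosum62()
  pa <- Biostrings::pairwiseAlignment(
    toupper(candidate), toupper(reference), type = "global",
    substitutionMatrix = mat,
    gapOpening = gap_opening, gapExtension = gap_extension)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  sum(s != "-" & p != "-") / nchar(reference)
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Select one ortholog per species by reference coverage
#'
#' Per species, picks the candidate with maximal coverage against the
#' reference; ties are broken in favour of RefSeq entries, and remaining ties
#' by lexicographically smallest source id. When several reference
#' representatives are supplied, a candidate's coverage is the maximum over
#' representatives (recorded per representative in the report).
#'
#' @param candidates Data frame with columns `species`, `source_id`,
#'   `sequence`, `is_refseq` (logical).
#' @param reference Character vector of one or more reference protein
#'   sequences.
#' @return A tibble of class `ortholog_selection`: all candidates with their
#'   `coverage` and a `chosen` flag; per-representative coverages are in the
#'   `coverage_by_ref` list-column.
#' @export
select_orthologs <- function(candidates, reference) {
  req <- c("species", "source_id", "sequence", "is_refseq")
  if (!all(req %in% names(candidates))) {
    stop_input("candidates must have columns ", paste(req, collapse = ", "))
  }
  if (nrow(candidates) == 0) stop_input("no candidates supplied")
  cov_by_ref <- purrr::map(candidates$sequence, function(sq) {
    vapply(reference, function(r) pairwise_coverage(sq, r), numeric(1),
           USE.NAMES = FALSE)
  })
  out <- as_tibble(candidates) |>
    dplyr::mutate(
      coverage_by_ref = cov_by_ref,
      coverage = vapply(cov_by_ref, max, numeric(1))
    ) |>
    dplyr::group_by(.data$species) |>
    dplyr::mutate(
      chosen = rank_candidates(.data$coverage, .data$is_refseq, .data$source_id)
    ) |>
    dplyr::ungroup()
  class(out) <- c("ortholog_selection", class(out))
  out
}

# TRUE for the single winning candidate under the coverage > refseq > id rule
rank_candidates <- function(coverage, is_refseq, source_id) {
  ord <- order(-coverage, !is_refseq, source_id)
  out <- rep(FALSE, length(coverage))
  out[ord[1]] <- TRUE
  out
}

#' Map alignment columns to reference residue numbers
#'
#' Column `c` maps to the count of non-gap reference characters in columns
#' `1..c` when the reference is not gapped at `c`, and to `NA` otherwise.
#'
#' @param alignment A [phenotype_alignment()].
#' @param reference Reference species (default: the alignment's reference).
#' @return Tibble with columns `column` and `ref_residue` (`NA` at reference
#'   gaps); `ref_residue` is strictly increasing over its non-`NA` entries.
#' @export
column_to_residue_map <- function(alignment, reference = NULL) {
  reference <- reference %||% alignment_reference(alignment)
  if (!reference %in% alignment$species) {
    stop_input("reference species '", reference, "' not in alignment")
  }
  refseq <- strsplit(alignment$seq[alignment$species == reference][1], "")[[1]]
  nongap <- refseq != "-"
  resnum <- cumsum(nongap)
  resnum[!nongap] <- NA_integer_
  tibble(column = seq_along(refseq), ref_residue = as.integer(resnum))
}

#' Find phenotype-separating alignment columns
#'
#' A column separates the phenotypes when the set of amino-acid identities in
#' the responder group is disjoint from the set in the non-responder group.
#' Ambiguity codes (X, B, Z) are dropped from the identity sets before the
#' disjointness test and flagged. Under the default gap policy, columns with a
#' gap in any sequence are excluded from the test and reported via the
#' `excluded_columns` attribute; `gap_policy = "identity"` instead treats
#' `-` as a 21st identity.
#'
#' @param alignment A [phenotype_alignment()].
#' @param gap_policy `"exclude"` (default) or `"identity"`.
#' @param reference Reference species for residue numbering.
#' @return Tibble of class `separating_positions`: one row per separating
#'   column with `column`, `ref_residue`, per-group identity multisets
#'   (comma-joined, in species order), unique identity sets, `pattern`
#'   (`conserved-in-responders`, `conserved-in-nonresponders`,
#'   `both-variable`, or `both-conserved`) and an `ambiguous` flag.
#' @export
find_separating_positions <- function(alignment,
                                      gap_policy = c("exclude", "identity"),
                                      reference = NULL) {
  gap_policy <- match.arg(gap_policy)
  if (!all(c("species", "phenotype", "seq") %in% names(alignment))) {
    stop_input("alignment must have columns species, phenotype, seq")
  }
  if (!any(alignment$phenotype == "responder") ||
      !any(alignment$phenotype == "nonresponder")) {
    stop_input("alignment must contain both phenotypes")
  }
  m <- alignment_matrix(alignment)
  is_resp <- alignment$phenotype == "responder"
  rmap <- column_to_residue_map(alignment, reference)$ref_residue

  rows <- vector("list", ncol(m))
  excluded <- integer(0)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (gap_policy == "exclude" && any(col == "-")) {
      excluded <- c(excluded, j)
      next
    }
    resp <- col[is_resp]
    nonr <- col[!is_resp]
    ambiguous <- any(col %in% AMBIGUOUS_AA)
    rset <- setdiff(unique(resp), AMBIGUOUS_AA)
    nset <- setdiff(unique(nonr), AMBIGUOUS_AA)
    if (length(rset) == 0 || length(nset) == 0) next
    if (length(intersect(rset, nset)) > 0) next
    pattern <- if (length(rset) == 1 && length(nset) == 1) "both-conserved"
      else if (length(rset) == 1) "conserved-in-responders"
      else if (length(nset) == 1) "conserved-in-nonresponders"
      else "both-variable"
    rows[[j]] <- tibble(
      column = j,
      ref_residue = rmap[j],
      responder_ids = paste(resp, collapse = ","),
      nonresponder_ids = paste(nonr, collapse = ","),
      responder_set = paste(sort(rset), collapse = ","),
      nonresponder_set = paste(sort(nset), collapse = ","),
      pattern = pattern,
      ambiguous = ambiguous
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(column = integer(), ref_residue = integer(),
                  responder_ids = character(), nonresponder_ids = character(),
                  responder_set = character(), nonresponder_set = character(),
                  pattern = character(), ambiguous = logical())
  }
  attr(out, "excluded_columns") <- excluded
  attr(out, "gap_policy") <- gap_policy
  attr(out, "reference") <- reference %||% alignment_reference(alignment)
  class(out) <- c("separating_positions", class(out))
  out
}

#' Per-group conservation profile of one alignment column
#'
#' Tallies identities per phenotype group and lists the species deviating from
#' the column's overall majority identity (e.g. a His in one species at an
#' otherwise universally conserved Tyr).
#'
#' @param alignment A [phenotype_alignment()].
#' @param column 1-based alignment column index.
#' @return A list of class `conservation_profile`: `counts` (tibble
#'   `phenotype`, `identity`, `n`), `majority` (modal identity, alphabetical
#'   tie-break), and `exceptions` (tibble `species`, `phenotype`, `identity`).
#' @export
conservation_profile <- function(alignment, column) {
  m <- alignment_matrix(alignment)
  if (!is.numeric(column) || length(column) != 1 ||
      column < 1 || column > ncol(m)) {
    stop_input("column must be a single index in 1..", ncol(m))
  }
  col <- m[, column]
  counts <- tibble(species = alignment$species,
                   phenotype = alignment$phenotype,
                   identity = col) |>
    dplyr::count(.data$phenotype, .data$identity, name = "n")
  tab <- sort(table(col), decreasing = TRUE)
  majority <- names(tab)[tab == max(tab)][1]
  exceptions <- tibble(species = alignment$species,
                       phenotype = alignment$phenotype,
                       identity = col)[col != majority, ]
  structure(list(column = column, counts = counts, majority = majority,
                 exceptions = exceptions),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("Column", x$column, "- majority identity:", x$majority, "\n")
  print(x$counts)
  if (nrow(x$exceptions) > 0) {
    cat("Exceptions:\n")
    print(x$exceptions)
  } else {
    cat("No exceptions (column uniform).\n")
  }
  invisible(x)
}

#' Write a separating-positions report as TSV
#'
#' @param positions A `separating_positions` tibble.
#' @param path Output path.
#' @return Invisibly, `positions`.
#' @export
write_positions_report <- function(positions, path) {
  utils::write.table(as.data.frame(positions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(positions)
}
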