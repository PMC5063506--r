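test_that("coverage is 1 for identical sequences and 0.5 for a half prefix", {
  expect_equal(pairwise_coverage("MKTAYIAKQR", "MKTAYIAKQR"), 1.0)
  ref <- "MKTAYIAKQRQISFVK"
  expect_equal(pairwise_coverage(substr(ref, 1, 8), ref), 0.5)
})

test_that("coverage rejects empty or invalid sequences", {
  expect_error(pairwise_coverage("", "MKT"), class = "specmap_input_error")
  expect_error(pairwise_coverage("MKT", "M1T"), class = "specmap_input_error")
})

test_that("alignment score behind coverage matches exhaustive affine-gap enumeration", {
  sub <- Biostrings::pairwiseAlignment  # just to assert the dep is present
  data(BLOSUM62, package = "Biostrings", envir = environment())
  withr::with_seed(21, {
    for (i in 1:25) {
      a <- paste(sample(c("A", "R", "K", "G", "W"), sample(2:5, 1),
                        replace = TRUE), collapse = "")
      b <- paste(sample(c("A", "R", "K", "G", "W"), sample(2:5, 1),
                        replace = TRUE), collapse = "")
      pa <- Biostrings::pairwiseAlignment(
        a, b, type = "global", substitutionMatrix = BLOSUM62,
        gapOpening = 10, gapExtension = 4)
      expect_equal(Biostrings::score(pa),
                   bf_global_affine_score(a, b, BLOSUM62), tolerance = 1e-9)
    }
  })
})

test_that("ortholog selection follows coverage > refseq > source-id", {
  cand <- tibble::tibble(
    species = c("sp1", "sp1", "sp2", "sp2", "sp2"),
    source_id = c("b1", "a1", "c2", "a2", "b2"),
    sequence = c("MKTAYIAKQR", "MKTAY", "MKTAYIAKQR", "MKTAYIAKQR", "MKTA"),
    is_refseq = c(FALSE, TRUE, FALSE, TRUE, TRUE))
  sel <- select_orthologs(cand, "MKTAYIAKQR")
  chosen <- sel[sel$chosen, ]
  # sp1: higher coverage wins despite refseq flag on the short one
  expect_identical(chosen$source_id[chosen$species == "sp1"], "b1")
  # sp2: coverage tie between a2 and c2 -> refseq wins
  expect_identical(chosen$source_id[chosen$species == "sp2"], "a2")
})

test_that("ortholog selection agrees with brute-force enumeration of the rule", {
  withr::with_seed(31, {
    for (trial in 1:5) {
      pool <- c("MKTAYIAKQR", "MKTAYIAK", "MKTAY", "MKTAYIAKQ", "KTAYIAKQR")
      cand <- tibble::tibble(
        species = rep(c("s1", "s2", "s3"), each = 3),
        source_id = paste0("id", sample(9)),
        sequence = sample(pool, 9, replace = TRUE),
        is_refseq = sample(c(TRUE, FALSE), 9, replace = TRUE))
      sel <- select_orthologs(cand, "MKTAYIAKQR")
      for (sp in unique(cand$species)) {
        rows <- sel[sel$species == sp, ]
        # brute force: scan all candidates keeping the best under the rule
        best <- 1L
        for (k in seq_len(nrow(rows))) {
          better <- rows$coverage[k] > rows$coverage[best] ||
            (rows$coverage[k] == rows$coverage[best] &&
               rows$is_refseq[k] > rows$is_refseq[best]) ||
            (rows$coverage[k] == rows$coverage[best] &&
               rows$is_refseq[k] == rows$is_refseq[best] &&
               rows$source_id[k] < rows$source_id[best])
          if (better) best <- k
        }
        expect_equal(which(rows$chosen), best)
      }
    }
  })
})

test_that("column-to-residue map handles gaps per definition", {
  aln <- phenotype_alignment(c("r1", "n1"), c("responder", "nonresponder"),
                             c("A-CD", "AACD"), reference = "r1")
  expect_identical(column_to_residue_map(aln)$ref_residue,
                   c(1L, NA_integer_, 2L, 3L))
  aln2 <- phenotype_alignment(c("r1", "n1"), c("responder", "nonresponder"),
                              c("ACDE", "ACDF"))
  expect_identical(column_to_residue_map(aln2)$ref_residue, 1:4)
  # random gapped references agree with a per-column brute-force count
  withr::with_seed(7, {
    for (i in 1:20) {
      chars <- sample(c("A", "C", "-", "K"), 30, replace = TRUE)
      aln3 <- phenotype_alignment(
        c("r1", "n1"), c("responder", "nonresponder"),
        c(paste(chars, collapse = ""), paste(rep("A", 30), collapse = "")),
        reference = "r1")
      got <- column_to_residue_map(aln3)$ref_residue
      for (j in seq_along(chars)) {
        expected <- if (chars[j] == "-") NA_integer_
                    else sum(chars[1:j] != "-")
        expect_identical(got[j], as.integer(expected))
      }
    }
  })
})

make_aln <- function(seqs_resp, seqs_nonresp) {
  phenotype_alignment(
    c(sprintf("r%d", seq_along(seqs_resp)),
      sprintf("n%d", seq_along(seqs_nonresp))),
    rep(c("responder", "nonresponder"),
        c(length(seqs_resp), length(seqs_nonresp))),
    c(seqs_resp, seqs_nonresp))
}

test_that("separating patterns match the canonical responder/non-responder cases", {
  # column 1: K/K/K vs H/H/R/Q (conserved in responders)
  # column 2: K/K/Y vs R/R/R/R (conserved in non-responders)
  # column 3: Y in six species, H in one non-responder (shared -> NOT separating)
  # column 4: all identical
  aln <- make_aln(c("KKYA", "KKYA", "KYYA"), c("HRYA", "HRYA", "RRYA", "QRHA"))
  pos <- find_separating_positions(aln)
  expect_identical(pos$column, c(1L, 2L))
  expect_identical(pos$pattern, c("conserved-in-responders",
                                  "conserved-in-nonresponders"))
  expect_identical(pos$responder_set, c("K", "K,Y"))
  expect_false(3L %in% pos$column)
  expect_false(4L %in% pos$column)
})

test_that("single-phenotype alignments are rejected", {
  aln <- tibble::tibble(species = c("a", "b"),
                        phenotype = c("responder", "responder"),
                        seq = c("AK", "AR"))
  expect_error(find_separating_positions(aln), class = "specmap_input_error")
})

test_that("gap policy excludes gapped columns by default and can treat '-' as identity", {
  aln <- make_aln(c("K-A"), c("R-A", "RKA"))
  pos <- find_separating_positions(aln)
  expect_identical(pos$column, 1L)
  expect_identical(attr(pos, "excluded_columns"), 2L)
  pos2 <- find_separating_positions(aln, gap_policy = "identity")
  # column 2: responder {-} vs non-responders {-, K} share the gap identity
  expect_identical(pos2$column, 1L)
})

test_that("ambiguity codes never create a separation", {
  aln <- make_aln(c("XA"), c("KA", "RA"))
  pos <- find_separating_positions(aln)
  expect_equal(nrow(pos), 0)
  aln2 <- make_aln(c("KA", "XA"), c("RA", "RA"))
  pos2 <- find_separating_positions(aln2)
  expect_identical(pos2$column, 1L)
  expect_true(pos2$ambiguous[1])
})

test_that("separating columns equal the brute-force set test on random alignments", {
  withr::with_seed(99, {
    for (i in 1:300) {
      n_resp <- sample(2:5, 1); n_non <- sample(2:5, 1)
      len <- sample(5:50, 1)
      alphabet <- c("A", "K", "R", "H", "-", "X")
      m <- matrix(sample(alphabet, (n_resp + n_non) * len, replace = TRUE),
                  n_resp + n_non, len)
      aln <- phenotype_alignment(
        sprintf("s%d", seq_len(n_resp + n_non)),
        rep(c("responder", "nonresponder"), c(n_resp, n_non)),
        apply(m, 1, paste, collapse = ""))
      for (policy in c("exclude", "identity")) {
        got <- find_separating_positions(aln, gap_policy = policy)$column
        want <- bf_separating_columns(m, rep(c(TRUE, FALSE), c(n_resp, n_non)),
                                      gap_policy = policy)
        expect_identical(got, as.integer(want))
      }
    }
  })
})

test_that("results are invariant to row order and equivariant to label swap", {
  aln <- gen_labeled_alignment(seed = 17)
  pos <- find_separating_positions(aln)
  perm <- withr::with_seed(1, sample(nrow(aln)))
  shuffled <- phenotype_alignment(aln$species[perm], aln$phenotype[perm],
                                  aln$seq[perm],
                                  reference = attr(aln, "reference"))
  pos_perm <- find_separating_positions(shuffled)
  expect_identical(pos$column, pos_perm$column)
  expect_identical(pos$pattern, pos_perm$pattern)
  flipped <- phenotype_alignment(
    aln$species,
    ifelse(aln$phenotype == "responder", "nonresponder", "responder"),
    aln$seq, reference = attr(aln, "reference"))
  pos_flip <- find_separating_positions(flipped)
  expect_identical(pos_flip$column, pos$column)
  swap <- c("conserved-in-responders" = "conserved-in-nonresponders",
            "conserved-in-nonresponders" = "conserved-in-responders",
            "both-variable" = "both-variable",
            "both-conserved" = "both-conserved")
  expect_identical(pos_flip$pattern, unname(swap[pos$pattern]))
})

test_that("conservation profile lists exception species", {
  aln <- gen_labeled_alignment(seed = 23)
  prof <- conservation_profile(aln, 131)
  expect_identical(prof$majority, "Y")
  expect_identical(prof$exceptions$species, "nonresponder_4")
  uniform <- make_aln(c("AA"), c("AA", "AA"))
  expect_equal(nrow(conservation_profile(uniform, 1)$exceptions), 0)
  expect_error(conservation_profile(aln, 9999), class = "specmap_input_error")
  # counts equal a brute-force tally on a random column
  m <- do.call(rbind, strsplit(aln$seq, ""))
  prof2 <- conservation_profile(aln, 57)
  for (k in seq_len(nrow(prof2$counts))) {
    row <- prof2$counts[k, ]
    expect_equal(row$n, sum(m[aln$phenotype == row$phenotype, 57] == row$identity))
  }
})

test_that("alignment files round-trip through the module's readers", {
  d <- withr::local_tempdir()
  aln <- gen_labeled_alignment(seed = 3)
  write_alignment(aln, file.path(d, "a.fa"), file.path(d, "l.tsv"))
  back <- read_alignment(file.path(d, "a.fa"), file.path(d, "l.tsv"))
  expect_identical(back$species, aln$species)
  expect_identical(back$seq, aln$seq)
  expect_identical(back$phenotype, aln$phenotype)
  expect_identical(find_separating_positions(back)$column,
                   find_separating_positions(aln)$column)
})
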