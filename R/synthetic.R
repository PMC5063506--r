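#' Planted truth for a synthetic phenotype alignment
#'
#' Describes the columns a synthetic ortholog alignment must reproduce
#' exactly: separating columns (disjoint responder/non-responder identity
#' sets with a stated pattern) and conserved columns (one identity across
#' all species, with an optional single-species exception). The default
#' mirrors the canonical triplet observed in MD2-like accessory proteins: a
#' column conserved in responders (Lys) and variable in non-responders, an
#' adjacent near-universally conserved Tyr with a single non-responder
#' exception, and a column conserved in non-responders (Arg) and variable in
#' responders.
#'
#' @param separating Tibble with columns `column`, `pattern`, and optional
#'   list-columns `responder_ids`, `nonresponder_ids` giving explicit
#'   per-species identities.
#' @param conserved Tibble with columns `column`, `identity`, and optional
#'   `exception_species`, `exception_identity`.
#' @return List of class `alignment_truth`.
#' @export
alignment_truth <- function(
    separating = tibble(
      column = c(130L, 132L),
      pattern = c("conserved-in-responders", "conserved-in-nonresponders"),
      responder_ids = list(c("K", "K", "K"), c("K", "K", "Y")),
      nonresponder_ids = list(c("H", "H", "R", "Q"), c("R", "R", "R", "R"))),
    conserved = tibble(
      column = 131L, identity = "Y",
      exception_species = "nonresponder_4", exception_identity = "H")) {
  separating <- as_tibble(separating)
  conserved <- as_tibble(conserved)
  if (nrow(separating) > 0) {
    if (!all(c("column", "pattern") %in% names(separating))) {
      stop_input("separating truth needs 'column' and 'pattern'")
    }
    ok <- separating$pattern %in% c("conserved-in-responders",
                                    "conserved-in-nonresponders",
                                    "both-variable")
    if (!all(ok)) stop_input("unknown pattern label in separating truth")
  }
  if (nrow(conserved) > 0 && !all(c("column", "identity") %in% names(conserved))) {
    stop_input("conserved truth needs 'column' and 'identity'")
  }
  overlap <- intersect(separating$column, conserved$column)
  if (length(overlap) > 0) {
    stop_input("separating and conserved truth columns must be disjoint: ",
               paste(overlap, collapse = ", "))
  }
  structure(list(separating = separating, conserved = conserved),
            class = "alignment_truth")
}

# draw explicit identities for a planted pattern when the truth gives none
draw_pattern_ids <- function(pattern, n_resp, n_nonresp) {
  ids <- sample(AA_ALPHABET)
  switch(pattern,
    "conserved-in-responders" = list(
      resp = rep(ids[1], n_resp),
      nonresp = sample(ids[2:4], n_nonresp, replace = TRUE) |>
        force_variable(ids[2:3])),
    "conserved-in-nonresponders" = list(
      resp = sample(ids[2:4], n_resp, replace = TRUE) |> force_variable(ids[2:3]),
      nonresp = rep(ids[1], n_nonresp)),
    "both-variable" = list(
      resp = sample(ids[1:3], n_resp, replace = TRUE) |> force_variable(ids[1:2]),
      nonresp = sample(ids[4:6], n_nonresp, replace = TRUE) |>
        force_variable(ids[4:5])))
}

# ensure a sampled identity vector has >= 2 distinct values
force_variable <- function(x, two) {
  if (length(x) >= 2 && length(unique(x)) < 2) x[1:2] <- two
  x
}

#' Generate a phenotype-labelled ortholog alignment with planted truth
#'
#' Planted separating and conserved columns reproduce the truth exactly;
#' every non-planted column is drawn i.i.d. with at least one identity
#' guaranteed shared between the two phenotype groups (so that exactly the
#' planted columns separate). Deterministic for a fixed seed.
#'
#' @param n_responders,n_nonresponders Group sizes (>= 1 each).
#' @param length Alignment length in columns.
#' @param truth An [alignment_truth()].
#' @param seed Integer seed.
#' @param shared_prob Probability that a background sequence position takes
#'   the column's shared identity (default 0.7).
#' @return A [phenotype_alignment()] (species `responder_1..n`,
#'   `nonresponder_1..m`; reference `responder_1`) with the truth stored in
#'   the `truth` attribute.
#' @export
gen_labeled_alignment <- function(n_responders = 3, n_nonresponders = 4,
                                  length = 160, truth = alignment_truth(),
                                  seed, shared_prob = 0.7) {
  if (n_responders < 1 || n_nonresponders < 1) {
    stop_input("need at least one species per phenotype group")
  }
  if (length < 1) stop_input("alignment length must be >= 1")
  planted <- c(truth$separating$column, truth$conserved$column)
  if (any(planted < 1 | planted > length)) {
    stop_input("planted column index out of range 1..", length)
  }
  n <- n_responders + n_nonresponders
  species <- c(sprintf("responder_%d", seq_len(n_responders)),
               sprintf("nonresponder_%d", seq_len(n_nonresponders)))
  phen <- rep(c("responder", "nonresponder"), c(n_responders, n_nonresponders))

  m <- with_seed(seed, {
    mat <- matrix("", n, length)
    for (j in seq_len(length)) {
      shared <- sample(AA_ALPHABET, 1)
      col <- ifelse(runif(n) < shared_prob, shared,
                    sample(AA_ALPHABET, n, replace = TRUE))
      # guarantee the shared identity occurs in both groups
      col[sample(seq_len(n_responders), 1)] <- shared
      col[n_responders + sample(seq_len(n_nonresponders), 1)] <- shared
      mat[, j] <- col
    }
    for (i in seq_len(nrow(truth$separating))) {
      row <- truth$separating[i, ]
      ids <- if (!is.null(row$responder_ids) && !is.null(row$nonresponder_ids) &&
                 !is.null(row$responder_ids[[1]])) {
        list(resp = row$responder_ids[[1]], nonresp = row$nonresponder_ids[[1]])
      } else {
        draw_pattern_ids(row$pattern, n_responders, n_nonresponders)
      }
      if (length(ids$resp) != n_responders ||
          length(ids$nonresp) != n_nonresponders) {
        stop_input("explicit truth identities do not match group sizes at column ",
                   row$column)
      }
      if (length(intersect(unique(ids$resp), unique(ids$nonresp))) > 0) {
        stop_input("truth identities at column ", row$column, " are not disjoint")
      }
      mat[, row$column] <- c(ids$resp, ids$nonresp)
    }
    for (i in seq_len(nrow(truth$conserved))) {
      row <- truth$conserved[i, ]
      mat[, row$column] <- row$identity
      if (!is.null(row$exception_species) && !is.na(row$exception_species)) {
        k <- match(row$exception_species, species)
        if (is.na(k)) stop_input("exception species '", row$exception_species,
                                 "' not among generated species")
        mat[k, row$column] <- row$exception_identity
      }
    }
    mat
  })
  aln <- phenotype_alignment(species, phen, apply(m, 1, paste, collapse = ""),
                             reference = species[1])
  attr(aln, "truth") <- truth
  aln
}

#' Planted truth for a toy receptor complex
#'
#' Residue ids (on the accessory chain) planted as pocket, interface and
#' distal surface; a loop whose coordinates differ between the bound and
#' unbound copies; and the rigid transform separating the two copies.
#'
#' @param pocket,interface,surface Accessory-chain residue numbers.
#' @param loop Residue numbers of the mobile loop.
#' @param rotation_deg Euler angles (x, y, z axes, degrees) of the rigid
#'   transform applied to the unbound copy.
#' @param translation Translation (Angstrom) of the unbound copy.
#' @param loop_displacement Extra displacement vector applied to loop
#'   residues before the rigid transform (default 3 Angstrom along z,
#'   emulating a binding-induced loop shift).
#' @return List of class `structure_truth`.
#' @export
structure_truth <- function(pocket = c(5L, 7L), interface = c(12L, 14L),
                            surface = c(2L, 18L, 30L), loop = 20:25,
                            rotation_deg = c(25, -15, 40),
                            translation = c(5, -3, 8),
                            loop_displacement = c(0, 0, 3)) {
  ids <- c(pocket, interface, surface)
  if (anyDuplicated(ids)) stop_input("pocket/interface/surface ids must be disjoint")
  if (length(intersect(loop, ids)) > 0) {
    stop_input("loop residues must not be planted as pocket/interface/surface")
  }
  structure(list(
    pocket = as.integer(pocket), interface = as.integer(interface),
    surface = as.integer(surface), loop = as.integer(loop),
    rotation = rotation_xyz(rotation_deg[1] * pi / 180,
                            rotation_deg[2] * pi / 180,
                            rotation_deg[3] * pi / 180),
    translation = translation,
    loop_displacement = loop_displacement),
    class = "structure_truth")
}

#' Generate a bound/unbound toy receptor complex pair
#'
#' Builds minimal single-atom-per-residue chains with enough geometry to
#' exercise every distance rule: an accessory chain (role `accessory-C`)
#' carrying the planted pocket/interface/surface residues and the mobile
#' loop, a multi-atom ligand placed within the pocket cutoff of the planted
#' pocket residues, a partner chain (role `partner-B`) within the interface
#' cutoff of the planted interface residues, and a distant receptor chain
#' (role `receptor-A`). The unbound copy lacks the partner chain and the
#' ligand, is rigidly rotated/translated by the truth transform, and has the
#' loop displaced by the truth vector. Planted margins are at least 1
#' Angstrom on either side of the 3.4/4.0 cutoffs by construction.
#'
#' @param n_residues Accessory-chain length (>= 10).
#' @param truth A [structure_truth()].
#' @param seed Integer seed (controls small coordinate jitter).
#' @return List of class `toy_complex`: `bound`, `unbound`
#'   (both `structure_model`), `truth`.
#' @export
gen_toy_complex <- function(n_residues = 40, truth = structure_truth(), seed) {
  if (n_residues < 10) stop_input("n_residues must be >= 10")
  max_id <- max(c(truth$pocket, truth$interface, truth$surface, truth$loop))
  if (max_id > n_residues) {
    stop_input("planted residue id ", max_id, " exceeds n_residues = ", n_residues)
  }
  base <- with_seed(seed, {
    jitter <- matrix(round(runif(3 * n_residues, -0.1, 0.1), 3), ncol = 3)
    cbind(5 * seq_len(n_residues), 0, 0) + jitter
  })
  acc <- tibble(chain = "C", resnum = seq_len(n_residues), resname = "GLY",
                atom = "CA", element = "C",
                x = base[, 1], y = base[, 2], z = base[, 3])
  lig_xyz <- rbind(
    base[truth$pocket, , drop = FALSE] + matrix(rep(c(0, -2.5, 0),
                                                    each = length(truth$pocket)), ncol = 3),
    base[truth$pocket[1], ] + c(0.8, -2.8, 0),
    base[truth$pocket[1], ] + c(-0.8, -2.8, 0.5))
  lig <- tibble(chain = "L", resnum = 201L, resname = "LIG",
                atom = sprintf("C%d", seq_len(nrow(lig_xyz))), element = "C",
                x = round(lig_xyz[, 1], 3), y = round(lig_xyz[, 2], 3),
                z = round(lig_xyz[, 3], 3))
  par_xyz <- base[truth$interface, , drop = FALSE] +
    matrix(rep(c(0, 3.0, 0), each = length(truth$interface)), ncol = 3)
  partner <- tibble(chain = "B", resnum = seq_along(truth$interface),
                    resname = "GLY", atom = "CA", element = "C",
                    x = round(par_xyz[, 1], 3), y = round(par_xyz[, 2], 3),
                    z = round(par_xyz[, 3], 3))
  receptor <- tibble(chain = "A", resnum = 1:5, resname = "GLY", atom = "CA",
                     element = "C", x = 5 * (1:5), y = 20, z = 0)
  bound <- structure_model(
    dplyr::bind_rows(receptor, acc, partner, lig),
    roles = c(A = "receptor-A", C = "accessory-C", B = "partner-B"),
    ligand = "L:201")

  # planted-margin invariants, checked at generation time
  ligm <- coords_of(ligand_atoms(bound))
  for (r in truth$pocket) {
    stopifnot(min_pair_dist(base[r, , drop = FALSE], ligm) < 3.4)
  }
  for (r in c(truth$interface, truth$surface)) {
    stopifnot(min_pair_dist(base[r, , drop = FALSE], ligm) > 4.4)
  }
  parm <- coords_of(role_atoms(bound, "partner-B"))
  for (r in truth$interface) {
    stopifnot(min_pair_dist(base[r, , drop = FALSE], parm) < 4.0)
  }
  for (r in truth$surface) {
    stopifnot(min_pair_dist(base[r, , drop = FALSE], parm) > 5.0)
  }

  unb_atoms <- dplyr::bind_rows(receptor, acc)
  xyz <- coords_of(unb_atoms)
  loop_rows <- unb_atoms$chain == "C" & unb_atoms$resnum %in% truth$loop
  xyz[loop_rows, ] <- sweep(xyz[loop_rows, , drop = FALSE], 2,
                            truth$loop_displacement, "+")
  xyz <- apply_transform(xyz, truth$rotation, truth$translation)
  unbound <- structure_model(
    dplyr::mutate(unb_atoms, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
    roles = c(A = "receptor-A", C = "accessory-C"))

  structure(list(bound = bound, unbound = unbound, truth = truth),
            class = "toy_complex")
}

#' Generate a synthetic docking pose set with planted binding modes
#'
#' Poses are copies of a rigid multi-atom template ligand translated to a
#' mode center plus an isotropic Gaussian displacement whose norm is clamped
#' at `spread` (so `spread` is the maximum displacement from the center and
#' within-mode pose RMSDs never exceed `2 * spread`). Scores are Gaussian
#' around the per-mode means. Mode labels are retained as ground truth.
#'
#' @param n_poses_per_mode Poses per mode per run.
#' @param mode_centers Matrix with one row per mode (Angstrom). Centers must
#'   be separated by more than 4 x `spread`.
#' @param spread Maximum displacement from the mode center (Angstrom).
#' @param score_means Per-mode score means (kcal/mol, more negative =
#'   better).
#' @param score_sd Score noise standard deviation (default 0.05 kcal/mol).
#' @param n_runs Number of independent runs (distinct `run` ids).
#' @param seed Integer seed.
#' @return A [pose_set()] with a `truth_mode` column.
#' @export
gen_pose_set <- function(n_poses_per_mode = 24,
                         mode_centers = rbind(c(0, 0, 0), c(20, 0, 0)),
                         spread = 0.5, score_means = c(-7.0, -6.8),
                         score_sd = 0.05, n_runs = 1, seed) {
  if (!is.matrix(mode_centers)) mode_centers <- matrix(mode_centers, ncol = 3)
  n_modes <- nrow(mode_centers)
  if (length(score_means) != n_modes) {
    stop_input("need one score mean per mode")
  }
  if (!is.numeric(spread) || spread <= 0) stop_input("spread must be positive")
  if (n_modes > 1) {
    d <- as.matrix(stats::dist(mode_centers))
    if (min(d[upper.tri(d)]) <= 4 * spread) {
      stop_input("mode centers must be separated by more than 4 x spread")
    }
  }
  template <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(-1.4, 0, 0),
                    c(0, 1.4, 0), c(0, 0, 1.4))
  # centred so the pose centroid is exactly the mode center plus displacement
  template <- sweep(template, 2, colMeans(template))
  with_seed(seed, {
    coords <- list(); score <- numeric(0); run <- character(0)
    mode_lab <- integer(0)
    for (r in seq_len(n_runs)) {
      for (k in seq_len(n_modes)) {
        for (p in seq_len(n_poses_per_mode)) {
          disp <- rnorm(3, 0, spread / sqrt(3))
          nrm <- sqrt(sum(disp^2))
          if (nrm > spread) disp <- disp * spread / nrm
          coords[[length(coords) + 1]] <-
            sweep(template, 2, mode_centers[k, ] + disp, "+")
          score <- c(score, rnorm(1, score_means[k], score_sd))
          run <- c(run, sprintf("run%d", r))
          mode_lab <- c(mode_lab, k)
        }
      }
    }
    pose_set(coords, round(score, 3), run = run, truth_mode = mode_lab)
  })
}

#' Planted truth for synthetic assay data
#'
#' @param ec50 True EC50 in molar (> 0).
#' @param hill Hill slope.
#' @param floor,ceiling Response floor and ceiling (`ceiling > floor`).
#' @param noise_sd Gaussian response noise standard deviation.
#' @return List of class `assay_truth`.
#' @export
assay_truth <- function(ec50 = 1e-6, hill = 1, floor = 0, ceiling = 1,
                        noise_sd = 0.01) {
  if (ec50 <= 0) stop_input("ec50 must be positive")
  if (ceiling <= floor) stop_input("ceiling must exceed floor")
  if (noise_sd < 0) stop_input("noise_sd must be non-negative")
  structure(list(ec50 = ec50, hill = hill, floor = floor, ceiling = ceiling,
                 noise_sd = noise_sd),
            class = "assay_truth")
}

#' Generate a synthetic dose-response curve
#'
#' Responses follow the four-parameter logistic in log10 concentration given
#' by the truth, plus Gaussian noise of the stated standard deviation.
#'
#' @param truth An [assay_truth()].
#' @param concentrations Molar concentrations (>= 4 distinct, spanning the
#'   EC50).
#' @param n_replicates Replicates per concentration.
#' @param seed Integer seed.
#' @return Tibble `concentration`, `replicate`, `response` with the truth in
#'   the `truth` attribute.
#' @export
gen_dose_response <- function(truth = assay_truth(), concentrations,
                              n_replicates = 3, seed) {
  if (any(concentrations <= 0)) stop_input("concentrations must be positive (molar)")
  if (length(unique(concentrations)) < 4) {
    stop_input("need at least 4 distinct concentrations")
  }
  if (min(concentrations) > truth$ec50 || max(concentrations) < truth$ec50) {
    stop_input("concentration range must span the true EC50")
  }
  x <- log10(sort(concentrations))
  mu <- fourpl(x, truth$floor, truth$ceiling - truth$floor,
               log10(truth$ec50), truth$hill)
  out <- with_seed(seed, {
    tidyr::expand_grid(replicate = seq_len(n_replicates),
                       concentration = sort(concentrations)) |>
      dplyr::mutate(response = rep(mu, times = n_replicates) +
                      rnorm(dplyr::n(), 0, truth$noise_sd)) |>
      dplyr::select("concentration", "replicate", "response")
  })
  attr(out, "truth") <- truth
  out
}

#' Generate synthetic reference/comparison cytokine replicates
#'
#' Two labelled replicate vectors with lognormal noise at the stated
#' coefficient of variation (strictly positive values, matching multiplex
#' cytokine data); the true percent difference is recorded.
#'
#' @param mean_ref,mean_cmp True group means (> 0).
#' @param cv Coefficient of variation of the lognormal noise.
#' @param n_per_group Replicates per group (>= 2).
#' @param seed Integer seed.
#' @return Tibble `group` (`reference`/`comparison`), `value`; attribute
#'   `true_pct_diff`.
#' @export
gen_group_assay <- function(mean_ref, mean_cmp, cv = 0.2, n_per_group = 3,
                            seed) {
  if (mean_ref <= 0 || mean_cmp <= 0) stop_input("group means must be positive")
  if (n_per_group < 2) stop_input("need at least 2 replicates per group")
  sdlog <- sqrt(log(1 + cv^2))
  draw <- function(m, n) rlnorm(n, log(m) - sdlog^2 / 2, sdlog)
  out <- with_seed(seed, {
    tibble(group = rep(c("reference", "comparison"), each = n_per_group),
           value = c(draw(mean_ref, n_per_group), draw(mean_cmp, n_per_group)))
  })
  attr(out, "true_pct_diff") <- 100 * (mean_cmp - mean_ref) / mean_ref
  out
}
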