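#' Construct a pose set
#'
#' Scored ligand poses sharing one atom ordering: a tibble with one row per
#' pose and the coordinates as a list-column of n_atom x 3 matrices.
#'
#' @param coords List of n_atom x 3 coordinate matrices, identical
#'   dimensions.
#' @param score Numeric scores in kcal/mol (more negative = better).
#' @param atoms Tibble describing the shared atoms (`atom`, `resname`,
#'   `resnum`, `chain`, `element`); a minimal default is built if omitted.
#' @param run Run identifier per pose (recycled).
#' @param truth_mode Optional planted mode labels (synthetic data).
#' @return Tibble of class `pose_set` with columns `pose`, `run`, `score`,
#'   `coords` (+ `truth_mode` when given) and an `atoms` attribute.
#' @export
pose_set <- function(coords, score, atoms = NULL, run = "run1",
                     truth_mode = NULL) {
  if (!is.list(coords) || length(coords) == 0) stop_input("coords must be a non-empty list")
  n_atom <- nrow(coords[[1]])
  ok <- vapply(coords, function(m) is.matrix(m) && ncol(m) == 3 && nrow(m) == n_atom,
               logical(1))
  if (!all(ok)) stop_input("all poses must be n_atom x 3 matrices with equal atom counts")
  if (length(score) != length(coords)) stop_input("one score per pose required")
  if (any(!is.finite(score) & !is.na(score))) stop_input("scores must be finite")
  if (is.null(atoms)) {
    atoms <- tibble(atom = sprintf("C%d", seq_len(n_atom)),
                    resname = "LIG", resnum = 1L, chain = "L",
                    element = "C")
  }
  if (nrow(atoms) != n_atom) stop_input("atoms table must match pose atom count")
  out <- tibble(pose = seq_along(coords),
                run = rep_len(run, length(coords)),
                score = as.numeric(score), coords = coords)
  if (!is.null(truth_mode)) out$truth_mode <- rep_len(truth_mode, nrow(out))
  attr(out, "atoms") <- as_tibble(atoms)
  class(out) <- c("pose_set", class(out))
  out
}

pose_atoms <- function(poses) attr(poses, "atoms")

parse_pdb_atom_lines <- function(lines, model_label) {
  xyz <- matrix(NA_real_, length(lines), 3)
  for (k in seq_along(lines)) {
    coords <- suppressWarnings(as.numeric(c(substr(lines[k], 31, 38),
                                            substr(lines[k], 39, 46),
                                            substr(lines[k], 47, 54))))
    if (any(is.na(coords))) {
      stop_input("malformed coordinates in ", model_label, ": '", lines[k], "'")
    }
    xyz[k, ] <- coords
  }
  xyz
}

#' Read scored docking poses
#'
#' Accepts multi-model PDB with a `REMARK SCORE <value>` per model, or
#' Vina/Smina PDBQT output with `REMARK VINA RESULT:` /
#' `REMARK minimizedAffinity` lines. Atom count and ordering must be
#' identical across models.
#'
#' @param path Pose file.
#' @param missing_score `"error"` (default) or `"na"`: what to do when a
#'   model carries no score remark.
#' @return A [pose_set()], poses in file order.
#' @export
read_poses <- function(path, missing_score = c("error", "na")) {
  missing_score <- match.arg(missing_score)
  if (!file.exists(path)) stop_input("pose file not found: ", path)
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) {
    # single unnumbered model
    starts <- 1L
    ends <- length(lines)
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) < length(starts)) {
      stop_input("truncated pose file: model ", length(starts),
                 " has no ENDMDL record")
    }
  }
  coords <- vector("list", length(starts))
  scores <- rep(NA_real_, length(starts))
  atoms <- NULL
  for (i in seq_along(starts)) {
    block <- lines[starts[i]:ends[i]]
    at <- block[grepl("^(ATOM|HETATM)", block)]
    if (length(at) == 0) stop_input("model ", i, " contains no atoms")
    sc_line <- grep("^REMARK (VINA RESULT:|SCORE|minimizedAffinity)", block, value = TRUE)
    if (length(sc_line) > 0) {
      nums <- regmatches(sc_line[1], gregexpr("-?[0-9]+\\.?[0-9]*", sc_line[1]))[[1]]
      scores[i] <- as.numeric(nums[1])
    } else if (missing_score == "error") {
      stop_input("model ", i, " has no score remark")
    }
    this_atoms <- tibble(
      atom = trimws(substr(at, 13, 16)),
      resname = trimws(substr(at, 18, 20)),
      chain = trimws(substr(at, 22, 22)),
      resnum = suppressWarnings(as.integer(substr(at, 23, 26))),
      element = trimws(substr(at, 77, 78)))
    this_atoms$element[!nzchar(this_atoms$element)] <-
      substr(this_atoms$atom[!nzchar(this_atoms$element)], 1, 1)
    if (is.null(atoms)) {
      atoms <- this_atoms
    } else if (nrow(this_atoms) != nrow(atoms)) {
      stop_input("model ", i, " has ", nrow(this_atoms),
                 " atoms; expected ", nrow(atoms))
    } else if (!identical(this_atoms$atom, atoms$atom)) {
      stop_input("model ", i, " atom names differ from model 1")
    }
    coords[[i]] <- parse_pdb_atom_lines(at, paste0("model ", i))
  }
  pose_set(coords, scores, atoms = atoms)
}

#' Write a pose set as multi-model PDB with score remarks
#'
#' @param poses A [pose_set()].
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_poses <- function(poses, path) {
  atoms <- pose_atoms(poses)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(poses))) {
    writeLines(sprintf("MODEL %8d", i), con)
    if (!is.na(poses$score[i])) {
      writeLines(sprintf("REMARK SCORE %.3f", poses$score[i]), con)
    }
    m <- poses$coords[[i]]
    writeLines(sprintf(
      "HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(m)), atoms$atom, atoms$resname, atoms$chain, atoms$resnum,
      m[, 1], m[, 2], m[, 3], atoms$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' RMSD between two poses of the same ligand
#'
#' Plain coordinate RMSD without refitting (poses share the receptor frame)
#' and without symmetry correction.
#'
#' @param a,b n x 3 coordinate matrices with identical atom ordering.
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(a, b) {
  a <- coords_of(a); b <- coords_of(b)
  if (!all(dim(a) == dim(b))) stop_input("poses have mismatched atoms")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Cluster poses into binding modes
#'
#' Greedy best-score-first clustering: the best-scored unassigned pose seeds
#' a new mode and absorbs every unassigned pose within the RMSD threshold of
#' the seed; repeats until all poses are assigned. Score ties are broken by
#' input order. Modes are ordered by best score (most negative first).
#'
#' @param poses A [pose_set()].
#' @param rmsd_threshold Cluster radius in Angstrom (default 2.0).
#' @return Tibble of class `binding_modes`: `mode`, `n_members`,
#'   `best_score`, `representative` (pose id of the seed), `members`
#'   (list-column of pose ids), `centroid` (list-column, mean ligand
#'   centroid); per-pose assignment in the `assignment` attribute.
#' @export
cluster_poses <- function(poses, rmsd_threshold = 2.0) {
  if (!inherits(poses, "pose_set")) stop_input("poses must be a pose_set")
  if (nrow(poses) == 0) stop_input("empty pose set")
  if (!is.numeric(rmsd_threshold) || rmsd_threshold <= 0) {
    stop_input("rmsd_threshold must be positive")
  }
  n <- nrow(poses)
  assignment <- rep(NA_integer_, n)
  seeds <- integer(0)
  ord <- order(poses$score, poses$pose)
  mode_id <- 0L
  for (i in ord) {
    if (!is.na(assignment[i])) next
    mode_id <- mode_id + 1L
    seeds[mode_id] <- i
    seed_xyz <- poses$coords[[i]]
    for (j in ord) {
      if (is.na(assignment[j]) &&
          pose_rmsd(seed_xyz, poses$coords[[j]]) <= rmsd_threshold) {
        assignment[j] <- mode_id
      }
    }
  }
  out <- purrr::map_dfr(seq_len(mode_id), function(k) {
    members <- poses$pose[assignment == k]
    cent <- colMeans(do.call(rbind, lapply(poses$coords[assignment == k],
                                           colMeans)))
    tibble(mode = k, n_members = length(members),
           best_score = poses$score[seeds[k]],
           representative = poses$pose[seeds[k]],
           members = list(members), centroid = list(unname(cent)))
  })
  attr(out, "assignment") <- assignment
  attr(out, "rmsd_threshold") <- rmsd_threshold
  class(out) <- c("binding_modes", class(out))
  out
}

#' Residues in contact with a ligand pose
#'
#' Residues of the receptor with any atom within the cutoff of any pose
#' atom, sorted by minimum distance.
#'
#' @param receptor A `structure_model` (ligand-role atoms are ignored).
#' @param pose n x 3 coordinate matrix (a `coords` entry of a pose set).
#' @param cutoff Contact cutoff in Angstrom (default 4.0).
#' @return Tibble `chain`, `resnum`, `resname`, `min_dist`.
#' @export
contact_residues <- function(receptor, pose, cutoff = 4.0) {
  pose <- coords_of(pose)
  if (nrow(pose) == 0) stop_input("empty pose")
  rec <- receptor[receptor$role != "ligand", , drop = FALSE]
  grp <- paste(rec$chain, rec$resnum, rec$icode, sep = "|")
  dmin <- group_min_dist(coords_of(rec), grp, pose)
  first <- !duplicated(grp)
  out <- tibble(chain = rec$chain[first], resnum = rec$resnum[first],
                resname = rec$resname[first],
                min_dist = as.numeric(dmin[grp[first]]))
  out <- out[out$min_dist <= cutoff, , drop = FALSE]
  out[order(out$min_dist), ]
}

#' Inter-mode docking score gap
#'
#' Within each run, the gap is the absolute difference between the best
#' scores of the top two binding modes; across runs the median and maximum
#' gaps are reported. Runs with fewer than two modes yield an `NA` gap with
#' a warning.
#'
#' @param x A [pose_set()] (clustered per run) or a `binding_modes` table
#'   (treated as one run).
#' @param rmsd_threshold Cluster radius when `x` is a pose set.
#' @return List of class `mode_gap_summary`: `per_run` (tibble `run`,
#'   `n_modes`, `gap`), `median_gap`, `max_gap`.
#' @export
mode_score_gap <- function(x, rmsd_threshold = 2.0) {
  per_run <- if (inherits(x, "binding_modes")) {
    tibble(run = "run1", n_modes = nrow(x),
           gap = gap_of_modes(x$best_score))
  } else if (inherits(x, "pose_set")) {
    purrr::map_dfr(split(seq_len(nrow(x)), x$run), function(idx) {
      sub <- x[idx, ]
      class(sub) <- class(x)
      attr(sub, "atoms") <- pose_atoms(x)
      modes <- cluster_poses(sub, rmsd_threshold)
      tibble(run = x$run[idx][1], n_modes = nrow(modes),
             gap = gap_of_modes(modes$best_score))
    })
  } else {
    stop_input("x must be a pose_set or binding_modes")
  }
  if (any(is.na(per_run$gap))) {
    warn("some runs produced fewer than 2 binding modes; their gap is NA")
  }
  structure(list(per_run = per_run,
                 median_gap = median(per_run$gap, na.rm = TRUE),
                 max_gap = if (all(is.na(per_run$gap))) NA_real_
                           else max(per_run$gap, na.rm = TRUE)),
            class = "mode_gap_summary")
}

gap_of_modes <- function(best_scores) {
  if (length(best_scores) < 2) return(NA_real_)
  sorted <- sort(best_scores)
  abs(sorted[1] - sorted[2])
}

#' @export
print.mode_gap_summary <- function(x, ...) {
  cat(sprintf("inter-mode score gap: median %.3f, max %.3f kcal/mol over %d run(s)\n",
              x$median_gap, x$max_gap, nrow(x$per_run)))
  invisible(x)
}

#' Overlap of predicted poses with a reference ligand
#'
#' Quantifies how much each pose occupies the binding position of a reference
#' ligand (e.g. an agonist from a solved complex brought over by
#' accessory-protein superposition): (a) the fraction of pose atoms within
#' `atom_cutoff` of any reference atom, and (b) the Jaccard index of the
#' contact-residue sets of pose and reference at `contact_cutoff` (requires
#' `receptor`).
#'
#' @param poses A [pose_set()].
#' @param reference n x 3 reference ligand coordinates.
#' @param superposition Optional [kabsch_superpose()] result bringing the
#'   reference into the pose frame.
#' @param receptor Optional `structure_model` for the contact-set metric.
#' @param atom_cutoff Atom-proximity cutoff in Angstrom (default 2.0).
#' @param contact_cutoff Contact cutoff in Angstrom (default 4.0).
#' @return Tibble `pose`, `score`, `atom_fraction`, `jaccard` (`NA` without
#'   a receptor).
#' @export
reference_overlap <- function(poses, reference, superposition = NULL,
                              receptor = NULL, atom_cutoff = 2.0,
                              contact_cutoff = 4.0) {
  ref <- coords_of(reference)
  if (nrow(ref) == 0) stop_input("empty reference ligand")
  if (!is.null(superposition)) ref <- apply_superposition(ref, superposition)
  ref_contacts <- if (!is.null(receptor)) {
    cr <- contact_residues(receptor, ref, cutoff = contact_cutoff)
    paste(cr$chain, cr$resnum)
  } else NULL
  purrr::map_dfr(seq_len(nrow(poses)), function(i) {
    m <- poses$coords[[i]]
    d2 <- outer(rowSums(m^2), rowSums(ref^2), "+") - 2 * tcrossprod(m, ref)
    near <- sqrt(pmax(apply(d2, 1, min), 0)) <= atom_cutoff
    jac <- NA_real_
    if (!is.null(ref_contacts)) {
      pc <- contact_residues(receptor, m, cutoff = contact_cutoff)
      pose_contacts <- paste(pc$chain, pc$resnum)
      uni <- union(pose_contacts, ref_contacts)
      jac <- if (length(uni) == 0) 0 else
        length(intersect(pose_contacts, ref_contacts)) / length(uni)
    }
    tibble(pose = poses$pose[i], score = poses$score[i],
           atom_fraction = mean(near), jaccard = jac)
  })
}
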