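# Independent brute-force oracles used across the suite. These deliberately
# take the dumbest correct route (double loops, enumeration, dense grids) so
# they share no code path with the package implementations they check.

# per-column set-intersection test for separating columns
bf_separating_columns <- function(mat, is_resp, gap_policy = "exclude",
                                  ambiguous = c("X", "B", "Z")) {
  out <- integer(0)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    if (gap_policy == "exclude" && any(col == "-")) next
    r <- unique(col[is_resp]); n <- unique(col[!is_resp])
    r <- setdiff(r, ambiguous); n <- setdiff(n, ambiguous)
    if (length(r) == 0 || length(n) == 0) next
    if (length(intersect(r, n)) == 0) out <- c(out, j)
  }
  out
}

# all-pairs minimum distance, plain double loop
bf_min_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((a[i, ] - b[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

# residue-level contacts of a pose against a structure tibble
bf_contact_residues <- function(model, pose, cutoff) {
  model <- model[model$role != "ligand", ]
  keys <- unique(paste(model$chain, model$resnum))
  hits <- character(0)
  for (k in keys) {
    rows <- model[paste(model$chain, model$resnum) == k, ]
    if (bf_min_dist(cbind(rows$x, rows$y, rows$z), pose) <= cutoff) {
      hits <- c(hits, k)
    }
  }
  hits
}

# flexible-shell membership, per-role cutoffs
bf_flexible_shell <- function(model, ref_list, cutoffs) {
  ref <- do.call(rbind, ref_list)
  model <- model[model$role %in% names(cutoffs), ]
  keys <- unique(paste(model$chain, model$resnum))
  hits <- character(0)
  for (k in keys) {
    rows <- model[paste(model$chain, model$resnum) == k, ]
    if (bf_min_dist(cbind(rows$x, rows$y, rows$z), ref) <=
        cutoffs[rows$role[1]]) {
      hits <- c(hits, k)
    }
  }
  hits
}

# minimal RMSD by dense rotation-grid search; the translation is optimal in
# closed form (centroid match) for any fixed rotation, so only SO(3) is
# gridded. Returns the minimum grid RMSD.
bf_grid_rmsd <- function(moving, fixed, step_deg = 10) {
  p <- sweep(moving, 2, colMeans(moving))
  q <- sweep(fixed, 2, colMeans(fixed))
  h <- crossprod(p, q)
  const <- sum(p^2) + sum(q^2)
  # full 2*pi range on every angle: redundant but guarantees SO(3) coverage
  ax <- seq(0, 2 * pi - 1e-9, by = step_deg * pi / 180)
  ay <- ax
  az <- ax
  grid <- expand.grid(ax = ax, ay = ay, az = az)
  cx <- cos(grid$ax); sx <- sin(grid$ax)
  cy <- cos(grid$ay); sy <- sin(grid$ay)
  cz <- cos(grid$az); sz <- sin(grid$az)
  # entries of Rz(az) %*% Ry(ay) %*% Rx(ax), vectorised over the grid
  r11 <- cz * cy; r12 <- cz * sy * sx - sz * cx; r13 <- cz * sy * cx + sz * sx
  r21 <- sz * cy; r22 <- sz * sy * sx + cz * cx; r23 <- sz * sy * cx - cz * sx
  r31 <- -sy;     r32 <- cy * sx;                r33 <- cy * cx
  # sum((p R^T - q)^2) = const - 2 * tr(R H); tr(R H) = sum over ij R_ij H_ji
  tr <- r11 * h[1, 1] + r12 * h[1, 2] + r13 * h[1, 3] +
        r21 * h[2, 1] + r22 * h[2, 2] + r23 * h[2, 3] +
        r31 * h[3, 1] + r32 * h[3, 2] + r33 * h[3, 3]
  sqrt(max(0, (const - 2 * max(tr)) / nrow(p)))
}

# global affine-gap alignment score by exhaustive recursion (tiny strings
# only); gap cost = opening + extension for the first gap position
bf_global_affine_score <- function(a, b, sub, gap_open = 10, gap_ext = 4) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  memo <- new.env()
  rec <- function(i, j, state) {
    if (i > length(a) && j > length(b)) return(0)
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i <= length(a) && j <= length(b)) {
      best <- max(best, sub[a[i], b[j]] + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(a)) {
      cost <- if (state == "a") gap_ext else gap_open + gap_ext
      best <- max(best, -cost + rec(i + 1, j, "a"))
    }
    if (j <= length(b)) {
      cost <- if (state == "b") gap_ext else gap_open + gap_ext
      best <- max(best, -cost + rec(i, j + 1, "b"))
    }
    memo[[key]] <- best
    best
  }
  rec(1, 1, "m")
}

# random atom tibble shaped like a structure_model, with roles
random_structure <- function(n_res = 12, atoms_per_res = 2, seed = 1) {
  withr::with_seed(seed, {
    n <- n_res * atoms_per_res
    tb <- tibble::tibble(
      chain = rep(sample(rep(c("A", "C", "B"), length.out = n_res)),
                  each = atoms_per_res),
      resnum = rep(seq_len(n_res), each = atoms_per_res),
      resname = "GLY",
      atom = rep(sprintf("A%d", seq_len(atoms_per_res)), n_res),
      x = runif(n, -15, 15), y = runif(n, -15, 15), z = runif(n, -15, 15))
    roles <- c(A = "receptor-A", C = "accessory-C", B = "partner-B")
    lig <- tibble::tibble(chain = "L", resnum = 201L, resname = "LIG",
                          atom = sprintf("C%d", 1:4),
                          x = runif(4, -6, 6), y = runif(4, -6, 6),
                          z = runif(4, -6, 6))
    structure_model(dplyr::bind_rows(tb, lig), roles = roles, ligand = "L:201")
  })
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}
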