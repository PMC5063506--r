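test_that("PDB write/read round-trips coordinates at fixed-column precision", {
  d <- withr::local_tempdir()
  cplx <- gen_toy_complex(seed = 4)
  f <- file.path(d, "bound.pdb")
  write_structure(cplx$bound, f)
  back <- read_structure(f, roles = c(A = "receptor-A", C = "accessory-C",
                                      B = "partner-B"), ligand = "L:201")
  expect_identical(back$chain, cplx$bound$chain)
  expect_identical(back$resnum, cplx$bound$resnum)
  expect_identical(back$atom, cplx$bound$atom)
  expect_equal(back$x, round(cplx$bound$x, 3), tolerance = 1e-9)
  expect_equal(back$z, round(cplx$bound$z, 3), tolerance = 1e-9)
  expect_identical(back$role, cplx$bound$role)
  # second round trip is exactly idempotent
  f2 <- file.path(d, "again.pdb")
  write_structure(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("duplicate atom keys are rejected on read and construction", {
  d <- withr::local_tempdir()
  f <- file.path(d, "dup.pdb")
  writeLines(c(
    "ATOM      1  CA  GLY C   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  GLY C   1       1.000   0.000   0.000  1.00  0.00",
    "END"), f)
  expect_error(read_structure(f), class = "specmap_input_error")
  expect_error(structure_model(tibble::tibble(
    chain = "C", resnum = c(1L, 1L), resname = "GLY", atom = "CA",
    x = 0:1, y = 0, z = 0)), class = "specmap_input_error")
})

test_that("altloc conflicts keep the highest-occupancy conformer", {
  d <- withr::local_tempdir()
  f <- file.path(d, "alt.pdb")
  writeLines(c(
    "ATOM      1  CA AGLY C   1       0.000   0.000   0.000  0.40  0.00",
    "ATOM      2  CA BGLY C   1       9.000   0.000   0.000  0.60  0.00",
    "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m), 1)
  expect_equal(m$x, 9)
})

test_that("kabsch recovers applied rigid transforms to machine precision", {
  withr::with_seed(5, {
    pts <- matrix(rnorm(30, sd = 4), 10, 3)
    sup0 <- kabsch_superpose(pts, pts)
    expect_equal(sup0$rmsd, 0, tolerance = 1e-12)
    expect_equal(sup0$rotation, diag(3), tolerance = 1e-9)
    for (i in 1:50) {
      rot <- random_rotation()
      tr <- rnorm(3, sd = 10)
      moved <- sweep(pts %*% t(rot), 2, tr, "+")
      sup <- kabsch_superpose(pts, moved)
      expect_lt(sup$rmsd, 1e-9)
      expect_equal(sup$rotation, rot, tolerance = 1e-8)
      expect_equal(sup$translation, tr, tolerance = 1e-8)
      expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
      # symmetric rmsd
      expect_equal(kabsch_superpose(moved, pts)$rmsd, sup$rmsd,
                   tolerance = 1e-9)
    }
  })
})

test_that("a 37-degree rotation about z is inverted exactly", {
  withr::with_seed(8, {
    pts <- matrix(rnorm(15), 5, 3)
    th <- 37 * pi / 180
    rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                  3, 3, byrow = TRUE)
    moved <- sweep(pts %*% t(rot), 2, c(1, -2, 3), "+")
    sup <- kabsch_superpose(moved, pts)
    expect_lt(sup$rmsd, 1e-9)
    expect_equal(sup$rotation, t(rot), tolerance = 1e-9)
  })
})

test_that("superposition never uses a reflection even when it would fit better", {
  withr::with_seed(12, {
    pts <- matrix(rnorm(15, sd = 3), 5, 3)
    mirrored <- pts %*% diag(c(-1, 1, 1))
    sup <- kabsch_superpose(pts, mirrored)
    expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
    expect_gt(sup$rmsd, 0.01)
  })
})

test_that("kabsch rmsd matches a dense rotation-grid oracle on 5-point sets", {
  withr::with_seed(14, {
    for (i in 1:3) {
      p <- matrix(rnorm(15, sd = 2), 5, 3)
      q <- matrix(rnorm(15, sd = 2), 5, 3)
      exact <- kabsch_superpose(p, q)$rmsd
      grid <- bf_grid_rmsd(p, q, step_deg = 10)
      expect_gte(grid + 1e-9, exact)
      # grid resolution bound: a 5-degree half-step moves points of radius
      # ~4 A by at most ~0.5 A
      expect_lt(grid - exact, 0.5)
    }
  })
})

test_that("kabsch rejects mismatched or tiny inputs and flags collinear sets", {
  expect_error(kabsch_superpose(matrix(0, 4, 3), matrix(0, 5, 3)),
               class = "specmap_input_error")
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               class = "specmap_input_error")
  line <- cbind(1:5, 0, 0)
  expect_warning(kabsch_superpose(line, line), "collinear")
})

test_that("residue minimum distances are exact", {
  cplx <- gen_toy_complex(seed = 6)
  b <- cplx$bound
  # 3-4-5 triangle on constructed atoms
  toy <- structure_model(tibble::tibble(
    chain = c("C", "L"), resnum = c(1L, 201L), resname = c("GLY", "LIG"),
    atom = c("CA", "C1"), x = c(0, 3), y = c(0, 4), z = c(0, 0)),
    roles = c(C = "accessory-C"), ligand = "L:201")
  expect_equal(residue_min_distance(toy, "C:1", "ligand"), 5.0)
  expect_equal(residue_min_distance(toy, "C:1", matrix(0, 1, 3)), 0)
  expect_error(residue_min_distance(b, "C:99999", "ligand"),
               class = "specmap_input_error")
  # random structures agree with the brute-force double loop
  for (seed in 1:10) {
    m <- random_structure(seed = seed)
    lig <- m[m$role == "ligand", ]
    for (r in sample(unique(m$resnum[m$role != "ligand"]), 5)) {
      ch <- m$chain[m$resnum == r & m$role != "ligand"][1]
      got <- residue_min_distance(m, sprintf("%s:%d", ch, r), "ligand")
      sub <- m[m$chain == ch & m$resnum == r, ]
      expect_equal(got, bf_min_dist(cbind(sub$x, sub$y, sub$z),
                                    cbind(lig$x, lig$y, lig$z)),
                   tolerance = 1e-9)
    }
  }
})

test_that("planted residue classes are recovered and rigidly invariant", {
  for (seed in 1:20) {
    cplx <- gen_toy_complex(seed = seed)
    ctx <- classify_residue_context(cplx$bound)
    truth <- cplx$truth
    expect_setequal(ctx$resnum[ctx$class == "pocket"], truth$pocket)
    expect_setequal(ctx$resnum[ctx$class == "interface"], truth$interface)
    expect_true(all(truth$surface %in% ctx$resnum[ctx$class == "surface-distal"]))
  }
  # joint rigid transform leaves every classification unchanged
  cplx <- gen_toy_complex(seed = 77)
  ctx <- classify_residue_context(cplx$bound)
  rot <- withr::with_seed(1, random_rotation())
  sup <- structure(list(rotation = rot, translation = c(3, -7, 2)),
                   class = "superposition")
  moved <- apply_superposition(cplx$bound, sup)
  ctx2 <- classify_residue_context(moved)
  expect_identical(ctx$class, ctx2$class)
  expect_equal(ctx$dist_ligand, ctx2$dist_ligand, tolerance = 1e-9)
})

test_that("classification requires a tagged ligand", {
  cplx <- gen_toy_complex(seed = 2)
  expect_error(classify_residue_context(cplx$unbound),
               class = "specmap_input_error")
})

test_that("conformational rmsd reflects planted jitter and handles missing atoms", {
  cplx <- gen_toy_complex(seed = 30)
  b <- cplx$bound
  expect_equal(as.numeric(conformational_rmsd(b, b, "C:1-10")), 0,
               tolerance = 1e-12)
  # 0.2 A isotropic jitter on three residues, fit on the rest of the chain
  withr::with_seed(44, {
    jit <- b
    rows <- jit$chain == "C" & jit$resnum %in% 26:35
    jit$x[rows] <- jit$x[rows] + rnorm(sum(rows), 0, 0.2 / sqrt(3))
    jit$y[rows] <- jit$y[rows] + rnorm(sum(rows), 0, 0.2 / sqrt(3))
    jit$z[rows] <- jit$z[rows] + rnorm(sum(rows), 0, 0.2 / sqrt(3))
    r <- conformational_rmsd(b, jit, "C:26-35", fit_selection = "C:1-19")
    expect_equal(as.numeric(r), 0.2, tolerance = 0.2)
  })
  # residues absent from one model: warning, intersection used
  pruned <- structure_model(b[!(b$chain == "C" & b$resnum == 10), ])
  expect_warning(r2 <- conformational_rmsd(b, pruned, "C:1-15"), "missing")
  expect_equal(as.numeric(r2), 0, tolerance = 1e-12)
  expect_error(conformational_rmsd(b, cplx$unbound, "B:1-2"),
               class = "specmap_input_error")
})

test_that("chimeric receptors graft transformed donor chains", {
  cplx <- gen_toy_complex(seed = 50)
  donor <- cplx$bound[cplx$bound$chain %in% c("A", "C"), ]
  donor <- structure_model(donor)
  acceptor <- structure_model(cplx$bound[cplx$bound$chain == "C", ])
  # pre-aligned shared selection: graft equals donor coordinates
  out <- build_chimeric_receptor(donor, acceptor, "C", "A")
  expect_setequal(unique(out$chain), c("A", "C"))
  a_out <- out[out$chain == "A", ]
  a_don <- donor[donor$chain == "A", ]
  expect_equal(a_out$x, a_don$x, tolerance = 1e-9)
  # acceptor keeps its own coordinates on the shared chain
  expect_equal(out$x[out$chain == "C"], acceptor$x, tolerance = 1e-12)
  # rotated donor: graft comes back through the fitted transform
  rot <- withr::with_seed(3, random_rotation())
  sup <- structure(list(rotation = rot, translation = c(10, 0, -5)),
                   class = "superposition")
  donor_rot <- apply_superposition(donor, sup)
  out2 <- build_chimeric_receptor(donor_rot, acceptor, "C", "A")
  expect_equal(out2$x[out2$chain == "A"], a_don$x, tolerance = 1e-9)
  expect_lt(attr(out2, "provenance")$fit_rmsd, 1e-9)
  # collision without remap errors; remap resolves it
  expect_error(build_chimeric_receptor(donor, donor, "C", "A"),
               class = "specmap_input_error")
  out3 <- build_chimeric_receptor(donor, donor, "C", "A",
                                  chain_map = c(A = "D"))
  expect_true("D" %in% out3$chain)
})

test_that("superposition by selection requires enough matched atoms", {
  cplx <- gen_toy_complex(seed = 60)
  expect_error(
    superpose_by_selection(cplx$bound, cplx$unbound, selection = "C:1"),
    class = "specmap_input_error")
})
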