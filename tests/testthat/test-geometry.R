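test_that("dihedral_angle reproduces planar cis/trans and rejects collinear input", {
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)), 0)
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)), 180)
  expect_error(
    dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
    "degenerate"
  )
})

test_that("dihedral_angle is invariant under rigid motion and obeys torsion symmetries", {
  set.seed(101)
  for (i in 1:25) {
    pts <- lapply(1:4, function(j) rnorm(3, sd = 2))
    ang <- tryCatch(do.call(dihedral_angle, pts), error = function(e) NULL)
    if (is.null(ang)) next
    # rigid rotation + translation leaves the torsion unchanged
    R <- random_rotation()
    t0 <- rnorm(3, sd = 5)
    moved <- lapply(pts, function(p) as.numeric(R %*% p + t0))
    expect_equal(do.call(dihedral_angle, moved), ang, tolerance = 1e-9)
    # reversal symmetry: same angle read from the other end
    expect_equal(dihedral_angle(pts[[4]], pts[[3]], pts[[2]], pts[[1]]), ang,
                 tolerance = 1e-9)
    # mirror reflection negates the torsion (modulo the 180 == -180 seam)
    mirrored <- lapply(pts, function(p) p * c(-1, 1, 1))
    ang_m <- do.call(dihedral_angle, mirrored)
    delta <- (ang_m + ang) %% 360
    expect_lt(min(delta, 360 - delta), 1e-9)
  }
})

test_that("classify_rotamer partitions (-180, 180] with deterministic edges", {
  sweep <- seq(-179, 180, by = 1)
  labels <- classify_rotamer(sweep)
  expect_true(all(labels %in% c("gauche-", "gauche+", "trans")))
  # exactly one label each (total function), and bin edges go to the bin
  # whose lower edge they are
  expect_identical(classify_rotamer(-120), "gauche-")
  expect_identical(classify_rotamer(0), "gauche+")
  expect_identical(classify_rotamer(120), "trans")
  expect_identical(classify_rotamer(180), "trans")
  expect_identical(classify_rotamer(-60), "gauche-")
  # matches nearest-canonical-rotamer assignment away from the edges
  interior <- sweep[!(sweep %in% c(-120, 0, 120))]
  expect_identical(classify_rotamer(interior),
                   nearest_canonical_rotamer(interior))
  # mirrored convention swaps the gauche bins
  expect_identical(classify_rotamer(-60, mirror = TRUE), "gauche+")
  expect_identical(classify_rotamer(60, mirror = TRUE), "gauche-")
  expect_identical(classify_rotamer(180, mirror = TRUE), "trans")
})

test_that("kabsch_superpose recovers planted rotations and is optimal", {
  set.seed(202)
  A <- random_cloud(50)
  expect_equal(kabsch_superpose(A, A)$rmsd, 0, tolerance = 1e-10)
  expect_equal(kabsch_superpose(A, A)$rotation, diag(3), tolerance = 1e-8)

  for (i in 1:5) {
    R0 <- random_rotation()
    t0 <- rnorm(3, sd = 10)
    B <- sweep(A %*% t(R0), 2, t0, `+`)
    s <- kabsch_superpose(A, B)
    expect_equal(s$rmsd, 0, tolerance = 1e-8)
    # recovered rotation undoes the planted one
    expect_equal(s$rotation %*% R0, diag(3), tolerance = 1e-8)
    expect_equal(det(s$rotation), 1, tolerance = 1e-8)
    expect_equal(crossprod(s$rotation), diag(3), tolerance = 1e-8)
  }

  # optimality: no random trial rotation beats the Kabsch RMSD
  B <- A %*% t(random_rotation()) + matrix(rnorm(150, sd = 0.4), ncol = 3)
  best <- kabsch_superpose(A, B)$rmsd
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  trial <- replicate(10000, {
    R <- random_rotation()
    sqrt(mean(rowSums((Bc %*% t(R) - Ac)^2)))
  })
  expect_true(all(best <= trial + 1e-12))
})

test_that("kabsch rmsd is invariant to pre-rotation and consistent permutation", {
  set.seed(303)
  A <- random_cloud(40)
  B <- A %*% t(random_rotation()) + matrix(rnorm(120, sd = 0.3), ncol = 3)
  base <- kabsch_superpose(A, B)$rmsd
  # pre-rotating the mobile cloud cannot change the optimum
  Rpre <- random_rotation()
  expect_equal(kabsch_superpose(A, B %*% t(Rpre))$rmsd, base,
               tolerance = 1e-9)
  # consistent permutation of both lists
  perm <- sample(nrow(A))
  expect_equal(kabsch_superpose(A[perm, ], B[perm, ])$rmsd, base,
               tolerance = 1e-12)
  expect_error(kabsch_superpose(A[1:2, ], B[1:2, ]), "at least 3")
  expect_error(kabsch_superpose(A, B[1:10, ]), "identical dimensions")
})

test_that("contact_search matches a brute-force scan and is symmetric", {
  mk <- function(n) tibble::tibble(
    atom_name = paste0("X", seq_len(n)),
    x = rnorm(n, sd = 4), y = rnorm(n, sd = 4), z = rnorm(n, sd = 4)
  )
  # spec examples: a 3.2 A pair inside a 3.6 A cutoff; 4.5 A outside it
  ne2 <- tibble::tibble(atom_name = "NE2", x = 0, y = 0, z = 0)
  o1 <- tibble::tibble(atom_name = "O1", x = 3.2, y = 0, z = 0)
  hit <- contact_search(ne2, o1, 3.6)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$distance, 3.2)
  o_far <- tibble::tibble(atom_name = "O1", x = 4.5, y = 0, z = 0)
  expect_equal(nrow(contact_search(ne2, o_far, 3.6)), 0)

  set.seed(404)
  a <- mk(100); b <- mk(100)
  got <- contact_search(a, b, 5)
  oracle <- brute_force_contacts(a, b, 5)
  expect_equal(nrow(got), nrow(oracle))
  expect_equal(got$distance, oracle$distance, tolerance = 1e-12)
  expect_identical(got[, c("idx_a", "idx_b")],
                   tibble::tibble(idx_a = as.integer(oracle$idx_a),
                                  idx_b = as.integer(oracle$idx_b)))
  # symmetry: swapped arguments give the transposed pair set
  rev <- contact_search(b, a, 5)
  expect_equal(
    dplyr::arrange(got[, c("idx_a", "idx_b")], idx_a, idx_b),
    dplyr::arrange(
      tibble::tibble(idx_a = rev$idx_b, idx_b = rev$idx_a), idx_a, idx_b)
  )
})
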