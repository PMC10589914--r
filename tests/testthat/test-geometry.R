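test_that("kabsch recovers exact rigid motions and rejects bad input", {
  set.seed(11)
  P <- matrix(rnorm(30), 10, 3)
  fit0 <- kabsch(P, P)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit0$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit0$transform$translation, c(0, 0, 0), tolerance = 1e-9)

  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Q <- P %*% t(R) + matrix(c(5, 0, 0), 10, 3, byrow = TRUE)
  fit <- kabsch(P, Q)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$transform$rotation, R, tolerance = 1e-6)
  expect_lt(abs(det(fit$transform$rotation) - 1), 1e-9)

  expect_error(kabsch(P[1:2, ], Q[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line), "rank-deficient")
})

test_that("kabsch matches the quaternion oracle on noisy instances", {
  set.seed(21)
  for (rep in 1:25) {
    P <- matrix(rnorm(30), 10, 3)
    Q <- P %*% t(random_rotation()) +
      matrix(rnorm(3, sd = 5), 10, 3, byrow = TRUE) +
      matrix(rnorm(30, sd = 0.1), 10, 3)
    fit <- kabsch(P, Q)
    expect_equal(fit$rmsd, horn_rmsd(P, Q), tolerance = 1e-6)
  }
  # a couple of instances against direct numerical minimization too
  for (rep in 1:3) {
    P <- matrix(rnorm(30), 10, 3)
    Q <- P %*% t(random_rotation()) + matrix(rnorm(30, sd = 0.2), 10, 3)
    expect_equal(kabsch(P, Q)$rmsd, optim_quat_rmsd(P, Q), tolerance = 1e-5)
  }
})

test_that("kabsch rmsd is symmetric and invariant to pre-rotation", {
  set.seed(31)
  P <- matrix(rnorm(24), 8, 3)
  Q <- matrix(rnorm(24), 8, 3)
  expect_equal(kabsch(P, Q)$rmsd, kabsch(Q, P)$rmsd, tolerance = 1e-9)
  R <- random_rotation()
  expect_equal(kabsch(P %*% t(R), Q %*% t(R))$rmsd, kabsch(P, Q)$rmsd,
               tolerance = 1e-9)
})

test_that("tidy/glance expose the fitted transform", {
  set.seed(5)
  P <- matrix(rnorm(30), 10, 3)
  fit <- kabsch(P, P %*% t(random_rotation()))
  td <- tidy(fit)
  expect_equal(td$term[1:3], c("r11", "r12", "r13"))
  expect_equal(nrow(td), 12)
  gl <- glance(fit)
  expect_equal(gl$n, 10)
  expect_equal(gl$det, 1, tolerance = 1e-9)
})

test_that("apply_transform is exact, invertible and distance-preserving", {
  h <- make_ideal_helix(8)
  ident <- rigid_transform()
  expect_equal(coords_of(apply_transform(h, ident)), coords_of(h))

  set.seed(41)
  tf <- random_rigid()
  back <- apply_transform(apply_transform(h, tf), invert_transform(tf))
  expect_lt(max(abs(coords_of(back) - coords_of(h))), 1e-9)

  moved <- apply_transform(h, tf)
  expect_equal(as.matrix(dist(coords_of(moved))),
               as.matrix(dist(coords_of(h))), tolerance = 1e-9)
  expect_equal(moved$atom, h$atom)  # hierarchy untouched
})

test_that("dihedral follows the standard convention", {
  # planar cis and trans
  expect_equal(dihedral(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, 1, 0)), 0)
  expect_equal(dihedral(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, -1, 0)), 180)
  # hand-derived (and biopython/biotite-confirmed) +90 case
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)), 90)
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("fit_axis is exact on lines, antisymmetric, and near the helix axis", {
  pts <- cbind(seq(0, 8, 2), 0, 0)
  ax <- fit_axis(pts)
  expect_equal(ax$direction, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(ax$n_start, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(ax$c_end, c(8, 0, 0), tolerance = 1e-12)

  rev_ax <- fit_axis(pts[5:1, ])
  expect_equal(rev_ax$direction, -ax$direction, tolerance = 1e-12)

  # helix built along a known frame: the fitted axis must agree with the
  # axis of the same helix refit after an exact rigid motion
  h <- make_ideal_helix(12)
  ca <- coords_of(h[h$atom == "CA", ])
  ax1 <- fit_axis(ca)
  set.seed(6)
  tf <- random_rigid()
  ax2 <- fit_axis(apply_transform(ca, tf))
  expect_equal(as.vector(tf$rotation %*% ax1$direction), ax2$direction,
               tolerance = 1e-9)
  # rise per residue along the fitted axis ~1.5 A for an alpha helix
  rise <- sqrt(sum((ax1$c_end - ax1$n_start)^2)) / 11
  expect_gt(rise, 1.3); expect_lt(rise, 1.7)
  expect_error(fit_axis(pts[1:2, ]), "at least 3")
})

test_that("pairwise_min_distances equals the brute-force double loop", {
  a1 <- tibble::tibble(atom = "CA", resname = "ALA", chain = "A", resno = 1L,
                       x = 0, y = 0, z = 0, element = "C")
  b1 <- tibble::tibble(atom = "CA", resname = "ALA", chain = "B", resno = 1L,
                       x = 3, y = 0, z = 0, element = "C")
  dm <- pairwise_min_distances(as_structure(a1), as_structure(b1), "ca")
  expect_equal(dm[1, 1], 3)

  d <- make_dimer(3, 4, seed = 9, n_per_chain = 6)
  A <- get_chain(d, "A"); B <- get_chain(d, "B")
  dm <- pairwise_min_distances(A, B, "heavy")
  for (i in 1:6) {
    for (j in 1:6) {
      ra <- A[A$resno == i, ]; rb <- B[B$resno == j, ]
      expect_equal(dm[i, j], brute_min_distance(ra, rb), tolerance = 1e-9)
    }
  }
})

test_that("cb mode substitutes CA for glycine and flags missing atoms", {
  a <- tibble::tibble(
    atom = c("CA", "CB", "CA"), resname = c("ALA", "ALA", "GLY"),
    chain = "A", resno = c(1L, 1L, 2L),
    x = c(0, 1, 5), y = 0, z = 0, element = "C")
  b <- tibble::tibble(atom = c("CA", "CB"), resname = "ALA", chain = "B",
                      resno = 1L, x = c(10, 9), y = 0, z = 0, element = "C")
  dm <- pairwise_min_distances(as_structure(a), as_structure(b), "cb")
  expect_equal(dm[1, 1], 8)  # CB(1) at x=1 to CB at x=9
  expect_equal(dm[2, 1], 4)  # GLY falls back to CA at x=5
  # a residue with no selected atom yields NA
  onlyn <- tibble::tibble(atom = "N", resname = "ALA", chain = "C",
                          resno = 1L, x = 0, y = 0, z = 0, element = "N")
  dmna <- pairwise_min_distances(as_structure(onlyn), as_structure(b), "cb")
  expect_true(is.na(dmna[1, 1]))
})
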