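test_that("dihedrals match independent torsion implementations atom by atom", {
  set.seed(4)
  xyz <- matrix(rnorm(60, sd = 3), 20, 3)
  for (i in 1:17) {
    expect_equal(dihedral_angle(xyz[i, ], xyz[i + 1, ], xyz[i + 2, ],
                                xyz[i + 3, ]),
                 oracle_dihedral(xyz[i, ], xyz[i + 1, ], xyz[i + 2, ],
                                 xyz[i + 3, ]),
                 tolerance = 1e-9)
  }
  # and against bio3d's torsion routine as a second, external oracle
  ref <- bio3d::torsion.xyz(as.numeric(t(xyz[1:4, ])), atm.inc = 4)
  expect_equal(dihedral_angle(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ]),
               as.numeric(ref), tolerance = 1e-6)
})

test_that("mirror images negate all backbone dihedrals", {
  h <- build_backbone(8, phi = -57, psi = -47)
  m <- h
  m$atoms$z <- -m$atoms$z
  dh <- compute_dihedrals(h)
  dm <- compute_dihedrals(m)
  expect_equal(dm$phi, -dh$phi, tolerance = 1e-9)
  expect_equal(dm$psi, -dh$psi, tolerance = 1e-9)
})

test_that("dihedral differences wrap, stay bounded and are symmetric", {
  expect_equal(wrap_angle(c(190, -190, 360, 180, -180)),
               c(-170, 170, 0, 180, 180))
  a <- tibble::tibble(chain = "A", resno = 1:3, resname = "ALA",
                      phi = c(170, 10, NA), psi = c(-170, -10, 5))
  b <- tibble::tibble(chain = "A", resno = 1:3, resname = "ALA",
                      phi = c(-170, 10, 20), psi = c(170, -10, 5))
  d <- dihedral_difference(a, b)
  expect_equal(d$dphi[1], 20)   # wraps, not 340
  expect_equal(d$dpsi[1], 20)
  expect_equal(d$dphi[2], 0)
  expect_true(is.na(d$dphi[3])) # undefined stays undefined
  d2 <- dihedral_difference(b, a)
  expect_equal(d$dphi, d2$dphi)
  # property: bounded by 180 for random angle pairs
  set.seed(1)
  x <- stats::runif(200, -720, 720)
  y <- stats::runif(200, -720, 720)
  dd <- abs(wrap_angle(x - y))
  expect_true(all(dd >= 0 & dd <= 180))
  # key mismatch rejected with offenders listed
  expect_error(dihedral_difference(a, b[1:2, ]), "resno|keys differ")
})

test_that("superposition recovers known transforms and is self-inverse", {
  set.seed(7)
  p <- matrix(rnorm(45, sd = 5), 15, 3)
  sa <- ca_structure(p)
  # identity on self
  self <- superpose(sa, sa)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  expect_equal(self$transform$rotation, diag(3), tolerance = 1e-9)
  for (k in 1:5) {
    axis <- stats::rnorm(3)
    ang <- stats::runif(1, 5, 175)
    tr <- screw_transform(axis, ang, pitch = stats::rnorm(1),
                          point = stats::rnorm(3))
    sb <- ca_structure(apply_transform(tr, p))
    fit <- superpose(sa, sb)
    expect_lt(max(abs(fit$transform$rotation - tr$rotation)), 1e-9)
    expect_lt(max(abs(fit$transform$translation - tr$translation)), 1e-9)
    expect_lt(fit$rmsd, 1e-9)
    # forward and reverse fits are mutually inverse with equal rmsd
    rev <- superpose(sb, sa)
    expect_lt(max(abs(rev$transform$rotation %*% fit$transform$rotation -
                        diag(3))), 1e-9)
    expect_equal(rev$rmsd, fit$rmsd, tolerance = 1e-9)
  }
  expect_error(superpose(ca_structure(p[1:2, ]), ca_structure(p[1:2, ])),
               "3 paired")
})

test_that("rmsd is invariant to a common rigid transform", {
  set.seed(8)
  p <- matrix(rnorm(30), 10, 3)
  q <- p + matrix(rnorm(30, sd = 0.3), 10, 3)
  base <- superpose(ca_structure(p), ca_structure(q))$rmsd
  tr <- screw_transform(c(1, 1, 0), 73, pitch = 4, point = c(2, 0, 0))
  moved <- superpose(ca_structure(apply_transform(tr, p)),
                     ca_structure(apply_transform(tr, q)))$rmsd
  expect_equal(moved, base, tolerance = 1e-9)
})

test_that("kabsch never returns a reflection", {
  set.seed(9)
  p <- matrix(rnorm(24), 8, 3)
  q <- p
  q[, 3] <- -q[, 3]  # mirrored target tempts a det = -1 solution
  fit <- superpose(ca_structure(p), ca_structure(q))
  expect_equal(det(fit$transform$rotation), 1, tolerance = 1e-9)
})

test_that("screw decomposition inverts screw composition", {
  # canonical example: 90 degrees about z, no translation
  s <- screw_decompose(screw_transform(c(0, 0, 1), 90))
  expect_equal(s$angle, 90, tolerance = 1e-9)
  expect_equal(s$axis, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(s$pitch, 0, tolerance = 1e-12)
  # identity flagged as pure translation
  s0 <- screw_decompose(rigid_transform(diag(3), c(1, 2, 2)))
  expect_true(s0$pure_translation)
  expect_equal(s0$pitch, 3)
  # property: parameters survive compose -> decompose for random screws
  set.seed(11)
  for (k in 1:20) {
    axis <- unit <- stats::rnorm(3)
    unit <- unit / sqrt(sum(unit^2))
    ang <- stats::runif(1, 1, 179)
    pitch <- stats::rnorm(1, sd = 3)
    pt <- stats::rnorm(3, sd = 5)
    s <- screw_decompose(screw_transform(unit, ang, pitch, pt))
    flip <- sign(sum(s$axis * unit))
    expect_equal(s$angle, ang, tolerance = 1e-6)
    expect_lt(max(abs(flip * s$axis - unit)), 1e-6)
    expect_equal(flip * s$pitch, pitch, tolerance = 1e-6)
    # returned axis point must lie on the axis: it maps to itself + pitch
    tr <- screw_transform(unit, ang, pitch, pt)
    img <- as.numeric(apply_transform(tr, rbind(s$axis_point)))
    expect_lt(max(abs(img - (s$axis_point + s$pitch * s$axis))), 1e-6)
  }
})

test_that("helix axes give correct inter-helix angles", {
  h <- build_backbone(12)
  ax1 <- helix_axis(h)
  # parallel copy: angle 0
  h2 <- h
  h2$atoms$x <- h2$atoms$x + 30
  expect_lt(inter_helix_angle(ax1, helix_axis(h2))$angle, 1e-9)
  # rotate a copy by exactly 90 degrees about an axis orthogonal to the
  # helix direction: fitted angle within fit tolerance of 90
  perp <- c(-ax1$direction[2], ax1$direction[1], 0)
  h3 <- apply_transform(screw_transform(perp, 90), h)
  ang <- inter_helix_angle(ax1, helix_axis(h3))
  expect_equal(ang$angle, 90, tolerance = 0.2)
  # antiparallel copy: unsigned angle 0, signed angle 180
  h4 <- apply_transform(screw_transform(perp, 180), h)
  ang4 <- inter_helix_angle(ax1, helix_axis(h4))
  expect_lt(ang4$angle, 0.2)
  expect_gt(ang4$signed_angle, 179.8)
  expect_error(helix_axis(ca_structure(matrix(rnorm(9), 3, 3))), ">= 5")
})

test_that("site displacement reports exact constructed translations", {
  h <- build_backbone(20)
  expect_equal(site_displacement(h, h, align_on = "A:1-10",
                                 site = "A:15-18",
                                 normal = c(0, 0, 1))$total, 0,
               tolerance = 1e-9)
  # translate residues 11-20 by exactly 5 A along z
  b <- h
  mob <- b$atoms$resno >= 11
  b$atoms$z[mob] <- b$atoms$z[mob] + 5
  d <- site_displacement(h, b, align_on = "A:1-10", site = "A:14-17",
                         normal = c(0, 0, 1))
  expect_equal(d$total, 5, tolerance = 1e-9)
  expect_equal(d$along_normal, 5, tolerance = 1e-9)
  # auto normal requires a dimer
  expect_error(site_displacement(h, b, align_on = "A:1-10",
                                 site = "A:14-17", normal = "auto"),
               "dimer|monomer")
})

test_that("auto membrane normal comes from the dimer two-fold axis", {
  h <- build_backbone(16)
  # build a C2 dimer: copy rotated 180 degrees about z, offset from the axis
  prot <- h
  prot$atoms$x <- prot$atoms$x + 10
  mate <- apply_transform(screw_transform(c(0, 0, 1), 180), prot)
  mate$atoms$chain <- "B"
  dimer <- structure_model(rbind(prot$atoms, mate$atoms), label = "dimer")
  b <- dimer
  mv <- b$atoms$chain == "A" & b$atoms$resno >= 9
  b$atoms$z[mv] <- b$atoms$z[mv] + 3
  d <- site_displacement(dimer, b, align_on = "A:1-8", site = "A:12-14",
                         normal = "auto")
  expect_equal(abs(d$normal), c(0, 0, 1), tolerance = 1e-6)
  expect_equal(d$along_normal, 3, tolerance = 1e-6)
})
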