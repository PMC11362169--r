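# NeRF internal-to-Cartesian placement: position the atom d bonded to c with
# bond length L, bond angle theta at c (b-c-d) and dihedral chi (a-b-c-d)
place_atom <- function(a, b, c, length, angle, dihedral) {
  th <- angle * pi / 180
  chi <- dihedral * pi / 180
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  d2 <- length * c(-cos(th), sin(th) * cos(chi), sin(th) * sin(chi))
  as.numeric(c + m %*% d2)
}

# standard backbone internal coordinates (Engh-Huber-like ideal values)
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7)

#' Build an ideal polypeptide backbone from phi/psi dihedrals
#'
#' Extends an N/CA/C backbone residue by residue using standard bond
#' lengths and angles and the supplied torsions (chain construction from
#' internal coordinates; omega fixed at 180).
#'
#' @param n_res number of residues.
#' @param phi,psi backbone torsions in degrees, recycled to `n_res`
#'   (defaults -57/-47, an ideal alpha helix).
#' @param resname residue names, recycled (default `"ALA"`).
#' @param chain chain identifier.
#' @param label structure label.
#' @return a `structure_model` with N, CA, C atoms per residue.
#' @export
build_backbone <- function(n_res, phi = -57, psi = -47, resname = "ALA",
                           chain = "A", label = "ideal") {
  stopifnot(n_res >= 2)
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)
  resname <- rep_len(resname, n_res)
  g <- BB_GEOM
  coords <- matrix(NA_real_, nrow = 3 * n_res, ncol = 3)
  # residue 1 in the xy-plane
  coords[1, ] <- c(0, 0, 0)
  coords[2, ] <- c(g$n_ca, 0, 0)
  th <- g$ang_n_ca_c * pi / 180
  coords[3, ] <- coords[2, ] + g$ca_c * c(-cos(th), sin(th), 0)
  for (i in 2:n_res) {
    nprev <- coords[3 * (i - 2) + 1, ]
    caprev <- coords[3 * (i - 2) + 2, ]
    cprev <- coords[3 * (i - 2) + 3, ]
    ni <- place_atom(nprev, caprev, cprev, g$c_n, g$ang_ca_c_n, psi[i - 1])
    cai <- place_atom(caprev, cprev, ni, g$n_ca, g$ang_c_n_ca, 180)
    ci <- place_atom(cprev, ni, cai, g$ca_c, g$ang_n_ca_c, phi[i])
    coords[3 * (i - 1) + 1:3, ] <- rbind(ni, cai, ci)
  }
  structure_model(
    tibble::tibble(chain = chain,
                   resno = rep(seq_len(n_res), each = 3),
                   resname = rep(resname, each = 3),
                   elety = rep(c("N", "CA", "C"), n_res),
                   x = coords[, 1], y = coords[, 2], z = coords[, 3],
                   element = rep(c("N", "C", "C"), n_res)),
    label = label
  )
}

#' Two-conformation toy hinge structures with known ground truth
#'
#' Builds an ideal two-helix peptide (2 * `n_res_per_helix` residues of
#' continuous alpha helix) and a second conformation in which the C-terminal
#' helix is rigidly rotated by `hinge_angle` about `hinge_axis` through the
#' amide nitrogen of the first rotated residue (the pivot). The pair plus
#' its ground truth drives round-trip tests of dihedral, superposition and
#' screw-axis analyses.
#'
#' @param n_res_per_helix residues per helix (>= 5).
#' @param hinge_angle rotation in degrees, in `[0, 180)`; 0 returns two
#'   identical structures.
#' @param hinge_axis rotation axis (need not be normalised; zero rejected).
#' @param phi,psi helix torsions in degrees.
#' @return list with `a`, `b` (`structure_model`s) and `truth` (hinge
#'   angle, unit axis, pivot point, pivot residue, mobile residue range).
#' @export
make_toy_hinge_structures <- function(n_res_per_helix = 12, hinge_angle = 25,
                                      hinge_axis = c(0, 0, 1),
                                      phi = -57, psi = -47) {
  stopifnot(n_res_per_helix >= 5, hinge_angle >= 0, hinge_angle < 180)
  axis <- unit3(hinge_axis)
  n <- 2 * n_res_per_helix
  a <- build_backbone(n, phi = phi, psi = psi, label = "conformation_A")
  b <- a
  b$label <- "conformation_B"
  pivot_res <- n_res_per_helix + 1
  pivot_atom <- a$atoms[a$atoms$resno == pivot_res & a$atoms$elety == "N", ]
  pivot <- as.numeric(pivot_atom[1, c("x", "y", "z")])
  mobile <- b$atoms$resno >= pivot_res
  if (hinge_angle > 0) {
    tr <- screw_transform(axis, hinge_angle, pitch = 0, point = pivot)
    xyz <- as.matrix(b$atoms[mobile, c("x", "y", "z")])
    xyz <- apply_transform(tr, xyz)
    b$atoms$x[mobile] <- xyz[, 1]
    b$atoms$y[mobile] <- xyz[, 2]
    b$atoms$z[mobile] <- xyz[, 3]
  }
  list(a = a, b = b,
       truth = list(hinge_angle = hinge_angle, axis = axis, pivot = pivot,
                    pivot_residue = pivot_res,
                    mobile_residues = c(pivot_res, n)))
}
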