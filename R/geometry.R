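#' Signed torsion angle of four points
#'
#' Standard atan2 formulation of the dihedral defined by four atoms,
#' following the IUPAC sign convention.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return angle in degrees on (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(b2 / sqrt(sum(b2^2)), n1)
  wrap_angle(atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) abort_hdx("degenerate (zero) vector")
  v / n
}

#' Backbone phi/psi dihedrals
#'
#' Computes per-residue phi (C'-N-CA-C) and psi (N-CA-C-N') torsions from
#' backbone atoms. Residues whose own backbone or whose neighbour's
#' bridging atom is missing -- including chain termini -- are reported as
#' `NA` (flagged, never fabricated).
#'
#' @param x a `structure_model`.
#' @param selection optional residue selection (string or tibble); the
#'   neighbouring residues needed for terminal torsions are taken from the
#'   full structure.
#' @return tibble with columns `chain`, `resno`, `resname`, `phi`, `psi`
#'   (degrees on (-180, 180]).
#' @export
compute_dihedrals <- function(x, selection = NULL) {
  stopifnot(inherits(x, "structure_model"))
  bb <- x$atoms[x$atoms$elety %in% c("N", "CA", "C"), , drop = FALSE]
  res <- resolve_selection(x, selection, atoms = "CA")[, c("chain", "resno",
                                                           "resname")]
  coord <- function(chain, resno, elety) {
    i <- which(bb$chain == chain & bb$resno == resno & bb$elety == elety)
    if (length(i) != 1) return(NULL)
    as.numeric(bb[i, c("x", "y", "z")])
  }
  phi <- psi <- rep(NA_real_, nrow(res))
  for (i in seq_len(nrow(res))) {
    ch <- res$chain[i]
    r <- res$resno[i]
    n <- coord(ch, r, "N"); ca <- coord(ch, r, "CA"); cc <- coord(ch, r, "C")
    if (is.null(n) || is.null(ca) || is.null(cc)) next
    cprev <- coord(ch, r - 1, "C")
    nnext <- coord(ch, r + 1, "N")
    if (!is.null(cprev)) phi[i] <- dihedral_angle(cprev, n, ca, cc)
    if (!is.null(nnext)) psi[i] <- dihedral_angle(n, ca, cc, nnext)
  }
  tibble::tibble(chain = res$chain, resno = res$resno, resname = res$resname,
                 phi = phi, psi = psi)
}

#' Wrapped absolute dihedral differences between two structures' series
#'
#' Per residue: `dphi = |wrap(phi_a - phi_b)|` and likewise `dpsi`, both in
#' `[0, 180]`. Symmetric in argument order. Residues undefined in either
#' series stay `NA`.
#'
#' @param a,b tibbles from [compute_dihedrals()] over the same residues.
#' @return tibble with `chain`, `resno`, `dphi`, `dpsi`.
#' @export
dihedral_difference <- function(a, b) {
  ka <- paste(a$chain, a$resno)
  kb <- paste(b$chain, b$resno)
  if (!setequal(ka, kb)) {
    off <- c(setdiff(ka, kb), setdiff(kb, ka))
    abort_hdx("residue keys differ between series: ",
              paste(utils::head(off, 6), collapse = ", "))
  }
  b <- b[match(ka, kb), ]
  tibble::tibble(chain = a$chain, resno = a$resno,
                 dphi = abs(wrap_angle(a$phi - b$phi)),
                 dpsi = abs(wrap_angle(a$psi - b$psi)))
}

#' Rigid-body transform
#'
#' Rotation + translation acting as `x' = R x + t` on column coordinate
#' vectors. The rotation must be proper (orthonormal, det +1).
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation vector (Angstrom).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      det(rotation) < 0) {
    abort_hdx("rotation is not a proper orthonormal matrix")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  s <- screw_decompose(x)
  if (s$pure_translation) {
    cat(sprintf("<rigid_transform> pure translation |t| = %.3f A\n",
                sqrt(sum(x$translation^2))))
  } else {
    cat(sprintf(
      "<rigid_transform> rotation %.2f deg about (%.3f, %.3f, %.3f), pitch %.3f A\n",
      s$angle, s$axis[1], s$axis[2], s$axis[3], s$pitch))
  }
  invisible(x)
}

#' Apply a rigid transform to coordinates or a structure
#'
#' @param transform a `rigid_transform`.
#' @param x an n x 3 coordinate matrix (rows are points) or a
#'   `structure_model`.
#' @return the transformed object, same type as `x`.
#' @export
apply_transform <- function(transform, x) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(x, "structure_model")) {
    xyz <- as.matrix(x$atoms[, c("x", "y", "z")])
    out <- apply_transform(transform, xyz)
    x$atoms$x <- out[, 1]
    x$atoms$y <- out[, 2]
    x$atoms$z <- out[, 3]
    return(x)
  }
  x <- rbind(x)
  sweep(x %*% t(transform$rotation), 2, -transform$translation)
}

# internal Kabsch fit of mobile points P onto reference points Q (rows)
kabsch_fit <- function(p, q) {
  stopifnot(nrow(p) == nrow(q), nrow(p) >= 3)
  pm <- colMeans(p)
  qm <- colMeans(q)
  h <- crossprod(sweep(p, 2, pm), sweep(q, 2, qm))
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- rigid_transform(r, qm - as.numeric(r %*% pm))
  fitted <- apply_transform(tr, p)
  list(transform = tr,
       rmsd = sqrt(mean(rowSums((fitted - q)^2))))
}

#' Least-squares superposition (Kabsch)
#'
#' Optimal rigid-body fit of `mobile` onto `reference` over atoms paired by
#' (chain, residue number, atom name). Reflections are corrected via the
#' determinant sign of the SVD solution, so the returned rotation is always
#' proper.
#'
#' @param mobile,reference `structure_model` objects.
#' @param selection residue selection applied to both structures.
#' @param atoms atom names used for the fit (default Calpha only;
#'   `c("N","CA","C","O")` gives a backbone fit).
#' @return list with `transform` (a `rigid_transform` mapping mobile onto
#'   reference), `rmsd` (Angstrom, after transform) and `n_atoms`.
#' @export
superpose <- function(mobile, reference, selection = NULL, atoms = "CA") {
  pr <- pair_atoms(mobile, reference, selection, atoms)
  fit <- kabsch_fit(pr$mobile, pr$reference)
  list(transform = fit$transform, rmsd = fit$rmsd,
       n_atoms = length(pr$keys))
}

#' Screw-axis decomposition of a rigid transform
#'
#' Any proper rigid motion is a rotation about a unique axis plus a
#' translation (pitch) along it. The axis is the rotation eigenvector for
#' eigenvalue 1, the angle comes from the trace, the pitch is the
#' translation component along the axis, and the axis point solves the
#' in-plane fixed-point equation.
#'
#' @param transform a `rigid_transform`.
#' @param angle_tol rotations below this angle (degrees) are reported as
#'   pure translations with undefined axis.
#' @return list with `axis` (unit vector), `angle` (degrees in (0, 180]),
#'   `pitch` (Angstrom along axis), `axis_point` (a point on the axis) and
#'   `pure_translation` flag.
#' @export
screw_decompose <- function(transform, angle_tol = 1e-7) {
  stopifnot(inherits(transform, "rigid_transform"))
  r <- transform$rotation
  tv <- transform$translation
  cth <- max(-1, min(1, (sum(diag(r)) - 1) / 2))
  angle <- acos(cth) * 180 / pi
  if (angle < angle_tol) {
    return(list(axis = c(NA_real_, NA_real_, NA_real_), angle = 0,
                pitch = sqrt(sum(tv^2)), axis_point = c(NA, NA, NA),
                pure_translation = TRUE))
  }
  skew <- c(r[3, 2] - r[2, 3], r[1, 3] - r[3, 1], r[2, 1] - r[1, 2])
  if (sqrt(sum(skew^2)) > 1e-8) {
    axis <- unit3(skew)
  } else {
    # angle ~ 180 deg: axis from the symmetric part, canonical sign
    ev <- eigen(r, symmetric = FALSE)
    i <- which.min(abs(ev$values - 1))
    axis <- unit3(Re(ev$vectors[, i]))
    j <- which.max(abs(axis))
    if (axis[j] < 0) axis <- -axis
  }
  pitch <- sum(tv * axis)
  tperp <- tv - pitch * axis
  # ((I - R) + a a^T) p = t_perp has a unique solution with a.p = 0
  p <- solve(diag(3) - r + tcrossprod(axis), tperp)
  list(axis = axis, angle = angle, pitch = pitch,
       axis_point = as.numeric(p), pure_translation = FALSE)
}

#' Build a rigid transform from screw parameters
#'
#' Inverse of [screw_decompose()]: Rodrigues rotation about `axis` through
#' `point`, plus `pitch` along the axis.
#'
#' @param axis rotation axis (normalised internally).
#' @param angle rotation angle in degrees.
#' @param pitch translation along the axis (Angstrom).
#' @param point a point the axis passes through.
#' @return a `rigid_transform`.
#' @export
screw_transform <- function(axis, angle, pitch = 0, point = c(0, 0, 0)) {
  a <- unit3(axis)
  th <- angle * pi / 180
  k <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  r <- diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
  tv <- as.numeric((diag(3) - r) %*% point) + pitch * a
  rigid_transform(r, tv)
}

#' Helix axis by principal-component fit
#'
#' Direction of the dominant singular vector of the centred Calpha
#' coordinates, with the sign fixed to point from the N- to the C-terminal
#' end of the selection.
#'
#' @param x a `structure_model`.
#' @param selection residue selection covering the helix (>= 5 Calpha).
#' @return list with `direction` (unit, N->C), `centroid`, `n_atoms`.
#' @export
helix_axis <- function(x, selection = NULL) {
  ca <- resolve_selection(x, selection, atoms = "CA")
  if (nrow(ca) < 5) abort_hdx("helix fit requires >= 5 Calpha atoms")
  m <- as.matrix(ca[, c("x", "y", "z")])
  cen <- colMeans(m)
  sv <- svd(sweep(m, 2, cen))
  if (sv$d[1] < 2 * sv$d[2]) {
    warning("helix axis fit is poorly determined (selection not rod-like)",
            call. = FALSE)
  }
  dir <- sv$v[, 1]
  if (sum(dir * (m[nrow(m), ] - m[1, ])) < 0) dir <- -dir
  list(direction = as.numeric(dir), centroid = as.numeric(cen),
       n_atoms = nrow(ca))
}

#' Angle between two helix axes
#'
#' @param a,b results of [helix_axis()].
#' @return list with `angle` in `[0, 90]` (line-line angle) and
#'   `signed_angle` in `[0, 180]` using the N->C direction convention.
#' @export
inter_helix_angle <- function(a, b) {
  d <- sum(unit3(a$direction) * unit3(b$direction))
  d <- max(-1, min(1, d))
  list(angle = acos(abs(d)) * 180 / pi,
       signed_angle = acos(d) * 180 / pi)
}

#' Displacement of a site between two conformations
#'
#' Superposes structure `b` onto structure `a` using the `align_on`
#' selection (typically the static scaffold domain), then reports how far
#' the Calpha centroid of the `site` selection moved: the total distance
#' and its component along a reference direction (e.g. the membrane
#' normal). With `normal = "auto"` the direction is taken as the dimer
#' two-fold axis, i.e. the screw axis of the transform mapping the second
#' chain onto the first.
#'
#' @param a,b `structure_model` objects sharing residue numbering.
#' @param align_on selection used for the superposition.
#' @param site selection whose Calpha centroid is tracked.
#' @param normal unit direction, or `"auto"` for the dimer two-fold axis.
#' @return list with `total` and `along_normal` (Angstrom), the
#'   displacement `vector`, and the `normal` used.
#' @export
site_displacement <- function(a, b, align_on, site, normal = "auto") {
  fit <- superpose(b, a, selection = align_on)
  site_a <- resolve_selection(a, site, atoms = "CA")
  site_b <- resolve_selection(b, site, atoms = "CA")
  if (nrow(site_a) == 0 || nrow(site_b) == 0) {
    abort_hdx("site selection missing in one of the structures")
  }
  ca <- colMeans(as.matrix(site_a[, c("x", "y", "z")]))
  cb_raw <- colMeans(as.matrix(site_b[, c("x", "y", "z")]))
  cb <- as.numeric(apply_transform(fit$transform, rbind(cb_raw)))
  d <- cb - ca
  if (identical(normal, "auto")) {
    chains <- unique(a$atoms$chain)
    if (length(chains) < 2) {
      abort_hdx("normal = \"auto\" needs a dimer; supply the membrane ",
                "normal explicitly for a monomer")
    }
    c1 <- a$atoms[a$atoms$chain == chains[1] & a$atoms$elety == "CA", ]
    c2 <- a$atoms[a$atoms$chain == chains[2] & a$atoms$elety == "CA", ]
    common <- intersect(c1$resno, c2$resno)
    if (length(common) < 3) abort_hdx("chains share too few residues")
    fit2 <- kabsch_fit(as.matrix(c2[match(common, c2$resno),
                                    c("x", "y", "z")]),
                       as.matrix(c1[match(common, c1$resno),
                                    c("x", "y", "z")]))
    sc <- screw_decompose(fit2$transform)
    if (sc$pure_translation) abort_hdx("dimer axis undefined")
    normal <- sc$axis
  }
  n <- unit3(normal)
  list(total = sqrt(sum(d^2)), along_normal = abs(sum(d * n)),
       vector = d, normal = n, alignment_rmsd = fit$rmsd)
}
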