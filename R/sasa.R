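# van der Waals radii (Angstrom), Bondi set; hydrogens are ignored by the
# callers (crystal structures lack them) but a radius is kept for completeness
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
               F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
VDW_DEFAULT <- 1.70

# near-uniform points on the unit sphere (Fibonacci lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(element, radii = VDW_RADII) {
  r <- radii[toupper(element)]
  if (anyNA(r)) {
    warning("unknown element radius for: ",
            paste(unique(element[is.na(r)]), collapse = ", "),
            "; using fallback ", VDW_DEFAULT, " A", call. = FALSE)
    r[is.na(r)] <- VDW_DEFAULT
  }
  unname(r)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA by sphere sampling: each atom's solvent-accessible sphere
#' (vdW radius + probe) is covered with a near-uniform point lattice and
#' the accessible fraction is the share of points outside every
#' neighbouring atom's accessible sphere. Hydrogens are ignored by
#' default.
#'
#' @param x a `structure_model`.
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sampling points per atom (default 960).
#' @param keep_hydrogens include hydrogen atoms (default FALSE).
#' @return tibble of atoms with an `sasa` column (Angstrom^2).
#' @export
sasa_atoms <- function(x, probe = 1.4, n_points = 960,
                       keep_hydrogens = FALSE) {
  stopifnot(inherits(x, "structure_model"), probe >= 0, n_points >= 10)
  at <- x$atoms
  if (!keep_hydrogens) at <- at[toupper(at$element) != "H", , drop = FALSE]
  n <- nrow(at)
  if (n == 0) abort_hdx("no atoms for SASA")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- atom_radii(at$element) + probe
  pts <- sphere_points(n_points)
  sasa <- numeric(n)
  # neighbour search on a cutoff of the largest radius sum
  maxr <- max(rad)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(di < rad[i] + maxr & seq_len(n) != i)
    nb <- nb[di[nb] < rad[i] + rad[nb]]
    surf <- sweep(pts * rad[i], 2, xyz[i, ], `+`)
    if (length(nb) == 0) {
      acc <- n_points
    } else {
      buried <- rep(FALSE, n_points)
      for (j in nb) {
        if (all(buried)) break
        keep <- !buried
        d2 <- (surf[keep, 1] - xyz[j, 1])^2 + (surf[keep, 2] - xyz[j, 2])^2 +
          (surf[keep, 3] - xyz[j, 3])^2
        buried[keep] <- d2 < rad[j]^2
      }
      acc <- sum(!buried)
    }
    sasa[i] <- 4 * pi * rad[i]^2 * acc / n_points
  }
  at$sasa <- sasa
  tibble::as_tibble(at)
}

#' Buried surface area of an interface
#'
#' For each side of a complex: SASA of the side isolated minus its SASA in
#' the complex. Swapping the side labels swaps the two values and
#' preserves their sum.
#'
#' @param complex a `structure_model` containing both sides.
#' @param side_a_chains,side_b_chains chain identifiers of the two sides
#'   (non-empty, disjoint).
#' @param probe probe radius (Angstrom).
#' @param n_points sampling points per atom.
#' @return list with `area_a`, `area_b` and `total` (Angstrom^2).
#' @export
buried_surface_area <- function(complex, side_a_chains, side_b_chains,
                                probe = 1.4, n_points = 960) {
  stopifnot(length(side_a_chains) > 0, length(side_b_chains) > 0)
  if (length(intersect(side_a_chains, side_b_chains)) > 0) {
    abort_hdx("side chain sets must be disjoint")
  }
  at <- complex$atoms
  sub <- function(chains) {
    structure_model(at[at$chain %in% chains, , drop = FALSE],
                    label = paste(chains, collapse = "+"))
  }
  both <- sub(c(side_a_chains, side_b_chains))
  s_ab <- sasa_atoms(both, probe, n_points)
  s_a <- sasa_atoms(sub(side_a_chains), probe, n_points)
  s_b <- sasa_atoms(sub(side_b_chains), probe, n_points)
  in_a <- s_ab$chain %in% side_a_chains
  area_a <- sum(s_a$sasa) - sum(s_ab$sasa[in_a])
  area_b <- sum(s_b$sasa) - sum(s_ab$sasa[!in_a])
  list(area_a = area_a, area_b = area_b, total = area_a + area_b)
}

#' Residues of a target in contact with a query
#'
#' Target residues with any heavy atom within `cutoff` of any heavy atom
#' of the query chains.
#'
#' @param complex a `structure_model`.
#' @param query_chains,target_chains chain identifiers.
#' @param cutoff distance cutoff in Angstrom (default 4.0).
#' @return tibble with `chain`, `resno`, `resname`, `min_dist` for each
#'   contacting target residue (empty tibble if none).
#' @export
contact_residues <- function(complex, query_chains, target_chains,
                             cutoff = 4.0) {
  stopifnot(cutoff > 0)
  at <- complex$atoms[toupper(complex$atoms$element) != "H", , drop = FALSE]
  q <- at[at$chain %in% query_chains, , drop = FALSE]
  tg <- at[at$chain %in% target_chains, , drop = FALSE]
  empty <- tibble::tibble(chain = character(), resno = integer(),
                          resname = character(), min_dist = numeric())
  if (nrow(q) == 0 || nrow(tg) == 0) return(empty)
  qm <- as.matrix(q[, c("x", "y", "z")])
  tm <- as.matrix(tg[, c("x", "y", "z")])
  # residue-wise min distance to any query atom
  d2min <- vapply(seq_len(nrow(tm)), function(i) {
    min((qm[, 1] - tm[i, 1])^2 + (qm[, 2] - tm[i, 2])^2 +
          (qm[, 3] - tm[i, 3])^2)
  }, numeric(1))
  tg$d <- sqrt(d2min)
  hits <- dplyr::summarise(
    dplyr::group_by(tg, .data$chain, .data$resno, .data$resname),
    min_dist = min(.data$d), .groups = "drop")
  hits <- hits[hits$min_dist <= cutoff, , drop = FALSE]
  hits[order(hits$chain, hits$resno), ]
}
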