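# shared fixtures and independent oracles, built in code at test time

# independent torsion implementation: acos magnitude + triple-product sign,
# a different route than the package's atan2 form
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  crs <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                          a[3] * b[1] - a[1] * b[3],
                          a[1] * b[2] - a[2] * b[1])
  n1 <- crs(b1, b2); n2 <- crs(b2, b3)
  ca <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(max(-1, min(1, ca))) * 180 / pi
  if (sum(crs(n1, n2) * b2) < 0) ang <- -ang
  ang
}

# small Calpha-only structure from a coordinate matrix
ca_structure <- function(xyz, chain = "A", label = "toy") {
  structure_model(data.frame(chain = chain, resno = seq_len(nrow(xyz)),
                             resname = "ALA", elety = "CA",
                             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                             element = "C"),
                  label = label)
}

# summary pair for the two-stage test: equal SEM at every labelled exposure
flat_summary_pair <- function(deltas, sem = 0.1, n = 4,
                              exposures = c(30, 360, 900, 2700)) {
  mk <- function(state, means) {
    tibble::tibble(protein = "p", start = 1, end = 10,
                   sequence = "AAAAAAAAAA", max_uptake = 9, state = state,
                   exposure = exposures, n = n, mean_uptake = means,
                   sd = sem * sqrt(n), sem = sem)
  }
  dplyr::bind_rows(mk("A", rep(0, length(exposures))), mk("B", deltas))
}

# independent t quantiles, frozen from a reference quantile computation
T_0975_DF3 <- 3.182446
T_0995_DF3 <- 5.840909
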