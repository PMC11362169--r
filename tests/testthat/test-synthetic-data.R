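test_that("EX2 residue deuteration matches the closed form and its limits", {
  m <- exchange_model("AG", cbind(S = c(1, 1)), k_int = c(0.01, 0.01),
                      back_exchange = 0)
  # k_obs = 0.01 / 10^1 = 1e-3; D(900) = 1 - exp(-0.9)
  expect_equal(unname(residue_deuteration(m, "S", 900)[2, 1]),
               1 - exp(-0.9), tolerance = 1e-12)
  # saturation limit and zero-time
  m2 <- exchange_model("AG", cbind(S = c(0, 0)), k_int = c(1, 1),
                       back_exchange = 0)
  expect_equal(unname(residue_deuteration(m2, "S", c(0, 1e9))[2, ]),
               c(0, 1), tolerance = 1e-12)
  # closed form agrees with numerical ODE integration of dD/dt = k (1 - D)
  k <- 0.01 / 10
  ode <- deSolve::ode(c(D = 0), times = c(0, 900),
                      function(t, y, p) list(k * (1 - y)), NULL)
  expect_equal(unname(residue_deuteration(m, "S", 900)[2, 1]),
               unname(ode[2, "D"]), tolerance = 1e-5)
})

test_that("deuteration is monotone in time and protection, prolines zero", {
  seqs <- "ACDPEFGHIK"
  m <- exchange_model(seqs, cbind(lo = rep(1, 10), hi = rep(2, 10)),
                      back_exchange = 0.25)
  d_lo <- residue_deuteration(m, "lo", c(0, 30, 360, 900, 2700))
  d_hi <- residue_deuteration(m, "hi", c(0, 30, 360, 900, 2700))
  expect_true(all(diff(t(d_lo)) >= 0))            # non-decreasing in t
  expect_true(all(d_hi <= d_lo + 1e-12))          # decreasing in logPF
  expect_true(all(d_lo[4, ] == 0))                # proline row
  expect_true(all(d_lo <= 1 - 0.25 + 1e-12))      # back-exchange ceiling
})

test_that("simulated uptake tables honour truth, bounds and determinism", {
  seqs <- random_protein(60, seed = 5)
  n <- nchar(seqs)
  m <- exchange_model(seqs, cbind(A = rep(1.5, n), B = rep(2.5, n)),
                      back_exchange = 0.2)
  map <- generate_peptide_map(seqs, mean_length = 9, step = 3, seed = 5)
  t1 <- simulate_uptake_table(m, map, n_replicates = 4, noise_sd = 0.1,
                              seed = 7)
  t2 <- simulate_uptake_table(m, map, n_replicates = 4, noise_sd = 0.1,
                              seed = 7)
  expect_identical(t1, t2)  # same seed, byte-identical
  t3 <- simulate_uptake_table(m, map, n_replicates = 4, noise_sd = 0.1,
                              seed = 8)
  expect_false(identical(t1$center, t3$center))
  # noise-free table: exposure-0 uptake exactly zero, uptake <= max uptake
  t0 <- simulate_uptake_table(m, map, noise_sd = 0, seed = 1)
  upt <- uptake_from_centroids(t0)$data
  expect_true(all(abs(upt$uptake[upt$exposure == 0]) < 1e-9))
  expect_true(all(upt$uptake <= upt$max_uptake + 1e-9))
  expect_true(all(upt$uptake >= -1e-9))
})

test_that("uptake simulation rejects invalid inputs", {
  m <- exchange_model("AAAA", cbind(A = rep(1, 4)))
  map_bad <- tibble::tibble(start = 2, end = 9, sequence = "AAAAAAAA")
  expect_error(simulate_uptake_table(m, map_bad), "outside")
  map <- tibble::tibble(start = 1, end = 4, sequence = "AAAA")
  expect_error(simulate_uptake_table(m, map, noise_sd = -1), "noise_sd")
  expect_error(simulate_uptake_table(m, map, exposures = c(30, 360)),
               "include 0")
  expect_error(simulate_uptake_table(m, map, n_replicates = 1), ">= 2")
  expect_error(exchange_model("AAAA", cbind(A = c(-1, 0, 0, 0))), "logPF")
  expect_error(exchange_model("AAAA", cbind(A = rep(0, 4)),
                              back_exchange = 1), "back_exchange")
})

test_that("generated peptide maps match brute-force coverage and redundancy", {
  # non-overlapping tiling of a 100-mer by 10-mers
  seqs <- random_protein(100, prolines = 0, seed = 2)
  tiles <- tibble::tibble(start = seq(1, 91, by = 10), end = seq(10, 100, 10))
  cm <- coverage_metrics(tiles, 100)
  expect_equal(cm$coverage, 100)
  expect_equal(cm$redundancy, 1.0)
  # duplicated peptide doubles redundancy
  dup <- tibble::tibble(start = c(1, 1), end = c(10, 10))
  expect_equal(coverage_metrics(dup, 10)$redundancy, 2.0)
  # any generated map equals direct enumeration
  map <- generate_peptide_map(random_protein(80, seed = 3),
                              mean_length = 10, step = 3, seed = 3)
  counts <- integer(80)
  for (i in seq_len(nrow(map))) {
    counts[map$start[i]:map$end[i]] <- counts[map$start[i]:map$end[i]] + 1L
  }
  cm2 <- coverage_metrics(map, 80)
  expect_equal(cm2$coverage, 100 * mean(counts > 0))
  expect_equal(cm2$redundancy, mean(counts[counts > 0]))
  expect_error(generate_peptide_map("ACDEF", mean_length = 10), "exceeds")
})

test_that("binding and melt simulators reproduce their closed forms", {
  # cold = 0 point of the competition model
  b <- simulate_binding_curve(600, 1000, 100, hot_conc = 34,
                              cold_concs = c(0, 1e2, 1e4, 1e6),
                              noise_sd = 0)
  expect_equal(b$cpm[b$cold_conc == 0][1], 1000 * 34 / 634 + 100,
               tolerance = 1e-12)
  # full competition: cold -> infinity approaches background
  expect_lt(abs(b$cpm[b$cold_conc == 1e6][1] - 100), 0.04)
  expect_error(simulate_binding_curve(-5, 1000, 100), "Kd")
  # noiseless melt: derivative maximum at the programmed Tm
  mc <- simulate_melt_curve(60, noise_sd = 0)
  expect_equal(melt_temperature(mc$temperature, mc$fluorescence)$tm, 60,
               tolerance = 0.25)
  expect_error(simulate_melt_curve(95), "within")
})

test_that("toy hinge structures carry an exact, recoverable ground truth", {
  # zero hinge: identical structures, zero differences
  t0 <- make_toy_hinge_structures(8, hinge_angle = 0)
  expect_identical(t0$a$atoms, t0$b$atoms)
  expect_equal(superpose(t0$a, t0$b)$rmsd, 0, tolerance = 1e-12)
  # construction inverse: programmed helix torsions recovered
  h <- build_backbone(10, phi = -57, psi = -47)
  dh <- compute_dihedrals(h)
  expect_lt(max(abs(dh$phi[-1] + 57)), 1e-6)
  expect_lt(max(abs(dh$psi[-10] + 47)), 1e-6)
  expect_true(is.na(dh$phi[1]) && is.na(dh$psi[10]))  # termini flagged
  # 25-degree hinge about z recovered by fit + screw decomposition
  th <- make_toy_hinge_structures(12, hinge_angle = 25,
                                  hinge_axis = c(0, 0, 1))
  fit <- superpose(th$a, th$b, selection = "A:13-24")
  sc <- screw_decompose(fit$transform)
  expect_equal(sc$angle, 25, tolerance = 1e-6)
  expect_lt(max(abs(sc$axis - c(0, 0, 1))), 1e-6)
  expect_error(make_toy_hinge_structures(8, 25, hinge_axis = c(0, 0, 0)),
               "degenerate")
})

test_that("simulated tables round-trip through the state-table reader", {
  ds <- simulate_two_state_dataset(n_res = 50, seed = 9)
  f <- tempfile(fileext = ".csv")
  write_state_table(ds$table, f)
  rt <- read_state_table(f)
  expect_equal(nrow(rt$rejected), 0)
  expect_equal(rt$data$center, ds$table$center, tolerance = 1e-9)
  expect_identical(rt$data$sequence, ds$table$sequence)
  unlink(f)
})
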