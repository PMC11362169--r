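test_that("replicate summaries use n-1 deviations and exclude singletons", {
  tab <- data.frame(protein = "p", start = 1, end = 5, sequence = "ACDEF",
                    state = "apo", exposure = 30, replicate = 1:4,
                    center = 0, score = 8, max_uptake = 4,
                    uptake = c(1, 2, 3, 4))
  s <- summarize_uptake(tab)$data
  expect_equal(s$mean_uptake, 2.5)
  expect_equal(s$sd, sd(c(1, 2, 3, 4)))
  expect_equal(s$sem, sd(1:4) / 2, tolerance = 1e-12)
  # constant replicates: zero SEM
  tab$uptake <- 1
  expect_equal(summarize_uptake(tab)$data$sem, 0)
  # singleton excluded with audit note
  one <- tab[1, ]
  one$start <- 9
  got <- summarize_uptake(rbind(tab, one))
  expect_equal(nrow(got$audit), 1)
  expect_false(9 %in% got$data$start)
})

test_that("two-stage worked examples reproduce the frozen thresholds", {
  r <- two_stage_test(flat_summary_pair(rep(1, 4)))
  p <- r$peptides
  # stage 1: quadrature SEM and the 95% t quantile at df = 3
  expect_equal(p$avg_sem, sqrt(0.02), tolerance = 1e-9)
  expect_equal(p$test_value_1, sqrt(0.02) * T_0975_DF3, tolerance = 1e-6)
  expect_equal(p$n_sig_exposures, 4)
  # stage 2: summed SEM and the 99% t quantile at df = 3
  expect_equal(p$summed_sem, 4 * sqrt(0.02), tolerance = 1e-9)
  expect_equal(p$test_value_2, 4 * sqrt(0.02) * T_0995_DF3,
               tolerance = 1e-6)
  expect_equal(p$sum_delta, 4)
  expect_true(p$stage1_pass && p$stage2_pass && p$significant)
  # second example: stage 1 passes on 3 of 4, stage 2 gate rejects
  r2 <- two_stage_test(flat_summary_pair(c(0.5, 0.5, 0.5, 0.2)))
  p2 <- r2$peptides
  expect_equal(p2$n_sig_exposures, 3)
  expect_true(p2$stage1_pass)
  expect_equal(p2$sum_delta, 1.7)
  expect_false(p2$stage2_pass)
  expect_false(p2$significant)
  # zero difference is never significant
  expect_false(two_stage_test(flat_summary_pair(rep(0, 4)))
               $peptides$significant)
})

test_that("threshold ties count as significant and pooling modes differ", {
  # delta exactly at the stage-1 test value passes ("equal or greater")
  tv <- sqrt(0.1^2 + 0.1^2) * stats::qt(0.975, 3)
  r <- two_stage_test(flat_summary_pair(rep(tv, 4)))
  expect_equal(r$peptides$n_sig_exposures, 4)
  # literal-average pooling: (sem_a + sem_b) summed over exposures / n
  rl <- two_stage_test(flat_summary_pair(rep(1, 4)), pooling = "literal")
  expect_equal(rl$peptides$avg_sem, 0.2, tolerance = 1e-12)
  expect_equal(rl$params$pooling, "literal")
})

test_that("swapping conditions negates deltas and preserves verdicts", {
  ds <- simulate_two_state_dataset(n_res = 120, frac_affected = 0.25,
                                   seed = 31)
  up <- uptake_from_centroids(ds$table)$data
  s <- summarize_uptake(up)$data
  fwd <- two_stage_test(s, state_a = "A", state_b = "B")
  rev <- two_stage_test(s, state_a = "B", state_b = "A")
  key <- function(x) paste(x$start, x$end)
  rev_m <- rev$peptides[match(key(fwd$peptides), key(rev$peptides)), ]
  expect_equal(rev_m$sum_delta, -fwd$peptides$sum_delta, tolerance = 1e-12)
  expect_identical(rev_m$significant, fwd$peptides$significant)
  expect_equal(rev_m$test_value_1, fwd$peptides$test_value_1,
               tolerance = 1e-12)
})

test_that("uniform uptake rescaling preserves verdicts", {
  ds <- simulate_two_state_dataset(n_res = 100, frac_affected = 0.3,
                                   seed = 32)
  up <- uptake_from_centroids(ds$table)$data
  s1 <- summarize_uptake(up)$data
  up2 <- up
  up2$uptake <- up2$uptake * 3
  s2 <- summarize_uptake(up2)$data
  r1 <- two_stage_test(s1)
  r2 <- two_stage_test(s2)
  expect_identical(r1$peptides$significant, r2$peptides$significant)
  expect_equal(r2$peptides$sum_delta, 3 * r1$peptides$sum_delta,
               tolerance = 1e-9)
})

test_that("mismatched exposures and undersized designs are rejected", {
  s <- flat_summary_pair(rep(1, 4))
  expect_error(two_stage_test(s[s$exposure != 30 | s$state != "B", ]),
               "differ")
  s1 <- flat_summary_pair(rep(1, 4))
  s1$n <- 1
  expect_error(two_stage_test(s1), "degrees of freedom")
})

test_that("power rises with effect size and replicate count", {
  frac_sig <- function(delta_logpf, n_rep) {
    ds <- simulate_two_state_dataset(n_res = 150, frac_affected = 0.2,
                                     delta_logpf = delta_logpf,
                                     n_replicates = n_rep, seed = 77)
    up <- uptake_from_centroids(ds$table)$data
    r <- two_stage_test(summarize_uptake(up)$data)
    mean(r$peptides$significant)
  }
  f0 <- frac_sig(0, 4)
  f05 <- frac_sig(0.5, 4)
  f1 <- frac_sig(1, 4)
  expect_lte(f0, f05)
  expect_lte(f05, f1)
  expect_gt(f1, 0)
  expect_lte(frac_sig(0.5, 3), frac_sig(0.5, 8))
})

test_that("residue maps aggregate covering peptides and flag gaps", {
  mk_diff <- function(peps) {
    s <- do.call(rbind, lapply(seq_len(nrow(peps)), function(i) {
      flat_summary_pair(rep(peps$delta[i], 4))  |>
        transform(start = peps$start[i], end = peps$end[i],
                  sequence = peps$sequence[i],
                  max_uptake = max_uptake(peps$sequence[i]))
    }))
    two_stage_test(s)
  }
  one <- mk_diff(data.frame(start = 10, end = 20,
                            sequence = "AAAAAAAAAAA", delta = 1))
  m <- residue_level_map(one, 30)
  expect_true(all(m$value[11:20] == 1))
  expect_false(m$covered[10])  # first peptide residue excluded
  expect_true(all(is.na(m$value[c(1:10, 21:30)])))
  expect_true(all(!m$covered[c(1:9, 21:30)]))
  # overlapping peptides average under "mean"
  two <- mk_diff(data.frame(start = c(10, 15), end = c(20, 25),
                            sequence = c("AAAAAAAAAAA", "AAAAAAAAAAA"),
                            delta = c(1, 3)))
  m2 <- residue_level_map(two, 30)
  expect_true(all(m2$value[16:20] == 2))
  expect_true(all(m2$value[11:15] == 1))
  expect_true(all(m2$value[21:25] == 3))
  # prolines never receive a value
  pro <- mk_diff(data.frame(start = 1, end = 7, sequence = "GAPAAAG",
                            delta = 1))
  mp <- residue_level_map(pro, 7)
  expect_false(mp$covered[3])
})

test_that("residue map concordance with simulated truth is high", {
  ds <- simulate_two_state_dataset(n_res = 430, frac_affected = 0.2,
                                   delta_logpf = 1, seed = 42)
  r <- run_hdx_pipeline(ds$table, "A", "B", protein_length = 430)
  m <- r$residue_map
  ok <- m$covered
  rho <- stats::cor(-m$value[ok], ds$truth$delta_logpf[ok],
                    method = "spearman")
  expect_gt(rho, 0.8)
  # affected residues carry the extreme (most negative) map values
  expect_lt(mean(m$value[ok & ds$truth$affected]),
            mean(m$value[ok & !ds$truth$affected]))
})
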