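#' Per-residue intrinsic amide exchange rates
#'
#' Configurable per-residue-type lookup with a single default rate. This is
#' deliberately simple: synthetic ground truth only needs rates of a
#' realistic order of magnitude, and the downstream statistics never depend
#' on the absolute rate scale. Fully sequence-dependent intrinsic-rate
#' tables are out of scope. Prolines receive a positive placeholder rate
#' but contribute no exchangeable amide anywhere downstream.
#'
#' @param sequence one-letter amino-acid string.
#' @param rates single default rate in 1/s, or a named vector of
#'   per-residue-type rates (unnamed types fall back to `default_rate`).
#' @param default_rate fallback rate (1/s).
#' @return numeric vector of rates, one per residue.
#' @export
intrinsic_rates <- function(sequence, rates = NULL, default_rate = 1.0) {
  res <- check_sequence(sequence)
  stopifnot(default_rate > 0)
  k <- rep(default_rate, length(res))
  if (!is.null(rates)) {
    if (is.null(names(rates))) {
      stopifnot(length(rates) == 1, rates > 0)
      k[] <- rates
    } else {
      stopifnot(all(rates > 0))
      hit <- res %in% names(rates)
      k[hit] <- rates[res[hit]]
    }
  }
  k
}

#' EX2 exchange model with state-dependent protection factors
#'
#' Ground-truth model for synthetic HDX data: each residue exchanges with
#' rate `k_int / 10^logPF` under the EX2 assumption, and each named state
#' carries its own per-residue log10 protection factors. A global
#' back-exchange fraction scales all deuteration.
#'
#' @param sequence one-letter amino-acid string.
#' @param logpf_by_state matrix (residues x states, named columns) or named
#'   list of per-residue log10 protection factors (all >= 0).
#' @param k_int per-residue intrinsic rates (1/s); default from
#'   [intrinsic_rates()].
#' @param back_exchange deuterium loss fraction in `[0, 1)`.
#' @return object of class `exchange_model`.
#' @export
exchange_model <- function(sequence, logpf_by_state, k_int = NULL,
                           back_exchange = 0.25) {
  res <- check_sequence(sequence)
  n <- length(res)
  if (is.list(logpf_by_state)) {
    logpf_by_state <- do.call(cbind, logpf_by_state)
  }
  logpf_by_state <- as.matrix(logpf_by_state)
  if (is.null(colnames(logpf_by_state))) {
    abort_hdx("logpf_by_state needs named states")
  }
  if (nrow(logpf_by_state) != n) {
    abort_hdx("logPF rows (", nrow(logpf_by_state),
              ") != sequence length (", n, ")")
  }
  if (any(logpf_by_state < 0)) abort_hdx("logPF must be >= 0")
  k_int <- k_int %||% intrinsic_rates(sequence)
  if (length(k_int) != n || any(k_int <= 0)) {
    abort_hdx("k_int must be positive, one per residue")
  }
  if (back_exchange < 0 || back_exchange >= 1) {
    abort_hdx("back_exchange must be in [0, 1)")
  }
  structure(list(sequence = sequence, residues = res, k_int = k_int,
                 logpf = logpf_by_state, back_exchange = back_exchange,
                 states = colnames(logpf_by_state)),
            class = "exchange_model")
}

#' @export
print.exchange_model <- function(x, ...) {
  cat(sprintf("<exchange_model> %d residues, states: %s, back-exchange %.2f\n",
              length(x$residues), paste(x$states, collapse = ", "),
              x$back_exchange))
  invisible(x)
}

#' Per-residue deuteration under EX2 kinetics
#'
#' `D_i(t) = (1 - back_exchange) * (1 - exp(-(k_int_i / 10^logPF_i) * t))`,
#' with prolines fixed at 0 (no exchangeable amide).
#'
#' @param model an `exchange_model`.
#' @param state state name.
#' @param times exposure times in seconds.
#' @return matrix residues x times of deuterium fractions.
#' @export
residue_deuteration <- function(model, state, times) {
  stopifnot(inherits(model, "exchange_model"), all(times >= 0))
  if (!state %in% model$states) abort_hdx("unknown state: ", state)
  k <- model$k_int / 10^model$logpf[, state]
  d <- (1 - model$back_exchange) * (1 - exp(-outer(k, times)))
  d[model$residues == "P", ] <- 0
  dimnames(d) <- list(NULL, as.character(times))
  d
}

#' Generate an overlapping peptide map
#'
#' Tiles the sequence with proteolysis-like overlapping peptides: start
#' positions advance by roughly `step` residues and lengths scatter around
#' `mean_length`, producing the redundant coverage typical of online
#' peptic digestion.
#'
#' @param sequence one-letter amino-acid string.
#' @param mean_length mean peptide length (>= 3).
#' @param step mean advance between consecutive starts.
#' @param seed integer seed.
#' @return tibble with `start`, `end` (1-based inclusive) and `sequence`.
#' @export
generate_peptide_map <- function(sequence, mean_length = 10, step = 3,
                                 seed = NULL) {
  res <- check_sequence(sequence)
  n <- length(res)
  stopifnot(mean_length >= 3, step >= 1)
  if (mean_length > n) abort_hdx("mean_length exceeds sequence length")
  with_seed(seed, {
    starts <- integer(0)
    s <- 1
    while (s <= n - 2) {
      starts <- c(starts, s)
      s <- s + max(1, round(step + stats::rnorm(1, 0, 1)))
    }
    len <- pmax(3, stats::rpois(length(starts), mean_length))
    end <- pmin(n, starts + len - 1)
    keep <- end - starts + 1 >= 3
    map <- tibble::tibble(start = starts[keep], end = end[keep])
    map$sequence <- vapply(seq_len(nrow(map)), function(i) {
      paste(res[map$start[i]:map$end[i]], collapse = "")
    }, character(1))
    map
  })
}

# internal: noise-free peptide uptake (Da) for one state across exposures.
# First peptide residue excluded (rapid back-exchange convention); prolines
# contribute zero via residue_deuteration.
peptide_true_uptake <- function(model, map, state, exposures) {
  d <- residue_deuteration(model, state, exposures)
  n <- length(model$residues)
  if (any(map$start < 1) || any(map$end > n) || any(map$end < map$start)) {
    abort_hdx("peptide outside sequence bounds")
  }
  up <- t(vapply(seq_len(nrow(map)), function(i) {
    rows <- seq(map$start[i] + 1, length.out = map$end[i] - map$start[i])
    if (length(rows) == 0) return(numeric(ncol(d)))
    colSums(d[rows, , drop = FALSE])
  }, numeric(ncol(d))))
  dimnames(up) <- list(NULL, as.character(exposures))
  up
}

#' Simulate a replicate-level peptide uptake table
#'
#' Builds a DynamX-style state table from an EX2 ground-truth model:
#' per-peptide true uptake (sum of residue deuteration over residues
#' `start+1 .. end`, prolines excluded), Gaussian centroid noise at the
#' peptide level, undeuterated centroid masses from average residue
#' masses, and a per-peptide identification score.
#'
#' @param model an `exchange_model`.
#' @param map peptide map tibble (`start`, `end`, `sequence`).
#' @param exposures labelling times in seconds; must include 0 (the
#'   undeuterated reference).
#' @param n_replicates technical replicates (>= 2).
#' @param noise_sd centroid noise in Da (>= 0).
#' @param states states to simulate (default: all states of the model).
#' @param protein protein identifier written into the table.
#' @param seed integer seed; identical seed and parameters reproduce the
#'   table exactly.
#' @return tibble with columns `protein`, `start`, `end`, `sequence`,
#'   `state`, `exposure`, `replicate`, `center`, `score`, `max_uptake`.
#' @export
simulate_uptake_table <- function(model, map,
                                  exposures = c(0, 30, 360, 900, 2700),
                                  n_replicates = 4, noise_sd = 0.1,
                                  states = NULL, protein = "synthetic",
                                  seed = NULL) {
  stopifnot(inherits(model, "exchange_model"))
  if (!0 %in% exposures) abort_hdx("exposures must include 0")
  if (n_replicates < 2) abort_hdx("n_replicates must be >= 2")
  if (noise_sd < 0) abort_hdx("noise_sd must be >= 0")
  states <- states %||% model$states
  exposures <- sort(unique(exposures))
  with_seed(seed, {
    base_mass <- vapply(map$sequence, function(s) {
      sum(AA_MASS[strsplit(s, "")[[1]]]) + WATER_MASS
    }, numeric(1), USE.NAMES = FALSE)
    score <- pmax(0, stats::rnorm(nrow(map), mean = 8, sd = 0.8))
    maxup <- vapply(map$sequence, max_uptake, numeric(1), USE.NAMES = FALSE)
    out <- lapply(states, function(st) {
      truth <- peptide_true_uptake(model, map, st, exposures)
      grid <- tidyr::expand_grid(pep = seq_len(nrow(map)),
                                 exposure = exposures,
                                 replicate = seq_len(n_replicates))
      grid$true_uptake <- truth[cbind(grid$pep,
                                      match(grid$exposure, exposures))]
      grid$center <- base_mass[grid$pep] + grid$true_uptake +
        stats::rnorm(nrow(grid), 0, noise_sd)
      tibble::tibble(protein = protein,
                     start = map$start[grid$pep], end = map$end[grid$pep],
                     sequence = map$sequence[grid$pep], state = st,
                     exposure = grid$exposure, replicate = grid$replicate,
                     center = grid$center, score = score[grid$pep],
                     max_uptake = maxup[grid$pep])
    })
    dplyr::bind_rows(out)
  })
}

#' Simulate a complete two-state differential HDX study
#'
#' Study-condition generator for end-to-end validation: a random protein,
#' heterogeneous baseline protection, a set of contiguous affected blocks
#' whose residues gain `delta_logpf` protection in state B, a redundant
#' peptide map, and a replicate-level uptake table for both states under
#' the standard labelling design (five exposures 0/30/360/900/2700 s,
#' four replicates).
#'
#' @param n_res protein length.
#' @param frac_affected fraction of residues with a true protection change.
#' @param delta_logpf added log10 protection factor in state B.
#' @param n_blocks number of contiguous affected blocks.
#' @param baseline_logpf range of the uniform baseline log10 protection.
#' @param noise_sd centroid noise (Da).
#' @param back_exchange back-exchange fraction.
#' @param exposures labelling times (s), including 0.
#' @param n_replicates technical replicates.
#' @param mean_length,step peptide-map parameters.
#' @param seed integer seed for the whole dataset.
#' @return list with `model`, `map`, `table` and `truth` (tibble of
#'   `resno`, `delta_logpf`, `affected`).
#' @export
simulate_two_state_dataset <- function(n_res = 300, frac_affected = 0.2,
                                       delta_logpf = 1, n_blocks = 3,
                                       baseline_logpf = c(0.5, 3),
                                       noise_sd = 0.1, back_exchange = 0.25,
                                       exposures = c(0, 30, 360, 900, 2700),
                                       n_replicates = 4,
                                       mean_length = 10, step = 3,
                                       seed = 1) {
  stopifnot(frac_affected >= 0, frac_affected <= 1, n_blocks >= 1)
  with_seed(seed, {
    sequence <- random_protein(n_res)
    base <- stats::runif(n_res, baseline_logpf[1], baseline_logpf[2])
    n_aff <- round(frac_affected * n_res)
    affected <- rep(FALSE, n_res)
    if (n_aff > 0) {
      sizes <- diff(round(seq(0, n_aff, length.out = n_blocks + 1)))
      gaps <- sort(sample.int(n_res - n_aff, n_blocks))
      pos <- 1
      for (b in seq_len(n_blocks)) {
        s <- min(gaps[b] + if (b > 1) sum(sizes[1:(b - 1)]) else 0,
                 n_res - sizes[b] + 1)
        affected[seq(s, length.out = sizes[b])] <- TRUE
      }
    }
    delta <- ifelse(affected, delta_logpf, 0)
    model <- exchange_model(sequence,
                            cbind(A = base, B = base + delta),
                            back_exchange = back_exchange)
    map <- generate_peptide_map(sequence, mean_length, step)
    table <- simulate_uptake_table(model, map, exposures = exposures,
                                   n_replicates = n_replicates,
                                   noise_sd = noise_sd)
    list(model = model, map = map, table = table,
         truth = tibble::tibble(resno = seq_len(n_res),
                                delta_logpf = delta, affected = affected))
  })
}

#' Simulate a homologous-competition binding curve
#'
#' Scintillation counts for a fixed hot-ligand concentration titrated with
#' unlabelled competitor: `Bmax * [hot] / ([hot] + [cold] + Kd) +
#' background`, plus Gaussian noise.
#'
#' @param kd dissociation constant (nM, > 0).
#' @param bmax maximal binding (CPM).
#' @param background background signal (CPM).
#' @param hot_conc hot-ligand concentration (nM).
#' @param cold_concs competitor concentrations (nM).
#' @param n_replicates replicates per concentration.
#' @param noise_sd Gaussian noise (CPM).
#' @param seed integer seed.
#' @return tibble with `cold_conc`, `replicate`, `cpm`, `truth`.
#' @export
simulate_binding_curve <- function(kd, bmax, background, hot_conc = 34,
                                   cold_concs = c(0, 10^seq(1, 5,
                                                            length.out = 11)),
                                   n_replicates = 3, noise_sd = 0,
                                   seed = NULL) {
  if (kd <= 0) abort_hdx("Kd must be > 0")
  stopifnot(all(cold_concs >= 0), hot_conc >= 0, noise_sd >= 0)
  with_seed(seed, {
    g <- tidyr::expand_grid(cold_conc = cold_concs,
                            replicate = seq_len(n_replicates))
    g$truth <- bmax * hot_conc / (hot_conc + g$cold_conc + kd) + background
    g$cpm <- g$truth + stats::rnorm(nrow(g), 0, noise_sd)
    g[, c("cold_conc", "replicate", "cpm", "truth")]
  })
}

#' Simulate a thermal melt (DSF) curve
#'
#' Logistic fluorescence transition between two baselines with midpoint
#' `tm`, sampled over a temperature ramp, plus Gaussian noise.
#'
#' @param tm melting temperature (deg C), within the ramp.
#' @param slope transition width parameter (deg C).
#' @param baseline_low,baseline_high fluorescence baselines.
#' @param temperatures ramp (deg C, strictly increasing; default 25-90 in
#'   0.5-degree steps).
#' @param noise_sd Gaussian noise (fluorescence units).
#' @param seed integer seed.
#' @return tibble with `temperature`, `fluorescence`, `truth`.
#' @export
simulate_melt_curve <- function(tm, slope = 1.5, baseline_low = 100,
                                baseline_high = 1000,
                                temperatures = seq(25, 90, by = 0.5),
                                noise_sd = 0, seed = NULL) {
  stopifnot(all(diff(temperatures) > 0), noise_sd >= 0, slope > 0)
  if (tm <= min(temperatures) || tm >= max(temperatures)) {
    abort_hdx("tm must lie within the temperature ramp")
  }
  with_seed(seed, {
    truth <- baseline_low + (baseline_high - baseline_low) *
      stats::plogis((temperatures - tm) / slope)
    tibble::tibble(temperature = temperatures,
                   fluorescence = truth + stats::rnorm(length(truth), 0,
                                                       noise_sd),
                   truth = truth)
  })
}
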