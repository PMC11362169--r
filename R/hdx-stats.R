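#' Summarise replicate uptake
#'
#' Mean, standard deviation (n-1 denominator) and standard error of the
#' mean per (peptide, state, exposure). Entries with fewer than two
#' replicates are excluded with an audit note, since they cannot enter
#' the significance test.
#'
#' @param table tibble with replicate-level `uptake` (from
#'   [uptake_from_centroids()] or [simulate_uptake_table()] +
#'   [uptake_from_centroids()]).
#' @return list with `data` (summary tibble: `n`, `mean_uptake`, `sd`,
#'   `sem`) and `audit`.
#' @export
summarize_uptake <- function(table) {
  stopifnot("uptake" %in% names(table))
  s <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(table), .data$protein, .data$start,
                    .data$end, .data$sequence, .data$max_uptake,
                    .data$state, .data$exposure),
    n = dplyr::n(),
    mean_uptake = mean(.data$uptake),
    sd = stats::sd(.data$uptake),
    .groups = "drop")
  s$sem <- s$sd / sqrt(s$n)
  bad <- s$n < 2
  audit <- tibble::tibble(
    pep = paste(s$protein[bad], s$start[bad], s$end[bad], s$sequence[bad]),
    state = s$state[bad], exposure = s$exposure[bad],
    reason = "fewer than 2 replicates")
  list(data = s[!bad, , drop = FALSE], audit = audit)
}

#' Hybrid two-stage significance test for differential uptake
#'
#' Tests every peptide for a significant deuterium-uptake difference
#' between two states across the labelled exposures (exposure 0 never
#' enters).
#'
#' Stage 1: the per-exposure SEM of the difference is pooled (see
#' `pooling`), averaged over the labelled exposures into `avg_sem`, and
#' multiplied by the two-sided t quantile at confidence `ci1` with
#' `n_replicates - 1` degrees of freedom to form the first test value. An
#' exposure is significant when its absolute uptake difference is greater
#' than or equal to the test value; the peptide passes when significant
#' exposures form a strict majority (3 of 4 at the standard design).
#'
#' Stage 2: the uptake differences are summed over labelled exposures,
#' the summed SEM is `avg_sem * n_exposures`, and the second test value
#' multiplies it by the two-sided t quantile at confidence `ci2` with
#' `n_exposures - 1` degrees of freedom (overridable via `df2`). The
#' peptide is significant only if both stages pass.
#'
#' @param summary_a,summary_b summary tibbles (from
#'   [summarize_uptake()]`$data`) for the two states, or a single tibble
#'   containing both states passed as `summary_a` with `summary_b`
#'   omitted.
#' @param state_a,state_b state labels; differences are `state_b -
#'   state_a`.
#' @param ci1,ci2 stage confidence levels (defaults 0.95 and 0.99).
#' @param pooling `"quadrature"` (default): per-exposure SEM of the
#'   difference is `sqrt(sem_a^2 + sem_b^2)`, then averaged.
#'   `"literal"`: `avg_sem` is the sum of all per-exposure, per-condition
#'   SEMs divided by the number of labelled exposures (the published
#'   phrasing taken verbatim).
#' @param df2 stage-2 degrees of freedom (default `n_exposures - 1`).
#' @return object of class `hdx_differential`: list with `peptides`
#'   (per-peptide verdicts and test values), `exposures` (per
#'   peptide-exposure differences and flags) and `params`.
#' @export
two_stage_test <- function(summary_a, summary_b = NULL, state_a = "A",
                           state_b = "B", ci1 = 0.95, ci2 = 0.99,
                           pooling = c("quadrature", "literal"),
                           df2 = NULL) {
  pooling <- match.arg(pooling)
  if (is.null(summary_b)) {
    both <- tibble::as_tibble(summary_a)
    summary_a <- both[both$state == state_a, , drop = FALSE]
    summary_b <- both[both$state == state_b, , drop = FALSE]
  }
  a <- tibble::as_tibble(summary_a)
  b <- tibble::as_tibble(summary_b)
  a <- a[a$state == state_a & a$exposure > 0, , drop = FALSE]
  b <- b[b$state == state_b & b$exposure > 0, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) abort_hdx("no labelled exposures found")
  key <- function(x) paste(x$protein, x$start, x$end, x$sequence, x$exposure)
  if (!setequal(key(a), key(b))) {
    abort_hdx("labelled exposures differ between states for: ",
              paste(utils::head(c(setdiff(key(a), key(b)),
                                  setdiff(key(b), key(a))), 4),
                    collapse = "; "))
  }
  b <- b[match(key(a), key(b)), ]
  ex <- tibble::tibble(
    protein = a$protein, start = a$start, end = a$end,
    sequence = a$sequence, max_uptake = a$max_uptake,
    exposure = a$exposure,
    delta = b$mean_uptake - a$mean_uptake,
    sem_a = a$sem, sem_b = b$sem,
    n_a = a$n, n_b = b$n)
  ex$sem_diff <- sqrt(ex$sem_a^2 + ex$sem_b^2)
  per <- dplyr::summarise(
    dplyr::group_by(ex, .data$protein, .data$start, .data$end,
                    .data$sequence, .data$max_uptake),
    n_exposures = dplyr::n(),
    avg_sem = if (pooling == "quadrature") mean(.data$sem_diff)
              else sum(.data$sem_a + .data$sem_b) / dplyr::n(),
    sum_delta = sum(.data$delta),
    n_rep = min(.data$n_a, .data$n_b),
    .groups = "drop")
  df1 <- per$n_rep - 1
  if (any(df1 <= 0)) abort_hdx("replicate degrees of freedom <= 0")
  stage2_df <- df2 %||% (per$n_exposures - 1)
  if (any(stage2_df <= 0)) abort_hdx("exposure degrees of freedom <= 0")
  per$test_value_1 <- per$avg_sem * stats::qt(1 - (1 - ci1) / 2, df1)
  per$summed_sem <- per$avg_sem * per$n_exposures
  per$test_value_2 <- per$summed_sem * stats::qt(1 - (1 - ci2) / 2, stage2_df)
  pkey <- function(x) paste(x$protein, x$start, x$end, x$sequence)
  ex$test_value_1 <- per$test_value_1[match(pkey(ex), pkey(per))]
  ex$significant <- abs(ex$delta) >= ex$test_value_1
  nsig <- dplyr::summarise(
    dplyr::group_by(ex, .data$protein, .data$start, .data$end,
                    .data$sequence),
    n_sig = sum(.data$significant), .groups = "drop")
  per$n_sig_exposures <- nsig$n_sig[match(pkey(per), pkey(nsig))]
  per$stage1_pass <- per$n_sig_exposures > per$n_exposures / 2
  per$stage2_pass <- abs(per$sum_delta) >= per$test_value_2
  per$significant <- per$stage1_pass & per$stage2_pass
  per$sign <- sign(per$sum_delta)
  structure(list(peptides = per, exposures = ex,
                 params = list(state_a = state_a, state_b = state_b,
                               ci1 = ci1, ci2 = ci2, pooling = pooling,
                               df2 = df2)),
            class = "hdx_differential")
}

#' @export
print.hdx_differential <- function(x, ...) {
  cat(sprintf(
    "<hdx_differential> %s - %s: %d peptides, %d significant (%s pooling)\n",
    x$params$state_b, x$params$state_a, nrow(x$peptides),
    sum(x$peptides$significant), x$params$pooling))
  invisible(x)
}

#' Project peptide differences onto residues
#'
#' Each residue covered by at least one peptide receives the aggregate of
#' the per-peptide mean uptake difference (Da, or relative when `value =
#' "rel_delta"`) over its covering peptides. Each peptide's first residue
#' is excluded (its amide retains no label) and prolines never receive
#' values. Uncovered residues are flagged `covered = FALSE` with an `NA`
#' value -- the "no data" stretches of a residue-level map -- and are
#' never reported as zero.
#'
#' With `significant_only = TRUE` (the published practice: only peptides
#' passing both stages are used) a residue covered by at least one
#' stage-passing peptide aggregates over those peptides only, and a
#' covered residue with no significant peptide is reported as an exact
#' zero ("no change") rather than a noisy estimate. Uncovered residues
#' remain `NA` in either mode.
#'
#' @param differential an `hdx_differential`.
#' @param protein_length total residue count of the protein.
#' @param aggregation `"mean"` or `"median"` across covering peptides.
#' @param value `"delta"` (Da) or `"rel_delta"` (fraction of max uptake).
#' @param significant_only use only stage-passing peptides' estimates.
#' @return tibble with `resno`, `value`, `n_peptides`,
#'   `frac_significant`, `covered`.
#' @export
residue_level_map <- function(differential, protein_length,
                              aggregation = c("mean", "median"),
                              value = c("delta", "rel_delta"),
                              significant_only = FALSE) {
  stopifnot(inherits(differential, "hdx_differential"))
  aggregation <- match.arg(aggregation)
  value <- match.arg(value)
  agg <- if (aggregation == "mean") mean else stats::median
  per <- differential$peptides
  if (any(per$end > protein_length)) {
    abort_hdx("peptide coordinates exceed protein length")
  }
  val <- per$sum_delta / per$n_exposures
  if (value == "rel_delta") {
    val <- ifelse(per$max_uptake > 0, val / per$max_uptake, NA_real_)
  }
  acc <- vector("list", protein_length)
  sig <- vector("list", protein_length)
  for (i in seq_len(nrow(per))) {
    rows <- seq(per$start[i] + 1, length.out = per$end[i] - per$start[i])
    if (length(rows) == 0) next
    res <- strsplit(per$sequence[i], "")[[1]][rows - per$start[i] + 1]
    rows <- rows[res != "P"]
    for (r in rows) {
      acc[[r]] <- c(acc[[r]], val[i])
      sig[[r]] <- c(sig[[r]], per$significant[i])
    }
  }
  n_pep <- lengths(acc)
  tibble::tibble(
    resno = seq_len(protein_length),
    value = vapply(seq_len(protein_length), function(r) {
      if (n_pep[r] == 0) return(NA_real_)
      if (significant_only) {
        keep <- sig[[r]]
        if (!any(keep)) return(0)
        return(agg(acc[[r]][keep], na.rm = TRUE))
      }
      agg(acc[[r]], na.rm = TRUE)
    }, numeric(1)),
    n_peptides = n_pep,
    frac_significant = vapply(seq_len(protein_length), function(r) {
      if (n_pep[r] == 0) NA_real_ else mean(sig[[r]])
    }, numeric(1)),
    covered = n_pep > 0)
}

#' Sequence coverage and redundancy of a peptide map
#'
#' Coverage is the percentage of residues inside at least one peptide
#' span; redundancy is the mean number of covering peptides over covered
#' residues (`NA` with a warning for an empty map).
#'
#' @param peptides tibble with `start`, `end`.
#' @param protein_length total residue count.
#' @return list with `coverage` (percent) and `redundancy`.
#' @export
coverage_metrics <- function(peptides, protein_length) {
  stopifnot(protein_length >= 1)
  counts <- integer(protein_length)
  for (i in seq_len(nrow(peptides))) {
    idx <- peptides$start[i]:peptides$end[i]
    counts[idx] <- counts[idx] + 1L
  }
  covered <- counts > 0
  if (!any(covered)) {
    warning("empty peptide map: redundancy undefined", call. = FALSE)
    return(list(coverage = 0, redundancy = NA_real_))
  }
  list(coverage = 100 * mean(covered),
       redundancy = mean(counts[covered]))
}
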