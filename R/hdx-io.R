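#' Default column map for DynamX-style state tables
#'
#' Maps the canonical internal field names to the column headers of a
#' DynamX-like state-data export. Every entry can be remapped, since
#' vendor export schemas vary.
#'
#' @param ... named overrides, e.g. `center = "Center SD"`.
#' @return named character vector (internal name -> file column).
#' @export
dynamx_column_map <- function(...) {
  map <- c(protein = "Protein", start = "Start", end = "End",
           sequence = "Sequence", state = "State", exposure = "Exposure",
           replicate = "Replicate", center = "Center", score = "Score",
           max_uptake = "MaxUptake")
  dots <- c(...)
  map[names(dots)] <- dots
  map
}

REQUIRED_FIELDS <- c("protein", "start", "end", "sequence", "state",
                     "exposure", "replicate", "center")

#' Read and validate a peptide-level HDX state table
#'
#' Parses a CSV of replicate-level peptide centroid measurements, renames
#' columns through `column_map`, validates row-level invariants
#' (coordinates, sequence length, exposure sign, key uniqueness) and
#' collects malformed rows into a rejection report instead of dropping
#' them silently. Missing `score` or `max_uptake` columns are tolerated
#' (`score` defaults to `NA`, `max_uptake` is recomputed from the
#' sequence).
#'
#' @param path CSV file with a header row.
#' @param column_map from [dynamx_column_map()].
#' @return list with `data` (validated tibble in canonical columns) and
#'   `rejected` (tibble of bad rows with a `reason` column).
#' @export
read_state_table <- function(path, column_map = dynamx_column_map()) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  missing_req <- setdiff(unname(column_map[REQUIRED_FIELDS]), names(raw))
  if (length(missing_req) > 0) {
    abort_hdx("missing required column(s): ",
              paste(missing_req, collapse = ", "))
  }
  present <- column_map[column_map %in% names(raw)]
  tab <- tibble::as_tibble(raw[, unname(present), drop = FALSE])
  names(tab) <- names(present)
  if (!"score" %in% names(tab)) tab$score <- NA_real_
  if (!"max_uptake" %in% names(tab)) {
    tab$max_uptake <- vapply(tab$sequence, max_uptake, numeric(1),
                             USE.NAMES = FALSE)
  }
  validate_state_table(tab)
}

# row-level validation shared by the reader and in-memory tables
validate_state_table <- function(tab) {
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  reason <- rep(NA_character_, nrow(tab))
  flag <- function(bad, why) {
    reason[bad & is.na(reason)] <<- why
  }
  flag(is.na(tab$start) | is.na(tab$end) | tab$end < tab$start,
       "end < start or missing coordinates")
  flag(!is.na(tab$start) & !is.na(tab$end) &
         nchar(tab$sequence) != tab$end - tab$start + 1,
       "sequence length != end - start + 1")
  flag(is.na(tab$exposure) | tab$exposure < 0, "negative or missing exposure")
  flag(is.na(tab$center), "missing centroid")
  flag(!is.na(tab$max_uptake) & tab$max_uptake < 0, "negative max uptake")
  key <- paste(tab$protein, tab$start, tab$end, tab$sequence, tab$state,
               tab$exposure, tab$replicate)
  flag(duplicated(key) | duplicated(key, fromLast = TRUE),
       "duplicate (peptide, state, exposure, replicate) key")
  ok <- is.na(reason)
  rejected <- tab[!ok, , drop = FALSE]
  rejected$reason <- reason[!ok]
  list(data = tab[ok, , drop = FALSE], rejected = rejected)
}

#' Write a state table as CSV
#'
#' Inverse of [read_state_table()] under the same column map; a written
#' table re-reads without loss.
#'
#' @param table canonical tibble (as returned in `$data`).
#' @param path output CSV.
#' @param column_map from [dynamx_column_map()].
#' @return `path`, invisibly.
#' @export
write_state_table <- function(table, path,
                              column_map = dynamx_column_map()) {
  out <- as.data.frame(table[, intersect(names(column_map), names(table))])
  names(out) <- unname(column_map[names(out)])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Maximum theoretical deuterium uptake of a peptide
#'
#' Number of exchangeable backbone amides under the standard convention:
#' peptide length minus prolines (no amide hydrogen) minus one (the
#' N-terminal residue, whose amide back-exchanges too fast to retain
#' label), floored at zero.
#'
#' @param sequence peptide amino-acid string.
#' @return integer count.
#' @examples
#' max_uptake("PEPTIDE") # 4
#' @export
max_uptake <- function(sequence) {
  res <- check_sequence(sequence)
  max(0L, length(res) - sum(res == "P") - 1L)
}

#' Filter peptides on identification confidence
#'
#' Keeps peptides with identification score strictly greater than
#' `min_score` and identified in at least `min_replicates` replicates of
#' the non-deuterated reference runs (exposure 0, or a dedicated reference
#' state). The peptide-level score is the mean score over its reference
#' rows. Every exclusion is recorded in an audit log. A strict
#' `per_exposure` mode additionally requires presence in
#' `min_replicates` replicates at every exposure.
#'
#' @param table canonical state-table tibble.
#' @param min_score exclusive score threshold (default 6: a score of
#'   exactly 6 is excluded).
#' @param min_replicates minimum identification replicates (default 3).
#' @param reference_state optional state label holding the identification
#'   runs; default uses exposure-0 rows of every state.
#' @param per_exposure apply the replicate rule at every exposure.
#' @return list with `data` (filtered tibble) and `audit` (tibble of
#'   excluded peptides with reasons).
#' @export
filter_peptides <- function(table, min_score = 6, min_replicates = 3,
                            reference_state = NULL, per_exposure = FALSE) {
  stopifnot(is.data.frame(table))
  tab <- tibble::as_tibble(table)
  tab$pep <- paste(tab$protein, tab$start, tab$end, tab$sequence)
  ref <- if (is.null(reference_state)) {
    tab[tab$exposure == 0, , drop = FALSE]
  } else {
    tab[tab$state == reference_state, , drop = FALSE]
  }
  stats_by_pep <- dplyr::summarise(
    dplyr::group_by(ref, .data$pep),
    score = mean(.data$score, na.rm = TRUE),
    n_ident = dplyr::n_distinct(.data$replicate), .groups = "drop")
  audit <- tibble::tibble(pep = character(), reason = character())
  add_audit <- function(peps, why) {
    if (length(peps) > 0) {
      audit <<- dplyr::bind_rows(audit,
                                 tibble::tibble(pep = peps, reason = why))
    }
  }
  all_peps <- unique(tab$pep)
  add_audit(setdiff(all_peps, stats_by_pep$pep),
            "no non-deuterated reference rows")
  low <- stats_by_pep$pep[!is.na(stats_by_pep$score) &
                            stats_by_pep$score <= min_score]
  add_audit(low, sprintf("score <= %g", min_score))
  few <- stats_by_pep$pep[stats_by_pep$n_ident < min_replicates]
  add_audit(few, sprintf("identified in < %d replicates", min_replicates))
  if (per_exposure) {
    per <- dplyr::summarise(
      dplyr::group_by(tab, .data$pep, .data$state, .data$exposure),
      n = dplyr::n_distinct(.data$replicate), .groups = "drop")
    bad <- unique(per$pep[per$n < min_replicates])
    add_audit(bad, sprintf("< %d replicates at some exposure",
                           min_replicates))
  }
  drop <- unique(audit$pep)
  out <- tab[!tab$pep %in% drop, , drop = FALSE]
  out$pep <- NULL
  list(data = out, audit = audit)
}

#' Deuterium uptake from centroid masses
#'
#' For every peptide and state, the undeuterated reference centroid is the
#' mean of its exposure-0 replicate centroids; uptake is
#' `centroid(t) - reference` in Da and relative uptake divides by the
#' peptide's maximum uptake. Negative uptake is allowed (noise) but rows
#' below -0.5 Da and relative uptake above 1.05 are flagged. Peptides
#' without a reference are excluded with an audit entry.
#'
#' @param table canonical state-table tibble.
#' @return list with `data` (tibble plus `uptake`, `rel_uptake`, `flag`
#'   columns) and `audit`.
#' @export
uptake_from_centroids <- function(table) {
  tab <- tibble::as_tibble(table)
  tab$pep <- paste(tab$protein, tab$start, tab$end, tab$sequence)
  refs <- dplyr::summarise(
    dplyr::group_by(tab[tab$exposure == 0, ], .data$pep, .data$state),
    ref_center = mean(.data$center), .groups = "drop")
  tab <- dplyr::left_join(tab, refs, by = c("pep", "state"))
  audit <- tibble::tibble(pep = unique(tab$pep[is.na(tab$ref_center)]),
                          reason = "no exposure-0 reference")
  tab <- tab[!is.na(tab$ref_center), , drop = FALSE]
  tab$uptake <- tab$center - tab$ref_center
  tab$rel_uptake <- ifelse(tab$max_uptake > 0,
                           tab$uptake / tab$max_uptake, NA_real_)
  tab$flag <- dplyr::case_when(
    tab$uptake < -0.5 ~ "uptake < -0.5 Da",
    !is.na(tab$rel_uptake) & tab$rel_uptake > 1.05 ~ "relative uptake > 1.05",
    TRUE ~ NA_character_)
  tab$pep <- NULL
  tab$ref_center <- NULL
  list(data = tab, audit = audit)
}
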