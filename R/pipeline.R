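#' Run the differential HDX pipeline end to end
#'
#' parse (optional) -> filter -> uptake from centroids -> replicate
#' summary -> two-stage test -> residue map, with an audit log recording
#' record counts at every stage. When `out_dir` is given, the per-peptide
#' differential table, the residue map, a per-residue structure-annotation
#' file (suitable for painting a B-factor column) and a provenance record
#' (parameters, package version, input checksum) are written there.
#'
#' @param table canonical state-table tibble, or a CSV path readable by
#'   [read_state_table()].
#' @param state_a,state_b states to compare (differences `state_b -
#'   state_a`).
#' @param protein_length residue count for the residue-level map; default
#'   is the largest peptide end coordinate.
#' @param min_score,min_replicates filtering thresholds (see
#'   [filter_peptides()]).
#' @param ci1,ci2,pooling,df2 test parameters (see [two_stage_test()]).
#' @param map_value,significant_only residue-map options (see
#'   [residue_level_map()]); the default follows the published practice of
#'   building maps from stage-passing peptides only.
#' @param out_dir optional output directory.
#' @param column_map column map when `table` is a path.
#' @return list with `filtered`, `uptake`, `summary`, `differential`,
#'   `residue_map` and `audit` (stage-wise record counts plus exclusion
#'   logs).
#' @export
run_hdx_pipeline <- function(table, state_a, state_b,
                             protein_length = NULL,
                             min_score = 6, min_replicates = 3,
                             ci1 = 0.95, ci2 = 0.99,
                             pooling = "quadrature", df2 = NULL,
                             map_value = "delta", significant_only = TRUE,
                             out_dir = NULL,
                             column_map = dynamx_column_map()) {
  input_path <- NULL
  if (is.character(table) && length(table) == 1) {
    input_path <- table
    parsed <- read_state_table(table, column_map)
    rejected <- parsed$rejected
    table <- parsed$data
  } else {
    rejected <- tibble::tibble()
    table <- validate_state_table(tibble::as_tibble(table))$data
  }
  counts <- list(input_rows = nrow(table) + nrow(rejected),
                 rejected_rows = nrow(rejected))
  filt <- filter_peptides(table, min_score = min_score,
                          min_replicates = min_replicates)
  counts$peptides_in <- length(unique(paste(table$start, table$end,
                                            table$sequence)))
  counts$peptides_filtered_out <- length(unique(filt$audit$pep))
  upt <- uptake_from_centroids(filt$data)
  summ <- summarize_uptake(upt$data)
  counts$summary_entries <- nrow(summ$data)
  if (nrow(summ$data) == 0 ||
      !all(c(state_a, state_b) %in% unique(summ$data$state))) {
    result <- list(filtered = filt$data, uptake = upt$data,
                   summary = summ$data, differential = NULL,
                   residue_map = NULL,
                   audit = c(counts, list(zero_result = TRUE,
                                          filter_log = filt$audit)))
    return(result)
  }
  diff <- two_stage_test(summ$data, state_a = state_a, state_b = state_b,
                         ci1 = ci1, ci2 = ci2, pooling = pooling, df2 = df2)
  protein_length <- protein_length %||% max(diff$peptides$end)
  rmap <- residue_level_map(diff, protein_length, value = map_value,
                            significant_only = significant_only)
  counts$peptides_tested <- nrow(diff$peptides)
  counts$peptides_significant <- sum(diff$peptides$significant)
  counts$residues_covered <- sum(rmap$covered)
  audit <- c(counts, list(zero_result = FALSE, filter_log = filt$audit,
                          uptake_log = upt$audit, summary_log = summ$audit))
  result <- list(filtered = filt$data, uptake = upt$data,
                 summary = summ$data, differential = diff,
                 residue_map = rmap, audit = audit)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(diff$peptides,
                     file.path(out_dir, "differential_peptides.csv"),
                     row.names = FALSE)
    utils::write.csv(rmap, file.path(out_dir, "residue_map.csv"),
                     row.names = FALSE)
    ann <- rmap[rmap$covered, c("resno", "value")]
    utils::write.csv(ann, file.path(out_dir, "residue_annotation.csv"),
                     row.names = FALSE)
    prov <- list(
      package = "hdxelevator",
      version = as.character(utils::packageVersion("hdxelevator")),
      timestamp = format(Sys.time(), tz = "UTC"),
      input = input_path,
      input_md5 = if (!is.null(input_path)) unname(tools::md5sum(input_path))
                  else NA,
      parameters = list(state_a = state_a, state_b = state_b,
                        min_score = min_score,
                        min_replicates = min_replicates, ci1 = ci1,
                        ci2 = ci2, pooling = pooling, df2 = df2,
                        map_value = map_value,
                        significant_only = significant_only,
                        protein_length = protein_length),
      counts = counts)
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}

#' Structural comparison report for two conformations
#'
#' Single report combining the geometry operations on a pair of
#' structures sharing residue numbering: backbone dihedral differences
#' over a region of interest, rigid-body domain superpositions with
#' RMSDs, the screw-axis decomposition of the mobile-domain transform
#' (after aligning on the static domain), helix-axis angles, and the
#' displacement of a site of interest.
#'
#' @param a,b `structure_model` objects (e.g. two conformations).
#' @param domains named list of selections, e.g.
#'   `list(scaffold = "A:128-210,A:355-429", transport = ...)`; each is
#'   superposed independently.
#' @param dihedral_region selection for the dihedral-difference series
#'   (default: whole structure).
#' @param helices optional named list of two selections whose axis angle
#'   is compared between the structures.
#' @param site optional selection tracked via [site_displacement()].
#' @param align_on domain name used as the static reference for the
#'   screw-axis and site-displacement analyses (default first domain).
#' @param mobile domain name treated as mobile (default second domain).
#' @param normal membrane normal for the site displacement (`"auto"` =
#'   dimer two-fold axis).
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return list with `dihedral_difference`, `domain_rmsd`, `screw`,
#'   `helix_angles`, `site` components (entries `NULL` when not
#'   requested).
#' @export
run_structure_report <- function(a, b, domains, dihedral_region = NULL,
                                 helices = NULL, site = NULL,
                                 align_on = names(domains)[1],
                                 mobile = names(domains)[2],
                                 normal = "auto", out_dir = NULL) {
  stopifnot(inherits(a, "structure_model"), inherits(b, "structure_model"),
            length(domains) >= 1, !is.null(names(domains)))
  dd <- dihedral_difference(compute_dihedrals(a, dihedral_region),
                            compute_dihedrals(b, dihedral_region))
  fits <- lapply(domains, function(sel) superpose(b, a, selection = sel))
  domain_rmsd <- tibble::tibble(
    domain = names(domains),
    rmsd = vapply(fits, `[[`, numeric(1), "rmsd"),
    n_atoms = vapply(fits, `[[`, numeric(1), "n_atoms"))
  screw <- NULL
  if (!is.null(mobile) && !is.na(mobile) && length(domains) >= 2) {
    # transform of the mobile domain in the frame of the static domain
    b_al <- apply_transform(fits[[align_on]]$transform, b)
    mob_fit <- superpose(a, b_al, selection = domains[[mobile]])
    screw <- screw_decompose(mob_fit$transform)
    screw$rmsd <- mob_fit$rmsd
  }
  helix_angles <- NULL
  if (!is.null(helices)) {
    stopifnot(length(helices) == 2)
    ang <- function(s) {
      inter_helix_angle(helix_axis(s, helices[[1]]),
                        helix_axis(s, helices[[2]]))
    }
    aa <- ang(a)
    ab <- ang(b)
    helix_angles <- list(a = aa, b = ab,
                         change = ab$signed_angle - aa$signed_angle)
  }
  site_res <- NULL
  if (!is.null(site)) {
    site_res <- site_displacement(a, b, align_on = domains[[align_on]],
                                  site = site, normal = normal)
  }
  report <- list(dihedral_difference = dd, domain_rmsd = domain_rmsd,
                 screw = screw, helix_angles = helix_angles,
                 site = site_res)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(dd, file.path(out_dir, "dihedral_differences.csv"),
                     row.names = FALSE)
    utils::write.csv(domain_rmsd, file.path(out_dir, "domain_rmsd.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(screw = screw, helix_angles = helix_angles,
           site = site_res[c("total", "along_normal")],
           labels = c(a = a$label, b = b$label)),
      file.path(out_dir, "structure_report.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' Packaged UraA domain selections (reconstruction)
#'
#' Loads the shipped scaffold/transport-domain and helix selections for
#' UraA-family comparisons. The residue ranges are a reconstruction
#' assembled from the published UraA topology (scaffold: TM5-7 + TM12-14;
#' transport: TM1-4 + TM8-11), not an authoritative definition, and are
#' meant to be edited by the user.
#'
#' @return named list of selection strings plus a `note` field.
#' @export
uraa_domain_selections <- function() {
  path <- system.file("extdata", "uraa_domains_synthetic.json",
                      package = "hdxelevator")
  jsonlite::read_json(path, simplifyVector = TRUE)
}
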