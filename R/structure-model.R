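#' Atomic structure model
#'
#' A light container for atomic coordinates used by all geometry operations:
#' a tibble of atoms with chain, residue number, residue name, atom name and
#' Cartesian coordinates in Angstrom, plus a source label. Waters and
#' heteroatoms are excluded at read time unless requested; where alternate
#' conformations exist only the highest-occupancy one is kept.
#'
#' @param atoms data frame with columns `chain`, `resno`, `resname`, `elety`
#'   (atom name), `x`, `y`, `z` and optionally `element`, `occ`, `b`.
#' @param label character source label (e.g. a state or accession name).
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, label = "structure") {
  atoms <- tibble::as_tibble(atoms)
  req <- c("chain", "resno", "resname", "elety", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0) {
    abort_hdx("atoms is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort_hdx("non-finite coordinates in structure")
  }
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key)) {
    abort_hdx("duplicate (chain, resno, atom name) keys: ",
              paste(utils::head(key[duplicated(key)], 3), collapse = "; "))
  }
  if (!"element" %in% names(atoms)) {
    atoms$element <- guess_element(atoms$elety)
  }
  structure(list(atoms = atoms, label = label), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s: %d atoms, %d residues, chains %s\n",
              x$label, nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain", "resno")])),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

# element from PDB atom name: leading digits stripped, first letter
guess_element <- function(elety) {
  e <- sub("^[0-9]+", "", elety)
  substr(e, 1, 1)
}

#' Read a structure from PDB or mmCIF
#'
#' Parses coordinates with bio3d and normalises them into a
#' [structure_model()]. Altloc conflicts are resolved to the
#' highest-occupancy conformer; waters are always dropped; other
#' heteroatoms are dropped unless `keep_hetero = TRUE`.
#'
#' @param path PDB (`.pdb`, `.ent`) or mmCIF (`.cif`) file.
#' @param label source label; defaults to the file name.
#' @param keep_hetero keep non-water HETATM records (default FALSE).
#' @return a `structure_model`.
#' @export
read_structure <- function(path, label = NULL, keep_hetero = FALSE) {
  if (!file.exists(path)) abort_hdx("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$resid != "HOH" & at$resid != "WAT", , drop = FALSE]
  if (!keep_hetero) at <- at[at$type == "ATOM", , drop = FALSE]
  at$chain[is.na(at$chain)] <- "A"
  at$o[is.na(at$o)] <- 1
  # altloc: keep the highest-occupancy record per (chain, resno, atom name)
  key <- paste(at$chain, at$resno, at$elety)
  at$.idx <- seq_len(nrow(at))
  at <- at[order(key, -at$o), , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$elety)), , drop = FALSE]
  at <- at[order(at$.idx), , drop = FALSE]
  structure_model(
    tibble::tibble(chain = at$chain, resno = at$resno, resname = at$resid,
                   elety = at$elety, x = at$x, y = at$y, z = at$z,
                   element = if (!is.null(at$elesy) && !all(is.na(at$elesy)))
                     ifelse(is.na(at$elesy) | at$elesy == "",
                            guess_element(at$elety), at$elesy)
                   else guess_element(at$elety),
                   occ = at$o, b = at$b),
    label = label %||% basename(path)
  )
}

#' Write a structure as a PDB file
#'
#' Fixed-width standard ATOM records via bio3d.
#'
#' @param x a `structure_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "structure_model"))
  a <- x$atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno, resid = a$resname,
                   eleno = seq_len(nrow(a)), elety = a$elety, chain = a$chain,
                   o = if ("occ" %in% names(a)) a$occ else rep(1, nrow(a)),
                   b = if ("b" %in% names(a)) a$b else rep(0, nrow(a)),
                   elesy = a$element)
  invisible(path)
}

#' Parse a residue-selection string
#'
#' Selections use the form `"A:15-40,A:300-335,B:1-120"`: comma-separated
#' `chain:start-end` ranges, 1-based and inclusive; `chain:n` selects a
#' single residue and a bare `chain` selects the whole chain.
#'
#' @param x selection string, or a data frame already holding columns
#'   `chain`, `start`, `end` (passed through).
#' @return tibble with columns `chain`, `start`, `end` (`NA` end = open).
#' @export
parse_selection <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("chain", "start", "end") %in% names(x)))
    return(tibble::as_tibble(x[, c("chain", "start", "end")]))
  }
  stopifnot(is.character(x), length(x) == 1, nzchar(x))
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  out <- lapply(parts, function(p) {
    bits <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (length(bits) == 1) {
      return(tibble::tibble(chain = bits[1], start = NA_integer_,
                            end = NA_integer_))
    }
    rng <- strsplit(bits[2], "-", fixed = TRUE)[[1]]
    s <- as.integer(rng[1])
    e <- if (length(rng) > 1) as.integer(rng[2]) else s
    if (is.na(s) || is.na(e) || e < s) {
      abort_hdx("malformed selection range: ", p)
    }
    tibble::tibble(chain = bits[1], start = s, end = e)
  })
  dplyr::bind_rows(out)
}

#' Resolve a selection against a structure
#'
#' @param x a `structure_model`.
#' @param selection selection string or tibble from [parse_selection()];
#'   `NULL` selects everything.
#' @param atoms atom-name filter (default `"CA"`); `NULL` keeps all atoms.
#' @param require_atoms error if the selection resolves to no atoms
#'   (default TRUE).
#' @return tibble of selected atom rows, in chain/residue order.
#' @export
resolve_selection <- function(x, selection = NULL, atoms = "CA",
                              require_atoms = TRUE) {
  stopifnot(inherits(x, "structure_model"))
  at <- x$atoms
  if (!is.null(atoms)) at <- at[at$elety %in% atoms, , drop = FALSE]
  if (!is.null(selection)) {
    sel <- parse_selection(selection)
    keep <- rep(FALSE, nrow(at))
    for (i in seq_len(nrow(sel))) {
      hit <- at$chain == sel$chain[i]
      if (!is.na(sel$start[i])) {
        hit <- hit & at$resno >= sel$start[i] & at$resno <= sel$end[i]
      }
      keep <- keep | hit
    }
    at <- at[keep, , drop = FALSE]
  }
  if (require_atoms && nrow(at) == 0) {
    abort_hdx("selection resolves to no atoms")
  }
  at
}

# internal: pair atoms of two structures by (chain, resno, elety)
pair_atoms <- function(mobile, reference, selection = NULL, atoms = "CA") {
  am <- resolve_selection(mobile, selection, atoms)
  ar <- resolve_selection(reference, selection, atoms)
  km <- paste(am$chain, am$resno, am$elety)
  kr <- paste(ar$chain, ar$resno, ar$elety)
  common <- intersect(km, kr)
  if (length(common) < 3) {
    abort_hdx("fewer than 3 paired atoms between structures")
  }
  list(mobile = as.matrix(am[match(common, km), c("x", "y", "z")]),
       reference = as.matrix(ar[match(common, kr), c("x", "y", "z")]),
       keys = common)
}
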