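#' Wrap angles into (-180, 180]
#'
#' Maps any angle in degrees onto the principal interval used for backbone
#' torsions. The right-closed convention means 180 stays 180 and -180 maps
#' to 180.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in (-180, 180].
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  # floor() puts exact -180 at the left edge; the convention is right-closed
  w[w <= -180] <- 180
  w
}

#' Final concentration after a dilution
#'
#' Plain conservation-of-mass dilution arithmetic, as used when diluting a
#' protein stock into equilibration or labelling buffer.
#'
#' @param stock_conc concentration of the stock (any unit, e.g. mg/mL).
#' @param v_stock volume of stock added.
#' @param v_diluent volume of diluent it is added to (same unit as `v_stock`).
#' @return final concentration in the units of `stock_conc`.
#' @examples
#' dilute_concentration(0.675, 4, 56) # 0.045 mg/mL
#' @export
dilute_concentration <- function(stock_conc, v_stock, v_diluent) {
  stopifnot(stock_conc >= 0, v_stock > 0, v_diluent >= 0)
  stock_conc * v_stock / (v_stock + v_diluent)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: stop with a consistent prefix
abort_hdx <- function(...) stop(..., call. = FALSE)

# internal: checked seed handling; every stochastic generator goes through this
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# internal: 20 standard amino acids, one-letter
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

# average residue masses (Da), used to place undeuterated peptide centroids
AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, Q = 128.1307, E = 129.1155, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

WATER_MASS <- 18.0153

check_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) >= 1)
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(res), AA1)
  if (length(bad) > 0) {
    abort_hdx("non-standard residue code(s): ", paste(bad, collapse = ", "))
  }
  res
}

#' Generate a random protein sequence
#'
#' Draws residues with uniform frequencies over the 20 standard amino acids
#' except proline, whose frequency is set separately (prolines carry no
#' exchangeable amide and are handled specially throughout).
#'
#' @param n sequence length.
#' @param prolines approximate proline frequency (default 0.04, close to
#'   natural abundance).
#' @param seed integer seed.
#' @return single character string of length `n`.
#' @export
random_protein <- function(n, prolines = 0.04, seed = NULL) {
  stopifnot(n >= 1, prolines >= 0, prolines < 1)
  with_seed(seed, {
    p <- rep((1 - prolines) / 19, 20)
    p[AA1 == "P"] <- prolines
    paste(sample(AA1, n, replace = TRUE, prob = p), collapse = "")
  })
}
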