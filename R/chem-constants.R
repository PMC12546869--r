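#' Monoisotopic chemical constants
#'
#' Returns the table of monoisotopic constants used by all mass arithmetic:
#' residue masses for the 20 standard amino acids, the mass of water (added
#' once per peptide), the proton mass (added once per charge), and the
#' modification mass shifts. All values are full-precision monoisotopic
#' shifts in Daltons; abbreviated display labels such as "Pr/56.03" used in
#' peptidoform notation are cosmetic and never enter a mass computation.
#'
#' The modification table covers the derivatization and labelling chemistry
#' of a propionylation/SILAC workflow: propionyl (+56.026215), mono-/di-/
#' tri-methyl, the composite propionyl-methyl carried by a derivatized
#' monomethyl-lysine (one residue, one key, mass = sum of the two shifts),
#' phospho, carbamidomethyl, oxidation, N-terminal acetyl, and the heavy
#' labels Arg10, Lys8 and Pro6.
#'
#' @param overrides optional named numeric vector (or path to a plain-text
#'   `key = value` file, see [read_constants()]) replacing or adding
#'   modification masses by name.
#' @return a list of class `chemical_constants` with elements
#'   `residue_masses`, `water_mass`, `proton_mass`, `modification_masses`.
#' @examples
#' cc <- chemical_constants()
#' cc$modification_masses[["propionyl"]]
#' @export
chemical_constants <- function(overrides = NULL) {
  residue_masses <- c(
    G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
    N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
    E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
    R = 156.10111, Y = 163.06333, W = 186.07931
  )
  modification_masses <- c(
    "propionyl"        = 56.026215,
    "methyl"           = 14.015650,
    "dimethyl"         = 28.031300,
    "trimethyl"        = 42.046950,
    "propionyl-methyl" = 70.041865,  # derivatized monomethyl-lysine
    "phospho"          = 79.966331,
    "carbamidomethyl"  = 57.021464,
    "oxidation"        = 15.994915,
    "acetyl-Nterm"     = 42.010565,
    "Arg10"            = 10.008269,
    "Lys8"             = 8.014199,
    "Pro6"             = 6.013809
  )
  if (!is.null(overrides)) {
    if (is.character(overrides) && length(overrides) == 1L) {
      overrides <- read_constants(overrides)
    }
    stopifnot(is.numeric(overrides), !is.null(names(overrides)))
    modification_masses[names(overrides)] <- overrides
  }
  structure(
    list(
      residue_masses = residue_masses,
      water_mass = 18.010565,
      proton_mass = 1.007276,
      modification_masses = modification_masses
    ),
    class = "chemical_constants"
  )
}

#' Read modification-mass overrides from a plain-text config
#'
#' Parses a `key = value` file (one entry per line, `#` comments allowed)
#' into a named numeric vector suitable for [chemical_constants()].
#'
#' @param path file path.
#' @return named numeric vector of mass shifts in Da.
#' @export
read_constants <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(stats::setNames(numeric(0), character(0)))
  parts <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    stop("malformed constants line: ", lines[bad][1L])
  }
  keys <- trimws(vapply(parts, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(parts, `[[`, "", 2L))))
  if (anyNA(vals)) {
    stop("non-numeric constant value for key: ", keys[is.na(vals)][1L])
  }
  stats::setNames(vals, keys)
}
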