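#' Neutral monoisotopic mass of a modified peptide
#'
#' Sum of residue masses plus one water plus all modification shifts.
#'
#' @param p a [modified_peptide()].
#' @param constants a [chemical_constants()] object.
#' @return neutral monoisotopic mass in Da.
#' @examples
#' neutral_mass(modified_peptide("G"))  # 75.03203
#' @export
neutral_mass <- function(p, constants = chemical_constants()) {
  stopifnot(inherits(p, "modified_peptide"))
  residues <- strsplit(p$sequence, "")[[1L]]
  rm <- constants$residue_masses[residues]
  if (anyNA(rm)) {
    stop("unknown residue letter: '", residues[is.na(rm)][1L], "'")
  }
  mod_mass <- 0
  if (nrow(p$mods) > 0L) {
    mm <- constants$modification_masses[p$mods$name]
    if (anyNA(mm)) {
      stop("unknown modification name: '", p$mods$name[is.na(mm)][1L], "'")
    }
    mod_mass <- sum(mm)
  }
  sum(rm) + constants$water_mass + mod_mass
}

#' Precursor m/z of a modified peptide at a given charge
#'
#' `(neutral mass + charge * proton mass) / charge`.
#'
#' @param p a [modified_peptide()].
#' @param charge positive integer charge state.
#' @param constants a [chemical_constants()] object.
#' @return m/z value (full precision; round on output only).
#' @examples
#' p <- modified_peptide("KSAPSTGGVKKPHR", c(1, 10, 11),
#'                       rep("propionyl", 3))
#' precursor_mz(p, 2)  # 809.45720 (2+), the unmethylated H3 27-40 target
#' @export
precursor_mz <- function(p, charge, constants = chemical_constants()) {
  stopifnot(length(charge) == 1L, is.numeric(charge))
  if (charge < 1 || charge != round(charge)) {
    stop("charge must be a positive integer, got ", charge)
  }
  (neutral_mass(p, constants) + charge * constants$proton_mass) / charge
}
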