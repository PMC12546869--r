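#' Tryptic digestion specification
#'
#' Cleavage rule dialect: cut C-terminal to K/R, never before proline, and
#' never after a lysine carrying one of the `blocked_lysine_mods` — chemical
#' derivatization (propionyl) and side-chain methylation abolish tryptic
#' cleavage at that lysine, which is what makes the derivatized H3 27-40
#' peptide KSAPSTGGVKKPHR a single product despite its internal lysines.
#'
#' @param enzyme only `"trypsin"` is supported.
#' @param max_missed_cleavages integer in 0..5; peptides with up to this many
#'   retained internal cleavage sites are emitted.
#' @param blocked_lysine_mods modification names that abolish cleavage after
#'   the modified lysine.
#' @return a list of class `digest_spec`.
#' @export
digest_spec <- function(enzyme = "trypsin", max_missed_cleavages = 2,
                        blocked_lysine_mods = c("propionyl",
                                                "propionyl-methyl",
                                                "methyl", "dimethyl",
                                                "trimethyl")) {
  if (!identical(enzyme, "trypsin")) {
    stop("unsupported enzyme: ", enzyme)
  }
  max_missed_cleavages <- as.integer(max_missed_cleavages)
  if (is.na(max_missed_cleavages) || max_missed_cleavages < 0L ||
      max_missed_cleavages > 5L) {
    stop("max_missed_cleavages must be in 0..5")
  }
  structure(list(enzyme = enzyme,
                 max_missed_cleavages = max_missed_cleavages,
                 blocked_lysine_mods = blocked_lysine_mods),
            class = "digest_spec")
}

#' In-silico tryptic digestion with cleavage-blocking modifications
#'
#' Cleaves `protein_sequence` under the rules of `spec` and returns every
#' peptide with 0 to `max_missed_cleavages` retained internal sites.
#' `fixed_mods` are given in 1-based protein coordinates and are remapped to
#' peptide coordinates on each product; a modification on a cleavage-site
#' lysine that is in `spec$blocked_lysine_mods` suppresses that cut. The set
#' of 0-missed-cleavage products concatenates exactly to the input.
#'
#' @param protein_sequence upper-case amino-acid string.
#' @param spec a [digest_spec()].
#' @param fixed_mods optional data frame with columns `position` (1-based
#'   protein coordinate) and `name`.
#' @return list of [modified_peptide()] objects, each carrying `start`,
#'   `end` (protein coordinates) and `missed` attributes.
#' @examples
#' vapply(digest("AKRPK", digest_spec(max_missed_cleavages = 0)),
#'        function(p) p$sequence, "")  # "AK", "RPK"
#' @export
digest <- function(protein_sequence, spec = digest_spec(),
                   fixed_mods = NULL) {
  stopifnot(is.character(protein_sequence), length(protein_sequence) == 1L)
  protein_sequence <- toupper(protein_sequence)
  if (!nzchar(protein_sequence)) stop("empty protein sequence")
  residues <- strsplit(protein_sequence, "")[[1L]]
  known <- names(chemical_constants()$residue_masses)
  if (any(!residues %in% known)) {
    stop("unknown residue letter: '",
         residues[!residues %in% known][1L], "'")
  }
  n <- length(residues)
  if (is.null(fixed_mods)) {
    fixed_mods <- data.frame(position = integer(0), name = character(0))
  }
  stopifnot(all(c("position", "name") %in% names(fixed_mods)))
  fixed_mods$position <- as.integer(fixed_mods$position)
  if (any(fixed_mods$position < 1L | fixed_mods$position > n)) {
    stop("fixed modification position outside protein")
  }

  mod_at <- function(i) {
    hit <- fixed_mods$name[fixed_mods$position == i]
    if (length(hit) == 0L) NA_character_ else hit[[1L]]
  }

  # cut points: after residue i
  cuts <- integer(0)
  for (i in seq_len(n - 1L)) {
    if (!residues[[i]] %in% c("K", "R")) next
    if (residues[[i + 1L]] == "P") next
    if (residues[[i]] == "K") {
      m <- mod_at(i)
      if (!is.na(m) && m %in% spec$blocked_lysine_mods) next
    }
    cuts <- c(cuts, i)
  }
  bounds <- c(0L, cuts, n)  # segment k spans bounds[k]+1 .. bounds[k+1]
  n_seg <- length(bounds) - 1L

  out <- list()
  for (k in seq_len(n_seg)) {
    for (mc in 0:spec$max_missed_cleavages) {
      k2 <- k + mc
      if (k2 > n_seg) break
      start <- bounds[[k]] + 1L
      end <- bounds[[k2 + 1L]]
      pep_seq <- substr(protein_sequence, start, end)
      in_pep <- fixed_mods$position >= start & fixed_mods$position <= end
      p <- modified_peptide(pep_seq,
                            positions = fixed_mods$position[in_pep] -
                              start + 1L,
                            names = fixed_mods$name[in_pep])
      p$start <- start
      p$end <- end
      p$missed <- mc
      out[[length(out) + 1L]] <- p
    }
  }
  out
}

#' Propionylate a peptide
#'
#' Models in-gel derivatization by propionic anhydride: every unmodified
#' lysine gains a propionyl group; monomethyl-lysine becomes the composite
#' propionyl-methyl (its epsilon-amine still carries a reactive proton);
#' di- and tri-methyl lysine and all other residues are left unchanged.
#' The peptide N-terminal alpha-amine is derivatized only when
#' `derivatize_nterm = TRUE` (a second, post-digestion round of
#' derivatization; the default models a single pre-digestion round).
#'
#' @param p a [modified_peptide()].
#' @param derivatize_nterm add an N-terminal propionyl group?
#' @return the derivatized [modified_peptide()].
#' @export
propionylate <- function(p, derivatize_nterm = FALSE) {
  .propionylate(p, derivatize_nterm = derivatize_nterm)
}

# internal variant with position exclusion, used by enumerate_methyl_forms
.propionylate <- function(p, derivatize_nterm = FALSE,
                          skip_positions = integer(0)) {
  stopifnot(inherits(p, "modified_peptide"))
  residues <- strsplit(p$sequence, "")[[1L]]
  skip <- as.character(skip_positions)
  for (i in seq_along(residues)) {
    if (residues[[i]] != "K" || as.character(i) %in% skip) next
    m <- .mod_name_at(p, i)
    if (is.na(m)) {
      p <- .set_mod(p, i, "propionyl")
    } else if (m == "methyl") {
      p <- .set_mod(p, i, "propionyl-methyl")
    }
  }
  if (derivatize_nterm && is.na(.mod_name_at(p, "N-term"))) {
    p <- .set_mod(p, "N-term", "propionyl")
  }
  p
}
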