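#' Enumerate methyl/derivatization forms of a histone lysine site
#'
#' For a propionylation workflow, the methylation states of one lysine map
#' to five chemical forms of the peptide: me0 carries a propionyl at the
#' site; me1 exists both underivatized (`me1_free`, monomethyl only) and
#' derivatized (`me1_prop`, composite propionyl-methyl); me2 and me3 are
#' not derivatizable and carry di-/tri-methyl only. All other lysines are
#' propionylated via [propionylate()].
#'
#' @param base a [modified_peptide()]; the residue at `site` must be K. Any
#'   modification already present at `site` is replaced.
#' @param site 1-based residue index of the monitored lysine.
#' @param derivatize_nterm passed through to the derivatization step.
#' @return named list of [modified_peptide()] objects with labels
#'   `me0`, `me1_free`, `me1_prop`, `me2`, `me3` (in that order).
#' @examples
#' forms <- enumerate_methyl_forms(modified_peptide("KSAPSTGGVKKPHR"), 10)
#' names(forms)
#' @export
enumerate_methyl_forms <- function(base, site, derivatize_nterm = FALSE) {
  stopifnot(inherits(base, "modified_peptide"))
  site <- as.integer(site)
  if (substr(base$sequence, site, site) != "K") {
    stop("site ", site, " is not a lysine (found '",
         substr(base$sequence, site, site), "')")
  }
  with_site <- function(mod, skip_site = FALSE) {
    p <- .set_mod(base, site, mod)
    .propionylate(p, derivatize_nterm = derivatize_nterm,
                  skip_positions = if (skip_site) site else integer(0))
  }
  list(
    me0      = with_site(NA_character_),       # site K -> propionyl
    me1_free = with_site("methyl", skip_site = TRUE),
    me1_prop = with_site("methyl"),            # converted to composite
    me2      = with_site("dimethyl"),
    me3      = with_site("trimethyl")
  )
}

#' Build a PRM inclusion list
#'
#' One target row per (form, charge), ordered form-major (as enumerated)
#' then by ascending charge.
#'
#' @param forms named list of [modified_peptide()] objects (names become the
#'   `label` column), e.g. from [enumerate_methyl_forms()].
#' @param charges integer vector of charge states (non-empty).
#' @param constants a [chemical_constants()] object.
#' @return data frame with columns `label`, `sequence`, `modifications`
#'   (peptidoform notation), `charge`, `mz`.
#' @examples
#' forms <- enumerate_methyl_forms(modified_peptide("KSAPSTGGVKKPHR"), 10)
#' build_inclusion_list(forms, charges = c(2, 3))
#' @export
build_inclusion_list <- function(forms, charges = c(2, 3),
                                 constants = chemical_constants()) {
  if (length(charges) == 0L) stop("charges must be non-empty")
  if (is.null(names(forms)) || any(!nzchar(names(forms)))) {
    stop("forms must be a named list")
  }
  rows <- list()
  for (label in names(forms)) {
    p <- forms[[label]]
    for (z in sort(as.integer(charges))) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = label,
        sequence = p$sequence,
        modifications = render_modified_peptide(p, constants),
        charge = z,
        mz = precursor_mz(p, z, constants),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Default H3K36 PRM inclusion list
#'
#' The ten-target list for the derivatized H3 peptide 27-40
#' (KSAPSTGGVKKPHR, monitored lysine K36 = peptide position 10): five
#' chemical forms at charges 2+ and 3+. The N-terminal alpha-amine is left
#' underivatized by default (single pre-digestion derivatization round).
#'
#' @param charges charge states, default `c(2, 3)`.
#' @param derivatize_nterm include an N-terminal propionyl group?
#' @param constants a [chemical_constants()] object.
#' @return inclusion-list data frame, see [build_inclusion_list()].
#' @examples
#' h3k36_inclusion_list()
#' @export
h3k36_inclusion_list <- function(charges = c(2, 3),
                                 derivatize_nterm = FALSE,
                                 constants = chemical_constants()) {
  base <- modified_peptide("KSAPSTGGVKKPHR")
  forms <- enumerate_methyl_forms(base, 10L,
                                  derivatize_nterm = derivatize_nterm)
  build_inclusion_list(forms, charges = charges, constants = constants)
}

#' Write an inclusion list as CSV
#'
#' Vendor-neutral CSV with a header row, UTF-8, '.' decimal separator; m/z
#' printed to five decimal places.
#'
#' @param targets inclusion-list data frame from [build_inclusion_list()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_inclusion_list <- function(targets, path) {
  out <- targets
  out$mz <- sprintf("%.5f", out$mz)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
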