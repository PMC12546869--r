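#' Construct a modified peptide
#'
#' A `modified_peptide` is an upper-case amino-acid sequence plus a list of
#' positioned modifications. Positions are 1-based residue indices, or the
#' sentinels `"N-term"` / `"C-term"`. At most one side-chain modification is
#' allowed per position; chemistry that stacks two groups on one residue
#' (propionylated monomethyl-lysine) is represented by the single composite
#' key `"propionyl-methyl"`.
#'
#' @param sequence upper-case amino-acid string (standard 20 letters).
#' @param positions vector of modification positions (integers, or
#'   `"N-term"`/`"C-term"`), parallel to `names`.
#' @param names character vector of modification keys (see
#'   [chemical_constants()]).
#' @return an object of class `modified_peptide`.
#' @examples
#' modified_peptide("KSAPSTGGVKKPHR", c(1, 10, 11),
#'                  c("propionyl", "dimethyl", "propionyl"))
#' @export
modified_peptide <- function(sequence, positions = character(0),
                             names = character(0)) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty peptide sequence")
  residues <- strsplit(sequence, "")[[1L]]
  known <- base::names(chemical_constants()$residue_masses)
  bad <- setdiff(residues, known)
  if (length(bad) > 0L) {
    stop("unknown residue letter: ", bad[1L])
  }
  positions <- as.character(positions)
  names <- as.character(names)
  if (length(positions) != length(names)) {
    stop("positions and names must have equal length")
  }
  n <- nchar(sequence)
  numeric_pos <- suppressWarnings(as.integer(positions))
  is_term <- positions %in% c("N-term", "C-term")
  if (any(!is_term & (is.na(numeric_pos) | numeric_pos < 1L |
                        numeric_pos > n))) {
    stop("modification position out of range: ",
         positions[!is_term & (is.na(numeric_pos) | numeric_pos < 1L |
                                 numeric_pos > n)][1L])
  }
  if (anyDuplicated(positions)) {
    stop("more than one modification at position ",
         positions[duplicated(positions)][1L])
  }
  p <- structure(
    list(sequence = sequence,
         mods = data.frame(position = positions, name = names,
                           stringsAsFactors = FALSE)),
    class = "modified_peptide"
  )
  .canonicalize_mods(p)
}

# order mods N-term first, then residue index, then C-term
.canonicalize_mods <- function(p) {
  m <- p$mods
  if (nrow(m) > 0L) {
    key <- suppressWarnings(as.numeric(m$position))
    key[m$position == "N-term"] <- 0
    key[m$position == "C-term"] <- nchar(p$sequence) + 1
    m <- m[order(key), , drop = FALSE]
    rownames(m) <- NULL
    p$mods <- m
  }
  p
}

.mod_name_at <- function(p, position) {
  position <- as.character(position)
  hit <- p$mods$name[p$mods$position == position]
  if (length(hit) == 0L) NA_character_ else hit[[1L]]
}

.set_mod <- function(p, position, name) {
  position <- as.character(position)
  m <- p$mods[p$mods$position != position, , drop = FALSE]
  if (!is.na(name)) {
    m <- rbind(m, data.frame(position = position, name = name,
                             stringsAsFactors = FALSE))
  }
  p$mods <- m
  .canonicalize_mods(p)
}

#' @export
print.modified_peptide <- function(x, ...) {
  cat("<modified_peptide> ", render_modified_peptide(x), "\n", sep = "")
  invisible(x)
}

# notation dialect: display tag <-> canonical modification key
.tag_aliases <- c(
  "Pr"  = "propionyl",
  "Me"  = "methyl",
  "Di"  = "dimethyl",
  "Tri" = "trimethyl",
  "Ph"  = "phospho",
  "Cam" = "carbamidomethyl",
  "Ox"  = "oxidation",
  "Ac"  = "acetyl-Nterm"
)

.display_tags <- c(
  "propionyl"        = "Pr/56.03",
  "methyl"           = "Me/14.012",
  "dimethyl"         = "Di/28.03",
  "trimethyl"        = "Tri/42.05",
  "propionyl-methyl" = "Pr/56.03 + Me/14.012",
  "phospho"          = "Ph/79.966"
)

# resolve one parenthesized tag, e.g. "Pr/56.03 + Me/14.012"
.resolve_tag <- function(tag, constants) {
  parts <- trimws(strsplit(tag, "+", fixed = TRUE)[[1L]])
  keys <- vapply(parts, function(part) {
    nm <- trimws(strsplit(part, "/", fixed = TRUE)[[1L]][1L])
    if (nm %in% base::names(.tag_aliases)) {
      .tag_aliases[[nm]]
    } else if (nm %in% base::names(constants$modification_masses)) {
      nm
    } else {
      stop("unknown modification name: '", nm, "'")
    }
  }, "")
  key <- paste(keys, collapse = "-")
  if (!key %in% base::names(constants$modification_masses)) {
    stop("unknown modification name: '", key, "'")
  }
  key
}

#' Parse peptidoform notation
#'
#' Parses the compact peptidoform dialect in which each residue letter may be
#' followed by a parenthesized modification tag, e.g.
#' `"K(Pr/56.03)SAPSTGGVK(Di/28.03)K(Pr/56.03)PHR"`. A composite tag joins
#' two groups on one residue with `" + "`, e.g. `"K(Pr/56.03 + Me/14.012)"`
#' for a propionylated monomethyl-lysine. A tag before the first residue is
#' an N-terminal modification. The numeric part of a tag is informational
#' display text only; the mass is always looked up by name in `constants`.
#'
#' Grammar (EBNF):
#' ```
#' peptidoform = [ tag ] , { residue , [ tag ] } ;
#' residue     = "A" | ... | "Y" ;           (20 standard letters)
#' tag         = "(" , modpart , { " + " , modpart } , ")" ;
#' modpart     = name , [ "/" , number ] ;
#' ```
#'
#' @param notation peptidoform string.
#' @param constants a [chemical_constants()] object.
#' @return a [modified_peptide()].
#' @examples
#' parse_modified_peptide("K(Pr/56.03)SAPSTGGVK(Di/28.03)K(Pr/56.03)PHR")
#' @export
parse_modified_peptide <- function(notation,
                                   constants = chemical_constants()) {
  stopifnot(is.character(notation), length(notation) == 1L)
  chars <- strsplit(notation, "")[[1L]]
  residue_letters <- base::names(constants$residue_masses)
  seq_chars <- character(0)
  positions <- character(0)
  mod_names <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[[i]]
    if (ch == "(") {
      close <- NULL
      for (j in seq(i + 1L, length.out = max(0L, n - i))) {
        if (chars[[j]] == ")") { close <- j; break }
        if (chars[[j]] == "(") stop("unbalanced parentheses near position ", j)
      }
      if (is.null(close)) stop("unbalanced parentheses: missing ')'")
      tag <- paste(chars[seq(i + 1L, close - 1L)], collapse = "")
      key <- .resolve_tag(tag, constants)
      pos <- if (length(seq_chars) == 0L) "N-term"
             else as.character(length(seq_chars))
      if (pos %in% positions) {
        stop("more than one modification at position ", pos)
      }
      positions <- c(positions, pos)
      mod_names <- c(mod_names, key)
      i <- close + 1L
    } else if (ch == ")") {
      stop("unbalanced parentheses: unexpected ')' at position ", i)
    } else {
      if (!ch %in% residue_letters) {
        stop("unknown residue letter: '", ch, "'")
      }
      seq_chars <- c(seq_chars, ch)
      i <- i + 1L
    }
  }
  if (length(seq_chars) == 0L) stop("empty peptide sequence")
  modified_peptide(paste(seq_chars, collapse = ""), positions, mod_names)
}

#' Render a modified peptide to peptidoform notation
#'
#' Inverse of [parse_modified_peptide()]: produces the compact dialect with
#' display tags (`Pr/56.03`, `Me/14.012`, ...). For modification keys without
#' a canonical display tag the tag is `name/shift` with the shift printed to
#' three decimals. C-terminal modifications have no notation in this dialect
#' and are rejected.
#'
#' @param p a [modified_peptide()].
#' @param constants a [chemical_constants()] object (for tag mass display).
#' @return peptidoform string.
#' @export
render_modified_peptide <- function(p, constants = chemical_constants()) {
  stopifnot(inherits(p, "modified_peptide"))
  if ("C-term" %in% p$mods$position) {
    stop("C-terminal modifications have no peptidoform notation")
  }
  tag_for <- function(name) {
    if (name %in% base::names(.display_tags)) return(.display_tags[[name]])
    mass <- constants$modification_masses[[name]]
    if (is.null(mass)) stop("unknown modification name: '", name, "'")
    sprintf("%s/%.3f", name, mass)
  }
  residues <- strsplit(p$sequence, "")[[1L]]
  out <- character(0)
  nterm <- .mod_name_at(p, "N-term")
  if (!is.na(nterm)) out <- paste0("(", tag_for(nterm), ")")
  for (i in seq_along(residues)) {
    out <- c(out, residues[[i]])
    nm <- .mod_name_at(p, i)
    if (!is.na(nm)) out <- c(out, paste0("(", tag_for(nm), ")"))
  }
  paste(out, collapse = "")
}
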