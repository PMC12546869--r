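#' Read protein sequences from FASTA
#'
#' Identifiers are the first whitespace-delimited token of each header;
#' sequences are upper-cased. Duplicate identifiers are an error; an empty
#' file yields an empty table with a warning.
#'
#' @param path FASTA file path.
#' @return data frame with columns `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L ||
      length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
    warning("empty FASTA file: ", path)
    return(data.frame(id = character(0), sequence = character(0)))
  }
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  }
  data.frame(id = ids, sequence = toupper(as.character(aa)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# delimiter by extension: .csv comma, anything else tab
.read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

# rename file columns to the internal schema via a profile mapping
.apply_profile <- function(x, profile, profiles, what) {
  if (is.character(profile) && length(profile) == 1L) {
    if (!profile %in% names(profiles)) {
      stop("unknown ", what, " reader profile: ", profile)
    }
    profile <- profiles[[profile]]
  }
  missing_cols <- setdiff(unname(profile), names(x))
  if (length(missing_cols) > 0L) {
    stop("input lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- x
  names(out)[match(unname(profile), names(x))] <- names(profile)
  out
}

#' Read an XIC area table
#'
#' Reads a CSV/TSV of integrated peak areas into the internal schema
#' (`group_id`, `form_id`, `n_phospho`, `site_labels`, `area`, `sample`,
#' `replicate`). The `"skyline"` profile maps a Skyline-style peptide
#' report (`Peptide Group`, `Peptide Modified Sequence`, `Total Area`,
#' `Condition`, `BioReplicate`, ...); pass a named character vector
#' (internal = file column) for other dialects.
#'
#' @param path file path (`.csv` comma-, otherwise tab-delimited).
#' @param profile `"default"`, `"skyline"`, or a named mapping.
#' @return data frame in the internal XIC schema.
#' @export
read_xic_table <- function(path, profile = "default") {
  profiles <- list(
    default = c(group_id = "group_id", form_id = "form_id",
                n_phospho = "n_phospho", site_labels = "site_labels",
                area = "area", sample = "sample",
                replicate = "replicate"),
    skyline = c(group_id = "Peptide Group",
                form_id = "Peptide Modified Sequence",
                n_phospho = "Phospho Count", site_labels = "Site Labels",
                area = "Total Area", sample = "Condition",
                replicate = "BioReplicate")
  )
  x <- .apply_profile(.read_delim_auto(path), profile, profiles, "XIC")
  x$area <- as.numeric(x$area)
  x$n_phospho <- as.integer(x$n_phospho)
  x$site_labels[is.na(x$site_labels)] <- ""
  x
}

#' Read a SILAC protein-level report
#'
#' Internal schema: `protein_id`, `replicate_id`, `orientation`,
#' `median_log2_hl`, `n_peptides`, `is_contaminant`, `is_decoy`. The
#' `"fragpipe"` profile maps a FragPipe-style combined-protein export
#' (`Protein ID`, `Median Log2 Ratio HL`, `Combined Total Peptides`, ...);
#' contaminant/decoy flags, if absent, are derived from identifier prefixes
#' via [flag_contaminants()].
#'
#' @param path file path.
#' @param profile `"default"`, `"fragpipe"`, or a named mapping.
#' @param contaminant_prefix,decoy_prefix used when flag columns are absent.
#' @return data frame in the internal SILAC schema.
#' @export
read_silac_table <- function(path, profile = "default",
                             contaminant_prefix = "contam_",
                             decoy_prefix = "rev_") {
  profiles <- list(
    default = c(protein_id = "protein_id", replicate_id = "replicate_id",
                orientation = "orientation",
                median_log2_hl = "median_log2_hl",
                n_peptides = "n_peptides"),
    fragpipe = c(protein_id = "Protein ID",
                 replicate_id = "Experiment",
                 orientation = "Label Orientation",
                 median_log2_hl = "Median Log2 Ratio HL",
                 n_peptides = "Combined Total Peptides")
  )
  x <- .apply_profile(.read_delim_auto(path), profile, profiles, "SILAC")
  x$median_log2_hl <- as.numeric(x$median_log2_hl)
  x$n_peptides <- as.integer(x$n_peptides)
  if (!all(c("is_contaminant", "is_decoy") %in% names(x))) {
    flags <- flag_contaminants(x$protein_id, contaminant_prefix,
                               decoy_prefix)
    x$is_contaminant <- flags$is_contaminant
    x$is_decoy <- flags$is_decoy
  } else {
    x$is_contaminant <- as.logical(x$is_contaminant)
    x$is_decoy <- as.logical(x$is_decoy)
  }
  x
}

#' Read a plate-reader growth table
#'
#' The `"default"` profile expects the long internal schema (`time_min`,
#' `od600`, `well`, `strain`, `condition`, `replicate`). The `"wide"`
#' profile expects the common plate-reader export with a `time_min` column
#' followed by one column per well, plus a separate `layout` table mapping
#' wells to strain/condition/replicate.
#'
#' @param path file path.
#' @param profile `"default"` or `"wide"`.
#' @param layout for `"wide"`: data frame (or path) with columns `well`,
#'   `strain`, `condition`, `replicate`.
#' @return long-format data frame for [fit_doubling_times()].
#' @export
read_growth_table <- function(path, profile = "default", layout = NULL) {
  x <- .read_delim_auto(path)
  if (identical(profile, "default")) {
    needed <- c("time_min", "od600", "well", "strain", "condition",
                "replicate")
    missing_cols <- setdiff(needed, names(x))
    if (length(missing_cols) > 0L) {
      stop("input lacks column(s): ", paste(missing_cols, collapse = ", "))
    }
    return(x)
  }
  if (!identical(profile, "wide")) {
    stop("unknown growth reader profile: ", profile)
  }
  if (is.character(layout)) layout <- .read_delim_auto(layout)
  if (is.null(layout)) stop("profile 'wide' requires a plate layout")
  stopifnot(all(c("well", "strain", "condition", "replicate") %in%
                  names(layout)))
  wells <- setdiff(names(x), "time_min")
  long <- do.call(rbind, lapply(wells, function(w) {
    data.frame(time_min = x$time_min, od600 = as.numeric(x[[w]]),
               well = w, stringsAsFactors = FALSE)
  }))
  merge(long, layout, by = "well", sort = FALSE)
}

#' Read a differential-expression results table
#'
#' Internal schema: `gene`, `log2_fc`, `adj_p`. The `"deseq2"` profile maps
#' a DESeq2-style results export (`gene`, `log2FoldChange`, `padj`).
#'
#' @param path file path.
#' @param profile `"default"`, `"deseq2"`, or a named mapping.
#' @return data frame for [classify_de()].
#' @export
read_de_table <- function(path, profile = "default") {
  profiles <- list(
    default = c(gene = "gene", log2_fc = "log2_fc", adj_p = "adj_p"),
    deseq2 = c(gene = "gene", log2_fc = "log2FoldChange", adj_p = "padj")
  )
  x <- .apply_profile(.read_delim_auto(path), profile, profiles, "DE")
  x$log2_fc <- as.numeric(x$log2_fc)
  x$adj_p <- as.numeric(x$adj_p)
  x
}

#' Read a gene-to-term annotation table
#'
#' Two-column tab- or comma-delimited gene/term mapping.
#'
#' @param path file path.
#' @return data frame with columns `gene`, `term`.
#' @export
read_annotations <- function(path) {
  x <- .read_delim_auto(path)
  if (!all(c("gene", "term") %in% names(x))) {
    if (ncol(x) >= 2L) {
      names(x)[1:2] <- c("gene", "term")
    } else {
      stop("annotation table needs columns gene, term")
    }
  }
  x[c("gene", "term")]
}
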