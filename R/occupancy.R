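#' Phosphosite occupancy from XIC areas
#'
#' Computes relative phosphorylation per quantification group, sample and
#' replicate from integrated extracted-ion-chromatogram areas. A
#' quantification group shares one backbone sequence and missed-cleavage
#' form; missed-cleavage variants are separate groups and are never pooled.
#'
#' Rules:
#' * a group with a single phospho form: `area(phospho) /
#'   (area(phospho) + area(unmodified))`;
#' * a group with several distinct singly-phosphorylated forms: each form's
#'   fraction uses the shared denominator `area(unmodified) + sum of all
#'   singly-phosphorylated areas`;
#' * co-eluting or non-localizable forms arrive as one row whose
#'   `site_labels` is the union of candidate sites and are reported as one
#'   result;
#' * multiply-phosphorylated forms (`n_phospho >= 2`) are excluded from the
#'   singly-phosphorylated denominator and reported as their own pooled form
#'   (`form_class = "multi"`) against the unmodified baseline;
#' * if every area in a group is zero the fraction is `NA` (absence of
#'   signal is not evidence of zero occupancy).
#'
#' @param records data frame with columns `group_id`, `form_id`,
#'   `n_phospho` (0 = unmodified, 1 = singly, >=2 = multiply
#'   phosphorylated), `site_labels` (semicolon-separated site names, empty
#'   for the unmodified form), `area`, `sample`, `replicate`.
#' @return tidy data frame: `group_id`, `sample`, `replicate`, `form_id`,
#'   `site_labels`, `form_class` (`"single"` or `"multi"`), `fraction`.
#' @examples
#' x <- data.frame(group_id = "g", form_id = c("u", "pA", "pB"),
#'                 n_phospho = c(0, 1, 1), site_labels = c("", "S1", "S2"),
#'                 area = c(60, 30, 10), sample = "ctrl", replicate = 1)
#' phospho_occupancy(x)  # fractions 0.30 and 0.10
#' @export
phospho_occupancy <- function(records) {
  .check_xic(records, c("group_id", "form_id", "n_phospho", "site_labels",
                        "area", "sample", "replicate"))
  key <- interaction(records$group_id, records$sample, records$replicate,
                     drop = TRUE)
  out <- lapply(split(records, key), .phospho_one)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.phospho_one <- function(g) {
  unmod <- g[g$n_phospho == 0, , drop = FALSE]
  if (nrow(unmod) == 0L) {
    stop("group '", g$group_id[[1L]], "' has no unmodified form")
  }
  if (nrow(unmod) > 1L) {
    stop("group '", g$group_id[[1L]], "' has more than one unmodified form")
  }
  singly <- g[g$n_phospho == 1, , drop = FALSE]
  multi <- g[g$n_phospho >= 2, , drop = FALSE]
  base <- data.frame(group_id = g$group_id[[1L]], sample = g$sample[[1L]],
                     replicate = g$replicate[[1L]],
                     stringsAsFactors = FALSE)
  rows <- list()
  denom1 <- unmod$area + sum(singly$area)
  for (i in seq_len(nrow(singly))) {
    frac <- if (denom1 > 0) singly$area[[i]] / denom1 else NA_real_
    rows[[length(rows) + 1L]] <- cbind(base, data.frame(
      form_id = singly$form_id[[i]], site_labels = singly$site_labels[[i]],
      form_class = "single", fraction = frac, stringsAsFactors = FALSE))
  }
  if (nrow(multi) > 0L) {
    denom2 <- unmod$area + sum(multi$area)
    frac <- if (denom2 > 0) sum(multi$area) / denom2 else NA_real_
    sites <- sort(unique(unlist(strsplit(multi$site_labels, ";",
                                         fixed = TRUE))))
    rows[[length(rows) + 1L]] <- cbind(base, data.frame(
      form_id = paste(sort(multi$form_id), collapse = "+"),
      site_labels = paste(sites, collapse = ";"),
      form_class = "multi", fraction = frac, stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

.check_xic <- function(x, cols) {
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(x$area < 0)) stop("negative XIC area")
  key <- interaction(x$group_id, x$form_id, x$sample, x$replicate,
                     drop = TRUE)
  if (anyDuplicated(key)) {
    stop("duplicate (group_id, form_id, sample, replicate) record")
  }
  invisible(x)
}

#' H3K36 methyl-state stoichiometry from XIC areas
#'
#' The relative amount of each methylation state is its area over the summed
#' area of all five chemical forms; the two me1 forms (underivatized
#' monomethyl and propionyl-methyl) are summed into one me1 state.
#' Quantification uses triply charged areas by default; set
#' `include_charge2 = TRUE` to also sum 2+ areas when a `charge` column is
#' present.
#'
#' @param records data frame with columns `form_id` (one of `me0`,
#'   `me1_free`, `me1_prop`, `me2`, `me3`), `area`, `sample`, `replicate`,
#'   and optionally `charge`.
#' @param include_charge2 also include doubly charged areas?
#' @return tidy data frame: `sample`, `replicate`, `state` (`me0`..`me3`),
#'   `fraction`. All-zero replicates yield `NA` fractions.
#' @examples
#' x <- data.frame(form_id = c("me0", "me1_free", "me1_prop", "me2", "me3"),
#'                 area = c(70, 10, 10, 5, 5), sample = "wt", replicate = 1)
#' methyl_stoichiometry(x)  # me1 = 0.20
#' @export
methyl_stoichiometry <- function(records, include_charge2 = FALSE) {
  forms <- c("me0", "me1_free", "me1_prop", "me2", "me3")
  needed <- c("form_id", "area", "sample", "replicate")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(records$area < 0)) stop("negative XIC area")
  if ("charge" %in% names(records)) {
    keep <- if (include_charge2) records$charge %in% c(2, 3)
            else records$charge == 3
    records <- records[keep, , drop = FALSE]
  }
  bad <- setdiff(unique(records$form_id), forms)
  if (length(bad) > 0L) stop("unknown chemical form: ", bad[[1L]])
  key <- interaction(records$sample, records$replicate, drop = TRUE)
  out <- lapply(split(records, key), function(g) {
    present <- forms %in% g$form_id
    if (!all(present)) {
      stop("replicate ", g$replicate[[1L]], " of sample '", g$sample[[1L]],
           "' is missing form(s): ",
           paste(forms[!present], collapse = ", "))
    }
    areas <- vapply(forms, function(f) sum(g$area[g$form_id == f]), 0)
    total <- sum(areas)
    state_area <- c(me0 = areas[["me0"]],
                    me1 = areas[["me1_free"]] + areas[["me1_prop"]],
                    me2 = areas[["me2"]], me3 = areas[["me3"]])
    frac <- if (total > 0) state_area / total
            else rep(NA_real_, 4L)
    data.frame(sample = g$sample[[1L]], replicate = g$replicate[[1L]],
               state = names(state_area), fraction = unname(frac),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize occupancy or stoichiometry across replicates
#'
#' Mean, standard deviation and replicate count per grouping cell, with
#' `NA` (flagged-missing) replicates excluded from `n`. The standard
#' deviation is `NA` when a single replicate remains.
#'
#' @param results tidy data frame with a `fraction` column and a
#'   `replicate` column, e.g. from [phospho_occupancy()] or
#'   [methyl_stoichiometry()].
#' @param by character vector of grouping columns; defaults to every column
#'   except `fraction` and `replicate`.
#' @return data frame with the grouping columns plus `mean`, `sd`, `n`.
#' @export
summarize_occupancy <- function(results,
                                by = setdiff(names(results),
                                             c("fraction", "replicate"))) {
  stopifnot("fraction" %in% names(results), length(by) > 0L)
  key <- interaction(results[by], drop = TRUE)
  out <- lapply(split(results, key), function(g) {
    v <- g$fraction[!is.na(g$fraction)]
    cbind(g[1L, by, drop = FALSE],
          data.frame(mean = if (length(v) > 0L) mean(v) else NA_real_,
                     sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
                     n = length(v)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
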