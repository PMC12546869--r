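#' Filter a SILAC protein-level report
#'
#' Applies the identification filters of a label-swap experiment: removes
#' contaminant and decoy entries, removes any protein quantified by fewer
#' than two peptides in either replicate, and retains only proteins with a
#' ratio in both replicates.
#'
#' @param summaries data frame with columns `protein_id`, `replicate_id`,
#'   `orientation` (`"forward"` or `"reverse"`), `median_log2_hl`,
#'   `n_peptides`, `is_contaminant`, `is_decoy`.
#' @param verbose log row counts in/removed/out via `message()`?
#' @return the filtered data frame.
#' @export
filter_proteins <- function(summaries, verbose = FALSE) {
  needed <- c("protein_id", "replicate_id", "orientation",
              "median_log2_hl", "n_peptides", "is_contaminant", "is_decoy")
  missing_cols <- setdiff(needed, names(summaries))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(summaries$orientation %in% c("forward", "reverse"))) {
    stop("orientation must be 'forward' or 'reverse'")
  }
  n_in <- nrow(summaries)
  x <- summaries[!summaries$is_contaminant & !summaries$is_decoy, ,
                 drop = FALSE]
  # a <2-peptide observation in either replicate disqualifies the protein
  low <- unique(x$protein_id[x$n_peptides < 2])
  x <- x[!x$protein_id %in% low, , drop = FALSE]
  n_reps <- length(unique(summaries$replicate_id))
  tab <- table(x$protein_id)
  both <- names(tab)[tab == n_reps]
  x <- x[x$protein_id %in% both, , drop = FALSE]
  if (verbose) {
    message("filter_proteins: ", n_in, " rows in, ", n_in - nrow(x),
            " removed, ", nrow(x), " out")
  }
  rownames(x) <- NULL
  x
}

#' Flag contaminants and decoys by identifier prefix
#'
#' @param protein_id character vector of protein identifiers.
#' @param contaminant_prefix,decoy_prefix identifier prefixes (search-engine
#'   dialects vary; defaults `"contam_"` and `"rev_"`).
#' @return data frame with logical columns `is_contaminant`, `is_decoy`.
#' @export
flag_contaminants <- function(protein_id, contaminant_prefix = "contam_",
                              decoy_prefix = "rev_") {
  data.frame(
    is_contaminant = startsWith(protein_id, contaminant_prefix),
    is_decoy = startsWith(protein_id, decoy_prefix)
  )
}

#' Normalize and orient label-swap log2 ratios
#'
#' Per replicate, median-centres the log2 heavy/light ratios (removing the
#' global mixing offset), then multiplies reverse-orientation replicates
#' (wildtype heavy) by -1 so every value is on the mutant:wildtype scale.
#'
#' @param summaries filtered data frame from [filter_proteins()].
#' @return the input with an added `oriented_log2` column.
#' @export
normalize_and_orient <- function(summaries) {
  x <- summaries
  x$oriented_log2 <- NA_real_
  for (rep_id in unique(x$replicate_id)) {
    idx <- x$replicate_id == rep_id
    if (!any(idx)) next
    v <- x$median_log2_hl[idx]
    if (all(is.na(v))) stop("replicate ", rep_id, " has no retained proteins")
    centred <- v - stats::median(v, na.rm = TRUE)
    orient <- unique(x$orientation[idx])
    if (length(orient) != 1L) {
      stop("replicate ", rep_id, " has mixed orientations")
    }
    x$oriented_log2[idx] <- if (orient == "reverse") -centred else centred
  }
  x
}

#' Label-swap differential abundance
#'
#' Per protein, a two-sided one-sample t-test of the oriented log2 ratios
#' against 0, Benjamini-Hochberg correction across all tested proteins, and
#' an up/down/unchanged call at the fold-change and q-value thresholds.
#' Proteins with fewer than two values are excluded (logged); proteins with
#' zero variance across replicates have no distributional basis for a t
#' statistic, get `NA` p-values, and are excluded from the BH adjustment.
#' With two replicates (one label swap) the test has a single degree of
#' freedom and minimal power; a warning notes this.
#'
#' @param oriented data frame from [normalize_and_orient()].
#' @param fc_threshold absolute log2 fold-change threshold (inclusive).
#' @param q_threshold q-value threshold (strict).
#' @return data frame: `protein_id`, `n`, `mean_log2_fc`, `t_stat`,
#'   `p_value`, `q_value`, `call`.
#' @export
differential_abundance <- function(oriented, fc_threshold = 0.8,
                                   q_threshold = 0.05) {
  stopifnot("oriented_log2" %in% names(oriented))
  vals <- split(oriented$oriented_log2, oriented$protein_id)
  n_vals <- vapply(vals, length, 1L)
  dropped <- names(vals)[n_vals < 2L]
  if (length(dropped) > 0L) {
    message(length(dropped),
            " protein(s) excluded: fewer than 2 replicate values")
    vals <- vals[n_vals >= 2L]
  }
  if (length(vals) == 0L) stop("no proteins with >= 2 replicate values")
  if (max(vapply(vals, length, 1L)) == 2L) {
    warning("only 2 replicates per protein: t-test has 1 df, ",
            "power is minimal")
  }
  res <- do.call(rbind, lapply(names(vals), function(id) {
    tt <- one_sample_t(vals[[id]], mu0 = 0)
    data.frame(protein_id = id, n = length(vals[[id]]),
               mean_log2_fc = mean(vals[[id]]), t_stat = tt$t,
               p_value = tt$p, stringsAsFactors = FALSE)
  }))
  res$q_value <- NA_real_
  tested <- !is.na(res$p_value)
  res$q_value[tested] <- bh_fdr(res$p_value[tested])
  res$call <- "unchanged"
  sig <- !is.na(res$q_value) & res$q_value < q_threshold
  res$call[sig & res$mean_log2_fc >= fc_threshold] <- "up"
  res$call[sig & res$mean_log2_fc <= -fc_threshold] <- "down"
  rownames(res) <- NULL
  res
}

#' Heavy-label incorporation estimate
#'
#' Per-peptide incorporation is `H / (H + L)` for peptides carrying heavy
#' arginine or lysine in a fully heavy-labelled sample; the estimate is the
#' mean across peptides. Peptides with `H + L = 0` are skipped.
#'
#' @param peptides data frame with columns `heavy` and `light` (intensities).
#' @return incorporation fraction in `[0, 1]`.
#' @examples
#' estimate_incorporation(data.frame(heavy = 99, light = 1))  # 0.99
#' @export
estimate_incorporation <- function(peptides) {
  stopifnot(all(c("heavy", "light") %in% names(peptides)))
  tot <- peptides$heavy + peptides$light
  keep <- !is.na(tot) & tot > 0
  if (!any(keep)) stop("no peptide with nonzero total intensity")
  mean(peptides$heavy[keep] / tot[keep])
}

#' Arginine-to-proline conversion estimate
#'
#' Metabolic conversion of heavy arginine to heavy proline (Pro6) biases
#' SILAC ratios of proline-containing peptides. Per peptide the conversion
#' is `Pro6 / (Pro6 + Pro0)` over the intensities of the Pro6-bearing and
#' Pro0-bearing forms; the estimate is the mean across peptides.
#'
#' @param peptides data frame with columns `pro6` and `pro0` (intensities of
#'   the heavy-proline and light-proline peptide forms).
#' @return conversion fraction in `[0, 1]`.
#' @examples
#' estimate_proline_conversion(data.frame(pro6 = 6.3, pro0 = 93.7))  # 0.063
#' @export
estimate_proline_conversion <- function(peptides) {
  stopifnot(all(c("pro6", "pro0") %in% names(peptides)))
  tot <- peptides$pro6 + peptides$pro0
  keep <- !is.na(tot) & tot > 0
  if (!any(keep)) stop("no peptide with nonzero total intensity")
  mean(peptides$pro6[keep] / tot[keep])
}
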