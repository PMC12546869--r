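#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values controlling the false discovery rate, in the
#' standard cumulative-minimum formulation, order-preserving with the input.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must be in [0, 1] and non-missing")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Two-sided one-sample t-test
#'
#' `t = (mean - mu0) / (sd / sqrt(n))` with `n - 1` degrees of freedom.
#' With fewer than two values, or zero variance, the statistic has no
#' distributional basis; both `t` and `p` are returned as `NA` with
#' `flagged = TRUE`.
#'
#' @param values numeric vector.
#' @param mu0 null-hypothesis mean.
#' @return list with `t`, `p` (two-sided), `df`, `flagged`.
#' @examples
#' one_sample_t(c(0.9, 1.1, 1.0), 0)$t  # about 17.32
#' @export
one_sample_t <- function(values, mu0 = 0) {
  n <- length(values)
  if (n < 2L || stats::sd(values) == 0) {
    return(list(t = NA_real_, p = NA_real_, df = NA_integer_,
                flagged = TRUE))
  }
  t_stat <- (mean(values) - mu0) / (stats::sd(values) / sqrt(n))
  list(t = t_stat, p = 2 * stats::pt(-abs(t_stat), df = n - 1L),
       df = n - 1L, flagged = FALSE)
}

#' Hypergeometric over-representation test with BH correction
#'
#' Per term, the one-sided upper-tail probability `P(X >= k)` for `X`
#' hypergeometric with background size `N`, term size `K` and study size
#' `n`, where `k` is the number of study genes annotated to the term.
#' Annotations are restricted to the background (the set of quantified
#' genes, not the whole genome); terms with no study hit are skipped; BH
#' correction is applied across all tested terms.
#'
#' @param study character vector of study genes (must be a subset of
#'   `background`).
#' @param background character vector of background genes.
#' @param annotations data frame with columns `gene` and `term`.
#' @return data frame: `term`, `k`, `n`, `K`, `N`, `p_value`, `q_value`,
#'   ordered by `p_value`.
#' @export
hypergeometric_enrichment <- function(study, background, annotations) {
  study <- unique(study)
  background <- unique(background)
  outside <- setdiff(study, background)
  if (length(outside) > 0L) {
    stop("study gene not in background: ", outside[[1L]])
  }
  stopifnot(all(c("gene", "term") %in% names(annotations)))
  ann <- annotations[annotations$gene %in% background, , drop = FALSE]
  ann <- unique(ann[c("gene", "term")])
  N <- length(background)
  n <- length(study)
  term_genes <- split(ann$gene, ann$term)
  rows <- lapply(names(term_genes), function(tm) {
    genes <- term_genes[[tm]]
    K <- length(genes)
    k <- sum(study %in% genes)
    if (k == 0L) return(NULL)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p_value = numeric(0),
                      q_value = numeric(0)))
  }
  res <- do.call(rbind, rows)
  res$q_value <- bh_fdr(res$p_value)
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify a differential-expression table
#'
#' Inclusive thresholds on the log2 fold change (`>= fc_threshold` up,
#' `<= -fc_threshold` down) combined with a strict threshold on the
#' adjusted p-value. Genes with a missing adjusted p-value are classified
#' `unchanged` with a warning.
#'
#' @param table data frame with columns `gene`, `log2_fc`, `adj_p`.
#' @param fc_threshold absolute log2 fold-change threshold (inclusive).
#' @param p_threshold adjusted p-value threshold (strict).
#' @return the input with an added `call` column (`up`/`down`/`unchanged`).
#' @examples
#' classify_de(data.frame(gene = "g", log2_fc = -0.8, adj_p = 0.049))
#' @export
classify_de <- function(table, fc_threshold = 0.8, p_threshold = 0.05) {
  stopifnot(all(c("gene", "log2_fc", "adj_p") %in% names(table)))
  x <- table
  x$call <- "unchanged"
  missing_p <- is.na(x$adj_p)
  if (any(missing_p)) {
    warning(sum(missing_p),
            " gene(s) with missing adjusted p classified unchanged")
  }
  sig <- !missing_p & x$adj_p < p_threshold
  x$call[sig & x$log2_fc >= fc_threshold] <- "up"
  x$call[sig & x$log2_fc <= -fc_threshold] <- "down"
  x
}

#' Remove genes with negligible total read count
#'
#' Drops rows (genes) whose summed read count across all samples is at
#' most 1.
#'
#' @param counts matrix or data frame of non-negative integer counts,
#'   genes in rows.
#' @return the filtered matrix.
#' @export
filter_low_counts <- function(counts) {
  m <- as.matrix(counts)
  if (any(m < 0)) stop("negative counts")
  if (any(m != round(m))) stop("counts must be integers")
  m[rowSums(m) > 1, , drop = FALSE]
}
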