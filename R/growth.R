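#' Doubling time from the steepest log-linear window
#'
#' Estimates the exponential-phase doubling time of a microplate growth
#' curve as `log10(2) / s`, where `s` is the maximum ordinary-least-squares
#' slope of `log10(OD600)` versus time over all contiguous windows of
#' `window` points whose OD values all exceed `od_floor`. Points at or below
#' the floor (blank-level signal, where log-transformation would fabricate
#' structure) shift the window start rather than being clipped.
#'
#' @param times time points in minutes, strictly increasing.
#' @param od OD600 values, same length as `times`.
#' @param window window width in points; the default 6 spans one hour at the
#'   usual 10-minute sampling interval.
#' @param od_floor OD values must exceed this (blank-subtracted) floor to
#'   enter a window.
#' @param blank optional blank OD subtracted from `od` first.
#' @return list with elements `status` (`"ok"`, `"non_growing"`, or
#'   `"no_window"`), `doubling_time` (minutes, `NA` unless `"ok"`),
#'   `slope` (log10 OD per minute), and `window_start` (index of the
#'   steepest window).
#' @examples
#' t <- seq(0, 600, by = 10)
#' fit <- doubling_time(t, 0.1 * 2^(t / 90))
#' fit$doubling_time  # 90
#' @export
doubling_time <- function(times, od, window = 6, od_floor = 0.02,
                          blank = 0) {
  stopifnot(length(times) == length(od), length(times) >= 1L)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  od <- od - blank
  window <- as.integer(window)
  if (window < 2L) stop("window must be >= 2 points")
  ok <- !is.na(od) & od > od_floor
  n <- length(od)
  best_slope <- -Inf
  best_start <- NA_integer_
  if (n >= window) {
    logod <- ifelse(ok, log10(od), NA_real_)
    for (start in seq_len(n - window + 1L)) {
      idx <- start:(start + window - 1L)
      if (!all(ok[idx])) next
      x <- times[idx]
      y <- logod[idx]
      s <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
      if (s > best_slope) {
        best_slope <- s
        best_start <- start
      }
    }
  }
  if (is.na(best_start)) {
    return(list(status = "no_window", doubling_time = NA_real_,
                slope = NA_real_, window_start = NA_integer_))
  }
  if (best_slope <= 0) {
    return(list(status = "non_growing", doubling_time = NA_real_,
                slope = best_slope, window_start = best_start))
  }
  list(status = "ok", doubling_time = log10(2) / best_slope,
       slope = best_slope, window_start = best_start)
}

#' Doubling times for a long-format plate table
#'
#' Applies [doubling_time()] to each curve of a long-format table.
#'
#' @param curves data frame with columns `time_min`, `od600`, `well`,
#'   `strain`, `condition`, `replicate`.
#' @inheritParams doubling_time
#' @return tidy data frame: `well`, `strain`, `condition`, `replicate`,
#'   `status`, `doubling_time_min`, `slope`.
#' @export
fit_doubling_times <- function(curves, window = 6, od_floor = 0.02,
                               blank = 0) {
  needed <- c("time_min", "od600", "well", "strain", "condition",
              "replicate")
  missing_cols <- setdiff(needed, names(curves))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  key <- interaction(curves$well, curves$strain, curves$condition,
                     curves$replicate, drop = TRUE)
  out <- lapply(split(curves, key), function(g) {
    g <- g[order(g$time_min), , drop = FALSE]
    fit <- doubling_time(g$time_min, g$od600, window = window,
                         od_floor = od_floor, blank = blank)
    data.frame(well = g$well[[1L]], strain = g$strain[[1L]],
               condition = g$condition[[1L]], replicate = g$replicate[[1L]],
               status = fit$status, doubling_time_min = fit$doubling_time,
               slope = fit$slope, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize doubling times by strain and condition
#'
#' Mean, standard deviation and replicate count per strain-by-condition
#' cell. Non-growing or unfittable replicates (`NA` doubling time) are
#' dropped with a warning; cells left empty are omitted.
#'
#' @param fits data frame from [fit_doubling_times()] (columns `strain`,
#'   `condition`, `doubling_time_min`).
#' @return data frame: `strain`, `condition`, `mean`, `sd`, `n`.
#' @export
compare_doubling_times <- function(fits) {
  stopifnot(all(c("strain", "condition", "doubling_time_min") %in%
                  names(fits)))
  n_na <- sum(is.na(fits$doubling_time_min))
  if (n_na > 0L) {
    warning(n_na, " replicate(s) without a doubling time were dropped")
    fits <- fits[!is.na(fits$doubling_time_min), , drop = FALSE]
  }
  if (nrow(fits) == 0L) {
    warning("no replicates with a doubling time; empty summary")
    return(data.frame(strain = character(0), condition = character(0),
                      mean = numeric(0), sd = numeric(0), n = integer(0)))
  }
  key <- interaction(fits$strain, fits$condition, drop = TRUE)
  out <- lapply(split(fits, key), function(g) {
    data.frame(strain = g$strain[[1L]], condition = g$condition[[1L]],
               mean = mean(g$doubling_time_min),
               sd = if (nrow(g) > 1L) stats::sd(g$doubling_time_min)
                    else NA_real_,
               n = nrow(g), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
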