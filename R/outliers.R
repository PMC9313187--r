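#' Grubbs' test statistic for the most extreme replicate
#'
#' Computes `G = |O - mean| / SD` for the single value `O` farthest from
#' the sample mean, with `SD` the sample standard deviation (n - 1
#' denominator). `G` is bounded above by `(n - 1) / sqrt(n)`.
#'
#' @param values Numeric vector of at least 3 replicate values.
#' @return A list with `G` and `flagged_index` (position of the most
#'   extreme value).
#' @export
#' @examples
#' grubbs_statistic(c(1, 2, 3, 50))  # G ~ 1.499, index 4
grubbs_statistic <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) abort_insufficient("Grubbs' test needs at least 3 values.")
  s <- sd(values)
  if (!is.finite(s) || s == 0) {
    abort_degenerate("All replicate values are identical (SD = 0); Grubbs' test undefined.")
  }
  dev <- abs(values - mean(values))
  idx <- which.max(dev)
  list(G = dev[idx] / s, flagged_index = idx)
}

#' Two-sided p-value for Grubbs' statistic
#'
#' Inverts the classical critical-value relation of the test: with
#' `t = sqrt(G^2 n (n - 2) / ((n - 1)^2 - n G^2))`, the two-sided p-value
#' is `min(1, 2 n P(T_{n-2} > t))`. When `G` meets or exceeds its
#' attainable maximum `(n - 1) / sqrt(n)` the p-value is 0.
#'
#' @param G Grubbs' statistic (>= 0).
#' @param n Sample size (>= 3).
#' @return p-value in \[0, 1\]; vectorised over `G`.
#' @export
grubbs_p_value <- function(G, n) {
  if (n < 3) abort_insufficient("Grubbs' test needs n >= 3.")
  if (any(G < 0)) abort_domain("G must be non-negative.")
  gmax2 <- (n - 1)^2 / n
  denom <- (n - 1)^2 - n * G^2
  t2 <- G^2 * n * (n - 2) / denom
  p <- ifelse(G^2 >= gmax2, 0,
              pmin(1, 2 * n * pt(sqrt(pmax(t2, 0)), df = n - 2, lower.tail = FALSE)))
  p
}

screen_group <- function(values, threshold) {
  trail <- list()
  keep <- values
  iter <- 0L
  repeat {
    if (length(keep) < 3) break
    s <- sd(keep)
    if (!is.finite(s) || s == 0) break
    st <- grubbs_statistic(keep)
    p <- grubbs_p_value(st$G, length(keep))
    iter <- iter + 1L
    remove <- p < threshold
    trail[[iter]] <- tibble(iteration = iter, n = length(keep), G = st$G,
                            p_value = p, flagged_value = keep[st$flagged_index],
                            removed = remove)
    if (!remove) break
    keep <- keep[-st$flagged_index]
  }
  list(kept = keep, trail = bind_rows(trail))
}

#' Iterative Grubbs outlier removal per dose group
#'
#' Applies Grubbs' test to the replicate fraction-affected values of each
#' dose group (of a [dr_data()] table) or each dose-pair cell (of a
#' [combo_grid()]). While the most extreme value has `p < threshold` and
#' at least 3 values remain, that value is removed and the group retested;
#' groups with fewer than 3 replicates are skipped. Screening operates on
#' the normalised `fa` values, so the same screen serves single-drug tables
#' and matrix cells.
#'
#' @param data A normalised [dr_data()] or [combo_grid()] tibble.
#' @param threshold p-value threshold in (0, 1); smaller is stricter.
#' @return A list with `data` (the cleaned tibble, same class as the
#'   input) and `report` (audit tibble: one row per test iteration with
#'   the group id, `n`, `G`, `p_value`, `flagged_value` and whether it was
#'   removed).
#' @export
remove_outliers <- function(data, threshold = 0.05) {
  UseMethod("remove_outliers")
}

check_threshold <- function(threshold) {
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold >= 1) {
    abort_validation("`threshold` must be a single p-value strictly inside (0, 1).")
  }
}

check_fa <- function(data) {
  if (is.null(data[["fa"]])) {
    abort_validation("No fa values; run normalize_responses() before remove_outliers().")
  }
}

screen_by_group <- function(tbl, group_cols, threshold) {
  groups <- split(tbl, tbl[group_cols], drop = TRUE, sep = "\r")
  kept <- list(); reports <- list()
  skipped <- 0L
  for (g in groups) {
    if (nrow(g) < 3) {
      skipped <- skipped + 1L
      kept[[length(kept) + 1L]] <- g
      next
    }
    res <- screen_group(g$fa, threshold)
    if (nrow(res$trail) > 0) {
      rep_g <- res$trail
      for (col in group_cols) rep_g[[col]] <- g[[col]][1]
      reports[[length(reports) + 1L]] <- rep_g[, c(group_cols, setdiff(names(rep_g), group_cols))]
    }
    drop_idx <- integer(0)
    vals <- g$fa
    removed_vals <- res$trail$flagged_value[res$trail$removed]
    for (v in removed_vals) {
      cand <- setdiff(which(vals == v), drop_idx)
      drop_idx <- c(drop_idx, cand[1])
    }
    kept[[length(kept) + 1L]] <- if (length(drop_idx)) g[-drop_idx, ] else g
  }
  if (skipped > 0) {
    inform(sprintf("%d group(s) with fewer than 3 replicates skipped by the outlier screen.",
                   skipped))
  }
  list(data = bind_rows(kept), report = bind_rows(reports))
}

#' @export
remove_outliers.dr_data <- function(data, threshold = 0.05) {
  check_threshold(threshold); check_fa(data)
  res <- screen_by_group(as_tibble(data), c("drug", "dose"), threshold)
  out <- res$data %>% arrange(.data$drug, .data$dose, .data$replicate)
  list(data = new_dr_data(out, normalization = attr(data, "normalization", exact = TRUE)),
       report = res$report)
}

#' @export
remove_outliers.combo_grid <- function(data, threshold = 0.05) {
  check_threshold(threshold); check_fa(data)
  res <- screen_by_group(as_tibble(data), c("dose_a", "dose_b"), threshold)
  out <- res$data %>% arrange(.data$dose_a, .data$dose_b, .data$replicate)
  cleaned <- combo_grid(out, drug_a = attr(data, "drug_a"), drug_b = attr(data, "drug_b"))
  cleaned$fa <- out$fa; cleaned$fa_raw <- out$fa_raw; cleaned$fa_clipped <- out$fa_clipped
  attr(cleaned, "normalization") <- attr(data, "normalization", exact = TRUE)
  list(data = cleaned, report = res$report)
}
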