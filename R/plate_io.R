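#' Construct a tidy single-drug dose-response table
#'
#' A `dr_data` tibble is the package's container for single-drug plate data:
#' one row per replicate well, columns `drug`, `dose` (molar, >= 0),
#' `replicate` and `response` (raw plate-reader signal). Doses are sorted
#' ascending within drug and duplicated doses are merged as extra replicates.
#' After [normalize_responses()] the table additionally carries `fa`
#' (fraction affected, clipped to \[0, 1\]), `fa_raw` (unclipped) and
#' `fa_clipped` (flag).
#'
#' @param data A data frame with columns `drug`, `dose`, `replicate`,
#'   `response` (`replicate` is optional and renumbered anyway).
#' @return A `dr_data` tibble.
#' @export
#' @examples
#' dr_data(data.frame(drug = "X", dose = c(0, 1e-8, 1e-7),
#'                    replicate = 1, response = c(1000, 600, 200)))
dr_data <- function(data) {
  if (!is.data.frame(data)) abort_schema("`data` must be a data frame.")
  need <- c("drug", "dose", "response")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort_schema(paste0("Missing required column(s): ",
                        paste0("`", missing_cols, "`", collapse = ", "), "."))
  }
  tbl <- as_tibble(data)
  if (!is.numeric(tbl$dose)) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(tbl$dose)))))
    abort_validation(paste0("Column `dose` is not numeric (first bad row: ",
                            if (length(bad)) bad[1] else "?", ")."))
  }
  if (!is.numeric(tbl$response)) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(tbl$response)))))
    abort_validation(paste0("Column `response` is not numeric (first bad row: ",
                            if (length(bad)) bad[1] else "?", ")."))
  }
  bad_dose <- which(!is.finite(tbl$dose) | tbl$dose < 0)
  if (length(bad_dose) > 0) {
    abort_validation(sprintf(
      "Negative or non-finite dose %s at row %d.", format(tbl$dose[bad_dose[1]]), bad_dose[1]))
  }
  bad_resp <- which(!is.finite(tbl$response))
  if (length(bad_resp) > 0) {
    abort_validation(sprintf("Non-finite response at row %d.", bad_resp[1]))
  }
  tbl <- tbl %>%
    mutate(drug = as.character(.data$drug)) %>%
    arrange(.data$drug, .data$dose) %>%
    group_by(.data$drug, .data$dose) %>%
    mutate(replicate = row_number()) %>%
    ungroup() %>%
    select(all_of(c("drug", "dose", "replicate", "response")),
           dplyr::any_of(c("fa", "fa_raw", "fa_clipped")))
  new_dr_data(tbl, normalization = attr(data, "normalization", exact = TRUE))
}

new_dr_data <- function(tbl, normalization = NULL) {
  structure(tbl,
            class = c("dr_data", class(as_tibble(tbl))),
            normalization = normalization)
}

#' @export
print.dr_data <- function(x, ...) {
  norm <- attr(x, "normalization", exact = TRUE)
  cat(sprintf("# dr_data: %d drug(s), %d wells%s\n",
              dplyr::n_distinct(x$drug), nrow(x),
              if (is.null(norm)) " (raw signals)" else paste0(" (fa via ", norm, ")")))
  NextMethod()
}

#' Read a single-drug plate table
#'
#' Reads plate CSVs into a [dr_data()] tibble. Two layouts are accepted.
#' The canonical `long` layout has columns `drug,dose,replicate,response`,
#' one well per row. The `wide` layout is one drug per row across a paired
#' pair of files: `path` holds doses (`drug,dose_1,...,dose_k`) and
#' `response_path` holds replicate responses
#' (`drug,replicate,response_1,...,response_k`) with columns matching the
#' dose file positionally.
#'
#' @param path Path to the CSV file (the dose file for `layout = "wide"`).
#' @param layout `"long"` (default) or `"wide"`.
#' @param response_path Path to the response CSV, required for `"wide"`.
#' @return A `dr_data` tibble covering all drugs in the file.
#' @export
read_single_drug_table <- function(path, layout = c("long", "wide"),
                                   response_path = NULL) {
  layout <- arg_match(layout)
  if (!file.exists(path)) abort_validation(paste0("File not found: ", path))
  if (layout == "long") {
    # numeric columns are parsed with strtod (correctly rounded), so a
    # write/read cycle reproduces doubles bit-identically
    tbl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
    need <- c("drug", "dose", "replicate", "response")
    missing_cols <- setdiff(need, names(tbl))
    if (length(missing_cols) > 0) {
      abort_schema(paste0("Long layout is missing column(s): ",
                          paste0("`", missing_cols, "`", collapse = ", "), "."))
    }
    tbl <- tbl %>% mutate(across(all_of(c("dose", "replicate", "response")),
                                 parse_strict))
    return(dr_data(tbl))
  }
  if (is.null(response_path)) {
    abort_schema("Wide layout needs `response_path` (paired dose/response files).")
  }
  if (!file.exists(response_path)) {
    abort_validation(paste0("File not found: ", response_path))
  }
  doses <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                           show_col_types = FALSE, progress = FALSE)
  resp <- readr::read_csv(response_path, col_types = readr::cols(.default = readr::col_character()),
                          show_col_types = FALSE, progress = FALSE)
  doses <- doses %>% mutate(across(-all_of("drug"), parse_strict))
  resp <- resp %>% mutate(across(-all_of("drug"), parse_strict))
  if (!identical(names(doses)[1], "drug") || ncol(doses) < 2) {
    abort_schema("Wide dose file must have columns `drug,dose_1,...,dose_k`.")
  }
  if (!identical(names(resp)[1:2], c("drug", "replicate"))) {
    abort_schema("Wide response file must have columns `drug,replicate,response_1,...`.")
  }
  k <- ncol(doses) - 1L
  if (ncol(resp) - 2L != k) {
    abort_schema(sprintf(
      "Dose file has %d dose columns but response file has %d response columns.",
      k, ncol(resp) - 2L))
  }
  extra <- setdiff(resp$drug, doses$drug)
  if (length(extra) > 0) {
    abort_validation(paste0("Response file names drug(s) absent from the dose file: ",
                            paste(extra, collapse = ", "), "."))
  }
  dose_long <- doses %>%
    tidyr::pivot_longer(-"drug", names_to = "slot", values_to = "dose")
  resp_long <- resp %>%
    tidyr::pivot_longer(-c("drug", "replicate"),
                        names_to = "slot", values_to = "response") %>%
    mutate(slot = sub("^response", "dose", .data$slot))
  tbl <- left_join(resp_long, dose_long, by = c("drug", "slot")) %>%
    select(all_of(c("drug", "dose", "replicate", "response"))) %>%
    filter(!is.na(.data$response))
  dr_data(tbl)
}

#' Write a single-drug table in the canonical long CSV dialect
#'
#' @param data A `dr_data` tibble (or compatible data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_single_drug_table <- function(data, path) {
  data <- dr_data(data)
  out <- tibble(drug = data$drug, dose = num_chr(data$dose),
                replicate = data$replicate, response = num_chr(data$response))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Construct a two-drug checkerboard grid
#'
#' A `combo_grid` tibble holds a factorial dose matrix in long form: one row
#' per replicate well with columns `dose_a`, `dose_b`, `replicate`,
#' `response`. Both dose axes must include 0; the `dose_b == 0` row and
#' `dose_a == 0` column are the embedded single-drug margins and the (0, 0)
#' cell is the untreated control. [normalize_responses()] adds `fa`,
#' `fa_raw` and `fa_clipped` exactly as for [dr_data()].
#'
#' @param data Data frame with columns `dose_a`, `dose_b`, `replicate`
#'   (optional), `response`.
#' @param drug_a,drug_b Drug names for the two axes.
#' @return A `combo_grid` tibble.
#' @export
combo_grid <- function(data, drug_a = "drug_A", drug_b = "drug_B") {
  if (!is.data.frame(data)) abort_schema("`data` must be a data frame.")
  need <- c("dose_a", "dose_b", "response")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort_schema(paste0("Missing required column(s): ",
                        paste0("`", missing_cols, "`", collapse = ", "), "."))
  }
  tbl <- as_tibble(data)
  for (col in c("dose_a", "dose_b", "response")) {
    if (!is.numeric(tbl[[col]])) abort_validation(paste0("Column `", col, "` is not numeric."))
  }
  if (any(tbl$dose_a < 0) || any(tbl$dose_b < 0)) {
    abort_validation("Doses must be non-negative.")
  }
  if (!any(tbl$dose_a == 0) || !any(tbl$dose_b == 0)) {
    abort_validation("A checkerboard grid must include the zero dose on both axes.")
  }
  if (!any(tbl$dose_a == 0 & tbl$dose_b == 0)) {
    abort_validation("The grid is missing the untreated (0, 0) control cell.")
  }
  tbl <- tbl %>%
    arrange(.data$dose_a, .data$dose_b) %>%
    group_by(.data$dose_a, .data$dose_b) %>%
    mutate(replicate = row_number()) %>%
    ungroup() %>%
    select(all_of(c("dose_a", "dose_b", "replicate", "response")),
           dplyr::any_of(c("fa", "fa_raw", "fa_clipped")))
  structure(tbl,
            class = c("combo_grid", class(as_tibble(tbl))),
            drug_a = drug_a, drug_b = drug_b,
            normalization = attr(data, "normalization", exact = TRUE))
}

#' @export
print.combo_grid <- function(x, ...) {
  cat(sprintf("# combo_grid: %s x %s, %d x %d doses (incl. zero), %d wells\n",
              attr(x, "drug_a"), attr(x, "drug_b"),
              dplyr::n_distinct(x$dose_a), dplyr::n_distinct(x$dose_b), nrow(x)))
  NextMethod()
}

#' Read a checkerboard dose-matrix CSV
#'
#' The matrix dialect mirrors a plate layout: the top-left cell is blank,
#' the first row holds the doses of drug A (including 0), the first column
#' the doses of drug B (including 0), and each body cell holds the
#' replicate responses for that dose pair joined with `";"`. Ragged
#' replicate counts across cells are allowed (a message reports them).
#'
#' @param path Path to the matrix CSV.
#' @param drug_a,drug_b Names for the column-axis and row-axis drugs.
#' @return A [combo_grid()] tibble.
#' @export
read_combination_matrix <- function(path, drug_a = "drug_A", drug_b = "drug_B") {
  if (!file.exists(path)) abort_validation(paste0("File not found: ", path))
  raw <- readr::read_csv(path, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) < 2 || ncol(raw) < 2) abort_schema("Matrix file needs a header row and column.")
  doses_a <- suppressWarnings(as.numeric(raw[1, -1][1, ]))
  doses_b <- suppressWarnings(as.numeric(raw[[1]][-1]))
  if (any(is.na(doses_a)) || any(is.na(doses_b))) {
    abort_schema("Matrix header row/column must be numeric doses.")
  }
  if (doses_a[1] != 0) abort_validation("Matrix is missing the dose-0 column for drug A.")
  if (doses_b[1] != 0) abort_validation("Matrix is missing the dose-0 row for drug B.")
  if (is.unsorted(doses_a, strictly = TRUE) || is.unsorted(doses_b, strictly = TRUE)) {
    abort_validation("Matrix doses must be strictly ascending from 0.")
  }
  cells <- purrr::map(seq_along(doses_b), function(i) {
    purrr::map(seq_along(doses_a), function(j) {
      cell <- raw[[j + 1]][i + 1]
      if (is.na(cell) || !nzchar(trimws(cell))) {
        abort_validation(sprintf("Empty cell at dose_a=%s, dose_b=%s.",
                                 format(doses_a[j]), format(doses_b[i])))
      }
      vals <- suppressWarnings(as.numeric(strsplit(cell, ";", fixed = TRUE)[[1]]))
      if (any(is.na(vals))) {
        abort_validation(sprintf("Non-numeric replicate in cell dose_a=%s, dose_b=%s.",
                                 format(doses_a[j]), format(doses_b[i])))
      }
      tibble(dose_a = doses_a[j], dose_b = doses_b[i],
             replicate = seq_along(vals), response = vals)
    }) %>% bind_rows()
  }) %>% bind_rows()
  counts <- cells %>% dplyr::count(.data$dose_a, .data$dose_b)
  if (dplyr::n_distinct(counts$n) > 1) {
    inform(sprintf("Ragged replicate counts across cells (%s).",
                   paste(sort(unique(counts$n)), collapse = ", ")))
  }
  combo_grid(cells, drug_a = drug_a, drug_b = drug_b)
}

#' Write a checkerboard grid in the canonical matrix CSV dialect
#'
#' @param grid A [combo_grid()] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_combination_matrix <- function(grid, path) {
  stopifnot(inherits(grid, "combo_grid"))
  doses_a <- sort(unique(grid$dose_a))
  doses_b <- sort(unique(grid$dose_b))
  lines <- c(paste(c("", num_chr(doses_a)), collapse = ","))
  for (db in doses_b) {
    row <- vapply(doses_a, function(da) {
      vals <- grid$response[grid$dose_a == da & grid$dose_b == db]
      paste(num_chr(vals), collapse = ";")
    }, character(1))
    lines <- c(lines, paste(c(num_chr(db), row), collapse = ","))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Normalise raw plate signals to fraction affected
#'
#' Converts raw signals to the fraction-affected (fa) scale used by every
#' downstream step: `fa = 1 - signal / reference`. With
#' `method = "zero_dose"` the reference is the mean signal of the untreated
#' wells (dose 0, or the (0, 0) cell of a grid); with
#' `method = "max_response"` it is the largest per-dose (per-cell) mean
#' signal, for plates without a vehicle control; with `method = "none"` the
#' responses are taken as already being fa values (they must lie in
#' \[-0.05, 1.05\]). In every case `fa` is clipped to \[0, 1\] with the
#' clip recorded in `fa_clipped`, and the unclipped value is kept in
#' `fa_raw` for curve fitting.
#'
#' @param data A [dr_data()] or [combo_grid()] tibble.
#' @param method Normalisation method.
#' @return The input tibble with `fa`, `fa_raw`, `fa_clipped` columns added
#'   and the `normalization` attribute set.
#' @export
#' @examples
#' d <- dr_data(data.frame(drug = "X", dose = c(0, 0, 1e-8),
#'                         response = c(200, 200, 50)))
#' normalize_responses(d, "zero_dose")$fa  # 0, 0, 0.75
normalize_responses <- function(data, method = c("zero_dose", "max_response", "none")) {
  UseMethod("normalize_responses")
}

#' @export
normalize_responses.data.frame <- function(data, method = c("zero_dose", "max_response", "none")) {
  normalize_responses(dr_data(data), method)
}

fa_from_reference <- function(response, reference, label) {
  if (!is.finite(reference) || reference <= 0) {
    abort_normalization(sprintf("Reference signal %s is not positive (%s).",
                                format(reference), label))
  }
  1 - response / reference
}

finish_fa <- function(tbl, fa_raw) {
  tbl$fa_raw <- fa_raw
  tbl$fa <- clamp(fa_raw, 0, 1)
  tbl$fa_clipped <- fa_raw < 0 | fa_raw > 1
  tbl
}

#' @export
normalize_responses.dr_data <- function(data, method = c("zero_dose", "max_response", "none")) {
  method <- arg_match(method)
  out <- as_tibble(data)
  parts <- lapply(split(out, out$drug), function(d) {
    if (method == "zero_dose") {
      if (!any(d$dose == 0)) {
        abort_normalization(paste0("Drug ", d$drug[1],
                                   " has no dose-0 wells; zero_dose normalisation impossible."))
      }
      ref <- mean(d$response[d$dose == 0])
      finish_fa(d, fa_from_reference(d$response, ref, d$drug[1]))
    } else if (method == "max_response") {
      per_dose <- tapply(d$response, d$dose, mean)
      ref <- max(per_dose)
      finish_fa(d, fa_from_reference(d$response, ref, d$drug[1]))
    } else {
      if (any(d$response < -0.05 | d$response > 1.05)) {
        abort_normalization(paste0(
          "method = \"none\" requires responses already on the fa scale ",
          "(within [-0.05, 1.05]); drug ", d$drug[1], " violates this."))
      }
      finish_fa(d, d$response)
    }
  })
  res <- bind_rows(parts) %>% arrange(.data$drug, .data$dose, .data$replicate)
  new_dr_data(res, normalization = method)
}

#' @export
normalize_responses.combo_grid <- function(data, method = c("zero_dose", "max_response", "none")) {
  method <- arg_match(method)
  tbl <- as_tibble(data)
  if (method == "zero_dose") {
    ref <- mean(tbl$response[tbl$dose_a == 0 & tbl$dose_b == 0])
    tbl <- finish_fa(tbl, fa_from_reference(tbl$response, ref, "(0,0) control"))
  } else if (method == "max_response") {
    per_cell <- tbl %>%
      group_by(.data$dose_a, .data$dose_b) %>%
      summarise(m = mean(.data$response), .groups = "drop")
    ref <- max(per_cell$m)
    tbl <- finish_fa(tbl, fa_from_reference(tbl$response, ref, "max cell mean"))
  } else {
    if (any(tbl$response < -0.05 | tbl$response > 1.05)) {
      abort_normalization("method = \"none\" requires responses within [-0.05, 1.05].")
    }
    tbl <- finish_fa(tbl, tbl$response)
  }
  out <- combo_grid(tbl, drug_a = attr(data, "drug_a"), drug_b = attr(data, "drug_b"))
  out$fa <- tbl$fa; out$fa_raw <- tbl$fa_raw; out$fa_clipped <- tbl$fa_clipped
  attr(out, "normalization") <- method
  out
}

#' Per-cell mean effects of a checkerboard grid
#'
#' Collapses replicates to the per-cell mean fraction affected: the
#' observed combined effect for interior cells, the single-drug effects
#' along the margins.
#'
#' @param grid A normalised [combo_grid()].
#' @return A tibble with `dose_a`, `dose_b`, `effect` (mean of clipped fa),
#'   `effect_raw` (mean of unclipped fa) and `n_replicates`.
#' @export
grid_effects <- function(grid) {
  stopifnot(inherits(grid, "combo_grid"))
  if (is.null(grid[["fa"]])) {
    abort_validation("Grid has no fa values; run normalize_responses() first.")
  }
  as_tibble(grid) %>%
    group_by(.data$dose_a, .data$dose_b) %>%
    summarise(effect = mean(.data$fa), effect_raw = mean(.data$fa_raw),
              n_replicates = dplyr::n(), .groups = "drop")
}

#' Extract a single-drug margin from a checkerboard grid
#'
#' The `dose_b == 0` row of the matrix is drug A's own dose series (and
#' symmetrically for drug B), including the shared (0, 0) control.
#'
#' @param grid A [combo_grid()].
#' @param which `"a"` or `"b"`.
#' @return A [dr_data()] tibble for the margin drug.
#' @export
grid_margin <- function(grid, which = c("a", "b")) {
  stopifnot(inherits(grid, "combo_grid"))
  which <- arg_match(which)
  tbl <- as_tibble(grid)
  if (which == "a") {
    sub <- tbl %>% filter(.data$dose_b == 0) %>%
      mutate(drug = attr(grid, "drug_a"), dose = .data$dose_a)
  } else {
    sub <- tbl %>% filter(.data$dose_a == 0) %>%
      mutate(drug = attr(grid, "drug_b"), dose = .data$dose_b)
  }
  sub <- sub %>% select(all_of(c("drug", "dose", "replicate", "response")),
                        dplyr::any_of(c("fa", "fa_raw", "fa_clipped")))
  out <- dr_data(sub)
  # carry over normalization state: fa columns are already consistent
  attr(out, "normalization") <- attr(grid, "normalization", exact = TRUE)
  out
}
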