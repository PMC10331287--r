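# Peak-table ingestion, internal-standard normalization and QC filters.

#' Read a peak table exported from MRM quantification software
#'
#' Expects delimited text with header columns `sample`, `role`
#' (`study`/`QC`/`blank`), `component`, `area`, `rt`, `fwhm`, `sn`.
#' Unknown columns are preserved. Rows whose area fails to parse are kept
#' with `area = NA` and flagged in the `problems` attribute; no row is
#' silently dropped.
#'
#' @param path File path.
#' @return A tibble of peak measurements; attribute `problems` holds a
#'   tibble of row-level parse issues.
#' @export
read_peak_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("sample", "role", "component", "area", "rt", "fwhm", "sn")
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0) {
    abort(paste0("missing column: ", paste(miss, collapse = ", ")))
  }
  problems <- tibble(row = integer(0), column = character(0),
                     value = character(0))
  for (col in c("area", "rt", "fwhm", "sn")) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(val) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      problems <- dplyr::bind_rows(problems,
                                   tibble(row = bad, column = col,
                                          value = raw[[col]][bad]))
    }
    raw[[col]] <- val
  }
  attr(raw, "problems") <- problems
  raw
}

#' Write a peak table
#'
#' @param peaks A peak tibble.
#' @param path File path.
#' @export
write_peak_table <- function(peaks, path) {
  readr::write_csv(peaks, path)
  invisible(path)
}

#' Normalize peak areas to matched internal standards
#'
#' Per sample, each species' area is divided by the area of its assigned
#' internal standard; IS components themselves are excluded from the
#' output. Division by a zero or missing IS area yields a missing cell
#' with an explicit reason, never a silent Inf. Because analyte and IS
#' share any per-sample instrument drift factor, the ratio cancels it.
#'
#' @param peaks A peak tibble (`sample`, `role`, `component`, `area`, ...).
#' @param is_assignments A tibble mapping `component` to `is_component`.
#' @return A long tibble: `component`, `sample`, `role`, `abundance`,
#'   `reason` (`NA` when the cell is present).
#' @export
normalize_to_is <- function(peaks, is_assignments) {
  is_areas <- peaks |>
    dplyr::filter(.data$component %in% is_assignments$is_component) |>
    dplyr::select(is_component = "component", "sample", is_area = "area")
  out <- peaks |>
    dplyr::filter(!.data$component %in% is_assignments$is_component) |>
    dplyr::inner_join(is_assignments, by = "component") |>
    dplyr::left_join(is_areas, by = c("is_component", "sample")) |>
    dplyr::mutate(
      abundance = dplyr::if_else(
        !is.na(.data$is_area) & .data$is_area > 0,
        .data$area / .data$is_area, NA_real_),
      reason = dplyr::case_when(
        is.na(.data$is_area) ~ "missing IS",
        .data$is_area == 0 ~ "zero IS",
        is.na(.data$area) ~ "missing area",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::select("component", "sample", "role", "abundance", "reason")
  out
}

#' QC coefficient-of-variation filter
#'
#' Per species, CV% = 100 * sd / mean across the QC injections (sample
#' standard deviation, n-1 denominator); species are kept when CV% is
#' below the threshold. Species with zero mean signal are dropped with
#' reason `"no signal"`.
#'
#' @param abundances Long tibble from [normalize_to_is()] (or any tibble
#'   with `component`, `role`, `abundance`).
#' @param threshold CV%% threshold (default 20).
#' @return Per-species tibble: `component`, `cv_pct`, `kept`, `reason`.
#' @export
qc_cv_filter <- function(abundances, threshold = 20) {
  qc <- dplyr::filter(abundances, .data$role == "QC", !is.na(.data$abundance))
  if (dplyr::n_distinct(qc$sample) < 3) {
    abort("need at least 3 QC injections")
  }
  qc |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(m = mean(.data$abundance), s = sd(.data$abundance),
                     .groups = "drop") |>
    dplyr::mutate(
      cv_pct = dplyr::if_else(.data$m > 0, 100 * .data$s / .data$m, NA_real_),
      kept = !is.na(.data$cv_pct) & .data$cv_pct < threshold,
      reason = dplyr::case_when(
        is.na(.data$cv_pct) ~ "no signal",
        .data$cv_pct >= threshold ~ sprintf("CV %.1f%% >= %g%%",
                                            .data$cv_pct, threshold),
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::select("component", "cv_pct", "kept", "reason")
}

#' Blank-ratio and signal-to-noise filter
#'
#' A species is considered true signal only when its mean study abundance
#' exceeds `blank_fold` times its mean blank abundance and its median S/N
#' reaches `sn_min`. When the input contains no blank injections the blank
#' rule is skipped with a warning.
#'
#' @param abundances Long abundance tibble (`component`, `sample`, `role`,
#'   `abundance`).
#' @param sn_table Per-measurement S/N: tibble with `component` and `sn`
#'   (typically the study rows of the peak table).
#' @param blank_fold Required study/blank signal ratio (default 5).
#' @param sn_min Required median S/N (default 10).
#' @param blank_stat Aggregation for the blank comparison: `"mean"`
#'   (default) or `"median"`.
#' @return Per-species tibble: `component`, `blank_ratio`, `median_sn`,
#'   `kept`, `reason`.
#' @export
blank_sn_filter <- function(abundances, sn_table, blank_fold = 5,
                            sn_min = 10, blank_stat = c("mean", "median")) {
  blank_stat <- match.arg(blank_stat)
  agg <- if (blank_stat == "mean") mean else median
  study <- abundances |>
    dplyr::filter(.data$role == "study", !is.na(.data$abundance)) |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(study_sig = agg(.data$abundance), .groups = "drop")
  blanks <- abundances |>
    dplyr::filter(.data$role == "blank", !is.na(.data$abundance)) |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(blank_sig = agg(.data$abundance), .groups = "drop")
  have_blanks <- nrow(blanks) > 0
  if (!have_blanks) {
    warning("no blank injections: blank rule skipped", call. = FALSE)
  }
  sn <- sn_table |>
    dplyr::filter(!is.na(.data$sn)) |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(median_sn = median(.data$sn), .groups = "drop")
  study |>
    dplyr::left_join(blanks, by = "component") |>
    dplyr::left_join(sn, by = "component") |>
    dplyr::mutate(
      blank_ratio = dplyr::if_else(
        !is.na(.data$blank_sig) & .data$blank_sig > 0,
        .data$study_sig / .data$blank_sig, Inf),
      blank_ok = !have_blanks | .data$blank_ratio > blank_fold,
      sn_ok = is.na(.data$median_sn) | .data$median_sn >= sn_min,
      kept = .data$blank_ok & .data$sn_ok,
      reason = dplyr::case_when(
        !.data$blank_ok & !.data$sn_ok ~ "blank ratio; S/N",
        !.data$blank_ok ~ sprintf("blank ratio %.1f <= %g",
                                  .data$blank_ratio, blank_fold),
        !.data$sn_ok ~ "S/N",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::select("component", "blank_ratio", "median_sn", "kept", "reason")
}

#' Compose the QC filters into one verdict table
#'
#' The KEPT set is the intersection of the individual filters, so the
#' result is identical whatever order the filters are applied in.
#'
#' @param cv_verdict Output of [qc_cv_filter()].
#' @param blank_verdict Output of [blank_sn_filter()].
#' @return Per-species tibble with `kept` and the combined `reason`.
#' @export
combine_qc_filters <- function(cv_verdict, blank_verdict) {
  dplyr::full_join(
    dplyr::select(cv_verdict, "component", cv_kept = "kept",
                  cv_reason = "reason"),
    dplyr::select(blank_verdict, "component", blank_kept = "kept",
                  blank_reason = "reason"),
    by = "component"
  ) |>
    dplyr::mutate(
      kept = dplyr::coalesce(.data$cv_kept, TRUE) &
        dplyr::coalesce(.data$blank_kept, TRUE)
    ) |>
    dplyr::rowwise() |>
    dplyr::mutate(reason = if (.data$kept) NA_character_ else
      paste(stats::na.omit(c(.data$cv_reason, .data$blank_reason)),
            collapse = "; ")) |>
    dplyr::ungroup() |>
    dplyr::select("component", "kept", "reason")
}

#' Method-robustness summary
#'
#' Distributional view of the diagnostics used to judge the method:
#' empirical cumulative distributions of |predicted - observed RT| and of
#' peak FWHM, per-subclass CV across QC injections, the internal-standard
#' peak-area series over injection order, and the fractions of species
#' within the design bounds (FWHM <= 0.7 min, |dRT| <= 0.5 min).
#'
#' @param peaks Peak tibble (needs `component`, `sample`, `role`, `area`,
#'   `rt`, `fwhm`; `subclass` optional).
#' @param predictions Optional tibble with `component` and `rt_pred`.
#' @param is_components Optional character vector naming IS components for
#'   the drift series.
#' @return A list of class `qc_report`: `rt_dev` tibble, `fwhm` tibble,
#'   `cv_by_subclass`, `is_drift`, `frac_fwhm_le_0.7`, `frac_rtdev_le_0.5`.
#' @export
robustness_summary <- function(peaks, predictions = NULL,
                               is_components = character(0)) {
  qc <- dplyr::filter(peaks, .data$role == "QC")
  if (dplyr::n_distinct(qc$sample) < 2 && nrow(qc) > 0) {
    abort("need at least 2 QC injections")
  }
  rt_dev <- NULL
  frac_rt <- NA_real_
  if (!is.null(predictions)) {
    obs <- peaks |>
      dplyr::filter(.data$role != "blank") |>
      dplyr::group_by(.data$component) |>
      dplyr::summarise(rt_obs = median(.data$rt), .groups = "drop")
    rt_dev <- dplyr::inner_join(obs, predictions, by = "component") |>
      dplyr::mutate(abs_dev = abs(.data$rt_obs - .data$rt_pred))
    frac_rt <- mean(rt_dev$abs_dev <= 0.5)
  }
  fwhm <- peaks |>
    dplyr::filter(.data$role != "blank", !is.na(.data$fwhm)) |>
    dplyr::select("component", "fwhm")
  cv_by_subclass <- NULL
  if (nrow(qc) > 0) {
    cv <- qc |>
      dplyr::group_by(.data$component) |>
      dplyr::summarise(m = mean(.data$area), s = sd(.data$area),
                       .groups = "drop") |>
      dplyr::mutate(cv_pct = dplyr::if_else(.data$m > 0, 100 * .data$s / .data$m,
                                            NA_real_))
    if ("subclass" %in% names(peaks)) {
      cv <- dplyr::left_join(
        cv, dplyr::distinct(peaks[, c("component", "subclass")]),
        by = "component")
    } else {
      cv$subclass <- "all"
    }
    cv_by_subclass <- cv
  }
  is_drift <- NULL
  if (length(is_components) > 0) {
    is_drift <- peaks |>
      dplyr::filter(.data$component %in% is_components,
                    .data$role == "QC") |>
      dplyr::arrange(.data$sample) |>
      dplyr::group_by(.data$component) |>
      dplyr::mutate(injection = dplyr::row_number()) |>
      dplyr::ungroup() |>
      dplyr::select("component", "injection", "area")
  }
  structure(list(
    rt_dev = rt_dev,
    fwhm = fwhm,
    cv_by_subclass = cv_by_subclass,
    is_drift = is_drift,
    frac_fwhm_le_0.7 = if (nrow(fwhm) > 0) mean(fwhm$fwhm <= 0.7) else NA_real_,
    frac_rtdev_le_0.5 = frac_rt
  ), class = "qc_report")
}

#' Impute missing abundance cells
#'
#' Species with more than `max_missing` fraction of missing cells are
#' dropped; remaining missing cells are imputed with half the species
#' minimum (the standard metabolomics detection-floor surrogate).
#'
#' @param abundances Long abundance tibble.
#' @param max_missing Maximum tolerated missing fraction (default 0.3).
#' @return The tibble with missing cells imputed.
#' @export
impute_halfmin <- function(abundances, max_missing = 0.3) {
  abundances |>
    dplyr::group_by(.data$component) |>
    dplyr::filter(mean(is.na(.data$abundance)) <= max_missing) |>
    dplyr::mutate(abundance = dplyr::if_else(
      is.na(.data$abundance),
      min(.data$abundance, na.rm = TRUE) / 2,
      .data$abundance)) |>
    dplyr::ungroup()
}
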