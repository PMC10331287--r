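# Internal-standard parameter inheritance and co-elution validation.

#' Inherit acquisition parameters from matched internal standards
#'
#' Each library species borrows collision energy, declustering potential
#' and dwell time from the internal standard (IS) of the same subclass
#' whose chain length and double-bond count are nearest: minimal |delta
#' carbons|, ties broken by minimal |delta double bonds|, remaining ties
#' toward the lower carbon count. Species of a subclass with no IS are
#' flagged `parameterized = FALSE` rather than given silent defaults.
#'
#' @param library A library tibble (needs `name`, `subclass`,
#'   `total_carbons`, `total_double_bonds`).
#' @param is_panel A tibble of IS records with columns `is_id`, `subclass`,
#'   `total_carbons`, `total_double_bonds`, `ce`, `dp`, `dwell_ms`
#'   (and typically `rt_min`).
#' @return The library joined with `is_id`, `ce`, `dp`, `dwell_ms` and a
#'   logical `parameterized` column.
#' @export
assign_acquisition_params <- function(library, is_panel) {
  if (nrow(is_panel) == 0) abort("internal-standard panel is empty")
  pick <- function(sc, tc, tdb) {
    cand <- is_panel[is_panel$subclass == sc, ]
    if (nrow(cand) == 0) return(NA_integer_)
    d_c <- abs(cand$total_carbons - tc)
    d_db <- abs(cand$total_double_bonds - tdb)
    ord <- order(d_c, d_db, cand$total_carbons)
    which(is_panel$is_id == cand$is_id[ord[1]])[1]
  }
  idx <- mapply(pick, library$subclass, library$total_carbons,
                library$total_double_bonds, USE.NAMES = FALSE)
  out <- library
  out$is_id <- ifelse(is.na(idx), NA_character_, is_panel$is_id[idx])
  out$ce <- ifelse(is.na(idx), NA_real_, is_panel$ce[idx])
  out$dp <- ifelse(is.na(idx), NA_real_, is_panel$dp[idx])
  out$dwell_ms <- ifelse(is.na(idx), NA_real_, is_panel$dwell_ms[idx])
  out$parameterized <- !is.na(idx)
  out
}

#' Validate species by multi-transition co-elution
#'
#' A species measured through several MRM channels is accepted when all
#' its channels elute at the same retention time (within `tol_min`) and
#' every channel clears the signal-to-noise floor. Channels showing
#' doublet peaks split the observations into isomer groups (RT clusters
#' separated by more than `tol_min`); each cluster covering all channels
#' counts as one validated isomer.
#'
#' @param peaks A tibble of observed peaks with columns `name` (species),
#'   `fragment` (channel), `rt_min` and optionally `sn`.
#' @param tol_min Maximum pairwise RT difference within a co-eluting
#'   group (default 0.1 min).
#' @param sn_min Signal-to-noise floor (ignored when `peaks` has no `sn`).
#' @return A tibble per species: `verdict` (`"VALIDATED"`,
#'   `"NOT_VALIDATED"`, `"UNTESTABLE"`), `n_channels`, `n_isomer_groups`,
#'   `offending` (channel annotation, `NA` unless not validated).
#' @export
validate_by_coelution <- function(peaks, tol_min = 0.1, sn_min = 10) {
  if (!"sn" %in% names(peaks)) peaks$sn <- Inf
  one <- function(df) {
    channels <- unique(df$fragment)
    if (length(channels) < 2) {
      return(tibble(verdict = "UNTESTABLE", n_channels = length(channels),
                    n_isomer_groups = NA_integer_, offending = NA_character_))
    }
    low_sn <- unique(df$fragment[df$sn < sn_min])
    # single-linkage RT clusters: split at gaps > tol_min
    df <- df[order(df$rt_min), ]
    gap <- c(FALSE, diff(df$rt_min) > tol_min)
    df$cluster <- cumsum(gap)
    complete <- vapply(split(df, df$cluster), function(cl) {
      setequal(unique(cl$fragment), channels) &&
        (max(cl$rt_min) - min(cl$rt_min)) <= tol_min
    }, logical(1))
    n_groups <- sum(complete)
    if (length(low_sn) > 0) {
      tibble(verdict = "NOT_VALIDATED", n_channels = length(channels),
             n_isomer_groups = n_groups,
             offending = paste0("S/N: ", paste(low_sn, collapse = ", ")))
    } else if (n_groups >= 1) {
      tibble(verdict = "VALIDATED", n_channels = length(channels),
             n_isomer_groups = n_groups, offending = NA_character_)
    } else {
      # channel whose median RT departs most from the species median
      med <- median(df$rt_min)
      dev <- vapply(split(df, df$fragment),
                    function(cl) abs(median(cl$rt_min) - med), numeric(1))
      tibble(verdict = "NOT_VALIDATED", n_channels = length(channels),
             n_isomer_groups = 0L,
             offending = names(dev)[which.max(dev)])
    }
  }
  peaks |>
    dplyr::group_by(.data$name) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}

#' Read or write an MRM transition list
#'
#' Vendor-neutral delimited table with columns Q1, Q3, polarity, species
#' name, fragment annotation, adduct and (when assigned) CE, DP, dwell.
#'
#' @param transitions A transition tibble.
#' @param path File path.
#' @return `read_transitions()` returns the tibble.
#' @export
write_transitions <- function(transitions, path) {
  readr::write_csv(transitions, path)
  invisible(path)
}

#' @rdname write_transitions
#' @export
read_transitions <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
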