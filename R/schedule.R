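# Scheduled-MRM acquisition design: per-lipid RT windows and
# abundance-weighted dwell times under a cycle-time budget.

#' Scheduling configuration
#'
#' @param cycle_budget_s Maximum concurrent cycle time in seconds
#'   (default 0.75 s: 8 points across the narrowest 0.1-min peak).
#' @param min_dwell_ms Minimum (and high-abundance) dwell per transition.
#' @param pause_ms Inter-transition pause overhead.
#' @param default_halfwidth_min Default RT window half-width (0.5 min, the
#'   worst-case RT prediction error).
#' @param min_points_per_peak Quality floor used by [concurrency_check()].
#' @param min_fwhm_min Narrowest peak width assumed when converting cycle
#'   time to points per peak.
#' @param grid_min Time-grid resolution for the concurrency solver.
#' @return A list of class `smrm_config`.
#' @export
schedule_config <- function(cycle_budget_s = 0.75, min_dwell_ms = 3,
                            pause_ms = 2, default_halfwidth_min = 0.5,
                            min_points_per_peak = 8, min_fwhm_min = 0.1,
                            grid_min = 0.01) {
  vals <- c(cycle_budget_s, min_dwell_ms, pause_ms, default_halfwidth_min,
            min_points_per_peak, min_fwhm_min, grid_min)
  if (any(vals <= 0)) abort("all scheduling parameters must be positive")
  structure(list(cycle_budget_s = cycle_budget_s, min_dwell_ms = min_dwell_ms,
                 pause_ms = pause_ms,
                 default_halfwidth_min = default_halfwidth_min,
                 min_points_per_peak = min_points_per_peak,
                 min_fwhm_min = min_fwhm_min, grid_min = grid_min),
            class = "smrm_config")
}

.TIER_MULT <- c(high = 1, medium = 2, low = 3)

#' Build a scheduled-MRM acquisition list
#'
#' Assigns each transition an RT window (default half-width, widened to
#' the species' flagged RT deviation when larger) and a dwell time by
#' abundance tier: high-abundance transitions get the minimum dwell, low
#' abundance up to three times it. Target dwells are then shrunk toward
#' the minimum by the single largest factor that keeps the concurrent
#' cycle time (sum of dwell + pause over co-scheduled transitions) within
#' the budget at every point of a fine time grid. Output is deterministic.
#'
#' @param transitions A tibble with `q1`, `q3`, `rt_center` (min) and
#'   optionally `tier` (`"high"`/`"medium"`/`"low"`, default `"medium"`),
#'   `rt_halfwidth` (per-transition override in min) and id columns.
#' @param config A [schedule_config()].
#' @return The input with `rt_halfwidth`, `dwell_ms` and `tier` columns
#'   resolved; class `smrm_schedule`.
#' @export
build_schedule <- function(transitions, config = schedule_config()) {
  stopifnot(inherits(config, "smrm_config"))
  if (nrow(transitions) == 0) abort("no transitions to schedule")
  if (!"rt_center" %in% names(transitions)) {
    abort("every transition needs an rt_center")
  }
  if (any(is.na(transitions$rt_center))) {
    abort("every transition needs an rt_center")
  }
  sched <- transitions
  if (!"tier" %in% names(sched)) sched$tier <- "medium"
  sched$tier[is.na(sched$tier)] <- "medium"
  if (!all(sched$tier %in% names(.TIER_MULT))) {
    abort("tier must be high, medium or low")
  }
  if (!"rt_halfwidth" %in% names(sched)) sched$rt_halfwidth <- NA_real_
  sched$rt_halfwidth <- pmax(config$default_halfwidth_min,
                             sched$rt_halfwidth, na.rm = TRUE)

  min_d <- config$min_dwell_ms
  target <- min_d * .TIER_MULT[sched$tier]
  budget_ms <- config$cycle_budget_s * 1000

  # connected components of overlapping RT windows: contention in one
  # elution cluster must not shrink dwells in another
  ord <- order(sched$rt_center - sched$rt_halfwidth)
  lo <- (sched$rt_center - sched$rt_halfwidth)[ord]
  hi <- (sched$rt_center + sched$rt_halfwidth)[ord]
  comp_of <- integer(nrow(sched))
  comp <- 1L
  reach <- hi[1]
  comp_of[ord[1]] <- comp
  for (k in seq_len(length(ord))[-1]) {
    if (lo[k] > reach) {
      comp <- comp + 1L
      reach <- hi[k]
    } else {
      reach <- max(reach, hi[k])
    }
    comp_of[ord[k]] <- comp
  }

  # within each cluster, the largest f in [0,1] with dwell_i = min +
  # f*(target_i - min) feasible at every grid point; cycle time is linear
  # in f so the binding grid point fixes f
  sched$dwell_ms <- NA_real_
  for (cc in seq_len(comp)) {
    idx <- comp_of == cc
    sub <- sched[idx, ]
    grid <- seq(max(0, min(sub$rt_center - sub$rt_halfwidth)),
                max(sub$rt_center + sub$rt_halfwidth),
                by = config$grid_min)
    f <- 1
    for (t in grid) {
      act <- abs(sub$rt_center - t) <= sub$rt_halfwidth
      if (!any(act)) next
      base <- sum(act) * (min_d + config$pause_ms)
      if (budget_ms - base < -1e-9) {
        abort(paste0("cycle budget infeasible near RT ", round(t, 2),
                     " min: ", sum(act), " concurrent transitions need ",
                     base, " ms at minimum dwell (budget ", budget_ms,
                     " ms)"))
      }
      extra <- sum(target[idx][act] - min_d)
      if (extra > 0) f <- min(f, (budget_ms - base) / extra)
    }
    sched$dwell_ms[idx] <- as.numeric(min_d + f * (target[idx] - min_d))
  }
  class(sched) <- c("smrm_schedule", class(sched))
  sched
}

#' Points-per-peak concurrency profile of a schedule
#'
#' For each transition, points per peak = assumed minimum FWHM (seconds)
#' divided by the worst-case cycle time inside its RT window. Reports the
#' schedule-wide minimum and all transitions below the configured floor.
#'
#' @param schedule An `smrm_schedule`.
#' @param config The [schedule_config()] used to build it.
#' @return A list: `profile` (per-transition tibble with `cycle_s` and
#'   `points_per_peak`), `min_points`, `below_floor` tibble.
#' @export
concurrency_check <- function(schedule, config = schedule_config()) {
  if (nrow(schedule) == 0) {
    return(list(profile = tibble(), min_points = NA_real_,
                below_floor = tibble()))
  }
  grid <- seq(max(0, min(schedule$rt_center - schedule$rt_halfwidth)),
              max(schedule$rt_center + schedule$rt_halfwidth),
              by = config$grid_min)
  cycle_at <- vapply(grid, function(t) {
    act <- abs(schedule$rt_center - t) <= schedule$rt_halfwidth
    sum(schedule$dwell_ms[act] + config$pause_ms * act[act]) / 1000
  }, numeric(1))
  worst_cycle <- vapply(seq_len(nrow(schedule)), function(i) {
    inside <- abs(grid - schedule$rt_center[i]) <= schedule$rt_halfwidth[i]
    max(cycle_at[inside])
  }, numeric(1))
  prof <- tibble::as_tibble(schedule) |>
    dplyr::mutate(cycle_s = worst_cycle,
                  points_per_peak = (config$min_fwhm_min * 60) / worst_cycle)
  list(profile = prof,
       min_points = min(prof$points_per_peak),
       below_floor = dplyr::filter(prof, .data$points_per_peak <
                                     config$min_points_per_peak))
}

#' Export / import an acquisition list
#'
#' Writes one vendor-neutral delimited file per polarity (positive and
#' negative runs are acquired separately), sorted by RT then Q1; the
#' round trip is lossless. Duplicate (Q1, Q3, RT) rows are rejected.
#'
#' @param schedule An `smrm_schedule` tibble.
#' @param dir Output directory.
#' @param stem File-name stem; files are `<stem>_<polarity>.csv`.
#' @return `export_schedule()` returns the written paths;
#'   `read_schedule()` the combined schedule tibble.
#' @export
export_schedule <- function(schedule, dir, stem = "schedule") {
  if (nrow(schedule) == 0) abort("schedule is empty")
  dup <- duplicated(schedule[, c("q1", "q3", "rt_center")])
  if (any(dup)) {
    abort(paste0("duplicate (Q1, Q3, RT) rows in schedule: row ",
                 which(dup)[1]))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (pol in sort(unique(schedule$polarity))) {
    sub <- schedule[schedule$polarity == pol, ] |>
      dplyr::arrange(.data$rt_center, .data$q1, .data$q3)
    p <- file.path(dir, paste0(stem, "_", pol, ".csv"))
    readr::write_csv(sub, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname export_schedule
#' @param paths Files previously written by `export_schedule()`.
#' @export
read_schedule <- function(paths) {
  out <- dplyr::bind_rows(lapply(paths, readr::read_csv,
                                 show_col_types = FALSE))
  class(out) <- c("smrm_schedule", class(out))
  out
}
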