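# ECN retention-time model: within a subclass, relative retention time is
# a quadratic in relative carbon number, y = a + b*x + c*x^2 with
# x = CN / CN_max and y = RT / gradient length. Added unsaturation shifts
# the curve down, so fits are stratified by double-bond count.

#' Fit the ECN quadratic retention model
#'
#' Fits ordinary least squares of relative RT on relative carbon number,
#' one curve per (subclass, double-bond count) stratum. `CN_max` is the
#' largest calibrated carbon number of the subclass, keeping x in (0, 1].
#' Strata with fewer than 3 distinct carbon numbers fall back to the
#' subclass's saturated curve plus a constant RT offset estimated from the
#' stratum's points.
#'
#' @param calibration A tibble of calibration points with columns
#'   `subclass`, `cn` (total acyl carbons), `double_bonds`, `rt_min`, and
#'   optionally `source`.
#' @param gradient_minutes LC gradient length used to normalize RT
#'   (default 17, the total runtime of the 17-min reverse-phase method).
#' @param pool_double_bonds If `TRUE`, fit one curve per subclass pooling
#'   all unsaturation levels.
#' @return An object of class `ecn_model`; see [tidy.ecn_model()] and
#'   [predict_rt()].
#' @export
fit_ecn <- function(calibration, gradient_minutes = 17,
                    pool_double_bonds = FALSE) {
  req <- c("subclass", "cn", "double_bonds", "rt_min")
  miss <- setdiff(req, names(calibration))
  if (length(miss) > 0) {
    abort(paste0("calibration is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(calibration) == 0) {
    abort("no calibration points: no stratum has 3 distinct carbon numbers")
  }
  if (any(calibration$rt_min <= 0 | calibration$rt_min > gradient_minutes)) {
    abort("calibration RTs must lie in (0, gradient_minutes]")
  }
  cal <- calibration
  if (pool_double_bonds) cal$double_bonds <- 0L

  fit_one <- function(df, cn_max) {
    if (length(unique(df$cn)) < 3) return(NULL)
    x <- df$cn / cn_max
    y <- df$rt_min / gradient_minutes
    if (stats::sd(df$cn) == 0) abort("all carbon numbers equal: cannot fit")
    fit <- stats::lm(y ~ x + I(x^2))
    co <- unname(stats::coef(fit))
    r2 <- if (stats::var(y) == 0) 1 else
      suppressWarnings(summary(fit)$r.squared)
    list(a = co[1], b = co[2], c = co[3], r_squared = r2, n = nrow(df),
         cn_min = min(df$cn), cn_max_seen = max(df$cn))
  }

  strata <- list()
  for (sc in unique(cal$subclass)) {
    sub <- cal[cal$subclass == sc, ]
    cn_max <- max(sub$cn)
    fits <- list()
    for (db in sort(unique(sub$double_bonds))) {
      df <- sub[sub$double_bonds == db, ]
      f <- fit_one(df, cn_max)
      fits[[as.character(db)]] <- list(df = df, fit = f)
    }
    # fall back to the saturated curve plus a constant offset for thin strata
    base <- NULL
    for (db in names(fits)) {
      if (!is.null(fits[[db]]$fit)) { base <- fits[[db]]$fit; break }
    }
    for (db in names(fits)) {
      f <- fits[[db]]$fit
      df <- fits[[db]]$df
      if (is.null(f)) {
        if (is.null(base)) {
          abort(paste0("subclass ", sc,
                       ": no stratum has 3 distinct carbon numbers"))
        }
        x <- df$cn / cn_max
        pred <- gradient_minutes * (base$a + base$b * x + base$c * x^2)
        off <- mean(df$rt_min - pred)
        strata[[length(strata) + 1]] <- tibble(
          subclass = sc, double_bonds = as.integer(db),
          a = base$a + off / gradient_minutes, b = base$b, c = base$c,
          cn_max = cn_max, r_squared = NA_real_, n = nrow(df),
          cn_min_seen = min(df$cn), cn_max_seen = max(df$cn),
          fallback = TRUE
        )
      } else {
        strata[[length(strata) + 1]] <- tibble(
          subclass = sc, double_bonds = as.integer(db),
          a = f$a, b = f$b, c = f$c, cn_max = cn_max,
          r_squared = f$r_squared, n = f$n,
          cn_min_seen = f$cn_min, cn_max_seen = f$cn_max_seen,
          fallback = FALSE
        )
      }
    }
  }
  structure(list(strata = dplyr::bind_rows(strata),
                 gradient_minutes = gradient_minutes,
                 pooled = pool_double_bonds),
            class = "ecn_model")
}

#' @export
print.ecn_model <- function(x, ...) {
  cat("ECN retention model (", nrow(x$strata), " strata, gradient ",
      x$gradient_minutes, " min)\n", sep = "")
  print(x$strata, ...)
  invisible(x)
}

#' Predict retention times from an ECN model
#'
#' RT = gradient * (a + b*x + c*x^2) with x = CN / CN_max of the species'
#' stratum. Predictions more than 4 carbons outside the calibrated carbon
#' range are still returned but flagged `extrapolated`.
#'
#' @param model An `ecn_model`.
#' @param species A tibble with columns `subclass`, `cn` (or
#'   `total_carbons`) and `double_bonds` (or `total_double_bonds`).
#' @return `species` with `rt_pred` (min) and `extrapolated` added.
#' @export
predict_rt <- function(model, species) {
  stopifnot(inherits(model, "ecn_model"))
  sp <- species
  if (!"cn" %in% names(sp) && "total_carbons" %in% names(sp)) {
    sp$cn <- sp$total_carbons
  }
  if (!"double_bonds" %in% names(sp) && "total_double_bonds" %in% names(sp)) {
    sp$double_bonds <- sp$total_double_bonds
  }
  db_key <- if (model$pooled) rep(0L, nrow(sp)) else sp$double_bonds
  strata <- model$strata
  rt <- rep(NA_real_, nrow(sp))
  extra <- rep(NA, nrow(sp))
  for (i in seq_len(nrow(sp))) {
    row <- strata[strata$subclass == sp$subclass[i] &
                    strata$double_bonds == db_key[i], ]
    if (nrow(row) == 0) {
      # nearest stratum of the same subclass by double-bond distance
      cand <- strata[strata$subclass == sp$subclass[i], ]
      if (nrow(cand) == 0) next
      row <- cand[which.min(abs(cand$double_bonds - db_key[i])), ]
    }
    x <- sp$cn[i] / row$cn_max
    rt[i] <- model$gradient_minutes * (row$a + row$b * x + row$c * x^2)
    extra[i] <- sp$cn[i] < row$cn_min_seen - 4 || sp$cn[i] > row$cn_max_seen + 4
  }
  sp$rt_pred <- rt
  sp$extrapolated <- extra
  sp
}

#' Compare predicted and observed retention times
#'
#' Pairs predictions with observations by species name, reports |delta RT|
#' per species, its empirical cumulative distribution, and the fraction
#' exceeding the flagging threshold; species above the threshold are
#' flagged for scheduling-window widening.
#'
#' @param predicted Tibble with `name` and `rt_pred`.
#' @param observed Tibble with `name` and `rt_min`.
#' @param flag_min Deviation threshold in minutes (default 0.5, the
#'   worst-case prediction error the model is designed for).
#' @return A list of class `rt_deviation_report`: `deviations` tibble
#'   (name, rt_pred, rt_min, abs_dev, flagged), `ecdf` function,
#'   `frac_exceeding`, `max_dev`, `n_unmatched`.
#' @export
rt_deviation_report <- function(predicted, observed, flag_min = 0.5) {
  joined <- dplyr::inner_join(predicted[, c("name", "rt_pred")],
                              observed[, c("name", "rt_min")], by = "name")
  n_unmatched <- (nrow(predicted) - nrow(joined)) +
    (nrow(observed) - nrow(joined))
  if (n_unmatched > 0) {
    warning(n_unmatched, " unmatched species ignored", call. = FALSE)
  }
  dev <- joined |>
    dplyr::mutate(abs_dev = abs(.data$rt_pred - .data$rt_min),
                  flagged = .data$abs_dev > flag_min)
  structure(list(
    deviations = dev,
    ecdf = if (nrow(dev) > 0) stats::ecdf(dev$abs_dev) else NULL,
    frac_exceeding = if (nrow(dev) > 0) mean(dev$flagged) else NA_real_,
    max_dev = if (nrow(dev) > 0) max(dev$abs_dev) else NA_real_,
    n_unmatched = n_unmatched
  ), class = "rt_deviation_report")
}

#' @export
print.rt_deviation_report <- function(x, ...) {
  cat("RT deviation report: ", nrow(x$deviations), " species, max |dRT| ",
      round(x$max_dev, 3), " min, ", round(100 * x$frac_exceeding, 1),
      "% above threshold\n", sep = "")
  invisible(x)
}

#' Tidy an ECN model
#'
#' @param x An `ecn_model`.
#' @param ... Unused.
#' @return One row per stratum and coefficient (broom convention).
#' @export
tidy.ecn_model <- function(x, ...) {
  x$strata |>
    tidyr::pivot_longer(cols = c("a", "b", "c"), names_to = "term",
                        values_to = "estimate") |>
    dplyr::select("subclass", "double_bonds", "term", "estimate")
}

#' Summarise ECN model fit quality
#'
#' @param x An `ecn_model`.
#' @param ... Unused.
#' @return One row per stratum with `r.squared`, `nobs` and the calibrated
#'   carbon range.
#' @export
glance.ecn_model <- function(x, ...) {
  x$strata |>
    dplyr::transmute(.data$subclass, .data$double_bonds,
                     r.squared = .data$r_squared, nobs = .data$n,
                     cn_min = .data$cn_min_seen, cn_max = .data$cn_max_seen,
                     fallback = .data$fallback)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot an ECN model
#'
#' Calibration-range curves per stratum: relative carbon number against
#' predicted retention time.
#'
#' @param object An `ecn_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ecn_model <- function(object, ...) {
  grid <- object$strata |>
    dplyr::rowwise() |>
    dplyr::reframe(
      subclass = .data$subclass, double_bonds = .data$double_bonds,
      cn = seq(.data$cn_min_seen, .data$cn_max_seen, length.out = 50),
      rt = object$gradient_minutes *
        (.data$a + .data$b * (cn / .data$cn_max) +
           .data$c * (cn / .data$cn_max)^2)
    )
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$cn, y = .data$rt,
                                     colour = factor(.data$double_bonds))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~subclass, scales = "free") +
    ggplot2::labs(x = "carbon number", y = "predicted RT (min)",
                  colour = "double bonds") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
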