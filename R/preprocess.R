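# Differential pipeline: preprocessing, univariate tests, PCA, selection.

# long (component, sample, abundance) -> samples x species matrix
abundance_matrix <- function(abund) {
  wide <- abund |>
    dplyr::select("component", "sample", "abundance") |>
    tidyr::pivot_wider(names_from = "component", values_from = "abundance")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample
  m
}

matrix_to_long <- function(m) {
  tibble(sample = rep(rownames(m), ncol(m)),
         component = rep(colnames(m), each = nrow(m)),
         abundance = as.vector(m))
}

#' Preprocess an abundance table for multivariate statistics
#'
#' The standard metabolomics normalization chain: (1) drop the least
#' variable species by interquartile range (the lowest `iqr_drop_fraction`
#' of the IQR distribution), (2) log-transform, (3) Pareto-scale each
#' species: (x - mean) / sqrt(sd). After scaling every species has mean
#' zero across samples. Constant species (sd = 0) cannot be scaled and
#' are dropped with a reason.
#'
#' @param abund Long tibble (`component`, `sample`, `abundance`), strictly
#'   positive abundances (impute first; see [impute_halfmin()]).
#' @param iqr_drop_fraction Fraction of species removed by the IQR filter
#'   (default 0.1; 0 disables it).
#' @param log_base Base of the log transform (default 10).
#' @param pareto Apply Pareto scaling (default `TRUE`).
#' @return Long tibble of processed abundances; attributes `state`
#'   (character flags) and `dropped` (tibble of removed species with
#'   reasons).
#' @export
preprocess_abundance <- function(abund, iqr_drop_fraction = 0.1,
                                 log_base = 10, pareto = TRUE) {
  if (any(is.na(abund$abundance))) {
    abort("abundances contain missing cells; impute first")
  }
  if (any(abund$abundance <= 0)) {
    abort("abundances must be positive for the log transform")
  }
  dropped <- tibble(component = character(0), reason = character(0))

  iqrs <- abund |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(iqr = stats::IQR(.data$abundance), .groups = "drop")
  if (iqr_drop_fraction > 0 && nrow(iqrs) > 1) {
    n_drop <- floor(iqr_drop_fraction * nrow(iqrs))
    low <- iqrs$component[order(iqrs$iqr)][seq_len(n_drop)]
    dropped <- dplyr::bind_rows(dropped,
                                tibble(component = low, reason = "low IQR"))
    abund <- dplyr::filter(abund, !.data$component %in% low)
  }

  out <- abund |>
    dplyr::mutate(abundance = log(.data$abundance, base = log_base))

  if (pareto) {
    sds <- out |>
      dplyr::group_by(.data$component) |>
      dplyr::summarise(s = sd(.data$abundance), .groups = "drop")
    const <- sds$component[sds$s == 0]
    if (length(const) > 0) {
      dropped <- dplyr::bind_rows(
        dropped, tibble(component = const, reason = "constant"))
      out <- dplyr::filter(out, !.data$component %in% const)
    }
    out <- out |>
      dplyr::group_by(.data$component) |>
      dplyr::mutate(abundance = (.data$abundance - mean(.data$abundance)) /
                      sqrt(sd(.data$abundance))) |>
      dplyr::ungroup()
  }
  attr(out, "state") <- c(
    if (iqr_drop_fraction > 0) "iqr-filtered",
    "logged",
    if (pareto) "pareto-scaled")
  attr(out, "dropped") <- dropped
  out
}

#' Welch tests and fold changes per species
#'
#' Two-sided Welch two-sample t-test (unequal variances) on the processed
#' abundances, Bonferroni-adjusted P, and the fold change computed on the
#' raw (pre-log) group means as mean(g2) / mean(g1).
#'
#' @param raw Long tibble of raw (IS-normalized, unlogged) abundances.
#' @param processed Long tibble from [preprocess_abundance()].
#' @param design Tibble with `sample` and `group`.
#' @param g1,g2 Group labels to compare (FC is g2 over g1).
#' @return Per-species tibble: `component`, `t`, `df`, `p`, `p_adj`, `fc`.
#' @export
welch_fc <- function(raw, processed, design, g1, g2) {
  des <- design[design$group %in% c(g1, g2), ]
  if (min(table(des$group)) < 3) abort("both groups need >= 3 samples")
  proc <- dplyr::inner_join(processed, des, by = "sample")
  rawj <- dplyr::inner_join(raw, des, by = "sample")

  test_one <- function(df) {
    x <- df$abundance[df$group == g1]
    y <- df$abundance[df$group == g2]
    if (sd(x) == 0 && sd(y) == 0) {
      if (isTRUE(all.equal(mean(x), mean(y)))) {
        return(tibble(t = 0, df = NA_real_, p = 1))
      }
      return(tibble(t = Inf * sign(mean(y) - mean(x)), df = NA_real_, p = 0))
    }
    tt <- stats::t.test(y, x, var.equal = FALSE)
    tibble(t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value)
  }
  tests <- proc |>
    dplyr::group_by(.data$component) |>
    dplyr::group_modify(~ test_one(.x)) |>
    dplyr::ungroup()
  fcs <- rawj |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(
      fc = mean(.data$abundance[.data$group == g2]) /
        mean(.data$abundance[.data$group == g1]),
      .groups = "drop")
  tests |>
    dplyr::mutate(p_adj = stats::p.adjust(.data$p, method = "bonferroni")) |>
    dplyr::left_join(fcs, by = "component") |>
    dplyr::select("component", "t", "df", "p", "p_adj", "fc")
}

#' PCA sample scores
#'
#' Centered singular-value decomposition of the processed samples-by-
#' species matrix. Score signs follow a fixed convention (the largest-
#' magnitude loading of each component is positive) so results are
#' reproducible across platforms.
#'
#' @param processed Long tibble from [preprocess_abundance()].
#' @param n_components Number of components to return (capped at the
#'   matrix rank, with a warning).
#' @return A list: `scores` tibble (sample x PC), `explained` variance
#'   fractions, `loadings` matrix.
#' @export
pca_scores <- function(processed, n_components = 2) {
  m <- abundance_matrix(processed)
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > 1e-12)
  if (n_components > rank) {
    warning("n_components exceeds rank (", rank, "); capped", call. = FALSE)
    n_components <- rank
  }
  keep <- seq_len(n_components)
  flip <- vapply(keep, function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x[, keep, drop = FALSE], 2, flip, `*`)
  loadings <- sweep(pc$rotation[, keep, drop = FALSE], 2, flip, `*`)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(
    scores = tibble(sample = rownames(m)) |>
      dplyr::bind_cols(tibble::as_tibble(scores)),
    explained = expl[keep],
    loadings = loadings
  )
}

#' Select differential species
#'
#' Applies the study's selection rules to a joined result table:
#' * differential rule: raw P < `p_max`, VIP > `vip_min` and
#'   direction-agnostic fold change `max(FC, 1/FC) >= fc_min` (default
#'   1.2, i.e. at least a 20% shift either way);
#' * volcano rule: `max(FC, 1/FC) >= volcano_fc` and P < `volcano_p`
#'   (defaults 2 and 0.1), with the up/down direction taken from FC.
#'
#' @param results Tibble with `component`, `p`, `p_adj`, `fc`, `vip`.
#' @param p_max,vip_min,fc_min Differential-rule thresholds.
#' @param volcano_fc,volcano_p Volcano-rule thresholds.
#' @param use_adjusted Select on Bonferroni-adjusted P instead of raw P.
#' @return `results` with `differential`, `volcano` and `direction`
#'   columns added.
#' @export
select_differential <- function(results, p_max = 0.05, vip_min = 1,
                                fc_min = 1.2, volcano_fc = 2,
                                volcano_p = 0.1, use_adjusted = FALSE) {
  pcol <- if (use_adjusted) results$p_adj else results$p
  fc_mag <- pmax(results$fc, 1 / results$fc)
  results |>
    dplyr::mutate(
      differential = pcol < p_max & .data$vip > vip_min & fc_mag >= fc_min,
      volcano = fc_mag >= volcano_fc & pcol < volcano_p,
      direction = dplyr::if_else(.data$fc >= 1, "up", "down")
    )
}

#' Venn intersection of two differential sets
#'
#' @param set1,set2 Character vectors of species names.
#' @return A named list: `only1`, `only2`, `both`.
#' @export
venn_sets <- function(set1, set2) {
  list(only1 = setdiff(set1, set2),
       only2 = setdiff(set2, set1),
       both = intersect(set1, set2))
}
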