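# Synthetic-data generator: internal-standard panels, ECN calibration
# points, and a three-group tissue study (distant normal / adjacent /
# tumor) with planted TAG and phospholipid effects, QC replicate
# injections and blanks. All randomness flows from the single config seed.

# Per-subclass instrument defaults inherited by matched species.
.IS_PARAMS <- tibble::tribble(
  ~subclass, ~ce, ~dp, ~dwell_ms,
  "TAG", 45, 100, 5, "DAG", 35, 80, 5, "MAG", 25, 60, 5,
  "PA", -42, -90, 5, "PC", -45, -100, 5, "PE", -45, -90, 5,
  "PG", -42, -90, 5, "PI", -48, -100, 5, "PS", -45, -90, 5,
  "LPC", -35, -80, 5, "LPE", -35, -80, 5,
  "SM", 30, 90, 5, "Cer", 32, 80, 5, "dhCer", 32, 80, 5,
  "HexCer", 38, 90, 5, "LacCer", 42, 90, 5, "FFA", -15, -60, 5
)

default_ecn_truth <- function(subclasses, gradient_minutes = 17) {
  arity <- vapply(subclasses, function(s) subclass_info(s)$arity, integer(1))
  tibble(
    subclass = subclasses,
    a = -0.5, b = 1.8, c = -0.4,
    cn_min = 13L * arity, cn_max = 23L * arity,
    unsat_offset_min = 0.4
  )
}

#' Simulation configuration
#'
#' Fixes the study conditions the generator emulates: a three-group colon
#' tissue design (CC-A distant normal, CC-B adjacent, CC-C tumor; 12
#' samples each), 10 QC injections with 7% multiplicative instrument
#' noise, solvent blanks at a small fraction of the study signal, ECN
#' retention curves with RT noise of 1% of the 17-min gradient, and
#' planted two-fold effects: a TAG subset up in CC-B, a phospholipid
#' subset down in CC-B, against both neighbouring groups.
#'
#' @param seed Single RNG seed driving every draw.
#' @param groups Group labels.
#' @param n_per_group Samples per group.
#' @param n_qc QC injections.
#' @param qc_sigma Log-scale sd of QC multiplicative noise.
#' @param blank_fraction Blank signal as a fraction of the study baseline.
#' @param rt_noise_sd RT noise sd in minutes (0.17 = 1% of gradient).
#' @param gradient_minutes LC gradient length.
#' @param bio_sigma Log-scale sd of biological variation across samples.
#' @param drift_sigma Log-scale sd of the per-injection drift factor
#'   shared by analytes and internal standards.
#' @param n_planted_tag,n_planted_pl Planted TAG (up) and phospholipid
#'   (down) species counts.
#' @param planted_fold Planted fold change in CC-B.
#' @param ecn_truth Per-subclass true curve coefficients
#'   (`subclass`, `a`, `b`, `c`, `cn_min`, `cn_max`, `unsat_offset_min`).
#' @param is_points_saturated,is_points_unsat Calibration points per
#'   saturated / unsaturated stratum.
#' @return A list of class `ol_sim_config`.
#' @export
sim_config <- function(seed = 20230529,
                       groups = c("CC-A", "CC-B", "CC-C"),
                       n_per_group = 12,
                       n_qc = 10, qc_sigma = 0.07,
                       blank_fraction = 0.05,
                       rt_noise_sd = 0.17,
                       gradient_minutes = 17,
                       bio_sigma = 0.35,
                       drift_sigma = 0.05,
                       n_planted_tag = 25, n_planted_pl = 25,
                       planted_fold = 2,
                       ecn_truth = NULL,
                       is_points_saturated = 12,
                       is_points_unsat = 5) {
  if (planted_fold <= 0) abort("planted_fold must be positive")
  structure(list(
    seed = seed, groups = groups, n_per_group = n_per_group,
    n_qc = n_qc, qc_sigma = qc_sigma, blank_fraction = blank_fraction,
    rt_noise_sd = rt_noise_sd, gradient_minutes = gradient_minutes,
    bio_sigma = bio_sigma, drift_sigma = drift_sigma,
    n_planted_tag = n_planted_tag, n_planted_pl = n_planted_pl,
    planted_fold = planted_fold,
    ecn_truth = ecn_truth %||%
      default_ecn_truth(lipid_subclasses()$subclass),
    is_points_saturated = is_points_saturated,
    is_points_unsat = is_points_unsat
  ), class = "ol_sim_config")
}

ecn_truth_rt <- function(truth_row, cn, db, gradient_minutes) {
  x <- cn / truth_row$cn_max
  gradient_minutes * (truth_row$a + truth_row$b * x + truth_row$c * x^2) -
    db * truth_row$unsat_offset_min
}

#' Simulate an internal-standard panel and its calibration points
#'
#' Per subclass in `subclasses`, places IS species along the true ECN
#' curve of each double-bond stratum and adds Gaussian RT noise.
#' Instrument parameters come from fixed per-subclass defaults.
#'
#' @param config An [sim_config()].
#' @param subclasses Subclasses to cover (default: all in the config's
#'   truth table).
#' @return A list: `is_panel` tibble (`is_id`, `subclass`,
#'   `total_carbons`, `total_double_bonds`, `rt_min`, `ce`, `dp`,
#'   `dwell_ms`), `calibration` tibble for [fit_ecn()].
#' @export
simulate_is_panel <- function(config = sim_config(),
                              subclasses = config$ecn_truth$subclass) {
  stopifnot(inherits(config, "ol_sim_config"))
  with_seed(config$seed, {
    rows <- list()
    for (sc in subclasses) {
      tr <- config$ecn_truth[config$ecn_truth$subclass == sc, ]
      if (nrow(tr) == 0) abort(paste0("no ECN truth for subclass ", sc))
      for (db in 0:2) {
        n_pts <- if (db == 0) config$is_points_saturated else
          config$is_points_unsat
        cn <- unique(round(seq(tr$cn_min, tr$cn_max, length.out = n_pts)))
        rt <- ecn_truth_rt(tr, cn, db, config$gradient_minutes) +
          stats::rnorm(length(cn), 0, config$rt_noise_sd)
        rt <- pmin(pmax(rt, 0.1), config$gradient_minutes)
        rows[[length(rows) + 1]] <- tibble(
          subclass = sc, cn = cn, double_bonds = db, rt_min = rt)
      }
    }
    calib <- dplyr::bind_rows(rows)
    calib$source <- "IS"
    params <- .IS_PARAMS
    is_panel <- calib |>
      dplyr::left_join(params, by = "subclass") |>
      dplyr::mutate(
        is_id = paste0("IS ", .data$subclass, " ", .data$cn, ":",
                       .data$double_bonds, "(d7)"),
        total_carbons = .data$cn,
        total_double_bonds = .data$double_bonds
      ) |>
      dplyr::select("is_id", "subclass", "total_carbons",
                    "total_double_bonds", "rt_min", "ce", "dp", "dwell_ms")
    list(is_panel = is_panel, calibration = calib)
  })
}

#' Compact study library used by the simulator defaults
#'
#' TAG from the odd 15/17/19-carbon pool (0-1 double bonds) and PC/PE/PI
#' phospholipids mixing odd 15/17 chains with even 16/18 partners: a
#' realistic odd-chain panel small enough for fast closed-loop tests.
#'
#' @return A library tibble.
#' @export
default_study_library <- function() {
  tag <- enumerate_odd_library(library_config(
    "TAG", odd_carbons = c(15L, 17L, 19L), even_carbons = integer(0),
    double_bonds = 0:1))
  pl <- enumerate_odd_library(library_config(
    c("PC", "PE", "PI"), odd_carbons = c(15L, 17L),
    even_carbons = c(16L, 18L), double_bonds = 0:1))
  dplyr::bind_rows(tag, pl)
}

#' Simulate a three-group study peak table
#'
#' Generates study, QC and blank injections for every species of the
#' library. Species areas are log-normal around a species baseline with
#' per-sample biological noise, multiplied by the planted group fold and
#' a per-injection drift factor shared with the matched internal standard
#' (so IS normalization cancels the drift). QC injections carry only the
#' multiplicative instrument noise around the pooled mean; blanks sit at
#' `blank_fraction` of the baseline. Retention times follow the subclass
#' ECN curve plus noise; FWHM is uniform on 0.1-0.7 min.
#'
#' @param config An [sim_config()].
#' @param library A library tibble (default [default_study_library()]).
#' @return A list: `peaks` (peak-table tibble including IS rows), `design`
#'   (`sample`, `group`), `is_assignments` (`component`,
#'   `is_component`), `is_panel`, `calibration`, `truth` (per-species
#'   planted status and per-group fold), `rt_true`.
#' @export
simulate_study <- function(config = sim_config(),
                           library = default_study_library()) {
  stopifnot(inherits(config, "ol_sim_config"))
  if (nrow(library) == 0) abort("library is empty")
  panel <- simulate_is_panel(
    config, subclasses = unique(library$subclass))

  with_seed(config$seed + 1, {
    n_spec <- nrow(library)
    lib <- assign_acquisition_params(library, panel$is_panel)
    lib$is_component <- lib$is_id

    # planted effects: TAG subset up in CC-B, phospholipid subset down
    tag_idx <- which(lib$subclass == "TAG")
    pl_idx <- which(subclass_info_vec(lib$subclass) == "glycerophospholipid")
    up <- sample(tag_idx, min(config$n_planted_tag, length(tag_idx)))
    down <- sample(pl_idx, min(config$n_planted_pl, length(pl_idx)))
    effect <- rep("null", n_spec)
    effect[up] <- "up_in_B"
    effect[down] <- "down_in_B"

    fold_b <- dplyr::case_when(
      effect == "up_in_B" ~ config$planted_fold,
      effect == "down_in_B" ~ 1 / config$planted_fold,
      TRUE ~ 1)
    group_fold <- matrix(1, n_spec, length(config$groups),
                         dimnames = list(NULL, config$groups))
    if ("CC-B" %in% config$groups) group_fold[, "CC-B"] <- fold_b

    baseline <- stats::rlnorm(n_spec, meanlog = log(1e5), sdlog = 1)
    truth <- tibble(component = lib$name, subclass = lib$subclass,
                    effect = effect, fold_ccb = fold_b,
                    baseline = baseline)

    # true RTs along the subclass ECN curve
    rt_true <- vapply(seq_len(n_spec), function(i) {
      tr <- config$ecn_truth[config$ecn_truth$subclass == lib$subclass[i], ]
      ecn_truth_rt(tr, lib$total_carbons[i], lib$total_double_bonds[i],
                   config$gradient_minutes)
    }, numeric(1))
    rt_true <- pmin(pmax(rt_true, 0.1), config$gradient_minutes)

    design <- tibble(
      sample = paste0(rep(config$groups, each = config$n_per_group), "_",
                      sprintf("%02d", seq_len(config$n_per_group))),
      group = rep(config$groups, each = config$n_per_group)
    )
    samples_qc <- paste0("QC_", sprintf("%02d", seq_len(config$n_qc)))
    samples_blank <- c("BLANK_01", "BLANK_02")
    all_samples <- c(design$sample, samples_qc, samples_blank)
    roles <- c(rep("study", nrow(design)), rep("QC", config$n_qc),
               rep("blank", length(samples_blank)))
    drift <- stats::rlnorm(length(all_samples), 0, config$drift_sigma)

    is_tbl <- dplyr::distinct(
      panel$is_panel[panel$is_panel$is_id %in% lib$is_component, ])
    is_baseline <- stats::rlnorm(nrow(is_tbl), meanlog = log(5e4),
                                 sdlog = 0.3)

    peak_rows <- vector("list", length(all_samples))
    pooled_mean <- baseline *
      rowMeans(group_fold[, design$group, drop = FALSE])
    for (s in seq_along(all_samples)) {
      role <- roles[s]
      if (role == "study") {
        g <- design$group[s]
        area <- baseline * group_fold[, g] *
          stats::rlnorm(n_spec, 0, config$bio_sigma) * drift[s]
        sn <- stats::runif(n_spec, 20, 200)
      } else if (role == "QC") {
        area <- pooled_mean * stats::rlnorm(n_spec, 0, config$qc_sigma) *
          drift[s]
        sn <- stats::runif(n_spec, 20, 200)
      } else {
        area <- baseline * config$blank_fraction *
          stats::rlnorm(n_spec, 0, config$qc_sigma)
        sn <- stats::runif(n_spec, 1, 3)
      }
      rt <- rt_true + stats::rnorm(n_spec, 0, config$rt_noise_sd)
      spec_rows <- tibble(
        sample = all_samples[s], role = role, component = lib$name,
        subclass = lib$subclass, area = area, rt = rt,
        fwhm = stats::runif(n_spec, 0.1, 0.7), sn = sn)
      is_area <- if (role == "blank") is_baseline else is_baseline * drift[s]
      is_rows <- tibble(
        sample = all_samples[s], role = role, component = is_tbl$is_id,
        subclass = is_tbl$subclass, area = is_area,
        rt = is_tbl$rt_min, fwhm = stats::runif(nrow(is_tbl), 0.1, 0.7),
        sn = stats::runif(nrow(is_tbl), 50, 200))
      peak_rows[[s]] <- dplyr::bind_rows(spec_rows, is_rows)
    }
    peaks <- dplyr::bind_rows(peak_rows)

    list(
      peaks = peaks,
      design = design,
      is_assignments = tibble(component = lib$name,
                              is_component = lib$is_component),
      is_panel = panel$is_panel,
      calibration = panel$calibration,
      truth = truth,
      rt_true = tibble(component = lib$name, rt_true = rt_true)
    )
  })
}

subclass_info_vec <- function(subclass) {
  lipid_subclasses()$category[match(subclass, lipid_subclasses()$subclass)]
}

#' Write simulated fixtures to disk
#'
#' Writes the IS panel, calibration table, peak table and design table in
#' the delimited dialects the other modules read; the round trip restores
#' equal tables.
#'
#' @param sim Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_fixtures <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    is_panel = file.path(dir, "is_panel.csv"),
    calibration = file.path(dir, "calibration.csv"),
    peaks = file.path(dir, "peaks.csv"),
    design = file.path(dir, "design.csv")
  )
  readr::write_csv(sim$is_panel, paths["is_panel"])
  readr::write_csv(sim$calibration, paths["calibration"])
  readr::write_csv(sim$peaks, paths["peaks"])
  readr::write_csv(sim$design, paths["design"])
  invisible(paths)
}
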