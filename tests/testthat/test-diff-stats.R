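test_that("preprocessing chains IQR filter, log and Pareto scaling", {
  # logs of (10, 100, 1000) are (1, 2, 3): sd 1, so Pareto gives (-1, 0, 1)
  ab <- tibble::tibble(
    component = "x", sample = paste0("S", 1:3), role = "study",
    abundance = c(10, 100, 1000))
  out <- preprocess_abundance(ab, iqr_drop_fraction = 0, log_base = 10)
  expect_equal(out$abundance, c(-1, 0, 1), tolerance = 1e-12)

  # every species row is centered after scaling
  set.seed(5)
  m <- matrix(rlnorm(200, log(100), 1), nrow = 10,
              dimnames = list(paste0("S", 1:10), paste0("sp", 1:20)))
  long <- make_long(m)
  proc <- preprocess_abundance(long, iqr_drop_fraction = 0.1)
  means <- proc |>
    dplyr::group_by(component) |>
    dplyr::summarise(m = mean(abundance))
  expect_true(all(abs(means$m) < 1e-12))
  expect_equal(dplyr::n_distinct(proc$component), 18)  # 10% of 20 dropped
  expect_setequal(attr(proc, "state"),
                  c("iqr-filtered", "logged", "pareto-scaled"))

  # constant species cannot be Pareto-scaled
  const <- dplyr::bind_rows(long, tibble::tibble(
    component = "const", sample = paste0("S", 1:10), abundance = 5))
  proc2 <- preprocess_abundance(const, iqr_drop_fraction = 0)
  expect_false("const" %in% proc2$component)
  expect_true("const" %in% attr(proc2, "dropped")$component)

  expect_error(preprocess_abundance(dplyr::mutate(long, abundance = -1)),
               "positive")
  # iqr_drop_fraction 0 keeps the species count
  expect_equal(dplyr::n_distinct(
    preprocess_abundance(long, iqr_drop_fraction = 0)$component), 20)
})

test_that("Welch tests match the hand-computed oracle to 1e-10", {
  design <- tibble::tibble(sample = paste0("S", 1:12),
                           group = rep(c("g1", "g2"), each = 6))
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(rlnorm(12 * 15, log(50), 0.5), nrow = 12,
                dimnames = list(design$sample, paste0("sp", 1:15)))
    long <- make_long(m)
    res <- welch_fc(long, long, design, "g1", "g2")
    for (j in 1:15) {
      x <- m[design$group == "g1", j]
      y <- m[design$group == "g2", j]
      expect_equal(res$p[res$component == paste0("sp", j)],
                   oracle_welch_p(x, y), tolerance = 1e-10)
      expect_equal(res$fc[res$component == paste0("sp", j)],
                   mean(y) / mean(x), tolerance = 1e-12)
    }
    # Bonferroni is min(1, m * p) and non-decreasing in m
    expect_equal(res$p_adj, pmin(1, res$p * 15), tolerance = 1e-12)
  }
})

test_that("Welch edge cases: identical groups and exact fold changes", {
  design <- tibble::tibble(sample = paste0("S", 1:6),
                           group = rep(c("g1", "g2"), each = 3))
  same <- tibble::tibble(component = "x", sample = design$sample,
                         abundance = rep(c(10, 20, 30), 2))
  res <- welch_fc(same, same, design, "g1", "g2")
  expect_equal(res$p, 1)
  expect_equal(res$fc, 1)

  flat <- tibble::tibble(component = "y", sample = design$sample,
                         abundance = c(10, 10, 10, 20, 20, 20))
  res2 <- welch_fc(flat, flat, design, "g1", "g2")
  expect_equal(res2$fc, 2)
  expect_equal(res2$p, 0)  # zero variance, different means

  expect_error(welch_fc(same, same, design[1:5, ], "g1", "g2"), ">= 3")
})

test_that("PCA scores behave like a centered SVD", {
  set.seed(9)
  m <- matrix(rnorm(8 * 12), nrow = 8,
              dimnames = list(paste0("S", 1:8), paste0("sp", 1:12)))
  m[7, ] <- m[8, ]  # duplicated samples
  long <- make_long(exp(m))
  proc <- preprocess_abundance(long, iqr_drop_fraction = 0, log_base = exp(1))
  pc <- pca_scores(proc, 3)
  expect_equal(unlist(pc$scores[7, -1]), unlist(pc$scores[8, -1]),
               tolerance = 1e-9)
  expect_true(all(diff(pc$explained) <= 1e-12))

  # rank-1 matrix: first component explains everything
  r1 <- outer(1:6, seq(0.5, 2, length.out = 5))
  rownames(r1) <- paste0("S", 1:6); colnames(r1) <- paste0("sp", 1:5)
  pr <- pca_scores(make_long(r1), 1)
  expect_equal(pr$explained[1], 1, tolerance = 1e-9)

  expect_warning(pca_scores(proc, 99), "capped")
})

test_that("VIP identity holds and informative species rank on top", {
  design <- tibble::tibble(sample = paste0("S", 1:16),
                           group = rep(c("A", "B"), each = 8))
  set.seed(31)
  m <- matrix(rlnorm(16 * 40, log(100), 0.3), nrow = 16,
              dimnames = list(design$sample, paste0("sp", 1:40)))
  m[design$group == "B", 1] <- m[design$group == "B", 1] * 4  # planted
  proc <- preprocess_abundance(make_long(m), iqr_drop_fraction = 0)
  fit <- plsda_vip(proc, design, "A", "B", ncomp = 2)
  p <- nrow(fit$vip)
  expect_equal(sum(fit$vip$vip^2), p, tolerance = 1e-6)
  expect_equal(fit$vip$component[which.max(fit$vip$vip)], "sp1")
  expect_gt(max(fit$vip$vip), 1)
  # scores orthogonal across components
  expect_lt(abs(crossprod(fit$scores[, 1], fit$scores[, 2])), 1e-8)
  # weights unit norm
  expect_equal(colSums(fit$weights^2), rep(1, fit$ncomp), tolerance = 1e-9,
               ignore_attr = TRUE)
  gl <- glance(fit)
  expect_gt(gl$r2y, 0.5)
  td <- tidy(fit)
  expect_equal(nrow(td), p)
})

test_that("Q2 collapses to noise level under permuted labels", {
  design <- tibble::tibble(sample = paste0("S", 1:16),
                           group = rep(c("A", "B"), each = 8))
  set.seed(13)
  m <- matrix(rlnorm(16 * 30, log(100), 0.3), nrow = 16,
              dimnames = list(design$sample, paste0("sp", 1:30)))
  proc <- preprocess_abundance(make_long(m), iqr_drop_fraction = 0)
  q2 <- vapply(1:50, function(s) {
    des_p <- design
    set.seed(1000 + s)
    des_p$group <- sample(des_p$group)
    fit <- plsda_vip(proc, des_p, "A", "B", ncomp = 1, cv_seed = s)
    fit$q2
  }, numeric(1))
  expect_lte(mean(q2), 0.05)
})

test_that("VIP agrees with an independent PLS-DA implementation", {
  design <- tibble::tibble(sample = paste0("S", 1:20),
                           group = rep(c("A", "B"), each = 10))
  set.seed(17)
  m <- matrix(rlnorm(20 * 25, log(100), 0.3), nrow = 20,
              dimnames = list(design$sample, paste0("sp", 1:25)))
  m[design$group == "B", 1:3] <- m[design$group == "B", 1:3] * 3
  proc <- preprocess_abundance(make_long(m), iqr_drop_fraction = 0)
  fit <- plsda_vip(proc, design, "A", "B", ncomp = 1)

  X <- matrix(proc$abundance[order(match(proc$sample, design$sample),
                                   match(proc$component, fit$vip$component))],
              nrow = 20, byrow = TRUE,
              dimnames = list(design$sample, fit$vip$component))
  ref <- mixOmics::plsda(X, factor(design$group), ncomp = 1, scale = FALSE)
  ref_vip <- mixOmics::vip(ref)[fit$vip$component, 1]
  expect_gt(cor(fit$vip$vip, ref_vip), 0.999)
  # same species called important (VIP > 1) by both routes
  expect_equal(fit$vip$vip > 1, unname(ref_vip > 1))
})

test_that("S-plot and SUS-plot coordinates behave geometrically", {
  design <- tibble::tibble(sample = paste0("S", 1:16),
                           group = rep(c("A", "B"), each = 8))
  set.seed(23)
  m <- matrix(rlnorm(16 * 20, log(100), 0.3), nrow = 16,
              dimnames = list(design$sample, paste0("sp", 1:20)))
  m[design$group == "B", 1] <- m[design$group == "B", 1] * 5
  proc <- preprocess_abundance(make_long(m), iqr_drop_fraction = 0)
  fit <- plsda_vip(proc, design, "A", "B", ncomp = 1)
  sp <- splot_coords(fit)
  expect_true(all(abs(sp$corr_t1) <= 1 + 1e-9))

  # a species proportional to t1 itself has correlation 1
  X2 <- fit$X
  X2 <- cbind(X2, t1copy = fit$scores[, 1])
  fit2 <- fit; fit2$X <- X2
  sp2 <- splot_coords(fit2)
  expect_equal(unname(abs(sp2$corr_t1[sp2$component == "t1copy"])), 1,
               tolerance = 1e-9)
  # orthogonal species: correlation near zero
  ortho <- residuals(lm(rnorm(16) ~ fit$scores[, 1]))
  fit3 <- fit; fit3$X <- cbind(fit$X, ortho = ortho)
  sp3 <- splot_coords(fit3)
  expect_lt(abs(sp3$corr_t1[sp3$component == "ortho"]), 1e-9)
})

test_that("opposite group effects land off-diagonal in the SUS plot", {
  groups <- rep(c("A", "B", "C"), each = 8)
  design <- tibble::tibble(sample = paste0("S", 1:24), group = groups)
  set.seed(29)
  m <- matrix(rlnorm(24 * 30, log(100), 0.25), nrow = 24,
              dimnames = list(design$sample, paste0("sp", 1:30)))
  # sp1 up in B vs both A and C (the TAG pattern)
  m[groups == "B", 1] <- m[groups == "B", 1] * 4
  proc <- preprocess_abundance(make_long(m), iqr_drop_fraction = 0)
  fit_ab <- plsda_vip(proc, design, "A", "B", ncomp = 1)
  fit_bc <- plsda_vip(proc, design, "B", "C", ncomp = 1)
  sus <- sus_coords(fit_ab, fit_bc)
  row <- sus[sus$component == "sp1", ]
  # up in comparison 1, down in comparison 2 (or the mirrored signs)
  expect_lt(row$corr1 * row$corr2, 0)
  expect_gt(abs(row$corr1), 0.5)
  expect_gt(abs(row$corr2), 0.5)
})

test_that("selection rules apply the P/VIP/FC thresholds and set arithmetic", {
  res <- tibble::tibble(
    component = c("a", "b", "c", "d"),
    p = c(0.04, 0.04, 0.2, 0.004),
    p_adj = c(0.16, 0.16, 0.8, 0.016),
    fc = c(1.3, 1.3, 3, 0.4),
    vip = c(1.5, 0.9, 1.2, 2))
  out <- select_differential(res)
  expect_true(out$differential[out$component == "a"])
  expect_false(out$differential[out$component == "b"])   # VIP fails
  expect_false(out$differential[out$component == "c"])   # P fails
  expect_true(out$differential[out$component == "d"])    # down-regulated
  expect_equal(out$direction, c("up", "up", "up", "down"))
  expect_false(out$volcano[out$component == "a"])        # FC below 2
  expect_true(out$volcano[out$component == "d"])         # 1/FC = 2.5

  adj <- select_differential(res, use_adjusted = TRUE)
  expect_false(adj$differential[adj$component == "a"])

  v <- venn_sets(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(v$both, c("b", "c"))
  expect_equal(v$only1, "a")
  expect_equal(v$only2, "d")
})
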