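# PLS-DA via NIPALS with VIP scores, cross-validated Q2, and the S-plot /
# SUS-plot coordinates used to read group-discriminating lipids.
#
# The discriminant model regresses a +/-1 class response on the processed
# abundance matrix. For a two-class model with a single predictive
# component this VIP ranking matches the orthogonally-filtered variant
# used by commercial software in practice; see the methods vignette.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

nipals_pls1 <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp); ss <- numeric(ncomp)
  Xd <- X; yd <- y
  achieved <- 0
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      warning("singular deflation: stopping at ", achieved, " component(s)",
              call. = FALSE)
      break
    }
    w <- w / nw
    t_a <- drop(Xd %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-12) {
      warning("singular deflation: stopping at ", achieved, " component(s)",
              call. = FALSE)
      break
    }
    p_a <- drop(crossprod(Xd, t_a)) / tt
    q_a <- sum(t_a * yd) / tt
    Xd <- Xd - tcrossprod(t_a, p_a)
    yd <- yd - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a
    q[a] <- q_a; ss[a] <- q_a^2 * tt
    achieved <- a
  }
  keep <- seq_len(achieved)
  list(W = W[, keep, drop = FALSE], P = P[, keep, drop = FALSE],
       scores = Tm[, keep, drop = FALSE], q = q[keep], ss = ss[keep],
       y_resid = yd, ncomp = achieved)
}

pls1_coef <- function(fit) {
  # regression vector B with y_hat = X B for centered X, y
  fit$W %*% solve(crossprod(fit$P, fit$W), fit$q)
}

#' Fit a PLS-DA model and compute VIP scores
#'
#' NIPALS partial least squares of a +/-1 group response on the processed
#' abundance matrix. Per-species variable importance in projection is
#' VIP_j = sqrt( p * sum_a SS_a w_ja^2 / sum_a SS_a ) with unit-norm
#' weight vectors w_a and SS_a the Y-variance explained by component a;
#' sum_j VIP_j^2 = p identically. Predictive power Q2 is estimated by
#' stratified 7-fold cross-validation with a fixed fold seed.
#'
#' @param processed Long tibble from [preprocess_abundance()].
#' @param design Tibble with `sample`, `group`.
#' @param g1,g2 The two class labels (`g1` is coded -1, `g2` +1).
#' @param ncomp Number of PLS components (capped at n - 1 and p).
#' @param cv_folds Cross-validation folds (default 7).
#' @param cv_seed Seed for the fold assignment (default 20230529).
#' @return An object of class `plsda_fit` with scores, weights, loadings,
#'   per-component explained Y-variance, `vip` tibble, `r2y`, `q2`.
#' @export
plsda_vip <- function(processed, design, g1, g2, ncomp = 2, cv_folds = 7,
                      cv_seed = 20230529) {
  des <- design[design$group %in% c(g1, g2), ]
  m <- abundance_matrix(dplyr::filter(processed,
                                      .data$sample %in% des$sample))
  des <- des[match(rownames(m), des$sample), ]
  y <- ifelse(des$group == g2, 1, -1)
  ncomp <- min(ncomp, nrow(m) - 1, ncol(m))
  Xc <- scale(m, center = TRUE, scale = FALSE)
  yc <- y - mean(y)

  fit <- nipals_pls1(Xc, yc, ncomp)
  p <- ncol(Xc)
  w2 <- fit$W^2
  vip <- sqrt(p * drop(w2 %*% fit$ss) / sum(fit$ss))
  r2y <- 1 - sum(fit$y_resid^2) / sum(yc^2)

  # stratified, seeded folds
  folds <- with_seed(cv_seed, {
    f <- integer(length(y))
    for (g in unique(des$group)) {
      idx <- which(des$group == g)
      f[idx] <- sample(rep(seq_len(cv_folds), length.out = length(idx)))
    }
    f
  })
  press <- 0
  for (k in sort(unique(folds))) {
    tr <- folds != k; te <- !tr
    if (sum(tr) < 3 || length(unique(y[tr])) < 2) next
    mu_x <- colMeans(m[tr, , drop = FALSE])
    mu_y <- mean(y[tr])
    ftr <- nipals_pls1(sweep(m[tr, , drop = FALSE], 2, mu_x),
                       y[tr] - mu_y, fit$ncomp)
    if (ftr$ncomp == 0) next
    b <- pls1_coef(ftr)
    yhat <- drop(sweep(m[te, , drop = FALSE], 2, mu_x) %*% b) + mu_y
    press <- press + sum((y[te] - yhat)^2)
  }
  q2 <- 1 - press / sum(yc^2)

  structure(list(
    scores = fit$scores, weights = fit$W, loadings = fit$P,
    q = fit$q, ss = fit$ss, ncomp = fit$ncomp,
    vip = tibble(component = colnames(m), vip = vip),
    r2y = r2y, q2 = q2,
    X = Xc, y = y, samples = rownames(m), groups = c(g1, g2)
  ), class = "plsda_fit")
}

#' @export
print.plsda_fit <- function(x, ...) {
  cat("PLS-DA (", x$ncomp, " component(s)): ", x$groups[1], " vs ",
      x$groups[2], "; R2Y = ", round(x$r2y, 3), ", Q2 = ",
      round(x$q2, 3), "\n", sep = "")
  invisible(x)
}

#' Tidy a PLS-DA fit
#'
#' @param x A `plsda_fit`.
#' @param ... Unused.
#' @return Per-species tibble with VIP and first-component weight.
#' @export
tidy.plsda_fit <- function(x, ...) {
  x$vip |>
    dplyr::mutate(weight1 = x$weights[, 1])
}

#' One-line PLS-DA model summary
#'
#' @param x A `plsda_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `ncomp`, `r2y`, `q2`, `nobs`.
#' @export
glance.plsda_fit <- function(x, ...) {
  tibble(ncomp = x$ncomp, r2y = x$r2y, q2 = x$q2, nobs = length(x$y))
}

#' S-plot coordinates of a PLS-DA model
#'
#' For each species, the covariance and the correlation of its (processed)
#' abundance with the first predictive score t1. High |covariance| with
#' high |correlation| marks reliable group-discriminating species.
#'
#' @param fit A `plsda_fit`.
#' @return Tibble: `component`, `cov_t1`, `corr_t1` (zero-variance species
#'   are excluded).
#' @export
splot_coords <- function(fit) {
  t1 <- fit$scores[, 1]
  n <- length(t1)
  sds <- apply(fit$X, 2, sd)
  keep <- sds > 0
  covs <- unname(drop(crossprod(fit$X[, keep, drop = FALSE], t1))) / (n - 1)
  cors <- covs / (sd(t1) * unname(sds[keep]))
  tibble(component = colnames(fit$X)[keep], cov_t1 = covs, corr_t1 = cors)
}

#' Shared-and-unique-structures (SUS) plot coordinates
#'
#' Pairs the t1 correlations of two PLS-DA models (e.g. normal-vs-adjacent
#' and adjacent-vs-tumor). Species on the diagonal behave alike in both
#' comparisons; off-diagonal (second/fourth quadrant) species are unique
#' to one transition, the signature read off the study's TAG and
#' phospholipid panels.
#'
#' @param fit1,fit2 `plsda_fit` objects on the two comparisons.
#' @return Tibble: `component`, `corr1`, `corr2`.
#' @export
sus_coords <- function(fit1, fit2) {
  s1 <- splot_coords(fit1) |> dplyr::select("component", corr1 = "corr_t1")
  s2 <- splot_coords(fit2) |> dplyr::select("component", corr2 = "corr_t1")
  dplyr::inner_join(s1, s2, by = "component")
}
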