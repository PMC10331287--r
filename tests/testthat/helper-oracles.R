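# Independent oracles: closed-form atom counts and masses computed with
# plain arithmetic, deliberately not sharing code with the package's
# formula objects.

oracle_masses <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, P = 30.97376151)
oracle_electron <- 0.000549

oracle_mass <- function(counts) {
  sum(counts[names(oracle_masses)] * oracle_masses, na.rm = TRUE)
}

# free fatty acid CnH(2n-2d)O2
oracle_fa_counts <- function(n, d) c(C = n, H = 2 * n - 2 * d, O = 2, N = 0, P = 0)
oracle_fa_mass <- function(n, d) oracle_mass(oracle_fa_counts(n, d))

# closed-form atom counts per subclass, acyls given as (n, d) matrix
oracle_species_counts <- function(subclass, nd) {
  n <- sum(nd[, 1]); d <- sum(nd[, 2]); k <- nrow(nd)
  fa <- c(C = n, H = 2 * n - 2 * d, O = 2 * k, N = 0, P = 0)
  add <- function(a, b) {
    out <- a
    for (el in names(b)) out[el] <- (if (is.na(out[el])) 0 else out[el]) + b[el]
    out
  }
  water <- c(H = 2, O = 1)
  minus_water <- function(x, times) add(x, -times * c(C = 0, H = 2, N = 0, O = 1, P = 0))
  base <- switch(
    subclass,
    FFA = fa,
    MAG = , DAG = , TAG =
      minus_water(add(fa, c(C = 3, H = 8, N = 0, O = 3, P = 0)), k),
    PA = minus_water(add(fa, c(C = 3, H = 9, N = 0, O = 6, P = 1)), 2),
    PC = minus_water(add(fa, c(C = 8, H = 22, N = 1, O = 7, P = 1)), 3),
    PE = minus_water(add(fa, c(C = 5, H = 16, N = 1, O = 7, P = 1)), 3),
    PG = minus_water(add(fa, c(C = 6, H = 17, N = 0, O = 9, P = 1)), 3),
    PI = minus_water(add(fa, c(C = 9, H = 21, N = 0, O = 12, P = 1)), 3),
    PS = minus_water(add(fa, c(C = 6, H = 16, N = 1, O = 9, P = 1)), 3),
    LPC = minus_water(add(fa, c(C = 8, H = 22, N = 1, O = 7, P = 1)), 2),
    LPE = minus_water(add(fa, c(C = 5, H = 16, N = 1, O = 7, P = 1)), 2),
    Cer = minus_water(add(fa, c(C = 18, H = 37, N = 1, O = 2, P = 0)), 1),
    dhCer = minus_water(add(fa, c(C = 18, H = 39, N = 1, O = 2, P = 0)), 1),
    SM = minus_water(add(fa, c(C = 23, H = 51, N = 2, O = 6, P = 1)), 2),
    HexCer = minus_water(add(fa, c(C = 24, H = 49, N = 1, O = 8, P = 0)), 2),
    LacCer = minus_water(add(fa, c(C = 30, H = 57, N = 1, O = 12, P = 0)), 1),
    stop("no oracle for ", subclass)
  )
  base[c("C", "H", "N", "O", "P")]
}

oracle_species_mass <- function(subclass, nd) {
  oracle_mass(oracle_species_counts(subclass, nd))
}

acyl_nd <- function(acyls) {
  do.call(rbind, lapply(strsplit(acyls, ":"), as.integer))
}

# exhaustive isomer search over all ordered tuples, deduplicated
oracle_isomers <- function(arity, total_c, total_d, pool) {
  nd <- acyl_nd(pool)
  idx <- do.call(expand.grid, rep(list(seq_along(pool)), arity))
  hits <- apply(idx, 1, function(i) {
    sum(nd[i, 1]) == total_c && sum(nd[i, 2]) == total_d
  })
  combos <- unique(apply(idx[hits, , drop = FALSE], 1, function(i) {
    paste(sort(pool[i]), collapse = "|")
  }))
  sort(combos)
}

# hand-computed Welch test
oracle_welch_p <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(y) - mean(x)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(t), df)
}

make_long <- function(m) {
  tibble::tibble(
    sample = rep(rownames(m), ncol(m)),
    component = rep(colnames(m), each = nrow(m)),
    abundance = as.vector(m)
  )
}
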