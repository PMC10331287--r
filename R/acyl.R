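# Fatty acyl chains are carried as "C:D" strings (e.g. "15:0") in tibbles;
# these helpers parse, validate and convert them.

#' Parse acyl shorthand
#'
#' @param acyl Character vector of `"carbons:double_bonds"` strings.
#' @return A tibble with columns `acyl`, `carbons`, `double_bonds`.
#' @examples
#' parse_acyl(c("15:0", "18:1"))
#' @export
parse_acyl <- function(acyl) {
  ok <- grepl("^[0-9]+:[0-9]+$", acyl)
  if (!all(ok)) {
    abort(paste0("malformed acyl shorthand: '", acyl[!ok][1], "'"))
  }
  parts <- strsplit(acyl, ":", fixed = TRUE)
  tibble(
    acyl = acyl,
    carbons = vapply(parts, function(p) as.integer(p[1]), integer(1)),
    double_bonds = vapply(parts, function(p) as.integer(p[2]), integer(1))
  )
}

#' @rdname parse_acyl
#' @param carbons,double_bonds Integer vectors.
#' @export
format_acyl <- function(carbons, double_bonds) {
  paste0(carbons, ":", double_bonds)
}

.ODD_POOL_CARBONS <- c(13L, 15L, 17L, 19L, 21L, 23L)

#' Is an acyl a member of the odd-chain pool?
#'
#' The odd pool covers acyl chains of 13-23 carbons with an odd carbon
#' count; even chains are allowed only as partners in mixed species.
#'
#' @param acyl Character vector of acyl shorthand.
#' @return Logical vector.
#' @export
is_odd_pool <- function(acyl) {
  parse_acyl(acyl)$carbons %in% .ODD_POOL_CARBONS
}

#' Free fatty-acid formula of an acyl chain
#'
#' An acyl with `n` carbons and `d` double bonds corresponds to the free
#' acid C\eqn{_n}H\eqn{_{2n-2d}}O\eqn{_2}: each double bond removes two
#' hydrogens, so species differing by one (two) double bond(s) at equal
#' carbon count differ by exactly 2 (4) Da in nominal mass.
#'
#' @param acyl A single acyl shorthand string, e.g. `"15:0"`.
#' @return An `ol_formula`.
#' @examples
#' formula_string(acyl_formula("15:0"))  # "C15H30O2"
#' @export
acyl_formula <- function(acyl) {
  p <- parse_acyl(acyl)
  if (nrow(p) != 1) abort("acyl_formula() takes a single acyl")
  n <- p$carbons
  d <- p$double_bonds
  if (n < 2) abort("acyl must have at least 2 carbons")
  if (d > n / 2 - 1) {
    abort(paste0("acyl ", acyl, ": ", d, " double bonds impossible for ",
                 n, " carbons"))
  }
  formula_new(C = n, H = 2 * n - 2 * d, O = 2)
}

#' Monoisotopic mass of the free fatty acid of an acyl
#'
#' @inheritParams acyl_formula
#' @return Mass in Da.
#' @export
acyl_mass <- function(acyl) {
  vapply(acyl, function(a) monoisotopic_mass(acyl_formula(a)), numeric(1),
         USE.NAMES = FALSE)
}

# Canonical acyl ordering: (carbons, double_bonds) ascending. sn-positions
# are never asserted; the sorted order is only a naming convention.
sort_acyls <- function(acyls) {
  p <- parse_acyl(acyls)
  acyls[order(p$carbons, p$double_bonds)]
}
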