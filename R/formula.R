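#' @importFrom rlang .data %||% abort
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows distinct across n row_number
#'   rename if_else pull slice first desc
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median sd setNames
NULL

# Monoisotopic atomic masses (Da) for the element set covered by the library.
.ELEMENTS <- c(
  C = 12.000000,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  P = 30.97376151
)

.ELECTRON_MASS <- 0.000549
.PROTON_MASS <- 1.007276

#' Build an elemental formula
#'
#' An elemental formula is a named numeric vector over the elements
#' C, H, N, O, P with non-negative integer counts. It is the molecular
#' composition behind every precursor and product m/z the package computes.
#'
#' @param C,H,N,O,P Non-negative integer atom counts.
#' @return A named numeric vector of class `ol_formula`.
#' @examples
#' formula_new(H = 2, O = 1)  # water
#' @export
formula_new <- function(C = 0, H = 0, N = 0, O = 0, P = 0) {
  x <- c(C = C, H = H, N = N, O = O, P = P)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    abort("atom counts must be non-negative integers")
  }
  structure(as.numeric(x), names = names(.ELEMENTS), class = "ol_formula")
}

#' @export
print.ol_formula <- function(x, ...) {
  cat(formula_string(x), "\n")
  invisible(x)
}

#' Formula arithmetic
#'
#' Add or subtract elemental formulas atom by atom. Subtraction that would
#' drive any count negative is a chemistry error (the condensation being
#' modelled is impossible) and aborts.
#'
#' @param x,y `ol_formula` objects (or vectors accepted by [formula_new()]).
#' @return An `ol_formula`.
#' @export
formula_add <- function(x, y) {
  structure(unclass(x) + unclass(y), names = names(.ELEMENTS),
            class = "ol_formula")
}

#' @rdname formula_add
#' @export
formula_subtract <- function(x, y) {
  z <- unclass(x) - unclass(y)
  if (any(z < -1e-9)) {
    bad <- names(.ELEMENTS)[z < -1e-9]
    abort(paste0("formula subtraction yields negative count for: ",
                 paste(bad, collapse = ", ")))
  }
  structure(pmax(z, 0), names = names(.ELEMENTS), class = "ol_formula")
}

#' Format a formula in Hill order
#'
#' Carbon first, hydrogen second, remaining elements alphabetically;
#' elements with zero count are omitted, count 1 is implicit.
#'
#' @param x An `ol_formula`.
#' @return A single string, e.g. `"C15H30O2"`.
#' @export
formula_string <- function(x) {
  ord <- c("C", "H", "N", "O", "P")
  parts <- vapply(ord, function(el) {
    n <- unclass(x)[[el]]
    if (n == 0) "" else if (n == 1) el else paste0(el, format(n, scientific = FALSE))
  }, character(1))
  s <- paste0(parts, collapse = "")
  if (s == "") "0" else s
}

#' Parse a Hill-order formula string
#'
#' @param s A string such as `"C44H83O13P"`.
#' @return An `ol_formula`.
#' @export
parse_formula <- function(s) {
  s <- gsub("\\s", "", s)
  if (s == "0" || s == "") return(formula_new())
  m <- gregexpr("([CHNOP])([0-9]*)", s)[[1]]
  toks <- regmatches(s, gregexpr("([CHNOP])([0-9]*)", s))[[1]]
  if (sum(nchar(toks)) != nchar(s)) {
    abort(paste0("malformed formula string: '", s, "'"))
  }
  counts <- setNames(numeric(length(.ELEMENTS)), names(.ELEMENTS))
  for (tok in toks) {
    el <- substr(tok, 1, 1)
    n <- substr(tok, 2, nchar(tok))
    counts[el] <- counts[el] + if (n == "") 1 else as.numeric(n)
  }
  do.call(formula_new, as.list(counts))
}

#' Monoisotopic mass of a formula
#'
#' Sum of atom counts times monoisotopic atomic masses
#' (C 12 exactly, H 1.0078250319, N 14.0030740052, O 15.9949146221,
#' P 30.97376151). Deterministic to better than 1e-6 Da.
#'
#' @param x An `ol_formula` or a formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(formula_new(H = 2, O = 1))  # 18.010565
#' @export
monoisotopic_mass <- function(x) {
  if (is.character(x)) x <- parse_formula(x)
  sum(unclass(x) * .ELEMENTS)
}

# Fixed building blocks used by the subclass construction rules.
.BLOCKS <- list(
  water          = formula_new(H = 2, O = 1),
  glycerol       = formula_new(C = 3, H = 8, O = 3),
  g3p            = formula_new(C = 3, H = 9, O = 6, P = 1),
  choline        = formula_new(C = 5, H = 13, N = 1, O = 1),
  ethanolamine   = formula_new(C = 2, H = 7, N = 1, O = 1),
  inositol       = formula_new(C = 6, H = 12, O = 6),
  serine         = formula_new(C = 3, H = 7, N = 1, O = 3),
  sphingosine    = formula_new(C = 18, H = 37, N = 1, O = 2),
  sphinganine    = formula_new(C = 18, H = 39, N = 1, O = 2),
  phosphocholine = formula_new(C = 5, H = 14, N = 1, O = 4, P = 1),
  hexose         = formula_new(C = 6, H = 12, O = 6),
  anhydrohexose  = formula_new(C = 6, H = 10, O = 5),
  ammonia        = formula_new(N = 1, H = 3)
)
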