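# In-silico enumeration of the odd-chain fatty acyl lipid library.

#' Library configuration
#'
#' Defines the combinatorial space the enumerator regenerates: the
#' subclasses, the mandatory odd-chain acyl pool, an optional even-chain
#' partner pool for mixed species, and the unsaturation range. The default
#' pools are the six odd chains 13:0-23:0 with 0-2 double bonds and even
#' partners 12-22 carbons.
#'
#' @param subclasses Character vector of subclass labels.
#' @param odd_carbons Odd carbon counts admitted to the odd pool.
#' @param even_carbons Even carbon counts for the partner pool (may be
#'   empty to forbid mixed species).
#' @param double_bonds Integer vector of allowed per-acyl double-bond
#'   counts.
#' @return A list of class `ol_library_config`.
#' @export
library_config <- function(subclasses = lipid_subclasses()$subclass,
                           odd_carbons = c(13L, 15L, 17L, 19L, 21L, 23L),
                           even_carbons = seq(12L, 22L, by = 2L),
                           double_bonds = 0:2) {
  if (length(subclasses) == 0) abort("at least one subclass is required")
  unknown <- setdiff(subclasses, lipid_subclasses()$subclass)
  if (length(unknown) > 0) {
    abort(paste0("unknown subclass: ", paste(unknown, collapse = ", ")))
  }
  if (any(odd_carbons %% 2 != 1)) abort("odd pool must have odd carbon counts")
  if (any(double_bonds < 0 | double_bonds > 2)) {
    abort("double_bonds must lie in 0..2")
  }
  structure(list(subclasses = subclasses,
                 odd_carbons = as.integer(odd_carbons),
                 even_carbons = as.integer(even_carbons),
                 double_bonds = as.integer(double_bonds)),
            class = "ol_library_config")
}

acyl_pool <- function(carbons, double_bonds) {
  if (length(carbons) == 0) return(character(0))
  g <- expand.grid(carbons = carbons, double_bonds = double_bonds)
  format_acyl(g$carbons, g$double_bonds)
}

# All multisets of size `arity` from `pool` (combinations with repetition),
# as a list of character vectors.
acyl_multisets <- function(pool, arity) {
  idx <- utils::combn(seq_len(length(pool) + arity - 1), arity,
                      simplify = FALSE)
  lapply(idx, function(i) pool[i - seq_len(arity) + 1])
}

#' Enumerate the odd-chain lipid library
#'
#' Generates every species of the configured subclasses whose acyls are
#' drawn from the odd pool plus (optionally) the even partner pool, keeping
#' only species that carry at least one odd-pool acyl. Species are unique
#' by (subclass, multiset of acyls) and sorted by subclass, total carbons,
#' total double bonds.
#'
#' @param config An [library_config()].
#' @return A tibble, one row per species, with the columns of
#'   [lipid_species()] plus `polarity` and `odd_acyls` (slash-joined
#'   odd-pool members of the species).
#' @examples
#' enumerate_odd_library(library_config("FFA", double_bonds = 0:2,
#'                                      even_carbons = integer(0)))
#' @export
enumerate_odd_library <- function(config = library_config()) {
  stopifnot(inherits(config, "ol_library_config"))
  odd <- acyl_pool(config$odd_carbons, config$double_bonds)
  even <- acyl_pool(config$even_carbons, config$double_bonds)
  pool <- c(odd, even)

  per_subclass <- lapply(config$subclasses, function(sc) {
    arity <- subclass_info(sc)$arity
    sets <- acyl_multisets(pool, arity)
    sets <- Filter(function(a) any(a %in% odd), sets)
    sets <- unique(lapply(sets, sort_acyls))
    dplyr::bind_rows(lapply(sets, function(a) lipid_species(sc, a)))
  })
  out <- dplyr::bind_rows(per_subclass)
  out <- dplyr::left_join(out, lipid_subclasses()[, c("subclass", "polarity")],
                          by = "subclass")
  out$odd_acyls <- vapply(strsplit(out$acyls, "/", fixed = TRUE),
                          function(a) paste(a[a %in% odd], collapse = "/"),
                          character(1))
  out |>
    dplyr::arrange(factor(.data$subclass, levels = config$subclasses),
                   .data$total_carbons, .data$total_double_bonds, .data$acyls)
}

#' Read or write a library table
#'
#' The on-disk dialect is a delimited table with one row per species:
#' canonical name, sum name, subclass, acyls, Hill-order formula and
#' neutral monoisotopic mass.
#'
#' @param library A library tibble from [enumerate_odd_library()].
#' @param path File path (`.csv` or `.tsv`).
#' @return `read_library()` returns the library tibble.
#' @export
write_library <- function(library, path) {
  readr::write_csv(library, path)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
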