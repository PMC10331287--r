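# Acyl-combination isomers behind a sum composition.

#' Enumerate acyl combinations matching a sum composition
#'
#' A sum composition such as TAG 51:3 hides many acyl combinations; this
#' enumerates every multiset of pool acyls whose carbons and double bonds
#' sum to the target and which contains at least one odd-pool acyl.
#'
#' @param subclass Subclass label (fixes the arity).
#' @param total_carbons,total_double_bonds Target sum composition.
#' @param pool Character vector of candidate acyls (`"15:0"` style).
#' @return A tibble with one row per candidate: `acyls` (canonical
#'   slash-joined multiset), `name` (acyl-resolved canonical name), sorted
#'   canonically.
#' @examples
#' isomer_candidates("DAG", 30, 0, pool = c("15:0", "13:0", "17:0"))
#' @export
isomer_candidates <- function(subclass, total_carbons, total_double_bonds,
                              pool) {
  if (length(pool) == 0) abort("acyl pool is empty")
  arity <- subclass_info(subclass)$arity
  p <- parse_acyl(pool)
  sets <- acyl_multisets(pool, arity)
  keep <- vapply(sets, function(a) {
    pa <- parse_acyl(a)
    sum(pa$carbons) == total_carbons &&
      sum(pa$double_bonds) == total_double_bonds &&
      any(a %in% pool[p$carbons %in% .ODD_POOL_CARBONS])
  }, logical(1))
  sets <- unique(lapply(sets[keep], sort_acyls))
  if (length(sets) == 0) {
    return(tibble(acyls = character(0), name = character(0)))
  }
  out <- tibble(
    acyls = vapply(sets, paste, character(1), collapse = "/"),
    name = vapply(sets, function(a) format_lipid_name(subclass, a),
                  character(1))
  )
  dplyr::arrange(out, .data$acyls)
}
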