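# Lipid subclass registry and species-level formula construction.

.SUBCLASSES <- tibble::tribble(
  ~subclass, ~arity, ~polarity,  ~category,
  "FFA",     1L,     "negative", "fatty_acid",
  "MAG",     1L,     "positive", "glycerolipid",
  "DAG",     2L,     "positive", "glycerolipid",
  "TAG",     3L,     "positive", "glycerolipid",
  "PA",      2L,     "negative", "glycerophospholipid",
  "PC",      2L,     "negative", "glycerophospholipid",
  "PE",      2L,     "negative", "glycerophospholipid",
  "PG",      2L,     "negative", "glycerophospholipid",
  "PI",      2L,     "negative", "glycerophospholipid",
  "PS",      2L,     "negative", "glycerophospholipid",
  "LPC",     1L,     "negative", "glycerophospholipid",
  "LPE",     1L,     "negative", "glycerophospholipid",
  "SM",      1L,     "positive", "sphingolipid",
  "Cer",     1L,     "positive", "sphingolipid",
  "dhCer",   1L,     "positive", "sphingolipid",
  "HexCer",  1L,     "positive", "sphingolipid",
  "LacCer",  1L,     "positive", "sphingolipid"
)

#' Supported lipid subclasses
#'
#' Registry of the subclasses the library can enumerate: acyl arity (how
#' many variable fatty acyls each species carries -- the sphingoid base of
#' sphingolipids is fixed and not counted), default detection polarity and
#' lipid category. Glycerolipids and sphingolipids are detected in positive
#' ESI mode, glycerophospholipids and free fatty acids in negative mode.
#'
#' @return A tibble with columns `subclass`, `arity`, `polarity`, `category`.
#' @export
lipid_subclasses <- function() .SUBCLASSES

subclass_info <- function(subclass) {
  row <- .SUBCLASSES[.SUBCLASSES$subclass == subclass, ]
  if (nrow(row) == 0) abort(paste0("unknown subclass: '", subclass, "'"))
  row
}

# Head-alcohol added onto phosphatidic acid (PA) to form each diacyl
# glycerophospholipid; the condensation removes one water.
.HEAD_ALCOHOL <- list(
  PC = "choline", PE = "ethanolamine", PG = "glycerol",
  PI = "inositol", PS = "serine", LPC = "choline", LPE = "ethanolamine"
)

#' Construct the elemental formula of a lipid species
#'
#' Applies fixed condensation rules per subclass:
#' * glycerolipids (MAG/DAG/TAG): glycerol + sum of free fatty acids minus
#'   one water per ester bond;
#' * PA: glycero-3-phosphate + 2 FA - 2 H2O; other diacyl phospholipids:
#'   PA + head alcohol - H2O; lyso forms drop one FA and one condensation;
#' * FFA: the free acid itself;
#' * ceramide: sphingosine (d18:1) + FA - H2O (sphinganine d18:0 for dhCer);
#'   SM adds phosphocholine - H2O; HexCer adds hexose - H2O; LacCer adds two
#'   anhydrohexose units.
#'
#' @param subclass One of [lipid_subclasses()]`$subclass`.
#' @param acyls Character vector of acyl shorthand (`"15:0"`); length must
#'   equal the subclass arity.
#' @return An `ol_formula`.
#' @examples
#' formula_string(lipid_formula("TAG", c("15:0", "15:0", "15:0")))  # C48H92O6
#' @export
lipid_formula <- function(subclass, acyls) {
  info <- subclass_info(subclass)
  if (length(acyls) != info$arity) {
    abort(paste0(subclass, " takes ", info$arity, " acyl(s), got ",
                 length(acyls)))
  }
  fa <- lapply(acyls, acyl_formula)
  fa_sum <- Reduce(formula_add, fa)
  k_water <- function(f, k) {
    Reduce(formula_subtract, rep(list(.BLOCKS$water), k), f)
  }
  switch(
    subclass,
    FFA = fa_sum,
    MAG = ,
    DAG = ,
    TAG = k_water(formula_add(.BLOCKS$glycerol, fa_sum), length(acyls)),
    PA  = k_water(formula_add(.BLOCKS$g3p, fa_sum), 2),
    PC  = ,
    PE  = ,
    PG  = ,
    PI  = ,
    PS  = {
      pa <- k_water(formula_add(.BLOCKS$g3p, fa_sum), 2)
      k_water(formula_add(pa, .BLOCKS[[.HEAD_ALCOHOL[[subclass]]]]), 1)
    },
    LPC = ,
    LPE = {
      lpa <- k_water(formula_add(.BLOCKS$g3p, fa_sum), 1)
      k_water(formula_add(lpa, .BLOCKS[[.HEAD_ALCOHOL[[subclass]]]]), 1)
    },
    Cer    = k_water(formula_add(.BLOCKS$sphingosine, fa_sum), 1),
    dhCer  = k_water(formula_add(.BLOCKS$sphinganine, fa_sum), 1),
    SM     = k_water(formula_add(
      k_water(formula_add(.BLOCKS$sphingosine, fa_sum), 1),
      .BLOCKS$phosphocholine), 1),
    HexCer = k_water(formula_add(
      k_water(formula_add(.BLOCKS$sphingosine, fa_sum), 1),
      .BLOCKS$hexose), 1),
    LacCer = formula_add(
      k_water(formula_add(.BLOCKS$sphingosine, fa_sum), 1),
      formula_add(.BLOCKS$anhydrohexose, .BLOCKS$anhydrohexose)),
    abort(paste0("unknown subclass: '", subclass, "'"))
  )
}

#' Build a lipid species record
#'
#' @param subclass Subclass label.
#' @param acyls Character vector of acyl shorthand, one per variable acyl.
#' @return A one-row tibble with canonical names, total carbons/double
#'   bonds (of the variable acyls), Hill formula string and neutral
#'   monoisotopic mass.
#' @examples
#' lipid_species("PI", c("17:0", "18:1"))
#' @export
lipid_species <- function(subclass, acyls) {
  acyls <- sort_acyls(acyls)
  p <- parse_acyl(acyls)
  f <- lipid_formula(subclass, acyls)
  tibble(
    name = format_lipid_name(subclass, acyls),
    sum_name = format_sum_name(subclass, sum(p$carbons), sum(p$double_bonds)),
    subclass = subclass,
    acyls = paste(acyls, collapse = "/"),
    total_carbons = sum(p$carbons),
    total_double_bonds = sum(p$double_bonds),
    formula = formula_string(f),
    neutral_mass = monoisotopic_mass(f)
  )
}
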