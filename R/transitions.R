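# MRM transition generation from subclass-specific fragmentation rules.

.ADDUCTS <- tibble::tribble(
  ~adduct,         ~delta,      ~charge,
  "[M+NH4]+",      18.034374,   +1,
  "[M+H]+",        1.007825,    +1,
  "[M-H]-",        -1.007825,   -1,
  "[M+CH3COO]-",   59.013305,   -1
)

#' Supported adducts
#'
#' Mass deltas (Da) added to the neutral monoisotopic mass before the
#' electron correction (minus one electron mass for cations, plus one for
#' anions).
#'
#' @return A tibble with columns `adduct`, `delta`, `charge`.
#' @export
adducts <- function() .ADDUCTS

#' Precursor m/z of a species under an adduct
#'
#' Ion m/z = neutral mass + adduct delta -/+ electron mass (0.000549 Da)
#' for positive/negative ions.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (vectorized).
#' @param adduct One of [adducts()]`$adduct`.
#' @return m/z values.
#' @examples
#' precursor_mz(764.6894, "[M+NH4]+")  # ammoniated tripentadecanoin
#' @export
precursor_mz <- function(neutral_mass, adduct) {
  row <- .ADDUCTS[.ADDUCTS$adduct == adduct, ]
  if (nrow(row) == 0) abort(paste0("unknown adduct: '", adduct, "'"))
  if (any(!is.finite(neutral_mass) | neutral_mass <= 0)) {
    abort("neutral_mass must be positive")
  }
  neutral_mass + row$delta - row$charge * .ELECTRON_MASS
}

# Default precursor adduct per subclass. PC/LPC are measured as acetate
# adducts in negative mode (ammonium acetate mobile phase); this choice is
# overridable via the `pc_adduct` argument of build_transitions().
default_adduct <- function(subclass, pc_adduct = "[M+CH3COO]-") {
  info <- subclass_info(subclass)
  if (subclass %in% c("PC", "LPC")) return(pc_adduct)
  if (info$polarity == "positive") {
    if (info$category == "sphingolipid") "[M+H]+" else "[M+NH4]+"
  } else {
    "[M-H]-"
  }
}

transition_row <- function(species, q1, q3, polarity, fragment, adduct) {
  tibble(name = species$name, subclass = species$subclass,
         q1 = round(q1, 4), q3 = round(q3, 4),
         polarity = polarity, fragment = fragment, adduct = adduct)
}

#' Transitions for glycerolipids (TAG, DAG, MAG)
#'
#' TAG: ammoniated precursor; one product channel per distinct acyl, the
#' neutral loss being the free fatty acid plus ammonia (nominal 259, 287
#' and 315 Da for 15:0, 17:0 and 19:0; each double bond lowers the loss by
#' 2 Da). DAG: ammoniated precursor; per acyl retained, the product is the
#' protonated dehydrated monoacylglycerol (nominal 299/327/355 for
#' 15:0/17:0/19:0). MAG: a single `[M+H-H2O]+` product.
#'
#' @param species A one-row species tibble ([lipid_species()]).
#' @return A tibble of transitions (name, subclass, q1, q3, polarity,
#'   fragment, adduct).
#' @export
tag_dag_transitions <- function(species) {
  sc <- species$subclass
  if (!sc %in% c("TAG", "DAG", "MAG")) {
    abort(paste0("tag_dag_transitions() does not handle ", sc))
  }
  acyls <- strsplit(species$acyls, "/", fixed = TRUE)[[1]]
  q1 <- precursor_mz(species$neutral_mass, "[M+NH4]+")
  nh3 <- monoisotopic_mass(.BLOCKS$ammonia)

  if (sc == "TAG") {
    rows <- lapply(unique(acyls), function(a) {
      nl <- acyl_mass(a) + nh3
      transition_row(species, q1, q1 - nl, "positive",
                     paste0("NL FA", a, "+NH3"), "[M+NH4]+")
    })
    dplyr::bind_rows(rows)
  } else if (sc == "DAG") {
    rows <- lapply(unique(acyls), function(a) {
      mag <- monoisotopic_mass(lipid_formula("MAG", a))
      q3 <- mag + .PROTON_MASS - monoisotopic_mass(.BLOCKS$water)
      transition_row(species, q1, q3, "positive",
                     paste0("MAG FA", a, " fragment"), "[M+NH4]+")
    })
    dplyr::bind_rows(rows)
  } else {
    q3 <- species$neutral_mass + .PROTON_MASS -
      monoisotopic_mass(.BLOCKS$water)
    transition_row(species, q1, q3, "positive", "[M+H-H2O]+", "[M+NH4]+")
  }
}

#' Transitions for glycerophospholipids
#'
#' Negative mode; the precursor is `[M-H]-` (acetate adduct for PC/LPC)
#' and each acyl gives a carboxylate-anion product `[FA-H]-`. Identical
#' acyls merge into a single channel whose annotation lists both sn sites;
#' sn positions themselves are never asserted.
#'
#' @inheritParams tag_dag_transitions
#' @param pc_adduct Negative-mode precursor adduct for PC/LPC.
#' @return A tibble of transitions.
#' @export
phospholipid_transitions <- function(species, pc_adduct = "[M+CH3COO]-") {
  sc <- species$subclass
  if (!sc %in% c("PA", "PC", "PE", "PG", "PI", "PS", "LPC", "LPE")) {
    abort(paste0("phospholipid_transitions() does not handle ", sc))
  }
  acyls <- strsplit(species$acyls, "/", fixed = TRUE)[[1]]
  adduct <- default_adduct(sc, pc_adduct)
  q1 <- precursor_mz(species$neutral_mass, adduct)
  distinct_acyls <- unique(acyls)
  rows <- lapply(distinct_acyls, function(a) {
    q3 <- acyl_mass(a) - 1.007825 + .ELECTRON_MASS
    sn <- if (length(distinct_acyls) == 1 && length(acyls) == 2) {
      "sn-1/sn-2"
    } else if (length(acyls) == 1) {
      "sn-1"
    } else {
      paste0("sn-", which(acyls == a))
    }
    transition_row(species, q1, q3, "negative",
                   paste0("carboxylate FA", a, " (", sn, ")"), adduct)
  })
  dplyr::bind_rows(rows)
}

#' Transitions for sphingolipids and free fatty acids
#'
#' SM fragments to the phosphocholine head (m/z 184.0733); ceramides and
#' glycosylceramides to the dehydrated long-chain base (264.2686 for d18:1,
#' 266.2842 for the d18:0 base of dhCer). FFA uses a pseudo-transition with
#' Q1 = Q3 = `[M-H]-`.
#'
#' @inheritParams tag_dag_transitions
#' @return A tibble of transitions.
#' @export
sphingo_ffa_transitions <- function(species) {
  sc <- species$subclass
  if (!sc %in% c("SM", "Cer", "dhCer", "HexCer", "LacCer", "FFA")) {
    abort(paste0("sphingo_ffa_transitions() does not handle ", sc))
  }
  water <- monoisotopic_mass(.BLOCKS$water)
  if (sc == "FFA") {
    q <- precursor_mz(species$neutral_mass, "[M-H]-")
    return(transition_row(species, q, q, "negative", "[M-H]-", "[M-H]-"))
  }
  q1 <- precursor_mz(species$neutral_mass, "[M+H]+")
  q3 <- switch(
    sc,
    SM = monoisotopic_mass(.BLOCKS$phosphocholine) + .PROTON_MASS,
    dhCer = monoisotopic_mass(.BLOCKS$sphinganine) + 1.007825 - 2 * water -
      .ELECTRON_MASS,
    monoisotopic_mass(.BLOCKS$sphingosine) + 1.007825 - 2 * water -
      .ELECTRON_MASS
  )
  frag <- switch(sc, SM = "phosphocholine 184",
                 dhCer = "LCB d18:0 - 2H2O", "LCB d18:1 - 2H2O")
  transition_row(species, q1, q3, "positive", frag, "[M+H]+")
}

#' Build the MRM transition list for a library
#'
#' Dispatches each species to its subclass fragmentation rule and returns
#' the combined transition table.
#'
#' @param library A library tibble from [enumerate_odd_library()].
#' @param pc_adduct Negative-mode precursor adduct for PC/LPC.
#' @return A tibble with one row per (species, fragment) pair.
#' @export
build_transitions <- function(library, pc_adduct = "[M+CH3COO]-") {
  rows <- lapply(seq_len(nrow(library)), function(i) {
    sp <- library[i, ]
    cat_ <- subclass_info(sp$subclass)$category
    if (sp$subclass %in% c("TAG", "DAG", "MAG")) {
      tag_dag_transitions(sp)
    } else if (cat_ == "glycerophospholipid") {
      phospholipid_transitions(sp, pc_adduct)
    } else {
      sphingo_ffa_transitions(sp)
    }
  })
  dplyr::bind_rows(rows)
}
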