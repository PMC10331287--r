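# Shorthand lipid nomenclature: formatting and parsing.
#
# Two dialects are supported, as used interchangeably in targeted
# lipidomics reports:
#   * acyl-resolved: "PI 17:0/18:1" (variants "PI (17:0/18:1)", "PI(17:0/18:1)");
#     sphingolipids carry the fixed long-chain base: "SM d18:1/17:0"
#   * sum-level:     "TAG 51:3" (variant "TAG51:3"), optionally with a
#     marker acyl: "TAG 51:3-FA17:0"
# parse_lipid_name(format(...)) is the identity on canonical forms; all
# variants normalize to the canonical spelling.

sphingo_base <- function(subclass) {
  if (subclass == "dhCer") "d18:0" else "d18:1"
}

#' Format canonical lipid names
#'
#' @param subclass Subclass label.
#' @param acyls Character vector of acyl shorthand.
#' @return `format_lipid_name()`: the canonical acyl-resolved name;
#'   `format_sum_name()`: the canonical sum-composition name.
#' @examples
#' format_lipid_name("PI", c("17:0", "18:1"))  # "PI 17:0/18:1"
#' format_sum_name("TAG", 51, 3)               # "TAG 51:3"
#' @export
format_lipid_name <- function(subclass, acyls) {
  info <- subclass_info(subclass)
  acyls <- sort_acyls(acyls)
  if (info$category == "sphingolipid") {
    paste0(subclass, " ", sphingo_base(subclass), "/",
           paste(acyls, collapse = "/"))
  } else {
    paste0(subclass, " ", paste(acyls, collapse = "/"))
  }
}

#' @rdname format_lipid_name
#' @param total_carbons,total_double_bonds Sum composition over the
#'   variable acyls.
#' @param marker_acyl Optional acyl shorthand appended as `-FA<acyl>` to
#'   record which odd chain the identification rests on.
#' @export
format_sum_name <- function(subclass, total_carbons, total_double_bonds,
                            marker_acyl = NULL) {
  s <- paste0(subclass, " ", total_carbons, ":", total_double_bonds)
  if (!is.null(marker_acyl)) s <- paste0(s, "-FA", marker_acyl)
  s
}

.NAME_RE <- paste0(
  "^\\s*([A-Za-z]+)\\s*",                       # subclass
  "(?:\\(\\s*([^)]*)\\s*\\)",                   # "(17:0/18:1)"
  "|((?:d\\d+:\\d+/)?\\d+:\\d+(?:/\\d+:\\d+)*)",# bare composition
  ")\\s*",
  "(?:-\\s*FA\\s*(\\d+:\\d+))?\\s*$"            # optional marker acyl
)

#' Parse a shorthand lipid name
#'
#' Accepts both dialects and their spacing/parenthesis variants; malformed
#' names abort with the character position of the offending part.
#'
#' @param name A single shorthand name.
#' @return A one-row tibble with `subclass`, `kind` (`"acyl"` or `"sum"`),
#'   `total_carbons`, `total_double_bonds`, `acyls` (slash-joined canonical
#'   acyls, `NA` for sum-level names), `marker_acyl` (`NA` if absent) and
#'   `canonical` (the normalized spelling).
#' @examples
#' parse_lipid_name("PI (17:0/18:1)")
#' parse_lipid_name("TAG51:3-FA17:0")
#' @export
parse_lipid_name <- function(name) {
  stopifnot(length(name) == 1)
  m <- regexec(.NAME_RE, name, perl = TRUE)[[1]]
  if (m[1] == -1) {
    # locate first character where the name stops looking like shorthand
    pos <- regexpr("[^A-Za-z]", name)
    abort(paste0("malformed lipid name '", name, "' (near position ",
                 max(pos, 1), ")"))
  }
  g <- regmatches(name, regexec(.NAME_RE, name, perl = TRUE))[[1]]
  subclass <- g[2]
  info <- subclass_info(subclass)
  comp <- if (g[3] != "") g[3] else g[4]
  marker <- if (length(g) >= 5 && g[5] != "") g[5] else NA_character_
  comp <- gsub("\\s", "", comp)
  parts <- strsplit(comp, "/", fixed = TRUE)[[1]]

  # strip a leading long-chain base ("d18:1") on sphingolipid names
  base <- NULL
  if (grepl("^d", parts[1])) {
    base <- sub("^d", "", parts[1])
    parts <- parts[-1]
    if (info$category != "sphingolipid") {
      abort(paste0("malformed lipid name '", name,
                   "': long-chain base on non-sphingolipid (position ",
                   regexpr("d", name), ")"))
    }
    if (paste0("d", base) != sphingo_base(subclass)) {
      abort(paste0("unsupported long-chain base d", base, " for ", subclass))
    }
  }
  if (!all(grepl("^\\d+:\\d+$", parts)) || length(parts) == 0) {
    abort(paste0("malformed lipid name '", name, "' (near position ",
                 regexpr(comp, name, fixed = TRUE), ")"))
  }
  p <- parse_acyl(parts)
  if (any(p$carbons == 0)) {
    abort(paste0("malformed lipid name '", name, "': zero-carbon acyl"))
  }

  # A single "C:D" token on a multi-acyl subclass is a sum composition;
  # on a one-acyl subclass it names the acyl itself.
  if (length(parts) > 1) {
    if (length(parts) != info$arity) {
      abort(paste0("name '", name, "' lists ", length(parts),
                   " acyls but ", subclass, " takes ", info$arity))
    }
    kind <- "acyl"
  } else if (info$arity == 1L && is.na(marker)) {
    kind <- "acyl"
  } else {
    kind <- "sum"
  }

  if (kind == "acyl") {
    sorted <- sort_acyls(parts)
    tibble(
      subclass = subclass, kind = "acyl",
      total_carbons = sum(p$carbons),
      total_double_bonds = sum(p$double_bonds),
      acyls = paste(sorted, collapse = "/"),
      marker_acyl = marker,
      canonical = format_lipid_name(subclass, sorted)
    )
  } else {
    tibble(
      subclass = subclass, kind = "sum",
      total_carbons = p$carbons[1],
      total_double_bonds = p$double_bonds[1],
      acyls = NA_character_,
      marker_acyl = marker,
      canonical = format_sum_name(subclass, p$carbons[1], p$double_bonds[1],
                                  if (is.na(marker)) NULL else marker)
    )
  }
}
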