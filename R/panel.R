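# The free-GAG disaccharide panel: 8 chondroitin sulfate (CS), 8 heparan
# sulfate (HS) and 1 hyaluronic acid (HA) disaccharide, identified by their
# sulfation code. Canonical display names are "<code> <class>", e.g. "0S CS";
# CSV column names are "<class>_<code>", e.g. "CS_0S".

.CS_CODES <- c("0S", "2S", "6S", "4S", "2S6S", "2S4S", "4S6S", "TriS")
.HS_CODES <- c("0S", "2S", "6S", "NS", "NS6S", "NS2S", "2S6S", "TriS")
.HA_CODES <- c("0S")

# sulfo-group count per sulfation code (total function over the panel codes)
.SULFO_COUNT <- c(
  "0S" = 0L,
  "2S" = 1L, "6S" = 1L, "4S" = 1L, "NS" = 1L,
  "2S6S" = 2L, "2S4S" = 2L, "4S6S" = 2L, "NS6S" = 2L, "NS2S" = 2L,
  "TriS" = 3L
)

#' The GAG disaccharide panel
#'
#' Enumerates the 17 disaccharide identities quantified by the free-GAG
#' assay: eight chondroitin sulfate (CS) sulfation forms, eight heparan
#' sulfate (HS) forms and unsulfated hyaluronic acid (HA).
#'
#' @return A tibble with one row per disaccharide and columns `name`
#'   (canonical display name, e.g. `"0S CS"`), `gag_class` (`"CS"`, `"HS"`
#'   or `"HA"`), `sulfation` (sulfation code), `column` (CSV column name,
#'   e.g. `"CS_0S"`) and `sulfo_count` (number of sulfo groups, 0--3).
#' @examples
#' gag_panel()
#' @export
gag_panel <- function() {
  cls <- c(rep("CS", 8L), rep("HS", 8L), "HA")
  code <- c(.CS_CODES, .HS_CODES, .HA_CODES)
  tibble::tibble(
    name = paste(code, cls),
    gag_class = cls,
    sulfation = code,
    column = paste(cls, code, sep = "_"),
    sulfo_count = unname(.SULFO_COUNT[code])
  )
}

#' Count sulfo groups of a disaccharide
#'
#' @param name Character vector of canonical disaccharide names
#'   (e.g. `"0S CS"`, `"TriS HS"`, `"NS6S HS"`).
#' @return Integer vector of sulfo-group counts (0 for `0S`, 1 for the
#'   mono-sulfated codes including `NS`, 2 for the di-sulfated codes,
#'   3 for `TriS`).
#' @examples
#' sulfo_count(c("0S CS", "NS6S HS", "TriS HS"))
#' @export
sulfo_count <- function(name) {
  panel <- gag_panel()
  idx <- match(name, panel$name)
  if (anyNA(idx)) {
    bad <- name[is.na(idx)]
    stop("unknown disaccharide identity: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  panel$sulfo_count[idx]
}

# internal: panel subsets by class, as canonical names
.class_members <- function(cls) {
  panel <- gag_panel()
  panel$name[panel$gag_class == cls]
}

#' Names of the expanded GAGome features
#'
#' A complete GAGome holds 39 features per sample: the 17 measured
#' absolute concentrations (ug/mL), the 16 CS/HS mass fractions
#' (ug/ug%), two sulfation ratios (`4S CS/0S CS`, `6S CS/0S CS`), the
#' class totals (`total CS`, `total HS`, ug/mL) and the dimensionless
#' sulfo-weighted class charges (`CS charge`, `HS charge`).
#'
#' @param which One of `"all"`, `"measured"` or `"derived"`.
#' @return Character vector of feature names in canonical order
#'   (concentrations, fractions, ratios, totals, charges).
#' @export
gagome_feature_names <- function(which = c("all", "measured", "derived")) {
  which <- match.arg(which)
  panel <- gag_panel()
  measured <- panel$name
  fractions <- paste(c(.class_members("CS"), .class_members("HS")), "fraction")
  ratios <- c("4S CS/0S CS", "6S CS/0S CS")
  totals <- c("total CS", "total HS")
  charges <- c("CS charge", "HS charge")
  derived <- c(fractions, ratios, totals, charges)
  switch(which, all = c(measured, derived), measured = measured, derived = derived)
}
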