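# GAGome feature engineering: expansion of the 17 measured disaccharide
# concentrations into the full 39-feature GAGome, the plasma detectability
# filter, and selection of the analyzable feature set.

# internal: coerce a wide profile table (sample_id + 17 disaccharide columns,
# named either canonically or CSV-style) to a numeric matrix with canonical
# column names. Missing columns are an error; unknown columns are an error.
.profile_matrix <- function(profiles) {
  panel <- gag_panel()
  stopifnot(is.data.frame(profiles))
  if (!"sample_id" %in% names(profiles)) {
    stop("profiles must have a 'sample_id' column", call. = FALSE)
  }
  cols <- setdiff(names(profiles), "sample_id")
  canon <- ifelse(cols %in% panel$column, panel$name[match(cols, panel$column)], cols)
  unknown <- canon[!canon %in% panel$name]
  if (length(unknown) > 0) {
    stop("unknown disaccharide column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(panel$name, canon)
  if (length(missing) > 0) {
    stop("profile table lacks disaccharide column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(profiles[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  colnames(m) <- canon
  m <- m[, panel$name, drop = FALSE]
  if (any(m < 0, na.rm = TRUE)) {
    bad <- colnames(m)[apply(m < 0, 2, any, na.rm = TRUE)]
    stop("negative concentration in: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  rownames(m) <- as.character(profiles$sample_id)
  m
}

#' Expand GAGome profiles into the 39-feature GAGome
#'
#' Expands the 17 measured disaccharide concentrations of each sample into
#' the full GAGome: for each class (CS, HS) the total concentration (sum of
#' the class's disaccharides, ug/mL), the mass fraction of each disaccharide
#' (100 x concentration / class total, ug/ug%), the class charge (the
#' sulfo-count-weighted sum of the class's mass fractions divided by 100,
#' dimensionless, in \[0, 3\]), and the two sulfation ratios
#' `4S CS/0S CS` and `6S CS/0S CS`.
#'
#' Derived features whose denominator is zero (e.g. fractions of a class
#' with zero total) are marked unavailable (`NA`), never `NaN`; missing
#' measured concentrations likewise propagate `NA` to every feature that
#' depends on them.
#'
#' @param profiles Data frame with `sample_id` plus the 17 disaccharide
#'   columns (canonical `"0S CS"` or CSV-style `"CS_0S"` names), in ug/mL.
#' @return A tibble with `sample_id` and the 39 feature columns of
#'   [gagome_feature_names()]; unavailable values are `NA`.
#' @examples
#' prof <- empty_profile("s1")
#' prof[["0S CS"]] <- 2; prof[["4S CS"]] <- 1; prof[["TriS CS"]] <- 1
#' expand_features(prof)[, c("total CS", "CS charge", "4S CS/0S CS")]
#' @export
expand_features <- function(profiles) {
  m <- .profile_matrix(profiles)
  rownames(m) <- NULL
  cs <- .class_members("CS")
  hs <- .class_members("HS")
  out <- list(sample_id = profiles$sample_id)
  for (d in colnames(m)) out[[d]] <- unname(m[, d])

  frac <- function(members, total) {
    f <- 100 * sweep(m[, members, drop = FALSE], 1, total, "/")
    f[is.na(total) | total == 0, ] <- NA_real_
    f
  }
  for (cls in list(list(n = "CS", mem = cs), list(n = "HS", mem = hs))) {
    total <- rowSums(m[, cls$mem, drop = FALSE])
    fr <- frac(cls$mem, total)
    for (d in cls$mem) out[[paste(d, "fraction")]] <- unname(fr[, d])
    w <- sulfo_count(cls$mem)
    out[[paste0("total ", cls$n)]] <- total
    out[[paste0(cls$n, " charge")]] <- as.vector(fr %*% w) / 100
  }
  ratio <- function(num, den) {
    r <- unname(m[, num] / m[, den])
    r[is.na(m[, den]) | m[, den] == 0] <- NA_real_
    r
  }
  out[["4S CS/0S CS"]] <- ratio("4S CS", "0S CS")
  out[["6S CS/0S CS"]] <- ratio("6S CS", "0S CS")

  tibble::as_tibble(out)[, c("sample_id", gagome_feature_names())]
}

#' An all-zero GAGome profile skeleton
#'
#' Convenience constructor for building small profiles in examples and
#' tests: one row per `sample_id`, all 17 disaccharide concentrations 0.
#'
#' @param sample_id Character vector of sample identifiers.
#' @return Tibble with `sample_id` and the 17 canonical disaccharide columns.
#' @export
empty_profile <- function(sample_id) {
  out <- tibble::tibble(sample_id = sample_id)
  for (d in gag_panel()$name) out[[d]] <- 0
  out
}

#' Plasma detectability of the measured disaccharides
#'
#' A disaccharide is considered detectable in plasma when its median
#' concentration across all samples is strictly above the limit of
#' detection (default 0.1 ug/mL). Medians are taken over samples with the
#' value present; for an even number of values the midpoint of the two
#' central order statistics is used.
#'
#' @param profiles Data frame of GAGome profiles (as for
#'   [expand_features()]).
#' @param lod Limit of detection in ug/mL (> 0); default `0.1`.
#' @return An object of class `gag_detectability`: list with `lod`,
#'   `medians` (named numeric, all 17 disaccharides) and `detectable`
#'   (character vector of canonical names with median > lod).
#' @export
detectable_features <- function(profiles, lod = 0.1) {
  if (nrow(profiles) < 1) stop("empty cohort: no profiles", call. = FALSE)
  stopifnot(is.numeric(lod), length(lod) == 1, lod > 0)
  m <- .profile_matrix(profiles)
  med <- apply(m, 2, stats::median, na.rm = TRUE)
  structure(
    list(lod = lod, medians = med, detectable = names(med)[!is.na(med) & med > lod]),
    class = "gag_detectability"
  )
}

#' @export
print.gag_detectability <- function(x, ...) {
  cat("GAGome detectability (LOD ", x$lod, " ug/mL): ",
      length(x$detectable), " of ", length(x$medians),
      " disaccharides detectable\n", sep = "")
  if (length(x$detectable)) {
    cat("  ", paste(x$detectable, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Select the analyzable GAGome features
#'
#' Restricts the 39-feature GAGome to the features supported by the
#' detectable disaccharides: the detectable absolute concentrations, plus
#' every derived feature all of whose measured constituents are
#' quantifiable. Concretely, a mass fraction requires its numerator
#' disaccharide detectable; a ratio requires both its disaccharides
#' detectable; a class total requires at least one disaccharide of the
#' class detectable (undetectable members contribute negligibly); a class
#' charge requires every sulfated disaccharide of the class detectable,
#' because each sulfated fraction contributes with weight >= 1.
#'
#' With the detectable set `{0S CS, 4S CS}` this yields the six analysis
#' features `0S CS`, `4S CS`, `0S CS fraction`, `4S CS fraction`,
#' `4S CS/0S CS` and `total CS`; with all 17 detectable it yields all 39.
#'
#' @param det A `gag_detectability` object from [detectable_features()],
#'   or a character vector of detectable canonical disaccharide names.
#' @return Ordered character vector of analysis feature names.
#' @export
select_analysis_features <- function(det) {
  detectable <- if (inherits(det, "gag_detectability")) det$detectable else det
  panel <- gag_panel()
  bad <- setdiff(detectable, panel$name)
  if (length(bad) > 0) {
    stop("unknown disaccharide identity: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cs <- .class_members("CS")
  hs <- .class_members("HS")
  keep_conc <- panel$name[panel$name %in% detectable]
  keep_frac <- unlist(lapply(c(cs, hs), function(d) {
    if (d %in% detectable) paste(d, "fraction") else character()
  }))
  keep_ratio <- character()
  if (all(c("4S CS", "0S CS") %in% detectable)) keep_ratio <- c(keep_ratio, "4S CS/0S CS")
  if (all(c("6S CS", "0S CS") %in% detectable)) keep_ratio <- c(keep_ratio, "6S CS/0S CS")
  keep_total <- character()
  if (any(cs %in% detectable)) keep_total <- c(keep_total, "total CS")
  if (any(hs %in% detectable)) keep_total <- c(keep_total, "total HS")
  keep_charge <- character()
  sulfated <- function(members) members[sulfo_count(members) > 0]
  if (all(sulfated(cs) %in% detectable)) keep_charge <- c(keep_charge, "CS charge")
  if (all(sulfated(hs) %in% detectable)) keep_charge <- c(keep_charge, "HS charge")
  c(keep_conc, keep_frac, keep_ratio, keep_total, keep_charge)
}

#' Read a wide GAGome CSV
#'
#' Expects a `sample_id` column plus the 17 disaccharide columns in
#' CSV-style names (`CS_0S`, ..., `HA_0S`), values in ug/mL; empty cells
#' are read as missing.
#'
#' @param path Path to the CSV file.
#' @return Tibble with `sample_id` and canonical disaccharide columns.
#' @export
read_gagome_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = c(sample_id = "character"))
  panel <- gag_panel()
  idx <- match(names(df), panel$column)
  names(df)[!is.na(idx)] <- panel$name[idx[!is.na(idx)]]
  .profile_matrix(df)  # validates
  tibble::as_tibble(df)
}

#' Write GAGome profiles or features to CSV
#'
#' Profiles are written with CSV-style column names; missing/unavailable
#' values become empty cells. For feature tables, `availability = TRUE`
#' appends one `<feature>__available` logical column per feature.
#'
#' @param x Tibble of profiles (from the generator / [read_gagome_csv()])
#'   or features (from [expand_features()]).
#' @param path Output path.
#' @param availability Write sidecar availability columns (features only).
#' @return `path`, invisibly.
#' @export
write_gagome_csv <- function(x, path, availability = FALSE) {
  panel <- gag_panel()
  out <- as.data.frame(x, check.names = FALSE)
  idx <- match(names(out), panel$name)
  names(out)[!is.na(idx)] <- panel$column[idx[!is.na(idx)]]
  if (availability) {
    feats <- setdiff(names(x), "sample_id")
    for (f in feats) out[[paste0(f, "__available")]] <- !is.na(x[[f]])
  }
  .write_csv_full(out, path)
  invisible(path)
}

# internal: CSV writer preserving doubles exactly (17 significant digits),
# NA as empty cell — so read(write(x)) round-trips bit-identically.
.write_csv_full <- function(df, path) {
  df <- as.data.frame(df, check.names = FALSE)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      v <- sprintf("%.17g", df[[j]])
      v[is.na(df[[j]])] <- NA_character_
      df[[j]] <- v
    }
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
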