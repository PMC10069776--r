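#' Declare a trait column
#'
#' A trait specification records how one column of a species-by-trait table
#' is typed and handled: its measurement type, the category labels for
#' categorical traits, whether the trait is natural-log transformed before
#' imputation, and how a missing-not-at-random deletion targets it.
#'
#' @param name Column name in the table.
#' @param dtype One of `"continuous"`, `"count"`, `"binary"`,
#'   `"multicategorical"`.
#' @param categories Character vector of category labels; required for
#'   `"binary"` (exactly two) and `"multicategorical"` (two or more),
#'   disallowed otherwise.
#' @param transform `"none"` or `"natural_log"`. The log transform is only
#'   permitted for numerical dtypes and requires strictly positive values;
#'   signed traits such as a latitude centroid must use `"none"`.
#' @param mnar Optional list describing the MNAR deletion rule for this
#'   trait. For numerical traits: `list(side, fraction)` with `side` one of
#'   `"lower"`, `"upper"`, `"center_on_zero"` and `fraction` defaulting to
#'   0.10. For categorical traits: `list(category, fraction, cap)` with
#'   `fraction` defaulting to 1 (the whole category). When `NULL`, a default
#'   is chosen at masking time (lower tail for numerical traits, the rarest
#'   category for categorical ones).
#' @param role `"trait"` for ordinary traits, `"eigenvector"` for appended
#'   phylogenetic eigenvector columns (predictor-only: never imputed, never
#'   evaluated).
#' @return An object of class `trait_spec`.
#' @seealso [trait_table()], [load_trait_table()]
#' @export
trait_spec <- function(name, dtype = c("continuous", "count", "binary",
                                       "multicategorical"),
                       categories = NULL, transform = c("none", "natural_log"),
                       mnar = NULL, role = c("trait", "eigenvector")) {
  dtype <- match.arg(dtype)
  transform <- match.arg(transform)
  role <- match.arg(role)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stopf("trait name must be a non-empty string")
  categorical <- dtype %in% c("binary", "multicategorical")
  if (categorical) {
    if (is.null(categories) || length(categories) < 2L)
      stopf("trait '%s': categorical dtypes need >= 2 category labels", name)
    if (dtype == "binary" && length(categories) != 2L)
      stopf("trait '%s': binary traits need exactly 2 categories", name)
    if (anyDuplicated(categories))
      stopf("trait '%s': duplicate category labels", name)
    if (transform == "natural_log")
      stopf("trait '%s': natural_log is only valid for numerical traits", name)
  } else if (!is.null(categories)) {
    stopf("trait '%s': categories are only valid for categorical dtypes", name)
  }
  structure(list(name = name, dtype = dtype,
                 categories = as.character(categories %||% character(0)),
                 transform = transform, mnar = mnar, role = role),
            class = "trait_spec")
}

is_categorical <- function(spec) spec$dtype %in% c("binary", "multicategorical")
is_numerical <- function(spec) !is_categorical(spec)

#' Assemble a species-by-trait table
#'
#' The central data container: unique species identifiers, one declared
#' [trait_spec()] per column, and a data frame of values in which `NA` marks
#' a missing observation. Count cells must be non-negative integers and
#' categorical cells members of their declared categories.
#'
#' @param species Character vector of unique, non-empty species identifiers.
#' @param specs List of [trait_spec()] objects, one per column of `data`.
#' @param data Data frame of trait values (rows follow `species`).
#' @return An object of class `trait_table` with elements `species`,
#'   `specs` (named list) and `data` (numeric columns for numerical traits,
#'   factors with the declared levels for categorical ones).
#' @export
trait_table <- function(species, specs, data) {
  species <- as.character(species)
  if (anyDuplicated(species)) stopf("duplicate species identifiers")
  if (any(!nzchar(species)) || anyNA(species))
    stopf("species identifiers must be non-empty")
  if (inherits(specs, "trait_spec")) specs <- list(specs)
  names(specs) <- vapply(specs, `[[`, "", "name")
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (nrow(data) != length(species))
    stopf("data has %d rows for %d species", nrow(data), length(species))
  missing_cols <- setdiff(names(specs), names(data))
  if (length(missing_cols))
    stopf("data lacks declared trait column(s): %s",
          paste(missing_cols, collapse = ", "))
  data <- data[names(specs)]
  for (sp in specs) data[[sp$name]] <- coerce_column(data[[sp$name]], sp, species)
  rownames(data) <- species
  structure(list(species = species, specs = specs, data = data),
            class = "trait_table")
}

coerce_column <- function(x, spec, species) {
  if (is_categorical(spec)) {
    x <- as.character(x)
    bad <- which(!is.na(x) & !(x %in% spec$categories))
    if (length(bad))
      stopf("trait '%s': unknown category '%s' for species '%s'",
            spec$name, x[bad[1L]], species[bad[1L]])
    factor(x, levels = spec$categories)
  } else {
    if (is.factor(x)) x <- as.character(x)
    if (is.character(x)) {
      xn <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & is.na(xn))
      if (length(bad))
        stopf("trait '%s': unparseable value '%s' for species '%s'",
              spec$name, x[bad[1L]], species[bad[1L]])
      x <- xn
    }
    x <- as.numeric(x)
    if (spec$dtype == "count" && !isTRUE(attr(spec, "transformed"))) {
      bad <- which(!is.na(x) & (x < 0 | x != floor(x)))
      if (length(bad))
        stopf("trait '%s': count value %s for species '%s' is not a non-negative integer",
              spec$name, format(x[bad[1L]]), species[bad[1L]])
    }
    x
  }
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("trait_table: %d species x %d traits\n",
              length(x$species), length(x$specs)))
  for (sp in x$specs) {
    miss <- mean(is.na(x$data[[sp$name]]))
    cat(sprintf("  %-20s %-16s %s%5.1f%% missing\n", sp$name, sp$dtype,
                if (sp$role == "eigenvector") "[eigenvector] " else "",
                100 * miss))
  }
  invisible(x)
}

#' @export
summary.trait_table <- function(object, ...) {
  out <- lapply(object$specs, function(sp) {
    x <- object$data[[sp$name]]
    c(n_observed = sum(!is.na(x)), missing_fraction = mean(is.na(x)))
  })
  do.call(rbind, out)
}

trait_names <- function(tt, role = "trait") {
  names(tt$specs)[vapply(tt$specs, `[[`, "", "role") == role]
}

evaluable_traits <- function(tt) trait_names(tt, "trait")

#' Per-trait missingness fractions
#'
#' @param tt A [trait_table()].
#' @return Named numeric vector of missing-value fractions, ordinary traits
#'   only.
#' @export
missing_fractions <- function(tt) {
  tr <- evaluable_traits(tt)
  vapply(tt$data[tr], function(x) mean(is.na(x)), 0)
}

#' Read a trait table from CSV
#'
#' Loads a UTF-8 CSV with a header row, one species-identifier column and
#' one column per declared trait, validating every cell against its
#' [trait_spec()]. Coercion failures are reported with the offending
#' species and trait.
#'
#' @param csv_path Path to the CSV file.
#' @param schema List of [trait_spec()] objects.
#' @param missing_token String marking a missing value (default `"NA"`).
#' @param id_column Name of the species-identifier column.
#' @return A validated [trait_table()].
#' @export
load_trait_table <- function(csv_path, schema, missing_token = "NA",
                             id_column = "species") {
  raw <- utils::read.csv(csv_path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL,
                         fileEncoding = "UTF-8")
  if (!(id_column %in% names(raw)))
    stopf("CSV lacks the species-identifier column '%s'", id_column)
  raw[raw == missing_token] <- NA
  trait_table(raw[[id_column]], schema,
              raw[setdiff(names(raw), id_column)])
}

#' Write a trait table to CSV
#'
#' Inverse of [load_trait_table()]: a round-trip reproduces the values and
#' missingness pattern exactly.
#'
#' @inheritParams load_trait_table
#' @param tt A [trait_table()].
#' @param csv_path Output path.
#' @export
write_trait_table <- function(tt, csv_path, missing_token = "NA",
                              id_column = "species") {
  out <- data.frame(tt$species, stringsAsFactors = FALSE)
  names(out) <- id_column
  for (sp in tt$specs) {
    x <- tt$data[[sp$name]]
    x <- if (is.factor(x)) as.character(x) else
      vapply(x, format_roundtrip, "")
    x[is.na(x)] <- missing_token
    out[[sp$name]] <- x
  }
  utils::write.csv(out, csv_path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(csv_path)
}

# shortest decimal string that parses back to the identical double
format_roundtrip <- function(v) {
  if (is.na(v)) return(NA_character_)
  for (digits in c(15L, 16L, 17L)) {
    s <- format(v, digits = digits, scientific = FALSE, trim = TRUE)
    if (identical(as.numeric(s), as.numeric(v))) return(s)
  }
  s
}

#' Flag severe outliers in a numeric vector
#'
#' A value is a severe outlier when it strictly exceeds
#' Q3 + 3 * IQR of the non-missing data, with quartiles computed by linear
#' interpolation of order statistics (type-7 quantiles). Used as a screen
#' when constructing a complete-case dataset; flagged values are meant to
#' be verified against primary sources, not dropped automatically.
#'
#' @param values Numeric vector, possibly with `NA`s.
#' @return Integer indices (into `values`) of severe outliers; missing
#'   values are never flagged.
#' @export
detect_severe_outliers <- function(values) {
  obs <- which(!is.na(values))
  if (length(obs) < 4L)
    stopf("need >= 4 non-missing values to screen for outliers")
  q <- stats::quantile(values[obs], c(0.25, 0.75), type = 7, names = FALSE)
  threshold <- q[2L] + 3 * (q[2L] - q[1L])
  obs[values[obs] > threshold]
}

#' Screen a categorical trait for severe class imbalance
#'
#' @param values Factor or character vector of category labels.
#' @param dominance_threshold Exclusion threshold on the modal category's
#'   share of non-missing observations (default 0.90).
#' @return `TRUE` when the trait should be kept, `FALSE` when the modal
#'   category's share strictly exceeds the threshold (e.g. 91/100 excludes,
#'   exactly 90/100 keeps).
#' @export
screen_class_imbalance <- function(values, dominance_threshold = 0.90) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stopf("all values missing")
  max(table(as.character(values))) / length(values) <= dominance_threshold
}

#' Build a near complete-case table
#'
#' Restricts a table to a row subset in which (a) every trait's missingness
#' is at most `max_missing_per_trait` and (b) every species with any
#' missing cell still has observed values for at least `min_observed_other`
#' of its other traits. Rows violating (b) are dropped first; then rows
#' with missing cells are dropped greedily (most missing cells first, ties
#' broken by species identifier) until (a) holds.
#'
#' @param tt A [trait_table()].
#' @param max_missing_per_trait Maximum per-trait missing fraction
#'   (default 0.10).
#' @param min_observed_other Minimum observed other traits for incomplete
#'   rows (default 3).
#' @return The filtered [trait_table()].
#' @export
build_near_complete_case <- function(tt, max_missing_per_trait = 0.10,
                                     min_observed_other = 3L) {
  traits <- evaluable_traits(tt)
  miss <- is.na(as.matrix(tt$data[traits]))
  n_missing <- rowSums(miss)
  # (b): a row missing in trait j has (p - n_missing) observed cells among
  # the other traits, so the bound is the same for every missing trait.
  n_observed <- length(traits) - n_missing
  keep <- n_missing == 0L | n_observed >= min_observed_other
  idx <- which(keep)
  repeat {
    frac <- colSums(miss[idx, , drop = FALSE]) / length(idx)
    if (length(idx) == 0L) stopf("near complete-case construction emptied the table")
    if (all(frac <= max_missing_per_trait)) break
    cand <- idx[rowSums(miss[idx, , drop = FALSE]) > 0L]
    if (length(cand) == 0L) stopf("cannot satisfy the per-trait missingness bound")
    ord <- order(-rowSums(miss[cand, , drop = FALSE]), tt$species[cand])
    idx <- setdiff(idx, cand[ord[1L]])
  }
  subset_trait_table(tt, tt$species[sort(idx)])
}

subset_trait_table <- function(tt, species) {
  i <- match(species, tt$species)
  if (anyNA(i)) stopf("unknown species: %s", species[which(is.na(i))[1L]])
  out <- tt
  out$species <- tt$species[i]
  out$data <- tt$data[i, , drop = FALSE]
  rownames(out$data) <- out$species
  out
}

#' Natural-log transform numerical traits
#'
#' Applies each trait's declared transform (currently `natural_log`) to put
#' numerical traits on the model scale used by the imputers and error
#' metrics; categorical traits are untouched. [invert_transforms()] maps a
#' table back to the original scale for reporting.
#'
#' @param tt A [trait_table()].
#' @return Transformed copy, marked so that a second application is
#'   rejected.
#' @export
apply_transforms <- function(tt) {
  if (isTRUE(attr(tt, "transformed"))) stopf("table is already transformed")
  for (sp in tt$specs) {
    if (sp$transform != "natural_log") next
    x <- tt$data[[sp$name]]
    bad <- which(!is.na(x) & x <= 0)
    if (length(bad))
      stopf("trait '%s': non-positive value for species '%s' cannot be log-transformed",
            sp$name, tt$species[bad[1L]])
    tt$data[[sp$name]] <- log(x)
  }
  attr(tt, "transformed") <- TRUE
  tt
}

#' @rdname apply_transforms
#' @param round_counts Round back-transformed count traits to integers
#'   (default `FALSE`: evaluation happens on the model scale, so reported
#'   back-transformed counts are left non-integer unless asked for).
#' @export
invert_transforms <- function(tt, round_counts = FALSE) {
  if (!isTRUE(attr(tt, "transformed"))) stopf("table is not transformed")
  for (sp in tt$specs) {
    if (sp$transform != "natural_log") next
    x <- exp(tt$data[[sp$name]])
    if (round_counts && sp$dtype == "count") x <- round_half_up(x)
    tt$data[[sp$name]] <- x
  }
  attr(tt, "transformed") <- FALSE
  tt
}
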