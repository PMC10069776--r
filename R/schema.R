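# Trait-schema I/O: the structured config block declaring each trait's
# type, categories, transform, and MNAR tail specification.

#' Read a trait schema from a YAML config
#'
#' The schema is a YAML document with fields `id_column` (default
#' `"species"`), `missing_token` (default `"NA"`), and `traits`, a list of
#' entries with `name`, `dtype`, optional `categories`, `transform`, and
#' `mnar` (tail specification).
#'
#' @param path Path to the YAML file.
#' @return List with `id_column`, `missing_token`, and `specs` (a list of
#'   [trait_spec()]).
#' @export
read_trait_schema <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$traits)) stopf("schema lacks a 'traits' block")
  specs <- lapply(doc$traits, function(tr)
    trait_spec(tr$name, tr$dtype,
               categories = unlist(tr$categories),
               transform = tr$transform %||% "none",
               mnar = tr$mnar))
  list(id_column = doc$id_column %||% "species",
       missing_token = as.character(doc$missing_token %||% "NA"),
       specs = specs)
}

#' Write the trait schema of a table as YAML
#'
#' @param tt A [trait_table()] (or a list of [trait_spec()]).
#' @param path Output path.
#' @param id_column,missing_token Stored alongside the trait declarations.
#' @export
write_trait_schema <- function(tt, path, id_column = "species",
                               missing_token = "NA") {
  specs <- if (inherits(tt, "trait_table")) tt$specs else tt
  traits <- lapply(specs, function(sp) {
    if (sp$role != "trait") return(NULL)
    entry <- list(name = sp$name, dtype = sp$dtype)
    if (length(sp$categories)) entry$categories <- as.list(sp$categories)
    if (sp$transform != "none") entry$transform <- sp$transform
    if (!is.null(sp$mnar)) entry$mnar <- sp$mnar
    entry
  })
  doc <- list(id_column = id_column, missing_token = missing_token,
              traits = Filter(Negate(is.null), unname(traits)))
  yaml::write_yaml(doc, path)
  invisible(path)
}
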