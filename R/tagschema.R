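#' The lexicogrammar tag schema
#'
#' The package annotates every word of a transcript with a fixed taxonomy of
#' 147 lexicogrammatical tag types drawn from Systemic Functional Linguistics
#' (SFL). Tags are grouped under 16 headings (e.g. "Modality", "Negotiating
#' particle", "Filler"); headings 1--6 realise the ideational metafunction,
#' headings 7--16 the interpersonal metafunction. The schema ships as a
#' versioned TSV resource so that the tag-to-column mapping is stable across
#' runs and serialisations.
#'
#' @return A tibble of class `sfl_schema` with one row per tag and columns
#'   `index` (0-based column index into tag matrices), `name` (unique slug,
#'   e.g. `"negotiating_particle.sfp_ne"`), `heading`, `metafunction`
#'   (`"ideational"` or `"interpersonal"`) and `description`. The attribute
#'   `schema_version` records the resource version.
#' @examples
#' s <- default_schema()
#' nrow(s) # 147
#' dplyr::count(s, heading)
#' @export
default_schema <- function() {
  if (is.null(.schema_cache$schema)) {
    path <- system.file("extdata", "tagschema_v1.tsv", package = "sflscreen")
    tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(
                            index = readr::col_integer(),
                            .default = readr::col_character()
                          ))
    tb <- validate_schema(tb)
    attr(tb, "schema_version") <- "v1"
    class(tb) <- c("sfl_schema", class(tb))
    .schema_cache$schema <- tb
  }
  .schema_cache$schema
}

.schema_cache <- new.env(parent = emptyenv())

#' Validate a tag schema table
#'
#' Checks the structural invariants of the taxonomy: 147 tags, unique names,
#' a bijective 0-based index, and non-empty headings.
#'
#' @param schema A data frame with columns `index`, `name`, `heading`,
#'   `metafunction`, `description`.
#' @return The schema, invisibly coerced to a tibble, or an error.
#' @export
validate_schema <- function(schema) {
  schema <- tibble::as_tibble(schema)
  need <- c("index", "name", "heading", "metafunction", "description")
  if (!all(need %in% names(schema))) {
    abort(paste0("schema is missing columns: ",
                 paste(setdiff(need, names(schema)), collapse = ", ")))
  }
  if (nrow(schema) != 147L) {
    abort(sprintf("schema must contain exactly 147 tags, got %d", nrow(schema)))
  }
  if (anyDuplicated(schema$name)) abort("tag names must be unique")
  if (!identical(sort(schema$index), 0:146)) {
    abort("schema index must be a bijection over 0..146")
  }
  if (any(!nzchar(schema$heading))) abort("headings must be non-empty")
  if (!all(schema$metafunction %in% c("ideational", "interpersonal"))) {
    abort("metafunction must be 'ideational' or 'interpersonal'")
  }
  schema
}

#' Number of tag categories in a schema
#'
#' @param schema A schema, as returned by [default_schema()].
#' @return Integer count of tag types (147 for the built-in schema).
#' @export
tag_count <- function(schema = default_schema()) nrow(schema)

#' Map tag names to matrix column indices and back
#'
#' Tag matrices are `L x 147` with columns ordered by the schema's `index`
#' field. `tag_index()` resolves a tag name to its 0-based column index;
#' `tag_name()` is the inverse.
#'
#' @param schema A schema, as returned by [default_schema()].
#' @param name Character vector of tag names.
#' @param index Integer vector of 0-based indices.
#' @return `tag_index()`: integer vector of 0-based indices. `tag_name()`:
#'   character vector of tag names.
#' @examples
#' s <- default_schema()
#' i <- tag_index(s, "negotiating_particle.sfp_ne")
#' tag_name(s, i)
#' @export
tag_index <- function(schema, name) {
  pos <- match(name, schema$name)
  if (anyNA(pos)) {
    abort(paste0("unknown tag name(s): ",
                 paste(name[is.na(pos)], collapse = ", ")))
  }
  schema$index[pos]
}

#' @rdname tag_index
#' @export
tag_name <- function(schema, index) {
  pos <- match(index, schema$index)
  if (anyNA(pos)) {
    abort(paste0("unknown tag index(es): ",
                 paste(index[is.na(pos)], collapse = ", ")))
  }
  schema$name[pos]
}

#' Write a schema to a TSV file
#'
#' Serialises the schema in the same flat format it ships in, so that
#' reading it back yields an identical index mapping.
#'
#' @param schema A schema tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  readr::write_tsv(tibble::as_tibble(schema)[, c("index", "name", "heading",
                                                 "metafunction", "description")],
                   path, progress = FALSE)
  invisible(path)
}

#' Read a schema from a TSV file
#'
#' @param path Path to a schema TSV written by [write_schema()].
#' @return A validated `sfl_schema` tibble.
#' @export
read_schema <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          index = readr::col_integer(),
                          .default = readr::col_character()
                        ))
  tb <- validate_schema(tb)
  class(tb) <- c("sfl_schema", class(tb))
  tb
}
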