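# Record cards: the dashed plain-text rendering of entities. Rendering is
# pure (no store access) and every printed value comes from the entity; the
# "?" marker is the render-time face of a typed unknown (NA).

card_separator <- strrep("-", 39L)

orq <- function(x) if (is.null(x) || is.na(x)) "?" else as.character(x)

card_lines <- function(entity, truncate_at) UseMethod("card_lines")

#' @export
card_lines.article <- function(entity, truncate_at) {
  author <- if (length(entity$authors)) {
    a <- entity$authors[[1]]
    trimws(paste(orq(a$last), orq(a$first)))
  } else "?"
  c(
    paste0("ID: ", entity$pmid),
    paste0("TITLE: ", orq(entity$title)),
    paste0("AUTHOR: ", author),
    paste0("JOURNAL: ", orq(entity$journal), " ", orq(entity$volume),
           "(", orq(entity$issue), "), ", orq(entity$year),
           ", DOI: ", orq(entity$doi))
  )
}

#' @export
card_lines.disease <- function(entity, truncate_at) {
  c(paste0("Name: ", orq(entity$name)),
    "Link at MalaCards:",
    entity$card_link)
}

#' @export
card_lines.biomodel <- function(entity, truncate_at) {
  desc <- orq(entity$description)
  if (nchar(desc) > truncate_at)
    desc <- paste0(substr(desc, 1L, truncate_at), "…")
  c(paste0("Id: ", entity$model_id),
    paste0("Description: ", desc))
}

#' @export
card_lines.aneurysm_case <- function(entity, truncate_at) {
  c(paste0("Patient ID: ", entity$patient_id),
    paste0("SEX: ", entity$sex, ", AGE: ", entity$age),
    paste0("Aneurysm type: ", entity$aneurysm_type,
           ", location:", entity$location,
           ", status: ", entity$status))
}

#' @export
card_lines.default <- function(entity, truncate_at) {
  stop_biocurate("biocurate_render_error",
                 paste0("no card rendering for class ", class(entity)[[1]]))
}

#' Render an entity as a record card
#'
#' Produces the dashed plain-text card for a single entity: a separator line
#' of 39 hyphens, the entity's field lines, and a closing separator. Unknown
#' values render as `?`; model descriptions longer than `truncate_at`
#' characters are cut and suffixed with an ellipsis.
#'
#' @param entity an [article()], [disease()], [biomodel()] or
#'   [aneurysm_case()].
#' @param truncate_at description truncation length for model cards.
#' @return The card as a single string (lines joined by `"\n"`).
#' @examples
#' cat(render_card(demo_articles()[[1]]))
#' @export
render_card <- function(entity, truncate_at = 80L) {
  lines <- card_lines(entity, truncate_at = truncate_at)
  paste(c(card_separator, lines, card_separator), collapse = "\n")
}

#' @rdname render_card
#' @param entities list of entities.
#' @details `render_cards()` stacks several cards into one block; adjacent
#'   cards share a single separator line, as on a terminal listing.
#' @export
render_cards <- function(entities, truncate_at = 80L) {
  stopifnot(is.list(entities))
  if (!length(entities)) return(card_separator)
  body <- lapply(entities, card_lines, truncate_at = truncate_at)
  chunks <- unlist(lapply(body, function(b) c(b, card_separator)))
  paste(c(card_separator, chunks), collapse = "\n")
}
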