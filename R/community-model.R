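#' Construct a set-based community metabolic model
#'
#' A community model is a medium (a set of freely available metabolites) plus,
#' per species, the set of metabolites it requires for growth and the set it
#' secretes when growing. This boolean abstraction of genome-scale metabolic
#' models keeps every community-level quantity (growth, coupling scores,
#' minimal media) exactly enumerable; all derived scores are set-based
#' analogs of their flux-based counterparts.
#'
#' @param species A data frame with columns `id` (character, unique),
#'   `required` and `secreted` (list-columns of character vectors).
#' @param medium Character vector of metabolites freely available to all.
#' @param metabolites Optional metabolite universe; defaults to the union of
#'   the medium and all required/secreted sets.
#' @return An object of class `community_model`.
#' @examples
#' sp <- tibble::tibble(
#'   id = c("a", "b"),
#'   required = list("m0", "m1"),
#'   secreted = list("m1", character())
#' )
#' community_model(sp, medium = "m0")
#' @export
community_model <- function(species, medium = character(), metabolites = NULL) {
  if (!is.data.frame(species) ||
      !all(c("id", "required", "secreted") %in% names(species))) {
    stop_invalid("`species` needs columns `id`, `required`, `secreted`")
  }
  species <- as_tibble(species)
  species$id <- as.character(species$id)
  if (anyDuplicated(species$id)) stop_invalid("species ids must be unique")
  species$required <- lapply(species$required, as.character)
  species$secreted <- lapply(species$secreted, as.character)
  medium <- as.character(medium)
  used <- unique(c(medium, unlist(species$required), unlist(species$secreted)))
  metabolites <- as.character(metabolites %||% sort(used))
  if (!all(used %in% metabolites)) {
    stop_invalid("all medium/required/secreted metabolites must be in `metabolites`")
  }
  n <- nrow(species)
  m <- length(metabolites)
  set_mat <- function(sets) {
    out <- matrix(FALSE, n, m, dimnames = list(species$id, metabolites))
    for (i in seq_len(n)) out[i, match(sets[[i]], metabolites)] <- TRUE
    out
  }
  structure(
    list(
      metabolites = metabolites,
      medium = medium,
      species = species,
      req = set_mat(species$required),
      sec = set_mat(species$secreted)
    ),
    class = "community_model"
  )
}

#' @export
print.community_model <- function(x, ...) {
  cat(sprintf("<community_model> %d species, %d metabolites, medium of %d\n",
              nrow(x$species), length(x$metabolites), length(x$medium)))
  invisible(x)
}

species_ids <- function(model) model$species$id

check_species <- function(model, ids, name = "species") {
  ids <- as.character(ids)
  missing <- setdiff(ids, species_ids(model))
  if (length(missing) > 0) {
    stop_invalid(sprintf("unknown %s id(s): %s", name,
                         paste(missing, collapse = ", ")))
  }
  ids
}

#' Read or write a community model as JSON
#'
#' Schema: `{"metabolites": [...], "medium": [...], "species":
#' [{"id": ..., "required": [...], "secreted": [...]}]}`.
#'
#' @param path File path.
#' @return `read_community_json()` returns a [community_model()].
#' @export
read_community_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  sp <- tibble(
    id = vapply(x$species, function(s) as.character(s$id), character(1)),
    required = lapply(x$species, function(s) as.character(unlist(s$required))),
    secreted = lapply(x$species, function(s) as.character(unlist(s$secreted)))
  )
  community_model(sp, medium = as.character(unlist(x$medium)),
                  metabolites = as.character(unlist(x$metabolites)))
}

#' @rdname read_community_json
#' @param model A [community_model()].
#' @export
write_community_json <- function(model, path) {
  payload <- list(
    metabolites = model$metabolites,
    medium = model$medium,
    species = lapply(seq_len(nrow(model$species)), function(i) {
      list(id = model$species$id[i],
           required = model$species$required[[i]],
           secreted = model$species$secreted[[i]])
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
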