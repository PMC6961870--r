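#' Serialize a DSI model to JSON
#'
#' Writes the complete fitted state — per (pair, feature) the sorted
#' reference breakpoints of both groups, orientation, relevance and
#' degeneracy flag — so a model can be reloaded bit-identically.
#'
#' @param model A `dsi_model`.
#' @param path JSON file path.
#' @return `write_dsi_model()`: `path` invisibly; `read_dsi_model()`:
#'   a `dsi_model`.
#' @export
write_dsi_model <- function(model, path) {
  pairs <- lapply(model$pairs, function(fits) {
    lapply(fits, function(ff) {
      list(pos = ff$pos, neg = ff$neg, orientation = ff$orientation,
           relevance = ff$relevance, degenerate = ff$degenerate)
    })
  })
  jsonlite::write_json(
    list(features = model$features, min_ref = model$min_ref,
         group_sizes = as.list(model$group_sizes), pairs = pairs),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_dsi_model
#' @export
read_dsi_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  pairs <- lapply(raw$pairs, function(fits) {
    lapply(fits, function(ff) {
      structure(
        list(pos = as.double(ff$pos), neg = as.double(ff$neg),
             orientation = as.integer(ff$orientation),
             relevance = as.double(ff$relevance),
             degenerate = isTRUE(ff$degenerate)),
        class = "fitness_function"
      )
    })
  })
  structure(
    list(pairs = pairs, features = as.character(raw$features),
         min_ref = as.integer(raw$min_ref),
         group_sizes = unlist(raw$group_sizes)),
    class = "dsi_model"
  )
}

#' Serialize a PCC model to JSON
#'
#' @param model A `pcc_model`.
#' @param path JSON file path.
#' @return `write_pcc_model()`: `path` invisibly; `read_pcc_model()`:
#'   a `pcc_model`.
#' @export
write_pcc_model <- function(model, path) {
  jsonlite::write_json(
    list(points = as.data.frame(model$points), k = model$k,
         standardization = model$standardization,
         features = model$features, min_ref = model$min_ref),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_pcc_model
#' @export
read_pcc_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(points = tibble::as_tibble(raw$points),
         k = as.integer(raw$k),
         standardization = as.list(raw$standardization),
         features = as.character(raw$features),
         min_ref = as.integer(raw$min_ref)),
    class = "pcc_model"
  )
}
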