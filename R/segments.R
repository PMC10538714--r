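#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a 16-segment model
#'
#' @param territories named character vector mapping segment ids
#'   \code{"1"}..\code{"16"} to \code{"LAD"}, \code{"LCX"} or \code{"BOTH"}.
#' @return A [SegmentModel-class].
#' @export
SegmentModel <- function(territories) {
  territories <- territories[order(as.integer(names(territories)))]
  new("SegmentModel", territories = stats::setNames(
    as.character(territories), names(territories)))
}

#' Default 16-segment coronary territory map
#'
#' Reads the segment-to-territory map shipped with the package
#' (\code{inst/extdata/segment_territories.json}). The assignment of
#' segments to the LAD, LCX and shared (BOTH) territories follows the usual
#' anterior/anteroseptal vs lateral/inferolateral division of the canine
#' short-axis model, but the published layout is pictorial only, so this
#' default is an editable approximation: pass your own file to
#' [readSegmentModel()] to override it.
#'
#' @return A [SegmentModel-class].
#' @examples
#' defaultSegmentModel()
#' @export
defaultSegmentModel <- function() {
  readSegmentModel(system.file("extdata", "segment_territories.json",
                               package = "myoflow", mustWork = TRUE))
}

#' Read a segment-territory map from JSON
#'
#' The file holds a single object \code{{"1": "LAD", ..., "16": "LCX"}}.
#'
#' @param path path to a JSON file mapping segment id to territory.
#' @return A [SegmentModel-class].
#' @export
readSegmentModel <- function(path) {
  m <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  m <- m[grepl("^[0-9]+$", names(m))]  # ignore comment/metadata keys
  SegmentModel(m)
}

#' Aggregate per-segment values over a coronary territory
#'
#' Unweighted mean of the per-segment values belonging to a territory.
#' Every segment assigned to the territory must have a value.
#'
#' @param values named numeric vector of per-segment values; names are
#'   segment ids \code{"1"}..\code{"16"} (a subset covering the territory
#'   suffices).
#' @param model a [SegmentModel-class].
#' @param territory \code{"LAD"}, \code{"LCX"}, \code{"BOTH"}, or
#'   \code{"GLOBAL"} for the unweighted mean over all 16 segments.
#' @return The territory mean (numeric scalar).
#' @examples
#' vals <- stats::setNames(rep(1, 16), as.character(1:16))
#' aggregateSegments(vals, defaultSegmentModel(), "LAD")  # 1
#' @export
aggregateSegments <- function(values, model, territory) {
  stopifnot(is(model, "SegmentModel"))
  if (!is.character(territory) || length(territory) != 1L ||
      !(territory %in% c(.TERRITORIES, "GLOBAL")))
    stop("unknown territory: must be LAD, LCX, BOTH or GLOBAL")
  segs <- if (territory == "GLOBAL") names(model@territories)
          else names(model@territories)[model@territories == territory]
  if (is.null(names(values)))
    stop("'values' must be named by segment id")
  missing <- setdiff(segs, names(values))
  if (length(missing))
    stop("missing values for segment(s): ", paste(missing, collapse = ", "))
  v <- values[segs]
  if (any(!is.finite(v)))
    stop("non-finite value in territory ", territory)
  mean(v)
}
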