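#' Build the multilayer finite-element grid
#'
#' Lays out uniformly spaced linear-element nodes within each layer and
#' duplicates the node at every interlayer boundary so that the concentration
#' field can be discontinuous there (one node carries the upstream-side
#' value, its twin the downstream-side value).
#'
#' @param layers List of \code{\link{layer_spec}} objects, ordered from the
#'   donor side.
#' @param geometry Optional \code{\link{cell_geometry}}; required when any
#'   layer is specified by volume.
#' @param disc A \code{\link{discretization}}; \code{nodes_per_layer} is
#'   recycled across layers.
#' @return A list with node positions \code{x} (cm, nondecreasing, duplicated
#'   exactly at interfaces), \code{layer_id} (per-node layer index),
#'   \code{layer_names}, per-layer \code{thickness}, element sizes \code{h},
#'   node index ranges \code{first}/\code{last}, and an \code{interfaces}
#'   data frame (left node, right node, position).
#' @examples
#' g <- build_grid(list(
#'   layer_spec("a", 1, thickness = 1),
#'   layer_spec("b", 1, thickness = 2)
#' ), disc = discretization(nodes_per_layer = 5))
#' sum(duplicated(g$x))  # 1 duplicated position at the single interface
#' @export
build_grid <- function(layers, geometry = NULL, disc = discretization()) {
  if (!is.list(layers) || length(layers) < 1L ||
      !all(vapply(layers, inherits, logical(1), "layer_spec"))) {
    stop("`layers` must be a list of layer_spec objects", call. = FALSE)
  }
  stopifnot(inherits(disc, "discretization"))
  nl <- length(layers)
  nn <- rep_len(disc$nodes_per_layer, nl)
  thick <- vapply(layers, resolve_thickness, numeric(1), geometry = geometry)
  if (any(thick <= 0)) stop("layer thickness must be positive", call. = FALSE)

  x <- numeric(0); layer_id <- integer(0)
  first <- integer(nl); last <- integer(nl)
  x0 <- 0
  for (i in seq_len(nl)) {
    xi <- x0 + seq(0, thick[i], length.out = nn[i])
    first[i] <- length(x) + 1L
    x <- c(x, xi)
    last[i] <- length(x)
    layer_id <- c(layer_id, rep.int(i, nn[i]))
    x0 <- x0 + thick[i]
  }
  ifc <- if (nl > 1L) {
    data.frame(left_node = last[-nl], right_node = first[-1L],
               position = cumsum(thick)[-nl])
  } else {
    data.frame(left_node = integer(0), right_node = integer(0),
               position = numeric(0))
  }
  list(x = x, layer_id = layer_id,
       layer_names = vapply(layers, `[[`, character(1), "name"),
       thickness = thick, h = thick / (nn - 1), n = nn,
       first = first, last = last, interfaces = ifc)
}
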