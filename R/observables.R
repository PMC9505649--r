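#' Mean concentration of one layer over time
#'
#' Volume-averaged (equivalently depth-averaged) concentration of a layer at
#' every recorded time, computed by trapezoidal integration of the nodal
#' field.
#'
#' @param result A \code{franz_sim}.
#' @param layer Layer name (e.g. \code{"receptor"}) or index.
#' @return Data frame with \code{time_h} and \code{concentration_mg_per_cm3}.
#' @export
layer_mean_concentration <- function(result, layer) {
  stopifnot(inherits(result, "franz_sim"))
  i <- layer_index(result, layer)
  idx <- result$grid$first[i]:result$grid$last[i]
  x <- result$x[idx]
  L <- result$grid$thickness[i]
  conc <- apply(result$C[, idx, drop = FALSE], 1, function(cc) trapz(x, cc) / L)
  data.frame(time_h = result$times, concentration_mg_per_cm3 = conc)
}

layer_index <- function(result, layer) {
  if (is.character(layer)) {
    i <- match(layer, result$grid$layer_names)
    if (is.na(i)) stop("no layer named '", layer, "'", call. = FALSE)
    i
  } else {
    i <- as.integer(layer)
    if (i < 1L || i > length(result$grid$layer_names)) {
      stop("layer index out of range", call. = FALSE)
    }
    i
  }
}

#' Receptor-chamber release curve
#'
#' The release curve is the volume-averaged receptor concentration at each
#' recorded time; it is what Franz-cell sampling measures (up to sampling
#' dilution).
#'
#' @param result A \code{franz_sim}.
#' @param layer Name of the receptor layer.
#' @return Data frame with \code{time_h} and \code{concentration_mg_per_cm3},
#'   of class \code{release_curve}.
#' @export
release_curve <- function(result, layer = "receptor") {
  out <- layer_mean_concentration(result, layer)
  class(out) <- c("release_curve", "data.frame")
  out
}

#' Drug amount in the top of the skin down to a given depth
#'
#' Integrates the skin concentration profile from the donor-facing surface
#' down to \code{depth} (trapezoid on the FEM nodes, linear interpolation at
#' the cut) and multiplies by the diffusional area. This is the quantity a
#' tape-strip assay measures when strips remove the outermost stratum
#' corneum to that depth.
#'
#' @param result A \code{franz_sim}.
#' @param t A recorded output time (h).
#' @param depth Depth from the skin surface, cm; must lie within the skin.
#' @param area Membrane area, cm^2 (defaults to the cell's exposure area).
#' @param layer Name of the skin layer.
#' @return Amount in mg.
#' @export
depth_window_amount <- function(result, t, depth,
                                area = result$geometry$exposure_area,
                                layer = "skin") {
  stopifnot(inherits(result, "franz_sim"))
  i <- layer_index(result, layer)
  L <- result$grid$thickness[i]
  if (!is.numeric(depth) || length(depth) != 1L || depth < 0 || depth > L + 1e-12) {
    stop("`depth` must lie within the skin layer [0, ", L, "] cm", call. = FALSE)
  }
  if (depth == 0) return(0)
  ti <- sim_time_index(result, t)
  idx <- result$grid$first[i]:result$grid$last[i]
  xs <- result$x[idx] - result$x[idx[1]]   # depth from donor-facing surface
  cc <- result$C[ti, idx]
  inside <- xs < depth - 1e-15
  xcut <- c(xs[inside], depth)
  ccut <- c(cc[inside], approx(xs, cc, xout = min(depth, max(xs)))$y)
  trapz(xcut, ccut) * area
}

#' Stratum-corneum window estimate of retained drug
#'
#' The total stripped thickness of a 70-strip tape-strip series is bounded
#' between 0.0035 cm (strips 0.5 um) and 0.0070 cm (strips 1 um). The
#' retained amount is estimated as the mean of the depth-window amounts at
#' the two bounds, mirroring how tape-strip totals are compared with the
#' simulated profile.
#'
#' @inheritParams depth_window_amount
#' @param depths The two depth bounds, cm.
#' @return Amount in mg.
#' @export
sc_window_estimate <- function(result, t,
                               area = result$geometry$exposure_area,
                               depths = c(0.0035, 0.0070), layer = "skin") {
  mean(vapply(depths, function(d) {
    depth_window_amount(result, t, d, area = area, layer = layer)
  }, numeric(1)))
}

#' Drug amount in each layer
#'
#' Per-layer trapezoidal integral of the concentration field times the
#' exposure area; the amounts sum to the (conserved) total mass.
#'
#' @param result A \code{franz_sim}.
#' @param t A recorded output time (h).
#' @param geometry A \code{\link{cell_geometry}} (defaults to the one stored
#'   in the result).
#' @return Named numeric vector of amounts (mg), one per layer.
#' @export
layer_amounts <- function(result, t, geometry = NULL) {
  stopifnot(inherits(result, "franz_sim"))
  if (is.null(geometry)) geometry <- result$geometry
  area <- if (is.null(geometry)) 1 else geometry$exposure_area
  ti <- sim_time_index(result, t)
  grid <- result$grid
  out <- vapply(seq_along(grid$layer_names), function(i) {
    idx <- grid$first[i]:grid$last[i]
    trapz(grid$x[idx], result$C[ti, idx]) * area
  }, numeric(1))
  setNames(out, grid$layer_names)
}

#' Concentration at a skin surface
#'
#' Nodal concentration at the donor-facing (\code{"top"}) or receptor-facing
#' (\code{"bottom"}) boundary of the skin layer, i.e. the skin-side value of
#' the interfacial jump.
#'
#' @param result A \code{franz_sim}.
#' @param t A recorded output time (h).
#' @param side \code{"top"} or \code{"bottom"}.
#' @param layer Name of the skin layer.
#' @return Concentration in mg/cm^3.
#' @export
skin_surface_concentration <- function(result, t, side = c("top", "bottom"),
                                       layer = "skin") {
  side <- match.arg(side)
  stopifnot(inherits(result, "franz_sim"))
  i <- layer_index(result, layer)
  ti <- sim_time_index(result, t)
  node <- if (side == "top") result$grid$first[i] else result$grid$last[i]
  result$C[ti, node]
}
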