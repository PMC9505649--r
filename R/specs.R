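#' Define a diffusion layer
#'
#' A layer is a one-dimensional slab with constant diffusivity and a uniform
#' initial concentration. Chamber layers (donor, receptor) may be specified
#' by their fluid volume instead of a thickness; the effective slab thickness
#' is then \code{volume / exposure_area} of the cell geometry, resolved when
#' the grid is built.
#'
#' @param name Text label, e.g. \code{"donor"}, \code{"skin"}, \code{"receptor"}.
#' @param diffusivity Diffusion coefficient within the layer, cm^2/h (> 0).
#' @param thickness Slab thickness in cm (> 0). Exactly one of
#'   \code{thickness} and \code{volume} must be given.
#' @param volume Fluid volume in cm^3 for chamber layers; converted to a
#'   thickness using the cell's exposure area.
#' @param initial_concentration Uniform initial concentration, mg/cm^3 (>= 0).
#' @return An object of class \code{layer_spec}.
#' @export
layer_spec <- function(name, diffusivity, thickness = NULL, volume = NULL,
                       initial_concentration = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(diffusivity) || length(diffusivity) != 1L ||
      !is.finite(diffusivity) || diffusivity <= 0) {
    stop("`diffusivity` must be a single positive number (cm^2/h)", call. = FALSE)
  }
  if (is.null(thickness) == is.null(volume)) {
    stop("give exactly one of `thickness` or `volume`", call. = FALSE)
  }
  if (!is.null(thickness) &&
      (!is.numeric(thickness) || length(thickness) != 1L ||
       !is.finite(thickness) || thickness <= 0)) {
    stop("`thickness` must be a single positive number (cm)", call. = FALSE)
  }
  if (!is.null(volume) &&
      (!is.numeric(volume) || length(volume) != 1L ||
       !is.finite(volume) || volume <= 0)) {
    stop("`volume` must be a single positive number (cm^3)", call. = FALSE)
  }
  if (!is.numeric(initial_concentration) || length(initial_concentration) != 1L ||
      !is.finite(initial_concentration) || initial_concentration < 0) {
    stop("`initial_concentration` must be a single non-negative number (mg/cm^3)",
         call. = FALSE)
  }
  structure(
    list(name = name, diffusivity = diffusivity, thickness = thickness,
         volume = volume, initial_concentration = initial_concentration),
    class = "layer_spec"
  )
}

#' Define an interlayer boundary condition
#'
#' The interfacial flux law combines a partition coefficient P (the
#' equilibrium skin:fluid concentration ratio across the boundary) with a
#' mass-transfer coefficient K (cm/h) expressing a surface barrier. The
#' `orientation` states which side of the boundary is the skin (the phase
#' whose equilibrium concentration is P times the adjacent fluid):
#' \describe{
#'   \item{\code{skin_downstream}}{fluid on the left, skin on the right:
#'     J = K (C_fluid - C_skin / P), e.g. the donor/skin boundary.}
#'   \item{\code{skin_upstream}}{skin on the left, fluid on the right:
#'     J = K (C_skin - P C_fluid), e.g. the skin/receptor boundary.}
#' }
#' Both give C_skin = P * C_fluid at equilibrium (the flux vanishes); they
#' differ in which side's concentration scale the rate coefficient acts on.
#'
#' @param partition Dimensionless partition coefficient P (> 0).
#' @param mass_transfer Mass-transfer coefficient K, cm/h (>= 0); K = 0 is an
#'   impermeable boundary, large K means near-instantaneous local equilibrium.
#' @param orientation One of \code{"skin_downstream"}, \code{"skin_upstream"}.
#' @return An object of class \code{interface_spec}.
#' @export
interface_spec <- function(partition, mass_transfer,
                           orientation = c("skin_downstream", "skin_upstream")) {
  orientation <- match.arg(orientation)
  if (!is.numeric(partition) || length(partition) != 1L ||
      !is.finite(partition) || partition <= 0) {
    stop("`partition` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(mass_transfer) || length(mass_transfer) != 1L ||
      !is.finite(mass_transfer) || mass_transfer < 0) {
    stop("`mass_transfer` must be a single non-negative number (cm/h)", call. = FALSE)
  }
  structure(
    list(partition = partition, mass_transfer = mass_transfer,
         orientation = orientation),
    class = "interface_spec"
  )
}

# Coefficients (a, b) of the directed flux law J = K (a * C_left - b * C_right).
interface_coefs <- function(iface) {
  p <- iface$partition
  if (iface$orientation == "skin_downstream") c(a = 1, b = 1 / p) else c(a = 1, b = p)
}

#' Franz-cell geometry
#'
#' @param exposure_area Orifice (diffusional) area, cm^2. The default 0.636
#'   cm^2 corresponds to a 0.9 cm orifice diameter.
#' @param donor_volume Donor chamber volume, cm^3.
#' @param receptor_volume Receptor chamber volume, cm^3.
#' @return An object of class \code{cell_geometry}. The effective thickness
#'   of a chamber modelled as a diffusion layer is volume / exposure_area.
#' @export
cell_geometry <- function(exposure_area = 0.636, donor_volume = 1,
                          receptor_volume = 12) {
  vals <- c(exposure_area, donor_volume, receptor_volume)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all geometry fields must be positive finite numbers", call. = FALSE)
  }
  structure(
    list(exposure_area = exposure_area, donor_volume = donor_volume,
         receptor_volume = receptor_volume),
    class = "cell_geometry"
  )
}

#' Space/time discretization controls
#'
#' @param nodes_per_layer Integer node count per layer (recycled across
#'   layers if scalar); at least 3 per layer. The default resolves the steep
#'   near-surface gradients in the skin while keeping the chamber layers
#'   cheap.
#' @param time_step Implicit-Euler step size in h (> 0). Output times that do
#'   not fall on the step grid are hit exactly by inserting shorter steps.
#' @return An object of class \code{discretization}.
#' @export
discretization <- function(nodes_per_layer = c(50L, 200L, 50L), time_step = 0.01) {
  if (!is.numeric(nodes_per_layer) || any(!is.finite(nodes_per_layer)) ||
      any(nodes_per_layer != round(nodes_per_layer)) || any(nodes_per_layer < 3)) {
    stop("`nodes_per_layer` must be integers >= 3", call. = FALSE)
  }
  if (!is.numeric(time_step) || length(time_step) != 1L ||
      !is.finite(time_step) || time_step <= 0) {
    stop("`time_step` must be a single positive number (h)", call. = FALSE)
  }
  structure(
    list(nodes_per_layer = as.integer(nodes_per_layer), time_step = time_step),
    class = "discretization"
  )
}

resolve_thickness <- function(layer, geometry = NULL) {
  if (!is.null(layer$thickness)) return(layer$thickness)
  if (is.null(geometry)) {
    stop("layer '", layer$name,
         "' is specified by volume; a cell_geometry is required to resolve ",
         "its thickness", call. = FALSE)
  }
  layer$volume / geometry$exposure_area
}

check_layers_interfaces <- function(layers, interfaces) {
  if (!is.list(layers) || length(layers) < 1L ||
      !all(vapply(layers, inherits, logical(1), "layer_spec"))) {
    stop("`layers` must be a list of layer_spec objects", call. = FALSE)
  }
  if (!is.list(interfaces) ||
      !all(vapply(interfaces, inherits, logical(1), "interface_spec"))) {
    stop("`interfaces` must be a list of interface_spec objects", call. = FALSE)
  }
  if (length(interfaces) != length(layers) - 1L) {
    stop("need exactly one interface between each pair of adjacent layers (",
         length(layers) - 1L, " expected, ", length(interfaces), " given)",
         call. = FALSE)
  }
  invisible(TRUE)
}
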