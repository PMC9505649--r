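#' Built-in Franz-cell case configurations
#'
#' Returns the complete parameter set for one of the three worked permeation
#' cases: diclofenac at room temperature, diclofenac at 32 degC, or caffeine
#' at 32 degC. Each case is a three-layer system (donor | skin | receptor)
#' with 5 mg/mL drug loaded in the donor at t = 0, standard cell geometry
#' (1 mL donor, 12 mL receptor, 0.636 cm^2 exposure area), and the estimated
#' skin diffusivity, partition coefficients P1 (donor/skin) and P2
#' (skin/receptor), and mass-transfer coefficients K1, K2 for that case.
#'
#' @param case_id One of \code{"diclofenac_RT"}, \code{"diclofenac_32C"},
#'   \code{"caffeine_32C"}.
#' @param chamber_diffusivity Diffusivity assigned to the donor and receptor
#'   layers, cm^2/h. Chosen large so the chamber contents stay well mixed
#'   (profiles flat to within 0.1\%); see the methods vignette.
#' @param C0 Initial donor concentration, mg/cm^3.
#' @return An object of class \code{franz_case}: a list with \code{layers},
#'   \code{interfaces}, \code{geometry}, \code{end_time} (h) and a
#'   \code{params} record of the scalar parameters.
#' @examples
#' cfg <- make_case_config("diclofenac_RT")
#' cfg$params$P1   # 8
#' cfg$end_time    # 47 h
#' @export
make_case_config <- function(case_id = c("diclofenac_RT", "diclofenac_32C",
                                         "caffeine_32C"),
                             chamber_diffusivity = 1000, C0 = 5) {
  if (!is.character(case_id) || length(case_id) != 1L) {
    stop("`case_id` must be a single case name", call. = FALSE)
  }
  tab <- list(
    diclofenac_RT  = list(skin_thickness = 0.07, D = 1.2e-3, P1 = 8,  P2 = 25,
                          K1 = 0.08, K2 = 0.04, end_time = 47),
    diclofenac_32C = list(skin_thickness = 0.10, D = 1.8e-3, P1 = 5,  P2 = 10,
                          K1 = 0.12, K2 = 0.10, end_time = 51.5),
    caffeine_32C   = list(skin_thickness = 0.10, D = 5.0e-3, P1 = 8,  P2 = 23,
                          K1 = 0.11, K2 = 0.08, end_time = 53)
  )
  if (!case_id %in% names(tab)) {
    stop("unknown case_id '", case_id, "'; expected one of ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  p <- tab[[case_id]]
  geometry <- cell_geometry()
  layers <- list(
    layer_spec("donor", diffusivity = chamber_diffusivity,
               volume = geometry$donor_volume, initial_concentration = C0),
    layer_spec("skin", diffusivity = p$D, thickness = p$skin_thickness,
               initial_concentration = 0),
    layer_spec("receptor", diffusivity = chamber_diffusivity,
               volume = geometry$receptor_volume, initial_concentration = 0)
  )
  interfaces <- list(
    interface_spec(partition = p$P1, mass_transfer = p$K1,
                   orientation = "skin_downstream"),
    interface_spec(partition = p$P2, mass_transfer = p$K2,
                   orientation = "skin_upstream")
  )
  structure(
    list(case_id = case_id, layers = layers, interfaces = interfaces,
         geometry = geometry, end_time = p$end_time,
         params = c(p, list(C0 = C0, chamber_diffusivity = chamber_diffusivity))),
    class = "franz_case"
  )
}

#' Simulate a built-in case
#'
#' Convenience wrapper running \code{\link{simulate_cell}} on a
#' \code{franz_case} configuration.
#'
#' @param case A \code{franz_case} from \code{\link{make_case_config}}.
#' @param output_times Times (h) at which to record the field; defaults to
#'   hourly output plus the case end time.
#' @param disc A \code{\link{discretization}}.
#' @return A \code{franz_sim} simulation result.
#' @export
simulate_case <- function(case, output_times = NULL, disc = discretization()) {
  stopifnot(inherits(case, "franz_case"))
  if (is.null(output_times)) {
    output_times <- sort(unique(c(0, seq(0, case$end_time, by = 1), case$end_time)))
  }
  simulate_cell(case$layers, case$interfaces, geometry = case$geometry,
                disc = disc, output_times = output_times)
}

#' @export
print.franz_case <- function(x, ...) {
  p <- x$params
  cat("<franz_case> ", x$case_id, "\n", sep = "")
  cat(sprintf("  skin: %.3g cm, D = %.3g cm^2/h\n", p$skin_thickness, p$D))
  cat(sprintf("  P1 = %.3g, P2 = %.3g, K1 = %.3g cm/h, K2 = %.3g cm/h\n",
              p$P1, p$P2, p$K1, p$K2))
  cat(sprintf("  C0 = %.3g mg/mL (donor), end time %.3g h\n", p$C0, x$end_time))
  invisible(x)
}
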