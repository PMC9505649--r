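#' Read and write release-curve CSV files
#'
#' The release CSV schema is \code{time_h, concentration_mg_per_ml} with an
#' optional \code{replicate} column; it is the schema produced by
#' \code{\link{generate_experiment}} and consumed by
#' \code{\link{calibrate_case}}.
#'
#' @param release Data frame to write.
#' @param path File path.
#' @return \code{read_release_csv} returns the data frame.
#' @export
write_release_csv <- function(release, path) {
  stopifnot(is.data.frame(release),
            all(c("time_h", "concentration_mg_per_ml") %in% names(release)))
  write.csv(release, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_release_csv
#' @export
read_release_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path)
  if (!all(c("time_h", "concentration_mg_per_ml") %in% names(df))) {
    stop("release CSV must have columns time_h, concentration_mg_per_ml",
         call. = FALSE)
  }
  df
}

#' Read and write tape-strip CSV files
#'
#' Schema: \code{replicate, tube_index, amount_mg}.
#'
#' @param strips A \code{\link{tape_strip_dataset}} (or compatible data
#'   frame) to write.
#' @param path File path.
#' @return \code{read_strip_csv} returns a validated
#'   \code{tape_strip_dataset}.
#' @export
write_strip_csv <- function(strips, path) {
  stopifnot(is.data.frame(strips),
            all(c("tube_index", "amount_mg") %in% names(strips)))
  write.csv(as.data.frame(strips), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_strip_csv
#' @export
read_strip_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path)
  tape_strip_dataset(df, n_tubes = max(df$tube_index))
}

#' Export a simulation result as long-format CSV
#'
#' One row per (time, node): \code{time_h, position_cm, layer,
#' concentration_mg_per_cm3}.
#'
#' @param result A \code{franz_sim}.
#' @param path File path.
#' @export
write_simulation_csv <- function(result, path) {
  stopifnot(inherits(result, "franz_sim"))
  long <- data.frame(
    time_h = rep(result$times, each = length(result$x)),
    position_cm = rep(result$x, length(result$times)),
    layer = rep(result$layer_names[result$layer_id], length(result$times)),
    concentration_mg_per_cm3 = as.vector(t(result$C))
  )
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read and write case configurations as JSON
#'
#' Serializes the full system definition (layers, interfaces, geometry, end
#' time) so runs are auditable and diffable.
#'
#' @param case A \code{franz_case} (or a list with \code{layers},
#'   \code{interfaces}, \code{geometry}, \code{end_time}).
#' @param path File path.
#' @return \code{read_case_config} returns a \code{franz_case}-shaped list
#'   with reconstructed spec objects.
#' @export
write_case_config <- function(case, path) {
  payload <- list(
    case_id = case$case_id,
    end_time = case$end_time,
    geometry = unclass(case$geometry),
    layers = lapply(case$layers, unclass),
    interfaces = lapply(case$interfaces, unclass)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_case_config
#' @export
read_case_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  geometry <- cell_geometry(p$geometry$exposure_area, p$geometry$donor_volume,
                            p$geometry$receptor_volume)
  layers <- lapply(p$layers, function(l) {
    layer_spec(l$name, l$diffusivity, thickness = l$thickness,
               volume = l$volume, initial_concentration = l$initial_concentration)
  })
  interfaces <- lapply(p$interfaces, function(i) {
    interface_spec(i$partition, i$mass_transfer, i$orientation)
  })
  structure(
    list(case_id = p$case_id, layers = layers, interfaces = interfaces,
         geometry = geometry, end_time = p$end_time,
         params = p$params),
    class = "franz_case"
  )
}

#' Write a permeation-fit report as JSON
#'
#' @param fit A \code{permeation_fit}.
#' @param path File path.
#' @return \code{read_fit_report} returns the report as a list.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "permeation_fit"))
  payload <- list(
    parameters = list(D_cm2_per_h = fit$D, P1 = fit$P1, P2 = fit$P2,
                      K1_cm_per_h = fit$K1, K2_cm_per_h = fit$K2),
    objective_ssr = fit$objective,
    converged = fit$converged,
    rounds = fit$rounds,
    lag_time_h = if (!is.null(fit$lag)) fit$lag$lag_time else NULL,
    n_starts = fit$n_starts
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_report
#' @export
read_fit_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
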