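#' Franz-cell experiment protocol
#'
#' Describes the sampling schedule and replication of an in-vitro release
#' experiment: samples drawn from the receptor chamber at fixed times (the
#' withdrawn volume replaced with fresh medium), several independent skin
#' replicates, and the tape-strip series performed at the end. The defaults
#' follow the standard protocol of the worked cases: sampling at 1, 2, 3,
#' 4.5, 6, 8, 10, 12, 23, 26, 29, 32, 35 and 48 h, 200 uL per sample, four
#' replicates, 70 strips of nominally 0.75 um pooled two per microtube.
#'
#' @param sampling_times Sampling times, h (strictly increasing, > 0).
#' @param sample_volume Withdrawn volume per sample, cm^3.
#' @param replicates Number of replicate cells.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   measurement noise (0 <= cv < 1).
#' @param seed Integer seed for synthetic-data generation.
#' @param strip_thickness_um Nominal per-strip thickness, um (0.5-1).
#' @param n_strips Number of tape strips.
#' @param strips_per_tube Strips pooled per microtube.
#' @param model_sampling Logical; if \code{TRUE}, the generator applies the
#'   200 uL removal/replacement to the simulated receptor at each sampling
#'   time (about a 1.7\% dilution per sample). Off by default: the forward
#'   model of the worked cases does not include it.
#' @return An object of class \code{experiment_protocol}.
#' @export
experiment_protocol <- function(sampling_times = c(1, 2, 3, 4.5, 6, 8, 10, 12,
                                                   23, 26, 29, 32, 35, 48),
                                sample_volume = 0.2, replicates = 4L,
                                noise_cv = 0.05, seed = 1L,
                                strip_thickness_um = 0.75, n_strips = 70L,
                                strips_per_tube = 2L, model_sampling = FALSE) {
  if (length(sampling_times) < 1L || any(!is.finite(sampling_times)) ||
      any(sampling_times <= 0) || any(diff(sampling_times) <= 0)) {
    stop("`sampling_times` must be strictly increasing and positive",
         call. = FALSE)
  }
  if (!is.numeric(noise_cv) || noise_cv < 0 || noise_cv >= 1) {
    stop("`noise_cv` must lie in [0, 1)", call. = FALSE)
  }
  if (sample_volume < 0) stop("`sample_volume` must be >= 0", call. = FALSE)
  if (replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)
  if (strip_thickness_um <= 0) stop("`strip_thickness_um` must be > 0", call. = FALSE)
  structure(
    list(sampling_times = sampling_times, sample_volume = sample_volume,
         replicates = as.integer(replicates), noise_cv = noise_cv,
         seed = as.integer(seed), strip_thickness_um = strip_thickness_um,
         n_strips = as.integer(n_strips),
         strips_per_tube = as.integer(strips_per_tube),
         model_sampling = isTRUE(model_sampling)),
    class = "experiment_protocol"
  )
}

#' Per-strip amounts from a simulated skin profile
#'
#' Slices the skin concentration profile at time \code{t} into consecutive
#' slabs of one strip thickness each and integrates the drug amount in each
#' slab (difference of cumulative depth-window amounts, so the per-strip
#' amounts sum exactly to the depth-window amount at the total stripped
#' depth).
#'
#' @param result A \code{franz_sim}.
#' @param t Time of stripping, h (must be a recorded output time).
#' @param strip_thickness Per-strip thickness, cm.
#' @param area Membrane area, cm^2.
#' @param n_strips Number of strips.
#' @return Vector of per-strip amounts, mg.
#' @export
strip_amounts_from_profile <- function(result, t, strip_thickness,
                                       area = result$geometry$exposure_area,
                                       n_strips = 70L) {
  stopifnot(inherits(result, "franz_sim"))
  i <- layer_index(result, "skin")
  if (n_strips * strip_thickness > result$grid$thickness[i] + 1e-12) {
    stop("total stripped depth exceeds the skin thickness", call. = FALSE)
  }
  cum <- vapply(seq_len(n_strips), function(j) {
    depth_window_amount(result, t, j * strip_thickness, area = area)
  }, numeric(1))
  diff(c(0, cum))
}

#' Generate a synthetic Franz-cell experiment
#'
#' Forward-simulates a case with known ground-truth parameters and emulates
#' the laboratory outputs: replicate receptor concentration measurements at
#' the protocol sampling times (multiplicative Gaussian noise with the
#' protocol's CV, truncated at zero), a tape-strip dataset built by slicing
#' the end-time skin profile into per-strip slabs and pooling them per
#' microtube, and an idealized sink-condition lag-time experiment
#' (\code{\link{membrane_sink_q}}) of the kind used to measure the skin
#' diffusivity. Generation is seeded and bit-reproducible.
#'
#' @param case A \code{franz_case} (ground truth).
#' @param protocol An \code{\link{experiment_protocol}}.
#' @param disc A \code{\link{discretization}}.
#' @param strip_time Time of the tape-strip series, h (default: last
#'   sampling time).
#' @return List with \code{release} (data frame: replicate, time_h,
#'   concentration_mg_per_ml), \code{strips} (a
#'   \code{\link{tape_strip_dataset}}), \code{lag} (data frame: time_h,
#'   q_mg_per_cm2 of the idealized lag experiment, noisy), and \code{truth}
#'   (the generating parameters).
#' @export
generate_experiment <- function(case, protocol = experiment_protocol(),
                                disc = discretization(), strip_time = NULL) {
  stopifnot(inherits(case, "franz_case"),
            inherits(protocol, "experiment_protocol"))
  if (is.null(strip_time)) strip_time <- max(protocol$sampling_times)
  if (protocol$sample_volume >= case$geometry$receptor_volume) {
    stop("sample volume must be smaller than the receptor volume", call. = FALSE)
  }

  # seeded, without disturbing the caller's RNG stream
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(protocol$seed)

  tt <- protocol$sampling_times
  if (protocol$model_sampling) {
    run <- simulate_with_sampling(case$layers, case$interfaces, case$geometry,
                                  disc, tt, protocol$sample_volume, strip_time)
    rc_clean <- run$observed
    sim_end <- run$final
  } else {
    sim <- simulate_cell(case$layers, case$interfaces, case$geometry, disc,
                         output_times = sort(unique(c(tt, strip_time))))
    rc <- release_curve(sim)
    rc_clean <- rc$concentration_mg_per_cm3[match_times(rc$time_h, tt)]
    sim_end <- sim
  }

  noisy <- function(x, n) {
    vapply(seq_len(n), function(r) {
      pmax(0, x * (1 + protocol$noise_cv * rnorm(length(x))))
    }, numeric(length(x)))
  }

  rel_mat <- noisy(rc_clean, protocol$replicates)
  release <- data.frame(
    replicate = rep(seq_len(protocol$replicates), each = length(tt)),
    time_h = rep(tt, protocol$replicates),
    concentration_mg_per_ml = as.vector(rel_mat)
  )

  delta_cm <- protocol$strip_thickness_um * 1e-4
  strips <- strip_amounts_from_profile(sim_end, strip_time, delta_cm,
                                       n_strips = protocol$n_strips)
  n_tubes <- protocol$n_strips %/% protocol$strips_per_tube
  tube_clean <- as.numeric(tapply(strips,
                                  rep(seq_len(n_tubes),
                                      each = protocol$strips_per_tube), sum))
  tube_mat <- noisy(tube_clean, protocol$replicates)
  strips_df <- tape_strip_dataset(data.frame(
    replicate = rep(seq_len(protocol$replicates), each = n_tubes),
    tube_index = rep(seq_len(n_tubes), protocol$replicates),
    amount_mg = as.vector(tube_mat)
  ), n_tubes = n_tubes)

  p <- case$params
  lag_clean <- membrane_sink_q(tt, p$skin_thickness, p$D,
                               surface_concentration = p$P1 * p$C0)
  lag_mat <- noisy(lag_clean, protocol$replicates)
  lag_df <- data.frame(time_h = tt, q_mg_per_cm2 = rowMeans(lag_mat))

  list(release = release, strips = strips_df, lag = lag_df,
       truth = list(case_id = case$case_id, D = p$D, P1 = p$P1, P2 = p$P2,
                    K1 = p$K1, K2 = p$K2, C0 = p$C0,
                    skin_thickness = p$skin_thickness,
                    strip_time = strip_time, seed = protocol$seed,
                    noise_cv = protocol$noise_cv,
                    model_sampling = protocol$model_sampling))
}

# Piecewise simulation with receptor removal/replacement events: at each
# sampling time the receptor field is recorded (pre-removal) and then scaled
# by (V - v)/V, emulating withdrawal of v cm^3 replaced by fresh medium.
simulate_with_sampling <- function(layers, interfaces, geometry, disc,
                                   sampling_times, sample_volume,
                                   end_time = max(sampling_times)) {
  stopifnot(!is.null(geometry))
  events <- sampling_times[sampling_times <= end_time + 1e-12]
  dilute <- (geometry$receptor_volume - sample_volume) / geometry$receptor_volume
  grid <- build_grid(layers, geometry, disc)
  ridx <- which(grid$layer_names == "receptor")
  rnodes <- grid$first[ridx]:grid$last[ridx]

  state <- NULL; t0 <- 0
  observed <- numeric(length(events))
  sim <- NULL
  for (k in seq_along(events)) {
    sim <- simulate_cell(layers, interfaces, geometry, disc,
                         output_times = events[k] - t0, init = state)
    observed[k] <- release_curve(sim)$concentration_mg_per_cm3[1]
    state <- sim$C[1, ]
    state[rnodes] <- state[rnodes] * dilute
    t0 <- events[k]
  }
  if (end_time > t0 + 1e-12) {
    sim <- simulate_cell(layers, interfaces, geometry, disc,
                         output_times = end_time - t0, init = state)
  } else {
    # expose the post-removal state at end_time for downstream profiling
    sim$C[1, ] <- state
  }
  sim$times <- end_time
  list(observed = observed, final = sim)
}
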