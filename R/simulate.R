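# Assemble the tridiagonal FEM system for the multilayer diffusion problem:
# consistent mass matrix M and A = stiffness + interface coupling, so that
# M dC/dt = -A C. Row sums of A over columns vanish, which makes the scheme
# conservative (total mass ∫C dx is constant in the semi-discrete system and
# under implicit Euler up to solver round-off).
assemble_system <- function(grid, layers, interfaces) {
  n <- length(grid$x)
  Md <- numeric(n); Ml <- numeric(n); Mu <- numeric(n)
  Ad <- numeric(n); Al <- numeric(n); Au <- numeric(n)

  for (i in seq_along(layers)) {
    idx <- grid$first[i]:grid$last[i]
    h <- grid$h[i]
    D <- layers[[i]]$diffusivity
    # element (j, j+1): mass h/6 [[2,1],[1,2]], stiffness D/h [[1,-1],[-1,1]]
    for (j in idx[-length(idx)]) {
      Md[j]     <- Md[j]     + h / 3
      Md[j + 1] <- Md[j + 1] + h / 3
      Mu[j]     <- Mu[j]     + h / 6
      Ml[j + 1] <- Ml[j + 1] + h / 6
      Ad[j]     <- Ad[j]     + D / h
      Ad[j + 1] <- Ad[j + 1] + D / h
      Au[j]     <- Au[j]     - D / h
      Al[j + 1] <- Al[j + 1] - D / h
    }
  }
  # interface flux J = K (a C_left - b C_right), entering the weak form as a
  # boundary term: -J on the left-layer end node row, +J on the right twin.
  for (k in seq_along(interfaces)) {
    ifc <- interfaces[[k]]
    ab <- interface_coefs(ifc)
    K <- ifc$mass_transfer
    a <- grid$interfaces$left_node[k]
    b <- grid$interfaces$right_node[k]
    Ad[a] <- Ad[a] + K * ab[["a"]]
    Au[a] <- Au[a] - K * ab[["b"]]
    Al[b] <- Al[b] - K * ab[["a"]]
    Ad[b] <- Ad[b] + K * ab[["b"]]
  }
  list(Md = Md, Ml = Ml, Mu = Mu, Ad = Ad, Al = Al, Au = Au)
}

# Step plan hitting every positive output time exactly: the union of the
# uniform dt grid and the requested times, collapsed when closer than 1e-10 h.
plan_steps <- function(output_times, dt) {
  end <- max(output_times)
  pos <- output_times[output_times > 0]
  grid_t <- seq(dt, end + dt * 1e-9, by = dt)
  grid_t <- grid_t[grid_t <= end + 1e-12]
  all_t <- sort(c(grid_t, pos))
  keep <- c(TRUE, diff(all_t) > 1e-10)
  all_t <- all_t[keep]
  is_out <- vapply(all_t, function(t) any(abs(pos - t) <= 1e-10), logical(1))
  list(steps = diff(c(0, all_t)), record = as.integer(is_out), times = all_t)
}

#' Simulate the multilayer Franz-cell diffusion system
#'
#' Solves the layered one-dimensional diffusion equation
#' dC_i/dt = d/dx (D_i dC_i/dx) with linear finite elements in space
#' (consistent mass matrix) and implicit Euler in time. Interlayer boundaries
#' enter as flux conditions J = K (a C_left - b C_right) with coefficients set
#' by each interface's partition coefficient and orientation (see
#' \code{\link{interface_spec}}); the outer boundaries are zero-flux (closed
#' cell). The scheme conserves total mass to solver round-off and preserves
#' nonnegativity for the default discretization.
#'
#' @param layers List of \code{\link{layer_spec}} objects (donor side first).
#' @param interfaces List of \code{\link{interface_spec}} objects, one per
#'   adjacent layer pair.
#' @param geometry Optional \code{\link{cell_geometry}} (required when
#'   chamber layers are specified by volume; also carried into the result for
#'   amount calculations).
#' @param disc A \code{\link{discretization}}.
#' @param output_times Times (h, >= 0) at which to record the field.
#' @param init Optional full nodal initial state (overrides the layers'
#'   uniform initial concentrations), e.g. to restart after a sampling event.
#' @return An object of class \code{franz_sim} with node positions \code{x},
#'   \code{layer_id}, \code{times}, and the concentration matrix \code{C}
#'   (rows = times, columns = nodes, mg/cm^3).
#' @examples
#' cfg <- make_case_config("diclofenac_RT")
#' sim <- simulate_cell(cfg$layers, cfg$interfaces, cfg$geometry,
#'                      disc = discretization(c(10, 40, 10), 0.1),
#'                      output_times = c(0, 1, 5))
#' @export
simulate_cell <- function(layers, interfaces, geometry = NULL,
                          disc = discretization(), output_times, init = NULL) {
  check_layers_interfaces(layers, interfaces)
  stopifnot(inherits(disc, "discretization"))
  if (missing(output_times) || length(output_times) == 0L ||
      !is.numeric(output_times) || any(!is.finite(output_times)) ||
      any(output_times < 0)) {
    stop("`output_times` must be a non-empty vector of finite times >= 0",
         call. = FALSE)
  }
  output_times <- sort(unique(output_times))

  grid <- build_grid(layers, geometry, disc)
  sys <- assemble_system(grid, layers, interfaces)

  C0 <- if (is.null(init)) {
    vapply(grid$layer_id, function(i) layers[[i]]$initial_concentration,
           numeric(1))
  } else {
    if (length(init) != length(grid$x) || any(!is.finite(init)) || any(init < 0)) {
      stop("`init` must be a non-negative state of length ", length(grid$x),
           call. = FALSE)
    }
    as.numeric(init)
  }

  n_nodes <- length(grid$x)
  Cmat <- matrix(NA_real_, nrow = length(output_times), ncol = n_nodes)
  if (output_times[1] == 0) Cmat[1, ] <- C0

  if (any(output_times > 0)) {
    plan <- plan_steps(output_times, disc$time_step)
    out <- step_implicit_euler(sys$Md, sys$Ml, sys$Mu, sys$Ad, sys$Al, sys$Au,
                               C0, plan$steps, plan$record)
    Cmat[output_times > 0, ] <- t(out)
  }

  structure(
    list(x = grid$x, layer_id = grid$layer_id, layer_names = grid$layer_names,
         times = output_times, C = Cmat, grid = grid, layers = layers,
         interfaces = interfaces, geometry = geometry, disc = disc),
    class = "franz_sim"
  )
}

#' @export
print.franz_sim <- function(x, ...) {
  cat("<franz_sim> ", length(x$layer_names), " layers (",
      paste(x$layer_names, collapse = " | "), "), ",
      length(x$x), " nodes, ", length(x$times), " output times in [",
      min(x$times), ", ", max(x$times), "] h\n", sep = "")
  invisible(x)
}

# Index of time t in a simulation result (exact up to 1e-8 h).
sim_time_index <- function(result, t) {
  i <- which(abs(result$times - t) <= 1e-8)
  if (length(i) != 1L) {
    stop("time ", t, " h is not among the recorded output times", call. = FALSE)
  }
  i
}

#' Interfacial flux at a recorded time
#'
#' Evaluates the interface flux law J = K (a C_left - b C_right) at the
#' duplicated boundary nodes. Positive values mean transport in the +x
#' direction (towards the receptor).
#'
#' @param result A \code{franz_sim}.
#' @param interface_index Which interface (1 = donor/skin, 2 = skin/receptor
#'   in the standard three-layer setup).
#' @param t A recorded output time (h).
#' @return Flux in mg/(cm^2 h).
#' @export
interface_flux <- function(result, interface_index, t) {
  stopifnot(inherits(result, "franz_sim"))
  if (!is.numeric(interface_index) || length(interface_index) != 1L ||
      interface_index < 1 || interface_index > length(result$interfaces)) {
    stop("`interface_index` out of range", call. = FALSE)
  }
  ti <- sim_time_index(result, t)
  ifc <- result$interfaces[[interface_index]]
  ab <- interface_coefs(ifc)
  a <- result$grid$interfaces$left_node[interface_index]
  b <- result$grid$interfaces$right_node[interface_index]
  unname(ifc$mass_transfer *
           (ab[["a"]] * result$C[ti, a] - ab[["b"]] * result$C[ti, b]))
}

#' Closed-form equilibrium state of the closed cell
#'
#' At equilibrium all interfacial fluxes vanish, so each layer is uniform and
#' the concentration ratios across the boundaries equal the partition
#' coefficients (skin = P x fluid with the conventions of
#' \code{\link{interface_spec}}). Total mass fixes the absolute level.
#'
#' @inheritParams simulate_cell
#' @return Data frame with per-layer equilibrium \code{concentration}
#'   (mg/cm^3) and \code{mass} (mg).
#' @export
equilibrium_state <- function(layers, interfaces, geometry = NULL) {
  check_layers_interfaces(layers, interfaces)
  thick <- vapply(layers, resolve_thickness, numeric(1), geometry = geometry)
  area <- if (is.null(geometry)) 1 else geometry$exposure_area
  vol <- thick * area
  f <- numeric(length(layers)); f[1] <- 1
  for (k in seq_along(interfaces)) {
    ab <- interface_coefs(interfaces[[k]])
    f[k + 1] <- f[k] * ab[["a"]] / ab[["b"]]
  }
  M <- sum(vol * vapply(layers, `[[`, numeric(1), "initial_concentration"))
  c1 <- M / sum(f * vol)
  conc <- f * c1
  data.frame(layer = vapply(layers, `[[`, character(1), "name"),
             concentration = conc, mass = conc * vol)
}

#' Well-mixed three-compartment reference solution
#'
#' Exact solution of the three-compartment (donor, skin, receptor) exchange
#' system obtained in the limit of large diffusivities, where each layer is
#' uniform and only the interfacial flux laws act:
#' V dC/dt = A x (net interfacial flux). Solved by eigen-decomposition of the
#' 3 x 3 rate matrix. Serves as an independent check of the PDE solver in the
#' well-mixed limit.
#'
#' @param interfaces List of two \code{\link{interface_spec}} objects.
#' @param geometry A \code{\link{cell_geometry}}.
#' @param skin_volume Skin compartment volume, cm^3 (thickness x area).
#' @param C0 Initial concentrations, length 3 (donor, skin, receptor).
#' @param times Output times (h).
#' @return Matrix (length(times) x 3) of compartment concentrations.
#' @export
compartment_oracle <- function(interfaces, geometry, skin_volume, C0, times) {
  stopifnot(inherits(geometry, "cell_geometry"), length(C0) == 3,
            length(interfaces) == 2)
  V <- c(geometry$donor_volume, skin_volume, geometry$receptor_volume)
  if (any(V <= 0)) stop("compartment volumes must be positive", call. = FALSE)
  A <- geometry$exposure_area
  G <- matrix(0, 3, 3)
  for (k in 1:2) {
    ab <- interface_coefs(interfaces[[k]])
    K <- interfaces[[k]]$mass_transfer
    i <- k; j <- k + 1
    # J = K (a C_i - b C_j); compartment i loses A*J, j gains A*J
    G[i, i] <- G[i, i] - A * K * ab[["a"]] / V[i]
    G[i, j] <- G[i, j] + A * K * ab[["b"]] / V[i]
    G[j, i] <- G[j, i] + A * K * ab[["a"]] / V[j]
    G[j, j] <- G[j, j] - A * K * ab[["b"]] / V[j]
  }
  eg <- eigen(G)
  Vi <- solve(eg$vectors)
  y0 <- Vi %*% C0
  out <- t(vapply(times, function(t) {
    Re(eg$vectors %*% (exp(eg$values * t) * y0))[, 1]
  }, numeric(3)))
  dimnames(out) <- list(NULL, c("donor", "skin", "receptor"))
  out
}

#' Mass-balance audit of a closed-system run
#'
#' Total mass at each recorded time is the per-layer trapezoidal integral of
#' the concentration field times the exposure area.
#'
#' @param result A \code{franz_sim}.
#' @param geometry A \code{\link{cell_geometry}} (defaults to the one stored
#'   in the result).
#' @return Maximum relative deviation of total mass from its initial value.
#' @export
mass_balance <- function(result, geometry = NULL) {
  stopifnot(inherits(result, "franz_sim"))
  m <- total_mass_series(result, geometry)
  max(abs(m - m[1]) / m[1])
}

total_mass_series <- function(result, geometry = NULL) {
  if (is.null(geometry)) geometry <- result$geometry
  area <- if (is.null(geometry)) 1 else geometry$exposure_area
  grid <- result$grid
  sapply(seq_along(result$times), function(ti) {
    conc <- result$C[ti, ]
    total <- 0
    for (i in seq_along(grid$layer_names)) {
      idx <- grid$first[i]:grid$last[i]
      total <- total + trapz(grid$x[idx], conc[idx])
    }
    total * area
  })
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
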