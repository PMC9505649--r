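# Shared builders for small test systems.

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

# Coarse discretization for tests that only need qualitative fields fast.
coarse_disc <- function(nodes = c(12L, 40L, 12L), dt = 0.05) {
  discretization(nodes_per_layer = nodes, time_step = dt)
}

# Moderate discretization used for the recovery studies: fine enough that
# the worked-case observables are within a fraction of a percent of the
# default grid, cheap enough for repeated fitting.
study_disc <- function() discretization(c(30L, 100L, 30L), 0.025)

# A single-layer slab with uniform D and a cosine initial profile, whose
# exact solution is C(x, t) = mean + amp * exp(-D (pi/L)^2 t) cos(pi x / L)
# under zero-flux ends. Used for convergence-order checks.
cosine_slab <- function(L = 1, D = 0.5, mean_c = 2, amp = 1) {
  list(
    layers = list(layer_spec("slab", D, thickness = L,
                             initial_concentration = mean_c)),
    exact = function(x, t) mean_c + amp * exp(-D * (pi / L)^2 * t) * cos(pi * x / L),
    L = L, D = D, mean_c = mean_c, amp = amp
  )
}

# Initial nodal state for the cosine slab on a given grid.
cosine_init <- function(slab, grid) {
  slab$mean_c + slab$amp * cos(pi * grid$x / slab$L)
}

# Dense matrix-exponential solution of the assembled semi-discrete system
# M dC/dt = -A C (independent reference for the time stepper).
expm_reference <- function(layers, interfaces, geometry, disc, C0, t) {
  grid <- franzcell::build_grid(layers, geometry, disc)
  sys <- franzcell:::assemble_system(grid, layers, interfaces)
  n <- length(grid$x)
  tri <- function(d, l, u) {
    m <- diag(d)
    for (i in 2:n) m[i, i - 1] <- l[i]
    for (i in 1:(n - 1)) m[i, i + 1] <- u[i]
    m
  }
  M <- tri(sys$Md, sys$Ml, sys$Mu)
  A <- tri(sys$Ad, sys$Al, sys$Au)
  G <- -solve(M, A)
  as.numeric(Matrix::expm(Matrix::Matrix(G * t)) %*% C0)
}

default_case_sim <- local({
  cache <- new.env(parent = emptyenv())
  function(case_id, times = NULL) {
    key <- paste0(case_id, ":", paste(times, collapse = ","))
    if (is.null(cache[[key]])) {
      cfg <- make_case_config(case_id)
      cache[[key]] <- list(cfg = cfg, sim = simulate_case(cfg, output_times = times))
    }
    cache[[key]]
  }
})
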