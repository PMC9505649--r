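test_that("spec constructors validate their invariants", {
  expect_error(layer_spec("skin", diffusivity = -1, thickness = 0.1), "positive")
  expect_error(layer_spec("skin", diffusivity = 1), "exactly one")
  expect_error(layer_spec("skin", 1, thickness = 0.1, volume = 1), "exactly one")
  expect_error(layer_spec("skin", 1, thickness = 0.1, initial_concentration = -2),
               "non-negative")
  expect_error(interface_spec(partition = 0, mass_transfer = 1), "positive")
  expect_error(interface_spec(partition = 2, mass_transfer = -1), "non-negative")
  expect_error(interface_spec(2, 1, orientation = "sideways"), "arg")
  expect_error(cell_geometry(exposure_area = 0), "positive")
  expect_error(discretization(nodes_per_layer = 2), ">= 3")
  expect_error(discretization(time_step = 0), "positive")
  expect_error(make_case_config("unknown_case"), "unknown case_id")
})

test_that("grid layout duplicates nodes exactly at interfaces", {
  layers3 <- list(layer_spec("a", 1, thickness = 1),
                  layer_spec("b", 1, thickness = 1),
                  layer_spec("c", 1, thickness = 1))
  ifcs <- list(interface_spec(2, 1), interface_spec(2, 1, "skin_upstream"))
  g <- build_grid(layers3, disc = discretization(nodes_per_layer = 5))
  expect_length(g$x, 15)
  expect_equal(sum(duplicated(g$x)), 2)
  expect_true(all(diff(g$x) >= 0))
  expect_equal(g$x[g$interfaces$left_node], g$x[g$interfaces$right_node])

  g1 <- build_grid(list(layer_spec("only", 1, thickness = 1)),
                   disc = discretization(nodes_per_layer = 7))
  expect_equal(sum(duplicated(g1$x)), 0)

  # chamber thickness from volume / area
  geo <- cell_geometry(exposure_area = 0.6362, donor_volume = 1)
  gd <- build_grid(list(layer_spec("donor", 1, volume = 1),
                        layer_spec("skin", 1, thickness = 0.07)),
                   geometry = geo, disc = discretization(nodes_per_layer = 5))
  expect_equal(gd$thickness[1], 1 / 0.6362, tolerance = 1e-12)
  expect_equal(round(gd$thickness[1], 3), 1.572)
})

test_that("an equilibrium initial condition is a fixed point of the solver", {
  layers <- list(layer_spec("a", 0.3, thickness = 0.5, initial_concentration = 2),
                 layer_spec("b", 0.3, thickness = 0.8, initial_concentration = 2),
                 layer_spec("c", 0.3, thickness = 0.2, initial_concentration = 2))
  ifcs <- list(interface_spec(1, 1e4), interface_spec(1, 1e4, "skin_upstream"))
  sim <- simulate_cell(layers, ifcs, disc = coarse_disc(c(8, 8, 8), 0.05),
                       output_times = c(0, 1, 10))
  expect_equal(max(abs(sim$C - 2)), 0, tolerance = 1e-10)
})

test_that("implicit Euler matches the matrix-exponential oracle after dt refinement", {
  skip_if_not_installed("Matrix")
  cfg <- make_case_config("diclofenac_RT")
  disc1 <- discretization(nodes_per_layer = 4, time_step = 0.02)
  disc2 <- discretization(nodes_per_layer = 4, time_step = 0.01)
  t_end <- 5
  s1 <- simulate_cell(cfg$layers, cfg$interfaces, cfg$geometry, disc1, t_end)
  s2 <- simulate_cell(cfg$layers, cfg$interfaces, cfg$geometry, disc2, t_end)
  richardson <- 2 * s2$C[1, ] - s1$C[1, ]
  C0 <- vapply(s1$layer_id, function(i) cfg$layers[[i]]$initial_concentration,
               numeric(1))
  ref <- expm_reference(cfg$layers, cfg$interfaces, cfg$geometry, disc1, C0, t_end)
  expect_lt(max(abs(richardson - ref)) / max(abs(ref)), 0.005)
})

test_that("closed-system runs conserve mass and stay nonnegative", {
  for (id in c("diclofenac_RT", "diclofenac_32C", "caffeine_32C")) {
    cs <- default_case_sim(id)
    expect_lt(mass_balance(cs$sim), 1e-4)
    expect_true(all(cs$sim$C >= 0))
    m <- layer_amounts(cs$sim, cs$cfg$end_time)
    expect_equal(sum(m), cs$cfg$params$C0 * cs$cfg$geometry$donor_volume,
                 tolerance = 1e-4)
  }
})

test_that("observed convergence orders are ~1 in dt and ~2 in h", {
  slab <- cosine_slab()
  t_end <- 0.2

  # dt order against the exact solution of the same semi-discrete system
  disc_h <- discretization(nodes_per_layer = 21, time_step = 0.05)
  g <- build_grid(slab$layers, disc = disc_h)
  C0 <- cosine_init(slab, g)
  err_dt <- vapply(c(0.05, 0.025, 0.0125), function(dt) {
    s <- simulate_cell(slab$layers, list(),
                       disc = discretization(21, dt), output_times = t_end,
                       init = C0)
    ref <- expm_reference(slab$layers, list(), NULL, disc_h, C0, t_end)
    max(abs(s$C[1, ] - ref))
  }, numeric(1))
  orders_dt <- log2(err_dt[-length(err_dt)] / err_dt[-1])
  expect_true(all(orders_dt > 0.8 & orders_dt < 1.3))

  # h order against the analytic solution, with dt error subdominant
  err_h <- vapply(c(6, 11, 21), function(nn) {
    gh <- build_grid(slab$layers, disc = discretization(nn, 1))
    s <- simulate_cell(slab$layers, list(),
                       disc = discretization(nn, 1e-4), output_times = t_end,
                       init = cosine_init(slab, gh))
    max(abs(s$C[1, ] - slab$exact(gh$x, t_end)))
  }, numeric(1))
  orders_h <- log2(err_h[-length(err_h)] / err_h[-1])
  expect_true(all(orders_h > 1.6 & orders_h < 2.6))
})

test_that("interfacial flux law holds at the duplicated nodes", {
  cs <- default_case_sim("diclofenac_RT", times = c(0, 0.25, 10, 47))
  sim <- cs$sim; p <- cs$cfg$params

  # early transport is donor -> skin while P1 * C_DC > C_skin-top
  donor_end <- sim$C[2, sim$grid$last[1]]
  skin_top <- sim$C[2, sim$grid$first[2]]
  j1 <- interface_flux(sim, 1, 0.25)
  expect_gt(j1, 0)
  expect_equal(j1, p$K1 * (donor_end - skin_top / p$P1), tolerance = 1e-12)
  expect_gt(p$P1 * donor_end, skin_top)

  # flux equals -D dC/dx on the skin side to discretization accuracy
  i2 <- sim$grid$first[2]
  h2 <- sim$grid$h[2]
  dcdx <- (sim$C[3, i2 + 1] - sim$C[3, i2]) / h2
  expect_equal(interface_flux(sim, 1, 10), -p$D * dcdx, tolerance = 0.02)

  # impermeable interface carries no flux and nothing leaves the donor
  cfg0 <- make_case_config("diclofenac_RT")
  ifc0 <- list(interface_spec(p$P1, 0), interface_spec(p$P2, 0, "skin_upstream"))
  s0 <- simulate_cell(cfg0$layers, ifc0, cfg0$geometry, coarse_disc(),
                      output_times = c(0, 5, 20))
  expect_equal(interface_flux(s0, 1, 20), 0)
  expect_equal(layer_amounts(s0, 20)[["donor"]], 5, tolerance = 1e-10)

  expect_error(interface_flux(sim, 3, 10), "out of range")
  expect_error(interface_flux(sim, 1, 3.21), "output times")
})

test_that("equilibrium state follows the partition coefficients", {
  cfg <- make_case_config("caffeine_32C")
  eq <- equilibrium_state(cfg$layers, cfg$interfaces, cfg$geometry)
  expect_equal(sum(eq$mass), 5, tolerance = 1e-12)
  expect_equal(eq$concentration[2] / eq$concentration[1], cfg$params$P1)
  expect_equal(eq$concentration[2] / eq$concentration[3], cfg$params$P2)

  # no partition: common concentration M / V_total
  ifc1 <- list(interface_spec(1, 0.1), interface_spec(1, 0.1, "skin_upstream"))
  eq1 <- equilibrium_state(cfg$layers, ifc1, cfg$geometry)
  vtot <- 1 + 12 + 0.1 * 0.636
  expect_equal(eq1$concentration, rep(5 / vtot, 3), tolerance = 1e-12)

  # long-horizon simulation approaches the closed form within 1%
  sim <- simulate_cell(cfg$layers, cfg$interfaces, cfg$geometry,
                       coarse_disc(dt = 0.1), output_times = c(0, 3000))
  for (i in 1:3) {
    expect_equal(layer_mean_concentration(sim, i)$concentration_mg_per_cm3[2],
                 eq$concentration[i], tolerance = 0.01)
  }
  ratio <- sim$C[2, sim$grid$first[2]] / sim$C[2, sim$grid$last[1]]
  expect_equal(ratio, cfg$params$P1, tolerance = 0.01)
})

test_that("well-mixed compartment oracle agrees with the PDE in the large-D limit", {
  cfg <- make_case_config("diclofenac_RT", chamber_diffusivity = 2000)
  layers <- cfg$layers
  layers[[2]] <- layer_spec("skin", 10, thickness = 0.07)  # well-mixed skin too
  times <- c(5, 20, 47)
  sim <- simulate_cell(layers, cfg$interfaces, cfg$geometry,
                       discretization(c(25, 25, 25), 0.005), output_times = times)
  skin_vol <- 0.07 * cfg$geometry$exposure_area
  orc <- compartment_oracle(cfg$interfaces, cfg$geometry, skin_vol,
                            C0 = c(5, 0, 0), times = times)
  for (k in seq_along(times)) {
    pde <- vapply(1:3, function(i) {
      layer_mean_concentration(sim, i)$concentration_mg_per_cm3[k]
    }, numeric(1))
    expect_equal(unname(pde), unname(orc[k, ]), tolerance = 0.01)
  }

  # zero mass transfer: compartments frozen at the initial state
  ifc0 <- list(interface_spec(8, 0), interface_spec(25, 0, "skin_upstream"))
  orc0 <- compartment_oracle(ifc0, cfg$geometry, skin_vol, c(5, 0, 0), c(1, 100))
  expect_equal(orc0, matrix(c(5, 5, 0, 0, 0, 0), 2, 3,
                            dimnames = list(NULL, c("donor", "skin", "receptor"))))

  # shared fixed point with the closed-form equilibrium
  orc_inf <- compartment_oracle(cfg$interfaces, cfg$geometry, skin_vol,
                                c(5, 0, 0), 1e6)
  eq <- equilibrium_state(cfg$layers, cfg$interfaces, cfg$geometry)
  expect_equal(unname(orc_inf[1, ]), eq$concentration, tolerance = 1e-6)

  expect_error(compartment_oracle(cfg$interfaces, cell_geometry(), 0,
                                  c(5, 0, 0), 1), "positive")
})

test_that("a larger K1 weakly raises the early skin-top concentration", {
  cfg <- make_case_config("diclofenac_RT")
  tops <- vapply(c(0.02, 0.08, 0.32), function(k1) {
    ifc <- cfg$interfaces
    ifc[[1]] <- interface_spec(8, k1)
    s <- simulate_cell(cfg$layers, ifc, cfg$geometry, coarse_disc(),
                       output_times = 2)
    skin_surface_concentration(s, 2, "top")
  }, numeric(1))
  expect_true(all(diff(tops) > 0))
})

test_that("simulation inputs are validated", {
  cfg <- make_case_config("diclofenac_RT")
  expect_error(simulate_cell(cfg$layers, cfg$interfaces, cfg$geometry,
                             output_times = numeric(0)), "output_times")
  expect_error(simulate_cell(cfg$layers, cfg$interfaces, cfg$geometry,
                             output_times = c(-1, 2)), "output_times")
  expect_error(simulate_cell(cfg$layers, cfg$interfaces[1], cfg$geometry,
                             output_times = 1), "one interface")
  expect_error(simulate_cell(cfg$layers, cfg$interfaces, NULL,
                             output_times = 1), "cell_geometry is required")
})
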