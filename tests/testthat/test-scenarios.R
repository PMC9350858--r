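# Packaged validation scenarios and their closed-form quantities.

test_that("penetration depth reproduces the published dermis values", {
  expect_equal(round(penetration_depth(0.23, 21), 3), 0.261)
  expect_equal(round(penetration_depth(1.8, 82), 3), 0.047)
  expect_equal(penetration_depth(1 / 3, 0), sqrt(3))
  expect_error(penetration_depth(0, 10), "mu_a")
  expect_error(penetration_depth(0.2, -1), "mu_s_reduced")
})

test_that("expected scatterings follow tau^2/2 + tau", {
  expect_equal(expected_scatterings(0), 0)
  expect_equal(expected_scatterings(1), 1.5)
  expect_equal(expected_scatterings(100), 5100)
  expect_equal(expected_scatterings(10), 60)
})

test_that("slab property rows carry the published coefficients", {
  p630 <- slab_properties("630")
  expect_equal(p630$mu_s, 210)  # mu_s' = 21 at g = 0.9
  expect_equal(p630$n, 1.38)
  expect_equal(round(p630$delta, 3), 0.261)
  p420 <- slab_properties("420")
  expect_equal(p420$mu_a, 1.8)
  expect_equal(round(p420$delta, 3), 0.047)
})

test_that("isotropic sphere benchmark at low optical depth", {
  r <- run_isotropic_sphere(0.1, n_photons = 5000, seed = 19)
  expect_lt(abs(r$mean - 0.105), 3 * r$se)
  expect_equal(r$n_capped, 0)
})

test_that("slab fit machinery recovers known coefficients from clean data", {
  delta <- 0.261
  z <- seq(0.002, 5 * delta, by = 0.005)
  psi <- 6.27 * exp(-z * 1.0 / delta) - 1.18 * exp(-z * 14.4 / delta)
  f <- fit_slab_profile(z, psi, delta = delta)
  expect_equal(f$k1, 1.0, tolerance = 1e-4)
  expect_equal(f$C1, 6.27, tolerance = 1e-4)
  expect_equal(f$k2, 14.4, tolerance = 1e-3)
  expect_true(all(is.finite(f$cov)))
})

test_that("glass-sphere rays agree with the two-interface Snell oracle", {
  gs <- build_glass_sphere_scene()
  oracle <- oracle_glass_sphere_ray(0.15, gs$center, gs$radius, gs$n_glass)
  hits <- 0
  for (i in 1:60) {
    tr <- propagate_trace(gs$scene, c(0.15, 0, 1.5), c(0, 0, -1),
                          seed = 71, substream = i)
    ev <- tr$history$event
    if (sum(ev == "refract") == 2 && !any(ev == "reflect")) {
      hits <- hits + 1
      expect_lt(angle_between(tr$exit_direction, oracle$direction), 1e-3)
      # exit point sits on the analytic refracted chord
      b <- which(ev == "refract")[2]
      got <- as.numeric(tr$history[b, c("x", "y", "z")])
      expect_lt(sqrt(sum((got - oracle$exit)^2)), 1e-4)
    }
  }
  expect_gt(hits, 40)  # ~96% of packets take the refract-refract path
})

test_that("reflected light off the glass sphere rises toward its edge", {
  gs <- build_glass_sphere_scene()
  n <- 3e4
  run <- mcrt_run(gs$scene, gs$source, n, seed = 73, record_exits = TRUE)
  launch <- emit(gs$source, n, seed = 73)     # same substreams as the run
  up <- run$exit_direction[, 3] > 0           # packets sent back upward
  # incidence angle (hence Fresnel R) grows with |x| toward the limb
  bins <- cut(abs(launch$position[, 1]), breaks = c(0, 0.6, 0.68, 0.745))
  frac <- tapply(up, bins, mean)
  expect_false(any(is.na(frac)))
  expect_true(all(diff(frac) > 0))  # monotone rising reflection profile
  expect_gt(frac[[3]], 3 * frac[[1]])  # strong rise near the edge
})

test_that("bottle scene has a 0.2 cm glass shell with correct media", {
  b <- build_bottle_scene()
  sc <- b$scene
  expect_equal(medium_at(sc, c(0, 0, 0))$n, 1.3)        # contents at centre
  expect_equal(medium_at(sc, c(1.65, 0, 0))$n, 1.5)     # glass in the wall
  expect_equal(medium_at(sc, c(0, 1.65, 0.5))$mu_s, 0)  # glass doesn't scatter
  expect_equal(medium_at(sc, c(2.0, 0, 0))$n, 1)        # air outside

  # shell thickness along random radial rays: distance between the inner and
  # outer zero crossings of the annulus SDF (bisection on the stored node)
  annulus_sdf <- function(p)
    photonsdf:::cpp_sdf_eval(sc$regions[[1]]$node, matrix(p, nrow = 1))
  for (th in with_seed(81, runif(6, 0, 2 * pi))) {
    dirv <- c(cos(th), sin(th), 0)
    r_out <- stats::uniroot(function(r) annulus_sdf(r * dirv),
                            c(1.6, 1.9), tol = 1e-10)$root
    r_in <- stats::uniroot(function(r) annulus_sdf(r * dirv),
                           c(1.4, 1.6), tol = 1e-10)$root
    expect_equal(r_out - r_in, 0.2, tolerance = 1e-8)
  }
})

test_that("vessel scene embeds capsules above the tissue layer", {
  caps <- data.frame(x1 = -0.01, y1 = 0, z1 = 0, x2 = 0.01, y2 = 0, z2 = 0,
                     radius = 0.002)
  v <- build_vessel_scene(caps)
  expect_equal(medium_at(v$scene, c(0, 0, 0))$mu_a, 231)      # vessel medium
  expect_equal(medium_at(v$scene, c(0, 0.01, 0))$mu_a, 0.459) # tissue
  expect_equal(medium_at(v$scene, c(0, 0, 0))$n, 1.38)
})

test_that("a 50-segment synthetic network transports robustly", {
  caps <- generate_capsule_network(n_segments = 50, seed = 5)
  v <- build_vessel_scene(caps)
  run <- mcrt_run(v$scene, v$source, 1e4, seed = 99)
  expect_lte(run$n_capped / run$n_photons, 1e-4)
  expect_equal(run$n_absorbed + run$n_escaped + run$n_capped +
                 run$n_degenerate, run$n_photons)
})

test_that("capsule network generation is deterministic and in-box", {
  b <- c(0.0163, 0.01525, 0.03055)
  a1 <- generate_capsule_network(n_segments = 30, box_half = b, seed = 42)
  a2 <- generate_capsule_network(n_segments = 30, box_half = b, seed = 42)
  expect_identical(a1, a2)
  a3 <- generate_capsule_network(n_segments = 30, box_half = b, seed = 43)
  expect_false(identical(a1, a3))
  expect_equal(nrow(a1), 30)
  for (cols in list(c("x1", "y1", "z1"), c("x2", "y2", "z2"))) {
    ends <- abs(as.matrix(a1[, cols]))
    expect_true(all(sweep(ends + a1$radius, 2, b, "<") ))
  }
  # the generator must not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_capsule_network(n_segments = 5, seed = 9))
  after <- runif(1)
  expect_identical(before, after)
})
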