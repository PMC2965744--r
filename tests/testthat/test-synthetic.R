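test_that("orientation sampling hits the target order parameter", {
  # zero case: isotropic, lambda = 0
  s0 <- sample_orientations(2000, S_target = 0, seed = 1)
  expect_equal(s0$lambda, 0)
  expect_lt(abs(mean((3 * s0$vectors[, 3]^2 - 1) / 2)), 3 / sqrt(2000))

  # the lambda <-> S map, checked against the numeric-integration oracle
  for (S in c(-0.4, 0.3, 0.7)) {
    lam <- dropletmetrics:::maier_saupe_lambda(S)
    num <- integrate(function(u) u^2 * exp(lam * u^2), 0, 1)$value /
      integrate(function(u) exp(lam * u^2), 0, 1)$value
    expect_equal((3 * num - 1) / 2, S, tolerance = 1e-6)
  }

  s <- sample_orientations(1e5, S_target = 0.7, seed = 42)
  expect_lt(abs(mean((3 * s$vectors[, 3]^2 - 1) / 2) - 0.7), 0.01)

  # approaching the S -> 1 limit theta concentrates near 0 (or pi: +/- axis
  # symmetry); cos(theta) piles up at |1|
  s1 <- sample_orientations(5000, S_target = 0.95, seed = 3)
  expect_gt(mean(abs(s1$vectors[, 3])), 0.9)

  expect_error(sample_orientations(10, S_target = 1), "inside|boundary|-0.5")
  expect_error(sample_orientations(10, S_target = -0.5), "inside|boundary|-0.5")
})

test_that("sphere walkers stay on the sphere and obey the 2D MSD law", {
  b0 <- brownian_on_sphere(R = 4.5, D = 0, dt_ns = 0.1, n_steps = 50,
                           n_walkers = 5, seed = 1)
  expect_equal(dplyr::n_distinct(round(b0$x, 12)), 5)  # stationary

  b <- brownian_on_sphere(R = 4.5, D = 1e-3, dt_ns = 0.1, n_steps = 2000,
                          n_walkers = 100, seed = 2)
  expect_lt(max(abs(sqrt(b$x^2 + b$y^2 + b$z^2) - 4.5)), 1e-6)
  for (k in c(1, 2)) {
    js <- jump_lengths(b, lag_ns = 0.1 * k)
    expect_lt(abs(mean(js$r^2) / (4 * 1e-3 * 0.1 * k) - 1), 0.05)
  }
  expect_error(brownian_on_sphere(R = 0.1, D = 1, dt_ns = 1, n_steps = 1,
                                  n_walkers = 1), "curvature|bound")
})

test_that("ball walkers stay inside and obey the 3D MSD law", {
  b0 <- brownian_in_ball(R = 3, D = 0, dt_ns = 0.1, n_steps = 50,
                         n_walkers = 5, seed = 1)
  expect_equal(dplyr::n_distinct(round(b0$x, 12)), 5)

  b <- brownian_in_ball(R = 3, D = 1e-4, dt_ns = 0.1, n_steps = 2000,
                        n_walkers = 100, seed = 3)
  expect_lte(max(sqrt(b$x^2 + b$y^2 + b$z^2)), 3)
  js <- jump_lengths(b, lag_ns = 0.1)
  expect_lt(abs(mean(js$r^2) / (6 * 1e-4 * 0.1) - 1), 0.05)
})

test_that("telegraph contact series have the prescribed statistics", {
  # effectively infinite off-time: no contacts ever switch on
  rec0 <- telegraph_contacts(1e-6, 1e12, dt_ns = 0.1, n_frames = 1000,
                             n_lipids = 5, seed = 1)
  expect_false(any(rec0$state))

  # stationary fraction
  rec <- telegraph_contacts(50, 50, dt_ns = 0.5, n_frames = 2e4,
                            n_lipids = 20, seed = 2)
  expect_lt(abs(mean(rec$state) - 0.5), 0.02)

  # seed-fixed bit reproducibility
  a <- telegraph_contacts(10, 20, dt_ns = 0.1, n_frames = 500, n_lipids = 3,
                          seed = 9)
  b <- telegraph_contacts(10, 20, dt_ns = 0.1, n_frames = 500, n_lipids = 3,
                          seed = 9)
  expect_identical(a$state, b$state)
})

test_that("droplet building respects composition and placement rules", {
  spec <- small_droplet_spec()
  d <- build_droplet(spec)
  cen <- species_census(d$topology)
  expect_equal(setNames(cen$n_molecules, cen$species)[names(spec$composition)],
               spec$composition[names(spec$composition)])

  nochol <- synthetic_spec(composition = c(POPC = 10, PPC = 2, CE = 5,
                                           CHOL = 0, TG = 3), n_frames = 1)
  expect_false("CHOL" %in% build_droplet(nochol)$topology$species)

  # generator's own placement rule: TG anchors in the core ball, POPC COMs
  # in the surface shell
  truth <- attr(d, "ground_truth")
  expect_true(all(truth$radius_nm[truth$species == "TG"] < 3.0))
  popc_ids <- truth$molecule_id[truth$species == "POPC"]
  rr <- vapply(popc_ids, function(m) sqrt(sum(molecule_com(d, m)^2)), 1)
  expect_true(all(rr >= 4.0 - 1e-9 & rr <= 4.5 + 0.02))

  expect_error(
    build_droplet(synthetic_spec(composition = c(POPC = 10, PPC = 0,
                                                 CE = 5000, CHOL = 0, TG = 0),
                                 n_frames = 1)),
    "particle_radius")
})

test_that("generators are deterministic under a fixed seed", {
  s1 <- sample_orientations(100, 0.3, seed = 5)
  s2 <- sample_orientations(100, 0.3, seed = 5)
  expect_identical(s1, s2)
  b1 <- brownian_on_sphere(4, 1e-3, 0.1, 10, 3, seed = 5)
  b2 <- brownian_on_sphere(4, 1e-3, 0.1, 10, 3, seed = 5)
  expect_identical(b1, b2)
  d1 <- build_droplet_trajectory(small_droplet_spec(n_frames = 3))
  d2 <- build_droplet_trajectory(small_droplet_spec(n_frames = 3))
  expect_identical(d1$coords, d2$coords)
})
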