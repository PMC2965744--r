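test_that("effective normal is the unit vector from COM to axis midpoint", {
  expect_equal(effective_normal(c(0, 0, 2)), cbind(0, 0, 1))
  expect_equal(effective_normal(c(3, 4, 0)), cbind(0.6, 0.8, 0))
  expect_equal(effective_normal(c(4, 4, 2), particle_com = c(1, 0, 2)),
               cbind(0.6, 0.8, 0))
  expect_error(effective_normal(c(0, 0, 0)), "undefined")
})

# build a one-frame system of two-bead CHOL "molecules" on a sphere with
# axes at prescribed angles to the radial direction; a mirrored copy of
# every molecule keeps the particle COM at the origin
axis_field_traj <- function(dirs, axes, radius = 4.25, half_len = 0.25) {
  n <- nrow(dirs)
  coords <- matrix(NA_real_, 4 * n, 3)
  for (i in seq_len(n)) {
    mid <- radius * dirs[i, ]
    coords[4 * i - 3, ] <- mid - half_len * axes[i, ]
    coords[4 * i - 2, ] <- mid + half_len * axes[i, ]
    coords[4 * i - 1, ] <- -(mid - half_len * axes[i, ])
    coords[4 * i, ] <- -(mid + half_len * axes[i, ])
  }
  top <- droplet_topology(tibble::tibble(
    molecule_id = rep(seq_len(2 * n), each = 2), species = "CHOL",
    bead_name = rep(c("R5", "R1"), 2 * n), moiety = "sterol_ring"))
  droplet_trajectory(top, coords)
}

test_that("order parameter is exact for forced radial and tangent fields", {
  set.seed(21)
  dirs <- matrix(rnorm(300), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  # radial axes: S = 1 in every occupied bin
  op1 <- order_parameter_profile(axis_field_traj(dirs, dirs), species = "CHOL",
                                 min_count = 1)
  expect_true(all(abs(op1$S - 1) < 1e-9))
  # tangent axes: S = -0.5
  tang <- t(vapply(seq_len(nrow(dirs)), function(i) {
    v <- c(-dirs[i, 2], dirs[i, 1], 0)
    v / sqrt(sum(v^2))
  }, numeric(3)))
  op2 <- order_parameter_profile(axis_field_traj(dirs, tang), species = "CHOL",
                                 min_count = 1)
  expect_true(all(abs(op2$S + 0.5) < 1e-9))
})

test_that("order parameter recovers prescribed order across targets", {
  # mirrored-pair geometry keeps the COM at the origin, so the measured
  # angles are exactly the sampled ones up to the second (mirrored) copy,
  # which shares the same P2 (P2 is even under axis flip)
  for (S in c(-0.4, 0, 0.3, 0.7, 0.95)) {
    sm <- sample_orientations(4000, S_target = S, seed = round(100 * S) + 500)
    set.seed(round(100 * S) + 1)
    dirs <- matrix(rnorm(3 * 4000), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    # rotate each sampled axis from the z frame into the local radial frame
    axes <- t(vapply(seq_len(4000), function(i) {
      as.vector(dropletmetrics:::rotation_z_to(dirs[i, ]) %*% sm$vectors[i, ])
    }, numeric(3)))
    op <- order_parameter_profile(axis_field_traj(dirs, axes),
                                  species = "CHOL", bin_width_nm = 1,
                                  min_count = 1)
    S_hat <- sum(op$S * op$n) / sum(op$n)
    expect_lt(abs(S_hat - S), 0.02)
  }
})

test_that("an isotropic axis field has S near zero", {
  n <- 1e5
  sm <- sample_orientations(n, S_target = 1e-9, seed = 77)
  S_hat <- mean((3 * sm$vectors[, 3]^2 - 1) / 2)
  expect_lt(abs(S_hat), 3 / sqrt(n))
})

test_that("angle distributions capture parallel, antiparallel and sin(theta)", {
  # parallel sn chains: all mass in the 0-degree bin
  dirs <- diag(3)
  tr <- axis_field_traj(dirs, dirs)
  ad0 <- angle_distribution(tr, axis_segment("CHOL", "R5", "R1"),
                            axis_segment("CHOL", "R5", "R1"), bins_deg = 5)
  expect_equal(ad0$prob[1], 1)
  expect_equal(sum(ad0$prob), 1)

  # vector vs its reverse: all mass at 180 degrees
  ad180 <- angle_distribution(tr, axis_segment("CHOL", "R5", "R1"),
                              axis_segment("CHOL", "R1", "R5"), bins_deg = 5)
  expect_equal(ad180$prob[length(ad180$prob)], 1)

  # isotropic pairs follow sin(theta)
  set.seed(5)
  n <- 4e4
  dirs <- matrix(rnorm(3 * n), ncol = 3); dirs <- dirs / sqrt(rowSums(dirs^2))
  axes <- matrix(rnorm(3 * n), ncol = 3); axes <- axes / sqrt(rowSums(axes^2))
  iso <- angle_distribution(axis_field_traj(dirs, axes),
                            axis_segment("CHOL", "R5", "R1"),
                            "effective_normal", bins_deg = 15)
  expected <- diff(-cos(seq(0, pi, length.out = 13))) / 2
  expect_lt(max(abs(iso$prob - expected)), 0.01)
})

test_that("angle distributions are invariant under global rotation", {
  d <- build_droplet(small_droplet_spec())
  seg <- axis_segment("POPC", "PO4", "NC3")
  a1 <- angle_distribution(d, seg, "effective_normal", bins_deg = 10)
  d2 <- rotate_trajectory(d, random_rotation(3))
  a2 <- angle_distribution(d2, seg, "effective_normal", bins_deg = 10)
  expect_equal(a2$prob, a1$prob, tolerance = 1e-9)
})

test_that("conformation maps localize fixed conformations and normalize", {
  # molecules built with theta = 30 deg, phi = 120 deg: one occupied cell
  n <- 40
  set.seed(9)
  dirs <- matrix(rnorm(3 * n), ncol = 3); dirs <- dirs / sqrt(rowSums(dirs^2))
  th <- 33 * pi / 180; ph <- 123 * pi / 180
  coords <- list(); rows <- list(); mid <- 0L
  for (i in seq_len(n)) {
    for (sgn in c(1, -1)) {
      mid <- mid + 1L
      e_r <- sgn * dirs[i, ]
      rot <- dropletmetrics:::rotation_z_to(e_r)
      ring_axis <- as.vector(rot %*% c(sin(th), 0, cos(th)))
      # chain vector at angle phi from the ring axis, in the plane spanned
      # by the ring axis and a perpendicular helper
      helper <- as.vector(rot %*% c(cos(th), 0, -sin(th)))
      chain <- cos(ph) * ring_axis + sin(ph) * helper
      m <- 4.25 * e_r
      coords[[mid]] <- rbind(m - 0.25 * ring_axis, m + 0.25 * ring_axis,
                             m + 0.3 * chain, m + 0.9 * chain)
      rows[[mid]] <- tibble::tibble(
        molecule_id = mid, species = "CE",
        bead_name = c("R5", "R1", "O1", "O4"),
        moiety = c("sterol_ring", "sterol_ring", "oleate_chain",
                   "oleate_chain"))
    }
  }
  tr <- droplet_trajectory(droplet_topology(dplyr::bind_rows(rows)),
                           do.call(rbind, coords))
  cm <- conformation_map(tr, bins_deg = 10)
  expect_equal(sum(cm$prob), 1)
  hot <- cm[cm$prob > 0, ]
  expect_equal(nrow(hot), 1L)
  expect_equal(hot$theta_deg, 35)  # 33 deg falls in the [30, 40) bin
  expect_equal(hot$phi_deg, 125)
  # region filter: all molecules sit at 4.25 nm (surface)
  expect_error(conformation_map(tr, region = "core"), "empty region")
  cs <- conformation_map(tr, region = "surface", bins_deg = 10)
  expect_equal(sum(cs$prob), 1)
})
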