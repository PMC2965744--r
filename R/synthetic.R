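#' Specification for a synthetic droplet
#'
#' Defines the composition, geometry, prescribed orientational order,
#' prescribed diffusion coefficients, and contact dwell-time parameters of a
#' synthetic spheroidal droplet with known ground truth. Defaults mirror the
#' studied HDL system: 260 POPC, 10 PPC, 122 CE, 49 CHOL, 39 TG plus two
#' 243-residue protein chains; core/surface boundaries at 3.0 and 4.0 nm with
#' a 4.5 nm particle radius; surface (2D) diffusion of 1e-3 nm^2/ns and core
#' (3D) diffusion ten-fold slower; contact/non-contact dwell means of
#' 146/175 ns.
#'
#' @param composition Named molecule counts for POPC, PPC, CE, CHOL, TG.
#' @param n_protein_chains Number of protein chains (each one synthetic
#'   apoA-I-like 243-mer).
#' @param shell_radii Inner and outer boundary radii `(r1, r2)` nm of the
#'   intermediate region.
#' @param particle_radius Outer particle radius (nm).
#' @param chol_surface_fraction Fraction of CHOL placed in the surface shell
#'   (the remainder goes to the core).
#' @param D2_true Surface (2D) diffusion coefficient, nm^2/ns.
#' @param D3_true Core (3D) diffusion coefficient, nm^2/ns.
#' @param S_target Named per-region target order parameter in (-0.5, 1).
#' @param dwell_on_ns,dwell_off_ns Mean contact / non-contact dwell times (ns).
#' @param dt_ns Frame interval (ns).
#' @param n_frames Number of trajectory frames.
#' @param seed Integer seed; every generator draw flows from it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(composition = c(POPC = 260, PPC = 10, CE = 122,
                                           CHOL = 49, TG = 39),
                           n_protein_chains = 2,
                           shell_radii = c(3.0, 4.0),
                           particle_radius = 4.5,
                           chol_surface_fraction = 0.85,
                           D2_true = 1e-3, D3_true = 1e-4,
                           S_target = c(core = 0, intermediate = 0.7,
                                        surface = 0.6),
                           dwell_on_ns = 146, dwell_off_ns = 175,
                           dt_ns = 1, n_frames = 100, seed = 1L) {
  assert_that(all(composition >= 0), "composition counts must be >= 0")
  assert_that(all(names(composition) %in% c("POPC", "PPC", "CE", "CHOL", "TG")),
              "composition names must be POPC, PPC, CE, CHOL, TG")
  assert_that(shell_radii[1] < shell_radii[2] &&
                shell_radii[2] <= particle_radius,
              "shell radii must be strictly increasing and within the particle radius")
  assert_that(D2_true > 0 && D3_true > 0, "diffusion coefficients must be > 0")
  assert_that(all(S_target > -0.5 & S_target < 1),
              "S_target must lie in (-0.5, 1)")
  assert_that(dwell_on_ns > 0 && dwell_off_ns > 0, "dwell means must be > 0")
  structure(
    list(composition = composition, n_protein_chains = n_protein_chains,
         shell_radii = shell_radii, particle_radius = particle_radius,
         chol_surface_fraction = chol_surface_fraction,
         D2_true = D2_true, D3_true = D3_true, S_target = S_target,
         dwell_on_ns = dwell_on_ns, dwell_off_ns = dwell_off_ns,
         dt_ns = dt_ns, n_frames = n_frames, seed = as.integer(seed)),
    class = "synthetic_spec")
}

# ---- orientational order: Maier-Saupe-type axis sampler ----------------

# <P2> under the density f(u) ~ exp(lambda * u^2) on u = cos(theta) in [-1,1]
p2_of_lambda <- function(lambda) {
  z <- integrate(function(u) exp(lambda * u^2), 0, 1, rel.tol = 1e-11)$value
  m2 <- integrate(function(u) u^2 * exp(lambda * u^2), 0, 1, rel.tol = 1e-11)$value / z
  (3 * m2 - 1) / 2
}

# Solve lambda so that <P2> = S_target (bracketed on [-50, 50]).
maier_saupe_lambda <- function(S_target, tol = 1e-6) {
  assert_that(S_target > -0.5 && S_target < 1,
              "S_target must lie strictly inside (-0.5, 1)")
  if (abs(S_target) < tol) return(0)
  lo <- -50; hi <- 50
  assert_that(S_target > p2_of_lambda(lo) && S_target < p2_of_lambda(hi),
              sprintf("S_target = %.3f outside the solvable range of lambda in [-50, 50]",
                      S_target))
  r <- uniroot(function(l) p2_of_lambda(l) - S_target, c(lo, hi), tol = 1e-9)
  # polish to tolerance in S
  assert_that(abs(p2_of_lambda(r$root) - S_target) < tol,
              "lambda root did not reach tolerance in S")
  r$root
}

# Rejection sampler for u = cos(theta) with density ~ exp(lambda u^2).
sample_cos_theta <- function(n, lambda) {
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 1000L)
    u <- runif(m, -1, 1)
    logacc <- if (lambda >= 0) lambda * (u^2 - 1) else lambda * u^2
    keep <- log(runif(m)) < logacc
    out <- c(out, u[keep])
  }
  out[seq_len(n)]
}

#' Sample molecular axis orientations with a prescribed order parameter
#'
#' Draws `n` unit vectors whose polar angle against the +z director follows a
#' Maier-Saupe-type density proportional to `exp(lambda cos^2 theta) sin theta`,
#' with `lambda` solved numerically so that the expected second Legendre
#' polynomial `<(3 cos^2 theta - 1)/2>` equals `S_target`. Azimuths are
#' uniform. Any distribution achieving the target order would serve; this
#' single-parameter family is a convenient, documented choice.
#'
#' @param n Number of axes.
#' @param S_target Target order parameter in (-0.5, 1) (exclusive: the
#'   boundary distributions are degenerate).
#' @param seed Integer seed.
#' @return A list with `vectors` (an `n x 3` matrix of unit axes) and
#'   `lambda` (the solved concentration parameter).
#' @export
#' @examples
#' s <- sample_orientations(1000, S_target = 0.7, seed = 1)
#' mean((3 * s$vectors[, 3]^2 - 1) / 2)
sample_orientations <- function(n, S_target, seed = 1L) {
  set.seed(as.integer(seed))
  lambda <- maier_saupe_lambda(S_target)
  u <- sample_cos_theta(n, lambda)
  phi <- runif(n, 0, 2 * pi)
  st <- sqrt(pmax(0, 1 - u^2))
  list(vectors = cbind(st * cos(phi), st * sin(phi), u), lambda = lambda)
}

# ---- Brownian ground-truth walkers -------------------------------------

# Tangent-plane stepper on spheres of (per-walker) radius R. start: n x 3.
sphere_walk <- function(start, R, D, dt_ns, n_steps) {
  n <- nrow(start)
  R <- rep_len(R, n)
  out <- array(NA_real_, dim = c(n_steps + 1L, n, 3L))
  x <- unit_rows(start) * R
  out[1, , ] <- x
  sig <- sqrt(2 * D * dt_ns)
  for (s in seq_len(n_steps)) {
    u <- x / R
    # tangent frame: e1 = u x a (a chosen away from u), e2 = u x e1
    a <- cbind(0, 0, 1)[rep(1, n), , drop = FALSE]
    swap <- abs(u[, 3]) > 0.9
    if (any(swap)) {
      a[swap, ] <- matrix(c(1, 0, 0), nrow = sum(swap), ncol = 3, byrow = TRUE)
    }
    e1 <- cbind(u[, 2] * a[, 3] - u[, 3] * a[, 2],
                u[, 3] * a[, 1] - u[, 1] * a[, 3],
                u[, 1] * a[, 2] - u[, 2] * a[, 1])
    e1 <- unit_rows(e1)
    e2 <- cbind(u[, 2] * e1[, 3] - u[, 3] * e1[, 2],
                u[, 3] * e1[, 1] - u[, 1] * e1[, 3],
                u[, 1] * e1[, 2] - u[, 2] * e1[, 1])
    g1 <- rnorm(n, 0, sig); g2 <- rnorm(n, 0, sig)
    x <- x + e1 * g1 + e2 * g2
    x <- unit_rows(x) * R
    out[s + 1L, , ] <- x
  }
  out
}

# Isotropic Gaussian stepper in balls of (per-walker) radius R with radial
# reflection at the boundary.
ball_walk <- function(start, R, D, dt_ns, n_steps) {
  n <- nrow(start)
  R <- rep_len(R, n)
  out <- array(NA_real_, dim = c(n_steps + 1L, n, 3L))
  x <- start
  out[1, , ] <- x
  sig <- sqrt(2 * D * dt_ns)
  for (s in seq_len(n_steps)) {
    x <- x + matrix(rnorm(3L * n, 0, sig), ncol = 3L)
    r <- row_norms(x)
    over <- r > R
    if (any(over)) {
      x[over, ] <- x[over, , drop = FALSE] * ((2 * R[over] - r[over]) / r[over])
    }
    out[s + 1L, , ] <- x
  }
  out
}

walk_to_tibble <- function(arr, dt_ns) {
  ns <- dim(arr)[1]; nw <- dim(arr)[2]
  tibble(
    walker = rep(seq_len(nw), each = ns),
    step = rep(seq_len(ns) - 1L, nw),
    time_ns = rep((seq_len(ns) - 1L) * dt_ns, nw),
    x = as.vector(arr[, , 1]), y = as.vector(arr[, , 2]),
    z = as.vector(arr[, , 3])
  )
}

#' Brownian walkers on a sphere (2D surface diffusion ground truth)
#'
#' Each step displaces the walker in its local tangent plane by a 2D Gaussian
#' of variance `4 D dt` per step (`2 D dt` per tangent axis), then re-projects
#' onto the sphere of radius `R`. The step must be small relative to the
#' curvature: `sqrt(4 D dt) <= 0.2 R` is enforced, which keeps the chord vs
#' geodesic bias of downstream jump-length fits below 1%.
#'
#' @param R Sphere radius (nm).
#' @param D Diffusion coefficient (nm^2/ns).
#' @param dt_ns Time step (ns).
#' @param n_steps Steps per walker.
#' @param n_walkers Number of walkers.
#' @param seed Integer seed.
#' @return A tibble with `walker`, `step`, `time_ns`, `x`, `y`, `z`.
#' @export
brownian_on_sphere <- function(R, D, dt_ns, n_steps, n_walkers, seed = 1L) {
  step <- sqrt(4 * D * dt_ns)
  if (step > 0.2 * R) {
    abort(sprintf(
      "step size sqrt(4 D dt) = %.3g nm exceeds the curvature bound 0.2 R = %.3g nm",
      step, 0.2 * R))
  }
  set.seed(as.integer(seed))
  start <- random_unit_vectors(n_walkers) * R
  walk_to_tibble(sphere_walk(start, R, D, dt_ns, n_steps), dt_ns)
}

#' Brownian walkers in a ball (3D interior diffusion ground truth)
#'
#' Isotropic Gaussian steps of variance `2 D dt` per axis with a reflecting
#' boundary at radius `R`. Requires `sqrt(6 D dt) <= 0.2 R`.
#'
#' @inheritParams brownian_on_sphere
#' @return A tibble with `walker`, `step`, `time_ns`, `x`, `y`, `z`.
#' @export
brownian_in_ball <- function(R, D, dt_ns, n_steps, n_walkers, seed = 1L) {
  step <- sqrt(6 * D * dt_ns)
  if (step > 0.2 * R) {
    abort(sprintf(
      "step size sqrt(6 D dt) = %.3g nm exceeds the bound 0.2 R = %.3g nm",
      step, 0.2 * R))
  }
  set.seed(as.integer(seed))
  u <- runif(n_walkers)^(1 / 3) * R
  start <- random_unit_vectors(n_walkers) * u
  walk_to_tibble(ball_walk(start, R, D, dt_ns, n_steps), dt_ns)
}

#' Two-state telegraph contact process
#'
#' Generates per-lipid boolean contact time series from an alternating
#' renewal process with exponential dwell times (means `mean_on_ns`,
#' `mean_off_ns`), discretized at the frame interval `dt_ns`. The stationary
#' contact fraction is `mean_on / (mean_on + mean_off)`; initial states are
#' drawn from it.
#'
#' @param mean_on_ns,mean_off_ns Mean contact / non-contact dwell times (ns).
#' @param dt_ns Frame interval (ns).
#' @param n_frames Number of frames.
#' @param n_lipids Number of independent lipid series.
#' @param seed Integer seed.
#' @return A [contact_record()] whose `state` is an `n_frames x n_lipids`
#'   logical matrix.
#' @export
telegraph_contacts <- function(mean_on_ns, mean_off_ns, dt_ns, n_frames,
                               n_lipids, seed = 1L) {
  assert_that(mean_on_ns > 0 && mean_off_ns > 0, "dwell means must be > 0")
  set.seed(as.integer(seed))
  total <- n_frames * dt_ns
  tgrid <- (seq_len(n_frames) - 1L) * dt_ns
  p_on <- mean_on_ns / (mean_on_ns + mean_off_ns)
  state <- matrix(NA, n_frames, n_lipids)
  for (j in seq_len(n_lipids)) {
    first_on <- runif(1) < p_on
    dwells <- numeric(0)
    while (sum(dwells) <= total) {
      k <- length(dwells)
      # batch sized from the expected number of remaining on/off cycles
      m <- 2L * ceiling((total - sum(dwells)) / (mean_on_ns + mean_off_ns)) + 8L
      means <- ifelse(xor(first_on, (k + seq_len(m) - 1L) %% 2 == 1),
                      mean_on_ns, mean_off_ns)
      dwells <- c(dwells, rexp(m, 1 / means))
    }
    idx <- findInterval(tgrid, cumsum(c(0, dwells)), left.open = FALSE)
    state[, j] <- xor(first_on, idx %% 2 == 0)
  }
  contact_record(state, times_ns = tgrid, cutoff_nm = NA_real_,
                 molecule_ids = seq_len(n_lipids),
                 species = rep("SYN", n_lipids))
}
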