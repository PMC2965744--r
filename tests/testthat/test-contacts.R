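test_that("cell-list neighbor search equals the all-pairs oracle", {
  set.seed(41)
  xa <- matrix(runif(300 * 3, 0, 5), ncol = 3)
  xb <- matrix(runif(200 * 3, 0, 5), ncol = 3)
  fast <- neighbor_pairs(xa, xb, 0.8, method = "cell")
  brute <- neighbor_pairs(xa, xb, 0.8, method = "brute")
  ora <- oracle_pairs(xa, xb, 0.8)
  expect_equal(fast[, 1:2], brute[, 1:2])
  expect_equal(as.data.frame(fast[, 1:2]), as.data.frame(ora[, 1:2]))
  expect_equal(fast$dist_nm, ora$dist_nm, tolerance = 1e-12)
})

test_that("annular definition is strict at the 0.8 nm cutoff", {
  a79 <- annular_states(annular_fixture(0.79))
  expect_true(a79$state[1, 1])
  a81 <- annular_states(annular_fixture(0.81))
  expect_false(a81$state[1, 1])
  expect_error(annular_states(tiny_lipid_traj(rbind(c(0, 0, 0), c(1, 0, 0)))),
               "no protein")
})

test_that("annular states match a brute-force oracle on a droplet frame", {
  tr <- build_droplet(small_droplet_spec(seed = 17))
  rec <- annular_states(tr, cutoff_nm = 0.8)
  top <- tr$topology
  xyz <- dropletmetrics:::frame_coords(tr, 1)
  prot <- xyz[top$species == "PROTEIN", , drop = FALSE]
  for (k in seq_along(rec$molecule_ids)) {
    idx <- top$molecule_id == rec$molecule_ids[k]
    d2 <- outer(rowSums(xyz[idx, , drop = FALSE]^2), rep(1, nrow(prot))) +
      outer(rep(1, sum(idx)), rowSums(prot^2)) -
      2 * xyz[idx, , drop = FALSE] %*% t(prot)
    expect_identical(unname(rec$state[1, k]), any(d2 < 0.8^2))
  }
})

test_that("annular summaries compute counts and fractions", {
  st <- matrix(TRUE, 10, 49)
  rec <- contact_record(st, 0:9, 0.8, seq_len(49), rep("CHOL", 49))
  s <- annular_summary(rec)
  expect_equal(s$mean_annular, 49)
  expect_equal(s$fraction, 1)

  alt <- matrix(rep(c(TRUE, FALSE), 5), 10, 4)
  rec2 <- contact_record(alt, 0:9, 0.8, 1:4, rep("CE", 4))
  expect_equal(annular_summary(rec2)$fraction, 0.5)

  rec3 <- telegraph_contacts(80, 80, dt_ns = 0.5, n_frames = 2e4,
                             n_lipids = 30, seed = 19)
  expect_lt(abs(annular_summary(rec3)$fraction - 0.5), 0.02)
})

test_that("gap tolerance merges short interruptions exactly as specified", {
  mkrec <- function(x) contact_record(matrix(x, ncol = 1),
                                      seq_along(x) * 0.01, 0.8, 1L, "CHOL")
  # 1,1,0x5,1,1 with tolerance 10: a single contact interval of 9 frames
  x1 <- c(TRUE, TRUE, rep(FALSE, 5), TRUE, TRUE)
  lt1 <- contact_lifetimes(mkrec(x1), tolerance_frames = 10)
  on1 <- lt1$dwells[lt1$dwells$state, ]
  expect_equal(nrow(on1), 1L)
  expect_equal(on1$n_frames, 9L)

  # 1,1,0x10,1,1: the gap is not < 10 frames, so two intervals remain
  x2 <- c(TRUE, TRUE, rep(FALSE, 10), TRUE, TRUE)
  lt2 <- contact_lifetimes(mkrec(x2), tolerance_frames = 10)
  expect_equal(nrow(lt2$dwells[lt2$dwells$state, ]), 2L)

  # tolerance 0 and 1 are both no-ops for frame-sampled binary series
  x3 <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  expect_identical(contact_lifetimes(mkrec(x3), 0)$dwells,
                   contact_lifetimes(mkrec(x3), 1)$dwells)
})

test_that("lifetime merging agrees with the brute-force oracle and is monotone", {
  rec <- telegraph_contacts(2, 3, dt_ns = 0.1, n_frames = 5000, n_lipids = 6,
                            seed = 23)
  for (tol in c(0, 3, 10)) {
    lt <- contact_lifetimes(rec, tolerance_frames = tol)
    for (j in 1:6) {
      merged <- dropletmetrics:::merge_gaps(rec$state[, j], tol)
      expect_identical(merged, oracle_merge(rec$state[, j], tol))
    }
  }
  means <- vapply(c(0, 2, 5, 10, 20), function(tol) {
    contact_lifetimes(rec, tolerance_frames = tol)$mean_on_ns
  }, numeric(1))
  expect_true(all(diff(means) >= -1e-12))
})

test_that("telegraph dwell means are recovered by the tolerance-0 estimator", {
  rec <- telegraph_contacts(20, 30, dt_ns = 0.1, n_frames = 2e5,
                            n_lipids = 8, seed = 29)
  lt <- contact_lifetimes(rec, tolerance_frames = 0)
  expect_lt(abs(lt$mean_on_ns / 20 - 1), 0.05)
  expect_lt(abs(lt$mean_off_ns / 30 - 1), 0.05)
  # and equals the independent single-pass dwell oracle
  om <- colMeans(do.call(rbind, lapply(1:8, function(j) {
    oracle_dwell_means(rec$state[, j], 0.1)
  })), na.rm = TRUE)
  expect_equal(lt$mean_on_ns, unname(om["on"]), tolerance = 0.02)
})

test_that("per-residue contact profiles normalize by residue multiplicity", {
  # one CHOL bead within the cutoff of one of 4 Trp beads
  top <- droplet_topology(dplyr::bind_rows(
    tibble::tibble(molecule_id = 1L, species = "CHOL", bead_name = "R1",
                   moiety = "sterol_ring"),
    tibble::tibble(molecule_id = 2L, species = "PROTEIN", bead_name = "BB",
                   moiety = "backbone", residue_index = 1:8,
                   residue_name = rep(c("TRP", "SER"), each = 4),
                   hydro_class = rep(c("hydrophobic", "hydrophilic"), each = 4),
                   chain = "A")))
  coords <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(5, 0, 0), c(6, 0, 0),
                  c(7, 0, 0), c(8, 0, 0), c(9, 0, 0), c(10, 0, 0),
                  c(11, 0, 0))
  tr <- droplet_trajectory(top, coords)
  prof <- residue_contact_profile(tr, "CHOL")
  expect_equal(prof$contacts_per_residue[prof$residue_name == "TRP"], 0.25)
  expect_equal(prof$contacts_per_residue[prof$residue_name == "SER"], 0)
  roll <- attr(prof, "hydro_rollup")
  expect_equal(roll$contacts_per_frame[roll$hydro_class == "hydrophobic"], 1)

  # no contacts at all: all zeros
  far <- droplet_trajectory(top, coords + cbind(c(100, rep(0, 8)), 0, 0))
  expect_true(all(residue_contact_profile(far, "CHOL")$contacts_per_frame == 0))
})

test_that("residue contact profiles equal the brute-force oracle", {
  tr <- build_droplet(small_droplet_spec(seed = 31))
  top <- tr$topology
  prof <- residue_contact_profile(tr, "CHOL")
  xyz <- dropletmetrics:::frame_coords(tr, 1)
  lip <- which(top$species == "CHOL")
  prot <- which(top$species == "PROTEIN")
  ora <- oracle_pairs(xyz[lip, , drop = FALSE], xyz[prot, , drop = FALSE], 0.8)
  cnt <- table(top$residue_name[prot][ora$j])
  for (rn in prof$residue_name) {
    expect_equal(prof$contacts_per_frame[prof$residue_name == rn],
                 unname(ifelse(rn %in% names(cnt), cnt[rn], 0)))
  }
})

test_that("moiety fractions reflect planted contact geometry", {
  # one CHOL with its ring bead in contact and its tail far away, plus one
  # CE touching only via the oleate chain
  top <- droplet_topology(dplyr::bind_rows(
    tibble::tibble(molecule_id = 1L, species = "CHOL",
                   bead_name = c("R1", "C2"),
                   moiety = c("sterol_ring", "sterol_tail")),
    tibble::tibble(molecule_id = 2L, species = "CE",
                   bead_name = c("O1", "R1"),
                   moiety = c("oleate_chain", "sterol_ring")),
    tibble::tibble(molecule_id = 3L, species = "PROTEIN", bead_name = "BB",
                   moiety = "backbone", residue_index = 1L,
                   residue_name = "LEU", hydro_class = "hydrophobic",
                   chain = "A")))
  coords <- rbind(c(0.5, 0, 0), c(3, 0, 0),   # CHOL ring in, tail out
                  c(0, 0.6, 0), c(0, 4, 0),   # CE oleate in, ring out
                  c(0, 0, 0))
  tr <- droplet_trajectory(top, coords)
  mf <- moiety_contact_fractions(tr)
  expect_equal(mf$pct[mf$species == "CHOL" & mf$moiety == "sterol_ring"], 100)
  expect_equal(mf$pct[mf$species == "CE" & mf$moiety == "oleate_chain"], 100)
  sums <- mf |> dplyr::group_by(species) |> dplyr::summarise(s = sum(pct))
  expect_true(all(abs(sums$s - 100) < 1e-9))
})

test_that("intergroup contact counts match simple geometry and the oracle", {
  tr <- tiny_lipid_traj(rbind(c(0, 0, 0), c(0.5, 0, 0)))
  expect_equal(intergroup_contacts(tr, 1L, 2L)$n_contacts, 1L)
  tr2 <- tiny_lipid_traj(rbind(c(0, 0, 0), c(0.9, 0, 0)))
  expect_equal(intergroup_contacts(tr2, 1L, 2L)$n_contacts, 0L)
  expect_error(intergroup_contacts(tr, 1L, 1L), "overlap")
  expect_error(intergroup_contacts(tr, integer(0), 2L), "empty")

  set.seed(43)
  xa <- matrix(runif(60 * 3, 0, 3), ncol = 3)
  xb <- matrix(runif(40 * 3, 0, 3), ncol = 3)
  top <- droplet_topology(tibble::tibble(
    molecule_id = 1:100, species = rep(c("CHOL", "TG"), c(60, 40)),
    bead_name = "C1", moiety = "other"))
  tr3 <- droplet_trajectory(top, rbind(xa, xb))
  expect_equal(intergroup_contacts(tr3, "CHOL", "TG")$n_contacts,
               nrow(oracle_pairs(xa, xb, 0.8)))
})

test_that("RMSF separates flexibility from rigid-body motion", {
  seq_res <- c("ALA", "LEU", "TRP", "SER", "GLU", "LYS")
  top <- droplet_topology(tibble::tibble(
    molecule_id = 1L, species = "PROTEIN", bead_name = "BB",
    moiety = "backbone", residue_index = seq_along(seq_res),
    residue_name = seq_res,
    hydro_class = ifelse(seq_res %in% c("ALA", "LEU", "TRP"),
                         "hydrophobic", "hydrophilic"), chain = "A"))
  base <- cbind(seq_along(seq_res), 0, 0)

  # static structure: zero everywhere
  coords <- array(NA_real_, dim = c(10, 6, 3))
  for (f in 1:10) coords[f, , ] <- base
  expect_true(all(rmsf(droplet_trajectory(top, coords))$rmsf_nm == 0))

  # isotropic jitter of sd sigma: RMSF ~ sigma * sqrt(3) without alignment
  set.seed(47)
  sigma <- 0.05
  nf <- 1e4
  coords <- array(NA_real_, dim = c(nf, 6, 3))
  for (f in 1:nf) coords[f, , ] <- base + matrix(rnorm(18, 0, sigma), 6, 3)
  rj <- rmsf(droplet_trajectory(top, coords), align = FALSE)
  expect_lt(max(abs(rj$rmsf_nm / (sigma * sqrt(3)) - 1)), 0.02)

  # rigid rotation: alignment removes it completely
  coords <- array(NA_real_, dim = c(20, 6, 3))
  for (f in 1:20) {
    ang <- 0.2 * (f - 1)
    Rz <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    coords[f, , ] <- base %*% t(Rz)
  }
  ra <- rmsf(droplet_trajectory(top, coords), align = TRUE)
  expect_lt(max(ra$rmsf_nm), 1e-9)
  expect_gt(max(rmsf(droplet_trajectory(top, coords), align = FALSE)$rmsf_nm),
            0.5)
})
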