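test_that("radial density places mass in the right shell with the right value", {
  tr <- tiny_lipid_traj(matrix(c(2.05, 0, 0), 1), bead_names = "R5")
  rd <- radial_density(tr, bin_width_nm = 0.1, center = c(0, 0, 0))
  hot <- rd[rd$count > 0, ]
  expect_equal(nrow(hot), 1L)
  expect_equal(hot$r, 2.05)
  vol <- 4 / 3 * pi * (2.1^3 - 2.0^3)
  expect_equal(hot$density, 1 / vol)
})

test_that("density normalization returns species counts on droplet fixtures", {
  d <- build_droplet(small_droplet_spec())
  rd <- radial_density(d, reference = "molecule_com")
  sums <- rd |> dplyr::group_by(species) |> dplyr::summarise(n = sum(count))
  counts <- setNames(sums$n, sums$species)
  expect_equal(counts[["POPC"]], 30)
  expect_equal(counts[["TG"]], 6)
  expect_equal(counts[["CE"]], 16)
  # generator placement: TG confined to the core, POPC to the surface shell
  expect_equal(sum(rd$count[rd$species == "TG" & rd$r > 3.1]), 0)
  expect_equal(sum(rd$count[rd$species == "POPC" & rd$r < 3.9]), 0)
  expect_error(radial_density(d, species = "WATER"), "empty selection")
})

test_that("an isotropic uniform-ball cloud has a flat density profile", {
  set.seed(8)
  n <- 2e5
  r <- 3 * runif(n)^(1 / 3)
  dirs <- matrix(rnorm(3 * n), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  top <- droplet_topology(tibble::tibble(
    molecule_id = seq_len(n), species = "TG", bead_name = "C1A",
    moiety = "sn1_chain"))
  tr <- droplet_trajectory(top, dirs * r)
  rd <- radial_density(tr, bin_width_nm = 0.25)
  core <- rd[rd$r > 0.5 & rd$r < 2.75, ]   # away from origin noise / edge
  rho <- n / (4 / 3 * pi * 27)
  expect_true(all(abs(core$density / rho - 1) < 0.05))
})

test_that("composition reproduces the reference mol% table", {
  d <- build_droplet(synthetic_spec(n_frames = 1))
  cmp <- composition(d$topology, include_protein = TRUE)
  pct <- setNames(round(cmp$mol_pct, 1), cmp$species)
  expect_equal(pct[["POPC"]], 53.9)
  expect_equal(pct[["PPC"]], 2.1)
  expect_equal(pct[["CE"]], 25.3)
  expect_equal(pct[["CHOL"]], 10.2)
  expect_equal(pct[["TG"]], 8.1)
  expect_equal(sum(cmp$mol_pct), 100, tolerance = 1e-9)

  lipid_only <- composition(d$topology, include_protein = FALSE)
  expect_equal(round(lipid_only$mol_pct[lipid_only$species == "POPC"], 1), 54.2)

  one <- composition(bead_cloud_topology(3, species = "TG"))
  expect_equal(one$mol_pct, 100)
})

test_that("radius of gyration matches closed forms", {
  pt <- tiny_lipid_traj(matrix(rep(c(1, 2, 3), 4), 4, byrow = TRUE),
                        bead_names = c("R5", "R1"))
  expect_equal(radius_of_gyration(pt)$rg_nm, 0)

  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  top <- droplet_topology(tibble::tibble(
    molecule_id = 1L, species = "TG", bead_name = paste0("C", 1:8, "A"),
    moiety = "sn1_chain"))
  tr <- droplet_trajectory(top, cube)
  expect_equal(radius_of_gyration(tr)$rg_nm, sqrt(3))

  set.seed(4)
  n <- 1e5
  r <- 4 * runif(n)^(1 / 3)
  dirs <- matrix(rnorm(3 * n), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  ball <- droplet_trajectory(
    droplet_topology(tibble::tibble(molecule_id = seq_len(n), species = "TG",
                                    bead_name = "C1A", moiety = "sn1_chain")),
    dirs * r)
  expect_equal(radius_of_gyration(ball)$rg_nm, sqrt(3 / 5) * 4,
               tolerance = 0.01)
  expect_error(radius_of_gyration(ball, species = "CHOL"), "empty")
})

test_that("region assignment uses the half-open boundary convention", {
  mk <- function(x) tiny_lipid_traj(matrix(c(x, 0, 0, x, 0, 0), 2,
                                           byrow = TRUE))
  # the particle COM of a single molecule is the molecule itself, so build
  # an explicit two-molecule system: one at the origin pins the COM there
  place <- function(r) {
    top <- droplet_topology(tibble::tibble(
      molecule_id = c(1L, 2L), species = "CHOL", bead_name = "R5",
      moiety = "sterol_ring"))
    droplet_trajectory(top, rbind(c(-r, 0, 0), c(r, 0, 0)))
  }
  lab <- function(r) {
    ar <- assign_region(place(r), boundaries = c(3, 4))
    ar$region[ar$molecule_id == 2]
  }
  expect_equal(lab(1), "core")
  expect_equal(lab(3.5), "intermediate")
  expect_equal(lab(4.0), "surface")    # boundary belongs to the outer region
  expect_equal(lab(3.0), "intermediate")
  expect_error(assign_region(place(1), boundaries = c(4, 3)), "r1 < r2")
})

test_that("region labels partition molecules exhaustively and exclusively", {
  tr <- build_droplet_trajectory(small_droplet_spec(n_frames = 3))
  ar <- assign_region(tr)
  n_lipid <- sum(species_census(tr$topology)$n_molecules[
    species_census(tr$topology)$species != "PROTEIN"])
  expect_equal(nrow(ar), n_lipid * 3)
  expect_true(all(ar$region %in% c("core", "intermediate", "surface")))
  expect_equal(nrow(dplyr::distinct(ar, molecule_id, frame)), n_lipid * 3)
  # >= 95% of POPC frames labeled surface under the generator's placement
  popc <- ar[ar$species == "POPC", ]
  expect_gte(mean(popc$region == "surface"), 0.95)
})
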