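test_that("toy dimer models load with addressable chains and residues", {
  path <- toy_dimer_pdb(n_res = 10)
  mod <- load_model(path)
  expect_setequal(mod$chains, c("A", "B"))
  expect_equal(length(unique(paste(mod$atoms$chain, mod$atoms$resno))), 20L)
  # prime-notation addressing: same residue number, distinct chains
  a5 <- lookup_atom(mod, "A", 5, "CB")
  b5 <- lookup_atom(mod, "B", 5, "CB")
  expect_false(isTRUE(all.equal(a5, b5)))
  expect_error(lookup_atom(mod, "A", 999), "residue 999")
  unlink(path)
})

test_that("an unobstructed site fills the whole linker ball", {
  mod <- load_model(toy_site_pdb())
  site <- label_site("A", 1, linker_length = 10)
  cl <- simulate_dye_cloud(mod, site, grid_spacing = 1)
  expect_equal(cl$n_allowed, cl$n_samples)
  # centroid within a grid spacing of the attachment point
  expect_lt(sqrt(sum((cl$mean_position - cl$attachment)^2)), 1)
  # grid candidate count approximates the ball volume
  expect_lt(abs(cl$n_samples - 4 / 3 * pi * 10^3) / (4 / 3 * pi * 10^3), 0.05)
})

test_that("a fully caged site errors as occluded", {
  # tight spherical cage 4 A from the attachment: with 4.5 A dye
  # clearance, every point of the 8 A linker ball clashes
  dirs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  dirs <- dirs[rowSums(dirs^2) > 0, ]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  cage <- as.data.frame(dirs * 4)
  mod <- load_model(toy_site_pdb(cage))
  site <- label_site("A", 1, linker_length = 8)
  expect_error(simulate_dye_cloud(mod, site), "fully occluded")
})

test_that("a blocking wall halves the allowed volume, matching Monte Carlo", {
  # wall of atoms at z = +4.75: dye clearance is 4.5 A, so roughly the
  # z < 0 half of the ball is allowed (the cut plane is deliberately off
  # the grid planes so grid and Monte-Carlo measure the same region)
  g <- seq(-18, 18, by = 2)
  wall <- expand.grid(x = g, y = g)
  wall$z <- 4.75
  mod <- load_model(toy_site_pdb(wall))
  site <- label_site("A", 1, linker_length = 12)
  grid_cl <- simulate_dye_cloud(mod, site, grid_spacing = 1)
  f_grid <- allowed_fraction(grid_cl)
  mc_cl <- sample_dye_cloud_mc(mod, site, n_samples = 30000, seed = 5)
  f_mc <- allowed_fraction(mc_cl)
  expect_lt(abs(f_grid - 0.5), 0.06)
  expect_lt(abs(f_grid - f_mc), 0.02)
  # centroid is pushed away from the wall
  expect_lt(grid_cl$mean_position[3], -2)
})

test_that("removing obstacles never shrinks the allowed set", {
  set.seed(21)
  obstacles <- data.frame(x = runif(25, -10, 10), y = runif(25, -10, 10),
                          z = runif(25, -10, 10))
  site <- label_site("A", 1, linker_length = 10)
  full <- simulate_dye_cloud(load_model(toy_site_pdb(obstacles)), site)
  fewer <- simulate_dye_cloud(load_model(toy_site_pdb(obstacles[1:10, ])), site)
  none <- simulate_dye_cloud(load_model(toy_site_pdb()), site)
  expect_lte(full$n_allowed, fewer$n_allowed)
  expect_lte(fewer$n_allowed, none$n_allowed)
})

test_that("two unobstructed sites 80 A apart are 8 nm apart", {
  atoms <- data.frame(chain = c("A", "B"), resno = 1L, elety = "CB",
                      x = c(0, 80), y = 0, z = 0)
  mod <- load_model(write_toy_pdb(atoms))
  s1 <- label_site("A", 1, linker_length = 8)
  s2 <- label_site("B", 1, linker_length = 8)
  c1 <- simulate_dye_cloud(mod, s1)
  c2 <- simulate_dye_cloud(mod, s2)
  d <- interdye_distance(c1, c2)
  expect_lt(abs(d - 8.0), 0.1)
  # symmetry and the coincident case
  expect_equal(interdye_distance(c2, c1), d)
  expect_equal(interdye_distance(c1, c1), 0)
})

test_that("mean-position distances obey the triangle inequality", {
  atoms <- data.frame(chain = c("A", "B", "C"), resno = 1L, elety = "CB",
                      x = c(0, 41, 13), y = c(0, 5, 28), z = 0)
  mod <- load_model(write_toy_pdb(atoms))
  cls <- lapply(c("A", "B", "C"), function(ch)
    simulate_dye_cloud(mod, label_site(ch, 1, linker_length = 6)))
  dab <- interdye_distance(cls[[1]], cls[[2]])
  dbc <- interdye_distance(cls[[2]], cls[[3]])
  dac <- interdye_distance(cls[[1]], cls[[3]])
  expect_lte(dac, dab + dbc + 1e-9)
})

test_that("point clouds collapse fret-averaged and mean-position modes", {
  pt <- function(x) structure(
    list(positions = matrix(c(x, 0, 0), 1), mean_position = c(x, 0, 0),
         n_samples = 1L, n_allowed = 1L, attachment = c(x, 0, 0),
         site = label_site("A", 1)), class = "dye_cloud")
  d_mean <- interdye_distance(pt(0), pt(55))
  d_fret <- interdye_distance(pt(0), pt(55), mode = "fret-averaged")
  expect_equal(d_fret, d_mean, tolerance = 1e-9)
  expect_equal(d_mean, 5.5)
})

test_that("fret-averaged distances weight close approaches more", {
  # two-position cloud: FRET averaging is dominated by the closer pair
  two <- structure(
    list(positions = matrix(c(0, 0, 0, 120, 0, 0), 2, byrow = TRUE),
         mean_position = c(60, 0, 0), n_samples = 2L, n_allowed = 2L,
         attachment = c(60, 0, 0), site = label_site("A", 1)),
    class = "dye_cloud")
  pt <- structure(
    list(positions = matrix(c(-20, 0, 0), 1), mean_position = c(-20, 0, 0),
         n_samples = 1L, n_allowed = 1L, attachment = c(-20, 0, 0),
         site = label_site("A", 1)), class = "dye_cloud")
  d_fret <- interdye_distance(two, pt, mode = "fret-averaged", n_pairs = 4000)
  d_mean <- interdye_distance(two, pt)  # centroid is 8 nm away
  expect_lt(d_fret, d_mean)
})
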