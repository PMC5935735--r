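# The solver is validated against closed forms: Coulomb and Debye-Hueckel
# potentials in a uniform medium, the Born ion reaction-field energy, and
# point-sampling oracles for the molecular-surface classification.

test_that("grid construction validates inputs and pads generously", {
  expect_error(grid_spec(c(0, 0, 0), spacing = 0, dims = c(9, 9, 9)), "spacing")
  expect_error(grid_spec(c(0, 0, 0), spacing = 0.4, dims = c(4, 9, 9)), "dims")
  ion <- born_ion(1, 2)
  g <- auto_grid(ion, spacing = 0.5)
  ext <- g$origin + g$spacing * (g$dims - 1)
  expect_true(all(g$origin <= -12) && all(ext >= 12))   # r=2 plus >= 10 A pad
})

test_that("solute mask matches a dense point-sampling sphere oracle", {
  ion <- born_ion(1, 2)
  g <- auto_grid(ion, spacing = 0.4)
  maps <- build_maps(ion, g)
  inside <- array(maps$diel$inside, g$dims)
  vol_frac_grid <- mean(inside)
  vol_sphere <- 4 / 3 * pi * 2^3
  vol_grid <- prod(g$spacing * (g$dims - 1))
  expect_equal(vol_frac_grid, vol_sphere / vol_grid, tolerance = 0.12)
  # nodes well inside / outside are classified exactly
  node_at <- function(pt) {
    i <- round((pt - g$origin) / g$spacing) + 1
    inside[i[1], i[2], i[3]]
  }
  expect_true(node_at(c(0, 0, 0)))
  expect_true(node_at(c(1.6, 0, 0)))
  expect_false(node_at(c(4, 0, 0)))
})

test_that("probe-inaccessible neck between two spheres is low-dielectric", {
  # two r=2 spheres 3.5 A apart; a 1.4 A probe cannot reach the midpoint:
  # any probe centre within 1.4 A of it is closer than 3.4 A to a centre
  s2 <- structure_set(data.frame(name = c("A", "B"), resname = "TST",
                                 x = c(-1.75, 1.75), y = 0, z = 0,
                                 charge = 0, radius = 2))
  g <- auto_grid(s2, spacing = 0.4)
  maps <- build_maps(s2, g)
  inside <- array(maps$diel$inside, g$dims)
  node_at <- function(pt) {
    i <- round((pt - g$origin) / g$spacing) + 1
    inside[i[1], i[2], i[3]]
  }
  # brute-force probe-accessibility oracle on a point cloud around the midpoint
  set.seed(42)
  for (pt in list(c(0, 0, 0), c(0, 0.8, 0), c(0, 0, -0.8))) {
    reachable <- FALSE
    for (i in 1:5000) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      q <- pt + 1.4 * runif(1)^(1 / 3) * u
      if (sqrt(sum((q - c(-1.75, 0, 0))^2)) >= 3.4 &&
          sqrt(sum((q - c(1.75, 0, 0))^2)) >= 3.4) { reachable <- TRUE; break }
    }
    expect_false(reachable)          # oracle: solvent cannot reach
    expect_true(node_at(pt))         # solver agrees: solute dielectric
  }
  expect_false(node_at(c(0, 3.4, 0)))  # well out in solvent
})

test_that("empty structure gives uniform solvent maps", {
  g <- grid_spec(c(-4, -4, -4), 1.0, c(9, 9, 9))
  empty <- structure_set(data.frame(name = character(0), resname = character(0),
                                    x = numeric(0), y = numeric(0), z = numeric(0),
                                    charge = numeric(0), radius = numeric(0)))
  maps <- build_maps(empty, g, ionic_strength = 0.15)
  expect_true(all(!maps$diel$inside))
  expect_true(all(maps$diel$eps_x == 80))
  expect_true(all(maps$kappa$kappa2 > 0))
  expect_error(build_maps(empty, g, probe_radius = -1), "probe_radius")
})

test_that("solver reproduces Coulomb and Debye-Hueckel closed forms", {
  g <- grid_spec(c(-16, -16, -16), 0.4, c(81, 81, 81))
  ion <- born_ion(1, 2)
  # zero charges -> potential identically zero
  zf <- solve_lpb(uniform_maps(g, 80)$diel, uniform_maps(g, 80)$kappa,
                  born_ion(0, 2))
  expect_equal(max(abs(zf$values)), 0)
  # Coulomb at 8 A in uniform eps 80
  mu <- uniform_maps(g, eps = 80, ionic_strength = 0)
  f <- solve_lpb(mu$diel, mu$kappa, ion, tol = 1e-6)
  pts <- rbind(c(8, 0, 0), c(0, -8, 0), c(0, 0, 8), c(4.8, 4.8, 4.8))
  v <- potential_at_atoms(f, probe_points(pts))
  r <- sqrt(rowSums(pts^2))
  expect_equal(v, 332.0636 / (80 * r), tolerance = 0.03)
  # Yukawa at 6-10 A with 0.15 M ions everywhere
  mi <- uniform_maps(g, eps = 80, ionic_strength = 0.15)
  fi <- solve_lpb(mi$diel, mi$kappa, ion, tol = 1e-6)
  d <- c(6, 7, 8, 9, 10)
  vi <- potential_at_atoms(fi, probe_points(cbind(d, 0, 0)))
  yuk <- 332.0636 * exp(-mi$kappa$kappa_out * d) / (80 * d)
  expect_equal(vi, yuk, tolerance = 0.03)
})

test_that("solution is linear in the charges (superposition)", {
  g <- grid_spec(c(-12, -12, -12), 0.8, c(31, 31, 31))
  s <- toy_structure(charges = c(0.5, -0.3, 0.8))
  maps <- build_maps(s, g, ionic_strength = 0.1)
  phi_of <- function(charges) {
    sc <- s; sc$atoms$charge <- charges
    solve_lpb(maps$diel, maps$kappa, sc, tol = 1e-8)$values
  }
  q1 <- c(0.5, 0, 0); q2 <- c(0, -0.3, 0.8)
  p1 <- phi_of(q1); p2 <- phi_of(q2); p12 <- phi_of(q1 + q2)
  expect_equal(p12, p1 + p2, tolerance = 1e-5)
  expect_equal(phi_of(2 * q1), 2 * p1, tolerance = 1e-5)
})

test_that("potential interpolation is exact for linear fields", {
  g <- grid_spec(c(0, 0, 0), 0.5, c(9, 9, 9))
  a <- 1.7
  xs <- g$origin[1] + g$spacing * (0:(g$dims[1] - 1))
  vals <- array(rep(a * xs, times = g$dims[2] * g$dims[3]), g$dims)
  field <- structure(list(grid = g, values = vals, iterations = 0, residual = 0),
                     class = "potential_field")
  pts <- rbind(c(1.23, 2.0, 3.1), c(0.5, 0.5, 0.5), c(3.99, 0.01, 2.5))
  expect_equal(potential_at_atoms(field, probe_points(pts)), a * pts[, 1],
               tolerance = 1e-12)
  # constant field reads the constant everywhere; node hits read the node
  fieldc <- structure(list(grid = g, values = array(2.5, g$dims)),
                      class = "potential_field")
  expect_equal(potential_at_atoms(fieldc, probe_points(c(1.1, 2.3, 0.7))), 2.5)
  expect_error(potential_at_atoms(fieldc, probe_points(c(99, 0, 0))), "outside")
})

test_that("Born reaction-field energy matches the closed form and converges", {
  ion <- born_ion(1, 2)
  exact <- born_energy(1, 2, eps_in = 2, eps_out = 80)
  expect_equal(exact, -166.0318 * (1 / 2 - 1 / 80) / 2.0, tolerance = 1e-4)
  errs <- vapply(c(0.8, 0.6, 0.4), function(h) {
    e <- reaction_field_energy(ion, spacing = h, ionic_strength = 0)
    abs(e / exact - 1)
  }, numeric(1))
  expect_lt(errs[3], 0.03)
  expect_true(all(diff(errs) < 0))   # monotone improvement 0.8 -> 0.4
  # charge-sign symmetry and quadratic scaling of the linearized model
  e_m <- reaction_field_energy(born_ion(-1, 2), spacing = 0.8, ionic_strength = 0)
  e_p <- reaction_field_energy(born_ion(1, 2), spacing = 0.8, ionic_strength = 0)
  e_2 <- reaction_field_energy(born_ion(2, 2), spacing = 0.8, ionic_strength = 0)
  expect_equal(e_m, e_p, tolerance = 1e-6)
  expect_equal(e_2, 4 * e_p, tolerance = 1e-4)
  expect_equal(reaction_field_energy(born_ion(0, 2), spacing = 0.8), 0)
})

test_that("reaction-field energy is stable under sub-grid translations", {
  ion <- born_ion(1, 2)
  g <- auto_grid(ion, spacing = 0.4)
  e0 <- reaction_field_energy(ion, grid = g, ionic_strength = 0)
  for (shift in list(c(0.2, 0, 0), c(0.13, 0.2, 0.07))) {
    ion_s <- set_coords(ion, matrix(shift, 1))
    es <- reaction_field_energy(ion_s, grid = g, ionic_strength = 0)
    expect_equal(es, e0, tolerance = 0.01)
  }
})

test_that("far-field screening is monotone in ionic strength", {
  g <- grid_spec(c(-14, -14, -14), 0.4, c(71, 71, 71))
  ion <- born_ion(1, 2)
  v <- vapply(c(0, 0.05, 0.15, 0.3), function(I) {
    mu <- uniform_maps(g, 80, ionic_strength = I)
    f <- solve_lpb(mu$diel, mu$kappa, ion)
    potential_at_atoms(f, probe_points(c(8, 0, 0)))
  }, numeric(1))
  expect_true(all(diff(abs(v)) < 0))
})

test_that("boundary nodes carry the imposed Debye-Hueckel values", {
  g <- grid_spec(c(-10, -10, -10), 1.0, c(21, 21, 21))
  ion <- born_ion(1, 1.5)
  mu <- uniform_maps(g, 80, ionic_strength = 0.15)
  f <- solve_lpb(mu$diel, mu$kappa, ion)
  # a corner boundary node
  r <- sqrt(3 * 10^2)
  expect_equal(f$values[1, 1, 1],
               332.0636 * exp(-mu$kappa$kappa_out * r) / (80 * r),
               tolerance = 1e-10)
})

test_that("atoms outside the grid are rejected", {
  g <- grid_spec(c(-4, -4, -4), 1.0, c(9, 9, 9))
  far <- set_coords(born_ion(1, 1), matrix(c(99, 0, 0), 1))
  expect_error(build_maps(far, g), "outside")
})

test_that("potential grids round-trip through OpenDX text format", {
  g <- grid_spec(c(0, 0, 0), 0.5, c(8, 9, 10))
  vals <- array(rnorm(prod(g$dims)), g$dims)
  f <- structure(list(grid = g, values = vals), class = "potential_field")
  p <- tempfile(fileext = ".dx")
  write_dx(f, p)
  lines <- readLines(p)
  expect_true(any(grepl("gridpositions counts 8 9 10", lines)))
  dat <- grep("data follows", lines)
  nums <- as.numeric(unlist(strsplit(paste(
    lines[(dat + 1):(dat + ceiling(prod(g$dims) / 3))], collapse = " "), "\\s+")))
  nums <- nums[!is.na(nums)]
  # z varies fastest in DX order
  expect_equal(nums[1:10], as.vector(aperm(vals, c(3, 2, 1)))[1:10],
               tolerance = 1e-5)
})
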