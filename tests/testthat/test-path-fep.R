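test_that("the exponential estimator is exact for constant samples", {
  expect_equal(fep_increment(rep(2.5, 50), beta = 1)$delta_a, 2.5)
  expect_equal(fep_increment(rep(0, 50), beta = 1)$delta_a, 0)
  expect_equal(fep_increment(7.3, beta = 2)$delta_a, 7.3)
  expect_error(fep_increment(numeric(0)), "at least one")
  expect_error(fep_increment(c(1, NA)), "non-finite")
  expect_error(fep_increment(1, beta = -1), "beta")
})

test_that("log-domain averaging survives huge perturbation energies", {
  # exp(-beta * -2000) overflows naive averaging; the estimator must not
  x <- c(-2000, -1999, -2001)
  r <- fep_increment(x, beta = 1, blocks = 1L)
  expect_true(is.finite(r$delta_a))
  expect_lt(r$delta_a, -1999)   # dominated by the most negative sample
  big <- fep_increment(c(5000, 5000), beta = 1)$delta_a
  expect_equal(big, 5000)
})

test_that("Gaussian samples reproduce the cumulant closed form", {
  set.seed(101)
  x <- rnorm(1e5, mean = 2, sd = 1)
  r <- fep_increment(x, beta = 1)
  # mu - beta sigma^2 / 2 = 1.5; allow 3 block-averaged standard errors
  expect_lt(abs(r$delta_a - 1.5), 3 * r$std_error)
  expect_lt(r$std_error, 0.05)
})

test_that("Jensen's inequality holds for every sample set", {
  set.seed(77)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    x <- rnorm(n, mean = runif(1, -5, 5), sd = runif(1, 0, 3))
    beta <- runif(1, 0.2, 3)
    expect_lte(fep_increment(x, beta = beta, blocks = 1L)$delta_a, mean(x))
  }
})

test_that("the increment is invariant under sample permutation", {
  set.seed(8)
  x <- rnorm(500, 1, 2)
  a <- fep_increment(x, beta = 1.3, blocks = 1L)$delta_a
  b <- fep_increment(sample(x), beta = 1.3, blocks = 1L)$delta_a
  expect_identical(round(a, 12), round(b, 12))
})

test_that("profiles over a Gaussian bath match the analytic increments", {
  # environment configuration: a scalar s ~ N(0,1); coupling c_i * s.
  # Each increment is exactly -beta (c_{i+1} - c_i)^2 / 2.
  cs <- c(0, 0.4, 0.7, 0.9, 1.3)
  p <- init_path(0, 1, length(cs))
  beta <- 1
  sampler <- function(i, n) { set.seed(1000 + i); as.list(rnorm(n)) }
  couple <- function(img, s) cs[round(img * (length(cs) - 1)) + 1] * s
  pr <- fep_profile(p, sampler, couple, beta = beta, n_samples = 3e4)
  exact_inc <- -beta * diff(cs)^2 / 2
  for (k in seq_along(exact_inc)) {
    expect_lt(abs(pr$increments[k] - exact_inc[k]),
              3 * max(pr$std_errors[k], 1e-4))
  }
  expect_equal(pr$cumulative, c(0, cumsum(pr$increments)), tolerance = 1e-12)
  expect_equal(pr$cumulative[1], 0)
  # identical adjacent images -> all increments zero
  pid <- init_path(c(0.5), c(0.5), 4)
  pr0 <- fep_profile(pid, sampler, couple, beta = beta, n_samples = 100)
  expect_equal(pr0$increments, rep(0, 3))
})

test_that("reversing the path negates the profile on a consistent bath", {
  # Boltzmann-consistent bath: state-i configurations are drawn from the
  # coupled Hamiltonian c_i s + s^2/2, i.e. s ~ N(-beta c_i, 1). The exact
  # free energies are A_i = -beta c_i^2 / 2, a state function, so the
  # end-to-end estimate negates under path reversal and telescopes.
  cs <- c(0, 0.5, 1.0)
  beta <- 1
  pf <- init_path(0, 1, 3)
  pb <- init_path(1, 0, 3)
  cidx_f <- function(img) round(img * 2) + 1
  sampler_f <- function(i, n) { set.seed(2000 + i); as.list(rnorm(n, -beta * cs[i + 1])) }
  sampler_b <- function(i, n) { set.seed(2100 + i); as.list(rnorm(n, -beta * rev(cs)[i + 1])) }
  cf <- function(img, s) cs[cidx_f(img)] * s
  cb <- cf      # the coupling is a function of the image coordinate
  prf <- fep_profile(pf, sampler_f, cf, beta = beta, n_samples = 3e4)
  prb <- fep_profile(pb, sampler_b, cb, beta = beta, n_samples = 3e4)
  exact_end <- -beta * (cs[3]^2 - cs[1]^2) / 2
  se <- sqrt(sum(prf$std_errors^2) + sum(prb$std_errors^2))
  expect_lt(abs(prf$cumulative[3] - exact_end), 3 * se)
  expect_lt(abs(prb$cumulative[3] + exact_end), 3 * se)
  expect_lt(abs(prf$cumulative[3] + prb$cumulative[3]), 3 * se)
  # telescoping: the single-jump estimate agrees with the summed increments
  pr_big <- fep_profile(init_path(0, 1, 2), sampler_f, cf, beta = beta,
                        n_samples = 3e4)
  se_big <- sqrt(pr_big$std_errors[1]^2 + sum(prf$std_errors^2))
  expect_lt(abs(pr_big$cumulative[2] - prf$cumulative[3]), 3 * se_big)
})

test_that("a monotone ramp yields a barrier-less monotone profile", {
  # couplings rising linearly: every increment is negative-definite drift
  # plus a deterministic mean shift; with a mean term the profile rises
  cs <- seq(0, 1, length.out = 8)
  mus <- seq(0, 3.5, length.out = 8)    # deterministic offset per image
  p <- init_path(0, 1, 8)
  sampler <- function(i, n) { set.seed(3000 + i); as.list(rnorm(n)) }
  couple <- function(img, s) {
    i <- round(img * 7) + 1
    mus[i] + cs[i] * s
  }
  pr <- fep_profile(p, sampler, couple, beta = 1, n_samples = 2e4)
  expect_true(all(diff(pr$cumulative) > 0))
  expect_equal(max(pr$cumulative), pr$cumulative[8])   # no interior maximum
})

test_that("vibrational free energy matches the single-mode closed form", {
  # k = 1 kcal/mol/A^2, m = 1 amu; independent oracle from SI constants
  h <- 6.62607015e-34; NA_ <- 6.02214076e23; amu <- 1.66053907e-27
  kB <- 1.380649e-23; c_cm <- 2.99792458e10
  w <- sqrt(1 * 4184 / NA_ / 1e-20 / amu)            # rad/s
  nu_cm <- w / (2 * pi * c_cm)
  zpe <- 0.5 * h * (w / (2 * pi)) * NA_ / 4184
  Tk <- 300
  g_exact <- zpe + (kB * Tk * NA_ / 4184) * log(1 - exp(-h * (w / (2 * pi)) / (kB * Tk)))
  r <- rrho_vibrational_free_energy(matrix(1), masses = 1,
                                    thermo = thermo_config(Tk))
  expect_equal(r$frequencies, nu_cm, tolerance = 1e-4)
  expect_equal(r$zero_point, zpe, tolerance = 1e-4)
  expect_equal(r$g_vib, g_exact, tolerance = 1e-3)
  expect_equal(r$n_imaginary, 0L)
})

test_that("vibrational free energy approaches the zero-point limit as T -> 0", {
  H <- diag(c(2, 5, 9))
  r300 <- rrho_vibrational_free_energy(H, masses = c(1, 2, 3),
                                       thermo = thermo_config(300))
  r1 <- rrho_vibrational_free_energy(H, masses = c(1, 2, 3),
                                     thermo = thermo_config(1e-3))
  expect_equal(r1$g_vib, r1$zero_point, tolerance = 1e-10)
  expect_lt(r300$g_vib, r300$zero_point)  # thermal term only lowers it
})

test_that("imaginary modes are counted and excluded", {
  H <- diag(c(4, -1, 3))
  r <- rrho_vibrational_free_energy(H, masses = c(1, 1, 1))
  expect_equal(r$n_imaginary, 1L)
  expect_length(r$frequencies, 2L)
  expect_true(all(r$frequencies > 0))
  expect_error(rrho_vibrational_free_energy(matrix(c(1, 2, 3, 4), 2), c(1, 1)),
               "symmetric")
  expect_error(rrho_vibrational_free_energy(diag(2), c(1, -1)), "masses")
})

test_that("mass weighting: heavier atoms vibrate slower", {
  light <- rrho_vibrational_free_energy(matrix(1), masses = 1)
  heavy <- rrho_vibrational_free_energy(matrix(1), masses = 16)
  expect_equal(heavy$frequencies, light$frequencies / 4, tolerance = 1e-10)
})
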