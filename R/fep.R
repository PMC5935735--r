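# Free-energy perturbation along a fixed reaction path: the one-sided
# exponential (Zwanzig) estimator between adjacent images,
#   dA(i -> i+1) = -(1/beta) ln < exp(-beta dE_pert) >_i ,
# where dE_pert is the energy of swapping in the next image's frozen
# "reactive region" coordinates while keeping the environment configuration
# sampled in state i. Plus the rigid-rotor/harmonic-oscillator vibrational
# free energy of the frozen region from normal-mode analysis.

#' One-sided free-energy perturbation increment
#'
#' Zwanzig exponential averaging computed in the log domain (shift by the
#' maximum of `-beta * dE`), so arbitrarily large perturbation energies never
#' overflow. The standard error is by 5-block averaging of the per-block
#' estimates.
#'
#' @param samples perturbation energies `dE` (kcal/mol) evaluated on the
#'   state-i ensemble.
#' @param beta inverse temperature, 1/(kcal/mol) (default 300 K).
#' @param blocks number of blocks for the uncertainty (default 5).
#' @return list with `delta_a` (kcal/mol) and `std_error`.
#' @examples
#' fep_increment(rep(2.5, 10), beta = 1)$delta_a # exactly 2.5
#' @export
fep_increment <- function(samples, beta = thermo_config()$beta, blocks = 5L) {
  samples <- as.numeric(samples)
  if (!length(samples)) stop("need at least one sample")
  if (!all(is.finite(samples))) stop("non-finite perturbation energy")
  if (!is.finite(beta) || beta <= 0) stop("beta must be positive")
  zw <- function(x) {
    a <- -beta * x
    m <- max(a)
    -(m + log(mean(exp(a - m)))) / beta
  }
  se <- NA_real_
  n <- length(samples)
  if (n >= blocks && blocks >= 2L) {
    idx <- cut(seq_len(n), blocks, labels = FALSE)
    bvals <- vapply(split(samples, idx), zw, numeric(1))
    se <- sd(bvals) / sqrt(length(bvals))
  }
  list(delta_a = zw(samples), std_error = se)
}

#' Free-energy profile along a path by per-image perturbation
#'
#' For each adjacent image pair (i, i+1), draws environment configurations
#' from the state-i sampler, evaluates the perturbation energy
#' `coupled_energy(image i+1, config) - coupled_energy(image i, config)`,
#' and accumulates the one-sided increments into a cumulative profile
#' referenced to the first image. The images themselves are frozen; only
#' the environment is sampled, mirroring a reaction path whose reactive
#' region is constrained to its optimized geometries.
#'
#' @param path a `path_chain` (its images are the frozen coordinates).
#' @param ensemble_source function(image_index, n) returning a list (or
#'   vector) of `n` environment configurations for that image's ensemble;
#'   `image_index` is 0-based.
#' @param coupled_energy function(image_coords, config) -> energy (kcal/mol).
#' @param beta inverse temperature, 1/(kcal/mol).
#' @param n_samples configurations per image ensemble (default 1000).
#' @return object of class `free_energy_profile`: `increments`,
#'   `cumulative` (length n_images, starting at 0), `std_errors`.
#' @export
fep_profile <- function(path, ensemble_source, coupled_energy,
                        beta = thermo_config()$beta, n_samples = 1000L) {
  stopifnot(inherits(path, "path_chain"), is.function(ensemble_source),
            is.function(coupled_energy))
  n <- path$n_images
  increments <- numeric(n - 1L)
  std_errors <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    cfgs <- ensemble_source(i - 1L, n_samples)
    if (!is.list(cfgs)) cfgs <- as.list(cfgs)
    if (length(cfgs) < 1L) stop("sampler returned no configurations for image ", i - 1L)
    xi <- path$images[i, ]; xj <- path$images[i + 1L, ]
    dE <- vapply(cfgs, function(cf) coupled_energy(xj, cf) - coupled_energy(xi, cf),
                 numeric(1))
    if (!all(is.finite(dE))) {
      stop("non-finite perturbation energy at image ", i - 1L)
    }
    inc <- fep_increment(dE, beta = beta)
    increments[i] <- inc$delta_a
    std_errors[i] <- inc$std_error
  }
  structure(list(increments = increments,
                 cumulative = c(0, cumsum(increments)),
                 std_errors = std_errors),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf("free_energy_profile: %d increments, end-to-end dA = %.4g kcal/mol\n",
              length(x$increments), x$cumulative[length(x$cumulative)]))
  invisible(x)
}

#' Profile as a data frame
#' @param profile a `free_energy_profile`.
#' @return data.frame with image, increment, cumulative, std_error columns.
#' @export
profile_table <- function(profile) {
  n <- length(profile$cumulative)
  data.frame(image = 0:(n - 1L),
             increment = c(NA, profile$increments),
             cumulative = profile$cumulative,
             std_error = c(NA, profile$std_errors))
}

# Unit-conversion constants for normal-mode analysis with Hessians in
# kcal/mol/A^2 and masses in amu:
#   omega[cm^-1] = WAVENUMBER_PER_SQRT * sqrt(lambda)
#   1 cm^-1      = KCAL_PER_WAVENUMBER kcal/mol of photon energy
#   h c / k_B    = HC_OVER_KB cm K
WAVENUMBER_PER_SQRT <- 108.593
KCAL_PER_WAVENUMBER <- 2.85914e-3
HC_OVER_KB <- 1.438777

#' Rigid-rotor/harmonic-oscillator vibrational free energy
#'
#' Mass-weighted normal-mode analysis of a Hessian (kcal/mol/Angstrom^2,
#' masses in amu). Positive eigenvalues become harmonic frequencies; the
#' vibrational free energy is `sum_k [h w_k / 2 + k_B T ln(1 - exp(-h w_k /
#' k_B T))]` in kcal/mol. Negative-curvature (imaginary) modes are counted
#' and excluded from the sums, as are near-zero modes (translations and
#' rotations of a free fragment).
#'
#' @param hessian symmetric matrix, kcal/mol/Angstrom^2; dimension must be a
#'   multiple of the mass vector length times 3, or equal to its length for
#'   reduced-dimensional models.
#' @param masses per-coordinate or per-atom masses, amu.
#' @param thermo a [thermo_config()].
#' @param zero_tol eigenvalues with |lambda| below this are treated as
#'   rigid-body modes and dropped (default 1e-8).
#' @return object of class `rrho_result`: `frequencies` (cm^-1),
#'   `zero_point` (kcal/mol), `g_vib` (kcal/mol), `n_imaginary`.
#' @examples
#' rrho_vibrational_free_energy(matrix(1), masses = 1)
#' @export
rrho_vibrational_free_energy <- function(hessian, masses,
                                         thermo = thermo_config(),
                                         zero_tol = 1e-8) {
  hessian <- as.matrix(hessian)
  if (nrow(hessian) != ncol(hessian)) stop("hessian must be square")
  if (max(abs(hessian - t(hessian))) > 1e-8 * max(1, max(abs(hessian)))) {
    stop("hessian is not symmetric")
  }
  masses <- as.numeric(masses)
  if (any(masses <= 0)) stop("masses must be positive")
  d <- nrow(hessian)
  mcoord <- if (length(masses) == d) masses
            else if (3L * length(masses) == d) rep(masses, each = 3L)
            else stop("mass vector length must equal the Hessian dimension or dim/3")
  invsqrt <- 1 / sqrt(mcoord)
  mw <- hessian * tcrossprod(invsqrt)
  lambda <- eigen((mw + t(mw)) / 2, symmetric = TRUE, only.values = TRUE)$values
  n_imag <- sum(lambda < -zero_tol)
  lam_pos <- lambda[lambda > zero_tol]
  freqs <- sort(WAVENUMBER_PER_SQRT * sqrt(lam_pos))
  zpe <- sum(0.5 * freqs * KCAL_PER_WAVENUMBER)
  kT <- thermo$R * thermo$T
  g_vib <- zpe + sum(kT * log(1 - exp(-HC_OVER_KB * freqs / thermo$T)))
  structure(list(frequencies = freqs, zero_point = zpe, g_vib = g_vib,
                 n_imaginary = n_imag),
            class = "rrho_result")
}

#' @export
print.rrho_result <- function(x, ...) {
  cat(sprintf("rrho_result: %d modes (%d imaginary), ZPE %.4g kcal/mol, G_vib %.4g kcal/mol\n",
              length(x$frequencies), x$n_imaginary, x$zero_point, x$g_vib))
  invisible(x)
}
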