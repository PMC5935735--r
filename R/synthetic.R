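# Synthetic fixtures with known exact answers: Born ions for the
# electrostatics solver, toy titratable sites for the protonation-state
# workflow, and Gaussian linear-response ensembles for which the
# two-ensemble free-energy estimator is exact. All generators are pure
# functions of their arguments and seed.

#' Born ion: a single charged sphere at the origin
#'
#' The canonical continuum-electrostatics benchmark. Its reaction-field
#' energy has the closed form `-C q^2 (1/eps_in - 1/eps_out) / (2 a)` with
#' C = 332.0636 kcal Angstrom/(mol e^2).
#'
#' @param q charge, e.
#' @param radius sphere radius, Angstrom (> 0).
#' @return a one-atom [structure_set()].
#' @export
born_ion <- function(q = 1, radius = 2) {
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  structure_set(data.frame(name = "ION", resname = "ION",
                           x = 0, y = 0, z = 0, charge = q, radius = radius),
                title = sprintf("Born ion q=%g r=%g", q, radius))
}

#' Closed-form Born solvation energy
#' @param q charge, e.
#' @param radius sphere radius, Angstrom.
#' @param eps_in,eps_out dielectric constants of the two media.
#' @return kcal/mol.
#' @export
born_energy <- function(q, radius, eps_in = 2, eps_out = 80) {
  -KCOUL * q^2 * (1 / eps_in - 1 / eps_out) / (2 * radius)
}

#' Toy active site with two titratable groups
#'
#' A small (<= 30 atom) synthetic active site mimicking a serine-ester
#' adduct flanked by an amino group and a tyrosine-like hydroxyl — the
#' minimal system in which two coupled protonatable groups give four
#' protonation states. The template charges are the doubly-deprotonated
#' state with net charge 0, so the 2 x 2 state enumeration yields net
#' charges {0, +1, +1, +2}. Geometry and charge noise are deterministic per
#' seed.
#'
#' @param seed integer RNG seed.
#' @return list with `structure` (a [structure_set()]), `site_amino` and
#'   `site_hydroxyl` (two disjoint [titratable_site()]s, each with
#'   `sum(delta_q) = +1`).
#' @export
toy_titratable_site <- function(seed = 1) {
  with_seed(seed, {
    # ester core (6), amino group (4), hydroxyl group (2), scaffold (6)
    base <- rbind(
      c(0.0, 0.0, 0.0), c(1.4, 0.3, 0.0), c(2.1, -0.8, 0.2),   # C-C=O ester
      c(2.0, 1.5, -0.3), c(-0.8, 1.2, 0.4), c(-1.1, -1.2, -0.2),
      c(3.5, 1.8, 0.5), c(4.3, 1.0, 1.1), c(4.0, 2.9, 0.0),    # amino N + 2H + C
      c(2.9, 2.6, 1.2),
      c(-2.5, 2.0, 1.5), c(-3.2, 2.8, 2.1),                    # hydroxyl O + H
      c(-2.0, 3.5, -0.5), c(-3.6, 0.8, 0.8), c(0.5, 3.0, 2.0),
      c(1.8, -2.2, -1.0), c(-0.5, -2.8, 1.2), c(3.0, 0.2, -1.8)
    )
    n <- nrow(base)
    xyz <- base + matrix(rnorm(3 * n, sd = 0.05), n, 3)
    charge <- round(rnorm(n, 0, 0.15), 4)
    charge[1] <- charge[1] - sum(charge)          # template net charge 0
    radius <- round(runif(n, 1.2, 2.0), 3)
    s <- structure_set(data.frame(
      name = sprintf("A%02d", seq_len(n) - 1L),
      resname = c(rep("EST", 6), rep("AMN", 4), rep("HYD", 2), rep("SCF", 6)),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      charge = charge, radius = radius), title = "toy titratable active site")
    # protonated-minus-deprotonated charge differences, each summing to +1
    site_amino <- titratable_site("amino", 6:9, c(0.33, 0.25, 0.25, 0.17),
                                  model_pka = 8.0)
    site_hydroxyl <- titratable_site("hydroxyl", 10:11, c(0.45, 0.55),
                                     model_pka = 10.1)
    list(structure = s, site_amino = site_amino, site_hydroxyl = site_hydroxyl)
  })
}

#' Specification of a Gaussian linear-response system
#'
#' Defines per-atom mean potentials for the two endpoint ensembles, a common
#' standard deviation, and the charge perturbation. Because the potential
#' fluctuations are Gaussian with equal variance in both states, the
#' two-ensemble average `sum dq (v_A + v_B)/2` equals the exact free energy
#' of the charge change; `exact_dG` is recorded on the spec.
#'
#' @param v_A,v_B per-atom mean potentials in states A and B, kcal/(mol e).
#' @param sigma common per-atom potential standard deviation (>= 0).
#' @param delta_q per-atom charge perturbation, e.
#' @return object of class `linear_response_spec` with field `exact_dG`.
#' @export
linear_response_spec <- function(v_A, v_B, sigma, delta_q) {
  v_A <- as.numeric(v_A); v_B <- as.numeric(v_B); delta_q <- as.numeric(delta_q)
  if (length(v_A) != length(v_B) || length(v_A) != length(delta_q)) {
    stop("v_A, v_B and delta_q must have equal length")
  }
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  structure(list(v_A = v_A, v_B = v_B, sigma = sigma, delta_q = delta_q,
                 exact_dG = sum(delta_q * (v_A + v_B) / 2)),
            class = "linear_response_spec")
}

#' Sample a linear-response potential ensemble
#'
#' Draws `n` independent snapshots per state with per-atom potentials
#' `Normal(v_A, sigma)` (state A) and `Normal(v_B, sigma)` (state B), and
#' returns the sample-mean `ensemble_potentials` together with the spec's
#' exact free energy. Deterministic per seed.
#'
#' @param spec a [linear_response_spec()].
#' @param n snapshots per state (>= 1).
#' @param seed RNG seed.
#' @return list: `pots` (an [ensemble_potentials()] with per-snapshot
#'   samples attached), `exact_dG`, `seed`.
#' @export
make_linear_response_ensemble <- function(spec, n, seed = 1) {
  stopifnot(inherits(spec, "linear_response_spec"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  k <- length(spec$v_A)
  with_seed(seed, {
    VA <- matrix(rnorm(n * k, mean = rep(spec$v_A, each = n), sd = spec$sigma), n, k)
    VB <- matrix(rnorm(n * k, mean = rep(spec$v_B, each = n), sd = spec$sigma), n, k)
    pots <- ensemble_potentials("linear-response", colMeans(VA), colMeans(VB),
                                n_A = n, n_B = n)
    pots$samples_A <- VA
    pots$samples_B <- VB
    list(pots = pots, exact_dG = spec$exact_dG, seed = seed)
  })
}
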