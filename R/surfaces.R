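# Pluggable analytic energy surfaces: the contract object consumed by the
# chain-of-states optimizer, plus numeric derivative checks used to validate
# every packaged surface.

#' Define an energy surface
#'
#' An `energy_surface` couples an energy function and its analytic gradient
#' on an n-dimensional coordinate space. Packaged surfaces are required to
#' pass [check_gradient()] (analytic vs central finite differences).
#'
#' @param dimension coordinate dimension.
#' @param energy function(x) -> scalar.
#' @param gradient function(x) -> numeric vector of length `dimension`.
#' @param label short name.
#' @return object of class `energy_surface`.
#' @export
energy_surface <- function(dimension, energy, gradient, label = "surface") {
  stopifnot(is.function(energy), is.function(gradient), dimension >= 1)
  structure(list(dimension = as.integer(dimension), energy = energy,
                 gradient = gradient, label = label),
            class = "energy_surface")
}

#' Compare analytic and finite-difference gradients
#'
#' Central differences with step `h` at each supplied point; returns the
#' worst relative deviation, where the scale is the larger of the two
#' gradient norms (floored at 1 to avoid 0/0 at stationary points).
#'
#' @param surface an [energy_surface()].
#' @param points matrix of test points (rows) or a single vector.
#' @param h finite-difference step.
#' @return max relative error across points.
#' @export
check_gradient <- function(surface, points, h = 1e-5) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  worst <- 0
  for (r in seq_len(nrow(points))) {
    x <- points[r, ]
    ga <- surface$gradient(x)
    gn <- vapply(seq_along(x), function(d) {
      e <- numeric(length(x)); e[d] <- h
      (surface$energy(x + e) - surface$energy(x - e)) / (2 * h)
    }, numeric(1))
    scale <- max(sqrt(sum(ga^2)), sqrt(sum(gn^2)), 1)
    worst <- max(worst, sqrt(sum((ga - gn)^2)) / scale)
  }
  worst
}

#' The Mueller-Brown benchmark surface
#'
#' The standard four-term exponential two-dimensional test surface for
#' transition-state search algorithms, with analytic gradient. Its two
#' deepest minima lie near (-0.558, 1.442) and (0.623, 0.028); the highest
#' saddle on the minimum-energy path connecting them is near
#' (-0.822, 0.624) at energy about -40.67.
#'
#' @return an [energy_surface()] of dimension 2.
#' @export
muller_brown <- function() {
  A <- c(-200, -100, -170, 15)
  a <- c(-1, -1, -6.5, 0.7)
  b <- c(0, 0, 11, 0.6)
  cc <- c(-10, -10, -6.5, 0.7)
  x0 <- c(1, 0, -0.5, -1)
  y0 <- c(0, 0.5, 1.5, 1)
  energy <- function(x) {
    dx <- x[1] - x0; dy <- x[2] - y0
    sum(A * exp(a * dx^2 + b * dx * dy + cc * dy^2))
  }
  gradient <- function(x) {
    dx <- x[1] - x0; dy <- x[2] - y0
    e <- A * exp(a * dx^2 + b * dx * dy + cc * dy^2)
    c(sum(e * (2 * a * dx + b * dy)), sum(e * (b * dx + 2 * cc * dy)))
  }
  energy_surface(2, energy, gradient, "muller-brown")
}

#' One-dimensional quartic double well
#'
#' `E(x) = scale * (x^2 - 1)^2`: minima at x = -1 and x = +1 (E = 0), one
#' saddle at x = 0 with barrier `scale`.
#'
#' @param scale barrier height (default 1).
#' @return an [energy_surface()] of dimension 1.
#' @export
double_well_1d <- function(scale = 1) {
  energy_surface(1,
    function(x) scale * (x[1]^2 - 1)^2,
    function(x) 4 * scale * x[1] * (x[1]^2 - 1),
    "quartic double well")
}

#' Paired direct and relay proton-transfer model surfaces
#'
#' Two 2-D surfaces modelling the competition between a direct proton
#' transfer and a relay-assisted transfer. The transfer coordinate is x,
#' the relay coordinate y. Both surfaces share the reactant minimum at
#' (-1, 0) and the product minimum at (+1, 0), both at zero energy, so their
#' reaction energies are identical; they differ only in the channel the
#' path can take:
#' \describe{
#'   \item{direct}{`E = D (1-x^2)^2 + k y^2` — the only channel runs over
#'     the full barrier `D` at (0, 0).}
#'   \item{relay}{`E = (1-x^2)^2 * [D - (D - Rb) exp(-(y - y_relay)^2 /
#'     (2 w^2))] + k y^2` — engaging the relay coordinate (y near
#'     `y_relay`) lowers the ridge to about `Rb + k y_relay^2`, a much
#'     cheaper crossing.}
#' }
#' `D = direct_barrier_scale` must exceed `Rb = relay_barrier_scale`; the
#' direct channel's barrier is strictly higher by construction, mirroring a
#' high-barrier self-assisted mechanism losing to a low-barrier relay
#' mechanism.
#'
#' @param direct_barrier_scale barrier of the direct channel (default 5).
#' @param relay_barrier_scale residual ridge height in the relay channel
#'   (default 1); must be smaller than `direct_barrier_scale`.
#' @param k confinement of the relay coordinate (default 0.5).
#' @param y_relay location of the relay channel (default 1).
#' @param w width of the relay channel (default 0.35).
#' @return list with `energy_surface` elements `direct` and `relay`.
#' @export
proton_transfer_surfaces <- function(direct_barrier_scale = 5,
                                     relay_barrier_scale = 1,
                                     k = 0.5, y_relay = 1, w = 0.35) {
  D <- direct_barrier_scale; Rb <- relay_barrier_scale
  if (!(D > 0 && Rb > 0)) stop("barrier scales must be positive")
  if (!(D > Rb)) stop("direct_barrier_scale must exceed relay_barrier_scale")
  direct <- energy_surface(2,
    function(x) D * (1 - x[1]^2)^2 + k * x[2]^2,
    function(x) c(-4 * D * x[1] * (1 - x[1]^2), 2 * k * x[2]),
    "direct proton transfer")
  B <- function(y) D - (D - Rb) * exp(-(y - y_relay)^2 / (2 * w^2))
  Bp <- function(y) (D - Rb) * ((y - y_relay) / w^2) * exp(-(y - y_relay)^2 / (2 * w^2))
  relay <- energy_surface(2,
    function(x) (1 - x[1]^2)^2 * B(x[2]) + k * x[2]^2,
    function(x) c(-4 * x[1] * (1 - x[1]^2) * B(x[2]),
                  (1 - x[1]^2)^2 * Bp(x[2]) + 2 * k * x[2]),
    "relay proton transfer")
  list(direct = direct, relay = relay,
       endpoints = list(reactant = c(-1, 0), product = c(1, 0)))
}

#' Brute-force minimax saddle energy on a dense grid
#'
#' Dense-grid oracle for the saddle energy between two basins of a 2-D
#' surface: evaluates the energy on an `n x n` grid over the given window
#' and finds, by a union-find sweep in order of increasing energy, the
#' lowest level at which the grid cells containing `a` and `b` become
#' 4-connected. That level is the energy of the highest saddle on the
#' optimal path, up to grid resolution. Independent of any chain-of-states
#' machinery; used to validate the path optimizer.
#'
#' @param surface an [energy_surface()] of dimension 2.
#' @param a,b 2-vectors, points in the two basins (e.g. the minima).
#' @param xlim,ylim evaluation window.
#' @param n grid resolution per axis (default 2000).
#' @return the minimax connection energy.
#' @export
grid_minimax_saddle <- function(surface, a, b, xlim, ylim, n = 2000) {
  stopifnot(surface$dimension == 2)
  xs <- seq(xlim[1], xlim[2], length.out = n)
  ys <- seq(ylim[1], ylim[2], length.out = n)
  E <- matrix(0, n, n)
  for (j in seq_len(n)) {
    E[, j] <- vapply(xs, function(x) surface$energy(c(x, ys[j])), numeric(1))
  }
  ij <- function(p) c(which.min(abs(xs - p[1])) - 1L, which.min(abs(ys - p[2])) - 1L)
  pa <- ij(a); pb <- ij(b)
  cpp_grid_minimax(E, pa[1], pa[2], pb[1], pb[2])
}
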