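# Chain-of-states minimum-energy-path machinery: a nudged-elastic-band force
# projection (improved upwind tangents) alternated with equal-arc-length
# string reparameterization, driven by the FIRE optimizer, plus
# climbing-image refinement of the highest image to the saddle point.

#' Initialize a chain of images between two endpoints
#'
#' Linear interpolation with equal parameter spacing; the endpoints are
#' stored exactly and stay fixed through all subsequent optimization.
#'
#' @param start,end coordinate vectors of equal dimension.
#' @param n_images number of images including the endpoints (default 20).
#' @return object of class `path_chain` with fields `images`
#'   (n_images x dimension matrix), `energies` (NA until evaluated),
#'   `n_images`, `dimension`.
#' @examples
#' init_path(c(0, 0), c(1, 1), n_images = 3)$images
#' @export
init_path <- function(start, end, n_images = 20) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != length(end)) stop("start and end must have the same dimension")
  n_images <- as.integer(n_images)
  if (n_images < 2L) stop("need at least 2 images")
  tfrac <- seq(0, 1, length.out = n_images)
  images <- outer(tfrac, end - start) + matrix(start, n_images, length(start), byrow = TRUE)
  images[1, ] <- start; images[n_images, ] <- end
  structure(list(images = images, energies = rep(NA_real_, n_images),
                 n_images = n_images, dimension = length(start)),
            class = "path_chain")
}

#' @export
print.path_chain <- function(x, ...) {
  cat(sprintf("path_chain: %d images, dimension %d%s\n", x$n_images, x$dimension,
              if (all(is.finite(x$energies)))
                sprintf(", barrier %.4g", max(x$energies) - x$energies[1]) else ""))
  invisible(x)
}

#' Evaluate surface energies for every image of a path
#' @param surface an [energy_surface()].
#' @param path a `path_chain`.
#' @return the path with `energies` populated.
#' @export
path_energies <- function(surface, path) {
  path$energies <- apply(path$images, 1, surface$energy)
  if (!all(is.finite(path$energies))) {
    stop("non-finite energy at image ", which(!is.finite(path$energies))[1] - 1L)
  }
  path
}

# Improved (energy-weighted upwind) tangents at the interior images;
# returns an (n-2) x dim matrix of unit tangents.
neb_tangents <- function(images, energies) {
  n <- nrow(images)
  tau <- matrix(0, n - 2L, ncol(images))
  for (i in 2:(n - 1L)) {
    dp <- images[i + 1L, ] - images[i, ]
    dm <- images[i, ] - images[i - 1L, ]
    Em <- energies[i - 1L]; E0 <- energies[i]; Ep <- energies[i + 1L]
    if (Ep > E0 && E0 > Em) {
      t <- dp
    } else if (Ep < E0 && E0 < Em) {
      t <- dm
    } else {
      dEmax <- max(abs(Ep - E0), abs(Em - E0))
      dEmin <- min(abs(Ep - E0), abs(Em - E0))
      t <- if (Ep > Em) dEmax * dp + dEmin * dm else dEmin * dp + dEmax * dm
      if (sqrt(sum(t^2)) < 1e-14) t <- dp + dm
    }
    nt <- sqrt(sum(t^2))
    tau[i - 1L, ] <- if (nt > 0) t / nt else t
  }
  tau
}

# Redistribute images to equal arc length along the current polyline
# (string-method reparameterization); endpoints untouched.
reparam_equal_arclength <- function(images) {
  n <- nrow(images)
  seg <- sqrt(rowSums((images[-1, , drop = FALSE] - images[-n, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  if (s[n] <= 0) return(images)                 # degenerate path (start == end)
  starget <- seq(0, s[n], length.out = n)
  out <- images
  for (d in seq_len(ncol(images))) {
    out[2:(n - 1L), d] <- approx(s, images[, d], xout = starget[2:(n - 1L)],
                                 ties = "ordered")$y
  }
  out[1, ] <- images[1, ]; out[n, ] <- images[n, ]
  out
}

# One FIRE velocity/step update. `state` carries v, dt, alpha, n_pos.
fire_step <- function(state, force, max_step) {
  p <- sum(force * state$v)
  if (p > 0) {
    state$n_pos <- state$n_pos + 1L
    if (state$n_pos > 5L) {
      state$dt <- min(state$dt * 1.1, state$dt_max)
      state$alpha <- state$alpha * 0.99
    }
    fn <- sqrt(sum(force^2)); vn <- sqrt(sum(state$v^2))
    if (fn > 0) state$v <- (1 - state$alpha) * state$v + state$alpha * vn * force / fn
  } else {
    state$v <- force * 0
    state$dt <- state$dt * 0.5
    state$alpha <- 0.1
    state$n_pos <- 0L
  }
  state$v <- state$v + state$dt * force
  dx <- state$dt * state$v
  nrm <- sqrt(sum(dx^2))
  if (nrm > max_step) dx <- dx * (max_step / nrm)
  state$dx <- dx
  state
}

fire_state <- function(shape, dt = 3e-3, dt_max = 3e-2) {
  list(v = array(0, dim = shape), dt = dt, dt_max = dt_max, alpha = 0.1,
       n_pos = 0L, dx = NULL)
}

#' Optimize a chain of states to the minimum-energy path
#'
#' Relaxes the interior images under the nudged-elastic-band force — the true
#' force with its component along the (energy-weighted upwind) tangent
#' removed, plus a spring force along the tangent — using the FIRE
#' optimizer, and re-distributes the images to equal arc length every
#' `reparam_every` iterations (string step). Endpoints never move.
#' Convergence is declared when the RMS perpendicular true force over the
#' interior images falls below `force_tol`.
#'
#' @param surface an [energy_surface()] matching the path dimension.
#' @param path a `path_chain` from [init_path()].
#' @param spring_k spring constant between adjacent images (default 1).
#' @param force_tol RMS perpendicular-force tolerance (default 1e-4).
#' @param max_iter iteration cap (default 20000).
#' @param reparam_every string reparameterization interval (default 10).
#' @param max_step per-image displacement cap per iteration (default 0.1).
#' @return the optimized `path_chain` with `energies` populated and
#'   attributes `converged`, `iterations`, `rms_perp_force`.
#' @export
optimize_path <- function(surface, path, spring_k = 1.0, force_tol = 1e-4,
                          max_iter = 20000L, reparam_every = 10L,
                          max_step = 0.1) {
  stopifnot(inherits(path, "path_chain"))
  if (surface$dimension != path$dimension) stop("surface and path dimension differ")
  n <- path$n_images
  if (n == 2L) {                                   # nothing to optimize
    path <- path_energies(surface, path)
    attr(path, "converged") <- TRUE
    attr(path, "iterations") <- 0L
    attr(path, "rms_perp_force") <- 0
    return(path)
  }
  x <- path$images
  x0 <- x[1, ]; x1 <- x[n, ]
  fs <- fire_state(dim(x[2:(n - 1L), , drop = FALSE]))
  rms_perp <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    E <- apply(x, 1, surface$energy)
    if (!all(is.finite(E))) stop("non-finite energy at image ", which(!is.finite(E))[1] - 1L)
    G <- t(apply(x, 1, surface$gradient))
    if (path$dimension == 1L) G <- matrix(G, ncol = 1L)
    if (!all(is.finite(G))) stop("non-finite gradient encountered")
    tau <- neb_tangents(x, E)
    gi <- G[2:(n - 1L), , drop = FALSE]
    gpar <- rowSums(gi * tau)
    g_perp <- gi - tau * gpar
    seg <- sqrt(rowSums((x[-1, , drop = FALSE] - x[-n, , drop = FALSE])^2))
    fspring <- spring_k * (seg[2:(n - 1L)] - seg[1:(n - 2L)])
    force <- -g_perp + tau * fspring
    rms_perp <- sqrt(mean(rowSums(g_perp^2)))
    if (rms_perp <= force_tol) break
    fs <- fire_step(fs, force, max_step * sqrt(n - 2L))
    x[2:(n - 1L), ] <- x[2:(n - 1L), , drop = FALSE] + fs$dx
    if (it %% reparam_every == 0L) {
      # equal-arc-length string step; velocities are kept (zeroing them after
      # every remap strands FIRE in its small-step regime and stalls the band)
      x <- reparam_equal_arclength(x)
    }
    x[1, ] <- x0; x[n, ] <- x1
  }
  x <- reparam_equal_arclength(x)
  x[1, ] <- x0; x[n, ] <- x1
  path$images <- x
  path <- path_energies(surface, path)
  attr(path, "converged") <- rms_perp <= force_tol
  attr(path, "iterations") <- it
  attr(path, "rms_perp_force") <- rms_perp
  path
}

#' Refine the highest image to the saddle point (climbing image)
#'
#' Applied after the band has converged: the highest-energy interior image is
#' driven uphill along the local tangent and downhill in all perpendicular
#' directions (force `-g + 2 (g . t) t`), with its neighbours held fixed,
#' until the full gradient norm falls below `tol`. At the fixed point the
#' force vanishes only where the gradient itself vanishes, so a converged
#' result is a genuine stationary point.
#'
#' @param surface an [energy_surface()].
#' @param path an optimized `path_chain`.
#' @param tol gradient-norm tolerance (default 1e-6).
#' @param max_iter iteration cap (default 50000).
#' @param max_step displacement cap per iteration (default 0.05).
#' @return object of class `saddle_result`: `coords`, `energy`, `grad_norm`,
#'   `converged`, and `image_index` (0-based) of the climbing image.
#' @export
climbing_image_refine <- function(surface, path, tol = 1e-6,
                                  max_iter = 50000L, max_step = 0.05) {
  stopifnot(inherits(path, "path_chain"))
  path <- path_energies(surface, path)
  n <- path$n_images
  if (n < 3L) stop("climbing image needs at least one interior image")
  interior <- 2:(n - 1L)
  m <- interior[which.max(path$energies[interior])]
  xm <- path$images[m, ]
  xa <- path$images[m - 1L, ]; xb <- path$images[m + 1L, ]
  tdir <- xb - xa
  ntd <- sqrt(sum(tdir^2))
  tdir <- if (ntd > 0) tdir / ntd else { e <- numeric(path$dimension); e[1] <- 1; e }
  e_start <- path$energies[m]
  e_cap <- e_start + 1e3 * (abs(e_start) + 1)    # divergence guard
  fs <- fire_state(length(xm), dt = 2e-3, dt_max = 2e-2)
  gn <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- surface$gradient(xm)
    if (!all(is.finite(g))) stop("non-finite gradient at climbing image")
    gn <- sqrt(sum(g^2))
    if (gn <= tol) { converged <- TRUE; break }
    force <- -g + 2 * sum(g * tdir) * tdir
    fs <- fire_step(fs, force, max_step)
    xm <- xm + fs$dx
    e_now <- surface$energy(xm)
    if (!is.finite(e_now) || e_now > e_cap) {
      stop("climbing image diverged (energy grew without bound)")
    }
  }
  structure(list(coords = xm, energy = surface$energy(xm), grad_norm = gn,
                 converged = converged, image_index = m - 1L),
            class = "saddle_result")
}

#' @export
print.saddle_result <- function(x, ...) {
  cat(sprintf("saddle_result: E = %.6g, |grad| = %.3g, %s\n", x$energy,
              x$grad_norm, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Activation and reaction energies of a path
#'
#' Barrier bookkeeping relative to the reactant (first image):
#' `activation = max(E) - E[first]`, `reaction = E[last] - E[first]`.
#'
#' @param path a `path_chain` with energies populated, or a numeric vector of
#'   per-image energies.
#' @return list with `activation` and `reaction` (kcal/mol or surface units).
#' @export
path_barrier <- function(path) {
  E <- if (inherits(path, "path_chain")) path$energies else as.numeric(path)
  if (length(E) == 0L) stop("empty path")
  if (!all(is.finite(E))) stop("path energies not populated")
  list(activation = max(E) - E[1], reaction = E[length(E)] - E[1])
}

#' Finite-difference Hessian of an energy surface
#'
#' Central second differences of the analytic gradient; used to verify that
#' refined saddle points have exactly one negative curvature direction.
#'
#' @param surface an [energy_surface()].
#' @param x evaluation point.
#' @param h step (default 1e-4).
#' @return symmetric matrix of second derivatives.
#' @export
numerical_hessian <- function(surface, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  for (k in seq_len(d)) {
    e <- numeric(d); e[k] <- h
    H[, k] <- (surface$gradient(x + e) - surface$gradient(x - e)) / (2 * h)
  }
  (H + t(H)) / 2
}
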