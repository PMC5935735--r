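# Shared builders for test fixtures; everything is generated in code.

# n uncharged probe points as a structure (for reading potentials off a grid)
probe_points <- function(xyz) {
  xyz <- matrix(xyz, ncol = 3)
  structure_set(data.frame(name = "PRB", resname = "PRB",
                           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                           charge = 0, radius = 0))
}

# small multi-atom structure with given charges at fixed positions
toy_structure <- function(charges = c(0.4, -0.4, 1.0),
                          radii = c(1.5, 1.8, 2.0)) {
  n <- length(charges)
  xyz <- cbind(seq(0, by = 2.5, length.out = n), 0, 0)
  structure_set(data.frame(name = sprintf("A%d", seq_len(n)),
                           resname = "TOY", x = xyz[, 1], y = xyz[, 2],
                           z = xyz[, 3], charge = charges,
                           radius = rep_len(radii, n)))
}

# write a whitespace-delimited PQR with controlled field values
write_raw_pqr <- function(lines, path = tempfile(fileext = ".pqr")) {
  writeLines(lines, path)
  path
}

# random rigid-body transform (rotation + translation), seeded
random_rigid_transform <- function(seed) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = rnorm(3, sd = 5))
}

apply_rigid <- function(xyz, tr) sweep(xyz %*% t(tr$R), 2, -tr$t)

# descend to a local minimum by damped gradient steps (test-side utility)
descend_to_minimum <- function(surface, x, step = 1e-4, iters = 20000) {
  for (i in seq_len(iters)) {
    g <- surface$gradient(x)
    if (sqrt(sum(g^2)) < 1e-11) break
    x <- x - step * g
  }
  x
}
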