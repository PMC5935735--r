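#' Molecular structure container
#'
#' A `structure_set` holds an ordered atom table: one row per atom with a
#' name, residue label, Cartesian coordinates (Angstrom), partial charge (e)
#' and radius (Angstrom). It is the solute description consumed by the
#' Poisson-Boltzmann solver, where protein and substrate form a single
#' low-dielectric medium. Atoms are indexed 0-based internally; file serial
#' numbers are preserved on read but never trusted for identity.
#'
#' @param atoms data.frame with columns `name`, `resname`, `x`, `y`, `z`,
#'   `charge`, `radius` (and optionally `serial`, `resid`).
#' @param title free-text description.
#' @return object of class `structure_set`.
#' @export
structure_set <- function(atoms, title = "") {
  req <- c("name", "resname", "x", "y", "z", "charge", "radius")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  num <- as.matrix(atoms[, c("x", "y", "z", "charge", "radius")])
  if (nrow(atoms) && !all(is.finite(num))) stop("non-finite coordinate, charge or radius")
  if (nrow(atoms) && any(atoms$radius < 0)) stop("negative atomic radius")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, title = as.character(title)[1]),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("structure_set: %d atoms, net charge %+.4f e%s\n",
              n_atoms(x), net_charge(x),
              if (nzchar(x$title)) paste0(" (", x$title, ")") else ""))
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a `structure_set`.
#' @return integer count.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Net charge of a structure
#' @param s a `structure_set`.
#' @return sum of partial charges, in e.
#' @export
net_charge <- function(s) sum(s$atoms$charge)

#' Atom coordinates as a matrix
#' @param s a `structure_set`.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(s) unname(as.matrix(s$atoms[, c("x", "y", "z")]))

#' Replace the coordinates of a structure
#'
#' Charges, radii and labels are kept; only positions change. This is how
#' snapshot frames are combined with a fixed-topology template.
#'
#' @param s a `structure_set`.
#' @param xyz n x 3 matrix matching the structure's atom count.
#' @return new `structure_set`.
#' @export
set_coords <- function(s, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != n_atoms(s) || ncol(xyz) != 3L) {
    stop("coordinate matrix must be ", n_atoms(s), " x 3")
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' Define a titratable site as a charge perturbation
#'
#' A titratable site is the set of atoms whose partial charges differ between
#' the protonated and deprotonated forms of a group (for example a tyrosine
#' hydroxyl or an N-terminal amino group). `delta_q` is the per-atom charge in
#' the protonated state minus the charge in the deprotonated state; a
#' protonation adds exactly one proton, so the deltas must sum to +1 e.
#'
#' @param label site name.
#' @param atom_indices 0-based indices into the host structure.
#' @param delta_q per-atom charge differences (e), summing to +1 within 1e-6.
#' @param model_pka pKa of the corresponding model compound free in solvent.
#' @return object of class `titratable_site`.
#' @examples
#' titratable_site("tyr-OH", c(0, 1), c(0.4, 0.6), model_pka = 10.1)
#' @export
titratable_site <- function(label, atom_indices, delta_q, model_pka = NA_real_) {
  atom_indices <- as.integer(atom_indices)
  delta_q <- as.numeric(delta_q)
  if (length(atom_indices) != length(delta_q)) {
    stop("atom_indices and delta_q must have equal length")
  }
  if (anyDuplicated(atom_indices)) stop("duplicate atom indices in site")
  if (any(atom_indices < 0L)) stop("atom indices are 0-based and must be >= 0")
  if (abs(sum(delta_q) - 1.0) >= 1e-6) {
    stop(sprintf("sum(delta_q) must be +1 e (a protonation adds one proton); got %.8f",
                 sum(delta_q)))
  }
  structure(list(label = as.character(label)[1], atom_indices = atom_indices,
                 delta_q = delta_q, model_pka = as.numeric(model_pka)[1]),
            class = "titratable_site")
}

#' Set the protonation state of a titratable site
#'
#' Adds or removes the site's charge perturbation so that the returned
#' structure carries the requested protonation state. The template structure
#' is taken to be in the deprotonated state for every site it has never been
#' assigned a state for; the state applied to each site is recorded on the
#' returned object, which makes the operation idempotent and makes
#' protonated -> deprotonated -> protonated cycles recover the original
#' charges exactly.
#'
#' @param s a `structure_set`.
#' @param site a `titratable_site` whose indices are valid for `s`.
#' @param state `"protonated"` or `"deprotonated"`.
#' @return new `structure_set`; the input is not modified.
#' @export
apply_charge_state <- function(s, site, state = c("protonated", "deprotonated")) {
  state <- match.arg(state)
  stopifnot(inherits(site, "titratable_site"))
  idx1 <- site$atom_indices + 1L
  if (any(idx1 > n_atoms(s))) {
    stop("site '", site$label, "' references atom indices outside the structure")
  }
  states <- attr(s, "site_states")
  if (is.null(states)) states <- list()
  current <- states[[site$label]]
  if (is.null(current)) current <- "deprotonated"
  if (!identical(current, state)) {
    sign <- if (state == "protonated") 1 else -1
    s$atoms$charge[idx1] <- s$atoms$charge[idx1] + sign * site$delta_q
  }
  states[[site$label]] <- state
  attr(s, "site_states") <- states
  s
}

#' Multi-frame coordinate set
#'
#' Holds an ordered list of coordinate snapshots sharing one atom count,
#' standing in for frames drawn from a molecular-dynamics trajectory. Frames
#' carry coordinates only; charges and radii always come from a template
#' structure (fixed topology).
#'
#' @param frames list of n x 3 coordinate matrices (Angstrom).
#' @return object of class `frame_set` with fields `n_atoms` and `frames`.
#' @export
frame_set <- function(frames) {
  if (!is.list(frames) || length(frames) < 1L) stop("need at least one frame")
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (ncol(f) != 3L) stop("each frame must be an n x 3 matrix")
    if (!all(is.finite(f))) stop("non-finite coordinates in frame")
    unname(f)
  })
  na <- vapply(frames, nrow, integer(1))
  if (length(unique(na)) != 1L) {
    stop("inconsistent atom count across frames: ", paste(unique(na), collapse = ", "))
  }
  structure(list(n_atoms = na[1], frames = frames), class = "frame_set")
}

#' Number of frames in a frame set
#' @param fs a `frame_set`.
#' @return integer count.
#' @export
n_frames <- function(fs) length(fs$frames)

#' Interatomic distance along a frame set
#'
#' Euclidean distance between two atoms in every frame — the geometric
#' observable used to follow, for example, how far a dipeptide's nucleophilic
#' nitrogen sits from the carbonyl carbon it must attack.
#'
#' @param fs a `frame_set`.
#' @param i,j 0-based atom indices, distinct.
#' @return numeric vector, one distance (Angstrom) per frame.
#' @examples
#' fs <- frame_set(list(rbind(c(0, 0, 0), c(3, 4, 0))))
#' distance_series(fs, 0, 1) # 5
#' @export
distance_series <- function(fs, i, j) {
  stopifnot(inherits(fs, "frame_set"))
  i <- as.integer(i); j <- as.integer(j)
  if (i == j) stop("atom indices must be distinct")
  if (i < 0L || j < 0L || i >= fs$n_atoms || j >= fs$n_atoms) {
    stop("atom index out of range [0, ", fs$n_atoms - 1L, "]")
  }
  vapply(fs$frames, function(f) sqrt(sum((f[i + 1L, ] - f[j + 1L, ])^2)), numeric(1))
}
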