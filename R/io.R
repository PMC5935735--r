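#' Read a PQR structure file
#'
#' Parses the whitespace-delimited PQR dialect (the common PDB2PQR output):
#' `ATOM/HETATM serial name resname [chain] resid x y z charge radius`.
#' The chain identifier is optional and detected per record. The reader is
#' permissive about spacing but strict about content: any ATOM record with a
#' non-numeric field, the wrong token count, or a negative radius is an error
#' naming the offending line.
#'
#' @param path path to a PQR file.
#' @return a [structure_set()].
#' @export
read_pqr <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("^(ATOM|HETATM)", lines)
  if (!any(keep)) stop("no ATOM/HETATM records in ", path)
  lineno <- which(keep)
  rows <- lapply(seq_along(lineno), function(k) {
    ln <- lineno[k]
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (!length(tok) %in% c(10L, 11L)) {
      stop(sprintf("line %d: expected 10 or 11 fields in PQR record, got %d",
                   ln, length(tok)))
    }
    has_chain <- length(tok) == 11L
    num <- suppressWarnings(as.numeric(tok[(length(tok) - 4L):length(tok)]))
    serial <- suppressWarnings(as.integer(tok[2]))
    if (anyNA(num) || is.na(serial)) {
      stop(sprintf("line %d: non-numeric field in PQR record", ln))
    }
    if (num[5] < 0) stop(sprintf("line %d: negative radius %.4f", ln, num[5]))
    data.frame(serial = serial, name = tok[3], resname = tok[4],
               chain = if (has_chain) tok[5] else "",
               resid = suppressWarnings(as.integer(tok[5L + has_chain])),
               x = num[1], y = num[2], z = num[3],
               charge = num[4], radius = num[5], stringsAsFactors = FALSE)
  })
  structure_set(do.call(rbind, rows), title = basename(path))
}

#' Write a structure as PQR
#'
#' Writes whitespace-delimited PQR with fixed precision (3 decimals for
#' coordinates, 4 for charges and radii) so that a read/write round trip is
#' field-identical at the written precision.
#'
#' @param s a non-empty [structure_set()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pqr <- function(s, path) {
  stopifnot(inherits(s, "structure_set"))
  if (n_atoms(s) == 0L) stop("refusing to write an empty structure")
  a <- s$atoms
  serial <- if ("serial" %in% names(a)) a$serial else seq_len(nrow(a))
  resid <- if ("resid" %in% names(a) && !anyNA(a$resid)) a$resid else rep(1L, nrow(a))
  rec <- sprintf("ATOM  %5d %-4s %-4s %4d    %8.3f %8.3f %8.3f %8.4f %7.4f",
                 serial, a$name, a$resname, resid, a$x, a$y, a$z, a$charge, a$radius)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(rec, "END"), con)
  invisible(path)
}

#' Read a multi-frame coordinate file
#'
#' Reads snapshot ensembles from multi-model PDB (via bio3d) or multi-block
#' XYZ files into a [frame_set()]. All frames must share one atom count.
#'
#' @param path input file.
#' @param format `"pdb"` or `"xyz"`; default guesses from the extension.
#' @return a [frame_set()], coordinates in Angstrom.
#' @export
read_frames <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xyz")) "xyz" else "pdb"
  }
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz                       # nframes x 3n matrix
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    frames <- lapply(seq_len(nrow(xyz)), function(m) {
      matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    })
    return(frame_set(frames))
  }
  read_xyz_frames(path)
}

# Multi-block XYZ: repeated [natoms, comment, natoms atom lines] blocks.
read_xyz_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  last <- max(c(0L, which(nzchar(trimws(lines)))))   # drop trailing blanks
  lines <- lines[seq_len(last)]
  frames <- list()
  pos <- 1L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat < 1L) stop("line ", pos, ": expected an atom count")
    if (pos + 1L + nat > length(lines)) {
      stop("line ", pos, ": XYZ block declares ", nat,
           " atoms but the file ends early")
    }
    body <- lines[(pos + 2L):(pos + 1L + nat)]
    toks <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(toks, length, integer(1)) < 4L)
    if (length(bad)) stop("line ", pos + 1L + bad[1], ": malformed XYZ atom record")
    xyz <- t(vapply(toks, function(tk) {
      v <- suppressWarnings(as.numeric(tk[2:4]))
      if (anyNA(v)) stop("non-numeric coordinate in XYZ block starting line ", pos)
      v
    }, numeric(3)))
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + nat
  }
  if (!length(frames)) stop("no XYZ blocks found in ", path)
  frame_set(frames)
}

#' Write a frame set as multi-block XYZ
#'
#' @param fs a [frame_set()].
#' @param path output path.
#' @param names atom element labels recycled across atoms (default "X").
#' @return invisibly, `path`.
#' @export
write_xyz_frames <- function(fs, path, names = "X") {
  stopifnot(inherits(fs, "frame_set"))
  names <- rep_len(names, fs$n_atoms)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(fs$frames)) {
    writeLines(c(as.character(fs$n_atoms), sprintf("frame %d", k)), con)
    f <- fs$frames[[k]]
    writeLines(sprintf("%-3s %14.8f %14.8f %14.8f", names, f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

#' Write a scalar grid field in OpenDX format
#'
#' Emits the plain-text OpenDX "regular positions, regular connections"
#' scalar format understood by common visualization tools.
#'
#' @param field a `potential_field` (or any list with `grid` and per-node
#'   `values` array).
#' @param path output path.
#' @param name dataset comment.
#' @return invisibly, `path`.
#' @export
write_dx <- function(field, path, name = "scalar field") {
  g <- field$grid
  v <- field$values
  stopifnot(length(v) == prod(g$dims))
  # OpenDX expects z fastest; internal arrays are x-fastest (R column-major).
  arr <- array(v, dim = g$dims)
  vz <- as.vector(aperm(arr, c(3, 2, 1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", name), con)
  writeLines(sprintf("object 1 class gridpositions counts %d %d %d",
                     g$dims[1], g$dims[2], g$dims[3]), con)
  writeLines(sprintf("origin %.6f %.6f %.6f", g$origin[1], g$origin[2], g$origin[3]), con)
  writeLines(sprintf("delta %.6f 0.0 0.0", g$spacing), con)
  writeLines(sprintf("delta 0.0 %.6f 0.0", g$spacing), con)
  writeLines(sprintf("delta 0.0 0.0 %.6f", g$spacing), con)
  writeLines(sprintf("object 2 class gridconnections counts %d %d %d",
                     g$dims[1], g$dims[2], g$dims[3]), con)
  writeLines(sprintf("object 3 class array type double rank 0 items %d data follows",
                     length(vz)), con)
  n3 <- (length(vz) %/% 3) * 3
  if (n3 > 0) {
    m <- matrix(vz[seq_len(n3)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.6e %.6e %.6e", m[, 1], m[, 2], m[, 3]), con)
  }
  if (n3 < length(vz)) {
    writeLines(paste(sprintf("%.6e", vz[(n3 + 1):length(vz)]), collapse = " "), con)
  }
  writeLines('attribute "dep" string "positions"', con)
  writeLines("object \"field\" class field", con)
  writeLines('component "positions" value 1', con)
  writeLines('component "connections" value 2', con)
  writeLines('component "data" value 3', con)
  invisible(path)
}
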