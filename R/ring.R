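#' Ring conformations
#'
#' A ring conformation is an ordered cycle of N bead positions in 3D, stored
#' as an N x 3 numeric matrix of class `"ring"`. Index arithmetic is periodic:
#' bead N+1 is bead 1. All lengths are in units of the bond length b.
#'
#' @param x an N x 3 numeric matrix (or something coercible) of bead positions.
#' @return an object of class `"ring"`.
#' @examples
#' r <- ring(cbind(cos(2 * pi * (0:19) / 20), sin(2 * pi * (0:19) / 20), 0))
#' n_beads(r)
#' @export
ring <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("ring positions must have 3 columns (x, y, z)")
  if (nrow(x) < 3L) stop("a ring needs at least 3 beads")
  if (!all(is.finite(x))) stop("ring positions must be finite")
  dimnames(x) <- NULL
  structure(x, class = c("ring", "matrix", "array"))
}

#' @rdname ring
#' @export
is_ring <- function(x) inherits(x, "ring")

#' @rdname ring
#' @export
n_beads <- function(x) nrow(x)

#' @export
print.ring <- function(x, ...) {
  cat(sprintf("ring conformation: %d beads, contour length %.4g\n",
              nrow(x), contour_length(x)))
  invisible(x)
}

#' Bond vectors of a ring
#'
#' Returns the N bond vectors u_n = r_{n+1} - r_n with periodic wrap
#' (u_N = r_1 - r_N).
#'
#' @param r a [ring()].
#' @return an N x 3 matrix of bond vectors.
#' @export
bond_vectors <- function(r) {
  r <- unclass(r)
  rbind(r[-1L, , drop = FALSE], r[1L, , drop = FALSE]) - r
}

#' Total contour length of a ring polygon
#'
#' @param r a [ring()].
#' @return the sum of bond lengths.
#' @export
contour_length <- function(r) {
  sum(sqrt(rowSums(bond_vectors(r)^2)))
}

#' Cyclically permute the bead labels of a ring
#'
#' Returns the same curve with bead n relabelled to bead n - n0, i.e. the
#' conformation whose bead 1 is the old bead 1 + n0. Used for the
#' circular-permutation endpoint conditioning of ring bridges.
#'
#' @param r a [ring()].
#' @param n0 integer shift (any value; interpreted modulo N).
#' @return a [ring()].
#' @export
cyclic_shift <- function(r, n0) {
  n <- nrow(r)
  idx <- ((seq_len(n) - 1L + as.integer(n0)) %% n) + 1L
  ring(unclass(r)[idx, , drop = FALSE])
}

#' Read and write (multi-frame) XYZ files
#'
#' Plain-text XYZ: for each frame a line with the atom count, a comment line,
#' then one `El x y z` line per bead. `write_xyz` writes one frame per ring;
#' the comment line carries `time=` when `times` is given. `read_xyz` returns
#' a list of rings with a `times` attribute when parseable.
#'
#' @param rings a [ring()] or list of rings.
#' @param file path.
#' @param times optional numeric vector of frame times for the comment lines.
#' @param element element symbol to write (cosmetic).
#' @return `read_xyz`: a list of rings; `write_xyz`: the file path, invisibly.
#' @export
write_xyz <- function(rings, file, times = NULL, element = "C") {
  if (is_ring(rings)) rings <- list(rings)
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_along(rings)) {
    r <- unclass(rings[[i]])
    comment <- if (!is.null(times)) sprintf("time=%.10g", times[i]) else sprintf("frame=%d", i)
    writeLines(c(sprintf("%d", nrow(r)), comment), con)
    writeLines(sprintf("%s %.12g %.12g %.12g", element, r[, 1], r[, 2], r[, 3]), con)
  }
  invisible(file)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  out <- list()
  times <- numeric()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i)
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexec("time=([-0-9.eE+]+)", comment))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else NA_real_)
    block <- lines[(i + 2L):(i + 1L + n)]
    fields <- do.call(rbind, strsplit(trimws(block), "[[:space:]]+"))
    out[[length(out) + 1L]] <- ring(matrix(as.numeric(fields[, 2:4]), ncol = 3))
    i <- i + 2L + n
  }
  attr(out, "times") <- times
  out
}
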