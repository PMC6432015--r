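#' Project a ring and extract its knot diagram
#'
#' Projects the oriented ring along `direction`, finds all pairwise segment
#' crossings in the plane (exact O(N^2) segment-pair tests), and records for
#' each crossing which strand passes over (depth along `direction`) and its
#' sign by the right-hand rule: sign((t_over x t_under) . direction).
#' Degenerate projections (near-coincident projected vertices, grazing
#' intersections, ambiguous depth) are retried with a slightly perturbed
#' direction up to `max_retries` times.
#'
#' @param r a [ring()].
#' @param direction a 3-vector (need not be unit); default random.
#' @param max_retries retries on degenerate projections.
#' @return an object of class `"knot_diagram"`: list with `crossings` (data
#'   frame: under_seg, under_pos, over_seg, over_pos, sign — positions are
#'   curve coordinates in [0, N)), `n` crossings, and `direction`.
#' @export
project_diagram <- function(r, direction = NULL, max_retries = 100L) {
  stopifnot(is_ring(r))
  if (is.null(direction)) direction <- random_directions(1)[1, ]
  d <- direction / sqrt(sum(direction^2))
  for (try in seq_len(max_retries)) {
    res <- cpp_diagram(unclass(r), d)
    if (!res$degenerate) {
      cr <- res$crossings
      if (nrow(cr) == 0) {
        crossings <- data.frame(under_seg = integer(), under_pos = numeric(),
                                over_seg = integer(), over_pos = numeric(),
                                sign = numeric())
      } else {
        i_over <- cr[, 5] == 1
        crossings <- data.frame(
          under_seg = as.integer(ifelse(i_over, cr[, 3], cr[, 1])),
          under_pos = ifelse(i_over, cr[, 3] + cr[, 4], cr[, 1] + cr[, 2]),
          over_seg  = as.integer(ifelse(i_over, cr[, 1], cr[, 3])),
          over_pos  = ifelse(i_over, cr[, 1] + cr[, 2], cr[, 3] + cr[, 4]),
          sign = cr[, 6])
      }
      return(structure(list(crossings = crossings, n = nrow(crossings),
                            direction = d), class = "knot_diagram"))
    }
    # deterministic small perturbation, then renormalize
    d <- d + 1e-6 * try * sin(try * c(1.3, 2.1, 3.7))
    d <- d / sqrt(sum(d^2))
  }
  stop("no generic projection found after ", max_retries, " retries")
}

#' @export
print.knot_diagram <- function(x, ...) {
  cat(sprintf("knot_diagram: %d crossings (writhe of diagram %+d)\n",
              x$n, if (x$n) sum(x$crossings$sign) else 0L))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Gauss-code simplification (Reidemeister I and II on the passage sequence)

# events: data.frame(cross = id, over = logical), ordered along the curve.
simplify_gauss <- function(events, signs) {
  repeat {
    n <- nrow(events)
    if (n == 0) break
    changed <- FALSE
    # R1: the two passages of one crossing are adjacent along the curve
    nxt <- c(2:n, 1L)
    r1 <- which(events$cross == events$cross[nxt])
    if (length(r1)) {
      drop <- events$cross[r1[1]]
      events <- events[events$cross != drop, , drop = FALSE]
      changed <- TRUE
    } else if (n >= 4) {
      # R2: crossings c, d adjacent on two stretches, one both-over, one both-under
      pair_id <- paste(pmin(events$cross, events$cross[nxt]),
                       pmax(events$cross, events$cross[nxt]))
      both_over <- events$over & events$over[nxt]
      both_under <- !events$over & !events$over[nxt]
      distinct <- events$cross != events$cross[nxt]
      over_pairs <- pair_id[both_over & distinct]
      under_pairs <- pair_id[both_under & distinct]
      hit <- intersect(over_pairs, under_pairs)
      if (length(hit)) {
        ids <- as.integer(strsplit(hit[1], " ")[[1]])
        events <- events[!(events$cross %in% ids), , drop = FALSE]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(events = events, signs = signs)
}

# ---------------------------------------------------------------------------
# Alexander matrix and exact (modular) determinant evaluations

# two primes below 2^26 so that products of residues stay exact in doubles
.kb_primes <- c(67108859, 67108837)

modmul <- function(a, b, p) (a * b) %% p
modpow <- function(a, e, p) {
  r <- 1
  a <- a %% p
  while (e > 0) {
    if (e %% 2 == 1) r <- modmul(r, a, p)
    a <- modmul(a, a, p)
    e <- e %/% 2
  }
  r
}
modinv <- function(a, p) modpow(a, p - 2, p)

# determinant of square matrix (entries already reduced mod p) by Gaussian
# elimination over GF(p)
det_mod <- function(M, p) {
  m <- nrow(M)
  if (m == 0) return(1)
  det <- 1
  for (k in seq_len(m)) {
    piv <- which(M[k:m, k] != 0)
    if (!length(piv)) return(0)
    i <- piv[1] + k - 1L
    if (i != k) {
      M[c(i, k), ] <- M[c(k, i), ]
      det <- (p - det) %% p
    }
    pk <- M[k, k]
    det <- modmul(det, pk, p)
    if (k < m) {
      inv <- modinv(pk, p)
      rows <- (k + 1L):m
      f <- modmul(M[rows, k], inv, p)
      M[rows, ] <- (M[rows, , drop = FALSE] - outer(f, M[k, ])) %% p
    }
  }
  det
}

# coefficients (mod p) of the degree <= m polynomial through points
# (x_j, y_j), x_j distinct mod p. Synthetic-division Lagrange, O(m^2).
interp_mod <- function(x, y, p) {
  m <- length(x)
  # full product P(t) = prod (t - x_j), coefficients ascending
  P <- 1
  for (xj in x) P <- c(0, P) - c(modmul(xj %% p, P, p), 0)
  P <- P %% p
  coef <- numeric(m)
  for (j in seq_len(m)) {
    xj <- x[j] %% p
    # Q = P / (t - x_j) by synthetic division (ascending coefficients)
    mdeg <- m
    Q <- numeric(mdeg)
    Q[mdeg] <- P[mdeg + 1L]
    for (i in (mdeg - 1L):1L) Q[i] <- (P[i + 1L] + modmul(xj, Q[i + 1L], p)) %% p
    denom <- 1
    for (i in seq_len(m)) if (i != j) denom <- modmul(denom, (x[j] - x[i]) %% p, p)
    coef <- (coef + modmul(y[j], modmul(Q, modinv(denom, p), p), p)) %% p
  }
  coef
}

# CRT for two primes; returns the representative of smallest absolute value
crt2 <- function(x1, x2, p1, p2) {
  m <- modmul((x2 - x1) %% p2, modinv(p1 %% p2, p2), p2)
  v <- x1 + p1 * m
  M <- p1 * p2
  if (v > M / 2) v <- v - M
  v
}

# Build the Alexander matrix rows as two integer matrices (A + t B) from an
# (already simplified) passage sequence + signs, then evaluate.
alexander_from_events <- function(events, signs) {
  n_cross <- length(unique(events$cross))
  if (n_cross == 0) return(c(det1 = 1, det2 = 1))
  if (n_cross <= 2) return(c(det1 = 1, det2 = 1)) # <=2 crossing knot diagram is trivial
  under_rows <- which(!events$over)
  n <- length(under_rows)
  if (n != n_cross) stop("inconsistent diagram: under-passage count mismatch")
  # underpass order defines crossing numbering and arcs: arc j starts at
  # underpass j. Locate each crossing's over passage between underpasses.
  cross_ids <- events$cross[under_rows]
  # position (row index in events) of each passage
  over_rows <- which(events$over)
  over_arc <- integer(n)
  # for event row r, the arc it lies on = number of underpasses at rows <= r
  upto <- cumsum(!events$over)
  for (k in seq_len(n)) {
    orow <- over_rows[events$cross[over_rows] == cross_ids[k]]
    arc <- upto[orow]
    if (arc == 0) arc <- n # before the first underpass: wraps to last arc
    over_arc[k] <- arc
  }
  A <- matrix(0, n, n) # constant part
  B <- matrix(0, n, n) # t coefficient
  for (k in seq_len(n)) {
    inA <- if (k == 1) n else k - 1L
    outA <- k
    o <- over_arc[k]
    eps <- signs[[as.character(cross_ids[k])]]
    # Fox calculus rows: positive: o: 1 - t, in: t, out: -1
    #                    negative: o: 1 - t, in: -1, out: t
    A[k, o] <- A[k, o] + 1
    B[k, o] <- B[k, o] - 1
    if (eps > 0) {
      B[k, inA] <- B[k, inA] + 1
      A[k, outA] <- A[k, outA] - 1
    } else {
      A[k, inA] <- A[k, inA] - 1
      B[k, outA] <- B[k, outA] + 1
    }
  }
  # first minor: drop last row and column
  A <- A[-n, -n, drop = FALSE]
  B <- B[-n, -n, drop = FALSE]
  m <- n - 1L
  det1m <- det2m <- kpow <- ok1 <- numeric(2)
  for (ip in 1:2) {
    p <- .kb_primes[ip]
    ts <- 0:m
    dets <- vapply(ts, function(t0) det_mod((A + t0 * B) %% p, p), numeric(1))
    coef <- interp_mod(ts, dets, p) # length m+1, ascending powers
    nz <- which(coef != 0)
    if (!length(nz)) return(c(det1 = 0, det2 = 0)) # vanishing determinant
    kpow[ip] <- nz[1] - 1L
    # evaluate at t = 1 (must be a unit), -1, -2 via Horner
    horner <- function(tval) {
      acc <- 0
      for (cf in rev(coef)) acc <- (modmul(acc, tval %% p, p) + cf) %% p
      acc
    }
    ok1[ip] <- horner(1)
    det1m[ip] <- horner(p - 1)
    v2 <- horner(p - 2)
    # strip the (+-t^k) unit: divide by (-2)^k mod p
    det2m[ip] <- modmul(v2, modinv(modpow(p - 2, kpow[ip], p), p), p)
  }
  k <- min(kpow)
  if (kpow[1] != kpow[2]) {
    # a leading coefficient vanished mod one prime; recompute with min k
    for (ip in 1:2) if (kpow[ip] != k) {
      p <- .kb_primes[ip]
      det2m[ip] <- modmul(det2m[ip], modpow(p - 2, kpow[ip] - k, p), p)
    }
  }
  unit <- abs(crt2(ok1[1], ok1[2], .kb_primes[1], .kb_primes[2]))
  if (unit != 1) stop("inconsistent knot diagram: Alexander evaluation at t=1 is not a unit")
  det1 <- abs(crt2(det1m[1], det1m[2], .kb_primes[1], .kb_primes[2]))
  det2 <- abs(crt2(det2m[1], det2m[2], .kb_primes[1], .kb_primes[2]))
  c(det1 = det1, det2 = det2)
}

#' Alexander determinants of a knot diagram
#'
#' Builds the Alexander matrix of the diagram from its crossing/arc incidence
#' (Wirtinger presentation, Fox derivatives), deletes one row and column, and
#' evaluates the determinant of the minor at t = -1 and t = -2 with exact
#' integer arithmetic (modular evaluations at two 26-bit primes, recombined by
#' the Chinese remainder theorem; a modular polynomial interpolation strips
#' the +-t^k unit so |Delta(-2)| is the standard invariant — naive removal of
#' factors of two would corrupt knots with even Delta(-2), e.g. 5_2). The
#' diagram is first reduced by Reidemeister I/II simplification of its Gauss
#' code. |Delta(-1)| is the knot determinant; the pair (|Delta(-1)|,
#' |Delta(-2)|) distinguishes all prime knots through 7 crossings.
#'
#' @param diagram a `"knot_diagram"` from [project_diagram()].
#' @return named integer-valued vector `c(det1, det2)` = (|Delta(-1)|, |Delta(-2)|).
#' @export
alexander_determinants <- function(diagram) {
  stopifnot(inherits(diagram, "knot_diagram"))
  cr <- diagram$crossings
  if (nrow(cr) == 0) return(c(det1 = 1, det2 = 1))
  # passage sequence along the curve
  ev <- data.frame(
    cross = rep(seq_len(nrow(cr)), 2L),
    pos = c(cr$under_pos, cr$over_pos),
    over = rep(c(FALSE, TRUE), each = nrow(cr)))
  ev <- ev[order(ev$pos), c("cross", "over")]
  signs <- stats::setNames(cr$sign, seq_len(nrow(cr)))
  simp <- simplify_gauss(ev, signs)
  alexander_from_events(simp$events, simp$signs)
}

# ---------------------------------------------------------------------------
# knot table: label, (|Delta(-1)|, |Delta(-2)|), achirality — all prime knots
# through 7 crossings, determinant pairs from the standard Alexander
# polynomials (pairwise distinct; asserted on first use).

knot_det_table <- function() {
  tab <- data.frame(
    label = c("0_1", "3_1", "4_1", "5_1", "5_2", "6_1", "6_2", "6_3",
              "7_1", "7_2", "7_3", "7_4", "7_5", "7_6", "7_7"),
    det1 = c(1, 3, 5, 5, 7, 9, 11, 13, 7, 11, 13, 15, 17, 19, 21),
    det2 = c(1, 7, 11, 31, 16, 20, 59, 67, 127, 25, 76, 34, 94, 95, 103),
    achiral = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE,
                FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  key <- paste(tab$det1, tab$det2)
  if (anyDuplicated(key)) stop("knot determinant table is not injective")
  tab
}

#' Crossing number encoded in a knot label
#'
#' @param label knot labels like "0_1", "5_2"; "unresolved" gives NA.
#' @return integer vector of minimal crossing numbers.
#' @export
label_crossings <- function(label) {
  out <- suppressWarnings(as.integer(sub("_.*$", "", label)))
  out
}

#' Identify the knot type of a ring conformation
#'
#' Computes Alexander determinant pairs from generic projections of the ring
#' (fresh random directions until two agree, a cheap guard against rare
#' misclassified degenerate projections), looks the pair up in the built-in
#' table of prime knots through 7 crossings, and attaches chirality from the
#' sign of the exact Gauss-integral writhe (Alexander determinants are blind
#' to mirror images). Uses the R RNG; seed with [set.seed()] for
#' reproducibility.
#'
#' @param r a [ring()].
#' @param n_directions maximum number of projection directions tried.
#' @return a list of class `"knot_id"`: `label` ("unresolved" if the pair is
#'   not in the table — e.g. composite or >7-crossing knots), `det1`, `det2`,
#'   `chirality` ("left", "right", "achiral", "ambiguous" or "n/a"), and
#'   `writhe` (exact Gauss writhe).
#' @export
knot_type <- function(r, n_directions = 10L) {
  stopifnot(is_ring(r), n_directions >= 1)
  seen <- list()
  dets <- NULL
  for (i in seq_len(max(2L, n_directions))) {
    d <- tryCatch(
      alexander_determinants(project_diagram(r)),
      error = function(e) NULL)
    if (is.null(d)) next
    key <- paste(d[1], d[2])
    if (!is.null(seen[[key]])) { dets <- d; break }
    seen[[key]] <- TRUE
    dets <- d
  }
  if (is.null(dets)) stop("knot identification failed: no generic projection")
  tab <- knot_det_table()
  hit <- which(tab$det1 == dets[1] & tab$det2 == dets[2])
  label <- if (length(hit)) tab$label[hit] else "unresolved"
  wr <- cpp_gauss_writhe(unclass(r))
  chirality <- if (!length(hit) || label == "0_1") "n/a"
    else if (tab$achiral[hit]) "achiral"
    else if (wr > 0.5) "right"
    else if (wr < -0.5) "left"
    else "ambiguous"
  structure(list(label = label, det1 = unname(dets[1]), det2 = unname(dets[2]),
                 chirality = chirality, writhe = wr),
            class = "knot_id")
}

#' @export
print.knot_id <- function(x, ...) {
  cat(sprintf("knot %s (|Delta(-1)|=%d, |Delta(-2)|=%d), chirality %s, Wr=%.3f\n",
              x$label, x$det1, x$det2, x$chirality, x$writhe))
  invisible(x)
}

# ---------------------------------------------------------------------------
# writhe and average crossing number

random_directions <- function(n) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

# counts with resampling of degenerate directions
crossing_counts <- function(r, n_proj) {
  dirs <- random_directions(n_proj)
  cnt <- cpp_crossing_counts(unclass(r), dirs)
  for (tries in 1:100) {
    bad <- cnt[, 3] == 1
    if (!any(bad)) break
    dirs[bad, ] <- random_directions(sum(bad))
    cnt[bad, ] <- cpp_crossing_counts(unclass(r), dirs[bad, , drop = FALSE])
  }
  if (any(cnt[, 3] == 1)) stop("could not find generic projection directions")
  cnt
}

#' Writhe of a ring
#'
#' `method = "gauss"` evaluates the discrete Gauss double integral over all
#' non-adjacent segment pairs (exact for polygons, variance-free).
#' `method = "projections"` averages the signed crossing count (right-hand
#' rule weights +-1) over `n_proj` uniformly random projection directions;
#' its expectation equals the Gauss writhe. Uses the R RNG for directions.
#'
#' @param r a [ring()].
#' @param method "gauss" or "projections".
#' @param n_proj number of random directions for the projection estimate.
#' @return the writhe (for "projections", with attribute `"se"`, the Monte
#'   Carlo standard error).
#' @export
writhe <- function(r, method = c("gauss", "projections"), n_proj = 1000L) {
  method <- match.arg(method)
  stopifnot(is_ring(r))
  if (method == "gauss") return(cpp_gauss_writhe(unclass(r)))
  cnt <- crossing_counts(r, n_proj)
  signed <- cnt[, 1] - cnt[, 2]
  structure(mean(signed), se = stats::sd(signed) / sqrt(n_proj))
}

#' Average crossing number of a ring
#'
#' Mean unsigned crossing count over `n_proj` uniformly random projection
#' directions (each crossing weighted +1).
#'
#' @inheritParams writhe
#' @return the estimate, with attribute `"se"`.
#' @export
average_crossing_number <- function(r, n_proj = 1000L) {
  stopifnot(is_ring(r))
  cnt <- crossing_counts(r, n_proj)
  tot <- cnt[, 1] + cnt[, 2]
  structure(mean(tot), se = stats::sd(tot) / sqrt(n_proj))
}
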