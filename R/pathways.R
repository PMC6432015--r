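#' Root-mean-square distance between two ring conformations
#'
#' Default is the absolute-frame RMSD (no superposition): the bridge dynamics
#' pins absolute coordinates, so the natural progress variable is the raw
#' per-bead distance. `superpose = TRUE` first removes the optimal rigid-body
#' rotation and translation (Kabsch, least squares), which is never larger.
#'
#' @param a,b [ring()] objects with equal bead counts.
#' @param superpose remove the optimal rigid-body transform first.
#' @return the RMSD (length units).
#' @export
rmsd <- function(a, b, superpose = FALSE) {
  stopifnot(is_ring(a), is_ring(b))
  if (nrow(a) != nrow(b)) stop("rings have different bead counts")
  x <- unclass(a)
  y <- unclass(b)
  if (superpose) {
    xc <- sweep(x, 2, colMeans(x))
    yc <- sweep(y, 2, colMeans(y))
    s <- svd(crossprod(yc, xc))
    d <- sign(det(s$u %*% t(s$v)))
    rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
    y <- yc %*% rot
    x <- xc
  }
  sqrt(mean(rowSums((x - y)^2)))
}

#' Rescale a ring's contour length
#'
#' Uniform scaling about the centre of mass so the polygon's total contour
#' length equals `target`. The Gaussian bridge does not conserve contour
#' length; this is the reporting-time rescaling (topology is scale invariant).
#'
#' @param r a [ring()].
#' @param target target contour length (> 0).
#' @return a [ring()].
#' @export
rescale_contour <- function(r, target) {
  stopifnot(is_ring(r), target > 0)
  L <- contour_length(r)
  if (L <= 0) stop("degenerate ring: zero contour length")
  cm <- colMeans(unclass(r))
  centred <- sweep(unclass(r), 2, cm)
  ring(centred * (target / L) + matrix(cm, nrow(r), 3, byrow = TRUE))
}

#' Per-frame topological and geometric report of a bridge trajectory
#'
#' Evaluates, every `stride`-th stored frame (first and last always included):
#' time, RMSD to the initial and final frames, knot label with Alexander
#' determinant pair, exact Gauss writhe, and (when `n_proj > 0`) the
#' projection-averaged writhe and average crossing number. Knot bands are the
#' maximal runs of constant knot label. Uses the R RNG (projection
#' directions); seed with [set.seed()].
#'
#' @param traj a `"bridge_trajectory"` from [run_bridge()].
#' @param stride evaluate every `stride`-th stored frame.
#' @param n_proj projections per frame for `<nc>` and `<Wr>` (0 = skip).
#' @return an object of class `"pathway_report"`: list with `table` (one row
#'   per evaluated frame), `bands` (label, t_start, t_end), and `summary`
#'   (knot sequence, max crossing number visited, whether intermediate
#'   topologies exceed both endpoint complexities).
#' @export
build_report <- function(traj, stride = 1L, n_proj = 0L) {
  stopifnot(inherits(traj, "bridge_trajectory"), stride >= 1)
  nf <- length(traj$frames)
  idx <- unique(c(seq(1L, nf, by = stride), nf))
  ref_i <- traj$frames[[1]]
  ref_f <- traj$frames[[nf]]
  rows <- lapply(idx, function(i) {
    fr <- traj$frames[[i]]
    kt <- knot_type(fr)
    row <- data.frame(
      time = traj$times[i],
      rmsd_initial = rmsd(fr, ref_i),
      rmsd_final = rmsd(fr, ref_f),
      knot = kt$label, det1 = kt$det1, det2 = kt$det2,
      writhe_gauss = kt$writhe)
    if (n_proj > 0) {
      row$writhe_proj <- as.numeric(writhe(fr, "projections", n_proj))
      row$acn <- as.numeric(average_crossing_number(fr, n_proj))
    }
    row
  })
  tab <- do.call(rbind, rows)
  runs <- rle(tab$knot)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  bands <- data.frame(label = runs$values,
                      t_start = tab$time[starts],
                      t_end = tab$time[ends])
  ncr <- label_crossings(tab$knot)
  end_ncr <- ncr[c(1, nrow(tab))]
  summary <- list(
    knot_sequence = runs$values,
    labels_visited = unique(tab$knot),
    max_crossings = if (all(is.na(ncr))) NA_integer_ else max(ncr, na.rm = TRUE),
    any_unresolved = any(tab$knot == "unresolved"),
    exceeds_endpoints = any(tab$knot == "unresolved") ||
      (any(!is.na(ncr)) && max(ncr, na.rm = TRUE) > max(end_ncr, na.rm = TRUE)))
  structure(list(table = tab, bands = bands, summary = summary),
            class = "pathway_report")
}

#' @export
print.pathway_report <- function(x, ...) {
  cat(sprintf("pathway_report: %d frames, knot sequence %s\n",
              nrow(x$table), paste(x$summary$knot_sequence, collapse = " -> ")))
  invisible(x)
}

#' Ensemble of conditioned knotting--unknotting trajectories
#'
#' Runs `n_traj` independently seeded circular-permutation bridges between
#' endpoint pairs (recycled over `pairs`), builds a [build_report()] for each,
#' and aggregates: the fraction of trajectories visiting each knot label as an
#' intermediate, the fraction visiting any label of at least `k_complex`
#' crossings beyond the endpoints, and the fraction with any nontrivial
#' intermediate. Frames whose determinant pair is not in the <= 7-crossing
#' table ("unresolved": composite or >= 8-crossing knots) count as complex.
#'
#' @param pairs a list of `list(initial =, final =)` ring pairs.
#' @param n_traj number of trajectories.
#' @param params a [chain_parameters()].
#' @param dt,tf integration step and total bridge time.
#' @param seed base seed; trajectory i uses `seed + i`.
#' @param frame_stride,stride,n_proj see [run_bridge()] and [build_report()].
#' @param k_complex crossing-number threshold for "complex intermediates".
#' @return a list with `fraction_visiting` (named, by label), `frac_complex`,
#'   `frac_nontrivial_intermediate`, `n_traj`, and `reports`.
#' @export
ensemble_experiment <- function(pairs, n_traj, params, dt = 1e-4, tf = 2,
                                seed = 1L, frame_stride = 100L, stride = 1L,
                                n_proj = 0L, k_complex = 6L) {
  stopifnot(n_traj >= 1, length(pairs) >= 1)
  reports <- vector("list", n_traj)
  for (i in seq_len(n_traj)) {
    pr <- pairs[[(i - 1L) %% length(pairs) + 1L]]
    traj <- run_bridge(pr$initial, pr$final, params, dt = dt, tf = tf,
                       conditioning = "bridge_permuted", seed = seed + i,
                       frame_stride = frame_stride)
    set.seed(seed + 500000L + i) # projection directions for the report
    reports[[i]] <- build_report(traj, stride = stride, n_proj = n_proj)
  }
  labels <- sort(unique(unlist(lapply(reports, function(r) r$summary$labels_visited))))
  visited <- vapply(labels, function(lb)
    mean(vapply(reports, function(r) lb %in% r$summary$labels_visited, logical(1))),
    numeric(1))
  intermediates <- lapply(reports, function(r) {
    tab <- r$table
    inner <- tab$knot[-c(1L, nrow(tab))]
    unique(inner)
  })
  endpoint_labels <- lapply(reports, function(r)
    r$table$knot[c(1L, nrow(r$table))])
  frac_complex <- mean(mapply(function(inter, ends) {
    ncr <- label_crossings(inter)
    any(inter == "unresolved") || any(ncr >= k_complex, na.rm = TRUE)
  }, intermediates, endpoint_labels))
  frac_nontrivial <- mean(vapply(seq_len(n_traj), function(i) {
    inter <- intermediates[[i]]
    any(!(inter %in% c(endpoint_labels[[i]])))
  }, logical(1)))
  list(fraction_visiting = stats::setNames(visited, labels),
       frac_complex = frac_complex,
       frac_nontrivial_intermediate = frac_nontrivial,
       n_traj = n_traj, reports = reports)
}
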