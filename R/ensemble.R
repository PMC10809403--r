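#' Minimal periodic self-image distance (halved)
#'
#' The "minimal distance to the box wall" diagnostic: the smallest distance
#' between any atom of the molecule and any atom of its periodic images
#' (minimum over all atom pairs, self-pairs included, and the 26 nonzero
#' neighbour-cell translations), halved. Translation-invariant by
#' construction; for a single atom it equals L/2 exactly.
#'
#' @param frame A periodic [charge_system()], or a list/matrix of positions
#'   with a `box_edge` attribute.
#' @param box_edge Cubic box edge in nm (overrides the frame's).
#' @return Distance in nm. A molecule whose extent reaches the box edge
#'   (self-overlapping images) returns 0 with a warning.
#' @export
min_image_self_distance <- function(frame, box_edge = NULL) {
  if (inherits(frame, "charge_system")) {
    pos <- frame$positions
    if (is.null(box_edge)) box_edge <- frame$box_edge
  } else {
    pos <- as.matrix(frame)
    if (is.null(box_edge)) box_edge <- attr(frame, "box_edge")
  }
  if (is.null(box_edge)) stop("a periodic frame (box edge) is required")
  L <- box_edge
  n <- nrow(pos)
  if (n < 1) stop("frame has no atoms")
  sh <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  sh <- sh[rowSums(abs(sh)) > 0, , drop = FALSE] * L
  dmin <- Inf
  for (s in seq_len(nrow(sh))) {
    dx <- outer(pos[, 1], pos[, 1], `-`) - sh[s, 1]
    dy <- outer(pos[, 2], pos[, 2], `-`) - sh[s, 2]
    dz <- outer(pos[, 3], pos[, 3], `-`) - sh[s, 3]
    dmin <- min(dmin, sqrt(min(dx^2 + dy^2 + dz^2)))
  }
  if (dmin <= 0) {
    warning("molecule extent reaches the box edge: periodic self-overlap")
    return(0)
  }
  dmin / 2
}

#' Wall-distance summary over trajectories
#'
#' Summarizes [min_image_self_distance()] over a set of replica trajectories:
#' `init` is the value on the initial structure (first frame of the first
#' replica), `avg` the mean of per-frame values over all post-equilibration
#' frames and replicas, `min` the global minimum. With
#' `avg_mode = "replica_min"`, `avg` instead averages the per-replica minima.
#'
#' @param trajectories A list of replicas, each a list of periodic frames
#'   (see [min_image_self_distance()]).
#' @param discard_frac Fraction of initial frames per replica discarded as
#'   equilibration before computing `avg` and `min` (default 0).
#' @param avg_mode `"frames"` (default: mean over all frames) or
#'   `"replica_min"` (mean of per-replica minima).
#' @return Named numeric vector `c(init, avg, min)` in nm.
#' @export
wall_distance_summary <- function(trajectories, discard_frac = 0,
                                  avg_mode = c("frames", "replica_min")) {
  avg_mode <- match.arg(avg_mode)
  if (length(trajectories) < 1 || length(trajectories[[1]]) < 1)
    stop("need at least one replica with at least one frame")
  stopifnot(discard_frac >= 0, discard_frac < 1)
  init <- min_image_self_distance(trajectories[[1]][[1]])
  per_rep <- lapply(trajectories, function(rep) {
    nf <- length(rep)
    keep <- seq.int(floor(discard_frac * nf) + 1, nf)
    vapply(rep[keep], min_image_self_distance, numeric(1))
  })
  allv <- unlist(per_rep)
  avg <- if (avg_mode == "frames") mean(allv)
  else mean(vapply(per_rep, min, numeric(1)))
  c(init = init, avg = avg, min = min(allv))
}

#' End-to-end distance and vector
#'
#' Euclidean distance between two anchor atoms (conventionally the nitrogen of
#' the first residue and the carboxyl carbon of the last); the molecule is
#' assumed intact (no periodic wrapping is applied).
#'
#' @param frame A [charge_system()] or position matrix.
#' @param n_index,c_index Atom indices of the two anchors.
#' @return For `end_to_end`, the distance in nm; for `end_to_end_vector`, the
#'   N-to-C vector.
#' @export
end_to_end <- function(frame, n_index, c_index) {
  sqrt(sum(end_to_end_vector(frame, n_index, c_index)^2))
}

#' @rdname end_to_end
#' @export
end_to_end_vector <- function(frame, n_index, c_index) {
  pos <- if (inherits(frame, "charge_system")) frame$positions
  else as.matrix(frame)
  n <- nrow(pos)
  if (n_index < 1 || n_index > n || c_index < 1 || c_index > n)
    stop("anchor index out of range (1..", n, ")")
  pos[c_index, ] - pos[n_index, ]
}

.as_replica_list <- function(distances) {
  if (is.data.frame(distances)) {
    if (!all(c("replica", "value_nm") %in% names(distances)))
      stop("distance data frame needs columns replica, value_nm")
    split(distances$value_nm, distances$replica)
  } else if (is.list(distances)) {
    distances
  } else {
    list(as.numeric(distances))
  }
}

#' Free-energy profile along a distance coordinate
#'
#' Per-replica Boltzmann inversion of the population histogram:
#' `dG_r(bin) = -k_B T log(p_r(bin))` with empty bins absent (NA), the
#' replica-mean profile anchored so its minimum is zero, and 95% confidence
#' intervals `1.96 * SE` over replicas.
#'
#' @param distances Per-replica samples: a data frame with columns `replica`,
#'   `value_nm` (e.g. from [read_distance_series()] or
#'   [two_state_distance_sampler()]), or a list of numeric vectors.
#' @param bins Either a single number of uniform bins or a vector of breaks.
#' @param temperature Temperature in K (default 300).
#' @param range Optional c(min, max) range for the bins; defaults to the data
#'   range.
#' @return A list of class `free_energy_profile`: `bin_centers`, `dG` (mean,
#'   anchored), `ci95`, `per_replica` (matrix bins x replicas, same anchor),
#'   `n_replicas`, `temperature`.
#' @export
free_energy_profile <- function(distances, bins = 40, temperature = 300,
                                range = NULL) {
  reps <- .as_replica_list(distances)
  vals <- unlist(reps)
  if (length(vals) == 0 || all(!is.finite(vals)))
    stop("no distance samples supplied")
  if (length(bins) == 1) {
    if (is.null(range)) range <- base::range(vals)
    breaks <- seq(range[1], range[2], length.out = bins + 1)
  } else breaks <- bins
  if (diff(breaks[1:2]) <= 0) stop("bin width must be positive")
  kT <- .K_B * temperature
  per <- vapply(reps, function(v) {
    h <- .bin_counts(v, breaks)
    p <- h / sum(h)
    ifelse(h > 0, -kT * log(p), NA_real_)
  }, numeric(length(breaks) - 1))
  per <- matrix(per, nrow = length(breaks) - 1)
  if (all(is.na(per))) stop("all histogram bins are empty")
  mean_dg <- rowMeans(per, na.rm = TRUE)
  nrep_bin <- rowSums(!is.na(per))
  se <- apply(per, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  })
  shift <- min(mean_dg, na.rm = TRUE)
  structure(
    list(bin_centers = (head(breaks, -1) + tail(breaks, -1)) / 2,
         dG = mean_dg - shift, ci95 = 1.96 * se,
         per_replica = per - shift, n_replicas = length(reps),
         n_in_bin = nrep_bin, temperature = temperature),
    class = "free_energy_profile")
}

.bin_counts <- function(v, breaks) {
  v <- v[v >= breaks[1] & v <= breaks[length(breaks)]]
  if (length(v) == 0) return(numeric(length(breaks) - 1))
  tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE),
                length(breaks) - 1),
           nbins = length(breaks) - 1)
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf("free-energy profile: %d bins, %d replicas, T = %g K\n",
              length(x$bin_centers), x$n_replicas, x$temperature))
  invisible(x)
}

#' Basin free-energy difference from population counts
#'
#' Counts samples in two disjoint distance windows per replica and reports
#' `dG_AB = -k_B T log(N_A / N_B)` (positive when basin A is less populated),
#' its replica mean, and the 95% confidence interval. Replicas with a zero
#' count in either window are excluded with a warning. With a `reference`
#' series, significance is whether zero falls outside the 95% CI of the
#' difference to the reference; without one, whether zero falls outside the
#' own CI.
#'
#' @param distances Per-replica samples (see [free_energy_profile()]).
#' @param range_A,range_B Disjoint half-open windows `c(lo, hi)` in nm.
#'   Defaults: A = salt-bridge contact `[0.4, 0.9)`, B = extended
#'   `[1.8, 2.6)` (implementation defaults, not literature values).
#' @param temperature Temperature in K (default 300).
#' @param reference Optional second distance set to compare against.
#' @return A list of class `basin_comparison` with `dG_AB`, `ci95`,
#'   `per_replica`, `counts` (matrix), `significant`, and the windows.
#' @export
basin_delta_g <- function(distances, range_A = c(0.4, 0.9),
                          range_B = c(1.8, 2.6), temperature = 300,
                          reference = NULL) {
  if (max(range_A[1], range_B[1]) < min(range_A[2], range_B[2]))
    stop("basin windows must be disjoint")
  reps <- .as_replica_list(distances)
  nA <- vapply(reps, function(v) sum(v >= range_A[1] & v < range_A[2]),
               numeric(1))
  nB <- vapply(reps, function(v) sum(v >= range_B[1] & v < range_B[2]),
               numeric(1))
  ok <- nA > 0 & nB > 0
  if (!any(ok)) stop("no replica has nonzero counts in both windows")
  if (any(!ok))
    warning(sum(!ok), " replica(s) excluded (zero count in a window)")
  kT <- .K_B * temperature
  per <- -kT * log(nA[ok] / nB[ok])
  m <- mean(per)
  ci <- if (sum(ok) > 1) 1.96 * sd(per) / sqrt(sum(ok)) else NA_real_
  if (!is.null(reference)) {
    ref <- basin_delta_g(reference, range_A, range_B, temperature)
    dd <- m - ref$dG_AB
    cid <- 1.96 * sqrt((ci / 1.96)^2 + (ref$ci95 / 1.96)^2)
    significant <- is.finite(cid) && (dd - cid > 0 || dd + cid < 0)
  } else {
    significant <- is.finite(ci) && (m - ci > 0 || m + ci < 0)
  }
  structure(list(dG_AB = m, ci95 = ci, per_replica = per,
                 counts = cbind(A = nA, B = nB), significant = significant,
                 range_A = range_A, range_B = range_B,
                 temperature = temperature),
            class = "basin_comparison")
}

#' @export
print.basin_comparison <- function(x, ...) {
  cat(sprintf("dG_AB = %.3f +/- %.3f kJ/mol (%d replicas)%s\n",
              x$dG_AB, x$ci95, length(x$per_replica),
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Orientation map on an equal-area sphere partition
#'
#' Bins unit direction vectors (e.g. peptide N-to-C vectors) on an equal-area
#' partition of the sphere: uniform in `cos(theta)` (bands) times uniform in
#' `phi` (sectors), so every bin subtends the same solid angle and an
#' isotropic ensemble is uniform across bins. Also reports a face-alignment
#' score: the fraction of vectors within angular radius `rho` of any of the
#' six cube-face directions (+x, -x, +y, -y, +z, -z), together with its
#' isotropic expectation `3 * (1 - cos(rho))`.
#'
#' @param vectors Numeric matrix (n x 3) of direction vectors (need not be
#'   normalized; zero-length vectors are skipped with a warning).
#' @param n_bands Number of equal-area bands in `cos(theta)` (default 12).
#' @param n_sectors Number of sectors in `phi` (default 24).
#' @param rho Angular radius (radians) of the face-alignment caps
#'   (default `pi/9`, 20 degrees).
#' @return A list of class `orientation_map`: `counts` (bands x sectors),
#'   `face_alignment`, `isotropic_expectation`, `n`, plus the binning
#'   definition.
#' @export
orientation_map <- function(vectors, n_bands = 12, n_sectors = 24,
                            rho = pi / 9) {
  v <- as.matrix(vectors)
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm < 1e-12)) {
    warning(sum(nrm < 1e-12), " zero-length vector(s) skipped")
    v <- v[nrm >= 1e-12, , drop = FALSE]
    nrm <- nrm[nrm >= 1e-12]
  }
  if (nrow(v) == 0) stop("no nonzero vectors")
  u <- v / nrm
  z <- pmin(pmax(u[, 3], -1), 1)
  band <- pmin(floor((z + 1) / 2 * n_bands) + 1, n_bands)
  phi <- atan2(u[, 2], u[, 1]) %% (2 * pi)
  sector <- pmin(floor(phi / (2 * pi) * n_sectors) + 1, n_sectors)
  counts <- matrix(0L, n_bands, n_sectors)
  for (i in seq_along(band))
    counts[band[i], sector[i]] <- counts[band[i], sector[i]] + 1L
  cosrho <- cos(rho)
  aligned <- apply(abs(u), 1, max) >= cosrho
  structure(list(counts = counts, n = nrow(u),
                 face_alignment = mean(aligned),
                 isotropic_expectation = 3 * (1 - cosrho),
                 n_bands = n_bands, n_sectors = n_sectors, rho = rho),
            class = "orientation_map")
}

#' @export
print.orientation_map <- function(x, ...) {
  cat(sprintf(
    "orientation map: %d vectors on %dx%d equal-area bins\n",
    x$n, x$n_bands, x$n_sectors))
  cat(sprintf("  face-alignment score %.3f (isotropic expectation %.3f)\n",
              x$face_alignment, x$isotropic_expectation))
  invisible(x)
}

#' Box-size series: differences to the largest box
#'
#' For an observable measured in several box sizes with replicate values,
#' reports per box the replica mean, the difference to the largest box, a 95%
#' confidence interval on that difference (normal approximation,
#' `1.96 * sqrt(SE_box^2 + SE_largest^2)`), and a significance flag (zero
#' outside the CI). The difference for the largest box is identically 0.
#'
#' @param data Data frame with columns `box_edge`, `replica`, `value`.
#' @return A data frame of class `box_series_report` with one row per box:
#'   `box_edge`, `n_replicas`, `mean`, `diff_to_largest`, `ci95`,
#'   `significant`.
#' @export
box_series <- function(data) {
  if (!all(c("box_edge", "replica", "value") %in% names(data)))
    stop("`data` needs columns box_edge, replica, value")
  boxes <- sort(unique(data$box_edge))
  if (length(boxes) < 2) stop("need at least 2 box sizes")
  stats_1 <- function(L) {
    v <- data$value[data$box_edge == L]
    c(n = length(v), mean = mean(v),
      se = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_)
  }
  st <- t(vapply(boxes, stats_1, numeric(3)))
  largest <- nrow(st)
  diff <- st[, "mean"] - st[largest, "mean"]
  diff[largest] <- 0
  ci <- 1.96 * sqrt(st[, "se"]^2 + st[largest, "se"]^2)
  ci[largest] <- 0
  single <- any(st[, "n"] < 2)
  if (single)
    warning("single-replica box(es): differences reported without CI")
  out <- data.frame(box_edge = boxes, n_replicas = as.integer(st[, "n"]),
                    mean = st[, "mean"], diff_to_largest = diff,
                    ci95 = ci,
                    significant = is.finite(ci) & ci > 0 &
                      (diff - ci > 0 | diff + ci < 0))
  out$significant[largest] <- FALSE
  class(out) <- c("box_series_report", "data.frame")
  out
}

#' Discard equilibration frames
#'
#' Drops the first `frac` fraction of each replica's samples (in frame order),
#' mirroring the usual discard of the initial part of each trajectory.
#'
#' @param distances Data frame with `replica`, `frame`, `value_nm`.
#' @param frac Fraction to discard (default 0.1).
#' @return The filtered data frame.
#' @export
discard_equilibration <- function(distances, frac = 0.1) {
  stopifnot(frac >= 0, frac < 1)
  do.call(rbind, lapply(split(distances, distances$replica), function(d) {
    d <- d[order(d$frame), ]
    d[seq.int(floor(frac * nrow(d)) + 1, nrow(d)), ]
  }))
}
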