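#' Radial distribution function around a reference atom
#'
#' Histogram of centre-to-point distances over frames, normalised per frame
#' by the spherical shell volume `4 pi r^2 dr` and the bulk number density:
#' `g(r) = <count in shell> / (rho * 4 pi r^2 dr)`. Also returns the
#' integrated RDF `n(r)`, the mean number of points within `r` of the centre
#' (unnormalised), whose value at the first minimum of `g` is the
#' first-solvation-shell occupancy.
#'
#' @param snapshots a `hydration_snapshots` (see [sample_hydration_shell]) or
#'   a list of point matrices; in the latter case supply `centers`.
#' @param r_max histogram range, A.
#' @param bin_width A (> 0).
#' @param density_bulk number density used for normalisation, A^-3. When
#'   `NULL`, estimated from the mean density in the outer 20% of `r_max`.
#' @param centers per-frame reference positions (matrix, one row per frame, or
#'   one row recycled) when `snapshots` is a bare list.
#' @return an `rdf_result`: list with `bin_centers`, `g`, `n_integrated`,
#'   `n_frames`, `density_bulk`.
#' @export
rdf <- function(snapshots, r_max = 8, bin_width = 0.1, density_bulk = NULL,
                centers = NULL) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (inherits(snapshots, "hydration_snapshots")) {
    frames <- snapshots$frames
    centers <- snapshots$centers
  } else {
    frames <- snapshots
    if (is.null(centers)) stop("centers must be supplied for a bare frame list")
    centers <- matrix(centers, ncol = 3)
  }
  nf <- length(frames)
  if (nf < 1) stop("need at least one frame")
  if (nrow(centers) == 1) centers <- centers[rep(1, nf), , drop = FALSE]
  edges <- seq(0, r_max, by = bin_width)
  if (max(edges) < r_max) edges <- c(edges, max(edges) + bin_width)
  nb <- length(edges) - 1
  counts <- numeric(nb)
  for (f in seq_len(nf)) {
    pts <- frames[[f]]
    if (nrow(pts) == 0) next
    dist <- sqrt(rowSums(sweep(pts, 2, centers[f, ])^2))
    dist <- dist[dist < max(edges)]
    if (length(dist))
      counts <- counts + tabulate(findInterval(dist, edges,
                                               rightmost.closed = TRUE), nb)
  }
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  shell_vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  per_frame <- counts / nf
  if (is.null(density_bulk)) {
    outer <- mids >= 0.8 * r_max
    density_bulk <- sum(per_frame[outer]) / sum(shell_vol[outer])
  }
  g <- if (density_bulk > 0) per_frame / (shell_vol * density_bulk)
       else rep(0, nb)
  structure(list(bin_centers = mids, g = g, n_integrated = cumsum(per_frame),
                 n_frames = nf, density_bulk = density_bulk),
            class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  cat(sprintf("<rdf_result> %d bins to %.2f A over %d frames (bulk density %.4g A^-3)\n",
              length(x$g), max(x$bin_centers), x$n_frames, x$density_bulk))
  invisible(x)
}

#' First solvation shell occupancy
#'
#' Locates the first minimum of the (lightly smoothed) RDF after its first
#' peak and integrates the RDF to that radius. A curve with no resolvable
#' peak-then-minimum structure (e.g. an ideal gas) yields an explicit
#' "no shell" outcome rather than an error.
#'
#' @param rdf_result an [rdf] result.
#' @param peak_threshold minimum smoothed `g` for a maximum to count as the
#'   first shell peak.
#' @param smooth_k moving-average window (bins, odd).
#' @return list with `shell` (logical), `r_min_first` (A) and `count`
#'   (occupancy) when a shell is found.
#' @export
first_shell_count <- function(rdf_result, peak_threshold = 1.3, smooth_k = 3) {
  g <- rdf_result$g
  nb <- length(g)
  k <- max(1L, smooth_k - (1 - smooth_k %% 2)) # force odd
  gs <- as.numeric(stats::filter(g, rep(1 / k, k), sides = 2))
  gs[is.na(gs)] <- g[is.na(gs)]
  # first local maximum above threshold
  peak <- NA_integer_
  for (i in 2:(nb - 1)) {
    if (gs[i] >= gs[i - 1] && gs[i] >= gs[i + 1] && gs[i] > peak_threshold) {
      peak <- i
      break
    }
  }
  if (is.na(peak))
    return(list(shell = FALSE, reason = "no resolvable first peak"))
  # walk outward tracking the running minimum; stop once g recovers by 25%
  # of the peak-to-minimum drop (start of the second shell or bulk)
  runmin <- gs[peak]
  m <- peak
  for (j in (peak + 1):nb) {
    if (gs[j] < runmin) {
      runmin <- gs[j]
      m <- j
    } else if (gs[j] > runmin + 0.25 * (gs[peak] - runmin)) {
      break
    }
  }
  if (m == peak)
    return(list(shell = FALSE, reason = "no minimum after the first peak"))
  list(shell = TRUE, r_min_first = rdf_result$bin_centers[m],
       count = rdf_result$n_integrated[m])
}

#' Distance time courses with mean and fluctuation bands
#'
#' Per-trajectory distance traces for one atom pair, their pointwise mean
#' across trajectories, and the root-mean-square fluctuation about the
#' combined time-and-trajectory mean — the representation used for
#' H-bond-distance time courses over independent simulation replicas.
#'
#' @param trajectories a list of `xyz_trajectory` objects (see [read_xyz]),
#'   or a list of precomputed numeric distance series.
#' @param atom_pair two atom indices or names (ignored for precomputed
#'   series).
#' @return a `timecourse`: `traces` (time x trajectory matrix, A),
#'   `mean_trace`, `rmsf_trace`, `n_trajectories`.
#' @export
distance_timecourse <- function(trajectories, atom_pair = NULL) {
  if (length(trajectories) < 1) stop("need at least one trajectory")
  series <- lapply(trajectories, function(tr) {
    if (is.numeric(tr)) return(as.numeric(tr))
    stopifnot(inherits(tr, "xyz_trajectory"))
    if (is.null(atom_pair)) stop("atom_pair required for coordinate trajectories")
    vapply(tr$frames, function(fr)
      distance_cv(fr, atom_pair[1], atom_pair[2], labels = tr$labels,
                  gradient = FALSE)$value, numeric(1))
  })
  lens <- lengths(series)
  if (length(unique(lens)) > 1) {
    warning("trajectories have unequal lengths; truncating to the shortest")
    series <- lapply(series, function(s) s[seq_len(min(lens))])
  }
  traces <- do.call(cbind, series)
  grand <- mean(traces)
  structure(list(traces = traces,
                 mean_trace = rowMeans(traces),
                 rmsf_trace = sqrt(rowMeans((traces - grand)^2)),
                 n_trajectories = ncol(traces)),
            class = "timecourse")
}
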