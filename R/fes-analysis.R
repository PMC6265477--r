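#' Free energy grids
#'
#' A `fes_grid` holds free energies (kcal/mol) on a regular 1-3D grid over
#' named collective variables, normalised so the global minimum is zero.
#' Values are stored in an array whose first axis varies fastest (R order);
#' linear node indices follow that convention.
#'
#' @name fes_grid
NULL

.new_fes_grid <- function(axes, values, origin_log_hash = "") {
  stopifnot(all(axes$max > axes$min), all(axes$n >= 2))
  arr <- array(values, dim = axes$n)
  if (any(!is.finite(arr))) stop("free energies must be finite")
  arr <- arr - min(arr)
  structure(list(axes = axes, values = arr,
                 origin_log_hash = origin_log_hash),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat("<fes_grid>", paste(x$axes$name, collapse = " x "),
      paste0("(", paste(x$axes$n, collapse = " x "), " points), max F = "),
      sprintf("%.3f kcal/mol\n", max(x$values)))
  invisible(x)
}

.axis_seq <- function(axes, i) seq(axes$min[i], axes$max[i], length.out = axes$n[i])

.axes_grid_points <- function(axes) {
  seqs <- lapply(seq_len(nrow(axes)), function(i) .axis_seq(axes, i))
  as.matrix(do.call(expand.grid, seqs))
}

#' @rdname fes_grid
#' @param fes a `fes_grid`.
#' @export
fes_points <- function(fes) {
  p <- .axes_grid_points(fes$axes)
  colnames(p) <- fes$axes$name
  p
}

# linear node index (1-based, first axis fastest) of the grid point nearest s
.nearest_node <- function(fes, s) {
  if (length(s) == 1 && is.numeric(s) && s == round(s) &&
      s >= 1 && s <= length(fes$values) && length(fes$axes$n) > 1)
    stop("ambiguous node: give CV coordinates or use node indices explicitly")
  idx <- vapply(seq_len(nrow(fes$axes)), function(i)
    which.min(abs(.axis_seq(fes$axes, i) - s[i])), integer(1))
  .sub_to_lin(fes, idx)
}

.sub_to_lin <- function(fes, idx) {
  n <- fes$axes$n
  lin <- idx[1]
  if (length(n) > 1) for (j in 2:length(n)) lin <- lin + (idx[j] - 1) * prod(n[1:(j - 1)])
  as.integer(lin)
}

.lin_to_sub <- function(fes, lin) {
  n <- fes$axes$n
  idx <- integer(length(n))
  rem <- lin - 1L
  for (j in seq_along(n)) {
    idx[j] <- rem %% n[j] + 1L
    rem <- rem %/% n[j]
  }
  idx
}

.node_coords <- function(fes, lin) {
  idx <- .lin_to_sub(fes, lin)
  vapply(seq_along(idx), function(j) .axis_seq(fes$axes, j)[idx[j]], numeric(1))
}

#' Default reconstruction axes for a hills log
#'
#' The bounding box of the hill centres padded by three widths on each side,
#' at the stated resolution.
#'
#' @param log a [hills_log].
#' @param resolution grid spacing, A (default 0.02).
#' @return an axes data frame (`name`, `min`, `max`, `n`).
#' @export
default_axes <- function(log, resolution = 0.02) {
  if (n_hills(log) == 0) stop("cannot infer axes from an empty log")
  pad <- 3 * apply(log$sigmas, 2, max)
  lo <- apply(log$centers, 2, min) - pad
  hi <- apply(log$centers, 2, max) + pad
  data.frame(name = log$cv_names, min = lo, max = hi,
             n = pmax(2L, as.integer(ceiling((hi - lo) / resolution)) + 1L),
             stringsAsFactors = FALSE)
}

.as_axes <- function(axes, cv_names) {
  axes <- as.data.frame(axes)
  if (is.null(axes$name)) axes$name <- cv_names
  stopifnot(all(c("name", "min", "max", "n") %in% names(axes)))
  axes[c("name", "min", "max", "n")]
}

#' Reconstruct a free energy surface from a hills log
#'
#' The standard metadynamics estimator: `F(s) = -V_bias(s)` on a regular
#' grid, shifted so its minimum is zero. Supports 1-3 CVs. Warns when the
#' axes exclude more than 1% of the hill centres; an empty log gives a flat
#' zero surface.
#'
#' With `average_from` set, the estimate is instead the average of the
#' running `-V_bias` over the deposition history from that fraction onwards
#' (implemented as per-hill weights): in fixed-height metadynamics the
#' instantaneous bias oscillates around the true surface with an amplitude of
#' several hill heights once the wells are filled, and averaging over the
#' post-fill history suppresses that ripple. Use the default (`NULL`, the
#' final accumulated bias) for diagnostics and the averaged estimator for
#' quantitative barrier recovery.
#'
#' @param log a [hills_log].
#' @param axes an axes data frame (`name`, `min`, `max`, `n`); defaults to
#'   [default_axes].
#' @param resolution used when `axes` is `NULL`.
#' @param average_from `NULL` for the final-bias estimator, or a fraction in
#'   `[0, 1)`: average the running estimate over the last
#'   `(1 - average_from)` of the deposition history.
#' @return a [fes_grid].
#' @export
reconstruct_fes <- function(log, axes = NULL, resolution = 0.02,
                            average_from = NULL) {
  if (is.null(axes)) axes <- default_axes(log, resolution)
  axes <- .as_axes(axes, log$cv_names)
  if (nrow(axes) != length(log$cv_names))
    stop("axes must cover every CV of the log")
  if (!is.null(average_from)) {
    if (average_from < 0 || average_from >= 1)
      stop("average_from must be in [0, 1)")
    N <- n_hills(log)
    N0 <- floor(average_from * N)
    i <- seq_len(N)
    # hill i appears in the running bias for snapshots N0+1 .. N at or after
    # its own deposition; its weight is the fraction of averaged snapshots
    # that include it
    w <- pmin(1, (N - pmax(i, N0 + 1) + 1) / (N - N0))
    log <- hills_log(log$cv_names, centers = log$centers, sigmas = log$sigmas,
                     heights = log$heights * w, times = log$times,
                     walkers = log$walkers)
  }
  pts <- .axes_grid_points(axes)
  if (n_hills(log) > 0) {
    inside <- rep(TRUE, n_hills(log))
    for (j in seq_len(ncol(log$centers)))
      inside <- inside & log$centers[, j] >= axes$min[j] &
                         log$centers[, j] <= axes$max[j]
    if (mean(!inside) > 0.01)
      warning(sprintf("axes exclude %.1f%% of hill centres",
                      100 * mean(!inside)))
    f <- -bias_energy(log, pts)
  } else {
    f <- rep(0, nrow(pts))
  }
  .new_fes_grid(axes, f, origin_log_hash = .log_hash(log))
}

.log_hash <- function(log) {
  v <- c(n_hills(log), log$heights, as.numeric(log$centers))
  sprintf("hills:%d:%.6e", n_hills(log), sum(v))
}

#' Extract a 2D slice from a 3D free energy surface
#'
#' Nearest-plane extraction along the named axis, re-normalised so the
#' slice's own minimum is zero; the offset between the slice minimum and the
#' global surface minimum is attached as attribute `global_offset`.
#'
#' @param fes a 3D [fes_grid].
#' @param axis_name which axis to fix.
#' @param value position along that axis (inside its range).
#' @return a 2D [fes_grid].
#' @export
slice_fes_2d <- function(fes, axis_name, value) {
  if (nrow(fes$axes) != 3) stop("slice_fes_2d needs a 3D surface")
  k <- match(axis_name, fes$axes$name)
  if (is.na(k))
    stop("unknown axis '", axis_name, "'; known axes: ",
         paste(fes$axes$name, collapse = ", "))
  if (value < fes$axes$min[k] || value > fes$axes$max[k])
    stop("slice value outside the axis range")
  i <- which.min(abs(.axis_seq(fes$axes, k) - value))
  idx <- list(quote(expr =), quote(expr =), quote(expr =))
  idx[[k]] <- i
  plane <- do.call(`[`, c(list(fes$values), idx, list(drop = TRUE)))
  off <- min(plane)
  out <- .new_fes_grid(fes$axes[-k, , drop = FALSE], plane,
                       origin_log_hash = fes$origin_log_hash)
  attr(out, "global_offset") <- off
  attr(out, "slice_at") <- .axis_seq(fes$axes, k)[i]
  out
}

.neighbour_offsets <- function(d) {
  g <- as.matrix(do.call(expand.grid, rep(list(-1:1), d)))
  g[rowSums(g != 0) > 0, , drop = FALSE]
}

#' Locate free energy basins
#'
#' Strict local minima of the grid under king-move adjacency (all `3^d - 1`
#' unit-offset neighbours); connected plateaus of equal value that are not
#' exceeded by any neighbour are merged and reported once. A flat surface
#' yields an empty result with a message.
#'
#' @param fes a [fes_grid].
#' @return a tibble with `node` (linear index), `energy` and the basin CV
#'   coordinates, sorted by energy.
#' @export
find_basins <- function(fes) {
  v <- fes$values
  n <- fes$axes$n
  d <- length(n)
  if (diff(range(v)) == 0) {
    message("flat surface: no basins")
    return(tibble::tibble(node = integer(), energy = numeric()))
  }
  offs <- .neighbour_offsets(d)
  sub <- as.matrix(do.call(expand.grid, lapply(n, seq_len)))
  le_all <- rep(TRUE, length(v))   # value <= all neighbours
  lt_any <- rep(FALSE, length(v))  # value < at least one neighbour
  vlin <- as.vector(v)
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(sub, 2, offs[o, ], "+")
    ok <- rep(TRUE, nrow(nb))
    for (j in seq_len(d)) ok <- ok & nb[, j] >= 1 & nb[, j] <= n[j]
    lin <- rep(NA_integer_, nrow(nb))
    lin[ok] <- as.integer((nb[ok, , drop = FALSE] - 1) %*%
                            cumprod(c(1, n[-d]))) + 1L
    cmp <- vlin[lin[ok]]
    here <- vlin[ok]
    le_here <- le_all[ok]
    le_here[cmp < here] <- FALSE
    le_all[ok] <- le_here
    lt_here <- lt_any[ok]
    lt_here[cmp > here] <- TRUE
    lt_any[ok] <- lt_here
  }
  cand <- which(le_all & lt_any)
  if (length(cand) == 0) {
    message("no strict basins found")
    return(tibble::tibble(node = integer(), energy = numeric()))
  }
  # merge plateau minima: group candidates adjacent in grid with equal value
  keep <- logical(length(cand))
  seen <- rep(FALSE, length(v))
  for (cidx in order(vlin[cand], cand)) {
    node <- cand[cidx]
    if (seen[node]) next
    # flood fill over equal-valued candidate neighbours
    comp <- node
    queue <- node
    seen[node] <- TRUE
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      us <- .lin_to_sub(fes, u)
      for (o in seq_len(nrow(offs))) {
        nb <- us + offs[o, ]
        if (any(nb < 1 | nb > n)) next
        l <- .sub_to_lin(fes, nb)
        if (!seen[l] && l %in% cand && vlin[l] == vlin[node]) {
          seen[l] <- TRUE
          comp <- c(comp, l)
          queue <- c(queue, l)
        }
      }
    }
    keep[cidx] <- TRUE
  }
  nodes <- cand[keep]
  coords <- matrix(unlist(lapply(nodes, function(l) .node_coords(fes, l))),
                   ncol = d, byrow = TRUE)
  colnames(coords) <- fes$axes$name
  out <- tibble::tibble(node = as.integer(nodes), energy = vlin[nodes])
  out <- cbind(out, tibble::as_tibble(coords))
  tibble::as_tibble(out[order(out$energy), ])
}

#' Minimum free energy (bottleneck) path between two basins
#'
#' Among all grid-adjacent paths (king moves, diagonal steps allowed) from
#' the reactant node to the product node, finds one minimising the maximum
#' free energy en route (Dijkstra on the bottleneck metric; ties broken by
#' hop count, then by predecessor order). The barrier is measured from the
#' minimum of the reactant basin (steepest-descent from the reactant node).
#'
#' @param fes a [fes_grid]; `NA`/non-finite values act as masked regions.
#' @param reactant_node,product_node CV coordinate vectors (nearest grid node
#'   is used) or linear node indices wrapped in [I()].
#' @return a `path_result`: `nodes` (linear indices), `free_energies`,
#'   `ts_index`, `barrier` (kcal/mol), `reactant_node`, `product_node`,
#'   `reactant_min_node`.
#' @export
minimax_path <- function(fes, reactant_node, product_node) {
  rn <- if (inherits(reactant_node, "AsIs")) as.integer(reactant_node)
        else .nearest_node(fes, reactant_node)
  pn <- if (inherits(product_node, "AsIs")) as.integer(product_node)
        else .nearest_node(fes, product_node)
  res <- bottleneck_path_cpp(as.vector(fes$values), as.integer(fes$axes$n),
                             rn - 1L, pn - 1L)
  nodes <- res$nodes
  fe <- as.vector(fes$values)[nodes]
  rmin <- grid_descend_cpp(as.vector(fes$values), as.integer(fes$axes$n),
                           rn - 1L)
  barrier <- max(fe) - as.vector(fes$values)[rmin]
  structure(list(nodes = nodes, free_energies = fe,
                 ts_index = which.max(fe), barrier = barrier,
                 reactant_node = rn, product_node = pn,
                 reactant_min_node = rmin),
            class = "path_result")
}

#' @export
print.path_result <- function(x, ...) {
  cat(sprintf("<path_result> %d nodes, barrier %.3f kcal/mol (TS at node %d of %d)\n",
              length(x$nodes), x$barrier, x$ts_index, length(x$nodes)))
  invisible(x)
}

#' Mechanism ordering report
#'
#' For each CV, the fraction of its reactant-to-product displacement that is
#' complete at the transition state of a [minimax_path], clipped to `[0, 1]`.
#' The ordering sentence ranks CVs by progress. The transition-state
#' tightness call follows phosphoryl-transfer taxonomy: when an axis named
#' like "phosphoryl transfer" is present, its TS progress within the central
#' 25% of the reactant-to-product range is called `tight` (associative,
#' SN2-like: the nucleophile binds before the leaving group departs);
#' progress beyond the central 60% is `loose`; otherwise `indeterminate`.
#'
#' @param fes the [fes_grid] the path was extracted from.
#' @param path a `path_result` from [minimax_path].
#' @return a `mechanism_report`: tibble `progress` (cv, reactant, ts, product,
#'   progress), `ordering` sentence, `tightness`.
#' @export
mechanism_order <- function(fes, path) {
  d <- nrow(fes$axes)
  s_r <- .node_coords(fes, path$nodes[1])
  s_p <- .node_coords(fes, path$nodes[length(path$nodes)])
  s_ts <- .node_coords(fes, path$nodes[path$ts_index])
  disp <- s_p - s_r
  prog <- rep(NA_real_, d)
  for (j in seq_len(d)) {
    if (abs(disp[j]) < 1e-12) next # zero-displacement CV: not applicable
    prog[j] <- min(max((s_ts[j] - s_r[j]) / disp[j], 0), 1)
  }
  tab <- tibble::tibble(cv = fes$axes$name, reactant = s_r, ts = s_ts,
                        product = s_p, progress = prog)
  ord <- order(-replace(prog, is.na(prog), -Inf))
  ordering <- paste0("Progress at the transition state: ",
                     paste(sprintf("%s %s", tab$cv[ord],
                                   ifelse(is.na(tab$progress[ord]), "n/a",
                                          sprintf("%.0f%%", 100 * tab$progress[ord]))),
                           collapse = ", "), ".")
  pt <- grep("phosphoryl", fes$axes$name, ignore.case = TRUE)
  tightness <- "indeterminate"
  if (length(pt) == 1 && !is.na(prog[pt])) {
    dev <- abs(prog[pt] - 0.5)
    if (dev <= 0.125) tightness <- "tight"
    else if (dev >= 0.30) tightness <- "loose"
  }
  structure(list(progress = tab, ordering = ordering, tightness = tightness),
            class = "mechanism_report")
}

#' @export
print.mechanism_report <- function(x, ...) {
  cat(x$ordering, "\nTS tightness:", x$tightness, "\n")
  invisible(x)
}

#' Split-log convergence diagnostic
#'
#' Reconstructs the surface from the first `split` fraction of the hills and
#' from the remainder (each normalised to its own minimum) and reports the
#' maximum absolute difference — a standard estimate of how far the
#' reconstruction is from convergence.
#'
#' @param log a [hills_log] with at least 10 hills.
#' @param axes optional axes (defaults to the full log's [default_axes]).
#' @param split fraction in (0, 1).
#' @param resolution grid spacing when axes are inferred.
#' @return max |Delta F| in kcal/mol.
#' @export
convergence_check <- function(log, axes = NULL, split = 0.5,
                              resolution = 0.02) {
  if (split <= 0 || split >= 1) stop("split must be in (0, 1)")
  nh <- n_hills(log)
  if (nh < 10) stop("too few hills for a split diagnostic (need >= 10)")
  if (is.null(axes)) axes <- default_axes(log, resolution)
  k <- max(1L, floor(split * nh))
  sub_log <- function(i) hills_log(log$cv_names,
                                   centers = log$centers[i, , drop = FALSE],
                                   sigmas = log$sigmas[i, , drop = FALSE],
                                   heights = log$heights[i],
                                   times = log$times[i],
                                   walkers = log$walkers[i])
  f1 <- reconstruct_fes(sub_log(seq_len(k)), axes)
  f2 <- reconstruct_fes(sub_log((k + 1):nh), axes)
  max(abs(f1$values - f2$values))
}
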