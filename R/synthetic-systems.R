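#' Toy reaction cluster for collective-variable tests
#'
#' Places the nine active-site atoms that define the reaction coordinates of a
#' 2',3'-cyclic-phosphate-forming ribonuclease (the 2'-O nucleophile and its
#' proton, the general base NE2, the reactive phosphorus with its 5'-O leaving
#' group and non-bridging oxygens O1P/O2P, and the general acid NE2/HE2 pair)
#' on simple linear tracks parameterised by a progress variable. At
#' `progress = 0` each proton sits 1.0 A from its donor and 1.8 A from its
#' acceptor; at `progress = 1` the distances are swapped, so each
#' antisymmetric-stretch CV sweeps linearly from -0.8 A to +0.8 A.
#'
#' @param progress reaction progress in `[0, 1]`.
#' @return a `toy_cluster`: list with `labels` (atom names), `coords`
#'   (9 x 3 matrix, A) and `progress`.
#' @examples
#' cl <- make_toy_reaction_cluster(0)
#' # nucleophile deprotonation CV at the reactant: -0.8 A
#' antisym_stretch(cl$coords, "O2p", "H2p", "NE2_120", labels = cl$labels)$value
#' @export
make_toy_reaction_cluster <- function(progress) {
  if (!is.numeric(progress) || length(progress) != 1 || is.na(progress) ||
      progress < 0 || progress > 1)
    stop("progress must be a single value in [0, 1]")
  p <- progress
  coords <- rbind(
    O2p     = c(0, 0, 0),
    H2p     = c(1.0 + 0.8 * p, 0, 0),          # donor O2p -> acceptor NE2_120
    NE2_120 = c(2.8, 0, 0),
    P       = c(0, -1.8 + 0.8 * p, 0),         # approaches O2p as p grows
    O5p     = c(0, -2.8, 0),
    NE2_208 = c(0, -2.8, 2.8),
    HE2_208 = c(0, -2.8, 2.8 - (1.0 + 0.8 * p)), # donor NE2_208 -> acceptor O5p
    O1P     = c(1.2, -1.5, 0.6),
    O2P     = c(-1.2, -1.5, 0.6))
  structure(list(labels = rownames(coords), coords = unname(coords),
                 progress = p),
            class = "toy_cluster")
}

#' Sweep the toy cluster through a reaction and return a trajectory
#'
#' @param progress numeric vector of progress values, one frame each.
#' @return an `xyz_trajectory` (see [read_xyz]).
#' @export
toy_reaction_trajectory <- function(progress = seq(0, 1, length.out = 11)) {
  frames <- lapply(progress, function(p) make_toy_reaction_cluster(p)$coords)
  structure(list(labels = make_toy_reaction_cluster(0)$labels, frames = frames,
                 comments = sprintf("progress %.4f", progress)),
            class = "xyz_trajectory")
}

#' Synthetic hydration snapshots with a planted first shell
#'
#' Generates frames of solvent-oxygen positions around a reference atom:
#' exactly `n_shell` points per frame at `r_shell +/- 0.05` A from the centre,
#' plus an ideal-gas background at number density `density_bulk` filling the
#' cubic box outside `r_shell + 1` A. Ground truth for radial distribution
#' function and first-shell integration tests.
#'
#' @param n_shell planted first-shell occupancy (>= 0).
#' @param r_shell shell radius, A (> 0).
#' @param density_bulk background number density, A^-3.
#' @param n_frames number of frames (>= 1).
#' @param seed integer seed; the generator is deterministic given the seed.
#' @param box cubic box edge, A; the centre atom sits at the box centre.
#' @return a `hydration_snapshots`: list with `frames` (point matrices),
#'   `centers`, `box`, `density_bulk`, `seed`.
#' @export
sample_hydration_shell <- function(n_shell, r_shell, density_bulk = 0,
                                   n_frames = 1, seed = 1, box = 20) {
  if (n_shell < 0) stop("n_shell must be >= 0")
  if (r_shell <= 0) stop("r_shell must be > 0")
  if (n_frames < 1) stop("n_frames must be >= 1")
  set.seed(seed)
  center <- rep(box / 2, 3)
  r_excl <- r_shell + 1
  v_box <- box^3
  v_excl <- min(4 / 3 * pi * r_excl^3, v_box)
  lambda <- density_bulk * (v_box - v_excl)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    pts <- matrix(numeric(0), ncol = 3)
    if (n_shell > 0) {
      dir <- matrix(rnorm(3 * n_shell), ncol = 3)
      dir <- dir / sqrt(rowSums(dir^2))
      rad <- r_shell + runif(n_shell, -0.05, 0.05)
      pts <- sweep(dir * rad, 2, center, "+")
    }
    if (lambda > 0) {
      n_bg <- rpois(1, lambda)
      got <- 0
      bg <- matrix(NA_real_, n_bg, 3)
      while (got < n_bg) {
        cand <- matrix(runif(3 * (n_bg - got), 0, box), ncol = 3)
        d <- sqrt(rowSums(sweep(cand, 2, center)^2))
        keep <- cand[d > r_excl, , drop = FALSE]
        if (nrow(keep) > 0) {
          bg[(got + 1):(got + nrow(keep)), ] <- keep
          got <- got + nrow(keep)
        }
      }
      pts <- rbind(pts, bg)
    }
    frames[[f]] <- pts
  }
  structure(list(frames = frames,
                 centers = matrix(center, n_frames, 3, byrow = TRUE),
                 box = box, density_bulk = density_bulk, seed = seed),
            class = "hydration_snapshots")
}

#' Synthetic single-cleavage Michaelis-Menten data
#'
#' Simulates initial-rate measurements for a single-cleavage substrate series:
#' `v = kcat * E0 * S / (Km + S)` plus additive Gaussian noise truncated at
#' zero. The default concentration series is the two-fold dilution ladder used
#' for single-cleavage exoribonuclease assays (0.85 to 55 uM).
#'
#' @param kcat turnover number, s^-1.
#' @param Km Michaelis constant, uM.
#' @param E0 enzyme concentration, uM.
#' @param S substrate concentrations, uM.
#' @param noise_sd standard deviation of additive velocity noise, uM/s.
#' @param replicates replicate measurements per concentration.
#' @param seed integer seed.
#' @return a `kinetics_sample`: list with `data` (tibble: `substrate_uM`,
#'   `replicate`, `velocity_uM_per_s`), `E0`, `truth` (kcat, Km), `noise_sd`,
#'   `seed`.
#' @examples
#' ks <- generate_mm_kinetics(kcat = 11.85e-3, Km = 3.12, E0 = 0.1)
#' @export
generate_mm_kinetics <- function(kcat, Km, E0,
                                 S = c(0.85, 1.7, 3.4, 6.8, 13.7, 27.5, 55),
                                 noise_sd = 0, replicates = 1, seed = 1) {
  if (any(c(kcat, Km, E0, S) <= 0)) stop("rates and concentrations must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(replicates), substrate_uM = S)
  v0 <- kcat * E0 * grid$substrate_uM / (Km + grid$substrate_uM)
  v <- v0 + if (noise_sd > 0) rnorm(length(v0), 0, noise_sd) else 0
  v <- pmax(v, 0)
  structure(list(
    data = tibble::tibble(substrate_uM = grid$substrate_uM,
                          replicate = grid$replicate,
                          velocity_uM_per_s = v),
    E0 = E0, truth = c(kcat = kcat, Km = Km),
    noise_sd = noise_sd, seed = seed),
    class = "kinetics_sample")
}
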