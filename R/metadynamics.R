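#' Hills logs: the record of deposited Gaussian bias
#'
#' A `hills_log` is the time-ordered record of the repulsive Gaussians
#' ("hills") deposited during metadynamics: per hill a deposition time (ps),
#' a centre in CV space (A), per-CV widths sigma (A), a height (kcal/mol), an
#' optional well-tempered bias factor and the id of the walker that deposited
#' it. The negative of the accumulated bias is the running estimate of the
#' free energy surface.
#'
#' @param cv_names ordered CV labels.
#' @param centers n x d matrix of hill centres (A).
#' @param sigmas n x d matrix of widths (A), or a vector recycled per CV.
#' @param heights hill heights (kcal/mol).
#' @param times deposition times (ps).
#' @param walkers per-hill walker id.
#' @param biasf well-tempered bias factor (`NA` for standard metadynamics).
#' @return a `hills_log`.
#' @export
hills_log <- function(cv_names, centers = NULL, sigmas = NULL, heights = NULL,
                      times = NULL, walkers = NULL, biasf = NA_real_) {
  d <- length(cv_names)
  if (is.null(centers)) centers <- matrix(numeric(0), 0, d)
  centers <- as.matrix(centers)
  n <- nrow(centers)
  if (ncol(centers) != d) stop("hill dimensionality must equal length(cv_names)")
  if (is.null(sigmas)) sigmas <- matrix(numeric(0), 0, d)
  if (!is.matrix(sigmas)) sigmas <- matrix(sigmas, n, d, byrow = length(sigmas) == d)
  if (is.null(heights)) heights <- numeric(0)
  if (length(heights) == 1L) heights <- rep(heights, n)
  if (is.null(times)) times <- seq_len(n) * NA_real_
  if (is.null(walkers)) walkers <- rep(1L, n)
  if (n > 0 && (any(sigmas <= 0) || any(heights < 0)))
    stop("hill widths must be > 0 and heights >= 0")
  # times must be non-decreasing within each walker
  for (w in unique(walkers)) {
    tw <- times[walkers == w]
    tw <- tw[!is.na(tw)]
    if (is.unsorted(tw)) stop("hill times must be non-decreasing within a walker")
  }
  structure(list(cv_names = cv_names, centers = centers, sigmas = sigmas,
                 heights = heights, times = times,
                 walkers = as.integer(walkers),
                 biasf = rep_len(biasf, n)),
            class = "hills_log")
}

#' @export
print.hills_log <- function(x, ...) {
  cat("<hills_log>", n_hills(x), "hills over CVs:",
      paste(x$cv_names, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname hills_log
#' @param log a `hills_log`.
#' @export
n_hills <- function(log) nrow(log$centers)

.check_log_dim <- function(log, s) {
  d <- length(log$cv_names)
  .as_point_matrix(s, d)
}

#' Bias potential accumulated in a hills log
#'
#' `V(s) = sum_i h_i exp(-sum_d (s_d - c_id)^2 / (2 sigma_id^2))`. An empty
#' log gives zero everywhere.
#'
#' @param log a [hills_log].
#' @param s a CV point or matrix of points (rows).
#' @return `bias_energy()`: kcal/mol per point. `bias_force()`: the negative
#'   gradient, kcal/mol/A, one row per point.
#' @export
bias_energy <- function(log, s) {
  s <- .check_log_dim(log, s)
  if (n_hills(log) == 0) return(rep(0, nrow(s)))
  as.numeric(bias_energy_cpp(log$centers, log$sigmas, log$heights, s))
}

#' @rdname bias_energy
#' @export
bias_force <- function(log, s) {
  s <- .check_log_dim(log, s)
  if (n_hills(log) == 0) return(matrix(0, nrow(s), ncol(s)))
  -bias_gradient_cpp(log$centers, log$sigmas, log$heights, s)
}

#' Merge hills logs (multi-walker pooling)
#'
#' @param ... `hills_log` objects over the same CVs.
#' @return a pooled `hills_log`; the bias of the pool equals the sum of the
#'   component biases.
#' @export
merge_hills <- function(...) {
  logs <- list(...)
  cvn <- logs[[1]]$cv_names
  for (l in logs) if (!identical(l$cv_names, cvn)) stop("CV names differ between logs")
  hills_log(cvn,
            centers = do.call(rbind, lapply(logs, `[[`, "centers")),
            sigmas = do.call(rbind, lapply(logs, `[[`, "sigmas")),
            heights = unlist(lapply(logs, `[[`, "heights")),
            times = unlist(lapply(logs, `[[`, "times")),
            walkers = unlist(lapply(logs, `[[`, "walkers")),
            biasf = unlist(lapply(logs, `[[`, "biasf")))
}

#' Sampler configuration
#'
#' Defaults follow the standard enhanced-sampling protocol for reaction
#' coordinates of this kind: hills of height 0.1 kcal/mol and width 0.1 A
#' deposited once every 200 timesteps of 0.5 fs (one hill per 100 fs of
#' dynamics per walker).
#'
#' @param timestep_fs integration timestep, fs.
#' @param temperature K.
#' @param friction Langevin friction, ps^-1.
#' @param mass effective CV mass, kcal mol^-1 ps^2 A^-2 (0.0239 corresponds to
#'   10 atomic mass units); scalar or per-CV.
#' @param hill_height kcal/mol; 0 turns deposition off (plain Langevin
#'   dynamics).
#' @param hill_width Gaussian sigma, A; scalar or per-CV.
#' @param pace deposition interval in steps.
#' @param n_walkers number of concurrently sampling walkers sharing one log.
#' @param steps_per_walker integration steps per walker.
#' @param seed master seed; walker noise streams derive from it
#'   deterministically.
#' @param bias_factor well-tempered bias factor (> 1) or `NULL` for standard
#'   fixed-height metadynamics (the default).
#' @param record_stride store the CV position every this many steps.
#' @return a `sampler_config`.
#' @export
sampler_config <- function(timestep_fs = 0.5, temperature = 298.15,
                           friction = 10, mass = 0.0239,
                           hill_height = 0.1, hill_width = 0.1, pace = 200,
                           n_walkers = 1, steps_per_walker = 10000, seed = 1,
                           bias_factor = NULL, record_stride = pace) {
  if (any(c(timestep_fs, temperature, friction, mass, hill_width,
            steps_per_walker) < 0) || pace < 1 || n_walkers < 1)
    stop("sampler parameters must be positive (pace >= 1)")
  if (hill_height < 0) stop("hill_height must be >= 0")
  structure(list(timestep_fs = timestep_fs, temperature = temperature,
                 friction = friction, mass = mass, hill_height = hill_height,
                 hill_width = hill_width, pace = as.integer(pace),
                 n_walkers = as.integer(n_walkers),
                 steps_per_walker = as.integer(steps_per_walker),
                 seed = as.integer(seed),
                 bias_factor = if (is.null(bias_factor)) NA_real_ else bias_factor,
                 record_stride = as.integer(record_stride)),
            class = "sampler_config")
}

.run_meta <- function(surface, config, init, shared_log, n_walkers) {
  d <- surface$dimension
  init <- .as_point_matrix(init, d)
  if (nrow(init) == 1 && n_walkers > 1)
    init <- init[rep(1, n_walkers), , drop = FALSE]
  if (nrow(init) != n_walkers)
    stop("need one initial point per walker")
  lo <- surface$domain_box[1, ]; hi <- surface$domain_box[2, ]
  if (any(t(init) < lo) || any(t(init) > hi))
    stop("initial point outside the surface domain box")
  if (is.null(shared_log)) shared_log <- hills_log(surface$cv_names)
  if (!identical(shared_log$cv_names, surface$cv_names))
    stop("shared log CVs do not match the surface")
  mass <- rep_len(config$mass, d)
  hw <- rep_len(config$hill_width, d)
  set.seed(config$seed)
  res <- meta_run_cpp(surface$kind_code, surface$params, lo, hi, init,
                      dt = config$timestep_fs * 1e-3,
                      temp = config$temperature, friction = config$friction,
                      mass = mass, hill_h = config$hill_height, hill_w = hw,
                      pace = config$pace, nsteps = config$steps_per_walker,
                      record_stride = config$record_stride,
                      biasf = if (is.na(config$bias_factor)) 0 else config$bias_factor,
                      hills0_centers = shared_log$centers,
                      hills0_sigmas = shared_log$sigmas,
                      hills0_heights = shared_log$heights,
                      t0 = if (n_hills(shared_log) > 0 &&
                               any(!is.na(shared_log$times)))
                             max(shared_log$times, na.rm = TRUE) else 0)
  new_log <- hills_log(surface$cv_names, centers = res$centers,
                       sigmas = res$sigmas, heights = res$heights,
                       times = res$times, walkers = res$walkers,
                       biasf = config$bias_factor)
  full_log <- if (n_hills(shared_log) > 0) merge_hills(shared_log, new_log) else new_log
  traj <- res$trajectory # array (walker, record, cv)
  dim3 <- dim(traj)
  trajectories <- lapply(seq_len(n_walkers), function(w) {
    m <- matrix(traj[w, , ], dim3[2], dim3[3])
    colnames(m) <- surface$cv_names
    m
  })
  list(log = full_log, trajectories = trajectories, final = res$final,
       config = config)
}

#' Run a single metadynamics walker
#'
#' Langevin (BAOAB) dynamics directly in CV space on
#' `surface energy + accumulated bias`, with reflecting walls at the domain
#' box and a hill deposited at the walker position every `pace` steps.
#' Dynamics in CV space with effective masses is the desk-scale surrogate for
#' biasing CVs of an atomistic simulation: it preserves the bias/free-energy
#' mathematics while removing the molecular-dynamics engine.
#'
#' @param surface a [model_surface].
#' @param config a [sampler_config] (its `n_walkers` is ignored here).
#' @param initial_s starting CV point (inside the domain box).
#' @param shared_log optional existing [hills_log] whose bias acts from step
#'   one (multi-walker sharing).
#' @return list with `log` (input log plus newly deposited hills),
#'   `trajectories` (list of recorded CV matrices), `final` positions and the
#'   `config`.
#' @export
run_walker <- function(surface, config, initial_s, shared_log = NULL) {
  .run_meta(surface, config, initial_s, shared_log, n_walkers = 1L)
}

#' Run multi-walker metadynamics
#'
#' All walkers advance in lockstep and share a single hills log: every `pace`
#' steps each walker deposits one hill, and from the next step every walker
#' feels all hills deposited so far (synchronous pooling at deposition
#' granularity). With `n_walkers = 1` this reduces exactly to [run_walker].
#'
#' @inheritParams run_walker
#' @param initial_s starting point(s): one CV vector (all walkers start
#'   there) or an `n_walkers` x d matrix. Defaults to the surface's first
#'   listed minimum.
#' @return as [run_walker], with one trajectory per walker.
#' @export
run_multiwalker <- function(surface, config, initial_s = NULL,
                            shared_log = NULL) {
  if (is.null(initial_s)) {
    feat <- surface$known_features
    mins <- which(feat$energy == min(feat$energy))[1]
    initial_s <- feat$position[[mins]]
  }
  .run_meta(surface, config, initial_s, shared_log,
            n_walkers = config$n_walkers)
}
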