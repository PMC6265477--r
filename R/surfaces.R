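#' Analytic model reaction surfaces
#'
#' Model free-energy surfaces in collective-variable (CV) space with
#' analytically known minima and saddles. They stand in for an expensive
#' quantum-chemical energy function so that every downstream stage of the
#' pipeline (biased sampling, surface reconstruction, path extraction,
#' barrier-to-rate conversion) can be validated against exact ground truth.
#'
#' A `model_surface` carries the surface kind, its parameters, CV names, a
#' rectangular domain box with reflecting boundaries for the sampler, and a
#' table of known stationary points (`known_features`).
#'
#' @name model_surface
NULL

.new_surface <- function(kind, kind_code, params, cv_names, domain_box,
                         known_features) {
  stopifnot(is.matrix(domain_box), nrow(domain_box) == 2)
  structure(
    list(kind = kind, kind_code = kind_code, params = params,
         dimension = length(cv_names), cv_names = cv_names,
         domain_box = domain_box, known_features = known_features),
    class = "model_surface")
}

.feature_table <- function(labels, positions, energies) {
  tibble::tibble(label = labels,
                 position = lapply(seq_along(labels), function(i) positions[[i]]),
                 energy = energies)
}

#' @export
print.model_surface <- function(x, ...) {
  cat("<model_surface>", x$kind, "in", x$dimension, "CV(s):",
      paste(x$cv_names, collapse = ", "), "\n")
  for (i in seq_len(nrow(x$known_features))) {
    cat(sprintf("  %-10s at (%s)  E = %.4g kcal/mol\n",
                x$known_features$label[i],
                paste(format(x$known_features$position[[i]], digits = 4),
                      collapse = ", "),
                x$known_features$energy[i]))
  }
  invisible(x)
}

.as_point_matrix <- function(s, d) {
  if (is.null(dim(s))) {
    if (length(s) %% d != 0L)
      stop("point length is not a multiple of the surface dimension")
    s <- matrix(s, ncol = d, byrow = TRUE)
  }
  if (ncol(s) != d) stop("points have wrong dimension for this surface")
  storage.mode(s) <- "double"
  s
}

#' Evaluate a model surface
#'
#' @param surface a `model_surface`.
#' @param s a CV point (numeric vector) or a matrix with one point per row.
#' @return `surface_energy()` returns energies in kcal/mol (one per point);
#'   `surface_gradient()` returns the analytic gradient in kcal/mol/A, one row
#'   per point.
#' @export
surface_energy <- function(surface, s) {
  s <- .as_point_matrix(s, surface$dimension)
  as.numeric(surf_energy_cpp(surface$kind_code, surface$params, s))
}

#' @rdname surface_energy
#' @export
surface_gradient <- function(surface, s) {
  s <- .as_point_matrix(s, surface$dimension)
  surf_gradient_cpp(surface$kind_code, surface$params, s)
}

#' Symmetric one-dimensional double well
#'
#' `V(x) = barrier * ((2 x / separation)^2 - 1)^2`: minima of energy zero at
#' `+/- separation/2` and a saddle of height `barrier` at the origin. The
#' primary test oracle for free-energy-surface recovery from biased sampling.
#'
#' @param barrier well-to-saddle barrier, kcal/mol (> 0).
#' @param separation distance between the two minima, CV units (> 0).
#' @return a [model_surface].
#' @examples
#' dw <- make_double_well(5, 2)
#' surface_energy(dw, c(0))    # 5
#' surface_energy(dw, c(-1))   # 0
#' @export
make_double_well <- function(barrier, separation) {
  if (!is.numeric(barrier) || barrier <= 0) stop("barrier must be > 0")
  if (!is.numeric(separation) || separation <= 0) stop("separation must be > 0")
  .new_surface(
    kind = "double_well", kind_code = 2L,
    params = c(barrier = barrier, separation = separation),
    cv_names = "x",
    domain_box = matrix(c(-separation, separation), nrow = 2,
                        dimnames = list(c("min", "max"), "x")),
    known_features = .feature_table(
      c("minimum_left", "saddle", "minimum_right"),
      list(-separation / 2, 0, separation / 2),
      c(0, barrier, 0)))
}

#' Isotropic harmonic well
#'
#' `V(s) = sum_j k_j/2 (s_j - c_j)^2`. Used to verify that the sampler obeys
#' equipartition when the bias is switched off.
#'
#' @param k spring constant(s), kcal/mol/A^2.
#' @param center well position (defaults to the origin).
#' @param half_width half edge of the domain box around the center.
#' @return a [model_surface].
#' @export
make_harmonic_well <- function(k, center = rep(0, length(k)), half_width = 6) {
  if (any(k <= 0)) stop("spring constants must be > 0")
  d <- length(k)
  cvn <- paste0("s", seq_len(d))
  .new_surface(
    kind = "harmonic", kind_code = 1L,
    params = c(k, center),
    cv_names = cvn,
    domain_box = matrix(rbind(center - half_width, center + half_width), nrow = 2,
                        dimnames = list(c("min", "max"), cvn)),
    known_features = .feature_table("minimum", list(center), 0))
}

#' Three-coordinate staged mechanism surface
#'
#' A 3D model landscape for a transphosphorylation reaction proceeding through
#' general acid-base catalysis, built so that the minimum free energy path
#' reproduces the staged mechanism of 2',3'-cyclic-phosphate-forming
#' ribonucleases: the path first climbs the nucleophile-deprotonation
#' coordinate by about `deprotonation_cost` to a shoulder with no appreciable
#' reverse barrier, and then moves the phosphoryl-transfer and
#' leaving-group-protonation coordinates together through a single
#' rate-limiting saddle `main_barrier` above the reactant minimum.
#'
#' The three CVs are antisymmetric-stretch-like coordinates running from -0.8
#' (reactant) to +0.8 (product), in A. The surface is a sum of C1 pieces built
#' from quintic smoothersteps, so every listed stationary point has an exactly
#' vanishing analytic gradient:
#' \describe{
#'   \item{reactant}{(-0.8, -0.8, -0.8), energy 0 (global minimum)}
#'   \item{shoulder}{(+0.8, -0.8, -0.8), energy `deprotonation_cost`}
#'   \item{ts}{(+0.8, `asynchronicity`, -`asynchronicity`), energy `main_barrier`}
#'   \item{product}{(+0.8, +0.8, +0.8), slightly above the reactant}
#' }
#' `asynchronicity` displaces the saddle along the difference of the
#' phosphoryl-transfer and leaving-group coordinates, advancing one at the
#' expense of the other without changing the barrier height.
#'
#' @param deprotonation_cost free-energy cost of the nucleophile
#'   deprotonation shoulder, kcal/mol; must satisfy
#'   `0 < deprotonation_cost < main_barrier`.
#' @param main_barrier height of the rate-limiting saddle above the reactant
#'   minimum, kcal/mol.
#' @param asynchronicity saddle displacement (A) along
#'   (phosphoryl transfer - leaving group protonation)/2; 0 gives a perfectly
#'   synchronous saddle.
#' @return a [model_surface] with CVs `nucleophile_deprotonation`,
#'   `phosphoryl_transfer`, `leaving_group_protonation`.
#' @export
make_mechanism_surface <- function(deprotonation_cost = 6,
                                   main_barrier = 21.6,
                                   asynchronicity = 0) {
  if (!(deprotonation_cost > 0))
    stop("deprotonation_cost must be > 0")
  if (!(main_barrier > deprotonation_cost))
    stop("main_barrier must exceed deprotonation_cost")
  a <- 0.8
  prod_energy <- min(2, main_barrier / 4)
  pars <- c(D = deprotonation_cost, B = main_barrier, alpha = asynchronicity,
            a = a, K = 2 * main_barrier / a^2, M = main_barrier / a^2,
            Ep = prod_energy, cw = 25)
  cvn <- c("nucleophile_deprotonation", "phosphoryl_transfer",
           "leaving_group_protonation")
  .new_surface(
    kind = "mechanism", kind_code = 3L, params = pars, cv_names = cvn,
    domain_box = matrix(rep(c(-1.3, 1.3), 3), nrow = 2,
                        dimnames = list(c("min", "max"), cvn)),
    known_features = .feature_table(
      c("reactant", "shoulder", "ts", "product"),
      list(c(-a, -a, -a),
           c(a, -a, -a),
           c(a, asynchronicity, -asynchronicity),
           c(a, a, a)),
      c(0, deprotonation_cost, main_barrier, prod_energy)))
}

#' Evaluate a model surface on a regular grid
#'
#' Produces an exact free-energy grid (a [fes_grid]) from the analytic surface,
#' normalised so its minimum is zero. This is the unsampled ground truth
#' against which metadynamics reconstructions are compared, and the input for
#' exact path/mechanism analysis.
#'
#' @param surface a `model_surface`.
#' @param n_points grid points per axis (scalar or per-CV vector).
#' @return a [fes_grid].
#' @export
surface_fes_grid <- function(surface, n_points = 41) {
  d <- surface$dimension
  n_points <- rep_len(as.integer(n_points), d)
  axes <- data.frame(name = surface$cv_names,
                     min = surface$domain_box[1, ],
                     max = surface$domain_box[2, ],
                     n = n_points, stringsAsFactors = FALSE)
  pts <- .axes_grid_points(axes)
  vals <- surface_energy(surface, pts)
  .new_fes_grid(axes, vals - min(vals), origin_log_hash = paste0("surface:", surface$kind))
}
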