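#' Collective variables for proton and phosphoryl transfer
#'
#' Reaction coordinates evaluated on atomic coordinates, with analytic
#' gradients. Three kinds are supported:
#' \describe{
#'   \item{`antisym_stretch`}{`d(A,H) - d(H,B)` for an atom triple A-H-B, the
#'     standard coordinate for a proton (or phosphoryl group) in flight between
#'     donor A and acceptor B. Negative in the reactant, positive in the
#'     product; atoms are ordered so that every CV increases as the reaction
#'     proceeds.}
#'   \item{`relay_zeta`}{the average of the two antisymmetric stretches of a
#'     double proton relay donor-H1-shuttle-H2-acceptor, a simplified
#'     centre-of-excess-charge coordinate for triester-like mechanisms in which
#'     an imidazole shuttles a proton to a non-bridging oxygen. It preserves
#'     the topology (monotone in overall relay progress) but not the literal
#'     Fermi-weighted form of the full coordinate.}
#'   \item{`distance`}{a plain Euclidean distance, for monitoring contacts.}
#' }
#' All values carry length units (A).
#'
#' @name collective_variables
NULL

.resolve_atoms <- function(idx, labels, coords) {
  if (is.character(idx)) {
    if (is.null(labels)) stop("atom names given but no labels supplied")
    pos <- match(idx, labels)
    if (anyNA(pos))
      stop("unknown atom label(s): ", paste(idx[is.na(pos)], collapse = ", "))
    pos
  } else {
    idx <- as.integer(idx)
    if (any(idx < 1 | idx > nrow(coords))) stop("atom index out of range")
    idx
  }
}

.cv_value <- function(label, value, gradient) {
  structure(list(label = label, value = value, gradient = gradient),
            class = "cv_value")
}

# unit vector from H towards X and the distance; errors on coincident atoms
.bond <- function(coords, x, h) {
  dvec <- coords[x, ] - coords[h, ]
  d <- sqrt(sum(dvec^2))
  if (d < 1e-8) stop("coincident atoms: distance is zero")
  list(d = d, u = dvec / d)
}

#' Antisymmetric stretch CV
#'
#' `value = d(A, H) - d(H, B)`.
#'
#' @param coords n x 3 coordinate matrix, A.
#' @param A,H,B atom indices (or names resolved against `labels`) of the
#'   donor, transferring atom and acceptor.
#' @param labels optional atom names matching the rows of `coords`.
#' @param gradient if `TRUE` (default) also return the analytic gradient, an
#'   n x 3 matrix that is zero for uninvolved atoms.
#' @return a `cv_value`: list with `label`, `value` (A) and `gradient`.
#' @examples
#' xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.5, 0, 0))
#' antisym_stretch(xyz, 1, 2, 3)$value  # -0.5
#' @export
antisym_stretch <- function(coords, A, H, B, labels = NULL, gradient = TRUE) {
  idx <- .resolve_atoms(c(A, H, B), labels, coords)
  if (anyDuplicated(idx)) stop("atoms of an antisymmetric stretch must be distinct")
  a <- idx[1]; h <- idx[2]; b <- idx[3]
  ah <- .bond(coords, a, h)
  hb <- .bond(coords, b, h)
  val <- ah$d - hb$d
  g <- NULL
  if (gradient) {
    g <- matrix(0, nrow(coords), 3)
    g[a, ] <- ah$u              # d d(A,H) / dA
    g[b, ] <- -hb$u             # -d d(H,B) / dB
    g[h, ] <- -ah$u + hb$u
  }
  .cv_value("antisym_stretch", val, g)
}

#' Proton-relay zeta CV
#'
#' Average of the two antisymmetric stretches of a donor-H1-shuttle-H2-acceptor
#' relay: `value = (antisym(D, H1, S) + antisym(S, H2, A)) / 2`.
#'
#' @inheritParams antisym_stretch
#' @param D,H1,S,H2,A donor, first proton, shuttle, second proton, acceptor.
#' @return a `cv_value`.
#' @export
relay_zeta <- function(coords, D, H1, S, H2, A, labels = NULL, gradient = TRUE) {
  idx <- .resolve_atoms(c(D, H1, S, H2, A), labels, coords)
  if (anyDuplicated(idx)) stop("relay atoms must be distinct")
  leg1 <- antisym_stretch(coords, idx[1], idx[2], idx[3], gradient = gradient)
  leg2 <- antisym_stretch(coords, idx[3], idx[4], idx[5], gradient = gradient)
  g <- if (gradient) (leg1$gradient + leg2$gradient) / 2 else NULL
  .cv_value("relay_zeta", (leg1$value + leg2$value) / 2, g)
}

#' Distance CV
#'
#' @inheritParams antisym_stretch
#' @param i,j the two atoms.
#' @return a `cv_value`.
#' @export
distance_cv <- function(coords, i, j, labels = NULL, gradient = TRUE) {
  idx <- .resolve_atoms(c(i, j), labels, coords)
  if (idx[1] == idx[2]) stop("distance requires two distinct atoms")
  b <- .bond(coords, idx[1], idx[2])
  g <- NULL
  if (gradient) {
    g <- matrix(0, nrow(coords), 3)
    g[idx[1], ] <- b$u
    g[idx[2], ] <- -b$u
  }
  .cv_value("distance", b$d, g)
}

#' Declare a CV specification
#'
#' @param kind one of `"antisym_stretch"`, `"relay_zeta"`, `"distance"`.
#' @param atoms ordered atom indices or names: 3 for an antisymmetric stretch
#'   (A, H, B), 5 for a relay (D, H1, S, H2, A), 2 for a distance.
#' @param label display label.
#' @return a `cv_spec`.
#' @export
cv_spec <- function(kind = c("antisym_stretch", "relay_zeta", "distance"),
                    atoms, label = kind) {
  kind <- match.arg(kind)
  need <- c(antisym_stretch = 3L, relay_zeta = 5L, distance = 2L)[[kind]]
  if (length(atoms) != need)
    stop(sprintf("%s needs exactly %d atoms, got %d", kind, need, length(atoms)))
  if (anyDuplicated(atoms)) stop("CV atoms must be distinct")
  structure(list(kind = kind, atoms = atoms, label = label), class = "cv_spec")
}

.eval_cv_spec <- function(spec, coords, labels) {
  v <- switch(spec$kind,
    antisym_stretch = antisym_stretch(coords, spec$atoms[1], spec$atoms[2],
                                      spec$atoms[3], labels, gradient = FALSE),
    relay_zeta = relay_zeta(coords, spec$atoms[1], spec$atoms[2], spec$atoms[3],
                            spec$atoms[4], spec$atoms[5], labels,
                            gradient = FALSE),
    distance = distance_cv(coords, spec$atoms[1], spec$atoms[2], labels,
                           gradient = FALSE))
  v$value
}

#' Evaluate CVs along a trajectory
#'
#' @param trajectory an `xyz_trajectory` (see [read_xyz]) or a list of
#'   coordinate matrices.
#' @param specs a list of [cv_spec] objects (possibly empty).
#' @return a tibble with columns `frame`, `label`, `value` (A), frame order
#'   preserved.
#' @export
evaluate_cvs <- function(trajectory, specs) {
  frames <- if (inherits(trajectory, "xyz_trajectory")) trajectory$frames else trajectory
  labels <- if (inherits(trajectory, "xyz_trajectory")) trajectory$labels else NULL
  if (length(specs) == 0)
    return(tibble::tibble(frame = integer(), label = character(),
                          value = numeric()))
  out <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    spec <- specs[[k]]
    vals <- vapply(seq_along(frames), function(f) {
      tryCatch(.eval_cv_spec(spec, frames[[f]], labels),
               error = function(e) stop(sprintf(
                 "CV '%s' failed at frame %d: %s", spec$label, f,
                 conditionMessage(e)), call. = FALSE))
    }, numeric(1))
    out[[k]] <- tibble::tibble(frame = seq_along(frames), label = spec$label,
                               value = vals)
  }
  do.call(rbind, out)
}
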