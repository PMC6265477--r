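#' Read a crystal structure into a flat atom table
#'
#' Parses PDB or mmCIF coordinates (via bio3d) into a `structure_model`: a
#' tibble of atoms with chain, residue number/name, atom name, element,
#' coordinates (A), occupancy, B-factor and altloc. Alternate locations are
#' resolved to the highest-occupancy conformer (ties: altloc "A", then first).
#'
#' @param path a `.pdb` or `.cif`/`.mmcif` file.
#' @param source_id identifier recorded on the model (defaults to the file
#'   name).
#' @param resolve_altloc collapse alternate locations (default `TRUE`).
#' @return a `structure_model`: list with `atoms` (tibble) and `source_id`.
#' @export
read_structure <- function(path, source_id = basename(path),
                           resolve_altloc = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path, rm.alt = FALSE)
         else bio3d::read.pdb(path, rm.alt = FALSE)
  a <- pdb$atom
  atoms <- tibble::tibble(
    chain = as.character(a$chain), resno = as.integer(a$resno),
    resid = as.character(a$resid), elety = as.character(a$elety),
    element = as.character(a$elesy), alt = as.character(a$alt),
    x = a$x, y = a$y, z = a$z,
    o = if (!is.null(a$o)) a$o else 1,
    b = if (!is.null(a$b)) a$b else 0)
  if (any(!is.finite(atoms$x + atoms$y + atoms$z)))
    stop("non-finite coordinates in ", path)
  atoms$element[is.na(atoms$element) | atoms$element == ""] <-
    substr(gsub("[^A-Za-z].*", "", atoms$elety[is.na(atoms$element) |
                                               atoms$element == ""]), 1, 1)
  m <- structure(list(atoms = atoms, source_id = source_id),
                 class = "structure_model")
  if (resolve_altloc) m <- .resolve_altloc(m)
  m
}

.resolve_altloc <- function(model) {
  a <- model$atoms
  key <- paste(a$chain, a$resno, a$elety, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(a)), key), function(i) {
    if (length(i) == 1) return(i)
    occ <- a$o[i]
    best <- i[occ == max(occ)]
    if (length(best) > 1) {
      pa <- best[a$alt[best] %in% "A"]
      best <- if (length(pa)) pa[1] else best[1]
    }
    best
  }), use.names = FALSE)
  model$atoms <- a[sort(keep), , drop = FALSE]
  model
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model>", x$source_id, "-", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues\n")
  invisible(x)
}

# atom selector "chain:resno:atomname"; returns row index
.find_atom <- function(model, id) {
  parts <- strsplit(id, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3) stop("atom id must be 'chain:resno:atomname': ", id)
  a <- model$atoms
  hit <- which(a$chain == parts[1] & a$resno == as.integer(parts[2]) &
               a$elety == parts[3])
  if (length(hit) == 0) stop("atom not found: ", id)
  hit[1]
}

.atom_xyz <- function(model, row) as.numeric(model$atoms[row, c("x", "y", "z")])

#' Interatomic distance in a structure
#'
#' @param model a [read_structure] model.
#' @param atom_a,atom_b atom ids `"chain:resno:atomname"`.
#' @param digits display rounding (full precision is returned in the
#'   `exact` attribute).
#' @return distance in A rounded to `digits` (default one decimal, the
#'   precision at which contact distances are reported on structures).
#' @export
measure_distance <- function(model, atom_a, atom_b, digits = 1) {
  d <- sqrt(sum((.atom_xyz(model, .find_atom(model, atom_a)) -
                 .atom_xyz(model, .find_atom(model, atom_b)))^2))
  structure(round(d, digits), exact = d)
}

#' Detect hydrogen bonds by heavy-atom geometry
#'
#' N/O heavy-atom pairs within `distance_cutoff` are reported as hydrogen
#' bonds; pairs in the 3.3-3.5 A band are flagged weak. When explicit
#' hydrogens are present on the donor the D-H...A angle must exceed
#' `angle_cutoff`; without hydrogens the angle test is skipped. The cutoff
#' bracket follows typical contact geometry: ~2.7 A is a good hydrogen bond,
#' 3.3 A is long but possible, 3.7 A cannot hydrogen bond.
#'
#' @param model a [read_structure] model.
#' @param distance_cutoff A (default 3.5).
#' @param angle_cutoff degrees (default 120).
#' @param weak_min lower edge of the weak band, A (default 3.3).
#' @param exclude_same_residue drop intra-residue pairs (default `TRUE`).
#' @return tibble with `donor`, `acceptor`, `distance`, `angle` (NA without
#'   hydrogens), `weak`.
#' @export
detect_hbonds <- function(model, distance_cutoff = 3.5, angle_cutoff = 120,
                          weak_min = 3.3, exclude_same_residue = TRUE) {
  a <- model$atoms
  heavy <- which(a$element %in% c("N", "O"))
  empty <- tibble::tibble(donor = character(), acceptor = character(),
                          distance = numeric(), angle = numeric(),
                          weak = logical())
  if (length(heavy) < 2) return(empty)
  xyz <- as.matrix(a[heavy, c("x", "y", "z")])
  id <- paste(a$chain[heavy], a$resno[heavy], a$elety[heavy], sep = ":")
  res <- paste(a$chain[heavy], a$resno[heavy], sep = ":")
  hyd <- which(a$element == "H")
  out <- list()
  for (i in seq_along(heavy)[-length(heavy)]) {
    for (j in (i + 1):length(heavy)) {
      if (exclude_same_residue && res[i] == res[j]) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d < 2.2 || d > distance_cutoff) next
      ang <- NA_real_
      if (length(hyd)) {
        # hydrogens within 1.25 A of either heavy atom define the angle test
        for (donor in c(i, j)) {
          acceptor <- if (donor == i) j else i
          dh <- hyd[sqrt((a$x[hyd] - xyz[donor, 1])^2 +
                         (a$y[hyd] - xyz[donor, 2])^2 +
                         (a$z[hyd] - xyz[donor, 3])^2) < 1.25]
          for (h in dh) {
            hxyz <- c(a$x[h], a$y[h], a$z[h])
            v1 <- xyz[donor, ] - hxyz
            v2 <- xyz[acceptor, ] - hxyz
            th <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
            ang <- if (is.na(ang)) th else max(ang, th)
          }
        }
        if (!is.na(ang) && ang < angle_cutoff) next
      }
      out[[length(out) + 1]] <- tibble::tibble(
        donor = id[i], acceptor = id[j], distance = d, angle = ang,
        weak = d >= weak_min)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

# signed dihedral p1-p2-p3-p4 in (-180, 180]
.torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Glycosidic torsion and syn/anti classification
#'
#' Computes chi = O4'-C1'-N9-C4 for purines (N1-C2 for pyrimidines) and
#' classifies the base orientation: syn for chi in (-30, 90] degrees, anti
#' otherwise (the standard nucleic-acid convention).
#'
#' @param model a [read_structure] model.
#' @param nucleotide `"chain:resno"` of the nucleotide.
#' @return list with `chi` (degrees) and `conformation` (`"syn"`/`"anti"`).
#' @export
glycosidic_chi <- function(model, nucleotide) {
  parts <- strsplit(nucleotide, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("nucleotide must be 'chain:resno'")
  a <- model$atoms
  res <- a[a$chain == parts[1] & a$resno == as.integer(parts[2]), , drop = FALSE]
  if (nrow(res) == 0) stop("nucleotide not found: ", nucleotide)
  purine <- "N9" %in% res$elety
  need <- if (purine) c("O4'", "C1'", "N9", "C4") else c("O4'", "C1'", "N1", "C2")
  miss <- setdiff(need, res$elety)
  if (length(miss))
    stop("missing atoms for chi: ", paste(miss, collapse = ", "))
  p <- lapply(need, function(nm)
    as.numeric(res[match(nm, res$elety), c("x", "y", "z")]))
  chi <- .torsion(p[[1]], p[[2]], p[[3]], p[[4]])
  list(chi = chi, conformation = if (chi > -30 && chi <= 90) "syn" else "anti")
}

#' Least-squares superposition RMSD (Kabsch)
#'
#' Root-mean-square deviation between two paired coordinate sets after
#' optimal rigid superposition (rotation + translation) by singular value
#' decomposition of the cross-covariance, with the usual determinant
#' correction so only proper rotations are allowed.
#'
#' @param coords_a,coords_b n x 3 matrices (n >= 3), paired row by row.
#' @return RMSD in A.
#' @export
kabsch_rmsd <- function(coords_a, coords_b) {
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  if (!all(dim(A) == dim(B))) stop("coordinate sets must be paired")
  if (nrow(A) < 3) stop("need at least 3 points")
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  s <- svd(crossprod(B, A)) # 3x3
  dsign <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, dsign))
  R <- s$u %*% D %*% t(s$v)
  sqrt(mean(rowSums((A - B %*% R)^2)))
}
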