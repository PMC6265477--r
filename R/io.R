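#' Read and write hills logs
#'
#' Text dialect compatible with common metadynamics engines: a header line
#' `#! FIELDS time <cv...> sigma_<cv...> height biasf` followed by
#' whitespace-delimited rows; a trailing `walker` column records the
#' depositing walker when present, and unknown trailing columns are ignored
#' with a warning. Values are written at full double precision so a
#' write/read round trip is lossless.
#'
#' @param log a [hills_log].
#' @param path file path.
#' @return `read_hills()` returns a [hills_log]; `write_hills()` returns
#'   `path` invisibly.
#' @export
write_hills <- function(log, path) {
  d <- length(log$cv_names)
  fields <- c("time", log$cv_names, paste0("sigma_", log$cv_names),
              "height", "biasf", "walker")
  lines <- paste("#! FIELDS", paste(fields, collapse = " "))
  if (n_hills(log) > 0) {
    num <- cbind(log$times, log$centers, log$sigmas, log$heights,
                 ifelse(is.na(log$biasf), 1, log$biasf))
    body <- apply(num, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
    lines <- c(lines, paste(body, log$walkers))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_hills
#' @export
read_hills <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "#! FIELDS"))
    stop("hills file must start with a '#! FIELDS' header: ", path)
  fields <- strsplit(sub("^#! FIELDS\\s+", "", lines[1]), "\\s+")[[1]]
  if (fields[1] != "time") stop("first field must be 'time'")
  sig <- grep("^sigma_", fields)
  if (length(sig) == 0) stop("no sigma_<cv> fields in header")
  cvn <- fields[2:(sig[1] - 1)]
  d <- length(cvn)
  if (!identical(fields[sig], paste0("sigma_", cvn)))
    stop("sigma fields do not match the CV fields")
  hcol <- match("height", fields)
  if (is.na(hcol)) stop("no 'height' field in header")
  bcol <- match("biasf", fields)
  wcol <- match("walker", fields)
  known <- c(1, 2:(sig[1] - 1), sig, hcol, bcol, wcol)
  extra <- setdiff(seq_along(fields), known[!is.na(known)])
  if (length(extra))
    warning("ignoring unknown column(s): ", paste(fields[extra], collapse = ", "))
  body <- lines[-1]
  body <- body[!grepl("^\\s*(#|$)", body)]
  if (length(body) == 0)
    return(hills_log(cvn))
  rows <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(rows) != length(fields))
  if (length(bad))
    stop(sprintf("malformed hills row at line %d of %s: expected %d columns, found %d",
                 bad[1] + 1L, path, length(fields), lengths(rows)[bad[1]]))
  num <- matrix(suppressWarnings(as.numeric(unlist(rows))),
                nrow = length(rows), byrow = TRUE)
  nn <- which(!stats::complete.cases(num[, c(1:(sig[1] - 1), sig, hcol),
                                         drop = FALSE]))
  if (length(nn))
    stop(sprintf("non-numeric value in hills row at line %d of %s",
                 nn[1] + 1L, path))
  hills_log(cvn,
            centers = num[, 2:(sig[1] - 1), drop = FALSE],
            sigmas = num[, sig, drop = FALSE],
            heights = num[, hcol],
            times = num[, 1],
            walkers = if (!is.na(wcol)) as.integer(num[, wcol]) else NULL,
            biasf = if (!is.na(bcol)) {
              b <- num[, bcol]
              ifelse(b <= 1, NA_real_, b)
            } else NA_real_)
}

#' Read and write free energy grids
#'
#' Plain-text grid format: one header line `# axis <name> <min> <max> <n>`
#' per axis, then one row per grid point `s1 [s2 [s3]] F` with the last axis
#' varying fastest. Rewriting a file read with [read_fes] reproduces it
#' byte for byte.
#'
#' @param fes a [fes_grid] (1-3 axes).
#' @param path file path.
#' @return `read_fes()` returns a [fes_grid]; `write_fes()` returns `path`
#'   invisibly.
#' @export
write_fes <- function(fes, path) {
  ax <- fes$axes
  if (nrow(ax) > 3) stop("at most 3 axes are supported")
  header <- sprintf("# axis %s %.17g %.17g %d", ax$name, ax$min, ax$max, ax$n)
  pts <- .axes_grid_points(ax)
  ord <- do.call(order, lapply(seq_len(ncol(pts)), function(j) pts[, j]))
  # order(): last key is pts[,d]; we need the LAST axis fastest, i.e. sort by
  # axis 1 first, breaking ties by later axes
  vals <- as.vector(fes$values)
  m <- cbind(pts, vals)[ord, , drop = FALSE]
  body <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_fes
#' @export
read_fes <- function(path) {
  lines <- readLines(path)
  hd <- grep("^# axis ", lines)
  if (length(hd) == 0) stop("no '# axis' header lines in ", path)
  if (length(hd) > 3) stop("at most 3 axes are supported")
  ax <- do.call(rbind, lapply(lines[hd], function(l) {
    p <- strsplit(trimws(l), "\\s+")[[1]]
    data.frame(name = p[3], min = as.numeric(p[4]), max = as.numeric(p[5]),
               n = as.integer(p[6]), stringsAsFactors = FALSE)
  }))
  body <- lines[-hd]
  body <- body[!grepl("^\\s*(#|$)", body)]
  d <- nrow(ax)
  rows <- strsplit(trimws(body), "\\s+")
  if (any(lengths(rows) != d + 1))
    stop("grid rows must have ", d + 1, " columns")
  num <- matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
  if (nrow(num) != prod(ax$n))
    stop("non-rectangular grid: expected ", prod(ax$n), " rows, found ",
         nrow(num))
  # rows are ordered with the last axis fastest; invert to R order
  pts <- .axes_grid_points(ax)
  ord <- do.call(order, lapply(seq_len(d), function(j) pts[, j]))
  vals <- numeric(nrow(num))
  vals[ord] <- num[, d + 1]
  .new_fes_grid(ax, vals, origin_log_hash = basename(path))
}

#' Read and write XYZ trajectories
#'
#' Standard multi-frame XYZ: per frame an atom-count line, a comment line,
#' then `label x y z` rows. All frames must have the same atom count and
#' labels.
#'
#' @param path file path.
#' @return `read_xyz()` returns an `xyz_trajectory`: list with `labels`,
#'   `frames` (list of n x 3 matrices, A) and `comments`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); comments <- character(0); labels <- NULL
  i <- 1
  fr <- 0
  while (i <= length(lines)) {
    if (grepl("^\\s*$", lines[i])) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    fr <- fr + 1
    if (is.na(n) || n < 1)
      stop("frame ", fr, ": expected an atom count at line ", i)
    if (i + 1 + n > length(lines))
      stop("frame ", fr, ": truncated (expected ", n, " atom rows)")
    comments <- c(comments, lines[i + 1])
    rows <- strsplit(trimws(lines[(i + 2):(i + 1 + n)]), "\\s+")
    if (any(lengths(rows) < 4))
      stop("frame ", fr, ": malformed atom row")
    lab <- vapply(rows, `[`, character(1), 1)
    xyz <- matrix(as.numeric(vapply(rows, function(r) r[2:4], character(3))),
                  ncol = 3, byrow = TRUE)
    if (is.null(labels)) labels <- lab
    else if (length(lab) != length(labels))
      stop("frame ", fr, ": atom count differs from frame 1")
    frames[[fr]] <- xyz
    i <- i + 2 + n
  }
  if (length(frames) == 0) stop("no frames in ", path)
  structure(list(labels = labels, frames = frames, comments = comments),
            class = "xyz_trajectory")
}

#' @rdname read_xyz
#' @param trajectory an `xyz_trajectory` (or a `toy_cluster`).
#' @export
write_xyz <- function(trajectory, path) {
  if (inherits(trajectory, "toy_cluster"))
    trajectory <- structure(list(labels = trajectory$labels,
                                 frames = list(trajectory$coords),
                                 comments = sprintf("progress %.4f",
                                                    trajectory$progress)),
                            class = "xyz_trajectory")
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(trajectory$frames)) {
    m <- trajectory$frames[[f]]
    writeLines(as.character(nrow(m)), con)
    writeLines(if (length(trajectory$comments) >= f) trajectory$comments[f] else "", con)
    writeLines(sprintf("%s %.17g %.17g %.17g", trajectory$labels,
                       m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}
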