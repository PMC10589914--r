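# ---- small vector helpers (internal) ----------------------------------------

vnorm <- function(v) sqrt(sum(v * v))

vhat <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector", call. = FALSE)
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle between two vectors, in degrees
#' @noRd
vangle <- function(a, b) {
  ct <- sum(vhat(a) * vhat(b))
  ct <- min(1, max(-1, ct))
  acos(ct) * 180 / pi
}

as_coord_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    return(unname(x))
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("x", "y", "z") %in% names(x)))
    return(unname(as.matrix(x[, c("x", "y", "z")])))
  }
  if (is.numeric(x) && length(x) == 3) return(matrix(x, 1, 3))
  stop("expected an N x 3 matrix, a data frame with x/y/z columns, or a 3-vector",
       call. = FALSE)
}

# ---- rigid transforms -------------------------------------------------------

#' Construct a rigid-body transform
#'
#' A transform is a proper rotation (3x3 orthonormal matrix with determinant
#' +1) plus a translation, applied as `x' = R x + t`.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation numeric 3-vector, in Angstrom.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be proper (det = +1)", call. = FALSE)
  if (max(abs(rotation %*% t(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("rotation:\n")
  print(round(x$rotation, 6))
  cat("translation:", paste(signif(x$translation, 6), collapse = " "), "\n")
  invisible(x)
}

#' Invert a rigid transform
#' @param t A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  rigid_transform(t(t$rotation), -as.vector(t(t$rotation) %*% t$translation))
}

#' Apply a rigid transform to coordinates
#'
#' Every coordinate x is replaced by `rotation %*% x + translation`; for a
#' structure tibble the hierarchy (all non-coordinate columns and attributes)
#' is untouched.
#'
#' @param x A structure/chain tibble with `x`,`y`,`z` columns, or an N x 3
#'   coordinate matrix.
#' @param transform A `rigid_transform`.
#' @return Same kind of object as `x`, transformed.
#' @export
apply_transform <- function(x, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (is.data.frame(x)) {
    m <- as_coord_matrix(x)
    m2 <- m %*% t(transform$rotation) +
      matrix(transform$translation, nrow(m), 3, byrow = TRUE)
    x$x <- m2[, 1]; x$y <- m2[, 2]; x$z <- m2[, 3]
    return(x)
  }
  m <- as_coord_matrix(x)
  m %*% t(transform$rotation) +
    matrix(transform$translation, nrow(m), 3, byrow = TRUE)
}

# ---- Kabsch superposition ---------------------------------------------------

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD of `mobile`
#' onto `target`, by SVD of the cross-covariance matrix with reflection
#' correction (the smallest singular direction is flipped when the determinant
#' of the candidate rotation is negative, so mirror images are never
#' produced).
#'
#' @param mobile,target N x 3 coordinate matrices (or data frames with
#'   x/y/z), N >= 3, paired row by row.
#' @return A `kabsch_fit`: list with `transform` (a [rigid_transform()]),
#'   `rmsd` (Angstrom) and `n` (number of points).
#' @examples
#' pts <- matrix(rnorm(30), 10, 3)
#' fit <- kabsch(pts, pts)
#' fit$rmsd # 0
#' @export
kabsch <- function(mobile, target) {
  P <- as_coord_matrix(mobile)
  Q <- as_coord_matrix(target)
  if (nrow(P) != nrow(Q)) stop("point counts differ", call. = FALSE)
  if (nrow(P) < 3) stop("need at least 3 points", call. = FALSE)
  pm <- colMeans(P); qm <- colMeans(Q)
  Pc <- sweep(P, 2, pm); Qc <- sweep(Q, 2, qm)
  # collinear point sets leave the rotation about the line undetermined
  sv_p <- svd(Pc, nu = 0, nv = 0)$d
  sv_q <- svd(Qc, nu = 0, nv = 0)$d
  if (sv_p[2] <= 1e-8 * max(sv_p[1], 1e-12) &&
      sv_q[2] <= 1e-8 * max(sv_q[1], 1e-12))
    stop("rank-deficient: point sets are collinear", call. = FALSE)
  H <- t(Pc) %*% Qc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- qm - as.vector(R %*% pm)
  moved <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  structure(list(transform = rigid_transform(R, tr), rmsd = rmsd, n = nrow(P)),
            class = "kabsch_fit")
}

#' @export
print.kabsch_fit <- function(x, ...) {
  cat(sprintf("<kabsch_fit> n = %d, rmsd = %.4f A\n", x$n, x$rmsd))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Kabsch fit into one row per transform component
#'
#' @param x A `kabsch_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate` covering the nine
#'   rotation entries (`r11`..`r33`, row-major) and the translation
#'   (`t1`..`t3`).
#' @export
tidy.kabsch_fit <- function(x, ...) {
  R <- x$transform$rotation
  tibble::tibble(
    term = c(paste0("r", rep(1:3, each = 3), rep(1:3, 3)), paste0("t", 1:3)),
    estimate = c(as.vector(t(R)), x$transform$translation)
  )
}

#' One-row summary of a Kabsch fit
#' @param x A `kabsch_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `rmsd`, `n` and the rotation determinant.
#' @export
glance.kabsch_fit <- function(x, ...) {
  tibble::tibble(rmsd = x$rmsd, n = x$n, det = det(x$transform$rotation))
}

# ---- torsion ----------------------------------------------------------------

#' Signed torsion angle of four points
#'
#' Standard IUPAC convention: looking down the p2->p3 bond, the angle from the
#' p1 side to the p4 side, positive clockwise, reported in degrees in
#' (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("collinear points: torsion undefined", call. = FALSE)
  ang <- atan2(sum(vcross(n1, n2) * vhat(b2)), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# ---- axis fitting -----------------------------------------------------------

#' Fit a straight axis through a run of C-alpha positions
#'
#' The axis is the first principal component of the centered coordinates,
#' oriented N-terminus to C-terminus: the sign is flipped if needed so that
#' `(last - first) . direction > 0`. The reported endpoints are the
#' orthogonal projections of the first and last point onto the axis line.
#'
#' @param coords N x 3 matrix (or data frame with x/y/z) of C-alpha
#'   positions in chain order, N >= 3.
#' @return An `axis_fit`: list with `point` (centroid), unit `direction`,
#'   `n_start` and `c_end` endpoint 3-vectors.
#' @export
fit_axis <- function(coords) {
  m <- as_coord_matrix(coords)
  if (nrow(m) < 3) stop("need at least 3 points to fit an axis", call. = FALSE)
  ctr <- colMeans(m)
  mc <- sweep(m, 2, ctr)
  dir <- svd(mc, nu = 0, nv = 3)$v[, 1]
  if (sum((m[nrow(m), ] - m[1, ]) * dir) < 0) dir <- -dir
  dir <- dir / vnorm(dir)
  proj <- function(p) ctr + sum((p - ctr) * dir) * dir
  structure(list(point = ctr, direction = dir,
                 n_start = proj(m[1, ]), c_end = proj(m[nrow(m), ])),
            class = "axis_fit")
}

#' @export
print.axis_fit <- function(x, ...) {
  cat("<axis_fit> direction:", paste(signif(x$direction, 4), collapse = " "),
      " length:", signif(vnorm(x$c_end - x$n_start), 4), "A\n")
  invisible(x)
}

# ---- residue-level distances ------------------------------------------------

#' Select the atoms taking part in distance calculations
#'
#' `heavy` keeps all non-hydrogen atoms, `ca` keeps C-alpha only, `cb` keeps
#' C-beta with C-alpha substituted for glycine.
#' @noRd
select_mode_atoms <- function(s, atom_mode) {
  s <- s[!is_hydrogen(s$atom, s$element), , drop = FALSE]
  switch(atom_mode,
    heavy = s,
    ca = s[s$atom == "CA", , drop = FALSE],
    cb = {
      keep <- s$atom == "CB" | (s$atom == "CA" & s$resname == "GLY")
      s[keep, , drop = FALSE]
    },
    stop("unknown atom_mode: ", atom_mode, call. = FALSE)
  )
}

is_hydrogen <- function(atom, element) {
  el <- toupper(trimws(element))
  byel <- el %in% c("H", "D")
  # fall back on the atom name when the element field is blank
  nm <- toupper(trimws(atom))
  stripped <- sub("^[0-9]+", "", nm)
  byname <- el == "" & substr(stripped, 1, 1) %in% c("H", "D")
  byel | byname
}

#' Minimum inter-residue distances between two residue sets
#'
#' Entry (i, j) is the minimum distance over the selected atom pairs of
#' residue i of `a` and residue j of `b`. A residue lacking every selected
#' atom yields `NA` in its row/column (flagged missing, excluded downstream).
#'
#' @param a,b Structure tibbles (residue sets, e.g. single chains).
#' @param atom_mode One of `"heavy"`, `"ca"`, `"cb"`.
#' @return Numeric matrix, rows = residues of `a`, columns = residues of `b`
#'   (in file order), dimnames = residue keys `"<chain>:<resno><ins>"`.
#' @export
pairwise_min_distances <- function(a, b, atom_mode = c("heavy", "ca", "cb")) {
  atom_mode <- match.arg(atom_mode)
  ra <- residue_keys(a); rb <- residue_keys(b)
  sa <- select_mode_atoms(a, atom_mode); sb <- select_mode_atoms(b, atom_mode)
  out <- matrix(NA_real_, length(ra), length(rb), dimnames = list(ra, rb))
  if (nrow(sa) == 0 || nrow(sb) == 0) return(out)
  ma <- as_coord_matrix(sa); mb <- as_coord_matrix(sb)
  ia <- match(residue_keys(sa, unique = FALSE), ra)
  ib <- match(residue_keys(sb, unique = FALSE), rb)
  d2 <- outer(rowSums(ma^2), rep(1, nrow(mb))) +
    outer(rep(1, nrow(ma)), rowSums(mb^2)) - 2 * ma %*% t(mb)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  for (i in seq_along(ra)) {
    ri <- which(ia == i)
    if (!length(ri)) next
    for (j in seq_along(rb)) {
      rj <- which(ib == j)
      if (!length(rj)) next
      out[i, j] <- min(d[ri, rj])
    }
  }
  out
}
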