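# Deterministic generators of synthetic structures with known ground truth.
# Chains are built by sequential internal-coordinate placement (NeRF) from
# ideal bond lengths/angles, so every geometric property asserted about them
# is a consequence of the construction, not of any reference file.

# ideal backbone internal coordinates (Angstrom / degrees)
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N  <- 1.329
BOND_C_O  <- 1.231
BOND_CA_CB <- 1.530
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.5
ANGLE_C_CA_CB <- 109.45
TORSION_N_C_CA_CB <- 120  # L-amino-acid branch

#' Place an atom from three reference atoms (NeRF)
#'
#' Returns the point D with |D-C| = `bond`, angle(B,C,D) = `angle` and
#' dihedral(A,B,C,D) = `torsion` (degrees).
#' @noRd
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  bc <- vhat(c - b)
  n <- vhat(vcross(b - a, bc))
  m <- vcross(n, bc)
  d_local <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  as.vector(c + cbind(bc, m, n) %*% d_local)
}

#' Build a poly-alanine backbone with prescribed torsions
#'
#' @param n Number of residues.
#' @param phi,psi Backbone torsions in degrees (recycled to length `n`).
#' @param omega Peptide-bond torsion, degrees.
#' @return List of per-residue coordinate lists (N, CA, C, O, CB).
#' @noRd
build_backbone <- function(n, phi, psi, omega = 180) {
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  res <- vector("list", n)
  N <- c(0, 0, 0)
  CA <- c(BOND_N_CA, 0, 0)
  C <- place_atom(c(0, 1, 0), N, CA, BOND_CA_C, ANGLE_N_CA_C, phi[1])
  res[[1]] <- list(N = N, CA = CA, C = C)
  for (i in seq_len(n)[-1]) {
    p <- res[[i - 1]]
    N <- place_atom(p$N, p$CA, p$C, BOND_C_N, ANGLE_CA_C_N, psi[i - 1])
    CA <- place_atom(p$CA, p$C, N, BOND_N_CA, ANGLE_C_N_CA, omega)
    C <- place_atom(p$C, N, CA, BOND_CA_C, ANGLE_N_CA_C, phi[i])
    res[[i]] <- list(N = N, CA = CA, C = C)
  }
  for (i in seq_len(n)) {
    r <- res[[i]]
    res[[i]]$O <- place_atom(r$N, r$CA, r$C, BOND_C_O, ANGLE_CA_C_O,
                             psi[i] - 180)
    res[[i]]$CB <- place_atom(r$N, r$C, r$CA, BOND_CA_CB, ANGLE_C_CA_CB,
                              TORSION_N_C_CA_CB)
  }
  res
}

backbone_to_structure <- function(res_list, chain = "A", start_resno = 1,
                                  entry_id = "fixture") {
  rows <- purrr::imap(res_list, function(r, i) {
    nm <- names(r)
    tibble::tibble(
      atom = nm,
      resname = "ALA",
      chain = chain,
      resno = start_resno + i - 1L,
      x = purrr::map_dbl(r, 1), y = purrr::map_dbl(r, 2),
      z = purrr::map_dbl(r, 3),
      element = substr(nm, 1, 1)
    )
  })
  a <- dplyr::bind_rows(rows)
  a$serial <- seq_len(nrow(a))
  as_structure(a, entry_id = entry_id)
}

#' Ideal poly-alanine alpha helix
#'
#' Built by sequential internal-coordinate placement with phi = -57, psi =
#' -47, omega = 180 degrees and ideal bond lengths/angles; the carbonyl O is
#' placed trans to the next amide N and each residue carries a C-beta.
#'
#' @param n Number of residues, n >= 4.
#' @return A single-chain structure tibble.
#' @export
make_ideal_helix <- function(n) {
  if (n < 4) stop("a helix needs at least 4 residues", call. = FALSE)
  backbone_to_structure(build_backbone(n, -57, -47), entry_id = "ideal_helix")
}

#' Ideal extended poly-alanine strand
#'
#' Same builder as [make_ideal_helix()] with phi = -120, psi = +120.
#'
#' @param n Number of residues, n >= 3.
#' @return A single-chain structure tibble.
#' @export
make_ideal_strand <- function(n) {
  if (n < 3) stop("a strand needs at least 3 residues", call. = FALSE)
  backbone_to_structure(build_backbone(n, -120, 120),
                        entry_id = "ideal_strand")
}

#' Deterministic pseudo-noise in [-1, 1] (no RNG state touched)
#' @noRd
dnoise <- function(seed, i, k = 0) {
  x <- sin(seed * 12.9898 + i * 78.233 + k * 37.719) * 43758.5453
  2 * (x - floor(x)) - 1
}

#' Rotation taking unit vector a onto unit vector b
#' @noRd
rotation_between <- function(a, b) {
  a <- vhat(a); b <- vhat(b)
  v <- vcross(a, b)
  cth <- sum(a * b)
  if (vnorm(v) < 1e-12) {
    if (cth > 0) return(diag(3))
    # opposite: rotate 180 degrees about any perpendicular
    p <- if (abs(a[1]) < 0.9) vhat(vcross(a, c(1, 0, 0))) else
      vhat(vcross(a, c(0, 1, 0)))
    return(2 * outer(p, p) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

sse_builder <- function(kind, len) {
  if (kind == "H") make_ideal_helix(max(len, 4)) else
    make_ideal_strand(max(len, 3))
}

ca_coords <- function(s) as_coord_matrix(s[s$atom == "CA", ])

#' Pseudo-residue backbone around prescribed C-alpha positions
#' @noRd
loop_pseudo_residues <- function(ca_pts, prev_pt, next_pt) {
  k <- nrow(ca_pts)
  all_pts <- rbind(prev_pt, ca_pts, next_pt)
  purrr::map(seq_len(k), function(i) {
    ca <- ca_pts[i, ]
    t <- vhat(all_pts[i + 2, ] - all_pts[i, ])
    ref <- if (abs(t[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    p <- vhat(vcross(t, ref))
    list(N = ca - 1.2 * t, CA = ca, C = ca + 1.2 * t,
         O = ca + 1.2 * t + 1.23 * p, CB = ca + 1.53 * vhat(vcross(p, t)))
  })
}

#' Two-SSE scaffold with prescribed inter-element geometry
#'
#' Builds a first secondary-structure element with its axis along +z ending
#' at the origin, a second element whose axis is rotated by `theta` (in the
#' xz-plane) and whose axis start sits at distance `D` from the first
#' element's axis end (the displacement direction is fixed at 45 degrees
#' from the first axis, so the hoist angle is ~45 degrees and the meridian
#' is well defined), and connects them with `loop_len` residues whose
#' C-alphas interpolate the gap with a small seed-deterministic jitter.
#'
#' @param sse1_kind,sse2_kind `"H"` or `"E"`.
#' @param sse1_len,sse2_len Residues per element (helix >= 4, strand >= 3).
#' @param loop_len Number of connecting loop residues (>= 0).
#' @param D Axis-end to axis-start distance, Angstrom.
#' @param theta Inter-axis packing angle, degrees in [0, 180].
#' @param seed Integer controlling the (deterministic) loop jitter.
#' @return A single-chain structure tibble with attributes `regions`
#'   (tibble of `resno`, `region` in sse1/loop/sse2) and `params`.
#' @export
make_scaffold <- function(sse1_kind = "H", sse1_len = 12,
                          sse2_kind = "H", sse2_len = 12,
                          loop_len = 6, D = 10, theta = 90, seed = 1) {
  stopifnot(sse1_kind %in% c("H", "E"), sse2_kind %in% c("H", "E"),
            D >= 0, theta >= 0, theta <= 180, loop_len >= 0)
  min1 <- if (sse1_kind == "H") 4 else 3
  min2 <- if (sse2_kind == "H") 4 else 3
  if (sse1_len < min1 || sse2_len < min2)
    stop("SSE shorter than its minimum length", call. = FALSE)

  c1 <- sse_builder(sse1_kind, sse1_len)
  ax1 <- fit_axis(ca_coords(c1))
  R1 <- rotation_between(ax1$direction, c(0, 0, 1))
  t1 <- -as.vector(R1 %*% ax1$c_end)
  c1 <- apply_transform(c1, rigid_transform(R1, t1))

  th <- theta * pi / 180
  M2 <- c(sin(th), 0, cos(th))
  dv_hat <- c(sin(pi / 4), 0, cos(pi / 4))
  P2 <- D * dv_hat

  c2 <- sse_builder(sse2_kind, sse2_len)
  ax2 <- fit_axis(ca_coords(c2))
  R2 <- rotation_between(ax2$direction, M2)
  t2 <- P2 - as.vector(R2 %*% ax2$n_start)
  c2 <- apply_transform(c2, rigid_transform(R2, t2))

  anchor1 <- as.numeric(c1[c1$atom == "C", c("x", "y", "z")][sum(c1$atom == "C"), ])
  anchor2 <- as.numeric(c2[c2$atom == "N", c("x", "y", "z")][1, ])
  gap <- vnorm(anchor2 - anchor1)
  if (gap > 3.8 * (loop_len + 1))
    stop(sprintf(
      "impossible closure: loop of %d residues cannot span %.1f A", loop_len,
      gap), call. = FALSE)

  loop_res <- list()
  if (loop_len > 0) {
    fr <- seq_len(loop_len) / (loop_len + 1)
    ca_pts <- t(vapply(seq_len(loop_len), function(k) {
      base <- anchor1 + fr[k] * (anchor2 - anchor1)
      base + 0.25 * c(dnoise(seed, k, 1), dnoise(seed, k, 2),
                      dnoise(seed, k, 3))
    }, numeric(3)))
    loop_res <- loop_pseudo_residues(ca_pts, anchor1, anchor2)
  }

  assemble_single_chain(list(c1), loop_res, list(c2),
                        regions = c("sse1", "loop", "sse2"),
                        params = list(sse1_kind = sse1_kind,
                                      sse2_kind = sse2_kind, D = D,
                                      theta = theta, loop_len = loop_len,
                                      seed = seed),
                        entry_id = "scaffold")
}

#' Stitch SSE chains and pseudo-residue loops into one renumbered chain
#' @noRd
assemble_single_chain <- function(pre_chains, loop_res, post_chains,
                                  regions, params, entry_id) {
  chunk_tbl <- function(s) {
    keys <- paste0(s$resno, "_", s$ins)
    split(s, factor(keys, levels = unique(keys)))
  }
  residues <- c(
    unlist(lapply(pre_chains, chunk_tbl), recursive = FALSE),
    lapply(loop_res, function(r) {
      tibble::tibble(atom = names(r), resname = "ALA", chain = "A",
                     resno = 0L, x = purrr::map_dbl(r, 1),
                     y = purrr::map_dbl(r, 2), z = purrr::map_dbl(r, 3),
                     element = substr(names(r), 1, 1))
    }),
    unlist(lapply(post_chains, chunk_tbl), recursive = FALSE)
  )
  n_pre <- sum(vapply(pre_chains, function(s)
    length(unique(paste0(s$resno, "_", s$ins))), numeric(1)))
  n_loop <- length(loop_res)
  region <- c(rep(regions[1], n_pre), rep(regions[2], n_loop),
              rep(regions[3], length(residues) - n_pre - n_loop))
  rows <- purrr::map(seq_along(residues), function(i) {
    r <- tibble::as_tibble(residues[[i]])[
      , c("atom", "resname", "x", "y", "z", "element")]
    r$chain <- "A"
    r$resno <- i
    r
  })
  a <- dplyr::bind_rows(rows)
  a$serial <- seq_len(nrow(a))
  out <- as_structure(a, entry_id = entry_id)
  attr(out, "regions") <- tibble::tibble(resno = seq_along(residues),
                                         region = region)
  attr(out, "params") <- params
  out
}

#' Antiparallel two-stranded beta hairpin
#'
#' Two ideal strands joined by a short pseudo-loop, the second strand placed
#' by a deterministic rigid-body fit to ideal antiparallel backbone
#' hydrogen-bond distances (N...O = 2.9 Angstrom on the directly-bonded
#' pairs), so the Kabsch-Sander assigner finds genuine inter-strand bridges.
#'
#' @param n_per_strand Residues per strand (>= 4).
#' @param loop_len Connecting pseudo-residues, default 2.
#' @return A single-chain structure tibble with a `regions` attribute
#'   (sse1 / loop / sse2).
#' @export
make_hairpin <- function(n_per_strand = 6, loop_len = 2) {
  stopifnot(n_per_strand >= 4)
  n <- n_per_strand
  sA <- make_ideal_strand(n)
  sB <- make_ideal_strand(n)
  getat <- function(s, resno, atom)
    as.numeric(s[s$resno == resno & s$atom == atom, c("x", "y", "z")])

  # pairing: A_i across from B_(n+1-i); hydrogen-bonded ("wide") pairs at
  # even i so the pair closest to the turn (A_n, B_1) is bonded
  wide <- seq(n, 2, by = -2)
  atmat <- function(s, name) {
    sel <- s[s$atom == name, ]
    as.matrix(sel[order(sel$resno), c("x", "y", "z")])
  }
  A_O <- atmat(sA, "O"); A_N <- atmat(sA, "N"); A_CA <- atmat(sA, "CA")
  B_O <- atmat(sB, "O"); B_N <- atmat(sB, "N"); B_CA <- atmat(sB, "CA")
  jw <- n + 1 - wide
  rev_idx <- n:1

  objective <- function(p) {
    R <- euler_rotation(p[1], p[2], p[3])
    shift <- function(m) m %*% t(R) + matrix(p[4:6], nrow(m), 3, byrow = TRUE)
    BtN <- shift(B_N); BtO <- shift(B_O); BtCA <- shift(B_CA)
    d1 <- sqrt(rowSums((A_O[wide, , drop = FALSE] -
                          BtN[jw, , drop = FALSE])^2))
    d2 <- sqrt(rowSums((A_N[wide, , drop = FALSE] -
                          BtO[jw, , drop = FALSE])^2))
    dca <- sqrt(rowSums((A_CA - BtCA[rev_idx, , drop = FALSE])^2))
    sum((d1 - 2.9)^2) + sum((d2 - 2.9)^2) + 0.2 * sum((dca - 4.9)^2)
  }
  init <- hairpin_init(sA, sB, n)
  fit <- stats::optim(init, objective, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  R <- euler_rotation(fit$par[1], fit$par[2], fit$par[3])
  sBt <- apply_transform(sB, rigid_transform(R, fit$par[4:6]))

  anchor1 <- getat(sA, n, "C")
  anchor2 <- getat(sBt, 1, "N")
  fr <- seq_len(loop_len) / (loop_len + 1)
  ca_pts <- t(vapply(seq_len(loop_len), function(k)
    anchor1 + fr[k] * (anchor2 - anchor1) + c(0, 0, 2.5 * sin(pi * fr[k])),
    numeric(3)))
  loop_res <- loop_pseudo_residues(ca_pts, anchor1, anchor2)
  assemble_single_chain(list(sA), loop_res, list(sBt),
                        regions = c("sse1", "loop", "sse2"),
                        params = list(n_per_strand = n, loop_len = loop_len),
                        entry_id = "hairpin")
}

euler_rotation <- function(a, b, c) {
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(c), sin(c), 0, -sin(c), cos(c)), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Starting placement for the hairpin fit: strand B antiparallel to A,
#' offset perpendicular to the strand axis.
#' @noRd
hairpin_init <- function(sA, sB, n) {
  axA <- fit_axis(ca_coords(sA))
  # rotate B 180 degrees about an axis perpendicular to A's direction
  perp <- vhat(vcross(axA$direction, c(0, 0, 1)))
  if (vnorm(vcross(axA$direction, c(0, 0, 1))) < 1e-6)
    perp <- vhat(vcross(axA$direction, c(0, 1, 0)))
  # initial params are refined numerically; a coarse antiparallel offset
  # placement is enough for convergence
  c(0, pi, 0, as.numeric(axA$c_end + 4.9 * perp - axA$n_start))
}

#' Synthetic two-chain dimer with an exact number of residue contacts
#'
#' Two poly-alanine chains laid out on well-separated lattices; the first
#' `n_contacts` residues of chain B are moved toward their chain-A partners
#' until the minimum heavy-atom distance equals `contact_distance` (root
#' finding, tolerance well under 0.01 Angstrom). Every other inter-chain
#' residue pair is farther than `contact_distance + 2`.
#'
#' @param n_contacts Number of contacting residue pairs (>= 0).
#' @param contact_distance Minimum heavy-atom distance of each contact,
#'   Angstrom (0 < d <= 5).
#' @param seed Integer; orients each residue deterministically.
#' @param n_per_chain Residues per chain.
#' @return A two-chain structure tibble.
#' @export
make_dimer <- function(n_contacts = 1, contact_distance = 3, seed = 1,
                       n_per_chain = 10) {
  stopifnot(n_contacts >= 0, contact_distance > 0, n_per_chain >= 1)
  if (n_contacts > n_per_chain)
    stop("infeasible packing: more contacts than residues", call. = FALSE)
  if (contact_distance > 5)
    stop("infeasible packing: contact_distance above 5 A", call. = FALSE)
  unit <- build_backbone(1, -57, -47)[[1]]
  unit <- lapply(unit, function(p) p - unit$CA)  # center on CA
  spacing <- contact_distance + 9
  sep <- contact_distance + 30

  place_res <- function(idx, chain, centre) {
    R <- euler_rotation(pi * dnoise(seed, idx, match(chain, c("A", "B"))),
                        pi * dnoise(seed, idx, 10 + match(chain, c("A", "B"))),
                        pi * dnoise(seed, idx, 20 + match(chain, c("A", "B"))))
    pts <- lapply(unit, function(p) as.vector(R %*% p) + centre)
    tibble::tibble(atom = names(pts), resname = "ALA", chain = chain,
                   resno = as.integer(idx),
                   x = purrr::map_dbl(pts, 1), y = purrr::map_dbl(pts, 2),
                   z = purrr::map_dbl(pts, 3),
                   element = substr(names(pts), 1, 1))
  }

  chainA <- dplyr::bind_rows(lapply(seq_len(n_per_chain), function(i)
    place_res(i, "A", c(spacing * i, 0, 0))))

  min_heavy <- function(t1, t2) {
    h1 <- t1[t1$element != "H", ]; h2 <- t2[t2$element != "H", ]
    m1 <- as.matrix(h1[, c("x", "y", "z")]); m2 <- as.matrix(h2[, c("x", "y", "z")])
    min(sqrt(outer(rowSums(m1^2), rep(1, nrow(m2))) +
               outer(rep(1, nrow(m1)), rowSums(m2^2)) - 2 * m1 %*% t(m2)))
  }

  chainB <- dplyr::bind_rows(lapply(seq_len(n_per_chain), function(i) {
    if (i <= n_contacts) {
      f <- function(y) {
        cand <- place_res(i, "B", c(spacing * i, y, 0))
        min_heavy(chainA[chainA$resno == i, ], cand) - contact_distance
      }
      y <- stats::uniroot(f, c(0, sep), tol = 1e-9)$root
      place_res(i, "B", c(spacing * i, y, 0))
    } else {
      place_res(i, "B", c(spacing * i, sep, 0))
    }
  }))

  a <- dplyr::bind_rows(chainA, chainB)
  a$serial <- seq_len(nrow(a))
  as_structure(a, entry_id = "dimer")
}
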