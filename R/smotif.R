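# Super-secondary structure motifs: two consecutive SSEs plus the
# connecting loop, described by four geometric parameters computed from the
# fitted SSE axes (M1, M2 = unit axis directions N->C; Dv = vector from the
# first axis C-end to the second axis N-start):
#   D     = |Dv|                      inter-SSE distance, Angstrom
#   delta = angle(M1, Dv)             "hoist", degrees in [0, 180]
#   theta = angle(M1, M2)             "packing", degrees in [0, 180]
#   rho   = azimuth of M2 about M1    "meridian", degrees in [0, 360),
#           measured right-handed about M1 from the (M1, Dv) half-plane
# The motif is flagged degenerate when |Dv| is ~0 or Dv is parallel to M1
# (the reference half-plane vanishes); delta/rho are then undefined.

#' Four-parameter loop geometry of an SSE pair
#'
#' @param axis1,axis2 [fit_axis()] results for the first and second SSE.
#' @return One-row tibble: `D`, `delta`, `theta`, `rho`, `degenerate`.
#' @export
smotif_geometry <- function(axis1, axis2) {
  M1 <- axis1$direction
  M2 <- axis2$direction
  Dv <- axis2$n_start - axis1$c_end
  D <- vnorm(Dv)
  theta <- vangle(M1, M2)
  if (D < 1e-6)
    return(tibble::tibble(D = D, delta = NA_real_, theta = theta,
                          rho = NA_real_, degenerate = TRUE))
  delta <- vangle(M1, Dv)
  e1 <- Dv - sum(Dv * M1) * M1
  if (vnorm(e1) < 1e-9)
    return(tibble::tibble(D = D, delta = delta, theta = theta,
                          rho = NA_real_, degenerate = TRUE))
  e1 <- vhat(e1)
  e2 <- vcross(M1, e1)
  w <- M2 - sum(M2 * M1) * M1
  rho <- if (vnorm(w) < 1e-9) 0 else {
    r <- atan2(sum(w * e2), sum(w * e1)) * 180 / pi
    (r + 360) %% 360
  }
  tibble::tibble(D = D, delta = delta, theta = theta, rho = rho,
                 degenerate = FALSE)
}


#' Extract smotifs (SSE-loop-SSE units) from a segmented chain
#'
#' One smotif per consecutive SSE pair; the loop is the run of residues
#' strictly between the first SSE's end and the second SSE's start (length 0
#' when the SSEs abut). Geometry is computed per motif from the fitted axes.
#'
#' @param chain_tbl The chain the SSEs were segmented on.
#' @param sses SSE tibble from [segment_sses()].
#' @return A tibble with one row per smotif: `motif_type` (HH/HE/EH/EE),
#'   SSE ranges, `loop_start`/`loop_end` (empty strings for a zero-length
#'   loop), `loop_length`, the four geometry parameters, `degenerate`, and
#'   `axis1`/`axis2` list-columns.
#' @export
extract_smotifs <- function(chain_tbl, sses) {
  if (nrow(sses) < 2)
    return(tibble::tibble(motif_type = character(), sse1_start = character(),
                          sse1_end = character(), sse2_start = character(),
                          sse2_end = character(), loop_start = character(),
                          loop_end = character(), loop_length = integer(),
                          D = double(), delta = double(), theta = double(),
                          rho = double(), degenerate = logical(),
                          axis1 = list(), axis2 = list()))
  res <- chain_tbl[!duplicated(paste0(chain_tbl$resno, "_", chain_tbl$ins)), ]
  res_id <- function(i) paste0(res$resno[i], res$ins[i])
  rows <- purrr::map(seq_len(nrow(sses) - 1), function(k) {
    s1 <- sses[k, ]; s2 <- sses[k + 1, ]
    loop_len <- s2$from - s1$to - 1L
    geom <- smotif_geometry(s1$axis[[1]], s2$axis[[1]])
    tibble::tibble(
      motif_type = paste0(s1$kind, s2$kind),
      sse1_start = s1$start, sse1_end = s1$end,
      sse2_start = s2$start, sse2_end = s2$end,
      loop_start = if (loop_len > 0) res_id(s1$to + 1L) else "",
      loop_end = if (loop_len > 0) res_id(s2$from - 1L) else "",
      loop_length = loop_len,
      geom,
      axis1 = s1$axis, axis2 = s2$axis
    )
  })
  dplyr::bind_rows(rows)
}

#' Weighted distance between two smotif geometries
#'
#' Euclidean distance over (dD, d.delta, d.theta, d.rho) with the meridian
#' difference taken circularly (`min(|r1-r2|, 360-|r1-r2|)`). Default
#' weights: 1 per Angstrom on D and 1/15 per degree on the three angles, so
#' 15 degrees trades against 1 Angstrom.
#'
#' @param g1,g2 One-row geometry tibbles (or lists) with `D`, `delta`,
#'   `theta`, `rho`; neither may be degenerate.
#' @param weights Numeric length-4 weights for (D, delta, theta, rho).
#' @return Non-negative scalar.
#' @export
geometry_distance <- function(g1, g2, weights = c(1, 1 / 15, 1 / 15, 1 / 15)) {
  if (isTRUE(g1$degenerate) || isTRUE(g2$degenerate) ||
      anyNA(c(g1$D, g1$delta, g1$theta, g1$rho,
              g2$D, g2$delta, g2$theta, g2$rho)))
    stop("degenerate smotif geometry", call. = FALSE)
  drho <- abs(g1$rho - g2$rho)
  drho <- min(drho, 360 - drho)
  d <- c(g1$D - g2$D, g1$delta - g2$delta, g1$theta - g2$theta, drho)
  sqrt(sum((weights * d)^2))
}

#' Find the geometrically nearest smotifs in a library
#'
#' @param library A smotif tibble (rows are candidate motifs).
#' @param query One smotif row (or one-row tibble) with geometry columns.
#' @param k Number of neighbours to return (> 0); if larger than the
#'   library, the whole library is returned sorted.
#' @param same_type When `TRUE`, restrict to candidates with the query's
#'   `motif_type` and `loop_length` within `loop_tolerance`.
#' @param loop_tolerance Allowed |loop length difference| under `same_type`.
#' @param weights Passed to [geometry_distance()].
#' @return The selected library rows, nearest first, with a `distance`
#'   column appended. Ties keep library order (stable sort).
#' @export
search_similar <- function(library, query, k = 5, same_type = FALSE,
                           loop_tolerance = 0,
                           weights = c(1, 1 / 15, 1 / 15, 1 / 15)) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (!nrow(library)) stop("empty smotif library", call. = FALSE)
  cand <- library[!library$degenerate, , drop = FALSE]
  if (same_type)
    cand <- cand[cand$motif_type == query$motif_type &
                   abs(cand$loop_length - query$loop_length) <= loop_tolerance,
                 , drop = FALSE]
  if (!nrow(cand)) return(dplyr::mutate(cand, distance = double()))
  cand$distance <- vapply(seq_len(nrow(cand)), function(i)
    geometry_distance(query, cand[i, ], weights = weights), numeric(1))
  cand <- cand[order(cand$distance), , drop = FALSE]  # stable: ties keep order
  utils::head(cand, k)
}
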