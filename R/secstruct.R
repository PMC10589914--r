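# Secondary-structure assignment. The internal assigner re-creates the
# hydrogen-bond electrostatics of the Kabsch-Sander method: a backbone
# CO(i)...HN(j) bond is declared when
#   E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)  <  -0.5 kcal/mol,
# with the amide H imputed when absent. Helices come from pairs of
# consecutive i -> i+4 turns, strands from parallel/antiparallel bridge
# patterns; everything else is coil.

KS_Q1Q2_F <- 0.084 * 332   # partial-charge product times electrostatic factor
KS_CUTOFF <- -0.5          # kcal/mol

#' Backbone table: one row per residue with N/CA/C/O coordinates
#' @noRd
backbone_table <- function(chain_tbl) {
  keys <- unique(paste0(chain_tbl$resno, "_", chain_tbl$ins))
  grab <- function(name) {
    sel <- chain_tbl[chain_tbl$atom == name, ]
    m <- matrix(NA_real_, length(keys), 3)
    idx <- match(paste0(sel$resno, "_", sel$ins), keys)
    first <- !duplicated(idx)
    m[idx[first], ] <- as.matrix(sel[first, c("x", "y", "z")])
    m
  }
  res <- chain_tbl[!duplicated(paste0(chain_tbl$resno, "_", chain_tbl$ins)), ]
  list(keys = keys, resno = res$resno, ins = res$ins, resname = res$resname,
       N = grab("N"), CA = grab("CA"), C = grab("C"), O = grab("O"))
}

#' Kabsch-Sander hydrogen-bond energy matrix
#'
#' entry (i, j) = energy of the CO(i) -> NH(j) bond; NA where undefined
#' (missing atoms, first residue's H, proline, |i - j| < 2).
#' @noRd
ks_energy_matrix <- function(bb) {
  n <- length(bb$keys)
  H <- matrix(NA_real_, n, 3)
  for (j in 2:n) {
    if (any(is.na(bb$N[j, ])) || any(is.na(bb$CA[j, ])) ||
        any(is.na(bb$C[j - 1, ]))) next
    u <- vhat(bb$C[j - 1, ] - bb$N[j, ]) + vhat(bb$CA[j, ] - bb$N[j, ])
    if (vnorm(u) < 1e-9) next
    H[j, ] <- bb$N[j, ] - 1.01 * vhat(u)
  }
  E <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    if (any(is.na(bb$C[i, ])) || any(is.na(bb$O[i, ]))) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2) next
      if (toupper(bb$resname[j]) == "PRO") next
      if (any(is.na(bb$N[j, ])) || any(is.na(H[j, ]))) next
      rON <- vnorm(bb$O[i, ] - bb$N[j, ])
      rCH <- vnorm(bb$C[i, ] - H[j, ])
      rOH <- vnorm(bb$O[i, ] - H[j, ])
      rCN <- vnorm(bb$C[i, ] - bb$N[j, ])
      if (min(rON, rCH, rOH, rCN) < 0.5) { E[i, j] <- -9.9; next }
      E[i, j] <- KS_Q1Q2_F * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    }
  }
  E
}

#' Assign secondary structure with the internal hydrogen-bond method
#'
#' Backbone amide hydrogens are imputed 1.01 Angstrom from N along the
#' direction opposite the bisector of the C(prev)-N-CA angle. Helix (H) is
#' assigned to runs covered by two consecutive i -> i+4 hydrogen-bonded
#' turns; strand (E) to residues in parallel or antiparallel bridges; coil
#' (C) otherwise. Residues with missing backbone atoms are forced to coil
#' and counted in the `n_incomplete` attribute.
#'
#' @param chain_tbl A single protein chain (structure tibble).
#' @return A tibble with columns `chain`, `resno`, `ins`, `resname`, `ss`
#'   (one of H/E/C); attributes `source = "internal"` and `n_incomplete`.
#' @export
assign_secondary <- function(chain_tbl) {
  if (chain_tbl$chain_type[1] != "protein")
    stop("secondary structure is assigned to protein chains", call. = FALSE)
  bb <- backbone_table(chain_tbl)
  n <- length(bb$keys)
  incomplete <- apply(cbind(bb$N, bb$CA, bb$C, bb$O), 1, anyNA)
  E <- ks_energy_matrix(bb)
  hb <- !is.na(E) & E < KS_CUTOFF
  ss <- rep("C", n)

  # helix: two consecutive i -> i+4 turns cover residues i .. i+3
  turn4 <- rep(FALSE, n)
  for (i in seq_len(n)) if (i + 4 <= n && hb[i, i + 4]) turn4[i] <- TRUE
  for (i in 2:n) {
    if (i + 3 <= n && turn4[i - 1] && turn4[i]) ss[i:(i + 3)] <- "H"
  }

  # strand: parallel / antiparallel bridge patterns, helix takes precedence
  bridge <- rep(FALSE, n)
  get <- function(i, j) i >= 1 && j >= 1 && i <= n && j <= n && hb[i, j]
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) < 3) next
      par <- (get(i - 1, j) && get(j, i + 1)) ||
        (get(j - 1, i) && get(i, j + 1))
      anti <- (get(i, j) && get(j, i)) ||
        (get(i - 1, j + 1) && get(j - 1, i + 1))
      if (par || anti) { bridge[i] <- TRUE; bridge[j] <- TRUE }
    }
  }
  ss[bridge & ss != "H"] <- "E"
  ss[incomplete] <- "C"

  out <- tibble::tibble(chain = chain_tbl$chain[1], resno = bb$resno,
                        ins = bb$ins, resname = bb$resname, ss = ss)
  attr(out, "source") <- "internal"
  attr(out, "n_incomplete") <- sum(incomplete)
  class(out) <- c("ss_assignment", class(out))
  out
}

#' Read a classic DSSP output file into an assignment
#'
#' The 8-state DSSP alphabet is collapsed to three states: H, G, I -> H;
#' E, B -> E; everything else -> C. Chain-break records (`!` in the residue
#' column) are skipped.
#'
#' @param text Character vector of DSSP output lines (or one string).
#' @param chain Optional chain id; when given, only that chain is kept.
#' @return An assignment tibble as from [assign_secondary()], with
#'   `source = "dssp_file"`.
#' @export
parse_dssp <- function(text, chain = NULL) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) stop("not a DSSP file: '  #  RESIDUE' header missing",
                         call. = FALSE)
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  aa <- substr(body, 14, 14)
  keep <- aa != "!"
  body <- body[keep]
  resno <- suppressWarnings(as.integer(trimws(substr(body, 6, 10))))
  ins <- trimws(substr(body, 11, 11))
  ch <- trimws(substr(body, 12, 12))
  code <- substr(body, 17, 17)
  ss <- dplyr::case_when(code %in% c("H", "G", "I") ~ "H",
                         code %in% c("E", "B") ~ "E",
                         TRUE ~ "C")
  out <- tibble::tibble(chain = ch, resno = resno, ins = ins,
                        resname = substr(body, 14, 14), ss = ss)
  if (!is.null(chain)) out <- out[out$chain == chain, , drop = FALSE]
  attr(out, "source") <- "dssp_file"
  attr(out, "n_incomplete") <- 0L
  class(out) <- c("ss_assignment", class(out))
  out
}

#' Segment an assignment into secondary-structure elements
#'
#' Maximal runs of H (length >= 4) and E (length >= 3) become SSEs with a
#' straight axis fitted through their C-alpha positions; shorter runs are
#' demoted to coil. SSEs are returned N- to C-terminal.
#'
#' @param assignment An assignment tibble aligned to `chain_tbl`.
#' @param chain_tbl The chain the assignment was computed on.
#' @return A tibble with one row per SSE: `kind`, `start`, `end` (residue
#'   ids), `length`, `from`, `to` (row indices into the residue sequence)
#'   and an `axis` list-column of [fit_axis()] results.
#' @export
segment_sses <- function(assignment, chain_tbl) {
  ss <- assignment$ss
  r <- rle(ss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- (r$values == "H" & r$lengths >= 4) |
    (r$values == "E" & r$lengths >= 3)
  if (!any(keep))
    return(tibble::tibble(kind = character(), start = character(),
                          end = character(), length = integer(),
                          from = integer(), to = integer(), axis = list()))
  ca <- chain_tbl[chain_tbl$atom == "CA", ]
  ca_keys <- paste0(ca$resno, "_", ca$ins)
  res_id <- function(i) paste0(assignment$resno[i], assignment$ins[i])
  rows <- purrr::map(which(keep), function(k) {
    i <- starts[k]; j <- ends[k]
    sel <- match(paste0(assignment$resno[i:j], "_", assignment$ins[i:j]),
                 ca_keys)
    axis <- fit_axis(as.matrix(ca[sel, c("x", "y", "z")]))
    tibble::tibble(kind = r$values[k], start = res_id(i), end = res_id(j),
                   length = j - i + 1L, from = i, to = j, axis = list(axis))
  })
  dplyr::bind_rows(rows)
}
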