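# Loop grafting: replace a loop in an acceptor chain with a donor loop by
# superposing the flanking stem residues (backbone N, CA, C, O) and splicing
# the transformed donor coordinates into the acceptor.

#' Graft a donor loop into an acceptor chain
#'
#' The `flank` residues on each side of the donor range are superposed (via
#' [kabsch()] on their backbone N/CA/C/O atoms) onto the corresponding
#' acceptor flanks; the resulting transform is applied to the donor loop,
#' which then replaces the acceptor loop. Grafted residues are renumbered
#' consecutively from the start of the acceptor range with empty insertion
#' codes; when the donor loop is longer, numbering continues past the old
#' end and downstream residues keep their numbers (gap-tolerant). Side
#' chains are carried over unmodified.
#'
#' The report counts steric clashes: grafted-loop heavy atoms closer than
#' `clash_cutoff` to any retained acceptor heavy atom, flank residues
#' excluded.
#'
#' @param acceptor Single-chain structure tibble receiving the loop.
#' @param a_range Length-2 residue-id vector, the replaced segment
#'   (inclusive), e.g. `c("19", "38")`.
#' @param donor Single-chain structure tibble providing the loop.
#' @param d_range Length-2 residue-id vector, the donor segment.
#' @param flank Stem residues per side used for the superposition.
#' @param clash_cutoff Heavy-atom clash distance, Angstrom.
#' @return The grafted chain as a structure tibble, with the one-row report
#'   tibble attached as attribute `"graft_report"` (see [graft_report()]).
#' @export
graft_loop <- function(acceptor, a_range, donor, d_range, flank = 4,
                       clash_cutoff = 2.5) {
  a_res <- split_residues(acceptor)
  d_res <- split_residues(donor)
  ai <- range_indices(acceptor, a_range, "acceptor")
  di <- range_indices(donor, d_range, "donor")
  if (ai$i - flank < 1 || ai$j + flank > length(a_res))
    stop("insufficient flank residues on the acceptor", call. = FALSE)
  if (di$i - flank < 1 || di$j + flank > length(d_res))
    stop("insufficient flank residues on the donor", call. = FALSE)

  a_flank_idx <- c((ai$i - flank):(ai$i - 1), (ai$j + 1):(ai$j + flank))
  d_flank_idx <- c((di$i - flank):(di$i - 1), (di$j + 1):(di$j + flank))
  a_bb <- flank_backbone(a_res, a_flank_idx)
  d_bb <- flank_backbone(d_res, d_flank_idx)
  fit <- kabsch(d_bb, a_bb)

  loop <- dplyr::bind_rows(d_res[di$i:di$j])
  loop <- apply_transform(loop, fit$transform)

  # renumber donor residues consecutively from the acceptor range start
  start_no <- a_res[[ai$i]]$resno[1]
  loop_keys <- unique(paste0(loop$resno, "_", loop$ins))
  new_no <- start_no + match(paste0(loop$resno, "_", loop$ins), loop_keys) - 1L
  loop$resno <- as.integer(new_no)
  loop$ins <- ""
  loop$chain <- acceptor$chain[1]

  before <- if (ai$i > 1) dplyr::bind_rows(a_res[1:(ai$i - 1)]) else NULL
  after <- if (ai$j < length(a_res))
    dplyr::bind_rows(a_res[(ai$j + 1):length(a_res)]) else NULL
  out <- dplyr::bind_rows(before, loop, after)
  out$serial <- seq_len(nrow(out))
  out <- as_structure(out, entry_id = attr(acceptor, "entry_id") %||% "")

  retained_idx <- setdiff(seq_along(a_res), c(ai$i:ai$j, a_flank_idx))
  clash_count <- 0L
  if (length(retained_idx)) {
    ret <- dplyr::bind_rows(a_res[retained_idx])
    ret <- ret[!is_hydrogen(ret$atom, ret$element), ]
    lh <- loop[!is_hydrogen(loop$atom, loop$element), ]
    if (nrow(ret) && nrow(lh)) {
      m1 <- as_coord_matrix(lh); m2 <- as_coord_matrix(ret)
      d2 <- outer(rowSums(m1^2), rep(1, nrow(m2))) +
        outer(rep(1, nrow(m1)), rowSums(m2^2)) - 2 * m1 %*% t(m2)
      clash_count <- sum(apply(d2, 1, min) < clash_cutoff^2)
    }
  }

  report <- tibble::tibble(
    flank_rmsd = fit$rmsd,
    n_flank_residues = as.integer(flank),
    donor_range = paste(d_range, collapse = "-"),
    acceptor_range = paste(a_range, collapse = "-"),
    donor_loop_length = length(di$i:di$j),
    acceptor_loop_length = length(ai$i:ai$j),
    clash_count = as.integer(clash_count)
  )
  class(report) <- c("graft_report", class(report))
  attr(out, "graft_report") <- report
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

split_residues <- function(chain_tbl) {
  keys <- paste0(chain_tbl$resno, "_", chain_tbl$ins)
  split(chain_tbl, factor(keys, levels = unique(keys)))
}

range_indices <- function(chain_tbl, rng, what) {
  stopifnot(length(rng) == 2)
  i <- resid_index(chain_tbl, rng[1])
  j <- resid_index(chain_tbl, rng[2])
  if (is.na(i)) stop(what, " residue not found: ", rng[1], call. = FALSE)
  if (is.na(j)) stop(what, " residue not found: ", rng[2], call. = FALSE)
  if (i > j) stop(what, " range start is after its end", call. = FALSE)
  list(i = i, j = j)
}

#' Backbone N/CA/C/O coordinates of flank residues, erroring on gaps
#' @noRd
flank_backbone <- function(res_list, idx) {
  rows <- lapply(idx, function(k) {
    r <- res_list[[k]]
    sel <- match(c("N", "CA", "C", "O"), r$atom)
    if (anyNA(sel))
      stop("flank residue ", r$resno[1], r$ins[1],
           " is missing backbone atoms", call. = FALSE)
    as.matrix(r[sel, c("x", "y", "z")])
  })
  do.call(rbind, rows)
}

#' Retrieve the report attached to a grafted chain
#' @param grafted A chain returned by [graft_loop()].
#' @return The one-row `graft_report` tibble.
#' @export
graft_report <- function(grafted) {
  r <- attr(grafted, "graft_report")
  if (is.null(r)) stop("no graft report attached", call. = FALSE)
  r
}

#' Human-readable graft summary
#'
#' @param report A `graft_report` (or a grafted chain carrying one).
#' @return Character vector of report lines.
#' @export
splice_report <- function(report) {
  if (!inherits(report, "graft_report")) report <- graft_report(report)
  c(
    sprintf("acceptor range: %s", report$acceptor_range),
    sprintf("donor range: %s", report$donor_range),
    sprintf("flank residues per side: %d", report$n_flank_residues),
    sprintf("acceptor loop length: %d", report$acceptor_loop_length),
    sprintf("donor loop length: %d", report$donor_loop_length),
    sprintf("flank rmsd %.3f A", report$flank_rmsd),
    sprintf("clashes: %d", report$clash_count)
  )
}
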