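# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the superposition oracle is Horn's
# quaternion-parametrized closed form (not SVD), distance oracles are plain
# double loops, and the PIR checker is a from-scratch grammar reader.

# Minimum RMSD of mobile onto target over proper rotations, via the largest
# eigenvalue of Horn's 4x4 quaternion matrix.
horn_rmsd <- function(mobile, target) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(target, 2, colMeans(target))
  S <- t(P) %*% Q
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[3, 1] + S[1, 3]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sq <- sum(P^2) + sum(Q^2) - 2 * lam
  sqrt(max(0, sq) / nrow(P))
}

# quaternion -> rotation matrix (for the direct-minimization cross-check)
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# numerical minimization over quaternion parameters (slow, very independent)
optim_quat_rmsd <- function(mobile, target) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(target, 2, colMeans(target))
  obj <- function(q) {
    R <- quat_to_rot(q)
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  best <- Inf
  for (start in list(c(1, 0, 0, 0), c(0.5, 0.5, 0.5, 0.5), c(0, 1, 0, 0))) {
    fit <- stats::optim(start, obj, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  quat_to_rot(q)
}

# exhaustive residue-pair minimum distance, straight double loop over atoms
brute_min_distance <- function(res_a_tbl, res_b_tbl) {
  best <- Inf
  for (i in seq_len(nrow(res_a_tbl))) {
    for (j in seq_len(nrow(res_b_tbl))) {
      d <- sqrt((res_a_tbl$x[i] - res_b_tbl$x[j])^2 +
                  (res_a_tbl$y[i] - res_b_tbl$y[j])^2 +
                  (res_a_tbl$z[i] - res_b_tbl$z[j])^2)
      best <- min(best, d)
    }
  }
  best
}

# brute-force inter-chain contact enumeration; returns "resa|resb" keys
brute_contacts <- function(a, b, cutoff, mode) {
  pick <- function(s) {
    s <- s[toupper(s$element) != "H", ]
    if (mode == "ca") s <- s[s$atom == "CA", ]
    if (mode == "cb")
      s <- s[s$atom == "CB" | (s$atom == "CA" & s$resname == "GLY"), ]
    s
  }
  a <- pick(a); b <- pick(b)
  keys_a <- unique(paste0(a$resno, "_", a$ins))
  keys_b <- unique(paste0(b$resno, "_", b$ins))
  out <- character(0)
  for (ka in keys_a) {
    ra <- a[paste0(a$resno, "_", a$ins) == ka, ]
    for (kb in keys_b) {
      rb <- b[paste0(b$resno, "_", b$ins) == kb, ]
      if (nrow(ra) && nrow(rb) && brute_min_distance(ra, rb) <= cutoff)
        out <- c(out, paste(ka, kb, sep = "|"))
    }
  }
  out
}

interface_pair_keys <- function(iface) {
  if (!nrow(iface)) return(character(0))
  paste(paste0(iface$resno_a, "_", iface$ins_a),
        paste0(iface$resno_b, "_", iface$ins_b), sep = "|")
}

# minimal from-scratch PIR grammar reader: returns list of entries with
# id, protein_type, description fields and the concatenated sequence
read_pir_oracle <- function(lines) {
  heads <- grep("^>P1;", lines)
  stopifnot(length(heads) >= 1)
  entries <- list()
  bounds <- c(heads, length(lines) + 1)
  for (k in seq_along(heads)) {
    id <- sub("^>P1;", "", lines[heads[k]])
    desc <- lines[heads[k] + 1]
    body <- lines[(heads[k] + 2):(bounds[k + 1] - 1)]
    seq <- paste(body, collapse = "")
    stopifnot(grepl("\\*$", seq))
    seq <- sub("\\*$", "", seq)
    stopifnot(!grepl("\\*", seq))
    stopifnot(all(nchar(body[-length(body)]) == 60 | length(body) == 1))
    entries[[k]] <- list(id = id, desc = strsplit(desc, ":")[[1]],
                         seq = seq)
  }
  entries
}

# direct Kabsch-Sander energy between donor residue i (C=O) and acceptor j
# (N-H), recomputed from raw coordinates without the package matrix code
ks_energy_oracle <- function(chain_tbl, i, j) {
  at <- function(rn, a)
    as.numeric(chain_tbl[chain_tbl$resno == rn & chain_tbl$atom == a,
                         c("x", "y", "z")][1, ])
  nrm <- function(v) sqrt(sum(v^2))
  N <- at(j, "N"); CA <- at(j, "CA"); Cprev <- at(j - 1, "C")
  u <- (Cprev - N) / nrm(Cprev - N) + (CA - N) / nrm(CA - N)
  H <- N - 1.01 * u / nrm(u)
  C <- at(i, "C"); O <- at(i, "O")
  0.084 * 332 * (1 / nrm(O - N) + 1 / nrm(C - H) -
                   1 / nrm(O - H) - 1 / nrm(C - N))
}

coords_of <- function(s) as.matrix(s[, c("x", "y", "z")])

random_rigid <- function() {
  structkit::rigid_transform(random_rotation(), stats::rnorm(3, sd = 10))
}
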