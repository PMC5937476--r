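# Shared helpers: tiny hand-built PDB files and brute-force oracles.

pdb_atom_line <- function(serial, name, resno, x, y, z, record = "ATOM",
                          resname = "ALA", chain = "A") {
  sprintf("%-6s%5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, name, resname, chain, resno, x, y, z,
          substr(name, 1L, 1L))
}

# n_res residues x 4 backbone atoms along x, plus two HETATM waters.
write_tiny_pdb <- function(path, n_res = 3L, offset = c(0, 0, 0),
                           hetatm = TRUE) {
  lines <- character(0)
  serial <- 0L
  for (r in seq_len(n_res)) {
    for (a in c("N", "CA", "C", "O")) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, a, r,
                                      serial * 1.5 + offset[1],
                                      offset[2], offset[3]))
    }
  }
  if (hetatm) {
    lines <- c(lines,
               pdb_atom_line(serial + 1L, "O", 101L, 30, 30, 30,
                             record = "HETATM", resname = "HOH"),
               pdb_atom_line(serial + 2L, "O", 102L, 31, 31, 31,
                             record = "HETATM", resname = "HOH"))
  }
  writeLines(c(lines, "END"), path)
  path
}

# Uniform random rotation matrix (det +1) from a QR decomposition.
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# Brute-force metric oracles: explicit double loops over the matrix.
oracle_metrics <- function(cm) {
  n <- nrow(cm)
  total <- 0; correct <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    total <- total + cm[i, j]
    if (i == j) correct <- correct + cm[i, j]
  }
  prec <- rec <- f1 <- numeric(n)
  for (i in seq_len(n)) {
    colsum <- 0; rowsum <- 0
    for (j in seq_len(n)) { colsum <- colsum + cm[j, i]; rowsum <- rowsum + cm[i, j] }
    prec[i] <- if (colsum > 0) cm[i, i] / colsum else 0
    rec[i] <- if (rowsum > 0) cm[i, i] / rowsum else 0
    f1[i] <- if (prec[i] + rec[i] > 0) 2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  pM <- sum(prec) / n; rM <- sum(rec) / n
  list(accuracy = correct / total, precision = prec, recall = rec, f1 = f1,
       macro = c(precision = pM, recall = rM,
                 f1 = if (pM + rM > 0) 2 * pM * rM / (pM + rM) else 0))
}

# Brute-force fusion oracle: explicit score accumulation per class.
oracle_fuse <- function(probs, coeff, mode = c("probability", "class")) {
  mode <- match.arg(mode)
  probs <- rbind(probs)
  ncl <- ncol(probs)
  score <- numeric(ncl)
  ptot <- numeric(ncl)
  for (j in seq_len(nrow(probs))) {
    for (i in seq_len(ncl)) ptot[i] <- ptot[i] + coeff[j] * probs[j, i]
    if (mode == "class") {
      win <- which.max(probs[j, ])
      score[win] <- score[win] + coeff[j]
    }
  }
  if (mode == "probability") return(which.max(ptot))
  best <- which(score >= max(score) - 1e-12)
  if (length(best) > 1L) best <- best[ptot[best] >= max(ptot[best]) - 1e-12]
  min(best)
}

expect_rel_equal <- function(x, y, tol = 1e-9) {
  expect_lt(max(abs(x - y)) / max(max(abs(y)), 1e-12), tol)
}
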