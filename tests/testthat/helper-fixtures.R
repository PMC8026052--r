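# Fixture builders and independent brute-force oracles shared by the suite.

pdb_atom_line <- function(serial, name, res, chain, resno, x, y, z,
                          occ = 1, alt = "", elem = substr(name, 1L, 1L)) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4L, paste0(" ", name), name), alt,
          res, chain, resno, x, y, z, occ, 0, elem)
}

# 3-residue ALA-GLY-SER fixture: GLY has no side-chain heavy atoms
write_toy_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0.0, 0.0, 0.0, elem = "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.5, 0.0, 0.0),
    pdb_atom_line(3, "C", "ALA", "A", 1, 2.5, 1.0, 0.0),
    pdb_atom_line(4, "O", "ALA", "A", 1, 2.5, 2.0, 0.0, elem = "O"),
    pdb_atom_line(5, "CB", "ALA", "A", 1, 1.5, -1.5, 0.0),
    pdb_atom_line(6, "N", "GLY", "A", 2, 4.0, 1.0, 0.0, elem = "N"),
    pdb_atom_line(7, "CA", "GLY", "A", 2, 5.0, 2.0, 0.0),
    pdb_atom_line(8, "C", "GLY", "A", 2, 6.0, 3.0, 0.0),
    pdb_atom_line(9, "O", "GLY", "A", 2, 6.0, 4.0, 0.0, elem = "O"),
    pdb_atom_line(10, "N", "SER", "A", 3, 7.0, 3.0, 0.0, elem = "N"),
    pdb_atom_line(11, "CA", "SER", "A", 3, 8.0, 4.0, 0.0),
    pdb_atom_line(12, "C", "SER", "A", 3, 9.0, 5.0, 0.0),
    pdb_atom_line(13, "O", "SER", "A", 3, 9.0, 6.0, 0.0, elem = "O"),
    pdb_atom_line(14, "CB", "SER", "A", 3, 8.0, 5.0, 1.0),
    pdb_atom_line(15, "OG", "SER", "A", 3, 8.0, 6.0, 2.0, elem = "O"),
    "END"), path)
  path
}

# 2-model NMR-style file; model 2 coordinates are shifted by +10 in x
write_two_model_pdb <- function(path = tempfile(fileext = ".pdb")) {
  res <- function(dx) c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0.0 + dx, 0.0, 0.0),
    pdb_atom_line(2, "CB", "ALA", "A", 1, 1.0 + dx, 1.0, 1.0),
    pdb_atom_line(3, "CA", "ALA", "A", 2, 3.8 + dx, 0.0, 0.0),
    pdb_atom_line(4, "CB", "ALA", "A", 2, 4.8 + dx, 1.0, 1.0))
  writeLines(c("MODEL     1", res(0), "ENDMDL",
               "MODEL     2", res(10), "ENDMDL", "END"), path)
  path
}

# two parallel 4-residue strands (chains A, B) separated by `gap` Angstrom
write_two_chain_pdb <- function(gap, path = tempfile(fileext = ".pdb")) {
  lines <- character(0L); serial <- 0L
  for (ch in c("A", "B")) {
    y0 <- if (ch == "A") 0 else gap
    for (i in 1:4) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, "CA", "ALA", ch, i,
                                      3.8 * (i - 1), y0, 0.0))
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, "CB", "ALA", ch, i,
                                      3.8 * (i - 1),
                                      y0 + if (ch == "A") 1.2 else -1.2, 0.5))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# random residue cloud built directly (no file round trip); guarantees
# pairwise separation so centroids never coincide
random_structure <- function(n, seed, spread = 4) {
  set.seed(seed)
  repeat {
    xyz <- matrix(stats::runif(3L * n, 0, spread * n^(1 / 3)), ncol = 3L)
    if (min(stats::dist(xyz)) > 0.5) break
  }
  res <- data.frame(chain = "A", resi = seq_len(n), resno = seq_len(n),
                    res_name = "ALA",
                    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                    scx = xyz[, 1L] + stats::runif(n, -0.4, 0.4),
                    scy = xyz[, 2L] + stats::runif(n, -0.4, 0.4),
                    scz = xyz[, 3L] + stats::runif(n, -0.4, 0.4),
                    rsa = NA_real_, stringsAsFactors = FALSE)
  protein_structure(paste0("rand", seed), res)
}

# ---- independent brute-force oracles ----

bf_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

bf_spearman <- function(x, y) bf_pearson(rank(x), rank(y))

bf_distmat <- function(xyz) {
  n <- nrow(xyz)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    m[i, j] <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  }
  m
}

bf_wcn <- function(cen) {
  n <- nrow(cen)
  out <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) out[i] <- out[i] + 1 / sum((cen[i, ] - cen[j, ])^2)
  }
  out
}
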