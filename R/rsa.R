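#' Theoretical maximum accessible surface areas
#'
#' Theoretical max ASA per amino-acid type (Angstrom^2), used to normalize
#' residue SASA into relative solvent accessibility. Declared here so
#' results are reproducible bit-for-bit.
#'
#' @format named numeric vector keyed by 3-letter residue code.
#' @export
MAX_ASA <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174
)

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, H = 1.20, D = 1.20)
VDW_DEFAULT <- 1.80

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Atomic solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolling-probe SASA: each atom's solvent-exposed sphere of radius
#' (vdW + probe) is sampled with a deterministic quasi-uniform point set;
#' a point is accessible if it lies outside every other atom's expanded
#' sphere.
#'
#' @param coords numeric matrix (n x 3) of heavy-atom coordinates.
#' @param elements character vector of element symbols (C, N, O, S, ...).
#' @param probe probe radius in Angstrom (water: 1.4).
#' @param n_points sphere sample points per atom; more points, finer SASA.
#' @return numeric vector of per-atom SASA in Angstrom^2.
#' @export
atom_sasa <- function(coords, elements, probe = 1.4, n_points = 240L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(n >= 1L, length(elements) == n)
  radii <- unname(VDW_RADII[toupper(elements)])
  radii[is.na(radii)] <- VDW_DEFAULT
  rs <- radii + probe
  pts <- sphere_points(n_points)
  out <- numeric(n)
  max_rs <- max(rs)
  for (i in seq_len(n)) {
    d2 <- colSums((t(coords) - coords[i, ])^2)
    nb <- which(d2 < (rs[i] + max_rs)^2 & seq_len(n) != i)
    nb <- nb[sqrt(d2[nb]) < rs[i] + rs[nb]]
    sp <- pts * rs[i]
    sp <- sweep(sp, 2L, coords[i, ], "+")
    if (length(nb) > 0L) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- (sp[, 1L] - coords[j, 1L])^2 + (sp[, 2L] - coords[j, 2L])^2 +
               (sp[, 3L] - coords[j, 3L])^2
        acc <- acc & dj2 > rs[j]^2
        if (!any(acc)) break
      }
      f <- sum(acc) / n_points
    } else f <- 1
    out[i] <- f * 4 * pi * rs[i]^2
  }
  out
}

#' Relative solvent accessibility per residue
#'
#' Residue SASA (sum over its heavy atoms, probe 1.4 Angstrom) divided by
#' the theoretical maximum ASA for its amino-acid type, clamped to [0, 1].
#' Unknown residue types use the mean of the max-ASA table with a warning.
#'
#' @param s a \code{protein_structure} carrying heavy-atom records
#'   (\code{s$atoms}), e.g. from [read_structure()].
#' @param probe probe radius in Angstrom.
#' @param n_points sphere sample points per atom.
#' @param atoms optional replacement atom table (used internally for
#'   partner-deleted recomputation).
#' @return numeric RSA vector in [0, 1], one entry per residue of \code{s};
#'   residues with no atoms in the table get \code{NA}.
#' @export
compute_rsa <- function(s, probe = 1.4, n_points = 240L, atoms = s$atoms) {
  if (is.null(atoms) || nrow(atoms) == 0L) {
    stop("structure has no atom records; RSA needs heavy-atom coordinates",
         call. = FALSE)
  }
  sasa <- atom_sasa(as.matrix(atoms[, c("x", "y", "z")]), atoms$elesy,
                    probe = probe, n_points = n_points)
  akey <- paste(atoms$chain, atoms$resno, sep = "\r")
  rkey <- paste(s$residues$chain, s$residues$resno, sep = "\r")
  res_sasa <- vapply(rkey, function(k) {
    idx <- which(akey == k)
    if (length(idx) == 0L) NA_real_ else sum(sasa[idx])
  }, numeric(1L), USE.NAMES = FALSE)
  mx <- unname(MAX_ASA[s$residues$res_name])
  if (anyNA(mx) && any(!is.na(res_sasa) & is.na(mx))) {
    warning("unknown residue type(s): ",
            paste(unique(s$residues$res_name[is.na(mx)]), collapse = ", "),
            "; using generic maximum ASA")
  }
  mx[is.na(mx)] <- mean(MAX_ASA)
  pmin(pmax(res_sasa / mx, 0), 1)
}

#' Burial class from relative solvent accessibility
#'
#' Classifies residues as \code{buried} (RSA = 0, compared with tolerance
#' 1e-9), \code{exposed} (RSA > 0.8) or \code{middle} (0 < RSA <= 0.8).
#'
#' @param rsa numeric RSA values in [0, 1]; \code{NA} yields \code{NA}.
#' @return character vector of classes.
#' @export
classify_burial <- function(rsa) {
  out <- rep(NA_character_, length(rsa))
  ok <- !is.na(rsa)
  out[ok & abs(rsa) <= 1e-9] <- "buried"
  out[ok & rsa > 0.8] <- "exposed"
  out[ok & rsa > 1e-9 & rsa <= 0.8] <- "middle"
  out
}

#' Interface residues by solvent-accessibility change
#'
#' Residues whose RSA differs between the two-chain complex and the isolated
#' chain (interacting partner deleted) by more than \code{tol} are flagged
#' as interface residues, for each chain in turn.
#'
#' @param s multi-chain \code{protein_structure} with atom records.
#' @param chain_a,chain_b chain identifiers.
#' @param tol minimum RSA difference to call a residue interfacial.
#' @param n_points sphere sample points per atom.
#' @return list with elements \code{chain_a} and \code{chain_b}: integer
#'   vectors of interface residue positions (\code{resi}, 1-based within
#'   chain).
#' @export
detect_interface <- function(s, chain_a, chain_b, tol = 1e-4,
                             n_points = 240L) {
  chains <- unique(s$residues$chain)
  if (!chain_a %in% chains) stop("chain '", chain_a, "' not found", call. = FALSE)
  if (!chain_b %in% chains) stop("chain '", chain_b, "' not found", call. = FALSE)
  if (identical(chain_a, chain_b)) {
    return(list(chain_a = integer(0L), chain_b = integer(0L)))
  }
  ab <- s$atoms[s$atoms$chain %in% c(chain_a, chain_b), , drop = FALSE]
  rsa_complex <- compute_rsa(s, n_points = n_points, atoms = ab)
  flag_chain <- function(ch) {
    mono <- s$atoms[s$atoms$chain == ch, , drop = FALSE]
    rsa_mono <- compute_rsa(s, n_points = n_points, atoms = mono)
    in_ch <- s$residues$chain == ch
    d <- abs(rsa_complex[in_ch] - rsa_mono[in_ch])
    s$residues$resi[in_ch][!is.na(d) & d > tol]
  }
  list(chain_a = flag_chain(chain_a), chain_b = flag_chain(chain_b))
}
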