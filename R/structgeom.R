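#' Read a protein structure from PDB or mmCIF
#'
#' Parses a coordinate file into a \code{protein_structure}: one record per
#' polymer residue that has a Calpha atom, together with the side-chain
#' centroid of its heavy atoms. Residues without a Calpha are skipped with a
#' message. Alternate locations are resolved per atom to the highest
#' occupancy, ties broken alphabetically by altloc code.
#'
#' @param path path to a PDB or mmCIF file.
#' @param model model number (1-based); relevant for multi-model NMR files.
#' @param chains optional character vector of chain identifiers to keep.
#' @param protein_id identifier stored on the object; defaults to the file
#'   base name.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or \code{"cif"}.
#'
#' @return A \code{protein_structure}: a list with \code{protein_id},
#'   \code{residues} (data.frame with \code{chain}, \code{resi} 1-based
#'   position within chain, \code{resno} author numbering, \code{res_name},
#'   Calpha coordinates \code{x,y,z}, side-chain centroid
#'   \code{scx,scy,scz}, \code{rsa}) and \code{atoms} (heavy-atom records
#'   used for solvent accessibility).
#' @export
read_structure <- function(path, model = 1L, chains = NULL,
                           protein_id = NULL,
                           format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  obj <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, rm.alt = FALSE) else
      bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse structure file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  atom <- obj$atom
  n_models <- if (is.matrix(obj$xyz)) nrow(obj$xyz) else 1L
  if (model < 1L || model > n_models) {
    stop("model ", model, " not present (file has ", n_models, " model",
         if (n_models > 1L) "s", ")", call. = FALSE)
  }
  if (is.matrix(obj$xyz) && n_models >= 1L) {
    xyz <- matrix(obj$xyz[model, ], ncol = 3L, byrow = TRUE)
    if (nrow(xyz) == nrow(atom)) {
      atom$x <- xyz[, 1L]; atom$y <- xyz[, 2L]; atom$z <- xyz[, 3L]
    }
  }
  atom <- atom[atom$type == "ATOM", , drop = FALSE]
  if (!is.null(chains)) atom <- atom[atom$chain %in% chains, , drop = FALSE]
  if (nrow(atom) == 0L) stop("no polymer atoms after filtering", call. = FALSE)

  atom$insert[is.na(atom$insert)] <- ""
  atom$alt[is.na(atom$alt)] <- ""
  atom$o[is.na(atom$o)] <- 1
  # altloc: keep, per (chain, resno, insert, atom name), highest occupancy
  # then alphabetically first altloc code
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "\r")
  ord <- order(key, -atom$o, atom$alt)
  keep <- ord[!duplicated(key[ord])]
  atom <- atom[sort(keep), , drop = FALSE]  # dedup, preserving file order

  # drop hydrogens/deuteriums
  elesy <- atom$elesy
  if (is.null(elesy) || all(is.na(elesy))) {
    elesy <- guess_element(atom$elety)
  } else {
    elesy[is.na(elesy) | elesy == ""] <- guess_element(atom$elety[is.na(elesy) | elesy == ""])
  }
  atom$elesy <- toupper(elesy)
  atom <- atom[!atom$elesy %in% c("H", "D"), , drop = FALSE]

  res_key <- paste(atom$chain, atom$resno, atom$insert, sep = "\r")
  res_first <- !duplicated(res_key)
  res_df <- atom[res_first, c("chain", "resno", "insert", "resid"), drop = FALSE]
  names(res_df)[names(res_df) == "resid"] <- "res_name"

  backbone <- c("N", "CA", "C", "O", "OXT")
  n_skipped <- 0L
  rows <- vector("list", nrow(res_df))
  for (i in seq_len(nrow(res_df))) {
    k <- paste(res_df$chain[i], res_df$resno[i], res_df$insert[i], sep = "\r")
    a <- atom[res_key == k, , drop = FALSE]
    ca <- a[a$elety == "CA", , drop = FALSE]
    if (nrow(ca) == 0L) { n_skipped <- n_skipped + 1L; next }
    sc <- a[!a$elety %in% backbone, , drop = FALSE]
    cen <- if (nrow(sc) > 0L) c(mean(sc$x), mean(sc$y), mean(sc$z))
           else c(ca$x[1L], ca$y[1L], ca$z[1L])
    rows[[i]] <- data.frame(
      chain = res_df$chain[i], resno = res_df$resno[i],
      res_name = res_df$res_name[i],
      x = ca$x[1L], y = ca$y[1L], z = ca$z[1L],
      scx = cen[1L], scy = cen[2L], scz = cen[3L],
      stringsAsFactors = FALSE
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) {
    stop("structure contains no residues with a Calpha atom", call. = FALSE)
  }
  if (n_skipped > 0L) {
    message(n_skipped, " residue(s) without a Calpha atom skipped")
  }
  residues <- do.call(rbind, rows)
  residues$resi <- stats::ave(seq_len(nrow(residues)), residues$chain,
                              FUN = seq_along)
  residues$rsa <- NA_real_
  residues <- residues[, c("chain", "resi", "resno", "res_name",
                           "x", "y", "z", "scx", "scy", "scz", "rsa")]
  rownames(residues) <- NULL
  protein_structure(
    protein_id = if (is.null(protein_id)) sub("\\.[^.]*$", "", basename(path)) else protein_id,
    residues = residues,
    atoms = atom[, c("chain", "resno", "insert", "resid", "elety", "elesy",
                     "x", "y", "z"), drop = FALSE]
  )
}

guess_element <- function(elety) {
  e <- toupper(sub("^[0-9]*", "", elety))
  out <- substr(e, 1L, 1L)
  out[startsWith(e, "SE")] <- "SE"
  out[startsWith(e, "CL")] <- "CL"
  out[startsWith(e, "ZN")] <- "ZN"
  out
}

#' Construct a protein structure object
#'
#' Low-level constructor used by [read_structure()] and the synthetic-data
#' generator.
#'
#' @param protein_id identifier.
#' @param residues residue data.frame (see [read_structure()]).
#' @param atoms optional heavy-atom data.frame for solvent-accessibility
#'   calculations.
#' @return A \code{protein_structure} object.
#' @export
protein_structure <- function(protein_id, residues, atoms = NULL) {
  stopifnot(is.data.frame(residues),
            all(c("chain", "resi", "res_name", "x", "y", "z",
                  "scx", "scy", "scz") %in% names(residues)))
  if (anyDuplicated(residues[, c("chain", "resi")])) {
    stop("duplicate (chain, resi) in residue table", call. = FALSE)
  }
  if (!all(is.finite(as.matrix(residues[, c("x", "y", "z", "scx", "scy", "scz")])))) {
    stop("non-finite coordinates in residue table", call. = FALSE)
  }
  if (!"resno" %in% names(residues)) residues$resno <- residues$resi
  if (!"rsa" %in% names(residues)) residues$rsa <- NA_real_
  structure(list(protein_id = protein_id, residues = residues, atoms = atoms),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure '", x$protein_id, "': ", nrow(x$residues),
      " residues, ", length(unique(x$residues$chain)), " chain(s)",
      if (!is.null(x$atoms)) paste0(", ", nrow(x$atoms), " heavy atoms"),
      "\n", sep = "")
  invisible(x)
}

#' Number of residues in a structure
#' @param s a \code{protein_structure}.
#' @return integer residue count.
#' @export
n_residues <- function(s) nrow(s$residues)

#' Calpha distance matrix
#'
#' Pairwise Euclidean distances between Calpha atoms, in Angstrom. All
#' residue-residue distances in the package are Calpha distances.
#'
#' @param s a \code{protein_structure} with at least two residues.
#' @return symmetric N x N matrix with zero diagonal.
#' @export
ca_distance_matrix <- function(s) {
  if (n_residues(s) < 2L) stop("need at least 2 residues", call. = FALSE)
  as.matrix(stats::dist(as.matrix(s$residues[, c("x", "y", "z")])))
}

#' Side-chain centroid of one residue
#'
#' Unweighted geometric center of the side-chain heavy atoms (everything
#' beyond backbone N, CA, C, O/OXT). Glycine, or any residue with no
#' side-chain heavy atoms, falls back to the Calpha coordinate.
#'
#' @param atoms data.frame with columns \code{elety}, \code{x}, \code{y},
#'   \code{z} for one residue (hydrogens already excluded).
#' @return numeric length-3 coordinate.
#' @export
side_chain_centroid <- function(atoms) {
  stopifnot(nrow(atoms) > 0L)
  backbone <- c("N", "CA", "C", "O", "OXT")
  sc <- atoms[!atoms$elety %in% backbone, , drop = FALSE]
  if (nrow(sc) > 0L) return(c(mean(sc$x), mean(sc$y), mean(sc$z)))
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) {
    stop("residue has neither side-chain heavy atoms nor a Calpha", call. = FALSE)
  }
  c(ca$x[1L], ca$y[1L], ca$z[1L])
}

#' Side-chain weighted contact number (SC-WCN)
#'
#' Packing/centrality measure per residue: the inverse-square-distance sum
#' over all other residues' side-chain centroids,
#' \eqn{WCN_i = \sum_{j \ne i} 1 / r_{ij}^2}, with no distance cutoff.
#'
#' @param s a \code{protein_structure} (>= 2 residues, centroids set).
#' @return numeric vector of SC-WCN values, one per residue.
#' @export
compute_sc_wcn <- function(s) {
  if (n_residues(s) < 2L) stop("need at least 2 residues", call. = FALSE)
  d <- as.matrix(stats::dist(as.matrix(s$residues[, c("scx", "scy", "scz")])))
  off <- d[upper.tri(d)]
  if (any(off == 0)) {
    stop("coincident side-chain centroids: degenerate geometry", call. = FALSE)
  }
  inv2 <- 1 / d^2
  diag(inv2) <- 0
  unname(rowSums(inv2))
}

#' Distance to the protein center
#'
#' The protein center is defined as the residue with the highest SC-WCN
#' (ties broken by lowest residue order); the function returns each
#' residue's Calpha distance from that residue, in Angstrom.
#'
#' @param s a \code{protein_structure}.
#' @param wcn SC-WCN vector for the same structure, from
#'   [compute_sc_wcn()]; computed if missing.
#' @return numeric vector of distances; exactly one entry is 0.
#' @export
distance_to_center <- function(s, wcn = compute_sc_wcn(s)) {
  stopifnot(length(wcn) == n_residues(s))
  center <- which.max(wcn)  # first max = lowest residue order on ties
  xyz <- as.matrix(s$residues[, c("x", "y", "z")])
  sqrt(colSums((t(xyz) - xyz[center, ])^2))
}

#' Per-residue packing profile
#'
#' Convenience wrapper returning SC-WCN and distance-to-center together.
#'
#' @param s a \code{protein_structure}.
#' @return data.frame with \code{chain}, \code{resi}, \code{sc_wcn},
#'   \code{dist_to_center}.
#' @export
packing_profile <- function(s) {
  wcn <- compute_sc_wcn(s)
  data.frame(chain = s$residues$chain, resi = s$residues$resi,
             sc_wcn = wcn, dist_to_center = distance_to_center(s, wcn),
             stringsAsFactors = FALSE)
}

#' Per-residue geometry table
#'
#' Joins packing, solvent accessibility and burial class into the
#' user-facing geometry table (residue numbering 1-based).
#'
#' @param s a \code{protein_structure}.
#' @param rsa optional per-residue RSA from [compute_rsa()]; if \code{NULL}
#'   and atom records are available it is computed, otherwise left missing.
#' @return data.frame with columns \code{protein_id}, \code{chain},
#'   \code{resi}, \code{res_name}, \code{sc_wcn}, \code{dist_to_center},
#'   \code{rsa}, \code{burial_class}.
#' @export
geometry_table <- function(s, rsa = NULL) {
  pk <- packing_profile(s)
  if (is.null(rsa)) {
    rsa <- if (!is.null(s$atoms) && nrow(s$atoms) > 0L) compute_rsa(s)
           else rep(NA_real_, n_residues(s))
  }
  data.frame(protein_id = s$protein_id, chain = s$residues$chain,
             resi = s$residues$resi, res_name = s$residues$res_name,
             sc_wcn = pk$sc_wcn, dist_to_center = pk$dist_to_center,
             rsa = rsa, burial_class = classify_burial(rsa),
             stringsAsFactors = FALSE)
}
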