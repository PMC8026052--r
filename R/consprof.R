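#' Read a ConSurf-style conservation score table
#'
#' Ingests a per-residue conservation score TSV with columns
#' \code{position} (1-based) and \code{score} (optionally a third
#' \code{grade} column, ignored). ConSurf's native convention is that lower
#' (more negative) scores are more conserved; with
#' \code{consurf_orientation = TRUE} scores are negated at ingest so that
#' throughout the package higher score always means more conserved.
#'
#' @param path path to the TSV file (or a connection).
#' @param protein_id identifier; defaults to the file base name.
#' @param consurf_orientation logical; \code{TRUE} if the source uses the
#'   ConSurf convention (lower = conserved) and scores must be negated.
#' @param n_residues optional protein length; positions absent from the
#'   file become missing scores (reported via a message).
#' @return a \code{conservation_profile}: list with \code{protein_id},
#'   \code{scores} (higher = more conserved) and \code{ranks} (from
#'   [conservation_ranks()], \code{NULL} until computed).
#' @export
read_consurf_scores <- function(path, protein_id = NULL,
                                consurf_orientation = TRUE,
                                n_residues = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("position", "score") %in% names(tab))) {
    stop("score table must have columns 'position' and 'score'", call. = FALSE)
  }
  pos <- tab$position
  if (!is.numeric(pos) || anyNA(pos) || any(pos != as.integer(pos)) ||
      any(pos < 1L)) {
    stop("positions must be positive integers", call. = FALSE)
  }
  if (anyDuplicated(pos)) stop("duplicate positions in score table", call. = FALSE)
  if (!is.numeric(tab$score)) stop("non-numeric scores", call. = FALSE)
  n <- if (is.null(n_residues)) max(pos) else n_residues
  scores <- rep(NA_real_, n)
  scores[pos] <- if (consurf_orientation) -tab$score else tab$score
  if (anyNA(scores)) {
    message(sum(is.na(scores)), " position(s) without a conservation score")
  }
  conservation_profile(
    protein_id = if (is.null(protein_id)) sub("\\.[^.]*$", "", basename(path)) else protein_id,
    scores = scores
  )
}

#' Construct a conservation profile
#'
#' @param protein_id identifier.
#' @param scores per-residue conservation scores, higher = more conserved;
#'   \code{NA} for missing.
#' @param ties tie-handling rule for ranks (\code{"average"}, \code{"min"}
#'   or \code{"max"}).
#' @return a \code{conservation_profile} with normalized ranks attached
#'   when at least two scores are present.
#' @export
conservation_profile <- function(protein_id, scores,
                                 ties = c("average", "min", "max")) {
  ties <- match.arg(ties)
  ranks <- if (sum(!is.na(scores)) >= 2L) conservation_ranks(scores, ties)
           else rep(NA_real_, length(scores))
  structure(list(protein_id = protein_id, scores = as.numeric(scores),
                 ranks = ranks),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("conservation_profile '", x$protein_id, "': ", length(x$scores),
      " residues (", sum(is.na(x$scores)), " missing)\n", sep = "")
  invisible(x)
}

#' Normalized conservation ranks
#'
#' Each residue's within-protein rank of conservation divided by the number
#' of scored residues, giving values in (0, 1] with higher rank = more
#' conserved. Ties share their average rank by default (\code{"min"} /
#' \code{"max"} selectable). Missing scores get missing ranks and are
#' excluded from the denominator.
#'
#' @param scores per-residue conservation scores (higher = more conserved).
#' @param ties tie rule passed to [base::rank()].
#' @return numeric vector of ranks in (0, 1], \code{NA} where the score is
#'   missing.
#' @export
conservation_ranks <- function(scores, ties = c("average", "min", "max")) {
  ties <- match.arg(ties)
  ok <- !is.na(scores)
  if (sum(ok) < 2L) stop("need at least 2 non-missing scores", call. = FALSE)
  out <- rep(NA_real_, length(scores))
  out[ok] <- rank(scores[ok], ties.method = ties) / sum(ok)
  out
}

#' Read a per-residue evolutionary-rate (dN/dS) table
#'
#' TSV with columns \code{position} (1-based) and \code{dnds}. Negative
#' rates are rejected; absent positions become missing.
#'
#' @param path path to the TSV file.
#' @param protein_id identifier; defaults to the file base name.
#' @param n_residues optional protein length.
#' @return a \code{rate_profile}: list with \code{protein_id} and
#'   \code{dnds} (non-negative or \code{NA}).
#' @export
read_rate_table <- function(path, protein_id = NULL, n_residues = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("position", "dnds") %in% names(tab))) {
    stop("rate table must have columns 'position' and 'dnds'", call. = FALSE)
  }
  if (anyDuplicated(tab$position)) stop("duplicate positions", call. = FALSE)
  if (!is.numeric(tab$dnds)) stop("non-numeric dN/dS values", call. = FALSE)
  if (any(tab$dnds < 0, na.rm = TRUE)) {
    stop("negative dN/dS values are invalid", call. = FALSE)
  }
  n <- if (is.null(n_residues)) max(tab$position) else n_residues
  dnds <- rep(NA_real_, n)
  dnds[tab$position] <- tab$dnds
  structure(list(protein_id = if (is.null(protein_id)) sub("\\.[^.]*$", "", basename(path)) else protein_id,
                 dnds = dnds),
            class = "rate_profile")
}

#' Read a pairwise alignment from aligned FASTA
#'
#' Reads a 2-sequence aligned FASTA ('-' gaps) for annotation transfer.
#'
#' @param path path to the FASTA file.
#' @return list with \code{source_id}, \code{target_id}, \code{source},
#'   \code{target} (aligned character strings of equal length).
#' @export
read_pairwise_alignment <- function(path) {
  aln <- bio3d::read.fasta(path)
  if (nrow(aln$ali) != 2L) {
    stop("pairwise alignment must contain exactly 2 sequences", call. = FALSE)
  }
  src <- paste(aln$ali[1L, ], collapse = "")
  tgt <- paste(aln$ali[2L, ], collapse = "")
  if (nchar(src) != nchar(tgt)) {
    stop("aligned sequences differ in length", call. = FALSE)
  }
  list(source_id = aln$id[1L], target_id = aln$id[2L],
       source = src, target = tgt)
}

#' Transfer per-residue values across a pairwise alignment
#'
#' Walks the alignment columns: a target position aligned to a source
#' residue receives that residue's value; target positions aligned to a gap
#' in the source receive missing. Used to carry conservation scores and
#' site annotations from a structural template onto the target sequence.
#'
#' @param aln pairwise alignment from [read_pairwise_alignment()] (or any
#'   list with \code{source} and \code{target} aligned strings).
#' @param values per-residue values on the degapped source sequence.
#' @return vector of values on the degapped target sequence (\code{NA}
#'   where the target column is gapped in the source).
#' @export
transfer_profile <- function(aln, values) {
  src <- strsplit(aln$source, "")[[1L]]
  tgt <- strsplit(aln$target, "")[[1L]]
  stopifnot(length(src) == length(tgt))
  n_src <- sum(src != "-")
  if (n_src != length(values)) {
    stop("alignment inconsistency: degapped source length ", n_src,
         " != value count ", length(values), call. = FALSE)
  }
  out <- rep(values[NA_integer_], sum(tgt != "-"))
  si <- 0L; ti <- 0L
  for (k in seq_along(src)) {
    s_res <- src[k] != "-"; t_res <- tgt[k] != "-"
    if (s_res) si <- si + 1L
    if (t_res) ti <- ti + 1L
    if (s_res && t_res) out[ti] <- values[si]
  }
  out
}
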