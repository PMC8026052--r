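#' Gradient variant specification
#'
#' A conservation gradient can be computed with Pearson or Spearman
#' correlation and over three distance windows: the full protein, residues
#' up to 30 Angstrom away, or residues between 6 and 30 Angstrom away.
#' Window bounds are lower-exclusive, upper-inclusive: (0, 30] includes a
#' pair at exactly 30.0 and (6, 30] excludes one at exactly 6.0.
#'
#' @param method \code{"pearson"} or \code{"spearman"} (Spearman = Pearson
#'   on ranks).
#' @param window \code{"full"}, or numeric \code{c(lower, upper)} in
#'   Angstrom; the shorthands \code{"30"} and \code{"6-30"} map to
#'   \code{c(0, 30)} and \code{c(6, 30)}.
#' @param min_points minimum residues (>= 3) in the window for the gradient
#'   to be defined; default 10.
#' @return a \code{gradient_variant} list with a canonical \code{label}.
#' @export
gradient_variant <- function(method = c("pearson", "spearman"),
                             window = "full", min_points = 10L) {
  method <- match.arg(method)
  if (is.character(window)) {
    window <- switch(window,
                     full = c(0, Inf),
                     "30" = c(0, 30),
                     "6-30" = c(6, 30),
                     stop("unknown window '", window, "'", call. = FALSE))
  }
  stopifnot(length(window) == 2L, window[1L] >= 0, window[2L] > window[1L])
  min_points <- as.integer(min_points)
  if (min_points < 3L) stop("min_points must be >= 3", call. = FALSE)
  lab_w <- if (is.infinite(window[2L])) "full" else
    paste0(window[1L], "-", window[2L])
  structure(list(method = method, window = window, min_points = min_points,
                 label = paste0(method, "_", lab_w)),
            class = "gradient_variant")
}

#' Conservation gradient from one reference residue
#'
#' The site-induced conservation gradient: the correlation between the
#' conservation scores of all \emph{other} residues in the protein and
#' their Calpha distance from the reference residue. With scores oriented
#' higher = more conserved, a site that radiates conservation yields a
#' \emph{negative} correlation; summary tables additionally report the
#' positive "strength" \code{-r}.
#'
#' @param distances distances (Angstrom) of every residue from the
#'   reference residue (the reference's own entry is ignored).
#' @param scores per-residue conservation scores (higher = more conserved).
#' @param ref_index index (1-based) of the reference residue.
#' @param variant a [gradient_variant()].
#' @return signed correlation in [-1, 1], or \code{NA} if fewer than
#'   \code{min_points} usable residues fall in the window or either
#'   variable is constant. Attribute \code{n_points} carries the number of
#'   residues used.
#' @export
conservation_gradient <- function(distances, scores, ref_index,
                                  variant = gradient_variant()) {
  n <- length(distances)
  stopifnot(length(scores) == n)
  if (ref_index < 1L || ref_index > n) {
    stop("ref_index out of range", call. = FALSE)
  }
  keep <- seq_len(n) != ref_index & !is.na(scores) & !is.na(distances) &
    distances > variant$window[1L] & distances <= variant$window[2L]
  d <- distances[keep]; s <- scores[keep]
  r <- NA_real_
  if (length(d) >= variant$min_points &&
      stats::sd(d) > 0 && stats::sd(s) > 0) {
    r <- stats::cor(d, s, method = variant$method)
  }
  structure(r, n_points = length(d))
}

#' Gradient profile of a protein
#'
#' Applies [conservation_gradient()] with every residue as the reference,
#' under one variant.
#'
#' @param s a \code{protein_structure}.
#' @param prof a \code{conservation_profile} covering the same residues.
#' @param variant a [gradient_variant()].
#' @param dmat optional precomputed Calpha distance matrix.
#' @return a \code{gradient_profile}: list with \code{protein_id},
#'   \code{variant}, \code{gradient} (signed r per residue, \code{NA} when
#'   undefined) and \code{n_points}.
#' @export
gradient_profile <- function(s, prof, variant = gradient_variant(),
                             dmat = ca_distance_matrix(s)) {
  n <- n_residues(s)
  if (length(prof$scores) != n) {
    stop("conservation profile covers ", length(prof$scores),
         " residues but structure has ", n, call. = FALSE)
  }
  if (sum(!is.na(prof$scores)) < 2L) {
    stop("need at least 2 residues with conservation scores", call. = FALSE)
  }
  grad <- numeric(n); npts <- integer(n)
  for (i in seq_len(n)) {
    g <- conservation_gradient(dmat[i, ], prof$scores, i, variant)
    grad[i] <- as.numeric(g)
    npts[i] <- attr(g, "n_points")
  }
  structure(list(protein_id = s$protein_id, variant = variant,
                 gradient = grad, n_points = npts),
            class = "gradient_profile")
}

#' @export
print.gradient_profile <- function(x, ...) {
  cat("gradient_profile '", x$protein_id, "' [", x$variant$label, "]: ",
      length(x$gradient), " residues (", sum(is.na(x$gradient)),
      " undefined)\n", sep = "")
  invisible(x)
}

#' Per-protein conservation-percolation correlation
#'
#' Pearson correlation, across the residues of one protein, between their
#' normalized conservation ranks and their induced conservation gradients.
#' Strongly negative values mean that within this protein the more
#' conserved residues induce the stronger (more negative) gradients.
#'
#' @param ranks per-residue conservation ranks.
#' @param gradients per-residue signed gradients.
#' @param min_points minimum paired observations (default 10).
#' @return Pearson r, or \code{NA} with fewer than \code{min_points}
#'   complete pairs or zero variance.
#' @export
percolation_correlation <- function(ranks, gradients, min_points = 10L) {
  stopifnot(length(ranks) == length(gradients))
  ok <- !is.na(ranks) & !is.na(gradients)
  if (sum(ok) < min_points) return(NA_real_)
  if (stats::sd(ranks[ok]) == 0 || stats::sd(gradients[ok]) == 0) {
    return(NA_real_)
  }
  stats::cor(ranks[ok], gradients[ok])
}

#' Remove a packing covariate's contribution from gradients
#'
#' Fits, over all pooled residues, the ordinary least squares model
#' \code{gradient ~ rank + covariate} (covariate: SC-WCN or
#' distance-to-center) and subtracts the covariate's centered contribution
#' from each residue's gradient:
#' \code{adjusted_i = gradient_i - c * (covariate_i - mean(covariate))}.
#' Centering on the fitted rows preserves the pooled mean gradient.
#'
#' @param gradients,ranks,covariate numeric vectors of equal length, pooled
#'   across the dataset.
#' @param min_rows minimum complete rows for the fit (default 10).
#' @return numeric vector of adjusted gradients (\code{NA} where gradient
#'   or covariate is missing), with attribute \code{coef} carrying the
#'   fitted coefficients.
#' @export
residualize_gradient <- function(gradients, ranks, covariate,
                                 min_rows = 10L) {
  stopifnot(length(gradients) == length(ranks),
            length(gradients) == length(covariate))
  fit_ok <- !is.na(gradients) & !is.na(ranks) & !is.na(covariate)
  if (sum(fit_ok) < min_rows) {
    stop("need at least ", min_rows, " complete rows for the regression",
         call. = FALSE)
  }
  if (stats::sd(ranks[fit_ok]) == 0) {
    stop("collinear design: ranks have zero variance", call. = FALSE)
  }
  if (stats::sd(covariate[fit_ok]) == 0) {
    # constant covariate carries no signal: nothing to subtract
    adj <- gradients
    adj[is.na(gradients) | is.na(covariate)] <- NA_real_
    return(structure(adj, coef = c("(Intercept)" = NA_real_, r = NA_real_,
                                   v = 0)))
  }
  fit <- stats::lm(g ~ r + v, data = data.frame(g = gradients[fit_ok],
                                                r = ranks[fit_ok],
                                                v = covariate[fit_ok]))
  cc <- stats::coef(fit)[["v"]]
  vbar <- mean(covariate[fit_ok])
  adj <- gradients - cc * (covariate - vbar)
  adj[is.na(gradients) | is.na(covariate)] <- NA_real_
  structure(adj, coef = stats::coef(fit))
}

#' Gradient summary table
#'
#' User-facing per-residue gradient table for one protein and one variant,
#' reporting both the signed correlation and the positive strength
#' \code{-r} (so that stronger percolation prints as a larger positive
#' number).
#'
#' @param gp a \code{gradient_profile}.
#' @return data.frame with \code{protein_id}, \code{resi} (1-based),
#'   \code{method}, \code{window}, \code{n_points}, \code{gradient_r},
#'   \code{gradient_strength}.
#' @export
gradient_table <- function(gp) {
  w <- gp$variant$window
  data.frame(protein_id = gp$protein_id,
             resi = seq_along(gp$gradient),
             method = gp$variant$method,
             window = if (is.infinite(w[2L])) "full" else paste0(w[1L], "-", w[2L]),
             n_points = gp$n_points,
             gradient_r = gp$gradient,
             gradient_strength = -gp$gradient,
             stringsAsFactors = FALSE)
}
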