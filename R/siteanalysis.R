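SITE_TYPES <- c("catalytic", "ligand_enzyme", "ligand_nonenzyme", "ppi",
                "allosteric", "buried_nonfunctional", "exposed_nonfunctional")

#' Read a functional-site annotation table
#'
#' TSV with columns \code{protein_id}, \code{site_id}, \code{site_type},
#' \code{resi} (1-based residue position, one row per residue). Site types:
#' catalytic, ligand_enzyme, ligand_nonenzyme, ppi, allosteric,
#' buried_nonfunctional, exposed_nonfunctional.
#'
#' @param path path to the TSV file.
#' @return data.frame of site annotations.
#' @export
read_sites_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("protein_id", "site_id", "site_type", "resi")
  if (!all(need %in% names(tab))) {
    stop("site table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(tab$site_type), SITE_TYPES)
  if (length(bad) > 0L) {
    stop("unknown site_type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Binned trend with a global linear fit
#'
#' Bins rows into equal-width bins of \code{x} over [0, 1] (right-closed;
#' the first bin includes 0) and reports per-bin means alongside a global
#' ordinary least squares fit and Pearson r computed over \emph{all} valid
#' rows, not over bin means. Used for conservation-rank trends with 20 or
#' 100 bins.
#'
#' @param x numeric vector in [0, 1] (e.g. conservation rank).
#' @param y numeric response (e.g. gradient or dN/dS).
#' @param n_bins number of equal-width bins (>= 2).
#' @return a \code{binned_trend}: list with \code{n_bins}, \code{edges},
#'   \code{bins} (data.frame \code{bin}, \code{mid}, \code{count},
#'   \code{mean_x}, \code{mean_y}; empty bins have count 0 and missing
#'   means) and \code{fit} (\code{slope}, \code{intercept}, \code{r},
#'   \code{n}).
#' @export
bin_trend <- function(x, y, n_bins = 20L) {
  stopifnot(length(x) == length(y))
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) stop("need at least 2 valid rows", call. = FALSE)
  if (any(x[ok] < 0 | x[ok] > 1)) stop("x values must lie in [0, 1]", call. = FALSE)
  x <- x[ok]; y <- y[ok]
  edges <- seq(0, 1, length.out = n_bins + 1L)
  idx <- cut(x, breaks = edges, include.lowest = TRUE, right = TRUE,
             labels = FALSE)
  count <- tabulate(idx, nbins = n_bins)
  mean_x <- rep(NA_real_, n_bins); mean_y <- rep(NA_real_, n_bins)
  filled <- sort(unique(idx))
  mean_x[filled] <- vapply(filled, function(b) mean(x[idx == b]), numeric(1L))
  mean_y[filled] <- vapply(filled, function(b) mean(y[idx == b]), numeric(1L))
  fit <- stats::lm(y ~ x)
  r <- if (stats::sd(x) > 0 && stats::sd(y) > 0) stats::cor(x, y) else NA_real_
  structure(list(
    n_bins = n_bins, edges = edges,
    bins = data.frame(bin = seq_len(n_bins),
                      mid = (edges[-1L] + edges[-(n_bins + 1L)]) / 2,
                      count = count, mean_x = mean_x, mean_y = mean_y),
    fit = list(slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               r = r, n = length(x))
  ), class = "binned_trend")
}

#' @export
print.binned_trend <- function(x, ...) {
  cat("binned_trend: ", x$n_bins, " bins, n = ", x$fit$n,
      ", slope = ", signif(x$fit$slope, 4L),
      ", r = ", signif(x$fit$r, 4L), "\n", sep = "")
  invisible(x)
}

#' Pool the residues of one functional-site class
#'
#' All residues annotated with \code{site_type} that have both dN/dS and
#' the gradient column defined (the resampling pool).
#'
#' @param table residue table (see [build_residue_table()]).
#' @param sites site annotation data.frame.
#' @param site_type one site class.
#' @param gradient_col gradient column name (default \code{"gradient_r"}).
#' @return subset of \code{table} rows (unique residues).
#' @export
pool_site_residues <- function(table, sites, site_type,
                               gradient_col = "gradient_r") {
  sel <- sites[sites$site_type == site_type, , drop = FALSE]
  key <- paste(table$protein_id, table$resi, sep = "\r")
  skey <- unique(paste(sel$protein_id, sel$resi, sep = "\r"))
  pool <- table[key %in% skey, , drop = FALSE]
  pool[!is.na(pool$dnds) & !is.na(pool[[gradient_col]]), , drop = FALSE]
}

#' Resample residue subsets from one functional-site class
#'
#' Draws \code{n_subsets} random subsets of \code{subset_size} residues
#' from the class pool (uniformly without replacement within a subset,
#' independently across subsets) and records each subset's mean dN/dS and
#' mean gradient. If the pool is smaller than \code{subset_size}, sampling
#' is with replacement and a warning is issued.
#'
#' @param table residue table.
#' @param sites site annotation data.frame.
#' @param site_type one site class.
#' @param n_subsets number of subsets (default 1000).
#' @param subset_size residues per subset (default 250).
#' @param seed RNG seed for reproducibility.
#' @param gradient_col gradient column name.
#' @return data.frame with one row per subset: \code{site_type},
#'   \code{subset}, \code{mean_dnds}, \code{mean_gradient_r},
#'   \code{mean_gradient_strength}.
#' @export
sample_site_subsets <- function(table, sites, site_type, n_subsets = 1000L,
                                subset_size = 250L, seed = NULL,
                                gradient_col = "gradient_r") {
  pool <- pool_site_residues(table, sites, site_type, gradient_col)
  if (nrow(pool) == 0L) {
    stop("empty residue pool for site type '", site_type, "'", call. = FALSE)
  }
  replace <- nrow(pool) < subset_size
  if (replace) {
    warning("pool for '", site_type, "' (", nrow(pool),
            ") smaller than subset size ", subset_size,
            "; sampling with replacement")
  }
  if (!is.null(seed)) set.seed(seed)
  res <- matrix(NA_real_, nrow = n_subsets, ncol = 2L)
  for (b in seq_len(n_subsets)) {
    idx <- sample.int(nrow(pool), subset_size, replace = replace)
    res[b, 1L] <- mean(pool$dnds[idx])
    res[b, 2L] <- mean(pool[[gradient_col]][idx])
  }
  data.frame(site_type = site_type, subset = seq_len(n_subsets),
             mean_dnds = res[, 1L], mean_gradient_r = res[, 2L],
             mean_gradient_strength = -res[, 2L],
             stringsAsFactors = FALSE)
}

#' The k most conserved residues of a site
#'
#' @param resi residue positions of the site.
#' @param ranks conservation ranks aligned with \code{resi}.
#' @param k number of residues to keep (default 3); sites with \code{<= k}
#'   residues are returned whole. Rank ties break toward the lowest
#'   residue position.
#' @return residue positions of the top-k conserved site residues.
#' @export
top_k_conserved <- function(resi, ranks, k = 3L) {
  stopifnot(length(resi) == length(ranks), length(resi) >= 1L)
  if (length(resi) <= k) return(resi)
  ord <- order(-ranks, resi)
  resi[ord[seq_len(k)]]
}

#' Auto-generate buried non-functional site annotations
#'
#' Builds per-protein \code{buried_nonfunctional} pseudo-sites from packing
#' thresholds — residues with SC-WCN > 3.0 (or, alternatively, distance to
#' the protein center < 5.0 Angstrom) — after removing every residue that
#' belongs to any annotated functional site.
#'
#' @param table residue table with \code{sc_wcn} / \code{dist_to_center}.
#' @param sites existing functional-site annotations.
#' @param by \code{"sc_wcn"} or \code{"dist_to_center"}.
#' @param wcn_threshold SC-WCN cutoff (default 3.0).
#' @param dist_threshold center-distance cutoff in Angstrom (default 5.0).
#' @return site annotation data.frame rows of type
#'   \code{buried_nonfunctional} (possibly empty).
#' @export
buried_nonfunctional_sites <- function(table, sites,
                                       by = c("sc_wcn", "dist_to_center"),
                                       wcn_threshold = 3.0,
                                       dist_threshold = 5.0) {
  by <- match.arg(by)
  hit <- if (by == "sc_wcn") !is.na(table$sc_wcn) & table$sc_wcn > wcn_threshold
         else !is.na(table$dist_to_center) & table$dist_to_center < dist_threshold
  key <- paste(table$protein_id, table$resi, sep = "\r")
  func <- unique(paste(sites$protein_id, sites$resi, sep = "\r"))
  pick <- hit & !key %in% func
  if (!any(pick)) {
    return(data.frame(protein_id = character(0L), site_id = character(0L),
                      site_type = character(0L), resi = integer(0L),
                      stringsAsFactors = FALSE))
  }
  data.frame(protein_id = table$protein_id[pick],
             site_id = paste0(table$protein_id[pick], "_buried"),
             site_type = "buried_nonfunctional",
             resi = table$resi[pick], stringsAsFactors = FALSE)
}

#' Exact binomial test
#'
#' Exact binomial tail probabilities for \code{k} successes in \code{n}
#' trials under success probability \code{p0}. The two-sided p-value sums
#' the probabilities of all outcomes no more likely than the observed one
#' (the minlike rule), capped at 1.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials.
#' @param p0 null success probability (default 0.5).
#' @param alternative \code{"two.sided"}, \code{"greater"} or
#'   \code{"less"}.
#' @return p-value.
#' @export
binomial_test <- function(k, n, p0 = 0.5,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(k) == 1L, length(n) == 1L, is.finite(k), is.finite(n))
  if (n < 1L || k < 0L || k > n || k != round(k) || n != round(n)) {
    stop("require integers 0 <= k <= n, n >= 1", call. = FALSE)
  }
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)", call. = FALSE)
  switch(alternative,
    greater = sum(stats::dbinom(k:n, n, p0)),
    less = sum(stats::dbinom(0:k, n, p0)),
    two.sided = {
      pmf <- stats::dbinom(0:n, n, p0)
      min(1, sum(pmf[pmf <= pmf[k + 1L] * (1 + 1e-7)]))
    })
}

#' Within-protein concordance of conservation and gradient orderings
#'
#' For every multi-site protein, enumerates residue pairs drawn from two
#' \emph{different} functional sites whose types match the two class
#' filters (one residue matching each filter, in either role). A pair is
#' concordant when the more conserved residue (higher rank) also induces
#' the stronger gradient (more negative signed r); pairs tied in rank or
#' gradient are dropped. The concordant count is tested against a fair
#' coin with the exact binomial test.
#'
#' @param table residue table with \code{rank} and the gradient column.
#' @param sites site annotation data.frame.
#' @param class_a,class_b character vectors of site types for the two
#'   sides of the comparison (the definition is symmetric in the two).
#' @param pairing_mode \code{"all_pairs"} (every residue of each site),
#'   \code{"top1_per_site"} or \code{"top3_per_site"} (each site first
#'   restricted to its most conserved residues).
#' @param gradient_col gradient column name.
#' @return list with \code{pairs} (one row per retained pair),
#'   \code{n_concordant}, \code{n_total}, \code{fraction},
#'   \code{n_dropped_ties} and two-sided \code{p_value}.
#' @export
concordance_analysis <- function(table, sites, class_a, class_b,
                                 pairing_mode = c("all_pairs",
                                                  "top1_per_site",
                                                  "top3_per_site"),
                                 gradient_col = "gradient_r") {
  pairing_mode <- match.arg(pairing_mode)
  topk <- switch(pairing_mode, all_pairs = Inf, top1_per_site = 1L,
                 top3_per_site = 3L)
  key <- paste(table$protein_id, table$resi, sep = "\r")
  sel <- sites[sites$site_type %in% union(class_a, class_b), , drop = FALSE]
  pair_rows <- list()
  for (pid in unique(sel$protein_id)) {
    ps <- sel[sel$protein_id == pid, , drop = FALSE]
    site_ids <- unique(ps$site_id)
    if (length(site_ids) < 2L) next
    # per-site residue records with rank and gradient
    site_res <- lapply(site_ids, function(sid) {
      rr <- ps[ps$site_id == sid, , drop = FALSE]
      m <- match(paste(pid, rr$resi, sep = "\r"), key)
      out <- data.frame(resi = rr$resi, site_id = sid,
                        site_type = rr$site_type[1L],
                        rank = table$rank[m],
                        gradient = table[[gradient_col]][m],
                        stringsAsFactors = FALSE)
      out <- out[!is.na(out$rank) & !is.na(out$gradient), , drop = FALSE]
      if (is.finite(topk) && nrow(out) > topk) {
        out <- out[order(-out$rank, out$resi)[seq_len(topk)], , drop = FALSE]
      }
      out
    })
    names(site_res) <- site_ids
    for (i in seq_along(site_ids)) {
      for (j in seq_along(site_ids)) {
        if (j <= i) next
        ti <- site_res[[i]]$site_type[1L]; tj <- site_res[[j]]$site_type[1L]
        if (length(ti) == 0L || length(tj) == 0L) next
        if (!((ti %in% class_a && tj %in% class_b) ||
              (ti %in% class_b && tj %in% class_a))) next
        a <- site_res[[i]]; b <- site_res[[j]]
        if (nrow(a) == 0L || nrow(b) == 0L) next
        g <- expand.grid(ia = seq_len(nrow(a)), ib = seq_len(nrow(b)))
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          protein_id = pid,
          site_a = a$site_id[g$ia], type_a = a$site_type[g$ia],
          resi_a = a$resi[g$ia], rank_a = a$rank[g$ia],
          gradient_a = a$gradient[g$ia],
          site_b = b$site_id[g$ib], type_b = b$site_type[g$ib],
          resi_b = b$resi[g$ib], rank_b = b$rank[g$ib],
          gradient_b = b$gradient[g$ib],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(pair_rows) == 0L) {
    stop("no cross-site residue pairs match the class filters", call. = FALSE)
  }
  pairs <- do.call(rbind, pair_rows)
  tie <- pairs$rank_a == pairs$rank_b | pairs$gradient_a == pairs$gradient_b
  n_dropped <- sum(tie)
  pairs <- pairs[!tie, , drop = FALSE]
  if (nrow(pairs) == 0L) {
    stop("all pairs tied in rank or gradient", call. = FALSE)
  }
  # concordant: the higher-rank residue has the more negative signed r
  a_higher <- pairs$rank_a > pairs$rank_b
  pairs$concordant <- ifelse(a_higher,
                             pairs$gradient_a < pairs$gradient_b,
                             pairs$gradient_b < pairs$gradient_a)
  k <- sum(pairs$concordant); n <- nrow(pairs)
  list(pairs = pairs, n_concordant = k, n_total = n, fraction = k / n,
       n_dropped_ties = n_dropped,
       p_value = binomial_test(k, n, 0.5, "two.sided"))
}

#' Bootstrap standard error of the mean
#'
#' Standard deviation of the sample mean across bootstrap resamples (with
#' replacement, same size as the input), the package-wide way of attaching
#' uncertainties to mean gradients and mean dN/dS.
#'
#' @param values numeric vector (>= 2 non-missing values).
#' @param n_rounds bootstrap rounds (default 50).
#' @param seed RNG seed.
#' @return bootstrap standard error.
#' @export
bootstrap_se <- function(values, n_rounds = 50L, seed = NULL) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  if (n_rounds < 2L) stop("n_rounds must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  means <- vapply(seq_len(n_rounds), function(b) {
    mean(values[sample.int(length(values), replace = TRUE)])
  }, numeric(1L))
  stats::sd(means)
}
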