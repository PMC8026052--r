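#' Build the joined per-residue analysis table
#'
#' Joins conservation (score, rank), rates, geometry (SC-WCN,
#' distance-to-center, RSA, burial class) and the gradient profiles of one
#' or more variants into the single table consumed by all dataset-level
#' statistics. The first variant supplies the default \code{gradient_r}
#' column; every variant additionally gets its own
#' \code{gradient_<label>} column.
#'
#' @param structures list of \code{protein_structure}.
#' @param profiles list of \code{conservation_profile} (same order/names).
#' @param gradients list (per protein) of lists (per variant) of
#'   \code{gradient_profile}.
#' @param rates optional list of \code{rate_profile}.
#' @param rsa optional list of per-residue RSA vectors.
#' @return data.frame keyed by (\code{protein_id}, \code{resi}).
#' @export
build_residue_table <- function(structures, profiles, gradients,
                                rates = NULL, rsa = NULL) {
  stopifnot(length(structures) == length(profiles),
            length(structures) == length(gradients))
  out <- vector("list", length(structures))
  for (p in seq_along(structures)) {
    s <- structures[[p]]; prof <- profiles[[p]]
    n <- n_residues(s)
    if (length(prof$scores) != n) {
      stop("profile/structure length mismatch for '", s$protein_id, "'",
           call. = FALSE)
    }
    pk <- packing_profile(s)
    rsa_p <- if (!is.null(rsa)) rsa[[p]] else s$residues$rsa
    tab <- data.frame(protein_id = s$protein_id, chain = s$residues$chain,
                      resi = s$residues$resi, res_name = s$residues$res_name,
                      score = prof$scores, rank = prof$ranks,
                      dnds = if (!is.null(rates)) rates[[p]]$dnds else NA_real_,
                      sc_wcn = pk$sc_wcn, dist_to_center = pk$dist_to_center,
                      rsa = rsa_p, burial_class = classify_burial(rsa_p),
                      stringsAsFactors = FALSE)
    gl <- gradients[[p]]
    if (inherits(gl, "gradient_profile")) gl <- list(gl)
    for (v in seq_along(gl)) {
      gp <- gl[[v]]
      if (length(gp$gradient) != n) {
        stop("gradient/structure length mismatch for '", s$protein_id, "'",
             call. = FALSE)
      }
      if (v == 1L) tab$gradient_r <- gp$gradient
      tab[[paste0("gradient_", gp$variant$label)]] <- gp$gradient
    }
    out[[p]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pipeline run configuration
#'
#' Exactly one of \code{synthetic} (a [synthetic_config()]) or
#' \code{manifest} must be supplied. A manifest is a list with named
#' character vectors \code{structures}, \code{grades}, optionally
#' \code{rates} (file paths keyed by protein_id), optionally a
#' \code{sites} path and a \code{consurf_orientation} flag for the grade
#' files.
#'
#' @param synthetic a [synthetic_config()] or \code{NULL}.
#' @param manifest input-file manifest or \code{NULL}.
#' @param variants list of [gradient_variant()]; the first is the primary
#'   variant used by downstream statistics.
#' @param n_bins_rank bins for the rank-vs-gradient trend (default 20).
#' @param n_bins_rate bins for the rank-binned dN/dS trend (default 100).
#' @param n_subsets,subset_size resampling parameters (defaults 1000 and
#'   250).
#' @param pairing_mode concordance pairing mode.
#' @param seed seed for the resampling stage.
#' @param outdir optional output directory for TSV/JSON results.
#' @return a \code{run_config} list.
#' @export
run_config <- function(synthetic = NULL, manifest = NULL,
                       variants = list(gradient_variant()),
                       n_bins_rank = 20L, n_bins_rate = 100L,
                       n_subsets = 1000L, subset_size = 250L,
                       pairing_mode = "all_pairs", seed = 1L,
                       outdir = NULL) {
  if (is.null(synthetic) == is.null(manifest)) {
    stop("supply exactly one of 'synthetic' or 'manifest'", call. = FALSE)
  }
  if (inherits(variants, "gradient_variant")) variants <- list(variants)
  structure(list(synthetic = synthetic, manifest = manifest,
                 variants = variants, n_bins_rank = as.integer(n_bins_rank),
                 n_bins_rate = as.integer(n_bins_rate),
                 n_subsets = as.integer(n_subsets),
                 subset_size = as.integer(subset_size),
                 pairing_mode = pairing_mode, seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

load_manifest <- function(man) {
  ids <- names(man$structures)
  if (is.null(ids)) stop("manifest$structures must be named by protein_id",
                         call. = FALSE)
  orient <- isTRUE(man$consurf_orientation) ||
    is.null(man$consurf_orientation)
  structures <- profiles <- rates <- stats::setNames(vector("list", length(ids)), ids)
  for (pid in ids) {
    structures[[pid]] <- read_structure(man$structures[[pid]], protein_id = pid)
    gp <- man$grades[[pid]]
    if (is.null(gp) || !file.exists(gp)) {
      stop("missing grades file for protein '", pid, "'", call. = FALSE)
    }
    profiles[[pid]] <- read_consurf_scores(
      gp, protein_id = pid, consurf_orientation = orient,
      n_residues = n_residues(structures[[pid]]))
    if (!is.null(man$rates[[pid]])) {
      rates[[pid]] <- read_rate_table(man$rates[[pid]], protein_id = pid,
                                      n_residues = n_residues(structures[[pid]]))
    }
  }
  if (all(vapply(rates, is.null, logical(1L)))) rates <- NULL
  sites <- if (!is.null(man$sites)) read_sites_tsv(man$sites) else NULL
  list(structures = structures, profiles = profiles, rates = rates,
       sites = sites)
}

#' Run the conservation-percolation pipeline end to end
#'
#' Sequences the full analysis: structures and conservation profiles (from
#' files or the synthetic generator), geometry, gradient profiles under
#' every requested variant, the joined residue table, the binned
#' rank-vs-gradient trend, per-protein conservation-percolation
#' correlations, SC-WCN residualization, and — when site annotations and
#' rates are available — rank-binned dN/dS, per-class subset resampling
#' and within-protein concordance. Deterministic for a fixed config and
#' seed.
#'
#' @param cfg a [run_config()].
#' @return result bundle: list with \code{table}, \code{sites},
#'   \code{trend_rank_gradient}, \code{percolation} (per-protein r),
#'   \code{residualized}, and (when inputs allow)
#'   \code{trend_rank_dnds}, \code{subsets}, \code{concordance}; plus a
#'   \code{manifest_info} record of seed and dimensions.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(cfg$synthetic)) {
    ds <- generate_dataset(cfg$synthetic)
    structures <- ds$structures; profiles <- ds$profiles
    rates <- ds$rates; sites <- ds$sites
  } else {
    loaded <- load_manifest(cfg$manifest)
    structures <- loaded$structures; profiles <- loaded$profiles
    rates <- loaded$rates; sites <- loaded$sites
  }
  gradients <- vector("list", length(structures))
  percol <- numeric(length(structures))
  for (p in seq_along(structures)) {
    s <- structures[[p]]
    dmat <- ca_distance_matrix(s)
    gradients[[p]] <- lapply(cfg$variants, function(v) {
      gradient_profile(s, profiles[[p]], v, dmat = dmat)
    })
    percol[p] <- percolation_correlation(profiles[[p]]$ranks,
                                         gradients[[p]][[1L]]$gradient)
  }
  tab <- build_residue_table(structures, profiles, gradients, rates)
  trend_rg <- bin_trend(tab$rank, tab$gradient_r, cfg$n_bins_rank)
  resid <- tryCatch(
    residualize_gradient(tab$gradient_r, tab$rank, tab$sc_wcn),
    error = function(e) NULL)
  out <- list(
    table = tab, sites = sites,
    percolation = data.frame(
      protein_id = vapply(structures, `[[`, character(1L), "protein_id"),
      percolation_r = percol, stringsAsFactors = FALSE),
    trend_rank_gradient = trend_rg,
    residualized = resid,
    manifest_info = list(seed = cfg$seed,
                         n_proteins = length(structures),
                         n_residues = nrow(tab),
                         variants = vapply(cfg$variants, `[[`,
                                           character(1L), "label"))
  )
  if (!is.null(rates) && any(!is.na(tab$dnds))) {
    out$trend_rank_dnds <- bin_trend(tab$rank, tab$dnds, cfg$n_bins_rate)
  }
  if (!is.null(sites) && nrow(sites) > 0L) {
    types <- unique(sites$site_type)
    out$subsets <- do.call(rbind, lapply(seq_along(types), function(k) {
      sample_site_subsets(tab, sites, types[k], cfg$n_subsets,
                          cfg$subset_size,
                          seed = split_seed(cfg$seed, 1000L + k))
    }))
    if (length(types) >= 2L) {
      out$concordance <- tryCatch(
        concordance_analysis(tab, sites, types[1L], types[-1L],
                             pairing_mode = cfg$pairing_mode),
        error = function(e) NULL)
    }
  }
  if (!is.null(cfg$outdir)) write_results(out, cfg$outdir)
  out
}

write_results <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(out$table, "residue_table.tsv")
  wt(out$percolation, "percolation.tsv")
  wt(out$trend_rank_gradient$bins, "trend_rank_gradient.tsv")
  if (!is.null(out$trend_rank_dnds)) wt(out$trend_rank_dnds$bins,
                                        "trend_rank_dnds.tsv")
  if (!is.null(out$subsets)) wt(out$subsets, "subsets.tsv")
  if (!is.null(out$concordance)) {
    wt(out$concordance$pairs, "concordance_pairs.tsv")
    jsonlite::write_json(
      out$concordance[c("n_concordant", "n_total", "fraction", "p_value")],
      file.path(dir, "concordance_summary.json"),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(out$manifest_info, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Cross-check input consistency
#'
#' Compares residue counts between structures, conservation profiles,
#' rate profiles and site annotations per protein, reporting mismatches
#' without aborting.
#'
#' @param structures list of \code{protein_structure}.
#' @param profiles list of \code{conservation_profile}.
#' @param rates optional list of \code{rate_profile}.
#' @param sites optional site annotation data.frame.
#' @return data.frame report (\code{protein_id}, \code{check},
#'   \code{detail}); zero rows when everything is consistent.
#' @export
validate_inputs <- function(structures, profiles, rates = NULL,
                            sites = NULL) {
  rows <- list()
  note <- function(pid, check, detail) {
    rows[[length(rows) + 1L]] <<- data.frame(
      protein_id = pid, check = check, detail = detail,
      stringsAsFactors = FALSE)
  }
  for (p in seq_along(structures)) {
    s <- structures[[p]]; pid <- s$protein_id; n <- n_residues(s)
    if (length(profiles) >= p && length(profiles[[p]]$scores) != n) {
      note(pid, "profile_length",
           sprintf("structure has %d residues, profile has %d", n,
                   length(profiles[[p]]$scores)))
    }
    if (!is.null(rates) && length(rates) >= p &&
        length(rates[[p]]$dnds) != n) {
      note(pid, "rate_length",
           sprintf("structure has %d residues, rate table has %d", n,
                   length(rates[[p]]$dnds)))
    }
    if (!is.null(sites)) {
      sr <- sites$resi[sites$protein_id == pid]
      bad <- sr[sr < 1L | sr > n]
      if (length(bad) > 0L) {
        note(pid, "site_residue_range",
             paste("site residues outside 1..N:",
                   paste(bad, collapse = ",")))
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(protein_id = character(0L), check = character(0L),
                      detail = character(0L), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
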