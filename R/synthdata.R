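#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the synthetic generator flows from one master seed;
#' per-protein and per-component seeds are split off deterministically so
#' any component can be regenerated in isolation.
#'
#' @param seed master seed (integer).
#' @param index stream index (>= 1).
#' @return integer sub-seed in [1, 2^31 - 2].
#' @export
split_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + index * 104729) %%
               2147483646 + 1)
}

#' Generate a compact globular residue cloud
#'
#' Places \code{n_residues} Calpha positions by rejection sampling
#' uniformly inside a sphere of radius \code{r0 * n^(1/3)} (constant
#' density, as in globular proteins), each at least \code{min_dist} from
#' every previous residue. Side-chain centroids are the Calpha plus a
#' small seeded jitter (under 1 Angstrom).
#'
#' @param n_residues number of residues (>= 20 recommended).
#' @param min_dist minimum inter-residue distance, Angstrom (default 3.8,
#'   the Calpha-Calpha virtual bond length).
#' @param r0 packing radius coefficient, Angstrom (default 3.0).
#' @param seed RNG seed.
#' @param protein_id identifier.
#' @return a \code{protein_structure} (single chain "A", no atom records).
#' @export
generate_structure <- function(n_residues, min_dist = 3.8, r0 = 3.0,
                               seed = NULL, protein_id = "synthetic") {
  stopifnot(n_residues >= 2L)
  if (!is.null(seed)) set.seed(seed)
  radius <- r0 * n_residues^(1 / 3)
  if (n_residues * min_dist^3 > (4 / 3) * pi * radius^3) {
    stop("packing infeasible: sphere too small for min_dist", call. = FALSE)
  }
  xyz <- matrix(NA_real_, nrow = n_residues, ncol = 3L)
  placed <- 0L
  rejections <- 0L
  while (placed < n_residues) {
    # uniform in the ball via radius ~ U^(1/3)
    u <- stats::runif(3L)
    r <- radius * u[1L]^(1 / 3)
    th <- acos(1 - 2 * u[2L]); ph <- 2 * pi * u[3L]
    p <- r * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    ok <- placed == 0L ||
      all(rowSums((xyz[seq_len(placed), , drop = FALSE] -
                     matrix(p, placed, 3L, byrow = TRUE))^2) >= min_dist^2)
    if (ok) {
      placed <- placed + 1L
      xyz[placed, ] <- p
      rejections <- 0L
    } else {
      rejections <- rejections + 1L
      if (rejections > 1e5) {
        stop("packing infeasible: too many consecutive rejections",
             call. = FALSE)
      }
    }
  }
  jit <- matrix(stats::runif(3L * n_residues, -0.5, 0.5), ncol = 3L)
  res <- data.frame(chain = "A", resi = seq_len(n_residues),
                    resno = seq_len(n_residues), res_name = "ALA",
                    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                    scx = xyz[, 1L] + jit[, 1L],
                    scy = xyz[, 2L] + jit[, 2L],
                    scz = xyz[, 3L] + jit[, 3L],
                    rsa = NA_real_, stringsAsFactors = FALSE)
  protein_structure(protein_id, res)
}

#' Plant a distance-decaying conservation field
#'
#' Emulates a functional site radiating selective pressure: the
#' deterministic score of residue i is \code{s0 - beta * d_i}, where
#' \code{d_i} is its minimum Calpha distance to any site residue, plus
#' Gaussian noise of standard deviation \code{sigma}. With several sites,
#' each with its own decay slope, the per-site decays superpose
#' additively (selective pressure from every site acts on every residue),
#' which reduces to the single affine decay for one site; a side effect
#' mirroring real proteins is that a steep-decay site depresses the scores
#' of distant residues — including the other site — so high-slope sites
#' are also relatively more conserved. Site residues additionally receive
#' \code{boost} (default two noise SDs) so planted sites are also
#' top-ranked in conservation.
#'
#' @param s a \code{protein_structure}.
#' @param site_residues integer vector (one site) or list of integer
#'   vectors (several disjoint sites).
#' @param beta decay slope(s) per Angstrom, recycled across sites
#'   (>= 0).
#' @param s0 base score at the site.
#' @param sigma noise SD.
#' @param boost additive score bonus for site residues.
#' @param seed RNG seed.
#' @return a \code{conservation_profile} covering the structure.
#' @export
plant_conservation <- function(s, site_residues, beta, s0 = 0, sigma = 1,
                               boost = 2 * sigma, seed = NULL) {
  if (!is.list(site_residues)) site_residues <- list(site_residues)
  beta <- rep_len(beta, length(site_residues))
  stopifnot(all(beta >= 0), sigma >= 0)
  n <- n_residues(s)
  for (sr in site_residues) {
    if (any(sr < 1L | sr > n)) stop("site residue outside structure", call. = FALSE)
  }
  dmat <- ca_distance_matrix(s)
  per_site <- vapply(seq_along(site_residues), function(k) {
    d <- apply(dmat[, site_residues[[k]], drop = FALSE], 1L, min)
    -beta[k] * d
  }, numeric(n))
  score <- s0 + rowSums(as.matrix(per_site))
  if (!is.null(seed)) set.seed(seed)
  if (sigma > 0) score <- score + stats::rnorm(n, 0, sigma)
  score[unique(unlist(site_residues))] <-
    score[unique(unlist(site_residues))] + boost
  conservation_profile(s$protein_id, score)
}

#' Plant per-residue evolutionary rates from conservation ranks
#'
#' dN/dS decreasing in conservation rank with Gaussian noise:
#' \code{dnds_i = max(0.001, c0 - c1 * rank_i + eta_i)}, so highly
#' conserved residues evolve under stronger purifying selection.
#'
#' @param prof a \code{conservation_profile} with ranks.
#' @param c0 intercept (> 0; the expected rate of a rank-0 residue).
#' @param c1 slope against rank.
#' @param rate_sd noise SD.
#' @param seed RNG seed.
#' @return a \code{rate_profile}.
#' @export
plant_rates <- function(prof, c0 = 1, c1 = 0.9, rate_sd = 0.2,
                        seed = NULL) {
  if (c0 <= 0) stop("c0 must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(prof$ranks)
  eta <- if (rate_sd > 0) stats::rnorm(n, 0, rate_sd) else numeric(n)
  dnds <- pmax(0.001, c0 - c1 * prof$ranks + eta)
  dnds[is.na(prof$ranks)] <- NA_real_
  structure(list(protein_id = prof$protein_id, dnds = dnds),
            class = "rate_profile")
}

#' Synthetic study configuration
#'
#' Defaults correspond to the package's reference study conditions:
#' proteins of 150 residues, unit score noise, a catalytic-like site of 5
#' residues with decay slope 0.3 per Angstrom, and a rate model with
#' intercept 1, rank slope 0.9 and noise SD 0.2.
#'
#' @param n_proteins number of proteins.
#' @param n_residues residues per protein (>= 20).
#' @param sites list of site specs, each
#'   \code{list(site_type =, k =, beta =, s0 =)}.
#' @param sigma conservation noise SD.
#' @param boost score bonus for site residues (default \code{2 * sigma}).
#' @param rate_c0,rate_c1,rate_sd rate model coefficients.
#' @param min_dist,r0 structure packing parameters (Angstrom).
#' @param seed master seed.
#' @return a \code{synthetic_config} list.
#' @export
synthetic_config <- function(n_proteins = 30L, n_residues = 150L,
                             sites = list(list(site_type = "catalytic",
                                               k = 5L, beta = 0.3, s0 = 0)),
                             sigma = 1, boost = 2 * sigma,
                             rate_c0 = 1, rate_c1 = 0.9, rate_sd = 0.2,
                             min_dist = 3.8, r0 = 3.0, seed = 1L) {
  stopifnot(n_residues >= 20L, sigma >= 0,
            all(vapply(sites, function(x) x$beta >= 0 && x$k >= 1L,
                       logical(1L))))
  structure(list(n_proteins = as.integer(n_proteins),
                 n_residues = as.integer(n_residues), sites = sites,
                 sigma = sigma, boost = boost, rate_c0 = rate_c0,
                 rate_c1 = rate_c1, rate_sd = rate_sd,
                 min_dist = min_dist, r0 = r0, seed = as.integer(seed)),
            class = "synthetic_config")
}

# pick k-residue spatially compact, mutually disjoint sites
pick_sites <- function(s, specs, seed) {
  set.seed(seed)
  dmat <- ca_distance_matrix(s)
  used <- integer(0L)
  out <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    avail <- setdiff(seq_len(n_residues(s)), used)
    core <- sample(avail, 1L)
    nb <- avail[order(dmat[core, avail])]
    members <- nb[seq_len(min(specs[[k]]$k, length(nb)))]
    out[[k]] <- sort(members)
    used <- c(used, members)
  }
  out
}

#' Generate a full synthetic dataset
#'
#' Per protein: a packed residue cloud, one planted site per site spec
#' (disjoint, spatially compact), a conservation field decaying from the
#' sites, and a rate profile tied to the conservation ranks. The planted
#' parameters are kept as ground truth for recovery tests.
#'
#' @param cfg a [synthetic_config()].
#' @return a \code{synthetic_dataset}: list with \code{structures},
#'   \code{profiles}, \code{rates} (per-protein lists), \code{sites}
#'   (annotation data.frame), \code{truth} and \code{config}.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  structures <- profiles <- rates <- truth <- vector("list", cfg$n_proteins)
  site_rows <- list()
  for (p in seq_len(cfg$n_proteins)) {
    pid <- sprintf("synth%03d", p)
    s <- generate_structure(cfg$n_residues, cfg$min_dist, cfg$r0,
                            seed = split_seed(cfg$seed, 4L * p),
                            protein_id = pid)
    site_res <- pick_sites(s, cfg$sites, seed = split_seed(cfg$seed, 4L * p + 1L))
    betas <- vapply(cfg$sites, `[[`, numeric(1L), "beta")
    s0 <- if (!is.null(cfg$sites[[1L]]$s0)) cfg$sites[[1L]]$s0 else 0
    prof <- plant_conservation(s, site_res, betas, s0 = s0,
                               sigma = cfg$sigma, boost = cfg$boost,
                               seed = split_seed(cfg$seed, 4L * p + 2L))
    rp <- plant_rates(prof, cfg$rate_c0, cfg$rate_c1, cfg$rate_sd,
                      seed = split_seed(cfg$seed, 4L * p + 3L))
    for (k in seq_along(cfg$sites)) {
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        protein_id = pid,
        site_id = sprintf("%s_site%d", pid, k),
        site_type = cfg$sites[[k]]$site_type,
        resi = site_res[[k]], stringsAsFactors = FALSE)
    }
    structures[[p]] <- s; profiles[[p]] <- prof; rates[[p]] <- rp
    truth[[p]] <- list(protein_id = pid, site_residues = site_res,
                       beta = betas, sigma = cfg$sigma)
  }
  ids <- vapply(structures, `[[`, character(1L), "protein_id")
  names(structures) <- names(profiles) <- names(rates) <- names(truth) <- ids
  structure(list(structures = structures, profiles = profiles,
                 rates = rates, sites = do.call(rbind, site_rows),
                 truth = truth, config = cfg),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset: ", length(x$structures), " proteins x ",
      x$config$n_residues, " residues, ",
      length(x$config$sites), " planted site(s)/protein, seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' One minimal CA-only PDB, one conservation-grade TSV (written in the
#' ConSurf orientation, lower = more conserved, to match real ingestion),
#' and one rate TSV per protein, plus a shared sites TSV and a
#' ground-truth JSON.
#'
#' @param ds a \code{synthetic_dataset}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0L)
  for (pid in names(ds$structures)) {
    s <- ds$structures[[pid]]
    pdb <- file.path(dir, paste0(pid, ".pdb"))
    bio3d::write.pdb(file = pdb,
                     xyz = as.numeric(t(as.matrix(s$residues[, c("x", "y", "z")]))),
                     resno = s$residues$resi, resid = s$residues$res_name,
                     chain = s$residues$chain,
                     elety = rep("CA", n_residues(s)))
    grades <- file.path(dir, paste0(pid, "_grades.tsv"))
    utils::write.table(
      data.frame(position = seq_along(ds$profiles[[pid]]$scores),
                 score = -ds$profiles[[pid]]$scores),
      grades, sep = "\t", quote = FALSE, row.names = FALSE)
    rate <- file.path(dir, paste0(pid, "_rates.tsv"))
    utils::write.table(
      data.frame(position = seq_along(ds$rates[[pid]]$dnds),
                 dnds = ds$rates[[pid]]$dnds),
      rate, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, structure(c(pdb, grades, rate),
                                names = paste0(pid, c("_pdb", "_grades", "_rates"))))
  }
  sites_path <- file.path(dir, "sites.tsv")
  utils::write.table(ds$sites, sites_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(ds$truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, sites = sites_path, truth = truth_path))
}
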