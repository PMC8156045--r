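# Seeded synthetic-data generator.
#
# Emulates the statistical structure the analysis assumes: domains with
# random PIP ligand sets; per-residue phosphorylation events arriving as
# a Poisson process whose in-Site rate is coupled to the domain's lipid
# specificity (rate lambda0 outside Sites, lambda0 + beta * LSI / 10
# inside); heavy-tailed citation counts (shifted geometric) per observed
# phosphosite; and three-peaked docking score profiles whose bumps sit in
# the configured Site windows. All randomness flows through R's RNG,
# seeded once per generated panel.

#' Configuration for the synthetic panel generator
#'
#' @param n_domains number of domains to simulate (>= 1).
#' @param seed integer seed (mandatory).
#' @param ligand_size_weights sampling weights for ligand-set sizes 1-7
#'   (default uniform).
#' @param domain_length residues per simulated domain (default 120).
#' @param windows Site residue intervals from [site_windows()]; default
#'   Sites 1-3 at [20,28), [55,63), [75,90) within the 120-residue
#'   domain, mirroring the beta1-beta2 loop, beta3-alpha1 region and
#'   PRE-alpha2 loop placement of a typical PX domain.
#' @param lambda0 baseline expected phosphorylation events per residue
#'   outside Sites (default 0.02).
#' @param beta added in-Site event rate per unit of LSI/10
#'   (default 0.5); `beta = 0` is the null model.
#' @param citation_geom_prob success probability of the shifted
#'   geometric citation-count distribution (smaller = heavier tail;
#'   default 0.3, mean about 3.3 citations per phosphosite).
#' @param residue_type_probs sampling probabilities for S/T/Y
#'   (default 0.50/0.25/0.25).
#' @return list of class `"px_sim_config"`.
#' @export
sim_config <- function(n_domains, seed,
                       ligand_size_weights = rep(1, 7),
                       domain_length = 120L,
                       windows = site_windows(c(20L, 55L, 75L),
                                              c(28L, 63L, 90L)),
                       lambda0 = 0.02, beta = 0.5,
                       citation_geom_prob = 0.3,
                       residue_type_probs = c(S = 0.50, T = 0.25, Y = 0.25)) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  n_domains <- as.integer(n_domains)
  if (is.na(n_domains) || n_domains < 1L) {
    stop("n_domains must be >= 1", call. = FALSE)
  }
  stopifnot(length(ligand_size_weights) == 7L, all(ligand_size_weights >= 0),
            sum(ligand_size_weights) > 0,
            lambda0 >= 0, beta >= 0,
            citation_geom_prob > 0, citation_geom_prob <= 1,
            length(residue_type_probs) == 3L, all(residue_type_probs > 0))
  domain_length <- as.integer(domain_length)
  if (max(windows$end) > domain_length + 1L) {
    stop("site windows exceed domain_length", call. = FALSE)
  }
  cfg <- list(n_domains = n_domains, seed = as.integer(seed),
              ligand_size_weights = ligand_size_weights,
              domain_length = domain_length, windows = windows,
              lambda0 = lambda0, beta = beta,
              citation_geom_prob = citation_geom_prob,
              residue_type_probs = residue_type_probs /
                sum(residue_type_probs))
  class(cfg) <- "px_sim_config"
  cfg
}

#' Draw one random PIP ligand set
#'
#' Draws a set size from the configured size weights, then samples that
#' many of the seven PIP codes uniformly without replacement. Uses the
#' current RNG state; seed via [generate_panel()] or `set.seed()`.
#'
#' @param config a [sim_config()] object.
#' @return character vector of PIP codes in canonical order.
#' @export
sample_ligand_set <- function(config) {
  size <- sample.int(7L, 1L, prob = config$ligand_size_weights)
  codes <- sample(PIP_CODES, size)
  codes[.pip_order(codes)]
}

#' Simulate phosphosite records for one domain
#'
#' Per residue, phosphorylation events arrive with Poisson rate
#' `lambda0` outside the Sites and `lambda0 + beta * LSI / 10` inside.
#' Residues with at least one event become phosphosites; each receives a
#' citation count of 1 plus a geometric draw and a residue type sampled
#' from the configured proportions. Citation counts are emitted in the
#' integer-count dialect of the phosphosite TSV.
#'
#' @param domain_id protein identifier for the records.
#' @param lsi the domain's Lipid Specificity Index (0-10).
#' @param config a [sim_config()] object.
#' @return data.frame of records (`protein_id`, `position`,
#'   `residue_type`, `citations`, `source`) with attribute
#'   `"ground_truth"`: per-domain realized event counts and true rates.
#' @export
simulate_phosphosites <- function(domain_id, lsi, config) {
  L <- config$domain_length
  in_site <- !is.na(assign_sites(seq_len(L), config$windows))
  rate <- ifelse(in_site, config$lambda0 + config$beta * lsi / 10,
                 config$lambda0)
  events <- stats::rpois(L, rate)
  pos <- which(events > 0L)
  n <- length(pos)
  rec <- data.frame(
    protein_id = rep(domain_id, n),
    position = pos,
    residue_type = if (n) sample(names(config$residue_type_probs), n,
                                 replace = TRUE,
                                 prob = config$residue_type_probs)
                   else character(),
    citations = if (n) as.character(1L + stats::rgeom(n, config$citation_geom_prob))
                else character(),
    source = rep("sim", n),
    stringsAsFactors = FALSE)
  attr(rec, "ground_truth") <- list(
    rate_in = config$lambda0 + config$beta * lsi / 10,
    rate_out = config$lambda0,
    n_in = sum(in_site), n_out = sum(!in_site),
    events_in = sum(events[in_site]), events_out = sum(events[!in_site]))
  rec
}

#' Simulate a three-peaked docking score profile
#'
#' Background scores are drawn uniformly in (5, 25); every residue of
#' each Site window receives a score in (40, 70), so the profile carries
#' exactly three proximal clusters under the default calling parameters,
#' centred on the configured windows.
#'
#' @inheritParams simulate_phosphosites
#' @param bumps set `FALSE` for a background-only (cluster-free) profile.
#' @return list (`domain_id`, `offset`, `scores`) as from
#'   [read_scores()].
#' @export
simulate_score_profile <- function(domain_id, config, bumps = TRUE) {
  L <- config$domain_length
  scores <- stats::runif(L, 5, 25)
  if (bumps) {
    for (i in seq_len(nrow(config$windows))) {
      idx <- config$windows$start[i]:(config$windows$end[i] - 1L)
      scores[idx] <- stats::runif(length(idx), 40, 70)
    }
  }
  list(domain_id = domain_id, offset = 1L, scores = round(scores, 3))
}

#' Generate a synthetic panel in memory
#'
#' Seeds the RNG from the configuration and draws, per domain, a ligand
#' set (scored to its true LSI), phosphosite records and a docking score
#' profile. [generate_panel()] additionally writes the panel to disk.
#'
#' @param config a [sim_config()] object.
#' @return list of class `"px_sim_panel"`: `panel` (ligand profiles with
#'   `mai` and `organism`), `phosphosites`, `score_profiles` (named
#'   list), `site_windows`, `ground_truth` (per-domain true LSI, rates
#'   and realized event counts, plus the generating parameters).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "px_sim_config"))
  with_seed(config$seed, {
    ids <- sprintf("SIM%04d", seq_len(config$n_domains))
    ligsets <- lapply(ids, function(i) sample_ligand_set(config))
    lsi <- vapply(ligsets, function(l) compute_lsi(l)$lsi, integer(1))
    recs <- vector("list", config$n_domains)
    gt <- vector("list", config$n_domains)
    profs <- vector("list", config$n_domains)
    for (i in seq_len(config$n_domains)) {
      r <- simulate_phosphosites(ids[i], lsi[i], config)
      recs[[i]] <- r
      g <- attr(r, "ground_truth")
      g$domain_id <- ids[i]
      g$lsi_true <- lsi[i]
      gt[[i]] <- g
      profs[[i]] <- simulate_score_profile(ids[i], config)
    }
    names(profs) <- ids
    panel <- data.frame(
      domain_id = ids,
      ligands = vapply(ligsets, paste, character(1), collapse = ","),
      mai = rep("S", config$n_domains),
      organism = rep("synthetic", config$n_domains),
      stringsAsFactors = FALSE)
    out <- list(panel = panel,
                phosphosites = do.call(rbind, recs),
                score_profiles = profs,
                site_windows = config$windows,
                ground_truth = list(
                  config = config[c("n_domains", "seed", "domain_length",
                                    "lambda0", "beta", "citation_geom_prob")],
                  domains = gt))
    class(out) <- "px_sim_panel"
    out
  })
}

#' Generate a synthetic panel and write it to disk
#'
#' Writes `panel.tsv`, `phosphosites.tsv`, `scores.csv`, `windows.json`
#' and `ground_truth.json` under `dir`. Re-running with the same
#' configuration (same seed) reproduces byte-identical files.
#'
#' @param config a [sim_config()] object.
#' @param dir output directory (created if absent).
#' @return the [simulate_panel()] result, invisibly, with a `paths`
#'   attribute naming the files written.
#' @export
generate_panel <- function(config, dir) {
  sim <- simulate_panel(config)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", dir),
                  call. = FALSE)
  }
  paths <- c(panel = file.path(dir, "panel.tsv"),
             phosphosites = file.path(dir, "phosphosites.tsv"),
             scores = file.path(dir, "scores.csv"),
             windows = file.path(dir, "windows.json"),
             ground_truth = file.path(dir, "ground_truth.json"))
  write_panel(sim$panel, paths["panel"])
  write_phosphosites(sim$phosphosites, paths["phosphosites"])
  write_scores(sim$score_profiles, paths["scores"])
  write_site_windows(sim$site_windows, paths["windows"])
  jsonlite::write_json(sim$ground_truth, paths["ground_truth"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(sim, "paths") <- paths
  invisible(sim)
}
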