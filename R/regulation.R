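# Specificity-regulation association analysis.
#
# Quantifies (i) enrichment of phosphorylation citations inside the
# membrane-binding Sites, (ii) phosphosite density in a region versus the
# full protein, and (iii) the association between lipid specificity (LSI)
# and phosphoregulation (PSS) as a Spearman rank correlation with a
# permutation p-value.

# evaluate code under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Citation enrichment in membrane-binding Sites
#'
#' Sums citation counts over all merged phosphosites, partitions them by
#' whether the residue falls inside Site 1, 2 or 3 of its protein, and
#' returns the in-Site fraction. With zero total citations the fraction
#' is undefined and reported as `NA` (serialized as null), never as 0.
#'
#' @param records merged phosphosite records (possibly many proteins;
#'   see [merge_phosphosites()]).
#' @param intervals per-domain Site intervals: either a single
#'   data.frame (`site`, `start`, `end`; applied to every protein) or a
#'   named list of such data.frames keyed by protein_id. Proteins absent
#'   from the list are counted as entirely out-of-Site.
#' @return list of class `"px_enrichment"`: `total_citations`,
#'   `in_site_citations`, `fraction`, `n_records`, `n_in_site`.
#' @export
site_enrichment <- function(records, intervals) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    res <- list(total_citations = 0L, in_site_citations = 0L,
                fraction = NA_real_, n_records = 0L, n_in_site = 0L)
    class(res) <- "px_enrichment"
    return(res)
  }
  site <- .assign_sites_by_protein(records, intervals)
  inn <- !is.na(site)
  total <- sum(records$n_citations)
  in_cit <- sum(records$n_citations[inn])
  res <- list(total_citations = as.integer(total),
              in_site_citations = as.integer(in_cit),
              fraction = if (total > 0) in_cit / total else NA_real_,
              n_records = nrow(records),
              n_in_site = sum(inn))
  class(res) <- "px_enrichment"
  res
}

.assign_sites_by_protein <- function(records, intervals) {
  if (is.data.frame(intervals)) {
    return(assign_sites(records$position, intervals))
  }
  stopifnot(is.list(intervals))
  site <- rep(NA_integer_, nrow(records))
  for (pid in unique(records$protein_id)) {
    if (is.null(intervals[[pid]])) next
    sel <- records$protein_id == pid
    site[sel] <- assign_sites(records$position[sel], intervals[[pid]])
  }
  site
}

#' @export
print.px_enrichment <- function(x, ...) {
  frac <- if (is.na(x$fraction)) "undefined"
          else sprintf("%.1f%%", 100 * x$fraction)
  cat(sprintf("citations: %d total, %d in Sites (%s); %d/%d residues in Sites\n",
              x$total_citations, x$in_site_citations, frac,
              x$n_in_site, x$n_records))
  invisible(x)
}

#' Phosphosite density in a region versus a reference
#'
#' Distinct phosphosite residues per residue of sequence, expressed as
#' percentages, for a sub-region (e.g. the PX domain) and for the full
#' protein. The region density counts only phosphosites inside the
#' region.
#'
#' @param positions integer vector of distinct phosphosite positions
#'   (1-based full-protein coordinates).
#' @param region half-open interval `c(start, end)` delimiting the
#'   region in full-protein coordinates.
#' @param reference_length full protein length (> 0).
#' @return named numeric vector: `region_pct`, `reference_pct`.
#' @export
phospho_density <- function(positions, region, reference_length) {
  stopifnot(is.numeric(positions), length(region) == 2L)
  region <- as.integer(region)
  region_length <- region[2] - region[1]
  if (is.na(region_length) || region_length <= 0L) {
    stop("region must be a non-empty half-open interval", call. = FALSE)
  }
  if (!is.numeric(reference_length) || reference_length <= 0) {
    stop("reference_length must be positive", call. = FALSE)
  }
  positions <- unique(positions)
  n_in <- sum(positions >= region[1] & positions < region[2])
  c(region_pct = 100 * n_in / region_length,
    reference_pct = 100 * length(positions) / reference_length)
}

#' Bubble table of domain counts by (LSI, capped PSS)
#'
#' The tabular form of the specificity-versus-regulation bubble plot:
#' counts of domains per (LSI, PSS) cell with PSS capped for display,
#' overall and stratified by any of the optional columns present
#' (`pss_st`/`pss_y` residue-type scores, `organism`). Rows with
#' undetermined LSI are excluded.
#'
#' @param panel data.frame with columns `lsi` and `pss`; optional
#'   `pss_st`, `pss_y` (Ser/Thr-only and Tyr-only PSS) and `organism`.
#' @param pss_cap display cap applied as `pmin(pss, pss_cap)`
#'   (default 15).
#' @return data.frame: `stratum`, `lsi`, `pss_capped`, `count`.
#' @export
specificity_regulation_table <- function(panel, pss_cap = 15L) {
  stopifnot(is.data.frame(panel), all(c("lsi", "pss") %in% names(panel)),
            pss_cap >= 0)
  panel <- panel[!is.na(panel$lsi), , drop = FALSE]
  tab_one <- function(lsi, pss, stratum) {
    keep <- !is.na(pss)
    lsi <- lsi[keep]; pss <- pmin(pss[keep], as.integer(pss_cap))
    if (length(lsi) == 0L) {
      return(data.frame(stratum = character(), lsi = integer(),
                        pss_capped = integer(), count = integer()))
    }
    agg <- aggregate(list(count = lsi),
                     by = list(lsi = lsi, pss_capped = pss), FUN = length)
    data.frame(stratum = stratum, lsi = agg$lsi,
               pss_capped = agg$pss_capped, count = agg$count,
               stringsAsFactors = FALSE)
  }
  out <- tab_one(panel$lsi, panel$pss, "all")
  if ("pss_st" %in% names(panel)) {
    out <- rbind(out, tab_one(panel$lsi, panel$pss_st, "pS/pT"))
  }
  if ("pss_y" %in% names(panel)) {
    out <- rbind(out, tab_one(panel$lsi, panel$pss_y, "pY"))
  }
  if ("organism" %in% names(panel)) {
    for (org in unique(panel$organism)) {
      sel <- panel$organism == org
      out <- rbind(out, tab_one(panel$lsi[sel], panel$pss[sel], org))
    }
  }
  out <- out[order(out$stratum, out$lsi, out$pss_capped), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank association between specificity and regulation
#'
#' Spearman rank correlation between LSI and PSS with a two-sided
#' permutation p-value obtained by shuffling the PSS values. Pairs are
#' canonically ordered internally so that the result is invariant under
#' any reordering of the input rows; for a fixed seed the test is fully
#' deterministic. A constant LSI or PSS vector leaves the correlation
#' undefined (`NA`).
#'
#' @param lsi,pss numeric vectors of equal length (pairs with `NA` in
#'   either are dropped; at least 3 complete pairs required).
#' @param n_permutations number of label permutations (>= 100; default
#'   10000).
#' @param seed integer seed (mandatory).
#' @return list of class `"px_assoc"`: `rho`, `p_value`, `n`,
#'   `n_permutations`, `seed`. `rho` and `p_value` are `NA` when the
#'   correlation is undefined.
#' @export
association_stat <- function(lsi, pss, n_permutations = 10000L, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(length(lsi) == length(pss))
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 100L) {
    stop("n_permutations must be >= 100", call. = FALSE)
  }
  keep <- !is.na(lsi) & !is.na(pss)
  lsi <- lsi[keep]; pss <- pss[keep]
  n <- length(lsi)
  if (n < 3L) stop("need at least 3 domains with defined LSI and PSS",
                   call. = FALSE)
  # canonical order => exact invariance to input row permutations
  o <- order(lsi, pss)
  lsi <- lsi[o]; pss <- pss[o]
  res <- list(rho = NA_real_, p_value = NA_real_, n = n,
              n_permutations = n_permutations, seed = seed)
  class(res) <- "px_assoc"
  if (length(unique(lsi)) == 1L || length(unique(pss)) == 1L) {
    return(res)
  }
  r1 <- rank(lsi); r2 <- rank(pss)
  rho_obs <- stats::cor(r1, r2)
  r1c <- r1 - mean(r1)
  denom <- (n - 1L) * stats::sd(r1) * stats::sd(r2)
  perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) r2[sample.int(n)],
           numeric(n))
  })
  rho_perm <- as.numeric(crossprod(r1c, perm - mean(r2))) / denom
  res$rho <- rho_obs
  res$p_value <- (1 + sum(abs(rho_perm) >= abs(rho_obs) - 1e-12)) /
    (n_permutations + 1)
  res
}

#' @export
print.px_assoc <- function(x, ...) {
  if (is.na(x$rho)) {
    cat(sprintf("Spearman association: undefined (n = %d)\n", x$n))
  } else {
    cat(sprintf(
      "Spearman rho = %.3f, permutation p = %.4g (n = %d, %d permutations)\n",
      x$rho, x$p_value, x$n, x$n_permutations))
  }
  invisible(x)
}
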