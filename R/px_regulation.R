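#' Joint specificity-regulation analysis of a PX domain panel
#'
#' The package's main entry point. Scores every domain's Lipid
#' Specificity Index from its PIP ligand set, merges the supplied
#' phosphoproteomic records and computes each domain's PIP-Stop Score
#' over its membrane-binding Site intervals, then summarises the panel:
#' citation enrichment in Sites, the (LSI, capped PSS) bubble table
#' behind the specificity-regulation plot, and a Spearman permutation
#' test of the association.
#'
#' @param panel domain panel data.frame as returned by [read_panel()] or
#'   [generate_panel()] (columns `domain_id`, `ligands`, `mai`, optional
#'   `organism`).
#' @param phosphosites phosphosite record data.frame as returned by
#'   [read_phosphosites()]; merged internally with
#'   [merge_phosphosites()].
#' @param intervals membrane-binding Site residue intervals: one
#'   data.frame (`site`, `start`, `end`, half-open) applied to every
#'   domain, or a named list of per-domain data.frames.
#' @param pss_cap display cap for the bubble table (default 15).
#' @param n_permutations permutations for the association test
#'   (default 10000).
#' @param seed integer seed for the permutation test (mandatory).
#' @return object of class `"px_regulation"` with elements `panel`
#'   (per-domain data.frame: domain_id, lsi, predominant_class, pss,
#'   pss_site1..3, pss_st, pss_y, n_phosphosites, pS, pT, pY, mai,
#'   organism), `enrichment` ([site_enrichment()] result), `bubble`
#'   ([specificity_regulation_table()] result), `association`
#'   ([association_stat()] result) and `params`.
#' @examples
#' cfg <- sim_config(n_domains = 25, seed = 7)
#' sim <- simulate_panel(cfg)
#' fit <- px_regulation(sim$panel, sim$phosphosites, sim$site_windows,
#'                      n_permutations = 200, seed = 7)
#' summary(fit)
#' @export
px_regulation <- function(panel, phosphosites, intervals, pss_cap = 15L,
                          n_permutations = 10000L, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  spec <- score_panel(panel, quiet = TRUE)
  merged <- merge_phosphosites(phosphosites)
  per_domain <- lapply(seq_len(nrow(spec)), function(i) {
    id <- spec$domain_id[i]
    iv <- if (is.data.frame(intervals)) intervals else intervals[[id]]
    rec <- merged[merged$protein_id == id, , drop = FALSE]
    if (is.null(iv)) {
      warning(sprintf("no Site intervals for domain %s; PSS set to NA", id),
              call. = FALSE)
      return(data.frame(pss = NA_integer_, pss_site1 = NA_integer_,
                        pss_site2 = NA_integer_, pss_site3 = NA_integer_,
                        pss_st = NA_integer_, pss_y = NA_integer_,
                        n_phosphosites = nrow(rec),
                        pS = NA_integer_, pT = NA_integer_, pY = NA_integer_))
    }
    p <- compute_pss(rec, iv, domain_id = id)
    st <- p$contributing$residue_type %in% c("S", "T")
    data.frame(pss = p$pss_total,
               pss_site1 = p$per_site[["site1"]],
               pss_site2 = p$per_site[["site2"]],
               pss_site3 = p$per_site[["site3"]],
               pss_st = sum(p$contributing$weight[st]),
               pss_y = sum(p$contributing$weight[!st]),
               n_phosphosites = nrow(rec),
               pS = p$per_residue_type[["pS"]],
               pT = p$per_residue_type[["pT"]],
               pY = p$per_residue_type[["pY"]])
  })
  tab <- cbind(spec, do.call(rbind, per_domain))
  if ("mai" %in% names(panel)) {
    tab$mai <- panel$mai[match(tab$domain_id, panel$domain_id)]
  }
  if ("organism" %in% names(panel)) {
    tab$organism <- panel$organism[match(tab$domain_id, panel$domain_id)]
  }
  rownames(tab) <- NULL
  known <- merged$protein_id %in% spec$domain_id
  enr <- site_enrichment(merged[known, , drop = FALSE], intervals)
  bubble <- specificity_regulation_table(tab, pss_cap = pss_cap)
  defined <- !is.na(tab$lsi) & !is.na(tab$pss)
  assoc <- if (sum(defined) >= 3L) {
    association_stat(tab$lsi[defined], tab$pss[defined],
                     n_permutations = n_permutations, seed = seed)
  } else {
    structure(list(rho = NA_real_, p_value = NA_real_, n = sum(defined),
                   n_permutations = n_permutations, seed = seed),
              class = "px_assoc")
  }
  res <- list(panel = tab, enrichment = enr, bubble = bubble,
              association = assoc,
              params = list(pss_cap = as.integer(pss_cap),
                            n_permutations = as.integer(n_permutations),
                            seed = seed),
              call = match.call())
  class(res) <- "px_regulation"
  res
}

#' @export
print.px_regulation <- function(x, ...) {
  cat("PX domain specificity-regulation analysis\n")
  cat(sprintf("  domains: %d (%d with determined LSI)\n",
              nrow(x$panel), sum(!is.na(x$panel$lsi))))
  print(x$association)
  invisible(x)
}

#' @export
summary.px_regulation <- function(object, ...) {
  p <- object$panel
  out <- list(
    n_domains = nrow(p),
    n_determined = sum(!is.na(p$lsi)),
    n_lsi10 = sum(p$lsi == 10L, na.rm = TRUE),
    n_lsi0 = sum(p$lsi == 0L, na.rm = TRUE),
    mean_pss = mean(p$pss, na.rm = TRUE),
    enrichment = object$enrichment,
    association = object$association)
  class(out) <- "summary.px_regulation"
  out
}

#' @export
print.summary.px_regulation <- function(x, ...) {
  cat("PX domain specificity-regulation analysis\n")
  cat(sprintf("  domains: %d (%d determined; %d at LSI 10, %d at LSI 0)\n",
              x$n_domains, x$n_determined, x$n_lsi10, x$n_lsi0))
  cat(sprintf("  mean PSS: %.2f\n", x$mean_pss))
  cat("  "); print(x$enrichment)
  cat("  "); print(x$association)
  invisible(x)
}

#' @export
coef.px_regulation <- function(object, ...) {
  c(rho = object$association$rho, p.value = object$association$p_value)
}

#' Bubble plot of the specificity-regulation relationship
#'
#' Plots capped PSS against LSI with circle areas proportional to the
#' number of domains in each cell, for one stratum of the bubble table.
#'
#' @param x a `px_regulation` object.
#' @param stratum stratum of the bubble table to draw (default "all").
#' @param ... passed to [graphics::symbols()].
#' @export
plot.px_regulation <- function(x, stratum = "all", ...) {
  b <- x$bubble[x$bubble$stratum == stratum, , drop = FALSE]
  if (nrow(b) == 0L) stop(sprintf("no stratum '%s' in bubble table", stratum),
                          call. = FALSE)
  graphics::symbols(b$lsi, b$pss_capped, circles = sqrt(b$count),
                    inches = 0.15, xlab = "Lipid Specificity Index",
                    ylab = sprintf("PIP-Stop Score (capped at %d)",
                                   x$params$pss_cap),
                    main = sprintf("Specificity vs regulation (%s)", stratum),
                    ...)
  invisible(x)
}
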