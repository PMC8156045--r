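# Phosphoproteomic record aggregation and the PIP-Stop Score (PSS).
#
# Phosphosite records from multiple database exports are merged per
# (protein, position): citation identifier sets are unioned so that the
# same study counted by two databases contributes once. The PSS of a
# domain sums, over phosphosites falling in membrane-binding Sites 1-3,
# a citation-binned weight: 1 citation -> 1, 2-4 -> 2, >= 5 -> 3.

# parse one citations field: semicolon-separated identifiers, or a bare
# integer acting as an anonymous per-source count
.parse_citations <- function(x) {
  x <- trimws(ifelse(is.na(x), "", x))
  lapply(x, function(s) {
    if (!nzchar(s)) return(list(ids = character(), anon = 0L))
    if (grepl("^[0-9]+$", s)) return(list(ids = character(),
                                          anon = as.integer(s)))
    ids <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    list(ids = unique(ids[nzchar(ids)]), anon = 0L)
  })
}

#' Merge phosphosite records across sources
#'
#' Records sharing (protein_id, position) are collapsed into one.
#' Citation identifier sets are unioned (set semantics deduplicate the
#' same study reported by several databases); sources that report only a
#' citation count (a bare integer in the citations field) contribute the
#' maximum such count, added to the identifier-union size and flagged in
#' `has_anonymous`. Conflicting residue types at one position raise an
#' error.
#'
#' @param records data.frame with columns `protein_id`, `position`,
#'   `residue_type` (S/T/Y), `citations` (semicolon-separated identifiers
#'   or an integer count; may be empty) and optionally `source`.
#' @return data.frame with one row per (protein_id, position):
#'   `protein_id`, `position`, `residue_type`, `n_citations`, `citations`
#'   (sorted identifier string), `has_anonymous`, `n_sources`.
#' @export
merge_phosphosites <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("protein_id", "position", "residue_type")
  if (!all(need %in% names(records))) {
    stop("records need columns protein_id, position, residue_type",
         call. = FALSE)
  }
  if (!"citations" %in% names(records)) records$citations <- ""
  if (nrow(records) == 0L) {
    return(data.frame(protein_id = character(), position = integer(),
                      residue_type = character(), n_citations = integer(),
                      citations = character(), has_anonymous = logical(),
                      n_sources = integer(), stringsAsFactors = FALSE))
  }
  if (any(is.na(records$position)) || any(records$position < 1L)) {
    stop("phosphosite positions must be 1-based and non-missing",
         call. = FALSE)
  }
  if (!all(records$residue_type %in% c("S", "T", "Y"))) {
    stop("residue_type must be one of S, T, Y", call. = FALSE)
  }
  cit <- .parse_citations(records$citations)
  anon_all <- vapply(cit, `[[`, integer(1), "anon")
  ids_all <- lapply(cit, `[[`, "ids")
  key <- paste(records$protein_id, records$position, sep = "\r")
  groups <- split(seq_len(nrow(records)), key)
  first <- vapply(groups, `[`, integer(1), 1L)
  rt <- vapply(groups, function(idx) {
    u <- unique(records$residue_type[idx])
    if (length(u) > 1L) {
      stop(sprintf(
        "conflicting residue types (%s) at %s position %d",
        paste(sort(u), collapse = "/"), records$protein_id[idx[1]],
        records$position[idx[1]]), call. = FALSE)
    }
    u
  }, character(1))
  ids <- lapply(groups, function(idx) {
    sort(unique(unlist(ids_all[idx], use.names = FALSE)))
  })
  anon <- vapply(groups, function(idx) max(anon_all[idx]), integer(1))
  out <- data.frame(
    protein_id = records$protein_id[first],
    position = as.integer(records$position[first]),
    residue_type = rt,
    n_citations = lengths(ids) + anon,
    citations = vapply(ids, paste, character(1), collapse = ";"),
    has_anonymous = anon > 0L,
    n_sources = lengths(groups),
    stringsAsFactors = FALSE)
  out <- out[order(out$protein_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Citation-binned phosphosite weight
#'
#' The contribution of one phosphorylated residue to its domain's
#' PIP-Stop Score as a function of its number of supporting citations:
#' 0 citations contribute 0, a single cited study contributes 1, 2-4
#' citations contribute 2, and 5 or more contribute 3.
#'
#' @param n_citations non-negative integer vector.
#' @return integer vector of weights in 0..3.
#' @export
citation_weight <- function(n_citations) {
  if (!is.numeric(n_citations) || anyNA(n_citations) ||
      any(n_citations < 0) || any(n_citations != floor(n_citations))) {
    stop("n_citations must be non-negative integers", call. = FALSE)
  }
  n <- as.integer(n_citations)
  ifelse(n == 0L, 0L, ifelse(n == 1L, 1L, ifelse(n <= 4L, 2L, 3L)))
}

#' Compute the PIP-Stop Score of one domain
#'
#' Sums citation-binned weights over merged phosphosites whose position
#' falls inside membrane-binding Site 1, 2 or 3. Phosphosites outside all
#' Sites contribute nothing but are retained in the `excluded` element
#' for downstream enrichment analysis.
#'
#' @param records merged phosphosite records for one protein
#'   (see [merge_phosphosites()]).
#' @param intervals per-domain Site residue intervals: data.frame with
#'   columns `site`, `start`, `end` (half-open), e.g. from
#'   [map_windows_to_residues()].
#' @param domain_id optional identifier carried into the result.
#' @return list of class `"px_pss"`: `domain_id`, `pss_total`, `per_site`
#'   (named integer, sites 1-3), `per_residue_type` (named counts `pS`,
#'   `pT`, `pY` of distinct in-Site residues), `contributing`
#'   (data.frame: position, residue_type, site, n_citations, weight) and
#'   `excluded` (out-of-Site records).
#' @export
compute_pss <- function(records, intervals, domain_id = NA_character_) {
  stopifnot(is.data.frame(records))
  if (nrow(records) > 0L && length(unique(records$protein_id)) > 1L) {
    stop("compute_pss expects records for a single protein", call. = FALSE)
  }
  site <- if (nrow(records)) assign_sites(records$position, intervals)
          else integer()
  w <- if (nrow(records)) citation_weight(records$n_citations) else integer()
  inn <- !is.na(site)
  contributing <- data.frame(position = records$position[inn],
                             residue_type = records$residue_type[inn],
                             site = site[inn],
                             n_citations = records$n_citations[inn],
                             weight = w[inn], stringsAsFactors = FALSE)
  per_site <- vapply(1:3, function(s) {
    sum(contributing$weight[contributing$site == s])
  }, integer(1))
  names(per_site) <- paste0("site", 1:3)
  prt <- vapply(c(S = "S", T = "T", Y = "Y"), function(r) {
    sum(contributing$residue_type == r)
  }, integer(1))
  names(prt) <- c("pS", "pT", "pY")
  res <- list(domain_id = domain_id,
              pss_total = sum(per_site),
              per_site = per_site,
              per_residue_type = prt,
              contributing = contributing,
              excluded = records[!inn, , drop = FALSE])
  class(res) <- "px_pss"
  res
}

#' @export
print.px_pss <- function(x, ...) {
  id <- if (is.na(x$domain_id)) "" else paste0(" (", x$domain_id, ")")
  cat(sprintf("PSS%s: %d  [site1 %d, site2 %d, site3 %d; pS %d, pT %d, pY %d]\n",
              id, x$pss_total, x$per_site[1], x$per_site[2], x$per_site[3],
              x$per_residue_type[1], x$per_residue_type[2],
              x$per_residue_type[3]))
  invisible(x)
}

#' Partition in-Site phosphosites by residue type
#'
#' Counts distinct phosphorylated residues inside the membrane-binding
#' Sites by type (each residue counted once, regardless of citations).
#'
#' @inheritParams compute_pss
#' @return named integer vector `c(pS, pT, pY)`.
#' @export
residue_type_partition <- function(records, intervals) {
  compute_pss(records, intervals)$per_residue_type
}
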