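#' @title PIP ligand classification and the Lipid Specificity Index
#' @description Core scoring of phosphatidylinositol phosphate (PIP) ligand
#'   sets. The seven PIP species are denoted by the phosphate positions on
#'   the inositol ring ("3", "4", "5", "34", "35", "45", "345"). Ligands
#'   fall into two classes: MONO (one terminal phosphate) and POLY (more
#'   than one). A domain's Lipid Specificity Index (LSI) is 10 for a
#'   single-PIP binder, 0 for a domain with no membrane binding, and
#'   otherwise 10 minus 1 per additional ligand of the predominant class
#'   and minus 2 per out-of-class ligand.
#' @name pip-ligands
NULL

#' The seven admissible PIP ligand codes
#'
#' Phosphate-position codes, in canonical order: mono-phosphorylated
#' species first, then bis-, then tris-phosphorylated.
#' @export
PIP_CODES <- c("3", "4", "5", "34", "35", "45", "345")

# canonical ordering index for a vector of canonical codes
.pip_order <- function(codes) order(match(codes, PIP_CODES))

#' Classify PIP ligand codes
#'
#' Validates and canonicalizes phosphate-position codes and derives the
#' phosphate count and mono/poly class. Codes are canonicalized to
#' ascending digit order ("43" becomes "34"); anything that does not
#' canonicalize to one of the seven admissible codes is rejected.
#'
#' @param code character vector of ligand codes.
#' @return A data.frame with columns `code` (canonical), `phosphate_count`
#'   and `ligand_class` ("MONO" for one phosphate, "POLY" otherwise).
#' @examples
#' classify_pip(c("3", "345", "43"))
#' @export
classify_pip <- function(code) {
  if (!is.character(code)) {
    stop("ligand codes must be supplied as a character vector", call. = FALSE)
  }
  if (length(code) == 0L) {
    return(data.frame(code = character(), phosphate_count = integer(),
                      ligand_class = character(), stringsAsFactors = FALSE))
  }
  if (anyNA(code) || any(!nzchar(code))) {
    stop("empty or missing ligand code", call. = FALSE)
  }
  canon <- vapply(strsplit(code, ""), function(ch) {
    paste(sort(ch), collapse = "")
  }, character(1))
  bad <- !(canon %in% PIP_CODES)
  if (any(bad)) {
    stop(sprintf("invalid PIP ligand code(s): %s (admissible: %s)",
                 paste(unique(code[bad]), collapse = ", "),
                 paste(PIP_CODES, collapse = ", ")), call. = FALSE)
  }
  n <- nchar(canon)
  data.frame(code = canon,
             phosphate_count = as.integer(n),
             ligand_class = ifelse(n == 1L, "MONO", "POLY"),
             stringsAsFactors = FALSE)
}

#' Predominant ligand class of a PIP ligand set
#'
#' The class (MONO or POLY) holding the majority of the set's members;
#' ties resolve to POLY. An empty set has class "NONE". This is the
#' predominance rule under which the published panel's specificity scores
#' are all reproduced.
#'
#' @param ligands character vector of PIP codes (a set; duplicates are
#'   collapsed after canonicalization).
#' @return "MONO", "POLY" or "NONE".
#' @examples
#' predominant_class(c("4", "5", "35"))   # MONO majority
#' predominant_class(c("3", "5", "35", "45")) # tie -> POLY
#' @export
predominant_class <- function(ligands) {
  if (length(ligands) == 0L) return("NONE")
  cls <- classify_pip(unique(classify_pip(ligands)$code))$ligand_class
  n_mono <- sum(cls == "MONO")
  n_poly <- sum(cls == "POLY")
  if (n_mono > n_poly) "MONO" else "POLY"
}

#' Compute the Lipid Specificity Index for one domain
#'
#' A single-ligand binder scores 10; a domain with no discernible membrane
#' binding scores 0; a domain whose specificity is undetermined scores
#' `NA`. Otherwise the score is 10 minus 1 for each additional ligand of
#' the predominant class (all in-class ligands beyond the one defining
#' representative) and minus 2 for each out-of-class ligand. Scores for
#' non-empty ligand sets always land in 1..10; a value outside that range
#' signals an internal inconsistency and raises an error rather than
#' being clamped.
#'
#' @param ligands character vector of PIP codes; empty for a non-binding
#'   domain.
#' @param binds_membrane logical; must be `TRUE` whenever `ligands` is
#'   non-empty. Defaults to `length(ligands) > 0`.
#' @param determined logical; `FALSE` for domains whose specificity is not
#'   determined ("nd" panel entries), which yield `lsi = NA`.
#' @param domain_id optional identifier carried into the result.
#' @return A list of class `"px_lsi"` with elements `domain_id`, `lsi`
#'   (integer, `NA` when undetermined), `predominant_class`,
#'   `in_class_demerit` and `out_class_demerit`.
#' @examples
#' compute_lsi("3")$lsi                          # 10
#' compute_lsi(c("3", "34", "45", "345"))$lsi    # 6
#' compute_lsi(character(), binds_membrane = FALSE)$lsi  # 0
#' @export
compute_lsi <- function(ligands, binds_membrane = length(ligands) > 0L,
                        determined = TRUE, domain_id = NA_character_) {
  stopifnot(is.logical(binds_membrane), length(binds_membrane) == 1L,
            is.logical(determined), length(determined) == 1L)
  res <- list(domain_id = domain_id, lsi = NA_integer_,
              predominant_class = NA_character_,
              in_class_demerit = NA_integer_,
              out_class_demerit = NA_integer_)
  class(res) <- "px_lsi"
  if (!determined) {
    if (length(ligands) > 0L) {
      stop("an undetermined profile cannot carry ligands", call. = FALSE)
    }
    return(res)
  }
  if (length(ligands) == 0L) {
    if (isTRUE(binds_membrane)) {
      stop(sprintf(
        "inconsistent profile%s: membrane binding annotated but no ligands",
        if (is.na(domain_id)) "" else paste0(" for ", domain_id)),
        call. = FALSE)
    }
    res$lsi <- 0L
    res$predominant_class <- "NONE"
    res$in_class_demerit <- 0L
    res$out_class_demerit <- 0L
    return(res)
  }
  if (!isTRUE(binds_membrane)) {
    stop("profile with ligands must have binds_membrane = TRUE", call. = FALSE)
  }
  lig <- classify_pip(ligands)
  lig <- lig[!duplicated(lig$code), , drop = FALSE]
  pc <- predominant_class(lig$code)
  n_in <- sum(lig$ligand_class == pc)
  n_out <- nrow(lig) - n_in
  in_dem <- n_in - 1L
  out_dem <- 2L * n_out
  lsi <- 10L - in_dem - out_dem
  if (lsi < 1L || lsi > 10L) {
    stop(sprintf("internal inconsistency: LSI %d outside 1..10 for {%s}",
                 lsi, paste(lig$code, collapse = ",")), call. = FALSE)
  }
  res$lsi <- lsi
  res$predominant_class <- pc
  res$in_class_demerit <- in_dem
  res$out_class_demerit <- out_dem
  res
}

#' @export
print.px_lsi <- function(x, ...) {
  id <- if (is.na(x$domain_id)) "" else paste0(" (", x$domain_id, ")")
  if (is.na(x$lsi)) {
    cat(sprintf("LSI%s: undetermined\n", id))
  } else {
    cat(sprintf("LSI%s: %d [class %s, demerits in %d / out %d]\n",
                id, x$lsi, x$predominant_class,
                x$in_class_demerit, x$out_class_demerit))
  }
  invisible(x)
}

#' Score a panel of ligand profiles
#'
#' Applies [compute_lsi()] to every row of a domain panel, preserving
#' input order, and reports summary counts (domains at LSI 10, at 0, and
#' undetermined) as a message.
#'
#' @param panel data.frame with columns `domain_id`, `ligands`
#'   (comma-separated PIP codes, `""` for a non-binder, `NA` for
#'   undetermined) and optionally `binds_membrane` / `determined` logicals
#'   (derived from `ligands` and `mai` when absent, as by [read_panel()]).
#' @param quiet suppress the summary message.
#' @return data.frame: `domain_id`, `lsi`, `predominant_class`,
#'   `in_class_demerit`, `out_class_demerit`.
#' @seealso [read_panel()], [px_table1()]
#' @export
score_panel <- function(panel, quiet = FALSE) {
  stopifnot(is.data.frame(panel))
  if (!all(c("domain_id", "ligands") %in% names(panel))) {
    stop("panel must have columns 'domain_id' and 'ligands'", call. = FALSE)
  }
  if (anyDuplicated(panel$domain_id)) {
    stop(sprintf("duplicate domain_id in panel: %s",
                 paste(unique(panel$domain_id[duplicated(panel$domain_id)]),
                       collapse = ", ")), call. = FALSE)
  }
  if (nrow(panel) == 0L) {
    return(data.frame(domain_id = character(), lsi = integer(),
                      predominant_class = character(),
                      in_class_demerit = integer(),
                      out_class_demerit = integer(),
                      stringsAsFactors = FALSE))
  }
  determined <- if ("determined" %in% names(panel)) panel$determined
                else !is.na(panel$ligands) & panel$ligands != "nd"
  has_lig <- determined & nzchar(ifelse(is.na(panel$ligands), "", panel$ligands)) &
    panel$ligands != "nd"
  binds <- if ("binds_membrane" %in% names(panel)) panel$binds_membrane else has_lig
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    ligs <- if (has_lig[i]) strsplit(panel$ligands[i], ",", fixed = TRUE)[[1]]
            else character()
    r <- tryCatch(
      compute_lsi(trimws(ligs), binds_membrane = binds[i],
                  determined = determined[i],
                  domain_id = panel$domain_id[i]),
      error = function(e) stop(sprintf("panel row %d (%s): %s", i,
                                       panel$domain_id[i], conditionMessage(e)),
                               call. = FALSE))
    data.frame(domain_id = r$domain_id, lsi = r$lsi,
               predominant_class = r$predominant_class,
               in_class_demerit = r$in_class_demerit,
               out_class_demerit = r$out_class_demerit,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!quiet) {
    message(sprintf(
      "scored %d domains: %d at LSI 10, %d at LSI 0, %d undetermined",
      nrow(out), sum(out$lsi == 10L, na.rm = TRUE),
      sum(out$lsi == 0L, na.rm = TRUE), sum(is.na(out$lsi))))
  }
  out
}
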