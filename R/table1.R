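#' The packaged human and yeast PX domain panel
#'
#' A transcription of the published panel of PX domain properties: PIP
#' ligand sets (phosphate-position codes), membrane affinity annotation
#' (MAI) and, as annotation columns, the published LSI and PSS values
#' (`lsi_printed`, `pss_printed`; the published PSS depends on database
#' snapshots and is carried for reference only, not recomputed).
#' Superscripted and Greek protein names are normalised to ASCII
#' (p40phox, p47phox, NOXO1B/NOXO1G, PIK3C2A/B/G). The yeast section
#' carries no published MAI and is annotated "nd".
#'
#' @param organism "human" (50 domains, 49 determined), "yeast"
#'   (15 domains) or "both".
#' @return panel data.frame as from [read_panel()].
#' @examples
#' panel <- px_table1("human")
#' nrow(panel)
#' @export
px_table1 <- function(organism = c("both", "human", "yeast")) {
  organism <- match.arg(organism)
  paths <- c(human = system.file("extdata", "table1_human.tsv",
                                 package = "pxreg"),
             yeast = system.file("extdata", "table1_yeast.tsv",
                                 package = "pxreg"))
  want <- if (organism == "both") c("human", "yeast") else organism
  do.call(rbind, lapply(unname(paths[want]), read_panel))
}

#' Rescore the packaged panel and compare with the published LSI values
#'
#' Runs [score_panel()] on the packaged human and yeast panels and
#' compares every determined LSI with the transcribed published value.
#'
#' @param organism passed to [px_table1()].
#' @return list of class `"px_table1_check"`: `n_match`, `n_total`
#'   (determined domains), `mismatches` (data.frame, empty on success)
#'   and the scored `table`.
#' @export
reproduce_table1 <- function(organism = "both") {
  panel <- px_table1(organism)
  scored <- score_panel(panel, quiet = TRUE)
  printed <- suppressWarnings(as.integer(panel$lsi_printed))
  det <- !is.na(printed)
  match_ok <- det & !is.na(scored$lsi) & scored$lsi == printed
  mism <- data.frame(domain_id = panel$domain_id,
                     ligands = panel$ligands,
                     lsi_printed = printed,
                     lsi_computed = scored$lsi,
                     stringsAsFactors = FALSE)[det & !match_ok, , drop = FALSE]
  rownames(mism) <- NULL
  res <- list(n_match = sum(match_ok), n_total = sum(det),
              mismatches = mism,
              table = cbind(scored, lsi_printed = printed))
  class(res) <- "px_table1_check"
  res
}

#' @export
print.px_table1_check <- function(x, ...) {
  cat(sprintf("%d/%d published LSI values reproduced\n",
              x$n_match, x$n_total))
  if (nrow(x$mismatches)) {
    cat("mismatches:\n")
    print(x$mismatches)
  }
  invisible(x)
}
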