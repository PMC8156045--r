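# Readers and writers for the package's file dialects.
#
# Panel TSV:       domain_id, ligands (comma-separated codes; "" = no
#                  binding; "nd" = undetermined), mai (S|W|N|nd),
#                  optional organism and annotation columns.
# Phosphosite TSV: protein_id, position, residue_type, citations
#                  (semicolon-separated identifiers or integer count),
#                  source.
# Score CSV:       domain_id, position (1-based), score.
# Alignment:       gapped FASTA, "-" gaps.
# Site windows:    JSON with three [start, end) column pairs and
#                  optional per-domain offsets.

.read_table_checked <- function(path, required, sep, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  if (file.size(path) == 0L) {
    warning(sprintf("empty %s file: %s", what, path), call. = FALSE)
    return(NULL)
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "",
                          comment.char = "", check.names = TRUE,
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s file %s lacks required column(s): %s", what, path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read a domain panel TSV
#'
#' Parses and validates ligand profiles. Ligand codes are canonicalized;
#' "nd" marks an undetermined profile; an empty ligand field with MAI
#' "N" marks a non-binder. Errors carry the offending data row number.
#'
#' @param path panel TSV path.
#' @return data.frame: `domain_id`, `ligands` (canonical comma string,
#'   `""` for non-binders, `NA` for undetermined), `mai`, `organism`
#'   (`NA` when absent), `determined`, `binds_membrane`, plus any
#'   annotation columns present (e.g. `lsi_printed`, `pss_printed`).
#' @export
read_panel <- function(path) {
  df <- .read_table_checked(path, c("domain_id", "ligands", "mai"),
                            sep = "\t", what = "panel")
  if (is.null(df)) {
    return(data.frame(domain_id = character(), ligands = character(),
                      mai = character(), organism = character(),
                      determined = logical(), binds_membrane = logical(),
                      stringsAsFactors = FALSE))
  }
  dup <- duplicated(df$domain_id)
  if (any(dup)) {
    stop(sprintf("row %d: duplicate domain_id '%s'", which(dup)[1],
                 df$domain_id[which(dup)[1]]), call. = FALSE)
  }
  bad_mai <- !(df$mai %in% c("S", "W", "N", "nd"))
  if (any(bad_mai)) {
    stop(sprintf("row %d: invalid MAI '%s' (expected S, W, N or nd)",
                 which(bad_mai)[1], df$mai[which(bad_mai)[1]]),
         call. = FALSE)
  }
  lig <- trimws(df$ligands)
  determined <- lig != "nd"
  ligands <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!determined[i]) { ligands[i] <- NA_character_; next }
    if (!nzchar(lig[i])) {
      if (df$mai[i] != "N") {
        stop(sprintf(
          "row %d (%s): empty ligand set but MAI '%s' (expected N)",
          i, df$domain_id[i], df$mai[i]), call. = FALSE)
      }
      ligands[i] <- ""
      next
    }
    codes <- trimws(strsplit(lig[i], ",", fixed = TRUE)[[1]])
    parsed <- tryCatch(classify_pip(codes), error = function(e) {
      stop(sprintf("row %d (%s): %s", i, df$domain_id[i],
                   conditionMessage(e)), call. = FALSE)
    })
    codes <- unique(parsed$code)
    ligands[i] <- paste(codes[.pip_order(codes)], collapse = ",")
  }
  out <- data.frame(domain_id = df$domain_id, ligands = ligands,
                    mai = df$mai,
                    organism = if ("organism" %in% names(df)) df$organism
                               else NA_character_,
                    determined = determined,
                    binds_membrane = determined & nzchar(ifelse(
                      is.na(ligands), "", ligands)),
                    stringsAsFactors = FALSE)
  extra <- setdiff(names(df), c(names(out), "ligands"))
  for (col in extra) out[[col]] <- df[[col]]
  out
}

#' Write a domain panel TSV
#' @param panel panel data.frame (as from [read_panel()] or
#'   [simulate_panel()]).
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  keep <- intersect(c("domain_id", "ligands", "mai", "organism",
                      "lsi_printed", "pss_printed"), names(panel))
  utils::write.table(panel[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phosphosite TSV
#'
#' Validates positions and residue types; rows with residue types other
#' than S/T/Y are rejected with a warning naming their rows.
#'
#' @param path phosphosite TSV path.
#' @return data.frame: `protein_id`, `position` (integer),
#'   `residue_type`, `citations` (string), `source`.
#' @export
read_phosphosites <- function(path) {
  df <- .read_table_checked(path, c("protein_id", "position", "residue_type"),
                            sep = "\t", what = "phosphosite")
  empty <- data.frame(protein_id = character(), position = integer(),
                      residue_type = character(), citations = character(),
                      source = character(), stringsAsFactors = FALSE)
  if (is.null(df) || nrow(df) == 0L) return(empty)
  pos <- suppressWarnings(as.integer(df$position))
  bad <- is.na(pos) | pos < 1L
  if (any(bad)) {
    stop(sprintf("row %d: invalid position '%s'", which(bad)[1],
                 df$position[which(bad)[1]]), call. = FALSE)
  }
  drop <- !(df$residue_type %in% c("S", "T", "Y"))
  if (any(drop)) {
    warning(sprintf(
      "dropping %d record(s) with non-S/T/Y residue type (row(s) %s)",
      sum(drop), paste(which(drop), collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(protein_id = df$protein_id, position = pos,
                    residue_type = df$residue_type,
                    citations = if ("citations" %in% names(df)) df$citations
                                else "",
                    source = if ("source" %in% names(df)) df$source
                             else NA_character_,
                    stringsAsFactors = FALSE)[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a phosphosite TSV
#' @param records phosphosite record data.frame.
#' @param path output path.
#' @export
write_phosphosites <- function(records, path) {
  keep <- intersect(c("protein_id", "position", "residue_type",
                      "citations", "source"), names(records))
  utils::write.table(records[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-residue docking score profiles from CSV
#'
#' @param path CSV with columns `domain_id`, `position` (1-based,
#'   contiguous per domain), `score` (non-negative).
#' @return named list of profiles, each
#'   `list(domain_id, offset, scores)` where `offset` is the
#'   full-protein position of the first profiled residue.
#' @export
read_scores <- function(path) {
  df <- .read_table_checked(path, c("domain_id", "position", "score"),
                            sep = ",", what = "score")
  if (is.null(df) || nrow(df) == 0L) return(structure(list(), names = character()))
  pos <- suppressWarnings(as.integer(df$position))
  sc <- suppressWarnings(as.numeric(df$score))
  bad <- is.na(pos) | pos < 1L | is.na(sc) | sc < 0
  if (any(bad)) {
    stop(sprintf("row %d: invalid position/score ('%s', '%s')",
                 which(bad)[1], df$position[which(bad)[1]],
                 df$score[which(bad)[1]]), call. = FALSE)
  }
  out <- lapply(split(seq_len(nrow(df)), df$domain_id), function(idx) {
    p <- pos[idx]; s <- sc[idx]
    o <- order(p); p <- p[o]; s <- s[o]
    if (any(diff(p) != 1L)) {
      stop(sprintf("non-contiguous positions for domain %s",
                   df$domain_id[idx[1]]), call. = FALSE)
    }
    list(domain_id = df$domain_id[idx[1]], offset = p[1], scores = s)
  })
  out[unique(df$domain_id)]
}

#' Write docking score profiles to CSV
#' @param profiles named list of profiles (see [read_scores()]).
#' @param path output path.
#' @export
write_scores <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    data.frame(domain_id = p$domain_id,
               position = seq_along(p$scores) + p$offset - 1L,
               score = format(p$scores, trim = TRUE, scientific = FALSE),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gapped FASTA alignment
#'
#' @param path FASTA path ("-" gap characters).
#' @return named character vector of equal-length gapped sequences.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("alignment file not found: %s", path), call. = FALSE)
  }
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    warning(sprintf("empty alignment file: %s", path), call. = FALSE)
    return(structure(character(), names = character()))
  }
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  if (length(unique(nchar(out))) != 1L) {
    stop("alignment sequences have unequal (ragged) lengths", call. = FALSE)
  }
  out
}

#' Read a Site-window configuration JSON
#'
#' Expected schema: `{"sites": [{"site": 1, "start": ..., "end": ...},
#' ...], "offsets": {"DOMAIN": <int>, ...}}` with half-open
#' `[start, end)` intervals; `offsets` is optional.
#'
#' @param path JSON path.
#' @return list with `windows` (a [site_windows()] data.frame) and
#'   `offsets` (named integer vector, possibly empty).
#' @export
read_site_windows <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  if (is.null(cfg$sites)) stop("windows JSON lacks 'sites'", call. = FALSE)
  s <- cfg$sites[order(cfg$sites$site), , drop = FALSE]
  w <- site_windows(s$start, s$end)
  offs <- integer()
  if (!is.null(cfg$offsets)) {
    offs <- vapply(cfg$offsets, as.integer, integer(1))
  }
  list(windows = w, offsets = offs)
}

#' Write a Site-window configuration JSON
#' @param windows a [site_windows()] data.frame.
#' @param path output path.
#' @param offsets optional named integer vector of per-domain offsets.
#' @export
write_site_windows <- function(windows, path, offsets = NULL) {
  obj <- list(sites = windows)
  if (!is.null(offsets)) obj$offsets <- as.list(offsets)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a PIP-Stop Score result
#'
#' @param x a `px_pss` object from [compute_pss()].
#' @param path output path; format chosen by extension (`.json` or
#'   `.tsv`).
#' @export
write_pss <- function(x, path) {
  stopifnot(inherits(x, "px_pss"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(domain_id = x$domain_id, pss_total = x$pss_total,
           per_site = as.list(x$per_site),
           per_residue_type = as.list(x$per_residue_type),
           contributing = x$contributing),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::write.table(
      cbind(domain_id = x$domain_id, x$contributing,
            pss_total = x$pss_total),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
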