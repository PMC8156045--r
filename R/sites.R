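# Membrane-docking site calling and alignment-window mapping.
#
# Per-residue membrane-docking propensity scores (MODA-style) arrive as
# ordered profiles. Residues scoring strictly above a threshold (default 30)
# are membrane-interactive; several such residues in close proximity mark a
# probable membrane interaction site. The three consensus membrane-binding
# elements of PX domains (Site 1: beta1-beta2 insertion loop; Site 2:
# beta3-alpha1 near the conserved YS motif; Site 3: proline-rich element to
# alpha2) are defined as alignment-column windows and resolved per domain
# to residue intervals. All residue positions are 1-based full-protein
# coordinates; intervals are half-open [start, end).

#' Flag membrane-interactive residues in a docking score profile
#'
#' A residue is flagged when its score strictly exceeds the threshold
#' (a score of exactly 30 is not flagged).
#'
#' @param scores numeric vector of non-negative per-residue docking scores,
#'   or a profile list with a `scores` element as returned by
#'   [read_scores()].
#' @param threshold positive score cutoff (default 30).
#' @return logical vector, one flag per residue.
#' @export
flag_membrane_residues <- function(scores, threshold = 30) {
  if (is.list(scores) && !is.null(scores$scores)) scores <- scores$scores
  stopifnot(is.numeric(scores), length(scores) >= 1L,
            is.numeric(threshold), length(threshold) == 1L)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  if (anyNA(scores) || any(scores < 0)) {
    stop("docking scores must be non-negative and non-missing", call. = FALSE)
  }
  scores > threshold
}

#' Find proximal clusters of flagged residues
#'
#' A membrane interaction site is called where at least `min_size` flagged
#' residues co-occur within any span of `window` consecutive residues.
#' Overlapping qualifying spans are merged; each maximal cluster is
#' reported from its first to its last flagged residue.
#'
#' @param flags logical vector from [flag_membrane_residues()].
#' @param min_size minimum number of flagged residues per window (>= 1).
#' @param window span length in residues (>= `min_size`); spans longer
#'   than the profile are truncated to its length.
#' @return data.frame with columns `start`, `end` (1-based, inclusive,
#'   profile coordinates) and `n_flagged`.
#' @export
find_proximal_clusters <- function(flags, min_size = 3L, window = 7L) {
  stopifnot(is.logical(flags), length(flags) >= 1L)
  min_size <- as.integer(min_size); window <- as.integer(window)
  if (min_size < 1L) stop("min_size must be >= 1", call. = FALSE)
  if (window < min_size) stop("window must be >= min_size", call. = FALSE)
  n <- length(flags)
  w <- min(window, n)
  empty <- data.frame(start = integer(), end = integer(),
                      n_flagged = integer())
  if (sum(flags) < min_size) return(empty)
  # windowed flag counts via cumulative sums
  cs <- c(0L, cumsum(flags))
  starts <- seq_len(n - w + 1L)
  cnt <- cs[starts + w] - cs[starts]
  qual <- starts[cnt >= min_size]
  if (length(qual) == 0L) return(empty)
  covered <- logical(n)
  for (s in qual) covered[s:(s + w - 1L)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- lapply(keep, function(k) {
    fl <- which(flags[begs[k]:ends[k]]) + begs[k] - 1L
    data.frame(start = min(fl), end = max(fl), n_flagged = length(fl))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Construct and validate the three consensus Site windows
#'
#' @param start,end integer vectors of length 3: half-open
#'   `[start, end)` intervals for Sites 1, 2 and 3, in ascending,
#'   non-overlapping order (1-based alignment columns, or residue
#'   coordinates when used directly on profiles).
#' @return data.frame with columns `site` (1:3), `start`, `end`.
#' @export
site_windows <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == 3L, length(end) == 3L)
  if (any(is.na(start)) || any(is.na(end))) {
    stop("site windows must be complete", call. = FALSE)
  }
  if (any(end <= start)) stop("site windows must be non-empty", call. = FALSE)
  if (any(start[-1L] < end[-3L])) {
    stop("site windows must be non-overlapping and ascending", call. = FALSE)
  }
  data.frame(site = 1:3, start = start, end = end)
}

#' Map alignment-column Site windows to per-domain residue intervals
#'
#' Converts each half-open window of 1-based alignment columns to the
#' half-open interval of ungapped residue positions (full-protein
#' coordinates) that the domain occupies there. A window in which the
#' domain is entirely gapped yields an empty interval (`NA` bounds) with
#' a warning.
#'
#' @param alignment named character vector of equal-length gapped
#'   sequences ("-" gaps), as from [read_alignment()].
#' @param domain_id name of the sequence to map.
#' @param windows data.frame from [site_windows()] (alignment columns).
#' @param offset 1-based full-protein position of the domain's first
#'   aligned residue.
#' @return data.frame with columns `site`, `start`, `end` — half-open
#'   residue intervals; `NA` start/end for an all-gap window.
#' @export
map_windows_to_residues <- function(alignment, domain_id, windows,
                                    offset = 1L) {
  stopifnot(is.character(alignment), !is.null(names(alignment)))
  if (!domain_id %in% names(alignment)) {
    stop(sprintf("domain '%s' not present in alignment", domain_id),
         call. = FALSE)
  }
  width <- unique(nchar(alignment))
  if (length(width) != 1L) {
    stop("alignment sequences have unequal lengths", call. = FALSE)
  }
  if (any(windows$end > width + 1L) || any(windows$start < 1L)) {
    stop("site window exceeds alignment width", call. = FALSE)
  }
  offset <- as.integer(offset)
  stopifnot(length(offset) == 1L, !is.na(offset), offset >= 1L)
  ch <- strsplit(alignment[[domain_id]], "")[[1]]
  is_res <- ch != "-"
  resno <- cumsum(is_res) + offset - 1L  # full-protein position per column
  out <- lapply(seq_len(nrow(windows)), function(i) {
    cols <- windows$start[i]:(windows$end[i] - 1L)
    occ <- cols[is_res[cols]]
    if (length(occ) == 0L) {
      warning(sprintf("site %d window is entirely gapped for %s",
                      windows$site[i], domain_id), call. = FALSE)
      return(data.frame(site = windows$site[i],
                        start = NA_integer_, end = NA_integer_))
    }
    data.frame(site = windows$site[i],
               start = min(resno[occ]), end = max(resno[occ]) + 1L)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map residue positions back to alignment columns
#'
#' Inverse of the column-to-residue direction of
#' [map_windows_to_residues()], used for round-trip checks: returns the
#' alignment column occupied by each (ungapped) residue position.
#'
#' @inheritParams map_windows_to_residues
#' @param positions 1-based full-protein residue positions.
#' @return integer vector of alignment columns (`NA` for positions the
#'   domain does not occupy).
#' @export
map_residues_to_columns <- function(alignment, domain_id, positions,
                                    offset = 1L) {
  stopifnot(domain_id %in% names(alignment))
  ch <- strsplit(alignment[[domain_id]], "")[[1]]
  occ_cols <- which(ch != "-")
  resno <- seq_along(occ_cols) + as.integer(offset) - 1L
  occ_cols[match(positions, resno)]
}

#' Assign membrane-binding Site labels to residue positions
#'
#' @param positions integer vector of 1-based full-protein positions.
#' @param intervals data.frame with columns `site`, `start`, `end`
#'   (half-open residue intervals, e.g. from
#'   [map_windows_to_residues()]); rows with `NA` bounds are skipped.
#' @return integer vector of site labels (1, 2 or 3), `NA` where the
#'   position lies in no Site.
#' @export
assign_sites <- function(positions, intervals) {
  stopifnot(is.numeric(positions),
            all(c("site", "start", "end") %in% names(intervals)))
  lab <- rep(NA_integer_, length(positions))
  for (i in seq_len(nrow(intervals))) {
    if (is.na(intervals$start[i]) || is.na(intervals$end[i])) next
    hit <- positions >= intervals$start[i] & positions < intervals$end[i]
    lab[hit] <- as.integer(intervals$site[i])
  }
  lab
}
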