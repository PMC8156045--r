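# Independent oracles and small fixture builders, deliberately written as
# naive enumerations so they share no code path with the package.

# brute-force LSI: evaluate the demerit formula under both candidate
# predominant classes and select by the majority/tie-to-POLY rule
oracle_lsi <- function(codes) {
  if (length(codes) == 0L) return(0L)
  cls <- ifelse(nchar(codes) == 1L, "MONO", "POLY")
  demerit_score <- function(pc) {
    n_in <- sum(cls == pc)
    n_out <- length(codes) - n_in
    10L - (n_in - 1L) - 2L * n_out
  }
  both <- c(MONO = demerit_score("MONO"), POLY = demerit_score("POLY"))
  pick <- if (sum(cls == "MONO") > sum(cls == "POLY")) "MONO" else "POLY"
  both[[pick]]
}

# all 127 non-empty subsets of the seven PIP codes
all_pip_subsets <- function() {
  codes <- c("3", "4", "5", "34", "35", "45", "345")
  subsets <- list()
  for (m in 1:127) {
    subsets[[m]] <- codes[as.logical(bitwAnd(m, 2^(0:6)) > 0)]
  }
  subsets
}

# exhaustive window scan for proximal clusters: mark every position lying
# in some window of `window` consecutive positions that holds >= min_size
# flags, then read off runs
oracle_clusters <- function(flags, min_size = 3L, window = 7L) {
  n <- length(flags)
  w <- min(window, n)
  member <- rep(FALSE, n)
  for (s in seq_len(n - w + 1L)) {
    span <- s:(s + w - 1L)
    if (sum(flags[span]) >= min_size) member[span] <- TRUE
  }
  out <- data.frame(start = integer(), end = integer(), n_flagged = integer())
  in_run <- FALSE
  run_start <- NA_integer_
  for (i in seq_len(n + 1L)) {
    inside <- i <= n && member[i]
    if (inside && !in_run) { in_run <- TRUE; run_start <- i }
    if (!inside && in_run) {
      in_run <- FALSE
      fl <- which(flags[run_start:(i - 1L)]) + run_start - 1L
      out <- rbind(out, data.frame(start = min(fl), end = max(fl),
                                   n_flagged = length(fl)))
    }
  }
  rownames(out) <- NULL
  out
}

# build a phosphosite record data.frame from parallel vectors
make_records <- function(protein_id, position, residue_type = "S",
                         citations = "", source = "test") {
  data.frame(protein_id = protein_id, position = position,
             residue_type = residue_type, citations = citations,
             source = source, stringsAsFactors = FALSE)
}

default_intervals <- function() site_windows(c(20L, 55L, 75L),
                                             c(28L, 63L, 90L))

# random merged-record table for property tests (already merged shape)
random_merged <- function(n, max_pos = 120L) {
  pos <- sample.int(max_pos, n)
  data.frame(protein_id = rep("P1", n), position = pos,
             residue_type = sample(c("S", "T", "Y"), n, replace = TRUE),
             n_citations = stats::rpois(n, 2),
             citations = "", has_anonymous = FALSE, n_sources = 1L,
             stringsAsFactors = FALSE)
}
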