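test_that("membrane residue flagging uses a strict threshold", {
  expect_equal(which(flag_membrane_residues(c(0, 10, 35, 40, 5))), c(3L, 4L))
  expect_false(flag_membrane_residues(30.0))   # exactly at threshold
  expect_true(flag_membrane_residues(30.0001))
  expect_equal(sum(flag_membrane_residues(rep(0, 50))), 0L)
  expect_error(flag_membrane_residues(c(1, -2, 3)), "non-negative")
  expect_error(flag_membrane_residues(c(1, 2), threshold = 0), "positive")
})

test_that("flag count is monotone non-increasing in the threshold", {
  set.seed(11)
  scores <- runif(200, 0, 60)
  counts <- vapply(seq(5, 55, by = 5),
                   function(t) sum(flag_membrane_residues(scores, t)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("proximal cluster calling matches hand-worked cases", {
  fl <- function(pos, n = 25) { f <- rep(FALSE, n); f[pos] <- TRUE; f }
  expect_equal(find_proximal_clusters(fl(3:5)),
               data.frame(start = 3L, end = 5L, n_flagged = 3L))
  expect_equal(nrow(find_proximal_clusters(fl(c(3, 20)))), 0L)
  # flags at 10,12,15,16: any 7-window covering them holds >= 3
  expect_equal(find_proximal_clusters(fl(c(10, 12, 15, 16))),
               data.frame(start = 10L, end = 16L, n_flagged = 4L))
  # profile shorter than the window
  expect_equal(find_proximal_clusters(fl(1:3, n = 5)),
               data.frame(start = 1L, end = 3L, n_flagged = 3L))
  expect_error(find_proximal_clusters(fl(1:3), min_size = 0), "min_size")
  expect_error(find_proximal_clusters(fl(1:3), min_size = 3, window = 2),
               "window")
})

test_that("cluster calling agrees with the exhaustive window-scan oracle", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(8:60, 1)
    flags <- runif(n) < runif(1, 0.05, 0.5)
    ms <- sample(2:4, 1)
    w <- sample(ms:9, 1)
    expect_equal(find_proximal_clusters(flags, ms, w),
                 oracle_clusters(flags, ms, w),
                 info = sprintf("case %d (n=%d ms=%d w=%d)", i, n, ms, w))
  }
})

test_that("alignment windows map to residue intervals with gaps skipped", {
  aln <- c(A = "AB-CD", B = "-BCD-", C = "-----")
  w <- site_windows(c(1L, 2L, 4L), c(2L, 4L, 6L))
  # domain A: cols [2,4) are B,- -> residue 2 only; cols [4,6) are C,D
  mapped <- map_windows_to_residues(aln, "A", w)
  expect_equal(mapped$start, c(1L, 2L, 3L))
  expect_equal(mapped$end, c(2L, 3L, 5L))
  # offsets shift to full-protein coordinates
  shifted <- map_windows_to_residues(aln, "A", w, offset = 101L)
  expect_equal(shifted$start, c(101L, 102L, 103L))
  # domain B is gapped at column 1: site-1 window is empty
  expect_warning(mb <- map_windows_to_residues(aln, "B", w), "gapped")
  expect_true(is.na(mb$start[1]))
  expect_equal(mb$start[2], 1L)
  expect_equal(mb$end[2], 3L)
  expect_error(map_windows_to_residues(aln, "Z", w), "not present")
  expect_error(
    map_windows_to_residues(aln, "A", site_windows(c(1L, 3L, 5L),
                                                   c(2L, 4L, 8L))),
    "width")
})

test_that("staggered three-sequence alignment matches hand enumeration", {
  aln <- c(s1 = "MK--TLV-GA",
           s2 = "-KAVTL--GA",
           s3 = "MKA-----GA")
  w <- site_windows(c(1L, 5L, 9L), c(4L, 8L, 11L))
  m1 <- map_windows_to_residues(aln, "s1", w)
  expect_equal(m1$start, c(1L, 3L, 6L)); expect_equal(m1$end, c(3L, 6L, 8L))
  m2 <- map_windows_to_residues(aln, "s2", w)
  expect_equal(m2$start, c(1L, 4L, 6L)); expect_equal(m2$end, c(3L, 6L, 8L))
  m3 <- suppressWarnings(map_windows_to_residues(aln, "s3", w))
  expect_equal(m3$start, c(1L, NA, 4L))
  expect_equal(m3$end, c(4L, NA, 6L))
})

test_that("column->residue->column round-trips for gap-free sequences", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    seqs <- c(X = paste(sample(LETTERS[1:20], n, TRUE), collapse = ""))
    cols <- sort(sample(2:(n - 1), 2))
    w <- site_windows(c(1L, cols[1], cols[2]), c(cols[1], cols[2], n + 1L))
    off <- sample.int(500, 1)
    mapped <- map_windows_to_residues(seqs, "X", w, offset = off)
    back_start <- map_residues_to_columns(seqs, "X", mapped$start, offset = off)
    expect_equal(back_start, w$start)
  }
})

test_that("site labels respect half-open interval bounds", {
  iv <- default_intervals()
  expect_equal(assign_sites(c(19, 20, 27, 28, 60, 90, 1), iv),
               c(NA, 1L, 1L, NA, 2L, NA, NA))
  expect_equal(assign_sites(integer(), iv), integer())
  # NA-bound (all-gap) intervals are skipped
  iv$start[2] <- NA; iv$end[2] <- NA
  expect_equal(assign_sites(c(60), iv), NA_integer_)
})

test_that("site window validation rejects malformed windows", {
  expect_error(site_windows(c(5L, 1L, 20L), c(8L, 4L, 25L)), "ascending")
  expect_error(site_windows(c(1L, 4L, 10L), c(4L, 4L, 12L)), "non-empty")
  expect_error(site_windows(c(1L, 3L, 10L), c(5L, 8L, 12L)),
               "non-overlapping")
})
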