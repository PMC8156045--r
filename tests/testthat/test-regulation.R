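test_that("site enrichment partitions citations and handles empty input", {
  iv <- default_intervals()
  m <- merge_phosphosites(make_records(
    "P1", c(21, 57, 100), citations = c("a;b;c;d", "e;f;g", "h;i;j")))
  e <- site_enrichment(m, iv)
  expect_equal(e$total_citations, 10L)
  expect_equal(e$in_site_citations, 7L)
  expect_equal(e$fraction, 0.7)
  # no records: undefined (NA) fraction, zero totals
  e0 <- site_enrichment(m[0, ], iv)
  expect_equal(e0$total_citations, 0L)
  expect_true(is.na(e0$fraction))
  # zero-citation records: defined totals of zero, NA fraction (not 0)
  ez <- site_enrichment(merge_phosphosites(make_records("P1", c(21, 100))), iv)
  expect_true(is.na(ez$fraction))
})

test_that("site enrichment resolves per-protein interval lists", {
  iv <- list(P1 = default_intervals(),
             P2 = site_windows(c(1L, 10L, 20L), c(5L, 15L, 25L)))
  m <- merge_phosphosites(make_records(
    c("P1", "P2", "P3"), c(21, 2, 21), citations = c("a", "b;c", "d")))
  e <- site_enrichment(m, iv)
  # P3 has no intervals -> out of Site
  expect_equal(e$in_site_citations, 3L)
  expect_equal(e$total_citations, 4L)
})

test_that("phosphosite density is a percentage over the stated lengths", {
  expect_equal(phospho_density(c(10, 20, 30), c(1, 101), 300),
               c(region_pct = 3.0, reference_pct = 1.0))
  expect_equal(phospho_density(integer(), c(1, 101), 100),
               c(region_pct = 0, reference_pct = 0))
  # only in-region positions count toward the region density
  d <- phospho_density(c(5, 50, 150, 150), c(100, 200), 400)
  expect_equal(unname(d["region_pct"]), 100 * 1 / 100)
  expect_equal(unname(d["reference_pct"]), 100 * 3 / 400)
  expect_error(phospho_density(1, c(10, 10), 100), "non-empty")
  expect_error(phospho_density(1, c(1, 10), 0), "positive")
})

test_that("bubble table caps PSS, counts cells and sums to the panel size", {
  panel <- data.frame(domain_id = letters[1:5],
                      lsi = c(10L, 10L, 7L, NA, 3L),
                      pss = c(3L, 3L, 16L, 2L, 0L),
                      stringsAsFactors = FALSE)
  b <- specificity_regulation_table(panel)
  expect_equal(b$count[b$lsi == 10 & b$pss_capped == 3], 2L)
  expect_equal(b$pss_capped[b$lsi == 7], 15L)   # capped at 15
  expect_equal(sum(b$count[b$stratum == "all"]), 4L)  # NA-LSI row excluded
  # every stratum sums to its scored-domain count
  panel$organism <- c("h", "h", "h", "y", "y")
  panel$pss_st <- panel$pss; panel$pss_y <- 0L
  b2 <- specificity_regulation_table(panel)
  for (s in unique(b2$stratum)) {
    n_expected <- switch(s, all = 4L, `pS/pT` = 4L, pY = 4L, h = 3L, y = 1L)
    expect_equal(sum(b2$count[b2$stratum == s]), n_expected, info = s)
  }
  # packaged panel: the (LSI 10, PSS 0) cell holds SNX8 and SNX10
  tab <- px_table1("human")
  scored <- score_panel(tab, quiet = TRUE)
  scored$pss <- as.integer(tab$pss_printed)
  cell <- tab$domain_id[!is.na(scored$lsi) & scored$lsi == 10 &
                          scored$pss == 0]
  expect_setequal(cell, c("SNX8", "SNX10"))
  b3 <- specificity_regulation_table(scored)
  expect_equal(b3$count[b3$lsi == 10 & b3$pss_capped == 0], 2L)
  expect_equal(b3$pss_capped[b3$lsi == 10 & b3$pss_capped == 15],
               15L)  # PLD2 (16) and SNX2 (17) bin at the cap with SNX1 (15)
  expect_equal(b3$count[b3$lsi == 10 & b3$pss_capped == 15], 3L)
})

test_that("association statistic detects perfect coupling and degeneracy", {
  a <- association_stat(1:10, 1:10, n_permutations = 500, seed = 1)
  expect_equal(a$rho, 1.0)
  expect_lt(a$p_value, 0.05)
  # constant PSS: undefined, reported as NA
  a0 <- association_stat(1:10, rep(2, 10), n_permutations = 500, seed = 1)
  expect_true(is.na(a0$rho))
  expect_true(is.na(a0$p_value))
  expect_error(association_stat(1:2, 1:2, seed = 1), "at least 3")
  expect_error(association_stat(1:10, 1:10, n_permutations = 10, seed = 1),
               ">= 100")
  expect_error(association_stat(1:10, 1:10), "seed")
})

test_that("association statistic is deterministic and order-invariant", {
  set.seed(33)
  lsi <- sample(0:10, 40, TRUE)
  pss <- sample(0:15, 40, TRUE)
  a1 <- association_stat(lsi, pss, n_permutations = 1000, seed = 9)
  a2 <- association_stat(lsi, pss, n_permutations = 1000, seed = 9)
  expect_identical(a1$p_value, a2$p_value)
  perm <- sample.int(40)
  a3 <- association_stat(lsi[perm], pss[perm], n_permutations = 1000,
                         seed = 9)
  expect_identical(a1$rho, a3$rho)
  expect_identical(a1$p_value, a3$p_value)
  # rho agrees with stats::cor
  expect_equal(a1$rho, cor(lsi, pss, method = "spearman"))
})

test_that("px_regulation assembles the panel analysis end to end", {
  cfg <- sim_config(n_domains = 40, seed = 5)
  sim <- simulate_panel(cfg)
  fit <- px_regulation(sim$panel, sim$phosphosites, sim$site_windows,
                       n_permutations = 500, seed = 5)
  expect_s3_class(fit, "px_regulation")
  expect_equal(nrow(fit$panel), 40L)
  expect_equal(fit$panel$pss,
               fit$panel$pss_site1 + fit$panel$pss_site2 +
                 fit$panel$pss_site3)
  expect_equal(fit$panel$pss, fit$panel$pss_st + fit$panel$pss_y)
  expect_equal(sum(fit$bubble$count[fit$bubble$stratum == "all"]), 40L)
  expect_true(!is.na(fit$enrichment$fraction))
  expect_named(coef(fit), c("rho", "p.value"))
  s <- summary(fit)
  expect_s3_class(s, "summary.px_regulation")
  expect_output(print(s), "Spearman")
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tmp))
  unlink(tmp)
})
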