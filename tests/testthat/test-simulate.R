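test_that("simulation configuration is validated", {
  expect_error(sim_config(n_domains = 0, seed = 1), "n_domains")
  expect_error(sim_config(n_domains = 10), "seed")
  expect_error(sim_config(n_domains = 10, seed = 1, lambda0 = -1))
  expect_error(sim_config(n_domains = 10, seed = 1, domain_length = 50),
               "exceed")
})

test_that("ligand-set sampling is deterministic and covers the size range", {
  cfg <- sim_config(n_domains = 1, seed = 1)
  set.seed(123); s1 <- sample_ligand_set(cfg)
  set.seed(123); s2 <- sample_ligand_set(cfg)
  expect_identical(s1, s2)
  expect_true(all(s1 %in% PIP_CODES))
  expect_equal(anyDuplicated(s1), 0L)
  # single-ligand draws score LSI 10
  cfg1 <- sim_config(n_domains = 1, seed = 1,
                     ligand_size_weights = c(1, 0, 0, 0, 0, 0, 0))
  set.seed(5)
  expect_equal(compute_lsi(sample_ligand_set(cfg1))$lsi, 10L)
  # empirical size distribution approaches the uniform weights
  set.seed(99)
  sizes <- replicate(10000, length(sample_ligand_set(cfg)))
  expect_true(all(abs(table(factor(sizes, 1:7)) / 10000 - 1 / 7) < 0.02))
})

test_that("phosphosite simulation follows the configured rate structure", {
  # lambda0 = 0, beta > 0: every phosphosite lies in a Site
  cfg <- sim_config(n_domains = 1, seed = 1, lambda0 = 0, beta = 0.8)
  set.seed(42)
  rec <- simulate_phosphosites("D1", lsi = 10L, cfg)
  expect_true(all(!is.na(assign_sites(rec$position, cfg$windows))))
  expect_true(all(rec$position >= 1 & rec$position <= cfg$domain_length))
  expect_true(all(as.integer(rec$citations) >= 1L))
  # realized in-Site event rate close to its expectation (moment check)
  cfg2 <- sim_config(n_domains = 1, seed = 1, lambda0 = 0.02, beta = 0.5)
  set.seed(7)
  tot_events <- 0L; tot_res <- 0L; rate <- NA_real_
  for (i in 1:200) {
    r <- simulate_phosphosites("D", lsi = 8L, cfg2)
    g <- attr(r, "ground_truth")
    tot_events <- tot_events + g$events_in
    tot_res <- tot_res + g$n_in
    rate <- g$rate_in
  }
  se <- sqrt(rate / tot_res)
  expect_lt(abs(tot_events / tot_res - rate), 3 * se)
})

test_that("under beta = 0 in- and out-of-Site rates are indistinguishable", {
  cfg <- sim_config(n_domains = 1, seed = 1, lambda0 = 0.1, beta = 0)
  set.seed(11)
  ev_in <- integer(); ev_out <- integer()
  for (i in 1:100) {
    r <- simulate_phosphosites("D", lsi = 10L, cfg)
    g <- attr(r, "ground_truth")
    ev_in <- c(ev_in, g$events_in); ev_out <- c(ev_out, g$events_out)
  }
  # realized in/out rate difference is within 4 SE of zero
  r_in <- sum(ev_in) / (100 * 31)
  r_out <- sum(ev_out) / (100 * 89)
  se <- sqrt(0.1 / (100 * 31) + 0.1 / (100 * 89))
  expect_lt(abs(r_in - r_out), 4 * se)
})

test_that("score profiles carry exactly three clusters on the windows", {
  cfg <- sim_config(n_domains = 1, seed = 1)
  set.seed(3)
  for (i in 1:20) {
    prof <- simulate_score_profile("D", cfg)
    cl <- find_proximal_clusters(flag_membrane_residues(prof$scores))
    expect_equal(nrow(cl), 3L)
    # centroids on the configured window centres
    centroids <- (cl$start + cl$end) / 2
    centres <- (cfg$windows$start + cfg$windows$end - 1) / 2
    expect_true(all(abs(centroids - centres) <= 2))
  }
  # background-only profiles yield no clusters
  set.seed(4)
  prof0 <- simulate_score_profile("D", cfg, bumps = FALSE)
  expect_equal(nrow(find_proximal_clusters(
    flag_membrane_residues(prof0$scores))), 0L)
})

test_that("generate_panel writes byte-identical files for a fixed seed", {
  cfg <- sim_config(n_domains = 15, seed = 77)
  d1 <- tempfile(); d2 <- tempfile()
  generate_panel(cfg, d1)
  generate_panel(cfg, d2)
  files <- c("panel.tsv", "phosphosites.tsv", "scores.csv", "windows.json",
             "ground_truth.json")
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  # written files round-trip through the readers
  panel <- read_panel(file.path(d1, "panel.tsv"))
  expect_equal(panel$domain_id, sprintf("SIM%04d", 1:15))
  rec <- read_phosphosites(file.path(d1, "phosphosites.tsv"))
  expect_true(all(rec$position >= 1 & rec$position <= cfg$domain_length))
  profs <- read_scores(file.path(d1, "scores.csv"))
  expect_length(profs, 15L)
  w <- read_site_windows(file.path(d1, "windows.json"))
  expect_equal(w$windows, cfg$windows)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("generated panels with strong coupling recover the association", {
  cfg <- sim_config(n_domains = 150, seed = 2024, lambda0 = 0.02, beta = 0.8)
  sim <- simulate_panel(cfg)
  fit <- px_regulation(sim$panel, sim$phosphosites, sim$site_windows,
                       n_permutations = 1000, seed = 2024)
  expect_gt(coef(fit)["rho"], 0)
  expect_lt(coef(fit)["p.value"], 0.05)
  # generator ground truth matches the rescored LSI
  gt_lsi <- vapply(sim$ground_truth$domains, `[[`, integer(1), "lsi_true")
  expect_equal(fit$panel$lsi, gt_lsi)
  # in-Site citation share exceeds the out-of-Site share under coupling
  expect_gt(fit$enrichment$fraction, 31 / 120)
})
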