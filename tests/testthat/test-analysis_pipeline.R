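test_that("pooled zone PDF reconciles with single-match distributions", {
  co <- small_corpus()
  pdf <- zone_pdf(co)
  expect_equal(sum(pdf$p), 1)
  expect_equal(pdf$n, nrow(co))
  one <- co[co$match_id == "M001", ]
  expect_equal(zone_pdf(one)$counts, zone_distribution(one$zone)$counts)
  expect_error(zone_pdf(co[0, ]), "empty")
})

test_that("zone PDF of a default corpus tracks the generator probabilities", {
  co <- generate_corpus(synthetic_config(n_matches = 50, seed = 61))
  pdf <- zone_pdf(co)
  p0 <- default_zone_probabilities()
  se <- sqrt(p0 * (1 - p0) / pdf$n)
  expect_true(all(abs(pdf$p - p0) <= 3.5 * se + 1e-12))
})

test_that("splits assign every stroke to one group apart from documented ties", {
  co <- small_corpus()
  for (s in c("won_vs_lost", "leading_vs_behind", "initial_vs_final")) {
    sp <- split_strokes(co, s)
    expect_equal(nrow(sp$group1) + nrow(sp$group2) + sp$n_excluded, nrow(co))
    if (s != "leading_vs_behind") expect_equal(sp$n_excluded, 0L)
  }
})

test_that("split rules follow their definitions on hand-built rallies", {
  m <- tiny_match()
  m$winner <- "P1"                      # player A wins every point
  sp <- split_strokes(m, "won_vs_lost")
  expect_true(all(sp$group1$player == "P1"))
  expect_true(all(sp$group2$player == "P2"))

  tie <- tiny_match()
  tie$score_p1 <- 5L; tie$score_p2 <- 5L
  sp <- split_strokes(tie, "leading_vs_behind")
  expect_equal(nrow(sp$group1), 0L)
  expect_equal(sp$n_excluded, nrow(tie))

  late <- tiny_match()
  late$score_p1 <- 11L; late$score_p2 <- 3L
  sp <- split_strokes(late, "initial_vs_final")
  expect_equal(nrow(sp$group2), nrow(late))   # (11, 3) is final phase
  expect_equal(nrow(split_strokes(late, "initial_vs_final", threshold = 12L)$group1),
               nrow(late))
})

test_that("leading/behind groups contain the right players' strokes", {
  m <- tiny_match()
  m$score_p1 <- c(rep(0L, 3), rep(1L, 4))   # rally 2: P1 leads 1-0
  m$score_p2 <- 0L
  sp <- split_strokes(m, "leading_vs_behind")
  expect_true(all(sp$group1$player == "P1"))
  expect_true(all(sp$group1$point == 2L))
  expect_equal(sp$n_excluded, 3L)           # rally 1 starts 0-0
})

test_that("per-match entropies are valid, paired, and match brute-force oracles", {
  co <- generate_corpus(synthetic_config(n_matches = 10, seed = 15))
  std <- per_match_entropy(co, "won_vs_lost", "standard")
  spa <- per_match_entropy(co, "won_vs_lost", "spatial")
  expect_true(all(std$H1 >= 0 & std$H1 <= 1))
  expect_true(all(std$H2 >= 0 & std$H2 <= 1))
  expect_true(all(spa$H1 > 0) && all(spa$H2 > 0))
  # recompute both measures independently for every match
  geom <- court_geometry()
  for (id in std$match_id) {
    m <- co[co$match_id == id, ]
    won <- m[m$player == m$winner, ]
    expect_equal(std$H1[std$match_id == id],
                 oracle_entropy(tabulate(won$zone, 12)), tolerance = 1e-12)
    expect_equal(spa$H1[spa$match_id == id],
                 oracle_spatial_entropy(won$x, won$y, geom$area),
                 tolerance = 1e-12)
  }
})

test_that("degenerate groups are dropped from pairing, not scored as zero", {
  m <- tiny_match()                      # 7 strokes, all short rallies
  solo <- m[1, ]                         # single-stroke match: <2 coordinates
  pm <- per_match_entropy(rbind(m, transform(solo, match_id = "M002")),
                          "won_vs_lost", "spatial")
  expect_false("M002" %in% pm$match_id)
  expect_equal(attr(pm, "n_dropped"), 1L)
})

test_that("spatial entropies of default corpora sit between clustered and random regimes", {
  co <- generate_corpus(synthetic_config(n_matches = 20, seed = 33))
  pm <- per_match_entropy(co, "won_vs_lost", "spatial")
  expect_true(all(pm$H1 > 0.3 & pm$H1 < 1.1))
  expect_true(all(pm$H2 > 0.3 & pm$H2 < 1.1))
})

test_that("receiving profile averages per-match entropies and flags unseen origins", {
  det <- strokes_from_zones(rep(c(9L, 12L), 40), rally_len = 2)
  rp <- receiving_profile(det)
  expect_equal(rp$profile$mean_H[9], 0)
  expect_true(is.na(rp$profile$mean_H[12]))
  expect_equal(rp$profile$n_matches[12], 0L)

  # uniform transitions: every origin's entropy near 1
  set.seed(3)
  u1 <- strokes_from_zones(sample(1:12, 30000, replace = TRUE), "M001",
                           rally_len = 30000)
  u2 <- strokes_from_zones(sample(1:12, 30000, replace = TRUE), "M002",
                           rally_len = 30000)
  rp <- receiving_profile(rbind(u1, u2))
  expect_true(all(abs(rp$profile$mean_H - 1) < 0.02))
  expect_equal(dim(rp$per_match), c(2L, 12L))
})

test_that("paired t-test reports means and errors on degenerate input", {
  expect_error(paired_t_test(1:5, 1:4), "pairing")
  expect_error(paired_t_test(c(1, 2, 3), c(1, 2, 3)), "degenerate")
  expect_error(paired_t_test(rep(0, 4), rep(1, 4)), "degenerate")
  set.seed(2)
  x <- rnorm(30); y <- x + rnorm(30, 0.5, 0.3)
  pc <- paired_t_test(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(pc$p_value, ref$p.value)
  expect_equal(pc$t, unname(ref$statistic))
  expect_equal(pc$n, 30L)
})

test_that("paired t-test rejection rate matches the noncentral-t power oracle", {
  n <- 259; shift <- 0.03; sd_diff <- 0.05
  nsim <- 400
  set.seed(77)
  rej <- vapply(seq_len(nsim), function(i) {
    d <- rnorm(n, shift, sd_diff)
    base <- rnorm(n, 0.5, 0.1)
    paired_t_test(base + d, base)$p_value < 0.05
  }, logical(1))
  power <- power.t.test(n = n, delta = shift, sd = sd_diff,
                        type = "paired")$power
  expect_lt(abs(mean(rej) - power), 0.03)
})

test_that("the full pipeline report is deterministic and conserves strokes", {
  co <- generate_corpus(synthetic_config(n_matches = 6, seed = 44))
  r1 <- run_pipeline(co)
  r2 <- run_pipeline(co)
  expect_identical(r1, r2)
  expect_equal(r1$provenance$n_strokes, nrow(co))
  expect_equal(sum(r1$zone_pdf$counts), nrow(co))
  expect_equal(r1$standard$won_vs_lost$n_matches +
                 r1$standard$won_vs_lost$n_dropped, 6)
  expect_true(all(r1$per_match_standard_H >= 0 & r1$per_match_standard_H <= 1))
  expect_length(r1$spatial, 3)
  expect_equal(unname(r1$spatial$won_vs_lost$p_bonferroni),
               unname(min(1, r1$spatial$won_vs_lost$p_value * 3)))
  f <- withr::local_tempfile(fileext = ".json")
  write_report(r1, f)
  expect_true(jsonlite::validate(paste(readLines(f), collapse = "\n")))
})

test_that("pipeline accepts a CSV path and reproduces the in-memory report", {
  co <- generate_corpus(synthetic_config(n_matches = 3, seed = 4))
  f <- withr::local_tempfile(fileext = ".csv")
  write_stroke_log(co, f)
  r_file <- run_pipeline(f)
  r_mem <- run_pipeline(as.data.frame(co))
  expect_equal(r_file$mean_standard_H, r_mem$mean_standard_H, tolerance = 1e-12)
  expect_equal(r_file$zone_pdf$counts, r_mem$zone_pdf$counts)
})

test_that("pipeline recovers the mixture gamma from a mixture-generated corpus", {
  g_star <- 0.5
  mats <- lapply(1:30, function(i) {
    z <- simulate_match_zones(842, g_star, seed = 5000 + i)
    strokes_from_zones(z, sprintf("M%03d", i), rally_len = 9, seed = i)
  })
  co <- do.call(rbind, mats)
  rep <- run_pipeline(co)
  expect_false(is.null(rep$gamma_fit))
  expect_lte(abs(rep$gamma_fit$gamma_hat - g_star), 0.05)
})
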