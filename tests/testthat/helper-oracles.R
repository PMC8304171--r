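# Independent oracles and fixture builders shared across test files.

# Direct evaluation of the normalized Shannon entropy from counts,
# independent of the package's implementation.
oracle_entropy <- function(counts) {
  p <- counts / sum(counts)
  s <- 0
  for (pi in p) if (pi > 0) s <- s - pi * log(pi)
  s / log(length(counts))
}

# O(N^2) all-pairs nearest-neighbour distances via the full distance matrix.
oracle_nn <- function(x, y) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  apply(d, 1, min)
}

oracle_spatial_entropy <- function(x, y, area) {
  mean(oracle_nn(x, y)) / (0.5 * sqrt(area / length(x)))
}

# Wrap a vector of zone indices into a valid stroke log: rallies of
# `rally_len` strokes, alternating strikers, random rally winners, scores
# accumulated from rally start. Coordinates sit at zone-cell centres so the
# zone/coordinate invariant holds exactly.
strokes_from_zones <- function(zones, match_id = "M001", rally_len = 9,
                               seed = 1, geom = court_geometry()) {
  set.seed(seed)
  n <- length(zones)
  n_rally <- ceiling(n / rally_len)
  point <- rep(seq_len(n_rally), each = rally_len)[seq_len(n)]
  sno <- as.integer(unlist(lapply(table(point), seq_len), use.names = FALSE))
  winners <- sample(c("P1", "P2"), n_rally, replace = TRUE)
  s1 <- c(0L, cumsum(winners == "P1"))[seq_len(n_rally)]
  s2 <- c(0L, cumsum(winners == "P2"))[seq_len(n_rally)]
  # coordinates uniform within each zone cell (centres would duplicate)
  cell <- zone_cell(zones, geom)
  x <- cell$xmin + runif(n) * (cell$xmax - cell$xmin)
  y <- cell$ymin + runif(n) * (cell$ymax - cell$ymin)
  data.frame(match_id = match_id, set = 1L, point = point, stroke_no = sno,
             player = ifelse(sno %% 2L == 1L, "P1", "P2"),
             zone = as.integer(zones), x = x, y = y,
             score_p1 = s1[point], score_p2 = s2[point],
             winner = winners[point], stringsAsFactors = FALSE)
}

# A tiny hand-written two-rally match used by the I/O tests.
tiny_match <- function() {
  zones <- c(9L, 12L, 9L, 1L, 4L, 2L, 11L)
  ctr <- zone_centre(zones)
  data.frame(match_id = "M001", set = 1L,
             point = c(1L, 1L, 1L, 2L, 2L, 2L, 2L),
             stroke_no = c(1L, 2L, 3L, 1L, 2L, 3L, 4L),
             player = c("P1", "P2", "P1", "P2", "P1", "P2", "P1"),
             zone = zones, x = ctr[, "x"], y = ctr[, "y"],
             score_p1 = c(0L, 0L, 0L, 1L, 1L, 1L, 1L),
             score_p2 = c(0L, 0L, 0L, 0L, 0L, 0L, 0L),
             winner = c("P1", "P1", "P1", "P2", "P2", "P2", "P2"),
             stringsAsFactors = FALSE)
}

small_corpus <- function(n_matches = 4, seed = 4) {
  generate_corpus(synthetic_config(n_matches = n_matches, seed = seed))
}
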