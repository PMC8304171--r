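#' Pooled zone distribution of a corpus
#'
#' @param strokes stroke-log data frame (one or many matches).
#' @return A [zone_distribution()] over all strokes.
#' @export
zone_pdf <- function(strokes) {
  if (is.null(strokes) || nrow(strokes) == 0) stop("empty input: no strokes")
  zone_distribution(strokes$zone)
}

# per-match player id that owns score_p1 / score_p2 (lexicographic order)
.player1 <- function(strokes) {
  stats::ave(strokes$player, strokes$match_id,
             FUN = function(p) rep(min(p), length(p)))
}
.player2 <- function(strokes) {
  stats::ave(strokes$player, strokes$match_id,
             FUN = function(p) rep(max(p), length(p)))
}

#' Split the strokes of a match by context
#'
#' Three splits mirror the contexts under which striking entropy is
#' compared:
#' * `won_vs_lost`: strokes by each rally's eventual winner vs. its loser.
#' * `leading_vs_behind`: within each rally, strokes by the player leading
#'   on the score at rally start vs. the player behind; rallies starting
#'   from a tied score contribute to neither group.
#' * `initial_vs_final`: all strokes of rallies whose starting score has
#'   both players below `threshold` vs. the rest of the rallies.
#'
#' @param strokes stroke-log data frame.
#' @param split one of `"won_vs_lost"`, `"leading_vs_behind"`,
#'   `"initial_vs_final"`.
#' @param threshold score defining the final phase (default 11).
#' @return List with `group1`, `group2` (stroke data frames), `n_excluded`
#'   (strokes in neither group, e.g. ties), `split` and `labels`.
#' @export
split_strokes <- function(strokes,
                          split = c("won_vs_lost", "leading_vs_behind",
                                    "initial_vs_final"),
                          threshold = 11L) {
  split <- match.arg(split)
  if (threshold < 1) stop("threshold must be >= 1")
  if (split == "won_vs_lost") {
    g1 <- strokes$player == strokes$winner
    g2 <- !g1
    labels <- c("won", "lost")
  } else if (split == "leading_vs_behind") {
    p1 <- .player1(strokes); p2 <- .player2(strokes)
    leader <- ifelse(strokes$score_p1 > strokes$score_p2, p1,
                     ifelse(strokes$score_p2 > strokes$score_p1, p2, NA))
    g1 <- !is.na(leader) & strokes$player == leader
    g2 <- !is.na(leader) & strokes$player != leader
    labels <- c("leading", "behind")
  } else {
    initial <- strokes$score_p1 < threshold & strokes$score_p2 < threshold
    g1 <- initial
    g2 <- !initial
    labels <- c("initial", "final")
  }
  list(group1 = strokes[g1, , drop = FALSE],
       group2 = strokes[g2, , drop = FALSE],
       n_excluded = sum(!g1 & !g2),
       split = split, labels = labels)
}

.group_entropy <- function(group, measure, geom) {
  if (measure == "standard") {
    if (nrow(group) == 0) return(NA_real_)
    standard_entropy(zone_distribution(group$zone))
  } else {
    if (nrow(group) < 2) return(NA_real_)
    spatial_entropy(point_pattern(group$x, group$y, geom = geom))$Hs
  }
}

#' Per-match paired entropies under a split
#'
#' For every match, splits the strokes with [split_strokes()] and computes
#' the entropy of each group: the standard (zone-distribution) entropy or
#' the spatial (Clark-Evans) entropy of the group's coordinates, always with
#' the full half-court area as the window so values are comparable across
#' matches and groups. Matches where a group is too small (no strokes for
#' the standard measure, fewer than 2 for the spatial one) are dropped from
#' the pairing and counted in the `n_dropped` attribute.
#'
#' @param strokes corpus stroke-log data frame.
#' @param split,threshold passed to [split_strokes()].
#' @param measure `"standard"` or `"spatial"`.
#' @param geom a [court_geometry()].
#' @return Data frame `match_id`, `H1`, `H2` (one row per retained match)
#'   with attributes `labels`, `n_dropped` and `n_excluded_strokes`.
#' @export
per_match_entropy <- function(strokes, split = "won_vs_lost",
                              measure = c("standard", "spatial"),
                              geom = court_geometry(), threshold = 11L) {
  measure <- match.arg(measure)
  by_match <- split(strokes, strokes$match_id)
  labels <- NULL
  excluded <- 0L
  rows <- lapply(names(by_match), function(id) {
    sp <- split_strokes(by_match[[id]], split, threshold)
    labels <<- sp$labels
    excluded <<- excluded + sp$n_excluded
    data.frame(match_id = id,
               H1 = .group_entropy(sp$group1, measure, geom),
               H2 = .group_entropy(sp$group2, measure, geom),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  keep <- stats::complete.cases(out[, c("H1", "H2")])
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "labels") <- labels
  attr(res, "n_dropped") <- sum(!keep)
  attr(res, "n_excluded_strokes") <- excluded
  res
}

#' Receiving-entropy profile of a corpus
#'
#' Computes [receiving_entropy()] per match, then averages per origin zone
#' over the matches where that zone has at least one outgoing pair. The
#' per-match values are retained for histogramming.
#'
#' @param strokes corpus stroke-log data frame.
#' @return List with `profile` (data frame `zone`, `mean_H`, `n_matches`)
#'   and `per_match` (matches x 12 matrix of per-origin entropies, `NA`
#'   where undefined).
#' @export
receiving_profile <- function(strokes) {
  by_match <- split(strokes, strokes$match_id)
  per_match <- t(vapply(by_match,
                        function(m) receiving_entropy(m)$H,
                        numeric(12)))
  rownames(per_match) <- names(by_match)
  colnames(per_match) <- paste0("zone", 1:12)
  n_def <- colSums(!is.na(per_match))
  mean_H <- ifelse(n_def > 0, colMeans(per_match, na.rm = TRUE), NA_real_)
  list(profile = data.frame(zone = 1:12, mean_H = unname(mean_H),
                            n_matches = unname(n_def)),
       per_match = per_match)
}

#' Paired t-test between per-match entropy groups
#'
#' Two-sided paired Student's t-test on per-match value pairs, reporting the
#' group means alongside the statistic as in standard match-analysis tables.
#'
#' @param values1,values2 numeric vectors of equal length (>= 2), paired by
#'   match.
#' @return Object of class `paired_comparison`: list with `mean1`, `mean2`,
#'   `t`, `df`, `p_value`, `n`.
#' @export
paired_t_test <- function(values1, values2) {
  if (length(values1) != length(values2))
    stop("pairing error: groups have different lengths")
  if (length(values1) < 2) stop("at least two pairs are required")
  d <- values1 - values2
  if (stats::sd(d) == 0)
    stop("degenerate test: paired differences have zero variance")
  tt <- stats::t.test(values1, values2, paired = TRUE)
  structure(list(mean1 = mean(values1), mean2 = mean(values2),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, n = length(values1)),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("paired t-test: mean1 = %.4f, mean2 = %.4f, t(%d) = %.3f, p = %.3g (n = %d)\n",
              x$mean1, x$mean2, x$df, x$t, x$p_value, x$n))
  invisible(x)
}

# 20-bin histogram summary over the pooled range of two groups
.hist_summary <- function(v1, v2, bins = 20L) {
  rng <- range(c(v1, v2))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5) * 1e-6
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  list(breaks = breaks,
       counts1 = as.integer(table(cut(v1, breaks, include.lowest = TRUE))),
       counts2 = as.integer(table(cut(v2, breaks, include.lowest = TRUE))))
}

.comparison_block <- function(per_match, bins) {
  if (nrow(per_match) < 2)
    return(list(labels = attr(per_match, "labels"),
                n_matches = nrow(per_match),
                n_dropped = attr(per_match, "n_dropped"),
                n_excluded_strokes = attr(per_match, "n_excluded_strokes"),
                p_value = NA_real_,
                note = "fewer than two complete pairs; comparison skipped"))
  test <- tryCatch(paired_t_test(per_match$H1, per_match$H2),
                   error = function(e) NULL)
  if (is.null(test))
    return(list(labels = attr(per_match, "labels"),
                n_matches = nrow(per_match),
                n_dropped = attr(per_match, "n_dropped"),
                n_excluded_strokes = attr(per_match, "n_excluded_strokes"),
                mean1 = mean(per_match$H1), mean2 = mean(per_match$H2),
                p_value = NA_real_,
                note = "degenerate paired differences; t-test skipped",
                per_match = per_match))
  list(labels = attr(per_match, "labels"),
       n_matches = nrow(per_match),
       n_dropped = attr(per_match, "n_dropped"),
       n_excluded_strokes = attr(per_match, "n_excluded_strokes"),
       mean1 = test$mean1, mean2 = test$mean2,
       t = test$t, df = test$df, p_value = test$p_value,
       histogram = .hist_summary(per_match$H1, per_match$H2, bins),
       per_match = per_match)
}

#' Run the full strike-entropy analysis over a corpus
#'
#' Orchestrates all analyses over a stroke-log corpus: the pooled zone
#' distribution; per-match standard entropy split by point outcome with a
#' paired t-test; per-match spatial entropy under the won/lost,
#' leading/behind and initial/final splits, each with a paired t-test (raw
#' p-values plus a Bonferroni-adjusted column over the three spatial
#' comparisons); the receiving-entropy profile; and the corpus mean standard
#' entropy inverted through the mixture model's analytic curve
#' ([fit_gamma()]) when it falls in the attainable range. The report is
#' deterministic given the corpus.
#'
#' @param corpus stroke-log data frame, or a path to a stroke-log CSV.
#' @param geom a [court_geometry()].
#' @param threshold final-phase score threshold (default 11).
#' @param bins histogram bins for report summaries (default 20).
#' @param delta_gamma grid step for the gamma fit.
#' @param validate run [validate_strokes()] on the corpus first.
#' @return Object of class `analysis_report` (a nested list; serialize with
#'   [write_report()]).
#' @export
run_pipeline <- function(corpus, geom = court_geometry(), threshold = 11L,
                         bins = 20L, delta_gamma = 0.01, validate = TRUE) {
  if (is.character(corpus)) corpus <- read_stroke_log(corpus, geom)
  if (validate) validate_strokes(corpus, geom)

  pdf_all <- zone_pdf(corpus)
  std_won_lost <- per_match_entropy(corpus, "won_vs_lost", "standard",
                                    geom, threshold)
  spatial <- lapply(c("won_vs_lost", "leading_vs_behind", "initial_vs_final"),
                    function(s) per_match_entropy(corpus, s, "spatial",
                                                  geom, threshold))
  names(spatial) <- c("won_vs_lost", "leading_vs_behind", "initial_vs_final")
  spatial_blocks <- lapply(spatial, .comparison_block, bins = bins)
  p_raw <- vapply(spatial_blocks, function(b) b$p_value %||% NA_real_,
                  numeric(1))
  p_adj <- stats::p.adjust(p_raw, method = "bonferroni")
  for (i in seq_along(spatial_blocks))
    spatial_blocks[[i]]$p_bonferroni <- unname(p_adj[i])

  by_match <- split(corpus$zone, corpus$match_id)
  per_match_H <- vapply(by_match,
                        function(z) standard_entropy(zone_distribution(z)),
                        numeric(1))
  H_obs <- mean(per_match_H)
  gamma <- tryCatch(fit_gamma(H_obs, delta_gamma),
                    error = function(e) NULL)

  structure(list(
    provenance = list(
      n_matches = length(by_match),
      n_strokes = nrow(corpus),
      geometry = unclass(geom),
      threshold = threshold,
      bins = bins),
    zone_pdf = list(counts = pdf_all$counts, p = pdf_all$p),
    standard = list(won_vs_lost = .comparison_block(std_won_lost, bins)),
    spatial = spatial_blocks,
    receiving = receiving_profile(corpus),
    per_match_standard_H = per_match_H,
    mean_standard_H = H_obs,
    gamma_fit = if (!is.null(gamma)) unclass(gamma) else NULL
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Strike-entropy analysis: %d matches, %d strokes\n",
              x$provenance$n_matches, x$provenance$n_strokes))
  cat(sprintf("  mean per-match standard entropy: %.4f\n", x$mean_standard_H))
  if (!is.null(x$gamma_fit))
    cat(sprintf("  fitted mixture gamma: %.2f\n", x$gamma_fit$gamma_hat))
  show <- function(what, b) {
    if (is.null(b$mean1)) {
      cat(sprintf("  %s, %s vs %s: %s\n", what, b$labels[1], b$labels[2],
                  b$note %||% "unavailable"))
    } else {
      cat(sprintf("  %s, %s vs %s: %.4f vs %.4f (p = %.3g)\n", what,
                  b$labels[1], b$labels[2], b$mean1, b$mean2, b$p_value))
    }
  }
  show("standard H", x$standard$won_vs_lost)
  for (nm in names(x$spatial)) show("spatial Hs", x$spatial[[nm]])
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' @param report an [run_pipeline()] result.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
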