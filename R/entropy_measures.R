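#' Zone distribution of a set of strokes
#'
#' Tallies strokes per zone and normalizes to a probability vector. The
#' normalized Shannon entropy of the result is [standard_entropy()].
#'
#' @param zones integer vector of zone indices, or a stroke-log data frame
#'   (its `zone` column is used).
#' @param n_zones number of zones (12 for the traditional partition).
#' @return An object of class `zone_distribution`: list with integer `counts`
#'   (length `n_zones`), probabilities `p`, and total stroke count `n`.
#' @examples
#' d <- zone_distribution(c(1, 1, 9, 12))
#' d$p
#' @export
zone_distribution <- function(zones, n_zones = 12L) {
  if (is.data.frame(zones)) zones <- zones$zone
  if (length(zones) == 0) stop("empty input: no strokes")
  zones <- as.integer(zones)
  if (any(is.na(zones)) || any(zones < 1L) || any(zones > n_zones))
    stop("zone indices must lie in 1..", n_zones)
  counts <- tabulate(zones, nbins = n_zones)
  structure(list(counts = counts, p = counts / sum(counts),
                 n = sum(counts)),
            class = "zone_distribution")
}

#' @export
print.zone_distribution <- function(x, ...) {
  cat(sprintf("Zone distribution over %d zones, %d strokes\n",
              length(x$counts), x$n))
  print(round(x$p, 4))
  invisible(x)
}

#' Normalized Shannon entropy of a zone distribution
#'
#' Computes `H = -sum(p_i * ln(p_i)) / ln(K)` over the `K` zones, with the
#' `0 * ln(0) = 0` convention for empty zones, so `H` lies in `[0, 1]`:
#' 0 when every stroke comes from a single zone, 1 when strokes are spread
#' uniformly over all zones.
#'
#' @param x a [zone_distribution()], or a numeric vector of zone counts (or
#'   probabilities; entropy is scale invariant) with one entry per zone.
#' @return Numeric scalar `H` in `[0, 1]`.
#' @examples
#' standard_entropy(rep(1, 12))          # uniform: 1
#' standard_entropy(c(5, rep(0, 11)))    # single zone: 0
#' @export
standard_entropy <- function(x) {
  counts <- if (inherits(x, "zone_distribution")) x$counts else as.numeric(x)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  total <- sum(counts)
  if (total <= 0) stop("empty input: all-zero counts")
  p <- counts / total
  p <- p[p > 0]
  h <- -sum(p * log(p)) / log(length(counts))
  # clip the last-ulp overshoot of the uniform case
  min(max(h, 0), 1)
}

#' Receiving-zone pair counts
#'
#' Every consecutive stroke pair within a rally contributes one transition
#' from the zone of stroke `k` (origin, where the shuttlecock was hit from)
#' to the zone of stroke `k + 1` (where it was received and returned from).
#' The last stroke of each rally has no successor, so a stroke log with `L`
#' strokes in `R` rallies yields exactly `L - R` pairs.
#'
#' @param strokes stroke-log data frame (any subset of matches).
#' @param n_zones number of zones.
#' @return An `n_zones` x `n_zones` integer matrix of counts, origins in
#'   rows, destinations in columns.
#' @export
receiving_pairs <- function(strokes, n_zones = 12L) {
  out <- matrix(0L, n_zones, n_zones,
                dimnames = list(origin = seq_len(n_zones),
                                destination = seq_len(n_zones)))
  n <- nrow(strokes)
  if (n < 2) return(out)
  ord <- order(strokes$match_id, strokes$set, strokes$point,
               strokes$stroke_no)
  strokes <- strokes[ord, ]
  key <- .rally_key(strokes)
  same <- key[-1] == key[-n]
  origin <- strokes$zone[-n][same]
  dest <- strokes$zone[-1][same]
  if (length(origin)) {
    idx <- tabulate((dest - 1L) * n_zones + origin, nbins = n_zones * n_zones)
    out[] <- idx
  }
  out
}

#' Receiving entropy per origin zone
#'
#' For each origin zone `i`, the conditional distribution of the next
#' stroke's zone is formed from the receiving pairs, and its entropy is
#' normalized by `ln(n_zones)` exactly as in [standard_entropy()], so values
#' are comparable with the zone-distribution entropy. Origin zones with no
#' outgoing pairs have no defined entropy and are reported as `NA` rather
#' than 0, keeping "never strikes from here" distinct from "fully
#' predictable".
#'
#' @param strokes stroke-log data frame (typically one match).
#' @param n_zones number of zones.
#' @return A data frame with one row per origin zone: `zone`, `n_pairs`, `H`.
#' @export
receiving_entropy <- function(strokes, n_zones = 12L) {
  pairs <- receiving_pairs(strokes, n_zones)
  n_pairs <- rowSums(pairs)
  H <- rep(NA_real_, n_zones)
  for (i in which(n_pairs > 0)) H[i] <- standard_entropy(pairs[i, ])
  data.frame(zone = seq_len(n_zones), n_pairs = as.integer(n_pairs), H = H)
}
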