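#' Court geometry for the zone partition
#'
#' Describes one player's half court as a rectangle partitioned into a grid
#' of hitting zones: `n_cols` columns across the width and `n_rows` rows from
#' the net to the baseline. The traditional partition is 4 columns x 3 rows,
#' giving 12 zones numbered row-major with row 1 adjacent to the net and
#' column 1 at the left sideline, so the front corners are zones 1 and 4, the
#' back corners 9 and 12, and the central back zones 10 and 11.
#'
#' @param width sideline-to-sideline width of one half court, in meters.
#'   Default 5.18 m (singles court).
#' @param depth net-to-baseline depth, in meters. Default 6.7 m.
#' @param n_cols number of zone columns across the width.
#' @param n_rows number of zone rows from net to baseline.
#' @return An object of class `court_geometry` with fields `width`, `depth`,
#'   `n_cols`, `n_rows`, `n_zones` and `area` (m^2).
#' @examples
#' geom <- court_geometry()
#' geom$area # 5.18 * 6.7
#' @export
court_geometry <- function(width = 5.18, depth = 6.7, n_cols = 4L, n_rows = 3L) {
  stopifnot(is.numeric(width), length(width) == 1, is.finite(width), width > 0,
            is.numeric(depth), length(depth) == 1, is.finite(depth), depth > 0)
  n_cols <- as.integer(n_cols); n_rows <- as.integer(n_rows)
  stopifnot(n_cols >= 1, n_rows >= 1)
  structure(
    list(width = width, depth = depth, n_cols = n_cols, n_rows = n_rows,
         n_zones = n_cols * n_rows, area = width * depth),
    class = "court_geometry"
  )
}

#' @export
print.court_geometry <- function(x, ...) {
  cat(sprintf("Half court %.2f m x %.2f m, %d x %d = %d zones (area %.3f m^2)\n",
              x$width, x$depth, x$n_cols, x$n_rows, x$n_zones, x$area))
  invisible(x)
}

#' Assign a striking coordinate to a court zone
#'
#' Maps coordinates in the striker's own half-court frame (origin at the
#' net/left-sideline corner, y growing toward the baseline) to the zone index
#' `(row - 1) * n_cols + col`. Coordinates outside the rectangle are clamped
#' to the border row/column: a stroke played from behind the baseline still
#' belongs to the back row, since the zones discretize striking position, not
#' legal court area.
#'
#' @param x,y numeric vectors of coordinates in meters.
#' @param geom a [court_geometry()].
#' @return Integer vector of zone indices in `1:geom$n_zones`.
#' @examples
#' assign_zone(0.5, 1.0)  # front-left corner, zone 1
#' assign_zone(5.0, 6.5)  # back-right corner, zone 12
#' assign_zone(2.0, 7.5)  # behind the baseline, clamped into zone 10
#' @export
assign_zone <- function(x, y, geom = court_geometry()) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("coordinates must be finite")
  col <- pmin(pmax(ceiling(x / (geom$width / geom$n_cols)), 1), geom$n_cols)
  row <- pmin(pmax(ceiling(y / (geom$depth / geom$n_rows)), 1), geom$n_rows)
  as.integer((row - 1) * geom$n_cols + col)
}

#' Zone cell bounds and centres
#'
#' @param zone integer vector of zone indices.
#' @param geom a [court_geometry()].
#' @return `zone_cell()`: a data frame with `zone`, `xmin`, `xmax`, `ymin`,
#'   `ymax`; `zone_centre()`: a two-column matrix of cell-centre coordinates.
#' @export
zone_cell <- function(zone, geom = court_geometry()) {
  zone <- as.integer(zone)
  if (any(zone < 1 | zone > geom$n_zones)) stop("zone index out of range")
  cw <- geom$width / geom$n_cols
  ch <- geom$depth / geom$n_rows
  col <- (zone - 1L) %% geom$n_cols
  row <- (zone - 1L) %/% geom$n_cols
  data.frame(zone = zone,
             xmin = col * cw, xmax = (col + 1L) * cw,
             ymin = row * ch, ymax = (row + 1L) * ch)
}

#' @rdname zone_cell
#' @export
zone_centre <- function(zone, geom = court_geometry()) {
  cell <- zone_cell(zone, geom)
  cbind(x = (cell$xmin + cell$xmax) / 2, y = (cell$ymin + cell$ymax) / 2)
}

#' Centres of the four corner zones
#'
#' @param geom a [court_geometry()].
#' @return 4 x 2 matrix of the cell centres of zones 1, 4, 9 and 12 (front
#'   left/right, back left/right for the default 4 x 3 grid).
#' @export
corner_centres <- function(geom = court_geometry()) {
  corners <- c(1L, geom$n_cols, (geom$n_rows - 1L) * geom$n_cols + 1L,
               geom$n_rows * geom$n_cols)
  zone_centre(corners, geom)
}

# canonical stroke-log column set; `winner` is written but optional on read
.stroke_cols <- c("match_id", "set", "point", "stroke_no", "player", "zone",
                  "x", "y", "score_p1", "score_p2", "winner")

.rally_key <- function(strokes) {
  paste(strokes$match_id, strokes$set, strokes$point, sep = "\r")
}

#' Validate a stroke-log data frame
#'
#' Checks the structural invariants of a stroke log: zones in range and
#' consistent with coordinates, stroke numbers contiguous from 1 within each
#' rally, alternating strikers, exactly two players per match, a winner that
#' is one of them, and non-negative scores constant within a rally.
#'
#' @param strokes stroke-log data frame (see [read_stroke_log()] for columns).
#' @param geom a [court_geometry()].
#' @return Invisibly `TRUE`; otherwise an error naming the offending rally.
#' @export
validate_strokes <- function(strokes, geom = court_geometry()) {
  if (!is.data.frame(strokes) || nrow(strokes) == 0)
    stop("empty stroke log")
  needed <- setdiff(.stroke_cols, "winner")
  miss <- setdiff(needed, names(strokes))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))

  if (any(strokes$zone < 1 | strokes$zone > geom$n_zones))
    stop("zone index outside 1..", geom$n_zones)
  bad <- strokes$zone != assign_zone(strokes$x, strokes$y, geom)
  if (any(bad))
    stop("zone does not match coordinates in rally ",
         .rally_label(strokes[which(bad)[1], ]))
  if (any(strokes$score_p1 < 0 | strokes$score_p2 < 0))
    stop("negative scores")

  rally <- .rally_key(strokes)
  ord <- order(strokes$match_id, strokes$set, strokes$point, strokes$stroke_no)
  strokes <- strokes[ord, ]
  rally <- rally[ord]

  sno <- strokes$stroke_no
  expected <- stats::ave(sno, rally, FUN = seq_along)
  if (any(sno != expected)) {
    i <- which(sno != expected)[1]
    stop("non-contiguous stroke numbers in rally ", .rally_label(strokes[i, ]))
  }
  n <- nrow(strokes)
  if (n > 1) {
    same <- rally[-1] == rally[-n]
    rep_player <- strokes$player[-1] == strokes$player[-n]
    if (any(same & rep_player)) {
      i <- which(same & rep_player)[1] + 1L
      stop("strikers do not alternate in rally ", .rally_label(strokes[i, ]))
    }
    for (col in c("score_p1", "score_p2", if ("winner" %in% names(strokes)) "winner")) {
      changed <- strokes[[col]][-1] != strokes[[col]][-n]
      if (any(same & changed)) {
        i <- which(same & changed)[1] + 1L
        stop(col, " changes within rally ", .rally_label(strokes[i, ]))
      }
    }
  }
  players <- tapply(strokes$player, strokes$match_id,
                    function(p) length(unique(p)))
  if (any(players > 2))
    stop("more than two players in match ",
         names(players)[which(players > 2)[1]])
  if ("winner" %in% names(strokes)) {
    ok <- tapply(seq_len(n), strokes$match_id, function(i) {
      all(strokes$winner[i] %in% unique(strokes$player[i]))
    })
    if (!all(unlist(ok)))
      stop("winner is not one of the match players in match ",
           names(ok)[which(!unlist(ok))[1]])
  }
  invisible(TRUE)
}

.rally_label <- function(row) {
  sprintf("(match %s, set %s, point %s)", row$match_id, row$set, row$point)
}

#' Read a stroke-log CSV
#'
#' Reads a comma-separated stroke log with header columns `match_id, set,
#' point, stroke_no, player, zone, x, y, score_p1, score_p2` and optionally
#' `winner`. Rallies are the groups of strokes sharing `(match_id, set,
#' point)`; `score_p1`/`score_p2` are the running scores at rally start, with
#' `score_p1` belonging to the lexicographically first player id of the
#' match. If the `zone` column is absent it is derived from the coordinates
#' via [assign_zone()]; if `x`/`y` are absent they are filled with zone-cell
#' centres. If `winner` is absent, each rally's winner is inferred from the
#' score change at the start of the following rally; for the last rally of a
#' set the player holding the unique maximum score is taken (a tied final
#' score is ambiguous and raises a validation error asking for an explicit
#' winner column).
#'
#' @param path file path (or connection) of the CSV.
#' @param geom a [court_geometry()].
#' @return A validated stroke-log data frame ordered by match, set, point and
#'   stroke number, with all eleven canonical columns.
#' @seealso [write_stroke_log()], [validate_strokes()]
#' @export
read_stroke_log <- function(path, geom = court_geometry()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  core <- c("match_id", "set", "point", "stroke_no", "player",
            "score_p1", "score_p2")
  miss <- setdiff(core, names(df))
  if (length(miss))
    stop("stroke log is missing required column(s): ",
         paste(miss, collapse = ", "))
  has_zone <- "zone" %in% names(df)
  has_xy <- all(c("x", "y") %in% names(df))
  if (!has_zone && !has_xy)
    stop("stroke log is missing required column(s): zone (or x and y)")
  if (!has_zone) df$zone <- assign_zone(df$x, df$y, geom)
  if (!has_xy) {
    ctr <- zone_centre(df$zone, geom)
    df$x <- ctr[, "x"]; df$y <- ctr[, "y"]
  }
  df$match_id <- as.character(df$match_id)
  df$player <- as.character(df$player)
  df <- df[order(df$match_id, df$set, df$point, df$stroke_no), , drop = FALSE]
  rownames(df) <- NULL
  if (!"winner" %in% names(df)) df$winner <- .infer_winner(df)
  df$winner <- as.character(df$winner)
  df <- df[, .stroke_cols]
  validate_strokes(df, geom)
  df
}

# Winner of each rally from score deltas: within a (match, set), the winner of
# rally j is the player whose score increased at rally j+1's score_before; the
# last rally's winner holds the unique maximum score_before.
.infer_winner <- function(df) {
  winner <- character(nrow(df))
  for (ms in split(seq_len(nrow(df)), paste(df$match_id, df$set, sep = "\r"))) {
    sub <- df[ms, ]
    pl <- sort(unique(sub$player))
    first <- ms[!duplicated(sub$point)]            # one row per rally, in order
    s1 <- df$score_p1[first]; s2 <- df$score_p2[first]
    nr <- length(first)
    w <- character(nr)
    if (nr > 1) {
      d1 <- diff(s1); d2 <- diff(s2)
      if (any(d1 + d2 != 1) || any(d1 < 0) || any(d2 < 0))
        stop("scores do not advance by one point per rally in match ",
             sub$match_id[1], ", set ", sub$set[1])
      w[-nr] <- ifelse(d1 == 1, pl[1], pl[min(2, length(pl))])
    }
    if (s1[nr] == s2[nr])
      stop("cannot infer the winner of the final rally of match ",
           sub$match_id[1], ", set ", sub$set[1],
           " (tied score); provide an explicit winner column")
    w[nr] <- if (s1[nr] > s2[nr]) pl[1] else pl[min(2, length(pl))]
    for (j in seq_len(nr)) {
      rows <- ms[sub$point == sub$point[!duplicated(sub$point)][j]]
      winner[rows] <- w[j]
    }
  }
  winner
}

#' Write a stroke-log CSV
#'
#' Serializes a stroke log with the canonical column order, including the
#' `winner` column so that rallies remain reconstructible even when the final
#' rally of a set starts from a tied score. [read_stroke_log()] of the result
#' reproduces the input field for field.
#'
#' @param strokes stroke-log data frame.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_stroke_log <- function(strokes, path) {
  if (nrow(strokes) == 0) {
    empty <- as.data.frame(stats::setNames(rep(list(logical(0)),
                                               length(.stroke_cols)),
                                           .stroke_cols))
    utils::write.csv(empty, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  miss <- setdiff(.stroke_cols, names(strokes))
  if (length(miss)) stop("cannot write: missing column(s) ",
                         paste(miss, collapse = ", "))
  utils::write.csv(strokes[, .stroke_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Per-rally summary of a stroke log
#'
#' @param strokes stroke-log data frame.
#' @return One row per rally: `match_id`, `set`, `point`, `winner`,
#'   `score_p1`, `score_p2` (score at rally start) and `n_strokes`.
#' @export
rally_table <- function(strokes) {
  key <- .rally_key(strokes)
  first <- !duplicated(key)
  out <- strokes[first, c("match_id", "set", "point", "winner",
                          "score_p1", "score_p2")]
  out$n_strokes <- as.integer(table(key)[key[first]])
  rownames(out) <- NULL
  out
}
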