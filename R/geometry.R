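#' Midvein axis
#'
#' A polyline from lamina base to tip, in image coordinates (pixels; y
#' increases downward, the scanner convention). Only relative positions
#' matter downstream, so the convention is never consulted directly.
#'
#' @param nodes two-column numeric matrix (or data frame) of (x, y) nodes,
#'   ordered base to tip; at least two distinct nodes.
#' @return an object of class `"midvein_axis"` with the node matrix,
#'   per-segment lengths and cumulative arc length.
#' @export
midvein_axis <- function(nodes) {
  nodes <- as.matrix(nodes)
  if (ncol(nodes) != 2 || nrow(nodes) < 2)
    stop("a midvein axis needs >= 2 (x, y) nodes")
  storage.mode(nodes) <- "double"
  if (!all(is.finite(nodes))) stop("axis nodes must be finite")
  seg <- diff(nodes)
  len <- sqrt(rowSums(seg^2))
  if (any(len == 0)) stop("consecutive axis nodes must be distinct")
  structure(
    list(nodes = unname(nodes), seg_len = len, cum_len = c(0, cumsum(len)),
         length = sum(len)),
    class = "midvein_axis")
}

# Project a set of points onto the axis. Returns, per point: arc-length
# position s, perpendicular (signed) offset, distance to the axis, and the
# index of the nearest segment. The sign of `offset` is the z-component of
# the cross product of the local base->tip tangent with the vector from the
# projection foot to the point: positive = "left" by convention.
project_onto_axis <- function(axis, points) {
  stopifnot(inherits(axis, "midvein_axis"))
  pts <- as.matrix(points)
  nodes <- axis$nodes
  nseg <- nrow(nodes) - 1
  np <- nrow(pts)
  s <- off <- dist <- numeric(np)
  segi <- integer(np)
  for (i in seq_len(np)) {
    p <- pts[i, ]
    best <- Inf; bs <- 0; boff <- 0; bseg <- 1L
    for (k in seq_len(nseg)) {
      a <- nodes[k, ]; b <- nodes[k + 1, ]
      ab <- b - a
      t <- sum((p - a) * ab) / sum(ab^2)
      t <- min(max(t, 0), 1)
      foot <- a + t * ab
      d2 <- sum((p - foot)^2)
      if (d2 < best) {
        best <- d2
        bs <- axis$cum_len[k] + t * axis$seg_len[k]
        tang <- ab / axis$seg_len[k]
        v <- p - foot
        boff <- tang[1] * v[2] - tang[2] * v[1]
        bseg <- k
      }
    }
    s[i] <- bs; off[i] <- boff; dist[i] <- sqrt(best); segi[i] <- bseg
  }
  tibble::tibble(s = s, offset = off, dist = dist, segment = segi)
}

#' Arc-length position of a point along the midvein
#'
#' The point is orthogonally projected onto the nearest axis segment
#' (clamped to the segment ends); the returned `s` is the cumulative arc
#' length from the lamina base to the projection foot, in the same units as
#' the coordinates.
#'
#' @param axis a [midvein_axis()].
#' @param point numeric length-2 vector `(x, y)`, or a two-column matrix of
#'   points.
#' @return numeric vector of axial positions in `[0, axis length]`.
#' @export
axial_position <- function(axis, point) {
  if (is.null(dim(point))) point <- matrix(point, ncol = 2, byrow = TRUE)
  project_onto_axis(axis, point)$s
}

#' Assign left/right side labels to vein origins
#'
#' The side is read off the sign of the cross product of the local axis
#' tangent (base to tip) with the offset vector from the projection foot to
#' the origin: positive cross product = `"left"`, negative = `"right"`.
#' Origins lying exactly on the axis (offset below `tol` times the axis
#' length) carry no side information; they are flagged `excluded` and a
#' warning names how many were dropped.
#'
#' @param axis a [midvein_axis()].
#' @param origins data frame with columns `x`, `y` (one row per vein
#'   origin); other columns are carried through.
#' @param tol relative offset tolerance for "on the axis" (default 1e-9).
#' @return `origins` with added columns `s` (axial position), `side`
#'   (`"left"`/`"right"`, `NA` when excluded) and `excluded` (logical).
#' @export
assign_sides <- function(axis, origins, tol = 1e-9) {
  origins <- tibble::as_tibble(origins)
  pr <- project_onto_axis(axis, origins[, c("x", "y")])
  eps <- tol * axis$length
  excluded <- abs(pr$offset) <= eps
  side <- ifelse(pr$offset > 0, "left", "right")
  side[excluded] <- NA_character_
  if (any(excluded))
    warning(sprintf("%d origin(s) lie on the midvein axis and were excluded",
                    sum(excluded)))
  origins$s <- pr$s
  origins$side <- side
  origins$excluded <- excluded
  origins
}

#' Order vein origins along the midvein
#'
#' Sorts ascending by axial position `s`; exact ties are broken by side and
#' then by input order, deterministically, and both members of an exactly
#' opposite pair are retained. A 0-based `index` column is (re)assigned.
#'
#' @param origins data frame with columns `s` and `side` (from
#'   [assign_sides()] or supplied directly).
#' @return the ordered origins with column `index` in `0..n-1`.
#' @export
order_along_midvein <- function(origins) {
  origins <- tibble::as_tibble(origins)
  stopifnot("s" %in% names(origins))
  ord <- order(origins$s, origins$side %||% seq_len(nrow(origins)),
               seq_len(nrow(origins)))
  out <- origins[ord, ]
  out$index <- seq_len(nrow(out)) - 1L
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spacing ratio r for every lateral vein
#'
#' For each vein origin, `d_same` is the distance to the nearest origin on
#' the same side strictly apical of it (`s' > s`), and `d_opposite` the
#' distance to the nearest origin on the opposite side apical of or
#' coincident with it (`s' >= s`, so an exactly opposite partner gives
#' `d_opposite = 0`). The ratio `r = d_opposite / d_same` characterises the
#' local arrangement: r near 0.5 is alternate-like, r near 0 or 1
#' opposite-like, and r > 1 marks the irregular pattern of two successive
#' same-side veins. Origins missing either apical neighbour (the most
#' apical vein on each side) have no defined ratio.
#'
#' @param origins ordered, side-labelled origins (see
#'   [order_along_midvein()]); rows with `excluded = TRUE` or `NA` side are
#'   dropped first. Columns `x`, `y` are required for the euclidean metric.
#' @param metric `"euclidean"` (straight-line distance between bifurcation
#'   points, the default) or `"axial"` (arc-length difference `|s' - s|`).
#' @param leaf_id leaf identifier stamped on the output (default taken from
#'   an `leaf_id` column if present).
#' @return a tibble of ratio records: `leaf_id`, `vein_index`, `side`, `s`,
#'   `d_opposite`, `d_same`, `r`, `defined`, `irregular`.
#' @export
compute_ratios <- function(origins, metric = c("euclidean", "axial"),
                           leaf_id = NULL) {
  metric <- match.arg(metric)
  origins <- tibble::as_tibble(origins)
  if (is.null(leaf_id))
    leaf_id <- if ("leaf_id" %in% names(origins) && nrow(origins) > 0)
      origins$leaf_id[1] else NA_character_
  if ("excluded" %in% names(origins)) origins <- origins[!origins$excluded, ]
  origins <- origins[!is.na(origins$side), ]
  origins <- order_along_midvein(origins)
  n <- nrow(origins)
  dist_to <- function(i, j) {
    if (metric == "axial") abs(origins$s[j] - origins$s[i])
    else sqrt((origins$x[j] - origins$x[i])^2 + (origins$y[j] - origins$y[i])^2)
  }
  d_opp <- d_same <- r <- rep(NA_real_, n)
  defined <- rep(FALSE, n)
  dup <- rep(FALSE, n)
  for (sd_ in unique(origins$side)) {
    idx <- which(origins$side == sd_)
    dup[idx] <- duplicated(origins$s[idx]) |
      duplicated(origins$s[idx], fromLast = TRUE)
  }
  if (any(dup))
    warning(sprintf(
      "leaf %s: %d origin(s) share a same-side position (d_same = 0); records invalid",
      leaf_id, sum(dup)))
  for (i in seq_len(n)) {
    if (dup[i]) next
    same <- which(origins$side == origins$side[i] & origins$s > origins$s[i])
    opp <- which(origins$side != origins$side[i] & origins$s >= origins$s[i])
    if (length(same) == 0 || length(opp) == 0) next
    js <- same[which.min(origins$s[same])]
    jo <- opp[which.min(origins$s[opp])]
    ds <- dist_to(i, js)
    dop <- dist_to(i, jo)
    if (ds == 0) {
      warning(sprintf("leaf %s: duplicate same-side position at s = %g; record invalid",
                      leaf_id, origins$s[i]))
      next
    }
    d_same[i] <- ds; d_opp[i] <- dop; r[i] <- dop / ds
    defined[i] <- TRUE
  }
  tibble::tibble(
    leaf_id = leaf_id,
    vein_index = origins$index,
    side = origins$side,
    s = origins$s,
    d_opposite = d_opp,
    d_same = d_same,
    r = r,
    defined = defined,
    irregular = defined & !is.na(r) & r > 1)
}

#' Full per-leaf pipeline: annotations to ratio records
#'
#' Builds the midvein axis from the axis annotations, projects the vein
#' origins, assigns sides, orders along the midvein and computes the
#' spacing ratios.
#'
#' @param leaf a leaf record: a list with elements `leaf_id`, `axis` (a
#'   [midvein_axis()] or node matrix) and `origins` (data frame with `x`,
#'   `y`, optionally a trusted `side` column).
#' @param metric distance metric passed to [compute_ratios()].
#' @param use_given_sides if `TRUE` and `leaf$origins$side` exists, trust
#'   the supplied side labels instead of recomputing them geometrically.
#' @return tibble of ratio records (see [compute_ratios()]).
#' @export
leaf_ratios <- function(leaf, metric = c("euclidean", "axial"),
                        use_given_sides = FALSE) {
  metric <- match.arg(metric)
  axis <- if (inherits(leaf$axis, "midvein_axis")) leaf$axis
          else midvein_axis(leaf$axis)
  origins <- tibble::as_tibble(leaf$origins)
  if (use_given_sides && "side" %in% names(origins)) {
    origins$s <- axial_position(axis, as.matrix(origins[, c("x", "y")]))
    origins$excluded <- FALSE
  } else {
    origins <- assign_sides(axis, origins)
  }
  compute_ratios(origins, metric = metric, leaf_id = leaf$leaf_id)
}
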