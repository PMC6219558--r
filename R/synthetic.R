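#' Parameters of the synthetic vein-arrangement generator
#'
#' The generator emulates ordered left/right lateral-vein origins along a
#' straight midvein. A single phase parameter `phase` (delta) spans the
#' continuum of arrangement archetypes: right-side origins are offset from
#' their left partners by `phase` times the local internode, so `phase = 0`
#' is an ideal opposite arrangement (exactly paired origins, spacing
#' ratios at 0 and 1) and `phase = 0.5` an ideal alternate one (every
#' ratio 0.5). Internodes are truncated-normal (resampled until positive)
#' with the stated mean and coefficient of variation; independent Gaussian
#' jitter perturbs every axial position; with probability `irregular_prob`
#' per vein an extra origin is inserted on the same side midway to the
#' next same-side origin, reproducing the irregular two-successive-
#' same-side-veins pattern (r > 1).
#'
#' @param n_pairs number of left/right vein pairs (>= 2).
#' @param internode_mean mean axial spacing between successive same-side
#'   origins, in coordinate units (default 100, think pixels).
#' @param internode_cv coefficient of variation of internodes (default
#'   0.2).
#' @param phase axial offset of right-side origins as a fraction of the
#'   local internode, in `[0, 0.5]`.
#' @param jitter_sd sd of additive axial noise, as a fraction of the mean
#'   internode (default 0.05).
#' @param irregular_prob per-vein probability of an extra same-side
#'   insertion, in `[0, 1)`.
#' @param lateral_offset perpendicular distance of origins from the axis,
#'   in coordinate units (default 2, i.e. 2% of the default internode, so
#'   euclidean and axial distances nearly coincide).
#' @param seed optional RNG seed.
#' @return a list of class `"synthetic_params"`.
#' @export
synthetic_params <- function(n_pairs = 10L, internode_mean = 100,
                             internode_cv = 0.2, phase = 0.5,
                             jitter_sd = 0.05, irregular_prob = 0,
                             lateral_offset = 2, seed = NULL) {
  stopifnot(n_pairs >= 2, internode_mean > 0, internode_cv >= 0,
            phase >= 0, phase <= 0.5, jitter_sd >= 0,
            irregular_prob >= 0, irregular_prob < 1, lateral_offset >= 0)
  structure(list(n_pairs = as.integer(n_pairs),
                 internode_mean = internode_mean,
                 internode_cv = internode_cv, phase = phase,
                 jitter_sd = jitter_sd, irregular_prob = irregular_prob,
                 lateral_offset = lateral_offset, seed = seed),
            class = "synthetic_params")
}

# positive truncated-normal internode draws (resample until positive)
draw_internodes <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, cv * mean)
  while (any(out <= 0))
    out[out <= 0] <- stats::rnorm(sum(out <= 0), mean, cv * mean)
  out
}

#' Generate one synthetic leaf (or leaflet)
#'
#' Constructs a straight vertical midvein with left origins at cumulative
#' internode positions and right origins offset by `phase` times the local
#' internode, applies jitter and irregular same-side insertions, and
#' returns a leaf record usable by [leaf_ratios()] together with
#' ground-truth labels (the noiseless per-vein ratio and the insertion
#' events with their relative positions).
#'
#' All randomness comes from the seeded RNG; the same `params` (with a
#' seed) give bit-identical output.
#'
#' @param params a [synthetic_params()] object.
#' @param leaf_id identifier for the generated leaf.
#' @param leaflet_position one of `"simple"`, `"terminal"`, `"left"`,
#'   `"right"`.
#' @return a list of class `"synthetic_leaf"`: `leaf_id`, `axis`,
#'   `origins` (columns `x`, `y`, `side`, `s`, `inserted`, `true_r`),
#'   `leaflet_position`, `params`, `insertions` (tibble of irregular-
#'   insertion events: `side`, `s`, `rel_pos`).
#' @export
generate_arrangement <- function(params, leaf_id = "synthetic",
                                 leaflet_position = c("simple", "terminal",
                                                      "left", "right")) {
  stopifnot(inherits(params, "synthetic_params"))
  leaflet_position <- match.arg(leaflet_position)
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)

  I <- draw_internodes(p$n_pairs + 1L, p$internode_mean, p$internode_cv)
  s_left <- cumsum(I[seq_len(p$n_pairs)])
  s_right <- s_left + p$phase * I[2:(p$n_pairs + 1L)]

  # noiseless ground-truth ratios (apical boundary veins undefined)
  true_left <- rep(p$phase, p$n_pairs)
  true_left[p$n_pairs] <- NA_real_
  k <- seq_len(p$n_pairs - 1L)
  true_right <- c((1 - p$phase) * I[k + 1L] /
                    (I[k + 1L] + p$phase * (I[k + 2L] - I[k + 1L])),
                  NA_real_)

  jit <- p$jitter_sd * p$internode_mean
  if (jit > 0) {
    s_left <- s_left + stats::rnorm(p$n_pairs, 0, jit)
    s_right <- s_right + stats::rnorm(p$n_pairs, 0, jit)
    s_left <- pmax(s_left, 0)
    s_right <- pmax(s_right, 0)
  }

  origins <- tibble::tibble(
    side = rep(c("left", "right"), each = p$n_pairs),
    s = c(s_left, s_right),
    inserted = FALSE,
    true_r = c(true_left, true_right))

  ins <- tibble::tibble(side = character(), s = numeric())
  if (p$irregular_prob > 0) {
    for (sd_ in c("left", "right")) {
      ss <- sort(origins$s[origins$side == sd_])
      if (length(ss) >= 2) {
        hit <- stats::runif(length(ss) - 1L) < p$irregular_prob
        if (any(hit)) {
          mid <- (ss[-length(ss)][hit] + ss[-1][hit]) / 2
          ins <- rbind(ins, tibble::tibble(side = sd_, s = mid))
        }
      }
    }
    if (nrow(ins) > 0)
      origins <- rbind(origins,
                       tibble::tibble(side = ins$side, s = ins$s,
                                      inserted = TRUE, true_r = NA_real_))
  }

  total_len <- max(origins$s) + p$internode_mean
  axis <- midvein_axis(rbind(c(0, 0), c(0, total_len)))
  origins$x <- ifelse(origins$side == "left", -p$lateral_offset,
                      p$lateral_offset)
  origins$y <- origins$s
  ins$rel_pos <- if (nrow(ins)) ins$s / total_len else numeric()

  structure(
    list(leaf_id = leaf_id, axis = axis,
         origins = origins[, c("x", "y", "side", "s", "inserted", "true_r")],
         leaflet_position = leaflet_position, params = p,
         insertions = ins),
    class = c("synthetic_leaf", "list"))
}

# place an extra origin on `side` at relative position `rel_pos` of an
# existing synthetic leaflet (used for mirrored irregular insertions)
insert_irregular_at <- function(leaf, side, rel_pos) {
  s <- rel_pos * leaf$axis$length
  x <- if (side == "left") -leaf$params$lateral_offset else
    leaf$params$lateral_offset
  leaf$origins <- rbind(
    leaf$origins,
    tibble::tibble(x = x, y = s, side = side, s = s, inserted = TRUE,
                   true_r = NA_real_))
  leaf$insertions <- rbind(leaf$insertions,
                           tibble::tibble(side = side, s = s,
                                          rel_pos = rel_pos))
  leaf
}

#' Generate a synthetic ternate compound leaf
#'
#' Draws three leaflets (terminal, left-positioned, right-positioned)
#' independently from the same parameters. With
#' `mirrored_irregulars = TRUE` the left and right leaflets receive
#' irregular insertions at identical relative positions (0 = base, 1 =
#' tip) with sides mirrored (an insertion on the left side of the
#' left-positioned leaflet appears on the right side of the
#' right-positioned leaflet), emulating a systematic, bilaterally
#' symmetric rule; otherwise insertion events on the two leaflets are
#' independent.
#'
#' @param params a [synthetic_params()] object; its `irregular_prob`
#'   governs the insertion draws.
#' @param mirrored_irregulars logical (default `FALSE`).
#' @param forced_irregulars optional tibble with columns `side`,
#'   `rel_pos`: insertion events applied to the left-positioned leaflet
#'   (and mirrored onto the right one when `mirrored_irregulars = TRUE`)
#'   regardless of `irregular_prob`.
#' @param compound_leaf_id identifier; leaflet ids get `_T`/`_L`/`_R`
#'   suffixes.
#' @return a list of class `"synthetic_compound_leaf"` with elements
#'   `compound_leaf_id`, `terminal`, `left`, `right`.
#' @export
generate_compound_leaf <- function(params, mirrored_irregulars = FALSE,
                                   forced_irregulars = NULL,
                                   compound_leaf_id = "compound") {
  stopifnot(inherits(params, "synthetic_params"))
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)
  p$seed <- NULL

  terminal <- generate_arrangement(p, paste0(compound_leaf_id, "_T"),
                                   "terminal")
  if (!mirrored_irregulars) {
    left <- generate_arrangement(p, paste0(compound_leaf_id, "_L"), "left")
    right <- generate_arrangement(p, paste0(compound_leaf_id, "_R"), "right")
    if (!is.null(forced_irregulars))
      for (i in seq_len(nrow(forced_irregulars)))
        left <- insert_irregular_at(left, forced_irregulars$side[i],
                                    forced_irregulars$rel_pos[i])
  } else {
    # draw both leaflets without spontaneous insertions, then apply one
    # shared set of insertion events, sides mirrored
    p0 <- p; p0$irregular_prob <- 0
    left <- generate_arrangement(p0, paste0(compound_leaf_id, "_L"), "left")
    right <- generate_arrangement(p0, paste0(compound_leaf_id, "_R"), "right")
    events <- tibble::tibble(side = character(), rel_pos = numeric())
    if (p$irregular_prob > 0) {
      for (sd_ in c("left", "right")) {
        ss <- sort(left$origins$s[left$origins$side == sd_])
        hit <- stats::runif(length(ss) - 1L) < p$irregular_prob
        if (any(hit)) {
          mid <- (ss[-length(ss)][hit] + ss[-1][hit]) / 2
          events <- rbind(events,
                          tibble::tibble(side = sd_,
                                         rel_pos = mid / left$axis$length))
        }
      }
    }
    if (!is.null(forced_irregulars))
      events <- rbind(events,
                      forced_irregulars[, c("side", "rel_pos")])
    mirror_side <- c(left = "right", right = "left")
    for (i in seq_len(nrow(events))) {
      left <- insert_irregular_at(left, events$side[i], events$rel_pos[i])
      right <- insert_irregular_at(right,
                                   unname(mirror_side[events$side[i]]),
                                   events$rel_pos[i])
    }
  }
  structure(list(compound_leaf_id = compound_leaf_id, terminal = terminal,
                 left = left, right = right),
            class = c("synthetic_compound_leaf", "list"))
}

#' Convert a synthetic leaf to a point-annotation table
#'
#' Emits the same `leaf_id`/`role`/`x`/`y` rows the io module reads, so the
#' file-based pipeline can be exercised end to end on generated data.
#'
#' @param leaf a `"synthetic_leaf"` (or any leaf record with `axis` and
#'   `origins`).
#' @return tibble with columns `leaf_id`, `role`, `x`, `y`.
#' @export
as_point_annotations <- function(leaf) {
  nodes <- leaf$axis$nodes
  n <- nrow(nodes)
  roles <- c("midvein_base",
             if (n > 2) rep("midvein_node", n - 2),
             "midvein_tip")
  tibble::tibble(
    leaf_id = leaf$leaf_id,
    role = c(roles, rep("vein_origin", nrow(leaf$origins))),
    x = c(nodes[, 1], leaf$origins$x),
    y = c(nodes[, 2], leaf$origins$y))
}
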