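#' Pool a species' spacing ratios and score departure from unimodality
#'
#' Runs the per-leaf geometry pipeline over a set of leaves (or leaflets)
#' of one species, pools all defined spacing ratios, and characterises the
#' pooled distribution with a Monte-Carlo dip test and a kernel-density
#' summary. A leaflet-position filter reproduces the terminal-only /
#' left / right / all-positions comparison used to check that a leaflet
#' can be analysed as if it were a leaf.
#'
#' @param leaves list of leaf records (see [leaf_ratios()]); synthetic
#'   leaves from [generate_arrangement()] work directly. Each may carry a
#'   `leaflet_position` tag (`"simple"`, `"terminal"`, `"left"`,
#'   `"right"`).
#' @param code species code stamped on the result.
#' @param leaflet_filter `"all"` or one of the leaflet positions.
#' @param metric distance metric for [compute_ratios()].
#' @param use_given_sides trust side labels carried by the origins (e.g.
#'   synthetic ground truth) instead of recomputing them geometrically.
#' @param truncate_r optional upper cutoff: discard ratios above it before
#'   testing (display-variant of the pooled analysis; the primary analysis
#'   keeps the full pool).
#' @param dip_reps Monte-Carlo replicates for the dip p-value.
#' @param seed RNG seed for the dip null draws.
#' @return a list of class `"species_result"`: `code`, `n_leaves`,
#'   `n_veins`, `r_values`, `n_irregular`, `dip` (a `vein_dip`), `density`
#'   (a `vein_density`), `ratios` (per-vein table), `empty`.
#' @export
analyze_species <- function(leaves, code = NA_character_,
                            leaflet_filter = c("all", "terminal", "left",
                                               "right"),
                            metric = c("euclidean", "axial"),
                            use_given_sides = FALSE,
                            truncate_r = NULL,
                            dip_reps = 10000L, seed = NULL) {
  leaflet_filter <- match.arg(leaflet_filter)
  metric <- match.arg(metric)
  if (leaflet_filter != "all") {
    pos <- vapply(leaves, function(l) l$leaflet_position %||% "simple",
                  character(1))
    leaves <- leaves[pos == leaflet_filter]
  }
  if (length(leaves) == 0)
    return(structure(list(code = code, n_leaves = 0L, n_veins = 0L,
                          r_values = numeric(), n_irregular = 0L,
                          dip = NULL, density = NULL, ratios = NULL,
                          empty = TRUE),
                     class = "species_result"))
  ratios <- do.call(rbind, lapply(leaves, leaf_ratios, metric = metric,
                                  use_given_sides = use_given_sides))
  r <- ratios$r[ratios$defined]
  if (!is.null(truncate_r)) r <- r[r <= truncate_r]
  if (length(r) == 0)
    return(structure(list(code = code, n_leaves = length(leaves),
                          n_veins = 0L, r_values = numeric(),
                          n_irregular = 0L, dip = NULL, density = NULL,
                          ratios = ratios, empty = TRUE),
                     class = "species_result"))
  structure(
    list(code = code, n_leaves = length(leaves), n_veins = length(r),
         r_values = r, n_irregular = sum(r > 1),
         dip = dip_test(r, reps = dip_reps, seed = seed),
         density = density_summary(r),
         ratios = ratios, empty = FALSE),
    class = "species_result")
}

#' @export
print.species_result <- function(x, ...) {
  cat(sprintf("Species %s: %d leaves, %d ratios, %d irregular (r > 1)\n",
              x$code, x$n_leaves, x$n_veins, x$n_irregular))
  if (!x$empty) {
    cat(sprintf("  dip = %.5g, p = %.4g; density modes at %s\n",
                x$dip$dip, x$dip$p_value,
                paste(signif(x$density$modes, 3), collapse = ", ")))
  }
  invisible(x)
}

#' Flatten species results to a tidy table
#'
#' @param results list of `species_result` objects.
#' @return tibble with one row per species: counts, dip statistic and
#'   p-value, number of density modes.
#' @export
species_result_table <- function(results) {
  do.call(rbind, lapply(results, function(s) tibble::tibble(
    code = s$code, n_leaves = s$n_leaves, n_veins = s$n_veins,
    n_irregular = s$n_irregular,
    dip = if (s$empty) NA_real_ else s$dip$dip,
    dip_p = if (s$empty) NA_real_ else s$dip$p_value,
    n_modes = if (s$empty) NA_integer_ else length(s$density$modes))))
}

#' Compare departure-from-unimodality between species groups
#'
#' Brunner-Munzel test on the species-level dip p-values split by a
#' two-level grouping variable (stem phyllotaxis: alternate vs. opposite,
#' or life form: woody vs. herbaceous). Each species contributes exactly
#' one p-value; the first factor level (alphabetical: `alternate`,
#' `herbaceous`) is the `x` sample.
#'
#' @param results list of `species_result` objects or a table from
#'   [species_result_table()] (needs columns `code` and `dip_p`).
#' @param meta species metadata (see [read_species_metadata()]).
#' @param grouping `"phyllotaxis"` or `"life_form"`.
#' @return the [brunner_munzel()] result, with added fields `grouping`,
#'   `groups` (level names) and `group_n`.
#' @export
compare_groups <- function(results, meta,
                           grouping = c("phyllotaxis", "life_form")) {
  grouping <- match.arg(grouping)
  tab <- if (is.data.frame(results)) results else species_result_table(results)
  if (!all(c("code", "dip_p") %in% names(tab)))
    stop("`results` must provide columns code and dip_p")
  m <- merge(tab, as.data.frame(meta)[, c("code", grouping)], by = "code")
  if (nrow(m) < nrow(tab))
    warning("some species codes missing from metadata were dropped")
  g <- m[[grouping]]
  levels <- sort(unique(g))
  if (length(levels) != 2)
    stop(sprintf("grouping `%s` must have exactly 2 levels, got: %s",
                 grouping, paste(levels, collapse = ", ")))
  sizes <- table(g)
  if (any(sizes < 2))
    stop(sprintf("each group needs >= 2 species (got %s)",
                 paste(sprintf("%s = %d", names(sizes), sizes),
                       collapse = ", ")))
  bm <- brunner_munzel(m$dip_p[g == levels[1]], m$dip_p[g == levels[2]])
  bm$grouping <- grouping
  bm$groups <- levels
  bm$group_n <- as.integer(sizes[levels])
  bm
}

#' Relative position of a point along the midvein
#'
#' Arc-length position divided by total axis length: 0 = lamina base,
#' 1 = tip.
#'
#' @param axis a [midvein_axis()].
#' @param point `(x, y)` vector or two-column matrix of points.
#' @return numeric vector in `[0, 1]`.
#' @export
relative_position <- function(axis, point) {
  if (axis$length <= 0) stop("degenerate axis of zero length")
  axial_position(axis, point) / axis$length
}

#' Mirror-image analysis of irregular cases on leaflet pairs
#'
#' For each compound leaf, maps every irregular (r > 1) case on the left-
#' and right-positioned leaflets to its relative position (0 = base, 1 =
#' tip) and to the signed pair coordinate in `[-1, 1]` used to display
#' leaflet pairs side by side: left-positioned leaflet cases at minus the
#' relative position (left tip = -1), right-positioned at plus (right tip
#' = +1), both bases at 0. A case is `mirror_matched` when the opposite
#' leaflet has an irregular case within `tau` of the same relative
#' position. The per-pair verdict is `"mirror"` only if both leaflets have
#' at least one irregular case and every case on either leaflet is
#' matched; pairs without any irregular case are excluded from verdicts.
#'
#' @param compound_leaves list of compound-leaf objects (elements `left`,
#'   `right`, `compound_leaf_id`); [generate_compound_leaf()] output works
#'   directly.
#' @param tau matching tolerance as a fraction of leaflet length
#'   (default 0.1).
#' @param metric,use_given_sides passed to [leaf_ratios()].
#' @return list with `records` (one row per irregular case:
#'   `compound_leaf_id`, `side`, `r`, `position`, `paired_coordinate`,
#'   `mirror_matched`), `verdicts` (one row per pair with >= 1 irregular
#'   case) and `tau`.
#' @export
leaflet_pair_analysis <- function(compound_leaves, tau = 0.1,
                                  metric = c("euclidean", "axial"),
                                  use_given_sides = FALSE) {
  metric <- match.arg(metric)
  records <- list()
  verdicts <- list()
  for (cl in compound_leaves) {
    if (is.null(cl$left) || is.null(cl$right)) {
      warning(sprintf("compound leaf %s: unpaired leaflet, skipped",
                      cl$compound_leaf_id %||% "<unnamed>"))
      next
    }
    irr_pos <- function(leaf) {
      rr <- leaf_ratios(leaf, metric = metric,
                        use_given_sides = use_given_sides)
      rr <- rr[rr$irregular, ]
      axis <- if (inherits(leaf$axis, "midvein_axis")) leaf$axis
              else midvein_axis(leaf$axis)
      tibble::tibble(r = rr$r, position = rr$s / axis$length)
    }
    L <- irr_pos(cl$left)
    R <- irr_pos(cl$right)
    if (nrow(L) + nrow(R) == 0) next  # nothing to match
    matched_in <- function(pos, other) {
      if (length(other) == 0) rep(FALSE, length(pos))
      else vapply(pos, function(p) any(abs(other - p) <= tau), logical(1))
    }
    L$mirror_matched <- matched_in(L$position, R$position)
    R$mirror_matched <- matched_in(R$position, L$position)
    rec <- rbind(
      if (nrow(L)) tibble::tibble(compound_leaf_id = cl$compound_leaf_id,
                                  side = "left_leaflet", r = L$r,
                                  position = L$position,
                                  paired_coordinate = -L$position,
                                  mirror_matched = L$mirror_matched),
      if (nrow(R)) tibble::tibble(compound_leaf_id = cl$compound_leaf_id,
                                  side = "right_leaflet", r = R$r,
                                  position = R$position,
                                  paired_coordinate = R$position,
                                  mirror_matched = R$mirror_matched))
    records[[length(records) + 1L]] <- rec
    verdicts[[length(verdicts) + 1L]] <- tibble::tibble(
      compound_leaf_id = cl$compound_leaf_id,
      n_left = nrow(L), n_right = nrow(R),
      verdict = if (nrow(L) >= 1 && nrow(R) >= 1 &&
                    all(c(L$mirror_matched, R$mirror_matched)))
        "mirror" else "not_mirror")
  }
  list(records = if (length(records)) do.call(rbind, records) else
         tibble::tibble(compound_leaf_id = character(), side = character(),
                        r = numeric(), position = numeric(),
                        paired_coordinate = numeric(),
                        mirror_matched = logical()),
       verdicts = if (length(verdicts)) do.call(rbind, verdicts) else
         tibble::tibble(compound_leaf_id = character(), n_left = integer(),
                        n_right = integer(), verdict = character()),
       tau = tau)
}
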