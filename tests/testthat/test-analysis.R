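make_leaves <- function(n_leaves, phase, jitter_sd = 0.05, n_pairs = 9,
                        irregular_prob = 0, seed_base = 0) {
  lapply(seq_len(n_leaves), function(i)
    generate_arrangement(
      synthetic_params(n_pairs = n_pairs, phase = phase,
                       jitter_sd = jitter_sd,
                       irregular_prob = irregular_prob,
                       seed = seed_base + i),
      leaf_id = paste0("leaf", i)))
}

test_that("species pooling recovers alternate-like and opposite-like archetypes", {
  alt <- analyze_species(make_leaves(20, phase = 0.5, jitter_sd = 0.02,
                                     seed_base = 100),
                         code = "ALT", dip_reps = 999, seed = 1)
  expect_length(alt$density$modes, 1)
  expect_lt(abs(alt$density$modes - 0.5), 0.05)
  expect_gt(alt$dip$p_value, 0.05)

  opp <- analyze_species(make_leaves(20, phase = 0.02, jitter_sd = 0.02,
                                     seed_base = 200),
                         code = "OPP", dip_reps = 999, seed = 1)
  expect_gte(length(opp$density$modes), 2)
  expect_lt(min(opp$density$modes), 0.1)
  expect_gt(max(opp$density$modes), 0.9)
  expect_lt(opp$dip$p_value, 0.05)

  expect_equal(alt$n_veins, length(alt$r_values))
  expect_equal(alt$n_irregular, sum(alt$r_values > 1))
})

test_that("pooling is invariant to the order of leaves", {
  leaves <- make_leaves(10, phase = 0.3, seed_base = 300)
  a <- analyze_species(leaves, code = "X", dip_reps = 299, seed = 4)
  b <- analyze_species(rev(leaves), code = "X", dip_reps = 299, seed = 4)
  expect_identical(sort(a$r_values), sort(b$r_values))
  expect_identical(a$dip$dip, b$dip$dip)
  expect_identical(a$dip$p_value, b$dip$p_value)
})

test_that("the leaflet filter reproduces the position-subset design", {
  set.seed(40)
  p <- synthetic_params(n_pairs = 10, phase = 0.3, jitter_sd = 0.05)
  compounds <- lapply(1:6, function(i)
    generate_compound_leaf(p, compound_leaf_id = paste0("c", i)))
  leaflets <- unlist(lapply(compounds, function(cl)
    list(cl$terminal, cl$left, cl$right)), recursive = FALSE)
  all_pool <- analyze_species(leaflets, code = "Ame", dip_reps = 199, seed = 2)
  term <- analyze_species(leaflets, code = "Ame", leaflet_filter = "terminal",
                          dip_reps = 199, seed = 2)
  expect_equal(term$n_leaves, 6)
  expect_equal(all_pool$n_leaves, 18)
  # terminal-only ratios are a sub-multiset of the all-positions pool
  tab_all <- table(round(all_pool$r_values, 12))
  tab_term <- table(round(term$r_values, 12))
  expect_true(all(names(tab_term) %in% names(tab_all)))
  expect_true(all(tab_term <= tab_all[names(tab_term)]))
  # empty filter result is flagged, not an error
  simple <- make_leaves(3, phase = 0.4, seed_base = 500)
  empty <- analyze_species(simple, leaflet_filter = "terminal")
  expect_true(empty$empty)
})

test_that("terminal-only and all-position analyses give concordant verdicts", {
  # on mirrored-design ternate fixtures the dip verdict (p vs 0.05) from
  # terminal leaflets alone should agree with the all-positions verdict in
  # at least 90% of seeded runs, at both ends of the phase continuum
  for (phase in c(0.1, 0.5)) {
    agree <- 0L
    for (run in 1:50) {
      set.seed(1000 * phase + run)
      p <- synthetic_params(n_pairs = 11, phase = phase, jitter_sd = 0.05)
      compounds <- lapply(1:5, function(i)
        generate_compound_leaf(p, compound_leaf_id = paste0("c", i)))
      leaflets <- unlist(lapply(compounds, function(cl)
        list(cl$terminal, cl$left, cl$right)), recursive = FALSE)
      pt <- analyze_species(leaflets, leaflet_filter = "terminal",
                            dip_reps = 199, seed = run)$dip$p_value
      pa <- analyze_species(leaflets, leaflet_filter = "all",
                            dip_reps = 199, seed = run)$dip$p_value
      agree <- agree + ((pt < 0.05) == (pa < 0.05))
    }
    expect_gte(agree / 50, 0.9)
  }
})

test_that("group comparison uses one dip p-value per species and validates groups", {
  meta <- read_species_metadata()
  tab <- tibble::tibble(code = meta$code,
                        dip_p = seq(0.01, 0.99, length.out = 30))
  res <- compare_groups(tab, meta, grouping = "phyllotaxis")
  expect_equal(sum(res$group_n), 30)
  expect_equal(res$group_n, c(18L, 12L))
  expect_s3_class(res, "vein_bm")

  # identical p-values in both groups: relative effect exactly one half
  tied <- tibble::tibble(code = meta$code, dip_p = rep(c(0.2, 0.8), 15))
  # force identical multisets across groups
  tied$dip_p <- 0.5
  expect_equal(compare_groups(tied, meta, "life_form")$p_hat, 0.5)

  # a group with fewer than 2 species is refused
  small_meta <- meta[c(1, 2, 3), ]
  small_tab <- tab[tab$code %in% small_meta$code, ]
  expect_error(compare_groups(small_tab, small_meta, "phyllotaxis"), ">= 2")
})

test_that("relative positions run from 0 at the base to 1 at the tip", {
  axis <- midvein_axis(rbind(c(0, 0), c(0, 80)))
  expect_equal(relative_position(axis, c(0, 0)), 0)
  expect_equal(relative_position(axis, c(2, 80)), 1)
  expect_equal(relative_position(axis, c(-1, 40)), 0.5)
})

test_that("mirror verdicts separate mirrored from one-sided irregular cases", {
  p <- synthetic_params(n_pairs = 15, phase = 0.4, jitter_sd = 0.02,
                        irregular_prob = 0, seed = 61)
  forced <- tibble::tibble(side = "left", rel_pos = 0.45)
  mirrored <- generate_compound_leaf(p, mirrored_irregulars = TRUE,
                                     forced_irregulars = forced,
                                     compound_leaf_id = "mir")
  one_sided <- generate_compound_leaf(p, mirrored_irregulars = FALSE,
                                      forced_irregulars = forced,
                                      compound_leaf_id = "one")
  plain <- generate_compound_leaf(p, compound_leaf_id = "none")
  # tau = 0.2: an irregular case can surface at the inserted origin or at
  # its basal same-side predecessor, i.e. within one internode (~1/15) of
  # the insertion point on either leaflet
  res <- leaflet_pair_analysis(list(mirrored, one_sided, plain), tau = 0.2)
  expect_equal(sort(unique(res$records$compound_leaf_id)), c("mir", "one"))
  v <- res$verdicts
  expect_equal(v$verdict[v$compound_leaf_id == "mir"], "mirror")
  expect_equal(v$verdict[v$compound_leaf_id == "one"], "not_mirror")
  expect_false("none" %in% v$compound_leaf_id)
  # signed pair coordinate: left leaflet negative, right positive
  rec <- res$records
  expect_true(all(rec$paired_coordinate[rec$side == "left_leaflet"] <= 0))
  expect_true(all(rec$paired_coordinate[rec$side == "right_leaflet"] >= 0))
  expect_true(all(abs(rec$paired_coordinate) <= 1))
  expect_true(all(rec$r > 1))
})

test_that("the file pipeline reproduces the in-memory analysis deterministically", {
  leaves <- make_leaves(5, phase = 0.25, seed_base = 700)
  direct <- analyze_species(leaves, code = "SYN", dip_reps = 199, seed = 3)

  f <- withr::local_tempfile(fileext = ".csv")
  pts <- do.call(rbind, lapply(leaves, as_point_annotations))
  utils::write.csv(pts, f, row.names = FALSE)
  back <- points_to_leaves(read_points_csv(f))
  redo <- analyze_species(back, code = "SYN", dip_reps = 199, seed = 3)
  expect_equal(sort(redo$r_values), sort(direct$r_values), tolerance = 1e-12)
  expect_equal(redo$dip$p_value, direct$dip$p_value)

  # byte-identical result files on repeated runs
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_results(species_result_table(list(direct, redo)), f1)
  write_results(species_result_table(list(direct, redo)), f2)
  expect_identical(readLines(f1), readLines(f2))
})
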