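test_that("junctions recover the planted heterochromatin boundaries exactly", {
  g <- small_genome(seed = 17, n_no_junction_chroms = 1)
  j <- find_junctions(g$arms, g$het)
  m <- dplyr::left_join(j, g$truth, by = c("chrom", "arm"),
                        suffix = c("", "_truth"))
  expect_equal(m$junction, m$junction_truth)
  expect_true(all(m$junction_status[is.na(m$junction_truth)] ==
                    "no_junction"))
})

test_that("planted contiguous tilings yield gap-free complete panels", {
  g <- small_genome(seed = 23)
  panels <- design_panels(g)
  designable <- panels[panels$status %in% c("complete", "incomplete_coverage"),
                       , drop = FALSE]
  expect_true(all(panels$status == "complete"))
  for (i in seq_len(nrow(panels))) {
    cl <- panels$clones[[i]]
    expect_gte(nrow(cl), 3)
    expect_lte(nrow(cl), 7)
    # consecutive clones must abut or overlap within the gap bound
    if (nrow(cl) > 1) {
      expect_true(all(cl$d0[-1] <= cl$d1[-nrow(cl)] + 50000))
    }
    # the tiled span covers the target from the proximal clone edge
    expect_gte(cl$d1[nrow(cl)] - cl$d0[1], 700000)
  }
})

test_that("panel edge states: no junction, empty arm, fully screened out", {
  arm <- arm_chrT()
  lib <- rand_tiling_library(n = 8)
  nj <- select_core_panel(arm, NA_real_, lib)
  expect_equal(nj$status, "incomplete_no_junction")

  none <- select_core_panel(arm, 1e7, lib[0, ])
  expect_equal(none$status, "unavailable_no_map")
  expect_equal(none$n_clones, 0L)

  blocked <- dplyr::mutate(lib, label = "cross_hybridizing")
  sd <- select_core_panel(arm, 1e7, blocked)
  expect_equal(sd$status, "incomplete_segdup")
})

test_that("a distant proximal clone is reported at its junction distance", {
  arm <- arm_chrT()
  # nearest eligible clone starts 0.76 Mb beyond the junction
  lib <- tibble::tibble(
    name = c("far1", "far2", "far3", "far4", "far5"),
    chrom = "chrT",
    start = 1e7 + 7.6e5 + c(0, 1.8e5, 3.6e5, 5.4e5, 7.2e5),
    end = 1e7 + 7.6e5 + c(0, 1.8e5, 3.6e5, 5.4e5, 7.2e5) + 1.9e5,
    alternates = rep(list(interval_tbl(character(), numeric(), numeric())), 5),
    segdup_fraction = 0, label = "specific")
  p <- select_core_panel(arm, 1e7, lib)
  expect_equal(p$d_het_prox_mb, 0.76)
})

test_that("greedy selection size equals the exhaustive minimum cover", {
  withr::with_seed(31, {
    arm <- arm_chrT()
    for (i in 1:60) {
      lib <- rand_tiling_library(n = sample(6:12, 1))
      p <- select_core_panel(arm, 1e7, lib)
      expect_equal(p$status, "complete")
      expect_equal(p$n_clones, oracle_min_cover(lib, 1e7))
    }
  })
})

test_that("enlarging the gap tolerance never increases the clone count", {
  withr::with_seed(37, {
    arm <- arm_chrT()
    for (i in 1:30) {
      lib <- rand_tiling_library(n = sample(6:12, 1))
      n_small <- select_core_panel(arm, 1e7, lib, max_gap_bp = 2e4)$n_clones
      n_big <- select_core_panel(arm, 1e7, lib, max_gap_bp = 1e5)$n_clones
      if (n_small > 0 && n_big > 0) expect_lte(n_big, n_small)
    }
  })
})

test_that("panel stats floor the junction distance and use outer clone edges", {
  arm <- arm_chrT()
  # single clone straddling the junction
  lib <- tibble::tibble(
    name = "solo", chrom = "chrT", start = 1e7 - 2e4, end = 1e7 + 8e5,
    alternates = list(interval_tbl(character(), numeric(), numeric())),
    segdup_fraction = 0, label = "specific")
  p <- select_core_panel(arm, 1e7, lib)
  st <- panel_stats(p)
  expect_equal(st$d_het_prox_mb, 0)
  expect_equal(st$core_span_mb, round_half_up((8e5 + 2e4) / 1e6, 2))
})

test_that("the published coverage table summarizes to the reported totals", {
  tab <- read_core_panel_table()
  s <- summarize_panels(tab)
  expect_equal(s$n_panels, 43)
  expect_equal(s$n_complete, 35)
  expect_equal(s$n_with_span, 42)
  expect_equal(s$mean_core_span_mb, 0.73)

  empty <- summarize_panels(tab[0, ])
  expect_equal(empty$n_panels, 0)
  expect_equal(empty$n_complete, 0)
})

test_that("the human arm table exposes 43 designable arms", {
  arms <- human_arm_table()
  expect_equal(nrow(arms), 48)
  expect_equal(sum(!arms$acrocentric), 43)
})

test_that("panel sets tidy to clone rows and glance to the set summary", {
  g <- small_genome(seed = 29)
  p <- design_panels(g)
  td <- generics::tidy(p)
  expect_true(all(c("arm_id", "name", "d0", "d1") %in% names(td)))
  expect_equal(sum(p$n_clones), nrow(td))
  gl <- generics::glance(p)
  expect_equal(gl$n_panels, nrow(p))
})
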