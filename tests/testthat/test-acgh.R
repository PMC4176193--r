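test_that("segment calls follow the log2 threshold and carry sizes", {
  segs <- tibble::tibble(
    chrom = c("chr4", "chr4", "chr11"),
    start = c(45754992, 1e6, 50378743),
    end = c(61126608, 2e6, 63743029),
    mean_log2 = c(0.52, 0.0, 0.55))
  out <- acgh_call(segs)
  expect_equal(out$call[out$start == 45754992], "gain")
  expect_equal(out$call[out$mean_log2 == 0], "normal")
  gain11 <- out[out$chrom == "chr11", ]
  expect_equal(width_mb(gain11, 1), 13.4)
  expect_equal(width_mb(out[out$chrom == "chr4" & out$call == "gain", ], 1),
               15.4)
  expect_equal(acgh_call(tibble::tibble(chrom = "chr1", start = 1, end = 2,
                                        mean_log2 = -0.4))$call, "loss")
})

test_that("overlapping gain segments raise a warning flag", {
  segs <- tibble::tibble(chrom = "chr2", start = c(1e6, 1.5e6),
                         end = c(2e6, 2.5e6), mean_log2 = 0.6)
  expect_warning(out <- acgh_call(segs), "overlapping gain")
  expect_true(all(out$flag_overlap))
})

test_that("aCGH refinement reproduces both published intersections", {
  fish4 <- tibble::tibble(chrom = "chr4", arm = "p", start = 44621297,
                          end = 45736237, basis = "flanking_probes",
                          open_distal = FALSE)
  r4 <- refine_breakpoint(fish4, interval_tbl("chr4", 45518972, 45754992))
  expect_equal(c(r4$start, r4$end), c(45518972, 45736237))
  expect_equal(r4$basis, "acgh_refined")
  expect_equal(round_half_up(r4$start / 1e6, 1), 45.5)
  expect_equal(round_half_up(r4$end / 1e6, 1), 45.7)

  fish11 <- tibble::tibble(chrom = "chr11", arm = "p", start = 49259387,
                           end = 50111641, basis = "flanking_probes",
                           open_distal = FALSE)
  r11 <- refine_breakpoint(fish11, interval_tbl("chr11", 49919441, 50378743))
  expect_equal(c(r11$start, r11$end), c(49919441, 50111641))
  expect_equal(round_half_up(r11$start / 1e6, 1), 49.9)
  expect_equal(round_half_up(r11$end / 1e6, 1), 50.1)
})

test_that("refinement is a no-op against itself and errors when disjoint", {
  fish <- tibble::tibble(chrom = "chr4", arm = "p", start = 44621297,
                         end = 45736237, basis = "flanking_probes",
                         open_distal = FALSE)
  same <- refine_breakpoint(fish, interval_tbl("chr4", fish$start, fish$end))
  expect_equal(c(same$start, same$end), c(fish$start, fish$end))
  expect_error(refine_breakpoint(fish, interval_tbl("chr4", 60e6, 61e6)),
               "disjoint")
})

test_that("refined intervals are contained in both inputs on random pairs", {
  withr::with_seed(13, {
    for (i in 1:200) {
      a <- rand_interval()
      b <- rand_interval()
      fish <- tibble::tibble(chrom = a$chrom, arm = "q", start = a$start,
                             end = a$end, basis = "flanking_probes",
                             open_distal = FALSE)
      disjoint <- b$start > a$end || b$end < a$start
      if (disjoint) {
        expect_error(refine_breakpoint(fish, b), "disjoint")
      } else {
        r <- refine_breakpoint(fish, b)
        expect_gte(r$start, max(a$start, b$start))
        expect_lte(r$end, min(a$end, b$end))
      }
    }
  })
})

test_that("an arm without informative probes gets an aCGH-only breakpoint", {
  arm <- tibble::tibble(chrom = "chr11", arm = "q", start = 54e6, end = 135e6,
                        distal_sign = 1, junction = 55.7e6)
  segs <- acgh_call(tibble::tibble(
    chrom = "chr11", start = 55.7e6, end = 63743029, mean_log2 = 0.55,
    boundary_start = 63743029, boundary_end = 63800000))
  b <- acgh_only_breakpoint(segs, arm)
  expect_equal(c(b$start, b$end), c(63743029, 63800000))
  expect_equal(b$basis, "acgh_refined")

  none <- acgh_only_breakpoint(segs[0, ], arm)
  expect_equal(nrow(none), 0)
})

test_that("simulated aCGH boundaries tighten FISH intervals around the truth", {
  g <- small_genome(seed = 19)
  arms <- find_junctions(g$arms, g$het)
  for (i in 1:15) {
    s <- simulate_case(g, structure = "ring", seed = 3000 + i)
    chz <- characterize_marker(s$calls, arms)
    ref <- refine_characterization(chz, s$acgh, arms)
    for (side in names(s$truth$arms)) {
      tr <- s$truth$arms[[side]]
      b0 <- chz$breakpoints[chz$breakpoints$arm == side, ]
      b1 <- ref$breakpoints[ref$breakpoints$arm == side, ]
      expect_true(any(b1$start <= tr$breakpoint & tr$breakpoint <= b1$end))
      expect_lte(sum(b1$end - b1$start), sum(b0$end - b0$start))
    }
    expect_lte(ref$content_max_mb, chz$content_max_mb)
  }
})
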