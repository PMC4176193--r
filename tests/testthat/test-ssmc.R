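test_that("markers with only absent core signals are heterochromatic-only", {
  het_calls <- tibble::tibble(
    case_id = "p14", probe_name = c("RP11-488I20", "CTD-2382P11"),
    chrom = "chr16", start = c(34.3e6, 47.1e6), end = c(34.5e6, 47.3e6),
    arm = c("p", "q"), signal = "absent", structure_hint = "ring",
    n_metaphases_with_marker = 16L, n_metaphases_total = 16L)
  expect_equal(classify_marker(het_calls), "heterochromatic_only")
  expect_equal(classify_marker(chr4p_calls()), "euchromatic")
  expect_equal(classify_marker(het_calls[0, ]), "undetermined")
})

test_that("breakpoints span the hull of the flanking present/absent clones", {
  b4 <- infer_breakpoint(chr4p_calls(), chr4p_arm())
  expect_equal(c(b4$start, b4$end), c(44621297, 45736237))
  expect_equal(b4$basis, "flanking_probes")
  expect_false(b4$open_distal)

  b11 <- infer_breakpoint(chr11p_calls(), chr11p_arm())
  expect_equal(c(b11$start, b11$end), c(49259387, 50111641))
})

test_that("a diminished signal localizes the breakpoint within the clone", {
  calls <- tibble::tibble(
    case_id = "p4", probe_name = "RP11-178A10", chrom = "chr10",
    start = 42.4e6, end = 42.58e6, arm = "q", signal = "diminished",
    structure_hint = "minute", n_metaphases_with_marker = 10L,
    n_metaphases_total = 16L)
  arm <- tibble::tibble(chrom = "chr10", arm = "q", start = 42.3e6,
                        end = 135e6, distal_sign = 1, junction = 42.3e6)
  b <- infer_breakpoint(calls, arm)
  expect_equal(c(b$start, b$end), c(42.4e6, 42.58e6))
  expect_equal(b$basis, "within_diminished_probe")
})

test_that("all-present call patterns leave the breakpoint open distally", {
  calls <- chr4p_calls()
  calls$signal <- c("single", "single")
  b <- infer_breakpoint(calls, chr4p_arm())
  expect_true(b$open_distal)
  expect_equal(b$basis, "flanking_probes")
  # region lies beyond the most distal probe, toward the p telomere
  expect_equal(b$end, 44621297)
  expect_equal(b$start, 0)
})

test_that("present-absent-present patterns split and flag an internal deletion", {
  calls <- tibble::tibble(
    case_id = "p15", probe_name = c("RP11-1069D4", "RP11-134N21", "RP11-71B7"),
    chrom = "chr2", start = c(95.0e6, 95.4e6, 95.8e6),
    end = c(95.2e6, 95.6e6, 96.0e6), arm = "q",
    signal = c("single", "absent", "single"), structure_hint = "unknown",
    n_metaphases_with_marker = 16L, n_metaphases_total = 16L)
  arm <- tibble::tibble(chrom = "chr2", arm = "q", start = 93e6, end = 243e6,
                        distal_sign = 1, junction = 94.9e6)
  b <- infer_breakpoint(calls, arm)
  expect_equal(nrow(b), 2)
  expect_equal(attr(b, "flags"), "internal_deletion")
})

test_that("calls from mixed arms or empty call lists are rejected", {
  expect_error(infer_breakpoint(chr4p_calls()[0, ], chr4p_arm()), "no calls")
  mixed <- chr4p_calls()
  mixed$arm <- c("p", "q")
  expect_error(infer_breakpoint(mixed, chr4p_arm()), "mixed arms")
})

test_that("dosage follows the double/single/diminished ladder of an idic", {
  arm <- tibble::tibble(chrom = "chr22", arm = "q", start = 15e6, end = 51e6,
                        distal_sign = 1, junction = 17.9e6)
  calls <- tibble::tibble(
    case_id = "p18", probe_name = c("RP11-1053O2", "RP11-690P21"),
    chrom = "chr22", start = c(17.95e6, 18.7e6), end = c(18.15e6, 18.9e6),
    arm = "q", signal = c("double", "diminished"), structure_hint = "idic",
    n_metaphases_with_marker = 5L, n_metaphases_total = 16L)
  segs <- infer_dosage(calls, arm)
  expect_equal(segs$total_dosage, c("tetrasomy", "partial_gain"))

  ring <- tibble::tibble(
    case_id = "r", probe_name = c("a", "b"), chrom = "chr22",
    start = c(18e6, 18.3e6), end = c(18.2e6, 18.5e6), arm = "q",
    signal = "single", structure_hint = "ring",
    n_metaphases_with_marker = 16L, n_metaphases_total = 16L)
  expect_equal(infer_dosage(ring, arm)$total_dosage, "trisomy")

  upward <- ring
  upward$signal <- c("absent", "single")
  expect_error(infer_dosage(upward, arm), "increase distally")
  expect_silent(infer_dosage(upward, arm, flags = "internal_deletion"))
})

test_that("content bounds derive from junction-to-breakpoint arm distances", {
  bp <- tibble::tibble(chrom = "chr4", arm = "p", start = 45518972,
                       end = 45736237, basis = "acgh_refined",
                       open_distal = FALSE)
  out <- size_content(bp, chr4p_arm())
  expect_equal(out$content_min_mb, 2.46)  # (48,200,000 - 45,736,237)/1e6
  expect_equal(out$content_max_mb, 2.68)  # (48,200,000 - 45,518,972)/1e6

  expect_equal(size_content(bp[0, ], chr4p_arm()),
               tibble::tibble(content_min_mb = 0, content_max_mb = 0))

  open_bp <- bp
  open_bp$open_distal <- TRUE
  expect_true(is.infinite(size_content(open_bp, chr4p_arm())$content_max_mb))
})

test_that("mosaic fractions carry exact Clopper-Pearson intervals", {
  full <- mosaic_fraction(16, 16)
  expect_equal(full$fraction, 1)
  expect_equal(full$upper, 1)

  none <- mosaic_fraction(0, 16)
  expect_equal(none$fraction, 0)
  expect_equal(none$lower, 0)
  expect_equal(c(none$lower, none$upper), oracle_cp(0, 16), tolerance = 1e-12)

  half <- mosaic_fraction(8, 16)
  expect_equal(c(half$lower, half$upper), oracle_cp(8, 16), tolerance = 1e-12)
  # symmetric about 1/2
  expect_equal(half$upper - 0.5, 0.5 - half$lower, tolerance = 1e-12)

  expect_error(mosaic_fraction(1, 0), "positive count")
  expect_error(mosaic_fraction(17, 16), "lie in")
})

test_that("required metaphase counts follow the geometric closed form", {
  expect_equal(required_metaphases(1, 0.95, floor = 0), 1L)
  expect_equal(required_metaphases(0.5, 0.95, floor = 0), 5L)
  expect_equal(required_metaphases(0.5, 0.95), 16L)  # floored
  expect_error(required_metaphases(0), "undetectable")
  m <- seq(0.01, 1, length.out = 100)
  n <- required_metaphases(m, 0.95, floor = 0)
  expect_true(all(diff(n) <= 0))
})

test_that("noiseless simulated markers are recovered end to end", {
  g <- small_genome(seed = 5)
  arms <- find_junctions(g$arms, g$het)
  withr::with_seed(101, {
    for (i in 1:40) {
      s <- simulate_case(g, case_id = sprintf("c%02d", i), seed = 1000 + i,
                         mosaic_level = runif(1, 0.2, 1))
      chz <- characterize_marker(s$calls, arms)
      expect_equal(chz$class, "euchromatic")
      for (side in names(s$truth$arms)) {
        tr <- s$truth$arms[[side]]
        b <- chz$breakpoints[chz$breakpoints$arm == side, ]
        expect_gte(nrow(b), 1)
        expect_true(any(b$start <= tr$breakpoint & tr$breakpoint <= b$end))
      }
      # het-only iff zero content
      expect_true((chz$class == "heterochromatic_only") ==
                    (chz$content_max_mb == 0))
    }
    het <- simulate_case(g, marker_class = "heterochromatic_only", seed = 77)
    chz <- characterize_marker(het$calls, arms)
    expect_equal(chz$class, "heterochromatic_only")
    expect_equal(chz$content_max_mb, 0)
  })
})

test_that("dosage labels of simulated idics match the planted copy zones", {
  # expected call for a probe at arm coordinates [d0, d1] under the stated
  # observation model, recomputed here from the planted truth
  oracle_copies <- function(d0, d1, t1, t2, floor = 1e4, dim_max = 0.8) {
    w <- d1 - d0
    ov <- min(max(min(d1, t1) - d0, 0), w)
    if (ov < floor) return("0")
    if (ov / w < dim_max) return("partial")
    ov2 <- min(max(min(d1, t2) - d0, 0), w)
    if (ov2 / w >= dim_max) "2" else "1"
  }
  g <- small_genome(seed = 5)
  arms <- find_junctions(g$arms, g$het)
  for (i in 1:15) {
    s <- simulate_case(g, structure = "idic", seed = 2000 + i)
    chz <- characterize_marker(s$calls, arms)
    for (side in names(s$truth$arms)) {
      tr <- s$truth$arms[[side]]
      a <- arms[arms$chrom == s$truth$chrom & arms$arm == side, ]
      ac <- s$calls[s$calls$arm == side, ]
      prox <- if (a$distal_sign > 0) ac$start else ac$end
      dist <- if (a$distal_sign > 0) ac$end else ac$start
      d0 <- (prox - a$junction) * a$distal_sign
      d1 <- (dist - a$junction) * a$distal_sign
      ord <- order(pmax(d0, 0), d1, ac$probe_name)
      want <- vapply(ord, function(r) oracle_copies(d0[r], d1[r],
                                                    tr$t1, tr$t2), "")
      got <- chz$segments[chz$segments$arm == side, ]
      expect_equal(got$marker_copies, rle(want)$values)
    }
  }
})

test_that("characterizations glance and tidy into case-level rows", {
  chz <- characterize_marker(chr4p_calls(), chr4p_arm())
  gl <- generics::glance(chz)
  expect_equal(gl$class, "euchromatic")
  expect_equal(gl$mosaic_fraction, 14 / 16)
  td <- generics::tidy(chz)
  expect_equal(td$case_id, "p3")
})

test_that("breakpoint intervals stay conservative under call noise", {
  g <- small_genome(seed = 5)
  arms <- find_junctions(g$arms, g$het)
  hits <- 0L; total <- 0L
  withr::with_seed(59, {
    for (i in 1:120) {
      s <- simulate_case(g, seed = 30000 + i,
                         noise = c(false_negative = 0.05,
                                   false_positive = 0.05))
      chz <- tryCatch(characterize_marker(s$calls, arms),
                      error = function(e) NULL)
      if (is.null(chz)) next
      for (side in names(s$truth$arms)) {
        tr <- s$truth$arms[[side]]
        b <- chz$breakpoints[chz$breakpoints$arm == side, ]
        total <- total + 1L
        if (nrow(b) > 0 &&
            any(b$start <= tr$breakpoint & tr$breakpoint <= b$end)) {
          hits <- hits + 1L
        }
      }
    }
  })
  expect_gt(hits / total, 0.9)
})
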