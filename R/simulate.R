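# run expr under a seed, restoring the caller's RNG state
with_seed_ <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a toy arm-structured genome with a clone library
#'
#' Emulates the landscape panel design assumes: each chromosome carries a
#' pericentromeric heterochromatin block on each arm root, euchromatin
#' beyond it, and a BAC-like clone library (150-200 kb inserts) tiling the
#' proximal euchromatin of every designable arm in a near-continuum.
#' Decoy clones with cross-hybridization signatures (alternate placements or
#' heavy segmental-duplication overlap) exercise the specificity screen; the
#' clean tiling path is unaffected by them. Output is deterministic under
#' `seed`.
#'
#' @param n_chromosomes Number of chromosomes (default 6).
#' @param chrom_length_range Length range in bp.
#' @param het_width_range Per-arm het block width range in bp.
#' @param clone_width_range Clone insert size range in bp (BAC-like).
#' @param tile_span Proximal span tiled by the library per arm (default
#'   1.2 Mb; comfortably beyond the 0.7 Mb core target).
#' @param overlap_range Overlap between consecutive tiling clones (bp).
#' @param n_acrocentric Leading chromosomes whose p arm is acrocentric
#'   (satellite-only, no clones).
#' @param n_no_junction_chroms Trailing chromosomes whose het blocks are
#'   left unannotated (their arms have no identifiable junction).
#' @param cen_gap Centromeric assembly gap between the two arm-root het
#'   blocks (bp).
#' @param decoy_rate Expected decoy clones per designable arm.
#' @param seed RNG seed.
#' @return A `pericore_genome` (same shape as [read_genome_tracks()]) with
#'   an extra `truth` element: the planted per-arm junction coordinates
#'   (`NA` where the annotation was withheld).
#' @export
sim_genome <- function(n_chromosomes = 6,
                       chrom_length_range = c(60e6, 120e6),
                       het_width_range = c(2e6, 4e6),
                       clone_width_range = c(150e3, 200e3),
                       tile_span = 1.2e6,
                       overlap_range = c(5e3, 30e3),
                       n_acrocentric = 1,
                       n_no_junction_chroms = 0,
                       cen_gap = 150e3,
                       decoy_rate = 0.5,
                       seed = 1) {
  stopifnot(n_chromosomes >= 1,
            diff(chrom_length_range) >= 0, min(chrom_length_range) > 0,
            min(het_width_range) > 0, min(clone_width_range) > 0,
            tile_span > 0)
  if (max(het_width_range) * 2 + 2 * tile_span > min(chrom_length_range)) {
    stop("chromosomes too short for the requested het blocks and tiling",
         call. = FALSE)
  }
  with_seed_(seed, {
    chroms <- paste0("chr", seq_len(n_chromosomes))
    lens <- round(stats::runif(n_chromosomes, chrom_length_range[1],
                               chrom_length_range[2]))
    assembly <- tibble::tibble(chrom = chroms, length = lens)
    no_junction <- if (n_no_junction_chroms > 0) {
      chroms[n_chromosomes - seq_len(n_no_junction_chroms) + 1]
    } else character()
    het <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric())
    clones <- list()
    segdups <- tibble::tibble(chrom = character(), start = numeric(),
                              end = numeric())
    junctions_p <- stats::setNames(rep(NA_real_, n_chromosomes), chroms)
    junctions_q <- junctions_p
    for (i in seq_len(n_chromosomes)) {
      ch <- chroms[i]
      L <- lens[i]
      cen <- round(L * stats::runif(1, 0.4, 0.6))
      wp <- round(stats::runif(1, het_width_range[1], het_width_range[2]))
      wq <- round(stats::runif(1, het_width_range[1], het_width_range[2]))
      jp <- cen - cen_gap / 2 - wp
      jq <- cen + cen_gap / 2 + wq
      junctions_p[ch] <- jp
      junctions_q[ch] <- jq
      if (!ch %in% no_junction) {
        het <- dplyr::bind_rows(
          het,
          tibble::tibble(chrom = ch, start = jp, end = cen - cen_gap / 2),
          tibble::tibble(chrom = ch, start = cen + cen_gap / 2, end = jq))
      }
      acro_p <- i <= n_acrocentric
      for (arm in c("p", "q")) {
        if (arm == "p" && acro_p) next
        j <- if (arm == "p") jp else jq
        sgn <- if (arm == "p") -1 else 1
        # tile [junction, junction + tile_span] in arm coordinates
        d0 <- -round(stats::runif(1, 0, 30e3))  # first clone straddles junction
        k <- 0L
        frontier <- d0
        while (frontier < tile_span) {
          k <- k + 1L
          w <- round(stats::runif(1, clone_width_range[1],
                                  clone_width_range[2]))
          d1 <- d0 + w
          gstart <- if (sgn > 0) j + d0 else j - d1
          clones[[length(clones) + 1L]] <- tibble::tibble(
            name = sprintf("SIM-%s%s-%03d", sub("chr", "", ch), arm, k),
            chrom = ch, start = gstart, end = gstart + w,
            segdup_fraction = 0)
          frontier <- d1
          d0 <- d1 - round(stats::runif(1, overlap_range[1],
                                        overlap_range[2]))
        }
        # decoys: excluded (other-chromosome alternate) or cross-hybridizing
        n_dec <- stats::rpois(1, decoy_rate)
        for (d in seq_len(n_dec)) {
          w <- round(stats::runif(1, clone_width_range[1],
                                  clone_width_range[2]))
          # placed distal to the tiled span so decoy segdup footprints never
          # contaminate the clean tiling clones
          off <- round(stats::runif(1, tile_span + 1e4, 1.5 * tile_span))
          gstart <- if (sgn > 0) j + off else j - off - w
          kind <- sample(c("alt", "segdup"), 1)
          clones[[length(clones) + 1L]] <- tibble::tibble(
            name = sprintf("DEC-%s%s-%03d", sub("chr", "", ch), arm, d),
            chrom = ch, start = gstart, end = gstart + w,
            segdup_fraction = if (kind == "segdup") 0.9 else 0,
            alt_chrom = if (kind == "alt") {
              chroms[(i %% n_chromosomes) + 1]
            } else NA_character_)
          if (kind == "segdup") {
            segdups <- dplyr::bind_rows(segdups, tibble::tibble(
              chrom = ch, start = gstart, end = gstart + w))
          }
        }
      }
    }
    cl <- dplyr::bind_rows(clones)
    cl$alternates <- purrr::map(seq_len(nrow(cl)), function(r) {
      if ("alt_chrom" %in% names(cl) && !is.na(cl$alt_chrom[r])) {
        interval_tbl(cl$alt_chrom[r], cl$start[r], cl$end[r])
      } else interval_tbl(character(), numeric(), numeric())
    })
    cl$alt_chrom <- NULL
    cl <- cl[, c("name", "chrom", "start", "end", "alternates",
                 "segdup_fraction")]
    g <- structure(
      list(assembly = assembly,
           arms = arms_from_het(assembly, het,
                                acrocentric_p = chroms[seq_len(n_acrocentric)]),
           het = het, clones = cl, segdups = segdups),
      class = "pericore_genome")
    # planted junction truth (NA where annotation was withheld)
    g$truth <- g$arms |>
      dplyr::transmute(.data$chrom, .data$arm,
                       junction = dplyr::if_else(
                         .data$chrom %in% no_junction, NA_real_,
                         unname(dplyr::if_else(.data$arm == "p",
                                               junctions_p[.data$chrom],
                                               junctions_q[.data$chrom]))))
    g
  })
}

#' Write a genome bundle as annotation-track files
#'
#' Emits the same formats [read_genome_tracks()] consumes: `chrom.sizes`
#' (TSV), `het.bed`, `clones.bed` (BED6 with alternate placements and segdup
#' fraction), `segdups.bed`.
#'
#' @param genome A `pericore_genome`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_genome_tracks <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(chrom_sizes = file.path(dir, "chrom.sizes"),
             het = file.path(dir, "het.bed"),
             clones = file.path(dir, "clones.bed"),
             segdups = file.path(dir, "segdups.bed"))
  readr::write_tsv(genome$assembly, paths["chrom_sizes"], col_names = FALSE)
  readr::write_tsv(genome$het, paths["het"], col_names = FALSE)
  alts <- vapply(genome$clones$alternates, function(a) {
    if (nrow(a) == 0L) "." else paste(sprintf("%s:%d-%d", a$chrom,
                                              as.integer(a$start),
                                              as.integer(a$end)),
                                      collapse = ",")
  }, "")
  cl <- genome$clones |>
    dplyr::transmute(.data$chrom, start = as.integer(.data$start),
                     end = as.integer(.data$end), .data$name,
                     alternates = alts, .data$segdup_fraction)
  readr::write_tsv(cl, paths["clones"], col_names = FALSE)
  readr::write_tsv(genome$segdups, paths["segdups"], col_names = FALSE)
  invisible(paths)
}

# true marker copy number at arm distance d (bp beyond the junction)
truth_copies_at <- function(d, t2, t1) {
  ifelse(d < t2, 2, ifelse(d < t1, 1, 0))
}

#' Simulate one marker-chromosome observation with known truth
#'
#' Plants a marker on one chromosome of a simulated genome and derives the
#' per-probe FISH calls the panel would produce, an array-CGH segment table
#' with probe-spacing boundary uncertainty, and binomial metaphase counts at
#' the planted mosaic level.
#'
#' The observation model: a probe whose overlap with the marker content is
#' below `detect_floor_bp` shows no signal (sub-resolution, `absent`); an
#' overlap fraction above `diminished_max` reads as a full signal (`single`,
#' or `double` inside the mirrored two-copy zone of an isodicentric);
#' anything between reads `diminished`. Ring and minute markers carry one
#' copy out to the per-arm breakpoint `t1`; an isodicentric carries two
#' copies out to `t2 <= t1` and one copy in the asymmetric margin
#' `[t2, t1)`.
#'
#' @param genome A `pericore_genome` from [sim_genome()].
#' @param case_id Case label.
#' @param structure `"ring"`, `"minute"`, `"idic"`, or `"random"`.
#' @param marker_class `"euchromatic"` or `"heterochromatic_only"`.
#' @param chrom Chromosome to draw the marker from (default: random
#'   designable chromosome).
#' @param mosaic_level True fraction of marker-positive cells.
#' @param n_metaphases Metaphases analyzed.
#' @param noise Named vector `false_negative`, `false_positive`: per-probe
#'   call flip rates.
#' @param t1_range_bp Range (bp beyond the junction) for the planted
#'   breakpoints.
#' @param acgh_spacing_bp Array probe spacing governing the boundary
#'   uncertainty pairs (default 43 kb).
#' @param detect_floor_bp,diminished_max Observation-model thresholds.
#' @param seed RNG seed.
#' @return List: `calls` (probe-call tibble), `acgh` (segment tibble with
#'   boundary pairs), `truth` (list: per-arm `t1`/`t2` arm distances,
#'   genomic breakpoints, structure, mosaic level).
#' @export
simulate_case <- function(genome, case_id = "sim1",
                          structure = c("random", "ring", "minute", "idic"),
                          marker_class = "euchromatic",
                          chrom = NULL, mosaic_level = 1,
                          n_metaphases = 16,
                          noise = c(false_negative = 0, false_positive = 0),
                          t1_range_bp = c(5e4, 1e6),
                          acgh_spacing_bp = 43e3,
                          detect_floor_bp = 1e4,
                          diminished_max = 0.8,
                          seed = 1) {
  structure_kind <- match.arg(structure)
  with_seed_(seed, {
    arms <- find_junctions(genome$arms, genome$het)
    ok <- arms[!arms$acrocentric & arms$junction_status == "ok", ]
    if (structure_kind == "random") {
      structure_kind <- sample(c("ring", "minute", "idic"), 1)
    }
    if (is.null(chrom)) {
      cand <- names(which(table(ok$chrom) == 2))
      chrom <- sample(cand, 1)
    }
    ca <- arms[arms$chrom == chrom, ]
    screened <- screen_clones(genome$clones)
    lib <- screened[screened$chrom == chrom & screened$label == "specific", ]
    truth_arms <- list()
    calls <- tibble::tibble()
    acgh <- tibble::tibble()
    for (side in c("p", "q")) {
      a <- ca[ca$arm == side, ]
      if (nrow(a) != 1L || is.na(a$junction)) next
      if (marker_class == "heterochromatic_only") {
        # breakpoint inside the het block: no euchromatic probe can overlap
        # the marker content, so every call reads absent
        t1 <- -round(stats::runif(1, detect_floor_bp, 2e5))
        t2 <- t1
      } else {
        t1 <- round(stats::runif(1, t1_range_bp[1], t1_range_bp[2]))
        t2 <- if (structure_kind == "idic") {
          round(t1 * stats::runif(1, 0.3, 0.9))
        } else 0
      }
      if (t1 > (a$end - a$start)) {
        stop("planted breakpoint outside the arm", call. = FALSE)
      }
      armlib <- lib[(lib$start + lib$end) / 2 >= a$start &
                      (lib$start + lib$end) / 2 < a$end, ]
      oc <- arm_clone_coords(armlib, a, a$junction)
      oc <- oc[order(pmax(oc$d0, 0), oc$d1, oc$name), ]
      sig <- vapply(seq_len(nrow(oc)), function(r) {
        w <- oc$d1[r] - oc$d0[r]
        ov <- max(min(oc$d1[r], t1) - oc$d0[r], 0)
        ov <- min(ov, w)
        if (ov < detect_floor_bp) return("absent")
        frac <- ov / w
        if (frac < diminished_max) return("diminished")
        if (structure_kind == "idic") {
          ov2 <- min(max(min(oc$d1[r], t2) - oc$d0[r], 0), w)
          if (ov2 / w >= diminished_max) return("double")
        }
        "single"
      }, "")
      # call noise
      for (r in seq_along(sig)) {
        if (sig[r] %in% c("single", "double", "diminished") &&
            stats::runif(1) < noise[["false_negative"]]) sig[r] <- "absent"
        else if (sig[r] == "absent" &&
                 stats::runif(1) < noise[["false_positive"]]) sig[r] <- "single"
      }
      calls <- dplyr::bind_rows(calls, tibble::tibble(
        case_id = case_id, probe_name = oc$name, chrom = chrom,
        start = oc$start, end = oc$end, arm = side, signal = sig,
        structure_hint = structure_kind,
        n_metaphases_with_marker = NA_integer_,
        n_metaphases_total = NA_integer_))
      g_break <- a$junction + a$distal_sign * t1
      truth_arms[[side]] <- list(t1 = t1, t2 = t2, junction = a$junction,
                                 breakpoint = g_break,
                                 breakpoint2 = a$junction + a$distal_sign * t2)
      if (t1 > 0) {
        lo <- min(a$junction, g_break)
        hi <- max(a$junction, g_break)
        copies_mean <- if (structure_kind == "idic") {
          (2 * t2 + 1 * (t1 - t2)) / t1
        } else 1
        d1 <- stats::runif(1, 0, acgh_spacing_bp)
        d2 <- stats::runif(1, 0, acgh_spacing_bp)
        acgh <- dplyr::bind_rows(acgh, tibble::tibble(
          chrom = chrom, start = lo, end = hi,
          mean_log2 = log2((2 + copies_mean * mosaic_level) / 2),
          boundary_start = g_break - d1, boundary_end = g_break + d2))
      }
    }
    n_with <- stats::rbinom(1, n_metaphases, mosaic_level)
    calls$n_metaphases_with_marker <- as.integer(n_with)
    calls$n_metaphases_total <- as.integer(n_metaphases)
    list(calls = calls,
         acgh = if (nrow(acgh)) acgh_call(acgh) else acgh,
         truth = list(case_id = case_id, structure = structure_kind,
                      chrom = chrom, arms = truth_arms,
                      marker_class = marker_class,
                      mosaic_level = mosaic_level, noise = noise))
  })
}
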