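#' Read array-CGH segment calls
#'
#' Segments come from the array platform's own segmentation (they are
#' consumed, not recomputed here). Each row gets a gain/loss/normal call by
#' thresholding its mean log2 ratio. Optional columns
#' `boundary_start`/`boundary_end` carry the probe-to-probe uncertainty
#' interval at the segment's distal edge (last normal probe to first
#' aberrant probe) used for breakpoint refinement.
#'
#' @param path TSV with header columns `chrom`, `start`, `end`, `mean_log2`
#'   and optionally `boundary_start`, `boundary_end`.
#' @param log2_threshold Absolute mean log2 at or above which a segment is a
#'   gain (positive) or loss (negative); default 0.3.
#' @return Tibble of segments sorted by chrom/start with a `call` column;
#'   overlapping same-chromosome gain segments raise a warning and set
#'   `flag_overlap`.
#' @export
read_acgh_segments <- function(path, log2_threshold = 0.3) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", start = "d", end = "d", mean_log2 = "d",
    .default = "d"), progress = FALSE)
  acgh_call(x, log2_threshold)
}

#' @rdname read_acgh_segments
#' @param segments Segment tibble (`chrom`, `start`, `end`, `mean_log2`).
#' @export
acgh_call <- function(segments, log2_threshold = 0.3) {
  x <- dplyr::arrange(segments, .data$chrom, .data$start)
  x$call <- dplyr::case_when(
    x$mean_log2 >= log2_threshold ~ "gain",
    x$mean_log2 <= -log2_threshold ~ "loss",
    TRUE ~ "normal"
  )
  x$flag_overlap <- FALSE
  g <- x[x$call == "gain", ]
  for (ch in unique(g$chrom)) {
    b <- g[g$chrom == ch, ]
    if (nrow(b) > 1L && any(b$start[-1] < b$end[-nrow(b)])) {
      warning(sprintf("overlapping gain segments on %s", ch), call. = FALSE)
      x$flag_overlap[x$chrom == ch & x$call == "gain"] <- TRUE
    }
  }
  x
}

#' Refine a FISH breakpoint interval with an array-CGH boundary
#'
#' FISH bounds a breakpoint between two clones; the array bounds it between
#' two oligonucleotide probes. When both assays agree the intersection of the
#' two intervals is a strictly tighter localization. Disjoint intervals mean
#' the assays contradict each other and raise an error carrying both regions.
#'
#' @param fish One-row breakpoint tibble ([infer_breakpoint()] row).
#' @param boundary One-row interval tibble: the aCGH boundary-uncertainty
#'   interval (probe-to-probe pair), or a gain-segment edge.
#' @return The refined breakpoint row, `basis = "acgh_refined"`.
#' @examples
#' fish <- interval_tbl("chr4", 44621297, 45736237)
#' fish$arm <- "p"; fish$basis <- "flanking_probes"; fish$open_distal <- FALSE
#' refine_breakpoint(fish, interval_tbl("chr4", 45518972, 45754992))
#' @export
refine_breakpoint <- function(fish, boundary) {
  stopifnot(nrow(fish) == 1L, nrow(boundary) == 1L)
  ix <- interval_intersect(interval_tbl(fish$chrom, fish$start, fish$end),
                           boundary)
  if (nrow(ix) == 0L) {
    stop(sprintf(paste0("FISH (%s) and array-CGH (%s) breakpoint intervals ",
                        "are disjoint; assays are inconsistent"),
                 format_region(fish), format_region(boundary)), call. = FALSE)
  }
  out <- fish
  out$start <- ix$start
  out$end <- ix$end
  out$basis <- "acgh_refined"
  out$open_distal <- FALSE
  out
}

#' Breakpoint from array CGH alone
#'
#' When the FISH panel probes on an arm are uninformative (all proximal to
#' the breakpoint), the distal edge of the gain segment still bounds it. The
#' breakpoint interval is the supplied boundary-uncertainty interval at that
#' edge; without an explicit pair it degenerates to the zero-width segment
#' edge.
#'
#' @param segments aCGH segment tibble with calls ([acgh_call()]).
#' @param arm_row One-row arm tibble (`chrom`, `arm`, `distal_sign`).
#' @return One-row breakpoint tibble (`basis = "acgh_refined"`), or a
#'   zero-row tibble when the arm carries no gain segment.
#' @export
acgh_only_breakpoint <- function(segments, arm_row) {
  g <- segments[segments$call == "gain" & segments$chrom == arm_row$chrom, ]
  # keep gains whose midpoint lies on the arm
  g <- g[(g$start + g$end) / 2 >= arm_row$start &
           (g$start + g$end) / 2 < arm_row$end, , drop = FALSE]
  if (nrow(g) == 0L) {
    return(tibble::tibble(chrom = character(), arm = character(),
                          start = numeric(), end = numeric(),
                          basis = character(), open_distal = logical()))
  }
  sgn <- arm_row$distal_sign
  # most distal gain segment edge along the arm
  edges <- if (sgn > 0) g$end else g$start
  i <- which.max(edges * sgn)
  seg <- g[i, ]
  edge <- edges[i]
  has_pair <- all(c("boundary_start", "boundary_end") %in% names(seg)) &&
    !is.na(seg$boundary_start) && !is.na(seg$boundary_end)
  lo <- if (has_pair) seg$boundary_start else edge
  hi <- if (has_pair) seg$boundary_end else edge
  tibble::tibble(chrom = seg$chrom, arm = arm_row$arm,
                 start = min(lo, hi), end = max(lo, hi),
                 basis = "acgh_refined", open_distal = FALSE)
}

#' Refine every open or flanking breakpoint of a characterization
#'
#' For each FISH breakpoint row, looks for an overlapping aCGH boundary
#' interval (explicit `boundary_start`/`boundary_end` pair of a gain segment
#' on the same chromosome) and replaces the row by the intersection. Arms
#' with calls but no informative FISH interval gain an aCGH-only breakpoint.
#' Content bounds are recomputed afterwards.
#'
#' A boundary pair disjoint from every FISH interval on its chromosome marks
#' an assay conflict: the characterization gains an `acgh_conflict` flag and
#' keeps the FISH interval.
#'
#' @param chz A `pericore_characterization`.
#' @param segments aCGH segment tibble with calls and boundary pairs.
#' @param arms Arm tibble used for the original characterization.
#' @return The updated characterization.
#' @export
refine_characterization <- function(chz, segments, arms) {
  if (nrow(chz$breakpoints) == 0L) return(chz)
  has_pair <- all(c("boundary_start", "boundary_end") %in% names(segments))
  refined <- purrr::map_dfr(seq_len(nrow(chz$breakpoints)), function(i) {
    b <- chz$breakpoints[i, ]
    if (!has_pair) return(b)
    gains <- segments[segments$call == "gain" &
                        segments$chrom == b$chrom &
                        !is.na(segments$boundary_start), , drop = FALSE]
    if (nrow(gains) == 0L) return(b)
    cand <- gains[gains$boundary_start <= b$end &
                    gains$boundary_end >= b$start, , drop = FALSE]
    if (nrow(cand) == 0L) {
      # gains on this chromosome but none compatible with the FISH interval:
      # only a conflict if a boundary pair targets this arm's side
      arm_row <- arms[arms$chrom == b$chrom & arms$arm == b$arm, ]
      on_arm <- (gains$boundary_start + gains$boundary_end) / 2 >=
        arm_row$start & (gains$boundary_start + gains$boundary_end) / 2 <
        arm_row$end
      if (any(on_arm)) {
        chz$flags <<- union(chz$flags, "acgh_conflict")
      }
      return(b)
    }
    # the boundary pair overlapping the FISH interval the most tightly
    j <- which.min(cand$boundary_end - cand$boundary_start)
    refine_breakpoint(b, interval_tbl(cand$chrom[j], cand$boundary_start[j],
                                      cand$boundary_end[j]))
  })
  chz$breakpoints <- refined
  content <- size_content(refined, arms)
  chz$content_min_mb <- content$content_min_mb
  chz$content_max_mb <- content$content_max_mb
  chz
}
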