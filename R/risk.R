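#' Read a critical/noncritical pericentromeric region map
#'
#' Extra dosage of pericentromeric euchromatin is tolerated inside the
#' arm-specific noncritical region next to the centromere, and associated
#' with abnormal phenotypes once the critical region (starting at
#' `critical_start` and extending distally) is involved; between the two a
#' gap of uncertain significance may be annotated. Boundaries come from
#' curated case collections and are supplied by the user, not shipped.
#'
#' @param path TSV with header columns `arm_id`, `chrom`, `arm`,
#'   `noncritical_start`, `noncritical_end`, `critical_start`, `gap_start`,
#'   `gap_end`, `provenance` (missing boundaries = `NA` -> unknown).
#' @return Tibble of per-arm region annotations.
#' @export
read_critical_regions <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    arm_id = "c", chrom = "c", arm = "c", noncritical_start = "d",
    noncritical_end = "d", critical_start = "d", gap_start = "d",
    gap_end = "d", provenance = "c"), progress = FALSE)
}

overlap_len <- function(s1, e1, s2, e2) pmax(pmin(e1, e2) - pmax(s1, s2), 0)

#' Assign a phenotype-risk label to a characterized marker
#'
#' Rules, in order of precedence, over every dosage segment with at least
#' one marker copy (including partial):
#' \itemize{
#'   \item heterochromatic-only marker: `likely_benign`;
#'   \item any segment overlapping an arm's critical region (from
#'     `critical_start` distally): `likely_pathogenic`;
#'   \item an involved arm whose boundaries are unknown in the map, or
#'     segments reaching only the annotated gap: `uncertain`;
#'   \item all segments confined to noncritical regions: `likely_benign`.
#' }
#' A mosaic fraction below `mosaic_attenuation_threshold` appends an
#' advisory note (low-level mosaicism may attenuate expression) but never
#' changes the label.
#'
#' @param chz A `pericore_characterization`.
#' @param region_map Tibble from [read_critical_regions()].
#' @param arms Arm tibble (for distal orientation of the critical regions).
#' @param mosaic_attenuation_threshold Mosaic fraction below which the
#'   attenuation note is added (default 0.30).
#' @return One-row tibble: `case_id`, `label`, `notes` (list column),
#'   `drivers` (list column of segment/overlap-class pairs).
#' @export
classify_risk <- function(chz, region_map, arms,
                          mosaic_attenuation_threshold = 0.30) {
  if (is.null(chz) || !inherits(chz, "pericore_characterization")) {
    stop("classify_risk needs a pericore_characterization", call. = FALSE)
  }
  notes <- character()
  drivers <- tibble::tibble(arm_id = character(), start = numeric(),
                            end = numeric(), overlap_class = character())
  if (chz$class == "undetermined") {
    stop("cannot assess risk for an undetermined marker", call. = FALSE)
  }
  if (chz$class == "heterochromatic_only") {
    label <- "likely_benign"
    notes <- c(notes, "no euchromatic content detected")
  } else {
    segs <- chz$segments[chz$segments$marker_copies != "0", , drop = FALSE]
    if (nrow(segs) == 0L) {
      stop("euchromatic marker with no dosage segments", call. = FALSE)
    }
    classes <- character(nrow(segs))
    for (i in seq_len(nrow(segs))) {
      s <- segs[i, ]
      arm_id <- paste0(sub("^chr", "", s$chrom), s$arm)
      m <- region_map[region_map$chrom == s$chrom & region_map$arm == s$arm, ]
      a <- arms[arms$chrom == s$chrom & arms$arm == s$arm, ]
      if (nrow(m) != 1L || is.na(m$critical_start)) {
        classes[i] <- "unknown_boundaries"
      } else {
        # critical region: from critical_start toward the telomere
        crit <- if (nrow(a) == 1L && a$distal_sign < 0) {
          c(a$start, m$critical_start)
        } else if (nrow(a) == 1L) {
          c(m$critical_start, a$end)
        } else c(m$critical_start, Inf)
        in_crit <- overlap_len(s$start, s$end, crit[1], crit[2]) > 0
        in_noncrit <- !is.na(m$noncritical_start) &&
          overlap_len(s$start, s$end, m$noncritical_start,
                      m$noncritical_end) > 0
        in_gap <- !is.na(m$gap_start) &&
          overlap_len(s$start, s$end, m$gap_start, m$gap_end) > 0
        classes[i] <- if (in_crit) "critical"
          else if (in_gap) "gap"
          else if (in_noncrit) "noncritical"
          else "unannotated"
      }
      drivers <- dplyr::bind_rows(drivers, tibble::tibble(
        arm_id = arm_id, start = s$start, end = s$end,
        overlap_class = classes[i]))
    }
    label <- if (any(classes == "critical")) "likely_pathogenic"
      else if (any(classes %in% c("unknown_boundaries", "gap", "unannotated")))
        "uncertain"
      else "likely_benign"
    if (any(classes == "gap")) {
      notes <- c(notes, "dosage confined to the gap between noncritical and critical regions")
    }
    if (any(classes == "unknown_boundaries")) {
      notes <- c(notes, "critical-region boundaries unknown for an involved arm")
    }
  }
  if (!is.null(chz$mosaic) &&
      chz$mosaic$fraction < mosaic_attenuation_threshold) {
    notes <- c(notes, sprintf(
      "low-level mosaicism (%.2f): phenotypic expression may be attenuated",
      chz$mosaic$fraction))
  }
  tibble::tibble(case_id = chz$case_id, label = label,
                 notes = list(notes), drivers = list(drivers))
}
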