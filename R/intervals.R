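#' Genomic interval tibbles
#'
#' `pericore` carries genomic coordinates as plain tibbles with columns
#' `chrom`, `start`, `end`. Intervals are half-open on the right, so
#' `width = end - start`; a zero-width row is a point. Coordinates printed in
#' locus strings (`"chr4:45,518,972-45,754,992"`) are kept verbatim on input
#' and output, which makes reported sizes equal to the difference of the
#' printed bounds.
#'
#' @param chrom Chromosome name(s), e.g. `"chr4"`.
#' @param start,end Integer-ish coordinates, `0 <= start <= end`.
#' @return A tibble with columns `chrom`, `start`, `end` (doubles; bp).
#' @examples
#' interval_tbl("chr4", 45518972, 45754992)
#' @export
interval_tbl <- function(chrom, start, end) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end))) {
    stop("interval coordinates must be numeric and non-missing", call. = FALSE)
  }
  if (any(start < 0)) stop("interval start must be >= 0", call. = FALSE)
  if (any(end < start)) {
    bad <- which(end < start)[1]
    stop(sprintf("interval end (%s) precedes start (%s)",
                 format(end[bad], big.mark = ","),
                 format(start[bad], big.mark = ",")), call. = FALSE)
  }
  tibble::tibble(chrom = as.character(chrom), start = start, end = end)
}

#' Parse a paper-style locus string
#'
#' Accepts `chrN:A-B` with optional thousands separators, spaces around the
#' dash, and hyphen / en-dash / minus-sign variants (published coordinate
#' strings mix all three).
#'
#' @param text Character vector of locus strings.
#' @param assembly Optional assembly tibble (`chrom`, `length`); when given,
#'   chromosome names are checked against it and coordinates against lengths.
#' @return A tibble with one row per input string: `chrom`, `start`, `end`.
#' @examples
#' parse_region_string("chr4:45,518,972 - 45,754,992")
#' @export
parse_region_string <- function(text, assembly = NULL) {
  text <- as.character(text)
  # normalise the dash zoo: en dash, em dash, minus sign -> hyphen
  norm <- gsub("[‒–—−]", "-", text)
  norm <- gsub("[,  ]", "", norm)
  m <- regmatches(norm, regexec("^(chr[0-9XYM]+):([0-9]+)-([0-9]+)$", norm))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop(sprintf("cannot parse region string: '%s'", text[which(bad)[1]]),
         call. = FALSE)
  }
  chrom <- vapply(m, `[[`, "", 2L)
  start <- as.numeric(vapply(m, `[[`, "", 3L))
  end <- as.numeric(vapply(m, `[[`, "", 4L))
  if (any(end < start)) {
    i <- which(end < start)[1]
    stop(sprintf("region '%s': end precedes start", text[i]), call. = FALSE)
  }
  if (!is.null(assembly)) {
    unknown <- !chrom %in% assembly$chrom
    if (any(unknown)) {
      stop(sprintf("unknown chromosome '%s'", chrom[which(unknown)[1]]),
           call. = FALSE)
    }
    len <- assembly$length[match(chrom, assembly$chrom)]
    if (any(end > len)) {
      i <- which(end > len)[1]
      stop(sprintf("region '%s' exceeds %s length (%s bp)", text[i], chrom[i],
                   format(len[i], big.mark = ",")), call. = FALSE)
    }
  }
  interval_tbl(chrom, start, end)
}

#' Format intervals as locus strings
#'
#' Inverse of [parse_region_string()]: renders `chrN:A-B` with thousands
#' separators, reproducing the input coordinates exactly.
#'
#' @param iv Interval tibble (`chrom`, `start`, `end`).
#' @return Character vector of locus strings.
#' @export
format_region <- function(iv) {
  sprintf("%s:%s-%s", iv$chrom,
          format(iv$start, big.mark = ",", scientific = FALSE, trim = TRUE),
          format(iv$end, big.mark = ",", scientific = FALSE, trim = TRUE))
}

#' Intersect two intervals on the same chromosome
#'
#' @param a,b Single-row interval tibbles on the same chromosome.
#' @return Their intersection as a one-row interval tibble, or a zero-row
#'   tibble when the intervals are disjoint.
#' @examples
#' interval_intersect(interval_tbl("chr4", 44621297, 45736237),
#'                    interval_tbl("chr4", 45518972, 45754992))
#' @export
interval_intersect <- function(a, b) {
  stopifnot(nrow(a) == 1L, nrow(b) == 1L)
  if (a$chrom != b$chrom) {
    stop(sprintf("cannot intersect intervals on different chromosomes (%s vs %s)",
                 a$chrom, b$chrom), call. = FALSE)
  }
  lo <- max(a$start, b$start)
  hi <- min(a$end, b$end)
  if (lo > hi) return(interval_tbl(character(), numeric(), numeric()))
  interval_tbl(a$chrom, lo, hi)
}

#' Round half away from zero at a fixed number of decimals
#'
#' Base `round()` rounds halves to even; published interval sizes use
#' commercial (half-up) rounding, e.g. 13,364,286 bp -> 13.4 Mb.
#' @param x Numeric vector.
#' @param decimals Decimal places to keep.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, decimals = 0) {
  p <- 10^decimals
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Interval width in megabases or kilobases
#'
#' Width is the coordinate difference `end - start`, divided by 1e6 (Mb) or
#' 1e3 (kb) and rounded half-up at the requested precision.
#'
#' @param iv Interval tibble.
#' @param decimals Decimal places (half-up rounding).
#' @return Numeric vector of widths.
#' @examples
#' width_mb(interval_tbl("chr4", 45754992, 61126608), 1)  # 15.4
#' @export
width_mb <- function(iv, decimals = 2) {
  round_half_up((iv$end - iv$start) / 1e6, decimals)
}

#' @rdname width_mb
#' @export
width_kb <- function(iv, decimals = 0) {
  round_half_up((iv$end - iv$start) / 1e3, decimals)
}

#' Signed distance along a chromosome arm
#'
#' Distance is positive toward the telomere. On a q arm the telomere lies at
#' larger coordinates (`distal_sign = +1`); on a p arm at smaller coordinates
#' (`distal_sign = -1`), so a move to a smaller position is positive.
#'
#' @param arm One-row arm tibble with a `distal_sign` column (see
#'   [arms_from_het()]), or the value `+1`/`-1` itself.
#' @param from_pos,to_pos Positions in bp.
#' @return Signed distance in bp.
#' @export
arm_distance <- function(arm, from_pos, to_pos) {
  sgn <- if (is.data.frame(arm)) arm$distal_sign[1] else arm
  stopifnot(sgn %in% c(-1, 1))
  (to_pos - from_pos) * sgn
}
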