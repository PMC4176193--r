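#' Read a per-probe FISH call table
#'
#' One row per hybridized probe per case. `signal` uses the closed
#' vocabulary `absent` (no signal on the marker), `diminished` (partial
#' signal: the breakpoint falls inside the probe), `single` (one copy on the
#' marker), `double` (two copies, e.g. the mirrored proximal region of an
#' isodicentric).
#'
#' @param path TSV with header columns `case_id`, `probe_name`, `chrom`,
#'   `start`, `end`, `arm`, `signal`, `structure_hint`,
#'   `n_metaphases_with_marker`, `n_metaphases_total`.
#' @return Tibble of calls.
#' @export
read_probe_calls <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    case_id = "c", probe_name = "c", chrom = "c", start = "d", end = "d",
    arm = "c", signal = "c", structure_hint = "c",
    n_metaphases_with_marker = "i", n_metaphases_total = "i"),
    progress = FALSE)
  bad <- !x$signal %in% c("absent", "diminished", "single", "double")
  if (any(bad)) {
    stop(sprintf("%s line %d: unknown signal '%s'", path, which(bad)[1],
                 x$signal[which(bad)[1]]), call. = FALSE)
  }
  if (any(x$n_metaphases_with_marker > x$n_metaphases_total, na.rm = TRUE)) {
    stop("n_metaphases_with_marker exceeds n_metaphases_total", call. = FALSE)
  }
  x
}

# order one arm's calls proximal -> distal and attach arm coordinates
ordered_arm_calls <- function(calls, arm_row) {
  stopifnot(nrow(arm_row) == 1L)
  if (any(calls$chrom != arm_row$chrom)) {
    stop("calls from a different chromosome than the stated arm", call. = FALSE)
  }
  sgn <- arm_row$distal_sign
  j <- arm_row$junction
  prox_edge <- if (sgn > 0) calls$start else calls$end
  dist_edge <- if (sgn > 0) calls$end else calls$start
  calls$d0 <- (prox_edge - j) * sgn
  calls$d1 <- (dist_edge - j) * sgn
  calls[order(pmax(calls$d0, 0), calls$d1, calls$probe_name), , drop = FALSE]
}

#' Classify a marker as heterochromatic-only or euchromatic
#'
#' The most proximal core probes answer the first diagnostic question: does
#' the marker carry any euchromatin at all? It is heterochromatic-only iff
#' every euchromatic probe call on it is `absent`; any single, double or
#' diminished signal proves euchromatic content.
#'
#' @param calls Call tibble for one case.
#' @return `"heterochromatic_only"`, `"euchromatic"`, or `"undetermined"`
#'   when there are no calls.
#' @export
classify_marker <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L) return("undetermined")
  if (all(calls$signal == "absent")) "heterochromatic_only" else "euchromatic"
}

#' Infer breakpoint intervals from ordered probe calls on one arm
#'
#' The breakpoint on an arm lies between the most distal probe still present
#' on the marker and the most proximal absent probe beyond it. The reported
#' interval is the convex hull of both clones (their outer edges), which is
#' conservative in both directions against partial, sub-probe overlaps. A
#' `diminished` call places the breakpoint inside that clone. When no absent
#' probe is seen distally the interval is open-ended (`open_distal`). A
#' non-monotone pattern (absent probes proximal to present ones) yields one
#' interval per present block plus an `internal_deletion` flag.
#'
#' @param calls Calls for one case on one arm.
#' @param arm_row One-row arm tibble with `chrom`, `arm`, `junction`,
#'   `distal_sign`, `start`, `end`.
#' @return Tibble of breakpoint intervals: `chrom`, `arm`, `start`, `end`,
#'   `basis` (`flanking_probes` / `within_diminished_probe`), `open_distal`,
#'   with attribute `flags` (possibly `"internal_deletion"`).
#' @export
infer_breakpoint <- function(calls, arm_row) {
  if (is.null(calls) || nrow(calls) == 0L) {
    stop("no calls on this arm", call. = FALSE)
  }
  if (length(unique(calls$arm)) > 1L) {
    stop("calls from mixed arms; infer one arm at a time", call. = FALSE)
  }
  oc <- ordered_arm_calls(calls, arm_row)
  flags <- character()
  present <- oc$signal != "absent"
  none <- tibble::tibble(chrom = character(), arm = character(),
                         start = numeric(), end = numeric(),
                         basis = character(), open_distal = logical())
  if (!any(present)) return(structure(none, flags = flags))
  # any absent call proximal to a present one breaks monotone loss
  if (any(which(!present) < max(which(present)))) {
    flags <- "internal_deletion"
  }
  # maximal blocks of non-absent calls
  r <- rle(present)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  blocks <- which(r$values)
  out <- purrr::map_dfr(blocks, function(b) {
    last_i <- ends[b]
    last_call <- oc[last_i, ]
    if (last_call$signal == "diminished") {
      return(tibble::tibble(chrom = last_call$chrom, arm = arm_row$arm,
                            start = last_call$start, end = last_call$end,
                            basis = "within_diminished_probe",
                            open_distal = FALSE))
    }
    distal_abs <- which(!present & seq_along(present) > last_i)
    if (length(distal_abs) == 0L) {
      # open-ended: breakpoint somewhere beyond the last probe
      sgn <- arm_row$distal_sign
      edge <- if (sgn > 0) last_call$end else last_call$start
      arm_tip <- if (sgn > 0) arm_row$end else arm_row$start
      return(tibble::tibble(chrom = last_call$chrom, arm = arm_row$arm,
                            start = min(edge, arm_tip),
                            end = max(edge, arm_tip),
                            basis = "flanking_probes", open_distal = TRUE))
    }
    a_call <- oc[distal_abs[1], ]
    hull <- range(c(last_call$start, last_call$end, a_call$start, a_call$end))
    tibble::tibble(chrom = last_call$chrom, arm = arm_row$arm,
                   start = hull[1], end = hull[2],
                   basis = "flanking_probes", open_distal = FALSE)
  })
  structure(out, flags = flags)
}

#' Infer per-segment marker dosage from ordered calls on one arm
#'
#' Maps signals to copies carried by the marker (`double` = 2, `single` = 1,
#' `diminished` = partial, `absent` = 0) and collapses consecutive equal
#' calls into segments. Against a constitutive two copies, 1 extra copy is a
#' trisomy and 2 a tetrasomy of the segment. Copies must not increase
#' distally — an isodicentric may step 2 to 1 to 0 along the arm
#' (asymmetric breakpoints), but 0 to 1 is only admissible when an internal
#' deletion was flagged by [infer_breakpoint()].
#'
#' @param calls Calls for one case on one arm.
#' @param arm_row One-row arm tibble.
#' @param flags Flags from [infer_breakpoint()] (`internal_deletion` lifts
#'   the monotonicity requirement).
#' @return Tibble of segments: `chrom`, `arm`, `start`, `end`,
#'   `marker_copies` (`"0"`, `"1"`, `"2"`, `"partial"`), `total_dosage`
#'   (`disomy` / `trisomy` / `tetrasomy` / `partial_gain`).
#' @export
infer_dosage <- function(calls, arm_row, flags = character()) {
  oc <- ordered_arm_calls(calls, arm_row)
  copies <- c(absent = "0", single = "1", double = "2",
              diminished = "partial")[oc$signal]
  num <- c(`0` = 0, `1` = 1, `2` = 2, partial = 0.5)[copies]
  inc <- diff(num) > 0
  if (any(inc) && !"internal_deletion" %in% flags) {
    stop("marker copies increase distally without an internal-deletion flag; ",
         "inconsistent call pattern", call. = FALSE)
  }
  r <- rle(unname(copies))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  purrr::map_dfr(seq_along(r$values), function(i) {
    seg <- oc[starts[i]:ends[i], ]
    cp <- r$values[i]
    tibble::tibble(
      chrom = seg$chrom[1], arm = arm_row$arm,
      start = min(seg$start), end = max(seg$end),
      marker_copies = cp,
      total_dosage = switch(cp, `0` = "disomy", `1` = "trisomy",
                            `2` = "tetrasomy", partial = "partial_gain")
    )
  })
}

#' Bound the euchromatic content of a marker
#'
#' Per involved arm, the content reaching from the junction to the breakpoint
#' is at least the junction-to-nearest-bound distance of the breakpoint
#' interval (clamped at 0) and at most the junction-to-farthest-bound
#' distance, or unbounded (`Inf`) when the breakpoint is open-ended. Totals
#' are summed over arms; a heterochromatic-only marker has content (0, 0).
#'
#' @param breakpoints Breakpoint tibble ([infer_breakpoint()], any arms).
#' @param arms Arm tibble with `junction` and `distal_sign` (rows matching
#'   the breakpoints' chrom/arm).
#' @param decimals Rounding (half-up) for the Mb bounds.
#' @return One-row tibble `content_min_mb`, `content_max_mb`.
#' @export
size_content <- function(breakpoints, arms, decimals = 2) {
  if (is.null(breakpoints) || nrow(breakpoints) == 0L) {
    return(tibble::tibble(content_min_mb = 0, content_max_mb = 0))
  }
  per_arm <- breakpoints |>
    dplyr::group_by(.data$chrom, .data$arm) |>
    dplyr::group_map(function(g, key) {
      a <- arms[arms$chrom == key$chrom & arms$arm == key$arm, ]
      stopifnot(nrow(a) == 1L)
      # outermost interval on the arm bounds the content
      open <- any(g$open_distal)
      outer <- g[which.max(pmax((g$start - a$junction) * a$distal_sign,
                                (g$end - a$junction) * a$distal_sign)), ]
      db <- sort((c(outer$start, outer$end) - a$junction) * a$distal_sign)
      c(min = max(db[1], 0), max = if (open) Inf else max(db[2], 0))
    })
  mins <- sum(vapply(per_arm, `[[`, 0, "min"))
  maxs <- sum(vapply(per_arm, `[[`, 0, "max"))
  tibble::tibble(
    content_min_mb = round_half_up(mins / 1e6, decimals),
    content_max_mb = if (is.finite(maxs)) round_half_up(maxs / 1e6, decimals)
      else Inf
  )
}

#' Mosaic fraction with an exact Clopper-Pearson interval
#'
#' The marker is present in `k` of `n` analyzed metaphases; the mosaic level
#' is the binomial proportion `k/n` with the exact (Clopper-Pearson)
#' two-sided confidence interval from the beta-quantile closed form.
#'
#' @param k Metaphases carrying the marker.
#' @param n Metaphases analyzed (>= 1).
#' @param alpha Two-sided error rate (default 0.05).
#' @return One-row tibble `fraction`, `lower`, `upper`, `n_with_marker`,
#'   `n_total`.
#' @export
mosaic_fraction <- function(k, n, alpha = 0.05) {
  if (length(n) != 1L || is.na(n) || n < 1) {
    stop("n_total must be a positive count", call. = FALSE)
  }
  if (is.na(k) || k < 0 || k > n) {
    stop("n_with_marker must lie in [0, n_total]", call. = FALSE)
  }
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  tibble::tibble(fraction = k / n, lower = lower, upper = upper,
                 n_with_marker = as.integer(k), n_total = as.integer(n))
}

#' Metaphases needed to detect a mosaic marker
#'
#' Smallest `n` such that at least one marker-positive metaphase is seen with
#' probability `conf` when the true mosaic level is `m`:
#' `n = ceil(log(1 - conf) / log(1 - m))`. Diagnostic practice analyzes at
#' least 16 metaphases regardless, so the result is floored at `floor`
#' (set `floor = 0` for the bare closed form).
#'
#' @param m Mosaic level in (0, 1].
#' @param conf Detection probability (default 0.95).
#' @param floor Minimum metaphase count (default 16).
#' @return Integer metaphase count.
#' @export
required_metaphases <- function(m, conf = 0.95, floor = 16) {
  if (any(m <= 0)) stop("a level-0 mosaic is undetectable", call. = FALSE)
  if (any(m > 1)) stop("mosaic level cannot exceed 1", call. = FALSE)
  stopifnot(conf > 0, conf < 1)
  n <- ifelse(m == 1, 1, ceiling(log(1 - conf) / log(1 - m) - 1e-12))
  as.integer(pmax(n, floor))
}

#' Characterize a marker chromosome from its probe calls
#'
#' Runs the full single-case inference: classification, per-arm breakpoint
#' intervals, per-segment dosage, euchromatic content bounds, and the mosaic
#' fraction with its exact interval.
#'
#' @param calls Call tibble for one case ([read_probe_calls()] rows).
#' @param arms Arm tibble with `chrom`, `arm`, `junction`, `distal_sign`,
#'   `start`, `end` covering the arms called.
#' @param alpha Error rate for the mosaic interval.
#' @return An object of class `pericore_characterization`: list with
#'   `case_id`, `structure`, `class`, `breakpoints`, `segments`,
#'   `content_min_mb`, `content_max_mb`, `mosaic`, `flags`.
#' @export
characterize_marker <- function(calls, arms, alpha = 0.05) {
  stopifnot(nrow(calls) > 0L)
  case_id <- calls$case_id[1]
  structure_hint <- if ("structure_hint" %in% names(calls)) {
    h <- unique(stats::na.omit(calls$structure_hint))
    if (length(h)) h[1] else "unknown"
  } else "unknown"
  cls <- classify_marker(calls)
  flags <- character()
  bps <- tibble::tibble()
  segs <- tibble::tibble()
  if (cls == "euchromatic") {
    arm_keys <- unique(calls[, c("chrom", "arm")])
    for (i in seq_len(nrow(arm_keys))) {
      ac <- calls[calls$chrom == arm_keys$chrom[i] &
                    calls$arm == arm_keys$arm[i], ]
      ar <- arms[arms$chrom == arm_keys$chrom[i] &
                   arms$arm == arm_keys$arm[i], ]
      if (nrow(ar) != 1L) {
        stop(sprintf("no arm annotation for %s%s", arm_keys$chrom[i],
                     arm_keys$arm[i]), call. = FALSE)
      }
      b <- infer_breakpoint(ac, ar)
      flags <- union(flags, attr(b, "flags"))
      bps <- dplyr::bind_rows(bps, b)
      segs <- dplyr::bind_rows(segs, infer_dosage(ac, ar, attr(b, "flags")))
    }
  }
  content <- size_content(bps, arms)
  mos <- if (!is.na(calls$n_metaphases_total[1])) {
    mosaic_fraction(calls$n_metaphases_with_marker[1],
                    calls$n_metaphases_total[1], alpha)
  } else NULL
  structure(
    list(case_id = case_id, structure = structure_hint, class = cls,
         breakpoints = bps, segments = segs,
         content_min_mb = content$content_min_mb,
         content_max_mb = content$content_max_mb,
         mosaic = mos, flags = flags),
    class = "pericore_characterization"
  )
}

#' @export
print.pericore_characterization <- function(x, ...) {
  cat(render_text(x), sep = "\n")
  invisible(x)
}
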