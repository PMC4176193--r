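#' Screen clones for FISH specificity
#'
#' A probe is only usable on a panel when its placement is unique enough for
#' an unambiguous FISH signal. Rules, applied in order:
#' \itemize{
#'   \item `excluded` — any alternate placement on a different chromosome
#'     than the primary (wrong/ambiguous chromosomal localization);
#'   \item `cross_hybridizing` — more than `max_alternate_placements`
#'     same-chromosome alternate placements, or a segmental-duplication
#'     overlap above `max_segdup_fraction`;
#'   \item `specific` otherwise.
#' }
#' Labels depend only on each clone's own record, so library order is
#' irrelevant.
#'
#' @param clones Clone tibble ([read_clones()]).
#' @param max_segdup_fraction Segdup-overlap fraction above which a clone is
#'   called cross-hybridizing (default 0.5).
#' @param max_alternate_placements Same-chromosome alternates tolerated
#'   before the cross-hybridizing call (default 0).
#' @return The clone tibble with `label` (`specific` / `cross_hybridizing` /
#'   `excluded`) and `reasons` (list of rule tags) columns appended.
#' @export
screen_clones <- function(clones, max_segdup_fraction = 0.5,
                          max_alternate_placements = 0) {
  res <- purrr::map(seq_len(nrow(clones)), function(i) {
    alt <- clones$alternates[[i]]
    reasons <- character()
    if (nrow(alt) > 0L && any(alt$chrom != clones$chrom[i])) {
      reasons <- "alternate_other_chromosome"
      return(list(label = "excluded", reasons = reasons))
    }
    n_same <- if (nrow(alt) > 0L) sum(alt$chrom == clones$chrom[i]) else 0L
    if (n_same > max_alternate_placements) {
      reasons <- c(reasons, "alternate_same_chromosome")
    }
    if (clones$segdup_fraction[i] > max_segdup_fraction) {
      reasons <- c(reasons, "segdup_overlap")
    }
    list(label = if (length(reasons)) "cross_hybridizing" else "specific",
         reasons = reasons)
  })
  dplyr::mutate(clones,
                label = purrr::map_chr(res, "label"),
                reasons = purrr::map(res, "reasons"))
}

#' Tally a screened library
#'
#' @param screened Tibble with a `label` column (from [screen_clones()]), or
#'   a bare character vector of labels.
#' @return One-row tibble: `n_assayed`, `n_specific`, `n_cross_hybridizing`,
#'   `n_excluded`, `n_retained` (assayed minus excluded), and the
#'   corresponding percentages (half-up, 1 decimal).
#' @export
screen_summary <- function(screened) {
  label <- if (is.data.frame(screened)) screened$label else screened
  n <- length(label)
  ns <- sum(label == "specific")
  nc <- sum(label == "cross_hybridizing")
  ne <- sum(label == "excluded")
  tibble::tibble(
    n_assayed = n, n_specific = ns, n_cross_hybridizing = nc, n_excluded = ne,
    n_retained = n - ne,
    pct_specific = round_half_up(100 * ns / n, 1),
    pct_cross_hybridizing = round_half_up(100 * nc / n, 1),
    pct_excluded = round_half_up(100 * ne / n, 1)
  )
}

#' Locate heterochromatin/euchromatin junctions per arm
#'
#' The junction anchors each core panel. For a p arm it is the start of the
#' het block closest to the centromere on the p side (euchromatin lies at
#' smaller coordinates); for a q arm, the end of the closest q-side block.
#' Arms with no het block at their root get `junction = NA` and status
#' `no_junction` — the reference annotation simply lacks a boundary there.
#'
#' @param arms Arm tibble ([arms_from_het()]).
#' @param het Het-block tibble.
#' @return The arm tibble with `junction` and `junction_status`
#'   (`ok` / `no_junction`) columns.
#' @export
find_junctions <- function(arms, het) {
  res <- purrr::map(seq_len(nrow(arms)), function(i) {
    a <- arms[i, ]
    b <- het[het$chrom == a$chrom, ]
    split <- if (a$arm == "p") a$end else a$start
    if (a$arm == "p") b <- b[b$start < split, ] else b <- b[b$end > split, ]
    if (nrow(b) == 0L) return(list(junction = NA_real_, status = "no_junction"))
    j <- if (a$arm == "p") max(b$start) else min(b$end)
    list(junction = j, status = "ok")
  })
  dplyr::mutate(arms,
                junction = purrr::map_dbl(res, "junction"),
                junction_status = purrr::map_chr(res, "status"))
}

# Arm-oriented clone coordinates: d0 = signed arm distance from the junction
# to the clone edge nearer the centromere, d1 = to the edge nearer the
# telomere. On p arms the proximal edge is the larger coordinate.
arm_clone_coords <- function(clones, arm, junction) {
  sgn <- arm$distal_sign[1]
  prox_edge <- if (sgn > 0) clones$start else clones$end
  dist_edge <- if (sgn > 0) clones$end else clones$start
  dplyr::mutate(clones,
                d0 = (prox_edge - junction) * sgn,
                d1 = (dist_edge - junction) * sgn)
}

#' Select a junction-anchored core panel for one arm
#'
#' Tiles the proximal euchromatin of an arm with clones, starting from the
#' heterochromatin/euchromatin junction. The anchor is the eligible clone
#' whose proximal edge lies nearest the junction (distance floored at 0 for
#' junction-straddling clones); each subsequent clone is chosen greedily
#' among those whose proximal edge falls within `max_gap_bp` of the current
#' distal frontier, taking the one reaching farthest distally. Selection
#' stops once the tiled span reaches `target_span_bp` or `max_clones` clones
#' are used. Farthest-reach greedy selection is the optimal strategy for
#' interval cover, so the panel uses the minimum possible number of clones
#' for the span it achieves.
#'
#' @param arm One-row arm tibble.
#' @param junction Junction coordinate (bp), or `NA`.
#' @param clones Screened clone tibble; only rows labelled in
#'   `eligible_labels` and placed on the arm are considered.
#' @param target_span_bp Span to tile from the proximal clone edge
#'   (default 700,000 bp — the proximal ~0.7 Mb of euchromatin).
#' @param max_gap_bp Largest tolerated gap between consecutive clones
#'   (default 50,000 bp, "contiguous or very close").
#' @param min_clones,max_clones Clone-count bounds (defaults 3 and 7).
#' @param eligible_labels Screening labels usable on a panel.
#' @return One-row tibble: `chrom`, `arm`, `arm_id`, `junction`, `status`,
#'   `status_note`, `n_clones`, `d_het_prox_mb`, `core_span_mb`, and a
#'   `clones` list column holding the ordered (proximal to distal) selected
#'   clones with their arm coordinates.
#' @export
select_core_panel <- function(arm, junction, clones,
                              target_span_bp = 700000, max_gap_bp = 50000,
                              min_clones = 3, max_clones = 7,
                              eligible_labels = "specific") {
  arm_id <- paste0(sub("^chr", "", arm$chrom), arm$arm)
  empty <- function(status, note) {
    tibble::tibble(chrom = arm$chrom, arm = arm$arm, arm_id = arm_id,
                   junction = junction, status = status, status_note = note,
                   n_clones = 0L, d_het_prox_mb = NA_real_,
                   core_span_mb = NA_real_,
                   clones = list(tibble::tibble()))
  }
  on_arm <- clones[clones$chrom == arm$chrom &
                     (clones$start + clones$end) / 2 >= arm$start &
                     (clones$start + clones$end) / 2 < arm$end, , drop = FALSE]
  if (is.na(junction)) {
    return(empty("incomplete_no_junction",
                 "no heterochromatin/euchromatin junction in the annotation"))
  }
  if (nrow(on_arm) == 0L) {
    return(empty("unavailable_no_map", "no mapped clones on this arm"))
  }
  eligible <- on_arm[(if ("label" %in% names(on_arm)) on_arm$label else
    "specific") %in% eligible_labels, , drop = FALSE]
  if (nrow(eligible) == 0L) {
    return(empty("incomplete_segdup",
                 "all mapped clones screened out (cross-hybridization/segdups)"))
  }
  cc <- arm_clone_coords(eligible, arm, junction)
  cc <- cc[cc$d1 > 0, , drop = FALSE]  # must extend into euchromatin
  if (nrow(cc) == 0L) {
    return(empty("unavailable_no_map", "no clones distal to the junction"))
  }

  # anchor: minimal junction distance, then farthest reach, then name
  dprox <- pmax(cc$d0, 0)
  ord <- order(dprox, -cc$d1, cc$name)
  sel <- cc[ord[1], , drop = FALSE]
  frontier <- sel$d1
  repeat {
    span <- frontier - sel$d0[1]
    if (span >= target_span_bp || nrow(sel) >= max_clones) break
    cand <- cc[!cc$name %in% sel$name & cc$d0 <= frontier + max_gap_bp &
                 cc$d1 > frontier, , drop = FALSE]
    if (nrow(cand) == 0L) break
    nxt <- cand[order(-cand$d1, cand$name)[1], , drop = FALSE]
    sel <- dplyr::bind_rows(sel, nxt)
    frontier <- nxt$d1
  }
  span <- frontier - sel$d0[1]
  status <- if (span >= target_span_bp) "complete" else "incomplete_coverage"
  note <- if (status == "complete" && nrow(sel) < min_clones) {
    sprintf("target met with %d clone(s), below the usual minimum of %d",
            nrow(sel), min_clones)
  } else if (status == "incomplete_coverage") {
    sprintf("tiling stalled at %.2f Mb of the %.2f Mb target",
            span / 1e6, target_span_bp / 1e6)
  } else ""
  tibble::tibble(
    chrom = arm$chrom, arm = arm$arm, arm_id = arm_id, junction = junction,
    status = status, status_note = note, n_clones = nrow(sel),
    d_het_prox_mb = round_half_up(max(sel$d0[1], 0) / 1e6, 2),
    core_span_mb = round_half_up(span / 1e6, 2),
    clones = list(sel)
  )
}

#' Design core panels for every non-acrocentric arm of a genome
#'
#' Screens the clone library, finds junctions, and runs
#' [select_core_panel()] on each designable arm.
#'
#' @param genome A `pericore_genome` bundle ([read_genome_tracks()] or
#'   [sim_genome()]).
#' @param ... Passed to [select_core_panel()] (spans, gaps, clone bounds).
#' @param max_segdup_fraction,max_alternate_placements Screening parameters
#'   ([screen_clones()]).
#' @return A `pericore_panel_set`: a tibble with one row per designed panel
#'   (see [select_core_panel()]) carrying the screened library as an
#'   attribute.
#' @export
design_panels <- function(genome, ..., max_segdup_fraction = 0.5,
                          max_alternate_placements = 0) {
  screened <- screen_clones(genome$clones, max_segdup_fraction,
                            max_alternate_placements)
  arms <- find_junctions(genome$arms, genome$het)
  arms <- arms[!arms$acrocentric, , drop = FALSE]
  panels <- purrr::map_dfr(seq_len(nrow(arms)), function(i) {
    select_core_panel(arms[i, ], arms$junction[i], screened, ...)
  })
  structure(panels, class = c("pericore_panel_set", class(panels)),
            screened = screened)
}

#' Recompute coverage statistics for a panel set
#'
#' For each panel: `d_het_prox_mb`, the arm distance from the junction to the
#' proximal edge of the proximal clone (0 when that clone straddles the
#' junction), and `core_span_mb`, the arm distance from the proximal edge of
#' the proximal clone to the distal edge of the distal clone. Both half-up at
#' 2 decimals. Panels without clones get `NA`.
#'
#' @param panels A `pericore_panel_set` or compatible tibble with a `clones`
#'   list column.
#' @return Tibble `arm_id`, `d_het_prox_mb`, `core_span_mb`.
#' @export
panel_stats <- function(panels) {
  purrr::map_dfr(seq_len(nrow(panels)), function(i) {
    cl <- panels$clones[[i]]
    if (is.null(cl) || nrow(cl) == 0L) {
      return(tibble::tibble(arm_id = panels$arm_id[i],
                            d_het_prox_mb = NA_real_, core_span_mb = NA_real_))
    }
    tibble::tibble(
      arm_id = panels$arm_id[i],
      d_het_prox_mb = round_half_up(max(cl$d0[1], 0) / 1e6, 2),
      core_span_mb = round_half_up((cl$d1[nrow(cl)] - cl$d0[1]) / 1e6, 2)
    )
  })
}

#' Summarize a panel set
#'
#' @param panels Panel tibble with `status` and `core_span_mb` columns (a
#'   designed `pericore_panel_set` or a published coverage table from
#'   [read_core_panel_table()]).
#' @return One-row tibble: `n_panels`, `n_complete`, per-status counts, and
#'   `mean_core_span_mb` — the arithmetic mean (half-up, 2 decimals) of
#'   `core_span_mb` over panels that have both a proximal and a distal core
#'   clone (i.e. a non-missing span).
#' @export
summarize_panels <- function(panels) {
  st <- table(panels$status)
  spans <- panels$core_span_mb[!is.na(panels$core_span_mb)]
  out <- tibble::tibble(
    n_panels = nrow(panels),
    n_complete = sum(panels$status == "complete"),
    n_with_span = length(spans),
    mean_core_span_mb = if (length(spans)) round_half_up(mean(spans), 2)
      else NA_real_
  )
  for (s in names(st)) out[[paste0("n_", s)]] <- as.integer(st[[s]])
  out
}

#' Published pericentromeric core-panel coverage table
#'
#' Loads the bundled per-arm coverage table for the human (hg19-like)
#' pericentromeric core panels: heterochromatin boundary positions, proximal
#' and distal core clones, junction-to-clone distance, core span, and panel
#' status (complete; incomplete for arms lacking an annotated junction or
#' blocked by pericentromeric segmental duplications; unavailable where the
#' reference has no physical map). Acrocentric p arms are not designable and
#' are absent.
#'
#' @return Tibble with columns `arm_id`, `chrom`, `arm`, `het_start_mb`,
#'   `het_end_mb`, `proximal_clone`, `d_het_prox_mb`, `distal_clone`,
#'   `core_span_mb`, `status`.
#' @export
read_core_panel_table <- function() {
  path <- system.file("extdata", "core_panel_table.tsv", package = "pericore")
  readr::read_tsv(path, col_types = "cccddcdcdc", progress = FALSE,
                  comment = "#")
}

#' Human-like chromosome arm table
#'
#' The 24 human chromosomes carry 48 arms; the five acrocentric p arms (13p,
#' 14p, 15p, 21p, 22p) hold only satellite material and are not designable,
#' leaving 43 arms that receive pericentromeric panels.
#'
#' @return Arm tibble: `chrom`, `arm`, `arm_id`, `acrocentric`.
#' @export
human_arm_table <- function() {
  chroms <- c(as.character(1:22), "X", "Y")
  acro <- c("13", "14", "15", "21", "22")
  tidyr::expand_grid(chrom = chroms, arm = c("p", "q")) |>
    dplyr::mutate(arm_id = paste0(.data$chrom, .data$arm),
                  acrocentric = .data$arm == "p" & .data$chrom %in% acro)
}
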