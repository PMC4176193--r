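fmt_bp <- function(x) format(x, big.mark = ",", scientific = FALSE, trim = TRUE)

#' Render a characterization as a human-readable summary
#'
#' @param chz A `pericore_characterization`.
#' @param risk Optional risk tibble ([classify_risk()]).
#' @return Character vector of report lines.
#' @export
render_text <- function(chz, risk = NULL) {
  lines <- sprintf("Case %s (%s marker)", chz$case_id, chz$structure)
  if (chz$class == "heterochromatic_only") {
    lines <- c(lines, "  heterochromatic only: no euchromatic probe signal")
  } else if (chz$class == "undetermined") {
    lines <- c(lines, "  undetermined: no informative probe calls")
  } else {
    lines <- c(lines, "  euchromatic marker")
    for (i in seq_len(nrow(chz$breakpoints))) {
      b <- chz$breakpoints[i, ]
      tag <- if (b$open_distal) " (open distal)" else ""
      lines <- c(lines, sprintf("  %s%s breakpoint: %s:%s-%s [%s]%s",
                                sub("chr", "", b$chrom), b$arm, b$chrom,
                                fmt_bp(b$start), fmt_bp(b$end), b$basis, tag))
    }
    lines <- c(lines, if (is.infinite(chz$content_max_mb)) {
      sprintf("  euchromatic content: > %.2f Mb", chz$content_min_mb)
    } else {
      sprintf("  euchromatic content: %.2f-%.2f Mb", chz$content_min_mb,
              chz$content_max_mb)
    })
  }
  if (!is.null(chz$mosaic)) {
    m <- chz$mosaic
    lines <- c(lines, sprintf(
      "  mosaic fraction: %d/%d = %.2f (95%% CI %.2f-%.2f)",
      m$n_with_marker, m$n_total, m$fraction, m$lower, m$upper))
  }
  if (length(chz$flags)) {
    lines <- c(lines, paste0("  flags: ", paste(chz$flags, collapse = ", ")))
  }
  if (!is.null(risk)) {
    lines <- c(lines, sprintf("  risk: %s", risk$label[1]))
    for (n in risk$notes[[1]]) lines <- c(lines, paste0("    note: ", n))
  }
  lines
}

# canonical plain-list form of a characterization (JSON-stable)
report_payload <- function(chz, risk = NULL) {
  list(
    case_id = chz$case_id,
    structure = chz$structure,
    class = chz$class,
    breakpoints = as.data.frame(chz$breakpoints),
    segments = as.data.frame(chz$segments),
    content = list(min_mb = chz$content_min_mb,
                   max_mb = if (is.finite(chz$content_max_mb))
                     chz$content_max_mb else NULL,
                   open = is.infinite(chz$content_max_mb)),
    mosaic = if (is.null(chz$mosaic)) NULL else as.data.frame(chz$mosaic),
    flags = as.list(chz$flags),
    risk = if (is.null(risk)) NULL else
      list(label = risk$label[1], notes = as.list(risk$notes[[1]])),
    tool = list(name = "pericore",
                version = as.character(utils::packageVersion("pericore")))
  )
}

#' Write / read a case report as JSON
#'
#' The JSON form is canonical: writing, reading and re-writing a report is
#' byte-identical.
#'
#' @param chz A `pericore_characterization`.
#' @param path Output file.
#' @param risk Optional risk tibble merged into the report.
#' @return `write_report` invisibly returns the JSON string; `read_report`
#'   the parsed report list.
#' @export
write_report <- function(chz, path, risk = NULL) {
  json <- report_json(report_payload(chz, risk))
  writeLines(json, path)
  invisible(json)
}

report_json <- function(payload) {
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, null = "null"))
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(paste(readLines(path), collapse = "\n"),
                     simplifyVector = TRUE, simplifyDataFrame = TRUE)
}

#' Run the full characterization pipeline over a call table
#'
#' Stage order per case: classify, infer breakpoints, dosage, content
#' sizing, mosaic fraction, array-CGH refinement (when segments are given),
#' phenotype risk (when a region map is given).
#'
#' @param calls Probe-call tibble ([read_probe_calls()]), any number of
#'   cases.
#' @param arms Arm tibble with junctions (`chrom`, `arm`, `junction`,
#'   `distal_sign`, `start`, `end`).
#' @param acgh Optional aCGH segment tibble with calls and boundary pairs.
#' @param region_map Optional critical-region map
#'   ([read_critical_regions()]).
#' @param alpha Mosaic CI error rate.
#' @param mosaic_attenuation_threshold See [classify_risk()].
#' @return Named list (by case id) of lists with elements `characterization`
#'   and `risk`.
#' @export
run_pipeline <- function(calls, arms, acgh = NULL, region_map = NULL,
                         alpha = 0.05, mosaic_attenuation_threshold = 0.30) {
  stopifnot(nrow(calls) > 0L)
  ids <- unique(calls$case_id)
  out <- lapply(ids, function(id) {
    chz <- characterize_marker(calls[calls$case_id == id, ], arms, alpha)
    if (!is.null(acgh)) chz <- refine_characterization(chz, acgh, arms)
    risk <- if (!is.null(region_map) && chz$class != "undetermined") {
      classify_risk(chz, region_map, arms, mosaic_attenuation_threshold)
    } else NULL
    list(characterization = chz, risk = risk)
  })
  stats::setNames(out, ids)
}
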