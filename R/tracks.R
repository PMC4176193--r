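#' Read a chromosome-sizes table
#'
#' Two-column TSV (chromosome name, length in bp), the assembly skeleton all
#' other tracks are validated against.
#'
#' @param path Path to the TSV (no header).
#' @return A tibble with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = "cd", progress = FALSE)
  if (any(duplicated(x$chrom))) {
    stop(sprintf("duplicate chromosome name '%s' in %s",
                 x$chrom[duplicated(x$chrom)][1], path), call. = FALSE)
  }
  if (any(x$length <= 0)) stop("chromosome lengths must be > 0", call. = FALSE)
  x
}

# merge abutting/overlapping blocks on one chromosome, sorted by start
merge_blocks <- function(b) {
  b <- b[order(b$start), , drop = FALSE]
  out <- b[1, , drop = FALSE]
  for (i in seq_len(nrow(b))[-1]) {
    if (b$start[i] <= out$end[nrow(out)]) {
      out$end[nrow(out)] <- max(out$end[nrow(out)], b$end[i])
    } else {
      out <- rbind(out, b[i, ])
    }
  }
  out
}

bed_check <- function(x, assembly, path) {
  if (!is.null(assembly)) {
    unknown <- !x$chrom %in% assembly$chrom
    if (any(unknown)) {
      stop(sprintf("%s line %d: unknown chromosome '%s'", path,
                   which(unknown)[1], x$chrom[which(unknown)[1]]), call. = FALSE)
    }
    len <- assembly$length[match(x$chrom, assembly$chrom)]
    bad <- x$start < 0 | x$end > len
    if (any(bad)) {
      stop(sprintf("%s line %d: interval outside chromosome bounds", path,
                   which(bad)[1]), call. = FALSE)
    }
  }
  if (any(x$end < x$start)) {
    stop(sprintf("%s line %d: end precedes start", path,
                 which(x$end < x$start)[1]), call. = FALSE)
  }
  invisible(x)
}

#' Read heterochromatin blocks (BED3)
#'
#' Blocks on the same chromosome must be sorted and non-overlapping; a block
#' at an arm root defines that arm's heterochromatin/euchromatin junction.
#'
#' @param path Path to a BED3 file.
#' @param assembly Optional assembly tibble for bounds checking.
#' @return Tibble `chrom`, `start`, `end`.
#' @export
read_het_blocks <- function(path, assembly = NULL) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                       col_types = "cdd", progress = FALSE)
  bed_check(x, assembly, path)
  for (ch in unique(x$chrom)) {
    b <- x[x$chrom == ch, ]
    if (is.unsorted(b$start)) {
      stop(sprintf("%s: het blocks on %s are unsorted", path, ch), call. = FALSE)
    }
    if (nrow(b) > 1L && any(b$start[-1] < b$end[-nrow(b)])) {
      stop(sprintf("%s: overlapping het blocks on %s", path, ch), call. = FALSE)
    }
  }
  x
}

#' @rdname read_het_blocks
#' @export
read_segdups <- function(path, assembly = NULL) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                       col_types = "cdd", progress = FALSE)
  bed_check(x, assembly, path)
  x
}

#' Read a clone (probe) library
#'
#' BED4+ with columns chrom, start, end, name; optional column 5 holds
#' comma-separated alternate placements as `chr:start-end` strings, optional
#' column 6 the fraction of the primary placement covered by segmental
#' duplications.
#'
#' @param path Path to the clone BED file.
#' @param assembly Optional assembly tibble for bounds checking.
#' @return Tibble `name`, `chrom`, `start`, `end`, `alternates` (list column
#'   of interval tibbles), `segdup_fraction`.
#' @export
read_clones <- function(path, assembly = NULL) {
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (ncol(raw) < 4L) stop(sprintf("%s: clone BED needs >= 4 columns", path),
                           call. = FALSE)
  x <- tibble::tibble(
    name = raw[[4]],
    chrom = raw[[1]],
    start = as.numeric(raw[[2]]),
    end = as.numeric(raw[[3]]),
    alternates = if (ncol(raw) >= 5L) parse_alternates(raw[[5]]) else
      rep(list(interval_tbl(character(), numeric(), numeric())), nrow(raw)),
    segdup_fraction = if (ncol(raw) >= 6L) {
      v <- suppressWarnings(as.numeric(raw[[6]]))
      ifelse(is.na(v), 0, v)
    } else 0
  )
  bed_check(x, assembly, path)
  if (any(duplicated(x$name))) {
    stop(sprintf("%s line %d: duplicate clone name '%s'", path,
                 which(duplicated(x$name))[1],
                 x$name[duplicated(x$name)][1]), call. = FALSE)
  }
  if (any(x$segdup_fraction < 0 | x$segdup_fraction > 1)) {
    stop(sprintf("%s: segdup_fraction outside [0, 1]", path), call. = FALSE)
  }
  x
}

parse_alternates <- function(field) {
  lapply(field, function(f) {
    if (is.na(f) || f == "" || f == ".") {
      return(interval_tbl(character(), numeric(), numeric()))
    }
    parse_region_string(strsplit(f, ",(?=chr)", perl = TRUE)[[1]])
  })
}

#' Annotate clones with their segmental-duplication overlap
#'
#' Computes, per clone, the fraction of the primary placement covered by the
#' union of segdup intervals on the same chromosome, and stores it in
#' `segdup_fraction` (overwriting any value read from column 6).
#'
#' @param clones Clone tibble from [read_clones()].
#' @param segdups Segdup tibble (`chrom`, `start`, `end`).
#' @return The clone tibble with `segdup_fraction` recomputed.
#' @export
annotate_segdup_fraction <- function(clones, segdups) {
  frac <- purrr::map2_dbl(seq_len(nrow(clones)), clones$chrom, function(i, ch) {
    cl <- clones[i, ]
    sd <- segdups[segdups$chrom == ch, ]
    if (nrow(sd) == 0L || cl$end == cl$start) return(0)
    lo <- pmax(sd$start, cl$start)
    hi <- pmin(sd$end, cl$end)
    cov <- sum(pmax(hi - lo, 0))
    min(cov / (cl$end - cl$start), 1)
  })
  dplyr::mutate(clones, segdup_fraction = frac)
}

#' Build chromosome arms from heterochromatin annotation
#'
#' Each chromosome gets a p and a q arm. The p/q split is placed inside the
#' pericentromeric heterochromatin complex: at the midpoint of the largest
#' gap between merged het blocks (assemblies leave a centromeric gap between
#' the two arm-root blocks), or at the midpoint of a single contiguous
#' complex. Chromosomes without het annotation are split at their midpoint.
#' On p arms distal (telomeric) direction is toward smaller coordinates
#' (`distal_sign = -1`), on q arms toward larger (`distal_sign = +1`).
#' Acrocentric p arms carry no designable euchromatin and are flagged.
#'
#' @param assembly Assembly tibble (`chrom`, `length`).
#' @param het Het-block tibble.
#' @param acrocentric_p Character vector of chromosomes whose p arm is
#'   acrocentric (e.g. `c("chr13","chr14","chr15","chr21","chr22")`).
#' @return Arm tibble: `chrom`, `arm`, `acrocentric`, `start`, `end`,
#'   `distal_sign`.
#' @export
arms_from_het <- function(assembly, het, acrocentric_p = character()) {
  purrr::map_dfr(seq_len(nrow(assembly)), function(i) {
    ch <- assembly$chrom[i]
    len <- assembly$length[i]
    b <- het[het$chrom == ch, ]
    split <- if (nrow(b) == 0L) {
      len / 2
    } else {
      m <- merge_blocks(b)
      if (nrow(m) == 1L) {
        (m$start + m$end) / 2
      } else {
        gaps <- m$start[-1] - m$end[-nrow(m)]
        g <- which.max(gaps)
        (m$end[g] + m$start[g + 1]) / 2
      }
    }
    tibble::tibble(
      chrom = ch,
      arm = c("p", "q"),
      acrocentric = c(ch %in% acrocentric_p, FALSE),
      start = c(0, split),
      end = c(split, len),
      distal_sign = c(-1, 1)
    )
  })
}

#' Load a full annotation-track bundle
#'
#' Reads chromosome sizes, het blocks, clone placements and (optionally) a
#' segdup track, validates the cross-file invariants, and returns the bundle
#' every downstream step consumes.
#'
#' @param chrom_sizes,het,clones,segdups File paths; `segdups` may be `NULL`.
#' @param acrocentric_p Chromosomes with acrocentric p arms.
#' @return A list of class `pericore_genome` with elements `assembly`,
#'   `arms`, `het`, `clones`, `segdups`.
#' @export
read_genome_tracks <- function(chrom_sizes, het, clones, segdups = NULL,
                               acrocentric_p = character()) {
  assembly <- read_chrom_sizes(chrom_sizes)
  hetb <- read_het_blocks(het, assembly)
  cl <- read_clones(clones, assembly)
  sd <- if (is.null(segdups)) {
    interval_tbl(character(), numeric(), numeric())
  } else {
    read_segdups(segdups, assembly)
  }
  if (!is.null(segdups)) cl <- annotate_segdup_fraction(cl, sd)
  structure(
    list(assembly = assembly,
         arms = arms_from_het(assembly, hetb, acrocentric_p),
         het = hetb, clones = cl, segdups = sd),
    class = "pericore_genome"
  )
}

#' @export
print.pericore_genome <- function(x, ...) {
  cat(sprintf("<pericore_genome> %d chromosomes, %d het blocks, %d clones, %d segdups\n",
              nrow(x$assembly), nrow(x$het), nrow(x$clones), nrow(x$segdups)))
  invisible(x)
}
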