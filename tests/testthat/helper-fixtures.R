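# Shared fixtures: published coordinate workups rebuilt as call tables, and
# independent brute-force oracles for the greedy/screening paths.

# 4p workup: present clone with outer (proximal) edge 45,736,237, absent
# clone with outer (distal) edge 44,621,297; junction at 48.2 Mb.
chr4p_arm <- function() {
  tibble::tibble(chrom = "chr4", arm = "p", start = 0, end = 48.2e6,
                 distal_sign = -1, junction = 48.2e6)
}

chr4p_calls <- function() {
  tibble::tibble(
    case_id = "p3", probe_name = c("RP11-178N2", "RP11-89F4"),
    chrom = "chr4",
    start = c(45556237, 44621297), end = c(45736237, 44801297),
    arm = "p", signal = c("single", "absent"), structure_hint = "ring",
    n_metaphases_with_marker = 14L, n_metaphases_total = 16L)
}

# 11p workup: present edge 50,111,641, absent edge 49,259,387; junction 51.6 Mb
chr11p_arm <- function() {
  tibble::tibble(chrom = "chr11", arm = "p", start = 0, end = 51.6e6,
                 distal_sign = -1, junction = 51.6e6)
}

chr11p_calls <- function() {
  tibble::tibble(
    case_id = "p5", probe_name = c("RP11-746P9", "RP11-1062A8"),
    chrom = "chr11",
    start = c(49931641, 49259387), end = c(50111641, 49439387),
    arm = "p", signal = c("single", "absent"), structure_hint = "ring",
    n_metaphases_with_marker = 15L, n_metaphases_total = 16L)
}

# random interval on a toy chromosome
rand_interval <- function(chrom = "chr1", max_pos = 2e8) {
  a <- sort(round(runif(2, 0, max_pos)))
  interval_tbl(chrom, a[1], a[2])
}

# independent re-statement of the three screening rules, evaluated bluntly
oracle_screen_label <- function(clone_row, max_segdup = 0.5, max_alt = 0) {
  alt <- clone_row$alternates[[1]]
  other <- nrow(alt) > 0 && any(alt$chrom != clone_row$chrom)
  if (other) return("excluded")
  same <- if (nrow(alt) > 0) sum(alt$chrom == clone_row$chrom) else 0
  if (same > max_alt || clone_row$segdup_fraction > max_segdup) {
    return("cross_hybridizing")
  }
  "specific"
}

# random clone library in arm coordinates on a q-like arm: junction at 0,
# clones as (d0, d1) pairs guaranteed to admit a tiling of the target
rand_tiling_library <- function(n = 10, target = 7e5, max_gap = 5e4,
                                width_range = c(1e5, 2.5e5)) {
  # a feasible chain first
  chain <- list()
  d0 <- -runif(1, 0, 2e4)
  frontier <- d0
  while (frontier < target) {
    w <- runif(1, width_range[1], width_range[2])
    start <- frontier - runif(1, 0, min(max_gap, 2e4))  # slight overlap
    chain[[length(chain) + 1L]] <- c(start, start + w)
    frontier <- start + w
  }
  extra <- max(n - length(chain), 0)
  pads <- replicate(extra, {
    s <- runif(1, -5e4, target)
    c(s, s + runif(1, width_range[1], width_range[2]))
  }, simplify = FALSE)
  all <- c(chain, pads)
  m <- do.call(rbind, all)
  tibble::tibble(
    name = sprintf("L%03d", seq_len(nrow(m))),
    chrom = "chrT", start = 1e7 + m[, 1], end = 1e7 + m[, 2],
    alternates = rep(list(interval_tbl(character(), numeric(), numeric())),
                     nrow(m)),
    segdup_fraction = 0, label = "specific")
}

arm_chrT <- function() {
  tibble::tibble(chrom = "chrT", arm = "q", acrocentric = FALSE,
                 start = 9e6, end = 5e7, distal_sign = 1)
}

# exhaustive minimum clone count: subsets containing the anchor clone, chained
# along the arm with gaps <= max_gap, reaching target span from the anchor's
# proximal edge; Inf if infeasible
oracle_min_cover <- function(lib, junction, target = 7e5, max_gap = 5e4) {
  d0 <- lib$start - junction
  d1 <- lib$end - junction
  keep <- d1 > 0
  d0 <- d0[keep]; d1 <- d1[keep]; nm <- lib$name[keep]
  if (!length(d0)) return(Inf)
  anchor <- order(pmax(d0, 0), -d1, nm)[1]
  n <- length(d0)
  others <- setdiff(seq_len(n), anchor)
  feasible <- function(idx) {
    idx <- idx[order(d0[idx], -d1[idx])]
    if (idx[1] != anchor && d0[idx[1]] > d0[anchor]) return(FALSE)
    frontier <- -Inf
    base <- d0[anchor]
    cur <- d1[anchor]
    rest <- setdiff(idx, anchor)
    rest <- rest[order(d0[rest])]
    for (j in rest) {
      if (d0[j] > cur + max_gap) return(FALSE)
      cur <- max(cur, d1[j])
    }
    cur - base >= target
  }
  for (k in 1:n) {
    if (k == 1) {
      if (feasible(anchor)) return(1L)
      next
    }
    if (length(others) < k - 1) break
    combs <- utils::combn(others, k - 1, simplify = FALSE)
    for (cmb in combs) {
      if (feasible(c(anchor, cmb))) return(k)
    }
  }
  Inf
}

# Clopper-Pearson oracle via the base binomial test (independent code path)
oracle_cp <- function(k, n, alpha = 0.05) {
  as.numeric(stats::binom.test(k, n, conf.level = 1 - alpha)$conf.int)
}

small_genome <- function(seed = 42, ...) sim_genome(seed = seed, ...)
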