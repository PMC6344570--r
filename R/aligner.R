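# Constrained alignment of a density trace onto one candidate sequence.
#
# The trace is a sequence of segments; each segment expands, for a given
# choice of gap lengths, into a run of "slots" (observed class or
# uninformative placeholder) that must map to consecutive candidate
# positions. Segments map left-to-right to non-overlapping candidate
# windows (missing regions between segments have length >= 0 and no upper
# bound), and the whole trace may sit anywhere inside the candidate (both
# candidate termini may be unmodeled). The search is exact enumeration
# over segment offsets and gap-length tuples; no insertions or deletions
# are allowed inside observed runs — only gap regions and missing regions
# absorb length uncertainty.

new_exclusion <- function(reason, detail = "") {
  structure(list(reason = reason, detail = detail), class = "trace_exclusion")
}

#' @export
print.trace_exclusion <- function(x, ...) {
  cat("<exclusion> ", x$reason,
      if (nzchar(x$detail)) paste0(": ", x$detail), "\n", sep = "")
  invisible(x)
}

#' Is an alignment outcome an exclusion?
#' @param x Result of [align_trace()] or [align_trace_oracle()].
#' @return Logical scalar.
#' @export
is_exclusion <- function(x) inherits(x, "trace_exclusion")

new_alignment_result <- function(candidate_id, segment_offsets, gap_lengths,
                                 mean_score, n_scored) {
  structure(list(
    candidate_id = candidate_id,
    start_offset = segment_offsets[1],
    segment_offsets = segment_offsets,
    gap_lengths = gap_lengths,
    mean_score = mean_score,
    n_scored = n_scored
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("<alignment> ", x$candidate_id, " @", x$start_offset,
      "  mean ", format(round(x$mean_score, 4)), " over ", x$n_scored,
      " scored position(s)\n", sep = "")
  invisible(x)
}

# Expand one segment under one gap-length tuple into slot classes:
# integer vector, NA = uninformative slot (ambiguous or inside a gap).
segment_slots <- function(seg, gaps) {
  kinds <- segment_kinds(seg)
  lens <- rep(1L, length(kinds))
  lens[kinds == "gap"] <- as.integer(gaps)
  slots <- rep(NA_integer_, sum(lens))
  starts <- cumsum(c(1L, lens[-length(lens)]))
  obs <- which(kinds == "obs")
  slots[starts[obs]] <- vapply(seg[obs], function(e) e$size, 0L)
  slots
}

segment_gap_ranges <- function(seg) {
  lapply(Filter(function(e) e$kind == "gap", seg), gap_bounds)
}

# Gap tuples of one segment in lexicographically ascending order.
gap_tuple_grid <- function(ranges) {
  if (!length(ranges)) return(matrix(integer(0), nrow = 1, ncol = 0))
  vals <- lapply(ranges, function(b) seq.int(b[1], b[2]))
  # expand.grid varies the first factor fastest; reverse so the first gap
  # varies slowest, giving rows in lexicographic order.
  g <- do.call(expand.grid, rev(vals))
  as.matrix(g[, rev(seq_len(ncol(g))), drop = FALSE])
}

# Per-offset score sums and scored-position counts for a fixed slot
# vector against candidate classes. Offsets are 0-based candidate
# positions of the first slot. -Inf sum marks an inadmissible placement.
slots_offset_table <- function(slots, cand, lookup) {
  len <- length(slots)
  L <- length(cand)
  n_off <- L - len + 1L
  if (n_off < 1L) {
    return(list(sums = numeric(0), counts = integer(0), len = len))
  }
  sums <- numeric(n_off)
  counts <- integer(n_off)
  obs_idx <- which(!is.na(slots))
  for (j in obs_idx) {
    cc <- cand[j:(j + n_off - 1L)]
    solid <- !is.na(cc)
    v <- numeric(n_off)
    v[solid] <- lookup[cbind(slots[j] + 1L, cc[solid] + 1L)]
    sums <- sums + v
    counts <- counts + as.integer(solid)
  }
  list(sums = sums, counts = counts, len = len)
}

# Precompute, per segment, the per-gap-tuple offset tables.
segment_tables <- function(trace, cand, lookup) {
  lapply(trace$segments, function(seg) {
    ranges <- segment_gap_ranges(seg)
    tuples <- gap_tuple_grid(ranges)
    tabs <- lapply(seq_len(nrow(tuples)), function(r) {
      slots <- segment_slots(seg, tuples[r, ])
      slots_offset_table(slots, cand, lookup)
    })
    list(tuples = tuples, tabs = tabs)
  })
}

#' Align a density trace onto one candidate sequence
#'
#' Finds, by exact enumeration, the admissible placement of the trace on
#' the candidate that maximizes the mean per-residue score. A placement is
#' admissible when every aligned (observed, candidate) pair passes the
#' one-sided exclusion rule (observed class must not exceed the candidate
#' class by `exclusion_delta` or more), each gap region takes a length
#' within its bounds, and segments map order-preservingly to
#' non-overlapping candidate windows. Ambiguous trace positions and
#' wildcard candidate positions consume one residue but neither add to the
#' score sum nor to `n_scored`. Ties in mean score break
#' deterministically: smallest `start_offset`, then lexicographically
#' smallest gap-length tuple, then smallest later segment offsets.
#'
#' @param trace A `density_trace`.
#' @param candidate An `encoded_sequence` (see [encode_sequence()]).
#' @param scores A `score_table`; default [default_score_table()].
#' @param placement_budget Warn when the enumeration would visit more than
#'   this many placements (default `5e6`); the search still runs.
#' @return An `alignment_result`, or a `trace_exclusion` with reason
#'   `candidate_too_short` (candidate shorter than the trace's minimum
#'   length), `size_violation` (no placement passes the exclusion rule at
#'   every aligned position), or `no_scored_positions` (placements exist
#'   but none aligns an observed class with a non-wildcard residue, so the
#'   mean is undefined). Offsets are 0-based.
#' @export
align_trace <- function(trace, candidate, scores = default_score_table(),
                        placement_budget = 5e6) {
  cand <- candidate$classes
  if (!length(cand)) stop("empty candidate sequence", call. = FALSE)
  bounds <- trace_length_bounds(trace)
  if (length(cand) < bounds$min_len) {
    return(new_exclusion("candidate_too_short",
                         sprintf("candidate %s has %d residues < trace minimum %d",
                                 candidate$id, length(cand), bounds$min_len)))
  }
  lookup <- score_lookup_matrix(scores)
  segs <- segment_tables(trace, cand, lookup)

  # admissible placements per segment, ignoring the ordering constraint
  est <- prod(vapply(segs, function(s) {
    max(1, sum(vapply(s$tabs, function(t) sum(is.finite(t$sums)), 0L)))
  }, 0))
  if (est > placement_budget) {
    warning(sprintf("alignment enumeration may visit ~%.3g placements (budget %.3g)",
                    est, placement_budget), call. = FALSE)
  }

  n_gaps <- vapply(segs, function(s) ncol(s$tuples), 0L)
  best <- new.env(parent = emptyenv())
  best$mean <- -Inf
  best$key <- NULL
  best$res <- NULL
  any_admissible <- FALSE

  # Depth-first over segments; min_start is the smallest admissible
  # 0-based start of the current segment.
  recurse <- function(i, min_start, acc_sum, acc_n, starts, gaps) {
    if (i > length(segs)) {
      any_admissible <<- TRUE
      if (acc_n < 1L) return(invisible())
      m <- acc_sum / acc_n
      key <- c(starts[1], unlist(gaps, use.names = FALSE), starts[-1])
      if (m > best$mean + 1e-12 ||
          (abs(m - best$mean) <= 1e-12 && !is.null(best$key) && key_less(key, best$key))) {
        best$mean <- m
        best$key <- key
        best$res <- list(starts = starts, gaps = gaps, sum = acc_sum, n = acc_n)
      }
      return(invisible())
    }
    s <- segs[[i]]
    for (r in seq_along(s$tabs)) {
      tab <- s$tabs[[r]]
      if (!length(tab$sums)) next
      offs <- seq.int(0L, length(tab$sums) - 1L)
      ok <- offs >= min_start & is.finite(tab$sums)
      for (k in which(ok)) {
        off <- offs[k]
        recurse(i + 1L, off + tab$len, acc_sum + tab$sums[k], acc_n + tab$counts[k],
                c(starts, off), c(gaps, list(s$tuples[r, ])))
      }
    }
    invisible()
  }
  recurse(1L, 0L, 0, 0L, integer(0), list())

  if (!is.null(best$res)) {
    r <- best$res
    return(new_alignment_result(candidate$id, as.integer(r$starts),
                                as.integer(unlist(r$gaps, use.names = FALSE)),
                                r$sum / r$n, r$n))
  }
  if (any_admissible) {
    return(new_exclusion("no_scored_positions",
                         sprintf("candidate %s: no aligned position carries side-chain evidence",
                                 candidate$id)))
  }
  new_exclusion("size_violation",
                sprintf("candidate %s: every placement has an observed class exceeding the candidate class by >= %d",
                        candidate$id, scores$exclusion_delta))
}

key_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Reference brute-force aligner for small instances
#'
#' Independent re-implementation of the [align_trace()] semantics by
#' naive enumeration of every segment placement and gap-length tuple,
#' scoring position by position with [score_pair()]. Used as the oracle
#' in equivalence tests; guarded to small instances.
#'
#' @inheritParams align_trace
#' @param max_positions Guard on total minimum trace length (default 25).
#' @param max_candidate Guard on candidate length (default 60).
#' @return Same contract as [align_trace()].
#' @export
align_trace_oracle <- function(trace, candidate, scores = default_score_table(),
                               max_positions = 25L, max_candidate = 60L) {
  cand <- candidate$classes
  if (!length(cand)) stop("empty candidate sequence", call. = FALSE)
  bounds <- trace_length_bounds(trace)
  if (bounds$min_len > max_positions || length(cand) > max_candidate) {
    stop("instance too large for the oracle aligner", call. = FALSE)
  }
  if (length(cand) < bounds$min_len) {
    return(new_exclusion("candidate_too_short", ""))
  }
  L <- length(cand)
  nseg <- length(trace$segments)

  placements <- list()
  enumerate <- function(i, min_start, starts, gaps) {
    if (i > nseg) {
      placements[[length(placements) + 1L]] <<- list(starts = starts, gaps = gaps)
      return(invisible())
    }
    seg <- trace$segments[[i]]
    ranges <- segment_gap_ranges(seg)
    tuples <- gap_tuple_grid(ranges)
    for (r in seq_len(nrow(tuples))) {
      g <- tuples[r, ]
      len <- sum(vapply(seg, function(e) {
        if (e$kind == "gap") 0L else 1L
      }, 0L)) + sum(g)
      if (min_start > L - len) next
      for (off in seq.int(min_start, L - len)) {
        enumerate(i + 1L, off + len, c(starts, off), c(gaps, list(g)))
      }
    }
    invisible()
  }
  enumerate(1L, 0L, integer(0), list())

  any_admissible <- FALSE
  best <- NULL
  for (p in placements) {
    total <- 0; n <- 0L; admissible <- TRUE
    for (i in seq_len(nseg)) {
      slots <- segment_slots(trace$segments[[i]], p$gaps[[i]])
      for (j in seq_along(slots)) {
        if (is.na(slots[j])) next
        cc <- cand[p$starts[i] + j]        # starts are 0-based
        sc <- score_pair(slots[j], cc, scores)
        if (is_excluded_score(sc)) { admissible <- FALSE; break }
        if (!is.na(sc)) { total <- total + sc; n <- n + 1L }
      }
      if (!admissible) break
    }
    if (!admissible) next
    any_admissible <- TRUE
    if (n < 1L) next
    m <- total / n
    key <- c(p$starts[1], unlist(p$gaps, use.names = FALSE), p$starts[-1])
    if (is.null(best) || m > best$mean + 1e-12 ||
        (abs(m - best$mean) <= 1e-12 && key_less(key, best$key))) {
      best <- list(mean = m, key = key, starts = p$starts, gaps = p$gaps, n = n)
    }
  }
  if (!is.null(best)) {
    return(new_alignment_result(candidate$id, as.integer(best$starts),
                                as.integer(unlist(best$gaps, use.names = FALSE)),
                                best$mean, best$n))
  }
  if (any_admissible) return(new_exclusion("no_scored_positions", ""))
  new_exclusion("size_violation", "")
}

#' Expand an alignment into per-position (observed, candidate) pairs
#'
#' Utility for independent post-hoc verification: lists every aligned
#' position with its trace evidence and candidate class, so the exclusion
#' rule and the mean score can be re-checked outside the search.
#'
#' @param trace A `density_trace`.
#' @param candidate An `encoded_sequence`.
#' @param result An `alignment_result` for this pair.
#' @return data.frame with columns `segment`, `cand_pos` (0-based),
#'   `observed` (`NA` for uninformative slots) and `candidate_class`.
#' @export
alignment_pairs <- function(trace, candidate, result) {
  rows <- list()
  for (i in seq_along(trace$segments)) {
    seg <- trace$segments[[i]]
    n_gap <- sum(vapply(seg, function(e) e$kind == "gap", TRUE))
    gi_before <- if (i == 1L) 0L else sum(vapply(trace$segments[seq_len(i - 1L)],
      function(s) sum(vapply(s, function(e) e$kind == "gap", TRUE)), 0L))
    gaps <- result$gap_lengths[gi_before + seq_len(n_gap)]
    slots <- segment_slots(seg, gaps)
    pos <- result$segment_offsets[i] + seq_along(slots) - 1L
    rows[[i]] <- data.frame(segment = i, cand_pos = pos, observed = slots,
                            candidate_class = candidate$classes[pos + 1L])
  }
  do.call(rbind, rows)
}
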