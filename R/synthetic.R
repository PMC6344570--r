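# Synthetic proteomes and noisy density traces with known ground truth.
# The noise model emulates the three poor-density situations seen when
# interpreting a map by eye: ambiguous positions (side chain unreadable),
# under-called size classes (partially disordered side chains — sizes are
# only ever depressed, never inflated, consistent with the one-sided
# exclusion rule), bounded-length gap regions, and completely missing
# stretches that break the trace into segments.

#' Noise model for simulated density traces
#'
#' @param p_ambiguous Per-position probability that the side chain is
#'   unreadable (element becomes ambiguous). Default 0.1.
#' @param p_underclass Per-position probability that the observed class is
#'   depressed by one (floored at 0). Default 0.05.
#' @param gap_rate Expected gap regions per 100 residues. Default 2 (one
#'   per 50 residues).
#' @param gap_x Maximum possible error `x` reported for each gap region.
#'   Default 2.
#' @param missing_rate Expected completely-missing regions (segment
#'   breaks) per trace. Default 0.
#' @param seed Optional integer seed applied by [simulate_trace()].
#' @return A `noise_model` list.
#' @export
noise_model <- function(p_ambiguous = 0.1, p_underclass = 0.05, gap_rate = 2,
                        gap_x = 2L, missing_rate = 0, seed = NULL) {
  stopifnot(p_ambiguous >= 0, p_ambiguous <= 1,
            p_underclass >= 0, p_underclass <= 1,
            gap_rate >= 0, gap_x >= 0, missing_rate >= 0)
  structure(list(p_ambiguous = p_ambiguous, p_underclass = p_underclass,
                 gap_rate = gap_rate, gap_x = as.integer(gap_x),
                 missing_rate = missing_rate, seed = seed),
            class = "noise_model")
}

#' Generate a reproducible decoy proteome
#'
#' Residues are drawn uniformly over the 20 standard amino acids;
#' sequence lengths uniformly over `length_range`.
#'
#' @param n_seqs Number of sequences (>= 1).
#' @param length_range Integer `c(min, max)` sequence length; default
#'   `c(100, 400)`.
#' @param seed Optional integer seed; identical seeds give identical
#'   proteomes.
#' @return Named character vector of sequences (ids `synth_001`, ...),
#'   directly usable by [screen_proteome()].
#' @export
generate_proteome <- function(n_seqs, length_range = c(100L, 400L), seed = NULL) {
  if (n_seqs < 1L) stop("n_seqs must be >= 1", call. = FALSE)
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || any(length_range < 1L) ||
      length_range[1] > length_range[2]) {
    stop("length_range must be c(min, max) with 1 <= min <= max", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  lens <- sample.int(length_range[2] - length_range[1] + 1L, n_seqs,
                     replace = TRUE) + length_range[1] - 1L
  seqs <- vapply(lens, function(L) {
    paste(sample(AA_STANDARD, L, replace = TRUE), collapse = "")
  }, "")
  stats::setNames(seqs, sprintf("synth_%03d", seq_len(n_seqs)))
}

#' Write a proteome to FASTA
#' @param proteome Named character vector of sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(proteome)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Simulate a density trace from a known source sequence
#'
#' Encodes the residues of `span` as true size classes, then applies the
#' noise model: each position may become ambiguous or have its class
#' depressed by one; runs of positions are replaced by gap regions whose
#' estimate `n` is the true run length plus a small perturbation, clamped
#' so the true length always stays within the gap's admissible bounds;
#' and, at positive `missing_rate`, runs are deleted entirely, splitting
#' the trace into segments. With zero noise the trace is the exact
#' encoding of the span in a single segment.
#'
#' @param seq Source amino-acid string.
#' @param span Integer `c(start, end)`, 1-based inclusive on `seq`.
#' @param noise A `noise_model`; default `noise_model()`.
#' @param size_table A `size_table`; default [default_size_table()].
#' @param trace_id Identifier for the emitted trace.
#' @param group_id Optional group identifier.
#' @return List with `trace` (a `density_trace`) and `truth` (source id,
#'   span, true classes, 0-based true segment offsets within the source,
#'   and a per-gap table of true length vs reported `n`/`x`).
#' @export
simulate_trace <- function(seq, span, noise = noise_model(),
                           size_table = default_size_table(),
                           trace_id = "sim", group_id = NULL) {
  span <- as.integer(span)
  L <- nchar(seq)
  if (length(span) != 2L || span[1] < 1L || span[2] > L || span[1] > span[2]) {
    stop("span must be c(start, end), 1-based inclusive, within the sequence",
         call. = FALSE)
  }
  if (!is.null(noise$seed)) set.seed(noise$seed)
  sub <- substr(seq, span[1], span[2])
  true_classes <- encode_sequence(sub, size_table, id = "span")$classes
  n <- length(true_classes)

  # Position roles: 0 = kept, 1 = in a gap region, 2 = missing.
  role <- integer(n)
  run_id <- integer(n)

  place_runs <- function(n_runs, len_min, len_max, tag) {
    placed <- 0L
    attempts <- 0L
    while (placed < n_runs && attempts < 50L * max(1L, n_runs)) {
      attempts <- attempts + 1L
      rl <- sample.int(len_max - len_min + 1L, 1L) + len_min - 1L
      if (rl > n - 2L) next
      start <- sample.int(n - rl - 1L, 1L) + 1L  # strictly interior
      idx <- start:(start + rl - 1L)
      # keep one untouched position between runs
      guard <- max(1L, start - 1L):min(n, start + rl)
      if (any(role[guard] != 0L)) next
      placed <- placed + 1L
      role[idx] <<- tag
      run_id[idx] <<- placed + if (tag == 2L) 1000L else 0L
    }
    invisible()
  }

  n_gaps <- if (noise$gap_rate > 0) stats::rpois(1L, noise$gap_rate * n / 100) else 0L
  if (n_gaps > 0L && n >= 5L) place_runs(n_gaps, 3L, 6L, 1L)
  n_missing <- if (noise$missing_rate > 0) stats::rpois(1L, noise$missing_rate) else 0L
  if (n_missing > 0L && n >= 8L) place_runs(n_missing, 3L, 8L, 2L)

  ambig <- stats::runif(n) < noise$p_ambiguous
  under <- stats::runif(n) < noise$p_underclass

  segments <- list()
  seg <- list()
  seg_start <- NULL       # 0-based source offset of current segment start
  seg_offsets <- integer(0)
  gap_truth <- list()
  i <- 1L
  while (i <= n) {
    if (role[i] == 2L) {                      # missing: break segment
      if (length(seg)) {
        segments[[length(segments) + 1L]] <- seg
        seg_offsets <- c(seg_offsets, seg_start)
        seg <- list(); seg_start <- NULL
      }
      j <- i
      while (j <= n && role[j] == 2L && run_id[j] == run_id[i]) j <- j + 1L
      i <- j
    } else if (role[i] == 1L) {               # gap region
      j <- i
      while (j <= n && role[j] == 1L && run_id[j] == run_id[i]) j <- j + 1L
      true_len <- j - i
      x <- noise$gap_x
      lo_n <- max(1L, true_len - x)
      hi_n <- as.integer(floor(true_len + x / 2))
      n_est <- true_len + sample(c(-1L, 0L, 1L), 1L)
      n_est <- min(max(n_est, lo_n), hi_n)
      if (is.null(seg_start)) seg_start <- span[1] - 1L + i - 1L
      seg[[length(seg) + 1L]] <- trace_gap(n_est, x)
      gap_truth[[length(gap_truth) + 1L]] <-
        data.frame(true_len = true_len, n = n_est, x = x)
      i <- j
    } else {
      if (is.null(seg_start)) seg_start <- span[1] - 1L + i - 1L
      seg[[length(seg) + 1L]] <- if (ambig[i]) trace_ambiguous() else
        trace_observed(if (under[i]) max(0L, true_classes[i] - 1L) else true_classes[i])
      i <- i + 1L
    }
  }
  if (length(seg)) {
    segments[[length(segments) + 1L]] <- seg
    seg_offsets <- c(seg_offsets, seg_start)
  }
  # Defensive: a segment left with only gap elements cannot stand alone.
  keep <- vapply(segments, function(s) any(segment_kinds(s) %in% c("obs", "ambig")), TRUE)
  segments <- segments[keep]
  seg_offsets <- seg_offsets[keep]
  if (!length(segments)) stop("empty span after noise; nothing to trace", call. = FALSE)

  trace <- density_trace(trace_id, segments, group_id = group_id)
  truth <- list(
    source_id = attr(seq, "id"),
    span = span,
    true_classes = true_classes,
    segment_offsets = as.integer(seg_offsets),
    gap_truth = if (length(gap_truth)) do.call(rbind, gap_truth) else
      data.frame(true_len = integer(0), n = integer(0), x = integer(0))
  )
  list(trace = trace, truth = truth)
}

#' End-to-end recovery benchmark on synthetic data
#'
#' For each run: draw a decoy proteome, pick one source protein and a
#' window on it, simulate a noisy trace, screen the full proteome, and
#' record whether the source protein ranks first and whether the final
#' decision assigns it. Fully deterministic for a fixed master seed.
#'
#' @param n_runs Number of independent runs.
#' @param n_seqs Proteome size per run; default 20.
#' @param length_range Sequence length range; default `c(100, 400)`.
#' @param span_len Length of the traced window; default 60.
#' @param noise A `noise_model`; default `noise_model()`.
#' @param margin Decision margin; default 0.1.
#' @param seed Master seed.
#' @return List with `runs` (per-run data.frame: run, source_id, rank of
#'   the source, decision status, correctly assigned, top-vs-second
#'   margin) and aggregates `rank1_rate`, `assignment_rate`,
#'   `mean_margin`.
#' @export
recovery_harness <- function(n_runs = 100L, n_seqs = 20L,
                             length_range = c(100L, 400L), span_len = 60L,
                             noise = noise_model(), margin = 0.1, seed = 1L) {
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(run_seeds[r])
    proteome <- generate_proteome(n_seqs, length_range, seed = NULL)
    target <- sample.int(n_seqs, 1L)
    target_id <- names(proteome)[target]
    L <- nchar(proteome[[target]])
    sl <- min(span_len, L)
    start <- sample.int(L - sl + 1L, 1L)
    sim <- simulate_trace(proteome[[target]], c(start, start + sl - 1L),
                          noise = noise, trace_id = sprintf("run_%03d", r))
    ranking <- screen_proteome(sim$trace, proteome)
    rank_of_truth <- match(target_id, ranking$candidate_id)
    aligned <- ranking[ranking$status == "aligned", , drop = FALSE]
    top2 <- if (nrow(aligned) >= 2L) {
      aligned$mean_score[1] - aligned$mean_score[2]
    } else if (nrow(aligned) == 1L) Inf else NA_real_
    decision <- decide_assignment(ranking, margin = margin)
    rows[[r]] <- data.frame(
      run = r, source_id = target_id, span_start = start, span_len = sl,
      rank = rank_of_truth,
      top_is_truth = ranking$candidate_id[1] == target_id &&
        ranking$status[1] == "aligned",
      decision = decision$status,
      assigned_correctly = decision$status == "assigned" &&
        identical(decision$winner, target_id),
      margin_top2 = top2,
      stringsAsFactors = FALSE)
  }
  runs <- do.call(rbind, rows)
  finite_m <- runs$margin_top2[is.finite(runs$margin_top2)]
  list(runs = runs,
       rank1_rate = mean(runs$top_is_truth),
       assignment_rate = mean(runs$assigned_correctly),
       mean_margin = if (length(finite_m)) mean(finite_m) else NA_real_)
}
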