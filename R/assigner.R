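# Proteome screening, multi-copy evidence combination, and the final
# assignment rules: a candidate is assigned either because it is the only
# sequence with an admissible alignment, or because its best score beats
# every other candidate's best by more than the decision margin (default
# 0.1 on the [0, 1] score scale).

#' Read a candidate proteome from FASTA
#'
#' @param path FASTA file of amino-acid sequences (e.g. the virion
#'   proteins identified by a proteomic study).
#' @return A named character vector of sequences; names are the first
#'   whitespace-delimited token of each FASTA header.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (!length(aa)) stop("proteome FASTA is empty: ", path, call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in proteome: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(as.character(aa), ids)
}

#' Screen a proteome with one density trace
#'
#' Encodes every candidate sequence as size classes, aligns the trace
#' against each with [align_trace()], and ranks candidates by best mean
#' score (descending; excluded candidates last, in input order). The
#' ranking is deterministic: ties in mean score keep the proteome's input
#' order.
#'
#' @param trace A `density_trace`.
#' @param proteome Named character vector of sequences (see
#'   [read_proteome()]), or a path to a FASTA file.
#' @param size_table A `size_table`; default [default_size_table()].
#' @param score_table A `score_table`; default [default_score_table()].
#' @return A `candidate_ranking`: data.frame with one row per candidate —
#'   `trace_id`, `candidate_id`, `status` (`"aligned"` or `"excluded"`),
#'   `reason`, `mean_score`, `n_scored`, `start_offset`, `gap_lengths`
#'   and `segment_offsets` (comma-separated) — carrying the full
#'   `alignment_result` objects in the `alignments` attribute.
#' @export
screen_proteome <- function(trace, proteome,
                            size_table = default_size_table(),
                            score_table = default_score_table()) {
  if (is.character(proteome) && length(proteome) == 1L && file.exists(proteome)) {
    proteome <- read_proteome(proteome)
  }
  if (!length(proteome)) stop("proteome is empty", call. = FALSE)
  if (is.null(names(proteome)) || anyDuplicated(names(proteome))) {
    stop("proteome sequences must have unique ids", call. = FALSE)
  }
  results <- lapply(names(proteome), function(id) {
    enc <- encode_sequence(proteome[[id]], size_table, id = id)
    align_trace(trace, enc, score_table)
  })
  names(results) <- names(proteome)

  rows <- lapply(names(results), function(id) {
    r <- results[[id]]
    if (is_exclusion(r)) {
      data.frame(trace_id = trace$trace_id, candidate_id = id,
                 status = "excluded", reason = r$reason,
                 mean_score = NA_real_, n_scored = NA_integer_,
                 start_offset = NA_integer_, gap_lengths = "",
                 segment_offsets = "", stringsAsFactors = FALSE)
    } else {
      data.frame(trace_id = trace$trace_id, candidate_id = id,
                 status = "aligned", reason = "",
                 mean_score = r$mean_score, n_scored = r$n_scored,
                 start_offset = r$start_offset,
                 gap_lengths = paste(r$gap_lengths, collapse = ","),
                 segment_offsets = paste(r$segment_offsets, collapse = ","),
                 stringsAsFactors = FALSE)
    }
  })
  df <- do.call(rbind, rows)
  key <- ifelse(is.na(df$mean_score), -Inf, df$mean_score)
  ord <- order(-key, seq_len(nrow(df)))   # stable: input order breaks ties
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "alignments") <- results
  class(df) <- c("candidate_ranking", class(df))
  df
}

#' Apply the final assignment rule to a candidate ranking
#'
#' Two situations yield an assignment: (1) exactly one candidate has an
#' admissible alignment; (2) several do, but the best mean score exceeds
#' every other candidate's by more than `margin`. Otherwise the decision
#' is `ambiguous`, listing every candidate within `margin` of the top, or
#' `no_match` when no candidate aligns at all. When an assignment wins by
#' margin over other admissible candidates (situation 2), the result
#' flags `needs_ss_check = TRUE`: the runner-ups should additionally be
#' rejected by an external secondary-structure comparison, which this
#' package does not compute.
#'
#' @param ranking A `candidate_ranking` from [screen_proteome()], or any
#'   data.frame with `candidate_id`, `status` and `mean_score` columns.
#' @param margin Decision margin on the \[0, 1\] score scale; default 0.1.
#' @return An `assignment`: list with `status` (`"assigned"`,
#'   `"ambiguous"` or `"no_match"`), `winner`, `contenders`, `top_score`,
#'   `margin`, and `needs_ss_check`.
#' @export
decide_assignment <- function(ranking, margin = 0.1) {
  if (margin < 0) stop("margin must be >= 0", call. = FALSE)
  ok <- ranking[ranking$status == "aligned" & !is.na(ranking$mean_score), , drop = FALSE]
  if (!nrow(ok)) {
    return(structure(list(status = "no_match", winner = NA_character_,
                          contenders = character(0), top_score = NA_real_,
                          margin = margin, needs_ss_check = FALSE),
                     class = "assignment"))
  }
  ok <- ok[order(-ok$mean_score), , drop = FALSE]
  top <- ok[1, ]
  if (nrow(ok) == 1L) {
    return(structure(list(status = "assigned", winner = top$candidate_id,
                          contenders = character(0), top_score = top$mean_score,
                          margin = margin, needs_ss_check = FALSE),
                     class = "assignment"))
  }
  second <- ok$mean_score[2]
  if (top$mean_score - second > margin) {
    structure(list(status = "assigned", winner = top$candidate_id,
                   contenders = character(0), top_score = top$mean_score,
                   margin = margin, needs_ss_check = TRUE),
              class = "assignment")
  } else {
    within <- ok$candidate_id[top$mean_score - ok$mean_score <= margin]
    structure(list(status = "ambiguous", winner = NA_character_,
                   contenders = within, top_score = top$mean_score,
                   margin = margin, needs_ss_check = FALSE),
              class = "assignment")
  }
}

#' @export
print.assignment <- function(x, ...) {
  cat("<assignment> ", x$status,
      if (x$status == "assigned") paste0(": ", x$winner,
        sprintf(" (score %.4f%s)", x$top_score,
                if (x$needs_ss_check) ", needs external secondary-structure check" else "")),
      if (x$status == "ambiguous") paste0(": ", paste(x$contenders, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

# Skeleton = the main-chain shape proxy: one slot per positional element
# (observed and ambiguous are the same position seen with different
# side-chain quality) and "gap" where a gap region sits.
trace_skeleton <- function(trace) {
  lapply(trace$segments, function(seg) {
    k <- segment_kinds(seg)
    ifelse(k == "gap", "gap", "pos")
  })
}

new_refusal <- function(reason, detail = "") {
  structure(list(reason = reason, detail = detail), class = "combine_refusal")
}

#' Is a combination outcome a refusal?
#' @param x Result of [combine_copies()].
#' @return Logical scalar.
#' @export
is_refusal <- function(x) inherits(x, "combine_refusal")

#' @export
print.combine_refusal <- function(x, ...) {
  cat("<refusal> ", x$reason,
      if (nzchar(x$detail)) paste0(": ", x$detail), "\n", sep = "")
  invisible(x)
}

#' Combine density evidence from multiple copies of one polypeptide
#'
#' When several traced chains are believed to be copies of the same
#' polypeptide (same `group_id`; in the map, similar main-chain
#' conformations), their evidence may be pooled into one richer trace —
#' but only when each copy's best match names the same candidate. The
#' skeletons must be identical (same segment count and position-wise
#' element kinds; structural similarity is the caller's assertion via the
#' grouping). Position-wise combination never loses information: an
#' observed class beats an ambiguous position; two conflicting observed
#' classes combine to the maximum (the fuller density) with the conflict
#' recorded in the `conflicts` attribute and a warning; gap regions
#' combine by intersecting their length bounds.
#'
#' @param traces List of >= 2 `density_trace` objects with identical
#'   skeletons.
#' @param best_matches Optional character vector, one best-match
#'   candidate id per trace (e.g. from [screen_proteome()] rankings);
#'   when given, combination is refused unless all agree.
#' @param trace_id Identifier of the combined trace; defaults to the
#'   shared `group_id` or the concatenated input ids.
#' @return A combined `density_trace`, or a `combine_refusal` with reason
#'   `skeleton_mismatch`, `best_match_disagrees` or `gap_bounds_disjoint`.
#' @export
combine_copies <- function(traces, best_matches = NULL, trace_id = NULL) {
  if (length(traces) < 2L) stop("need at least two traces to combine", call. = FALSE)
  if (!is.null(best_matches)) {
    if (length(best_matches) != length(traces)) {
      stop("best_matches must have one entry per trace", call. = FALSE)
    }
    if (length(unique(best_matches)) > 1L) {
      return(new_refusal("best_match_disagrees",
                         paste(unique(best_matches), collapse = " vs ")))
    }
  }
  skel <- trace_skeleton(traces[[1]])
  for (t in traces[-1]) {
    if (!identical(trace_skeleton(t), skel)) {
      return(new_refusal("skeleton_mismatch",
                         sprintf("'%s' vs '%s'", traces[[1]]$trace_id, t$trace_id)))
    }
  }
  if (is.null(trace_id)) {
    gid <- traces[[1]]$group_id
    trace_id <- if (!is.null(gid)) paste0(gid, "_combined") else
      paste(vapply(traces, function(t) t$trace_id, ""), collapse = "+")
  }
  conflicts <- list()
  segments <- vector("list", length(skel))
  for (si in seq_along(skel)) {
    kinds <- skel[[si]]
    seg <- vector("list", length(kinds))
    for (ei in seq_along(kinds)) {
      els <- lapply(traces, function(t) t$segments[[si]][[ei]])
      if (kinds[ei] == "gap") {
        bnds <- vapply(els, gap_bounds, integer(2))
        lo <- max(bnds[1, ]); hi <- min(bnds[2, ])
        if (lo > hi) {
          return(new_refusal("gap_bounds_disjoint",
                             sprintf("segment %d element %d: [%s] have empty intersection",
                                     si, ei,
                                     paste(apply(bnds, 2, paste, collapse = ".."),
                                           collapse = "] x ["))))
        }
        e1 <- els[[1]]
        nb <- gap_bounds(e1)
        seg[[ei]] <- if (nb[1] == lo && nb[2] == hi) e1 else
          trace_gap(e1$n, e1$x, lo = lo, hi = hi)
      } else {
        sizes <- unlist(lapply(els, function(e) if (e$kind == "obs") e$size else NULL))
        if (!length(sizes)) {
          seg[[ei]] <- trace_ambiguous()
        } else {
          if (length(unique(sizes)) > 1L) {
            conflicts[[length(conflicts) + 1L]] <-
              data.frame(segment = si, element = ei,
                         sizes = paste(sort(sizes), collapse = ","),
                         kept = max(sizes))
          }
          seg[[ei]] <- trace_observed(max(sizes))
        }
      }
    }
    segments[[si]] <- seg
  }
  out <- density_trace(trace_id, segments, group_id = traces[[1]]$group_id)
  if (length(conflicts)) {
    conf <- do.call(rbind, conflicts)
    warning(nrow(conf), " position(s) had conflicting observed sizes; ",
            "kept the maximum (fullest density)", call. = FALSE)
    attr(out, "conflicts") <- conf
  }
  out
}

#' Write a screening report as TSV
#'
#' One detail row per (trace, candidate) and one summary row per trace
#' with the final assignment; deterministic column and row order, with
#' header comment lines recording the tool version and a configuration
#' hash so reruns are byte-identical.
#'
#' @param results List of per-trace results, each a list with elements
#'   `ranking` (a `candidate_ranking`) and `assignment` (an
#'   `assignment`); may be empty.
#' @param path Output TSV path.
#' @param config The configuration list used (for the hash); default
#'   [load_config()] defaults.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, config = load_config()) {
  cols <- c("row_type", "trace_id", "candidate_id", "status", "reason",
            "mean_score", "n_scored", "start_offset", "gap_lengths",
            "segment_offsets", "assignment", "winner", "contenders",
            "needs_ss_check")
  rows <- list()
  for (res in results) {
    rk <- res$ranking
    for (i in seq_len(nrow(rk))) {
      rows[[length(rows) + 1L]] <- data.frame(
        row_type = "detail", trace_id = rk$trace_id[i],
        candidate_id = rk$candidate_id[i], status = rk$status[i],
        reason = rk$reason[i],
        mean_score = ifelse(is.na(rk$mean_score[i]), "",
                            format(rk$mean_score[i], digits = 10)),
        n_scored = ifelse(is.na(rk$n_scored[i]), "", rk$n_scored[i]),
        start_offset = ifelse(is.na(rk$start_offset[i]), "", rk$start_offset[i]),
        gap_lengths = rk$gap_lengths[i], segment_offsets = rk$segment_offsets[i],
        assignment = "", winner = "", contenders = "", needs_ss_check = "",
        stringsAsFactors = FALSE)
    }
    a <- res$assignment
    rows[[length(rows) + 1L]] <- data.frame(
      row_type = "summary", trace_id = rk$trace_id[1], candidate_id = "",
      status = "", reason = "", mean_score = "", n_scored = "",
      start_offset = "", gap_lengths = "", segment_offsets = "",
      assignment = a$status,
      winner = ifelse(is.na(a$winner), "", a$winner),
      contenders = paste(a$contenders, collapse = ","),
      needs_ss_check = tolower(as.character(a$needs_ss_check)),
      stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(character(0), 0, length(cols)),
                               stringsAsFactors = FALSE), cols)
  con <- file(path, open = "wb")
  on.exit(close(con))
  version <- as.character(utils::packageVersion("cryotrace"))
  writeLines(c(paste0("# cryotrace ", version),
               paste0("# config_hash=", config_hash(config))),
             con, sep = "\n")
  writeLines(paste(cols, collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    writeLines(do.call(paste, c(df[cols], sep = "\t")), con, sep = "\n")
  }
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  unname(tools::md5sum(tmp))
}
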