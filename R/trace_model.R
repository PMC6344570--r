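# Density traces: ordered per-position side-chain observations exported
# from manual interpretation of a cryo-EM map. Three poor-density
# situations are modelled: an ambiguous position (reliable C-alpha, no
# usable side chain -> could be any of the 20 residues), a gap region
# (main-chain connectivity but unreliable C-alpha count: between
# ceil(n - x/2) and n + x residues, where n is the builder's estimate and
# x the maximum possible error), and a completely missing region, encoded
# implicitly as a boundary between two trace segments.

#' Trace element constructors
#'
#' A density trace is built from three element kinds:
#' \describe{
#'   \item{`trace_observed(size)`}{a residue with good side-chain density,
#'     summarized as an integer size class 0--6;}
#'   \item{`trace_ambiguous()`}{a position with a reliable C-alpha but no
#'     usable side-chain density — could be any of the 20 residues;}
#'   \item{`trace_gap(n, x)`}{a region with main-chain connectivity but
#'     unreliable C-alpha placement, holding between `ceil(n - x/2)` and
#'     `n + x` residues (`n` = estimated count, `x` = maximum error).}
#' }
#'
#' @param size Integer size class in 0--6.
#' @param n Estimated residue count in the gap region (>= 1).
#' @param x Maximum possible error of the estimate (>= 0).
#' @param lo,hi Optional explicit bound overrides (used when combining
#'   copies intersects two gap intervals that no single `(n, x)` pair can
#'   express); normally `NULL`.
#' @return A `trace_element` list with a `kind` field.
#' @name trace_elements
NULL

#' @rdname trace_elements
#' @export
trace_observed <- function(size) {
  size <- as.integer(size)
  if (is.na(size) || size < 0L || size > 6L) {
    stop("observed size class must be an integer in [0, 6]", call. = FALSE)
  }
  structure(list(kind = "obs", size = size), class = "trace_element")
}

#' @rdname trace_elements
#' @export
trace_ambiguous <- function() {
  structure(list(kind = "ambig"), class = "trace_element")
}

#' @rdname trace_elements
#' @export
trace_gap <- function(n, x, lo = NULL, hi = NULL) {
  n <- as.integer(n); x <- as.integer(x)
  if (is.na(n) || n < 1L) stop("gap region estimate n must be >= 1", call. = FALSE)
  if (is.na(x) || x < 0L) stop("gap region max error x must be >= 0", call. = FALSE)
  el <- list(kind = "gap", n = n, x = x)
  if (!is.null(lo) || !is.null(hi)) {
    lo <- as.integer(lo); hi <- as.integer(hi)
    if (is.na(lo) || is.na(hi) || lo < 0L || lo > hi) {
      stop("explicit gap bounds must satisfy 0 <= lo <= hi", call. = FALSE)
    }
    el$lo <- lo; el$hi <- hi
  }
  structure(el, class = "trace_element")
}

#' Admissible residue-count bounds of a gap element
#'
#' The builder's estimate `n` with maximum error `x` admits between
#' `n - x/2` and `n + x` residues. With odd `x` the half-width `x/2` is
#' fractional; the lower bound rounds toward the wider interval
#' (`max(0, ceiling(n - x/2))`) so no length the interval admits is ever
#' excluded. Explicit `lo`/`hi` overrides (from gap intersection during
#' copy combination) take precedence.
#'
#' @param el A gap `trace_element`.
#' @return Integer vector `c(lo, hi)`.
#' @export
#' @examples
#' gap_bounds(trace_gap(3, 2))  # 2 5
gap_bounds <- function(el) {
  stopifnot(el$kind == "gap")
  if (!is.null(el$lo)) return(c(el$lo, el$hi))
  c(max(0L, as.integer(ceiling(el$n - el$x / 2))), el$n + el$x)
}

#' Build and validate a density trace
#'
#' @param trace_id Unique identifier of the traced polypeptide.
#' @param segments List of segments; each segment is a list of
#'   `trace_element`s (see [trace_elements]). Consecutive segments are
#'   separated by a completely missing region of unknown (unbounded)
#'   length; within the parent sequence they must appear in chain order.
#' @param group_id Optional identifier shared by traces believed to be
#'   copies of the same polypeptide (used by [combine_copies()]).
#' @return A `density_trace` object.
#' @export
density_trace <- function(trace_id, segments, group_id = NULL) {
  if (!is.character(trace_id) || length(trace_id) != 1L || !nzchar(trace_id)) {
    stop("trace_id must be one non-empty string", call. = FALSE)
  }
  if (!length(segments)) stop("a trace needs at least one segment", call. = FALSE)
  for (si in seq_along(segments)) {
    seg <- segments[[si]]
    if (!length(seg)) {
      stop("segment ", si, " of trace '", trace_id, "' is empty", call. = FALSE)
    }
    kinds <- vapply(seg, function(e) e$kind, "")
    if (!any(kinds %in% c("obs", "ambig"))) {
      stop("segment ", si, " of trace '", trace_id,
           "' has no observed or ambiguous element", call. = FALSE)
    }
  }
  structure(list(trace_id = trace_id, group_id = group_id, segments = segments),
            class = "density_trace")
}

#' @export
print.density_trace <- function(x, ...) {
  ns <- length(x$segments)
  ne <- sum(lengths(x$segments))
  b <- trace_length_bounds(x)
  cat("<density_trace> ", x$trace_id,
      if (!is.null(x$group_id)) paste0(" (group ", x$group_id, ")"),
      ": ", ns, " segment(s), ", ne, " element(s), length in [",
      b$min_len, ", ", if (is.finite(b$max_len)) b$max_len else "unbounded",
      "]\n", sep = "")
  invisible(x)
}

segment_kinds <- function(seg) vapply(seg, function(e) e$kind, "")

#' Residue-count bounds implied by a trace
#'
#' The minimum length counts every observed/ambiguous position plus each
#' gap region at its lower bound. Within a single segment the maximum adds
#' the gap upper bounds; as soon as a trace has two or more segments the
#' maximum is unbounded (`Inf`), because a completely missing region has
#' no stated upper length.
#'
#' @param trace A `density_trace`.
#' @return List with integer `min_len` and `max_len` (`Inf` if unbounded).
#' @export
trace_length_bounds <- function(trace) {
  per_seg <- lapply(trace$segments, function(seg) {
    lo <- 0L; hi <- 0L
    for (e in seg) {
      if (e$kind == "gap") {
        b <- gap_bounds(e)
        lo <- lo + b[1]; hi <- hi + b[2]
      } else {
        lo <- lo + 1L; hi <- hi + 1L
      }
    }
    c(lo, hi)
  })
  min_len <- sum(vapply(per_seg, `[`, 0L, 1L))
  max_len <- if (length(per_seg) > 1L) Inf else per_seg[[1]][2]
  list(min_len = as.integer(min_len), max_len = max_len)
}

element_to_json <- function(e) {
  switch(e$kind,
    obs = list(kind = "obs", size = e$size),
    ambig = list(kind = "ambig"),
    gap = {
      out <- list(kind = "gap", n = e$n, x = e$x)
      if (!is.null(e$lo)) { out$lo <- e$lo; out$hi <- e$hi }
      out
    },
    stop("unknown element kind: ", e$kind)
  )
}

element_from_json <- function(obj, where) {
  kind <- obj$kind
  if (is.null(kind)) stop("element ", where, ": missing 'kind'", call. = FALSE)
  tryCatch(
    switch(as.character(kind),
      obs = trace_observed(obj$size),
      ambig = trace_ambiguous(),
      gap = trace_gap(obj$n, obj$x, lo = obj$lo, hi = obj$hi),
      stop("unknown kind '", kind, "'", call. = FALSE)
    ),
    error = function(err) {
      stop("element ", where, ": ", conditionMessage(err), call. = FALSE)
    }
  )
}

#' Read density traces from their JSON interchange format
#'
#' The format is a top-level JSON array of objects
#' `{trace_id, group_id?, segments: [{elements: [...]}]}` where each
#' element is `{"kind":"obs","size":0..6}`, `{"kind":"ambig"}` or
#' `{"kind":"gap","n":..,"x":..}` (optionally with explicit `lo`/`hi`
#' bounds). Element coordinates are 0-based within their segment; chain
#' direction follows array order. Validation failures name the trace,
#' segment and element index.
#'
#' @param path Path to a trace JSON file.
#' @return List of `density_trace` objects.
#' @export
parse_traces <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.list(raw)) stop("trace file must contain a JSON array", call. = FALSE)
  ids <- character(0)
  traces <- lapply(seq_along(raw), function(ti) {
    tr <- raw[[ti]]
    if (is.null(tr$trace_id)) stop("trace #", ti, ": missing trace_id", call. = FALSE)
    segs <- lapply(seq_along(tr$segments), function(si) {
      seg <- tr$segments[[si]]
      lapply(seq_along(seg$elements), function(ei) {
        element_from_json(seg$elements[[ei]],
                          sprintf("trace '%s' segment %d element %d (0-based %d)",
                                  tr$trace_id, si, ei, ei - 1L))
      })
    })
    density_trace(tr$trace_id, segs, group_id = tr$group_id)
  })
  ids <- vapply(traces, function(t) t$trace_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate trace_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  traces
}

#' Write density traces to the JSON interchange format
#'
#' Inverse of [parse_traces()]: `parse_traces(write_traces(t, p))` yields
#' a structure identical to `t`.
#'
#' @param traces List of `density_trace` objects (may be empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  out <- lapply(traces, function(tr) {
    obj <- list(trace_id = tr$trace_id)
    if (!is.null(tr$group_id)) obj$group_id <- tr$group_id
    obj$segments <- lapply(tr$segments, function(seg) {
      list(elements = lapply(seg, element_to_json))
    })
    obj
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
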