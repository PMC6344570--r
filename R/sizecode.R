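AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V")
AA_WILDCARD <- c("X", "B", "Z", "U")

#' Default amino-acid to side-chain size-class table
#'
#' Maps each of the 20 standard amino acids to an integer size class in
#' 0--6, binned by side-chain heavy-atom count so that the classes are
#' monotone in physical side-chain bulk and span the full 0--6 range:
#' 0: G; 1: A; 2: S, C; 3: P, T, V; 4: D, N, I, L, M; 5: E, Q, K, H;
#' 6: R, F, Y, W. Non-standard letters (X, B, Z, U) are wildcards: they
#' are compatible with any observation and contribute nothing to an
#' alignment's mean score. The table is a stand-in calibration; the real
#' map-derived table can be supplied verbatim through [load_config()].
#'
#' @return A `size_table` object: a named integer vector over the 20
#'   standard one-letter codes, values in 0--6.
#' @seealso [encode_sequence()], [load_config()]
#' @export
#' @examples
#' tab <- default_size_table()
#' tab[["G"]]  # 0, the smallest side chain
#' tab[["W"]]  # 6, the bulkiest
default_size_table <- function() {
  map <- c(
    G = 0L,
    A = 1L,
    S = 2L, C = 2L,
    P = 3L, T = 3L, V = 3L,
    D = 4L, N = 4L, I = 4L, L = 4L, M = 4L,
    E = 5L, Q = 5L, K = 5L, H = 5L,
    R = 6L, F = 6L, Y = 6L, W = 6L
  )
  new_size_table(map)
}

new_size_table <- function(map) {
  map <- map[order(names(map))]
  validate_size_table(map)
  structure(map, class = "size_table")
}

validate_size_table <- function(map) {
  if (!setequal(names(map), AA_STANDARD)) {
    missing <- setdiff(AA_STANDARD, names(map))
    extra <- setdiff(names(map), AA_STANDARD)
    if (length(missing)) {
      stop("size table is missing standard residue(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    stop("size table contains non-standard residue(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  v <- as.integer(map)
  if (anyNA(v) || any(v < 0L) || any(v > 6L)) {
    stop("size classes must be integers in [0, 6]", call. = FALSE)
  }
  if (!any(v == 0L) || !any(v == 6L)) {
    stop("size table must use the full dynamic range: at least one residue ",
         "in class 0 and one in class 6", call. = FALSE)
  }
  invisible(map)
}

#' Default per-pair size-class score table
#'
#' The 7x7 score matrix `score[observed, candidate]` used to score one
#' aligned residue, on a fixed \[0, 1\] scale so that alignment means (and
#' the 0.1 decision margin) are comparable across traces:
#' \itemize{
#'   \item exact class match: 1;
#'   \item candidate exceeds observed by 1: 0.5; by 2 or more: 0.25
#'     (partial side-chain disorder plausibly truncates density);
#'   \item observed exceeds candidate by 1: 0.5;
#'   \item observed exceeds candidate by `exclusion_delta` (default 2) or
#'     more: the pair is excluded, not scored — density cannot show more
#'     side chain than the sequence has.
#' }
#' The exclusion rule is structural: it applies for any
#' `observed - candidate >= exclusion_delta` regardless of matrix
#' overrides supplied through [load_config()].
#'
#' @param exclusion_delta Integer threshold for the one-sided exclusion
#'   rule; default 2.
#' @return A `score_table` object: list with elements `score` (7x7 numeric
#'   matrix, rows = observed class 0--6, columns = candidate class 0--6;
#'   excluded cells are `NA`) and `exclusion_delta`.
#' @export
#' @examples
#' st <- default_score_table()
#' st$score["3", "3"]  # 1
#' st$score["2", "3"]  # 0.5
default_score_table <- function(exclusion_delta = 2L) {
  score <- matrix(NA_real_, 7, 7, dimnames = list(observed = 0:6, candidate = 0:6))
  for (obs in 0:6) {
    for (cand in 0:6) {
      d <- cand - obs
      score[obs + 1L, cand + 1L] <-
        if (d == 0L) 1 else if (d == 1L) 0.5 else if (d >= 2L) 0.25 else if (d == -1L) 0.5 else NA_real_
    }
  }
  new_score_table(score, exclusion_delta)
}

new_score_table <- function(score, exclusion_delta = 2L) {
  dimnames(score) <- list(observed = 0:6, candidate = 0:6)
  tab <- structure(list(score = score, exclusion_delta = as.integer(exclusion_delta)),
                   class = "score_table")
  validate_score_table(tab)
  tab
}

validate_score_table <- function(tab) {
  score <- tab$score
  if (!is.matrix(score) || !identical(dim(score), c(7L, 7L))) {
    stop("score table must be a 7x7 matrix", call. = FALSE)
  }
  dimnames(score) <- list(observed = 0:6, candidate = 0:6)
  if (any(diag(score) != 1)) {
    stop("score table diagonal must be 1 (exact match is maximal)", call. = FALSE)
  }
  d <- as.integer(tab$exclusion_delta)
  if (is.na(d) || d < 1L) stop("exclusion_delta must be a positive integer", call. = FALSE)
  excl <- outer(0:6, 0:6, function(o, c) o - c >= d)
  vals <- score[!excl]
  if (any(!is.na(vals) & (vals < 0 | vals > 1))) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.na(score[excl]))) {
    stop("pairs with observed - candidate >= exclusion_delta are excluded ",
         "and cannot carry a score", call. = FALSE)
  }
  if (anyNA(score[!excl])) {
    stop("non-excluded score cells must all be specified", call. = FALSE)
  }
  invisible(tab)
}

#' Load (or fall back to) the size and score configuration
#'
#' Reads a YAML or JSON configuration with keys `size_table` (one-letter
#' code to integer class 0--6, all 20 standard residues), `score_table`
#' (7x7 row-major numeric matrix, rows = observed class; excluded cells
#' may be given as `null`/`NA` or `.excluded`) and `exclusion_delta`.
#' Absent keys fall back to [default_size_table()] /
#' [default_score_table()], so an empty file yields the documented
#' defaults. Cells made unreachable by the exclusion rule are dropped with
#' a warning if supplied.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` config file, or `NULL` for
#'   the defaults.
#' @return A list with elements `size_table` and `score_table`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) {
    return(list(size_table = default_size_table(),
                score_table = default_score_table()))
  }
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("malformed config file: ", path, call. = FALSE)

  size_table <- if (is.null(cfg$size_table)) {
    default_size_table()
  } else {
    vals <- unlist(cfg$size_table)
    new_size_table(stats::setNames(as.integer(vals), names(vals)))
  }

  delta <- if (is.null(cfg$exclusion_delta)) 2L else as.integer(cfg$exclusion_delta)
  score_table <- if (is.null(cfg$score_table)) {
    default_score_table(delta)
  } else {
    rows <- cfg$score_table
    if (is.matrix(rows)) {
      m <- matrix(as.numeric(rows), 7, 7, byrow = FALSE)
    } else {
      if (length(rows) != 7L || any(lengths(rows) != 7L)) {
        stop("score_table must be 7 rows of 7 scores (rows = observed class)",
             call. = FALSE)
      }
      m <- do.call(rbind, lapply(rows, function(r) {
        r <- unlist(r)
        r[r %in% ".excluded"] <- NA
        as.numeric(r)
      }))
    }
    excl <- outer(0:6, 0:6, function(o, c) o - c >= delta)
    if (any(!is.na(m[excl]))) {
      warning("score_table entries in the excluded region (observed - ",
              "candidate >= ", delta, ") are ignored", call. = FALSE)
      m[excl] <- NA_real_
    }
    new_score_table(m, delta)
  }
  list(size_table = size_table, score_table = score_table)
}

#' Save a configuration so that loading reproduces it exactly
#'
#' @param config List with `size_table` and `score_table`, as returned by
#'   [load_config()].
#' @param path Output path; format chosen by extension (`.json` or YAML).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  m <- config$score_table$score
  out <- list(
    size_table = as.list(stats::setNames(as.integer(config$size_table),
                                         names(config$size_table))),
    score_table = lapply(seq_len(7), function(i) as.numeric(m[i, ])),
    exclusion_delta = config$score_table$exclusion_delta
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' Encode an amino-acid sequence as side-chain size classes
#'
#' Positional lookup of each residue's size class; wildcard letters
#' (X, B, Z, U) become `NA`, the neutral marker that matches any
#' observation without contributing to the score average.
#'
#' @param seq Amino-acid string (one-letter codes), or an
#'   [Biostrings::AAString]-coercible object.
#' @param table A `size_table`; default [default_size_table()].
#' @param id Sequence identifier carried into results.
#' @return An `encoded_sequence`: list with `id` and `classes`, an integer
#'   vector the same length as `seq` with `NA` at wildcard positions.
#' @export
#' @examples
#' encode_sequence("GAW")$classes  # 0 1 6
encode_sequence <- function(seq, table = default_size_table(), id = "seq") {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L || !nzchar(seq)) stop("seq must be one non-empty string", call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c(AA_STANDARD, AA_WILDCARD))
  if (length(bad)) {
    stop("illegal amino-acid code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  classes <- unname(unclass(table)[chars])  # wildcards -> NA by absent name
  structure(list(id = id, classes = as.integer(classes)), class = "encoded_sequence")
}

#' @export
length.encoded_sequence <- function(x) length(x$classes)

#' @export
print.encoded_sequence <- function(x, ...) {
  cat("<encoded_sequence> ", x$id, ": ", length(x$classes), " residues\n", sep = "")
  invisible(x)
}

#' Score one aligned (observed, candidate) size-class pair
#'
#' Applies the one-sided exclusion rule before the score lookup: if the
#' observed class exceeds the candidate class by `exclusion_delta` or
#' more, the pair is excluded (`-Inf`), regardless of any table override —
#' the map cannot show a larger side chain than the sequence provides. A
#' wildcard candidate (`NA`) is compatible with any observation and
#' returns `NA`, the neutral no-contribution marker.
#'
#' @param observed Integer observed class(es) in 0--6.
#' @param candidate Integer candidate class(es) in 0--6, or `NA` for a
#'   wildcard. Recycled against `observed`.
#' @param table A `score_table`; default [default_score_table()].
#' @return Numeric vector: the score in \[0, 1\], `-Inf` for an excluded
#'   pair, `NA` for a wildcard candidate.
#' @export
#' @examples
#' score_pair(3, 3)  # 1
#' score_pair(5, 3)  # -Inf (excluded: observed larger by 2)
#' score_pair(2, 3)  # 0.5
score_pair <- function(observed, candidate, table = default_score_table()) {
  observed <- as.integer(observed)
  candidate <- as.integer(candidate)
  if (any(is.na(observed)) || any(observed < 0L | observed > 6L)) {
    stop("observed classes must be integers in [0, 6]", call. = FALSE)
  }
  if (any(!is.na(candidate) & (candidate < 0L | candidate > 6L))) {
    stop("candidate classes must be integers in [0, 6] or NA (wildcard)", call. = FALSE)
  }
  n <- max(length(observed), length(candidate))
  observed <- rep_len(observed, n)
  candidate <- rep_len(candidate, n)
  out <- rep(NA_real_, n)
  solid <- !is.na(candidate)
  excl <- solid & (observed - candidate >= table$exclusion_delta)
  out[excl] <- -Inf
  keep <- solid & !excl
  out[keep] <- table$score[cbind(observed[keep] + 1L, candidate[keep] + 1L)]
  out
}

#' Is a score_pair result the excluded marker?
#' @param score Result of [score_pair()].
#' @return Logical vector.
#' @export
is_excluded_score <- function(score) !is.na(score) & score == -Inf

# 7x7 lookup matrix with -Inf in the excluded region, for vectorized
# alignment scoring; indexed [observed + 1, candidate + 1].
score_lookup_matrix <- function(table) {
  m <- table$score
  m[outer(0:6, 0:6, function(o, c) o - c >= table$exclusion_delta)] <- -Inf
  m
}
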