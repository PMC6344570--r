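# Fixtures are generated in code; nothing is read from disk.

# Random candidate sequence of length L (standard residues only unless
# wildcards requested).
rand_seq <- function(L, p_wildcard = 0) {
  letters <- sample(cryotrace:::AA_STANDARD, L, replace = TRUE)
  if (p_wildcard > 0) {
    w <- runif(L) < p_wildcard
    letters[w] <- sample(c("X", "B", "Z", "U"), sum(w), replace = TRUE)
  }
  paste(letters, collapse = "")
}

# Random small trace: 1-2 segments, a few observed/ambiguous elements,
# 0-2 gap regions with small bounds. Guaranteed valid.
rand_small_trace <- function(max_segments = 2L) {
  n_seg <- sample.int(max_segments, 1L)
  segs <- lapply(seq_len(n_seg), function(s) {
    n_el <- sample(2:5, 1L)
    seg <- lapply(seq_len(n_el), function(i) {
      u <- runif(1)
      if (u < 0.55) trace_observed(sample(0:6, 1L))
      else if (u < 0.8) trace_ambiguous()
      else trace_gap(sample(1:3, 1L), sample(0:2, 1L))
    })
    if (!any(vapply(seg, function(e) e$kind, "") %in% c("obs", "ambig"))) {
      seg[[length(seg) + 1L]] <- trace_observed(sample(0:6, 1L))
    }
    seg
  })
  density_trace(paste0("rand_", sample.int(1e6, 1L)), segs)
}

# Random (trace, candidate) pair sized so the brute-force oracle stays
# fast: two-segment instances get shorter candidates and at most one gap,
# since the oracle's placement count is a product across segments.
rand_oracle_case <- function(i) {
  if (runif(1) < 0.7) {
    n_el <- sample(3:7, 1L)
    n_gap_left <- 2L
    seg <- lapply(seq_len(n_el), function(j) {
      u <- runif(1)
      if (u < 0.55) trace_observed(sample(0:6, 1L))
      else if (u < 0.8) trace_ambiguous()
      else if (n_gap_left > 0L) {
        n_gap_left <<- n_gap_left - 1L
        trace_gap(sample(1:3, 1L), sample(0:2, 1L))
      } else trace_ambiguous()
    })
    if (!any(vapply(seg, function(e) e$kind, "") %in% c("obs", "ambig"))) {
      seg <- c(seg, list(trace_observed(sample(0:6, 1L))))
    }
    tr <- density_trace(sprintf("o1_%d", i), list(seg))
    cand_len <- sample(15:40, 1L)
  } else {
    mk <- function() lapply(seq_len(sample(2:3, 1L)), function(j) {
      if (runif(1) < 0.7) trace_observed(sample(0:6, 1L)) else trace_ambiguous()
    })
    s1 <- mk(); s2 <- mk()
    if (runif(1) < 0.5) s1[[length(s1) + 1L]] <- trace_gap(sample(1:2, 1L), sample(0:1, 1L))
    tr <- density_trace(sprintf("o2_%d", i), list(s1, s2))
    cand_len <- sample(18:28, 1L)
  }
  list(trace = tr,
       cand = encode_sequence(rand_seq(cand_len, p_wildcard = 0.05),
                              id = sprintf("c%04d", i)))
}

# Independent post-hoc check of an alignment: re-derive every aligned
# (observed, candidate) pair and assert the one-sided exclusion rule and
# the reported mean, using only score_pair() and simple loops.
verify_alignment <- function(trace, candidate, result, scores = default_score_table()) {
  pairs <- alignment_pairs(trace, candidate, result)
  total <- 0; n <- 0L
  for (i in seq_len(nrow(pairs))) {
    obs <- pairs$observed[i]
    if (is.na(obs)) next
    cc <- pairs$candidate_class[i]
    sc <- score_pair(obs, cc, scores)
    if (is_excluded_score(sc)) {
      return(list(ok = FALSE, why = sprintf("excluded pair at cand_pos %d (obs %d vs cand %d)",
                                            pairs$cand_pos[i], obs, cc)))
    }
    if (!is.na(sc)) { total <- total + sc; n <- n + 1L }
  }
  if (n != result$n_scored) {
    return(list(ok = FALSE, why = sprintf("n_scored %d != recount %d", result$n_scored, n)))
  }
  if (abs(total / n - result$mean_score) > 1e-9) {
    return(list(ok = FALSE, why = "mean mismatch"))
  }
  # segment windows must be ordered and non-overlapping
  ends <- tapply(pairs$cand_pos, pairs$segment, max)
  starts <- tapply(pairs$cand_pos, pairs$segment, min)
  if (length(starts) > 1L && any(starts[-1] <= ends[-length(ends)])) {
    return(list(ok = FALSE, why = "overlapping segment windows"))
  }
  list(ok = TRUE, why = "")
}

expect_same_alignment <- function(a, b, label = "") {
  if (is_exclusion(a) || is_exclusion(b)) {
    expect_true(is_exclusion(a) && is_exclusion(b),
                label = paste("both exclusions", label))
    expect_identical(a$reason, b$reason, label = paste("same reason", label))
  } else {
    expect_equal(a$mean_score, b$mean_score, tolerance = 1e-10,
                 label = paste("same mean", label))
    expect_identical(a$segment_offsets, b$segment_offsets,
                     label = paste("same offsets", label))
    expect_identical(a$gap_lengths, b$gap_lengths,
                     label = paste("same gaps", label))
    expect_identical(a$n_scored, b$n_scored, label = paste("same n", label))
  }
}
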