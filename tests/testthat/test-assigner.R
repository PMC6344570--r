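make_ranking <- function(scores, excluded = character(0)) {
  # minimal ranking data.frame for decide_assignment
  ok <- data.frame(trace_id = rep("t", length(scores)),
                   candidate_id = as.character(names(scores)),
                   status = rep("aligned", length(scores)),
                   reason = rep("", length(scores)),
                   mean_score = unname(scores), stringsAsFactors = FALSE)
  ex <- if (length(excluded)) {
    data.frame(trace_id = "t", candidate_id = excluded, status = "excluded",
               reason = "size_violation", mean_score = NA_real_,
               stringsAsFactors = FALSE)
  } else NULL
  rbind(ok, ex)
}

test_that("screening a noiseless trace recovers its source protein at rank 1", {
  proteome <- generate_proteome(20, c(100, 400), seed = 7)
  target <- names(proteome)[7]
  sim <- simulate_trace(proteome[[target]], c(41, 100),
                        noise = noise_model(0, 0, 0, 0, 0, seed = 7))
  rk <- screen_proteome(sim$trace, proteome)
  expect_s3_class(rk, "candidate_ranking")
  expect_identical(nrow(rk), 20L)
  expect_identical(rk$candidate_id[1], target)
  expect_equal(rk$mean_score[1], 1)
  expect_identical(rk$start_offset[1], 40L)   # 0-based true offset
})

test_that("degenerate screens report the documented exclusions", {
  proteome <- generate_proteome(5, c(100, 150), seed = 3)
  amb <- density_trace("amb", list(lapply(1:6, function(i) trace_ambiguous())))
  rk <- screen_proteome(amb, proteome)
  expect_true(all(rk$status == "excluded"))
  expect_true(all(rk$reason == "no_scored_positions"))

  shorties <- generate_proteome(5, c(5, 8), seed = 4)
  long_tr <- density_trace("long", list(lapply(1:50, function(i) trace_observed(2))))
  rk2 <- screen_proteome(long_tr, shorties)
  expect_true(all(rk2$reason == "candidate_too_short"))

  expect_error(screen_proteome(amb, character(0)), "empty")
  expect_error(screen_proteome(amb, setNames(c("GAW", "GAW"), c("a", "a"))), "unique")
})

test_that("the final assignment follows the two-situation margin rule", {
  # only one candidate has an admissible alignment -> assigned outright
  a1 <- decide_assignment(make_ranking(c(A = 0.92), excluded = c("B", "C")))
  expect_identical(a1$status, "assigned")
  expect_identical(a1$winner, "A")
  expect_false(a1$needs_ss_check)

  # 0.90 vs 0.85: within the 0.1 margin -> ambiguous, both listed
  a2 <- decide_assignment(make_ranking(c(A = 0.90, B = 0.85)))
  expect_identical(a2$status, "ambiguous")
  expect_setequal(a2$contenders, c("A", "B"))

  # 0.95 vs 0.80: clear of the margin -> assigned, runner-up needs the
  # external secondary-structure rejection
  a3 <- decide_assignment(make_ranking(c(A = 0.95, B = 0.80)))
  expect_identical(a3$status, "assigned")
  expect_identical(a3$winner, "A")
  expect_true(a3$needs_ss_check)

  # boundary: a difference of exactly the margin is not enough
  a4 <- decide_assignment(make_ranking(c(A = 0.90, B = 0.80)))
  expect_identical(a4$status, "ambiguous")

  # nothing aligned at all
  a5 <- decide_assignment(make_ranking(setNames(numeric(0), character(0)),
                                       excluded = c("A", "B")))
  expect_identical(a5$status, "no_match")

  # ambiguous lists every candidate within the margin of the top
  a6 <- decide_assignment(make_ranking(c(A = 0.9, B = 0.85, C = 0.82, D = 0.5)))
  expect_setequal(a6$contenders, c("A", "B", "C"))

  # a full-width margin forces ambiguity whenever >= 2 candidates align
  a7 <- decide_assignment(make_ranking(c(A = 1, B = 0.25)), margin = 1)
  expect_identical(a7$status, "ambiguous")
  a8 <- decide_assignment(make_ranking(c(A = 1), excluded = "B"), margin = 1)
  expect_identical(a8$status, "assigned")
})

test_that("raising the top score never demotes an assignment", {
  set.seed(61)
  for (i in 1:50) {
    n <- sample(2:6, 1)
    sc <- sort(runif(n), decreasing = TRUE)
    names(sc) <- paste0("c", seq_len(n))
    before <- decide_assignment(make_ranking(sc))
    sc[1] <- min(1, sc[1] + runif(1, 0, 0.5))
    after <- decide_assignment(make_ranking(sc))
    if (before$status == "assigned") expect_identical(after$status, "assigned")
  }
})

test_that("combining copies pools evidence and never loses information", {
  segA <- list(trace_observed(4), trace_ambiguous(), trace_gap(3, 2),
               trace_observed(1))
  segB <- list(trace_observed(4), trace_observed(2), trace_gap(5, 2),
               trace_observed(1))
  tA <- density_trace("copy1", list(segA), group_id = "g1")
  tB <- density_trace("copy2", list(segB), group_id = "g1")

  comb <- combine_copies(list(tA, tB), best_matches = c("P6", "P6"))
  expect_s3_class(comb, "density_trace")
  el <- comb$segments[[1]]
  expect_identical(el[[1]]$size, 4L)
  expect_identical(el[[2]]$size, 2L)              # observed beats ambiguous
  expect_identical(gap_bounds(el[[3]]), c(4L, 5L))  # [2,5] vs [4,7] intersect
  # every combined position is at least as constrained as in each input
  expect_gte(trace_length_bounds(comb)$min_len,
             max(trace_length_bounds(tA)$min_len, trace_length_bounds(tB)$min_len))

  # identical copies combine to an identical trace body
  twin <- combine_copies(list(tA, tA), trace_id = tA$trace_id)
  expect_identical(twin$segments, tA$segments)
})

test_that("combination is refused on disagreement or incompatible evidence", {
  segA <- list(trace_observed(4), trace_observed(1))
  tA <- density_trace("a", list(segA))
  tB <- density_trace("b", list(segA))
  r1 <- combine_copies(list(tA, tB), best_matches = c("P6", "P9"))
  expect_true(is_refusal(r1))
  expect_identical(r1$reason, "best_match_disagrees")

  tC <- density_trace("c", list(list(trace_observed(4), trace_ambiguous(),
                                     trace_observed(1))))
  r2 <- combine_copies(list(tA, tC))
  expect_identical(r2$reason, "skeleton_mismatch")

  g1 <- density_trace("g1", list(list(trace_observed(1), trace_gap(2, 1))))
  g2 <- density_trace("g2", list(list(trace_observed(1), trace_gap(8, 2))))
  r3 <- combine_copies(list(g1, g2))
  expect_identical(r3$reason, "gap_bounds_disjoint")

  # conflicting observed sizes: maximum wins, conflict recorded
  o1 <- density_trace("o1", list(list(trace_observed(3))))
  o2 <- density_trace("o2", list(list(trace_observed(5))))
  expect_warning(cc <- combine_copies(list(o1, o2)), "conflicting")
  expect_identical(cc$segments[[1]][[1]]$size, 5L)
  expect_identical(attr(cc, "conflicts")$kept, 5L)

  expect_error(combine_copies(list(tA)), "at least two")
})

test_that("reports are deterministic TSV with detail and summary rows", {
  proteome <- generate_proteome(3, c(60, 90), seed = 9)
  sim <- simulate_trace(proteome[[2]], c(11, 40),
                        noise = noise_model(0, 0, 0, 0, 0, seed = 9))
  rk <- screen_proteome(sim$trace, proteome)
  res <- list(list(ranking = rk, assignment = decide_assignment(rk)))

  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_report(res, f1)
  write_report(res, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))  # byte-identical rerun

  lines <- readLines(f1)
  expect_true(any(grepl("^# config_hash=[0-9a-f]{32}$", lines)))
  body <- lines[!startsWith(lines, "#")]
  expect_identical(length(body), 1L + 3L + 1L)  # header + 3 detail + 1 summary
  expect_identical(sum(grepl("^detail\t", body)), 3L)
  expect_identical(sum(grepl("^summary\t", body)), 1L)

  f0 <- tempfile(fileext = ".tsv")
  write_report(list(), f0)
  body0 <- readLines(f0)
  expect_identical(sum(!startsWith(body0, "#")), 1L)  # header only
})
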