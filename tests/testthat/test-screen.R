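sc <- default_scale()

make_seqs <- function(lengths) {
  lapply(seq_along(lengths), function(i) {
    protein_sequence(paste0("s", i), random_sequence(lengths[i]))
  })
}

test_that("length filtering keeps exactly the in-range sequences", {
  set.seed(2)
  seqs <- make_seqs(c(100, 300, 310, 900))
  fl <- filter_length(seqs, 250, 400)
  expect_identical(vapply(fl$kept, function(s) s$id, ""), c("s2", "s3"))
  expect_identical(fl$n_dropped, 2L)

  all_in <- filter_length(seqs, 1)
  expect_length(all_in$kept, 4L)
  expect_identical(all_in$n_dropped, 0L)

  none <- filter_length(list(), 250, 400)
  expect_length(none$kept, 0L)
  expect_identical(none$n_dropped, 0L)
})

test_that("deduplication keeps first occurrences and maps removed records", {
  set.seed(3)
  base <- random_sequence(60)
  seqs <- list(
    protein_sequence("a", base),
    protein_sequence("b", random_sequence(60)),
    protein_sequence("c", base)
  )
  dd <- deduplicate(seqs)
  expect_identical(vapply(dd$kept, function(s) s$id, ""), c("a", "b"))
  expect_identical(dd$duplicate_map$removed_id, "c")
  expect_identical(dd$duplicate_map$kept_id, "a")

  distinct <- make_seqs(rep(60, 5))
  expect_length(deduplicate(distinct)$kept, 5L)

  copies <- lapply(1:10, function(i) protein_sequence(paste0("c", i), base))
  dd10 <- deduplicate(copies)
  expect_length(dd10$kept, 1L)
  expect_identical(nrow(dd10$duplicate_map), 9L)

  # exact-cap mode keys on the window only
  same_cap <- list(
    protein_sequence("x", paste0(substr(base, 1, 45), random_sequence(20))),
    protein_sequence("y", paste0(substr(base, 1, 45), random_sequence(20)))
  )
  expect_length(deduplicate(same_cap, mode = "exact-cap")$kept, 1L)
  expect_length(deduplicate(same_cap, mode = "exact-sequence")$kept, 2L)
})

test_that("distribution summaries follow the documented type-7 convention", {
  d <- summarize_distribution(c(0, 10, 20, 30))
  expect_equal(d$mean, 15)
  expect_equal(d$min, 0)
  expect_equal(d$max, 30)
  expect_equal(d$q3, as.numeric(stats::quantile(c(0, 10, 20, 30), 0.75, type = 7)))
  expect_equal(sum(d$histogram$counts), d$n)

  single <- summarize_distribution(5)
  expect_equal(
    c(single$mean, single$min, single$max, single$q1, single$median, single$q3),
    rep(5, 6)
  )

  expect_error(summarize_distribution(numeric()), "empty")

  set.seed(1)
  draws <- stats::rnorm(10000, 13.65, 8)
  dd <- summarize_distribution(draws)
  se <- 8 / sqrt(10000)
  expect_lt(abs(dd$mean - 13.65), 3 * se)
  expect_true(d$min <= d$q1 && d$q1 <= d$median && d$median <= d$q3 && d$q3 <= d$max)
})

test_that("candidate selection equals brute-force rule evaluation on random libraries", {
  set.seed(4)
  for (n in c(4, 17, 100, 1000, 10000)) {
    scored <- data.frame(
      id = sprintf("r%05d", seq_len(n)),
      H = stats::rnorm(n, 13.65, 8),
      stringsAsFactors = FALSE
    )
    sel <- select_candidates(scored, summarize_distribution(scored$H))
    expect_setequal(sel$id, brute_force_selection(scored$id, scored$H))
  }
})

test_that("boundary semantics: ties at the mean are excluded, at Q3 included", {
  scored <- data.frame(id = letters[1:4], H = c(0, 10, 20, 30))
  d <- summarize_distribution(scored$H)
  sel <- select_candidates(scored, d)
  # mean 15, Q3 (type 7) 22.5: only H = 20 qualifies
  expect_identical(sel$id, "c")

  same <- data.frame(id = letters[1:5], H = rep(7, 5))
  expect_identical(nrow(select_candidates(same, summarize_distribution(same$H))), 0L)

  at_q3 <- data.frame(id = letters[1:5], H = c(1, 2, 3, 4, 4))
  d2 <- summarize_distribution(at_q3$H)
  expect_true(all(at_q3$H[at_q3$H == d2$q3] %in% select_candidates(at_q3, d2)$H))
})

test_that("the end-to-end screen matches an independently scripted pipeline", {
  lib <- gen_library(200,
    duplicate_fraction = 0.1, short_fraction = 0.05, seed = 42
  )
  config <- screen_config()
  res <- run_screen(lib, sc, config)

  # independent pipeline: length filter, first-occurrence dedup, brute-force
  # scoring, type-7 quantiles, literal selection rule
  lens <- vapply(lib, function(s) nchar(s$residues), 1L)
  kept <- lib[lens >= 250 & lens <= 400]
  keys <- vapply(kept, function(s) s$residues, "")
  uniq <- kept[!duplicated(keys)]
  h <- vapply(uniq, function(s) brute_force_cap_score(s$residues, sc$values, 45L), numeric(1))
  ids <- vapply(uniq, function(s) s$id, "")

  expect_identical(res$counts$n_input, 200L)
  expect_identical(res$counts$n_length_dropped, sum(lens < 250 | lens > 400))
  expect_identical(res$counts$n_duplicates_removed, sum(duplicated(keys)))
  expect_identical(res$counts$n_scored, length(uniq))
  expect_equal(stats::setNames(res$scores$H, res$scores$id), stats::setNames(h, ids),
    tolerance = 1e-12
  )
  expect_setequal(res$selected$id, brute_force_selection(ids, h))

  # planted truth: every planted duplicate and short record was removed
  truth <- attr(lib, "truth")
  expect_identical(res$counts$n_duplicates_removed, length(truth$duplicate_ids))
  expect_false(any(truth$short_ids %in% res$scores$id))
})

test_that("stage counts are conserved and selection is order-invariant", {
  lib <- gen_library(120, duplicate_fraction = 0.1, short_fraction = 0.1, seed = 9)
  res <- run_screen(lib, sc)
  with(res$counts, {
    expect_identical(
      n_input,
      n_length_dropped + n_duplicates_removed + n_unscoreable + n_scored
    )
  })
  # order invariance holds for the selected sequence content; which id of a
  # duplicated sequence survives dedup is first-occurrence by design
  res_sorted <- run_screen(lib[order(names(lib))], sc)
  seq_of <- function(r) {
    sort(vapply(lib[r$selected$id], function(s) s$residues, ""))
  }
  expect_identical(unname(seq_of(res)), unname(seq_of(res_sorted)))
})

test_that("an all-too-short library yields an empty result with diagnostics", {
  seqs <- lapply(1:5, function(i) protein_sequence(paste0("t", i), random_sequence(80)))
  res <- run_screen(seqs, sc)
  expect_identical(res$counts$n_scored, 0L)
  expect_identical(res$counts$n_length_dropped, 5L)
  expect_null(res$distribution)
})

test_that("identical inputs produce byte-identical screen outputs", {
  lib <- gen_library(60, seed = 17)
  res <- run_screen(lib, sc)
  d1 <- file.path(tempdir(), "screen_rep1")
  d2 <- file.path(tempdir(), "screen_rep2")
  write_screen_result(res, d1)
  write_screen_result(run_screen(lib, sc), d2)
  for (f in c("screen_scores.tsv", "screen_selected.tsv", "screen_summary.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
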