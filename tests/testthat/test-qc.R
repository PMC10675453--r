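clean_segs <- segment_record(generate_case(sim_config(seed = 8)))

test_that("clean simulator segments pass every rule", {
  for (s in clean_segs) {
    res <- evaluate_rules(s)
    expect_true(res$passed)
    expect_true(all(res$rules))
  }
})

test_that("each rule trips on its own violation and no other", {
  base <- clean_segs[[5]]

  seg <- base
  seg$art_raw <- 100 + 29.9 * (seq_len(2048) - 1) / 2047  # peak-to-peak 29.9
  res <- evaluate_rules(seg)
  expect_false(res$rules[["art_peak_to_peak"]])
  expect_true(all(res$rules[names(res$rules) != "art_peak_to_peak"]))

  seg <- base
  seg$ppg_raw[1000] <- seg$ppg_raw[999] + 20.5            # one 20.5 jump
  seg$ppg_raw[1001] <- seg$ppg_raw[1000] - 20.5
  res <- evaluate_rules(seg)
  expect_false(res$rules[["ppg_slew"]])
  expect_true(all(res$rules[names(res$rules) != "ppg_slew"]))

  seg <- base
  seg$co_label <- 1.9
  res <- evaluate_rules(seg)
  expect_false(res$rules[["co_range"]])
  expect_true(all(res$rules[names(res$rules) != "co_range"]))

  expect_error(evaluate_rules(list(ppg_raw = 1:10, art_raw = 1:10)), "2048")
})

test_that("screening preserves order, tallies rules and is idempotent", {
  rec <- generate_case(sim_config(seed = 14))
  bad1 <- inject_artifact(rec, "spike_ppg", at = 5000)
  bad2 <- inject_artifact(rec, "low_pulse_pressure_art", at = 15000)
  bad3 <- inject_artifact(rec, "out_of_range_co", at = 25000)
  pick <- function(r) {
    segs <- segment_record(r)
    segs[[which(vapply(segs, function(s) s$center_index, integer(1)) ==
                  attr(r, "target_center"))]]
  }
  clean10 <- clean_segs[1:10]
  mixed <- c(clean10, list(pick(bad1), pick(bad2), pick(bad3)))
  out <- screen_dataset(mixed)
  expect_identical(out$report$n_candidates, 13L)
  expect_identical(out$report$n_passed, 10L)
  expect_identical(out$report$n_failed, 3L)
  expect_identical(out$report$rule_failures[["ppg_slew"]], 1L)
  expect_identical(out$report$rule_failures[["art_peak_to_peak"]], 1L)
  expect_identical(out$report$rule_failures[["co_range"]], 1L)
  expect_identical(sum(out$report$rule_failures), 3L)
  # order of kept segments preserved
  expect_identical(lapply(out$kept, function(s) s$center_index),
                   lapply(clean10, function(s) s$center_index))
  # idempotence
  again <- screen_dataset(out$kept)
  expect_identical(again$report$n_failed, 0L)
  expect_length(again$kept, 10)
  # degenerate inputs
  empty <- screen_dataset(list())
  expect_identical(empty$report$n_candidates, 0L)
  expect_length(empty$kept, 0)
})

test_that("tightening one threshold changes only that rule's tally", {
  set.seed(71)
  fixture <- replicate(60, random_raw_segment(), simplify = FALSE)
  base_tally <- screen_dataset(fixture)$report$rule_failures
  tight <- screen_dataset(fixture, qc_config(ppg_pp_min = 60))
  changed <- tight$report$rule_failures
  expect_gt(changed[["ppg_peak_to_peak"]], base_tally[["ppg_peak_to_peak"]])
  same <- setdiff(names(base_tally), "ppg_peak_to_peak")
  expect_identical(changed[same], base_tally[same])
})

test_that("rule evaluation matches the brute-force oracle", {
  set.seed(72)
  for (i in 1:200) {
    seg <- random_raw_segment()
    fast <- evaluate_rules(seg)$rules
    slow <- naive_qc(seg)
    expect_identical(fast, slow)
  }
})
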