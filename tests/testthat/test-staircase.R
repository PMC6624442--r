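cfg <- staircase_config()

test_that("staircase config validates its grid", {
  expect_error(staircase_config(step = 0), class = "illusim_config_error")
  expect_error(staircase_config(level_min = 108, level_max = 92),
               class = "illusim_config_error")
  expect_error(staircase_config(step = 3), class = "illusim_config_error")
  expect_error(staircase_config(start_ascending = 92.5),
               class = "illusim_config_error")
  expect_error(staircase_config(reversal_criterion = 0),
               class = "illusim_config_error")
})

test_that("update rule: moves, reversals and termination", {
  st <- new_staircase("a", "ascending", cfg)
  expect_equal(st$current_level, 92)
  # first response initialises direction without a reversal
  st <- update_staircase(st, "standard_larger", cfg)
  expect_false(attr(st, "reversal"))
  expect_equal(st$current_level, 93)
  # walk up to 101, then a "comparative larger" flips direction: reversal
  for (i in 1:8) st <- update_staircase(st, "standard_larger", cfg)
  expect_equal(st$current_level, 101)
  st <- update_staircase(st, "comparative_larger", cfg)
  expect_true(attr(st, "reversal"))
  expect_equal(st$reversal_levels, 101)
  expect_equal(st$current_level, 100)
  # alternate until six reversals -> terminated
  r <- "standard_larger"
  while (!st$terminated) {
    st <- update_staircase(st, r, cfg)
    r <- if (r == "standard_larger") "comparative_larger" else "standard_larger"
  }
  expect_length(st$reversal_levels, 6)
  expect_equal(sort(unique(st$reversal_levels)), c(100, 101))
  expect_false(st$capped)
  expect_error(update_staircase(st, "standard_larger", cfg),
               class = "illusim_usage_error")
})

test_that("levels clamp at the grid bounds without spurious reversals", {
  st <- new_staircase("a", "ascending", cfg)
  st <- update_staircase(st, "comparative_larger", cfg)   # down at the floor
  expect_equal(st$current_level, 92)
  expect_false(attr(st, "reversal"))
  st <- update_staircase(st, "comparative_larger", cfg)   # still clamped
  expect_equal(st$current_level, 92)
  expect_false(attr(st, "reversal"))
  # the clamped responses still set the direction: an "up" now is a reversal
  st <- update_staircase(st, "standard_larger", cfg)
  expect_true(attr(st, "reversal"))
  expect_equal(st$reversal_levels, 92)
})

test_that("trial cap terminates and flags a pathological staircase", {
  short <- staircase_config(max_trials = 10)
  st <- new_staircase("a", "descending", short)
  for (i in 1:10) st <- update_staircase(st, "standard_larger", short)
  expect_true(st$terminated)
  expect_true(st$capped)
  expect_lt(length(st$reversal_levels), short$reversal_criterion)
})

test_that("deterministic threshold observer brackets 100 in every staircase", {
  obs <- det_observer(threshold = 100, angles = 0)
  set.seed(61)
  blk <- run_block(obs, 0, cfg)
  expect_true(all(blk$comparative_level %in% 92:108))
  revs <- blk[blk$reversal, ]
  expect_true(all(revs$comparative_level %in% c(100, 101)))
  expect_equal(unname(table(revs$staircase_id)), rep(6L, 4),
               ignore_attr = TRUE)
})

test_that("blocks interleave four staircases and are seed-reproducible", {
  spec <- population_spec(n_subjects = 2, angles = 0)
  obs <- as.list(sample_population(spec, seed = 71)[1, ])
  set.seed(72); blk1 <- run_block(obs, 0, cfg)
  set.seed(72); blk2 <- run_block(obs, 0, cfg)
  expect_identical(blk1, blk2)
  expect_setequal(unique(blk1$staircase_id),
                  c("noshadow_asc", "shadow_asc", "noshadow_desc",
                    "shadow_desc"))
  # every completed staircase has exactly the criterion's reversals
  expect_equal(unname(tapply(blk1$reversal, blk1$staircase_id, sum)),
               rep(6L, 4), ignore_attr = TRUE)
  expect_length(attr(blk1, "capped_staircases"), 0)
  expect_true(all(blk1$standard_side %in% c("left", "right")))
})

test_that("experiment design arithmetic and reproducibility hold", {
  spec <- population_spec(n_subjects = 3, angles = c(-30, 0, 30))
  pop <- sample_population(spec, seed = 81)
  tr1 <- run_experiment(pop, c(-30, 0, 30), cfg, seed = 82)
  tr2 <- run_experiment(pop, c(-30, 0, 30), cfg, seed = 82)
  expect_identical(tr1, tr2)
  # 3 subjects x 3 angles = 9 blocks, 36 staircases
  blocks <- unique(tr1[, c("subject_id", "angle")])
  expect_equal(nrow(blocks), 9)
  expect_equal(nrow(unique(tr1[, c("subject_id", "angle", "staircase_id")])),
               36)
  expect_true(all(tr1$comparative_level %in% 92:108))
  # block order is a permutation per subject
  per_subj <- split(tr1$block_order, tr1$subject_id)
  for (b in per_subj) expect_setequal(unique(b), 1:3)
})

test_that("all staircases terminate by reversals at moderate slopes", {
  spec <- population_spec(n_subjects = 3, angles = c(0, 30), slope = 4,
                          lapse_rate = 0.05)
  pop <- sample_population(spec, seed = 91)
  tr <- run_experiment(pop, c(0, 30), cfg, seed = 92)
  expect_length(attr(tr, "capped"), 0)
  nrev <- tapply(tr$reversal,
                 interaction(tr$subject_id, tr$angle, tr$staircase_id), sum)
  expect_true(all(nrev == 6))
})

test_that("empty designs are refused", {
  spec <- population_spec(n_subjects = 2, angles = 0)
  pop <- sample_population(spec, seed = 1)
  expect_error(run_experiment(pop, numeric(0), cfg, seed = 1),
               class = "illusim_config_error")
  expect_error(run_experiment(pop[0, ], 0, cfg, seed = 1),
               class = "illusim_config_error")
})
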