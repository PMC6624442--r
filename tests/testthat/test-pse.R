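cfg <- staircase_config()

# hand-build a minimal two-staircase cell log from response sequences
make_cell <- function(asc_resp, desc_resp, config = cfg) {
  walk <- function(resp, direction) {
    st <- new_staircase("x", direction, config)
    lev <- numeric(length(resp))
    for (i in seq_along(resp)) {
      lev[i] <- st$current_level
      st <- update_staircase(st, resp[i], config)
    }
    lev
  }
  tibble::tibble(
    subject_id = "s01", shadow = FALSE, angle = 0,
    staircase_id = rep(c("asc", "desc"), c(length(asc_resp), length(desc_resp))),
    trial_index = c(seq_along(asc_resp), seq_along(desc_resp)),
    comparative_level = c(walk(asc_resp, "ascending"),
                          walk(desc_resp, "descending")),
    response = c(asc_resp, desc_resp)
  )
}

test_that("PSE is the mean of pooled reversal levels", {
  up <- "standard_larger"; down <- "comparative_larger"
  # ascending: climb 92..101 then alternate; descending mirror
  asc <- c(rep(up, 9), rep(c(down, up), 3))
  desc <- c(rep(down, 8), rep(c(up, down), 3))
  cell <- make_cell(asc, desc)
  # both staircases oscillate across the threshold: reversals at 100/101
  expect_equal(estimate_pse(cell, cfg, method = "pool"), 100.5)
  expect_equal(estimate_pse(cell, cfg, method = "staircase_means"), 100.5)
})

test_that("reversals are recomputed from the ordered response sequence", {
  up <- "standard_larger"; down <- "comparative_larger"
  trials <- tibble::tibble(
    subject_id = "s01", shadow = FALSE, angle = 0,
    staircase_id = "asc",
    trial_index = 1:18,
    comparative_level = c(92:103, rep(c(104, 103), 3)),
    response = c(rep(up, 12), rep(c(down, up), 3))
  )
  # direction flips on trials 13-18 -> reversal levels 104,103,... -> 103.5
  expect_equal(estimate_pse(trials, cfg), 103.5)
  # shuffling the file order changes nothing: trial_index defines the walk
  set.seed(7)
  expect_equal(estimate_pse(trials[sample(18), ], cfg), 103.5)
})

test_that("cells without reversals are flagged as estimation errors", {
  trials <- tibble::tibble(
    subject_id = "s01", shadow = FALSE, angle = 0,
    staircase_id = "asc", trial_index = 1:5,
    comparative_level = 92:96,
    response = rep("standard_larger", 5)
  )
  expect_error(estimate_pse(trials, cfg), class = "illusim_structure_error")
})

test_that("end-to-end deterministic observer PSE lies within one step of truth", {
  obs <- det_observer(threshold = 100, angles = 0)
  set.seed(101)
  blk <- run_block(obs, 0, cfg)
  for (sc in unique(blk$staircase_id)) {
    est <- estimate_pse(blk[blk$staircase_id == sc, ], cfg)
    expect_gte(est, 100); expect_lte(est, 101)
  }
  cellwise <- dplyr::mutate(blk, subject_id = "s01", angle = 0)
  tab <- pse_table(cellwise, cfg)
  expect_true(all(tab$pse >= 100 & tab$pse <= 101))
})

test_that("pse_table has one row per design cell and is order-invariant", {
  spec <- population_spec(n_subjects = 4, angles = c(-30, 0, 30))
  pop <- sample_population(spec, seed = 111)
  tr <- run_experiment(pop, c(-30, 0, 30), cfg, seed = 112)
  tab <- pse_table(tr, cfg)
  expect_s3_class(tab, "pse_table")
  expect_equal(nrow(tab), 4 * 2 * 3)
  expect_true(all(tab$pse >= 92 & tab$pse <= 108))
  set.seed(113)
  shuffled <- tr[sample(nrow(tr)), ]
  expect_equal(pse_table(shuffled, cfg), tab)
  # side metadata does not enter the estimate
  flipped <- dplyr::mutate(tr, standard_side = rev(standard_side))
  expect_equal(pse_table(flipped, cfg), tab)
})

test_that("pooling and staircase-wise averaging agree for balanced reversals", {
  obs <- det_observer(threshold = 100, angles = 0)
  set.seed(121)
  blk <- dplyr::mutate(run_block(obs, 0, cfg), subject_id = "s01", angle = 0)
  expect_equal(pse_table(blk, cfg, method = "pool")$pse,
               pse_table(blk, cfg, method = "staircase_means")$pse)
})

test_that("incomplete designs raise structural errors naming missing cells", {
  tab <- rand_pse_table(3, c(0, 30), seed = 131)
  expect_error(validate_pse_table(tab[-1, ]),
               class = "illusim_structure_error")
  expect_error(illusion_magnitude(tab[-5, ]),
               class = "illusim_structure_error")
  expect_error(pse_table(data.frame(subject_id = "a")),
               class = "illusim_structure_error")
})

test_that("illusion magnitude handles null and constant-shift tables exactly", {
  tab <- rand_pse_table(5, c(0, 30), seed = 141, noise_sd = 0)
  m0 <- illusion_magnitude(tab)
  expect_equal(m0$mean_magnitude, rep(0, 3))
  tab2 <- dplyr::mutate(tab, pse = pse + 2 * shadow)
  m2 <- illusion_magnitude(tab2)
  expect_equal(m2$mean_magnitude, rep(2, 3))
  expect_equal(m2$sd, rep(0, 3))
  expect_equal(m2$angle, c("0", "30", "overall"))
})

test_that("known illusion magnitudes are recovered through the staircases", {
  # noise-free observers with a 3-point shift: every subject's recovered
  # difference lies within one staircase step of the truth
  spec <- population_spec(n_subjects = 6, angles = c(0, 30),
                          baseline_sd = 0, shadow_mean = 3, shadow_sd = 0,
                          slope = 1, lapse_rate = 0)
  pop <- sample_population(spec, seed = 151)
  tr <- run_experiment(pop, c(0, 30), cfg, seed = 152)
  tab <- pse_table(tr, cfg)
  diffs <- tidyr::pivot_wider(tab, names_from = shadow, values_from = pse)
  d <- diffs$`TRUE` - diffs$`FALSE`
  expect_true(all(abs(d - 3) <= 1))
  # grand illusion magnitude within 2 SE of the configured truth
  ov <- illusion_magnitude(tab)
  ov <- ov[ov$angle == "overall", ]
  expect_lt(abs(ov$mean_magnitude - 3), 2 * max(ov$se, 0.25))
})
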