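test_that("adaptor sequences cycle the four-stimulus pattern at exact 200 ms spacing", {
  topup <- build_adaptation_sequence("visual_leading", "top_up")
  expect_equal(nrow(topup), 25)                   # 5 s / 200 ms
  expect_equal(attr(topup, "n_patterns"), 6.25)   # fractional final pattern
  initial <- build_adaptation_sequence("auditory_leading", "initial")
  expect_equal(nrow(initial), 300)                # 60 s / 200 ms
  expect_equal(attr(initial, "n_patterns"), 75)
  for (s in list(topup, initial)) {
    expect_true(all(diff(s$onset) == 200))
    expect_true(all(s$modality[-1] != s$modality[-nrow(s)]))  # strict alternation
    expect_true(all(s$duration == 20))
  }
  # visual-leading opening: high tone, lower circle, low tone, upper circle
  expect_equal(topup$modality[1:4], c("auditory", "visual", "auditory", "visual"))
  expect_equal(topup$pitch[c(1, 3)], c(4000, 1000))
  expect_equal(topup$elevation[c(2, 4)], c(-3, 3))
  # auditory-leading swaps the circle positions
  expect_equal(initial$elevation[c(2, 4)], c(3, -3))
  expect_error(build_adaptation_sequence("sideways"), "'arg'")
})

test_that("congruency-implied pairs have the condition's leader and a 200 ms lag", {
  vl <- congruent_pairs(build_adaptation_sequence("visual_leading", "top_up"))
  expect_true(all(vl$leader == "visual"))
  expect_true(all(vl$lag_ms == 200))
  expect_true(all(vl$visual_onset < vl$audio_onset))
  al <- congruent_pairs(build_adaptation_sequence("auditory_leading", "top_up"))
  expect_true(all(al$leader == "auditory"))
  expect_true(all(al$lag_ms == 200))
  # pairs are the congruent pitch-elevation combinations only
  expect_true(all((vl$pitch == 4000) == (vl$elevation > 0)))
  expect_true(all((al$pitch == 4000) == (al$elevation > 0)))
})

test_that("congruency labeling is consistent under feature flips", {
  # flipping both pitch and elevation preserves congruency; flipping one flips it
  expect_equal(pair_congruency("high_tone_upper"), "congruent")
  expect_equal(pair_congruency("low_tone_lower"), "congruent")
  expect_equal(pair_congruency("high_tone_lower"), "incongruent")
  expect_equal(pair_congruency("low_tone_upper"), "incongruent")
  expect_error(pair_congruency("mid_tone_center"), "unknown pair_type")
})

test_that("trial enumeration matches the factorial design totals and balance", {
  d1 <- experiment_design(1)
  t1 <- enumerate_trials(d1, participant = 1, seed = 41)
  expect_equal(nrow(t1), 440)
  expect_true(all(table(t1$block) == 55))
  # every (SOA, pairing, condition) cell holds exactly `occasions` trials
  counts <- table(t1$soa, t1$pair_type, t1$condition)
  expect_true(all(counts == d1$occasions))
  d2 <- experiment_design(2)
  t2 <- enumerate_trials(d2, participant = 1, seed = 41)
  expect_equal(nrow(t2), 880)
  expect_true(all(table(t2$block) == 55))
  expect_true(all(table(t2$soa, t2$pair_type, t2$condition) == d2$occasions))
  # adaptation alternates every 2 blocks (design 1) / 4 blocks (design 2)
  cond_by_block1 <- as.vector(tapply(t1$condition, t1$block, unique))
  expect_equal(rle(cond_by_block1)$lengths, rep(2L, 4))
  cond_by_block2 <- as.vector(tapply(t2$condition, t2$block, unique))
  expect_equal(rle(cond_by_block2)$lengths, rep(4L, 4))
  # starting condition is counterbalanced by participant parity
  t1b <- enumerate_trials(d1, 2, seed = 41)
  expect_false(cond_by_block1[1] == t1b$condition[t1b$block == 1][1])
})

test_that("simulated responses follow the observer's response probabilities", {
  d1 <- experiment_design(1)
  trials <- enumerate_trials(d1, 1, seed = 42)
  # criteria at +/- 1e6: probability is at ceiling, responses all simultaneous
  always <- sim_observer(base = criterion_params(-1e6, 1e6, 50, 50),
                         pss_shift = 0)
  rec <- simulate_responses(always, trials, seed = 42)
  expect_true(all(rec$response == 1L))
  # determinism per seed
  obs <- sim_observer(id = 3)
  r1 <- simulate_responses(obs, trials, seed = 7)
  r2 <- simulate_responses(obs, trials, seed = 7)
  expect_identical(r1, r2)
  expect_equal(unique(r1$participant), 3L)
  # law of large numbers at one SOA cell
  big <- data.frame(participant = 1L, block = 1L, condition = "visual_leading",
                    pair_type = "high_tone_upper", congruency = "congruent",
                    soa = 100, occasion = 1L)[rep(1, 1e4), ]
  p_target <- prob_simultaneous(obs$params$visual_leading$congruent, 100)
  sim <- simulate_responses(obs, big, seed = 8)
  expect_lt(abs(mean(sim$response) - p_target), 0.02)
})

test_that("missing observer cells are reported", {
  obs <- sim_observer(id = 1)
  obs$params$visual_leading$congruent <- NULL
  trials <- enumerate_trials(experiment_design(1), 1, seed = 1)
  expect_error(simulate_responses(obs, trials, seed = 1), "no parameters")
})

test_that("aggregation pools pairings within congruency at the design trial counts", {
  d1 <- experiment_design(1)
  obs <- sim_observer(id = 1)
  rec <- simulate_responses(obs, enumerate_trials(d1, 1, seed = 5), seed = 6)
  agg <- aggregate_trials(rec)
  expect_equal(nrow(agg), 11 * 2)            # 11 SOAs x 2 conditions
  expect_true(all(agg$n == 20))              # 2 pairings x 10 occasions
  expect_equal(sum(agg$k), sum(rec$response))
  d2 <- experiment_design(2)
  rec2 <- simulate_responses(obs, enumerate_trials(d2, 1, seed = 5), seed = 6)
  agg2 <- aggregate_trials(rec2)
  expect_equal(nrow(agg2), 11 * 2 * 2)       # x 2 congruency classes
  expect_true(all(agg2$n == 20))
  # empty input gives an empty frame; mixed grids are refused
  expect_equal(nrow(aggregate_trials(rec[0, ])), 0)
  rec2$participant <- 2L
  expect_error(aggregate_trials(rbind(rec, rec2)), "SOA grids")
  expect_s3_class(cells_for(agg, 1, "visual_leading"), "binomial_cells")
})

test_that("observer populations inject the condition shift into congruent cells only", {
  pop <- sim_observer_population(5, pss_shift = 15, pss_sd = 0, shift_sd = 0,
                                 seed = 3)
  for (obs in pop) {
    diff_con <- pss(obs$params$visual_leading$congruent) -
      pss(obs$params$auditory_leading$congruent)
    diff_inc <- pss(obs$params$visual_leading$incongruent) -
      pss(obs$params$auditory_leading$incongruent)
    expect_equal(diff_con, 15)
    expect_equal(diff_inc, 0)
    # shifts move both criteria equally: window identical across cells
    wins <- sapply(obs$params, function(byc) sapply(byc, sj_window))
    expect_true(all(abs(wins - wins[1]) < 1e-9))
  }
})
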