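test_that("a per-fly record equals independently calling each metric", {
  tr <- simulate_trajectory(simulation_config(n_frames = 1500, seed = 8,
                                              dose = 0.4))
  p <- aim_params()
  rec <- summarize_fly(tr, p, epsilon_mm = 0.05, fly_id = "f1", group = "g")
  k <- kinematic_series(tr)
  expect_equal(rec$mean_speed_mm_s, mean_speed(k))
  expect_equal(rec$yawing_deg_per_frame, yawing_metric(k))
  expect_equal(rec$freezing_fraction, freezing_fraction(k, 0.05))
  expect_equal(rec$raw_H, aim_score(k, p)$raw_H)
  expect_equal(rec$peak_deviation_pct, peak_deviation(k, p))
  expect_equal(rec$n_frames, 1500L)
  expect_false(rec$aim_all_skipped)
})

test_that("degenerate flies produce flagged, finite records", {
  # constant-speed fly: no freezing, no yawing, no AIMs
  tr <- trajectory_from_speeds(rep(2, 100))
  rec <- summarize_fly(tr)
  expect_equal(rec$freezing_fraction, 0)
  expect_equal(rec$raw_H, 0L)
  expect_equal(rec$yawing_deg_per_frame, 0)

  # fully frozen fly: freezing 1, speed 0, AIM skipped-flagged
  still <- fly_trajectory(0:99, rep(0, 100), rep(0, 100), rep(0, 100))
  expect_warning(rec2 <- summarize_fly(still), "zero-speed guard")
  expect_equal(rec2$freezing_fraction, 1)
  expect_equal(rec2$mean_speed_mm_s, 0)
  expect_true(rec2$aim_all_skipped)
  expect_equal(rec2$raw_H, 0L)
  expect_true(is.na(rec2$peak_deviation_pct))
  expect_error(summarize_fly(still, group = ""), "non-empty")
})

make_records <- function(groups, speeds, H = seq_along(speeds)) {
  data.frame(fly_id = paste0("f", seq_along(speeds)), group = groups,
             mean_speed_mm_s = speeds,
             yawing_deg_per_frame = speeds * 2,
             freezing_fraction = pmin(1, speeds / 10),
             raw_H = H, normalized_H = NA_real_,
             peak_deviation_pct = speeds * 10,
             aim_all_skipped = FALSE, n_frames = 9018L,
             stringsAsFactors = FALSE)
}

test_that("group summaries compute mean, SEM and percent change vs control", {
  rec <- make_records(c("ctrl", "ctrl", "ldopa", "ldopa"),
                      c(1.1, 1.3, 0.4, 0.6))
  gs <- summarize_group(rec, "ctrl")
  sp <- gs[gs$metric == "mean_speed_mm_s", ]
  expect_equal(sp$mean[sp$group == "ctrl"], 1.2)
  expect_equal(sp$mean[sp$group == "ldopa"], 0.5)
  # (0.5 - 1.2)/1.2 * 100: a 58.33% decrease in speed
  expect_equal(sp$pct_change_vs_control[sp$group == "ldopa"], -58.33333,
               tolerance = 1e-6)
  expect_equal(sp$sem[sp$group == "ctrl"], sd(c(1.1, 1.3)) / sqrt(2))
  # control percent change is exactly 0 for every metric
  expect_true(all(gs$pct_change_vs_control[gs$group == "ctrl"] == 0))

  single <- summarize_group(make_records(c("ctrl", "solo"), c(1, 2)), "ctrl")
  expect_true(all(single$sem[single$group == "solo"] == 0))
  expect_true(all(single$sem_degenerate[single$group == "solo"]))
  expect_error(summarize_group(rec, "nope"), "not present")
})

test_that("group summaries match naive recomputation on random cohorts", {
  set.seed(14)
  rec <- make_records(sample(c("a", "b", "c"), 30, replace = TRUE),
                      runif(30, 0.2, 5), H = rpois(30, 20))
  gs <- summarize_group(rec, "a")
  for (g in unique(rec$group)) {
    vals <- rec$raw_H[rec$group == g]
    row <- gs[gs$group == g & gs$metric == "raw_H", ]
    expect_equal(row$mean, sum(vals) / length(vals))
    expect_equal(row$sem, sd(vals) / sqrt(length(vals)))
    cm <- mean(rec$raw_H[rec$group == "a"])
    expect_equal(row$pct_change_vs_control,
                 if (g == "a") 0 else (mean(vals) - cm) / cm * 100)
  }
})

test_that("normalized AIM anchors the control group at zero", {
  rec <- make_records(c("ctrl", "ctrl", "ctrl", "tr"), c(1, 1, 1, 1),
                      H = c(3, 5, 4, 12))
  out <- add_normalized_aim(rec, "ctrl")
  expect_equal(out$normalized_H, c(-1, 1, 0, 8))
  expect_equal(mean(out$normalized_H[out$group == "ctrl"]), 0)
  expect_error(add_normalized_aim(rec, "zz"), "not present")
})

test_that("dose trend recovers perfect monotone trends and rejects nothing under the null", {
  # one fly per dose, strictly increasing values: rho is exactly 1
  d1 <- c(0, 0.25, 0.5, 0.75, 1)
  expect_equal(dose_trend(d1, c(2, 5, 7, 9, 30), seed = 4)$rho, 1,
               tolerance = 1e-12)
  expect_equal(dose_trend(d1, -c(2, 5, 7, 9, 30), seed = 4)$rho, -1,
               tolerance = 1e-12)

  d <- rep(d1, each = 4)
  up <- d * 10 + rep(c(0.01, 0.02, 0.03, 0.04), 5)
  tr_up <- dose_trend(d, up, n_permutations = 999, seed = 4)
  expect_gt(tr_up$rho, 0.9)  # tied dose ranks cap rho just below 1
  expect_lt(tr_up$p_value, 0.01)

  # dose-shuffled data: |rho| small, p typically large
  set.seed(99)
  rhos <- numeric(20); ps <- numeric(20)
  for (i in 1:20) {
    y <- sample(up)
    t0 <- dose_trend(d, y, n_permutations = 499, seed = i)
    rhos[i] <- t0$rho; ps[i] <- t0$p_value
  }
  expect_lt(mean(abs(rhos)), 0.3)
  expect_gte(sum(ps > 0.05), 15L)

  expect_error(dose_trend(c(0, 0, 1, 1), 1:4), "3 distinct dose levels")
})

test_that("the cohort pipeline is deterministic end to end and trends with dose", {
  cfg <- simulation_config(n_frames = 1503, seed = 55)
  co <- simulate_cohort(cfg, n_flies = 3, dose_levels = c(0, 0.5, 1))
  recs <- summarize_cohort(co)
  expect_equal(nrow(recs), 9L)
  expect_equal(mean(recs$normalized_H[recs$dose == 0]), 0)
  recs2 <- summarize_cohort(simulate_cohort(cfg, 3, c(0, 0.5, 1)))
  expect_identical(recs, recs2)

  tr <- dose_trend(recs$dose, recs$raw_H, n_permutations = 999, seed = 2)
  expect_gt(tr$rho, 0)
  gs <- summarize_group(recs, "dose_0")
  expect_s3_class(gs, "group_summary")

  an <- group_anova(recs, "mean_speed_mm_s")
  expect_s3_class(an$anova, "aov")
  expect_s3_class(an$tukey, "TukeyHSD")
})

test_that("acute rescue restores speed without raising AIM scores", {
  n <- 3006  # 1-minute recordings keep the scenario light
  ctrl_cfg <- simulation_config(n_frames = n, seed = 70)
  pd_cfg <- simulation_config(n_frames = n, seed = 71, walk_speed_mm_s = 3.5,
                              freeze_enter_p = 0.03, burst_rate_per_min = 0)
  rescue_cfg <- simulation_config(n_frames = n, seed = 72)
  chronic_cfg <- simulation_config(n_frames = n, seed = 73, dose = 1)
  mstats <- function(cfg) {
    co <- simulate_cohort(cfg, n_flies = 5, dose_levels = cfg$dose)
    r <- summarize_cohort(co)
    c(speed = mean(r$mean_speed_mm_s), H = mean(r$raw_H))
  }
  ctrl <- mstats(ctrl_cfg); pd <- mstats(pd_cfg)
  rescue <- mstats(rescue_cfg); chronic <- mstats(chronic_cfg)
  expect_gt(rescue["speed"], pd["speed"])          # motor defect rescued
  expect_gt(chronic["H"], 2 * ctrl["H"])           # chronic dosing scores AIMs
  # rescued flies stay near the control AIM baseline
  expect_lt(abs(rescue["H"] - ctrl["H"]), (chronic["H"] - ctrl["H"]) / 2)
})
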