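test_that("event binning converts counts to rates in half-open 500-ms bins", {
  spk <- spikes_tbl(u1 = c(0.1, 0.2, 0.3, 0.6), u2 = 2.5)
  ev <- tibble::tibble(event = "drop", level = 1L, onset = 0)
  b <- bin_event_responses(spk, ev)
  expect_equal(b$rate[b$unit_id == "u1" & b$bin == 1], 6)   # 3 spikes / 0.5 s
  expect_equal(b$rate[b$unit_id == "u1" & b$bin == 2], 2)
  expect_equal(b$rate[b$unit_id == "u2" & b$bin == 1], 0)
  # boundary spike at exactly onset + 0.5 belongs to bin 2
  b2 <- bin_event_responses(spikes_tbl(u1 = 0.5), ev)
  expect_equal(b2$rate[b2$bin == 1], 0)
  expect_equal(b2$rate[b2$bin == 2], 2)
  # overlapping events warn
  ev2 <- tibble::tibble(event = c("drop", "drop"), level = 1L, onset = c(0, 0.4))
  expect_warning(bin_event_responses(spk, ev2), "overlap")
})

test_that("binned mean rate of a Poisson unit matches its rate", {
  set.seed(42)
  spk <- tibble::tibble(unit_id = "u1", time = poisson_train(10, 2000))
  ev <- tibble::tibble(event = "drop", level = 1L, onset = seq(0.5, 1990, by = 2))
  b <- bin_event_responses(spk, ev)
  n_bins <- nrow(ev) * 2
  se <- sqrt(10 / (0.5 * n_bins))
  expect_lt(abs(mean(b$rate) - 10), 3 * se)
})

test_that("baseline excludes post-event windows and errors without eligible time", {
  set.seed(43)
  spk <- tibble::tibble(unit_id = "u1", time = poisson_train(2, 1000))
  attr(spk, "span") <- c(0, 1000)
  ev <- tibble::tibble(event = "drop", level = 1L, onset = c(300, 600))
  base <- compute_baseline(spk, ev)
  expect_lt(abs(base$f0$f0 - 2), 3 * sqrt(2 / 994))
  expect_equal(base$g0, mean(base$f0$f0))
  # spikes only inside event windows -> f0 = 0
  spk2 <- spikes_tbl(u1 = c(300.5, 600.5))
  attr(spk2, "span") <- c(0, 1000)
  expect_equal(compute_baseline(spk2, ev)$f0$f0, 0)
  # no eligible time
  ev3 <- tibble::tibble(event = "drop", level = 1L, onset = seq(0, 999, by = 2))
  spk3 <- spikes_tbl(u1 = 1)
  attr(spk3, "span") <- c(0, 1000)
  expect_error(compute_baseline(spk3, ev3, exclude_after = 3),
               class = "reverb_no_baseline")
})

test_that("response normalization matches its closed form", {
  # identity: f_startle = f0 -> R = T = 0
  expect_equal(normalize_response(2, 2, 2.7)$t_score, 0)
  # frozen arithmetic: (5 - 1) / (2.7 + 1) and log1p of it
  out <- normalize_response(5, 1, 2.7)
  expect_equal(out$r_normalized, 4 / 3.7, tolerance = 1e-12)
  expect_equal(out$t_score, log(1 + 4 / 3.7), tolerance = 1e-12)
  expect_equal(round(out$r_normalized, 4), 1.0811)
  expect_equal(round(out$t_score, 4), 0.7329)
  # low-baseline limit: R -> f_startle / g0
  expect_equal(normalize_response(5, 0, 2.7)$r_normalized, 5 / 2.7)
  # monotone in f_startle
  tt <- normalize_response(seq(0, 10, by = 0.5), 1, 2.7)$t_score
  expect_true(all(diff(tt) > 0))
  expect_error(normalize_response(1, 0, 0), class = "reverb_bad_input")
})

test_that("responsiveness selection honours threshold and significance settings", {
  pop <- small_population()
  rt <- response_table(pop$spikes, pop$schedule)
  none <- select_responsive(rt, threshold_t = Inf)
  expect_equal(sum(none$units$responsive), 0)
  all_units <- select_responsive(rt, threshold_t = 0, alpha = NULL)
  expect_true(all(all_units$units$responsive))
})

test_that("selectivity labels follow the responsive-type count", {
  pop <- small_population()
  rt <- response_table(pop$spikes, pop$schedule)
  resp <- select_responsive(rt)
  resp$by_type$responsive <- resp$by_type$unit_id %in% c("u001", "u002") &
    (resp$by_type$unit_id == "u001" | resp$by_type$event == "drop")
  sel <- suppressWarnings(classify_selectivity(resp))
  expect_equal(sel$selectivity_group[sel$unit_id == "u001"], "general")
  expect_equal(sel$selectivity[sel$unit_id == "u002"], "specific:drop")
  expect_equal(sel$selectivity[sel$unit_id == "u003"], "none")
})

test_that("intensity dependence separates flat from proportional responses", {
  # deterministic trial rates via a constructed response table
  cfg <- tiny_config()
  sched <- build_schedule(cfg, seed = 104)
  pop <- generate_population(cfg, sched, seed = 105)
  rt <- response_table(pop$spikes, sched)
  resp <- select_responsive(rt, threshold_t = 0, alpha = NULL)
  # overwrite one unit's drop trials with exact patterns
  drop_rows <- rt$trials$event == "drop" & rt$trials$unit_id == "u001"
  rt$trials$rate[drop_rows] <- 4                                  # flat
  resp$by_type$responsive <- resp$by_type$unit_id == "u001" &
    resp$by_type$event == "drop"
  flat <- classify_intensity_dependence(rt, resp, seed = 1)
  expect_equal(flat$intensity_class[flat$unit_id == "u001"], "invariant")
  rt$trials$rate[drop_rows] <- 2 * rt$trials$level[drop_rows]     # proportional
  up <- classify_intensity_dependence(rt, resp, seed = 1)
  expect_equal(up$intensity_class[up$unit_id == "u001"], "sensitive-up")
  rt$trials$rate[drop_rows] <- 8 / rt$trials$level[drop_rows]     # decreasing
  dn <- classify_intensity_dependence(rt, resp, seed = 1)
  expect_equal(dn$intensity_class[dn$unit_id == "u001"], "sensitive-down")
})

test_that("unit-type classification and complex spike index follow their definitions", {
  # regular 400-ms train: no 2-15 ms ISIs -> CSI 0; 2.5 Hz mean -> pyramidal
  reg <- tibble::tibble(unit_id = "u1", time = seq(0.1, 100, by = 0.4),
                        amplitude = 1)
  attr(reg, "span") <- c(0, 100)
  out <- classify_unit_type(reg)
  expect_equal(out$csi, 0)
  expect_equal(out$unit_class, "pyramidal")
  # constant amplitude bursty train: ISI criterion met but no decrease -> 0
  t2 <- as.vector(rbind(seq(1, 60, by = 0.5), seq(1, 60, by = 0.5) + 0.005))
  b2 <- tibble::tibble(unit_id = "u1", time = sort(t2), amplitude = 1)
  expect_equal(classify_unit_type(b2)$csi, 0)
  # constructed train: 30% of spike pairs are 2-15 ms with decreasing amplitude
  n_pairs <- 30; n_single <- 139   # 200 spikes, 30 qualifying of 199 lags
  burst_start <- seq(1, by = 1, length.out = n_pairs)
  singles <- seq(40, by = 0.5, length.out = n_single + 1)
  tt <- sort(c(burst_start, burst_start + 0.01, singles))
  amp <- rep(1, length(tt))
  amp[match(burst_start + 0.01, tt)] <- 0.5
  b3 <- tibble::tibble(unit_id = "u1", time = tt, amplitude = amp)
  expect_equal(classify_unit_type(b3)$csi, 100 * n_pairs / (length(tt) - 1))
  # < 100 spikes -> unknown
  expect_equal(classify_unit_type(spikes_tbl(u1 = 1:10))$unit_class, "unknown")
  # 20 Hz train -> interneuron
  fast <- tibble::tibble(unit_id = "u1", time = seq(0.05, 100, by = 0.05))
  attr(fast, "span") <- c(0, 100)
  expect_equal(classify_unit_type(fast)$unit_class, "interneuron")
})

test_that("exponential-kernel rate estimate is causal and mass-preserving", {
  # empty train -> zero function
  expect_true(all(smooth_rate(numeric(), 0, 1)$rate == 0))
  # single spike -> shifted kernel
  sr <- smooth_rate(1, 0, 3, dt = 0.001, tau = 0.1)
  expect_true(all(sr$rate[sr$time < 1] == 0))
  at <- sr$rate[abs(sr$time - 1.2) < 1e-9]
  expect_equal(at, exp(-0.2 / 0.1) / 0.1, tolerance = 1e-6)
  # integral equals the spike count within 1%
  set.seed(44)
  tt <- sort(runif(200, 0, 50))
  sr2 <- smooth_rate(tt, 0, 52, dt = 0.002, tau = 0.1)
  expect_equal(sum(sr2$rate) * 0.002, 200, tolerance = 0.01)
})

test_that("smoothed and binned rates agree over the event window", {
  set.seed(45)
  tt <- poisson_train(20, 30)
  spk <- tibble::tibble(unit_id = "u1", time = tt)
  ev <- tibble::tibble(event = "drop", level = 1L, onset = 10)
  b <- bin_event_responses(spk, ev)
  binned_mean <- mean(b$rate)
  sr <- smooth_rate(tt, 10, 11, dt = 0.001, tau = 0.02)
  expect_lt(abs(mean(sr$rate) - binned_mean), 0.1 * binned_mean)
})

test_that("taxonomy report reproduces the published composition percentages", {
  rep <- taxonomy_report(list(
    n_total = 1623, n_responsive = 583,
    invariant = c(general = 152, subgeneral = 75, specific = 57),
    sensitive = c(general = 134, subgeneral = 75, specific = 89)
  ))
  expect_equal(rep$pct_printed[rep$group == "all"], 35.9)
  inv <- rep[rep$group == "invariant", ]
  expect_equal(inv$pct_printed[match(c("general", "subgeneral", "specific"),
                                     inv$category)], c(54, 26, 20))
  sen <- rep[rep$group == "sensitive", ]
  expect_equal(sen$pct_printed[match(c("general", "subgeneral", "specific"),
                                     sen$category)], c(45, 25, 30))
})
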