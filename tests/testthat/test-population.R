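test_that("ground-truth category counts match configured fractions exactly", {
  cfg <- simulation_config(n_units = 250)
  sched <- build_schedule(cfg, seed = 1)
  pop <- generate_population(cfg, sched, seed = 2)
  tr <- pop$truth
  expect_equal(sum(tr$responsive), round(250 * 0.36))
  n_resp <- sum(tr$responsive)
  expect_equal(sum(tr$intensity_class == "invariant"), round(n_resp / 2))
  inv <- tr[tr$intensity_class == "invariant", ]
  # largest-remainder apportionment of 45 into 0.54/0.26/0.20
  expect_equal(as.integer(table(inv$selectivity_group)[c("general", "subgeneral", "specific")]),
               c(24L, 12L, 9L))
  # selectivity label is none iff not responsive
  expect_true(all((tr$selectivity == "none") == !tr$responsive))
  # subgeneral subsets have 2-3 types, specific exactly 1
  ns <- lengths(tr$resp_types)
  expect_true(all(ns[tr$selectivity_group == "subgeneral"] %in% 2:3))
  expect_true(all(ns[tr$selectivity_group == "specific"] == 1))
})

test_that("generation is deterministic given the seed and fails on n_units = 0", {
  cfg <- tiny_config()
  sched <- build_schedule(cfg, seed = 1)
  p1 <- generate_population(cfg, sched, seed = 5)
  p2 <- generate_population(cfg, sched, seed = 5)
  expect_identical(p1$spikes, p2$spikes)
  expect_identical(p1$truth, p2$truth)
  cfg0 <- tiny_config()
  cfg0$n_units <- 0
  expect_error(generate_population(cfg0, sched, seed = 1),
               class = "reverb_invalid_config")
})

test_that("baseline firing matches the configured Poisson rate", {
  # a single non-responsive unit at exactly 2 Hz over ~1000 s
  cfg <- simulation_config(n_units = 1, p_responsive = 0, p_pyramidal = 1,
                           baseline_pyramidal = c(2, 2),
                           event_types = list(drop = 1L), n_repetitions = 2,
                           iti_s = c(30, 30), baseline_s = 900, tail_s = 40)
  sched <- build_schedule(cfg, seed = 3)
  pop <- generate_population(cfg, sched, seed = 4)
  span <- attr(pop$spikes, "span")
  dur <- diff(span)
  rate <- nrow(pop$spikes) / dur
  se <- sqrt(2 / dur)
  expect_lt(abs(rate - 2), 3 * se)
})

test_that("zero gains leave peri-event rates at baseline", {
  cfg <- tiny_config(p_invariant = 1, gain_invariant_hz = 0)
  sched <- build_schedule(cfg, seed = 6)
  pop <- generate_population(cfg, sched, seed = 7)
  rt <- response_table(pop$spikes, sched)
  # pooled event-window rate should match pooled baseline closely
  expect_equal(mean(rt$by_type$f_startle), mean(rt$by_type$f0), tolerance = 0.05)
})

test_that("sensitive-up gains produce strictly ordered trial-mean rates", {
  # strong rates so the ordering holds with overwhelming probability
  cfg <- simulation_config(n_units = 4, p_responsive = 1, p_invariant = 0,
                           p_sensitive_down = 0, p_pyramidal = 1,
                           baseline_pyramidal = c(2, 2),
                           gain_sensitive_hz = c(2, 4, 8) * 2,
                           sensitive_split = c(general = 1, subgeneral = 0, specific = 0),
                           trial_coupling = c(general = 0, subgeneral = 0, specific = 0),
                           event_types = list(drop = 1:3),
                           iti_s = c(10, 20), baseline_s = 30, tail_s = 10)
  ok <- vapply(1:50, function(s) {
    sched <- build_schedule(cfg, seed = 100 + s)
    pop <- generate_population(cfg, sched, seed = 200 + s)
    rt <- bin_event_responses(pop$spikes, sched)
    mu <- rt |>
      dplyr::group_by(unit_id, level) |>
      dplyr::summarise(rate = mean(rate), .groups = "drop") |>
      dplyr::group_by(unit_id) |>
      dplyr::summarise(mono = all(diff(rate[order(level)]) > 0), .groups = "drop")
    all(mu$mono)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("window spike counts are Poisson-dispersed under the configured rate", {
  cfg <- simulation_config(n_units = 1, p_responsive = 0, p_pyramidal = 0,
                           baseline_interneuron = c(10, 10),
                           event_types = list(drop = 1L), n_repetitions = 2,
                           iti_s = c(30, 30), baseline_s = 500, tail_s = 30)
  sched <- build_schedule(cfg, seed = 1)
  pop <- generate_population(cfg, sched, seed = 101)
  starts <- seq(0, 495, by = 5)[1:100]
  cnt <- vapply(starts, function(s) {
    sum(pop$spikes$time >= s & pop$spikes$time < s + 2)
  }, numeric(1))
  # dispersion index test: (n-1) s^2 / mean ~ chi^2_{n-1} at alpha = 0.01
  stat <- (length(cnt) - 1) * var(cnt) / mean(cnt)
  expect_gt(stat, qchisq(0.005, length(cnt) - 1))
  expect_lt(stat, qchisq(0.995, length(cnt) - 1))
})

test_that("reactivation injection bookkeeping and amplitude behave as configured", {
  pop0 <- small_population()
  # recorded injection times match the requested explicit times
  base <- generate_population(tiny_config(), build_schedule(tiny_config(), seed = 101),
                              seed = 102)
  t_req <- c(200, 260)
  inj <- inject_reactivations(base, seed = 1, times = t_req)
  expect_equal(sort(inj$injections$time), sort(t_req))
  expect_error(inject_reactivations(base, times = 1e7), class = "reverb_range_error")
  # amplitude 0 adds no spikes
  cfg0 <- tiny_config(react_amplitude = 0)
  sched <- build_schedule(cfg0, seed = 101)
  p0 <- generate_population(cfg0, sched, seed = 102)
  p0i <- inject_reactivations(p0, seed = 103)
  expect_identical(nrow(p0i$spikes), nrow(p0$spikes))
})

test_that("injections drive invariant but not sensitive units above baseline", {
  cfg <- simulation_config(n_units = 120, react_per_event = c(2, 3))
  sched <- build_schedule(cfg, seed = 31)
  pop0 <- generate_population(cfg, sched, seed = 32)
  pop <- inject_reactivations(pop0, seed = 33)
  inj <- pop$injections
  expect_gte(nrow(inj), 100)
  rate_in <- function(spikes, ids, windows_start, dur = 1) {
    s <- spikes[spikes$unit_id %in% ids, ]
    n <- sum(vapply(windows_start, function(t) {
      sum(s$time >= t & s$time < t + dur)
    }, numeric(1)))
    n / (length(windows_start) * dur * length(ids))
  }
  inv <- pop$truth$unit_id[pop$truth$intensity_class == "invariant"]
  sen <- pop$truth$unit_id[startsWith(pop$truth$intensity_class, "sensitive")]
  base_inv <- mean(pop$truth$baseline_hz[pop$truth$unit_id %in% inv])
  base_sen <- mean(pop$truth$baseline_hz[pop$truth$unit_id %in% sen])
  r_inv <- rate_in(pop$spikes, inv, inj$time)
  r_sen <- rate_in(pop$spikes, sen, inj$time)
  expect_gt(r_inv, base_inv * 1.2)
  expect_lt(r_sen, base_sen * 1.15)
})
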