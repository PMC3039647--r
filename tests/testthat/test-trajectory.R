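# One shared medium-sized fitted model for the trajectory tests.
traj_fixture <- local({
  env <- new.env()
  function() {
    if (is.null(env$fx)) {
      cfg <- simulation_config(n_units = 120,
                               event_types = list(sound = 1L, drop = 1:3),
                               baseline_s = 60, tail_s = 60, iti_s = c(20, 40))
      sched <- build_schedule(cfg, seed = 301)
      pop <- generate_population(cfg, sched, seed = 302)
      pop <- inject_reactivations(pop, seed = 303)
      resp <- sort(pop$truth$unit_id[pop$truth$responsive])
      spk <- dplyr::filter(pop$spikes, unit_id %in% resp)
      attr(spk, "span") <- attr(pop$spikes, "span")
      pats <- make_labelled_patterns(spk, sched, units = resp, seed = 304)
      model <- calibrate_rest(fit_mda(pats, lambda = 0.5), spk, sched, seed = 305)
      env$fx <- list(cfg = cfg, sched = sched, pop = pop, spk = spk,
                     model = model,
                     excl = tibble::tibble(start = sched$onset - 1,
                                           end = sched$onset + 3))
    }
    env$fx
  }
})

test_that("sliding projection validates units, span and step geometry", {
  fx <- traj_fixture()
  alien <- dplyr::bind_rows(fx$spk, tibble::tibble(unit_id = "zzz", time = 1))
  expect_error(sliding_projection(alien, fx$model), class = "reverb_unit_mismatch")
  expect_error(sliding_projection(fx$spk, fx$model, t_start = 0, t_end = 0.5),
               class = "reverb_bad_input")
  expect_error(sliding_projection(fx$spk, fx$model, step = 0.03),
               class = "reverb_bad_input")
})

test_that("trajectory timestamps advance uniformly and match the model dimension", {
  fx <- traj_fixture()
  tr <- sliding_projection(fx$spk, fx$model, t_start = 0, t_end = 30)
  expect_equal(unique(round(diff(tr$time), 10)), 0.01)
  expect_equal(sum(grepl("^lda_", names(tr))), fx$model$d)
})

test_that("trajectory values have no look-ahead beyond the window", {
  fx <- traj_fixture()
  tr <- sliding_projection(fx$spk, fx$model, t_start = 10, t_end = 20)
  # removing all spikes after t + window leaves the value at t unchanged
  cut <- dplyr::filter(fx$spk, time < 14)
  attr(cut, "span") <- attr(fx$spk, "span")
  tr2 <- sliding_projection(cut, fx$model, t_start = 10, t_end = 20)
  i <- which(abs(tr$time - 12.9) < 1e-9)
  expect_equal(unlist(tr[i, paste0("lda_", 1:fx$model$d)]),
               unlist(tr2[i, paste0("lda_", 1:fx$model$d)]))
})

test_that("stationary baseline activity stays inside the rest boundary", {
  fx <- traj_fixture()
  # scan a quiet stretch before the first event
  tr <- sliding_projection(fx$spk, fx$model, t_start = 0,
                           t_end = min(fx$sched$onset) - 1)
  expect_gte(mean(tr$rest_score < 2), 0.95)
})

test_that("an event epoch leaves the rest cluster toward its own class and returns", {
  fx <- traj_fixture()
  on <- fx$sched$onset[fx$sched$event == "drop" & fx$sched$level == 3][3]
  tr <- sliding_projection(fx$spk, fx$model, t_start = on - 5, t_end = on + 6)
  during <- tr[tr$time > on - 0.5 & tr$time < on + 0.5, ]
  after <- tr[tr$time > on + 3, ]
  expect_gt(max(during$rest_score), 4)
  expect_lt(median(after$rest_score), 2)
  # at the excursion peak the matching class is the nearest non-rest cluster
  pk <- during[which.max(during$rest_score), ]
  z <- unlist(pk[paste0("lda_", 1:fx$model$d)], use.names = FALSE)
  dists <- vapply(setdiff(fx$model$classes, "rest"), function(cl) {
    sqrt(stats::mahalanobis(matrix(z, 1), fx$model$class_means[cl, ],
                            fx$model$class_cov[[cl]]))
  }, numeric(1))
  expect_equal(names(which.min(dists)), "drop_3")
})

test_that("detection respects threshold monotonicity and the exclusion mask", {
  fx <- traj_fixture()
  tr <- sliding_projection(fx$spk, fx$model)
  expect_equal(nrow(detect_reactivations(tr, fx$model, theta = Inf)), 0)
  counts <- vapply(c(2, 2.5, 3, 4), function(th) {
    nrow(detect_reactivations(tr, fx$model, theta = th, exclude = fx$excl))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # without the exclusion mask the (strong) event epochs are detected too
  n_excl <- nrow(detect_reactivations(tr, fx$model, theta = 2, exclude = fx$excl))
  n_all <- nrow(detect_reactivations(tr, fx$model, theta = 2))
  expect_gt(n_all, n_excl)
})

test_that("detected reactivations overlap injected ones", {
  fx <- traj_fixture()
  tr <- sliding_projection(fx$spk, fx$model)
  det <- detect_reactivations(tr, fx$model, theta = 2, exclude = fx$excl)
  inj <- fx$pop$injections
  hits <- vapply(inj$time, function(t) {
    any(det$time >= t - 1 & det$time <= t + 2)
  }, logical(1))
  expect_gt(mean(hits), 0.5)
  expect_true(all(det$target != "rest"))
  expect_true(all(det$peak_score >= 2))
})

test_that("subpopulation projections are isolated and size-guarded", {
  fx <- traj_fixture()
  short <- function(sub) subpopulation_projection(
    fx$pop$spikes, fx$sched, fx$pop$truth, sub,
    seed = 306, t_start = 0, t_end = 100)
  inv <- short("invariant")
  sen <- short("sensitive")
  expect_equal(inv$model$units, sort(intersect(
    fx$pop$truth$unit_id[fx$pop$truth$intensity_class == "invariant"],
    fx$pop$truth$unit_id[fx$pop$truth$responsive])))
  # removing a sensitive unit leaves the invariant trajectory unchanged
  drop_one <- dplyr::filter(fx$pop$spikes, unit_id != sen$units[1])
  attr(drop_one, "span") <- attr(fx$pop$spikes, "span")
  inv2 <- subpopulation_projection(drop_one, fx$sched, fx$pop$truth, "invariant",
                                   seed = 306, t_start = 0, t_end = 100)
  expect_equal(inv2$trajectory$rest_distance, inv$trajectory$rest_distance)
  # too few units -> error
  few <- fx$pop$truth[1:12, ]
  few$responsive <- c(rep(TRUE, 3), rep(FALSE, 9))
  expect_error(subpopulation_projection(fx$pop$spikes, fx$sched, few, "all"),
               class = "reverb_bad_input")
})

test_that("projection is affine in the rate input", {
  fx <- traj_fixture()
  m <- fx$model
  p <- length(m$feature_names)
  set.seed(67)
  a <- matrix(runif(3 * p, 0, 10), 3)
  b <- matrix(runif(3 * p, 0, 10), 3)
  zero <- matrix(0, 3, p)
  # z(a + b) - z(a) - z(b) + z(0) = 0 for an affine map
  resid <- project_patterns(m, a + b) - project_patterns(m, a) -
    project_patterns(m, b) + project_patterns(m, zero)
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("magnitude statistics compare matched window peaks", {
  fx <- traj_fixture()
  tr <- sliding_projection(fx$spk, fx$model)
  # null construction: random windows behave like their matched baselines
  set.seed(60)
  quiet <- tibble::tibble(start = runif(20, 5, 45))
  quiet$end <- quiet$start + 2
  pk <- peak_in_windows(tr, quiet)
  ms0 <- reactivation_magnitude_stats(pk, tr, exclude = fx$excl, seed = 61)
  expect_gt(ms0$test$p_value, 0.05)
  # injected windows score significantly above matched baselines
  w <- tibble::tibble(start = fx$pop$injections$time - 0.5,
                      end = fx$pop$injections$time + 1.5)
  pki <- peak_in_windows(tr, w)
  ms1 <- reactivation_magnitude_stats(pki, tr, exclude = fx$excl, seed = 62)
  expect_lt(ms1$test$p_value, 0.05)
  expect_gt(ms1$test$mean_peak, ms1$test$mean_baseline)
})
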