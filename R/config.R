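#' Configuration for the synthetic ensemble generator
#'
#' Builds the parameter set that drives [build_schedule()],
#' [generate_population()] and [inject_reactivations()]. Defaults reproduce the
#' population structure the downstream analyses assume: four startling event
#' types (acoustic sound, air-blow, elevator drop, cage shake), seven
#' repetitions per (type, intensity) session at randomized 1--3 minute
#' intervals, roughly 36% responsive units split 1:1 between intensity-invariant
#' and intensity-sensitive cells, selectivity fractions of 54/26/20%
#' (invariant) and 45/25/30% (sensitive) across the general / subgeneral /
#' specific categories, and post-event reduced-amplitude reactivations carried
#' predominantly by the invariant subpopulation with co-participation strength
#' ordered general > subgeneral > specific.
#'
#' @param n_units Number of units in the population.
#' @param p_responsive Fraction of units responsive to at least one event type.
#' @param p_invariant Fraction of responsive units that are intensity-invariant
#'   (the remainder are intensity-sensitive).
#' @param invariant_split,sensitive_split Named fractions (general, subgeneral,
#'   specific) partitioning each intensity class across selectivity categories.
#' @param p_sensitive_down Fraction of sensitive units whose rate decreases
#'   (rather than increases) monotonically with intensity.
#' @param p_pyramidal Fraction of putative pyramidal cells; the rest are
#'   putative interneurons.
#' @param baseline_pyramidal,baseline_interneuron Uniform baseline firing-rate
#'   ranges (Hz) per unit class.
#' @param gain_invariant_hz Additive event-window rate gain (Hz) of invariant
#'   units, identical across intensity levels.
#' @param gain_sensitive_hz Length-3 additive gains (Hz) of sensitive-up units
#'   at intensity levels 1..3 (strictly increasing).
#' @param down_multiplier Length-3 multiplicative event-window rate factors for
#'   sensitive-down units at levels 1..3 (strictly decreasing).
#' @param event_window_s Duration (s) of the elevated-rate window after each
#'   event onset.
#' @param trial_coupling Named per-selectivity-group log-normal sd of the
#'   shared per-trial response-gain jitter; this is the knob that creates
#'   event-period pairwise correlations within a group.
#' @param event_types Named list mapping event type to its intensity levels.
#' @param level_meta Named list of physical intensity labels per type (metadata
#'   carried on the schedule; drop heights 5/13/30 cm, air-blow durations
#'   200/400/800 ms).
#' @param n_repetitions Events per (type, level) session.
#' @param iti_s Length-2 inter-trial interval bounds (s), randomized uniformly.
#' @param baseline_s Quiet span (s) before the first event of the recording.
#' @param tail_s Quiet span (s) appended after the final event window.
#' @param react_per_event Length-2 integer bounds on the number of injected
#'   reactivations per event.
#' @param react_window_s Length-2 bounds (s after the source event) within
#'   which injected reactivation times are drawn uniformly.
#' @param react_amplitude Reactivation amplitude as a fraction of the event
#'   response gain, in (0, 1].
#' @param react_duration_s Duration (s) of each injected reactivation.
#' @param react_gate_prob Named per-group Bernoulli probability that the whole
#'   selectivity group participates in a given injection (shared gating),
#'   ordered general > subgeneral > specific.
#' @param react_weight Named per-group multiplicative participation weight on
#'   the reactivated gain, ordered general > subgeneral > specific.
#' @param react_sensitive_prob Per-unit participation probability for
#'   intensity-sensitive units (near zero: reactivation is carried by the
#'   invariant subpopulation).
#'
#' @return A list of class `"simulation_config"`.
#' @export
#' @examples
#' cfg <- simulation_config(n_units = 50)
#' sched <- build_schedule(cfg, seed = 1)
simulation_config <- function(n_units = 200,
                              p_responsive = 0.36,
                              p_invariant = 0.5,
                              invariant_split = c(general = 0.54, subgeneral = 0.26, specific = 0.20),
                              sensitive_split = c(general = 0.45, subgeneral = 0.25, specific = 0.30),
                              p_sensitive_down = 0.2,
                              p_pyramidal = 0.85,
                              baseline_pyramidal = c(0.2, 3),
                              baseline_interneuron = c(8, 30),
                              gain_invariant_hz = 8,
                              gain_sensitive_hz = c(4, 8, 16),
                              down_multiplier = c(0.5, 0.25, 0.05),
                              event_window_s = 1,
                              trial_coupling = c(general = 0.35, subgeneral = 0.25, specific = 0.15),
                              event_types = list(sound = 1L, air = 1:3, drop = 1:3, shake = 1L),
                              level_meta = list(drop = c("5cm", "13cm", "30cm"),
                                                air = c("200ms", "400ms", "800ms")),
                              n_repetitions = 7,
                              iti_s = c(60, 180),
                              baseline_s = 120,
                              tail_s = 180,
                              react_per_event = c(1, 3),
                              react_window_s = c(5, 120),
                              react_amplitude = 0.4,
                              react_duration_s = 1,
                              react_gate_prob = c(general = 0.9, subgeneral = 0.65, specific = 0.45),
                              react_weight = c(general = 1, subgeneral = 0.7, specific = 0.45),
                              react_sensitive_prob = 0.02) {
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  bad <- function(msg) abort(msg, class = "reverb_invalid_config")
  if (cfg$n_units < 1) bad("`n_units` must be at least 1.")
  fr <- c(cfg$p_responsive, cfg$p_invariant, cfg$p_sensitive_down, cfg$p_pyramidal,
          cfg$react_sensitive_prob, cfg$react_gate_prob)
  if (any(fr < 0 | fr > 1)) bad("All probabilities/fractions must lie in [0, 1].")
  for (nm in c("invariant_split", "sensitive_split")) {
    sp <- cfg[[nm]]
    if (!setequal(names(sp), c("general", "subgeneral", "specific")) ||
        any(sp < 0) || abs(sum(sp) - 1) > 1e-8) {
      bad(sprintf("`%s` must be named general/subgeneral/specific fractions summing to 1.", nm))
    }
  }
  if (cfg$iti_s[1] > cfg$iti_s[2]) bad("Inter-trial interval bounds are inverted.")
  if (any(cfg$iti_s <= 0)) bad("Inter-trial intervals must be positive.")
  if (any(cfg$baseline_pyramidal < 0) || any(cfg$baseline_interneuron < 0)) {
    bad("Baseline rate ranges must be non-negative.")
  }
  if (diff(cfg$react_window_s) < 0 || any(cfg$react_window_s < 0)) {
    bad("`react_window_s` bounds are invalid.")
  }
  if (cfg$react_amplitude < 0 || cfg$react_amplitude > 1) {
    bad("`react_amplitude` must lie in [0, 1].")
  }
  if (length(cfg$gain_sensitive_hz) != 3 || any(diff(cfg$gain_sensitive_hz) <= 0)) {
    bad("`gain_sensitive_hz` must be 3 strictly increasing gains.")
  }
  if (length(cfg$down_multiplier) != 3 || any(diff(cfg$down_multiplier) >= 0)) {
    bad("`down_multiplier` must be 3 strictly decreasing factors.")
  }
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat("  units:", x$n_units,
      sprintf("(%.0f%% responsive, invariant:sensitive %.2f)", 100 * x$p_responsive,
              x$p_invariant / max(1 - x$p_invariant, 1e-12)), "\n")
  cat("  sessions:", paste(vapply(names(x$event_types), function(t) {
    sprintf("%s x%d", t, length(x$event_types[[t]]))
  }, character(1)), collapse = ", "), "\n")
  cat("  repetitions:", x$n_repetitions, " ITI:", paste(x$iti_s, collapse = "-"), "s\n")
  invisible(x)
}
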