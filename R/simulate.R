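#' Task design for simulated rivalry sessions
#'
#' Describes the trial stream of a session: how many non-mock (rivalry) trials
#' to run before terminating, the per-slot probability of inserting a mock
#' display, and whether the imagery cues are balanced. Defaults mirror the
#' standard administration: 32 rivalry trials, 12.5% mock displays, balanced
#' cue schedule. Because the session terminates on the 32nd rivalry trial
#' while mocks are inserted stochastically, the realised mock count varies
#' around 4-5.
#'
#' @param n_nonmock Number of rivalry trials per session (>= 2, default 32).
#' @param mock_rate Per-slot probability of a mock display (default 0.125).
#' @param cue_balance If `TRUE` (default) the cue sequence is a shuffled
#'   exactly-balanced multiset of R and B (counts differing by at most 1 when
#'   `n_nonmock` is odd); otherwise cues are i.i.d. fair draws.
#' @return A list of class `design_spec`.
#' @export
design_spec <- function(n_nonmock = 32, mock_rate = 0.125, cue_balance = TRUE) {
  stopifnot(is_scalar_number(n_nonmock), n_nonmock >= 2,
            is_scalar_number(mock_rate), mock_rate >= 0, mock_rate < 1,
            is.logical(cue_balance), length(cue_balance) == 1)
  structure(list(n_nonmock = as.integer(n_nonmock), mock_rate = mock_rate,
                 cue_balance = cue_balance),
            class = "design_spec")
}

#' Latent response phenotype of a simulated observer
#'
#' Parameterises the generative response model of one observer. `v` is latent
#' imagery strength on `[0, 1]` (0: no imagery, as hypothesised in aphantasia;
#' 1: maximally vivid). On each rivalry trial the observer reports a mixed
#' percept with probability `mixed_base * (1 - v * mixed_damping)`; otherwise
#' the reported colour is drawn from a logistic model in which the imagery cue
#' pushes with weight `priming_gain * v` and the previous non-mixed percept
#' pushes with weight `stability_weight * (1 - v)` -- weak imagers are
#' stability-dominant, strong imagers priming-dominant, the two biases the
#' task is designed to separate. Mock trials are answered with the displayed
#' colour, flipped with probability `mock_error_rate`.
#'
#' @param v Imagery strength in `[0, 1]`.
#' @param mixed_base Baseline mixed-percept probability in `[0, 1)`.
#' @param priming_gain Log-odds weight of the imagery cue (>= 0, default 0.5,
#'   which puts a typical imager's cue-consistent response probability in the
#'   mid-50s percent range reported for this paradigm).
#' @param stability_weight Log-odds weight of the previous percept (>= 0,
#'   default 2.0, putting stability-dominant observers' repeat probability in
#'   the low-80s percent range reported for this paradigm).
#' @param mock_error_rate Probability of answering a mock trial with the wrong
#'   colour (default 0).
#' @param mixed_damping Fraction by which full-strength imagery reduces the
#'   mixed-percept probability (default 0: mixed rate independent of imagery).
#' @return A list of class `phenotype`.
#' @export
phenotype <- function(v, mixed_base = 0.2, priming_gain = 0.5,
                      stability_weight = 2.0, mock_error_rate = 0,
                      mixed_damping = 0) {
  stopifnot(is_scalar_number(v), v >= 0, v <= 1,
            is_scalar_number(mixed_base), mixed_base >= 0, mixed_base < 1,
            is_scalar_number(priming_gain), priming_gain >= 0,
            is_scalar_number(stability_weight), stability_weight >= 0,
            is_scalar_number(mock_error_rate), mock_error_rate >= 0, mock_error_rate <= 1,
            is_scalar_number(mixed_damping), mixed_damping >= 0, mixed_damping <= 1)
  structure(list(v = v, mixed_base = mixed_base, priming_gain = priming_gain,
                 stability_weight = stability_weight,
                 mock_error_rate = mock_error_rate, mixed_damping = mixed_damping),
            class = "phenotype")
}

#' Simulate one rivalry session
#'
#' Generates the trial stream of a single observer under a [phenotype()] and
#' [design_spec()]. Each slot is a mock display with probability `mock_rate`,
#' otherwise the next rivalry trial; the stream stops when `n_nonmock` rivalry
#' trials have been completed. Identical seeds give identical sessions.
#'
#' @param phen A [phenotype()].
#' @param design A [design_spec()].
#' @param seed Integer seed; the session is a pure function of
#'   `(phen, design, seed)`.
#' @param participant_id Identifier used in the output table.
#' @return A trial tibble in the [read_sessions()] schema.
#' @export
#' @examples
#' simulate_session(phenotype(v = 0.8), design_spec(), seed = 42)
simulate_session <- function(phen, design = design_spec(), seed,
                             participant_id = "sim_1") {
  stopifnot(inherits(phen, "phenotype"), inherits(design, "design_spec"))
  withr::with_seed(as.integer(seed), {
    n <- design$n_nonmock
    cues <- if (design$cue_balance) {
      sample(c(rep("R", ceiling(n / 2)), rep("B", floor(n / 2))))
    } else {
      sample(CUES, n, replace = TRUE)
    }
    p_mixed <- phen$mixed_base * (1 - phen$v * phen$mixed_damping)
    trial_type <- character(0)
    cue <- character(0)
    response <- character(0)
    n_riv <- 0L
    x_prev <- 0 # previous non-mixed rivalry percept: +1 red, -1 blue, 0 none
    while (n_riv < n) {
      if (runif(1) < design$mock_rate) {
        shown <- sample(c("red", "blue"), 1)
        resp <- if (runif(1) < phen$mock_error_rate) setdiff(c("red", "blue"), shown) else shown
        trial_type <- c(trial_type, paste0("mock_", shown))
        cue <- c(cue, sample(CUES, 1))
        response <- c(response, resp)
      } else {
        n_riv <- n_riv + 1L
        this_cue <- cues[n_riv]
        if (runif(1) < p_mixed) {
          resp <- "mixed"
        } else {
          x_cue <- if (this_cue == "R") 1 else -1
          eta <- phen$priming_gain * phen$v * x_cue +
            phen$stability_weight * (1 - phen$v) * x_prev
          resp <- if (runif(1) < plogis(eta)) "red" else "blue"
          x_prev <- if (resp == "red") 1 else -1
        }
        trial_type <- c(trial_type, "rivalry")
        cue <- c(cue, this_cue)
        response <- c(response, resp)
      }
    }
    tibble::tibble(
      participant_id = participant_id,
      trial_index = seq_along(trial_type),
      trial_type = trial_type,
      cue = cue,
      response = response
    )
  })
}

#' Cohort composition for simulated studies
#'
#' Describes a two-group cohort: observers with aphantasia (low latent imagery
#' strength, questionnaire scores concentrated at or below the conventional
#' VVIQ cutoff of 32) and controls. Latent imagery strength `v` is drawn per
#' group from a Beta distribution; the baseline mixed-percept probability is
#' drawn from a shared Beta unless fixed via `mixed_base`. The reported VVIQ
#' is emitted as `round(16 + 64 * clamp(v + noise, 0, 1))` with Gaussian noise
#' on the unit scale, producing the characteristic bimodal VVIQ histogram of
#' targeted aphantasia samples.
#'
#' @param n_aphantasic,n_control Group sizes (defaults 38 and 73, a typical
#'   targeted-recruitment cohort).
#' @param v_shape_aphantasic,v_shape_control Beta shape pairs for latent
#'   imagery strength per group.
#' @param mixed_base Fixed baseline mixed-percept probability for every
#'   observer, or `NULL` (default) to draw per observer from
#'   `mixed_base_shape`.
#' @param mixed_base_shape Beta shape pair for the per-observer mixed-percept
#'   baseline (default mean about 0.21, matching typical observed mixed
#'   proportions).
#' @param priming_gain,stability_weight,mock_error_rate,mixed_damping Shared
#'   [phenotype()] parameters.
#' @param vviq_noise_sd SD of the VVIQ emission noise on the unit scale
#'   (default 0.12, about 8 questionnaire points; covers both report noise and
#'   genuine self-report/behaviour dissociation, so that simulated score-VVIQ
#'   correlations land near the moderate values this paradigm produces rather
#'   than at the latent-trait ceiling).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_aphantasic = 38, n_control = 73,
                        v_shape_aphantasic = c(2, 13),
                        v_shape_control = c(6, 3),
                        mixed_base = NULL,
                        mixed_base_shape = c(1.5, 5.5),
                        priming_gain = 0.5, stability_weight = 2.0,
                        mock_error_rate = 0, mixed_damping = 0,
                        vviq_noise_sd = 0.12) {
  stopifnot(is_scalar_number(n_aphantasic), n_aphantasic >= 0,
            is_scalar_number(n_control), n_control >= 0,
            length(v_shape_aphantasic) == 2, all(v_shape_aphantasic > 0),
            length(v_shape_control) == 2, all(v_shape_control > 0),
            is.null(mixed_base) ||
              (is_scalar_number(mixed_base) && mixed_base >= 0 && mixed_base < 1),
            length(mixed_base_shape) == 2, all(mixed_base_shape > 0),
            is_scalar_number(vviq_noise_sd), vviq_noise_sd >= 0)
  structure(list(n_aphantasic = as.integer(n_aphantasic),
                 n_control = as.integer(n_control),
                 v_shape_aphantasic = v_shape_aphantasic,
                 v_shape_control = v_shape_control,
                 mixed_base = mixed_base, mixed_base_shape = mixed_base_shape,
                 priming_gain = priming_gain, stability_weight = stability_weight,
                 mock_error_rate = mock_error_rate, mixed_damping = mixed_damping,
                 vviq_noise_sd = vviq_noise_sd),
            class = "cohort_spec")
}

#' Simulate a full cohort of rivalry sessions
#'
#' Draws per-observer phenotypes from a [cohort_spec()], simulates one session
#' per observer under the [design_spec()], and emits the observed VVIQ. A
#' single master seed drives everything; per-session streams are derived
#' deterministically from it, so a given `(spec, design, seed)` always yields
#' the same cohort.
#'
#' @param spec A [cohort_spec()].
#' @param design A [design_spec()].
#' @param seed Integer master seed.
#' @return A list with two tibbles: `trials` (all sessions, trial-log schema)
#'   and `participants` (ground truth per observer: `participant_id`, `group`,
#'   `v`, `mixed_base`, `vviq`).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_aphantasic = 5, n_control = 5), seed = 1)
#' dplyr::count(cohort$participants, group)
simulate_cohort <- function(spec = cohort_spec(), design = design_spec(), seed) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(design, "design_spec"))
  n_total <- spec$n_aphantasic + spec$n_control
  stopifnot(n_total > 0)
  truth <- withr::with_seed(as.integer(seed), {
    group <- c(rep("aphantasic", spec$n_aphantasic), rep("control", spec$n_control))
    v <- c(rbeta(spec$n_aphantasic, spec$v_shape_aphantasic[1], spec$v_shape_aphantasic[2]),
           rbeta(spec$n_control, spec$v_shape_control[1], spec$v_shape_control[2]))
    mb <- if (is.null(spec$mixed_base)) {
      rbeta(n_total, spec$mixed_base_shape[1], spec$mixed_base_shape[2])
    } else {
      rep(spec$mixed_base, n_total)
    }
    # cap the draw just under 1 so a phenotype is always constructible
    mb <- pmin(mb, 0.999)
    vviq <- as.integer(round(16 + 64 * clamp01(v + rnorm(n_total, 0, spec$vviq_noise_sd))))
    session_seed <- sample.int(.Machine$integer.max - 1L, n_total)
    tibble::tibble(
      participant_id = sprintf("sim_%03d", seq_len(n_total)),
      group = group, v = v, mixed_base = mb, vviq = vviq,
      session_seed = session_seed
    )
  })
  trials <- purrr::pmap(
    truth[, c("participant_id", "v", "mixed_base", "session_seed")],
    function(participant_id, v, mixed_base, session_seed) {
      simulate_session(
        phenotype(v = v, mixed_base = mixed_base,
                  priming_gain = spec$priming_gain,
                  stability_weight = spec$stability_weight,
                  mock_error_rate = spec$mock_error_rate,
                  mixed_damping = spec$mixed_damping),
        design = design, seed = session_seed, participant_id = participant_id
      )
    }
  ) |>
    purrr::list_rbind()
  list(trials = trials,
       participants = truth[, c("participant_id", "group", "v", "mixed_base", "vviq")])
}
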