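# Synthetic adaptation/test experiments.
#
# Generates the adaptor timelines, enumerates the factorial test designs,
# and simulates two-criterion observers, so the full analysis pipeline can
# run without any external data. Stimulus vocabulary: tones at 1000 Hz
# (low) or 4000 Hz (high); circles 3 degrees above (+3) or below (-3)
# fixation; every stimulus lasts 20 ms. "Congruent" means high tone with
# upper circle or low tone with lower circle.

ADAPT_CONDITIONS <- c("visual_leading", "auditory_leading")

# Four-stimulus adaptor patterns. Within each congruent tone/circle pairing
# the visual stimulus leads in visual_leading and the auditory stimulus
# leads in auditory_leading; stimuli are equally spaced so temporal
# proximity itself offers no grouping cue.
.adapt_pattern <- function(condition) {
  switch(condition,
    visual_leading = data.frame(
      modality  = c("auditory", "visual", "auditory", "visual"),
      pitch     = c(4000, NA, 1000, NA),
      elevation = c(NA, -3, NA, 3)),
    auditory_leading = data.frame(
      modality  = c("auditory", "visual", "auditory", "visual"),
      pitch     = c(4000, NA, 1000, NA),
      elevation = c(NA, 3, NA, -3)),
    stop(sprintf("unknown adaptation condition '%s'", condition),
         call. = FALSE))
}

is_congruent_pairing <- function(pitch, elevation) {
  (pitch == 4000 & elevation > 0) | (pitch == 1000 & elevation < 0)
}

#' Build an adaptor stimulus sequence
#'
#' Events start at 0 ms and follow at exactly 200 ms spacing, cycling the
#' condition's four-stimulus pattern for `floor(duration_ms / 200)` events
#' (a fractional final pattern is allowed: the 5 s top-up holds 6.25
#' pattern repetitions). Each event lasts 20 ms.
#'
#' @param condition `"visual_leading"` or `"auditory_leading"`.
#' @param phase `"initial"` (default 60 s) or `"top_up"` (default 5 s).
#' @param duration_ms Sequence duration in ms; overrides the phase default.
#' @return A data frame of class `adaptation_sequence` with columns
#'   `onset`, `modality`, `pitch`, `elevation`, `duration`, and attributes
#'   `condition`, `phase`, `n_patterns`.
#' @export
#' @examples
#' topup <- build_adaptation_sequence("visual_leading", "top_up")
#' nrow(topup)                  # 25 events
#' attr(topup, "n_patterns")    # 6.25
build_adaptation_sequence <- function(condition = ADAPT_CONDITIONS,
                                      phase = c("initial", "top_up"),
                                      duration_ms = NULL) {
  condition <- match.arg(condition)
  phase <- match.arg(phase)
  if (is.null(duration_ms))
    duration_ms <- if (phase == "initial") 60000 else 5000
  if (!is.numeric(duration_ms) || duration_ms <= 0)
    stop("duration_ms must be positive", call. = FALSE)
  n_events <- floor(duration_ms / 200)
  if (n_events < 1L) stop("duration too short for any event", call. = FALSE)
  pattern <- .adapt_pattern(condition)
  idx <- rep_len(seq_len(4L), n_events)
  seq_df <- data.frame(
    onset = 200 * (seq_len(n_events) - 1),
    modality = pattern$modality[idx],
    pitch = pattern$pitch[idx],
    elevation = pattern$elevation[idx],
    duration = 20)
  structure(seq_df,
            class = c("adaptation_sequence", "data.frame"),
            condition = condition, phase = phase,
            n_patterns = n_events / 4)
}

#' Congruency-implied audiovisual pairs in an adaptor sequence
#'
#' Pairs each stimulus with its congruent cross-modal partner 200 ms later:
#' the grouping the pitch-elevation correspondence implies. In the
#' visual-leading sequence every pair's leader is visual; in the
#' auditory-leading sequence it is auditory; all intra-pair lags are 200 ms.
#'
#' @param seq An [build_adaptation_sequence()] result.
#' @return A data frame with one row per pair: `leader`, `audio_onset`,
#'   `visual_onset`, `lag_ms`, `pitch`, `elevation`.
#' @export
congruent_pairs <- function(seq) {
  if (!inherits(seq, "adaptation_sequence"))
    stop("seq must be an adaptation_sequence", call. = FALSE)
  if (nrow(seq) < 2L)
    return(data.frame(leader = character(0), audio_onset = numeric(0),
                      visual_onset = numeric(0), lag_ms = numeric(0),
                      pitch = numeric(0), elevation = numeric(0)))
  i <- seq_len(nrow(seq) - 1L)
  a <- seq[i, , drop = FALSE]
  b <- seq[i + 1L, , drop = FALSE]
  pitch <- ifelse(a$modality == "auditory", a$pitch, b$pitch)
  elev <- ifelse(a$modality == "visual", a$elevation, b$elevation)
  keep <- a$modality != b$modality & is_congruent_pairing(pitch, elev)
  data.frame(
    leader = a$modality[keep],
    audio_onset = ifelse(a$modality == "auditory", a$onset, b$onset)[keep],
    visual_onset = ifelse(a$modality == "visual", a$onset, b$onset)[keep],
    lag_ms = (b$onset - a$onset)[keep],
    pitch = pitch[keep],
    elevation = elev[keep])
}

#' Factorial test-phase design
#'
#' The two designs supported: design 1 uses an 11-level SOA grid from -350
#' to 350 ms and the two congruent test pairings over 8 blocks of 55
#' trials (440 trials); design 2 widens the grid to -400..400 ms, crosses
#' in the two incongruent pairings, and doubles the blocks (880 trials).
#' Negative SOA means auditory first.
#'
#' @param experiment 1 or 2.
#' @return A list of class `experiment_design`: `experiment`, `soa_grid`,
#'   `pair_types`, `conditions`, `occasions`, `blocks`, `trials_per_block`.
#' @export
experiment_design <- function(experiment = 1) {
  experiment <- as.integer(experiment)
  if (!experiment %in% c(1L, 2L))
    stop("experiment must be 1 or 2", call. = FALSE)
  if (experiment == 1L) {
    soa_grid <- c(-350, -250, -150, -100, -50, 0, 50, 100, 150, 250, 350)
    pair_types <- c("high_tone_upper", "low_tone_lower")
    blocks <- 8L
  } else {
    soa_grid <- c(-400, -320, -240, -160, -80, 0, 80, 160, 240, 320, 400)
    pair_types <- c("high_tone_upper", "low_tone_lower",
                    "high_tone_lower", "low_tone_upper")
    blocks <- 16L
  }
  design <- structure(
    list(experiment = experiment, soa_grid = soa_grid,
         pair_types = pair_types, conditions = ADAPT_CONDITIONS,
         occasions = 10L, blocks = blocks, trials_per_block = 55L),
    class = "experiment_design")
  total <- length(soa_grid) * length(pair_types) * 2L * design$occasions
  if (total != blocks * design$trials_per_block)
    stop("factorial total does not match blocks x trials_per_block",
         call. = FALSE)
  design
}

#' Congruency class of a test pairing
#'
#' @param pair_type Character vector of pair-type labels.
#' @return `"congruent"` or `"incongruent"` per element.
#' @export
pair_congruency <- function(pair_type) {
  known <- c(high_tone_upper = "congruent", low_tone_lower = "congruent",
             high_tone_lower = "incongruent", low_tone_upper = "incongruent")
  bad <- setdiff(unique(pair_type), names(known))
  if (length(bad))
    stop(sprintf("unknown pair_type '%s'", bad[1L]), call. = FALSE)
  unname(known[pair_type])
}

#' Enumerate test trials for one participant
#'
#' Full factorial crossing of SOA x pair type x adaptation condition x
#' occasion, laid out in blocks of 55 trials with randomized within-block
#' trial order. Design 1 alternates the adaptation condition every two
#' blocks and dedicates each block to one test pairing; design 2
#' alternates every four blocks and randomizes SOA and pairing jointly
#' within block. The starting condition is counterbalanced by participant
#' parity unless given.
#'
#' @param design An [experiment_design()].
#' @param participant Participant id (integer; drives counterbalancing).
#' @param start_condition Optional starting adaptation condition.
#' @param seed Integer seed for the within-block trial order.
#' @return A data frame with columns `participant`, `block`, `condition`,
#'   `pair_type`, `congruency`, `soa`, `occasion` (one row per trial; no
#'   responses yet).
#' @export
enumerate_trials <- function(design, participant = 1L,
                             start_condition = NULL, seed = 1L) {
  if (!inherits(design, "experiment_design"))
    stop("design must be an experiment_design", call. = FALSE)
  participant <- as.integer(participant)
  if (is.null(start_condition))
    start_condition <- design$conditions[(participant + 1L) %% 2L + 1L]
  start_condition <- match.arg(start_condition, design$conditions)
  other <- setdiff(design$conditions, start_condition)
  set.seed(seed)
  run_len <- if (design$experiment == 1L) 2L else 4L
  block_condition <- rep(rep(c(start_condition, other), each = run_len),
                         length.out = design$blocks)
  trials <- vector("list", design$blocks)
  if (design$experiment == 1L) {
    # one pairing per block; the two blocks sharing a (condition, pairing)
    # cell carry occasions 1-5 and 6-10
    for (cond in design$conditions) {
      cond_blocks <- which(block_condition == cond)
      pair_for_block <- rep_len(design$pair_types, length(cond_blocks))
      if (participant %% 2L == 0L) pair_for_block <- rev(pair_for_block)
      seen <- setNames(integer(length(design$pair_types)), design$pair_types)
      for (j in seq_along(cond_blocks)) {
        b <- cond_blocks[j]
        pt <- pair_for_block[j]
        occ <- seen[pt] * 5L + 1:5
        seen[pt] <- seen[pt] + 1L
        grid <- expand.grid(soa = design$soa_grid, occasion = occ,
                            KEEP.OUT.ATTRS = FALSE)
        grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
        trials[[b]] <- data.frame(
          participant = participant, block = b, condition = cond,
          pair_type = pt, congruency = pair_congruency(pt),
          soa = grid$soa, occasion = grid$occasion)
      }
    }
  } else {
    # pairings randomized within block: shuffle each condition's full
    # factorial and cut it into that condition's blocks
    for (cond in design$conditions) {
      cond_blocks <- which(block_condition == cond)
      grid <- expand.grid(soa = design$soa_grid, pair_type = design$pair_types,
                          occasion = seq_len(design$occasions),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
      split_idx <- rep(cond_blocks, each = design$trials_per_block)
      for (j in seq_along(cond_blocks)) {
        b <- cond_blocks[j]
        part <- grid[split_idx == b, , drop = FALSE]
        trials[[b]] <- data.frame(
          participant = participant, block = b, condition = cond,
          pair_type = part$pair_type,
          congruency = pair_congruency(part$pair_type),
          soa = part$soa, occasion = part$occasion)
      }
    }
  }
  out <- do.call(rbind, trials)
  rownames(out) <- NULL
  out
}

#' Construct a simulated observer
#'
#' A simulated observer carries one two-criterion parameter set per
#' (adaptation condition, congruency class). Adaptation is modelled as an
#' additive PSS shift applied equally to both criteria (the window is
#' preserved), split between the two conditions: the visual-leading
#' condition gets `+pss_shift * shift_split`, the auditory-leading
#' condition `-pss_shift * (1 - shift_split)`, so the condition difference
#' is always `pss_shift`. The shift applies only to the congruency classes
#' named in `shifted_congruency`; whether real adaptation moves one or
#' both conditions is unknown, hence the exposed split.
#'
#' @param base [criterion_params()] of the unadapted observer.
#' @param pss_shift Condition difference in PSS (ms) injected by
#'   adaptation (default 13.5).
#' @param shift_split Fraction of the shift assigned to the
#'   visual-leading condition (default 0.5).
#' @param shifted_congruency Congruency classes receiving the shift
#'   (default `"congruent"`).
#' @param id Participant id attached to simulated trials.
#' @return An object of class `sim_observer`.
#' @export
sim_observer <- function(base = criterion_params(-213, 237, 90, 90),
                         pss_shift = 13.5, shift_split = 0.5,
                         shifted_congruency = "congruent", id = 1L) {
  stopifnot(inherits(base, "criterion_params"),
            is.numeric(pss_shift), shift_split >= 0, shift_split <= 1)
  shift_by <- function(p, d)
    criterion_params(p$c_low + d, p$c_high + d, p$sigma_low, p$sigma_high)
  params <- list()
  for (cond in ADAPT_CONDITIONS) {
    params[[cond]] <- list()
    for (cg in c("congruent", "incongruent")) {
      d <- 0
      if (cg %in% shifted_congruency)
        d <- if (cond == "visual_leading") pss_shift * shift_split
             else -pss_shift * (1 - shift_split)
      params[[cond]][[cg]] <- shift_by(base, d)
    }
  }
  structure(list(id = as.integer(id), params = params,
                 pss_shift = pss_shift, shift_split = shift_split,
                 shifted_congruency = shifted_congruency),
            class = "sim_observer")
}

#' Draw a population of simulated observers
#'
#' Participant heterogeneity enters as a Gaussian offset of the baseline
#' PSS (both criteria shifted together) and Gaussian variation of the
#' individual adaptation shift around the population value.
#'
#' @param n Number of observers.
#' @param base Population baseline [criterion_params()].
#' @param pss_shift Population mean condition difference (ms).
#' @param pss_sd Between-participant sd of baseline PSS (ms).
#' @param shift_sd Between-participant sd of the individual shift (ms).
#' @param shift_split,shifted_congruency Passed to [sim_observer()].
#' @param seed Integer master seed.
#' @return A list of `sim_observer` objects.
#' @export
sim_observer_population <- function(n = 20L,
                                    base = criterion_params(-213, 237, 90, 90),
                                    pss_shift = 13.5, pss_sd = 30,
                                    shift_sd = 18, shift_split = 0.5,
                                    shifted_congruency = "congruent",
                                    seed = 1L) {
  stopifnot(n >= 1, pss_sd >= 0, shift_sd >= 0)
  set.seed(seed)
  offsets <- rnorm(n, 0, pss_sd)
  shifts <- rnorm(n, pss_shift, shift_sd)
  lapply(seq_len(n), function(i) {
    b <- criterion_params(base$c_low + offsets[i], base$c_high + offsets[i],
                          base$sigma_low, base$sigma_high)
    sim_observer(base = b, pss_shift = shifts[i], shift_split = shift_split,
                 shifted_congruency = shifted_congruency, id = i)
  })
}

#' Simulate binary simultaneity responses
#'
#' Each trial's response is a Bernoulli draw with success probability given
#' by the observer's two-criterion parameters for that trial's (condition,
#' congruency) cell at the trial's SOA. Reproducible per seed.
#'
#' @param observer A [sim_observer()].
#' @param trials Trial skeletons from [enumerate_trials()].
#' @param seed Integer seed.
#' @return `trials` with added integer column `response` (1 =
#'   simultaneous) and `participant` set to the observer id.
#' @export
simulate_responses <- function(observer, trials, seed = 1L) {
  if (!inherits(observer, "sim_observer"))
    stop("observer must be a sim_observer", call. = FALSE)
  set.seed(seed)
  p <- numeric(nrow(trials))
  for (cond in unique(trials$condition)) {
    for (cg in unique(trials$congruency)) {
      idx <- trials$condition == cond & trials$congruency == cg
      if (!any(idx)) next
      pars <- observer$params[[cond]][[cg]]
      if (is.null(pars))
        stop(sprintf("observer has no parameters for condition '%s', congruency '%s'",
                     cond, cg), call. = FALSE)
      p[idx] <- prob_simultaneous(pars, trials$soa[idx])
    }
  }
  trials$response <- rbinom(nrow(trials), 1L, p)
  trials$participant <- observer$id
  trials
}

#' Aggregate trial records into per-SOA binomial cells
#'
#' Pools the test pairings within each congruency class (in design 1 the
#' two congruent pairings pool to n = 20 per SOA per condition) and counts
#' trials and simultaneous responses per participant x condition x
#' congruency x SOA. All participants must share one SOA grid.
#'
#' @param records Trial records with columns `participant`, `condition`,
#'   `congruency`, `soa`, `response`.
#' @return A data frame with columns `participant`, `condition`,
#'   `congruency`, `soa`, `n`, `k`. Use [cells_for()] to extract one
#'   cell set as a [binomial_cells()] object.
#' @export
aggregate_trials <- function(records) {
  req <- c("participant", "condition", "congruency", "soa", "response")
  if (!all(req %in% names(records)))
    stop(sprintf("records must contain columns %s",
                 paste(req, collapse = ", ")), call. = FALSE)
  if (nrow(records) == 0L)
    return(data.frame(participant = integer(0), condition = character(0),
                      congruency = character(0), soa = numeric(0),
                      n = integer(0), k = integer(0)))
  grids <- tapply(records$soa, records$participant,
                  function(x) paste(sort(unique(x)), collapse = ","))
  if (length(unique(grids)) > 1L)
    stop("records mix different SOA grids across participants", call. = FALSE)
  by <- list(participant = records$participant,
             condition = records$condition,
             congruency = records$congruency,
             soa = records$soa)
  n <- aggregate(list(n = records$response), by = by, FUN = length)
  k <- aggregate(list(k = records$response), by = by, FUN = sum)
  out <- merge(n, k, by = names(by), sort = TRUE)
  out <- out[order(out$participant, out$condition, out$congruency, out$soa), ]
  rownames(out) <- NULL
  out
}

#' Extract one participant/condition cell set
#'
#' @param agg Output of [aggregate_trials()].
#' @param participant,condition,congruency Cell selectors; `congruency`
#'   may be `NULL` to take all rows of the participant x condition pair.
#' @return A [binomial_cells()] object.
#' @export
cells_for <- function(agg, participant, condition, congruency = NULL) {
  idx <- agg$participant == participant & agg$condition == condition
  if (!is.null(congruency)) idx <- idx & agg$congruency == congruency
  sub <- agg[idx, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no aggregated cells match the requested selectors", call. = FALSE)
  binomial_cells(sub$soa, sub$n, sub$k)
}
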