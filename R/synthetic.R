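# ---- default concept set ----------------------------------------------------

#' Default determinant labels for synthetic cohorts
#'
#' Fifteen psychosocial and home-environment determinants of fruit intake
#' plus the outcome concept, mirroring the structure of a determinant panel
#' measured on 5-point Likert (and nominal environmental) scales.
#'
#' @return Character vector of 16 concept labels.
#' @export
fruit_intake_concepts <- function() {
  c("awareness", "attitude", "attitude_price",
    "self_efficacy_1", "self_efficacy_2",
    "social_influence_1", "social_influence_2",
    "intention",
    "action_planning_1", "action_planning_2", "action_planning_3",
    "coping_planning_1", "coping_planning_2",
    "availability_home", "visibility_home",
    "fruit_intake")
}

#' Specification of a synthetic cohort
#'
#' Describes a cohort of participants who share a common base causal map
#' with individual Gaussian perturbations; each participant is observed
#' over a few time points with observation noise and optional Likert
#' discretization. Defaults emulate a panel of 257 adults measured on 16
#' concepts over 3 waves.
#'
#' @param n_participants cohort size.
#' @param concepts concept labels.
#' @param n_timepoints number of measurement waves (>= 2).
#' @param density probability that an off-diagonal edge of the base map is
#'   nonzero.
#' @param weight_scale nonzero base weights are Uniform on
#'   \[-weight_scale, weight_scale\].
#' @param noise_sd standard deviation of Gaussian observation noise.
#' @param individual_variation_sd SD of the per-participant cellwise
#'   perturbation of the base map.
#' @param likert_levels number of Likert levels for discretization; set
#'   `discretize = FALSE` for continuous observations.
#' @param discretize whether observations are snapped to the Likert grid.
#' @param seed integer seed driving all randomness of the cohort.
#' @return A list of class `"fcm_cohort_spec"`.
#' @export
fcm_cohort_spec <- function(n_participants = 257L,
                            concepts = fruit_intake_concepts(),
                            n_timepoints = 3L,
                            density = 0.2, weight_scale = 0.5,
                            noise_sd = 0.05,
                            individual_variation_sd = 0.1,
                            likert_levels = 5L, discretize = TRUE,
                            seed = 1L) {
  concepts <- fcm_concepts(concepts)
  n_participants <- as.integer(n_participants)
  n_timepoints <- as.integer(n_timepoints)
  likert_levels <- as.integer(likert_levels)
  stopifnot(n_participants >= 1L, n_timepoints >= 2L,
            density > 0 || density == 0, density <= 1,
            weight_scale > 0, weight_scale <= 1,
            noise_sd >= 0, individual_variation_sd >= 0,
            likert_levels >= 2L)
  structure(list(n_participants = n_participants, concepts = concepts,
                 n_timepoints = n_timepoints, density = density,
                 weight_scale = weight_scale, noise_sd = noise_sd,
                 individual_variation_sd = individual_variation_sd,
                 likert_levels = likert_levels, discretize = discretize,
                 seed = as.integer(seed)),
            class = "fcm_cohort_spec")
}

# ---- generators -------------------------------------------------------------

#' Sample a random ground-truth causal map
#'
#' Each off-diagonal cell is nonzero with probability `density`; nonzero
#' weights are Uniform on \[-weight_scale, weight_scale\]. The diagonal is
#' zero (no explicit self-loop beyond the update rule's own memory term).
#'
#' @param spec an [fcm_cohort_spec()] (its `concepts`, `density` and
#'   `weight_scale` fields are used). Consumes the global RNG stream.
#' @return A weight matrix.
#' @export
fcm_sample_map <- function(spec) {
  n <- length(spec$concepts)
  W <- matrix(0, n, n)
  off <- which(row(W) != col(W))
  on <- off[stats::runif(length(off)) < spec$density]
  W[on] <- stats::runif(length(on), -spec$weight_scale, spec$weight_scale)
  fcm_weights(W, spec$concepts)
}

likert_snap <- function(x, levels) {
  grid <- seq(0, 1, length.out = levels)
  grid[pmax(1L, pmin(levels, round(x * (levels - 1L)) + 1L))]
}

#' Generate one synthetic participant
#'
#' The participant's map is the base map plus cellwise Gaussian
#' perturbations (SD `individual_variation_sd`), clipped to \[-1, 1\]. The
#' baseline state is Uniform on \[0.2, 0.8\] (bounded away from the sigmoid
#' saturation), the trajectory is the deterministic rollout over
#' `n_timepoints - 1` steps, and observations add Gaussian noise (SD
#' `noise_sd`), clipped to \[0, 1\] and optionally snapped to the nearest
#' of `likert_levels` evenly spaced levels.
#'
#' @param W_base base weight matrix shared by the cohort.
#' @param spec an [fcm_cohort_spec()].
#' @param participant_id identifier for the generated trajectory.
#' @param control simulation control for the rollout.
#' @return A list with `weights` (the participant's ground-truth map) and
#'   `trajectory` (an [fcm_trajectory()]). Consumes the global RNG stream.
#' @export
fcm_generate_participant <- function(W_base, spec, participant_id = "p1",
                                     control = fcm_sim_control()) {
  n <- nrow(W_base)
  W <- W_base + matrix(stats::rnorm(n * n, 0, spec$individual_variation_sd),
                       n, n)
  W <- fcm_weights(pmin(pmax(W, -1), 1), rownames(W_base))
  init <- stats::runif(n, 0.2, 0.8)
  names(init) <- rownames(W_base)
  truth <- fcm_rollout(init, W, control, n_steps = spec$n_timepoints - 1L)
  obs <- truth
  if (spec$noise_sd > 0) {
    obs <- obs + matrix(stats::rnorm(length(obs), 0, spec$noise_sd),
                        nrow(obs), ncol(obs))
  }
  obs <- pmin(pmax(obs, 0), 1)
  if (isTRUE(spec$discretize)) {
    obs[] <- likert_snap(obs, spec$likert_levels)
  }
  list(weights = W,
       trajectory = fcm_trajectory(obs, rownames(W_base), participant_id))
}

#' Generate a full synthetic cohort
#'
#' Samples one base map, then one perturbed map and observed trajectory
#' per participant. Fully reproducible from `spec$seed`.
#'
#' @param spec an [fcm_cohort_spec()].
#' @param control simulation control for the rollouts.
#' @return A list of class `"fcm_cohort"` with `trajectories` (named list
#'   of [fcm_trajectory()]), `ground_truth` (named list of weight matrices,
#'   for evaluation only — never written with the observables),
#'   `base_map`, and `spec`.
#' @examples
#' coh <- fcm_generate_cohort(fcm_cohort_spec(n_participants = 3,
#'                                            concepts = c("a", "b", "c"),
#'                                            seed = 7))
#' @export
fcm_generate_cohort <- function(spec, control = fcm_sim_control()) {
  set.seed(spec$seed)
  base <- fcm_sample_map(spec)
  ids <- sprintf("p%03d", seq_len(spec$n_participants))
  out <- lapply(ids, function(id) {
    fcm_generate_participant(base, spec, id, control)
  })
  structure(list(trajectories = stats::setNames(
                   lapply(out, `[[`, "trajectory"), ids),
                 ground_truth = stats::setNames(
                   lapply(out, `[[`, "weights"), ids),
                 base_map = base,
                 spec = spec),
            class = "fcm_cohort")
}

#' @export
print.fcm_cohort <- function(x, ...) {
  cat("Synthetic cohort: ", length(x$trajectories), " participants, ",
      length(x$spec$concepts), " concepts, ",
      x$spec$n_timepoints, " time points (seed ", x$spec$seed, ")\n",
      sep = "")
  invisible(x)
}
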