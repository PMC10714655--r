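# ---- trajectories -----------------------------------------------------------

#' Construct a longitudinal trajectory
#'
#' A trajectory is the T x n matrix of one participant's observed concept
#' states, time-ordered, with values normalized to \[0, 1\] and at least a
#' baseline and one follow-up (T >= 2).
#'
#' @param observations T x n numeric matrix (or data frame), one column per
#'   concept, one row per time point.
#' @param concepts concept labels; defaults to column names.
#' @param participant_id identifier stored as an attribute.
#' @return A numeric matrix of class `"fcm_trajectory"` with a
#'   `participant_id` attribute.
#' @export
fcm_trajectory <- function(observations, concepts = NULL,
                           participant_id = "p1") {
  obs <- as.matrix(observations)
  storage.mode(obs) <- "double"
  if (nrow(obs) < 2L) {
    stop("a trajectory needs at least two time points", call. = FALSE)
  }
  if (is.null(concepts)) {
    concepts <- colnames(obs)
    if (is.null(concepts)) concepts <- paste0("C", seq_len(ncol(obs)))
  }
  concepts <- fcm_concepts(concepts)
  if (length(concepts) != ncol(obs)) {
    stop("concept labels and column count disagree", call. = FALSE)
  }
  if (anyNA(obs) || any(obs < 0 | obs > 1)) {
    stop("all observed values must be finite and in [0, 1]", call. = FALSE)
  }
  colnames(obs) <- concepts
  rownames(obs) <- NULL
  structure(obs, participant_id = as.character(participant_id),
            class = c("fcm_trajectory", class(obs)))
}

as_trajectory <- function(x) {
  if (inherits(x, "fcm_trajectory")) x else fcm_trajectory(x)
}

# ---- fitness and errors -----------------------------------------------------

# one-step-ahead mean absolute error (teacher forcing): each observed state
# at t-1 is pushed through one update and compared with the observation at t
one_step_error <- function(W, obs, control) {
  prev <- obs[-nrow(obs), , drop = FALSE]
  pred <- onestep_predict(prev, W, control$lambda)
  mean(abs(pred - obs[-1L, , drop = FALSE]))
}

#' Trajectory fitness of a candidate weight matrix
#'
#' The fitness scores how closely a candidate map reproduces every observed
#' transition of a participant's trajectory. Let E be the mean absolute
#' one-step-ahead error over all transitions t = 1..T-1 and all concepts,
#' where each prediction starts from the *observed* previous state. The
#' fitness is `1 / (1 + 100 * E)`, a bounded score in (0, 1] that equals 1
#' exactly when every transition is reproduced perfectly.
#'
#' @param W candidate weight matrix (rows = sources, columns = targets).
#' @param trajectory an [fcm_trajectory()] (or T x n matrix).
#' @param control an [fcm_sim_control()]; only `lambda` matters here.
#' @return Fitness in (0, 1].
#' @export
fcm_fitness <- function(W, trajectory, control = fcm_sim_control()) {
  obs <- as_trajectory(trajectory)
  if (ncol(obs) != nrow(W)) {
    stop("trajectory and weight matrix dimensions disagree", call. = FALSE)
  }
  1 / (1 + 100 * one_step_error(W, obs, control))
}

#' In-sample error of a learned map
#'
#' Mean absolute difference between the observed trajectory and a
#' free-running simulation of the map started from the observed baseline
#' (t = 0), averaged over time points t = 1..T-1 and all concepts.
#'
#' @inheritParams fcm_fitness
#' @return Non-negative error.
#' @export
fcm_in_sample_error <- function(W, trajectory, control = fcm_sim_control()) {
  obs <- as_trajectory(trajectory)
  if (ncol(obs) != nrow(W)) {
    stop("trajectory and weight matrix dimensions disagree", call. = FALSE)
  }
  sim <- fcm_rollout(obs[1L, ], W, control, n_steps = nrow(obs) - 1L)
  mean(abs(sim[-1L, , drop = FALSE] - obs[-1L, , drop = FALSE]))
}

#' Out-of-sample error against a reference dynamics
#'
#' Draws `k` random initial states (uniform on \[0, 1\] per concept), rolls
#' each forward `n_steps` steps under the candidate map `W` and under the
#' reference map, and returns the mean absolute difference between the two
#' rollouts over draws, steps and concepts. The reference is explicit — in
#' synthetic experiments the generating map, in cohort runs typically a
#' held-out participant's learned map.
#'
#' @inheritParams fcm_fitness
#' @param reference reference weight matrix with the same dimensions.
#' @param n_steps rollout length (defaults to T-1 of a typical short panel,
#'   2 steps).
#' @param k number of random initial states.
#' @return Non-negative Monte-Carlo error estimate.
#' @export
fcm_out_of_sample_error <- function(W, reference, n_steps = 2L,
                                    control = fcm_sim_control(), k = 100L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  if (!all(dim(W) == dim(reference))) {
    stop("candidate and reference matrices must share dimensions",
         call. = FALSE)
  }
  n <- nrow(W)
  total <- 0
  for (i in seq_len(k)) {
    init <- stats::runif(n)
    names(init) <- rownames(W)
    a <- fcm_rollout(init, W, control, n_steps)
    b <- fcm_rollout(init, reference, control, n_steps)
    total <- total + mean(abs(a[-1L, , drop = FALSE] - b[-1L, , drop = FALSE]))
  }
  total / k
}

# ---- genetic operators ------------------------------------------------------

#' Single-edge crossover of two candidate maps
#'
#' With probability `prob`, one cell (j, i) is chosen uniformly at random
#' and its weight is exchanged between the two offspring; otherwise the
#' offspring are exact copies of the parents. The multiset of all cell
#' values across the pair is always conserved.
#'
#' @param a,b parent weight matrices of equal dimension.
#' @param prob crossover probability.
#' @return A list with elements `offspring` (list of the two matrices) and
#'   `modified` (logical, whether a swap occurred). Consumes the global RNG
#'   stream.
#' @export
fcm_crossover <- function(a, b, prob = 0.9) {
  if (!all(dim(a) == dim(b))) {
    stop("parents must share dimensions", call. = FALSE)
  }
  modified <- FALSE
  if (stats::runif(1) < prob) {
    cell <- sample.int(length(a), 1L)
    tmp <- a[cell]
    a[cell] <- b[cell]
    b[cell] <- tmp
    modified <- TRUE
  }
  list(offspring = list(a, b), modified = modified)
}

#' Uniform single-edge mutation of a candidate map
#'
#' With probability `prob`, one cell chosen uniformly at random is replaced
#' by a fresh draw from Uniform\[-1, 1\]; all other cells are untouched.
#'
#' @param W weight matrix.
#' @param prob mutation probability.
#' @return A list with elements `weights` and `modified`. Consumes the
#'   global RNG stream.
#' @export
fcm_mutate <- function(W, prob = 0.1) {
  modified <- FALSE
  if (stats::runif(1) < prob) {
    cell <- sample.int(length(W), 1L)
    W[cell] <- stats::runif(1, -1, 1)
    modified <- TRUE
  }
  list(weights = W, modified = modified)
}

#' Tournament selection indices
#'
#' Draws `size` individuals (with replacement across slots) by tournaments
#' of `tournament_size` distinct competitors; each tournament returns its
#' fittest member, so a full-population tournament is an argmax. Elitism is
#' handled by the caller ([fcm_learn()] always carries the single best
#' chromosome unchanged into the next generation).
#'
#' @param fitness numeric vector of evaluated fitnesses.
#' @param size number of individuals to select.
#' @param tournament_size tournament size.
#' @return Integer vector of selected indices. Consumes the global RNG
#'   stream.
#' @export
fcm_select <- function(fitness, size = length(fitness), tournament_size = 3L) {
  if (length(fitness) == 0L) stop("empty population", call. = FALSE)
  k <- min(tournament_size, length(fitness))
  vapply(seq_len(size), function(i) {
    cand <- sample.int(length(fitness), k)
    cand[which.max(fitness[cand])]
  }, integer(1))
}

# ---- control ----------------------------------------------------------------

#' Control parameters for the genetic-algorithm learner
#'
#' @param population_size number of candidate maps kept per generation.
#' @param max_generations generation budget.
#' @param crossover_prob probability that a parent pair exchanges one edge.
#' @param mutation_prob probability that an offspring has one edge redrawn.
#' @param fitness_goal early-stopping fitness; with the `1/(1+100E)` scale,
#'   0.99 corresponds to a mean one-step error of about 1e-4.
#' @param tournament_size tournament size for selection.
#' @param seed optional integer seed; if given, [fcm_learn()] seeds the RNG
#'   so a run is exactly reproducible.
#' @param sim an [fcm_sim_control()] carrying the transfer parameters.
#' @return A list of class `"fcm_control"`.
#' @export
fcm_control <- function(population_size = 100L, max_generations = 200L,
                        crossover_prob = 0.9, mutation_prob = 0.1,
                        fitness_goal = 0.99, tournament_size = 3L,
                        seed = NULL, sim = fcm_sim_control()) {
  population_size <- as.integer(population_size)
  max_generations <- as.integer(max_generations)
  tournament_size <- as.integer(tournament_size)
  stopifnot(population_size >= 2L, max_generations >= 1L,
            tournament_size >= 1L,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            fitness_goal > 0, fitness_goal <= 1)
  structure(list(population_size = population_size,
                 max_generations = max_generations,
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 fitness_goal = fitness_goal,
                 tournament_size = tournament_size,
                 seed = seed, sim = sim),
            class = "fcm_control")
}

# ---- the fitting function ---------------------------------------------------

#' Learn an individual's fuzzy cognitive map from a trajectory
#'
#' Fits one signed weight matrix to one participant's observed trajectory
#' with a real-coded genetic algorithm whose fitness is evaluated at every
#' observed transition (not only the final state): candidate maps start as
#' i.i.d. Uniform\[-1, 1\] matrices and evolve by tournament selection with
#' elitism, single-edge crossover and uniform single-edge mutation until the
#' fitness goal or the generation budget is reached.
#'
#' @param trajectory an [fcm_trajectory()] (or T x n matrix in \[0, 1\]).
#' @param control an [fcm_control()] object.
#' @param reference optional reference weight matrix for the out-of-sample
#'   error (e.g. the generating map of a synthetic participant, or a
#'   held-out participant's learned map); if `NULL` the out-of-sample error
#'   is `NA`.
#' @param k_oos number of random initial states for the out-of-sample error.
#' @return An object of class `"fcm_fit"` with components `weights` (the
#'   best map found), `fitness`, `fitness_history` (best per generation,
#'   non-decreasing), `generations`, `in_sample_error`,
#'   `out_of_sample_error`, `trajectory`, and `control`. Supports `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `residuals`, `simulate` and
#'   `plot`.
#' @examples
#' W <- fcm_weights(rbind(c(0, 0.4), c(-0.3, 0)), c("a", "b"))
#' obs <- fcm_rollout(fcm_state(c(a = 0.3, b = 0.7)), W, n_steps = 3)
#' fit <- fcm_learn(obs, fcm_control(population_size = 30,
#'                                   max_generations = 30, seed = 1))
#' coef(fit)
#' @export
fcm_learn <- function(trajectory, control = fcm_control(), reference = NULL,
                      k_oos = 100L) {
  obs <- as_trajectory(trajectory)
  n <- ncol(obs)
  if (!is.null(control$seed)) set.seed(control$seed)
  sim <- control$sim
  pop_size <- control$population_size

  prev <- obs[-nrow(obs), , drop = FALSE]
  nxt <- obs[-1L, , drop = FALSE]
  eval_fit <- function(W) {
    1 / (1 + 100 * mean(abs(onestep_predict(prev, W, sim$lambda) - nxt)))
  }

  population <- lapply(seq_len(pop_size), function(i) {
    matrix(stats::runif(n * n, -1, 1), n, n)
  })
  fitness <- vapply(population, eval_fit, numeric(1))

  history <- numeric(control$max_generations)
  gen <- 0L
  repeat {
    best_idx <- which.max(fitness)
    best_fit <- fitness[best_idx]
    if (gen >= 1L) history[gen] <- best_fit
    if (best_fit >= control$fitness_goal || gen >= control$max_generations) {
      break
    }
    gen <- gen + 1L
    elite_W <- population[[best_idx]]
    elite_f <- best_fit

    parents <- fcm_select(fitness, pop_size, control$tournament_size)
    new_pop <- vector("list", pop_size)
    new_fit <- numeric(pop_size)
    i <- 1L
    while (i <= pop_size) {
      a <- parents[i]
      b <- if (i < pop_size) parents[i + 1L] else parents[1L]
      cx <- fcm_crossover(population[[a]], population[[b]],
                          control$crossover_prob)
      for (slot in 1:2) {
        j <- i + slot - 1L
        if (j > pop_size) break
        mu <- fcm_mutate(cx$offspring[[slot]], control$mutation_prob)
        new_pop[[j]] <- mu$weights
        if (cx$modified || mu$modified) {
          new_fit[j] <- eval_fit(mu$weights)
        } else {
          # untouched copy: inherit the parent's evaluated fitness
          new_fit[j] <- fitness[if (slot == 1L) a else b]
        }
      }
      i <- i + 2L
    }
    # elitism: the generation's best survives unchanged
    new_pop[[1L]] <- elite_W
    new_fit[1L] <- elite_f
    population <- new_pop
    fitness <- new_fit
    history[gen] <- max(fitness)
  }

  best_idx <- which.max(fitness)
  W <- fcm_weights(pmin(pmax(population[[best_idx]], -1), 1),
                   colnames(obs))
  oos <- NA_real_
  if (!is.null(reference)) {
    oos <- fcm_out_of_sample_error(W, reference, n_steps = nrow(obs) - 1L,
                                   control = sim, k = k_oos)
  }
  structure(list(weights = W,
                 fitness = fitness[best_idx],
                 fitness_history = history[seq_len(gen)],
                 generations = gen,
                 in_sample_error = fcm_in_sample_error(W, obs, sim),
                 out_of_sample_error = oos,
                 trajectory = obs,
                 control = control),
            class = "fcm_fit")
}

# ---- fcm_fit methods --------------------------------------------------------

#' @export
print.fcm_fit <- function(x, ...) {
  cat("Fuzzy cognitive map fit (real-coded genetic algorithm)\n")
  cat("  participant:      ", attr(x$trajectory, "participant_id"), "\n",
      sep = "")
  cat("  concepts:         ", ncol(x$trajectory), "\n", sep = "")
  cat("  time points:      ", nrow(x$trajectory), "\n", sep = "")
  cat("  generations run:  ", x$generations, "\n", sep = "")
  cat("  fitness:          ", format(x$fitness, digits = 4), "\n", sep = "")
  cat("  in-sample error:  ", format(x$in_sample_error, digits = 4), "\n",
      sep = "")
  if (!is.na(x$out_of_sample_error)) {
    cat("  out-of-sample err:", format(x$out_of_sample_error, digits = 4),
        "\n")
  }
  invisible(x)
}

#' @export
coef.fcm_fit <- function(object, ...) object$weights

#' @export
summary.fcm_fit <- function(object, ...) {
  W <- object$weights
  nz <- W[W != 0]
  out <- list(fit = object,
              n_edges = sum(W != 0),
              mean_abs_weight = if (length(nz)) mean(abs(nz)) else 0,
              strongest = if (length(nz)) {
                idx <- which(abs(W) == max(abs(W)), arr.ind = TRUE)[1L, ]
                data.frame(source = rownames(W)[idx[1L]],
                           target = colnames(W)[idx[2L]],
                           weight = W[idx[1L], idx[2L]])
              } else NULL)
  class(out) <- "summary.fcm_fit"
  out
}

#' @export
print.summary.fcm_fit <- function(x, ...) {
  print(x$fit)
  cat("  nonzero edges:    ", x$n_edges, "\n", sep = "")
  cat("  mean |weight|:    ", format(x$mean_abs_weight, digits = 4), "\n",
      sep = "")
  if (!is.null(x$strongest)) {
    cat("  strongest edge:   ", x$strongest$source, "->",
        x$strongest$target, "=", format(x$strongest$weight, digits = 4),
        "\n")
  }
  invisible(x)
}

#' Predict concept states from a fitted map
#'
#' `type = "onestep"` pushes every observed state of `newdata` (default: the
#' training trajectory) through one update — the transitions the fitness
#' was trained on. `type = "rollout"` runs free from the first row of
#' `newdata` for `nrow(newdata) - 1` steps, the regime the in-sample error
#' measures.
#'
#' @param object an `fcm_fit`.
#' @param newdata optional T x n matrix; defaults to the training
#'   trajectory.
#' @param type `"onestep"` or `"rollout"`.
#' @param ... unused.
#' @return A matrix of predicted states for t = 1..T-1.
#' @export
predict.fcm_fit <- function(object, newdata = NULL,
                            type = c("onestep", "rollout"), ...) {
  type <- match.arg(type)
  obs <- if (is.null(newdata)) object$trajectory else as_trajectory(newdata)
  sim <- object$control$sim
  if (type == "onestep") {
    onestep_predict(obs[-nrow(obs), , drop = FALSE], object$weights,
                    sim$lambda)
  } else {
    fcm_rollout(obs[1L, ], object$weights, sim,
                n_steps = nrow(obs) - 1L)[-1L, , drop = FALSE]
  }
}

#' @export
fitted.fcm_fit <- function(object, ...) predict(object, type = "onestep")

#' @export
residuals.fcm_fit <- function(object, ...) {
  object$trajectory[-1L, , drop = FALSE] - fitted(object)
}

#' Simulate a fitted map to equilibrium
#'
#' Runs the deterministic equilibrium simulation of the learned map from
#' the participant's observed baseline (or a supplied initial state).
#'
#' @param object an `fcm_fit`.
#' @param nsim unused (the dynamics are deterministic); kept for the
#'   generic's signature.
#' @param seed unused.
#' @param initial optional initial state; defaults to the observed baseline.
#' @param ... unused.
#' @return An `"fcm_sim"` object.
#' @export
simulate.fcm_fit <- function(object, nsim = 1, seed = NULL, initial = NULL,
                             ...) {
  if (is.null(initial)) initial <- object$trajectory[1L, ]
  fcm_simulate(initial, object$weights, object$control$sim)
}

#' @export
plot.fcm_fit <- function(x, ...) {
  graphics::plot(seq_along(x$fitness_history), x$fitness_history,
                 type = "s", xlab = "generation", ylab = "best fitness",
                 ylim = c(0, 1), ...)
  graphics::abline(h = x$control$fitness_goal, lty = 2)
  invisible(x)
}
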