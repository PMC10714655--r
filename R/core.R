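#' @keywords internal
"_PACKAGE"

# ---- concept sets -----------------------------------------------------------

#' Validate a set of concept labels
#'
#' A concept set is an ordered character vector of unique, non-empty labels.
#' It fixes the row/column order of weight matrices and the element order of
#' state vectors throughout the package.
#'
#' @param concepts character vector of concept labels.
#' @return The validated character vector, invisibly usable as-is.
#' @examples
#' fcm_concepts(c("awareness", "attitude", "fruit_intake"))
#' @export
fcm_concepts <- function(concepts) {
  concepts <- as.character(concepts)
  if (length(concepts) < 1L) {
    stop("a concept set needs at least one label", call. = FALSE)
  }
  if (anyNA(concepts) || any(!nzchar(concepts))) {
    stop("concept labels must be non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(concepts)) {
    stop("concept labels must be unique: duplicated ",
         paste(unique(concepts[duplicated(concepts)]), collapse = ", "),
         call. = FALSE)
  }
  concepts
}

# ---- weight matrices --------------------------------------------------------

#' Construct a causal weight matrix
#'
#' Builds the n x n signed weight matrix of a fuzzy cognitive map. Entry
#' `W[j, i]` is the causal impact of source concept `j` (row) on target
#' concept `i` (column); all entries lie in \[-1, 1\]. The object is a plain
#' base matrix with concept labels as dimnames, so all of R's matrix algebra
#' applies.
#'
#' @param weights numeric matrix (or something coercible) with entries in
#'   \[-1, 1\].
#' @param concepts concept labels; defaults to existing row names, or
#'   `C1..Cn`.
#' @return A named numeric matrix with rows = sources, columns = targets.
#' @examples
#' W <- fcm_weights(matrix(c(0, 0.5, -0.2, 0), 2, 2),
#'                  concepts = c("a", "b"))
#' @export
fcm_weights <- function(weights, concepts = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop("weight matrix must be square", call. = FALSE)
  }
  if (is.null(concepts)) {
    concepts <- rownames(weights)
    if (is.null(concepts)) concepts <- paste0("C", seq_len(nrow(weights)))
  }
  concepts <- fcm_concepts(concepts)
  if (length(concepts) != nrow(weights)) {
    stop("concept labels and matrix dimension disagree", call. = FALSE)
  }
  storage.mode(weights) <- "double"
  if (anyNA(weights) || any(weights < -1 | weights > 1)) {
    stop("all causal weights must be finite and in [-1, 1]", call. = FALSE)
  }
  dimnames(weights) <- list(concepts, concepts)
  weights
}

#' Construct a concept state vector
#'
#' @param values numeric vector with entries in \[0, 1\].
#' @param concepts concept labels; defaults to existing names.
#' @return A named numeric vector.
#' @export
fcm_state <- function(values, concepts = NULL) {
  if (is.null(concepts)) concepts <- names(values)
  values <- as.numeric(values)
  if (is.null(concepts)) concepts <- paste0("C", seq_along(values))
  concepts <- fcm_concepts(concepts)
  if (length(values) != length(concepts)) {
    stop("state length and concept count disagree", call. = FALSE)
  }
  if (anyNA(values) || any(values < 0 | values > 1)) {
    stop("all state values must be finite and in [0, 1]", call. = FALSE)
  }
  names(values) <- concepts
  values
}

# ---- simulation control -----------------------------------------------------

#' Simulation control parameters
#'
#' @param lambda sigmoid steepness, in (0, 10].
#' @param threshold convergence tolerance on the max-norm change between
#'   successive states; simulation stops once no concept moves by more.
#' @param max_iter maximum number of update steps.
#' @param clamped integer indices (or concept labels) held fixed at their
#'   current value on every step, e.g. an always-on intervention node.
#' @return A list of class `"fcm_sim_control"`.
#' @export
fcm_sim_control <- function(lambda = 1, threshold = 0.001, max_iter = 2000,
                            clamped = integer(0)) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0 || lambda > 10) {
    stop("lambda must be a single number in (0, 10]", call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a single positive number", call. = FALSE)
  }
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L) {
    stop("max_iter must be a positive integer", call. = FALSE)
  }
  structure(list(lambda = lambda, threshold = threshold,
                 max_iter = max_iter, clamped = clamped),
            class = "fcm_sim_control")
}

resolve_clamped <- function(clamped, concepts) {
  if (length(clamped) == 0L) return(integer(0))
  if (is.character(clamped)) {
    idx <- match(clamped, concepts)
    if (anyNA(idx)) {
      stop("unknown clamped concept(s): ",
           paste(clamped[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    idx
  } else {
    idx <- as.integer(clamped)
    if (anyNA(idx) || any(idx < 1L | idx > length(concepts))) {
      stop("clamped indices out of range", call. = FALSE)
    }
    idx
  }
}

# ---- transfer and update ----------------------------------------------------

#' Sigmoid transfer function
#'
#' The squashing function keeping concept values in (0, 1):
#' `f(x) = 1 / (1 + exp(-lambda * x))`.
#'
#' @param x numeric vector.
#' @param lambda steepness parameter, in (0, 10].
#' @return Numeric vector of the same length, values in (0, 1).
#' @examples
#' fcm_sigmoid(0)       # 0.5
#' fcm_sigmoid(1)       # ~0.731
#' @export
fcm_sigmoid <- function(x, lambda = 1) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0 || lambda > 10) {
    stop("lambda must be a single number in (0, 10]", call. = FALSE)
  }
  1 / (1 + exp(-lambda * x))
}

check_state_matrix <- function(state, W) {
  if (length(state) != nrow(W)) {
    stop("state vector and weight matrix dimensions disagree", call. = FALSE)
  }
  sn <- names(state)
  if (!is.null(sn) && !is.null(rownames(W)) && !identical(sn, rownames(W))) {
    stop("state and weight matrix concept labels disagree", call. = FALSE)
  }
  invisible(NULL)
}

# Activation transport used by every simulation and fitness path. The
# interaction sum is an ordered colSums, never a BLAS matrix product, so
# one-step predictions, rollouts and augmented (zero-padded) maps agree
# bit-for-bit.
propagate_state <- function(state, W, lambda) {
  fcm_sigmoid(state + colSums(state * W), lambda)
}

# row-wise one-step-ahead predictions for a block of observed states
onestep_predict <- function(prev, W, lambda) {
  out <- matrix(NA_real_, nrow(prev), ncol(prev),
                dimnames = list(NULL, colnames(prev)))
  for (t in seq_len(nrow(prev))) {
    out[t, ] <- propagate_state(prev[t, ], W, lambda)
  }
  out
}

#' One synchronous update step of a fuzzy cognitive map
#'
#' Applies the state update `A_i' = f(A_i + sum_j A_j * W[j, i])`, where `f`
#' is the sigmoid transfer with steepness `control$lambda`. Concepts listed
#' in `control$clamped` keep their incoming value unchanged.
#'
#' @param state named numeric state vector in \[0, 1\].
#' @param W weight matrix, rows = sources, columns = targets.
#' @param control an [fcm_sim_control()] object.
#' @return The next state vector.
#' @export
fcm_step <- function(state, W, control = fcm_sim_control()) {
  check_state_matrix(state, W)
  out <- propagate_state(state, W, control$lambda)
  idx <- resolve_clamped(control$clamped, names(state))
  if (length(idx)) out[idx] <- state[idx]
  names(out) <- names(state)
  out
}

#' Simulate a fuzzy cognitive map to equilibrium
#'
#' Repeatedly applies [fcm_step()] until no concept changes by more than
#' `control$threshold` (max-norm over all concepts) or `control$max_iter`
#' steps have been taken.
#'
#' @inheritParams fcm_step
#' @param initial named numeric initial state in \[0, 1\].
#' @return An object of class `"fcm_sim"`: a list with `states` (a
#'   (iterations+1) x n matrix of the full history, row 1 the initial
#'   state), `converged`, `iterations`, and the `control` used.
#' @examples
#' W <- fcm_weights(matrix(0, 2, 2), c("a", "b"))
#' fcm_simulate(fcm_state(c(a = 0.2, b = 0.9)), W)
#' @export
fcm_simulate <- function(initial, W, control = fcm_sim_control()) {
  check_state_matrix(initial, W)
  n <- length(initial)
  states <- matrix(NA_real_, nrow = control$max_iter + 1L, ncol = n,
                   dimnames = list(NULL, names(initial)))
  states[1L, ] <- initial
  cur <- initial
  converged <- FALSE
  iter <- 0L
  while (iter < control$max_iter) {
    nxt <- fcm_step(cur, W, control)
    if (any(!is.finite(nxt))) {
      stop("non-finite state encountered during simulation", call. = FALSE)
    }
    iter <- iter + 1L
    states[iter + 1L, ] <- nxt
    if (max(abs(nxt - cur)) <= control$threshold) {
      converged <- TRUE
      cur <- nxt
      break
    }
    cur <- nxt
  }
  structure(list(states = states[seq_len(iter + 1L), , drop = FALSE],
                 converged = converged, iterations = iter,
                 control = control),
            class = "fcm_sim")
}

#' @export
print.fcm_sim <- function(x, ...) {
  cat("Fuzzy cognitive map simulation\n")
  cat("  concepts:  ", ncol(x$states), "\n", sep = "")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  cat("  final state:\n")
  print(round(x$states[nrow(x$states), ], 4), ...)
  invisible(x)
}

#' @export
plot.fcm_sim <- function(x, ...) {
  graphics::matplot(seq_len(nrow(x$states)) - 1L, x$states, type = "l",
                    lty = 1, xlab = "iteration", ylab = "concept value",
                    ylim = c(0, 1), ...)
  invisible(x)
}

#' Fixed-length rollout of a fuzzy cognitive map
#'
#' Applies exactly `n_steps` update steps and returns the full trajectory,
#' regardless of convergence. Used by the learning fitness and the
#' synthetic-cohort generator.
#'
#' @inheritParams fcm_simulate
#' @param n_steps number of update steps (>= 1).
#' @return A (n_steps + 1) x n matrix of states; row 1 is `initial`.
#' @export
fcm_rollout <- function(initial, W, control = fcm_sim_control(), n_steps) {
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L) {
    stop("n_steps must be a positive integer", call. = FALSE)
  }
  check_state_matrix(initial, W)
  out <- matrix(NA_real_, nrow = n_steps + 1L, ncol = length(initial),
                dimnames = list(NULL, names(initial)))
  out[1L, ] <- initial
  cur <- initial
  for (t in seq_len(n_steps)) {
    cur <- fcm_step(cur, W, control)
    out[t + 1L, ] <- cur
  }
  out
}
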