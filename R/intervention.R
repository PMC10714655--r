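# ---- intervention specification ---------------------------------------------

#' Specify an intervention scenario
#'
#' An intervention is modelled as one extra always-active concept whose
#' outgoing edges carry the (elicited or supplied) causal weights onto the
#' target determinants. In `"continuous"` mode (the default) the node is
#' clamped at `activation` on every simulation step, representing sustained
#' exposure; in `"single-shot"` mode the target determinants' baseline
#' values are perturbed once by the weights and the map then runs free.
#'
#' @param weights named numeric vector: target concept -> signed weight in
#'   \[-1, 1\]. May also be the data frame returned by
#'   [fcm_elicit_weights()] (columns `target`, `weight`).
#' @param name scenario name, used to label the added node.
#' @param activation activation level of the intervention node, in (0, 1\].
#' @param mode `"continuous"` or `"single-shot"`.
#' @return A list of class `"fcm_intervention"`.
#' @examples
#' basic <- fcm_intervention(c(awareness = 0.591, attitude = 0.340),
#'                           name = "basic")
#' @export
fcm_intervention <- function(weights, name = "intervention",
                             activation = 1.0,
                             mode = c("continuous", "single-shot")) {
  mode <- match.arg(mode)
  if (is.data.frame(weights)) {
    weights <- stats::setNames(weights$weight, weights$target)
  }
  weights <- unlist(weights)
  if (length(weights) && (is.null(names(weights)) || any(!nzchar(names(weights))))) {
    stop("intervention weights must be named by target concept",
         call. = FALSE)
  }
  if (anyNA(weights) || any(weights < -1 | weights > 1)) {
    stop("intervention weights must be finite and in [-1, 1]", call. = FALSE)
  }
  if (!is.numeric(activation) || length(activation) != 1L ||
      activation <= 0 || activation > 1) {
    stop("activation must be a single value in (0, 1]", call. = FALSE)
  }
  structure(list(name = as.character(name), weights = weights,
                 activation = activation, mode = mode),
            class = "fcm_intervention")
}

#' @export
print.fcm_intervention <- function(x, ...) {
  cat("Intervention scenario '", x$name, "' (", x$mode, ", activation ",
      x$activation, ")\n", sep = "")
  if (length(x$weights)) {
    print(round(x$weights, 3))
  } else {
    cat("  (no target determinants)\n")
  }
  invisible(x)
}

#' Augment a weight matrix with an intervention node
#'
#' Adds one source concept `intervention:<name>` whose outgoing edges are
#' the scenario weights and whose incoming edges are all zero. The original
#' n x n block is copied unchanged.
#'
#' @param W weight matrix.
#' @param spec an [fcm_intervention()].
#' @return An (n+1) x (n+1) weight matrix.
#' @export
fcm_augment <- function(W, spec) {
  concepts <- rownames(W)
  unknown <- setdiff(names(spec$weights), concepts)
  if (length(unknown)) {
    stop("intervention targets not in the map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  node <- paste0("intervention:", spec$name)
  n <- nrow(W)
  out <- matrix(0, n + 1L, n + 1L,
                dimnames = list(c(concepts, node), c(concepts, node)))
  out[seq_len(n), seq_len(n)] <- W
  out[node, names(spec$weights)] <- spec$weights
  out
}

# ---- scenario runs ----------------------------------------------------------

#' Run one intervention scenario for one participant
#'
#' Runs the equilibrium simulation twice — once on the participant's map
#' alone (baseline) and once with the intervention applied — and reports
#' the percent change of every determinant between the two equilibria.
#' In continuous mode the intervention node starts at `spec$activation` and
#' is clamped there on every step; in single-shot mode the baseline state
#' is perturbed by the weights (clipped to \[0, 1\]) and no node is added.
#'
#' @param W the participant's weight matrix.
#' @param baseline_state named initial state, typically the observed
#'   baseline (t = 0) measurement.
#' @param spec an [fcm_intervention()].
#' @param control an [fcm_sim_control()].
#' @param eps baseline-equilibrium guard: concepts whose baseline
#'   equilibrium is below `eps` get `NA` percent change (flagged) instead
#'   of an explosive ratio.
#' @return A list of class `"fcm_scenario"` with `participant_id`,
#'   `baseline_equilibrium`, `intervention_equilibrium`, `percent_change`
#'   (named, %), and `converged` (both runs).
#' @export
fcm_run_scenario <- function(W, baseline_state, spec,
                             control = fcm_sim_control(), eps = 1e-6) {
  check_state_matrix(baseline_state, W)
  base <- fcm_simulate(baseline_state, W, control)
  if (spec$mode == "continuous") {
    Wa <- fcm_augment(W, spec)
    node <- nrow(Wa)
    init <- c(baseline_state, spec$activation)
    names(init) <- rownames(Wa)
    ctrl2 <- control
    ctrl2$clamped <- node
    intv <- fcm_simulate(init, Wa, ctrl2)
    intv_eq <- intv$states[nrow(intv$states), -node]
  } else {
    init <- baseline_state
    init[names(spec$weights)] <-
      pmin(1, pmax(0, init[names(spec$weights)] +
                     spec$activation * spec$weights))
    intv <- fcm_simulate(init, W, control)
    intv_eq <- intv$states[nrow(intv$states), ]
  }
  base_eq <- base$states[nrow(base$states), ]
  pct <- ifelse(abs(base_eq) > eps,
                100 * (intv_eq - base_eq) / base_eq, NA_real_)
  names(pct) <- names(base_eq)
  structure(list(participant_id = attr(baseline_state, "participant_id"),
                 scenario = spec$name,
                 baseline_equilibrium = base_eq,
                 intervention_equilibrium = intv_eq,
                 percent_change = pct,
                 converged = base$converged && intv$converged),
            class = "fcm_scenario")
}

#' @export
print.fcm_scenario <- function(x, ...) {
  cat("Scenario '", x$scenario, "'",
      if (!is.null(x$participant_id)) paste0(" for ", x$participant_id),
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  cat("  percent change vs baseline equilibrium:\n")
  print(round(x$percent_change, 2))
  invisible(x)
}

#' Run a scenario across a cohort of fitted maps
#'
#' @param fits list of `fcm_fit` objects (or bare weight matrices paired
#'   with `baselines`).
#' @param spec an [fcm_intervention()].
#' @param control an [fcm_sim_control()].
#' @param baselines optional list/matrix of initial states; defaults to
#'   each fit's observed baseline.
#' @return A list of `fcm_scenario` results.
#' @export
fcm_run_cohort <- function(fits, spec, control = fcm_sim_control(),
                           baselines = NULL) {
  lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    if (inherits(f, "fcm_fit")) {
      W <- f$weights
      b <- if (is.null(baselines)) f$trajectory[1L, ] else baselines[[i]]
      pid <- attr(f$trajectory, "participant_id")
    } else {
      W <- f
      b <- baselines[[i]]
      pid <- names(fits)[i]
    }
    attr(b, "participant_id") <- pid
    fcm_run_scenario(W, b, spec, control)
  })
}

#' Summarize scenario results across a cohort
#'
#' Computes the per-determinant mean and sample standard deviation (n - 1)
#' of the percent change over participants whose baseline and intervention
#' runs both converged, plus the per-participant values of a designated
#' outcome concept for individual-level reporting.
#'
#' @param results list of `fcm_scenario` objects.
#' @param outcome optional outcome concept label (e.g. `"fruit_intake"`).
#' @return A list of class `"fcm_cohort_summary"` with `table` (data frame:
#'   concept, mean_pct_change, sd_pct_change, n), `n_converged`,
#'   `n_excluded`, `scenario`, and if `outcome` is given a data frame
#'   `individual` (participant_id, pct_change).
#' @export
fcm_summarize_cohort <- function(results, outcome = NULL) {
  if (length(results) == 0L) stop("empty cohort", call. = FALSE)
  keep <- vapply(results, function(r) isTRUE(r$converged), logical(1))
  if (!any(keep)) {
    stop("no converged scenario runs to summarize", call. = FALSE)
  }
  used <- results[keep]
  pct <- do.call(rbind, lapply(used, `[[`, "percent_change"))
  tab <- data.frame(
    concept = colnames(pct),
    mean_pct_change = colMeans(pct, na.rm = TRUE),
    sd_pct_change = if (nrow(pct) > 1L) {
      apply(pct, 2, stats::sd, na.rm = TRUE)
    } else {
      rep(0, ncol(pct))  # single participant: SD undefined, reported as 0
    },
    n = colSums(!is.na(pct)),
    row.names = NULL)
  out <- list(table = tab,
              scenario = used[[1L]]$scenario,
              n_converged = sum(keep),
              n_excluded = sum(!keep),
              sd_defined = nrow(pct) > 1L)
  if (!is.null(outcome)) {
    if (!outcome %in% colnames(pct)) {
      stop("outcome concept '", outcome, "' not present", call. = FALSE)
    }
    ids <- vapply(used, function(r) {
      if (is.null(r$participant_id)) NA_character_ else r$participant_id
    }, character(1))
    out$individual <- data.frame(participant_id = ids,
                                 pct_change = pct[, outcome],
                                 row.names = NULL)
    out$outcome <- outcome
  }
  class(out) <- "fcm_cohort_summary"
  out
}

#' @export
print.fcm_cohort_summary <- function(x, digits = 3, ...) {
  cat("Cohort summary for scenario '", x$scenario, "' (",
      x$n_converged, " converged",
      if (x$n_excluded) paste0(", ", x$n_excluded, " excluded"), ")\n",
      sep = "")
  tab <- x$table
  tab$mean_pct_change <- round(tab$mean_pct_change, digits)
  tab$sd_pct_change <- round(tab$sd_pct_change, digits)
  print(tab, row.names = FALSE)
  if (!is.null(x$outcome)) {
    cat("Outcome '", x$outcome, "': mean ",
        round(mean(x$individual$pct_change, na.rm = TRUE), digits),
        "% across participants\n", sep = "")
  }
  invisible(x)
}

#' @export
plot.fcm_cohort_summary <- function(x, ...) {
  if (!is.null(x$individual)) {
    graphics::plot(seq_len(nrow(x$individual)), x$individual$pct_change,
                   xlab = "participant", ylab = "% change in outcome",
                   main = paste("Scenario", x$scenario), ...)
    graphics::abline(h = 0, lty = 2)
  } else {
    graphics::barplot(x$table$mean_pct_change,
                      names.arg = x$table$concept, las = 2,
                      ylab = "% change vs baseline", ...)
  }
  invisible(x)
}
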