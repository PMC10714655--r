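# ---- linguistic vocabulary --------------------------------------------------

.fcm_terms <- c("non-existent", "very-low", "low", "medium", "high",
                "very-high")

#' The closed vocabulary of linguistic terms
#'
#' @return Character vector of the six valid terms, ordered from
#'   non-existent to very-high.
#' @export
fcm_terms <- function() .fcm_terms

#' Triangular membership function
#'
#' @param a,b,c left foot, peak, right foot with `a <= b <= c` on the
#'   magnitude universe \[0, 1\].
#' @return A list of class `"triangular_mf"`; evaluate it on a grid with
#'   [mf_membership()].
#' @export
triangular_mf <- function(a, b, c) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            a <= b, b <= c, a >= 0, c <= 1)
  structure(list(a = a, b = b, c = c), class = "triangular_mf")
}

#' Evaluate a triangular membership function
#'
#' Membership is 0 outside \[a, c\], 1 at the peak b, and piecewise linear
#' in between. A degenerate shoulder (a == b or b == c) is handled by
#' taking membership 1 on the degenerate side at the peak.
#'
#' @param mf a [triangular_mf()].
#' @param x numeric vector of points in \[0, 1\].
#' @return Numeric vector of membership degrees in \[0, 1\].
#' @export
mf_membership <- function(mf, x) {
  up <- if (mf$b > mf$a) (x - mf$a) / (mf$b - mf$a) else as.numeric(x >= mf$b)
  dn <- if (mf$c > mf$b) (mf$c - x) / (mf$c - mf$b) else as.numeric(x <= mf$b)
  pmax(0, pmin(up, dn, 1))
}

#' Linguistic vocabulary of intervention-impact terms
#'
#' Maps the six linguistic terms (non-existent, very-low, low, medium,
#' high, very-high) to triangular membership functions on the magnitude
#' universe \[0, 1\]. By default the peaks sit at 0.1, 0.25, 0.5, 0.75 and
#' 0.9 (an expert saying "medium" tends to mean 0.5) with each function's
#' feet at the neighbouring peaks, so adjacent terms overlap. The term
#' "non-existent" contributes nothing: it carries no membership function
#' and a unanimous "non-existent" rating yields weight exactly 0.
#'
#' @param peaks named numeric vector of peak positions for the five
#'   non-null terms.
#' @param resolution number of grid points over \[0, 1\] used for
#'   aggregation and centroid defuzzification.
#' @return A list of class `"fcm_vocabulary"` with elements `mfs` (named
#'   list of [triangular_mf()], `NULL` for non-existent), `grid`, and
#'   `peaks`.
#' @export
fcm_vocabulary <- function(peaks = c("very-low" = 0.1, "low" = 0.25,
                                     "medium" = 0.5, "high" = 0.75,
                                     "very-high" = 0.9),
                           resolution = 1001L) {
  terms <- c("very-low", "low", "medium", "high", "very-high")
  if (!all(terms %in% names(peaks))) {
    stop("peaks must name all of: ", paste(terms, collapse = ", "),
         call. = FALSE)
  }
  peaks <- peaks[terms]
  if (is.unsorted(peaks, strictly = TRUE)) {
    stop("peaks must be strictly increasing", call. = FALSE)
  }
  feet_l <- c(0, peaks[-length(peaks)])
  feet_r <- c(peaks[-1L], 1)
  mfs <- stats::setNames(vector("list", 6L), .fcm_terms)
  for (i in seq_along(terms)) {
    mfs[[terms[i]]] <- triangular_mf(feet_l[i], peaks[[i]], feet_r[i])
  }
  resolution <- as.integer(resolution)
  stopifnot(resolution >= 2L)
  structure(list(mfs = mfs,
                 grid = seq(0, 1, length.out = resolution),
                 peaks = peaks),
            class = "fcm_vocabulary")
}

check_terms <- function(terms) {
  bad <- setdiff(terms, .fcm_terms)
  if (length(bad)) {
    stop("unknown linguistic term(s): ", paste(bad, collapse = ", "),
         "; valid terms are ", paste(.fcm_terms, collapse = ", "),
         call. = FALSE)
  }
  invisible(terms)
}

# ---- activation, aggregation, defuzzification -------------------------------

#' Activate membership functions by expert endorsement
#'
#' Each distinct term among the ratings is activated at the fraction of
#' experts endorsing it: with three experts saying \{low, medium, medium\},
#' "low" is activated at 1/3 and "medium" at 2/3. "non-existent" ratings
#' count toward the denominator but contribute no membership function.
#'
#' @param terms character vector of linguistic terms, one per expert.
#' @param vocab an [fcm_vocabulary()].
#' @return Named numeric vector of activation levels per distinct
#'   contributing term (may be empty if all ratings are "non-existent").
#' @export
fcm_activate <- function(terms, vocab = fcm_vocabulary()) {
  if (length(terms) == 0L) {
    stop("at least one expert rating is required", call. = FALSE)
  }
  check_terms(terms)
  levels <- table(terms) / length(terms)
  levels <- stats::setNames(as.numeric(levels), names(levels))
  levels[setdiff(names(levels), "non-existent")]
}

#' Family-max aggregation of activated membership functions
#'
#' Clips each activated membership function at its activation level and
#' takes the pointwise maximum over the vocabulary grid.
#'
#' @param activation named numeric vector of activation levels (as from
#'   [fcm_activate()]).
#' @param vocab an [fcm_vocabulary()].
#' @return Numeric vector: the aggregated membership curve sampled on
#'   `vocab$grid` (all zeros if no function is activated).
#' @export
fcm_aggregate <- function(activation, vocab = fcm_vocabulary()) {
  curve <- numeric(length(vocab$grid))
  for (term in names(activation)) {
    mf <- vocab$mfs[[term]]
    if (is.null(mf)) next
    curve <- pmax(curve, pmin(mf_membership(mf, vocab$grid),
                              activation[[term]]))
  }
  curve
}

#' Centroid defuzzification of a sampled membership curve
#'
#' Returns the discrete centre of mass `sum(x * mu(x)) / sum(mu(x))` over
#' the grid. An identically-zero curve (all experts rated the impact
#' non-existent) returns 0 by convention.
#'
#' @param curve numeric membership curve sampled on `grid`.
#' @param grid the sample points (defaults to a uniform grid on \[0, 1\]).
#' @return The centroid, in \[0, 1\].
#' @export
fcm_defuzzify <- function(curve, grid = seq(0, 1, length.out = length(curve))) {
  stopifnot(length(curve) == length(grid))
  total <- sum(curve)
  if (total == 0) return(0)
  sum(grid * curve) / total
}

# ---- end-to-end elicitation -------------------------------------------------

#' Elicit one signed causal weight from expert ratings
#'
#' Runs the four-step fuzzy procedure for a single intervention-target
#' pair: activate each rated term at its endorsement fraction, clip and
#' aggregate the membership functions by family-max, defuzzify the
#' aggregate by its centroid, and apply the shared polarity. Experts rate
#' the magnitude with a linguistic term and the direction with a polarity
#' (+1 or -1); a sign disagreement between experts is substantive and
#' raises an error rather than being averaged away.
#'
#' @param terms character vector of linguistic terms, one per expert.
#' @param polarity +1 or -1, either one value or one per expert (all must
#'   agree; "non-existent" ratings are sign-neutral).
#' @param vocab an [fcm_vocabulary()].
#' @return Signed weight in \[-1, 1\]; exactly 0 when all experts said
#'   "non-existent".
#' @examples
#' fcm_elicit_weight(c("low", "medium", "medium"))
#' fcm_elicit_weight("high", polarity = -1)
#' @export
fcm_elicit_weight <- function(terms, polarity = 1L,
                              vocab = fcm_vocabulary()) {
  check_terms(terms)
  polarity <- as.integer(polarity)
  if (!all(polarity %in% c(-1L, 1L))) {
    stop("polarity must be +1 or -1", call. = FALSE)
  }
  if (length(polarity) > 1L && length(polarity) != length(terms)) {
    stop("supply one polarity, or one per expert", call. = FALSE)
  }
  eff <- if (length(polarity) == 1L) rep(polarity, length(terms)) else polarity
  eff <- eff[terms != "non-existent"]
  if (length(unique(eff)) > 1L) {
    stop("experts disagree on the direction of the effect; ",
         "resolve the polarity conflict explicitly before eliciting",
         call. = FALSE)
  }
  sign_ <- if (length(eff)) eff[1L] else 1L
  magnitude <- fcm_defuzzify(fcm_aggregate(fcm_activate(terms, vocab), vocab),
                             vocab$grid)
  as.numeric(sign_) * magnitude
}

#' Elicit a vector of intervention weights from a ratings table
#'
#' @param ratings data frame with columns `target` (concept label), `term`
#'   (linguistic term) and optionally `expert_id`, `polarity` (+1/-1,
#'   default +1) and `scenario`.
#' @param vocab an [fcm_vocabulary()].
#' @return A data frame with one row per target: `target`, `weight`,
#'   `n_experts`. If `ratings` has a `scenario` column, also `scenario`
#'   (one block per scenario-target pair).
#' @export
fcm_elicit_weights <- function(ratings, vocab = fcm_vocabulary()) {
  ratings <- as.data.frame(ratings)
  if (!all(c("target", "term") %in% names(ratings))) {
    stop("ratings need 'target' and 'term' columns", call. = FALSE)
  }
  if (is.null(ratings$polarity)) ratings$polarity <- 1L
  keys <- if ("scenario" %in% names(ratings)) {
    unique(ratings[c("scenario", "target")])
  } else {
    unique(ratings["target"])
  }
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- ratings$target == keys$target[i]
    if (!is.null(keys$scenario)) sel <- sel & ratings$scenario == keys$scenario[i]
    sub <- ratings[sel, , drop = FALSE]
    w <- fcm_elicit_weight(sub$term, sub$polarity, vocab)
    cbind(keys[i, , drop = FALSE],
          data.frame(weight = w, n_experts = nrow(sub)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
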