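# ---- weight matrices --------------------------------------------------------

#' Read and write weight matrices
#'
#' CSV files carry the concept labels as both the header row and the first
#' column, with source concepts as rows and target concepts as columns.
#' JSON files use the form `{"concepts": [...], "weights": [[...]]}` with
#' the same row/column orientation.
#'
#' @param W weight matrix.
#' @param path file path; format is chosen by extension (`.csv` or
#'   `.json`).
#' @return `read_fcm_weights` returns a validated weight matrix;
#'   `write_fcm_weights` returns `path` invisibly.
#' @export
write_fcm_weights <- function(W, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(concepts = rownames(W),
                              weights = unname(apply(W, 1, as.numeric,
                                                     simplify = FALSE))),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(W), path, row.names = TRUE)
  }
  invisible(path)
}

#' @rdname write_fcm_weights
#' @export
read_fcm_weights <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    W <- if (is.matrix(obj$weights)) obj$weights else
      matrix(as.numeric(unlist(obj$weights)),
             nrow = length(obj$concepts), byrow = TRUE)
    fcm_weights(W, obj$concepts)
  } else {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    fcm_weights(as.matrix(df), rownames(df))
  }
}

#' Read and write state vectors
#'
#' Single-row CSV keyed by concept labels.
#'
#' @param state named state vector.
#' @param path file path.
#' @return `read_fcm_state` returns a validated state vector.
#' @export
write_fcm_state <- function(state, path) {
  df <- as.data.frame(as.list(state), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fcm_state
#' @export
read_fcm_state <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  fcm_state(as.numeric(df[1L, ]), names(df))
}

# ---- trajectories -----------------------------------------------------------

#' Read and write longitudinal trajectory tables
#'
#' Two CSV dialects are supported. Wide: columns `participant_id`, `t`,
#' then one column per concept. Long: columns `participant_id`, `t`,
#' `concept`, `value`. Values must already be normalized to \[0, 1\]
#' (see [fcm_normalize()]).
#'
#' @param trajectories a named list of [fcm_trajectory()] objects, or an
#'   `fcm_cohort`.
#' @param path file path.
#' @param format `"wide"` or `"long"`.
#' @return `read_trajectories` returns a named list of trajectories in
#'   file order.
#' @export
write_trajectories <- function(trajectories, path,
                               format = c("wide", "long")) {
  format <- match.arg(format)
  if (inherits(trajectories, "fcm_cohort")) {
    trajectories <- trajectories$trajectories
  }
  rows <- lapply(trajectories, function(tr) {
    pid <- attr(tr, "participant_id")
    if (format == "wide") {
      cbind(data.frame(participant_id = pid, t = seq_len(nrow(tr)) - 1L),
            as.data.frame(unclass(tr)[seq_len(nrow(tr)), , drop = FALSE],
                          check.names = FALSE))
    } else {
      data.frame(participant_id = pid,
                 t = rep(seq_len(nrow(tr)) - 1L, times = ncol(tr)),
                 concept = rep(colnames(tr), each = nrow(tr)),
                 value = as.vector(tr))
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("participant_id", "t") %in% names(df))) {
    stop("trajectory file needs 'participant_id' and 't' columns",
         call. = FALSE)
  }
  ids <- unique(df$participant_id)
  out <- lapply(ids, function(pid) {
    sub <- df[df$participant_id == pid, , drop = FALSE]
    if (format == "long") {
      concepts <- unique(sub$concept)
      ts <- sort(unique(sub$t))
      m <- matrix(NA_real_, length(ts), length(concepts),
                  dimnames = list(NULL, concepts))
      m[cbind(match(sub$t, ts), match(sub$concept, concepts))] <- sub$value
    } else {
      sub <- sub[order(sub$t), , drop = FALSE]
      m <- as.matrix(sub[, setdiff(names(sub), c("participant_id", "t")),
                         drop = FALSE])
    }
    fcm_trajectory(m, participant_id = pid)
  })
  stats::setNames(out, ids)
}

# ---- normalization ----------------------------------------------------------

#' Declare how a raw measurement column maps to \[0, 1\]
#'
#' @param concept concept/column label.
#' @param type `"likert"` (k ordered levels 1..k mapped affinely to
#'   \[0, 1\]), `"nominal"` (explicit category -> value table) or
#'   `"continuous"` (min-max rescaling).
#' @param levels number of Likert levels (for `"likert"`).
#' @param table named numeric vector mapping categories to values in
#'   \[0, 1\] (for `"nominal"`).
#' @param min,max observed range (for `"continuous"`).
#' @return A list of class `"fcm_norm_rule"`.
#' @export
fcm_norm_rule <- function(concept,
                          type = c("likert", "nominal", "continuous"),
                          levels = 5L, table = NULL, min = 0, max = 1) {
  type <- match.arg(type)
  if (type == "nominal" &&
      (is.null(table) || is.null(names(table)) ||
       any(table < 0 | table > 1))) {
    stop("nominal rules need a named table with values in [0, 1]",
         call. = FALSE)
  }
  if (type == "continuous" && max <= min) {
    stop("continuous rules need max > min", call. = FALSE)
  }
  structure(list(concept = concept, type = type,
                 levels = as.integer(levels), table = table,
                 min = min, max = max),
            class = "fcm_norm_rule")
}

apply_norm_rule <- function(rule, x, column) {
  switch(rule$type,
    likert = {
      v <- as.numeric(x)
      bad <- which(is.na(v) | v < 1 | v > rule$levels)
      if (length(bad)) {
        stop("column '", column, "', row ", bad[1L],
             ": value outside Likert range 1..", rule$levels, call. = FALSE)
      }
      (v - 1) / (rule$levels - 1)
    },
    nominal = {
      v <- rule$table[as.character(x)]
      bad <- which(is.na(v))
      if (length(bad)) {
        stop("column '", column, "', row ", bad[1L],
             ": unmapped category '", as.character(x)[bad[1L]], "'",
             call. = FALSE)
      }
      as.numeric(v)
    },
    continuous = {
      v <- (as.numeric(x) - rule$min) / (rule$max - rule$min)
      bad <- which(is.na(v) | v < 0 | v > 1)
      if (length(bad)) {
        stop("column '", column, "', row ", bad[1L],
             ": value outside declared range", call. = FALSE)
      }
      v
    })
}

#' Normalize a raw measurement table to the \[0, 1\] state space
#'
#' Applies one [fcm_norm_rule()] per concept column. Likert values v in
#' 1..k map to (v - 1) / (k - 1); nominal categories map through their
#' declared table; continuous values are min-max rescaled. Validation
#' failures name the offending row and column and nothing is returned.
#'
#' @param raw data frame with `participant_id`, `t` and one raw column per
#'   concept.
#' @param rules list of [fcm_norm_rule()] covering every concept column.
#' @return A named list of [fcm_trajectory()] objects.
#' @export
fcm_normalize <- function(raw, rules) {
  raw <- as.data.frame(raw)
  concepts <- setdiff(names(raw), c("participant_id", "t"))
  rule_names <- vapply(rules, `[[`, character(1), "concept")
  missing <- setdiff(concepts, rule_names)
  if (length(missing)) {
    stop("no normalization rule for column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in concepts) {
    rule <- rules[[match(col, rule_names)]]
    raw[[col]] <- apply_norm_rule(rule, raw[[col]], col)
  }
  ids <- unique(raw$participant_id)
  out <- lapply(ids, function(pid) {
    sub <- raw[raw$participant_id == pid, , drop = FALSE]
    sub <- sub[order(sub$t), , drop = FALSE]
    fcm_trajectory(as.matrix(sub[, concepts, drop = FALSE]),
                   participant_id = pid)
  })
  stats::setNames(out, ids)
}

#' Map normalized values back to Likert levels
#'
#' Inverse of the Likert branch of [fcm_normalize()]: a value x in
#' \[0, 1\] returns `x * (k - 1) + 1`.
#'
#' @param x numeric vector in \[0, 1\].
#' @param levels number of Likert levels.
#' @return Numeric vector on the 1..k scale.
#' @export
fcm_denormalize_likert <- function(x, levels = 5L) {
  x * (levels - 1) + 1
}

# ---- ratings and scenarios --------------------------------------------------

#' Read an expert-ratings CSV
#'
#' Expected columns: `expert_id`, `target`, `term`, and optionally
#' `scenario` and `polarity` (+1/-1, default +1).
#'
#' @param path file path.
#' @return A validated data frame ready for [fcm_elicit_weights()].
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("expert_id", "target", "term")
  if (!all(need %in% names(df))) {
    stop("ratings file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  check_terms(df$term)
  if (is.null(df$polarity)) df$polarity <- 1L
  df
}

#' Read an intervention scenario from YAML
#'
#' The file declares `name`, optional `mode` ("continuous" or
#' "single-shot"), optional `activation`, and either an explicit `weights`
#' mapping (target concept -> signed weight) or a `ratings` path to an
#' expert-ratings CSV (resolved relative to the YAML file) to be elicited
#' with [fcm_elicit_weights()].
#'
#' @param path YAML file path.
#' @param vocab vocabulary used if the scenario elicits from ratings.
#' @return An [fcm_intervention()].
#' @export
read_scenario <- function(path, vocab = fcm_vocabulary()) {
  y <- yaml::read_yaml(path)
  if (is.null(y$name)) stop("scenario YAML needs a 'name'", call. = FALSE)
  weights <- if (!is.null(y$weights)) {
    unlist(y$weights)
  } else if (!is.null(y$ratings)) {
    rpath <- if (file.exists(y$ratings)) y$ratings else
      file.path(dirname(path), y$ratings)
    tab <- fcm_elicit_weights(read_ratings(rpath), vocab)
    stats::setNames(tab$weight, tab$target)
  } else {
    stop("scenario YAML needs 'weights' or 'ratings'", call. = FALSE)
  }
  fcm_intervention(weights, name = y$name,
                   activation = if (is.null(y$activation)) 1.0 else
                     y$activation,
                   mode = if (is.null(y$mode)) "continuous" else y$mode)
}
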