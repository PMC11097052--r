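#' Parameter grid
#'
#' @param ... named vectors of candidate values, one per parameter.
#' @return a `param_grid` object (data.frame of the cartesian product, in
#'   enumeration order: first argument varies fastest).
#' @export
param_grid <- function(...) {
  vals <- list(...)
  if (!length(vals) || is.null(names(vals)) || any(names(vals) == ""))
    stop("param_grid needs named parameter value vectors")
  if (any(vapply(vals, length, integer(1)) == 0L))
    stop("every parameter needs at least one candidate value")
  g <- expand.grid(vals, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  structure(g, class = c("param_grid", "data.frame"))
}

#' Grid-search parameter tuning against an annotated corpus
#'
#' Evaluates every parameter combination of the grid with the given detector
#' over the corpus, aggregates the per-recording panels as a single pooled
#' group and ranks combinations by the objective (the performance index by
#' default, matching the selection criterion of the validation protocol;
#' `"sensitivity_at_specificity"` ranks by sensitivity among combinations
#' meeting a specificity floor). Deterministic; ties break to the first
#' combination in enumeration order. A detector failure on a combination
#' scores `-Inf` and the search continues.
#'
#' @param algorithm registry key.
#' @param grid a [param_grid()].
#' @param corpus list of `annotated_recording` objects.
#' @param objective `"performance_index"` or `"sensitivity_at_specificity"`.
#' @param weights performance-index weights.
#' @param min_specificity specificity floor for the alternative objective.
#' @param window_s evaluation window (s).
#' @return list with `best` (named list of the best parameters),
#'   `best_objective`, and `leaderboard` (one row per combination, in
#'   enumeration order, with an `objective` column).
#' @export
grid_search <- function(algorithm, grid, corpus,
                        objective = c("performance_index",
                                      "sensitivity_at_specificity"),
                        weights = default_perf_weights(),
                        min_specificity = 0.95, window_s = 0.1) {
  objective <- match.arg(objective)
  if (!inherits(grid, "param_grid")) stop("grid must be a param_grid")
  if (!length(corpus)) stop("corpus must be nonempty")
  n_comb <- nrow(grid)
  message(sprintf("[wristgsd] grid search: %s, %d combination(s) x %d recording(s)",
                  algorithm, n_comb, length(corpus)))
  scores <- numeric(n_comb)
  for (i in seq_len(n_comb)) {
    params <- as.list(grid[i, , drop = FALSE])
    scores[i] <- tryCatch({
      panels <- evaluate_corpus(corpus, algorithm, bank = "default",
                                params_override = params, window_s = window_s)
      panels$group <- "pooled"
      summ <- summarize_group(panels, weights)
      if (objective == "performance_index") {
        summ$performance_index[1L]
      } else {
        if (is.na(summ$specificity[1L]) || summ$specificity[1L] < min_specificity)
          -Inf
        else summ$sensitivity[1L]
      }
    }, error = function(e) {
      message(sprintf("[wristgsd] combination %d failed (%s); scored -Inf",
                      i, conditionMessage(e)))
      -Inf
    })
    if (is.na(scores[i])) scores[i] <- -Inf
  }
  leaderboard <- cbind(as.data.frame(grid), objective = scores)
  best_i <- which.max(scores)  # first index on ties
  list(best = as.list(grid[best_i, , drop = FALSE]),
       best_objective = scores[best_i],
       leaderboard = leaderboard)
}
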