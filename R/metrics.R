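#' Gini coefficient of agent scores
#'
#' Inequality of a score vector, defined from the mean absolute difference
#' between all pairs of agents:
#' \deqn{G = \frac{\sum_i \sum_j |x_i - x_j|}{2 n^2 \bar{x}}}
#' computed here via the equivalent sorted-vector formula. The all-zero vector
#' (a population that has discovered nothing) is perfectly equal, so `G = 0`
#' by convention. The raw coefficient is bounded by `1 - 1/n`.
#'
#' @param x Non-negative numeric vector of per-agent scores (length >= 2).
#' @return The Gini coefficient in `[0, 1 - 1/n]`.
#' @export
gini <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("gini requires at least 2 scores")
  if (any(x < 0)) stop("gini requires non-negative scores")
  s <- sum(x)
  if (s <= 0) return(0)
  xs <- sort(x)
  (2 * sum(seq_len(n) * xs)) / (n^2 * (s / n)) - (n + 1) / n
}

#' Small-sample normalized Gini coefficient
#'
#' `gini(x) * n / (n - 1)`, which rescales the raw coefficient so that the
#' one-holder configuration (one agent owns everything) equals exactly 1
#' regardless of population size.
#'
#' @inheritParams gini
#' @return Normalized Gini in `[0, 1]`.
#' @export
normalized_gini <- function(x) {
  gini(x) * length(x) / (length(x) - 1L)
}

#' Rank-based Gini coefficient
#'
#' The Gini coefficient computed on each agent's maximum item rank (the tier
#' of its best item) instead of the tier score, a robustness variant of the
#' score-based measure.
#'
#' @param inventories Either a `potion_run` or a logical agents-by-items
#'   matrix whose column names are item names.
#' @param table Recipe table supplying item ranks; defaults to the run's
#'   table (for a `potion_run`) or the bundled table.
#' @return The Gini coefficient of the per-agent maximum rank.
#' @export
rank_gini <- function(inventories, table = NULL) {
  if (inherits(inventories, "potion_run")) {
    if (is.null(table)) table <- inventories$config$recipe_table
    inventories <- inventories$inventories
  }
  if (is.null(table)) table <- load_recipe_table()
  stopifnot(is.matrix(inventories), !is.null(colnames(inventories)))
  ranks <- table$items$rank[match(colnames(inventories), table$items$name)]
  x <- apply(inventories, 1L, function(has) max(ranks[has]))
  gini(x)
}

#' Normalized node centralities
#'
#' Degree (degree / (n - 1)), betweenness and closeness centralities, all in
#' their standard normalized `[0, 1]` forms, computed on the unweighted
#' topology.
#'
#' @param net A connected `igraph` graph.
#' @return Data frame with columns `agent`, `degree`, `betweenness`,
#'   `closeness`.
#' @export
centralities <- function(net) {
  if (!igraph::is_connected(net)) {
    stop("centralities require a connected network")
  }
  n <- igraph::vcount(net)
  data.frame(
    agent = seq_len(n),
    degree = igraph::degree(net) / (n - 1),
    betweenness = igraph::betweenness(net, weights = NA, normalized = TRUE),
    closeness = igraph::closeness(net, weights = NA, normalized = TRUE),
    row.names = NULL
  )
}

#' Centrality report for first discoverers
#'
#' Joins the run's first-discoverer identities onto node centralities. Each
#' agent gets one role: `"crossover"` if it was in the dyad that first created
#' the crossover item, else `"a_terminal"` / `"b_terminal"` for the dyads that
#' first created the trajectory terminals, else `"other"`. When the run ended
#' without a crossover the `crossover` role is absent and the report carries
#' the attribute `crossover = FALSE`.
#'
#' @param result A `potion_run`.
#' @param net Graph to compute centralities on; defaults to the run's initial
#'   network (identical to the final one when `rewire = 0`).
#' @return Data frame `agent`, `degree`, `betweenness`, `closeness`, `role`.
#' @export
innovator_report <- function(result, net = NULL) {
  stopifnot(inherits(result, "potion_run"))
  if (is.null(net)) net <- result$network
  rep <- centralities(net)
  role <- rep("other", nrow(rep))
  fd <- result$first_discoverers
  if (!is.null(fd$a_terminal)) role[fd$a_terminal] <- "a_terminal"
  if (!is.null(fd$b_terminal)) role[fd$b_terminal] <- "b_terminal"
  if (!is.null(fd$crossover)) role[fd$crossover] <- "crossover"
  rep$role <- role
  attr(rep, "crossover") <- !is.null(fd$crossover)
  rep
}

#' Inequality-persistence trace of a run
#'
#' Per-step Gini with the step axis normalized to `[0, 1]` between the first
#' step and the crossover step; the post-crossover segment (requires a run
#' with `post_crossover_steps > 0`) continues on `(1, 2]`, scaled by the
#' post-crossover horizon. On connected networks with positive diffusion the
#' post-crossover Gini decays toward zero as the crossover item saturates the
#' population.
#'
#' @param result A `potion_run` that achieved a crossover.
#' @return Data frame `step`, `time_norm`, `gini`.
#' @export
inequality_trace <- function(result) {
  stopifnot(inherits(result, "potion_run"))
  if (!result$crossover_achieved) {
    stop("inequality_trace requires a run that achieved a crossover")
  }
  cross <- result$steps_to_crossover
  post <- result$steps - cross
  step <- result$series$step
  time_norm <- ifelse(
    step <= cross,
    if (cross > 1L) (step - 1) / (cross - 1) else 1,
    1 + (step - cross) / max(post, 1L)
  )
  data.frame(step = step, time_norm = time_norm, gini = result$series$gini)
}
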