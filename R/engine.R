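# Simulation engine: dyad formation, score-weighted item selection,
# combination, diffusion, scoring, rewiring, termination.
#
# All stochastic choices use a single RNG stream (R's, governed by set.seed)
# in the fixed order documented at the top of src/engine.cpp. The pure-R
# reference implementation below consumes the stream identically, so compiled
# and reference runs of the same (config, seed) are interchangeable.

# --- shared low-level draws ------------------------------------------------

.unif_pick <- function(k) {
  j <- floor(stats::runif(1) * k)
  if (j >= k) j <- k - 1
  as.integer(j) + 1L
}

.ws_pick <- function(w) {
  u <- stats::runif(1) * sum(w)
  acc <- 0
  for (i in seq_along(w)) {
    acc <- acc + w[i]
    if (u < acc) return(i)
  }
  length(w)
}

.fy_shuffle <- function(n) {
  v <- seq_len(n)
  if (n < 2L) return(v)
  for (i in n:2) {
    j <- .unif_pick(i)
    tmp <- v[i]; v[i] <- v[j]; v[j] <- tmp
  }
  v
}

# --- configuration ---------------------------------------------------------

#' Simulation configuration
#'
#' @param network Either an `igraph` graph or a generator spec: a list with
#'   `type` one of `"er"`, `"ring"`, `"caveman"`, `"complete"`, `"edgelist"`
#'   plus the relevant parameters (`n`, `p`, `cliques`, `clique_size`, `path`,
#'   `weighted`). Generator draws (for `"er"`) use the run's seeded RNG
#'   stream, so a run is fully reproducible from `seed`.
#' @param diffusion Probability in \[0, 1\] that each neighbour lacking a
#'   freshly created item receives it (checked independently per neighbour of
#'   each dyad member, one hop only).
#' @param rewire Probability in \[0, 1\] that an agent replaces one random
#'   incident edge with an edge to a random non-neighbour at the end of each
#'   step.
#' @param max_steps Step cap; a run without a crossover stops here.
#' @param post_crossover_steps Extra steps to simulate (and record) after the
#'   crossover step, for inequality-persistence traces.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param recipe_table A `recipe_table`, or `NULL` for the bundled table.
#' @return A `sim_config` object.
#' @export
sim_config <- function(network, diffusion = 1, rewire = 0, max_steps = 1000L,
                       post_crossover_steps = 0L, seed = NULL,
                       recipe_table = NULL) {
  stopifnot(diffusion >= 0, diffusion <= 1, rewire >= 0, rewire <= 1,
            max_steps >= 1, post_crossover_steps >= 0)
  if (!igraph::is_igraph(network)) {
    if (!is.list(network) || is.null(network$type)) {
      stop("network must be an igraph graph or a spec list with a 'type' field")
    }
    ok <- c("er", "ring", "caveman", "complete", "edgelist", "karate")
    if (!network$type %in% ok) {
      stop("unknown network type '", network$type, "'; use one of: ",
           paste(ok, collapse = ", "))
    }
    num <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x)
    valid <- switch(network$type,
      er = num(network$n) && network$n >= 2 &&
        num(network$p) && network$p > 0 && network$p <= 1,
      ring = num(network$n) && network$n >= 3,
      caveman = num(network$cliques) && network$cliques >= 2 &&
        num(network$clique_size) && network$clique_size >= 2,
      complete = num(network$n) && network$n >= 2,
      edgelist = is.character(network$path) && file.exists(network$path),
      karate = TRUE
    )
    if (!valid) {
      stop("invalid or missing parameters for network type '",
           network$type, "'")
    }
  }
  if (is.null(recipe_table)) recipe_table <- load_recipe_table()
  structure(list(
    network = network, diffusion = diffusion, rewire = rewire,
    max_steps = as.integer(max_steps),
    post_crossover_steps = as.integer(post_crossover_steps),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    recipe_table = recipe_table
  ), class = "sim_config")
}

resolve_network <- function(network) {
  if (igraph::is_igraph(network)) return(network)
  switch(network$type,
    er = make_random_network(network$n, network$p),
    ring = make_ring(network$n),
    caveman = make_connected_caveman(network$cliques, network$clique_size),
    complete = igraph::make_full_graph(network$n),
    edgelist = load_edge_list(network$path, isTRUE(network$weighted)),
    karate = karate_club()
  )
}

engine_inputs <- function(tab) {
  items <- tab$items
  if (nrow(items) > 32L) stop("recipe tables are limited to 32 items")
  ing <- cbind(match(tab$recipes$i1, items$name),
               match(tab$recipes$i2, items$name),
               match(tab$recipes$i3, items$name))
  ter <- items[items$tier == 3L, , drop = FALSE]
  list(
    ing = ing,
    prod = match(tab$recipes$product, items$name),
    item_w = items$innovation_score,
    item_ts = items$tier_score,
    item_rank = items$rank,
    basics = items$id[items$tier == 0L],
    a_term = ter$id[1L], b_term = ter$id[2L],
    cross = items$id[items$tier == 4L],
    names = items$name, m = nrow(items),
    max_score = max(items$tier_score)
  )
}

# --- exported model operations --------------------------------------------

#' Choose a partner for a focal agent
#'
#' Uniform over the focal agent's neighbours on unweighted networks;
#' proportional to incident edge weight on weighted networks. Several focal
#' agents may pick the same partner within a step.
#'
#' @param net An `igraph` graph.
#' @param focal Vertex id of the focal agent.
#' @return A neighbour's vertex id, or `NA` when the focal agent is isolated
#'   (the agent then skips its turn).
#' @export
select_partner <- function(net, focal) {
  A <- as_adjacency(net)
  nb <- A$adj[[focal]]
  if (length(nb) == 0L) return(NA_integer_)
  if (A$weighted) nb[.ws_pick(A$wadj[[focal]])] else nb[.unif_pick(length(nb))]
}

#' Split a triad between focal agent and partner
#'
#' The focal agent contributes one or two of the three combined items with
#' equal probability; the partner provides the remainder.
#'
#' @return Named integer vector `c(focal = ., partner = .)` summing to 3.
#' @export
split_contribution <- function() {
  if (stats::runif(1) < 0.5) c(focal = 1L, partner = 2L) else c(focal = 2L, partner = 1L)
}

#' Item-selection probabilities over an inventory
#'
#' Each item's probability is its innovation score divided by the inventory's
#' score sum, so higher-tier discoveries dominate later draws — the mechanism
#' behind the task's path dependency.
#'
#' @param inventory A data frame of items with columns `name` and
#'   `innovation_score` (e.g. from [initial_inventory()]).
#' @return Named numeric vector of probabilities summing to 1.
#' @export
selection_weights <- function(inventory) {
  stopifnot(nrow(inventory) >= 1L)
  w <- inventory$innovation_score / sum(inventory$innovation_score)
  names(w) <- inventory$name
  w
}

#' Draw items from an inventory without replacement
#'
#' Sequential draws, each proportional to the innovation scores of the items
#' still in the pool.
#'
#' @param inventory Item data frame (columns `name`, `innovation_score`, ...).
#' @param k Number of items to draw (1 or 2 in the model).
#' @return A `k`-row data frame of the drawn items.
#' @export
sample_items <- function(inventory, k) {
  if (k > nrow(inventory)) stop("cannot draw ", k, " items from an inventory of ",
                                nrow(inventory))
  pool <- seq_len(nrow(inventory))
  pw <- inventory$innovation_score
  take <- integer(k)
  for (t in seq_len(k)) {
    idx <- .ws_pick(pw)
    take[t] <- pool[idx]
    pool <- pool[-idx]
    pw <- pw[-idx]
  }
  inventory[take, , drop = FALSE]
}

#' Attempt one triad combination between two agents
#'
#' Composes [split_contribution()] and [sample_items()] from each inventory.
#' If the three drawn names are distinct and match a recipe, the product is
#' added to both inventories (a no-op for an agent already holding it).
#' A draw in which the partner supplies a name the focal agent also drew has
#' fewer than three distinct names and is invalid.
#'
#' @param focal_inventory,partner_inventory Item data frames.
#' @param table A validated `recipe_table`.
#' @return A list with `item` (one-row data frame or `NULL`),
#'   `focal_inventory` and `partner_inventory` (possibly extended).
#' @export
attempt_combination <- function(focal_inventory, partner_inventory, table) {
  split <- split_contribution()
  mine <- sample_items(focal_inventory, split[["focal"]])
  theirs <- sample_items(partner_inventory, split[["partner"]])
  triad <- c(mine$name, theirs$name)
  item <- if (anyDuplicated(triad)) NULL else lookup_combination(table, triad)
  if (!is.null(item)) {
    if (!item$name %in% focal_inventory$name) {
      focal_inventory <- rbind(focal_inventory, item)
    }
    if (!item$name %in% partner_inventory$name) {
      partner_inventory <- rbind(partner_inventory, item)
    }
  }
  list(item = item, focal_inventory = focal_inventory,
       partner_inventory = partner_inventory)
}

#' Diffuse a freshly created item from a dyad to its neighbours
#'
#' For each dyad member in turn, every neighbour not yet holding the item
#' receives it with independent probability `d`. One hop only: recipients do
#' not re-diffuse. Diffusion ignores edge weights.
#'
#' @param net An `igraph` graph.
#' @param dyad Integer vector of the two creating agents' vertex ids.
#' @param has_item Logical vector over all vertices: who already holds the
#'   item.
#' @param d Diffusion probability in \[0, 1\].
#' @return Integer vector of recipient vertex ids (possibly empty).
#' @export
diffuse_item <- function(net, dyad, has_item, d) {
  if (d <= 0) return(integer(0))
  A <- as_adjacency(net)
  recipients <- integer(0)
  for (mb in dyad) {
    for (v in A$adj[[mb]]) {
      if (!has_item[v] && stats::runif(1) < d) {
        has_item[v] <- TRUE
        recipients <- c(recipients, v)
      }
    }
  }
  recipients
}

#' Rewire one of an agent's edges
#'
#' With probability `r` the agent removes a uniformly random incident edge
#' and adds an edge to a uniformly random non-neighbour; its degree and the
#' total edge count are conserved. No-op when the agent is isolated or has no
#' non-neighbours (complete graph). On weighted graphs the new edge inherits
#' the removed edge's weight. A rewire may disconnect the graph; the model
#' tolerates this (isolated agents skip their turn).
#'
#' @param net An `igraph` graph.
#' @param agent Vertex id.
#' @param r Rewiring probability in \[0, 1\].
#' @return The (possibly modified) graph.
#' @export
rewire_agent <- function(net, agent, r) {
  if (r <= 0) return(net)
  if (stats::runif(1) >= r) return(net)
  A <- as_adjacency(net)
  nb <- A$adj[[agent]]
  deg <- length(nb)
  if (deg == 0L) return(net)
  nonnb <- setdiff(seq_len(A$n), c(agent, nb))
  if (length(nonnb) == 0L) return(net)
  ei <- .unif_pick(deg)
  old <- nb[ei]
  nw <- nonnb[.unif_pick(length(nonnb))]
  wgt <- if (A$weighted) A$wadj[[agent]][ei] else NULL
  net <- igraph::delete_edges(net, igraph::get_edge_ids(net, c(agent, old)))
  net <- igraph::add_edges(net, c(agent, nw))
  if (A$weighted) {
    igraph::E(net)$weight[igraph::ecount(net)] <- wgt
  }
  net
}

# --- reference engine ------------------------------------------------------

#' Initialize simulation state
#'
#' Builds the full mutable state consumed by [sim_step()]: the resolved
#' network's adjacency lists, one inventory per agent (the six basics), zero
#' scores, and empty metric series. Called by [run_potions()]; exported so
#' the epoch dynamics can be driven and inspected step by step.
#'
#' @param config A [sim_config()] (its `seed` is applied here when set).
#' @return An environment of class `potion_state`.
#' @export
sim_init <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  net <- resolve_network(config$network)
  A <- as_adjacency(net)
  ei <- engine_inputs(config$recipe_table)

  lk <- rep(-1L, 32768L)
  for (k in seq_len(nrow(ei$ing))) {
    t <- sort(ei$ing[k, ]) - 1L
    key <- bitwOr(bitwOr(bitwShiftL(t[1L], 10L), bitwShiftL(t[2L], 5L)), t[3L])
    lk[key + 1L] <- ei$prod[k]
  }

  st <- new.env(parent = emptyenv())
  st$net0 <- net
  st$adj <- A$adj; st$wadj <- A$wadj
  st$weighted <- A$weighted; st$n <- A$n
  st$ei <- ei; st$lookup <- lk
  st$inv <- matrix(FALSE, A$n, ei$m)
  st$inv[, ei$basics] <- TRUE
  st$score <- numeric(A$n)
  st$discovered <- logical(ei$m)
  st$first_a <- integer(0); st$first_b <- integer(0); st$first_x <- integer(0)
  st$d <- config$diffusion; st$r <- config$rewire
  st$max_steps <- config$max_steps; st$post_steps <- config$post_crossover_steps
  st$steps <- 0L; st$crossed <- FALSE; st$cross_step <- NA_integer_
  st$post_left <- -1L; st$done <- FALSE
  st$mean_s <- numeric(0); st$gini_s <- numeric(0); st$max_s <- numeric(0)
  class(st) <- c("potion_state", "environment")
  st
}

#' Advance the simulation by one step (epoch)
#'
#' One epoch: every agent acts once as focal in a freshly shuffled order
#' (partner choice, triad combination, diffusion on success); then, when the
#' rewiring probability is positive, each agent independently rewires in a
#' second shuffled order; then per-step metrics (mean score, Gini, max score)
#' are recorded and termination is evaluated.
#'
#' @param st A `potion_state` from [sim_init()]; modified in place.
#' @return The state, invisibly.
#' @export
sim_step <- function(st) {
  if (st$done) return(invisible(st))
  st$steps <- st$steps + 1L
  n <- st$n; ei <- st$ei
  item_w <- ei$item_w; item_ts <- ei$item_ts
  d <- st$d

  order1 <- .fy_shuffle(n)
  for (focal in order1) {
    nb <- st$adj[[focal]]
    deg <- length(nb)
    if (deg == 0L) next
    partner <- if (st$weighted) nb[.ws_pick(st$wadj[[focal]])] else nb[.unif_pick(deg)]

    kf <- if (stats::runif(1) < 0.5) 1L else 2L
    who <- c(focal, partner); kk <- c(kf, 3L - kf)
    triad <- integer(3); nd <- 0L
    for (s in 1:2) {
      pool <- which(st$inv[who[s], ])
      pw <- item_w[pool]
      for (t in seq_len(kk[s])) {
        idx <- .ws_pick(pw)
        nd <- nd + 1L
        triad[nd] <- pool[idx]
        pool <- pool[-idx]; pw <- pw[-idx]
      }
    }
    tt <- sort(triad)
    if (tt[1L] == tt[2L] || tt[2L] == tt[3L]) next
    key <- bitwOr(bitwOr(bitwShiftL(tt[1L] - 1L, 10L),
                         bitwShiftL(tt[2L] - 1L, 5L)), tt[3L] - 1L)
    pr <- st$lookup[key + 1L]
    if (pr < 0L) next

    if (!st$discovered[pr]) {
      st$discovered[pr] <- TRUE
      if (pr == ei$a_term) st$first_a <- c(focal, partner)
      if (pr == ei$b_term) st$first_b <- c(focal, partner)
      if (pr == ei$cross) { st$first_x <- c(focal, partner); st$crossed <- TRUE }
    }
    for (ag in who) {
      if (!st$inv[ag, pr]) {
        st$inv[ag, pr] <- TRUE
        if (item_ts[pr] > st$score[ag]) st$score[ag] <- item_ts[pr]
      }
    }
    if (d > 0) {
      for (ag in who) {
        for (v in st$adj[[ag]]) {
          if (!st$inv[v, pr] && stats::runif(1) < d) {
            st$inv[v, pr] <- TRUE
            if (item_ts[pr] > st$score[v]) st$score[v] <- item_ts[pr]
          }
        }
      }
    }
  }

  if (st$r > 0) {
    order2 <- .fy_shuffle(n)
    for (a in order2) {
      if (stats::runif(1) >= st$r) next
      nb <- st$adj[[a]]
      deg <- length(nb)
      if (deg == 0L) next
      nonnb <- setdiff(seq_len(n), c(a, nb))
      if (length(nonnb) == 0L) next
      ei2 <- .unif_pick(deg)
      old <- nb[ei2]
      nw <- nonnb[.unif_pick(length(nonnb))]
      wgt <- if (st$weighted) st$wadj[[a]][ei2] else 1
      st$adj[[a]] <- st$adj[[a]][-ei2]
      pos <- match(a, st$adj[[old]])
      st$adj[[old]] <- st$adj[[old]][-pos]
      st$adj[[a]] <- c(st$adj[[a]], nw)
      st$adj[[nw]] <- c(st$adj[[nw]], a)
      if (st$weighted) {
        st$wadj[[a]] <- c(st$wadj[[a]][-ei2], wgt)
        st$wadj[[old]] <- st$wadj[[old]][-pos]
        st$wadj[[nw]] <- c(st$wadj[[nw]], wgt)
      }
    }
  }

  st$mean_s <- c(st$mean_s, mean(st$score))
  st$gini_s <- c(st$gini_s, gini(st$score))
  st$max_s <- c(st$max_s, max(st$score))

  if (st$crossed) {
    if (is.na(st$cross_step)) {
      st$cross_step <- st$steps
      st$post_left <- st$post_steps
    } else if (st$post_left > 0L) {
      st$post_left <- st$post_left - 1L
    }
    if (st$post_left == 0L) st$done <- TRUE
  } else if (st$steps >= st$max_steps) {
    st$done <- TRUE
  }
  invisible(st)
}

run_reference <- function(config) {
  st <- sim_init(config)
  while (!st$done) sim_step(st)
  list(steps = st$steps, crossover_achieved = st$crossed,
       crossover_step = st$cross_step,
       mean_series = st$mean_s, gini_series = st$gini_s, max_series = st$max_s,
       scores = st$score, inventory = st$inv,
       first_a = st$first_a, first_b = st$first_b, first_x = st$first_x,
       adj_final = st$adj,
       wadj_final = if (st$weighted) st$wadj else NULL,
       net0 = st$net0)
}

# --- full run --------------------------------------------------------------

#' Run one Potions Task simulation
#'
#' Initializes the network and agents, iterates epochs until some agent holds
#' the crossover item or `max_steps` is reached, then (optionally) continues
#' for `post_crossover_steps` recorded steps.
#'
#' @param config A [sim_config()].
#' @param engine `"compiled"` (default) runs the C++ core; `"reference"` runs
#'   the pure-R engine. Both consume the RNG stream identically, so results
#'   for equal (config, seed) agree.
#' @return A `potion_run` object: `steps`, `crossover_achieved`,
#'   `steps_to_crossover`, `series` (per-step `mean_score`, `gini`,
#'   `max_score`), final `scores`, `inventories` (agents x items logical
#'   matrix), `first_discoverers` (dyads that first created the A terminal,
#'   B terminal and crossover items; diffusion recipients excluded),
#'   `combinations` (= steps x n), `network` (initial graph),
#'   `final_adjacency`, `seed` and `config`.
#' @examples
#' cfg <- sim_config(network = list(type = "complete", n = 5), seed = 1)
#' run_potions(cfg)
#' @export
run_potions <- function(config, engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "sim_config"))

  if (engine == "reference") {
    res <- run_reference(config)
    net <- res$net0
  } else {
    if (!is.null(config$seed)) set.seed(config$seed)
    net <- resolve_network(config$network)
    A <- as_adjacency(net)
    ei <- engine_inputs(config$recipe_table)
    res <- run_engine_cpp(
      lapply(A$adj, as.integer),
      if (A$weighted) A$wadj else NULL,
      ei$ing, as.integer(ei$prod),
      ei$item_w, ei$item_ts, as.integer(ei$basics),
      config$diffusion, config$rewire,
      config$max_steps, config$post_crossover_steps,
      as.integer(ei$a_term), as.integer(ei$b_term), as.integer(ei$cross))
  }

  ei <- engine_inputs(config$recipe_table)
  inv <- res$inventory
  colnames(inv) <- ei$names
  fd <- list(
    a_terminal = if (length(res$first_a)) as.integer(res$first_a) else NULL,
    b_terminal = if (length(res$first_b)) as.integer(res$first_b) else NULL,
    crossover = if (length(res$first_x)) as.integer(res$first_x) else NULL
  )
  structure(list(
    steps = as.integer(res$steps),
    crossover_achieved = isTRUE(res$crossover_achieved),
    steps_to_crossover = if (is.na(res$crossover_step)) NA_integer_ else
      as.integer(res$crossover_step),
    series = data.frame(step = seq_len(res$steps),
                        mean_score = res$mean_series,
                        gini = res$gini_series,
                        max_score = res$max_series),
    scores = as.numeric(res$scores),
    inventories = inv,
    first_discoverers = fd,
    combinations = as.integer(res$steps) * igraph::vcount(net),
    n = igraph::vcount(net),
    network = net,
    final_adjacency = res$adj_final,
    seed = config$seed,
    config = config,
    engine = engine
  ), class = "potion_run")
}

#' @export
print.potion_run <- function(x, ...) {
  cat(sprintf("Potions Task run: n = %d agents, %d steps (%d combinations)\n",
              x$n, x$steps, x$combinations))
  if (x$crossover_achieved) {
    cat(sprintf("  crossover at step %d; final Gini %.3f, mean score %.1f\n",
                x$steps_to_crossover,
                x$series$gini[nrow(x$series)],
                x$series$mean_score[nrow(x$series)]))
  } else {
    cat(sprintf("  no crossover within %d steps (max score %.0f)\n",
                x$steps, max(x$scores)))
  }
  invisible(x)
}

#' Flatten a run to a one-row summary data frame
#'
#' @param x A `potion_run`.
#' @param row.names,optional,... Standard [as.data.frame()] arguments, unused.
#' @return One-row data frame with the end-of-run summary columns used by the
#'   batch runner.
#' @export
as.data.frame.potion_run <- function(x, row.names = NULL, optional = FALSE, ...) {
  last <- nrow(x$series)
  data.frame(
    n = x$n,
    steps = x$steps,
    steps_to_crossover = x$steps_to_crossover,
    crossover_achieved = x$crossover_achieved,
    combinations = x$combinations,
    gini = if (last) x$series$gini[last] else NA_real_,
    gini_normalized = if (last) x$series$gini[last] * x$n / (x$n - 1) else NA_real_,
    gini_rank = rank_gini(x),
    mean_score = if (last) x$series$mean_score[last] else NA_real_,
    max_score = if (last) x$series$max_score[last] else NA_real_,
    seed = if (is.null(x$seed)) NA_integer_ else x$seed
  )
}
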