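# Batch experiment runner: parameter sweeps with deterministic per-replicate
# seeding, presets mirroring the study's figure/table conditions, and
# group-wise summaries.

# Counter-based replicate seed: a couple of Lehmer-style mixing rounds over
# (base_seed, cell, replicate), all arithmetic exact in doubles and the result
# kept inside the 32-bit signed range R accepts in set.seed().
derive_seed <- function(base_seed, cell, replicate) {
  m <- 2147483647
  s <- (abs(base_seed) %% m)
  s <- (s * 48271 + cell * 69621 + replicate * 16807 + 1) %% m
  s <- (s * 16807 + 12345) %% m
  as.integer(s)
}

#' Specify a parameter sweep
#'
#' @param cells Data frame with one row per parameter combination. Recognized
#'   columns: `network` (`"er"`, `"ring"`, `"caveman"`, `"complete"`,
#'   `"edgelist"`), `n`, `p`, `cliques`, `clique_size`, `path`, `weighted`,
#'   `diffusion`, `rewire`, `max_steps`, `post_crossover_steps`. Missing
#'   dynamics columns default to diffusion 1, rewire 0, 1000 steps, 0 post
#'   steps.
#' @param replicates Replicates per cell.
#' @param base_seed Base seed; each replicate's seed is derived
#'   deterministically from (base seed, cell index, replicate index), so runs
#'   are reproducible and order-independent.
#' @return A `sweep_spec` object.
#' @export
sweep_spec <- function(cells, replicates = 100L, base_seed = 1L) {
  stopifnot(is.data.frame(cells), replicates >= 1)
  if (is.null(cells$network)) stop("cells must have a 'network' column")
  structure(list(cells = cells, replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed)),
            class = "sweep_spec")
}

cell_config <- function(cell, seed, table) {
  g <- function(f, default = NULL) {
    v <- cell[[f]]
    if (is.null(v) || length(v) == 0L || is.na(v)) default else v
  }
  netspec <- switch(as.character(cell$network),
    er = list(type = "er", n = g("n"), p = g("p")),
    karate = list(type = "karate"),
    ring = list(type = "ring", n = g("n")),
    caveman = list(type = "caveman", cliques = g("cliques"),
                   clique_size = g("clique_size")),
    complete = list(type = "complete", n = g("n")),
    edgelist = list(type = "edgelist", path = g("path"),
                    weighted = isTRUE(g("weighted", FALSE))),
    stop("unknown network type in sweep cell: ", cell$network)
  )
  sim_config(
    network = netspec,
    diffusion = g("diffusion", 1),
    rewire = g("rewire", 0),
    max_steps = g("max_steps", 1000L),
    post_crossover_steps = g("post_crossover_steps", 0L),
    seed = seed,
    recipe_table = table
  )
}

#' Run a parameter sweep
#'
#' Runs every (cell, replicate) pair independently with its derived seed and
#' stacks the one-row run summaries. Deterministic given the sweep's base seed:
#' the same spec always yields an identical table.
#'
#' @param spec A [sweep_spec()] (or a preset from [preset()]).
#' @param engine Engine passed to [run_potions()].
#' @param recipe_table Recipe table shared by all runs (`NULL` = bundled).
#' @param keep_runs If `TRUE`, the full `potion_run` objects are attached as
#'   the `"runs"` attribute (needed for centrality aggregation).
#' @param progress Print one line per cell to stderr.
#' @return A `ResultsTable` data frame: one row per replicate with the cell's
#'   configuration columns, `cell`, `replicate`, `seed`, `steps`,
#'   `steps_to_crossover`, `crossover_achieved`, `combinations`, `gini`,
#'   `gini_normalized`, `gini_rank`, `mean_score`, `max_score`.
#' @export
run_sweep <- function(spec, engine = c("compiled", "reference"),
                      recipe_table = NULL, keep_runs = FALSE,
                      progress = FALSE) {
  engine <- match.arg(engine)
  stopifnot(inherits(spec, "sweep_spec"))
  if (is.null(recipe_table)) recipe_table <- load_recipe_table()
  cells <- spec$cells
  header <- c("cell", "replicate", "seed", names(cells), "n", "steps",
              "steps_to_crossover", "crossover_achieved", "combinations",
              "gini", "gini_normalized", "gini_rank", "mean_score", "max_score")
  if (nrow(cells) == 0L) {
    out <- as.data.frame(matrix(nrow = 0L, ncol = length(header)))
    names(out) <- header
    return(out)
  }
  # fail fast: resolvable configuration for every cell
  for (ci in seq_len(nrow(cells))) {
    cell_config(cells[ci, , drop = FALSE], seed = 1L, table = recipe_table)
  }
  rows <- vector("list", nrow(cells) * spec$replicates)
  runs <- if (keep_runs) vector("list", length(rows)) else NULL
  k <- 0L
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, , drop = FALSE]
    if (progress) message(sprintf("cell %d/%d: %s", ci, nrow(cells),
                                  paste(names(cell), unlist(cell),
                                        sep = "=", collapse = " ")))
    for (ri in seq_len(spec$replicates)) {
      sd <- derive_seed(spec$base_seed, ci, ri)
      cfg <- cell_config(cell, seed = sd, table = recipe_table)
      run <- run_potions(cfg, engine = engine)
      row <- as.data.frame(run)
      meta <- cell
      rownames(meta) <- NULL
      row <- cbind(data.frame(cell = ci, replicate = ri), meta,
                   row[setdiff(names(row), c("seed", names(meta)))],
                   data.frame(seed = sd))
      k <- k + 1L
      rows[[k]] <- row
      if (keep_runs) runs[[k]] <- run
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_runs) attr(out, "runs") <- runs
  out
}

#' Experiment presets mirroring the study conditions
#'
#' Returns the parameter grid for a named experiment at a desk-scale replicate
#' count (default 100; the original analyses used 1000 per cell, available via
#' `replicates = 1000`).
#'
#' * `fig2_connectivity` — Erdos-Renyi networks, population sizes 25/50/100,
#'   edge probabilities 0.05/0.1/0.5/1, diffusion 1, no rewiring.
#' * `fig2_diffusion` — complete networks, sizes 25/50/100, diffusion
#'   0.1/0.25/0.5/1, no rewiring.
#' * `fig2_rewire` — Erdos-Renyi (p = 0.05), sizes 25/50/100, rewiring
#'   0/0.25/0.5/1, diffusion 1.
#' * `fig3_percapita` — Erdos-Renyi (p = 0.3), sizes 15/30/60, step cap
#'   10000 so essentially every run completes; per-capita combination counts.
#' * `fig4_persistence` — Erdos-Renyi, n = 50, p in 0.1/0.3/1, 100 recorded
#'   post-crossover steps.
#' * `fig5_centrality` — Erdos-Renyi, n = 100, p = 0.05 (the centrality
#'   condition).
#' * `table1_realworld` — the six real-world networks; the karate club is
#'   built in, the other five require edge-list files named `baboon.csv`,
#'   `chimp.csv`, `coastal_agta.csv`, `forest_agta.csv`, `department.csv`
#'   under `data_dir` (cells whose file is missing are dropped with a
#'   warning).
#' * `caveman_cliques` — connected caveman networks of 48 agents,
#'   (cliques, clique size) in (12,4), (8,6), (6,8), (4,12).
#'
#' @param name Preset name.
#' @param replicates Replicates per cell.
#' @param base_seed Base seed for [sweep_spec()].
#' @param data_dir Directory with real-world edge lists (only used by
#'   `table1_realworld`).
#' @return A `sweep_spec`.
#' @export
preset <- function(name, replicates = 100L, base_seed = 1L, data_dir = NULL) {
  known <- c("fig2_connectivity", "fig2_diffusion", "fig2_rewire",
             "fig3_percapita", "fig4_persistence", "fig5_centrality",
             "table1_realworld", "caveman_cliques")
  if (!name %in% known) {
    stop("unknown preset '", name, "'; available: ",
         paste(known, collapse = ", "))
  }
  cells <- switch(name,
    fig2_connectivity = expand.grid(network = "er", n = c(25L, 50L, 100L),
                                    p = c(0.05, 0.1, 0.5, 1),
                                    diffusion = 1, rewire = 0,
                                    stringsAsFactors = FALSE),
    fig2_diffusion = expand.grid(network = "complete", n = c(25L, 50L, 100L),
                                 diffusion = c(0.1, 0.25, 0.5, 1), rewire = 0,
                                 stringsAsFactors = FALSE),
    fig2_rewire = expand.grid(network = "er", n = c(25L, 50L, 100L), p = 0.05,
                              diffusion = 1, rewire = c(0, 0.25, 0.5, 1),
                              stringsAsFactors = FALSE),
    fig3_percapita = expand.grid(network = "er", n = c(15L, 30L, 60L), p = 0.3,
                                 diffusion = 1, rewire = 0,
                                 max_steps = 10000L,
                                 stringsAsFactors = FALSE),
    fig4_persistence = expand.grid(network = "er", n = 50L,
                                   p = c(0.1, 0.3, 1),
                                   diffusion = 1, rewire = 0,
                                   post_crossover_steps = 100L,
                                   stringsAsFactors = FALSE),
    fig5_centrality = data.frame(network = "er", n = 100L, p = 0.05,
                                 diffusion = 1, rewire = 0,
                                 stringsAsFactors = FALSE),
    table1_realworld = {
      nets <- data.frame(
        label = c("baboon", "chimp", "karate_club", "coastal_agta",
                  "forest_agta", "department"),
        weighted = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
        stringsAsFactors = FALSE
      )
      paths <- character(nrow(nets))
      keep <- logical(nrow(nets))
      for (i in seq_len(nrow(nets))) {
        if (nets$label[i] == "karate_club") {
          keep[i] <- TRUE
          paths[i] <- NA_character_
        } else {
          f <- if (is.null(data_dir)) "" else
            file.path(data_dir, paste0(nets$label[i], ".csv"))
          if (nzchar(f) && file.exists(f)) {
            keep[i] <- TRUE
            paths[i] <- f
          }
        }
      }
      if (any(!keep)) {
        warning("edge list(s) not found, cell(s) dropped: ",
                paste(nets$label[!keep], collapse = ", "), call. = FALSE)
      }
      cells <- data.frame(
        network = ifelse(is.na(paths[keep]), "karate", "edgelist"),
        label = nets$label[keep], path = paths[keep],
        weighted = nets$weighted[keep],
        diffusion = 1, rewire = 0, max_steps = 1000L,
        stringsAsFactors = FALSE
      )
      cells
    },
    caveman_cliques = data.frame(network = "caveman",
                                 cliques = c(12L, 8L, 6L, 4L),
                                 clique_size = c(4L, 6L, 8L, 12L),
                                 diffusion = 1, rewire = 0,
                                 stringsAsFactors = FALSE)
  )
  sweep_spec(cells, replicates = replicates, base_seed = base_seed)
}

#' Group-wise summary of a results table
#'
#' Per group: replicate count, crossover success rate, and mean/standard error
#' of steps-to-crossover (capped runs excluded), combinations-to-crossover and
#' each end-of-run Gini variant. Groups with a single (or no) completed run get
#' `se_* = NA`.
#'
#' @param table A results table from [run_sweep()].
#' @param group_by Character vector of grouping column names.
#' @return A summary data frame, one row per group.
#' @export
summarize_results <- function(table, group_by) {
  stopifnot(is.data.frame(table), nrow(table) > 0L)
  missing_cols <- setdiff(group_by, names(table))
  if (length(missing_cols) > 0L) {
    stop("unknown grouping column(s): ", paste(missing_cols, collapse = ", "))
  }
  key <- interaction(table[group_by], drop = TRUE, lex.order = TRUE)
  groups <- split(table, key)
  se <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  rows <- lapply(groups, function(gdf) {
    done <- gdf[gdf$crossover_achieved, , drop = FALSE]
    cbind(
      gdf[1L, group_by, drop = FALSE],
      data.frame(
        replicates = nrow(gdf),
        crossover_rate = mean(gdf$crossover_achieved),
        mean_steps = if (nrow(done)) mean(done$steps_to_crossover) else NA_real_,
        se_steps = se(done$steps_to_crossover),
        mean_combinations = if (nrow(done))
          mean(done$steps_to_crossover * done$n) else NA_real_,
        se_combinations = se(done$steps_to_crossover * done$n),
        mean_gini = mean(gdf$gini),
        se_gini = se(gdf$gini),
        mean_gini_normalized = mean(gdf$gini_normalized),
        mean_gini_rank = mean(gdf$gini_rank)
      )
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Deterministic test fixtures
#'
#' @param kind One of `"toy_recipes"` (the bundled, structurally valid recipe
#'   table), `"toy_network"` (a fixed 6-node connected graph), `"tiny_run"`
#'   (a completed 2-agent run with a fixed seed).
#' @return The fixture object.
#' @export
make_fixture <- function(kind) {
  switch(kind,
    toy_recipes = load_recipe_table(),
    toy_network = igraph::make_graph(c(1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6, 1, 1, 4),
                                n = 6, directed = FALSE),
    tiny_run = run_potions(sim_config(network = list(type = "complete", n = 2),
                                      seed = 20231122L)),
    stop("unknown fixture kind '", kind,
         "'; use toy_recipes, toy_network or tiny_run")
  )
}
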