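tab <- load_recipe_table()

test_that("selection weights are score-proportional", {
  w <- selection_weights(initial_inventory(tab))
  expect_equal(sum(w), 1)
  expect_equal(unname(round(w, 3)), c(0.125, 0.167, 0.208, 0.125, 0.167, 0.208))
  one <- initial_inventory(tab)[3, ]
  expect_equal(unname(selection_weights(one)), 1)
  toy <- data.frame(name = c("x", "y", "z"), innovation_score = c(1, 1, 2))
  expect_equal(unname(selection_weights(toy)), c(0.25, 0.25, 0.5))
})

test_that("the focal/partner split is fair and always sums to three", {
  set.seed(11)
  draws <- t(replicate(10000, split_contribution()))
  expect_true(all(rowSums(draws) == 3))
  expect_true(all(draws[, "focal"] %in% 1:2))
  f1 <- mean(draws[, "focal"] == 1)
  expect_lt(abs(f1 - 0.5), 3 * sqrt(0.25 / 10000))
  set.seed(99); a <- replicate(20, split_contribution()[["focal"]])
  set.seed(99); b <- replicate(20, split_contribution()[["focal"]])
  expect_identical(a, b)
})

test_that("item draws without replacement match exhaustive enumeration", {
  toy <- data.frame(name = c("x", "y", "z"), innovation_score = c(1, 1, 2))
  # exact ordered-draw law: P(first = i) = w_i/W, P(second = j | i) renormalized
  w <- c(x = 1, y = 1, z = 2)
  exact <- c()
  for (i in names(w)) for (j in setdiff(names(w), i)) {
    exact[paste(i, j)] <- (w[i] / sum(w)) * (w[j] / (sum(w) - w[i]))
  }
  expect_equal(unname(exact["z x"]), 0.25)
  set.seed(21)
  reps <- 20000
  obs <- table(replicate(reps, paste(sample_items(toy, 2)$name, collapse = " ")))
  for (k in names(exact)) {
    p <- exact[k]
    expect_lt(abs(obs[k] / reps - p), 4 * sqrt(p * (1 - p) / reps))
  }
  # k = 1 from the initial inventory: P(a3) = 10/48
  set.seed(22)
  inv <- initial_inventory(tab)
  hits <- mean(replicate(20000, sample_items(inv, 1)$name) == "a3")
  expect_lt(abs(hits - 10 / 48), 4 * sqrt((10 / 48) * (38 / 48) / 20000))
  # forced draw and impossible draw
  expect_setequal(sample_items(toy[1:2, ], 2)$name, c("x", "y"))
  expect_error(sample_items(toy, 4), "cannot draw")
})

test_that("partner choice is uniform when unweighted, weight-proportional when weighted", {
  star <- igraph::make_star(4, mode = "undirected", center = 1)
  expect_equal(select_partner(star, 2), 1L)      # single neighbour
  set.seed(31)
  picks <- replicate(9000, select_partner(star, 1))
  for (v in 2:4) {
    expect_lt(abs(mean(picks == v) - 1 / 3), 4 * sqrt((1 / 3) * (2 / 3) / 9000))
  }
  wg <- igraph::make_graph(c(1, 2, 1, 3), n = 3, directed = FALSE)
  igraph::E(wg)$weight <- c(1, 3)
  set.seed(32)
  wp <- replicate(9000, select_partner(wg, 1))
  expect_lt(abs(mean(wp == 3) - 0.75), 4 * sqrt(0.75 * 0.25 / 9000))
  lonely <- igraph::make_graph(c(1, 2), n = 3, directed = FALSE)
  expect_true(is.na(select_partner(lonely, 3)))  # isolated: skip signal
})

test_that("attempt_combination only ever creates recipe products and grows both inventories", {
  set.seed(41)
  inv <- initial_inventory(tab)
  f <- inv; p <- inv
  created <- character(0)
  for (i in 1:300) {
    out <- attempt_combination(f, p, tab)
    if (is.null(out$item)) {
      expect_identical(out$focal_inventory$name, f$name)
      expect_identical(out$partner_inventory$name, p$name)
    } else {
      expect_true(out$item$name %in% tab$recipes$product)
      expect_true(out$item$name %in% out$focal_inventory$name)
      expect_true(out$item$name %in% out$partner_inventory$name)
      created <- c(created, out$item$name)
    }
    f <- out$focal_inventory; p <- out$partner_inventory
    # inventories only grow and never leave the recipe closure
    expect_true(all(inv$name %in% f$name))
    expect_true(all(f$name %in% tab$items$name))
  }
  expect_gt(length(created), 0)
  # from the six basics the first creation is always a tier-1 item
  expect_true(tab$items$tier[tab$items$name == created[1]] == 1)
})

test_that("diffusion is one-hop, per-neighbour Bernoulli", {
  full <- igraph::make_full_graph(41)
  has <- rep(FALSE, 41); has[c(1, 2)] <- TRUE
  expect_length(diffuse_item(full, c(1, 2), has, 0), 0)
  expect_setequal(diffuse_item(full, c(1, 2), has, 1), 3:41)
  set.seed(51)
  counts <- replicate(400, length(diffuse_item(full, c(1, 2), has, 0.5)))
  # union over the dyad's neighbours on a complete graph: each of the 39
  # others is reached unless missed by both members, so P = 1 - 0.25 = 0.75
  expect_lt(abs(mean(counts) - 39 * 0.75), 3 * stats::sd(counts) / sqrt(400))
  # star: only the centre's neighbours are one hop away from the dyad
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  has2 <- rep(FALSE, 6); has2[c(1, 2)] <- TRUE
  expect_setequal(diffuse_item(star, c(1, 2), has2, 1), 3:6)
})

test_that("rewiring conserves degree and edge count, and no-ops when forced", {
  path <- igraph::make_graph(c(1, 2, 2, 3), n = 3, directed = FALSE)
  expect_equal(igraph::ecount(rewire_agent(path, 1, 0)), 2)
  full <- igraph::make_full_graph(5)
  expect_equal(igraph::ecount(rewire_agent(full, 1, 1)), 10)  # no non-neighbours
  # path A-B-C, agent 1 rewires: the only legal move is A-B -> A-C
  set.seed(61)
  g2 <- rewire_agent(path, 1, 1)
  el <- igraph::as_edgelist(g2)
  expect_equal(igraph::ecount(g2), 2)
  expect_setequal(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])),
                  c("1 3", "2 3"))
  expect_equal(igraph::degree(g2, 1), 1)
  # property: edge count and focal degree conserved across random rewires
  set.seed(62)
  for (i in 1:25) {
    g <- make_random_network(12, 0.3)
    a <- sample(12, 1)
    d0 <- igraph::degree(g, a)
    g3 <- rewire_agent(g, a, 1)
    expect_equal(igraph::ecount(g3), igraph::ecount(g))
    expect_equal(igraph::degree(g3, a), d0)
    expect_equal(igraph::count_multiple(g3), rep(1, igraph::ecount(g3)))
  }
})

test_that("a two-agent network always pairs the two agents", {
  r <- run_potions(sim_config(network = list(type = "complete", n = 2),
                              seed = 71, max_steps = 100000L))
  expect_true(r$crossover_achieved)
  expect_equal(r$combinations, r$steps * 2)
  # both agents end with identical inventories: every discovery is shared
  expect_equal(r$inventories[1, ], r$inventories[2, ])
})

test_that("inventories are monotone and scores climb the ladder without skips", {
  cfg <- sim_config(network = list(type = "er", n = 12, p = 0.3), seed = 81)
  st <- sim_init(cfg)
  prev_inv <- st$inv
  prev_score <- st$score
  ladder <- c(0, 48, 109, 188, 358)
  while (!st$done) {
    sim_step(st)
    expect_true(all(st$inv[prev_inv]))            # supersets of pre-step value
    expect_true(all(st$score >= prev_score))      # non-decreasing scores
    expect_true(all(st$score %in% ladder))
    # basics always present; nothing outside the closure
    expect_true(all(st$inv[, st$ei$basics]))
    prev_inv <- st$inv
    prev_score <- st$score
  }
  expect_equal(st$steps, length(st$gini_s))
})

test_that("equal config and seed give identical runs; engines agree exactly", {
  cfg <- sim_config(network = list(type = "er", n = 15, p = 0.3),
                    diffusion = 0.6, rewire = 0.2, seed = 91,
                    post_crossover_steps = 5L)
  r1 <- run_potions(cfg)
  r2 <- run_potions(cfg)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$inventories, r2$inventories)
  expect_identical(r1$first_discoverers, r2$first_discoverers)

  r3 <- run_potions(cfg, engine = "reference")
  expect_equal(r1$steps, r3$steps)
  expect_equal(r1$steps_to_crossover, r3$steps_to_crossover)
  expect_equal(r1$series$gini, r3$series$gini, tolerance = 1e-12)
  expect_identical(r1$inventories, r3$inventories)
  expect_identical(r1$first_discoverers, r3$first_discoverers)
  expect_equal(lapply(r1$final_adjacency, sort), lapply(r3$final_adjacency, sort))

  # weighted network: partner choice follows edge weights in both engines
  f <- tempfile(fileext = ".csv")
  set.seed(92)
  el <- t(utils::combn(8, 2))
  keep <- el[stats::runif(nrow(el)) < 0.6, ]
  writeLines(c("source,target,weight",
               sprintf("%d,%d,%.1f", keep[, 1], keep[, 2],
                       stats::runif(nrow(keep), 0.5, 3))), f)
  wcfg <- sim_config(network = list(type = "edgelist", path = f, weighted = TRUE),
                     diffusion = 0.8, rewire = 0.1, seed = 93)
  w1 <- run_potions(wcfg)
  w2 <- run_potions(wcfg, engine = "reference")
  expect_equal(w1$steps, w2$steps)
  expect_identical(w1$inventories, w2$inventories)
  expect_equal(w1$series$gini, w2$series$gini, tolerance = 1e-12)
})

test_that("termination: cap binds without crossover, crossover ends the run at 358", {
  r <- run_potions(sim_config(network = list(type = "er", n = 60, p = 0.1),
                              diffusion = 0, max_steps = 1L, seed = 101))
  expect_false(r$crossover_achieved)
  expect_equal(r$steps, 1L)
  expect_true(is.na(r$steps_to_crossover))

  r2 <- run_potions(sim_config(network = karate_club(), seed = 102))
  expect_true(r2$crossover_achieved)
  expect_equal(r2$steps, r2$steps_to_crossover)
  expect_equal(max(r2$scores), 358)
  expect_equal(r2$series$max_score[r2$steps], 358)
  expect_true(all(r2$series$max_score[seq_len(r2$steps - 1)] < 358))

  # post-crossover steps extend the recorded series
  r3 <- run_potions(sim_config(network = list(type = "complete", n = 10),
                               seed = 103, post_crossover_steps = 20L))
  expect_true(r3$crossover_achieved)
  expect_equal(r3$steps, r3$steps_to_crossover + 20L)
})

test_that("two-agent first-passage times match the exact Markov-chain oracle", {
  expected <- dyad_expected_steps(tab)
  reps <- 3000
  steps <- vapply(seq_len(reps), function(i) {
    run_potions(sim_config(network = list(type = "complete", n = 2),
                           seed = 7000 + i, max_steps = 100000L))$steps_to_crossover
  }, 0L)
  expect_true(all(!is.na(steps)))
  se <- stats::sd(steps) / sqrt(reps)
  expect_lt(abs(mean(steps) - expected), 3.5 * se)
})
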