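# Independent brute-force oracles. These deliberately avoid the package's own
# code paths (and igraph where the package relies on it), trading speed for
# transparency; they are only ever applied to tiny inputs.

gini_brute <- function(x) {
  n <- length(x)
  if (mean(x) == 0) return(0)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

# dense adjacency matrix of an igraph graph, ignoring weights
adj_matrix <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  a <- matrix(0L, n, n)
  for (e in seq_len(nrow(el))) {
    a[el[e, 1], el[e, 2]] <- 1L
    a[el[e, 2], el[e, 1]] <- 1L
  }
  a
}

# all-pairs shortest-path lengths by Floyd-Warshall
dist_brute <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a == 1L] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

apl_brute <- function(g) {
  d <- dist_brute(adj_matrix(g))
  mean(d[upper.tri(d)])
}

clustering_brute <- function(g) {
  a <- adj_matrix(g)
  n <- nrow(a)
  local <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(a[v, ] == 1L)
    k <- length(nb)
    if (k < 2) { local[v] <- 0; next }
    links <- 0
    for (i in seq_along(nb)) for (j in seq_along(nb)) {
      if (i < j && a[nb[i], nb[j]] == 1L) links <- links + 1
    }
    local[v] <- 2 * links / (k * (k - 1))
  }
  mean(local)
}

# enumerate every shortest path between two vertices by depth-first search
all_shortest_paths_brute <- function(a, d, s, t) {
  paths <- list()
  walk <- function(v, path) {
    if (v == t) { paths[[length(paths) + 1]] <<- path; return(invisible()) }
    for (w in which(a[v, ] == 1L)) {
      if (d[w, t] == d[v, t] - 1) walk(w, c(path, w))
    }
  }
  walk(s, s)
  paths
}

centralities_brute <- function(g) {
  a <- adj_matrix(g)
  n <- nrow(a)
  d <- dist_brute(a)
  btw <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t) next
    paths <- all_shortest_paths_brute(a, d, s, t)
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      thru <- sum(vapply(paths, function(p) v %in% p, TRUE))
      btw[v] <- btw[v] + thru / length(paths)
    }
  }
  data.frame(
    agent = seq_len(n),
    degree = rowSums(a) / (n - 1),
    betweenness = btw / ((n - 1) * (n - 2) / 2),
    closeness = (n - 1) / rowSums(d)
  )
}

# naive rejection sampler for connected G(n, p): upper-triangle Bernoulli
# draws plus a hand-rolled BFS connectivity check
er_connected_edges_brute <- function(n, p) {
  repeat {
    a <- matrix(0L, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (stats::runif(1) < p) { a[i, j] <- 1L; a[j, i] <- 1L }
    }
    seen <- logical(n)
    queue <- 1L
    seen[1L] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in which(a[v, ] == 1L)) {
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    if (all(seen)) return(sum(a) / 2)
  }
}

# Exact expected steps-to-crossover for the two-agent dyad, by enumerating the
# Markov chain over shared-inventory states. Both agents hold identical
# inventories at all times (every discovery is added to both), each step is
# two sequential combination attempts, and an attempt creates recipe product
# T = {t1,t2,t3} (subset of the inventory) with probability
#   sum over the item x contributed alone:
#     P(x) * [P(y)P(z | not y) + P(z)P(y | not z)]
# under score-proportional sampling without replacement (both split choices
# give the same law because the two inventories are identical).
dyad_expected_steps <- function(table) {
  items <- table$items
  w <- items$innovation_score
  names(w) <- items$name
  recipes <- table$recipes
  basics <- items$name[items$tier == 0L]
  cross <- items$name[items$tier == 4L]

  # reachable shared-inventory states
  states <- list(sort(basics))
  key <- function(s) paste(s, collapse = "|")
  seen <- key(states[[1]])
  i <- 1
  while (i <= length(states)) {
    s <- states[[i]]
    for (r in seq_len(nrow(recipes))) {
      tri <- c(recipes$i1[r], recipes$i2[r], recipes$i3[r])
      pr <- recipes$product[r]
      if (all(tri %in% s) && !(pr %in% s)) {
        s2 <- sort(c(s, pr))
        if (!key(s2) %in% seen) {
          states[[length(states) + 1]] <- s2
          seen <- c(seen, key(s2))
        }
      }
    }
    i <- i + 1
  }
  ns <- length(states)
  skey <- vapply(states, key, "")

  p_triad <- function(s, tri) {
    W <- sum(w[s])
    tot <- 0
    for (xi in 1:3) {
      x <- tri[xi]; yz <- tri[-xi]
      py_z <- (w[yz[1]] / W) * (w[yz[2]] / (W - w[yz[1]]))
      pz_y <- (w[yz[2]] / W) * (w[yz[1]] / (W - w[yz[2]]))
      tot <- tot + (w[x] / W) * (py_z + pz_y)
    }
    unname(tot)
  }

  A <- matrix(0, ns, ns)
  for (si in seq_len(ns)) {
    s <- states[[si]]
    if (cross %in% s) { A[si, si] <- 1; next }  # absorbing
    stay <- 1
    for (r in seq_len(nrow(recipes))) {
      tri <- c(recipes$i1[r], recipes$i2[r], recipes$i3[r])
      pr <- recipes$product[r]
      if (!all(tri %in% s)) next
      p <- p_triad(s, tri)
      if (pr %in% s) next  # re-discovery: no state change
      ti <- match(key(sort(c(s, pr))), skey)
      A[si, ti] <- A[si, ti] + p
      stay <- stay - p
    }
    A[si, si] <- A[si, si] + stay
  }
  S <- A %*% A  # one step = two sequential attempts
  transient <- !vapply(states, function(s) cross %in% s, TRUE)
  Q <- S[transient, transient, drop = FALSE]
  E <- solve(diag(nrow(Q)) - Q, rep(1, nrow(Q)))
  E[match(key(sort(basics)), skey[transient])]
}

# all C(k,3) triads of a name vector
all_triads <- function(names) {
  utils::combn(names, 3L, simplify = FALSE)
}
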