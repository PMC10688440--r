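tab <- load_recipe_table()

test_that("bundled recipe table has the full tiered structure and validates", {
  expect_s3_class(tab, "recipe_table")
  expect_length(validate_recipe_table(tab), 0)
  expect_equal(nrow(tab$items), 13)
  expect_equal(nrow(tab$recipes), 7)
  expect_equal(sort(unique(tab$items$tier)), 0:4)
  # one tier-4 item, trajectory crossover
  top <- tab$items[tab$items$tier == 4, ]
  expect_equal(nrow(top), 1)
  expect_equal(top$trajectory, "crossover")
  # tier scores strictly increasing: 0 < 48 < 109 < 188 < 358
  ts <- vapply(0:4, function(k) unique(tab$items$tier_score[tab$items$tier == k]), 0)
  expect_equal(ts, c(0, 48, 109, 188, 358))
})

test_that("initial inventory is the six basics with scores 6/8/10 per trajectory", {
  inv <- initial_inventory(tab)
  expect_equal(nrow(inv), 6)
  expect_true(all(inv$tier == 0))
  expect_equal(sort(inv$innovation_score), c(6, 6, 8, 8, 10, 10))
  expect_true(all(inv$tier_score == 0))
  # independent copies: mutating one draw never affects another
  a <- initial_inventory(tab)
  b <- initial_inventory(tab)
  a$innovation_score[1] <- 999
  expect_equal(b$innovation_score[1], 6)
})

test_that("exactly two of the 20 basic triads are valid combinations", {
  inv <- initial_inventory(tab)
  hits <- Filter(Negate(is.null),
                 lapply(all_triads(inv$name), lookup_combination, table = tab))
  expect_equal(length(hits), 2)
  prods <- sort(vapply(hits, function(it) it$name, ""))
  expect_true(all(vapply(hits, function(it) it$tier, 0L) == 1L))
  expect_equal(length(unique(prods)), 2)
})

test_that("lookup_combination matches unordered triads and rejects the rest", {
  basics <- tab$items$name[tab$items$tier == 0]
  a <- basics[tab$items$trajectory[tab$items$tier == 0] == "basic_a"]
  b <- basics[tab$items$trajectory[tab$items$tier == 0] == "basic_b"]
  hit <- lookup_combination(tab, sample(a))  # any order
  expect_equal(hit$tier, 1L)
  expect_equal(hit$tier_score, 48)
  expect_equal(lookup_combination(tab, rev(b))$tier, 1L)
  expect_null(lookup_combination(tab, c(a[1], a[2], b[1])))
  # fewer than 3 distinct names is invalid, not an error
  expect_null(lookup_combination(tab, c(a[1], a[1], a[2])))
})

test_that("recipe closure from the basics reproduces the item set exactly", {
  have <- tab$items$name[tab$items$tier == 0]
  repeat {
    new <- character(0)
    for (tri in all_triads(have)) {
      it <- lookup_combination(tab, tri)
      if (!is.null(it) && !(it$name %in% have)) new <- c(new, it$name)
    }
    if (length(new) == 0) break
    have <- c(have, unique(new))
  }
  expect_setequal(have, tab$items$name)
})

test_that("path dependency is structural: tier-k needs tier-(k-1), crossover needs both terminals", {
  items <- tab$items
  recipes <- tab$recipes
  for (k in 2:3) {
    for (tr in c("a", "b")) {
      p <- items$name[items$tier == k & items$trajectory == tr]
      prev <- items$name[items$tier == k - 1 & items$trajectory == tr]
      r <- recipes[recipes$product == p, ]
      expect_true(prev %in% c(r$i1, r$i2, r$i3))
    }
  }
  terminals <- items$name[items$tier == 3]
  rx <- recipes[recipes$product == items$name[items$tier == 4], ]
  expect_true(all(terminals %in% c(rx$i1, rx$i2, rx$i3)))
})

test_that("validate_recipe_table reports constructed violations", {
  # crossover recipe missing the B-trajectory terminal
  broken <- tab
  rx <- which(broken$recipes$product == broken$items$name[broken$items$tier == 4])
  bterm <- broken$items$name[broken$items$tier == 3][2]
  basics <- broken$items$name[broken$items$tier == 0]
  tri <- c(broken$recipes$i1[rx], broken$recipes$i2[rx], broken$recipes$i3[rx])
  tri[tri == bterm] <- setdiff(basics, tri)[1]
  tri <- sort(tri)
  broken$recipes[rx, c("i1", "i2", "i3")] <- as.list(tri)
  expect_true(any(grepl("crossover recipe must contain both tier-3",
                        validate_recipe_table(broken))))
  # two recipes producing the same item
  dup <- tab
  dup$recipes$product[2] <- dup$recipes$product[1]
  expect_true(any(grepl("more than one recipe", validate_recipe_table(dup))))
})

test_that("loading malformed or incomplete recipe files fails informatively", {
  src <- system.file("extdata", "recipes_synthetic.csv", package = "potionsim")
  lines <- readLines(src)

  # empty file
  f0 <- tempfile(fileext = ".csv")
  writeLines(lines[1], f0)
  expect_error(load_recipe_table(f0), "empty")

  # only basics + the two basic recipes + crossover: closure broken
  keep <- c(1:8, 11, 14)  # header, 6 basics, recipe 1a, 1b, crossover
  f1 <- tempfile(fileext = ".csv")
  writeLines(lines[keep], f1)
  expect_error(load_recipe_table(f1), "validation")

  # malformed ingredient list names the offending line
  f2 <- tempfile(fileext = ".csv")
  bad <- lines
  bad[8] <- sub("a1;a2;a3", "a1;a2", bad[8])
  writeLines(bad, f2)
  expect_error(load_recipe_table(f2), "line 8")

  # duplicate triad
  f3 <- tempfile(fileext = ".csv")
  writeLines(c(lines, sub(",1a,", ",1a_bis,", lines[8])), f3)
  expect_error(load_recipe_table(f3), "duplicate")

  expect_error(load_recipe_table(tempfile()), "not found")
})

test_that("recipe tables round-trip through YAML", {
  skip_if_not_installed("yaml")
  rows <- lapply(seq_len(nrow(tab$items)), function(i) {
    it <- tab$items[i, ]
    r <- tab$recipes[tab$recipes$product == it$name, ]
    list(
      ingredients = if (nrow(r)) c(r$i1, r$i2, r$i3) else NULL,
      product = it$name, trajectory = it$trajectory, tier = it$tier,
      innovation_score = it$innovation_score, tier_score = it$tier_score,
      rank = it$rank
    )
  })
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(rows, f)
  tab2 <- load_recipe_table(f)
  expect_equal(tab2$items$name, tab$items$name)
  expect_equal(nrow(tab2$recipes), nrow(tab$recipes))
})
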