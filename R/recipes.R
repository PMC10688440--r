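#' Potion recipe tables
#'
#' The Potions Task is built on a small, closed item universe: six basic
#' ingredients (three per trajectory, with selection weights 6, 8 and 10),
#' three tiers of increasingly valuable items along each of an A and a B
#' trajectory (tier scores 48, 109 and 188), and a single tier-4 crossover
#' item (tier score 358) whose recipe requires the terminal items of both
#' trajectories. A recipe table maps unordered triads of item names to the
#' item they produce; the tiered structure induces path dependency because a
#' tier-k recipe always contains the tier-(k-1) item of its own trajectory.
#'
#' The bundled table (`inst/extdata/recipes_synthetic.csv`) is a synthetic
#' reconstruction: it satisfies every structural constraint of the task
#' (two all-basic recipes, per-trajectory tier chains, a crossover recipe
#' containing both terminal items) but the exact triads for tiers 2-3 are a
#' structural fallback (tier-k item combined from the tier-(k-1) item plus two
#' same-trajectory basics; crossover from both terminals plus a top-weight
#' basic), not a transcription of the original task material.
#'
#' @param path Path to a recipe file (CSV, or YAML when the `yaml` package is
#'   available). `NULL` loads the bundled synthetic table. Columns/keys:
#'   `ingredients` (three names separated by `;`, empty for basic items),
#'   `product`, `trajectory`, `tier`, `innovation_score`, `tier_score`,
#'   `rank`.
#' @return An object of class `recipe_table`: a list with `items` (one row per
#'   item: `name`, `trajectory`, `tier`, `innovation_score`, `tier_score`,
#'   `rank`, `id`) and `recipes` (one row per recipe: `i1`, `i2`, `i3`,
#'   `product`). The table is validated on load; structural violations are an
#'   error.
#' @seealso [validate_recipe_table()], [lookup_combination()],
#'   [initial_inventory()]
#' @examples
#' tab <- load_recipe_table()
#' lookup_combination(tab, c("a1", "a2", "a3"))$name
#' @export
load_recipe_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "recipes_synthetic.csv",
                        package = "potionsim", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("recipe file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML recipe files requires the 'yaml' package")
    }
    rows <- yaml::read_yaml(path)
    if (length(rows) == 0L) stop("recipe file is empty: ", path)
    raw <- do.call(rbind, lapply(rows, function(r) {
      data.frame(
        ingredients = if (is.null(r$ingredients)) "" else
          paste(r$ingredients, collapse = ";"),
        product = r$product, trajectory = r$trajectory,
        tier = r$tier, innovation_score = r$innovation_score,
        tier_score = r$tier_score,
        rank = if (is.null(r$rank)) r$tier else r$rank,
        stringsAsFactors = FALSE
      )
    }))
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = list(ingredients = "character"))
  }
  if (nrow(raw) == 0L) stop("recipe file is empty: ", path)
  needed <- c("ingredients", "product", "trajectory", "tier",
              "innovation_score", "tier_score")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop("recipe file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(raw$rank)) raw$rank <- raw$tier
  raw$ingredients[is.na(raw$ingredients)] <- ""

  items <- data.frame(
    name = as.character(raw$product),
    trajectory = as.character(raw$trajectory),
    tier = as.integer(raw$tier),
    innovation_score = as.numeric(raw$innovation_score),
    tier_score = as.numeric(raw$tier_score),
    rank = as.integer(raw$rank),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(items$name) | items$name == "" | is.na(items$tier) |
                 is.na(items$innovation_score) | is.na(items$tier_score))
  if (length(bad) > 0L) {
    stop("malformed recipe row(s) at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  }
  if (anyDuplicated(items$name)) {
    stop("duplicate product name(s): ",
         paste(unique(items$name[duplicated(items$name)]), collapse = ", "))
  }
  items$id <- seq_len(nrow(items))

  has_recipe <- raw$ingredients != ""
  triads <- lapply(which(has_recipe), function(i) {
    ing <- strsplit(raw$ingredients[i], ";", fixed = TRUE)[[1]]
    ing <- trimws(ing)
    ing <- ing[ing != ""]
    if (length(ing) != 3L || anyDuplicated(ing)) {
      stop("malformed recipe row at line ", i + 1L, " of ", path,
           ": expected 3 distinct ingredient names, got '",
           raw$ingredients[i], "'")
    }
    sort(ing)
  })
  recipes <- data.frame(
    i1 = vapply(triads, `[`, "", 1L),
    i2 = vapply(triads, `[`, "", 2L),
    i3 = vapply(triads, `[`, "", 3L),
    product = items$name[has_recipe],
    stringsAsFactors = FALSE
  )
  keys <- paste(recipes$i1, recipes$i2, recipes$i3, sep = "|")
  if (anyDuplicated(keys)) {
    stop("duplicate recipe triad(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = "; "))
  }

  tab <- structure(list(items = items, recipes = recipes), class = "recipe_table")
  problems <- validate_recipe_table(tab)
  if (length(problems) > 0L) {
    stop("recipe table fails validation:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  tab
}

triad_key <- function(triad) paste(sort(triad), collapse = "|")

#' Validate the structure of a recipe table
#'
#' Checks every structural invariant of the task: six basic items (three per
#' trajectory with selection weights 6, 8, 10), exactly two all-basic recipes,
#' tier chains in which every tier-k recipe (k = 2, 3) contains the tier-(k-1)
#' item of its own trajectory, a unique tier-4 crossover recipe containing
#' both tier-3 terminal items, tier scores strictly increasing in tier, each
#' item produced by exactly one recipe, and closure (every non-basic item
#' reachable from the basics by repeated combination).
#'
#' @param table A `recipe_table` (see [load_recipe_table()]); structural
#'   checks also run on hand-built lists with the same shape.
#' @return A character vector of violation messages; `character(0)` when the
#'   table satisfies all invariants.
#' @export
validate_recipe_table <- function(table) {
  items <- table$items
  recipes <- table$recipes
  out <- character(0)

  basics <- items[items$tier == 0L, ]
  if (nrow(basics) != 6L) {
    out <- c(out, sprintf("expected 6 basic (tier-0) items, found %d", nrow(basics)))
  } else {
    for (tr in unique(basics$trajectory)) {
      sc <- sort(basics$innovation_score[basics$trajectory == tr])
      if (length(sc) != 3L || !identical(sc, c(6, 8, 10))) {
        out <- c(out, sprintf(
          "basic trajectory '%s' must have exactly 3 items with scores 6, 8, 10", tr))
      }
    }
  }
  if (any(basics$tier_score != 0)) {
    out <- c(out, "basic items must have tier_score 0")
  }

  is_basic <- items$name %in% basics$name
  all_basic_recipe <- recipes$i1 %in% basics$name &
    recipes$i2 %in% basics$name & recipes$i3 %in% basics$name
  if (sum(all_basic_recipe) != 2L) {
    out <- c(out, sprintf("expected exactly 2 all-basic recipes, found %d",
                          sum(all_basic_recipe)))
  }

  unknown <- setdiff(unique(c(recipes$i1, recipes$i2, recipes$i3)), items$name)
  if (length(unknown) > 0L) {
    out <- c(out, paste0("recipes use unknown item(s): ",
                         paste(unknown, collapse = ", ")))
  }

  prod_counts <- table(recipes$product)
  multi <- names(prod_counts)[prod_counts > 1L]
  if (length(multi) > 0L) {
    out <- c(out, paste0("item(s) produced by more than one recipe: ",
                         paste(multi, collapse = ", ")))
  }
  nonbasic <- items$name[!is_basic]
  orphan <- setdiff(nonbasic, recipes$product)
  if (length(orphan) > 0L) {
    out <- c(out, paste0("non-basic item(s) with no recipe: ",
                         paste(orphan, collapse = ", ")))
  }
  basic_products <- intersect(basics$name, recipes$product)
  if (length(basic_products) > 0L) {
    out <- c(out, paste0("basic item(s) must not be recipe products: ",
                         paste(basic_products, collapse = ", ")))
  }

  # tier chain: the recipe of a tier-k item (k = 2, 3) must contain the
  # tier-(k-1) item of the same trajectory
  for (k in 2:3) {
    for (tr in setdiff(unique(items$trajectory[items$tier %in% 1:3]), NA)) {
      prod_k <- items$name[items$tier == k & items$trajectory == tr]
      prev <- items$name[items$tier == k - 1L & items$trajectory == tr]
      for (p in prod_k) {
        r <- recipes[recipes$product == p, , drop = FALSE]
        if (nrow(r) == 1L && length(prev) == 1L &&
            !(prev %in% c(r$i1, r$i2, r$i3))) {
          out <- c(out, sprintf(
            "tier-%d recipe for '%s' must contain the tier-%d item '%s'",
            k, p, k - 1L, prev))
        }
      }
    }
  }

  # unique crossover containing both tier-3 terminals
  top <- items[items$tier == 4L, , drop = FALSE]
  if (nrow(top) != 1L) {
    out <- c(out, sprintf("expected exactly 1 tier-4 item, found %d", nrow(top)))
  } else {
    if (top$trajectory != "crossover") {
      out <- c(out, "the tier-4 item must have trajectory 'crossover'")
    }
    terminals <- items$name[items$tier == 3L]
    r <- recipes[recipes$product == top$name, , drop = FALSE]
    if (nrow(r) == 1L && !all(terminals %in% c(r$i1, r$i2, r$i3))) {
      out <- c(out, "crossover recipe must contain both tier-3 items")
    }
    if (length(terminals) != 2L) {
      out <- c(out, sprintf("expected exactly 2 tier-3 items, found %d",
                            length(terminals)))
    }
  }

  # tier scores strictly increasing in tier
  by_tier <- split(items$tier_score, items$tier)
  tier_levels <- sort(as.integer(names(by_tier)))
  means <- vapply(by_tier[as.character(tier_levels)], function(x) x[1], 0)
  if (any(vapply(by_tier, function(x) length(unique(x)) > 1L, TRUE))) {
    out <- c(out, "items of the same tier must share one tier_score")
  } else if (is.unsorted(means, strictly = TRUE)) {
    out <- c(out, "tier_score must be strictly increasing in tier")
  }

  if (any(items$innovation_score <= 0)) {
    out <- c(out, "innovation scores must be positive")
  }

  # closure: everything reachable from the basics, and nothing else
  if (nrow(basics) > 0L && length(unknown) == 0L) {
    have <- basics$name
    repeat {
      reach <- recipes$product[recipes$i1 %in% have & recipes$i2 %in% have &
                                 recipes$i3 %in% have]
      new <- setdiff(reach, have)
      if (length(new) == 0L) break
      have <- c(have, new)
    }
    unreachable <- setdiff(items$name, have)
    if (length(unreachable) > 0L) {
      out <- c(out, paste0("item(s) unreachable from the basics: ",
                           paste(unreachable, collapse = ", ")))
    }
  }

  out
}

#' Look up the product of a triad of item names
#'
#' Recipes are unordered sets of three distinct names; a draw with fewer than
#' three distinct names matches nothing.
#'
#' @param table A validated `recipe_table`.
#' @param triad Character vector of item names.
#' @return A one-row data frame (the product item) or `NULL` when the triad is
#'   not a valid combination.
#' @export
lookup_combination <- function(table, triad) {
  triad <- as.character(triad)
  if (length(triad) != 3L || anyDuplicated(triad)) return(NULL)
  key <- triad_key(triad)
  keys <- paste(table$recipes$i1, table$recipes$i2, table$recipes$i3, sep = "|")
  hit <- match(key, keys)
  if (is.na(hit)) return(NULL)
  table$items[table$items$name == table$recipes$product[hit], , drop = FALSE]
}

#' Starting inventory of the six basic items
#'
#' Every agent begins with an identical, independent copy of the six basics
#' (three per trajectory, selection weights 6, 8, 10; tier score 0, so the
#' starting agent score is 0).
#'
#' @param table A validated `recipe_table`.
#' @return A six-row data frame of the tier-0 items.
#' @export
initial_inventory <- function(table) {
  basics <- table$items[table$items$tier == 0L, , drop = FALSE]
  if (nrow(basics) != 6L) {
    stop("recipe table must contain exactly 6 basic items, found ", nrow(basics))
  }
  rownames(basics) <- NULL
  basics
}

#' @export
print.recipe_table <- function(x, ...) {
  cat("Potions recipe table:", nrow(x$items), "items,",
      nrow(x$recipes), "recipes\n")
  cat("  tiers:", paste(sort(unique(x$items$tier)), collapse = " "), "\n")
  invisible(x)
}
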