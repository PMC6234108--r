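#' GRNN-monitored fitness of a descriptor subset
#'
#' The wrapper-selection objective: restrict the table to a candidate
#' descriptor subset, standardize by training statistics, fit a GRNN on
#' the training rows with the bandwidth chosen on the verification rows,
#' and return the verification RMSE (smaller is fitter).
#'
#' @param table A `descriptor_table` with a logBCF target.
#' @param subset Non-empty character vector of descriptor names.
#' @param split A `split_assignment` with non-empty train and verify parts.
#' @param grid Bandwidth grid passed to [grnn_select_bandwidth()].
#' @return Verification RMSE, with attribute `"sigma"` (chosen bandwidth).
#' @export
subset_fitness <- function(table, subset, split, grid = grnn_sigma_grid()) {
  if (length(subset) == 0L) {
    stop("domain error: empty descriptor subset", call. = FALSE)
  }
  stopifnot(inherits(split, "split_assignment"))
  if (length(split$train_ids) == 0L || length(split$verify_ids) == 0L) {
    stop("split must have train and verification rows", call. = FALSE)
  }
  sub <- subset_descriptors(table, subset)
  std <- standardize(sub, split$train_ids)
  Xtr <- subset_rows(std$table, split$train_ids)$X
  Xv <- subset_rows(std$table, split$verify_ids)$X
  ytr <- table$logbcf[split$train_ids]
  yv <- table$logbcf[split$verify_ids]
  d2 <- cross_dist2(Xv, Xtr)
  rmse <- vapply(grid, function(s) {
    sqrt(mean((grnn_predict_d2(d2, ytr, s) - yv)^2))
  }, numeric(1))
  best <- max(which(rmse <= min(rmse) + 1e-12))
  structure(rmse[best], sigma = grid[best])
}

#' Genetic-algorithm configuration
#'
#' Defaults follow the study settings (population 500, 250 generations,
#' mutation rate 0.1, crossover rate 1); the `"ci"` preset is a reduced
#' configuration for tests and examples. Mutation rate is interpreted as
#' the per-chromosome probability that one random bit is flipped
#' (`per_bit = FALSE`); set `per_bit = TRUE` for independent per-bit flips.
#'
#' @param population Population size (>= 2).
#' @param generations Maximum generations.
#' @param mutation_rate Probability in `[0, 1]`.
#' @param crossover_rate Probability in `[0, 1]` that a mating pair
#'   undergoes uniform crossover.
#' @param elitism Number of best chromosomes copied unchanged.
#' @param patience Generations without best-fitness improvement before
#'   stopping (>= 1).
#' @param tournament Tournament size for parent selection.
#' @param per_bit Mutation interpretation (see above).
#' @param seed Integer seed.
#' @param preset `"full"` (full-scale defaults) or `"ci"` (population 60,
#'   40 generations).
#' @return A validated `ga_config`.
#' @export
ga_config <- function(population = 500, generations = 250,
                      mutation_rate = 0.1, crossover_rate = 1,
                      elitism = 2, patience = 25, tournament = 3,
                      per_bit = FALSE, seed = 1L, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("full", "ci"))
    if (preset == "ci") {
      population <- 60; generations <- 40; patience <- 40
    }
  }
  stopifnot(population >= 2, generations >= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            elitism >= 0, elitism < population,
            patience >= 1, tournament >= 1)
  structure(
    list(population = as.integer(population),
         generations = as.integer(generations),
         mutation_rate = mutation_rate, crossover_rate = crossover_rate,
         elitism = as.integer(elitism), patience = as.integer(patience),
         tournament = as.integer(tournament), per_bit = per_bit,
         seed = as.integer(seed)),
    class = "ga_config"
  )
}

new_selection_result <- function(selected, fitness, history, method,
                                 evaluations, path = NULL) {
  structure(
    list(selected = selected, fitness = as.numeric(fitness),
         history = history, method = method,
         evaluations = as.integer(evaluations), path = path),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result (%s): %d descriptor(s), fitness %.4f (%d evaluations)\n",
              x$method, length(x$selected), x$fitness, x$evaluations))
  cat("selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

# memoized fitness over bit masks, shared by GA and stepwise search
make_fitness_cache <- function(table, split, grid) {
  cache <- new.env(parent = emptyenv())
  evals <- 0L
  all_names <- descriptor_names(table)
  fit <- function(mask) {
    key <- paste(which(mask), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- as.numeric(subset_fitness(table, all_names[mask], split, grid))
    evals <<- evals + 1L
    cache[[key]] <- val
    val
  }
  list(fitness = fit, n_evaluations = function() evals)
}

#' Genetic-algorithm descriptor selection
#'
#' Evolves bitmask chromosomes (one bit per descriptor) by tournament
#' selection, uniform crossover and mutation, with elitism, scoring each
#' subset by its GRNN-monitored verification RMSE ([subset_fitness()]).
#' Returns the best subset ever evaluated; the best-so-far fitness trace
#' is non-increasing by construction. All-zero chromosomes are repaired by
#' activating one random bit so the empty subset is never evaluated.
#'
#' @param table A `descriptor_table` with >= 2 descriptors and a target.
#' @param split A `split_assignment`.
#' @param config A [ga_config()].
#' @param grid Bandwidth grid for the GRNN monitor.
#' @return A `selection_result` with the chosen descriptor names, final
#'   fitness, per-generation history (`generation`, `best_fitness`,
#'   `best_mask`) and the number of distinct subsets evaluated.
#' @export
ga_select <- function(table, split, config = ga_config(), grid = grnn_sigma_grid()) {
  stopifnot(inherits(config, "ga_config"))
  p <- length(descriptor_names(table))
  if (p < 2L) stop("need at least 2 descriptors", call. = FALSE)
  set.seed(config$seed)
  cache <- make_fitness_cache(table, split, grid)

  repair <- function(mask) {
    if (!any(mask)) mask[sample.int(p, 1)] <- TRUE
    mask
  }
  pop <- lapply(seq_len(config$population), function(i) {
    repair(stats::runif(p) < 0.5)
  })
  scores <- vapply(pop, cache$fitness, numeric(1))

  best_fit <- Inf
  best_mask <- NULL
  stale <- 0L
  history <- vector("list", config$generations)

  for (gen in seq_len(config$generations)) {
    gen_best <- which.min(scores)
    if (scores[gen_best] < best_fit - 1e-12) {
      best_fit <- scores[gen_best]
      best_mask <- pop[[gen_best]]
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    history[[gen]] <- data.frame(
      generation = gen, best_fitness = best_fit,
      best_mask = paste(as.integer(best_mask), collapse = ""),
      stringsAsFactors = FALSE)
    if (stale >= config$patience) break
    if (gen == config$generations) break

    ord <- order(scores)
    elites <- pop[ord[seq_len(config$elitism)]]
    tournament <- function() {
      cand <- sample.int(config$population, config$tournament, replace = TRUE)
      pop[[cand[which.min(scores[cand])]]]
    }
    offspring <- lapply(seq_len(config$population - config$elitism),
                        function(i) {
      p1 <- tournament()
      p2 <- tournament()
      child <- if (stats::runif(1) < config$crossover_rate) {
        ifelse(stats::runif(p) < 0.5, p1, p2)
      } else {
        p1
      }
      if (config$per_bit) {
        flip <- stats::runif(p) < config$mutation_rate
        child[flip] <- !child[flip]
      } else if (stats::runif(1) < config$mutation_rate) {
        b <- sample.int(p, 1)
        child[b] <- !child[b]
      }
      repair(child)
    })
    pop <- c(elites, offspring)
    scores <- vapply(pop, cache$fitness, numeric(1))
  }

  history <- do.call(rbind, history[!vapply(history, is.null, logical(1))])
  new_selection_result(descriptor_names(table)[best_mask], best_fit, history,
                       method = "GA", evaluations = cache$n_evaluations())
}

#' Stepwise descriptor selection
#'
#' Greedy forward (start empty, add the descriptor that most reduces the
#' GRNN-monitored RMSE) or backward (start full, remove) search; stops
#' after `patience` consecutive non-improving steps or when no candidate
#' moves remain. The returned subset is the one at the best fitness point
#' on the path, not necessarily the last one visited.
#'
#' @param table A `descriptor_table` with a target.
#' @param direction `"forward"` or `"backward"`.
#' @param split A `split_assignment`.
#' @param patience Consecutive non-improving steps tolerated (default 2).
#' @param grid Bandwidth grid for the GRNN monitor.
#' @return A `selection_result`; `$path` records each step's action,
#'   descriptor and fitness.
#' @export
stepwise_select <- function(table, direction = c("forward", "backward"),
                            split, patience = 2, grid = grnn_sigma_grid()) {
  direction <- match.arg(direction)
  all_names <- descriptor_names(table)
  p <- length(all_names)
  if (p < 1L) stop("need at least 1 descriptor", call. = FALSE)
  cache <- make_fitness_cache(table, split, grid)
  mask_of <- function(nms) all_names %in% nms

  current <- if (direction == "forward") character(0) else all_names
  best_fit <- if (direction == "forward") Inf else cache$fitness(mask_of(current))
  best_set <- current
  path <- list()
  stale <- 0L
  step <- 0L

  repeat {
    if (direction == "forward") {
      candidates <- setdiff(all_names, current)
      if (length(candidates) == 0L) break
      moves <- lapply(candidates, function(d) union(current, d))
    } else {
      if (length(current) <= 1L) break
      candidates <- current
      moves <- lapply(candidates, function(d) setdiff(current, d))
    }
    fits <- vapply(moves, function(s) cache$fitness(mask_of(s)), numeric(1))
    pick <- which.min(fits)
    step <- step + 1L
    current <- moves[[pick]]
    path[[step]] <- data.frame(
      step = step,
      action = if (direction == "forward") "add" else "remove",
      descriptor = candidates[pick], fitness = fits[pick],
      n_selected = length(current), stringsAsFactors = FALSE)
    if (fits[pick] < best_fit - 1e-12) {
      best_fit <- fits[pick]
      best_set <- current
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  if (length(best_set) == 0L) {
    # forward search where no single descriptor was evaluated cannot happen
    # (the first step always evaluates all singletons); guard anyway
    best_set <- path[[1]]$descriptor
    best_fit <- path[[1]]$fitness
  }
  path <- do.call(rbind, path)
  new_selection_result(best_set, best_fit, history = path,
                       method = if (direction == "forward") "FA" else "BA",
                       evaluations = cache$n_evaluations(), path = path)
}

#' Add user-curated descriptors to a selection
#'
#' Takes the union of a selected subset and a forced-in list (order-stable:
#' selected first, then new forced names), mirroring the practice of
#' appending descriptors with previously demonstrated influence on
#' bioaccumulation to an algorithmic selection.
#'
#' @param result A `selection_result` or character vector of names.
#' @param forced_in Descriptor names to force into the subset.
#' @param available Optional character vector (or `descriptor_table`) the
#'   forced names must belong to.
#' @return Character vector of descriptor names.
#' @export
curate_subset <- function(result, forced_in, available = NULL) {
  selected <- if (inherits(result, "selection_result")) result$selected
              else as.character(result)
  forced_in <- as.character(forced_in)
  if (!is.null(available)) {
    if (inherits(available, "descriptor_table")) {
      available <- descriptor_names(available)
    }
    missing <- setdiff(forced_in, available)
    if (length(missing)) {
      stop("validation error: forced descriptor(s) not in table: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  c(selected, setdiff(forced_in, selected))
}
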