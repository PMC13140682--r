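# Elitist genetic algorithm selecting the S most useful augmented images
# from a candidate pool. An individual is a size-S set of distinct pool
# indices; its fitness is a classifier's accuracy on those samples. Each
# generation keeps the top T individuals unchanged (so the running best
# fitness never decreases) and refills the population by mutating elites.

#' Genetic-algorithm configuration
#'
#' @param generations number of generations G
#' @param pop_size number of individuals N
#' @param sample_size images per individual S
#' @param elite number of top individuals retained unchanged T
#' @param mutation_rate per-individual mutation rate r; each mutation pass
#'   resamples `floor(r * S)` positions
#' @param seed integer master seed
#' @return a `ga_config` list
#' @export
ga_config <- function(generations = 30, pop_size = 20, sample_size = 500,
                      elite = 4, mutation_rate = 0.1, seed = 1) {
  stopifnot(generations >= 1, pop_size >= 1,
            elite >= 1, elite <= pop_size,
            mutation_rate >= 0, mutation_rate <= 1, sample_size >= 1)
  structure(list(generations = generations, pop_size = pop_size,
                 sample_size = sample_size, elite = elite,
                 mutation_rate = mutation_rate, seed = seed),
            class = "ga_config")
}

#' Flatten images into a fitness feature matrix
#'
#' Images are optionally resized, intensity-scaled to `[0, 1]` and
#' flattened row-per-image, the representation the fitness classifier
#' consumes.
#'
#' @param dataset list of `labeled_image`
#' @param resize target side in pixels (default 128; smaller values trade
#'   fidelity for speed)
#' @return numeric matrix with a `labels` attribute
#' @export
flatten_images <- function(dataset, resize = 128) {
  X <- t(vapply(dataset, function(im) {
    img <- im$pixels / 255
    if (dim(img)[1] != resize || dim(img)[2] != resize) {
      img <- resize_bilinear(img, resize, resize)
    }
    as.vector(img)
  }, numeric(resize * resize * 3)))
  attr(X, "labels") <- dataset_labels(dataset)
  X
}

#' Classifier-accuracy fitness of an individual
#'
#' Stratified 3-fold cross-validation accuracy of a gradient-boosted tree
#' classifier (100 rounds, depth 3) on the individual's own samples. When
#' a class has fewer members than folds the fold count shrinks to the
#' smallest class (minimum 2); with any class at a single sample a seeded
#' 50/50 holdout is used instead; a single-class individual scores 0 with
#' a warning.
#'
#' @param indices individual: distinct 1-based positions into the pool
#' @param features pool feature matrix (rows = pool images)
#' @param labels pool labels (factor or character)
#' @param seed integer seed (derived per individual so evaluation order
#'   does not matter)
#' @param folds maximum number of CV folds
#' @return accuracy in `[0, 1]`
#' @export
evaluate_fitness <- function(indices, features, labels, seed = 1, folds = 3) {
  stopifnot(!anyDuplicated(indices), all(indices >= 1),
            all(indices <= nrow(features)))
  y <- droplevels(as.factor(labels[indices]))
  if (nlevels(y) < 2) {
    warning("single-class individual: fitness 0")
    return(0)
  }
  X <- features[indices, , drop = FALSE]
  sub_seed <- derive_seed(seed, "fitness", paste(sort(indices), collapse = ","))
  min_count <- min(table(y))
  k <- min(folds, min_count)
  if (k < 2) {
    # seeded 50/50 holdout fallback for near-degenerate individuals
    n <- length(y)
    tr <- with_seed(sub_seed, sample.int(n, ceiling(n / 2)))
    if (nlevels(droplevels(y[tr])) < 2 || length(tr) == n) return(0)
    fit <- fit_gbt(X[tr, , drop = FALSE], as.integer(y[tr]) - 1L,
                   nlevels(y), seed = sub_seed)
    pred <- max.col(predict_gbt(fit, X[-tr, , drop = FALSE]),
                    ties.method = "first")
    return(mean(pred == as.integer(y[-tr])))
  }
  fold_id <- stratified_folds(y, k, sub_seed)
  correct <- 0L
  for (fi in seq_len(k)) {
    tr <- fold_id != fi
    fit <- fit_gbt(X[tr, , drop = FALSE], as.integer(y[tr]) - 1L,
                   nlevels(y), seed = derive_seed(sub_seed, fi))
    pred <- max.col(predict_gbt(fit, X[!tr, , drop = FALSE]),
                    ties.method = "first")
    correct <- correct + sum(pred == as.integer(y[!tr]))
  }
  correct / length(y)
}

#' Mutate an individual
#'
#' Draws `m = floor(rate * length(parent))` mutation passes; each pass
#' picks a random position and replaces it with a random in-bounds pool
#' index, resampling until the index is absent from the child so the
#' individual stays a set of distinct samples. `rate = 0` (or a rate small
#' enough that `m = 0`) returns the parent unchanged.
#'
#' @param parent integer vector of distinct pool indices
#' @param rate mutation rate r in `[0, 1]`
#' @param pool_size number of images in the pool
#' @return mutated child, same length, distinct in-bounds indices
#' @export
mutate <- function(parent, rate, pool_size) {
  child <- parent
  m <- floor(rate * length(parent))
  if (m == 0) return(child)
  for (i in seq_len(m)) {
    j <- sample.int(length(child), 1)
    repeat {
      k <- sample.int(pool_size, 1)
      if (!(k %in% child[-j])) break
    }
    child[j] <- k
  }
  child
}

#' Evolve the population and return the best image subset
#'
#' @param features pool feature matrix (one row per pool image), e.g. from
#'   [flatten_images()]
#' @param labels pool labels
#' @param config a [ga_config()]
#' @param fitness_fn optional fitness override `function(indices)` in
#'   `[0, 1]`; defaults to [evaluate_fitness()] on `features` / `labels`
#' @return list: `selected` (the best individual's indices, length S),
#'   `fitness` (its score), `history` (best fitness per generation, length
#'   G), `evaluations` (number of distinct individuals scored)
#' @export
evolve <- function(features, labels, config, fitness_fn = NULL) {
  stopifnot(inherits(config, "ga_config"))
  pool_size <- nrow(features)
  S <- config$sample_size
  N <- config$pop_size
  TT <- config$elite
  if (S > pool_size) stop("sample_size exceeds pool size")
  if (is.null(fitness_fn)) {
    fitness_fn <- function(idx) {
      evaluate_fitness(idx, features, labels, seed = config$seed)
    }
  }
  cache <- new.env(parent = emptyenv())
  score <- function(idx) {
    key <- paste(sort(idx), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- fitness_fn(idx)
    cache[[key]] <- val
    val
  }
  pop <- with_seed(derive_seed(config$seed, "init"), {
    lapply(seq_len(N), function(i) sort(sample.int(pool_size, S)))
  })
  history <- numeric(config$generations)
  for (g in seq_len(config$generations)) {
    fit <- vapply(pop, score, numeric(1))
    ord <- order(fit, decreasing = TRUE)
    elites <- pop[ord[seq_len(TT)]]
    history[g] <- fit[ord[1]]
    if (g == config$generations) {
      pop <- pop[ord]
      break
    }
    children <- with_seed(derive_seed(config$seed, "gen", g), {
      lapply(seq_len(N - TT), function(i) {
        parent <- elites[[sample.int(TT, 1)]]
        mutate(parent, config$mutation_rate, pool_size)
      })
    })
    pop <- c(elites, children)
  }
  best <- pop[[1]]
  list(selected = best, fitness = score(best), history = history,
       evaluations = length(ls(cache)))
}

#' Run the full augmentation-selection stage
#'
#' Generates a candidate pool from the source dataset, evolves the genetic
#' algorithm under the classifier-accuracy fitness and returns the
#' selected images (the D1-style set).
#'
#' @param dataset source images (typically training + validation)
#' @param config a [ga_config()]
#' @param per_image pool candidates per source image
#' @param policy augmentation policy for pool generation
#' @param fitness_resize image side used for the flattened fitness
#'   representation
#' @return list: `selected_images`, `selected_indices`, `pool`, `history`,
#'   `fitness`
#' @export
select_augmented <- function(dataset, config, per_image = 1,
                             policy = augmentation_policy(),
                             fitness_resize = 128) {
  pool <- generate_pool(dataset, per_image = per_image, policy = policy,
                        seed = derive_seed(config$seed, "pool"))
  feats <- flatten_images(pool, resize = fitness_resize)
  res <- evolve(feats, attr(feats, "labels"), config)
  list(selected_images = pool[res$selected],
       selected_indices = res$selected,
       pool = pool,
       history = res$history,
       fitness = res$fitness)
}
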