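# Inheritable bi-objective combinatorial genetic algorithm (IBCGA):
# simultaneous binary feature selection and SVM (C, gamma) tuning,
# maximizing stratified 10-fold CV accuracy. The feature-count r is
# inherited downward from r_start to r_end: each phase runs a full GA at
# fixed r (every chromosome holds exactly r selected features), then all
# individuals drop one random selected gene and r decreases by one. The
# final model X_m is the best individual across all per-phase bests,
# ties broken toward fewer features.

#' IBCGA configuration
#'
#' Defaults are the published operating point: population 50, selection
#' fraction 1.0, crossover fraction 0.8, mutation fraction 0.05, 100
#' generations per phase, r from 70 down to 5, 10-fold CV fitness. The
#' C and gamma grids are standard log2 lattices (the method states none).
#'
#' @param n_pop population size.
#' @param p_s fraction entering the mating pool (tournament selection).
#' @param p_c fraction undergoing orthogonal-array crossover.
#' @param p_m fraction undergoing bit-swap mutation.
#' @param g_max generations per r phase.
#' @param r_start,r_end inclusive range of selected-feature counts.
#' @param cv_folds fitness cross-validation folds.
#' @param c_grid,gamma_grid SVM hyperparameter lattices indexed by the
#'   two parameter genes.
#' @param seed run seed (drives folds and all GA randomness).
#' @return an object of class `ibcga_config`.
#' @export
ibcga_config <- function(n_pop = 50, p_s = 1.0, p_c = 0.8, p_m = 0.05,
                         g_max = 100, r_start = 70, r_end = 5,
                         cv_folds = 10,
                         c_grid = 2^seq(-5, 15, by = 2),
                         gamma_grid = 2^seq(-15, 3, by = 2),
                         seed = 1) {
  stopifnot(r_end >= 1, r_end <= r_start, n_pop >= 2,
            p_s >= 0, p_s <= 1, p_c >= 0, p_c <= 1, p_m >= 0, p_m <= 1)
  structure(list(n_pop = n_pop, p_s = p_s, p_c = p_c, p_m = p_m,
                 g_max = g_max, r_start = r_start, r_end = r_end,
                 cv_folds = cv_folds, c_grid = c_grid,
                 gamma_grid = gamma_grid, seed = seed),
            class = "ibcga_config")
}

new_chromosome <- function(genes, c_idx, g_idx) {
  list(genes = genes, c_idx = as.integer(c_idx), g_idx = as.integer(g_idx))
}

#' Initialize an IBCGA population
#'
#' Each individual selects exactly `r_start` of `n` genes uniformly at
#' random; the C and gamma genes are uniform over their grids.
#'
#' @param config an [ibcga_config()].
#' @param n number of candidate features.
#' @return list of `config$n_pop` chromosomes.
#' @export
initialize_population <- function(config, n) {
  if (config$r_start > n)
    nr_stop("noderad_config_error", "r_start (%d) exceeds n (%d)",
            config$r_start, n)
  lapply(seq_len(config$n_pop), function(i) {
    genes <- logical(n)
    genes[sample.int(n, config$r_start)] <- TRUE
    new_chromosome(genes,
                   sample.int(length(config$c_grid), 1),
                   sample.int(length(config$gamma_grid), 1))
  })
}

#' Chromosome fitness: cross-validated one-vs-one SVM accuracy
#'
#' A pure function of the chromosome within a run: the fold assignment
#' is fixed, so identical chromosomes always score identically.
#'
#' @param chromosome a chromosome (fields `genes`, `c_idx`, `g_idx`).
#' @param X candidate-pool feature matrix. @param y labels (factor).
#' @param fold fold ids from [make_folds()].
#' @param config an [ibcga_config()] (supplies the parameter grids).
#' @return accuracy in \[0, 1\].
#' @export
ibcga_fitness <- function(chromosome, X, y, fold, config) {
  sel <- which(chromosome$genes)
  if (length(sel) == 0)
    nr_stop("noderad_invalid_chromosome", "chromosome selects no features")
  svm_cv_accuracy(X[, sel, drop = FALSE], y, fold,
                  C = config$c_grid[chromosome$c_idx],
                  gamma = config$gamma_grid[chromosome$g_idx])
}

# two-level orthogonal array L_{2^k}: rows x (2^k - 1) columns, levels 1/2
orthogonal_array <- function(rows) {
  k <- as.integer(log2(rows))
  stopifnot(2^k == rows)
  ncols <- rows - 1L
  oa <- matrix(1L, rows, ncols)
  for (i in 0:(rows - 1)) {
    for (j in 1:ncols) {
      oa[i + 1, j] <- 1L + (sum(bitwAnd(i, j) %/% 2^(0:(k - 1)) %% 2) %% 2L)
    }
  }
  oa
}

# restore exact popcount r by random flips, preferring the differing
# positions (keeps children inside the parents' subspace)
repair_popcount <- function(genes, r, positions) {
  cur <- sum(genes)
  while (cur > r) {
    cand <- positions[genes[positions]]
    if (length(cand) == 0) cand <- which(genes)
    genes[cand[sample.int(length(cand), 1)]] <- FALSE
    cur <- cur - 1
  }
  while (cur < r) {
    cand <- positions[!genes[positions]]
    if (length(cand) == 0) cand <- which(!genes)
    genes[cand[sample.int(length(cand), 1)]] <- TRUE
    cur <- cur + 1
  }
  genes
}

#' Orthogonal-array crossover
#'
#' Genes identical in both parents are copied. Differing gene positions
#' are grouped into contiguous factors; the C and gamma genes join as
#' one factor each when they differ. Factor combinations are sampled by
#' a two-level orthogonal array (L8, or L16 when more than 14 genes
#' differ); every row chromosome is repaired to exactly `r` selected
#' genes and evaluated. Child 1 is the best evaluated row; child 2 is
#' the main-effect composition (for each factor, the level with the
#' higher mean row fitness), repaired. Identical parents return copies
#' without any evaluation.
#'
#' @param p1,p2 parent chromosomes with `sum(genes) == r`.
#' @param r current phase feature count.
#' @param fitness_fn function(chromosome) -> fitness.
#' @return list of two child chromosomes (fitness in attribute
#'   `"fitness"` when evaluated).
#' @export
oa_crossover <- function(p1, p2, r, fitness_fn) {
  d <- which(p1$genes != p2$genes)
  cdiff <- p1$c_idx != p2$c_idx
  gdiff <- p1$g_idx != p2$g_idx
  if (length(d) == 0 && !cdiff && !gdiff) {
    attr(p1, "fitness") <- NULL  # never return stale carried fitness
    attr(p2, "fitness") <- NULL
    return(list(p1, p2))
  }

  rows <- if (length(d) > 14) 16L else 8L
  max_gene_factors <- (rows - 1L) - cdiff - gdiff
  k_gene <- min(length(d), max_gene_factors)
  gene_factors <- if (k_gene > 0)
    split(d, ceiling(seq_along(d) / (length(d) / k_gene))) else list()
  n_fac <- length(gene_factors) + cdiff + gdiff
  if (n_fac == 0) n_fac <- 1  # unreachable guard
  oa <- orthogonal_array(rows)[, seq_len(n_fac), drop = FALSE]

  build_row <- function(levels) {
    genes <- p1$genes
    li <- 0
    for (fct in gene_factors) {
      li <- li + 1
      if (levels[li] == 2L) genes[fct] <- p2$genes[fct]
    }
    ci <- p1$c_idx; gi <- p1$g_idx
    if (cdiff) { li <- li + 1; if (levels[li] == 2L) ci <- p2$c_idx }
    if (gdiff) { li <- li + 1; if (levels[li] == 2L) gi <- p2$g_idx }
    new_chromosome(repair_popcount(genes, r, d), ci, gi)
  }

  row_ch <- lapply(seq_len(rows), function(i) build_row(oa[i, ]))
  row_fit <- vapply(row_ch, fitness_fn, 0)

  c1 <- row_ch[[which.max(row_fit)]]
  attr(c1, "fitness") <- max(row_fit)

  best_levels <- vapply(seq_len(n_fac), function(j) {
    m1 <- mean(row_fit[oa[, j] == 1L])
    m2 <- mean(row_fit[oa[, j] == 2L])
    if (m2 > m1) 2L else 1L
  }, 0L)
  c2 <- build_row(best_levels)
  attr(c2, "fitness") <- fitness_fn(c2)
  list(c1, c2)
}

#' Bit-swap mutation
#'
#' One uniformly chosen selected gene and one uniformly chosen
#' unselected gene exchange values (popcount is preserved); with
#' probability `p_m` each of the C and gamma genes moves one grid step
#' up or down. Chromosomes with all genes set or unset are returned
#' unchanged with a warning (no swap is possible).
#'
#' @param chromosome the chromosome to mutate.
#' @param config an [ibcga_config()].
#' @return the mutated chromosome.
#' @export
bit_swap_mutation <- function(chromosome, config) {
  on <- which(chromosome$genes)
  off <- which(!chromosome$genes)
  if (length(on) == 0 || length(off) == 0) {
    nr_warn("bit-swap impossible (popcount %d of %d)", length(on),
            length(chromosome$genes))
    return(chromosome)
  }
  attr(chromosome, "fitness") <- NULL  # genes change below
  i <- on[sample.int(length(on), 1)]
  j <- off[sample.int(length(off), 1)]
  chromosome$genes[i] <- FALSE
  chromosome$genes[j] <- TRUE
  step <- function(idx, n) {
    delta <- if (idx <= 1) 1L else if (idx >= n) -1L else sample(c(-1L, 1L), 1)
    idx + delta
  }
  if (runif(1) < config$p_m)
    chromosome$c_idx <- step(chromosome$c_idx, length(config$c_grid))
  if (runif(1) < config$p_m)
    chromosome$g_idx <- step(chromosome$g_idx, length(config$gamma_grid))
  chromosome
}

#' Run the IBCGA
#'
#' Executes the full inheritance loop over r = r_start .. r_end. Within
#' each phase: fitness evaluation (memoized), tournament-2 selection
#' into a mating pool of size `p_s * n_pop`, orthogonal-array crossover
#' on `p_c * n_pop` randomly chosen individuals, bit-swap mutation on
#' `p_m * n_pop` individuals excluding the best, with elitism (the phase
#' best always survives). After each phase the best individual is
#' recorded as X_r and every chromosome drops one random selected gene.
#' Returns the overall best X_m (ties toward smaller m) plus the
#' main-effect-difference ranking of its features: MED(f) = fitness(X_m)
#' - fitness(X_m with f removed).
#'
#' @param table feature table with `label` (or a numeric matrix given
#'   `y`).
#' @param features candidate-pool feature names (default: all).
#' @param config an [ibcga_config()].
#' @param y labels, required when `table` is a bare matrix.
#' @return an object of class `ibcga_fit`: `features` (selected names),
#'   `m`, `fitness`, `C`, `gamma`, `per_r` (per-phase bests), `med`
#'   (ranking data.frame), `pool`, `config`, `n_evaluations`.
#' @export
ibcga_run <- function(table, features = NULL, config = ibcga_config(), y = NULL) {
  if (is.data.frame(table)) {
    xy <- table_xy(table, features)
    X <- xy$X; y <- droplevels(xy$y); pool <- xy$features
  } else {
    X <- as.matrix(table)
    pool <- features %||% colnames(X)
    X <- X[, pool, drop = FALSE]
    y <- droplevels(as.factor(y))
  }
  n <- ncol(X)
  if (config$r_start > n)
    nr_stop("noderad_config_error", "r_start (%d) exceeds pool size (%d)",
            config$r_start, n)
  fold <- make_folds(y, config$cv_folds, config$seed)

  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  fit_fn <- function(ch) {
    key <- paste(c(ch$c_idx, ch$g_idx, which(ch$genes)), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    v <- ibcga_fitness(ch, X, y, fold, config)
    n_eval <<- n_eval + 1L
    cache[[key]] <- v
    v
  }

  with_seed(config$seed + 104729L, {
    pop <- initialize_population(config, n)
    r <- config$r_start
    per_r <- list()
    trace_r <- integer(0); trace_g <- integer(0); trace_best <- numeric(0)

    repeat {
      fits <- vapply(pop, fit_fn, 0)
      for (g in seq_len(config$g_max)) {
        best_i <- which.max(fits)
        elite <- pop[[best_i]]
        elite_fit <- fits[best_i]

        # tournament-2 selection into the mating pool
        n_sel <- max(2L, round(config$p_s * config$n_pop))
        a <- sample.int(length(pop), n_sel, replace = TRUE)
        b <- sample.int(length(pop), n_sel, replace = TRUE)
        win <- ifelse(fits[a] >= fits[b], a, b)
        pop <- pop[win]
        fits <- fits[win]

        # orthogonal-array crossover on p_c * n_pop individuals
        n_c <- floor(config$p_c * length(pop) / 2) * 2
        if (n_c >= 2) {
          who <- sample.int(length(pop), n_c)
          for (t in seq(1, n_c, by = 2)) {
            i1 <- who[t]; i2 <- who[t + 1]
            ch <- oa_crossover(pop[[i1]], pop[[i2]], r, fit_fn)
            pop[[i1]] <- ch[[1]]
            pop[[i2]] <- ch[[2]]
            # both children were evaluated inside the crossover, so these
            # are cache hits; never trust a carried attribute
            fits[i1] <- fit_fn(ch[[1]])
            fits[i2] <- fit_fn(ch[[2]])
          }
        }

        # bit-swap mutation, excluding the current best
        n_m <- max(1L, round(config$p_m * length(pop)))
        exclude <- which.max(fits)
        cand <- setdiff(seq_along(pop), exclude)
        who_m <- sample(cand, min(n_m, length(cand)))
        for (i in who_m) {
          pop[[i]] <- bit_swap_mutation(pop[[i]], config)
          fits[i] <- fit_fn(pop[[i]])
        }

        # elitism: the previous best always survives
        if (max(fits) < elite_fit) {
          worst <- which.min(fits)
          pop[[worst]] <- elite
          fits[worst] <- elite_fit
        }
        trace_r <- c(trace_r, r)
        trace_g <- c(trace_g, g)
        trace_best <- c(trace_best, max(fits))
      }

      best_i <- which.max(fits)
      per_r[[length(per_r) + 1]] <- list(
        r = r, fitness = fits[best_i], chromosome = pop[[best_i]])

      if (r <= config$r_end) break
      # inheritance: every individual drops one random selected gene
      pop <- lapply(pop, function(ch) {
        attr(ch, "fitness") <- NULL
        on <- which(ch$genes)
        ch$genes[on[sample.int(length(on), 1)]] <- FALSE
        ch
      })
      fits <- vapply(pop, fit_fn, 0)
      r <- r - 1
    }

    per_fit <- vapply(per_r, `[[`, 0, "fitness")
    per_m <- vapply(per_r, `[[`, 0, "r")
    pick <- order(-per_fit, per_m)[1]  # ties -> smaller m (parsimony)
    best <- per_r[[pick]]
    sel <- which(best$chromosome$genes)

    med <- vapply(sel, function(f) {
      ch <- best$chromosome
      ch$genes[f] <- FALSE
      if (sum(ch$genes) == 0) return(best$fitness)
      best$fitness - fit_fn(ch)
    }, 0)
    med_df <- data.frame(feature = pool[sel], med = med)
    med_df <- med_df[order(-med_df$med, med_df$feature), ]
    rownames(med_df) <- NULL

    structure(list(
      features = pool[sel], m = length(sel), fitness = best$fitness,
      C = config$c_grid[best$chromosome$c_idx],
      gamma = config$gamma_grid[best$chromosome$g_idx],
      chromosome = best$chromosome,
      per_r = data.frame(
        r = per_m, fitness = per_fit,
        features = vapply(per_r, function(p)
          paste(pool[which(p$chromosome$genes)], collapse = ";"), "")),
      med = med_df, pool = pool, config = config,
      trace = data.frame(r = trace_r, generation = trace_g,
                         best_fitness = trace_best),
      n_evaluations = n_eval),
      class = "ibcga_fit")
  })
}

#' @export
print.ibcga_fit <- function(x, ...) {
  cat(sprintf("<ibcga_fit> m=%d features, 10-CV fitness %.4f, C=%g, gamma=%g (%d evaluations)\n",
              x$m, x$fitness, x$C, x$gamma, x$n_evaluations))
  cat("top features:", paste(head(x$med$feature, 5), collapse = ", "), "\n")
  invisible(x)
}
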