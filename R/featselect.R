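# closed-form ridge fit (centered), the fast surrogate model behind the
# genetic search and the default RFE trainer
.ridgeFit <- function(X, y, lambda = 1e-2) {
  X <- as.matrix(X)
  xc <- colMeans(X); yc <- mean(y)
  Z <- sweep(X, 2, xc, "-")
  A <- crossprod(Z) + diag(lambda, ncol(Z))
  beta <- solve(A, crossprod(Z, y - yc))
  list(beta = as.numeric(beta), xc = xc, yc = yc)
}

.ridgePredict <- function(fit, X) {
  as.numeric(sweep(as.matrix(X), 2, fit$xc, "-") %*% fit$beta + fit$yc)
}

#' Ridge trainer for feature selection
#'
#' A model-fitting contract usable by [rfeSelect()] and
#' [q2CrossValidation()]: returns a prediction function with a per-feature
#' `importance` attribute (|coefficient| of the centered ridge fit).
#'
#' @param lambda ridge penalty.
#' @return function(X, y) -> prediction function.
#' @export
ridgeTrainer <- function(lambda = 1e-2) {
  function(X, y) {
    fit <- .ridgeFit(X, y, lambda)
    f <- function(Xnew) .ridgePredict(fit, Xnew)
    attr(f, "importance") <- stats::setNames(abs(fit$beta), colnames(X))
    f
  }
}

#' SVR trainer contract
#'
#' Wraps a fixed-hyperparameter RBF SVR as a trainer usable by
#' [q2CrossValidation()] (e.g. for permutation controls or the mean-only
#' baseline comparison).
#'
#' @param mode,C,gamma,epsilon,nu SVR hyperparameters.
#' @return function(X, y) -> prediction function.
#' @export
svrTrainer <- function(mode = "eps", C = 8, gamma = NULL, epsilon = 0.1,
                       nu = 0.5) {
  function(X, y) {
    g <- if (is.null(gamma)) 1 / ncol(X) else gamma
    raw <- .fitSvrRaw(as.matrix(X), y, mode, C, g, epsilon, nu)
    function(Xnew) .predictSvrRaw(raw, g, as.matrix(Xnew))
  }
}

# k-fold CV mean squared error of the ridge surrogate on a column subset
.subsetCvMse <- function(X, y, cols, folds, fold) {
  pred <- rep(NA_real_, length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- .ridgeFit(X[tr, cols, drop = FALSE], y[tr])
    pred[!tr] <- .ridgePredict(fit, X[!tr, cols, drop = FALSE])
  }
  mean((y - pred)^2)
}

#' Genetic-algorithm descriptor subset selection
#'
#' Stochastic subset search in the spirit of the genetic function
#' approximation used in QSAR pipelines: a population of descriptor subsets
#' evolves by tournament selection, uniform crossover and point mutation.
#' Fitness is the (negated) 5-fold cross-validated mean squared error of a
#' ridge-penalized linear fit on the subset; elitism makes the best fitness
#' non-decreasing across generations. Fully deterministic given `seed`.
#'
#' @param X normalized descriptor matrix (columns named).
#' @param y response vector.
#' @param population population size.
#' @param generations number of generations.
#' @param subsetSizeRange integer range c(min, max) of subset sizes explored.
#' @param mutationRate per-offspring gene mutation probability.
#' @param seed integer seed.
#' @param folds CV folds of the fitness evaluation.
#' @return list of class `"GfaResult"`: `selected` (column names), `fitness`
#'   (CV-MSE of the winner, lower is better), `history` (best CV-MSE per
#'   generation).
#' @export
gfaSelect <- function(X, y, population = 100, generations = 50,
                      subsetSizeRange = c(2, 10), mutationRate = 0.2,
                      seed = 1, folds = 5) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  lo <- max(1L, as.integer(subsetSizeRange[1]))
  hi <- as.integer(subsetSizeRange[2])
  if (hi > p) .stopf("subsetSizeRange max (%d) exceeds column count (%d)", hi, p)
  if (lo >= p && hi >= p) lo <- hi <- p
  .withSeed(seed, {
    fold <- sample(rep_len(seq_len(folds), length(y)))
    cache <- new.env(parent = emptyenv())
    fitOf <- function(cols) {
      keyv <- paste(cols, collapse = ",")
      if (!is.null(cache[[keyv]])) return(cache[[keyv]])
      v <- .subsetCvMse(X, y, cols, folds, fold)
      cache[[keyv]] <- v
      v
    }
    pickSize <- function() if (lo == hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
    newChrom <- function() sort(sample.int(p, pickSize()))
    pop <- replicate(population, newChrom(), simplify = FALSE)
    fit <- vapply(pop, fitOf, numeric(1))
    history <- numeric(generations)
    for (g in seq_len(generations)) {
      nextPop <- pop[order(fit)[1:2]]            # elitism
      while (length(nextPop) < population) {
        pick <- function() {                     # tournament of 3
          c3 <- sample.int(population, 3L)
          pop[[c3[which.min(fit[c3])]]]
        }
        a <- pick(); b <- pick()
        pool <- unique(c(a, b))
        size <- min(max(lo, c(length(a), length(b))[sample.int(2L, 1L)]),
                    hi, length(pool))
        child <- sort(pool[sample.int(length(pool), size)])
        if (stats::runif(1) < mutationRate) {    # point mutation: swap a gene
          out <- setdiff(seq_len(p), child)
          if (length(out) && length(child)) {
            drop1 <- child[sample.int(length(child), 1L)]
            child <- sort(c(setdiff(child, drop1),
                            out[sample.int(length(out), 1L)]))
          }
        }
        nextPop[[length(nextPop) + 1L]] <- child
      }
      pop <- nextPop
      fit <- vapply(pop, fitOf, numeric(1))
      history[g] <- min(fit)
    }
    best <- pop[[which.min(fit)]]
    out <- list(selected = colnames(X)[best], fitness = min(fit),
                history = cummin(history))
    class(out) <- c("GfaResult", "list")
    out
  })
}

#' Recursive feature elimination
#'
#' Backward elimination: fit the trainer on the surviving columns, drop the
#' least important one, repeat until `nKeep` columns remain. The elimination
#' order is recorded (first eliminated first).
#'
#' @param X feature matrix (columns named).
#' @param y response.
#' @param trainer a trainer contract whose prediction function carries an
#'   `importance` attribute (see [ridgeTrainer()]).
#' @param nKeep number of columns to retain.
#' @return list of class `"RfeResult"`: `selected`, `eliminated` (in order).
#' @export
rfeSelect <- function(X, y, trainer = ridgeTrainer(), nKeep) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nKeep > ncol(X))
    .stopf("nKeep (%d) exceeds column count (%d)", nKeep, ncol(X))
  surviving <- colnames(X)
  eliminated <- character(0)
  while (length(surviving) > nKeep) {
    f <- tryCatch(trainer(X[, surviving, drop = FALSE], y),
                  error = function(e)
                    .stopf("trainer failed with %d feature(s): %s",
                           length(surviving), conditionMessage(e)))
    imp <- attr(f, "importance")
    if (is.null(imp)) .stopf("trainer does not report feature importance")
    worst <- surviving[which.min(imp[surviving])]
    eliminated <- c(eliminated, worst)
    surviving <- setdiff(surviving, worst)
  }
  out <- list(selected = surviving, eliminated = eliminated)
  class(out) <- c("RfeResult", "list")
  out
}
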