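#' @import methods
NULL

# the 5-part candidate key shared by all pose-level tables
.keyCols <- c("ligand_id", "structure_id", "conformer_id", "run_id", "pose_id")

# single sortable string per candidate; used for deterministic tie-breaks
.keyString <- function(df) {
  paste(df$ligand_id,
        df$structure_id,
        sprintf("%09d", as.integer(df$conformer_id)),
        sprintf("%09d", as.integer(df$run_id)),
        sprintf("%09d", as.integer(df$pose_id)),
        sep = "\r")
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assertScalarNum <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    .stopf("'%s' must be a finite number in [%s, %s]", name, lower, upper)
  invisible(x)
}

# derive a stage-specific 31-bit seed from one global seed, so stages can be
# re-run independently yet reproducibly
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 100003 + h * 7919) %% 2147483647)
}

# run expr with a local RNG state: seeds, then restores the caller's stream
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# seeded fold assignment, stratified by response quantile so every fold sees
# the full response range
.makeFolds <- function(y, folds, seed) {
  n <- length(y)
  if (n < folds) .stopf("need at least %d observations for %d folds", folds, folds)
  .withSeed(seed, {
    ord <- order(y, sample.int(n))      # response order, random within ties
    fold <- integer(n)
    fold[ord] <- ((seq_len(n) - 1L) %% folds) + 1L
    # shuffle fold labels within consecutive response blocks
    for (b in split(ord, ceiling(seq_len(n) / folds))) {
      fold[b] <- sample(fold[b])
    }
    fold
  })
}

.pearsonR2 <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}
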