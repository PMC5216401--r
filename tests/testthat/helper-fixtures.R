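# small fixture builders shared across test files; everything is generated
# in code, nothing is stored on disk

tinyPoseDf <- function(nLigands = 2, nStructures = 2, nConf = 1, nPoses = 3,
                       terms = c("vdw_ext", "hbond"), seed = 42,
                       withRmsd = TRUE) {
  set.seed(seed)
  df <- expand.grid(pose_id = seq_len(nPoses), run_id = 1L,
                    conformer_id = seq_len(nConf),
                    structure_id = sprintf("S%d", seq_len(nStructures)),
                    ligand_id = sprintf("L%d", seq_len(nLigands)),
                    stringsAsFactors = FALSE)
  df <- df[, c("ligand_id", "structure_id", "conformer_id", "run_id", "pose_id")]
  for (t in terms) df[[t]] <- round(rnorm(nrow(df)), 6)
  if (withRmsd) df$observed_rmsd <- round(runif(nrow(df), 0, 5), 6)
  df
}

# a single-group pose table from a raw score matrix (rows = candidates)
scoreTablePose <- function(S) {
  m <- nrow(S)
  df <- data.frame(ligand_id = "L1", structure_id = "S1",
                   conformer_id = 1L, run_id = 1L, pose_id = seq_len(m))
  for (j in seq_len(ncol(S))) df[[paste0("t", j)]] <- S[, j]
  PoseTable(df)
}

# deterministic low-noise regression fixture: y depends on the first column
linearFixture <- function(n = 40, p = 5, noise = 0, seed = 7) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  y <- 3 * X[, 1] + noise * rnorm(n)
  list(X = X, y = y)
}

# benchmark studies are expensive; cache per configuration within a test run
.studyCache <- new.env(parent = emptyenv())
cachedStudy <- function(label, config) {
  if (is.null(.studyCache[[label]]))
    .studyCache[[label]] <- benchmarkStudy(config)
  .studyCache[[label]]
}
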