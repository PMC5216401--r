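# independent direct-formula oracle for every regression statistic; written
# from the definitions with sums only, deliberately not sharing code with the
# package implementation
oracleReport <- function(y, p) {
  n <- length(y)
  res <- y - p
  r <- sum((y - mean(y)) * (p - mean(p))) /
    sqrt(sum((y - mean(y))^2) * sum((p - mean(p))^2))
  k <- sum(y * p) / sum(p * p)
  kp <- sum(y * p) / sum(y * y)
  r02 <- 1 - sum((y - k * p)^2) / sum((y - mean(y))^2)
  r02p <- 1 - sum((p - kp * y)^2) / sum((p - mean(p))^2)
  rm2 <- r^2 * (1 - sqrt(abs(r^2 - r02)))
  rm2p <- r^2 * (1 - sqrt(abs(r^2 - r02p)))
  sxy <- sum((y - mean(y)) * (p - mean(p))) / n
  ccc <- 2 * sxy / (sum((y - mean(y))^2) / n + sum((p - mean(p))^2) / n +
                      (mean(y) - mean(p))^2)
  list(r2 = r^2, rmse = sqrt(sum(res^2) / n), mae = sum(abs(res)) / n,
       s = sqrt(sum((res - mean(res))^2) / (n - 1)), deltaMax = max(abs(res)),
       k = k, kPrime = kp, r02 = r02, r02Prime = r02p, rm2 = rm2,
       rm2Prime = rm2p, rm2Avg = (rm2 + rm2p) / 2,
       deltaRm2 = abs(rm2 - rm2p), ccc = ccc)
}
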