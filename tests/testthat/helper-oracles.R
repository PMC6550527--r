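# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementations they check.

oracle_pwm <- function(sites, k = 0.8, bg = rep(0.25, 4)) {
  bases <- c("A", "C", "G", "T")
  w <- nchar(sites[1])
  n <- matrix(0, 4, w, dimnames = list(bases, NULL))
  for (s in sites) {
    ch <- strsplit(s, "")[[1]]
    for (j in seq_len(w)) n[ch[j], j] <- n[ch[j], j] + 1
  }
  N <- length(sites)
  P <- matrix(0, 4, w, dimnames = list(bases, NULL))
  for (b in 1:4) for (j in 1:w)
    P[b, j] <- (n[b, j] + k * bg[b] * sqrt(N)) / (N + k * sqrt(N))
  list(P = P, W = log2(P / (bg / sum(bg))))
}

oracle_motif_distance <- function(P1, P2) {
  w <- ncol(P1)
  tot <- 0
  for (j in seq_len(w)) {
    ss <- 0
    for (b in 1:4) ss <- ss + (P1[b, j] - P2[b, j])^2
    tot <- tot + sqrt(ss / 2)
  }
  tot / w
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_ols <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  intercept <- my - slope * mx
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - my)^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

oracle_aggregate <- function(records) {
  key <- paste(records$challenger, records$defender, sep = "|")
  out <- list()
  for (kk in unique(key)) {
    rows <- which(key == kk)
    scores <- unlist(records$scores[rows])
    out[[kk]] <- c(n = length(scores), mean = mean(scores),
                   min = min(scores), max = max(scores))
  }
  out
}

random_protein <- function(n) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"), n, TRUE), collapse = "")
}

random_dna_str <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")

random_motif_model <- function(w = 13, n_sites = 10) {
  build_pwm(replicate(n_sites, random_dna_str(w)))
}
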