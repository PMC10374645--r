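# Independent brute-force oracles used by the unit and acceptance tests.
# Each is written as a direct transcription of the defining computation and
# stays independent of the package's implementation path.

# explicit agglomerative average-linkage cophenetic distances
bruteCophenetic <- function(D) {
  n <- nrow(D)
  active <- as.list(seq_len(n))
  cd <- matrix(0, n, n)
  dist2 <- function(a, b) mean(D[a, b])
  while (length(active) > 1) {
    best <- c(1, 2)
    bv <- Inf
    for (i in seq_along(active)) {
      for (j in seq_len(i - 1)) {
        v <- dist2(active[[i]], active[[j]])
        if (v < bv) { bv <- v; best <- c(j, i) }
      }
    }
    a <- active[[best[1]]]
    b <- active[[best[2]]]
    cd[a, b] <- bv
    cd[b, a] <- bv
    active[[best[1]]] <- c(a, b)
    active[[best[2]]] <- NULL
  }
  cd
}

# per-point silhouette widths averaged, straight from the definition
bruteSilhouette <- function(labels, D) {
  n <- length(labels)
  mean(vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1) return(0)
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(D[i, labels == l])
    }, 1))
    (b - a) / max(a, b)
  }, 1))
}

# step-by-step weighted running-sum enrichment score
bruteES <- function(genes, S, set, w = 1) {
  hit <- genes %in% set
  inc <- abs(S)^w * hit
  inc <- if (sum(inc) > 0) inc / sum(inc) else hit / sum(hit)
  dec <- (!hit) / sum(!hit)
  run <- 0
  best <- 0
  for (i in seq_along(genes)) {
    run <- run + inc[i] - dec[i]
    if (abs(run) > abs(best)) best <- run
  }
  best
}
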