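# independent oracles shared across test files; each is a from-scratch
# route that never calls the implementation it checks

# iterative scaling of a 2-way cell table run to tight convergence
rake_2x2_oracle <- function(counts, row_targets, col_targets, iters = 1000) {
  w <- counts
  for (i in seq_len(iters)) {
    w <- w * (row_targets / rowSums(w))
    w <- t(t(w) * (col_targets / colSums(w)))
  }
  w
}

# dimension-1 MCA row scores via eigen() on the standardized residual matrix
mca_row_scores_oracle <- function(df, w) {
  Q <- ncol(df)
  Z <- do.call(cbind, lapply(df, function(col) {
    lv <- sort(unique(as.character(col)))
    vapply(lv, function(l) as.numeric(as.character(col) == l),
           numeric(length(col)))
  }))
  r <- w / sum(w)
  cm <- colSums(Z * r) / Q
  P <- Z * r / Q
  S <- (P - outer(r, cm)) / outer(sqrt(r), sqrt(cm))
  E <- eigen(S %*% t(S), symmetric = TRUE)
  E$vectors[, 1] * sqrt(E$values[1]) / sqrt(r)
}

rand_cat_table <- function(n, q, seed) {
  withr::with_seed(seed, {
    as.data.frame(lapply(seq_len(q), function(j) {
      k <- sample(2:4, 1)
      sample(letters[seq_len(k)], n, replace = TRUE)
    }), col.names = sprintf("v%d", seq_len(q)))
  })
}

# multi-source least-cost distance by plain Bellman-Ford-style relaxation
travel_time_oracle <- function(friction, cell_size, fac_rc) {
  nr <- nrow(friction); nc <- ncol(friction)
  d <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(fac_rc))) d[fac_rc[k, 1], fac_rc[k, 2]] <- 0
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (is.na(friction[r, c])) next
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (is.na(friction[r2, c2])) next
        len <- cell_size * sqrt(dr^2 + dc^2)
        cost <- (friction[r, c] + friction[r2, c2]) / 2 * len
        if (d[r2, c2] + cost < d[r, c] - 1e-15) {
          d[r, c] <- d[r2, c2] + cost
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  d[is.na(friction)] <- NA
  d
}
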