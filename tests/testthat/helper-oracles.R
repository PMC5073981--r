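# Independent brute-force oracles. These deliberately avoid the package's
# own computation paths: dense double loops, pair counting and explicit
# BFS, so that equality tests are meaningful cross-checks.

# AUC as the fraction of (positive, negative) pairs ranked correctly,
# ties counting one half.
brute_auc <- function(scores, positives) {
  ids <- names(scores)
  pos <- scores[ids %in% positives]
  neg <- scores[!(ids %in% positives)]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + (p > n) + 0.5 * (p == n)
    }
  }
  total / (length(pos) * length(neg))
}

# Entrywise log-entropy weighting of a dense count matrix.
brute_log_entropy <- function(F) {
  n <- ncol(F)
  A <- matrix(0, nrow(F), ncol(F), dimnames = dimnames(F))
  for (i in seq_len(nrow(F))) {
    tot <- sum(F[i, ])
    ent <- 0
    for (j in seq_len(n)) {
      p <- F[i, j] / tot
      if (p > 0) ent <- ent + p * log2(p)
    }
    g <- if (n == 1L) 1 else 1 + ent / log2(n)
    for (j in seq_len(n)) {
      A[i, j] <- log2(1 + F[i, j]) * g
    }
  }
  A
}

# Pairwise cosine matrix of the rows of X by explicit double loop.
brute_cosine_rows <- function(X) {
  n <- nrow(X)
  M <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ni <- sqrt(sum(X[i, ]^2))
      nj <- sqrt(sum(X[j, ]^2))
      M[i, j] <- if (ni == 0 || nj == 0) 0 else
        sum(X[i, ] * X[j, ]) / (ni * nj)
    }
  }
  M
}

# Connected components of a symmetric logical adjacency matrix by BFS
# from every node; returns a membership integer vector.
bfs_components <- function(adj) {
  n <- nrow(adj)
  membership <- rep(NA_integer_, n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (!is.na(membership[s])) next
    comp <- comp + 1L
    queue <- s
    membership[s] <- comp
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & is.na(membership))
      membership[nb] <- comp
      queue <- c(queue, nb)
    }
  }
  names(membership) <- rownames(adj)
  membership
}

# Shared-citation counts by explicit set intersection.
brute_shared_citations <- function(map) {
  ents <- sort(unique(map$entity_id))
  sets <- lapply(ents, function(e) unique(map$citation_id[map$entity_id == e]))
  M <- matrix(0L, length(ents), length(ents), dimnames = list(ents, ents))
  for (i in seq_along(ents)) {
    for (j in seq_along(ents)) {
      M[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  M
}
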