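# Independent oracles used to check the estimators against first principles.
# These deliberately share no code with the package internals: the glasso
# oracle maximizes the penalized likelihood directly by cyclic 1-D search
# over the entries of K, and the centrality oracles enumerate every simple
# path of the graph.

# Penalized Gaussian log-likelihood (diagonal unpenalized); -Inf outside PD.
penalized_loglik <- function(K, S, lambda) {
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  2 * sum(log(diag(ch))) - sum(S * K) -
    lambda * (sum(abs(K)) - sum(abs(diag(K))))
}

# Direct numerical maximization over symmetric K by cyclic golden-section
# search on each free entry (a convex problem, so this converges to the
# global optimum regardless of the algorithm used by the implementation).
brute_force_glasso <- function(S, lambda, tol = 1e-10, max_cycles = 500) {
  p <- nrow(S)
  K <- diag(1 / diag(S))
  free <- which(upper.tri(S, diag = TRUE), arr.ind = TRUE)
  for (cycle in seq_len(max_cycles)) {
    K_old <- K
    for (r in seq_len(nrow(free))) {
      i <- free[r, 1]; j <- free[r, 2]
      f1 <- function(v) {
        Kt <- K
        Kt[i, j] <- Kt[j, i] <- v
        ll <- penalized_loglik(Kt, S, lambda)
        if (!is.finite(ll)) return(1e10)  # outside the PD cone
        -ll
      }
      cur <- K[i, j]
      opt <- optimize(f1, interval = c(cur - 2, cur + 2), tol = 1e-12)
      K[i, j] <- K[j, i] <- opt$minimum
    }
    if (max(abs(K - K_old)) < tol) break
  }
  K
}

# Random correlation matrix via a random factor loading.
random_corr <- function(p, k = p + 2) {
  A <- matrix(rnorm(p * k), p, k)
  stats::cov2cor(A %*% t(A) + diag(p) * 0.5)
}

# Build a pcor_network container directly from a weights matrix.
make_net <- function(W, labels = NULL) {
  p <- nrow(W)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  dimnames(W) <- list(labels, labels)
  sc <- matrix("", p, p, dimnames = dimnames(W))
  sc[W > 0] <- "positive"; sc[W < 0] <- "negative"
  structure(list(labels = labels, weights = W, sign_class = sc,
                 lambda = NA_real_, ebic = NA_real_,
                 binary_nodes = character()),
            class = "pcor_network")
}

# Random sparse symmetric weight matrix (zero diagonal) for p <= 7 nodes.
random_weights <- function(p, edge_prob = 0.5) {
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (runif(1) < edge_prob) {
        w <- runif(1, 0.1, 0.9) * sample(c(-1, 1), 1)
        W[i, j] <- W[j, i] <- w
      }
    }
  }
  W
}

# Exhaustive shortest-path census: all simple paths between every pair,
# with distances 1/|w|. Returns per-pair minimum distance, the number of
# tied shortest paths and, per node, the fractional betweenness credit.
enumerate_paths <- function(W, tie_tol = 1e-9) {
  p <- nrow(W)
  D <- 1 / abs(W); diag(D) <- 0
  paths_between <- function(s, t) {
    out <- list()
    walk <- function(path, len) {
      v <- path[length(path)]
      if (v == t) { out[[length(out) + 1]] <<- list(path = path, len = len); return() }
      for (u in seq_len(p)) {
        if (is.finite(D[v, u]) && u != v && !(u %in% path)) {
          walk(c(path, u), len + D[v, u])
        }
      }
    }
    walk(s, 0)
    out
  }
  dist <- matrix(Inf, p, p); diag(dist) <- 0
  credit <- rep(0, p)
  for (s in seq_len(p - 1)) {
    for (t in (s + 1):p) {
      ps <- paths_between(s, t)
      if (length(ps) == 0) next
      lens <- vapply(ps, `[[`, numeric(1), "len")
      dmin <- min(lens)
      dist[s, t] <- dist[t, s] <- dmin
      short <- ps[lens <= dmin + tie_tol]
      nshort <- length(short)
      for (sp in short) {
        inner <- setdiff(sp$path, c(s, t))
        credit[inner] <- credit[inner] + 1 / nshort
      }
    }
  }
  list(dist = dist, betweenness = credit / ((p - 1) * (p - 2) / 2))
}

oracle_closeness <- function(W) {
  d <- enumerate_paths(W)$dist
  vapply(seq_len(nrow(d)), function(i) {
    x <- d[i, -i]; x <- x[is.finite(x)]
    if (length(x) == 0) 0 else 1 / sum(x)
  }, numeric(1))
}

oracle_betweenness <- function(W) enumerate_paths(W)$betweenness
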