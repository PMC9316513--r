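#' Graphical lasso fit at a fixed penalty
#'
#' Estimates a sparse precision matrix by maximizing the L1-penalized
#' Gaussian log-likelihood
#' `log det K - tr(S K) - lambda * sum_{i != j} |K_ij|`
#' (diagonal unpenalized) with blockwise coordinate descent over columns and
#' an inner lasso solve (compiled). Zeros in `K` are exact, produced by the
#' soft-threshold operator, so the regularization-induced sparsity pattern
#' is preserved through all downstream transforms.
#'
#' @param S A [mixed_matrix()] result or a symmetric PSD matrix with unit
#'   diagonal.
#' @param lambda Penalty, >= 0.
#' @param tol Convergence: max absolute change in `K` per full sweep.
#' @param max_sweeps Sweep budget before a non-convergence error.
#' @return An object of class `precision_matrix`: list with `labels`, `K`,
#'   `W` (the working covariance), `lambda`, `sweeps`.
#' @export
glasso_fit <- function(S, lambda, tol = 1e-6, max_sweeps = 500) {
  Sm <- corr_values(S)
  stopifnot(lambda >= 0)
  fit <- .glasso_cd(Sm, lambda, tol = tol, max_sweeps = max_sweeps)
  if (!fit$converged) {
    K <- fit$K
    gap <- sum(Sm * K) + lambda * (sum(abs(K)) - sum(abs(diag(K)))) - nrow(Sm)
    stop("glasso did not converge after ", max_sweeps,
         " sweeps (duality gap ", signif(gap, 4), ")")
  }
  K <- fit$K
  dimnames(K) <- dimnames(Sm)
  structure(list(labels = colnames(Sm), K = K, W = fit$W, lambda = lambda,
                 sweeps = fit$sweeps),
            class = "precision_matrix")
}

corr_values <- function(S) {
  if (inherits(S, "correlation_matrix")) return(S$values)
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (max(abs(S - t(S))) > 1e-8) stop("S is not symmetric")
  if (is.null(colnames(S))) {
    dimnames(S) <- list(paste0("V", seq_len(ncol(S))),
                        paste0("V", seq_len(ncol(S))))
  }
  S
}

#' Extended Bayesian Information Criterion of a glasso solution
#'
#' `score = -n * (log det K - tr(S K)) + E log(n) + 4 E gamma log(p)`,
#' where `E` counts the nonzero off-diagonal entries of the upper triangle
#' of `K`. Only differences across candidate penalties matter for model
#' selection; the additive likelihood constant is fixed by this convention.
#'
#' @param K A `precision_matrix` or positive-definite matrix.
#' @param S Correlation matrix the model was fit to.
#' @param n Sample size (>= 2).
#' @param gamma EBIC hyperparameter (0 = plain BIC; 0.5 conventional).
#' @return The EBIC score (smaller is better).
#' @export
ebic <- function(K, S, n, gamma = 0.5) {
  Km <- if (inherits(K, "precision_matrix")) K$K else K
  Sm <- corr_values(S)
  stopifnot(nrow(Km) == nrow(Sm), n >= 2)
  ld <- determinant(Km, logarithm = TRUE)
  if (ld$sign <= 0) stop("K is not positive definite")
  p <- nrow(Km)
  E <- sum(Km[upper.tri(Km)] != 0)
  -n * (as.numeric(ld$modulus) - sum(Sm * Km)) + E * log(n) + 4 * E * gamma * log(p)
}

#' Partial-correlation network from a precision matrix
#'
#' Applies the standard identity `w_ij = -K_ij / sqrt(K_ii K_jj)` (zero
#' diagonal). Edges incident to a binary node carry sign class
#' `"unsigned-categorical"` (rendered grey in the usual display
#' convention), other edges `"positive"` (green) or `"negative"` (red).
#'
#' @param K A `precision_matrix` (or PD matrix).
#' @param binary_nodes Labels of binary nodes.
#' @param lambda,ebic_value Optional metadata recorded on the network.
#' @return An object of class `pcor_network`: list with `labels`, `weights`
#'   (symmetric, zero diagonal, entries in (-1, 1)), `sign_class`, `lambda`,
#'   `ebic`, `binary_nodes`.
#' @export
precision_to_partial <- function(K, binary_nodes = character(),
                                 lambda = NA_real_, ebic_value = NA_real_) {
  Km <- if (inherits(K, "precision_matrix")) K$K else K
  if (inherits(K, "precision_matrix") && is.na(lambda)) lambda <- K$lambda
  ev <- eigen(Km, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("K is not positive definite")
  d <- sqrt(diag(Km))
  W <- -Km / outer(d, d)
  W[Km == 0] <- 0            # keep glasso's exact zeros exact
  diag(W) <- 0
  labels <- colnames(Km)
  if (is.null(labels)) labels <- paste0("V", seq_len(ncol(Km)))
  dimnames(W) <- list(labels, labels)
  sign_class <- matrix("", nrow(W), ncol(W), dimnames = dimnames(W))
  nz <- W != 0
  cat_node <- labels %in% binary_nodes
  cat_edge <- outer(cat_node, cat_node, `|`)
  sign_class[nz & cat_edge] <- "unsigned-categorical"
  sign_class[nz & !cat_edge & W > 0] <- "positive"
  sign_class[nz & !cat_edge & W < 0] <- "negative"
  structure(list(labels = labels, weights = W, sign_class = sign_class,
                 lambda = lambda, ebic = ebic_value,
                 binary_nodes = binary_nodes),
            class = "pcor_network")
}

#' @export
print.pcor_network <- function(x, ...) {
  el <- as_edge_list(x)
  cat(sprintf("<pcor_network> %d nodes, %d edges (lambda = %s)\n",
              length(x$labels), nrow(el),
              if (is.na(x$lambda)) "?" else signif(x$lambda, 4)))
  if (nrow(el) > 0) {
    for (r in seq_len(nrow(el))) {
      cat(sprintf("  %s -- %s: %+0.3f (%s)\n", el$from[r], el$to[r],
                  el$weight[r], el$sign[r]))
    }
  }
  invisible(x)
}

#' Edge list of a partial-correlation network
#'
#' @param net A `pcor_network`.
#' @return Data frame with `from`, `to`, `weight`, `sign` and `color`
#'   (green/red/grey per the usual rendering convention).
#' @export
as_edge_list <- function(net) {
  stopifnot(inherits(net, "pcor_network"))
  idx <- which(upper.tri(net$weights) & net$weights != 0, arr.ind = TRUE)
  colmap <- c(positive = "green", negative = "red",
              `unsigned-categorical` = "grey")
  sgn <- net$sign_class[idx]
  data.frame(
    from = net$labels[idx[, 1]], to = net$labels[idx[, 2]],
    weight = net$weights[idx],
    sign = sgn, color = unname(colmap[sgn]),
    stringsAsFactors = FALSE
  )
}

#' EBIC-selected regularized partial-correlation network
#'
#' Fits the graphical lasso along a log-spaced penalty grid from
#' `lambda_max` (the largest off-diagonal absolute correlation, where the
#' network is empty) down to `min_ratio * lambda_max`, warm-starting each
#' fit from the previous one, scores every solution with [ebic()], and
#' returns the minimizer. Ties are broken toward the larger penalty
#' (sparser network).
#'
#' @param S A [mixed_matrix()] result, or a plain correlation matrix (then
#'   `n` must be given).
#' @param n Sample size; taken from `S` when it is a `correlation_matrix`.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param grid_size Number of penalty values (default 100).
#' @param min_ratio Smallest penalty as a fraction of `lambda_max`
#'   (default 0.01).
#' @param binary_nodes Labels of binary nodes; taken from `S` when
#'   available.
#' @return A list with `network` (the selected `pcor_network`) and `path`
#'   (class `ebic_path`: data frame of `lambda`, `ebic`, `edges`, plus the
#'   per-lambda precision matrices).
#' @export
select_network <- function(S, n = NULL, gamma = 0.5, grid_size = 100,
                           min_ratio = 0.01, binary_nodes = NULL) {
  if (inherits(S, "correlation_matrix")) {
    if (is.null(n)) n <- S$n
    if (is.null(binary_nodes)) {
      binary_nodes <- S$labels[S$kinds == "binary"]
    }
  }
  if (is.null(binary_nodes)) binary_nodes <- character()
  Sm <- corr_values(S)
  p <- nrow(Sm)
  stopifnot(!is.null(n), n >= 2)
  if (n < p) warning("n < p: estimates will be heavily regularized")
  lambda_max <- max(abs(Sm[upper.tri(Sm)]))
  if (lambda_max < .Machine$double.eps) {
    # independence: empty network at any penalty
    K <- diag(1 / diag(Sm)); dimnames(K) <- dimnames(Sm)
    net <- precision_to_partial(K, binary_nodes, lambda = 0,
                                ebic_value = ebic(K, Sm, n, gamma))
    path <- data.frame(lambda = 0, ebic = net$ebic, edges = 0)
    return(list(network = net,
                path = structure(list(grid = path, K = list(K)),
                                 class = "ebic_path")))
  }
  lambdas <- exp(seq(log(lambda_max), log(min_ratio * lambda_max),
                     length.out = grid_size))
  fit <- .glasso_path_cd(Sm, lambdas)
  scores <- rep(NA_real_, grid_size)
  edges <- rep(NA_integer_, grid_size)
  for (t in seq_len(grid_size)) {
    if (!fit$converged[t]) next
    K <- fit$K[[t]]
    ld <- determinant(K, logarithm = TRUE)
    if (ld$sign <= 0) next
    E <- sum(K[upper.tri(K)] != 0)
    scores[t] <- -n * (as.numeric(ld$modulus) - sum(Sm * K)) +
      E * log(n) + 4 * E * gamma * log(p)
    edges[t] <- E
  }
  if (all(is.na(scores))) stop("no penalty on the grid produced a valid fit")
  # grid is decreasing in lambda; first index attaining the minimum within
  # numerical tolerance is the sparser (larger-lambda) tie-break
  best <- which(scores <= min(scores, na.rm = TRUE) + 1e-9)[1]
  K <- fit$K[[best]]
  dimnames(K) <- dimnames(Sm)
  net <- precision_to_partial(K, binary_nodes, lambda = lambdas[best],
                              ebic_value = scores[best])
  path <- structure(
    list(grid = data.frame(lambda = lambdas, ebic = scores, edges = edges),
         K = fit$K),
    class = "ebic_path"
  )
  list(network = net, path = path)
}

#' Convert a network to an igraph object
#'
#' Vertices keep the node labels (isolated nodes included); edges carry
#' `weight` (signed partial correlation), `distance` (`1/|weight|`),
#' `sign` and `color` attributes.
#'
#' @param net A `pcor_network`.
#' @return An [igraph::graph_from_data_frame()] object.
#' @export
as_igraph <- function(net) {
  el <- as_edge_list(net)
  el$distance <- 1 / abs(el$weight)
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = data.frame(name = net$labels))
  if (!is.na(net$lambda)) g <- igraph::set_graph_attr(g, "lambda", net$lambda)
  if (!is.na(net$ebic)) g <- igraph::set_graph_attr(g, "ebic", net$ebic)
  g
}

#' Export a network as GraphML or labeled adjacency CSV
#'
#' @param net A `pcor_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_csv <- function(net, path) {
  write.csv(as.data.frame(net$weights), path, row.names = TRUE)
  invisible(path)
}
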