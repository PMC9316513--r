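#' Default planted edge list
#'
#' The eight partial correlations reported for the post-COVID pain symptom
#' network: the neuropathic cluster (PainDETECT with S-LANSS and CSI), the
#' sensitization/psychological cluster (CSI with HADS-A, TSK-11 and female
#' gender; HADS-A with HADS-D; TSK-11 with PCS), and the single negative
#' association between sleep quality and quality of life.
#'
#' @return A data frame with columns `from`, `to`, `rho`.
#' @export
default_edge_list <- function() {
  data.frame(
    from = c("PainDETECT", "PainDETECT", "CSI", "CSI", "CSI",
             "HADS_A", "TSK_11", "PSQI"),
    to   = c("S_LANSS", "CSI", "HADS_A", "TSK_11", "Gender",
             "HADS_D", "PCS", "EQ5D5L"),
    rho  = c(0.388, 0.207, 0.269, 0.165, 0.413, 0.598, 0.405, -0.162),
    stringsAsFactors = FALSE
  )
}

#' Build a ground-truth partial-correlation network
#'
#' Constructs the symmetric matrix of planted partial correlations and checks
#' that the implied precision matrix (unit diagonal, off-diagonal
#' `kappa_ij = -rho_ij`) is positive definite, i.e. that a Gaussian graphical
#' model with exactly these partial correlations exists. Infeasible edge sets
#' fail loudly rather than being silently repaired.
#'
#' @param edges Data frame with columns `from`, `to`, `rho` (|rho| < 1).
#'   Defaults to [default_edge_list()].
#' @param labels Ordered node labels; defaults to [default_node_labels()].
#'
#' @return An object of class `ground_truth_network` with elements `labels`,
#'   `partials` (p x p symmetric, zero diagonal), `precision` (the implied
#'   precision matrix) and `sigma` (its inverse, the model covariance).
#' @export
build_ground_truth <- function(edges = default_edge_list(),
                               labels = default_node_labels()) {
  stopifnot(is.character(labels), !anyDuplicated(labels))
  p <- length(labels)
  P <- matrix(0, p, p, dimnames = list(labels, labels))
  if (nrow(edges) > 0) {
    stopifnot(all(c("from", "to", "rho") %in% names(edges)))
    bad <- setdiff(c(edges$from, edges$to), labels)
    if (length(bad) > 0) stop("unknown node label(s): ", paste(bad, collapse = ", "))
    if (any(edges$from == edges$to)) stop("self-edges are not allowed")
    if (any(abs(edges$rho) >= 1)) stop("planted |rho| must be < 1")
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (anyDuplicated(key)) stop("duplicate edge pair(s) in edge list")
    for (e in seq_len(nrow(edges))) {
      i <- edges$from[e]; j <- edges$to[e]
      P[i, j] <- P[j, i] <- edges$rho[e]
    }
  }
  K <- diag(p) - P          # unit diagonal, kappa_ij = -rho_ij
  dimnames(K) <- dimnames(P)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("infeasible network: implied precision is not positive definite ",
         "(eigenvalues ", paste(signif(sort(ev)[seq_len(min(3, p))], 4),
                                collapse = ", "), " ...)")
  }
  sigma <- solve(K)
  structure(list(labels = labels, partials = P, precision = K, sigma = sigma),
            class = "ground_truth_network")
}

#' @export
print.ground_truth_network <- function(x, ...) {
  nz <- which(upper.tri(x$partials) & x$partials != 0, arr.ind = TRUE)
  cat(sprintf("<ground_truth_network> %d nodes, %d planted edges\n",
              length(x$labels), nrow(nz)))
  for (r in seq_len(nrow(nz))) {
    cat(sprintf("  %s -- %s: %+0.3f\n", x$labels[nz[r, 1]],
                x$labels[nz[r, 2]], x$partials[nz[r, 1], nz[r, 2]]))
  }
  invisible(x)
}
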