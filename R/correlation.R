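#' Listwise complete-case filter
#'
#' Drops every record with at least one missing cell, preserving row order,
#' and reports how many records were removed. This mirrors the study's
#' handling of missing questionnaire scores (records dropped, not imputed).
#'
#' @param table A [cohort_table()].
#' @return A list with `table` (the filtered cohort) and `dropped` (count).
#' @export
complete_case_filter <- function(table) {
  keep <- stats::complete.cases(as.data.frame(table))
  if (!any(keep)) stop("empty cohort: every record has a missing cell")
  out <- cohort_table(as.data.frame(table)[keep, , drop = FALSE],
                      cohort_metas(table), check_bounds = FALSE)
  rownames(out) <- NULL
  list(table = out, dropped = sum(!keep))
}

#' Pearson correlation of two continuous vectors
#'
#' Thin wrapper over the product-moment estimator with explicit
#' degenerate-input errors, used for every continuous-continuous pair of
#' the mixed correlation matrix.
#'
#' @param x,y Numeric vectors of equal length >= 3, no missing values.
#' @param xname,yname Labels used in error messages.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_cor <- function(x, y, xname = "x", yname = "y") {
  stopifnot(length(x) == length(y), length(x) >= 3,
            !anyNA(x), !anyNA(y))
  if (var(x) == 0) stop("constant variable: '", xname, "' has zero variance")
  if (var(y) == 0) stop("constant variable: '", yname, "' has zero variance")
  cor(x, y)
}

#' Polyserial correlation of a continuous and a binary vector
#'
#' Two-step maximum-likelihood estimate of the latent correlation under the
#' standard polyserial model: the binary variable arises by thresholding a
#' latent standard normal that is bivariate-normal with the (standardized)
#' continuous variable. Step 1 fixes the threshold from the observed
#' positive rate via the inverse normal CDF; step 2 maximizes the
#' conditional log-likelihood over the correlation by 1-D search bracketed
#' in (-0.999, 0.999) with tolerance 1e-6. Unlike the point-biserial
#' Pearson correlation, this estimator is not attenuated by the
#' dichotomization.
#'
#' @param x Continuous vector (non-constant, no missing values).
#' @param y Binary 0/1 vector with both classes present.
#' @return Latent-scale correlation in `(-1, 1)`.
#' @export
polyserial_cor <- function(x, y) {
  stopifnot(length(x) == length(y), !anyNA(x), !anyNA(y),
            all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("binary variable has a single class")
  if (var(x) == 0) stop("constant variable: x has zero variance")
  z <- (x - mean(x)) / sd(x)
  tau <- qnorm(1 - mean(y))           # y = 1 when latent > tau
  negll <- function(rho) {
    s <- sqrt(1 - rho^2)
    # P(latent > tau | x) = Phi((rho*z - tau)/s)
    p1 <- pnorm((rho * z - tau) / s)
    p1[p1 < 1e-12] <- 1e-12
    p1[p1 > 1 - 1e-12] <- 1 - 1e-12
    -sum(y * log(p1) + (1 - y) * log1p(-p1))
  }
  opt <- optimize(negll, interval = c(-0.999, 0.999), tol = 1e-6)
  opt$minimum
}

#' Mixed Pearson/polyserial correlation matrix of a complete cohort
#'
#' Builds the correlation matrix fed to the graphical lasso: Pearson for
#' continuous-continuous pairs and, in `mode = "mixed"`, polyserial for
#' continuous-binary pairs (binary-binary pairs are not supported; the
#' modeled variable set has a single binary node). If the assembled matrix
#' is indefinite (possible because polyserial entries are estimated
#' pairwise) it is projected to the nearest correlation matrix with
#' [nearest_pd()].
#'
#' @param table A complete [cohort_table()] (no missing cells).
#' @param mode `"mixed"` (default) or `"pearson"`, which treats every
#'   column, including binary ones, with the Pearson estimator (a
#'   sensitivity mode).
#' @return An object of class `correlation_matrix`: list with `labels`,
#'   `values` (symmetric, unit diagonal), `method` (per-entry tag matrix),
#'   `kinds`, `n`, and `repaired` (logical: PSD projection applied).
#' @export
mixed_matrix <- function(table, mode = c("mixed", "pearson")) {
  mode <- match.arg(mode)
  df <- as.data.frame(table)
  if (anyNA(df)) stop("cohort has missing cells; run complete_case_filter() first")
  metas <- cohort_metas(table)
  kinds <- meta_kinds(metas)
  p <- ncol(df)
  labels <- names(df)
  if (nrow(df) < 3) stop("need at least 3 complete records")
  X <- as.matrix(df)
  v <- apply(X, 2, var)
  if (any(v == 0)) {
    stop("constant variable: '", labels[which(v == 0)[1]],
         "' has zero variance")
  }
  binary <- kinds == "binary"
  if (mode == "mixed" && sum(binary) > 1) {
    stop("more than one binary variable: polychoric correlations are not ",
         "supported")
  }
  V <- cor(X)                      # Pearson for every pair ...
  tags <- matrix("pearson", p, p)
  dimnames(V) <- dimnames(tags) <- list(labels, labels)
  diag(tags) <- ""
  if (mode == "mixed" && any(binary)) {
    b <- which(binary)             # ... then overwrite the binary column
    for (j in which(!binary)) {
      V[b, j] <- V[j, b] <- polyserial_cor(X[, j], X[, b])
      tags[b, j] <- tags[j, b] <- "polyserial"
    }
  }
  diag(V) <- 1
  repaired <- FALSE
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    V <- nearest_pd(V)
    repaired <- TRUE
  }
  structure(list(labels = labels, values = V, method = tags, kinds = kinds,
                 n = nrow(df), repaired = repaired),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d x %d (n = %d)%s\n",
              length(x$labels), length(x$labels), x$n,
              if (x$repaired) ", PSD-repaired" else ""))
  print(round(x$values, 3))
  invisible(x)
}

#' Export a correlation matrix as labeled CSV
#'
#' Writes the values with row labels; a companion `*_methods.csv` records
#' the per-entry estimator tags when present.
#'
#' @param S A [mixed_matrix()] result or plain matrix.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(S, path) {
  if (inherits(S, "correlation_matrix")) {
    write.csv(as.data.frame(S$values), path, row.names = TRUE)
    write.csv(as.data.frame(S$method),
              sub("\\.csv$", "_methods.csv", path), row.names = TRUE)
  } else {
    write.csv(as.data.frame(S), path, row.names = TRUE)
  }
  invisible(path)
}

#' Nearest correlation matrix (positive-definite repair)
#'
#' Projects a symmetric matrix to the nearest correlation matrix in
#' Frobenius norm via Higham's alternating-projections scheme (through
#' `Matrix::nearPD`), then floors the spectrum so the smallest eigenvalue
#' is at least `min_eig` while keeping a unit diagonal. Inputs that already
#' satisfy the constraints are returned unchanged.
#'
#' @param m Symmetric numeric matrix.
#' @param min_eig Smallest admissible eigenvalue (default 1e-8).
#' @param maxit Maximum alternating-projection iterations.
#' @return A symmetric positive-definite matrix with unit diagonal.
#' @export
nearest_pd <- function(m, min_eig = 1e-8, maxit = 200) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-8) stop("input is not symmetric")
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= min_eig && max(abs(diag(m) - 1)) < 1e-12) {
    return(m)  # fixed point: already a valid correlation matrix
  }
  fit <- Matrix::nearPD(m, corr = TRUE, maxit = maxit,
                        conv.tol = 1e-10, posd.tol = 1e-7)
  if (!fit$converged) {
    stop("nearest_pd did not converge after ", maxit,
         " iterations (residual ", signif(fit$normF, 4), ")")
  }
  out <- as.matrix(fit$mat)
  ev <- eigen(out, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < min_eig) {
    # blend with the identity just enough to clear the floor
    a <- (min_eig - min(ev)) / (1 - min(ev))
    out <- (1 - a) * out + a * diag(nrow(out))
  }
  diag(out) <- 1
  dimnames(out) <- dimnames(m)
  (out + t(out)) / 2
}
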