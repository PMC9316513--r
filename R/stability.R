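#' Nonparametric bootstrap of edge weights
#'
#' Resamples records with replacement `B` times, re-runs the full
#' estimation pipeline (mixed correlation matrix, then EBIC-glasso) on
#' each resample, and summarizes every node pair by the 2.5th/97.5th
#' percentile interval of its replicate edge weights. Because the penalty
#' shrinks small edges exactly to zero, intervals of weak edges may sit
#' asymmetrically around (or exclude) the point estimate; replicates where
#' estimation fails are excluded and counted, never retried, so results
#' are reproducible under the seed.
#'
#' @param table A complete [cohort_table()].
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param mode Correlation mode passed to [mixed_matrix()].
#' @param gamma,grid_size,min_ratio Passed to [select_network()].
#' @param conf_level Interval coverage (default 0.95).
#' @return An object of class `edge_bootstrap`: list with `point` (the
#'   full-sample `pcor_network`), `ci` (data frame: `from`, `to`, `point`,
#'   `lower`, `upper`, `prop_nonzero`), `replicates` (pairs x B matrix of
#'   weights), `B`, `failed`, `seed`.
#' @export
bootstrap_edges <- function(table, B = 1000, seed, mode = "mixed",
                            gamma = 0.5, grid_size = 100, min_ratio = 0.01,
                            conf_level = 0.95) {
  stopifnot(B >= 1)
  if (missing(seed)) stop("bootstrap_edges() requires an explicit seed")
  df <- as.data.frame(table)
  if (anyNA(df)) stop("cohort has missing cells; run complete_case_filter() first")
  n <- nrow(df)
  metas <- cohort_metas(table)
  fit_once <- function(tab) {
    S <- mixed_matrix(tab, mode = mode)
    select_network(S, gamma = gamma, grid_size = grid_size,
                   min_ratio = min_ratio)$network
  }
  point <- fit_once(table)
  p <- length(point$labels)
  ut <- which(upper.tri(point$weights), arr.ind = TRUE)
  idx <- with_seed(seed, {
    matrix(sample.int(n, n * B, replace = TRUE), nrow = n, ncol = B)
  })
  reps <- matrix(NA_real_, nrow(ut), B)
  failed <- 0L
  for (b in seq_len(B)) {
    tab_b <- cohort_table(df[idx[, b], , drop = FALSE], metas,
                          check_bounds = FALSE)
    net_b <- tryCatch(fit_once(tab_b), error = function(e) NULL)
    if (is.null(net_b)) { failed <- failed + 1L; next }
    reps[, b] <- net_b$weights[ut]
  }
  alpha <- (1 - conf_level) / 2
  ok <- reps[, colSums(is.na(reps)) == 0, drop = FALSE]
  qs <- t(apply(ok, 1, quantile, probs = c(alpha, 1 - alpha), names = FALSE))
  ci <- data.frame(
    from = point$labels[ut[, 1]], to = point$labels[ut[, 2]],
    point = point$weights[ut],
    lower = qs[, 1], upper = qs[, 2],
    prop_nonzero = rowMeans(ok != 0),
    stringsAsFactors = FALSE
  )
  structure(list(point = point, ci = ci, replicates = reps, B = B,
                 failed = failed, conf_level = conf_level, seed = seed),
            class = "edge_bootstrap")
}

#' @export
print.edge_bootstrap <- function(x, ...) {
  cat(sprintf("<edge_bootstrap> B = %d (%d failed), %d%% percentile CIs\n",
              x$B, x$failed, round(100 * x$conf_level)))
  nz <- x$ci[x$ci$point != 0 | x$ci$prop_nonzero > 0.5, ]
  print(nz, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Case-dropping subset bootstrap of centrality indices
#'
#' For each drop proportion `q`, draws `B` subsamples of
#' `ceiling((1 - q) * n)` records without replacement, re-estimates the
#' network and its centralities, and records the Pearson correlation
#' between each subsample centrality vector and the full-sample vector
#' (raw, unscaled values). Replicates whose estimation fails, or whose
#' centrality vector is constant (correlation undefined), are stored as
#' `NA` and treated as non-passing by [cs_coefficient()].
#'
#' @param table A complete [cohort_table()].
#' @param proportions Drop-proportion grid (default 0.05 to 0.75 by 0.05).
#' @param B Subsamples per proportion (default 250).
#' @param seed Integer seed.
#' @param mode,gamma,grid_size,min_ratio Estimator settings as in
#'   [bootstrap_edges()].
#' @return An object of class `case_drop_result`: list with `correlations`
#'   (data frame: `proportion`, `replicate`, `strength`, `closeness`,
#'   `betweenness`), `full` (full-sample [centrality_table()]), `n`, `B`,
#'   `skipped`, `seed`.
#' @export
case_dropping <- function(table, proportions = seq(0.05, 0.75, by = 0.05),
                          B = 250, seed, mode = "mixed", gamma = 0.5,
                          grid_size = 100, min_ratio = 0.01) {
  if (missing(seed)) stop("case_dropping() requires an explicit seed")
  stopifnot(all(proportions >= 0), all(proportions < 1), B >= 1)
  df <- as.data.frame(table)
  if (anyNA(df)) stop("cohort has missing cells; run complete_case_filter() first")
  n <- nrow(df)
  metas <- cohort_metas(table)
  p <- ncol(df)
  if (any(ceiling((1 - proportions) * n) < p + 1)) {
    warning("some retained subsets have fewer than p + 1 records")
  }
  cent_once <- function(tab) {
    S <- mixed_matrix(tab, mode = mode)
    net <- select_network(S, gamma = gamma, grid_size = grid_size,
                          min_ratio = min_ratio)$network
    centrality_table(net)
  }
  full <- cent_once(table)
  # pre-draw all subsample index sets so exclusions cannot break determinism
  draws <- with_seed(seed, {
    lapply(proportions, function(q) {
      m <- ceiling((1 - q) * n)
      lapply(seq_len(B), function(b) sample.int(n, m))
    })
  })
  cor_safe <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }
  rows <- vector("list", length(proportions) * B)
  skipped <- 0L
  r <- 0L
  for (qi in seq_along(proportions)) {
    q <- proportions[qi]
    for (b in seq_len(B)) {
      r <- r + 1L
      ids <- draws[[qi]][[b]]
      res <- if (length(ids) < p + 1) NULL else tryCatch({
        tab_b <- cohort_table(df[ids, , drop = FALSE], metas,
                              check_bounds = FALSE)
        cent_once(tab_b)
      }, error = function(e) NULL)
      if (is.null(res)) {
        skipped <- skipped + 1L
        rows[[r]] <- data.frame(proportion = q, replicate = b,
                                strength = NA_real_, closeness = NA_real_,
                                betweenness = NA_real_)
      } else {
        rows[[r]] <- data.frame(
          proportion = q, replicate = b,
          strength = if (q == 0) 1 else cor_safe(res$strength, full$strength),
          closeness = if (q == 0) 1 else cor_safe(res$closeness, full$closeness),
          betweenness = if (q == 0) 1 else cor_safe(res$betweenness, full$betweenness)
        )
      }
    }
  }
  structure(list(correlations = do.call(rbind, rows), full = full,
                 n = n, B = B, proportions = proportions,
                 skipped = skipped, seed = seed),
            class = "case_drop_result")
}

#' Correlation-stability (CS) coefficient
#'
#' The CS coefficient of a centrality index is the largest drop proportion
#' `q` on the grid such that, at every proportion up to and including `q`,
#' at least the `confidence` fraction of replicates correlate at least
#' `cor_threshold` with the full-sample centralities; 0 when even the
#' smallest proportion fails. Undefined replicate correlations (`NA`)
#' count as failures.
#'
#' @param result A [case_dropping()] result, or a compatible data frame of
#'   per-replicate correlations.
#' @param cor_threshold Correlation retention threshold (default 0.7).
#' @param confidence Required fraction of passing replicates (default 0.95).
#' @return An object of class `cs_coefficient`: named list with one CS
#'   value per index, plus the thresholds used.
#' @export
cs_coefficient <- function(result, cor_threshold = 0.7, confidence = 0.95) {
  cors <- if (inherits(result, "case_drop_result")) result$correlations else result
  stopifnot(is.data.frame(cors), nrow(cors) > 0,
            all(c("proportion", "strength", "closeness", "betweenness")
                %in% names(cors)))
  props <- sort(unique(cors$proportion))
  cs <- vapply(c("strength", "closeness", "betweenness"), function(index) {
    pass <- vapply(props, function(q) {
      v <- cors[[index]][cors$proportion == q]
      mean(!is.na(v) & v >= cor_threshold) >= confidence
    }, logical(1))
    ok <- cumprod(pass) == 1      # every proportion up to q must qualify
    if (!any(ok)) 0 else max(props[ok])
  }, numeric(1))
  structure(list(strength = cs[["strength"]], closeness = cs[["closeness"]],
                 betweenness = cs[["betweenness"]],
                 cor_threshold = cor_threshold, confidence = confidence),
            class = "cs_coefficient")
}

#' @export
print.cs_coefficient <- function(x, ...) {
  cat(sprintf("<cs_coefficient> (cor >= %g, confidence %g)\n",
              x$cor_threshold, x$confidence))
  cat(sprintf("  strength: %g  closeness: %g  betweenness: %g\n",
              x$strength, x$closeness, x$betweenness))
  invisible(x)
}

#' Assemble and serialize a stability report
#'
#' @param edge_boot An [bootstrap_edges()] result (or `NULL`).
#' @param case_drop A [case_dropping()] result (or `NULL`).
#' @param cs A [cs_coefficient()] result (or `NULL`).
#' @return A list of class `stability_report`.
#' @export
stability_report <- function(edge_boot = NULL, case_drop = NULL, cs = NULL) {
  out <- list()
  if (!is.null(edge_boot)) {
    out$edge_bootstrap <- list(B = edge_boot$B, failed = edge_boot$failed,
                               conf_level = edge_boot$conf_level,
                               seed = edge_boot$seed, ci = edge_boot$ci)
  }
  if (!is.null(case_drop)) {
    agg <- stats::aggregate(
      cbind(strength, closeness, betweenness) ~ proportion,
      data = case_drop$correlations, FUN = mean, na.action = stats::na.pass
    )
    out$case_dropping <- list(n = case_drop$n, B = case_drop$B,
                              skipped = case_drop$skipped,
                              seed = case_drop$seed,
                              mean_correlation = agg)
  }
  if (!is.null(cs)) out$cs <- unclass(cs)
  structure(out, class = "stability_report")
}

#' @rdname stability_report
#' @param report A `stability_report`.
#' @param path Output JSON path.
#' @export
write_stability_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Band plot of case-dropping stability
#'
#' Plots, per centrality index, the mean replicate correlation against the
#' drop proportion with a 2.5-97.5 percentile band.
#'
#' @param case_drop A [case_dropping()] result.
#' @param indices Indices to draw.
#' @return Invisibly, the per-proportion summary data frame.
#' @export
plot_case_dropping <- function(case_drop,
                               indices = c("strength", "closeness",
                                           "betweenness")) {
  cors <- case_drop$correlations
  props <- sort(unique(cors$proportion))
  cols <- stats::setNames(c("#1b9e77", "#d95f02", "#7570b3"),
                          c("strength", "closeness", "betweenness"))
  graphics::plot(NULL, xlim = range(props), ylim = c(-1, 1),
                 xlab = "proportion of cases dropped",
                 ylab = "correlation with full-sample centrality")
  graphics::abline(h = 0.7, lty = 3)
  summ <- list()
  for (index in indices) {
    st <- t(vapply(props, function(q) {
      v <- cors[[index]][cors$proportion == q]
      c(mean(v, na.rm = TRUE),
        quantile(v, c(0.025, 0.975), na.rm = TRUE, names = FALSE))
    }, numeric(3)))
    graphics::polygon(c(props, rev(props)), c(st[, 2], rev(st[, 3])),
                      col = grDevices::adjustcolor(cols[index], 0.2),
                      border = NA)
    graphics::lines(props, st[, 1], col = cols[index], lwd = 2)
    summ[[index]] <- data.frame(index = index, proportion = props,
                                mean = st[, 1], lo = st[, 2], hi = st[, 3])
  }
  graphics::legend("bottomleft", legend = indices, col = cols[indices],
                   lwd = 2, bty = "n")
  invisible(do.call(rbind, summ))
}
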