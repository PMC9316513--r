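#' Cohort table
#'
#' A patient-by-variable data frame carrying per-variable metadata. Missing
#' cells are `NA`. Binary columns are coded 0/1.
#'
#' @param records Data frame, one column per variable.
#' @param metas Named list of [variable_meta()] objects, one per column, in
#'   column order.
#' @param check_bounds Validate that observed continuous cells lie within
#'   their instrument bounds (disable for latent-scale data).
#'
#' @return An object of classes `cohort_table` and `data.frame`.
#' @export
cohort_table <- function(records, metas, check_bounds = TRUE) {
  records <- as.data.frame(records)
  if (ncol(records) != length(metas)) {
    stop("cohort has ", ncol(records), " columns but ", length(metas),
         " variable metas")
  }
  names(records) <- vapply(metas, `[[`, "", "name")
  for (m in metas) {
    x <- records[[m$name]]
    if (!is.numeric(x)) stop("column '", m$name, "' is not numeric")
    obs <- x[!is.na(x)]
    if (m$kind == "binary" && !all(obs %in% c(0, 1))) {
      stop("binary column '", m$name, "' has values outside {0, 1}")
    }
    if (m$kind == "continuous" && check_bounds &&
        length(obs) > 0 &&
        (min(obs) < m$scale_min - 1e-9 || max(obs) > m$scale_max + 1e-9)) {
      stop("column '", m$name, "' has values outside [", m$scale_min, ", ",
           m$scale_max, "]")
    }
  }
  structure(records, metas = metas, class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d records x %d variables (%d missing cells)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  NextMethod()
}

cohort_metas <- function(table) {
  m <- attr(table, "metas")
  if (is.null(m)) stop("not a cohort_table: missing variable metadata")
  m
}

#' Sample latent multivariate-normal observations from a planted network
#'
#' Draws i.i.d. rows from the zero-mean Gaussian whose precision matrix is
#' the one implied by the ground-truth partial correlations, so that the
#' population partial correlation of every variable pair given the rest
#' equals the planted value.
#'
#' @param gt A [build_ground_truth()] network.
#' @param n Number of rows (>= 2).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#'
#' @return An `n` x `p` numeric matrix with the network's node labels as
#'   column names.
#' @export
sample_latent <- function(gt, n, seed = NULL) {
  stopifnot(inherits(gt, "ground_truth_network"), n >= 2)
  draw <- function() {
    X <- MASS::mvrnorm(n, mu = rep(0, length(gt$labels)), Sigma = gt$sigma)
    colnames(X) <- gt$labels
    X
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Realize a questionnaire cohort from latent Gaussian data
#'
#' Maps each latent column onto its instrument scale: continuous variables
#' are affinely rescaled to the target mean/SD, clipped to the instrument
#' bounds and rounded to the instrument resolution; the binary variable is
#' produced by thresholding its latent column at the empirical quantile that
#' yields the target positive rate. `continuous = TRUE` skips clipping and
#' rounding (and by default leaves binary variables on the latent scale),
#' which preserves all pairwise Pearson correlations exactly and is used by
#' parameter-recovery simulations.
#'
#' @param latent Numeric matrix from [sample_latent()].
#' @param metas Variable metadata list matching the columns.
#' @param seed Unused (realization is deterministic given the latent data);
#'   kept for interface symmetry with the sampling stage.
#' @param continuous Latent-scale mode: rescale only, no clip/round.
#' @param binarize Threshold binary variables (default: yes unless in
#'   continuous mode; set `TRUE` with `continuous = TRUE` to get a binary
#'   gender over otherwise latent-scale columns).
#'
#' @return A [cohort_table()].
#' @export
realize_cohort <- function(latent, metas, seed = NULL,
                           continuous = FALSE, binarize = !continuous) {
  latent <- as.matrix(latent)
  if (ncol(latent) != length(metas)) {
    stop("latent matrix has ", ncol(latent), " columns but ", length(metas),
         " variable metas")
  }
  out <- as.data.frame(latent)
  metas_out <- metas
  any_latent_scale <- FALSE
  for (k in seq_along(metas)) {
    m <- metas[[k]]
    x <- latent[, k]
    if (m$kind == "binary") {
      if (binarize) {
        thr <- quantile(x, probs = 1 - m$positive_rate, names = FALSE)
        out[[k]] <- as.numeric(x > thr)
      } else {
        # left on the latent scale: downstream treats it as continuous
        metas_out[[k]] <- variable_meta(m$name, "continuous",
                                        mean = 0, sd = 1, digits = 3L)
        any_latent_scale <- TRUE
      }
    } else {
      z <- (x - mean(x)) / sd(x)
      v <- m$mean + m$sd * z
      if (!continuous) {
        v <- pmin(pmax(v, m$scale_min), m$scale_max)
        v <- round(v, m$digits)
      } else {
        any_latent_scale <- TRUE
      }
      out[[k]] <- v
    }
  }
  cohort_table(out, metas_out, check_bounds = !any_latent_scale)
}

#' Missingness specification (missing completely at random)
#'
#' @param counts Named integer vector: exact number of cells to blank per
#'   variable.
#' @param probs Named numeric vector in `[0, 1]`: per-cell missingness
#'   probability per variable (alternative to `counts`).
#'
#' @return An object of class `missingness_spec`.
#' @export
missingness_spec <- function(counts = NULL, probs = NULL) {
  if (!is.null(counts)) {
    stopifnot(!is.null(names(counts)), all(counts >= 0),
              all(counts == round(counts)))
  }
  if (!is.null(probs)) {
    stopifnot(!is.null(names(probs)), all(probs >= 0), all(probs <= 1))
  }
  structure(list(counts = counts, probs = probs, mechanism = "MCAR"),
            class = "missingness_spec")
}

#' Default missingness: 3 missing PainDETECT and 3 missing S-LANSS cells
#' @return A [missingness_spec()].
#' @export
default_missingness_spec <- function() {
  missingness_spec(counts = c(PainDETECT = 3, S_LANSS = 3))
}

#' Blank cells of a cohort completely at random
#'
#' @param table A [cohort_table()].
#' @param spec A [missingness_spec()]; exact counts are placed uniformly at
#'   random within each named variable.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#'
#' @return The cohort with the requested cells set to `NA`.
#' @export
inject_missingness <- function(table, spec, seed = NULL) {
  stopifnot(inherits(spec, "missingness_spec"))
  run <- function() {
    n <- nrow(table)
    for (v in names(spec$counts)) {
      k <- spec$counts[[v]]
      if (!v %in% names(table)) stop("unknown variable '", v, "' in spec")
      if (k > n) stop("missing count for '", v, "' exceeds cohort size")
      if (k > 0) table[sample.int(n, k), v] <- NA
    }
    for (v in names(spec$probs)) {
      if (!v %in% names(table)) stop("unknown variable '", v, "' in spec")
      hit <- stats::runif(n) < spec$probs[[v]]
      table[hit, v] <- NA
    }
    table
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate a complete synthetic cohort in one call
#'
#' Chains [sample_latent()], [realize_cohort()] and [inject_missingness()]
#' under a single seed. Defaults reproduce the study conditions: 146
#' records over the 14 default variables, generated from the eight-edge
#' planted network, with 3 PainDETECT and 3 S-LANSS cells missing
#' completely at random.
#'
#' @param n Cohort size.
#' @param seed Integer seed (required: every stochastic stage is seeded).
#' @param gt Ground-truth network.
#' @param metas Variable metadata.
#' @param missing A [missingness_spec()] or `NULL` for none.
#' @param continuous,binarize Passed to [realize_cohort()].
#'
#' @return A [cohort_table()].
#' @export
simulate_cohort <- function(n = 146, seed, gt = build_ground_truth(),
                            metas = default_variable_metas(),
                            missing = default_missingness_spec(),
                            continuous = FALSE, binarize = !continuous) {
  if (missing(seed)) stop("simulate_cohort() requires an explicit seed")
  with_seed(seed, {
    X <- sample_latent(gt, n)
    tab <- realize_cohort(X, metas, continuous = continuous,
                          binarize = binarize)
    if (!is.null(missing)) tab <- inject_missingness(tab, missing)
    tab
  })
}

#' Write / read a cohort as CSV with a JSON metadata sidecar
#'
#' Missing cells are written as empty fields. The sidecar records each
#' variable's kind, bounds, marginals and resolution so the cohort can be
#' round-tripped.
#'
#' @param table A [cohort_table()].
#' @param path CSV path.
#' @param meta_path Sidecar path; default `paste0(path, ".meta.json")`.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns a [cohort_table()].
#' @export
write_cohort_csv <- function(table, path,
                             meta_path = paste0(path, ".meta.json")) {
  write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  metas <- cohort_metas(table)
  jsonlite::write_json(
    lapply(unname(metas), function(m) m[!vapply(m, function(v) is.na(v) || is.null(v), TRUE)]),
    meta_path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param check_bounds Passed to [cohort_table()].
#' @export
read_cohort_csv <- function(path, meta_path = paste0(path, ".meta.json"),
                            check_bounds = TRUE) {
  df <- read.csv(path, check.names = TRUE)
  raw <- jsonlite::read_json(meta_path, simplifyVector = FALSE)
  metas <- lapply(raw, function(m) {
    variable_meta(m$name, m$kind,
                  scale_min = m$scale_min %||% -Inf,
                  scale_max = m$scale_max %||% Inf,
                  mean = m$mean %||% NA_real_, sd = m$sd %||% NA_real_,
                  positive_rate = m$positive_rate %||% NA_real_,
                  digits = m$digits %||% 0L)
  })
  names(metas) <- vapply(metas, `[[`, "", "name")
  cohort_table(df, metas, check_bounds = check_bounds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
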