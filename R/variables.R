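#' Variable metadata for a cohort column
#'
#' Describes one node of the symptom network: its measurement kind, the
#' instrument's score bounds, the target marginal moments used by the
#' synthetic-cohort generator, and the score resolution (`digits`) the
#' instrument reports.
#'
#' @param name Variable label (syntactic R name).
#' @param kind `"continuous"` or `"binary"`.
#' @param scale_min,scale_max Instrument score bounds (score units).
#' @param mean,sd Target marginal mean and standard deviation (continuous
#'   variables only).
#' @param positive_rate Proportion of 1s (binary variables only), in (0, 1).
#' @param digits Decimal places the instrument resolves to (0 for integer
#'   Likert totals).
#'
#' @return An object of class `variable_meta`.
#' @export
variable_meta <- function(name, kind = c("continuous", "binary"),
                          scale_min = -Inf, scale_max = Inf,
                          mean = NA_real_, sd = NA_real_,
                          positive_rate = NA_real_, digits = 0L) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (!(scale_min < scale_max)) {
    stop("variable_meta('", name, "'): scale_min must be < scale_max")
  }
  if (kind == "continuous") {
    stopifnot(is.finite(mean), is.finite(sd))
    if (sd <= 0) stop("variable_meta('", name, "'): sd must be > 0")
  } else {
    if (!is.finite(positive_rate) || positive_rate <= 0 || positive_rate >= 1) {
      stop("variable_meta('", name, "'): positive_rate must be in (0, 1)")
    }
  }
  structure(
    list(name = name, kind = kind,
         scale_min = scale_min, scale_max = scale_max,
         mean = mean, sd = sd, positive_rate = positive_rate,
         digits = as.integer(digits)),
    class = "variable_meta"
  )
}

#' @export
print.variable_meta <- function(x, ...) {
  if (x$kind == "continuous") {
    cat(sprintf("<variable_meta> %s: continuous [%g, %g], mean %g, sd %g\n",
                x$name, x$scale_min, x$scale_max, x$mean, x$sd))
  } else {
    cat(sprintf("<variable_meta> %s: binary, positive rate %g\n",
                x$name, x$positive_rate))
  }
  invisible(x)
}

#' Default variable set for a post-COVID pain cohort
#'
#' The 14 network nodes with their instrument bounds and published cohort
#' marginals: demographics (age, gender, weight, height, months since
#' symptom onset), health-related quality of life (EQ-5D-5L index), sensory
#' measures (PainDETECT, S-LANSS, CSI), psychological measures (HADS-A,
#' HADS-D, PCS, TSK-11) and sleep quality (PSQI). Gender is the single
#' binary node, coded 0 = male, 1 = female (so `positive_rate` is the
#' female proportion, 1 - 0.468), which makes a positive gender edge mean
#' "higher in females".
#'
#' @return Named list of [variable_meta()] objects in canonical node order.
#' @export
default_variable_metas <- function() {
  m <- list(
    variable_meta("Age",        scale_min = 18,  scale_max = 100, mean = 57.3, sd = 11.7, digits = 0L),
    variable_meta("Gender",     kind = "binary", scale_min = 0, scale_max = 1, positive_rate = 1 - 0.468),
    variable_meta("Weight",     scale_min = 30,  scale_max = 200, mean = 81.8, sd = 17.0, digits = 1L),
    variable_meta("Height",     scale_min = 1.20, scale_max = 2.20, mean = 1.65, sd = 0.10, digits = 2L),
    variable_meta("Duration",   scale_min = 0,   scale_max = 60,  mean = 18.8, sd = 1.8,  digits = 1L),
    variable_meta("HADS_A",     scale_min = 0,   scale_max = 21,  mean = 5.2,  sd = 4.2,  digits = 0L),
    variable_meta("HADS_D",     scale_min = 0,   scale_max = 21,  mean = 4.9,  sd = 4.3,  digits = 0L),
    variable_meta("PSQI",       scale_min = 0,   scale_max = 21,  mean = 8.0,  sd = 4.2,  digits = 0L),
    variable_meta("PainDETECT", scale_min = -1,  scale_max = 38,  mean = 7.0,  sd = 6.2,  digits = 0L),
    variable_meta("S_LANSS",    scale_min = 0,   scale_max = 24,  mean = 7.5,  sd = 8.5,  digits = 0L),
    variable_meta("CSI",        scale_min = 0,   scale_max = 100, mean = 33.9, sd = 17.2, digits = 0L),
    variable_meta("PCS",        scale_min = 0,   scale_max = 52,  mean = 12.3, sd = 12.0, digits = 0L),
    variable_meta("TSK_11",     scale_min = 0,   scale_max = 44,  mean = 24.0, sd = 8.6,  digits = 0L),
    variable_meta("EQ5D5L",     scale_min = 0,   scale_max = 1,   mean = 0.8,  sd = 0.2,  digits = 3L)
  )
  names(m) <- vapply(m, `[[`, "", "name")
  m
}

#' Canonical node labels of the default network
#' @return Character vector of length 14.
#' @export
default_node_labels <- function() names(default_variable_metas())

meta_kinds <- function(metas) vapply(metas, `[[`, "", "kind")
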