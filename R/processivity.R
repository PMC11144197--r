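#' Forward two-allele addition model
#'
#' Probability that the next added repeat matches the current allele:
#' the enzyme either continues processively (probability `p_x`) or
#' dissociates and, by chance, re-associates carrying the same allele
#' (probability `(1 - p_x) * rho`):
#' `P(Add) = p_x + (1 - p_x) * rho`.
#'
#' @param p_x Processive-addition probability, in `[0,1]` (vectorized).
#' @param rho Re-association probability toward the same allele, in
#'   `[0,1]` (vectorized).
#' @return `p_x + (1 - p_x) * rho`.
#' @examples
#' forward_p_add(0, 0.5)    # non-processive: 0.5
#' forward_p_add(0.9, 0.5)  # highly processive: 0.95
#' @export
forward_p_add <- function(p_x, rho) {
  if (!is.numeric(p_x) || any(is.na(p_x)) || any(p_x < 0) || any(p_x > 1))
    stop("p_x must be in [0, 1]", call. = FALSE)
  if (!is.numeric(rho) || any(is.na(rho)) || any(rho < 0) || any(rho > 1))
    stop("rho must be in [0, 1]", call. = FALSE)
  p_x + (1 - p_x) * rho
}

#' Model run-length survival
#'
#' Under the geometric addition model, the probability that a run of
#' same-allele repeats reaches length at least `x` is
#' `P(Add)^(x - 1)`.
#'
#' @inheritParams forward_p_add
#' @param x Run length (`>= 1`, vectorized).
#' @return `forward_p_add(p_x, rho)^(x - 1)`.
#' @examples
#' model_survival(0, 0.5, x = 2:3)  # 0.5, 0.25
#' @export
model_survival <- function(p_x, rho, x) {
  if (any(x < 1)) stop("x must be >= 1", call. = FALSE)
  forward_p_add(p_x, rho)^(x - 1)
}

#' Empirical run-length survival curve
#'
#' `S(x)` is the proportion of maximal runs of the class whose length
#' is at least `x`.  Points are included for `x = 1` up to the largest
#' `x` whose cumulative run count is at least `min_runs`, so that the
#' noisy extreme tail does not enter the log-linear fit.
#'
#' @param table A [run_length_table()].
#' @param repeat_class `"wt"` or `"var"`.
#' @param min_runs Minimum cumulative run count for a point to be kept
#'   (default 5).
#' @param max_x Optional upper limit on `x` (default unlimited).
#' @return A tibble of class `survival_curve` with columns `x`,
#'   `n_at_least`, `S`; total run count in `attr(, "n_runs")` and the
#'   class in `attr(, "repeat_class")`.
#' @export
survival_from_runs <- function(table, repeat_class = c("var", "wt"),
                               min_runs = 5L, max_x = Inf) {
  repeat_class <- match.arg(repeat_class)
  check_count(min_runs, "min_runs")
  tab <- table[table$class == repeat_class, , drop = FALSE]
  if (nrow(tab) == 0L || sum(tab$n_runs) == 0L)
    stop(no_runs_error(repeat_class))
  max_len <- max(tab$run_length)
  counts <- integer(max_len)
  counts[tab$run_length] <- tab$n_runs
  n_at_least <- rev(cumsum(rev(counts)))
  total <- n_at_least[1L]
  keep <- which(n_at_least >= min_runs)
  x_max <- if (length(keep)) min(max(keep), max_x) else 0L
  if (x_max < 1L)
    stop(no_runs_error(repeat_class,
                       msg = paste0("no survival point reaches min_runs = ",
                                    min_runs, " for class ", repeat_class)))
  x <- seq_len(x_max)
  out <- tibble::tibble(x = x, n_at_least = n_at_least[x],
                        S = n_at_least[x] / total)
  class(out) <- c("survival_curve", class(out))
  attr(out, "n_runs") <- total
  attr(out, "repeat_class") <- repeat_class
  out
}

no_runs_error <- function(repeat_class, msg = NULL) {
  structure(
    class = c("telovar_no_runs_error", "error", "condition"),
    list(message = msg %||%
           paste0("no runs observed for repeat class '", repeat_class, "'"),
         call = NULL)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit repeat-addition processivity from a survival curve
#'
#' Ordinary least squares of `log2 S(x)` against `x` (the "line of best
#' fit" on the log2 survival curve).  Under the geometric model the
#' slope is `log2 P(Add)`, so `p_add = 2^slope`, and the
#' processive-addition probability is backed out of the re-association
#' model as `p_x = (p_add - rho) / (1 - rho)`.  Raw values outside
#' `[0,1]` are clamped, flagged, and reported with a warning (a slope
#' steeper than `log2(rho)` has no model interpretation).
#'
#' @param curve A `survival_curve` from [survival_from_runs()], or any
#'   data frame with columns `x` and `S`.
#' @param rho Re-association probability toward this class's allele,
#'   in `[0, 1)`.
#' @param include_s1 Keep the `x = 1` point (`S = 1`) in the
#'   regression (default `TRUE`).
#' @return An object of class `processivity_estimate`: a list with
#'   `repeat_class`, `slope`, `intercept`, `p_add`, `p_x`, `rho_used`,
#'   `n_points_fit`, `r_squared`, `clamped`, plus the unclamped
#'   `p_add_raw` and `p_x_raw`.
#' @examples
#' curve <- data.frame(x = 1:5, S = 0.95^(0:4))
#' fit_processivity(curve, rho = 0.5)  # p_x = 0.9
#' @export
fit_processivity <- function(curve, rho = 0.5, include_s1 = TRUE) {
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) ||
      rho < 0 || rho >= 1)
    stop("rho must be a single probability in [0, 1)", call. = FALSE)
  pts <- as.data.frame(curve)[, c("x", "S")]
  pts <- pts[pts$S > 0, , drop = FALSE]
  if (!include_s1) pts <- pts[pts$x != 1L, , drop = FALSE]
  if (nrow(pts) < 2L)
    stop(structure(
      class = c("telovar_fit_error", "error", "condition"),
      list(message = paste0("insufficient run-length range: ", nrow(pts),
                            " usable point(s), need >= 2"),
           call = NULL)))

  fit <- stats::lm(log2(S) ~ x, data = pts)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  r2 <- suppressWarnings(summary(fit)$r.squared)

  p_add_raw <- 2^slope
  p_x_raw <- (p_add_raw - rho) / (1 - rho)
  clamped <- p_add_raw > 1 || p_x_raw < 0 || p_x_raw > 1
  if (clamped)
    warning("processivity estimate outside [0, 1] was clamped ",
            "(raw p_x = ", signif(p_x_raw, 4), ")", call. = FALSE)

  structure(list(
    repeat_class = attr(curve, "repeat_class") %||% NA_character_,
    slope = slope, intercept = intercept,
    p_add = min(max(p_add_raw, 0), 1),
    p_x = min(max(p_x_raw, 0), 1),
    p_add_raw = p_add_raw, p_x_raw = p_x_raw,
    rho_used = rho, n_points_fit = nrow(pts),
    r_squared = r2, clamped = clamped
  ), class = "processivity_estimate")
}

#' @export
print.processivity_estimate <- function(x, ...) {
  cat(sprintf(
    "Processivity estimate%s\n",
    if (is.na(x$repeat_class)) "" else paste0(" [", x$repeat_class, "]")))
  cat(sprintf("  slope %.4f (log2/repeat), P(Add) = %.4f, P(x) = %.4f%s\n",
              x$slope, x$p_add, x$p_x, if (x$clamped) " [clamped]" else ""))
  cat(sprintf("  rho = %.3f, %d points, R^2 = %.4f\n",
              x$rho_used, x$n_points_fit, x$r_squared))
  invisible(x)
}

#' Estimate processivity for both repeat classes
#'
#' Runs the full estimation path: run-length tabulation (for raw reads:
#' detection, trimming, orientation first), survival-curve
#' construction, and the log2-linear fit, once per repeat class.  The
#' variant class uses re-association probability `rho` and the
#' wild-type class `1 - rho`.  A class with no observed runs yields a
#' `processivity_error` element (with the condition message) instead of
#' aborting, so the other class is still estimated.
#'
#' @param x Raw reads (any container accepted by [as_read_records()]),
#'   a `telovar_array`, or a precomputed [run_length_table()].
#' @param config A [detection_config()] (used for reads input).
#' @param rho Probability that a re-associating telomerase carries the
#'   variant template (default 0.5).
#' @param min_runs,max_x,include_s1 Passed to [survival_from_runs()] /
#'   [fit_processivity()].
#' @return A list of class `processivity_estimates` with elements `wt`
#'   and `var`, each a `processivity_estimate` or `processivity_error`.
#' @export
estimate_processivity <- function(x, config = detection_config(),
                                  rho = 0.5, min_runs = 5L, max_x = Inf,
                                  include_s1 = TRUE) {
  check_prob(rho, "rho")
  table <- if (inherits(x, "run_length_table")) x
           else if (inherits(x, "telovar_array")) run_length_table(x)
           else telomere_runs_from_reads(x, config)
  est_one <- function(cls, rho_used) {
    tryCatch({
      curve <- survival_from_runs(table, cls, min_runs = min_runs,
                                  max_x = max_x)
      est <- fit_processivity(curve, rho = rho_used,
                              include_s1 = include_s1)
      est$repeat_class <- cls
      est
    }, telovar_no_runs_error = function(e) {
      structure(list(repeat_class = cls, error = conditionMessage(e)),
                class = "processivity_error")
    }, telovar_fit_error = function(e) {
      structure(list(repeat_class = cls, error = conditionMessage(e)),
                class = "processivity_error")
    })
  }
  structure(list(wt = est_one("wt", 1 - rho), var = est_one("var", rho)),
            class = "processivity_estimates")
}

#' @export
print.processivity_estimates <- function(x, ...) {
  for (cls in c("wt", "var")) {
    e <- x[[cls]]
    if (inherits(e, "processivity_error")) {
      cat(sprintf("[%s] estimation failed: %s\n", cls, e$error))
    } else {
      print(e)
    }
  }
  invisible(x)
}

#' Plot a log2 survival curve
#'
#' Log2 of the run-length survival fraction against run length, with
#' the fitted line when an estimate is supplied.  Requires ggplot2.
#'
#' @param curve A `survival_curve`.
#' @param estimate Optional `processivity_estimate` to overlay.
#' @return A ggplot object.
#' @export
plot_survival <- function(curve, estimate = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- as.data.frame(curve)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = log2(.data$S))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "consecutive repeats (x)",
                  y = expression(log[2] ~ "proportion of runs" >= x)) +
    ggplot2::theme_minimal()
  if (!is.null(estimate))
    p <- p + ggplot2::geom_abline(slope = estimate$slope,
                                  intercept = estimate$intercept,
                                  linetype = "dashed")
  p
}
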