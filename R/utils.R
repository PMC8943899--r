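# Shared helpers: configuration, classed conditions, weighted statistics.

#' Build a run configuration
#'
#' Central configuration for the pipeline. Unknown keys (top-level or nested)
#' are rejected so typos cannot silently fall back to defaults.
#'
#' @param ... Named overrides. Top-level groups are `descriptor`, `kernel`,
#'   `error_model`, `assignment`, `calibration`, `benchmark`, plus scalar
#'   keys `temperature_K`, `units` and `seed`. Nested overrides are given as
#'   lists, e.g. `dp5_config(kernel = list(sigma = 2))`.
#'
#' @return A named list of class `dp5_config`.
#' @export
#'
#' @examples
#' cfg <- dp5_config(error_model = list(scheme = "two_tail"))
#' cfg$error_model$scheme
dp5_config <- function(...) {
  defaults <- list(
    descriptor = list(
      cutoff = 5.0,            # Angstrom
      n_radial_bins = 24L,
      width = 0.5,             # Angstrom, Gaussian smearing
      elements = c("C", "H", "O", "N"),
      decay_power = 4,         # r^-p damping of neighbour contributions
      angular = FALSE,
      n_angular_bins = 12L
    ),
    kernel = list(sigma = "auto", sigma_quantile = 0.1),
    error_model = list(
      scheme = "window",       # or "two_tail"
      bandwidth = "auto"       # ppm, or "auto" (Silverman, floored at 0.1)
    ),
    assignment = list(allow_partial = TRUE),
    calibration = list(prior_correct = 0.5, n_grid = 512L),
    benchmark = list(folds = 10L, case = "case1", max_error_filter = 10.0),
    temperature_K = 298.15,
    units = list(energy = "kJ/mol"),
    seed = NULL
  )
  overrides <- list(...)
  cfg <- merge_config(defaults, overrides, path = "")
  class(cfg) <- "dp5_config"
  cfg
}

merge_config <- function(base, overrides, path) {
  if (length(overrides) == 0L) return(base)
  nms <- names(overrides)
  if (is.null(nms) || any(!nzchar(nms))) {
    dp5_stop("configuration overrides must be named", "dp5_config_error")
  }
  for (nm in nms) {
    full <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base)) {
      dp5_stop(sprintf("unknown configuration key '%s'", full),
               "dp5_config_error")
    }
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(overrides[[nm]])) {
        dp5_stop(sprintf("configuration key '%s' takes a named list", full),
                 "dp5_config_error")
      }
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]], full)
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

# Gas constant in kJ/(mol K)
.RGAS_KJ <- 8.31446e-3

dp5_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "dp5_error"), call = call))
}

dp5_warn <- function(msg, class = "dp5_warning") {
  warning(warningCondition(msg, class = c(class, "dp5_warning_base")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Area under the ROC curve with case weights
#'
#' Weighted Mann-Whitney statistic: the probability that a randomly drawn
#' positive (weighted) scores above a randomly drawn negative, ties counting
#' one half.
#'
#' @param score Numeric scores (larger = more positive-like).
#' @param label Logical or 0/1, `TRUE` for the positive class.
#' @param weight Optional non-negative case weights (default all 1).
#'
#' @return AUROC in `[0, 1]`.
#' @export
weighted_auroc <- function(score, label, weight = NULL) {
  label <- as.logical(label)
  stopifnot(length(score) == length(label))
  if (is.null(weight)) weight <- rep(1, length(score))
  keep <- is.finite(score) & weight > 0
  score <- score[keep]; label <- label[keep]; weight <- weight[keep]
  sp <- score[label]; wp <- weight[label]
  sn <- score[!label]; wn <- weight[!label]
  if (length(sp) == 0L || length(sn) == 0L) {
    dp5_stop("both classes must be present to compute AUROC", "dp5_value_error")
  }
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  sum(cmp * outer(wp, wn)) / (sum(wp) * sum(wn))
}

# Weighted empirical CDF distance (two-sample Kolmogorov-Smirnov statistic
# with per-observation weights).
weighted_ks_distance <- function(x, y, wx = NULL, wy = NULL) {
  if (is.null(wx)) wx <- rep(1, length(x))
  if (is.null(wy)) wy <- rep(1, length(y))
  grid <- sort(unique(c(x, y)))
  ox <- order(x); oy <- order(y)
  Fx <- stats::stepfun(x[ox], c(0, cumsum(wx[ox]) / sum(wx)))
  Fy <- stats::stepfun(y[oy], c(0, cumsum(wy[oy]) / sum(wy)))
  max(abs(Fx(grid) - Fy(grid)))
}

# Weighted quantile (type-4-like, linear in cumulative weight).
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  sapply(probs, function(p) {
    i <- which(cw >= p)[1]
    if (is.na(i)) x[length(x)] else x[i]
  })
}

# Trapezoid rule on a (possibly non-uniform) grid.
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
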