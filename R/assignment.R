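# Optimal assignment of calculated shifts to experimental peaks, and
# internal (linear) scaling of the resulting prediction errors.

# Square linear sum assignment by the shortest-augmenting-path (Hungarian /
# Jonker-Volgenant) algorithm, O(n^3). Returns, for each row, the column it
# is assigned to. Written here because no LSAP solver is among the package's
# dependencies; exactness is enforced by brute-force comparison in the tests.
solve_lsap <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 0L) return(integer(0))
  u <- numeric(n)            # row potentials
  v <- numeric(n + 1)        # column potentials; slot 1 is the virtual column
  p <- integer(n + 1)        # p[j]: row matched to column j (slot 1 virtual)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      js <- which(!used)
      js <- js[js >= 2L]              # slot 1 is virtual, never a real column
      if (length(js) == 0L) break
      cur <- cost[i0, js - 1L] - u[i0] - v[js]
      upd <- cur < minv[js]
      if (any(upd)) {
        minv[js[upd]] <- cur[upd]
        way[js[upd]] <- j0
      }
      k <- which.min(minv[js])
      delta <- minv[js[k]]
      j1 <- js[k]
      iu <- which(used)
      u[p[iu]] <- u[p[iu]] + delta
      v[iu] <- v[iu] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {                          # augment along the alternating path
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assignment <- integer(n)
  for (j in 2:(n + 1)) assignment[p[j]] <- j - 1L
  assignment
}

#' Assign calculated shifts to experimental peaks
#'
#' Minimum-total-absolute-deviation assignment of the molecule's calculated
#' carbon shifts to the experimental peak list (optimal linear assignment).
#' Peaks with multiplicity m are expanded into m slots before matching. When
#' there are more carbons than peak slots, the optimal subset of carbons is
#' matched and the remainder flagged unassigned; surplus peaks are simply
#' unused.
#'
#' @param calculated_shifts Numeric vector of per-carbon calculated shifts
#'   (ppm, ascending carbon atom index order).
#' @param peaks A `dp5_peaklist`.
#'
#' @return An object of class `dp5_assignment` with fields `mapping`
#'   (assigned peak ppm per carbon, `NA` where unassigned), `peak_index`
#'   (index into the expanded slot list), `unassigned_atoms`, and `cost`
#'   (total absolute deviation over assigned carbons).
#' @export
#'
#' @examples
#' a <- assign_peaks(c(20, 120), peak_list(c(119, 21)))
#' a$mapping    # 21 and 119
#' a$cost       # 2
assign_peaks <- function(calculated_shifts, peaks) {
  if (!inherits(peaks, "dp5_peaklist")) {
    dp5_stop("peaks must be a dp5_peaklist", "dp5_value_error")
  }
  na <- length(calculated_shifts)
  if (na == 0L) dp5_stop("no calculated shifts to assign", "dp5_value_error")
  slots <- rep(peaks$shifts, peaks$multiplicity)
  ns <- length(slots)
  N <- max(na, ns)
  # Pad to square with zero-cost dummies: every dummy row/column is matched
  # exactly once in a perfect matching, so the real part is still minimised.
  cost <- matrix(0, N, N)
  cost[seq_len(na), seq_len(ns)] <- abs(outer(calculated_shifts, slots, "-"))
  sol <- solve_lsap(cost)
  mapping <- rep(NA_real_, na)
  peak_index <- rep(NA_integer_, na)
  for (i in seq_len(na)) {
    j <- sol[i]
    if (j <= ns) {
      mapping[i] <- slots[j]
      peak_index[i] <- j
    }
  }
  structure(list(mapping = mapping, peak_index = peak_index,
                 unassigned_atoms = which(is.na(mapping)),
                 cost = sum(abs(calculated_shifts - mapping), na.rm = TRUE)),
            class = "dp5_assignment")
}

#' Internally scaled prediction errors
#'
#' Fits `delta_exp ~ a * delta_calc + b` by least squares over the assigned
#' carbons and returns the scaled errors
#' `Delta_i = (a * delta_calc_i + b) - delta_exp_i`, removing systematic
#' slope/offset error before statistical analysis. With fewer than three
#' assigned atoms, or a degenerate fit (all calculated shifts equal), the
#' unscaled errors are returned with a warning.
#'
#' @param assignment A `dp5_assignment`.
#' @param calculated_shifts The same per-carbon shifts that were assigned.
#'
#' @return Numeric vector of scaled errors (ppm), `NA` for unassigned atoms,
#'   with attributes `slope`, `intercept` and `scaled`.
#' @export
scale_errors <- function(assignment, calculated_shifts) {
  exp_shift <- assignment$mapping
  ok <- !is.na(exp_shift)
  calc <- calculated_shifts
  if (sum(ok) < 3L || stats::sd(calc[ok]) == 0) {
    if (sum(ok) < 3L) {
      dp5_warn("fewer than 3 assigned atoms; returning unscaled errors",
               "dp5_unscaled_warning")
    } else {
      dp5_warn("degenerate fit (all calculated shifts equal); returning unscaled errors",
               "dp5_unscaled_warning")
    }
    delta <- calc - exp_shift
    attr(delta, "slope") <- 1; attr(delta, "intercept") <- 0
    attr(delta, "scaled") <- FALSE
    return(delta)
  }
  fit <- stats::lm(exp_shift[ok] ~ calc[ok])
  b <- unname(stats::coef(fit)[1]); a <- unname(stats::coef(fit)[2])
  delta <- (a * calc + b) - exp_shift
  attr(delta, "slope") <- a; attr(delta, "intercept") <- b
  attr(delta, "scaled") <- TRUE
  delta
}
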