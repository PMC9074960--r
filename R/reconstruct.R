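# rounding helper: half-away-from-zero with a carried remainder, so that the
# sum of the rounded counts tracks the sum of the ideal (real-valued) counts
round_with_carry <- function(xs) {
  out <- numeric(length(xs))
  carry <- 0
  for (i in seq_along(xs)) {
    v <- xs[i] + carry
    d <- sign(v) * floor(abs(v) + 0.5)
    out[i] <- d
    carry <- v - d
  }
  out
}

#' Reconstruct individual patient data from a digitized Kaplan-Meier curve
#'
#' Inverts the product-limit estimator: given survival coordinates read off
#' a published plot and the matching numbers-at-risk table, allocates whole
#' events and censorings to each inter-risk-time interval so that (a) the
#' Kaplan-Meier estimate of the output reproduces the input survival values
#' and (b) the implied number at risk at each tabulated time matches the
#' table. Within an interval, events sit at the digitized drop times and
#' censorings are spread uniformly; the censoring count is iterated until
#' the implied at-risk count reconciles. Counts are rounded
#' half-away-from-zero with a carried remainder so totals are conserved.
#' The procedure is fully deterministic.
#'
#' When the risk table carries a `total_events` attribute, a final
#' rebalancing pass adjusts the allocation beyond the last tabulated risk
#' time so the overall event count matches it.
#'
#' @param curve A [digitized_curve()].
#' @param risk A [risk_table()]; its first entry gives the initial cohort
#'   size and must lie at (or before) the first curve time.
#' @return An [ipd()] whose KM estimate matches `curve` (to within the
#'   integer-allocation granularity, <= 0.02 absolute for internally
#'   consistent inputs).
#' @export
reconstruct_ipd <- function(curve, risk) {
  stopifnot(inherits(curve, "digitized_curve"), inherits(risk, "risk_table"))
  total_events <- attr(risk, "total_events")

  # drop a leading (0, 1) anchor: no allocation happens at time zero
  pts <- as.data.frame(curve)
  if (pts$time[1] == 0) pts <- pts[-1, , drop = FALSE]
  if (nrow(pts) == 0L) stop("curve has no points after time zero", call. = FALSE)
  if (risk$time[1] > pts$time[1]) {
    stop("risk table must start at or before the first curve time", call. = FALSE)
  }

  J <- nrow(risk)
  ev_time <- numeric(0); ev_n <- numeric(0)     # event times and counts
  cn_time <- numeric(0); cn_n <- numeric(0)     # censor times and counts
  S_cur <- 1                                    # running KM level
  n_cur <- risk$n_at_risk[1]                    # running at-risk count

  # walk one interval: given entry at-risk n0, entry KM level S0, the curve
  # points inside, and a censor count c spread uniformly over (t_lo, t_hi);
  # returns the event allocation and exit state
  walk <- function(n0, S0, pts_j, c, t_lo, t_hi) {
    cens <- if (c > 0) t_lo + (seq_len(c) - 0.5) / c * (t_hi - t_lo) else numeric(0)
    n <- n0; S <- S0; used_cens <- 0; carry <- 0
    d <- numeric(nrow(pts_j))
    for (k in seq_len(nrow(pts_j))) {
      # censorings scheduled before this drop leave the risk set first
      before <- sum(cens <= pts_j$time[k]) - used_cens
      n <- n - before; used_cens <- used_cens + before
      # events needed so the running KM level meets the digitized value,
      # carry-rounded so totals are conserved across drops
      ideal <- if (S > 0 && n > 0) n * (1 - pts_j$survival[k] / S) else 0
      v <- max(0, min(n, ideal)) + carry
      dk <- max(0, min(n, floor(v + 0.5)))
      carry <- v - dk
      if (n > 0 && dk > 0) S <- S * (1 - dk / n)
      n <- n - dk
      d[k] <- dk
    }
    n <- n - (c - used_cens)
    list(d = d, cens = cens, n_end = n, S_end = S)
  }

  for (j in seq_len(J)) {
    t_lo <- risk$time[j]
    t_hi <- if (j < J) risk$time[j + 1] else max(pts$time[nrow(pts)], t_lo)
    in_j <- if (j < J) pts$time > t_lo & pts$time <= t_hi else pts$time > t_lo
    pts_j <- pts[in_j, , drop = FALSE]
    n_target <- if (j < J) risk$n_at_risk[j + 1] else NA_real_

    if (j < J) {
      # iterate the censor count until the implied at-risk matches the table
      c <- 0; res <- NULL
      for (iter in 1:30) {
        res <- walk(n_cur, S_cur, pts_j, c, t_lo, t_hi)
        gap <- res$n_end - n_target
        if (gap == 0 || (gap < 0 && c + gap < 0)) break
        c <- c + gap
      }
      gap <- res$n_end - n_target
      if (gap > 0) {
        # event/censor interplay can oscillate by a unit; park the residual
        # censorings at the interval boundary, where they cannot disturb
        # any drop
        res$cens <- c(res$cens, rep(t_hi, gap))
        res$n_end <- res$n_end - gap
        gap <- 0
      }
      if (gap < 0) {
        # more subjects removed than the risk table allows even with no
        # censoring: a unit or two is integer-rounding slack, absorbed by
        # trimming events at the largest drops; anything larger means the
        # curve and the risk table are genuinely inconsistent
        trim <- -gap
        if (trim > max(2, ceiling(0.02 * n_cur)) || sum(res$d) < trim) {
          stop(sprintf(
            "risk table cannot be reconciled on interval %d [%g, %g]: survival drops imply %d more subjects lost than the at-risk decline allows",
            j, t_lo, t_hi, as.integer(trim)), call. = FALSE)
        }
        d <- res$d
        while (trim > 0) {
          k <- which.max(d)
          d[k] <- d[k] - 1
          trim <- trim - 1
        }
        # recompute the exit KM level along the adjusted path
        n <- n_cur; S <- S_cur; used <- 0
        for (k in seq_len(nrow(pts_j))) {
          before <- sum(res$cens <= pts_j$time[k]) - used
          n <- n - before; used <- used + before
          if (n > 0 && d[k] > 0) S <- S * (1 - d[k] / n)
          n <- n - d[k]
        }
        res$d <- d
        res$S_end <- S
        res$n_end <- n - (length(res$cens) - used)
      }
    } else {
      # terminal interval: no closing risk number; honour total_events if known
      res <- walk(n_cur, S_cur, pts_j, 0, t_lo, t_hi)
      if (!is.null(total_events) && nrow(pts_j) > 0) {
        deficit <- total_events - (sum(ev_n) + sum(res$d))
        if (deficit != 0) {
          d <- res$d
          # distribute the correction one event at a time across the drops,
          # never allocating more events than subjects entering the interval
          capacity <- n_cur - sum(d)
          deficit <- min(deficit, capacity)
          k <- 1L
          while (deficit != 0) {
            if (deficit > 0) {
              d[k] <- d[k] + 1; deficit <- deficit - 1
            } else if (d[k] > 0) {
              d[k] <- d[k] - 1; deficit <- deficit + 1
            }
            k <- if (k == length(d)) 1L else k + 1L
            if (deficit < 0 && all(d == 0)) break
          }
          res$d <- d
          res$n_end <- n_cur - sum(d)
        }
      }
    }

    keep <- res$d > 0
    ev_time <- c(ev_time, pts_j$time[keep]); ev_n <- c(ev_n, res$d[keep])
    if (j < J) {
      c_used <- length(res$cens)
      if (c_used > 0) { cn_time <- c(cn_time, res$cens); cn_n <- c(cn_n, rep(1, c_used)) }
    }
    n_cur <- if (j < J) n_target else res$n_end
    S_cur <- res$S_end
  }

  # subjects still at risk at the end of the curve: administratively censored
  if (n_cur > 0) {
    cn_time <- c(cn_time, max(pts$time))
    cn_n <- c(cn_n, n_cur)
  }

  time <- c(rep(ev_time, ev_n), rep(cn_time, cn_n))
  event <- c(rep(1L, sum(ev_n)), rep(0L, sum(cn_n)))
  if (length(time) == 0L) stop("reconstruction produced no records", call. = FALSE)
  ord <- order(time, -event)
  ipd(time[ord], event[ord])
}
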