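#' Split a periodic trace into phase-aligned cycles
#'
#' Splits a trace recorded under a periodic protocol at the protocol's phase
#' zero-crossings (t = k / f) and resamples every complete cycle onto a
#' common uniform phase grid by linear interpolation; partial cycles are
#' discarded.
#'
#' @param trace A [current_trace()].
#' @param protocol The periodic [voltage_protocol()] that was applied.
#' @param n_phase Number of phase-grid points per cycle.
#' @return A `cycle_set`: list with `phase` (in cycles, \[0, 1)), `voltage`
#'   (V on the phase grid), `currents` (cycles x phase matrix), `period`
#'   (s) and `protocol`.
#' @export
segment_cycles <- function(trace, protocol, n_phase = 2048L) {
  stopifnot(inherits(trace, "current_trace"))
  if (!protocol$kind %in% c("sinusoid", "triangle"))
    stop("cycle segmentation requires a periodic protocol")
  period <- 1 / protocol$frequency
  t0 <- trace$time[1]
  t_end <- trace$time[length(trace$time)] + (trace$time[2] - trace$time[1])
  n_cyc <- floor((t_end - t0) / period + 1e-9)
  if (n_cyc < 1) stop("trace contains no complete cycle")
  phase <- (seq_len(n_phase) - 1) / n_phase
  cur <- matrix(NA_real_, n_cyc, n_phase)
  vol <- matrix(NA_real_, n_cyc, n_phase)
  for (k in seq_len(n_cyc)) {
    tq <- t0 + (k - 1 + phase) * period
    cur[k, ] <- stats::approx(trace$time, trace$current, xout = tq, rule = 2)$y
    vol[k, ] <- stats::approx(trace$time, trace$voltage, xout = tq, rule = 2)$y
  }
  structure(list(phase = phase, voltage = colMeans(vol), currents = cur,
                 period = period, protocol = protocol),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set> %d cycle(s) of %.4g s on a %d-point phase grid\n",
              nrow(x$currents), x$period, length(x$phase)))
  invisible(x)
}

#' Estimate the number of pores in a cycle
#'
#' Regresses the ensemble current against the single-pore open-IV current in
#' a voltage window around V = 0 where no gating takes place; the regression
#' slope is the pore count (possibly fractional).
#'
#' @param current,voltage Samples of one cycle.
#' @param open_iv Single-pore open IV curve.
#' @param window Half-width of the voltage window in V.
#' @return A list with `n_pores`, `r_squared` and `ok` (FALSE if the cycle
#'   should be excluded: non-positive slope or R^2 < 0.5).
#' @export
estimate_pore_count <- function(current, voltage, open_iv, window = 0.05) {
  sel <- abs(voltage) < window
  if (sum(sel) < 20) stop("fewer than 20 samples in the pore-count window")
  x <- iv_interpolate(open_iv, voltage[sel])
  y <- current[sel]
  if (all(abs(y) < .Machine$double.eps) || stats::var(x) == 0)
    stop("no current in the pore-count window (no pores?)")
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  list(n_pores = unname(slope), r_squared = r2,
       ok = is.finite(slope) && slope > 0 && is.finite(r2) && r2 >= 0.5)
}

#' Pore-normalized ensemble current over the cycle
#'
#' Per cycle, the current is divided by that cycle's estimated pore count;
#' cycles are then combined by a pore-count-weighted mean and divided
#' pointwise by the single-pore open current \eqn{I_O(\phi)}.
#'
#' @param cycles A `cycle_set`.
#' @param open_iv Single-pore open IV curve.
#' @param window Pore-count regression window (V).
#' @return List with `phase`, `voltage`, `ratio` (\eqn{I_{ens}/I_O}),
#'   `i_open`, per-cycle `n_pores`, `r_squared` and logical `retained`.
#' @export
normalized_ensemble_current <- function(cycles, open_iv, window = 0.05) {
  stopifnot(inherits(cycles, "cycle_set"))
  n_cyc <- nrow(cycles$currents)
  np <- r2 <- numeric(n_cyc)
  ok <- logical(n_cyc)
  for (k in seq_len(n_cyc)) {
    est <- estimate_pore_count(cycles$currents[k, ], cycles$voltage, open_iv,
                               window)
    np[k] <- est$n_pores; r2[k] <- est$r_squared; ok[k] <- est$ok
  }
  if (!any(ok)) stop("all cycles excluded by the pore-count QC")
  i_open <- iv_interpolate(open_iv, cycles$voltage)
  mean_cur <- colSums(cycles$currents[ok, , drop = FALSE]) / sum(np[ok])
  list(phase = cycles$phase, voltage = cycles$voltage,
       ratio = mean_cur / i_open, i_open = i_open,
       n_pores = np, r_squared = r2, retained = ok)
}

#' Closed-state probability from the normalized current
#'
#' Inverts the two-state ensemble conductance relation: with
#' \eqn{I_{ens}/I_O = 1 - p (1 - \epsilon)}, the closed probability is
#' \eqn{p = (1 - I_{ens}/I_O) / (1 - \epsilon)}. Samples with
#' \eqn{|V| <} `v_mask` are masked (the ratio is ill-defined around the
#' origin). Reported p is clipped to \[0, 1\]; the raw values are kept for
#' QC.
#'
#' @param ratio Normalized ensemble current \eqn{I_{ens}/I_O}.
#' @param epsilon Gated/open conductance ratio in (0, 1).
#' @param voltage Voltage at each sample (for masking); optional.
#' @param v_mask Mask half-width in V.
#' @return List with `p` (clipped, masked with NA), `p_raw` and `mask`.
#' @export
closed_probability <- function(ratio, epsilon = 0.14, voltage = NULL,
                               v_mask = 0.02) {
  if (!(epsilon > 0 && epsilon < 1)) stop("epsilon must be in (0, 1)")
  p_raw <- (1 - ratio) / (1 - epsilon)
  mask <- if (is.null(voltage)) rep(FALSE, length(ratio))
          else abs(voltage) < v_mask
  p <- pmin(pmax(p_raw, 0), 1)
  p[mask] <- NA_real_
  list(p = p, p_raw = p_raw, mask = mask)
}

# Smoothed first derivative by local quadratic (Savitzky-Golay) fitting;
# x may contain NA runs, which are handled segment-wise.
.sg_derivative <- function(x, dt, n_window) {
  n_window <- max(5L, as.integer(n_window))
  if (n_window %% 2 == 0) n_window <- n_window + 1L
  out <- rep(NA_real_, length(x))
  runs <- rle(!is.na(x))
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1
  for (j in seq_along(runs$values)) {
    if (!runs$values[j]) next
    seg <- idx_start[j]:idx_end[j]
    if (length(seg) < n_window) next
    out[seg] <- signal::sgolayfilt(x[seg], p = 2, n = n_window, m = 1, ts = dt)
  }
  out
}

#' Closing rate from the closed-probability waveform
#'
#' The closing-rate estimate \eqn{k_X} is the maximum of \eqn{dp/dt} over
#' the rising-|V| half of each voltage polarity, with the derivative taken
#' by a local-quadratic smoothing filter (window = `window_frac` of one
#' cycle); masked samples are excluded.
#'
#' @param p Closed probability on the phase grid (possibly masked with NA).
#' @param voltage Voltage on the phase grid (V).
#' @param period Cycle period in s.
#' @param window_frac Derivative window as a fraction of the cycle.
#' @return Named vector `c(negative =, positive =)` in 1/s.
#' @export
closing_rate <- function(p, voltage, period, window_frac = 1 / 64) {
  n <- length(p)
  if (length(voltage) != n) stop("p and voltage length mismatch")
  dt <- period / n
  nw <- round(n * window_frac)
  if (nw >= sum(!is.na(p))) stop("derivative window larger than available data")
  dpdt <- .sg_derivative(p, dt, nw)
  dabsv <- c(diff(abs(voltage)), abs(voltage[1]) - abs(voltage[n]))
  rising <- dabsv > 0
  kx <- c(negative = 0, positive = 0)
  for (pol in c("negative", "positive")) {
    sel <- rising & !is.na(dpdt) &
      (if (pol == "negative") voltage < 0 else voltage > 0)
    if (any(sel)) kx[pol] <- max(0, max(dpdt[sel]))
  }
  kx
}

#' Segment a constant-voltage trace into conductance levels
#'
#' Two-cluster segmentation of a d.c. gating trace: the current histogram is
#' thresholded at the density minimum between its two highest modes
#' (fallback: midpoint of the extreme quantiles), and contiguous runs of at
#' least `min_dwell` seconds become levels labelled `open` (larger |current|
#' cluster) or `gated`. A unimodal histogram yields a single open level.
#'
#' @param trace A constant-voltage [current_trace()].
#' @param min_dwell Minimum dwell time of a level in s.
#' @return A data frame with columns `mean_current` (A), `dwell_time` (s)
#'   and `label`; attribute `"ratio"` holds the per-trace mean gated /
#'   mean open current ratio (NA if no gated level).
#' @export
level_segmentation <- function(trace, min_dwell = 0.005) {
  stopifnot(inherits(trace, "current_trace"))
  if (diff(range(trace$voltage)) > 1e-9)
    stop("level segmentation requires a constant-voltage trace")
  x <- trace$current
  dt <- trace$time[2] - trace$time[1]
  dens <- stats::density(x, n = 512)
  dy <- diff(dens$y)
  peaks <- which(c(FALSE, dy[-length(dy)] > 0 & dy[-1] <= 0, FALSE))
  # require modes to be meaningfully separated relative to the spread
  if (length(peaks) >= 2) {
    top <- peaks[order(dens$y[peaks], decreasing = TRUE)][1:2]
    top <- sort(top)
    if (abs(diff(dens$x[top])) < 4 * stats::mad(diff(x)) / sqrt(2))
      peaks <- peaks[1]  # modes indistinguishable from noise: unimodal
  }
  if (length(peaks) < 2) {
    lev <- data.frame(mean_current = mean(x),
                      dwell_time = length(x) * dt, label = "open")
    attr(lev, "ratio") <- NA_real_
    return(lev)
  }
  between <- dens$y[top[1]:top[2]]
  thr <- dens$x[top[1] - 1 + which.min(between)]
  if (!is.finite(thr) || length(between) < 3)
    thr <- mean(stats::quantile(x, c(0.01, 0.99)))
  # cluster with larger |current| is the open state
  open_high <- abs(dens$x[top[2]]) > abs(dens$x[top[1]])
  is_open <- if (open_high) x > thr else x < thr
  runs <- rle(is_open)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$lengths * dt >= min_dwell
  if (!any(keep)) {
    lev <- data.frame(mean_current = mean(x),
                      dwell_time = length(x) * dt, label = "open")
    attr(lev, "ratio") <- NA_real_
    return(lev)
  }
  lev <- data.frame(
    mean_current = vapply(which(keep), function(j) mean(x[starts[j]:ends[j]]),
                          numeric(1)),
    dwell_time = runs$lengths[keep] * dt,
    label = ifelse(runs$values[keep], "open", "gated"))
  open_mean <- mean(x[is_open])
  gated <- lev$label == "gated"
  attr(lev, "ratio") <- if (any(gated))
    mean(lev$mean_current[gated]) / open_mean else NA_real_
  attr(lev, "open_mean") <- open_mean
  lev
}

#' Per-event gated/open current ratios of a d.c. trace
#'
#' @param segments Output of [level_segmentation()].
#' @return Numeric vector of per-gating-event ratios (empty if none).
#' @export
gating_event_ratios <- function(segments) {
  open_mean <- attr(segments, "open_mean")
  if (is.null(open_mean)) return(numeric(0))
  segments$mean_current[segments$label == "gated"] / open_mean
}

# beta from the rising-|V| branches of each retained cycle: per polarity,
# interpolate the pore-normalized current at +/- vref on the branch swept
# from 0 towards that extreme (where no gating has yet occurred for pores
# that reopen near 0 V).
.beta_from_cycles <- function(cycles, np, retained, vref) {
  v <- cycles$voltage
  n <- length(v)
  dabsv <- c(diff(abs(v)), abs(v[1]) - abs(v[n]))
  branch_current <- function(target) {
    sel <- dabsv > 0 & (if (target > 0) v > 0 else v < 0)
    idx <- which(sel)
    vals <- vapply(which(retained), function(k) {
      stats::approx(v[idx], cycles$currents[k, idx], xout = target)$y
    }, numeric(1))
    sum(vals) / sum(np[retained])
  }
  ip <- branch_current(vref)
  im <- branch_current(-vref)
  (ip - abs(im)) / (ip + abs(im))
}

#' Full a.c. gating analysis pipeline
#'
#' Runs cycle segmentation, per-cycle pore-count estimation and QC,
#' pore-weighted cycle averaging, closed-probability inversion, closing-rate
#' extraction and rectification-factor measurement on an ensemble trace.
#'
#' @param trace A [current_trace()] recorded under a periodic protocol.
#' @param open_iv Single-pore open IV curve.
#' @param protocol The applied [voltage_protocol()].
#' @param epsilon Gated/open conductance ratio assumed in the inversion.
#' @param v_mask Mask half-width around V = 0 (V).
#' @param np_window Pore-count regression window (V).
#' @param window_frac Derivative window as a fraction of the cycle.
#' @param vref Reference voltage for the rectification factor (V).
#' @return A `gating_summary` list: `phase`, `voltage`, `p` (masked),
#'   `p_raw`, `ratio`, `k_x` (named, 1/s), `beta`, `n_cycles`,
#'   `n_pores_mean` and `qc`.
#' @export
analyze <- function(trace, open_iv, protocol, epsilon = 0.14, v_mask = 0.02,
                    np_window = 0.05, window_frac = 1 / 64, vref = 0.1) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  cycles <- stage("segment_cycles", segment_cycles(trace, protocol))
  nec <- stage("normalized_ensemble_current",
               normalized_ensemble_current(cycles, open_iv, np_window))
  cp <- stage("closed_probability",
              closed_probability(nec$ratio, epsilon, nec$voltage, v_mask))
  kx <- stage("closing_rate",
              closing_rate(cp$p, nec$voltage, cycles$period, window_frac))
  beta <- stage("rectification_factor",
                .beta_from_cycles(cycles, nec$n_pores, nec$retained, vref))
  structure(list(
    phase = nec$phase, voltage = nec$voltage, p = cp$p, p_raw = cp$p_raw,
    ratio = nec$ratio, k_x = kx, beta = beta,
    n_cycles = sum(nec$retained),
    n_pores_mean = mean(nec$n_pores[nec$retained]),
    qc = list(n_excluded = sum(!nec$retained), r_squared = nec$r_squared,
              n_pores = nec$n_pores, v_mask = v_mask)),
    class = "gating_summary")
}

#' @export
print.gating_summary <- function(x, ...) {
  cat(sprintf("<gating_summary> %d cycle(s), N_p ~ %.2f, beta = %.3f, k_X(-) = %.3g /s, k_X(+) = %.3g /s\n",
              x$n_cycles, x$n_pores_mean, x$beta,
              x$k_x[["negative"]], x$k_x[["positive"]]))
  invisible(x)
}
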