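#' Voltage-dependent two-state gating rate model
#'
#' Phenomenological two-state (open/gated) kinetics: pores close only beyond
#' a critical voltage of the active polarity, with a closing rate that grows
#' exponentially with overvoltage,
#' \eqn{k_{close}(V) = A \exp((|V| - V_c) / v_e)} for \eqn{|V| > V_c} and
#' matching sign, else 0. Pores may reopen, at constant rate
#' `opening_rate`, only while \eqn{|V| <} `reopening_window` and (for
#' single-polarity gaters) the voltage does not exceed a small
#' `release_voltage` on the closing side: a substantial bias of the closing
#' polarity holds the pore shut, while small biases, 0 mV or an
#' opposite-sign bias let it reopen.
#'
#' @param polarity Which voltage sign drives closing: `"negative"`,
#'   `"positive"`, `"both"` or `"none"`.
#' @param critical_voltage Critical voltage \eqn{V_c} in V (> 0). For
#'   `polarity = "both"`, a named vector `c(negative =, positive =)` gives
#'   independent thresholds.
#' @param closing_prefactor Closing rate at \eqn{|V| = V_c}, 1/s.
#' @param closing_efold_voltage e-fold voltage of the closing rate, V.
#' @param opening_rate Reopening rate inside the reopening window, 1/s.
#' @param reopening_window Pores may reopen only when |V| is below this (V).
#' @param release_voltage For single-polarity gaters, largest magnitude of a
#'   closing-sign voltage at which reopening still proceeds (V).
#' @return A `rate_model` object.
#' @examples
#' rm <- rate_model()
#' closing_rate_at(rm, c(-0.2, -0.05, 0.2))
#' @export
rate_model <- function(polarity = c("negative", "positive", "both", "none"),
                       critical_voltage = 0.1,
                       closing_prefactor = 1,
                       closing_efold_voltage = 0.04,
                       opening_rate = 50,
                       reopening_window = 0.15,
                       release_voltage = 0.06) {
  polarity <- match.arg(polarity)
  if (any(critical_voltage <= 0)) stop("critical_voltage must be positive")
  if (closing_prefactor < 0 || opening_rate < 0 || closing_efold_voltage <= 0 ||
      reopening_window < 0 || release_voltage < 0)
    stop("rate parameters must be non-negative (e-fold voltage positive)")
  structure(list(polarity = polarity, critical_voltage = critical_voltage,
                 closing_prefactor = closing_prefactor,
                 closing_efold_voltage = closing_efold_voltage,
                 opening_rate = opening_rate,
                 reopening_window = reopening_window,
                 release_voltage = release_voltage),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("<rate_model> polarity %s, V_c = %s V, A = %.3g /s, v_e = %.3g V, k_open = %.3g /s (|V| < %.3g V)\n",
              x$polarity, paste(signif(x$critical_voltage, 3), collapse = "/"),
              x$closing_prefactor, x$closing_efold_voltage, x$opening_rate,
              x$reopening_window))
  invisible(x)
}

.vc_for_sign <- function(model, negative) {
  vc <- model$critical_voltage
  if (length(vc) == 2 && !is.null(names(vc)))
    return(unname(if (negative) vc[["negative"]] else vc[["positive"]]))
  vc[1]
}

#' Closing and opening rates at a voltage
#'
#' @param model A [rate_model()].
#' @param voltage Voltage(s) in V.
#' @return Rate(s) in 1/s.
#' @export
closing_rate_at <- function(model, voltage) {
  stopifnot(inherits(model, "rate_model"))
  out <- numeric(length(voltage))
  if (model$polarity == "none") return(out)
  for (neg in c(TRUE, FALSE)) {
    if (model$polarity == "positive" && neg) next
    if (model$polarity == "negative" && !neg) next
    vc <- .vc_for_sign(model, neg)
    sel <- if (neg) voltage < 0 else voltage > 0
    act <- sel & abs(voltage) > vc
    out[act] <- model$closing_prefactor *
      exp((abs(voltage[act]) - vc) / model$closing_efold_voltage)
  }
  out
}

#' @rdname closing_rate_at
#' @export
opening_rate_at <- function(model, voltage) {
  stopifnot(inherits(model, "rate_model"))
  ok <- abs(voltage) < model$reopening_window
  # for single-polarity gaters, reopening requires relief from the closing
  # polarity: a substantial voltage of the closing sign holds the pore shut
  # even inside the reopening window, while |V| < release_voltage, 0 mV or
  # an opposite-sign bias reopens it
  if (model$polarity == "negative") ok <- ok & voltage >= -model$release_voltage
  if (model$polarity == "positive") ok <- ok & voltage <= model$release_voltage
  ifelse(ok, model$opening_rate, 0)
}

#' Distribution of gated-state conductance ratios
#'
#' Each closing event draws a fresh conductance ratio
#' \eqn{\epsilon \in (0, 1)} (gated current / open current) from a normal
#' distribution truncated to (0, 1). The default mean of 0.14 reproduces the
#' observation that the gated state conducts 14% of the open-pore current on
#' average, with wide event-to-event diversity.
#'
#' @param mean_ratio Mean of the (untruncated) normal, in (0, 1).
#' @param sd_ratio Standard deviation (>= 0).
#' @return A `closed_state_distribution` object.
#' @export
closed_state_distribution <- function(mean_ratio = 0.14, sd_ratio = 0.05) {
  if (!(mean_ratio > 0 && mean_ratio < 1)) stop("mean_ratio must be in (0, 1)")
  if (sd_ratio < 0) stop("sd_ratio must be >= 0")
  structure(list(mean_ratio = mean_ratio, sd_ratio = sd_ratio),
            class = "closed_state_distribution")
}

#' Draw gated-state conductance ratios
#'
#' @param dist A [closed_state_distribution()].
#' @param n Number of draws.
#' @return Numeric vector in (0, 1).
#' @export
draw_epsilon <- function(dist, n) {
  stopifnot(inherits(dist, "closed_state_distribution"))
  if (n == 0) return(numeric(0))
  if (dist$sd_ratio == 0) return(rep(dist$mean_ratio, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- stats::rnorm(length(need), dist$mean_ratio, dist$sd_ratio)
    ok <- draw > 0 & draw < 1
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Ensemble-mean closed probability (ODE)
#'
#' Deterministic mean-field dynamics of the closed-state probability under a
#' voltage protocol: \eqn{dp/dt = k_{close}(V(t)) (1 - p) - k_{open}(V(t)) p},
#' integrated adaptively.
#'
#' @param model A [rate_model()].
#' @param protocol A [voltage_protocol()].
#' @param p0 Initial closed probability in \[0, 1\].
#' @param sample_rate Optional protocol sample-rate override (Hz).
#' @return A list with `time` (s), `voltage` (V) and `p`.
#' @export
closed_probability_ode <- function(model, protocol, p0 = 0, sample_rate = NULL) {
  if (p0 < 0 || p0 > 1) stop("p0 must be in [0, 1]")
  s <- protocol_samples(protocol, sample_rate)
  vfun <- stats::approxfun(s$time, s$voltage, rule = 2)
  rhs <- function(t, y, parms) {
    v <- vfun(t)
    kc <- closing_rate_at(model, v)
    ko <- opening_rate_at(model, v)
    list(kc * (1 - y) - ko * y)
  }
  sol <- deSolve::ode(y = c(p = p0), times = s$time, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  p <- pmin(pmax(as.numeric(sol[, "p"]), 0), 1)
  if (any(!is.finite(p))) stop("non-finite closed probability")
  list(time = s$time, voltage = s$voltage, p = p)
}

#' Stochastic simulation of a gating pore ensemble
#'
#' Simulates `n_pores` independent two-state pores under a voltage protocol.
#' Per time step `dt` each open pore closes with probability
#' \eqn{1 - e^{-k_{close} dt}} (and symmetrically for reopening); the step is
#' refined internally so that \eqn{\max(k)\,dt < 0.05}. Each closing event
#' draws a fresh gated-conductance ratio \eqn{\epsilon_i}. The ensemble
#' current is the sum of per-pore currents obtained from the open-pore IV
#' curve (gated pores scaled by their \eqn{\epsilon_i}), plus additive
#' Gaussian noise. Fully reproducible from `seed`.
#'
#' @param n_pores Number of pores.
#' @param model A [rate_model()].
#' @param dist A [closed_state_distribution()].
#' @param open_iv Single-pore open IV curve spanning the protocol range.
#' @param protocol A [voltage_protocol()].
#' @param noise_sd Gaussian current-noise standard deviation in A.
#' @param seed Integer RNG seed (mandatory for reproducibility).
#' @param sample_rate Optional protocol sample-rate override (Hz).
#' @param initial_closed_fraction Fraction of pores closed at t = 0 (their
#'   ratios are drawn from `dist`).
#' @return A [current_trace()] whose metadata records the configuration and
#'   the ground truth (`p_true`, the per-event epsilon draws and event
#'   count).
#' @export
simulate_ensemble <- function(n_pores, model, dist, open_iv, protocol,
                              noise_sd = 0, seed = 1, sample_rate = NULL,
                              initial_closed_fraction = 0) {
  stopifnot(inherits(open_iv, "iv_curve"), n_pores >= 1)
  s <- protocol_samples(protocol, sample_rate)
  if (min(s$voltage) < min(open_iv$voltages) ||
      max(s$voltage) > max(open_iv$voltages))
    stop("protocol exceeds the span of the open IV curve")
  dt <- s$time[2] - s$time[1]
  # Per-step rates are averaged over an 8x refined voltage sub-grid so that
  # hard rate switches (V_c, reopening window edges) crossing mid-step are
  # weighted by the fraction of the step they are active, matching the
  # continuous-time kinetics to O(dt/8).
  nv <- length(s$voltage)
  vfine <- stats::approx(seq_len(nv), s$voltage,
                         xout = seq(1, nv + 7 / 8, by = 1 / 8), rule = 2)$y
  kc <- colMeans(matrix(closing_rate_at(model, vfine), nrow = 8))
  ko <- colMeans(matrix(opening_rate_at(model, vfine), nrow = 8))
  # The per-step transition probability 1 - exp(-k dt) is exact while only
  # one rate is active; sub-stepping (capped) is needed only where closing
  # and reopening compete within the same step.
  nsub_i <- ifelse(kc > 0 & ko > 0,
                   pmin(64, pmax(1, ceiling(pmax(kc, ko) * dt / 0.05))), 1L)
  nT <- length(s$time)
  io <- iv_interpolate(open_iv, s$voltage)

  set.seed(seed)
  n <- as.integer(n_pores)
  open <- rep(TRUE, n)
  eps <- rep(NA_real_, n)
  n0 <- round(initial_closed_fraction * n)
  if (n0 > 0) {
    open[seq_len(n0)] <- FALSE
    eps[seq_len(n0)] <- draw_epsilon(dist, n0)
  }
  current <- numeric(nT)
  p_true <- numeric(nT)
  ev_buf <- numeric(0)
  for (i in seq_len(nT)) {
    # sample the state at t_i, then evolve over [t_i, t_i + dt)
    current[i] <- io[i] * (sum(open) + sum(eps[!open]))
    p_true[i] <- (n - sum(open)) / n
    nsub <- nsub_i[i]
    dts <- dt / nsub
    pc <- 1 - exp(-kc[i] * dts)
    po <- 1 - exp(-ko[i] * dts)
    if (pc > 0 || po > 0) {
      for (k in seq_len(nsub)) {
        u <- stats::runif(n)
        closing <- open & u < pc
        reopen <- !open & u < po
        nc <- sum(closing)
        if (nc > 0) {
          eps[closing] <- draw_epsilon(dist, nc)
          ev_buf <- c(ev_buf, eps[closing])
          open[closing] <- FALSE
        }
        if (any(reopen)) open[reopen] <- TRUE
      }
    }
  }
  if (noise_sd > 0) current <- current + stats::rnorm(nT, 0, noise_sd)
  meta <- list(
    protocol = protocol$kind, frequency = protocol$frequency,
    amplitude = protocol$amplitude, baseline = protocol$baseline,
    n_pores = n, seed = seed, noise_sd = noise_sd,
    epsilon_mean = dist$mean_ratio, epsilon_sd = dist$sd_ratio,
    rate_model = unclass(model),
    convention = "positive current = cation flux cis->trans; z = 0 at cis",
    truth = list(p_true = p_true, epsilon_draws = ev_buf,
                 n_closing_events = length(ev_buf)))
  current_trace(s$time, s$voltage, current, metadata = meta)
}

#' Synaptic pulse-protocol simulation
#'
#' Runs a pulse-train protocol over an ensemble and reports the membrane
#' conductance sampled at the baseline voltage after each pulse, normalized
#' by the fully-gated (closed-state) conductance
#' \eqn{N_p \bar\epsilon G_O(V_{base})}. Repeated opening pulses potentiate
#' the conductance towards the fully-open plateau (\eqn{1/\bar\epsilon});
#' repeated closing pulses depress it towards 1.
#'
#' @inheritParams simulate_ensemble
#' @param protocol A pulse-train [voltage_protocol()] (e.g.
#'   `make_protocol("fig6_potentiation")`).
#' @param initial_closed_fraction Initial state; defaults to all-closed for
#'   opening (non-closing) pulse levels and all-open otherwise.
#' @return A data frame with columns `pulse`, `conductance` (S) and
#'   `normalized` (conductance / closed-state conductance), plus the trace
#'   as attribute `"trace"`.
#' @export
run_pulse_protocol <- function(n_pores, model, dist, open_iv, protocol,
                               noise_sd = 0, seed = 1,
                               initial_closed_fraction = NULL) {
  if (protocol$kind != "pulse_train") stop("protocol must be a pulse train")
  if (is.null(initial_closed_fraction))
    initial_closed_fraction <-
      if (closing_rate_at(model, protocol$amplitude) == 0) 1 else 0
  tr <- simulate_ensemble(n_pores, model, dist, open_iv, protocol,
                          noise_sd = noise_sd, seed = seed,
                          initial_closed_fraction = initial_closed_fraction)
  vb <- protocol$baseline
  if (vb == 0) stop("baseline must be non-zero to sample conductance")
  g_open <- iv_interpolate(open_iv, vb) / vb
  g_closed <- n_pores * dist$mean_ratio * g_open
  cyc <- protocol$pulse_width + protocol$inter_pulse_wait
  g <- numeric(protocol$n_pulses)
  for (k in seq_len(protocol$n_pulses)) {
    # sample over the second half of the post-pulse wait
    t0 <- (k - 1) * cyc + protocol$pulse_width + protocol$inter_pulse_wait / 2
    t1 <- k * cyc
    sel <- tr$time >= t0 & tr$time < t1
    g[k] <- mean(tr$current[sel]) / vb
  }
  out <- data.frame(pulse = seq_len(protocol$n_pulses), conductance = g,
                    normalized = g / g_closed)
  attr(out, "trace") <- tr
  out
}

#' Ergodicity check: time average vs ensemble average
#'
#' Compares the cycle-averaged, pore-normalized current loop of a single
#' pore measured over many cycles with that of a multi-pore ensemble
#' measured over fewer cycles, on a common phase grid. Both loops are
#' normalized by the open-pore current, lightly smoothed over a
#' `smooth_frac` fraction of the cycle, and masked around V = 0 where the
#' normalization is ill-defined.
#'
#' @param trace_single,trace_ensemble [current_trace()]s recorded under the
#'   same periodic protocol.
#' @param protocol The shared [voltage_protocol()].
#' @param open_iv Single-pore open IV curve.
#' @param mask_v Half-width of the voltage mask around 0 V.
#' @param n_bins Number of voltage bins per sweep branch.
#' @return Maximum absolute discrepancy of the two normalized loops.
#' @export
ergodicity_check <- function(trace_single, trace_ensemble, protocol, open_iv,
                             mask_v = 0.02, n_bins = 24L) {
  f1 <- trace_single$metadata$frequency
  f2 <- trace_ensemble$metadata$frequency
  if (!is.null(f1) && !is.null(f2) && !isTRUE(all.equal(f1, f2)))
    stop("traces were recorded under different protocols")
  loop <- function(tr) {
    cs <- segment_cycles(tr, protocol)
    nec <- normalized_ensemble_current(cs, open_iv)
    v <- nec$voltage
    n <- length(v)
    rising <- c(diff(v), v[1] - v[n]) > 0
    keep <- abs(v) >= mask_v
    edges <- seq(min(v), max(v), length.out = n_bins + 1)
    bin <- findInterval(v, edges, rightmost.closed = TRUE)
    # branch-resolved bin index: rising and falling sweeps kept separate
    key <- bin + n_bins * rising
    vapply(split(nec$ratio[keep], key[keep]), mean, numeric(1))
  }
  l1 <- loop(trace_single)
  l2 <- loop(trace_ensemble)
  common <- intersect(names(l1), names(l2))
  if (length(common) == 0) stop("loops share no voltage bins")
  max(abs(l1[common] - l2[common]))
}

#' Heuristic gating polarity from the lumen charge map
#'
#' A documented heuristic hook, not an established result: guesses which
#' voltage polarity is likely to drive gating from the sign of the
#' position-weighted net lumen charge (charges weighted by their distance
#' from the pore midpoint, trans-side charges counted positively). A net
#' negative trans-weighted charge suggests a negative gater. Use it only as
#' a starting point for configuring a [rate_model()].
#'
#' @param problem A [transport_problem()].
#' @return `"negative"`, `"positive"` or `"none"` (no net weighted charge).
#' @export
suggest_polarity <- function(problem) {
  stopifnot(inherits(problem, "transport_problem"))
  if (length(problem$charges) == 0) return("none")
  L <- problem$geometry$length
  w <- vapply(problem$charges, function(ch)
    ch$valence * ch$multiplicity * (ch$axial_position - L / 2) / (L / 2),
    numeric(1))
  s <- sum(w)
  if (abs(s) < 1e-9) "none" else if (s < 0) "negative" else "positive"
}
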