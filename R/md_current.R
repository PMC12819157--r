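#' Framewise ion trajectory
#'
#' Per-frame ion charges and axial coordinates for the displacement-based
#' ionic current estimator. Frames are uniformly spaced by `frame_interval`;
#' ion ids are consistent across frames.
#'
#' @param frames Data frame with columns `frame` (1-based integer), `ion_id`,
#'   `charge_e` (elementary charges) and `z_nm`.
#' @param frame_interval Time between consecutive frames in s (0.2 ns for
#'   the aerolysin simulations).
#' @param pore_length Length of the pore beta-barrel in nm (9 for aerolysin).
#' @param lumen_bounds `c(z_lo, z_hi)` axial extent of the lumen in nm.
#' @return An `ion_trajectory` object.
#' @export
ion_trajectory <- function(frames, frame_interval = 0.2e-9, pore_length = 9,
                           lumen_bounds = c(0, 9)) {
  need <- c("frame", "ion_id", "charge_e", "z_nm")
  if (!all(need %in% names(frames))) stop("frames must have columns ",
                                          paste(need, collapse = ", "))
  if (frame_interval <= 0 || pore_length <= 0)
    stop("frame_interval and pore_length must be positive")
  if (lumen_bounds[2] <= lumen_bounds[1]) stop("invalid lumen_bounds")
  structure(list(frames = frames, frame_interval = frame_interval,
                 pore_length = pore_length, lumen_bounds = lumen_bounds,
                 n_frames = max(frames$frame)),
            class = "ion_trajectory")
}

#' @export
print.ion_trajectory <- function(x, ...) {
  cat(sprintf("<ion_trajectory> %d frames x %d ions, dt = %.3g ns, L_p = %.3g nm\n",
              x$n_frames, length(unique(x$frames$ion_id)),
              x$frame_interval * 1e9, x$pore_length))
  invisible(x)
}

# z matrix (frames x ions) and charge vector, NA where an ion is absent.
.traj_matrix <- function(traj) {
  f <- traj$frames
  ids <- sort(unique(f$ion_id))
  z <- matrix(NA_real_, traj$n_frames, length(ids))
  z[cbind(f$frame, match(f$ion_id, ids))] <- f$z_nm
  q <- f$charge_e[match(ids, f$ion_id)]
  list(z = z, q = q, ids = ids)
}

#' Instantaneous ionic current from frame displacements
#'
#' \eqn{I(t) = \frac{1}{\Delta t L_p} \sum_{ion} Q_{ion}
#' [z_{ion}(t + \Delta t) - z_{ion}(t)]}, summing over ions inside the
#' lumen; ions absent from either frame contribute zero.
#'
#' @param traj An [ion_trajectory()].
#' @param t Frame index (frames `t` and `t + 1` must exist); omit to get the
#'   full series over all frame pairs.
#' @param inclusion Count an ion if inside the lumen at frame `t`
#'   (`"at_start"`, default) or at both frames (`"both"`).
#' @return Current in A (vector if `t` is omitted).
#' @export
instantaneous_current <- function(traj, t = NULL,
                                  inclusion = c("at_start", "both")) {
  inclusion <- match.arg(inclusion)
  m <- .traj_matrix(traj)
  nf <- nrow(m$z)
  if (!is.null(t)) {
    if (any(t < 1 | t >= nf)) stop("frame t+1 does not exist")
    rows <- t
  } else rows <- seq_len(nf - 1)
  lo <- traj$lumen_bounds[1]; hi <- traj$lumen_bounds[2]
  out <- vapply(rows, function(i) {
    z0 <- m$z[i, ]; z1 <- m$z[i + 1, ]
    inside <- z0 >= lo & z0 <= hi
    if (inclusion == "both") inside <- inside & z1 >= lo & z1 <= hi
    use <- inside & !is.na(z0) & !is.na(z1)
    sum(m$q[use] * (z1[use] - z0[use]))
  }, numeric(1))
  out * .const$e / (traj$frame_interval * traj$pore_length)
}

#' Average ionic current of a trajectory
#'
#' The average current is the slope of a linear regression of the cumulative
#' transported charge, \eqn{\sum_{t' \le t} I(t') \Delta t}, against time.
#'
#' @param traj An [ion_trajectory()] with at least 10 frames.
#' @param inclusion See [instantaneous_current()].
#' @return Average current in A.
#' @export
average_current <- function(traj, inclusion = "at_start") {
  if (traj$n_frames < 10) stop("need at least 10 frames")
  I <- instantaneous_current(traj, inclusion = inclusion)
  dt <- traj$frame_interval
  q <- cumsum(I) * dt
  tt <- seq_along(I) * dt
  unname(stats::coef(stats::lm.fit(cbind(1, tt), q))[2])
}

#' Synthetic drift-diffusion ion trajectory
#'
#' Independent 1D biased random walks for each species in the slab
#' `[z_lo - margin, z_hi + margin]` with periodic reinjection (an ion
#' leaving one end re-enters at the other), maintaining a steady state.
#' With the default margin of one pore length, reinjection jumps happen far
#' outside the lumen and never contaminate the counted displacements.
#'
#' @param n_cations,n_anions Ions per species (+1 e and -1 e).
#' @param drift_cation,drift_anion Drift velocities in nm/ns.
#' @param diffusion Diffusion coefficient in nm^2/ns.
#' @param n_frames Number of frames to generate.
#' @param seed RNG seed.
#' @param frame_interval Frame spacing in s.
#' @param pore_length,lumen_bounds See [ion_trajectory()].
#' @param margin Extra slab length beyond each lumen end (nm); defaults to
#'   `pore_length`.
#' @return An [ion_trajectory()].
#' @export
synth_trajectory <- function(n_cations = 20, n_anions = 20,
                             drift_cation = 0, drift_anion = 0,
                             diffusion = 0.2, n_frames = 1000, seed = 1,
                             frame_interval = 0.2e-9, pore_length = 9,
                             lumen_bounds = c(0, 9), margin = NULL) {
  if (n_frames < 2) stop("need at least 2 frames")
  if (is.null(margin)) margin <- pore_length
  set.seed(seed)
  lo <- lumen_bounds[1] - margin; hi <- lumen_bounds[2] + margin
  width <- hi - lo
  n <- n_cations + n_anions
  q <- c(rep(1, n_cations), rep(-1, n_anions))
  v <- c(rep(drift_cation, n_cations), rep(drift_anion, n_anions))
  dt_ns <- frame_interval * 1e9
  z <- matrix(NA_real_, n_frames, n)
  z[1, ] <- stats::runif(n, lo, hi)
  sd_step <- sqrt(2 * diffusion * dt_ns)
  for (i in 2:n_frames) {
    znew <- z[i - 1, ] + v * dt_ns +
      (if (sd_step > 0) stats::rnorm(n, 0, sd_step) else 0)
    z[i, ] <- lo + (znew - lo) %% width
  }
  frames <- data.frame(
    frame = rep(seq_len(n_frames), each = n),
    ion_id = rep(seq_len(n), n_frames),
    charge_e = rep(q, n_frames),
    z_nm = as.vector(t(z)))
  ion_trajectory(frames, frame_interval, pore_length, lumen_bounds)
}

#' Write / read an ion trajectory
#'
#' Tab-separated columns `frame`, `ion_id`, `charge_e`, `z_nm` with `#`
#' header lines, plus a JSON sidecar (`.meta.json`) holding the frame
#' interval, pore length and lumen bounds.
#'
#' @param traj An [ion_trajectory()].
#' @param path TSV file path.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# columns: frame\tion_id\tcharge_e\tz_nm", con)
  f <- traj$frames
  writeLines(paste(f$frame, f$ion_id, .fmt17(f$charge_e), .fmt17(f$z_nm),
                   sep = "\t"), con)
  jsonlite::write_json(
    list(frame_interval_s = traj$frame_interval,
         pore_length_nm = traj$pore_length,
         lumen_bounds_nm = traj$lumen_bounds),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  m <- matrix(as.numeric(unlist(strsplit(lines, "\t", fixed = TRUE))),
              ncol = 4, byrow = TRUE)
  side <- .sidecar_path(path)
  if (!file.exists(side)) stop("trajectory sidecar not found: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  ion_trajectory(data.frame(frame = as.integer(m[, 1]),
                            ion_id = as.integer(m[, 2]),
                            charge_e = m[, 3], z_nm = m[, 4]),
                 frame_interval = meta$frame_interval_s,
                 pore_length = meta$pore_length_nm,
                 lumen_bounds = meta$lumen_bounds_nm)
}
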