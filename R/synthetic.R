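#' Configuration of the synthetic session generator
#'
#' The generator produces sessions in which kinematic information enters the
#' firing rates strictly causally-forward over a known, configurable lag
#' window of `lag_window` bins: the rate at bin `t` encodes the upcoming
#' velocities `v_t .. v_{t+L-1}` (rates lead the kinematics they encode,
#' emulating preparatory activity). Consequently the velocity at bin `t` is
#' carried, with kernel weight, by the rates of bins `t-L+1 .. t` and by
#' nothing older -- a decoder predicting `v_t` from a causal window ending
#' at bin `t` needs exactly the last `L` rate bins, so the "true" essential
#' timestep count is known by construction.
#'
#' @param n_units Number of simulated units C (default 64).
#' @param n_bins Session length in bins (default 3000).
#' @param lag_window L, the number of most-recent timesteps over which
#'   velocity drives the rates (default 4).
#' @param baseline_rate Baseline firing rate, spikes/s (default 10).
#' @param gain Tuning gain, spikes/s per unit speed (default 8).
#' @param noise_model `"gaussian"` (additive, sd `noise_scale`) or
#'   `"poisson"` (counts drawn per bin, `noise_scale` ignored).
#' @param noise_scale Gaussian noise sd in spikes/s (default 2). The
#'   default sets the per-unit SNR near 1, so that the readout from any
#'   single bin's lead group is clearly insufficient while pooling the
#'   whole `L`-bin zone recovers the kinematics well -- the regime in which
#'   the information horizon is expressed in the attention profile. Much
#'   smaller noise makes every bin individually sufficient (redundancy
#'   hides the horizon); much larger noise degrades decoding outright.
#' @param movement_epoch_len Movement epoch length in bins (default 2: a
#'   ~0.13 s micro-movement at 64 ms bins). Each movement epoch has an
#'   independent random direction, so the kinematic autocorrelation dies at
#'   epoch boundaries. The default is deliberately shorter than any lag
#'   horizon one would study: the essential decoding window of a session is
#'   the larger of the injected lag and the kinematic correlation time, so
#'   the latter must stay below the former for the injected horizon to be
#'   the true essential timestep count. 0 produces a rest-only session.
#' @param rest_epoch_len Rest epoch length in bins (default 3).
#' @param lag_kernel `"uniform"` (equal weight per lead) or `"exponential"`
#'   (weight decaying with lead: the rate responds most strongly to the
#'   imminent velocity, so for decoding, the most recent bins carry the
#'   heaviest salience).
#' @param bin_width Bin width in seconds (default 0.064).
#' @param seed Integer seed; identical configurations produce identical
#'   sessions.
#' @return An object of class `synthetic_config`.
#' @seealso [make_session()]
#' @export
synthetic_config <- function(n_units = 64L, n_bins = 3000L, lag_window = 4L,
                             baseline_rate = 10, gain = 8,
                             noise_model = c("gaussian", "poisson"),
                             noise_scale = 2,
                             movement_epoch_len = 2L, rest_epoch_len = 3L,
                             lag_kernel = c("uniform", "exponential"),
                             bin_width = 0.064, seed = 1L) {
  noise_model <- match.arg(noise_model)
  lag_kernel <- match.arg(lag_kernel)
  if (lag_window < 1L) stop("`lag_window` must be >= 1", call. = FALSE)
  if (n_units < 1L || n_bins < 1L) {
    stop("`n_units` and `n_bins` must be positive", call. = FALSE)
  }
  if (baseline_rate <= 0 || gain < 0 || noise_scale < 0) {
    stop("`baseline_rate` must be positive; `gain`, `noise_scale` nonnegative",
         call. = FALSE)
  }
  if (movement_epoch_len < 0L || rest_epoch_len < 1L) {
    stop("`movement_epoch_len` must be >= 0 and `rest_epoch_len` >= 1",
         call. = FALSE)
  }
  structure(
    list(
      n_units = as.integer(n_units), n_bins = as.integer(n_bins),
      lag_window = as.integer(lag_window),
      baseline_rate = baseline_rate, gain = gain,
      noise_model = noise_model, noise_scale = noise_scale,
      movement_epoch_len = as.integer(movement_epoch_len),
      rest_epoch_len = as.integer(rest_epoch_len),
      lag_kernel = lag_kernel, bin_width = bin_width,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

lag_kernel_weights <- function(config) {
  L <- config$lag_window
  w <- switch(config$lag_kernel,
    uniform = rep(1, L),
    exponential = exp(-(seq_len(L) - 1) / 2)
  )
  w / sum(w)
}

#' Simulate a 2-D velocity trace
#'
#' Alternates rest epochs (zero velocity) with movement epochs carrying a
#' smooth bell-shaped (squared-sine) speed profile in a random direction
#' with a random peak speed around 1 a.u./s. The bells rise from and return
#' to zero, so the trace is continuous across epoch boundaries.
#'
#' @param config A [synthetic_config()].
#' @return Numeric matrix `n_bins x 2` of `vx`, `vy`.
#' @export
simulate_velocity <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(split_seed(config$seed, 2L)[1])
  nb <- config$n_bins
  v <- matrix(0, nb, 2L)
  t <- 1L
  moving <- FALSE
  # epoch lengths are jittered by +/- 1 bin around their configured value:
  # a deterministic schedule would make the movement/rest phase globally
  # periodic and hence predictable from any window segment, which degrades
  # the positional meaning of attention during rest
  draw_len <- function(len) max(1L, len + sample(-1L:1L, 1L))
  while (t <= nb) {
    if (moving && config$movement_epoch_len > 0L) {
      nominal <- draw_len(config$movement_epoch_len)
      len <- min(nominal, nb - t + 1L)
      prof <- sin(pi * seq_len(len) / (nominal + 1))^2
      amp <- stats::runif(1, 0.8, 1.2)
      theta <- stats::runif(1, 0, 2 * pi)
      v[t:(t + len - 1L), ] <- amp * prof %o% c(cos(theta), sin(theta))
      t <- t + len
    } else {
      t <- t + min(draw_len(config$rest_epoch_len), nb - t + 1L)
    }
    moving <- !moving
  }
  v
}

#' Simulate population firing rates encoding a velocity trace
#'
#' Each unit `c` has a random preferred direction `p_c` (unit 2-vector) and
#' its own preparatory lead `k_c` in `0 .. L-1` (leads are assigned
#' round-robin so every lead is covered by about `C/L` units). Its
#' noiseless rate at bin `t` is
#' `baseline_rate + gain * L * w_{k_c} * max(0, <p_c, v_{t+k_c}>)`:
#' the unit fires `k_c` bins before the velocity it encodes, like
#' preparatory activity, with the lead kernel `w` setting the relative
#' strength of each lead group (uniform by default). Consequently the
#' velocity at bin `t` is carried -- redundantly, by about `1/L` of the
#' population per bin -- by the rates of bins `t-L+1 .. t` and by nothing
#' older: a causal decoder needs exactly the last `L` bins to see the whole
#' population's evidence about `v_t`, and bins beyond `L` add nothing by
#' construction. (A unit-specific pure lead, rather than one shared
#' multi-lag kernel for all units, is what makes this exact: a shared
#' kernel mixes `L` velocities into every bin, and disentangling them would
#' drag older bins back into the problem.) Gaussian noise is added (or
#' Poisson counts drawn) and rates are clipped at zero.
#'
#' @param kinematics Numeric matrix `n_bins x 2`.
#' @param config A [synthetic_config()].
#' @return Numeric matrix `n_bins x n_units` of nonnegative rates (spikes/s).
#' @export
simulate_rates <- function(kinematics, config) {
  stopifnot(inherits(config, "synthetic_config"))
  kinematics <- as.matrix(kinematics)
  if (ncol(kinematics) != 2L) stop("`kinematics` must have two columns",
                                   call. = FALSE)
  set.seed(split_seed(config$seed, 2L)[2])
  nb <- nrow(kinematics)
  C <- config$n_units
  L <- config$lag_window
  w <- lag_kernel_weights(config)
  theta <- stats::runif(C, 0, 2 * pi)
  P <- cbind(cos(theta), sin(theta))          # C x 2 preferred directions
  leads <- sample(rep_len(0:(L - 1L), C))     # per-unit preparatory lead
  # unit c at bin t sees v at bin t + leads[c] (zero beyond the session)
  vpad <- rbind(kinematics, matrix(0, L, 2L))
  act <- matrix(0, nb, C)
  for (c_i in seq_len(C)) {
    k <- leads[c_i]
    act[, c_i] <- vpad[(1L + k):(nb + k), , drop = FALSE] %*% P[c_i, ]
  }
  gain_c <- config$gain * L * w[leads + 1L]   # lead-group strength profile
  clean <- config$baseline_rate +
    pmax(act, 0) * rep(gain_c, each = nb)
  rates <- switch(config$noise_model,
    gaussian = pmax(clean + stats::rnorm(nb * C, sd = config$noise_scale), 0),
    poisson = {
      counts <- stats::rpois(nb * C, lambda = clean * config$bin_width)
      matrix(counts, nb, C) / config$bin_width
    }
  )
  matrix(rates, nb, C)
}

#' Generate a synthetic binned session
#'
#' Composes [simulate_velocity()] and [simulate_rates()] and stores the full
#' generator configuration (including `lag_window` and `seed`) in the session
#' metadata, so the ground-truth information horizon survives a write/read
#' round trip.
#'
#' @param config A [synthetic_config()].
#' @return A [binned_session()].
#' @export
make_session <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  kin <- simulate_velocity(config)
  rates <- simulate_rates(kin, config)
  binned_session(
    rates = rates,
    kinematics = kin,
    bin_width = config$bin_width,
    session_id = sprintf("synthetic-L%d-seed%d", config$lag_window, config$seed),
    metadata = list(
      generator = "ttsdecode::make_session",
      lag_window = config$lag_window,
      seed = config$seed,
      n_units = config$n_units,
      baseline_rate = config$baseline_rate,
      gain = config$gain,
      noise_model = config$noise_model,
      noise_scale = config$noise_scale,
      movement_epoch_len = config$movement_epoch_len,
      rest_epoch_len = config$rest_epoch_len,
      lag_kernel = config$lag_kernel
    )
  )
}
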