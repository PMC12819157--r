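#' Read a scenario configuration
#'
#' A scenario bundles everything needed to generate a synthetic recording:
#' a pore (config file or tabulated IV), a gating rate model, a gated-state
#' conductance distribution, a pore count, a voltage protocol, a noise
#' level and a seed. Shipped presets (`"dc_gater"`, `"wt_fig2c"`,
#' `"neutral_fig2a"`) live under `inst/extdata/scenarios/`.
#'
#' @param name_or_path Preset name or path to a scenario JSON file.
#' @return A `scenario_config` list.
#' @export
read_scenario_config <- function(name_or_path) {
  path <- if (file.exists(name_or_path)) name_or_path
          else system.file("extdata", "scenarios",
                           paste0(name_or_path, ".json"),
                           package = "poreflux", mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path))
    stop("unknown scenario: ", name_or_path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(path)
  pore_path <- cfg$pore
  if (!file.exists(pore_path)) pore_path <- file.path(base, cfg$pore)
  if (!file.exists(pore_path)) stop("pore config not found: ", cfg$pore)
  rm_args <- cfg$rate_model
  rm_args$critical_voltage <- unlist(rm_args$critical_voltage)
  structure(list(
    problem = read_pore_config(pore_path),
    model = do.call(rate_model, rm_args),
    dist = closed_state_distribution(cfg$closed_state$mean_ratio,
                                     cfg$closed_state$sd_ratio),
    n_pores = cfg$n_pores,
    protocol = do.call(make_protocol, as.list(cfg$protocol)),
    noise_sd = cfg$noise_sd,
    seed = cfg$seed,
    name = cfg$name), class = "scenario_config")
}

#' Generate a synthetic recording with ground truth
#'
#' Composes the transport model (open-pore IV of the configured pore), the
#' stochastic gating simulation and additive noise into a synthetic current
#' trace, together with a ground-truth record sufficient to evaluate every
#' analysis output without re-running the simulator: the true closed
#' probability p(t), the true pore count, all gated-conductance draws and
#' the open-pore rectification factor.
#'
#' @param config A `scenario_config` (or preset name).
#' @param seed Optional seed override.
#' @param sample_rate Optional protocol sample-rate override (Hz).
#' @param out Optional output basename; if given, the trace (TSV + metadata
#'   sidecar) is written to `<out>.tsv`.
#' @return List with `trace` (a [current_trace()]), `open_iv` and `truth`
#'   (list: `p_true`, `epsilon_draws`, `n_pores`, `beta_open`, `seed`).
#' @export
generate_scenario <- function(config, seed = NULL, sample_rate = NULL,
                              out = NULL) {
  if (is.character(config)) config <- read_scenario_config(config)
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(seed)) seed <- config$seed
  vmax <- max(abs(config$protocol$amplitude) + abs(config$protocol$baseline),
              abs(config$protocol$baseline), 0.11)
  open_iv <- iv_curve(config$problem,
                      seq(-1.05 * vmax, 1.05 * vmax, length.out = 85))
  tr <- simulate_ensemble(config$n_pores, config$model, config$dist, open_iv,
                          config$protocol, noise_sd = config$noise_sd,
                          seed = seed, sample_rate = sample_rate)
  truth <- list(p_true = tr$metadata$truth$p_true,
                epsilon_draws = tr$metadata$truth$epsilon_draws,
                n_pores = config$n_pores,
                beta_open = rectification_factor(open_iv),
                seed = seed)
  tr$metadata$scenario <- config$name
  if (!is.null(out)) write_trace(tr, paste0(out, ".tsv"))
  list(trace = tr, open_iv = open_iv, truth = truth)
}

#' Generate a batch of single-pore d.c. gating traces
#'
#' Convenience generator for the constant-voltage gating phenomenology: many
#' independent single-pore traces at a fixed holding voltage, each with
#' stochastic closing and a freshly drawn gated-conductance ratio.
#'
#' @param n_traces Number of traces.
#' @param config A `scenario_config` with a constant protocol (default the
#'   `"dc_gater"` preset).
#' @param seed Base seed; trace i uses `seed + i - 1`.
#' @param sample_rate Optional sample-rate override (Hz).
#' @return List of [current_trace()]s.
#' @export
generate_dc_traces <- function(n_traces = 200, config = "dc_gater", seed = 1,
                               sample_rate = NULL) {
  if (is.character(config)) config <- read_scenario_config(config)
  lapply(seq_len(n_traces), function(i)
    generate_scenario(config, seed = seed + i - 1,
                      sample_rate = sample_rate)$trace)
}
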