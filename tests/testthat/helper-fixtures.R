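# shared small fixtures
wt_problem <- function() read_pore_config(
  system.file("extdata", "pores", "wt_like.json", package = "poreflux"))

wt_open_iv <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- iv_curve(wt_problem(),
                                           seq(-0.21, 0.21, length.out = 85))
    cache
  }
})

sharp_model <- function() rate_model("negative", critical_voltage = 0.1,
                                     closing_prefactor = 1,
                                     closing_efold_voltage = 0.002,
                                     opening_rate = 50,
                                     reopening_window = 0.15)
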