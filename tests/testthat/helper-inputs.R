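# Shared fixture-mode input set: published consumption table, synthetic
# epi schedule, full-scale (25.7M) population. Built once per test run.
fixture_inputs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_inputs(synth_spec())
    cache
  }
})

fit_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      inp <- fixture_inputs()
      cache <<- ssb_cea(inp$params, inp$schedule, inp$profiles,
                        inp$population, horizon = 10, n_draws = 100,
                        seed = 42)
    }
    cache
  }
})
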