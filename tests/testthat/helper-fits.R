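# Full-scale simulate + fit replicates (default landscape, desk schedule),
# cached so the recovery and diagnostic tests share the same fits.
acceptance_fit <- local({
  cache <- list()
  function(i) {
    key <- as.character(i)
    if (is.null(cache[[key]])) {
      ds <- generate_dataset(landscape_config(seed = 100 + i))
      d <- prepare_model_data(ds$sites, ds$soil, ds$trees, ds$leaves)
      fit <- run_mcmc(d, desk_schedule(seed = 500 + 10 * i))
      cache[[key]] <<- list(ds = ds, d = d, fit = fit)
    }
    cache[[key]]
  }
})
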