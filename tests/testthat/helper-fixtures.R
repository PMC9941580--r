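# Shared synthetic fixtures, generated once per test run.

shared_genome <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_genome(n_chromosomes = 3, n_genes = 18,
                                tandem_spec = list(c(3, 5000, 0.97),
                                                   c(2, 8000, 0.98)),
                                te_density = 20, seed = 42)
    cache
  }
})

shared_profiles <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_profile_set()
    cache
  }
})
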