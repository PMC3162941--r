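# Shared fixtures, built in code once per run.

test_engine <- local({
  eng <- NULL
  function() {
    if (is.null(eng)) eng <<- default_engine()
    eng
  }
})

# One labelled dataset shared by the generator, classifier and acceptance
# tests (5000 samples, uniform five-class mix, fixed seed).
shared_dataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds))
      ds <<- generate_labelled_dataset(5000, seed = 42,
                                       engine = test_engine())
    ds
  }
})

# The printed output bands of the five situations on the [0,10] scale.
situation_bands <- list(
  instability = c(0, 2.5),
  low_MBP     = c(2.5, 4.5),
  hypoxemia   = c(4, 6),
  stable      = c(5.5, 8),
  high_MBP    = c(8, 10))
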