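# Standard fixtures are deterministic in the seed, so build each once
# per session and share across test files.
std_fixture <- local({
  cache <- list()
  function(seed = 42) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- generate_fixture(seed = seed)
    }
    cache[[key]]
  }
})
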