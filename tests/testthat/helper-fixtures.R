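# Shared fixtures, generated in code (cached per test run).

fixtureNormals <- local({
  cache <- NULL
  function(n = 12, size = 64) {
    key <- paste(n, size)
    if (is.null(cache[[key]])) {
      imgs <- lapply(seq_len(n), function(i)
        generateMucosa(mucosaSpec(size = size, seed = i,
                                  specularCount = 2)))
      names(imgs) <- sprintf("n%03d", seq_len(n))
      cache[[key]] <<- imgs
    }
    cache[[key]]
  }
})

fixtureTextures <- local({
  cache <- NULL
  function(n = 3, size = 64) {
    key <- paste(n, size)
    if (is.null(cache[[key]]))
      cache[[key]] <<- lapply(seq_len(n), function(i)
        generateTexture(textureSpec(size = size, seed = i)))
    cache[[key]]
  }
})

fixtureTemplates <- local({
  cache <- NULL
  function(n = 6, seed = 3) {
    key <- paste(n, seed)
    if (is.null(cache[[key]]))
      cache[[key]] <<- buildTemplateSet(count = n, seed = seed)
    cache[[key]]
  }
})

# tiny model + bank shared by the network tests
fixtureSmokeModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- buildModel(smokeModelConfig(64L))
      bank <- buildMemory(m, fixtureNormals(8), N = 5, seed = 1)
      cache <<- list(model = m, bank = bank)
    }
    cache
  }
})

withSeed <- polypseg:::withSeed
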