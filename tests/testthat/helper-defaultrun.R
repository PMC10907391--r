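# The default-profile end-to-end run is the most expensive fixture in the
# suite; compute it once on first use and share it across test files.
.defaultRunCache <- new.env(parent = emptyenv())

defaultRunResult <- function() {
  if (is.null(.defaultRunCache$res)) {
    t0 <- Sys.time()
    .defaultRunCache$res <- runPipeline(defaultRunConfig(seed = 1L))
    .defaultRunCache$seconds <- as.numeric(Sys.time() - t0, units = "secs")
  }
  .defaultRunCache$res
}

defaultRunSeconds <- function() {
  defaultRunResult()
  .defaultRunCache$seconds
}
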