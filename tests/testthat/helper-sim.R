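# One shared demonstration configuration, built lazily and reused across
# tests; variants adjust plain fields without rebuilding the fixtures.
base_demo_cfg <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- demo_config(seed = 1)
    cache
  }
})

variant_cfg <- function(base = base_demo_cfg(), ...) {
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}
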