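# Lazily built, memoized fixtures shared across test files.
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

full_network <- function() memo("net", function() {
  build_proximal_network(pulmonary_vessel_table())
})

# one coarse full-network solution with distal caches, reused widely
coarse_solution <- function() memo("coarse_sol", function() {
  num <- coarse_numerics()
  num$keep_cache <- TRUE
  simulate_network(full_network(), default_theta(), default_waveforms(), num)
})

small_bed <- function() memo("small_bed", function() {
  at <- generate_tree(0.1, alpha = 0.85, beta = 0.68, lrr = 20, r_min = 0.028)
  vt <- mirror_tree(at, 0.09, 25)
  list(at = at, vt = vt)
})
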