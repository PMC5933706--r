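# Shared heavy fixture: ABC reference tables under the European branch,
# built once per test run and reused across test files. Sizes are chosen to
# keep the default suite within a desk-scale run (the methods vignette
# documents the scaling).
abc_cache <- new.env(parent = emptyenv())

get_abc_reference <- function() {
  if (!is.null(abc_cache$ref)) return(abc_cache$ref)
  dem <- gravel_demography("EUR")
  set.seed(260920)
  ref <- rbind(
    build_reference_table("SDN", 2000, dem, max_draws = 60000),
    build_reference_table("SSV", 2000, dem, max_draws = 60000),
    build_reference_table("NTR", 2000, dem, max_draws = 120000),
    build_reference_table("SSV_halted", 1000, dem, max_draws = 60000))
  abc_cache$ref <- ref
  ref
}
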