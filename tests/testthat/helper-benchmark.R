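# The default synthetic benchmark and its seed-1 pipeline run are expensive
# (embedding training), so they are built once per test session and shared.
.bench_cache <- new.env(parent = emptyenv())

bench_fixture_dir <- function() {
  if (is.null(.bench_cache$dir)) {
    dir <- file.path(tempdir(), "radcoder-bench")
    simulate_benchmark(synth_config(), dir)
    .bench_cache$dir <- dir
    .bench_cache$sim <- simulate_benchmark(synth_config())
  }
  .bench_cache$dir
}

bench_sim <- function() {
  bench_fixture_dir()
  .bench_cache$sim
}

# seed-1 pipeline over the default fixtures, with output files written
bench_run <- function() {
  if (is.null(.bench_cache$run)) {
    out <- file.path(tempdir(), "radcoder-bench-out1")
    .bench_cache$run <- run_pipeline(bench_fixture_dir(), out, seed = 1)
    .bench_cache$out <- out
  }
  .bench_cache$run
}

bench_out_dir <- function() {
  bench_run()
  .bench_cache$out
}

tiny_taxonomy <- function() {
  build_taxonomy(tibble::tibble(
    id     = c("r", "A", "B", "x", "y", "z"),
    parent = c(NA, "r", "r", "A", "A", "B"),
    label  = c("root", "alpha", "beta", "xray", "yank", "zulu")
  ))
}

tiny_lexicon <- function() {
  tibble::tibble(
    code = c("RID1", "RID2", "RID3"),
    preferred_name = c("lung", "nodule", "lobe of lung"),
    synonyms = list(character(0), c("tubercle"), c("pulmonary lobe"))
  )
}
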