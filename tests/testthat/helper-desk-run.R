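# Desk-preset experiment shared by the acceptance tests; computed once per
# test run, on first use.
.desk_cache <- new.env(parent = emptyenv())

desk_records <- function() {
  if (is.null(.desk_cache$records)) {
    cfg <- experiment_config(base_seed = 1L)
    .desk_cache$records <- suppressWarnings(run_experiment(cfg))
    .desk_cache$summary <- summarize_experiment(.desk_cache$records)
  }
  .desk_cache$records
}

desk_summary <- function() {
  desk_records()
  .desk_cache$summary
}
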