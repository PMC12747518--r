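# One shared demo-pipeline run per test session (it is the expensive
# fixture for both the smoke test and the determinism check).
fix_pipeline_run <- function() fixture("pipeline_a", {
  cfgfile <- system.file("extdata", "demo_small.yaml",
                         package = "gyralkit")
  cfg <- yaml::read_yaml(cfgfile)
  out <- file.path(tempdir(), "pipe_a")
  cfg$output_dir <- out
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, tmp)
  run_pipeline(tmp)
})

manifest_hashes <- function(m) {
  h <- unlist(lapply(m$outputs, function(st)
    vapply(st, function(f) f$md5, "")))
  h[order(names(h))]
}
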