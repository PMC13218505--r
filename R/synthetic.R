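#' Fixture generation
#'
#' Writes everything needed to exercise the full pipeline with no external
#' data: the packaged base-case parameter configuration, a synthetic
#' Gompertz-Makeham life table in the reader's CSV dialect, and a tiny
#' 3-cycle smoke configuration. Output is deterministic, so repeated calls
#' produce byte-identical files.
#'
#' @param out_dir Writable output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
make_fixture_bundle <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    params     = file.path(out_dir, "params_default.yaml"),
    life_table = file.path(out_dir, "life_table_synthetic.csv"),
    smoke      = file.path(out_dir, "params_smoke.yaml")
  )
  save_parameters(default_parameters(), paths[["params"]])
  write_life_table(generate_life_table(), paths[["life_table"]])
  smoke <- default_parameters()
  smoke$settings$horizon_years <- 3L
  smoke$settings$psa_draws <- 20L
  save_parameters(smoke, paths[["smoke"]])
  invisible(paths)
}
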