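# shared fixture builders

sim_trace <- function(seed, ...) generate_trace(fixture_spec(seed = seed, ...))

run_pipeline <- function(trace, config = NULL) {
  characterize_trace(trace, config = config)
}

# hand-constructed deviation set with explicit (period, fwhm) features
make_deviation_set <- function(time, fwhm, period, type = "peak",
                               height = 1) {
  ev <- tibble::tibble(time = time, height = height, fwhm = fwhm,
                       type = type, period = period, coherent = NA)
  ev <- dplyr::arrange(ev, time)
  class(ev) <- c("deviation_set", class(ev))
  ev
}

# write a small wide-format recordings CSV and return its path
write_recording_csv <- function(df, header = TRUE) {
  path <- tempfile(fileext = ".csv")
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = header, qmethod = "double")
  path
}
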