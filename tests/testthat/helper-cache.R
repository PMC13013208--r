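# expensive case-study trajectories shared across test blocks
.traj_cache <- new.env(parent = emptyenv())

cached_case <- function(name, ...) {
  key <- paste(name, ..., sep = "_")
  if (is.null(.traj_cache[[key]]))
    .traj_cache[[key]] <- run_case_study(name, ...)
  .traj_cache[[key]]
}
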