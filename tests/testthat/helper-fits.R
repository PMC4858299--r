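# Full fitted objects for the eight-scenario roster (solutions retained for
# equilibrium checks); computed once.
cached_fits <- function() {
  cached("fits", lapply(default_scenarios(), run_scenario))
}
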