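# Shared fixtures for the test suite.
default_sched <- build_schedule(default_framing())
default_aif <- default_phantom_aif()

# Maximum deviation relative to the reference curve's peak magnitude.
rel_err <- function(x, ref) max(abs(x - ref)) / max(abs(ref))
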