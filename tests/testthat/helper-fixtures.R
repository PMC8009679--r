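# Shared fixtures: the default model, the standard pH 6.0 pulse protocol,
# and lazily-built expensive objects reused across test files.

default_model <- channel_model()
std_protocol <- pulse_protocol()          # 2 s + 10 s pH 6 + 40 s recovery
short_protocol <- pulse_protocol(post_s = 5)

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

std_calibrations <- function() {
  cached("cal", vcf_calibrations(default_model, std_protocol))
}

std_trajectory <- function() {
  cached("traj", integrate_gates(default_model, std_protocol))
}

# noise-free recording for a ground-truth factor set under std_protocol
clean_recording <- function(factors, seed = 1L) {
  generate_recording(default_model, factors, std_protocol,
                     noise_spec(0, 0, 0, seed = seed))
}
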