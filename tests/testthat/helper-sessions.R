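# Desk-scale synthetic session: the generative model at the 1 Hz analysis
# rate with a single EEG channel, which is all most statistics need.
desk_cfg <- function(..., duration = 7200, fs = 1, n_eeg = 1,
                     channel_phase_sd = 0) {
  synthetic_config(duration = duration, fs = fs, n_eeg = n_eeg,
                   channel_phase_sd = channel_phase_sd, ...)
}

# generate + preprocess in one go
desk_session <- function(cfg) {
  s <- gen_session(cfg)
  list(pp = preprocess_recording(s$recording), truth = s$truth,
       rec = s$recording)
}

gsr_row <- function(pp) channels_of(pp, "GSR")[1]
resp_row <- function(pp) channels_of(pp, "RESP")[1]
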