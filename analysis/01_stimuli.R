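#!/usr/bin/env Rscript
# Stage 1: synthesize the figure-ground stimuli.
#
# Places the 20-tone ERB-spaced bank, lays out a session (N = 6/12/18
# interleaved, ISI 1.2-1.3 s), and renders one example trial per condition
# to WAV. Writes the session log and the tone-bank table to results/.

library(tonecoh)

out <- "results/stimuli"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1

bank <- place_tones(20, 200, 8000, per_tone_level = 60)
cat(sprintf("Tone bank: %d tones, %.0f-%.0f Hz, spacing %.3f ERB, overall %.2f dB SPL\n",
            length(bank$frequencies), min(bank$frequencies),
            max(bank$frequencies), bank$spacing_erb, bank$overall_level))
write.table(data.frame(tone = seq_along(bank$frequencies),
                       frequency_hz = bank$frequencies,
                       erb_number = erb_number(bank$frequencies)),
            file.path(out, "tone_bank.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

env <- envelope_params()  # 4-24 Hz band, 48 kHz
log <- make_session(bank, env, trials_per_condition = 240, seed = seed)
write_event_log(log, file.path(out, "session_events.tsv"))
cat(sprintf("Session: %d trials (%s per condition), ISI %.2f-%.2f s\n",
            nrow(log), paste(table(log$condition_N), collapse = "/"),
            min(log$isi_s), max(log$isi_s)))

for (N in c(6, 12, 18)) {
  i <- which(log$condition_N == N)[1]
  tr <- render_session_trial(log, i, bank, env)
  write_wav(tr$waveform, file.path(out, sprintf("example_N%02d.wav", N)),
            tr$sample_rate)
}
cat("Example trials written to", out, "\n")
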