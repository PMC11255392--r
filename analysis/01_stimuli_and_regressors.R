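#!/usr/bin/env Rscript

# Build the two luminance protocols, sample them on the imaging clock, and
# construct the kernel-convolved regressor bank used by all later steps.
# Outputs: results/protocol_{steps,flashes}.json, results/regressor_bank.csv

suppressPackageStartupMessages(library(lumicell))
dir.create("results", showWarnings = FALSE)

steps <- build_steps_protocol(n_repetitions = 6)
flashes <- build_flashes_protocol(n_repetitions = 6)
write_protocol_json(steps, "results/protocol_steps.json")
write_protocol_json(flashes, "results/protocol_flashes.json")

cat(sprintf("steps: %d epochs/repetition, %.0f s total; transitions cover %d ordered level pairs\n",
            nrow(steps$epochs), protocol_duration(steps),
            nrow(unique(protocol_transitions(steps)))))
cat(sprintf("flashes: %s s at full brightness\n",
            paste(flashes$epochs$duration[flashes$epochs$level == 1],
                  collapse = "/")))

stim <- sample_protocol(steps, 0.24888)
bank <- build_regressor_bank(stim)
df <- as.data.frame(bank$matrix)
names(df) <- bank$names
write.csv(rbind(group = bank$group, round(df, 6)),
          "results/regressor_bank.csv", row.names = FALSE)
cat(sprintf("regressor bank: %d frames x %d regressors (%d luminance, %d transition)\n",
            nrow(bank$matrix), ncol(bank$matrix),
            sum(bank$group == "luminance"), sum(bank$group == "transition")))
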