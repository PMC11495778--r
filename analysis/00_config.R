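# Shared configuration for the analysis scripts: the demo study written
# under results/pipeline. Each numbered script runs one pipeline stage and
# reports what it found; stages read their inputs from the previous stage's
# files, so the scripts must be run in order (01 .. 05).

suppressMessages(library(tempmort))

analysis_config <- function() {
  default_config(out_dir = "results/pipeline")
}
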