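DNA_BASES <- c("A", "C", "G", "T")

# Validation failures get their own condition class so the CLI can map them
# to exit code 2 while genuine runtime errors map to 3.
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("dna6ma_validation_error", "error")))
}
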