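#!/usr/bin/env Rscript
# Thin shell wrapper over slassosum::run_cli(); see ?run_cli for flags.
suppressPackageStartupMessages(library(slassosum))
status <- tryCatch({
  run_cli(commandArgs(trailingOnly = TRUE))
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  1L
})
quit(save = "no", status = status)
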