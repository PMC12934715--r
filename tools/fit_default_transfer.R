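# Fits the package's default transfer-function coefficients against the
# AdEx spiking oracle and writes inst/extdata/transfer_coefficients_default.tsv.
# Run from the package root:  Rscript tools/fit_default_transfer.R
library(mfbrain)

grid <- measure_transfer_grid(
  nu_E = c(0, 0.5, 1, 2, 4, 8, 16, 30),
  nu_I = c(0, 1, 2, 4, 8, 16, 32, 60),
  w = c(0, 100),
  n_per_type = 100, duration = 10, discard = 1, dt = 0.1, seed = 20260101)

tfE <- fit_transfer(transfer_samples(grid, "E"), "E")
tfI <- fit_transfer(transfer_samples(grid, "I"), "I")
print(tfE)
print(tfI)

write_transfer_table(list(tfE, tfI),
                     "inst/extdata/transfer_coefficients_default.tsv")
cat("written inst/extdata/transfer_coefficients_default.tsv\n")
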