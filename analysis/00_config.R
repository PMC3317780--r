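# Shared configuration for the analysis scripts.  All computation lives in
# the tractrepro package; these scripts are thin staged drivers.
#
# Desk-scale study: 4 phantom subjects x 2 sessions, three tract geometries
# (straight deep-white-matter analogue, 90-degree crossing, subcortical-style
# fanning), 64 electrostatically spread directions at b = 1200 s/mm^2,
# b0 SNR 20.  Tables land in results/, imaging volumes in scratch/.

library(tractrepro)

MASTER_SEED <- 20120402L

CFG <- run_config(
  n_subjects = 4,
  tracts = c("straight", "crossing", "fanning"),
  n_streamlines = 400,
  n_tdi_streamlines = 8000
)

RESULTS_DIR <- "results"
SCRATCH_DIR <- "scratch/analysis"
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create(SCRATCH_DIR, showWarnings = FALSE, recursive = TRUE)

state_path <- function(name) file.path(SCRATCH_DIR, paste0(name, ".rds"))
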