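# Shared fixtures and frozen oracle values.

# Mean structure at W = 2 computed with an independent rejection sampler
# (numpy, 4e6 accepted-domain draws, MC standard error ~2e-4), frozen here.
ORACLE_W2 <- list(
  before = c(free = 0.185654, di = 0.387513, tri = 0.426833),
  after  = c(free = 0.092827, di = 0.355886, tri = 0.551287)
)

all_residues <- function() residue_table()$residues

# every dipeptide / tripeptide sequence over the standard alphabet
all_peptides <- function(len) {
  g <- do.call(expand.grid, rep(list(all_residues()), len))
  apply(g, 1, paste0, collapse = "")
}

# one subject x MMTT series in the assay-record schema
make_series <- function(times = c(-60, -1, 5, 15, 30, 45, 60, 120),
                        F, T, subject = "S01", group = "Control",
                        health = "Healthy", mmtt = "HFD") {
  data.frame(subject_id = subject, group = group, health_state = health,
             mmtt = mmtt, time_min = times, F = F, T = T,
             stringsAsFactors = FALSE)
}

fast_config <- function(resolution = 150L) estimator_config(resolution = resolution)
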