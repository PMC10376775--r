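# Shared fixtures, generated in code. The reduced montages keep runtimes
# proportionate while covering every cluster (two channels each) or the
# electrodes a test needs.

montage18 <- c("Fp1", "AF3", "F3", "F4", "FC1", "FC2", "C3", "C4",
               "CP1", "CP2", "P3", "P4", "PO3", "PO4", "T7", "T8",
               "Fz", "Cz")

montage_erp <- c("C5", "F6", "F7", "FCz", "Cz", "CPz", "Pz", "T7", "T8", "POz")

montage_T <- c("FT7", "FT8", "T7", "T8")

# a tiny quiet config: no entropy mixing (skips calibration), small montage
quiet_config <- function(channels = montage_T, ...) {
  effect_config(channels = channels, entropy_offsets = c(FC = 0), ...)
}

# cache heavyweight shared datasets across test files within one run
.fixture_env <- new.env()
fixture_once <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}
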