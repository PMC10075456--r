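# Frozen parameter sets used across the tests.

# Typical operating point: single stable fixed point.
params_stable <- function() liley_typical()

# With stronger balanced input the deterministic model settles on a limit
# cycle (verified by classify_attractor and the eigenvalue spectrum).
params_oscillatory <- function() liley_params(p_ee = 3, p_ei = 3)

# Extreme gain/connectivity: the trajectory blows up past the divergence
# guard.
params_divergent <- function()
  liley_params(Gamma_e = 2, N_ee = 5000, gamma_e = 0.1, tau_e = 5, p_ee = 10)

# A set whose reduced steady-state system has three distinct roots (found by
# randomly scanning the bounds; frozen here).
params_multiroot <- function() {
  liley_params(.values = c(
    he_rest = -67.394, hi_rest = -65.923, N_ee = 3773.601, N_ei = 4989.549,
    N_ie = 140.802, N_ii = 991.065, Gamma_e = 1.516, Gamma_i = 0.93,
    gamma_e = 0.238, gamma_i = 0.23, tau_e = 32.017, tau_i = 66.85,
    Se_max = 0.419, Si_max = 0.073, mu_e = -50.119, mu_i = -42.364,
    sigma_e = 2.201, sigma_i = 5.959, he_eq = -10.384, hi_eq = -73.477,
    p_ee = 0.087, p_ei = 4.658, xi = 7.166))
}

# Uniform random parameter set within the bounds.
random_params <- function() {
  b <- liley_bounds()
  liley_params(.values = b$lower + stats::runif(23) * (b$upper - b$lower))
}

# Wrap a bare series as a trajectory object for objective-function tests.
make_traj <- function(samples, rate = 256, divergent = FALSE) {
  structure(list(samples = as.numeric(samples), rate = rate,
                 divergent = divergent, params = NULL, config = NULL),
            class = "liley_trajectory")
}

# Minimal EDF writer (int16 records, one fixed calibration for all signals),
# for constructing read-back fixtures at test time.
write_test_edf <- function(path, channels, labels, rate, rec_dur = 1,
                           phys_range = c(-200, 200)) {
  channels <- as.matrix(channels)
  ns <- ncol(channels)
  spr <- as.integer(rate * rec_dur)
  n_rec <- nrow(channels) / spr
  stopifnot(n_rec == round(n_rec))
  pad <- function(s, n) {
    s <- as.character(s)
    stopifnot(all(nchar(s) <= n))
    formatC(s, width = n, flag = "-")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("test patient", 80), pad("test recording", 80),
                pad("01.01.20", 8), pad("00.00.00", 8),
                pad(256 + ns * 256, 8), pad("", 44), pad(n_rec, 8),
                pad(format(rec_dur), 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  writeChar(paste0(pad(labels, 16), collapse = ""), con, eos = NULL)
  writeChar(paste0(pad(rep("", ns), 80), collapse = ""), con, eos = NULL)
  writeChar(paste0(pad(rep("uV", ns), 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(pad(rep(phys_range[1], ns), 8), collapse = ""), con,
            eos = NULL)
  writeChar(paste0(pad(rep(phys_range[2], ns), 8), collapse = ""), con,
            eos = NULL)
  writeChar(paste0(pad(rep(-32768, ns), 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(pad(rep(32767, ns), 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(pad(rep("HP:none", ns), 80), collapse = ""), con,
            eos = NULL)
  writeChar(paste0(pad(rep(spr, ns), 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(pad(rep("", ns), 32), collapse = ""), con, eos = NULL)
  scale <- (32767 - (-32768)) / (phys_range[2] - phys_range[1])
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(ns)) {
      dig <- as.integer(round((channels[rows, i] - phys_range[1]) * scale +
                                (-32768)))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

# Standard 10-20 scalp labels (19 channels).
labels_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz", "C4",
    "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}
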