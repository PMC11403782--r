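# Independent oracles used across test files.

# Brute-force closed-form recomputation of the long-TE sequence signal,
# written directly from the formula (no package code).
oracle_cdsc <- function(T1, T2, TR = 10000, TE = 1347, ES = 3.2, ETL = 1024) {
  (1 - exp(-(TR - ES * ETL) / T1)) * exp(-TE / T2)
}

oracle_flair <- function(T1, T2, TR = 6000, TI = 2000, TE = 180) {
  (1 - 2 * exp(-TI / T1) + exp(-TR / T1)) * exp(-TE / T2)
}

oracle_t1gd <- function(T1_0, r1, c) 1 / (1 / T1_0 + r1 * c / 1000)
oracle_t2gd <- function(T2_0, r2, c) 1 / (1 / T2_0 + r2 * c / 1000)

# Brute-force L1-ball transition shell for a convex ventricle: enumerate
# every voxel and keep those whose minimum L1 distance to a CP voxel is
# in (0, layers], intersected with the ventricle.
oracle_transition_l1 <- function(cp, vent, layers) {
  idx_cp <- which(cp, arr.ind = TRUE)
  out <- array(FALSE, dim(cp))
  all_idx <- which(vent & !cp, arr.ind = TRUE)
  for (i in seq_len(nrow(all_idx))) {
    d <- min(rowSums(abs(sweep(idx_cp, 2, all_idx[i, ]))))
    if (d <= layers) out[all_idx[i, 1], all_idx[i, 2], all_idx[i, 3]] <- TRUE
  }
  out
}

# Build a dynamic_series whose ROI-mean time course is exactly `values`
# (every voxel identical), on a 2x2x2 grid.
series_from_values <- function(values, frame_interval, injection_time,
                               session_label = "post") {
  dat <- array(rep(values, each = 8), c(2, 2, 2, length(values)))
  dynamic_series(dat, frame_interval, injection_time, session_label)
}

full_mask <- function() array(TRUE, c(2, 2, 2))
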