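#' Gadolinium-shortened T1
#'
#' Applies the linear relaxivity model `1/T1_Gd = 1/T1_0 + r1 * c`. Times
#' are in ms while relaxivities are the conventional L mmol^-1 s^-1, so the
#' rate sum is formed in s^-1 (`1000/T1_0`) before converting back to ms.
#' The result never exceeds `T1_0` and is strictly decreasing and convex in
#' `c`.
#'
#' @param T1_0 Baseline T1 in ms (> 0).
#' @param r1 Longitudinal relaxivity in L mmol^-1 s^-1 (>= 0).
#' @param c Gadolinium concentration in mmol/L (>= 0); vectorized.
#' @return Post-contrast T1 in ms.
#' @export
#' @examples
#' t1_with_gd(4310, 2.8, 0.2) # CSF at 0.2 mmol/L -> ~1262.6 ms
t1_with_gd <- function(T1_0, r1, c) {
  if (!all(T1_0 > 0)) stop("T1_0 must be positive", call. = FALSE)
  if (!all(r1 >= 0)) stop("r1 must be non-negative", call. = FALSE)
  if (!all(c >= 0)) stop("concentration must be non-negative", call. = FALSE)
  1000 / (1000 / T1_0 + r1 * c)
}

#' Gadolinium-shortened T2
#'
#' Same relaxivity model as [t1_with_gd()] applied to the transverse
#' relaxation time: `1/T2_Gd = 1/T2_0 + r2 * c` with the ms/s unit bridge.
#'
#' @param T2_0 Baseline T2 in ms (> 0).
#' @param r2 Transverse relaxivity in L mmol^-1 s^-1 (>= 0).
#' @param c Gadolinium concentration in mmol/L (>= 0); vectorized.
#' @return Post-contrast T2 in ms.
#' @export
#' @examples
#' t2_with_gd(1400, 3.4, 0.2) # CSF at 0.2 mmol/L -> ~717.2 ms
t2_with_gd <- function(T2_0, r2, c) {
  if (!all(T2_0 > 0)) stop("T2_0 must be positive", call. = FALSE)
  if (!all(r2 >= 0)) stop("r2 must be non-negative", call. = FALSE)
  if (!all(c >= 0)) stop("concentration must be non-negative", call. = FALSE)
  1000 / (1000 / T2_0 + r2 * c)
}

#' Steady-state signal of the long-TE CSF-selective sequence
#'
#' Saturation-recovery model for a single-shot long echo-train spin-echo
#' acquisition: the longitudinal magnetization recovers for the part of TR
#' not occupied by the echo train, and decays mono-exponentially at the
#' nominal echo time,
#' \deqn{S = (1 - e^{-(TR - ES \cdot ETL)/T1}) \; e^{-TE/T2}.}
#' The result is a dimensionless fraction of the equilibrium magnetization
#' in (0, 1). At TE = 1347 ms every compartment with T2 under ~150 ms
#' (blood, parenchyma) is suppressed below 1e-3, which is what makes the
#' sequence CSF-selective.
#'
#' @param seq A [cdsc_params()] object.
#' @param T1,T2 Relaxation times in ms; vectorized (recycled together).
#' @return Signal as a fraction of equilibrium magnetization.
#' @export
#' @examples
#' cdsc_signal(cdsc_params(), 4310, 1400) # CSF ~0.302
#' cdsc_signal(cdsc_params(), 1878, 157)  # blood, suppressed < 1e-3
cdsc_signal <- function(seq, T1, T2) {
  stopifnot(inherits(seq, "sequence_params"))
  if (seq$name != "cdsc") {
    stop("cdsc_signal needs sequence_params with name 'cdsc'", call. = FALSE)
  }
  train <- seq$echo_spacing * seq$etl
  if (train >= seq$TR) {
    stop("echo-train duration exceeds TR", call. = FALSE)
  }
  (1 - exp(-(seq$TR - train) / T1)) * exp(-seq$TE / T2)
}

#' Steady-state FLAIR signal
#'
#' Classic inversion-recovery steady state with mono-exponential T2 decay,
#' \deqn{S = (1 - 2 e^{-TI/T1} + e^{-TR/T1}) \; e^{-TE/T2},}
#' as a signed fraction of the equilibrium magnetization. Near the fluid
#' null point (TI chosen to null long-T1 CSF) the value is small and may be
#' negative; magnitude reconstruction means image comparisons use
#' `abs(flair_signal(...))`. No echo-train flip-angle modulation,
#' magnetization transfer, or flow effects are modeled.
#'
#' @inheritParams cdsc_signal
#' @param seq A [flair_params()] object.
#' @return Signed signal fraction of equilibrium magnetization.
#' @export
#' @examples
#' flair_signal(flair_params(), 4310, 1400)  # pre-contrast CSF ~nulled
flair_signal <- function(seq, T1, T2) {
  stopifnot(inherits(seq, "sequence_params"))
  if (seq$name != "flair") {
    stop("flair_signal needs sequence_params with name 'flair'", call. = FALSE)
  }
  if (seq$TI >= seq$TR) stop("TI must be shorter than TR", call. = FALSE)
  (1 - 2 * exp(-seq$TI / T1) + exp(-seq$TR / T1)) * exp(-seq$TE / T2)
}

#' Partial-volume mixing of compartment signals
#'
#' A voxel containing several compartments contributes the volume-fraction
#' weighted sum of their signals. Every compartment with a positive
#' fraction must have a signal supplied.
#'
#' @param comp A [voxel_composition()] object.
#' @param signals Named numeric vector of per-compartment signals.
#' @return The mixed voxel signal (dimensionless).
#' @export
#' @examples
#' comp <- voxel_composition(c(csf = 0.5, blood = 0.5))
#' voxel_signal(comp, c(csf = 0.3018, blood = 1.8e-4))
voxel_signal <- function(comp, signals) {
  stopifnot(inherits(comp, "voxel_composition"))
  fr <- comp$fractions
  active <- names(fr)[fr > 0]
  missing <- setdiff(active, names(signals))
  if (length(missing)) {
    stop("no signal supplied for compartment(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sum(fr[active] * signals[active])
}

#' Contrast curve: signal change as a function of gadolinium concentration
#'
#' Evaluates the chosen sequence's signal at each concentration after
#' relaxivity-modifying T1 and T2, and returns the change relative to the
#' zero-concentration signal. Two conventions are offered:
#' `normalize = "equilibrium"` gives the change in magnitude signal as a
#' fraction of the equilibrium magnetization (the simulation-plot
#' convention, `|S(c)| - |S(0)|`); `normalize = "baseline"` gives the
#' relative change `(S(c) - S(0))/S(0)` that corresponds to the measured
#' per-ROI quantity for the CSF-selective sequence.
#'
#' For CSF under the long-TE sequence the curve is negative and decreasing
#' over the working range (see [estimate_concentration()] for the exact
#' monotone branch); for blood it stays below 1e-3 in magnitude at every
#' concentration because the sequence suppresses short-T2 spins.
#'
#' @param seq A [cdsc_params()] or [flair_params()] object.
#' @param tissue A [tissue_relaxation()] object.
#' @param c_grid Non-negative, ascending concentrations in mmol/L.
#' @param normalize `"equilibrium"` or `"baseline"` (see Details).
#' @return A data.frame with columns `c` (mmol/L) and `delta`
#'   (dimensionless signal change in the requested convention).
#' @export
#' @examples
#' contrast_curve(cdsc_params(), tissue_defaults("csf"), seq(0, 0.5, 0.05))
contrast_curve <- function(seq, tissue, c_grid,
                           normalize = c("equilibrium", "baseline")) {
  stopifnot(inherits(seq, "sequence_params"),
            inherits(tissue, "tissue_relaxation"))
  normalize <- match.arg(normalize)
  if (any(c_grid < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (is.unsorted(c_grid, strictly = FALSE)) {
    stop("c_grid must be ascending", call. = FALSE)
  }
  sig <- function(c) {
    T1 <- t1_with_gd(tissue$T1_0, tissue$r1, c)
    T2 <- t2_with_gd(tissue$T2_0, tissue$r2, c)
    switch(seq$name,
           cdsc = cdsc_signal(seq, T1, T2),
           flair = flair_signal(seq, T1, T2))
  }
  s0 <- sig(0)
  s <- sig(c_grid)
  delta <- switch(normalize,
                  equilibrium = abs(s) - abs(s0),
                  baseline = (s - s0) / s0)
  data.frame(c = c_grid, delta = delta)
}
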