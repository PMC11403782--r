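#' Forward model: relative CSF signal change at a given concentration
#'
#' Predicts the percent relative signal change of the long-TE CSF-selective
#' sequence, `100 * (S(c) - S(0)) / S(0)`, where `S` is [cdsc_signal()]
#' evaluated after relaxivity-shortening T1 and T2. Zero at `c = 0`;
#' negative and monotonically decreasing over the working concentration
#' range for CSF parameters (see [estimate_concentration()] for the exact
#' shape near zero).
#'
#' @param c Concentration in mmol/L (>= 0); vectorized.
#' @param seq A [cdsc_params()] object.
#' @param tissue A [tissue_relaxation()] object (typically
#'   `tissue_defaults("csf")`).
#' @return Relative signal change in percent.
#' @export
#' @examples
#' forward_delta_s(0.0501, cdsc_params(), tissue_defaults("csf")) # ~ -7.6
forward_delta_s <- function(c, seq, tissue) {
  stopifnot(inherits(seq, "sequence_params"),
            inherits(tissue, "tissue_relaxation"))
  if (any(c < 0)) stop("concentration must be non-negative", call. = FALSE)
  s0 <- cdsc_signal(seq, tissue$T1_0, tissue$T2_0)
  s <- cdsc_signal(seq,
                   t1_with_gd(tissue$T1_0, tissue$r1, c),
                   t2_with_gd(tissue$T2_0, tissue$r2, c))
  100 * (s - s0) / s0
}

# Characterize the forward curve on a grid over the bracket: locate the
# (possibly degenerate) argmax and check that the remainder is strictly
# decreasing. The T1-recovery term can outpace T2 decay in a narrow band
# near c = 0, producing a shallow positive lobe (< 0.1 % for the default
# CSF model); inversion therefore targets the strictly decreasing branch.
.forward_profile <- function(seq, tissue, bracket, n_grid = 1000) {
  grid <- seq.int(0L, n_grid - 1L) / (n_grid - 1) * diff(bracket) + bracket[1]
  fg <- forward_delta_s(grid, seq, tissue)
  i_max <- which.max(fg)
  tail_d <- diff(fg[i_max:length(fg)])
  # non-increasing everywhere past the peak (tolerating floating-point
  # saturation where the signal has fully decayed) and strictly lower at
  # the far end
  decreasing <- all(tail_d < 1e-10) && fg[length(fg)] < fg[i_max]
  lobe_ok <- grid[i_max] <= bracket[1] + 0.01 * diff(bracket)
  list(grid = grid, fg = fg, i_max = i_max,
       c_peak = grid[i_max], f_peak = fg[i_max],
       monotone = decreasing && lobe_ok)
}

#' Invert a measured relative signal change to gadolinium concentration
#'
#' The relative signal change of the CSF-selective sequence decreases
#' monotonically with concentration over the working range, so a measured
#' negative `delta` maps to a unique concentration, found by bracketed
#' root finding (Brent) on the decreasing branch of the forward curve.
#'
#' Before any inversion the forward model is profiled on a 1000-point grid
#' over `bracket`: it must be strictly decreasing beyond its maximum, and
#' any initial rising lobe (a sub-0.1 % artifact of T1 recovery at very low
#' concentration for the default model) must be confined to the first 1 %
#' of the bracket. A model failing this guard aborts with an error.
#' Positive `delta` is rejected rather than clipped: for this sequence a
#' positive CSF change indicates contamination (partial volume, motion)
#' that the caller must see.
#'
#' @param delta Measured relative signal change in percent (<= 0).
#' @param seq A [cdsc_params()] object.
#' @param tissue A [tissue_relaxation()] object.
#' @param bracket Search interval in mmol/L, default `c(0, 5)`.
#' @param tol Root tolerance in mmol/L.
#' @return A `concentration_estimate` object: list with `c` (mmol/L),
#'   `delta_s_over_s_input` (percent), `bracket`, and `model`
#'   (sequence/tissue used).
#' @export
#' @examples
#' est <- estimate_concentration(-7.58, cdsc_params(), tissue_defaults("csf"))
#' est$c  # ~0.0501 mmol/L
estimate_concentration <- function(delta, seq, tissue,
                                   bracket = c(0, 5), tol = 1e-8) {
  stopifnot(length(delta) == 1, is.finite(delta),
            length(bracket) == 2, bracket[1] >= 0, bracket[2] > bracket[1])
  prof <- .forward_profile(seq, tissue, bracket)
  if (!prof$monotone) {
    stop("forward model is not monotone decreasing over the bracket; ",
         "inversion precondition violated", call. = FALSE)
  }
  f_lo <- prof$fg[length(prof$fg)]          # most negative attainable
  if (delta > 0) {
    stop(sprintf(
      "positive delta-S/S (%.3f%%) cannot arise from gadolinium in CSF under this sequence; attainable range is [%.3f%%, 0%%]",
      delta, f_lo), call. = FALSE)
  }
  if (delta < f_lo) {
    stop(sprintf(
      "delta-S/S = %.3f%% is below the attainable range [%.3f%%, 0%%] on the bracket [%g, %g] mmol/L",
      delta, f_lo, bracket[1], bracket[2]), call. = FALSE)
  }
  if (delta == 0) {
    c_star <- bracket[1]
  } else {
    lo <- prof$c_peak
    root <- stats::uniroot(
      function(c) forward_delta_s(c, seq, tissue) - delta,
      lower = lo, upper = bracket[2], tol = tol)
    c_star <- root$root
  }
  structure(
    list(c = c_star, delta_s_over_s_input = delta, bracket = bracket,
         model = list(sequence = seq, tissue = tissue), tol = tol),
    class = "concentration_estimate"
  )
}

#' @export
print.concentration_estimate <- function(x, ...) {
  cat(sprintf("<concentration_estimate> [Gd] = %.4f mmol/L (from delta-S/S = %.2f%%)\n",
              x$c, x$delta_s_over_s_input))
  invisible(x)
}

#' Sensitivity of the concentration estimate to model parameters
#'
#' Re-inverts the same measured signal change under multiplicatively
#' perturbed model parameters, one scenario per row. A scenario is a named
#' list/vector of factors applied to any of `T1_0`, `T2_0`, `r1`, `r2`
#' (e.g. `c(T1_0 = 0.8, r1 = 0.8, r2 = 1.2)`); parameters not named are
#' left at their configured values, and an empty scenario reproduces the
#' baseline estimate.
#'
#' @param delta Measured relative signal change in percent (<= 0).
#' @param scenarios A list of named numeric vectors of positive factors.
#'   Names of the list label the output rows.
#' @param seq A [cdsc_params()] object.
#' @param tissue The unperturbed [tissue_relaxation()] object.
#' @inheritParams estimate_concentration
#' @return A data.frame with one row per scenario: the factors applied and
#'   the re-estimated concentration `c` in mmol/L.
#' @export
#' @examples
#' sensitivity_analysis(-7.58,
#'   list(baseline = c(), pessimistic = c(T1_0 = 0.8, r1 = 0.8, r2 = 1.2)),
#'   cdsc_params(), tissue_defaults("csf"))
sensitivity_analysis <- function(delta, scenarios, seq, tissue,
                                 bracket = c(0, 5), tol = 1e-8) {
  stopifnot(is.list(scenarios))
  fields <- c("T1_0", "T2_0", "r1", "r2")
  rows <- lapply(seq_along(scenarios), function(i) {
    fac <- scenarios[[i]]
    if (length(fac)) {
      bad <- setdiff(names(fac), fields)
      if (length(bad)) {
        stop("unknown parameter(s) in scenario: ", paste(bad, collapse = ", "),
             call. = FALSE)
      }
      if (any(fac <= 0)) stop("perturbation factors must be positive", call. = FALSE)
    }
    full <- stats::setNames(rep(1, length(fields)), fields)
    full[names(fac)] <- fac
    pert <- tissue_relaxation(tissue$compartment,
                              T1_0 = tissue$T1_0 * full["T1_0"],
                              T2_0 = tissue$T2_0 * full["T2_0"],
                              r1 = tissue$r1 * full["r1"],
                              r2 = tissue$r2 * full["r2"],
                              hct = tissue$hct)
    est <- estimate_concentration(delta, seq, pert, bracket = bracket, tol = tol)
    data.frame(scenario = names(scenarios)[i] %||% as.character(i),
               t(full), c = est$c)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convert a molar gadolinium concentration to a mass concentration
#'
#' Uses the stock formulation ratio of the injected agent to convert
#' mmol/L to ng/mL: `c * (mg_per_ml / mmol_per_ml) * 1000`. The defaults
#' are the Gadoteridol (ProHance) formulation, 279.3 mg/mL at 0.5 mmol/mL,
#' i.e. an effective molar mass of 558.6 mg/mmol.
#'
#' @param c Concentration in mmol/L (>= 0); vectorized.
#' @param mg_per_ml Stock mass concentration in mg/mL (> 0).
#' @param mmol_per_ml Stock molar concentration in mmol/mL (> 0).
#' @return Concentration in ng/mL.
#' @export
#' @examples
#' mmol_per_l_to_ng_per_ml(0.0501) # 27986 ng/mL
mmol_per_l_to_ng_per_ml <- function(c, mg_per_ml = 279.3, mmol_per_ml = 0.5) {
  if (any(c < 0)) stop("concentration must be non-negative", call. = FALSE)
  if (mg_per_ml <= 0 || mmol_per_ml <= 0) {
    stop("stock concentrations must be positive", call. = FALSE)
  }
  c * (mg_per_ml / mmol_per_ml) * 1000
}
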