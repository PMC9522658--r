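# Forward simulator: line-scan waveforms, per-profile sets, whole-tubule
# kinetics and axial uptake profiles with the statistical structure the
# decomposition assumes.

#' Fluorescence unquenching gain of a labeling scheme
#'
#' An intact protein carrying n fluorophores emits \code{n * q^(n-1)} (each
#' additional fluorophore quenches all by a factor q); full proteolysis into
#' single-dye fragments emits \code{n}. The gain is the degraded/intact
#' brightness ratio \code{q^(1-n)}, which is 1 for a single fluorophore or
#' q = 1, and strictly increasing in n for q < 1.
#'
#' @param labeling a \linkS4class{LabelingSpec}.
#' @return Dimensionless gain >= 1.
#' @examples
#' unquenchGain(LabelingSpec(nLabels = 4, quenchQ = 0.6))  # 0.6^-3 = 4.63
#' @export
unquenchGain <- function(labeling) {
  stopifnot(is(labeling, "LabelingSpec"))
  validObject(labeling)
  labeling@quenchQ^(1 - labeling@nLabels)
}

#' Time course of one compartment
#'
#' Sums the compartment's kinetic phases at the given times. Each phase
#' contributes \code{a (1 - exp(-(t-t0)/tau_r)) exp(-(t-t0)/tau_d)} for
#' \code{t >= t0}, zero before. Phases gated by unquenching are multiplied by
#' \code{\link{unquenchGain}} and zeroed under cathepsin inhibition.
#'
#' @param spec a \linkS4class{CompartmentSpec}.
#' @param times increasing time vector (min).
#' @param labeling a \linkS4class{LabelingSpec}.
#' @param cathepsinInhibited logical.
#' @return Non-negative intensity vector, one value per time.
#' @export
compartmentTimeCourse <- function(spec, times, labeling = LabelingSpec(),
                                  cathepsinInhibited = FALSE) {
  stopifnot(is(spec, "CompartmentSpec"))
  if (!length(times)) stop("times must be non-empty")
  if (length(times) >= 2L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  gain <- unquenchGain(labeling)
  out <- numeric(length(times))
  for (p in spec@phases) {
    amp <- p@amplitude
    if (p@gatedByUnquenching) {
      if (cathepsinInhibited) next
      amp <- amp * gain
    }
    tau <- times - p@onset
    on <- tau >= 0
    contrib <- numeric(length(times))
    decay <- if (is.finite(p@decayTau)) exp(-tau[on] / p@decayTau) else 1
    contrib[on] <- amp * (1 - exp(-tau[on] / p@riseTau)) * decay
    out <- out + contrib
  }
  pmax(out, 0)
}

#' Gaussian spatial footprint of a compartment
#'
#' @param spec a \linkS4class{CompartmentSpec}.
#' @param positions normalised positions in [0, 1].
#' @return \code{exp(-(x - center)^2 / (2 width^2))}.
#' @export
spatialProfile <- function(spec, positions) {
  stopifnot(is(spec, "CompartmentSpec"))
  exp(-(positions - spec@center)^2 / (2 * spec@width^2))
}

# Evaluate all RNG under the scenario seed, leaving the caller's RNG state
# untouched.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.scenarioTimes <- function(scenario)
  seq(0, scenario@duration, length.out = scenario@nTimepoints)

# Noiseless mixture evaluated at arbitrary positions x times.
.noiselessMatrix <- function(scenario, positions, times) {
  comps <- scenarioCompartments(scenario)
  acc <- matrix(0, length(positions), length(times))
  for (cp in comps) {
    acc <- acc + outer(spatialProfile(cp, positions),
                       compartmentTimeCourse(cp, times, scenario@labeling,
                                             scenario@cathepsinInhibited))
  }
  acc
}

.addNoise <- function(values, scenario) {
  if (scenario@noiseSigma == 0) return(values)
  if (scenario@noiseModel == "poisson") {
    q <- scenario@noiseSigma^2  # variance = q * signal
    matrix(stats::rpois(length(values), pmax(values, 0) / q) * q,
           nrow(values), ncol(values))
  } else {
    pmax(values + stats::rnorm(length(values), 0, scenario@noiseSigma), 0)
  }
}

#' Simulate a binned waveform matrix
#'
#' Evaluates the compartment mixture on uniform position bins and the
#' scenario's time grid, then adds noise (clipped at zero). Entry (x, t) is
#' \code{sum_c G_c(x) k_c(t) + noise}. Identical scenarios (including seed)
#' give identical output; with zero noise and a single compartment the result
#' is an exact outer product (rank 1).
#'
#' @param scenario a \linkS4class{Scenario}.
#' @param nBins number of position bins (default 100).
#' @return A \linkS4class{WaveformMatrix}.
#' @examples
#' w <- simulateWaveform(defaultScenario("healthy-S1"))
#' @export
simulateWaveform <- function(scenario, nBins = 100L) {
  stopifnot(is(scenario, "Scenario"))
  validObject(scenario)
  positions <- (seq_len(nBins) - 0.5) / nBins
  times <- .scenarioTimes(scenario)
  clean <- .noiselessMatrix(scenario, positions, times)
  values <- .withSeed(scenario@seed, .addNoise(clean, scenario))
  WaveformMatrix(values, times, tubuleId = scenario@name)
}

#' Simulate raw line-scan profiles
#'
#' Generates the per-ROI sample set underlying a waveform: each of the
#' scenario's \code{nProfiles} ROIs is a line across the cell sampled at
#' \code{samplesPerProfile} points per frame, with exact membrane endpoints,
#' slight interior sample jitter (hand-drawn ROIs do not sample a perfect
#' grid), and per-sample noise. Positions are emitted apical-first in pixel
#' units to exercise downstream rescaling.
#'
#' @param scenario a \linkS4class{Scenario}.
#' @param samplesPerProfile samples per ROI per frame (default 200).
#' @param pixelLength physical length of the scan line in pixels (default
#'   120).
#' @return A long-format \code{data.frame} with columns \code{tubule_id},
#'   \code{profile_id}, \code{time_min}, \code{position}, \code{intensity}.
#' @export
simulateProfiles <- function(scenario, samplesPerProfile = 200L,
                             pixelLength = 120) {
  stopifnot(is(scenario, "Scenario"))
  validObject(scenario)
  ns <- as.integer(samplesPerProfile)
  stopifnot(ns >= 2L)
  times <- .scenarioTimes(scenario)
  np <- scenario@nProfiles
  .withSeed(scenario@seed + 1L, {
    # per-profile normalised sample positions: exact endpoints, jittered interior
    posList <- lapply(seq_len(np), function(p) {
      x <- seq(0, 1, length.out = ns)
      jit <- stats::runif(ns - 2L, -0.2, 0.2) / (ns - 1L)
      x[-c(1L, ns)] <- sort(x[-c(1L, ns)] + jit)
      x
    })
    rows <- lapply(seq_len(np), function(p) {
      x <- posList[[p]]
      clean <- .noiselessMatrix(scenario, x, times)
      noisy <- .addNoise(clean, scenario)
      data.frame(
        tubule_id = scenario@name,
        profile_id = sprintf("roi%02d", p),
        time_min = rep(times, each = ns),
        position = rep(x * pixelLength, times = length(times)),
        intensity = as.vector(noisy))
    })
    do.call(rbind, rows)
  })
}

#' Simulate whole-tubule fluorescence time series
#'
#' Deterministic compartmental model of whole-segment signals: plasma decays
#' mono-exponentially; S1 takes up intact protein in proportion to plasma
#' concentration (scaled by \code{uptakeScale}); after
#' \code{degradationDelay} (plus any \code{eeTransitDelay}), lysosomal
#' proteolysis converts intact protein into unquenched fragments (brightness
#' times the unquenching gain) that are released into the lumen; S2 and the
#' distal-tubule lumen take up the released fragments after their transport
#' lags. Cathepsin inhibition disables proteolysis, so S2 and DT signals
#' vanish.
#'
#' @param scenario a \linkS4class{Scenario}.
#' @return Named list of \linkS4class{TubuleTimeSeries}: \code{plasma},
#'   \code{S1}, \code{S2}, \code{DT_lumen}.
#' @export
simulateTubuleSeries <- function(scenario) {
  stopifnot(is(scenario, "Scenario"))
  validObject(scenario)
  gain <- unquenchGain(scenario@labeling)
  d <- scenario@degradationDelay + scenario@eeTransitDelay
  lag2 <- scenario@transportLagS2
  lagd <- scenario@transportLagDT
  us <- scenario@uptakeScale
  tauP <- 3; kdeg <- 1; krel <- 0.15; kloss2 <- 0.7; kout <- 0.7
  dt <- 0.02
  tg <- seq(0, scenario@duration, by = dt)
  n <- length(tg)
  P <- exp(-tg / tauP)
  I <- D <- S2 <- DT <- numeric(n)
  i2 <- round(lag2 / dt); idl <- round(lagd / dt)
  for (i in 2:n) {
    t0 <- tg[i - 1L]
    deg <- if (!scenario@cathepsinInhibited && t0 >= d) kdeg * I[i - 1L] else 0
    I[i] <- I[i - 1L] + dt * (us * P[i - 1L] - deg)
    D[i] <- D[i - 1L] + dt * (deg - krel * D[i - 1L])
    R2 <- if (i - 1L - i2 >= 1L) krel * D[i - 1L - i2] else 0
    Rd <- if (i - 1L - idl >= 1L) krel * D[i - 1L - idl] else 0
    S2[i] <- S2[i - 1L] + dt * (R2 - kloss2 * S2[i - 1L])
    DT[i] <- DT[i - 1L] + dt * (Rd - kout * DT[i - 1L])
  }
  ts <- .scenarioTimes(scenario)
  idx <- pmin(round(ts / dt) + 1L, n)
  list(
    plasma   = TubuleTimeSeries("plasma", ts, P[idx]),
    S1       = TubuleTimeSeries("S1", ts, (I + gain * D)[idx]),
    S2       = TubuleTimeSeries("S2", ts, S2[idx]),
    DT_lumen = TubuleTimeSeries("DT_lumen", ts, DT[idx]))
}

#' Simulate an axial uptake and dispersion profile
#'
#' Emulates single-time-point ROIs drawn around successive proximal-tubule
#' segments (rank 1 = most proximal by reference uptake). Uptake decays
#' along the tubule with a length constant that grows as endocytotic
#' capacity falls (\code{L = L0 / uptakeScale}), so reduced-uptake disease
#' scenarios redistribute uptake distally. Intracellular dispersion (the SD
#' of the signal inside each ROI) declines linearly along the healthy axis
#' (condensed apical vesicles early, diffuse signal late); the gradient is
#' flattened when \code{uptakeScale < 1}.
#'
#' @param scenario a \linkS4class{Scenario}.
#' @param nRois number of ROIs along the tubule (default 20).
#' @param l0 healthy uptake length constant, in ROIs (default 3).
#' @return \code{data.frame} with columns \code{roi_id},
#'   \code{reference_intensity}, \code{signal_intensity}, \code{dispersion}.
#' @export
simulateAxialProfile <- function(scenario, nRois = 20L, l0 = 3) {
  stopifnot(is(scenario, "Scenario"))
  validObject(scenario)
  nRois <- as.integer(nRois)
  us <- scenario@uptakeScale
  .withSeed(scenario@seed + 2L, {
    i <- seq_len(nRois)
    if (us > 0) {
      L <- l0 / us
      uptake <- us * exp(-(i - 1) / L)
    } else {
      uptake <- rep(0, nRois)
    }
    mult <- pmax(1 + stats::rnorm(nRois, 0, 0.05), 0)
    # dispersion gradient: steep in health, flattened with uptake defects
    slope <- 0.8 * us
    disp <- pmax(1 - slope * (i - 1) / (nRois - 1) +
                   stats::rnorm(nRois, 0, 0.1), 0)
    data.frame(roi_id = sprintf("seg%02d", i),
               reference_intensity = uptake * mult,
               signal_intensity = uptake * mult,
               dispersion = disp)
  })
}
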