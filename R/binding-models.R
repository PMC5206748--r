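## One-site ITC isotherm and 1:1 SPR kinetics: closed-form models, seeded
## simulators, and trust-region least-squares fitters (minpack.lm) with
## deterministic multi-start.

#' Default ITC experiment layout
#'
#' Antibody in the cell, cadherin construct in the syringe: 20 uM cell
#' species (within the 15-30 uM range typical for these titrations), 200 uM
#' titrant (10x), 200 uL cell, 25 injections of 1.5 uL at 15 degrees C.
#'
#' @param cellConc,syringeConc molar.
#' @param cellVolume litre.
#' @param nInjections,injectionVolume count and litre per injection.
#' @param temperature kelvin.
#' @return list layout consumed by [simulateItc()].
#' @export
itcLayout <- function(cellConc = 20e-6, syringeConc = 200e-6,
                      cellVolume = 200e-6, nInjections = 25,
                      injectionVolume = 1.5e-6, temperature = 288.15) {
  list(cellConc = cellConc, syringeConc = syringeConc,
       cellVolume = cellVolume,
       injectionVolumes = rep(injectionVolume, nInjections),
       temperature = temperature)
}

# cumulative heat (cal) of the one-site model at total cell species Mt and
# total titrant Xt (both molar, dilution-corrected), cell volume V0 (L)
oneSiteCumulativeHeat <- function(n, K, dH, Mt, Xt, V0) {
  a <- 1 + Xt / (n * Mt) + 1 / (n * K * Mt)
  n * Mt * dH * V0 / 2 * (a - sqrt(pmax(0, a * a - 4 * Xt / (n * Mt))))
}

# per-injection dilution bookkeeping: factor (1 - dV/V0) on everything in
# the cell, fresh titrant dV/V0 * syringe concentration added
itcConcentrationSeries <- function(layout) {
  dv <- layout$injectionVolumes
  V0 <- layout$cellVolume
  k <- length(dv)
  Mt <- numeric(k); Xt <- numeric(k)
  m <- layout$cellConc; x <- 0
  for (i in seq_len(k)) {
    f <- 1 - dv[i] / V0
    m <- m * f
    x <- x * f + layout$syringeConc * dv[i] / V0
    Mt[i] <- m; Xt[i] <- x
  }
  list(Mt = Mt, Xt = Xt)
}

itcModelHeats <- function(n, K, dH, layout) {
  conc <- itcConcentrationSeries(layout)
  V0 <- layout$cellVolume
  dv <- layout$injectionVolumes
  Q <- oneSiteCumulativeHeat(n, K, dH, conc$Mt, conc$Xt, V0)
  Qprev <- c(0, Q[-length(Q)])
  # displaced-volume correction: heat carried out with the overflow liquid
  dq <- Q - Qprev + dv / V0 * (Q + Qprev) / 2
  dq * 1e6   # microcal
}

#' Simulate a one-site ITC titration
#'
#' Generates per-injection heats from the closed-form one-site binding
#' isotherm with per-injection dilution bookkeeping and a displaced-volume
#' heat correction, plus Gaussian noise.
#'
#' @param n stoichiometry (titrant per cell molecule).
#' @param K association constant, 1/M.
#' @param dH enthalpy, cal/mol.
#' @param layout experiment layout from [itcLayout()].
#' @param noiseSd Gaussian noise SD in microcal per injection.
#' @param seed RNG seed (explicit: fixtures are reproducible by construction).
#' @return an [ItcExperiment-class].
#' @export
simulateItc <- function(n, K, dH, layout = itcLayout(), noiseSd = 0,
                        seed = 1L) {
  if (n <= 0 || K <= 0) stop("n and K must be positive")
  heats <- itcModelHeats(n, K, dH, layout)
  if (noiseSd > 0) {
    rng <- localRng(seed)
    heats <- heats + rng$rnorm(length(heats), 0, noiseSd)
  }
  new("ItcExperiment", cellConc = layout$cellConc,
      syringeConc = layout$syringeConc, cellVolume = layout$cellVolume,
      injectionVolumes = layout$injectionVolumes, heats = heats,
      temperature = layout$temperature)
}

#' Molar ratio axis of an ITC experiment
#'
#' @param experiment an [ItcExperiment-class].
#' @return titrant/cell molar ratio after each injection.
#' @export
molarRatio <- function(experiment) {
  conc <- itcConcentrationSeries(
    list(cellConc = experiment@cellConc, syringeConc = experiment@syringeConc,
         cellVolume = experiment@cellVolume,
         injectionVolumes = experiment@injectionVolumes))
  conc$Xt / conc$Mt
}

#' Fit the one-site binding model to an ITC experiment
#'
#' Nonlinear least squares (Levenberg-Marquardt with box constraints) on the
#' same closed-form model used by [simulateItc()], with a constant
#' per-injection baseline offset as a nuisance parameter. One-site fits are
#' multimodal at low c-values, so the fit is restarted from a deterministic
#' grid of stoichiometries (n in 0.5, 1, 1.5, 2) with K seeded from the
#' isotherm slope around the equivalence point; ties are broken by residual
#' norm, then lowest n. The first injection is excluded by default
#' (standard practice: its effective volume is corrupted by syringe
#' diffusion).
#'
#' @param experiment an [ItcExperiment-class] with >= 8 injections.
#' @param excludeFirst drop the first injection (default TRUE).
#' @param starts numeric vector of stoichiometry starts.
#' @return an [ItcFit-class]. Standard errors come from the Jacobian at the
#'   optimum.
#' @export
fitItc <- function(experiment, excludeFirst = TRUE,
                   starts = c(0.5, 1, 1.5, 2)) {
  heats <- experiment@heats
  if (length(heats) < 8) stop("need at least 8 injections")
  layout <- list(cellConc = experiment@cellConc,
                 syringeConc = experiment@syringeConc,
                 cellVolume = experiment@cellVolume,
                 injectionVolumes = experiment@injectionVolumes)
  use <- seq_along(heats)
  if (excludeFirst) use <- use[-1]
  ratio <- molarRatio(experiment)

  # ballpark dH from the early plateau, K from the transition sharpness
  perMol <- heats[use] / (layout$syringeConc * layout$injectionVolumes[use] * 1e6)
  dH0 <- stats::median(perMol[seq_len(min(3, length(perMol)))])
  if (!is.finite(dH0) || dH0 == 0) dH0 <- -1e4
  K0 <- 1 / (0.05 * layout$cellConc)   # slope heuristic: c-value ~ 20

  resid <- function(p) {
    mod <- itcModelHeats(p[1], 10^p[2], p[3], layout)
    (mod[use] + p[4]) - heats[use]
  }
  best <- NULL
  for (n0 in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = c(n0, log10(K0), dH0, 0), fn = resid,
      lower = c(1e-3, 0, -1e9, -Inf), upper = c(100, 16, 1e9, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn - 1e-9 ||
        (abs(rn - best$rn) <= 1e-9 && fit$par[1] < best$fit$par[1]))
      best <- list(fit = fit, rn = rn)
  }
  if (is.null(best))
    stop("ITC fit did not converge from any start")
  fit <- best$fit
  p <- fit$par
  # standard errors from the Jacobian; delta method for K = 10^p2
  se <- rep(NA_real_, 4)
  cv <- try(stats::vcov(fit), silent = TRUE)
  if (!inherits(cv, "try-error") && all(is.finite(diag(cv))))
    se <- sqrt(pmax(0, diag(cv)))
  seK <- se[2] * log(10) * 10^p[2]
  new("ItcFit", n = p[1], K = 10^p[2], dH = p[3], offset = p[4],
      stderr = c(n = se[1], K = seK, dH = se[3], offset = se[4]),
      residuals = fit$fvec, molarRatio = ratio[use])
}

## --- SPR -------------------------------------------------------------------

spr11Model <- function(kon, koff, Rmax, conc, time, phase, tAssoc) {
  kobs <- conc * kon + koff
  req <- conc * kon * Rmax / kobs
  rAssoc <- req * (1 - exp(-kobs * time))
  rEnd <- req * (1 - exp(-kobs * tAssoc))
  ifelse(phase == "association", rAssoc,
         rEnd * exp(-koff * (time - tAssoc)))
}

#' Simulate a 1:1 SPR kinetic titration
#'
#' Association `R(t) = C kon Rmax/(C kon + koff) (1 - exp(-(C kon + koff) t))`
#' followed by exponential dissociation from the association end point, for
#' a series of analyte concentrations, with seeded Gaussian noise.
#'
#' @param kon association rate, 1/(M s).
#' @param koff dissociation rate, 1/s.
#' @param Rmax saturation response, RU.
#' @param concentrations molar analyte concentrations (>= 2 for a global fit).
#' @param associationTime,dissociationTime window lengths, seconds.
#' @param dt sampling interval, seconds.
#' @param noiseSd Gaussian noise SD in RU.
#' @param seed RNG seed.
#' @return an [SprExperiment-class].
#' @export
simulateSensorgram <- function(kon, koff, Rmax,
                               concentrations = c(1.25, 2.5, 5, 10, 20) * 1e-9,
                               associationTime = 120, dissociationTime = 300,
                               dt = 1, noiseSd = 0, seed = 1L) {
  if (kon <= 0 || koff <= 0 || Rmax <= 0)
    stop("kon, koff and Rmax must be positive")
  tA <- seq(dt, associationTime, by = dt)
  tD <- if (dissociationTime >= dt)
    seq(associationTime + dt, associationTime + dissociationTime, by = dt)
  else numeric(0)
  rows <- lapply(concentrations, function(C) {
    data.frame(concentration = C,
               time = c(tA, tD),
               response = spr11Model(kon, koff, Rmax, C, c(tA, tD),
                                     rep(c("association", "dissociation"),
                                         c(length(tA), length(tD))),
                                     associationTime),
               phase = rep(c("association", "dissociation"),
                           c(length(tA), length(tD))))
  })
  df <- do.call(rbind, rows)
  if (noiseSd > 0) {
    rng <- localRng(seed)
    df$response <- df$response + rng$rnorm(nrow(df), 0, noiseSd)
  }
  new("SprExperiment", data = df, associationTime = associationTime,
      dissociationTime = dissociationTime)
}

#' Global 1:1 fit of an SPR concentration series
#'
#' One shared (kon, koff, Rmax) fitted by least squares over the
#' concatenated association and dissociation phases of all sensorgrams
#' (Levenberg-Marquardt on log-rates). `KD = koff/kon` by identity. No
#' mass-transport term: a plain 1:1 interaction model.
#'
#' @param experiment an [SprExperiment-class] with >= 2 concentrations.
#' @return a [KineticFit-class].
#' @export
fitSprGlobal <- function(experiment) {
  df <- experiment@data
  if (length(unique(df$concentration)) < 2)
    stop("global fit needs at least 2 analyte concentrations")
  tA <- experiment@associationTime
  # koff start from the pooled log-linear dissociation tail
  dis <- df[df$phase == "dissociation" & df$response > 0, ]
  koff0 <- 1e-3
  if (nrow(dis) > 10) {
    sl <- try(stats::coef(stats::lm(log(response) ~ time, dis))[2], silent = TRUE)
    if (!inherits(sl, "try-error") && is.finite(sl) && sl < 0)
      koff0 <- min(max(-sl, 1e-6), 1)
  }
  kon0 <- koff0 / stats::median(df$concentration)   # KD ~ mid concentration
  Rmax0 <- max(df$response) * 1.2
  resid <- function(p)
    spr11Model(10^p[1], 10^p[2], p[3], df$concentration, df$time, df$phase,
               tA) - df$response
  fit <- minpack.lm::nls.lm(
    par = c(log10(kon0), log10(koff0), Rmax0), fn = resid,
    lower = c(-2, -8, 1e-6), upper = c(12, 3, 1e7),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  if (fit$info == 0 || !all(is.finite(fit$par)))
    stop("SPR global fit did not converge; residual norm ",
         sqrt(sum(fit$fvec^2)))
  p <- fit$par
  se <- rep(NA_real_, 3)
  cv <- try(stats::vcov(fit), silent = TRUE)
  if (!inherits(cv, "try-error") && all(is.finite(diag(cv))))
    se <- sqrt(pmax(0, diag(cv)))
  kon <- 10^p[1]; koff <- 10^p[2]
  new("KineticFit", kon = kon, koff = koff, Rmax = p[3], KD = koff / kon,
      stderr = c(kon = se[1] * log(10) * kon, koff = se[2] * log(10) * koff,
                 Rmax = se[3]),
      residuals = fit$fvec)
}

## --- file I/O for the fitters ---------------------------------------------

#' Read an ITC experiment from CSV + YAML header
#'
#' CSV columns: `injection_volume_uL`, `heat_ucal`. YAML keys:
#' `cell_concentration_M`, `syringe_concentration_M`, `cell_volume_L`,
#' `temperature_K`.
#'
#' @param heatsCsv path to the per-injection CSV.
#' @param headerYaml path to the YAML experiment header.
#' @return an [ItcExperiment-class].
#' @export
readItcExperiment <- function(heatsCsv, headerYaml) {
  h <- yaml::read_yaml(headerYaml)
  df <- utils::read.csv(heatsCsv)
  new("ItcExperiment",
      cellConc = h$cell_concentration_M, syringeConc = h$syringe_concentration_M,
      cellVolume = h$cell_volume_L,
      injectionVolumes = df$injection_volume_uL * 1e-6,
      heats = df$heat_ucal,
      temperature = if (!is.null(h$temperature_K)) h$temperature_K else 288.15)
}

#' Write / read SPR sensorgrams as long-format CSV
#'
#' Columns: `concentration_M`, `time_s`, `RU`, `phase`. The association
#' window length is inferred from the phase labels.
#'
#' @param experiment an [SprExperiment-class].
#' @param path CSV path.
#' @return `path` / an [SprExperiment-class].
#' @export
writeSprCsv <- function(experiment, path) {
  df <- experiment@data
  utils::write.csv(data.frame(concentration_M = df$concentration,
                              time_s = df$time, RU = df$response,
                              phase = df$phase),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSprCsv
#' @export
readSprCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tA <- max(df$time_s[df$phase == "association"])
  new("SprExperiment",
      data = data.frame(concentration = df$concentration_M, time = df$time_s,
                        response = df$RU, phase = df$phase),
      associationTime = tA,
      dissociationTime = max(df$time_s) - tA)
}
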