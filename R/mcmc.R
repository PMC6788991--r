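# Metropolis-within-Gibbs orchestration: chain configuration, priors,
# initialization, and multi-chain fitting via the compiled sampler.

#' Chain configuration
#'
#' Defaults are desk-scale; the motivating study ran 3 chains with 20,000
#' adaptive iterations, 440,000 sampling iterations and 40,000 burn-in
#' (and a 6x longer schedule for its smallest, slowest-mixing survey).
#'
#' @param n_chains number of chains.
#' @param adapt_iters adaptive-phase iterations (proposal scales tuned toward
#'   0.44 acceptance, then frozen).
#' @param sample_iters sampling-phase iterations per chain.
#' @param burnin_iters initial sampling iterations discarded.
#' @param thin thinning interval.
#' @param seed integer seed; chain k uses \code{seed + k}.
#' @return list of class \code{ChainConfig}.
#' @export
chainConfig <- function(n_chains = 3, adapt_iters = 2000, sample_iters = 20000,
                        burnin_iters = 5000, thin = 10, seed = 1) {
  stopifnot(n_chains >= 1, adapt_iters >= 0, sample_iters > 0,
            burnin_iters >= 0, burnin_iters < sample_iters, thin >= 1)
  structure(list(n_chains = n_chains, adapt_iters = adapt_iters,
                 sample_iters = sample_iters, burnin_iters = burnin_iters,
                 thin = thin, seed = seed), class = "ChainConfig")
}

#' Prior specification
#'
#' Diffuse defaults: cloglog intercepts and effects Normal(0, sd 10); log
#' sigma Normal(log(mask diameter / 10), sd 2); delta Uniform(0, 0.5); alpha
#' Uniform(0, 1); abundance prior p(N) proportional to 1/N (scale prior) or
#' uniform, truncated at \code{NmaxFactor} times the number of observed
#' histories.
#'
#' @param mask a \linkS4class{HabitatMask} (sets the log-sigma prior centre).
#' @param betaSd,effSd,logSigmaSd Normal prior SDs.
#' @param logSigmaMean optional override of the log-sigma prior mean.
#' @param priorN \code{"scale"} (1/N) or \code{"uniform"}.
#' @param NmaxFactor upper truncation of N as a multiple of M_obs.
#' @return list of class \code{ScrPriors}.
#' @export
scrPriors <- function(mask, betaSd = 10, effSd = 10, logSigmaSd = 2,
                      logSigmaMean = NULL, priorN = c("scale", "uniform"),
                      NmaxFactor = 50) {
  cells <- maskCells(mask)
  diam <- sqrt(diff(range(cells[, 1]))^2 + diff(range(cells[, 2]))^2)
  structure(list(betaSd = betaSd, effSd = effSd, logSigmaSd = logSigmaSd,
                 logSigmaMean = logSigmaMean %||% log(max(diam, 1) / 10),
                 priorN = match.arg(priorN), NmaxFactor = NmaxFactor),
            class = "ScrPriors")
}

scrParamNames <- function(spec, T) {
  c(if (spec@timeMode == "time") paste0("beta", seq_len(T)) else "beta",
    if (spec@timeMode == "Time") "trend",
    if (spec@behav) "c",
    if (spec@placement) "water",
    if (spec@interactCP) "c_x_water",
    "logSigma", "rawDelta", "rawAlpha")
}

# raw sampler vector -> (DetectionParams, FlankParams)
rawToParams <- function(raw, spec, T) {
  pn <- scrParamNames(spec, T)
  v <- stats::setNames(as.numeric(raw), pn)
  beta <- if (spec@timeMode == "time") v[paste0("beta", seq_len(T))]
          else v[["beta"]]
  params <- detectionParams(
    beta = unname(beta), sigma_km = exp(v[["logSigma"]]),
    behav_effect = if (spec@behav) v[["c"]] else 0,
    placement_effect = if (spec@placement) v[["water"]] else 0,
    interact_effect = if (spec@interactCP) v[["c_x_water"]] else 0,
    trend_slope = if (spec@timeMode == "Time") v[["trend"]] else 0)
  flank <- flankParams(0.5 * stats::plogis(v[["rawDelta"]]),
                       stats::plogis(v[["rawAlpha"]]))
  list(params = params, flank = flank)
}

maskToList <- function(mask) {
  inc <- which(mask@include)
  cells <- mask@cells[inc, , drop = FALSE]
  ox <- min(mask@cells[, 1]); oy <- min(mask@cells[, 2])
  mesh <- mask@mesh_km
  nx <- round((max(mask@cells[, 1]) - ox) / mesh) + 1
  ny <- round((max(mask@cells[, 2]) - oy) / mesh) + 1
  grid <- rep(-1L, nx * ny)
  ix <- round((cells[, 1] - ox) / mesh)
  iy <- round((cells[, 2] - oy) / mesh)
  grid[ix + nx * iy + 1] <- seq_len(nrow(cells)) - 1L
  list(cellx = cells[, 1], celly = cells[, 2], mesh = mesh,
       originx = ox, originy = oy, nx = as.integer(nx), ny = as.integer(ny),
       grid = grid)
}

dataToList <- function(data) {
  design <- data@design
  list(codes = data@codes,
       kind = match(data@kind, c("left", "right", "known")) - 1L,
       op = t(design@op),
       trapx = design@stations$x_km, trapy = design@stations$y_km,
       water = as.integer(design@stations$placement == "water"))
}

priorsToList <- function(priors, data, mask) {
  M <- nHistories(data)
  list(betaSd = priors$betaSd, effSd = priors$effSd,
       logSigmaMean = priors$logSigmaMean, logSigmaSd = priors$logSigmaSd,
       priorN = if (priors$priorN == "scale") 0L else 1L,
       Nmax = as.integer(max(priors$NmaxFactor * max(M, 1), 50)))
}

#' Initialize the latent state
#'
#' Parameters are drawn from the priors; the matching starts with every
#' single-flank history unmerged; each history's activity centre starts at the
#' detection-weighted mean trap location, jittered and snapped to the nearest
#' included mask cell.
#'
#' @param data an \linkS4class{EncounterArray}.
#' @param mask a \linkS4class{HabitatMask}.
#' @param spec a \linkS4class{ScrModel}.
#' @param priors a \code{\link{scrPriors}} list.
#' @return list with \code{params} (raw scale), \code{partner},
#'   \code{cellOfHist}, \code{N} as consumed by the sampler.
#' @export
initScrState <- function(data, mask, spec, priors = scrPriors(mask)) {
  Tn <- nOccasions(data@design)
  M <- nHistories(data)
  pn <- scrParamNames(spec, Tn)
  raw <- numeric(length(pn))
  names(raw) <- pn
  for (k in seq_along(pn)) {
    raw[k] <- switch(sub("[0-9]+$", "", pn[k]),
      beta = stats::rnorm(1, 0, priors$betaSd),
      trend = stats::rnorm(1, 0, priors$effSd),
      c = stats::rnorm(1, 0, priors$effSd),
      water = stats::rnorm(1, 0, priors$effSd),
      c_x_water = stats::rnorm(1, 0, priors$effSd),
      logSigma = stats::rnorm(1, priors$logSigmaMean, priors$logSigmaSd),
      rawDelta = stats::qlogis(stats::runif(1)),
      rawAlpha = stats::qlogis(stats::runif(1)))
  }
  cells <- maskCells(mask)
  st <- data@design@stations
  cellOfHist <- integer(M)
  for (m in seq_len(M)) {
    det <- apply(data@codes[m, , , drop = FALSE] > 0, 3, sum)
    w <- det / sum(det)
    x <- sum(w * st$x_km) + stats::rnorm(1, 0, mask@mesh_km / 2)
    y <- sum(w * st$y_km) + stats::rnorm(1, 0, mask@mesh_km / 2)
    cellOfHist[m] <- which.min((cells[, 1] - x)^2 + (cells[, 2] - y)^2) - 1L
  }
  Nmax <- max(priors$NmaxFactor * max(M, 1), 50)
  Nprior <- if (priors$priorN == "scale")
    sample.int(Nmax, 1, prob = 1 / seq_len(Nmax))
  else sample.int(Nmax, 1)
  list(params = unname(raw), partner = rep(-1L, M),
       cellOfHist = cellOfHist, N = as.integer(max(Nprior, M)))
}

specToList <- function(spec) {
  list(timeMode = match(spec@timeMode, c("const", "time", "Time")) - 1L,
       behav = spec@behav, placement = spec@placement,
       interact = spec@interactCP)
}

# derived capture (p) and recapture (c) probabilities at distance zero,
# following the reporting convention: p/c at first/last (second/last for c)
# occasion, plus water/trail versions (equal when no placement term)
deriveRates <- function(draws, spec, T) {
  pn <- scrParamNames(spec, T)
  col <- function(nm) if (nm %in% colnames(draws)) draws[, nm] else 0
  betaAt <- function(t) {
    b <- if (spec@timeMode == "time") draws[, paste0("beta", t)]
         else draws[, "beta"]
    if (spec@timeMode == "Time")
      b <- b + col("trend") * (if (T > 1) (t - 1) / (T - 1) - 0.5 else 0)
    b
  }
  eta <- function(t, b, w)
    betaAt(t) + b * col("c") + w * col("water") + b * w * col("c_x_water")
  cbind(p_first = cloglogInv(eta(1, 0, 0)),
        p_last = cloglogInv(eta(T, 0, 0)),
        c_second = cloglogInv(eta(min(2, T), 1, 0)),
        c_last = cloglogInv(eta(T, 1, 0)),
        p_water = cloglogInv(eta(1, 0, 1)),
        p_trail = cloglogInv(eta(1, 0, 0)),
        c_water = cloglogInv(eta(1, 1, 1)),
        c_trail = cloglogInv(eta(1, 1, 0)))
}

#' Fit the bilateral-flank SCR model by MCMC
#'
#' Runs \code{n_chains} Metropolis-within-Gibbs chains over detection and
#' flank parameters (random-walk blocks; sigma on the log scale, delta and
#' alpha on logit scales), activity centres (random-walk on the mask lattice),
#' the latent left-right identity matching (collapsed merge/split moves with
#' activity centres integrated over the mask and redrawn from their exact cell
#' conditional) and abundance N (exact categorical Gibbs draw). Initial values
#' are drawn from the priors; a chain whose initial log posterior is not
#' finite is re-initialized (up to 100 attempts).
#'
#' @param data an \linkS4class{EncounterArray}.
#' @param mask a \linkS4class{HabitatMask}.
#' @param spec a \linkS4class{ScrModel}.
#' @param config a \code{\link{chainConfig}}.
#' @param priors a \code{\link{scrPriors}} list.
#' @param updates which blocks to update (mainly for validation studies).
#' @param fixed named list of parameters to hold fixed, on the natural scale:
#'   any of \code{beta}, \code{trend}, \code{c}, \code{water},
#'   \code{c_x_water}, \code{sigma_km}, \code{delta}, \code{alpha}.
#' @param init optional initial state (as \code{\link{initScrState}}).
#' @param storeLatent keep per-draw matching encodings (needed for multimodel
#'   inference).
#' @param storeCentresEvery store activity-centre draws every k-th retained
#'   draw (0 disables).
#' @param matchMoves matching proposals per iteration (default: one per
#'   potential pair).
#' @return An \linkS4class{ScrFit}. Monitored columns include \code{D}
#'   (individuals per 100 km^2; exactly \code{N / area * 100} for every draw),
#'   \code{sigma_km}, \code{delta}, \code{alpha}, \code{psi} (share of
#'   observed histories attributed to the current latent individuals),
#'   \code{N}, \code{n}, derived capture/recapture probabilities and the log
#'   posterior density.
#' @export
fitScr <- function(data, mask, spec = scrModel("~1"), config = chainConfig(),
                   priors = scrPriors(mask),
                   updates = c("params", "centres", "matching", "N"),
                   fixed = list(), init = NULL, storeLatent = TRUE,
                   storeCentresEvery = 100, matchMoves = NULL) {
  Tn <- nOccasions(data@design)
  M <- nHistories(data)
  pn <- scrParamNames(spec, Tn)
  if ((spec@placement || spec@interactCP) &&
      !any(data@design@stations$placement == "water"))
    stopf("placement terms require a placement covariate in the design")
  dataL <- dataToList(data)
  maskL <- maskToList(mask)
  specL <- specToList(spec)
  priorsL <- priorsToList(priors, data, mask)
  if (is.null(matchMoves)) {
    nL <- sum(data@kind == "left"); nR <- sum(data@kind == "right")
    matchMoves <- max(1L, min(nL, nR))
  }
  fixedVec <- fixedToRaw(fixed, spec, Tn)
  configL <- list(nAdapt = config$adapt_iters, nSample = config$sample_iters,
                  nBurn = config$burnin_iters, thin = config$thin,
                  updParams = "params" %in% updates,
                  updCentres = "centres" %in% updates,
                  updMatching = "matching" %in% updates,
                  updN = "N" %in% updates,
                  matchMoves = as.integer(matchMoves),
                  storeLatent = storeLatent,
                  storeCentresEvery = as.integer(storeCentresEvery),
                  targetAccept = 0.44,
                  centreScale = 2 * mask@mesh_km,
                  fixedParams = fixedVec$mask)
  area <- areaTotal(mask)
  chains <- vector("list", config$n_chains)
  latent <- vector("list", config$n_chains)
  accepts <- NULL
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch)
    st <- NULL
    for (attempt in seq_len(100)) {
      st <- init %||% initScrState(data, mask, spec, priors)
      st$params[fixedVec$mask] <- fixedVec$values[fixedVec$mask]
      lp <- .scr_logpost(dataL, maskL, specL, priorsL, st)
      if (is.finite(lp$fullLogpost)) break
      if (!is.null(init))
        stopf("supplied initial state has non-finite log posterior")
      if (attempt == 100)
        stopf("no finite initial state found in 100 attempts")
    }
    res <- .scr_chain(dataL, maskL, specL, priorsL, configL, st)
    d <- res$draws
    colnames(d) <- c(pn, "sigma_km", "delta", "alpha", "N", "n", "psi",
                     "logpost")
    d <- cbind(d, D = d[, "N"] / area * 100, deriveRates(d, spec, Tn))
    chains[[ch]] <- d
    latent[[ch]] <- res$latent
    acc <- unlist(res$accept)
    accepts <- rbind(accepts, acc)
    attr(chains[[ch]], "centres") <- res$centres
  }
  new("ScrFit", draws = chains, latent = latent,
      accept = colMeans(accepts, na.rm = TRUE), spec = spec,
      config = unclass(config), area = area,
      meta = list(paramNames = pn, T = Tn, M = M, kind = data@kind,
                  priors = priors, maskList = maskL,
                  historyIds = data@historyIds))
}

fixedToRaw <- function(fixed, spec, T) {
  pn <- scrParamNames(spec, T)
  mask <- rep(FALSE, length(pn))
  values <- rep(NA_real_, length(pn))
  names(mask) <- names(values) <- pn
  setp <- function(nm, v) {
    if (!all(nm %in% pn)) stopf("fixed parameter not in this model: %s",
                                paste(setdiff(nm, pn), collapse = ", "))
    mask[nm] <<- TRUE; values[nm] <<- v
  }
  for (nm in names(fixed)) {
    v <- fixed[[nm]]
    switch(nm,
      sigma_km = setp("logSigma", log(v)),
      delta = setp("rawDelta", stats::qlogis(v / 0.5)),
      alpha = setp("rawAlpha", stats::qlogis(v)),
      beta = if (spec@timeMode == "time")
               setp(paste0("beta", seq_len(T)), v) else setp("beta", v),
      setp(nm, v))
  }
  list(mask = unname(mask), values = unname(values))
}

#' Posterior summary of a fitted model
#'
#' @param fit an \linkS4class{ScrFit}.
#' @param params columns to summarize (default: all monitored).
#' @return data.frame with posterior mean, SD and equal-tailed 95\% credible
#'   interval per parameter; sigma is reported in both km and m.
#' @export
posteriorSummary <- function(fit, params = NULL) {
  d <- do.call(rbind, fit@draws)
  params <- params %||% colnames(d)
  out <- data.frame(parameter = params,
                    mean = colMeans(d[, params, drop = FALSE]),
                    sd = apply(d[, params, drop = FALSE], 2, stats::sd),
                    lower = apply(d[, params, drop = FALSE], 2,
                                  stats::quantile, 0.025),
                    upper = apply(d[, params, drop = FALSE], 2,
                                  stats::quantile, 0.975),
                    row.names = NULL)
  if ("sigma_km" %in% params) {
    s <- out[out$parameter == "sigma_km", -1] * 1000
    s <- cbind(parameter = "sigma_m", s)
    out <- rbind(out, s)
  }
  out
}

#' Evaluate the model's log posterior at a given state
#'
#' Exposes the compiled sampler's posterior evaluation (likelihood with
#' activity centres at their current cells, the semi-complete abundance terms,
#' and parameter priors) for validation against the R-level likelihood
#' functions.
#'
#' @inheritParams fitScr
#' @param state a state list as returned by \code{\link{initScrState}}.
#' @return list with \code{dataLogpost}, \code{fullLogpost}, \code{logp0},
#'   per-individual log-likelihoods and \code{n}.
#' @export
scrLogpost <- function(data, mask, spec, state, priors = scrPriors(mask)) {
  .scr_logpost(dataToList(data), maskToList(mask), specToList(spec),
               priorsToList(priors, data, mask), state)
}
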