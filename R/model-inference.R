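# Model-set fitting, Barker-Link posterior model probabilities (product-space
# Gibbs over the model indicator with moment-matched pseudo-priors), and
# model-averaged posterior summaries.

#' Fit a set of detection models
#'
#' Independent fits per specification, sharing data, mask, priors and seed
#' policy. Placement models require a placement covariate in the design (the
#' motivating study fitted 4 base models everywhere plus 3 placement models
#' where both water and trail stations were deployed).
#'
#' @param data an \linkS4class{EncounterArray}.
#' @param mask a \linkS4class{HabitatMask}.
#' @param specs list of \linkS4class{ScrModel}s or formula strings.
#' @param config a \code{\link{chainConfig}}.
#' @param ... passed to \code{\link{fitScr}}.
#' @return named list of \linkS4class{ScrFit}s (class \code{ModelSetFit}).
#' @export
fitModelSet <- function(data, mask, specs, config = chainConfig(), ...) {
  specs <- lapply(specs, function(s) if (is.character(s)) scrModel(s) else s)
  labels <- vapply(specs, function(s) s@pFormula, "")
  if (anyDuplicated(labels))
    stopf("configuration error: duplicate model specifications")
  if (!length(specs)) stopf("specs must be non-empty")
  fits <- lapply(specs, function(s) fitScr(data, mask, s, config, ...))
  names(fits) <- labels
  class(fits) <- c("ModelSetFit", "list")
  fits
}

#' The study's candidate model set
#'
#' Four base detection models (constant, per-occasion time variation, linear
#' temporal trend, behavioural response) plus, when the design carries a
#' placement covariate, placement, additive behaviour + placement, and
#' interactive behaviour x placement models.
#'
#' @param design a \linkS4class{SurveyDesign}.
#' @return character vector of model formulas.
#' @export
candidateModels <- function(design) {
  base <- c("~1", "~time", "~Time", "~c")
  if (any(design@stations$placement == "water") &&
      any(design@stations$placement == "trail"))
    c(base, "~Placement", "~c+Placement", "~c*Placement")
  else base
}

#' Barker-Link posterior model probabilities (generic engine)
#'
#' Product-space Gibbs sampler over the model indicator. Each model supplies
#' posterior draws of its own parameter vector, an observed-data log
#' likelihood and a log prior; pseudo-priors are independent Normals moment
#' matched to each model's posterior draws (plus an empirical categorical
#' pseudo-prior for an optional discrete latent component). When the current
#' model is k, its parameters are refreshed from its stored posterior draws
#' and all other models' parameters are drawn from their pseudo-priors; the
#' indicator is then redrawn from its full conditional.
#'
#' @param models list; each element a list with \code{draws} (matrix, possibly
#'   0 columns), \code{logLik(theta, latent)}, \code{logPrior(theta, latent)},
#'   and optionally \code{latent} (matrix of integer-coded discrete draws
#'   aligned with \code{draws} rows).
#' @param nIter,burn Gibbs iterations and burn-in per chain.
#' @param nChains number of indicator chains.
#' @param priorModel prior model probabilities (default equal).
#' @param seed RNG seed.
#' @return list with \code{prob} (posterior model probabilities), \code{se}
#'   (Monte-Carlo standard errors from the indicator chains), and
#'   \code{indicator} (list of chains).
#' @export
barkerLinkProbabilities <- function(models, nIter = 11000, burn = 1000,
                                    nChains = 3, priorModel = NULL, seed = 1) {
  K <- length(models)
  if (K == 0) stopf("no models supplied")
  priorModel <- priorModel %||% rep(1 / K, K)
  if (K == 1)
    return(list(prob = 1.0, se = 0.0, indicator = list(rep(1L, nIter - burn))))
  pp <- lapply(models, makePseudo)
  chains <- vector("list", nChains)
  for (ch in seq_len(nChains)) {
    set.seed(seed + ch)
    k <- sample.int(K, 1)
    ind <- integer(nIter)
    for (it in seq_len(nIter)) {
      w <- numeric(K)
      for (m in seq_len(K)) {
        if (m == k) {
          r <- sample.int(max(nrow(models[[m]]$draws), 1), 1)
          theta <- if (ncol(models[[m]]$draws)) models[[m]]$draws[r, ] else numeric(0)
          latent <- if (!is.null(models[[m]]$latent))
            models[[m]]$latent[r, ] else NULL
        } else {
          s <- samplePseudo(pp[[m]])
          theta <- s$theta; latent <- s$latent
        }
        w[m] <- log(priorModel[m]) +
          models[[m]]$logLik(theta, latent) +
          models[[m]]$logPrior(theta, latent) -
          logPseudo(pp[[m]], theta, latent)
      }
      w <- w - max(w)
      k <- sample.int(K, 1, prob = exp(w))
      ind[it] <- k
    }
    chains[[ch]] <- ind[(burn + 1):nIter]
  }
  all <- unlist(chains)
  prob <- vapply(seq_len(K), function(m) mean(all == m), 0)
  se <- vapply(seq_len(K), function(m) {
    per <- vapply(chains, function(x) batchSE(as.numeric(x == m)), 0)
    sqrt(sum(per^2)) / length(chains)
  }, 0)
  list(prob = prob, se = se, indicator = chains)
}

batchSE <- function(x, nBatch = 25) {
  n <- length(x)
  b <- max(2, floor(n / nBatch))
  nb <- floor(n / b)
  means <- vapply(seq_len(nb), function(i) mean(x[((i - 1) * b + 1):(i * b)]), 0)
  stats::sd(means) / sqrt(nb)
}

makePseudo <- function(model) {
  d <- model$draws
  cont <- if (ncol(d)) list(mean = colMeans(d),
                            sd = pmax(apply(d, 2, stats::sd), 1e-8))
          else NULL
  lat <- NULL
  if (!is.null(model$latent)) {
    keys <- apply(model$latent, 1, paste, collapse = ",")
    tab <- table(keys)
    lat <- list(rows = model$latent[match(names(tab), keys), , drop = FALSE],
                prob = as.numeric(tab) / length(keys),
                keys = names(tab))
  }
  list(cont = cont, lat = lat)
}

samplePseudo <- function(pp) {
  theta <- if (!is.null(pp$cont))
    stats::rnorm(length(pp$cont$mean), pp$cont$mean, pp$cont$sd)
  else numeric(0)
  latent <- NULL
  if (!is.null(pp$lat)) {
    i <- sample.int(length(pp$lat$prob), 1, prob = pp$lat$prob)
    latent <- pp$lat$rows[i, ]
  }
  list(theta = theta, latent = latent)
}

logPseudo <- function(pp, theta, latent) {
  lp <- 0
  if (!is.null(pp$cont))
    lp <- lp + sum(stats::dnorm(theta, pp$cont$mean, pp$cont$sd, log = TRUE))
  if (!is.null(pp$lat)) {
    key <- paste(latent, collapse = ",")
    i <- match(key, pp$lat$keys)
    if (is.na(i)) return(-Inf)
    lp <- lp + log(pp$lat$prob[i])
  }
  lp
}

#' Posterior model probabilities for a fitted SCR model set
#'
#' Wraps each \linkS4class{ScrFit} for the Barker-Link engine: the continuous
#' parameters are the sampler's raw-scale coefficients, the discrete latent
#' component is the (matching, N) pair, and the observed-data log likelihood
#' is the semi-complete likelihood with activity centres integrated over the
#' mask. The study ran this Gibbs sampler for 3 chains of 110,000 iterations
#' with 10,000 burn-in; defaults here are a desk-scale fraction of that
#' schedule.
#'
#' @param fits a \code{ModelSetFit} (see \code{\link{fitModelSet}}); each fit
#'   must have been run with \code{storeLatent = TRUE}.
#' @param data,mask the shared data and mask used for the fits.
#' @param nIter,burn,nChains,seed Gibbs schedule.
#' @return named probabilities (an attribute \code{"se"} carries Monte-Carlo
#'   SEs); sums to 1.
#' @export
multimodelProbabilities <- function(fits, data, mask, nIter = 3000,
                                    burn = 300, nChains = 3, seed = 1) {
  models <- lapply(fits, function(fit) scrBlModel(fit, data, mask))
  res <- barkerLinkProbabilities(models, nIter = nIter, burn = burn,
                                 nChains = nChains, seed = seed)
  prob <- stats::setNames(res$prob, names(fits))
  attr(prob, "se") <- stats::setNames(res$se, names(fits))
  prob
}

# build a Barker-Link model wrapper from an ScrFit
scrBlModel <- function(fit, data, mask) {
  spec <- fit@spec
  Tn <- fit@meta$T
  pn <- fit@meta$paramNames
  np <- length(pn)
  draws <- do.call(rbind, lapply(fit@draws, function(d) d[, pn, drop = FALSE]))
  lat <- do.call(rbind, lapply(seq_along(fit@latent), function(i) {
    cbind(fit@latent[[i]], fit@draws[[i]][, "N"])
  }))
  storage.mode(lat) <- "integer"
  if (!nrow(lat) || ncol(lat) != nHistories(data) + 1)
    stopf("multimodel inference needs fits run with storeLatent = TRUE")
  priors <- fit@meta$priors
  design <- data@design
  dataL <- dataToList(data)
  maskL <- maskToList(mask)
  specL <- specToList(spec)
  priorsL <- priorsToList(priors, data, mask)
  logLik <- function(theta, latent) {
    partner <- as.integer(latent[seq_len(length(latent) - 1)])
    N <- as.integer(latent[length(latent)])
    .scr_semicomplete(dataL, maskL, specL, priorsL, as.numeric(theta),
                      partner, N)
  }
  logPrior <- function(theta, latent) {
    v <- stats::setNames(theta, pn)
    lp <- sum(stats::dnorm(v[grep("^beta", pn)], 0, priors$betaSd, log = TRUE))
    for (nm in intersect(c("trend", "c", "water", "c_x_water"), pn))
      lp <- lp + stats::dnorm(v[[nm]], 0, priors$effSd, log = TRUE)
    lp <- lp + stats::dnorm(v[["logSigma"]], priors$logSigmaMean,
                            priors$logSigmaSd, log = TRUE)
    for (nm in c("rawDelta", "rawAlpha")) {
      s <- stats::plogis(v[[nm]])
      lp <- lp + log(s) + log1p(-s)
    }
    N <- latent[length(latent)]
    if (priors$priorN == "scale") lp <- lp - log(N)
    lp
  }
  list(draws = draws, latent = lat, logLik = logLik, logPrior = logPrior)
}

# combine observed histories into latent-individual histories given the
# matching encoding (0-based right-partner index per left history, -1 if none)
assembleLatentHistories <- function(histList, kind, partner) {
  M <- length(histList)
  isPartnerR <- rep(FALSE, M)
  take <- kind == "left" & partner >= 0
  isPartnerR[partner[take] + 1] <- TRUE
  out <- list()
  for (m in seq_len(M)) {
    if (isPartnerR[m]) next
    out[[length(out) + 1]] <-
      if (take[m]) mergeHistories(histList[[m]], histList[[partner[m] + 1]])
      else histList[[m]]
  }
  out
}

#' Model-averaged posterior summaries
#'
#' Mixture-weighted resampling of the raw posterior draws in proportion to the
#' posterior model probabilities, summarized as means, SDs and equal-tailed
#' 95\% credible intervals over the monitored parameters shared by all
#' weighted models.
#'
#' @param fits a \code{ModelSetFit}.
#' @param probs posterior model probabilities (normalized).
#' @param nDraws size of the pooled mixture sample.
#' @param seed RNG seed for the resampling.
#' @return data.frame with \code{parameter}, \code{mean}, \code{sd},
#'   \code{lower}, \code{upper}.
#' @export
modelAverage <- function(fits, probs, nDraws = 10000, seed = 1) {
  stopifnot(length(fits) == length(probs))
  if (abs(sum(probs) - 1) > 1e-9) stopf("model probabilities must sum to 1")
  set.seed(seed)
  cols <- Reduce(intersect, lapply(fits, function(f) colnames(f@draws[[1]])))
  cols <- setdiff(cols, c("logpost", "n"))
  counts <- as.vector(stats::rmultinom(1, nDraws, probs))
  pooled <- NULL
  for (m in seq_along(fits)) {
    if (counts[m] == 0) next
    d <- do.call(rbind, fits[[m]]@draws)[, cols, drop = FALSE]
    pooled <- rbind(pooled, d[sample.int(nrow(d), counts[m], replace = TRUE), ,
                              drop = FALSE])
  }
  out <- data.frame(parameter = cols,
                    mean = colMeans(pooled),
                    sd = apply(pooled, 2, stats::sd),
                    lower = apply(pooled, 2, stats::quantile, 0.025),
                    upper = apply(pooled, 2, stats::quantile, 0.975),
                    row.names = NULL)
  if ("sigma_km" %in% cols) {
    s <- out[out$parameter == "sigma_km", -1] * 1000
    out <- rbind(out, cbind(parameter = "sigma_m", s))
  }
  out
}

#' Sex-specific fits
#'
#' Fits the per-area best model separately to the male and female subsets of
#' the observed histories (histories of unknown sex are dropped) and reports
#' whether the 95\% credible intervals overlap for the detection-related
#' parameters. A sex with no histories is skipped with a warning.
#'
#' @param data an \linkS4class{EncounterArray} with per-history sex labels.
#' @param mask a \linkS4class{HabitatMask}.
#' @param best_spec the per-area best \linkS4class{ScrModel} (or formula).
#' @param config a \code{\link{chainConfig}}.
#' @param ... passed to \code{\link{fitScr}}.
#' @return list with \code{male}, \code{female} (\linkS4class{ScrFit} or
#'   NULL) and \code{overlap} (data.frame of interval overlap per parameter).
#' @export
fitBySex <- function(data, mask, best_spec, config = chainConfig(), ...) {
  if (is.character(best_spec)) best_spec <- scrModel(best_spec)
  fits <- list(male = NULL, female = NULL)
  for (sx in c("M", "F")) {
    idx <- which(data@sex == sx)
    nm <- if (sx == "M") "male" else "female"
    if (!length(idx)) {
      warning(sprintf("no histories with sex %s: fit skipped", sx),
              call. = FALSE)
      next
    }
    fits[[nm]] <- fitScr(subsetHistories(data, idx), mask, best_spec, config,
                         ...)
  }
  overlap <- NULL
  if (!is.null(fits$male) && !is.null(fits$female)) {
    pars <- c("sigma_km", "delta", "p_first", "p_last", "c_second", "c_last")
    sm <- posteriorSummary(fits$male, pars)
    sf <- posteriorSummary(fits$female, pars)
    overlap <- data.frame(parameter = sm$parameter,
                          male_lower = sm$lower, male_upper = sm$upper,
                          female_lower = sf$lower, female_upper = sf$upper,
                          overlap = sm$lower <= sf$upper & sf$lower <= sm$upper)
  }
  list(male = fits$male, female = fits$female, overlap = overlap)
}

#' Subset an encounter array by history index
#'
#' @param data an \linkS4class{EncounterArray}.
#' @param idx history indices to keep.
#' @return An \linkS4class{EncounterArray}.
#' @export
subsetHistories <- function(data, idx) {
  encounterArray(data@codes[idx, , , drop = FALSE], data@kind[idx],
                 data@design, sex = data@sex[idx],
                 historyIds = data@historyIds[idx])
}
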