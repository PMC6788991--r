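# Synthetic camera-trap survey generator emulating single-camera bilateral
# photo-identification surveys; doubles as the parameter-recovery engine.

#' Simulation configuration
#'
#' Defaults are the package's reference survey conditions for validation: a
#' density of 6 individuals/100 km^2 moving with half-normal scale 1.5 km over
#' an 8 x 8 single-camera grid at 1.25-km spacing sampled for 11 five-day
#' occasions, single-flank probability delta = 0.4, simultaneity probability
#' alpha = 0.8, and half the population bilaterally known a priori.
#'
#' @param D_true density, individuals per 100 km^2 (ignored when
#'   \code{N_true} given).
#' @param N_true optional fixed abundance.
#' @param sigma_km half-normal movement/detection scale, km.
#' @param beta cloglog detection intercept.
#' @param delta,alpha flank-observation parameters.
#' @param behav_effect,placement_effect,trend_slope optional detection effects.
#' @param trap_rows,trap_cols,spacing_km camera grid geometry.
#' @param water_fraction fraction of stations placed at water (rest on trails).
#' @param T number of occasions; \code{occasion_days} their length.
#' @param known_both_fraction probability an individual's identity is
#'   bilaterally known a priori.
#' @param buffer_km,mesh_km habitat-mask geometry (buffer defaults to 3 sigma).
#' @param sigma_male_km optional male-specific sigma (sex effect studies).
#' @param occasion_days occasion length in days.
#' @return a list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(D_true = 6, N_true = NULL, sigma_km = 1.5,
                             beta = -2, delta = 0.4, alpha = 0.8,
                             behav_effect = 0, placement_effect = 0,
                             trend_slope = 0,
                             trap_rows = 8, trap_cols = 8, spacing_km = 1.25,
                             water_fraction = 0, T = 11, occasion_days = 5,
                             known_both_fraction = 0.5,
                             buffer_km = 3 * sigma_km, mesh_km = 1,
                             sigma_male_km = NULL) {
  stopifnot(is.null(N_true) || N_true >= 0, sigma_km > 0, spacing_km > 0,
            delta >= 0, delta <= 0.5, alpha >= 0, alpha <= 1,
            known_both_fraction >= 0, known_both_fraction <= 1,
            water_fraction >= 0, water_fraction <= 1)
  if (is.null(N_true) && D_true <= 0) stopf("D_true must be > 0")
  structure(as.list(environment()), class = "SimulationConfig")
}

#' Trap grid and occasion calendar from a simulation configuration
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param start survey start date-time.
#' @return A \linkS4class{SurveyDesign} with a rows x cols grid; a
#'   \code{water_fraction} share of stations (chosen at random) is placed at
#'   water, the rest on trails.
#' @export
simulateDesign <- function(config, start = as.POSIXct("2016-06-01 00:00:00",
                                                      tz = "UTC")) {
  g <- expand.grid(r = seq_len(config$trap_rows) - 1,
                   c = seq_len(config$trap_cols) - 1)
  J <- nrow(g)
  placement <- rep("trail", J)
  nw <- round(config$water_fraction * J)
  if (nw > 0) placement[sample.int(J, nw)] <- "water"
  stations <- data.frame(id = sprintf("S%03d", seq_len(J)),
                         x_km = g$c * config$spacing_km,
                         y_km = g$r * config$spacing_km,
                         placement = placement)
  dayS <- 86400
  st <- start + (seq_len(config$T) - 1) * config$occasion_days * dayS
  occasions <- data.frame(start = st,
                          end = st + config$occasion_days * dayS - 1)
  surveyDesign(stations, occasions)
}

#' Simulate the latent population
#'
#' Abundance is Poisson with mean \code{D_true * area / 100} (or fixed at
#' \code{N_true}); activity centres fall uniformly over included mask cells
#' (uniform within the chosen cell); identities are bilaterally known with
#' probability \code{known_both_fraction}; sex is M/F with probability 0.5.
#'
#' @param mask a \linkS4class{HabitatMask}.
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{centres} (N x 2), \code{known}, \code{sex},
#'   \code{N}.
#' @export
simulatePopulation <- function(mask, config) {
  area <- areaTotal(mask)
  N <- if (!is.null(config$N_true)) as.integer(config$N_true)
       else stats::rpois(1, config$D_true * area / 100)
  cells <- maskCells(mask)
  if (N == 0)
    return(list(centres = matrix(0, 0, 2), known = logical(0),
                sex = character(0), N = 0L))
  pick <- sample.int(nrow(cells), N, replace = TRUE)
  jit <- matrix(stats::runif(2 * N, -mask@mesh_km / 2, mask@mesh_km / 2), N, 2)
  list(centres = cells[pick, , drop = FALSE] + jit,
       known = stats::runif(N) < config$known_both_fraction,
       sex = sample(c("M", "F"), N, replace = TRUE),
       N = N)
}

#' Simulate true (complete) detection histories
#'
#' Bernoulli detection per (individual, occasion, trap) with the half-normal
#' cloglog model, updating the trap-specific behavioural state as detections
#' accrue (permanent after first capture at the trap).
#'
#' @param centres N x 2 activity centres (km).
#' @param design a \linkS4class{SurveyDesign}.
#' @param params \code{\link{detectionParams}}.
#' @param spec \linkS4class{ScrModel} (defaults to the generating structure
#'   implied by nonzero effects in \code{params}).
#' @param sigma_by_ind optional per-individual sigma overrides (km).
#' @return integer 0/1 array N x occasions x traps.
#' @export
simulateTrueHistories <- function(centres, design, params,
                                  spec = NULL, sigma_by_ind = NULL) {
  if (is.null(spec)) spec <- impliedSpec(params)
  N <- nrow(centres); Tn <- nOccasions(design); J <- nStations(design)
  out <- array(0L, dim = c(N, Tn, J))
  op <- t(design@op)
  for (i in seq_len(N)) {
    pars <- params
    if (!is.null(sigma_by_ind)) pars$sigma_km <- sigma_by_ind[i]
    d <- sqrt((design@stations$x_km - centres[i, 1])^2 +
              (design@stations$y_km - centres[i, 2])^2)
    seen <- rep(FALSE, J)
    for (t in seq_len(Tn)) {
      p <- vapply(seq_len(J), function(j)
        detectionProb(d[j], t, j, seen[j], pars, spec, design), 0)
      det <- stats::runif(J) < p & op[t, ]
      out[i, t, ] <- as.integer(det)
      seen <- seen | det
    }
  }
  out
}

impliedSpec <- function(params) {
  terms <- c(if (params$behav_effect != 0) "c",
             if (params$trend_slope != 0) "Time",
             if (params$placement_effect != 0) "Placement")
  f <- if (length(terms)) paste0("~", paste(terms, collapse = "+")) else "~1"
  m <- scrModel(f)
  if (params$interact_effect != 0) m <- scrModel("~c*Placement")
  m
}

#' Realize flank observations from true histories
#'
#' Each true detection becomes a code 1/2/3/4 by the conditional encounter-type
#' multinomial. Individuals that are not bilaterally known have their left and
#' right codes split into separate observed single-flank histories; an
#' individual with any simultaneous both-flank (code 4) event becomes known,
#' as does any individual flagged known a priori.
#'
#' @param trueHist 0/1 array from \code{\link{simulateTrueHistories}}.
#' @param flank \code{\link{flankParams}}.
#' @param known logical per individual: identity known a priori.
#' @param design a \linkS4class{SurveyDesign}.
#' @param sex optional per-individual sex labels.
#' @return list: \code{data} (\linkS4class{EncounterArray}), \code{trueCodes}
#'   (coded true histories), \code{truthMap} (true individual index per
#'   observed history), \code{knownFinal}.
#' @export
simulateFlankObservation <- function(trueHist, flank, known, design,
                                     sex = NULL) {
  N <- dim(trueHist)[1]; Tn <- dim(trueHist)[2]; J <- dim(trueHist)[3]
  if (is.null(sex)) sex <- rep("U", N)
  pr <- encounterTypeProbs(1, flank)[2:5]
  codes <- trueHist
  ndet <- sum(trueHist)
  if (ndet > 0)
    codes[trueHist == 1L] <- sample(1:4, ndet, replace = TRUE, prob = pr)
  knownFinal <- known | apply(codes == 4L, 1, any)
  hist <- list(); kind <- character(0); hsex <- character(0)
  map <- integer(0); ids <- character(0)
  for (i in seq_len(N)) {
    ci <- array(codes[i, , ], dim = c(Tn, J))
    if (all(ci == 0L)) next
    if (knownFinal[i]) {
      hist[[length(hist) + 1]] <- ci
      kind <- c(kind, "known"); map <- c(map, i); hsex <- c(hsex, sex[i])
      ids <- c(ids, sprintf("L%03d|R%03d", i, i))
    } else {
      lf <- matrix(as.integer(ci %in% c(1L, 3L)), Tn, J)
      rt <- matrix(2L * as.integer(ci %in% c(2L, 3L)), Tn, J)
      if (any(lf > 0)) {
        hist[[length(hist) + 1]] <- lf
        kind <- c(kind, "left"); map <- c(map, i); hsex <- c(hsex, sex[i])
        ids <- c(ids, sprintf("L%03d", i))
      }
      if (any(rt > 0)) {
        hist[[length(hist) + 1]] <- rt
        kind <- c(kind, "right"); map <- c(map, i); hsex <- c(hsex, sex[i])
        ids <- c(ids, sprintf("R%03d", i))
      }
    }
  }
  M <- length(hist)
  arr <- array(0L, dim = c(M, Tn, J))
  for (m in seq_len(M)) arr[m, , ] <- hist[[m]]
  list(data = encounterArray(arr, kind, design, sex = hsex, historyIds = ids),
       trueCodes = codes, truthMap = map, knownFinal = knownFinal)
}

#' Simulate a complete survey
#'
#' Convenience wrapper: design, mask, population, true histories and flank
#' observation in one call.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param seed optional RNG seed.
#' @return list with \code{data}, \code{design}, \code{mask}, \code{truth}
#'   (centres, N, true codes, truth map, known flags, sex), \code{config}.
#' @export
simulateSurvey <- function(config = simulationConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  design <- simulateDesign(config)
  mask <- buildMask(design, config$buffer_km, config$mesh_km)
  pop <- simulatePopulation(mask, config)
  params <- detectionParams(beta = config$beta, sigma_km = config$sigma_km,
                            behav_effect = config$behav_effect,
                            placement_effect = config$placement_effect,
                            trend_slope = config$trend_slope)
  sigInd <- if (!is.null(config$sigma_male_km))
    ifelse(pop$sex == "M", config$sigma_male_km, config$sigma_km) else NULL
  th <- simulateTrueHistories(pop$centres, design, params,
                              sigma_by_ind = sigInd)
  flank <- flankParams(config$delta, config$alpha)
  obs <- simulateFlankObservation(th, flank, pop$known, design, pop$sex)
  list(data = obs$data, design = design, mask = mask,
       truth = list(N = pop$N, centres = pop$centres, trueDet = th,
                    trueCodes = obs$trueCodes, truthMap = obs$truthMap,
                    known = obs$knownFinal, sex = pop$sex),
       config = config)
}
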