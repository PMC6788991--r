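#' @import methods
NULL

#' Camera-trap survey design
#'
#' Stations with planar kilometre coordinates, a placement covariate
#' (\code{"water"} or \code{"trail"}), per-occasion operation flags, and the
#' ordered occasion windows (five-day intervals in the motivating surveys).
#'
#' @slot stations data.frame with columns \code{id}, \code{x_km}, \code{y_km},
#'   \code{placement}.
#' @slot op logical matrix, stations x occasions; \code{TRUE} where the camera
#'   was operational.
#' @slot occasions data.frame with \code{POSIXct} columns \code{start},
#'   \code{end}; non-overlapping and chronologically ordered.
#'
#' @export
setClass("SurveyDesign",
  representation(stations = "data.frame", op = "matrix", occasions = "data.frame"))

setValidity("SurveyDesign", function(object) {
  st <- object@stations
  need <- c("id", "x_km", "y_km", "placement")
  if (!all(need %in% names(st)))
    return(paste("stations must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(st$id)) return("duplicate station ids")
  if (!all(is.finite(st$x_km)) || !all(is.finite(st$y_km)))
    return("station coordinates must be finite")
  if (!all(st$placement %in% c("water", "trail")))
    return("placement must be 'water' or 'trail'")
  occ <- object@occasions
  if (!all(c("start", "end") %in% names(occ))) return("occasions need start/end")
  if (nrow(occ) > 0) {
    if (any(occ$end <= occ$start)) return("occasion end must exceed start")
    if (nrow(occ) > 1 && any(occ$start[-1] < occ$end[-nrow(occ)]))
      return("occasions must be non-overlapping and ordered")
  }
  if (nrow(object@op) != nrow(st) || ncol(object@op) != nrow(occ))
    return("op must be stations x occasions")
  TRUE
})

#' Construct a SurveyDesign
#'
#' @param stations data.frame with \code{id}, \code{x_km}, \code{y_km},
#'   \code{placement} (\code{"water"}/\code{"trail"}).
#' @param occasions data.frame with \code{POSIXct} \code{start}, \code{end}.
#' @param op optional logical matrix stations x occasions; defaults to all
#'   operational.
#' @return A \linkS4class{SurveyDesign}.
#' @export
surveyDesign <- function(stations, occasions, op = NULL) {
  stations$id <- as.character(stations$id)
  if (is.null(op)) op <- matrix(TRUE, nrow(stations), nrow(occasions))
  op <- matrix(as.logical(op), nrow(stations), nrow(occasions))
  new("SurveyDesign", stations = stations, op = op, occasions = occasions)
}

#' @describeIn surveyDesign number of stations
#' @param design a SurveyDesign
#' @export
nStations <- function(design) nrow(design@stations)

#' @describeIn surveyDesign number of occasions
#' @export
nOccasions <- function(design) nrow(design@occasions)

setMethod("show", "SurveyDesign", function(object) {
  cat(sprintf("SurveyDesign: %d stations (%d water), %d occasions\n",
              nStations(object), sum(object@stations$placement == "water"),
              nOccasions(object)))
})

#' Discretized habitat mask
#'
#' Regular lattice of candidate activity-centre cells with an inclusion flag;
#' activity centres are integrated over included cells (midpoint rule, uniform
#' prior). Cell area is \code{mesh_km^2} (1 km^2 by default).
#'
#' @slot cells numeric matrix (n cells x 2) of centre coordinates in km.
#' @slot include logical inclusion flag per cell.
#' @slot mesh_km lattice spacing in km.
#'
#' @export
setClass("HabitatMask",
  representation(cells = "matrix", include = "logical", mesh_km = "numeric"))

setValidity("HabitatMask", function(object) {
  if (ncol(object@cells) != 2) return("cells must have two columns")
  if (length(object@include) != nrow(object@cells))
    return("include flag per cell required")
  if (!any(object@include)) return("all cells excluded: empty habitat mask")
  if (object@mesh_km <= 0) return("mesh_km must be positive")
  for (k in 1:2) {
    u <- sort(unique(object@cells[, k]))
    if (length(u) > 1) {
      r <- (diff(u) / object@mesh_km)
      if (any(abs(r - round(r)) > 1e-6))
        return("cell centres do not lie on a regular lattice")
    }
  }
  TRUE
})

#' Total habitat area of a mask
#'
#' @param mask a \linkS4class{HabitatMask}
#' @return area in km^2 (cell area times number of included cells)
#' @export
areaTotal <- function(mask) sum(mask@include) * mask@mesh_km^2

#' Included cell centres of a mask
#' @param mask a \linkS4class{HabitatMask}
#' @return numeric matrix of included (x, y) centres in km
#' @export
maskCells <- function(mask) mask@cells[mask@include, , drop = FALSE]

setMethod("show", "HabitatMask", function(object) {
  cat(sprintf("HabitatMask: %d/%d cells included, mesh %.3g km, area %.1f km^2\n",
              sum(object@include), length(object@include), object@mesh_km,
              areaTotal(object)))
})

#' Flank-coded observed encounter histories
#'
#' Histories x occasions x traps array with encounter codes 0 (absence),
#' 1 (left flank), 2 (right flank), 3 (both flanks, non-simultaneous) and
#' 4 (both flanks, simultaneous). Histories are labelled left-only, right-only
#' or known-both; the single-camera "sometimes" data type allows simultaneous
#' both-flank events that resolve identity.
#'
#' @slot codes integer array, histories x occasions x traps.
#' @slot kind character per history: \code{"left"}, \code{"right"},
#'   \code{"known"}.
#' @slot known logical per history (bilaterally known identity).
#' @slot sex character per history: \code{"M"}, \code{"F"} or \code{"U"}.
#' @slot dataType fixed token \code{"sometimes"}.
#' @slot design the \linkS4class{SurveyDesign} the histories refer to.
#' @slot historyIds character labels (flank-specific ids or known pair label).
#'
#' @export
setClass("EncounterArray",
  representation(codes = "array", kind = "character", known = "logical",
                 sex = "character", dataType = "character",
                 design = "SurveyDesign", historyIds = "character"))

setValidity("EncounterArray", function(object) {
  cd <- object@codes
  if (length(dim(cd)) != 3) return("codes must be a 3-D array")
  M <- dim(cd)[1]
  if (dim(cd)[2] != nOccasions(object@design) ||
      dim(cd)[3] != nStations(object@design))
    return("codes dimensions must match the design")
  if (length(object@kind) != M || length(object@known) != M ||
      length(object@sex) != M)
    return("per-history annotations must have one entry per history")
  if (M > 0) {
    if (!all(cd %in% 0:4)) return("codes must be in 0..4")
    if (!all(object@kind %in% c("left", "right", "known")))
      return("kind must be left/right/known")
    if (any((object@kind == "known") != object@known))
      return("known flag must agree with kind == 'known'")
    for (m in seq_len(M)) {
      v <- cd[m, , ]
      if (object@kind[m] == "left" && !all(v %in% c(0L, 1L)))
        return("left-only histories may contain only codes {0,1}")
      if (object@kind[m] == "right" && !all(v %in% c(0L, 2L)))
        return("right-only histories may contain only codes {0,2}")
      if (all(v == 0L)) return("each history needs at least one detection")
    }
  }
  if (!identical(object@dataType, "sometimes"))
    return("dataType must be 'sometimes'")
  TRUE
})

#' @describeIn encounterArray number of observed histories (M_obs)
#' @export
nHistories <- function(x) dim(x@codes)[1]

#' @describeIn encounterArray per-history kind labels
#' @export
historyKind <- function(x) x@kind

#' @describeIn encounterArray per-history known-identity flags
#' @export
knownFlag <- function(x) x@known

#' Construct an EncounterArray
#'
#' @param codes integer array histories x occasions x traps with values 0..4.
#' @param kind character vector: \code{"left"}, \code{"right"}, \code{"known"}.
#' @param design a \linkS4class{SurveyDesign}.
#' @param sex optional per-history sex labels (default \code{"U"}).
#' @param historyIds optional labels.
#' @param x an EncounterArray (accessors).
#' @return An \linkS4class{EncounterArray}.
#' @export
encounterArray <- function(codes, kind, design, sex = NULL, historyIds = NULL) {
  M <- dim(codes)[1]
  storage.mode(codes) <- "integer"
  new("EncounterArray", codes = codes, kind = kind, known = kind == "known",
      sex = sex %||% rep("U", M), dataType = "sometimes", design = design,
      historyIds = historyIds %||% paste0("h", seq_len(M)))
}

setMethod("show", "EncounterArray", function(object) {
  k <- table(factor(object@kind, levels = c("left", "right", "known")))
  cat(sprintf(paste0("EncounterArray ('sometimes'): %d histories ",
                     "(%d left-only, %d right-only, %d known-both), ",
                     "%d occasions x %d traps, %d detections\n"),
              nHistories(object), k[["left"]], k[["right"]], k[["known"]],
              dim(object@codes)[2], dim(object@codes)[3],
              sum(object@codes > 0)))
})

#' Detection-model specification
#'
#' Linear-model shorthand for the cloglog detection probability: additive
#' combinations of \code{1} (intercept only), \code{time} (one intercept per
#' occasion), \code{Time} (linear trend on the standardized occasion index),
#' \code{c} (trap-specific behavioural response to first capture) and
#' \code{Placement} (water vs trail); \code{c*Placement} adds the interaction.
#' The flank model is always \code{delta ~ 1} with \code{delta1 = delta2}.
#'
#' @slot pFormula character, e.g. \code{"~c+Placement"}.
#' @slot timeMode \code{"const"}, \code{"time"} or \code{"Time"}.
#' @slot behav logical, behavioural response term.
#' @slot placement logical, placement term.
#' @slot interactCP logical, behaviour x placement interaction.
#'
#' @export
setClass("ScrModel",
  representation(pFormula = "character", timeMode = "character",
                 behav = "logical", placement = "logical",
                 interactCP = "logical"))

#' Parse a detection-model formula
#'
#' @param pFormula one of \code{"~1"}, \code{"~time"}, \code{"~Time"},
#'   \code{"~c"}, \code{"~Placement"}, or additive/interaction combinations
#'   such as \code{"~c+Placement"}, \code{"~c*Placement"}, \code{"~c+Time"}.
#' @return A \linkS4class{ScrModel}.
#' @export
scrModel <- function(pFormula = "~1") {
  s <- gsub("[~ ]", "", pFormula)
  terms <- unlist(strsplit(s, "+", fixed = TRUE))
  timeMode <- "const"; behav <- FALSE; placement <- FALSE; inter <- FALSE
  for (tm in terms) {
    if (tm == "1" || tm == "") next
    else if (tm == "time") timeMode <- "time"
    else if (tm == "Time") timeMode <- "Time"
    else if (tm == "c") behav <- TRUE
    else if (tm == "Placement") placement <- TRUE
    else if (tm %in% c("c*Placement", "c:Placement")) {
      behav <- TRUE; placement <- TRUE; inter <- TRUE
    } else stopf("unknown detection-model term '%s'", tm)
  }
  new("ScrModel", pFormula = pFormula, timeMode = timeMode, behav = behav,
      placement = placement, interactCP = inter)
}

setMethod("show", "ScrModel", function(object) {
  cat(sprintf("ScrModel: p(%s) delta(~1)\n", object@pFormula))
})

#' Detection parameters of the half-normal cloglog model
#'
#' The linear predictor is
#' \code{eta = beta(t) + behav_effect*prevCapture + placement_effect*water +
#' interact_effect*prevCapture*water + trend_slope*tTilde - d^2/(2 sigma_km^2)}
#' and \code{p = 1 - exp(-exp(eta))}.
#'
#' @param beta cloglog intercept(s); length 1, or one per occasion for
#'   \code{~time}.
#' @param sigma_km spatial scale (km) of the half-normal detection function.
#' @param behav_effect additive effect of previous capture at the trap.
#' @param placement_effect additive effect of water placement.
#' @param interact_effect behaviour x placement interaction effect.
#' @param trend_slope slope on the standardized occasion index in [-0.5, 0.5].
#' @return A list of class \code{DetectionParams}.
#' @export
detectionParams <- function(beta, sigma_km, behav_effect = 0,
                            placement_effect = 0, interact_effect = 0,
                            trend_slope = 0) {
  if (!all(is.finite(c(beta, sigma_km, behav_effect, placement_effect,
                       interact_effect, trend_slope))))
    stopf("detection parameters must be finite")
  if (sigma_km <= 0) stopf("sigma_km must be > 0")
  structure(list(beta = beta, sigma_km = sigma_km,
                 behav_effect = behav_effect,
                 placement_effect = placement_effect,
                 interact_effect = interact_effect,
                 trend_slope = trend_slope),
            class = "DetectionParams")
}

#' Flank-observation parameters
#'
#' Given a detection, the encounter type is multinomial: a single left or
#' right flank each with probability \code{delta} (constrained
#' \code{delta1 = delta2 = delta <= 0.5}), a simultaneous both-flank photo with
#' probability \code{alpha*(1-2*delta)} and a non-simultaneous both-flank
#' encounter with probability \code{(1-alpha)*(1-2*delta)}.
#'
#' @param delta conditional single-flank probability, in [0, 0.5].
#' @param alpha conditional simultaneity probability, in [0, 1].
#' @return A list of class \code{FlankParams}.
#' @export
flankParams <- function(delta, alpha) {
  if (delta < 0 || delta > 0.5) stopf("delta must lie in [0, 0.5]")
  if (alpha < 0 || alpha > 1) stopf("alpha must lie in [0, 1]")
  structure(list(delta = delta, alpha = alpha), class = "FlankParams")
}

#' Fitted SCR model (MCMC output)
#'
#' @slot draws list of per-chain numeric matrices (retained draws x monitored
#'   columns; includes \code{D}, \code{N}, \code{sigma_km}, \code{delta},
#'   \code{alpha}, \code{psi}, \code{n}, \code{logpost} and the raw
#'   detection-model coefficients).
#' @slot latent list of per-chain latent draws (matching encoding and N) used
#'   by multimodel inference.
#' @slot accept named acceptance rates per update block.
#' @slot spec the \linkS4class{ScrModel} fitted.
#' @slot config chain configuration used.
#' @slot area habitat-mask area (km^2).
#' @slot meta misc metadata (seeds, parameter names, occasion count).
#'
#' @export
setClass("ScrFit",
  representation(draws = "list", latent = "list", accept = "numeric",
                 spec = "ScrModel", config = "list", area = "numeric",
                 meta = "list"))

setMethod("show", "ScrFit", function(object) {
  d <- do.call(rbind, object@draws)
  cat(sprintf("ScrFit p(%s): %d chains x %d retained draws\n",
              object@spec@pFormula, length(object@draws), nrow(object@draws[[1]])))
  cat(sprintf("  D = %.2f (SD %.2f) per 100 km^2 | sigma = %.2f km | area %.0f km^2\n",
              mean(d[, "D"]), stats::sd(d[, "D"]), mean(d[, "sigma_km"]),
              object@area))
})

#' Chain convergence report
#'
#' @slot psrf univariate potential scale reduction factors per parameter.
#' @slot mpsrf multivariate potential scale reduction factor.
#' @slot ess effective sample sizes per parameter (initial monotone positive
#'   sequence estimator, summed over chains).
#' @slot pass logical under the configured thresholds.
#' @slot flags character notes (zero-variance parameters etc.).
#'
#' @export
setClass("ConvergenceReport",
  representation(psrf = "numeric", mpsrf = "numeric", ess = "numeric",
                 pass = "logical", flags = "character"))

setMethod("show", "ConvergenceReport", function(object) {
  cat(sprintf("ConvergenceReport: mpsrf = %.4f, min ESS = %.0f -> %s\n",
              object@mpsrf, if (length(object@ess)) min(object@ess) else NA,
              if (object@pass) "PASS" else "NOT CONVERGED"))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})
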