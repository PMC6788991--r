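# Detection model, flank-observation multinomial, per-history likelihoods over
# the habitat mask, and the semi-complete-data likelihood in N.
#
# The cloglog/half-normal composition factorizes as a hazard product:
#   p = 1 - exp(-h),  h = exp(eta0) * exp(-d^2 / (2 sigma^2))
# with eta0 the distance-free linear predictor. Non-detection cells therefore
# contribute -sum(h) on the log scale, which the cell-wise engine exploits.

tTilde <- function(t, T) if (T > 1) (t - 1) / (T - 1) - 0.5 else 0

# distance-free linear predictor; b = previous-capture indicator (0/1),
# water = placement indicator (0/1)
etaBase <- function(t, b, water, params, spec, T) {
  beta <- if (spec@timeMode == "time") {
    if (length(params$beta) != T)
      stopf("~time model needs one beta per occasion (%d), got %d",
            T, length(params$beta))
    params$beta[t]
  } else params$beta[1]
  eta <- beta
  if (spec@timeMode == "Time") eta <- eta + params$trend_slope * tTilde(t, T)
  if (spec@behav) eta <- eta + params$behav_effect * b
  if (spec@placement) eta <- eta + params$placement_effect * water
  if (spec@interactCP) eta <- eta + params$interact_effect * b * water
  eta
}

#' Half-normal cloglog detection probability
#'
#' \code{p = 1 - exp(-exp(eta))} with
#' \code{eta = beta(t) + behav_effect*prev + placement_effect*water +
#' interact_effect*prev*water + trend_slope*tTilde - d^2/(2 sigma_km^2)}.
#' Strictly decreasing in distance; at \code{eta = log(log(2))} and distance 0
#' the detection probability is exactly 0.5.
#'
#' @param distance_km distance(s) from activity centre to trap, km (>= 0).
#' @param t occasion index (1-based).
#' @param trap station index into \code{design}, or \code{NULL} when no
#'   placement term is in the model.
#' @param prev_capture logical: previous capture at this trap (behavioural
#'   state).
#' @param params a \code{\link{detectionParams}} list.
#' @param spec a \linkS4class{ScrModel}.
#' @param design a \linkS4class{SurveyDesign}; required for placement or
#'   occasion-structured terms.
#' @return detection probabilities in (0, 1), same length as
#'   \code{distance_km}.
#' @export
detectionProb <- function(distance_km, t = 1L, trap = NULL,
                          prev_capture = FALSE, params = NULL,
                          spec = scrModel("~1"), design = NULL) {
  if (any(distance_km < 0)) stopf("distance_km must be >= 0")
  if (params$sigma_km <= 0) stopf("sigma_km must be > 0")
  Tn <- if (!is.null(design)) nOccasions(design)
        else max(t, length(params$beta))
  water <- 0
  if (spec@placement || spec@interactCP) {
    if (is.null(design) || is.null(trap))
      stopf("placement terms need a design and a trap index")
    water <- as.integer(design@stations$placement[trap] == "water")
  }
  eta <- etaBase(t, as.integer(prev_capture), water, params, spec, Tn) -
    distance_km^2 / (2 * params$sigma_km^2)
  cloglogInv(eta)
}

#' Encounter-type probabilities
#'
#' Probability vector over codes {0,1,2,3,4}: absence \code{1-p}; conditional
#' on detection, single left or right flank each with probability
#' \code{delta}, non-simultaneous both-flank \code{(1-alpha)*(1-2*delta)} and
#' simultaneous both-flank \code{alpha*(1-2*delta)}.
#'
#' @param p detection probability.
#' @param flank a \code{\link{flankParams}} list.
#' @return numeric vector of length 5 summing to 1.
#' @export
encounterTypeProbs <- function(p, flank) {
  if (flank$delta > 0.5 || flank$delta < 0) stopf("delta must lie in [0, 0.5]")
  if (p < 0 || p > 1) stopf("p must be a probability")
  both <- 1 - 2 * flank$delta
  c(1 - p,
    p * flank$delta,
    p * flank$delta,
    p * (1 - flank$alpha) * both,
    p * flank$alpha * both)
}

# log multinomial factor of a nonzero code, excluding the detection part
logCodeFactor <- function(code, flank) {
  switch(code,
         log(flank$delta),                              # 1
         log(flank$delta),                              # 2
         log1p(-flank$alpha) + log(1 - 2 * flank$delta),# 3
         log(flank$alpha) + log(1 - 2 * flank$delta))   # 4
}

# behaviour-state matrix for a history: prev[t, j] is TRUE when the history has
# a detection at trap j at an occasion strictly before t (trap-specific,
# permanent response)
prevCaptureMatrix <- function(history) {
  Tn <- nrow(history); J <- ncol(history)
  prev <- matrix(FALSE, Tn, J)
  if (Tn > 1) {
    seen <- history[1, ] > 0
    for (t in 2:Tn) {
      prev[t, ] <- seen
      seen <- seen | history[t, ] > 0
    }
  }
  prev
}

# hazard tables H[t, j] = exp(eta0) for behaviour states 0 and 1
hazardTables <- function(params, spec, design) {
  Tn <- nOccasions(design); J <- nStations(design)
  water <- as.integer(design@stations$placement == "water")
  H0 <- matrix(0, Tn, J); H1 <- matrix(0, Tn, J)
  for (t in seq_len(Tn)) {
    H0[t, ] <- exp(vapply(seq_len(J), function(j)
      etaBase(t, 0L, water[j], params, spec, Tn), 0))
    H1[t, ] <- exp(vapply(seq_len(J), function(j)
      etaBase(t, 1L, water[j], params, spec, Tn), 0))
  }
  list(H0 = H0, H1 = H1)
}

# half-normal distance kernel, cells x traps
gMatrix <- function(cells, design, sigma_km) {
  dx <- outer(cells[, 1], design@stations$x_km, "-")
  dy <- outer(cells[, 2], design@stations$y_km, "-")
  exp(-(dx^2 + dy^2) / (2 * sigma_km^2))
}

# log-likelihood of one history evaluated at every cell (rows of `cells`)
historyCellLoglik <- function(history, params, flank, spec, design, cells) {
  Tn <- nOccasions(design); J <- nStations(design)
  op <- t(design@op)  # occasions x traps
  if (any(history[!op] > 0))
    stopf("data error: encounter code at a non-operational trap-occasion")
  H <- hazardTables(params, spec, design)
  prev <- prevCaptureMatrix(history)
  Hb <- ifelse(prev, H$H1, H$H0)
  A <- colSums(Hb * (op & history == 0))
  G <- gMatrix(cells, design, params$sigma_km)
  ll <- -as.vector(G %*% A)
  idx <- which(history > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    t <- idx[k, 1]; j <- idx[k, 2]
    h <- Hb[t, j] * G[, j]
    ll <- ll + logCodeFactor(history[t, j], flank) + log1mexpNeg(h)
  }
  ll
}

#' Log-likelihood of a history at a fixed activity centre
#'
#' Sums, over operational trap-occasions, the log multinomial mass of the
#' observed encounter code given the detection probability at the centre-trap
#' distance; non-operational trap-occasions contribute nothing. The same code
#' mass rule applies to all history kinds because the mapping from true to
#' observed histories is deterministic given the latent identity matching: a
#' left-only history's observed 1 is a true code 1 (mass \code{p*delta}) and
#' its 0 a true non-detection.
#'
#' @param history integer matrix occasions x traps with codes 0..4.
#' @param centre numeric length-2 centre coordinates (km).
#' @param params \code{\link{detectionParams}}.
#' @param flank \code{\link{flankParams}}.
#' @param spec \linkS4class{ScrModel}.
#' @param design \linkS4class{SurveyDesign}.
#' @return log-probability of the history.
#' @export
historyLoglikAtCentre <- function(history, centre, params, flank, spec, design) {
  historyCellLoglik(history, params, flank, spec, design,
                    matrix(centre, 1, 2))[1]
}

#' Marginal log-likelihood of a history over the habitat mask
#'
#' Midpoint-rule integration of the activity centre with a uniform prior over
#' included mask cells: the log of the cell-average of
#' \code{exp(historyLoglikAtCentre)}.
#'
#' @inheritParams historyLoglikAtCentre
#' @param mask a \linkS4class{HabitatMask}.
#' @return log-probability.
#' @export
marginalHistoryLoglik <- function(history, params, flank, spec, mask, design) {
  logMeanExp(historyCellLoglik(history, params, flank, spec, design,
                               maskCells(mask)))
}

#' Probability that an individual is never detected
#'
#' Mask-cell average, over activity centres, of the product over operational
#' trap-occasions of the non-detection probability in the no-previous-capture
#' behavioural state.
#'
#' @inheritParams marginalHistoryLoglik
#' @return probability \code{p0} in [0, 1].
#' @export
probNeverDetected <- function(params, flank, spec, mask, design) {
  H <- hazardTables(params, spec, design)
  op <- t(design@op)
  A0 <- colSums(H$H0 * op)
  G <- gMatrix(maskCells(mask), design, params$sigma_km)
  mean(exp(-as.vector(G %*% A0)))
}

#' Semi-complete-data log-likelihood
#'
#' \code{log N!/(N-n)! + (N-n) log p0 + sum_i marginalHistoryLoglik(history_i)}
#' for abundance \code{N} and \code{n} latent (matched) individuals whose true
#' histories are given; the activity centres of the \code{N - n} undetected
#' individuals are integrated out through \code{p0}.
#'
#' @param N abundance (integer, \code{N >= n}).
#' @param histories list of occasions x traps code matrices, one per latent
#'   individual.
#' @inheritParams marginalHistoryLoglik
#' @return log-likelihood.
#' @export
semiCompleteLoglik <- function(N, histories, params, flank, spec, mask, design) {
  n <- length(histories)
  if (N < n) stopf("domain error: N (%d) < n (%d)", N, n)
  p0 <- probNeverDetected(params, flank, spec, mask, design)
  ll <- lgamma(N + 1) - lgamma(N - n + 1) + (N - n) * log(p0)
  for (h in histories)
    ll <- ll + marginalHistoryLoglik(h, params, flank, spec, mask, design)
  ll
}

#' Merge a left-only and a right-only history into one latent individual
#'
#' Cells seen on both flanks in the same interval become code 3
#' (non-simultaneous both-flank encounter); under the "sometimes" data type a
#' true simultaneous (code 4) event would have resolved the identity, so no
#' merged cell can be a 4 and every (left-only, right-only) pair is
#' structurally feasible.
#'
#' @param left occasions x traps matrix with codes in {0, 1}.
#' @param right occasions x traps matrix with codes in {0, 2}.
#' @return combined code matrix.
#' @export
mergeHistories <- function(left, right) {
  if (!all(left %in% c(0L, 1L)) || !all(right %in% c(0L, 2L)))
    stopf("mergeHistories expects a left-only and a right-only history")
  left + right
}

#' Feasibility of left-right history merges
#'
#' Conflict matrix between left-only and right-only observed histories: entry
#' (l, r) is \code{TRUE} when the two histories may belong to one latent
#' individual. Under the single-camera "sometimes" data type every pair is
#' feasible (a shared cell implies a non-simultaneous code 3, and a
#' simultaneous event would already have resolved the identity), so the matrix
#' is all-\code{TRUE}; the function exists as the extension point for
#' deployment types with stricter observation rules.
#'
#' @param data an \linkS4class{EncounterArray}.
#' @return logical matrix, left-only histories x right-only histories, with
#'   dimnames from the history ids.
#' @export
mergeFeasibility <- function(data) {
  l <- which(data@kind == "left"); r <- which(data@kind == "right")
  matrix(TRUE, length(l), length(r),
         dimnames = list(data@historyIds[l], data@historyIds[r]))
}
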