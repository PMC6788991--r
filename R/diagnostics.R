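# Convergence assessment: Gelman-Rubin-Brooks potential scale reduction
# (univariate and multivariate, from within/between chain covariances) and
# autocorrelation-based effective sample sizes (Geyer's initial monotone
# positive sequence estimator). Rank normalization is deliberately not
# applied, matching the coda-era workflow.

#' Potential scale reduction factors
#'
#' Univariate Gelman-Rubin R-hat per parameter and the Brooks-Gelman
#' multivariate factor from the within- and between-chain covariance matrices:
#' \code{Rhat^2 = 1 + (1 + 1/m) * (B/n) / W} per parameter and
#' \code{mpsrf^2 = 1 + (1 + 1/m) * lambda_1(W^{-1} B/n)} jointly. The pooled
#' variance is not shrunk by \code{(n-1)/n}, so chains that are exact copies
#' report exactly 1 and the factor is never below 1. Parameters with zero
#' within-chain variance are flagged and excluded from the multivariate
#' statistic.
#'
#' @param chains list of draw matrices (equal dimensions, >= 2 chains) or an
#'   \linkS4class{ScrFit}.
#' @param params optional column subset.
#' @return list with \code{psrf} (named vector), \code{mpsrf} and
#'   \code{flagged} (zero-variance parameter names).
#' @export
psrf <- function(chains, params = NULL) {
  chains <- chainMatrices(chains, params)
  m <- length(chains)
  if (m < 2) stopf("psrf needs at least 2 chains")
  n <- nrow(chains[[1]])
  if (n < 10) stopf("psrf needs chains of length >= 10")
  wvar <- sapply(colnames(chains[[1]]), function(p)
    min(vapply(chains, function(x) stats::var(x[, p]), 0)))
  flagged <- names(wvar)[wvar <= .Machine$double.eps]
  use <- setdiff(colnames(chains[[1]]), flagged)
  sub <- lapply(chains, function(x) x[, use, drop = FALSE])
  W <- Reduce(`+`, lapply(sub, stats::cov)) / m
  means <- do.call(rbind, lapply(sub, colMeans))
  Bn <- stats::cov(means)   # B/n: covariance of chain means
  fac <- 1 + 1 / m
  psrfv <- sqrt(1 + fac * diag(Bn) / diag(W))
  names(psrfv) <- use
  mp <- if (length(use) > 1) {
    lam <- try({
      max(Re(eigen(solve(W, Bn), only.values = TRUE)$values))
    }, silent = TRUE)
    if (inherits(lam, "try-error") || !is.finite(lam)) {
      flagged <- c(flagged, "mpsrf: singular within-chain covariance")
      max(psrfv)
    } else sqrt(1 + fac * max(lam, 0))
  } else unname(psrfv[1])
  list(psrf = psrfv, mpsrf = mp, flagged = flagged)
}

#' Effective sample size
#'
#' Geyer's initial monotone positive sequence estimator of the integrated
#' autocorrelation time; the ESS of multiple chains is the sum of per-chain
#' estimates, capped at the total number of retained draws. A constant chain
#' reports 0 with a flag.
#'
#' @param x numeric vector, a draws matrix, a list of draw matrices, or an
#'   \linkS4class{ScrFit}.
#' @param params optional column subset.
#' @return named vector of effective sample sizes (attribute \code{"flagged"}
#'   lists constant parameters).
#' @export
effectiveSampleSize <- function(x, params = NULL) {
  if (is.numeric(x) && is.null(dim(x))) x <- list(matrix(x, ncol = 1,
                                                  dimnames = list(NULL, "x")))
  chains <- chainMatrices(x, params)
  cols <- colnames(chains[[1]])
  flagged <- character(0)
  ess <- vapply(cols, function(p) {
    per <- vapply(chains, function(m) geyerESS(m[, p]), 0)
    sum(per)
  }, 0)
  total <- sum(vapply(chains, nrow, 0L))
  const <- vapply(cols, function(p)
    all(vapply(chains, function(m) stats::var(m[, p]) <= .Machine$double.eps,
               TRUE)), TRUE)
  ess[const] <- 0
  flagged <- cols[const]
  ess <- pmin(ess, total)
  attr(ess, "flagged") <- flagged
  ess
}

geyerESS <- function(v) {
  n <- length(v)
  if (n < 10 || stats::var(v) <= .Machine$double.eps) return(0)
  lagMax <- min(n - 2, 10 * ceiling(sqrt(n)))
  rho <- as.vector(stats::acf(v, lag.max = lagMax, plot = FALSE,
                              demean = TRUE)$acf)
  nPairs <- floor((length(rho)) / 2)
  gam <- rho[2 * seq_len(nPairs) - 1] + rho[2 * seq_len(nPairs)]
  pos <- which(gam <= 0)
  if (length(pos)) gam <- gam[seq_len(pos[1] - 1)]
  if (length(gam) > 1) gam <- cummin(gam)  # initial monotone sequence
  tau <- max(2 * sum(gam) - 1, .Machine$double.eps)
  n / tau
}

chainMatrices <- function(x, params = NULL) {
  if (is(x, "ScrFit")) x <- x@draws
  if (is.matrix(x)) x <- list(x)
  x <- lapply(x, function(m) {
    m <- as.matrix(m)
    if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
    m
  })
  if (!is.null(params)) x <- lapply(x, function(m) m[, params, drop = FALSE])
  x
}

#' Convergence report for a fitted model
#'
#' @param fit an \linkS4class{ScrFit} or a list of draw matrices.
#' @param params parameters assessed (default: density, abundance, detection
#'   and flank parameters; derived rate columns are excluded).
#' @param mpsrf_threshold,ess_threshold pass criteria (defaults: multivariate
#'   PSRF near 1, i.e. <= 1.1, and every ESS >= 4000).
#' @return A \linkS4class{ConvergenceReport}. With a single chain the PSRF is
#'   unavailable (reported as NA with a flag) and only the ESS criterion is
#'   applied.
#' @export
convergenceDiagnostics <- function(fit, params = NULL,
                                   mpsrf_threshold = 1.1,
                                   ess_threshold = 4000) {
  chains <- chainMatrices(fit)
  if (is.null(params)) {
    default <- c("D", "sigma_km", "delta", "alpha", "psi", "logpost")
    params <- intersect(default, colnames(chains[[1]]))
    if (!length(params)) params <- colnames(chains[[1]])
  }
  chains <- lapply(chains, function(m) m[, params, drop = FALSE])
  ess <- effectiveSampleSize(chains)
  flags <- character(0)
  constant <- attr(ess, "flagged")
  if (length(constant))
    flags <- c(flags, paste("constant:", paste(constant, collapse = ",")))
  # constant monitored quantities (e.g. psi when every identity is known) are
  # flagged but do not fail the ESS criterion
  essUse <- ess[setdiff(names(ess), constant)]
  essOk <- length(essUse) > 0 && min(essUse) >= ess_threshold
  if (length(chains) >= 2) {
    ps <- psrf(chains)
    if (length(ps$flagged))
      flags <- c(flags, paste("zero-variance:", paste(ps$flagged,
                                                      collapse = ",")))
    pass <- is.finite(ps$mpsrf) && ps$mpsrf <= mpsrf_threshold && essOk
    new("ConvergenceReport", psrf = ps$psrf, mpsrf = ps$mpsrf, ess = ess,
        pass = pass, flags = flags)
  } else {
    warning("single chain: PSRF unavailable, assessing ESS only",
            call. = FALSE)
    new("ConvergenceReport", psrf = stats::setNames(numeric(0), character(0)),
        mpsrf = NA_real_, ess = ess, pass = essOk,
        flags = c(flags, "single chain: psrf unavailable"))
  }
}
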