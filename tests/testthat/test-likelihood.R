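# detection model, flank multinomial, per-history likelihoods, semi-complete
# likelihood; oracles are independent step-by-step arithmetic

test_that("detectionProb follows the cloglog half-normal contract", {
  p <- toyParams(beta = log(log(2)), sigma = 1.5)
  expect_equal(detectionProb(0, params = p), 0.5)
  expect_lt(detectionProb(50 * 1.5, params = p), 1e-12)

  # independent arithmetic for beta = -2, sigma = 1.5, d = 1.5
  pr <- detectionProb(1.5, params = toyParams(beta = -2, sigma = 1.5))
  eta <- -2 - 1.5^2 / (2 * 1.5^2)
  expect_equal(pr, 1 - exp(-exp(eta)), tolerance = 1e-12)

  expect_error(detectionParams(0, -1), "sigma")
  expect_error(detectionProb(-1, params = p), "distance")

  # monotone decreasing in distance, increasing in additive effects
  d <- seq(0, 6, by = 0.25)
  expect_true(all(diff(detectionProb(d, params = p)) < 0))
  design <- toyDesign(placement = c("water", "trail", "trail", "trail"))
  spec <- scrModel("~c+Placement")
  base <- detectionProb(1, t = 1, trap = 2, prev_capture = FALSE,
                        toyParams(behav_effect = 0.7, placement_effect = 0.4),
                        spec, design)
  withC <- detectionProb(1, t = 1, trap = 2, prev_capture = TRUE,
                         toyParams(behav_effect = 0.7, placement_effect = 0.4),
                         spec, design)
  atWater <- detectionProb(1, t = 1, trap = 1, prev_capture = FALSE,
                           toyParams(behav_effect = 0.7,
                                     placement_effect = 0.4), spec, design)
  expect_gt(withC, base)
  expect_gt(atWater, base)
})

test_that("encounterTypeProbs is the stated multinomial", {
  # boundary: delta = 0.5 leaves no both-flank mass
  v <- encounterTypeProbs(0.3, flankParams(0.5, 0.2))
  expect_equal(v[4], 0); expect_equal(v[5], 0)

  # the published flank posterior means for the smallest survey imply a 0.10
  # both-flank conditional mass split 0.079 simultaneous / 0.021 sequential
  v2 <- encounterTypeProbs(1, flankParams(0.45, 0.79))
  expect_equal(unname(v2[4]), 0.021, tolerance = 1e-12)
  expect_equal(unname(v2[5]), 0.079, tolerance = 1e-12)

  expect_equal(encounterTypeProbs(0, toyFlank()), c(1, 0, 0, 0, 0))
  expect_error(encounterTypeProbs(0.5, flankParams(0.6, 0.5)))

  # sums to one across the (p, delta, alpha) cube
  set.seed(1)
  for (i in 1:200) {
    v <- encounterTypeProbs(runif(1), flankParams(runif(1, 0, 0.5), runif(1)))
    expect_equal(sum(v), 1, tolerance = 1e-12)
  }
})

test_that("historyLoglikAtCentre matches exhaustive cell-by-cell arithmetic", {
  design <- toyDesign(nx = 2, ny = 1, spacing = 2, T = 2)
  spec <- scrModel("~c")
  params <- toyParams(beta = -0.8, sigma = 1.2, behav_effect = 0.9)
  flank <- toyFlank(0.35, 0.7)
  hist <- matrix(0L, 2, 2)
  hist[1, 1] <- 4L; hist[2, 1] <- 1L; hist[2, 2] <- 3L
  centre <- c(0.4, -0.3)

  # independent oracle: compose encounterTypeProbs(detectionProb()) per cell,
  # tracking the trap-specific behavioural state by hand
  dist <- sqrt((design@stations$x_km - centre[1])^2 +
               (design@stations$y_km - centre[2])^2)
  seen <- c(FALSE, FALSE)
  ll <- 0
  for (t in 1:2) {
    for (j in 1:2) {
      p <- detectionProb(dist[j], t, j, seen[j], params, spec, design)
      ll <- ll + log(encounterTypeProbs(p, flank)[hist[t, j] + 1])
    }
    seen <- seen | hist[t, ] > 0
  }
  expect_equal(historyLoglikAtCentre(hist, centre, params, flank, spec,
                                     design), ll, tolerance = 1e-12)

  # all-zero history far from every trap is certain non-detection
  far <- matrix(0L, 2, 2); far[1, 1] <- 1L
  h0 <- matrix(0L, 2, 2)
  expect_error(historyLoglikAtCentre(h0, c(60, 60), params, flank, spec,
                                     design), NA)
  allzero <- historyLoglikAtCentre(h0, c(60, 60), params, flank, spec, design)
  expect_equal(allzero, 0, tolerance = 1e-10)

  # a single simultaneous both-flank detection composes p * alpha * (1-2delta)
  h4 <- matrix(0L, 2, 2); h4[1, 1] <- 4L
  spec1 <- scrModel("~1")
  p11 <- detectionProb(dist[1], 1, 1, FALSE, params, spec1, design)
  pm <- sapply(1:2, function(t) vapply(1:2, function(j)
    detectionProb(dist[j], t, j, FALSE, params, spec1, design), 0))
  manual <- log(p11 * flank$alpha * (1 - 2 * flank$delta)) +
    sum(log(1 - pm)) - log(1 - p11)
  expect_equal(historyLoglikAtCentre(h4, centre, params, flank, spec1, design),
               manual, tolerance = 1e-12)

  # codes at non-operational trap-occasions are a data error
  opOff <- toyDesign(nx = 2, ny = 1, spacing = 2, T = 2,
                     op = matrix(c(FALSE, TRUE, TRUE, TRUE), 2, 2))
  expect_error(historyLoglikAtCentre(h4, centre, params, flank, spec1, opOff),
               "non-operational")
})

test_that("marginal likelihood is the mask-cell average", {
  design <- toyDesign(nx = 2, ny = 1, spacing = 2, T = 2)
  params <- toyParams(); flank <- toyFlank(); spec <- scrModel("~1")
  hist <- matrix(0L, 2, 2); hist[1, 1] <- 1L

  mask1 <- readMask(writeMask(
    new("HabitatMask", cells = cbind(0.3, 0.1), include = TRUE, mesh_km = 1),
    tempfile(fileext = ".csv")))
  expect_equal(marginalHistoryLoglik(hist, params, flank, spec, mask1, design),
               historyLoglikAtCentre(hist, c(0.3, 0.1), params, flank, spec,
                                     design))

  # five scattered lattice cells: equals the log of the explicit average
  cells <- cbind(c(-1, 0, 1, 2, 3), c(0.5, -0.5, 0, 1, -1))
  mask5 <- new("HabitatMask", cells = cells, include = rep(TRUE, 5),
               mesh_km = 0.5)
  percell <- vapply(1:5, function(s)
    historyLoglikAtCentre(hist, cells[s, ], params, flank, spec, design), 0)
  expect_equal(marginalHistoryLoglik(hist, params, flank, spec, mask5, design),
               log(mean(exp(percell))), tolerance = 1e-12)

  # symmetric two-cell mask around a symmetric layout: equals either cell
  histsym <- matrix(0L, 2, 2); histsym[1, 1] <- 1L; histsym[1, 2] <- 1L
  masksym <- new("HabitatMask", cells = cbind(c(0, 2), c(0, 0)),
                 include = c(TRUE, TRUE), mesh_km = 2)
  expect_equal(marginalHistoryLoglik(histsym, params, flank, spec, masksym,
                                     design),
               historyLoglikAtCentre(histsym, c(0, 0), params, flank, spec,
                                     design), tolerance = 1e-12)
})

test_that("probNeverDetected integrates non-detection over the mask", {
  design <- toyDesign(nx = 2, ny = 1, spacing = 2, T = 2)
  params <- toyParams(); flank <- toyFlank(); spec <- scrModel("~1")
  mask <- toyMask(design, buffer = 2)

  # brute force product-average over cells
  cells <- maskCells(mask)
  direct <- mean(vapply(seq_len(nrow(cells)), function(s) {
    d <- sqrt((design@stations$x_km - cells[s, 1])^2 +
              (design@stations$y_km - cells[s, 2])^2)
    prod(vapply(1:2, function(t)
      prod(1 - detectionProb(d, t, params = params, spec = spec,
                             design = design)), 0))
  }, 0))
  expect_equal(probNeverDetected(params, flank, spec, mask, design), direct,
               tolerance = 1e-12)

  # no operational trap-occasions -> certain non-detection
  offDesign <- toyDesign(nx = 2, ny = 1, spacing = 2, T = 2,
                         op = matrix(FALSE, 4, 2)[1:2, , drop = FALSE])
  expect_equal(probNeverDetected(params, flank, spec, mask, offDesign), 1)

  # vanishing hazard -> 1
  expect_equal(probNeverDetected(toyParams(beta = -40), flank, spec, mask,
                                 design), 1, tolerance = 1e-12)
})

test_that("semiCompleteLoglik assembles its terms", {
  design <- toyDesign(nx = 2, ny = 1, spacing = 2, T = 2)
  params <- toyParams(); flank <- toyFlank(); spec <- scrModel("~1")
  mask <- toyMask(design, buffer = 2)
  p0 <- probNeverDetected(params, flank, spec, mask, design)

  # n = 0: N * log p0
  expect_equal(semiCompleteLoglik(3, list(), params, flank, spec, mask,
                                  design), 3 * log(p0))

  h1 <- matrix(0L, 2, 2); h1[1, 1] <- 1L
  h2 <- matrix(0L, 2, 2); h2[2, 2] <- 2L
  m1 <- marginalHistoryLoglik(h1, params, flank, spec, mask, design)
  m2 <- marginalHistoryLoglik(h2, params, flank, spec, mask, design)

  # N = n = 1 reduces to the single marginal
  expect_equal(semiCompleteLoglik(1, list(h1), params, flank, spec, mask,
                                  design), m1)

  # n = 2, N = 3: term-by-term hand assembly
  expect_equal(semiCompleteLoglik(3, list(h1, h2), params, flank, spec, mask,
                                  design),
               log(6) + log(p0) + m1 + m2, tolerance = 1e-12)

  expect_error(semiCompleteLoglik(1, list(h1, h2), params, flank, spec, mask,
                                  design), "N")
})

test_that("every left-right merge is feasible under the 'sometimes' type", {
  design <- toyDesign()
  arr <- toyArray(design, list(c(1, 1, 1, 1), c(2, 1, 1, 2), c(3, 2, 2, 2)),
                  kind = c("left", "right", "right"))
  fm <- mergeFeasibility(arr)
  expect_equal(dim(fm), c(1, 2))
  expect_true(all(fm))
  # merging a shared-cell pair yields a non-simultaneous both-flank code
  merged <- mergeHistories(matrix(arr@codes[1, , ], 2, 4),
                           matrix(arr@codes[2, , ], 2, 4))
  expect_equal(merged[1, 1], 3L)
  expect_error(mergeHistories(matrix(arr@codes[2, , ], 2, 4),
                              matrix(arr@codes[1, , ], 2, 4)),
               "left-only")
})

test_that("compiled and R-level posteriors agree on random states", {
  set.seed(99)
  sim <- simulateSurvey(simulationConfig(N_true = 10, trap_rows = 3,
                                         trap_cols = 3, T = 4, buffer_km = 2,
                                         water_fraction = 0.3,
                                         behav_effect = 0.8,
                                         placement_effect = 0.5), seed = 99)
  for (f in c("~1", "~c", "~Time", "~c+Placement", "~c*Placement", "~time")) {
    spec <- scrModel(f)
    st <- initScrState(sim$data, sim$mask, spec)
    # merge one left-right pair when possible to exercise matched histories
    lefts <- which(sim$data@kind == "left"); rights <- which(sim$data@kind == "right")
    if (length(lefts) && length(rights))
      st$partner[lefts[1]] <- rights[1] - 1L
    lp <- scrLogpost(sim$data, sim$mask, spec, st)
    pf <- flankSCR:::rawToParams(st$params, spec, 4)
    histList <- lapply(seq_len(nHistories(sim$data)), function(m)
      matrix(sim$data@codes[m, , ], 4, 9))
    merged <- flankSCR:::assembleLatentHistories(histList, sim$data@kind,
                                                 st$partner)
    scl <- semiCompleteLoglik(st$N, merged, pf$params, pf$flank, spec,
                              sim$mask, sim$design)
    # the compiled state evaluates centres at their cells; marginalize by hand
    n <- length(merged)
    p0 <- probNeverDetected(pf$params, pf$flank, spec, sim$mask, sim$design)
    expect_equal(lp$logp0, log(p0), tolerance = 1e-10)
    expect_equal(lp$n, n)
    cells <- maskCells(sim$mask)
    # owner history index per latent individual, in assembly order
    M <- nHistories(sim$data)
    own <- list(); used <- rep(FALSE, M)
    for (m in seq_len(M)) {
      if (used[m]) next
      if (sim$data@kind[m] == "left" && st$partner[m] >= 0)
        used[st$partner[m] + 1] <- TRUE
      own[[length(own) + 1]] <- m
      used[m] <- TRUE
    }
    llR <- vapply(seq_len(n), function(i) {
      cc <- cells[st$cellOfHist[own[[i]][1]] + 1, ]
      historyLoglikAtCentre(merged[[i]], cc, pf$params, pf$flank, spec,
                            sim$design)
    }, 0)
    expect_equal(as.numeric(lp$llInd), llR, tolerance = 1e-9)
  }
})
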