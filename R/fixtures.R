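# Writing simulated surveys out as the file set a field survey would produce:
# photo-record, station, occasion, mask and known-pair CSVs plus a truth JSON.

# photo records implied by the simulated true codes; each encounter event
# yields one photo (two for non-simultaneous both-flank events, separated by
# more than the independence window), plus occasional same-flank duplicates
# within the window so the 0.5-h rule has work to do
recordsFromSurvey <- function(sim, dup_prob = 0.3) {
  tr <- sim$truth$trueCodes
  design <- sim$design
  occ <- design@occasions
  N <- dim(tr)[1]
  rows <- list()
  addRow <- function(time, j, side, li, ri, sex) {
    rows[[length(rows) + 1]] <<- data.frame(
      station = design@stations$id[j],
      datetime = format(time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      side = side, left_id = li, right_id = ri,
      age = "independent", sex = sex, mother_id = NA_character_)
  }
  for (i in seq_len(N)) {
    li <- sprintf("L%03d", i); ri <- sprintf("R%03d", i)
    sex <- sim$truth$sex[i]
    idx <- which(array(tr[i, , ], dim = dim(tr)[2:3]) > 0, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      t <- idx[k, 1]; j <- idx[k, 2]
      code <- tr[i, t, j]
      span <- as.numeric(occ$end[t]) - as.numeric(occ$start[t]) - 5 * 3600
      base <- occ$start[t] + stats::runif(1, 0, span)
      emit <- function(time, side) {
        l <- if (side %in% c("left", "both")) li else NA_character_
        r <- if (side %in% c("right", "both")) ri else NA_character_
        addRow(time, j, side, l, r, sex)
        if (stats::runif(1) < dup_prob)
          addRow(time + stats::runif(1, 60, 1500), j, side, l, r, sex)
      }
      if (code == 1L) emit(base, "left")
      else if (code == 2L) emit(base, "right")
      else if (code == 4L) emit(base, "both")
      else { # non-simultaneous both-flank: two photos > 0.5 h apart
        emit(base, "left")
        emit(base + 3600 * stats::runif(1, 0.7, 3), "right")
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(station = character(0), datetime = character(0),
                      side = character(0), left_id = character(0),
                      right_id = character(0), age = character(0),
                      sex = character(0), mother_id = character(0))
    return(out)
  }
  out <- do.call(rbind, rows)
  out[order(out$datetime), , drop = FALSE]
}

# attach leopard families: cubs are photographed at a subset of their mother's
# detection events (same station, one minute later)
addFamilies <- function(records, nFamilies, nCubs, p_with = 0.55) {
  mothers <- unique(records$right_id[records$sex == "F" &
                                     !is.na(records$right_id)])
  nFamilies <- min(nFamilies, length(mothers))
  if (nFamilies == 0) return(records)
  mothers <- mothers[seq_len(nFamilies)]
  cubCounts <- rep(1L, nFamilies)
  extra <- nCubs - nFamilies
  if (extra > 0) cubCounts[seq_len(min(extra, nFamilies))] <- 2L
  rows <- list()
  for (f in seq_len(nFamilies)) {
    mrec <- records[!is.na(records$right_id) & records$right_id == mothers[f], ]
    for (cb in seq_len(cubCounts[f])) {
      cid <- sprintf("%sC%d", mothers[f], cb)
      with_mom <- which(stats::runif(nrow(mrec)) < p_with)
      if (!length(with_mom)) with_mom <- 1L
      for (r in with_mom) {
        tm <- as.POSIXct(mrec$datetime[r], tz = "UTC",
                         format = "%Y-%m-%dT%H:%M:%S") + 60
        rows[[length(rows) + 1]] <- data.frame(
          station = mrec$station[r],
          datetime = format(tm, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
          side = "right", left_id = NA_character_, right_id = cid,
          age = "cub", sex = "U", mother_id = mothers[f])
      }
    }
  }
  out <- rbind(records, do.call(rbind, rows))
  out[order(out$datetime), , drop = FALSE]
}

fixtureProfiles <- function() {
  list(
    tiny = list(cfg = simulationConfig(N_true = 4, sigma_km = 1, beta = 0.5,
                                       trap_rows = 2, trap_cols = 2,
                                       spacing_km = 1.5, T = 2,
                                       buffer_km = 2),
                nStations = 4, families = 0, cubs = 0),
    tandoureh_like = list(
      cfg = simulationConfig(D_true = 5.6, sigma_km = 2, beta = -4,
                             behav_effect = 2, placement_effect = 1,
                             trap_rows = 8, trap_cols = 10,
                             spacing_km = 1.22, water_fraction = 25 / 80,
                             T = 11, known_both_fraction = 0.6,
                             buffer_km = 5),
      nStations = 80, families = 5, cubs = 7),
    salouk_like = list(
      cfg = simulationConfig(D_true = 3.1, sigma_km = 3.9, beta = -3,
                             trend_slope = -2, trap_rows = 2, trap_cols = 11,
                             spacing_km = 1.25, T = 12,
                             known_both_fraction = 0.58, buffer_km = 5),
      nStations = 22, families = 1, cubs = 2),
    sarigol_like = list(
      cfg = simulationConfig(D_true = 8.9, sigma_km = 0.72, beta = -2,
                             trap_rows = 4, trap_cols = 5, spacing_km = 1.4,
                             T = 11, known_both_fraction = 0.3,
                             buffer_km = 5),
      nStations = 19, families = 1, cubs = 1))
}

#' Write a synthetic survey fixture to disk
#'
#' Profiles emulate the motivating surveys at desk scale: \code{tiny} (4
#' stations, 2 occasions, a handful of individuals), \code{tandoureh_like}
#' (80 stations, 25 at water, 11 occasions), \code{salouk_like} (22 stations,
#' 12 occasions) and \code{sarigol_like} (19 stations, 11 occasions). Writes
#' \code{records.csv}, \code{design.csv}, \code{occasions.csv},
#' \code{mask.csv}, \code{known_pairs.csv} and \code{truth.json}; identical
#' seeds give byte-identical files.
#'
#' @param profile one of \code{"tiny"}, \code{"tandoureh_like"},
#'   \code{"salouk_like"}, \code{"sarigol_like"}.
#' @param dir output directory (created if needed).
#' @param seed RNG seed.
#' @return named character vector of file paths, invisibly; the simulated
#'   survey is attached as attribute \code{"survey"}.
#' @export
makeFixture <- function(profile, dir = tempfile("fixture"), seed = 1) {
  profs <- fixtureProfiles()
  if (!profile %in% names(profs))
    stopf("argument error: unknown fixture profile '%s'", profile)
  pr <- profs[[profile]]
  set.seed(seed)
  sim <- simulateSurveyTrimmed(pr$cfg, pr$nStations)
  records <- recordsFromSurvey(sim)
  if (pr$families > 0)
    records <- addFamilies(records, pr$families, pr$cubs)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(records = file.path(dir, "records.csv"),
             design = file.path(dir, "design.csv"),
             occasions = file.path(dir, "occasions.csv"),
             mask = file.path(dir, "mask.csv"),
             known_pairs = file.path(dir, "known_pairs.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(records, paths["records"], row.names = FALSE, quote = FALSE)
  des <- sim$design
  opDf <- as.data.frame(des@op * 1L)
  names(opDf) <- sprintf("op_%d", seq_len(ncol(opDf)))
  utils::write.csv(cbind(des@stations, opDf), paths["design"],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(
    start = format(des@occasions$start, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    end = format(des@occasions$end, "%Y-%m-%dT%H:%M:%S", tz = "UTC")),
    paths["occasions"], row.names = FALSE, quote = FALSE)
  writeMask(sim$mask, paths["mask"])
  kn <- which(sim$truth$known & apply(sim$truth$trueCodes > 0, 1, any))
  utils::write.csv(data.frame(left_id = sprintf("L%03d", kn),
                              right_id = sprintf("R%03d", kn)),
                   paths["known_pairs"], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(
    profile = profile, seed = seed, N_true = sim$truth$N,
    D_true = pr$cfg$D_true %||% (sim$truth$N / areaTotal(sim$mask) * 100),
    sigma_km = pr$cfg$sigma_km, delta = pr$cfg$delta, alpha = pr$cfg$alpha,
    centres = sim$truth$centres, known = sim$truth$known,
    sex = sim$truth$sex, truthMap = sim$truth$truthMap),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  attr(paths, "survey") <- sim
  invisible(paths)
}

# simulate a survey, trimming the trap grid to the first nStations stations
simulateSurveyTrimmed <- function(cfg, nStations) {
  design <- simulateDesign(cfg)
  if (nStations < nStations(design)) {
    design <- surveyDesign(design@stations[seq_len(nStations), , drop = FALSE],
                           design@occasions,
                           design@op[seq_len(nStations), , drop = FALSE])
  }
  mask <- buildMask(design, cfg$buffer_km, cfg$mesh_km)
  pop <- simulatePopulation(mask, cfg)
  params <- detectionParams(beta = cfg$beta, sigma_km = cfg$sigma_km,
                            behav_effect = cfg$behav_effect,
                            placement_effect = cfg$placement_effect,
                            trend_slope = cfg$trend_slope)
  th <- simulateTrueHistories(pop$centres, design, params)
  flank <- flankParams(cfg$delta, cfg$alpha)
  obs <- simulateFlankObservation(th, flank, pop$known, design, pop$sex)
  list(data = obs$data, design = design, mask = mask,
       truth = list(N = pop$N, centres = pop$centres, trueDet = th,
                    trueCodes = obs$trueCodes, truthMap = obs$truthMap,
                    known = obs$knownFinal, sex = pop$sex),
       config = cfg)
}

#' Read a survey design from fixture CSVs
#'
#' @param designPath stations CSV (\code{id,x_km,y_km,placement,op_1..op_T}).
#' @param occasionsPath occasions CSV (\code{start,end}, ISO-8601).
#' @return A \linkS4class{SurveyDesign}.
#' @export
readDesign <- function(designPath, occasionsPath) {
  st <- utils::read.csv(designPath, colClasses = NA)
  occ <- utils::read.csv(occasionsPath, colClasses = "character")
  occasions <- data.frame(
    start = as.POSIXct(occ$start, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S"),
    end = as.POSIXct(occ$end, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S"))
  opCols <- grep("^op_", names(st), value = TRUE)
  op <- as.matrix(st[, opCols, drop = FALSE]) > 0
  surveyDesign(st[, c("id", "x_km", "y_km", "placement")], occasions, op)
}
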