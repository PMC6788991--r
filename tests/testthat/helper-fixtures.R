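# shared in-code fixtures for the test suite

utcTime <- function(x) as.POSIXct(x, tz = "UTC")

# small design: traps on a grid, daily occasions
toyDesign <- function(nx = 2, ny = 2, spacing = 1, T = 2, placement = NULL,
                      op = NULL) {
  g <- expand.grid(x = seq_len(nx) - 1, y = seq_len(ny) - 1) * spacing
  J <- nrow(g)
  st <- data.frame(id = sprintf("S%d", seq_len(J)), x_km = g$x, y_km = g$y,
                   placement = placement %||% rep("trail", J))
  start <- utcTime("2016-06-01 00:00:00") + (seq_len(T) - 1) * 5 * 86400
  occ <- data.frame(start = start, end = start + 5 * 86400 - 1)
  surveyDesign(st, occ, op)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mask centred on the toy design
toyMask <- function(design, buffer = 2, mesh = 1) {
  buildMask(design, buffer, mesh)
}

# a minimal encounter array: specify codes as list of (h, t, j, code)
toyArray <- function(design, entries, kind, sex = NULL) {
  Tn <- nOccasions(design); J <- nStations(design)
  M <- length(kind)
  codes <- array(0L, dim = c(M, Tn, J))
  for (e in entries) codes[e[1], e[2], e[3]] <- as.integer(e[4])
  encounterArray(codes, kind, design, sex = sex)
}

toyParams <- function(beta = -0.5, sigma = 1, ...) {
  detectionParams(beta = beta, sigma_km = sigma, ...)
}

toyFlank <- function(delta = 0.4, alpha = 0.8) flankParams(delta, alpha)

# photo-record data.frame builder
rec <- function(station, datetime, side, left_id = NA, right_id = NA,
                age = "independent", sex = "U", mother_id = NA) {
  n <- max(length(station), length(datetime), length(side))
  if (length(datetime) == 0) n <- 0
  r <- function(x) rep(as.character(x), length.out = n)
  data.frame(station = r(station), datetime = r(datetime), side = r(side),
             left_id = r(left_id), right_id = r(right_id), age = r(age),
             sex = r(sex), mother_id = r(mother_id))
}

writeRecords <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

recordsWithTimestamps <- function(df, design) {
  p <- writeRecords(df)
  on.exit(unlink(p))
  readPhotoRecords(p, design)
}
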