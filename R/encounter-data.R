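# Photo-record ingestion, the 0.5-h independence rule, and construction of
# flank-coded encounter-history arrays.

recordColumns <- c("station", "datetime", "side", "left_id", "right_id",
                   "age", "sex")

#' Read camera-trap photo records
#'
#' CSV columns: \code{station}, \code{datetime} (ISO-8601), \code{side}
#' (\code{left}/\code{right}/\code{both}), \code{left_id}, \code{right_id},
#' \code{age} (\code{independent}/\code{cub}/\code{unknown}), \code{sex}
#' (\code{M}/\code{F}/\code{U}); optional \code{mother_id} linking cubs to
#' their mother's right-flank id. Records outside the survey's occasion
#' windows are dropped with a message; records at stations absent from the
#' design are dropped with a warning.
#'
#' @param path CSV file path.
#' @param design a \linkS4class{SurveyDesign}.
#' @return data.frame of validated records sorted by timestamp, with an
#'   \code{occasion} index column.
#' @export
readPhotoRecords <- function(path, design) {
  df <- utils::read.csv(path, colClasses = "character")
  for (col in recordColumns)
    if (!col %in% names(df))
      stopf("format error: photo-record CSV is missing column '%s'", col)
  if (!"mother_id" %in% names(df)) df$mother_id <- NA_character_
  df$left_id[!nzchar(df$left_id)] <- NA_character_
  df$right_id[!nzchar(df$right_id)] <- NA_character_
  df$mother_id[!nzchar(df$mother_id)] <- NA_character_
  if (nrow(df) == 0) {
    df$timestamp <- as.POSIXct(character(0), tz = "UTC")
    df$occasion <- integer(0)
    return(df)
  }
  ts <- as.POSIXct(df$datetime, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  if (anyNA(ts)) stopf("format error: unparseable datetime in photo records")
  df$timestamp <- ts
  bad <- !all(df$side %in% c("left", "right", "both"))
  if (bad) stopf("side must be one of left/right/both")
  if (any(df$side %in% c("left", "both") & is.na(df$left_id)) ||
      any(df$side %in% c("right", "both") & is.na(df$right_id)))
    stopf("flank id missing for the photographed side")
  unknownSt <- !(df$station %in% design@stations$id)
  if (any(unknownSt)) {
    warning(sprintf("dropping %d record(s) at stations not in the design",
                    sum(unknownSt)), call. = FALSE)
    df <- df[!unknownSt, , drop = FALSE]
  }
  occ <- design@occasions
  df$occasion <- NA_integer_
  for (k in seq_len(nrow(occ)))
    df$occasion[df$timestamp >= occ$start[k] & df$timestamp <= occ$end[k]] <- k
  out <- is.na(df$occasion)
  if (any(out))
    message(sprintf("dropped %d record(s) outside the occasion windows",
                    sum(out)))
  df <- df[!out, , drop = FALSE]
  df <- df[order(df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# canonical individual key: right id where available (directly or through a
# side=both record linking the left id), else the bare left id
canonicalIds <- function(records, known_pairs = NULL) {
  linkL <- character(0)
  both <- records$side == "both"
  if (any(both)) linkL <- stats::setNames(records$right_id[both],
                                          records$left_id[both])
  if (!is.null(known_pairs) && nrow(known_pairs) > 0)
    linkL[known_pairs$left_id] <- known_pairs$right_id
  key <- ifelse(!is.na(records$right_id), paste0("R:", records$right_id),
         ifelse(records$left_id %in% names(linkL),
                paste0("R:", linkL[records$left_id]),
                paste0("L:", records$left_id)))
  key
}

#' Collapse detections within the independence window
#'
#' Applies the rule that discards all but one capture of the same individual
#' taken at the same camera station no more than \code{window_hours} apart.
#' The rule is read pairwise on consecutive photos, so a chain
#' 10:00/10:25/10:50 collapses to the single earliest record.
#'
#' @param records data.frame from \code{\link{readPhotoRecords}}.
#' @param window_hours independence window (default 0.5 h).
#' @return the collapsed records, sorted by timestamp.
#' @export
collapseDetections <- function(records, window_hours = 0.5) {
  if (window_hours < 0) stopf("argument error: window_hours must be >= 0")
  if (nrow(records) == 0) return(records)
  records <- records[order(records$timestamp), , drop = FALSE]
  key <- paste(records$station, canonicalIds(records))
  keep <- rep(TRUE, nrow(records))
  lastTime <- split(seq_len(nrow(records)), key)
  for (idx in lastTime) {
    if (length(idx) < 2) next
    gaps <- diff(as.numeric(records$timestamp[idx]))
    keep[idx[-1]] <- gaps > window_hours * 3600
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the flank-coded observed encounter array
#'
#' One history per unmatched left id, one per unmatched right id, one per
#' bilaterally known individual (given by \code{known_pairs} or implied by
#' \code{side = "both"} records). Within each (individual, occasion, trap)
#' cell, the code of highest information is kept: 4 (a simultaneous both-flank
#' photo) over 3 (both flanks seen in the interval, never in one photo) over
#' 1/2. Dependent cubs are excluded (the density target is independent
#' leopards).
#'
#' @param records collapsed records (see \code{\link{collapseDetections}}).
#' @param design a \linkS4class{SurveyDesign}.
#' @param known_pairs optional data.frame with columns \code{left_id},
#'   \code{right_id} for externally known bilateral identities.
#' @return An \linkS4class{EncounterArray}.
#' @export
buildEncounterArray <- function(records, design, known_pairs = NULL) {
  if (!is.null(known_pairs)) {
    known_pairs <- as.data.frame(known_pairs)
    if (anyDuplicated(known_pairs$left_id) ||
        anyDuplicated(known_pairs$right_id))
      stopf("data error: a flank id appears in two known pairs")
  }
  records <- records[records$age != "cub", , drop = FALSE]
  Tn <- nOccasions(design); J <- nStations(design)
  stIdx <- match(records$station, design@stations$id)

  # linkage left_id -> right_id from both-photos and known pairs
  linkL <- character(0)
  both <- records$side == "both"
  if (any(both))
    linkL[records$left_id[both]] <- records$right_id[both]
  if (!is.null(known_pairs) && nrow(known_pairs) > 0)
    linkL[known_pairs$left_id] <- known_pairs$right_id

  knownR <- unique(unname(linkL))
  allR <- unique(records$right_id[!is.na(records$right_id)])
  allL <- unique(records$left_id[!is.na(records$left_id)])
  soloR <- setdiff(allR, knownR)
  soloL <- setdiff(allL, names(linkL))
  knownR <- intersect(knownR, union(allR, unname(linkL)))

  ids <- c(soloL, soloR, knownR)
  kind <- c(rep("left", length(soloL)), rep("right", length(soloR)),
            rep("known", length(knownR)))
  M <- length(ids)
  codes <- array(0L, dim = c(M, Tn, J))
  sexTab <- rep("U", M)
  if (nrow(records) > 0) {
    # map each record to its history
    histOf <- function(rec_left, rec_right) {
      if (!is.na(rec_right)) {
        if (rec_right %in% knownR) return(match(rec_right, ids) )
        return(match(rec_right, ids))
      }
      if (rec_left %in% names(linkL)) return(match(linkL[[rec_left]], ids))
      match(rec_left, ids)
    }
    for (r in seq_len(nrow(records))) {
      m <- histOf(records$left_id[r], records$right_id[r])
      t <- records$occasion[r]; j <- stIdx[r]
      if (!design@op[j, t])
        stopf("data error: record at non-operational station-occasion (%s)",
              records$station[r])
      side <- records$side[r]
      cur <- codes[m, t, j]
      new <- if (side == "both") 4L
             else if (side == "left") 1L else 2L
      codes[m, t, j] <- combineCodes(cur, new)
      if (records$sex[r] %in% c("M", "F")) sexTab[m] <- records$sex[r]
    }
  }
  keep <- apply(codes > 0, 1, any)
  encounterArray(codes[keep, , , drop = FALSE], kind[keep], design,
                 sex = sexTab[keep], historyIds = ids[keep])
}

# information order 4 > 3 > {1, 2}; a 1 and a 2 in the same cell give a 3
combineCodes <- function(cur, new) {
  if (cur == 0L) return(new)
  if (cur == 4L || new == 4L) return(4L)
  if (cur == 3L || new == 3L) return(3L)
  if (cur != new) return(3L)
  cur
}

#' Write an encounter array as long-format CSV plus a JSON sidecar
#'
#' The CSV holds one row per nonzero cell (\code{history}, \code{occasion},
#' \code{trap}, \code{code}); the sidecar records per-history kind, known
#' flag, sex, ids and the data type.
#'
#' @param data an \linkS4class{EncounterArray}.
#' @param path CSV output path; the sidecar is written next to it as
#'   \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
writeEncounterArray <- function(data, path) {
  idx <- which(data@codes > 0, arr.ind = TRUE)
  df <- data.frame(history = idx[, 1], occasion = idx[, 2], trap = idx[, 3],
                   code = data@codes[idx])
  df <- df[order(df$history, df$occasion, df$trap), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(M_obs = nHistories(data), data_type = data@dataType,
         history_kind = data@kind, known_flag = data@known, sex = data@sex,
         history_ids = data@historyIds),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an encounter array written by \code{\link{writeEncounterArray}}
#'
#' @param path the long-format CSV path (sidecar expected at
#'   \code{<path>.json}).
#' @param design the \linkS4class{SurveyDesign} the histories refer to.
#' @return An \linkS4class{EncounterArray}.
#' @export
readEncounterArray <- function(path, design) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  codes <- array(0L, dim = c(side$M_obs, nOccasions(design),
                             nStations(design)))
  codes[cbind(df$history, df$occasion, df$trap)] <- as.integer(df$code)
  encounterArray(codes, side$history_kind, design, sex = side$sex,
                 historyIds = side$history_ids)
}

#' Baseline survey summary counts
#'
#' Pictures, independent detections (after the 0.5-h rule), individuals
#' detected by flank, sex composition and family counts, following the
#' right-flank counting convention for sex, families and cubs.
#'
#' @param records data.frame of photo records (uncollapsed).
#' @param window_hours independence window for the detection count.
#' @return list with components \code{pictures}, \code{detections},
#'   \code{right_individuals}, \code{left_individuals},
#'   \code{known_individuals}, \code{sex} (named M/F/U counts, independent
#'   individuals by right flank), \code{families}, \code{cubs}.
#' @export
summarizeCounts <- function(records, window_hours = 0.5) {
  if (nrow(records) == 0)
    return(list(pictures = 0L, detections = 0L, right_individuals = 0L,
                left_individuals = 0L, known_individuals = 0L,
                sex = c(M = 0L, F = 0L, U = 0L), families = 0L, cubs = 0L))
  coll <- collapseDetections(records, window_hours)
  indep <- records[records$age != "cub", , drop = FALSE]
  rightIds <- unique(indep$right_id[!is.na(indep$right_id)])
  leftIds <- unique(indep$left_id[!is.na(indep$left_id)])
  bothIds <- unique(indep$right_id[indep$side == "both" & !is.na(indep$right_id)])
  sexOf <- vapply(rightIds, function(id) {
    s <- indep$sex[!is.na(indep$right_id) & indep$right_id == id]
    s <- s[s %in% c("M", "F")]
    if (length(s)) s[1] else "U"
  }, "")
  cubs <- records[records$age == "cub", , drop = FALSE]
  list(pictures = nrow(records),
       detections = nrow(coll),
       right_individuals = length(rightIds),
       left_individuals = length(leftIds),
       known_individuals = length(bothIds),
       sex = c(M = sum(sexOf == "M"), F = sum(sexOf == "F"),
               U = sum(sexOf == "U")),
       families = length(unique(cubs$mother_id[!is.na(cubs$mother_id)])),
       cubs = length(unique(cubs$right_id[!is.na(cubs$right_id)])))
}
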