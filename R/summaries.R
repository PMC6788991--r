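# Descriptive survey summaries: detections per individual, family/cub
# summaries, and water-vs-trail detection-frequency comparisons. Counting
# follows the right-flank convention. Inferential tests on these tables
# (negative-binomial regression, Poisson GLMMs, Fisher's exact tests) are
# deliberately not reimplemented here; the tidy per-individual table these
# summaries produce is their input.

rightIdRecords <- function(records) {
  records[!is.na(records$right_id), , drop = FALSE]
}

#' Detections per individual
#'
#' Counts of independent detections per right-flank individual after the 0.5-h
#' rule, with the median, range and the number of individuals detected exactly
#' once.
#'
#' @param records photo records (collapsed or raw; the independence rule is
#'   applied).
#' @param window_hours independence window.
#' @param age_classes which age classes to count (default independent
#'   individuals only).
#' @return list with \code{counts} (named per individual), \code{median},
#'   \code{range}, \code{singletons}, \code{total_detections}.
#' @export
detectionsPerIndividual <- function(records, window_hours = 0.5,
                                    age_classes = "independent") {
  coll <- collapseDetections(records, window_hours)
  coll <- coll[coll$age %in% age_classes, , drop = FALSE]
  coll <- rightIdRecords(coll)
  if (nrow(coll) == 0)
    return(list(counts = integer(0), median = NA_real_, range = c(NA, NA),
                singletons = 0L, total_detections = 0L))
  counts <- table(coll$right_id)
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       median = stats::median(as.integer(counts)),
       range = range(as.integer(counts)),
       singletons = sum(counts == 1),
       total_detections = sum(counts))
}

#' Family and cub summary
#'
#' Families are identified by the \code{mother_id} links on cub records (a
#' link to a right-flank id absent from the records is a data error). Reports
#' the number of families and cubs, mean cubs per family with its standard
#' error, the cub share of detected individuals, and the share of family
#' detections in which a cub was photographed together with the female (a cub
#' record at the same station within the independence window of a mother
#' record).
#'
#' @param records photo records.
#' @param window_hours independence window.
#' @return list with \code{families}, \code{cubs}, \code{mean_cubs_per_family},
#'   \code{se_cubs_per_family}, \code{cub_share}, \code{family_detections},
#'   \code{with_female_count}, \code{with_female_share}.
#' @export
familySummary <- function(records, window_hours = 0.5) {
  cubs <- records[records$age == "cub" & !is.na(records$mother_id), ,
                  drop = FALSE]
  if (nrow(cubs) == 0)
    return(list(families = 0L, cubs = 0L, mean_cubs_per_family = NA_real_,
                se_cubs_per_family = NA_real_, cub_share = NA_real_,
                family_detections = 0L, with_female_count = 0L,
                with_female_share = NA_real_))
  adults <- records[records$age != "cub", , drop = FALSE]
  motherIds <- unique(cubs$mother_id)
  known <- unique(adults$right_id[!is.na(adults$right_id)])
  if (!all(motherIds %in% known))
    stopf("data error: family link to unknown mother id %s",
          paste(setdiff(motherIds, known), collapse = ", "))
  cubIds <- unique(cubs$right_id[!is.na(cubs$right_id)])
  perFam <- vapply(motherIds, function(m)
    length(unique(cubs$right_id[cubs$mother_id == m])), 0L)
  coll <- collapseDetections(records, window_hours)
  motherDet <- coll[!is.na(coll$right_id) & coll$right_id %in% motherIds &
                    coll$age != "cub", , drop = FALSE]
  cubDet <- coll[coll$age == "cub", , drop = FALSE]
  withCub <- 0L
  for (r in seq_len(nrow(motherDet))) {
    fam <- cubs$right_id[cubs$mother_id == motherDet$right_id[r]]
    near <- cubDet$station == motherDet$station[r] &
      cubDet$right_id %in% fam &
      abs(as.numeric(cubDet$timestamp) -
          as.numeric(motherDet$timestamp[r])) <= window_hours * 3600
    if (any(near)) withCub <- withCub + 1L
  }
  indep <- length(unique(adults$right_id[!is.na(adults$right_id)]))
  list(families = length(motherIds),
       cubs = length(cubIds),
       mean_cubs_per_family = mean(perFam),
       se_cubs_per_family = stats::sd(perFam) / sqrt(length(perFam)),
       cub_share = length(cubIds) / (indep + length(cubIds)),
       family_detections = nrow(motherDet),
       with_female_count = withCub,
       with_female_share = if (nrow(motherDet)) withCub / nrow(motherDet)
                           else NA_real_)
}

#' Water vs trail detection frequencies
#'
#' Group-wise (independent male, independent female, cub, and all identified
#' individuals) mean detections per individual with standard errors, split by
#' camera placement, and the water/trail ratio. An individual detected at both
#' placements contributes its placement-specific counts to both columns; the
#' per-placement n is the number of individuals in the group detected at that
#' placement. Individuals of unknown sex are excluded from the sex-specific
#' rows. With no water (or no trail) stations the ratio is reported as NA.
#'
#' @param records photo records.
#' @param design a \linkS4class{SurveyDesign} carrying the placement covariate.
#' @param window_hours independence window.
#' @return data.frame with one row per group: means, SEs, n's and
#'   \code{water_trail_ratio} (full precision; round to 1 decimal for
#'   reporting).
#' @export
placementComparison <- function(records, design, window_hours = 0.5) {
  coll <- collapseDetections(records, window_hours)
  coll <- rightIdRecords(coll)
  placement <- design@stations$placement[match(coll$station,
                                               design@stations$id)]
  coll$placement <- placement
  grp <- function(sub) {
    perInd <- function(pl) {
      x <- sub[sub$placement == pl, , drop = FALSE]
      if (!nrow(x)) return(c(mean = NA, se = NA, n = 0))
      cnt <- as.integer(table(x$right_id))
      c(mean = mean(cnt),
        se = if (length(cnt) > 1) stats::sd(cnt) / sqrt(length(cnt)) else 0,
        n = length(cnt))
    }
    w <- perInd("water"); t <- perInd("trail")
    ratio <- if (!is.na(w["mean"]) && !is.na(t["mean"]) && t["mean"] > 0)
      unname(w["mean"] / t["mean"]) else NA_real_
    data.frame(water_mean = w[["mean"]], water_se = w[["se"]],
               water_n = w[["n"]], trail_mean = t[["mean"]],
               trail_se = t[["se"]], trail_n = t[["n"]],
               water_trail_ratio = ratio)
  }
  groups <- list(
    independent_male = coll[coll$age == "independent" & coll$sex == "M", ],
    independent_female = coll[coll$age == "independent" & coll$sex == "F", ],
    cub = coll[coll$age == "cub", ],
    all = coll)
  out <- do.call(rbind, lapply(groups, grp))
  cbind(group = names(groups), out, row.names = NULL)
}
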