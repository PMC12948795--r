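#' Default Composite Morningness Questionnaire scoring key
#'
#' The Composite Morningness Questionnaire (CMQ) has 13 items. Each item offers
#' 4 or 5 response options worth 1..4 or 1..5 points, so totals span 13-55,
#' with higher totals indicating an earlier chronotype. The published
#' instrument is not redistributable, so the package ships a structural key:
#' ten 4-option items followed by three 5-option items (the only mix of 4- and
#' 5-point items consistent with a 13-55 range), each option worth its index in
#' points. Replace it with the verbatim published key via [read_cmq_key()] if
#' you hold the instrument; every scoring function accepts a `key` argument.
#'
#' @return A tibble with columns `item`, `option`, `points` (one row per
#'   response option).
#' @seealso [score_cmq()], [read_cmq_key()]
#' @export
#' @examples
#' key <- cmq_default_key()
#' range(tapply(key$points, key$item, max)) # 4 and 5
cmq_default_key <- function() {
  n_opt <- c(rep(4L, 10), rep(5L, 3))
  tibble::tibble(
    item = rep(seq_len(13L), n_opt),
    option = unlist(lapply(n_opt, seq_len), use.names = FALSE),
    points = unlist(lapply(n_opt, seq_len), use.names = FALSE)
  )
}

#' Read a CMQ scoring key from CSV
#'
#' @param path CSV with columns `item`, `option`, `points`.
#' @return A validated key tibble (see [cmq_default_key()]).
#' @export
read_cmq_key <- function(path) {
  key <- readr::read_csv(path, col_types = readr::cols(
    item = readr::col_integer(),
    option = readr::col_integer(),
    points = readr::col_integer()
  ))
  validate_cmq_key(key)
  key
}

validate_cmq_key <- function(key) {
  if (!all(c("item", "option", "points") %in% names(key))) {
    stop("CMQ key needs columns item, option, points", call. = FALSE)
  }
  items <- sort(unique(key$item))
  if (!identical(as.integer(items), 1:13)) {
    stop("CMQ key must define exactly items 1..13", call. = FALSE)
  }
  lo <- sum(tapply(key$points, key$item, min))
  hi <- sum(tapply(key$points, key$item, max))
  if (lo != 13L || hi != 55L) {
    stop(sprintf(
      "CMQ key totals must span 13..55 (got %d..%d)", lo, hi
    ), call. = FALSE)
  }
  invisible(key)
}

#' Score a 13-item CMQ response sheet
#'
#' Sums the point values of the selected options; totals range 13-55 and a
#' higher score indicates an earlier chronotype.
#'
#' @param selections integer vector of 13 chosen option indices (item order).
#' @param key scoring key, see [cmq_default_key()].
#' @return integer total score in `[13, 55]`.
#' @export
#' @examples
#' score_cmq(rep(1L, 13)) # 13
score_cmq <- function(selections, key = cmq_default_key()) {
  validate_cmq_key(key)
  selections <- as.integer(selections)
  if (length(selections) != 13L) {
    stop("a CMQ response sheet has exactly 13 selections", call. = FALSE)
  }
  pts <- integer(13)
  for (i in seq_len(13L)) {
    opts <- key[key$item == i, , drop = FALSE]
    sel <- selections[i]
    if (is.na(sel) || sel < 1L || sel > max(opts$option)) {
      stop(sprintf(
        "item %d: selection %s outside option range 1..%d",
        i, as.character(selections[i]), max(opts$option)
      ), call. = FALSE)
    }
    pts[i] <- opts$points[match(sel, opts$option)]
  }
  as.integer(sum(pts))
}

# vectorised scoring of a cohort table holding cmq_01..cmq_13 columns
score_cmq_cohort <- function(cohort, key = cmq_default_key()) {
  cols <- sprintf("cmq_%02d", 1:13)
  if (!all(cols %in% names(cohort))) {
    stop("cohort table must contain columns cmq_01..cmq_13", call. = FALSE)
  }
  sel <- as.matrix(cohort[, cols])
  tibble::tibble(
    participant_id = cohort$participant_id,
    cmq_score = vapply(
      seq_len(nrow(sel)),
      function(r) score_cmq(sel[r, ], key = key),
      integer(1)
    )
  )
}

#' Assign quintile chronotype groups from CMQ scores
#'
#' Participants are ranked by score and cut at the empirical 20/40/60/80
#' percentiles into five groups. Because a higher CMQ score means an earlier
#' chronotype, the lowest quintile is labelled `late` and the highest `early`.
#' Tied scores never straddle a group boundary: every member of a tied block is
#' placed in the lowest group index any member would occupy, so group sizes can
#' be unequal (as in real cohorts).
#'
#' @param scores data frame with columns `participant_id` and `cmq_score`.
#' @return tibble `participant_id`, `cmq_score`, `chronotype_group` (ordered
#'   factor late < late_intermediate < neutral < early_intermediate < early).
#' @export
assign_quintiles <- function(scores) {
  stopifnot(all(c("participant_id", "cmq_score") %in% names(scores)))
  n <- nrow(scores)
  if (n < 5L) stop("quintile grouping needs at least 5 participants", call. = FALSE)
  labels <- c("late", "late_intermediate", "neutral", "early_intermediate", "early")
  r <- rank(scores$cmq_score, ties.method = "min")
  grp <- ceiling(5 * r / n)
  if (any(tabulate(grp, nbins = 5L) == 0L)) {
    warning("ties collapse one or more chronotype groups to empty", call. = FALSE)
  }
  tibble::tibble(
    participant_id = scores$participant_id,
    cmq_score = scores$cmq_score,
    chronotype_group = factor(labels[grp], levels = labels, ordered = TRUE)
  )
}

#' Body mass index
#'
#' @param mass_kg body mass in kilograms.
#' @param height_m height in metres.
#' @return BMI in kg/m^2.
#' @export
compute_bmi <- function(mass_kg, height_m) {
  assert_positive(mass_kg, "mass_kg")
  assert_positive(height_m, "height_m")
  mass_kg / height_m^2
}

#' Waist-to-height ratio
#'
#' @param waist_cm waist circumference in centimetres.
#' @param height_cm height in centimetres.
#' @return dimensionless ratio.
#' @export
compute_wthr <- function(waist_cm, height_cm) {
  assert_positive(waist_cm, "waist_cm")
  assert_positive(height_cm, "height_cm")
  waist_cm / height_cm
}
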