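# Participant-level and aggregate trial tables: schema, validation, I/O,
# outcome-hierarchy resolution and time-to-event derivation.

# Column order of the participant table, version 1 of the schema.
PARTICIPANT_COLUMNS <- c(
  "trial_id", "participant_id", "arm", "sex", "family_history_atopy",
  "flg_mutations", "age_at_initiation_days",
  "adherence_days_per_week_intervention_period",
  "adherence_days_per_week_first3mo",
  "eczema_ukwp", "eczema_doctor", "eczema_parent", "food_allergy_ofc",
  "ae_skin_infection", "ae_sting", "ae_slippage", "sae_count",
  "visit_ages_days", "eczema_first_visit_index"
)

AGGREGATE_COLUMNS <- c(
  "trial_id", "outcome", "events_treat", "n_treat", "events_ctrl", "n_ctrl",
  "mean_treat", "sd_treat", "mean_ctrl", "sd_ctrl",
  "reported_hr", "reported_hr_ci_low", "reported_hr_ci_high",
  "reported_adjusted", "sae_reporting_threshold"
)

#' Construct a participant table
#'
#' Builds and validates a participant-level data frame, one row per
#' randomized infant.  `visit_ages_days` is a list column of strictly
#' increasing integer vectors (ages in days since birth; the trials enrol
#' from birth).  `eczema_first_visit_index` is the 1-based index of the
#' first visit at which eczema was diagnosed, or `NA` if never.
#' `flg_mutations` is coded 0 (no loss-of-function FLG mutations) or
#' 1 (one or two mutations).
#'
#' @param trial_id,participant_id identifiers (coerced to character).
#' @param arm 1 = skin-care intervention, 0 = control.
#' @param sex,family_history_atopy,flg_mutations binary covariates (`NA`
#'   allowed for the latter two).
#' @param age_at_initiation_days non-negative integer or `NA`.
#' @param adherence_days_per_week_intervention_period,adherence_days_per_week_first3mo
#'   mean application days per week, in `[0, 7]` or `NA`.
#' @param eczema_ukwp,eczema_doctor,eczema_parent binary eczema outcomes at
#'   the three hierarchy levels (UKWP/Hanifin-Rajka criteria, doctor
#'   diagnosis, parent report).
#' @param food_allergy_ofc binary food allergy confirmed by oral food
#'   challenge.
#' @param ae_skin_infection,ae_sting,ae_slippage binary adverse events.
#' @param sae_count number of serious adverse events experienced.
#' @param visit_ages_days list of integer vectors (or a single vector
#'   recycled to all participants).
#' @param eczema_first_visit_index 1-based visit index of eczema onset.
#' @return a validated `data.frame` of participant records.
#' @export
#' @examples
#' participant_table(
#'   trial_id = "T1", participant_id = c("p1", "p2"), arm = c(0, 1),
#'   sex = c(0, 1), eczema_ukwp = c(1, 0),
#'   visit_ages_days = list(c(90L, 180L, 365L)),
#'   eczema_first_visit_index = c(2, NA)
#' )
participant_table <- function(trial_id, participant_id, arm,
                              sex = NA, family_history_atopy = NA,
                              flg_mutations = NA,
                              age_at_initiation_days = NA,
                              adherence_days_per_week_intervention_period = NA,
                              adherence_days_per_week_first3mo = NA,
                              eczema_ukwp = NA, eczema_doctor = NA,
                              eczema_parent = NA, food_allergy_ofc = NA,
                              ae_skin_infection = NA, ae_sting = NA,
                              ae_slippage = NA, sae_count = NA,
                              visit_ages_days = list(integer(0)),
                              eczema_first_visit_index = NA) {
  n <- length(participant_id)
  if (!is.list(visit_ages_days)) visit_ages_days <- list(visit_ages_days)
  if (length(visit_ages_days) == 1L && n > 1L) {
    visit_ages_days <- rep(visit_ages_days, n)
  }
  df <- data.frame(
    trial_id = as.character(rep_len(trial_id, n)),
    participant_id = as.character(participant_id),
    arm = as.numeric(rep_len(arm, n)),
    sex = as.numeric(rep_len(sex, n)),
    family_history_atopy = as.numeric(rep_len(family_history_atopy, n)),
    flg_mutations = as.numeric(rep_len(flg_mutations, n)),
    age_at_initiation_days = as.numeric(rep_len(age_at_initiation_days, n)),
    adherence_days_per_week_intervention_period =
      as.numeric(rep_len(adherence_days_per_week_intervention_period, n)),
    adherence_days_per_week_first3mo =
      as.numeric(rep_len(adherence_days_per_week_first3mo, n)),
    eczema_ukwp = as.numeric(rep_len(eczema_ukwp, n)),
    eczema_doctor = as.numeric(rep_len(eczema_doctor, n)),
    eczema_parent = as.numeric(rep_len(eczema_parent, n)),
    food_allergy_ofc = as.numeric(rep_len(food_allergy_ofc, n)),
    ae_skin_infection = as.numeric(rep_len(ae_skin_infection, n)),
    ae_sting = as.numeric(rep_len(ae_sting, n)),
    ae_slippage = as.numeric(rep_len(ae_slippage, n)),
    sae_count = as.numeric(rep_len(sae_count, n)),
    stringsAsFactors = FALSE
  )
  df$visit_ages_days <- lapply(visit_ages_days, as.integer)
  df$eczema_first_visit_index <-
    as.numeric(rep_len(eczema_first_visit_index, n))
  validate_participants(df)
}

#' Validate a participant table
#'
#' Checks every row against the record invariants: `arm` in \{0, 1\},
#' binary fields in \{0, 1, NA\}, adherence within `[0, 7]`, strictly
#' increasing visit ages, `eczema_first_visit_index` a valid 1-based index
#' into the visit list, and non-negative counts.  All violations are
#' collected and reported with their row numbers.
#'
#' @param df a participant data frame with the documented columns.
#' @return `df`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_participants <- function(df) {
  missing_cols <- setdiff(c("trial_id", "participant_id", "arm"), names(df))
  if (length(missing_cols) > 0) {
    stop("participant table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(PARTICIPANT_COLUMNS, names(df))) {
    df[[col]] <- if (col == "visit_ages_days") {
      rep(list(integer(0)), nrow(df))
    } else {
      NA_real_
    }
  }
  df <- df[, PARTICIPANT_COLUMNS]

  bad <- function(idx, what) {
    if (length(idx) == 0) character(0) else {
      paste0("row ", idx, ": ", what)
    }
  }
  problems <- character(0)
  chk_binary <- c("arm", "sex", "family_history_atopy", "flg_mutations",
                  "eczema_ukwp", "eczema_doctor", "eczema_parent",
                  "food_allergy_ofc", "ae_skin_infection", "ae_sting",
                  "ae_slippage")
  for (col in chk_binary) {
    i <- which(!(is.na(df[[col]]) | df[[col]] %in% c(0, 1)))
    problems <- c(problems, bad(i, paste0(col, " must be 0, 1 or missing")))
  }
  i <- which(is.na(df$arm))
  problems <- c(problems, bad(i, "arm is mandatory"))
  for (col in c("adherence_days_per_week_intervention_period",
                "adherence_days_per_week_first3mo")) {
    x <- df[[col]]
    i <- which(!is.na(x) & (x < 0 | x > 7))
    problems <- c(problems, bad(i, paste0(col, " outside [0, 7]")))
  }
  for (col in c("age_at_initiation_days", "sae_count")) {
    x <- df[[col]]
    i <- which(!is.na(x) & x < 0)
    problems <- c(problems, bad(i, paste0(col, " must be non-negative")))
  }
  visits_ok <- vapply(df$visit_ages_days, function(v) {
    length(v) == 0 || (all(v >= 0) && all(diff(v) > 0))
  }, logical(1))
  problems <- c(problems,
                bad(which(!visits_ok),
                    "visit_ages_days must be non-negative and strictly increasing"))
  idx_ok <- mapply(function(ix, v) {
    is.na(ix) || (ix >= 1 && ix <= length(v) && ix == floor(ix))
  }, df$eczema_first_visit_index, df$visit_ages_days)
  problems <- c(problems,
                bad(which(!idx_ok),
                    "eczema_first_visit_index is not a valid visit index"))
  if (length(problems) > 0) {
    stop("participant table validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(df)
}

#' Read a participant table from CSV
#'
#' Comma-separated, UTF-8, mandatory header; missing values are empty
#' fields; `visit_ages_days` is serialized as semicolon-separated integers
#' (e.g. `"90;180;365"`).  Every row is validated against the record
#' invariants and violations are reported with their row numbers.
#'
#' @param path path to the CSV file.
#' @param schema_version schema identifier; only `"1"` is defined.
#' @return a validated participant `data.frame`.
#' @seealso [write_participants()]
#' @export
read_participants <- function(path, schema_version = "1") {
  if (!identical(as.character(schema_version), "1")) {
    stop("unknown participant schema version: ", schema_version,
         call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "")
  missing_cols <- setdiff(c("trial_id", "participant_id", "arm"), names(raw))
  if (length(missing_cols) > 0) {
    stop("participant CSV is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(trial_id = raw$trial_id,
                   participant_id = raw$participant_id,
                   stringsAsFactors = FALSE)
  num_cols <- setdiff(PARTICIPANT_COLUMNS,
                      c("trial_id", "participant_id", "visit_ages_days"))
  for (col in num_cols) {
    df[[col]] <- if (col %in% names(raw)) {
      suppressWarnings(as.numeric(raw[[col]]))
    } else {
      NA_real_
    }
  }
  df$visit_ages_days <- if ("visit_ages_days" %in% names(raw)) {
    lapply(raw$visit_ages_days, function(s) {
      if (is.na(s) || !nzchar(s)) integer(0) else {
        as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
      }
    })
  } else {
    rep(list(integer(0)), nrow(df))
  }
  validate_participants(df)
}

#' Write a participant table to CSV
#'
#' Emits the exact schema read by [read_participants()] so that a
#' write/read cycle is lossless field-by-field.
#'
#' @param df a validated participant data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(df, path) {
  df <- validate_participants(df)
  out <- df
  out$visit_ages_days <- vapply(df$visit_ages_days, paste, character(1),
                                collapse = ";")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Resolve the eczema outcome hierarchy
#'
#' Eczema is taken from the highest available level of the fixed hierarchy:
#' UKWP / Hanifin-Rajka diagnostic criteria, then doctor diagnosis, then
#' parent report.  The source records which level supplied the value;
#' participants with all three missing are `unresolved`.
#'
#' @param participants a participant data frame (or any data frame with the
#'   three `eczema_*` columns).
#' @return a `data.frame` with one row per participant: `value` (0/1/`NA`)
#'   and `source` (one of `"ukwp_or_hanifin_rajka"`, `"doctor"`,
#'   `"parent"`, `"unresolved"`).
#' @export
resolve_eczema_outcome <- function(participants) {
  ukwp <- participants$eczema_ukwp
  doctor <- participants$eczema_doctor
  parent <- participants$eczema_parent
  value <- ifelse(!is.na(ukwp), ukwp,
                  ifelse(!is.na(doctor), doctor, parent))
  source <- ifelse(!is.na(ukwp), "ukwp_or_hanifin_rajka",
                   ifelse(!is.na(doctor), "doctor",
                          ifelse(!is.na(parent), "parent", "unresolved")))
  data.frame(value = as.numeric(value), source = source,
             stringsAsFactors = FALSE)
}

#' Derive time-to-eczema from visit schedule and onset index
#'
#' Onset times are interval-censored at scheduled visits: a participant
#' whose eczema was first recorded at visit `j` contributes an event at the
#' age of that visit; a participant never diagnosed is right-censored at
#' their last attended visit.  Participants with no recorded visits get a
#' missing time.
#'
#' @param participants a participant data frame.
#' @return a `data.frame` with `time_days` (positive integer or `NA`) and
#'   `event` (0/1) per participant.
#' @export
derive_time_to_event <- function(participants) {
  n <- nrow(participants)
  time <- rep(NA_real_, n)
  event <- rep(0, n)
  for (i in seq_len(n)) {
    v <- participants$visit_ages_days[[i]]
    if (length(v) == 0) next
    ix <- participants$eczema_first_visit_index[i]
    if (!is.na(ix)) {
      time[i] <- v[ix]
      event[i] <- 1
    } else {
      time[i] <- v[length(v)]
    }
  }
  data.frame(time_days = time, event = event)
}

# Outcomes countable by aggregate_from_participants(); "eczema" goes
# through the hierarchy, "sae" counts participants with >= 1 event (IPD
# truth) subject to the publication threshold.
BINARY_OUTCOMES <- c("eczema", "food_allergy_ofc", "ae_skin_infection",
                     "ae_sting", "ae_slippage", "sae")

outcome_values <- function(participants, outcome) {
  switch(outcome,
    eczema = resolve_eczema_outcome(participants)$value,
    sae = ifelse(is.na(participants$sae_count), NA,
                 as.numeric(participants$sae_count >= 1)),
    participants[[outcome]]
  )
}

#' Aggregate a trial's participant records into a published view
#'
#' Computes per-arm event counts over participants with a non-missing
#' resolved outcome.  For serious adverse events (`outcome = "sae"`), a
#' participant contributes to the published count only if their number of
#' SAEs reaches `reporting_threshold` — the selective-reporting policy in
#' which publications list only participants with two or more events.
#' Threshold 1 reproduces the full participant-level count.
#'
#' @param participants participant records from a single trial.
#' @param outcome one of `"eczema"`, `"food_allergy_ofc"`,
#'   `"ae_skin_infection"`, `"ae_sting"`, `"ae_slippage"`, `"sae"`.
#' @param reporting_threshold integer >= 1; SAE publication threshold
#'   (events per participant below which the participant is omitted).
#' @return a one-row aggregate `data.frame` (see [read_aggregates()] for
#'   the schema).
#' @export
aggregate_from_participants <- function(participants, outcome,
                                        reporting_threshold = 1L) {
  outcome <- match.arg(outcome, BINARY_OUTCOMES)
  ids <- unique(participants$trial_id)
  if (length(ids) > 1) {
    stop("participants span several trials: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  if (reporting_threshold < 1) {
    stop("reporting_threshold must be >= 1", call. = FALSE)
  }
  y <- if (outcome == "sae") {
    ifelse(is.na(participants$sae_count), NA,
           as.numeric(participants$sae_count >= reporting_threshold))
  } else {
    outcome_values(participants, outcome)
  }
  arm <- participants$arm
  keep <- !is.na(y)
  agg <- data.frame(
    trial_id = if (length(ids) == 1) ids else NA_character_,
    outcome = outcome,
    events_treat = sum(y[keep & arm == 1]),
    n_treat = sum(keep & arm == 1),
    events_ctrl = sum(y[keep & arm == 0]),
    n_ctrl = sum(keep & arm == 0),
    mean_treat = NA_real_, sd_treat = NA_real_,
    mean_ctrl = NA_real_, sd_ctrl = NA_real_,
    reported_hr = NA_real_, reported_hr_ci_low = NA_real_,
    reported_hr_ci_high = NA_real_,
    reported_adjusted = FALSE,
    sae_reporting_threshold = as.integer(reporting_threshold),
    stringsAsFactors = FALSE
  )
  validate_aggregates(agg)
}

#' Validate an aggregate trial table
#'
#' @param df aggregate data frame (one row per trial x outcome).
#' @return `df` invisibly if valid, else an error naming offending rows.
#' @export
validate_aggregates <- function(df) {
  for (col in setdiff(AGGREGATE_COLUMNS, names(df))) {
    df[[col]] <- switch(col,
      reported_adjusted = FALSE,
      sae_reporting_threshold = 1L,
      NA_real_
    )
  }
  df <- df[, AGGREGATE_COLUMNS]
  problems <- character(0)
  i <- which(!is.na(df$events_treat) & df$events_treat > df$n_treat)
  if (length(i)) problems <- c(problems, paste0("row ", i, ": events_treat > n_treat"))
  i <- which(!is.na(df$events_ctrl) & df$events_ctrl > df$n_ctrl)
  if (length(i)) problems <- c(problems, paste0("row ", i, ": events_ctrl > n_ctrl"))
  hr_full <- !is.na(df$reported_hr) & !is.na(df$reported_hr_ci_low) &
    !is.na(df$reported_hr_ci_high)
  i <- which(hr_full & !(df$reported_hr_ci_low < df$reported_hr &
                           df$reported_hr < df$reported_hr_ci_high))
  if (length(i)) problems <- c(problems, paste0("row ", i, ": HR CI must bracket the point"))
  i <- which(!is.na(df$sae_reporting_threshold) & df$sae_reporting_threshold < 1)
  if (length(i)) problems <- c(problems, paste0("row ", i, ": sae_reporting_threshold < 1"))
  if (length(problems) > 0) {
    stop("aggregate table validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(df)
}

#' Read / write aggregate trial tables
#'
#' One row per trial and outcome, with per-arm counts
#' (`events_treat`, `n_treat`, `events_ctrl`, `n_ctrl`), continuous
#' summaries (`mean_*`, `sd_*`), optionally a published hazard ratio with
#' its 95% CI, the `reported_adjusted` flag and the trial's
#' `sae_reporting_threshold` (1 = full reporting).
#'
#' @param path CSV path.
#' @return `read_aggregates()` returns a validated `data.frame`;
#'   `write_aggregates()` returns `path` invisibly.
#' @export
read_aggregates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if (!all(c("trial_id", "outcome") %in% names(df))) {
    stop("aggregate CSV must contain trial_id and outcome columns",
         call. = FALSE)
  }
  if ("reported_adjusted" %in% names(df)) {
    df$reported_adjusted <- as.logical(df$reported_adjusted)
  }
  validate_aggregates(df)
}

#' @rdname read_aggregates
#' @param df validated aggregate data frame.
#' @export
write_aggregates <- function(df, path) {
  df <- validate_aggregates(df)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
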