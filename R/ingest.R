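#' Read a tag-resight sightings file
#'
#' Reads long-format sighting records, one row per animal-year observation.
#' The file must be comma-separated UTF-8 with a header naming the five
#' required columns. Rows duplicated on (animal_id, obs_year, obs_colony)
#' are collapsed to one record; an observation year before the birth year is
#' an impossible age and is rejected.
#'
#' @param path Path to a CSV file with columns `animal_id`, `birth_colony`,
#'   `birth_year`, `obs_year`, `obs_colony`.
#' @param colonies Optional character vector of exactly two colony labels.
#'   When omitted, the labels found in the file are used (there must be at
#'   most two). Labels outside this set are an error.
#' @return A data.frame of sighting records sorted by (animal_id, obs_year),
#'   with a `"colonies"` attribute giving the two-element label set.
#' @export
read_sightings <- function(path, colonies = NULL) {
  if (!file.exists(path)) stop("sightings file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  req <- c("animal_id", "birth_colony", "birth_year", "obs_year",
           "obs_colony")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0)
    stop("sightings file is missing column(s): ",
         paste(miss, collapse = ", "))
  raw <- raw[req]
  for (col in c("birth_year", "obs_year")) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    bad <- which(is.na(v) & nzchar(raw[[col]]))
    if (length(bad) > 0)
      stop("malformed ", col, " at data line ", bad[1], ": '",
           raw[[col]][bad[1]], "'")
    if (anyNA(v)) stop("empty ", col, " at data line ", which(is.na(v))[1])
    raw[[col]] <- v
  }
  seen <- sort(unique(c(raw$birth_colony, raw$obs_colony)))
  if (is.null(colonies)) {
    colonies <- seen
    if (length(colonies) > 2)
      stop("more than two colony labels in file: ",
           paste(colonies, collapse = ", "))
    if (length(colonies) == 0) colonies <- character(0)
  } else {
    if (length(colonies) != 2)
      stop("'colonies' must name exactly two colonies")
    unknown <- setdiff(seen, colonies)
    if (length(unknown) > 0)
      stop("unknown colony label(s): ", paste(unknown, collapse = ", "))
  }
  bad_age <- which(raw$obs_year < raw$birth_year)
  if (length(bad_age) > 0)
    stop("obs_year before birth_year at data line ", bad_age[1],
         " (animal ", raw$animal_id[bad_age[1]], ")")
  ## a tag must map to one birth colony and one birth year
  per <- unique(raw[c("animal_id", "birth_colony", "birth_year")])
  dup <- per$animal_id[duplicated(per$animal_id)]
  if (length(dup) > 0)
    stop("inconsistent birth records for animal(s): ",
         paste(unique(dup), collapse = ", "))
  rec <- raw[!duplicated(raw[c("animal_id", "obs_year", "obs_colony")]), ]
  rec <- rec[order(rec$animal_id, rec$obs_year, rec$obs_colony), ]
  rownames(rec) <- NULL
  attr(rec, "colonies") <- colonies
  rec
}

#' Read a cohort tagging-totals file
#'
#' @param path CSV with columns `birth_year`, `colony`, `n_tagged`.
#' @return A data.frame with those columns, years as integers.
#' @export
read_tagged_totals <- function(path) {
  tt <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("birth_year", "colony", "n_tagged")
  if (!all(req %in% names(tt)))
    stop("tagging-totals file must have columns: ",
         paste(req, collapse = ", "))
  tt$birth_year <- as.integer(tt$birth_year)
  tt$n_tagged <- as.integer(tt$n_tagged)
  if (any(tt$n_tagged < 0)) stop("negative tagging total")
  tt[req]
}

colony_set <- function(records, colonies = NULL) {
  if (is.null(colonies)) colonies <- attr(records, "colonies")
  if (is.null(colonies))
    colonies <- sort(unique(c(records$birth_colony, records$obs_colony)))
  if (length(colonies) > 2) stop("more than two colonies")
  colonies
}

## One observation per animal-year: when an animal was recorded at both
## colonies in the same season the record at the earlier-listed colony in
## `colonies` wins (a declared priority, with a warning), since observation
## dates within the season are not retained.
resolve_season <- function(records, colonies) {
  if (nrow(records) == 0) return(records)
  prio <- match(records$obs_colony, colonies)
  o <- order(records$animal_id, records$obs_year, prio)
  rec <- records[o, ]
  key <- paste(rec$animal_id, rec$obs_year, sep = "\r")
  dupe <- duplicated(key)
  if (any(dupe))
    warning(sum(dupe), " within-season multi-colony sighting(s) resolved ",
            "by colony priority (", paste(colonies, collapse = " > "), ")")
  rec <- rec[!dupe, ]
  rownames(rec) <- NULL
  rec
}

#' Tally cohort dispersal counts
#'
#' Reduces sighting records to the per-cohort table of tagged, breeding,
#' resident and emigrant counts. Each animal observed at breeding age
#' (`obs_year - birth_year >= min_breeding_age`) is counted once, assigned
#' to resident or emigrant by the colony of its first breeding-age
#' observation; later moves are adult dispersal and do not change the
#' assignment. Animals never seen at breeding age contribute only to the
#' tagged total.
#'
#' @param records Sighting records from [read_sightings()] (or the
#'   simulator).
#' @param tagged_totals data.frame with `birth_year`, `colony`, `n_tagged`.
#' @param min_breeding_age Minimum breeding age in years (default 3).
#' @param colonies Optional two-element colony label set.
#' @return A data.frame with columns `birth_year`, `colony`, `tagged`,
#'   `breeding`, `resident`, `emigrant`, one row per cohort in
#'   `tagged_totals`.
#' @export
tally_cohorts <- function(records, tagged_totals, min_breeding_age = 3,
                          colonies = NULL) {
  colonies <- colony_set(records, colonies)
  age <- records$obs_year - records$birth_year
  br <- resolve_season(records[age >= min_breeding_age, , drop = FALSE],
                       colonies)
  first <- br[!duplicated(br$animal_id), , drop = FALSE]
  out <- tagged_totals
  names(out)[names(out) == "n_tagged"] <- "tagged"
  key_out <- paste(out$birth_year, out$colony)
  key_first <- paste(first$birth_year, first$birth_colony)
  stray <- setdiff(key_first, key_out)
  if (length(stray) > 0)
    stop("breeding records for cohort(s) absent from tagging totals: ",
         paste(stray, collapse = "; "))
  out$breeding <- as.integer(table(factor(key_first, levels = key_out)))
  res <- first[first$obs_colony == first$birth_colony, ]
  out$resident <- as.integer(table(factor(paste(res$birth_year,
                                                res$birth_colony),
                                          levels = key_out)))
  out$emigrant <- out$breeding - out$resident
  if (any(out$breeding > out$tagged))
    stop("more breeders than tagged animals in cohort(s): ",
         paste(key_out[out$breeding > out$tagged], collapse = "; "))
  rownames(out) <- NULL
  out
}

#' Tally reappearance of breeding females
#'
#' Every breeding-age observation in years up to `final_year - 1` is one
#' trial; the trial succeeds if the female is observed anywhere the
#' following year, classified as the same or the opposite colony. A female
#' seen in k qualifying years contributes k trials. The final study year is
#' excluded as a year-1 location because its year-2 outcome is unobserved.
#'
#' @inheritParams tally_cohorts
#' @param final_year Last year with complete search effort; trials use
#'   years `<= final_year - 1` and outcomes years `<= final_year`.
#' @return A data.frame with columns `colony`, `trials`, `same`, `other`.
#' @export
tally_reappearance <- function(records, final_year, min_breeding_age = 3,
                               colonies = NULL) {
  colonies <- colony_set(records, colonies)
  age <- records$obs_year - records$birth_year
  br <- resolve_season(records[age >= min_breeding_age &
                                 records$obs_year <= final_year, ,
                               drop = FALSE], colonies)
  if (nrow(br) == 0 || min(br$obs_year) > final_year - 1)
    stop("no breeding records at or before final_year - 1 = ",
         final_year - 1)
  y1 <- br[br$obs_year <= final_year - 1, , drop = FALSE]
  nxt_key <- paste(br$animal_id, br$obs_year, sep = "\r")
  look <- match(paste(y1$animal_id, y1$obs_year + 1, sep = "\r"), nxt_key)
  outcome <- ifelse(is.na(look), "none",
                    ifelse(br$obs_colony[look] == y1$obs_colony,
                           "same", "other"))
  data.frame(
    colony = colonies,
    trials = as.integer(table(factor(y1$obs_colony, levels = colonies))),
    same = as.integer(table(factor(y1$obs_colony[outcome == "same"],
                                   levels = colonies))),
    other = as.integer(table(factor(y1$obs_colony[outcome == "other"],
                                    levels = colonies))))
}

#' Adult dispersal rate from reappearance counts
#'
#' Among females observed breeding in consecutive years, the fraction at
#' the opposite colony in the second year is a direct estimate of annual
#' adult dispersal.
#'
#' @param reapp Reappearance table from [tally_reappearance()].
#' @return A list with `pairs` (consecutive-year observation pairs),
#'   `movers` (pairs at the opposite colony in year 2), and `rate`.
#' @export
tally_adult_dispersal <- function(reapp) {
  pairs <- sum(reapp$same) + sum(reapp$other)
  if (pairs == 0) stop("no consecutive-year pairs; adult rate undefined")
  movers <- sum(reapp$other)
  list(pairs = pairs, movers = movers, rate = movers / pairs)
}

#' Pooled age distribution of observed breeding females
#'
#' Counts distinct animal-age observations per colony of observation,
#' pooled over all calendar years. Under detection that is constant across
#' years and adult ages, the ratio of successive age counts estimates the
#' annual return rate.
#'
#' @inheritParams tally_cohorts
#' @param max_age Oldest age tabulated (default 25).
#' @return A data.frame with columns `colony`, `age`, `count`, covering
#'   ages `min_breeding_age:max_age` for each colony.
#' @export
tally_ages <- function(records, min_breeding_age = 3, max_age = 25,
                       colonies = NULL) {
  colonies <- colony_set(records, colonies)
  age <- records$obs_year - records$birth_year
  br <- resolve_season(records[age >= min_breeding_age, , drop = FALSE],
                       colonies)
  ages <- min_breeding_age:max_age
  grid <- expand.grid(age = ages, colony = colonies,
                      stringsAsFactors = FALSE)[c("colony", "age")]
  a <- br$obs_year - br$birth_year
  tab <- table(factor(br$obs_colony, levels = colonies),
               factor(a, levels = ages))
  ## expand.grid varies age fastest; table() gives colony x age -- align
  grid$count <- as.integer(t(tab))
  rownames(grid) <- NULL
  grid
}
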