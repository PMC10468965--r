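# Data model, CSV I/O and sample-filtering rules for stomach-content tables.

#' The closed prey-category vocabulary
#'
#' Stomach contents are aggregated into ten broad prey categories; finer
#' taxonomic resolution is out of scope. All readers reject category strings
#' outside this vocabulary, and diet matrices carry all ten columns in this
#' fixed order.
#'
#' @return Character vector of the ten prey-category labels.
#' @export
#' @examples
#' prey_categories()
prey_categories <- function() {
  c("fishes", "reptiles", "mammals", "birds", "crustaceans", "gastropods",
    "insects_arachnids", "seeds", "amphibians", "horseshoe_crabs")
}

.IND_COLS <- c("individual_id", "population", "capture_date",
               "total_length_cm", "snout_vent_length_cm", "sex",
               "capture_salinity_ppt", "recapture")
.PREY_COLS <- c("individual_id", "prey_category", "item_count", "wet_mass_g")

#' Construct a validated diet dataset
#'
#' Bundles a table of captured individuals with a table of per-stomach prey
#' observations and validates both against the data model: positive total
#' lengths, snout-vent length not exceeding total length, non-negative
#' salinity, item counts of at least one, non-negative wet masses, prey
#' categories drawn from [prey_categories()], and referential integrity
#' (every observation resolves to an individual). Duplicate
#' `individual_id` values are permitted only when all but the
#' earliest-dated record are flagged as recaptures.
#'
#' @param individuals Data frame with columns `individual_id`, `population`,
#'   `capture_date` (`Date`), `total_length_cm`, `snout_vent_length_cm`,
#'   `sex` (`"M"`, `"F"` or `"unknown"`), `capture_salinity_ppt`,
#'   `recapture` (logical). Optional measurements may be `NA`.
#' @param observations Data frame with columns `individual_id`,
#'   `prey_category`, `item_count`, `wet_mass_g`. One row per
#'   individual-by-category aggregate (or finer; rows for the same
#'   individual and category are summed when the diet matrix is built).
#' @param provenance Character vector of free-text notes recording source
#'   files and applied filters.
#' @return An object of class `diet_dataset`.
#' @seealso [read_diet_tables()], [filter_analysis_set()],
#'   [build_diet_matrix()]
#' @export
diet_dataset <- function(individuals, observations, provenance = character()) {
  stopifnot(is.data.frame(individuals), is.data.frame(observations))
  miss <- setdiff(.IND_COLS, names(individuals))
  if (length(miss) > 0) {
    stop("schema error: individuals table is missing column(s) ",
         paste(sQuote(miss), collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(.PREY_COLS, names(observations))
  if (length(miss) > 0) {
    stop("schema error: prey table is missing column(s) ",
         paste(sQuote(miss), collapse = ", "), call. = FALSE)
  }
  individuals$individual_id <- as.character(individuals$individual_id)
  individuals$population <- as.character(individuals$population)
  if (!inherits(individuals$capture_date, "Date")) {
    individuals$capture_date <- as.Date(individuals$capture_date)
  }
  sex <- as.character(individuals$sex)
  sex[is.na(sex) | sex == ""] <- "unknown"
  bad_sex <- setdiff(unique(sex), c("M", "F", "unknown"))
  if (length(bad_sex) > 0) {
    stop("invalid sex value(s): ", paste(sQuote(bad_sex), collapse = ", "),
         " (expected M, F or unknown)", call. = FALSE)
  }
  individuals$sex <- sex
  individuals$recapture <- as.logical(individuals$recapture)
  if (anyNA(individuals$recapture)) {
    stop("recapture flag must be true or false for every individual",
         call. = FALSE)
  }

  tl <- individuals$total_length_cm
  if (any(!is.na(tl) & tl <= 0)) {
    stop("total_length_cm must be positive; offending id(s): ",
         .fmt_ids(individuals$individual_id[!is.na(tl) & tl <= 0]),
         call. = FALSE)
  }
  svl <- individuals$snout_vent_length_cm
  both <- !is.na(tl) & !is.na(svl)
  if (any(both & svl > tl)) {
    stop("snout_vent_length_cm exceeds total_length_cm for id(s): ",
         .fmt_ids(individuals$individual_id[both & svl > tl]), call. = FALSE)
  }
  sal <- individuals$capture_salinity_ppt
  if (any(!is.na(sal) & sal < 0)) {
    stop("capture_salinity_ppt must be non-negative", call. = FALSE)
  }

  # duplicate ids: tolerated only for recapture records after the first capture
  dup_ids <- unique(individuals$individual_id[duplicated(individuals$individual_id)])
  for (id in dup_ids) {
    rows <- individuals[individuals$individual_id == id, , drop = FALSE]
    first <- which.min(rows$capture_date)
    if (any(!rows$recapture[-first])) {
      stop("duplicate individual_id ", sQuote(id),
           " with unflagged later record(s); only recapture records may repeat an id",
           call. = FALSE)
    }
  }

  observations$individual_id <- as.character(observations$individual_id)
  observations$prey_category <- as.character(observations$prey_category)
  bad_cat <- setdiff(unique(observations$prey_category), prey_categories())
  if (length(bad_cat) > 0) {
    stop("unknown prey categor", if (length(bad_cat) > 1) "ies: " else "y: ",
         paste(sQuote(bad_cat), collapse = ", "),
         " (not in the 10-category vocabulary)", call. = FALSE)
  }
  cnt <- observations$item_count
  if (anyNA(cnt) || any(cnt < 1) || any(cnt != round(cnt))) {
    stop("item_count must be a positive integer for every prey row",
         call. = FALSE)
  }
  observations$item_count <- as.integer(round(cnt))
  wm <- observations$wet_mass_g
  if (anyNA(wm) || any(wm < 0)) {
    stop("wet_mass_g must be non-negative for every prey row", call. = FALSE)
  }
  orphan <- setdiff(unique(observations$individual_id),
                    individuals$individual_id)
  if (length(orphan) > 0) {
    stop("referential error: prey rows reference unknown individual id(s): ",
         .fmt_ids(orphan), call. = FALSE)
  }

  structure(list(individuals = individuals,
                 observations = observations,
                 provenance = as.character(provenance)),
            class = "diet_dataset")
}

.fmt_ids <- function(ids) paste(sQuote(unique(ids)), collapse = ", ")

#' @export
print.diet_dataset <- function(x, ...) {
  cat("Diet dataset:", nrow(x$individuals), "individual record(s),",
      nrow(x$observations), "prey observation(s)\n")
  pops <- table(x$individuals$population)
  cat("Populations:",
      paste(sprintf("%s (n=%d)", names(pops), as.integer(pops)),
            collapse = ", "), "\n")
  if (length(x$provenance) > 0) {
    cat("Provenance:\n")
    cat(paste0("  - ", x$provenance, collapse = "\n"), "\n")
  }
  invisible(x)
}

.read_csv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = character())
}

.parse_num <- function(x, col, path) {
  x <- trimws(x)
  blank <- x == "" | is.na(x)
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!blank & is.na(v))
  if (length(bad) > 0) {
    stop(sprintf("unparseable numeric in column '%s' of %s at data row(s) %s",
                 col, basename(path), paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  v
}

.parse_date <- function(x, col, path) {
  x <- trimws(x)
  v <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(!(x == "" | is.na(x)) & is.na(v))
  if (length(bad) > 0) {
    stop(sprintf("unparseable ISO-8601 date in column '%s' of %s at data row(s) %s",
                 col, basename(path), paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  v
}

.parse_bool <- function(x, col, path) {
  key <- tolower(trimws(x))
  v <- rep(NA, length(key))
  v[key %in% c("true", "t", "1")] <- TRUE
  v[key %in% c("false", "f", "0")] <- FALSE
  bad <- which(is.na(v))
  if (length(bad) > 0) {
    stop(sprintf("unparseable boolean in column '%s' of %s at data row(s) %s (use true/false)",
                 col, basename(path), paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  v
}

#' Read individual and prey tables from CSV
#'
#' Reads the two-file CSV layout (see Details), validates it, and returns a
#' [diet_dataset()]. Parsing is strict: missing required columns, unknown
#' prey categories, unparseable numerics/dates (reported with their row
#' number) and prey rows referencing absent individuals are all errors,
#' never silent coercions. Input row order is preserved.
#'
#' @details
#' `individuals_path` must have the header
#' `individual_id,population,capture_date,total_length_cm,snout_vent_length_cm,sex,capture_salinity_ppt,recapture`
#' with ISO-8601 dates, `true`/`false` recapture flags and empty strings for
#' missing optional fields. `prey_path` must have the header
#' `individual_id,prey_category,item_count,wet_mass_g` with categories from
#' [prey_categories()].
#'
#' @param individuals_path,prey_path Paths to the two CSV files.
#' @return A validated `diet_dataset`.
#' @seealso [write_diet_tables()] for the inverse operation.
#' @export
read_diet_tables <- function(individuals_path, prey_path) {
  ind_raw <- .read_csv_strict(individuals_path)
  prey_raw <- .read_csv_strict(prey_path)
  miss <- setdiff(.IND_COLS, names(ind_raw))
  if (length(miss) > 0) {
    stop("schema error: ", basename(individuals_path),
         " is missing required column(s) ",
         paste(sQuote(miss), collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(.PREY_COLS, names(prey_raw))
  if (length(miss) > 0) {
    stop("schema error: ", basename(prey_path),
         " is missing required column(s) ",
         paste(sQuote(miss), collapse = ", "), call. = FALSE)
  }
  individuals <- data.frame(
    individual_id = trimws(ind_raw$individual_id),
    population = trimws(ind_raw$population),
    capture_date = .parse_date(ind_raw$capture_date, "capture_date",
                               individuals_path),
    total_length_cm = .parse_num(ind_raw$total_length_cm, "total_length_cm",
                                 individuals_path),
    snout_vent_length_cm = .parse_num(ind_raw$snout_vent_length_cm,
                                      "snout_vent_length_cm",
                                      individuals_path),
    sex = trimws(ind_raw$sex),
    capture_salinity_ppt = .parse_num(ind_raw$capture_salinity_ppt,
                                      "capture_salinity_ppt",
                                      individuals_path),
    recapture = .parse_bool(ind_raw$recapture, "recapture", individuals_path),
    stringsAsFactors = FALSE
  )
  observations <- data.frame(
    individual_id = trimws(prey_raw$individual_id),
    prey_category = trimws(prey_raw$prey_category),
    item_count = .parse_num(prey_raw$item_count, "item_count", prey_path),
    wet_mass_g = .parse_num(prey_raw$wet_mass_g, "wet_mass_g", prey_path),
    stringsAsFactors = FALSE
  )
  diet_dataset(individuals, observations,
               provenance = sprintf("read from %s + %s",
                                    basename(individuals_path),
                                    basename(prey_path)))
}

#' Write a diet dataset back to the two-file CSV layout
#'
#' Inverse of [read_diet_tables()]: round-tripping a conforming pair of
#' files reproduces them cell for cell. Missing optional values are written
#' as empty strings; dates as ISO-8601; recapture flags as `true`/`false`.
#'
#' @param data A `diet_dataset`.
#' @param individuals_path,prey_path Output CSV paths.
#' @return Invisibly, `data`.
#' @export
write_diet_tables <- function(data, individuals_path, prey_path) {
  stopifnot(inherits(data, "diet_dataset"))
  ind <- data$individuals
  out_ind <- data.frame(
    individual_id = ind$individual_id,
    population = ind$population,
    capture_date = format(ind$capture_date, "%Y-%m-%d"),
    total_length_cm = .fmt_num(ind$total_length_cm),
    snout_vent_length_cm = .fmt_num(ind$snout_vent_length_cm),
    sex = ifelse(ind$sex == "unknown", "unknown", ind$sex),
    capture_salinity_ppt = .fmt_num(ind$capture_salinity_ppt),
    recapture = ifelse(ind$recapture, "true", "false"),
    stringsAsFactors = FALSE
  )
  obs <- data$observations
  out_obs <- data.frame(
    individual_id = obs$individual_id,
    prey_category = obs$prey_category,
    item_count = as.character(obs$item_count),
    wet_mass_g = .fmt_num(obs$wet_mass_g),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out_ind, individuals_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(out_obs, prey_path, row.names = FALSE, quote = FALSE)
  invisible(data)
}

.fmt_num <- function(x) ifelse(is.na(x), "", format(x, trim = TRUE, digits = 15, scientific = FALSE))

#' Configure the analysis-set filters
#'
#' Captures the sample-selection rules applied before any diet statistic:
#' restriction to a life stage by total length (juvenile means strictly less
#' than the cutoff, so an animal exactly at the cutoff is an adult), removal
#' of empty stomachs (individuals with no prey observations), and removal of
#' recaptures (records flagged as recaptures, plus later-dated duplicates of
#' an id, keeping the earliest capture). The salinity threshold only labels
#' habitat classes (freshwater/intermediate at or below the threshold,
#' marine above); no statistic conditions on it.
#'
#' @param juvenile_cutoff Total length in cm separating juveniles from
#'   adults; classification is strict less-than. Default 180.
#' @param drop_empty Drop individuals with zero prey observations. Default
#'   `TRUE`.
#' @param drop_recaptures Drop recapture records. Default `TRUE`.
#' @param life_stage One of `"juveniles_only"`, `"adults_only"`, `"all"`.
#'   Default `"juveniles_only"`.
#' @param salinity_class_threshold Salinity in ppt at or below which a
#'   capture site is classed freshwater/intermediate. Default 15.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(juvenile_cutoff = 180, drop_empty = TRUE,
                          drop_recaptures = TRUE,
                          life_stage = c("juveniles_only", "adults_only", "all"),
                          salinity_class_threshold = 15) {
  life_stage <- match.arg(life_stage)
  stopifnot(is.numeric(juvenile_cutoff), juvenile_cutoff > 0,
            is.numeric(salinity_class_threshold),
            salinity_class_threshold >= 0)
  structure(list(juvenile_cutoff = juvenile_cutoff,
                 drop_empty = isTRUE(drop_empty),
                 drop_recaptures = isTRUE(drop_recaptures),
                 life_stage = life_stage,
                 salinity_class_threshold = salinity_class_threshold),
            class = "filter_config")
}

#' Apply the sample filters and record a ledger
#'
#' Applies, in order, the recapture, life-stage and empty-stomach filters of
#' a [filter_config()]. The three filters are row predicates and therefore
#' commute; the order only affects how drops are attributed in the ledger.
#' The returned dataset carries a `filter_ledger` attribute (a data frame of
#' per-stage in/removed/out counts) and appends human-readable notes to the
#' provenance. A `salinity_class` column is added to the individuals table.
#'
#' @param data A `diet_dataset`.
#' @param cfg A `filter_config`; default [filter_config()].
#' @return The filtered `diet_dataset`, in input row order.
#' @export
filter_analysis_set <- function(data, cfg = filter_config()) {
  stopifnot(inherits(data, "diet_dataset"), inherits(cfg, "filter_config"))
  ind <- data$individuals
  keep <- rep(TRUE, nrow(ind))
  ledger <- data.frame(stage = character(), n_in = integer(),
                       n_removed = integer(), n_out = integer(),
                       stringsAsFactors = FALSE)
  note <- function(stage, before, after) {
    ledger[nrow(ledger) + 1L, ] <<- list(stage, before, before - after, after)
  }

  if (cfg$drop_recaptures) {
    before <- sum(keep)
    drop <- ind$recapture
    # defensive: also de-duplicate repeated ids, keeping the earliest capture
    for (id in unique(ind$individual_id[duplicated(ind$individual_id)])) {
      rows <- which(ind$individual_id == id)
      drop[rows[-which.min(ind$capture_date[rows])]] <- TRUE
    }
    keep <- keep & !drop
    note("recaptures", before, sum(keep))
  }

  if (cfg$life_stage != "all") {
    before <- sum(keep)
    tl <- ind$total_length_cm
    if (any(keep & is.na(tl))) {
      stop("total_length_cm is missing for id(s) ",
           .fmt_ids(ind$individual_id[keep & is.na(tl)]),
           " but a life-stage filter is enabled", call. = FALSE)
    }
    is_juv <- tl < cfg$juvenile_cutoff
    keep <- keep & if (cfg$life_stage == "juveniles_only") is_juv else !is_juv
    note(cfg$life_stage, before, sum(keep))
  }

  if (cfg$drop_empty) {
    before <- sum(keep)
    has_prey <- ind$individual_id %in% data$observations$individual_id
    keep <- keep & has_prey
    note("empty_stomachs", before, sum(keep))
  }

  if (sum(keep) == 0) {
    stop("all individuals were removed by the filters; ",
         "relax the filter configuration (downstream statistics are undefined)",
         call. = FALSE)
  }

  out_ind <- ind[keep, , drop = FALSE]
  rownames(out_ind) <- NULL
  out_ind$salinity_class <- ifelse(
    is.na(out_ind$capture_salinity_ppt), NA_character_,
    ifelse(out_ind$capture_salinity_ppt <= cfg$salinity_class_threshold,
           "freshwater_intermediate", "marine"))
  out_obs <- data$observations[
    data$observations$individual_id %in% out_ind$individual_id, , drop = FALSE]
  rownames(out_obs) <- NULL
  prov_new <- sprintf("filter %s: %d in, %d removed, %d out",
                      ledger$stage, ledger$n_in, ledger$n_removed, ledger$n_out)
  out <- diet_dataset(out_ind, out_obs,
                      provenance = c(data$provenance, prov_new))
  attr(out, "filter_ledger") <- ledger
  out
}

#' Aggregate a diet dataset into paired count and mass matrices
#'
#' Builds the individuals-by-categories matrices that every statistic in the
#' package consumes: `counts[i, j]` is the summed item count of category `j`
#' in stomach `i`, `masses[i, j]` the summed wet mass in grams. Columns
#' follow the fixed vocabulary order of [prey_categories()]; rows follow the
#' order of the individuals table. Individuals with no observations are
#' absent from the matrix (apply [filter_analysis_set()] first if empty
#' stomachs should be dropped explicitly).
#'
#' @param data A `diet_dataset` with unique individual ids (recaptures
#'   already removed).
#' @return An object of class `diet_matrix`: a list with integer matrix
#'   `counts` and numeric matrix `masses` sharing dimnames.
#' @export
build_diet_matrix <- function(data) {
  stopifnot(inherits(data, "diet_dataset"))
  obs <- data$observations
  if (nrow(obs) == 0) {
    stop("no prey observations; a diet matrix needs at least one", call. = FALSE)
  }
  ids <- data$individuals$individual_id
  if (anyDuplicated(ids)) {
    stop("duplicate individual ids remain; remove recaptures before building the matrix",
         call. = FALSE)
  }
  ids <- ids[ids %in% obs$individual_id]
  f_id <- factor(obs$individual_id, levels = ids)
  f_cat <- factor(obs$prey_category, levels = prey_categories())
  counts <- unclass(stats::xtabs(item_count ~ f_id + f_cat, data = obs))
  masses <- unclass(stats::xtabs(wet_mass_g ~ f_id + f_cat, data = obs))
  dimnames(counts) <- dimnames(masses) <-
    list(individual_id = ids, category = prey_categories())
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, masses = masses), class = "diet_matrix")
}

#' @export
print.diet_matrix <- function(x, ...) {
  cat("Diet matrix:", nrow(x$counts), "individuals x", ncol(x$counts),
      "categories;", sum(x$counts), "items,",
      format(sum(x$masses)), "g total\n")
  if (!is.null(attr(x, "mono_dropped_ids"))) {
    cat("Mono-category exclusion (", attr(x, "mono_mode"), "): dropped ",
        length(attr(x, "mono_dropped_ids")), " individual(s)\n", sep = "")
  }
  invisible(x)
}

#' Exclude mono-category stomachs before specialization analysis
#'
#' Individual specialization indices are biased by stomachs whose few items
#' all fall in one prey category. The `"literal"` mode drops rows whose
#' non-zero cells lie in exactly one category *and* whose total item count
#' is at most two (one or two items of a single category and nothing else).
#' The `"any_single_category"` mode drops every single-category row
#' regardless of count. Both readings are offered because either is
#' defensible; the dropped ids and mode are recorded as attributes
#' (`mono_dropped_ids`, `mono_mode`).
#'
#' @param matrix A `diet_matrix`.
#' @param mode `"literal"` (default) or `"any_single_category"`.
#' @return The reduced `diet_matrix`. Errors if fewer than two rows remain,
#'   since specialization statistics are undefined for fewer than two
#'   individuals.
#' @export
exclude_monocategory <- function(matrix,
                                 mode = c("literal", "any_single_category")) {
  stopifnot(inherits(matrix, "diet_matrix"))
  mode <- match.arg(mode)
  counts <- matrix$counts
  n_cat <- rowSums(counts > 0)
  n_items <- rowSums(counts)
  drop <- if (mode == "literal") n_cat == 1 & n_items <= 2 else n_cat == 1
  out <- structure(list(counts = counts[!drop, , drop = FALSE],
                        masses = matrix$masses[!drop, , drop = FALSE]),
                   class = "diet_matrix")
  attr(out, "mono_dropped_ids") <- rownames(counts)[drop]
  attr(out, "mono_mode") <- mode
  if (nrow(out$counts) < 2) {
    stop("fewer than 2 individuals remain after mono-category exclusion; ",
         "specialization statistics are undefined", call. = FALSE)
  }
  out
}
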