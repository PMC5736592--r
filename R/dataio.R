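# On-disk table schemas, validation, and eligibility filters.

# Required columns per table.  Order here is the canonical write order.
.isonet_schemas <- list(
  individuals = c("id", "sex", "birth_year", "mother_id", "natal_group"),
  membership  = c("id", "group", "year", "full_year"),
  grooming    = c("actor", "recipient", "group", "year", "seconds"),
  effort      = c("id", "group", "year", "hours_observed"),
  agonistic   = c("winner", "loser", "group", "year", "count"),
  pedigree    = c("id", "mother_id", "father_id")
)

# Identifier-valued columns, coerced to character on read (an all-NA
# column would otherwise come back logical).
.isonet_id_cols <- list(
  individuals = c("id", "sex", "mother_id", "natal_group"),
  membership  = c("id", "group"),
  grooming    = c("actor", "recipient", "group"),
  effort      = c("id", "group"),
  agonistic   = c("winner", "loser", "group"),
  pedigree    = c("id", "mother_id", "father_id")
)

.abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "isonet_error")))
}

#' Assemble and validate demography tables held in memory
#'
#' Bundles the six observational tables into a validated
#' `demography_tables` object, the common currency of the package.  The
#' same checks run when tables are read from disk with [load_tables()].
#'
#' @param individuals data frame: `id`, `sex` (`"F"`/`"M"`), `birth_year`,
#'   `mother_id` (may be `NA`), `natal_group` (may be `NA`).
#' @param membership data frame: `id`, `group`, `year`, `full_year`
#'   (logical).  One row per individual per year.
#' @param grooming data frame: `actor`, `recipient`, `group`, `year`,
#'   `seconds` groomed (actor grooms recipient).
#' @param effort data frame: `id`, `group`, `year`, `hours_observed`.
#' @param agonistic data frame: `winner`, `loser`, `group`, `year`,
#'   `count` of decided agonistic bouts.
#' @param pedigree data frame: `id`, `mother_id`, `father_id` (parents
#'   `NA` for founders), or `NULL` when no pedigree is available.
#' @return An object of class `demography_tables` (a named list of the
#'   validated data frames).
#' @seealso [load_tables()], [write_tables()], [filter_eligible()]
#' @export
demography_tables <- function(individuals, membership, grooming, effort,
                              agonistic, pedigree = NULL) {
  tables <- list(individuals = individuals, membership = membership,
                 grooming = grooming, effort = effort,
                 agonistic = agonistic, pedigree = pedigree)
  validate_tables(tables)
  structure(tables, class = "demography_tables")
}

#' @export
print.demography_tables <- function(x, ...) {
  cat("demography_tables:",
      nrow(x$individuals), "individuals,",
      nrow(x$membership), "membership rows,",
      nrow(x$grooming), "grooming rows,",
      nrow(x$effort), "effort rows,",
      nrow(x$agonistic), "agonistic rows,",
      if (is.null(x$pedigree)) "no pedigree" else
        paste(nrow(x$pedigree), "pedigree rows"), "\n")
  invisible(x)
}

.check_columns <- function(df, table_name, required) {
  if (!is.data.frame(df))
    .abort(sprintf("table '%s' is not a data frame", table_name),
           "isonet_schema_error")
  missing <- setdiff(required, names(df))
  if (length(missing))
    .abort(sprintf("table '%s' is missing column(s): %s", table_name,
                   paste(missing, collapse = ", ")),
           "isonet_schema_error")
}

.check_ids_known <- function(ids, known, table_name, column) {
  bad <- setdiff(unique(ids[!is.na(ids)]), known)
  if (length(bad))
    .abort(sprintf(
      "table '%s' column '%s' refers to id(s) absent from individuals: %s",
      table_name, column, paste(utils::head(bad, 5L), collapse = ", ")),
      "isonet_integrity_error")
}

validate_tables <- function(tables) {
  for (nm in setdiff(names(.isonet_schemas), "pedigree"))
    .check_columns(tables[[nm]], nm, .isonet_schemas[[nm]])
  ind <- tables$individuals
  if (anyDuplicated(ind$id))
    .abort("individuals$id contains duplicates", "isonet_schema_error")
  if (!all(ind$sex %in% c("F", "M")))
    .abort("individuals$sex must be 'F' or 'M'", "isonet_schema_error")
  known <- ind$id

  mem <- tables$membership
  if (anyDuplicated(mem[, c("id", "year")]))
    .abort("membership has more than one group for an (id, year)",
           "isonet_schema_error")
  if (!is.logical(mem$full_year))
    .abort("membership$full_year must be logical", "isonet_schema_error")
  .check_ids_known(mem$id, known, "membership", "id")
  by <- ind$birth_year[match(mem$id, ind$id)]
  if (any(mem$year < by))
    .abort("membership year precedes an individual's birth year",
           "isonet_schema_error")

  grm <- tables$grooming
  if (any(grm$actor == grm$recipient))
    .abort("grooming rows with actor == recipient", "isonet_schema_error")
  if (any(grm$seconds < 0))
    .abort("grooming$seconds must be non-negative", "isonet_schema_error")
  .check_ids_known(grm$actor, known, "grooming", "actor")
  .check_ids_known(grm$recipient, known, "grooming", "recipient")

  eff <- tables$effort
  if (any(eff$hours_observed <= 0))
    .abort("effort$hours_observed must be positive", "isonet_schema_error")
  if (anyDuplicated(eff[, c("id", "group", "year")]))
    .abort("duplicate effort rows for an (id, group, year)",
           "isonet_schema_error")
  .check_ids_known(eff$id, known, "effort", "id")

  ago <- tables$agonistic
  if (any(ago$winner == ago$loser))
    .abort("agonistic rows with winner == loser", "isonet_schema_error")
  if (any(ago$count < 1))
    .abort("agonistic$count must be a positive integer",
           "isonet_schema_error")
  .check_ids_known(ago$winner, known, "agonistic", "winner")
  .check_ids_known(ago$loser, known, "agonistic", "loser")

  ped <- tables$pedigree
  if (!is.null(ped)) {
    .check_columns(ped, "pedigree", .isonet_schemas$pedigree)
    if (anyDuplicated(ped$id))
      .abort("pedigree$id contains duplicates", "isonet_schema_error")
    for (col in c("mother_id", "father_id")) {
      p <- ped[[col]]
      bad <- setdiff(unique(p[!is.na(p)]), ped$id)
      if (length(bad))
        .abort(sprintf("pedigree %s refers to id(s) with no pedigree row: %s",
                       col, paste(utils::head(bad, 5L), collapse = ", ")),
               "isonet_integrity_error")
    }
    .check_pedigree_acyclic(ped)
  }
  invisible(TRUE)
}

.check_pedigree_acyclic <- function(ped) {
  # Kahn-style peel: founders first; leftovers imply a cycle.
  remaining <- ped$id
  mo <- ped$mother_id
  fa <- ped$father_id
  repeat {
    founder <- !(mo %in% remaining) & !(fa %in% remaining)
    drop <- remaining[founder] # parents already peeled (or NA)
    keep <- !founder
    if (!any(keep)) return(invisible(TRUE))
    if (!length(drop))
      .abort("pedigree contains a cycle", "isonet_schema_error")
    remaining <- remaining[keep]
    mo <- mo[keep]
    fa <- fa[keep]
  }
}

#' Read the observational tables from CSV files
#'
#' Reads the six CSV tables, optionally renaming columns through a
#' mapping (so a deposited file with different headers can be adapted),
#' and validates schemas, invariants and referential integrity.
#'
#' @param paths Named character vector or list with elements
#'   `individuals`, `membership`, `grooming`, `effort`, `agonistic` and
#'   optionally `pedigree`, each an existing CSV file.
#' @param col_map Optional named list, one element per table, each a
#'   named character vector mapping the schema column name to the column
#'   name used in the file, e.g.
#'   `list(grooming = c(actor = "groomer", recipient = "groomee"))`.
#' @return A validated [demography_tables()] object.
#' @export
load_tables <- function(paths, col_map = NULL) {
  need <- setdiff(names(.isonet_schemas), "pedigree")
  missing <- setdiff(need, names(paths))
  if (length(missing))
    .abort(paste("load_tables: missing path(s) for:",
                 paste(missing, collapse = ", ")), "isonet_schema_error")
  read_one <- function(nm) {
    path <- paths[[nm]]
    if (is.null(path)) return(NULL)
    if (!file.exists(path))
      .abort(paste("file not found:", path), "isonet_schema_error")
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    for (cc in names(df)) # empty fields in character columns are missing
      if (is.character(df[[cc]])) df[[cc]][df[[cc]] == ""] <- NA
    map <- col_map[[nm]]
    if (!is.null(map)) {
      idx <- match(unname(map), names(df))
      if (anyNA(idx))
        .abort(sprintf("col_map for '%s' names absent column(s): %s", nm,
                       paste(map[is.na(idx)], collapse = ", ")),
               "isonet_schema_error")
      names(df)[idx] <- names(map)
    }
    for (cc in intersect(.isonet_id_cols[[nm]], names(df)))
      df[[cc]] <- as.character(df[[cc]])
    df
  }
  tabs <- lapply(stats::setNames(nm = names(.isonet_schemas)), read_one)
  if (!is.null(tabs$membership))
    tabs$membership$full_year <- as.logical(tabs$membership$full_year)
  demography_tables(tabs$individuals, tabs$membership, tabs$grooming,
                    tabs$effort, tabs$agonistic, tabs$pedigree)
}

#' Write the observational tables to CSV files
#'
#' Inverse of [load_tables()]: writes each table as an uncompressed CSV
#' with the canonical column order.  `load_tables(write_tables(x, dir))`
#' round-trips.
#'
#' @param tables A [demography_tables()] object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (nm in names(.isonet_schemas)) {
    df <- tables[[nm]]
    if (is.null(df)) next
    path <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(df[, .isonet_schemas[[nm]]], path, row.names = FALSE,
                     quote = FALSE, na = "")
    paths[nm] <- path
  }
  invisible(paths)
}

#' Identify adults eligible for analysis in a year
#'
#' Applies the study's eligibility filter: mature adults (age at least
#' `min_age` years, age = year - birth year) that were members of their
#' group for the full year.  Animals that entered or left a group part
#' way through the year are excluded.
#'
#' @param tables A [demography_tables()] object.
#' @param year Integer observation year.
#' @param min_age Adult age threshold in years (default 6).
#' @return Named list mapping each group observed that year to the
#'   character vector of eligible ids (possibly empty).
#' @export
filter_eligible <- function(tables, year, min_age = 6) {
  mem <- tables$membership
  mem <- mem[mem$year == year & mem$full_year, , drop = FALSE]
  age <- year - tables$individuals$birth_year[match(mem$id,
                                                    tables$individuals$id)]
  mem <- mem[age >= min_age, , drop = FALSE]
  groups <- sort(unique(tables$membership$group[tables$membership$year == year]))
  out <- lapply(stats::setNames(nm = groups),
                function(g) sort(mem$id[mem$group == g]))
  out
}

#' Assemble the analysis-ready dataset for one group-year
#'
#' Restricts grooming, observation effort and agonistic records to the
#' eligible adults of one group in one year.  Records involving
#' ineligible animals (juveniles, partial-year residents) are dropped.
#'
#' @inheritParams filter_eligible
#' @param group Group identifier.
#' @return An object of class `group_year_dataset`: list with `ids`
#'   (sorted), `grooming`, `effort` (named hours vector), `agonistic`,
#'   `group`, `year`.
#' @export
assemble_group_year <- function(tables, group, year, min_age = 6) {
  elig <- filter_eligible(tables, year, min_age)[[as.character(group)]]
  if (is.null(elig)) elig <- character()
  if (length(elig) < 2)
    .abort(sprintf("group %s in %s has %d eligible individual(s); need >= 2",
                   group, year, length(elig)), "isonet_degenerate_group_error")
  grm <- tables$grooming
  grm <- grm[grm$group == group & grm$year == year &
               grm$actor %in% elig & grm$recipient %in% elig, , drop = FALSE]
  eff <- tables$effort
  eff <- eff[eff$group == group & eff$year == year & eff$id %in% elig, ,
             drop = FALSE]
  hours <- stats::setNames(eff$hours_observed, eff$id)
  ago <- tables$agonistic
  ago <- ago[ago$group == group & ago$year == year &
               ago$winner %in% elig & ago$loser %in% elig, , drop = FALSE]
  structure(list(ids = elig, grooming = grm, effort = hours,
                 agonistic = ago, group = group, year = year),
            class = "group_year_dataset")
}

#' @export
print.group_year_dataset <- function(x, ...) {
  cat("group_year_dataset: group", x$group, "year", x$year, "-",
      length(x$ids), "adults,", nrow(x$grooming), "grooming rows\n")
  invisible(x)
}
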