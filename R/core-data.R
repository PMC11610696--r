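## Ingest and validation of the three input tables: community samples,
## taxon traits, station metadata. Everything is tidy (long) in memory;
## a wide station x taxon export is provided for inspection.

.sample_cols <- c("gradient_id", "station_id", "replicate_id", "taxon",
                  "abundance", "biomass")
.station_cols <- c("gradient_id", "station_id", "pressure_value",
                   "pressure_type", "pressure_scale", "gear", "depth_m",
                   "sediment", "salinity", "worsening")
.trait_cols <- c("taxon", "ecological_group", "besito_group",
                 "longevity_years", "score_mobility", "score_fragility",
                 "score_position", "score_size", "score_feeding",
                 "protected", "mean_individual_mass")

.normalize_taxon <- function(x) {
  stringr::str_squish(tolower(as.character(x)))
}

.apply_schema <- function(df, schema, required, where) {
  if (!is.null(schema)) {
    known <- schema[schema %in% names(df)]
    if (length(known) > 0) df <- dplyr::rename(df, !!!known)
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("schema error in ", where, ": missing required column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read community sample records
#'
#' Reads a long-format CSV of community samples: one row per
#' (gradient, station, replicate, taxon), with abundance (individuals per
#' sample) and/or biomass (grams per sample). Taxon names are normalized
#' (case and whitespace) before matching against the trait table.
#'
#' @param path CSV path (comma separated, header row, UTF-8).
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(taxon = "species_name", abundance = "count")`.
#' @return A tibble of validated sample records.
#' @export
read_samples <- function(path, schema = NULL) {
  stopifnot(file.exists(path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df <- .apply_schema(df, schema,
                      c("gradient_id", "station_id", "taxon"), path)
  if (!"replicate_id" %in% names(df)) df$replicate_id <- 1L
  if (!"abundance" %in% names(df)) df$abundance <- NA_real_
  if (!"biomass" %in% names(df)) df$biomass <- NA_real_
  validate_samples(dplyr::select(df, dplyr::all_of(.sample_cols)))
}

#' Validate sample records
#'
#' Checks non-negativity of abundance and biomass, presence of at least one
#' of the two per row, and uniqueness of (gradient, station, replicate,
#' taxon) after taxon-name normalization. Offending rows are reported by
#' row number.
#'
#' @param records A data frame of sample records.
#' @return The validated tibble, taxon names normalized.
#' @export
validate_samples <- function(records) {
  records <- tibble::as_tibble(records)
  records$taxon <- .normalize_taxon(records$taxon)
  bad_neg <- which(records$abundance < 0 | records$biomass < 0)
  if (length(bad_neg) > 0) {
    stop("validation error: negative abundance/biomass in row(s) ",
         paste(head(bad_neg, 5), collapse = ", "), call. = FALSE)
  }
  bad_empty <- which(is.na(records$abundance) & is.na(records$biomass))
  if (length(bad_empty) > 0) {
    stop("validation error: neither abundance nor biomass in row(s) ",
         paste(head(bad_empty, 5), collapse = ", "), call. = FALSE)
  }
  dups <- duplicated(records[, c("gradient_id", "station_id",
                                 "replicate_id", "taxon")])
  if (any(dups)) {
    stop("validation error: duplicated (gradient, station, replicate, taxon) ",
         "key in row(s) ", paste(head(which(dups), 5), collapse = ", "),
         call. = FALSE)
  }
  records
}

#' Read station metadata
#'
#' @inheritParams read_samples
#' @param samples Optional sample records; stations present in the metadata
#'   but absent from the samples are dropped with a warning, and an error is
#'   raised for sampled stations without metadata.
#' @return A tibble of station metadata.
#' @export
read_stations <- function(path, schema = NULL, samples = NULL) {
  stopifnot(file.exists(path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df <- .apply_schema(df, schema,
                      c("gradient_id", "station_id", "pressure_value",
                        "pressure_type"), path)
  for (col in setdiff(.station_cols, names(df))) df[[col]] <- NA
  df <- tibble::as_tibble(df[, .station_cols])
  ok_types <- c("trawling", "oxygen_depletion", "eutrophication", "pollution")
  if (!all(df$pressure_type %in% ok_types)) {
    stop("validation error: unknown pressure_type; expected one of ",
         paste(ok_types, collapse = ", "), call. = FALSE)
  }
  n_types <- dplyr::summarise(dplyr::group_by(df, .data$gradient_id),
                              n = dplyr::n_distinct(.data$pressure_type))
  if (any(n_types$n > 1)) {
    stop("validation error: pressure_type varies within a gradient",
         call. = FALSE)
  }
  if (is.null(df$worsening) || all(is.na(df$worsening))) {
    df$worsening <- ifelse(df$pressure_type == "oxygen_depletion",
                           "decreasing", "increasing")
  }
  if (!is.null(samples)) {
    key_s <- paste(samples$gradient_id, samples$station_id)
    key_m <- paste(df$gradient_id, df$station_id)
    orphan_meta <- !key_m %in% key_s
    if (any(orphan_meta)) {
      warning(sum(orphan_meta), " station(s) in metadata have no samples; ",
              "dropped", call. = FALSE)
      df <- df[!orphan_meta, ]
    }
    if (!all(key_s %in% key_m)) {
      stop("validation error: sampled station(s) lack metadata", call. = FALSE)
    }
  }
  df
}

#' Read the taxon trait table
#'
#' @inheritParams read_samples
#' @param config Indicator configuration; supplies the midpoints used to
#'   convert categorical longevity classes to years.
#' @return A tibble of per-taxon traits with normalized names.
#' @export
read_traits <- function(path, schema = NULL, config = indicator_config()) {
  stopifnot(file.exists(path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df <- .apply_schema(df, schema, "taxon", path)
  for (col in setdiff(.trait_cols, names(df))) df[[col]] <- NA
  df <- tibble::as_tibble(df[, .trait_cols])
  df$taxon <- .normalize_taxon(df$taxon)
  if (anyDuplicated(df$taxon)) {
    stop("validation error: duplicated taxon in trait table", call. = FALSE)
  }
  if (is.character(df$longevity_years)) {
    mid <- config$longevity_class_midpoints
    cls <- df$longevity_years %in% names(mid)
    num <- suppressWarnings(as.numeric(df$longevity_years))
    df$longevity_years <- ifelse(cls, unname(mid[df$longevity_years]), num)
  }
  validate_traits(df)
}

#' Validate a trait table
#'
#' @param traits Trait data frame.
#' @return The validated tibble.
#' @export
validate_traits <- function(traits) {
  traits <- tibble::as_tibble(traits)
  chk <- function(cond, msg) if (any(cond, na.rm = TRUE)) {
    stop("validation error in trait table: ", msg, call. = FALSE)
  }
  chk(!traits$ecological_group %in% c("I", "II", "III", "IV", "V", NA),
      "ecological_group outside I-V")
  chk(traits$besito_group < 1 | traits$besito_group > 5,
      "besito_group outside 1-5")
  chk(traits$longevity_years <= 0, "non-positive longevity")
  for (col in grep("^score_", names(traits), value = TRUE)) {
    chk(traits[[col]] < 0 | traits[[col]] > 3,
        paste(col, "outside 0-3"))
  }
  traits
}

#' Sum replicates into a station-by-taxon community table
#'
#' Replicate samples taken at the same station are summed, for abundance
#' and biomass separately, giving one record per (station, taxon). Raw
#' sample values are summed as collected (no standardization by sampled
#' area is applied before summation).
#'
#' @param records Sample records for a single gradient.
#' @return A tibble (station_id, taxon, abundance, biomass) with the
#'   gradient id attached as attribute `gradient_id`.
#' @export
aggregate_replicates <- function(records) {
  records <- tibble::as_tibble(records)
  gids <- unique(records$gradient_id)
  if (length(gids) != 1) {
    stop("aggregate_replicates() expects records from a single gradient; got ",
         length(gids), call. = FALSE)
  }
  sum_keep_na <- function(x) if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
  out <- records |>
    dplyr::group_by(.data$station_id, .data$taxon) |>
    dplyr::summarise(
      abundance = sum_keep_na(.data$abundance),
      biomass = sum_keep_na(.data$biomass),
      .groups = "drop"
    )
  attr(out, "gradient_id") <- gids
  out
}

#' Wide station-by-taxon matrix export
#'
#' @param community Output of [aggregate_replicates()].
#' @param value `"abundance"` or `"biomass"`.
#' @return A numeric matrix, stations as rows.
#' @export
community_matrix <- function(community, value = c("abundance", "biomass")) {
  value <- match.arg(value)
  wide <- tidyr::pivot_wider(
    community[, c("station_id", "taxon", value)],
    names_from = "taxon", values_from = dplyr::all_of(value),
    values_fill = 0
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- as.character(wide$station_id)
  m
}

#' Per-station trait coverage
#'
#' Fraction of each station's abundance (or biomass) that belongs to taxa
#' with the given trait assigned. Trait-based indices are only computed
#' where this coverage meets the configured threshold.
#'
#' @param community Output of [aggregate_replicates()].
#' @param traits Trait table.
#' @param field Trait name: one of the trait-table columns, or
#'   `"tdi_trait_scores"` meaning all five TDI trait scores present.
#' @param basis `"abundance"` or `"biomass"`.
#' @return Tibble (station_id, coverage).
#' @export
trait_coverage <- function(community, traits, field,
                           basis = c("abundance", "biomass")) {
  basis <- match.arg(basis)
  scored <- .trait_assigned(traits, field)
  community |>
    dplyr::mutate(.scored = .data$taxon %in% traits$taxon[scored]) |>
    dplyr::group_by(.data$station_id) |>
    dplyr::summarise(coverage = {
      w <- .data[[basis]]
      tot <- sum(w, na.rm = TRUE)
      if (!is.finite(tot) || tot == 0) NA_real_ else
        sum(w[.data$.scored], na.rm = TRUE) / tot
    }, .groups = "drop")
}

## logical index over trait rows: does this taxon have `field` assigned?
.trait_assigned <- function(traits, field) {
  score_cols <- c("score_mobility", "score_fragility", "score_position",
                  "score_size", "score_feeding")
  if (field == "tdi_trait_scores") {
    stats::complete.cases(traits[, score_cols])
  } else if (field %in% names(traits)) {
    !is.na(traits[[field]])
  } else {
    stop("unknown trait field: ", field, call. = FALSE)
  }
}
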