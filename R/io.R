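#' Read a species trait table
#'
#' Reads a CSV of per-species trait data (one row per species) and validates
#' it. Required columns (after applying `schema`): `species`, `neonatal_brain`,
#' `adult_brain`, `neonatal_body`, `maternal_body`, `gestation`,
#' `generation_time`. Masses are grams, gestation days, generation time years
#' (age at first reproduction). Rows with any missing required value are
#' dropped and reported; non-positive or non-numeric values in a required
#' column are an error. A `clade` column is optional (missing labels become
#' `"other"`).
#'
#' @param path CSV file path.
#' @param schema optional named character vector mapping required names to the
#'   file's column names, e.g. `c(species = "Taxon", gestation = "Gest_d")`.
#' @return a tibble of validated species records; dropped rows are reported
#'   via a message and recorded in the `dropped` attribute.
#' @export
read_species_table <- function(path, schema = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_species_table(raw, schema = schema)
}

species_cols <- c(
  "species", "neonatal_brain", "adult_brain", "neonatal_body",
  "maternal_body", "gestation", "generation_time"
)

#' Validate a species trait table
#'
#' Same contract as [read_species_table()] but starting from an in-memory
#' data frame; the synthetic generator funnels its tables through this.
#'
#' @inheritParams read_species_table
#' @param data a data frame of species records.
#' @export
validate_species_table <- function(data, schema = NULL) {
  data <- as_tibble(data)
  if (!is.null(schema)) {
    for (want in names(schema)) {
      have <- schema[[want]]
      if (!have %in% names(data)) {
        abort(paste0("schema column not found in file: ", have))
      }
      names(data)[names(data) == have] <- want
    }
  }
  missing_cols <- setdiff(species_cols, names(data))
  if (length(missing_cols)) {
    abort(paste0(
      "missing required columns: ", paste(missing_cols, collapse = ", ")
    ))
  }
  if (!"clade" %in% names(data)) data$clade <- "other"
  data$clade[is.na(data$clade)] <- "other"
  num_cols <- setdiff(species_cols, "species")
  for (cc in num_cols) {
    if (!is.numeric(data[[cc]])) {
      abort(paste0("column ", cc, " must be numeric"))
    }
  }
  ## species are not included when they have missing data
  complete <- complete.cases(data[species_cols])
  dropped <- data$species[!complete]
  if (length(dropped)) {
    inform(paste0(
      length(dropped), " row(s) dropped for missing data: ",
      paste(head(dropped, 5), collapse = ", ")
    ))
  }
  data <- data[complete, , drop = FALSE]
  bad <- purrr::map(num_cols, function(cc) data$species[data[[cc]] <= 0])
  bad <- unique(unlist(bad))
  if (length(bad)) {
    abort(paste0(
      "non-positive trait values for: ", paste(head(bad, 5), collapse = ", ")
    ))
  }
  dup <- data$species[duplicated(normalize_name(data$species))]
  if (length(dup)) {
    abort(paste0("duplicate species name(s): ", paste(dup, collapse = ", ")))
  }
  out <- data[c(species_cols, "clade", setdiff(names(data), c(species_cols, "clade")))]
  attr(out, "dropped") <- dropped
  out
}

#' Write a species trait table to CSV
#'
#' @param data a species table (tibble).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Match a phylogeny against a species table and prune both
#'
#' Species names are matched case-insensitively with underscores and spaces
#' interchangeable. The returned tree is pruned to the common species (branch
#' lengths along retained paths are preserved; suppressed unary nodes have
#' their lengths summed, as done by [ape::keep.tip()]), and the returned table
#' is subset and reordered to the tree's tip order.
#'
#' @param tree a rooted `phylo`.
#' @param table a species table with a `species` column.
#' @return a list with elements `tree` and `table`.
#' @export
match_and_prune <- function(tree, table) {
  tip_norm <- normalize_name(tree$tip.label)
  tab_norm <- normalize_name(table$species)
  if (anyDuplicated(tip_norm)) {
    abort("tip labels collide after name normalization")
  }
  if (anyDuplicated(tab_norm)) {
    abort("species names collide after name normalization")
  }
  common <- intersect(tip_norm, tab_norm)
  if (length(common) < 3) {
    abort("fewer than 3 species shared between tree and table")
  }
  keep <- tree$tip.label[tip_norm %in% common]
  pruned <- ape::keep.tip(tree, keep)
  idx <- match(normalize_name(pruned$tip.label), tab_norm)
  tab <- table[idx, , drop = FALSE]
  ## canonical labels: those of the tree
  tab$species <- pruned$tip.label
  list(tree = pruned, table = tab)
}

#' Read a neurodevelopmental event table
#'
#' CSV columns: `label`, `score` (event score in \[0, 1\]), `category`, and
#' `cortical_neurogenesis` (0/1). Events in excluded categories (whole-brain
#' size, sensory periphery/retina, whole-organism behaviour) are filtered out
#' before analysis.
#'
#' @param path CSV file path.
#' @param drop_excluded drop events whose `category` is `"excluded"`.
#' @return a tibble of events.
#' @export
read_event_table <- function(path, drop_excluded = TRUE) {
  ev <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("label", "score", "category", "cortical_neurogenesis")
  missing_cols <- setdiff(need, names(ev))
  if (length(missing_cols)) {
    abort(paste0("event table missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(ev$score < 0 | ev$score > 1)) {
    abort("event scores must lie in [0, 1]")
  }
  if (drop_excluded) ev <- ev[ev$category != "excluded", , drop = FALSE]
  as_tibble(ev)
}

#' Read a hominin specification table
#'
#' CSV columns: `species`, `ecv_cc` (endocranial volume, optional, may be NA),
#' `brain_mass` (adult brain mass, g; derived from `ecv_cc` via
#' [ecv_to_brain_mass()] when NA), `neonatal_body_mean`, `neonatal_body_min`,
#' `neonatal_body_max` (g), and optionally `observed_gestation` (days) for
#' extant species whose gestation is known rather than estimated.
#'
#' @param path CSV file path.
#' @param ecv_coef conversion spec passed to [ecv_to_brain_mass()] for rows
#'   with missing `brain_mass`.
#' @return a tibble.
#' @export
read_hominin_table <- function(path, ecv_coef = list(method = "identity", density = 1)) {
  h <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("species", "neonatal_body_mean", "neonatal_body_min", "neonatal_body_max")
  missing_cols <- setdiff(need, names(h))
  if (length(missing_cols)) {
    abort(paste0("hominin table missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"brain_mass" %in% names(h)) h$brain_mass <- NA_real_
  fill <- is.na(h$brain_mass)
  if (any(fill)) {
    if (!"ecv_cc" %in% names(h) || any(is.na(h$ecv_cc[fill]))) {
      abort("rows with missing brain_mass need an ecv_cc value")
    }
    h$brain_mass[fill] <- ecv_to_brain_mass(h$ecv_cc[fill], ecv_coef)
  }
  with_bounds <- !(h$neonatal_body_min <= h$neonatal_body_mean &
    h$neonatal_body_mean <= h$neonatal_body_max)
  if (any(with_bounds)) {
    abort("neonatal body mass must satisfy min <= mean <= max")
  }
  as_tibble(h)
}
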