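## Cohort container and readers.
##
## A cohort is a longitudinal table of stool samples: per-sample clinical
## covariates plus per-taxon 16S read counts grouped at the class level.
## Canonical covariates: subject_id, day_of_life, gestational_age (weeks at
## birth), postconceptional_age (unit declared in config, weeks by
## default), antibiotics (days or percent-of-days, declared in config), and
## open_room ("open"/"closed" nursery room).

COVARIATES_CONTINUOUS <- c("day_of_life", "gestational_age",
                           "postconceptional_age", "antibiotics")
COVARIATES_DISCRETE <- "open_room"
COVARIATES <- c(COVARIATES_CONTINUOUS, COVARIATES_DISCRETE)
OPEN_ROOM_LEVELS <- c("closed", "open")

#' Cohort configuration
#'
#' Column mapping and unit declarations used by [read_cohort()].  The
#' `column_map` maps canonical names to the column headers found in the
#' input file; taxa are every remaining column unless `taxa_columns` is
#' given.  Configurations can be stored as JSON (or YAML when the `yaml`
#' package is installed) and loaded with [read_cohort_config()].
#'
#' @param column_map Named character vector mapping canonical covariate
#'   names (`subject_id`, `day_of_life`, `gestational_age`,
#'   `postconceptional_age`, `antibiotics`, `open_room`) to input headers.
#' @param taxa_columns Optional character vector naming the taxon count
#'   columns; default: all columns not claimed by `column_map`.
#' @param pca_unit Unit of `postconceptional_age`: `"weeks"` or `"days"`.
#' @param antibiotics_unit `"days"` or `"percent"` of days of life.
#' @param min_fraction Default inclusion threshold for [select_taxa()].
#' @param duplicates How to treat repeated (subject, day) rows: `"error"`
#'   or `"sum"` (sum the counts, keep the first covariate row).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(column_map = NULL, taxa_columns = NULL,
                          pca_unit = c("weeks", "days"),
                          antibiotics_unit = c("percent", "days"),
                          min_fraction = 0.01,
                          duplicates = c("error", "sum")) {
  default_map <- stats::setNames(c("subject_id", COVARIATES),
                                 c("subject_id", COVARIATES))
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    bad <- setdiff(names(column_map), names(default_map))
    if (length(bad)) {
      stop("unknown canonical column(s) in column_map: ",
           paste(bad, collapse = ", "))
    }
    default_map[names(column_map)] <- column_map
  }
  structure(list(column_map = default_map,
                 taxa_columns = taxa_columns,
                 pca_unit = match.arg(pca_unit),
                 antibiotics_unit = match.arg(antibiotics_unit),
                 min_fraction = min_fraction,
                 duplicates = match.arg(duplicates)),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @param path Path to a JSON (or YAML) configuration file whose fields
#'   mirror the `cohort_config()` arguments.
#' @export
read_cohort_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configuration requires the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(cohort_config, raw[intersect(names(raw),
                                       names(formals(cohort_config)))])
}

#' Construct a cohort from a metadata frame and a count matrix
#'
#' Validates and assembles the package's central container: per-sample
#' covariates plus a nonnegative integer count matrix with one column per
#' taxon.  Rows are sorted by subject then day of life; day of life must be
#' strictly increasing within a subject (after optional duplicate
#' handling), and every sample must have at least one positive count.
#'
#' @param meta Data frame with columns `subject_id`, `day_of_life`,
#'   `gestational_age`, `postconceptional_age`, `antibiotics`, `open_room`.
#' @param counts Numeric matrix (samples x taxa) of nonnegative integers,
#'   with column names.
#' @param config A [cohort_config()].
#' @return An object of class `dbn_cohort` with elements `meta`, `counts`,
#'   `taxa`, `config`.
#' @export
as_cohort <- function(meta, counts, config = cohort_config()) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("count matrix must have taxon names")
  if (nrow(meta) != nrow(counts)) stop("meta and counts row mismatch")
  missing_cols <- setdiff(c("subject_id", COVARIATES), names(meta))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(counts))) stop("non-numeric or missing count value")
  if (any(counts < 0)) stop("negative count value")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integers")
  }
  counts <- round(counts)
  meta$subject_id <- as.character(meta$subject_id)
  meta$open_room <- normalize_open_room(meta$open_room)
  colnames(counts) <- normalize_taxon(colnames(counts))
  if (anyDuplicated(colnames(counts))) stop("duplicate taxon column names")

  ord <- order(meta$subject_id, meta$day_of_life)
  meta <- meta[ord, , drop = FALSE]
  counts <- counts[ord, , drop = FALSE]

  dup <- duplicated(meta[c("subject_id", "day_of_life")])
  if (any(dup)) {
    if (config$duplicates == "error") {
      stop("duplicate (subject, day) rows: ",
           paste(unique(meta$subject_id[dup]), collapse = ", "),
           " (set duplicates = \"sum\" to merge)")
    }
    key <- paste(meta$subject_id, meta$day_of_life, sep = "\r")
    counts <- rowsum(counts, key, reorder = FALSE)
    meta <- meta[!duplicated(key), , drop = FALSE]
  }
  if (any(rowSums(counts) == 0)) {
    stop("sample(s) with all-zero counts at row(s): ",
         paste(which(rowSums(counts) == 0), collapse = ", "))
  }
  rownames(meta) <- NULL
  rownames(counts) <- NULL
  structure(list(meta = meta, counts = counts, taxa = colnames(counts),
                 config = config),
            class = "dbn_cohort")
}

normalize_open_room <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.logical(x)) x <- ifelse(x, "open", "closed")
  if (is.numeric(x)) x <- ifelse(x > 0, "open", "closed")
  x <- tolower(trimws(x))
  bad <- !x %in% OPEN_ROOM_LEVELS
  if (any(bad)) stop("open_room must be 'open' or 'closed'; saw: ",
                     paste(unique(x[bad]), collapse = ", "))
  factor(x, levels = OPEN_ROOM_LEVELS)
}

# Case-normalized taxon names; "unclassified" is a first-class taxon and is
# always spelled lower-case.
normalize_taxon <- function(x) {
  x <- trimws(x)
  ifelse(tolower(x) == "unclassified", "unclassified",
         paste0(toupper(substring(x, 1, 1)), substring(x, 2)))
}

# Canonical taxon ordering: case-insensitive alphabetical with
# "unclassified" last (matching the conventional class-level listing).
canonical_taxon_order <- function(taxa) {
  uncl <- taxa[tolower(taxa) == "unclassified"]
  rest <- taxa[tolower(taxa) != "unclassified"]
  c(rest[order(tolower(rest), method = "radix")], uncl)
}

#' Read a longitudinal cohort table
#'
#' Reads a wide-format CSV/TSV with one row per stool sample: covariate
#' columns (mapped through `config$column_map`) plus one count column per
#' taxon.  An optional reader for the study spreadsheet layout is available
#' via `format = "study-xlsx"` when the `readxl` package is installed.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"`, or
#'   `"study-xlsx"`.
#' @param config A [cohort_config()].
#' @param sheet Sheet index or name for the xlsx reader.
#' @return A `dbn_cohort`.
#' @export
read_cohort <- function(path, format = c("auto", "csv", "tsv", "study-xlsx"),
                        config = cohort_config(), sheet = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv", xlsx = "study-xlsx", "csv")
  }
  df <- switch(format,
    csv = utils::read.csv(path, check.names = FALSE),
    tsv = utils::read.delim(path, check.names = FALSE),
    `study-xlsx` = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("reading xlsx requires the 'readxl' package; ",
             "export the sheet to CSV and use format = \"csv\"")
      }
      as.data.frame(readxl::read_excel(path, sheet = sheet))
    })
  cohort_from_frame(df, config)
}

cohort_from_frame <- function(df, config = cohort_config()) {
  map <- config$column_map
  have <- map %in% names(df)
  if (!all(have)) {
    stop("missing required column(s): ",
         paste(map[!have], collapse = ", "))
  }
  meta <- data.frame(subject_id = df[[map["subject_id"]]],
                     stringsAsFactors = FALSE)
  for (v in COVARIATES) meta[[v]] <- df[[map[v]]]
  taxa_cols <- config$taxa_columns
  if (is.null(taxa_cols)) taxa_cols <- setdiff(names(df), map)
  if (!length(taxa_cols)) stop("no taxon count columns found")
  counts <- df[taxa_cols]
  for (j in seq_along(counts)) {
    cj <- counts[[j]]
    if (!is.numeric(cj)) {
      parsed <- suppressWarnings(as.numeric(cj))
      if (anyNA(parsed)) {
        stop("non-numeric count in column '", taxa_cols[j], "', row ",
             which(is.na(parsed))[1])
      }
      counts[[j]] <- parsed
    }
  }
  as_cohort(meta, as.matrix(counts), config)
}

#' @export
print.dbn_cohort <- function(x, ...) {
  cat(sprintf("dbn_cohort: %d samples, %d subjects, %d taxa\n",
              nrow(x$meta), length(unique(x$meta$subject_id)),
              length(x$taxa)))
  invisible(x)
}

#' Write a cohort back to disk
#'
#' `write_cohort()` writes the canonical wide CSV (round-trips through
#' [read_cohort()]); `write_cohort_long()` writes a long-format CSV with
#' one row per (sample, taxon) carrying both the raw count and the
#' relative abundance.
#'
#' @param cohort A `dbn_cohort`.
#' @param path Output file.
#' @export
write_cohort <- function(cohort, path) {
  df <- cbind(cohort$meta, as.data.frame(cohort$counts))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
write_cohort_long <- function(cohort, path) {
  ab <- abundances(cohort)
  n <- nrow(cohort$meta)
  k <- length(cohort$taxa)
  long <- cbind(cohort$meta[rep(seq_len(n), each = k), , drop = FALSE],
                data.frame(taxon = rep(cohort$taxa, n),
                           count = as.vector(t(cohort$counts)),
                           rel_abundance = as.vector(t(ab))))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Divides each count by the sample total so that every sample is a
#' composition summing to one.  Scaling all counts by a common positive
#' factor leaves the result unchanged.
#'
#' @param counts Nonnegative numeric vector (one sample) or matrix
#'   (samples x taxa).
#' @return Proportions of the same shape.
#' @export
relative_abundance <- function(counts) {
  if (is.matrix(counts)) {
    tot <- rowSums(counts)
    if (any(tot <= 0)) stop("degenerate sample: all-zero counts")
    return(counts / tot)
  }
  tot <- sum(counts)
  if (tot <= 0) stop("degenerate sample: all-zero counts")
  counts / tot
}

#' @rdname relative_abundance
#' @param cohort A `dbn_cohort`.
#' @export
abundances <- function(cohort) relative_abundance(cohort$counts)

#' Build the paired transition dataset
#'
#' Pairs every sample with the immediately preceding sample of the same
#' subject.  A subject with k samples contributes k - 1 transitions; pairs
#' never cross subjects.  Parent-slice variables are the taxa relative
#' abundances and covariates at time t; child-slice variables are the taxa
#' abundances at time t + 1 (and, optionally, the open-room indicator at
#' t + 1, giving the network a discrete child).
#'
#' @param cohort A `dbn_cohort`.
#' @param taxa Taxa to carry as nodes (default: all cohort taxa in
#'   canonical order).  Abundances are computed over the full taxon set
#'   before any subsetting.
#' @param include_discrete_children Model `open_room` at t + 1 as a child?
#'   Default `FALSE`: covariates are treated as exogenous clocks.
#' @return An object of class `dbn_transitions` with parallel data frames
#'   `parents` (slice t) and `children` (slice t + 1), plus `subject`,
#'   `gap_days`, `target_day`, `taxa`.
#' @export
build_transitions <- function(cohort, taxa = NULL,
                              include_discrete_children = FALSE) {
  if (is.null(taxa)) {
    taxa <- canonical_taxon_order(cohort$taxa)
  } else {
    missing_taxa <- setdiff(taxa, cohort$taxa)
    if (length(missing_taxa)) {
      stop("taxa not in cohort: ", paste(missing_taxa, collapse = ", "))
    }
  }
  ab <- abundances(cohort)
  meta <- cohort$meta
  n <- nrow(meta)
  same_subject <- meta$subject_id[-1] == meta$subject_id[-n]
  src <- which(same_subject)         # row t; row t+1 is src + 1
  tgt <- src + 1L

  parents <- as.data.frame(ab[src, taxa, drop = FALSE])
  for (v in COVARIATES_CONTINUOUS) parents[[v]] <- meta[[v]][src]
  parents$open_room <- meta$open_room[src]

  children <- as.data.frame(ab[tgt, taxa, drop = FALSE])
  if (include_discrete_children) children$open_room <- meta$open_room[tgt]
  rownames(parents) <- NULL
  rownames(children) <- NULL

  structure(list(parents = parents, children = children,
                 subject = meta$subject_id[src],
                 gap_days = as.integer(meta$day_of_life[tgt] -
                                         meta$day_of_life[src]),
                 target_day = meta$day_of_life[tgt],
                 taxa = taxa),
            class = "dbn_transitions")
}

#' @export
print.dbn_transitions <- function(x, ...) {
  cat(sprintf(
    "dbn_transitions: %d pairs, %d subjects, %d taxa, %d parent variables\n",
    nrow(x$parents), length(unique(x$subject)), length(x$taxa),
    ncol(x$parents)))
  invisible(x)
}

# Number of transitions contributed by each subject (k - 1 rule).
n_transitions <- function(cohort) {
  k <- table(cohort$meta$subject_id)
  sum(pmax(as.integer(k) - 1L, 0L))
}

#' Select taxa for modeling and error computation
#'
#' A taxon is retained if it appears in the network structure (as parent or
#' child) or reaches at least `min_fraction` relative abundance in at least
#' one sample.  The returned order is canonical: case-insensitive
#' alphabetical with "unclassified" last.
#'
#' @param cohort A `dbn_cohort`.
#' @param structure Optional `dbn_structure`; its taxa are always included.
#' @param min_fraction Abundance threshold in `[0, 1]`.
#' @return Character vector of taxon names.
#' @export
select_taxa <- function(cohort, structure = NULL, min_fraction = 0.01) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  ab <- abundances(cohort)
  peak <- apply(ab, 2, max)
  keep <- names(peak)[peak >= min_fraction]
  if (!is.null(structure)) {
    # "in the network" means incident to at least one edge (children with
    # empty parent sets are placeholders, not modelled relationships)
    ed <- structure_edges(structure)
    keep <- union(keep, intersect(c(ed$parent, ed$child), cohort$taxa))
  }
  canonical_taxon_order(keep)
}

# Split transitions by row index (used by evaluation protocols).
subset_transitions <- function(tr, idx) {
  structure(list(parents = tr$parents[idx, , drop = FALSE],
                 children = tr$children[idx, , drop = FALSE],
                 subject = tr$subject[idx],
                 gap_days = tr$gap_days[idx],
                 target_day = tr$target_day[idx],
                 taxa = tr$taxa),
            class = "dbn_transitions")
}
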