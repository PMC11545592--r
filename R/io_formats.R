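# Readers/writers and validated containers for the three tabular inputs
# (sample x OTU read counts, per-OTU taxonomy hits, field-survey abundances)
# and for all result tables.

PREY_GROUPS <- c("fish", "benthic_invertebrate")

#' Normalise prey-group labels
#'
#' Maps common spellings ("fish", "Benthic invertebrates",
#' "benthic macro invertebrates", ...) onto the two canonical group labels
#' `"fish"` and `"benthic_invertebrate"`.
#'
#' @param x character vector of group labels.
#' @return character vector with entries in `c("fish", "benthic_invertebrate")`.
#' @export
normalise_prey_group <- function(x) {
  key <- gsub("[^a-z]+", "_", tolower(trimws(as.character(x))))
  key <- gsub("^_+|_+$", "", key)
  fish <- c("fish", "fishes")
  benthic <- c(
    "benthic_invertebrate", "benthic_invertebrates",
    "invertebrate", "invertebrates",
    "benthic_macro_invertebrate", "benthic_macro_invertebrates",
    "benthic_macroinvertebrate", "benthic_macroinvertebrates"
  )
  out <- rep(NA_character_, length(key))
  out[key %in% fish] <- "fish"
  out[key %in% benthic] <- "benthic_invertebrate"
  if (anyNA(out)) {
    stop(
      "unknown prey group label(s): ",
      paste(unique(x[is.na(out)]), collapse = ", "),
      call. = FALSE
    )
  }
  out
}

# Internal: check a numeric matrix of read counts and report the first
# offending cell by its row/column name.
validate_count_matrix <- function(counts) {
  bad <- !is.finite(counts) | counts < 0 | counts != floor(counts)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(
      sprintf(
        "invalid read count at sample '%s', OTU '%s': must be a non-negative integer",
        rownames(counts)[idx[1L]], colnames(counts)[idx[2L]]
      ),
      call. = FALSE
    )
  }
  invisible(counts)
}

#' Construct a read-count table from a matrix
#'
#' @param counts numeric matrix of non-negative integer read counts with
#'   samples as rows and OTUs as columns; dimnames are required and must be
#'   unique.
#' @return an object of class `read_count_table`: a list with elements
#'   `counts` (integer matrix, samples x OTUs), `sample_ids`, `otu_ids` and
#'   `total_reads`.
#' @export
as_read_count_table <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stop("no samples", call. = FALSE)
  if (ncol(counts) == 0L) stop("no OTUs", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts matrix must carry sample and OTU ids as dimnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample id(s): ",
      paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate OTU id(s): ",
      paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "),
      call. = FALSE
    )
  }
  storage.mode(counts) <- "double"
  validate_count_matrix(counts)
  structure(
    list(
      counts = counts,
      sample_ids = rownames(counts),
      otu_ids = colnames(counts),
      total_reads = sum(counts)
    ),
    class = "read_count_table"
  )
}

#' @export
print.read_count_table <- function(x, ...) {
  cat(
    sprintf(
      "read_count_table: %d samples x %d OTUs, %s reads total\n",
      length(x$sample_ids), length(x$otu_ids),
      format(x$total_reads, big.mark = ",")
    )
  )
  invisible(x)
}

#' Read a sample x OTU read-count table from TSV
#'
#' The canonical dialect is tab-separated UTF-8 with a "." decimal mark, one
#' header row of ids and one id column. Both table orientations occur in the
#' wild, so the `dialect` switch states which axis holds the samples.
#'
#' @param path path to a TSV file.
#' @param dialect `"samples-as-rows"` (default) or `"samples-as-columns"`.
#' @return a [as_read_count_table()] object.
#' @export
read_count_table <- function(path,
                             dialect = c("samples-as-rows", "samples-as-columns")) {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path,
    check.names = FALSE, stringsAsFactors = FALSE,
    colClasses = NA, na.strings = NULL
  )
  if (nrow(df) == 0L) stop("no samples", call. = FALSE)
  if (ncol(df) < 2L) stop("no OTUs", call. = FALSE)
  hdr <- names(df)[-1L]
  if (anyDuplicated(hdr)) {
    label <- if (dialect == "samples-as-rows") "OTU" else "sample"
    stop("duplicate ", label, " id(s): ",
      paste(unique(hdr[duplicated(hdr)]), collapse = ", "),
      call. = FALSE
    )
  }
  ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      if (anyNA(num)) {
        i <- which(is.na(num))[1L]
        stop(
          sprintf(
            "non-numeric read count '%s' at row '%s', column '%s'",
            col[i], ids[i], names(body)[j]
          ),
          call. = FALSE
        )
      }
      body[[j]] <- num
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (dialect == "samples-as-columns") m <- t(m)
  as_read_count_table(m)
}

#' Write a read-count table to TSV
#'
#' @param x a `read_count_table`.
#' @param path output path.
#' @param dialect orientation to write, see [read_count_table()].
#' @param id_header header of the id column.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path,
                              dialect = c("samples-as-rows", "samples-as-columns"),
                              id_header = "sample_id") {
  dialect <- match.arg(dialect)
  m <- x$counts
  if (dialect == "samples-as-columns") {
    m <- t(m)
    if (missing(id_header)) id_header <- "otu_id"
  }
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_header
  write_result_tsv(df, path)
}

TAXONOMY_COLUMNS <- c(
  "otu_id", "taxon", "percent_identity", "query_coverage_pct",
  "max_score", "accession"
)

#' Validate a data frame of per-OTU taxonomy hits
#'
#' One best BLAST-style hit per OTU: taxon name (a binomial, a genus-level
#' morphotaxon such as "Zacco sp.", or the literal `"no match"`), percent
#' identity and query coverage in \[0, 100\], bit score, accession.
#'
#' @param df data frame with columns `otu_id`, `taxon`, `percent_identity`,
#'   `query_coverage_pct`, `max_score`, `accession`.
#' @return the validated data frame with class `taxonomy_hits`.
#' @export
as_taxonomy_hits <- function(df) {
  missing_cols <- setdiff(TAXONOMY_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("taxonomy table lacks column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  df <- as.data.frame(df)[TAXONOMY_COLUMNS]
  df$otu_id <- as.character(df$otu_id)
  df$taxon <- trimws(as.character(df$taxon))
  df$accession <- as.character(df$accession)
  if (anyDuplicated(df$otu_id)) {
    stop("duplicate otu_id in taxonomy hits (one best hit per OTU expected): ",
      paste(unique(df$otu_id[duplicated(df$otu_id)]), collapse = ", "),
      call. = FALSE
    )
  }
  for (col in c("percent_identity", "query_coverage_pct")) {
    v <- df[[col]]
    ok <- is.na(v) | (is.finite(v) & v >= 0 & v <= 100)
    if (!all(ok)) {
      stop(
        sprintf(
          "%s outside [0, 100] for OTU(s): %s", col,
          paste(df$otu_id[!ok], collapse = ", ")
        ),
        call. = FALSE
      )
    }
  }
  class(df) <- c("taxonomy_hits", "data.frame")
  df
}

#' Read per-OTU taxonomy hits from TSV
#'
#' @param path path to a TSV with the columns listed in [as_taxonomy_hits()].
#' @return a `taxonomy_hits` data frame.
#' @export
read_taxonomy_hits <- function(path) {
  df <- utils::read.delim(path,
    check.names = FALSE,
    stringsAsFactors = FALSE, na.strings = "NA"
  )
  as_taxonomy_hits(df)
}

#' Validate a field-survey abundance table
#'
#' @param df data frame with columns `group`, `genus`, `species` (optional
#'   values, may be empty/NA) and `count` (non-negative integer number of
#'   individuals surveyed).
#' @return validated data frame with class `field_survey`, groups normalised.
#' @export
as_field_survey <- function(df) {
  need <- c("group", "genus", "count")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("field survey lacks column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  df <- as.data.frame(df)
  if (is.null(df$species)) df$species <- NA_character_
  df <- df[c("group", "genus", "species", "count")]
  df$group <- normalise_prey_group(df$group)
  df$genus <- trimws(as.character(df$genus))
  df$species <- trimws(as.character(df$species))
  df$species[!nzchar(df$species) | is.na(df$species)] <- NA_character_
  cnt <- df$count
  if (!is.numeric(cnt) || any(!is.finite(cnt) | cnt < 0 | cnt != floor(cnt))) {
    stop("field survey counts must be non-negative integers", call. = FALSE)
  }
  key <- paste(df$group, df$genus, df$species, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE]
    stop(
      "duplicate field survey record(s) for: ",
      paste(paste(dup$group, dup$genus, dup$species), collapse = "; "),
      call. = FALSE
    )
  }
  class(df) <- c("field_survey", "data.frame")
  df
}

#' Read a field-survey abundance table from TSV
#'
#' @param path path to a TSV with columns `group`, `genus`, `species`, `count`.
#' @return a `field_survey` data frame.
#' @export
read_field_survey <- function(path) {
  df <- utils::read.delim(path,
    check.names = FALSE,
    stringsAsFactors = FALSE, na.strings = c("NA", "")
  )
  as_field_survey(df)
}

#' Write a result table to TSV
#'
#' Tab-separated, no quoting, no row names; numeric values at full precision
#' unless `pct_digits` is given, in which case columns whose name starts with
#' `pct_` are rounded half-up to that many decimals (the convention for
#' report files; analysis functions always return full precision).
#'
#' @param df data frame to write.
#' @param path output path.
#' @param pct_digits `NULL` (full precision) or an integer.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path, pct_digits = NULL) {
  if (!is.null(pct_digits)) {
    for (col in grep("^pct_", names(df), value = TRUE)) {
      df[[col]] <- round_half_up(df[[col]], pct_digits)
    }
  }
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, na = "NA", fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used when
#' formatting percentages for reports), unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
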