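#' Read an ordinal response matrix from CSV
#'
#' The response file has a header of item ids and one row per person (an
#' optional `person_id` column is honoured); the metadata file declares each
#' item's `n_categories`. Codes are validated against `1..n_categories`;
#' blank cells become missing.
#'
#' @param path Response CSV.
#' @param metadata_path Item metadata CSV with columns `item_id`,
#'   `n_categories` (optionally `scale`).
#' @return List with `responses` (tibble), `items` (tibble).
#' @export
read_response_csv <- function(path, metadata_path) {
  responses <- as_tibble(read.csv(path, check.names = FALSE))
  items <- as_tibble(read.csv(metadata_path))
  if (!all(c("item_id", "n_categories") %in% names(items))) {
    stopf("metadata must declare item_id and n_categories")
  }
  item_cols <- setdiff(names(responses), "person_id")
  missing_meta <- setdiff(item_cols, items$item_id)
  if (length(missing_meta)) {
    stopf("metadata missing for item(s): %s", paste(missing_meta, collapse = ", "))
  }
  ncat <- setNames(items$n_categories, items$item_id)
  pid <- responses$person_id %||% seq_len(nrow(responses))
  for (j in item_cols) {
    x <- responses[[j]]
    bad <- which(!is.na(x) & (x < 1 | x > ncat[j] | x != round(x)))
    if (length(bad)) {
      stopf("out-of-range code at person %s, item %s (value %s, %d categories)",
            pid[bad[1]], j, x[bad[1]], ncat[j])
    }
    responses[[j]] <- as.integer(x)
  }
  list(responses = responses, items = items[items$item_id %in% item_cols, ])
}

#' Write an ordinal response matrix (and metadata) to CSV
#'
#' Round-trips with [read_response_csv()]: missing responses become blank
#' cells.
#'
#' @param responses Tibble (`person_id` + item columns).
#' @param items Item metadata tibble (`item_id`, `n_categories`, ...).
#' @param path,metadata_path Output files.
#' @return Invisibly, `path`.
#' @export
write_response_csv <- function(responses, items, path, metadata_path) {
  write.csv(responses, path, row.names = FALSE, na = "")
  write.csv(items, metadata_path, row.names = FALSE)
  invisible(path)
}

#' Write a correlation matrix as labeled CSV
#'
#' @param R Matrix with dimnames.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_cor_csv <- function(R, path) {
  df <- data.frame(item = rownames(R), R, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a labeled correlation matrix written by [write_cor_csv()]
#'
#' @param path CSV file.
#' @return Matrix with dimnames.
#' @export
read_cor_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
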