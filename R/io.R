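#' Read a table of food webs from CSV
#'
#' Expects a header `web_id,S,L` (extra columns are kept). Validates that
#' `S` and `L` are integers with `S >= 2` and `L >= 1`, reporting the
#' offending row numbers. Webs with `L` outside `[S - 1, S^2]` are kept
#' but flagged in the `in_bounds` column with a warning — they are valid
#' observations for the negative binomial models yet impossible under
#' flexible links (see [validate_webs()]).
#'
#' @param path CSV file path.
#' @return A tibble with columns `web_id`, `S`, `L`, `in_bounds`.
#' @export
read_webs <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("No such file: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(c("web_id", "S", "L"), names(df))
  if (length(missing) > 0) {
    rlang::abort(sprintf("Missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) rlang::abort("The file has a header but no webs.")
  for (col in c("S", "L")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v != floor(v))
    if (length(bad) > 0) {
      rlang::abort(sprintf("Column `%s` is not integer at row(s): %s",
                           col, paste(utils::head(bad, 10), collapse = ", ")))
    }
    df[[col]] <- as.integer(v)
  }
  bad_s <- which(df$S < 2)
  if (length(bad_s) > 0) {
    rlang::abort(sprintf("`S` must be >= 2; violated at row(s): %s",
                         paste(utils::head(bad_s, 10), collapse = ", ")))
  }
  bad_l <- which(df$L < 1)
  if (length(bad_l) > 0) {
    rlang::abort(sprintf("`L` must be >= 1; violated at row(s): %s",
                         paste(utils::head(bad_l, 10), collapse = ", ")))
  }
  df$in_bounds <- df$L >= df$S - 1 & df$L <= df$S^2
  if (any(!df$in_bounds)) {
    rlang::warn(sprintf(
      "%d web(s) have L outside [S - 1, S^2] (rows %s); kept and flagged in `in_bounds`.",
      sum(!df$in_bounds),
      paste(utils::head(which(!df$in_bounds), 10), collapse = ", ")))
  }
  tibble::as_tibble(df)
}

#' Write a table of food webs to CSV
#'
#' @param data A data frame with at least `web_id`, `S`, `L`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_webs <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}
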