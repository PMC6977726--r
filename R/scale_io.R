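#' Read and recode the 9-item child food security scale
#'
#' Reads a delimited text file of answers, recodes the three-level answer
#' vocabulary to binary indicators ("a lot" and "sometimes" are
#' affirmative, "never" negative), drops respondents with any missing item
#' (listwise deletion; no imputation) and reports the exclusions. Input
#' already coded 0/1 is accepted as-is (recoding is skipped when every
#' non-missing value is already binary).
#'
#' @param path CSV file path.
#' @param config optional list overriding the dialect:
#'   * `sep` field separator (default ",");
#'   * `items` item column names or indices (default: the 9 columns whose
#'     names start with "item", or all non-id columns);
#'   * `id` respondent id column name (default: a column named "id" if
#'     present, else row index);
#'   * `recode` named map from answer token to 0/1 (default: `a lot`,
#'     `a-lot`, `sometimes` -> 1; `never` -> 0); matching is
#'     case-insensitive after trimming;
#'   * `missing` tokens treated as missing in addition to empty strings
#'     and `NA` (default `c("", "NA")`). Any other unrecognized token is
#'     an error naming the row and column.
#' @return list: `responses` (n x 9 0/1 integer matrix, rownames = ids),
#'   `report` (list: `n_read`, `n_dropped`, `n_kept`, `dropped_ids`).
#' @export
load_responses <- function(path, config = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- modifyList(list(sep = ",", items = NULL, id = NULL,
                         recode = c("a lot" = 1L, "a-lot" = 1L,
                                    "sometimes" = 1L, "never" = 0L),
                         missing = c("", "NA")), config)
  raw <- utils::read.table(path, sep = cfg$sep, header = TRUE,
                           colClasses = "character",
                           check.names = FALSE, strip.white = TRUE)
  id_col <- cfg$id %||% (if ("id" %in% names(raw)) "id" else NULL)
  ids <- if (is.null(id_col)) as.character(seq_len(nrow(raw)))
         else as.character(raw[[id_col]])
  item_cols <- cfg$items
  if (is.null(item_cols)) {
    item_cols <- grep("^item", names(raw), value = TRUE)
    if (!length(item_cols)) item_cols <- setdiff(names(raw), id_col)
  }
  if (is.numeric(item_cols)) item_cols <- names(raw)[item_cols]
  if (length(item_cols) < 9L)
    stop("expected 9 item columns, found ", length(item_cols))
  if (length(item_cols) > 9L)
    stop("expected exactly 9 item columns, found ", length(item_cols),
         "; pass config$items to disambiguate")
  vals <- as.matrix(raw[, item_cols, drop = FALSE])
  norm <- tolower(trimws(vals))
  is_missing <- is.na(norm) | norm %in% tolower(cfg$missing)
  tokens <- unique(norm[!is_missing])
  binary_input <- length(tokens) > 0L && all(tokens %in% c("0", "1"))
  out <- matrix(NA_integer_, nrow(vals), 9L,
                dimnames = list(ids, paste0("item", 1:9)))
  if (binary_input) {
    out[!is_missing] <- as.integer(norm[!is_missing])
  } else {
    map <- cfg$recode
    names(map) <- tolower(trimws(names(map)))
    known <- norm %in% names(map)
    bad <- which(!known & !is_missing, arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("unknown answer token '%s' at row %d, column '%s'",
                   vals[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
                   item_cols[bad[1L, 2L]]))
    }
    out[known] <- as.integer(map[norm[known]])
  }
  drop <- rowSums(is.na(out)) > 0L
  report <- list(n_read = nrow(out), n_dropped = sum(drop),
                 n_kept = sum(!drop), dropped_ids = ids[drop])
  list(responses = out[!drop, , drop = FALSE], report = report)
}

#' Raw scale score
#'
#' Number of affirmative responses per respondent, the integer row sum of
#' the 0/1 response matrix (range 0..J).
#'
#' @param data 0/1 response matrix (or [load_responses()] result).
#' @return integer vector.
#' @export
raw_score <- function(data) {
  y <- as_response_matrix(data)
  as.integer(rowSums(y))
}

#' Cronbach's alpha
#'
#' \eqn{\alpha = J/(J-1) (1 - \sum_j s^2_j / s^2_{total})} with sample
#' variances (n - 1 denominator, the convention of mainstream statistical
#' packages).
#'
#' @param data 0/1 response matrix (>= 2 respondents, >= 2 items).
#' @return scalar alpha.
#' @export
cronbach_alpha <- function(data) {
  y <- as_response_matrix(data)
  if (nrow(y) < 2L) stop("alpha requires at least 2 respondents")
  j <- ncol(y)
  if (j < 2L) stop("alpha requires at least 2 items")
  total_var <- stats::var(rowSums(y))
  if (total_var == 0) stop("total score variance is zero; alpha undefined")
  item_var <- apply(y, 2, stats::var)
  (j / (j - 1)) * (1 - sum(item_var) / total_var)
}
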