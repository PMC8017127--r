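#' Joint response/response-time dataset
#'
#' Container for per-person, per-item scored responses (ordered categories
#' `0..m_i`) and response times (positive durations in minutes), plus a
#' group label per person. Missing entries are `NA`; a response may be
#' missing while its time is observed and vice versa.
#'
#' @param responses Integer matrix, persons x items; entries in `0..m_i`
#'   or `NA`.
#' @param times Numeric matrix of the same shape with positive times in
#'   minutes, or `NULL` when no timing data exist.
#' @param group Per-person group labels (factor or character); `NULL`
#'   makes a single group `"all"`.
#' @param n_cat Integer vector giving the number of score categories per
#'   item; inferred as `max(observed) + 1` when `NULL`.
#' @param units `"minutes"` (default) or `"seconds"`; seconds are converted
#'   to minutes on input (only the time-intensity scale shifts).
#' @return An object of class `rt_data`.
#' @export
rt_dataset <- function(responses, times = NULL, group = NULL, n_cat = NULL,
                       units = c("minutes", "seconds")) {
  units <- match.arg(units)
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  n <- nrow(responses); I <- ncol(responses)
  if (is.null(colnames(responses)))
    colnames(responses) <- sprintf("item%02d", seq_len(I))
  if (!is.null(times)) {
    times <- as.matrix(times)
    storage.mode(times) <- "double"
    if (!all(dim(times) == dim(responses)))
      stop("'responses' and 'times' must share shape and person order")
    if (units == "seconds") times <- times / 60
    if (any(times[!is.na(times)] <= 0))
      stop("times must be positive (in minutes) or NA")
    colnames(times) <- colnames(responses)
  }
  if (is.null(group)) group <- rep("all", n)
  if (length(group) != n) stop("'group' must have one label per person")
  group <- factor(group)
  if (is.null(n_cat)) {
    n_cat <- apply(responses, 2L, function(x)
      if (all(is.na(x))) 2L else max(x, na.rm = TRUE) + 1L)
    n_cat <- pmax(as.integer(n_cat), 2L)
  } else {
    n_cat <- as.integer(n_cat)
    if (length(n_cat) != I) stop("'n_cat' must have one entry per item")
  }
  for (i in seq_len(I)) {
    xi <- responses[, i]
    bad <- !is.na(xi) & (xi < 0L | xi >= n_cat[i])
    if (any(bad))
      stop("responses of item ", i, " outside categories 0..", n_cat[i] - 1L)
  }
  structure(list(responses = responses, times = times, group = group,
                 n_cat = n_cat, items = colnames(responses)),
            class = "rt_data")
}

#' @export
print.rt_data <- function(x, ...) {
  cat(sprintf("<rt_data: %d persons, %d items, %d group(s)%s>\n",
              nrow(x$responses), ncol(x$responses), nlevels(x$group),
              if (is.null(x$times)) ", no times" else ""))
  invisible(x)
}

#' @export
`[.rt_data` <- function(x, i, ...) {
  rt_dataset(x$responses[i, , drop = FALSE],
             if (!is.null(x$times)) x$times[i, , drop = FALSE],
             droplevels(x$group[i]), n_cat = x$n_cat)
}

# persons belonging to one group, as an rt_data subset
group_subset <- function(data, g) data[data$group == g]

#' Read a long-format response/time table
#'
#' Reads a delimited text file with columns `person_id`, `group`,
#' `item_id`, `score`, `time` (time in minutes) into an [rt_dataset()].
#' The missing-value token is configurable; by default empty fields and
#' `"NA"` are missing.
#'
#' @param path File path (any delimiter `data.table::fread` detects).
#' @param missing Character token(s) treated as missing, in addition to
#'   empty fields.
#' @param n_cat Optional per-item category counts (named by item or in
#'   item order after sorting by `item_id`).
#' @return An [rt_dataset()].
#' @export
read_rt_long <- function(path, missing = "NA", n_cat = NULL) {
  dt <- data.table::fread(path, na.strings = c(missing, ""),
                          colClasses = list(character = c("person_id",
                                                          "group",
                                                          "item_id")))
  need <- c("person_id", "group", "item_id", "score", "time")
  if (!all(need %in% names(dt)))
    stop("long-format file must have columns: ", paste(need, collapse = ", "))
  items <- sort(unique(dt$item_id))
  persons <- unique(dt$person_id)
  X <- matrix(NA_integer_, length(persons), length(items),
              dimnames = list(persons, items))
  Tm <- matrix(NA_real_, length(persons), length(items),
               dimnames = list(persons, items))
  pi_ <- match(dt$person_id, persons); ii <- match(dt$item_id, items)
  X[cbind(pi_, ii)] <- as.integer(dt$score)
  Tm[cbind(pi_, ii)] <- as.numeric(dt$time)
  grp <- dt$group[!duplicated(dt$person_id)]
  if (!is.null(n_cat) && !is.null(names(n_cat))) n_cat <- n_cat[items]
  rt_dataset(X, Tm, grp, n_cat = n_cat)
}

#' Write a dataset in the long format
#'
#' @param data An [rt_dataset()].
#' @param path Output path; written as tab-separated text with header
#'   `person_id group item_id score time` and `NA` as the missing token.
#' @return `path`, invisibly.
#' @export
write_rt_long <- function(data, path) {
  stopifnot(inherits(data, "rt_data"))
  n <- nrow(data$responses); I <- ncol(data$responses)
  long <- data.table::data.table(
    person_id = rep(sprintf("p%05d", seq_len(n)), times = I),
    group = rep(as.character(data$group), times = I),
    item_id = rep(data$items, each = n),
    score = as.vector(data$responses),
    time = if (is.null(data$times)) NA_real_ else as.vector(data$times))
  data.table::fwrite(long, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Assemble a dataset from wide matrices
#'
#' Convenience wrapper around [rt_dataset()] for callers holding a score
#' matrix, a time matrix and a group vector; accepts an explicit missing
#' sentinel code used in both matrices.
#'
#' @param responses,times,group,n_cat See [rt_dataset()].
#' @param missing_code Optional numeric sentinel recoded to `NA` in both
#'   matrices (e.g. `-99`).
#' @return An [rt_dataset()].
#' @export
read_rt_wide <- function(responses, times = NULL, group = NULL,
                         n_cat = NULL, missing_code = NULL) {
  if (!is.null(missing_code)) {
    responses[responses == missing_code] <- NA
    if (!is.null(times)) times[times == missing_code] <- NA
  }
  rt_dataset(responses, times, group, n_cat = n_cat)
}
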