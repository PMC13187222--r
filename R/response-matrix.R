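#' Ordinal response matrix with group labels
#'
#' The universal input container: a participants x items matrix of integer
#' Likert ratings together with a binary group label per participant
#' ("case" vs "comparison"). All pipeline stages consume this object.
#'
#' @param values integer matrix (participants x items), ratings in
#'   `1:n_categories`.
#' @param group character or factor of length `nrow(values)` with exactly the
#'   two levels `"case"` and `"comparison"` (both must be present).
#' @param item_ids unique item identifiers (default `"IP1"`, `"IP2"`, ...).
#' @param participant_ids unique participant identifiers.
#' @param n_categories number of ordered rating categories (default 7).
#'
#' @return An object of class `response_matrix`: a list with elements
#'   `values`, `group`, `item_ids`, `participant_ids`, `n_categories`.
#' @export
response_matrix <- function(values, group,
                            item_ids = paste0("IP", seq_len(ncol(values))),
                            participant_ids = paste0("P", seq_len(nrow(values))),
                            n_categories = 7L) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (anyNA(values))
    stop("response values contain missing cells")
  bad <- which(values < 1L | values > n_categories, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("rating outside 1..%d at participant %s, item %s",
                 n_categories, bad[1, 1], bad[1, 2]))
  if (anyDuplicated(item_ids))
    stop("item ids must be unique")
  if (length(item_ids) != ncol(values))
    stop("item_ids length does not match number of columns")
  if (length(group) != nrow(values))
    stop("group length does not match number of rows")
  group <- factor(as.character(group), levels = c("case", "comparison"))
  if (anyNA(group))
    stop("group labels must be 'case' or 'comparison'")
  dimnames(values) <- list(participant_ids, item_ids)
  structure(
    list(values = values, group = group,
         item_ids = as.character(item_ids),
         participant_ids = as.character(participant_ids),
         n_categories = as.integer(n_categories)),
    class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("Response matrix: %d participants x %d items (categories 1..%d)\n",
              nrow(x$values), ncol(x$values), x$n_categories))
  cat(sprintf("  groups: case n = %d, comparison n = %d\n",
              sum(x$group == "case"), sum(x$group == "comparison")))
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$values)

#' Subset the items of a response matrix
#'
#' @param x a [response_matrix()].
#' @param items item ids to keep (order preserved as given).
#' @return A `response_matrix` restricted to `items`.
#' @export
subset_items <- function(x, items) {
  stopifnot(inherits(x, "response_matrix"))
  missing_ids <- setdiff(items, x$item_ids)
  if (length(missing_ids))
    stop("unknown item id(s): ", paste(missing_ids, collapse = ", "))
  response_matrix(x$values[, items, drop = FALSE], x$group,
                  item_ids = items, participant_ids = x$participant_ids,
                  n_categories = x$n_categories)
}

#' Write / read a response matrix as CSV
#'
#' Layout: first column `participant_id`, second column `group`
#' (`case`/`comparison`), then one integer column per item.
#'
#' @param x a [response_matrix()].
#' @param path file path.
#' @return `write_responses` returns `path` invisibly; `read_responses`
#'   returns a `response_matrix`.
#' @export
write_responses <- function(x, path) {
  stopifnot(inherits(x, "response_matrix"))
  df <- data.frame(participant_id = x$participant_ids,
                   group = as.character(x$group),
                   x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @param n_categories number of rating categories expected in the file.
#' @export
read_responses <- function(path, n_categories = 7L) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("participant_id", "group") %in% names(df)[1:2]))
    stop("expected columns participant_id, group, then item columns")
  items <- setdiff(names(df), c("participant_id", "group"))
  response_matrix(as.matrix(df[, items, drop = FALSE]), df$group,
                  item_ids = items, participant_ids = as.character(df$participant_id),
                  n_categories = n_categories)
}

#' Reverse-code selected items
#'
#' A reverse-keyed item on a `1..K` scale is recoded as `K + 1 - x`, so a
#' high latent trait maps to a high recoded rating for every item.
#'
#' @param x a [response_matrix()].
#' @param reverse_items item ids to recode.
#' @return A `response_matrix` with the named columns recoded.
#' @export
recode_reversed <- function(x, reverse_items) {
  stopifnot(inherits(x, "response_matrix"))
  if (length(reverse_items) == 0) return(x)
  missing_ids <- setdiff(reverse_items, x$item_ids)
  if (length(missing_ids))
    stop("unknown item id(s): ", paste(missing_ids, collapse = ", "))
  v <- x$values
  v[, reverse_items] <- x$n_categories + 1L - v[, reverse_items]
  response_matrix(v, x$group, x$item_ids, x$participant_ids, x$n_categories)
}
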