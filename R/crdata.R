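#' Construct a competing-risks dataset
#'
#' A `crdata` object holds right-censored time-to-first-event data with two
#' competing event types: one row per subject with the observed time
#' \eqn{\min(T, C)}, a status code, and optionally a binary treatment group.
#' Status 1 is the event of interest, status 2 the competing event and
#' status 0 right-censoring.
#'
#' @param time Numeric vector of positive, finite observed times.
#' @param status Integer vector with values in \{0, 1, 2\}.
#' @param group Optional integer vector with values in \{0, 1\}
#'   (0 = control, 1 = treatment).
#' @param id Optional vector of subject labels; defaults to row numbers.
#'
#' @return A data frame of class `"crdata"` with columns `id`, `time`,
#'   `status` and, when supplied, `group`. Row order is preserved.
#'
#' @examples
#' d <- crdata(time = c(1, 2, 3), status = c(1, 2, 0))
#' summary(d)
#' @export
crdata <- function(time, status, group = NULL, id = NULL) {
  if (length(time) != length(status)) {
    stop_crsim("`time` and `status` must have the same length", "validation")
  }
  n <- length(time)
  if (n == 0L) stop_crsim("dataset is empty", "empty")
  time <- as.numeric(time)
  bad <- which(!is.finite(time) | time <= 0)
  if (length(bad)) {
    stop_crsim(sprintf("invalid time (non-finite or <= 0) in row %d", bad[1L]),
               "validation")
  }
  status <- check_code(status, 0:2, "status")
  if (!is.null(group)) {
    if (length(group) != n) {
      stop_crsim("`group` must have the same length as `time`", "validation")
    }
    group <- check_code(group, 0:1, "group")
  }
  if (is.null(id)) id <- seq_len(n)
  out <- data.frame(id = id, time = time, status = status,
                    stringsAsFactors = FALSE)
  if (!is.null(group)) out$group <- group
  class(out) <- c("crdata", "data.frame")
  out
}

check_code <- function(x, allowed, what) {
  xi <- suppressWarnings(as.integer(x))
  bad <- which(is.na(xi) | xi != x | !(xi %in% allowed))
  if (length(bad)) {
    stop_crsim(sprintf("invalid %s (must be one of %s) in row %d",
                       what, paste(allowed, collapse = ", "), bad[1L]),
               "validation")
  }
  xi
}

stop_crsim <- function(msg, subclass) {
  stop(errorCondition(msg,
                      class = c(paste0("crsim_", subclass, "_error"),
                                "crsim_error", "error", "condition")))
}

#' Coerce to a competing-risks dataset
#'
#' @param x A data frame with columns `time` and `status` (and optionally
#'   `group`, `id`).
#' @param columns Named character vector mapping the canonical column names
#'   (`id`, `time`, `status`, `group`) to the names used in `x`.
#' @return A validated [crdata] object.
#' @export
as_crdata <- function(x, columns = c(id = "id", time = "time",
                                     status = "status", group = "group")) {
  columns <- resolve_columns(columns)
  need <- c("time", "status")
  miss <- need[!(columns[need] %in% names(x))]
  if (length(miss)) {
    stop_crsim(sprintf("missing required column(s): %s",
                       paste(columns[miss], collapse = ", ")), "validation")
  }
  tm <- x[[columns[["time"]]]]
  if (!is.numeric(tm)) {
    suppressWarnings(tmn <- as.numeric(as.character(tm)))
    bad <- which(is.na(tmn) & !is.na(tm))
    if (length(bad)) {
      stop_crsim(sprintf("non-numeric time in row %d", bad[1L]), "validation")
    }
    tm <- tmn
  }
  grp <- if (columns[["group"]] %in% names(x)) x[[columns[["group"]]]]
  idv <- if (columns[["id"]] %in% names(x)) x[[columns[["id"]]]]
  crdata(time = tm, status = x[[columns[["status"]]]], group = grp, id = idv)
}

resolve_columns <- function(columns) {
  default <- c(id = "id", time = "time", status = "status", group = "group")
  default[names(columns)] <- columns
  default
}

#' Read a competing-risks dataset from CSV
#'
#' Expects an RFC-4180-style comma-separated file with a header row. The
#' default schema is `id,time,status,group` (`id` and `group` optional);
#' other column names can be mapped through `columns`.
#'
#' @param path Path to a CSV file.
#' @inheritParams as_crdata
#' @return A validated [crdata] object; row order follows the file.
#' @export
read_crdata <- function(path, columns = c(id = "id", time = "time",
                                          status = "status", group = "group")) {
  if (!file.exists(path)) stop_crsim(sprintf("file not found: %s", path), "io")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_crdata(raw, columns)
}

#' Write a competing-risks dataset to CSV
#'
#' Writes the same schema that [read_crdata()] reads, so simulated data can
#' be re-estimated without conversion.
#'
#' @param x A [crdata] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_crdata <- function(x, path) {
  stopifnot(inherits(x, "crdata"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.crdata <- function(x, ...) {
  cat(sprintf("Competing-risks dataset: %d subjects%s\n", nrow(x),
              if ("group" %in% names(x)) " (two-arm)" else ""))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Summarise a competing-risks dataset
#'
#' Counts and proportions by status code, overall and per group when a group
#' column is present, in the reporting style "243 (38.2%) events of interest".
#'
#' @param object A [crdata] object.
#' @param ... Unused.
#' @return An object of class `"summary.crdata"`: a list with a `counts`
#'   matrix (rows: status 0, 1, 2), a `proportions` matrix, and `n`.
#' @export
summary.crdata <- function(object, ...) {
  if (nrow(object) == 0L) stop_crsim("dataset is empty", "empty")
  tab_for <- function(d) tabulate(d$status + 1L, nbins = 3L)
  counts <- tab_for(object)
  out <- list(n = nrow(object),
              counts = counts,
              proportions = counts / nrow(object))
  names(out$counts) <- names(out$proportions) <-
    c("censored", "event of interest", "competing event")
  if ("group" %in% names(object)) {
    bygrp <- lapply(split(object, object$group), tab_for)
    out$by_group <- do.call(rbind, bygrp)
    colnames(out$by_group) <- names(out$counts)
  }
  class(out) <- "summary.crdata"
  out
}

#' @export
print.summary.crdata <- function(x, ...) {
  cat(sprintf("n = %d subjects\n", x$n))
  ord <- c("event of interest", "competing event", "censored")
  for (nm in ord) {
    cat(sprintf("  %-18s %5d (%.1f%%)\n", nm, x$counts[[nm]],
                100 * x$proportions[[nm]]))
  }
  if (!is.null(x$by_group)) {
    cat("by group (rows = group code):\n")
    print(x$by_group)
  }
  invisible(x)
}
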