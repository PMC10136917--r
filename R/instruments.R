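#' Define an ordinal symptom instrument
#'
#' An instrument is a named set of ordinal items sharing one response scale
#' (e.g. 0--3 for "not at all" through "nearly every day") together with
#' severity bands over the total score. Bands are metadata, not hard-coded,
#' so instruments other than the bundled PHQ-9/GAD-7 can be plugged in.
#'
#' @param name Instrument name; also used as the default community label of
#'   its items in network analyses.
#' @param items Character vector of unique item ids (column names in the
#'   raw response table).
#' @param labels Human-readable item labels, same length as `items`.
#' @param min_response,max_response Integer bounds of the per-item response
#'   scale (default 0 and 3).
#' @param severity_bands Data frame with columns `band`, `lo`, `hi`
#'   describing inclusive, contiguous, non-overlapping total-score bands that
#'   jointly cover `0 .. length(items) * max_response`.
#' @return An object of class `instrument`.
#' @examples
#' instr <- instrument("toy", c("t1", "t2"),
#'   severity_bands = data.frame(band = c("low", "high"), lo = c(0, 4), hi = c(3, 6)))
#' @export
instrument <- function(name, items, labels = items,
                       min_response = 0L, max_response = 3L,
                       severity_bands) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  items <- as.character(items)
  if (anyDuplicated(items)) {
    stop("instrument '", name, "': item ids must be unique", call. = FALSE)
  }
  if (length(labels) != length(items)) {
    stop("labels must have one entry per item", call. = FALSE)
  }
  min_response <- as.integer(min_response)
  max_response <- as.integer(max_response)
  if (min_response >= max_response) {
    stop("min_response must be smaller than max_response", call. = FALSE)
  }
  bands <- as.data.frame(severity_bands)
  if (!all(c("band", "lo", "hi") %in% names(bands))) {
    stop("severity_bands needs columns band, lo, hi", call. = FALSE)
  }
  bands <- bands[order(bands$lo), , drop = FALSE]
  max_total <- length(items) * max_response
  if (bands$lo[1] != 0 || bands$hi[nrow(bands)] != max_total ||
      any(bands$lo > bands$hi) ||
      (nrow(bands) > 1 && any(bands$lo[-1] != bands$hi[-nrow(bands)] + 1L))) {
    stop("severity bands must be contiguous, non-overlapping and cover 0..",
         max_total, call. = FALSE)
  }
  structure(
    list(name = name, items = items, labels = as.character(labels),
         min_response = min_response, max_response = max_response,
         severity_bands = bands),
    class = "instrument"
  )
}

#' @export
print.instrument <- function(x, ...) {
  cat("<instrument> ", x$name, ": ", length(x$items), " items scored ",
      x$min_response, "-", x$max_response, "\n", sep = "")
  cat("  bands: ", paste0(x$severity_bands$band, " [", x$severity_bands$lo,
                          "-", x$severity_bands$hi, "]", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Bundled PHQ-9 depression instrument
#'
#' Nine depression items (D1--D9) scored 0--3, with the standard severity
#' bands: normal 0--4, mild 5--9, moderate 10--14, moderately severe 15--19,
#' severe 20--27.
#'
#' @return An [instrument].
#' @export
phq9 <- function() {
  instrument(
    name = "depression",
    items = paste0("D", 1:9),
    labels = c("Anhedonia", "Feeling depressed or hopeless", "Sleep problems",
               "Energy loss", "Appetite changes", "Feeling of worthlessness",
               "Trouble concentrating", "Psychomotor issues",
               "Suicidal ideation"),
    severity_bands = data.frame(
      band = c("normal", "mild", "moderate", "moderately severe", "severe"),
      lo = c(0L, 5L, 10L, 15L, 20L),
      hi = c(4L, 9L, 14L, 19L, 27L))
  )
}

#' Bundled GAD-7 anxiety instrument
#'
#' Seven anxiety items (A1--A7) scored 0--3, with severity bands
#' normal 0--4, mild 5--9, moderate 10--14, severe 15--21.
#'
#' @return An [instrument].
#' @export
gad7 <- function() {
  instrument(
    name = "anxiety",
    items = paste0("A", 1:7),
    labels = c("Feeling nervous or anxious", "Unable to control worry",
               "Excessive worry", "Relaxation difficulty",
               "Too restless to sit still", "Easily annoyed or irritable",
               "Afraid something awful might happen"),
    severity_bands = data.frame(
      band = c("normal", "mild", "moderate", "severe"),
      lo = c(0L, 5L, 10L, 15L),
      hi = c(4L, 9L, 14L, 21L))
  )
}

#' Validate a raw response table into an item response matrix
#'
#' Applies complete-case exclusion: any subject (row) with a missing,
#' non-integer, or out-of-range value on any instrument item is dropped and
#' reported. This mirrors the usual screening-study exclusion of incomplete
#' questionnaires; no imputation is performed.
#'
#' @param raw A data frame (or matrix) with one subject per row and item
#'   columns named by item id. Extra columns are ignored.
#' @param instruments A list of [instrument] objects whose items must all be
#'   present as columns.
#' @param id_col Optional name of a subject-id column; row numbers are used
#'   otherwise.
#' @return An object of class `item_matrix`: integer matrix `values`
#'   (subjects x items), per-item community labels, and a `rejected` data
#'   frame with one row per dropped subject and the reason.
#' @export
validate_responses <- function(raw, instruments, id_col = NULL) {
  if (inherits(instruments, "instrument")) instruments <- list(instruments)
  raw <- as.data.frame(raw)
  all_items <- unlist(lapply(instruments, `[[`, "items"))
  if (anyDuplicated(all_items)) {
    stop("instruments share item ids: ",
         paste(unique(all_items[duplicated(all_items)]), collapse = ", "),
         call. = FALSE)
  }
  missing_cols <- setdiff(all_items, names(raw))
  if (length(missing_cols)) {
    stop("raw table lacks item columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  subjects <- if (!is.null(id_col)) as.character(raw[[id_col]]) else
    as.character(seq_len(nrow(raw)))

  communities <- rep(vapply(instruments, `[[`, "", "name"),
                     vapply(instruments, function(i) length(i$items), 0L))
  names(communities) <- all_items

  vals <- suppressWarnings(
    vapply(all_items, function(it) as.numeric(raw[[it]]), numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(subjects, all_items))

  lo <- hi <- numeric(length(all_items))
  k <- 1L
  for (ins in instruments) {
    lo[k:(k + length(ins$items) - 1L)] <- ins$min_response
    hi[k:(k + length(ins$items) - 1L)] <- ins$max_response
    k <- k + length(ins$items)
  }
  reasons <- character(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    v <- vals[i, ]
    if (anyNA(v)) {
      reasons[i] <- "missing"
    } else if (any(v < lo | v > hi)) {
      reasons[i] <- "out of range"
    } else if (any(v != round(v))) {
      reasons[i] <- "non-integer"
    }
  }
  keep <- reasons == ""
  rejected <- data.frame(subject = subjects[!keep], reason = reasons[!keep],
                         stringsAsFactors = FALSE)
  if (!any(keep)) {
    stop("all ", nrow(raw), " subjects rejected during validation",
         call. = FALSE)
  }
  item_matrix(vals[keep, , drop = FALSE], communities = communities,
              rejected = rejected)
}

#' Construct an item response matrix directly
#'
#' Low-level constructor used by [validate_responses()] and the synthetic
#' cohort generator. Values are assumed already validated.
#'
#' @param values Integer matrix, subjects x items, with item ids as column
#'   names.
#' @param communities Named character vector mapping every item id to a
#'   community label; at least 2 items per community.
#' @param rejected Optional data frame of rejected subjects (bookkeeping).
#' @return An `item_matrix`.
#' @export
item_matrix <- function(values, communities, rejected = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(colnames(values))) stop("values needs item column names",
                                      call. = FALSE)
  if (!setequal(names(communities), colnames(values))) {
    stop("communities must name exactly the item columns", call. = FALSE)
  }
  communities <- communities[colnames(values)]
  if (any(table(communities) < 2L)) {
    stop("each community needs at least 2 items", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- as.character(seq_len(nrow(values)))
  }
  if (is.null(rejected)) {
    rejected <- data.frame(subject = character(), reason = character(),
                           stringsAsFactors = FALSE)
  }
  structure(list(values = values, communities = communities,
                 rejected = rejected),
            class = "item_matrix")
}

#' @export
print.item_matrix <- function(x, ...) {
  cat("<item_matrix> ", nrow(x$values), " subjects x ", ncol(x$values),
      " items (", paste(names(table(x$communities)), table(x$communities),
                        sep = ": ", collapse = ", "), ")\n", sep = "")
  if (nrow(x$rejected)) cat("  rejected subjects:", nrow(x$rejected), "\n")
  invisible(x)
}

#' @export
dim.item_matrix <- function(x) dim(x$values)

#' Per-subject total score for one instrument
#'
#' The total is the plain sum of the instrument's item responses, so for a
#' 9-item 0--3 instrument the maximum is 27 and for a 7-item one it is 21.
#'
#' @param responses An `item_matrix`.
#' @param instrument An [instrument] whose items are all present.
#' @return Named integer vector of totals, one per subject.
#' @export
total_score <- function(responses, instrument) {
  stopifnot(inherits(responses, "item_matrix"),
            inherits(instrument, "instrument"))
  missing_items <- setdiff(instrument$items, colnames(responses$values))
  if (length(missing_items)) {
    stop("responses lack items: ", paste(missing_items, collapse = ", "),
         call. = FALSE)
  }
  as.integer(rowSums(responses$values[, instrument$items, drop = FALSE])) |>
    setNames(rownames(responses$values))
}

#' Map total scores to severity bands
#'
#' @param score Integer vector of total scores.
#' @param instrument The [instrument] defining the bands.
#' @return Character vector of band labels.
#' @export
severity_band <- function(score, instrument) {
  stopifnot(inherits(instrument, "instrument"))
  bands <- instrument$severity_bands
  max_total <- length(instrument$items) * instrument$max_response
  if (any(score < 0 | score > max_total)) {
    stop("score outside 0..", max_total, call. = FALSE)
  }
  idx <- findInterval(score, bands$lo)
  bands$band[idx]
}

#' Tally subjects per severity band
#'
#' @param responses An `item_matrix`.
#' @param instrument An [instrument].
#' @return Data frame with band, score range, count and percentage; counts
#'   sum to the number of subjects and percentages to 100.
#' @export
severity_tally <- function(responses, instrument) {
  scores <- total_score(responses, instrument)
  bands <- instrument$severity_bands
  band <- factor(severity_band(scores, instrument), levels = bands$band)
  counts <- as.integer(table(band))
  data.frame(band = bands$band, lo = bands$lo, hi = bands$hi,
             count = counts,
             percent = 100 * counts / length(scores),
             stringsAsFactors = FALSE)
}

#' Cronbach's alpha internal consistency
#'
#' alpha = k/(k-1) * (1 - sum of item variances / variance of the total),
#' computed with the sample (n-1) variance convention.
#'
#' @param responses An `item_matrix`.
#' @param instrument An [instrument] with at least two items present.
#' @return Numeric alpha in (-Inf, 1].
#' @export
cronbach_alpha <- function(responses, instrument) {
  stopifnot(inherits(responses, "item_matrix"),
            inherits(instrument, "instrument"))
  x <- responses$values[, instrument$items, drop = FALSE]
  k <- ncol(x)
  if (k < 2L || nrow(x) < 2L) {
    stop("Cronbach's alpha needs >= 2 items and >= 2 subjects", call. = FALSE)
  }
  total_var <- var(rowSums(x))
  if (total_var <= .Machine$double.eps) {
    stop("total-score variance is zero; alpha undefined", call. = FALSE)
  }
  (k / (k - 1)) * (1 - sum(apply(x, 2, var)) / total_var)
}

#' Score a cohort on every instrument
#'
#' Convenience wrapper producing the scored table exported by the pipeline:
#' one row per subject with each instrument's total and severity band.
#'
#' @param responses An `item_matrix`.
#' @param instruments List of [instrument] objects.
#' @return Data frame: subject, then `<name>_total`, `<name>_band` pairs.
#' @export
score_table <- function(responses, instruments) {
  if (inherits(instruments, "instrument")) instruments <- list(instruments)
  out <- data.frame(subject = rownames(responses$values),
                    stringsAsFactors = FALSE)
  for (ins in instruments) {
    totals <- total_score(responses, ins)
    out[[paste0(ins$name, "_total")]] <- unname(totals)
    out[[paste0(ins$name, "_band")]] <- severity_band(totals, ins)
  }
  out
}
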