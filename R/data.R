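#' Indicator datasets
#'
#' An `indicator_dataset` holds the per-block, per-round observations for a
#' single survey indicator. Binary (yes/no) indicators store successes `y`
#' out of denominator `n`; count indicators store the block-level summed
#' count `y` out of the summed maximum possible count `n` (see
#' [weighted_count_ratio()]). Block-rounds with no respondents are recorded
#' explicitly in `missing` and are never coded as zero counts: the model
#' imputes them.
#'
#' @param indicator_id indicator name.
#' @param family `"binary"` or `"count"`.
#' @param observations data frame with columns `block_id`, `round`, `y`, `n`.
#' @param rounds ordered integer round labels; defaults to the rounds seen.
#' @param block_ids full block universe; defaults to the blocks seen. Blocks
#'   (or rounds) in the universe with no observation row become missing
#'   cells.
#' @return an `indicator_dataset`.
#' @export
indicator_dataset <- function(indicator_id, family = c("binary", "count"),
                              observations, rounds = NULL, block_ids = NULL) {
  family <- match.arg(family)
  obs <- as.data.frame(observations)
  req <- c("block_id", "round", "y", "n")
  if (!all(req %in% names(obs)))
    stop("observations need columns ", paste(req, collapse = ", "))
  obs$block_id <- as.character(obs$block_id)
  obs$round <- as.integer(obs$round)
  obs$y <- as.numeric(obs$y)
  obs$n <- as.numeric(obs$n)
  if (any(obs$n < 1)) stop("denominator n must be >= 1 (missing cells are omitted rows, not n = 0)")
  bad <- which(obs$y < 0 | obs$y > obs$n)
  if (length(bad))
    stop(sprintf("row %d (block %s, round %d): y = %g outside [0, n = %g]",
                 bad[1L], obs$block_id[bad[1L]], obs$round[bad[1L]],
                 obs$y[bad[1L]], obs$n[bad[1L]]))
  key <- paste(obs$block_id, obs$round)
  if (anyDuplicated(key))
    stop("duplicate observation for (block, round): ",
         key[duplicated(key)][1L])
  if (is.null(rounds)) rounds <- sort(unique(obs$round))
  rounds <- as.integer(rounds)
  if (!all(obs$round %in% rounds))
    stop("observation round outside declared rounds")
  if (is.null(block_ids)) block_ids <- sort(unique(obs$block_id))
  block_ids <- as.character(block_ids)
  if (!all(obs$block_id %in% block_ids))
    stop("observation block not in declared block universe: ",
         setdiff(obs$block_id, block_ids)[1L])
  full <- expand.grid(block_id = block_ids, round = rounds,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fkey <- paste(full$block_id, full$round)
  missing <- full[!(fkey %in% key), , drop = FALSE]
  rownames(missing) <- NULL
  obs <- obs[order(match(obs$block_id, block_ids), obs$round),
             req, drop = FALSE]
  rownames(obs) <- NULL
  structure(list(indicator_id = indicator_id, family = family,
                 observations = obs, rounds = rounds,
                 block_ids = block_ids, missing = missing),
            class = "indicator_dataset")
}

#' @export
print.indicator_dataset <- function(x, ...) {
  cat(sprintf(
    "<indicator_dataset> '%s' (%s): %d blocks x %d rounds, %d observed, %d missing\n",
    x$indicator_id, x$family, length(x$block_ids), length(x$rounds),
    nrow(x$observations), nrow(x$missing)))
  invisible(x)
}

#' Raw block-level proportion
#'
#' The unsmoothed estimate `y / n` for one observed cell. A zero denominator
#' is not a zero proportion but an unobserved cell, and is rejected.
#'
#' @param y successes (binary) or summed count (count family).
#' @param n denominator (binary) or summed maximum possible count.
#' @return `y / n`, in `[0, 1]`.
#' @export
raw_proportion <- function(y, n) {
  if (any(n == 0)) stop("n = 0 marks a missing cell, not a zero proportion")
  if (any(n < 1) || any(y < 0) || any(y > n)) stop("need 0 <= y <= n, n >= 1")
  y / n
}

#' Block-level ratio for count indicators
#'
#' Aggregates per-respondent `(count, max_count)` records into the block
#' estimate as a ratio of sums, `sum(count) / sum(max_count)`. This equals a
#' mean of per-respondent ratios weighted by each respondent's maximum
#' possible count, which is the natural weighting when the maximum varies
#' across respondents (e.g. a shorter advice-item list in one survey round),
#' and it yields an aggregated `(y, n)` pair directly usable by the Poisson
#' model with `n` as exposure.
#'
#' @param counts per-respondent observed counts.
#' @param max_counts per-respondent maximum possible counts (>= 1).
#' @return list with `value` (the ratio), and the aggregated `y` and `n`.
#' @export
#' @examples
#' weighted_count_ratio(c(3, 4), c(5, 10))$value  # 7/15
weighted_count_ratio <- function(counts, max_counts) {
  if (length(counts) != length(max_counts))
    stop("counts and max_counts must have equal length")
  if (any(max_counts < 1)) stop("max_count must be >= 1")
  bad <- which(counts > max_counts | counts < 0)
  if (length(bad))
    stop(sprintf("record %d: count %g outside [0, max_count = %g]",
                 bad[1L], counts[bad[1L]], max_counts[bad[1L]]))
  y <- sum(counts); n <- sum(max_counts)
  list(value = y / n, y = y, n = n)
}

#' Read indicator observations from CSV
#'
#' Two dialects are accepted. Aggregated:
#' `indicator_id,family,block_id,round,y,n`. Individual-level (count family
#' only): `indicator_id,block_id,round,count,max_count`, aggregated per
#' block-round on read via [weighted_count_ratio()].
#'
#' @param file CSV path.
#' @param graph optional `block_graph`; when given, its block ids define the
#'   universe so graph blocks absent from the table become missing cells.
#' @param family family override for the individual-level dialect (which
#'   carries no `family` column); defaults to `"count"` there.
#' @return named list of `indicator_dataset`, one per indicator in the file.
#' @export
read_observations <- function(file, graph = NULL, family = NULL) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  block_ids <- if (!is.null(graph)) graph$block_ids else NULL
  if (all(c("count", "max_count") %in% names(tab))) {
    fam <- if (is.null(family)) "count" else family
    if (fam != "count")
      stop("individual-level dialect is defined for the count family only")
    split_ind <- split(tab, tab$indicator_id)
    return(lapply(split_ind, function(d) {
      agg <- do.call(rbind, lapply(
        split(d, paste(d$block_id, d$round)),
        function(g) {
          w <- weighted_count_ratio(g$count, g$max_count)
          data.frame(block_id = g$block_id[1L], round = g$round[1L],
                     y = w$y, n = w$n, stringsAsFactors = FALSE)
        }))
      indicator_dataset(d$indicator_id[1L], "count", agg,
                        block_ids = block_ids)
    }))
  }
  req <- c("indicator_id", "family", "block_id", "round", "y", "n")
  if (!all(req %in% names(tab)))
    stop("observation CSV needs columns ", paste(req, collapse = ","))
  lapply(split(tab, tab$indicator_id), function(d) {
    fam <- unique(d$family)
    if (length(fam) != 1L || !fam %in% c("binary", "count"))
      stop("unknown or inconsistent family for indicator ",
           d$indicator_id[1L], ": ", paste(fam, collapse = ", "))
    indicator_dataset(d$indicator_id[1L], fam, d, block_ids = block_ids)
  })
}

#' Write indicator observations to CSV
#'
#' Emits the aggregated dialect plus a `raw_value` column (`y / n`).
#' Missing cells are omitted rows, preserving the round-trip property
#' `read_observations(write_observations(x))`.
#'
#' @param datasets an `indicator_dataset` or list of them.
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_observations <- function(datasets, file) {
  if (inherits(datasets, "indicator_dataset")) datasets <- list(datasets)
  rows <- do.call(rbind, lapply(datasets, function(d) {
    cbind(indicator_id = d$indicator_id, family = d$family,
          d$observations,
          raw_value = raw_proportion(d$observations$y, d$observations$n))
  }))
  utils::write.csv(rows, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Raw estimates table for a dataset
#'
#' @param dataset an `indicator_dataset`.
#' @return data frame `block_id, round, value` over observed cells.
#' @export
raw_estimates <- function(dataset) {
  o <- dataset$observations
  data.frame(block_id = o$block_id, round = o$round,
             value = raw_proportion(o$y, o$n), stringsAsFactors = FALSE)
}

#' Validate a dataset against a contiguity graph
#'
#' Hard-fails when an observation's block is unknown to the graph (the model
#' could not place it); otherwise collects advisory issues: graph blocks
#' fully unobserved, rounds with zero observations, and the denominator
#' range.
#'
#' @param dataset an `indicator_dataset`.
#' @param graph a `block_graph`.
#' @return list with `issues` (character), `denominator_range`, and
#'   `missing_cells`.
#' @export
validate_dataset <- function(dataset, graph) {
  stopifnot(inherits(dataset, "indicator_dataset"),
            inherits(graph, "block_graph"))
  unknown <- setdiff(dataset$observations$block_id, graph$block_ids)
  if (length(unknown))
    stop("observation block(s) absent from graph: ",
         paste(unknown, collapse = ", "))
  issues <- character(0)
  silent_blocks <- setdiff(graph$block_ids, dataset$observations$block_id)
  if (length(silent_blocks))
    issues <- c(issues, sprintf("%d block(s) with no observations in any round",
                                length(silent_blocks)))
  for (r in dataset$rounds)
    if (!any(dataset$observations$round == r))
      issues <- c(issues, sprintf("round %d has zero observations", r))
  rng <- range(dataset$observations$n)
  list(issues = issues, denominator_range = rng,
       missing_cells = nrow(dataset$missing))
}
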