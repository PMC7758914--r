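#' Deviance information criterion of a fit
#'
#' `Dbar` is the posterior mean deviance, `pD = Dbar - D(posterior mean)`
#' the effective number of parameters, and `DIC = Dbar + pD`. Lower DIC is
#' preferred.
#'
#' @param fit a `bym_fit`, or any list carrying `deviance_draws` and
#'   `deviance_at_mean`.
#' @return list `dbar, d_at_mean, pd, dic`.
#' @export
compute_dic <- function(fit) {
  stopifnot(is.list(fit), !is.null(fit$deviance_draws),
            !is.null(fit$deviance_at_mean))
  if (length(fit$deviance_draws) < 100L)
    stop("need at least 100 posterior deviance draws for DIC")
  dbar <- mean(fit$deviance_draws)
  pd <- dbar - fit$deviance_at_mean
  list(dbar = dbar, d_at_mean = fit$deviance_at_mean, pd = pd,
       dic = dbar + pd)
}

#' Select between interaction and no-interaction fits by DIC
#'
#' The fit with the lower DIC is chosen; a lower DIC for the interaction
#' model is taken as evidence of block-level variation in trends. Exact ties
#' resolve to the simpler (no-interaction) model.
#'
#' @param fit_no_interaction,fit_interaction `bym_fit`s of the same dataset
#'   on the same graph.
#' @return list with `chosen` (a `bym_fit`), `interaction_evidence`,
#'   `dic_table` (data frame), and the two DIC summaries.
#' @export
select_model <- function(fit_no_interaction, fit_interaction) {
  f0 <- fit_no_interaction; f1 <- fit_interaction
  stopifnot(inherits(f0, "bym_fit"), inherits(f1, "bym_fit"))
  if (f0$include_interaction || !f1$include_interaction)
    stop("arguments must be (no-interaction fit, interaction fit)")
  if (!identical(f0$block_ids, f1$block_ids) ||
      !identical(f0$rounds, f1$rounds) ||
      !identical(f0$obs, f1$obs) ||
      !identical(f0$y, f1$y))
    stop("the two fits are not on the same dataset")
  d0 <- compute_dic(f0); d1 <- compute_dic(f1)
  evidence <- d1$dic < d0$dic
  list(chosen = if (evidence) f1 else f0,
       interaction_evidence = evidence,
       dic_no_interaction = d0, dic_interaction = d1,
       dic_table = data.frame(
         model = c("no_interaction", "interaction"),
         dbar = c(d0$dbar, d1$dbar), pd = c(d0$pd, d1$pd),
         dic = c(d0$dic, d1$dic)))
}

#' Block-level trend estimates by posterior resampling
#'
#' For each block, resamples `resamples` values of `beta + delta_i`, the
#' per-year change in the linear predictor, exponentiates, and summarises by
#' the median and the 2.5th/97.5th quantiles — the trend odds ratio (binary)
#' or rate ratio (count) per year, with its 95% credible interval. Each
#' block's trend is then classified by [classify_trend()].
#'
#' In `"joint"` mode (default) `beta` and `delta_i` are resampled as pairs
#' from the same posterior draw, preserving their posterior correlation. In
#' `"independent"` mode each is resampled independently from its own
#' marginal, which mirrors adding two independently drawn values per
#' resample. For a no-interaction fit every block shares the single trend
#' built from `beta` alone.
#'
#' @param fit a `bym_fit`, or any list carrying `beta`, `delta`,
#'   `block_ids` and `include_interaction` (posterior draws).
#' @param resamples number of posterior resamples (>= 1000).
#' @param seed integer seed; results are deterministic given the seed.
#' @param mode `"joint"` or `"independent"`.
#' @return data frame `block_id, or_point, lo, hi, category`.
#' @export
block_trends <- function(fit, resamples = 10000L, seed,
                         mode = c("joint", "independent")) {
  stopifnot(is.list(fit), !is.null(fit$beta), !is.null(fit$block_ids),
            !is.null(fit$include_interaction))
  mode <- match.arg(mode)
  resamples <- as.integer(resamples)
  if (resamples < 1000L) stop("resamples must be >= 1000")
  if (missing(seed)) stop("a seed is required")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  nd <- length(fit$beta)
  nb <- length(fit$block_ids)

  if (!fit$include_interaction) {
    b <- fit$beta[sample.int(nd, resamples, replace = TRUE)]
    q <- stats::quantile(exp(b), c(0.5, 0.025, 0.975), names = FALSE)
    out <- data.frame(block_id = fit$block_ids,
                      or_point = q[1L], lo = q[2L], hi = q[3L],
                      stringsAsFactors = FALSE)
    out$category <- classify_trend(out$lo, out$hi)
    return(out)
  }

  ib <- sample.int(nd, resamples, replace = TRUE)
  id <- if (mode == "joint") ib else sample.int(nd, resamples, replace = TRUE)
  b <- fit$beta[ib]
  out <- do.call(rbind, lapply(seq_len(nb), function(i) {
    s <- b + fit$delta[id, i]
    q <- stats::quantile(exp(s), c(0.5, 0.025, 0.975), names = FALSE)
    data.frame(block_id = fit$block_ids[i],
               or_point = q[1L], lo = q[2L], hi = q[3L],
               stringsAsFactors = FALSE)
  }))
  out$category <- classify_trend(out$lo, out$hi)
  rownames(out) <- NULL
  out
}

#' Classify a trend by its 95% credible interval
#'
#' A 95% CrI lying entirely below 1.0 means at least 97.5% posterior
#' probability that the relative change per year is below 1.0 (`decrease`);
#' entirely above 1.0 means at least 97.5% probability of a rise
#' (`increase`); otherwise `indeterminate`. Bounds exactly equal to 1.0 are
#' indeterminate.
#'
#' @param lo,hi vectors of CrI bounds on the OR scale (positive, `lo <= hi`).
#' @return character vector of categories.
#' @export
#' @examples
#' classify_trend(c(0.36, 1.02, 0.83), c(0.59, 1.32, 1.23))
classify_trend <- function(lo, hi) {
  if (any(lo <= 0) || any(hi <= 0)) stop("CrI bounds must be positive")
  if (any(lo > hi)) stop("lo must not exceed hi")
  ifelse(hi < 1.0, "decrease", ifelse(lo > 1.0, "increase", "indeterminate"))
}

#' Summarise an indicator's trend classification
#'
#' @param trends data frame from [block_trends()].
#' @param selection result of [select_model()] (optional; supplies the
#'   interaction flag and DICs).
#' @param indicator_id indicator name (defaults from selection's chosen fit).
#' @return one-row data frame: indicator, interaction flag, DICs, category
#'   counts and OR range.
#' @export
summarize_indicator <- function(trends, selection = NULL,
                                indicator_id = NULL) {
  stopifnot(all(c("block_id", "or_point", "category") %in% names(trends)))
  if (is.null(indicator_id))
    indicator_id <- if (!is.null(selection)) selection$chosen$indicator_id
                    else NA_character_
  data.frame(
    indicator_id = indicator_id,
    interaction_selected = if (!is.null(selection))
      selection$interaction_evidence else NA,
    dic_no_int = if (!is.null(selection))
      selection$dic_no_interaction$dic else NA_real_,
    dic_int = if (!is.null(selection))
      selection$dic_interaction$dic else NA_real_,
    n_increase = sum(trends$category == "increase"),
    n_decrease = sum(trends$category == "decrease"),
    n_indeterminate = sum(trends$category == "indeterminate"),
    or_min = min(trends$or_point), or_max = max(trends$or_point),
    stringsAsFactors = FALSE)
}

#' Annotate GeoJSON polygons with trend results
#'
#' Adds `or_point` and `category` properties per feature, for downstream
#' choropleth rendering.
#'
#' @param geojson path to the input GeoJSON FeatureCollection.
#' @param trends data frame from [block_trends()].
#' @param file output path.
#' @param id_property feature property holding the block id.
#' @return `file`, invisibly.
#' @export
write_trends_geojson <- function(geojson, trends, file,
                                 id_property = "block_id") {
  gj <- jsonlite::fromJSON(geojson, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  idx <- stats::setNames(seq_len(nrow(trends)), trends$block_id)
  gj$features <- lapply(gj$features, function(f) {
    id <- as.character(f$properties[[id_property]])
    k <- idx[id]
    if (!is.na(k)) {
      f$properties$or_point <- trends$or_point[k]
      f$properties$category <- trends$category[k]
    }
    f
  })
  jsonlite::write_json(gj, file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(file)
}
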