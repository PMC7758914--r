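#' Specify the generating truth for a synthetic indicator dataset
#'
#' The generator draws data from the same model the analysis assumes:
#' a zero-centred intrinsic CAR spatial field `u` (sd `sd_u`), iid
#' unstructured effects `v` (sd `sd_v`), centred per-block trend deviations
#' `delta` (sd `sd_delta`; 0 disables the interaction), a state-average
#' linear trend `beta0` per year on the link scale, and a baseline `alpha0`.
#' Denominators are drawn uniformly from `n_range` per block-round — the
#' survey-scale default (19, 123) reflects block sample sizes of
#' community-based household surveys — and a fraction of cells can be set
#' missing (no respondents).
#'
#' @param alpha0 baseline level on the logit (binary) or log (count) scale.
#' @param beta0 true per-year trend on the link scale (`exp(beta0)` is the
#'   state-average OR per year).
#' @param sd_u,sd_v,sd_delta standard deviations of the spatial field, the
#'   unstructured effects, and the trend deviations.
#' @param n_range integer denominator range per block-round.
#' @param rounds number of survey rounds.
#' @param missing_fraction fraction of individual block-round cells set
#'   missing (scattered single-round gaps).
#' @param missing_block_fraction fraction of blocks set missing in every
#'   round — the "no respondents for this indicator" pattern whose
#'   imputation rests entirely on the spatial neighbourhood.
#' @param family `"binary"` or `"count"`.
#' @param delta_values optional explicit per-block trend deviations (used
#'   for designed truths, e.g. a bimodal split of rising and declining
#'   blocks); overrides `sd_delta` when given.
#' @return a `truth_spec`.
#' @export
truth_spec <- function(alpha0 = 0, beta0 = 0, sd_u = 0.5, sd_v = 0.1,
                       sd_delta = 0, n_range = c(19L, 123L), rounds = 4L,
                       missing_fraction = 0, missing_block_fraction = 0,
                       family = c("binary", "count"),
                       delta_values = NULL) {
  family <- match.arg(family)
  stopifnot(sd_u >= 0, sd_v >= 0, sd_delta >= 0,
            length(n_range) == 2L, n_range[1L] >= 1,
            n_range[1L] <= n_range[2L], rounds >= 1,
            missing_fraction >= 0, missing_fraction < 1,
            missing_block_fraction >= 0, missing_block_fraction < 1)
  structure(list(alpha0 = alpha0, beta0 = beta0, sd_u = sd_u, sd_v = sd_v,
                 sd_delta = sd_delta, n_range = as.integer(n_range),
                 rounds = as.integer(rounds),
                 missing_fraction = missing_fraction,
                 missing_block_fraction = missing_block_fraction,
                 family = family,
                 delta_values = delta_values),
            class = "truth_spec")
}

#' Named generating scenarios
#'
#' Documented presets for the qualitative regimes the analysis is meant to
#' distinguish: a universal rise (`beta0 = log 1.25`, near-common trends), a
#' universal decline (`beta0 = log 0.8`), trends in opposite directions
#' across blocks (`beta0 = 0`, `sd_delta = 0.4`), a common trend with no
#' interaction at all (`sd_delta = 0`), and a dataset with missing
#' block-rounds.
#'
#' @param name one of `"universal_rise"`, `"universal_decline"`,
#'   `"opposite_trends"`, `"no_interaction"`, `"with_missing"`.
#' @param ... overrides passed to [truth_spec()].
#' @return a `truth_spec`.
#' @export
scenario <- function(name, ...) {
  presets <- list(
    universal_rise = list(alpha0 = -0.5, beta0 = log(1.25), sd_u = 0.3,
                          sd_v = 0.1, sd_delta = 0.05),
    universal_decline = list(alpha0 = 0.5, beta0 = log(0.8), sd_u = 0.3,
                             sd_v = 0.1, sd_delta = 0.05),
    opposite_trends = list(alpha0 = 0, beta0 = 0, sd_u = 0.5, sd_v = 0.1,
                           sd_delta = 0.4),
    no_interaction = list(alpha0 = 0, beta0 = log(1.1), sd_u = 0.5,
                          sd_v = 0.1, sd_delta = 0),
    with_missing = list(alpha0 = 0, beta0 = log(1.15), sd_u = 0.5,
                        sd_v = 0.1, sd_delta = 0.2,
                        missing_block_fraction = 0.02))
  if (!name %in% names(presets))
    stop("unknown scenario '", name, "'; valid: ",
         paste(names(presets), collapse = ", "))
  args <- utils::modifyList(presets[[name]], list(...))
  do.call(truth_spec, args)
}

#' Default synthetic block map
#'
#' A 23 x 24 rook lattice with 18 cells removed from one corner, giving 534
#' contiguous blocks — a stand-in for a state block map with the same scale
#' and a realistic adjacency structure (the analysis depends on the map only
#' through adjacency).
#'
#' @return a `block_graph` with 534 blocks.
#' @export
default_block_map <- function() {
  g <- make_lattice(23L, 24L)
  drop <- sprintf("r%dc%d", 23L, 24L - seq_len(18L) + 1L)
  drop_blocks(g, drop)
}

#' Generate a synthetic indicator dataset with known truth
#'
#' Draws `u ~ ICAR(sd_u)` (zero-centred per component), `v` and `delta`
#' iid normal (`delta` centred), sets
#' `eta_it = alpha0 + beta0 t + u_i + v_i + delta_i t` with `t = 0, 1, ...`
#' per round, draws denominators uniformly from `n_range` and outcomes from
#' the binomial (logit) or Poisson (log) model, then deletes
#' `missing_fraction` of cells. Deterministic given `seed`.
#'
#' @param graph a `block_graph`.
#' @param truth a `truth_spec`.
#' @param seed integer seed.
#' @param indicator_id name for the generated indicator.
#' @return list with `dataset` (an `indicator_dataset`) and `truth` (the
#'   realised `alpha`, `beta`, `u`, `v`, `delta`, per-block `true_or`, and
#'   per-cell true values).
#' @export
generate_dataset <- function(graph, truth, seed,
                             indicator_id = "synthetic") {
  stopifnot(inherits(graph, "block_graph"), inherits(truth, "truth_spec"))
  if (missing(seed)) stop("a seed is required")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  nb <- graph$n_blocks
  nr <- truth$rounds
  tvals <- seq_len(nr) - 1

  u <- if (truth$sd_u > 0)
    sample_icar_field(icar_precision(graph), 1 / truth$sd_u^2,
                      seed = as.integer(seed) * 2L + 1L)
  else stats::setNames(numeric(nb), graph$block_ids)

  set.seed(as.integer(seed))
  v <- stats::rnorm(nb, 0, truth$sd_v)
  delta <- if (!is.null(truth$delta_values)) {
    stopifnot(length(truth$delta_values) == nb)
    as.numeric(truth$delta_values)
  } else if (truth$sd_delta > 0) {
    d <- stats::rnorm(nb, 0, truth$sd_delta)
    d - mean(d)
  } else numeric(nb)

  eta <- outer(u + v, rep(1, nr)) + truth$alpha0 +
    outer(delta, tvals) + outer(rep(1, nb), truth$beta0 * tvals)
  n <- matrix(sample(seq(truth$n_range[1L], truth$n_range[2L]),
                     nb * nr, replace = TRUE), nb, nr)
  if (truth$family == "binary") {
    p <- stats::plogis(eta)
    y <- matrix(stats::rbinom(nb * nr, as.vector(n), as.vector(p)), nb, nr)
    true_val <- p
  } else {
    mu <- exp(eta)
    lam <- n * mu
    y <- matrix(stats::rpois(nb * nr, as.vector(lam)), nb, nr)
    y <- pmin(y, n)  # counts cannot exceed the maximum possible count
    true_val <- mu
  }

  obs <- data.frame(
    block_id = rep(graph$block_ids, nr),
    round = rep(seq_len(nr), each = nb),
    y = as.vector(y), n = as.vector(n), stringsAsFactors = FALSE)
  if (truth$missing_block_fraction > 0) {
    nbm <- max(1L, round(truth$missing_block_fraction * nb))
    gone <- sample(graph$block_ids, nbm)
    obs <- obs[!(obs$block_id %in% gone), , drop = FALSE]
  }
  if (truth$missing_fraction > 0) {
    nmiss <- round(truth$missing_fraction * nrow(obs))
    if (nmiss >= nrow(obs)) stop("missing_fraction removes every cell")
    if (nmiss > 0) obs <- obs[-sample.int(nrow(obs), nmiss), , drop = FALSE]
  }
  if (nrow(obs) == 0L) stop("missingness removed every observation")
  ds <- indicator_dataset(indicator_id, truth$family, obs,
                          rounds = seq_len(nr), block_ids = graph$block_ids)
  list(dataset = ds,
       truth = list(alpha = truth$alpha0, beta = truth$beta0,
                    u = u, v = stats::setNames(v, graph$block_ids),
                    delta = stats::setNames(delta, graph$block_ids),
                    true_or = stats::setNames(exp(truth$beta0 + delta),
                                              graph$block_ids),
                    true_values = true_val, spec = truth))
}

#' Write a synthetic dataset and its truth to disk
#'
#' Emits the observation CSV dialect of [write_observations()] plus a
#' `truth.csv` (`block_id,u,v,delta,true_or`) and, when the graph came from
#' [make_lattice()]/[default_block_map()], a lattice GeoJSON.
#'
#' @param sim result of [generate_dataset()].
#' @param graph the `block_graph` used.
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
write_synthetic <- function(sim, graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_obs <- file.path(dir, "observations.csv")
  write_observations(sim$dataset, f_obs)
  f_truth <- file.path(dir, "truth.csv")
  tr <- sim$truth
  utils::write.csv(data.frame(block_id = names(tr$u), u = tr$u, v = tr$v,
                              delta = tr$delta, true_or = tr$true_or,
                              row.names = NULL),
                   f_truth, row.names = FALSE)
  f_geo <- file.path(dir, "blocks.geojson")
  write_lattice_geojson(graph, f_geo)
  f_edges <- file.path(dir, "edges.csv")
  utils::write.csv(data.frame(
    block_a = graph$block_ids[graph$edges[, 1L]],
    block_b = graph$block_ids[graph$edges[, 2L]]),
    f_edges, row.names = FALSE)
  invisible(c(observations = f_obs, truth = f_truth, geojson = f_geo,
              edges = f_edges))
}

#' Write lattice block polygons as GeoJSON
#'
#' Block ids of the form `"r<i>c<j>"` become unit squares at column/row
#' coordinates, producing a FeatureCollection whose rook adjacency matches
#' the lattice graph.
#'
#' @param graph a lattice-derived `block_graph`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_lattice_geojson <- function(graph, file) {
  rc <- regmatches(graph$block_ids,
                   regexec("^r([0-9]+)c([0-9]+)$", graph$block_ids))
  if (any(lengths(rc) != 3L))
    stop("graph block ids are not lattice ids (r<i>c<j>)")
  feats <- lapply(seq_along(graph$block_ids), function(k) {
    r <- as.numeric(rc[[k]][2L]); c <- as.numeric(rc[[k]][3L])
    ring <- list(c(c, r), c(c + 1, r), c(c + 1, r + 1), c(c, r + 1),
                 c(c, r))
    list(type = "Feature",
         properties = list(block_id = graph$block_ids[k]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
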