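test_that("edge-list graphs symmetrise, deduplicate and reject bad input", {
  g <- build_graph_from_edgelist(cbind(c("A", "B"), c("B", "A")), c("A", "B"))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$n_components, 1L)

  g0 <- build_graph_from_edgelist(matrix(character(0), ncol = 2),
                                  c("A", "B", "C"))
  expect_equal(nrow(g0$edges), 0L)
  expect_equal(g0$n_components, 3L)

  expect_error(build_graph_from_edgelist(cbind("A", "A"), c("A", "B")),
               "self-loop")
  expect_error(build_graph_from_edgelist(cbind("A", "Z"), c("A", "B")),
               "unknown block id")
  expect_error(build_graph_from_edgelist(cbind("A", "B"), c("A", "A", "B")),
               "duplicate")
})

test_that("lattice graphs have rook structure", {
  g <- make_lattice(6, 6)
  expect_equal(g$n_blocks, 36L)
  expect_equal(nrow(g$edges), 60L)  # 2 * 6 * 5

  expect_equal(nrow(make_lattice(1, 1)$edges), 0L)
  p <- make_lattice(1, 4)
  expect_equal(nrow(p$edges), 3L)
  deg <- tabulate(c(p$edges), nbins = 4L)
  expect_equal(sort(deg), c(1L, 1L, 2L, 2L))

  expect_error(make_lattice(0, 3), "positive")
})

test_that("polygon contiguity is rook by default, queen optionally", {
  tmp <- withr::local_tempfile(fileext = ".geojson")
  write_lattice_geojson(make_lattice(2, 2), tmp)
  g <- build_graph_from_polygons(tmp)
  expect_equal(g$n_blocks, 4L)
  expect_equal(nrow(g$edges), 4L)   # no diagonal edge on a 2x2 grid
  gq <- build_graph_from_polygons(tmp, contiguity = "queen")
  expect_equal(nrow(gq$edges), 6L)  # diagonals join at the shared corner

  w3 <- withr::local_tempfile(fileext = ".geojson")
  write_lattice_geojson(make_lattice(1, 3), w3)
  g3 <- build_graph_from_polygons(w3)
  expect_equal(sort(tabulate(c(g3$edges), 3L)), c(1L, 1L, 2L))

  one <- withr::local_tempfile(fileext = ".geojson")
  write_lattice_geojson(make_lattice(1, 1), one)
  g1 <- build_graph_from_polygons(one)
  expect_equal(nrow(g1$edges), 0L)
  expect_equal(g1$n_components, 1L)
})

test_that("polygon reader rejects duplicate ids and empty geometries", {
  gj <- jsonlite::fromJSON(
    '{"type":"FeatureCollection","features":[
       {"type":"Feature","properties":{"block_id":"X"},
        "geometry":{"type":"Polygon",
          "coordinates":[[[0,0],[1,0],[1,1],[0,1],[0,0]]]}},
       {"type":"Feature","properties":{"block_id":"X"},
        "geometry":{"type":"Polygon",
          "coordinates":[[[1,0],[2,0],[2,1],[1,1],[1,0]]]}}]}',
    simplifyVector = FALSE)
  expect_error(build_graph_from_polygons(gj), "duplicate")
  gj$features[[2]]$properties$block_id <- "Y"
  gj$features[[2]]$geometry <- NULL
  expect_error(build_graph_from_polygons(gj), "Y")
})

test_that("ICAR precision has the degree/adjacency form and exact row sums", {
  pair <- icar_precision(two_block_graph())
  expect_equal(as.matrix(pair$Q),
               matrix(c(1, -1, -1, 1), 2,
                      dimnames = list(c("A", "B"), c("A", "B"))))

  g <- make_lattice(2, 2)
  ic <- icar_precision(g)
  expect_equal(unname(Matrix::diag(ic$Q)), rep(2, 4))
  expect_equal(max(abs(Matrix::rowSums(ic$Q))), 0)
  expect_equal(ic$rank_deficiency, 1L)
})

test_that("quadratic form of Q equals the sum of squared edge differences", {
  set.seed(11)
  for (g in list(make_lattice(3, 4), make_lattice(5, 2),
                 build_graph_from_edgelist(matrix(character(0), ncol = 2),
                                           letters[1:4]))) {
    Q <- as.matrix(icar_precision(g)$Q)
    for (rep in 1:5) {
      x <- rnorm(g$n_blocks)
      direct <- if (nrow(g$edges)) # oracle: explicit pairwise differences
        sum((x[g$edges[, 1]] - x[g$edges[, 2]])^2) else 0
      expect_equal(drop(t(x) %*% Q %*% x), direct, tolerance = 1e-10)
    }
  }
})

test_that("Q eigenstructure: zero eigenvalue multiplicity = components", {
  g2 <- drop_blocks(make_lattice(2, 4), c("r1c3", "r2c3"))  # splits in two
  expect_equal(g2$n_components, 2L)
  ic <- icar_precision(g2)
  ev <- eigen(as.matrix(ic$Q), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-9), 2L)
  expect_true(min(ev) > -1e-9)  # positive semidefinite
})

test_that("ICAR field draws are centred, reproducible and correctly scaled", {
  g <- make_lattice(3, 3)
  ic <- icar_precision(g)
  u1 <- sample_icar_field(ic, tau_u = 2, seed = 5)
  u2 <- sample_icar_field(ic, tau_u = 2, seed = 5)
  expect_identical(u1, u2)
  expect_lt(abs(mean(u1)), 1e-10)
  expect_error(sample_icar_field(ic, tau_u = 0, seed = 1), "positive")

  # pairwise-difference marginal on a 2-block pair is Normal(0, 1/tau_u)
  pair <- icar_precision(two_block_graph())
  d <- vapply(1:1000, function(s) {
    u <- sample_icar_field(pair, tau_u = 1, seed = s)
    u[["A"]] - u[["B"]]
  }, numeric(1))
  expect_equal(var(d), 1, tolerance = 0.15)
  expect_gt(ks.test(d, pnorm, sd = 1)$p.value, 0.01)
})

test_that("disconnected fields centre per component", {
  g <- build_graph_from_edgelist(rbind(c("a", "b"), c("c", "d")),
                                 letters[1:4])
  u <- sample_icar_field(icar_precision(g), tau_u = 1, seed = 3)
  expect_lt(abs(u[["a"]] + u[["b"]]), 1e-10)
  expect_lt(abs(u[["c"]] + u[["d"]]), 1e-10)
})

test_that("edge-list CSV reader round-trips a lattice", {
  g <- make_lattice(3, 3)
  ed <- withr::local_tempfile(fileext = ".csv")
  bl <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(block_a = g$block_ids[g$edges[, 1]],
                       block_b = g$block_ids[g$edges[, 2]]),
            ed, row.names = FALSE)
  write.csv(data.frame(block_id = g$block_ids), bl, row.names = FALSE)
  g2 <- read_graph_csv(ed, bl)
  expect_equal(g2$block_ids, g$block_ids)
  expect_equal(g2$edges, g$edges)
})
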