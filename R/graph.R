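#' Block contiguity graphs
#'
#' A `block_graph` records the administrative blocks under analysis and the
#' symmetric contiguity relation ("which blocks share a border") that drives
#' the intrinsic CAR spatial prior. Build one from an edge list
#' ([build_graph_from_edgelist()]), from GeoJSON polygons
#' ([build_graph_from_polygons()]), or as a synthetic rook lattice
#' ([make_lattice()]).
#'
#' @name block_graph
#' @keywords internal
NULL

new_block_graph <- function(block_ids, edges) {
  block_ids <- as.character(block_ids)
  stopifnot(!anyDuplicated(block_ids))
  n <- length(block_ids)
  # edges: 2-column integer matrix of block indices, i < j, deduplicated
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self-loop edges are not allowed")
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  comp <- graph_components(n, edges)
  structure(
    list(block_ids = block_ids,
         edges = edges,
         n_blocks = n,
         components = comp,
         n_components = max(comp, 0L)),
    class = "block_graph")
}

# Connected components by repeated label propagation over the edge list.
graph_components <- function(n, edges) {
  if (n == 0L) return(integer(0))
  comp <- seq_len(n)
  if (nrow(edges) > 0L) {
    repeat {
      m1 <- pmin(comp[edges[, 1L]], comp[edges[, 2L]])
      changed <- FALSE
      for (k in seq_len(nrow(edges))) {
        i <- edges[k, 1L]; j <- edges[k, 2L]
        m <- min(comp[i], comp[j])
        if (comp[i] != m || comp[j] != m) {
          comp[i] <- m; comp[j] <- m; changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  match(comp, sort(unique(comp)))
}

#' @export
print.block_graph <- function(x, ...) {
  cat(sprintf("<block_graph> %d blocks, %d edges, %d component%s\n",
              x$n_blocks, nrow(x$edges), x$n_components,
              if (x$n_components == 1L) "" else "s"))
  invisible(x)
}

#' Build a contiguity graph from an edge list
#'
#' Edges are symmetrised and deduplicated; self-loops and references to
#' unknown blocks are rejected. Blocks named in `ids` but appearing in no
#' pair become isolated single-block components.
#'
#' @param pairs two-column matrix or data frame of block-id pairs
#'   (character), one row per contiguity relation; may be empty.
#' @param ids character vector of all block ids (the id universe).
#' @return a `block_graph`.
#' @export
#' @examples
#' g <- build_graph_from_edgelist(cbind(c("A", "B"), c("B", "A")), c("A", "B"))
#' g$edges  # one undirected edge
build_graph_from_edgelist <- function(pairs, ids) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate block ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs)
  if (length(pairs) == 0L) {
    return(new_block_graph(ids, NULL))
  }
  pairs <- matrix(as.character(pairs), ncol = 2L)
  ia <- match(pairs[, 1L], ids)
  ib <- match(pairs[, 2L], ids)
  bad <- which(is.na(ia) | is.na(ib))
  if (length(bad))
    stop("edge pair references unknown block id: (",
         pairs[bad[1L], 1L], ", ", pairs[bad[1L], 2L], ")")
  loops <- which(ia == ib)
  if (length(loops))
    stop("self-loop edge not allowed: (", pairs[loops[1L], 1L], ", ",
         pairs[loops[1L], 2L], ")")
  new_block_graph(ids, cbind(ia, ib))
}

#' Read an edge-list CSV into a contiguity graph
#'
#' Expects columns `block_a,block_b`; the id universe comes from
#' `blocks_file` (column `block_id`) when given, otherwise from the ids seen
#' in the edge file.
#'
#' @param edges_file path to the edge CSV.
#' @param blocks_file optional path to a `blocks.csv` naming all blocks.
#' @return a `block_graph`.
#' @export
read_graph_csv <- function(edges_file, blocks_file = NULL) {
  ed <- utils::read.csv(edges_file, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("block_a", "block_b") %in% names(ed)))
    stop("edge file must have columns block_a,block_b")
  ids <- if (is.null(blocks_file)) {
    sort(unique(c(ed$block_a, ed$block_b)))
  } else {
    bl <- utils::read.csv(blocks_file, stringsAsFactors = FALSE,
                          colClasses = "character")
    if (!"block_id" %in% names(bl)) stop("blocks file must have column block_id")
    bl$block_id
  }
  build_graph_from_edgelist(cbind(ed$block_a, ed$block_b), ids)
}

#' Build a contiguity graph from GeoJSON polygons
#'
#' Reads a GeoJSON FeatureCollection with one (Multi)Polygon feature per
#' block and connects blocks whose boundaries share a segment of positive
#' length (rook contiguity, the default) or at least one vertex (queen).
#' Coordinates are snapped on a 1e-9 grid before comparison so that
#' floating-point sliver gaps between nominally identical boundaries do not
#' break adjacency. The layer is assumed to be topologically noded
#' (neighbouring polygons share their boundary vertices), which holds for
#' the generated lattice files and for typical administrative boundary
#' exports.
#'
#' @param geojson path to a GeoJSON file, or an already-parsed list as
#'   returned by `jsonlite::fromJSON(..., simplifyVector = FALSE)`.
#' @param id_property name of the feature property holding the block id.
#' @param contiguity `"rook"` (shared border of positive length) or
#'   `"queen"` (shared vertex suffices).
#' @param snap snapping grid for coordinate comparison.
#' @return a `block_graph`.
#' @export
build_graph_from_polygons <- function(geojson, id_property = "block_id",
                                      contiguity = c("rook", "queen"),
                                      snap = 1e-9) {
  contiguity <- match.arg(contiguity)
  gj <- if (is.character(geojson)) {
    jsonlite::fromJSON(geojson, simplifyVector = FALSE)
  } else geojson
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  feats <- gj$features
  ids <- vapply(feats, function(f) {
    id <- f$properties[[id_property]]
    if (is.null(id)) stop("feature missing id property '", id_property, "'")
    as.character(id)
  }, character(1))
  if (anyDuplicated(ids))
    stop("duplicate block ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  # Per block: boundary rings as 2-column coordinate matrices.
  rings_of <- function(geom, id) {
    if (is.null(geom) || is.null(geom$type))
      stop("empty geometry for block '", id, "'")
    cm <- function(ring) {
      m <- matrix(unlist(ring, use.names = FALSE), ncol = 2L, byrow = TRUE)
      round(m / snap) * snap
    }
    switch(geom$type,
      Polygon = lapply(geom$coordinates, cm),
      MultiPolygon = unlist(lapply(geom$coordinates,
                                   function(poly) lapply(poly, cm)),
                            recursive = FALSE),
      stop("unsupported geometry type '", geom$type, "' for block '", id, "'"))
  }
  all_rings <- mapply(function(f, id) rings_of(f$geometry, id),
                      feats, ids, SIMPLIFY = FALSE)

  # Keys: vertices and undirected segments, as strings after snapping.
  vkey <- function(m) paste(format(m[, 1L], digits = 15),
                            format(m[, 2L], digits = 15), sep = ",")
  seg_keys <- function(rings) {
    unlist(lapply(rings, function(m) {
      k <- vkey(m)
      a <- k[-length(k)]; b <- k[-1L]
      keep <- a != b            # drop zero-length segments after snapping
      paste(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]), sep = "|")
    }))
  }
  vert_keys <- function(rings) unique(unlist(lapply(rings, vkey)))

  keys <- lapply(all_rings,
                 if (contiguity == "rook") seg_keys else vert_keys)
  # invert: key -> blocks touching it
  nblk <- length(ids)
  blk <- rep.int(seq_len(nblk), lengths(keys))
  key <- unlist(keys, use.names = FALSE)
  if (length(key)) {
    grp <- split(blk, key)
    grp <- grp[lengths(grp) > 1L]
    edges <- do.call(rbind, lapply(grp, function(b) {
      b <- unique(b)
      if (length(b) < 2L) return(NULL)
      t(utils::combn(b, 2L))
    }))
  } else edges <- NULL
  new_block_graph(ids, edges)
}

#' Rook-contiguity lattice graph
#'
#' A `rows` by `cols` grid of unit-square blocks with rook adjacency
#' (horizontal and vertical neighbours only); the standard synthetic stand-in
#' for an administrative block map. Block ids are `"r<i>c<j>"`.
#'
#' @param rows,cols positive lattice dimensions.
#' @return a `block_graph` with `rows * cols` blocks.
#' @export
#' @examples
#' make_lattice(6, 6)  # 36 blocks, 60 edges
make_lattice <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 1L || cols < 1L)
    stop("rows and cols must be positive integers")
  idx <- function(r, c) (r - 1L) * cols + c
  ids <- as.vector(t(outer(seq_len(rows), seq_len(cols),
                           function(r, c) sprintf("r%dc%d", r, c))))
  h <- if (cols > 1L) {
    r <- rep(seq_len(rows), each = cols - 1L)
    c <- rep(seq_len(cols - 1L), rows)
    cbind(idx(r, c), idx(r, c + 1L))
  } else NULL
  v <- if (rows > 1L) {
    r <- rep(seq_len(rows - 1L), each = cols)
    c <- rep(seq_len(cols), rows - 1L)
    cbind(idx(r, c), idx(r + 1L, c))
  } else NULL
  new_block_graph(ids, rbind(h, v))
}

#' Drop blocks from a lattice graph
#'
#' Used to carve irregular synthetic maps (for example 534 blocks from a
#' 23 x 24 lattice). Edges incident to dropped blocks are removed.
#'
#' @param graph a `block_graph`.
#' @param drop_ids block ids to remove.
#' @return a `block_graph` on the remaining blocks.
#' @export
drop_blocks <- function(graph, drop_ids) {
  stopifnot(inherits(graph, "block_graph"))
  keep <- !(graph$block_ids %in% drop_ids)
  ids <- graph$block_ids[keep]
  remap <- match(graph$block_ids, ids)
  e <- graph$edges
  if (nrow(e)) {
    e <- cbind(remap[e[, 1L]], remap[e[, 2L]])
    e <- e[stats::complete.cases(e), , drop = FALSE]
  }
  new_block_graph(ids, e)
}

#' ICAR precision structure of a contiguity graph
#'
#' The intrinsic conditional autoregressive prior on the spatial effect has
#' (scaled) precision matrix `Q` with `Q[i,i] = degree(i)` and
#' `Q[i,j] = -1` for neighbouring blocks. `Q` is symmetric positive
#' semidefinite with row sums zero; its null space is spanned by the
#' indicator vectors of the connected components, so its rank deficiency
#' equals the component count.
#'
#' @param graph a `block_graph`.
#' @return list with `Q` (a sparse symmetric [Matrix::sparseMatrix()]),
#'   `rank_deficiency`, and the block ordering `block_ids`.
#' @export
icar_precision <- function(graph) {
  stopifnot(inherits(graph, "block_graph"))
  n <- graph$n_blocks
  e <- graph$edges
  deg <- tabulate(c(e[, 1L], e[, 2L]), nbins = n)
  Q <- Matrix::sparseMatrix(
    i = c(seq_len(n), e[, 1L], e[, 2L]),
    j = c(seq_len(n), e[, 2L], e[, 1L]),
    x = c(as.numeric(deg), rep(-1, 2L * nrow(e))),
    dims = c(n, n), symmetric = FALSE)
  Q <- Matrix::forceSymmetric(Q)
  dimnames(Q) <- list(graph$block_ids, graph$block_ids)
  list(Q = Q, rank_deficiency = graph$n_components,
       block_ids = graph$block_ids)
}

#' Draw a zero-centred intrinsic CAR field
#'
#' Samples from the intrinsic ICAR density with precision `tau_u * Q`,
#' constrained to sum to zero within each connected component (the standard
#' resolution of the ICAR rank deficiency). The draw is generated in the
#' eigenbasis of `Q`: coordinates along eigenvectors with eigenvalue
#' `lambda > 0` are independent `N(0, 1 / (tau_u * lambda))`; null-space
#' coordinates are fixed at zero.
#'
#' @param precision result of [icar_precision()] (or a `block_graph`, which
#'   is converted).
#' @param tau_u positive precision scalar.
#' @param seed integer RNG seed; the draw is deterministic given `seed`.
#' @return numeric vector of per-block field values, named by block id.
#' @export
sample_icar_field <- function(precision, tau_u, seed) {
  if (inherits(precision, "block_graph")) precision <- icar_precision(precision)
  if (!is.numeric(tau_u) || length(tau_u) != 1L || !is.finite(tau_u) ||
      tau_u <= 0)
    stop("tau_u must be a positive scalar")
  Q <- as.matrix(precision$Q)
  n <- nrow(Q)
  eg <- eigen(Q, symmetric = TRUE)
  lam <- eg$values
  pos <- lam > max(lam, 1) * 1e-9
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  z <- numeric(n)
  z[pos] <- stats::rnorm(sum(pos), 0, 1 / sqrt(tau_u * lam[pos]))
  u <- as.vector(eg$vectors %*% z)
  # exact per-component centering guards against numerical drift
  comp <- graph_components(n, edge_index_matrix(Q))
  u <- u - stats::ave(u, comp)
  names(u) <- precision$block_ids
  u
}

# recover the edge list (i < j) from a dense Q matrix
edge_index_matrix <- function(Q) {
  w <- which(Q < -0.5 & upper.tri(Q), arr.ind = TRUE)
  if (!nrow(w)) matrix(integer(0), ncol = 2L) else unname(w)
}
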