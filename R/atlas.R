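#' Measurement types of a vertex atlas
#'
#' Vertexwise gray-matter measurements come in four types: cortical thickness
#' (`ct`), cortical surface area (`ca`), subcortical radial thickness (`st`)
#' and subcortical surface area (`sa`, a log-Jacobian analogue).
#'
#' @export
MEAS_TYPES <- c("ct", "ca", "st", "sa")

#' Construct a vertex atlas
#'
#' A vertex atlas records, for every vertex of the tessellated surfaces, its
#' measurement type, hemisphere and structure, together with the mesh
#' adjacency as an edge list. Vertex ids are 0-based and edges are stored with
#' the smaller id first. Edges may only connect vertices of the same
#' measurement type, hemisphere and structure (meshes are per-structure, so
#' clusters can never bridge structures).
#'
#' @param vertices data.frame with columns `vertex_id` (0-based integer,
#'   consecutive from 0), `meas_type` (one of [MEAS_TYPES]), `hemisphere`
#'   (`"L"`/`"R"`) and `structure_id` (integer).
#' @param edges two-column integer matrix of unordered vertex-id pairs
#'   (0-based), no self-loops, no duplicates.
#' @return An object of class `vertex_atlas`.
#' @export
vertex_atlas <- function(vertices, edges) {
  stopifnot(is.data.frame(vertices),
            all(c("vertex_id", "meas_type", "hemisphere", "structure_id")
                %in% names(vertices)))
  p <- nrow(vertices)
  vertices$vertex_id <- as.integer(vertices$vertex_id)
  if (!identical(vertices$vertex_id, 0:(p - 1L)))
    stop("vertex_id must be consecutive 0-based integers")
  if (!all(vertices$meas_type %in% MEAS_TYPES))
    stop("meas_type must be one of: ", paste(MEAS_TYPES, collapse = ", "))
  if (!all(vertices$hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L' or 'R'")
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges)) {
    if (any(edges < 0L) || any(edges >= p))
      stop("edge endpoints outside vertex range")
    if (any(edges[, 1] == edges[, 2])) stop("self-loop in edge list")
    edges <- t(apply(edges, 1L, sort))
    if (anyDuplicated(edges)) stop("duplicate edges in edge list")
    key1 <- paste(vertices$meas_type[edges[, 1] + 1L],
                  vertices$hemisphere[edges[, 1] + 1L],
                  vertices$structure_id[edges[, 1] + 1L])
    key2 <- paste(vertices$meas_type[edges[, 2] + 1L],
                  vertices$hemisphere[edges[, 2] + 1L],
                  vertices$structure_id[edges[, 2] + 1L])
    if (any(key1 != key2))
      stop("edges must stay within one meas_type/hemisphere/structure")
    o <- order(edges[, 1], edges[, 2])
    edges <- edges[o, , drop = FALSE]
  }
  structure(list(vertices = vertices, edges = edges, p = p,
                 cache = new.env(parent = emptyenv())),
            class = "vertex_atlas")
}

#' @export
print.vertex_atlas <- function(x, ...) {
  cat("vertex_atlas:", x$p, "vertices,", nrow(x$edges), "edges\n")
  print(table(x$vertices$meas_type, x$vertices$hemisphere))
  invisible(x)
}

#' Vertex ids (0-based) of one measurement type
#'
#' @param atlas a [vertex_atlas()].
#' @param type one of [MEAS_TYPES].
#' @return Integer vector of 0-based vertex ids.
#' @export
atlas_type_ids <- function(atlas, type) {
  type <- match.arg(type, MEAS_TYPES)
  atlas$vertices$vertex_id[atlas$vertices$meas_type == type]
}

#' Mesh adjacency as an igraph object
#'
#' Built once and cached on the atlas; vertex names are the 0-based ids.
#'
#' @param atlas a [vertex_atlas()].
#' @return An igraph undirected graph with `atlas$p` vertices.
#' @export
atlas_graph <- function(atlas) {
  g <- atlas$cache$graph
  if (is.null(g)) {
    g <- igraph::make_empty_graph(n = atlas$p, directed = FALSE)
    if (nrow(atlas$edges))
      g <- igraph::add_edges(g, as.vector(t(atlas$edges)) + 1L)
    atlas$cache$graph <- g
  }
  g
}

# One-step neighbour-averaging operator as a sparse p x p matrix:
# self-weight 1/2, the remaining 1/2 shared equally among mesh neighbours
# (isolated vertices keep weight 1). Smoothed values are X %*% t(S).
smoothing_operator <- function(atlas) {
  S <- atlas$cache$smooth_op
  if (is.null(S)) {
    p <- atlas$p
    e <- atlas$edges
    i <- c(e[, 1], e[, 2]) + 1L
    j <- c(e[, 2], e[, 1]) + 1L
    deg <- tabulate(i, nbins = p)
    w <- 0.5 / deg[i]
    diag_w <- ifelse(deg > 0, 0.5, 1)
    S <- Matrix::sparseMatrix(i = c(i, seq_len(p)), j = c(j, seq_len(p)),
                              x = c(w, diag_w), dims = c(p, p))
    atlas$cache$smooth_op <- S
  }
  S
}

#' Smooth vertex values along the mesh graph
#'
#' A graph-smoothing stand-in for a surface-based Gaussian kernel: each round
#' replaces every vertex value by half its own value plus half the mean of its
#' mesh neighbours. Smoothing never crosses structure boundaries (the
#' adjacency does not). `rounds = 0` is the identity. Smoothing is applied to
#' raw values; standardize afterwards.
#'
#' @param data a raw (unstandardized) [cohort_matrix()].
#' @param atlas the matching [vertex_atlas()].
#' @param rounds non-negative integer number of averaging rounds.
#' @return A new `cohort_matrix` with smoothed values.
#' @export
smooth_graph <- function(data, atlas, rounds) {
  stop_if_not_cohort(data)
  if (isTRUE(data$standardized))
    stop("smooth raw values and standardize afterwards")
  stopifnot(rounds >= 0, rounds == round(rounds))
  if (ncol(data$values) != atlas$p) stop("data/atlas dimension mismatch")
  if (rounds == 0) return(data)
  St <- Matrix::t(smoothing_operator(atlas))
  V <- data$values
  for (r in seq_len(rounds)) V <- as.matrix(V %*% St)
  dimnames(V) <- dimnames(data$values)
  out <- data
  out$values <- V
  out$cache <- new.env(parent = emptyenv())
  out
}

#' Read / write atlas TSV files
#'
#' The atlas is serialized as two TSVs: a vertex annotation table
#' (`vertex_id`, `meas_type`, `hemisphere`, `structure_id`) and an edge list
#' (`v1`, `v2`, smaller id first).
#'
#' @param anno_file,edge_file file paths.
#' @return `read_atlas` returns a [vertex_atlas()]; `write_atlas` returns the
#'   file paths invisibly.
#' @export
read_atlas <- function(anno_file, edge_file) {
  vert <- as.data.frame(data.table::fread(anno_file, sep = "\t"))
  edges <- as.data.frame(data.table::fread(edge_file, sep = "\t"))
  vertex_atlas(vert, as.matrix(edges[, c("v1", "v2")]))
}

#' @param atlas a [vertex_atlas()].
#' @rdname read_atlas
#' @export
write_atlas <- function(atlas, anno_file, edge_file) {
  data.table::fwrite(atlas$vertices, anno_file, sep = "\t")
  data.table::fwrite(data.frame(v1 = atlas$edges[, 1], v2 = atlas$edges[, 2]),
                     edge_file, sep = "\t")
  invisible(c(anno_file, edge_file))
}
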