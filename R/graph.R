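#' Threshold a correlation triangle to a target edge density
#'
#' Determines a correlation threshold theta per matrix such that the
#' resulting binary graph has density kappa = 2|E| / (V(V-1)), selecting the
#' top `round(kappa * V(V-1)/2)` pairs by correlation (ties broken by
#' lexicographic (i, j) order so graphs are reproducible). Missing entries
#' (degenerate pairs) are never selected. theta is reported as the midpoint
#' between the smallest selected and the largest unselected value (-1 when
#' every pair is selected), so `c > theta` reproduces the edge set whenever
#' the boundary is tie-free.
#'
#' @param C A `cor_triangle`.
#' @param kappa Target density in (0, 1).
#' @return An `fc_graph`: list with `V`, `edges` (m x 2 integer matrix,
#'   i < j, 1-based), `theta`, `kappa` (realized), `kappa_target`,
#'   `estimator`.
#' @export
density_threshold <- function(C, kappa) {
  stopifnot(inherits(C, "cor_triangle"))
  if (kappa <= 0 || kappa >= 1) stop("kappa must be in (0, 1)")
  V <- C$V
  np <- V * (V - 1) / 2
  m <- as.integer(round(kappa * np))
  ok <- !C$missing
  if (!any(ok)) stop("no non-missing correlations to threshold")
  if (m > sum(ok)) {
    stop("target density needs ", m, " edges but only ", sum(ok),
         " non-missing pairs exist")
  }
  ord <- order(-C$values, seq_len(np), na.last = TRUE)
  sel <- ord[seq_len(m)]
  i <- rep.int(seq_len(V - 1L), (V - 1L):1L)
  j <- sequence((V - 1L):1L) + i
  theta <- if (m == 0L) {
    max(C$values, na.rm = TRUE)
  } else {
    inc <- min(C$values[sel])
    excluded <- if (m < sum(ok)) C$values[ord[(m + 1L):sum(ok)]] else -1
    (inc + max(excluded)) / 2
  }
  structure(
    list(V = V,
         edges = cbind(i = i[sel], j = j[sel])[order(sel), , drop = FALSE],
         theta = theta,
         kappa = 2 * m / (V * (V - 1)),
         kappa_target = kappa,
         estimator = C$estimator),
    class = "fc_graph"
  )
}

#' @export
print.fc_graph <- function(x, ...) {
  cat("<fc_graph> V =", x$V, " |E| =", nrow(x$edges),
      " kappa =", signif(x$kappa, 4), " theta =", signif(x$theta, 4), "\n")
  invisible(x)
}

#' Edge table of a binary graph
#'
#' @param x An `fc_graph`.
#' @param ... Unused.
#' @return Tibble with columns `i`, `j` (1-based, i < j).
#' @export
tidy.fc_graph <- function(x, ...) {
  tibble::tibble(i = x$edges[, 1L], j = x$edges[, 2L])
}

#' @export
glance.fc_graph <- function(x, ...) {
  tibble::tibble(V = x$V, n_edges = nrow(x$edges), kappa = x$kappa,
                 kappa_target = x$kappa_target, theta = x$theta,
                 estimator = x$estimator)
}

#' Node degrees of a binary graph
#'
#' k_i is the number of edges incident to node i; the degree sum equals
#' 2|E|.
#'
#' @param G An `fc_graph`.
#' @return Integer vector of length V.
#' @export
graph_degree <- function(G) {
  stopifnot(inherits(G, "fc_graph"))
  tabulate(c(G$edges[, 1L], G$edges[, 2L]), nbins = G$V)
}

#' Standardize node degrees
#'
#' z-scores the degree sequence with the population (n-denominator) standard
#' deviation, giving maps a comparable scale across subjects: z_i =
#' (k_i - mean(k)) / sd_pop(k).
#'
#' @param k Numeric vector of raw degrees (>= 2 nodes).
#' @return Numeric vector with mean 0 and unit population variance.
#' @export
standardize_degrees <- function(k) {
  stopifnot(is.numeric(k), length(k) >= 2)
  s <- sqrt(mean((k - mean(k))^2))
  if (s == 0) stop("zero degree variance: cannot standardize")
  (k - mean(k)) / s
}

#' Per-node degree table
#'
#' @param G An `fc_graph`.
#' @param mask Optional `voxel_mask` from [load_dataset()]; adds the voxel
#'   coordinates of each node.
#' @param standardize Add a `z` column of standardized degrees.
#' @return Tibble with `node`, `degree`, optionally `z` and `x`, `y`, `z_vox`.
#' @export
degree_map <- function(G, mask = NULL, standardize = TRUE) {
  k <- graph_degree(G)
  out <- tibble::tibble(node = seq_len(G$V), degree = k)
  if (standardize) out$z <- standardize_degrees(k)
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "voxel_mask"))
    if (nrow(mask$coords) != G$V) stop("mask node count differs from graph")
    out$x <- mask$coords[, 1L]
    out$y <- mask$coords[, 2L]
    out$z_vox <- mask$coords[, 3L]
  }
  out
}

#' Group-average standardized degree map
#'
#' Averages per-subject standardized degree maps voxel-wise on a shared,
#' pre-aligned grid. Each subject supports only the voxels inside its own
#' mask (non-NA entries); voxels supported by fewer than
#' `support_fraction` of all subjects are discarded.
#'
#' @param kmaps List of 3D numeric arrays with identical dimensions; NA marks
#'   voxels outside a subject's mask.
#' @param support_fraction Minimum supporting fraction of subjects, in
#'   (0, 1]; default 0.2.
#' @return A `group_kmap`: list with `mean` (3D array, NA where discarded),
#'   `support` (3D integer array), `n_subjects`, `support_fraction`.
#' @export
group_average <- function(kmaps, support_fraction = 0.2) {
  if (length(kmaps) == 0L) stop("empty subject list")
  stopifnot(support_fraction > 0, support_fraction <= 1)
  dims <- dim(kmaps[[1L]])
  if (length(dims) != 3L) stop("maps must be 3D arrays")
  for (m in kmaps) {
    if (!identical(dim(m), dims)) stop("maps are not on a shared grid")
  }
  n <- length(kmaps)
  support <- Reduce(`+`, lapply(kmaps, function(m) !is.na(m)))
  total <- Reduce(`+`, lapply(kmaps, function(m) ifelse(is.na(m), 0, m)))
  avg <- total / support
  avg[support < support_fraction * n] <- NA_real_
  structure(list(mean = array(avg, dims),
                 support = array(as.integer(support), dims),
                 n_subjects = n, support_fraction = support_fraction),
            class = "group_kmap")
}

#' @export
print.group_kmap <- function(x, ...) {
  cat("<group_kmap>", paste(dim(x$mean), collapse = "x"),
      "grid, n_subjects =", x$n_subjects,
      " retained voxels =", sum(!is.na(x$mean)), "\n")
  invisible(x)
}

#' @export
as_tibble.group_kmap <- function(x, ...) {
  keep <- which(!is.na(x$mean))
  co <- arrayInd(keep, dim(x$mean))
  tibble::tibble(x = co[, 1L], y = co[, 2L], z = co[, 3L],
                 mean_z = x$mean[keep], support = x$support[keep])
}

#' Write a graph as an edge-list text file
#'
#' One edge per line, `i j`, 0-based by default (interoperability with
#' typical graph tools). A JSON sidecar `<path>.json` records V, theta and
#' kappa.
#'
#' @param G An `fc_graph`.
#' @param path Output path for the edge list.
#' @param zero_based Write 0-based node ids (default TRUE).
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(G, path, zero_based = TRUE) {
  stopifnot(inherits(G, "fc_graph"))
  e <- G$edges
  if (zero_based) e <- e - 1L
  utils::write.table(e, path, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(V = G$V, n_edges = nrow(G$edges), theta = G$theta,
         kappa = G$kappa, kappa_target = G$kappa_target,
         estimator = G$estimator, zero_based = zero_based),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read an edge-list written by [write_edgelist()]
#'
#' @param path Edge-list path (JSON sidecar `<path>.json` must exist).
#' @return An `fc_graph`.
#' @export
read_edgelist <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  e <- as.matrix(utils::read.table(path, col.names = c("i", "j")))
  if (nrow(e) != meta$n_edges) stop("edge count differs from sidecar")
  if (isTRUE(meta$zero_based)) e <- e + 1L
  structure(list(V = meta$V, edges = e, theta = meta$theta,
                 kappa = meta$kappa, kappa_target = meta$kappa_target,
                 estimator = meta$estimator),
            class = "fc_graph")
}
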