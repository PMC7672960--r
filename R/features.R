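#' Construct a feature matrix
#'
#' Thin container for a subjects-by-features block with a modality tag
#' (`GMV`, `SPL`, their selected variants `GMVS`/`SPLS`, or the
#' concatenated `C`) and optional provenance describing how it was made.
#'
#' @param values Numeric matrix, subjects in rows (rownames = subject
#'   ids), features in columns (colnames = feature names).
#' @param modality One of `"GMV"`, `"SPL"`, `"GMV+SPL"`, `"GMVS"`,
#'   `"SPLS"`, `"C"`.
#' @param provenance Optional list (source columns, scheme, parameters).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, modality, provenance = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  modality <- match.arg(modality,
                        c("GMV", "SPL", "GMV+SPL", "GMVS", "SPLS", "C"))
  if (is.null(rownames(values))) {
    abort("feature_matrix values need subject ids as rownames.",
          class = "braingcn_data_error")
  }
  structure(list(values = values, modality = modality,
                 subjects = rownames(values),
                 feature_names = colnames(values),
                 provenance = provenance),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix ", x$modality, "> ", nrow(x$values), " subjects x ",
      ncol(x$values), " features\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.feature_matrix <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(subject_id = x$subjects),
                   tibble::as_tibble(x$values))
}

#' Read a grey-matter-volume table
#'
#' Ingests a delimited table with header `subject_id, region_001, ...`.
#' Raw image processing (segmentation, atlas registration, surface-based
#' volume estimation) is upstream of this package; this is the entry
#' point for its per-region output.
#'
#' @param path CSV file path.
#' @param n_regions Expected number of region columns (default 90). Use
#'   `NULL` to accept whatever contiguous `region_###` set is present.
#' @return A [feature_matrix()] with modality `"GMV"`; row order is file
#'   order.
#' @export
read_gmv_table <- function(path, n_regions = 90L) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  if (!"subject_id" %in% names(tbl)) {
    abort("GMV table must have a `subject_id` column.",
          class = "braingcn_data_error")
  }
  reg_cols <- grep("^region_\\d+$", names(tbl), value = TRUE)
  p <- n_regions %||% length(reg_cols)
  expected <- region_names(p)
  missing <- setdiff(expected, reg_cols)
  if (length(missing)) {
    abort(paste0("GMV table is missing region column(s): ",
                 paste(head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) ", ..." else ""),
          class = "braingcn_data_error")
  }
  if (anyDuplicated(tbl$subject_id)) {
    dup <- unique(tbl$subject_id[duplicated(tbl$subject_id)])
    abort(paste0("Duplicate subject_id in GMV table: ",
                 paste(head(dup, 5), collapse = ", ")),
          class = "braingcn_data_error")
  }
  vals <- as.matrix(tbl[expected])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)
    abort(paste0("Non-numeric or non-finite GMV value at row ",
                 bad[1, 1], ", column ", expected[bad[1, 2]], "."),
          class = "braingcn_data_error")
  }
  rownames(vals) <- tbl$subject_id
  feature_matrix(vals, "GMV", provenance = list(source = path))
}

#' Pearson functional-connectivity matrix of one subject
#'
#' Pairwise Pearson correlation between the average time series of each
#' pair of regions.
#'
#' @param ts Region-by-time numeric matrix (one row per region, T >= 3
#'   columns).
#' @param subject_id Optional id carried along for diagnostics.
#' @return Symmetric correlation matrix with unit diagonal, class
#'   `connectivity_matrix`, attribute `subject_id`.
#' @export
compute_connectivity <- function(ts, subject_id = NULL) {
  stopifnot(is.matrix(ts), is.numeric(ts))
  if (ncol(ts) < 3) {
    abort("Need at least 3 timepoints to estimate correlations.",
          class = "braingcn_data_error")
  }
  if (anyNA(ts)) {
    abort("Time series contain missing values.",
          class = "braingcn_data_error")
  }
  v <- apply(ts, 1, stats::var)
  if (any(v == 0)) {
    abort(paste0("Zero-variance region(s): ",
                 paste(which(v == 0), collapse = ", "),
                 if (!is.null(subject_id)) paste0(" (subject ", subject_id, ")")),
          class = "braingcn_data_error")
  }
  r <- cor(t(ts))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(r, class = c("connectivity_matrix", "matrix", "array"),
            subject_id = subject_id)
}

parse_scheme <- function(scheme) {
  if (identical(scheme, "weighted")) return(list(kind = "weighted"))
  m <- regmatches(scheme, regexec("^proportional:(\\d*\\.?\\d+)$", scheme))[[1]]
  if (length(m) == 2) {
    p <- as.numeric(m[2])
    if (!(p > 0 && p <= 1)) {
      abort("Proportional threshold must lie in (0, 1].",
            class = "braingcn_config_error")
    }
    return(list(kind = "proportional", p = p))
  }
  abort(paste0("Unknown network scheme: ", scheme),
        class = "braingcn_config_error")
}

#' Build an individual brain network from a connectivity matrix
#'
#' The Pearson matrix is turned into an undirected graph under one of two
#' schemes. `"proportional:p"` keeps the `floor(p * n(n-1)/2)` strongest
#' off-diagonal edges by |r| (ties broken lexicographically by (i, j))
#' with unit edge lengths — the usual proportional-thresholding practice
#' in the MCI network literature. `"weighted"` keeps every edge with
#' nonzero |r| and assigns length 1/|r|, so weaker connections are longer
#' paths.
#'
#' @param conn A [compute_connectivity()] result (or symmetric matrix).
#' @param scheme `"proportional:p"` with p in (0, 1], or `"weighted"`.
#' @return An object of class `brain_network`: a list with `n_nodes`,
#'   `edges` (tibble `from`, `to`, `length`), and `scheme`.
#' @export
build_brain_network <- function(conn, scheme = "proportional:0.2") {
  sch <- parse_scheme(scheme)
  r <- unclass(conn)
  n <- nrow(r)
  ut <- which(upper.tri(r), arr.ind = TRUE)
  w <- abs(r[upper.tri(r)])
  if (sch$kind == "proportional") {
    m <- floor(sch$p * n * (n - 1) / 2)
    # order by |r| descending, ties by (i, j) lexicographic
    ord <- order(-w, ut[, 1], ut[, 2])
    keep <- head(ord, m)
    edges <- tibble::tibble(from = ut[keep, 1], to = ut[keep, 2],
                            length = 1)
  } else {
    keep <- which(w > 0)
    edges <- tibble::tibble(from = ut[keep, 1], to = ut[keep, 2],
                            length = 1 / w[keep])
  }
  structure(list(n_nodes = n, edges = edges, scheme = scheme),
            class = "brain_network")
}

#' Nodal shortest path length
#'
#' For each node, the mean shortest-path distance to every node reachable
#' from it (self excluded). A node with no reachable partner gets 0 and a
#' warning — a hub falling silent is information worth surfacing, not an
#' infinity worth propagating.
#'
#' @param net A [build_brain_network()] result.
#' @return Numeric vector of length `n_nodes`.
#' @export
nodal_spl <- function(net) {
  stopifnot(inherits(net, "brain_network"))
  g <- igraph::make_empty_graph(n = net$n_nodes, directed = FALSE)
  if (nrow(net$edges)) {
    g <- igraph::add_edges(g, rbind(net$edges$from, net$edges$to))
    igraph::E(g)$weight <- net$edges$length
  }
  d <- igraph::distances(g, algorithm = "dijkstra")
  diag(d) <- NA
  spl <- apply(d, 1, function(row) {
    reach <- row[is.finite(row)]
    if (!length(reach)) NA_real_ else mean(reach)
  })
  if (anyNA(spl)) {
    warn(paste0("Isolated node(s) with no reachable partner: ",
                paste(which(is.na(spl)), collapse = ", "),
                "; nodal SPL set to 0."))
    spl[is.na(spl)] <- 0
  }
  unname(spl)
}

#' Extract the two regional feature sets of a cohort
#'
#' Pairs the ingested grey-matter volumes (`F_GMV`) with nodal
#' shortest-path-length features (`F_SPL`) computed from each subject's
#' functional brain network, aligned on the same subject order.
#'
#' @param gmv A `feature_matrix` with modality `"GMV"` (e.g. from
#'   [read_gmv_table()]), or a `synthetic_cohort`.
#' @param timeseries Named list of region-by-time matrices keyed by
#'   subject id (ignored when `gmv` is a cohort).
#' @param scheme Network scheme passed to [build_brain_network()].
#' @return List with elements `gmv` and `spl`, both `feature_matrix`
#'   objects with identical subject order.
#' @export
extract_features <- function(gmv, timeseries = NULL,
                             scheme = "proportional:0.2") {
  if (inherits(gmv, "synthetic_cohort")) {
    cohort <- gmv
    vals <- as.matrix(cohort$gmv[, -1])
    rownames(vals) <- cohort$gmv$subject_id
    gmv <- feature_matrix(vals, "GMV")
    timeseries <- cohort$timeseries
  }
  stopifnot(inherits(gmv, "feature_matrix"))
  ids <- gmv$subjects
  missing_ts <- setdiff(ids, names(timeseries))
  extra_ts <- setdiff(names(timeseries), ids)
  if (length(missing_ts) || length(extra_ts)) {
    abort(paste0(
      "Subject sets differ between GMV and time series.",
      if (length(missing_ts)) paste0(" Missing time series: ",
        paste(head(missing_ts, 5), collapse = ", "), "."),
      if (length(extra_ts)) paste0(" Unmatched time series: ",
        paste(head(extra_ts, 5), collapse = ", "), ".")),
      class = "braingcn_data_error")
  }
  spl <- t(vapply(ids, function(id) {
    conn <- compute_connectivity(timeseries[[id]], subject_id = id)
    nodal_spl(build_brain_network(conn, scheme))
  }, numeric(nrow(timeseries[[ids[1]]]))))
  colnames(spl) <- region_names(ncol(spl))
  rownames(spl) <- ids
  list(gmv = gmv,
       spl = feature_matrix(spl, "SPL", provenance = list(scheme = scheme)))
}
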