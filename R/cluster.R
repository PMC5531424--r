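#' Choose the number of clusters by the gap statistic
#'
#' Runs k-means (best of `nstart` restarts) for each candidate `k` and
#' compares the log within-cluster dispersion to its expectation under
#' reference sets drawn uniformly over the PCA-aligned bounding box of the
#' data. The selected `k` is the smallest with
#' `gap(k) >= gap(k + 1) - s_(k + 1)`. Computation is delegated to
#' [cluster::clusGap()] with `spaceH0 = "scaledPCA"`.
#'
#' Floored dCt values participate as ordinary numbers, mirroring how the
#' expression heat maps treat them.
#'
#' @param data Wide expression tibble (cells x genes; metadata columns such
#'   as `cell_id`, `time_point` are ignored automatically).
#' @param k_max Largest candidate `k`.
#' @param n_refs Number of reference data sets.
#' @param seed Seed for restarts and reference draws.
#' @param nstart k-means restarts per `k` (default 25).
#' @param genes Optional explicit gene columns.
#' @return An object of class `gap_stat`: list with `table` (tibble: `k`,
#'   `log_w`, `e_log_w`, `gap`, `se`), `k_selected`, and the call settings.
#'   `tidy()` returns the table, `glance()` the selection.
#' @export
#' @examples
#' sim <- simulate_expression(
#'   expression_sim_config(seed = 1),
#'   c(lineage1 = 40, lineage2 = 40)
#' )
#' expr <- normalize_cts(qc_filter(sim$ct))
#' select_k_gap(expr, k_max = 3, n_refs = 10, seed = 1)$k_selected
select_k_gap <- function(data, k_max = 6, n_refs = 50, seed = 1,
                         nstart = 25, genes = NULL) {
  m <- expr_matrix(data, genes)
  if (nrow(m) < k_max + 1) abort("need at least k_max + 1 cells")
  if (k_max < 1) abort("k_max must be >= 1")
  if (all(apply(m, 2, sd) == 0)) {
    warn("constant expression matrix; returning k = 1")
    return(structure(
      list(
        table = tibble::tibble(
          k = 1L, log_w = NA_real_, e_log_w = NA_real_,
          gap = NA_real_, se = NA_real_
        ),
        k_selected = 1L, k_max = k_max, n_refs = n_refs, seed = seed
      ),
      class = "gap_stat"
    ))
  }
  set.seed(seed)
  km_fun <- function(x, k) kmeans(x, k, nstart = nstart, iter.max = 100)
  gap <- cluster::clusGap(
    m, FUNcluster = km_fun, K.max = k_max, B = n_refs,
    spaceH0 = "scaledPCA", verbose = FALSE
  )
  tab <- gap$Tab
  k_sel <- cluster::maxSE(
    tab[, "gap"], tab[, "SE.sim"], method = "Tibs2001SEmax"
  )
  structure(
    list(
      table = tibble::tibble(
        k = seq_len(k_max),
        log_w = tab[, "logW"],
        e_log_w = tab[, "E.logW"],
        gap = tab[, "gap"],
        se = tab[, "SE.sim"]
      ),
      k_selected = as.integer(k_sel),
      k_max = k_max, n_refs = n_refs, seed = seed
    ),
    class = "gap_stat"
  )
}

#' @export
print.gap_stat <- function(x, ...) {
  cat("Gap statistic over k = 1..", x$k_max, " (", x$n_refs,
    " reference sets)\n",
    sep = ""
  )
  cat("Selected k =", x$k_selected, "\n")
  print(x$table)
  invisible(x)
}

#' Assign cells to k clusters by k-means
#'
#' Best of `nstart` restarts by within-cluster sum of squares, deterministic
#' given `seed`. The input tibble is returned with a `cluster` column
#' appended; centroids and inertia ride along as attributes and via
#' [glance()].
#'
#' @inheritParams select_k_gap
#' @param k Number of clusters (e.g. from [select_k_gap()]).
#' @return The input tibble with an integer `cluster` column, classed
#'   `hspc_clusters`.
#' @export
cluster_cells <- function(data, k, seed = 1, nstart = 25, genes = NULL) {
  m <- expr_matrix(data, genes)
  if (k > nrow(m)) abort("k cannot exceed the number of cells")
  set.seed(seed)
  if (k == nrow(m)) {
    # one cell per cluster: zero inertia, no need for Lloyd iterations
    fit <- list(
      cluster = seq_len(nrow(m)), centers = m, tot.withinss = 0
    )
  } else {
    fit <- kmeans(m, k, nstart = nstart, iter.max = 100)
  }
  out <- dplyr::mutate(data, cluster = as.integer(unname(fit$cluster)))
  class(out) <- c("hspc_clusters", class(out))
  attr(out, "kmeans") <- list(
    centroids = fit$centers, inertia = fit$tot.withinss, k = k, seed = seed
  )
  out
}

#' Gene-gene correlation networks and the correlation-burst indicator
#'
#' Computes, per cell group (typically time point x cluster), the Pearson
#' correlation of every gene pair over the group's cells and keeps the edges
#' with `r > threshold` (`r` is signed; set `absolute = TRUE` for `|r|`).
#' Genes detected — i.e. above the dCt floor — in fewer than `min_detected`
#' cells of the group are excluded, since floor-heavy genes produce spurious
#' correlations. The per-group edge count is the transition indicator: a
#' transient rise flags an imminent state transition.
#'
#' @inheritParams select_k_gap
#' @param group Character vector of grouping columns (e.g.
#'   `c("time_point", "cluster")`), or `NULL` for one global group.
#' @param threshold Correlation threshold (default 0.8).
#' @param min_detected Minimum number of cells a gene must be detected in.
#' @param absolute Threshold on `|r|` instead of signed `r`.
#' @param min_cells Groups smaller than this are skipped with a warning.
#' @param floor dCt floor used to define detection; defaults to the value
#'   attached by [normalize_cts()].
#' @return Object of class `correlation_networks`: `edges` (tibble: group
#'   columns, `gene1`, `gene2`, `r`) and `counts` (tibble: group columns,
#'   `n_cells`, `n_genes_used`, `n_edges`, `mean_r`). `tidy()` returns the
#'   edges, `glance()` the counts.
#' @export
correlation_burst <- function(data, group = NULL, threshold = 0.8,
                              min_detected = 10, absolute = FALSE,
                              min_cells = 10, floor = NULL, genes = NULL) {
  genes <- genes %||% gene_cols(data)
  floor <- floor %||% attr(data, "floor") %||% -17
  groups <- if (is.null(group)) {
    list(`all` = data)
  } else {
    split(data, data[group], drop = TRUE, sep = " / ")
  }
  edges <- list()
  counts <- list()
  for (g in names(groups)) {
    d <- groups[[g]]
    meta <- if (is.null(group)) {
      tibble::tibble(group = g)
    } else {
      dplyr::distinct(d[group])
    }
    if (nrow(d) < min_cells) {
      warn(paste0("group '", g, "' has < ", min_cells, " cells; skipped"))
      next
    }
    m <- expr_matrix(d, genes)
    keep <- colSums(m > floor) >= min_detected
    mk <- m[, keep, drop = FALSE]
    if (ncol(mk) < 2) {
      counts[[g]] <- dplyr::mutate(
        meta, n_cells = nrow(d), n_genes_used = ncol(mk),
        n_edges = 0L, mean_r = NA_real_
      )
      next
    }
    cm <- suppressWarnings(cor(mk))
    cm[!is.finite(cm)] <- 0 # zero-variance genes correlate with nothing
    ut <- upper.tri(cm)
    rv <- cm[ut]
    idx <- which(ut, arr.ind = TRUE)
    score <- if (absolute) abs(rv) else rv
    sel <- score > threshold
    if (any(sel)) {
      edges[[g]] <- dplyr::bind_cols(
        meta[rep(1, sum(sel)), , drop = FALSE],
        tibble::tibble(
          gene1 = colnames(cm)[idx[sel, 1]],
          gene2 = colnames(cm)[idx[sel, 2]],
          r = rv[sel]
        )
      )
    }
    counts[[g]] <- dplyr::mutate(
      meta, n_cells = nrow(d), n_genes_used = ncol(mk),
      n_edges = sum(sel), mean_r = mean(rv)
    )
  }
  structure(
    list(
      edges = dplyr::bind_rows(edges),
      counts = dplyr::bind_rows(counts),
      threshold = threshold, min_detected = min_detected,
      absolute = absolute
    ),
    class = "correlation_networks"
  )
}

#' @export
print.correlation_networks <- function(x, ...) {
  cat(
    "Gene-gene correlation networks (r >", x$threshold,
    if (x$absolute) "absolute" else "signed", ")\n"
  )
  print(x$counts)
  invisible(x)
}

#' Per-component gene contributions from PCA
#'
#' Principal components of the centred (not scaled) expression matrix;
#' a gene's contribution to a component is its squared loading, which sums to
#' one over genes per component. Returns the `n_top` highest contributions
#' per component.
#'
#' @inheritParams select_k_gap
#' @param n_top Contributions retained per component (default 40).
#' @param n_components Components reported (default 2).
#' @return Tibble: `component`, `gene`, `contribution`, `rank`.
#' @export
pca_contributions <- function(data, n_top = 40, n_components = 2,
                              genes = NULL) {
  m <- expr_matrix(data, genes)
  if (ncol(m) < 2) abort("need at least two genes")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  n_components <- min(n_components, ncol(pc$rotation))
  purrr::map_dfr(seq_len(n_components), function(j) {
    contrib <- pc$rotation[, j]^2
    tibble::tibble(
      component = paste0("PC", j),
      gene = names(sort(contrib, decreasing = TRUE)),
      contribution = unname(sort(contrib, decreasing = TRUE))
    ) |>
      dplyr::mutate(rank = dplyr::row_number()) |>
      dplyr::slice_head(n = n_top)
  })
}

#' Embed cells in two dimensions for visualisation
#'
#' `"tsne"` uses Barnes-Hut t-SNE ([Rtsne::Rtsne()]); `"pca"` returns the
#' first two principal-component scores. Deterministic given `seed`.
#' Coordinates are visualisation plumbing and carry no metric contract.
#'
#' @inheritParams select_k_gap
#' @param method `"tsne"` or `"pca"`.
#' @param perplexity t-SNE perplexity; must satisfy
#'   `3 * perplexity < n_cells - 1`.
#' @return Tibble: `cell_id` (if present), metadata columns, `dim1`, `dim2`.
#' @export
embed_2d <- function(data, method = c("tsne", "pca"), perplexity = 10,
                     seed = 1, genes = NULL) {
  method <- match.arg(method)
  m <- expr_matrix(data, genes)
  if (nrow(m) < 5) abort("need at least 5 cells to embed")
  meta <- data[intersect(names(data), .meta_cols)]
  if (method == "tsne") {
    if (3 * perplexity >= nrow(m) - 1) {
      abort("perplexity too large for the number of cells")
    }
    set.seed(seed)
    fit <- Rtsne::Rtsne(
      m, dims = 2, perplexity = perplexity,
      check_duplicates = FALSE, pca = TRUE, num_threads = 1
    )
    coords <- fit$Y
  } else {
    pc <- prcomp(m, center = TRUE, scale. = FALSE)
    coords <- pc$x[, 1:2, drop = FALSE]
    if (ncol(coords) < 2) coords <- cbind(coords, 0)
  }
  dplyr::bind_cols(
    meta,
    tibble::tibble(dim1 = coords[, 1], dim2 = coords[, 2], method = method)
  )
}
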