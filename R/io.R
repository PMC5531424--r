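#' Write / read time-lapse tracks as TSV
#'
#' Two files: a cells table (`clone_id`, `cell_id`, `parent_id`, `t_birth_h`,
#' `t_end_h`, `end_event`) and an intervals table (`cell_id`, `t_start_h`,
#' `t_stop_h`, `shape`). On read, intervals are normalised with
#' [normalize_tracks()] (same-shape runs merged, sub-frame gaps closed) and
#' generations are recomputed from parent links when absent. `column_map`
#' renames non-standard headers of hand-curated spreadsheets,
#' e.g. `list(cells = c(cell_id = "Cell"), intervals = c(shape = "Form"))`.
#'
#' @param pedigrees List with `cells` and `intervals` tibbles.
#' @param cells_path,intervals_path TSV paths.
#' @param column_map Optional list of named rename vectors (see above).
#' @param frame_interval_h Frame interval used by [normalize_tracks()].
#' @return `write_tracks_tsv()`: the paths, invisibly. `read_tracks_tsv()`:
#'   list with `cells` and `intervals`.
#' @export
write_tracks_tsv <- function(pedigrees, cells_path, intervals_path) {
  readr::write_tsv(pedigrees$cells, cells_path, progress = FALSE)
  readr::write_tsv(pedigrees$intervals, intervals_path, progress = FALSE)
  invisible(c(cells_path, intervals_path))
}

#' @rdname write_tracks_tsv
#' @export
read_tracks_tsv <- function(cells_path, intervals_path, column_map = NULL,
                            frame_interval_h = 1 / 60) {
  cells <- readr::read_tsv(cells_path, show_col_types = FALSE, progress = FALSE)
  intervals <- readr::read_tsv(
    intervals_path,
    show_col_types = FALSE, progress = FALSE
  )
  rename_with_map <- function(tbl, map) {
    for (std in names(map)) names(tbl)[names(tbl) == map[[std]]] <- std
    tbl
  }
  if (!is.null(column_map)) {
    cells <- rename_with_map(cells, column_map$cells %||% character())
    intervals <- rename_with_map(
      intervals, column_map$intervals %||% character()
    )
  }
  need <- c("clone_id", "cell_id", "parent_id", "t_birth_h", "t_end_h", "end_event")
  miss <- setdiff(need, names(cells))
  if (length(miss) > 0) {
    abort(paste0(
      "cells table ", cells_path, " lacks columns: ",
      paste(miss, collapse = ", ")
    ))
  }
  if (!"generation" %in% names(cells)) {
    cells$generation <- compute_generations(cells)
  }
  list(
    cells = cells,
    intervals = normalize_tracks(intervals, frame_interval_h)
  )
}

compute_generations <- function(cells) {
  gen <- setNames(rep(NA_integer_, nrow(cells)), cells$cell_id)
  parent <- setNames(cells$parent_id, cells$cell_id)
  resolve <- function(id) {
    if (!is.na(gen[[id]])) return(gen[[id]])
    p <- parent[[id]]
    g <- if (is.na(p)) 1L else resolve(p) + 1L
    gen[[id]] <<- g
    g
  }
  unname(vapply(cells$cell_id, resolve, integer(1)))
}

#' Export clone topologies as Newick trees
#'
#' One Newick string per clone, branch lengths in hours (each branch is the
#' cell's observed lifetime). Multi-cell clones are built as [ape] `phylo`
#' objects and serialised with [ape::write.tree()]; an undivided founder
#' becomes a single-leaf tree.
#'
#' @param cells Pedigree cells tibble.
#' @param path Optional file to write all trees to (one per line).
#' @return Named character vector of Newick strings (by clone).
#' @export
pedigrees_to_newick <- function(cells, path = NULL) {
  out <- vapply(split(cells, cells$clone_id), clone_newick, character(1))
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

clone_newick <- function(cc) {
  cc$life <- cc$t_end_h - cc$t_birth_h
  kids <- split(cc$cell_id, cc$parent_id)
  internal <- cc$cell_id %in% names(kids)
  tips <- cc$cell_id[!internal]
  if (length(tips) == 1) {
    return(sprintf("(%s:%.6g);", tips, cc$life[!internal]))
  }
  nodes <- cc$cell_id[internal]
  id <- c(setNames(seq_along(tips), tips),
    setNames(length(tips) + seq_along(nodes), nodes)
  )
  # reorder internal ids so the root is first internal node, as ape expects
  root <- cc$cell_id[is.na(cc$parent_id)]
  nodes <- c(root, setdiff(nodes, root))
  id[nodes] <- length(tips) + seq_along(nodes)
  has_parent <- !is.na(cc$parent_id)
  edge <- cbind(
    unname(id[cc$parent_id[has_parent]]),
    unname(id[cc$cell_id[has_parent]])
  )
  tree <- structure(
    list(
      edge = edge,
      edge.length = cc$life[has_parent],
      tip.label = tips,
      node.label = nodes,
      Nnode = length(nodes)
    ),
    class = "phylo", order = "cladewise"
  )
  ape::write.tree(tree)
}

#' Write simulation ground truth as JSON
#'
#' @param truth The `truth` element of [simulate_pedigrees()] or
#'   [simulate_expression()] output.
#' @param path JSON path.
#' @return The path, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  ser <- truth
  if (!is.null(ser$config)) {
    ser$config <- unclass(ser$config)
    ser$config$phenotype_inheritance <-
      as.data.frame(ser$config$phenotype_inheritance)
  }
  if (!is.null(ser$inheritance)) {
    ser$inheritance <- as.data.frame(ser$inheritance)
  }
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Nested key/value configuration for [run_pipeline()]; any subset can be
#' overridden via `overrides` or loaded from a YAML file with
#' [read_pipeline_config()]. CLI flags (in the shipped `hspcfate.R` script)
#' take precedence over the file, which takes precedence over these defaults.
#'
#' @param overrides Named nested list merged over the defaults.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(overrides = list()) {
  defaults <- list(
    seed = 1L,
    out_dir = "hspcfate_out",
    stages = c("simulate", "normalize", "cluster", "correlate", "lineage", "report"),
    simulate = list(
      n_cells_per_state = c(lineage1 = 100, lineage2 = 100),
      n_clones = 100
    ),
    normalize = list(floor = -17),
    cluster = list(k_max = 6, n_refs = 50, perplexity = 10),
    correlate = list(threshold = 0.8, min_detected = 10),
    lineage = list(trim_founder_h = 0, classify = "kmeans3")
  )
  cfg <- modifyList(defaults, overrides)
  if (!is.numeric(cfg$seed)) abort("config seed must be numeric")
  structure(cfg, class = c("pipeline_config", "list"))
}

#' @rdname pipeline_config
#' @param path YAML configuration file.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in order — `simulate` (expression + pedigrees),
#' `normalize` (QC + spike normalisation), `cluster` (gap statistic, k-means,
#' embedding), `correlate` (correlation-burst networks), `lineage` (dynamic
#' phenotypes, inheritance, cycle stats) and `report` — writing each stage's
#' outputs under `config$out_dir` and returning a run manifest (also written
#' as `manifest.json`) listing the config snapshot, input checksums, per-stage
#' outputs and warnings.
#'
#' @param config A [pipeline_config()].
#' @param ct_table Optional path to a raw Ct CSV (used when the `simulate`
#'   stage is disabled).
#' @param tracks,intervals Optional paths to track TSVs (idem).
#' @param matrix Optional path to a normalised expression TSV (used when the
#'   `normalize` stage is disabled).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), ct_table = NULL,
                         tracks = NULL, intervals = NULL, matrix = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    config = unclass(config), inputs = list(), outputs = list(),
    warnings = character()
  )
  note <- function(stage, files) {
    manifest$outputs[[stage]] <<- unname(files)
  }
  catch_warn <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  stages <- config$stages
  p <- function(...) file.path(config$out_dir, ...)
  expr <- NULL
  ped <- NULL

  if ("simulate" %in% stages) {
    sim <- simulate_expression(
      expression_sim_config(seed = config$seed),
      unlist(config$simulate$n_cells_per_state)
    )
    write_ct_csv(sim$ct, p("ct_table.csv"))
    ped <- simulate_pedigrees(pedigree_sim_config(
      n_clones = config$simulate$n_clones, seed = config$seed
    ))
    write_tracks_tsv(ped, p("tracks.tsv"), p("intervals.tsv"))
    pedigrees_to_newick(ped$cells, p("pedigrees.nwk"))
    write_ground_truth_json(ped$truth, p("ground_truth.json"))
    ct_table <- p("ct_table.csv")
    tracks <- p("tracks.tsv")
    intervals <- p("intervals.tsv")
    note("simulate", c(
      ct_table, tracks, intervals, p("pedigrees.nwk"), p("ground_truth.json")
    ))
  }
  for (f in c(ct_table, tracks, intervals, matrix)) {
    if (!is.null(f)) manifest$inputs[[f]] <- unname(tools::md5sum(f))
  }

  if ("normalize" %in% stages) {
    if (is.null(ct_table)) abort("normalize stage needs a Ct table")
    raw <- read_ct_csv(ct_table)
    if (nrow(raw) == 0) abort(paste0("empty Ct table: ", ct_table))
    filtered <- catch_warn(qc_filter(raw))
    expr <- normalize_cts(filtered, floor = config$normalize$floor)
    write_expression_tsv(expr, p("expression.tsv"))
    jsonlite::write_json(
      qc_report(filtered), p("qc_report.json"),
      auto_unbox = TRUE, digits = NA
    )
    note("normalize", c(p("expression.tsv"), p("qc_report.json")))
  }

  if (is.null(expr) && !is.null(matrix)) {
    expr <- read_expression_tsv(matrix)
  }
  gap <- nets <- NULL
  if ("cluster" %in% stages && !is.null(expr)) {
    gap <- select_k_gap(
      expr,
      k_max = config$cluster$k_max,
      n_refs = config$cluster$n_refs, seed = config$seed
    )
    clustered <- cluster_cells(expr, gap$k_selected, seed = config$seed)
    coords <- embed_2d(
      clustered,
      method = "tsne",
      perplexity = min(
        config$cluster$perplexity, floor((nrow(expr) - 2) / 3)
      ),
      seed = config$seed
    )
    readr::write_tsv(tidy(gap), p("gap_curve.tsv"), progress = FALSE)
    readr::write_tsv(
      dplyr::select(
        clustered, dplyr::any_of(c("cell_id", "time_point", "cluster"))
      ),
      p("clusters.tsv"),
      progress = FALSE
    )
    readr::write_tsv(coords, p("embedding.tsv"), progress = FALSE)
    expr <- clustered
    note("cluster", c(p("gap_curve.tsv"), p("clusters.tsv"), p("embedding.tsv")))
  }

  if ("correlate" %in% stages && !is.null(expr)) {
    grp <- if ("cluster" %in% names(expr)) "cluster" else NULL
    nets <- catch_warn(correlation_burst(
      expr,
      group = grp,
      threshold = config$correlate$threshold,
      min_detected = config$correlate$min_detected
    ))
    readr::write_tsv(nets$edges, p("correlation_edges.tsv"), progress = FALSE)
    readr::write_tsv(nets$counts, p("correlation_counts.tsv"), progress = FALSE)
    note("correlate", c(p("correlation_edges.tsv"), p("correlation_counts.tsv")))
  }

  trans <- cyc <- NULL
  if ("lineage" %in% stages && !is.null(tracks)) {
    td <- read_tracks_tsv(tracks, intervals)
    summaries <- summarize_cells(
      td$cells, td$intervals,
      trim_founder_h = config$lineage$trim_founder_h
    )
    labelled <- classify_phenotypes(
      summaries,
      method = config$lineage$classify, seed = config$seed
    )
    trans <- transition_frequencies(td$cells, labelled)
    cyc <- cycle_length_stats(td$cells)
    sis <- catch_warn(tryCatch(
      sister_similarity(td$cells, summaries, seed = config$seed),
      error = function(e) NULL
    ))
    readr::write_tsv(labelled, p("cell_dynamics.tsv"), progress = FALSE)
    readr::write_tsv(tidy(trans), p("transitions.tsv"), progress = FALSE)
    readr::write_tsv(cyc, p("cycle_stats.tsv"), progress = FALSE)
    if (!is.null(sis)) {
      readr::write_tsv(sis, p("sister_pairs.tsv"), progress = FALSE)
    }
    note("lineage", c(
      p("cell_dynamics.tsv"), p("transitions.tsv"), p("cycle_stats.tsv")
    ))
  }

  if ("report" %in% stages) {
    note("report", render_report(config$out_dir))
  }

  jsonlite::write_json(
    manifest, p("manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE
  )
  invisible(manifest)
}

#' Assemble the run report from a pipeline output directory
#'
#' Reads whichever stage outputs exist under `out_dir` (gap curve, cluster
#' assignments, correlation counts, transition matrix, cycle-length table)
#' and writes a single Markdown summary, `report.md`. Because it works from
#' the files, it can regenerate the report of any previous run given its
#' output directory / manifest.
#'
#' @param out_dir A [run_pipeline()] output directory.
#' @return The report path, invisibly.
#' @export
render_report <- function(out_dir) {
  rd <- function(f) {
    path <- file.path(out_dir, f)
    if (file.exists(path)) {
      readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    } else {
      NULL
    }
  }
  lines <- c("# hspcfate run report", "")
  gap <- rd("gap_curve.tsv")
  if (!is.null(gap) && nrow(gap) > 1) {
    sel <- which(
      gap$gap[-nrow(gap)] >= gap$gap[-1] - gap$se[-1]
    )
    k_sel <- if (length(sel) > 0) min(sel) else nrow(gap)
    lines <- c(
      lines, sprintf("Selected k (gap statistic): %d", k_sel), "",
      "## Gap curve", knit_table(gap)
    )
  }
  clusters <- rd("clusters.tsv")
  if (!is.null(clusters)) {
    lines <- c(
      lines, "", "## Cluster sizes",
      knit_table(dplyr::count(clusters, .data$cluster))
    )
  }
  counts <- rd("correlation_counts.tsv")
  if (!is.null(counts)) {
    lines <- c(lines, "", "## Correlation-burst counts", knit_table(counts))
  }
  trans <- rd("transitions.tsv")
  if (!is.null(trans)) {
    lines <- c(lines, "", "## Phenotype transitions", knit_table(trans))
  }
  cyc <- rd("cycle_stats.tsv")
  if (!is.null(cyc)) {
    lines <- c(lines, "", "## Cycle lengths by generation", knit_table(cyc))
  }
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}

knit_table <- function(df) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 5))
  header <- paste(names(df), collapse = " | ")
  sep <- paste(rep("---", ncol(df)), collapse = " | ")
  body <- apply(df, 1, function(r) paste(r, collapse = " | "))
  c(header, sep, body)
}
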