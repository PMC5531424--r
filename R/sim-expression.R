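#' Simulate a raw single-cell qRT-PCR Ct table
#'
#' Draws cells from the expression states defined in the configuration and
#' returns a Biomark-style raw Ct table (long format: one row per cell x
#' assay reading) together with per-cell ground truth. Each cell carries two
#' spike-in readings (`spike1`, `spike4`) drawn independently around
#' `spike_mean_ct`; for each gene, detection is Bernoulli with the state's
#' per-module probability and, when detected, the gene's Ct is chosen so that
#' the implied dCt (spike geometric mean minus Ct) follows the state's law.
#' Lineage and transition states share one latent factor per cell across their
#' loading module, inducing pairwise correlation equal to the loading.
#' A fraction `dropout_fail_rate` of readings is flagged `"Failed"`.
#'
#' @param config An [expression_sim_config()].
#' @param n_cells_per_state Named integer vector, e.g.
#'   `c(lineage1 = 100, lineage2 = 100)`; names must be states of the config.
#' @param time_point Optional label (e.g. `"48h"`) attached to all cells.
#' @param condition Optional condition label (e.g. `"control"`, `"VPA"`).
#' @param seed Seed; defaults to `config$seed`.
#' @return A list with `ct` (tibble: `cell_id`, `assay`, `ct`, `flag`),
#'   `truth` (tibble: `cell_id`, `state`), and `config`.
#' @export
#' @examples
#' sim <- simulate_expression(
#'   expression_sim_config(seed = 1),
#'   c(lineage1 = 20, lineage2 = 20)
#' )
#' dplyr::count(sim$ct, flag)
simulate_expression <- function(config, n_cells_per_state,
                                time_point = NULL, condition = NULL,
                                seed = NULL) {
  stopifnot(inherits(config, "expression_sim_config"))
  states <- names(n_cells_per_state)
  if (is.null(states) || !all(states %in% names(config$states))) {
    abort(paste0(
      "n_cells_per_state must be named with states among: ",
      paste(names(config$states), collapse = ", ")
    ))
  }
  if (any(n_cells_per_state < 1)) abort("need at least one cell per state")
  set.seed(seed %||% config$seed)

  genes <- gene_names(config)
  module_of <- rep(NA_character_, config$n_genes)
  for (m in names(config$gene_modules)) {
    module_of[config$gene_modules[[m]]] <- m
  }

  rows <- list()
  truth <- list()
  cell_counter <- 0L
  for (st_name in states) {
    st <- config$states[[st_name]]
    for (i in seq_len(n_cells_per_state[[st_name]])) {
      cell_counter <- cell_counter + 1L
      cid <- sprintf("cell_%04d", cell_counter)
      spikes <- rnorm(2, config$spike_mean_ct, config$spike_sd)
      s_geo <- sqrt(spikes[1] * spikes[2])
      z <- rnorm(1) # shared latent factor for this cell
      detected <- runif(config$n_genes) < st$detect[module_of]
      mu <- st$mean_dct[module_of]
      in_load <- !is.null(st$loading_module) &
        module_of == (st$loading_module %||% "")
      l <- ifelse(in_load, st$loading, 0)
      dct <- mu + sqrt(l) * st$sd_dct * z +
        sqrt(1 - l) * st$sd_dct * rnorm(config$n_genes)
      ct_gene <- ifelse(detected, s_geo - dct, NA_real_)
      rows[[cell_counter]] <- tibble::tibble(
        cell_id = cid,
        assay = c("spike1", "spike4", genes),
        ct = c(spikes, ct_gene)
      )
      truth[[cell_counter]] <- tibble::tibble(cell_id = cid, state = st_name)
    }
  }
  ct <- dplyr::bind_rows(rows)
  ct$flag <- ifelse(runif(nrow(ct)) < config$dropout_fail_rate, "Failed", "OK")
  if (!is.null(time_point)) ct$time_point <- time_point
  if (!is.null(condition)) ct$condition <- condition
  list(ct = ct, truth = dplyr::bind_rows(truth), config = config)
}

gene_names <- function(config) {
  nm <- character(config$n_genes)
  prefix <- c(
    stem = "STEM", lineage1 = "L1G", lineage2 = "L2G", background = "BG"
  )
  for (m in names(config$gene_modules)) {
    idx <- config$gene_modules[[m]]
    p <- prefix[[m]] %||% toupper(m)
    nm[idx] <- sprintf("%s%02d", p, seq_along(idx))
  }
  nm
}

#' Simulate a CD133-sorted cell fraction
#'
#' Emulates sorting on a surface-marker proxy for the two stable morphologies:
#' the `"high"` fraction is drawn from the lineage1 (multipotent-like) state,
#' `"low"` from the lineage2 (CMP-like) state, and `"medium"` is a mixture of
#' both plus cells with state parameters interpolated halfway between them
#' (uncorrelated, reflecting their intermediate character).
#'
#' @param config An [expression_sim_config()].
#' @param fraction One of `"high"`, `"medium"`, `"low"`.
#' @param n_cells Number of cells to draw.
#' @param mixture_weight For `"medium"`, the proportion of interpolated-state
#'   cells; the remainder splits evenly between the two lineage states.
#' @param seed Seed; defaults to `config$seed`.
#' @return As [simulate_expression()], with a `fraction` column on `ct`.
#' @export
simulate_sorted_fractions <- function(config, fraction, n_cells = 100,
                                      mixture_weight = 0.3, seed = NULL) {
  stopifnot(inherits(config, "expression_sim_config"))
  fraction <- match.arg(fraction, c("high", "medium", "low"))
  cfg <- config
  if (fraction == "medium") {
    l1 <- cfg$states$lineage1
    l2 <- cfg$states$lineage2
    cfg$states$medium_interp <- list(
      detect = (l1$detect + l2$detect) / 2,
      mean_dct = (l1$mean_dct + l2$mean_dct) / 2,
      sd_dct = (l1$sd_dct + l2$sd_dct) / 2,
      loading = 0, loading_module = NULL
    )
    n_int <- round(n_cells * mixture_weight)
    n_each <- floor((n_cells - n_int) / 2)
    n <- c(
      lineage1 = n_each, lineage2 = n_cells - n_int - n_each,
      medium_interp = n_int
    )
    n <- n[n > 0]
  } else {
    n <- setNames(n_cells, if (fraction == "high") "lineage1" else "lineage2")
  }
  sim <- simulate_expression(cfg, n, seed = seed)
  sim$ct$fraction <- fraction
  sim
}
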