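#' Normalise morphology tracks
#'
#' Merges consecutive same-shape intervals and closes sub-frame gaps
#' (< `frame_interval_h`) by extending the earlier interval, so that
#' annotation artefacts cannot inflate switch counts. Validates that each
#' cell's intervals are ordered, non-overlapping and contiguous after
#' closing.
#'
#' @param intervals Tibble: `cell_id`, `t_start_h`, `t_stop_h`, `shape`.
#' @param frame_interval_h Imaging frame interval (h); gaps shorter than this
#'   are closed.
#' @return Normalised intervals tibble.
#' @export
normalize_tracks <- function(intervals, frame_interval_h = 1 / 60) {
  need <- c("cell_id", "t_start_h", "t_stop_h", "shape")
  miss <- setdiff(need, names(intervals))
  if (length(miss) > 0) {
    abort(paste0("intervals lack columns: ", paste(miss, collapse = ", ")))
  }
  if (!all(intervals$shape %in% c("round", "polarised"))) {
    abort("shape must be 'round' or 'polarised'")
  }
  out <- intervals |>
    dplyr::arrange(.data$cell_id, .data$t_start_h) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::mutate(
      gap = .data$t_start_h - dplyr::lag(.data$t_stop_h),
      t_start_h = dplyr::if_else(
        !is.na(.data$gap) & .data$gap > 0 & .data$gap < frame_interval_h,
        .data$t_start_h - .data$gap, .data$t_start_h
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"gap")
  bad <- out |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      ok = all(.data$t_stop_h > .data$t_start_h) &&
        all(abs(.data$t_start_h[-1] - .data$t_stop_h[-dplyr::n()]) < 1e-9),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(paste0(
      "non-contiguous or ill-ordered tracks for cells: ",
      paste(head(bad$cell_id, 5), collapse = ", ")
    ))
  }
  out |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(~ merge_same_shape(
      dplyr::mutate(.x, cell_id = .y$cell_id)
    ) |> dplyr::select(-"cell_id")) |>
    dplyr::ungroup()
}

#' Summarise each cell's dynamic phenotype parameters
#'
#' For every tracked cell, computes the three dynamic-phenotype parameters:
#' *roundness* (fraction of the observed lifetime spent in the round shape),
#' *switch frequency* (shape changes per observed hour) and *cycle length*
#' (birth to division; absent for right-censored cells). Roundness uses the
#' observed lifetime as denominator so censored cells remain usable.
#'
#' @param cells Tibble with `clone_id`, `cell_id`, `parent_id`, `generation`,
#'   `t_birth_h`, `t_end_h`, `end_event` (as produced by
#'   [simulate_pedigrees()] or [read_tracks_tsv()]).
#' @param intervals Normalised intervals tibble covering each cell's
#'   `[t_birth_h, t_end_h]`.
#' @param trim_founder_h Hours to drop from the start of founder
#'   (generation 1) tracks before computing roundness/switch frequency, to
#'   discount post-isolation recovery. Default 0 (off).
#' @return Tibble: `clone_id`, `cell_id`, `generation`, `end_event`,
#'   `observed_h`, `roundness`, `switch_freq`, `cycle_length_h` (`NA` when
#'   censored).
#' @export
#' @examples
#' ped <- simulate_pedigrees(pedigree_sim_config(n_clones = 3, seed = 1))
#' summarize_cells(ped$cells, ped$intervals)
summarize_cells <- function(cells, intervals, trim_founder_h = 0) {
  iv <- intervals
  if (nrow(iv) == 0) abort("no intervals supplied")
  missing_cells <- setdiff(cells$cell_id, iv$cell_id)
  if (length(missing_cells) > 0) {
    abort(paste0(
      "cells without morphology track: ",
      paste(head(missing_cells, 5), collapse = ", ")
    ))
  }
  info <- cells |>
    dplyr::select(
      "clone_id", "cell_id", "parent_id", "generation",
      "t_birth_h", "t_end_h", "end_event"
    )
  iv <- dplyr::inner_join(iv, info, by = "cell_id")
  cover <- iv |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      ok = abs(min(.data$t_start_h) - .data$t_birth_h[1]) < 1e-6 &&
        abs(max(.data$t_stop_h) - .data$t_end_h[1]) < 1e-6 &&
        all(abs(sort(.data$t_start_h)[-1] -
          sort(.data$t_stop_h)[-dplyr::n()]) < 1e-6),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(cover) > 0) {
    abort(paste0(
      "tracks not covering [birth, end] contiguously for: ",
      paste(head(cover$cell_id, 5), collapse = ", ")
    ))
  }
  if (trim_founder_h > 0) {
    iv <- iv |>
      dplyr::mutate(
        cut = dplyr::if_else(
          .data$generation == 1L,
          pmin(.data$t_birth_h + trim_founder_h, .data$t_end_h),
          .data$t_birth_h
        ),
        t_start_h = pmax(.data$t_start_h, .data$cut)
      ) |>
      dplyr::filter(.data$t_stop_h > .data$t_start_h) |>
      dplyr::select(-"cut")
  }
  iv |>
    dplyr::arrange(.data$cell_id, .data$t_start_h) |>
    dplyr::group_by(
      .data$clone_id, .data$cell_id, .data$generation, .data$end_event
    ) |>
    dplyr::summarise(
      observed_h = sum(.data$t_stop_h - .data$t_start_h),
      roundness = sum(
        (.data$t_stop_h - .data$t_start_h)[.data$shape == "round"]
      ) / sum(.data$t_stop_h - .data$t_start_h),
      switch_freq = sum(
        .data$shape[-1] != .data$shape[-dplyr::n()]
      ) / sum(.data$t_stop_h - .data$t_start_h),
      cycle_length_h = dplyr::if_else(
        .data$end_event[1] == "division",
        .data$t_end_h[1] - .data$t_birth_h[1], NA_real_
      ),
      .groups = "drop"
    )
}

#' Classify cells into dynamic phenotypes P / S / R
#'
#' Cells are placed in the space of their dynamic parameters and grouped into
#' three categories: stable-polarised (P), frequent-switcher (S) and
#' stable-round (R). The default method runs k-means (k = 3) on standardized
#' `(roundness, switch_freq)` and maps clusters to labels by centroid rules:
#' the highest-switch-frequency centroid is S; of the remaining two, the
#' lower-roundness one is P and the higher is R. A deterministic threshold
#' rule is also available. Set `features` to include `"cycle_length_h"` for
#' the three-parameter variant (censored cells are then dropped).
#'
#' @param summaries Tibble from [summarize_cells()].
#' @param method `"kmeans3"` or `"thresholds"`.
#' @param features Clustering features (default roundness + switch frequency).
#' @param thresholds For `method = "thresholds"`: list with `switch_freq`
#'   (cells above are S) and `roundness` (remaining cells above are R).
#' @param seed Seed for k-means restarts.
#' @return `summaries` with a `phenotype` factor column (levels P, S, R).
#' @export
classify_phenotypes <- function(summaries, method = c("kmeans3", "thresholds"),
                                features = c("roundness", "switch_freq"),
                                thresholds = list(
                                  switch_freq = 0.15, roundness = 0.5
                                ),
                                seed = 1) {
  method <- match.arg(method)
  dat <- summaries
  if (!all(features %in% names(dat))) {
    abort("features must be columns of the summaries table")
  }
  keep <- complete.cases(dat[features])
  if (method == "thresholds") {
    ph <- ifelse(
      dat$switch_freq > thresholds$switch_freq, "S",
      ifelse(dat$roundness > thresholds$roundness, "R", "P")
    )
    dat$phenotype <- factor(ph, levels = c("P", "S", "R"))
    return(dat)
  }
  x <- as.matrix(dat[keep, features])
  if (nrow(x) < 6) abort("need at least 6 cells to classify")
  if (all(apply(x, 2, sd) == 0)) {
    abort("all cells identical in the chosen features; cannot classify")
  }
  z <- scale(x)
  z[, apply(x, 2, sd) == 0] <- 0
  set.seed(seed)
  fit <- kmeans(z, 3, nstart = 25, iter.max = 100)
  cen <- sapply(seq_len(3), function(cl) {
    colMeans(x[fit$cluster == cl, , drop = FALSE])
  })
  lab <- character(3)
  s_cl <- which.max(cen["switch_freq", ])
  lab[s_cl] <- "S"
  rest <- setdiff(1:3, s_cl)
  lab[rest[which.min(cen["roundness", rest])]] <- "P"
  lab[rest[which.max(cen["roundness", rest])]] <- "R"
  ph <- rep(NA_character_, nrow(dat))
  ph[keep] <- lab[fit$cluster]
  dat$phenotype <- factor(ph, levels = c("P", "S", "R"))
  dat
}

#' Mother-to-daughter phenotype transition matrix
#'
#' Counts, over all mother-daughter edges with both ends labelled, how often
#' a mother of each phenotype produced daughters of each phenotype, and
#' row-normalises to frequencies. Founders have no mother and are excluded
#' as daughters.
#'
#' @param cells Pedigree cells tibble (needs `cell_id`, `parent_id`).
#' @param phenotypes Tibble `cell_id`, `phenotype` — either ground truth from
#'   the simulator or the output of [classify_phenotypes()].
#' @return Object of class `phenotype_transition` with `counts` and `freq`
#'   3x3 matrices (rows = mothers), `n_edges`, and `no_data_rows` (mother
#'   phenotypes never observed). `tidy()` gives a long tibble.
#' @export
transition_frequencies <- function(cells, phenotypes) {
  ph <- phenotypes |>
    dplyr::select("cell_id", "phenotype") |>
    dplyr::mutate(phenotype = as.character(.data$phenotype))
  non_founders <- dplyr::filter(cells, !is.na(.data$parent_id))
  orphans <- setdiff(non_founders$parent_id, cells$cell_id)
  if (length(orphans) > 0) {
    abort(paste0(
      "pedigree integrity error: unknown mothers ",
      paste(head(orphans, 5), collapse = ", ")
    ))
  }
  edges <- non_founders |>
    dplyr::select("cell_id", "parent_id") |>
    dplyr::left_join(ph, by = "cell_id") |>
    dplyr::rename(daughter = "phenotype") |>
    dplyr::left_join(ph, by = c(parent_id = "cell_id")) |>
    dplyr::rename(mother = "phenotype") |>
    dplyr::filter(!is.na(.data$mother), !is.na(.data$daughter))
  lv <- c("P", "S", "R")
  counts <- table(
    factor(edges$mother, levels = lv),
    factor(edges$daughter, levels = lv)
  )
  counts <- unclass(counts)
  names(dimnames(counts)) <- c("mother", "daughter")
  rs <- rowSums(counts)
  freq <- counts / ifelse(rs > 0, rs, NA_real_)
  structure(
    list(
      counts = counts, freq = freq, n_edges = nrow(edges),
      no_data_rows = lv[rs == 0]
    ),
    class = "phenotype_transition"
  )
}

#' @export
print.phenotype_transition <- function(x, ...) {
  cat(
    "Mother-to-daughter phenotype transitions (", x$n_edges, " edges)\n",
    sep = ""
  )
  print(round(x$freq, 3))
  if (length(x$no_data_rows) > 0) {
    cat("No observed mothers for:", paste(x$no_data_rows, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare sister cells' dynamic phenotypes
#'
#' For each complete sister pair (both sisters divided, so cycle length is
#' defined), computes the Euclidean distance between the sisters over
#' standardized `(cycle_length_h, roundness, switch_freq)` (z-scored over all
#' cells entering the comparison; disable with `standardize = FALSE`), then
#' splits pairs into `"similar"` and `"divergent"` by k-means (k = 2) on the
#' distances; the lower-centroid group is `"similar"`.
#'
#' @param cells Pedigree cells tibble.
#' @param summaries Tibble from [summarize_cells()].
#' @param seed Seed for k-means.
#' @param standardize Z-score features before the distance (default TRUE).
#' @return Tibble: `pair_id`, `parent_id`, `cell_id_1`, `cell_id_2`,
#'   `distance`, `class`.
#' @export
sister_similarity <- function(cells, summaries, seed = 1, standardize = TRUE) {
  feats <- c("cycle_length_h", "roundness", "switch_freq")
  pairs <- cells |>
    dplyr::filter(!is.na(.data$parent_id)) |>
    dplyr::group_by(.data$parent_id) |>
    dplyr::filter(dplyr::n() == 2) |>
    dplyr::summarise(
      cell_id_1 = .data$cell_id[1], cell_id_2 = .data$cell_id[2],
      .groups = "drop"
    )
  sm <- dplyr::select(summaries, "cell_id", dplyr::all_of(feats))
  complete_ids <- sm$cell_id[complete.cases(sm)]
  censored_pairs <- !(pairs$cell_id_1 %in% complete_ids &
    pairs$cell_id_2 %in% complete_ids)
  if (any(censored_pairs)) {
    warn(paste0(
      sum(censored_pairs),
      " sister pair(s) with censored cycle length excluded"
    ))
    pairs <- pairs[!censored_pairs, , drop = FALSE]
  }
  if (nrow(pairs) < 4) abort("need at least 4 complete sister pairs")
  used <- sm |>
    dplyr::filter(.data$cell_id %in% c(pairs$cell_id_1, pairs$cell_id_2))
  m <- as.matrix(used[feats])
  rownames(m) <- used$cell_id
  if (standardize) {
    sds <- apply(m, 2, sd)
    m <- scale(m)
    m[, sds == 0] <- 0
  }
  d <- sqrt(rowSums(
    (m[pairs$cell_id_1, , drop = FALSE] -
      m[pairs$cell_id_2, , drop = FALSE])^2
  ))
  if (length(unique(d)) < 2) {
    warn("all sister distances identical; classing every pair 'similar'")
    cls <- rep("similar", length(d))
  } else {
    set.seed(seed)
    fit <- kmeans(d, 2, nstart = 25)
    low <- which.min(fit$centers)
    cls <- unname(ifelse(fit$cluster == low, "similar", "divergent"))
  }
  tibble::tibble(
    pair_id = seq_len(nrow(pairs)),
    parent_id = pairs$parent_id,
    cell_id_1 = pairs$cell_id_1,
    cell_id_2 = pairs$cell_id_2,
    distance = unname(d),
    class = cls
  )
}

#' Maximum-likelihood switching rates from interval data
#'
#' For two-state continuous-time Markov switching observed as shape
#' intervals, the exact MLE of each rate is the number of transitions out of
#' a shape divided by the total time spent in it;
#' `rate_pr` = polarised-to-round, `rate_rp` = round-to-polarised, with
#' standard error `rate / sqrt(n_transitions)`. Supply `phenotypes` to
#' estimate per phenotype group.
#'
#' @param intervals Normalised intervals tibble.
#' @param phenotypes Optional tibble `cell_id`, `phenotype`; omitted = one
#'   pooled group.
#' @return Tibble per group: times, transition counts, `rate_pr`, `se_pr`,
#'   `rate_rp`, `se_rp` (`NA` where the occupied time is zero).
#' @export
estimate_switch_rates <- function(intervals, phenotypes = NULL) {
  iv <- intervals
  if (is.null(phenotypes)) {
    iv$phenotype <- "all"
  } else {
    iv <- dplyr::inner_join(
      iv,
      dplyr::mutate(
        dplyr::select(phenotypes, "cell_id", "phenotype"),
        phenotype = as.character(.data$phenotype)
      ),
      by = "cell_id"
    )
  }
  iv |>
    dplyr::arrange(.data$cell_id, .data$t_start_h) |>
    dplyr::group_by(.data$phenotype, .data$cell_id) |>
    dplyr::summarise(
      time_pol = sum(
        (.data$t_stop_h - .data$t_start_h)[.data$shape == "polarised"]
      ),
      time_round = sum(
        (.data$t_stop_h - .data$t_start_h)[.data$shape == "round"]
      ),
      n_pr = sum(
        .data$shape[-dplyr::n()] == "polarised" & .data$shape[-1] == "round"
      ),
      n_rp = sum(
        .data$shape[-dplyr::n()] == "round" & .data$shape[-1] == "polarised"
      ),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$phenotype) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      time_polarised_h = sum(.data$time_pol),
      time_round_h = sum(.data$time_round),
      n_pr = sum(.data$n_pr),
      n_rp = sum(.data$n_rp),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      rate_pr = ifelse(
        .data$time_polarised_h > 0, .data$n_pr / .data$time_polarised_h,
        NA_real_
      ),
      se_pr = ifelse(
        .data$n_pr > 0, .data$rate_pr / sqrt(.data$n_pr), NA_real_
      ),
      rate_rp = ifelse(
        .data$time_round_h > 0, .data$n_rp / .data$time_round_h, NA_real_
      ),
      se_rp = ifelse(
        .data$n_rp > 0, .data$rate_rp / sqrt(.data$n_rp), NA_real_
      )
    )
}

#' Per-generation cell-cycle-length statistics
#'
#' Censored cells are excluded; divided cells contribute
#' `t_end_h - t_birth_h`. Returns a per-generation table (count, mean,
#' median, quartiles, range) in the layout of a box-plot summary.
#'
#' @param cells Pedigree cells tibble.
#' @return Tibble: `generation`, `n`, `mean_h`, `median_h`, `q25_h`, `q75_h`,
#'   `min_h`, `max_h`. Empty (with a warning) if every cell is censored.
#' @export
cycle_length_stats <- function(cells) {
  divided <- dplyr::filter(cells, .data$end_event == "division")
  if (nrow(divided) == 0) {
    warn("all cells censored; no cycle lengths to summarise")
    return(tibble::tibble(
      generation = integer(), n = integer(), mean_h = double(),
      median_h = double(), q25_h = double(), q75_h = double(),
      min_h = double(), max_h = double()
    ))
  }
  divided |>
    dplyr::mutate(cycle = .data$t_end_h - .data$t_birth_h) |>
    dplyr::group_by(generation = .data$generation) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_h = mean(.data$cycle),
      median_h = median(.data$cycle),
      q25_h = quantile(.data$cycle, 0.25),
      q75_h = quantile(.data$cycle, 0.75),
      min_h = min(.data$cycle),
      max_h = max(.data$cycle),
      .groups = "drop"
    )
}
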