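#' Simulate clone pedigrees with heritable morphology-switching phenotypes
#'
#' Each clone starts from one founder whose phenotype is drawn from the
#' configured initial distribution. Cycle lengths come from the
#' generation-appropriate law (a truncated log-normal for the long first
#' cycle, truncated normal afterwards). Every cell's morphology path is a
#' two-state continuous-time Markov chain between polarised and round with
#' its phenotype's rates, discretised to the imaging frame interval.
#' Daughters draw their phenotype from the mother's row of the inheritance
#' matrix; cells alive at `observation_end_h` are right-censored.
#'
#' @param config A [pedigree_sim_config()].
#' @param seed Seed; defaults to `config$seed`. Per-clone sub-streams are
#'   derived from it, so individual clones are reproducible.
#' @return A list with:
#'   * `cells`: tibble `clone_id`, `cell_id`, `parent_id`, `generation`,
#'     `t_birth_h`, `t_end_h`, `end_event` (`"division"`/`"censored"`);
#'   * `intervals`: tibble `cell_id`, `t_start_h`, `t_stop_h`, `shape`
#'     (`"round"`/`"polarised"`), contiguous and alternating per cell;
#'   * `truth`: tibble `cell_id`, `phenotype` plus the generating `config`.
#' @export
#' @examples
#' ped <- simulate_pedigrees(pedigree_sim_config(n_clones = 5, seed = 2))
#' head(ped$cells)
simulate_pedigrees <- function(config, seed = NULL) {
  stopifnot(inherits(config, "pedigree_sim_config"))
  set.seed(seed %||% config$seed)
  clone_seeds <- sample.int(.Machine$integer.max - 1L, config$n_clones)
  phen <- c("P", "S", "R")

  res <- purrr::map(seq_len(config$n_clones), function(ci) {
    set.seed(clone_seeds[ci])
    clone_id <- sprintf("c%04d", ci)
    founder_ph <- sample(phen, 1, prob = config$initial_phenotype)
    cells <- list()
    intervals <- list()
    # breadth-first queue of (cell_id, parent_id, generation, birth, phenotype)
    queue <- list(list(
      id = paste0(clone_id, "_1"), parent = NA_character_,
      gen = 1L, birth = 0, ph = founder_ph
    ))
    while (length(queue) > 0) {
      cur <- queue[[1]]
      queue <- queue[-1]
      cycle <- draw_cycle_length(config, cur$gen)
      t_div <- cur$birth + cycle
      censored <- t_div > config$observation_end_h
      t_end <- if (censored) config$observation_end_h else t_div
      cells[[length(cells) + 1L]] <- tibble::tibble(
        clone_id = clone_id, cell_id = cur$id, parent_id = cur$parent,
        generation = cur$gen, t_birth_h = cur$birth, t_end_h = t_end,
        end_event = if (censored) "censored" else "division",
        phenotype = cur$ph
      )
      intervals[[length(intervals) + 1L]] <- sample_morphology_path(
        cur$id, cur$birth, t_end,
        config$switch_rates[[cur$ph]], config$frame_interval_h, cur$ph
      )
      if (!censored && cur$gen < config$max_generations) {
        row <- config$phenotype_inheritance[cur$ph, ]
        if (config$correlated_sisters) {
          ph_d <- rep(sample(phen, 1, prob = row), 2)
        } else {
          ph_d <- sample(phen, 2, replace = TRUE, prob = row)
        }
        for (d in 1:2) {
          queue[[length(queue) + 1L]] <- list(
            id = paste0(cur$id, d), parent = cur$id,
            gen = cur$gen + 1L, birth = t_div, ph = ph_d[d]
          )
        }
      }
    }
    list(
      cells = dplyr::bind_rows(cells),
      intervals = dplyr::bind_rows(intervals)
    )
  })

  cells <- dplyr::bind_rows(purrr::map(res, "cells"))
  list(
    cells = dplyr::select(cells, -"phenotype"),
    intervals = dplyr::bind_rows(purrr::map(res, "intervals")),
    truth = list(
      phenotypes = dplyr::select(cells, "cell_id", "phenotype"),
      inheritance = config$phenotype_inheritance,
      switch_rates = config$switch_rates,
      config = config
    )
  )
}

# First cycle: log-normal truncated to [min, max] with meanlog solved so the
# truncated median equals the configured one. Later cycles: normal truncated
# below at min_h. Both sampled by inverse CDF.
draw_cycle_length <- function(config, generation) {
  if (generation == 1L) {
    fl <- config$first_cycle_law
    ml <- trunc_lnorm_meanlog(fl$median_h, fl$min_h, fl$max_h, fl$sdlog)
    lo <- plnorm(fl$min_h, ml, fl$sdlog)
    hi <- plnorm(fl$max_h, ml, fl$sdlog)
    qlnorm(runif(1, lo, hi), ml, fl$sdlog)
  } else {
    ll <- config$later_cycle_law
    lo <- pnorm(ll$min_h, ll$mean_h, ll$sd_h)
    qnorm(runif(1, lo, 1), ll$mean_h, ll$sd_h)
  }
}

trunc_lnorm_meanlog <- function(median_h, min_h, max_h, sdlog) {
  if (min_h == max_h) return(log(median_h))
  f <- function(ml) {
    plnorm(median_h, ml, sdlog) -
      (plnorm(min_h, ml, sdlog) + plnorm(max_h, ml, sdlog)) / 2
  }
  uniroot(f, c(log(min_h) - 1, log(max_h) + 1), tol = 1e-10)$root
}

# Two-state CTMC path on [t0, t1], transition times snapped to the frame grid
# (relative to birth); zero-length intervals dropped, same-shape runs merged.
sample_morphology_path <- function(cell_id, t0, t1, rates, frame, phenotype) {
  pr <- rates[["pr"]]
  rp <- rates[["rp"]]
  total <- pr + rp
  shape0 <- if (total > 0) {
    if (runif(1) < pr / total) "round" else "polarised"
  } else {
    switch(phenotype, R = "round", "polarised")
  }
  t <- t0
  shape <- shape0
  breaks <- numeric(0)
  shapes <- shape0
  repeat {
    rate <- if (shape == "polarised") pr else rp
    if (rate <= 0) break
    t <- t + rexp(1, rate)
    if (t >= t1) break
    breaks <- c(breaks, t)
    shape <- if (shape == "polarised") "round" else "polarised"
    shapes <- c(shapes, shape)
  }
  if (length(breaks) > 0) {
    breaks <- t0 + round((breaks - t0) / frame) * frame
    keep <- breaks > t0 & breaks < t1 & !duplicated(breaks)
    breaks <- breaks[keep]
    shapes <- shapes[c(TRUE, keep)]
  }
  out <- tibble::tibble(
    cell_id = cell_id,
    t_start_h = c(t0, breaks),
    t_stop_h = c(breaks, t1),
    shape = shapes
  )
  merge_same_shape(out)
}

merge_same_shape <- function(intervals) {
  if (nrow(intervals) <= 1) return(intervals)
  run <- cumsum(c(TRUE, intervals$shape[-1] != intervals$shape[-nrow(intervals)]))
  intervals |>
    dplyr::group_by(.data$cell_id, run = run) |>
    dplyr::summarise(
      t_start_h = min(.data$t_start_h),
      t_stop_h = max(.data$t_stop_h),
      shape = .data$shape[1],
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$t_start_h) |>
    dplyr::select("cell_id", "t_start_h", "t_stop_h", "shape")
}

#' Deterministic synthetic founder cohort
#'
#' A synthetic stand-in for a hand-curated time-lapse founder table: 32
#' founder cells whose division times are constructed to match the published
#' cohort's printed summary features — median first-cycle length 58 h, all
#' divisions within \[35, 80\] h, 11 founders divided by 48 h, and 3 founders
#' still undivided at 72 h. Tracks are deterministic (no RNG): founders hold a
#' polarised shape apart from one brief round excursion.
#'
#' This is generated data, not the published raw measurements; it exists so
#' the track-reading and cycle-statistics pipeline can be exercised against
#' known printed marginals.
#'
#' @return A list with `cells` and `intervals` tibbles in the same layout as
#'   [simulate_pedigrees()].
#' @export
synthetic_founder_tracks <- function() {
  division_h <- c(
    35.5, 37, 38.5, 40, 41.5, 43, 44, 45, 46, 47, 48, # 11 divided by 48 h
    50, 52, 54, 56, 57, 59, # positions 16 and 17 average to 58
    60, 61, 62, 63, 64, 65, 66, 67, 68, 70, 71, 72,
    74, 76, 79 # 3 founders undivided at 72 h
  )
  cells <- tibble::tibble(
    clone_id = sprintf("f%03d", seq_along(division_h)),
    cell_id = sprintf("f%03d_1", seq_along(division_h)),
    parent_id = NA_character_,
    generation = 1L,
    t_birth_h = 0,
    t_end_h = division_h,
    end_event = "division"
  )
  intervals <- purrr::map_dfr(seq_along(division_h), function(i) {
    d <- division_h[i]
    tibble::tibble(
      cell_id = cells$cell_id[i],
      t_start_h = c(0, d / 2, d / 2 + 1),
      t_stop_h = c(d / 2, d / 2 + 1, d),
      shape = c("polarised", "round", "polarised")
    )
  })
  list(cells = cells, intervals = intervals)
}
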