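simple_cells <- function(id = "a", birth = 0, end = 20,
                         event = "division", gen = 1L) {
  tibble::tibble(
    clone_id = "cl", cell_id = id, parent_id = NA_character_,
    generation = gen, t_birth_h = birth, t_end_h = end, end_event = event
  )
}

test_that("dynamic parameters match hand-computed values", {
  # P 10 h, R 5 h, P 5 h: roundness 5/20, two switches over 20 h
  cells <- simple_cells(end = 20)
  iv <- tibble::tibble(
    cell_id = "a",
    t_start_h = c(0, 10, 15), t_stop_h = c(10, 15, 20),
    shape = c("polarised", "round", "polarised")
  )
  s <- summarize_cells(cells, iv)
  expect_equal(s$roundness, 0.25)
  expect_equal(s$switch_freq, 2 / 20)
  expect_equal(s$cycle_length_h, 20)

  all_pol <- summarize_cells(cells, tibble::tibble(
    cell_id = "a", t_start_h = 0, t_stop_h = 20, shape = "polarised"
  ))
  expect_equal(all_pol$roundness, 0)
  expect_equal(all_pol$switch_freq, 0)
})

test_that("censored cells keep roundness and switch frequency but no cycle length", {
  cells <- simple_cells(end = 15, event = "censored")
  iv <- tibble::tibble(
    cell_id = "a", t_start_h = c(0, 6), t_stop_h = c(6, 15),
    shape = c("round", "polarised")
  )
  s <- summarize_cells(cells, iv)
  expect_true(is.na(s$cycle_length_h))
  expect_equal(s$roundness, 6 / 15)
  expect_equal(s$switch_freq, 1 / 15)
})

test_that("summaries are invariant to splitting same-shape intervals after normalisation", {
  cells <- simple_cells(end = 20)
  iv <- tibble::tibble(
    cell_id = "a",
    t_start_h = c(0, 10, 15), t_stop_h = c(10, 15, 20),
    shape = c("polarised", "round", "polarised")
  )
  split_iv <- tibble::tibble(
    cell_id = "a",
    t_start_h = c(0, 4, 10, 15), t_stop_h = c(4, 10, 15, 20),
    shape = c("polarised", "polarised", "round", "polarised")
  )
  norm <- normalize_tracks(split_iv)
  expect_equal(nrow(norm), 3L)
  expect_equal(
    summarize_cells(cells, norm), summarize_cells(cells, iv)
  )
})

test_that("sub-frame gaps are closed on load but real gaps are an error", {
  cells <- simple_cells(end = 20)
  gappy <- tibble::tibble(
    cell_id = "a",
    t_start_h = c(0, 10.01), t_stop_h = c(10, 20),
    shape = c("polarised", "round")
  )
  norm <- normalize_tracks(gappy) # 0.01 h < one frame: closed
  expect_equal(norm$t_start_h[2], 10)
  big_gap <- tibble::tibble(
    cell_id = "a",
    t_start_h = c(0, 12), t_stop_h = c(10, 20),
    shape = c("polarised", "round")
  )
  expect_error(summarize_cells(cells, big_gap), "contiguous")
  expect_error(
    summarize_cells(cells, gappy[0, ]), "no intervals"
  )
})

test_that("summaries are invariant to a global time shift", {
  cells <- simple_cells(birth = 0, end = 20)
  iv <- tibble::tibble(
    cell_id = "a", t_start_h = c(0, 8), t_stop_h = c(8, 20),
    shape = c("polarised", "round")
  )
  shifted_cells <- dplyr::mutate(
    cells, t_birth_h = t_birth_h + 100, t_end_h = t_end_h + 100
  )
  shifted_iv <- dplyr::mutate(
    iv, t_start_h = t_start_h + 100, t_stop_h = t_stop_h + 100
  )
  expect_equal(
    summarize_cells(cells, iv), summarize_cells(shifted_cells, shifted_iv)
  )
})

test_that("founder-recovery trimming only affects generation 1", {
  cells <- dplyr::bind_rows(
    simple_cells("f", 0, 20, gen = 1L),
    dplyr::mutate(simple_cells("d", 20, 40, gen = 2L), parent_id = "f")
  )
  iv <- tibble::tibble(
    cell_id = c("f", "f", "d"),
    t_start_h = c(0, 2, 20), t_stop_h = c(2, 20, 40),
    shape = c("round", "polarised", "polarised")
  )
  s <- summarize_cells(cells, iv, trim_founder_h = 3)
  expect_equal(s$roundness[s$cell_id == "f"], 0) # round excursion trimmed
  expect_equal(s$observed_h[s$cell_id == "f"], 17)
  expect_equal(s$observed_h[s$cell_id == "d"], 20)
})

test_that("archetype cells classify perfectly into P, S, R", {
  s <- archetype_summaries()
  out <- classify_phenotypes(s, seed = 1)
  expect_equal(as.character(out$phenotype), out$truth)
  thr <- classify_phenotypes(s, method = "thresholds")
  expect_equal(as.character(thr$phenotype), thr$truth)
})

test_that("degenerate identical summaries are refused", {
  s <- archetype_summaries(jitter = 0)
  s$roundness <- 0.5
  s$switch_freq <- 0.1
  expect_error(classify_phenotypes(s), "identical")
  expect_error(classify_phenotypes(s[1:4, ]), "6 cells")
})

test_that("classification recovers simulated ground-truth phenotypes", {
  cfg <- pedigree_sim_config(n_clones = 120, max_generations = 3, seed = 21)
  ped <- simulate_pedigrees(cfg)
  s <- summarize_cells(ped$cells, ped$intervals)
  out <- classify_phenotypes(s, seed = 1)
  truth <- ped$truth$phenotypes$phenotype[
    match(out$cell_id, ped$truth$phenotypes$cell_id)
  ]
  expect_gte(mean(as.character(out$phenotype) == truth), 0.9)
})

test_that("transition matrix handles founder-only and orphan pedigrees", {
  founders <- simple_cells("only", 0, 50)
  tr <- transition_frequencies(
    founders, tibble::tibble(cell_id = "only", phenotype = "P")
  )
  expect_equal(tr$n_edges, 0L)
  expect_setequal(tr$no_data_rows, c("P", "S", "R"))
  expect_true(all(is.na(tr$freq)))

  orphan <- dplyr::mutate(simple_cells("lost", 10, 30), parent_id = "ghost")
  expect_error(
    transition_frequencies(
      orphan, tibble::tibble(cell_id = "lost", phenotype = "P")
    ),
    "integrity"
  )
})

test_that("transition tidier returns row-stochastic frequencies", {
  ped <- simulate_pedigrees(pedigree_sim_config(n_clones = 60, seed = 22))
  tr <- transition_frequencies(ped$cells, ped$truth$phenotypes)
  td <- tidy(tr)
  rs <- td |>
    dplyr::group_by(mother) |>
    dplyr::summarise(s = sum(freq))
  expect_true(all(abs(rs$s[!is.na(rs$s)] - 1) < 1e-9))
  expect_equal(sum(td$n), tr$n_edges)
})

test_that("classify -> transition pipeline respects round closure on closed data", {
  cfg <- pedigree_sim_config(n_clones = 120, max_generations = 3, seed = 23)
  ped <- simulate_pedigrees(cfg)
  s <- summarize_cells(ped$cells, ped$intervals)
  out <- classify_phenotypes(s, seed = 1)
  tr <- transition_frequencies(ped$cells, out)
  # closure is exact on ground-truth labels (tested in test-sim-pedigree);
  # under estimated labels it holds up to the classifier's error rate
  expect_lte(sum(tr$freq["R", c("P", "S")]), 0.05)
  truth_tr <- transition_frequencies(ped$cells, ped$truth$phenotypes)
  expect_identical(unname(truth_tr$freq["R", ]), c(0, 0, 1))
})

test_that("sister distances: duplicates are similar, archetype opposites divergent", {
  mk_pair <- function(pid, r1, sw1, cy1, r2, sw2, cy2) {
    list(
      cells = tibble::tibble(
        clone_id = pid, cell_id = paste0(pid, c("_1", "_2")),
        parent_id = pid, generation = 2L, t_birth_h = 0,
        t_end_h = c(cy1, cy2), end_event = "division"
      ),
      sm = tibble::tibble(
        cell_id = paste0(pid, c("_1", "_2")),
        roundness = c(r1, r2), switch_freq = c(sw1, sw2),
        cycle_length_h = c(cy1, cy2)
      )
    )
  }
  pairs <- list(
    mk_pair("tw1", 0.1, 0.02, 20, 0.1, 0.02, 20), # identical twins
    mk_pair("tw2", 0.9, 0.03, 21, 0.9, 0.03, 21),
    mk_pair("tw3", 0.5, 0.40, 19, 0.5, 0.40, 19),
    mk_pair("dv1", 0.05, 0.02, 20, 0.95, 0.5, 40), # P vs R archetypes
    mk_pair("dv2", 0.05, 0.02, 21, 0.95, 0.5, 42)
  )
  cells <- dplyr::bind_rows(purrr::map(pairs, "cells"))
  sm <- dplyr::bind_rows(purrr::map(pairs, "sm"))
  out <- sister_similarity(cells, sm, seed = 1)
  expect_equal(out$distance[out$parent_id == "tw1"], 0)
  expect_equal(out$class[out$parent_id %in% c("tw1", "tw2", "tw3")],
    rep("similar", 3))
  expect_equal(out$class[out$parent_id %in% c("dv1", "dv2")],
    rep("divergent", 2))
})

test_that("censored sisters are excluded with a warning", {
  ped <- simulate_pedigrees(pedigree_sim_config(
    n_clones = 40, max_generations = 3, observation_end_h = 90, seed = 24
  ))
  s <- summarize_cells(ped$cells, ped$intervals)
  expect_warning(out <- sister_similarity(ped$cells, s, seed = 1), "censored")
  complete <- s$cell_id[!is.na(s$cycle_length_h)]
  expect_true(all(out$cell_id_1 %in% complete & out$cell_id_2 %in% complete))
})

test_that("switch-rate MLE matches hand formulas on a single track", {
  iv <- tibble::tibble(
    cell_id = "a", t_start_h = c(0, 10), t_stop_h = c(10, 20),
    shape = c("polarised", "round")
  )
  est <- estimate_switch_rates(iv)
  expect_equal(est$rate_pr, 0.1) # one P->R transition over 10 h polarised
  expect_equal(est$rate_rp, 0) # no R->P transition in 10 h round
  expect_equal(est$se_pr, 0.1)
  expect_true(is.na(est$se_rp))

  no_switch <- tibble::tibble(
    cell_id = "b", t_start_h = 0, t_stop_h = 20, shape = "polarised"
  )
  est2 <- estimate_switch_rates(no_switch)
  expect_equal(est2$rate_pr, 0)
  expect_true(is.na(est2$rate_rp)) # never observed round
})

test_that("cycle statistics: censored-only input yields an empty table", {
  cens <- simple_cells(event = "censored")
  expect_warning(out <- cycle_length_stats(cens), "censored")
  expect_equal(nrow(out), 0L)
})

test_that("the synthetic founder cohort reproduces its printed marginals", {
  fx <- synthetic_founder_tracks()
  expect_equal(nrow(fx$cells), 32L)
  stats <- cycle_length_stats(fx$cells)
  expect_equal(stats$median_h, 58)
  expect_true(stats$min_h >= 35 && stats$max_h <= 80)
  expect_equal(sum(fx$cells$t_end_h <= 48), 11L)
  expect_equal(sum(fx$cells$t_end_h > 72), 3L)
  # tracks are valid input for the summary pipeline
  s <- summarize_cells(fx$cells, fx$intervals)
  expect_true(all(s$switch_freq > 0))
  expect_true(all(s$roundness > 0 & s$roundness < 0.1))
})
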