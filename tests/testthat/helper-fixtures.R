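make_raw_ct <- function(cells) {
  # cells: named list cell_id -> list(spike1, spike4, genes = named ct vector,
  # flags = optional named flag vector)
  purrr::imap_dfr(cells, function(spec, id) {
    assays <- c("spike1", "spike4", names(spec$genes))
    ct <- c(spec$spike1, spec$spike4, unname(spec$genes))
    flag <- rep("OK", length(assays))
    if (!is.null(spec$flags)) {
      flag[match(names(spec$flags), assays)] <- unname(spec$flags)
    }
    tibble::tibble(cell_id = id, assay = assays, ct = ct, flag = flag)
  })
}

# best label-agreement over all permutations of cluster labels (exact
# Hungarian solution for k <= 3 by enumeration)
perm_accuracy <- function(truth, labels) {
  truth <- as.integer(factor(truth))
  labels <- as.integer(factor(labels))
  k <- max(truth, labels)
  perms <- gtools_permutations(k)
  best <- 0
  for (i in seq_len(nrow(perms))) {
    best <- max(best, mean(perms[i, labels] == truth))
  }
  best
}

gtools_permutations <- function(k) {
  if (k == 1) return(matrix(1))
  sub <- gtools_permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, matrix(c(seq_len(k)[-i])[sub], nrow(sub)))
  }))
}

# archetype dynamic-phenotype summaries: three well-separated groups
archetype_summaries <- function(n_per = 20, jitter = 0.01, seed = 42) {
  set.seed(seed)
  arch <- tibble::tribble(
    ~phen, ~roundness, ~switch_freq,
    "P", 0.05, 0.02,
    "R", 0.95, 0.02,
    "S", 0.50, 0.50
  )
  purrr::pmap_dfr(arch, function(phen, roundness, switch_freq) {
    tibble::tibble(
      clone_id = "x", generation = 2L, end_event = "division",
      cell_id = paste0(phen, seq_len(n_per)),
      observed_h = 20,
      roundness = pmin(1, pmax(0, roundness + rnorm(n_per, 0, jitter))),
      switch_freq = pmax(0, switch_freq + rnorm(n_per, 0, jitter)),
      cycle_length_h = 20 + rnorm(n_per, 0, 0.5),
      truth = phen
    )
  })
}
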