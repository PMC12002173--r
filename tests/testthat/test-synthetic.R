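test_that("all generators are pure functions of their seed", {
  tr <- sim_tree(12, 9)
  expect_identical(sim_dollo_character(tr, tr$root, 0.1, 5),
                   sim_dollo_character(tr, tr$root, 0.1, 5))
  expect_identical(sim_profile_matrix(tr, 10, 2, 0.02, 11),
                   sim_profile_matrix(tr, 10, 2, 0.02, 11))
  model <- default_site_model()
  expect_identical(sim_catalytic_msa(tr, model, "n2", 7),
                   sim_catalytic_msa(tr, model, "n2", 7))
  specs <- default_gene_specs(3, seed = 2)
  expect_identical(sim_mutation_catalog(specs, 50, 4),
                   sim_mutation_catalog(specs, 50, 4))
  expect_identical(sim_alkylation_table(3, 3, 6, 8),
                   sim_alkylation_table(3, 3, 6, 8))
  expect_identical(sim_assay(c(0, 1e-11), noise_sd = 0.002, seed = 3),
                   sim_assay(c(0, 1e-11), noise_sd = 0.002, seed = 3))
})

test_that("sim_dollo_character: no-loss limit fills the gain clade", {
  tr <- sim_tree(10, 2)
  s <- sim_dollo_character(tr, tr$root, 0, 1)
  expect_true(all(s$tip_states == 1))
  expect_length(s$events$loss_edges, 0)

  # gain on an internal edge: presence confined to that clade
  inner <- setdiff(tr$labels, c(tr$tips, tr$root))[1]
  s2 <- sim_dollo_character(tr, inner, 0, 1)
  expect_setequal(names(s2$tip_states)[s2$tip_states == 1],
                  tr$desc_tips[[inner]])

  expect_error(sim_dollo_character(tr, "nope", 0.1, 1), "not found")
  expect_error(sim_dollo_character(tr, tr$root, 1, 1), "loss_rate")
})

test_that("sim_dollo_character agrees with an independent replay of the propagation rule", {
  tr <- sim_tree(20, 6)
  for (s in 1:20) {
    got <- sim_dollo_character(tr, tr$root, 0.1, 100 + s)
    oracle <- replay_dollo_sim(tr, tr$root, 0.1, 100 + s)
    expect_identical(got$tip_states, oracle$tip_states)
    expect_setequal(got$events$loss_edges, oracle$loss_edges)
  }
})

test_that("per-edge loss frequency matches loss_rate over many replicates", {
  tr <- sim_tree(10, 3)
  loss_rate <- 0.1
  n_rep <- 10000
  edges <- setdiff(tr$labels, tr$root)
  n_active <- stats::setNames(rep(0L, length(edges)), edges)
  n_lost <- n_active
  for (i in seq_len(n_rep)) {
    ev <- sim_dollo_character(tr, tr$root, loss_rate, i)$events
    # reconstruct which edges had an active parent by walking down
    state <- stats::setNames(rep(1L, length(tr$labels)), tr$labels)
    for (v in tr$labels) {
      p <- tr$parent[[v]]
      if (is.na(p)) next
      state[v] <- if (state[[p]] == 0L || v %in% ev$loss_edges) 0L else 1L
      if (state[[p]] == 1L) {
        n_active[v] <- n_active[v] + 1L
        if (v %in% ev$loss_edges) n_lost[v] <- n_lost[v] + 1L
      }
    }
  }
  freq <- n_lost / n_active
  se <- sqrt(loss_rate * (1 - loss_rate) / n_active)
  expect_true(all(abs(freq - loss_rate) <= 3 * se))
})

test_that("sim_profile_matrix plants exact copies at zero flip noise", {
  tr <- sim_tree(30, 4)
  sim <- sim_profile_matrix(tr, 20, 3, 0, 13)
  expect_equal(dim(sim$matrix), c(30L, 21L))
  expect_length(sim$truth$coevolving_gene_ids, 3)
  for (g in sim$truth$coevolving_gene_ids) {
    expect_identical(unname(sim$matrix[, g]), unname(sim$matrix[, "query"]))
    expect_equal(phi_correlation(sim$matrix[, g], sim$matrix[, "query"]), 1)
  }
  empty <- sim_profile_matrix(tr, 5, 0, 0, 2)
  expect_length(empty$truth$coevolving_gene_ids, 0)
  expect_error(sim_profile_matrix(tr, 3, 4, 0, 1), "n_coevolving")
})

test_that("sim_catalytic_msa degrades required sites only inside the pseudo clade", {
  tr <- sim_tree(14, 5)
  model <- default_site_model()
  inner <- setdiff(tr$labels, c(tr$tips, tr$root))[2]
  sim <- sim_catalytic_msa(tr, model, inner, 21)
  truth <- sim$truth$sequence_classes
  expect_setequal(names(truth)[truth == "pseudo"], tr$desc_tips[[inner]])

  calls <- call_active_site(sim$alignment, model)
  got <- stats::setNames(calls$class, calls$sequence_id)[names(truth)]
  expect_identical(unname(got), unname(truth))

  # a one-tip pseudo clade labels exactly one sequence pseudo
  one <- sim_catalytic_msa(tr, model, tr$tips[1], 3)
  expect_equal(sum(one$truth$sequence_classes == "pseudo"), 1L)

  # cysteine shows up at an M2 aspartate position in some replicate
  m2cols <- model$position[model$role == "M2"]
  saw_c <- any(vapply(1:10, function(s) {
    a <- sim_catalytic_msa(tr, model, inner, s)$alignment
    any(vapply(a[tr$desc_tips[[inner]]], function(seq)
      any(substring(seq, m2cols, m2cols) == "C"), logical(1)))
  }, logical(1)))
  expect_true(saw_c)
})

test_that("a site model with no required positions cannot be built", {
  expect_error(site_model("R", "M3", 10, "D", FALSE), "required")
  expect_error(site_model("R", c("M1", "M2"), c(5, 4), c("D", "D"), c(TRUE, TRUE)),
               "increasing")
})

test_that("sim_mutation_catalog honors class structure", {
  specs <- default_gene_specs(3, seed = 5)
  sim <- sim_mutation_catalog(specs, 200, 6)

  # positions within gene bounds, vocabulary closed
  expect_true(all(sim$catalog$position >= 1 &
                    sim$catalog$position <= sim$gene_lengths[sim$catalog$gene]))
  expect_true(all(sim$catalog$consequence %in%
                    c("synonymous", "missense", "nonsense", "frameshift")))

  # zero background rate empties neutral genes
  sim0 <- sim_mutation_catalog(specs[specs$class == "neutral", ], 50, 1,
                               syn_rate = 0, nonsyn_rate = 0)
  expect_equal(nrow(sim0$catalog), 0L)

  # hotspot is the modal missense codon for an oncogene
  onc <- specs$gene[specs$class == "oncogene"][1]
  hs <- as.integer(strsplit(specs$hotspots[specs$gene == onc], ",")[[1]])
  recs <- sim$catalog[sim$catalog$gene == onc & sim$catalog$consequence == "missense", ]
  modal <- as.integer(names(which.max(table(recs$position))))
  expect_true(modal %in% hs)

  # strong CNL skew spec dominates CNG at generated scale
  tsg_spec <- data.frame(gene = "T1", class = "tsg", length_aa = 500L,
                         hotspots = "", truncating_fraction = 0.4,
                         cnl_prob = 0.8, cng_prob = 0.05)
  cn <- sim_mutation_catalog(tsg_spec, 200, 7)$cnv
  expect_gt(sum(cn$call == "loss"), sum(cn$call == "gain"))

  expect_error(sim_mutation_catalog(specs, 100, 1, syn_rate = -1), "nonnegative")
  bad <- specs; bad$length_aa <- 10L
  expect_error(sim_mutation_catalog(bad, 100, 1), "50 aa")
})

test_that("sim_alkylation_table separates classes as requested", {
  sim <- sim_alkylation_table(0, 5, 6, 2)
  expect_true(all(sim$truth$cysteine_classes == "exposed"))
  expect_equal(nrow(sim$table), 5L)

  sim2 <- sim_alkylation_table(4, 6, 6, 3)
  calls <- alkylation_accessibility(sim2$table)
  truth <- sim2$truth$cysteine_classes[as.character(calls$residue)]
  expect_equal(mean(calls$call == truth), 1)
  expect_error(sim_alkylation_table(2, 2, 0, 1), "separation")
})

test_that("sim_assay is exactly invertible at zero noise", {
  sa <- sim_assay(c(0, 2e-11), contaminant_rate = 0, noise_sd = 0, seed = 4)
  cal <- fit_calibration(sa$standards)
  expect_equal(cal$slope, sa$truth$calib_slope)
  expect_equal(cal$r_squared, 1)
  for (id in names(sa$truth$true_rates)) {
    a <- sa$endpoints$absorbance[sa$endpoints$rate_id == id &
                                   sa$endpoints$treatment == "untreated"]
    r <- endpoint_rate(a, sa$blanks, cal, sa$incubation_time)$rate
    expect_equal(r, unname(sa$truth$true_rates[id]), tolerance = 1e-12)
  }
  # zero target + inhibited contaminant: treated course is flat
  sa2 <- sim_assay(0, contaminant_rate = 1e-11, oa_inhibits_contaminant = TRUE,
                   noise_sd = 0, seed = 5)
  tc <- sa2$timecourses[sa2$timecourses$treatment == "inhibitor", ]
  r <- timecourse_rate(tc$time_s, tc$absorbance, 1 / sa2$truth$calib_slope)
  expect_equal(r$rate, 0)
})
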