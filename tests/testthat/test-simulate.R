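test_that("identical seeds give bit-identical repertoires", {
  cfg <- sim_config(seed = 81, n_sequences = 150, n_clones = 40)
  a <- simulate_repertoire(cfg)
  b <- simulate_repertoire(cfg)
  expect_identical(a$table, b$table)
  expect_identical(a$truth, b$truth)
  c <- simulate_repertoire(sim_config(seed = 82, n_sequences = 150,
                                      n_clones = 40))
  expect_false(identical(a$table$junction, c$table$junction))
})

test_that("configuration is validated before any sampling", {
  expect_error(sim_config(), "seed is mandatory")
  expect_error(sim_config(seed = 1, rf_weights = c(I = 0, II = 0, III = 0)),
               "at least one positive")
  expect_error(sim_config(seed = 1, rf_weights = c(a = 1, b = 1, c = 1)),
               "named I, II, III")
  expect_error(sim_config(seed = 1, d_weights = c("D1-1" = -1, "D2-2" = 1)),
               "non-negative")
  expect_error(sim_config(seed = 1, clone_sizes = c(3, 0)))
})

test_that("every emitted record passes the productive filter (preserve mode)", {
  sim <- simulate_repertoire(sim_config(seed = 83, n_sequences = 400,
                                        n_clones = 80))
  kept <- filter_productive(sim$table)
  expect_equal(nrow(kept), nrow(sim$table))
  expect_true(all(sim$truth$productive))
  # junction structure: starts at the Cys codon, ends with Trp
  expect_true(all(substr(sim$table$junction_aa, 1, 1) == "C"))
  expect_true(all(substr(sim$table$junction_aa,
                         nchar(sim$table$junction_aa),
                         nchar(sim$table$junction_aa)) == "W"))
  expect_true(all(nchar(sim$table$junction) %% 3 == 0))
})

test_that("explicit clone sizes [40, 2, 1] classify as HE / HE / single", {
  cfg <- sim_config(seed = 89, clone_sizes = c(40L, 2L, 1L))
  sim <- simulate_repertoire(cfg)
  expect_equal(nrow(sim$table), 43L)
  strat <- classify_expansion(group_clones(filter_productive(sim$table)))
  sizes <- sort(strat$n, decreasing = TRUE)
  expect_equal(sizes, c(40L, 2L, 1L))
  got <- as.character(strat$category[order(-strat$n)])
  expect_equal(got, c("highly_expanded", "highly_expanded", "single"))
  # pipeline classification agrees with the simulator's intended categories
  truth_cat <- unique(sim$truth[, c("clone_size", "category")])
  expect_equal(truth_cat$category[order(-truth_cat$clone_size)], got)
})

test_that("empirical construction RF distribution matches exact enumeration", {
  germ <- reduced_germline()
  cfg <- sim_config(seed = 97, clone_sizes = rep(1L, 4000),
                    germline = germ, n_add_max = 4, shm_rate = 0)
  expected <- oracle_rf_construction(germ, cfg$trim_p, cfg$n_add_lambda,
                                     n_add_max = 4)
  sim <- simulate_repertoire(cfg)
  rf <- suppressMessages(assign_rf(sim$table))
  dist <- rf_distribution(rf)
  n <- attr(dist, "n_assigned")
  for (lab in c("I", "II", "III")) {
    p0 <- expected$rf[[lab]]
    obs <- dist$proportion[dist$rf == lab]
    half_width <- stats::qnorm(0.995) * sqrt(p0 * (1 - p0) / n)
    expect_lt(abs(obs - p0), half_width + 1e-12)
  }
})

test_that("RF selection shifts usage towards the favoured frame", {
  germ <- reduced_germline()
  w <- c(I = 1, II = 0.1, III = 0.1)
  base <- oracle_rf_construction(germ, list(d5 = 0.35, d3 = 0.35, j5 = 0.35),
                                 2.5, n_add_max = 4)
  sel <- oracle_rf_construction(germ, list(d5 = 0.35, d3 = 0.35, j5 = 0.35),
                                2.5, n_add_max = 4, rf_weights = w)
  expect_gt(sel$rf[["I"]], base$rf[["I"]])
  cfg <- sim_config(seed = 101, clone_sizes = rep(1L, 3000), germline = germ,
                    n_add_max = 4, rf_weights = w, shm_rate = 0)
  sim <- simulate_repertoire(cfg)
  dist <- rf_distribution(suppressMessages(assign_rf(sim$table)))
  n <- attr(dist, "n_assigned")
  p0 <- sel$rf[["I"]]
  half_width <- stats::qnorm(0.995) * sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(dist$proportion[dist$rf == "I"] - p0), half_width + 1e-12)
  expect_gt(dist$proportion[dist$rf == "I"], base$rf[["I"]])
})

test_that("configured RF acceptance weights are recovered from emitted data", {
  germ <- reduced_germline()
  w <- c(I = 1, II = 0.4, III = 0.2)
  base_cfg <- sim_config(seed = 103, clone_sizes = rep(1L, 10000),
                         germline = germ, n_add_max = 4, shm_rate = 0)
  sel_cfg <- sim_config(seed = 104, clone_sizes = rep(1L, 10000),
                        germline = germ, n_add_max = 4, rf_weights = w,
                        shm_rate = 0)
  base <- rf_distribution(suppressMessages(
    assign_rf(simulate_repertoire(base_cfg)$table)))
  sel <- rf_distribution(suppressMessages(
    assign_rf(simulate_repertoire(sel_cfg)$table)))
  ratio <- sel$proportion / base$proportion
  w_hat <- ratio / max(ratio)
  for (lab in c("I", "II", "III")) {
    expect_lt(abs(w_hat[sel$rf == lab] - w[[lab]] / max(w)), 0.1)
  }
})

test_that("WT-like selection vs KO-like neutrality shows the expected contrasts", {
  sc <- get_scenario()
  expect_equal(unique(sc$wt$table$genotype), "WT")
  expect_equal(unique(sc$ko$table$genotype), "KO")
  rf_wt <- rf_distribution(suppressMessages(assign_rf(sc$wt$table)))
  rf_ko <- rf_distribution(suppressMessages(assign_rf(sc$ko$table)))
  expect_gt(rf_wt$proportion[rf_wt$rf == "I"],
            rf_ko$proportion[rf_ko$rf == "I"])
  # unselected arm keeps more very short loops
  short_frac <- function(tbl) {
    len <- annotate_loops(tbl)$loop_length
    mean(len >= 2 & len <= 7)
  }
  expect_gte(short_frac(sc$ko$table), short_frac(sc$wt$table))
})

test_that("hypermutation stays outside the junction in preserve mode", {
  cfg <- sim_config(seed = 107, n_sequences = 300, n_clones = 30,
                    shm_rate = 0.02)
  sim <- simulate_repertoire(cfg)
  # every member of a clone shares the founder loop
  by_clone <- split(sim$truth$loop_aa, sim$truth$clone_id)
  expect_true(all(vapply(by_clone, function(x) length(unique(x)) == 1L,
                         logical(1))))
  # mutations land in the V region outside the junction-contributing tail
  mutated <- sim$table$v_sequence_alignment != sim$table$v_germline_alignment
  expect_true(any(mutated))
  tails_equal <- substr(sim$table$v_sequence_alignment,
                        nchar(sim$table$v_sequence_alignment) - 8L,
                        nchar(sim$table$v_sequence_alignment)) ==
    substr(sim$table$v_germline_alignment,
           nchar(sim$table$v_germline_alignment) - 8L,
           nchar(sim$table$v_germline_alignment))
  expect_true(all(tails_equal))

  stress <- simulate_repertoire(sim_config(seed = 108, n_sequences = 300,
                                           n_clones = 30, shm_rate = 0.02,
                                           preserve_clone_key = FALSE))
  by_clone2 <- split(stress$truth$loop_aa, stress$truth$clone_id)
  expect_true(any(vapply(by_clone2, function(x) length(unique(x)) > 1L,
                         logical(1))))
})
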