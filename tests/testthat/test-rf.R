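rf_record <- function(d_junction_start, d_germline_start, d_call = "D1-1",
                      d_length = 5L) {
  tibble::tibble(
    sequence_id = "s1", d_call = d_call,
    d_junction_start = as.integer(d_junction_start),
    d_germline_start = as.integer(d_germline_start),
    d_length = as.integer(d_length)
  )
}

test_that("frame offset arithmetic and anchor lookup", {
  anchors <- rf_anchor_map()
  # offset 0: germline read from its first base
  a0 <- assign_rf(rf_record(0, 0), anchors)
  expect_equal(a0$frame_offset, 0L)
  expect_equal(as.character(a0$rf_label),
               unname(anchors$genes[["D1-1"]]["0"]))
  expect_equal(assign_rf(rf_record(0, 1), anchors)$frame_offset, 1L)
  # the bundled anchors put the tyrosine-rich frame (offset 2) at RFI
  expect_equal(as.character(assign_rf(rf_record(0, 2), anchors)$rf_label), "I")
  expect_equal(as.character(assign_rf(rf_record(0, 0), anchors)$rf_label), "II")
  expect_equal(as.character(assign_rf(rf_record(0, 1), anchors)$rf_label), "III")
})

test_that("frame offset is invariant to re-anchoring the alignment", {
  anchors <- rf_anchor_map()
  base <- assign_rf(rf_record(3, 1), anchors)
  for (shift in 1:5) {
    shifted <- assign_rf(rf_record(3 + shift, 1 + shift), anchors)
    expect_equal(shifted$frame_offset, base$frame_offset)
    expect_equal(shifted$rf_label, base$rf_label)
  }
})

test_that("unknown genes fall back to the default anchor or error without one", {
  anchors <- rf_anchor_map()
  novel <- assign_rf(rf_record(0, 0, d_call = "D7-9"), anchors)
  expect_equal(as.character(novel$rf_label), "I")  # documented fallback
  no_default <- list(default = NULL, genes = anchors$genes)
  expect_error(assign_rf(rf_record(0, 0, d_call = "D7-9"), no_default),
               "D7-9")
})

test_that("records without a usable D alignment are left unassigned", {
  tbl <- tibble::tibble(
    sequence_id = c("s1", "s2", "s3"),
    d_call = c("D1-1", NA, "D1-1"),
    d_junction_start = c(9L, NA, 9L),
    d_germline_start = c(0L, NA, 0L),
    d_length = c(5L, NA, 0L)
  )
  expect_message(rf <- assign_rf(tbl), "2 record")
  expect_equal(is.na(rf$rf_label), c(FALSE, TRUE, TRUE))
  dist <- rf_distribution(rf)
  expect_equal(attr(dist, "n_assigned"), 1L)
  expect_equal(attr(dist, "no_d_fraction"), 2 / 3)
})

test_that("untrimmed D at a codon boundary appears verbatim in the translation", {
  g <- sim_germline()
  anchors <- rf_anchor_map()
  for (di in seq_len(nrow(g$d))) {
    d_seq <- g$d$sequence_nt[di]
    for (offset in 0:2) {
      # build a junction whose D part starts at a codon boundary and is
      # read from germline base `offset`
      d_part <- substr(d_seq, offset + 1L, nchar(d_seq))
      d_part <- substr(d_part, 1L, 3L * (nchar(d_part) %/% 3L))
      if (nchar(d_part) < 3L) next
      junction <- paste0("TGTGCGAGA", d_part, "TACTGG")
      aa <- hcdr3:::.translate_nt(junction)
      d_aa <- hcdr3:::.translate_nt(d_part)
      if (grepl("*", d_aa, fixed = TRUE)) next
      expect_true(grepl(d_aa, aa, fixed = TRUE))
      rec <- rf_record(9, offset, d_call = g$d$name[di],
                       d_length = nchar(d_part))
      lab <- assign_rf(rec, anchors)
      expect_equal(lab$frame_offset, offset %% 3L)
    }
  }
})

test_that("per-clone weighting counts each clone once", {
  # one huge clone + two singletons, three distinct frames
  tbl <- tibble::tibble(
    sequence_id = sprintf("s%04d", 1:1002),
    junction_aa = c(rep("CARAAAW", 1000), "CARCCCW", "CARDDDW"),
    d_call = "D1-1",
    d_junction_start = 9L,
    d_germline_start = c(rep(2L, 1000), 0L, 1L),
    d_length = 5L
  )
  strat <- group_clones(tbl)
  rf <- assign_rf(tbl)
  per_clone <- rf_distribution_per_clone(strat, rf)
  expect_equal(per_clone$proportion, rep(1 / 3, 3))
  per_seq <- rf_distribution(rf)
  expect_gt(per_seq$proportion[per_seq$rf == "I"], 0.99)

  # with all clone sizes 1, the two weightings coincide
  singles <- tbl[1000:1002, ]
  s_strat <- group_clones(singles)
  s_rf <- assign_rf(singles)
  expect_equal(rf_distribution_per_clone(s_strat, s_rf)$proportion,
               rf_distribution(s_rf)$proportion)
})

test_that("discordant clones are counted by majority with a warning", {
  tbl <- tibble::tibble(
    sequence_id = c("s1", "s2", "s3"),
    junction_aa = "CARAAAW",
    d_call = "D1-1",
    d_junction_start = 9L,
    d_germline_start = c(2L, 2L, 0L),
    d_length = 5L
  )
  strat <- group_clones(tbl)
  rf <- assign_rf(tbl)
  expect_warning(dist <- rf_distribution_per_clone(strat, rf), "discordant")
  expect_equal(dist$n[dist$rf == "I"], 1L)
  expect_equal(sum(dist$n), 1L)
})

test_that("simulated reading frames are recovered perfectly from coordinates", {
  sim <- simulate_repertoire(sim_config(seed = 67, n_sequences = 800,
                                        n_clones = 150))
  rf <- suppressMessages(assign_rf(sim$table))
  joined <- dplyr::inner_join(rf, sim$truth[, c("sequence_id", "rf_label")],
                              by = "sequence_id", suffix = c("", "_true"))
  has_d <- !is.na(joined$rf_label_true)
  expect_true(all(as.character(joined$rf_label[has_d]) ==
                    joined$rf_label_true[has_d]))
  expect_true(all(is.na(joined$rf_label[!has_d])))
})

test_that("D gene and family usage tallies calls and unresolved records", {
  tbl <- tibble::tibble(
    sequence_id = sprintf("s%d", 1:5),
    d_call = c("IGHD1-1*01", "D1-1", "D2-2", NA, "D2-2")
  )
  usage <- d_usage(tbl)
  expect_equal(usage$n[usage$d_gene == "D1-1"], 2L)
  expect_equal(usage$n[usage$d_gene == "D2-2"], 2L)
  expect_equal(usage$n[usage$d_gene == "unresolved"], 1L)
  expect_equal(usage$d_family[usage$d_gene == "D1-1"], "D1")
  expect_equal(sum(usage$proportion), 1)

  all_d11 <- tibble::tibble(sequence_id = "s1", d_call = "D1-1")
  expect_equal(d_usage(all_d11)$proportion, 1)

  none <- tibble::tibble(sequence_id = c("s1", "s2"), d_call = NA_character_)
  expect_equal(d_usage(none)$d_gene, "unresolved")
  expect_equal(d_usage(none)$proportion, 1)
})

test_that("configured D sampling weights are recovered from emitted repertoires", {
  # productivity acceptance depends on the gene (stop-codon content and
  # length differ), so the weight is identified as a ratio against a
  # uniform-weight run at matched settings, where acceptance cancels
  w <- c("D1-1" = 0.8, "D2-2" = 0.2)
  d_prop <- function(seed, weights) {
    sim <- simulate_repertoire(sim_config(
      seed = seed, clone_sizes = rep(1L, 4000), d_weights = weights
    ))
    d <- sim$truth$d_gene
    prop.table(table(d[!is.na(d)]))
  }
  base <- d_prop(71, NULL)
  sel <- d_prop(72, w)
  ratio <- sel[names(w)] / base[names(w)] * 0.5  # baseline samples at 1/2
  w_hat <- ratio / sum(ratio)
  for (gene in names(w)) {
    expect_lt(abs(w_hat[[gene]] - w[[gene]]), 0.03)
  }
})
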