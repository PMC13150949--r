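# Shared fixtures and independent oracles for the test suite.

# Toy rearrangement table built directly in code.
toy_table <- function() {
  tibble::tibble(
    sequence_id = c("s1", "s2", "s3"),
    junction = c("TGTACTACTATTCGGTACTGG", "TGTACTACTATTCGGTACTGG",
                 "TGTGCGAGACTTGCTGATTACTACTGG"),
    junction_aa = c("CTTIRYW", "CTTIRYW", "CARLADYYW"),
    v_call = c("VH14-4", "VH14-1", "VH1-9"),
    d_call = c("D1-1", "D1-1", "D2-2"),
    j_call = c("JH2", "JH2", "JH4"),
    c_call = c("IgG2b", "IgG2b", "IgG2c"),
    productive = TRUE,
    population = "PC_SPL",
    genotype = "KO"
  )
}

# Stratification over explicit clone sizes (loop keys invented).
make_strat <- function(sizes, he_threshold = 0.01) {
  loops <- sprintf("L%03d", seq_along(sizes))
  tbl <- tibble::tibble(
    sequence_id = sprintf("s%05d", seq_len(sum(sizes))),
    junction_aa = paste0("CAR", rep(loops, sizes), "W")
  )
  classify_expansion(group_clones(tbl), he_threshold = he_threshold)
}

# Independent Henderson-Hasselbalch oracle, written as protonation
# fractions (alternative algebraic form to the implementation).
oracle_charge <- function(peptide, pH = 7, include_termini = TRUE) {
  pka <- c(nTer = 9.69, cTer = 2.34, C = 8.33, D = 3.65, E = 4.25,
           H = 6.00, K = 10.53, R = 12.48, Y = 10.07)
  res <- strsplit(peptide, "")[[1]]
  frac_protonated <- function(pk) 10^(pk - pH) / (1 + 10^(pk - pH))
  q <- 0
  for (r in res) {
    if (r %in% c("R", "K", "H")) q <- q + frac_protonated(pka[[r]])
    if (r %in% c("D", "E", "C", "Y")) q <- q - (1 - frac_protonated(pka[[r]]))
  }
  if (include_termini) {
    q <- q + frac_protonated(pka[["nTer"]]) - (1 - frac_protonated(pka[["cTer"]]))
  }
  q
}

# Brute-force Mann-Whitney oracle: null distribution of U by enumerating
# every assignment of pooled values to the first group.
oracle_mwu_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Exact construction distribution of the D reading frame in the simulator,
# by enumeration over (D gene, trims, N lengths) with stop-codon
# probabilities computed per codon (N bases uniform over ACGT).
oracle_rf_construction <- function(germ, trim_p, lambda, n_add_max,
                                   rf_weights = c(I = 1, II = 1, III = 1),
                                   anchors = rf_anchor_map()) {
  stopifnot(nrow(germ$v) == 1L, nrow(germ$j) == 1L)
  v_tail <- substr(germ$v$sequence_nt, nchar(germ$v$sequence_nt) - 8L,
                   nchar(germ$v$sequence_nt))
  j_seq <- germ$j$sequence_nt
  stops <- c("TAA", "TAG", "TGA")
  p_no_stop <- function(chars) {
    # chars: fixed base or NA for a random N position; codons disjoint
    p <- 1
    for (k in seq(1L, length(chars), 3L)) {
      cod <- chars[k:(k + 2L)]
      p_stop <- sum(vapply(stops, function(s) {
        sv <- strsplit(s, "")[[1]]
        prod(ifelse(is.na(cod), 0.25, ifelse(cod == sv, 1, 0)))
      }, numeric(1)))
      p <- p * (1 - p_stop)
    }
    p
  }
  tg <- function(max, p) {
    if (max <= 0L) return(1)
    pr <- stats::dgeom(0:max, p)
    pr / sum(pr)
  }
  tp <- function(max, lambda) {
    if (max <= 0L) return(1)
    pr <- stats::dpois(0:max, lambda)
    pr / sum(pr)
  }
  v_chars <- strsplit(v_tail, "")[[1]]
  w_max <- max(rf_weights)
  acc <- c(I = 0, II = 0, III = 0)
  p_nd <- 0  # accepted but without a D remnant
  for (di in seq_len(nrow(germ$d))) {
    d_seq <- germ$d$sequence_nt[di]
    d_name <- germ$d$name[di]
    d_len <- nchar(d_seq)
    p_d <- 1 / nrow(germ$d)
    p_t5 <- tg(d_len, trim_p$d5)
    p_n <- tp(n_add_max, lambda)
    p_j5 <- tg(nchar(j_seq) - 3L, trim_p$j5)
    for (t5 in 0:d_len) {
      p_t3 <- tg(d_len - t5, trim_p$d3)
      for (t3 in 0:(d_len - t5)) {
        d_rem <- d_len - t5 - t3
        d_part <- if (d_rem > 0) strsplit(substr(d_seq, t5 + 1, t5 + d_rem),
                                          "")[[1]] else character(0)
        for (n1 in 0:n_add_max) {
          for (n2 in 0:n_add_max) {
            for (j5 in 0:(nchar(j_seq) - 3L)) {
              chars <- c(v_chars, rep(NA_character_, n1), d_part,
                         rep(NA_character_, n2),
                         strsplit(substr(j_seq, j5 + 1, nchar(j_seq)), "")[[1]])
              if (length(chars) %% 3L != 0L) next
              w <- p_d * p_t5[t5 + 1] * p_t3[t3 + 1] * p_n[n1 + 1] *
                p_n[n2 + 1] * p_j5[j5 + 1] * p_no_stop(chars)
              if (d_rem > 0) {
                offset <- (t5 - (9L + n1)) %% 3L
                lab <- hcdr3:::.lookup_rf(d_name, offset, anchors)
                acc[lab] <- acc[lab] + w * rf_weights[[lab]] / w_max
              } else {
                p_nd <- p_nd + w
              }
            }
          }
        }
      }
    }
  }
  list(rf = acc / sum(acc), no_d = p_nd / (sum(acc) + p_nd))
}

# Reduced single-V single-J germline set for enumeration tests.
reduced_germline <- function() {
  g <- sim_germline()
  list(
    v = g$v[g$v$name == "VH14-4", ],
    d = g$d[g$d$name == "D2-2", ],
    j = g$j[g$j$name == "JH2", ]
  )
}

# WT/KO scenario computed once per test run.
.scenario_cache <- new.env(parent = emptyenv())
get_scenario <- function() {
  if (is.null(.scenario_cache$sc)) {
    .scenario_cache$sc <- scenario_wt_vs_ko(
      seed = 7001, n_sequences = 2500, n_clones = 400
    )
  }
  .scenario_cache$sc
}

rect_overlap_area <- function(a, b) {
  dx <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
  dy <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
  dx * dy
}

# largest pairwise intersection area over all tile pairs (vectorised)
max_pairwise_overlap <- function(layout) {
  if (nrow(layout) < 2) return(0)
  x1 <- layout$x; x2 <- layout$x + layout$w
  y1 <- layout$y; y2 <- layout$y + layout$h
  dx <- pmax(outer(x2, x2, pmin) - outer(x1, x1, pmax), 0)
  dy <- pmax(outer(y2, y2, pmin) - outer(y1, y1, pmax), 0)
  ov <- dx * dy
  diag(ov) <- 0
  max(ov)
}

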