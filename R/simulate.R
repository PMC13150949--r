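.NT <- c("A", "C", "G", "T")

# codon -> one-letter aa (stop = "*"), built once from the standard code
.translate_nt <- function(s) {
  gc <- Biostrings::GENETIC_CODE
  vapply(s, function(x) {
    codons <- substring(x, seq(1L, nchar(x), 3L), seq(3L, nchar(x), 3L))
    paste(gc[codons], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# geometric / Poisson draws truncated to 0..max and renormalised
.rtrunc_geom <- function(n, p, max) {
  if (max <= 0L) return(rep(0L, n))
  probs <- stats::dgeom(0:max, p)
  sample(0:max, n, replace = TRUE, prob = probs)
}

.rtrunc_pois <- function(n, lambda, max) {
  if (max <= 0L) return(rep(0L, n))
  probs <- stats::dpois(0:max, lambda)
  sample(0:max, n, replace = TRUE, prob = probs)
}

#' Bundled germline segment sets for simulation and tests
#'
#' Mouse D segments (D1-1, D2-2; transcribed germline sequences whose three
#' translation frames match the tyrosine / valine / arginine-stop pattern of
#' the reading-frame nomenclature) plus synthetic V tails and J heads
#' constructed for this package (labelled synthetic; the V tail contributes
#' the junction's first three residues, C-x-x, and the J head its final
#' Trp codon).
#'
#' @return A list of three tibbles `v`, `d`, `j` as returned by
#'   [read_germline_fasta()].
#' @export
sim_germline <- function() {
  ext <- function(f) system.file("extdata", f, package = "hcdr3")
  list(
    v = read_germline_fasta(ext("germline_v_synthetic.fasta"), "V"),
    d = read_germline_fasta(ext("germline_d_mouse.fasta"), "D"),
    j = read_germline_fasta(ext("germline_j_synthetic.fasta"), "J")
  )
}

#' Simulator configuration
#'
#' Assembles and validates the parameter set of the VDJ-repertoire
#' simulator. Defaults describe an unselected ("KO-like") repertoire;
#' [scenario_wt_vs_ko()] builds the selected counterpart.
#'
#' @param seed Mandatory integer seed; all randomness flows from it.
#' @param n_sequences Target number of sequences per population.
#' @param n_clones Number of founder clones per population (ignored when
#'   `clone_sizes` is given).
#' @param clone_sizes Optional explicit integer clone sizes (overrides the
#'   Zipf law).
#' @param zipf_exponent Exponent `s` of the rank-frequency clone-size law
#'   `size_r` proportional to `r^-s`.
#' @param populations Population labels to emit (one independent
#'   repertoire each).
#' @param n_shared_clones Number of leading founder clones reused in every
#'   population (for shared-clone recovery tests).
#' @param genotype Genotype label stored on every record.
#' @param v_weights,d_weights,j_weights Optional named sampling weights
#'   over the germline segment names (uniform when `NULL`).
#' @param rf_weights Acceptance weight per reading-frame label
#'   (named `I`, `II`, `III`, each in (0, 1] after normalisation by the
#'   maximum); records without a D remnant are accepted with weight 1.
#' @param short_loop_penalty Acceptance multiplier in (0, 1] applied to
#'   loops shorter than `short_loop_cutoff` residues.
#' @param short_loop_cutoff Loop length (aa) below which the penalty
#'   applies (default 8).
#' @param charge_coef Non-negative coefficient of the charge acceptance
#'   factor `min(1, exp(-charge_coef * net_charge))` (0 disables it).
#' @param trim_p Named list of geometric trimming parameters `d5`, `d3`,
#'   `j5` (probability parameter of the truncated geometric draw).
#' @param n_add_lambda Poisson mean of the N-addition length per joint.
#' @param n_add_max Cap on N-addition length.
#' @param shm_rate Per-site substitution probability applied within
#'   expanded clones.
#' @param preserve_clone_key Restrict hypermutation to the V region outside
#'   the junction so a clone's loop amino-acid sequence is never altered
#'   (default `TRUE`); with `FALSE` junction sites mutate too.
#' @param isotype_probs Named list: per population, a named probability
#'   vector over isotype labels (`NULL` entries emit no `c_call`).
#' @param germline List of `v`, `d`, `j` segment tibbles
#'   (default [sim_germline()]).
#' @param max_retries Attempt bound for the productivity/selection
#'   rejection loop, per founder.
#' @return A validated list of class `hcdr3_sim_config`.
#' @export
sim_config <- function(seed,
                       n_sequences = 3000,
                       n_clones = 300,
                       clone_sizes = NULL,
                       zipf_exponent = 1.5,
                       populations = "PC_SPL",
                       n_shared_clones = 0,
                       genotype = "KO",
                       v_weights = NULL, d_weights = NULL, j_weights = NULL,
                       rf_weights = c(I = 1, II = 1, III = 1),
                       short_loop_penalty = 1,
                       short_loop_cutoff = 8,
                       charge_coef = 0,
                       trim_p = list(d5 = 0.35, d3 = 0.35, j5 = 0.35),
                       n_add_lambda = 2.5,
                       n_add_max = 10,
                       shm_rate = 0.005,
                       preserve_clone_key = TRUE,
                       isotype_probs = list(
                         PC_SPL = c(IgG2b = 0.52, IgG2c = 0.38,
                                    IgG3 = 0.08, IgG1 = 0.02),
                         PC_BM = c(IgG2c = 0.59, IgG2b = 0.30,
                                   IgG1 = 0.06, IgG3 = 0.05)
                       ),
                       germline = sim_germline(),
                       max_retries = 500) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("seed is mandatory", call. = FALSE)
  }
  if (any(rf_weights < 0) || all(rf_weights == 0)) {
    stop("rf_weights must be non-negative with at least one positive",
         call. = FALSE)
  }
  if (!setequal(names(rf_weights), c("I", "II", "III"))) {
    stop("rf_weights must be named I, II, III", call. = FALSE)
  }
  stopifnot(
    short_loop_penalty > 0, short_loop_penalty <= 1,
    charge_coef >= 0, shm_rate >= 0, shm_rate <= 1,
    n_add_lambda >= 0, n_add_max >= 0, max_retries >= 1
  )
  for (w in list(v_weights, d_weights, j_weights)) {
    if (!is.null(w) && (any(w < 0) || all(w == 0))) {
      stop("segment weights must be non-negative with at least one positive",
           call. = FALSE)
    }
  }
  if (!is.null(clone_sizes)) {
    stopifnot(all(clone_sizes >= 1))
    clone_sizes <- as.integer(clone_sizes)
  }
  structure(
    list(
      seed = as.integer(seed), n_sequences = n_sequences,
      n_clones = n_clones, clone_sizes = clone_sizes,
      zipf_exponent = zipf_exponent, populations = populations,
      n_shared_clones = n_shared_clones, genotype = genotype,
      v_weights = v_weights, d_weights = d_weights, j_weights = j_weights,
      rf_weights = rf_weights, short_loop_penalty = short_loop_penalty,
      short_loop_cutoff = short_loop_cutoff, charge_coef = charge_coef,
      trim_p = trim_p, n_add_lambda = n_add_lambda, n_add_max = n_add_max,
      shm_rate = shm_rate, preserve_clone_key = preserve_clone_key,
      isotype_probs = isotype_probs, germline = germline,
      max_retries = max_retries
    ),
    class = "hcdr3_sim_config"
  )
}

# clone sizes from the configured law, summing to roughly n_sequences
.clone_sizes <- function(config) {
  if (!is.null(config$clone_sizes)) return(config$clone_sizes)
  r <- seq_len(config$n_clones)
  w <- r^(-config$zipf_exponent)
  pmax(1L, as.integer(round(config$n_sequences * w / sum(w))))
}

.pick <- function(tbl, weights) {
  if (is.null(weights)) {
    sample(nrow(tbl), 1L)
  } else {
    w <- weights[tbl$name]
    if (anyNA(w)) stop("weights must cover all segment names", call. = FALSE)
    sample(nrow(tbl), 1L, prob = w)
  }
}

# one productive, selection-accepted founder junction
.sample_founder <- function(config, anchors) {
  g <- config$germline
  w_max <- max(config$rf_weights)
  for (attempt in seq_len(config$max_retries)) {
    vi <- .pick(g$v, config$v_weights)
    di <- .pick(g$d, config$d_weights)
    ji <- .pick(g$j, config$j_weights)
    v_seq <- g$v$sequence_nt[vi]
    d_seq <- g$d$sequence_nt[di]
    j_seq <- g$j$sequence_nt[ji]
    v_tail <- substr(v_seq, nchar(v_seq) - 8L, nchar(v_seq))
    d_len <- nchar(d_seq)
    t5 <- .rtrunc_geom(1L, config$trim_p$d5, d_len)
    t3 <- .rtrunc_geom(1L, config$trim_p$d3, d_len - t5)
    d_rem <- d_len - t5 - t3
    n1 <- .rtrunc_pois(1L, config$n_add_lambda, config$n_add_max)
    n2 <- .rtrunc_pois(1L, config$n_add_lambda, config$n_add_max)
    n1_seq <- paste(sample(.NT, n1, replace = TRUE), collapse = "")
    n2_seq <- paste(sample(.NT, n2, replace = TRUE), collapse = "")
    j5 <- .rtrunc_geom(1L, config$trim_p$j5, nchar(j_seq) - 3L)
    d_part <- if (d_rem > 0L) substr(d_seq, t5 + 1L, t5 + d_rem) else ""
    junction <- paste0(v_tail, n1_seq, d_part, n2_seq,
                       substr(j_seq, j5 + 1L, nchar(j_seq)))
    if (nchar(junction) %% 3L != 0L) next
    aa <- .translate_nt(junction)
    if (grepl("*", aa, fixed = TRUE)) next
    loop <- substr(aa, 4L, nchar(aa) - 1L)
    if (d_rem > 0L) {
      d_junction_start <- 9L + n1
      d_germline_start <- t5
      offset <- as.integer((d_germline_start - d_junction_start) %% 3L)
      rf <- .lookup_rf(g$d$name[di], offset, anchors)
    } else {
      d_junction_start <- NA_integer_
      d_germline_start <- NA_integer_
      offset <- NA_integer_
      rf <- NA_character_
    }
    # selection: rejection with acceptance probability w / max weight
    w <- if (is.na(rf)) w_max else config$rf_weights[[rf]]
    if (nchar(loop) < config$short_loop_cutoff) {
      w <- w * config$short_loop_penalty
    }
    if (config$charge_coef > 0 && nchar(loop) > 0L) {
      w <- w * min(1, exp(-config$charge_coef * net_charge(loop)))
    }
    if (stats::runif(1L) >= w / w_max) next
    return(list(
      v_call = g$v$name[vi],
      d_call = if (d_rem > 0L) g$d$name[di] else NA_character_,
      j_call = g$j$name[ji],
      v_seq = v_seq,
      junction = junction, junction_aa = aa, loop_aa = loop,
      d_junction_start = d_junction_start,
      d_germline_start = d_germline_start,
      d_length = if (d_rem > 0L) as.integer(d_rem) else NA_integer_,
      frame_offset = offset, rf_label = rf
    ))
  }
  stop("no productive junction accepted after ", config$max_retries,
       " attempts; check the configuration", call. = FALSE)
}

.mutate_sites <- function(seq, sites) {
  if (length(sites) == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (pos in sites) {
    chars[pos] <- sample(setdiff(.NT, chars[pos]), 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate an annotated heavy-chain repertoire with ground truth
#'
#' Generates, per population: founder junctions by V(D)J sampling with
#' exonuclease trimming (truncated geometric per end), N-additions
#' (truncated Poisson length, uniform bases), productivity by rejection
#' (in-frame, no stop; the conserved Cys/Trp bounds hold by construction),
#' and reading-frame / loop-shape selection by rejection with the
#' configured acceptance weights. Founders are expanded to the configured
#' clone sizes with somatic point mutations, and isotypes are drawn from
#' the per-compartment probabilities.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `table` (rearrangement tibble, internal
#'   coordinates), `truth` (per-sequence tibble: `sequence_id`,
#'   `population`, `clone_id`, `clone_size`, `category`, `d_gene`,
#'   `frame_offset`, `rf_label`, `v_mutation_count`, `productive`,
#'   `loop_aa`) and `config`.
#' @export
simulate_repertoire <- function(config) {
  stopifnot(inherits(config, "hcdr3_sim_config"))
  set.seed(config$seed)
  anchors <- rf_anchor_map()
  sizes <- .clone_sizes(config)
  total <- sum(sizes)
  he_min <- min_he_clone_size(total)
  categories <- ifelse(sizes == 1L, "single",
                       ifelse(sizes >= he_min, "highly_expanded",
                              "expanded_lt1"))
  pop_tables <- list()
  pop_truths <- list()
  shared_founders <- NULL
  for (pop in config$populations) {
    founders <- vector("list", length(sizes))
    for (i in seq_along(sizes)) {
      if (!is.null(shared_founders) && i <= config$n_shared_clones) {
        founders[[i]] <- shared_founders[[i]]
      } else {
        founders[[i]] <- .sample_founder(config, anchors)
      }
    }
    if (is.null(shared_founders) && config$n_shared_clones > 0) {
      shared_founders <- founders
    }
    iso_p <- config$isotype_probs[[pop]]
    n_pop <- sum(sizes)
    clone_idx <- rep(seq_along(sizes), sizes)
    member_idx <- unlist(lapply(sizes, seq_len))
    junction <- vapply(founders, `[[`, character(1), "junction")[clone_idx]
    junction_aa <- vapply(founders, `[[`, character(1), "junction_aa")[clone_idx]
    v_seq <- vapply(founders, `[[`, character(1), "v_seq")[clone_idx]
    v_germ <- v_seq
    n_mut <- integer(n_pop)
    productive <- rep(TRUE, n_pop)
    mutate_rows <- which(sizes[clone_idx] > 1L & config$shm_rate > 0)
    for (r in mutate_rows) {
      v_body_len <- nchar(v_seq[r]) - 9L
      sites <- which(stats::runif(v_body_len) < config$shm_rate)
      v_seq[r] <- .mutate_sites(v_seq[r], sites)
      n_mut[r] <- length(sites)
      if (!config$preserve_clone_key) {
        jsites <- which(stats::runif(nchar(junction[r])) < config$shm_rate)
        if (length(jsites) > 0L) {
          junction[r] <- .mutate_sites(junction[r], jsites)
          junction_aa[r] <- .translate_nt(junction[r])
          n_mut[r] <- n_mut[r] + length(jsites)
          productive[r] <- !grepl("*", junction_aa[r], fixed = TRUE) &&
            substr(junction_aa[r], 1L, 1L) == "C" &&
            substr(junction_aa[r], nchar(junction_aa[r]),
                   nchar(junction_aa[r])) %in% c("W", "F")
        }
      }
    }
    c_call <- if (!is.null(iso_p)) {
      sample(names(iso_p), n_pop, replace = TRUE, prob = iso_p)
    } else {
      rep(NA_character_, n_pop)
    }
    sid <- sprintf("%s_c%04d_s%05d", pop, clone_idx, member_idx)
    d_call <- vapply(founders, `[[`, character(1), "d_call")[clone_idx]
    pop_tables[[pop]] <- tibble::tibble(
      sequence_id = sid, population = pop, genotype = config$genotype,
      junction = junction, junction_aa = junction_aa,
      v_call = vapply(founders, `[[`, character(1), "v_call")[clone_idx],
      d_call = d_call,
      j_call = vapply(founders, `[[`, character(1), "j_call")[clone_idx],
      c_call = c_call, productive = productive,
      d_junction_start = vapply(founders, `[[`, integer(1),
                                "d_junction_start")[clone_idx],
      d_germline_start = vapply(founders, `[[`, integer(1),
                                "d_germline_start")[clone_idx],
      d_length = vapply(founders, `[[`, integer(1), "d_length")[clone_idx],
      v_sequence_alignment = v_seq,
      v_germline_alignment = v_germ
    )
    pop_truths[[pop]] <- tibble::tibble(
      sequence_id = sid, population = pop,
      clone_id = sprintf("%s_c%04d", pop, clone_idx),
      clone_size = sizes[clone_idx], category = categories[clone_idx],
      d_gene = ifelse(is.na(d_call), NA_character_, normalize_d_gene(d_call)),
      frame_offset = vapply(founders, `[[`, integer(1),
                            "frame_offset")[clone_idx],
      rf_label = vapply(founders, function(f) {
        if (is.na(f$rf_label)) NA_character_ else f$rf_label
      }, character(1))[clone_idx],
      v_mutation_count = n_mut, productive = productive,
      loop_aa = substr(junction_aa, 4L, nchar(junction_aa) - 1L)
    )
  }
  list(
    table = purrr::list_rbind(unname(pop_tables)),
    truth = purrr::list_rbind(unname(pop_truths)),
    config = config
  )
}

#' Paired selected / unselected repertoire scenario
#'
#' Builds two repertoires at matched size: a "WT-like" arm with reading-
#' frame selection favouring RFI plus mild short-loop and positive-charge
#' counter-selection, and a "KO-like" arm with no selection. The arms
#' share all other parameters, so differences reflect selection only.
#'
#' @param seed Integer seed (the KO arm uses `seed + 1`).
#' @param n_sequences Sequences per arm.
#' @param n_clones Founder clones per arm.
#' @param rf_weights_wt WT acceptance weights (default favouring RFI).
#' @param ... Further arguments passed to both [sim_config()] calls.
#' @return A list with elements `wt` and `ko`, each a
#'   [simulate_repertoire()] result; tables carry `genotype` labels
#'   `"WT"` / `"KO"`.
#' @export
scenario_wt_vs_ko <- function(seed, n_sequences = 3000, n_clones = 300,
                              rf_weights_wt = c(I = 1, II = 0.35, III = 0.25),
                              ...) {
  wt_cfg <- sim_config(
    seed = seed, n_sequences = n_sequences, n_clones = n_clones,
    genotype = "WT", rf_weights = rf_weights_wt,
    short_loop_penalty = 0.3, charge_coef = 0.15, ...
  )
  ko_cfg <- sim_config(
    seed = seed + 1L, n_sequences = n_sequences, n_clones = n_clones,
    genotype = "KO", ...
  )
  list(wt = simulate_repertoire(wt_cfg), ko = simulate_repertoire(ko_cfg))
}
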