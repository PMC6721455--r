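#' Scenario configuration for the synthetic-data generator
#'
#' Bundles the study conditions the generator emulates: cohort size and
#' replication, the multiplicative (lognormal) replicate noise of the
#' luminescence ratio, per-seed-type mean repression (ordered so that more
#' extensive seed pairing represses more), the typical R0 ranges of
#' positive controls (0.1-0.2) and targets (0.5-0.95), the planted
#' correlation between R1 and log expression, and sequence geometry.
#'
#' @param rng_seed Integer seed; every downstream number is reproducible
#'   from it.
#' @param n_targets Constructs per miRNA (default 196).
#' @param replicates Biological replicates per condition (default 3).
#' @param noise_cv Relative (lognormal sigma) replicate noise of R0
#'   (default 0.10).
#' @param seed_type_effects Named mean true R0 per seed type; must be
#'   non-decreasing along 8mer, 7mer-m8, 7mer-A1, 6mer, else.
#' @param positive_control_r0_range,target_r0_range True-R0 ranges.
#' @param non_target_frac Fraction of planted non-targets (true R0 = 1),
#'   default 0.2, mirroring the observed ~72-85% confirmation band.
#' @param expression_corr Planted Pearson r between R1 and log abundance.
#' @param utr_len,fragment_len UTR and insert lengths in nt.
#' @param batch_size Constructs per experimental batch (each batch carries
#'   its own positive-control reporter), default 20.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(rng_seed,
                            n_targets = 196L,
                            replicates = 3L,
                            noise_cv = 0.10,
                            seed_type_effects = c("8mer" = 0.55, "7mer-m8" = 0.65,
                                                  "7mer-A1" = 0.75, "6mer" = 0.85,
                                                  "else" = 1.0),
                            positive_control_r0_range = c(0.1, 0.2),
                            target_r0_range = c(0.5, 0.95),
                            non_target_frac = 0.2,
                            expression_corr = 0.3,
                            utr_len = 2000L,
                            fragment_len = 500L,
                            batch_size = 20L,
                            seed_type_mix = c("8mer" = 0.25, "7mer-m8" = 0.30,
                                              "7mer-A1" = 0.20, "6mer" = 0.15,
                                              "else" = 0.10)) {
  stopifnot(is.numeric(rng_seed), length(rng_seed) == 1L,
            replicates >= 3L, noise_cv >= 0,
            all(diff(seed_type_effects[.SEED_TYPES]) >= 0),
            all(positive_control_r0_range > 0), all(target_r0_range > 0),
            all(positive_control_r0_range <= 1), all(target_r0_range <= 1),
            abs(expression_corr) < 1)
  structure(as.list(environment()), class = "scenario_config")
}

#' Generate a random miRNA
#'
#' Draws a uniform random 22-nt RNA and wraps it as a [mirna_spec()].
#' Reproducible from the R RNG state (use `set.seed()` or
#' [simulate_scenario()] for end-to-end determinism).
#'
#' @param name miRNA identifier.
#' @param length Sequence length (default 22).
#' @return A `mirna_spec`.
#' @export
gen_mirna <- function(name = "synth-miR", length = 22L) {
  mirna_spec(name, paste(sample(c("A", "C", "G", "U"), length, replace = TRUE),
                         collapse = ""))
}

# the exact string to implant for a given seed type, plus guard bases
.site_payload <- function(mirna, type) {
  ss <- .site_strings(mirna)
  switch(type,
    "8mer" = paste0(ss$m8, "A"),
    "7mer-m8" = ss$m8,
    "7mer-A1" = paste0(ss$core, "A"),
    "6mer" = ss$core,
    stop("cannot plant seed type '", type, "'", call. = FALSE))
}

#' Generate a UTR with planted seed sites
#'
#' Builds a random-background UTR and implants the requested site strings
#' at non-overlapping positions; the background is patched so it contains
#' no accidental 2-7 core match of the miRNA outside the planted sites
#' (and planted 7mer-m8/7mer-A1/6mer sites are guarded against accidental
#' upgrade by their flanking bases). Round-trip property: the scanner
#' recovers exactly the planted sites.
#'
#' @param mirna A `mirna_spec`.
#' @param seed_types Character vector of site types to plant (may be
#'   empty; `"else"` entries plant nothing).
#' @param utr_len UTR length in nt.
#' @param positions Optional 0-based site start positions (one per
#'   requested site); sampled when NULL.
#' @param utr_id Identifier for the generated UTR.
#' @return A list with `utr` (sequence) and `sites` (planted-site tibble
#'   as from [find_seed_sites()]).
#' @export
gen_utr_with_sites <- function(mirna, seed_types, utr_len = 2000L,
                               positions = NULL, utr_id = "utr") {
  plant <- seed_types[seed_types != "else"]
  payloads <- vapply(plant, function(t) .site_payload(mirna, t), character(1))
  lens <- nchar(payloads)
  if (is.null(positions)) {
    positions <- integer(0)
    if (length(plant)) {
      if (sum(lens + 2L) > utr_len) {
        stop("requested sites do not fit in the UTR", call. = FALSE)
      }
      for (try in 1:200) {
        cand <- sort(sample(seq_len(utr_len - max(lens) - 2L), length(plant)))
        ok <- all(cand + lens <= utr_len - 1L) &&
          (length(cand) == 1L ||
             all(diff(cand) >= utils::head(lens, -1L) + 2L))
        if (ok) { positions <- cand; break }
      }
      if (length(positions) == 0L) {
        stop("could not place sites without overlap", call. = FALSE)
      }
    }
  } else {
    positions <- as.integer(positions)
    stopifnot(length(positions) == length(plant))
    ord <- order(positions)
    positions <- positions[ord]; payloads <- payloads[ord]
    lens <- lens[ord]; plant <- plant[ord]
    if (any(positions < 1L) || any(positions + lens > utr_len - 1L)) {
      stop("planted sites must leave 1 nt of flank inside the UTR", call. = FALSE)
    }
    if (length(positions) > 1L &&
        any(positions[-1] < utils::head(positions + lens + 1L, -1L))) {
      stop("planted sites overlap", call. = FALSE)
    }
  }
  chars <- sample(c("A", "C", "G", "U"), utr_len, replace = TRUE)
  guard <- rep(FALSE, utr_len)
  ss <- .site_strings(mirna)
  m8_base <- substr(ss$m8, 1L, 1L)
  not_base <- function(avoid) sample(setdiff(c("A", "C", "G", "U"), avoid), 1L)
  for (k in seq_along(plant)) {
    p <- positions[k]  # 0-based
    chars[p + seq_len(lens[k])] <- strsplit(payloads[k], "", fixed = TRUE)[[1]]
    # guard flanks: no accidental m8 extension 5', no accidental A1 (or A) 3'
    if (plant[k] %in% c("7mer-A1", "6mer") && chars[p] == m8_base) {
      chars[p] <- not_base(m8_base)
    }
    if (plant[k] %in% c("7mer-m8", "6mer") &&
        p + lens[k] + 1L <= utr_len && chars[p + lens[k] + 1L] == "A") {
      chars[p + lens[k] + 1L] <- not_base("A")
    }
    guard[(max(1L, p)):(min(utr_len, p + lens[k] + 1L))] <- TRUE
  }
  planted_cores <- positions + ifelse(plant %in% c("8mer", "7mer-m8"), 1L, 0L)
  for (iter in 1:100) {
    utr <- paste(chars, collapse = "")
    subject <- Biostrings::RNAString(utr)
    cores <- BiocGenerics::start(
      Biostrings::matchPattern(ss$core, subject)) - 1L
    stray <- setdiff(cores, planted_cores)
    if (length(stray) == 0L) break
    for (j in stray) {
      free <- (j + 1L):(j + 6L)
      free <- free[!guard[free]]
      if (length(free) == 0L) {
        stop("cannot patch background without touching a planted site",
             call. = FALSE)
      }
      p <- free[sample.int(length(free), 1L)]
      chars[p] <- not_base(chars[p])
    }
  }
  sites <- find_seed_sites(utr, mirna, utr_id = utr_id)
  if (!identical(sort(sites$start), sort(as.integer(positions))) ||
      !identical(sites$seed_type[order(sites$start)],
                 unname(plant[order(positions)]))) {
    stop("planted-site round trip failed (degenerate seed?)", call. = FALSE)
  }
  list(utr = utr, sites = sites)
}

#' Simulate a dual-luciferase assay table
#'
#' Generates replicate firefly/Renilla readings for a cohort of
#' constructs with known true R0. Each batch of constructs carries its
#' own positive-control reporter with true R0 uniform in the
#' positive-control range. Per replicate, the realized R0 equals
#' trueR0 * lognormal(0, noise_cv): Renilla readings are drawn lognormally
#' around a batch mean, firefly readings follow from each construct's
#' baseline expression, and all measurement noise is carried by the ratio.
#'
#' @param constructs A data frame with `construct_id` and `true_r0`
#'   (e.g. from [assign_true_r0()]).
#' @param config A [scenario_config()].
#' @return A list with `measurements` (construct_id, condition, replicate,
#'   firefly, renilla) and `batches` (construct_id, batch,
#'   positive_control_id).
#' @export
gen_assay <- function(constructs, config) {
  stopifnot(all(c("construct_id", "true_r0") %in% names(constructs)))
  n <- nrow(constructs)
  batch <- rep(seq_len(ceiling(n / config$batch_size)),
               each = config$batch_size)[seq_len(n)]
  nb <- max(batch)
  pos_ids <- sprintf("posctrl_b%02d", seq_len(nb))
  pos_r0 <- runif(nb, config$positive_control_r0_range[1],
                  config$positive_control_r0_range[2])
  all_ids <- c(constructs$construct_id, pos_ids)
  all_r0 <- c(constructs$true_r0, pos_r0)
  all_batch <- c(batch, seq_len(nb))
  reps <- config$replicates
  rows <- lapply(seq_along(all_ids), function(k) {
    strength <- stats::rlnorm(1, log(1000), 0.3)
    ren <- matrix(stats::rlnorm(2 * reps, log(1e5), 0.2), nrow = 2)
    r0_rep <- all_r0[k] * stats::rlnorm(reps, 0, config$noise_cv)
    tibble::tibble(
      construct_id = all_ids[k],
      condition = rep(c("control", "mir"), each = reps),
      replicate = rep(seq_len(reps), 2L),
      firefly = c(strength * ren[1, ], strength * ren[2, ] * r0_rep),
      renilla = c(ren[1, ], ren[2, ]))
  })
  list(measurements = do.call(rbind, rows),
       batches = tibble::tibble(construct_id = all_ids, batch = all_batch,
                                positive_control_id = pos_ids[all_batch],
                                is_positive_control = all_ids %in% pos_ids,
                                true_r0 = all_r0))
}

#' Assign true repression levels to a construct cohort
#'
#' Targets draw their true R0 from the seed-type effect (clipped to the
#' target R0 range); a `non_target_frac` fraction of the cohort is
#' planted as non-targets with true R0 = 1.
#'
#' @param seed_types Character vector of per-construct seed types.
#' @param config A [scenario_config()].
#' @param effect_sd Between-construct spread of true R0 around the
#'   seed-type mean (default 0.08).
#' @return A tibble with `construct_id`, `seed_type`, `is_target`,
#'   `true_r0`.
#' @export
assign_true_r0 <- function(seed_types, config, effect_sd = 0.08) {
  n <- length(seed_types)
  is_target <- runif(n) >= config$non_target_frac
  mu <- config$seed_type_effects[seed_types] + rnorm(n, 0, effect_sd)
  r0 <- pmin(pmax(mu, config$target_r0_range[1]), config$target_r0_range[2])
  r0[!is_target | seed_types == "else"] <- 1.0
  tibble::tibble(construct_id = sprintf("g%04d", seq_len(n)),
                 seed_type = seed_types,
                 is_target = is_target & seed_types != "else",
                 true_r0 = unname(r0))
}

#' Generate an expression table with a planted R1 correlation
#'
#' Log abundances are built by the bivariate-normal construction
#' log(abundance) = mu + sigma * (r * z + sqrt(1 - r^2) * eps), with z the
#' standardized R1 vector, so the planted Pearson correlation between R1
#' and log abundance equals `target_r`. A fraction of genes is set below
#' the detection threshold to exercise filtering.
#'
#' @param r1_table Data frame with `gene_id`, `r1`.
#' @param target_r Planted correlation (|r| < 1).
#' @param frac_undetected Fraction of genes forced below the detection
#'   threshold (default 0.1).
#' @param mean_log,sd_log Location/scale of log abundance (defaults
#'   log(10) and 1).
#' @param min_expr Detection threshold used for the undetected genes.
#' @return A tibble (`gene_id`, `abundance`).
#' @export
gen_expression <- function(r1_table, target_r, frac_undetected = 0.1,
                           mean_log = log(10), sd_log = 1, min_expr = 0.004) {
  stopifnot(abs(target_r) < 1)
  n <- nrow(r1_table)
  z <- as.numeric(scale(r1_table$r1))
  if (any(!is.finite(z))) z <- rep(0, n)  # constant r1 degenerates to noise
  eps <- rnorm(n)
  la <- mean_log + sd_log * (target_r * z + sqrt(1 - target_r^2) * eps)
  abundance <- exp(la)
  low <- runif(n) < frac_undetected
  abundance[low] <- runif(sum(low), 0, min_expr)
  tibble::tibble(gene_id = r1_table$gene_id, abundance = abundance)
}

#' Generate a paired miRNA/control expression table set
#'
#' Control abundances are lognormal; the miRNA-transfection table couples
#' the per-gene log fold change to R1 at the planted strength, so that
#' Pearson(R1, log FC) equals `target_r` in expectation.
#'
#' @inheritParams gen_expression
#' @param sd_logfc Scale of the log fold change (default 0.5).
#' @return A list with `expr_mir` and `expr_control` tibbles.
#' @export
gen_expression_pair <- function(r1_table, target_r, frac_undetected = 0.1,
                                mean_log = log(10), sd_log = 1,
                                sd_logfc = 0.5, min_expr = 0.004) {
  stopifnot(abs(target_r) < 1)
  n <- nrow(r1_table)
  control <- exp(mean_log + sd_log * rnorm(n))
  z <- as.numeric(scale(r1_table$r1))
  if (any(!is.finite(z))) z <- rep(0, n)
  lfc <- sd_logfc * (target_r * z + sqrt(1 - target_r^2) * rnorm(n)) -
    0.2  # mild global down-shift under miRNA transfection
  mir <- control * exp(lfc)
  low <- runif(n) < frac_undetected
  mir[low] <- runif(sum(low), 0, min_expr)
  list(expr_mir = tibble::tibble(gene_id = r1_table$gene_id, abundance = mir),
       expr_control = tibble::tibble(gene_id = r1_table$gene_id,
                                     abundance = control))
}

#' Generate an R1 cohort with planted seed-type means
#'
#' Statistical fixture for the seed-type analysis: per seed type, `n`
#' Gaussian R1 values around the planted mean.
#'
#' @param means Named vector of planted mean R1 per seed type.
#' @param sd Common standard deviation (default 1).
#' @param n Observations per group (default 40).
#' @return A tibble (`construct_id`, `gene_id`, `seed_type`, `r1`,
#'   `confirmed`, `n_mres`).
#' @export
gen_r1_cohort <- function(means = c("8mer" = 3, "7mer-m8" = 4,
                                    "7mer-A1" = 5, "6mer" = 6),
                          sd = 1, n = 40L) {
  types <- rep(names(means), each = n)
  ids <- sprintf("c%04d", seq_along(types))
  tibble::tibble(construct_id = ids, gene_id = ids, seed_type = types,
                 r1 = rnorm(length(types), means[types], sd),
                 confirmed = TRUE, n_mres = 1L)
}

#' Generate prediction-program annotations for a cohort
#'
#' Random program memberships (every construct predicted by at least one
#' program), a TargetScan-like score anti-correlated with repression
#' depth plus noise, and sparse miRTarBase flags.
#'
#' @param records Data frame with `construct_id` and `true_r0` (or `r1`).
#' @return A tibble with `gene_id`, `programs`, `mirtarbase`, `n_mres`,
#'   and `score_TargetScan`/`score_miRanda`/`score_PicTar` columns.
#' @export
gen_annotations <- function(records) {
  n <- nrow(records)
  depth <- if ("true_r0" %in% names(records)) records$true_r0 else records$r1
  progs <- replicate(n, {
    k <- sample(c(1, 2, 3), 1, prob = c(0.25, 0.5, 0.25))
    paste(sort(sample(c("TargetScan", "miRanda", "PicTar"), k)), collapse = ";")
  })
  score <- function(sign = -1) sign * (1 - depth) + rnorm(n, 0, 0.3)
  tibble::tibble(
    gene_id = records$construct_id,
    programs = progs,
    mirtarbase = runif(n) < 0.05,
    n_mres = 1L + (runif(n) < 0.15),
    score_TargetScan = score(-1),
    score_miRanda = 100 * score(-1),
    score_PicTar = rnorm(n, 5, 2))
}
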