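#' Compute R0/R1 records from an assay table
#'
#' Runs [compute_r0()] and [call_target()] per construct, then normalizes
#' each target's mean R0 by its batch-matched positive control to obtain
#' R1.
#'
#' @param measurements Long assay table (construct_id, condition,
#'   replicate, firefly, renilla).
#' @param batches Batch table (construct_id, batch, positive_control_id,
#'   is_positive_control), e.g. from [gen_assay()].
#' @param alpha Significance level for the confirmation call.
#' @param paired Replicate pairing mode (see [compute_r0()]).
#' @return A tibble with one row per construct: `construct_id`,
#'   `r0_mean`, `p_value`, `confirmed`, `callable`, `r1`,
#'   `is_positive_control`.
#' @export
call_reporters <- function(measurements, batches, alpha = 0.05,
                           paired = TRUE) {
  m <- as.data.frame(measurements)
  b <- as.data.frame(batches)
  per <- split(m, m$construct_id)
  r0 <- lapply(per, compute_r0, paired = paired)
  ids <- names(per)
  calls <- lapply(r0, function(x) call_target(x$r0_replicates, alpha = alpha))
  rec <- tibble::tibble(
    construct_id = ids,
    r0_mean = vapply(r0, `[[`, numeric(1), "r0_mean"),
    p_value = vapply(calls, `[[`, numeric(1), "p_value"),
    confirmed = vapply(calls, function(x) x$confirmed, logical(1)),
    callable = vapply(calls, `[[`, logical(1), "callable"))
  rec <- merge(rec, b[c("construct_id", "positive_control_id",
                        "is_positive_control")], by = "construct_id")
  pos_r0 <- setNames(rec$r0_mean, rec$construct_id)
  rec$r1 <- vapply(seq_len(nrow(rec)), function(i) {
    compute_r1(rec$r0_mean[i], pos_r0[[rec$positive_control_id[i]]])
  }, numeric(1))
  tibble::as_tibble(rec)
}

#' Run a full synthetic reporter-screen scenario
#'
#' End-to-end pipeline on generated data: draws a miRNA, plants seed
#' sites in random UTRs, designs reporter inserts, simulates the
#' dual-luciferase assay, computes R0/R1 and confirmation calls,
#' tabulates confirmation by prediction category, and runs the seed-type,
#' score, expression and fold-change association analyses. Fully
#' deterministic given `config$rng_seed`.
#'
#' @param config A [scenario_config()].
#' @param features Also compute per-construct sequence/thermodynamic
#'   features (slower; default FALSE).
#' @return A list: `mirna`, `constructs` (manifest tibble), `sequences`
#'   (named insert sequences), `truth`, `measurements`, `batches`,
#'   `records`, `annotations`, `summary`, `seed_types`, `score_corr`,
#'   `expression`, `expr_corr`, `fold_change`, and optionally `features`.
#' @export
simulate_scenario <- function(config, features = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$rng_seed)
  mirna <- gen_mirna()
  mix <- config$seed_type_mix
  seed_types <- sample(names(mix), config$n_targets, replace = TRUE,
                       prob = mix)
  truth <- assign_true_r0(seed_types, config)

  constructs <- vector("list", config$n_targets)
  for (k in seq_len(config$n_targets)) {
    gen <- gen_utr_with_sites(
      mirna, seed_types[k], utr_len = config$utr_len,
      utr_id = truth$construct_id[k])
    if (nrow(gen$sites) > 0L) {
      con <- select_fragment(gen$utr, gen$sites,
                             target_len = config$fragment_len,
                             gene_id = truth$construct_id[k],
                             utr_id = truth$construct_id[k])
    } else {
      start <- (config$utr_len - config$fragment_len) %/% 2L
      con <- structure(list(
        gene_id = truth$construct_id[k], utr_id = truth$construct_id[k],
        fragment_start = start,
        fragment_end = start + config$fragment_len,
        fragment_seq = substr(gen$utr, start + 1L,
                              start + config$fragment_len),
        sites = gen$sites), class = "reporter_construct")
    }
    con$pass_restriction <- screen_restriction(con$fragment_seq)$pass
    constructs[[k]] <- con
  }

  assay <- gen_assay(truth, config)
  records <- call_reporters(assay$measurements, assay$batches)
  records <- merge(records,
                   rbind(truth,
                         tibble::tibble(construct_id = setdiff(
                           assay$batches$construct_id, truth$construct_id),
                           seed_type = NA, is_target = NA, true_r0 = NA)),
                   by = "construct_id")
  records <- tibble::as_tibble(records)

  annotations <- gen_annotations(truth)
  rec_t <- records[!records$is_positive_control, ]
  ann <- annotations
  names(ann)[names(ann) == "gene_id"] <- "construct_id"
  rec_ann <- merge(rec_t, ann, by = "construct_id")
  summary <- summarize_confirmation(rec_ann)

  rec_ann$gene_id <- rec_ann$construct_id
  seed_types_res <- seed_type_analysis(rec_ann)
  score_corr <- score_correlations(
    rec_ann[rec_ann$confirmed %in% TRUE, c("gene_id", "r1")], annotations)

  conf <- rec_ann[rec_ann$confirmed %in% TRUE, c("gene_id", "r1")]
  expression <- gen_expression(conf, config$expression_corr)
  expr_corr <- correlate_with_expression(conf, expression)
  pair <- gen_expression_pair(conf, config$expression_corr)
  fold_change <- fold_change_analysis(conf, pair$expr_mir, pair$expr_control)

  out <- list(mirna = mirna, constructs = construct_manifest(constructs),
              sequences = setNames(
                vapply(constructs, `[[`, character(1), "fragment_seq"),
                vapply(constructs, `[[`, character(1), "gene_id")),
              construct_objects = constructs,
              truth = truth, measurements = assay$measurements,
              batches = assay$batches, records = records,
              annotations = annotations, summary = summary,
              seed_types = seed_types_res, score_corr = score_corr,
              expression = expression, expr_corr = expr_corr,
              fold_change = fold_change)
  if (features) {
    out$features <- compute_features(constructs, mirna)
  }
  out
}

# ---- command-line surface --------------------------------------------------

.cli_usage <- "usage: mirep <simulate|design|call|features|associate|summarize|run-all> [options]
global options: --seed <int> --out-dir <dir>
  simulate   --seed N --out-dir D [--n-targets N]   write a full fixture set
  design     --utrs F.fasta --mirna F.fasta --out-dir D
  call       --measurements F.tsv --batches F.tsv --out-dir D
  features   --constructs F.fasta --sites F.tsv --mirna F.fasta --out-dir D
  associate  --records F.tsv --annotations F.tsv --expression F.tsv --out-dir D
  summarize  --records F.tsv --annotations F.tsv --out-dir D
  run-all    --seed N --out-dir D [--n-targets N]"

.cli_args <- function(argv) {
  opts <- list(); i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    if (i + 1L > length(argv)) stop("missing value for ", a, call. = FALSE)
    opts[[substring(a, 3L)]] <- argv[i + 1L]
    i <- i + 2L
  }
  opts
}

.cli_need <- function(opts, keys) {
  for (k in keys) {
    if (is.null(opts[[k]])) stop("missing required option --", k, call. = FALSE)
  }
}

.cli_infile <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  path
}

.read_constructs <- function(constructs_fasta, sites_tsv) {
  seqs <- read_fasta(.cli_infile(constructs_fasta))
  sites <- read_table_tsv(.cli_infile(sites_tsv),
                          schema = c(utr_id = "character", start = "integer",
                                     end = "integer", seed_type = "character",
                                     matched_seq = "character"))
  lapply(names(seqs), function(id) {
    s <- sites[sites$utr_id == id, ]
    s$matched_seq <- substring(seqs[[id]], s$start + 1L, s$end)
    structure(list(gene_id = id, utr_id = id, fragment_start = 0L,
                   fragment_end = nchar(seqs[[id]]), fragment_seq = seqs[[id]],
                   sites = tibble::as_tibble(s)),
              class = "reporter_construct")
  })
}

.cli_log <- function(...) message("[mirep] ", ...)

#' Command-line entry point
#'
#' Thin dispatcher over the package's pipeline stages; see the shipped
#' `exec/mirep` script. Subcommands: `simulate`, `design`, `call`,
#' `features`, `associate`, `summarize`, `run-all`. Every statistical
#' threshold used is echoed to the log, and outputs carry provenance
#' headers.
#'
#' @param argv Character vector of arguments (excluding the program name).
#' @return Integer exit status (0 on success, 2 on validation failure).
#' @export
mirep_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(argv) == 0L || argv[1] %in% c("-h", "--help")) {
      cat(.cli_usage, "\n")
      return(invisible(0L))
    }
    cmd <- argv[1]
    opts <- .cli_args(argv[-1])
    out_dir <- opts[["out-dir"]] %||% "."
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    seed <- as.integer(opts[["seed"]] %||% "1")
    alpha <- as.numeric(opts[["alpha"]] %||% "0.05")
    min_expr <- as.numeric(opts[["min-expr"]] %||% "0.004")
    prov <- list(seed = seed, alpha = alpha, min_expr = min_expr,
                 command = paste(argv, collapse = " "))
    .cli_log("alpha = ", alpha, ", detection threshold = ", min_expr,
             ", seed = ", seed)
    switch(cmd,
      "simulate" = ,
      "run-all" = {
        cfg <- scenario_config(
          rng_seed = seed,
          n_targets = as.integer(opts[["n-targets"]] %||% "196"))
        res <- simulate_scenario(cfg)
        write_fasta(setNames(res$mirna$sequence, res$mirna$name),
                    file.path(out_dir, "mirna.fasta"))
        write_fasta(res$sequences, file.path(out_dir, "constructs.fasta"))
        sites <- do.call(rbind, lapply(res$construct_objects, `[[`, "sites"))
        write_table_tsv(sites, file.path(out_dir, "sites.tsv"), prov)
        write_table_tsv(res$constructs, file.path(out_dir, "manifest.tsv"), prov)
        write_table_tsv(res$measurements,
                        file.path(out_dir, "measurements.tsv"), prov)
        write_table_tsv(res$batches, file.path(out_dir, "batches.tsv"), prov)
        write_table_tsv(res$annotations,
                        file.path(out_dir, "annotations.tsv"), prov)
        write_table_tsv(res$expression,
                        file.path(out_dir, "expression.tsv"), prov)
        if (cmd == "run-all") {
          write_table_tsv(res$records, file.path(out_dir, "records.tsv"), prov)
          write_table_tsv(res$summary, file.path(out_dir, "summary.tsv"), prov)
          assoc <- rbind(res$score_corr, res$expr_corr,
                         res$fold_change$correlation)
          write_table_tsv(assoc, file.path(out_dir, "associations.tsv"), prov)
          write_table_tsv(res$seed_types$comparisons,
                          file.path(out_dir, "seed_type_tests.tsv"), prov)
        }
        .cli_log("wrote ", cmd, " outputs to ", out_dir)
      },
      "design" = {
        .cli_need(opts, c("utrs", "mirna"))
        utrs <- read_fasta(.cli_infile(opts$utrs))
        mseq <- read_fasta(.cli_infile(opts$mirna))
        mirna <- mirna_spec(names(mseq)[1], mseq[[1]])
        cons <- list()
        for (id in names(utrs)) {
          cons <- c(cons, design_constructs(utrs[[id]], mirna, gene_id = id,
                                            utr_id = id))
        }
        keep <- vapply(cons, function(x) isTRUE(x$pass_restriction), logical(1))
        write_fasta(setNames(
          vapply(cons[keep], `[[`, character(1), "fragment_seq"),
          vapply(cons[keep], `[[`, character(1), "gene_id")),
          file.path(out_dir, "constructs.fasta"))
        write_table_tsv(construct_manifest(cons),
                        file.path(out_dir, "manifest.tsv"), prov)
        sites <- do.call(rbind, lapply(cons[keep], function(x) {
          s <- x$sites; s$utr_id <- x$gene_id; s
        }))
        write_table_tsv(sites, file.path(out_dir, "sites.tsv"), prov)
        .cli_log(sum(keep), "/", length(cons), " constructs pass restriction screen")
      },
      "call" = {
        .cli_need(opts, c("measurements", "batches"))
        m <- read_table_tsv(.cli_infile(opts$measurements),
                            schema = c(construct_id = "character",
                                       condition = "character",
                                       replicate = "integer",
                                       firefly = "double", renilla = "double"))
        b <- read_table_tsv(.cli_infile(opts$batches))
        rec <- call_reporters(m, b, alpha = alpha)
        write_table_tsv(rec, file.path(out_dir, "records.tsv"), prov)
        .cli_log(sum(rec$confirmed %in% TRUE), "/", nrow(rec), " confirmed")
      },
      "features" = {
        .cli_need(opts, c("constructs", "sites", "mirna"))
        cons <- .read_constructs(opts$constructs, opts$sites)
        mseq <- read_fasta(.cli_infile(opts$mirna))
        mirna <- mirna_spec(names(mseq)[1], mseq[[1]])
        feats <- compute_features(cons, mirna)
        write_table_tsv(feats, file.path(out_dir, "features.tsv"), prov)
      },
      "summarize" = {
        .cli_need(opts, c("records", "annotations"))
        rec <- read_table_tsv(.cli_infile(opts$records))
        ann <- read_table_tsv(.cli_infile(opts$annotations))
        names(ann)[names(ann) == "gene_id"] <- "construct_id"
        merged <- merge(rec, ann, by = "construct_id")
        write_table_tsv(summarize_confirmation(merged),
                        file.path(out_dir, "summary.tsv"), prov)
      },
      "associate" = {
        .cli_need(opts, c("records", "annotations"))
        rec <- read_table_tsv(.cli_infile(opts$records))
        ann <- read_table_tsv(.cli_infile(opts$annotations))
        rec$gene_id <- rec$construct_id
        merged <- merge(rec, ann, by = "gene_id")
        res <- score_correlations(
          merged[merged$confirmed %in% TRUE, c("gene_id", "r1")], ann)
        if (!is.null(opts$expression)) {
          expr <- read_table_tsv(.cli_infile(opts$expression),
                                 schema = c(gene_id = "character",
                                            abundance = "double"))
          res <- rbind(res, correlate_with_expression(
            merged[merged$confirmed %in% TRUE, c("gene_id", "r1")], expr,
            min_expr = min_expr))
        }
        write_table_tsv(res, file.path(out_dir, "associations.tsv"), prov)
        st <- seed_type_analysis(merged)
        write_table_tsv(st$comparisons,
                        file.path(out_dir, "seed_type_tests.tsv"), prov)
      },
      stop("unknown subcommand: ", cmd, call. = FALSE)
    )
    0L
  }, error = function(e) {
    message("mirep error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
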