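.stage <- function(name, input, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed for %s: %s", name, input,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full census pipeline on an input bundle directory
#'
#' Expects the layout written by [write_bundle()]: per-taxon FASTA and
#' headerless hit tables under `taxa/`, plus `tree.nwk` and
#' `life_history.tsv`.  Stages: classify candidates, coalesce loci per
#' taxon and family, build the counts table, summarise by life-history
#' group, and (when a tree is present) fit `counts ~ life_history` by PGLS
#' for each requested response.  The pipeline is deterministic: identical
#' inputs and configuration give identical outputs.
#'
#' @param input_dir bundle directory.
#' @param outdir optional; when given, per-stage TSV/JSON outputs and a
#'   `report.json` (configuration, package version, output checksums) are
#'   written there.
#' @param mode `"denovo"` (component + Ks + short-overlap rules) or
#'   `"genome"` (shared mapping locations, falling back to de novo for
#'   unmapped transcripts).
#' @param classify_cfg a [classify_config()].
#' @param coalesce_cfg a [coalesce_config()].
#' @param group_map see [summarize_groups()].
#' @param pgls_responses count columns to test against life history.
#' @return list of class `aat_run_report`: `candidates`, `locus_sets`,
#'   `pair_logs`, `counts`, `summary`, `pgls`, `config`.
#' @export
run_pipeline <- function(input_dir, outdir = NULL,
                         mode = c("denovo", "genome"),
                         classify_cfg = classify_config(),
                         coalesce_cfg = coalesce_config(),
                         group_map = c(galling = "galling",
                                       inquiline = "galling",
                                       free_living = "free_living"),
                         pgls_responses = c("apc", "aaap", "total")) {
  mode <- match.arg(mode)
  taxa_dir <- file.path(input_dir, "taxa")
  fastas <- sort(dir(taxa_dir, pattern = "_transcripts\\.fasta$",
                     full.names = TRUE))
  if (length(fastas) == 0L)
    stop("no '*_transcripts.fasta' files under ", taxa_dir, call. = FALSE)

  all_candidates <- list()
  locus_sets <- list()
  pair_logs <- list()
  for (fa in fastas) {
    tx <- sub("_transcripts\\.fasta$", "", basename(fa))
    transcripts <- .stage("read_fasta", fa,
                          read_transcript_fasta(fa, taxon = tx))
    dh <- .stage("parse_domain_hits", fa, parse_domain_hits(
      file.path(taxa_dir, paste0(tx, "_domain_hits.tsv"))))
    bh <- .stage("parse_blast_hits", fa, parse_blast_hits(
      file.path(taxa_dir, paste0(tx, "_blast_hits.tsv"))))
    cand <- .stage("select_candidates", fa,
                   select_candidates(transcripts, dh, bh, classify_cfg))
    all_candidates[[tx]] <- cand
    mh <- NULL
    if (mode == "genome") {
      mf <- file.path(taxa_dir, paste0(tx, "_mapping_hits.tsv"))
      if (!file.exists(mf))
        stop("genome mode needs a mapping table: ", mf, call. = FALSE)
      mh <- .stage("parse_mapping_hits", mf, parse_mapping_hits(mf))
    }
    for (fam in sort(unique(cand$family))) {
      sub <- cand[cand$family == fam, , drop = FALSE]
      ls <- .stage("coalesce", fa, if (mode == "genome")
        coalesce_genome_guided(sub, mh, coalesce_cfg) else
          coalesce_denovo(sub, coalesce_cfg))
      locus_sets[[length(locus_sets) + 1L]] <- ls
      if (nrow(ls$pair_log) > 0L) {
        pl <- ls$pair_log
        pl$taxon <- tx
        pl$family <- fam
        pair_logs[[length(pair_logs) + 1L]] <- pl
      }
    }
  }

  lh_file <- file.path(input_dir, "life_history.tsv")
  life_history <- .stage("read_life_history", lh_file,
                         utils::read.delim(lh_file,
                                           stringsAsFactors = FALSE))
  counts <- .stage("build_counts", input_dir,
                   build_counts(locus_sets, life_history))
  summary_tab <- .stage("summarize_groups", input_dir,
                        summarize_groups(counts, group_map))

  pgls <- NULL
  tree_file <- file.path(input_dir, "tree.nwk")
  if (file.exists(tree_file)) {
    tree <- .stage("read_newick", tree_file, read_newick(tree_file))
    keep <- intersect(tree$tip.label, counts$taxon)
    Ct <- brownian_vcv(ape::keep.tip(tree, keep), keep)
    grp <- factor(unname(group_map[counts$life_history[
      match(keep, counts$taxon)]]), levels = unique(unname(group_map)))
    pgls <- lapply(stats::setNames(pgls_responses, pgls_responses),
                   function(resp) .stage("pgls", tree_file, {
                     y <- stats::setNames(counts[[resp]][
                       match(keep, counts$taxon)], keep)
                     pgls_fit(y, grp, Ct)
                   }))
  }

  report <- list(candidates = all_candidates, locus_sets = locus_sets,
                 pair_logs = if (length(pair_logs))
                   do.call(rbind, pair_logs) else NULL,
                 counts = counts, summary = summary_tab, pgls = pgls,
                 config = list(mode = mode, classify = unclass(classify_cfg),
                               coalesce = unclass(coalesce_cfg),
                               group_map = as.list(group_map),
                               package_version = as.character(
                                 utils::packageVersion("aatcensus"))))
  class(report) <- "aat_run_report"
  if (!is.null(outdir)) .write_report(report, outdir)
  report
}

.write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cand <- do.call(rbind, lapply(report$candidates, as.data.frame))
  write_candidate_table(cand, file.path(outdir, "candidates.tsv"))
  write_locus_table(report$locus_sets, file.path(outdir, "loci.tsv"))
  if (!is.null(report$pair_logs))
    utils::write.table(report$pair_logs,
                       file.path(outdir, "pair_log.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(report$counts, file.path(outdir, "counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$summary,
                     file.path(outdir, "group_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pgls_json <- lapply(report$pgls, function(p)
    list(beta = as.list(p$beta), sigma2 = p$sigma2, F = p$F,
         df = p$df, p.value = p$p.value, n = p$n))
  out_files <- c("candidates.tsv", "loci.tsv", "counts.tsv",
                 "group_summary.tsv")
  jsonlite::write_json(
    list(config = report$config, pgls = pgls_json,
         checksums = as.list(stats::setNames(
           unname(tools::md5sum(file.path(outdir, out_files))),
           out_files))),
    file.path(outdir, "report.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(outdir)
}

#' @export
print.aat_run_report <- function(x, ...) {
  cat("AAT census run (", x$config$mode, " mode)\n", sep = "")
  print(x$counts)
  cat("\nGroup summary (truncated means):\n")
  print(x$summary)
  if (!is.null(x$pgls)) {
    for (resp in names(x$pgls)) {
      p <- x$pgls[[resp]]
      cat(sprintf("\nPGLS %s ~ life history: F(%d, %d) = %.3g, p = %.3g\n",
                  resp, p$df[1], p$df[2], p$F, p$p.value))
    }
  }
  invisible(x)
}

.cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    key <- gsub("-", "_", sub("^--", "", a))
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opts[[key]] <- TRUE        # bare flag
      i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}

.opt <- function(opts, key, default = NULL, required = FALSE,
                 as = identity) {
  if (is.null(opts[[key]])) {
    if (required) stop("missing required option --",
                       gsub("_", "-", key), call. = FALSE)
    return(default)
  }
  as(opts[[key]])
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic bundle), `run-all` (full
#' pipeline), `classify`, `coalesce`, `summarize`, `pgls`.  See the
#' package README for flags.  Callable from a script as
#' `aatcensus::aat_cli()`.
#'
#' @param args character vector of command-line arguments; defaults to the
#'   calling script's.
#' @return invisibly, the subcommand's result.
#' @export
aat_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop("usage: aat_cli <simulate|run-all|classify|coalesce|",
         "summarize|pgls> [--flags]", call. = FALSE)
  cmd <- args[1]
  opts <- .cli_opts(args[-1])
  num <- as.numeric
  int <- function(x) as.integer(as.numeric(x))

  coalesce_from_opts <- function() coalesce_config(
    ks_threshold = .opt(opts, "ks_threshold", 0.25, as = num),
    overlap_bp = .opt(opts, "overlap_bp", 50, as = num),
    merge_gap_bp = .opt(opts, "merge_gap_bp", 5000, as = num))

  res <- switch(
    cmd,
    "simulate" = {
      cfg <- sim_config(
        n_taxa = .opt(opts, "n_taxa", 16, as = int),
        delta = .opt(opts, "delta", 7, as = num),
        baseline = c(APC = .opt(opts, "baseline_apc", 10, as = num),
                     AAAP = .opt(opts, "baseline_aaap", 14, as = num)),
        background_n = .opt(opts, "background_n", 10, as = int),
        genome_mode = isTRUE(.opt(opts, "genome_mode", FALSE)),
        seed = .opt(opts, "seed", required = TRUE, as = int))
      write_bundle(simulate_bundle(cfg),
                   .opt(opts, "outdir", required = TRUE),
                   force = isTRUE(.opt(opts, "force", FALSE)))
    },
    "run-all" = ,
    "count" = {
      run_pipeline(.opt(opts, "input", required = TRUE),
                   outdir = .opt(opts, "outdir"),
                   mode = .opt(opts, "mode", "denovo"),
                   coalesce_cfg = coalesce_from_opts())
    },
    "classify" = {
      tr <- read_transcript_fasta(.opt(opts, "fasta", required = TRUE),
                                  taxon = .opt(opts, "taxon", "unknown"))
      cand <- select_candidates(
        tr, parse_domain_hits(.opt(opts, "domain_hits", required = TRUE)),
        parse_blast_hits(.opt(opts, "blast_hits", required = TRUE)))
      write_candidate_table(cand, .opt(opts, "out", required = TRUE))
      cand
    },
    "coalesce" = {
      tr <- read_transcript_fasta(.opt(opts, "fasta", required = TRUE),
                                  taxon = .opt(opts, "taxon", "unknown"))
      cand <- select_candidates(
        tr, parse_domain_hits(.opt(opts, "domain_hits", required = TRUE)),
        parse_blast_hits(.opt(opts, "blast_hits", required = TRUE)))
      cfg <- coalesce_from_opts()
      mode <- .opt(opts, "mode", "denovo")
      sets <- lapply(sort(unique(cand$family)), function(fam) {
        sub <- cand[cand$family == fam, , drop = FALSE]
        if (mode == "genome")
          coalesce_genome_guided(sub, parse_mapping_hits(
            .opt(opts, "mapping_hits", required = TRUE)), cfg)
        else coalesce_denovo(sub, cfg)
      })
      write_locus_table(sets, .opt(opts, "out", required = TRUE))
      sets
    },
    "summarize" = {
      counts <- utils::read.delim(.opt(opts, "counts", required = TRUE),
                                  stringsAsFactors = FALSE)
      s <- summarize_groups(counts)
      out <- .opt(opts, "out")
      if (!is.null(out))
        utils::write.table(s, out, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      print(s)
      s
    },
    "pgls" = {
      counts <- utils::read.delim(.opt(opts, "counts", required = TRUE),
                                  stringsAsFactors = FALSE)
      tree <- read_newick(.opt(opts, "tree", required = TRUE))
      resp <- .opt(opts, "response", "total")
      keep <- intersect(tree$tip.label, counts$taxon)
      C <- brownian_vcv(ape::keep.tip(tree, keep), keep)
      idx <- match(keep, counts$taxon)
      fit <- pgls_fit(stats::setNames(counts[[resp]][idx], keep),
                      factor(counts$life_history[idx]), C)
      print(fit)
      out <- .opt(opts, "out")
      if (!is.null(out))
        jsonlite::write_json(list(response = resp,
                                  beta = as.list(fit$beta),
                                  F = fit$F, df = fit$df,
                                  p.value = fit$p.value, n = fit$n),
                             out, auto_unbox = TRUE, digits = NA)
      fit
    },
    stop("unknown subcommand: ", cmd, call. = FALSE))
  invisible(res)
}
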