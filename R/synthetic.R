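#' Configuration for the synthetic-data generator
#'
#' Defaults state a world shaped like the published transporter census:
#' ~16 taxa, galling baselines of 10 APC and 14 AAAP loci, a free-living
#' effect of +7 loci per family, paralogs diverged well past the collapse
#' threshold and isoforms well under it.
#'
#' @param n_taxa number of taxa (tips).
#' @param birth_rate pure-birth speciation rate for the simulated tree.
#' @param sigma2 Brownian rate of the latent per-family count.
#' @param delta additive life-history effect on the latent count for
#'   free-living taxa.
#' @param baseline named numeric: latent baseline count per family.
#' @param p_free fraction of taxa assigned the free-living state.
#' @param isoform_range integer range (min, max) of transcripts per
#'   unfragmented locus sharing one component.
#' @param isoform_ks target synonymous divergence of extra isoforms.
#' @param allele_prob probability that a locus also emits a divergent copy
#'   under its own component at `allele_ks` (collapsed by the Ks rule).
#' @param allele_ks target Ks for allelic copies.
#' @param fragment_prob probability (per taxon/family) that one locus is
#'   represented only by two barely-overlapping fragments with distinct
#'   components (collapsed by the short-overlap rule).
#' @param fragment_overlap_codons range of codon overlap between the two
#'   fragments (kept under the 50-bp rule).
#' @param paralog_ks range of target pairwise Ks between distinct loci.
#' @param ks_tol relative tolerance for Ks targeting.
#' @param nonsyn_frac fraction of mutation events that are nonsynonymous
#'   (stop-avoiding), giving paralogs mildly divergent proteins.
#' @param contaminant_fraction contaminant transcripts per true locus.
#' @param background_n background (non-AAT) transcripts per taxon.
#' @param cds_len_codons CDS length range in codons (default 100-500,
#'   i.e. 300-1500 nt).
#' @param utr_len UTR length range (nt) on each side.
#' @param label_noise probability that an AAT transcript's best BLAST hit
#'   is mislabelled (non-zero breaks the noise-free guarantee).
#' @param genome_mode also emit transcript-to-genome mapping tables.
#' @param fam_accessions named map family -> domain accession.
#' @param seed mandatory integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 16, birth_rate = 1, sigma2 = 1.5,
                       delta = 7, baseline = c(APC = 10, AAAP = 14),
                       p_free = 1 / 3,
                       isoform_range = c(1, 3), isoform_ks = 0.05,
                       allele_prob = 0.15, allele_ks = 0.1,
                       fragment_prob = 0.15,
                       fragment_overlap_codons = c(3, 10),
                       paralog_ks = c(0.5, 0.9), ks_tol = 0.1,
                       nonsyn_frac = 0.1,
                       contaminant_fraction = 0.1, background_n = 10,
                       cds_len_codons = c(100, 500), utr_len = c(20, 60),
                       label_noise = 0, genome_mode = FALSE,
                       fam_accessions = c(APC = "PF03024",
                                          AAAP = "PF01490"),
                       seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory",
                                           call. = FALSE)
  stopifnot(n_taxa >= 3, birth_rate > 0, sigma2 >= 0,
            all(baseline >= 1), p_free > 0, p_free < 1,
            isoform_range[1] >= 1, isoform_ks > 0, allele_prob >= 0,
            allele_prob <= 1, fragment_prob >= 0, fragment_prob <= 1,
            paralog_ks[1] > 0, paralog_ks[2] < 1.2, ks_tol > 0,
            nonsyn_frac >= 0, nonsyn_frac < 1,
            contaminant_fraction >= 0, background_n >= 0,
            cds_len_codons[1] >= 60, label_noise >= 0, label_noise <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate an ultrametric pure-birth tree
#'
#' @param n_taxa number of tips (labelled `taxon01`, ...).
#' @param birth_rate speciation rate.
#' @param seed integer seed; the same seed gives an identical tree.
#' @return a `phylo` object.
#' @export
simulate_tree <- function(n_taxa, birth_rate = 1, seed) {
  stopifnot(n_taxa >= 3)
  set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("taxon%02d", seq_len(n_taxa))
  tree
}

#' Simulate true per-taxon, per-family locus counts
#'
#' Latent value = baseline + Brownian realisation (covariance
#' `sigma2 * C`) + `delta` for free-living taxa; the count is
#' `max(1, round(latent))`.
#'
#' @param tree a `phylo` object.
#' @param life_history named character vector over the tips
#'   (`"galling"`/`"free_living"`).
#' @param sigma2,delta,baseline see [sim_config()].
#' @param seed integer seed.
#' @return data frame: `taxon`, one integer column per family,
#'   `life_history`.
#' @export
simulate_counts <- function(tree, life_history, sigma2, delta, baseline,
                            seed) {
  stopifnot(setequal(names(life_history), tree$tip.label))
  set.seed(seed)
  taxa <- tree$tip.label
  C <- brownian_vcv(tree, taxa)
  L <- if (sigma2 > 0) t(chol(sigma2 * C)) else matrix(0, length(taxa),
                                                       length(taxa))
  ind <- as.numeric(life_history[taxa] == "free_living")
  out <- data.frame(taxon = taxa, stringsAsFactors = FALSE)
  for (f in names(baseline)) {
    latent <- baseline[[f]] + as.numeric(L %*% stats::rnorm(length(taxa))) +
      delta * ind
    out[[f]] <- pmax(1L, as.integer(round(latent)))
  }
  out$life_history <- unname(life_history[taxa])
  out
}

.random_sense_codons <- function(n) {
  sample(.sense_codons(), n, replace = TRUE)
}

.random_cds_codons <- function(n_codons) {
  c("ATG", .random_sense_codons(n_codons - 1L))
}

.random_utr <- function(len) {
  u <- paste(sample(.NT, len, replace = TRUE), collapse = "")
  while (grepl("ATG", u, fixed = TRUE))
    u <- sub("ATG", "ACG", u, fixed = TRUE)
  u
}

.ks_codons <- function(a, b) {
  .ks_core(a, b, overlap_bp = 3L * length(a), min_overlap_bp = 0)
}

# One random single-nucleotide change on a codon vector.  Synonymous moves
# draw from the precomputed synonymous-neighbour lists; nonsynonymous moves
# draw any non-stop, non-synonymous single-nt neighbour.
.mutate_once <- function(codons, synonymous = TRUE) {
  tab <- .ng_tables()
  for (attempt in 1:50) {
    # codon 1 is the start codon; mutating it would move the ORF
    i <- sample.int(length(codons) - 1L, 1L) + 1L
    if (synonymous) {
      nb <- tab$syn_neighbors[[codons[i]]]
    } else {
      cd <- codons[i]
      all_nb <- unlist(lapply(1:3, function(pos) {
        alt <- setdiff(.NT, substr(cd, pos, pos))
        vapply(alt, function(n) {
          x <- cd
          substr(x, pos, pos) <- n
          x
        }, "")
      }), use.names = FALSE)
      nb <- all_nb[GENETIC_CODE_TABLE[all_nb] != "*" &
                     GENETIC_CODE_TABLE[all_nb] !=
                       GENETIC_CODE_TABLE[[cd]]]
    }
    if (length(nb) > 0L) {
      codons[i] <- if (length(nb) == 1L) nb else sample(nb, 1L)
      return(codons)
    }
  }
  codons
}

# Diverge a copy of `codons` until the measured Ks against the original
# reaches the target.  Mutations are applied in batches far from the
# target and one at a time near it, and the estimate is re-measured with
# the package's own Ks calculator, so generator and estimator agree by
# construction.  Single substitutions move Ks in discrete steps (about
# 1/S), so the loop returns the achievable state closest to the target
# that does not exceed `target * (1 + tol)`.
.mutate_to_ks <- function(codons, target, tol = 0.1, nonsyn_frac = 0.1,
                          max_iter = 20000) {
  out <- codons
  ks <- 0
  S_est <- .ks_codons(codons, codons)$S
  pS_of <- function(k) 0.75 * (1 - exp(-4 / 3 * k))
  for (iter in seq_len(max_iter)) {
    if (ks >= target) break
    # roughly half the synonymous substitutions still needed
    batch <- max(1L, as.integer(floor(
      0.5 * S_est * (pS_of(target) - pS_of(ks)))))
    prev <- out
    prev_ks <- ks
    for (b in seq_len(batch))
      out <- .mutate_once(out, synonymous = stats::runif(1) >= nonsyn_frac)
    ks <- .ks_codons(codons, out)$ks
    if (is.na(ks))
      stop(sprintf("Ks target %.3f drove the pair to saturation", target),
           call. = FALSE)
    if (ks >= target) {
      # keep whichever side of the target is closer, but never exceed
      # the upper tolerance bound
      if (ks > target * (1 + tol) ||
          abs(prev_ks - target) <= abs(ks - target)) {
        out <- prev
        ks <- prev_ks
      }
      break
    }
  }
  if (ks < target * (1 - tol) &&
      abs(ks - target) > 1.5 / max(1, 0.25 * 3 * length(codons)))
    stop(sprintf("could not reach Ks target %.3f (achieved %.3f)",
                 target, ks), call. = FALSE)
  out
}

# Assemble a transcript (UTR + CDS + stop + UTR) and verify that the
# pipeline's own ORF finder recovers exactly the designed CDS; pathological
# random sequences (e.g. a longer spurious ORF in another frame) are
# resampled so that the truth table stays exact.
.wrap_cds <- function(cds_codons, cfg, max_tries = 20) {
  cds <- paste(cds_codons, collapse = "")
  for (i in seq_len(max_tries)) {
    u5 <- .random_utr(sample(cfg$utr_len[1]:cfg$utr_len[2], 1L))
    u3 <- .random_utr(sample(cfg$utr_len[1]:cfg$utr_len[2], 1L))
    seq <- paste0(u5, cds, "TAA", u3)
    orf <- longest_orf(seq, min_aa = 50)
    if (!is.null(orf) && orf$cds == paste0(cds, "TAA"))
      return(seq)
  }
  NULL
}

# Wrap a designed CDS, jittering it with nonsynonymous single-nt changes
# (which leave Ks essentially unchanged) when a spurious longer ORF in
# another frame keeps the validation in .wrap_cds from passing.
.wrap_validated <- function(codons, cfg) {
  for (attempt in 1:50) {
    s <- .wrap_cds(codons, cfg, max_tries = 5)
    if (!is.null(s)) return(list(seq = s, codons = codons))
    codons <- .mutate_once(codons, synonymous = FALSE)
  }
  stop("could not construct a transcript whose longest ORF is the designed CDS",
       call. = FALSE)
}

.sim_one_family <- function(taxon, family, n_loci, cfg) {
  len <- sample(cfg$cds_len_codons[1]:cfg$cds_len_codons[2], 1L)
  anc <- .wrap_validated(.random_cds_codons(len), cfg)$codons
  loci <- vector("list", n_loci)
  loci[[1]] <- list(codons = anc, ks_target = 0)
  if (n_loci > 1L) {
    for (k in 2:n_loci) {
      tgt <- stats::runif(1, cfg$paralog_ks[1], cfg$paralog_ks[2])
      cd <- .wrap_validated(.mutate_to_ks(anc, tgt, cfg$ks_tol,
                                          cfg$nonsyn_frac), cfg)$codons
      loci[[k]] <- list(codons = cd, ks_target = tgt)
    }
  }
  frag_locus <- if (stats::runif(1) < cfg$fragment_prob)
    sample.int(n_loci, 1L) else 0L

  tr <- list()
  truth <- list()
  add <- function(id, comp, seq, locus, role, ks_target = NA_real_) {
    tr[[length(tr) + 1L]] <<- data.frame(
      id = id, taxon = taxon, component_id = comp, seq = seq,
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      transcript_id = id, taxon = taxon, family = family,
      true_locus = sprintf("%s|%s|T%02d", taxon, family, locus),
      role = role, ks_target = ks_target, stringsAsFactors = FALSE)
  }

  for (k in seq_len(n_loci)) {
    codons <- loci[[k]]$codons
    base <- sprintf("%s_%s_g%02d", taxon, tolower(family), k)
    if (k == frag_locus) {
      # two barely-overlapping fragments under distinct components
      L <- length(codons)
      s <- L %/% 2L
      ov <- sample(cfg$fragment_overlap_codons[1]:
                     cfg$fragment_overlap_codons[2], 1L)
      fragA <- codons[1:(s + ov)]
      fragB <- c("ATG", codons[(s + 1L):L])
      add(paste0(base, "f1_i1"), paste0(base, "f1"),
          .wrap_validated(fragA, cfg)$seq, k, "fragment")
      add(paste0(base, "f2_i1"), paste0(base, "f2"),
          .wrap_validated(fragB, cfg)$seq, k, "fragment")
      next
    }
    n_iso <- sample(cfg$isoform_range[1]:cfg$isoform_range[2], 1L)
    for (j in seq_len(n_iso)) {
      iso <- if (j == 1L) codons else
        .mutate_to_ks(codons, cfg$isoform_ks, cfg$ks_tol, nonsyn_frac = 0)
      if (j > 1L && stats::runif(1) < 0.3) {
        keep <- max(60L, as.integer(length(iso) *
                                      stats::runif(1, 0.6, 0.9)))
        iso <- iso[seq_len(keep)]  # 3'-truncated splice/assembly variant
      }
      role <- if (j == 1L) "paralog-representative" else "isoform"
      add(sprintf("%s_i%d", base, j), base, .wrap_validated(iso, cfg)$seq,
          k, role, if (k > 1L && j == 1L) loci[[k]]$ks_target else NA_real_)
    }
    if (stats::runif(1) < cfg$allele_prob) {
      al <- .mutate_to_ks(codons, cfg$allele_ks, cfg$ks_tol,
                          nonsyn_frac = 0)
      add(paste0(base, "a_i1"), paste0(base, "a"),
          .wrap_validated(al, cfg)$seq, k, "allele", cfg$allele_ks)
    }
  }
  list(transcripts = do.call(rbind, tr), truth = do.call(rbind, truth))
}

.fam_accession <- function(family, cfg) {
  if (family %in% names(cfg$fam_accessions))
    unname(cfg$fam_accessions[[family]]) else paste0("PFX_", family)
}

#' Simulate one taxon's transcriptome and matching hit tables
#'
#' Per true locus: a stop-free CDS wrapped in ATG-free UTRs, with isoforms
#' and truncated variants sharing a component, occasional allelic copies at
#' low Ks under their own component, and (at most one locus per family)
#' fragment pairs overlapping by under 50 bp.  Contaminant transcripts get
#' plant-labelled best BLAST hits; background transcripts get no domain
#' hits.  Hit tables are consistent with the truth when
#' `cfg$label_noise == 0`.
#'
#' @param taxon taxon label.
#' @param true_counts named integer vector: true locus count per family.
#' @param cfg a [sim_config()].
#' @param seed integer seed for this taxon.
#' @return list: `transcripts`, `domain_hits`, `blast_hits`,
#'   `mapping_hits` (`NULL` unless `cfg$genome_mode`), `truth`,
#'   `true_counts`.
#' @export
simulate_transcriptome <- function(taxon, true_counts, cfg, seed) {
  stopifnot(inherits(cfg, "sim_config"), all(true_counts >= 1))
  set.seed(seed)
  fams <- lapply(names(true_counts), function(f)
    .sim_one_family(taxon, f, true_counts[[f]], cfg))
  transcripts <- do.call(rbind, lapply(fams, `[[`, "transcripts"))
  truth <- do.call(rbind, lapply(fams, `[[`, "truth"))

  n_contam <- round(cfg$contaminant_fraction * sum(true_counts))
  if (n_contam > 0L) {
    for (k in seq_len(n_contam)) {
      codons <- .random_cds_codons(
        sample(cfg$cds_len_codons[1]:cfg$cds_len_codons[2], 1L))
      id <- sprintf("%s_contam%02d", taxon, k)
      transcripts <- rbind(transcripts, data.frame(
        id = id, taxon = taxon, component_id = paste0(id, "c"),
        seq = .wrap_validated(codons, cfg)$seq, stringsAsFactors = FALSE))
      truth <- rbind(truth, data.frame(
        transcript_id = id, taxon = taxon, family = NA_character_,
        true_locus = NA_character_, role = "contaminant",
        ks_target = NA_real_, stringsAsFactors = FALSE))
    }
  }
  if (cfg$background_n > 0L) {
    for (k in seq_len(cfg$background_n)) {
      id <- sprintf("%s_bg%03d", taxon, k)
      transcripts <- rbind(transcripts, data.frame(
        id = id, taxon = taxon, component_id = paste0(id, "c"),
        seq = paste(sample(.NT, sample(200:800, 1L), replace = TRUE),
                    collapse = ""),
        stringsAsFactors = FALSE))
      truth <- rbind(truth, data.frame(
        transcript_id = id, taxon = taxon, family = NA_character_,
        true_locus = NA_character_, role = "background",
        ks_target = NA_real_, stringsAsFactors = FALSE))
    }
  }

  blast_row <- function(id, subject, fam, group, evalue, bitscore) {
    data.frame(qseqid = id, sseqid = subject, pident = 90, length = 300,
               mismatch = 30, gapopen = 0, qstart = 1, qend = 300,
               sstart = 1, send = 300, evalue = evalue,
               bitscore = bitscore, subject_family = fam,
               subject_taxon_group = group, stringsAsFactors = FALSE)
  }
  dh <- list()
  bh <- list()
  for (r in seq_len(nrow(truth))) {
    id <- truth$transcript_id[r]
    role <- truth$role[r]
    if (role %in% c("isoform", "fragment", "allele",
                    "paralog-representative")) {
      fam <- truth$family[r]
      dh[[length(dh) + 1L]] <- data.frame(
        transcript_id = id, domain_accession = .fam_accession(fam, cfg),
        evalue = 10^(-stats::runif(1, 10, 60)),
        score = round(stats::runif(1, 100, 400), 1),
        stringsAsFactors = FALSE)
      group <- if (stats::runif(1) < cfg$label_noise) "plant" else
        "hemiptera"
      bh[[length(bh) + 1L]] <- blast_row(
        id, sprintf("%s_ref_%s", tolower(fam), id), fam, group,
        10^(-stats::runif(1, 40, 120)),
        round(stats::runif(1, 250, 600), 1))
      bh[[length(bh) + 1L]] <- blast_row(
        id, paste0("plant_decoy_", id), "OTHER", "plant",
        10^(-stats::runif(1, 2, 8)), round(stats::runif(1, 40, 90), 1))
    } else if (role == "contaminant") {
      dh[[length(dh) + 1L]] <- data.frame(
        transcript_id = id,
        domain_accession = .fam_accession(names(true_counts)[1], cfg),
        evalue = 10^(-stats::runif(1, 4, 10)),
        score = round(stats::runif(1, 50, 150), 1),
        stringsAsFactors = FALSE)
      bh[[length(bh) + 1L]] <- blast_row(
        id, paste0("plant_aap_", id), "AAAP", "plant",
        10^(-stats::runif(1, 60, 120)),
        round(stats::runif(1, 400, 700), 1))
      bh[[length(bh) + 1L]] <- blast_row(
        id, paste0("hemip_weak_", id), "APC", "hemiptera",
        10^(-stats::runif(1, 4, 9)), round(stats::runif(1, 60, 120), 1))
    }
  }
  domain_hits <- if (length(dh)) do.call(rbind, dh) else
    data.frame(transcript_id = character(), domain_accession = character(),
               evalue = numeric(), score = numeric(),
               stringsAsFactors = FALSE)
  blast_hits <- if (length(bh)) do.call(rbind, bh) else NULL

  mapping_hits <- NULL
  if (cfg$genome_mode) {
    mh <- list()
    aat <- truth[truth$role %in% c("isoform", "fragment", "allele",
                                   "paralog-representative"), ,
                 drop = FALSE]
    for (r in seq_len(nrow(aat))) {
      locus_k <- as.integer(sub(".*T", "", aat$true_locus[r]))
      nfrag <- if (aat$role[r] == "fragment") {
        sum(aat$true_locus == aat$true_locus[r] &
              aat$transcript_id <= aat$transcript_id[r])
      } else 1L
      start <- 100000L * locus_k + (nfrag - 1L) * 2000L
      mh[[length(mh) + 1L]] <- data.frame(
        transcript_id = aat$transcript_id[r],
        scaffold = sprintf("scf_%s_%s", taxon, tolower(aat$family[r])),
        strand = "+", start = start, end = start + 1500L,
        evalue = 1e-50, bitscore = 1000, stringsAsFactors = FALSE)
    }
    mapping_hits <- do.call(rbind, mh)
  }
  rownames(transcripts) <- rownames(truth) <- NULL
  list(transcripts = transcripts, domain_hits = domain_hits,
       blast_hits = blast_hits, mapping_hits = mapping_hits,
       truth = truth, true_counts = true_counts)
}

#' Simulate a complete multi-taxon input bundle
#'
#' Tree, life histories, true counts, per-taxon transcriptomes and hit
#' tables, plus truth tables.  Fully determined by `cfg` (including its
#' seed).
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_bundle`: `config`, `tree`, `life_history`
#'   (data frame), `true_counts`, `taxa` (named list of
#'   [simulate_transcriptome()] results).
#' @export
simulate_bundle <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  tree <- simulate_tree(cfg$n_taxa, cfg$birth_rate, cfg$seed)
  set.seed(cfg$seed + 1L)
  n_free <- max(1L, round(cfg$p_free * cfg$n_taxa))
  lh <- stats::setNames(rep("galling", cfg$n_taxa), tree$tip.label)
  lh[sample(tree$tip.label, n_free)] <- "free_living"
  counts <- simulate_counts(tree, lh, cfg$sigma2, cfg$delta, cfg$baseline,
                            cfg$seed + 2L)
  taxa <- list()
  for (i in seq_len(cfg$n_taxa)) {
    tx <- tree$tip.label[i]
    tc <- stats::setNames(
      as.integer(counts[counts$taxon == tx, names(cfg$baseline)]),
      names(cfg$baseline))
    taxa[[tx]] <- simulate_transcriptome(tx, tc, cfg,
                                         seed = cfg$seed + 1000L + i)
  }
  out <- list(config = cfg, tree = tree,
              life_history = data.frame(taxon = tree$tip.label,
                                        life_history = unname(
                                          lh[tree$tip.label]),
                                        stringsAsFactors = FALSE),
              true_counts = counts, taxa = taxa)
  class(out) <- "sim_bundle"
  out
}

#' Write a simulated bundle to disk
#'
#' Produces `tree.nwk`, `life_history.tsv`, `truth_counts.tsv`,
#' `truth_transcripts.tsv`, per-taxon FASTA and hit tables under `taxa/`,
#' and `manifest.json` recording the full configuration, seed and per-file
#' MD5 checksums.  Re-running with the same configuration reproduces
#' byte-identical files.
#'
#' @param bundle a `sim_bundle`.
#' @param outdir output directory (created if missing).
#' @param force overwrite a non-empty directory.
#' @return invisibly, the manifest list.
#' @export
write_bundle <- function(bundle, outdir, force = FALSE) {
  stopifnot(inherits(bundle, "sim_bundle"))
  if (dir.exists(outdir) && length(dir(outdir)) > 0L && !force)
    stop("output directory ", outdir,
         " is not empty (use force = TRUE)", call. = FALSE)
  dir.create(file.path(outdir, "taxa"), recursive = TRUE,
             showWarnings = FALSE)
  wt <- function(df, f) utils::write.table(
    df, file.path(outdir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  ape::write.tree(bundle$tree, file.path(outdir, "tree.nwk"))
  wt(bundle$life_history, "life_history.tsv")
  wt(bundle$true_counts, "truth_counts.tsv")
  wt(do.call(rbind, lapply(bundle$taxa, `[[`, "truth")),
     "truth_transcripts.tsv")
  for (tx in names(bundle$taxa)) {
    b <- bundle$taxa[[tx]]
    write_transcript_fasta(b$transcripts,
                           file.path(outdir, "taxa",
                                     paste0(tx, "_transcripts.fasta")))
    # hit tables are headerless, like the tools they emulate
    utils::write.table(b$domain_hits,
                       file.path(outdir, "taxa",
                                 paste0(tx, "_domain_hits.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(b$blast_hits,
                       file.path(outdir, "taxa",
                                 paste0(tx, "_blast_hits.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    if (!is.null(b$mapping_hits)) {
      # BLAST-tabular shape: subject coordinates carry the strand
      mh <- b$mapping_hits
      blast12 <- data.frame(qseqid = mh$transcript_id, sseqid = mh$scaffold,
                            pident = 99, length = mh$end - mh$start + 1,
                            mismatch = 0, gapopen = 0, qstart = 1,
                            qend = mh$end - mh$start + 1,
                            sstart = ifelse(mh$strand == "+", mh$start,
                                            mh$end),
                            send = ifelse(mh$strand == "+", mh$end,
                                          mh$start),
                            evalue = mh$evalue, bitscore = mh$bitscore,
                            stringsAsFactors = FALSE)
      utils::write.table(blast12,
                         file.path(outdir, "taxa",
                                   paste0(tx, "_mapping_hits.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
  }
  files <- sort(setdiff(dir(outdir, recursive = TRUE), "manifest.json"))
  manifest <- list(
    config = unclass(bundle$config),
    package_version = as.character(utils::packageVersion("aatcensus")),
    checksums = as.list(stats::setNames(
      unname(tools::md5sum(file.path(outdir, files))), files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
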