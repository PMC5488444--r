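#' Configuration for locus coalescing
#'
#' @param ks_threshold pairs with a defined Ks strictly below this collapse
#'   into one locus (default 0.25).
#' @param overlap_bp pairs whose aligned overlap is strictly below this
#'   many base pairs collapse (default 50); the same value is the minimum
#'   overlap for a pair to be Ks-comparable.
#' @param merge_gap_bp genome-guided mode merges mapped intervals on the
#'   same scaffold and strand when they overlap or lie within this gap.
#' @param map_evalue mapping hits must pass this evalue to be used.
#' @param gap_open,gap_extend protein alignment gap costs.
#' @param align_type alignment flavour for pairwise comparisons; the
#'   default `"overlap"` (ends-free) keeps non-overlapping fragments from
#'   being force-aligned.
#' @return list of class `coalesce_config`.
#' @export
coalesce_config <- function(ks_threshold = 0.25, overlap_bp = 50,
                            merge_gap_bp = 5000, map_evalue = 1e-3,
                            gap_open = 11, gap_extend = 1,
                            align_type = c("overlap", "global")) {
  stopifnot(ks_threshold > 0, overlap_bp > 0, merge_gap_bp >= 0,
            map_evalue > 0)
  cfg <- list(ks_threshold = ks_threshold, overlap_bp = overlap_bp,
              merge_gap_bp = merge_gap_bp, map_evalue = map_evalue,
              gap_open = gap_open, gap_extend = gap_extend,
              align_type = match.arg(align_type))
  class(cfg) <- "coalesce_config"
  cfg
}

#' Collapse transcripts sharing an assembly component
#'
#' One group per (taxon, component); the representative is the member with
#' the longest ORF protein, ties broken by lexicographic id.
#'
#' @param candidates an `aat_candidates` data frame.
#' @return list with `representatives` (candidate rows, one per component)
#'   and `members` (named list: representative id -> member ids).
#' @export
collapse_by_component <- function(candidates) {
  stopifnot(is.data.frame(candidates), nrow(candidates) > 0)
  if (any(is.na(candidates$component_id) | !nzchar(candidates$component_id)))
    stop("all candidates need a component_id for de novo collapsing",
         call. = FALSE)
  key <- paste(candidates$taxon, candidates$component_id, sep = "\r")
  reps <- members <- list()
  for (k in sort(unique(key))) {
    grp <- candidates[key == k, , drop = FALSE]
    grp <- grp[order(-nchar(grp$protein), grp$id), , drop = FALSE]
    reps[[length(reps) + 1L]] <- grp[1, , drop = FALSE]
    members[[grp$id[1]]] <- sort(grp$id)
  }
  reps <- do.call(rbind, reps)
  reps <- reps[order(reps$id), , drop = FALSE]
  rownames(reps) <- NULL
  list(representatives = reps, members = members[reps$id])
}

#' Decide whether two locus representatives collapse
#'
#' Aligns the two ORF proteins, back-translates to codons, and applies the
#' two collapse rules: aligned overlap under `cfg$overlap_bp` base pairs
#' (fragments of one gene that barely overlap cannot be told apart), or a
#' defined pairwise Ks under `cfg$ks_threshold` (too little synonymous
#' divergence to be separate loci).  Saturated pairs never collapse.
#'
#' @param rep_a,rep_b single-row `aat_candidates` data frames (or lists)
#'   with `protein` and `cds` fields.
#' @param cfg a [coalesce_config()].
#' @return list with `collapse` (logical), `reason` (`"ks_below_threshold"`,
#'   `"short_overlap"` or `"none"`), `ks` (a `ks_result`) and `overlap_bp`.
#' @export
pair_decision <- function(rep_a, rep_b, cfg = coalesce_config()) {
  aln <- align_proteins(rep_a$protein, rep_b$protein,
                        gap_open = cfg$gap_open,
                        gap_extend = cfg$gap_extend,
                        type = cfg$align_type)
  ca <- codon_alignment(aln, rep_a$cds, rep_b$cds)
  ks <- ks_pair(ca, min_overlap_bp = cfg$overlap_bp)
  if (ca$overlap_bp < cfg$overlap_bp)
    return(list(collapse = TRUE, reason = "short_overlap", ks = ks,
                overlap_bp = ca$overlap_bp))
  if (ks$status == "ok" && ks$ks < cfg$ks_threshold)
    return(list(collapse = TRUE, reason = "ks_below_threshold", ks = ks,
                overlap_bp = ca$overlap_bp))
  list(collapse = FALSE, reason = "none", ks = ks,
       overlap_bp = ca$overlap_bp)
}

# Minimal union-find over 1..n.
.uf_new <- function(n) seq_len(n)
.uf_find <- function(uf, i) {
  while (uf[i] != i) i <- uf[i]
  i
}
.uf_union <- function(uf, i, j) {
  ri <- .uf_find(uf, i)
  rj <- .uf_find(uf, j)
  if (ri != rj) uf[max(ri, rj)] <- min(ri, rj)
  uf
}

.make_locus_set <- function(candidates, groups, taxon, family, pair_log,
                            mode, reasons = NULL) {
  # groups: list of character vectors of member transcript ids
  rep_of <- function(ids) {
    sub <- candidates[match(ids, candidates$id), , drop = FALSE]
    sub <- sub[order(-nchar(sub$protein), sub$id), , drop = FALSE]
    sub$id[1]
  }
  reps <- vapply(groups, rep_of, "")
  ord <- order(reps)
  groups <- groups[ord]
  reps <- reps[ord]
  loci <- lapply(seq_along(groups), function(i)
    list(locus_id = sprintf("%s|%s|L%03d", taxon, family, i),
         representative_id = reps[i],
         members = sort(groups[[i]])))
  out <- list(taxon = taxon, family = family, loci = loci,
              pair_log = pair_log, mode = mode)
  class(out) <- "locus_set"
  # partition sanity: disjoint and covering
  all_members <- unlist(lapply(loci, `[[`, "members"))
  stopifnot(!anyDuplicated(all_members),
            setequal(all_members, candidates$id))
  out
}

#' De novo locus coalescing
#'
#' Candidates (one taxon, one family) are first collapsed by assembly
#' component; every pair of component representatives is then tested with
#' [pair_decision()] and loci are the connected components of the resulting
#' collapse graph (transitive closure).  The result is invariant under
#' permutation of the input rows.
#'
#' @param candidates an `aat_candidates` data frame, single taxon and
#'   family.
#' @param cfg a [coalesce_config()].
#' @return object of class `locus_set`: `taxon`, `family`, `loci` (each
#'   with `locus_id`, `representative_id`, `members`), `pair_log` (one row
#'   per tested representative pair) and `mode`.
#' @export
coalesce_denovo <- function(candidates, cfg = coalesce_config()) {
  stopifnot(length(unique(candidates$taxon)) == 1L,
            length(unique(candidates$family)) == 1L)
  taxon <- candidates$taxon[1]
  family <- candidates$family[1]
  comp <- collapse_by_component(candidates)
  reps <- comp$representatives
  n <- nrow(reps)
  uf <- .uf_new(n)
  log_rows <- list()
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        dec <- pair_decision(reps[i, ], reps[j, ], cfg)
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          id_a = reps$id[i], id_b = reps$id[j],
          collapse = dec$collapse, reason = dec$reason,
          ks = if (is.na(dec$ks$ks)) NA_real_ else dec$ks$ks,
          ks_status = dec$ks$status, overlap_bp = dec$overlap_bp,
          stringsAsFactors = FALSE)
        if (dec$collapse) uf <- .uf_union(uf, i, j)
      }
    }
  }
  pair_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(id_a = character(), id_b = character(),
               collapse = logical(), reason = character(),
               ks = numeric(), ks_status = character(),
               overlap_bp = integer(), stringsAsFactors = FALSE)
  root <- vapply(seq_len(n), function(i) .uf_find(uf, i), 0L)
  groups <- lapply(split(seq_len(n), root), function(idx)
    unlist(comp$members[reps$id[idx]], use.names = FALSE))
  .make_locus_set(candidates, unname(groups), taxon, family, pair_log,
                  mode = "denovo")
}

.best_mapping <- function(mapping_hits, id) {
  h <- mapping_hits[mapping_hits$transcript_id == id, , drop = FALSE]
  if (nrow(h) == 0L) return(NULL)
  h <- h[order(-h$bitscore, h$evalue, h$scaffold, h$start), , drop = FALSE]
  h[1, , drop = FALSE]
}

#' Genome-guided locus coalescing
#'
#' Each candidate's best-scoring mapping interval is taken; intervals on
#' the same scaffold and strand that overlap or lie within
#' `cfg$merge_gap_bp` are merged into one locus.  Candidates without a
#' mapping hit passing `cfg$map_evalue` fall back to de novo coalescing
#' within the taxon/family (logged in the returned `unmapped` field).
#'
#' @param candidates an `aat_candidates` data frame, single taxon/family.
#' @param mapping_hits data frame from [parse_mapping_hits()].
#' @param cfg a [coalesce_config()].
#' @return a `locus_set` (mode `"genome"`) with an extra `unmapped`
#'   character vector naming fall-back transcripts.
#' @export
coalesce_genome_guided <- function(candidates, mapping_hits,
                                   cfg = coalesce_config()) {
  stopifnot(length(unique(candidates$taxon)) == 1L,
            length(unique(candidates$family)) == 1L)
  taxon <- candidates$taxon[1]
  family <- candidates$family[1]
  best <- lapply(candidates$id, function(id) {
    b <- .best_mapping(mapping_hits, id)
    if (!is.null(b) && b$evalue < cfg$map_evalue) b else NULL
  })
  mapped <- !vapply(best, is.null, TRUE)
  unmapped_ids <- candidates$id[!mapped]
  if (length(unmapped_ids) > 0L)
    message("genome-guided coalescing: ", length(unmapped_ids),
            " candidate(s) lack a passing mapping hit; ",
            "falling back to de novo rules for: ",
            paste(unmapped_ids, collapse = ", "))

  groups <- list()
  if (any(mapped)) {
    iv <- do.call(rbind, best[mapped])
    iv$transcript_id <- candidates$id[mapped]
    iv <- iv[order(iv$scaffold, iv$strand, iv$start, iv$end,
                   iv$transcript_id), , drop = FALSE]
    cur_ids <- iv$transcript_id[1]
    cur_scaffold <- iv$scaffold[1]
    cur_strand <- iv$strand[1]
    cur_end <- iv$end[1]
    if (nrow(iv) > 1L) {
      for (r in 2:nrow(iv)) {
        same <- iv$scaffold[r] == cur_scaffold & iv$strand[r] == cur_strand
        near <- same && iv$start[r] <= cur_end + cfg$merge_gap_bp
        if (near) {
          cur_ids <- c(cur_ids, iv$transcript_id[r])
          cur_end <- max(cur_end, iv$end[r])
        } else {
          groups[[length(groups) + 1L]] <- cur_ids
          cur_ids <- iv$transcript_id[r]
          cur_scaffold <- iv$scaffold[r]
          cur_strand <- iv$strand[r]
          cur_end <- iv$end[r]
        }
      }
    }
    groups[[length(groups) + 1L]] <- cur_ids
  }

  pair_log <- data.frame(id_a = character(), id_b = character(),
                         collapse = logical(), reason = character(),
                         ks = numeric(), ks_status = character(),
                         overlap_bp = integer(), stringsAsFactors = FALSE)
  if (length(unmapped_ids) > 0L) {
    fb <- coalesce_denovo(
      candidates[candidates$id %in% unmapped_ids, , drop = FALSE], cfg)
    groups <- c(groups, lapply(fb$loci, `[[`, "members"))
    pair_log <- fb$pair_log
  }
  out <- .make_locus_set(candidates, groups, taxon, family, pair_log,
                         mode = "genome")
  out$unmapped <- unmapped_ids
  out
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("locus_set: %s / %s (%s mode): %d loci, %d transcripts\n",
              x$taxon, x$family, x$mode, length(x$loci),
              length(unlist(lapply(x$loci, `[[`, "members")))))
  invisible(x)
}

#' Write a locus table
#'
#' @param locus_sets a `locus_set` or list of them.
#' @param path output TSV (taxon, family, locus_id, representative_id,
#'   members comma-joined, n_members).
#' @export
write_locus_table <- function(locus_sets, path) {
  if (inherits(locus_sets, "locus_set")) locus_sets <- list(locus_sets)
  rows <- do.call(rbind, lapply(locus_sets, function(ls)
    do.call(rbind, lapply(ls$loci, function(l)
      data.frame(taxon = ls$taxon, family = ls$family,
                 locus_id = l$locus_id,
                 representative_id = l$representative_id,
                 members = paste(l$members, collapse = ","),
                 n_members = length(l$members),
                 stringsAsFactors = FALSE)))))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
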