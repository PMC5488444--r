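# Build related CDS pairs with the generator's own mutation machinery.
mutate_cds <- function(cds, target_ks, nonsyn = 0) {
  ac <- asNamespace("aatcensus")
  codons <- strsplit(cds, "(?<=.{3})", perl = TRUE)[[1]]
  paste(ac$.mutate_to_ks(codons, target_ks, tol = 0.1,
                         nonsyn_frac = nonsyn), collapse = "")
}

wrap <- function(cds) paste0("GGGCCC", cds, "TAA")

test_that("collapse_by_component groups isoforms and picks longest ORF", {
  cds_long <- random_cds(120, seed = 9)
  cds_short <- substr(cds_long, 1, 240)
  cand <- as_candidates(
    candidate_row("iso2", wrap(cds_short), component = "c7"),
    candidate_row("iso1", wrap(cds_long), component = "c7"),
    candidate_row("solo", wrap(random_cds(90, seed = 10)),
                  component = "c9"))
  grp <- collapse_by_component(cand)
  expect_equal(nrow(grp$representatives), 2L)
  expect_equal(grp$members[["iso1"]], c("iso1", "iso2"))
  # equal-length ORFs: lexicographically smaller id wins
  cand2 <- as_candidates(
    candidate_row("b", wrap(cds_long), component = "cx"),
    candidate_row("a", wrap(cds_long), component = "cx"))
  expect_equal(collapse_by_component(cand2)$representatives$id, "a")
  # all-distinct components: groups == candidates
  cand3 <- as_candidates(
    candidate_row("p", wrap(cds_long), component = "c1"),
    candidate_row("q", wrap(cds_short), component = "c2"))
  expect_equal(nrow(collapse_by_component(cand3)$representatives), 2L)
})

test_that("pair_decision applies Ks and short-overlap rules", {
  set.seed(123)
  base <- random_cds(150)
  near <- mutate_cds(base, 0.10)
  far <- mutate_cds(base, 0.60, nonsyn = 0.1)
  a <- candidate_row("a", wrap(base))
  b <- candidate_row("b", wrap(near))
  c_ <- candidate_row("c", wrap(far))

  d_ab <- pair_decision(a, b)
  expect_true(d_ab$collapse)
  expect_equal(d_ab$reason, "ks_below_threshold")
  expect_lt(d_ab$ks$ks, 0.25)

  d_ac <- pair_decision(a, c_)
  expect_false(d_ac$collapse)
  expect_equal(d_ac$reason, "none")
  expect_gt(d_ac$ks$ks, 0.25)

  # barely-overlapping fragments of one gene collapse by short_overlap
  codons <- strsplit(base, "(?<=.{3})", perl = TRUE)[[1]]
  fragA <- paste(codons[1:80], collapse = "")
  fragB <- paste(c("ATG", codons[78:150]), collapse = "")
  d_fr <- pair_decision(candidate_row("fA", wrap(fragA)),
                        candidate_row("fB", wrap(fragB)))
  expect_true(d_fr$collapse)
  expect_equal(d_fr$reason, "short_overlap")
  expect_lt(d_fr$overlap_bp, 50)
})

test_that("coalesce_denovo takes the transitive closure, matching igraph", {
  set.seed(321)
  base <- random_cds(150)
  codons <- strsplit(base, "(?<=.{3})", perl = TRUE)[[1]]
  # A and C are left/right fragments; B is full length: A-B and B-C
  # collapse, A-C has no overlap -> all three are one locus
  cand <- as_candidates(
    candidate_row("A", wrap(paste(codons[1:70], collapse = ""))),
    candidate_row("B", wrap(base)),
    candidate_row("C", wrap(paste(c("ATG", codons[85:150]),
                                  collapse = ""))),
    candidate_row("D", wrap(mutate_cds(base, 0.65, nonsyn = 0.1))))
  ls <- coalesce_denovo(cand)
  expect_equal(length(ls$loci), 2L)
  members <- lapply(ls$loci, `[[`, "members")
  expect_true(any(vapply(members, identical, TRUE, y = c("A", "B", "C"))))
  expect_equal(ls$loci[[1]]$representative_id, "B")  # longest ORF

  # oracle: connected components over the explicit pair-decision matrix
  skip_if_not_installed("igraph")
  ids <- cand$id
  edges <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    if (pair_decision(cand[i, ], cand[j, ])$collapse)
      edges <- c(edges, ids[i], ids[j])
  }
  g <- igraph::make_graph(edges, isolates = setdiff(ids, edges),
                          directed = FALSE)
  comp <- igraph::components(g)
  expect_equal(comp$no, length(ls$loci))
})

test_that("coalesce_denovo is order-invariant and threshold-monotone", {
  set.seed(55)
  base <- random_cds(130)
  cand <- as_candidates(
    candidate_row("r1", wrap(base)),
    candidate_row("r2", wrap(mutate_cds(base, 0.2))),
    candidate_row("r3", wrap(mutate_cds(base, 0.35))),
    candidate_row("r4", wrap(mutate_cds(base, 0.7, nonsyn = 0.1))))
  ls <- coalesce_denovo(cand)
  for (perm in 1:3) {
    shuffled <- cand[sample(nrow(cand)), ]
    ls2 <- coalesce_denovo(shuffled)
    expect_equal(lapply(ls2$loci, `[[`, "members"),
                 lapply(ls$loci, `[[`, "members"))
    expect_equal(vapply(ls2$loci, `[[`, "", "representative_id"),
                 vapply(ls$loci, `[[`, "", "representative_id"))
  }
  # raising the threshold can only merge more
  n_loci <- vapply(c(0.05, 0.25, 0.5, 1.0), function(thr)
    length(coalesce_denovo(cand,
                           coalesce_config(ks_threshold = thr))$loci), 0L)
  expect_true(all(diff(n_loci) <= 0))
})

test_that("genome-guided coalescing merges by mapped location", {
  set.seed(77)
  base <- random_cds(120)
  cand <- as_candidates(
    candidate_row("m1", wrap(base)),
    candidate_row("m2", wrap(mutate_cds(base, 0.1))),
    candidate_row("m3", wrap(mutate_cds(base, 0.7, nonsyn = 0.1))),
    candidate_row("m4", wrap(mutate_cds(base, 0.75, nonsyn = 0.1))))
  mh <- data.frame(
    transcript_id = c("m1", "m2", "m3", "m4"),
    scaffold = c("scf1", "scf1", "scf1", "scf2"),
    strand = "+",
    start = c(1000, 1500, 10000, 1000),
    end = c(2000, 2500, 12600, 2000),
    evalue = 1e-50, bitscore = 900, stringsAsFactors = FALSE)
  # overlapping -> merged; far on same scaffold -> separate; other
  # scaffold -> separate
  ls <- coalesce_genome_guided(cand, mh)
  expect_equal(length(ls$loci), 3L)

  # non-overlapping but within merge_gap -> merged
  mh2 <- mh
  mh2$start[2] <- 2300
  mh2$end[2] <- 2900   # gap of 300 <= 5000
  ls2 <- coalesce_genome_guided(cand, mh2)
  expect_equal(length(ls2$loci), 3L)

  # unmapped candidate falls back to de novo rules (m2 collapses with m1
  # by Ks even without a mapping hit)
  expect_message(
    ls3 <- coalesce_genome_guided(cand, mh[-2, ]),
    "falling back")
  expect_equal(length(ls3$loci), 4L)  # m2 alone in de novo fallback
  expect_equal(ls3$unmapped, "m2")
})

test_that("locus sets always satisfy partition and representative rules", {
  set.seed(888)
  for (rep in 1:5) {
    base <- random_cds(sample(100:200, 1))
    cand <- as_candidates(
      candidate_row("x1", wrap(base), component = "k1"),
      candidate_row("x2", wrap(mutate_cds(base, 0.1)), component = "k2"),
      candidate_row("x3", wrap(mutate_cds(base, 0.6, nonsyn = 0.1)),
                    component = "k3"))
    ls <- coalesce_denovo(cand)
    members <- unlist(lapply(ls$loci, `[[`, "members"))
    expect_setequal(members, cand$id)
    expect_equal(anyDuplicated(members), 0L)
    for (l in ls$loci) {
      lens <- nchar(cand$protein[match(l$members, cand$id)])
      expect_equal(nchar(cand$protein[cand$id == l$representative_id]),
                   max(lens))
    }
  }
})
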