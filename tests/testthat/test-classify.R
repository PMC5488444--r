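write_domain_tsv <- function(rows, path) {
  writeLines(c("# domain hits", rows), path)
  path
}

blast_line <- function(id, subject, evalue, bitscore, family, group) {
  paste(id, subject, 90, 300, 30, 0, 1, 300, 1, 300, evalue, bitscore,
        family, group, sep = "\t")
}

test_that("parse_domain_hits reads and validates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_domain_tsv(c("t1\tPF03024\t1e-10\t120.5",
                     "t2\tPF01490\t0.01\t20",
                     "t3\tPF99999\t1e-8\t55"), f)
  dh <- parse_domain_hits(f)
  expect_equal(nrow(dh), 3L)
  expect_type(dh$evalue, "double")

  writeLines("# only comments", f)
  expect_equal(nrow(parse_domain_hits(f)), 0L)

  writeLines("t1\tPF03024\tnot_a_number\t5", f)
  expect_error(parse_domain_hits(f), "non-numeric")
  writeLines("t1\tPF03024\t1e-5", f)
  expect_error(parse_domain_hits(f), "expected 4 fields")
})

test_that("parse_blast_hits keeps rows and demands annotations", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(blast_line("t1", "s1", 1e-20, 200, "APC", "hemiptera"),
               blast_line("t1", "s2", 1e-20, 180, "APC", "hemiptera")),
             f)
  bh <- parse_blast_hits(f)
  expect_equal(nrow(bh), 2L)
  expect_equal(bh$sseqid, c("s1", "s2"))  # tie rows kept in input order
  # missing annotation columns
  writeLines(paste("t1", "s1", 90, 300, 30, 0, 1, 300, 1, 300, 1e-20,
                   200, sep = "\t"), f)
  expect_error(parse_blast_hits(f), "expected 14 fields")
})

test_that("parse_mapping_hits derives strand from subject orientation", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("t1", "scf1", 99, 500, 0, 0, 1, 500, 1000, 1499,
                     1e-50, 900, sep = "\t"),
               paste("t2", "scf1", 99, 500, 0, 0, 1, 500, 2499, 2000,
                     1e-50, 900, sep = "\t")), f)
  mh <- parse_mapping_hits(f)
  expect_equal(mh$strand, c("+", "-"))
  expect_true(all(mh$start <= mh$end))
  expect_equal(mh$start, c(1000, 2000))
})

make_classify_fixture <- function() {
  cds <- random_cds(80, seed = 42)
  seqs <- vapply(1:6, function(i) paste0("GGGCCC", cds, "TAA"), "")
  transcripts <- data.frame(
    id = paste0("t", 1:6), taxon = "tx",
    component_id = paste0("c", 1:6), seq = seqs,
    stringsAsFactors = FALSE)
  dom <- withr::local_tempfile(fileext = ".tsv",
                               .local_envir = parent.frame())
  # t1 good APC; t2 weak domain evalue; t3 good AAAP; t4 good domain but
  # plant best hit; t5 hits both domains; t6 no domain hit at all
  write_domain_tsv(c("t1\tPF03024\t1e-5\t100",
                     "t2\tPF03024\t0.01\t30",
                     "t3\tPF01490\t1e-12\t200",
                     "t4\tPF03024\t1e-9\t90",
                     "t5\tPF03024\t1e-6\t80",
                     "t5\tPF01490\t1e-9\t120"), dom)
  bl <- withr::local_tempfile(fileext = ".tsv",
                              .local_envir = parent.frame())
  writeLines(c(
    blast_line("t1", "apc_ref", 1e-20, 300, "APC", "hemiptera"),
    blast_line("t2", "apc_ref", 1e-30, 300, "APC", "hemiptera"),
    blast_line("t3", "aaap_ref", 1e-40, 400, "AAAP", "hemiptera"),
    blast_line("t4", "plant_prot", 1e-30, 500, "APC", "plant"),
    blast_line("t4", "apc_ref", 1e-10, 200, "APC", "hemiptera"),
    blast_line("t5", "aaap_ref", 1e-25, 350, "AAAP", "hemiptera"),
    blast_line("t6", "apc_ref", 1e-50, 600, "APC", "hemiptera")), bl)
  list(transcripts = transcripts, dom = parse_domain_hits(dom),
       bl = parse_blast_hits(bl))
}

test_that("select_candidates applies domain, best-hit and ORF rules", {
  fx <- make_classify_fixture()
  cand <- select_candidates(fx$transcripts, fx$dom, fx$bl)
  expect_equal(cand$id, c("t1", "t3", "t5"))
  expect_equal(cand$family[cand$id == "t1"], "APC")
  expect_equal(cand$family[cand$id == "t3"], "AAAP")
  # t5 hit both domains; the lower evalue (AAAP) wins
  expect_equal(cand$family[cand$id == "t5"], "AAAP")
  expect_true(all(nchar(cand$protein) >= 50))
})

test_that("select_candidates is order-independent and idempotent", {
  fx <- make_classify_fixture()
  base <- select_candidates(fx$transcripts, fx$dom, fx$bl)
  set.seed(1)
  perm <- select_candidates(fx$transcripts[sample(6), ],
                            fx$dom[sample(nrow(fx$dom)), ],
                            fx$bl[sample(nrow(fx$bl)), ])
  expect_equal(perm, base)
})

test_that("unknown transcript ids are skipped with a warning", {
  fx <- make_classify_fixture()
  dom2 <- rbind(fx$dom,
                data.frame(transcript_id = "ghost",
                           domain_accession = "PF03024",
                           evalue = 1e-9, score = 10))
  expect_warning(cand <- select_candidates(fx$transcripts, dom2, fx$bl),
                 "ghost")
  expect_equal(cand$id, c("t1", "t3", "t5"))
  cfg <- classify_config(on_unknown_transcript = "error")
  expect_error(select_candidates(fx$transcripts, dom2, fx$bl, cfg),
               "ghost")
})

test_that("noise-free synthetic hit tables classify exactly the AAT set", {
  cfg <- sim_config(seed = 500, background_n = 5)
  tx <- simulate_transcriptome("sensT", c(APC = 3, AAAP = 2), cfg,
                               seed = 501)
  cand <- select_candidates(tx$transcripts, tx$domain_hits, tx$blast_hits)
  truth_aat <- sort(tx$truth$transcript_id[
    tx$truth$role %in% c("isoform", "fragment", "allele",
                         "paralog-representative")])
  expect_equal(sort(cand$id), truth_aat)   # 100% sensitivity+specificity
  expect_setequal(unique(cand$family), c("APC", "AAAP"))
})
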