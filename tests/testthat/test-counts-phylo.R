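fake_locus_set <- function(taxon, family, n) {
  loci <- lapply(seq_len(n), function(i)
    list(locus_id = sprintf("%s|%s|L%03d", taxon, family, i),
         representative_id = sprintf("%s_%s_r%d", taxon, family, i),
         members = sprintf("%s_%s_r%d", taxon, family, i)))
  out <- list(taxon = taxon, family = family, loci = loci,
              pair_log = NULL, mode = "denovo")
  class(out) <- "locus_set"
  out
}

test_that("build_counts tabulates loci and joins life history", {
  lh <- data.frame(taxon = c("dvit", "pque"),
                   life_history = c("galling", "free_living"))
  counts <- build_counts(list(fake_locus_set("dvit", "APC", 11),
                              fake_locus_set("dvit", "AAAP", 12),
                              fake_locus_set("pque", "APC", 19),
                              fake_locus_set("pque", "AAAP", 24)), lh)
  expect_equal(counts$apc, c(11, 19))
  expect_equal(counts$aaap, c(12, 24))
  expect_equal(counts$total, c(23, 43))
  # counting is family-agnostic: arbitrary labels get their own column
  counts2 <- build_counts(list(fake_locus_set("dvit", "APC", 2),
                               fake_locus_set("dvit", "SLC99", 4)), lh[1, ])
  expect_equal(counts2$slc99, 4)
  expect_equal(counts2$total, 6)
  expect_equal(counts2$aaap, 0)
  # missing label errors by name
  expect_error(build_counts(list(fake_locus_set("ghost", "APC", 1)), lh),
               "ghost")
})

test_that("summarize_groups reproduces published group averages", {
  fx <- published_counts()
  s <- summarize_groups(fx[fx$set == "ingroup", ])
  galling <- s[s$group == "galling", ]
  free <- s[s$group == "free_living", ]
  expect_equal(galling$apc, 10)
  expect_equal(galling$aaap, 14)
  expect_equal(galling$total, 24)
  expect_equal(free$apc, 17)
  expect_equal(free$aaap, 21)
  expect_equal(free$total, 38)
  expect_equal(galling$n_taxa, 12)   # inquiline folded into galling
  # single-taxon group: mean is the value
  one <- summarize_groups(fx[fx$taxon %in% c("Phylloxera_quercus",
                                             "Phylloxera_foveola"), ])
  expect_equal(one[one$group == "free_living", "apc"], 19)
  expect_error(summarize_groups(fx[fx$life_history == "galling", ]),
               "no taxa")
})

test_that("read_newick parses, defaults and validates", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1);", f)
  expect_equal(length(read_newick(f)$tip.label), 2L)
  writeLines("((A:1,B:1):1,C:2);", f)
  tr <- read_newick(f)
  expect_equal(length(tr$tip.label), 3L)
  writeLines("(A,B);", f)
  expect_warning(tr2 <- read_newick(f), "branch lengths")
  expect_equal(tr2$edge.length, rep(1, nrow(tr2$edge)))
  writeLines("((A:1,B:1:2;", f)
  expect_error(suppressWarnings(read_newick(f)))
})

test_that("brownian_vcv matches path summation and ape::vcv", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- brownian_vcv(tr, c("A", "B", "C"))
  expect_equal(unname(C),
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3))
  expect_error(brownian_vcv(tr, c("A", "Z")), "Z")
  # star tree
  Cs <- brownian_vcv(ape::read.tree(text = "(A:1,B:1);"))
  expect_equal(unname(Cs), diag(2))
  # random trees against the reference implementation
  for (seed in 1:10) {
    rt <- simulate_tree(sample(5:25, 1), 1, seed)
    Cm <- brownian_vcv(rt)
    Ca <- ape::vcv(rt)[rownames(Cm), colnames(Cm)]
    expect_equal(Cm, Ca, tolerance = 1e-12)
    # linearity in branch lengths
    rt2 <- rt
    rt2$edge.length <- rt$edge.length * 3.5
    expect_equal(brownian_vcv(rt2), 3.5 * Cm, tolerance = 1e-12)
  }
})

test_that("pgls_fit equals OLS ANOVA when C is the identity", {
  y <- c(1, 2, 3, 11, 12, 13)
  x <- c(0, 0, 0, 1, 1, 1)
  fit <- pgls_fit(y, x, diag(6))
  expect_equal(fit$F, 150, tolerance = 1e-12)
  expect_equal(fit$df, c(1, 4))
  set.seed(2024)
  for (rep in 1:100) {
    n <- sample(6:30, 1)
    x <- factor(sample(c("g", "f"), n, replace = TRUE))
    if (length(unique(x)) < 2) next
    y <- rnorm(n) + 3 * (x == "f")
    fit <- pgls_fit(y, x, diag(n))
    an <- anova(lm(y ~ x))
    expect_equal(fit$F, an$`F value`[1], tolerance = 1e-9)
    expect_equal(fit$p.value, an$`Pr(>F)`[1], tolerance = 1e-9)
    expect_equal(unname(fit$beta), unname(coef(lm(y ~ x))),
                 tolerance = 1e-9)
  }
})

test_that("pgls_fit edge cases behave", {
  C <- brownian_vcv(simulate_tree(8, 1, 3))
  y <- rnorm(8) + 2
  x <- rep(c(0, 1), 4)
  fit <- pgls_fit(y, x, C)
  # scale invariance of F
  fit_k <- pgls_fit(y, x, 7.3 * C)
  expect_equal(fit$F, fit_k$F, tolerance = 1e-9)
  expect_equal(fit_k$sigma2 * 7.3, fit$sigma2, tolerance = 1e-6)
  # constant response
  fit0 <- pgls_fit(rep(5, 8), x, C)
  expect_equal(fit0$F, 0)
  expect_equal(fit0$p.value, 1)
  # single-level predictor is singular
  expect_error(pgls_fit(y, rep(1, 8), C), "singular")
  # named response is aligned to C's rownames
  names(y) <- rownames(C)
  yr <- y[rev(names(y))]
  fit_r <- pgls_fit(yr, x[match(names(yr), names(y))], C)
  expect_equal(fit_r$F, fit$F, tolerance = 1e-9)
})

test_that("pgls_fit recovers a simulated life-history effect", {
  tree <- simulate_tree(16, 1, 42)
  C <- brownian_vcv(tree)
  L <- t(chol(C))
  set.seed(4242)
  x <- rep(c(0, 1), 8)
  est <- replicate(200, {
    y <- 10 + as.numeric(L %*% rnorm(16)) + 10 * x
    unname(pgls_fit(y, x, C)$beta[2])
  })
  expect_equal(mean(est), 10, tolerance = 0.05)  # within 5%
})
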