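#' Build the taxon-by-family locus counts table
#'
#' @param locus_sets list of `locus_set` objects (any mix of taxa and
#'   families).
#' @param life_history data frame with columns `taxon` and `life_history`
#'   (levels such as `galling`, `free_living`, `inquiline`); every counted
#'   taxon must have a label.
#' @return data frame with one row per taxon: a lower-case column per
#'   family (`apc` and `aaap` always present), `total`, `life_history`.
#' @export
build_counts <- function(locus_sets, life_history) {
  if (inherits(locus_sets, "locus_set")) locus_sets <- list(locus_sets)
  stopifnot(all(c("taxon", "life_history") %in% names(life_history)))
  taxa <- sort(unique(c(vapply(locus_sets, `[[`, "", "taxon"))))
  fams <- unique(c("APC", "AAAP",
                   vapply(locus_sets, `[[`, "", "family")))
  counts <- matrix(0L, length(taxa), length(fams),
                   dimnames = list(taxa, fams))
  for (ls in locus_sets)
    counts[ls$taxon, ls$family] <- counts[ls$taxon, ls$family] +
      length(ls$loci)
  missing <- setdiff(taxa, life_history$taxon)
  if (length(missing) > 0L)
    stop("no life-history label for taxon/taxa: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- data.frame(taxon = taxa, stringsAsFactors = FALSE)
  for (f in fams) out[[tolower(f)]] <- unname(counts[, f])
  out$total <- as.integer(rowSums(counts))
  out$life_history <-
    life_history$life_history[match(taxa, life_history$taxon)]
  rownames(out) <- NULL
  out
}

#' Summarise locus counts by life-history group
#'
#' Arithmetic group means per family, truncated toward zero; the group
#' total is the sum of the truncated family means (the convention needed to
#' reproduce published per-group averages computed on integer-truncated
#' columns).
#'
#' @param counts data frame from [build_counts()] (or the packaged
#'   published-counts fixture).
#' @param group_map named character vector mapping `life_history` levels to
#'   summary groups; the default folds the inquiline in with the gallers.
#' @param families family columns to summarise.
#' @return data frame with one row per group: truncated mean per family,
#'   `total`, `n_taxa`.
#' @export
summarize_groups <- function(counts,
                             group_map = c(galling = "galling",
                                           inquiline = "galling",
                                           free_living = "free_living"),
                             families = c("apc", "aaap")) {
  stopifnot(all(families %in% names(counts)))
  unknown <- setdiff(unique(counts$life_history), names(group_map))
  if (length(unknown) > 0L)
    stop("life-history level(s) not in group_map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  grp <- unname(group_map[counts$life_history])
  out <- list()
  for (g in unique(unname(group_map))) {
    sel <- which(grp == g)
    if (length(sel) == 0L)
      stop("group '", g, "' has no taxa", call. = FALSE)
    row <- data.frame(group = g, stringsAsFactors = FALSE)
    for (f in families)
      row[[f]] <- trunc(mean(counts[[f]][sel]))
    row$total <- sum(unlist(row[families]))
    row$n_taxa <- length(sel)
    out[[length(out) + 1L]] <- row
  }
  do.call(rbind, out)
}

#' Read a phylogenetic tree from a Newick file
#'
#' @param path Newick file.
#' @param default_branch_length used (with a warning) when the tree has no
#'   branch lengths; zero-length branches and polytomies are allowed.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path, default_branch_length = 1) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("cannot parse Newick file ",
                                            path, ": ", conditionMessage(e),
                                            call. = FALSE))
  if (is.null(tree))
    stop("cannot parse Newick file ", path, call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels in ", path, call. = FALSE)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; using ", default_branch_length,
            " for every edge", call. = FALSE)
    tree$edge.length <- rep(default_branch_length, nrow(tree$edge))
  }
  if (any(tree$edge.length < 0))
    stop("negative branch length in ", path, call. = FALSE)
  tree
}

#' Brownian-motion covariance matrix implied by a tree
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips `i` and `j`
#' (`C[i, i]` is the root-to-tip distance), the covariance structure of a
#' Brownian trait with unit rate.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param taxa_order tip labels giving row/column order; default the tree's
#'   tip order.
#' @return symmetric positive semidefinite matrix with dimnames.
#' @export
brownian_vcv <- function(tree, taxa_order = tree$tip.label) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  missing <- setdiff(taxa_order, tree$tip.label)
  if (length(missing) > 0L)
    stop("taxa not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  parent <- integer(nnode)
  plen <- numeric(nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  plen[tree$edge[, 2]] <- tree$edge.length
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]

  path_to_root <- function(node) {
    path <- node
    while (node != root) {
      node <- parent[node]
      path <- c(path, node)
    }
    rev(path)  # root first
  }
  depth <- numeric(nnode)
  depth[root] <- 0
  # node depths via edge list (edges reference parents defined earlier or
  # later; iterate until settled)
  done <- rep(FALSE, nnode)
  done[root] <- TRUE
  edges <- tree$edge
  while (!all(done[edges[, 2]])) {
    progressed <- FALSE
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]
      if (done[a] && !done[b]) {
        depth[b] <- depth[a] + tree$edge.length[e]
        done[b] <- TRUE
        progressed <- TRUE
      }
    }
    if (!progressed) stop("malformed tree edge matrix", call. = FALSE)
  }
  tips <- match(taxa_order, tree$tip.label)
  paths <- lapply(tips, path_to_root)
  n <- length(tips)
  C <- matrix(0, n, n, dimnames = list(taxa_order, taxa_order))
  for (i in seq_len(n)) {
    C[i, i] <- depth[tips[i]]
    if (i < n) {
      for (j in (i + 1L):n) {
        pi_ <- paths[[i]]; pj <- paths[[j]]
        m <- min(length(pi_), length(pj))
        shared <- pi_[seq_len(m)] == pj[seq_len(m)]
        mrca <- pi_[max(which(shared))]
        C[i, j] <- C[j, i] <- depth[mrca]
      }
    }
  }
  C
}

#' Phylogenetic generalized least squares under a Brownian covariance
#'
#' Fits `y ~ x` by GLS with error covariance proportional to `C`, via a
#' Cholesky whitening transform, and tests the `x` term with a nested-model
#' F test: `F = ((RSS0 - RSS1)/q) / (RSS1/(n - p))` where RSS0/RSS1 are the
#' intercept-only and full-model residual sums of squares in whitened
#' space.  With `C` the identity this is ordinary one-way ANOVA.
#'
#' @param y numeric response (e.g. per-taxon locus counts), named or in the
#'   order of `C`'s rows.
#' @param x life-history predictor: a factor, character, or 0/1 indicator.
#' @param C Brownian covariance matrix from [brownian_vcv()].
#' @param ridge added to the diagonal (times `mean(diag(C))`) when `C` is
#'   not positive definite; applied automatically with a warning.
#' @return object of class `pgls_fit`: `beta`, `sigma2`, `F`, `df`
#'   (numerator, denominator), `p.value`, `n`, `RSS0`, `RSS1`.
#' @examples
#' C <- diag(6)
#' pgls_fit(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1), C)  # F = 150
#' @export
pgls_fit <- function(y, x, C, ridge = 1e-8) {
  n <- length(y)
  stopifnot(n >= 3, nrow(C) == n, ncol(C) == n)
  if (!is.null(names(y)) && !is.null(rownames(C))) {
    if (!setequal(names(y), rownames(C)))
      stop("names of y do not match rownames of C", call. = FALSE)
    x <- x[match(rownames(C), names(y))]
    y <- y[rownames(C)]
  }
  if (is.character(x)) x <- factor(x)
  X <- stats::model.matrix(~x)
  p <- ncol(X)
  q <- p - 1L
  if (q < 1L || qr(X)$rank < p)
    stop("singular design: 'x' must take at least two values",
         call. = FALSE)
  L <- tryCatch(t(chol(C)), error = function(e) {
    warning("C is not positive definite; adding ridge ", ridge,
            " * mean(diag(C))", call. = FALSE)
    t(chol(C + diag(ridge * mean(diag(C)), n)))
  })
  yw <- forwardsolve(L, y)
  Xw <- forwardsolve(L, X)
  fit1 <- stats::lm.fit(Xw, yw)
  RSS1 <- sum(fit1$residuals^2)
  fit0 <- stats::lm.fit(forwardsolve(L, matrix(1, n, 1)), yw)
  RSS0 <- sum(fit0$residuals^2)
  df2 <- n - p
  eps <- 1e-12 * max(1, RSS0)
  if (RSS0 - RSS1 <= eps && RSS1 <= eps) {
    Fstat <- 0
    pval <- 1
  } else {
    Fstat <- ((RSS0 - RSS1) / q) / (RSS1 / df2)
    pval <- stats::pf(Fstat, q, df2, lower.tail = FALSE)
  }
  out <- list(beta = stats::setNames(fit1$coefficients, colnames(X)),
              sigma2 = RSS1 / df2, F = Fstat, df = c(q, df2),
              p.value = pval, n = n, RSS0 = RSS0, RSS1 = RSS1)
  class(out) <- "pgls_fit"
  out
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit (Brownian correlation)\n")
  cat("  coefficients:\n")
  for (nm in names(x$beta))
    cat(sprintf("    %-20s % .4f\n", nm, x$beta[nm]))
  cat(sprintf("  sigma2 = %.4f\n", x$sigma2))
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p.value))
  invisible(x)
}
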