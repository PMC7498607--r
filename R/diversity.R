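## allele frequencies at one locus from the genotype calls of a set of
## individuals (default all); counts both alleles of each non-missing call
.freqs_at <- function(gt, locus, individuals = NULL) {
  j <- match(locus, gt$loci)
  if (is.na(j)) stop("unknown locus: ", locus)
  i <- if (is.null(individuals)) seq_along(gt$individuals)
       else match(individuals, gt$individuals)
  al <- c(gt$a1[i, j], gt$a2[i, j])
  al <- al[!is.na(al)]
  if (!length(al)) return(numeric(0))
  tab <- table(al)
  p <- as.numeric(tab) / sum(tab)
  names(p) <- names(tab)
  p
}

#' Per-group allele frequencies
#'
#' @param gt A `genotype_table`.
#' @param locus Locus id.
#' @param groups Optional named character vector mapping individual to
#'   group; when `NULL` a single pooled group is used.
#' @return Named list of frequency vectors (allele size -> frequency).
#' @export
allele_freqs <- function(gt, locus, groups = NULL) {
  if (is.null(groups)) return(list(all = .freqs_at(gt, locus)))
  stopifnot(all(gt$individuals %in% names(groups)))
  gs <- sort(unique(unname(groups[gt$individuals])), method = "radix")
  out <- lapply(gs, function(g) {
    .freqs_at(gt, locus, gt$individuals[groups[gt$individuals] == g])
  })
  names(out) <- gs
  out
}

#' Per-locus diversity statistics
#'
#' Computes allele frequencies and, from them, expected heterozygosity
#' (gene diversity) `He = 1 - sum(p_i^2)` (no small-sample correction, the
#' gene-diversity convention of marker-assay software), observed
#' heterozygosity `Ho` (fraction of non-missing individuals carrying two
#' distinct alleles), polymorphism information content
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2` (Botstein formulation),
#' and the fixation index `F = 1 - Ho/He` (`NA` when `He == 0`).
#'
#' @param gt A `genotype_table`.
#' @param locus Locus id.
#' @return A list of class `locus_stats`: `locus_id`, `allele_freqs`,
#'   `n_alleles`, `n_typed`, `He`, `Ho`, `PIC`, `F`.
#' @export
locus_stats <- function(gt, locus) {
  j <- match(locus, gt$loci)
  if (is.na(j)) stop("unknown locus: ", locus)
  ok <- !is.na(gt$a1[, j])
  if (!any(ok)) stop("locus has no non-missing calls: ", locus)
  p <- .freqs_at(gt, locus)
  s2 <- sum(p^2)
  s4 <- sum(p^4)
  he <- 1 - s2
  ho <- mean(gt$a1[ok, j] != gt$a2[ok, j])
  pic <- 1 - s2 - (s2^2 - s4) / 1  # sum_{i<j} 2 p_i^2 p_j^2 = ((sum p^2)^2 - sum p^4)
  structure(list(locus_id = locus, allele_freqs = p, n_alleles = length(p),
                 n_typed = sum(ok), He = he, Ho = ho, PIC = pic,
                 F = if (he > 0) 1 - ho / he else NA_real_),
            class = "locus_stats")
}

#' Diversity statistics for every locus
#'
#' @param gt A `genotype_table`.
#' @return Data frame with one row per locus: `locus_id`, `n_alleles`,
#'   `n_typed`, `He`, `Ho`, `PIC`, `F`.
#' @export
diversity_stats <- function(gt) {
  rows <- lapply(gt$loci, function(l) {
    s <- locus_stats(gt, l)
    data.frame(locus_id = s$locus_id, n_alleles = s$n_alleles,
               n_typed = s$n_typed, He = s$He, Ho = s$Ho, PIC = s$PIC,
               F = s$F, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Nei (1972) standard genetic distance between groups
#'
#' `D = -ln( Jxy / sqrt(Jx Jy) )` with `Jxy`, `Jx`, `Jy` the means over
#' loci of the cross- and within-group sums of squared (products of) allele
#' frequencies. Disjoint allele sets give `Inf`.
#'
#' @param gt A `genotype_table`.
#' @param groups Named character vector mapping individual to group.
#' @return Symmetric matrix of pairwise distances with zero diagonal.
#' @export
nei_distance <- function(gt, groups) {
  gs <- sort(unique(unname(groups[gt$individuals])), method = "radix")
  stopifnot(length(gs) >= 2L)
  freqs <- lapply(gt$loci, function(l) allele_freqs(gt, l, groups))
  D <- matrix(0, length(gs), length(gs), dimnames = list(gs, gs))
  for (i in seq_along(gs)) {
    for (j in seq_along(gs)) {
      if (j <= i) next
      jx <- jy <- jxy <- numeric(length(gt$loci))
      for (l in seq_along(gt$loci)) {
        px <- freqs[[l]][[gs[i]]]
        py <- freqs[[l]][[gs[j]]]
        alleles <- union(names(px), names(py))
        vx <- ifelse(alleles %in% names(px), px[alleles], 0)
        vy <- ifelse(alleles %in% names(py), py[alleles], 0)
        jx[l] <- sum(vx^2)
        jy[l] <- sum(vy^2)
        jxy[l] <- sum(vx * vy)
      }
      num <- mean(jxy)
      d <- if (num == 0) Inf else -log(num / sqrt(mean(jx) * mean(jy)))
      ## guard tiny negative values from floating-point noise
      if (is.finite(d) && d < 0 && d > -1e-12) d <- 0
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Multi-locus G_ST among groups
#'
#' `G_ST = (H_T - H_S) / H_T` where `H_S` is the mean within-group expected
#' heterozygosity and `H_T` the total expected heterozygosity from the
#' pooled (unweighted mean over groups) allele frequencies, each averaged
#' over loci.
#'
#' @param gt A `genotype_table`.
#' @param groups Named character vector mapping individual to group.
#' @return G_ST in `[0, 1]`, or `NA` when `H_T == 0`.
#' @export
gst <- function(gt, groups) {
  gs <- sort(unique(unname(groups[gt$individuals])), method = "radix")
  stopifnot(length(gs) >= 2L)
  hs <- ht <- numeric(length(gt$loci))
  for (l in seq_along(gt$loci)) {
    fr <- allele_freqs(gt, gt$loci[l], groups)
    hs[l] <- mean(vapply(fr, function(p) 1 - sum(p^2), numeric(1)))
    alleles <- sort(unique(unlist(lapply(fr, names))), method = "radix")
    pools <- vapply(fr, function(p) {
      ifelse(alleles %in% names(p), p[alleles], 0)
    }, numeric(length(alleles)))
    pbar <- rowMeans(matrix(pools, nrow = length(alleles)))
    ht[l] <- 1 - sum(pbar^2)
  }
  if (mean(ht) == 0) return(NA_real_)
  (mean(ht) - mean(hs)) / mean(ht)
}

#' Shared-allele dissimilarity between individuals
#'
#' `1 -` the proportion of shared alleles per locus (0, 0.5 or 1 for
#' diploid calls, counting multiplicity), averaged over loci where both
#' individuals are typed. The standard individual-level input for
#' distance-based tree building from microsatellite assays.
#'
#' @param gt A `genotype_table`.
#' @param loci Optional subset/resample of locus ids (with repetition
#'   allowed, for bootstrapping).
#' @return Symmetric dissimilarity matrix over individuals.
#' @export
shared_allele_dist <- function(gt, loci = NULL) {
  if (is.null(loci)) loci <- gt$loci
  jj <- match(loci, gt$loci)
  stopifnot(!anyNA(jj))
  n <- length(gt$individuals)
  D <- matrix(0, n, n, dimnames = list(gt$individuals, gt$individuals))
  a1 <- gt$a1[, jj, drop = FALSE]
  a2 <- gt$a2[, jj, drop = FALSE]
  for (i in seq_len(n - 1L)) {
    for (k in (i + 1L):n) {
      both <- !is.na(a1[i, ]) & !is.na(a1[k, ])
      if (!any(both)) {
        D[i, k] <- D[k, i] <- 1
        next
      }
      ## multiset intersection of two sorted diploid calls: the better of
      ## the two possible allele matchings
      sh <- pmax((a1[i, both] == a1[k, both]) + (a2[i, both] == a2[k, both]),
                 (a1[i, both] == a2[k, both]) + (a2[i, both] == a1[k, both]))
      D[i, k] <- D[k, i] <- 1 - mean(sh / 2)
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Q criterion. Branch lengths come from
#' the standard two-point formulas; a negative branch length is clamped to
#' zero with the deficit moved to its sister edge, preserving the pair sum.
#' Ties in Q are broken deterministically by the lexicographically smallest
#' label pair.
#'
#' @param D Symmetric distance matrix with labels, zero diagonal, `n >= 3`.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  if (!isSymmetric(unname(D), tol = 1e-8)) {
    stop("distance matrix is not symmetric")
  }
  n <- nrow(D)
  stopifnot(n >= 3L)
  labels <- rownames(D)
  frag <- labels                       # newick fragment per active node
  key <- labels                        # tie-break key per active node
  fmt <- function(x) sprintf("%.10g", x)
  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_key <- vapply(seq_len(nrow(cand)), function(z) {
      paste(sort(c(key[cand[z, 1]], key[cand[z, 2]])), collapse = "\r")
    }, character(1))
    z <- .ord(pair_key)[1L]
    i <- cand[z, 1L]
    j <- cand[z, 2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newfrag <- paste0("(", frag[i], ":", fmt(li), ",", frag[j], ":",
                      fmt(lj), ")")
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    frag <- c(frag[keep], newfrag)
    key <- c(key[keep], min(key[i], key[j]))
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], "internal")
    D <- D2
    n <- n - 1L
  }
  ## final three-point resolution
  lx <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  ly <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lz <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ls <- c(lx, ly, lz)
  neg <- ls < 0
  if (any(neg)) {
    ## move each deficit onto the other two edges equally
    deficit <- sum(ls[neg])
    ls[neg] <- 0
    ls[!neg] <- pmax(0, ls[!neg] + deficit / max(1, sum(!neg)))
  }
  nwk <- paste0("(", frag[1], ":", fmt(ls[1]), ",", frag[2], ":",
                fmt(ls[2]), ",", frag[3], ":", fmt(ls[3]), ");")
  ape::read.tree(text = nwk)
}

## tip-label bipartition of each internal edge of an unrooted tree,
## canonicalised so the side not containing the reference tip is kept
.bipartitions <- function(tree) {
  ref <- sort(tree$tip.label, method = "radix")[1L]
  ntip <- length(tree$tip.label)
  inner <- setdiff(unique(tree$edge[, 1L]), NA)
  parts <- character(0)
  nodes <- integer(0)
  for (node in inner) {
    tips <- tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1L]]]
    if (length(tips) <= 1L || length(tips) >= ntip - 1L) {
      side <- NA_character_
    } else {
      if (ref %in% tips) tips <- setdiff(tree$tip.label, tips)
      side <- paste(sort(tips, method = "radix"), collapse = "|")
    }
    parts <- c(parts, side)
    nodes <- c(nodes, node)
  }
  names(parts) <- nodes
  parts
}

#' Bootstrap support of a given tip bipartition
#'
#' @param tree A tree from [bootstrap_nj()] (node labels hold support
#'   percentages).
#' @param tips Character vector: the tip set on one side of the bipartition.
#' @return Support percentage, or `NA` when the bipartition is not an
#'   internal edge of the tree.
#' @export
bipartition_support <- function(tree, tips) {
  ref <- sort(tree$tip.label, method = "radix")[1L]
  if (ref %in% tips) tips <- setdiff(tree$tip.label, tips)
  want <- paste(sort(tips, method = "radix"), collapse = "|")
  parts <- .bipartitions(tree)
  node <- names(parts)[!is.na(parts) & parts == want]
  if (!length(node)) return(NA_real_)
  as.numeric(tree$node.label[as.integer(node[1L]) -
                               length(tree$tip.label)])
}

#' Bootstrap neighbor-joining tree from a genotype table
#'
#' Builds the full-data tree from the shared-allele dissimilarity between
#' individuals, then resamples loci with replacement `reps` times,
#' rebuilding the tree each time; the support of each internal bipartition
#' of the full-data tree is the percentage of replicates containing it,
#' stored in the tree's node labels.
#'
#' @param gt A `genotype_table` with at least 2 loci.
#' @param reps Number of bootstrap replicates (>= 1).
#' @param seed Optional RNG seed for reproducible resampling.
#' @return An [ape::phylo] tree with `node.label` holding bootstrap support
#'   percentages (empty for trivial bipartitions).
#' @export
bootstrap_nj <- function(gt, reps = 200L, seed = NULL) {
  stopifnot(length(gt$loci) >= 2L)
  if (reps < 1L) stop("reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  full <- nj_tree(shared_allele_dist(gt))
  target <- .bipartitions(full)
  counts <- setNames(numeric(length(target)), names(target))
  for (b in seq_len(reps)) {
    loci_b <- sample(gt$loci, length(gt$loci), replace = TRUE)
    tb <- nj_tree(shared_allele_dist(gt, loci_b))
    seen <- .bipartitions(tb)
    counts <- counts + as.numeric(!is.na(target) & target %in%
                                    seen[!is.na(seen)])
  }
  support <- 100 * counts / reps
  lab <- ifelse(is.na(target), "", sprintf("%g", support))
  ## node labels indexed from the root node (ntip + 1)
  ntip <- length(full$tip.label)
  full$node.label <- rep("", full$Nnode)
  full$node.label[as.integer(names(target)) - ntip] <- lab
  full
}
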